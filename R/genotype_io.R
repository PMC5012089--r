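#' @title Genotype data containers and delimited-text IO
#'
#' @description
#' A `geno_set` bundles the four tables every analysis consumes:
#' individuals (id, site, biotype, ploidy, mitochondrial haplotype), a long
#' allele table (id, locus, haplome, allele as an integer repeat count), a
#' locus panel and a site table. Alleles are repeat counts, not fragment
#' sizes, so stepwise-mutation distances are exact integer step counts.
#'
#' @name genotype_io
NULL

GENOME_CLASSES <- c("host_specific", "dual_distinguishable", "dual_overlapping")
BIOTYPES <- c("host", "maternal", "hybrid")
HAPLOMES <- c("host", "maternal", "un")

#' Build and validate a locus panel
#'
#' @param name locus names (unique).
#' @param genome_class one of `host_specific` (amplifies only the host
#'   genome), `dual_distinguishable` (amplifies both genomes, parental
#'   alleles distinguishable) or `dual_overlapping` (amplifies both, allele
#'   ranges overlap; excluded from any haplome-resolved computation).
#' @param motif_length repeat-unit length in bp (>= 1).
#' @param marker_type `"microsat"` or `"indel"`; only microsatellites enter
#'   stepwise-mutation distances.
#' @return a `data.frame` locus panel.
#' @export
locus_panel <- function(name, genome_class, motif_length,
                        marker_type = "microsat") {
  loci <- data.frame(name = as.character(name),
                     genome_class = as.character(genome_class),
                     motif_length = as.integer(motif_length),
                     marker_type = rep_len(as.character(marker_type),
                                           length(name)))
  if (anyDuplicated(loci$name)) stop("locus names must be unique")
  if (!all(loci$genome_class %in% GENOME_CLASSES))
    stop("unknown genome_class; expected one of: ",
         paste(GENOME_CLASSES, collapse = ", "))
  if (any(loci$motif_length < 1)) stop("motif_length must be >= 1")
  if (!all(loci$marker_type %in% c("microsat", "indel")))
    stop("marker_type must be 'microsat' or 'indel'")
  loci
}

#' Expected allele copy numbers per haplome
#'
#' Copy-number table implied by the reproductive system: sexual host
#' individuals are diploid at every locus; diploid hybrids carry one host
#' haplome (hemizygous at host-specific loci) plus one maternal haplome at
#' dual loci; triploid hybrids carry one extra host haplome acquired from
#' the fertilizing sperm; the maternal species does not amplify at
#' host-specific loci.
#'
#' @param biotype,ploidy,genome_class scalars.
#' @return named integer vector `c(host=, maternal=, un=)`.
#' @export
expected_allele_counts <- function(biotype, ploidy, genome_class) {
  key <- paste(biotype, ploidy, genome_class, sep = "|")
  tab <- list(
    "host|2|host_specific"          = c(2L, 0L, 0L),
    "host|2|dual_distinguishable"   = c(2L, 0L, 0L),
    "host|2|dual_overlapping"       = c(2L, 0L, 0L),
    "maternal|2|host_specific"      = c(0L, 0L, 0L),
    "maternal|2|dual_distinguishable" = c(0L, 2L, 0L),
    "maternal|2|dual_overlapping"   = c(0L, 2L, 0L),
    "hybrid|2|host_specific"        = c(1L, 0L, 0L),
    "hybrid|2|dual_distinguishable" = c(1L, 1L, 0L),
    "hybrid|2|dual_overlapping"     = c(0L, 0L, 2L),
    "hybrid|3|host_specific"        = c(2L, 0L, 0L),
    "hybrid|3|dual_distinguishable" = c(2L, 1L, 0L),
    "hybrid|3|dual_overlapping"     = c(0L, 0L, 3L)
  )
  out <- tab[[key]]
  if (is.null(out)) stop("no copy-number rule for ", key)
  names(out) <- HAPLOMES
  out
}

#' Assemble a validated genotype dataset
#'
#' @param individuals data.frame with columns id, site, biotype, ploidy,
#'   mito (mito may be NA for sexual individuals).
#' @param alleles long data.frame with columns id, locus, haplome, allele.
#'   A locus absent for an individual is treated as missing data and is
#'   excluded pairwise from every statistic.
#' @param loci a [locus_panel()].
#' @param sites data.frame with columns id, region, x, y (projected
#'   coordinates in km).
#' @return object of class `geno_set`.
#' @export
geno_set <- function(individuals, alleles, loci, sites) {
  individuals <- as.data.frame(individuals)
  alleles <- as.data.frame(alleles)
  sites <- as.data.frame(sites)
  stopifnot(all(c("id", "site", "biotype", "ploidy", "mito") %in%
                  names(individuals)),
            all(c("id", "locus", "haplome", "allele") %in% names(alleles)),
            all(c("id", "region", "x", "y") %in% names(sites)))
  if (anyDuplicated(individuals$id))
    stop("duplicate individual id: ",
         paste(unique(individuals$id[duplicated(individuals$id)]),
               collapse = ", "))
  if (anyDuplicated(sites$id)) stop("duplicate site id")
  if (!all(is.finite(sites$x)) || !all(is.finite(sites$y)))
    stop("site coordinates must be finite")
  if (!all(individuals$biotype %in% BIOTYPES)) stop("unknown biotype")
  if (!all(alleles$locus %in% loci$name))
    stop("unknown locus name: ",
         paste(setdiff(unique(alleles$locus), loci$name), collapse = ", "))
  if (!all(alleles$haplome %in% HAPLOMES)) stop("unknown haplome label")
  if (any(alleles$allele < 1, na.rm = TRUE))
    stop("allele repeat counts must be >= 1")
  structure(list(individuals = individuals, alleles = alleles,
                 loci = loci, sites = sites),
            class = "geno_set")
}

#' @export
print.geno_set <- function(x, ...) {
  cat("geno_set:", nrow(x$individuals), "individuals |",
      nrow(x$loci), "loci |", nrow(x$sites), "sites\n")
  cat("  biotypes:",
      paste(names(table(x$individuals$biotype)),
            table(x$individuals$biotype), collapse = ", "), "\n")
  invisible(x)
}

# number of allele columns a locus needs in the wide layout
locus_width <- function(genome_class) {
  ifelse(genome_class == "host_specific", 2L, 3L)
}

#' Validate individual rows against the copy-number table
#'
#' @param individuals,alleles,loci as in [geno_set()].
#' @return data.frame of violations (id, locus, message); zero rows if all
#'   rows are valid. A locus with no alleles at all is missing data, not a
#'   violation; a partially or over-filled locus is rejected.
#' @export
validate_copy_numbers <- function(individuals, alleles, loci) {
  bad <- list()
  al_by_id <- split(alleles, alleles$id)
  for (i in seq_len(nrow(individuals))) {
    ind <- individuals[i, ]
    if (ind$biotype == "host" && ind$ploidy != 2) {
      bad[[length(bad) + 1L]] <- data.frame(
        id = ind$id, locus = NA_character_,
        message = "host biotype must be diploid")
      next
    }
    if (ind$ploidy == 3 && ind$biotype != "hybrid") {
      bad[[length(bad) + 1L]] <- data.frame(
        id = ind$id, locus = NA_character_,
        message = "triploidy allowed only for hybrids")
      next
    }
    al <- al_by_id[[as.character(ind$id)]]
    for (l in seq_len(nrow(loci))) {
      loc <- loci[l, ]
      exp_n <- expected_allele_counts(ind$biotype, ind$ploidy,
                                      loc$genome_class)
      a <- al[!is.null(al) & al$locus == loc$name, , drop = FALSE]
      if (is.null(al) || nrow(a) == 0) next   # missing locus: allowed
      obs <- table(factor(a$haplome, levels = HAPLOMES))
      if (!all(obs == exp_n)) {
        bad[[length(bad) + 1L]] <- data.frame(
          id = ind$id, locus = loc$name,
          message = sprintf(
            "allele count inconsistent with %s ploidy %d (expected %s, got %s)",
            ind$biotype, ind$ploidy,
            paste(exp_n, collapse = "/"), paste(as.integer(obs), collapse = "/")))
      }
    }
  }
  if (length(bad) == 0)
    return(data.frame(id = character(), locus = character(),
                      message = character()))
  do.call(rbind, bad)
}

#' Read a genotype dataset from delimited text files
#'
#' Genotype files are wide CSVs: one row per individual with columns
#' `id,site,biotype,ploidy,mito` followed by allele columns named
#' `<locus>.<copy_index>`. Within a locus, host-haplome alleles come first,
#' then the maternal allele, then unlabelled alleles (dual-overlapping
#' loci); within a haplome block the order is irrelevant. An all-empty
#' locus is missing data. Rows violating the copy-number table are rejected
#' with row-level diagnostics (attribute `"rejected"`, plus a warning).
#'
#' @param genotype_file,locus_file,site_file paths to CSV files.
#' @return a [geno_set()]; rejected rows in `attr(, "rejected")`.
#' @export
read_dataset <- function(genotype_file, locus_file, site_file) {
  loci <- utils::read.csv(locus_file, stringsAsFactors = FALSE)
  loci <- locus_panel(loci$name, loci$genome_class, loci$motif_length,
                      loci$marker_type)
  sites <- utils::read.csv(site_file, stringsAsFactors = FALSE)
  geno <- utils::read.csv(genotype_file, stringsAsFactors = FALSE)
  meta_cols <- c("id", "site", "biotype", "ploidy", "mito")
  stopifnot(all(meta_cols %in% names(geno)))
  allele_cols <- setdiff(names(geno), meta_cols)
  col_locus <- sub("\\.[0-9]+$", "", allele_cols)
  unknown <- setdiff(unique(col_locus), loci$name)
  if (length(unknown))
    stop("unknown locus name in genotype columns: ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(geno$id))
    stop("duplicate individual id: ",
         paste(unique(geno$id[duplicated(geno$id)]), collapse = ", "))

  individuals <- geno[meta_cols]
  names(individuals) <- c("id", "site", "biotype", "ploidy", "mito")
  individuals$mito <- as.character(individuals$mito)

  rows <- list(); rejected <- list()
  for (i in seq_len(nrow(geno))) {
    ind <- individuals[i, ]
    if ((ind$biotype == "host" && ind$ploidy != 2) ||
        (ind$ploidy == 3 && ind$biotype != "hybrid") ||
        !(ind$ploidy %in% c(2, 3)) || !(ind$biotype %in% BIOTYPES)) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        row = i, id = ind$id, locus = NA_character_,
        message = "biotype/ploidy combination not allowed")
      next
    }
    ok <- TRUE; ind_alleles <- list()
    for (l in seq_len(nrow(loci))) {
      loc <- loci[l, ]
      cols <- allele_cols[col_locus == loc$name]
      vals <- suppressWarnings(as.numeric(geno[i, cols]))
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) next
      exp_n <- expected_allele_counts(ind$biotype, ind$ploidy,
                                      loc$genome_class)
      if (length(vals) != sum(exp_n)) {
        rejected[[length(rejected) + 1L]] <- data.frame(
          row = i, id = ind$id, locus = loc$name,
          message = sprintf("expected %d alleles, found %d",
                            sum(exp_n), length(vals)))
        ok <- FALSE
        break
      }
      haplome <- rep(HAPLOMES, times = exp_n)
      ind_alleles[[loc$name]] <- data.frame(
        id = ind$id, locus = loc$name, haplome = haplome,
        allele = as.integer(vals))
    }
    if (ok && length(ind_alleles))
      rows[[length(rows) + 1L]] <- do.call(rbind, ind_alleles)
  }
  alleles <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), locus = character(),
               haplome = character(), allele = integer())
  rejected <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(row = integer(), id = character(), locus = character(),
               message = character())
  keep <- !(individuals$id %in% rejected$id)
  if (nrow(rejected))
    warning(nrow(rejected), " genotype row(s) rejected; see attr(x, 'rejected')")
  gs <- geno_set(individuals[keep, , drop = FALSE],
                 alleles[alleles$id %in% individuals$id[keep], , drop = FALSE],
                 loci, sites)
  attr(gs, "rejected") <- rejected
  rownames(gs$individuals) <- NULL
  gs
}

#' Write a genotype dataset to delimited text files
#'
#' Inverse of [read_dataset()]: `read_dataset()` on the emitted files
#' recovers the dataset field-for-field.
#'
#' @param gs a `geno_set`.
#' @param genotype_file,locus_file,site_file output paths.
#' @return invisibly, the genotype data.frame written.
#' @export
write_dataset <- function(gs, genotype_file, locus_file, site_file) {
  loci <- gs$loci
  widths <- locus_width(loci$genome_class)
  cols <- unlist(mapply(function(nm, w) paste0(nm, ".", seq_len(w)),
                        loci$name, widths, SIMPLIFY = FALSE))
  out <- gs$individuals[c("id", "site", "biotype", "ploidy", "mito")]
  mat <- matrix(NA_integer_, nrow = nrow(out), ncol = length(cols),
                dimnames = list(NULL, cols))
  al_by_id <- split(gs$alleles, gs$alleles$id)
  for (i in seq_len(nrow(out))) {
    al <- al_by_id[[as.character(out$id[i])]]
    if (is.null(al)) next
    for (l in seq_len(nrow(loci))) {
      a <- al[al$locus == loci$name[l], , drop = FALSE]
      if (nrow(a) == 0) next
      vals <- unlist(lapply(HAPLOMES, function(h)
        sort(a$allele[a$haplome == h])))
      mat[i, paste0(loci$name[l], ".", seq_along(vals))] <- vals
    }
  }
  geno <- cbind(out, as.data.frame(mat))
  utils::write.csv(geno, genotype_file, row.names = FALSE, na = "")
  utils::write.csv(loci, locus_file, row.names = FALSE)
  utils::write.csv(gs$sites, site_file, row.names = FALSE)
  invisible(geno)
}

#' Convert fragment sizes in bp to integer repeat counts
#'
#' @param sizes fragment sizes in bp.
#' @param offset non-repeat (flanking) length in bp.
#' @param motif_length repeat-unit length in bp.
#' @return integer repeat counts; fails on non-integral results.
#' @export
size_to_repeat <- function(sizes, offset, motif_length) {
  counts <- (sizes - offset) / motif_length
  bad <- is.finite(counts) & abs(counts - round(counts)) > 1e-8
  if (any(bad))
    stop("non-integral repeat count for size(s): ",
         paste(sizes[bad], collapse = ", "))
  as.integer(round(counts))
}

#' Export sexual-host genotypes in Genepop 4-digit format
#'
#' One POP block per site; each allele is a zero-padded 2-digit repeat
#' count (so a genotype is 4 digits); missing loci are `0000`.
#'
#' @param gs a `geno_set`; only `biotype == "host"` individuals are used.
#' @param file output path.
#' @param title header line.
#' @return invisibly, the path.
#' @export
write_genepop <- function(gs, file, title = "gynolin host export") {
  hosts <- gs$individuals[gs$individuals$biotype == "host", , drop = FALSE]
  if (any(hosts$ploidy != 2)) stop("non-diploid host individual passed in")
  if (nrow(hosts) == 0) stop("no diploid host individuals to export")
  if (any(gs$alleles$allele > 99, na.rm = TRUE))
    stop("repeat counts > 99 cannot be encoded in the 4-digit dialect")
  loci <- gs$loci$name
  lines <- c(title, loci)
  al <- gs$alleles
  for (s in unique(hosts$site)) {
    lines <- c(lines, "Pop")
    ids <- hosts$id[hosts$site == s]
    for (id in ids) {
      genos <- vapply(loci, function(l) {
        a <- sort(al$allele[al$id == id & al$locus == l])
        if (length(a) != 2) "0000" else sprintf("%02d%02d", a[1], a[2])
      }, character(1))
      lines <- c(lines, paste0(s, "_", id, " ,  ",
                               paste(genos, collapse = " ")))
    }
  }
  writeLines(lines, file)
  invisible(file)
}

#' Parse a Genepop 4-digit file (round-trip helper)
#'
#' @param file path to a Genepop file in the dialect written by
#'   [write_genepop()].
#' @return list with `loci` and a data.frame `genotypes` (pop, id, locus,
#'   a1, a2; missing as NA).
#' @export
read_genepop <- function(file) {
  lines <- readLines(file)
  pop_idx <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (length(pop_idx) == 0) stop("no POP blocks found")
  loci <- lines[2:(pop_idx[1] - 1)]
  out <- list()
  bounds <- c(pop_idx, length(lines) + 1L)
  for (p in seq_along(pop_idx)) {
    block <- lines[(bounds[p] + 1L):(bounds[p + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    for (ln in block) {
      parts <- strsplit(ln, ",")[[1]]
      id <- trimws(parts[1])
      genos <- strsplit(trimws(parts[2]), "\\s+")[[1]]
      a1 <- as.integer(substr(genos, 1, 2))
      a2 <- as.integer(substr(genos, 3, 4))
      a1[a1 == 0] <- NA; a2[a2 == 0] <- NA
      out[[length(out) + 1L]] <- data.frame(
        pop = p, id = id, locus = loci, a1 = a1, a2 = a2)
    }
  }
  list(loci = loci, genotypes = do.call(rbind, out))
}

#' Read a labelled square distance matrix
#'
#' @param file CSV with site labels as first column and header.
#' @param tol symmetry tolerance.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
read_distance_matrix <- function(file, tol = 1e-9) {
  m <- as.matrix(utils::read.csv(file, row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (any(abs(diag(m)) > tol)) stop("distance matrix diagonal must be zero")
  if (any(abs(m - t(m)) > tol)) stop("distance matrix must be symmetric")
  if (any(m < 0)) stop("distances must be nonnegative")
  (m + t(m)) / 2
}

#' Extract one individual's genotype as a per-locus list
#'
#' @param gs a `geno_set`.
#' @param id individual id.
#' @return named list: per locus, `list(host=, maternal=, un=)` integer
#'   vectors; loci with no data are absent.
#' @export
get_genotype <- function(gs, id) {
  al <- gs$alleles[gs$alleles$id == id, , drop = FALSE]
  out <- list()
  for (l in unique(al$locus)) {
    a <- al[al$locus == l, ]
    out[[l]] <- list(host = sort(a$allele[a$haplome == "host"]),
                     maternal = sort(a$allele[a$haplome == "maternal"]),
                     un = sort(a$allele[a$haplome == "un"]))
  }
  out
}
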