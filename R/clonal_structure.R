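#' @title Clonal distances, trees and divergence summaries
#'
#' @description
#' The clonal distance between two multilocus genotypes under a stepwise
#' mutation model is, per locus, the minimum over allele pairings of the
#' summed absolute repeat-count differences, summed over loci. Haplome
#' labels are respected where available (host alleles are paired with host
#' alleles, maternal with maternal); for the 1-D ground metric |a - b| the
#' optimal pairing of equal-size multisets is the sorted-order pairing,
#' which is what is computed (exact, and equal to exhaustive enumeration
#' over pairings).
#'
#' @name clonal_structure
NULL

#' Default locus inclusion for clonal distances
#'
#' Microsatellite loci whose parental alleles can be resolved (i.e.
#' excluding dual-overlapping loci and non-microsatellite markers).
#'
#' @param loci a [locus_panel()].
#' @param include_overlapping include dual-overlapping loci (pooled
#'   multiset comparison) as well.
#' @return character vector of locus names.
#' @export
clonal_loci <- function(loci, include_overlapping = FALSE) {
  keep <- loci$marker_type == "microsat"
  if (!include_overlapping) keep <- keep & loci$genome_class != "dual_overlapping"
  loci$name[keep]
}

# minimum-cost pairing of two equal-length sorted integer vectors
.pair_cost <- function(a, b) sum(abs(sort(a) - sort(b)))

#' Clonal distance between two genotypes
#'
#' @param gA,gB genotype lists as returned by [get_genotype()].
#' @param loci a [locus_panel()].
#' @param included_loci locus names to use; defaults to [clonal_loci()].
#' @return integer number of stepwise mutations; loci missing in either
#'   genotype, or with unequal allele-multiset sizes, are skipped
#'   (pairwise exclusion).
#' @export
clonal_distance <- function(gA, gB, loci, included_loci = clonal_loci(loci)) {
  total <- 0L; used <- 0L
  for (l in included_loci) {
    a <- gA[[l]]; b <- gB[[l]]
    if (is.null(a) || is.null(b)) next
    d <- 0L; ok <- FALSE
    for (h in c("host", "maternal", "un")) {
      va <- a[[h]]; vb <- b[[h]]
      if (length(va) == 0 && length(vb) == 0) next
      if (length(va) != length(vb)) { ok <- FALSE; d <- NA; break }
      d <- d + .pair_cost(va, vb); ok <- TRUE
    }
    if (!is.na(d) && ok) { total <- total + d; used <- used + 1L }
  }
  if (used == 0L) stop("no shared non-missing loci between genotypes")
  as.integer(total)
}

# slot representation for fast pairwise distances: one numeric matrix
# (individual x slot) plus the locus each slot belongs to. Requires all
# individuals to share the same per-locus multiset layout (e.g. diploid
# hybrids, or consensus genotypes). Missing loci yield NA slots.
slot_matrix <- function(gs, ids, included_loci,
                        loci = gs$loci) {
  genos <- lapply(ids, function(id) get_genotype(gs, id))
  names(genos) <- ids
  slot_matrix_from_genotypes(genos, loci, included_loci)
}

slot_matrix_from_genotypes <- function(genos, loci, included_loci) {
  ids <- names(genos)
  # layout discovered from the first genotype carrying each locus
  layout <- list()
  for (l in included_loci) {
    for (g in genos) {
      if (!is.null(g[[l]])) {
        layout[[l]] <- vapply(HAPLOMES, function(h) length(g[[l]][[h]]),
                              integer(1))
        break
      }
    }
  }
  cols <- character(0); locus_of <- character(0); hap_of <- character(0)
  for (l in names(layout)) {
    for (h in HAPLOMES) {
      n <- layout[[l]][[h]]
      if (n > 0) {
        cols <- c(cols, paste0(l, ".", h, ".", seq_len(n)))
        locus_of <- c(locus_of, rep(l, n))
        hap_of <- c(hap_of, rep(h, n))
      }
    }
  }
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(cols),
              dimnames = list(ids, cols))
  for (i in seq_along(ids)) {
    g <- genos[[i]]
    for (l in names(layout)) {
      if (is.null(g[[l]])) next
      for (h in HAPLOMES) {
        n <- layout[[l]][[h]]
        if (n == 0) next
        v <- sort(g[[l]][[h]])
        if (length(v) != n) next  # layout mismatch -> missing
        m[i, paste0(l, ".", h, ".", seq_len(n))] <- v
      }
    }
  }
  attr(m, "locus_of") <- locus_of
  attr(m, "hap_of") <- hap_of
  m
}

# pairwise step distances and number of differing loci from a slot matrix
pairwise_from_slots <- function(m) {
  locus_of <- attr(m, "locus_of")
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  ndiff <- matrix(0L, n, n, dimnames = dimnames(D))
  shared <- matrix(0L, n, n, dimnames = dimnames(D))
  for (l in unique(locus_of)) {
    sl <- which(locus_of == l)
    Dl <- matrix(0, n, n)
    avail <- rep(TRUE, n)
    for (s in sl) {
      x <- m[, s]
      avail <- avail & !is.na(x)
      dd <- abs(outer(x, x, "-"))
      dd[is.na(dd)] <- 0
      Dl <- Dl + dd
    }
    av <- outer(avail, avail, "&")
    Dl[!av] <- 0
    D <- D + Dl
    ndiff <- ndiff + (Dl > 0)
    shared <- shared + av
  }
  list(steps = D, n_diff_loci = ndiff, n_shared_loci = shared)
}

#' Pairwise clonal distance matrix
#'
#' @param gs a `geno_set`.
#' @param ids individual ids (>= 2) sharing a genotype layout (e.g. the
#'   diploid hybrids).
#' @param included_loci locus names; defaults to [clonal_loci()].
#' @return symmetric integer matrix of stepwise distances with zero
#'   diagonal (class `clonal_dist`, attribute `metric_name`).
#' @export
clonal_distance_matrix <- function(gs, ids,
                                   included_loci = clonal_loci(gs$loci)) {
  if (length(ids) < 2) stop("need at least 2 genotypes")
  m <- slot_matrix(gs, ids, included_loci)
  pw <- pairwise_from_slots(m)
  if (any(pw$n_shared_loci[upper.tri(pw$n_shared_loci)] == 0))
    warning("some genotype pairs share no non-missing loci; distance 0 reported")
  out <- pw$steps
  attr(out, "metric_name") <- "clonal_steps"
  out
}

#' Unrooted neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with a deterministic tie-break (when two
#' Q-matrix entries are equal the lexicographically lowest label pair is
#' joined, so the result depends on the labels, not the input order) and
#' a post-pass that clamps negative branch lengths to zero and moves the
#' deficit to the adjacent branch, preserving path lengths.
#'
#' @param d symmetric distance matrix (n >= 3) with labels.
#' @return an [ape::read.tree()]-style `phylo` object.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(d))) stop("non-finite distances")
  if (is.null(rownames(d)))
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  tr <- ape::read.tree(text = .nj_newick(d))
  # clamp negative branches; transfer the deficit to the sister branch
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sisters <- which(tr$edge[, 1] == parent & seq_along(tr$edge.length) != e)
    if (length(sisters))
      tr$edge.length[sisters[1]] <- tr$edge.length[sisters[1]] + deficit
  }
  tr
}

# Saitou-Nei agglomeration emitting a Newick string. Each active node
# carries a subtree string and a sort key (its lexicographically smallest
# tip label) used for deterministic tie-breaking.
.nj_newick <- function(d) {
  labels <- rownames(d)
  sub <- paste0(gsub("[(),:;]", "_", labels))
  key <- labels
  while (nrow(d) > 3) {
    n <- nrow(d)
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-9, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- apply(cand, 1, function(ij)
      paste(sort(c(key[ij[1]], key[ij[2]])), collapse = "\r"))
    pick <- cand[order(pair_key)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    new_sub <- sprintf("(%s:%.10g,%s:%.10g)", sub[i], bi, sub[j], bj)
    new_key <- min(key[i], key[j])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    sub <- c(sub[keep], new_sub)
    key <- c(key[keep], new_key)
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", sub[1], la, sub[2], lb,
          sub[3], lc)
}

#' Within- and among-lineage divergence summary
#'
#' Within-lineage statistics pool member-pair distances across lineages
#' with at least two members; among-lineage statistics are over pairs of
#' consensus genotypes.
#'
#' @param member_dist distance matrix among individual hybrid genotypes.
#' @param membership data.frame (id, lineage_id) for the individuals in
#'   `member_dist`.
#' @param consensus_dist distance matrix among lineage consensus genotypes.
#' @return list with within_mean/within_sd/among_mean/among_sd/among_max.
#' @export
divergence_summary <- function(member_dist, membership, consensus_dist) {
  within <- numeric(0)
  for (lid in unique(membership$lineage_id)) {
    ids <- membership$id[membership$lineage_id == lid]
    ids <- intersect(ids, rownames(member_dist))
    if (length(ids) >= 2) {
      sub <- member_dist[ids, ids]
      within <- c(within, sub[upper.tri(sub)])
    }
  }
  among <- consensus_dist[upper.tri(consensus_dist)]
  list(within_mean = if (length(within)) mean(within) else NA_real_,
       within_sd = if (length(within) > 1) stats::sd(within) else NA_real_,
       among_mean = if (length(among)) mean(among) else NA_real_,
       among_sd = if (length(among) > 1) stats::sd(among) else NA_real_,
       among_max = if (length(among)) max(among) else NA_real_)
}

# all permutations of 1..n (for small n)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Lineage accumulation curve by site permutation
#'
#' Mean and standard deviation, over random orderings of sites (without
#' replacement), of the cumulative number of distinct lineages in the
#' first k sites. When `factorial(n_sites) <= n_perm` all orderings are
#' enumerated exactly.
#'
#' @param mat site x lineage abundance matrix.
#' @param n_perm number of random site orderings.
#' @param seed RNG seed.
#' @return data.frame (n_sites, mean_richness, sd_richness).
#' @export
accumulation_curve <- function(mat, n_perm = 999, seed = 1) {
  mat <- as.matrix(mat)
  if (length(mat) == 0 || nrow(mat) == 0) stop("empty site-lineage matrix")
  if (n_perm < 1) stop("n_perm must be >= 1")
  n <- nrow(mat)
  pres <- mat > 0
  set.seed(seed)
  orders <- if (n <= 7 && factorial(n) <= n_perm) {
    .permutations(n)
  } else {
    t(replicate(n_perm, sample.int(n)))
  }
  rich <- apply(orders, 1, function(o) {
    seen <- rep(FALSE, ncol(pres))
    out <- integer(n)
    for (k in seq_len(n)) {
      seen <- seen | pres[o[k], ]
      out[k] <- sum(seen)
    }
    out
  })
  rich <- matrix(rich, nrow = n)  # n x n_orderings
  data.frame(n_sites = seq_len(n),
             mean_richness = rowMeans(rich),
             sd_richness = apply(rich, 1, stats::sd))
}
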