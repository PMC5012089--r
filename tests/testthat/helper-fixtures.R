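# shared fixtures: a small locus panel and genotype constructors

toy_loci <- function() {
  locus_panel(
    name = c("hsA", "hsB", "ddA", "doA"),
    genome_class = c("host_specific", "host_specific",
                     "dual_distinguishable", "dual_overlapping"),
    motif_length = 2L)
}

# genotype list for a diploid hybrid on the toy panel
dip_geno <- function(hsA, hsB, ddA_h, ddA_m, doA = c(30, 45)) {
  list(hsA = list(host = as.integer(hsA), maternal = integer(0),
                  un = integer(0)),
       hsB = list(host = as.integer(hsB), maternal = integer(0),
                  un = integer(0)),
       ddA = list(host = as.integer(ddA_h), maternal = as.integer(ddA_m),
                  un = integer(0)),
       doA = list(host = integer(0), maternal = integer(0),
                  un = sort(as.integer(doA))))
}

# genotype list for a diploid host on the toy panel
host_geno <- function(hsA, hsB, ddA, doA) {
  g <- list()
  for (l in c("hsA", "hsB", "ddA", "doA")) {
    v <- switch(l, hsA = hsA, hsB = hsB, ddA = ddA, doA = doA)
    g[[l]] <- list(host = sort(as.integer(v)), maternal = integer(0),
                   un = integer(0))
  }
  g
}

# add one sperm host allele per locus to a diploid hybrid genotype
make_triploid <- function(g, sperm) {
  for (l in names(sperm)) {
    if (l == "doA") g[[l]]$un <- sort(c(g[[l]]$un, as.integer(sperm[[l]])))
    else g[[l]]$host <- sort(c(g[[l]]$host, as.integer(sperm[[l]])))
  }
  g
}

# assemble a geno_set from a list of individuals:
# list(id=, site=, biotype=, ploidy=, mito=, geno=<genotype list>)
build_gs <- function(inds, loci = toy_loci(), sites = NULL) {
  ind_df <- do.call(rbind, lapply(inds, function(i)
    data.frame(id = i$id, site = i$site, biotype = i$biotype,
               ploidy = i$ploidy,
               mito = if (is.null(i$mito)) NA_character_ else i$mito)))
  rows <- list()
  for (i in inds) for (l in names(i$geno)) for (h in names(i$geno[[l]])) {
    a <- i$geno[[l]][[h]]
    if (length(a))
      rows[[length(rows) + 1L]] <- data.frame(
        id = i$id, locus = l, haplome = h, allele = as.integer(a))
  }
  if (is.null(sites)) {
    sid <- unique(ind_df$site)
    sites <- data.frame(id = sid, region = "R1",
                        x = seq_along(sid) * 10, y = 0)
  }
  geno_set(ind_df, do.call(rbind, rows), loci, sites)
}
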