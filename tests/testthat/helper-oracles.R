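# independent oracles kept deliberately naive

# all permutations of 1..n (recursive, independent of package internals)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}

# minimum pairing cost by exhaustive enumeration over pairings
brute_pair_cost <- function(a, b) {
  if (length(a) == 0) return(0)
  min(vapply(all_perms(length(a)), function(p)
    sum(abs(a - b[p])), numeric(1)))
}

# exhaustive clonal distance between two genotype lists
brute_clonal_distance <- function(gA, gB, included_loci) {
  total <- 0
  for (l in included_loci) {
    a <- gA[[l]]; b <- gB[[l]]
    if (is.null(a) || is.null(b)) next
    skip <- FALSE; d <- 0
    for (h in c("host", "maternal", "un")) {
      if (length(a[[h]]) != length(b[[h]])) { skip <- TRUE; break }
      d <- d + brute_pair_cost(a[[h]], b[[h]])
    }
    if (!skip) total <- total + d
  }
  total
}

# closed-form Weir-Cockerham variance components summed over alleles
wc_closed_form <- function(pop, a1, a2) {
  alleles <- sort(unique(c(a1, a2)))
  r <- length(unique(pop)); ni <- as.vector(table(pop))
  nbar <- mean(ni)
  nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
  abc <- sapply(alleles, function(al) {
    pi <- tapply((a1 == al) + (a2 == al), pop, sum) / (2 * ni)
    hi <- tapply((a1 == al) + (a2 == al) == 1, pop, sum) / ni
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    c(a, b, hbar / 2)
  })
  rowSums(abc)
}

# LCBD by explicit double-centering loops (independent linear algebra)
lcbd_loops <- function(D) {
  n <- nrow(D)
  A <- -0.5 * D^2
  G <- matrix(0, n, n)
  rm_ <- rowMeans(A); cm_ <- colMeans(A); gm <- mean(A)
  for (i in 1:n) for (j in 1:n)
    G[i, j] <- A[i, j] - rm_[i] - cm_[j] + gm
  diag(G) / sum(diag(G))
}

# random diploid-hybrid genotype on the toy panel
random_dip_geno <- function() {
  dip_geno(hsA = sample(8:20, 1), hsB = sample(8:20, 1),
           ddA_h = sample(8:20, 1), ddA_m = sample(40:50, 1),
           doA = sample(25:50, 2, replace = TRUE))
}
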