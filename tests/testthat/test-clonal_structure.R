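test_that("clonal distance matches hand-worked examples", {
  g1 <- dip_geno(10, 11, 14, 44)
  expect_equal(clonal_distance(g1, g1, toy_loci()), 0L)
  # one locus, multisets {10,12} vs {11,15}: optimal pairing costs 4
  a <- dip_geno(10, 11, 14, 44, doA = c(10, 12))
  b <- dip_geno(10, 11, 14, 44, doA = c(11, 15))
  expect_equal(clonal_distance(a, b, toy_loci(), included_loci = "doA"), 4L)
  # haplome-resolved loci compare within haplome
  c_ <- dip_geno(12, 11, 16, 47)
  expect_equal(clonal_distance(g1, c_, toy_loci()), 2L + 2L + 3L)
})

test_that("sorted pairing equals exhaustive enumeration over pairings", {
  set.seed(101)
  loci <- toy_loci()
  included <- clonal_loci(loci, include_overlapping = TRUE)
  for (rep in 1:60) {
    gA <- random_dip_geno(); gB <- random_dip_geno()
    expect_equal(clonal_distance(gA, gB, loci, included),
                 as.integer(brute_clonal_distance(gA, gB, included)))
  }
  # triploid-sized multisets (3 alleles) at the pooled locus
  t1 <- list(doA = list(host = integer(0), maternal = integer(0),
                        un = sort(sample(20:40, 3, TRUE))))
  t2 <- list(doA = list(host = integer(0), maternal = integer(0),
                        un = sort(sample(20:40, 3, TRUE))))
  expect_equal(clonal_distance(t1, t2, loci, "doA"),
               as.integer(brute_clonal_distance(t1, t2, "doA")))
})

test_that("missing loci are excluded pairwise and empty overlap is an error", {
  g1 <- dip_geno(10, 11, 14, 44)
  g2 <- dip_geno(12, 11, 14, 44)
  g2$hsA <- NULL
  expect_equal(clonal_distance(g1, g2, toy_loci()), 0L)  # hsA skipped
  g3 <- list(hsA = list(host = 10L, maternal = integer(0), un = integer(0)))
  g4 <- list(hsB = list(host = 10L, maternal = integer(0), un = integer(0)))
  expect_error(clonal_distance(g3, g4, toy_loci()), "no shared")
})

test_that("the distance matrix equals per-pair recomputation and is a metric", {
  sim <- simulate_dataset(sim_params(seed = 31))
  gs <- sim$dataset
  dips <- gs$individuals$id[gs$individuals$biotype == "hybrid" &
                              gs$individuals$ploidy == 2][1:30]
  D <- clonal_distance_matrix(gs, dips)
  expect_true(isSymmetric(unclass(D)))
  expect_true(all(diag(D) == 0))
  for (pair in list(c(1, 2), c(5, 20), c(11, 28))) {
    expect_equal(D[pair[1], pair[2]],
                 as.numeric(clonal_distance(
                   get_genotype(gs, dips[pair[1]]),
                   get_genotype(gs, dips[pair[2]]), gs$loci)))
  }
  # triangle inequality over all triples
  n <- nrow(D)
  viol <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    viol <- viol + (D[i, k] > D[i, j] + D[j, k] + 1e-9) +
      (D[i, j] > D[i, k] + D[j, k] + 1e-9) +
      (D[j, k] > D[i, j] + D[i, k] + 1e-9)
  }
  expect_equal(viol, 0)
})

test_that("neighbor joining recovers an additive four-taxon tree", {
  # tree ((A:2,B:3):1,(C:4,D:5)): additive distances
  D <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 9, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(D)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  coph <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(coph, D, tolerance = 1e-9)
  # correct split: removing the internal edge separates {A,B} from {C,D}
  expect_equal(unname(coph["A", "B"]), 5)
})

test_that("star distances yield equal terminal branches and 3 taxa solve the closed form", {
  D <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  tr <- neighbor_joining(D)
  term <- tr$edge.length[tr$edge[, 2] <= 4]
  expect_equal(term, rep(1, 4), tolerance = 1e-9)

  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- neighbor_joining(D3)
  coph <- ape::cophenetic.phylo(tr3)[rownames(D3), colnames(D3)]
  expect_equal(coph, D3, tolerance = 1e-9)
})

test_that("neighbor joining is invariant to input label order", {
  set.seed(8)
  sim <- simulate_dataset(sim_params(seed = 8))
  gs <- sim$dataset
  dips <- gs$individuals$id[gs$individuals$biotype == "hybrid" &
                              gs$individuals$ploidy == 2][1:8]
  D <- clonal_distance_matrix(gs, dips) + 0.0
  tr1 <- neighbor_joining(D)
  p <- sample(nrow(D))
  tr2 <- neighbor_joining(D[p, p])
  expect_equal(ape::dist.topo(ape::unroot(tr1), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
})

test_that("native neighbor joining agrees with the reference implementation", {
  set.seed(14)
  for (rep in 1:5) {
    x <- matrix(runif(7 * 3, 0, 10), 7, 3)
    D <- as.matrix(dist(x))   # continuous distances: no Q ties
    dimnames(D) <- list(letters[1:7], letters[1:7])
    tr <- neighbor_joining(D)
    tr_ape <- ape::nj(as.dist(D))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr_ape)), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(tr)[letters[1:7], letters[1:7]],
                 ape::cophenetic.phylo(tr_ape)[letters[1:7], letters[1:7]],
                 tolerance = 1e-6)
  }
})

test_that("divergence summary matches a hand-enumerated toy", {
  g1 <- dip_geno(10, 11, 14, 44); g1b <- dip_geno(11, 11, 14, 44)
  g2 <- dip_geno(30, 31, 34, 44); g2b <- dip_geno(30, 31, 35, 44)
  gs <- build_gs(list(
    list(id = "a1", site = "s1", biotype = "hybrid", ploidy = 2, mito = "A",
         geno = g1),
    list(id = "a2", site = "s1", biotype = "hybrid", ploidy = 2, mito = "A",
         geno = g1b),
    list(id = "b1", site = "s2", biotype = "hybrid", ploidy = 2, mito = "A",
         geno = g2),
    list(id = "b2", site = "s2", biotype = "hybrid", ploidy = 2, mito = "A",
         geno = g2b)))
  lins <- cluster_diploid_lineages(gs)
  cons_ids <- lins$lineages$id
  m <- gynolin:::slot_matrix_from_genotypes(lins$consensus[cons_ids],
                                            gs$loci, clonal_loci(gs$loci))
  cons_d <- gynolin:::pairwise_from_slots(m)$steps
  ds <- divergence_summary(lins$diploid_dist, lins$membership, cons_d)
  expect_equal(ds$within_mean, 1)       # each lineage: one 1-step pair
  expect_equal(ds$within_sd, 0)
  # consensus genotypes: (10,11,14) vs (30,31,34): 20+20+20 = 60
  expect_equal(ds$among_mean, 60)
  expect_equal(ds$among_max, 60)
})

test_that("accumulation curves hit exact endpoints and exhaustive means", {
  mat <- matrix(c(1, 1, 1), 3, 1,
                dimnames = list(c("s1", "s2", "s3"), "L1"))
  ac <- accumulation_curve(mat, n_perm = 50, seed = 1)
  expect_equal(ac$mean_richness, rep(1, 3))
  expect_equal(ac$sd_richness, rep(0, 3))

  # 3 sites with sets {L1}, {L1,L2}, {L3}: exhaustive over 6 orderings
  mat2 <- matrix(c(1, 1, 0,
                   0, 1, 0,
                   0, 0, 1), 3, 3,
                 dimnames = list(c("s1", "s2", "s3"), c("L1", "L2", "L3")))
  ac2 <- accumulation_curve(mat2, n_perm = 999, seed = 1)
  # k=1: mean of 1,2,1 = 4/3 over equally likely first sites
  expect_equal(ac2$mean_richness[1], 4 / 3)
  orders <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  rich2 <- mean(vapply(orders, function(o)
    sum(colSums(mat2[o[1:2], , drop = FALSE]) > 0), numeric(1)))
  expect_equal(ac2$mean_richness[2], rich2)
  expect_equal(ac2$mean_richness[3], 3)  # gamma exactly
  expect_equal(ac2$sd_richness[3], 0)
})
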