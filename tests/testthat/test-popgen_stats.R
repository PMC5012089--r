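# small pop_data builder bypassing geno_set
make_pd <- function(pop, genos_by_locus) {
  geno <- lapply(genos_by_locus, function(g) {
    states <- sort(unique(c(g$a1, g$a2)))
    list(states = states, a1 = match(g$a1, states), a2 = match(g$a2, states))
  })
  structure(list(ind = data.frame(id = paste0("i", seq_along(pop)),
                                  pop = pop),
                 loci = names(genos_by_locus), geno = geno),
            class = "pop_data")
}

test_that("Nei's unbiased gene diversity matches closed form and brute force", {
  pop <- rep("p1", 10)
  a1 <- c(rep(10L, 5), rep(12L, 5)); a2 <- c(rep(10L, 5), rep(12L, 5))
  # shuffle into 0.5/0.5 frequencies
  pd <- make_pd(pop, list(L1 = list(a1 = a1, a2 = rev(a2))))
  s <- pop_summary(pd)
  expect_equal(s$per_locus$he, (20 / 19) * 0.5, tolerance = 1e-12)
  expect_equal(s$per_locus$k, 2)
  # brute force: probability two copies drawn without replacement differ
  copies <- c(a1, rev(a2))
  diff_pairs <- sum(outer(copies, copies, "!=")) / (20 * 19)
  expect_equal(s$per_locus$he, diff_pairs, tolerance = 1e-12)
})

test_that("Hardy-Weinberg permutation test behaves at both extremes", {
  # all heterozygotes, 2 alleles, n = 20: extreme Fis
  res <- hwe_test(rep(10L, 20), rep(12L, 20), n_iter = 2000, seed = 1)
  expect_lte(res$p, 0.01)
  expect_lt(res$fis, 0)
  # exact HW proportions at large n: unremarkable p
  a1 <- c(rep(10L, 50), rep(10L, 100), rep(12L, 50))
  a2 <- c(rep(10L, 50), rep(12L, 100), rep(12L, 50))
  ps <- vapply(1:5, function(s)
    hwe_test(a1, a2, n_iter = 500, seed = s)$p, numeric(1))
  expect_gt(median(ps), 0.3)
  # monomorphic: p = 1 by convention
  expect_equal(hwe_test(rep(10L, 10), rep(10L, 10))$p, 1)
  expect_error(hwe_test(1:3, 1:3), "at least 5")
})

test_that("linkage test flags co-varying loci and passes independent ones", {
  g1 <- rep(c("10/10", "12/12", "10/12"), times = c(10, 10, 10))
  res <- ld_test(g1, g1, n_iter = 2000, seed = 2)
  expect_lte(res$p, 0.001)
  expect_equal(ld_test(g1, rep("5/5", 30))$p, 1)
  set.seed(33)
  rej <- 0
  for (b in 1:100) {
    x <- paste(sample(1:3, 40, TRUE), sample(1:3, 40, TRUE), sep = "/")
    y <- paste(sample(1:3, 40, TRUE), sample(1:3, 40, TRUE), sep = "/")
    rej <- rej + (ld_test(x, y, n_iter = 99, seed = b)$p <= 0.05)
  }
  expect_gt(rej / 100, 0.005)
  expect_lt(rej / 100, 0.13)
})

test_that("theta equals the closed-form Weir-Cockerham estimator", {
  set.seed(17)
  pop <- rep(c("p1", "p2", "p3"), times = c(9, 14, 7))
  a1 <- sample(c(10L, 12L, 14L), 30, TRUE, c(.5, .3, .2))
  a2 <- sample(c(10L, 12L, 14L), 30, TRUE, c(.2, .4, .4))
  pd <- make_pd(pop, list(L1 = list(a1 = a1, a2 = a2)))
  th <- fst_theta(pd)
  wc <- wc_closed_form(pop, a1, a2)
  expect_equal(unname(th$components), unname(wc), tolerance = 1e-12)
  expect_equal(th$global, wc[1] / sum(wc), tolerance = 1e-12)
})

test_that("theta hits the fixed-difference and panmictic limits", {
  pop <- rep(c("p1", "p2"), each = 10)
  pd <- make_pd(pop, list(L1 = list(a1 = rep(c(10L, 20L), each = 10),
                                    a2 = rep(c(10L, 20L), each = 10))))
  expect_equal(fst_theta(pd)$global, 1)
  # a panmictic sample split at random has expectation ~ 0
  set.seed(23)
  est <- vapply(1:50, function(s) {
    a1 <- sample(10:16, 100, TRUE); a2 <- sample(10:16, 100, TRUE)
    pd <- make_pd(sample(rep(c("p1", "p2"), each = 50)),
                  list(L1 = list(a1 = a1, a2 = a2),
                       L2 = list(a1 = sample(5:9, 100, TRUE),
                                 a2 = sample(5:9, 100, TRUE))))
    fst_theta(pd)$global
  }, numeric(1))
  expect_lt(abs(mean(est)), 0.01)
})

test_that("rho equals theta exactly on 2-allele loci", {
  set.seed(29)
  for (rep in 1:10) {
    pop <- rep(c("p1", "p2", "p3"), each = 12)
    a1 <- sample(c(10L, 17L), 36, TRUE, c(.7, .3))
    a2 <- sample(c(10L, 17L), 36, TRUE, c(.4, .6))
    pd <- make_pd(pop, list(L1 = list(a1 = a1, a2 = a2)))
    expect_equal(rho_st(pd, n_size_perm = 0)$global,
                 fst_theta(pd)$global, tolerance = 1e-12)
  }
})

test_that("a directional size ladder inflates rho over theta and is detected", {
  set.seed(37)
  # pop2 shifted +8 repeats: mutation-driven divergence
  a1 <- c(sample(10:13, 25, TRUE), sample(18:21, 25, TRUE))
  a2 <- c(sample(10:13, 25, TRUE), sample(18:21, 25, TRUE))
  pd <- make_pd(rep(c("p1", "p2"), each = 25),
                list(L1 = list(a1 = a1, a2 = a2)))
  rho <- rho_st(pd, n_size_perm = 999, seed = 5)
  th <- fst_theta(pd)
  expect_gt(rho$global, th$global)
  expect_lte(rho$size_perm_p, 0.05)
})

test_that("the allele-size permutation test keeps its nominal level under drift", {
  set.seed(41)
  rej <- 0
  for (b in 1:100) {
    k <- 8
    states <- sort(sample(10:40, k))
    p_anc <- as.vector(gynolin:::rdirichlet1(rep(1, k)))
    pop <- rep(paste0("P", 1:4), each = 15)
    a1 <- integer(0); a2 <- integer(0)
    for (p in 1:4) {
      f <- gynolin:::bn_freqs(p_anc, 0.1)
      a1 <- c(a1, sample(seq_len(k), 15, TRUE, f))
      a2 <- c(a2, sample(seq_len(k), 15, TRUE, f))
    }
    pd <- structure(list(ind = data.frame(id = paste0("i", 1:60), pop = pop),
                         loci = "L1",
                         geno = list(L1 = list(states = states,
                                               a1 = a1, a2 = a2))),
                    class = "pop_data")
    rej <- rej + (rho_st(pd, n_size_perm = 99, seed = b)$size_perm_p <= 0.05)
  }
  expect_lt(rej / 100, 0.12)
})

test_that("pairwise differentiation carries permutation and Holm-corrected p", {
  set.seed(43)
  pop <- rep(c("p1", "p2", "p3"), each = 12)
  a1 <- c(rep(10L, 24), rep(20L, 12)); a2 <- a1
  pd <- make_pd(pop, list(L1 = list(a1 = a1, a2 = sample(a2))))
  th <- fst_theta(pd, pairwise = TRUE, n_perm = 99, seed = 3)
  expect_equal(dim(th$pairwise), c(3, 3))
  expect_gt(th$pairwise["p1", "p3"], th$pairwise["p1", "p2"])
  expect_true(all(th$pairwise_p >= 1 / 100, na.rm = TRUE))
  expect_true(all(th$pairwise_p_holm >= th$pairwise_p, na.rm = TRUE))
})

test_that("AMOVA satisfies the ANOVA identities and its limits", {
  # sums of squares add up
  set.seed(47)
  pop <- rep(paste0("P", 1:4), each = 10)
  a1 <- sample(10:15, 40, TRUE); a2 <- sample(10:15, 40, TRUE)
  pd <- make_pd(pop, list(L1 = list(a1 = a1, a2 = a2)))
  grouping <- c(P1 = "G1", P2 = "G1", P3 = "G2", P4 = "G2")
  am <- amova_two_level(pd, grouping, mode = "rho", n_perm = 99, seed = 1)
  y <- as.numeric(c(a1, a2))
  ss_total <- sum((y - mean(y))^2)
  expect_equal(sum(am$ss), ss_total, tolerance = 1e-9)
  expect_true(all(am$sigma_pct >= 0))
  expect_equal(sum(am$sigma_pct), 100, tolerance = 1e-9)
  expect_gte(am$p_fct, 1 / 100)

  # mutually fixed groups of internally identical pops: F_CT -> 1
  a1f <- rep(c(10L, 10L, 30L, 30L), each = 10)
  pdf_ <- make_pd(pop, list(L1 = list(a1 = a1f, a2 = a1f)))
  amf <- amova_two_level(pdf_, grouping, mode = "theta", n_perm = 0)
  expect_gt(amf$f_ct, 0.95)

  # random grouping of structured pops: F_CT ~ 0 on average
  set.seed(53)
  est <- vapply(1:20, function(s) {
    a1s <- integer(0)
    for (p in 1:4) a1s <- c(a1s, sample(10:20, 10, TRUE))
    a2s <- sample(a1s)
    pds <- make_pd(pop, list(L1 = list(a1 = a1s, a2 = a2s)))
    g <- setNames(sample(c("G1", "G1", "G2", "G2")), paste0("P", 1:4))
    amova_two_level(pds, g, mode = "theta", n_perm = 0)$f_ct
  }, numeric(1))
  expect_lt(abs(mean(est)), 0.05)
})

test_that("chord distances match hand arithmetic and limits", {
  pd <- make_pd(rep(c("p1", "p2"), each = 10),
                list(L1 = list(a1 = rep(c(10L, 20L), each = 10),
                               a2 = rep(c(10L, 20L), each = 10))))
  D <- dce_matrix(pd)
  expect_equal(D["p1", "p2"], (2 / pi) * sqrt(2), tolerance = 1e-12)

  # p = (0.8, 0.2) vs (0.2, 0.8): f = 1 - 2 sqrt(0.16) = 0.2
  a1 <- c(rep(10L, 8), rep(20L, 2), rep(10L, 2), rep(20L, 8))
  pd2 <- make_pd(rep(c("p1", "p2"), each = 10),
                 list(L1 = list(a1 = a1, a2 = a1)))
  expect_equal(dce_matrix(pd2)["p1", "p2"], (2 / pi) * sqrt(2 * 0.2),
               tolerance = 1e-12)
  # identical frequencies -> 0
  pd3 <- make_pd(rep(c("p1", "p2"), each = 10),
                 list(L1 = list(a1 = rep(c(10L, 20L), 10),
                                a2 = rep(c(20L, 10L), 10))))
  expect_equal(dce_matrix(pd3)["p1", "p2"], 0, tolerance = 1e-12)
})

test_that("PCA separates fixed groups and respects invariances", {
  pop <- rep(c("p1", "p2"), each = 10)
  pd <- make_pd(pop, list(L1 = list(a1 = rep(c(10L, 20L), each = 10),
                                    a2 = rep(c(10L, 20L), each = 10)),
                          L2 = list(a1 = rep(c(5L, 9L), each = 10),
                                    a2 = rep(c(5L, 9L), each = 10))))
  pc <- pca_scores(pd)
  expect_gt(pc$eig_share[1], 0.9)
  s1 <- pc$scores[pop == "p1", 1]; s2 <- pc$scores[pop == "p2", 1]
  expect_true(max(s1) < min(s2) || min(s1) > max(s2))
  # duplicated individuals get identical scores
  expect_equal(pc$scores[1, ], pc$scores[2, ])
  # locus order only flips signs at most
  pd_rev <- pd; pd_rev$loci <- rev(pd$loci)
  pc2 <- pca_scores(pd_rev)
  expect_equal(abs(pc2$scores[, 1]), abs(pc$scores[, 1]), tolerance = 1e-9)
})

test_that("population data construction excludes small sites and splits alleles", {
  sim <- simulate_dataset(sim_params(seed = 61, sites_per_region = 3,
                                     n_host_per_site = 8))
  gs <- sim$dataset
  # shrink one site below the threshold
  drop_ids <- head(gs$individuals$id[gs$individuals$biotype == "host" &
                                       gs$individuals$site == "S01"], 4)
  gs$individuals <- gs$individuals[!(gs$individuals$id %in% drop_ids), ]
  gs$alleles <- gs$alleles[!(gs$alleles$id %in% drop_ids), ]
  expect_message(pd <- pop_data(gs, min_n = 7), "S01")
  expect_false("S01" %in% pd$ind$pop)
  expect_equal(sort(unique(pd$ind$pop)), sort(setdiff(
    unique(gs$individuals$site[gs$individuals$biotype == "host"]), "S01")))
})
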