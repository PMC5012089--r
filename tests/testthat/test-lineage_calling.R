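make_clone_set <- function(genos, mito, ploidy = NULL, sites = NULL) {
  n <- length(genos)
  if (is.null(ploidy)) ploidy <- rep(2, n)
  if (is.null(sites)) sites <- rep("s1", n)
  build_gs(lapply(seq_len(n), function(i)
    list(id = sprintf("x%02d", i), site = sites[i], biotype = "hybrid",
         ploidy = ploidy[i], mito = mito[i], geno = genos[[i]])))
}

test_that("identical genotypes form one lineage whose consensus is the shared genotype", {
  g <- dip_geno(10, 11, 14, 44)
  gs <- make_clone_set(rep(list(g), 5), mito = rep("A", 5))
  lins <- cluster_diploid_lineages(gs)
  expect_equal(nrow(lins$lineages), 1)
  expect_equal(lins$lineages$n_diploid, 5)
  cons <- lins$consensus[[lins$lineages$id]]
  expect_equal(cons$hsA$host, 10L)
  expect_equal(cons$ddA$maternal, 44L)
})

test_that("groups tens of steps apart split while few-step variants merge", {
  # lineage 1 around (10,11,14), lineage 2 shifted ~50 steps in total
  genos <- list(dip_geno(10, 11, 14, 44), dip_geno(10, 12, 14, 44),
                dip_geno(10, 11, 15, 44),
                dip_geno(28, 28, 30, 44), dip_geno(28, 29, 30, 44))
  gs <- make_clone_set(genos, mito = rep("A", 5))
  lins <- cluster_diploid_lineages(gs)
  expect_equal(nrow(lins$lineages), 2)
  expect_setequal(lins$lineages$n_diploid, c(3, 2))
})

test_that("the mitochondrial haplotype gates lineage membership", {
  g <- dip_geno(10, 11, 14, 44)
  gs <- make_clone_set(list(g, g), mito = c("A", "B"))
  lins <- cluster_diploid_lineages(gs)
  expect_equal(nrow(lins$lineages), 2)
  expect_setequal(lins$lineages$mito, c("A", "B"))
})

test_that("consensus takes the modal allele and breaks ties to the lowest", {
  gmk <- function(a) dip_geno(a, 11, 14, 44)
  expect_equal(consensus_genotype(lapply(c(10, 10, 11), gmk))$hsA$host, 10L)
  expect_equal(consensus_genotype(lapply(c(10, 10, 11, 11), gmk))$hsA$host,
               10L)
  expect_equal(consensus_genotype(lapply(c(11, 11, 10), gmk))$hsA$host, 11L)
  single <- dip_geno(12, 13, 15, 45)
  expect_identical(consensus_genotype(list(single)), single)
  expect_error(consensus_genotype(list()), "empty")
})

test_that("triploids fold into the containing lineage", {
  clone <- dip_geno(10, 11, 14, 44)
  far <- dip_geno(30, 31, 34, 44)
  trip <- make_triploid(clone, list(hsA = 18, hsB = 12, ddA = 16, doA = 33))
  gs <- make_clone_set(list(clone, clone, far, trip),
                       mito = rep("A", 4), ploidy = c(2, 2, 2, 3))
  lins <- cluster_diploid_lineages(gs)
  lins <- assign_triploids(lins, gs)
  rep_ <- lins$triploid_report
  expect_equal(rep_$status, "assigned")
  host_lin <- lins$membership$lineage_id[lins$membership$id == "x01"]
  expect_equal(rep_$lineage_id, host_lin)
  expect_equal(lins$lineages$n_triploid[lins$lineages$id == host_lin], 1)
})

test_that("an unmatched triploid founds a new unresolved lineage", {
  clone <- dip_geno(10, 11, 14, 44)
  lone <- make_triploid(dip_geno(30, 31, 34, 48),
                        list(hsA = 18, hsB = 12, ddA = 16, doA = 33))
  gs <- make_clone_set(list(clone, lone), mito = c("A", "A"),
                       ploidy = c(2, 3))
  lins <- assign_triploids(cluster_diploid_lineages(gs), gs)
  expect_equal(nrow(lins$lineages), 2)
  new_lin <- lins$lineages[lins$lineages$n_triploid == 1, ]
  expect_false(new_lin$resolved)
  expect_null(extract_host_haplotype(lins, new_lin$id))
})

test_that("an equidistant triploid is flagged ambiguous, not auto-assigned", {
  linA <- dip_geno(10, 11, 14, 44)
  linB <- dip_geno(30, 11, 14, 44)   # 20 steps away at hsA: its own lineage
  # triploid whose hsA multiset {10,30} contains either lineage at cost 0
  trip <- make_triploid(linA, list(hsA = 30, hsB = 12, ddA = 16, doA = 33))
  gs <- make_clone_set(list(linA, linB, trip), mito = rep("A", 3),
                       ploidy = c(2, 2, 3))
  lins <- assign_triploids(cluster_diploid_lineages(gs), gs)
  rep_ <- lins$triploid_report
  expect_equal(rep_$status, "ambiguous")
  expect_equal(sort(strsplit(rep_$candidates, ";")[[1]]),
               sort(lins$lineages$id[1:2]))
  # partition property still holds: the triploid sits in its own lineage
  expect_equal(nrow(lins$membership), 3)
  expect_equal(anyDuplicated(lins$membership$id), 0)
})

test_that("two unmatched triploids sharing a clone resolve by intersection", {
  clone <- dip_geno(10, 11, 14, 44)
  t1 <- make_triploid(clone, list(hsA = 18, hsB = 15, ddA = 17, doA = 33))
  t2 <- make_triploid(clone, list(hsA = 19, hsB = 16, ddA = 19, doA = 35))
  gs <- make_clone_set(list(t1, t2, dip_geno(30, 31, 34, 48)),
                       mito = rep("A", 3), ploidy = c(3, 3, 2))
  lins <- assign_triploids(cluster_diploid_lineages(gs), gs)
  grp <- lins$lineages[lins$lineages$n_triploid == 2, ]
  expect_equal(nrow(grp), 1)
  expect_true(grp$resolved)
  h <- extract_host_haplotype(lins, grp$id)
  expect_equal(unname(h[c("hsA", "hsB", "ddA")]), c(10L, 11L, 14L))
})

test_that("host haplome extraction respects locus classes", {
  g <- dip_geno(12, 11, 14, 44)
  gs <- make_clone_set(list(g, g), mito = c("A", "A"))
  lins <- cluster_diploid_lineages(gs)
  h <- extract_host_haplotype(lins, lins$lineages$id)
  expect_equal(unname(h["hsA"]), 12L)
  expect_error(extract_host_haplotype(lins, lins$lineages$id,
                                      included_loci = "doA"),
               "dual_overlapping")
})

test_that("clustering partitions hybrids and is monotone in the distance threshold", {
  sim <- simulate_dataset(sim_params(seed = 21))
  gs <- sim$dataset
  n_lineages <- vapply(c(0, 2, 6, 20, 60), function(thr) {
    lins <- cluster_diploid_lineages(gs, max_step_distance = thr,
                                     max_variable_loci = 99)
    lins <- assign_triploids(lins, gs, tolerance_steps = 2)
    # partition: every hybrid in exactly one lineage
    hyb <- gs$individuals$id[gs$individuals$biotype == "hybrid"]
    expect_setequal(lins$membership$id, hyb)
    expect_equal(anyDuplicated(lins$membership$id), 0)
    sum(lins$lineages$n_diploid > 0)
  }, numeric(1))
  expect_true(all(diff(n_lineages) <= 0))
})

test_that("individuals with no typed locus are refused", {
  g <- dip_geno(10, 11, 14, 44)
  gs <- make_clone_set(list(g, g), mito = c("A", "A"))
  gs$alleles <- gs$alleles[gs$alleles$id != "x02", ]
  expect_error(cluster_diploid_lineages(gs), "missing")
})
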