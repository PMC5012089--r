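#' @title Population-genetic statistics for the sexual host
#'
#' @description
#' Diversity summaries, Hardy-Weinberg and linkage-disequilibrium
#' permutation tests, Weir-Cockerham theta, Michalakis-Excoffier rho_ST
#' with the allele-size permutation test, two-level AMOVA, Cavalli-Sforza
#' and Edwards chord distances, and PCA on individual allele indicators.
#'
#' Theta and rho_ST share one nested analysis-of-variance engine
#' (populations / individuals / gene copies). Applied to allele indicator
#' variables and combined as a ratio of summed components it yields the
#' Weir-Cockerham estimator exactly; applied to allele sizes (repeat
#' counts) it yields the size-based rho_ST. Because a 2-allele locus makes
#' allele size an affine transform of the indicator, rho_ST equals theta
#' identically there.
#'
#' @name popgen_stats
NULL

#' Prepare diploid host genotypes grouped into populations
#'
#' @param gs a `geno_set`.
#' @param min_n minimum number of host individuals for a site to be
#'   retained as a population (default 7).
#' @param loci locus names to use (default: the full panel).
#' @return object of class `pop_data`: `ind` (id, pop), `loci`, and per
#'   locus `states` (sorted allele values) with index vectors `a1`, `a2`
#'   (NA where untyped).
#' @export
pop_data <- function(gs, min_n = 7, loci = gs$loci$name) {
  hosts <- gs$individuals[gs$individuals$biotype == "host", , drop = FALSE]
  if (nrow(hosts) == 0) stop("no host individuals")
  counts <- table(hosts$site)
  keep <- names(counts)[counts >= min_n]
  dropped <- setdiff(names(counts), keep)
  if (length(dropped))
    message(length(dropped), " site(s) below min_n dropped: ",
            paste(dropped, collapse = ", "))
  hosts <- hosts[hosts$site %in% keep, , drop = FALSE]
  al <- gs$alleles[gs$alleles$id %in% hosts$id &
                     gs$alleles$locus %in% loci, , drop = FALSE]
  geno <- list()
  for (l in loci) {
    a <- al[al$locus == l, , drop = FALSE]
    a1 <- rep(NA_integer_, nrow(hosts)); a2 <- a1
    spl <- split(a$allele, a$id)
    hit <- match(names(spl), hosts$id)
    ok <- !is.na(hit) & lengths(spl) == 2
    vals1 <- vapply(spl[ok], function(v) sort(v)[1], numeric(1))
    vals2 <- vapply(spl[ok], function(v) sort(v)[2], numeric(1))
    states <- sort(unique(c(vals1, vals2)))
    a1[hit[ok]] <- match(vals1, states)
    a2[hit[ok]] <- match(vals2, states)
    geno[[l]] <- list(states = states, a1 = a1, a2 = a2)
  }
  structure(list(ind = data.frame(id = hosts$id, pop = hosts$site),
                 loci = loci, geno = geno), class = "pop_data")
}

# Nested ANOVA (populations / individuals / gene copies) on the value
# columns of S (n_states x M). Returns a 3 x M matrix of variance
# components (a = among populations, b = among individuals within, c =
# within individuals). Columns are independent responses (allele
# indicators for theta; allele sizes, or permuted sizes, for rho).
.locus_anova <- function(pop, a1, a2, S) {
  typed <- !is.na(a1) & !is.na(a2)
  pop <- factor(pop[typed]); a1 <- a1[typed]; a2 <- a2[typed]
  pop <- droplevels(pop)
  r <- nlevels(pop)
  M <- ncol(S)
  if (r < 2 || length(a1) < 2)
    return(matrix(NA_real_, 3, M))
  n_i <- as.vector(table(pop))
  N <- sum(n_i)
  if (N - r < 1) return(matrix(NA_real_, 3, M))
  y1 <- S[a1, , drop = FALSE]; y2 <- S[a2, , drop = FALSE]
  ybar_ind <- (y1 + y2) / 2
  SS_g <- colSums((y1 - y2)^2) / 2
  Tp <- rowsum(y1 + y2, pop)                 # pop totals (r x M)
  ybar_pop <- Tp / (2 * n_i)
  R <- rowsum(ybar_ind^2, pop)               # sum of ind means^2 per pop
  SS_b <- 2 * colSums(R - n_i * ybar_pop^2)
  ybar <- colSums(Tp) / (2 * N)
  SS_a <- 2 * colSums(n_i * sweep(ybar_pop, 2, ybar)^2)
  nc <- (N - sum(n_i^2) / N) / (r - 1)
  MS_g <- SS_g / N
  MS_b <- SS_b / (N - r)
  MS_a <- SS_a / (r - 1)
  sig_c <- MS_g
  sig_b <- (MS_b - MS_g) / 2
  sig_a <- (MS_a - MS_b) / (2 * nc)
  rbind(a = sig_a, b = sig_b, c = sig_c)
}

# accumulate per-locus components for a differentiation estimator.
# value_fun(states) returns the S matrix for a locus.
.differentiation <- function(pd, pops = NULL, value_fun) {
  ind <- pd$ind
  sel <- if (is.null(pops)) rep(TRUE, nrow(ind)) else ind$pop %in% pops
  comp <- NULL
  per_locus <- list()
  for (l in pd$loci) {
    g <- pd$geno[[l]]
    S <- value_fun(g$states)
    if (is.null(S)) next
    vc <- .locus_anova(ind$pop[sel], g$a1[sel], g$a2[sel], S)
    if (all(is.na(vc))) next
    vc_sum <- rowSums(vc, na.rm = TRUE)
    per_locus[[l]] <- vc_sum
    comp <- if (is.null(comp)) vc_sum else comp + vc_sum
  }
  if (is.null(comp)) stop("no usable locus")
  list(components = comp,
       estimate = comp[["a"]] / sum(comp),
       per_locus = per_locus)
}

.indicator_S <- function(states) diag(length(states))
.size_S <- function(states) matrix(as.numeric(states), ncol = 1)

# exclude populations represented by a single individual
.check_pop_sizes <- function(pd) {
  sizes <- table(pd$ind$pop)
  singles <- names(sizes)[sizes < 2]
  if (length(singles)) {
    warning("population(s) of size 1 excluded: ",
            paste(singles, collapse = ", "))
    keep <- !(pd$ind$pop %in% singles)
    pd$ind <- pd$ind[keep, , drop = FALSE]
    for (l in pd$loci) {
      pd$geno[[l]]$a1 <- pd$geno[[l]]$a1[keep]
      pd$geno[[l]]$a2 <- pd$geno[[l]]$a2[keep]
    }
  }
  pd
}

#' Weir-Cockerham theta (F_ST)
#'
#' Multi-locus theta combines variance components as a ratio of sums over
#' loci and alleles. Pairwise values restrict the analysis to each
#' population pair; their significance comes from permuting individuals
#' among the two populations.
#'
#' @param pd a [pop_data()].
#' @param pairwise compute the pairwise matrix.
#' @param n_perm permutations for pairwise p-values (0 = none).
#' @param seed RNG seed.
#' @return list: `global`, `per_locus`, `components`, and if requested
#'   `pairwise` (matrix), `pairwise_p`, `pairwise_p_holm`.
#' @export
fst_theta <- function(pd, pairwise = FALSE, n_perm = 1000, seed = 1) {
  pd <- .check_pop_sizes(pd)
  res <- .differentiation(pd, NULL, .indicator_S)
  out <- list(estimator = "theta", global = res$estimate,
              components = res$components,
              per_locus = vapply(res$per_locus, function(v)
                v[["a"]] / sum(v), numeric(1)))
  if (pairwise)
    out <- c(out, .pairwise_differentiation(pd, .indicator_S, n_perm, seed))
  out
}

#' Michalakis-Excoffier rho_ST with allele-size permutation test
#'
#' The estimator applies the same nested ANOVA to allele sizes (repeat
#' counts). The allele-size permutation test (p-rho_ST) permutes the size
#' labels among the allelic states at each locus and recomputes rho_ST;
#' a significant result means stepwise mutation contributes to the
#' differentiation beyond drift.
#'
#' @param pd a [pop_data()].
#' @param n_size_perm allele-size permutations (default 20000).
#' @param pairwise,n_perm,seed as in [fst_theta()].
#' @return list: `global`, `components`, `per_locus`, `size_perm_p`,
#'   `size_perm_null` (the permutation distribution), and pairwise tables
#'   if requested.
#' @export
rho_st <- function(pd, n_size_perm = 20000, pairwise = FALSE,
                   n_perm = 1000, seed = 1) {
  pd <- .check_pop_sizes(pd)
  res <- .differentiation(pd, NULL, .size_S)
  out <- list(estimator = "rho", global = res$estimate,
              components = res$components,
              per_locus = vapply(res$per_locus, function(v)
                v[["a"]] / sum(v), numeric(1)))
  if (n_size_perm > 0) {
    set.seed(child_seed(seed, 7L))
    comp_perm <- matrix(0, 3, n_size_perm)
    ok <- FALSE
    for (l in pd$loci) {
      g <- pd$geno[[l]]
      k <- length(g$states)
      if (k < 2) next
      Sp <- vapply(seq_len(n_size_perm), function(b)
        as.numeric(g$states[sample.int(k)]), numeric(k))
      vc <- .locus_anova(pd$ind$pop, g$a1, g$a2, Sp)
      if (all(is.na(vc))) next
      comp_perm <- comp_perm + vc
      ok <- TRUE
    }
    if (ok) {
      null_rho <- comp_perm[1, ] / colSums(comp_perm)
      out$size_perm_null <- null_rho
      out$size_perm_p <- (sum(null_rho >= out$global - 1e-12) + 1) /
        (n_size_perm + 1)
    }
  }
  if (pairwise)
    out <- c(out, .pairwise_differentiation(pd, .size_S, n_perm, seed))
  out
}

# pairwise estimates + individual-permutation p-values, Holm-corrected
.pairwise_differentiation <- function(pd, value_fun, n_perm, seed) {
  pops <- sort(unique(pd$ind$pop))
  np <- length(pops)
  est <- matrix(NA_real_, np, np, dimnames = list(pops, pops))
  pmat <- est
  set.seed(child_seed(seed, 11L))
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    pair <- c(pops[i], pops[j])
    obs <- .differentiation(pd, pair, value_fun)$estimate
    est[i, j] <- est[j, i] <- obs
    if (n_perm > 0) {
      sel <- pd$ind$pop %in% pair
      labs <- pd$ind$pop[sel]
      count <- 0L
      pd_perm <- pd
      for (b in seq_len(n_perm)) {
        pd_perm$ind$pop[sel] <- sample(labs)
        st <- tryCatch(.differentiation(pd_perm, pair, value_fun)$estimate,
                       error = function(e) NA_real_)
        count <- count + (!is.na(st) && st >= obs - 1e-12)
      }
      pmat[i, j] <- pmat[j, i] <- (count + 1) / (n_perm + 1)
    }
  }
  ph <- pmat
  ut <- upper.tri(pmat)
  ph[ut] <- stats::p.adjust(pmat[ut], method = "holm")
  ph[lower.tri(ph)] <- t(ph)[lower.tri(ph)]
  list(pairwise = est, pairwise_p = pmat, pairwise_p_holm = ph)
}

#' Two-level AMOVA (regions / populations / gene copies)
#'
#' Hierarchical partition of allelic variance into among-groups,
#' among-populations-within-groups and within-populations components,
#' using allele identity (`mode = "theta"`) or squared allele-size
#' differences (`mode = "rho"`). F_CT significance comes from permuting
#' whole populations among groups.
#'
#' @param pd a [pop_data()].
#' @param grouping named character vector: population -> group.
#' @param mode `"theta"` or `"rho"`.
#' @param n_perm permutations for the F_CT test.
#' @param seed RNG seed.
#' @return list: `sigma` (raw components), `sigma_pct` (percentages after
#'   truncating negative components to 0), `f_ct`, `f_sc`, `f_st`,
#'   `ss` (sums of squares per stratum), `p_fct`.
#' @export
amova_two_level <- function(pd, grouping, mode = c("theta", "rho"),
                            n_perm = 1000, seed = 1) {
  mode <- match.arg(mode)
  value_fun <- if (mode == "theta") .indicator_S else .size_S
  pops <- sort(unique(pd$ind$pop))
  if (!all(pops %in% names(grouping)))
    stop("grouping must name every population")
  groups <- grouping[pops]
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  # per-locus gene-copy count matrices pops x states
  count_mats <- lapply(pd$loci, function(l) {
    g <- pd$geno[[l]]
    typed <- !is.na(g$a1)
    pop <- factor(pd$ind$pop[typed], levels = pops)
    idx <- factor(c(g$a1[typed], g$a2[typed]),
                  levels = seq_along(g$states))
    tab <- table(rep(pop, 2), idx)
    matrix(as.numeric(tab), nrow = length(pops),
           dimnames = list(pops, NULL))
  })
  names(count_mats) <- pd$loci
  states_list <- lapply(pd$loci, function(l) pd$geno[[l]]$states)
  names(states_list) <- pd$loci

  fct_from_groups <- function(groups) {
    sig <- c(0, 0, 0); ss <- c(0, 0, 0)
    for (l in pd$loci) {
      C <- count_mats[[l]]
      S <- value_fun(states_list[[l]])
      res <- .copy_amova(C, groups, S)
      if (any(is.na(res$sigma))) next
      sig <- sig + res$sigma
      ss <- ss + res$ss
    }
    list(sigma = sig, ss = ss)
  }
  obs <- fct_from_groups(groups)
  sigma <- obs$sigma
  f_ct <- sigma[1] / sum(sigma)
  f_sc <- sigma[2] / (sigma[2] + sigma[3])
  f_st <- (sigma[1] + sigma[2]) / sum(sigma)
  p_fct <- NA_real_
  if (n_perm > 0) {
    set.seed(child_seed(seed, 13L))
    count <- 0L
    for (b in seq_len(n_perm)) {
      gp <- sample(groups)
      names(gp) <- pops
      fp <- fct_from_groups(gp)
      fct_p <- fp$sigma[1] / sum(fp$sigma)
      count <- count + (fct_p >= f_ct - 1e-12)
    }
    p_fct <- (count + 1) / (n_perm + 1)
  }
  trunc_sig <- pmax(sigma, 0)
  list(sigma = stats::setNames(sigma, c("among_groups",
                                        "among_pops_within", "within_pops")),
       sigma_pct = 100 * trunc_sig / sum(trunc_sig),
       f_ct = f_ct, f_sc = f_sc, f_st = f_st,
       ss = stats::setNames(obs$ss, c("among_groups", "among_pops_within",
                                      "within_pops")),
       p_fct = p_fct, mode = mode)
}

# gene-copy AMOVA for one locus from a pops x states count matrix
.copy_amova <- function(C, groups, S) {
  c_i <- rowSums(C)
  keep <- c_i > 0
  C <- C[keep, , drop = FALSE]; c_i <- c_i[keep]
  groups <- groups[keep]
  P <- nrow(C); G <- length(unique(groups)); N <- sum(c_i)
  if (P < 2 || G < 2 || N <= P)
    return(list(sigma = rep(NA_real_, 3), ss = rep(NA_real_, 3)))
  M <- ncol(S)
  Tm <- C %*% S                       # pop totals      (P x M)
  Q <- C %*% (S^2)
  ybar_pop <- Tm / c_i
  gf <- factor(groups)
  T_G <- rowsum(Tm, gf); C_G <- as.vector(rowsum(c_i, gf))
  ybar_G <- T_G / C_G
  ybar <- colSums(Tm) / N
  SS_wp <- sum(Q - c_i * ybar_pop^2)
  SS_apg <- sum(c_i * ybar_pop^2) - sum(C_G * ybar_G^2)
  SS_ag <- sum(C_G * ybar_G^2) - N * sum(ybar^2)
  df_wp <- N - P; df_apg <- P - G; df_ag <- G - 1
  if (df_apg < 1)
    return(list(sigma = rep(NA_real_, 3), ss = rep(NA_real_, 3)))
  grp_of <- split(c_i, gf)
  s1 <- sum(vapply(grp_of, function(v) sum(v^2) / sum(v), numeric(1)))
  n1 <- (N - s1) / df_apg
  n2 <- (s1 - sum(c_i^2) / N) / df_ag
  n3 <- (N - sum(C_G^2) / N) / df_ag
  MS_wp <- SS_wp / df_wp; MS_apg <- SS_apg / df_apg; MS_ag <- SS_ag / df_ag
  sig_c <- MS_wp
  sig_b <- (MS_apg - sig_c) / n1
  sig_a <- (MS_ag - sig_c - n2 * sig_b) / n3
  list(sigma = c(sig_a, sig_b, sig_c), ss = c(SS_ag, SS_apg, SS_wp))
}

#' Per-population diversity summary
#'
#' @param pd a [pop_data()].
#' @return list: `per_locus` data.frame (pop, locus, n, k, he) with Nei's
#'   unbiased gene diversity he = 2n/(2n-1) (1 - sum p^2), and `per_pop`
#'   panel means (n sites x mean k, H_S).
#' @export
pop_summary <- function(pd) {
  rows <- list()
  for (p in sort(unique(pd$ind$pop))) {
    sel <- pd$ind$pop == p
    for (l in pd$loci) {
      g <- pd$geno[[l]]
      a <- c(g$a1[sel], g$a2[sel])
      a <- a[!is.na(a)]
      n <- length(a) / 2
      if (n == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          pop = p, locus = l, n = 0, k = NA_integer_, he = NA_real_)
        next
      }
      freqs <- as.vector(table(factor(a, levels = seq_along(g$states)))) /
        length(a)
      he <- (2 * n / (2 * n - 1)) * (1 - sum(freqs^2))
      rows[[length(rows) + 1L]] <- data.frame(
        pop = p, locus = l, n = n, k = sum(freqs > 0), he = he)
    }
  }
  per_locus <- do.call(rbind, rows)
  per_pop <- do.call(rbind, lapply(split(per_locus, per_locus$pop),
    function(d) data.frame(pop = d$pop[1],
                           mean_k = mean(d$k, na.rm = TRUE),
                           h_s = mean(d$he, na.rm = TRUE))))
  rownames(per_pop) <- NULL
  list(per_locus = per_locus, per_pop = per_pop)
}

#' Hardy-Weinberg permutation test for one population and locus
#'
#' The statistic is Fis = 1 - Ho/He; the null distribution shuffles the
#' 2n alleles among genotype slots. Two-sided extremeness (both
#' heterozygote deficiency and excess count).
#'
#' @param a1,a2 the two allele values per individual (NA dropped pairwise).
#' @param n_iter permutations (default 10000).
#' @param seed RNG seed.
#' @return list (fis, p); monomorphic loci give p = 1 by convention.
#' @export
hwe_test <- function(a1, a2, n_iter = 10000, seed = 1) {
  typed <- !is.na(a1) & !is.na(a2)
  a1 <- a1[typed]; a2 <- a2[typed]
  n <- length(a1)
  if (n < 5) stop("need at least 5 typed genotypes")
  pool <- c(a1, a2)
  if (length(unique(pool)) < 2) return(list(fis = NA_real_, p = 1))
  fis <- function(x, y) {
    ho <- mean(x != y)
    p <- table(c(x, y)) / (2 * length(x))
    he <- 1 - sum(p^2)
    1 - ho / he
  }
  obs <- fis(a1, a2)
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_iter)) {
    perm <- sample(pool)
    count <- count + (abs(fis(perm[1:n], perm[(n + 1):(2 * n)])) >=
                        abs(obs) - 1e-12)
  }
  list(fis = obs, p = (count + 1) / (n_iter + 1))
}

#' Population-level Hardy-Weinberg test across loci
#'
#' @param pd a [pop_data()].
#' @param pop population id.
#' @param n_iter,seed as in [hwe_test()].
#' @return list: `per_locus` (locus, fis, p) and `p_global` (Fisher's
#'   method across loci).
#' @export
global_hwe <- function(pd, pop, n_iter = 10000, seed = 1) {
  sel <- pd$ind$pop == pop
  rows <- list()
  for (l in pd$loci) {
    g <- pd$geno[[l]]
    res <- tryCatch(hwe_test(g$a1[sel], g$a2[sel], n_iter,
                             child_seed(seed, match(l, pd$loci))),
                    error = function(e) list(fis = NA_real_, p = NA_real_))
    rows[[l]] <- data.frame(locus = l, fis = res$fis, p = res$p)
  }
  per_locus <- do.call(rbind, rows)
  list(per_locus = per_locus, p_global = fisher_combine(per_locus$p))
}

#' Linkage-disequilibrium permutation test for a locus pair
#'
#' G statistic on the two-locus genotype contingency table; the null
#' permutes one locus' genotypes among individuals.
#'
#' @param g1,g2 character vectors of genotype labels (e.g. "12/14"),
#'   NA dropped pairwise.
#' @param n_iter permutations.
#' @param seed RNG seed.
#' @return list (g_stat, p); monomorphic loci give p = 1.
#' @export
ld_test <- function(g1, g2, n_iter = 10000, seed = 1) {
  typed <- !is.na(g1) & !is.na(g2)
  g1 <- g1[typed]; g2 <- g2[typed]
  if (length(g1) < 5) stop("need at least 5 individuals typed at both loci")
  if (length(unique(g1)) < 2 || length(unique(g2)) < 2)
    return(list(g_stat = NA_real_, p = 1))
  gstat <- function(x, y) {
    tab <- table(x, y)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    o <- tab[tab > 0]
    e <- E[tab > 0]
    2 * sum(o * log(o / e))
  }
  obs <- gstat(g1, g2)
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_iter))
    count <- count + (gstat(g1, sample(g2)) >= obs - 1e-12)
  list(g_stat = obs, p = (count + 1) / (n_iter + 1))
}

#' Genotype labels for a locus (helper for [ld_test()])
#'
#' @param pd a [pop_data()].
#' @param locus locus name.
#' @param sel optional logical selector over individuals.
#' @return character vector, NA where untyped.
#' @export
genotype_labels <- function(pd, locus, sel = NULL) {
  g <- pd$geno[[locus]]
  if (is.null(sel)) sel <- rep(TRUE, length(g$a1))
  out <- ifelse(is.na(g$a1[sel]), NA_character_,
                paste(g$states[g$a1[sel]], g$states[g$a2[sel]], sep = "/"))
  out
}

#' Cavalli-Sforza and Edwards chord distances among populations
#'
#' Per locus f = 1 - sum over alleles of sqrt(p1 p2); the multi-locus
#' chord distance is (2/pi) sqrt(2 mean(f)) over loci typed in both
#' populations.
#'
#' @param pd a [pop_data()].
#' @return symmetric distance matrix over populations.
#' @export
dce_matrix <- function(pd) {
  pops <- sort(unique(pd$ind$pop))
  freqs <- lapply(pops, function(p) {
    sel <- pd$ind$pop == p
    lapply(pd$loci, function(l) {
      g <- pd$geno[[l]]
      a <- c(g$a1[sel], g$a2[sel]); a <- a[!is.na(a)]
      if (length(a) == 0) return(NULL)
      as.vector(table(factor(a, levels = seq_along(g$states)))) / length(a)
    })
  })
  names(freqs) <- pops
  D <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (j <= i) next
    f <- c()
    for (l in seq_along(pd$loci)) {
      p1 <- freqs[[i]][[l]]; p2 <- freqs[[j]][[l]]
      if (is.null(p1) || is.null(p2)) next
      f <- c(f, 1 - sum(sqrt(p1 * p2)))
    }
    if (length(f) == 0) stop("populations share no typed locus")
    D[i, j] <- D[j, i] <- (2 / pi) * sqrt(2 * mean(f))
  }
  D
}

#' PCA of individual multilocus genotypes
#'
#' Individuals are coded as allele-indicator vectors (copies of each
#' allele / 2), columns centered, missing loci imputed to the column
#' mean; scores come from the eigendecomposition of the covariance.
#'
#' @param pd a [pop_data()].
#' @param n_axes number of leading axes to return.
#' @return list: `scores` (individuals x axes, with pop attribute),
#'   `eig_share` (proportion of variance per axis), `pop`.
#' @export
pca_scores <- function(pd, n_axes = 4) {
  if (nrow(pd$ind) < 3) stop("need at least 3 individuals")
  blocks <- list()
  for (l in pd$loci) {
    g <- pd$geno[[l]]
    k <- length(g$states)
    m <- matrix(NA_real_, nrow(pd$ind), k)
    typed <- !is.na(g$a1)
    for (s in seq_len(k))
      m[typed, s] <- ((g$a1[typed] == s) + (g$a2[typed] == s)) / 2
    colnames(m) <- paste0(l, ".", g$states)
    blocks[[l]] <- m
  }
  X <- do.call(cbind, blocks)
  keep <- apply(X, 2, function(col) stats::var(col, na.rm = TRUE) > 0)
  if (!any(keep)) stop("all loci monomorphic")
  X <- X[, keep, drop = FALSE]
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  X <- sweep(X, 2, colMeans(X))
  pc <- stats::prcomp(X, center = FALSE)
  n_axes <- min(n_axes, ncol(pc$x))
  list(scores = pc$x[, seq_len(n_axes), drop = FALSE],
       eig_share = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_axes)],
       pop = pd$ind$pop)
}
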