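#' @title Frequency-based assignment of hybrid host haplomes
#'
#' @description
#' Each resolvable hybrid lineage carries a single host haplome (one host
#' allele per haplome-resolvable locus). Its likelihood of originating
#' from a candidate host population is the product over loci of that
#' allele's frequency in the population sample, substituting a small
#' floor (1e-5) for alleles absent from the sample. Percentage scores
#' normalize likelihoods across the candidate populations; a
#' simulation-based probability ranks the observed likelihood against
#' haplomes simulated from the population's own frequencies.
#'
#' @name assignment
NULL

#' Reference allele frequencies from host individuals
#'
#' @param gs a `geno_set`.
#' @param loci locus names (default: all haplome-resolvable loci, i.e.
#'   excluding dual-overlapping).
#' @param pooling optional named list mapping reference-population name ->
#'   character vector of site ids to pool; default one population per
#'   site holding host individuals.
#' @param min_n minimum host individuals per reference population.
#' @return named list: population -> locus -> named frequency vector
#'   (names are allele repeat counts as characters).
#' @export
reference_frequencies <- function(gs, loci = NULL, pooling = NULL,
                                  min_n = 7) {
  if (is.null(loci)) {
    loci <- gs$loci$name[gs$loci$genome_class != "dual_overlapping"]
  }
  hosts <- gs$individuals[gs$individuals$biotype == "host", , drop = FALSE]
  if (is.null(pooling)) {
    pooling <- split(unique(hosts$site), unique(hosts$site))
  }
  al <- gs$alleles[gs$alleles$id %in% hosts$id, , drop = FALSE]
  out <- list()
  for (pop in names(pooling)) {
    ids <- hosts$id[hosts$site %in% pooling[[pop]]]
    if (length(ids) < min_n) next
    a <- al[al$id %in% ids & al$locus %in% loci, , drop = FALSE]
    out[[pop]] <- lapply(stats::setNames(loci, loci), function(l) {
      v <- a$allele[a$locus == l]
      if (length(v) == 0) return(stats::setNames(numeric(0), character(0)))
      tab <- table(v)
      stats::setNames(as.numeric(tab) / sum(tab), names(tab))
    })
  }
  if (length(out) == 0) stop("no reference population reaches min_n")
  out
}

#' Log-likelihood of a host haplome in one population
#'
#' @param h named integer vector: one host allele per locus (NA = missing,
#'   skipped).
#' @param pop_freqs locus -> frequency vector for one population (one
#'   element of [reference_frequencies()]).
#' @param missing_allele_freq frequency substituted for alleles absent
#'   from the population sample (default 1e-5).
#' @return log-likelihood (sum over non-missing loci of log frequency).
#' @export
haplotype_likelihood <- function(h, pop_freqs, missing_allele_freq = 1e-5) {
  h <- h[!is.na(h)]
  if (length(h) == 0) stop("empty haplotype")
  ll <- 0
  for (l in names(h)) {
    f <- pop_freqs[[l]]
    freq <- if (!is.null(f)) unname(f[as.character(h[[l]])]) else NA_real_
    if (is.null(freq) || length(freq) == 0 || is.na(freq))
      freq <- missing_allele_freq
    ll <- ll + log(freq)
  }
  ll
}

#' Assignment scores of a haplome across candidate populations
#'
#' Percentage score of population p is L_p / sum(L) * 100, computed
#' stably from log-likelihoods.
#'
#' @param h haplotype as in [haplotype_likelihood()].
#' @param freqs a [reference_frequencies()] list (>= 2 populations).
#' @param missing_allele_freq see [haplotype_likelihood()].
#' @return data.frame (pop, log_lik, score_pct, top) sorted by the input
#'   population order; scores sum to 100.
#' @export
assignment_scores <- function(h, freqs, missing_allele_freq = 1e-5) {
  if (length(freqs) < 2) stop("need at least 2 candidate populations")
  ll <- vapply(freqs, function(f)
    haplotype_likelihood(h, f, missing_allele_freq), numeric(1))
  score <- exp(ll - logsumexp(ll)) * 100
  data.frame(pop = names(freqs), log_lik = unname(ll),
             score_pct = unname(score),
             top = seq_along(ll) == which.max(ll))
}

#' Simulation-based assignment probability
#'
#' Simulates `n_sim` haplomes by drawing one allele per locus from the
#' population's frequencies and ranks the observed log-likelihood among
#' them: p = (count of simulated log-L <= observed + 1) / (n_sim + 1).
#' Small p means the haplome is unlikely to be a member of the
#' population.
#'
#' @param h haplotype.
#' @param pop_freqs one population's locus -> frequency list.
#' @param n_sim number of simulated haplomes (default 10000).
#' @param seed RNG seed.
#' @param missing_allele_freq see [haplotype_likelihood()].
#' @return probability in (0, 1].
#' @export
simulation_probability <- function(h, pop_freqs, n_sim = 10000, seed = 1,
                                   missing_allele_freq = 1e-5) {
  h <- h[!is.na(h)]
  obs <- haplotype_likelihood(h, pop_freqs, missing_allele_freq)
  set.seed(seed)
  sim_ll <- rep(0, n_sim)
  for (l in names(h)) {
    f <- pop_freqs[[l]]
    if (is.null(f) || length(f) == 0) next
    idx <- sample.int(length(f), n_sim, replace = TRUE,
                      prob = as.numeric(f))
    sim_ll <- sim_ll + log(as.numeric(f))[idx]
  }
  (sum(sim_ll <= obs + 1e-12) + 1) / (n_sim + 1)
}

#' Assign every resolvable lineage to candidate host populations
#'
#' @param lins a `lineage_set`.
#' @param gs the `geno_set`.
#' @param pooling optional pooling map (see [reference_frequencies()]).
#' @param sympatric_sites optional named list lineage -> site ids where
#'   the lineage occurs (derived from membership when NULL).
#' @param n_sim simulated haplomes per lineage x population (0 = skip).
#' @param seed RNG seed.
#' @param min_n minimum reference sample size.
#' @return data.frame: lineage, pop, log_lik, score_pct, top, sympatric,
#'   sim_p. Unresolved (single-triploid) lineages are excluded.
#' @export
assign_lineages <- function(lins, gs, pooling = NULL,
                            sympatric_sites = NULL, n_sim = 10000,
                            seed = 1, min_n = 7) {
  freqs <- reference_frequencies(gs, pooling = pooling, min_n = min_n)
  if (is.null(pooling))
    pooling <- lapply(stats::setNames(names(freqs), names(freqs)), identity)
  resolvable <- lins$lineages$id[lins$lineages$resolved]
  out <- list()
  for (lid in resolvable) {
    h <- extract_host_haplotype(lins, lid)
    if (is.null(h) || all(is.na(h))) next
    sc <- assignment_scores(h, freqs)
    member_sites <- unique(gs$individuals$site[
      gs$individuals$id %in% lins$membership$id[
        lins$membership$lineage_id == lid]])
    if (!is.null(sympatric_sites) && !is.null(sympatric_sites[[lid]]))
      member_sites <- sympatric_sites[[lid]]
    sc$sympatric <- vapply(sc$pop, function(p)
      any(pooling[[p]] %in% member_sites), logical(1))
    sc$sim_p <- NA_real_
    if (n_sim > 0) {
      sc$sim_p <- vapply(seq_len(nrow(sc)), function(i)
        simulation_probability(h, freqs[[sc$pop[i]]], n_sim,
                               child_seed(seed, i + 100L * match(
                                 lid, resolvable))), numeric(1))
    }
    sc$lineage <- lid
    out[[lid]] <- sc[c("lineage", "pop", "log_lik", "score_pct", "top",
                       "sympatric", "sim_p")]
  }
  if (length(out) == 0)
    return(data.frame(lineage = character(), pop = character(),
                      log_lik = numeric(), score_pct = numeric(),
                      top = logical(), sympatric = logical(),
                      sim_p = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
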