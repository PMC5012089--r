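#' @title Synthetic gynogenetic-complex data generator
#'
#' @description
#' Generates datasets with the statistical structure the inference chain
#' assumes: island-model structured sexual host populations (Balding-
#' Nichols frequency draws targeting a chosen differentiation level),
#' clonal hybrid lineages founded by pairing a host haplome (local or
#' dispersed) with a maternal haplome from one shared pool, stepwise-
#' mutation-model divergence within lineages, triploid formation by sperm
#' incorporation, and site-level sampling across regions. Ground truth
#' (lineage labels, founders, source populations, scenario tags) is
#' recorded for recovery tests.
#'
#' @name synthetic_data
NULL

#' Default synthetic locus panel
#'
#' Mirrors a typical gynogenetic-complex marker panel: four host-specific
#' microsatellites, one dual distinguishable microsatellite, one dual
#' distinguishable intron indel, and one dual microsatellite with
#' overlapping parental allele ranges.
#'
#' @return a [locus_panel()].
#' @export
default_locus_panel <- function() {
  locus_panel(
    name = c("msat_h1", "msat_h2", "msat_h3", "msat_h4",
             "msat_d1", "intron_d1", "msat_o1"),
    genome_class = c(rep("host_specific", 4),
                     "dual_distinguishable", "dual_distinguishable",
                     "dual_overlapping"),
    motif_length = c(2L, 2L, 2L, 2L, 2L, 1L, 2L),
    marker_type = c(rep("microsat", 5), "indel", "microsat"))
}

#' Simulation parameters
#'
#' Defaults describe a two-region survey of a sperm-dependent hybrid
#' complex: moderately structured host populations, one to a few
#' hybridization events per occupied site, hundreds of clonal generations
#' of microsatellite divergence, and frequent triploid formation. The
#' mutation rate default (5e-4 per allele per generation) is an
#' order-of-magnitude microsatellite placeholder, not an estimate.
#'
#' @param n_regions number of regions.
#' @param sites_per_region sites per region.
#' @param loci a [locus_panel()].
#' @param fst target host differentiation (Balding-Nichols divergence
#'   parameter); 0 means panmixia.
#' @param lambda_hyb Poisson mean of founding hybridization events per site.
#' @param p_dispersed probability that a founding event's host haplome
#'   comes from a random non-local population (dispersal scenario) instead
#'   of the local one (in-situ scenario).
#' @param clonal_generations clonal generations between founding and
#'   sampling.
#' @param mu per-allele per-generation stepwise mutation rate (symmetric
#'   +/-1 repeat; microsatellite loci only).
#' @param tau probability a sampled hybrid is triploid.
#' @param n_host_per_site,n_hybrid_per_site sample sizes per site.
#' @param n_allele_states number of allelic states per microsatellite pool.
#' @param mito_probs named probabilities of mitochondrial haplotypes for
#'   founding events.
#' @param seed mandatory RNG seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_regions = 2L,
                       sites_per_region = 10L,
                       loci = default_locus_panel(),
                       fst = 0.05,
                       lambda_hyb = 1.5,
                       p_dispersed = 0,
                       clonal_generations = 200L,
                       mu = 5e-4,
                       tau = 0.3,
                       n_host_per_site = 15L,
                       n_hybrid_per_site = 12L,
                       n_allele_states = 20L,
                       mito_probs = c(A = 0.83, B = 0.17),
                       seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(fst >= 0, fst < 1, mu >= 0, mu <= 1, tau >= 0, tau <= 1,
            p_dispersed >= 0, p_dispersed <= 1, lambda_hyb >= 0)
  structure(list(n_regions = n_regions, sites_per_region = sites_per_region,
                 loci = loci, fst = fst, lambda_hyb = lambda_hyb,
                 p_dispersed = p_dispersed,
                 clonal_generations = clonal_generations, mu = mu, tau = tau,
                 n_host_per_site = n_host_per_site,
                 n_hybrid_per_site = n_hybrid_per_site,
                 n_allele_states = n_allele_states,
                 mito_probs = mito_probs, seed = as.integer(seed)),
            class = "sim_params")
}

# Dirichlet draw via gamma variates
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[sample.int(length(g), 1)] <- 1
  g / sum(g)
}

# Balding-Nichols population frequencies around ancestral p with divergence F
bn_freqs <- function(p_anc, fst) {
  if (fst <= 0) return(p_anc)
  rdirichlet1(p_anc * (1 - fst) / fst)
}

#' Simulate clonal descent under the stepwise mutation model
#'
#' Each microsatellite allele mutates independently each generation with
#' probability `mu`, moving +/-1 repeat with equal probability; the walk
#' reflects at 1 repeat so counts never drop below 1. Indel loci do not
#' mutate.
#'
#' @param founder genotype list as returned by [get_genotype()].
#' @param g number of clonal generations.
#' @param mu per-allele per-generation mutation rate.
#' @param loci locus panel (to identify microsatellite loci).
#' @return mutated genotype list.
#' @export
simulate_clonal_descent <- function(founder, g, mu, loci) {
  if (mu == 0 || g == 0) return(founder)
  msat <- loci$name[loci$marker_type == "microsat"]
  for (l in names(founder)) {
    if (!(l %in% msat)) next
    for (h in names(founder[[l]])) {
      a <- founder[[l]][[h]]
      if (length(a) == 0) next
      founder[[l]][[h]] <- vapply(a, function(x) {
        m <- stats::rbinom(1, g, mu)
        if (m > 0) {
          for (s in sample(c(-1L, 1L), m, replace = TRUE)) {
            x <- x + s
            if (x < 1) x <- 2L - x  # reflect at 1 repeat
          }
        }
        as.integer(x)
      }, integer(1))
    }
  }
  founder
}

#' Simulate a full dataset with ground truth
#'
#' @param params a [sim_params()].
#' @return list with elements `dataset` (a [geno_set()]), `truth`
#'   (data.frame: id, lineage, site, source_pop, scenario, mito),
#'   `founders` (list of founder genotypes per lineage) and `params`.
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  loci <- params$loci
  n_sites <- params$n_regions * params$sites_per_region
  site_ids <- sprintf("S%02d", seq_len(n_sites))
  regions <- rep(sprintf("R%d", seq_len(params$n_regions)),
                 each = params$sites_per_region)
  # two regional clusters of coordinates ~100 km apart
  sites <- data.frame(
    id = site_ids, region = regions,
    x = stats::runif(n_sites, 0, 60) +
      100 * (as.integer(factor(regions)) - 1),
    y = stats::runif(n_sites, 0, 60))

  if (params$lambda_hyb == 0 && params$n_hybrid_per_site > 0)
    stop("lambda_hyb = 0 but hybrid sampling requested")

  k <- params$n_allele_states
  # allelic state pools (integer repeat counts); maternal pools offset so
  # dual_distinguishable loci are resolvable, overlapping for msat_o-type
  pools <- list()
  for (l in seq_len(nrow(loci))) {
    nm <- loci$name[l]
    host_states <- 10:(10 + k - 1)
    if (loci$marker_type[l] == "indel") host_states <- 10:15
    mat_states <- switch(loci$genome_class[l],
                         host_specific = integer(0),
                         dual_distinguishable =
                           (max(host_states) + 21):(max(host_states) + 21 +
                                                      length(host_states) - 1),
                         dual_overlapping = host_states + 5L)
    p_anc <- rdirichlet1(rep(1, length(host_states)))
    pop_freqs <- lapply(seq_len(n_sites), function(s)
      bn_freqs(p_anc, params$fst))
    mat_freq <- if (length(mat_states))
      rdirichlet1(rep(1, length(mat_states))) else numeric(0)
    pools[[nm]] <- list(host_states = host_states, mat_states = mat_states,
                        pop_freqs = pop_freqs, mat_freq = mat_freq)
  }
  draw_host_allele <- function(locus, site_idx, n = 1L) {
    p <- pools[[locus]]
    as.integer(sample(p$host_states, n, replace = TRUE,
                      prob = p$pop_freqs[[site_idx]]))
  }
  draw_mat_allele <- function(locus) {
    p <- pools[[locus]]
    as.integer(sample(p$mat_states, 1, prob = p$mat_freq))
  }

  individuals <- list(); allele_rows <- list(); truth <- list()
  founders <- list()
  add_alleles <- function(id, geno) {
    rows <- list()
    for (l in names(geno)) {
      for (h in HAPLOMES) {
        a <- geno[[l]][[h]]
        if (length(a))
          rows[[length(rows) + 1L]] <- data.frame(
            id = id, locus = l, haplome = h, allele = a)
      }
    }
    do.call(rbind, rows)
  }

  # founding hybridization events
  lineage_counter <- 0L
  lineages_by_site <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    n_events <- stats::rpois(1, params$lambda_hyb)
    if (n_events == 0) next
    for (e in seq_len(n_events)) {
      lineage_counter <- lineage_counter + 1L
      dispersed <- stats::runif(1) < params$p_dispersed
      src <- if (dispersed) sample(setdiff(seq_len(n_sites), s), 1) else s
      geno <- list()
      for (l in seq_len(nrow(loci))) {
        nm <- loci$name[l]; cls <- loci$genome_class[l]
        host_a <- draw_host_allele(nm, src, 1L)
        if (cls == "host_specific") {
          geno[[nm]] <- list(host = host_a, maternal = integer(0),
                             un = integer(0))
        } else if (cls == "dual_distinguishable") {
          geno[[nm]] <- list(host = host_a, maternal = draw_mat_allele(nm),
                             un = integer(0))
        } else {
          geno[[nm]] <- list(host = integer(0), maternal = integer(0),
                             un = sort(c(host_a, draw_mat_allele(nm))))
        }
      }
      lid <- sprintf("TL%03d", lineage_counter)
      founders[[lid]] <- geno
      lineages_by_site[[s]] <- c(lineages_by_site[[s]], lid)
      truth[[length(truth) + 1L]] <- data.frame(
        id = NA_character_, lineage = lid, site = site_ids[s],
        source_pop = site_ids[src],
        scenario = if (dispersed) "dispersed" else "in_situ",
        mito = sample(names(params$mito_probs), 1,
                      prob = params$mito_probs))
    }
  }
  lineage_meta <- do.call(rbind, truth)
  truth <- list()

  ind_counter <- 0L
  # sample hosts and hybrids per site
  for (s in seq_len(n_sites)) {
    for (j in seq_len(params$n_host_per_site)) {
      ind_counter <- ind_counter + 1L
      id <- sprintf("H%04d", ind_counter)
      geno <- list()
      for (l in seq_len(nrow(loci))) {
        nm <- loci$name[l]
        geno[[nm]] <- list(host = sort(draw_host_allele(nm, s, 2L)),
                           maternal = integer(0), un = integer(0))
      }
      individuals[[length(individuals) + 1L]] <- data.frame(
        id = id, site = site_ids[s], biotype = "host", ploidy = 2L,
        mito = NA_character_)
      allele_rows[[length(allele_rows) + 1L]] <- add_alleles(id, geno)
    }
    local_lineages <- lineages_by_site[[s]]
    if (length(local_lineages) == 0) next
    for (j in seq_len(params$n_hybrid_per_site)) {
      ind_counter <- ind_counter + 1L
      id <- sprintf("X%04d", ind_counter)
      lid <- if (length(local_lineages) == 1) local_lineages else
        sample(local_lineages, 1)
      geno <- simulate_clonal_descent(founders[[lid]],
                                      params$clonal_generations,
                                      params$mu, loci)
      triploid <- stats::runif(1) < params$tau
      if (triploid) {
        for (l in seq_len(nrow(loci))) {
          nm <- loci$name[l]
          sperm <- draw_host_allele(nm, s, 1L)
          if (loci$genome_class[l] == "dual_overlapping") {
            geno[[nm]]$un <- sort(c(geno[[nm]]$un, sperm))
          } else {
            geno[[nm]]$host <- sort(c(geno[[nm]]$host, sperm))
          }
        }
      }
      mito <- lineage_meta$mito[lineage_meta$lineage == lid][1]
      individuals[[length(individuals) + 1L]] <- data.frame(
        id = id, site = site_ids[s], biotype = "hybrid",
        ploidy = if (triploid) 3L else 2L, mito = mito)
      allele_rows[[length(allele_rows) + 1L]] <- add_alleles(id, geno)
      truth[[length(truth) + 1L]] <- data.frame(
        id = id, lineage = lid, site = site_ids[s],
        source_pop = lineage_meta$source_pop[lineage_meta$lineage == lid][1],
        scenario = lineage_meta$scenario[lineage_meta$lineage == lid][1],
        mito = mito)
    }
  }

  dataset <- geno_set(do.call(rbind, individuals),
                      do.call(rbind, allele_rows), loci, sites)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id = character(), lineage = character(), site = character(),
               source_pop = character(), scenario = character(),
               mito = character())
  rownames(truth) <- NULL
  list(dataset = dataset, truth = truth, founders = founders,
       lineage_meta = lineage_meta, params = params)
}
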