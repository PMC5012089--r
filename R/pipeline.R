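#' @title End-to-end analysis pipeline
#'
#' @description
#' Orchestrates simulate/load -> lineage calling -> diversity and spatial
#' statistics -> host population genetics -> assignment, writing a report
#' bundle (CSV tables, Newick tree, JSON report with per-stage
#' bookkeeping). All randomness derives from one root seed spawning
#' per-stage streams, so a config run twice produces byte-identical
#' output.
#'
#' @name cli_pipeline
NULL

#' Build a pipeline configuration
#'
#' @param sim a [sim_params()] for synthetic input, or `NULL` when reading
#'   files.
#' @param input named list of paths (genotype_file, locus_file, site_file,
#'   optional waterway_file) when `sim` is `NULL`.
#' @param max_step_distance,max_variable_loci,triploid_tolerance lineage
#'   calling thresholds (see [cluster_diploid_lineages()],
#'   [assign_triploids()]).
#' @param n_perm named list of permutation counts: lcbd, correlogram,
#'   mantel, pairwise, size_perm, accumulation.
#' @param min_host_n minimum host sample per population.
#' @param pooling assignment pooling map (see [reference_frequencies()]).
#' @param n_sim_assign simulated haplomes per lineage-population test.
#' @param seed root seed (mandatory).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, input = NULL,
                            max_step_distance = 6, max_variable_loci = 3,
                            triploid_tolerance = 2,
                            n_perm = list(), min_host_n = 7,
                            pooling = NULL, n_sim_assign = 1000,
                            seed) {
  if (missing(seed)) stop("every stochastic stage needs a seed")
  defaults <- list(lcbd = 999, correlogram = 999, mantel = 999,
                   pairwise = 0, size_perm = 2000, accumulation = 999)
  n_perm <- utils::modifyList(defaults, n_perm)
  if (is.null(sim) && is.null(input))
    stop("either sim params or input paths are required")
  structure(list(sim = sim, input = input,
                 max_step_distance = max_step_distance,
                 max_variable_loci = max_variable_loci,
                 triploid_tolerance = triploid_tolerance,
                 n_perm = n_perm, min_host_n = min_host_n,
                 pooling = pooling, n_sim_assign = n_sim_assign,
                 seed = as.integer(seed)), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` suppresses
#'   file output.
#' @return the report list, invisibly when writing files. Elements:
#'   `counts` (per-stage bookkeeping), `lineages`, `membership`,
#'   `diversity` (per region), `lcbd`, `correlograms`, `correlation_comparison`,
#'   `popgen`, `amova`, `assignment`, `tree` (Newick), `accumulation`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  report <- list(config_seed = seed)

  # stage 1: data
  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- simulate_dataset(config$sim)
    gs <- sim$dataset
    truth <- sim$truth
  } else {
    gs <- read_dataset(config$input$genotype_file, config$input$locus_file,
                       config$input$site_file)
  }
  ind <- gs$individuals
  report$counts <- list(
    individuals_read = nrow(ind),
    hosts = sum(ind$biotype == "host"),
    hybrids_diploid = sum(ind$biotype == "hybrid" & ind$ploidy == 2),
    hybrids_triploid = sum(ind$biotype == "hybrid" & ind$ploidy == 3),
    rejected_rows = if (!is.null(attr(gs, "rejected")))
      nrow(attr(gs, "rejected")) else 0L)

  # stage 2: lineage calling
  lins <- cluster_diploid_lineages(gs, config$max_step_distance,
                                   config$max_variable_loci)
  lins <- assign_triploids(lins, gs, config$triploid_tolerance)
  tr <- lins$triploid_report
  report$counts$lineages_called <- nrow(lins$lineages)
  report$counts$triploids_assigned <- sum(tr$status == "assigned")
  report$counts$triploids_new_lineage <- sum(tr$status == "new_lineage")
  report$counts$triploids_ambiguous <- sum(tr$status == "ambiguous")
  report$counts$lineages_unresolved_single_triploid <-
    sum(!lins$lineages$resolved & !lins$lineages$ambiguous)
  stopifnot(report$counts$hybrids_diploid + report$counts$hybrids_triploid ==
              nrow(lins$membership))
  if (!is.null(truth)) {
    lab <- lins$membership$lineage_id[match(truth$id, lins$membership$id)]
    report$lineage_recovery_ari <- adjusted_rand_index(truth$lineage, lab)
  }

  # stage 3: diversity and spatial structure, per region and overall
  slm <- site_lineage_matrix(lins, gs)
  report$diversity <- list(total = alpha_beta_gamma(slm))
  region_of <- gs$sites$region[match(rownames(slm), gs$sites$id)]
  report$correlograms <- list()
  report$accumulation <- list()
  first_class <- list()
  for (r in unique(region_of)) {
    sub <- slm[region_of == r, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    report$diversity[[r]] <- alpha_beta_gamma(sub)
    if (nrow(sub) >= 4) {
      dgeo <- site_distances(gs$sites, rownames(sub))
      dresp <- binary_jaccard(sub)
      cg <- tryCatch(
        mantel_correlogram(dresp, dgeo,
                           n_perm = config$n_perm$correlogram,
                           seed = child_seed(seed, 31L)),
        error = function(e) NULL)  # e.g. constant response in tiny regions
      if (!is.null(cg)) {
        report$correlograms[[r]] <- cg
        first_class[[r]] <- cg[1, ]
      }
      report$accumulation[[r]] <-
        accumulation_curve(sub, config$n_perm$accumulation,
                           child_seed(seed, 37L))
    }
  }
  if (length(first_class) >= 2) {
    f1 <- first_class[[1]]; f2 <- first_class[[2]]
    if (is.finite(f1$mantel_r) && is.finite(f2$mantel_r) &&
        abs(f1$mantel_r) < 1 && abs(f2$mantel_r) < 1) {
      report$correlation_comparison <- compare_correlations(
        f1$mantel_r, f1$n_pairs, f2$mantel_r, f2$n_pairs)
      report$correlation_comparison$regions <- names(first_class)[1:2]
    }
  }
  if (nrow(slm) >= 3)
    report$lcbd <- lcbd(slm, n_perm = config$n_perm$lcbd,
                        seed = child_seed(seed, 41L))

  # stage 4: clonal structure among resolvable consensus genotypes
  resolvable <- lins$lineages$id[lins$lineages$resolved]
  if (length(resolvable) >= 3) {
    genos <- lins$consensus[resolvable]
    m <- slot_matrix_from_genotypes(genos, gs$loci,
                                    clonal_loci(gs$loci))
    cons_d <- pairwise_from_slots(m)$steps
    report$divergence <- divergence_summary(
      lins$diploid_dist, lins$membership[lins$membership$ploidy == 2, ],
      cons_d)
    report$tree <- ape::write.tree(neighbor_joining(cons_d))
  }

  # stage 5: host population genetics
  pops_ok <- table(ind$site[ind$biotype == "host"]) >= config$min_host_n
  if (sum(pops_ok) >= 2) {
    pd <- pop_data(gs, min_n = config$min_host_n)
    report$popgen <- list(
      summary = pop_summary(pd)$per_pop,
      theta = fst_theta(pd, pairwise = FALSE)$global,
      rho = rho_st(pd, n_size_perm = config$n_perm$size_perm,
                   seed = child_seed(seed, 43L))[c("global", "size_perm_p")])
    grouping <- stats::setNames(
      gs$sites$region[match(sort(unique(pd$ind$pop)), gs$sites$id)],
      sort(unique(pd$ind$pop)))
    if (length(unique(grouping)) >= 2) {
      report$amova <- amova_two_level(pd, grouping, mode = "theta",
                                      n_perm = config$n_perm$pairwise,
                                      seed = child_seed(seed, 47L))[
                                        c("sigma", "f_ct", "p_fct")]
    }
  }

  # stage 6: assignment
  report$assignment <- tryCatch(
    assign_lineages(lins, gs, pooling = config$pooling,
                    n_sim = config$n_sim_assign,
                    seed = child_seed(seed, 53L),
                    min_n = config$min_host_n),
    error = function(e) NULL)
  if (!is.null(truth) && !is.null(report$assignment) &&
      nrow(report$assignment) > 0) {
    top <- report$assignment[report$assignment$top, ]
    src <- truth$source_pop[match(
      vapply(top$lineage, function(lid)
        lins$membership$id[lins$membership$lineage_id == lid][1],
        character(1)), truth$id)]
    ok <- !is.na(src)
    report$assignment_top_accuracy <- mean(top$pop[ok] == src[ok])
  }

  report$lineages <- lins$lineages
  report$membership <- lins$membership

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(lins$lineages, file.path(out_dir, "lineages.csv"),
                     row.names = FALSE)
    utils::write.csv(lins$membership, file.path(out_dir, "membership.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(slm),
                     file.path(out_dir, "site_lineage_matrix.csv"))
    if (!is.null(report$lcbd))
      utils::write.csv(report$lcbd, file.path(out_dir, "lcbd.csv"),
                       row.names = FALSE)
    for (r in names(report$correlograms))
      utils::write.csv(report$correlograms[[r]],
                       file.path(out_dir, paste0("correlogram_", r, ".csv")),
                       row.names = FALSE)
    if (!is.null(report$tree))
      writeLines(report$tree, file.path(out_dir, "consensus_nj.nwk"))
    if (!is.null(report$assignment))
      utils::write.csv(report$assignment,
                       file.path(out_dir, "assignment.csv"),
                       row.names = FALSE)
    report_json <- report
    report_json$lineages <- NULL; report_json$membership <- NULL
    writeLines(.simple_json(report_json),
               file.path(out_dir, "report.json"))
    return(invisible(report))
  }
  report
}

# minimal JSON serializer for the report (lists, data.frames, atomics)
.simple_json <- function(x, indent = 0) {
  pad <- strrep(" ", indent)
  if (is.data.frame(x)) {
    rows <- vapply(seq_len(nrow(x)), function(i)
      .simple_json(as.list(x[i, , drop = FALSE]), indent + 2), character(1))
    return(paste0("[", paste(rows, collapse = ","), "]"))
  }
  if (is.list(x)) {
    nm <- names(x)
    items <- vapply(seq_along(x), function(i) {
      key <- if (!is.null(nm) && nzchar(nm[i])) paste0("\"", nm[i], "\":")
      else ""
      paste0(key, .simple_json(x[[i]], indent + 2))
    }, character(1))
    open <- if (is.null(nm)) "[" else "{"
    close <- if (is.null(nm)) "]" else "}"
    return(paste0(open, paste(items, collapse = ","), close))
  }
  if (length(x) != 1) {
    return(paste0("[", paste(vapply(x, .simple_json, character(1)),
                             collapse = ","), "]"))
  }
  if (is.character(x) || is.factor(x))
    return(paste0("\"", gsub("\"", "\\\\\"", as.character(x)), "\""))
  if (is.logical(x)) return(if (is.na(x)) "null" else tolower(as.character(x)))
  if (is.na(x)) return("null")
  format(x, digits = 10, scientific = FALSE, trim = TRUE)
}
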