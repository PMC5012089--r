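#' @title Clonal lineage calling
#'
#' @description
#' A lineage is the set of hybrid individuals descending clonally from one
#' hybridization event. Diploid hybrids are clustered by single linkage on
#' the stepwise clonal distance, joining two genotypes only if they are
#' within `max_step_distance` steps, differ at no more than
#' `max_variable_loci` loci, and share the mitochondrial haplotype (clones
#' inherit the maternal mitochondrion, so differing haplotypes cannot be
#' the same lineage). Each cluster is summarized by a consensus genotype
#' (per-slot modal allele). Triploids, which carry a lineage's full
#' diploid genotype plus one sperm-derived host haplome, are folded in by
#' containment; unmatched triploids found new lineages whose host haplome
#' is unresolvable when the lineage holds a single triploid only.
#'
#' @name lineage_calling
NULL

#' Cluster diploid hybrids into lineages
#'
#' @param gs a `geno_set`.
#' @param max_step_distance maximum stepwise distance joined by single
#'   linkage (default 6, motivated by the order-of-magnitude gap between
#'   within-lineage variation, a few steps, and among-lineage divergence,
#'   tens of steps).
#' @param max_variable_loci maximum number of differing loci joined
#'   (default 3).
#' @param included_loci loci used for distances; defaults to
#'   [clonal_loci()].
#' @return object of class `lineage_set`: list with `lineages`
#'   (data.frame: id, mito, n_diploid, n_triploid, resolved, ambiguous),
#'   `consensus` (list of genotype lists), `membership` (data.frame: id,
#'   lineage_id, ploidy), and the pairwise distance matrix used
#'   (`diploid_dist`).
#' @export
cluster_diploid_lineages <- function(gs, max_step_distance = 6,
                                     max_variable_loci = 3,
                                     included_loci = clonal_loci(gs$loci)) {
  ind <- gs$individuals
  dips <- ind[ind$biotype == "hybrid" & ind$ploidy == 2, , drop = FALSE]
  if (nrow(dips) == 0) stop("no diploid hybrids to cluster")
  typed <- unique(gs$alleles$id)
  untyped <- setdiff(dips$id, typed)
  if (length(untyped))
    stop("individuals with all loci missing: ", paste(untyped, collapse = ", "))

  m <- slot_matrix(gs, dips$id, included_loci)
  pw <- pairwise_from_slots(m)
  D <- pw$steps; nd <- pw$n_diff_loci
  mito <- dips$mito[match(rownames(D), dips$id)]
  compatible <- D <= max_step_distance & nd <= max_variable_loci &
    outer(mito, mito, "==")
  comp <- .components(compatible)

  # order lineages by decreasing size, then by first member id
  sizes <- table(comp)
  ord <- order(-as.integer(sizes),
               vapply(names(sizes), function(k)
                 min(rownames(D)[comp == k]), character(1)))
  lineage_ids <- character(length(comp))
  lineages <- list(); consensus <- list()
  for (j in seq_along(ord)) {
    k <- names(sizes)[ord[j]]
    members <- rownames(D)[comp == k]
    lmito <- mito[comp == k][1]
    lid <- sprintf("%s-%02d", lmito, sum(vapply(lineages, function(x)
      x$mito == lmito, logical(1))) + 1L)
    lineage_ids[comp == k] <- lid
    consensus[[lid]] <- consensus_genotype(
      lapply(members, function(id) get_genotype(gs, id)))
    lineages[[lid]] <- data.frame(id = lid, mito = lmito,
                                  n_diploid = length(members),
                                  n_triploid = 0L, resolved = TRUE,
                                  ambiguous = FALSE)
  }
  structure(list(
    lineages = do.call(rbind, lineages),
    consensus = consensus,
    membership = data.frame(id = rownames(D), lineage_id = lineage_ids,
                            ploidy = 2L),
    diploid_dist = D,
    included_loci = included_loci,
    loci = gs$loci), class = "lineage_set")
}

# connected components of a logical adjacency matrix (single linkage)
.components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  as.character(comp)
}

#' Consensus genotype of a set of members
#'
#' Per locus and haplome slot, the modal allele; ties break to the
#' numerically lowest allele (deterministic). Invariant slots pass through
#' unchanged. Members missing a locus are ignored for that locus.
#'
#' @param member_genotypes list of genotype lists ([get_genotype()]).
#' @return a genotype list.
#' @export
consensus_genotype <- function(member_genotypes) {
  if (length(member_genotypes) == 0) stop("empty member list")
  all_loci <- unique(unlist(lapply(member_genotypes, names)))
  out <- list()
  for (l in all_loci) {
    slots <- list(host = integer(0), maternal = integer(0), un = integer(0))
    for (h in HAPLOMES) {
      vals <- lapply(member_genotypes, function(g) {
        if (is.null(g[[l]])) return(NULL)
        sort(g[[l]][[h]])
      })
      vals <- vals[!vapply(vals, is.null, logical(1))]
      if (length(vals) == 0) next
      n_slots <- max(lengths(vals))
      if (n_slots == 0) next
      vals <- vals[lengths(vals) == n_slots]
      slot_mat <- do.call(rbind, vals)
      slots[[h]] <- as.integer(apply(slot_mat, 2, modal_value))
    }
    if (sum(lengths(slots)) > 0) out[[l]] <- slots
  }
  out
}

# containment cost of a diploid consensus genotype within a triploid
# genotype at one locus: minimum total |step| cost of matching each
# consensus allele to a distinct triploid allele (per haplome class;
# unlabelled classes enumerate which surplus allele is left out).
.containment_cost_locus <- function(cons, trip) {
  cost <- 0
  for (h in HAPLOMES) {
    ca <- sort(cons[[h]]); ta <- sort(trip[[h]])
    if (length(ca) == 0) next
    if (length(ta) < length(ca)) return(NA_real_)
    if (length(ta) == length(ca)) {
      cost <- cost + .pair_cost(ca, ta)
    } else {
      # choose which triploid alleles to drop (surplus = sperm allele)
      drop_sets <- utils::combn(length(ta), length(ta) - length(ca),
                                simplify = FALSE)
      cost <- cost + min(vapply(drop_sets, function(dr)
        .pair_cost(ca, ta[-dr]), numeric(1)))
    }
  }
  cost
}

# total containment cost over included loci (NA-skipping); list(cost, n_loci)
.containment_cost <- function(cons, trip, included_loci) {
  total <- 0; used <- 0L
  for (l in included_loci) {
    if (is.null(cons[[l]]) || is.null(trip[[l]])) next
    cl <- .containment_cost_locus(cons[[l]], trip[[l]])
    if (is.na(cl)) return(list(cost = Inf, n_loci = 0L))
    total <- total + cl; used <- used + 1L
  }
  list(cost = if (used == 0) Inf else total, n_loci = used)
}

#' Fold triploid hybrids into called lineages
#'
#' A triploid matches a lineage if the lineage's consensus alleles are
#' containable in the triploid's allele multiset at every shared locus
#' with at most `tolerance_steps` total stepwise mutations, and the
#' mitochondrial haplotypes agree. A strictly closest match wins; exact
#' ties are not auto-assigned: the triploid founds its own singleton
#' lineage flagged `ambiguous`, with the candidate lineages reported.
#' Unmatched triploids found new lineages; those sharing their clonal
#' genotype (mutual containment compatibility) are grouped, and groups of
#' two or more triploids are resolvable by per-locus intersection of host
#' alleles, whereas a single-triploid lineage is flagged unresolved.
#'
#' @param lins a `lineage_set` from [cluster_diploid_lineages()].
#' @param gs the `geno_set` containing the triploids.
#' @param tolerance_steps containment tolerance in stepwise mutations
#'   (default 2, absorbing a post-formation mutation).
#' @return updated `lineage_set`; triploid assignments in
#'   `$triploid_report` (id, lineage_id, status, cost, candidates).
#' @export
assign_triploids <- function(lins, gs, tolerance_steps = 2) {
  ind <- gs$individuals
  trips <- ind[ind$biotype == "hybrid" & ind$ploidy == 3, , drop = FALSE]
  report <- list()
  if (nrow(trips) == 0) {
    lins$triploid_report <- data.frame(
      id = character(), lineage_id = character(), status = character(),
      cost = numeric(), candidates = character())
    return(lins)
  }
  included <- lins$included_loci
  unmatched <- list()
  for (i in seq_len(nrow(trips))) {
    id <- trips$id[i]
    tg <- get_genotype(gs, id)
    lids <- lins$lineages$id[lins$lineages$mito == trips$mito[i]]
    costs <- vapply(lids, function(lid)
      .containment_cost(lins$consensus[[lid]], tg, included)$cost,
      numeric(1))
    hit <- which(is.finite(costs) & costs <= tolerance_steps)
    if (length(hit) == 0) {
      unmatched[[id]] <- list(geno = tg, mito = trips$mito[i])
      next
    }
    best <- min(costs[hit])
    winners <- lids[hit][costs[hit] == best]
    if (length(winners) == 1) {
      lid <- winners
      lins$membership <- rbind(lins$membership,
                               data.frame(id = id, lineage_id = lid,
                                          ploidy = 3L))
      lins$lineages$n_triploid[lins$lineages$id == lid] <-
        lins$lineages$n_triploid[lins$lineages$id == lid] + 1L
      report[[id]] <- data.frame(id = id, lineage_id = lid,
                                 status = "assigned", cost = best,
                                 candidates = lid)
    } else {
      # exact tie: flagged ambiguous, becomes its own singleton lineage
      lid <- .new_triploid_lineage(lins, trips$mito[i])
      lins <- .add_lineage(lins, lid, trips$mito[i], tg, id,
                           resolved = FALSE, ambiguous = TRUE)
      report[[id]] <- data.frame(id = id, lineage_id = lid,
                                 status = "ambiguous", cost = best,
                                 candidates = paste(winners, collapse = ";"))
    }
  }
  # group unmatched triploids that share their clonal genotype
  if (length(unmatched)) {
    ids <- names(unmatched)
    n <- length(ids)
    adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) { adj[i, j] <- TRUE; next }
      if (unmatched[[i]]$mito != unmatched[[j]]$mito) next
      adj[i, j] <- .triploids_share_clone(unmatched[[i]]$geno,
                                          unmatched[[j]]$geno, included,
                                          gs$loci)
    }
    adj <- adj & t(adj)
    comp <- .components(adj)
    for (k in unique(comp)) {
      members <- ids[comp == k]
      mito <- unmatched[[members[1]]]$mito
      lid <- .new_triploid_lineage(lins, mito)
      genos <- lapply(members, function(id) unmatched[[id]]$geno)
      if (length(members) >= 2) {
        cons <- .triploid_intersection_consensus(genos, included, gs$loci)
        resolved <- TRUE
      } else {
        cons <- genos[[1]]
        resolved <- FALSE   # single triploid: host haplome unresolvable
      }
      lins <- .add_lineage(lins, lid, mito, cons, members,
                           resolved = resolved, ambiguous = FALSE)
      for (id in members)
        report[[id]] <- data.frame(id = id, lineage_id = lid,
                                   status = "new_lineage", cost = NA_real_,
                                   candidates = "")
    }
  }
  lins$triploid_report <- do.call(rbind, c(report, make.row.names = FALSE))
  lins
}

.new_triploid_lineage <- function(lins, mito) {
  n <- sum(lins$lineages$mito == mito)
  sprintf("%s-%02d", mito, n + 1L)
}

.add_lineage <- function(lins, lid, mito, consensus, member_ids,
                         resolved, ambiguous) {
  lins$lineages <- rbind(lins$lineages,
                         data.frame(id = lid, mito = mito, n_diploid = 0L,
                                    n_triploid = length(member_ids),
                                    resolved = resolved,
                                    ambiguous = ambiguous))
  lins$consensus[[lid]] <- consensus
  lins$membership <- rbind(lins$membership,
                           data.frame(id = member_ids, lineage_id = lid,
                                      ploidy = 3L))
  lins
}

# do two triploid genotypes share a clonal (diploid) core? true when at
# every shared included locus the allele multisets overlap in at least the
# clonal copy number (host: expected minus the one sperm allele; maternal
# and unlabelled alleles must share the clone's copies).
.triploids_share_clone <- function(g1, g2, included_loci, loci) {
  shared <- FALSE
  for (l in included_loci) {
    a <- g1[[l]]; b <- g2[[l]]
    if (is.null(a) || is.null(b)) next
    shared <- TRUE
    cls <- loci$genome_class[loci$name == l]
    need <- expected_allele_counts("hybrid", 2, cls)  # clonal copy numbers
    for (h in HAPLOMES) {
      if (need[[h]] == 0) next
      if (.multiset_intersection_size(a[[h]], b[[h]]) < need[[h]])
        return(FALSE)
    }
  }
  shared
}

.multiset_intersection_size <- function(x, y) {
  tx <- table(x); ty <- table(y)
  common <- intersect(names(tx), names(ty))
  sum(pmin(tx[common], ty[common]))
}

.multiset_intersection <- function(x, y) {
  tx <- table(x); ty <- table(y)
  common <- intersect(names(tx), names(ty))
  as.integer(rep(as.integer(common), pmin(tx[common], ty[common])))
}

# consensus of >= 2 unmatched triploids sharing a clone: per locus, the
# intersection of allele multisets (the sperm alleles differ and drop out);
# reduced to the diploid-hybrid layout where the intersection is unique.
.triploid_intersection_consensus <- function(genos, included_loci, loci) {
  all_loci <- unique(unlist(lapply(genos, names)))
  out <- list()
  for (l in all_loci) {
    gl <- lapply(genos, function(g) g[[l]])
    gl <- gl[!vapply(gl, is.null, logical(1))]
    if (length(gl) == 0) next
    cls <- loci$genome_class[loci$name == l]
    need <- expected_allele_counts("hybrid", 2, cls)
    slots <- list(host = integer(0), maternal = integer(0), un = integer(0))
    for (h in HAPLOMES) {
      inter <- Reduce(.multiset_intersection, lapply(gl, `[[`, h))
      if (need[[h]] > 0 && length(inter) == need[[h]]) {
        slots[[h]] <- sort(inter)
      } else if (need[[h]] > 0) {
        # non-unique or empty intersection: leave missing
        slots[[h]] <- integer(0)
      }
    }
    if (sum(lengths(slots)) > 0) out[[l]] <- slots
  }
  out
}

#' Extract the host haplome of a lineage or individual
#'
#' For a resolvable lineage the haplome is read from the consensus host
#' slots of host-specific and dual-distinguishable loci (dual-overlapping
#' loci cannot be attributed to a parental genome and are refused). For a
#' single-triploid lineage the sperm and clone host alleles cannot be
#' discriminated and `NULL` is returned (unresolved sentinel).
#'
#' @param lins a `lineage_set`.
#' @param lineage_id lineage to extract.
#' @param included_loci loci to report; defaults to all host-specific and
#'   dual-distinguishable loci in the panel.
#' @return named integer vector (NA = missing) or `NULL` if unresolved.
#' @export
extract_host_haplotype <- function(lins, lineage_id,
                                   included_loci = NULL) {
  loci <- lins$loci
  if (is.null(included_loci))
    included_loci <- loci$name[loci$genome_class != "dual_overlapping"]
  if (any(loci$genome_class[match(included_loci, loci$name)] ==
            "dual_overlapping"))
    stop("dual_overlapping locus requested for a haplome-resolved computation")
  row <- lins$lineages[lins$lineages$id == lineage_id, ]
  if (nrow(row) == 0) stop("unknown lineage id")
  if (!row$resolved) return(NULL)
  cons <- lins$consensus[[lineage_id]]
  out <- stats::setNames(rep(NA_integer_, length(included_loci)),
                         included_loci)
  for (l in included_loci) {
    if (is.null(cons[[l]])) next
    hv <- cons[[l]]$host
    if (length(hv) == 1) out[l] <- hv
  }
  out
}
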