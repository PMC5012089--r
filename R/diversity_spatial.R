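#' @title Lineage diversity and spatial autocorrelation
#'
#' @description
#' Site-by-lineage abundance matrices feed a multiplicative diversity
#' partition (alpha = mean per-site richness, gamma = regional richness,
#' beta = gamma/alpha), local contributions to beta diversity (LCBD) from
#' the quantitative Jaccard (Ruzicka) dissimilarity with permutation
#' tests, Mantel tests, and Mantel correlograms with Sturges distance
#' classes and progressive Holm correction.
#'
#' @name diversity_spatial
NULL

#' Build a site-by-lineage abundance matrix
#'
#' @param lins a `lineage_set` (or a membership data.frame with columns
#'   id, lineage_id).
#' @param gs the `geno_set` (for individual -> site mapping).
#' @param drop_empty drop sites without hybrids (default TRUE).
#' @return integer matrix, sites x lineages.
#' @export
site_lineage_matrix <- function(lins, gs, drop_empty = TRUE) {
  membership <- if (inherits(lins, "lineage_set")) lins$membership else lins
  site <- gs$individuals$site[match(membership$id, gs$individuals$id)]
  tab <- table(site, membership$lineage_id)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  if (drop_empty) m <- m[rowSums(m) > 0, , drop = FALSE]
  m
}

#' Multiplicative alpha/beta/gamma diversity partition
#'
#' @param mat site x lineage abundance matrix (sites without any lineage
#'   are dropped with a warning).
#' @return list: gamma (total richness), alpha (mean per-site richness),
#'   beta (= gamma/alpha).
#' @export
alpha_beta_gamma <- function(mat) {
  mat <- as.matrix(mat)
  if (length(mat) == 0 || nrow(mat) == 0) stop("empty site-lineage matrix")
  empty <- rowSums(mat) == 0
  if (any(empty)) {
    warning(sum(empty), " empty site(s) dropped")
    mat <- mat[!empty, , drop = FALSE]
  }
  gamma <- sum(colSums(mat) > 0)
  alpha <- mean(rowSums(mat > 0))
  list(gamma = gamma, alpha = alpha, beta = whittaker_beta(gamma, alpha))
}

#' Quantitative Jaccard (Ruzicka) dissimilarity
#'
#' d(A,B) = 1 - sum(min)/sum(max) over lineage abundances.
#'
#' @param mat site x lineage abundance matrix.
#' @return symmetric dissimilarity matrix.
#' @export
ruzicka_dissimilarity <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    mn <- sum(pmin(mat[i, ], mat[j, ]))
    mx <- sum(pmax(mat[i, ], mat[j, ]))
    D[i, j] <- D[j, i] <- if (mx == 0) NA_real_ else 1 - mn / mx
  }
  D
}

#' Binary Jaccard dissimilarity on presence/absence
#'
#' @param mat site x lineage abundance matrix.
#' @return symmetric dissimilarity matrix; pairs of empty sites are NA
#'   (undefined) with a warning.
#' @export
binary_jaccard <- function(mat) {
  mat <- as.matrix(mat) > 0
  if (nrow(mat) < 2) stop("need at least 2 sites")
  D <- ruzicka_dissimilarity(mat * 1L)
  if (any(is.na(D[upper.tri(D)])))
    warning("pairs of empty sites have undefined dissimilarity (NA)")
  D
}

# Gower-centered matrix from a dissimilarity matrix
.gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  H <- diag(n) - matrix(1 / n, n, n)
  H %*% A %*% H
}

# LCBD values from a dissimilarity matrix: diagonal of the Gower-centered
# matrix over its trace (the total beta sum of squares)
.lcbd_from_D <- function(D) {
  G <- .gower_center(D)
  ss <- diag(G)
  if (sum(ss) <= 1e-14) return(rep(1 / nrow(D), nrow(D)))  # no uniqueness
  ss / sum(ss)
}

#' Local contributions to beta diversity (LCBD)
#'
#' LCBD partitions the total community variance among sites: the
#' site-by-lineage matrix is converted to a dissimilarity matrix
#' (quantitative Jaccard by default), Gower-centered, and each site's
#' share of the total sum of squares is its LCBD; values sum to 1.
#' Significance of each site's contribution is assessed by permuting each
#' lineage's abundances independently across sites.
#'
#' @param mat site x lineage abundance matrix (>= 3 sites, no empty site).
#' @param dissimilarity `"ruzicka"` (abundance-based Jaccard) or
#'   `"binary_jaccard"`.
#' @param n_perm number of permutations for p-values (0 = none).
#' @param seed RNG seed.
#' @return data.frame (site, lcbd, p_value) plus attribute `"ss_total"`.
#' @export
lcbd <- function(mat, dissimilarity = c("ruzicka", "binary_jaccard"),
                 n_perm = 999, seed = 1) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3) stop("LCBD needs at least 3 sites")
  if (any(rowSums(mat) == 0)) stop("site with all-zero abundances")
  dissimilarity <- match.arg(dissimilarity)
  dfun <- switch(dissimilarity, ruzicka = ruzicka_dissimilarity,
                 binary_jaccard = binary_jaccard)
  D <- dfun(mat)
  obs <- .lcbd_from_D(D)
  p <- rep(NA_real_, length(obs))
  if (n_perm > 0) {
    set.seed(seed)
    count <- rep(0L, length(obs))
    for (b in seq_len(n_perm)) {
      perm <- apply(mat, 2, function(col) col[sample.int(nrow(mat))])
      Dp <- suppressWarnings(dfun(perm))
      Dp[is.na(Dp)] <- 0   # permutation may empty a site; treat as identical
      lp <- .lcbd_from_D(Dp)
      count <- count + (lp >= obs - 1e-12)
    }
    p <- (count + 1) / (n_perm + 1)
  }
  out <- data.frame(site = rownames(mat), lcbd = unname(obs),
                    p_value = p)
  attr(out, "ss_total") <- sum(diag(.gower_center(D)))
  out
}

# lower-triangle vector of a symmetric matrix
.lt <- function(m) m[lower.tri(m)]

#' Simple Mantel test
#'
#' Standardized Mantel statistic (Pearson correlation over off-diagonal
#' pairs) with a one-sided (greater) permutation test; for small matrices
#' the permutation distribution can be enumerated exhaustively.
#'
#' @param D1,D2 symmetric matrices with matching labels.
#' @param n_perm number of random permutations.
#' @param seed RNG seed.
#' @param exact enumerate all label permutations (n! must be modest).
#' @return list (r, p, n_perm).
#' @export
mantel_test <- function(D1, D2, n_perm = 999, seed = 1, exact = FALSE) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  stopifnot(all(dim(D1) == dim(D2)))
  if (!is.null(rownames(D1)) && !is.null(rownames(D2)))
    D2 <- D2[rownames(D1), rownames(D1)]
  v1 <- .lt(D1); v2 <- .lt(D2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("Mantel statistic undefined for a constant matrix")
  r_obs <- stats::cor(v1, v2)
  n <- nrow(D1)
  if (exact) {
    perms <- .permutations(n)
    rs <- apply(perms, 1, function(p) stats::cor(.lt(D1[p, p]), v2))
    p <- mean(rs >= r_obs - 1e-12)
    return(list(r = r_obs, p = p, n_perm = nrow(perms)))
  }
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    p_idx <- sample.int(n)
    count <- count + (stats::cor(.lt(D1[p_idx, p_idx]), v2) >= r_obs - 1e-12)
  }
  list(r = r_obs, p = (count + 1) / (n_perm + 1), n_perm = n_perm)
}

#' Mantel correlogram
#'
#' Distance classes are equal-width bins over the observed geographic
#' distances, with the number of classes given by Sturges' rule
#' k = ceiling(1 + log2(m)) applied to the m pairwise distances. Per
#' class, the standardized Mantel statistic between the response
#' dissimilarity and the class-membership indicator is computed and
#' sign-flipped so that positive r means sites within the class are more
#' similar than average. P-values come from permuting the site labels of
#' the response matrix (two-sided) and are corrected progressively
#' (Holm over the classes tested so far, from the shortest distance
#' outward).
#'
#' @param D_response response dissimilarity matrix.
#' @param D_geo geographic distance matrix (same labels).
#' @param n_classes number of distance classes; default Sturges.
#' @param n_perm permutations per class.
#' @param seed RNG seed.
#' @param progressive progressive Holm (default) or simultaneous.
#' @return data.frame (class, d_lower, d_upper, d_center, n_pairs,
#'   mantel_r, p_value, p_holm); classes with < 2 pairs are dropped with
#'   a warning.
#' @export
mantel_correlogram <- function(D_response, D_geo, n_classes = NULL,
                               n_perm = 999, seed = 1, progressive = TRUE) {
  D_response <- as.matrix(D_response); D_geo <- as.matrix(D_geo)
  stopifnot(all(dim(D_response) == dim(D_geo)))
  if (!is.null(rownames(D_response)) && !is.null(rownames(D_geo)))
    D_geo <- D_geo[rownames(D_response), rownames(D_response)]
  if (any(D_geo < 0)) stop("geographic distances must be nonnegative")
  dvec <- .lt(D_response); gvec <- .lt(D_geo)
  if (stats::sd(dvec) == 0)
    stop("constant response matrix: correlogram undefined")
  if (stats::sd(gvec) == 0) stop("constant geographic distances")
  m <- length(gvec)
  if (is.null(n_classes)) n_classes <- ceiling(1 + log2(m))
  breaks <- seq(min(gvec), max(gvec), length.out = n_classes + 1)
  cls <- findInterval(gvec, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  keep <- which(tabulate(cls, n_classes) >= 2)
  if (length(keep) < n_classes)
    warning("dropping ", n_classes - length(keep),
            " distance class(es) with < 2 pairs")
  ind <- lapply(keep, function(k) as.numeric(cls == k))
  r_class <- function(v) vapply(ind, function(ik) -stats::cor(v, ik),
                                numeric(1))
  r_obs <- r_class(dvec)
  set.seed(seed)
  n <- nrow(D_response)
  count <- rep(0L, length(keep))
  for (b in seq_len(n_perm)) {
    p_idx <- sample.int(n)
    rp <- r_class(.lt(D_response[p_idx, p_idx]))
    count <- count + (abs(rp) >= abs(r_obs) - 1e-12)
  }
  p_raw <- (count + 1) / (n_perm + 1)
  data.frame(class = keep,
             d_lower = breaks[keep], d_upper = breaks[keep + 1],
             d_center = (breaks[keep] + breaks[keep + 1]) / 2,
             n_pairs = tabulate(cls, n_classes)[keep],
             mantel_r = r_obs, p_value = p_raw,
             p_holm = holm_progressive(p_raw, progressive))
}

#' Compare two correlation coefficients (Fisher's z)
#'
#' z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3)), with a standard
#' normal reference.
#'
#' @param r1,r2 correlations (|r| < 1).
#' @param n1,n2 sample sizes (>= 4).
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return list (r1, n1, r2, n2, fisher_z, p, alternative).
#' @export
compare_correlations <- function(r1, n1, r2, n2,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 < 4 || n2 < 4) stop("n must be >= 4")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  list(r1 = r1, n1 = n1, r2 = r2, n2 = n2, fisher_z = z, p = p,
       alternative = alternative)
}

#' Euclidean distances among sites
#'
#' @param sites data.frame with id, x, y (projected km).
#' @param ids optional subset/order of site ids.
#' @return labelled distance matrix in km.
#' @export
site_distances <- function(sites, ids = NULL) {
  if (!is.null(ids)) sites <- sites[match(ids, sites$id), , drop = FALSE]
  d <- as.matrix(stats::dist(sites[, c("x", "y")]))
  dimnames(d) <- list(sites$id, sites$id)
  d
}

#' Regional detection summary
#'
#' @param sites site table (id, region).
#' @param occupied_ids ids of sites where the taxon was detected.
#' @return data.frame (region, n_sites, n_occupied, pct) plus a total row.
#' @export
detection_summary <- function(sites, occupied_ids) {
  regions <- unique(sites$region)
  rows <- lapply(regions, function(r) {
    ids <- sites$id[sites$region == r]
    occ <- sum(ids %in% occupied_ids)
    data.frame(region = r, n_sites = length(ids), n_occupied = occ,
               pct = 100 * occ / length(ids))
  })
  occ_all <- sum(sites$id %in% occupied_ids)
  rbind(do.call(rbind, rows),
        data.frame(region = "total", n_sites = nrow(sites),
                   n_occupied = occ_all,
                   pct = 100 * occ_all / nrow(sites)))
}
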