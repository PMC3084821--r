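# Distance-based permutation statistics for comparing multivariate egg
# color distributions: MRPP, Mantel and partial Mantel tests, one-factor
# permutational MANOVA, a multivariate dispersion (Levene-analogue) test,
# and great-circle distance matrices.
#
# All Monte-Carlo p-values follow the add-one convention
# p = (number of permuted statistics as-or-more extreme + 1) / (n_perm + 1)
# and are reproducible given `seed`.

perm_test_result <- function(statistic, p_value, n_perm, seed,
                             alternative = NA_character_, ...) {
  structure(c(list(statistic = statistic, p_value = p_value,
                   n_perm = n_perm, seed = seed,
                   alternative = alternative), list(...)),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  st <- x$statistic
  cat("Permutation test:",
      paste(names(st), "=", format(unname(st), digits = 5),
            collapse = ", "),
      "\n  p =", format(x$p_value, digits = 4),
      paste0("(", x$n_perm, " permutations"),
      if (!is.na(x$alternative)) paste0(", ", x$alternative), ")\n")
  invisible(x)
}

# Accept coordinates (n x p), a dist object, or a square symmetric matrix.
as_dist_matrix <- function(x) {
  if (inherits(x, "dist")) return(as.matrix(x))
  m <- as.matrix(x)
  if (nrow(m) == ncol(m) && nrow(m) > 1 &&
      max(abs(m - t(m))) < 1e-8 && all(abs(diag(m)) < 1e-12))
    return(m)
  as.matrix(dist(m))
}

#' Multiresponse permutation procedure (MRPP)
#'
#' Tests for overall differences between the multivariate distributions of
#' two or more groups, using the Euclidean-distance version: the observed
#' statistic is `delta = sum_i (n_i / N) * (mean within-group pairwise
#' distance of group i)`, compared to its distribution under random
#' permutation of the group labels. The chance-corrected effect size
#' `A = 1 - delta / E[delta]` is always reported, with `E[delta]` the mean
#' pairwise distance over all observations (the expectation of delta under
#' random labels).
#'
#' @param x Coordinates (n x p matrix/data frame), `dist`, or a square
#'   distance matrix.
#' @param groups Group labels; every group needs >= 2 members.
#' @param n_perm Number of label permutations.
#' @param seed Optional RNG seed.
#' @param exhaustive If `TRUE`, enumerate all label permutations
#'   (n <= 9) for an exact p-value instead of Monte-Carlo sampling.
#' @return A `perm_test` with statistic `delta`, effect size `A`,
#'   `E_delta`, and the permutation p-value.
#' @export
mrpp <- function(x, groups, n_perm = 10000, seed = NULL,
                 exhaustive = FALSE) {
  d <- as_dist_matrix(x)
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(d))
  sizes <- table(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2L)) stop("singleton group", call. = FALSE)
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  n <- nrow(d)
  w <- as.numeric(sizes) / n
  delta_for <- function(g) {
    within <- vapply(levels(groups), function(lv) {
      i <- which(g == lv)
      sum(d[i, i]) / (length(i) * (length(i) - 1L))
    }, numeric(1L))
    sum(w * within)
  }
  delta_obs <- delta_for(groups)
  e_delta <- sum(d) / (n * (n - 1L))
  if (exhaustive) {
    perms <- all_permutations(n)
    stats <- apply(perms, 1L, function(p) delta_for(groups[p]))
    # identity permutation included: exact p over the full group
    p_val <- mean(stats <= delta_obs + 1e-12)
    n_perm <- nrow(perms) - 1L
  } else {
    stats <- with_seed(seed, vapply(seq_len(n_perm), function(k)
      delta_for(groups[sample.int(n)]), numeric(1L)))
    p_val <- (sum(stats <= delta_obs + 1e-12) + 1) / (n_perm + 1)
  }
  perm_test_result(c(delta = delta_obs), p_val, n_perm, seed,
                   alternative = "less",
                   A = 1 - delta_obs / e_delta, E_delta = e_delta)
}

# upper-triangle vector of a square matrix
ut <- function(m) m[upper.tri(m)]

#' Mantel test of matrix concordance
#'
#' Pearson correlation between the upper triangles of two distance
#' matrices (e.g. geographic distance vs color contrast), with
#' significance from simultaneous row/column permutation of the second
#' matrix. One-sided toward positive concordance by default.
#'
#' @param d1,d2 Distance structures over the same objects in the same
#'   order (n >= 4).
#' @param n_perm Number of permutations.
#' @param seed Optional RNG seed.
#' @param alternative `"greater"` (default), `"less"`, or `"two.sided"`.
#' @param exhaustive If `TRUE`, enumerate all n! row/column permutations
#'   (n <= 9) for an exact p-value.
#' @return A `perm_test` with statistic `r`.
#' @export
mantel_test <- function(d1, d2, n_perm = 1000, seed = NULL,
                        alternative = c("greater", "less", "two.sided"),
                        exhaustive = FALSE) {
  alternative <- match.arg(alternative)
  m1 <- as_dist_matrix(d1); m2 <- as_dist_matrix(d2)
  n <- nrow(m1)
  if (n != nrow(m2)) stop("matrices differ in size", call. = FALSE)
  if (n < 4L) stop("need at least 4 objects", call. = FALSE)
  v1 <- ut(m1)
  if (sd(v1) == 0 || sd(ut(m2)) == 0)
    stop("constant distance matrix: correlation undefined", call. = FALSE)
  r_obs <- cor(v1, ut(m2))
  stat_fun <- function(p) cor(v1, ut(m2[p, p]))
  if (exhaustive) {
    perms <- all_permutations(n)
    stats <- apply(perms[-1L, , drop = FALSE], 1L, stat_fun)
    p_val <- exact_p(r_obs, stats, nrow(perms), alternative)
    n_perm <- nrow(perms) - 1L
  } else {
    stats <- with_seed(seed, vapply(seq_len(n_perm), function(k)
      stat_fun(sample.int(n)), numeric(1L)))
    p_val <- mc_p(r_obs, stats, n_perm, alternative)
  }
  perm_test_result(c(r = r_obs), p_val, n_perm, seed, alternative)
}

mc_p <- function(obs, stats, n_perm, alternative) {
  b <- switch(alternative,
              greater = sum(stats >= obs - 1e-12),
              less = sum(stats <= obs + 1e-12),
              two.sided = sum(abs(stats) >= abs(obs) - 1e-12))
  (b + 1) / (n_perm + 1)
}

exact_p <- function(obs, stats, n_total, alternative) {
  b <- switch(alternative,
              greater = sum(stats >= obs - 1e-12),
              less = sum(stats <= obs + 1e-12),
              two.sided = sum(abs(stats) >= abs(obs) - 1e-12))
  (b + 1) / n_total
}

#' Partial Mantel test
#'
#' Correlation between `d1` and `d2` controlling for a third matrix `d3`
#' (e.g. color vs geography controlling for collection year): the
#' first-order partial correlation of the upper triangles. Significance
#' comes from row/column permutation of the residualized first matrix:
#' both `d1` and `d2` are replaced by their elementwise least-squares
#' residuals on `d3`, and the residual matrix of `d1` is permuted.
#'
#' @inheritParams mantel_test
#' @param d3 Distance structure for the controlled variable.
#' @return A `perm_test` with statistic `r` (partial correlation).
#' @export
partial_mantel <- function(d1, d2, d3, n_perm = 1000, seed = NULL,
                           alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  m1 <- as_dist_matrix(d1); m2 <- as_dist_matrix(d2)
  m3 <- as_dist_matrix(d3)
  n <- nrow(m1)
  if (nrow(m2) != n || nrow(m3) != n)
    stop("matrices differ in size", call. = FALSE)
  if (n < 4L) stop("need at least 4 objects", call. = FALSE)
  r1 <- residual_matrix(m1, m3)
  r2 <- residual_matrix(m2, m3)
  v2 <- ut(r2)
  if (sd(ut(r1)) == 0 || sd(v2) == 0)
    stop("constant residual matrix: correlation undefined", call. = FALSE)
  r_obs <- cor(ut(r1), v2)
  stats <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    cor(ut(r1[p, p]), v2)
  }, numeric(1L)))
  p_val <- mc_p(r_obs, stats, n_perm, alternative)
  perm_test_result(c(r = r_obs), p_val, n_perm, seed, alternative)
}

# elementwise least-squares residuals of matrix a on matrix b
# (computed on the upper triangle, mirrored back into symmetric form)
residual_matrix <- function(a, b) {
  va <- ut(a); vb <- ut(b)
  fit <- if (sd(vb) == 0) mean(va) else {
    beta <- cov(va, vb) / var(vb)
    mean(va) + beta * (vb - mean(vb))
  }
  res <- va - fit
  out <- matrix(0, nrow(a), ncol(a))
  out[upper.tri(out)] <- res
  out + t(out)
}

#' One-factor permutational MANOVA
#'
#' Partitions the variation in a distance matrix by one covariate
#' (categorical factor or single continuous regressor) via the Gower
#' centering of the squared distances: `pseudo-F =
#' (SS_model / df_model) / (SS_resid / df_resid)`, with partial
#' `R^2 = SS_model / SS_total`. Significance comes from permutation of
#' the raw observations (rows of the distance matrix). For Euclidean
#' distances and a categorical factor the pseudo-F equals the classical
#' one-way ANOVA F.
#'
#' @param x Coordinates, `dist`, or square distance matrix.
#' @param covariate Factor or numeric vector, one value per observation.
#' @param n_perm Number of permutations.
#' @param seed Optional RNG seed.
#' @return A `perm_test` with statistic `F`, plus `R2`, `df_model`,
#'   `df_residual`.
#' @export
permanova_1factor <- function(x, covariate, n_perm = 10000, seed = NULL) {
  d <- as_dist_matrix(x)
  n <- nrow(d)
  if (n < 5L) stop("need at least 5 observations", call. = FALSE)
  stopifnot(length(covariate) == n)
  if (is.character(covariate)) covariate <- factor(covariate)
  if (is.factor(covariate) && nlevels(droplevels(covariate)) < 2L)
    stop("constant covariate", call. = FALSE)
  if (is.numeric(covariate) && sd(covariate) == 0)
    stop("constant covariate", call. = FALSE)
  # Gower-centered inner-product matrix of the squared distances
  A <- -0.5 * d^2
  G <- A - outer(rowMeans(A), colMeans(A), "+") + mean(A)
  X <- model.matrix(~covariate)
  qx <- qr(X)
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  H <- tcrossprod(Q) - 1 / n         # hat matrix minus intercept part
  df_m <- qx$rank - 1L
  df_r <- n - qx$rank
  ss_tot <- sum(diag(G))
  f_for <- function(Gp) {
    ss_m <- sum(H * Gp)
    (ss_m / df_m) / ((ss_tot - ss_m) / df_r)
  }
  f_obs <- f_for(G)
  ss_model <- sum(H * G)
  stats <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    f_for(G[p, p])
  }, numeric(1L)))
  p_val <- (sum(stats >= f_obs - 1e-12) + 1) / (n_perm + 1)
  perm_test_result(c(F = f_obs), p_val, n_perm, seed,
                   alternative = "greater", R2 = ss_model / ss_tot,
                   df_model = df_m, df_residual = df_r)
}

#' Multivariate homogeneity of group dispersions
#'
#' Levene-type test for differences in multivariate spread: each
#' observation's Euclidean distance to its group centroid is computed and
#' those distances are compared between groups with ordinary one-way
#' ANOVA; pairwise Tukey HSD comparisons are available on request.
#'
#' @param coords n x p coordinate matrix or data frame.
#' @param groups Group labels; every group needs >= 2 members.
#' @param tukey If `TRUE`, attach a Tukey HSD table of pairwise group
#'   differences in mean centroid distance.
#' @return List of class `dispersion_test`: `F`, `df`, `p_value`,
#'   per-observation `distances`, group mean distances, optional `tukey`.
#' @export
group_dispersion_test <- function(coords, groups, tukey = FALSE) {
  m <- as.matrix(coords)
  storage.mode(m) <- "double"
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(m))
  if (nlevels(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2L)) stop("singleton group", call. = FALSE)
  centroids <- rowsum(m, groups) / as.vector(table(groups))
  dists <- sqrt(rowSums((m - centroids[as.integer(groups), , drop = FALSE])^2))
  fit <- aov(dists ~ groups)
  at <- anova(fit)
  out <- list(F = at$`F value`[1L], df = at$Df, p_value = at$`Pr(>F)`[1L],
              distances = dists,
              group_means = tapply(dists, groups, mean),
              tukey = if (tukey) TukeyHSD(fit)$groups else NULL)
  class(out) <- "dispersion_test"
  out
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat("Multivariate homogeneity of group dispersions\n  F =",
      format(x$F, digits = 5), " df =", paste(x$df, collapse = ", "),
      " p =", format(x$p_value, digits = 4), "\n")
  if (!is.null(x$tukey)) {
    cat("  Tukey HSD:\n")
    print(round(x$tukey, 4))
  }
  invisible(x)
}

#' Great-circle distance matrix between localities
#'
#' Haversine distances on a sphere (default mean Earth radius
#' 6371.009 km), via `geosphere::distHaversine()`. Accepts a locality
#' data frame (columns `latitude_deg`, `longitude_deg`, optional `id`)
#' or separate coordinate vectors.
#'
#' @param localities Data frame of locality records, or a numeric vector
#'   of latitudes when `longitude_deg` is given separately.
#' @param longitude_deg Longitudes when `localities` is a latitude vector.
#' @param radius_km Sphere radius in km (configurable to replicate
#'   analyses run with other radii).
#' @return Symmetric matrix of distances in km with zero diagonal.
#' @export
great_circle_distances <- function(localities, longitude_deg = NULL,
                                   radius_km = 6371.009) {
  if (is.data.frame(localities)) {
    lat <- localities$latitude_deg
    lon <- localities$longitude_deg
    ids <- if ("id" %in% names(localities)) as.character(localities$id)
  } else {
    lat <- as.numeric(localities)
    lon <- as.numeric(longitude_deg)
    ids <- NULL
  }
  if (is.null(lat) || is.null(lon) || length(lat) != length(lon))
    stop("need matching latitude and longitude vectors", call. = FALSE)
  check_coords(lat, lon)
  m <- geosphere::distm(cbind(lon, lat),
                        fun = function(a, b)
                          geosphere::distHaversine(a, b, r = radius_km))
  diag(m) <- 0
  if (!is.null(ids)) dimnames(m) <- list(ids, ids)
  m
}
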