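# Optimal-mimic computation: which host clutch color is the best
# achievable mimetic egg for a population, what rejection rate it would
# suffer, and how real parasite eggs sit relative to the achievable bounds.

#' Pairwise color contrasts between clutches
#'
#' Symmetric matrix of color contrasts (tetrahedral-space Euclidean
#' distances) between all clutches in a population.
#'
#' @param clutch_colors Cartesian colors: n x 3 matrix or data frame with
#'   columns `x`, `y`, `z` (n >= 2).
#' @param ids Optional clutch identifiers for the dimnames.
#' @return n x n symmetric matrix with zero diagonal.
#' @export
pairwise_contrasts <- function(clutch_colors, ids = NULL) {
  p <- as_xyz(clutch_colors)
  if (nrow(p) < 2L) stop("need at least two clutches", call. = FALSE)
  d <- as.matrix(dist(p))
  if (is.null(ids) && is.data.frame(clutch_colors) &&
      "clutch_id" %in% names(clutch_colors))
    ids <- as.character(clutch_colors$clutch_id)
  dimnames(d) <- if (!is.null(ids)) list(ids, ids)
  d
}

# mean contrast of each clutch to all the others (self excluded)
mean_offdiag <- function(cm) {
  n <- nrow(cm)
  rowSums(cm) / (n - 1)
}

check_contrast_matrix <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  if (any(!is.finite(cm)) || any(cm < 0) ||
      max(abs(cm - t(cm))) > 1e-8 || any(abs(diag(cm)) > 1e-12))
    stop("not a valid contrast matrix (symmetric, non-negative, ",
         "zero diagonal)", call. = FALSE)
  invisible(cm)
}

#' Optimal (best achievable mimetic) egg for a population
#'
#' The optimal parasite egg type is taken to equal the host clutch with
#' the lowest average color contrast to all other clutches in the
#' population (self-pairings excluded). Ties are broken toward the lowest
#' index.
#'
#' @param cm Contrast matrix from [pairwise_contrasts()].
#' @return List with `index`, `id` (if the matrix has dimnames),
#'   `mean_contrast` of the optimum, and the full `mean_contrasts` vector.
#' @export
optimal_egg <- function(cm) {
  check_contrast_matrix(cm)
  mc <- unname(mean_offdiag(cm))
  idx <- as.integer(which.min(mc))
  list(index = idx,
       id = if (!is.null(rownames(cm))) rownames(cm)[idx] else NA_character_,
       mean_contrast = mc[[idx]], mean_contrasts = mc)
}

#' Achievable-mimicry bounds for a population
#'
#' `lower`: the lowest average color contrast any egg restricted to the
#' observed clutch colors can achieve (the optimum's mean contrast).
#' `upper`: the highest average contrast an egg could have while still
#' being a perfect match to at least one host clutch (the mean contrast of
#' the most peripheral clutch).
#'
#' @inheritParams optimal_egg
#' @return List with `lower` and `upper`.
#' @export
mimicry_bounds <- function(cm) {
  check_contrast_matrix(cm)
  mc <- mean_offdiag(cm)
  list(lower = min(mc), upper = max(mc))
}

# cross-contrast matrix: rows = a, cols = b
cross_contrasts <- function(a, b) {
  pa <- as_xyz(a); pb <- as_xyz(b)
  sq <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  sqrt(pmax(sq, 0))
}

#' Fitness profile of parasite eggs against a host population
#'
#' For each candidate parasite egg: the mean color contrast over all host
#' clutches, the mean predicted rejection probability under the host
#' discrimination function (averaged over clutch pairings, with its SD
#' across pairings), and the position of the egg's mean contrast relative
#' to the population's achievable-mimicry bounds.
#'
#' @param cuckoo_colors Parasite egg colors (k x 3 or data frame).
#' @param clutch_colors Host clutch colors (n x 3 or data frame).
#' @param model Fitted univariate `discrimination_model`.
#' @return Data frame with one row per parasite egg: `mean_contrast`,
#'   `mean_rejection`, `sd_rejection`, `within_bounds`; the bounds are
#'   attached as attribute `"bounds"`.
#' @export
cuckoo_fitness_profile <- function(cuckoo_colors, clutch_colors, model) {
  stopifnot(inherits(model, "discrimination_model"))
  d <- cross_contrasts(cuckoo_colors, clutch_colors)
  pr <- matrix(predict_rejection(model, as.vector(d)), nrow = nrow(d))
  bounds <- if (nrow(as_xyz(clutch_colors)) >= 2L)
    mimicry_bounds(pairwise_contrasts(clutch_colors))
  else list(lower = NA_real_, upper = NA_real_)
  out <- data.frame(
    egg = seq_len(nrow(d)),
    mean_contrast = rowMeans(d),
    mean_rejection = rowMeans(pr),
    sd_rejection = apply(pr, 1L, sd))
  out$within_bounds <- !is.na(bounds$lower) &
    out$mean_contrast >= bounds$lower - 1e-12 &
    out$mean_contrast <= bounds$upper + 1e-12
  attr(out, "bounds") <- bounds
  out
}

#' Optimal-egg report for a host population
#'
#' Bundles [optimal_egg()], [mimicry_bounds()] and the expected fate of
#' the optimal egg under the discrimination function into one summary.
#'
#' @inheritParams cuckoo_fitness_profile
#' @return List with `optimal_index`, `optimal_id`, `mean_contrast`,
#'   `mean_rejection`, `sd_rejection`, `lower_bound`, `upper_bound`.
#' @export
optimal_egg_report <- function(clutch_colors, model) {
  cm <- pairwise_contrasts(clutch_colors)
  opt <- optimal_egg(cm)
  b <- mimicry_bounds(cm)
  # contrasts of the optimal egg to every other clutch
  dd <- cm[opt$index, -opt$index]
  pr <- predict_rejection(model, dd)
  list(optimal_index = opt$index, optimal_id = opt$id,
       mean_contrast = opt$mean_contrast,
       mean_rejection = mean(pr), sd_rejection = sd(pr),
       lower_bound = b$lower, upper_bound = b$upper)
}
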