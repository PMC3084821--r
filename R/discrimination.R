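# The host discrimination function: probability that a host rejects a
# parasitic egg as a function of the color contrast between own and
# foreign egg, fitted as a binomial logistic regression (logit link) with
# deviance-based backward model selection over candidate covariates.

#' Brightness (achromatic) contrast between two spectra
#'
#' Brightness lies outside the tetrachromatic color space; its contrast is
#' computed as the absolute difference in total reflectance, i.e. the
#' wavelength integral of each spectrum over the shared grid (trapezoid
#' rule). The formula is isolated here so an alternative achromatic proxy
#' can be swapped in without touching downstream code.
#'
#' @param s1,s2 [reflectance_spectrum] objects on identical grids.
#' @return Non-negative scalar contrast (nm-weighted reflectance units).
#' @export
brightness_contrast <- function(s1, s2) {
  stopifnot(inherits(s1, "reflectance_spectrum"),
            inherits(s2, "reflectance_spectrum"))
  if (length(s1$wavelengths) != length(s2$wavelengths) ||
      any(s1$wavelengths != s2$wavelengths))
    stop("grid mismatch between spectra", call. = FALSE)
  w <- trap_weights(s1$wavelengths)
  abs(sum(w * s1$reflectance) - sum(w * s2$reflectance))
}

#' Egg volume from length and breadth
#'
#' Classic egg-volume approximation `V = k_v * L * B^2` with the standard
#' coefficient `k_v = 0.51`.
#'
#' @param length_mm,breadth_mm Positive egg dimensions, mm.
#' @param coefficient Volume coefficient.
#' @return Volume in mm^3.
#' @export
egg_volume <- function(length_mm, breadth_mm, coefficient = 0.51) {
  if (any(length_mm <= 0) || any(breadth_mm <= 0))
    stop("egg dimensions must be positive", call. = FALSE)
  coefficient * length_mm * breadth_mm^2
}

#' Egg shape (elongation) index
#'
#' Length over breadth; 1 for a spherical egg.
#'
#' @inheritParams egg_volume
#' @return Unitless elongation index.
#' @export
egg_shape_index <- function(length_mm, breadth_mm) {
  if (any(length_mm <= 0) || any(breadth_mm <= 0))
    stop("egg dimensions must be positive", call. = FALSE)
  length_mm / breadth_mm
}

#' Fit the host discrimination function
#'
#' Binomial logistic regression (logit link) of rejection outcome on the
#' requested covariate terms, by iteratively reweighted least squares.
#' Convergence is declared when the relative change in deviance falls
#' below 1e-8 (at most 100 iterations). Complete separation and rank
#' deficiency raise explicit errors.
#'
#' @param trials Data frame with column `outcome` (1 = rejection) and the
#'   covariates named in `terms` (e.g. `delta_tc`, `delta_tb`, `species`,
#'   `shape_contrast`, `volume_contrast`; interactions as `"a:b"`).
#' @param terms Character vector of model terms; default the univariate
#'   color-contrast model.
#' @return An object of class `discrimination_model` with elements
#'   `coefficients`, `se`, `vcov`, `deviance`, `null_deviance`, `n`,
#'   `terms`, `converged`, `iterations` and the model data.
#' @export
fit_logistic <- function(trials, terms = "delta_tc") {
  stopifnot(is.data.frame(trials), "outcome" %in% names(trials))
  if (is.null(terms)) terms <- character(0)
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  missing_vars <- setdiff(vars, names(trials))
  if (length(missing_vars))
    stop("trials table lacks covariate(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  used <- trials[, c("outcome", vars), drop = FALSE]
  keep <- complete.cases(used)
  if (any(!keep)) {
    message("dropped ", sum(!keep), " incomplete trial row(s)")
    used <- used[keep, , drop = FALSE]
  }
  y <- decode_outcome(used$outcome)
  if (length(unique(y)) < 2L)
    stop("degenerate outcomes: need both acceptances and rejections",
         call. = FALSE)
  X <- if (length(terms))
    model.matrix(reformulate(terms), data = used)
  else
    model.matrix(~1, data = used)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design: collinear term(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- irls_logit(X, y)
  if (!fit$converged)
    warning("IRLS did not converge in 100 iterations", call. = FALSE)
  mu <- fit$fitted
  if (all(mu[y == 1] > 1 - 1e-4) && all(mu[y == 0] < 1e-4))
    stop("complete separation: rejection outcome perfectly predicted, ",
         "coefficients diverge", call. = FALSE)
  dev_null <- binomial_deviance(y, rep(mean(y), length(y)))
  structure(
    list(coefficients = fit$beta, se = sqrt(diag(fit$vcov)),
         vcov = fit$vcov, deviance = fit$deviance,
         null_deviance = dev_null, df_residual = length(y) - ncol(X),
         n = length(y), terms = terms, data = used,
         converged = fit$converged, iterations = fit$iterations),
    class = "discrimination_model")
}

binomial_deviance <- function(y, mu) {
  eps <- 1e-15
  mu <- pmin(1 - eps, pmax(eps, mu))
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

irls_logit <- function(X, y, max_iter = 100L, rtol = 1e-8) {
  p <- ncol(X)
  beta <- numeric(p)
  dev <- binomial_deviance(y, rep(0.5, length(y)))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta <- drop(solve(XtW %*% X, XtW %*% z))
    dev_new <- binomial_deviance(y, plogis(drop(X %*% beta)))
    if (abs(dev_new - dev) / (abs(dev) + 0.1) < rtol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  vcov <- solve(t(X * w) %*% X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(beta = setNames(beta, colnames(X)), vcov = vcov, deviance = dev,
       fitted = mu, converged = converged, iterations = it)
}

#' @export
print.discrimination_model <- function(x, ...) {
  cat("Host discrimination function (binomial logistic regression)\n")
  cat("  n =", x$n, " deviance =", format(x$deviance, digits = 6),
      " null deviance =", format(x$null_deviance, digits = 6), "\n")
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se,
               z = x$coefficients / x$se,
               `Pr(>|z|)` = 2 * pnorm(-abs(x$coefficients / x$se)))
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.discrimination_model <- function(object, ...) object$coefficients

#' Backward model selection by deviance tests
#'
#' Starting from the full candidate model, repeatedly tests each currently
#' droppable term (interactions are droppable immediately; a main effect
#' only once no retained interaction contains it) by the change in deviance
#' between the models with and without the term (chi-squared test on the
#' term's degrees of freedom). The term with the largest p-value at or
#' above `alpha` is removed (ties broken toward the smaller deviance
#' change) and the procedure repeats until every remaining term is
#' significant. `method = "single"` instead performs one round of
#' single-term deletions from the full model and retains the terms with
#' p below `alpha`.
#'
#' @inheritParams fit_logistic
#' @param terms Full candidate term set.
#' @param alpha Retention threshold for the deviance-test p-value.
#' @param method `"sequential"` (default) or `"single"`.
#' @return List with elements `model` (the minimal adequate
#'   `discrimination_model`), `selection` (data frame of every test: term,
#'   df, deviance change, p, step, retained flag) and `retained`.
#' @export
backward_eliminate <- function(trials, terms, alpha = 0.05,
                               method = c("sequential", "single")) {
  method <- match.arg(method)
  current <- terms
  rows <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    fit_full <- fit_logistic(trials, current)
    # single-deletion mode tests every term of the full model (Table-1
    # style); sequential elimination respects marginality
    droppable <- if (method == "single") current else
      droppable_terms(current)
    tests <- lapply(droppable, function(tm) {
      reduced <- setdiff(current, tm)
      fit_r <- fit_logistic(trials, reduced)
      df <- (fit_r$df_residual) - (fit_full$df_residual)
      dd <- fit_r$deviance - fit_full$deviance
      data.frame(term = tm, df = df, deviance = dd,
                 p = pchisq(dd, df, lower.tail = FALSE), step = step)
    })
    tab <- do.call(rbind, tests)
    if (method == "single") {
      tab$retained <- tab$p < alpha
      retained <- tab$term[tab$retained]
      model <- fit_logistic(trials, if (length(retained)) retained else NULL)
      return(list(model = model, selection = tab, retained = retained))
    }
    ns <- tab[tab$p >= alpha, , drop = FALSE]
    if (nrow(ns) == 0L || length(current) == 0L) {
      tab$retained <- TRUE
      rows[[step]] <- tab
      break
    }
    # drop largest p; ties broken by the smaller deviance change
    drop_term <- ns$term[order(-ns$p, ns$deviance)][1L]
    tab$retained <- FALSE
    rows[[step]] <- tab[tab$term == drop_term, , drop = FALSE]
    current <- setdiff(current, drop_term)
    if (length(current) == 0L) break
  }
  selection <- do.call(rbind, rows)
  rownames(selection) <- NULL
  model <- fit_logistic(trials, if (length(current)) current else NULL)
  list(model = model, selection = selection, retained = current)
}

# Terms not contained in any higher-order term still in the model.
droppable_terms <- function(terms) {
  if (length(terms) == 0L) return(character())
  is_inter <- grepl(":", terms, fixed = TRUE)
  parents <- unique(unlist(strsplit(terms[is_inter], ":", fixed = TRUE)))
  terms[is_inter | !(terms %in% parents)]
}

#' Predict rejection probability from color contrast
#'
#' Applies the fitted univariate host discrimination function: the
#' inverse-logit of the linear predictor at the supplied color contrast.
#' With a non-negative slope the curve is monotone nondecreasing. Optional
#' pointwise confidence intervals use the delta method on the linear
#' predictor scale.
#'
#' @param model A univariate `discrimination_model` (single continuous
#'   term, normally `delta_tc`).
#' @param delta_tc Non-negative color contrast value(s).
#' @param ci If `TRUE`, return a data frame with a pointwise interval.
#' @param level Confidence level for the interval.
#' @return Numeric probabilities, or a data frame with columns
#'   `delta_tc`, `p`, `lower`, `upper` when `ci = TRUE`.
#' @export
predict_rejection <- function(model, delta_tc, ci = FALSE, level = 0.95) {
  stopifnot(inherits(model, "discrimination_model"))
  if (length(model$coefficients) != 2L)
    stop("predict_rejection needs a univariate discrimination model",
         call. = FALSE)
  if (any(delta_tc < 0)) stop("negative color contrast", call. = FALSE)
  eta <- model$coefficients[1L] + model$coefficients[2L] * delta_tc
  p <- plogis(unname(eta))
  if (!ci) return(p)
  v <- model$vcov
  se_eta <- sqrt(v[1L, 1L] + 2 * delta_tc * v[1L, 2L] + delta_tc^2 * v[2L, 2L])
  zq <- qnorm(1 - (1 - level) / 2)
  data.frame(delta_tc = delta_tc, p = p,
             lower = plogis(unname(eta) - zq * se_eta),
             upper = plogis(unname(eta) + zq * se_eta))
}

#' Pooled rejection rate from per-species counts
#'
#' Aggregates per-species rejection counts (e.g. from control experiments
#' with non-mimetic parasitic eggs) into a pooled rejection proportion.
#'
#' @param counts Data frame with columns `rejected` and `trials`.
#' @return Pooled proportion rejected.
#' @export
pooled_rejection_rate <- function(counts) {
  stopifnot(all(c("rejected", "trials") %in% names(counts)),
            all(counts$rejected <= counts$trials))
  sum(counts$rejected) / sum(counts$trials)
}

#' Control egg-exchange experiment counts
#'
#' Outcomes of control experiments in which the parasitic egg came from a
#' species outside the hosts' own trait space (non-mimetic controls):
#' rejections and totals per host species. Such eggs are nearly always
#' rejected irrespective of the host's own egg type, pooling to a 92%
#' rejection rate.
#'
#' @return Data frame with columns `host`, `rejected`, `trials`.
#' @export
fringilla_control_counts <- function() {
  data.frame(host = c("brambling", "chaffinch"),
             rejected = c(19L, 42L),
             trials = c(19L, 47L))
}
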