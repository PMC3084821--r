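# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards so no global state leaks.
# A NULL seed uses (and advances) the session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number or NULL", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Trapezoid quadrature weights for an (increasing) wavelength grid.
trap_weights <- function(wl) {
  n <- length(wl)
  if (n < 2L) stop("wavelength grid needs at least two points", call. = FALSE)
  d <- diff(wl)
  c(d[1L] / 2, (d[-(n - 1L)] + d[-1L]) / 2, d[n - 1L] / 2)
}

# Coerce color input to an n x 3 matrix of Cartesian coordinates.
# Accepts a numeric vector of length 3, a matrix, or a data frame with
# columns x, y, z (e.g. output of spectra_to_colors / synth_population).
as_xyz <- function(x) {
  if (is.data.frame(x)) {
    if (all(c("x", "y", "z") %in% names(x)))
      m <- as.matrix(x[, c("x", "y", "z")])
    else if (ncol(x) == 3L) m <- as.matrix(x)
    else stop("data frame must contain columns x, y, z", call. = FALSE)
  } else if (is.matrix(x)) {
    if (ncol(x) != 3L) stop("coordinate matrix must have 3 columns", call. = FALSE)
    m <- x
  } else if (is.numeric(x) && length(x) == 3L) {
    m <- matrix(x, nrow = 1L)
  } else {
    stop("cannot interpret input as Cartesian color coordinates", call. = FALSE)
  }
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y", "z")
  m
}

# All n! permutations of seq_len(n) as an (n! x n) matrix, first row identity.
all_permutations <- function(n) {
  if (n > 9L) stop("exhaustive enumeration limited to n <= 9", call. = FALSE)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, factorial(n), n)
  row <- 0L
  for (v in seq_len(n)) {
    rest_vals <- setdiff(seq_len(n), v)
    for (r in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(v, rest_vals[sub[r, ]])
    }
  }
  out
}
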