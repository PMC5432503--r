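# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Moore-Penrose pseudo-inverse
#'
#' SVD-based pseudo-inverse with a relative singular-value tolerance. Used for
#' all ordinary-least-squares solves in the encoding model so that full-rank
#' problems give the exact OLS solution while near-degenerate ones remain
#' numerically stable.
#'
#' @param x numeric matrix.
#' @param tol relative tolerance: singular values below `tol * max(d)` are
#'   treated as zero.
#' @return the pseudo-inverse of `x` (dimensions transposed).
#' @keywords internal
pinv <- function(x, tol = 1e-10) {
  s <- svd(x)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(x), nrow(x)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# circular distance between channel indices on a ring of k channels
circ_dist_channels <- function(i, j, k) {
  d <- abs(i - j) %% k
  pmin(d, k - d)
}

# circular distance between two angles in degrees
circ_dist_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# wrapped (circular) Gaussian over channel distance, peak-normalised to 1
wrapped_gaussian <- function(dist, sigma) exp(-dist^2 / (2 * sigma^2))

# circular shift of a vector: element i of the result is x[i - by] (mod n),
# i.e. shifting by +1 moves the content one slot to the right
circshift <- function(x, by) {
  n <- length(x)
  if (n == 0L) return(x)
  by <- ((by %% n) + n) %% n
  if (by == 0L) return(x)
  c(x[(n - by + 1L):n], x[1L:(n - by)])
}

# population (divide-by-n) standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# check an integer-valued scalar
is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-8
}
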