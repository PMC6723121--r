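#' Map test times onto the Legendre interval
#'
#' Affinely rescales an increasing set of time points so that the earliest
#' maps to -1 and the latest to +1, the domain of the Legendre polynomials
#' used as random regression covariates.
#'
#' @param time_points numeric vector of at least two distinct, ordered time
#'   points (e.g. weekly test days `1:6`).
#' @return numeric vector of the same length in `[-1, 1]`.
#' @examples
#' standardize_times(1:6)
#' @export
standardize_times <- function(time_points) {
  if (length(time_points) < 2 || length(unique(time_points)) < 2)
    stop("need at least 2 distinct time points")
  if (is.unsorted(time_points, strictly = TRUE))
    stop("time points must be strictly increasing")
  rng <- range(time_points)
  2 * (time_points - rng[1]) / (rng[2] - rng[1]) - 1
}

## Plain Legendre polynomial values P_0..P_k at x via Bonnet's recurrence.
.legendre_raw <- function(x, order) {
  out <- matrix(0, length(x), order + 1)
  out[, 1] <- 1
  if (order >= 1) out[, 2] <- x
  if (order >= 2) {
    for (k in 2:order)
      out[, k + 1] <- ((2 * k - 1) * x * out[, k] - (k - 1) * out[, k - 1]) / k
  }
  out
}

#' Normalized Legendre covariate matrix
#'
#' Builds the T x (order + 1) matrix of normalized Legendre polynomial
#' covariates, entry (t, k) = sqrt((2k+1)/2) P_k(x_t), the convention used
#' throughout random regression test-day models. Under this convention the
#' basis is orthonormal on `[-1, 1]`.
#'
#' @param time_points numeric vector of ordered test times.
#' @param order polynomial order (0 = intercept only; the package default
#'   analyses use first order).
#' @return matrix with `length(time_points)` rows and `order + 1` columns;
#'   the standardized times are attached as attribute `"x"`.
#' @examples
#' legendre_matrix(1:6, 1)
#' @export
legendre_matrix <- function(time_points, order = 1) {
  if (order < 0) stop("order must be >= 0")
  x <- standardize_times(time_points)
  L <- .legendre_raw(x, order)
  norm <- sqrt((2 * seq(0, order) + 1) / 2)
  L <- sweep(L, 2, norm, "*")
  dimnames(L) <- list(paste0("t", seq_along(x)), paste0("phi", seq(0, order)))
  attr(L, "x") <- x
  attr(L, "time_points") <- time_points
  L
}

#' Variance trajectory implied by a coefficient covariance matrix
#'
#' For a random regression effect with coefficient covariance `C`, the
#' variance contributed at time t is the quadratic form phi(x_t)' C phi(x_t).
#'
#' @param C symmetric positive semi-definite covariance matrix of the
#'   regression coefficients, dimension matching `ncol(L)`.
#' @param L Legendre covariate matrix from [legendre_matrix()].
#' @return numeric vector of per-time variances.
#' @export
trajectory_variance <- function(C, L) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8 * (max(abs(C)) + 1))
    stop("C must be a symmetric matrix")
  if (ncol(L) != nrow(C)) stop("dimension of C does not match basis order")
  rowSums((L %*% C) * L)
}

#' Heritability along the test trajectory
#'
#' h2(t) = g(t) / (g(t) + p(t) + sigma_e2) where g and p are the additive and
#' permanent-environment variance trajectories implied by the coefficient
#' covariances.
#'
#' @param params a [trait_params()] object.
#' @param L Legendre covariate matrix.
#' @return numeric vector of heritabilities, one per time point.
#' @examples
#' L <- legendre_matrix(1:6, 1)
#' heritability_trajectory(trait_params(), L)
#' @export
heritability_trajectory <- function(params, L) {
  params <- as_trait_params(params, require_pd = FALSE)
  if (params$sigma_e2 <= 0) stop("sigma_e2 must be > 0")
  g <- trajectory_variance(params$G, L)
  p <- trajectory_variance(params$P, L)
  g / (g + p + params$sigma_e2)
}
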