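#' Generating / estimated trait (co)variance structures
#'
#' Bundles the additive-genetic coefficient covariance `G`, the
#' permanent-environment coefficient covariance `P` and the residual variance
#' `sigma_e2` of the longitudinal feed-intake model. The defaults are the
#' generating values of the simulation study the package reproduces: an
#' intercept + slope (first-order Legendre) genetic curve with
#' `G = [[63.42, -5.42], [-5.42, 6.85]]`, `P = [[30.61, 4.28], [4.28, 29.25]]`
#' and a homogeneous residual variance of 53.45.
#'
#' @param G additive-genetic covariance matrix of the regression coefficients.
#' @param P permanent-environment covariance matrix.
#' @param sigma_e2 residual variance (scalar, > 0).
#' @return an object of class `trait_params`.
#' @examples
#' trait_params()
#' @export
trait_params <- function(G = matrix(c(63.42, -5.42, -5.42, 6.85), 2, 2),
                         P = matrix(c(30.61, 4.28, 4.28, 29.25), 2, 2),
                         sigma_e2 = 53.45) {
  out <- structure(list(G = as.matrix(G), P = as.matrix(P),
                        sigma_e2 = as.numeric(sigma_e2)),
                   class = "trait_params")
  as_trait_params(out, require_pd = FALSE)
}

#' @rdname trait_params
#' @param x object to coerce: a `trait_params`, or a numeric 7-vector packed
#'   as `(G11, G12, G22, P11, P12, P22, sigma_e2)`.
#' @param require_pd if `TRUE`, fail unless `G` and `P` are positive definite
#'   and `sigma_e2 > 0`.
#' @export
as_trait_params <- function(x, require_pd = TRUE) {
  if (is.numeric(x) && length(x) == 7) {
    x <- structure(list(G = matrix(x[c(1, 2, 2, 3)], 2, 2),
                        P = matrix(x[c(4, 5, 5, 6)], 2, 2),
                        sigma_e2 = unname(x[7])),
                   class = "trait_params")
  }
  if (!inherits(x, "trait_params")) stop("cannot coerce to trait_params")
  for (nm in c("G", "P")) {
    M <- x[[nm]]
    if (!is.matrix(M) || nrow(M) != ncol(M))
      stop(nm, " must be a square matrix")
    if (max(abs(M - t(M))) > 1e-8 * (max(abs(M)) + 1))
      stop(nm, " must be symmetric")
  }
  if (require_pd) {
    if (min(eigen(x$G, symmetric = TRUE, only.values = TRUE)$values) <= 1e-8)
      stop("G is not positive definite")
    if (min(eigen(x$P, symmetric = TRUE, only.values = TRUE)$values) <= 1e-8)
      stop("P is not positive definite")
    if (x$sigma_e2 <= 0) stop("sigma_e2 must be > 0")
  }
  x
}

## Pack a trait_params into the 7-vector used by the REML optimizer.
.pack_theta <- function(params) {
  c(params$G[1, 1], params$G[1, 2], params$G[2, 2],
    params$P[1, 1], params$P[1, 2], params$P[2, 2], params$sigma_e2)
}

.theta_names <- c("G11", "G12", "G22", "P11", "P12", "P22", "sigma_e2")

## TRUE when the packed parameter vector lies inside the REML parameter space
## (PD matrices up to an eigenvalue floor, positive residual variance).
.theta_in_space <- function(theta, floor = 1e-8) {
  G <- matrix(theta[c(1, 2, 2, 3)], 2, 2)
  P <- matrix(theta[c(4, 5, 5, 6)], 2, 2)
  min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) > floor &&
    min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) > floor &&
    theta[7] > floor
}

#' @method print trait_params
#' @export
print.trait_params <- function(x, ...) {
  cat("Trait (co)variance parameters\n")
  cat("G (additive, intercept/slope):\n"); print(x$G)
  cat("P (permanent environment):\n"); print(x$P)
  cat("sigma_e2 (residual):", x$sigma_e2, "\n")
  invisible(x)
}
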