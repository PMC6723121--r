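## AI-REML for the random regression models: the coefficient matrix is
## factored once per iteration with CHOLMOD (simplicial LDL'); trace terms of
## the gradient and of the EM update come from a Takahashi selected inverse
## of the factor (dense inverse below `dense_threshold` equations), and the
## average-information matrix from one extra multi-RHS solve.

.default_start <- function(design) {
  ## heuristic: half the raw phenotypic variance to the residual, a quarter
  ## to each of the intercept variances, 1/T of a quarter to the slopes
  v <- if (design$model == "group") var(design$y / sqrt(design$d))
       else var(design$y)
  Tn <- nrow(design$L)
  c(v / 4, 0, v / 4 / Tn, v / 4, 0, v / 4 / Tn, v / 2)
}

.logdet_A <- function(a_inv) {
  ld <- attr(a_inv, "logdet_A")
  if (is.null(ld))
    ld <- -as.numeric(Matrix::determinant(a_inv, logarithm = TRUE)$modulus)
  ld
}

## Factorize C(theta) and evaluate the REML deviance.
.fit_state <- function(theta, parts, design, a_inv, logdetA, ridge) {
  params <- as_trait_params(theta, require_pd = FALSE)
  C <- .build_C(parts, design, a_inv, params, ridge)
  ch <- tryCatch(Matrix::Cholesky(C, LDL = TRUE, super = FALSE, perm = TRUE),
                 error = function(e) NULL)
  if (is.null(ch))
    return(list(ok = FALSE, m2ll = Inf, theta = theta))
  n_eq <- nrow(C)
  dvec <- ch@x[ch@p[seq_len(n_eq)] + 1L]
  if (any(dvec <= 0))
    return(list(ok = FALSE, m2ll = Inf, theta = theta))
  sol <- as.vector(Matrix::solve(ch, parts$WtDy / params$sigma_e2))
  yPy <- parts$ytDy / params$sigma_e2 -
    sum(sol * parts$WtDy) / params$sigma_e2
  q <- design$q
  npe <- length(design$pe_ids)
  m2ll <- sum(log(dvec)) + parts$N * log(params$sigma_e2) + parts$logdet_D +
    design$k * logdetA + q * as.numeric(determinant(params$G)$modulus) +
    npe * as.numeric(determinant(params$P)$modulus) + yPy
  ehat <- design$y - as.vector(parts$W %*% sol)
  list(ok = TRUE, theta = theta, params = params, C = C, ch = ch,
       n_eq = n_eq, sol = sol, yPy = yPy, m2ll = m2ll, ehat = ehat,
       eDe = sum(ehat^2 / design$d))
}

## Full symmetric triplet expansion of sparse A^-1.
.ainv_triplets <- function(a_inv) {
  tr <- Matrix::summary(a_inv)
  off <- tr$i != tr$j
  list(i = c(tr$i, tr$j[off]), j = c(tr$j, tr$i[off]),
       x = c(tr$x, tr$x[off]))
}

## Symbolic context of the selected inverse: the full pattern of the factor
## and the positions of every C^-1 entry entering the trace terms. The factor
## pattern is fixed over REML iterations, so this is built once per fit.
.selinv_context <- function(ch, design, tri, npe) {
  n <- length(ch@perm)
  ana <- cpp_takahashi_analyze(ch@p, ch@i, n)
  iperm <- integer(n)
  iperm[ch@perm + 1L] <- seq_len(n) - 1L
  pos0 <- function(rows, cols)
    cpp_full_positions(ana$Zp, ana$Zi, iperm[rows], iperm[cols])
  k <- design$k
  pe_seq <- seq_len(npe)
  pos_a <- pos_p <- vector("list", k * k)
  for (kk in 1:k) for (ll in 1:k) {
    pos_a[[(kk - 1) * k + ll]] <- pos0(.eq_additive(design, tri$i, kk),
                                       .eq_additive(design, tri$j, ll))
    if (ll >= kk)
      pos_p[[(kk - 1) * k + ll]] <- pos0(.eq_pe(design, pe_seq, kk),
                                         .eq_pe(design, pe_seq, ll))
  }
  list(key_p = ch@p, key_i = ch@i, ana = ana, pos_a = pos_a, pos_p = pos_p)
}

## Gradient, average information and EM update at the current state.
## `cache` persists the symbolic selected-inverse analysis across iterations.
.reml_update <- function(state, parts, design, a_inv, tri,
                         dense_threshold, cache = new.env()) {
  k <- design$k
  stopifnot(k == 2)
  q <- design$q
  npe <- length(design$pe_ids)
  se2 <- state$params$sigma_e2
  Ginv <- solve(state$params$G)
  Pinv <- solve(state$params$P)

  ## trace blocks T_a = sum_ij a^ij C^aa_[(i,.),(j,.)], T_p = sum_i C^pe_ii
  T_a <- matrix(0, k, k)
  T_p <- matrix(0, k, k)
  pe_seq <- seq_len(npe)
  if (state$n_eq <= dense_threshold) {
    Cinv <- chol2inv(chol(as.matrix(state$C)))
    for (kk in 1:k) for (ll in 1:k)
      T_a[kk, ll] <- sum(tri$x * Cinv[cbind(.eq_additive(design, tri$i, kk),
                                            .eq_additive(design, tri$j, ll))])
    for (kk in 1:k) for (ll in kk:k)
      T_p[kk, ll] <- T_p[ll, kk] <-
        sum(Cinv[cbind(.eq_pe(design, pe_seq, kk),
                       .eq_pe(design, pe_seq, ll))])
  } else {
    ch <- state$ch
    sctx <- cache$sctx
    if (is.null(sctx) || !identical(sctx$key_p, ch@p) ||
        !identical(sctx$key_i, ch@i)) {
      sctx <- .selinv_context(ch, design, tri, npe)
      cache$sctx <- sctx
    }
    Zx <- cpp_takahashi(ch@p, ch@i, ch@x, state$n_eq,
                        sctx$ana$Zp, sctx$ana$Zi, sctx$ana$mirror)
    getv <- function(pos) {
      v <- numeric(length(pos))
      nz <- pos > 0L
      v[nz] <- Zx[pos[nz]]
      v
    }
    for (kk in 1:k) for (ll in 1:k)
      T_a[kk, ll] <- sum(tri$x * getv(sctx$pos_a[[(kk - 1) * k + ll]]))
    for (kk in 1:k) for (ll in kk:k)
      T_p[kk, ll] <- T_p[ll, kk] <-
        sum(getv(sctx$pos_p[[(kk - 1) * k + ll]]))
  }
  T_a <- (T_a + t(T_a)) / 2

  Uhat <- matrix(state$sol[design$n_fixed + seq_len(q * k)],
                 ncol = k, byrow = TRUE)
  Pehat <- matrix(state$sol[design$n_fixed + q * k + seq_len(npe * k)],
                  ncol = k, byrow = TRUE)
  S_a <- as.matrix(Matrix::crossprod(Uhat, a_inv %*% Uhat))
  S_p <- crossprod(Pehat)

  ## score: -2 dlogL/dG = tr(M [q Ginv - Ginv (T_a + S_a) Ginv]) etc.
  WG <- q * Ginv - Ginv %*% (T_a + S_a) %*% Ginv
  WP <- npe * Pinv - Pinv %*% (T_p + S_p) %*% Pinv
  trCS <- sum(Ginv * T_a) + sum(Pinv * T_p)
  dse <- (parts$N - state$n_eq + trCS) / se2 - state$eDe / se2^2
  gradient <- -0.5 * c(WG[1, 1], 2 * WG[1, 2], WG[2, 2],
                       WP[1, 1], 2 * WP[1, 2], WP[2, 2], dse)

  ## average information: AI_ij = 0.5 f_i' P f_j with f_i = dV/dtheta_i P y
  Ms <- list(matrix(c(1, 0, 0, 0), 2), matrix(c(0, 1, 1, 0), 2),
             matrix(c(0, 0, 0, 1), 2))
  F <- matrix(0, parts$N, 7)
  for (j in 1:3) {
    V <- Uhat %*% Ginv %*% Ms[[j]]
    F[, j] <- as.vector(design$Z_a %*% as.vector(t(V)))
    Vp <- Pehat %*% Pinv %*% Ms[[j]]
    F[, 3 + j] <- as.vector(design$Z_pe %*% as.vector(t(Vp)))
  }
  F[, 7] <- state$ehat / se2
  B <- as.matrix(Matrix::crossprod(parts$W, F / design$d)) / se2
  S <- as.matrix(Matrix::solve(state$ch, B))
  PF <- (F - as.matrix(parts$W %*% S)) / design$d / se2
  AI <- 0.5 * crossprod(F, PF)
  AI <- (AI + t(AI)) / 2
  dimnames(AI) <- list(.theta_names, .theta_names)

  ## EM-REML fixed-point update
  G_em <- (T_a + S_a) / q
  P_em <- (T_p + S_p) / npe
  se_em <- (state$eDe + se2 * (state$n_eq - trCS)) / parts$N
  theta_em <- c(G_em[1, 1], G_em[1, 2], G_em[2, 2],
                P_em[1, 1], P_em[1, 2], P_em[2, 2], se_em)

  list(gradient = setNames(gradient, .theta_names), AI = AI,
       theta_em = theta_em)
}

#' REML deviance of a random regression model
#'
#' Evaluates `-2 log L_R` (up to the `(N - p) log 2 pi` constant) at the
#' given variance components through the sparse mixed-model-equation route:
#' `log|C| + log|R| + k log|A| + q log|G| + n_pe log|P| + y'Py`. On small
#' data this equals the dense formula
#' `log|V| + log|X' V^-1 X| + y'Py`.
#'
#' @param params [trait_params()] or packed 7-vector
#'   `(G11, G12, G22, P11, P12, P22, sigma_e2)`.
#' @param design an `rr_design` from [build_design()].
#' @param a_inv sparse `A^-1`.
#' @param ridge fixed-effect ridge, see [assemble_mme()].
#' @return the deviance (scalar).
#' @export
reml_loglik <- function(params, design, a_inv, ridge = NULL) {
  theta <- if (is.numeric(params)) params else .pack_theta(params)
  if (!.theta_in_space(theta)) stop("parameters outside the REML space")
  if (is.null(ridge)) ridge <- .default_ridge(design)
  parts <- .mme_parts(design)
  st <- .fit_state(theta, parts, design, a_inv, .logdet_A(a_inv), ridge)
  if (!st$ok) stop("coefficient matrix not positive definite")
  st$m2ll
}

#' One AI-REML score and information evaluation
#'
#' Returns the gradient of the REML log-likelihood and the
#' average-information matrix at the given parameters, the ingredients of
#' one AI-REML iteration.
#'
#' @inheritParams reml_loglik
#' @param dense_threshold below this number of equations the traces use a
#'   dense inverse; above, the Takahashi selected inverse of the sparse
#'   factor.
#' @return list with `gradient` (length 7, logL scale), `AI` (7 x 7) and
#'   `theta_em` (the EM-REML update of the packed parameters).
#' @export
ai_update <- function(params, design, a_inv, ridge = NULL,
                      dense_threshold = 5000) {
  theta <- if (is.numeric(params)) params else .pack_theta(params)
  if (!.theta_in_space(theta)) stop("parameters outside the REML space")
  if (is.null(ridge)) ridge <- .default_ridge(design)
  parts <- .mme_parts(design)
  st <- .fit_state(theta, parts, design, a_inv, .logdet_A(a_inv), ridge)
  if (!st$ok) stop("coefficient matrix not positive definite")
  tri <- .ainv_triplets(a_inv)
  .reml_update(st, parts, design, a_inv, tri, dense_threshold)
}

#' Estimate variance components by AI-REML with EM fallback
#'
#' Quasi-Newton iteration `theta <- theta + AI^-1 grad` with step halving;
#' whenever the proposed step leaves the parameter space (non-PD `G`/`P` or
#' non-positive residual) or fails to improve the likelihood, an EM-REML
#' step is substituted. Convergence requires both a small relative parameter
#' change and a small gradient norm.
#'
#' @inheritParams ai_update
#' @param theta0 starting values (packed 7-vector or `trait_params`);
#'   defaults to a heuristic split of the raw phenotypic variance.
#' @param options list overriding any of `tol_param` (1e-8), `tol_grad`
#'   (1e-6), `max_iter` (200), `dense_threshold` (5000), `ridge`, `verbose`.
#' @return object of class `reml_result`: estimated `params`, packed
#'   `theta`, deviance `m2ll`, `converged`, `stalled` (`TRUE` when the fit
#'   stopped because successive EM steps at a parameter-space boundary no
#'   longer moved the likelihood), `iterations`, final `gradient` and `AI`,
#'   the count of EM fallback steps, and the MME solutions at the optimum
#'   (`fixed`, `a_hat`, `pe_hat`).
#' @export
estimate_vc <- function(design, a_inv, theta0 = NULL, options = list()) {
  opt <- list(tol_param = 1e-8, tol_grad = 1e-6, max_iter = 200,
              dense_threshold = 5000, ridge = NULL, verbose = FALSE)
  opt[names(options)] <- options
  if (is.null(opt$ridge)) opt$ridge <- .default_ridge(design)
  theta <- if (is.null(theta0)) .default_start(design)
           else if (is.numeric(theta0)) theta0 else .pack_theta(theta0)
  if (!.theta_in_space(theta)) stop("starting values outside parameter space")
  parts <- .mme_parts(design)
  logdetA <- .logdet_A(a_inv)
  tri <- .ainv_triplets(a_inv)
  state <- .fit_state(theta, parts, design, a_inv, logdetA, opt$ridge)
  if (!state$ok) stop("starting values give a non-positive-definite system")
  rel_change <- Inf
  converged <- FALSE
  stalled <- FALSE
  n_em <- 0L
  n_stall <- 0L
  iter <- 0L
  upd <- NULL
  cache <- new.env(parent = emptyenv())
  while (iter < opt$max_iter) {
    iter <- iter + 1L
    upd <- .reml_update(state, parts, design, a_inv, tri,
                        opt$dense_threshold, cache)
    gnorm <- sqrt(sum(upd$gradient^2))
    if (opt$verbose)
      message(sprintf("it %3d  -2logL %.6f  |grad| %.3e  rel %.3e%s",
                      iter, state$m2ll, gnorm, rel_change,
                      if (n_em) paste0("  (EM steps: ", n_em, ")") else ""))
    if (gnorm < opt$tol_grad && rel_change < opt$tol_param) {
      converged <- TRUE
      break
    }
    cand_state <- NULL
    delta <- tryCatch(solve(upd$AI, upd$gradient),
                      error = function(e) NULL)
    if (!is.null(delta)) {
      step <- 1
      for (h in seq_len(15)) {
        cand <- state$theta + step * delta
        if (.theta_in_space(cand)) {
          trial <- .fit_state(cand, parts, design, a_inv, logdetA, opt$ridge)
          if (trial$ok && trial$m2ll <= state$m2ll + 1e-8) {
            cand_state <- trial
            break
          }
        }
        step <- step / 2
      }
    }
    if (is.null(cand_state)) {
      ## EM-REML fallback step
      cand <- upd$theta_em
      if (!.theta_in_space(cand))
        stop("EM fallback left the parameter space; data may carry no ",
             "information on some component")
      cand_state <- .fit_state(cand, parts, design, a_inv, logdetA,
                               opt$ridge)
      if (!cand_state$ok) stop("EM fallback produced a singular system")
      n_em <- n_em + 1L
      ## boundary estimates make the AI step unusable and the EM step creep:
      ## stop once successive EM steps no longer move the likelihood
      if (state$m2ll - cand_state$m2ll < 1e-9 * (1 + abs(state$m2ll)))
        n_stall <- n_stall + 1L
      else
        n_stall <- 0L
    } else {
      n_stall <- 0L
    }
    rel_change <- max(abs(cand_state$theta - state$theta) /
                        (abs(state$theta) + 1))
    state <- cand_state
    if (n_stall >= 5L) {
      stalled <- TRUE
      break
    }
  }
  k <- design$k
  q <- design$q
  npe <- length(design$pe_ids)
  a_hat <- matrix(state$sol[design$n_fixed + seq_len(q * k)],
                  ncol = k, byrow = TRUE)
  pe_hat <- matrix(state$sol[design$n_fixed + q * k + seq_len(npe * k)],
                   ncol = k, byrow = TRUE)
  rownames(pe_hat) <- design$pe_ids
  structure(list(
    params = as_trait_params(state$theta, require_pd = FALSE),
    theta = setNames(state$theta, .theta_names),
    m2ll = state$m2ll, loglik = -0.5 * state$m2ll,
    converged = converged, stalled = stalled, iterations = iter,
    gradient = upd$gradient, grad_norm = sqrt(sum(upd$gradient^2)),
    AI = upd$AI, n_em_steps = n_em,
    fixed = state$sol[seq_len(design$n_fixed)],
    a_hat = a_hat, pe_hat = pe_hat
  ), class = "reml_result")
}

#' @method print reml_result
#' @export
print.reml_result <- function(x, ...) {
  cat("AI-REML fit:",
      if (x$converged) "converged"
      else if (x$stalled) "stalled at a parameter-space boundary"
      else "NOT converged",
      "after", x$iterations, "iterations",
      if (x$n_em_steps) paste0("(", x$n_em_steps, " EM fallback steps)")
      else "", "\n")
  cat("-2 logL_R:", format(x$m2ll, digits = 10), "  |grad|:",
      format(x$grad_norm, digits = 3), "\n")
  print(round(rbind(estimate = x$theta), 4))
  invisible(x)
}
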