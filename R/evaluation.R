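#' Solve the mixed model equations for BLUP
#'
#' Sparse Cholesky solve of an assembled [assemble_mme()] system at fixed
#' variance components, returning the fixed-effect solutions (BLUE) and the
#' additive and permanent-environment coefficient predictions (BLUP).
#'
#' @param mme an `mme_system`.
#' @return list of class `blup_solution` with `fixed`, `a_hat` (one row per
#'   pedigree animal), `pe_hat` (one row per recorded animal, rownames =
#'   ids) and the full `solution` vector.
#' @export
solve_blup <- function(mme) {
  ch <- tryCatch(Matrix::Cholesky(mme$C, LDL = TRUE, super = FALSE,
                                  perm = TRUE),
                 error = function(e)
                   stop("singular mixed model equations: ",
                        conditionMessage(e)))
  sol <- as.vector(Matrix::solve(ch, mme$rhs))
  design <- mme$design
  k <- design$k
  q <- design$q
  npe <- length(design$pe_ids)
  a_hat <- matrix(sol[design$n_fixed + seq_len(q * k)], ncol = k,
                  byrow = TRUE)
  pe_hat <- matrix(sol[design$n_fixed + q * k + seq_len(npe * k)],
                   ncol = k, byrow = TRUE)
  rownames(pe_hat) <- design$pe_ids
  structure(list(fixed = sol[seq_len(design$n_fixed)], a_hat = a_hat,
                 pe_hat = pe_hat, solution = sol),
            class = "blup_solution")
}

#' Whole-trajectory selection index
#'
#' The index of an animal is the weighted sum of its (estimated or true)
#' breeding values over the test time points,
#' `index = sum_t w_t phi(t)' a = (L' w)' a`; the study design weighs all
#' six time points equally (`w = 1`).
#'
#' @param a matrix of regression coefficients, one row per animal.
#' @param L Legendre covariate matrix.
#' @param weights per-time-point weights (length `nrow(L)`).
#' @return numeric vector of index values.
#' @export
selection_index <- function(a, L, weights = rep(1, nrow(L))) {
  if (length(weights) != nrow(L))
    stop("weights must have one entry per time point")
  as.vector(a %*% crossprod(L, weights))
}

#' EBV table with true counterparts
#'
#' Combines estimated coefficients with the simulated true breeding values
#' into the per-animal table used for validation: estimated coefficients,
#' per-time-point EBV, the selection index and its true counterpart.
#'
#' @param a_hat estimated additive coefficients (rows = pedigree animals).
#' @param effects true additive coefficients from
#'   [simulate_genetic_effects()], or `NULL`.
#' @param L Legendre covariate matrix.
#' @param weights index weights.
#' @return `data.frame` with columns `id`, `a0_hat`, `a1_hat`,
#'   `ebv_t1..ebv_tT`, `index` and (when truth is supplied) `true_index`.
#' @export
ebv_table <- function(a_hat, effects = NULL, L = legendre_matrix(1:6, 1),
                      weights = rep(1, nrow(L))) {
  ebv <- a_hat %*% t(L)
  out <- data.frame(id = seq_len(nrow(a_hat)), a0_hat = a_hat[, 1],
                    a1_hat = a_hat[, 2])
  colnames(ebv) <- paste0("ebv_t", seq_len(ncol(ebv)))
  out <- cbind(out, ebv)
  out$index <- selection_index(a_hat, L, weights)
  if (!is.null(effects))
    out$true_index <- selection_index(effects, L, weights)
  out
}

#' Accuracy and bias of genetic evaluation
#'
#' Accuracy is the Pearson correlation between the estimated and true
#' selection indices; bias is summarized by the slope `b1` of the regression
#' of the true index on the estimated index (1 = unbiased, > 1 = deflated
#' EBVs). Both are computed over the validation cohort (animals having
#' phenotypic data).
#'
#' @param ebv table from [ebv_table()] including `true_index`.
#' @param cohort_ids ids over which to validate.
#' @return list with `r`, `b1` and `n_animals`.
#' @export
evaluate_ebv <- function(ebv, cohort_ids) {
  if (length(cohort_ids) == 0) stop("empty validation cohort")
  if (is.null(ebv$true_index)) stop("true breeding values missing")
  sub <- ebv[ebv$id %in% cohort_ids, ]
  if (var(sub$index) == 0 || var(sub$true_index) == 0)
    stop("undefined metric: zero variance in an index")
  list(r = cor(sub$index, sub$true_index),
       b1 = cov(sub$true_index, sub$index) / var(sub$index),
       n_animals = nrow(sub))
}
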