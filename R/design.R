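#' Sum pen mates' records into group measurements
#'
#' For every (pen, time) combination sums the observed phenotypes of the pen
#' members still on test; dropped members are excluded, so the active group
#' size `n` shrinks over time. Combinations with no active member emit no
#' record.
#'
#' @param phen phenotype table (after any drop out).
#' @param pens pen assignment from [assign_pens()] (rows `pen`, `id`, ...);
#'   assignments from several generations can be row-bound if pen ids are
#'   made unique first.
#' @return `data.frame` of class `group_records` with columns `pen`, `time`,
#'   `y_star`, `n`, and a list column `members` holding the active member
#'   ids of each record.
#' @export
aggregate_group_records <- function(phen, pens) {
  if (!all(pens$id %in% phen$id))
    stop("pen member missing from the phenotype table")
  sub <- phen[phen$id %in% pens$id & phen$observed, ]
  sub$pen <- pens$pen[match(sub$id, pens$id)]
  key <- split(seq_len(nrow(sub)), list(pen = sub$pen, time = sub$time),
               drop = TRUE)
  recs <- lapply(key, function(rows) {
    list(pen = sub$pen[rows[1]], time = sub$time[rows[1]],
         y_star = sum(sub$value[rows]), n = length(rows),
         members = sort(sub$id[rows]))
  })
  out <- data.frame(
    pen = vapply(recs, `[[`, numeric(1), "pen"),
    time = vapply(recs, `[[`, numeric(1), "time"),
    y_star = vapply(recs, `[[`, numeric(1), "y_star"),
    n = vapply(recs, `[[`, numeric(1), "n")
  )
  ord <- order(out$pen, out$time)
  out <- out[ord, ]
  out$members <- I(unname(lapply(recs, `[[`, "members"))[ord])
  rownames(out) <- NULL
  class(out) <- c("group_records", "data.frame")
  out
}

#' Design matrices for the individual- or group-record random regression model
#'
#' Builds the sparse fixed (`X`) and random (`Z_a`, additive; `Z_pe`,
#' permanent environment) design matrices over Legendre covariates, the
#' response `y` and the residual scale `d` (per-record multiplier of
#' `sigma_e2`).
#'
#' For individual records each row carries `phi(t)` once, the fixed part is a
#' single population regression curve, and `d = 1`. For group records the
#' covariates of all active members are summed into their coefficient
#' columns, the fixed part holds one regression curve per observed group-size
#' class (absorbing the group-size main effect), and `d = n_jt`.
#'
#' Additive equations are ordered coefficient-within-animal for every
#' pedigree animal; permanent-environment equations exist only for animals
#' with at least one observed record.
#'
#' @param data a `phenotypes` table (individual model) or `group_records`
#'   table (group model).
#' @param ped pedigree defining the additive equation order.
#' @param L Legendre covariate matrix.
#' @return an object of class `rr_design`.
#' @export
build_design <- function(data, ped, L = legendre_matrix(1:6, 1)) {
  .check_pedigree(ped)
  k <- ncol(L)
  q <- nrow(ped)
  Tn <- nrow(L)
  if (inherits(data, "group_records")) {
    recs <- data
    if (any(recs$time > Tn)) stop("record at a time point outside the basis")
    N <- nrow(recs)
    pe_ids <- sort(unique(unlist(recs$members)))
    if (!all(pe_ids %in% ped$id)) stop("group member not in pedigree")
    classes <- sort(unique(recs$n))
    cls <- match(recs$n, classes)
    ## X: curve per size class
    Xi <- rep(seq_len(N), each = k)
    Xj <- as.vector(vapply(cls, function(m) (m - 1) * k + seq_len(k),
                           numeric(k)))
    Xx <- as.vector(t(L[recs$time, , drop = FALSE]))
    X <- Matrix::sparseMatrix(i = Xi, j = Xj, x = Xx,
                              dims = c(N, k * length(classes)))
    ## Z: summed covariates of active members
    mlen <- lengths(recs$members)
    ri <- rep(rep(seq_len(N), mlen), each = k)
    mem <- unlist(recs$members)
    phit <- t(L[rep(recs$time, mlen), , drop = FALSE])
    Zx <- as.vector(phit)
    Za <- Matrix::sparseMatrix(i = ri,
                               j = as.vector(vapply(mem, function(a)
                                 (a - 1) * k + seq_len(k), numeric(k))),
                               x = Zx, dims = c(N, k * q))
    perank <- match(mem, pe_ids)
    Zpe <- Matrix::sparseMatrix(i = ri,
                                j = as.vector(vapply(perank, function(a)
                                  (a - 1) * k + seq_len(k), numeric(k))),
                                x = Zx, dims = c(N, k * length(pe_ids)))
    out <- list(model = "group", y = recs$y_star, X = X, Z_a = Za,
                Z_pe = Zpe, d = recs$n, n_fixed = ncol(X), k = k, q = q,
                pe_ids = pe_ids, L = L, classes = classes,
                records = recs[, c("pen", "time", "n")])
  } else {
    obs <- data[data$observed, ]
    if (any(obs$time > Tn)) stop("record at a time point outside the basis")
    if (!all(obs$id %in% ped$id)) stop("phenotyped animal not in pedigree")
    N <- nrow(obs)
    pe_ids <- sort(unique(obs$id))
    Xx <- as.vector(t(L[obs$time, , drop = FALSE]))
    ri <- rep(seq_len(N), each = k)
    X <- Matrix::sparseMatrix(i = ri, j = rep(seq_len(k), N), x = Xx,
                              dims = c(N, k))
    Za <- Matrix::sparseMatrix(i = ri,
                               j = as.vector(vapply(obs$id, function(a)
                                 (a - 1) * k + seq_len(k), numeric(k))),
                               x = Xx, dims = c(N, k * q))
    perank <- match(obs$id, pe_ids)
    Zpe <- Matrix::sparseMatrix(i = ri,
                                j = as.vector(vapply(perank, function(a)
                                  (a - 1) * k + seq_len(k), numeric(k))),
                                x = Xx, dims = c(N, k * length(pe_ids)))
    out <- list(model = "individual", y = obs$value, X = X, Z_a = Za,
                Z_pe = Zpe, d = rep(1, N), n_fixed = k, k = k, q = q,
                pe_ids = pe_ids, L = L, classes = NULL,
                records = obs[, c("id", "time")])
  }
  class(out) <- "rr_design"
  out
}

## Data-dependent, theta-independent pieces of the MME, computed once per fit.
.mme_parts <- function(design) {
  W <- cbind(design$X, design$Z_a, design$Z_pe)
  dinv <- 1 / design$d
  Wd <- W * dinv  # row-scaled
  list(W = W,
       WtDW = Matrix::forceSymmetric(Matrix::crossprod(W, Wd)),
       WtDy = as.vector(Matrix::crossprod(Wd, design$y)),
       ytDy = sum(design$y^2 * dinv),
       N = length(design$y),
       logdet_D = sum(log(design$d)))
}

## Default ridge on the fixed-effect diagonal: rare group-size classes can be
## observed at a single time point, leaving the class's curve rank deficient.
.default_ridge <- function(design) if (design$model == "group") 1e-8 else 0

## Coefficient matrix C(theta) and its Sigma^-1 summaries.
.build_C <- function(parts, design, a_inv, params, ridge = NULL) {
  if (is.null(ridge)) ridge <- .default_ridge(design)
  Ginv <- solve(params$G)
  Pinv <- solve(params$P)
  nf <- design$n_fixed
  q <- design$q
  npe <- length(design$pe_ids)
  Sinv <- Matrix::bdiag(
    Matrix::Diagonal(nf, x = 0),
    Matrix::kronecker(a_inv, Ginv),
    Matrix::kronecker(Matrix::Diagonal(npe), Pinv)
  )
  C <- parts$WtDW / params$sigma_e2 + Sinv
  ## a fixed equation with no data (zero diagonal) must still be solvable
  if (any(Matrix::diag(parts$WtDW)[seq_len(nf)] == 0))
    ridge <- max(ridge, 1e-8)
  if (ridge > 0) {
    eps <- ridge * (mean(Matrix::diag(parts$WtDW)[seq_len(nf)]) /
                      params$sigma_e2 + 1)
    C <- C + Matrix::bdiag(Matrix::Diagonal(nf, x = eps),
                           Matrix::Diagonal(nrow(C) - nf, x = 0))
  }
  Matrix::forceSymmetric(C)
}

#' Assemble Henderson's mixed model equations
#'
#' Forms the symmetric sparse coefficient matrix
#' `C = W' R^-1 W + blockdiag(0, A^-1 (x) G^-1, I (x) P^-1)` and right-hand
#' side `W' R^-1 y` with `W = [X, Z_a, Z_pe]` and `R = D sigma_e2`.
#'
#' @param design an `rr_design`.
#' @param a_inv sparse `A^-1` from [a_inverse()].
#' @param params [trait_params()] (must be positive definite).
#' @param ridge relative ridge added to the fixed-effect diagonal; defaults
#'   to 0 for the individual model and 1e-8 for the group model.
#' @return object of class `mme_system` with elements `C`, `rhs` and the
#'   equation index map.
#' @export
assemble_mme <- function(design, a_inv, params, ridge = NULL) {
  params <- as_trait_params(params)
  parts <- .mme_parts(design)
  C <- .build_C(parts, design, a_inv, params, ridge)
  structure(list(C = C, rhs = parts$WtDy / params$sigma_e2,
                 design = design, params = params, parts = parts,
                 a_inv = a_inv),
            class = "mme_system")
}

## Equation index helpers -----------------------------------------------------

.eq_additive <- function(design, animal, coef) {
  design$n_fixed + (animal - 1) * design$k + coef
}

.eq_pe <- function(design, pe_rank, coef) {
  design$n_fixed + design$q * design$k + (pe_rank - 1) * design$k + coef
}
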