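#' Simulate a closed pig population pedigree
#'
#' Generates `n_generations` non-overlapping generations. Generation 0 holds
#' unrelated founders: `n_sires` males and `n_sires * n_dams_per_sire`
#' females. In each later generation `n_sires` sires and
#' `n_sires * n_dams_per_sire` dams are selected at random from the previous
#' generation (random selection, random mating); every dam produces one
#' litter of `litter_size` piglets with sex assigned as Bernoulli(0.5).
#'
#' @param n_generations total number of generations including the founders
#'   (the study design uses 11: founders plus 10 offspring generations).
#' @param n_sires sires selected per generation.
#' @param n_dams_per_sire dams mated to each sire.
#' @param litter_size piglets per litter.
#' @param seed integer seed; the pedigree stage runs on its own stream.
#' @return a `data.frame` of class `pedigree` with columns `id`, `sire`,
#'   `dam` (0 = unknown), `sex` (`"M"`/`"F"`), `generation` (0-based) and
#'   `litter` (0 for founders); rows sorted parents-before-offspring.
#' @examples
#' ped <- simulate_pedigree(3, 2, 2, 4, seed = 1)
#' table(ped$generation)
#' @export
simulate_pedigree <- function(n_generations, n_sires, n_dams_per_sire,
                              litter_size, seed = 1) {
  stopifnot(n_generations >= 1, n_sires >= 1, n_dams_per_sire >= 1,
            litter_size >= 1)
  .set_stage_seed(seed, "pedigree")
  n_dams <- n_sires * n_dams_per_sire
  id <- seq_len(n_sires + n_dams)
  ped <- data.frame(
    id = id, sire = 0L, dam = 0L,
    sex = c(rep("M", n_sires), rep("F", n_dams)),
    generation = 0L, litter = 0L
  )
  next_id <- length(id) + 1L
  next_litter <- 1L
  if (n_generations > 1) {
    for (g in seq_len(n_generations - 1)) {
      prev <- ped[ped$generation == g - 1L, ]
      males <- prev$id[prev$sex == "M"]
      females <- prev$id[prev$sex == "F"]
      if (length(males) < n_sires || length(females) < n_dams)
        stop("infeasible design: generation ", g - 1, " has ",
             length(males), " males and ", length(females),
             " females; need ", n_sires, " sires and ", n_dams, " dams")
      sires <- sample(males, n_sires)
      dams <- sample(females, n_dams)
      sire_of_dam <- rep(sires, each = n_dams_per_sire)
      n_off <- n_dams * litter_size
      off <- data.frame(
        id = seq.int(next_id, length.out = n_off),
        sire = rep(sire_of_dam, each = litter_size),
        dam = rep(dams, each = litter_size),
        sex = ifelse(runif(n_off) < 0.5, "M", "F"),
        generation = g,
        litter = rep(seq.int(next_litter, length.out = n_dams),
                     each = litter_size)
      )
      next_id <- next_id + n_off
      next_litter <- next_litter + n_dams
      ped <- rbind(ped, off)
    }
  }
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

.check_pedigree <- function(ped) {
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(ped))) stop("pedigree needs columns id, sire, dam")
  if (!identical(as.integer(ped$id), seq_len(nrow(ped))))
    stop("pedigree ids must be 1..n in order")
  bad <- ped$sire >= ped$id & ped$sire != 0 | ped$dam >= ped$id & ped$dam != 0
  if (any(bad))
    stop("pedigree not sorted parents-before-offspring (or cyclic)")
  invisible(ped)
}

#' Inbreeding coefficients from a sorted pedigree
#'
#' Meuwissen-Luo recursion on the `A = T D T'` decomposition of the numerator
#' relationship matrix; equals `diag(A) - 1` of the tabular relationship
#' matrix.
#'
#' @param ped pedigree `data.frame` with `id`, `sire`, `dam` (ids `1..n`,
#'   parents before offspring, 0 = unknown parent).
#' @return numeric vector `F` with the Mendelian-sampling variance diagonal
#'   attached as attribute `"d"`.
#' @export
compute_inbreeding <- function(ped) {
  .check_pedigree(ped)
  res <- cpp_inbreeding(as.integer(ped$sire), as.integer(ped$dam))
  structure(res$F, d = res$d)
}

#' Simulate additive-genetic regression coefficients down a pedigree
#'
#' Founders draw their intercept/slope coefficient vector from `N(0, G)`;
#' each non-founder receives the parent average plus a Mendelian-sampling
#' deviation `m_i ~ N(0, 0.5 * (1 - F_i) * G)` with
#' `F_i = 0.5 * (F_s + F_d)`. For an animal with one or no known parent the
#' unknown parent is treated as a non-inbred founder draw, so the variance of
#' the animal's coefficients stays `G` in expectation.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param G additive coefficient covariance matrix.
#' @param seed integer seed (dedicated stream).
#' @param F inbreeding coefficients; computed from `ped` when missing.
#' @return numeric matrix `n x ncol(G)` of true breeding-value coefficients.
#' @export
simulate_genetic_effects <- function(ped, G = trait_params()$G, seed = 1,
                                     F = NULL) {
  .check_pedigree(ped)
  G <- as.matrix(G)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (any(G != 0) && min(ev) < -1e-8 * max(abs(ev)))
    stop("G is not positive semi-definite")
  if (is.null(F)) F <- compute_inbreeding(ped)
  .set_stage_seed(seed, "effects")
  n <- nrow(ped)
  k <- ncol(G)
  ch <- if (all(G == 0)) matrix(0, k, k) else chol(G)
  ## standard normals drawn in pedigree order, one k-vector per animal
  zmat <- matrix(rnorm(n * k), n, k) %*% ch
  a <- matrix(0, n, k)
  sire <- ped$sire; dam <- ped$dam
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    if (s == 0 && d == 0) {
      a[i, ] <- zmat[i, ]
    } else {
      pa <- (if (s > 0) a[s, ] else 0) + (if (d > 0) a[d, ] else 0)
      Fi <- 0.5 * ((if (s > 0) F[s] else 0) + (if (d > 0) F[d] else 0))
      ## Mendelian variance: 0.5(1-Fi)G both parents known; with an unknown
      ## parent, its founder draw contributes an extra G/4.
      vscale <- if (s > 0 && d > 0) 0.5 * (1 - Fi) else 0.75 - 0.25 * Fi
      a[i, ] <- 0.5 * pa + sqrt(vscale) * zmat[i, ]
    }
  }
  colnames(a) <- paste0("a", seq_len(k) - 1)
  a
}

#' Simulate permanent-environment effects and longitudinal phenotypes
#'
#' For each phenotyped animal draws permanent-environment coefficients
#' `pe ~ N(0, P)` and residuals `e_it ~ N(0, sigma_e2)` and forms
#' `y_it = phi(t)' a_i + phi(t)' pe_i + e_it` at every time point of the
#' basis. The simulated trait mean is zero and no fixed effects are
#' generated.
#'
#' @param ped pedigree.
#' @param effects matrix of additive coefficients from
#'   [simulate_genetic_effects()].
#' @param params [trait_params()].
#' @param L Legendre covariate matrix over the test times.
#' @param generations integer vector of generation indices to phenotype
#'   (e.g. the last five); default: all.
#' @param seed integer seed (dedicated stream).
#' @return a `data.frame` of class `phenotypes` with columns `id`, `time`
#'   (1-based index into the basis rows), `value`, `observed` (all `TRUE`
#'   until drop out is applied); the permanent-environment coefficient matrix
#'   is attached as attribute `"pe"` (rows named by id).
#' @export
simulate_pe_and_phenotypes <- function(ped, effects, params = trait_params(),
                                       L = legendre_matrix(1:6, 1),
                                       generations = NULL, seed = 1) {
  .check_pedigree(ped)
  params <- as_trait_params(params, require_pd = FALSE)
  if (nrow(effects) != nrow(ped))
    stop("effects must have one row per pedigree animal")
  if (is.null(generations)) generations <- unique(ped$generation)
  ids <- ped$id[ped$generation %in% generations]
  if (length(ids) == 0) stop("no animals in the requested generations")
  .set_stage_seed(seed, "phenotype")
  n <- length(ids)
  T <- nrow(L)
  k <- ncol(L)
  P <- as.matrix(params$P)
  chP <- if (all(P == 0)) matrix(0, k, k) else chol(P)
  pe <- matrix(rnorm(n * k), n, k) %*% chP
  rownames(pe) <- ids
  e <- matrix(rnorm(n * T, sd = sqrt(params$sigma_e2)), n, T)
  Y <- (effects[ids, , drop = FALSE] + pe) %*% t(L) + e
  out <- data.frame(
    id = rep(ids, each = T),
    time = rep(seq_len(T), n),
    value = as.vector(t(Y)),
    observed = TRUE
  )
  attr(out, "pe") <- pe
  class(out) <- c("phenotypes", "data.frame")
  out
}
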