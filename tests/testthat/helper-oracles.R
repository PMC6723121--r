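# Independent dense oracles for the sparse MME machinery. These build the
# phenotypic covariance V = Z_a (A x G) Z_a' + Z_pe (I x P) Z_pe' + D se2
# explicitly and work from V, never touching the MME route they check.

dense_V <- function(theta, design, A) {
  G <- matrix(theta[c(1, 2, 2, 3)], 2)
  P <- matrix(theta[c(4, 5, 5, 6)], 2)
  Za <- as.matrix(design$Z_a)
  Zpe <- as.matrix(design$Z_pe)
  Za %*% kronecker(A, G) %*% t(Za) +
    Zpe %*% kronecker(diag(length(design$pe_ids)), P) %*% t(Zpe) +
    diag(design$d, nrow = length(design$d)) * theta[7]
}

oracle_m2ll <- function(theta, design, A) {
  V <- dense_V(theta, design, A)
  X <- as.matrix(design$X)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  Pm <- Vi - Vi %*% X %*% solve(XVX, t(X) %*% Vi)
  as.numeric(determinant(V)$modulus + determinant(XVX)$modulus +
               t(design$y) %*% Pm %*% design$y)
}

oracle_blup <- function(theta, design, A) {
  G <- matrix(theta[c(1, 2, 2, 3)], 2)
  P <- matrix(theta[c(4, 5, 5, 6)], 2)
  V <- dense_V(theta, design, A)
  X <- as.matrix(design$X)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% design$y)
  resid <- design$y - X %*% beta
  ua <- kronecker(A, G) %*% t(as.matrix(design$Z_a)) %*% Vi %*% resid
  upe <- kronecker(diag(length(design$pe_ids)), P) %*%
    t(as.matrix(design$Z_pe)) %*% Vi %*% resid
  list(fixed = as.vector(beta),
       a_hat = matrix(ua, ncol = 2, byrow = TRUE),
       pe_hat = matrix(upe, ncol = 2, byrow = TRUE))
}

# Random valid pedigree: founders plus animals with parents drawn from
# earlier animals (occasionally unknown), for property-style checks.
random_pedigree <- function(n, n_founders = 10, seed = 1) {
  set.seed(seed)
  sire <- dam <- integer(n)
  sex <- c(rep(c("M", "F"), length.out = n_founders),
           sample(c("M", "F"), max(n - n_founders, 0), replace = TRUE))
  for (i in seq_len(n)[-seq_len(n_founders)]) {
    males <- which(sex[seq_len(i - 1)] == "M")
    females <- which(sex[seq_len(i - 1)] == "F")
    sire[i] <- if (runif(1) < 0.9) sample(males, 1) else 0L
    dam[i] <- if (runif(1) < 0.9) sample(females, 1) else 0L
  }
  ped <- data.frame(id = seq_len(n), sire = sire, dam = dam, sex = sex,
                    generation = c(rep(0L, n_founders),
                                   rep(1L, n - n_founders)),
                    litter = 0L)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Small simulated individual-record dataset used by several fixtures.
small_dataset <- function(seed = 11, n_generations = 3, n_sires = 2,
                          n_dams = 2, litter = 3, gens = 1:2) {
  L <- legendre_matrix(1:6, 1)
  # tiny populations can draw an infeasible sex split; step the seed until
  # the design is feasible (deterministic given `seed`)
  for (s in seed + 1000 * (0:50)) {
    ped <- try(simulate_pedigree(n_generations, n_sires, n_dams, litter,
                                 seed = s), silent = TRUE)
    if (!inherits(ped, "try-error")) break
  }
  seed <- s
  eff <- simulate_genetic_effects(ped, trait_params()$G, seed = seed)
  phen <- simulate_pe_and_phenotypes(ped, eff, trait_params(), L,
                                     generations = gens, seed = seed)
  list(L = L, ped = ped, eff = eff, phen = phen,
       design = build_design(phen, ped, L),
       A = tabular_A(ped), ainv = a_inverse(ped))
}
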