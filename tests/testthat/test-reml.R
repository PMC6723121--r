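theta_near <- c(60, -5, 7, 30, 4, 29, 50)

test_that("MME-route REML deviance equals the dense-V formula", {
  dat <- small_dataset(seed = 41)
  expect_equal(reml_loglik(theta_near, dat$design, dat$ainv),
               oracle_m2ll(theta_near, dat$design, dat$A),
               tolerance = 1e-8)
  # and for the group model (ridge disabled so the formulas agree exactly)
  ids <- unique(dat$phen$id)
  pens <- data.frame(pen = rep(seq_len(length(ids) / 3), each = 3),
                     generation = NA, id = ids, litter = NA)
  gr <- aggregate_group_records(dat$phen, pens)
  des_g <- build_design(gr, dat$ped, dat$L)
  expect_equal(reml_loglik(theta_near, des_g, dat$ainv, ridge = 0),
               oracle_m2ll(theta_near, des_g, dat$A),
               tolerance = 1e-8)
})

test_that("deviance responds to data transformations as a quadratic form", {
  dat <- small_dataset(seed = 42)
  des <- dat$design
  # scaling y by c changes y'Py by c^2 (log-determinant terms unchanged)
  V <- dense_V(theta_near, des, dat$A)
  X <- as.matrix(des$X)
  Vi <- solve(V)
  Pm <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X, t(X) %*% Vi)
  yPy <- as.numeric(t(des$y) %*% Pm %*% des$y)
  des_c <- des
  des_c$y <- 2 * des$y
  expect_equal(reml_loglik(theta_near, des_c, dat$ainv) -
                 reml_loglik(theta_near, des, dat$ainv),
               (4 - 1) * yPy, tolerance = 1e-6)
  # an independent duplicate of the data doubles the deviance, except for
  # the fixed-effect information term: the shared regression curve sees
  # twice the information, log|2 X'V^-1 X| = p log 2 + log|X'V^-1 X|
  n <- nrow(dat$ped)
  ped2 <- rbind(dat$ped, transform(dat$ped, id = id + n,
                                   sire = ifelse(sire > 0, sire + n, 0),
                                   dam = ifelse(dam > 0, dam + n, 0)))
  class(ped2) <- c("pedigree", "data.frame")
  phen2 <- rbind(dat$phen, transform(dat$phen, id = id + n))
  des2 <- build_design(phen2, ped2, dat$L)
  XVX <- t(X) %*% Vi %*% X
  expect_equal(reml_loglik(theta_near, des2, a_inverse(ped2)),
               2 * reml_loglik(theta_near, des, dat$ainv) +
                 2 * log(2) - as.numeric(determinant(XVX)$modulus),
               tolerance = 1e-6)
})

test_that("analytic score matches finite differences of the deviance", {
  dat <- small_dataset(seed = 43)
  for (des in list(dat$design)) {
    upd <- ai_update(theta_near, des, dat$ainv)
    fd <- vapply(1:7, function(i) {
      h <- 1e-4 * (abs(theta_near[i]) + 1)
      tp <- tm <- theta_near
      tp[i] <- tp[i] + h
      tm[i] <- tm[i] - h
      -0.5 * (reml_loglik(tp, des, dat$ainv) -
                reml_loglik(tm, des, dat$ainv)) / (2 * h)
    }, numeric(1))
    expect_equal(unname(upd$gradient), fd, tolerance = 1e-4)
    expect_gt(min(eigen(upd$AI, symmetric = TRUE,
                        only.values = TRUE)$values), -1e-8)
  }
})

test_that("Takahashi selected inverse agrees with the dense inverse", {
  dat <- small_dataset(seed = 44, n_generations = 4)
  dense <- ai_update(theta_near, dat$design, dat$ainv,
                     dense_threshold = 1e9)
  sparse <- ai_update(theta_near, dat$design, dat$ainv,
                      dense_threshold = 0)
  expect_equal(dense$gradient, sparse$gradient, tolerance = 1e-9)
  expect_equal(dense$theta_em, sparse$theta_em, tolerance = 1e-9)
  expect_equal(dense$AI, sparse$AI, tolerance = 1e-9)
})

test_that("the REML score is centered at the generating parameters", {
  truth <- c(63.42, -5.42, 6.85, 30.61, 4.28, 29.25, 53.45)
  grads <- t(vapply(1:25, function(s) {
    dat <- small_dataset(seed = 400 + s, n_generations = 3, n_sires = 3,
                         n_dams = 3, litter = 4, gens = 1:2)
    unname(ai_update(truth, dat$design, dat$ainv)$gradient)
  }, numeric(7)))
  se <- apply(grads, 2, sd) / sqrt(nrow(grads))
  expect_true(all(abs(colMeans(grads)) < 3 * se + 1e-12))
})

test_that("AI-REML converges, improves monotonically and honors theta0", {
  dat <- small_dataset(seed = 7, n_generations = 4, n_sires = 4,
                       n_dams = 4, litter = 6, gens = 2:3)
  fit <- estimate_vc(dat$design, dat$ainv)
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-6)
  # accepted iterations never worsened the deviance
  start <- groupRR:::.default_start(dat$design)
  expect_lte(fit$m2ll, reml_loglik(start, dat$design, dat$ainv) + 1e-8)
  # restarting at the optimum stays put, without EM fallback
  fit2 <- estimate_vc(dat$design, dat$ainv, theta0 = fit$theta)
  expect_true(fit2$converged)
  expect_lte(fit2$iterations, 3)
  expect_equal(fit2$n_em_steps, 0L)
  expect_equal(unname(fit2$theta), unname(fit$theta), tolerance = 1e-5)
})

test_that("pure-noise data drives the variance ratios to the boundary", {
  L <- legendre_matrix(1:6, 1)
  ped <- simulate_pedigree(2, 4, 4, 5, seed = 46)
  noise <- trait_params(G = matrix(0, 2, 2), P = matrix(0, 2, 2),
                        sigma_e2 = 25)
  a0 <- matrix(0, nrow(ped), 2)
  phen <- simulate_pe_and_phenotypes(ped, a0, noise, L, seed = 46)
  des <- build_design(phen, ped, L)
  fit <- estimate_vc(des, a_inverse(ped), options = list(max_iter = 60))
  expect_equal(unname(fit$theta[["sigma_e2"]]), var(phen$value),
               tolerance = 0.1)
  expect_lt(fit$theta[["G11"]], 0.15 * var(phen$value))
  expect_lt(fit$theta[["P11"]], 0.15 * var(phen$value))
})
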