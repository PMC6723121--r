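test_that("pedigree simulation produces the designed family structure", {
  ped <- simulate_pedigree(3, 2, 2, 4, seed = 1)
  expect_equal(sum(ped$generation == 0), 2 + 4)
  expect_equal(sum(ped$generation == 1), 2 * 2 * 4)
  expect_equal(sum(ped$generation == 2), 2 * 2 * 4)
  # full sibs share sire, dam and litter; litters have the set size
  off <- ped[ped$generation > 0, ]
  for (l in split(off, off$litter)) {
    expect_equal(nrow(l), 4)
    expect_equal(length(unique(l$sire)), 1)
    expect_equal(length(unique(l$dam)), 1)
  }
  # parents precede offspring; sires male, dams female
  expect_true(all(ped$sire < ped$id & ped$dam < ped$id))
  expect_true(all(ped$sex[off$sire] == "M"))
  expect_true(all(ped$sex[off$dam] == "F"))

  tiny <- simulate_pedigree(2, 1, 1, 6, seed = 1)
  expect_equal(sum(tiny$generation == 1), 6)
  expect_equal(length(unique(tiny$litter[tiny$generation == 1])), 1)

  # a generation too small to supply the required dams fails loudly
  expect_error(simulate_pedigree(3, 4, 8, 1, seed = 1), "infeasible")

  expect_identical(simulate_pedigree(3, 2, 2, 4, seed = 7),
                   simulate_pedigree(3, 2, 2, 4, seed = 7))
})

test_that("inbreeding recursion agrees with the tabular relationship matrix", {
  ped <- simulate_pedigree(4, 3, 3, 4, seed = 2)
  expect_equal(as.vector(compute_inbreeding(ped)),
               diag(tabular_A(ped)) - 1, tolerance = 1e-12)
  expect_true(all(compute_inbreeding(ped)[ped$generation == 0] == 0))
  # offspring of two full sibs with unrelated grandparents
  ped2 <- data.frame(id = 1:5, sire = c(0, 0, 1, 1, 3),
                     dam = c(0, 0, 2, 2, 4), sex = c("M", "F", "M", "F", "M"),
                     generation = c(0, 0, 1, 1, 2), litter = c(0, 0, 1, 1, 2))
  expect_equal(as.vector(compute_inbreeding(ped2)), c(0, 0, 0, 0, 0.25))
})

test_that("founder breeding values recover the generating covariance", {
  ped <- simulate_pedigree(1, 150, 132, 1, seed = 3)  # ~20k founders
  G <- trait_params()$G
  a <- simulate_genetic_effects(ped, G, seed = 3)
  emp <- cov(a)
  n <- nrow(a)
  mc_se <- sqrt((outer(diag(G), diag(G)) + G^2) / n)
  expect_true(all(abs(emp - G) < 3 * mc_se))
  expect_equal(simulate_genetic_effects(ped, matrix(0, 2, 2), seed = 3),
               matrix(0, nrow(ped), 2), ignore_attr = TRUE)
})

test_that("Mendelian sampling has variance G/2 for non-inbred parents", {
  n_off <- 4000
  ped <- data.frame(id = seq_len(n_off + 2),
                    sire = c(0, 0, rep(1L, n_off)),
                    dam = c(0, 0, rep(2L, n_off)),
                    sex = c("M", "F", rep("M", n_off)),
                    generation = c(0, 0, rep(1L, n_off)),
                    litter = c(0, 0, rep(1L, n_off)))
  class(ped) <- c("pedigree", "data.frame")
  G <- trait_params()$G
  a <- simulate_genetic_effects(ped, G, seed = 4)
  m <- a[-(1:2), ] - rep(1, n_off) %o% ((a[1, ] + a[2, ]) / 2)
  emp <- cov(m)
  mc_se <- sqrt((outer(diag(G) / 2, diag(G) / 2) + (G / 2)^2) / n_off)
  expect_true(all(abs(emp - G / 2) < 3 * mc_se))
})

test_that("parent-offspring regression of breeding values is about 1/2", {
  ped <- simulate_pedigree(3, 8, 8, 5, seed = 5)
  a <- simulate_genetic_effects(ped, trait_params()$G, seed = 5)
  off <- ped[ped$generation > 0, ]
  for (coef in 1:2) {
    b <- coef(lm(a[off$id, coef] ~ a[off$sire, coef]))[2]
    expect_lt(abs(unname(b) - 0.5), 0.15)
  }
})

test_that("phenotypes carry the implied variance and mean structure", {
  L <- legendre_matrix(1:6, 1)
  tp <- trait_params()
  ped <- simulate_pedigree(1, 60, 82, 1, seed = 6)  # ~5k founders
  a <- simulate_genetic_effects(ped, tp$G, seed = 6)
  phen <- simulate_pe_and_phenotypes(ped, a, tp, L, seed = 6)
  expect_equal(nrow(phen), nrow(ped) * 6)
  expect_true(all(phen$observed))
  v_expected <- trajectory_variance(tp$G, L) +
    trajectory_variance(tp$P, L) + tp$sigma_e2
  expect_equal(v_expected[[1]], 156.59, tolerance = 1e-3)
  for (t in c(1, 6)) {
    y_t <- phen$value[phen$time == t]
    se <- v_expected[t] * sqrt(2 / (length(y_t) - 1))
    expect_lt(abs(var(y_t) - v_expected[t]), 3 * se)
  }
  # pure-noise parameters give iid standard normals
  noise <- trait_params(G = matrix(0, 2, 2), P = matrix(0, 2, 2),
                        sigma_e2 = 1)
  a0 <- matrix(0, nrow(ped), 2)
  ph0 <- simulate_pe_and_phenotypes(ped, a0, noise, L, seed = 6)
  expect_equal(var(ph0$value), 1, tolerance = 0.05)
  expect_equal(mean(ph0$value), 0, tolerance = 0.05)
  expect_error(
    simulate_pe_and_phenotypes(ped, a, tp, L, generations = 99, seed = 1),
    "no animals")
})
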