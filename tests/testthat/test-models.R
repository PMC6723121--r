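make_pen_phen <- function(values, times = 1, ids = seq_along(values)) {
  data.frame(id = rep(ids, each = length(times)),
             time = rep(times, length(ids)),
             value = rep(values, each = length(times)),
             observed = TRUE)
}

test_that("group records sum the active members at each time point", {
  phen <- data.frame(id = rep(1:3, each = 2), time = rep(1:2, 3),
                     value = c(10, 10, 12, 12, 14, 14), observed = TRUE)
  pens <- data.frame(pen = 1, generation = 1, id = 1:3, litter = 1:3)
  gr <- aggregate_group_records(phen, pens)
  expect_equal(gr$y_star, c(36, 36))
  expect_equal(gr$n, c(3, 3))
  expect_equal(gr$members[[1]], 1:3)
  # a member dropped before t is excluded from that record
  phen2 <- apply_dropout(phen, data.frame(id = 3, drop_time = 2,
                                          strategy = "random"))
  gr2 <- aggregate_group_records(phen2, pens)
  expect_equal(gr2$y_star[gr2$time == 2], 22)
  expect_equal(gr2$n[gr2$time == 2], 2)
  # an all-dropped pen emits no record at that time
  phen3 <- apply_dropout(phen, data.frame(id = 1:3, drop_time = 2,
                                          strategy = "random"))
  gr3 <- aggregate_group_records(phen3, pens)
  expect_equal(gr3$time, 1)
  expect_error(aggregate_group_records(phen[phen$id != 2, ], pens),
               "missing")
})

test_that("group design rows carry summed member covariates and D = n", {
  L <- legendre_matrix(1:6, 1)
  ped <- random_pedigree(12, n_founders = 12, seed = 1)
  phen <- make_pen_phen(rnorm(12), times = 1:6, ids = 1:12)
  pens <- data.frame(pen = 1, generation = 0, id = 1:12, litter = 1:12)
  gr <- aggregate_group_records(phen, pens)
  des <- build_design(gr, ped, L)
  expect_equal(des$d, rep(12, 6))  # residual variance 12 sigma_e2 per row
  r1 <- which(gr$time == 1)
  za <- as.matrix(des$Z_a)[r1, ]
  for (m in 1:12)
    expect_equal(unname(za[(m - 1) * 2 + 1:2]),
                 unname(L[1, ]), tolerance = 1e-10)
})

test_that("singleton pens reproduce the individual-model design", {
  L <- legendre_matrix(1:6, 1)
  dat <- small_dataset(seed = 31)
  ids <- unique(dat$phen$id)
  pens <- data.frame(pen = seq_along(ids), generation = NA, id = ids,
                     litter = NA)
  gr <- aggregate_group_records(dat$phen, pens)
  des_g <- build_design(gr, dat$ped, L)
  des_i <- dat$design
  expect_equal(des_g$d, des_i$d)
  # same records up to row order: match on (animal, time)
  key_g <- paste(vapply(gr$members, `[[`, numeric(1), 1), gr$time)
  key_i <- paste(des_i$records$id, des_i$records$time)
  ord <- match(key_i, key_g)
  expect_equal(as.matrix(des_g$Z_a)[ord, ], as.matrix(des_i$Z_a),
               ignore_attr = TRUE)
  expect_equal(as.matrix(des_g$Z_pe)[ord, ], as.matrix(des_i$Z_pe),
               ignore_attr = TRUE)
  expect_equal(as.matrix(des_g$X)[ord, ], as.matrix(des_i$X),
               ignore_attr = TRUE)
  expect_equal(des_g$y[ord], des_i$y)
})

test_that("group-model predictions sum the members' individual predictions", {
  L <- legendre_matrix(1:6, 1)
  dat <- small_dataset(seed = 32)
  ids <- unique(dat$phen$id)
  pens <- data.frame(pen = rep(seq_len(length(ids) / 4), each = 4),
                     generation = NA, id = ids, litter = NA)
  gr <- aggregate_group_records(dat$phen, pens)
  des_g <- build_design(gr, dat$ped, L)
  des_i <- dat$design
  pe <- attr(dat$phen, "pe")
  u_a <- as.vector(t(dat$eff))
  u_pe <- as.vector(t(pe))
  pred_g <- as.vector(des_g$Z_a %*% u_a + des_g$Z_pe %*% u_pe)
  pred_i <- as.vector(des_i$Z_a %*% u_a + des_i$Z_pe %*% u_pe)
  agg <- tapply(pred_i,
                paste(pens$pen[match(des_i$records$id, pens$id)],
                      des_i$records$time),
                sum)
  expect_equal(pred_g, as.vector(agg[paste(gr$pen, gr$time)]),
               tolerance = 1e-10)
})

test_that("assembled equations are symmetric PD and solve edge cases", {
  dat <- small_dataset(seed = 33)
  tp <- trait_params()
  mme <- assemble_mme(dat$design, dat$ainv, tp)
  C <- mme$C
  expect_s4_class(C, "dsCMatrix")
  expect_silent(Matrix::Cholesky(C))  # PD after adding Sigma^-1
  # no records: BLUP falls back to the prior mean of zero
  none <- dat$phen
  none$observed <- FALSE
  des0 <- build_design(none, dat$ped, legendre_matrix(1:6, 1))
  bl0 <- solve_blup(assemble_mme(des0, dat$ainv, tp))
  expect_equal(max(abs(bl0$a_hat)), 0)
  expect_error(assemble_mme(dat$design, dat$ainv,
                            trait_params(G = matrix(c(1, 2, 2, 1), 2))),
               "positive definite")
})
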