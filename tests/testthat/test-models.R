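gm_pars <- c(kappa = -2, alpha = 1.4, beta = 0.7, gamma = 3.2,
             epsilon = 2.1, disp = 1)

test_that("directional gravity flows follow the offset power-law kernel", {
  # self-flow: kernel is 1 at d = 0
  sys1 <- line_system(10)
  F1 <- gravity_flow_directional(sys1, c(kappa = 0, alpha = 1, beta = 1,
                                         gamma = 3, epsilon = 2))
  expect_equal(F1[1, 1], 100)

  # at d = 10^gamma the kernel equals 2
  sys2 <- spatial_system(data.frame(id = 1:2, x = c(0, 10^3), y = 0,
                                    population = 1, admin_id = 1:2), "toy")
  F2 <- gravity_flow_directional(sys2, c(kappa = 0, alpha = 1, beta = 1,
                                         gamma = 3, epsilon = 2))
  expect_equal(F2[1, 2], 0.5)

  # random system vs scalar oracle
  sys <- random_system(5, 2, seed = 5)
  F <- gravity_flow_directional(sys, gm_pars)
  O <- oracle_gravity(sys$cells, sys$D, -2, 1.4, 0.7, 3.2, 2.1)
  expect_equal(unclass(F), O, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(F > 0))
  expect_identical(attr(F, "diagonal_policy"), "included")

  sys_zero <- suppressWarnings(
    spatial_system(data.frame(id = 1:2, x = c(0, 1), y = 0,
                              population = c(0, 1), admin_id = 1), "z"))
  expect_error(gravity_flow_directional(sys_zero, gm_pars), "positive")
})

test_that("the directional gravity model can be rewritten with the kernel scale absorbed", {
  # 10^k m^a m^b / (1 + (d/10^g)^e)  ==  10^(k+ge) m^a m^b / (10^(ge) + d^e)
  sys <- random_system(20, 3, seed = 9)
  F <- gravity_flow_directional(sys, gm_pars)
  m <- sys$cells$population
  ge <- gm_pars[["gamma"]] * gm_pars[["epsilon"]]
  alt <- 10^(gm_pars[["kappa"]] + ge) *
    tcrossprod(m^gm_pars[["alpha"]], m^gm_pars[["beta"]]) /
    (10^ge + sys$D^gm_pars[["epsilon"]])
  expect_equal(unclass(F), alt, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("symmetrised gravity flows are exactly symmetric and match the transpose identity", {
  sys <- random_system(12, 3, seed = 21)
  Fs <- gravity_flow_symmetrised(sys, gm_pars)
  expect_identical(unclass(Fs), t(unclass(Fs)))

  # equals 10^(-gamma*epsilon) * (directional + its transpose)
  Fd <- unclass(gravity_flow_directional(sys, gm_pars))
  ge <- gm_pars[["gamma"]] * gm_pars[["epsilon"]]
  expect_equal(unclass(Fs), 10^(-ge) * (Fd + t(Fd)), tolerance = 1e-12,
               ignore_attr = TRUE)

  # alpha = beta collapses the two numerator terms
  pars_ab <- c(kappa = 1, alpha = 1.2, beta = 1.2, gamma = 3, epsilon = 2)
  Fab <- gravity_flow_symmetrised(sys, pars_ab)
  m <- sys$cells$population
  kern <- 1 + (sys$D / 10^3)^2
  expect_equal(unclass(Fab), 10^(1 - 6) * 2 * tcrossprod(m^1.2) / kern,
               tolerance = 1e-12, ignore_attr = TRUE)

  # plain 10^kappa scaling differs by exactly 10^(gamma*epsilon)
  Fp <- gravity_flow_symmetrised(sys, gm_pars, kappa_adjusted = FALSE)
  expect_equal(unclass(Fp), 10^ge * unclass(Fs), tolerance = 1e-12)
})

test_that("radiation flows match the emission-absorption formula per variant", {
  # two locations, RM1: r = 0 so flow is kappa * m0 m1 / (m0 + m1)
  sys2 <- line_system(c(30, 70))
  rings2 <- ring_population(sys2)
  F2 <- radiation_flow(sys2, rings2, c(kappa = 1, disp = 0), "RM1")
  expect_equal(F2[1, 2], 30 * 70 / 100)
  expect_equal(diag(unclass(F2)), c(0, 0))
  expect_identical(attr(F2, "diagonal_policy"), "excluded")

  # RM3: inflating the origin population by theta kills the flow in the
  # limit, decreasing monotonically once theta dominates ring + destination
  sys <- random_system(8, 2, seed = 31)
  rings <- ring_population(sys)
  f_at <- function(th) radiation_flow(sys, rings,
                                      c(kappa = 0, theta = th), "RM3")[1, 2]
  big <- sum(sys$cells$population)
  fs <- vapply(big * c(1, 10, 100, 1e4), f_at, numeric(1))
  expect_true(all(diff(fs) < 0))
  expect_lt(fs[4] / f_at(0), 1e-2)

  # RM4 on a 5-cell line vs scalar oracle
  line5 <- line_system(c(100, 250, 50, 400, 120), spacing_km = 7)
  r5 <- ring_population(line5)
  F4 <- radiation_flow(line5, r5, c(kappa = 0, alpha = 1, theta = 100), "RM4")
  O4 <- oracle_radiation(line5$cells, line5$D, "RM4", kappa = 0, alpha = 1,
                         theta = 100)
  expect_equal(unclass(F4), O4, tolerance = 1e-12, ignore_attr = TRUE)

  # RM2 vs oracle on a random system
  FR2 <- radiation_flow(sys, rings, c(kappa = -1, alpha = 1.3), "RM2")
  OR2 <- oracle_radiation(sys$cells, sys$D, "RM2", kappa = -1, alpha = 1.3)
  expect_equal(unclass(FR2), OR2, tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(radiation_flow(sys, rings, c(kappa = -1), "RM1"), "RM1")
  expect_error(radiation_flow(sys, rings, c(kappa = 0, theta = -5), "RM3"),
               "theta")
})

test_that("symmetrised radiation flows are the transpose sum of directional flows", {
  sys <- random_system(10, 3, seed = 41)
  rings <- ring_population(sys)
  pars <- c(kappa = -0.5, alpha = 1.1, theta = 500)
  Fd <- unclass(radiation_flow(sys, rings, pars, "RM4"))
  Fs <- radiation_flow_symmetrised(sys, rings, pars, "RM4")
  expect_equal(unclass(Fs), Fd + t(Fd), ignore_attr = TRUE)
  expect_identical(unclass(Fs), t(unclass(Fs)))

  # equal populations in symmetric geometry: symmetrised = 2 x directional
  sq <- spatial_system(data.frame(
    id = 1:4, x = c(0, 1e4, 0, 1e4), y = c(0, 0, 1e4, 1e4),
    population = 50, admin_id = 1:4), "square")
  rq <- ring_population(sq)
  Fd_sq <- unclass(radiation_flow(sq, rq, c(kappa = 2), "RM1"))
  Fs_sq <- unclass(radiation_flow_symmetrised(sq, rq, c(kappa = 2), "RM1"))
  expect_equal(Fs_sq, 2 * Fd_sq, ignore_attr = TRUE)
})

test_that("admin aggregation sums cell-pair flows and respects the diagonal policy", {
  # one cell per unit: identity
  sys1 <- random_system(4, 4, seed = 51)
  F1 <- gravity_flow_directional(sys1, gm_pars)
  A1 <- aggregate_to_admin(F1, sys1)
  perm <- order(sys1$cells$admin_id)
  expect_equal(unclass(A1), unclass(F1)[perm, perm], ignore_attr = TRUE)

  # 2 units x 2 cells, unit flows = 1 everywhere, diagonal excluded -> 4
  sys2 <- spatial_system(data.frame(id = 1:4, x = c(0, 1, 2, 3) * 1e4, y = 0,
                                    population = 10,
                                    admin_id = c(1, 1, 2, 2)), "toy")
  ones <- mobfit:::.flow_matrix(matrix(1, 4, 4), "excluded", FALSE, 1:4)
  A2 <- aggregate_to_admin(ones, sys2)
  expect_equal(unclass(A2), matrix(c(0, 4, 4, 0), 2), ignore_attr = TRUE)

  # random GM cell flows on 30 cells / 4 units vs brute-force double loop
  sys3 <- random_system(30, 4, seed = 61)
  F3 <- gravity_flow_directional(sys3, gm_pars)
  A3 <- aggregate_to_admin(F3, sys3)
  O3 <- oracle_aggregate(unclass(F3), sys3$cells, sys3$units$id,
                         include_diag = TRUE)
  expect_equal(unclass(A3), O3, tolerance = 1e-12, ignore_attr = TRUE)

  # total flow conserved over included entries
  expect_equal(sum(A3), sum(F3))
  rings3 <- ring_population(sys3)
  R3 <- radiation_flow(sys3, rings3, c(kappa = 1), "RM1")
  AR3 <- aggregate_to_admin(R3, sys3)
  within <- outer(sys3$unit_index, sys3$unit_index, `==`)
  expect_equal(sum(AR3), sum(unclass(R3)[!within]))
})

test_that("gravity flows do not increase with distance at fixed populations", {
  d <- seq(0, 3e5, by = 1e4)
  sys <- spatial_system(data.frame(id = 1:2, x = c(0, 1), y = 0,
                                   population = c(100, 100), admin_id = 1:2),
                        "toy")
  f <- vapply(d, function(dd) {
    sys$D[1, 2] <- sys$D[2, 1] <- dd
    gravity_flow_directional(sys, gm_pars)[1, 2]
  }, numeric(1))
  expect_true(all(diff(f) <= 0))
})
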