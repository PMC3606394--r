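test_that("stoichiometry matrix encodes the reaction list", {
  N <- build_stoichiometry()
  expect_equal(dim(N), c(8, 16))
  expect_true(all(N %in% c(-1L, 0L, 1L)))
  # assembly consumes x2, x4, x6, x7 and produces x1
  expect_equal(unname(N[, "f1"]), c(1, -1, 0, -1, 0, -1, -1, 0))
  # proteolysis removes only the active complex
  expect_equal(unname(N[, "f14"]), c(-1, 0, 0, 0, 0, 0, 0, 0))
  # each recycling pathway consumes x1, returns Nox1/p22 plus the three
  # cytosolic subunits with exactly one inactive form
  expect_equal(unname(N[, "f2"]), c(-1, 1, 0, 1, 0, 1, 0, 1))  # NoxA1_P
  expect_equal(unname(N[, "f3"]), c(-1, 1, 1, 0, 0, 1, 1, 0))  # p47
  expect_equal(unname(N[, "f4"]), c(-1, 1, 0, 1, 1, 0, 1, 0))  # Rac1_GDP
  # every column conserves mass within its moiety bookkeeping:
  # recycling columns sum to +3 (1 complex -> 4 subunits), f1 to -3
  expect_equal(sum(N[, "f1"]), -3L)
  expect_true(all(colSums(N[, c("f2", "f3", "f4")]) == 3L))
})

test_that("influx/efflux bookkeeping carries the stoichiometric factor of 4", {
  # summing the x2..x8 balance rows of N F = 0 over any balanced flux
  # vector reproduces f11 + f12 + f13 + f15 = 4 f14 + f16
  for (i in 1:50) {
    F <- random_balanced_fluxes()
    expect_equal(F[["f11"]] + F[["f12"]] + F[["f13"]] + F[["f15"]],
                 4 * F[["f14"]] + F[["f16"]])
  }
})

test_that("N F vanishes exactly for balanced flux vectors", {
  N <- build_stoichiometry()
  set.seed(11)
  for (i in 1:200) {
    F <- random_balanced_fluxes()
    expect_equal(max(abs(N %*% F)), 0)
  }
})

test_that("mass-action fluxes match their monomials", {
  g <- setNames(runif(16), paste0("gamma", 1:16))
  zero <- rep(0, 8)
  f0 <- evaluate_fluxes(zero, control_signals(), g)
  expect_equal(unname(f0[c(1:10, 14, 16)]), rep(0, 12))
  expect_equal(unname(f0[c(11, 12, 13, 15)]),
               unname(g[c(11, 12, 13, 15)]))

  g2 <- rep(0, 16); g2[2] <- 0.1
  st <- c(100, rep(1, 7))
  expect_equal(evaluate_fluxes(st, gamma = g2)[["f2"]], 10)

  g1 <- rep(0, 16); g1[1] <- 1
  expect_equal(evaluate_fluxes(rep(1, 8), gamma = g1)[["f1"]], 1)

  expect_error(evaluate_fluxes(c(NA, rep(1, 7)), gamma = g))
  expect_error(evaluate_fluxes(rep(-1, 8), gamma = g))
})

test_that("time derivative agrees with the hand-coded balance expansion", {
  set.seed(21)
  for (i in 1:50) {
    x <- runif(8, 0, 100)
    s <- runif(3, 0.5, 10)
    g <- runif(16, 0, 2)
    expect_equal(unname(time_derivative(x, s, g)), oracle_rhs(x, s, g),
                 tolerance = 1e-12)
  }
  expect_equal(unname(time_derivative(runif(8), gamma = rep(0, 16))),
               rep(0, 8))
})

test_that("analytic Jacobian matches finite differences", {
  set.seed(31)
  x <- runif(8, 1, 50); s <- c(2, 3, 1); g <- runif(16, 0, 1)
  J <- rhs_jacobian(x, s, g)
  h <- 1e-6
  Jnum <- sapply(1:8, function(j) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    (time_derivative(xp, s, g) - time_derivative(xm, s, g)) / (2 * h)
  })
  expect_equal(unname(J), unname(Jnum), tolerance = 1e-5)
})

test_that("integration preserves a constructed steady state", {
  set.seed(41)
  param <- random_param()
  traj <- integrate_nox1(param$state, control_signals(), param$gamma,
                         times = seq(0, 100, by = 10))
  final <- as.numeric(traj[nrow(traj), paste0("x", 1:8)])
  expect_equal(final, unname(param$state), tolerance = 1e-6)
})

test_that("compiled and pure-R right-hand sides integrate identically", {
  set.seed(51)
  param <- random_param()
  sig <- signal_step(c("s1", "s2"), 10)
  times <- seq(0, 30, by = 5)
  tc <- integrate_nox1(param$state, sig, param$gamma, times,
                       compiled = TRUE)
  tr <- integrate_nox1(param$state, sig, param$gamma, times,
                       compiled = FALSE)
  expect_equal(as.matrix(tc[, paste0("x", 1:8)]),
               as.matrix(tr[, paste0("x", 1:8)]), tolerance = 1e-5)
})

test_that("solution is stable under tolerance tightening", {
  set.seed(61)
  param <- random_param()
  sig <- signal_step("s1", 10)
  t1 <- integrate_nox1(param$state, sig, param$gamma, c(0, 50),
                       rtol = 1e-6, atol = 1e-9)
  t2 <- integrate_nox1(param$state, sig, param$gamma, c(0, 50),
                       rtol = 5e-7, atol = 5e-10)
  f1 <- as.numeric(t1[2, paste0("x", 1:8)])
  f2 <- as.numeric(t2[2, paste0("x", 1:8)])
  expect_lt(max(abs(f1 - f2) / pmax(abs(f2), 1e-6)), 1e-4)
})

test_that("closed-system moiety totals are first integrals", {
  set.seed(71)
  for (i in 1:10) {
    param <- closed_param(code = sample.int(8, 1))
    sig <- signal_step(c("s1", "s2"), 10)
    traj <- integrate_nox1(param$state, sig, param$gamma,
                           times = seq(0, 200, length.out = 21))
    tot <- moiety_totals(traj)
    drift <- apply(tot, 2, function(v) max(abs(v - v[1])) / v[1])
    expect_lt(max(drift), 1e-6)
  }
})
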