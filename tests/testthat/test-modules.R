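test_that("the seven designs are the nonempty recycling subsets", {
  md <- module_designs()
  expect_length(md, 7)
  expect_equal(md[["1"]], "f2")                 # single pathway via f2
  lacking_f2 <- names(Filter(function(x) !"f2" %in% x, md))
  expect_setequal(lacking_f2, c("2", "3", "6"))
  both_f3_f4 <- names(Filter(function(x) all(c("f3", "f4") %in% x), md))
  expect_setequal(both_f3_f4, c("6", "7"))
  expect_equal(anyDuplicated(sapply(md, paste, collapse = "+")), 0)
})

test_that("scenario flux sampling honours the NoxA1 balance", {
  set.seed(501)
  closed <- scenario_config("closed", "slow")
  sc <- scenario_flux_sampler(closed, f2 = 100, f9 = 7)
  expect_equal(sc$f10, 107)
  expect_equal(sc$f16, 0)

  s1 <- scenario_config("open", "slow", 1)
  s2 <- scenario_config("open", "slow", 2)
  for (i in 1:40) {
    f2 <- runif(1, 0, 100); f9 <- runif(1, 0, 90)
    a <- scenario_flux_sampler(s1, f2, f9)
    expect_equal(a$f9 + f2, a$f10 + a$f16, tolerance = 1e-12)
    expect_gt(a$f9, a$f10)      # scenario 1 ordering
    expect_gte(a$f10, 0)
    b <- scenario_flux_sampler(s2, max(f2, 0.02), f9)
    expect_equal(b$f9 + max(f2, 0.02), b$f10 + b$f16, tolerance = 1e-12)
    expect_lte(b$f9, b$f10)     # scenario 2 ordering
  }
  # designs without the f2 pathway cannot satisfy scenario 2 with f16 > 0
  # at an exact steady state; the boundary fallback is flagged
  sb <- scenario_flux_sampler(s2, f2 = 0, f9 = 5)
  expect_true(sb$structural_infeasible)
  expect_equal(sb$f16, 1e-6)
})

test_that("module parameterizations obey the fair-comparison contract", {
  set.seed(511)
  p7 <- parameterize_module(7, scenario_config("closed", "slow"),
                            apportion = "equal")
  expect_equal(unname(p7$flux[c("f2", "f3", "f4")]), rep(100 / 3, 3))
  expect_equal(p7$flux[["f1"]], 100)
  expect_equal(p7$flux[["f14"]], 0)
  expect_lte(verify_steady(p7), 1e-9)

  p1 <- parameterize_module(1, scenario_config("closed", "slow"))
  expect_equal(p1$flux[["f2"]], 100)
  # absent pathways carry exactly zero flux and rate constant
  expect_identical(unname(p1$gamma[c("gamma3", "gamma4")]), c(0, 0))
  # closed design 1: f10 = f9 + 100, a large net NoxA1_P -> NoxA1 flow
  expect_equal(p1$flux[["f10"]], p1$flux[["f9"]] + 100)

  for (d in c(2, 6)) {
    set.seed(520 + d)
    p <- parameterize_module(d, scenario_config("open", "fast", 1))
    expect_equal(p$flux[["f2"]], 0)
    expect_lte(verify_steady(p), 1e-9)
    expect_gt(p$flux[["f9"]], p$flux[["f10"]])
  }
})

test_that("identical seeds give identical draws across designs", {
  set.seed(531)
  p1 <- parameterize_module(1, scenario_config("closed", "slow"))
  set.seed(531)
  p7 <- parameterize_module(7, scenario_config("closed", "slow"))
  expect_equal(p1$state, p7$state)
  # reversible-reaction rate constants are drawn before the apportionment
  expect_equal(p1$gamma[c("gamma6", "gamma8")],
               p7$gamma[c("gamma6", "gamma8")])
})

test_that("module comparison emits a reproducible tidy table", {
  cfg <- scenario_config("closed", "fast")
  r1 <- compare_modules(cfg, n = 3, seed = 541, designs = c(1, 7))
  r2 <- compare_modules(cfg, n = 3, seed = 541, designs = c(1, 7))
  expect_identical(r1$samples, r2$samples)
  expect_equal(nrow(r1$samples), 6)
  expect_true(all(r1$samples$ok))
  expect_true(all(r1$samples$fold > 1))
  expect_equal(sort(unique(r1$summary$design)), c(1, 7))
})

test_that("experiment orchestration covers the grid and reproduces", {
  cells <- list(closed_fast = scenario_config("closed", "fast"),
                open_fast_s2 = scenario_config("open", "fast", 2))
  g1 <- run_module_grid(n = 2, seed = 551, cells = cells,
                        designs = c(2, 5), measure_times = FALSE)
  expect_setequal(unique(g1$samples$cell), names(cells))
  expect_equal(nrow(g1$samples), 2 * 2 * 2)
  g2 <- run_module_grid(n = 2, seed = 551, cells = cells,
                        designs = c(2, 5), measure_times = FALSE)
  expect_identical(g1, g2)

  rp <- run_responsiveness(n = 2, seed = 561, regimes = "f14_zero",
                           codes = c(1, 8))
  expect_equal(nrow(rp$summary), 2 * 4)
  out <- tempfile()
  se <- run_screening_experiment(n = 10, seed = 571, out_dir = out)
  expect_true(file.exists(file.path(out, "screening_samples.csv")))
  expect_true(file.exists(file.path(out, "screening_summary.json")))
  expect_equal(unname(se$retained_counts["all"]),
               sum(se$samples$pass_all))
  unlink(out, recursive = TRUE)
})
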