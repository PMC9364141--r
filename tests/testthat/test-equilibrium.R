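test_that("the calibrated model replicates the benchmark with zero shocks", {
  inst <- fx_instance()
  r <- assemble_residuals(inst, foodcge:::benchmark_z(inst))
  expect_lt(max(abs(r)), 1e-10)
  # residual vector is square with the unknown count
  expect_length(r, 2 * length(inst$sectors) + length(inst$factors) + 2)

  st <- solve_levels(inst)
  expect_lt(max(abs(st$pct_change)), 1e-8)
  expect_identical(st$iterations, 0L)
})

test_that("perturbing one price moves only the affected zero-profit rows", {
  inst <- fx_instance()
  z <- foodcge:::benchmark_z(inst)
  z["p_grain"] <- log(1.01)
  r <- assemble_residuals(inst, z)
  zp <- r[grep("^zp_", names(r))]
  # sectors that do not use grain (and are not grain) stay at zero profit
  users <- names(which(inst$sam$flows["c_grain",
                                      paste0("a_", inst$sectors)] > 0))
  unaffected <- setdiff(paste0("zp_", inst$sectors),
                        c(paste0("zp_", sub("^a_", "", users)), "zp_grain"))
  expect_lt(max(abs(zp[unaffected])), 1e-12)
  expect_gt(abs(r["zp_grain"]), 1e-3)
})

test_that("equilibrium is homogeneous of degree zero in the numeraire", {
  s <- fx_sam()
  sh <- build_beef_replacement_shock(fx_instance(), 0.10, "plant_based")
  st1 <- solve_levels(fx_instance(), sh)
  cfg <- default_config()
  cfg$closure$numeraire_target <- 2
  inst2 <- build_model(s, cfg)
  st2 <- solve_levels(inst2, sh)
  # nominal variables double, quantities unchanged
  expect_equal(st2$levels$p / st1$levels$p,
               setNames(rep(2, 15), names(st1$levels$p)), tolerance = 1e-7)
  expect_equal(st2$levels$Y / st1$levels$Y, 2, tolerance = 1e-7)
  expect_equal(st2$levels$x, st1$levels$x, tolerance = 1e-7)
})

test_that("Walras' law holds on solved states and is reported (not thrown) otherwise", {
  inst <- fx_instance()
  st <- solve_levels(inst)
  expect_lt(abs(check_walras(inst, st)), 1e-9)
  res <- fx_result("ALTP30")
  expect_lt(abs(res$walras), 1e-9)
  # a deliberately unsolved state just reports its imbalance
  z <- foodcge:::benchmark_z(inst)
  z["p_beef_proc"] <- log(1.2)
  expect_silent(w <- check_walras(inst, z))
  expect_true(is.finite(w))
})

test_that("income-side and expenditure-side GDP agree on solved states", {
  for (nm in c("BEEF10", "ALTP60")) {
    agg <- fx_result(nm)$economy
    inc <- agg$pct_change[agg$variable == "gdp_income_side"]
    ex <- agg$pct_change[agg$variable == "gdp_expenditure_side"]
    expect_equal(inc, ex, tolerance = 1e-6)
  }
  # benchmark: all aggregates zero
  agg0 <- gdp_and_aggregates(solve_levels(fx_instance()), fx_instance())
  expect_equal(agg0$economy$pct_change, rep(0, 5), tolerance = 1e-8)
})

test_that("full-employment closure pins aggregate employment; sticky wage frees it", {
  agg <- fx_result("ALTP30")$economy
  expect_equal(agg$pct_change[agg$variable == "employment"], 0,
               tolerance = 1e-8)
  cfg <- default_config()
  cfg$closure$type <- "sticky_wage"
  inst_sw <- build_model(fx_sam(), cfg)
  sh <- build_beef_replacement_shock(inst_sw, 0.30, "plant_based")
  st <- solve_levels(inst_sw, sh)
  agg_sw <- gdp_and_aggregates(st, inst_sw)$economy
  expect_equal(agg_sw$pct_change[agg_sw$variable == "wage"], 0,
               tolerance = 1e-8)
  expect_gt(abs(agg_sw$pct_change[agg_sw$variable == "employment"]), 1e-6)
})

test_that("Johansen solution is linear in the shock and converges to levels", {
  inst <- fx_instance()
  sh0 <- build_beef_replacement_shock(inst, 0, "plant_based")
  expect_length(sh0$taste, 0)  # r = 0 is the identity
  j0 <- solve_johansen(inst, sh0, 1)
  expect_lt(max(abs(j0$pct_change)), 1e-8)

  sh <- build_beef_replacement_shock(inst, 0.10, "plant_based")
  j1 <- solve_johansen(inst, sh, 1)
  # halving the shock (on the log-multiplier scale) halves the linear answer
  sh_half <- sh
  sh_half$taste <- lapply(sh$taste, function(m) exp(0.5 * log(m)))
  j_half <- solve_johansen(inst, sh_half, 1)
  expect_equal(j_half$pct_change, j1$pct_change / 2, tolerance = 1e-4)

  # multi-step Euler approaches the levels solution
  lev <- solve_levels(inst, sh)
  err <- function(j) max(abs(j$pct_change - lev$pct_change))
  j8 <- solve_johansen(inst, sh, 8)
  expect_lt(err(j8), err(j1))
  j16 <- solve_johansen(inst, sh, 16)
  expect_lt(err(j16), err(j8))
  # Richardson extrapolation beats the plain Euler answer it builds on
  jr <- solve_johansen(inst, sh, 8, richardson = TRUE)
  expect_lt(err(jr), err(j8))
})

test_that("a small shock is matched by the one-step linearization to first order", {
  inst <- fx_instance()
  sh <- build_beef_replacement_shock(inst, 0.001, "plant_based")
  lev <- solve_levels(inst, sh)
  j1 <- solve_johansen(inst, sh, 1)
  # o(shock): with a 0.1% replacement the responses are a few percent at
  # most and the linearization error is second order in them
  expect_lt(max(abs(j1$pct_change - lev$pct_change)), 0.1)
  expect_lt(max(abs(j1$pct_change - lev$pct_change)),
            0.05 * max(abs(lev$pct_change)))
})
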