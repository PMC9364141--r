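test_that("packaged baseline reproduces the printed column totals", {
  tb <- load_baseline_footprint()
  expect_equal(sum(tb$water_km3, na.rm = TRUE), 94)
  expect_equal(sum(tb$n_kt, na.rm = TRUE), 10067)
  expect_equal(sum(tb$p_kt, na.rm = TRUE), 1636)
  expect_equal(sum(tb$ghg_mt, na.rm = TRUE), 347)
  # blank vs zero is meaningful: animal rows carry NA water/N/P (attributed
  # to feed crops), soya-oil processing an explicit 0
  animals <- tb[tb$group == "animal_products", ]
  expect_true(all(is.na(animals$water_km3)))
  expect_true(all(is.na(animals$n_kt)))
  expect_true(all(is.na(animals$p_kt)))
  expect_identical(tb$water_km3[tb$commodity == "soya_oil_processing"], 0)
})

test_that("output changes scale the baseline linearly and additively", {
  tb <- load_baseline_footprint()
  # zero changes: baseline echoed, zero change
  r0 <- apply_output_changes(tb, c(live_cattle = 0))
  expect_equal(r0$totals$change[r0$totals$available], rep(0, 4))
  expect_equal(r0$totals$baseline[r0$totals$dimension == "ghg_mt"], 347)
  # full shutdown of cattle removes exactly the cattle GHG baseline
  r100 <- apply_output_changes(tb, c(live_cattle = -100))
  expect_equal(r100$totals$change[r100$totals$dimension == "ghg_mt"], -142)
  # a 7% cattle contraction removes ~10 Mt CO2eq (nearest Mt)
  r7 <- apply_output_changes(tb, c(live_cattle = -7))
  ghg <- r7$totals$change[r7$totals$dimension == "ghg_mt"]
  expect_equal(round(abs(ghg)), 10)
  # linearity and additivity over commodity partitions
  ra <- apply_output_changes(tb, c(live_cattle = -4))
  rb <- apply_output_changes(tb, c(grain_farms = 3))
  rab <- apply_output_changes(tb, c(live_cattle = -4, grain_farms = 3))
  expect_equal(rab$totals$change[rab$totals$available],
               ra$totals$change[ra$totals$available] +
                 rb$totals$change[rb$totals$available], tolerance = 1e-12)
  expect_equal(apply_output_changes(tb, c(live_cattle = -8))$totals$change,
               2 * ra$totals$change, tolerance = 1e-12)
  # cropland ships without a baseline and reports as unavailable, not zero
  expect_false(r7$totals$available[r7$totals$dimension == "cropland_kha"])
  expect_true(is.na(r7$totals$change[r7$totals$dimension == "cropland_kha"]))
})

test_that("sector mapping is explicit; silent drops are errors", {
  tb <- load_baseline_footprint()
  mp <- default_footprint_mapping()
  pct <- c(cattle_ranch = -7, beef_proc = -7, rest = 0.1)
  r <- apply_output_changes(tb, pct, mapping = mp)
  ghg <- r$totals$change[r$totals$dimension == "ghg_mt"]
  expect_equal(ghg, -0.07 * 142, tolerance = 1e-12)  # only the farm row maps
  # an unmapped sector with nonzero change is an error
  expect_error(apply_output_changes(tb, c(algae_farm = -1), mapping = mp),
               "algae_farm")
  expect_error(apply_output_changes(tb, c(algae_farm = -1)), "algae_farm")
  # ... but a zero change on an unmapped name passes through
  expect_silent(apply_output_changes(tb, c(algae_farm = 0), mapping = mp))
})

test_that("animal head counts scale linearly from their baselines", {
  ab <- animal_baseline()
  # +1% chickens on the 8.5 billion baseline is +85 million birds
  r <- animal_numbers(ab, c(chickens = 1))
  expect_equal(r$change[r$species == "chickens"], 85e6)
  # the printed upper pig bound as arithmetic: +1.87% of 75 million
  r2 <- animal_numbers(ab, c(pigs = 1.87))
  expect_equal(r2$change[r2$species == "pigs"] / 1e6, 1.4025)
  expect_equal(round(r2$change[r2$species == "pigs"] / 1e6, 1), 1.4)
  # zero changes give zero head-count changes
  r0 <- animal_numbers(ab, c(chickens = 0, pigs = 0, cattle = 0))
  expect_equal(r0$change, rep(0, 3))
  expect_error(animal_baseline(cattle = -1))
})

test_that("shares sum to 100 per dimension and flag undefined dimensions", {
  tb <- load_baseline_footprint()
  sh <- share_report(tb)
  for (d in c("water_km3", "n_kt", "p_kt", "ghg_mt")) {
    expect_equal(sum(sh[[paste0("share_", d)]], na.rm = TRUE), 100,
                 tolerance = 1e-10)
  }
  # live cattle account for >= 40% of agricultural GHG emissions
  cattle_share <- sh$share_ghg_mt[sh$commodity == "live_cattle"]
  expect_equal(cattle_share, 100 * 142 / 347, tolerance = 1e-12)
  expect_gte(cattle_share, 40)
  # cropland has no baseline: shares undefined, reported as NA
  expect_true(all(is.na(sh$share_cropland_kha)))
  # single-row table: share 100
  one <- tb[tb$commodity == "grain_farms", ]
  class(one) <- class(tb)
  expect_equal(share_report(one)$share_ghg_mt, 100)
})
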