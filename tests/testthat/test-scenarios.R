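test_that("scenario presets encode the four standard replacements", {
  expect_equal(scenario("BEEF10")[c("rate", "target")],
               list(rate = 0.10, target = "other_foods"))
  expect_equal(scenario("ALTP60")[c("rate", "target")],
               list(rate = 0.60, target = "plant_based"))
  expect_error(scenario("ALTP90"), "unknown scenario")
  expect_error(scenario("custom", rate = 1.0, target = "plant_based"))
})

test_that("the preference shift hits beef exactly and conserves food expenditure", {
  inst <- fx_instance()
  tree <- inst$trees$utility
  exp0 <- foodcge:::tree_benchmark_leaf_expenditure(tree)
  unit <- setNames(rep(1, length(exp0)), names(exp0))
  food_leaves <- foodcge:::subtree_leaves(tree, "u_food")

  # identity at r = 0
  sh0 <- build_beef_replacement_shock(inst, 0, "plant_based")
  expect_length(sh0$taste, 0)

  for (r in c(0.05, 0.10, 0.30, 0.60, 0.95)) {
    for (tg in c("plant_based", "other_foods")) {
      sh <- build_beef_replacement_shock(inst, r, tg)
      d <- tree_leaf_demand(tree, unit, sum(exp0), taste = sh$taste)
      e_new <- d$leaf_quantities[names(exp0)]  # unit prices: expenditure
      # beef expenditure scaled by exactly (1 - r)
      expect_equal(e_new[["c_beef_proc"]],
                   (1 - r) * exp0[["c_beef_proc"]], tolerance = 1e-10)
      # total food expenditure conserved; non-food untouched
      expect_equal(sum(e_new[food_leaves]), sum(exp0[food_leaves]),
                   tolerance = 1e-10)
      nonfood <- setdiff(names(exp0), food_leaves)
      expect_equal(e_new[nonfood], exp0[nonfood], tolerance = 1e-10)
      if (tg == "plant_based") {
        # all freed expenditure lands on the plant-based alternative
        expect_equal(e_new[["c_plant_based"]],
                     exp0[["c_plant_based"]] + r * exp0[["c_beef_proc"]],
                     tolerance = 1e-10)
      } else {
        # proportional reallocation across the rest of the food bundle
        others <- setdiff(food_leaves, "c_beef_proc")
        expect_equal(unname(e_new[others] / exp0[others]),
                     rep(1 + r * exp0[["c_beef_proc"]] / sum(exp0[others]),
                         length(others)),
                     tolerance = 1e-10)
      }
    }
  }
  expect_error(build_beef_replacement_shock(inst, 1.0, "plant_based"),
               "\\[0, 1\\)")
})

test_that("an ALTP shock requires a plant-based sector in the tree", {
  cfg <- default_config()
  cfg$nests$groups$plant_based <- NULL
  cfg$nests$groups$other_foods <- c(cfg$nests$groups$other_foods,
                                    "plant_based")
  inst <- build_model(fx_sam(), cfg)
  expect_error(build_beef_replacement_shock(inst, 0.1, "plant_based"),
               "no plant-based")
  # BEEF-style reallocation still works
  sh <- build_beef_replacement_shock(inst, 0.1, "other_foods")
  expect_gt(length(sh$taste), 0)
})

test_that("BEEF10 contracts beef and expands the other animal sectors", {
  res <- fx_result("BEEF10")
  out <- setNames(res$sectors$output_pct, res$sectors$sector)
  expect_lt(out[["beef_proc"]], 0)
  expect_lt(out[["cattle_ranch"]], 0)
  expect_gt(out[["oth_anim_farm"]], 0)
  expect_gt(out[["oth_anim_proc"]], 0)
})

test_that("beef contraction deepens with the replacement rate", {
  beef <- vapply(c("ALTP10", "ALTP30", "ALTP60"), function(nm) {
    r <- fx_result(nm)
    r$sectors$output_pct[r$sectors$sector == "beef_proc"]
  }, 0)
  expect_true(all(diff(beef) < 0))
  expect_true(all(beef < 0))
})

test_that("exports buffer the beef sector: output falls less than domestic demand", {
  res <- fx_result("ALTP30")
  inst <- fx_instance()
  out_drop <- -res$sectors$output_pct[res$sectors$sector == "beef_proc"]
  # domestic household beef demand change
  h <- res$state$levels$h[["beef_proc"]]
  h0 <- inst$C0[["beef_proc"]]
  dem_drop <- -100 * (h / h0 - 1)
  expect_gt(dem_drop, 0)
  expect_lt(out_drop, dem_drop)
  # and exports rise as the domestic price falls
  expect_gt(res$state$levels$E[["beef_proc"]], inst$E0[["beef_proc"]])
})

test_that("a zero-rate custom scenario returns an all-zero report", {
  inst <- fx_instance()
  res <- run_scenario(inst, scenario("custom", 0, "plant_based"))
  expect_lt(max(abs(res$sectors$output_pct)), 1e-8)
  expect_lt(max(abs(res$economy$pct_change)), 1e-8)
  expect_equal(res$animals$change, rep(0, 3), tolerance = 1e-6)
})

test_that("trade sensitivity: more elastic export demand cushions beef output", {
  inst <- fx_instance()
  grid <- c(0.25, 1, 4)
  tab <- trade_sensitivity(inst, scenario("ALTP30"), grid)
  expect_identical(nrow(tab), length(grid))
  expect_identical(tab$eta, grid)
  # beef output falls less (is larger) as eta grows
  expect_true(all(diff(tab$beef_output_pct) > 0))
  # eta -> 0 limit: exports barely move; output fall approaches the
  # domestic demand fall (10% replacement scaled by the domestic share)
  expect_lt(abs(tab$beef_export_pct[1]), 1)
  expect_true("beef_export_share" %in% names(tab))
})

test_that("scenario comparison aligns results and preserves names", {
  r1 <- fx_result("BEEF10"); r2 <- fx_result("ALTP10")
  cmp <- compare_scenarios(list(r1, r2))
  expect_setequal(unique(cmp$economy$scenario), c("BEEF10", "ALTP10"))
  expect_setequal(unique(cmp$animals$scenario), c("BEEF10", "ALTP10"))
  # replacing beef with other foods grows chicken+pig numbers more than
  # replacing it with plant-based alternatives
  chick_pig <- function(nm) {
    a <- cmp$animals[cmp$animals$scenario == nm, ]
    sum(a$change[a$species %in% c("chickens", "pigs")])
  }
  expect_gt(chick_pig("BEEF10"), chick_pig("ALTP10"))
  # a duplicated result compares to itself with zero differences
  cmp2 <- compare_scenarios(list(r1, r1))
  w <- cmp2$sectors
  expect_equal(w$output_pct[w$scenario == "BEEF10"],
               w$output_pct[w$scenario == "BEEF10"])
  # results from different instances are rejected
  cfg <- default_config(); cfg$closure$numeraire_target <- 2
  inst2 <- build_model(fx_sam(), cfg)
  r3 <- run_scenario(inst2, "ALTP10")
  expect_equal(r3$sectors$output_pct,
               fx_result("ALTP10")$sectors$output_pct, tolerance = 1e-6)
  tpl <- economy_template(seed = 99L)
  inst3 <- build_model(generate_sam(tpl))
  r4 <- run_scenario(inst3, "ALTP10")
  expect_error(compare_scenarios(list(r1, r4)), "different model instances")
})
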