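#' Beef-replacement scenarios
#'
#' The four standard scenarios replace a share `rate` of household beef
#' expenditure, valued at benchmark prices: `BEEF10` reallocates 10% of beef
#' expenditure across the other foods already in the household's consumption
#' bundle (proportionally to benchmark expenditures); `ALTP10`, `ALTP30`,
#' `ALTP60` redirect 10/30/60% of beef expenditure to the plant-based
#' alternative. Custom scenarios take any `rate` in `[0, 1)` and either
#' target.
#'
#' @param name one of `"BEEF10"`, `"ALTP10"`, `"ALTP30"`, `"ALTP60"`, or
#'   `"custom"`.
#' @param rate replacement rate in `[0, 1)`; implied by `name` for the four
#'   standard scenarios.
#' @param target `"other_foods"` or `"plant_based"`; implied by `name` for
#'   the standard scenarios.
#' @return an object of class `scenario`.
#' @export
scenario <- function(name, rate = NULL, target = NULL) {
  presets <- list(BEEF10 = list(rate = 0.10, target = "other_foods"),
                  ALTP10 = list(rate = 0.10, target = "plant_based"),
                  ALTP30 = list(rate = 0.30, target = "plant_based"),
                  ALTP60 = list(rate = 0.60, target = "plant_based"))
  if (name %in% names(presets)) {
    preset <- presets[[name]]
    if (!is.null(rate) && rate != preset$rate)
      stop(name, " implies rate ", preset$rate)
    if (!is.null(target) && target != preset$target)
      stop(name, " implies target ", preset$target)
    rate <- preset$rate; target <- preset$target
  } else if (identical(name, "custom")) {
    if (is.null(rate) || is.null(target))
      stop("custom scenarios need `rate` and `target`")
  } else {
    stop("unknown scenario '", name, "'; available: ",
         paste(c(names(presets), "custom"), collapse = ", "))
  }
  stopifnot(rate >= 0, rate < 1,
            target %in% c("other_foods", "plant_based"))
  structure(list(name = name, rate = rate, target = target),
            class = "scenario")
}

#' Construct the preference shift for a beef-replacement scenario
#'
#' Encodes the replacement as taste multipliers on the household utility
#' tree: at benchmark prices and income, beef expenditure falls by exactly
#' the factor `1 - r`, the freed expenditure is reallocated within the food
#' nest (to the plant-based alternative, or proportionally across the rest
#' of the existing food bundle), and total food and non-food expenditures
#' are both unchanged — the shift is symmetric between food and non-food by
#' construction, so it is a pure preference twist inside the food nest.
#'
#' Multipliers are derived from the target expenditure shares: for each node
#' in the food subtree the new child share is the target expenditure share
#' and the multiplier is its ratio to the benchmark share (renormalization
#' inside [ces_node] keeps shares on the simplex). In the calibrated share
#' form, expenditure shares at unit prices equal the share parameters for
#' every elasticity, so the reallocation is exact, not approximate.
#'
#' @param instance a [build_model()] instance.
#' @param r replacement rate in `[0, 1)`.
#' @param target `"other_foods"` or `"plant_based"`.
#' @return an object of class `shock_set`: list with `taste` (node ->
#'   named child multipliers), `r`, `target`.
#' @export
build_beef_replacement_shock <- function(instance, r,
                                         target = c("plant_based",
                                                    "other_foods")) {
  stopifnot(inherits(instance, "model_instance"))
  target <- match.arg(target)
  if (r < 0 || r >= 1) stop("replacement rate must be in [0, 1); got ", r)
  tree <- instance$trees$utility
  groups <- instance$config$nests$groups
  beef_leaves <- account_id("c", groups$beef)
  pb_leaves <- account_id("c", groups$plant_based)
  exp0 <- tree_benchmark_leaf_expenditure(tree)
  food_leaves <- subtree_leaves(tree, "u_food")
  if (!all(beef_leaves %in% food_leaves))
    stop("beef leaves not found in the food nest")
  if (target == "plant_based" &&
      (!length(pb_leaves) || !all(pb_leaves %in% food_leaves)))
    stop("no plant-based sector in the utility tree; cannot build an ALTP ",
         "shock (configure nests$groups$plant_based)")

  target_exp <- exp0
  freed <- r * sum(exp0[beef_leaves])
  target_exp[beef_leaves] <- (1 - r) * exp0[beef_leaves]
  if (target == "plant_based") {
    target_exp[pb_leaves] <- exp0[pb_leaves] +
      freed * exp0[pb_leaves] / sum(exp0[pb_leaves])
  } else {
    others <- setdiff(food_leaves, beef_leaves)
    target_exp[others] <- exp0[others] +
      freed * exp0[others] / sum(exp0[others])
  }

  # per-node multipliers inside the food subtree (everything above u_food,
  # and the non-food side, stays at 1: food total is conserved exactly)
  subtree_total <- function(id) {
    if (id %in% names(tree$nodes)) sum(target_exp[subtree_leaves(tree, id)])
    else target_exp[[id]]
  }
  taste <- list()
  for (nid in food_nodes(tree)) {
    node <- tree$nodes[[nid]]
    tgt <- vapply(node$children, subtree_total, 0)
    new_share <- tgt / sum(tgt)
    m <- new_share / node$delta
    if (max(abs(m - 1)) > 1e-12) taste[[nid]] <- m
  }
  structure(list(taste = taste, r = r, target = target),
            class = "shock_set")
}

# leaves under a given node id (the id itself if already a leaf)
subtree_leaves <- function(tree, id) {
  if (!id %in% names(tree$nodes)) return(id)
  unlist(lapply(tree$nodes[[id]]$children,
                function(ch) subtree_leaves(tree, ch)), use.names = FALSE)
}

# node ids of the food subtree (u_food and below)
food_nodes <- function(tree) {
  out <- character(0)
  walk <- function(id) {
    if (!id %in% names(tree$nodes)) return(invisible())
    out <<- c(out, id)
    for (ch in tree$nodes[[id]]$children) walk(ch)
  }
  walk("u_food")
  out
}

#' Run one scenario end-to-end
#'
#' Builds the preference shock, solves the model in levels, and attaches the
#' standard reports: macro aggregates and sector output/employment changes,
#' the environmental satellite account, and animal head-count changes.
#' Percent changes are relative to the benchmark; a zero-rate scenario
#' returns zeros throughout. Results are pure functions of (SAM, config,
#' scenario) — reruns are identical.
#'
#' @param instance a [build_model()] instance.
#' @param scen a [scenario()] (or a name accepted by it).
#' @param footprint baseline [footprint_table]; default the packaged
#'   baseline.
#' @param mapping sector-to-footprint-row mapping, see
#'   [default_footprint_mapping()].
#' @param animals an [animal_baseline()].
#' @return an object of class `scenario_result`.
#' @export
run_scenario <- function(instance, scen,
                         footprint = load_baseline_footprint(),
                         mapping = default_footprint_mapping(),
                         animals = animal_baseline()) {
  if (is.character(scen)) scen <- scenario(scen)
  stopifnot(inherits(scen, "scenario"))
  shock <- build_beef_replacement_shock(instance, scen$rate, scen$target)
  state <- tryCatch(
    solve_levels(instance, shocks = shock),
    error = function(e) stop("scenario ", scen$name, ": ",
                             conditionMessage(e)))
  report <- gdp_and_aggregates(state, instance)
  pct <- stats::setNames(report$sectors$output_pct, report$sectors$sector)
  fp <- apply_output_changes(footprint, pct, mapping = mapping)
  herd <- animal_numbers(animals, c(
    chickens = unname(pct["oth_anim_farm"]),
    pigs = unname(pct["oth_anim_farm"]),
    cattle = unname(pct["cattle_ranch"])))
  structure(list(scenario = scen, shock = shock, state = state,
                 economy = report$economy, sectors = report$sectors,
                 footprint = fp, animals = herd,
                 walras = state$walras,
                 benchmark_output = instance$x0),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> ", x$scenario$name, " (r = ", x$scenario$rate,
      ", target ", x$scenario$target, ")\n", sep = "")
  beef <- x$sectors[x$sectors$sector == "beef_proc", ]
  cat("  beef output ", round(beef$output_pct, 2), "%; GDP ",
      round(x$economy$pct_change[1], 3), "%; Walras ",
      format(x$walras, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Trade sensitivity sweep
#'
#' Re-solves one scenario under a grid of export-demand elasticities for the
#' agriculture/food commodities. More elastic foreign demand lets exports
#' absorb more of a domestic demand shock, so the beef sector's output falls
#' less; as the elasticity approaches zero exports are effectively fixed and
#' the output decline approaches the domestic demand decline.
#'
#' @param instance a [build_model()] instance.
#' @param scen a [scenario()].
#' @param eta_grid positive export-demand elasticities to sweep.
#' @return data.frame with one row per elasticity: beef output and export
#'   percent changes, beef export share of output, and other-animal output
#'   change.
#' @export
trade_sensitivity <- function(instance, scen, eta_grid = c(0.5, 1, 2, 4, 8)) {
  if (is.character(scen)) scen <- scenario(scen)
  stopifnot(all(eta_grid > 0))
  rows <- lapply(eta_grid, function(eta) {
    cfg <- instance$config
    cfg$trade$eta_food <- eta
    inst <- build_model(instance$sam, cfg)
    shock <- build_beef_replacement_shock(inst, scen$rate, scen$target)
    st <- solve_levels(inst, shocks = shock)
    beef_x <- st$levels$x[["beef_proc"]]
    beef_e <- st$levels$E[["beef_proc"]]
    data.frame(
      eta = eta,
      beef_output_pct = unname(st$pct_change["x_beef_proc"]),
      beef_export_pct = 100 * (beef_e / inst$E0[["beef_proc"]] - 1),
      beef_export_share = 100 * beef_e / beef_x,
      oth_anim_output_pct = unname(st$pct_change["x_oth_anim_farm"]))
  })
  do.call(rbind, rows)
}

#' Compare scenario results
#'
#' Aligns two or more results from the same model instance into long tables:
#' macro aggregates, sector changes, and animal head counts (so the contrast
#' between replacing beef with other foods versus with plant-based
#' alternatives — many more chickens and pigs under the former — can be read
#' off directly).
#'
#' @param results list of `scenario_result`s from [run_scenario()] on the
#'   same instance.
#' @return list of data.frames `economy`, `sectors`, `animals`, each with a
#'   `scenario` column.
#' @export
compare_scenarios <- function(results) {
  stopifnot(length(results) >= 2L,
            all(vapply(results, inherits, TRUE, "scenario_result")))
  ref <- results[[1L]]$benchmark_output
  for (r in results[-1L]) {
    if (!isTRUE(all.equal(r$benchmark_output, ref)))
      stop("scenario results come from different model instances")
  }
  tag <- function(df, nm) cbind(scenario = nm, df, stringsAsFactors = FALSE)
  nms <- vapply(results, function(r) r$scenario$name, "")
  list(
    economy = do.call(rbind, Map(function(r, nm) tag(r$economy, nm),
                                 results, nms)),
    sectors = do.call(rbind, Map(function(r, nm) tag(r$sectors, nm),
                                 results, nms)),
    animals = do.call(rbind, Map(function(r, nm) tag(r$animals, nm),
                                 results, nms))
  )
}
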