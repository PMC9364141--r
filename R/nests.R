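#' Default model configuration
#'
#' Elasticities, nest membership, trade response, closure and solver
#' settings, and the four standard beef-replacement scenarios. Everything is
#' overridable; the structure matches the `config.yaml` written by
#' [write_synthetic_economy()] and read by [cmd_run()].
#'
#' Default substitution elasticities: meat nest 2.0 (beef vs other animal
#' products substitute readily), food nest 0.8, food vs non-food 0.35 (food
#' demand is expenditure-inelastic), value added 0.5, Armington
#' (domestic vs imported variety) 2.0. Export demand elasticities default to
#' 4 for agriculture/food commodities and 2 elsewhere.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    nests = list(
      sigma = list(top = 0.35, food = 0.8, meat = 2.0, other_foods = 1.0,
                   nonfood = 1.0, value_added = 0.5, armington = 2.0),
      groups = list(
        beef = "beef_proc",
        meat_other = "oth_anim_proc",
        plant_based = "plant_based",
        other_foods = c("dairy", "grain", "fruit_nut", "vegetable",
                        "oth_crops", "soya_proc", "sugar_proc", "food_serv"),
        nonfood = "rest"
      )
    ),
    trade = list(
      eta_food = 4, eta_other = 2,
      food_sectors = c("cattle_ranch", "beef_proc", "oth_anim_farm",
                       "oth_anim_proc", "dairy", "grain", "oilseed",
                       "fruit_nut", "vegetable", "oth_crops", "soya_proc",
                       "sugar_proc", "plant_based", "food_serv")
    ),
    closure = list(type = "full_employment", numeraire = "cpi",
                   numeraire_target = 1),
    solver = list(tol = 1e-9, max_iter = 60),
    scenarios = list(
      list(name = "BEEF10", rate = 0.10, target = "other_foods"),
      list(name = "ALTP10", rate = 0.10, target = "plant_based"),
      list(name = "ALTP30", rate = 0.30, target = "plant_based"),
      list(name = "ALTP60", rate = 0.60, target = "plant_based")
    )
  )
}

#' Build and calibrate the default nest trees
#'
#' Production: each sector gets a fixed-proportions (Leontief) top nest over
#' its value-added composite and the intermediate commodity composites it
#' uses, with a CES value-added nest over the primary factors it employs.
#' Utility: a CES tree with food vs non-food at the top, then
#' \{meat composite, plant-based alternative, other foods\} inside the food
#' nest, and \{beef, other animal products\} inside the meat nest. All nodes
#' are calibrated to the benchmark SAM, so with unit prices and taste
#' multipliers of 1 the trees reproduce the benchmark flows exactly.
#'
#' @param sam a balanced benchmark [sam].
#' @param config a configuration list, see [default_config()]; sectors named
#'   in `config$nests$groups` must exist in the SAM.
#' @return list with elements `production` (named list of [nest_tree]s, one
#'   per activity) and `utility` (the household [nest_tree]).
#' @export
build_default_trees <- function(sam, config = default_config()) {
  stopifnot(inherits(sam, "sam"))
  fl <- sam$flows
  activities <- accounts_of_kind(sam, "activity")
  commodities <- accounts_of_kind(sam, "commodity")
  factors <- accounts_of_kind(sam, "factor")
  sectors <- sub("^a_", "", activities)

  groups <- config$nests$groups
  named <- unlist(groups, use.names = FALSE)
  missing_sec <- setdiff(named, sectors)
  if (length(missing_sec))
    stop("sector(s) named in config but absent from SAM: ",
         paste(missing_sec, collapse = ", "))
  sg <- config$nests$sigma

  # --- household utility tree ---------------------------------------------
  cons <- fl[commodities, "household"]
  names(cons) <- commodities
  leaf_exp <- function(secs) {
    e <- cons[account_id("c", secs)]
    bad <- secs[is.na(e) | e <= 0]
    if (length(bad))
      stop("household benchmark expenditure is zero for sector(s) in the ",
           "utility nest: ", paste(bad, collapse = ", "))
    e
  }
  nodes <- list()
  meat_exp <- leaf_exp(c(groups$beef, groups$meat_other))
  nodes$u_meat <- calibrate_ces_node(meat_exp, sg$meat, id = "u_meat")
  oth_exp <- leaf_exp(groups$other_foods)
  nodes$u_othfoods <- calibrate_ces_node(oth_exp, sg$other_foods,
                                         id = "u_othfoods")
  food_children <- c(u_meat = sum(meat_exp), u_othfoods = sum(oth_exp))
  if (length(groups$plant_based)) {
    pb_exp <- leaf_exp(groups$plant_based)
    food_children <- c(food_children[1L],
                       stats::setNames(pb_exp, account_id("c", groups$plant_based)),
                       food_children[2L])
  }
  nodes$u_food <- calibrate_ces_node(food_children, sg$food, id = "u_food")
  nf_exp <- leaf_exp(groups$nonfood)
  nodes$u_nonfood <- calibrate_ces_node(nf_exp, sg$nonfood, id = "u_nonfood")
  nodes$u_top <- calibrate_ces_node(
    c(u_food = sum(food_children), u_nonfood = sum(nf_exp)),
    sg$top, id = "u_top")
  utility <- nest_tree("u_top", nodes, kind = "utility")

  # every commodity the household buys must sit somewhere in the tree
  bought <- commodities[cons > 0]
  stray <- setdiff(bought, tree_leaves(utility))
  if (length(stray))
    stop("commodity(ies) with household expenditure but no utility leaf: ",
         paste(stray, collapse = ", "))

  # --- production trees ---------------------------------------------------
  production <- stats::setNames(vector("list", length(sectors)), sectors)
  for (s in sectors) {
    a <- account_id("a", s)
    fp <- fl[factors, a]
    fp <- fp[fp > 0]
    if (!length(fp))
      stop("sector ", s, " has no factor payments; cannot calibrate")
    va_id <- paste0("va_", s)
    vnode <- calibrate_ces_node(fp, sg$value_added, id = va_id)
    ints <- fl[commodities, a]
    ints <- ints[ints > 0]
    top_exp <- c(stats::setNames(sum(fp), va_id), ints)
    tnode <- calibrate_ces_node(top_exp, 0, id = paste0("prod_", s))
    production[[s]] <- nest_tree(
      paste0("prod_", s),
      stats::setNames(list(tnode, vnode), c(paste0("prod_", s), va_id)),
      kind = "production", sector = s)
  }
  list(production = production, utility = utility)
}
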