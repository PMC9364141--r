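#' Template for a synthetic food-system economy
#'
#' Describes a stylized small open economy with a disaggregated beef value
#' chain, from which [generate_sam()] constructs balanced benchmark SAMs.
#' The defaults emulate the structural facts of the US food system: beef
#' exports around 12% of beef-sector output; about 1 million workers in
#' cattle operations and 0.5 million in animal processing; agriculture under
#' 2% of total employment; the broader food system (farming, food
#' manufacturing, food services) around 11%; economy grand total on the
#' order of 2e7 million USD/yr.
#'
#' Generation is a deterministic share skeleton (which pins the structural
#' targets exactly) plus seeded multiplicative noise on the non-pinned
#' coefficients, followed by a feasibility repair and a final RAS polish —
#' feasibility is guaranteed by construction rather than by rejection
#' sampling.
#'
#' @param noise lognormal noise scale (sdlog) applied to non-pinned
#'   technology and demand coefficients; 0 disables noise.
#' @param seed integer seed; a given (template, seed) pair reproduces the
#'   SAM byte-identically.
#' @param total_employment economy-wide employment, millions of workers.
#' @param beef_export_share pinned beef-commodity export share of beef gross
#'   output (structural target, default 0.12).
#' @return an object of class `economy_template`; element `sectors` is a
#'   data.frame with one row per sector (id, label, group, food_system,
#'   hh_leaf, output0, export_share, import_share, inv_absorb,
#'   workers_millions), `io_coef` the intermediate input coefficient matrix
#'   (input commodity x buying sector, per unit of output value), and
#'   `fac_share` the factor split of value added.
#' @export
economy_template <- function(noise = 0.05, seed = 0L,
                             total_employment = 160,
                             beef_export_share = 0.12) {
  stopifnot(noise >= 0, noise <= 0.5,
            beef_export_share > 0, beef_export_share < 1)
  ids <- c("cattle_ranch", "beef_proc", "oth_anim_farm", "oth_anim_proc",
           "dairy", "grain", "oilseed", "fruit_nut", "vegetable",
           "oth_crops", "soya_proc", "sugar_proc", "plant_based",
           "food_serv", "rest")
  sectors <- data.frame(
    id = ids,
    label = c("Cattle ranching", "Beef processing", "Other animal farming",
              "Other animal processing", "Dairy farms", "Grain farms",
              "Oilseed farms", "Fruit and nut farms",
              "Vegetable or melon farms", "Other crops",
              "Soya oil processing", "Sugar processing",
              "Plant-based manufacturing", "Food services",
              "Rest of economy"),
    group = c("agriculture", "processing", "agriculture", "processing",
              "agriculture", "agriculture", "agriculture", "agriculture",
              "agriculture", "agriculture", "processing", "processing",
              "processing", "services", "other"),
    food_system = c(rep(TRUE, 14), FALSE),
    # household utility leaf grouping; "none" = not bought by households
    hh_leaf = c("none", "beef", "none", "meat_other", "other_foods",
                "other_foods", "none", "other_foods", "other_foods",
                "other_foods", "other_foods", "other_foods", "plant_based",
                "other_foods", "nonfood"),
    # gross output, million USD/yr
    output0 = c(70000, 110000, 60000, 100000, 45000, 65000, 50000, 35000,
                25000, 40000, 25000, 15000, 2000, 900000, 6400000),
    export_share = c(0.010, beef_export_share, 0.010, 0.150, 0.050, 0.250,
                     0.300, 0.300, 0.100, 0.200, 0.250, 0.020, 0.050,
                     0.020, 0.100),
    import_share = c(0.010, 0.040, 0.010, 0.050, 0.030, 0.030, 0.020,
                     0.250, 0.200, 0.100, 0.080, 0.150, 0.020, 0.010, NA),
    # share of a commodity's final demand absorbed by investment rather than
    # household consumption (1 for goods households do not buy directly)
    inv_absorb = c(1, 0, 1, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0.25),
    workers_millions = c(1.00, 0.30, 0.25, 0.20, 0.15, 0.35, 0.20, 0.35,
                         0.25, 0.25, 0.05, 0.04, 0.01, 14.00, NA),
    stringsAsFactors = FALSE
  )
  sectors$workers_millions[sectors$id == "rest"] <-
    total_employment - sum(sectors$workers_millions, na.rm = TRUE)

  io <- matrix(0, 15, 15, dimnames = list(ids, ids))
  # feed and input structure (input commodity row, buying sector column)
  io["grain",        "cattle_ranch"]  <- 0.16
  io["oilseed",      "cattle_ranch"]  <- 0.05
  io["oth_crops",    "cattle_ranch"]  <- 0.04
  io["rest",         "cattle_ranch"]  <- 0.22
  io["cattle_ranch", "beef_proc"]     <- 0.58
  io["rest",         "beef_proc"]     <- 0.14
  io["grain",        "oth_anim_farm"] <- 0.20
  io["oilseed",      "oth_anim_farm"] <- 0.09
  io["rest",         "oth_anim_farm"] <- 0.18
  io["oth_anim_farm","oth_anim_proc"] <- 0.54
  io["rest",         "oth_anim_proc"] <- 0.15
  io["grain",        "dairy"]         <- 0.13
  io["oilseed",      "dairy"]         <- 0.04
  io["rest",         "dairy"]         <- 0.24
  io["rest",         "grain"]         <- 0.36
  io["rest",         "oilseed"]       <- 0.34
  io["rest",         "fruit_nut"]     <- 0.30
  io["rest",         "vegetable"]     <- 0.30
  io["rest",         "oth_crops"]     <- 0.32
  io["oilseed",      "soya_proc"]     <- 0.52
  io["rest",         "soya_proc"]     <- 0.16
  io["oth_crops",    "sugar_proc"]    <- 0.42
  io["rest",         "sugar_proc"]    <- 0.20
  # plant-based manufacturing: ~50% plant ingredients (grains/legumes-
  # oilseeds/starches 40/40/20), rest labour+capital+other inputs
  io["grain",        "plant_based"]   <- 0.20
  io["oilseed",      "plant_based"]   <- 0.20
  io["oth_crops",    "plant_based"]   <- 0.10
  io["rest",         "plant_based"]   <- 0.15
  io["beef_proc",    "food_serv"]     <- 0.040
  io["oth_anim_proc","food_serv"]     <- 0.040
  io["dairy",        "food_serv"]     <- 0.018
  io["grain",        "food_serv"]     <- 0.008
  io["fruit_nut",    "food_serv"]     <- 0.008
  io["vegetable",    "food_serv"]     <- 0.010
  io["oth_crops",    "food_serv"]     <- 0.004
  io["soya_proc",    "food_serv"]     <- 0.006
  io["sugar_proc",   "food_serv"]     <- 0.004
  io["plant_based",  "food_serv"]     <- 0.0006
  io["rest",         "food_serv"]     <- 0.350
  io["grain",        "rest"]          <- 0.0008
  io["oilseed",      "rest"]          <- 0.0008
  io["oth_crops",    "rest"]          <- 0.0006
  io["rest",         "rest"]          <- 0.4300

  # factor split of value added (columns sum to 1); land only on farms
  farm <- sectors$group == "agriculture"
  fac <- matrix(0, 3, 15, dimnames = list(c("labour", "capital", "land"), ids))
  fac["labour", ]  <- ifelse(farm, 0.45, 0.58)
  fac["capital", ] <- ifelse(farm, 0.35, 0.42)
  fac["land", ]    <- ifelse(farm, 0.20, 0.00)

  structure(list(sectors = sectors, io_coef = io, fac_share = fac,
                 noise = noise, seed = as.integer(seed),
                 total_employment = total_employment,
                 beef_export_share = beef_export_share,
                 targets = list(beef_export_share = beef_export_share,
                                beef_export_tol = 0.001,
                                ag_labour_share_max = 0.02,
                                food_system_share = 0.11,
                                food_system_tol = 0.01)),
            class = "economy_template")
}

#' @export
print.economy_template <- function(x, ...) {
  cat("<economy_template> ", nrow(x$sectors), " sectors, noise ", x$noise,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

account_id <- function(kind, sector) paste0(kind, "_", sector)

#' Generate a balanced synthetic SAM
#'
#' Constructs the benchmark SAM of the template economy: activity columns pay
#' intermediates and factors; commodity accounts route domestic output,
#' imports, intermediate sales, household consumption, investment and
#' exports; factors pay the household; household saves into the savings
#' account, which funds investment; the export and import accounts settle
#' against each other (trade balanced at benchmark). The matrix is balanced
#' by construction and finished with a [ras_balance()] polish, so residuals
#' are at numerical zero and all structural zeros are preserved.
#'
#' The beef-commodity export share is pinned exactly at the template's
#' `beef_export_share` (noise never touches it); all other technology and
#' demand coefficients receive seeded multiplicative lognormal noise.
#'
#' @param template an [economy_template()].
#' @return a balanced [sam] whose accounts are `a_<sector>` (activities),
#'   `c_<sector>` (commodities), `labour`/`capital`/`land` (factors),
#'   `household`, `export`, `import`, `savings`.
#' @export
generate_sam <- function(template = economy_template()) {
  stopifnot(inherits(template, "economy_template"))
  sec <- template$sectors
  ids <- sec$id
  n <- length(ids)
  io <- template$io_coef
  fac <- template$fac_share
  e_sh <- stats::setNames(sec$export_share, ids)
  m_sh <- stats::setNames(sec$import_share, ids)
  x0 <- stats::setNames(sec$output0, ids)

  if (template$noise > 0) {
    # seeded noise, isolated from the caller's RNG state
    with_seed(template$seed, {
      jitter <- function(v) {
        nz <- which(v != 0 & !is.na(v))
        v[nz] <- v[nz] * exp(stats::rnorm(length(nz)) * template$noise)
        v
      }
      for (j in seq_len(ncol(io))) io[, j] <- jitter(io[, j])
      x0 <- jitter(x0)
      keep_beef <- e_sh[["beef_proc"]]
      e_sh <- jitter(e_sh); m_sh <- jitter(m_sh)
      e_sh[["beef_proc"]] <- keep_beef    # structural target, never noised
      lab <- jitter(fac["labour", ]); cap <- jitter(fac["capital", ])
      lnd <- fac["land", ]
      tot <- lab + cap + lnd
      fac["labour", ] <- lab / tot; fac["capital", ] <- cap / tot
      fac["land", ] <- lnd / tot
    })
  }

  # keep value added positive: cap intermediate cost share at 0.92
  csum <- colSums(io)
  over <- csum > 0.92
  if (any(over)) io[, over] <- sweep(io[, over, drop = FALSE], 2L,
                                     0.92 / csum[over], `*`)

  build_flows <- function(io) {
    V <- sweep(io, 2L, x0, `*`)               # intermediate flows
    E <- e_sh * x0                            # exports
    M <- m_sh * x0                            # imports (rest balances trade)
    M[["rest"]] <- sum(E) - sum(M[-which(ids == "rest")])
    if (M[["rest"]] <= 0)
      stop("infeasible trade pattern: rest-of-economy imports would be ",
           M[["rest"]], "; binding constraint: export shares too small")
    FD <- x0 + M - E - rowSums(V)             # final demand by commodity
    list(V = V, E = E, M = M, FD = FD)
  }
  fl <- build_flows(io)
  # feasibility repair: a commodity over-used as an input gets its
  # intermediate deliveries scaled back until final demand is positive
  floor_fd <- 0.002 * x0
  bad <- fl$FD < floor_fd
  if (any(bad)) {
    for (j in ids[bad]) {
      avail <- x0[[j]] + fl$M[[j]] - fl$E[[j]] - floor_fd[[j]]
      io[j, ] <- io[j, ] * avail / sum(fl$V[j, ])
    }
    fl <- build_flows(io)
  }
  if (any(fl$FD < 0))
    stop("infeasible template: negative final demand for ",
         paste(ids[fl$FD < 0], collapse = ", "))

  inv <- stats::setNames(sec$inv_absorb, ids) * fl$FD
  cons <- fl$FD - inv
  va <- x0 * (1 - colSums(io))
  Fpay <- sweep(fac, 2L, va, `*`)             # factor payments
  Y <- sum(Fpay)
  S <- sum(inv)
  if (S >= Y) stop("infeasible: implied savings exceed factor income")

  acc <- data.frame(
    id = c(account_id("a", ids), account_id("c", ids),
           "labour", "capital", "land", "household", "export", "import",
           "savings"),
    kind = c(rep("activity", n), rep("commodity", n), rep("factor", 3),
             "household", "export", "import", "savings"),
    label = c(paste(sec$label, "(activity)"), paste(sec$label, "(commodity)"),
              "Labour", "Capital", "Land", "Household",
              "Exports (rest of world)", "Imports (rest of world)",
              "Savings-investment"),
    stringsAsFactors = FALSE)
  fm <- matrix(0, nrow(acc), nrow(acc), dimnames = list(acc$id, acc$id))
  a <- account_id("a", ids); cc <- account_id("c", ids)
  fm[cbind(a, cc)] <- x0                      # commodities buy domestic output
  fm[cc, a] <- fl$V                           # activities buy intermediates
  fm[c("labour", "capital", "land"), a] <- Fpay
  fm[cc, "household"] <- cons
  fm[cc, "export"] <- fl$E
  fm["import", cc] <- fl$M
  fm["household", c("labour", "capital", "land")] <- rowSums(Fpay)
  fm["savings", "household"] <- S
  fm[cc, "savings"] <- inv
  fm["export", "import"] <- sum(fl$E)         # trade settlement

  out <- sam(fm, acc)
  # construction is balanced; RAS polish to numerical zero residuals
  ras_balance(out, tol = 1e-12)
}

# evaluate code under a fixed seed, restoring the caller's RNG state after
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Employment satellite for a synthetic economy
#'
#' Worker head counts per sector are fixed by the template (cattle
#' operations 1.0 million, animal processing 0.5 million in total, by
#' construction); hours worked are allocated proportionally to the SAM's
#' labour-row payments, mirroring the convention of measuring sector
#' employment in hours of labour input.
#'
#' @param template an [economy_template()].
#' @param sam the benchmark SAM; regenerated from the template if omitted.
#' @param hours_per_worker annual full-time hours used to scale total hours.
#' @return data.frame with columns `sector`, `workers_millions`,
#'   `hours_millions`, `food_system`.
#' @export
generate_employment_satellite <- function(template = economy_template(),
                                          sam = generate_sam(template),
                                          hours_per_worker = 2000) {
  sec <- template$sectors
  labpay <- sam$flows["labour", account_id("a", sec$id)]
  total_hours <- template$total_employment * hours_per_worker
  data.frame(sector = sec$id,
             workers_millions = sec$workers_millions,
             hours_millions = total_hours * labpay / sum(labpay),
             food_system = sec$food_system,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Structural shares of a synthetic economy
#'
#' Measures the shares the generator targets: beef export share of beef
#' output, agriculture share of employment, food-system share of employment.
#'
#' @param sam a generated [sam].
#' @param template the generating [economy_template()].
#' @return named numeric vector (fractions).
#' @export
structural_shares <- function(sam, template = economy_template()) {
  sec <- template$sectors
  beef_x <- sum(sam$flows[account_id("a", "beef_proc"), ])
  beef_e <- sam$flows[account_id("c", "beef_proc"), "export"]
  emp <- sec$workers_millions
  c(beef_export_share = unname(beef_e / beef_x),
    ag_employment_share = sum(emp[sec$group == "agriculture"]) / sum(emp),
    food_system_employment_share = sum(emp[sec$food_system]) / sum(emp))
}

#' Perturb a SAM with multiplicative noise and re-balance
#'
#' Applies seeded lognormal noise to every nonzero cell, then restores
#' balance by RAS against the original (balanced) margins, which are always
#' feasible for the unchanged sparsity pattern. Structural zeros are
#' preserved. Used to build robustness fixtures.
#'
#' @param x a balanced [sam].
#' @param noise lognormal sdlog in `[0, 0.5]`; 0 returns `x` unchanged.
#' @param seed integer seed.
#' @return a balanced [sam].
#' @export
perturb_sam <- function(x, noise = 0.1, seed = 0L) {
  stopifnot(inherits(x, "sam"), noise >= 0, noise <= 0.5)
  if (noise == 0) return(x)
  m <- x$flows
  nz <- which(m != 0)
  m[nz] <- m[nz] * exp(with_seed(seed, stats::rnorm(length(nz))) * noise)
  pert <- sam(m, x$accounts)
  ras_balance(pert, row_targets = rowSums(x$flows),
              col_targets = colSums(x$flows), tol = 1e-10)
}

#' Write a synthetic economy to disk
#'
#' Writes `sam.csv`, `accounts.csv`, `employment.csv`,
#' `footprint_mapping.csv` and `config.yaml` for a seeded synthetic economy,
#' ready for [cmd_run()].
#'
#' @param dir output directory (created if needed).
#' @param template an [economy_template()].
#' @return the directory, invisibly.
#' @export
write_synthetic_economy <- function(dir, template = economy_template()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- generate_sam(template)
  write_sam(s, file.path(dir, "sam.csv"),
            accounts_path = file.path(dir, "accounts.csv"))
  utils::write.csv(generate_employment_satellite(template, s),
                   file.path(dir, "employment.csv"), row.names = FALSE)
  utils::write.csv(default_footprint_mapping(),
                   file.path(dir, "footprint_mapping.csv"), row.names = FALSE)
  yaml::write_yaml(default_config(), file.path(dir, "config.yaml"))
  invisible(dir)
}
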