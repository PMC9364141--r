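#' Baseline environmental footprint of agricultural production
#'
#' The packaged per-commodity baseline of annual direct resource use by US
#' agricultural production: blue water (km3/yr), nitrogen and phosphorus
#' application (thousand tonnes/yr), and greenhouse gases (Mt CO2eq/yr).
#' Blank (NA) water/N/P cells for the animal commodities are deliberate:
#' blue water and fertiliser for livestock are accounted for under the feed
#' crops that use them, not as direct animal inputs, so an NA means
#' "attributed elsewhere", never zero. The cropland column ships empty (no
#' packaged baseline exists for it); users may supply their own
#' coefficients, and reports label the dimension unavailable rather than
#' zero.
#'
#' Column totals of the packaged table: 94 km3 water, 10,067 kt N, 1,636 kt
#' P, 347 Mt CO2eq.
#'
#' @param path CSV to read; defaults to the packaged baseline. Expected
#'   columns: `commodity, group, water_km3, n_kt, p_kt, ghg_mt,
#'   cropland_kha`.
#' @return a `footprint_table`: data.frame of non-negative (or NA) values.
#' @export
load_baseline_footprint <- function(path = system.file("extdata",
                                                       "footprint_baseline.csv",
                                                       package = "foodcge")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("commodity", "water_km3", "n_kt", "p_kt", "ghg_mt")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("footprint table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"cropland_kha" %in% names(df)) df$cropland_kha <- NA_real_
  for (d in footprint_dimensions()) {
    df[[d]] <- as.numeric(df[[d]])
    v <- df[[d]]
    if (any(!is.na(v) & v < 0))
      stop("negative footprint value in column ", d)
  }
  if (anyDuplicated(df$commodity))
    stop("duplicate footprint commodity: ",
         df$commodity[duplicated(df$commodity)][1L])
  class(df) <- c("footprint_table", "data.frame")
  df
}

footprint_dimensions <- function() {
  c("water_km3", "n_kt", "p_kt", "ghg_mt", "cropland_kha")
}

#' Default mapping from model sectors to footprint commodities
#'
#' Maps the synthetic economy's sectors onto the baseline footprint rows.
#' Farm-level rows carry the footprint (processing output scales with its
#' farm input through the model itself), so beef processing and the
#' downstream/service sectors map to `"none"` explicitly — an unmapped
#' sector with a nonzero output change is an error, never a silent drop.
#' The combined other-animal sector drives both the poultry and the
#' other-live-animal rows.
#'
#' @return data.frame with columns `sector`, `footprint_row`.
#' @export
default_footprint_mapping <- function() {
  data.frame(
    sector = c("cattle_ranch", "dairy", "oth_anim_farm", "oth_anim_farm",
               "grain", "fruit_nut", "vegetable", "oilseed", "oth_crops",
               "soya_proc", "sugar_proc",
               "beef_proc", "oth_anim_proc", "plant_based", "food_serv",
               "rest"),
    footprint_row = c("live_cattle", "dairy_cattle", "live_poultry",
                      "other_live_animals", "grain_farms", "fruit_nut_farms",
                      "vegetable_melon_farms", "oilseed_farms", "other_crops",
                      "soya_oil_processing", "sugar_processing",
                      "none", "none", "none", "none", "none"),
    stringsAsFactors = FALSE)
}

#' Scale the footprint baseline by sector output changes
#'
#' The satellite-account linkage: each footprint row changes linearly with
#' the gross output of the sector mapped to it,
#' `change = baseline x pct_change / 100`. Rows whose sector shows no
#' change (or that are absent from `pct_changes`) stay at zero change.
#' Totals are the exact sums of per-commodity contributions; the linkage is
#' linear and additive by construction.
#'
#' @param table a [load_baseline_footprint()] table.
#' @param pct_changes named vector of percent output changes. Names are
#'   model sectors when `mapping` is supplied, footprint commodities
#'   otherwise.
#' @param mapping optional data.frame (`sector`, `footprint_row`; row
#'   `"none"` discards a sector explicitly). Any name in `pct_changes` with
#'   a nonzero change that maps to no footprint row and is not explicitly
#'   `"none"` is an error.
#' @return a `footprint_result`: list with `totals` (data.frame: dimension,
#'   baseline, change, pct_change, available) and `contributions`
#'   (per-commodity changes by dimension).
#' @export
apply_output_changes <- function(table, pct_changes, mapping = NULL) {
  stopifnot(inherits(table, "footprint_table"))
  if (is.null(names(pct_changes)))
    stop("`pct_changes` must be named")
  row_pct <- stats::setNames(rep(0, nrow(table)), table$commodity)
  if (is.null(mapping)) {
    unknown <- setdiff(names(pct_changes)[pct_changes != 0], table$commodity)
    if (length(unknown))
      stop("unmapped commodity(ies) with nonzero change: ",
           paste(unknown, collapse = ", "),
           " (provide a mapping; silent drops are not allowed)")
    hit <- intersect(names(pct_changes), table$commodity)
    row_pct[hit] <- pct_changes[hit]
  } else {
    stopifnot(all(c("sector", "footprint_row") %in% names(mapping)))
    unknown <- setdiff(names(pct_changes)[pct_changes != 0], mapping$sector)
    if (length(unknown))
      stop("sector(s) with nonzero change missing from the mapping: ",
           paste(unknown, collapse = ", "),
           " (map them, or map them to 'none' explicitly)")
    bad_row <- setdiff(setdiff(mapping$footprint_row, "none"),
                       table$commodity)
    if (length(bad_row))
      stop("mapping names footprint row(s) not in the table: ",
           paste(bad_row, collapse = ", "))
    for (k in seq_len(nrow(mapping))) {
      fr <- mapping$footprint_row[k]
      if (fr == "none") next
      sc <- mapping$sector[k]
      if (sc %in% names(pct_changes)) row_pct[fr] <- pct_changes[[sc]]
    }
  }
  dims <- footprint_dimensions()
  contrib <- data.frame(commodity = table$commodity,
                        pct_change = unname(row_pct))
  totals <- data.frame(dimension = dims, baseline = NA_real_,
                       change = NA_real_, pct_change = NA_real_,
                       available = FALSE, stringsAsFactors = FALSE)
  for (d in dims) {
    v <- table[[d]]
    contrib[[paste0("change_", d)]] <- ifelse(is.na(v), NA, v * row_pct / 100)
    if (all(is.na(v))) next   # dimension unavailable (e.g. cropland)
    base <- sum(v, na.rm = TRUE)
    chg <- sum(v * row_pct / 100, na.rm = TRUE)
    i <- totals$dimension == d
    totals$baseline[i] <- base
    totals$change[i] <- chg
    totals$pct_change[i] <- if (base > 0) 100 * chg / base else NA_real_
    totals$available[i] <- TRUE
  }
  structure(list(totals = totals, contributions = contrib),
            class = "footprint_result")
}

#' @export
print.footprint_result <- function(x, ...) {
  cat("<footprint_result>\n")
  t <- x$totals
  t$change <- round(t$change, 3); t$pct_change <- round(t$pct_change, 3)
  t$baseline[!t$available] <- NA
  print(t, row.names = FALSE)
  invisible(x)
}

#' Baseline animal head counts
#'
#' Annual numbers of animals reared for meat production. The chicken and
#' pig baselines reflect reported US rearing numbers (more than 8.5 billion
#' chickens; 70-80 million pigs, midpoint used). The cattle baseline of 30
#' million is a derived, synthetic figure: it is back-solved so that
#' simulated beef-output contractions translate into head-count declines of
#' the reported order, and it is expected to be overridden where a measured
#' baseline is available.
#'
#' @param chickens,pigs,cattle head counts per year, > 0.
#' @return named numeric vector of class `animal_baseline`.
#' @export
animal_baseline <- function(chickens = 8.5e9, pigs = 7.5e7, cattle = 3.0e7) {
  stopifnot(chickens > 0, pigs > 0, cattle > 0)
  structure(c(chickens = chickens, pigs = pigs, cattle = cattle),
            class = "animal_baseline")
}

#' Animal head-count changes from sector output changes
#'
#' Linear linkage: `change = baseline x pct_change / 100` per species.
#'
#' @param baseline an [animal_baseline()].
#' @param pct_changes named vector with (any of) `chickens`, `pigs`,
#'   `cattle`: percent output changes of the rearing sectors; species not
#'   mentioned are held at 0.
#' @return data.frame with columns `species`, `baseline`, `pct_change`,
#'   `change` (head/yr).
#' @export
animal_numbers <- function(baseline, pct_changes) {
  stopifnot(inherits(baseline, "animal_baseline"))
  species <- names(unclass(baseline))
  pct <- stats::setNames(rep(0, length(species)), species)
  hit <- intersect(names(pct_changes), species)
  pct[hit] <- pct_changes[hit]
  data.frame(species = species,
             baseline = unname(unclass(baseline)[species]),
             pct_change = unname(pct),
             change = unname(unclass(baseline)[species] * pct / 100),
             stringsAsFactors = FALSE)
}

#' Per-commodity shares of each footprint dimension
#'
#' Shares of the column totals, in percent, summing to 100 per available
#' dimension (NA cells contribute nothing; a dimension with a zero or
#' absent total is reported as undefined rather than divided through).
#'
#' @param table a [load_baseline_footprint()] table.
#' @return data.frame: `commodity` plus one share column per dimension.
#' @export
share_report <- function(table) {
  stopifnot(inherits(table, "footprint_table"))
  out <- data.frame(commodity = table$commodity, stringsAsFactors = FALSE)
  for (d in footprint_dimensions()) {
    v <- table[[d]]
    tot <- sum(v, na.rm = TRUE)
    out[[paste0("share_", d)]] <-
      if (all(is.na(v)) || tot == 0) NA_real_ else 100 * v / tot
  }
  out
}
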