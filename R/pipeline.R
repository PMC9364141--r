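#' Validate a run configuration
#'
#' Schema check before any computation: unknown top-level or block keys are
#' rejected, elasticities must be non-negative, the closure must be known,
#' scenario entries must name a rate and target. Returns the config (with
#' defaults filled in) invisibly on success.
#'
#' @param config a configuration list, e.g. from [default_config()] or
#'   `yaml::read_yaml()`.
#' @return the validated config, invisibly.
#' @export
validate_config <- function(config) {
  known_top <- c("nests", "trade", "closure", "solver", "scenarios", "paths",
                 "seed")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  blocks <- list(nests = c("sigma", "groups"),
                 trade = c("eta_food", "eta_other", "food_sectors"),
                 closure = c("type", "numeraire", "numeraire_target"),
                 solver = c("tol", "max_iter"),
                 paths = c("sam", "accounts", "footprint", "mapping", "out"))
  for (b in names(blocks)) {
    unknown <- setdiff(names(config[[b]]), blocks[[b]])
    if (length(unknown))
      stop("unknown key(s) in config block '", b, "': ",
           paste(unknown, collapse = ", "))
  }
  sig <- config$nests$sigma
  if (any(unlist(sig) < 0)) stop("substitution elasticities must be >= 0")
  if (!is.null(config$closure$type) &&
      !config$closure$type %in% c("full_employment", "sticky_wage"))
    stop("unknown closure type: ", config$closure$type)
  for (sc in config$scenarios) {
    if (is.null(sc$name)) stop("scenario entry without a name")
    scenario(sc$name, rate = sc$rate, target = sc$target)  # validates
  }
  invisible(config)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

#' Run the full scenario pipeline and write reports
#'
#' Loads (or generates) the benchmark SAM, calibrates the model, runs the
#' named scenarios, and writes tidy long-format CSVs to `out_dir`:
#' per-scenario economy, sector, footprint and animal-number tables, a
#' cross-scenario comparison, and a `run_log.csv` with the config hash,
#' seed, solver iterations and Walras residuals. Reruns on identical inputs
#' are byte-identical.
#'
#' @param config configuration list (validated first). `config$paths$sam`
#'   may point at a SAM CSV; without it a synthetic benchmark is generated
#'   from `economy_template(seed = config$seed)`.
#' @param scenarios character vector of scenario names to run; defaults to
#'   all scenarios in the config.
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the scenario results and the comparison.
#' @export
cmd_run <- function(config = default_config(), scenarios = NULL,
                    out_dir = ".") {
  validate_config(config)
  available <- vapply(config$scenarios, `[[`, "", "name")
  if (is.null(scenarios)) scenarios <- available
  unknown <- setdiff(scenarios, available)
  if (length(unknown))
    stop("unknown scenario(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(available, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  if (!is.null(config$paths$sam)) {
    acc <- config$paths$accounts
    s <- if (is.null(acc)) read_sam(config$paths$sam)
         else read_sam(config$paths$sam, acc)
  } else {
    s <- generate_sam(economy_template(seed = seed))
  }
  instance <- build_model(s, config)
  hash <- config_hash(config)

  results <- list()
  log_rows <- list()
  for (nm in scenarios) {
    def <- config$scenarios[[match(nm, available)]]
    scen <- scenario(def$name, rate = def$rate, target = def$target)
    res <- run_scenario(instance, scen)
    results[[nm]] <- res
    for (piece in c("economy", "sectors", "animals")) {
      df <- res[[piece]]
      df$scenario <- nm; df$config_hash <- hash
      utils::write.csv(df, file.path(out_dir,
                                     paste0(nm, "_", piece, ".csv")),
                       row.names = FALSE)
    }
    fp <- res$footprint$totals
    fp$scenario <- nm; fp$config_hash <- hash
    utils::write.csv(fp, file.path(out_dir, paste0(nm, "_footprint.csv")),
                     row.names = FALSE)
    log_rows[[nm]] <- data.frame(scenario = nm, seed = seed,
                                 config_hash = hash,
                                 iterations = res$state$iterations,
                                 residual = res$state$residual,
                                 walras = res$walras)
  }
  comparison <- NULL
  if (length(results) >= 2L) {
    comparison <- compare_scenarios(unname(results))
    for (piece in names(comparison)) {
      df <- comparison[[piece]]
      df$config_hash <- hash
      utils::write.csv(df, file.path(out_dir,
                                     paste0("comparison_", piece, ".csv")),
                       row.names = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, unname(log_rows)),
                   file.path(out_dir, "run_log.csv"), row.names = FALSE)
  invisible(list(results = results, comparison = comparison,
                 config_hash = hash))
}

#' Standalone satellite-account run
#'
#' Applies a table of sector output percent changes to a footprint baseline
#' without running the equilibrium model, and writes the resulting totals
#' and contributions as CSVs.
#'
#' @param pct_csv CSV with columns `sector` (or `commodity`) and
#'   `pct_change`.
#' @param footprint_csv optional footprint baseline CSV; defaults to the
#'   packaged baseline.
#' @param mapping_csv optional sector-to-row mapping CSV (`sector`,
#'   `footprint_row`); defaults to [default_footprint_mapping()] when
#'   `pct_csv` uses sector names, or no mapping when it uses footprint
#'   commodity names directly.
#' @param out_dir output directory.
#' @return invisibly, the `footprint_result`.
#' @export
cmd_footprint <- function(pct_csv, footprint_csv = NULL, mapping_csv = NULL,
                          out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pc <- utils::read.csv(pct_csv, stringsAsFactors = FALSE)
  key <- intersect(c("sector", "commodity"), names(pc))[1L]
  if (is.na(key) || !"pct_change" %in% names(pc))
    stop("percent-change CSV needs columns 'sector' (or 'commodity') and ",
         "'pct_change'; got: ", paste(names(pc), collapse = ", "))
  table <- if (is.null(footprint_csv)) load_baseline_footprint()
           else load_baseline_footprint(footprint_csv)
  mapping <- if (!is.null(mapping_csv))
    utils::read.csv(mapping_csv, stringsAsFactors = FALSE)
  else if (key == "sector") default_footprint_mapping()
  res <- apply_output_changes(table,
                              stats::setNames(pc$pct_change, pc[[key]]),
                              mapping = mapping)
  utils::write.csv(res$totals, file.path(out_dir, "footprint_totals.csv"),
                   row.names = FALSE)
  utils::write.csv(res$contributions,
                   file.path(out_dir, "footprint_contributions.csv"),
                   row.names = FALSE)
  invisible(res)
}
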