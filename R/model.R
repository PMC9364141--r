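#' Calibrate a model instance to a benchmark SAM
#'
#' Assembles everything the equilibrium solver needs: calibrated production
#' and utility nest trees, Armington (domestic vs imported variety)
#' composites per commodity, constant-elasticity export demand schedules,
#' the savings rate read off the SAM, factor endowments, and the closure.
#' At the benchmark all prices equal 1 and the model replicates the SAM
#' exactly; that replication is the defining property of the calibration and
#' is what [assemble_residuals()] verifies at the zero-shock point.
#'
#' Trade closure: import prices equal `PFX` (world prices fixed at 1 in
#' foreign currency), export demand for commodity *i* is
#' \eqn{E_i = E^0_i (p_i/PFX)^{-\eta_i}}. The external-balance equation is
#' dropped from the solved system (Walras' law) and serves as the
#' [check_walras()] diagnostic. The numeraire is the household consumer
#' price index (benchmark-consumption-weighted composite prices), so
#' reported changes are real in CPI units.
#'
#' @param sam a balanced [sam] with `a_*`/`c_*` activity/commodity pairs.
#' @param config configuration list, see [default_config()].
#' @return an object of class `model_instance`.
#' @export
build_model <- function(sam, config = default_config()) {
  stopifnot(inherits(sam, "sam"))
  if (!is_balanced(sam, tol = 1e-6))
    stop("SAM is not balanced (max residual ",
         format(max(abs(balance_residuals(sam)))), "); balance it first")
  fl <- sam$flows
  activities <- accounts_of_kind(sam, "activity")
  commodities <- accounts_of_kind(sam, "commodity")
  factors <- accounts_of_kind(sam, "factor")
  sectors <- sub("^a_", "", activities)
  if (!setequal(account_id("c", sectors), commodities))
    stop("activities and commodities must pair one-to-one as a_<s>/c_<s>")
  cids <- account_id("c", sectors)
  aids <- account_id("a", sectors)

  x0 <- stats::setNames(rowSums(fl[aids, , drop = FALSE]), sectors)
  E0 <- stats::setNames(fl[cids, "export"], sectors)
  M0 <- stats::setNames(fl["import", cids], sectors)
  dom0 <- x0 - E0
  if (any(dom0 < 0))
    stop("exports exceed gross output for: ",
         paste(sectors[dom0 < 0], collapse = ", "))
  C0 <- stats::setNames(fl[cids, "household"], sectors)
  inv0 <- stats::setNames(fl[cids, "savings"], sectors)
  S0 <- fl["savings", "household"]
  Fpay0 <- fl[factors, aids, drop = FALSE]
  colnames(Fpay0) <- sectors
  F0 <- rowSums(Fpay0)
  Y0 <- sum(F0)
  s_rate <- S0 / Y0

  trees <- build_default_trees(sam, config)

  sg_arm <- config$nests$sigma$armington
  armington <- stats::setNames(vector("list", length(sectors)), sectors)
  for (s in sectors) {
    if (M0[[s]] > 0) {
      armington[[s]] <- calibrate_ces_node(
        c(dom = dom0[[s]], imp = M0[[s]]), sg_arm,
        id = paste0("arm_", s))
    }
  }

  eta <- ifelse(sectors %in% config$trade$food_sectors,
                config$trade$eta_food, config$trade$eta_other)
  names(eta) <- sectors

  closure <- config$closure
  if (!closure$type %in% c("full_employment", "sticky_wage"))
    stop("unknown closure type: ", closure$type)
  if (is.null(closure$numeraire_target)) closure$numeraire_target <- 1

  structure(list(
    sam = sam, config = config,
    sectors = sectors, factors = factors,
    x0 = x0, E0 = E0, M0 = M0, dom0 = dom0, C0 = C0, inv0 = inv0,
    S0 = S0, F0 = F0, Y0 = Y0, s_rate = s_rate,
    invshare = if (S0 > 0) inv0 / S0 else inv0 * 0,
    Fpay0 = Fpay0,
    trees = trees, armington = armington, eta = eta,
    closure = closure
  ), class = "model_instance")
}

#' @export
print.model_instance <- function(x, ...) {
  cat("<model_instance> ", length(x$sectors), " sectors, ",
      length(x$factors), " factors, closure ", x$closure$type,
      ", savings rate ", round(x$s_rate, 3), "\n", sep = "")
  invisible(x)
}

# benchmark log-variable vector: prices/wages 1, activities x0, income Y0
benchmark_z <- function(instance) {
  n <- length(instance$sectors)
  z <- c(rep(0, n), log(instance$x0), rep(0, length(instance$factors)),
         log(instance$Y0), 0)
  names(z) <- c(paste0("p_", instance$sectors),
                paste0("x_", instance$sectors),
                paste0("w_", instance$factors), "Y", "PFX")
  z
}

# full evaluation of the economy at a log-variable point; returns all
# derived quantities needed for residuals and reporting
eval_state <- function(instance, z, taste = NULL) {
  sec <- instance$sectors
  fac <- instance$factors
  n <- length(sec)
  p <- stats::setNames(exp(z[seq_len(n)]), sec)
  x <- stats::setNames(exp(z[n + seq_len(n)]), sec)
  w <- stats::setNames(exp(z[2 * n + seq_along(fac)]), fac)
  Y <- exp(z[["Y"]])
  PFX <- exp(z[["PFX"]])

  # Armington composite price per commodity
  q <- p
  for (s in sec) {
    node <- instance$armington[[s]]
    if (!is.null(node))
      q[[s]] <- ces_price_index(node, c(dom = p[[s]], imp = PFX))
  }
  leaf_prices <- c(stats::setNames(q, account_id("c", sec)),
                   stats::setNames(w, fac))

  # production: unit costs, intermediate and factor demands
  unit_cost <- stats::setNames(numeric(n), sec)
  int_dem <- matrix(0, n, n, dimnames = list(sec, sec))  # input x sector
  fdem <- matrix(0, length(fac), n, dimnames = list(fac, sec))
  for (s in sec) {
    tree <- instance$trees$production[[s]]
    pr <- tree_price_index(tree, leaf_prices)
    uc <- pr[[tree$root]]
    unit_cost[[s]] <- uc
    dem <- tree_leaf_demand(tree, leaf_prices, expenditure = uc * x[[s]])
    ql <- dem$leaf_quantities
    isc <- intersect(names(ql), account_id("c", sec))
    if (length(isc)) int_dem[sub("^c_", "", isc), s] <- ql[isc]
    isf <- intersect(names(ql), fac)
    fdem[isf, s] <- ql[isf]
  }

  # household demand under the (possibly shocked) utility tree
  hh_exp <- (1 - instance$s_rate) * Y
  hh <- tree_leaf_demand(instance$trees$utility, leaf_prices, hh_exp,
                         taste = taste)
  h <- stats::setNames(numeric(n), sec)
  h[sub("^c_", "", names(hh$leaf_quantities))] <- hh$leaf_quantities

  # investment demand: fixed value shares of nominal savings
  inv_q <- instance$invshare * instance$s_rate * Y / q

  # export demand and Armington split of composite absorption
  E <- instance$E0 * ifelse(instance$E0 > 0, (p / PFX)^(-instance$eta), 0)
  Q <- rowSums(int_dem) + h + inv_q
  dom <- Q; M <- stats::setNames(numeric(n), sec)
  for (s in sec) {
    node <- instance$armington[[s]]
    if (!is.null(node)) {
      dd <- ces_demand(node, c(dom = p[[s]], imp = PFX), q[[s]] * Q[[s]])
      dom[[s]] <- dd[["dom"]]; M[[s]] <- dd[["imp"]]
    }
  }

  cpi <- sum(q * instance$C0) / sum(instance$C0)
  factor_income <- sum(w * rowSums(fdem))

  list(p = p, x = x, w = w, Y = Y, PFX = PFX, q = q,
       unit_cost = unit_cost, int_dem = int_dem, fdem = fdem,
       h = h, inv_q = inv_q, E = E, M = M, dom = dom, Q = Q,
       cpi = cpi, factor_income = factor_income, hh_exp = hh_exp)
}

#' Residuals of the general-equilibrium system
#'
#' Blocks: zero profit (unit cost = output price), commodity-market clearing
#' (domestic output = domestic sales of the domestic variety + exports),
#' factor-market clearing (or a fixed wage under the sticky-wage closure),
#' household income (= factor payments actually made), and the numeraire
#' (CPI = target). All blocks are scaled relative so tolerances are
#' comparable across variables; at the benchmark with zero shocks every
#' residual is numerically zero.
#'
#' @param instance a [build_model()] instance.
#' @param state either a named log-variable vector (internal) or an
#'   `equilibrium_state`.
#' @param shocks optional shock set from [build_beef_replacement_shock()].
#' @return named residual vector, one entry per unknown.
#' @export
assemble_residuals <- function(instance, state, shocks = NULL) {
  z <- if (inherits(state, "equilibrium_state")) state$z else state
  ev <- eval_state(instance, z, taste = shock_taste(shocks))
  residuals_from_eval(instance, ev)
}

residuals_from_eval <- function(instance, ev) {
  sec <- instance$sectors
  fac <- instance$factors
  r_zp <- ev$unit_cost - ev$p
  r_mc <- (ev$dom + ev$E - ev$x) / instance$x0
  r_fm <- stats::setNames(numeric(length(fac)), fac)
  for (f in fac) {
    if (instance$closure$type == "sticky_wage" && f == "labour") {
      r_fm[[f]] <- ev$w[[f]] - 1       # real wage fixed in CPI units
    } else {
      r_fm[[f]] <- (sum(ev$fdem[f, ]) - instance$F0[[f]]) / instance$F0[[f]]
    }
  }
  r_inc <- (ev$factor_income - ev$Y) / instance$Y0
  r_num <- ev$cpi - instance$closure$numeraire_target
  out <- c(r_zp, r_mc, r_fm, r_inc, r_num)
  names(out) <- c(paste0("zp_", sec), paste0("mc_", sec),
                  paste0("fm_", fac), "inc", "num")
  out
}

shock_taste <- function(shocks, scale = 1) {
  if (is.null(shocks)) return(NULL)
  taste <- if (inherits(shocks, "shock_set")) shocks$taste else shocks
  if (is.null(taste)) return(NULL)
  if (scale != 1) taste <- lapply(taste, function(m) exp(scale * log(m)))
  taste
}
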