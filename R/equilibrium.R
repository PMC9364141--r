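#' Solve the model in levels
#'
#' Damped Newton iteration on the log of all variables (commodity prices,
#' activity levels, factor prices, household income, the exchange-rate
#' variable `PFX`), with a finite-difference Jacobian — adequate at the
#' intended model size (a few dozen sectors). Working in logs keeps every
#' iterate strictly positive; steps are halved until they reduce the
#' residual norm.
#'
#' @param instance a [build_model()] instance.
#' @param shocks optional shock set ([build_beef_replacement_shock()]).
#' @param init initial log-variable vector; defaults to the benchmark.
#' @param tol convergence tolerance on the maximum absolute (relative)
#'   residual.
#' @param max_iter Newton iteration cap.
#' @return an object of class `equilibrium_state`: the solved levels, the
#'   percent changes from benchmark for every variable, employment by
#'   sector, and solver diagnostics (`iterations`, `residual`,
#'   `walras`).
#' @export
solve_levels <- function(instance, shocks = NULL, init = NULL,
                         tol = NULL, max_iter = NULL) {
  stopifnot(inherits(instance, "model_instance"))
  if (is.null(tol)) tol <- instance$config$solver$tol
  if (is.null(max_iter)) max_iter <- instance$config$solver$max_iter
  taste <- shock_taste(shocks)
  z <- if (is.null(init)) benchmark_z(instance) else init
  resfun <- function(z) {
    residuals_from_eval(instance, eval_state(instance, z, taste))
  }
  r <- resfun(z)
  trace <- max(abs(r))
  it <- 0L
  while (max(abs(r)) > tol) {
    if (it >= max_iter)
      stop("levels solver failed to converge in ", max_iter,
           " iterations; residual trace: ",
           paste(format(trace, digits = 3), collapse = " -> "))
    J <- fd_jacobian(resfun, z, r)
    step <- tryCatch(solve(J, -r), error = function(e)
      stop("singular Jacobian in levels solver (closure ",
           instance$closure$type, "): ", conditionMessage(e)))
    lam <- 1
    repeat {
      z_new <- z + lam * step
      r_new <- resfun(z_new)
      if (max(abs(r_new)) < max(abs(r)) || lam < 1e-6) break
      lam <- lam / 2
    }
    if (max(abs(r_new)) >= max(abs(r)) && max(abs(r)) > tol)
      stop("levels solver stalled at residual ", format(max(abs(r))),
           "; residual trace: ",
           paste(format(trace, digits = 3), collapse = " -> "))
    z <- z_new; r <- r_new
    it <- it + 1L
    trace <- c(trace, max(abs(r)))
  }
  as_equilibrium_state(instance, z, taste, iterations = it,
                       residual = max(abs(r)))
}

fd_jacobian <- function(fun, z, f0 = fun(z), h = 1e-7) {
  n <- length(z)
  J <- matrix(0, length(f0), n, dimnames = list(names(f0), names(z)))
  for (j in seq_len(n)) {
    zj <- z
    zj[j] <- zj[j] + h
    J[, j] <- (fun(zj) - f0) / h
  }
  J
}

as_equilibrium_state <- function(instance, z, taste, iterations = NA_integer_,
                                 residual = NA_real_) {
  ev <- eval_state(instance, z, taste)
  z0 <- benchmark_z(instance)
  pct <- 100 * (exp(z - z0) - 1)
  emp0 <- instance$Fpay0["labour", ]
  structure(list(
    z = z, levels = ev,
    pct_change = pct,
    prices = ev$p, activity = ev$x, factor_prices = ev$w,
    income = ev$Y, exports = ev$E, imports = ev$M,
    employment = ev$fdem["labour", ],
    employment_pct = 100 * (ev$fdem["labour", ] / emp0 - 1),
    walras = walras_residual(instance, ev),
    iterations = iterations, residual = residual
  ), class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("<equilibrium_state> residual ", format(x$residual),
      " after ", x$iterations, " iterations; Walras residual ",
      format(x$walras), "\n", sep = "")
  top <- sort(abs(x$pct_change), decreasing = TRUE)
  show <- names(top)[seq_len(min(5L, length(top)))]
  cat("  largest changes (%):\n")
  print(round(x$pct_change[show], 3))
  invisible(x)
}

walras_residual <- function(instance, ev) {
  (sum(ev$p * ev$E) - ev$PFX * sum(ev$M)) / instance$Y0
}

#' Walras' law diagnostic
#'
#' Value of the dropped market equation — external balance: export receipts
#' minus import payments, relative to benchmark GDP. If every retained
#' equation holds, the accounting identities of the model force this to
#' zero; a material residual signals an inconsistent solution. Reported, not
#' thrown.
#'
#' @param instance a [build_model()] instance.
#' @param state an `equilibrium_state` (or log-variable vector).
#' @param shocks the shock set the state was solved under, if any.
#' @return scalar residual (relative to benchmark GDP).
#' @export
check_walras <- function(instance, state, shocks = NULL) {
  z <- if (inherits(state, "equilibrium_state")) state$z else state
  ev <- eval_state(instance, z, taste = shock_taste(shocks))
  walras_residual(instance, ev)
}

#' Johansen / multi-step Euler percent-change solution
#'
#' Solves the linearized model in percent changes: with one step this is the
#' pure Johansen solution (exactly proportional to the shock size); with
#' `n_steps > 1` the shock is applied along an Euler path, re-linearizing at
#' each point, which converges to the [solve_levels()] solution as the step
#' count grows. `richardson = TRUE` extrapolates solutions at `n_steps` and
#' `2 * n_steps` (error is O(1/n) for Euler).
#'
#' @inheritParams solve_levels
#' @param n_steps number of Euler steps (1 = pure linearization).
#' @param richardson logical; Richardson-extrapolate the Euler solution.
#' @return list with `pct_change` (named vector over all model variables)
#'   and `z` (final log-variable vector).
#' @export
solve_johansen <- function(instance, shocks, n_steps = 1L,
                           richardson = FALSE) {
  stopifnot(inherits(instance, "model_instance"), n_steps >= 1L)
  if (richardson) {
    a <- solve_johansen(instance, shocks, n_steps, richardson = FALSE)
    b <- solve_johansen(instance, shocks, 2L * n_steps, richardson = FALSE)
    return(list(pct_change = 2 * b$pct_change - a$pct_change,
                z = 2 * b$z - a$z, n_steps = n_steps, richardson = TRUE))
  }
  z0 <- benchmark_z(instance)
  z <- z0
  dt <- 1 / n_steps
  for (k in seq_len(n_steps)) {
    t_here <- (k - 1) * dt
    resfun_z <- function(zz) {
      residuals_from_eval(instance,
                          eval_state(instance, zz, shock_taste(shocks, t_here)))
    }
    r0 <- resfun_z(z)
    Jz <- fd_jacobian(resfun_z, z, r0)
    ht <- 1e-6
    r_t <- residuals_from_eval(
      instance, eval_state(instance, z, shock_taste(shocks, t_here + ht)))
    Jt <- (r_t - r0) / ht
    dz <- tryCatch(solve(Jz, -(Jt * dt + r0)),
                   error = function(e)
                     stop("singular Jacobian at the benchmark; the closure (",
                          instance$closure$type,
                          ") is the likely cause: ", conditionMessage(e)))
    z <- z + dz
  }
  dlog <- z - z0
  pct <- if (n_steps == 1L) 100 * dlog else 100 * (exp(dlog) - 1)
  list(pct_change = pct, z = z, n_steps = n_steps, richardson = FALSE)
}

#' Macro and sector aggregates of a solved state
#'
#' The reporting set of a comparative-static run: GDP (computed separately
#' from the income side — factor payments — and the expenditure side —
#' consumption + investment + exports - imports; the two agree to solver
#' accuracy and both are reported), total household expenditure, aggregate
#' employment, the economy-wide average wage, and per-sector output and
#' employment. All as percent changes from the benchmark; with the CPI as
#' numeraire these are real changes. Under the full-employment closure
#' aggregate employment change is identically zero by construction.
#'
#' @param state an `equilibrium_state` from [solve_levels()].
#' @param instance the generating [build_model()] instance.
#' @return list with `economy` (data.frame: variable, pct_change) and
#'   `sectors` (data.frame: sector, output_pct, employment_pct).
#' @export
gdp_and_aggregates <- function(state, instance) {
  stopifnot(inherits(state, "equilibrium_state"))
  ev <- state$levels
  gdp_inc <- ev$factor_income
  gdp_exp <- sum(ev$q * ev$h) + sum(ev$q * ev$inv_q) +
    sum(ev$p * ev$E) - ev$PFX * sum(ev$M)
  Y0 <- instance$Y0
  econ <- data.frame(
    variable = c("gdp_income_side", "gdp_expenditure_side",
                 "household_expenditure", "employment", "wage"),
    pct_change = c(100 * (gdp_inc / Y0 - 1),
                   100 * (gdp_exp / Y0 - 1),
                   100 * (ev$hh_exp / ((1 - instance$s_rate) * Y0) - 1),
                   100 * (sum(ev$fdem["labour", ]) /
                            instance$F0[["labour"]] - 1),
                   100 * (ev$w[["labour"]] - 1)),
    stringsAsFactors = FALSE)
  sect <- data.frame(
    sector = instance$sectors,
    output_pct = unname(state$pct_change[paste0("x_", instance$sectors)]),
    employment_pct = unname(state$employment_pct[instance$sectors]),
    stringsAsFactors = FALSE)
  list(economy = econ, sectors = sect)
}
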