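# Shared fixtures, memoized: the default synthetic benchmark and model are
# deterministic, so building them once per test run is safe and keeps the
# suite fast.
.fx <- new.env()

fx_sam <- function() {
  if (is.null(.fx$sam)) .fx$sam <- generate_sam(economy_template())
  .fx$sam
}

fx_instance <- function() {
  if (is.null(.fx$instance)) .fx$instance <- build_model(fx_sam())
  .fx$instance
}

# solved scenario results on the default seeded benchmark
fx_result <- function(name) {
  key <- paste0("res_", name)
  if (is.null(.fx[[key]])) .fx[[key]] <- run_scenario(fx_instance(), name)
  .fx[[key]]
}

# tiny hand-built SAM: one activity, one commodity, household, factor,
# export/import/savings kept minimal
toy_accounts <- function() {
  data.frame(id = c("a_farm", "c_farm", "labour", "household",
                    "export", "import", "savings"),
             kind = c("activity", "commodity", "factor", "household",
                      "export", "import", "savings"),
             label = c("Farm", "Farm goods", "Labour", "Household",
                       "Exports", "Imports", "Savings"),
             stringsAsFactors = FALSE)
}

# independent constrained-optimization oracle for CES demand: maximize
# [sum delta^(1/sigma) q^rho]^(1/rho) (Cobb-Douglas at sigma = 1) subject to
# the budget, searching over expenditure shares via a softmax
# parameterization. Never calls ces_demand.
oracle_ces_demand <- function(delta, sigma, prices, expenditure) {
  k <- length(delta)
  cobb <- abs(sigma - 1) < 1e-12
  rho <- (sigma - 1) / sigma
  a <- delta^(1 / sigma)
  # the CES is homothetic: optimize over expenditure shares with the budget
  # scale normalized out, which keeps the objective well-conditioned for
  # every sigma
  util <- function(qn) {
    if (cobb) sum(delta * log(qn)) else sum(a * qn^rho) / rho
  }
  mu <- function(qn) if (cobb) delta / qn else a * qn^(rho - 1)
  obj <- function(theta) {
    sh <- exp(c(theta, 0)); sh <- sh / sum(sh)
    -util(sh / prices)
  }
  grad <- function(theta) {
    sh <- exp(c(theta, 0)); sh <- sh / sum(sh)
    g <- mu(sh / prices) / prices
    -(g * sh - sh * sum(g * sh))[seq_len(k - 1)]
  }
  theta0 <- log(delta[seq_len(k - 1)] / delta[k])  # benchmark-share start
  fit <- stats::optim(theta0, obj, grad, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 5000))
  # damped Newton polish on the first-order conditions to machine precision
  theta <- fit$par
  g <- grad(theta)
  for (i in 1:100) {
    if (max(abs(g)) < 1e-13) break
    H <- vapply(seq_len(k - 1), function(j) {
      tj <- theta; tj[j] <- tj[j] + 1e-6
      (grad(tj) - g) / 1e-6
    }, numeric(k - 1))
    step <- solve(matrix(H, k - 1, k - 1), g)
    lam <- 1
    repeat {
      g_new <- grad(theta - lam * step)
      if (max(abs(g_new)) < max(abs(g)) || lam < 1e-8) break
      lam <- lam / 2
    }
    theta <- theta - lam * step
    g <- g_new
  }
  sh <- exp(c(theta, 0)); sh <- sh / sum(sh)
  stats::setNames(sh * expenditure / prices, names(delta))
}
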