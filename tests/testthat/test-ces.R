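test_that("calibration recovers expenditure shares at unit prices", {
  n <- calibrate_ces_node(c(x = 60, y = 40), sigma = 0.7)
  expect_equal(unname(n$delta), c(0.6, 0.4))
  expect_equal(n$A, 100)
  # calibrated demands at unit prices reproduce the benchmark for any sigma
  for (sg in c(0, 0.5, 1, 2, 8)) {
    nd <- calibrate_ces_node(c(x = 60, y = 40), sg)
    expect_equal(ces_demand(nd, c(x = 1, y = 1), 100),
                 c(x = 60, y = 40), tolerance = 1e-12)
  }
  # symmetry: equal expenditures over k children give 1/k shares
  k <- 5
  ns <- calibrate_ces_node(setNames(rep(20, k), letters[1:k]), 1.3)
  expect_equal(unname(ns$delta), rep(1 / k, k))
  # zero-expenditure child dropped with a warning; all-zero is an error
  expect_warning(nz <- calibrate_ces_node(c(a = 10, b = 0), 1), "dropping")
  expect_identical(nz$children, "a")
  expect_error(calibrate_ces_node(c(a = 0, b = 0), 1), "all benchmark")
})

test_that("sigma = 1 demands match the closed-form Cobb-Douglas solution", {
  nd <- calibrate_ces_node(c(a = 30, b = 50, c = 20), sigma = 1)
  p <- c(a = 1.4, b = 0.8, c = 2.2)
  q <- ces_demand(nd, p, 200)
  expect_equal(q, nd$delta * 200 / p, tolerance = 1e-12)
  # continuity of the Cobb-Douglas limit
  lo <- calibrate_ces_node(c(a = 30, b = 50, c = 20), 1 - 1e-6)
  hi <- calibrate_ces_node(c(a = 30, b = 50, c = 20), 1 + 1e-6)
  expect_equal(ces_demand(lo, p, 200) / q, c(a = 1, b = 1, c = 1),
               tolerance = 1e-4)
  expect_equal(ces_demand(hi, p, 200) / q, c(a = 1, b = 1, c = 1),
               tolerance = 1e-4)
})

test_that("demands agree with a brute-force constrained optimizer", {
  # a fixed worked case
  nd <- ces_node("n", c("a", "b"), sigma = 0.5, delta = c(0.6, 0.4))
  p <- c(a = 1.1, b = 1.0)
  q <- ces_demand(nd, p, 100)
  q_star <- oracle_ces_demand(nd$delta, 0.5, p, 100)
  expect_equal(q, q_star, tolerance = 1e-8)
  expect_equal(sum(p * q), 100, tolerance = 1e-10)

  # property: random nodes, prices and budgets (100 draws)
  set.seed(7)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    delta <- as.numeric(rexp(k)); delta <- delta / sum(delta)
    names(delta) <- paste0("g", 1:k)
    sigma <- sample(c(0.3, 0.8, 1, 1.6, 3), 1)
    p <- setNames(exp(runif(k, -0.5, 0.5)), names(delta))
    ex <- runif(1, 50, 150)
    nd <- ces_node("n", names(delta), sigma, delta)
    q <- ces_demand(nd, p, ex)
    expect_equal(sum(p * q), ex, tolerance = 1e-10 * ex) # adding-up
    q_star <- oracle_ces_demand(delta, sigma, p, ex)
    expect_equal(q, q_star, tolerance = 1e-6)
  }
})

test_that("demand is homogeneous of degree zero in jointly scaled prices and budget", {
  nd <- ces_node("n", c("a", "b", "c"), 1.4, c(0.2, 0.5, 0.3))
  p <- c(a = 0.9, b = 1.2, c = 1.0)
  expect_equal(ces_demand(nd, 2 * p, 2 * 80), ces_demand(nd, p, 80),
               tolerance = 1e-12)
  expect_error(ces_demand(nd, c(a = -1, b = 1, c = 1), 10), "non-positive")
})

test_that("price index is 1 at benchmark, dual to demand, and tends to the min price", {
  nd <- ces_node("n", c("a", "b"), 2.5, c(0.45, 0.55))
  expect_equal(ces_price_index(nd, c(a = 1, b = 1)), 1, tolerance = 1e-12)
  # duality: index x composite quantity = expenditure = sum p q
  p <- c(a = 1.3, b = 0.7); ex <- 120
  q <- ces_demand(nd, p, ex)
  P <- ces_price_index(nd, p)
  expect_equal(P * (ex / P), sum(p * q), tolerance = 1e-10)
  # large-sigma limit: the index approaches the cheapest child price
  nd_inf <- ces_node("n", c("a", "b"), 100, c(0.5, 0.5))
  expect_lt(abs(ces_price_index(nd_inf, c(a = 1, b = 2)) - 1), 0.01)
  # nondecreasing in each child price
  expect_gt(ces_price_index(nd, c(a = 1.4, b = 0.7)), P)
})

test_that("taste multipliers of one recover the benchmark; twists stay on the simplex", {
  nd <- ces_node("n", c("a", "b"), 1.2, c(0.6, 0.4))
  nd_t <- ces_node("n", c("a", "b"), 1.2, c(0.6, 0.4), taste = c(1, 1))
  p <- c(a = 1.05, b = 0.96)
  expect_identical(ces_demand(nd, p, 70), ces_demand(nd_t, p, 70))
  # a twist re-weights but expenditure still adds up
  nd_s <- ces_node("n", c("a", "b"), 1.2, c(0.6, 0.4), taste = c(0.5, 1.3))
  q <- ces_demand(nd_s, p, 70)
  expect_equal(sum(p * q), 70, tolerance = 1e-10)
  expect_lt(q[["a"]], ces_demand(nd, p, 70)[["a"]])
})

test_that("nest trees validate topology and satisfy adding-up at every node", {
  na <- ces_node("top", c("mid", "z"), 0.5, c(0.7, 0.3))
  nb <- ces_node("mid", c("x", "y"), 2.0, c(0.5, 0.5))
  tr <- nest_tree("top", list(top = na, mid = nb), kind = "utility")
  expect_setequal(tree_leaves(tr), c("x", "y", "z"))
  p <- c(x = 1.1, y = 0.9, z = 1.3)
  d <- tree_leaf_demand(tr, p, 500)
  q <- d$leaf_quantities
  expect_equal(sum(p[names(q)] * q), 500, tolerance = 1e-10 * 500)
  # internal node adding-up: mid expenditure = its children's outlay
  expect_equal(d$node_expenditure[["mid"]],
               sum(p[c("x", "y")] * d$leaf_quantities[c("x", "y")]),
               tolerance = 1e-10)
  # duplicate leaf across nests rejected
  nc <- ces_node("mid", c("x", "z"), 2.0, c(0.5, 0.5))
  expect_error(nest_tree("top", list(top = na, mid = nc), kind = "utility"),
               "duplicate")
})
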