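#' CES aggregator nodes
#'
#' A constant-elasticity-of-substitution (CES) node combines the quantities
#' of its children (commodities, factors, or lower-level composites) into one
#' composite. The package uses the *calibrated share form*: with substitution
#' elasticity \eqn{\sigma}, share parameters \eqn{\delta_i} (summing to 1) and
#' benchmark composite quantity \eqn{A}, the cost-minimizing demand for child
#' \eqn{i} given child prices \eqn{p_i} and total expenditure \eqn{E} is
#' \deqn{q_i = \tilde\delta_i (P/p_i)^{\sigma} \, E/P, \qquad
#'       P = \left(\sum_i \tilde\delta_i p_i^{1-\sigma}\right)^{1/(1-\sigma)},}
#' where \eqn{\tilde\delta} are the share parameters after applying taste
#' multipliers (see below). In this form \eqn{\delta_i} equals the benchmark
#' expenditure share of child \eqn{i} at unit prices, for every \eqn{\sigma},
#' which makes calibration to a SAM unique and directly testable.
#' \eqn{\sigma = 1} is evaluated as the Cobb-Douglas limit
#' (\eqn{P = \prod p_i^{\tilde\delta_i}}); \eqn{\sigma = 0} is Leontief
#' (fixed proportions, \eqn{P = \sum \tilde\delta_i p_i}).
#'
#' Taste multipliers \eqn{t_i > 0} (default 1) are the shock handle for
#' preference shifts: the effective shares are
#' \eqn{\tilde\delta_i = t_i \delta_i / \sum_j t_j \delta_j}, so a shock
#' re-weights children while keeping the shares on the unit simplex — a pure
#' preference twist with no scale effect.
#'
#' @param id node id.
#' @param children character vector of child ids (leaf commodity/factor ids
#'   or ids of lower CES nodes).
#' @param sigma substitution elasticity, \eqn{\ge 0}.
#' @param delta share parameters, one per child, non-negative, summing to 1.
#' @param A benchmark composite quantity (scale), > 0.
#' @param taste taste multipliers per child, > 0; default all 1.
#' @return an object of class `ces_node`.
#' @seealso [calibrate_ces_node()], [ces_demand()], [ces_price_index()]
#' @export
ces_node <- function(id, children, sigma, delta, A = 1, taste = NULL) {
  stopifnot(length(children) >= 1L, sigma >= 0, A > 0,
            length(delta) == length(children))
  if (any(delta < 0)) stop("negative share parameter in node ", id)
  if (abs(sum(delta) - 1) > 1e-10)
    stop("share parameters of node ", id, " must sum to 1 (got ",
         sum(delta), ")")
  if (is.null(taste)) taste <- rep(1, length(children))
  if (any(taste <= 0)) stop("taste multipliers must be positive in node ", id)
  structure(list(id = id, children = children, sigma = sigma,
                 delta = stats::setNames(as.numeric(delta), children),
                 A = A,
                 taste = stats::setNames(as.numeric(taste), children)),
            class = "ces_node")
}

# effective (taste-twisted, renormalized) shares
ces_shares <- function(node) {
  d <- node$taste * node$delta
  d / sum(d)
}

#' Calibrate a CES node to benchmark expenditures
#'
#' Standard CGE benchmark calibration: at unit prices, the share parameters
#' are the benchmark expenditure shares and the scale is the benchmark
#' composite quantity (= total expenditure at unit prices). With the returned
#' parameters, [ces_demand()] at unit prices reproduces the benchmark
#' quantities exactly.
#'
#' Children with zero benchmark expenditure cannot be calibrated and are
#' dropped with a warning (their demand is identically zero in a CES).
#'
#' @param expenditures named non-negative vector of benchmark expenditures
#'   per child, valued at unit prices.
#' @param sigma substitution elasticity.
#' @param id node id for the returned node.
#' @return a calibrated [ces_node] with `delta` = expenditure shares and
#'   `A` = total expenditure.
#' @examples
#' n <- calibrate_ces_node(c(x = 60, y = 40), sigma = 0.5)
#' n$delta   # 0.6, 0.4
#' ces_demand(n, c(x = 1, y = 1), 100)  # benchmark quantities 60, 40
#' @export
calibrate_ces_node <- function(expenditures, sigma, id = "node") {
  if (is.null(names(expenditures)))
    stop("`expenditures` must be named by child id")
  if (all(expenditures == 0))
    stop("cannot calibrate node ", id, ": all benchmark expenditures are zero")
  if (any(expenditures < 0))
    stop("negative benchmark expenditure in node ", id)
  drop <- expenditures == 0
  if (any(drop)) {
    warning("dropping zero-expenditure child(ren) of node ", id, ": ",
            paste(names(expenditures)[drop], collapse = ", "))
    expenditures <- expenditures[!drop]
  }
  ces_node(id, names(expenditures), sigma,
           delta = expenditures / sum(expenditures),
           A = sum(expenditures))
}

#' CES composite price index
#'
#' The unit-cost (dual) function of a node. At unit child prices the index is
#' 1 by calibration; it is nondecreasing and concave in each child price.
#' As \eqn{\sigma \to \infty} the index approaches the minimum child price;
#' at \eqn{\sigma = 0} it is the share-weighted mean (Leontief).
#'
#' @param node a [ces_node].
#' @param prices named (or positional) positive price vector for the
#'   children.
#' @return scalar composite price.
#' @export
ces_price_index <- function(node, prices) {
  p <- resolve_child_prices(node, prices)
  if (any(p <= 0)) stop("non-positive child price in node ", node$id)
  d <- ces_shares(node)
  s <- node$sigma
  if (abs(s - 1) < 1e-12) {
    exp(sum(d * log(p)))
  } else {
    sum(d * p^(1 - s))^(1 / (1 - s))
  }
}

#' CES demands given child prices and total expenditure
#'
#' Cost-minimizing child quantities exhausting `expenditure` (adding-up:
#' \eqn{\sum p_i q_i} = expenditure, exactly). Demands are homogeneous of
#' degree zero in prices and expenditure jointly scaled.
#'
#' @inheritParams ces_price_index
#' @param expenditure total outlay on this node, \eqn{\ge 0}.
#' @return named vector of child quantities.
#' @export
ces_demand <- function(node, prices, expenditure) {
  p <- resolve_child_prices(node, prices)
  if (any(p <= 0)) stop("non-positive child price in node ", node$id)
  stopifnot(expenditure >= 0)
  d <- ces_shares(node)
  P <- ces_price_index(node, p)
  Q <- expenditure / P
  d * (P / p)^node$sigma * Q
}

resolve_child_prices <- function(node, prices) {
  if (!is.null(names(prices))) {
    miss <- setdiff(node$children, names(prices))
    if (length(miss))
      stop("missing price(s) for child(ren) of node ", node$id, ": ",
           paste(miss, collapse = ", "))
    prices <- prices[node$children]
  } else if (length(prices) != length(node$children)) {
    stop("price vector length mismatch in node ", node$id)
  }
  stats::setNames(as.numeric(prices), node$children)
}

#' Nested CES trees
#'
#' A `nest_tree` is a set of [ces_node]s forming a tree whose leaves are SAM
#' commodity or factor ids. One tree describes each sector's production
#' technology; one describes the household's utility. Evaluation is
#' two-pass: price indices bottom-up ([tree_price_index()]), then
#' expenditures and leaf demands top-down ([tree_leaf_demand()]).
#'
#' @param root id of the root node.
#' @param nodes named list of [ces_node]s (names = node ids).
#' @param kind `"production"` or `"utility"`.
#' @param sector sector id for production trees.
#' @return an object of class `nest_tree`.
#' @export
nest_tree <- function(root, nodes, kind = c("production", "utility"),
                      sector = NULL) {
  kind <- match.arg(kind)
  if (!root %in% names(nodes)) stop("root node ", root, " not in node list")
  all_children <- unlist(lapply(nodes, `[[`, "children"), use.names = FALSE)
  dup <- all_children[duplicated(all_children)]
  if (length(dup))
    stop("duplicate leaf/child in tree ", root, ": ",
         paste(unique(dup), collapse = ", "), " appears under two nests")
  if (root %in% all_children) stop("root ", root, " cannot be a child (cycle)")
  # every non-root node id must appear exactly once as a child
  internal <- setdiff(names(nodes), root)
  orphan <- setdiff(internal, all_children)
  if (length(orphan))
    stop("node(s) not attached to tree ", root, ": ",
         paste(orphan, collapse = ", "))
  structure(list(root = root, nodes = nodes, kind = kind, sector = sector),
            class = "nest_tree")
}

#' @return `tree_leaves` returns the leaf ids of a tree.
#' @rdname nest_tree
#' @export
tree_leaves <- function(tree) {
  all_children <- unlist(lapply(tree$nodes, `[[`, "children"),
                         use.names = FALSE)
  setdiff(all_children, names(tree$nodes))
}

#' Evaluate a nest tree
#'
#' `tree_price_index` computes the composite price of every node bottom-up
#' from leaf prices. `tree_leaf_demand` then allocates a total expenditure
#' top-down, returning the leaf quantities (and, via `nodes = TRUE`, the
#' per-node expenditures). Adding-up holds at every node.
#'
#' @param tree a [nest_tree].
#' @param leaf_prices named positive price vector covering all leaves.
#' @param taste optional taste-multiplier set (named list: node id ->
#'   named multiplier vector over that node's children), as produced by
#'   [build_beef_replacement_shock()]; applied on top of the nodes' own
#'   multipliers.
#' @return `tree_price_index`: named vector of node composite prices.
#' @export
tree_price_index <- function(tree, leaf_prices, taste = NULL) {
  nodes <- apply_taste(tree, taste)
  prices <- leaf_prices
  for (nid in postorder(tree)) {
    node <- nodes[[nid]]
    prices[nid] <- ces_price_index(node, prices)
  }
  prices[names(tree$nodes)]
}

#' @param expenditure total expenditure at the root.
#' @return `tree_leaf_demand`: list with `leaf_quantities` (named vector),
#'   `node_expenditure` (named vector, incl. the root) and `node_prices`.
#' @rdname tree_price_index
#' @export
tree_leaf_demand <- function(tree, leaf_prices, expenditure, taste = NULL) {
  nodes <- apply_taste(tree, taste)
  prices <- leaf_prices
  for (nid in postorder(tree)) prices[nid] <- ces_price_index(nodes[[nid]], prices)
  expend <- stats::setNames(numeric(0), character(0))
  expend[tree$root] <- expenditure
  qty <- stats::setNames(numeric(0), character(0))
  for (nid in rev(postorder(tree))) {   # preorder: parents before children
    node <- nodes[[nid]]
    q <- ces_demand(node, prices, expend[[nid]])
    for (ch in node$children) {
      if (ch %in% names(tree$nodes)) {
        expend[ch] <- q[[ch]] * prices[[ch]]
      } else {
        qty[ch] <- q[[ch]]
      }
    }
  }
  list(leaf_quantities = qty,
       node_expenditure = expend,
       node_prices = prices[names(tree$nodes)])
}

apply_taste <- function(tree, taste) {
  nodes <- tree$nodes
  if (is.null(taste)) return(nodes)
  for (nid in names(taste)) {
    if (!nid %in% names(nodes)) next
    m <- taste[[nid]]
    node <- nodes[[nid]]
    idx <- intersect(names(m), node$children)
    node$taste[idx] <- node$taste[idx] * m[idx]
    nodes[[nid]] <- node
  }
  nodes
}

# node ids, children before parents
postorder <- function(tree) {
  out <- character(0)
  visit <- function(nid) {
    for (ch in tree$nodes[[nid]]$children)
      if (ch %in% names(tree$nodes)) visit(ch)
    out <<- c(out, nid)
  }
  visit(tree$root)
  out
}

# benchmark leaf expenditures of a tree (at unit prices): delta shares
# cascaded down from the root scale A of each node
tree_benchmark_leaf_expenditure <- function(tree) {
  root <- tree$nodes[[tree$root]]
  expend <- stats::setNames(numeric(0), character(0))
  walk <- function(nid, total) {
    node <- tree$nodes[[nid]]
    e <- node$delta * total
    for (ch in node$children) {
      if (ch %in% names(tree$nodes)) walk(ch, e[[ch]])
      else expend[ch] <<- e[[ch]]
    }
  }
  walk(tree$root, root$A)
  expend
}
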