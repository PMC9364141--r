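#' Social accounting matrices
#'
#' A social accounting matrix (SAM) records every monetary flow in an economy
#' over one year as a square matrix: rows receive, columns pay. Account kinds
#' distinguish activities (producing sectors), commodities, primary factors,
#' the household, and the external/capital accounts. A SAM is *balanced* when
#' every account's receipts (row sum) equal its outlays (column sum); a
#' balanced SAM is the benchmark a CGE model is calibrated to.
#'
#' Units are million USD per year throughout.
#'
#' @param flows square numeric matrix of non-negative flows, with
#'   `rownames`/`colnames` equal to the account ids (rows receive, columns
#'   pay).
#' @param accounts data.frame with columns `id`, `kind`, `label`; `kind` must
#'   be one of `r paste(ACCOUNT_KINDS, collapse = ", ")`.
#' @return An object of class `sam`: a list with elements `accounts`
#'   (data.frame) and `flows` (matrix).
#' @examples
#' acc <- data.frame(id = c("a_farm", "c_farm", "hh"),
#'                   kind = c("activity", "commodity", "household"),
#'                   label = c("Farming", "Farm goods", "Household"))
#' fl <- matrix(0, 3, 3, dimnames = list(acc$id, acc$id))
#' fl["a_farm", "c_farm"] <- 10; fl["c_farm", "hh"] <- 10; fl["hh", "a_farm"] <- 10
#' s <- sam(fl, acc)
#' balance_residuals(s)
#' @export
sam <- function(flows, accounts) {
  if (!is.matrix(flows) || nrow(flows) != ncol(flows))
    stop("`flows` must be a square matrix (got ", nrow(flows), " x ",
         ncol(flows), ")")
  if (is.null(rownames(flows)) || is.null(colnames(flows)))
    stop("`flows` must carry account ids as dimnames")
  if (!identical(rownames(flows), colnames(flows)))
    stop("row and column account ids differ")
  if (anyDuplicated(accounts$id))
    stop("duplicate account id: ",
         accounts$id[duplicated(accounts$id)][1L])
  if (!setequal(accounts$id, rownames(flows)) ||
      nrow(accounts) != nrow(flows))
    stop("`accounts$id` must match the flow matrix dimnames")
  bad_kind <- setdiff(unique(accounts$kind), ACCOUNT_KINDS)
  if (length(bad_kind))
    stop("unknown account kind: ", paste(bad_kind, collapse = ", "))
  neg <- which(flows < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative flow at cell [", rownames(flows)[neg[1, 1]], ", ",
         colnames(flows)[neg[1, 2]], "]: ", flows[neg[1, , drop = FALSE]])
  accounts <- accounts[match(rownames(flows), accounts$id), , drop = FALSE]
  rownames(accounts) <- NULL
  if (is.null(accounts$label)) accounts$label <- accounts$id
  structure(list(accounts = accounts, flows = flows), class = "sam")
}

#' @rdname sam
#' @export
ACCOUNT_KINDS <- c("activity", "commodity", "factor", "household",
                   "export", "import", "savings")

#' @export
print.sam <- function(x, ...) {
  cat("<sam> ", nrow(x$flows), " accounts, grand total ",
      format(sum(x$flows), big.mark = ","), " (million USD/yr)\n", sep = "")
  cat("  kinds:", paste(sprintf("%s=%d", names(table(x$accounts$kind)),
                                table(x$accounts$kind)), collapse = " "), "\n")
  res <- balance_residuals(x)
  cat("  max |row-col| imbalance:", format(max(abs(res))), "\n")
  invisible(x)
}

#' Read / write a SAM as square CSV plus an account sidecar
#'
#' The on-disk format is a square CSV (UTF-8) whose header row and first
#' column both hold the account ids, accompanied by a sidecar `accounts.csv`
#' with columns `id,kind,label`. Reading does not require balance; it only
#' validates squareness, non-negativity and known account kinds.
#'
#' @param path path of the flow CSV.
#' @param accounts_path path of the account sidecar; defaults to
#'   `accounts.csv` next to `path`.
#' @return `read_sam` returns a [sam] object; `write_sam` returns `path`
#'   invisibly. A write/read round trip reproduces the flows bit-exactly
#'   (values are serialized with 17 significant digits).
#' @export
read_sam <- function(path, accounts_path = file.path(dirname(path), "accounts.csv")) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m))
    stop("SAM file ", path, " is not square: ", nrow(m), " rows vs ",
         ncol(m), " flow columns")
  rownames(m) <- ids
  if (!identical(ids, colnames(m)))
    stop("header ids and first-column ids differ in ", path)
  acc <- utils::read.csv(accounts_path, stringsAsFactors = FALSE)
  need <- setdiff(c("id", "kind"), names(acc))
  if (length(need))
    stop("account sidecar ", accounts_path, " lacks column(s): ",
         paste(need, collapse = ", "))
  sam(m, acc)
}

#' @param x a [sam] object.
#' @rdname read_sam
#' @export
write_sam <- function(x, path, accounts_path = file.path(dirname(path), "accounts.csv")) {
  stopifnot(inherits(x, "sam"))
  df <- data.frame(id = rownames(x$flows),
                   format(x$flows, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  names(df)[1L] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(x$accounts, accounts_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-account balance residuals
#'
#' For each account, receipts minus outlays (row sum minus column sum).
#' A SAM is balanced iff the residual vector is (numerically) zero. The
#' residuals always sum to zero exactly in exact arithmetic: every flow
#' enters one row sum and one column sum.
#'
#' @param x a [sam] object.
#' @return named numeric vector, currency units.
#' @export
balance_residuals <- function(x) {
  stopifnot(inherits(x, "sam"))
  rowSums(x$flows) - colSums(x$flows)
}

#' Is a SAM balanced?
#'
#' Relative tolerance: default `1e-6` times the grand total, since SAM cells
#' span many orders of magnitude.
#'
#' @param x a [sam] object.
#' @param tol relative tolerance (fraction of the grand total of flows).
#' @export
is_balanced <- function(x, tol = 1e-6) {
  max(abs(balance_residuals(x))) <= tol * sum(x$flows)
}

#' RAS (biproportional) balancing
#'
#' Alternately scales rows and columns of the flow matrix so that its margins
#' hit `row_targets` / `col_targets`. Structural zeros are preserved: a zero
#' cell can never become positive under row/column scaling, so the sparsity
#' pattern — which the CES nesting depends on — is invariant.
#'
#' @param x a [sam] object.
#' @param row_targets,col_targets positive targets where the corresponding
#'   margin has support; their totals must agree within `tol` (relative).
#' @param tol relative convergence tolerance on the margins.
#' @param max_iter iteration cap.
#' @return a balanced-to-target [sam]; attribute `iterations` records the
#'   count.
#' @export
ras_balance <- function(x, row_targets = NULL, col_targets = NULL,
                        tol = 1e-9, max_iter = 10000L) {
  stopifnot(inherits(x, "sam"))
  m <- x$flows
  n <- nrow(m)
  if (is.null(row_targets)) row_targets <- rowSums(m)
  if (is.null(col_targets)) col_targets <- colSums(m)
  row_targets <- rep_len(row_targets, n)
  col_targets <- rep_len(col_targets, n)
  tot <- sum(row_targets)
  if (abs(tot - sum(col_targets)) > tol * max(tot, 1))
    stop("row targets total (", tot, ") and column targets total (",
         sum(col_targets), ") disagree")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(row_targets > 0 & rs == 0) || any(col_targets > 0 & cs == 0))
    stop("infeasible support pattern: positive target on an all-zero margin (",
         paste(rownames(m)[row_targets > 0 & rs == 0], collapse = ", "), " ",
         paste(colnames(m)[col_targets > 0 & cs == 0], collapse = ", "), ")")
  scale_tol <- tol * max(tot, 1)
  it <- 0L
  repeat {
    rs <- rowSums(m)
    r <- ifelse(rs > 0, row_targets / rs, 1)
    m <- m * r
    cs <- colSums(m)
    s <- ifelse(cs > 0, col_targets / cs, 1)
    m <- sweep(m, 2L, s, `*`)
    it <- it + 1L
    err <- max(abs(rowSums(m) - row_targets), abs(colSums(m) - col_targets))
    if (err <= scale_tol) break
    if (it >= max_iter)
      stop("RAS failed to converge in ", max_iter,
           " iterations; last margin residual ", format(err))
  }
  out <- sam(m, x$accounts)
  attr(out, "iterations") <- it
  out
}

#' Aggregate SAM accounts
#'
#' Sums flows into merged accounts under a total mapping of old ids to new
#' ids. Only accounts of the same kind may merge; the grand total of flows is
#' conserved exactly, and the balance residual of a merged account equals the
#' sum of its constituents' residuals (aggregation commutes with the
#' accounting identities).
#'
#' @param x a [sam] object.
#' @param mapping named character vector: `names(mapping)` are existing
#'   account ids (all of them), values the new ids.
#' @param labels optional named character vector of labels for new ids.
#' @return the aggregated [sam].
#' @export
aggregate_accounts <- function(x, mapping, labels = NULL) {
  stopifnot(inherits(x, "sam"))
  ids <- x$accounts$id
  missing_ids <- setdiff(ids, names(mapping))
  if (length(missing_ids))
    stop("mapping is not total; unmapped account(s): ",
         paste(missing_ids, collapse = ", "))
  new_of <- mapping[ids]
  kinds <- split(x$accounts$kind, new_of)
  mixed <- names(kinds)[vapply(kinds, function(k) length(unique(k)) > 1L, TRUE)]
  if (length(mixed))
    stop("mapping merges accounts of different kinds into: ",
         paste(mixed, collapse = ", "))
  new_ids <- unique(unname(new_of))
  agg <- matrix(0, length(new_ids), length(new_ids),
                dimnames = list(new_ids, new_ids))
  g <- factor(new_of, levels = new_ids)
  # sum rows within groups, then columns
  rsum <- rowsum(x$flows, g)
  agg <- t(rowsum(t(rsum), g))
  acc <- data.frame(id = new_ids,
                    kind = vapply(kinds[new_ids], `[`, "", 1L),
                    label = if (is.null(labels)) new_ids
                            else ifelse(new_ids %in% names(labels),
                                        labels[new_ids], new_ids),
                    stringsAsFactors = FALSE)
  sam(agg[new_ids, new_ids, drop = FALSE], acc)
}

# ids of accounts of a given kind
accounts_of_kind <- function(x, kind) {
  x$accounts$id[x$accounts$kind == kind]
}
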