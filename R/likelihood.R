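#' Per-branch message for a pendant branch
#'
#' Tabulates, at every node `tau_s` of the time grid, the probability that a
#' branch starting at `tau_s` ends in a single sampled cell at the
#' observation time carrying `m` mutations:
#' \deqn{P(\nu\mid\tau_s) = \rho \sum_{i=0}^{i_{max}}
#'   P(m\mid i)\, p_1^{(\rho)}(i\mid\tau_s, 0).}
#'
#' @param m Non-negative integer mutation count of the branch.
#' @param grid A [time_grid()].
#' @param params A [model_params()] object.
#' @param i_max Generation-sum truncation (default [default_i_max()]).
#' @return A `divphy_message`: list with `log_values` (log probabilities at
#'   the grid nodes) and the grid.
#' @export
pendant_message <- function(m, grid, params, i_max = default_i_max(params$rho)) {
  params <- as_params(params)
  grid <- as_grid(grid)
  check_m_scalar(m)
  lv <- cpp_pendant_logmsg(as.integer(m), grid$nodes, params$q, params$mu,
                           params$rho, as.integer(i_max))
  new_message(lv, grid)
}

#' Per-branch message for an internal branch
#'
#' Combines the messages of the two child branches by integrating over the
#' branch end time `tau_e` (trapezoidal rule over the grid nodes below
#' `tau_s`) and summing over the hidden generation count:
#' \deqn{P(\nu\mid\tau_s) = \sum_i \int_0^{\tau_s} d\tau_e\,
#'   P(m\mid i)\, p_1^{(\rho)}(i\mid\tau_s,\tau_e)\,
#'   2 P(\nu'\mid\tau_e) P(\nu''\mid\tau_e).}
#' The factor two accounts for the exchangeable labelling of the two
#' daughter clades.
#'
#' @inheritParams pendant_message
#' @param child_a,child_b Messages of the two child branches, tabulated on
#'   the same grid.
#' @return A `divphy_message`.
#' @export
internal_message <- function(m, child_a, child_b, grid, params,
                             i_max = default_i_max(params$rho)) {
  params <- as_params(params)
  grid <- as_grid(grid)
  check_m_scalar(m)
  check_same_grid(child_a, child_b, grid)
  lv <- cpp_internal_logmsg(as.integer(m), child_a$log_values,
                            child_b$log_values, grid$nodes, params$q,
                            params$mu, params$rho, as.integer(i_max))
  new_message(lv, grid)
}

#' Log-likelihood of a mutation-annotated tree
#'
#' Evaluates the model likelihood by post-order message passing: pendant
#' messages from the closed-form generation distribution, internal messages
#' by quadrature over branch end times, and finally integration over the
#' (uniform-prior, truncated) time of origin:
#' \deqn{L(q,\mu) = \int_0^{T} d\tau_s\, 2 P(\nu'\mid\tau_s) P(\nu''\mid\tau_s),}
#' where \eqn{\nu', \nu''} are the two branches emanating from the most
#' recent common ancestor and `T` is the grid upper bound.
#'
#' @param tree A `phylo`/[as_mutation_tree()] tree with integer mutation
#'   counts as branch lengths.
#' @param params A [model_params()] object.
#' @param grid A [time_grid()]; by default `[0, 2 log(n_tips/rho)/(1-q)]`
#'   divided into `n_subintervals` steps.
#' @param i_max Generation-sum truncation (default [default_i_max()]).
#' @param n_subintervals Grid resolution used when `grid` is `NULL`.
#' @param n_tips_for_bound Tip count used for the default grid upper bound
#'   (defaults to the tree's own tip count; multi-clade analyses pass the
#'   full-tree count for a shared time scale).
#' @return The log-likelihood (scalar; `-Inf` if the data have probability
#'   zero under the parameters, e.g. mutations with `mu = 0`).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:2):1,C:3);")
#' tree_log_likelihood(tr, model_params(q = 0.5, mu = 1),
#'                     n_subintervals = 100)
#' @export
tree_log_likelihood <- function(tree, params, grid = NULL,
                                i_max = default_i_max(params$rho),
                                n_subintervals = 1000L,
                                n_tips_for_bound = NULL) {
  params <- as_params(params)
  tree <- as_mutation_tree(tree)
  if (is.null(grid)) {
    grid <- default_grid(tree, params, n_subintervals, n_tips_for_bound)
  }
  grid <- as_grid(grid)
  lay <- tree_dp_layout(tree)
  ll <- cpp_tree_loglik(lay$order, lay$children, lay$edge_m, lay$ntip,
                        grid$nodes, params$q, params$mu, params$rho,
                        as.integer(i_max))
  if (!is.finite(ll) && is.na(ll)) stop("likelihood evaluation failed", call. = FALSE)
  ll
}

#' Log-likelihood under the constant-rate molecular clock
#'
#' Comparison model in which mutations accrue in calendar time: the
#' per-branch factor is `Pois(m; mu_t * (tau_s - tau_e))` times the
#' probability that the branch window is bridged by a lineage none of whose
#' side offspring are sampled ([sum_p1_over_generations()]). The tree-level
#' recursion and origin-time prior are identical to
#' [tree_log_likelihood()], so the two models are directly comparable at a
#' fixed grid policy.
#'
#' @inheritParams tree_log_likelihood
#' @param params A [clock_params()] object.
#' @return The log-likelihood (scalar).
#' @export
clock_tree_log_likelihood <- function(tree, params, grid = NULL,
                                      n_subintervals = 1000L,
                                      n_tips_for_bound = NULL) {
  if (!inherits(params, "divphy_clock_params")) {
    stop("'params' must be created with clock_params()", call. = FALSE)
  }
  tree <- as_mutation_tree(tree)
  if (is.null(grid)) {
    grid <- default_grid(tree, params, n_subintervals, n_tips_for_bound)
  }
  grid <- as_grid(grid)
  lay <- tree_dp_layout(tree)
  cpp_clock_tree_loglik(lay$order, lay$children, lay$edge_m, lay$ntip,
                        grid$nodes, params$q, params$mu_t, params$rho)
}

#' Dump per-branch messages for debugging
#'
#' Recomputes all messages of a tree and writes them as a TSV with columns
#' `branch` (child-node id of the branch), `tau_s` (grid node) and
#' `log_value`.
#'
#' @inheritParams tree_log_likelihood
#' @param path Output TSV path.
#' @return Invisibly, the data frame written.
#' @export
dump_messages <- function(tree, params, path, grid = NULL,
                          i_max = default_i_max(params$rho),
                          n_subintervals = 200L) {
  params <- as_params(params)
  tree <- as_mutation_tree(tree)
  if (is.null(grid)) grid <- default_grid(tree, params, n_subintervals)
  lay <- tree_dp_layout(tree)
  msgs <- vector("list", lay$ntip + length(lay$order))
  for (nd in seq_len(lay$ntip)) {
    msgs[[nd]] <- pendant_message(lay$edge_m[nd], grid, params, i_max)
  }
  rows <- list()
  for (nd in lay$order) {
    ch <- lay$children[nd - lay$ntip, ]
    if (nd != lay$root) {
      msgs[[nd]] <- internal_message(lay$edge_m[nd], msgs[[ch[1]]],
                                     msgs[[ch[2]]], grid, params, i_max)
    }
  }
  keep <- which(!vapply(msgs, is.null, logical(1)))
  df <- do.call(rbind, lapply(keep, function(nd) {
    data.frame(branch = nd, tau_s = grid$nodes,
               log_value = msgs[[nd]]$log_values)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

new_message <- function(log_values, grid) {
  structure(list(log_values = log_values, grid = grid),
            class = "divphy_message")
}

#' @export
print.divphy_message <- function(x, ...) {
  cat(sprintf("Branch message on %d grid nodes; max log value %.4g\n",
              length(x$log_values), max(x$log_values)))
  invisible(x)
}

check_m_scalar <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || m < 0 || m != floor(m)) {
    stop("'m' must be a single non-negative integer", call. = FALSE)
  }
  invisible(TRUE)
}

check_same_grid <- function(a, b, grid) {
  if (!inherits(a, "divphy_message") || !inherits(b, "divphy_message")) {
    stop("child messages must be 'divphy_message' objects", call. = FALSE)
  }
  if (length(a$log_values) != length(grid$nodes) ||
      length(b$log_values) != length(grid$nodes) ||
      !isTRUE(all.equal(a$grid$nodes, grid$nodes)) ||
      !isTRUE(all.equal(b$grid$nodes, grid$nodes))) {
    stop("child messages are tabulated on a different grid", call. = FALSE)
  }
  invisible(TRUE)
}
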