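#' Select postnatal clades from a mutation-annotated tree
#'
#' Returns the maximal clades whose root node lies strictly more than
#' `min_root_mutations` mutations from the tree root (taken as evidence the
#' clade arose after birth of the donor) and which contain at least
#' `min_leaves` sampled cells. Maximality makes the returned clades
#' disjoint: a qualifying node with a qualifying ancestor is subsumed by it.
#'
#' @param tree A `phylo`/[as_mutation_tree()] tree.
#' @param min_root_mutations Strict mutation-distance threshold (default
#'   100).
#' @param min_leaves Minimum clade size in sampled cells (default 23, i.e.
#'   45 nodes in a binary clade).
#' @return A list of clades (`phylo` subtrees via [ape::extract.clade()]),
#'   with a `data.frame` attribute `"info"` holding `node`, `root_distance`
#'   and `n_leaves`; clades are ordered by tree traversal.
#' @export
select_postnatal_clades <- function(tree, min_root_mutations = 100,
                                    min_leaves = 23) {
  tree <- as_mutation_tree(tree)
  ntip <- length(tree$tip.label)
  dist <- node_root_distance(tree)
  sizes <- node_tip_counts(tree)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  qualifying <- internal[dist[internal] > min_root_mutations &
                           sizes[internal] >= min_leaves]
  if (!length(qualifying)) {
    out <- list()
    attr(out, "info") <- data.frame(node = integer(0),
                                    root_distance = numeric(0),
                                    n_leaves = integer(0))
    return(out)
  }
  # drop nodes with a qualifying ancestor (maximality)
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  is_max <- vapply(qualifying, function(nd) {
    p <- parent_of[nd]
    while (p != 0L) {
      if (p %in% qualifying) return(FALSE)
      p <- parent_of[p]
    }
    TRUE
  }, logical(1))
  keep <- sort(qualifying[is_max])
  clades <- lapply(keep, function(nd) {
    cl <- ape::extract.clade(tree, nd)
    class(cl) <- c("mutation_tree", "phylo")
    cl
  })
  attr(clades, "info") <- data.frame(
    node = keep,
    root_distance = dist[keep],
    n_leaves = sizes[keep]
  )
  clades
}

#' Likelihood-ratio test for clade-specific parameters
#'
#' Compares a homogeneous model, in which all clades share one parameter
#' pair `(q, mu)`, against a heterogeneous model in which one focal clade
#' has its own pair `(q_dist, mu_dist)` while the remaining clades share
#' `(q_main, mu_main)`. Clades are analyzed independently (each has its own
#' origin-time integral), so the heterogeneous likelihood factorizes and the
#' two blocks are optimized separately; both fits use the same grid policy
#' (a shared upper bound from `n_tips_for_bound`), which guarantees the
#' models are nested numerically. The statistic
#' \deqn{\lambda_{LR} = -2(\max\log L_{hom} - \max\log L_{het})}
#' is referred to a chi-squared distribution with 2 degrees of freedom (the
#' number of extra parameters).
#'
#' @param clades List of at least two mutation-annotated clades (e.g. from
#'   [select_postnatal_clades()]).
#' @param focal Index of the clade given distinct parameters.
#' @param rho Shared sampling probability.
#' @param n_tips_for_bound Tip count fixing the shared grid upper bound
#'   (default: total tips over the clades; pass the full-tree tip count when
#'   the clades come from one larger tree).
#' @param ... Further arguments passed to [fit_mle()] (grid resolution,
#'   coarse settings, ...).
#' @return An object of class `divphy_lrt` with the homogeneous and
#'   heterogeneous fits, `lambda_LR`, `df = 2` and `p_value`.
#' @export
heterogeneity_test <- function(clades, focal, rho = 1,
                               n_tips_for_bound = NULL, ...) {
  if (!is.list(clades) || length(clades) < 2L) {
    stop("need at least two clades", call. = FALSE)
  }
  if (focal < 1L || focal > length(clades)) {
    stop("'focal' out of range", call. = FALSE)
  }
  clades <- normalize_tree_list(clades)
  if (is.null(n_tips_for_bound)) {
    n_tips_for_bound <- sum(vapply(clades, function(tr) length(tr$tip.label), 1L))
  }
  hom <- fit_mle(clades, rho = rho, n_tips_for_bound = n_tips_for_bound, ...)
  hom_start <- c(hom$params$q, hom$params$mu)
  fit_main <- fit_mle(clades[-focal], rho = rho,
                      n_tips_for_bound = n_tips_for_bound,
                      start = hom_start, ...)
  fit_dist <- fit_mle(clades[focal], rho = rho,
                      n_tips_for_bound = n_tips_for_bound,
                      start = hom_start, ...)
  ll_het <- fit_main$log_likelihood + fit_dist$log_likelihood
  lambda <- -2 * (hom$log_likelihood - ll_het)
  p <- pchisq(lambda, df = 2, lower.tail = FALSE)
  structure(
    list(
      focal = focal,
      homogeneous = hom,
      main = fit_main,
      distinct = fit_dist,
      lambda_LR = lambda,
      df = 2L,
      p_value = p
    ),
    class = "divphy_lrt"
  )
}

#' @export
print.divphy_lrt <- function(x, ...) {
  cat(sprintf("Clade-heterogeneity likelihood-ratio test (focal clade %d)\n",
              x$focal))
  cat(sprintf("  homogeneous : q = %.3f, mu = %.3f, log L = %.3f\n",
              x$homogeneous$params$q, x$homogeneous$params$mu,
              x$homogeneous$log_likelihood))
  cat(sprintf("  main clades : q = %.3f, mu = %.3f\n",
              x$main$params$q, x$main$params$mu))
  cat(sprintf("  focal clade : q = %.3f, mu = %.3f\n",
              x$distinct$params$q, x$distinct$params$mu))
  cat(sprintf("  lambda_LR = %.4f, df = %d, p = %.4g\n",
              x$lambda_LR, x$df, x$p_value))
  invisible(x)
}

#' Bonferroni selection of significant heterogeneity scenarios
#'
#' Given likelihood-ratio results for several single-clade heterogeneity
#' scenarios, returns those whose p-value falls below the Bonferroni
#' corrected threshold `alpha / n_scenarios`.
#'
#' @param results A list of [heterogeneity_test()] results, or a numeric
#'   vector of p-values.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Integer indices of the accepted scenarios.
#' @export
bonferroni_select <- function(results, alpha = 0.05) {
  if (!length(results)) return(integer(0))
  p <- if (is.numeric(results)) {
    results
  } else {
    vapply(results, function(r) {
      if (!inherits(r, "divphy_lrt")) stop("expected divphy_lrt results",
                                           call. = FALSE)
      r$p_value
    }, numeric(1))
  }
  which(p < alpha / length(p))
}
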