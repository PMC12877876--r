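#' Read a mutation-annotated tree from a Newick file
#'
#' The Newick branch-length field carries the integer mutation count of each
#' branch (calendar time is latent and never appears in files). Non-integer
#' lengths are rounded with a warning, negative lengths are an error, and
#' multifurcations are resolved into consecutive zero-mutation divisions
#' (see [as_mutation_tree()]).
#'
#' @param path Path to a Newick file.
#' @return A `mutation_tree`.
#' @export
read_mutation_tree <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop(sprintf("could not parse Newick file: %s", path),
                        call. = FALSE)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  as_mutation_tree(tr)
}

#' Write a mutation-annotated tree as Newick
#'
#' Branch lengths are written as exact integers, so a write/read round trip
#' preserves topology and mutation counts bit for bit. Optionally writes a
#' TSV sidecar with the per-branch simulation truth (duration and hidden
#' division count) when present.
#'
#' @param tree A `mutation_tree` (or `phylo` with integer branch lengths).
#' @param path Output Newick path.
#' @param truth_path Optional path for the truth sidecar TSV (columns
#'   `parent`, `child`, `mutations`, `duration`, `generations`).
#' @return Invisibly, `path`.
#' @export
write_mutation_tree <- function(tree, path, truth_path = NULL) {
  tree <- as_mutation_tree(tree)
  tree$edge.length <- round(tree$edge.length)
  ape::write.tree(tree, file = path)
  if (!is.null(truth_path)) {
    if (is.null(tree$edge_duration) || is.null(tree$edge_generations)) {
      stop("tree carries no simulation truth annotations", call. = FALSE)
    }
    truth <- data.frame(
      parent = tree$edge[, 1L],
      child = tree$edge[, 2L],
      mutations = tree$edge.length,
      duration = tree$edge_duration,
      generations = tree$edge_generations
    )
    write.table(truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Write a maximum-likelihood fit as JSON
#'
#' Serializes the fitted parameters, log-likelihood and every setting
#' needed to reproduce the fit (grid resolution, generation cap, bounds,
#' package version, optional seed).
#'
#' @param fit A [fit_mle()] result.
#' @param path Output JSON path.
#' @param seed Optional seed to record in the provenance block.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path, seed = NULL) {
  if (!inherits(fit, "divphy_fit")) stop("'fit' must be a divphy_fit",
                                         call. = FALSE)
  payload <- list(
    model = fit$settings$model,
    params = unclass(fit$params),
    log_likelihood = fit$log_likelihood,
    convergence = fit$convergence,
    n_evaluations = nrow(fit$trace),
    settings = fit$settings,
    provenance = list(
      package = "divphy",
      version = as.character(utils::packageVersion("divphy")),
      seed = seed
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back a fit JSON
#'
#' @param path Path written by [write_fit_json()].
#' @return The deserialized list.
#' @export
read_fit_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a likelihood landscape as TSV
#'
#' Long format with one row per `(q, mu)` grid point: columns `q`, `mu`,
#' `log_likelihood` (masked values are `NA`).
#'
#' @param landscape A [likelihood_landscape()] matrix.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_landscape_tsv <- function(landscape, path) {
  qv <- as.numeric(rownames(landscape))
  mv <- as.numeric(colnames(landscape))
  df <- data.frame(
    q = rep(qv, times = length(mv)),
    mu = rep(mv, each = length(qv)),
    log_likelihood = as.vector(landscape)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tabulate heterogeneity-test results
#'
#' Builds the standard result table with one row per focal-clade scenario:
#' columns `clade`, `lambda_LR`, `p_value`, `q_main`, `mu_main`, `q_sub`,
#' `mu_sub` (the focal clade's distinct parameters).
#'
#' @param results List of [heterogeneity_test()] results.
#' @return A `data.frame`.
#' @export
lrt_table <- function(results) {
  if (!length(results)) {
    return(data.frame(clade = integer(0), lambda_LR = numeric(0),
                      p_value = numeric(0), q_main = numeric(0),
                      mu_main = numeric(0), q_sub = numeric(0),
                      mu_sub = numeric(0)))
  }
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      clade = r$focal,
      lambda_LR = r$lambda_LR,
      p_value = r$p_value,
      q_main = r$main$params$q,
      mu_main = r$main$params$mu,
      q_sub = r$distinct$params$q,
      mu_sub = r$distinct$params$mu
    )
  }))
}

#' Write the heterogeneity-test table as TSV
#'
#' @param results List of [heterogeneity_test()] results (or a ready
#'   [lrt_table()] data frame).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_lrt_tsv <- function(results, path) {
  tab <- if (is.data.frame(results)) results else lrt_table(results)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
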