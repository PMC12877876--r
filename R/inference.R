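#' Maximum-likelihood fit of the division-coupled mutation model
#'
#' Maximizes the summed log-likelihood of one or more mutation-annotated
#' trees over `(q, mu)` at fixed sampling probability `rho` (or over
#' `(q, mu_t)` for the molecular-clock comparison model). The optimizer runs
#' a coarse grid scan (optionally at reduced grid resolution) followed by
#' Nelder-Mead refinement at full resolution; because the grid upper bound
#' `2 log(N/rho)/(1-q)` depends on `q`, the time grid is rebuilt at every
#' parameter point. The boundary `q = 0` is permitted.
#'
#' @param trees A `phylo` tree or list of trees (clades are treated as
#'   independent, each with its own origin-time integral).
#' @param rho Sampling probability (fixed during the fit).
#' @param model `"division"` (default) or `"clock"`.
#' @param n_subintervals Grid resolution for refinement evaluations.
#' @param i_max Generation-sum truncation (division model).
#' @param q_bounds Search box for `q` (default `c(0, 0.98)`).
#' @param mu_bounds Search box for the mutation parameter; by default
#'   `(1e-4, 2 * mean branch mutation count + 2)`, which always contains the
#'   MLE since the mean count per branch is at least `mu`.
#' @param coarse_n Number of coarse-scan points per axis (default 7).
#' @param coarse_subintervals Grid resolution for the coarse scan (default
#'   `min(n_subintervals, 100)`).
#' @param start Optional `c(q, mu)` used as an additional Nelder-Mead start.
#' @param n_tips_for_bound Tip count fixing the grid upper bound (default:
#'   total tips over `trees`; multi-clade analyses of one tree pass the
#'   full-tree tip count).
#' @param control Passed to [stats::optim()] (Nelder-Mead stage).
#' @return An object of class `divphy_fit`: `params` (fitted parameter
#'   object), `log_likelihood`, `trace` (all evaluations), `settings`,
#'   `convergence`.
#' @examples
#' \donttest{
#' tr <- simulate_mutation_tree(60, model_params(q = 0.5, mu = 1), seed = 1)
#' fit_mle(tr, rho = 1, n_subintervals = 100)
#' }
#' @export
fit_mle <- function(trees, rho = 1, model = c("division", "clock"),
                    n_subintervals = 1000L, i_max = default_i_max(rho),
                    q_bounds = c(0, 0.98), mu_bounds = NULL,
                    coarse_n = 7L, coarse_subintervals = NULL,
                    start = NULL, n_tips_for_bound = NULL,
                    control = list(maxit = 200L, reltol = 1e-6)) {
  model <- match.arg(model)
  trees <- normalize_tree_list(trees)
  if (is.null(n_tips_for_bound)) {
    n_tips_for_bound <- sum(vapply(trees, function(tr) length(tr$tip.label), 1L))
  }
  layouts <- lapply(trees, tree_dp_layout)
  mean_m <- mean(unlist(lapply(trees, function(tr) tr$edge.length)))
  if (is.null(mu_bounds)) mu_bounds <- c(1e-4, max(2 * mean_m + 2, 2))
  if (is.null(coarse_subintervals)) {
    coarse_subintervals <- min(n_subintervals, 100L)
  }

  trace <- list()
  objective <- function(q, mu, subint, stage) {
    grid <- time_grid(2 * log(n_tips_for_bound / rho) / (1 - q), subint)
    ll <- 0
    for (lay in layouts) {
      ll <- ll + if (model == "division") {
        cpp_tree_loglik(lay$order, lay$children, lay$edge_m, lay$ntip,
                        grid$nodes, q, mu, rho, as.integer(i_max))
      } else {
        cpp_clock_tree_loglik(lay$order, lay$children, lay$edge_m, lay$ntip,
                              grid$nodes, q, mu, rho)
      }
      if (!is.finite(ll)) break
    }
    trace[[length(trace) + 1L]] <<- data.frame(
      stage = stage, q = q, mu = mu, log_likelihood = ll
    )
    ll
  }

  # coarse scan
  qs <- seq(q_bounds[1], q_bounds[2], length.out = coarse_n)
  mus <- seq(mu_bounds[1], mu_bounds[2], length.out = coarse_n)
  best <- c(NA_real_, NA_real_)
  best_ll <- -Inf
  for (qq in qs) for (mm in mus) {
    ll <- objective(qq, mm, coarse_subintervals, "coarse")
    if (is.finite(ll) && ll > best_ll) {
      best_ll <- ll
      best <- c(qq, mm)
    }
  }
  starts <- list(best)
  if (!is.null(start)) starts <- c(starts, list(as.numeric(start)))
  starts <- Filter(function(s) all(is.finite(s)), starts)
  if (!length(starts)) {
    stop("log-likelihood is -Inf over the whole coarse grid; check the data",
         call. = FALSE)
  }

  # Nelder-Mead refinement at full resolution, box enforced by clamping
  # with a quadratic pull-back penalty
  penalized <- function(par) {
    qc <- min(max(par[1], q_bounds[1]), q_bounds[2])
    mc <- min(max(par[2], mu_bounds[1]), mu_bounds[2])
    pen <- (par[1] - qc)^2 + (par[2] - mc)^2
    ll <- objective(qc, mc, n_subintervals, "refine")
    if (!is.finite(ll)) return(1e12)
    -ll + 1e6 * pen
  }
  best_fit <- NULL
  for (s in starts) {
    opt <- optim(s, penalized, method = "Nelder-Mead", control = control)
    if (is.null(best_fit) || opt$value < best_fit$value) best_fit <- opt
  }
  qhat <- min(max(best_fit$par[1], q_bounds[1]), q_bounds[2])
  muhat <- min(max(best_fit$par[2], mu_bounds[1]), mu_bounds[2])
  ll_hat <- objective(qhat, muhat, n_subintervals, "final")
  trace_df <- do.call(rbind, trace)
  # guard: never return worse than the best point ever evaluated at full
  # resolution (Nelder-Mead cannot deteriorate, but clamping could)
  ref <- trace_df[trace_df$stage %in% c("refine", "final"), ]
  ix <- which.max(ref$log_likelihood)
  if (ref$log_likelihood[ix] > ll_hat) {
    qhat <- ref$q[ix]; muhat <- ref$mu[ix]; ll_hat <- ref$log_likelihood[ix]
  }
  params_hat <- if (model == "division") {
    model_params(qhat, muhat, rho)
  } else {
    clock_params(qhat, muhat, rho)
  }
  structure(
    list(
      params = params_hat,
      log_likelihood = ll_hat,
      trace = trace_df,
      settings = list(
        model = model, rho = rho, n_subintervals = n_subintervals,
        i_max = if (model == "division") i_max else NA_integer_,
        coarse_n = coarse_n, coarse_subintervals = coarse_subintervals,
        q_bounds = q_bounds, mu_bounds = mu_bounds,
        n_tips_for_bound = n_tips_for_bound, n_trees = length(trees)
      ),
      convergence = best_fit$convergence
    ),
    class = "divphy_fit"
  )
}

#' @export
print.divphy_fit <- function(x, ...) {
  lab <- if (x$settings$model == "division") "mu " else "mu_t"
  val <- if (x$settings$model == "division") x$params$mu else x$params$mu_t
  cat(sprintf("Maximum-likelihood fit (%s model, %d tree%s)\n",
              x$settings$model, x$settings$n_trees,
              if (x$settings$n_trees == 1L) "" else "s"))
  cat(sprintf("  q-hat    = %.4f\n", x$params$q))
  cat(sprintf("  %s-hat = %.4f\n", lab, val))
  cat(sprintf("  log L    = %.4f  (%d evaluations)\n",
              x$log_likelihood, nrow(x$trace)))
  invisible(x)
}

#' Log-likelihood landscape over a parameter grid
#'
#' Evaluates the (summed) log-likelihood at every combination of `q_values`
#' and `mu_values`. Values below `floor` are masked to `NA` (the display
#' convention used for landscape heat maps).
#'
#' @inheritParams fit_mle
#' @param q_values,mu_values Parameter grids (non-empty).
#' @param floor Optional masking floor for low log-likelihoods.
#' @return A numeric matrix (`length(q_values)` rows, `length(mu_values)`
#'   columns) with dimnames, classed `divphy_landscape`.
#' @export
likelihood_landscape <- function(trees, rho = 1, q_values, mu_values,
                                 model = c("division", "clock"),
                                 n_subintervals = 1000L,
                                 i_max = default_i_max(rho),
                                 n_tips_for_bound = NULL, floor = NULL) {
  model <- match.arg(model)
  if (!length(q_values) || !length(mu_values)) {
    stop("'q_values' and 'mu_values' must be non-empty", call. = FALSE)
  }
  trees <- normalize_tree_list(trees)
  if (is.null(n_tips_for_bound)) {
    n_tips_for_bound <- sum(vapply(trees, function(tr) length(tr$tip.label), 1L))
  }
  layouts <- lapply(trees, tree_dp_layout)
  out <- matrix(NA_real_, length(q_values), length(mu_values),
                dimnames = list(q = signif(q_values, 8),
                                mu = signif(mu_values, 8)))
  for (a in seq_along(q_values)) {
    q <- q_values[a]
    grid <- time_grid(2 * log(n_tips_for_bound / rho) / (1 - q),
                      n_subintervals)
    for (b in seq_along(mu_values)) {
      ll <- 0
      for (lay in layouts) {
        ll <- ll + if (model == "division") {
          cpp_tree_loglik(lay$order, lay$children, lay$edge_m, lay$ntip,
                          grid$nodes, q, mu_values[b], rho,
                          as.integer(i_max))
        } else {
          cpp_clock_tree_loglik(lay$order, lay$children, lay$edge_m,
                                lay$ntip, grid$nodes, q, mu_values[b], rho)
        }
        if (!is.finite(ll)) break
      }
      out[a, b] <- ll
    }
  }
  if (!is.null(floor)) out[out < floor] <- NA_real_
  class(out) <- c("divphy_landscape", class(out))
  out
}

normalize_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!is.list(trees) || !length(trees) ||
      !all(vapply(trees, inherits, logical(1), "phylo"))) {
    stop("'trees' must be a phylo object or a non-empty list of them",
         call. = FALSE)
  }
  lapply(trees, as_mutation_tree)
}
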