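#' Default upper bound for the time of origin of a tree
#'
#' The improper uniform prior over the origin time of a tree is truncated at
#' twice the expected age of a tree of `n_tips` sampled cells, i.e. at
#' `2 log(n_tips / rho) / (1 - q)`. Under complete sampling (`rho = 1`) this
#' reduces to `2 log(N) / (1 - q)`. Time runs backwards from the observation
#' (observation = 0), in units of the inverse division rate.
#'
#' @param n_tips Number of sampled cells (tree tips), at least 2.
#' @param params A [model_params()] or [clock_params()] object (only `q` and
#'   `rho` are used).
#' @return The upper truncation time (a positive scalar).
#' @examples
#' default_upper_bound(300, model_params(q = 0.75, mu = 1))  # 8 log 300
#' @export
default_upper_bound <- function(n_tips, params) {
  if (!is.numeric(n_tips) || length(n_tips) != 1L || n_tips < 2) {
    stop("'n_tips' must be a single number >= 2", call. = FALSE)
  }
  q <- params$q
  rho <- params$rho
  if (is.null(q) || is.null(rho)) stop("invalid 'params'", call. = FALSE)
  if (q >= 1 || rho <= 0) stop("require q < 1 and rho > 0", call. = FALSE)
  2 * log(n_tips / rho) / (1 - q)
}

#' Uniform time grid for the likelihood quadrature
#'
#' All quadrature over latent branch times uses a shared uniform grid of
#' `n_subintervals + 1` nodes spanning `[0, upper_bound]`, with node 0 at the
#' observation time and the last node at the truncated origin-time bound.
#'
#' @param upper_bound Positive calendar-time bound (backwards from
#'   observation).
#' @param n_subintervals Number of equal subintervals (default 1000).
#' @return An object of class `divphy_grid` with elements `nodes`,
#'   `upper_bound`, `n_subintervals`, `dt`.
#' @export
time_grid <- function(upper_bound, n_subintervals = 1000L) {
  check_scalar(upper_bound, "upper_bound")
  if (upper_bound <= 0) stop("'upper_bound' must be > 0", call. = FALSE)
  n_subintervals <- as.integer(n_subintervals)
  if (is.na(n_subintervals) || n_subintervals < 1L) {
    stop("'n_subintervals' must be a positive integer", call. = FALSE)
  }
  nodes <- seq(0, upper_bound, length.out = n_subintervals + 1L)
  structure(
    list(
      nodes = nodes,
      upper_bound = upper_bound,
      n_subintervals = n_subintervals,
      dt = upper_bound / n_subintervals
    ),
    class = "divphy_grid"
  )
}

#' @export
print.divphy_grid <- function(x, ...) {
  cat(sprintf(
    "Time grid: [0, %g] in %d subintervals (dt = %g)\n",
    x$upper_bound, x$n_subintervals, x$dt
  ))
  invisible(x)
}

as_grid <- function(grid) {
  if (!inherits(grid, "divphy_grid")) {
    stop("'grid' must be created with time_grid()", call. = FALSE)
  }
  grid
}

default_grid <- function(tree, params, n_subintervals = 1000L,
                         n_tips_for_bound = NULL) {
  n <- if (is.null(n_tips_for_bound)) length(tree$tip.label) else n_tips_for_bound
  time_grid(default_upper_bound(n, params), n_subintervals)
}
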