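#' Model parameters for the division-coupled mutation model
#'
#' Bundles and validates the three parameters of the birth-death mutation
#' model. The unit of time is fixed by setting the cell division (birth) rate
#' to one, so all other rates are relative to it.
#'
#' @param q Relative death rate: rate of cell death (plus differentiation,
#'   where applicable) divided by the division rate. Must satisfy
#'   `0 <= q < 1` (supercritical growth).
#' @param mu Mean number of mutations per cell division (`mu >= 0`). Each
#'   division contributes a Poisson(`mu`) number of mutations to each
#'   daughter genome.
#' @param rho Sampling probability: each extant cell is included in the data
#'   independently with probability `rho` (`0 < rho <= 1`).
#' @return An object of class `divphy_params`.
#' @examples
#' model_params(q = 0.75, mu = 1)
#' @seealso [clock_params()] for the molecular-clock comparison model.
#' @export
model_params <- function(q, mu, rho = 1) {
  check_scalar(q, "q")
  check_scalar(mu, "mu")
  check_scalar(rho, "rho")
  if (q < 0 || q >= 1) {
    stop("'q' must satisfy 0 <= q < 1 (supercritical growth)", call. = FALSE)
  }
  if (mu < 0) stop("'mu' must be >= 0", call. = FALSE)
  if (rho <= 0 || rho > 1) stop("'rho' must satisfy 0 < rho <= 1", call. = FALSE)
  structure(list(q = q, mu = mu, rho = rho), class = "divphy_params")
}

#' Parameters for the constant-rate molecular-clock comparison model
#'
#' Same birth-death population process as [model_params()], but mutations
#' accrue as a Poisson process in calendar time at rate `mu_t` along each
#' branch, independently of the number of divisions.
#'
#' @inheritParams model_params
#' @param mu_t Mutation rate per unit time (`mu_t >= 0`); the time unit is
#'   the inverse division rate.
#' @return An object of class `divphy_clock_params`.
#' @export
clock_params <- function(q, mu_t, rho = 1) {
  check_scalar(q, "q")
  check_scalar(mu_t, "mu_t")
  check_scalar(rho, "rho")
  if (q < 0 || q >= 1) {
    stop("'q' must satisfy 0 <= q < 1 (supercritical growth)", call. = FALSE)
  }
  if (mu_t < 0) stop("'mu_t' must be >= 0", call. = FALSE)
  if (rho <= 0 || rho > 1) stop("'rho' must satisfy 0 < rho <= 1", call. = FALSE)
  structure(list(q = q, mu_t = mu_t, rho = rho), class = "divphy_clock_params")
}

#' @export
print.divphy_params <- function(x, ...) {
  cat("Division-coupled mutation model parameters\n")
  cat(sprintf("  q   (relative death rate)       : %g\n", x$q))
  cat(sprintf("  mu  (mutations per division)    : %g\n", x$mu))
  cat(sprintf("  rho (sampling probability)      : %g\n", x$rho))
  invisible(x)
}

#' @export
print.divphy_clock_params <- function(x, ...) {
  cat("Constant-rate molecular-clock model parameters\n")
  cat(sprintf("  q    (relative death rate)      : %g\n", x$q))
  cat(sprintf("  mu_t (mutations per unit time)  : %g\n", x$mu_t))
  cat(sprintf("  rho  (sampling probability)     : %g\n", x$rho))
  invisible(x)
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(TRUE)
}

as_params <- function(params) {
  if (!inherits(params, "divphy_params")) {
    stop("'params' must be created with model_params()", call. = FALSE)
  }
  params
}

#' Default truncation of the sums over hidden generations
#'
#' Sums over the per-branch generation count are truncated at `i_max`. Under
#' complete sampling a cap of 50 suffices on trees of a few hundred cells;
#' under incomplete sampling branches span more generations and the cap is
#' raised to 200.
#'
#' @param rho Sampling probability.
#' @return Integer truncation level.
#' @export
default_i_max <- function(rho = 1) {
  if (rho < 1) 200L else 50L
}
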