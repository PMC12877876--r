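#' Poisson mean of the hidden-generation count along a branch
#'
#' The number of divisions `i` along a reconstructed branch spanning the
#' backward-time window `[tau_e, tau_s]` (whose extra offspring leave no
#' sampled descendants) is Poisson distributed. Its mean is
#' \deqn{\Lambda = 2q(\tau_s-\tau_e) + 2\log\frac{(1-\rho-q)e^{-(1-q)\tau_e}+\rho}
#'   {(1-\rho-q)e^{-(1-q)\tau_s}+\rho},}
#' which under complete sampling (`rho = 1`) reduces to
#' `2q tau + 2 log((1 - q e^{-(1-q)tau_e}) / (1 - q e^{-(1-q)tau_s}))`.
#'
#' @param tau_s Branch start time (backwards from observation), `tau_s >= tau_e`.
#' @param tau_e Branch end time, `tau_e >= 0`.
#' @param params A [model_params()] object.
#' @return The non-negative Poisson mean (vectorized over `tau_s`/`tau_e`).
#' @export
log_generation_mean <- function(tau_s, tau_e, params) {
  params <- as_params(params)
  check_window(tau_s, tau_e)
  q <- params$q
  rho <- params$rho
  om <- 1 - q
  num <- (1 - rho - q) * exp(-om * tau_e) + rho
  den <- (1 - rho - q) * exp(-om * tau_s) + rho
  lam <- 2 * q * (tau_s - tau_e) + 2 * (log(num) - log(den))
  # guard round-off at tau_s == tau_e or q = 0, rho = 1
  pmax(lam, 0)
}

#' Joint probability of i hidden generations along a branch
#'
#' Probability that a lineage starting at backward time `tau_s` is alive at
#' `tau_e` having undergone `i` divisions in between, with every side lineage
#' produced by those divisions leaving no sampled descendant at the
#' observation time:
#' \deqn{p_1^{(\rho)}(i\mid\tau_s,\tau_e) =
#'   e^{-(1+q)(\tau_s-\tau_e)}\Lambda^i / i!.}
#' With `rho = 1` the side lineages must simply die out.
#'
#' @param i Non-negative integer generation count (vectorized).
#' @param tau_s,tau_e Branch window (backwards time), `tau_s >= tau_e >= 0`.
#' @param params A [model_params()] object.
#' @param log Return log-probability?
#' @return Probability (or log-probability).
#' @export
p1_generations <- function(i, tau_s, tau_e, params, log = FALSE) {
  params <- as_params(params)
  if (any(i < 0) || any(i != floor(i))) {
    stop("'i' must contain non-negative integers", call. = FALSE)
  }
  lam <- log_generation_mean(tau_s, tau_e, params)
  # i * log(lam) with the 0 * log(0) = 0 convention
  ilog <- i * ifelse(lam == 0, -Inf, log(lam))
  ilog[i == 0] <- 0
  lp <- -(1 + params$q) * (tau_s - tau_e) + ilog - lgamma(i + 1)
  if (log) lp else exp(lp)
}

#' Probability that a branch window is bridged by a surviving lineage
#'
#' Closed form of the sum of [p1_generations()] over all generation counts,
#' \eqn{e^{-(1+q)(\tau_s-\tau_e)} e^{\Lambda}}: the probability that the
#' lineage is alive at `tau_e` and none of its side lineages is sampled,
#' irrespective of how many divisions occurred. This is the per-branch
#' survival factor of the molecular-clock comparison model.
#'
#' @inheritParams p1_generations
#' @return Probability (or log-probability).
#' @export
sum_p1_over_generations <- function(tau_s, tau_e, params, log = FALSE) {
  params <- as_params(params)
  lam <- log_generation_mean(tau_s, tau_e, params)
  lp <- -(1 + params$q) * (tau_s - tau_e) + lam
  if (log) lp else exp(lp)
}

#' Probabilities of no or one sampled offspring
#'
#' For a birth-death process started from a single cell a backward time `tau`
#' before observation, with each extant cell sampled independently with
#' probability `rho`:
#' \deqn{p_0^{(\rho)}(\tau) = 1 - \frac{\rho(1-q)}{\rho+(1-\rho-q)e^{-(1-q)\tau}},
#' \qquad
#' p_1^{(\rho)}(\tau) = \frac{\rho(1-q)^2 e^{-(1-q)\tau}}
#'   {(\rho+(1-\rho-q)e^{-(1-q)\tau})^2}.}
#'
#' @param tau Non-negative backward time (vectorized).
#' @param params A [model_params()] object.
#' @return Probability in `[0, 1]`.
#' @export
p0_sampled <- function(tau, params) {
  params <- as_params(params)
  if (any(tau < 0)) stop("'tau' must be >= 0", call. = FALSE)
  q <- params$q
  rho <- params$rho
  d <- rho + (1 - rho - q) * exp(-(1 - q) * tau)
  1 - rho * (1 - q) / d
}

#' @rdname p0_sampled
#' @export
p1_sampled <- function(tau, params) {
  params <- as_params(params)
  if (any(tau < 0)) stop("'tau' must be >= 0", call. = FALSE)
  q <- params$q
  rho <- params$rho
  d <- rho + (1 - rho - q) * exp(-(1 - q) * tau)
  rho * (1 - q)^2 * exp(-(1 - q) * tau) / d^2
}

#' Mutations along a branch given its generation count
#'
#' Each division deposits a Poisson(`mu`) number of mutations on each
#' daughter genome. A branch with `i` divisions along it, plus the one
#' division founding the branch, therefore carries
#' \deqn{P(m\mid i) = e^{-(i+1)\mu}((i+1)\mu)^m/m!.}
#'
#' @param m Non-negative integer mutation count (vectorized).
#' @param i Non-negative integer generation count (vectorized).
#' @param mu Mean mutations per division.
#' @param log Return log-probability?
#' @return Probability (or log-probability).
#' @export
mutations_given_generations <- function(m, i, mu, log = FALSE) {
  if (any(m < 0) || any(m != floor(m))) {
    stop("'m' must contain non-negative integers", call. = FALSE)
  }
  if (any(i < 0) || any(i != floor(i))) {
    stop("'i' must contain non-negative integers", call. = FALSE)
  }
  if (!is.numeric(mu) || any(mu < 0)) stop("'mu' must be >= 0", call. = FALSE)
  dpois(m, (i + 1) * mu, log = log)
}

#' Compound Poisson distribution of branch mutation counts
#'
#' Marginal distribution of the number of mutations along a branch when the
#' number of generations is Poisson(`mean_generations`) and each generation
#' deposits Poisson(`mu`) mutations:
#' \deqn{P(m) = \sum_i \mathrm{Pois}(i;\langle i\rangle)\,
#'   \mathrm{Pois}(m;(i+k)\mu),}
#' with `k = 1` when the division founding the branch is included
#' (`include_founder = TRUE`, the convention used in the likelihood) and
#' `k = 0` otherwise (the display convention when comparing against a simple
#' Poisson of equal mean `<i> mu`). The compound distribution has variance
#' `<i> mu (1 + mu) (+ mu if the founder is included)`, strictly larger than
#' the equal-mean Poisson whenever `mu > 0` and `<i> > 0`.
#'
#' @param m Non-negative integer mutation count (vectorized).
#' @param mean_generations Mean number of generations along the branch.
#' @param mu Mean mutations per division.
#' @param include_founder Include the founding division (default `TRUE`)?
#' @param i_max Truncation of the generation sum (default [default_i_max()]
#'   at full sampling); a warning is raised if the truncated tail is not
#'   negligible.
#' @return Probability mass at `m`.
#' @export
compound_poisson_pmf <- function(m, mean_generations, mu,
                                 include_founder = TRUE,
                                 i_max = default_i_max(1)) {
  if (any(m < 0) || any(m != floor(m))) {
    stop("'m' must contain non-negative integers", call. = FALSE)
  }
  if (mean_generations < 0) stop("'mean_generations' must be >= 0", call. = FALSE)
  if (mu < 0) stop("'mu' must be >= 0", call. = FALSE)
  k <- if (include_founder) 1 else 0
  i <- 0:i_max
  wi <- dpois(i, mean_generations)
  check_truncation_tail(wi, "compound_poisson_pmf")
  vapply(m, function(mm) sum(wi * dpois(mm, (i + k) * mu)), numeric(1))
}

check_window <- function(tau_s, tau_e) {
  if (any(tau_e < 0) || any(tau_s < tau_e)) {
    stop("branch window requires 0 <= tau_e <= tau_s", call. = FALSE)
  }
  invisible(TRUE)
}

check_truncation_tail <- function(weights, where) {
  n <- length(weights)
  s <- sum(weights)
  if (s > 0 && weights[n] > 1e-15 * s) {
    warning(sprintf("generation sum in %s truncated before its tail is negligible; raise i_max",
                    where), call. = FALSE)
  }
  invisible(TRUE)
}
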