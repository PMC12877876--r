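test_that("log_generation_mean matches the complete-sampling special case", {
  p <- model_params(q = 0.75, mu = 1)
  ts <- c(0.5, 1, 2, 5)
  te <- c(0, 0.5, 1, 2)
  got <- log_generation_mean(ts, te, p)
  om <- 0.25
  want <- 2 * 0.75 * (ts - te) +
    2 * log((1 - 0.75 * exp(-om * te)) / (1 - 0.75 * exp(-om * ts)))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("incomplete-sampling mean reduces to the rho = 1 form", {
  q <- 0.6
  ts <- 3
  te <- 1
  lam_full <- log_generation_mean(ts, te, model_params(q, 1, rho = 1))
  # rho -> 1 limit of the general expression
  lam_gen <- log_generation_mean(ts, te, model_params(q, 1, rho = 1 - 1e-12))
  expect_equal(lam_gen, lam_full, tolerance = 1e-8)
  # degenerate window
  expect_equal(log_generation_mean(2, 2, model_params(q, 1)), 0)
})

test_that("p1_generations is a Poisson over i and matches its closed sum", {
  p <- model_params(q = 0.5, mu = 1, rho = 0.3)
  ts <- 4
  te <- 1
  i <- 0:150
  pr <- p1_generations(i, ts, te, p)
  expect_true(all(pr >= 0))
  expect_equal(sum(pr), sum_p1_over_generations(ts, te, p), tolerance = 1e-12)
  lam <- log_generation_mean(ts, te, p)
  expect_equal(sum(pr * i) / sum(pr), lam, tolerance = 1e-10)
  # log form consistent
  expect_equal(p1_generations(3, ts, te, p, log = TRUE), log(pr[4]),
               tolerance = 1e-12)
})

test_that("p1_generations handles the zero-window and q = 0 cases", {
  p <- model_params(q = 0, mu = 1)
  expect_equal(p1_generations(0, 2, 0.5, p), exp(-1.5))
  expect_equal(p1_generations(1, 2, 0.5, p), 0)
  expect_equal(p1_generations(0:3, 1, 1, model_params(0.5, 1)),
               c(1, 0, 0, 0))
  expect_error(p1_generations(-1, 1, 0, p), "non-negative")
  expect_error(p1_generations(0, 1, 2, p), "tau_e")
})

test_that("sampled-offspring probabilities at tau = 0 are (1 - rho, rho)", {
  for (q in c(0, 0.3, 0.9)) for (rho in c(0.01, 0.4, 1)) {
    p <- model_params(q, 1, rho)
    expect_equal(p0_sampled(0, p), 1 - rho, tolerance = 1e-14)
    expect_equal(p1_sampled(0, p), rho, tolerance = 1e-14)
  }
})

test_that("p0_sampled matches the rho = 1 extinction probability", {
  # with rho = 1, p0 is the classical extinction probability
  # q (1 - e^{-(1-q)tau}) / (1 - q e^{-(1-q)tau})
  q <- 0.75
  tau <- c(0.1, 1, 10)
  p <- model_params(q, 1)
  want <- q * (1 - exp(-0.25 * tau)) / (1 - q * exp(-0.25 * tau))
  expect_equal(p0_sampled(tau, p), want, tolerance = 1e-12)
  expect_equal(p0_sampled(1e6, p), q, tolerance = 1e-12)
})

test_that("summing p1_generations over i recovers the one-offspring curve", {
  # rho * sum_i p1(i | tau, 0) must equal p1_sampled(tau)
  for (cfg in list(c(0.75, 1), c(0.5, 0.1), c(0, 0.5))) {
    p <- model_params(cfg[1], 1, cfg[2])
    for (tau in c(0.3, 2, 6)) {
      s <- p$rho * sum(p1_generations(0:400, tau, 0, p))
      expect_equal(s, p1_sampled(tau, p), tolerance = 1e-9)
    }
  }
})

test_that("mutations_given_generations is the shifted Poisson", {
  expect_equal(mutations_given_generations(3, 2, 0.5),
               exp(-1.5) * 1.5^3 / 6, tolerance = 1e-12)
  expect_equal(mutations_given_generations(0, 0, 0), 1)
  expect_equal(mutations_given_generations(2, 0, 0), 0)
  expect_error(mutations_given_generations(-1, 0, 1), "non-negative")
  expect_error(mutations_given_generations(1, 1.5, 1), "non-negative")
})

test_that("compound Poisson has the correct mean and excess variance", {
  mean_gen <- 3
  mu <- 0.8
  m <- 0:200
  pmf <- compound_poisson_pmf(m, mean_gen, mu, include_founder = FALSE)
  expect_equal(sum(pmf), 1, tolerance = 1e-10)
  mean_m <- sum(m * pmf)
  var_m <- sum(m^2 * pmf) - mean_m^2
  expect_equal(mean_m, mean_gen * mu, tolerance = 1e-8)
  expect_equal(var_m, mean_gen * mu * (1 + mu), tolerance = 1e-6)
  # founder shifts both moments by one division
  pmf1 <- compound_poisson_pmf(m, mean_gen, mu, include_founder = TRUE)
  expect_equal(sum(m * pmf1), (mean_gen + 1) * mu, tolerance = 1e-8)
})

test_that("a too-small truncation triggers the tail warning", {
  expect_warning(compound_poisson_pmf(0, mean_generations = 40, mu = 1,
                                      i_max = 45),
                 "truncated")
})
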