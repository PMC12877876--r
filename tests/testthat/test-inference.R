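# Inference tests use small trees and coarse grids to stay fast; the
# full-scale recovery experiment lives in test-acceptance.R.

test_that("fit_mle recovers q near 0 on a q = 0 simulated tree", {
  p <- model_params(q = 0, mu = 2)
  tr <- simulate_mutation_tree(60, p, seed = 101)
  f <- fit_mle(tr, rho = 1, n_subintervals = 100, coarse_n = 5L,
               coarse_subintervals = 50L,
               control = list(maxit = 150L, reltol = 1e-5))
  expect_s3_class(f, "divphy_fit")
  expect_lt(f$params$q, 0.15)
  expect_gt(f$params$mu, 1.5)
  expect_lt(f$params$mu, 2.6)
  expect_true(is.finite(f$log_likelihood))
  expect_true(all(c("stage", "q", "mu", "log_likelihood") %in%
                    names(f$trace)))
})

test_that("fit_mle accepts a list of trees and sums their likelihoods", {
  p <- model_params(q = 0.5, mu = 1)
  trs <- lapply(1:3, function(k) simulate_mutation_tree(25, p, seed = 200 + k))
  f <- fit_mle(trs, rho = 1, n_subintervals = 80, coarse_n = 5L,
               coarse_subintervals = 40L,
               control = list(maxit = 100L, reltol = 1e-4))
  # fitted log-likelihood equals the sum of per-tree evaluations at the MLE
  ll <- sum(vapply(trs, function(tr)
    tree_log_likelihood(tr, f$params, n_subintervals = 80,
                        n_tips_for_bound = f$settings$n_tips_for_bound),
    numeric(1)))
  expect_equal(f$log_likelihood, ll, tolerance = 1e-10)
})

test_that("likelihood_landscape matches pointwise evaluations", {
  tr <- nwk("((A:2,B:4):1,C:7);")
  qv <- c(0.2, 0.5)
  mv <- c(0.5, 1, 2)
  L <- likelihood_landscape(tr, rho = 1, q_values = qv, mu_values = mv,
                           n_subintervals = 60)
  expect_equal(dim(L), c(2L, 3L))
  for (a in 1:2) for (b in 1:3) {
    expect_equal(L[a, b],
                 tree_log_likelihood(tr, model_params(qv[a], mv[b]),
                                     n_subintervals = 60),
                 tolerance = 1e-12)
  }
  # masking floor
  L2 <- likelihood_landscape(tr, rho = 1, q_values = qv, mu_values = mv,
                            n_subintervals = 60, floor = max(L) - 1)
  expect_true(anyNA(L2))
  expect_equal(max(L2, na.rm = TRUE), max(L))
})

test_that("landscape is invariant to leaf order", {
  qv <- c(0.3, 0.7)
  mv <- c(1, 2)
  L1 <- likelihood_landscape(nwk("((A:2,B:4):1,C:7);"), rho = 1,
                             q_values = qv, mu_values = mv,
                             n_subintervals = 60)
  L2 <- likelihood_landscape(nwk("(C:7,(B:4,A:2):1);"), rho = 1,
                             q_values = qv, mu_values = mv,
                             n_subintervals = 60)
  expect_equal(L1, L2, tolerance = 1e-12)
})

test_that("select_postnatal_clades applies a strict distance threshold", {
  # two candidate clades hang at depth 150 and one shallow clade at 100
  big <- ape::stree(30, "left")
  big$edge.length <- rep(1, nrow(big$edge))
  small <- ape::stree(10, "left")
  small$edge.length <- rep(1, nrow(small$edge))
  shallow <- ape::stree(25, "left")
  shallow$edge.length <- rep(1, nrow(shallow$edge))
  base <- ape::read.tree(text = "((X:150,Y:150):1,(Z:100,W:300):1);")
  tr <- ape::bind.tree(base, big, where = which(base$tip.label == "X"))
  tr <- ape::bind.tree(tr, small, where = which(tr$tip.label == "Y"))
  tr <- ape::bind.tree(tr, shallow, where = which(tr$tip.label == "Z"))
  tr <- as_mutation_tree(tr)
  cl <- select_postnatal_clades(tr, min_root_mutations = 100,
                                min_leaves = 23)
  info <- attr(cl, "info")
  # the 30-leaf clade at 151 qualifies; the 10-leaf clade is too small; the
  # 25-leaf clade at exactly 101 qualifies? no: its root sits at 101 > 100
  expect_true(all(info$root_distance > 100))
  expect_true(all(info$n_leaves >= 23))
  expect_setequal(info$n_leaves, c(30L, 25L))
  # strictness: a clade root exactly at the threshold is excluded
  cl2 <- select_postnatal_clades(tr, min_root_mutations = 150,
                                 min_leaves = 23)
  expect_equal(attr(cl2, "info")$n_leaves, 30L)  # 25-leaf clade at 101 drops
  # the 30-leaf clade root sits at exactly 151: with a 151 threshold it is
  # excluded (strict >) and its 29-leaf child at depth 152 takes over
  cl3 <- select_postnatal_clades(tr, min_root_mutations = 151,
                                 min_leaves = 23)
  info3 <- attr(cl3, "info")
  expect_equal(info3$n_leaves, 29L)
  expect_equal(info3$root_distance, 152)
})

test_that("select_postnatal_clades returns maximal (disjoint) clades", {
  # nested qualifying nodes: only the outermost is returned
  tr <- nwk("(((A:10,B:10):50,(C:10,D:10):50):150,E:400);")
  cl <- select_postnatal_clades(tr, min_root_mutations = 100, min_leaves = 2)
  info <- attr(cl, "info")
  expect_equal(nrow(info), 1L)
  expect_equal(info$n_leaves, 4L)
  # no qualifying clade -> empty list with empty info
  cl0 <- select_postnatal_clades(tr, min_root_mutations = 1000)
  expect_length(cl0, 0L)
  expect_equal(nrow(attr(cl0, "info")), 0L)
})

test_that("heterogeneity_test yields a non-negative statistic and fits", {
  p <- model_params(q = 0.4, mu = 1)
  clades <- lapply(1:3, function(k) simulate_mutation_tree(15, p, seed = 300 + k))
  lrt <- heterogeneity_test(clades, focal = 2, rho = 1,
                            n_subintervals = 60, coarse_n = 5L,
                            coarse_subintervals = 30L,
                            control = list(maxit = 100L, reltol = 1e-4))
  expect_s3_class(lrt, "divphy_lrt")
  expect_gte(lrt$lambda_LR, -1e-6)
  expect_equal(lrt$df, 2L)
  expect_equal(lrt$p_value,
               pchisq(lrt$lambda_LR, 2, lower.tail = FALSE))
  expect_error(heterogeneity_test(clades[1], focal = 1), "two clades")
  expect_error(heterogeneity_test(clades, focal = 9), "out of range")
})

test_that("chi-squared(2) p-values have the closed form exp(-lambda/2)", {
  expect_equal(pchisq(16.23, 2, lower.tail = FALSE), exp(-16.23 / 2))
  expect_equal(pchisq(6.17, 2, lower.tail = FALSE), exp(-6.17 / 2))
})

test_that("bonferroni_select applies the alpha / n rule", {
  pvals <- c(0.0003, 0.046, 0.2, 0.004, 0.9, 0.0062, 0.5, 0.7)
  expect_equal(bonferroni_select(pvals, alpha = 0.05), c(1L, 4L, 6L))
  expect_equal(bonferroni_select(numeric(0)), integer(0))
  expect_equal(bonferroni_select(c(0.05, 0.6), alpha = 1), 1L)
})
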