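---
title: "Division-coupled phylodynamics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Division-coupled phylodynamics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divphy)
```

# The model

`divphy` implements likelihood-based inference for somatic cell
populations in which mutations arise at cell divisions rather than
continuously in time. The population follows a supercritical
birth–death process: each cell divides at rate 1 (fixing the unit of
time) and dies — or differentiates out of the observed compartment —
at rate `q`, with `0 <= q < 1`. At each division, each daughter genome
independently acquires a Poisson(`mu`) number of novel mutations
(infinite-sites assumption). At the observation time each extant cell
is sampled independently with probability `rho`.

The data are reconstructed phylogenies of the sampled cells whose
branch lengths are **integer mutation counts**; calendar time is
latent. The central quantity linking the two is the distribution of
the number of *hidden divisions* along a reconstructed branch:
divisions whose second daughter lineage left no sampled descendant and
which are therefore invisible in the reconstruction.

## Branch statistics

Work in backward time `tau`, with `tau = 0` at observation. For a
branch spanning the window `[tau_e, tau_s]`, the number `i` of hidden
divisions along it — given that the lineage survives the window and
none of its side lineages is sampled — is Poisson with mean

```
Lambda(tau_s, tau_e) = 2 q (tau_s - tau_e)
  + 2 log[ ((1 - rho - q) e^{-(1-q) tau_e} + rho)
         / ((1 - rho - q) e^{-(1-q) tau_s} + rho) ] ,
```

and the joint probability of bridging the window with `i` hidden
divisions is

```
p1(i | tau_s, tau_e) = e^{-(1+q)(tau_s - tau_e)} Lambda^i / i! .
```

At `rho = 1` the bracket reduces to the familiar complete-sampling
expression with `1 - q e^{-(1-q) tau}` factors. These functions are
exposed as `log_generation_mean()` and `p1_generations()` and are
validated in two independent ways:

* a forward Monte-Carlo oracle, `mc_estimate_p1()`, which simulates
  clades and counts lineages alive at `tau_e` with `i` path divisions
  and no sampled side descendants;
* the analytic check that `rho * sum_i p1(i | tau, 0)` equals the
  probability `p1_sampled(tau)` that a lineage leaves exactly one
  sampled descendant,

```
p0(tau) = 1 - rho (1-q) / D(tau),
p1(tau) = rho (1-q)^2 e^{-(1-q) tau} / D(tau)^2,
D(tau)  = rho + (1 - rho - q) e^{-(1-q) tau} .
```

A branch with `i` hidden divisions carries `m` mutations with
probability `Pois(m; (i+1) mu)`: the `+1` counts the division founding
the branch. Marginally the count is compound-Poisson
(`compound_poisson_pmf()`), over-dispersed relative to a Poisson of
equal mean by the factor `1 + mu` — the signature that distinguishes
division-coupled mutation from a molecular clock.

# Likelihood by dynamic programming

The tree likelihood integrates over all latent node times. Each branch
`nu` carries a *message* `P(nu | tau_s)`: the probability of the
observed subtree below the branch given that the branch starts at
`tau_s`.

* **Pendant branches** (`pendant_message()`):
  `P(nu | tau_s) = rho * sum_i P(m | i) p1(i | tau_s, 0)`.
* **Internal branches** (`internal_message()`): integrate the two
  child messages over the branch end time,
  `P(nu | tau_s) = sum_i int_0^{tau_s} d tau_e P(m | i)
  p1(i | tau_s, tau_e) 2 P(nu' | tau_e) P(nu'' | tau_e)`,
  the factor 2 accounting for the exchangeable daughter labelling.
* **Root**: the origin time of the most recent common ancestor has an
  (improper) uniform prior truncated at `T = 2 log(N / rho) / (1 - q)`
  — twice the expected age of the tree — giving
  `L = int_0^T d tau 2 P(nu' | tau) P(nu'' | tau)`.

All integrals use the trapezoidal rule on one shared uniform grid of
`n_subintervals` steps on `[0, T]` (`time_grid()`), so the inner
integral for a branch starting at grid node `g` runs over nodes
`h <= g`. The truncated prior is used as is, without renormalising by
`1/T`; this adds a constant to the log-likelihood that cancels in all
comparisons at a fixed grid policy. Because `T` depends on `q`, the
grid is rebuilt at every parameter value during optimization; for
multi-clade analyses every clade shares the `T` computed from the full
tree's tip count so that likelihoods remain comparable.

## Numerics

The generation sum is truncated at `i_max` (50 under complete
sampling, 200 otherwise, `default_i_max()`); a diagnostic warning
fires if the truncated tail is non-negligible. The C++ kernel
(`src/dp_kernel.cpp`) evaluates, for each pair of grid nodes, the
polynomial `S(Lambda) = sum_i u_i Lambda^i` with
`u_i = P(m | i) / i!` via Horner's rule on max-shifted coefficients,
using the identity `Lambda(g, h) = phi(g) - phi(h)` with
`phi(t) = 2 q t - 2 log((1 - rho - q) e^{-(1-q) t} + rho)` so the
`O(G^2)` pair table needs only `O(G)` transcendental evaluations.
Messages are stored as logs and each message is rescaled by its
maximum before accumulation.

Two evaluation paths guard against overflow: a fast vectorized
linear-space path used whenever the largest intermediate,
`exp(maxterm + (1+q) T)`, provably stays below the double-precision
ceiling, and a per-pair log-sum-exp path for extreme regimes (deep
grids at high `q` and small `rho`). Both paths are compared against a
plain-R reference implementation in the test suite; the dynamic
program is validated to `1e-8` relative error against brute-force
nested quadrature on 3- and 4-leaf trees and to `1e-10` against the
closed form for the 2-leaf tree at `q = 0`,
`e^{-2 mu} mu^{m1 + m2} / (m1! m2!)` times the explicit truncation
factor `1 - e^{-2T}`.

A trapezoid on `G` subintervals carries `O(G^-2)` bias, so
log-likelihood *differences* converge quickly: on an `N = 300` tree,
moving from `G = 200` to `G = 1000` changes the log-likelihood by
about 0.2 units and maximum-likelihood estimates by under 0.01 —
fitting at `G = 200` and reporting at `G = 1000` is a sensible
economy. Cost scales as `G^2` per branch.

## The clock comparison model

`clock_tree_log_likelihood()` implements the same recursion for a
constant-rate molecular clock: the per-branch factor is
`Pois(m; mu_t (tau_s - tau_e))` times the window-bridging probability
`sum_i p1(i | tau_s, tau_e)`. Because the Poisson part depends only on
the window length, the kernel tabulates it once per lag. The two
models share the grid policy and are therefore directly comparable by
log-likelihood.

# Simulation

`simulate_birth_death()` grows a population from one founder by exact
Gillespie simulation until it *first* reaches `n_stop` cells, the
observation time; populations that die out restart with fresh
randomness (the restart count is recorded). `sample_and_reconstruct()`
samples extant cells with probability `rho`, prunes to the spanning
subtree of the sample, suppresses non-branching nodes, and annotates
every reconstructed branch with its true duration and hidden-division
count. `assign_mutations()` then draws `Pois((i+1) mu)` mutations per
branch. `simulate_mutation_tree()` chains the three.

The first-passage convention differs subtly from conditioning on
observing size `N` at a fixed time; the differences are minor for the
inference experiments shipped here, and the convention is applied
consistently in simulation and validation.

# Inference

`fit_mle()` maximizes the summed log-likelihood over `(q, mu)` at
fixed `rho` by a coarse grid scan followed by Nelder–Mead refinement,
with the box enforced by clamping plus a quadratic penalty. The
default coarse stage is a `7 x 7` scan at a reduced grid resolution
(100 subintervals); the landscapes are smooth and unimodal in all
regimes we exercised, so a denser scan only adds cost — pass
`coarse_n = 21` for a more conservative search. The boundary `q = 0`
is permitted; clock fits on division-generated data routinely end
there. All evaluations are logged in the returned `trace`.

`likelihood_landscape()` tabulates the log-likelihood over a parameter
grid with optional floor masking. `select_postnatal_clades()` returns
the maximal disjoint clades lying deeper than a mutation-distance
threshold (strict `>`, default 100) with at least `min_leaves` sampled
cells (default 23). `heterogeneity_test()` compares a homogeneous fit
of several clades against one granting a focal clade its own
parameters,

```
lambda_LR = -2 (log L_hom - log L_het),    p = Chi^2_2 upper tail,
```

with the heterogeneous block fits started from the homogeneous
optimum, which enforces `lambda_LR >= 0` up to optimizer tolerance.
Because clades are analyzed independently, the heterogeneous
likelihood factorizes and the 4-parameter fit splits into two
2-parameter fits. `bonferroni_select()` applies the `alpha / n`
multiple-testing rule across focal-clade scenarios.

## Problem sizes and limitations

The shipped validation experiments use trees of up to a few hundred
sampled cells, `G` up to 1000 (up to `4e5` for 2-leaf quadrature
checks), and null calibrations of the likelihood-ratio test on
8-clade ensembles. Known limitations:

* rates are constant in time and across the tree within a fit;
  heterogeneity is modelled only clade-wise;
* `rho` is fixed during a fit rather than estimated;
* the trapezoid grid is uniform — very deep trees at `q` close to 1
  may need larger `G`;
* per-site sequences and age-structured cell cycles are out of scope.
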