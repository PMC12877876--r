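#' Forward simulation of a birth-death cell population
#'
#' Exact (Gillespie) simulation of a population of cells with division rate 1
#' and death rate `q`, grown from a single founder until the population first
#' reaches `n_stop` cells. Observation takes place at that first-passage
#' time. If the population dies out before reaching `n_stop`, the simulation
#' restarts from scratch with fresh randomness (the number of restarts is
#' recorded).
#'
#' @param n_stop Target population size (`>= 2`).
#' @param params A [model_params()] object (only `q` is used here).
#' @param seed Optional integer seed (`set.seed()` is called when supplied;
#'   otherwise the current RNG stream is used).
#' @param max_restarts Safety cap on extinction restarts.
#' @return An object of class `lineage_tree`: the full genealogy of every
#'   cell ever alive, with components `parent`, `t_birth`, `t_end`, `status`
#'   (`"died"`, `"divided"`, `"extant"`), `obs_time`, `n_extant`, `restarts`.
#' @examples
#' lin <- simulate_birth_death(20, model_params(q = 0.5, mu = 1), seed = 1)
#' lin$n_extant
#' @export
simulate_birth_death <- function(n_stop, params, seed = NULL,
                                 max_restarts = 10000L) {
  params <- as_params(params)
  if (!is.numeric(n_stop) || length(n_stop) != 1L || n_stop < 2) {
    stop("'n_stop' must be a single integer >= 2", call. = FALSE)
  }
  n_stop <- as.integer(n_stop)
  if (!is.null(seed)) set.seed(seed)
  q <- params$q
  p_birth <- 1 / (1 + q)
  restarts <- 0L
  repeat {
    cap <- 4L * n_stop + 8L
    parent <- integer(cap)
    t_birth <- numeric(cap)
    t_end <- numeric(cap)
    status <- integer(cap)  # 0 died, 1 divided, 2 extant
    n_nodes <- 1L
    parent[1L] <- 0L
    alive <- integer(2L * n_stop)
    alive[1L] <- 1L
    n_alive <- 1L
    t <- 0
    repeat {
      t <- t + rexp(1L, n_alive * (1 + q))
      k <- if (n_alive == 1L) 1L else sample.int(n_alive, 1L)
      cell <- alive[k]
      if (runif(1L) < p_birth) {
        # division: two daughters replace the mother
        if (n_nodes + 2L > cap) {
          cap <- 2L * cap
          length(parent) <- cap; length(t_birth) <- cap
          length(t_end) <- cap; length(status) <- cap
        }
        t_end[cell] <- t
        status[cell] <- 1L
        d1 <- n_nodes + 1L
        d2 <- n_nodes + 2L
        n_nodes <- n_nodes + 2L
        parent[d1] <- cell; parent[d2] <- cell
        t_birth[d1] <- t; t_birth[d2] <- t
        alive[k] <- d1
        n_alive <- n_alive + 1L
        alive[n_alive] <- d2
        if (n_alive == n_stop) { obs_time <- t; break }
      } else {
        t_end[cell] <- t
        status[cell] <- 0L
        alive[k] <- alive[n_alive]
        n_alive <- n_alive - 1L
        if (n_alive == 0L) { obs_time <- NA_real_; break }
      }
    }
    if (!is.na(obs_time)) break
    restarts <- restarts + 1L
    if (restarts > max_restarts) {
      stop("population went extinct in every attempt; check 'q'", call. = FALSE)
    }
  }
  idx <- seq_len(n_nodes)
  extant <- alive[seq_len(n_alive)]
  status[extant] <- 2L
  t_end[extant] <- obs_time
  structure(
    list(
      parent = parent[idx],
      t_birth = t_birth[idx],
      t_end = t_end[idx],
      status = c("died", "divided", "extant")[status[idx] + 1L],
      obs_time = obs_time,
      n_extant = n_alive,
      restarts = restarts
    ),
    class = "lineage_tree"
  )
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf(
    "Birth-death genealogy: %d cells ever alive, %d extant at t = %.3f (%d restart%s)\n",
    length(x$parent), x$n_extant, x$obs_time, x$restarts,
    if (x$restarts == 1L) "" else "s"
  ))
  invisible(x)
}

#' Sample extant cells and reconstruct the phylogenetic tree
#'
#' Each extant cell is sampled independently with probability `rho`; if
#' fewer than `min_sampled` cells are drawn, sampling is repeated with fresh
#' randomness (the number of redraws is recorded). The reconstructed tree is
#' the subtree spanning the sampled cells with non-branching nodes
#' suppressed. Each reconstructed branch is annotated with its true calendar
#' duration and its number of hidden divisions (divisions whose other
#' daughter left no sampled descendant).
#'
#' @param lineage A [simulate_birth_death()] genealogy.
#' @param rho Sampling probability.
#' @param seed Optional integer seed.
#' @param min_sampled Minimum number of sampled cells (default 2).
#' @param max_redraws Safety cap on sampling redraws.
#' @return A `phylo` object (tips labelled `c<cell id>`, `edge.length`
#'   unset) with extra components `edge_tau_s`, `edge_tau_e` (backward
#'   times), `edge_duration`, `edge_generations` (hidden division counts per
#'   edge, in `edge` order), `n_sampled`, `redraws`.
#' @export
sample_and_reconstruct <- function(lineage, rho, seed = NULL,
                                   min_sampled = 2L, max_redraws = 10000L) {
  if (!inherits(lineage, "lineage_tree")) {
    stop("'lineage' must come from simulate_birth_death()", call. = FALSE)
  }
  if (rho <= 0 || rho > 1) stop("'rho' must satisfy 0 < rho <= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  extant <- which(lineage$status == "extant")
  redraws <- 0L
  repeat {
    sampled <- extant[runif(length(extant)) < rho]
    if (length(sampled) >= min_sampled) break
    redraws <- redraws + 1L
    if (redraws > max_redraws) {
      stop("could not draw enough sampled cells; raise 'rho' or population size",
           call. = FALSE)
    }
  }
  n <- length(lineage$parent)
  parent <- lineage$parent
  has_samp <- logical(n)
  has_samp[sampled] <- TRUE
  # cells are created parent-before-child, so a reverse sweep propagates
  for (id in n:1) {
    if (has_samp[id] && parent[id] > 0L) has_samp[parent[id]] <- TRUE
  }
  n_samp_child <- integer(n)
  for (id in seq_len(n)) {
    if (has_samp[id] && parent[id] > 0L) {
      n_samp_child[parent[id]] <- n_samp_child[parent[id]] + 1L
    }
  }
  # most recent common ancestor of the sample
  mrca <- 1L
  while (n_samp_child[mrca] == 1L) {
    kids <- which(parent == mrca & has_samp)
    mrca <- kids[1L]
  }
  obs <- lineage$obs_time
  n_tip <- length(sampled)
  n_internal <- sum(n_samp_child == 2L)  # includes the mrca split
  # ape numbering: tips 1..n_tip, root n_tip + 1, internals following
  edge <- matrix(0L, nrow = 2L * n_tip - 2L, ncol = 2L)
  edge_tau_s <- numeric(nrow(edge))
  edge_tau_e <- numeric(nrow(edge))
  edge_gen <- integer(nrow(edge))
  tip_label <- character(n_tip)
  e_ct <- 0L
  tip_ct <- 0L
  int_ct <- 1L  # the mrca is node n_tip + 1
  # iterative DFS over reconstructed branches
  kids_of <- function(cell) which(parent == cell & has_samp)
  stack_cell <- kids_of(mrca)   # daughters of the mrca division
  stack_node <- c(n_tip + 1L, n_tip + 1L)
  while (length(stack_cell)) {
    cell <- stack_cell[length(stack_cell)]
    pnode <- stack_node[length(stack_node)]
    stack_cell <- stack_cell[-length(stack_cell)]
    stack_node <- stack_node[-length(stack_node)]
    t_top <- lineage$t_birth[cell]
    gens <- 0L
    cur <- cell
    while (n_samp_child[cur] == 1L) {
      gens <- gens + 1L
      cur <- kids_of(cur)
    }
    e_ct <- e_ct + 1L
    if (n_samp_child[cur] == 2L) {
      int_ct <- int_ct + 1L
      node <- n_tip + int_ct
      edge[e_ct, ] <- c(pnode, node)
      edge_tau_e[e_ct] <- obs - lineage$t_end[cur]
      ch <- kids_of(cur)
      stack_cell <- c(stack_cell, ch)
      stack_node <- c(stack_node, node, node)
    } else {
      # sampled extant cell: pendant branch
      tip_ct <- tip_ct + 1L
      tip_label[tip_ct] <- paste0("c", cur)
      edge[e_ct, ] <- c(pnode, tip_ct)
      edge_tau_e[e_ct] <- 0
    }
    edge_tau_s[e_ct] <- obs - t_top
    edge_gen[e_ct] <- gens
  }
  phy <- structure(
    list(edge = edge, tip.label = tip_label, Nnode = n_tip - 1L),
    class = "phylo", order = "cladewise"
  )
  phy$edge_tau_s <- edge_tau_s
  phy$edge_tau_e <- edge_tau_e
  phy$edge_duration <- edge_tau_s - edge_tau_e
  phy$edge_generations <- edge_gen
  phy$n_sampled <- n_tip
  phy$redraws <- redraws
  phy
}

#' Draw mutation counts onto a reconstructed tree
#'
#' Each branch with `i` hidden divisions receives a Poisson(`(i + 1) mu`)
#' mutation count, independently across branches: one Poisson(`mu`) batch
#' per division along the branch plus one for the division founding it.
#'
#' @param recon A reconstructed tree from [sample_and_reconstruct()] (must
#'   carry `edge_generations`).
#' @param mu Mean mutations per division.
#' @param seed Optional integer seed.
#' @return The tree with integer `edge.length` set to the mutation counts,
#'   classed as `mutation_tree`.
#' @export
assign_mutations <- function(recon, mu, seed = NULL) {
  if (is.null(recon$edge_generations)) {
    stop("'recon' must carry edge_generations (see sample_and_reconstruct)",
         call. = FALSE)
  }
  if (mu < 0) stop("'mu' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  recon$edge.length <- as.numeric(rpois(nrow(recon$edge),
                                        (recon$edge_generations + 1) * mu))
  class(recon) <- c("mutation_tree", "phylo")
  recon
}

#' Simulate a mutation-annotated tree end to end
#'
#' Convenience wrapper: grows a population to `n_stop` cells
#' ([simulate_birth_death()]), samples extant cells with probability
#' `params$rho` and reconstructs the tree ([sample_and_reconstruct()]), then
#' draws per-branch mutation counts ([assign_mutations()]).
#'
#' @inheritParams simulate_birth_death
#' @param min_sampled Minimum number of sampled cells.
#' @return A `mutation_tree` with truth annotations (`edge_duration`,
#'   `edge_generations`) retained.
#' @examples
#' tr <- simulate_mutation_tree(50, model_params(q = 0.5, mu = 1), seed = 7)
#' @export
simulate_mutation_tree <- function(n_stop, params, seed = NULL,
                                   min_sampled = 2L) {
  params <- as_params(params)
  if (!is.null(seed)) set.seed(seed)
  lin <- simulate_birth_death(n_stop, params)
  recon <- sample_and_reconstruct(lin, params$rho, min_sampled = min_sampled)
  assign_mutations(recon, params$mu)
}

#' Monte-Carlo estimate of the hidden-generation distribution
#'
#' Forward-simulates clades started at backward time `tau_s` and estimates
#' the expected number of lineages alive at `tau_e` with exactly `i`
#' divisions whose side clades all lack sampled descendants at the
#' observation time. This expectation equals [p1_generations()] and serves
#' as its simulation oracle.
#'
#' @param i Vector of generation counts to estimate.
#' @param tau_s,tau_e Branch window (backwards time).
#' @param params A [model_params()] object.
#' @param n_reps Number of simulated clades (`>= 1e4` recommended).
#' @param seed Optional integer seed.
#' @return A data frame with columns `i`, `estimate`, `se`.
#' @export
mc_estimate_p1 <- function(i, tau_s, tau_e, params, n_reps = 1e5,
                           seed = NULL) {
  params <- as_params(params)
  check_window(tau_s, tau_e)
  if (any(i < 0) || any(i != floor(i))) {
    stop("'i' must contain non-negative integers", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  i_cap <- max(i)
  res <- cpp_mc_p1(tau_s, tau_e, params$q, params$rho, as.integer(n_reps),
                   as.integer(i_cap))
  est <- res[1, ] / n_reps
  v <- pmax(res[2, ] / n_reps - est^2, 0)
  se <- sqrt(v / n_reps)
  data.frame(i = i, estimate = est[i + 1], se = se[i + 1])
}
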