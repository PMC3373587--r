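# Stochastic simulation: configuration, single trajectories, ensembles.
#
# Realization r of a run with seed s is a pure function of (s, r): each
# path draws from its own counter-seeded random stream, so ensemble
# results are bit-identical for a fixed (seed, n_realizations) regardless
# of how realizations are distributed over processes.

#' Stochastic simulation configuration
#'
#' @param t_final Final model time.
#' @param n_grid Number of uniform sampling points on `[0, t_final]`.
#' @param n_realizations Number of independent realizations.
#' @param seed Integer seed; realization `r` uses the stream `(seed, r)`.
#' @param method `"direct"` (Gillespie direct method) or `"odm"`
#'   (optimized direct method: frequency-ordered reaction search with
#'   dependency-graph propensity updates).
#' @param threads Number of worker processes for ensemble runs.  Results
#'   do not depend on this value.
#' @return A list of class `ssa_config`.
#' @export
ssa_config <- function(t_final = 10, n_grid = 100, n_realizations = 1000,
                       seed = 1, method = c("direct", "odm"), threads = 1L) {
  method <- match.arg(method)
  stopifnot(t_final > 0, n_grid >= 2, n_realizations >= 1)
  structure(list(t_final = t_final, n_grid = as.integer(n_grid),
                 n_realizations = as.integer(n_realizations),
                 seed = as.integer(seed), method = method,
                 threads = as.integer(threads)), class = "ssa_config")
}

# count-space rate factors for the C++ core; NULL if any reaction is custom
mass_action_table <- function(net) {
  w <- system_size(net)
  kc <- numeric(n_reactions(net))
  for (j in seq_len(n_reactions(net))) {
    rx <- net$reactions[[j]]
    if (rx$type != "mass_action") return(NULL)
    order <- sum(rx$reactants)
    kc[j] <- rx$rate * w^(1 - order)
  }
  kc
}

ssa_inputs <- function(net, config) {
  list(Sr = stoich_matrix(net, "reactant"),
       Sn = stoich_matrix(net),
       kc = mass_action_table(net),
       n0 = initial_state(net, "count", integer = TRUE),
       grid = seq(0, config$t_final, length.out = config$n_grid),
       odm_t_limit = 0.1 * config$t_final,
       odm_max_ev = 1e4)
}

#' Simulate a single exact trajectory
#'
#' Samples one realization of the chemical master equation by the Gillespie
#' direct method: waiting times are exponential with rate equal to the total
#' propensity and the reaction index is drawn proportionally to its
#' propensity.  When the total propensity reaches zero the state is frozen
#' until `t_final`.
#'
#' @param net A [reaction_network()] whose reactions are all mass-action.
#' @param config An [ssa_config()].
#' @param realization_index Stream index (>= 1); different indices give
#'   independent paths under the same seed.
#' @param record_events Maximum number of explicit (time, state) events to
#'   record in addition to the grid samples.
#' @return An `ssa_trajectory`: `t`/`x` grid samples (counts), and
#'   `event_times` / `event_states` for the recorded jump sequence.
#' @export
ssa_direct <- function(net, config = ssa_config(), realization_index = 1L,
                       record_events = 100000L) {
  ssa_run_one(net, config, realization_index, odm = FALSE, record_events)
}

#' Simulate a single trajectory with the optimized direct method
#'
#' Statistically identical to [ssa_direct()]; reactions are reordered by
#' descending firing frequency estimated from a short presimulation window,
#' and only propensities connected to the fired reaction through the
#' species dependency graph are recomputed after each event.
#'
#' @inheritParams ssa_direct
#' @return An `ssa_trajectory`.
#' @export
ssa_odm <- function(net, config = ssa_config(), realization_index = 1L,
                    record_events = 100000L) {
  ssa_run_one(net, config, realization_index, odm = TRUE, record_events)
}

ssa_run_one <- function(net, config, realization_index, odm, record_events) {
  inp <- ssa_inputs(net, config)
  if (is.null(inp$kc))
    stop("stochastic simulation requires mass-action reactions")
  if (any(inp$kc < 0)) stop("negative rate constant")
  res <- ssa_path_cpp(inp$Sr, inp$Sn, inp$kc, inp$n0, inp$grid,
                      config$t_final, config$seed, realization_index, odm,
                      as.integer(record_events), inp$odm_t_limit,
                      inp$odm_max_ev)
  colnames(res$grid_states) <- net$species$id
  if (nrow(res$event_states)) colnames(res$event_states) <- net$species$id
  structure(list(t = inp$grid, x = res$grid_states,
                 event_times = res$event_times,
                 event_states = res$event_states,
                 x0 = inp$n0, truncated = res$truncated,
                 species = net$species$id, omega = system_size(net),
                 method = if (odm) "odm" else "direct",
                 seed = config$seed, realization = realization_index),
            class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat(sprintf("SSA trajectory (%s method, seed %d, stream %d): %d events recorded%s\n",
              x$method, x$seed, x$realization, length(x$event_times),
              if (isTRUE(x$truncated)) " (record truncated)" else ""))
  invisible(x)
}

#' Sample a trajectory on a time grid
#'
#' The state at grid time `t` is the state after the last event at time
#' `<= t` (the right-continuous step-function convention of jump
#' processes).
#'
#' @param traj An `ssa_trajectory` (its recorded event sequence is used).
#' @param grid Non-decreasing vector of times within the simulated range.
#' @return Matrix of states (`length(grid)` x N).
#' @export
sample_on_grid <- function(traj, grid) {
  ev_t <- traj$event_times
  out <- matrix(0, length(grid), length(traj$x0))
  colnames(out) <- traj$species
  for (g in seq_along(grid)) {
    k <- findInterval(grid[g], ev_t)   # last event with time <= grid[g]
    out[g, ] <- if (k == 0L) traj$x0 else traj$event_states[k, ]
  }
  out
}

#' Run an ensemble of stochastic simulations
#'
#' Simulates `n_realizations` independent paths (each a pure function of
#' `(seed, realization)`), samples them on the uniform grid and aggregates
#' mean, variance and covariance of the concentrations with a streaming
#' (Welford) accumulator combined deterministically across fixed-size
#' chunks, so the result is independent of the number of worker processes.
#'
#' @param net A [reaction_network()] with mass-action reactions.
#' @param config An [ssa_config()].
#' @return An `ssa_ensemble` with fields `t`, `mean`, `var`, `sd` (all in
#'   the concentration frame), `cov` (array `G x N x N`), `corr`,
#'   `n_realizations`, `seed`, `omega`.
#' @export
run_ensemble <- function(net, config = ssa_config()) {
  inp <- ssa_inputs(net, config)
  if (is.null(inp$kc))
    stop("stochastic simulation requires mass-action reactions")
  nr <- config$n_realizations
  odm <- config$method == "odm"
  chunk_size <- 256L
  starts <- seq(1L, nr, by = chunk_size)
  sizes <- pmin(chunk_size, nr - starts + 1L)
  run_chunk <- function(i)
    ssa_chunk_cpp(inp$Sr, inp$Sn, inp$kc, inp$n0, inp$grid, config$t_final,
                  config$seed, starts[i], sizes[i], odm, inp$odm_t_limit,
                  inp$odm_max_ev)
  chunks <- if (config$threads > 1L) {
    parallel::mclapply(seq_along(starts), run_chunk,
                       mc.cores = config$threads)
  } else {
    lapply(seq_along(starts), run_chunk)
  }
  G <- length(inp$grid); N <- n_species(net)
  # deterministic pairwise (Chan) combination in chunk order
  mean_acc <- matrix(0, G, N); m2_acc <- array(0, c(G, N, N)); n_acc <- 0
  for (ch in chunks) {
    nB <- ch$n
    mB <- ch$mean
    m2B <- array(ch$m2, c(N, N, G))   # flattened as [i2 + i*N + g*N*N]
    for (g in seq_len(G)) {
      d <- mB[g, ] - mean_acc[g, ]
      m2g <- t(m2B[, , g])
      if (n_acc == 0) {
        m2_acc[g, , ] <- m2g
      } else {
        m2_acc[g, , ] <- m2_acc[g, , ] + m2g +
          outer(d, d) * n_acc * nB / (n_acc + nB)
      }
      mean_acc[g, ] <- mean_acc[g, ] + d * nB / (n_acc + nB)
    }
    n_acc <- n_acc + nB
  }
  w <- system_size(net)
  mean_c <- mean_acc / w
  cov_c <- m2_acc / max(n_acc - 1L, 1L) / w^2
  var_c <- t(apply(cov_c, 1L, diag)); dim(var_c) <- c(G, N)
  sd_c <- sqrt(pmax(var_c, 0))
  corr <- array(0, c(G, N, N))
  for (g in seq_len(G)) {
    dd <- outer(sd_c[g, ], sd_c[g, ])
    corr[g, , ] <- ifelse(dd > 0, cov_c[g, , ] / dd, 0)
  }
  ids <- net$species$id
  colnames(mean_c) <- colnames(var_c) <- colnames(sd_c) <- ids
  dimnames(cov_c) <- dimnames(corr) <- list(NULL, ids, ids)
  structure(list(t = inp$grid, mean = mean_c, var = var_c, sd = sd_c,
                 cov = cov_c, corr = corr, n_realizations = n_acc,
                 seed = config$seed, method = config$method,
                 species = ids, omega = w),
            class = "ssa_ensemble")
}

#' @export
print.ssa_ensemble <- function(x, ...) {
  cat(sprintf("SSA ensemble (%s method): %d realizations, seed %d, %d grid points\n",
              x$method, x$n_realizations, x$seed, length(x$t)))
  invisible(x)
}
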