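test_that("an absorbing state freezes the trajectory", {
  net <- reaction_network(1e-15)
  net <- add_species(net, "X", 0)
  net <- add_reaction(net, "X -> 0", rate = 1)
  tr <- ssa_direct(net, ssa_config(t_final = 5, n_grid = 11, seed = 1))
  expect_identical(length(tr$event_times), 0L)
  expect_true(all(tr$x == 0))
})

test_that("inter-event times of a pure input process are exponential", {
  # 0 -> X at constant propensity a = k_in * omega
  net <- reaction_network(1e-15)
  net <- add_species(net, "X", 0)
  net <- add_reaction(net, "0 -> X", rate = 2e-6)
  a <- 2e-6 * system_size(net)
  cfg <- ssa_config(t_final = 11000 / a, n_grid = 2, seed = 7)
  tr <- ssa_direct(net, cfg, record_events = 20000L)
  gaps <- diff(c(0, tr$event_times))
  expect_gt(length(gaps), 1e4)
  ks <- stats::ks.test(gaps, "pexp", rate = a)
  expect_gt(ks$p.value, 0.01)
})

test_that("conservation totals are exactly constant along trajectories", {
  net <- make_paper_model("F1")
  tr <- ssa_direct(net, ssa_config(t_final = 0.5, n_grid = 11, seed = 2),
                   record_events = 50000L)
  tot <- tr$event_states[, "E"] + tr$event_states[, "ES"]
  expect_true(all(tot == 1204))
  expect_true(all(tr$event_states >= 0))
})

test_that("direct and optimized direct methods agree in distribution", {
  net <- make_paper_model("F1")
  cfg <- function(m) ssa_config(t_final = 1, n_grid = 2, seed = 11, method = m)
  ends_d <- vapply(1:2000, function(r) {
    tr <- ssa_direct(net, cfg("direct"), r, record_events = 0L)
    tr$x[2, "S"]
  }, 0)
  ends_o <- vapply(1:2000, function(r) {
    tr <- ssa_odm(net, cfg("odm"), r, record_events = 0L)
    tr$x[2, "S"]
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ends_d, ends_o))
  expect_gt(ks$p.value, 0.01)
})

test_that("a single-reaction model makes ordering irrelevant", {
  net <- reaction_network(1e-15)
  net <- add_species(net, "X", 0)
  net <- add_reaction(net, "0 -> X", rate = 1e-6)
  cfg <- ssa_config(t_final = 0.1, n_grid = 21, seed = 5)
  tr1 <- ssa_direct(net, cfg)
  tr2 <- ssa_odm(net, cfg)
  expect_identical(tr1$x, tr2$x)
  expect_identical(tr1$event_times, tr2$event_times)
})

test_that("grid sampling is right-continuous and refinement-consistent", {
  net <- make_birth_death(1e-6, 1, 1e-16)
  tr <- ssa_direct(net, ssa_config(t_final = 2, n_grid = 5, seed = 9),
                   record_events = 10000L)
  ev <- tr$event_times
  expect_gt(length(ev), 10)
  # before the first event: initial state
  g0 <- sample_on_grid(tr, ev[1] / 2)
  expect_identical(as.numeric(g0), as.numeric(tr$x0))
  # exactly at an event time: the post-event state
  g1 <- sample_on_grid(tr, ev[5])
  expect_identical(as.numeric(g1), as.numeric(tr$event_states[5, ]))
  # refining a grid never changes shared points
  coarse <- sample_on_grid(tr, c(0.5, 1.0, 1.5))
  fine <- sample_on_grid(tr, seq(0, 1.5, by = 0.25))
  expect_identical(coarse[1, ], fine[3, ])
  expect_identical(coarse[2, ], fine[5, ])
  expect_identical(coarse[3, ], fine[7, ])
  # the C++ grid sampler agrees with the R one
  expect_identical(as.numeric(tr$x[3, ]),
                   as.numeric(sample_on_grid(tr, tr$t[3])))
})

test_that("birth-death ensembles are Poisson at stationarity", {
  # stationary mean 100 copies
  net <- make_birth_death(1e-6, 1, 100 / (1e-6 * 6.02214076e23))
  w <- system_size(net)
  en <- run_ensemble(net, ssa_config(t_final = 8, n_grid = 17,
                                     n_realizations = 5000, seed = 3))
  G <- length(en$t)
  m <- en$mean[G, 1] * w
  v <- en$var[G, 1] * w^2
  se_mean <- sqrt(v / en$n_realizations)
  expect_lt(abs(m - 100), 3 * se_mean)
  fano <- v / m
  expect_lt(abs(fano - 1), 3 * sqrt(2 / en$n_realizations))
  # ensemble mean follows the rate equations along the whole grid (linear
  # network): within 3 standard errors everywhere
  tc <- integrate_re(net, solver_config(t_final = 8, n_points = 17))
  for (g in 2:G)
    expect_lt(abs(en$mean[g, 1] - tc$phi[g, 1]),
              3 * sqrt(en$var[g, 1] / en$n_realizations) + 1e-15)
})

test_that("ensemble covariance approaches the LNA at large volumes", {
  net <- make_paper_model("F1")
  st <- steady_state(net)
  en <- run_ensemble(net, ssa_config(t_final = 6, n_grid = 13,
                                     n_realizations = 1000, seed = 4))
  G <- length(en$t)
  # variance of the sample variance ~ 2 sigma^4 / n for near-Gaussian data
  for (sp in c("S", "P")) {
    v_ssa <- en$var[G, sp]
    v_lna <- st$cov_ss[sp, sp]
    expect_lt(abs(v_ssa - v_lna), 5 * sqrt(2 / en$n_realizations) * v_lna)
  }
  # correlation structure: enzyme and complex anti-correlated
  expect_lt(en$corr[G, "E", "ES"], -0.99)
})

test_that("ensembles are bit-identical regardless of worker count", {
  net <- make_paper_model("F2")
  cfg1 <- ssa_config(t_final = 2, n_grid = 9, n_realizations = 300, seed = 42,
                     threads = 1)
  cfg2 <- ssa_config(t_final = 2, n_grid = 9, n_realizations = 300, seed = 42,
                     threads = 4)
  e1 <- run_ensemble(net, cfg1)
  e2 <- run_ensemble(net, cfg2)
  expect_identical(e1$mean, e2$mean)
  expect_identical(e1$cov, e2$cov)
  # rerunning with the same seed reproduces exactly; a different seed differs
  e3 <- run_ensemble(net, cfg1)
  expect_identical(e1$mean, e3$mean)
  cfg4 <- cfg1; cfg4$seed <- 43L
  expect_false(identical(run_ensemble(net, cfg4)$mean, e1$mean))
})
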