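test_that("rate equations reproduce the birth-death closed form", {
  k_in <- 1e-6; k_out <- 1
  net <- make_birth_death(k_in, k_out, 1e-15)
  tc <- integrate_re(net, solver_config(t_final = 1 / k_out, n_points = 11,
                                        abs_tol = 1e-15))
  # phi(t) = (k_in/k_out) (1 - exp(-k_out t))
  expect_close(tc$phi[11, "X"], (k_in / k_out) * (1 - exp(-1)), 1e-6)
  # tightening tolerances barely moves the endpoint
  tc2 <- integrate_re(net, solver_config(t_final = 1, n_points = 11,
                                         rel_tol = 5e-7, abs_tol = 1e-16))
  expect_lt(abs(tc2$phi[11, "X"] - tc$phi[11, "X"]) / tc$phi[11, "X"], 1e-5)
})

test_that("Newton steady state matches the flux-balance oracle for F1", {
  net <- make_paper_model("F1")
  phi <- steady_state_re(net)
  oracle <- mm_flux_balance()
  expect_equal(as.numeric(phi), unname(oracle[names(phi)]), tolerance = 1e-8)
  expect_lt(attr(phi, "residual"), solver_config()$newton_tol)
  # F1 relaxes to the fixed point within a few seconds of model time
  tc <- integrate_re(net, solver_config(t_final = 5, n_points = 51))
  expect_equal(unname(tc$phi[51, ]), unname(oracle), tolerance = 1e-2)
})

test_that("damped Newton converges from guesses far outside the basin", {
  for (name in c("F1", "F3")) {
    net <- make_paper_model(name)
    g <- initial_state(net)
    g["S"] <- 1e-3; g["P"] <- 1e-3        # three orders above steady state
    phi <- steady_state_re(net, guess = g)
    phi0 <- steady_state_re(net)
    expect_equal(as.numeric(phi), as.numeric(phi0), tolerance = 1e-6,
                 info = name)
  }
  # birth-death: unique linear fixed point from any guess
  net <- make_birth_death(1e-6, 2, 1e-15)
  expect_equal(as.numeric(steady_state_re(net, guess = c(X = 1))), 5e-7,
               tolerance = 1e-9)
})

test_that("steady-state LNA covariance solves the Lyapunov equation", {
  # birth-death: xi-frame variance = phi (Poisson), C = phi / omega
  net <- make_birth_death(1e-6, 1, 1e-15)
  w <- system_size(net)
  phi <- steady_state_re(net)
  C <- lna_steady(net, phi)
  expect_close(C[1, 1], 1e-6 / w, 1e-9)
  expect_lt(attr(C, "lyapunov_residual"), 1e-8)
  # Fano factor in copy numbers is exactly 1
  expect_close(C[1, 1] * w^2 / (phi[1] * w), 1, 1e-9)
  # residual bound holds on a multi-species fixture too
  net3 <- make_paper_model("F3")
  phi3 <- steady_state_re(net3)
  C3 <- lna_steady(net3, phi3)
  expect_lt(attr(C3, "lyapunov_residual"), 1e-8)
  expect_gt(min(eigen(C3, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10 * max(abs(C3)))
  # a non-Hurwitz Jacobian is rejected (autocatalytic growth)
  neta <- reaction_network(1e-15)
  neta <- add_species(neta, "X", 1e-6)
  neta <- add_reaction(neta, "X -> 2 X", rate = 1)
  neta <- add_reaction(neta, "0 -> X", rate = 1e-9)
  expect_error(lna_steady(neta, c(X = 1e-6)), "Hurwitz")
})

test_that("time-course and steady-state routes agree at long times", {
  net <- make_paper_model("F1")
  st <- steady_state(net)
  tc <- emre_timecourse(net, solver_config(t_final = 20, n_points = 41,
                                           rel_tol = 1e-9, abs_tol = 1e-12))
  nT <- length(tc$t)
  expect_equal(unname(tc$phi[nT, ]), as.numeric(st$phi_ss), tolerance = 1e-6)
  expect_equal(unname(tc$cov[nT, , ]),
               matrix(as.numeric(st$cov_ss), 4, 4), tolerance = 1e-5)
  expect_equal(unname(tc$emre_mean[nT, ]), as.numeric(st$emre_ss),
               tolerance = 1e-6)
  # covariance stays symmetric PSD along the way
  for (r in c(2, 21, 41)) {
    Cr <- tc$cov[r, , ]
    expect_equal(Cr, t(Cr))
    expect_gt(min(eigen(Cr, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10 * max(abs(Cr), 1e-300))
  }
})

test_that("EMRE equals the rate equations for unimolecular networks", {
  net <- make_paper_model("linear_chain")
  tc <- emre_timecourse(net, solver_config(t_final = 5, n_points = 21))
  expect_equal(tc$emre_mean, tc$phi, tolerance = 1e-9)
  st <- steady_state(net)
  expect_equal(as.numeric(st$emre_ss), as.numeric(st$phi_ss),
               tolerance = 1e-12)
})

test_that("the EMRE correction scales as inverse volume", {
  vols <- 1e-17 * 4^(0:3)
  dS <- vapply(vols, function(v) {
    st <- steady_state(make_paper_model("F2", volume = v))
    as.numeric(st$emre_ss["S"] - st$phi_ss["S"])
  }, 0)
  fit <- stats::lm(log(dS) ~ log(vols))
  expect_close(unname(stats::coef(fit)[2]), -1, 0.05)
  # doubling the volume halves the correction
  expect_close(dS[1] / dS[2], 4, 1e-3)
})

test_that("solved system sizes count N, N(N+1)/2 and N extra equations", {
  net <- make_paper_model("F1")
  prob <- ssenoise:::sse_problem(net)
  ni <- prob$ni
  phi0 <- initial_state(net)
  expect_length(ssenoise:::level_state0(prob, "re", phi0), ni)
  expect_length(ssenoise:::level_state0(prob, "lna", phi0),
                ni + ni * (ni + 1) / 2)
  expect_length(ssenoise:::level_state0(prob, "emre", phi0),
                ni + ni * (ni + 1) / 2 + ni)
  # conservation reduction removed exactly one species here
  expect_identical(ni, n_species(net) - 1L)
})

test_that("noise summaries define CV and correlation consistently", {
  st <- steady_state(make_paper_model("F1"))
  ns <- noise_summaries(list(phi = st$phi_ss, cov = st$cov_ss))
  expect_equal(unname(ns$cv), as.numeric(ns$sd / st$phi_ss))
  expect_equal(unname(diag(ns$corr)), rep(1, 4))
  expect_true(all(abs(ns$corr) <= 1 + 1e-12))
  # enzyme and complex fluctuations are perfectly anti-correlated
  # (conservation: xi_E = -xi_ES)
  expect_close(ns$corr["E", "ES"], -1, 1e-9)
  # zero-variance species get correlation 0 with a flag
  ns0 <- noise_summaries(list(phi = c(a = 1, b = 2),
                              cov = matrix(c(1, 0, 0, 0), 2,
                                           dimnames = list(c("a", "b"),
                                                           c("a", "b")))))
  expect_true(ns0$zero_variance[["b"]])
  expect_equal(ns0$corr["a", "b"], 0)
})

test_that("the critical-volume closed form matches an EMRE bisection", {
  k_in <- 1.8e-5; k_out <- 7; k1 <- 5e7; km1 <- 5; k2 <- 5; E_T <- 4e-6
  Oc <- critical_volume_mm(k_in, k_out, k1, km1, k2, E_T)
  # independent oracle: bisection on sign([S]_EMRE - [P]_EMRE) over volume
  gap <- function(v) {
    st <- steady_state(make_paper_model("F1", volume = v))
    as.numeric(st$emre_ss["S"] - st$emre_ss["P"])
  }
  lo <- 1e-18; hi <- 1e-15
  expect_gt(gap(lo), 0)
  expect_lt(gap(hi), 0)
  for (i in 1:25) {
    mid <- sqrt(lo * hi)
    if (gap(mid) > 0) lo <- mid else hi <- mid
  }
  expect_close(as.numeric(Oc), sqrt(lo * hi), 0.01)
  # ordering flips across the critical volume
  expect_gt(gap(as.numeric(Oc) / 3), 0)   # substrate above product below Oc
  expect_lt(gap(as.numeric(Oc) * 3), 0)   # product above substrate above Oc
  expect_close(attr(Oc, "saturation"), (k_in / k2) / E_T, 1e-12)
  # closed form is homogeneous of degree -1 in the concentration gap:
  # scaling all concentration-like inputs by c scales Omega_c by 1/c
  cfac <- 2
  Oc2 <- critical_volume_mm(k_in * cfac, k_out, k1 / cfac, km1, k2,
                            E_T * cfac)
  expect_close(as.numeric(Oc2), as.numeric(Oc) / cfac, 1e-9)
  # saturated regime has no steady state
  expect_error(critical_volume_mm(3e-5, k_out, k1, km1, k2, E_T),
               "saturated")
})

test_that("breakdown volumes are flagged, not fatal", {
  # far below the critical volume the EMRE substrate correction is huge;
  # shrink the volume until some mean goes negative
  st <- steady_state(make_paper_model("F2", volume = 3e-19))
  expect_true(st$breakdown ||
                all(as.numeric(st$emre_ss) >= 0))  # either flagged or valid
  # inversion flags mark reordered pairs in F2
  st2 <- steady_state(make_paper_model("F2"))
  expect_true(st2$inversion_flag["S", "P"])
  expect_false(st2$inversion_flag["E", "ES"])
})
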