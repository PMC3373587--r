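# Numerical solution of the rate equations, the LNA covariance and the
# EMRE mean corrections, in time-course and steady-state modes.
#
# All three levels integrate the conservation-reduced system: the
# independent concentrations phi (N - M equations), the upper triangle of
# the xi-frame covariance Sigma (ni (ni + 1) / 2), and the EMRE correction
# delta (ni).  Sigma is propagated in the fluctuation frame and scaled to
# concentration covariance C = Sigma / omega only at output, so the system
# size never appears inside the LNA right-hand side.

#' Solver configuration
#'
#' @param t_final Final model time of integration.
#' @param n_points Number of equally spaced output points (>= 2).
#' @param abs_tol,rel_tol Absolute/relative local error tolerances of the
#'   adaptive integrator.
#' @param max_newton_iter Maximum damped-Newton iterations for steady-state
#'   search.
#' @param newton_tol Convergence threshold on the rate-equation residual.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(t_final = 10, n_points = 200, abs_tol = 1e-9,
                          rel_tol = 1e-6, max_newton_iter = 100L,
                          newton_tol = 1e-9) {
  stopifnot(t_final > 0, n_points >= 2, abs_tol > 0, rel_tol > 0,
            newton_tol > 0, max_newton_iter >= 1)
  structure(list(t_final = t_final, n_points = as.integer(n_points),
                 abs_tol = abs_tol, rel_tol = rel_tol,
                 max_newton_iter = as.integer(max_newton_iter),
                 newton_tol = newton_tol), class = "solver_config")
}

# Assemble the reduced problem: tensors, conservation structure, indices.
sse_problem <- function(net, tensors = NULL) {
  if (is.null(tensors)) tensors <- sse_coefficients(net)
  cons <- find_conservation_laws(net)
  ni <- length(cons$independent_idx)
  iu <- which(upper.tri(diag(ni), diag = TRUE), arr.ind = TRUE)
  list(net = net, tensors = tensors, cons = cons, w = system_size(net),
       N = n_species(net), ni = ni, ind = cons$independent_idx,
       L = cons$L, iu = iu, nf = nrow(iu))
}

unpack_sym <- function(v, iu, ni) {
  Sg <- matrix(0, ni, ni)
  Sg[iu] <- v
  Sg + t(Sg) - diag(diag(Sg), ni)
}

# Right-hand side at the requested level ("re", "lna", "emre").
sse_rhs <- function(prob, level) {
  ni <- prob$ni; nf <- prob$nf; iu <- prob$iu
  L <- prob$L; ind <- prob$ind; w <- prob$w
  tensors <- prob$tensors; Smat <- tensors$S
  function(t, y, parms) {
    phi <- prob$cons$offset + as.numeric(L %*% y[seq_len(ni)])
    ev <- eval_tensors(tensors, phi)
    dphi <- as.numeric(Smat %*% ev$F)[ind]
    if (level == "re") return(list(dphi))
    Ar <- (ev$A %*% L)[ind, , drop = FALSE]
    Sg <- unpack_sym(y[ni + seq_len(nf)], iu, ni)
    dSg <- Ar %*% Sg + Sg %*% t(Ar) + ev$D[ind, ind, drop = FALSE]
    if (level == "lna") return(list(c(dphi, dSg[iu])))
    Sfull <- L %*% Sg %*% t(L)
    delta <- y[ni + nf + seq_len(ni)]
    Delta <- emre_delta_from_eval(tensors, ev, Sfull)
    ddelta <- as.numeric(Ar %*% delta) + Delta[ind] / w
    list(c(dphi, dSg[iu], ddelta))
  }
}

level_state0 <- function(prob, level, phi0, Sigma0 = NULL) {
  y <- phi0[prob$ind]
  if (level == "re") return(y)
  S0 <- if (is.null(Sigma0)) matrix(0, prob$ni, prob$ni)
        else Sigma0[prob$ind, prob$ind, drop = FALSE]
  y <- c(y, S0[prob$iu])
  if (level == "emre") y <- c(y, numeric(prob$ni))
  y
}

run_sse_ode <- function(prob, level, config, initial = NULL, Sigma0 = NULL) {
  phi0 <- if (is.null(initial)) initial_state(prob$net, "concentration")
          else initial
  if (any(phi0 < 0)) stop("initial concentrations must be non-negative")
  y0 <- level_state0(prob, level, phi0, Sigma0)
  times <- seq(0, config$t_final, length.out = config$n_points)
  sol <- deSolve::lsoda(y = y0, times = times, func = sse_rhs(prob, level),
                        parms = NULL, rtol = config$rel_tol,
                        atol = config$abs_tol)
  if (attr(sol, "istate")[1L] < 0)
    stop(sprintf("integration failed at t = %.6g", sol[nrow(sol), 1L]))
  sol
}

postprocess_tc <- function(prob, level, sol) {
  ni <- prob$ni; nf <- prob$nf
  P <- prob$cons$offset
  Tt <- sol[, 1L]
  nT <- length(Tt)
  ids <- prob$net$species$id
  N <- prob$N
  phi <- matrix(0, nT, N, dimnames = list(NULL, ids))
  for (r in seq_len(nT))
    phi[r, ] <- P + as.numeric(prob$L %*% sol[r, 1L + seq_len(ni)])
  res <- list(t = Tt, phi = phi, species = ids, level = level,
              omega = prob$w)
  if (level != "re") {
    cov <- array(0, c(nT, N, N), dimnames = list(NULL, ids, ids))
    for (r in seq_len(nT)) {
      Sg <- unpack_sym(sol[r, 1L + ni + seq_len(nf)], prob$iu, ni)
      cov[r, , ] <- (prob$L %*% Sg %*% t(prob$L)) / prob$w
    }
    res$cov <- cov
    res$sd <- sqrt(pmax(apply(cov, 1L, diag), 0))
    if (N > 1L) res$sd <- t(res$sd)
    dim(res$sd) <- c(nT, N); dimnames(res$sd) <- list(NULL, ids)
  }
  if (level == "emre") {
    emre <- matrix(0, nT, N, dimnames = list(NULL, ids))
    for (r in seq_len(nT))
      emre[r, ] <- phi[r, ] +
        as.numeric(prob$L %*% sol[r, 1L + ni + nf + seq_len(ni)])
    res$emre_mean <- emre
    if (any(emre < 0))
      res$breakdown <- TRUE
  }
  structure(res, class = "sse_timecourse")
}

#' Integrate the macroscopic rate equations
#'
#' Solves `dphi/dt = S F(phi)` on the conservation-reduced system with an
#' adaptive integrator (automatic stiff/non-stiff method switching).
#'
#' @param net A [reaction_network()].
#' @param config A [solver_config()].
#' @param initial Optional initial concentration vector; defaults to the
#'   network's initial state.
#' @param tensors Optional precomputed [sse_coefficients()].
#' @return An `sse_timecourse` with fields `t` and `phi`.
#' @export
integrate_re <- function(net, config = solver_config(), initial = NULL,
                         tensors = NULL) {
  prob <- sse_problem(net, tensors)
  postprocess_tc(prob, "re", run_sse_ode(prob, "re", config, initial))
}

#' Time course of the linear noise approximation
#'
#' Jointly integrates the rate equations and the fluctuation covariance
#' `dSigma/dt = A Sigma + Sigma A^T + D` (upper triangle only), mapping to
#' the concentration covariance `C = Sigma / omega` at output.
#'
#' @inheritParams integrate_re
#' @param Sigma0 Optional initial xi-frame covariance (defaults to the
#'   deterministic initial condition `Sigma = 0`).
#' @return An `sse_timecourse` with fields `t`, `phi`, `cov`, `sd`.
#' @export
lna_timecourse <- function(net, config = solver_config(), initial = NULL,
                           Sigma0 = NULL, tensors = NULL) {
  prob <- sse_problem(net, tensors)
  postprocess_tc(prob, "lna",
                 run_sse_ode(prob, "lna", config, initial, Sigma0))
}

#' Time course of the effective mesoscopic rate equations
#'
#' Integrates the EMRE correction `d delta/dt = A delta + Delta(phi, Sigma)
#' / omega` jointly with the rate equations and the LNA covariance, and
#' returns `emre_mean = phi + delta`.  Negative EMRE means are flagged
#' (`breakdown = TRUE`) rather than treated as fatal, since locating the
#' breakdown volume is itself informative.
#'
#' @inheritParams lna_timecourse
#' @return An `sse_timecourse` with fields `t`, `phi`, `cov`, `sd`,
#'   `emre_mean`.
#' @export
emre_timecourse <- function(net, config = solver_config(), initial = NULL,
                            Sigma0 = NULL, tensors = NULL) {
  prob <- sse_problem(net, tensors)
  postprocess_tc(prob, "emre",
                 run_sse_ode(prob, "emre", config, initial, Sigma0))
}

#' Steady state of the rate equations by damped Newton iteration
#'
#' Finds a non-negative root of the conservation-reduced rate equations by
#' Newton-Raphson with backtracking line search on the squared residual
#' norm.  If the iteration stalls from the supplied guess, the rate
#' equations are pre-integrated for a few characteristic times and the
#' search restarted.
#'
#' @param net A [reaction_network()].
#' @param config A [solver_config()]; `newton_tol` is the convergence
#'   threshold on `max(abs(S F(phi)))`.
#' @param guess Optional initial concentration vector.
#' @param line_search Set `FALSE` to disable the backtracking safeguard
#'   (plain Newton), mainly useful for demonstrating why it is needed.
#' @param tensors Optional precomputed [sse_coefficients()].
#' @return Named concentration vector `phi_ss` with attribute `residual`.
#' @export
steady_state_re <- function(net, config = solver_config(), guess = NULL,
                            line_search = TRUE, tensors = NULL) {
  prob <- sse_problem(net, tensors)
  phi0 <- if (is.null(guess)) initial_state(prob$net, "concentration") else guess
  if (any(phi0 < 0)) stop("guess must be non-negative")
  attempt <- function(y) newton_reduced(prob, y, config, line_search)
  y <- phi0[prob$ind]
  res <- attempt(y)
  if (!res$converged) {
    # pre-integrate for ~10 characteristic times of the fastest decay
    cfg2 <- config
    ev <- eval_tensors(prob$tensors, prob$cons$offset + as.numeric(prob$L %*% y))
    Ar <- (ev$A %*% prob$L)[prob$ind, , drop = FALSE]
    rate <- max(abs(Re(eigen(Ar, only.values = TRUE)$values)), 1e-8)
    cfg2$t_final <- 10 / min(abs(Re(eigen(Ar, only.values = TRUE)$values))[
      abs(Re(eigen(Ar, only.values = TRUE)$values)) > 1e-12], na.rm = TRUE)
    if (!is.finite(cfg2$t_final)) cfg2$t_final <- 10 / rate
    cfg2$n_points <- 2L
    sol <- run_sse_ode(prob, "re", cfg2, phi0)
    y <- sol[nrow(sol), 1L + seq_len(prob$ni)]
    res <- attempt(y)
  }
  if (!res$converged)
    stop("Newton iteration did not converge; consider pre-integrating the rate equations")
  phi <- prob$cons$offset + as.numeric(prob$L %*% res$y)
  if (any(phi < -config$newton_tol))
    stop("steady state has negative components")
  phi <- pmax(phi, 0)
  names(phi) <- prob$net$species$id
  structure(phi, residual = res$resid)
}

newton_reduced <- function(prob, y, config, line_search) {
  resid_fun <- function(y) {
    phi <- prob$cons$offset + as.numeric(prob$L %*% y)
    ev <- eval_tensors(prob$tensors, phi)
    list(r = as.numeric(prob$tensors$S %*% ev$F)[prob$ind],
         Ar = (ev$A %*% prob$L)[prob$ind, , drop = FALSE])
  }
  scale <- max(abs(y), 1e-30)
  for (it in seq_len(config$max_newton_iter)) {
    rr <- resid_fun(y)
    if (max(abs(rr$r)) < config$newton_tol)
      return(list(converged = TRUE, y = y, resid = max(abs(rr$r))))
    step <- tryCatch(solve(rr$Ar, -rr$r), error = function(e) NULL)
    if (is.null(step)) return(list(converged = FALSE, y = y))
    if (line_search) {
      f0 <- sum(rr$r^2); lam <- 1
      repeat {
        ynew <- y + lam * step
        fnew <- tryCatch(sum(resid_fun(ynew)$r^2), error = function(e) Inf)
        if (is.finite(fnew) && fnew < f0 * (1 - 1e-4 * lam)) break
        lam <- lam / 2
        if (lam < 1e-12) return(list(converged = FALSE, y = y))
      }
      y <- y + lam * step
    } else {
      y <- y + step
    }
  }
  rr <- resid_fun(y)
  list(converged = max(abs(rr$r)) < config$newton_tol, y = y,
       resid = max(abs(rr$r)))
}

#' Steady-state LNA covariance
#'
#' Solves the algebraic Lyapunov equation `A Sigma + Sigma A^T + D = 0` on
#' the conservation-reduced system (by flattening the symmetric unknown)
#' and maps back to the concentration covariance `C = Sigma / omega`.
#'
#' @param net A [reaction_network()].
#' @param phi_ss Steady-state concentrations from [steady_state_re()].
#' @param tensors Optional precomputed [sse_coefficients()].
#' @return `N x N` concentration covariance matrix with attribute
#'   `Sigma_xi` (the xi-frame covariance).
#' @export
lna_steady <- function(net, phi_ss, tensors = NULL) {
  prob <- sse_problem(net, tensors)
  ev <- eval_tensors(prob$tensors, phi_ss)
  Ar <- (ev$A %*% prob$L)[prob$ind, , drop = FALSE]
  lam <- eigen(Ar, only.values = TRUE)$values
  if (any(Re(lam) >= 0))
    stop("Jacobian is not Hurwitz at the supplied steady state; LNA covariance undefined")
  ni <- prob$ni
  K <- kronecker(diag(ni), Ar) + kronecker(Ar, diag(ni))
  Sg <- matrix(solve(K, -as.vector(ev$D[prob$ind, prob$ind, drop = FALSE])),
               ni, ni)
  Sg <- (Sg + t(Sg)) / 2
  Sfull <- prob$L %*% Sg %*% t(prob$L)
  dimnames(Sfull) <- list(prob$net$species$id, prob$net$species$id)
  resid <- Ar %*% Sg + Sg %*% t(Ar) + ev$D[prob$ind, prob$ind]
  C <- Sfull / prob$w
  attr(C, "Sigma_xi") <- Sfull
  attr(C, "lyapunov_residual") <- max(abs(resid)) / max(abs(Sg), 1e-300)
  C
}

#' Steady-state EMRE means
#'
#' Solves `A delta = -Delta(phi_ss, Sigma) / omega` on the reduced system
#' and returns `phi_ss + delta`.  Negative means are flagged via the
#' `breakdown` attribute.
#'
#' @param net A [reaction_network()].
#' @param phi_ss Steady-state concentrations.
#' @param C_ss Concentration covariance from [lna_steady()].
#' @param tensors Optional precomputed [sse_coefficients()].
#' @return Named vector of EMRE mean concentrations, with attribute
#'   `delta`.
#' @export
emre_steady <- function(net, phi_ss, C_ss, tensors = NULL) {
  prob <- sse_problem(net, tensors)
  Sigma <- attr(C_ss, "Sigma_xi")
  if (is.null(Sigma)) Sigma <- as.matrix(C_ss) * prob$w
  ev <- eval_tensors(prob$tensors, phi_ss)
  Ar <- (ev$A %*% prob$L)[prob$ind, , drop = FALSE]
  Delta <- emre_delta_from_eval(prob$tensors, ev, Sigma)
  dred <- solve(Ar, -Delta[prob$ind] / prob$w)
  delta <- as.numeric(prob$L %*% dred)
  out <- phi_ss + delta
  names(out) <- prob$net$species$id
  attr(out, "delta") <- delta
  if (any(out < 0)) attr(out, "breakdown") <- TRUE
  out
}

#' Noise summaries of a steady-state or time-course result
#'
#' Coefficients of variation `CV_i = sd_i / phi_i` (RE means, consistent
#' with the LNA) and Pearson correlation matrices
#' `corr_ij = C_ij / sqrt(C_ii C_jj)`.  Species with zero variance get
#' correlation 0 and are flagged.
#'
#' @param x An `sse_timecourse` (uses the final time point) or a list with
#'   elements `phi` and `cov`.
#' @return List with `cv`, `corr`, `sd`, `zero_variance`.
#' @export
noise_summaries <- function(x) {
  if (inherits(x, "sse_timecourse")) {
    nT <- length(x$t)
    C <- x$cov[nT, , ]
    phi <- x$phi[nT, ]
  } else {
    C <- as.matrix(x$cov); phi <- x$phi
  }
  v <- pmax(diag(as.matrix(C)), 0)
  sd <- sqrt(v)
  cv <- ifelse(phi > 0, sd / phi, NA_real_)
  zero <- v <= 0
  dd <- outer(sd, sd)
  corr <- ifelse(dd > 0, as.matrix(C) / dd, 0)
  diag(corr)[!zero] <- 1
  list(cv = cv, corr = corr, sd = sd, zero_variance = zero)
}

#' Full steady-state analysis
#'
#' Convenience wrapper running [steady_state_re()], [lna_steady()],
#' [emre_steady()] and [noise_summaries()] in one call.
#'
#' @param net A [reaction_network()].
#' @param config A [solver_config()].
#' @param guess Optional Newton starting point.
#' @return An object of class `sse_steady_state` with fields `phi_ss`,
#'   `cov_ss`, `emre_ss`, `cv`, `sd`, `corr`, `inversion_flag` (logical
#'   matrix of ordered species pairs whose RE concentration ordering is
#'   reversed by the EMRE).
#' @examples
#' st <- steady_state(make_paper_model("F1"))
#' print(st)
#' @export
steady_state <- function(net, config = solver_config(), guess = NULL) {
  tensors <- sse_coefficients(net)
  phi_ss <- steady_state_re(net, config, guess, tensors = tensors)
  C <- lna_steady(net, phi_ss, tensors = tensors)
  emre <- emre_steady(net, phi_ss, C, tensors = tensors)
  ns <- noise_summaries(list(phi = phi_ss, cov = C))
  N <- length(phi_ss)
  inv <- matrix(FALSE, N, N, dimnames = dimnames(C))
  for (i in seq_len(N)) for (j in seq_len(N))
    inv[i, j] <- sign(phi_ss[i] - phi_ss[j]) * sign(emre[i] - emre[j]) < 0
  structure(list(phi_ss = phi_ss, cov_ss = C, emre_ss = emre,
                 cv = ns$cv, sd = ns$sd, corr = ns$corr,
                 inversion_flag = inv,
                 breakdown = isTRUE(attr(emre, "breakdown")),
                 species = net$species$id, omega = system_size(net)),
            class = "sse_steady_state")
}

#' @export
print.sse_steady_state <- function(x, digits = 4, ...) {
  cat("Steady-state analysis (RE / LNA / EMRE)\n")
  tab <- data.frame(species = x$species,
                    RE = signif(as.numeric(x$phi_ss), digits),
                    EMRE = signif(as.numeric(x$emre_ss), digits),
                    SD = signif(as.numeric(x$sd), digits),
                    CV = signif(as.numeric(x$cv), digits))
  print(tab, row.names = FALSE)
  if (x$breakdown)
    cat("warning: negative EMRE means; below the EMRE breakdown volume\n")
  invisible(x)
}

#' @export
print.sse_timecourse <- function(x, ...) {
  cat(sprintf("SSE time course (%s level): %d species, %d time points on [0, %.4g]\n",
              x$level, length(x$species), length(x$t), max(x$t)))
  if (isTRUE(x$breakdown))
    cat("warning: negative EMRE means; below the EMRE breakdown volume\n")
  invisible(x)
}

#' Critical volume of the substrate-input Michaelis-Menten reaction
#'
#' For the five-reaction substrate-input Michaelis-Menten scheme
#' (input, binding, unbinding, catalysis, product removal) the steady-state
#' EMRE correction vanishes for enzyme, complex and product, while the
#' substrate correction is strictly positive and scales as `1 / Omega`:
#'
#' ```
#' delta_S = k2 k_in^2 (k2 + k_minus1) /
#'   ( omega (E_T k2 - k_in)
#'     (E_T^2 k1 k2^2 - 2 E_T k1 k2 k_in + E_T k2^3 + E_T k2^2 k_minus1
#'      + k1 k_in^2) )
#' ```
#'
#' with `omega = Omega N_A` (obtained by solving the steady-state Lyapunov
#' equation and the EMRE linear system in closed form).  There is therefore
#' a unique compartment volume at which the EMRE substrate and product
#' concentrations coincide, `delta_S(Omega_c) = phi_P - phi_S`; below it
#' the rate-equation ordering of substrate and product is inverted.
#'
#' @param k_in Substrate input rate (concentration/time).
#' @param k_out Product removal rate constant (1/time).
#' @param k1 Binding rate constant (1/(concentration time)).
#' @param k_minus1 Unbinding rate constant (1/time).
#' @param k2 Catalytic rate constant (1/time).
#' @param E_T Total enzyme concentration.
#' @return Critical volume in litres, with attribute `saturation` (the
#'   fractional enzyme saturation at steady state).
#' @export
critical_volume_mm <- function(k_in, k_out, k1, k_minus1, k2, E_T) {
  if (k_in >= k2 * E_T)
    stop("saturated regime: no rate-equation steady state (k_in >= k2 * E_T)")
  KM <- (k_minus1 + k2) / k1
  phi_ES <- k_in / k2
  phi_E <- E_T - phi_ES
  phi_S <- KM * phi_ES / phi_E
  phi_P <- k_in / k_out
  if (phi_P <= phi_S)
    stop("product does not exceed substrate at the macroscopic steady state; no inversion volume")
  # omega * delta_S, independent of volume
  c_S <- k2 * k_in^2 * (k2 + k_minus1) /
    ((E_T * k2 - k_in) *
       (E_T^2 * k1 * k2^2 - 2 * E_T * k1 * k2 * k_in + E_T * k2^3 +
          E_T * k2^2 * k_minus1 + k1 * k_in^2))
  omega_c <- c_S / (phi_P - phi_S)
  Omega_c <- omega_c / AVOGADRO
  attr(Omega_c, "saturation") <- phi_ES / E_T
  Omega_c
}
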