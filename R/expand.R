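# Construction of the system-size-expansion objects by exact symbolic
# differentiation of the macroscopic rate functions.
#
# Conventions.  Let omega = system_size(net) and phi the concentration
# vector.  Writing the microscopic propensity of reaction j as h_j(n) and
# g_j(phi, omega) = h_j(omega * phi) / omega, the expansion in powers of
# 1/omega is
#
#     g_j = f0_j(phi) + (1/omega) f1_j(phi) + O(omega^-2).
#
# For mass-action kinetics with reactant stoichiometries s_ij the
# falling-factorial propensity gives the exact finite series
#
#     f0_j = k_j prod_i phi_i^s_ij
#     f1_j = -k_j sum_i C(s_ij, 2) phi_i^(s_ij - 1) prod_{l != i} phi_l^s_lj
#
# (only species entering a reaction more than once contribute to f1).
# Custom propensities whose count -> concentration substitution leaves no
# residual omega dependence have f0 equal to the substituted expression and
# all higher coefficients zero; anything else falls back to evaluating the
# microscopic propensity at the deterministic concentrations with a warning.

prod_expr <- function(factors) {
  factors <- factors[!vapply(factors, function(f) identical(f, 1), TRUE)]
  if (!length(factors)) return(1)
  Reduce(function(a, b) call("*", a, b), factors)
}

pow_expr <- function(sym, p) {
  if (p == 0L) 1 else if (p == 1L) sym else call("^", sym, p)
}

#' Expand the propensities of a network in inverse powers of system size
#'
#' Computes, for every reaction, the macroscopic rate function `f0` and the
#' first finite-size coefficient `f1` of the propensity expansion (see the
#' package vignette for the underlying series).  Mass-action reactions are
#' expanded exactly from their falling-factorial propensities; custom
#' symbolic propensities are converted by the substitution
#' `n = omega * phi` and accepted when the result carries no residual
#' dependence on the system size, in which case all coefficients beyond
#' `f0` vanish.  Propensities that cannot be expanded are flagged
#' `expandable = FALSE` and enter downstream solvers only through their
#' numeric value at the deterministic concentrations.
#'
#' @param net A validated [reaction_network()].
#' @return An object of class `propensity_expansion`: per reaction, `f0`
#'   and `f1` (R expressions over species-id symbols holding
#'   concentrations), `expandable`, and `higher_zero` (TRUE when all
#'   coefficients beyond `f1` vanish identically).
#' @export
expand_propensity <- function(net) {
  ids <- net$species$id
  w <- system_size(net)
  out <- vector("list", n_reactions(net))
  warn <- character(0)
  for (j in seq_len(n_reactions(net))) {
    rx <- net$reactions[[j]]
    if (rx$type == "mass_action") {
      s <- rx$reactants
      f0 <- prod_expr(c(list(rx$rate),
                        lapply(names(s), function(i) pow_expr(as.name(i), s[[i]]))))
      terms <- list()
      for (i in names(s)) {
        ci <- choose(s[[i]], 2)
        if (ci == 0) next
        rest <- lapply(setdiff(names(s), i),
                       function(l) pow_expr(as.name(l), s[[l]]))
        terms <- c(terms, list(prod_expr(c(list(-rx$rate * ci),
                                           list(pow_expr(as.name(i), s[[i]] - 1L)),
                                           rest))))
      }
      f1 <- if (!length(terms)) 0 else Reduce(function(a, b) call("+", a, b), terms)
      out[[j]] <- list(f0 = f0, f1 = f1, expandable = TRUE,
                       higher_zero = TRUE)
    } else {
      # substitute counts by omega * phi, divide by omega
      subs <- stats::setNames(lapply(ids, function(i) call("*", quote(.omega), as.name(i))), ids)
      g <- call("/", substitute_values(rx$propensity, subs), quote(.omega))
      dep <- omega_dependent(g, ids, w)
      if (!dep) {
        out[[j]] <- list(f0 = g, f1 = 0, expandable = TRUE,
                         higher_zero = TRUE)
      } else {
        out[[j]] <- list(f0 = g, f1 = 0, expandable = FALSE,
                         higher_zero = TRUE)
        warn <- c(warn, sprintf(
          "propensity of reaction %s does not expand in powers of 1/omega; using its numeric value at the deterministic concentrations",
          rx$id))
      }
    }
  }
  structure(list(reactions = out, species = ids, omega = w,
                 warnings = warn), class = "propensity_expansion")
}

# Does expression g (over species ids, .omega and Omega) depend on the
# system size?  Probed numerically at fixed positive concentrations.
omega_dependent <- function(g, ids, w) {
  for (rep in 1:3) {
    phi <- 0.1 + ((seq_along(ids) * 7 + rep * 13) %% 17) / 10
    e1 <- eval_expr(g, ids, phi, 1e6)
    e2 <- eval_expr(g, ids, phi, 1e9)
    if (!is.finite(e1) || !is.finite(e2)) return(TRUE)
    if (abs(e1 - e2) > 1e-8 * max(1, abs(e1))) return(TRUE)
  }
  FALSE
}

eval_expr <- function(expr, ids, phi, omega) {
  env <- list2env(stats::setNames(as.list(phi), ids))
  assign(".omega", omega, envir = env)
  assign("Omega", omega, envir = env)
  eval(expr, env)
}

#' Symbolic SSE tensors of a reaction network
#'
#' Builds, by exact symbolic differentiation of the macroscopic rate
#' functions, all tensors needed by the rate equations, the LNA and the
#' EMRE: the rate vector `F`, the Jacobian
#' `A[i,k] = sum_j S[i,j] d f0_j / d phi_k`, the diffusion matrix
#' `D[i,k] = sum_j S[i,j] S[k,j] f0_j`, the per-reaction Hessians of `f0`,
#' and the `f1` coefficients entering the EMRE correction.
#'
#' @param net A [reaction_network()].
#' @param expansion Optionally a precomputed [expand_propensity()] result.
#' @return An object of class `sse_tensors` holding symbolic expressions
#'   and an evaluator; see [eval_tensors()].
#' @export
sse_coefficients <- function(net, expansion = expand_propensity(net)) {
  ids <- net$species$id
  N <- length(ids); R <- n_reactions(net)
  S <- stoich_matrix(net)
  f0 <- lapply(expansion$reactions, `[[`, "f0")
  f1 <- lapply(expansion$reactions, `[[`, "f1")
  expandable <- vapply(expansion$reactions, `[[`, TRUE, "expandable")
  # first derivatives: R x N list matrix
  df0 <- vector("list", R * N); dim(df0) <- c(R, N)
  for (j in seq_len(R)) for (k in seq_len(N))
    df0[[j, k]] <- if (expandable[j]) stats::D(f0[[j]], ids[k]) else 0
  # Hessians, stored sparsely per reaction as (k, l, expr) triples
  hess <- vector("list", R)
  for (j in seq_len(R)) {
    tri <- list()
    if (expandable[j]) {
      vars <- intersect(all.vars(f0[[j]]), ids)
      for (k in match(vars, ids)) for (l in match(vars, ids)) {
        if (l < k) next
        d2 <- stats::D(df0[[j, k]], ids[l])
        if (!identical(d2, 0) && !(is.numeric(d2) && d2 == 0))
          tri <- c(tri, list(list(k = k, l = l, expr = d2)))
      }
    }
    hess[[j]] <- tri
  }
  structure(list(species = ids, S = S, f0 = f0, f1 = f1, df0 = df0,
                 hess = hess, expandable = expandable,
                 omega = expansion$omega,
                 warnings = expansion$warnings),
            class = "sse_tensors")
}

#' Evaluate SSE tensors at a concentration vector
#'
#' @param tensors An [sse_coefficients()] object.
#' @param phi Concentration vector (network unit frame), length `N`.
#' @return A list with `F` (length R rate vector), `A` (N x N Jacobian),
#'   `D` (N x N diffusion matrix), `f1` (length R), and `hess` (the raw
#'   sparse Hessian evaluations used by [emre_delta_vector()]).
#' @export
eval_tensors <- function(tensors, phi) {
  ids <- tensors$species
  N <- length(ids); R <- length(tensors$f0)
  env <- list2env(stats::setNames(as.list(phi), ids))
  assign(".omega", tensors$omega, envir = env)
  assign("Omega", tensors$omega, envir = env)
  ev <- function(e) if (is.numeric(e)) e else eval(e, env)
  Fv <- vapply(tensors$f0, ev, 0)
  f1v <- vapply(tensors$f1, ev, 0)
  Jf <- matrix(0, R, N)
  for (j in seq_len(R)) for (k in seq_len(N)) {
    d <- tensors$df0[[j, k]]
    if (!identical(d, 0)) Jf[j, k] <- ev(d)
  }
  A <- tensors$S %*% Jf
  D <- tensors$S %*% (Fv * t(tensors$S))
  hv <- lapply(tensors$hess, function(tri)
    lapply(tri, function(t3) list(k = t3$k, l = t3$l, v = ev(t3$expr))))
  list(F = Fv, A = A, D = D, f1 = f1v, hess = hv)
}

#' EMRE coupling vector
#'
#' The vector `Delta(phi, Sigma)` coupling the mean concentrations to the
#' fluctuation covariance in the EMRE:
#' `Delta_i = sum_j S[i,j] ( 1/2 sum_kl d2 f0_j/dphi_k dphi_l Sigma[k,l] + f1_j )`.
#' For purely unimolecular mass-action networks it vanishes identically;
#' for elementary networks it is non-zero only through dimerizing species
#' (the `f1` term) and the curvature of bimolecular rates.
#'
#' @param tensors An [sse_coefficients()] object.
#' @param phi Concentration vector.
#' @param Sigma Fluctuation covariance matrix in the xi frame (i.e.
#'   `omega` times the concentration covariance), `N x N`.
#' @return Numeric length-`N` vector.
#' @export
emre_delta_vector <- function(tensors, phi, Sigma) {
  ev <- eval_tensors(tensors, phi)
  emre_delta_from_eval(tensors, ev, Sigma)
}

# internal fast path when tensors are already evaluated
emre_delta_from_eval <- function(tensors, ev, Sigma) {
  R <- length(ev$F)
  per_rx <- numeric(R)
  for (j in seq_len(R)) {
    acc <- ev$f1[j]
    for (t3 in ev$hess[[j]]) {
      contrib <- 0.5 * t3$v * Sigma[t3$k, t3$l]
      if (t3$l != t3$k) contrib <- 2 * contrib   # symmetric off-diagonal pair
      acc <- acc + contrib
    }
    per_rx[j] <- acc
  }
  as.numeric(tensors$S %*% per_rx)
}

#' Write the symbolic SSE objects as a plain-text equation listing
#'
#' One expression per line, species indexed by id: the macroscopic rates,
#' the Jacobian and diffusion entries, and the `f1` coefficients.
#'
#' @param tensors An [sse_coefficients()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_equations <- function(tensors, path) {
  ids <- tensors$species
  N <- length(ids)
  con <- file(path, "w"); on.exit(close(con))
  dp <- function(e) paste(deparse(e), collapse = " ")
  for (j in seq_along(tensors$f0))
    writeLines(sprintf("F[%d] = %s", j, dp(tensors$f0[[j]])), con)
  for (j in seq_along(tensors$f1))
    if (!identical(tensors$f1[[j]], 0))
      writeLines(sprintf("f1[%d] = %s", j, dp(tensors$f1[[j]])), con)
  for (i in seq_len(N)) for (k in seq_len(N)) {
    terms <- character(0)
    for (j in seq_along(tensors$f0)) {
      if (tensors$S[i, j] == 0 || identical(tensors$df0[[j, k]], 0)) next
      terms <- c(terms, sprintf("%d*(%s)", tensors$S[i, j], dp(tensors$df0[[j, k]])))
    }
    if (length(terms))
      writeLines(sprintf("A[%s,%s] = %s", ids[i], ids[k],
                         paste(terms, collapse = " + ")), con)
  }
  invisible(path)
}
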