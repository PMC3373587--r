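eval_at <- function(expr, vals) eval(expr, as.list(vals))

test_that("mass-action propensities expand to the exact closed forms", {
  # dimerization 2X -> 0: f0 = k phi^2, f1 = -k phi
  net <- make_paper_model("dimerization")
  ex <- expand_propensity(net)
  k <- net$reactions[[2]]$rate
  for (phi in c(0.3e-6, 1.7e-6)) {
    expect_equal(eval_at(ex$reactions[[2]]$f0, c(X = phi)), k * phi^2)
    expect_equal(eval_at(ex$reactions[[2]]$f1, c(X = phi)), -k * phi)
  }
  # unimolecular: f1 vanishes identically
  expect_identical(ex$reactions[[1]]$f1, 0)   # zeroth order input
  netl <- make_paper_model("linear_chain")
  exl <- expand_propensity(netl)
  for (r in exl$reactions) expect_identical(r$f1, 0)
  # bimolecular with distinct species: f1 = 0 as well
  net1 <- make_paper_model("F1")
  ex1 <- expand_propensity(net1)
  expect_identical(ex1$reactions[[2]]$f1, 0)
})

test_that("finite-size residual of the mass-action expansion is second order", {
  # |h(omega phi)/omega - f0 - f1/omega| must shrink like omega^-2
  net <- make_paper_model("dimerization")
  ex <- expand_propensity(net)
  k <- net$reactions[[2]]$rate
  phi <- 1.3e-6
  resid <- function(w) {
    n <- w * phi
    h <- k * n * (n - 1) / w      # falling-factorial count propensity
    abs(h / w - (k * phi^2) + k * phi / w)
  }
  # exact series here: the residual is pure floating-point noise
  expect_lt(resid(1e8), 1e-14 * k * phi^2)
  # trimolecular check where the series truncates at omega^-2
  net3 <- reaction_network(1e-15)
  net3 <- add_species(net3, "X", 2e-6)
  net3 <- add_reaction(net3, "3 X -> 0", rate = 1e12)
  ex3 <- expand_propensity(net3)
  f0 <- eval_at(ex3$reactions[[1]]$f0, c(X = phi))
  f1 <- eval_at(ex3$reactions[[1]]$f1, c(X = phi))
  expect_equal(f0, 1e12 * phi^3)
  expect_equal(f1, -1e12 * 3 * phi^2)
  resid3 <- function(w) {
    n <- w * phi
    abs(1e12 * n * (n - 1) * (n - 2) / w^3 - f0 - f1 / w)
  }
  expect_close(resid3(1e8) / resid3(1e9), 100, 1e-6)
})

test_that("non-elementary propensities follow the substitution rule", {
  # effective Michaelis-Menten propensity: count -> concentration
  # substitution leaves no system-size dependence, so f0 is the
  # macroscopic rate and all higher coefficients vanish
  Vmax <- 2e-6; KM <- 0.5e-6
  net <- reaction_network(1e-15)
  net <- add_species(net, "S", 1e-6)
  net <- add_reaction(net, "0 -> S", rate = 1e-6)
  net <- add_reaction(net, "S -> 0",
    propensity = bquote(.(Vmax) * Omega * (S / Omega) / (.(KM) + S / Omega)))
  ex <- expand_propensity(net)
  expect_true(ex$reactions[[2]]$expandable)
  expect_identical(ex$reactions[[2]]$f1, 0)
  ten <- sse_coefficients(net, ex)
  ev <- eval_tensors(ten, c(S = 1e-6))
  expect_equal(ev$F[2], Vmax * 1e-6 / (KM + 1e-6))
  expect_length(ex$warnings, 0)
  # a propensity with residual size dependence degrades gracefully
  net2 <- reaction_network(1e-15)
  net2 <- add_species(net2, "X", 1e-6)
  net2 <- add_reaction(net2, "0 -> X", rate = 1e-6)
  net2 <- add_reaction(net2, "X -> 0", propensity = quote(2 * X * X))
  ex2 <- expand_propensity(net2)
  expect_false(ex2$reactions[[2]]$expandable)
  expect_match(ex2$warnings, "does not expand")
})

test_that("Jacobian and diffusion agree with finite differences of the rates", {
  for (name in c("F1", "F3")) {
    net <- make_paper_model(name)
    ten <- sse_coefficients(net)
    S <- stoich_matrix(net)
    N <- nrow(S)
    ids <- net$species$id
    for (p in 1:5) {
      phi <- (1 + (seq_len(N) * 3 + p * 7) %% 11) * 2e-7
      names(phi) <- ids
      ev <- eval_tensors(ten, phi)
      # diffusion from its definition
      Dref <- S %*% diag(ev$F) %*% t(S)
      expect_equal(unname(ev$D), unname(Dref), tolerance = 1e-12)
      # Jacobian of S F(phi) by central differences
      J <- matrix(0, N, N)
      for (kk in seq_len(N)) {
        h <- 1e-6 * phi[kk]
        pp <- phi; pm <- phi
        pp[kk] <- pp[kk] + h; pm[kk] <- pm[kk] - h
        J[, kk] <- as.numeric(S %*% (eval_tensors(ten, pp)$F -
                                       eval_tensors(ten, pm)$F)) / (2 * h)
      }
      expect_equal(unname(ev$A), J, tolerance = 1e-6)
      # D is symmetric PSD at non-negative concentrations
      expect_equal(unname(ev$D), unname(t(ev$D)))
      expect_gt(min(eigen(ev$D, symmetric = TRUE, only.values = TRUE)$values),
                -1e-12 * max(abs(ev$D)))
    }
  }
})

test_that("EMRE coupling vector has the expected structure", {
  # unimolecular network: Delta identically zero
  netl <- make_paper_model("linear_chain")
  tenl <- sse_coefficients(netl)
  phi <- c(X1 = 1e-6, X2 = 2e-6, X3 = 3e-6)
  Sig <- diag(3) * 1e-12
  expect_equal(emre_delta_vector(tenl, phi, Sig), rep(0, 3))
  # birth-death: linear propensities, Delta = 0
  netb <- make_paper_model("birth_death")
  tenb <- sse_coefficients(netb)
  expect_equal(emre_delta_vector(tenb, c(X = 1e-6), matrix(2e-12)), 0)
  # dimerization 2X -> 0 at rate k: f1 = -k phi and curvature 2k give
  # Delta = S (1/2 f0'' Sigma + f1) = -2 (k Sigma - k phi)
  netd <- make_paper_model("dimerization")
  tend <- sse_coefficients(netd)
  k <- netd$reactions[[2]]$rate
  phi <- 1.1e-6; Sg <- 4e-13
  expect_equal(emre_delta_vector(tend, c(X = phi), matrix(Sg)),
               -2 * (k * Sg - k * phi))
})

test_that("Jacobian of the MM model is Hurwitz at its steady state", {
  net <- make_paper_model("F1")
  ten <- sse_coefficients(net)
  cons <- find_conservation_laws(net)
  phi <- mm_flux_balance()
  ev <- eval_tensors(ten, phi)
  Ar <- (ev$A %*% cons$L)[cons$independent_idx, ]
  expect_true(all(Re(eigen(Ar, only.values = TRUE)$values) < 0))
})

test_that("equation listings export one expression per line", {
  net <- make_paper_model("birth_death")
  ten <- sse_coefficients(net)
  f <- tempfile()
  export_equations(ten, f)
  lines <- readLines(f)
  expect_true(any(grepl("^F\\[1\\] = ", lines)))
  expect_true(any(grepl("^A\\[X,X\\] = ", lines)))
})
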