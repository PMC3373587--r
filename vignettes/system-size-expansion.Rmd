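---
title: "Intrinsic noise from the system size expansion: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrinsic noise from the system size expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssenoise)
```

## The modelling problem

A well-mixed compartment of volume $\Omega$ contains $N$ chemical species
interacting through $R$ irreversible reactions. The mesoscopic state is the
vector of molecule counts $n$, and each reaction $j$ carries a propensity
$f_j(n, \Omega)$ such that $f_j\,dt$ is the probability that reaction $j$
fires in $[t, t+dt)$. The probability distribution over states evolves
under the chemical master equation (CME). The CME is exact but rarely
tractable: its state space is the set of all count vectors. Two
complementary routes around it are implemented here.

The first is exact stochastic simulation: sample paths of the jump process
(Gillespie's direct method, and the optimized direct method which reorders
the reaction search by firing frequency and updates only the propensities
connected to the fired reaction through a species dependency graph).
Ensemble averaging over paths estimates means, variances and correlations,
at a cost that grows with both the noise magnitude and the copy numbers.

The second is van Kampen's system size expansion (SSE). Writing
$\omega$ for the system size (the count per unit concentration:
$\Omega N_A$ for molar models) and splitting the instantaneous
concentration into a deterministic part and a fluctuation,
$n/\omega = \phi + \omega^{-1/2}\xi$, the CME expands in powers of
$\omega^{-1/2}$. Order by order this yields:

* **Rate equations (REs).** $\dot\phi = S F(\phi)$, with $S$ the
  stoichiometric matrix and $F$ the vector of macroscopic rate functions
  $f^{(0)}_j$ — the leading terms of the propensities per unit volume.
* **Linear noise approximation (LNA).** The fluctuation $\xi$ is Gaussian
  with covariance $\Sigma$ obeying
  $\dot\Sigma = A\Sigma + \Sigma A^T + D$, where
  $A_{ik} = \sum_j S_{ij}\, \partial f^{(0)}_j / \partial \phi_k$ is the
  Jacobian and $D = S\,\mathrm{diag}(F)\,S^T$ the diffusion matrix. The
  concentration covariance is $C = \Sigma / \omega$; standard deviations,
  coefficients of variation $\mathrm{CV}_i = \sqrt{C_{ii}}/\phi_i$ and
  Pearson correlations follow.
* **EMRE (effective mesoscopic rate equations).** The next order couples
  the mean back to the fluctuations. The mean concentration correction
  $\delta$ obeys $\dot\delta = A\delta + \Delta(\phi,\Sigma)/\omega$ with
  $$\Delta_i \;=\; \sum_j S_{ij}\Big(\tfrac12 \sum_{kl}
  \frac{\partial^2 f^{(0)}_j}{\partial\phi_k\,\partial\phi_l}\,\Sigma_{kl}
  \;+\; f^{(1)}_j\Big),$$
  and the EMRE mean is $\phi + \delta$. For networks containing only
  zeroth- and first-order reactions every term vanishes and the EMRE
  coincides with the REs; bimolecular steps and non-vanishing $f^{(1)}$
  generate genuine finite-volume corrections of order $\omega^{-1}$.

The expansion coefficients come from the propensities. For mass-action
kinetics with reactant multiplicities $s_{ij}$ the propensity is the
falling-factorial form, and substituting $n = \omega\phi$ gives an exact
finite series
$f_j(\omega\phi)/\omega = f^{(0)}_j + \omega^{-1} f^{(1)}_j + \dots$ with
$f^{(0)}_j = k_j \prod_i \phi_i^{s_{ij}}$ and
$f^{(1)}_j = -k_j \sum_i \binom{s_{ij}}{2} \phi_i^{s_{ij}-1}
\prod_{l\neq i}\phi_l^{s_{lj}}$; only species consumed more than once
(dimerization and higher) contribute to $f^{(1)}$. Non-elementary
propensities (Hill or Michaelis–Menten laws used as effective rates) are
handled by the substitution rule: if replacing counts by $\omega\phi$
leaves no residual $\omega$ dependence, the macroscopic rate equals the
microscopic one and all higher coefficients vanish; if a residual
dependence remains, the package falls back to evaluating the propensity at
the deterministic concentrations, records a warning on the expansion
object, and uses no higher-order terms. All derivatives entering $A$, $D$
and $\Delta$ are taken symbolically (exact differentiation of the rate
expressions), never by numerical differencing; symbolic and
finite-difference tensors are compared in the test suite instead.

These correctness checks were chosen to be *independent oracles*: the
linear birth–death process, whose stationary CME solution is Poisson
(variance equals mean, no EMRE correction); pure dimerization, whose
stationary factorial-moment balance can be computed exactly by hand and
reproduces the implemented $\Delta$; and flux-balance algebra for the
enzyme models, solved without any ODE machinery.

## Conservation analysis

Left null vectors of $S$ are conserved: $b^T S = 0$ implies $b^T n$ never
changes. The basis is computed by exact rational Gaussian elimination
(integer numerators and denominators, reduced by gcd at every step), so a
law either holds exactly or is not reported — there is no floating-point
rank tolerance to choose. One pivot species per law is eliminated and all
solvers run on the reduced system; the reduction also removes the zero
eigenvalues that would otherwise make the steady-state Lyapunov equation
singular. The reduced and full formulations agree by construction and the
reconstruction map is affine and exact.

## Numerical choices

* **Integration.** All SSE levels (REs: $n_i$ equations; plus LNA:
  $n_i(n_i+1)/2$ for the upper triangle of $\Sigma$; plus EMRE: $n_i$
  more) are integrated jointly with `deSolve::lsoda`, an adaptive solver
  that switches automatically between non-stiff and stiff methods — the
  practical equivalent of an explicit pair with a stiff fallback.
  Default tolerances are $10^{-6}$ relative, $10^{-9}$ absolute.
  $\Sigma$ is propagated in the $\xi$ frame and scaled to concentration
  covariance only at output, so $\omega$ never enters the right-hand side
  of the LNA.
* **Steady states.** Newton–Raphson on the reduced residual with
  backtracking line search on the squared norm; convergence at residual
  $10^{-9}$. If the iteration stalls, the REs are pre-integrated for ten
  characteristic times (from the Jacobian eigenvalues at the guess) and
  the search restarts. The steady-state covariance solves the algebraic
  Lyapunov equation by flattening the symmetric unknown; the solver
  refuses Jacobians that are not Hurwitz, since the LNA around an
  unstable point is meaningless.
* **EMRE breakdown.** Below a model-specific volume the EMRE means can
  go negative. This is reported as a flag (`breakdown`), not an error:
  locating the breakdown volume is informative in itself. Likewise the
  steady-state object records which ordered species pairs have their RE
  concentration ordering inverted by the EMRE.
* **Zero-variance species** get correlation 0 and a flag, so exported
  tables contain no NaN.
* **Stochastic simulation.** Realization $r$ of a run with seed $s$ draws
  from a counter-seeded xoshiro256++ stream that is a pure function of
  $(s, r)$. Ensemble statistics use a streaming Welford accumulator
  within fixed-size chunks of realizations, combined deterministically in
  chunk order, so results are bit-identical however many worker processes
  are used. Grid sampling is right-continuous (the state at a grid time
  is the state after the last event at or before it), the standard
  convention for jump processes. Non-integer initial amounts are rounded
  to the nearest integer at simulation initialization only. The
  optimized direct method estimates firing frequencies in a presimulation
  window of at most $10^4$ events or one tenth of the final time.

## The built-in models

The package ships programmatic reconstructions of seven demonstration
models (`make_paper_model`).

**F1/F2 — Michaelis–Menten kinetics with substrate input.** Substrate
input at $k_{in} = 1.8\times10^{-5}$ M/s, binding
$k_1 = 5\times10^7\,(\mathrm{Ms})^{-1}$, unbinding $k_{-1}=5$/s,
catalysis $k_2=5$/s, product removal $k_{out}=7$/s; total enzyme 4 µM.
F1 places the reaction in $5\times10^{-16}$ l (1204 enzyme copies), F2 in
$10^{-17}$ l (24 copies). The total enzyme concentration and the volumes
are reconstructed jointly from the stated copy numbers and the existence
of a steady state (which needs $E_T > k_{in}/k_2 = 3.6$ µM); 4 µM is the
round value satisfying all of these at once. At the small volume the
model exhibits the noise-induced concentration inversion: the EMRE
substrate concentration exceeds the product concentration although the
REs predict the opposite ordering. The closed-form critical volume of
this inversion (`critical_volume_mm`) was derived by solving the
steady-state Lyapunov equation and the EMRE linear system analytically
for this five-reaction scheme; the test suite checks it against a
bisection on the numeric EMRE, which shares no code with the formula.

**F3/F4 — cooperative four-subunit enzyme.** Sequential binding
$E \to ES_1 \to \dots \to ES_4$ with rate constants 1, 10, 100,
1000 (µM s)$^{-1}$, all unbinding at 10/s, catalysis from every bound
state at 10/s ($ES_i \to ES_{i-1} + P$), substrate input 9 µM/s and
product removal 10/s; total enzyme 1 µM in $10^{-15}$ l (F3, about 600
copies) or $10^{-16}$ l (F4, 60 copies). The catalytic topology — every
complex releases product at the single quoted catalytic constant — is the
one reconstruction that reproduces the quoted Michaelis-constant ladder
$K_{M,1..4} = 20, 2, 0.2, 0.02$ µM exactly and leaves the input flux at
90% of catalytic capacity, consistent with the large substrate noise the
model is used to demonstrate.

**F5/F6/F7 — single-copy circadian clock gene.** A gene `G` transcribes
mRNA `M`, translated into cytosolic protein `Pc`, transported into the
nucleus (`Pn`) and back; two nuclear proteins bind the promoter in
sequence (cooperativity: the second binding is tenfold faster), silencing
transcription; `M` and `Pc` are degraded both linearly and by two
Michaelis–Menten enzymes. Time is measured in days. Rates on the gene
(transcription and repressor binding/unbinding) are scaled proportionally
to the system size, which removes the volume dependence that the fixed
single gene copy would otherwise impose on the rate equations: the RE
fixed point and the effective transcription/repression rates are volume
independent (only the gene-switching relaxation speed still scales with
volume), so volume dependence of the noise statistics is a pure
discreteness effect. F5 uses 2 fl, F6 0.2 fl; F7 is F6 with the
repression constant $k_1$ multiplied by 100.

Two quantities in this circuit are not fixed by the published constants:
the total concentrations of the two degradation enzymes. They were chosen
once, as `E_M` = 1 µM and `E_P` = 8 µM, so that the reconstruction
reproduces the documented phenomenology of all three files
simultaneously: damped population-level oscillations with a period just
under a day at the large volume; sustained single-cell oscillations of
about one day at the small volume with weak feedback; and, with strong
feedback, rate equations that are essentially non-oscillatory while the
EMRE means show clear damped oscillations of period about one day and
single-cell simulations show slower sustained oscillations. They are
exposed as overridable parameters.

## Measuring oscillation periods

Deterministic trajectories (EMRE means) use the mean peak-to-peak
interval after the initial transient (`peak_to_peak`). Stochastic
single-cell series are harder: noise-induced oscillations have a broad
spectral peak, and on synthetic damped-oscillator benchmarks with known
period we found the first autocorrelation peak biased upward by 15–20%
at realistic damping, and the location of the raw periodogram maximum
fluctuating by ±0.2 days between realizations. `dominant_period`
therefore averages periodograms over Welch segments, subtracts the flat
noise floor within the analysis band, and returns the power-weighted mean
period (spectral centroid). On the synthetic benchmarks this estimator
is accurate to a few percent with seed-to-seed scatter of about 0.03
days; those benchmarks are part of the test suite.

## A worked steady state

```{r f1}
st <- steady_state(make_paper_model("F1"))
st
```

The coefficient of variation of the substrate is an order of magnitude
larger than that of the complex although both have comparable means — the
classic signature that noise is species specific and not a simple
square-root law across a network.

```{r f2}
st2 <- steady_state(make_paper_model("F2"))
round(100 * (st2$emre_ss[["S"]] - st2$phi_ss[["S"]]) / st2$phi_ss[["S"]])
```

At 24 enzyme copies the mean substrate concentration sits roughly 60%
above the deterministic prediction, and `st2$inversion_flag["S", "P"]`
records the substrate/product ordering inversion.

## What the synthetic models do and do not show

The built-in models are genuine mechanistic reaction networks, not
surrogate data: their stochastic paths are exact CME samples. What they
do not emulate is everything outside the well-mixed, constant-volume,
single-compartment idealization: spatial gradients and diffusion-limited
encounters, cell growth and division, extrinsic (cell-to-cell) parameter
variability, and transcriptional bursting mechanisms beyond the explicit
gene states modelled here. Agreement of the SSE methods with stochastic
simulation on these models therefore validates the implementation and the
expansion, but says nothing about those excluded sources of variability
in real data. The SSE itself assumes a monostable deterministic flow;
multistable or limit-cycle regimes are outside its validity and the
package makes no attempt to detect them beyond the Hurwitz check at
steady state.

## Problem sizes used in the checks

The automated checks run the enzyme-model ensembles with 2,000–5,000
realizations, the clock simulations for 200 model days, and the SSE
integrations with 2,001 output points over 5 model days — sizes at which
the stochastic standard errors are comfortably below the tolerances being
asserted, chosen so the whole suite runs on a single CPU in a few
minutes.

## Known limitations

* SSE orders beyond the EMRE (variance corrections, higher cumulants)
  are not implemented; where the EMRE phase or frequency drifts from the
  simulated ensemble (visible in the strong-feedback clock), those
  higher orders would be needed.
* The SBML subset is Level 2 Version 4 without events, rules, reversible
  reactions, multiple compartments or time-dependent rates; such
  documents are rejected with per-rule error codes rather than silently
  reinterpreted.
* Stochastic simulation requires mass-action reactions (the compiled
  path); networks with custom symbolic propensities are fully supported
  by the RE/LNA/EMRE solvers but not by the simulator.
* Tau-leaping and spatial simulation are out of scope.
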