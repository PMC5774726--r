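---
title: "A stochastic random-walk model of translational elongation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic random-walk model of translational elongation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribowalk)
```

## The model

`ribowalk` models the elongation phase of translation as a unidirectional
continuous-time random walk of the *lead* ribosome on a discrete lattice of
`d` codons. Each residue addition at codon `i` follows first-order kinetics
with rate constant $\epsilon_i$ (units 1/time). Because the pool of
aminoacyl-tRNAs and the rest of the translational machinery differ slightly
from cell to cell and transcript to transcript, the $\epsilon_i$ are treated
as random variables: each mRNA template in a population carries its own
vector $\epsilon_{1..d}$ drawn from a configurable site-wise distribution.

On reaching the termination codon `d` a completed protein is released and
the ribosome either re-enters the same template at the initiation site
(probability $\lambda$, the closed-loop/recycling configuration typical of
eukaryotic polysomes) or returns to the free ribosome pool (probability
$1-\lambda$). The free pool is represented implicitly: for $\lambda < 1$
the occupancy vector simply loses mass, so the generator and transition
matrices retain their minimal $d \times d$ form.

The occupancy $V(t)$ (probability of the lead ribosome sitting at each
codon) evolves as $V(t) = e^{tT}V(0)$ with the bidiagonal-plus-corner
generator $T$ (diagonal $-\epsilon_i$, subdiagonal $\epsilon_i$, corner
$\lambda\epsilon_d$). The discrete-step representation $U$ with
$\alpha p_i = \epsilon_i$ is also provided; all continuous-time results are
independent of the scale $\alpha$, whose default $1.2\max_i\epsilon_i$
merely keeps every step probability below 1.

Why this model produces approximately log-normal protein distributions: the
propagator entries are sums of *products* of the random rates (see the
closed form below). Products of many comparable random factors have
approximately log-normal laws, and sums of a few log-normals remain close to
log-normal except in the tails — so the across-template distribution of any
protein-output readout inherits a log-normal center with non-universal
tails. The package's ensemble and fitting layers exist to demonstrate and
quantify exactly this.

## Propagator algorithms and their numerics

Four independent algorithms compute $Q(t) = e^{tT}$; their pairwise
agreement on overlapping domains is asserted in the test suite, with the
general matrix exponential as arbiter.

* **`expm_propagator`** — Padé scaling-and-squaring via the Matrix package.
  Works for every $\lambda$ and any rate configuration; the reference.
* **`closed_form_propagator`** ($\lambda = 0$, distinct rates) — the
  explicit pole expansion
  $Q_{ij}(t) = (-1)^{i+j}\prod_{m=j}^{i-1}\epsilon_m \sum_{k=j}^i
  e^{-t\epsilon_k}\big/\prod_{l \ne k}(\epsilon_k-\epsilon_l)$.
  Its denominators are singular at ties; rates closer than a relative
  `confluence_tol` of `1e-6` raise a typed condition instead of returning
  garbage. The tolerance marks the point where, empirically, the
  alternating sum has lost roughly half its significant digits at double
  precision.
* **`divdiff_propagator`** ($\lambda = 0$, any rates) — the same entries as
  rate products times divided differences of $e^{-t\epsilon}$. Divided
  differences of the exponential over an arbitrary (possibly repeated) node
  set are computed as the exponential of the Opitz bidiagonal node matrix,
  by diagonal shift, truncated Taylor series and repeated squaring. Every
  entry of that exponential is positive, so the squaring phase is free of
  cancellation and the confluent limit (repeated nodes, $f^{(n)}/n!$) is
  handled without a separate code path. This keeps the high-order
  differences — which naive recursion cannot evaluate stably — accurate in
  ordinary double precision; the suite checks agreement with the reference
  at `1e-6` even for rate pairs separated by `1e-7` relative.
* **`spectral_propagator`** ($0 < \lambda \le 1$) — a residue/partial-
  fraction expansion over the roots of
  $P(s) = \prod_k(s+\epsilon_k) - \lambda\prod_m\epsilon_m$. Roots come
  from the companion-matrix eigenvalues (`polyroot`) and are polished with
  Newton steps; they cluster near $s = -\epsilon_k$, and for $\lambda = 1$
  the root at $s = 0$ contributes the stationary distribution. The
  original contour-integral formulation is never quadratured in production
  code (the residue sum is mathematically identical); a literal
  trapezoid-rule contour integral is kept in the tests as an independent
  oracle. Root-finding failure — large polished residual, a surviving
  Newton step above `1e-8`, or root separation below
  $10^{-5}\max_i\epsilon_i$ (near-multiple roots, which arise when
  $\lambda \to 0$ with tied rates) — raises a typed condition so callers
  can fall back to the matrix exponential.

The Laplace-domain operator $\int_0^\infty c\,e^{-ct}Q(t)\,dt$ for a
transcript decaying at rate $c$ has closed-form entries built from products
of $\epsilon_k$ and $(c+\epsilon_k)$; these and the per-template statistics
are evaluated as chains of per-site ratios $\epsilon_k/(c+\epsilon_k) < 1$,
which neither overflow nor underflow prematurely at any chain length
(naive products overflow double precision before $d = 30$ at rates of
order 50).

One modelling convention deserves note: the lifetime-weighted polypeptide
count per template carries a leading factor $c$ (it is the expectation
under the transcript's exponential lifetime). With that factor the count
approaches the steady circulation flux ratio as $c \to 0$ on the recycling
chain, but vanishes on the open chain; the per-initiation normalisation
(`lifetime_weighted = FALSE`), which tends to 1 completed protein as
$c \to 0$ at $\lambda = 0$, is exposed as a documented flag. Relatedly, the
lifetime-weighted count is monotone decreasing in $c$ only on the fully
recycling chain; the per-initiation count is monotone for every $\lambda$.

## What the synthetic ensembles emulate

`rate_ensemble_spec` + `sample_rate_profiles` generate the study
populations: `n_templates` templates of length `d` with iid per-site rates
from gamma, (positive-truncated) normal, exponential, log-normal or fixed
families. The default study conditions are `d = 30`, circular boundary
($\lambda = 1$), gamma rates with shape 10 and scale 5 (site mean 50), and
ensembles of 25,000 templates for full reproduction runs.
The test suite uses 200–5,000 templates so the default run completes in a
few minutes; the acceptance script uses the full 25,000.

Choices the protocol leaves open, fixed here once:

* **Truncation of normal draws** — rejection sampling until positive,
  preserving independence and the intended support; parameter sets with
  more than 40% sub-zero mass are rejected outright because their truncated
  law no longer resembles a normal (the canonical normal(50, 15) ensemble
  truncates 4 parts in 10⁴).
* **Slow-codon mean** — "near zero" is realized as mean 1 against
  surrounding site means of 50–150; occupancy then piles up at the slow
  site within a fraction of one mean traversal.
* **Time unit** — one mean traversal $T = d/\overline{\epsilon}$;
  "late" times are several multiples of $T$. The terminal-occupancy
  distribution is invariant (consecutive Kolmogorov–Smirnov distance
  below 0.01) from roughly $8T$ at `d = 30`, and that is the time the
  acceptance script samples.
* **Protein decay** — completed proteins decay at a first-order rate that
  biology does not pin to one value; the default here is
  $0.02\,\overline{\epsilon}/d$, small enough that the transient chain
  growth stays linear over the first traversal and large enough that the
  late-time expected chain length visibly bends below the linear
  extrapolation.
* **Correlated rates** — between-site or between-template dependence is
  generated through a Gaussian copula with an AR(1) latent field whose
  lag-1 autocorrelation is the `strength` parameter (a supplied
  `length_scale` L maps to strength $e^{-1/L}$). The copula preserves each
  site's marginal family exactly, which is the property the robustness
  claims rest on; it does not emulate any particular biochemical source of
  correlation, only its statistical footprint.
* **Out-of-bound handling** — templates whose propagation produces
  non-finite values are dropped and counted (`n_in = n_out + n_dropped`
  always); a run aborts if more than 1% drop.

What passing these simulations does *not* show about real cells: the model
tracks only the lead ribosome (no exclusion/queueing between ribosomes — a
slow site stands in for collision effects, and the spacing parameter `R`
converts progress to ribosome load only on average), uses a single
effective rate per codon rather than the underlying multi-step kinetics,
and treats transcription, initiation control and degradation pathways as
exogenous. The log-normal shape claim concerns the distribution's center;
tail behaviour varies with the rate family and is reported, not assumed.

## The fitting layer

The protein samples are characterized by maximum likelihood: single
families (log-normal, log-logistic, gamma, normal) and two-component
mixtures. The log-logistic is parameterized on the log scale (location
`mu`, scale `s` of the logistic law of $\log X$; equivalently scale
$e^{\mu}$ and shape $1/s$). Mixtures are fit by EM with weighted
M-steps (closed-form for log-normal/normal, direct likelihood optimization
for log-logistic and gamma), 10 seeded random restarts (each splits the
sample at a random quantile between the 5th and 95th percentiles),
convergence at relative log-likelihood change below `1e-8` or 500
iterations, components sorted by descending weight, and a `degenerate` flag
when a weight collapses below 0.01.

"Unbiased" model selection is operationalized as BIC over a fixed library
(four singles plus three two-component mixtures), ties broken toward fewer
parameters — a transparent stand-in for opaque automatic distribution
finders. BIC rather than AIC is a documented package choice, not a claim
about what any external tool uses. One empirical caveat the tests make
explicit: on near-log-normal samples the two-component likelihood surface
is an extremely flat ridge in the weights, so the fully converged MLE can
sit far from dominant-plus-small-tail decompositions reported by other
software for visually identical fits; the dominant weight is only
meaningful together with the component parameters.

Q-Q diagnostics (`qq_points`, `tail_deviation_metric`) use plotting
positions $(k - \tfrac12)/n$, exact family quantiles for single components
and monotone bisection of the mixture CDF otherwise, log-transforming both
axes for log-domain references so a perfect fit lies on $y = x$. The tail
metric reports mean signed residuals over the outer 5% per side and the
inner-90% RMS as a central-fit score.

## Problem sizes

The shipped test suite runs ensembles of 200–5,000 templates at `d = 30`
(and up to 25,000 template-level closed-form evaluations, which are
vectorized and cheap), keeping a full run within a few minutes on one CPU.
The acceptance script reproduces the headline quantities at the full
protocol size of 25,000 templates. These sizes are stated so results can be
reproduced exactly; distributional tolerances in the tests scale with the
ensemble sizes used.
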