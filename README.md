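# ribowalk

Stochastic modelling of translational elongation for quantitative biologists
studying cell-to-cell variability in protein abundance. `ribowalk` asks a
narrow question with broad consequences: if each codon of an mRNA is
translated with its own random first-order rate constant, what distribution
of protein output should a cell population show? The answer — approximately
log-normal, with family-dependent tails — follows from the structure of the
model, and this package provides the machinery to derive, simulate and test
it.

## The model

The lead ribosome on a template of `d` codons performs a unidirectional
continuous-time random walk: residue addition at codon `i` has rate
constant εᵢ, and a ribosome reaching the termination codon releases a
completed protein and reinitiates on the same template with probability λ
(the closed-loop configuration; λ = 0 is the open/prokaryotic chain). The
occupancy vector V(t) of the lead ribosome evolves as

    V(t) = exp(tT) V(0),      T = tridiag(−εᵢ; εᵢ) + λ ε_d e₁ e_dᵀ

a compound-Poisson semigroup. Population variability enters by drawing each
template's ε₁..ε_d from a site-wise random-rate distribution: the entries of
exp(tT) are sums of *products* of the random εᵢ, and products of random
variables have approximately log-normal laws — hence the shape of protein
abundance distributions.

The package provides, per template: the transition matrix and generator;
four independent propagator algorithms (matrix exponential; the closed-form
pole expansion for λ = 0; a divided-difference formulation stable at tied
rates; a spectral residue expansion for the circular chain) that
cross-validate one another; the Laplace-domain operator for transcripts
decaying at rate c; the stationary distribution πᵢ ∝ 1/εᵢ; expected
polypeptides and ribosomes per transcript; and a greedy codon-optimization
heuristic. Across templates: ensemble samplers (gamma / normal /
exponential / log-normal / fixed rates, optional slow codons and copula
correlation), occupancy simulation with drop accounting, protein-output
distributions, transient statistics, and a maximum-likelihood fitting layer
(single families, two-component mixtures by seeded multi-restart EM, BIC
model selection, Q-Q and tail diagnostics).

## A worked example

Ribosomes accumulate where elongation is slow. Put a near-zero-rate codon
at site 20 of a 30-codon template and the stationary occupancy concentrates
there; protein output across a population of such templates is
approximately log-normal:

```r
library(ribowalk)

pr <- rate_profile(c(2, 3), reinit_prob = 1)
steady_state_distribution(pr)$probs
#> [1] 0.6 0.4                      # occupancy ∝ 1/ε: (1/2, 1/3) normalized

spec <- rate_ensemble_spec("gamma", list(shape = 10, scale = 5),
                           d = 30, n_templates = 5000, seed = 1)
ens  <- sample_rate_profiles(spec)
x    <- steady_state_protein_sample(ens)   # stationary terminal occupancy
fit  <- select_best_model(x, seed = 1)
fit
#> <fit_result>
#>   lognormal    w = 0.8500  (meanlog = -3.529, sdlog = 0.2785)
#>   loglogistic  w = 0.1500  (mu = -3.059, s = 0.1518)
#>   loglik = 15846.77, BIC = -31650.95, n = 5000
tail_deviation_metric(x, fit)$central_rms
#> [1] 0.003906184                  # inner-90% Q-Q residual RMS, log scale
```

The population sample `x` is the per-template stationary probability that
the lead ribosome sits at the termination codon (the protein-output readout
used for population histograms). BIC picks a log-normal plus log-logistic
mixture over any single family by a small margin — the sample is log-normal
at its center with mild heavy-tail structure, which is exactly the model's
prediction; the tiny central Q-Q residual quantifies the central fit.

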