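# cleansig

Bayesian baseline correction for somatic mutational signatures.

In mutagenesis experiments (cell lines, organoids, animal models, duplex
sequencing) and in cancer genomes, the mutation spectrum of an exposed
sample mixes the signature of the exposure of interest with background
processes — endogenous mutagenesis, culture artifacts, sequencing noise.
`cleansig` separates the two: given a sample's mutation-count spectrum and
one or more background spectra, it infers the latent exposure-associated
signature, the background and exposure activities with credible intervals,
and a count-scale "rescued" exposure profile, while reconstructing the
observed profile with count fidelity.

## Model

For an observed profile with total mutation burden *N* over channels *c*
(SBS96, SBS288, DBS78, ID83, or any custom classification):

```
Reconstructed_c = N * ( sum_k theta_b[k] * s_b[k,c]  +  theta_e * s_e,c )
```

where `s_b[k]` are the supplied background signatures, `s_e` is the latent
exposure signature (flat Dirichlet prior on the simplex), and
`theta_b[k]`, `theta_e` are activities with right-skewed Gamma priors
centered at 1 (background) and 0.2 (exposure). The data enter twice:

- **Spectrum shape** — observed proportions follow
  `Dirichlet(rho_Reconstructed)`;
- **Counts** — each channel's count follows a truncated
  Conway–Maxwell–Poisson distribution located at the reconstructed count,
  with a shared dispersion `nu ~ Normal(2, 0.5)` bounded below at 1.1
  (underdispersion penalizes deviations from the observed counts). The
  infinite normalizing constant is truncated adaptively at
  `y + ceil(6*sqrt(y)) + 10`.

Parameter configurations whose reconstruction reaches cosine similarity
above 0.95 with the observed profile receive a smooth additive reward.
Posterior sampling is adaptive Hamiltonian Monte Carlo (analytic
gradients, dual-averaging step size, diagonal mass adaptation) on the
unconstrained parameterization; defaults are 4 chains with 1000 warmup and
1500 sampling iterations. Summaries follow the activity posterior medians
and the 2.5% posterior quantile of `s_e` (renormalized); the rescued
profile is `N * theta_e * s_e`.

Comparator cleaning methods (simple subtraction with clipping; NNLS with
90% shrinkage), evaluation metrics (cosine similarity, Jensen–Shannon
divergence, count accuracy, injection precision/sensitivity/F1), and a
synthetic spectrum/injection generator are included, so the whole
benchmark workflow runs without external data.

## Worked example

```r
library(cleansig)

schema <- channel_schema("SBS96")
pair <- random_signature_pair(schema, seed = 42)        # cosine < 0.3
sim <- simulate_sample(schema, burden = 3000,
                       pair$background, pair$exposure,
                       theta_split = c(0.6, 0.4), seed = 42)

res <- rescue(sim$profile, pair$background,
              mcmc = mcmc_config(chains = 4, warmup = 500,
                                 sampling = 750, seed = 1))
res
#> <rescue_result> sim_42 (SBS96, burden 3000)
#>   activities (posterior median): background 0.578, exposure 0.422
#>   relative: background 57.8%, exposure 42.2%
#>   exposure 95% CI [0.381, 0.472]; fit cosine 0.9987; max R-hat 1.003

cosine_similarity(res$s_e_hat$proportions, pair$exposure$proportions)
#> [1] 0.952
```

The sample was generated as a 60/40 background/exposure mixture; the
posterior medians recover the split (42.2% exposure, truth 40% inside the
95% credible interval), the reconstruction matches the observed spectrum
(cosine 0.9987), and the denoised exposure signature has cosine 0.95 to
the generating signature. The comparators on the same sample illustrate
the clipping artifact the Bayesian model avoids:

```r
simple_subtraction(sim$profile, pair$background)
#> <baseline_result> subtraction on sim_42: exposure total 730.016, 46 clipped channel(s)
nnls_subtraction(sim$profile, pair$background, shrinkage = 0.9)
#> <baseline_result> nnls on sim_42: exposure total 1099.05, 15 clipped channel(s), background activity 0.654

count_accuracy(res$reconstructed, sim$profile)
#> [1] -0.16
```

Batch runs (`rescue_many()`, up to 20 samples in parallel), TMB-weighted
consensus signatures (`consensus_signature()`), TSV import/export in the
SigProfiler matrix layout (`read_matrix()`/`write_matrix()`), and full
posterior export (`write_draws()`) round out the workflow. A command-line
interface with `rescue`, `baseline`, `simulate`, `inject`, and `score`
subcommands is installed at `inst/cli/cleansig.R`.

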