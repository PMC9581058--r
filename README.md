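# flsmlm

Fluorescence-lifetime estimation and statistics for single-molecule TCSPC
data, as used in fluorescence-lifetime single-molecule localization
microscopy (FL-SMLM).

A localized single molecule delivers a TCSPC histogram — photon counts
$m_i$ in $K$ time channels of width $\Delta t$ tiling the laser repetition
period $T$ — from which its fluorescence lifetime must be estimated, often
from only a few hundred photons on a background. The package is built for
the people who do that estimation: microscopists and image analysts running
confocal or wide-field TCSPC SMLM experiments, and method developers who
need a reference implementation with its statistical limits attached.

At its core is the mono-exponential decay model with constant background,

$$p(t) = (1-b)\,\frac{e^{-t/\tau}}{\tau\,(1-e^{-T/\tau})} + \frac{b}{T},$$

and everything the model supports:

* **Fitting** — maximum likelihood ($\lambda = -\sum_i m_i \ln p_i$),
  Pearson/Neyman weighted and unweighted least squares, and the Poisson
  deviance, by Nelder-Mead simplex with bound-safe parameterization;
  reduced-$\chi^2$ goodness of fit with $\nu = K - 3$ and bin rebinning.
* **Uncertainty** — the Cramér–Rao lower bound $\sigma_\tau$ for
  $\theta = (\tau, b)$, in closed form (polylogarithmic) certified against
  adaptive quadrature, plus the $T\to\infty$ and zero-background limits.
* **IRF handling** — empirical and shifted-Gamma instrument response
  functions, circular reconvolution, tail fitting, and IRF fitting from a
  scattering measurement.
* **Pattern matching** — species classification and grid-search MLE via a
  single matrix product $\Lambda = -M P_{\ln}$, with softmin posteriors and
  confidence-based rejection.
* **Monte-Carlo harnesses** — estimator bias/efficiency benchmarks, the
  IRF-bias benchmark, and synthetic inhomogeneous samples.
* **Molecule-level statistics** — filtering, photon-binned
  lifetime-variance curves against the CRLB, intrinsic sample-variance
  extraction ($\sigma = a\langle N\rangle^{-k} + \sigma_\text{sample}$),
  and ROC/AUC classification comparisons.

Results come back as tibbles, fitted objects support `tidy()`/`glance()`,
and result types have `autoplot()` methods, so everything chains with the
pipe.

## Worked example

Simulate one molecule under the standard conditions ($\tau = 2$ ns,
$b = 0.2$, $T = 25$ ns, $\Delta t = 0.016$ ns, 500 expected photons) and
fit it by maximum likelihood:

```r
library(flsmlm)

g <- tcspc_grid(delta_t = 0.016, period = 25)
truth <- decay_params(tau = 2, b = 0.2, n_hat = 500)
h <- simulate_histogram(truth, g, seed = 7)
f <- fit_decay(h, "neg_loglik")
f
#> <decay_fit:neg_loglik> tau = 1.96 ns (CRLB sigma 0.132), b = 0.206, N = 515 photons, chi2/nu = 0.95
tidy(f)
#> # A tibble: 3 × 3
#>   term  estimate std.error
#>   <chr>    <dbl>     <dbl>
#> 1 tau      1.96      0.132
#> 2 b        0.206    NA
#> 3 n_hat  515        NA
```

The fitted lifetime (1.96 ns) sits well within one CRLB standard deviation
(0.132 ns at the fitted parameters) of the truth; the detected 515 photons
are the Poisson realization of the 500 expected; the reduced Pearson
$\chi^2$ of 0.95 says the mono-exponential model describes the histogram.
The bound itself is available directly — at the true parameters,

```r
crlb_sigma_tau(tau = 2, b = 0.2, N = 500, T = 25)
#> [1] 0.1359544
```

i.e. no unbiased estimator can beat a ±0.136 ns spread at 500 photons with
20 % background. Batch workflows chain the same pieces:

```r
sample <- simulate_inhomogeneous_sample(5000, tau_mean = 2, sigma_sample = 0.1)
fit_decay_batch(sample$counts, sample$grid) |>
  dplyr::left_join(sample$records, by = "id", suffix = c("", ".true")) |>
  filter_molecules() |>
  group_by_photons(30) |>
  variance_curve(period = 25) |>
  fit_intrinsic_variance()
```

A thin command-line interface over the same functions ships in
`inst/cli/flsmlm` (subcommands `crlb`, `simulate`, `fit`, `classify`,
`analyze`, `benchmark`; see `--help`).

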