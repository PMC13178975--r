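# mrsimss

Summary-level Mendelian randomization (MR) with built-in correction for
**Winner's Curse** and **sample-overlap bias**, requiring nothing beyond
the exposure and outcome GWAS summary statistics.

## The problem it solves

Two-sample MR estimates the causal effect of an exposure on an outcome
from per-variant association estimates
$\{\hat\beta_{Xj},\sigma_{Xj}\}$ and $\{\hat\beta_{Yj},\sigma_{Yj}\}$.
In routine practice, instruments are selected at genome-wide significance
from the *same* exposure GWAS used for estimation, which overestimates
the selected variant-exposure effects (Winner's Curse) and attenuates the
causal estimate toward the null. When the two GWASs share participants,
estimation errors are additionally correlated
($\lambda = n_{\mathrm{overlap}}\rho/\sqrt{n_X n_Y}$) and weak-instrument
bias points toward the confounded observational association instead.

**MR-SimSS** (MR via simulated sample splitting) removes both biases by
exploiting the asymptotic conditional distribution of split-sample GWAS
estimates given the full-sample estimates. Each iteration simulates the
summary statistics that independent sample splits would have produced,
selects instruments in the simulated selection split, and estimates the
causal effect from the complementary split(s) with a pluggable
two-sample estimator (fixed-effect IVW, profile-score RAPS, Egger,
weighted median, dIVW). Estimates are averaged over iterations, with a
standard error that subtracts the between-iteration Monte Carlo variance:

$$\hat\beta=\frac1N\sum_k\hat\beta^{(k)},\qquad
\mathrm{se}(\hat\beta)=\sqrt{\tfrac1N\sum_k\mathrm{se}(\hat\beta^{(k)})^2-\tfrac1N\sum_k(\hat\beta^{(k)}-\hat\beta)^2}.$$

The 2-split mode suffices for independent samples; the 3-split mode
additionally subdivides the estimation fraction so exposure and outcome
statistics mimic disjoint samples, staying unbiased under full overlap.
The error correlation $\lambda$ can be supplied from the study design or
estimated from null variants (with an exact correction for the
truncation bias of the null-set z-score correlation).

## Worked example

The package ships a small simulated summary-statistics pair (1,000
variants, 50% sample overlap, true causal effect 0.3):

```r
library(mrsimss)

exposure <- system.file("extdata", "synthetic_exposure.tsv", package = "mrsimss")
outcome  <- system.file("extdata", "synthetic_outcome.tsv",  package = "mrsimss")
pair <- read_summary_pair(exposure, outcome, n_x = 100000, n_y = 100000)

estimate_lambda(pair)
#> # A tibble: 1 x 4
#>   lambda     se n_null z_cut
#>    <dbl>  <dbl>  <int> <dbl>
#> 1  0.306 0.0384    874  1.96

fit <- mr_simss(pair, n_iter = 500, seed = 1)   # 3-split + RAPS defaults
fit
#> MR-SimSS (3-split, raps)
#>   beta = 0.3005  se = 0.0046  95% CI [0.2916, 0.3094]
#>   iterations used: 500 (skipped 0), mean instruments: 33.8
#>   lambda = 0.3058 (estimated from 874 null variants (se 0.0384))

tidy(fit)
#> # A tibble: 1 x 7
#>   method      estimate std_error statistic p_value conf_low conf_high
#>   <chr>          <dbl>     <dbl>     <dbl>   <dbl>    <dbl>     <dbl>
#> 1 simss3_raps    0.301   0.00455      66.0       0    0.292     0.309
```

The fitted value recovers the generating effect (0.3) and the
data-driven overlap estimate (0.31) agrees with the design value (0.25)
within its standard error. `glance(fit)` reports iteration diagnostics
and `autoplot(fit)` shows the per-iteration estimate distribution.

The simulation harness makes the bias story concrete. At a weak-instrument
architecture (exposure heritability 0.3 spread over 10,000 causal
variants, independent samples of 200,000), naive IVW is strongly
attenuated while MR-SimSS with RAPS is not:

```r
scn <- sim_scenario(n_variants = 1e5, p_causal = 0.1, h2 = 0.3,
                    n_x = 2e5, n_y = 2e5, overlap_frac = 0, rho = 0.5)
evaluate_methods(scn, c("ivw", "simss2_raps"), n_replicates = 5,
                 seed = 42, simss_control = list(n_iter = 150))
#>        method mean_beta    bias   rmse coverage mean_n_instruments
#> 1         ivw     0.253 -0.0466 0.0468        0              403.8
#> 2 simss2_raps     0.295 -0.0046 0.0096        1               63.1
```

The true effect is 0.3: naive IVW is biased toward the null by ~16% with
zero CI coverage, while the simulated-splitting estimate is essentially
unbiased.

## Command line

A thin wrapper over the same functions lives in `inst/cli/simss`:

```sh
simss run --exposure exp.tsv --outcome out.tsv --nx 200000 --ny 200000 \
      --mode 3split --estimator raps --iters 1000 --seed 1 --out results.tsv
simss estimate-lam --exposure exp.tsv --outcome out.tsv --nx 200000 --ny 200000
simss simulate --scenario scenario.yaml --seed 1 --out pair.tsv
simss benchmark --grid grid.yaml --replicates 25 --out metrics.tsv
```

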