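# swellkin

Swelling-kinetics analysis for hydrogels: fit time-resolved water-uptake
data with a single three-parameter equation, decompose uptake into its
Fickian-diffusion and macromolecular-relaxation contributions, classify the
transport mechanism, and compare formulations statistically.

## The problem and the model

When a dry polymer network is immersed in solvent, the swelling degree
S(t) = (w(t) − w₀)/w₀ (grams of water per gram of dry gel) rises toward an
equilibrium through two coupled processes: diffusion of solvent down its
concentration gradient (√t signature) and rearrangement of the polymer
chains (linear-in-t signature). Classical tools capture one regime each —
the power law S = k·tⁿ only on the first ~60% of uptake, first-order
kinetics S = S∞(1 − e^(−kt)) only when relaxation controls, the two-term
Peppas–Sahlin form only at early times. `swellkin` is built around a single
equation that spans the whole curve:

    S(t) = (1 − e^(−k·t)) · (a*·√t + b*)

with three parameters:

* `k` (h⁻¹) — the speed of solvent penetration,
* `a*` ((g/g)·h^(−1/2)) — the diffusive amplitude,
* `b*` (g/g) — the relaxational amplitude.

Each classical model is a limiting case: `a* = 0` gives first-order
kinetics exactly (S∞ = b*), the order-1 Taylor truncation of the
exponential gives the two-term early-time structure, and higher truncations
give the short-time expansion family. The ratio a\*/b\* fixes the
mechanism independently of `k`: the Fickian contribution at time t is

    CF(t) = 1 / (1 + (b*/a*)·√t),    CR = 1 − CF,

so relaxation dominates (CR > 0.9 at t = 1 h) once b\* ≥ 10·a\*, and
diffusion dominates (CF > 0.99) once a\* ≥ 100·b\*. A negative `a*` with
positive `b*` reproduces swelling overshoot — a transient uptake maximum
followed by drainage toward equilibrium. The package also fits the
companion network-density decay law ρ_net(t) = β·t^(−1/2) + ρ_eq.

## Worked example

Every stage runs on synthetic data with known ground truth; no download is
needed. `make_study_fixture()` generates a three-sample, triplicate study
of fast ionizable gels (plateaus ≈ 24, 25 and 30 g/g, the last one
overshoot-shaped):

```r
library(swellkin)

study <- make_study_fixture("alginate_like", seed = 42)
fit <- fit_study(study)
fit$summary[, c("sample_id", "k_mean", "k_sd", "ratio_mean", "S_eq_mean",
                "r2_swelling", "mechanism_ratio", "overshoot", "k_letters")]
#> # A tibble: 3 × 9
#>   sample_id k_mean   k_sd ratio_mean S_eq_mean r2_swelling mechanism_ratio overshoot k_letters
#> 1 A1         0.268 0.0190     0.312       23.8       0.998 anomalous       FALSE     a
#> 2 A2         0.510 0.0527     0.223       25.1       0.996 anomalous       FALSE     b
#> 3 A3         0.518 0.0168    -0.0285      29.8       0.997 anomalous       TRUE      b
```

Reading the table: each replicate curve was fitted with the unified
equation (all R² ≈ 0.997), per-sample parameters are reported as
mean ± sd over the triplicates, the a\*/b\* ratios ≈ 0.2–0.3 indicate
anomalous transport with a strong relaxational contribution, sample A3 is
flagged as overshooting (its fitted a\* is negative), and the Tukey compact
letters show A2/A3 share a significantly faster `k` than A1.

A single overshooting replicate, its peak, and the mechanism profile:

```r
one <- dplyr::filter(study, sample_id == "A3", replicate_id == "r1")
f <- fit_swelling_eq(one)
f
#> <swell_fit: swelling_eq>
#>   k         0.5319 (se 0.01821)
#>   a_star   -0.8830 (se 0.15150)
#>   b_star   34.8300 (se 0.70290)
#>   R2 0.9969  adj. R2 0.9967  n 40  window [0, 50]  converged

overshoot_peak(f$params$k, f$params$a_star, f$params$b_star)
#> # A tibble: 1 × 2
#>   t_peak S_peak
#> 1   8.95   31.9

fickian_contribution(c(1, 5, 25), a_star = 2.46, b_star = 11.2)
#> # A tibble: 3 × 4
#>   time_h     CF    CR valid
#> 1      1 0.180  0.820 TRUE
#> 2      5 0.0894 0.911 TRUE
#> 3     25 0.0421 0.958 TRUE
```

The uptake of this formulation family is ~18% Fickian at 1 h and
relaxation-controlled from a few hours on. `tidy()`, `glance()`,
`augment()` and `autoplot()` methods are provided for all fit objects;
`plot_study_fits()` shows every replicate with its fitted curve.

A thin command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","swellkin.R",package="swellkin"))')" \
  simulate --preset alginate_like --seed 7 --out study.csv
```

with subcommands `simulate`, `fit`, `mechanism`, `density` and `compare`.

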