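# haflex

Is a hyaluronan (HA) gel flexible enough, on the nanosecond time scale, to
contort into receptor-binding conformations? `haflex` implements an
NMR-based answer for people who study HA hydrogels and their mechanics:
structural-NMR spectroscopists, hydrogel rheologists, and modellers of
polymer dynamics.

The physics in one paragraph. ¹H spin-lattice relaxation in a water-swollen
polymer is fed by (i) nanosecond internal motion and (ii) cross-relaxation
carried through the dipole-coupled ¹H network by spin diffusion. For a
¹H–¹H vector moving on a cone of angle θ (order parameter
S(θ) = (3cos²θ−1)/2) inside a slowly tumbling chain (τ_macro), the two
rates are

    R1_motion = (3/10) d² (1−S²) [ L(ω₀, τₑ) + 4 L(2ω₀, τₑ) ]
    R1_sd     = c_sd d² S² τ_macro,          L(ω, τ) = τ / (1 + ω²τ²)

with d the dipolar coupling constant, 1/τₑ = 1/τ_macro + 1/τ, and c_sd
calibrated so max(R1_sd)/max(R1_motion) = 10 across the map. Spin diffusion
wins everywhere except where internal motion is both large-amplitude and
near its spectral-density optimum (ω₀τₑ ≈ 0.616). The experimental probe
follows: if spin diffusion dominates, ring and methyl ¹H share one T₁;
if motion dominates, their T₁ differ. `haflex` simulates the regime map,
fits T₁ from recovery curves, runs the equal-vs-distinct test, extracts
the G′/G″ crossover from oscillatory rheology as an orthogonal flexibility
measure, and generates all synthetic inputs needed to exercise the chain.

## Worked example

```r
library(haflex)

## 1. When should motion beat spin diffusion? (simulation)
map <- compute_regime_map(spin_pair())     # 500 MHz, r = 2 A, tau_macro = 1e-7 s
map
#> <regime_map>
#>   grid          : 91 angles x 151 correlation times
#>   tau_macro     : 1e-07 s;  order parameter: legendre
#>   c_sd          : 0.0136;  max(sd)/max(motion) = 10
#>   motion wins   : theta >= 44 deg, tau in [1e-12, 1e-06] s

## 2. Does a dilute gel show distinct ring/methyl T1? (synthetic 2 wt% case)
pr <- gen_t1_pair(1.0, 0.5, spec = generator_spec(seed = 11, noise_sd_frac = 0.02),
                  sample = "HMW-2wt")
cmp <- compare_t1(fit_recovery(pr$ring), fit_recovery(pr$methyl))
cmp
#> <t1_comparison> ring (1.059 s) vs methyl (0.494 s): z = 9.88, p = 5.06e-23 -> distinct
classify_flexibility(cmp)
#> [1] "motion_dominated"

## 3. Rheology: disentanglement-rate contrast between two gels
x2 <- find_crossover(gen_maxwell_sweep(100, 0.01, generator_spec(11, 0.01), sample = "HMW-2wt"))
x5 <- find_crossover(gen_maxwell_sweep(500, 0.10, generator_spec(12, 0.01), sample = "HMW-5wt"))
compare_crossovers(x2, x5)
#> [1] 10.00713
```

Reading the numbers: the map says motion can only dominate above ~44° cone
angle (the τ range printed is inflated by the order-parameter zero at the
magic angle — see the vignette); the dilute-gel pair fits T₁ = 1.06 ± 0.05 s
vs 0.49 ± 0.03 s, z = 9.9, so the resonances are *distinct* and the gel is
classified motion-dominated (flexible); and its G′/G″ crossover sits 10×
higher in frequency than the dense gel's, i.e. it disentangles ten times
faster — the independent mechanical signature of the same flexibility.

## Command line

`exec/haflex` (installed to `<library>/haflex/exec/haflex`) wraps
`haflex_cli()`:

```sh
haflex regime-map --config cfg.yml --out map.csv --report report.json
haflex simulate pair --t1-ring 1.0 --t1-methyl 0.5 --seed 5 --out curves.csv
haflex fit-t1 --in curves.csv --alpha 0.05 --out t1_report.json
haflex rheo-crossover --in sweep.csv --ratio A,B --out xover.json
haflex run --config cfg.yml --seed 1 --out report.json   # full pipeline
```

All commands take `--config` (YAML, unknown keys rejected), `--seed` and
`--log-level`; every report echoes the fully resolved configuration, and a
fixed seed gives byte-identical output.

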