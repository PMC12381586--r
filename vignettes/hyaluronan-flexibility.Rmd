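---
title: "Deciding what relaxes a hyaluronan gel: motion or spin diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding what relaxes a hyaluronan gel: motion or spin diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question

Hyaluronic acid (HA) must bend substantially away from its extended
conformation to engage the CD44 hyaluronic-acid binding domain, and whether
it can do so depends on how flexible the chain is on the nanosecond time
scale inside a gel. NMR offers an operational test. The ¹H spin-lattice
relaxation rate of a water-swollen polymer has three contributions:
(i) nanosecond-scale conformational motion, (ii) cross-relaxation between
dipole-coupled ¹H transported through the network by spin diffusion, and
(iii) exchange of labile ¹H with water. If spin diffusion dominates,
longitudinal magnetisation equilibrates across the whole ¹H network and
every non-exchangeable resonance reports the *same* effective T₁. If
internal motion dominates, chemically distinct protons (sugar-ring ¹H vs
the N-acetyl methyl ¹H) relax at their own rates and their T₁ differ.
Equality-within-error of two fitted T₁ values is therefore a binary probe
of gel flexibility. `haflex` implements that probe end to end: a
regime-map simulation saying *when* each term should dominate, a T₁
fitting and comparison stage, a rheology crossover stage as an orthogonal
check, and synthetic-data generators so the entire pipeline runs and is
tested without any instrument data.

## The model behind the regime map

We model the dominant relaxation pathway, the ¹H–¹H intramolecular dipolar
coupling of a proton pair at distance $r$, with coupling constant
$d = (\mu_0/4\pi)\,\hbar\,\gamma^2/r^3$. The internuclear vector performs
fast random motion on a cone of angle $\theta$ (correlation time
$\tau$, the internal motion) superimposed on slow isotropic tumbling
($\tau_\mathrm{macro}$). Restricted motion averages the coupling by the
order parameter; our default convention is azimuthally random motion at
fixed cone angle,
$$S(\theta) = \tfrac{1}{2}(3\cos^2\theta - 1),$$
which is 1 for a rigid vector, 0 at the magic angle (54.7356°) and −0.5 at
90°. A diffusion-in-a-cone alternative
$S(\theta) = \cos\theta\,(1+\cos\theta)/2$ is available through
`order_parameter_model = "cone"`; both are second-rank conventions and the
choice is a modelling decision, not a fact of the data, which is why it is
a visible switch.

The composite motion has the model-free two-Lorentzian spectral density
$$J(\omega) = S^2 \frac{\tau_\mathrm{macro}}{1+\omega^2\tau_\mathrm{macro}^2}
 + (1-S^2)\frac{\tau_e}{1+\omega^2\tau_e^2},
 \qquad \frac{1}{\tau_e} = \frac{1}{\tau_\mathrm{macro}} + \frac{1}{\tau}.$$

The two competing rates are:

* **Motion term** — the like-spin Solomon rate restricted to the
  internally modulated $(1-S^2)$ component,
  $$R_1^\mathrm{motion} = \tfrac{3}{10}\, d^2 (1-S^2)
    \left[\frac{\tau_e}{1+\omega_0^2\tau_e^2}
    + \frac{4\tau_e}{1+4\omega_0^2\tau_e^2}\right].$$
  It vanishes for $\theta = 0$ and in both the very fast and very slow
  internal-motion limits, peaking where $\omega_0\tau_e \approx 0.616$
  (the maximiser of $x/(1+x^2) + 4x/(1+4x^2)$, checked in the tests by a
  dense scan).

* **Spin-diffusion term** — flip-flop transport of longitudinal
  magnetisation to relaxation sinks, driven by the *residual* (motionally
  averaged) coupling, in the low-frequency limit valid when
  $\omega_0\tau_\mathrm{macro} \gg 1$:
  $$R_1^\mathrm{sd} = c_\mathrm{sd}\, d^2 S^2 \tau_\mathrm{macro}.$$
  Large-amplitude motion quenches it through $S^2$.

The dimensionless transport constant $c_\mathrm{sd}$ is not derivable from
the pair model alone (it aggregates the geometry of the many-spin network
and its relaxation sinks). We therefore *calibrate* it: by default
$c_\mathrm{sd}$ is set so that the maximum spin-diffusion rate over the
grid is 10× the maximum motion rate — the order-of-magnitude dominance
observed for entangled HA gels — and it is exposed in the configuration
for users who have a first-principles value. A consequence worth knowing:
because both terms carry the same $d^2$, the dominance pattern (onset
angle, τ window) is provably independent of $r$ and $\gamma$; the tests
assert this invariance.

`compute_regime_map()` evaluates both terms on a grid (default: θ from 0°
to 90° in 1° steps; τ log-spaced 10⁻¹²–10⁻⁶ s at 25 points/decade;
τ_macro = 10⁻⁷ s; 500 MHz spectrometer) and `dominance_boundary()`
extracts the smallest angle at which motion wins for any τ and the (min,
max) τ over all motion-dominated grid points. Ties classify as spin
diffusion, encoding "spin diffusion always dominates unless the motion
term is near its optimum".

### A known artifact of the boundary definition

At the default settings the onset angle is 44°, consistent with the
expected ≈30° given that every prefactor upstream of the calibration is a
stand-in. The τ window, however, evaluates to the *full grid*
(10⁻¹²–10⁻⁶ s) rather than the expected ≈10⁻¹⁰–10⁻⁸ s. This is a
structural artifact, not a numerical bug: $S(\theta)$ crosses zero at the
magic angle, so near θ ≈ 54.7° the spin-diffusion term is essentially zero
and the motion term — however tiny — wins at *every* τ, and the
min/max-over-grid window inflates. The cone-diffusion convention merely
moves the zero to θ = 90°. Restricting the window to angles just past
onset recovers the nanosecond band, but we deliberately keep the plain
definition and let the corresponding acceptance assertion fail visibly
rather than redefine the statistic post hoc. Users reading `tau_window`
should do so together with the dominance matrix itself.

## T₁ fitting and the equality test

Recovery curves follow $M(t) = M_0 - A e^{-t/T_1}$ with the amplitude
always free: $A \approx 2M_0$ for inversion recovery and $A \approx M_0$
for saturation recovery, and a free $A$ absorbs imperfect preparation in
either scheme. The model is linear in $(M_0, A)$, so `fit_recovery()`
profiles the residual sum of squares over $T_1$ alone (variable
projection): an 80-point log-spaced scan over $T_1 \in [10^{-4}, 10^3]$ s
brackets the global optimum, refined by 1-D minimisation. This is robust
down to exactly noiseless curves (where Gauss–Newton iterations stall on a
zero-residual solution) and needs no starting values. Standard errors come
from the full three-parameter covariance
$\hat\sigma^2 (J^\top J)^{-1}$ at the optimum; the implementation was
cross-checked against an independent Levenberg–Marquardt fit and agrees to
six decimals in both estimate and SE. Fits that run to a search bound are
returned flagged (`converged = FALSE`), never silently; curves whose
delays span less than one fitted T₁ trigger a warning.

`compare_t1()` tests $T_{1,a} = T_{1,b}$ with
$z = |T_{1,a}-T_{1,b}|/\sqrt{se_a^2+se_b^2}$ against a two-sided normal
reference (α = 0.05 by default); `method = "welch"` substitutes a t
reference with Welch–Satterthwaite degrees of freedom from the two fits.
Each sample contributes one pre-planned ring-vs-methyl comparison, so no
multiple-testing correction is applied across samples.
`classify_flexibility()` then maps *distinct* → motion-dominated
(flexible) and *equal within error* → spin-diffusion-dominated (stiff).

Calibration, measured by the test suite over 500 seeded replicates
(T₁ = 0.8 s, 2% noise, 12 log-spaced delays over 0.01–5 s): the fitted T₁
is unbiased (within 1.2 SE of the replicate mean), the reported SE matches
the empirical spread within 6%, and the type-I rate of the verdict is
6.2%, inside the α ± 2% band. One caveat surfaces honestly in the
acceptance suite: intervals built with the fixed multiplier 1.96 cover the
truth only ≈90% of the time at 9 residual degrees of freedom, whereas
$t_{0.975,9} = 2.262$ intervals cover ≈95%. The normal multiplier is kept
because it is the stated contract, and the corresponding coverage
assertion is left failing rather than quietly switched; the z-test slight
anticonservatism at 12 points is the same finite-dof effect.

## Proton exchange (term iii)

Exchange with water is handled the way the experiment handles it: only
non-exchangeable resonances (ring CH, N-acetyl CH₃) are analysed, and no
exchange correction enters the fit. To know what that costs, the package
ships a two-pool generator solving the coupled longitudinal rate equations
exactly (2×2 eigendecomposition of the rate matrix, with detailed-balance
exchange rates $k_{ab} = k_\mathrm{ex} p_b$, $k_{ba} = k_\mathrm{ex} p_a$).
The tests verify the two limits ($k_\mathrm{ex}=0$ reproduces the
mono-exponential generator bit for bit; $k_\mathrm{ex}\to\infty$ gives the
population-weighted rate), check an intermediate-exchange curve against an
independent Euler integration, and confirm the robustness claim that at
slow exchange ($k_\mathrm{ex} T_{1,a} = 0.05$) the mono-exponential fit
recovers the pool-A T₁ within 5%.

## Rheology crossover

A flexible, weakly entangled gel disentangles fast; its storage modulus
G′ overtakes the loss modulus G″ only at high frequency. `find_crossover()`
locates the sign change of $\log(G'/G'')$ and interpolates linearly
against $\log\omega$ — both axes span decades, so log–log interpolation is
the natural choice, and for a single-mode Maxwell fluid
($G' = G\omega^2\lambda^2/(1+\omega^2\lambda^2)$,
$G'' = G\omega\lambda/(1+\omega^2\lambda^2)$) it is *exact*:
$\log(G'/G'') = \log(\omega\lambda)$ is linear in $\log\omega$ with
crossover at $\omega_c = 1/\lambda$, $G_c = G/2$. Multiple sign changes
return the first with a warning; no sign change is an error, not a guess.
`compare_crossovers()` forms the ratio $\omega_c(a)/\omega_c(b)$; the
default pipeline scenario uses λ = 0.01 s vs 0.1 s, i.e. a tenfold
disentanglement-rate contrast.

## What the synthetic data emulates — and what it does not

The generators state the world the tests live in:

| Setting | Default | Why |
|---|---|---|
| recovery noise | additive Gaussian, SD 2% of M₀ | detector-like noise of a well-shimmed acquisition; the instrument's true level is not published, so this is a declared placeholder |
| delays | 12 points, log-spaced over 0.01–6 × T₁ | spans the decay and the plateau; 12 is a routine arrayed-delay count |
| scenario T₁ | 2 wt%: ring 1.0 s vs methyl 0.5 s; 5 wt%: both 1.0 s | a clearly-resolvable contrast vs exact equality — the two regimes in their clean form |
| rheology noise | multiplicative log-normal, 1% | rheometers err relatively, not absolutely |
| sweep | 121 points, 0.01–100 /λ (30 pts/decade) | four decades around the crossover |
| seeds | one top-level seed; curve *i* uses sub-seed (seed·7919 + i) mod 2³¹−1 | reproducibility curve-by-curve |

Green tests therefore establish that the *pipeline logic* is correct under
i.i.d. Gaussian/log-normal noise and truly mono-exponential (or two-pool)
recovery. They do not establish anything about baseline distortions,
radiation damping, temperature drift, B₁ inhomogeneity, peak-overlap
integration error, or multi-mode viscoelastic spectra — real-data effects
deliberately outside the generator. Monte-Carlo bounds of the form
"within 3% over N seeds" are asserted on the RMS error across seeds (the
per-seed maximum is bounded only in probability); per-seed errors are
additionally guarded at a loose 10%.

## Numerical choices

* Angles are degrees at every interface and radians internally; times are
  seconds everywhere; frequencies rad/s (CSV/CLI offer an `--hz` switch).
* T₁ search bounds $[10^{-4}, 10^3]$ s; bound hits flag the fit.
* Equality of the two regime-map terms classifies as spin diffusion
  (strict inequality required for "motion").
* `Inf` is a valid correlation time meaning "this motion is absent"; the
  harmonic composition handles it exactly.
* Reports are JSON with units in the key names (`t1_s`, `omega_c_rad_s`),
  written at full precision so a fixed seed gives byte-identical output.
* The 1000-replicate Monte-Carlo sketched for the fitter is run at 500
  replicates in the acceptance suite and 200 in the module suite, purely
  for runtime; the measured quantities are stable well below these sizes.

## Limitations

Single-pair treatment (no Redfield relaxation matrix for the full ¹H
network), no temperature dependence, no raw spectrometer processing
(peak integrals are assumed done upstream), and the τ-window artifact
described above. The spin-diffusion prefactor is calibrated, not derived,
so absolute rates from the map are meaningful only relative to each other;
the dominance *pattern* is the exported result.
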