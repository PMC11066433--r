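---
title: "Methods: the bistable TGF-β1 switch and its analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the bistable TGF-β1 switch and its analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgfswitch)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, the numerical
choices, and the limits of what the synthetic-data experiments can show.

## 1. The core switch model

Dermal fibroblast senescence is organized around a double-feedback motif:
THBS1 activates latent TGF-β1 (positive arm) and FMOD sequesters active
TGF-β1 away from its receptor (negative arm), while TGF-β1 in turn induces
THBS1 and represses FMOD. The core model captures this with three ODEs in
nondimensional units:

$$\frac{d[\mathrm{THBS1}]}{dt} = a\frac{T^{n_a}}{T^{n_a}+K_a} - d_1[\mathrm{THBS1}],\qquad
\frac{d[\mathrm{FMOD}]}{dt} = b\frac{K_b}{T^{n_b}+K_b} - d_2[\mathrm{FMOD}],$$
$$\frac{dT}{dt} = c\,\frac{[\mathrm{THBS1}]}{[\mathrm{THBS1}]+K_1}\,
\frac{K_2}{[\mathrm{FMOD}]+K_2} - d_3 T, \qquad T \equiv [\mathrm{TGF\beta1}].$$

Assumptions worth making explicit:

- **Quasi-equilibrium transcription.** The Hill terms lump transcription,
  translation and secretion into single saturating responses. $K_a$ and
  $K_b$ act on $T^{n_a}$ and $T^{n_b}$ directly, so their units are
  concentration$^{n_a}$ and concentration$^{n_b}$ — they are *not* EC50
  values (the EC50s are $K_a^{1/n_a}$, $K_b^{1/n_b}$).
- **Unit decay normalization.** Only the ratios $a/d_1$, $b/d_2$, $c/d_3$
  are identifiable from steady-state data, and the stochastic extension
  assumes unit mean-reversion. The package therefore defaults
  $d_1=d_2=d_3=1$, so time is measured in relaxation times and `a`, `b`,
  `c` coincide with the ratios.
- **Fitted defaults.** The dose–response fit pins $a/d_1 = 2.36$,
  $b/d_2 = 0.33$, $K_a = 0.016$, $K_b = 0.002$, $n_a = 1.6$, $n_b = 1.7$.
  The constants $c/d_3$, $K_1$, $K_2$ are *not* determined by that fit;
  `default_core_params()` fills them with the endogenous-model values
  (3.5, 0.46, 0.62) and documents the provenance in the shipped
  `fitted_params.yaml`.

Setting the derivatives to zero gives the steady arms
$\bar{TH}(T)$, $\bar{F}(T)$ and, after substitution, the scalar map
$f(T) = (c/d_3)\,\bar{TH}/(\bar{TH}+K_1)\cdot K_2/(\bar F + K_2)$ whose
fixed points $T=f(T)$ are exactly the TGF-β1 steady states. Because
$n_a > 1$, $f$ is superlinear at the origin, so the trivial state
$(0,\ b/d_2,\ 0)$ always exists and is stable for positive $K_1$, $K_2$ —
the "young" state.

### Numerics of root finding and stability

The map is extremely steep near the origin ($K_a = 0.016$ with
$n_a = 1.6$ makes $\bar{TH}$ rise almost vertically), so
`find_fixed_points()` brackets sign changes of $T - f(T)$ on a dense
composite grid — half log-spaced from $10^{-13}$, half linear — before
refining each bracket with Newton's method on the closed-form derivative
(residual tolerance $10^{-10}$). Newton steps that leave their bracket fall
back to bisection and the result records that fallback. Roots below
$10^{-12}$ are merged into the zero state; genuine unstable roots down to
$\sim10^{-10}$ do occur for steep parameter sets and are kept.

Stability uses the scalar criterion ($f'(T) < 1 \Rightarrow$ stable) by
default, with the full 3×3 Jacobian (eigenvalue real parts) as an
alternative mode; the two agree whenever $d_1=d_2=d_3$, which the test
suite checks across random parameter sets. A derivative within $10^{-6}$
of 1 is labeled *marginal* with a warning rather than silently classified,
because it almost always means the parameters sit on a fold.

## 2. Endogenous (PDL) extension and bifurcation analysis

Replicative age enters through the population doubling level (PDL):
$\overline{[\mathrm{THBS1}\cdot\mathrm{PDL}]} = \alpha\,\mathrm{PDL}/(\mathrm{PDL}+K_\alpha)$ and
$\overline{[\mathrm{FMOD}\cdot\mathrm{PDL}]} = \beta K_\beta/(\mathrm{PDL}+K_\beta)$, with endogenous
TGF-β1 production rate $\gamma$ and half-saturation constants
$\tilde K_1$, $\tilde K_2$ (defaults $\alpha=3$, $\beta=5$, $\gamma=3.5$,
$K_\alpha=10.1$, $K_\beta=5$, $\tilde K_1=0.46$, $\tilde K_2=0.62$). For
bifurcation analysis the package follows the replacement convention:
`substitute_endogenous()` maps $c/d_3 \to \gamma$, $K_1 \to \tilde K_1$,
$K_2 \to \tilde K_2$ in the core map. The full PDL curves are used only in
fitting — whether they should also feed the dynamics is genuinely
ambiguous, and the replacement convention is the one the steady-state
analysis defines unambiguously.

Fold (saddle-node) detection is done two ways, and the package exposes
both because they cross-validate each other:

1. **Count-change bisection** along any scanned parameter
   (`scan_parameter`): robust, needs no structure.
2. **Variational form**: along $\gamma$ the map factorizes as
   $f = \gamma\,g(T)$ with $g$ independent of $\gamma$, so the nonzero
   branch exists iff $\gamma \ge \min_{T>0} T/g(T)$
   (`saddle_node_gamma`, bounded minimization on a log scale, relative
   tolerance $10^{-6}$). The same trick solves for the fold along $K_1$
   explicitly (`saddle_node_k1`).

With the fitted constants the $\gamma$ fold sits at $\gamma^* \approx
0.0743$; at the fitted $\gamma = 3.5$ the system is bistable with the
unstable threshold at $T \approx 1.7\times10^{-5}$ and the high state at
$T \approx 2.93$.

### The production scale of the (K1, K2) scans

The two-parameter bistability analysis is run at a $c/d_3$ that the
steady-state fit leaves free. The package makes that choice explicit and
computable: `calibrate_cd3_for_k1_fold(k1_fold = 15)` solves for the
$c/d_3$ that places the $K_1$ fold at 15 ($c/d_3 \approx 1.093$), so that
$K_1 = 14$ sits just inside the bistable region and $K_1 = 16$ just
outside. The bistable region is markedly asymmetric: $K_1$ variation can
always cross the fold, whereas for $K_1$ far enough above the fold
($K_1 = 25$ at this scale) no value of $K_2$ restores bistability, because
the FMOD factor $K_2/(\bar F + K_2)$ is bounded between
$K_2/(b/d_2 + K_2)$ and 1.

## 3. Stochastic extension

Gene-expression noise is modeled as Ornstein–Uhlenbeck fluctuations of
THBS1 and FMOD around their steady arms, with TGF-β1 treated as a control
parameter. This two-stage structure is implemented literally — TGF-β1
carries **no** noise:

1. draw $T(0) \sim U(0, T_{\max})$, relax $dT/dt = f(T) - T$ by forward
   Euler until the per-step change is below $10^{-9}$ (each path lands on
   its basin's fixed point $\bar T$);
2. run Euler–Maruyama on
   $dX = (\bar X(\bar T) - X)\,dt + \sigma\,dB$ for both variables from
   zero initial conditions, clamping negative excursions to zero.

Defaults mirror the imaging-scale experiment: $\sigma_1=\sigma_2=0.2$,
$T_{\max}=0.2$, 10,000 paths, $dt = 0.01$; the alternative supplementary
setting ($\sigma=0.05$, $T_{\max}=1$) is one constructor call away.
"Long enough" is operationalized as $t_{\mathrm{stationary}} = 20$
relaxation times: the OU autocorrelation decays as $e^{-t}$, so 20 units
is far beyond mixing, and the scheme's stationary standard deviation is
$\sigma/\sqrt{2}$ (checked to Monte-Carlo accuracy in the tests).

Clamping introduces a bias only when a variable's mean sits within a few
$\sigma$ of zero. On the upper branch the THBS1 mean ($\approx 2.35$) is
17 standard deviations from zero, and the measured clamped-step fraction
is far below 1%; FMOD's upper-branch mean is itself nearly zero, so its
marginal is intrinsically a clamped (censored) Gaussian — that is a
property of the model, not an artifact. The analyses of modality therefore
use the THBS1 marginal.

Randomness is organized as per-path substreams derived from the ensemble
seed (initial draws and noise streams use disjoint offsets), so enlarging
`n_paths` extends the ensemble without reshuffling earlier paths, and
identical configurations are bit-identical.

### Silverman modality test

`silverman_test()` implements the critical-bandwidth bootstrap: the
smallest Gaussian-KDE bandwidth $h_{\mathrm{crit}}$ with at most $k$ modes
(modes counted on a 512-point grid over the sample range extended by three
bandwidths; mode counts are monotone in $h$ for the Gaussian kernel, so
bisection applies), then the proportion of variance-rescaled smoothed
resamples whose KDE at $h_{\mathrm{crit}}$ has more than $k$ modes
(999 bootstraps by default, add-one p-value). Two practical caveats the
tests respect: the test is anticonservative for $k$ above the true mode
count, and a *single* extreme outlier can inflate $h_{\mathrm{crit}}$ and
force a spurious rejection — which is why the "far from the fold"
demonstration below uses a regime whose low basin is genuinely unpopulated.

### The bimodal-to-unimodal shift

Near the $K_1$ fold (at the calibrated production scale, $K_1 = 14$,
fold at 15) the uniform initial distribution straddles the unstable
threshold: about 20% of paths relax to the low state and the terminal
THBS1 marginal is strongly bimodal (Silverman $k=1$ rejects). Deep in the
monostable-high regime the threshold collapses toward zero and essentially
every path lands high, giving a unimodal marginal. With the fitted Hill
arms the threshold shrinks only gradually as $K_1$ decreases, so the
package demonstrates the contrast at $K_1 = 0.05$, where the expected
low-basin occupancy of a 1,500-cell sample is below 0.1 cells. At
intermediate $K_1$ the low mode persists as a small subpopulation — the
shift is gradual, which is exactly what "relatively unimodal" describes.

## 4. Least-squares fitting

Both fitters are bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) on
pooled per-replicate residuals (replicates are *not* averaged first; the
N = 3 structure contributes three residuals per design point). Defaults,
chosen because the source analysis reports none:

- bounds: amplitudes $(10^{-6}, 100]$, half-saturations
  $(10^{-6}, 10^3]$, Hill exponents $[0.5, 6]$;
- starts: amplitude = max observation, half-saturation = median dose
  raised to the trial exponent, plus a deterministic ladder of exponent
  starts $\{1, 1.5, 2, 3\}$ — the multi-start makes noise-free recovery
  robust despite the near-vertical small-dose region;
- the dose axis is unit-agnostic; the default synthetic design uses the
  assay doses $\{0, 0.2, 0.8, 4\}$ purely as labels.

On noise-free self-generated data both fitters recover the generating
parameters to optimizer precision; at 10% replicate CV the amplitude
parameters are recovered with <10% median error over 20 seeds, while the
Hill exponents are (as expected for 4-point designs) considerably wider.
`residual_profile()` provides a profile-likelihood-style identifiability
diagnostic by refitting all other parameters along a grid.

## 5. The reduced pathway model

The mechanistic TGF-β/VEGF model is a deliberate desk-scale reduction: 38
reactions and 30 species carrying the stated topology — THBS1-mediated
latent TGF-β1 activation (positive feedback), FMOD·TGF-β1 sequestration,
SMAD2/3 phosphorylation, SMAD2–SMAD3–SMAD4 trimer formation
(`trimer_form`), SMAD7 negative feedback on the receptor, an AND-gated
THBS1 promoter (SMAD trimer × AP-1), the VEGFR–Raf–MEK–ERK cascade driving
an anonymous lumped FMOD transcription factor, and PI3K–Akt crosstalk in
which receptor-driven pAkt represses FMOD transcription. The published
large model's exact rate values are not reproduction targets; the reduced
model is calibrated to reproduce the *orderings* the experiments
established.

Design choices that matter:

- **Rate laws.** Binding and complex formation are mass action;
  transcription-like steps are Hill. Every reaction is a declarative
  descriptor (`k × linear factors × Hill activations × repressions`)
  compiled once into a fast rate function, so networks serialize to YAML
  and reload to identical trajectories.
- **Trimer stoichiometry vs. rate.** The trimer consumes one pSMAD2, one
  pSMAD3 and one SMAD4, but its *rate* is linear only in SMAD4 and
  saturating in the phospho-SMADs: SMAD4 (0.0044 nM by ELISA) is orders of
  magnitude scarcer than SMAD2 (0.060 nM) and SMAD3 (0.38 nM), so the
  abundant partners operate near saturation. This is what makes SMAD4
  knockdown the most effective intervention and the trimer reaction the
  sensitivity bottleneck.
- **Bistability and irreversibility.** The basal latent-activation rate is
  set far below the THBS1-feedback ignition threshold, giving a stable
  low resting state (computed by settling the unstimulated network, so
  zero-dose simulations are flat) and a self-sustaining high state. A
  single TGF-β1 bolus commits the network within well under 4 h, which is
  why a 4 h washout and sustained dosing reach terminal THBS1 within a
  fraction of a percent of each other.
- **FMOD timescale.** FMOD turnover is 0.08 h⁻¹, so releasing the Akt
  brake at 0, 8 or 24 h leaves enough of the 48 h horizon for ≥80%
  recovery toward the resting level, while release at 32 h (16 h left,
  $1-e^{-1.28}\approx0.72$) does not — the 24 h breakpoint emerges from
  the turnover rate, not from an explicit switch.
- **Interventions.** Knockdowns scale the initial values of a conserved
  pool (siRNA pretreatment precedes stimulation); inhibitor events scale a
  named reaction's rate from their event time on; washout zeroes
  extracellular active TGF-β1 at its event time. All event times are
  integration breakpoints (piecewise `deSolve::ode`/lsoda), and outputs at
  an event time report the post-event state.
- **Differential evolution.** rand/1/bin with greedy selection
  (per-generation best is provably non-increasing), F = 0.8, CR = 0.9,
  seeded per run (`seed + 1 … seed + n_runs`), bounds required for every
  free parameter. The in-package implementation is ~50 lines and is
  exercised by recovery tests against self-generated data.
- **Sensitivity.** $S_y = \partial\ln M/\partial\ln y_j$ by forward finite
  differences with 1% perturbations, where $M$ is the trapezoidal THBS1
  time integral under stimulation. Both target conventions are provided —
  reaction rate constants (default, matching how the bottleneck reaction
  is reported) and nonzero initial species values.

## 6. Synthetic data: what it does and does not show

Every input the analyses consume is generated in code from the model
curves plus multiplicative replicate noise (lognormal by default, since
expression measurements are positive with SD scaling with the mean;
Gaussian available). Designs copy the assays: doses $\{0, 0.2, 0.8, 4\}$,
PDLs $\{24, 36, 47\}$, eight time points (0, 15, 30, 60, 120 min, 8, 24,
48 h), N = 3. Measurement-noise magnitudes are nowhere reported, so the
5–10% CV defaults are package choices, flagged as such.

Because the generators draw from the same families the fitters assume,
passing recovery tests demonstrates *implementation correctness and
identifiability under the stated designs* — not that real western-blot or
ELISA data satisfy those error models, and not that the printed parameter
values are the global optimum for the (unavailable) raw measurements.
Per-cell "intensity" samples are terminal ensemble draws; they emulate the
mixture structure of imaging data but none of its optics (background,
segmentation error, intensity nonlinearity).

## 7. Problem sizes and determinism

The shipped tests run the full pipeline at sizes chosen for a laptop-class
single core: 10,000-path ensembles where the stationary moments are
asserted, 1,500-cell populations for modality, 20-seed recovery studies,
and differential evolution at small populations/generations for the
count/monotonicity contracts (recovery uses a larger budget on two free
parameters). Every stochastic component is seeded; identical
configuration + seed reproduces byte-identical output files, which the
suite verifies by diffing files from repeated CLI runs.

## 8. Known limitations

- The scalar-map analysis covers the reduced system; no continuation
  methods (pseudo-arclength, codimension-2) are provided or needed.
- The Silverman test inherits the known fragilities of critical-bandwidth
  bootstraps (outlier sensitivity, anticonservativeness for large $k$).
- The reduced pathway network reproduces orderings, not published rate
  values; its parameterization is one defensible point in a large
  equivalence class, and `estimate_parameters()` exists precisely so users
  can recalibrate it against their own data.
- Imaging-derived modality p-values from the original experiments are not
  reproducible from tabular data and are not targets; the package
  reproduces the qualitative bimodal-to-unimodal shift instead.
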