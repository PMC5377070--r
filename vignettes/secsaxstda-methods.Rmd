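---
title: "Methods: automated SEC-SAXS/TDA analysis and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated SEC-SAXS/TDA analysis and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secsaxstda)
```

This vignette documents the models, algorithms, parameter choices and
numerical decisions behind the package, and what the synthetic-run tests
do and do not demonstrate about real beamline data.

## The measurement model

A split-stream SEC-SAXS/TDA experiment divides the column eluent between
a triple detector array (UV, right-angle light scattering, refractive
index, in series) and the SAXS capillary. Splitting reduces flow, not
concentration, so the same component concentrations pass both branches;
the TDA chain and the capillary sit behind different dead volumes, so the
two data streams are offset in time.

The detector responses for a dilute ideal solution are

$$RI(t) = \frac{dn}{dc}\,k_{RI}\,c(t), \qquad
  RALS(t) = \left(\frac{dn}{dc}\right)^2 k_{RALS}\, MW\, c(t),$$

with $dn/dc = 0.185$ mL/g for unmodified protein, and the background-
subtracted SAXS intensity of a mixture is the concentration-weighted sum
of component form factors, $I(q,t) \propto \sum_i c_i(t)\,MW_i\,P_i(q)$
with $P_i(0)=1$. Everything the pipeline computes is an inversion of one
of these relations:

* $MW_{RALS} = (RALS/RI)\cdot k_{RI}/(k_{RALS}\,dn/dc)$, pointwise across
  the elution peak;
* $c = RI/(dn/dc \cdot k_{RI})$, interpolated onto frame midpoints after
  timeline alignment;
* $MW_{I(0)} = MW_{ref}\cdot\frac{I(0)/c}{(I(0)/c)_{ref}}$ against a
  standard (BSA, 66.5 kDa) measured under the identical beam and
  geometry;
* $MW_{SEC} = 10^{a - b V_e}$ from the conventional column calibration;
* mixture weight fractions from the constrained decomposition
  $I_{mix} \approx k\sum_i f_i I_i$, $f_i \ge 0$, $\sum f_i = 1$, where
  the $I_i$ are concentration-normalized component curves, and
  independently from the weight-average inversion
  $f_{small} = (MW_{big} - MW_w)/(MW_{big}-MW_{small})$ applied to the
  $MW_{RALS}$ trace.

Disagreement between the routes is itself a result: it flags composition
effects (bound ligands, detergent, altered $dn/dc$) rather than a failed
analysis, and is reported as a verdict, not an error.

### Calibration and the split stream

$k_{RI}$ comes from the integrated RI peak of a standard of known
injected mass: only `injectedMass * splitFraction` milligrams traverse
the detectors, so the same constants are only valid for one split
configuration — recalibration after changing the split is by design.
$k_{RALS}$ is derived at the peak apex (not the integral) from the apex
concentration implied by the fresh $k_{RI}$; an apex ratio avoids
band-broadening mismatch between detector integrals. The registry of
$\varepsilon_{1\%}$ coefficients (BSA 6.14, HSA 5.8, ...) supports the UV
concentration route $c = 10A/(\varepsilon_{1\%}\,\ell)$.

## The synthetic-run generator

`simulateSecRun()` is a first-class, tested component, not a fixture: it
defines the study conditions under which the pipeline's accuracy is
measured.

* **Elution**: each species is a Gaussian in detector-stream volume
  ($V = t \cdot flow \cdot split/60$); the integral of $c\,dV$ equals
  injected mass × split fraction (mass conservation through the split).
* **Detector traces** follow the response equations above, evaluated on
  the frame time grid, with additive Gaussian noise of 1% of each trace
  maximum (`noiseFractionTda`).
* **Dead volumes** (defaults 2.8 µl splitter, 10/11/12 µl chambers) act
  on the TDA branch as one common pure delay plus one common Gaussian
  broadening with $\sigma_V$ equal to the total dead volume. Two
  modeling decisions are folded in here. First, broadening is shared
  rather than per-chamber: per-detector broadening would make the
  RALS/RI apex ratio systematically wrong in a way no pointwise analysis
  could repair, contradicting the apex-calibration design. Second, the
  exported traces are *inter-detector aligned* (all three carry the
  total delay), emulating what vendor acquisition software does when it
  maps the serial chambers onto one retention axis; without it the 3.6 s
  RALS-vs-RI offset skews the MW trace by ~15% at peak half-height. The
  SAXS branch sees only the splitter delay, so the SAXS-vs-TDA lag that
  `alignTimelines()` must recover remains physical (≈10 s at default
  settings).
* **Frames**: the expected photon rate is
  `countsScale * sum(c_i MW_i P_i(q)) + buffer(q)`; counts are
  Poisson-sampled over the exposure and stored with $\sigma=\sqrt{N}$.
  Defaults (`countsScale = 100`, flat buffer 2000 counts/s, 0.4 ml/min,
  1 s frames, ~0.5 mg injected) put ~10⁴ counts per point at a peak
  apex — chosen once as a realistic synchrotron regime in which the
  5–10% molecular-weight accuracy expected of the light-scattering route
  is a meaningful test, since detector noise levels are otherwise a free
  parameter.
* **Form factors**: homogeneous spheres by default
  ($R_g = \sqrt{3/5}\,R$), or `shape = "guinier"` for a pure exponential
  $\exp(-q^2R_g^2/3)$. The exponential shape exists for identity
  testing: a sphere's curvature inside the standard Guinier window
  biases the fitted $R_g$ by ~1.5%, so exact-recovery tests would
  otherwise conflate model mismatch with implementation error.
* **Determinism**: one RNG stream seeded per run with a fixed draw
  order; identical seeds give bit-identical frames and traces.

What the simulator does *not* emulate — and what passing tests therefore
do not show about real data: inter-particle interference, capillary
fouling, non-Gaussian elution (tailing), slow buffer drift or mismatch,
detergent micelles, and radiation damage in SEC mode (damage is modeled
in batch mode only, as a linear $R_g$ inflation). On real runs those
effects surface through the diagnostics (buffer-window similarity
failures, inconsistent MW verdicts), not through silent correction.

## Algorithmic choices

**Buffer identification.** The paper-level intent ("identify frames
containing solely buffer") leaves the criterion open. Implemented: the
earliest contiguous window (default 50 frames for SEC, ~5 for batch)
whose smoothed total intensity sits on the run's low plateau, whose
frames score below 1.5 reduced discrepancy against the window mean, and
— when an RI trace is present — whose frames lie within 3× noise of the
RI baseline, the RI signal being a sensitive monitor of solvent
composition. Pre-peak windows are preferred (column-bleed risk
post-peak); post-peak selection is opt-in. On 20-seed simulations the
selected window never contains more than 1% of the apex solute
concentration.

**Frame similarity** is the mean of $(I_a-I_b)^2/(\sigma_a^2+\sigma_b^2)$
— a reduced discrepancy that is ≈1 for statistically identical frames.
It deliberately replaces exact correlation-map P-value machinery; the
radiation-damage screen (score > 4 against the running average of
accepted frames, two consecutive exceedances) and the buffer similarity
gate both ride on it.

**Automatic Guinier analysis.** `autoRg()` exhaustively scans all
contiguous windows of ≥ 5 points (prefix-sum weighted least squares,
$O(n^2)$ fits, fully deterministic) and keeps windows self-consistently
satisfying $q_{max}R_g \le 1.3$ and $q_{min}R_g \le 1.0$ — the
community-standard validity bounds, configurable. Scoring multiplies a
fit-quality term (logistic in $R^2$, damped by
$e^{-(\chi^2_{red}-1)/2}$ for weighted fits), a breadth term
($\sqrt{\text{window fraction}}$) and a neighbor-consistency term
(Gaussian in the relative $R_g$ change against one-step-smaller/larger
windows). The design intent: on exact data every window fits and the
widest wins; under model curvature the $\chi^2$ damping shrinks the
window into the regime where the Guinier law actually holds; under noise
all admissible windows have $\chi^2_{red}\approx 1$ and breadth
stabilizes the choice. Frames whose low-angle signal is below 3× its
propagated uncertainty are marked *undetected* rather than fitted —
weakly scattering components are expected to escape automatic detection,
and the trace records that honestly.

**Peak handling.** Baseline correction interpolates between the medians
of the two flattest low-lying windows (5% of trace length) in the first
and last thirds; flatness is residual variance about a local line, so a
sloping but linear baseline qualifies, and among near-minimal-variance
windows the lowest-lying wins (a low peak apex is locally flat too).
Peaks are regions above 5× baseline noise, extended to the 0.5× noise
crossings, split at internal minima deeper than 20% of the lower
flanking apex (on a 5-point smoothed profile, and only where both flanks
clear twice the detection threshold). Apexes are refined by a
least-squares parabola on the log signal over the upper half of the peak
— exact for a Gaussian, noise-averaged over many points — which is what
makes the column-calibration MW reproducible to better than 0.1%.

**Timeline alignment** maximizes the normalized cross-correlation
between the per-frame I(0) trace and the RI trace (UV fallback)
resampled onto the frame grid, on a lag grid of a quarter frame interval
with parabolic peak refinement, and refuses to align below correlation
0.5. RI is the primary reference because the concentration route is
RI-based.

**Frame selection and component curves.** Frames within a peak whose
$R_g$ lies within max(5%, 2σ) of the running median are averaged — in
intensity-per-concentration units, so the final curve is directly
comparable across runs. The component $R_g$ is the precision-weighted
mean over selected frames (tail frames carry large uncertainties; equal
weighting would bias it), with a scatter-scaled uncertainty. $I(0)/c$ is
a ratio of sums over selected frames for the same reason. The reported
MW dispersions are the spread across selected frames/points; the
instrument-software error model they would correspond to is not
specified anywhere, so no claim of equivalence is made.

**Mixture decomposition** solves the constrained fit by non-negative
least squares on unnormalized weights (Lawson–Hanson via
`pracma::lsqnonneg`), normalizing afterwards so the overall scale
absorbs the sum; an exhaustive simplex-lattice search is kept as an
independent oracle in the tests. Component curves must be
concentration-normalized so the fitted weights are weight fractions —
the "volume fraction" terminology of the field is retained. The
two-variant small-species fraction (`weight_average`, the exact
two-state inversion, vs `paper_literal`, the ratio against the small
mass alone) exists because both conventions circulate; for a large:small
mass ratio of exactly 2 they coincide, which is easy to mistake for
general equivalence. The default is the exact inversion; the literal
variant is provided unmodified for reproducing analyses that used it.

## Numerical and degenerate-case policy

* Negative subtracted intensities are preserved; clipping would bias
  Guinier fits. Log-fits simply exclude windows containing non-positive
  points.
* Two-column .dat files load with $\sigma=0$ and a warning; all weighted
  fits then fall back to unweighted.
* All-zero uncertainties in the similarity score fall back to a relative
  RMS difference, with a warning.
* Division guards: the MW trace is masked where RI < 5× baseline noise;
  concentrations are masked below 3× noise and frames below 0.01 mg/ml
  are excluded from normalization. Masked points are `NA`, never zero.
* q is nm⁻¹ internally; Å⁻¹ input converts at the boundary (×10).
* The mixture fit refuses design matrices with condition number > 10⁶.
* Peaks whose retention falls > 20% outside the calibrated column range
  flag the MW as extrapolated rather than refusing.

## Problem sizes in the tests

The test and acceptance simulations use 480-frame runs (120 q points,
~8 minutes of elution at 1 s frames) and 20 seeds per accuracy figure;
the study system is the 66.5 kDa standard plus a 220 kDa tetramer with a
trailing 110 kDa dimer at ~10% of the mass, mirroring the
oligomer-equilibrium situation the method is designed to resolve. The
noiseless identity checks run the ideal configuration (zero dead
volumes, exponential form factors, no noise), where every estimator must
return ground truth to 10⁻³ or better; the accuracy checks run the
realistic configuration, where the acceptance bounds are 15 kDa on the
I(0) route, 10 kDa on the dimer plateau, 10% on the light-scattering
route and 0.1 RMS on the fraction cross-validation.

## Known limitations

* Overlapping elution peaks are not deconvolved on the chromatogram side
  (no evolving-factor-style analysis); co-eluting regions are handled on
  the scattering side by the mixture module.
* RALS is single-angle by definition: no angular extrapolation of the
  light scattering, and no viscometry.
* The forward-scattering calibration is relative (per-instrument
  standard), not absolute (cm⁻¹).
* The band-broadening model is a single Gaussian; strongly tailing
  columns will push the RI-derived per-frame concentrations and hence
  $MW_{I(0)}$ systematically at peak edges (the ratio against the
  standard cancels most, but not all, of this).
* UV-based stoichiometry of multi-component complexes is out of scope;
  only the UV concentration conversion is provided.
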