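---
title: "Models and methods behind repeatsizer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind repeatsizer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatsizer)
```

# The measurement principle

In a band-stacking microfluidic chip, DNA conveyed by a hydrodynamic flow is
opposed by an electrophoretic force inside a funnel-shaped channel. The two
forces balance at a length-dependent position, so all fragments of one length
accumulate ("stack") at a single distance from the channel constriction, and
that distance grows with molecular weight. Intensity at a band therefore
grows linearly with time: every minute the flow delivers
`concentration × flow rate` of additional DNA to the stack. A second,
identically actuated channel carries a reference ladder, turning one
micrograph into a calibrated sizing and quantitation experiment.

`repeatsizer` models exactly this observable layer — positions, widths and
integrated intensities of Gaussian bands along the channel axis — and stays
deliberately agnostic about the viscoelastic force physics that produces it.

# The position model

Band position versus fragment length is, empirically, an inhomogeneous power
law: steep (good resolution) for mid-size fragments, compressed at high
molecular weight. The instrument's own response curve is a per-chip,
per-actuation calibration that is not portable, so the package ships a
synthetic default: two power-law segments

$$x(L) = a_i\,L^{b_i},\qquad b_1 = 1.2\ (100\text{–}800\ \mathrm{bp}),\quad
b_2 = 0.7\ (800\text{–}4000\ \mathrm{bp}),$$

joined continuously at 800 bp, with the prefactor solved at run time from the
one geometric fact worth honoring: the 400 and 500 bp ladder bands sit 80 µm
apart. This choice makes 2 µm of position error correspond to ~3 bp in the
400–500 bp range, and gives adjacent-ladder resolution lengths of a few tens
of bp in the 200–1000 bp range — both in line with the behavior of real
dual-channel chips. The coefficients are defaults of the simulator, not
measurements; only relative geometry matters for closed-loop testing, and the
model is overridable wherever it is consumed.

Both ladder kinds share the law — the position–size response belongs to the
chip and actuation, not to the ladder run through it; `ladderKind` selects
the declared band list (100 bp ladder: 100–1000 bp plus 1500 bp, 11 bands;
1 kb ladder: 0.5/1/1.5/2/3/4 kb).

# The simulator

`renderFrame()` draws each band as a Gaussian ridge along the axis (sd
`sigma_um`) with a top-hat transverse profile filling its channel strip,
scaled so the integrated profile area equals `dye_gain × accumulated mass` —
intensity proportional to mass, as for an intercalating dye. Background is a
constant plus a linear gradient; noise is additive Gaussian, seeded;
counts are rounded and clipped to 16 bits.

Defaults, chosen once as a realistic operating point and then left alone:

| parameter | default | rationale |
|---|---|---|
| pixel size | 0.65 µm | 6.5 µm camera pixel behind a 10× objective |
| frame | 160 × 3200 px | ~2 mm of channel axis, two 40-row strips |
| band sd `sigma_um` | 8 µm | sharp amplicon bands; well sampled at 12 px |
| expanded-allele sd | 2.5 × 8 µm | the heterogeneity signature of unstable alleles |
| `dye_gain` | 20 counts·µm/fg | arbitrary unit; keeps operating-point peaks ~10³ counts, far from 16-bit clipping |
| noise sd | 5 counts | detection-limit bands (~50 counts) remain detectable after frame differencing, as they should be |
| background | 100 + 0.005·x counts | smooth offset plus gentle axial gradient |
| flow rate | 0.09 µL/min | standard operating point |
| position jitter | 0.5 µm sd per band | emulates run-to-run registration error; yields inter-channel discrepancies typically ≲ 2 µm |

The simulator emulates band stacking, linear intensity build-up, camera
noise, background, and registration jitter. It does **not** model
photobleaching, optical point-spread, band drift, Poisson statistics,
non-specific amplification products, or smears from continuous allele
distributions (heterogeneity appears only as Gaussian broadening). Passing
closed-loop tests therefore demonstrates the correctness of the analysis
chain under the stated image model, not robustness to every artifact of real
chips.

Scenarios (`listScenarios()`) pin down the study conditions: the
three-fragment calibration (466/798/1512 bp at 80 pg/µL against the 100 bp
ladder), the high-MW pair (1091/3314 bp), the dual-ladder concordance frame,
the detection-limit time series (8 bands at 0.125 pg/µL each, i.e. 1 pg/µL
total), and one scenario per patient-derived sample with its expected allele
sizes and measured stock concentrations diluted 100-fold.

# Densitometry

**Profiles.** The transverse reduction over a declared ROI strip (mean by
default; max available) gives one intensity per axial pixel; positions are
reported in µm from the constriction and increase with fragment length.

**Background.** Reference mode subtracts a same-grid frame (the natural
choice for time series, where the t = 0 frame predates any accumulation).
Model mode fits a polynomial of order ≤ 2 by iterated sigma-clipping
(high-side clipping at 3 robust sds, ≤ 6 iterations), so peaks do not bias
the baseline. Output is not clipped: small negatives are honest noise.

**Noise.** `1.4826 × MAD(diff(profile))/√2` — insensitive to peaks, which
occupy few grid points.

**Detection.** Local maxima of a lightly smoothed profile (Gaussian kernel,
2 grid points sd) ranked by topographic prominence: descend from each
maximum until a higher point is met; the key saddle is the higher of the two
stretch minima. This is the definition that does *not* award shoulder noise
the height of its parent peak. Thresholds: `min_snr` (default 5) times the
robust noise sd, with an absolute floor of 2 counts because integer-count
images cannot carry sub-count structure (quantizing a smooth gradient leaves
up to 1 count of staircase ripple even in noise-free frames). Maxima closer
than `min_separation_um` (default 20 µm) merge, keeping the more prominent;
exact ties keep the smaller position. Smoothing exists only for detection —
fitting always uses the raw profile.

**Fitting.** Sum-of-Gaussians plus one shared constant baseline per window,
by Levenberg–Marquardt least squares. Windows are the seed's nearest grid
point ± ⌈4·σ₀/Δx⌉ pixels (σ₀ = 8 µm initial sd); pixel-snapping makes
refitting from converged parameters idempotent to < 10⁻⁶ µm, since a
sub-pixel seed shift cannot change window membership. Overlapping windows
merge and are fitted jointly. A component is dropped, with a warning, if its
amplitude ends below 2 noise sds or its sd exceeds the window half-width;
non-convergence returns a flagged band carrying the seed values rather than
an error. Whether real-instrument fits share a baseline between neighboring
peaks is not documented anywhere we know of; the local shared-constant
policy is this package's own choice, made for robustness next to smears.

# Sizing

Calibration pairs fitted ladder positions with declared sizes by rank —
after fit rejection, a count mismatch aborts calibration rather than guess a
pairing. Interpolation is piecewise linear in (position, size) by default;
the log–log mode fits a local power law through the same knots and agrees
with linear interpolation to well under 3 % at inter-knot midpoints, which
is why the simpler default stands. Both modes pass exactly through the
knots, so the ladder sizes itself with zero error.

Out-of-range bands extrapolate linearly from the terminal segment and carry
a mandatory flag: extrapolated calls for very long heterogeneous alleles are
systematically under-read on real chips, and the flag is the interface for
that caveat. Uncertainty is first-order propagation through the local slope
with a fixed 2 µm registration term added in quadrature to the fitted
position error; the registration term is configurable and represents
inter-channel accuracy, not fit quality.

The resolution length uses `Rs = Δμ / 2(σ₁+σ₂)` (baseline width taken as 4σ
per band). The separation-resolution definition varies across the
electrophoresis literature; this explicit stand-in is recorded here and in
the function documentation.

# Quantitation

Concentration is the declared concentration of the nearest ladder band
(by |Δμ|, ties toward lower MW) scaled by the fitted-area ratio. Fitted
areas — not raw window sums — keep overlapping neighbors out of the
estimate. All concentrations are relative to the declared ladder amounts;
there is no absolute radiometric calibration, by design. The per-cycle
amplification factor is the geometric mean `g = (c₂/c₁)^{1/(n₂−n₁)}`, which
composes exactly across cycle spans. Molecule counts use 650 g·mol⁻¹·bp⁻¹.

# Repeat calling

Each locus is `L(N) = flank + 3N`, with the flank derived from a printed
anchor pair. Shipped anchors: *HTT* 15 repeats → 446 bp (the adjacent
polymorphic CCG tract is folded into the flank; per-sample CCG variation is
not modeled), GFP transgene 15 → 672 bp, *DMPK* 5 → 1051 bp (per-allele
flank 1036 bp). Published DM1 conversions are mutually inconsistent — one
band reproduces only under a subtractive convention that counts repeats in
excess of the 1051 bp normal amplicon — so both conventions ship as separate
loci (`DMPK`, `DMPK_subtractive`) and neither is silently preferred.
Likewise, the one tabulated *HTT* expanded allele (≈750 repeats at 2193 bp)
does not satisfy the linear model that fits every other entry (the model
predicts 2651 bp); the package keeps the model's prediction and surfaces the
discrepancy in its tests instead of reconciling it.

Calls round to the nearest integer by default; `floor` mode exists because
subtractive DM1 conversions are floor-consistent. Sizes at or below the
flank give a zero-repeat call with a warning, never a negative count.
Heterogeneity is the width ratio against the matched ladder band
(threshold 1.8, configurable), converted to bp and repeat spread through the
local calibration slope.

# Numerical choices and degenerate inputs

* Levenberg–Marquardt: ≤ 200 iterations, `ftol = ptol = 1e-12`.
* Sub-count prominences are never peaks (2-count absolute floor).
* Empty truth tables render background-only frames; empty seed lists are an
  error for fitting but an allowed (empty) result for detection.
* Zero ladder area or zero ladder width are hard errors (saturated or failed
  reference), not NaN propagation.
* Identical seeds give bit-identical frames; time series share the band
  jitter (bands do not move between exposures) with independent camera noise
  per frame.

# Problem sizes

Closed-loop checks run 20 seeded replicates of the calibration-trio frame
(3 targets each, 60 errors) for sizing/quantitation percentiles and 10
replicates of the dual-ladder frame for concordance — enough for stable 95th
percentiles and medians while keeping the full suite and the acceptance
script in the tens of seconds on one core.

# Known limitations

* The default position model is synthetic; absolute positions are not a
  chip's. Real use requires the instrument's own ladder calibration, which
  the analysis side consumes naturally (the position model is only a
  simulator input).
* Smeared, non-Gaussian allele distributions are approximated by a single
  broadened Gaussian; no component splitting is attempted (a band whose sd
  exceeds 1.8 × the ladder median is tagged `broad` instead).
* Single stabilized frame per analysis; time series feed only background
  subtraction and detection-limit checks, not band tracking.
* Fragments above ~4 kb are outside the shipped models and ladders.
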