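---
title: "Methods: independent TG-43 dose verification for HDR brachytherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: independent TG-43 dose verification for HDR brachytherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brachycheck)
```

## What the package computes

`brachycheck` is a second-check engine for HDR brachytherapy: given the
dwell geometry, dwell times and source calibration of a plan, it recomputes
the dose at named verification points independently of the treatment
planning system (TPS) and compares the two. The dose model is the AAPM
TG-43U1 general 2D formalism for a line source,

$$\dot D(r,\theta) = S_k \,\Lambda\,
  \frac{G_L(r,\theta)}{G_L(r_0,\theta_0)}\, g_L(r)\, F(r,\theta),
  \qquad r_0 = 1\ \mathrm{cm},\ \theta_0 = 90^\circ,$$

summed over dwells with their dwell times, $D = \sum_i \dot D_i t_i$.

The defining choice of this engine — and the reason a second check catches
TPS configuration errors rather than merely repeating them — is that
$g_L(r)$ and $F(r,\theta)$ are **not** interpolated from the tabulated data
the TPS uses. They are evaluated from analytic forms fitted to Monte Carlo
data:

$$g_L(r) = \frac{h\,r^{i}}{1 + j\,r^{k}}, \qquad
  F(r,\theta) = k(r) + \frac{a(r)\,u^{e(r)}}{1 + b(r)\,u^{e(r)}}
  + \frac{a'(r)\,(1-u)^{e'(r)}}{1 + b'(r)\,(1-u)^{e'(r)}},
  \quad u = \tfrac{\theta}{180^\circ},$$

where each coefficient function is a quad
$c(r) = c_1 r^{c_2} + c_3 r + c_4$ (zero entries are exact zeros, and
$c_1 r^0 = c_1$ for all $r > 0$ — a zero exponent means a constant term).
The geometry function uses the line-source form

$$G_L(r,\theta) = \frac{\beta}{L\,r\sin\theta} \ (\theta \neq 0^\circ),
  \qquad G_L = \left(r^2 - \tfrac{L^2}{4}\right)^{-1} \ (\theta = 0^\circ),$$

with $\beta$ the angle subtended at the point by the two tips of the active
length $L$. Because the fitted functions carry a known average deviation
from the Monte Carlo reference ($\Delta g_L$, $\Delta F_L$), the pass/fail
band is not arbitrary: linear error propagation gives the half-width
$\Delta(g_L F_L) = \sqrt{\Delta g_L^2 + \Delta F_L^2}$, which for the
built-in GammaMed Plus Ir-192 model ($0.5\%$, $0.9\%$) is $\pm 1.03\%$ at
display precision.

## Assumptions

* Water-equivalent, unbounded scattering medium: no heterogeneity,
  applicator attenuation or shielding corrections (the standard TG-43
  assumption set).
* The source is a rigid line segment; each dwell is fully described by a
  center, a unit orientation and a dwell time.
* All dwells and points share one patient coordinate frame. Internally
  everything is in centimetres; DICOM millimetres are converted once at the
  I/O boundary.
* Dose additivity across dwells (no transit dose between positions).

## Parameters that matter

| Parameter | Units | Default | Notes |
|---|---|---|---|
| `active_length_cm` (L) | cm | 0.35 | consensus value for the built-in source; overridable in the source YAML |
| `dose_rate_constant` ($\Lambda$) | cGy·h⁻¹·U⁻¹ | 1.118 | consensus value; overridable — the engine never hard-codes it |
| `half_life_days` | d | 73.83 | Ir-192 |
| `delta_g_percent`, `delta_F_percent` | % | 0.5, 0.9 | mean fit-vs-Monte-Carlo deviations; set the default band per source model |
| `r_min`, `r_max` | cm | 0.2, 10 | validity window of the fitted forms (see below) |
| `capsule_radius_cm` | cm | 0.05 | near-source guard radius around the source segment |
| `theta_min` | deg | 0.05 | clamp margin for the anisotropy poles |

The physical parameters ship as defaults because plans normally carry them
from the TPS; every test that depends on them states its fixture values
explicitly.

## Numerical choices

**Anisotropy at the poles.** With negative exponents, $u^{e}$ and
$(1-u)^{e'}$ diverge at $u = 0$ or $u = 1$. The fitted form is a smooth
surrogate that is never needed exactly on the axis (the geometry function
has its own collinear branch), so $\theta$ is clamped to
$[0.05^\circ, 179.95^\circ]$ and the evaluation is flagged
`clamped-theta`; the flag propagates into the verification report as a
warning. $F$ is reported as computed — it is not clamped to be
non-negative, so a pathological parameter set would surface as a visibly
wrong value rather than be masked.

**$\beta$ without `acos`.** $\beta$ is computed in the plane spanned by the
source axis and the point as the difference of two `atan2` angles,
$\beta = \mathrm{atan2}(\rho, z - L/2) - \mathrm{atan2}(\rho, z + L/2)$,
which is quadrant-safe and avoids `acos` round-off near $0^\circ$ and
$180^\circ$. The test suite cross-checks it against a law-of-cosines
evaluation from explicit tip coordinates.

**Collinear branch.** The closed form is applied when
$\sin\theta < 10^{-6}$, covering $\theta = 180^\circ$ as well as
$0^\circ$ by the mirror symmetry of the segment. A collinear point with
$r \le L/2$ is inside the source and raises the near-source error.

**Near-source guard.** Any point whose distance to the source *segment*
(capsule distance) is below 0.05 cm fails with a diagnosis naming the dwell
index and distance. The verification layer converts this error into a
failed result so batch verification continues — a point accidentally placed
on a dwell position is exactly the situation where a huge, meaningless
difference would otherwise be reported as a number.

**Validity window.** The fitted forms are analytic everywhere but accurate
only within the fit domain. The engine evaluates everywhere and *flags*
$r < 0.2$ cm and $r > 10$ cm (`near-field` / `far-field`) instead of
refusing: out-of-range points are a prompt to check the point's location,
not a computational failure. The window defaults are a judgement call in
the absence of a stated fit range for this parameterisation and are
configurable (`--rmin`, `--rmax`).

**Decay-date semantics.** Calibration and treatment dates are taken at
midnight and $\Delta t$ is the whole-day calendar difference. Sub-day decay
of Ir-192 is below 0.5% and far below what would flip a judgement at a
1.03% band; if exactness against a specific TPS convention is ever needed,
this day-count rule is the single place to change.

**Inclusive boundary.** $|D_{\mathrm{diff}\%}|$ exactly equal to the band
passes; the conventional reading of "within tolerance". No secondary legacy
gate (e.g. a ±5% fallback) is applied — the band is configuration, and a
different source model carries its own deviations.

**Display vs. comparison precision.** Reports print percentages to two
decimals; all comparisons use full precision.

## Plan input

The DICOM RT Plan reader (explicit VR little endian) flattens application
setups → channels → brachy control points. Dwell times are recovered by the
cumulative-time-weight convention: interval $i$ between consecutive control
points receives $t_i = T_{\mathrm{channel}} (w_{i+1} - w_i)/w_{\mathrm{final}}$
at the position of its end control point; zero-weight movement intervals
are kept as zero-time dwells (they contribute nothing). Because the brachy
module stores positions only, each dwell's orientation is derived as the
normalized central difference of the neighbouring distinct positions along
the channel polyline (forward/backward at the ends; a configurable default
axis for single-dwell channels) — the physical tangent of the source train.
Dose reference points carry a *target* dose, not necessarily the TPS point
dose; they are imported with a `target` label and the report shows which
dose was compared.

The portable text dialect (YAML) stores explicit center + orientation per
dwell — the content of the TPS's per-dwell transform matrix — and an
authoritative `tps_dose_cGy` per point, sidestepping both derivations. It
is the faithful carrier for second-check workflows and round-trips
losslessly (doubles serialized at 15 significant digits).

## The synthetic plan generator

`generate_synthetic_plan()` emulates a gynaecological HDR insertion: a
straight tandem along the patient axis (5 dwells, 0.5 cm steps) or a
tandem-ovoid arrangement with two short lateral channels tilted 25° outward;
dwell times uniform in 10–40 s; a 10 Ci-class calibration (40700 U) with a
seeded 0–30 day calibration-to-treatment interval; and four verification
points in the classical arrangement — point A 2 cm superior / 2 cm lateral
to the tandem on each side, a bladder point anterior, a rectum point
posterior — with ±0.2 cm seeded jitter so plans differ. These are realistic
magnitudes for the application, chosen once.

By default the TPS dose of each point is filled with the engine's own
output, optionally times $(1 + \mathrm{bias})$. That makes the generator a
*consistency* instrument: zero bias must verify to exactly 0.00% and PASS
(any discrepancy is a real defect in geometry, decay or summation), and a
known bias or dwell-time scaling must reproduce exactly through the
relative-difference algebra (a global $+2\%$ time scaling yields
$+2.00\%$ and FAIL at the 1.03% band). What passing these tests does *not*
show is agreement with an actual TPS dose engine on patient plans: the TPS
side computes $g_L$ and $F$ by table interpolation, so real-plan
differences are small but nonzero, and points too close to or too far from
the sources can fall outside the band even on correct plans. The
qualitative failure diagnostics (near-source, far-field) mirror that
behaviour; the quantitative clinical distribution cannot be reproduced
without patient plans.

## Problem sizes

The test suite and acceptance script run at desk scale, chosen to exercise
the properties without waste: $10^5$ random draws for the
constant-anisotropy identity, $10^4$ random geometries for the
point-source limit, 100 seeded synthetic plans (4 points each) for
end-to-end self-consistency, 1000 random day offsets for decay
monotonicity. The whole suite completes in well under a minute.

## Known limitations

* 2D formalism only: no 1D approximation, no along-away tables, no dose
  grids or DVHs.
* No heterogeneity, shielding or applicator attenuation corrections.
* DICOM support is read-only, explicit-VR little-endian, brachy module
  only; the per-dwell transform matrix some TPSs store in private
  attributes is not parsed — the text dialect carries that information
  instead.
* Source models are line sources; fitting new parameters to Monte Carlo
  tables is out of scope (the coefficient quads are configuration).
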