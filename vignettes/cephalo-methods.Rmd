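---
title: "Measuring head circumference from photographs: models, parameters and validation design"
author: "cephalo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring head circumference from photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cephalo)
```

# The measurement model

`cephalo` estimates occipitofrontal head circumference (HC) from a single
photograph under three modelling commitments.

**The head outline is an ellipse.** The widest circumference of a head
projects, at clinical photographing distances, to a closed convex curve
that an ellipse approximates well. We therefore reduce the traced pixel
contour to five parameters (center, semi-axes $a \ge b$, rotation
$\theta$) and report the circumference of that ellipse — not the arc
length of the raw pixel chain. This is a deliberate choice: a pixelated
boundary is a staircase whose arc length systematically *overestimates*
the length of the smooth curve it samples, and the bias depends on
orientation. The fitted-ellipse perimeter is unbiased in a way the raw
chain cannot be; the (corner-smoothed) chain length is still reported in
`arcLengthCm` as a diagnostic, and the two should agree within a couple of
percent on a clean image.

**Scale comes from a circular fiducial.** A reference object of known
physical diameter $D$ photographed in the same plane as the head gives the
conversion $s = d_{px}/D$ (px/cm). We estimate $d_{px}$ as the diameter of
the area-equivalent circle of the detected component,
$d_{px} = 2\sqrt{A/\pi}$, because pixel-count area is far more stable
under digitization than any perimeter- or extent-based diameter.

**Four manual landmarks correct the automatic contour.** The user marks
the top, bottom and two outermost lateral points of the head. These enter
a weighted refit of the ellipse in which each landmark carries the weight
of `landmarkWeight = 100` contour points. The weight is a design choice on
a genuinely open question — how strongly manual input should override the
automatic contour. At 100, four landmarks jointly weigh as much as ~400
contour points, comparable to the full contour of a desk-scale phantom, so
landmarks can pull a contour damaged by occlusion or shadow back onto the
true boundary, yet a fit that is already consistent with the landmarks is
essentially unchanged (landmarks exactly on the ellipse are a fixed point
of the refit, verified to 1e-6 in the tests).

## The perimeter formula

HC is computed with Ramanujan's second approximation,
$$P \approx \pi(a+b)\left(1 + \frac{3h}{10+\sqrt{4-3h}}\right),
\qquad h = \left(\frac{a-b}{a+b}\right)^2,$$
chosen over the exact elliptic integral because it is closed-form,
iteration-free and wrong by less than $10^{-5}$ % at any aspect ratio a
head can present ($a/b \le 3$; heads sit near 1.25). The exact adaptive
quadrature ($4aE(e)$) is retained behind `method = "exact"` and is what
the phantom generator uses for ground truth, so the formula and the
oracle are never the same code path. At the degenerate limit $b = 0$ the
approximation returns 3.9984 against the true 4 — a 0.04 % error that
marks the worst case of the formula, far outside the operating regime.

## Segmentation and detection gates

Foreground is whatever departs from the border-estimated background color
by more than `colorTolerance = 0.15` RGB Euclidean distance (unit scale).
After morphological closing (5 px disc), each connected component's traced
outer contour is fitted with an ellipse, and a component qualifies as
"oval" only if the fit's RMS orthogonal residual is below
`residualGate = 0.05` of its area-equivalent radius. Among qualifiers the
largest area wins, ties broken by lower residual. The gate operationalizes
"find the oval object": gray distractor polygons pass the color test but
fail the residual gate, and the reference disc passes both but loses on
area. A 5 % residual gate accepts mild boundary raggedness (hair) while
rejecting polygons and blobs.

The reference detector masks pixels within `tol = 0.35` RGB distance of
the stated reference color (default saturated blue, `c(0.10, 0.20, 0.95)`
— a bright, skin-dissimilar color is exactly what one wants in a physical
fiducial) and requires circularity $4\pi A/P^2 > 0.85$. The perimeter $P$
in that test uses a corner-smoothed contour polygon (two averaging
passes), because the raw pixel chain of a digital circle measures a few
percent long and would push true circles toward the gate. 0.85 accepts
bottle-cap-like discs under noise and perspective while rejecting
elongated or concave clutter.

Orthogonal point-to-ellipse distance, needed for residuals, is
approximated by mapping each point to the boundary along the ray from the
ellipse center. This is exact for circles and accurate to second order
near the boundary, where all fit residuals live; the exact distance
requires iterating a quartic per point and would buy nothing here.

# The phantom generator

The generator is the package's substitute for a clinical photograph
archive: it renders scenes where the correct answer is known exactly, so
every pipeline stage can be tested quantitatively.

What it emulates, and the defaults:

| Parameter | Default | What it stands for |
|---|---|---|
| `headSemiMajorCm`, `headSemiMinorCm` | 7.5, 6.0 cm | an infant-sized head (HC ≈ 42.5 cm, mid growth-chart) |
| `scalePxPerCm` | 20 px/cm | a phone photo at arm's length |
| `refDiameterCm` | 3.0 cm | a bottle cap |
| `noiseSd` | 2 (8-bit) | sensor noise; 5 in stress tests |
| speckle amplitude | 0.03 (fixed) | hair texture that makes the boundary non-trivial |
| `clutterCount` | 0 | gray distractor objects on the table |
| `foreshorten` | 1.0 | out-of-plane camera tilt, as a multiplicative shortening of the minor axis |
| `seed` | 0 | one seeded generator per render |

The boundary is anti-aliased via an approximate signed-distance coverage,
the image is quantized to 8 bits before return, and all randomness (clutter
placement, speckle, noise) comes from one generator seeded per call —
identical specs give byte-identical PNGs, which the suite asserts.

Ground truth records the *rendered* ellipse and its extremal landmark
points, plus two circumferences: `trueHcCm`, the perimeter of the
specified head before tilt (what a tape would measure), and
`renderedHcCm`, the perimeter of the foreshortened ellipse actually in
the image (the best any 2-D method can recover). Both are computed by
exact quadrature, never by the Ramanujan formula under test.

Tilt is modelled as foreshortening of one axis rather than full projective
rendering. That suffices to exercise the angle-sensitivity confounder —
the measured ellipse genuinely shrinks along one axis — but it does not
reproduce perspective's asymmetric distortions; see Limitations.

What passing phantom tests does **not** show: robustness to real skin/hair
color diversity, shadows, complex backgrounds, lens distortion, or
landmark placement error by actual users (generator landmarks are exact).
The phantom suite validates the geometry and the plumbing, not clinical
performance.

The rater-study simulator draws
$HC_{ijr} = T_i + b_j + e_{ijr}$ with $T_i \sim N(\mu, \sigma_s^2)$, fixed
rater biases $b_j$ and $e_{ijr} \sim N(0, \sigma_j^2)$ — exactly the
two-way model the ICC estimator assumes, which is what makes closed-form
parameter recovery checks possible
($ICC = \sigma_s^2 / (\sigma_s^2 + \sigma_e^2)$ for unbiased equal-error
raters). Defaults ($n = 37$ subjects, $\mu = 45$ cm, $\sigma_s = 2$ cm,
two raters with 0.5 cm error SD) mirror a small single-clinic validation
study in size and spread.

# The statistics

**ICC.** The package computes ICC from two-way ANOVA mean squares on the
subjects × raters cell matrix (duplicate cells averaged first; incomplete
designs are refused by name rather than silently dropped). The default
form is ICC(2,1) — two-way *random* effects, *absolute agreement*,
*single* measurement:
$$ICC(2,1) = \frac{MS_S - MS_E}{MS_S + (k-1)MS_E + \frac{k}{n}(MS_R - MS_E)}.$$
Absolute agreement is the right criterion when the two columns must agree
on the value itself (an app replacing a tape), not merely rank subjects
consistently; the consistency form ICC(3,1) and the one-way and
average-measures forms are available behind `form` for sensitivity
analysis. Confidence intervals follow the McGraw–Wong F constructions,
cross-checked in the suite against an independent implementation.
Negative point estimates are reported as computed — clamping to zero would
hide pathological variance structure. Interpretation bands are
lower-bound-inclusive: 0.5 is moderate, 0.75 is good, 0.9 is good, and
only values strictly above 0.9 are excellent.

**Bland-Altman.** Limits are mean ± 1.96·SD of paired differences (sample
SD, n−1), which bracket ~95 % of differences under normality — asserted
empirically at n = 100 000 in the suite.

**Cohen kappa on continuous data.** Kappa requires categories, so HC
values are binned into fixed-width intervals $[kw, (k+1)w)$ anchored at 0,
default $w$ = 1 cm — roughly the clinical granularity of a tape reading.
The width is configurable and reported in the result, because kappa's
magnitude depends on it; anchoring at 0 makes the binning reproducible
across datasets. When chance agreement $p_e$ reaches 1 (all values in one
bin), kappa is defined as 1 if observed agreement is also perfect and is
an error otherwise.

**SEM.** Reported as SD·√(1 − ICC), the standard error of a *measurement*
— the typical error attached to a single reading. The phrase "standard
error of the mean" (SD/√n) denotes a different quantity that shrinks with
sample size and says nothing about instrument precision; it is available
via `mode = "mean"` for completeness.

**t, F, Shapiro-Wilk.** Delegated to the standard routines (pooled
`t.test`, `var.test`, `shapiro.test`) and wrapped in a uniform result
class; the suite validates them by type-I-error calibration (10 000 null
replicates each, within 3 binomial SEs of 5 %) rather than by re-deriving
their distributions. No multiple-testing correction is applied anywhere;
the report presents each statistic as-is.

**Survey summaries** round percentages to integers with halves away from
zero (31/37 → 84 %).

# Numerical choices

* Ellipse fitting uses the Halir–Flusser block decomposition of
  Fitzgibbon's constrained fit, after centering and scaling the points to
  mean radius 1 for conditioning. Noiseless parametric points are
  recovered to 1e-6; collinear or < 5 points raise a fit error rather than
  returning garbage.
* Pixel coordinates refer to pixel centers, origin at the top-left, x
  rightward, y downward; angles counter-clockwise from +x; fitted
  ellipses are canonicalized to $a \ge b$, $\theta \in [0, \pi)$.
* Component selection ties (equal areas) break toward lower fit residual.
* The candidate gate, color tolerances and circularity threshold are fixed
  package defaults, exposed as arguments; they were chosen from the
  geometry of the scene (contrast between skin, background, clutter and
  fiducial colors) and not tuned per image.

# Validation design and problem sizes

The test suite is built on independent oracles: the perimeter oracle
integrates the full parametric arc length (a different integral from the
package's quarter-period form); the ICC oracle spells out sums of squares
in explicit loops; toy statistics are hand-computed. Phantom-based checks
assert: ≤ 1 % ellipse recovery on clean renders, ≤ 0.5 cm end-to-end
error, ≤ 0.5 cm SD across 30 re-renders with noise SD 5 and tilt in
[0.97, 1] (the instrument's repeatability target), scale equivariance
within 1 % for joint rescaling by 0.5–2×, and rotation invariance within
0.5 %. Statistical checks run at sizes where Monte-Carlo error is
negligible relative to the asserted tolerance: ICC parameter recovery
averages 100 replicates of 200-subject studies against the closed-form
truth (±0.05), coverage runs at n = 100 000 (±0.5 pp), and test
calibration at 10 000 replicates (3 binomial SEs). These sizes were chosen
so each check's sampling noise sits well below its tolerance.

# Limitations

* The ellipse model caps accuracy for genuinely non-elliptical head
  outlines (molding, severe plagiocephaly); the residual gate will still
  accept mildly irregular shapes, silently absorbing the discrepancy into
  the fit.
* Foreshortening is a one-axis scale factor; true perspective also shifts
  the apparent center and bends the outline. Small tilts (≤ 3 %) are
  covered; oblique shots are not.
* The reference must be coplanar with the head's widest plane; the package
  cannot detect violation of that assumption from a single image.
* Landmarks are trusted as given (subject to ordering sanity checks); the
  simulator does not model human clicking error, so the landmark-fusion
  benefit measured here is an upper bound.
* Kappa on binned continuous data depends on the bin width and is reported
  only alongside it; comparisons across studies require equal widths.
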