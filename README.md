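# cephalo

Photogrammetric head-circumference measurement and the agreement
statistics used to validate it.

## The problem

Occipitofrontal head circumference (HC) is the standard surveillance
measurement for infant head growth: the widest circumference of the head,
taken in clinic with a flexible tape. Tape measurements are quick but
operator-dependent — hair, tape placement and tension all inject error —
which has motivated app-based alternatives that estimate HC from a single
photograph. The photographic approach needs two ingredients: a way to
recover the head's outline in the image, and a way to convert pixels to
centimeters, supplied by a bright circular reference object of known
physical diameter (a bottle cap, for instance) placed in the frame.

`cephalo` implements that measurement back end at desk scale, together
with everything needed to validate it **without any clinical data**:

* **`phantom_sim`** — renders synthetic "phantom" photographs (a skin-tone
  head ellipse with speckle texture, a saturated blue reference disc, gray
  distractor clutter, sensor noise, optional out-of-plane tilt) with exact
  ground truth, and simulates crossed subject × rater measurement studies
  with known variance components.
* **`vision_core`** — segments the oval head candidate, fits its contour
  with a direct least-squares ellipse, fuses four manually supplied
  landmark points (top, bottom, two lateral extremes) into the fit,
  calibrates the pixels-per-cm scale from the reference disc, and reports
  HC in centimeters.
* **`agreement_stats`** — intraclass correlation with interpretation
  bands, Bland-Altman limits of agreement, binned Cohen kappa, standard
  error of measurement, variance-ratio and pooled t tests, Shapiro-Wilk
  normality checks and survey summaries.
* **`hcapp`** — a command-line workflow
  (`measure` / `simulate-phantom` / `simulate-raters` / `agree` / `survey`)
  over the same functions.

## The method

**Measurement.** The head contour is traced from a color-distance
foreground mask and fitted with the ellipse-specific direct least-squares
conic fit (Fitzgibbon's method with the Halir–Flusser stabilization). The
four landmarks are folded in by a weighted refit — each landmark counts as
100 contour points — so manual input corrects the automatic contour
without discarding it. The reference disc is found by color, gated on
circularity 4πA/P² > 0.85, and its area-equivalent diameter gives the
scale s (px/cm). HC is the Ramanujan II perimeter of the fused ellipse:

    h = ((a − b) / (a + b))²
    HC = π (a/s + b/s) (1 + 3h / (10 + √(4 − 3h)))

accurate to far better than 0.001 % at head-like aspect ratios (an exact
elliptic-integral mode is provided for reference).

**Reliability.** The default ICC is ICC(2,1) — two-way random effects,
absolute agreement, single measurement — from ANOVA mean squares, with the
McGraw–Wong F-based 95 % interval and the conventional bands (< 0.5 poor,
0.5–0.75 moderate, 0.75–0.9 good, > 0.9 excellent). Limits of agreement
are mean ± 1.96 SD of the paired differences. Cohen kappa is computed
after binning the continuous HC values into fixed 1 cm bins (configurable).
SEM is SD·√(1 − ICC).

## Worked example

```r
library(cephalo)

## render a phantom: 7.5 x 6.0 cm head at 20 px/cm, 3 cm reference disc
ph <- renderPhantom(phantomSpec(seed = 1, noiseSd = 5))
ph$truth
#> GroundTruth: true HC 42.543 cm (rendered 42.543 cm), ref 60.0 px, scale 20.0 px/cm

## measure it back, using the generator's landmarks as the manual input
m <- measureHC(ph$image, groundTruthLandmarks(ph$truth), knownDiameterCm = 3.0)
m
#> HCMeasurement [app]: HC = 42.68 cm (scale 19.91 px/cm, fit RMS 0.244 px)
```

The pipeline recovers 42.68 cm against a ground truth of 42.54 cm — an
error of 0.13 cm, inside the 0.5 cm repeatability the instrument targets.
A simulated two-rater study (37 subjects, parent rater with +0.3 cm bias
and 0.6 cm error SD) exercises the statistics:

```r
tbl <- simulateRaterStudy(raterStudySpec(
  nSubjects = 37, subjectMeanCm = 45, subjectSdCm = 2,
  raters = data.frame(rater_id = c("researcher", "parent"),
                      bias_cm = c(0, 0.3), error_sd_cm = c(0.4, 0.6)),
  seed = 1))
agreementReport(tbl, arms = c("researcher", "parent"), by = "rater")
#> AgreementReport: researcher vs parent (rater) (n pairs = 37)
#> ICC(2,1) = 0.916 [95% CI 0.824, 0.958] - excellent reliability (n=37, k=2)
#> Bland-Altman: mean diff -0.289 cm, SD 0.668 cm, LoA [-1.599, 1.020] (n=37)
#> Cohen kappa = 0.415 (p_o 0.514, p_e 0.168, bin width 1.00 cm)
#> SEM = 0.504 cm
#> f_variance: statistic 0.9950, df (36, 36), p = 0.988
#> t_two_sample: statistic -0.7138, df (72), p = 0.4776
#> shapiro_wilk: statistic 0.9467, df (-), p = 0.0757
```

The ICC of 0.92 says 92 % of the variance in these measurements is true
between-subject variance; the limits of agreement say a parent and the
researcher will disagree by less than ~1.6 cm for 95 % of infants; the
mean difference of −0.29 cm reflects the injected parent bias.

The same workflow from a shell:

```sh
HCAPP=$(Rscript -e 'cat(system.file("scripts", "hcapp.R", package = "cephalo"))')
Rscript $HCAPP simulate-phantom --out-dir phantoms --seeds 1,2,3
Rscript $HCAPP measure --image phantoms/phantom_0001.png --out m.json
Rscript $HCAPP simulate-raters --n-subjects 37 --out study.csv --seed 1
Rscript $HCAPP agree --table study.csv --compare rater:researcher-vs-parent --out report.json
```

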