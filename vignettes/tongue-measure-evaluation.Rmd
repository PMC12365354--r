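---
title: "Evaluating measures of midsagittal lingual articulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating measures of midsagittal lingual articulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonguespace)
```

## The problem

Ultrasound tongue imaging, post-processed with a landmark tracker, reduces
each vowel token to 11 ordered points ("knots") on the midsagittal tongue
surface: knot 1 at the vallecula, knots 2–3 on the tongue root, knots 5–7
on the dorsum, knot 11 on the tongue tip, with two extra knots crowded
into the tip/blade region.  After rotation to the occlusal plane the x
axis is anatomically horizontal (x increases anteriorly, y superiorly,
units mm).  Phonetic practice then summarises a token with one scalar
measure of tongue *position* (frontness) and one of tongue *height* or
*shape*, but the field has no agreed answer to which pair of scalars best
captures the lingual contrast between vowels.  This package implements a
measure battery and three complementary evaluation strands for exactly
that question, together with a synthetic cohort generator that makes the
whole pipeline testable with known ground truth.

## The measure battery

Sixteen measures per token, eight of position and eight of height/shape;
their cross product gives the 64 pairs swept by both evaluation strands.

* **Knot coordinates** — `K2_X … K7_X` (position), `K5_Y … K7_Y` (height)
  are the raw landmark coordinates, in mm.
* **Highest point (HP)** — the point of maximal y on a 100-point
  spline-densified contour; `HP_X`, `HP_Y`.  Ties break to the most
  posterior point.  HP is deliberately *not* rotation-invariant: it
  inherits the occlusal-plane orientation.
* **Highest vertex (HV)** — the densified point farthest, in
  perpendicular distance, from the chord joining vallecula (A) and tongue
  tip (B); `HV_X`, `HV_Y`.  The chord triangle (apex height HVD, foot of
  the perpendicular D) yields the shape ratios **TCP = HVD/AB** and
  **TC = AD/DB**.  A source table in the literature lists the "TCP"
  abbreviation twice; we follow the triangle-figure assignment above, and
  `measure_combos(alias = )` can relabel the two columns without touching
  the math.
* **MCI** — the Modified Curvature Index, the integral of absolute
  curvature with respect to arc length, i.e. the total absolute turning
  of the contour in radians.  A straight line gives 0; a circular arc
  gives its subtended angle regardless of radius.

TCP, TC and MCI are invariant under rigid motion and uniform scaling;
knot coordinates and HP are not, which is why the classification and
correlation strands z-score every measure within speaker first.

## Numerical choices

**Densification.** x(t) and y(t) are interpolated independently with
piecewise cubic polynomials against a shared parameter t, the cumulative
chord length of the 11 knots (chord-length parameterisation avoids
artificial parameter speed-ups where the anterior knots crowd together).
We use Forsythe–Malcolm–Moler end conditions (`stats::splinefun(method =
"fmm")`) rather than natural end conditions: forcing zero curvature at
the contour ends biases the curvature integral near the endpoints and
costs about 5.7% on the circular-arc oracle, whereas the FMM interpolant
reproduces arc turning to about 0.4%.  The 100 output parameters are the
11 knot parameters plus 89 interior values allocated per segment in
proportion to chord length, so the curve passes through every original
knot exactly while remaining near-uniformly sampled.

**MCI discretisation.** The densified contour is resampled at 100 points
equally spaced in cumulative arc length; first and second derivatives are
estimated by central finite differences (one-sided at the ends), the
signed curvature by $(x'y'' - y'x'')/(x'^2+y'^2)^{3/2}$, and $\int
|\kappa|\,ds$ by the trapezoid rule.  On circular arcs subtending
$\pi/6$ to $\pi$ this recovers the subtended angle within 2%.

**Degenerate shapes.** A contour whose apex height is below
$\varepsilon_{\text{flat}} = 10^{-6}$ mm has no meaningful apex: TCP is
0, TC is `NaN` and the token carries a degeneracy flag.  Downstream,
`NaN` values are dropped pairwise per measure pair with a logged count,
so the 64-pair bookkeeping is preserved.  An apex projecting exactly onto
the tongue tip yields a `TC = Inf` sentinel.

## The three evaluation strands

**MDS baseline + Procrustes residuals.** Per speaker, each token's 22
stacked coordinates enter a Euclidean-distance non-metric MDS
(`vegan::monoMDS`, global model) in two dimensions, run from the
classical principal-coordinate start plus 20 random restarts; the
configuration with the lowest Kruskal stress-1 (computed by one shared
formula, with monotone regression via `stats::isoreg`) is kept, rescaled
to the input dissimilarity scale, and PCA-rotated so MDS1 carries maximal
variance.  The non-metric variant is the default because stress is
conventionally judged against non-metric adequacy thresholds (~0.05 =
good); a classical (principal-coordinate) variant is available for
sensitivity checks.  Each of the 64 measure pairs then forms a 2-column
physical configuration per speaker, superimposed on that speaker's MDS
space by ordinary Procrustes analysis (SVD solution, written in the
package; `vegan::procrustes` cross-checks it in the tests).  Defaults:
symmetric normalisation ON — both configurations centred and scaled to
unit root sum of squares, so the residual ss lies in [0, 1] and is
symmetric in its arguments — and reflections allowed, since MDS axes have
arbitrary orientation.  Measures enter in raw mm here; the
superimposition absorbs scale.

**Speaker-held-out classification.** Measures are z-scored within
speaker (sample sd, n−1), removing anatomy and probe-placement offsets.
Per replicate, 75% of speakers (floor, without replacement) train a
linear discriminant classifier (`MASS::lda`, empirical class priors —
the design is near-balanced) on the two measures of a pair; all tokens
of the held-out speakers are classified into the five vowels, and
accuracy is pooled within the replicate, then averaged over 100
replicates.  The same split sequence is reused across all 64 pairs
(common random numbers), so ranking differences are not split-noise
artifacts.  A replicate whose training set lacks a vowel class is
redrawn (at most 10 times, logged).  Classification errors then feed a
Bernoulli mixed-effects logistic regression — error ~ vowel ×
position-measure + vowel × height/shape-measure with random intercepts
for speaker and for replicate (`lme4::glmer`, `nAGQ = 0`) — with a weak
ridge-penalised fixed-effects fallback (IRLS, λ = 10⁻³) if the mixed fit
fails.  The "trial" grouping factor is interpreted as the resampling
replicate; the package exposes the trial table so a token-level grouping
can be fitted instead.

**Correlations.** Within-speaker-scaled values are reduced to one mean
per (speaker, item) cell — the item being one of the five word types —
to remove repetition-level autocorrelation, then pairwise-complete
Pearson correlations are computed among the 16 measures and against
within-speaker-scaled F1/F2 midpoint formants.  Raw coefficients are
reported, no p-values and no multiplicity correction.

## The synthetic cohort generator

No generative model accompanies the original measurement scheme, so the
package defines a deliberately minimal one with closed-form latents.  A
token's surface is a circular tongue-body arc (radius 40 mm) plus a
Gaussian constriction bump of height `degree_mm` at angle `theta_c`
(radians along the arc; small = anterior), a root-advancement shear of
the posterior third, and an anterior tongue-body shift for front vowels
whose weight profile peaks over the dorsum — the tongue body carries
vowel frontness while root and tip are comparatively anchored.  The 11
knots sit at fixed arc fractions (nine equally spaced, two extra
anterior).  Speaker anatomy adds a uniform scale (0.85–1.15), a
translation (±8 mm) and per-token probe rotation jitter (sd 2°);
landmark noise is Gaussian (0.5 mm per coordinate) with per-knot
multipliers that inflate posterior and tip knots, mirroring the poorer
image quality near the hyoid shadow and the sublingual airspace.
Formants follow F2 = 2550 − 600·θc + ε (frontness raises F2) and
F1 = 1150 − 16·apex_height + ε (height lowers F1), ε Gaussian with sds
60 and 40 Hz.

Speakers differ in their idiolectal vowel targets (per-speaker jitter of
θc, degree and advancement; sds 0.20 rad, 1.3 mm, 0.7 mm), and tokens
jitter further around the idiolectal target.  The idiolectal sds were
fixed once so that held-out classification on the default cohort lands
between chance and ceiling (best pair ≈ 0.77, overall mean ≈ 0.68), the
regime in which pair rankings are informative; all of these values live
in `cohort_config()`, not in code.

The generator emulates the *structure* of articulatory cohort data —
vowel-specific constriction location/degree, anatomical scaling, probe
jitter, landmark noise, monotone articulation–acoustics coupling — but
not its texture: real tongues are not circular arcs, real constrictions
are asymmetric, formant couplings are nonlinear near extreme
constrictions, and tracker errors are not isotropic Gaussian.  Passing
tests therefore demonstrate that the pipeline recovers known structure
through the full measurement chain, not that any particular measure is
best for real data.

## Problem sizes and reproducibility

The default study conditions are 40 speakers × 5 vowels × 4–6
repetitions (~1000 tokens).  The bundled analysis scripts and the
acceptance script run the full 64-pair sweeps at 100 classification
replicates; the error model is fitted on a thinned trial set (5
replicates × 64 pairs, ~78k trials), which estimates the same
fixed-effect structure at a fraction of the cost of the full 1.6M-trial
set.  The unit-test suite uses smaller cohorts (3–20 speakers) for
bookkeeping and property checks and the full default cohort for
end-to-end recovery.  Every stochastic step — cohort generation, MDS
restarts, speaker splits, error simulations — is a pure function of an
integer seed, and pipeline reruns with the same configuration are
byte-identical.

## Known limitations

* The highest-point search defaults to the whole contour; flat tongue
  shapes can put HP at a contour end and make it uninformative (it can
  even be constant within a speaker, in which case within-speaker
  scaling emits zeros with a warning).  A knot-window switch
  (`hp_window`) restricts the search, but the default analysis does not
  use it.
* Procrustes and MDS are 2-D only; no generalised (multi-set)
  Procrustes.
* The occlusal rotation takes the bite-plane angle as given; acquisition
  software sign conventions vary and must be checked by the user.
* Formants are consumed or synthesised, never estimated from audio.
* The stress statistics of any particular recorded corpus depend on the
  MDS variant and restart policy; the classical variant is provided to
  quantify that sensitivity.
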