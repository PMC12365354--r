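# tonguespace

Quantitative evaluation of scalar measures of vowel articulation from
midsagittal tongue-contour landmarks.

Ultrasound tongue imaging pipelines reduce each vowel token to 11 ordered
landmarks ("knots") on the tongue surface — knot 1 at the vallecula,
knots 2–3 on the root, 5–7 on the dorsum, knot 11 at the tip — rotated to
the occlusal plane so that x is anatomically horizontal (mm).  Working
phoneticians then summarise a token with one scalar of tongue *position*
and one of tongue *height* or *shape*.  This package is for researchers
who need to choose such a pair defensibly: it computes a 16-measure
battery per token and evaluates all 64 position × height/shape pairs
three complementary ways, against a per-speaker multidimensional-scaling
(MDS) reference space, in a cross-speaker classification task, and
through correlation structure.

## The battery and the evaluations

Per token: knot coordinates `K2_X…K7_X`, `K5_Y…K7_Y`; highest point
`HP_X`, `HP_Y` (max-y point of a 100-point interpolating cubic spline);
highest vertex `HV_X`, `HV_Y` (point farthest from the vallecula–tip
chord AB, with apex height HVD and chord foot D); the shape ratios

    TCP = HVD / AB        TC = AD / DB

and the Modified Curvature Index, the total absolute turning of the
contour,

    MCI = ∫ |κ(s)| ds     κ = (x′y″ − y′x″) / (x′² + y′²)^{3/2},

which is 0 for a line and θ for a circular arc subtending θ.

Evaluation strands:

1. **MDS + Procrustes** — per speaker, the 22-dim knot vectors are
   ordained in 2-D by non-metric MDS (Kruskal stress-1, classical start +
   20 random restarts); each measure pair's 2-column configuration is
   superimposed on the MDS space by ordinary Procrustes analysis
   (symmetric normalisation, reflections allowed) and pairs are ranked by
   mean residual sum of squares across speakers.
2. **Speaker-held-out LDA** — measures z-scored within speaker; linear
   discriminant classifiers trained on 75% of speakers classify the five
   vowels of the held-out 25%, 100 resampling replicates with splits
   shared across pairs; errors feed a mixed-logistic model (vowel ×
   measure interactions, random intercepts for speaker and replicate).
3. **Correlations** — pairwise-complete Pearson r among measures and
   against within-speaker-scaled F1/F2, on by-speaker by-item means.

A synthetic articulatory cohort generator (`generate_cohort()`) produces
landmark datasets with known constriction location/degree, speaker
anatomy, landmark noise and formant coupling, so the whole chain is
testable with ground truth.  See the methods vignette
(`vignettes/tongue-measure-evaluation.Rmd`) for models, defaults and
numerical choices.

## Worked example

```r
library(tonguespace)

cohort <- generate_cohort(cohort_config(seed = 1))   # 40 speakers, 990 tokens
measures <- measure_table(cohort$dataset)            # 16 measures per token

ords <- ordinate_speakers(cohort$dataset, seed = 1)  # per-speaker MDS
stress_summary(ords)
#>   n_speakers median upper_quartile
#>           40 0.0250         0.0307

head(as.data.frame(combo_sweep(measures, ords))[, 1:3], 3)
#>   position height_shape mean_ss
#> 1     K7_X         K7_Y  0.0735
#> 2     K6_X         K7_Y  0.0828
#> 3     K5_X         K7_Y  0.0835
```

Stress well under 0.05 means two MDS dimensions represent each speaker's
lingual vowel contrast well; the sweep then says which physical measure
pair reconstructs that space with least residual — here the x and y of
dorsum knots, with `K7_X`/`K7_Y` best (mean symmetric Procrustes ss
0.073).  On the same cohort, the classification strand ranks dorsum-x +
height pairs on top (best pair accuracy ≈ 0.77, mean across pairs ≈
0.68), and the correlation strand recovers the designed couplings —
r(K5_X, F2) = 0.985, with height measures correlating negatively with F1.

The full analysis is scripted as a numbered workflow:

```sh
Rscript analysis/01_simulate.R 1        # cohort -> results/cohort/
Rscript analysis/02_measures.R          # 16-measure battery
Rscript analysis/03_procrustes_sweep.R 1
Rscript analysis/04_classification.R 1
Rscript analysis/05_correlations.R
```

Each script states what it found and writes its tables under `results/`.

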