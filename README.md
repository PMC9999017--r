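# stirq

Predicting quantitative muscle-MRI biomarkers from conventional STIR
radiomics.

## The problem

Quantitative MRI of skeletal muscle delivers two biomarkers that track
disease activity in slowly progressive myopathies such as
facioscapulohumeral muscular dystrophy (FSHD): the **fat fraction** (FF, in
percentage points) of each muscle, and the **water T2** (wT2, in ms), a
marker of edema/inflammation. Both normally require dedicated multi-echo
sequences. A short-tau inversion recovery (STIR) sequence, by contrast, is
fast and available on essentially every scanner: residual fat appears dark,
edema bright. `stirq` implements a pipeline that asks how well FF and wT2
of the six calf muscles — Soleus (S), Medial/Lateral Gastrocnemius (MG,
LG), Anterior Tibialis (TA), Extensor Digitorum Longus (ELD), Peroneus
Longus (Pe) — can be predicted from a single mid-calf STIR slice, for
radiologists and imaging scientists who have STIR but not qMRI.

Three feature workflows feed seven regression models (LR, Ridge, Lasso,
TREE, RF, KNN, SVM) under 5-fold cross-validation:

* **WF1** — an IBSI-style 56-feature radiomic catalog per muscle ROI
  (25 first-order, 26 second-order from GLCM/GLZLM/GLRLM matrices, 5
  shape), reduced to 6 principal components;
* **WF2** — the same features, reduced instead by **information
  imbalance** feature selection: for a feature subset A and target B,
  Δ(A→B) ≈ (2/N) ⟨r<sup>B</sup> | r<sup>A</sup> = 1⟩ — the mean, over
  points, of the rank in B of the point's nearest neighbour in A. Low Δ
  means A's neighbourhoods predict B's; the subset minimizing Δ towards
  FF or wT2 is selected;
* **WF3** — two bespoke scalar features from healthy-control reference
  limits: per muscle an upper limit **UL = μ + 2σ** of pooled healthy
  muscle intensity and a global lower limit **LL** = mode of the pooled
  subcutaneous-fat intensity histogram. The **fat infiltration grade**
  (FFG) is the fraction of ROI pixels strictly below LL and the **muscle
  edema grade** (MEG) the fraction strictly above UL; FFG predicts FF and
  MEG predicts wT2.

Models are scored per muscle by the mean absolute error over folds
(MAE̅ = mean of the five fold MAEs, reported as "mean (sd)"), plus
coefficient-of-variation summaries (CV = σ/μ) and Pearson/Spearman screens
between KNN errors and cohort variability.

Because the original patient data are restricted, the package ships a
seeded **phantom generator**: cohorts of 2D calf-like slices with labeled
muscle ROIs whose pixel mixtures (dark fat patches, mid-gray muscle,
bright edema patches) are tied to known ground-truth FF and wT2 through a
linear-plus-noise link, so every stage is testable offline and parameter
recovery is measurable.

## Worked example

```r
library(stirq)

fshd   <- generate_fshd_cohort(phantom_params(n_subjects = 25, seed = 1234))
hc     <- generate_hc_cohort(phantom_params(n_subjects = 6, seed = 7))
limits <- compute_reference_limits(hc)
limits
#> <stirq_limits> LL = 31.00 (mode of 46080 fat pixels, bin 1.0)
#>   UL: S=120.0, MG=120.0, LG=120.0, TA=120.1, ELD=120.1, Pe=120.0

study <- run_workflow(3, fshd, limits = limits, models = c("KNN", "LR"), seed = 1)
glance(study)
#> # A tibble: 4 × 5
#>   workflow target model mean_mae sd_across_muscles
#>   <chr>    <chr>  <chr>    <dbl>             <dbl>
#> 1 WF3      FF     KNN      3.93             0.500
#> 2 WF3      FF     LR       2.80             0.563
#> 3 WF3      wT2    KNN      1.01             0.121
#> 4 WF3      wT2    LR       0.861            0.0647
```

The healthy-reference limits land where the generator puts the tissue
laws (muscle ≈ N(100, 10) pools to UL ≈ 120; the fat mode is 30, recovered
within one histogram bin), and the muscle-averaged WF3 errors — e.g. KNN
within ~4 pp for FF and ~1 ms for wT2 — sit close to the irreducible
ground-truth noise of the generator (3 pp and 1 ms). `tidy(study)` breaks
the same results down per muscle and fold; `autoplot(study)` draws the
per-muscle boxplots, and `summarize_study(study, fshd, dir)` writes the
muscles-by-models result tables, the CV table and the correlation screen
as CSV.

A thin command-line wrapper over the same functions ships in
`inst/cli/stirq`:

```sh
stirq simulate --n-fshd 25 --n-hc 6 --seed 1234 -o run/
stirq limits -o run/
stirq run --wf 3 -o run/
```

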