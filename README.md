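# seqstain

Sequential (multiplex) chromogenic IHC analysis in R: co-registration of
staining rounds, stain deconvolution, positive-cell quantification,
cross-round co-expression phenotyping, and the paired-cohort statistics
layer used to evaluate treatment-induced changes in the tumor immune
microenvironment.

`seqstain` is written for translational immuno-oncology groups who profile
tumor-infiltrating lymphocytes (CD4, CD8, Foxp3, GZMB) and checkpoint
ligands (PDL1) on bright-field whole-slide images across repeated
stain–scan–destain rounds of the *same* section, and who then need paired
pre/post-treatment statistics over a small patient cohort.

## What it computes

* **Registration.** Rounds are aligned from user-clicked reference marks by
  the closed-form least-squares similarity fit (Procrustes/Umeyama):
  minimize &Sigma;<sub>i</sub> ‖sR(&theta;)m<sub>i</sub> + t −
  f<sub>i</sub>‖² over scale s, rotation &theta;, translation t (affine
  optional), followed by an iterative landmark-free fine alignment that
  descends the mean squared hematoxylin-OD difference. Aligned rounds are
  re-assembled into a z-stack.
* **Stain separation.** Bright-field RGB is converted to optical density,
  OD = −log₁₀(max(I, 1)/255), and unmixed with a 3×3 stain matrix
  (hematoxylin + AEC/DAB chromogen + residual, Ruifrok–Johnston vectors by
  default), giving per-pixel stain concentrations.
* **Cell quantification.** Nuclei are segmented from the hematoxylin OD (or
  OD-sum) channel, split at distance-transform maxima, filtered by area,
  and expanded into cell/cytoplasm compartments; positivity is an OD
  threshold on a compartment statistic. Summaries are positive cells per
  mm² of the annotated tumor region (minus stroma/necrosis/artifacts) and
  percent positive of all cells.
* **Co-expression.** Detections from different rounds are mapped into one
  frame and paired by mutual-nearest-neighbor matching (default radius
  6 µm) to count phenotypes such as GZMB⁺CD8⁺, plus slide-level ratios
  (GZMB:CD8 = positive GZMB cells ÷ positive CD8 cells).
* **Cohort statistics.** Exact two-sided Wilcoxon signed-rank test (zeros
  dropped, mid-ranks, full sign-assignment enumeration for n ≤ 25),
  Spearman rank correlation, mean ± SEM descriptives, post/pre ratios,
  RECIST-style lesion-response classes, and stratification of patients into
  naive/CT/RT vs immuno-treated groups from their prior-treatment strings.
* **Synthetic data.** A deterministic generator renders multi-round tiles
  of disk nuclei with configurable marker co-expression through the same
  Beer–Lambert model the deconvolution inverts, plus ground truth
  (centroids, labels, transforms, landmarks), and Table-style cohorts with
  known paired effects — so the whole pipeline is testable offline.

## Worked example

The package ships a 16-patient metastatic-melanoma cohort table
(dendritic-cell vaccination; comma decimal separators, `"na"` missing
codes). The one-call report:

```r
library(seqstain)
reproduce_table1_stats()
#> Cohort statistics report
#>   all: n = 14, PDL1% 3.721 +/- 1.316 (pre) vs 10.37 +/- 2.456 (post), p = 0.0353
#>   naive_ct_rt: n = 9, PDL1% 3.056 +/- 1.268 (pre) vs 13.74 +/- 3.242 (post), p = 0.0078
#>   immuno_treated: n = 5, PDL1% 4.920 +/- 3.068 (pre) vs 4.295 +/- 1.653 (post), p = 0.6250
#>   10 of 14 assessable pairs with a PDL1 increase
#>   CD8 post/pre ratio: 0.5147 +/- 0.2318 (post-treatment, n = 3); 0.8578 +/- 0.2528 (on-treatment immuno, n = 4)
#>   months surgery-to-vaccine mean 6.250; post-treatment vaccine-to-biopsy mean 9.333 (median 7.000)
```

Reading: PDL1 percent positivity rises significantly after vaccination over
the 14 assessable pairs (exact signed-rank p = 0.0353), driven entirely by
the 9 patients who were treatment-naive or had only chemo/radiotherapy
before vaccination (p = 0.0078 = 4/512); previously immuno-treated patients
show no shift (p = 0.6250). The CD8 post/pre density ratios of biopsies
taken *after* the last vaccine dose are compatible with those taken on
treatment.

The imaging side on synthetic data with known truth:

```r
sim <- generate_multiround_slide(slide_sim_params(seed = 7))
sm  <- stain_matrix("AEC")
an  <- full_tile_annotation(dim(sim$rounds$cd8$pixels)[1:2], 0.5)
t_b <- estimate_transform(sim$landmarks$gzmb, sim$landmarks$cd8)
ca  <- classify_positive(detect_cells(sim$rounds$cd8,  sm, detection_params(), an),
                         "CD8",  "cell", "mean", 0.12)
cb  <- classify_positive(detect_cells(sim$rounds$gzmb, sm, detection_params(), an),
                         "GZMB", "cell", "mean", 0.12)
m   <- match_cells(ca, transfer_coordinates(cb, t_b), radius = 6)
phenotype_counts(m, ca, cb,
                 rules = list(ctl = c(CD8 = "positive", GZMB = "positive")))
```

A command-line wrapper with subcommands `align`, `deconv`, `quantify`,
`cohort`, `simulate`, `reproduce-table1` is installed at
`system.file("scripts", "seqstain", package = "seqstain")` (exit codes: 0
success, 2 input error, 3 internal error).

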