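# pftquant

Quantification engine for secretin-enhanced MR pancreatic function tests
(MR-PFT).

MR-PFT assesses exocrine pancreatic function non-invasively: coronal
T2-weighted stacks are acquired before and ~15 minutes after secretin
administration, and the volume of bright bowel fluid secreted in the
interval — the secretory response ΔV = V_post − V_pre, in mL — is the
clinical metric. Manual thresholding and segmentation of these stacks is
slow and rater-dependent. `pftquant` implements the automated part of a
semi-automated workflow, scriptable refinement tools, and the agreement
statistics used to validate rater reproducibility, plus a synthetic
abdominal phantom generator with exact ground truth so the whole pipeline
is testable without patient data.

The automated chain, for a geometry-matched exam pair:

1. normalize both volumes against one pooled clip value (the 99.999th
   percentile of the pooled pre+post intensities, clamped to [0, 1]);
2. threshold both at the single pooled level that maximizes the Kapur
   (maximum-entropy) criterion — the sum of Shannon entropies of the
   below- and above-threshold classes — over a 256-bin histogram;
3. delete 26-connected clusters smaller than 1 mL;
4. resample the labelled mask to isotropic voxels, compute per-cluster
   morphometry (volume, centroid, bounding box, sphericity by
   exposed-face counting, principal-axis angle, craniocaudal span), and
   delete clusters matching an editable rule table of non-bowel fluid
   objects (spinal canal, intervertebral discs, renal pelvis/ureter,
   bladder, gallbladder, unsaturated fat rim), with removal applied in
   native geometry through the label correspondence;
5. convert masks to volumes (voxel count × row × col spacing × slice
   thickness / 1000) and per-slice fluid-volume curves, and report
   ΔV = V_post − V_pre.

Scripted equivalents of the four interactive refinement tools are
included (seeded Chan-Vese add/remove with a provably non-increasing
energy, regional maximum-entropy add, regional remove), as are the
validation statistics: ICC(2,1) with McGraw–Wong F-based confidence
intervals, Bland–Altman limits of agreement (mean ± 1.96 sd), Dice
coefficients, and paired t-tests on logit-transformed Dice. See the
methods vignette (`vignettes/pftquant-methods.Rmd`) for the model,
conventions and design decisions.

## Worked example

```r
library(pftquant)

# a noise-free phantom: 3 bowel tubes, all six confounders, ΔV = 55 mL
ph <- generate_phantom(phantom_config(seed = 1, noise_sd = 0))
ph$truth$true_pre_ml   # 36.2 mL of bowel fluid before secretin
ph$truth$true_post_ml  # 91.2 mL after

bundle <- run_exam(exam = ph$exam)
sprintf("pre %.1f mL  post %.1f mL  delta %.1f mL",
        bundle$pre_volume_ml, bundle$post_volume_ml,
        bundle$delta_volume_ml)
#> "pre 36.2 mL  post 91.2 mL  delta 55.0 mL"
bundle$analysis_meta$removed_classes_pre
#> "fat_rim,renal_pelvis_ureter,gallbladder,bladder,spinal_canal"
round(bundle$slice_curve_post[12:18], 2)   # per-slice mL, post series
#> 5.78 11.18 16.02 18.02 17.12 12.06  6.39
```

The chain removed all five ≥ 1 mL confounders by morphometry (the discs
fall to the 1 mL size filter) and recovered the true volumes exactly: on
a noise-free phantom the pooled threshold (here 0.281, between the tissue
and fluid intensity classes) reproduces the rendered fluid voxels, so the
measured ΔV is the constructed 55 mL. The per-slice curve is the fluid
volume per coronal slice — the quantity plotted as a fluid-volume curve
in the interactive workflow.

Agreement statistics on a simulated 20-exam, two-rater table (between-exam
sd 9 mL, rater error sd 3 mL, population ICC 0.9):

```r
tbl <- simulate_rating_table(20, 9, 3, mu = 55, seed = 1)
r <- build_report(tbl)
sprintf("ICC %.3f (%.3f-%.3f, %s); mean diff %.2f mL; LOA (%.1f, %.1f)",
        r$icc$estimate, r$icc$ci["lo"], r$icc$ci["hi"], r$icc$label,
        r$ba$mean_diff, r$ba$loa["lo"], r$ba$loa["hi"])
#> "ICC 0.895 (0.755-0.957, good); mean diff -0.44 mL; LOA (-8.4, 7.5)"
```

## Command line

A thin dispatcher over the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/pftquant.R phantom --out /tmp/ph --seed 1
Rscript inst/cli/pftquant.R run --pre /tmp/ph/pre --post /tmp/ph/post \
        --out /tmp/result
Rscript inst/cli/pftquant.R agree --ratings ratings.csv --out report.json
```

`run` reads single-frame DICOM series (Explicit VR Little Endian), writes
the masks as NIfTI and the volumes/curves/metadata as a JSON report;
`agree` consumes a CSV with columns `exam_id, rater_id, delta_ml`. Exit
codes: 0 success, 2 input/config error, 3 processing error.

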