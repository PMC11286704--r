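---
title: "Quantifying secretin-stimulated bowel fluid: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying secretin-stimulated bowel fluid: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pftquant)
```

## The measurement problem

MR pancreatic function testing (MR-PFT) assesses exocrine pancreatic
function non-invasively: coronal T2-weighted stacks are acquired before and
about 15 minutes after administration of secretin, and the volume of bright
bowel fluid secreted in the interval — the secretory response
$\Delta V = V_{\mathrm{post}} - V_{\mathrm{pre}}$, in mL — is the clinical
metric. Manual segmentation of the fluid is slow and rater-dependent, which
has limited quantitative use of the test. This package implements an
automated quantification chain for geometry-matched exam pairs, scriptable
equivalents of the interactive refinement tools such software provides, and
the agreement statistics used to validate rater reproducibility, together
with a synthetic phantom generator so that every step is testable without
patient data.

## The automated chain

Given a pre/post pair with identical array shape, pixel spacing and slice
thickness:

1. **Normalization.** Both volumes are divided by a single clip value, the
   99.999th percentile (linear interpolation) of the *pooled* pre+post
   intensities, then clamped to $[0,1]$; the brightest 0.001% of voxels
   saturate at 1. Pooling guarantees the two series share one intensity
   scale, which is what makes a single threshold meaningful for both.
   Whether clipping should instead be per-series is genuinely open; the
   pooled form was chosen because the threshold is pooled.
2. **Maximum-entropy threshold.** A 256-bin histogram over $[0,1]$ pools
   all voxels of both series. The threshold is the bin edge maximizing the
   Kapur criterion — the sum of the Shannon entropies (natural log) of the
   below- and above-threshold classes, each renormalized within its class;
   empty bins contribute zero, cuts leaving a class empty are not
   candidates, and ties resolve to the lowest threshold. "Inter-class
   entropy" is read as this maximum-entropy criterion rather than Otsu's
   inter-class *variance*, because the criterion named is entropy. Voxels
   strictly above the threshold form the candidate-fluid masks.
3. **Small-cluster removal.** 26-connected 3D clusters with volume strictly
   below 1 mL (native voxel geometry) are deleted. 26-connectivity is used
   throughout because fluid structures are thin and oblique; stricter
   connectivity fragments tubes.
4. **Heuristic non-bowel removal.** The labelled mask is resampled to
   isotropic voxels (edge = smaller in-plane spacing, nearest-neighbour —
   appropriate for binary data), per-cluster morphometry is computed there,
   and each cluster is tested against an ordered rule table of interval
   predicates; the first matching rule wins. Matched clusters are deleted
   from the *native* mask through the label correspondence, so measured
   volumes always come from acquisition geometry. The six target classes
   are spinal canal, intervertebral discs, renal pelvis/proximal ureter,
   bladder, gallbladder, and incompletely saturated fat rim.
5. **Volumetry.** Volume is voxel count × row spacing × col spacing ×
   slice thickness / 1000 (mL), at full floating-point precision (rounding
   is display-only); per-slice curves sum exactly to the totals, and
   $\Delta V$ is the exact difference of the measured totals.

### Morphometric features and the rule table

Features per cluster: volume (mL); centroid as fractions of the array
extent (axes: slice, row, col); axis-aligned bounding-box extents (mm);
sphericity; principal-axis angle from the craniocaudal axis (degrees,
0–90, from the leading eigenvector of the voxel-coordinate covariance);
and craniocaudal span fraction. Coronal orientation is assumed, so the
craniocaudal axis is the in-plane row axis; a `cc_axis` argument selects
another axis for other orientations.

Sphericity is $\pi^{1/3} (6V)^{2/3} / A$ with the surface area $A$ counted
as exposed voxel faces. Face counting is exact, deterministic and
unit-testable (a single voxel has $A = 6$ and sphericity
$\pi^{1/3} 6^{2/3} / 6 \approx 0.806$), but it overestimates smooth
surfaces by a factor approaching $3/2$ (the Cauchy projection bound), so a
digitized ball scores about $2/3$, not 1 — and the cube, not the ball, is
the face-count maximizer. The shipped rule thresholds are calibrated to
this scale: compact organs (bladder, gallbladder) sit near 0.6–0.7,
tubular structures near 0.4–0.5, thin shells and rods below 0.35. A
mesh-based area estimate would restore the conventional scale at the cost
of determinism and testability; face counting was kept and documented.

The feature set and the six object classes are fixed, but their numeric
ranges are not published anywhere we can draw on; the defaults in
`inst/extdata/rules.json` are an implementation choice calibrated on this
package's phantoms (each phantom confounder is a caricature keyed to its
rule). Equivalence with any other implementation's ranges cannot be
claimed — only functional equivalence on phantoms. The table is an
editable JSON file validated at load time, and `remove_nonbowel()` logs
every removal with class, volume and centroid.

## Refinement operators

The four interactive tools are reproduced as deterministic 2D operators on
one slice of one series, composable into a batch edit script:

- **Seeded add/remove** run a two-phase piecewise-constant (Chan-Vese)
  active contour from a 3-pixel disk at the seed and OR/subtract the
  converged foreground component containing the seed. The energy is
  $\mu \cdot \mathrm{perimeter} + \lambda_1 \sum_{\mathrm{in}} (u - c_1)^2
  + \lambda_2 \sum_{\mathrm{out}} (u - c_2)^2$ with the perimeter counted
  as 4-neighbour label-discordant edges. Minimization alternates exact
  mean updates with Gauss–Seidel pixel-flip sweeps that only accept
  energy-decreasing flips, so the per-iteration energy trace is provably
  non-increasing (asserted in tests). Defaults
  ($\mu = 0.25$, $\lambda_1 = \lambda_2 = 1$, 200 iterations, tolerance
  $10^{-3}$, init radius 3) are exposed via `chan_vese_params()`; none of
  them are published values, all are implementation decisions. Two guards
  make scripted use fail safely: a uniform slice rejects the edit ("no
  boundary found"), and a component exceeding 50% of the slice — a leaked
  contour — rejects it with a warning.
- **Regional add** rasterizes a freeform polygon (even-odd rule at pixel
  centres, half-open edges, self-intersection rejected) and applies the
  same Kapur criterion to the in-polygon histogram only; **regional
  remove** clears in-polygon voxels unconditionally.

## The phantom generator

`generate_phantom()` renders a torso-like ellipsoid (tissue intensity
0.25) containing bright fluid structures (intensity 0.9) on a $32 \times
96 \times 96$ grid with 1.5 mm in-plane spacing and 4 mm slices — the
slice thickness of the target acquisitions, with a coarsened in-plane
matrix to keep phantoms small; problem sizes throughout (20 phantoms for
volume recovery, 100 ICC replicates, 1000 null t-test replicates) were
chosen as the package's own test conditions. Bowel fluid is two to four
smooth curved tubes (7 mm radius) in the mid-abdomen; the post-secretin
stack equals the pre stack except the tubes are dilated shell by shell
(with a deterministic partial final shell) until exactly the requested
$\Delta V$ has been added, mimicking matched acquisitions with preserved
voxelwise registration. Confounders are analytic caricatures matched to
the rule table's feature ranges; a placement audit enforces pairwise
disjointness with a one-voxel moat and raises "placement failure"
otherwise. Truth volumes are exact voxel counts times the voxel volume,
and the generator is bit-reproducible per seed.

Noise is additive Gaussian (default sd 0.03, i.e. fluid SNR 30), clamped
to $[0,1]$ — not Rician, since magnitude-MRI realism is not needed to
exercise the algorithms. Rater imperfection is simulated by toggling a
random fraction of a truth mask's one-voxel boundary band, with the
toggle probability bisected until the two simulated raters' mutual Dice
hits the target; rating tables draw exam truths
$N(\mu, \sigma_b^2)$ plus rater errors $N(0, \sigma_r^2)$, giving
population ICC(2,1) $= \sigma_b^2 / (\sigma_b^2 + \sigma_r^2)$.

### What passing phantom tests does and does not show

The phantom has piecewise-constant intensities, no bias field, no motion
or respiratory artifacts, no partial-volume blur, and caricatured organ
geometry. Noise-free phantoms make end-to-end volume recovery essentially
exact because the threshold separates the three intensity classes
perfectly — that validates the plumbing (thresholding, labelling,
filtering, label correspondence, volumetry), not clinical segmentation
accuracy. At the default noise level the fully automated chain is *not*
reliable end to end: the Kapur cut admits a speckle of tissue-tail voxels
(~10%), and isolated speckle voxels can bridge distinct organs under
26-connectivity, merging clusters and defeating per-object classification.
This mirrors the intended use of such software — the automated pass is an
initialization that raters refine — and is why the package's accuracy
claims are confined to noise-free phantoms. No denoising or morphological
opening was added, because preprocessing beyond the described chain is
out of scope.

## Agreement statistics

- **ICC(2,1)** — two-way random effects, absolute agreement, single
  rater: $\mathrm{ICC} = (MS_R - MS_E) / (MS_R + (k-1) MS_E +
  \frac{k}{n}(MS_C - MS_E))$ from the two-way ANOVA decomposition
  (rows = exams, columns = raters). The 95% CI uses the McGraw–Wong
  F-based construction (the CI method is not dictated by the convention
  itself; this is the standard choice). Interpretation bands: $<0.5$
  poor, 0.5–0.75 moderate, 0.75–0.9 good, $>0.9$ excellent. A useful
  check implemented in the tests: with $k = 2$ and equal column moments,
  the *consistency* form $(MS_R - MS_E)/(MS_R + MS_E)$ equals Pearson's
  $r$ exactly, and ICC(2,1) converges to it as $n$ grows.
- **Bland–Altman**: mean difference with 95% limits of agreement
  $\bar d \pm 1.96\, s_d$ (sample sd; 1.96, not a t-quantile, matching
  the "95% limits of agreement" convention).
- **Dice**: $2|A \cap B| / (|A| + |B|)$; two empty masks score 1
  (agreement on absence, with a logged note) rather than being undefined,
  so pipelines over many exams are not poisoned by an empty pair.
- **Paired t on logit(DSC)**: $\mathrm{logit}(v) = \ln[v/(1-v)]$ maps
  $(0,1)$ to the real line before the standard paired t-test
  (df $= n-1$, two-sided). Values at exactly 0 or 1 are an error unless
  the caller opts into an explicit $\varepsilon$-clamp
  ($\varepsilon = 10^{-6}$, logged) — never silent.

## Numerical conventions and degenerate inputs

Arrays are (slice, row, col); thresholds are strict ($>$); histogram bins
are right-open except the last; percentiles use linear interpolation;
mm³→mL is an exact /1000. Degenerate inputs fail loudly with specific
errors: all-zero exams ("degenerate intensities"), single-bin histograms,
zero rating variance, zero-variance paired differences (detected with a
relative tolerance so float-exact constant shifts are caught), logit at
the boundary, mixed DICOM series, geometry-mismatched pairs, bundles whose
accounting identities fail (validated before any file is written).

## Known limitations

- The DICOM layer reads and writes single-frame, uncompressed, Explicit
  VR Little Endian Part-10 files only — sufficient for the fixture writer
  and typical exports, cross-checked against pydicom in the tests; it is
  not a general DICOM implementation (no implicit VR, no compressed
  transfer syntaxes, no multi-frame enhanced objects).
- Heuristic rule ranges are phantom-calibrated defaults, not clinically
  validated values; on real data they are a starting point for site
  tuning via the JSON rule file.
- The automated chain performs no inter-series registration (acquisitions
  are assumed protocol-matched), no bias-field correction and no
  denoising; see the noise discussion above.
- Refinement operators are per-slice 2D by design, mirroring the
  interactive tools they reproduce; there is no 3D contour evolution.
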