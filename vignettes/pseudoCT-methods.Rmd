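---
title: "Pseudo-CT synthesis from dual-contrast MRI: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-CT synthesis from dual-contrast MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

MRI-only radiotherapy planning needs CT numbers (Hounsfield units, HU) that
MRI does not measure. This package implements a voxel-based synthesis method:
given two co-registered MRI volumes of the same patient acquired with
different sequences (a T1-weighted-like channel MR1 and a T2-weighted-like
channel MR2) plus a training cohort with reference CT on the same voxel grid,
it learns, per anatomical region, a map from the joint intensity pair
$(S_1, S_2)$ to the expected CT number, and applies it voxel-wise to produce a
pseudo-CT (pCT) volume.

The central assumption is statistical, not physical: voxels of the same
tissue class with similar intensities in *both* channels have similar CT
numbers *on average*. A single MRI channel is ambiguous — very different
tissues can share one intensity — and the second channel exists precisely to
break those ties. Residual within-pair CT spread is irreducible for any
intensity-only method, and the evaluation framework below quantifies exactly
that.

## The model

**Regions.** The body is partitioned into three regions — bony, soft, and a
mixed transition shell — because the intensity-to-HU relation differs sharply
between bone and soft tissue while their intensity ranges can overlap. The
bony region is the bone mask eroded by a ~1 mm margin; the soft region
excludes a 2.5 mm margin around bone (the midpoint of the conventional
2–3 mm); what remains of the body is the mixed region. Margins are ellipsoidal
structuring elements with per-axis voxel radii derived from the voxel spacing
(round half up, minimum 0 — with 5 mm slices a 2.5 mm margin spans one slice
axially but three in-plane voxels at 0.81 mm). An independent *excluded*
overlay marks voxels with MRI–CT anatomical mismatch (bladder/bowel); they are
dropped from training and evaluation but still receive predictions.

**Normalization.** Per sequence, each patient's intensities are multiplied by
`cohort_mean / patient_mean`, where both means are taken over body voxels and
the cohort mean is the unweighted mean of per-patient means (so large bodies
do not dominate — the pooled-voxel alternative is an equally defensible
reading and is deliberately not used).

**Binning.** Per region, training voxels are accumulated on an
`Nbin × Nbin` grid over the $(S_1, S_2)$ plane (default `Nbin = 200`; axis
ranges default to the observed cohort maxima). Each filled bin stores its
voxel count $N_{ij}$ and mean CT $\overline{CT}_{ij}$. Empty bins are imputed
with the mean CT of the nearest filled bin in index distance
$d=\sqrt{(i-i_e)^2+(j-j_e)^2}$ — averaging over exact ties — and are given
10 % of the donor's regression weight (mean donor weight for a tie; the tied
*weight* rule is our declared choice, the tied *value* rule is standard).
Squared index distances are integers, so tie detection is exact.

**Regression.** A total-degree-$n$ bivariate polynomial
$pCT(S_1,S_2)=\sum_{i_1+i_2\le n} c_{i_1 i_2} S_1^{i_1} S_2^{i_2}$ (default
$n = 30$) is fitted to the bin means at the bin centers by weighted least
squares with the bin weights. Two numerical choices matter:

* inputs are rescaled to $[0,1]$ per axis before monomials are built — raw
  intensities in the tens of thousands raised to the 30th power overflow;
* the system is solved by SVD with a relative singular-value cutoff of
  `1e-10`; degree-30 monomial bases are severely ill-conditioned, and the
  truncation makes the fit deterministic and reproducible. Consequently the
  *coefficients* are basis/cutoff-dependent; only fitted surface values are
  meaningful, and that is what all tests assert.

A bilinear-lookup alternative (`model_type = "interpolation"`) interpolates
the imputed bin-mean lattice over the four surrounding bin centers, with
constant extrapolation outside the lattice hull (unspecified in the
literature; a clamp is the conservative choice).

**Prediction.** Each body voxel goes through its region's model; outputs are
clamped to $[-1000, 2000]$ HU and voxels outside the body are set to exactly
−1000 HU. Queries beyond the trained intensity range clamp to it — the
polynomial is untrained out there and high-degree extrapolation diverges
violently.

## Error decomposition

Besides the mean absolute error $MAE = \frac1N\sum_k |pCT_k - rCT_k|$ and its
rms counterpart $\sigma_{pCT}$, the package separates two sources:

* **fit error** — count-weighted MAE/rms deviation between the fitted surface
  and the bin means at bin centers ($MAE_{fit}, \sigma_{fit}$);
* **intra-bin spread** — deviation of each voxel's reference CT from its own
  bin mean ($MAE_{rCT}, \sigma_{rCT}$), the irreducible part.

If the two sources were independent one expects
$\sigma_{pCT}^2 = \sigma_{rCT}^2 + \sigma_{fit}^2$. When every voxel is
assigned its bin-center prediction ("per-bin" mode) this is an exact algebraic
identity — the cross term $\sum (rCT-\overline{CT})(\overline{CT}-pred)$
vanishes within each bin by the bin-mean property — and the test suite checks
it to 1e−12. In per-voxel mode the prediction varies within a bin and the
identity holds only approximately (observed discrepancy < 0.5 % on smooth
phantoms; asserted < 5 %).

Region accounting: weighted MAE = raw MAE × voxel fraction, so region rows
sum exactly to the overall MAE whenever the regions partition the evaluated
mask.

**Dose comparison.** Two dose grids are compared point-to-point (DTA = 0): a
voxel passes when $|D_p - D_r|$ is within 2 % (inclusive) of a reference
dose. Whether the 2 % is prescription- or local-dose-normalized is
ambiguous in the field; both are implemented, and the global-reference
(prescription, 56 Gy by default) normalization is the default.

## The synthetic stated world

No patient data are deposited, so the generator *is* the test bed. One
phantom patient consists of:

* **geometry** — nested ellipsoids in normalized voxel coordinates: a body
  ellipsoid (semi-axes 0.82/0.78/0.85 of the half-dimensions) containing a
  bone shell between body-normalized radii 0.45 and 0.62 (≈15 % of the body,
  in the range of pelvic bone fractions). Labels come from the package's own
  margin rules applied to these masks.
* **intensities** — per region, $S = \mu_r + \sigma_r G$ with $G$ a smooth
  Gaussian random field (white noise filtered at ~2.5 voxels in-plane),
  floored at 0. The fields are standardized to exact zero mean/unit sd within
  each region *before* the floor, so patients differ only by their random
  texture and by explicit per-sequence log-normal gain factors
  (sd 0.15) — which is precisely the variation cohort normalization is meant
  to remove. The floor leaves a sub-0.1 % residual between patients, small
  enough not to disturb the exact-recovery oracle. Region parameters (bony
  MR1 250±90 / MR2 350±110; soft 800±160 / 2000±420; mixed 550±180 /
  1300±380) put bone low in both channels, soft tissue high, and the mixed
  shell in between, overlapping the soft cloud.
* **CT** — a known per-region polynomial map of total degree ≤ 2 on
  $u=S_1/1000$, $v=S_2/2500$, plus Gaussian noise (default sd 50 HU,
  consistent with observed soft-tissue intra-bin spreads of ~40 HU), clipped
  to $[-1000, 2000]$. Coefficients were chosen once so that *both* channels
  contribute ≈25–60 HU of CT variation in every region (dual-channel ablation
  must point the right way for a real reason, not sampling noise) and so that
  the mixed region maps overlapping intensities to very different HU than the
  soft region (making segmentation genuinely informative). An optional
  sigmoidal bone map exercises non-polynomial approximation error.
* **excluded overlay** — a contiguous blob (thresholded coarse random field)
  covering 5 % of the body, with CT overwritten by −400 HU (a bowel-gas-like
  mismatch outlier).

All randomness flows from one seed through a fixed per-patient substream;
generation is bit-reproducible.

**What a green test does and does not establish.** The phantoms have the
statistical structure the method assumes: region-dependent smooth intensity
fields, a deterministic intensity→HU relation plus noise, patient-level gain
variation. They do not have real MR physics (no relaxometry, no bias fields,
no sequence-dependent artifacts), no registration error, and far simpler
anatomy than a pelvis. Green tests establish correctness of the pipeline and
its statistical behavior in its own model world — not clinical accuracy. The
published clinical headline numbers (overall LOOCV MAE ≈ 40 HU on six
patients, ≈ 95 % dose passing rate) are therefore *not* reproduction targets;
it is however reassuring that the noise-floor LOOCV of the default phantom
world lands in the same range by construction (50 HU noise ⇒ MAE →
$50\sqrt{2/\pi} \approx 39.9$ HU).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `nbin` | 200 | bins/axis | past ~40 the MAE is flat; 200 future-proofs denser cohorts cheaply |
| `degree` | 30 | — | MAE plateaus near degree 20; 30 is the published operating point |
| `empty_weight_fraction` | 0.1 | — | imputed bins stabilize the fit without dominating it |
| `bone_inner_margin_mm` | 1 | mm | keeps partial-volume cortical edge out of the bony training set |
| `soft_exclusion_margin_mm` | 2.5 | mm | midpoint of the 2–3 mm convention |
| `ct_noise_sd` | 50 | HU | matches observed soft-tissue intra-bin spread |
| `dose_reference` | 56 | Gy | typical cervix prescription |

Tests and examples use `nbin` 10–50 and degree 2–4: at phantom sample sizes
larger grids leave most bins empty and the imputation bias, not the model,
dominates. This is a scale choice, not a different method.

## Degenerate inputs and tie-breaks

* Intensities are clamped to ≥ 0 before binning; values above `axis_max`
  fall into the last bin (closed top).
* Imputation ties average both value and weight over the tied set.
* A region present in the labels but with zero usable training voxels is an
  error naming the region; a label map containing a region the model set
  lacks fails at prediction time.
* An entirely empty bin grid is an error (nothing to impute from).
* Single-sequence configurations zero the unused channel, collapsing it to
  one bin; the polynomial degenerates to one variable exactly.

## Known limitations

* Registration is out of scope: inputs must share one voxel grid.
* Exact polynomial coefficients are not comparable across implementations
  (basis scaling and cutoff differ); compare fitted values instead.
* The brute-force nearest-filled-bin imputation is $O(E \cdot F)$; fine up to
  `Nbin = 200`, no k-d tree is provided.
* LOOCV summaries report mean ± *sample* standard deviation across cycles;
  the dispersion convention in published tables is unstated, and
  cycle-to-cycle spread is the consistent reading.
* The NIfTI reader/writer is deliberately minimal (3D scalar images,
  spacing, slope/intercept); it is not a general neuroimaging I/O layer.
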