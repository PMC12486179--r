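---
title: "Methods: quantitative analysis of femoral-head cystic lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative analysis of femoral-head cystic lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cysthead` implements a desk-reproducible version of a specimen micro-CT
analysis of subchondral bone cysts in the femoral head: extraction of the
cystic voids, their anatomical localisation in a six-region / three-pillar
partition of the head, trabecular morphometry of the peri-cyst shell, 2D
histomorphometry, and the two-group comparison statistics used to contrast
osteoarthritic (OA) and osteonecrotic (ONFH) heads. This vignette explains
the models and procedures, the parameters that matter, what the synthetic
phantom does and does not emulate, and the numerical choices behind the
voxel primitives.

## The cyst-extraction model

A cyst is defined morphologically, not by intensity alone: an interior
void of the head whose largest inscribed sphere exceeds 1 mm in diameter.
The chain is:

1. **Binarization.** Bone is thresholded in the fixed 8-bit window
   `[90, 255]` (inclusive at both ends). The window is a convention for
   8-bit micro-CT exports in which marrow/soft tissue sits well below 90
   and mineralized tissue well above it; it is configurable per run.
2. **Total region.** The head envelope is the morphological closing of
   the bone mask with a 1.5 mm ball followed by 3D cavity filling. 1.5 mm
   bridges trabecular pores (which are a few hundred micrometres) without
   bridging the joint space; every bone voxel is contained by
   construction.
3. **Empty regions.** The set difference `total \ bone` — all non-bone
   space inside the head: marrow, pores and cysts.
4. **Size filter.** An erosion by a Euclidean ball of radius
   `min_diameter/2` (the composition of `k` erosions of `step` mm, which
   is algebraically a single ball erosion) removes every void whose
   inscribed sphere is below the threshold; the survivors are then
   restored. Two restoration semantics are provided:
   * `restore = "reconstruction"` — geodesic dilation to stability:
     every surviving connected component returns *exactly* to its
     original voxel set. This is the mathematically clean
     opening-by-reconstruction, and it is the semantics the test suite's
     brute-force inscribed-sphere oracle checks exactly. Its caveat: a
     void is kept or dropped *as a whole*, so if the cystic void is
     connected to the marrow network anywhere, the entire network floods
     back.
   * `restore = "opening"` — the eroded seeds are dilated back in `k`
     clipped increments of `step` mm (an increment-limited geodesic
     dilation; for `k = 1` a ball opening), plus a final clipped
     1.5-voxel step that compensates the one-voxel-layer loss of the
     strict-erosion/inclusive-dilation pair on digitized spheres. This
     restores compact voids to their exact original shape while leaving
     sub-threshold marrow untouched, and is the pipeline default: in
     trabecular bone the marrow space is always connected to a cyst
     somewhere, so full reconstruction is the wrong tool there.
5. **Labelling.** Connected components (26-connectivity foreground,
   6-connectivity background — the standard complementary pair) become
   cyst records with volume (voxel count x voxel volume), largest
   inscribed-sphere diameter, and centroid. Components touching the
   exterior shell of the total region are flagged `touches_exterior` and
   excluded by default: they are cartilage-defect/collapse-type surface
   voids, which the original analysis excluded by expert judgement; the
   automatic rule stands in for that judgement and can be overridden.

The boundary of the ">1 mm" rule is implemented through the erosion
radius: a component survives iff its largest inscribed sphere has
diameter at least `min_diameter` as measured between voxel centres with a
relative tolerance of 1e-7 (so a digitized sphere of exactly the
threshold diameter survives; a 0.8 mm decoy never does).

## Six-region / three-pillar geometry

The reference plane passes through the head centre, the fovea centre and
the neck (calcar) centre; it separates anterior from posterior. The
anterior orientation of its normal is fixed by a documented rule: with
medial axis $\hat m$ (head centre to fovea) and superior axis $\hat s$
(neck centre to head centre), anterior is $\hat s \times \hat m$ for a
right hip and $\hat m \times \hat s$ for a left hip.

The width axis $w$ is the unit vector perpendicular to the main
trabeculae direction (MTD) lying in the reference plane, oriented towards
the fovea (the fovea is anatomically medial, which removes any hidden
handedness parameter). Head width is the extent of the head-mask voxel
centres projected on $w$; the two cut planes sit at the cumulative 30%
and 70% quantiles of that extent. Placement by width quantiles (rather
than symmetrically about the head centre) was chosen because the pillar
fractions are defined as fractions *of the head width*, and it handles
non-spherical heads. Voxels are classified by the signed distance of
their centres to true planes in world coordinates; regions I-III are the
anterior lateral/central/medial pillars, IV-VI their posterior
counterparts. Every head voxel gets exactly one label, so region volumes
sum to the head volume by construction.

A lesion spreading over several regions is assigned to the region holding
the largest fraction of its voxels (argmax); exact ties go to the lower
region index and are flagged, and the full overlap vector is retained in
the record.

When the landmark file carries no MTD, `estimate_mtd()` supplies a
stand-in: the principal axis of the mean-intercept-length tensor of the
bone mask, with sign chosen superior. This estimator is *not* part of the
original analysis (which placed the MTD manually) and is labelled as a
stand-in; nearly isotropic structure (principal MIL ratio < 1.05) falls
back to the superoinferior axis with a warning.

## Peri-cyst morphometry (Cys-Tb)

The Cys-Tb ROI is the shell extending 0.5 mm outward from the cyst
surface (`dilate(cyst, 0.5 mm) \ cyst`, clipped to the head). On any
bone/ROI pair the panel is:

* **BV/TV** (%): voxel-count fraction, exact.
* **BS, BS/BV** (mm^2, 1/mm): surface area by the coarea formula — the
  binary indicator is smoothed with a 0.6-voxel Gaussian (narrow enough
  that the antiparallel faces of structures four or more voxels thick do
  not cancel each other's gradients) and the integral of the gradient
  magnitude taken, restricted to the ROI. This estimator
  is orientation-unbiased (exact for planes at any orientation, within
  ~2% on digitized spheres), which a triangulated marching-cubes surface
  would also achieve but no installed primitive provides; the coarea
  route is self-contained and differentiable in resolution. At the array
  edge the field is mirror-continued, so structure cut by the volume
  boundary contributes no spurious cut-face area.
* **Tb.Th, Tb.Sp** (um): sphere-fitting local thickness (distance-ridge):
  every phase voxel carries the diameter of the largest inscribed sphere
  containing it, and the ROI mean is reported. Distances are between
  voxel centres with the exterior as background and a half-voxel surface
  offset; the convention is exact for odd-parity digitized widths and
  under-reads even-parity widths by one voxel — inside the stated
  one-voxel tolerance. Tb.Sp is the same measure on the void-within-head
  phase.
* **Tb.N** (1/mm): `1 / (Tb.Th + Tb.Sp)` — one strut-gap period per
  millimetre. The source analysis names the parameter without a formula;
  this plate-model-free hybrid is the declared convention.
* **SMI**: `6 V S' / S^2` with `S` and `S'` taken from a quadratic fit to
  the parallel-surface volume expansion `V(t)` — the anti-aliased volume
  enclosed by the surface offset a signed distance `t` (sublevel sets of
  the signed Euclidean distance field with half-voxel surface
  positioning), sampled at whole-voxel offsets over +-3 voxels (clipped
  to the deepest interior distance, so thin structures are fitted only
  over the range where the eroded phase still exists). A
  one-sided finite difference of re-digitized dilations, the textbook
  construction, is biased at feasible resolutions because digitized
  offset surfaces undershoot their nominal radius; in the `V(t)` fit any
  linear distortion of the effective offset cancels out of SMI. Ideal
  plate/rod/sphere phantoms at 0.1 mm voxels give 0.00 / 2.90 / 3.80.
  As is known for this index, concave structures can go negative.
* **DA**: mean intercept length sampled over >= 128 quasi-uniform
  directions (Fibonacci spiral with a seeded random rotation) with
  parallel test-line rasters; an ellipsoid is fitted to `1/MIL^2` and DA
  is the longest/shortest principal MIL axis (>= 1). The `1 - min/max`
  convention used by some commercial packages is available via
  `da_convention = "one_minus"`.
* **Conn.D** (1/mm^3): `(1 - chi)/TV`, with the Euler characteristic
  `chi` computed exactly on the cubical complex of the foreground voxels
  (union of closed unit cubes, realising 26-connectivity), zero-padded at
  the ROI boundary (no mirror continuation: a strut cut by the ROI is
  capped, not doubled).

## Histomorphometry and microvessel density

The 2D module consumes already-labelled sections (class 0 marrow, 1
mineralized bone, 2 osteoid, 3 eroded-surface marker); colour
deconvolution of stained images is out of scope, as the original
segmentation used proprietary software. The bone surface is the set of
pixel edges between the solid phase (bone + osteoid) and non-solid pixels
inside the image; image-border edges are not surface. OV/BV is an area
ratio; OS/BS and ES/BS are edge-count fractions (length corrections
cancel); O.Th is the 2D inscribed-disc local thickness of the osteoid
seams. Surface *densities* (OS/BV, ES/BV, ES/TV) are reported as raw 2D
length/area by default; `stereology = TRUE` applies the standard pi/4
correction of staircase length to smooth perimeter, matching the
conventional mm^2/mm^3 readout — both conventions are exposed because the
original tables print 3D-style units from 2D sections without stating the
stereological model.

Microvessel density follows the isolated-cluster rule: any connected
cluster of positive pixels (8-connectivity) in a high-power field is one
microvessel; per-field counts, their mean and their total are reported
(the mean is the headline number; the total is emitted because the
source's convention is not stated).

## The synthetic phantom

`generate_head()` renders a spherical head (marrow 40, bone 160 on the
8-bit scale, so the 90-255 window separates the classes before noise)
with:

* a **band-pass Gaussian random field** trabecular texture — white noise
  smoothed at `strut_scale` minus the same noise smoothed at 2.5x that
  scale, thresholded at the quantile matching `bone_fraction_target`.
  The band-pass step matters: a plain low-pass field keeps arbitrarily
  large low-frequency pores, whereas real trabecular bone has a
  characteristic pore size; with the default texture the marrow pores
  stay well below the 1 mm cyst threshold, as they do in life.
  The anisotropy stretch elongates the autocorrelation along the
  phantom's MTD, which is fixed to the grid +z axis (the landmarks are
  generated consistently; downstream geometry takes the MTD from the
  landmarks, so an arbitrary-direction stretch would buy nothing).
* a solid **cortical shell** of `cortical_thickness`;
* **spherical cyst voids** at specified centres/diameters, optionally
  wrapped in a sclerotic rim of solid bone (`rim_thickness`). The rim
  mirrors the bony rim seen around real lesions, and it is what makes a
  cyst a *closed* void: without it the void communicates with the marrow
  through every pore it touches. The pipeline's default phantom uses a
  0.3 mm rim;
* Gaussian blur and additive intensity noise, then 8-bit quantization.

Ground truth (bone mask before noise, cyst label volume, per-cyst
analytic and voxelized volumes, landmarks) is returned alongside. All
outputs are bit-reproducible for a fixed seed; the generator restores the
caller's RNG state.

**What the phantom does not emulate:** beam hardening, scatter and ring
artefacts; plate-and-rod mixtures with realistic SMI around 1-2;
collapse/fracture defects; the intensity distribution of any particular
scanner (contrast values are conventions, as no quantitative intensity
data are available). Passing phantom tests therefore demonstrates that
the *measurement chain* is correct on structures of known geometry, not
that any particular clinical contrast will binarize cleanly at 90.

The default study conditions were fixed once: pipeline phantoms use a
10 mm head at 0.25 mm voxels (desk-scale stand-in for the 73.6 um
specimen scans), bone fraction 0.45 and strut scale 0.14 mm (realized
strut thickness ~0.46 mm, pores ~0.5 mm — a coarse-grid surrogate of
subchondral trabecular bone, thickened to stay resolvable at 0.25 mm),
three cysts of 3/2/1.5 mm. The sclerotic-vs-lytic contrast uses bone
fraction 0.45 vs 0.18, strut scale 0.12 vs 0.09 mm and anisotropy
stretch 1.1 vs 1.8 — sclerosis is denser, thicker-strutted and more
isotropic; lysis sparser, thinner and more oriented.

## Statistics

The two-group table reproduces the classical clinical decision tree:

* **Normality**: one-sample Kolmogorov-Smirnov against a normal with
  estimated mean/SD. The default applies the Lilliefors correction
  (estimated parameters invalidate the plain KS null distribution); the
  uncorrected variant — the readout of older SPSS one-sample KS dialogs —
  is available via `method = "ks"`. The Lilliefors implementation
  requires n >= 5, so that is the guard (samples of 2-4 observations
  take the parametric route in `compare_continuous`, documented).
* **Continuous**: pooled-variance two-sided t-test when both samples
  pass the screen at alpha = 0.05, otherwise the asymptotic two-sided
  Mann-Whitney U with tie correction and no continuity correction
  (matching the SPSS asymptotic p). Welch's t is behind a flag.
* **Categorical**: uncorrected Pearson chi-squared by default — the
  choice is not arbitrary: it reproduces the printed baseline-table
  p-values (0.903, 0.908, 0.292, 0.425) from the printed counts to three
  decimals, which neither Yates nor Fisher does. Fisher's exact test is
  auto-selected when any expected count falls below 1, and both Yates
  and Fisher are available explicitly. One printed row (hypertension,
  p = 0.724) is not reproduced by any of the three tests on the printed
  counts (uncorrected chi-squared gives ~0.707) and is not targeted.
* No multiple-testing correction is applied, matching the source.

## Problem sizes and runtime choices

The test suite runs phantoms at 0.1-0.3 mm voxels on grids up to ~133^3:
large enough that the analytic tolerances (+-1 voxel on thickness, +-5%
on 3/r, +-0.3 on SMI, +-10% on cyst volumes) are meaningful, small
enough that the whole suite completes in minutes. Oracle-equivalence
checks (brute-force inscribed-sphere filter, cell-counted Euler
characteristic, brute-force local thickness) run on <= 32^3 instances
where exhaustive enumeration is feasible. The type-I-error simulation
uses 2,000 replicates of the 45/105 design at event probability 0.2.

## Known limitations

* Tb.Th/Tb.Sp inherit the one-voxel parity bias of centre-to-centre
  distance maps; at the 73.6 um voxels of the source scans this is ~7 um.
* SMI requires the structure to be at least ~3 voxels thick for the
  +-3-voxel offset fit; thinner struts push SMI negative (plate-like
  bias), a known property of the index near the resolution limit.
* The MIL tensor is fitted to `1/MIL^2`; for strongly plate-like
  structures the MIL ellipsoid is itself only an approximation, and DA
  between differently shaped but equally oriented structures is not
  comparable across conventions.
* `estimate_mtd()` is a stand-in for a manually placed axis and should
  not be trusted within ~10 degrees on nearly isotropic heads.
* The exterior-void exclusion is a geometric proxy for an expert's
  exclusion of collapse defects; on real collapsed heads it will also
  exclude genuine cysts that have broken through the articular surface.
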