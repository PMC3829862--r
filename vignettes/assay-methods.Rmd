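---
title: "Methods: simulating and analyzing a single-cell FRET calcium screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing a single-cell FRET calcium screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The assay

`fretscreen` models a high-content screening assay in which HEK293 monolayers
expressing a genetically encoded FRET calcium sensor (a cameleon-type
CFP/YFP construct) are imaged in 384-well plates while a muscarinic agonist
(carbachol, CCh) is dispensed mid-acquisition. Carbachol triggers
IP3-mediated calcium release from the endoplasmic reticulum; calcium binding
raises the sensor's acceptor/donor emission ratio. Cells carrying
familial-Alzheimer presenilin-1 mutations show an exaggerated evoked release
— roughly 3-fold the wild-type peak amplitude — and near-universal
responsiveness (>95% of cells versus ~29% in wild type), which is the
screening window: compounds are scored by how far they pull the evoked peak
back toward wild-type levels.

The package provides the complete desk-scale emulation of that screen: a
ground-truthed synthetic plate generator, the image-analysis pipeline
(nuclear segmentation, cell-boundary assignment, edge exclusion, ratio and
dF/F0 trace extraction, responsiveness calls, well summaries), the screen's
decision layer (per-plate DMSO normalization, replicate aggregation, hit
calling, artifact filtering, Z'-factor QC), dose-response fitting, and
fingerprint clustering for structure-activity summaries.

# Acquisition timebase

Each well is imaged for a nominal 23.5 s: a 5 s baseline at 2.5 s intervals
(frames at t = 0, 2.5, 5 s), agonist dispensed immediately after the last
baseline frame, then 5 s at 1 s resolution (t = 6..10 s) to capture the fast
rise, and 2.5 s resolution for the decay (t = 12.5..22.5 s) — 13 frames in
all (`default_timebase()`). Note the frame times span 22.5 s; the remaining
second of the nominal duration is the dispense gap between the t = 5 s and
t = 6 s frames plus the final exposure. The protocol's stated sub-windows
(5 s + 5 s + 12.5 s) likewise sum to 22.5 s of sampled time. We implement
the 13-frame grid above and treat "23.5 s" as the protocol's nominal wall
time, not a frame timestamp. `dispense_index` is recorded 0-based (equal to
the number of baseline frames, 3) in all sidecar files.

# The synthetic plate generator

The generator's purpose is to emulate every statistical structure the
analysis relies on, with full ground truth retained, not to be photorealistic.

**Cell fields.** `simulate_field()` places nucleus centers by random
sequential adsorption with a minimum spacing. Cells are disks: a nucleus
(radius 4 px) inside a cytoplasm (radius 9 px); contested pixels between
overlapping cytoplasm disks belong to the nearer nucleus. Defaults seed
175 cells in a 420x420 px field — the midpoint of the 150-200 cells the
real assay detects per well, in a geometry where the strict edge-exclusion
rule removes roughly 10% of cells, so detected counts land inside that
band. Centers may fall arbitrarily close to the border on purpose: those
are the cells the edge filter must catch.

**Calcium dynamics.** Each cell has flat baseline calcium (0.1 arbitrary
units). Responders — drawn i.i.d. with probability `responder_fraction`
(0.96 for the FAD-like default, 0.29 for wild-type presets) — add an evoked
transient with exponential rise (tau 0.8 s) and decay (tau 4 s), amplitude

```
A = evoked_amplitude * peak_scale * genotype_amplitude * (1 - suppression)
```

with `evoked_amplitude` 0.6, per-cell `peak_scale` ~ N(1, 0.15) truncated
below at 0.5 (so every planted responder clears the responsiveness
threshold in noiseless conditions), `genotype_amplitude` 3 for FAD-like
versus 1 for wild-type wells, and `suppression` the well's pharmacological
block (0 for DMSO/untreated, 0.9 for TP/CPA/TMB-8 positive controls, which
are all modeled as plain evoked-release suppressors).

**Sensor map and rendering.** Calcium maps to an acceptor/donor ratio
through a saturating Hill-type curve `r0 + r_dyn * ca/(ca + k_half)`
(defaults r0 = 1, r_dyn = 32, k_half = 80). The half-saturation sits far
above the evoked calcium range (peak FAD calcium ~1.9 units), keeping the
screen-relevant regime near-linear — this is what lets the 3-fold genotype
multiplier propagate to an approximately 3-fold measured dF/F0 peak (mild
saturation plus the responsive-only averaging bias leave the measured ratio
slightly below 3). A constant per-pixel sensor emission is split between
donor and acceptor so that their ratio equals the mapped value exactly at
zero noise. The nuclear channel is static. Shot noise is Gaussian with
sd = `photon_noise_scale * sqrt(intensity)` (a Poisson approximation,
exact zero-noise path at scale 0), plus uniform per-channel background.
Autofluorescent compounds are emulated as additive per-channel offsets,
toxic ones as a reduced cell count.

**What is not modeled:** optical PSF, photobleaching, cell movement or
division, dispense artifacts, channel cross-talk, spatial plate effects.
Passing tests therefore demonstrate correctness of the analysis logic on
data satisfying its assumptions, not robustness to those real-world
nuisances.

# Segmentation

Nuclei are detected on the first timepoint's nuclear channel: Gaussian
smoothing (sigma 1 px), Otsu threshold (the paper-style pipeline names no
algorithm; an absolute threshold is available), distance-transform
watershed to split touching nuclei, minimum area 20 px. Cell boundaries are
assigned by nucleus-seeded propagation on the summed donor+acceptor image,
restricted to foreground pixels within `max_radius_px` (10) of a nucleus;
contested pixels are partitioned so no pixel has two owners and every
nucleus gets exactly one region. Segmentation is computed once on the first
frame and reused — cells are assumed static over the 13 frames.

The edge rule is the strict reading: a cell is excluded if *any* pixel of
its region (not just the nucleus) touches the frame border. Labels are
preserved rather than renumbered so ground-truth bookkeeping stays trivial.

# Trace analysis

Per cell and frame, donor and acceptor means within the cell mask are
background-corrected by the mean over non-cell pixels of the same frame
(policy `"field"`; `"none"` is available). The ratio series is
acceptor/donor; a corrected donor <= 0 in any frame invalidates the trace.
F0 is the mean ratio over the pre-dispense frames and dF/F0 = (F - F0)/F0.
The peak is the maximum dF/F0 at or after the dispense frame; baseline
frames are never eligible. A cell is responsive iff peak >= 0.1 (boundary
inclusive; the real assay's threshold is described only as "arbitrarily
defined", so it is exposed in configuration, and `calibrate_threshold()`
reports the threshold achieving a target responsive fraction on control
wells). The 0.1 default sits well below wild-type evoked peaks (~0.22 at
default optics) and far above the noise floor of a ~250-pixel cell mean.

The well readout is the mean peak over responsive cells; a well with fewer
than 20 responsive cells is invalid (an operational QC floor — generous
given 150-200 detected cells, but it bites in strongly suppressed or
wild-type-like wells with ~29 responders, whose readouts drop out of
genotype comparisons rather than contributing unstable means).

# Screen analytics

Each valid well's readout is divided by the mean readout of the same
plate's valid DMSO wells — the *normalized ER calcium response* (typically
<1 under suppression). Replicates (4 by default) aggregate by arithmetic
mean and sample sd over valid wells. A compound is a **hit** iff its mean
normalized response is strictly below 0.9 — the printed "<90% of DMSO
controls" rule, with the boundary excluded — and it carries no artifact
flag.

Artifact filters are name-only in the source assay, so thresholds are
operational defaults: **autofluorescent** if a compound's wells' raw
pre-dispense per-cell donor or acceptor baseline exceeds the DMSO mean by
5 DMSO-sds (margin floored at 1e-6 relative, so an idealized zero-variance
noise-free plate cannot flag float jitter); **toxic** if the detected cell
count falls below 0.3x the plate median. A compound is flagged when the
majority of its replicate wells trigger the rule.

**Z'-factor.** Two variants are computed from TP and DMSO control wells:
the canonical Zhang et al. statistic `1 - 3(sd_TP + sd_DMSO)/|mu_TP -
mu_DMSO|` (the default) and an "as printed" variant `1 - (3 sd_TP +
sd_DMSO)/|mu_TP - mu_DMSO|` that appears in some reports and weights only
the positive-control sd by 3; the two coincide when sd_DMSO = 0 and the
as-printed value is otherwise the larger. Plate QC in the image pipeline
uses the *all-cell* mean peak normalized to DMSO, because a well under 90%
suppression legitimately has almost no responsive cells and the
responsive-only readout is undefined there. For plate-level QC studies
(many plates, no imaging), `simulate_control_wells()` draws well-level
readouts directly: DMSO ~ N(1.0, 0.03), TP ~ N(0.3, 0.01), 16 wells per
group. The population Z' of those defaults is 0.829; note that with 16
wells per group the plate *estimate* has a sampling sd of about 0.025, so
occasional plates below 0.8 are expected behavior of the statistic, not a
failure of the assay window.

# Dose-response fitting

`fit_hill()` fits the four-parameter log-logistic curve

```
response = bottom + (top - bottom) / (1 + (ec50/dose)^hill_slope)
```

by Levenberg-Marquardt least squares on log(ec50), with multi-start over
slope signs and magnitudes (+-0.5, +-1, +-3), initial ec50 at the geometric
mean of the doses bracketing half-response, and an honest `converged` flag.
Rising (agonist, EC50) and falling (antagonist, IC50) curves differ only in
the slope sign; `top >= bottom` is canonicalized when both plateaus are
free. Fits are refused for constant responses or fewer than 4 distinct
doses. For normalized data the plateaus can be pinned
(`fix = list(bottom = 0, top = 1)`).

The parameter-recovery benchmark (tested) uses that normalized-data mode on
a 7-point log grid centered on the expected EC50 with Gaussian noise at 5%
of range, where the median relative EC50 error is below 10%. This is a
design statement, not generosity: a Fisher-information calculation shows a
free 4-parameter fit on 7 points is information-limited to roughly twice
that error, so sparse-grid screening data should be fit with plateaus
pinned whenever responses are DMSO-normalized.

# Structure-activity clustering

Compounds are binary fingerprints compared by Tanimoto dissimilarity
(1 - shared/combined set bits). Representatives are chosen from the
*active* compounds (normalized response < 0.9) by OptiSim selection: after
canonical ordering by compound id, repeatedly draw a random subsample (at
most k = 10) of the compounds farther than r = 0.4 from every current
representative and promote the subsample member with the largest minimum
dissimilarity to the selected set (ties to the earlier compound; the first
representative is the first draw). Selection is deterministic per seed and
invariant to input permutation. Actives join their nearest representative;
inactives join only within the assignment radius (= r) and otherwise pool
as unclustered; representative chains within the merge radius (= r) are
merged single-link. Per-cluster annotation follows the map rules: *star*
iff >50% of members are active, *highlighted* iff additionally more than
four members are active. The published algorithm's parameters are not
stated in the source; k and r are configurable with the defaults above.
The 2-D map layout itself is out of scope — only the membership and
annotation tables are produced.

# Problem sizes and runtime choices

The package's own test and acceptance studies run at desk scale: 20 wells
x 100 cells per genotype for responder-fraction recovery, 10 wells per
genotype for the amplitude ratio, 10 control plates of 16+16 wells for Z',
10 default-density fields for segmentation, a 32-compound noise-free
single-replicate screen for hit recovery, and 100 random instances of <= 15
compounds for the OptiSim oracle comparison. Full 384-well plates render
well by well (a stack is ~55 MB in memory), streamed through the analysis
or written to disk as 32-bit float TIFF scaled into [0, 1] with the scale
recorded in the JSON sidecar (float TIFF round-trips to ~1e-9 relative
precision, not bit-identity).

# Known limitations

- The generator's idealized optics make segmentation nearly perfect;
  recall/precision bounds validate the plumbing, not performance on real
  microscopy.
- TP/CPA/TMB-8 are interchangeable suppressors here; their distinct
  pharmacology (SERCA inhibition versus IP3-pathway antagonism) is not
  modeled.
- No B-score or spatial-effect correction; normalization is per-plate DMSO
  scaling only.
- Cluster merging approximates the source's manual "combined according to
  their structures" step by representative-distance single-linkage.
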