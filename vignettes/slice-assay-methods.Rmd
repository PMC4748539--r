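---
title: "Quantifying drug response in ex vivo tumor slice cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drug response in ex vivo tumor slice cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicetox)
```

## The assay and what this package computes

Organotypic tumor slices — thin (~300 µm) living sections of a resected
tumor — can be cultured for about a week while retaining their native
architecture, proliferation and low background cell death. Exposing slices
from one tumor to a ladder of chemotherapy concentrations and reading out
proliferation and cell death yields a per-tumor chemosensitivity profile
long before clinical response data exist.

`slicetox` implements the analytical half of such an assay for FAC
chemotherapy (5-fluorouracil, doxorubicin, and the pre-activated
cyclophosphamide metabolite 4-HC) in breast tumor slices:

1. **Image quantification.** From multi-channel confocal fields
   (512×512 px, ~0.7 µm/px; DAPI, pan-cytokeratin, EdU, TUNEL):
   - *keratin-positive tumor area* — grayscale hole filling by
     morphological reconstruction, Sobel edge detection with a
     user-defined threshold, morphological cleanup and region filling;
     the pixel count of the filled mask is the tumor area.
   - *EdU-positive cell count* — intensity threshold, removal of objects
     smaller than 10 px, hole filling by reconstruction, erosion with a
     flat disc, and counting of objects larger than 10 px.
   - *TUNEL-positive fraction of DAPI pixels* — per-channel Otsu
     thresholds and a binary Manders-style overlap fraction. Counting
     pixels instead of nuclei sidesteps the overlapping-nuclei problem of
     dense tumor tissue; the DAPI mask is the internal reference for all
     nuclei present.
2. **Per-field and per-slice statistics.** The proliferation index is
   EdU-positive cells per 10⁴ µm² of keratin-positive area (the area
   normalization removes bias from stroma-rich fields). Slices are
   summarized by the median and interquartile range across multiple
   randomly imaged fields — the IQR is the assay's dispersion measure for
   intra-tumor heterogeneity.
3. **Dose–response classification.** The FAC ladder holds the three
   components at the clinical molar ratio 46:1:22 and spans dilutions #1
   (strongest: 460/10/220 µM) to #10, one decade per three steps, plus an
   untreated control (#11). Per dilution, an *effect flag* is set
   (proliferation inhibited, or cell death induced); the *threshold
   dilution* is the weakest dilution of the unbroken flagged run starting
   at the strongest tested dilution. Tumors are classified sensitive
   (threshold ≥ 7), resistant (threshold ≤ 2 or none), or intermediate.
4. **Synthetic microscopy.** A seeded generator produces fields and whole
   cohorts with full ground truth, standing in for patient material so
   every operator and the end-to-end classification can be validated.

## A worked example

```{r example}
# simulate a small two-tumor experiment: one mid-sensitivity, one resistant
profiles <- list(tumor_sim_profile("T1", true_threshold = 5),
                 tumor_sim_profile("T2", true_threshold = 2))
fields <- simulate_response_experiment(
  profiles, dilutions = c(2:7, 11), n_fields = 6,
  spec = field_spec(width = 96, height = 96, n_nuclei = 25,
                    nucleus_radius_range = c(3, 5)),
  seed = 42)
call_cohort_thresholds(fields, "edu")
```

Both simulated thresholds are recovered from the rendered pixels alone.
The published 15-tumor reference cohort is shipped with the package:

```{r cohort}
cohort_counts(fac_reference_cohort(), "morphology")$counts
```

## Design choices and their rationale

**Threshold semantics.** "The weakest dilution at which the effect is
seen" is interpreted on the concentration scale: the threshold is the
*largest* dilution index of the unbroken flagged run from the strongest
tested dilution. This is the only reading under which the most sensitive
group of the reference cohort thresholds at dilution #5 and the known
resistant tumors score #2. A non-monotone flag series (an isolated flag at
a weaker dilution) does not occur under the assay's dose-effect logic;
the caller ignores such flags with a warning rather than extending the
run.

**Effect criteria.** The assay describes inhibition and "clear induction"
qualitatively. The defaults are: proliferation inhibited when the slice
median falls below 0.5× the control median; death induced when the slice
median TUNEL fraction exceeds the control median by more than 1.5 control
IQRs. Both are exposed as configuration parameters.

**Resistance boundary.** "Not inhibited up to dilution #3" is read as:
the effect appears only at #2/#1 or never, so a threshold of exactly 3 is
intermediate and ≤ 2 (or none) is resistant. The boundary is a
`classify_tumor()` argument.

**Keratin pipeline order.** Edge detection yields a ridge ~2 px thick that
straddles the true boundary. An opening applied before region filling
destroys that ridge outright, so the default cleanup order is closing →
fill → erosion → opening (configurable and recorded in provenance). The
post-fill erosion (radius 2) compensates the outward offset of the filled
contour — without it areas run 15–25 % high on synthetic truth; with it a
sharp 100×100 square measures 9,600 px and synthetic tumor regions land
within ~6 % of their ground-truth masks.

**Otsu ties.** The between-class variance is maximized over the 255
interior boundaries of a 256-bin histogram; tied plateaus return their
midpoint, so a two-valued image thresholds exactly between its modes.

**Structuring elements.** Discs of radius 1 (erosion before counting) and
radius 2 (opening/closing); under this discretization a radius-1 disc is
the full 3×3 neighborhood. Components and reconstruction use
8-connectivity by default; both are configurable.

**Size rules.** "Smaller than 10 px removed" and "more than 10 px
counted" are applied with strict inequalities; an object of exactly 10 px
survives removal but is only counted if erosion leaves it above 10 px.

## What the generator emulates — and what it does not

Each synthetic field renders: nuclei as discs (radius 4–6 px at the
default 512×512 geometry) placed by rejection sampling with pairwise
center separation ≥ 2·r_max + 3 px; a cytokeratin region drawn from a
smoothed Gaussian random field, tapered so it never touches the frame
border, thresholded at the requested coverage; EdU- and TUNEL-positive
subsets of exactly `round(fraction × n_nuclei)` members, with EdU members
drawn preferentially from nuclei inside the keratin region (proliferating
tumor cells); a Gaussian optical blur (σ = 0.6 px); additive Gaussian
sensor noise (σ = 0.02) clipped to [0,1]; and 16-bit quantization. One
master seed drives everything; per-field sub-seeds are derived and
recorded, and identical specs reproduce bit-identical rasters.

The separation guarantee and the border taper are *generator guarantees*
chosen so that object counting and edge-based area estimation have exact
oracles — they are not biological claims. Real tissue has touching and
overlapping nuclei, uneven illumination, staining artifacts and
out-of-focus light; the pixel-based TUNEL readout was designed for exactly
that situation, but a green test battery here demonstrates correctness of
the operators under the generator's assumptions, not performance on
clinical material.

Dose response is simulated as a four-parameter logistic in log
doxorubicin concentration (the reference component of the fixed-ratio
mixture). The curve midpoint sits at the geometric mean of the
concentrations of the tumor's true threshold dilution and the next weaker
one: the threshold dilution then sees ≤ 20 % of baseline proliferation
and the next weaker dilution ≥ 80 % (Hill slope 4), which is what makes
threshold recovery a sharp, falsifiable property rather than a coin flip.
Per-field realized fractions are beta-distributed around the model mean
with dispersion `heterogeneity_sd` (default 0.05), matching the
median/IQR style of reporting without claiming the real distribution —
the assay's own publications report only medians and IQRs. Untreated
baselines default to an EdU fraction of 0.20 and a TUNEL fraction of
0.05, with death saturating at 0.40 at the strongest concentrations.

## Numerical conventions

- Intensities are normalized to [0,1] from the bit depth before any
  thresholding, so user thresholds are bit-depth independent.
- Sobel magnitude is the Euclidean norm of the two 3×3 responses divided
  by the maximum attainable response (4√2), with replicate boundary
  handling; a uniformly bright frame therefore has zero gradient
  everywhere and yields area 0 with a `no_edges` flag.
- Quartiles use the linear-interpolation convention (R type 7).
- Degenerate inputs: constant rasters are a "degenerate histogram" error
  for Otsu; an empty DAPI mask is a "no nuclei detected" error; a
  degenerate TUNEL channel is treated as having no positive pixels; a
  keratin-free field is flagged and excluded from summaries rather than
  imputed; an all-flagged slice is an error.
- Grayscale reconstruction uses the hybrid raster-sweep + FIFO algorithm
  in compiled code; its test oracle is an independent iterative
  dilate-and-clamp loop.

## Problem sizes used in the validation suite

The test battery and the acceptance script exercise cohort-scale runs at
96×96 px per field, 25 nuclei, 10 fields per slice, dilutions #2–#7 plus
control — 1,050 rendered and quantified fields per master seed, 20 seeds
for the recovery experiment. Field size is a free generator parameter;
the operators are resolution-independent and the default single-field
geometry remains 512×512. The recovery experiment regenerates roughly
21,000 fields, which is why the cohort path streams each field through
quantification and retains no rasters.

## Known limitations

- The TUNEL readout inherits Otsu's bimodality assumption: on a field
  with no true TUNEL signal, noise alone can be split into two classes
  and produce a spurious positive fraction. The assay uses it to detect
  major differences, not subtle ones, and the simulated baselines keep a
  nonzero true fraction.
- Morphology scoring (karyolysis, pyknosis, karyorrhexis, apoptotic
  bodies) is a human judgment; the package only aggregates binary
  per-dilution calls and never computes them from pixels.
- No pharmacokinetics: the dilution ladder is an ex vivo exposure design,
  so classifications speak to intrinsic sensitivity, not clinical dosing.
- Operators are strictly 2D, matching the section-based acquisition; no
  3D reconstruction or deconvolution is attempted.
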