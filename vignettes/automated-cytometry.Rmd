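---
title: "Methods: underway automated cytometry of marine prokaryotes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: underway automated cytometry of marine prokaryotes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytocruise)
```

## The measurement model

An automated sampler coupled to a bench-top flow cytometer takes a surface
seawater sample at a fixed cadence (at least 15 min apart — the machine's
cleaning cycle sets that floor), mixes it 1:1 with a SYBR Green I working
solution, incubates 10 min at 37 °C, and pushes the stained sample through
the cytometer for 1 min at 66 µL/min. Every particle crossing the laser
produces one *event* with forward scatter (FSC, a relative size proxy), side
scatter (SSC), green fluorescence (FL1, the nucleic-acid stain signal) and
red fluorescence (FL3, photosynthetic-pigment autofluorescence).

Counting is volumetric. If $N$ events fall inside the prokaryote gate, the
concentration is

$$C = \frac{N}{V} \times d \times 1000 \quad \text{cells mL}^{-1},$$

with $V$ the analyzed volume in µL (66 µL at the defaults) and $d$ the stain
dilution factor (2 for the 1:1 mix). Every downstream quantity — diel
contrasts, growth rates, biomass, diversity — is built on the per-sample
event tables this model produces.

```{r}
events_to_concentration(16500, volume = 66, dilution = 2)
```

## Event-level preprocessing

The chain is: acquisition threshold → asinh transform → (optional) polygon
gate → global normalization → subsampling.

* **Threshold.** The instrument triggers on green fluorescence; events below
  the FL1 threshold are never recorded. The boundary is inclusive
  (`FL1 >= threshold`), emulating a hardware trigger. The Accuri template
  value is 800; synthetic campaigns use the generator's own trigger (below).
* **Transform.** Intensities are mapped through $\operatorname{asinh}(x/c)$.
  We read the common shorthand "arcsin transform" in cytometry workflows as
  the inverse hyperbolic sine: the circular arcsine is undefined above 1,
  while asinh is the standard variance-stabilizing choice (linear near zero,
  logarithmic in the bright tail, defined at zero, strictly monotone). The
  cofactor defaults to 1 (plain asinh), matching the convention of the usual
  R cytometry toolchain.
* **Gating** uses simple polygons with an even-odd (ray casting) test;
  events on an edge count as inside, so a gate drawn on the data hull keeps
  everything. Gates carry a `transformed` flag so they cannot silently be
  applied on the wrong scale.
* **Normalization.** All fingerprint channels are divided by the *global*
  maximum transformed FL1 across the analyzed set, so the brightest green
  event of the campaign maps to 1 and bin positions are comparable between
  samples — the prerequisite for fingerprint-based diversity. A per-sample
  mode exists but breaks that comparability. Because the anchor is FL1, an
  extreme red-fluorescence tail can exceed 1 by a small margin; the pipeline
  counts such events in the top bin (up to +10%), while clearly unnormalized
  data still raises an error.
* **Subsampling.** Each cytogram is cut to the common minimum event count
  (uniform, without replacement, seeded) before diversity is computed, so
  richness differences are not driven by sampling depth.

## Abundance statistics

Day/night contrasts classify samples by local-time window (default
06:00–21:00, early-June western-Mediterranean daylight) and compare group
medians with a two-sample t-test — Welch by default, since equal variances
are not guaranteed between day and night; the pooled-variance Student
variant is available by flag. Net growth is the OLS slope of
$\ln C$ on time in days; the doubling time $\ln 2 / \mu$ is reported only
for $\mu > 0$ (slopes at floating-point noise level count as zero).

## Size and biomass

FSC is only a relative size measure; beads of known diameter (0.5 µm by
default) anchor it. The conversion uses a single-point power law

$$d = d_\text{bead} \left(\frac{\overline{FSC}}{FSC_\text{bead}}\right)^{1/\gamma},$$

a modelling choice, not a physical law: $\gamma = 2$ (default) follows the
heuristic that scattered intensity grows with the cell's projected area, and
$\gamma = 1$ reduces to linear scaling. Cells are treated as spheres
($V = \pi d^3/6$) and carbon follows the marine-bacterioplankton allometry
$0.2\,V^{0.72}$ pgC per cell; total biomass is carbon per cell times
concentration. Both the mean and the median FSC are computed, since either
summary can anchor the calibration.

## Fingerprints and Hill diversity

A processed cytogram is binned on a $128 \times 128$ grid over one or more
two-channel planes (default: the FL1 × FL3 stain/autofluorescence plane).
The relative bin densities $p_i$ act as phenotype abundances, and diversity
is the Hill number

$$D_q = \Big(\sum_i p_i^q\Big)^{1/(1-q)},$$

with $D_0$ the number of occupied bins, $D_1 = \exp(-\sum p_i \ln p_i)$
taken by the entropy limit (never by plugging $q = 1$), and $D_2$ the
inverse Simpson index. Raw counts are used — the bin densities themselves
are the phenotype abundances — with an optional Gaussian pre-smoothing
(off by default) for sensitivity analysis only; smoothing is renormalized to
preserve the event mass exactly. Beta diversity is Bray–Curtis,
$1 - \sum_i \min(p_{ai}, p_{bi})$, on the normalized concatenated densities.

```{r}
hill_diversity(c(0.75, 0.25), q = c(0, 1, 2))
```

## Population structure: SOM, metaclusters, labels

Pooled events (an even draw across samples) train a $10 \times 10$
self-organizing map — 100 clusters — on the transformed FL1, FL3, FSC and
SSC channels. We use the *batch* Kohonen rule with a PCA-spanned linear
initialization: each epoch assigns every event to its nearest code vector
and replaces each code by the Gaussian-neighborhood-weighted mean of the
assigned events, with the radius shrinking linearly from half the grid to
0.3. Batch training with a deterministic start needs no random stream at
all, which makes every run exactly reproducible — the same reason the
metaclustering step uses deterministic Ward hierarchical clustering of the
code vectors (cut at 10 groups by default) rather than a consensus scheme.
A short winner-take-all fine-tuning phase follows, in which units that
attract no events are relocated onto the worst-quantized events; this uses
the map's full capacity and empirically drives the quantization error to
zero in the degenerate case of as many distinct points as units. Ties in
nearest-code assignment break to the lowest cluster index.

Labelling works in two steps on the transformed (un-normalized) scale,
where fluorescence separations have fixed magnitude:

1. **PHOTO.** Metacluster FL3 medians are sorted and the largest jump
   located. If that jump exceeds 1.0 asinh units — photosynthetic cells sit
   roughly 2 asinh units above stained heterotrophs, while metaclusters of a
   red-free community form a near-continuum of jumps below ~0.5 — the
   threshold is the jump's midpoint and everything above it is PHOTO.
   A community without red cells therefore yields zero PHOTO metaclusters.
2. **HNA/LNA.** Remaining metaclusters split by their event-weighted median
   FL1 against a split point on the pooled non-PHOTO FL1 values. The
   default split is Otsu's minimum-within-class-variance threshold, which
   lands in the valley between the two fluorescence modes. A plain pooled
   median (available via `split_method = "median"`) forces half the events
   below the split and systematically drags borderline metaclusters toward
   a 1:1 ratio when the true groups are unbalanced; on ground-truth
   mixtures this inflated ratio errors several-fold, while the Otsu split
   keeps them within a few percent.

Metaclusters with no events are labelled OTHER. The HNA/LNA event-count
ratio is the usual community-activity proxy; it is undefined (error) when
no LNA events exist.

## The synthetic campaign generator

The generator is the package's ground-truth instrument. It emulates:

* **Populations** as independent log10-Gaussian channel intensities.
  Defaults: LNA at FL1 log10-mean 2.8 and HNA at 3.4 (shared sd 0.15 —
  separable but overlapping, as real HNA/LNA clouds are), photosynthetic
  prokaryotes marked by FL3 log10-mean 3.5 versus ≤ 2.5 for everything
  else, and fractions LNA 0.55 / HNA 0.40 / PHOTO 0.05, typical
  proportions for an oligotrophic Mediterranean surface community. These
  are fixture defaults, not claims about any dataset.
* **Background noise** as a dim cloud (FL1 log10-mean 1.8, sd 0.25) at 0.1
  events per expected stainable event. The emulated instrument triggers at
  $10^{2.35} \approx 224$ arbitrary units, placed in the gap between the
  noise cloud and the dimmest stained cells; this plays the role the
  threshold 800 plays on the real instrument's intensity scale, and
  analyses of synthetic campaigns should use it
  (`synthetic_fl1_threshold()`).
* **Counting statistics**: stainable events are Poisson with
  $\lambda = C \cdot V / (1000\,d)$, split multinomially across
  populations — so abundance estimation can be tested against exact
  ground truth.
* **The cruise**: a ≥ 15-min sampling clock with tubes rotating in
  succession (one sample per tick), station segments with their own base
  concentration and environmental levels, an exponential net-growth trend,
  a diel sinusoid $1 + A\sin(2\pi(h-6)/24)$ (minimum at midnight, maximum
  at noon, phase configurable), mean-one log-normal sample-to-sample noise,
  and a conductivity channel built as the log-abundance anomaly plus
  Gaussian noise scaled so the abundance–conductivity correlation hits a
  target value in expectation — the simplest mechanism that makes the
  coupling strength a single controllable dial. The thermosalinograph
  stream is written at 1-min cadence.

What the generator deliberately does **not** emulate: optical physics of
scatter (channels are statistically, not physically, linked to size),
channel correlations within a population, instrument drift, clogging,
spillover structure, or doublets. Passing the recovery tests therefore
shows the *computational* chain is correct and unbiased under the stated
statistical model — not that the instrument model captures every feature of
real cytograms. Real data keep their manual-gate and calibration steps.

## Numerical choices and degenerate inputs

* Timestamps are handled in UTC throughout; run folders must be named
  `YYYY-MM-DD_HH-MM-SS` and other layouts are skipped with a warning, not
  guessed.
* FCS files are written as FCS 3.1, list mode, 32-bit little-endian floats;
  reading supports FCS 2.0/3.0/3.1 with integer (8/16/32-bit), float or
  double data, either byte order, linear amplification only.
* Zero-event cytograms read and write cleanly; empty run trees and empty
  sample sets abort with explicit errors.
* Environmental matching is nearest-in-time (no interpolation) with a
  450-s tolerance — half the sampling cadence — and ties take the earlier
  record; unmatched samples keep `NA` environment rather than dropping.
* Correlations are computed on raw abundance by default, with a log flag;
  p-values are unadjusted (no multiple-testing correction is silently
  added).
* All stochastic stages (subsampling, pooling, simulation) derive their
  seeds from one configured integer; SOM training itself is deterministic.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to make the statistical
bounds sharp yet quick on a single core: 200 simulated acquisitions at
$\lambda = 16{,}500$ for abundance recovery, 200 synthetic days (85 samples
each) for growth-rate bias, 100 days for diel detection power, 20 seeds of
$10^4$ three-blob events for metacluster recovery, 50 seeds of 6,000-event
mixtures for the HNA/LNA ratio, and one 350-sample campaign for the
environmental-coupling check. Full campaigns in the examples span a few
hours of ship time; the code paths are identical at any length.

## Known limitations

* The FSC→diameter power law is a one-point calibration; absolute sizes
  inherit its exponent choice and should be read as relative unless beads
  bracketing the cell sizes are available.
* Hill numbers depend on the binning grid and the channel planes used;
  values are comparable within a campaign processed with one configuration,
  not across configurations.
* The PHOTO detection heuristic assumes red cells are rare-but-distinct; a
  community dominated by photosynthetic cells would defeat the
  largest-jump rule and should use an explicit `red_threshold`.
* Multi-dataset FCS files, log-amplified parameters and
  spillover/compensation are out of scope (the targeted acquisition applies
  none).
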