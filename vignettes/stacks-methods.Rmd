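---
title: "Methods: multicolor cell detection and Confetti clonal composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multicolor cell detection and Confetti clonal composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stacksr)
```

## The color model

A homozygous Brainbow2.1/Confetti animal carries the recombinable cassette on
both alleles. Cre exposure stochastically resolves each allele to one of four
fluorescent outcomes — nuclear hrGFPnls (nGFP), cytoplasmic eYFP, cytoplasmic
tdimer2(12) (RFP), membrane-tethered mCerulean (mCFP) — or leaves it
unrecombined. Collapsing the unordered allele pair to its set of distinct
expressed colors gives $\binom{4}{1} + \binom{4}{2} = 10$ observable classes:

```{r}
enumerate_color_classes()
```

`stacksr` computes this by exhaustive enumeration of allele-outcome pairs, not
by hard-coding. When the Cre enzyme arrives on a retroviral vector carrying
its own GFP marker, a cell can carry at most two distinct cassette colors plus
the viral GFP, so the per-cell signal bound is

```{r}
max_distinct_signals(with_viral_marker = TRUE)
```

The viral marker is modeled as an annotation (`none` / `transient` /
`integrated`), never as a fifth cassette color: transient expression is lost
within days, and the rare stably integrated provirus (about 1% of transduced
cells) is distinguishable only by its much higher green intensity (the GFP-hi
tier), which is why classification treats it as an intensity flag on the
green channel.

### Simulator assumptions and defaults

`simulate_population()` draws each allele independently from a common outcome
distribution. The two-allele independence is the simplest model consistent
with the existence of two-color cells; no inter-allele coupling is assumed.
Defaults, chosen once as the study conditions:

* `transduction_efficiency = 0.175` — the midpoint of the 15–20% window that
  virus titration targets to limit Cre toxicity.
* `unrecombined_mass = 0.2`, remainder uniform over the four colors.
  Empirical outcome frequencies are non-uniform and complexity-dependent
  (double-recombination outcomes appear depressed in real data), but no
  usable numbers exist, so the distribution is a parameter with a neutral
  default rather than a constant.
* `integration_fraction = 0.01` — the observed share of GFP-hi cells among
  transduced cells.
* One explicitly seeded generator per simulation call (`withr::with_seed`);
  the session RNG is never touched, and a fixed seed reproduces a population
  byte for byte.

The closed-form class distribution implied by allele independence (singles
$p_c^2 + 2 p_c p_0$, doubles $2 p_{c_1} p_{c_2}$, negative $p_0^2$) is
exposed as `class_probabilities()` and used by the tests as a
parameter-recovery oracle.

## The synthetic imaging model

`render_scene()` draws round suspension-type cells as disks of radius 8–12 px
on 512×512 fields (all geometry is in pixels; no physical pixel size is
assumed). Subcellular localization follows the fluorophore: cytoplasmic
colors fill the disk, nGFP fills a concentric nuclear disk of half the
radius, mCFP a 2 px rim annulus. A visible viral provirus adds green over the
whole cell body (transient level 3000, integrated 25000 by default). Signal
is 10000 over a background of 1000 with Gaussian noise (sd 800 by default),
rounded and clipped to the 16-bit range. A configurable fraction of cells
(default 20%) is placed as touching pairs with centers closer than the
radius sum (1–2 px overlap); debris is rendered as 1–4 px specks at 0.8×
signal to exercise the small-object filter.

What the renderer deliberately does **not** emulate: 3D stacks, point-spread
functions, spectral bleed-through (none was observed in the source data),
autofluorescent cytoplasm, elongated morphologies, or expression kinetics.
Passing tests therefore demonstrate the pipeline's correctness on idealized
disk-shaped cells with compartment-pure signal, not performance on real
tissue images.

## The detection pipeline

`run_pipeline()` chains the stages of the automated "Stacks" workflow:

1. **Stretch and smooth** each channel: linear rescale of the 1st–99th
   percentile window to [0, 1] with clipping, then Gaussian smoothing
   (sigma 1 px). A constant channel maps to all zeros rather than erroring,
   so empty channels degrade gracefully. One caveat is documented in
   `pipeline_config()`: if a channel's foreground covers well under 1% of
   the field, the upper anchor lands in the noise tail and amplifies that
   channel's noise in the composite. Raising the anchor (e.g. 99.9) fixes
   the amplification but lowers the composite threshold and widens the blur
   halo around objects, which re-merges touching cells; the default keeps
   the tighter masks.
2. **Composite** the four stretched channels by pixelwise maximum. Maximum
   rather than summation preserves single-channel cells at full contrast
   and cannot exceed 1; summation (available as `merge = "sum"`) inflates
   multi-color cells relative to single-color ones.
3. **Threshold just above the background peak**: the mode of a 256-bin
   histogram of the composite plus `threshold_offset_k` (default 3) times a
   robust background spread, estimated as the RMS deviation of the sub-mode
   half of the distribution reflected about the mode. The spread is floored
   at one bin width so clipped-to-zero backgrounds still give a strictly
   positive offset. A constant composite has no separable background peak
   and errors.
4. **Erode and expand**: the binary mask is eroded with a 3×3 box element
   for `erosion_cycles` (default 5) to disconnect touching cells, surviving
   components are labeled (8-connectivity by default), and every label is
   regrown by geodesic dilation constrained to the original mask: all
   fronts advance one 4-connected pixel per iteration, contested pixels go
   to the lowest label, labels never merge, and mask pixels unreachable
   from any seed stay background. The default cycle count is geometric: for
   radius 8–12 px cells overlapping by 1–2 px the binary neck is ~8–12 px
   wide (plus ~2 px of blur halo), which 3 cycles cannot cut, while nuclear
   seeds (≥4 px radius) still survive 5 cycles; 6 cycles begins to erase
   them.
5. **Filter**: objects under `min_object_px` (default 30 px) and, by
   default, objects touching the field border are removed; survivors are
   relabeled consecutively.
6. **Measure**: per label, area, centroid (0-based row/col) and per-channel
   means of the *original* (unstretched) intensities — the reported values
   are absolute intensities, not display units — plus relative channel
   contributions: channel mean minus the median background of non-object
   pixels, floored at zero and normalized to sum 1.

Connectivity (4 vs 8) for labeling and the structuring element are exposed as
configuration because the original description fixes neither; 8-connected
labeling with 4-connected fronts gives deterministic, orientation-unbiased
boundaries. The threshold on the composite is applied after per-channel
smoothing (the alternative — smoothing the composite itself — is a different
but equally defensible reading; this one keeps channel noise suppression
independent of the merge operator).

### Known limitations of the segmentation

* **Membrane-only cells**: a cell expressing only mCFP is visible as a 2 px
  annulus, which erosion removes entirely; such cells (~6% under uniform
  outcomes) are undetectable at the default cycle count. This mirrors the
  empirical observation that the blue channel has the least apparent
  threshold owing to its non-uniform localization.
* **Nuclear-only cells without a viral pedestal**: when nothing makes the
  cytoplasm visible, the detectable object is the nucleus (diameter ≈ the
  cell radius), which survives 5 erosion cycles only for the larger radii.
* **Disjoint compartments**: in an nGFP+mCFP cell with invisible cytoplasm
  the nuclear disk and membrane rim are separate mask components; the rim is
  unreachable by constrained expansion from the nuclear seed, so the
  measured object can miss the rim signal and read as nGFP alone.
* **Large touching pairs**: necks wider than 2×`erosion_cycles`+1 px stay
  merged. Erosion-based splitting cannot cut them without also erasing the
  nuclear seeds above.

These limitations motivate the evaluation design: object recovery is scored
by F1 (greedy centroid matching within the true radius), while intensity
quantification is scored as the relative error between the measured mean and
the noise-free rendered mean *over the same segmented mask* (the geometry
oracle). Scoring intensities against the true-disk mean instead would
double-count boundary placement — any thresholded mask carries a ~1 px blur
halo of background-valued pixels, which alone exceeds a few percent for
realistic radii — and boundary quality is already captured by F1.

## Threshold derivation and classification

Visual threshold reading ("a clear threshold was apparent") is formalized in
`derive_thresholds()` as valley detection on a log1p scale: the cutoff is the
midpoint of the lowest clear gap — an empty log-intensity interval at least
0.5 wide (~1.6-fold intensity jump) with at least 5% of events on each side.
Taking the lowest clear valley, not the widest, keeps the cutoff at the
negative/positive boundary even when a GFP-hi tier creates a wider gap higher
up; a pure variance-minimizing split fails the same three-tier case because
the distant hi tier dominates the variance. When no clear valley exists (the
membrane channel often lacks one), the method falls back to the two-class
variance-minimizing split, and the per-channel method tag records which rule
fired. The side requirement is a fraction, not a count, so thresholds are
invariant to event order and to duplicating the whole table; it also bounds
the smallest resolvable GFP-hi tier at 5% of green-positive events.

`classify_event()` applies exclusion-gating semantics: the class is the set
of channels above their cutoffs; events positive in more than two cassette
channels are assigned an explicit `unresolved` category rather than forced
into a class, and unresolved counts are always reported, never dropped. With
a GFP-hi cutoff enabled, green intensity above it is attributed to the viral
marker (the event is flagged `gfp_hi` and green positivity no longer implies
nGFP). The GFP-hi cutoff is disabled by default because the hi population is
not always present; it is only accepted when a clear gap supports it.
Spectral compensation is out of scope — inputs are assumed compensated.

`simulate_events()` models the post-transient timepoint: the viral marker
contributes no green signal by default (transient expression is lost within
days, and reconstituted organs showed no GFP-hi cells), while an optional
`gfp_hi_level` adds bright green to integrated-provirus cells for studying
the hi tier.

## Composition reporting

`compose_classes()` counts classified events per group in lexicographic group
order. Class fractions are computed among labeled events; `unresolved` is
counted separately and `negative` enters only the totals, so per group
`classes + unresolved + negative = total` always holds. Labeling efficiency
is labeled/total within the gated events of the group — gate membership is a
metadata column, not computed here. Display order is fixed (four singles in
canonical color order, then the six doubles) for stable cross-report
comparison. `compare_groups()` reports shared and unique classes plus the
total variation distance $\tfrac12\sum_c |p_c - q_c|$ between class-fraction
vectors. A "clone" here is a color class: with only 10 classes, multiple true
clones can share a class, so compositions measure marking diversity, not
clone counts, and no deconvolution is attempted.

## End-to-end demos and their expectations

`demo_confocal()` runs simulate → render → segment → classify → report on a
fully transduced population imaged after transient viral GFP has decayed (a
uniform viral pedestal would otherwise be absorbed into the adaptive green
threshold and mask nuclear nGFP). Its per-cell accuracy is scored against the
expected confocal class, where a visible viral marker makes the green channel
positive and a three-channel cell is expected to read `unresolved`. Because
of the compartment limitations above, matched-cell accuracy at the default
conditions is 0.92–1.0 across seeds (object F1 0.78–0.87, the misses being
nuclear-only and membrane-only cells), while the event-table classification
route — which has no segmentation in the loop — is exact without noise and
above 98% at a signal-to-noise ratio of 10.

`demo_flow()` runs simulate → organ subsampling with organ-specific class
weights → noisy events → classify → compose → pairwise organ comparison,
emulating ex vivo flow analysis of reconstituted organs.

## Problem sizes and verification

The test suite verifies, among others: the 10-class enumeration and 3-signal
bound by exhaustive genotype enumeration; the composite against a per-pixel
maximum oracle; the C++ labeling and geodesic expansion against independent
R reference implementations (explicit stack walk; synchronized matrix-shift
fronts) on hundreds of random masks up to 32×32; segmentation recovery on
twenty 512×512 fields of 50 cells at SNR 10 with 20% touching pairs and
debris (mean F1 ≥ 0.95, matched-cell intensity error ≤ 5%); classification
exactness on 10^4 noise-free events and ≥98% at SNR 10; class-frequency
recovery against the closed form at n = 10^5 within 4 binomial SE; and the
conservation invariants (count conservation per group, contributions summing
to 1, expansion contained in the pre-erosion mask). These sizes keep the full
suite under two minutes on a single CPU while leaving the binomial checks
well-powered.
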