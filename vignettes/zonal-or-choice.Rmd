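---
title: "Zonal olfactory receptor choice: the model behind orzone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zonal olfactory receptor choice: the model behind orzone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orzone)
library(dplyr)
```

## The biological problem

Each mature olfactory sensory neuron (mOSN) of the mouse main olfactory
epithelium (MOE) stably expresses one allele of one olfactory receptor (OR)
gene out of a repertoire of more than a thousand, and the outcome is biased
by the neuron's position along the dorsoventral (DV) axis: the epithelium is
segmented into five zones, each expressing a characteristic OR repertoire.
Two graded, opposing processes can explain this topography. In neuronal
progenitors (INPs), many ORs are transcribed together at low level —
*polygenic transcription* — and the mixture is position-dependent: cells
transcribe ORs of their own zonal identity and of more dorsal identities.
As progenitors differentiate, *heterochromatic silencing* (H3K9me3/H3K79me3
marking and recruitment into interchromosomal "OR compartments") prunes the
mixture, acting most strongly on the ORs most dorsal relative to the cell.
Whatever survives both filters is the pool from which one OR is chosen.
`orzone` turns this verbal model into an explicit generative process and
implements the analyses used to interrogate it in real data: zonal
annotation, single-cell polygenic profiles, heterochromatin gene-body
gradients, zone-annotated Hi-C aggregation, single-cell 3D-structure
compartment calling, and spatial-spot zonal assignment.

## The generative model

For a cell of zone $z_c \in \{1..5\}$ (1 = dorsal-most) and a class II OR
gene $o$ of zonal identity $z_o$:

**Transcription (first rheostat).** The transcriptional propensity is
$a_0\, s(z_o)\, A$, where $s(z)$ is a positive, non-increasing promoter
strength profile over zones and $A$ is the zonal permission: $A = 1$ when
$z_o \le z_c$ and $A = \varepsilon$ (the *ectopic leak*, default 0)
otherwise. The OR is polygenically transcribed with probability
$1 - e^{-a_0 s(z_o) A}$. Class I ORs form a separate, zone-1-restricted
system: they are transcribable only in zone-1 cells, at strength
`class_i_strength`, and are never silenced. The model makes ventral
progenitors transcribe broader mixtures than dorsal ones for two reasons
that the data cannot currently separate — more identities are permitted
($z_o \le z_c$) and dorsal promoters are stronger — so both knobs ($s(z)$
and $\varepsilon$) are exposed rather than fixed by assumption.

**Silencing (second rheostat).** Each transcribed OR is silenced with
probability $\sigma(d)\cdot e^{-\text{propensity}/\theta}$, where
$d = z_c - z_o$ is the dorsal offset and

$$\sigma(d) = \sigma_{\text{own}} + (1-\sigma_{\text{own}})\,(1 - e^{-\lambda d}),
\qquad d \ge 0.$$

ORs of the cell's own identity are silenced at the floor
$\sigma_{\text{own}}$; more dorsal ORs approach certain silencing at rate
$\lambda$ per zone of offset. For $d < 0$ (reachable only through ectopic
leak or artificial induction) we extend the curve as
$\sigma_{\text{own}}\,e^{\lambda d}$: continuous and monotone at $d = 0$,
and consistent with heterochromatin on a given OR being lowest in cells
dorsal to its zone — which is what makes an induced dorsomedial allele
spread *dorsally* first when induction is weak.

**Choice.** A mature neuron chooses among the transcribed, unsilenced
survivors with probability proportional to propensity. If no OR survives,
the cell redraws transcription and silencing with fresh randomness (up to
`redraw_max` attempts; the redraw count is recorded per cell). This captures
the view that choice is a competition among recently activated alleles
rather than a global scan of the genome.

**Escape and induction.** The multiplicative escape term
$e^{-\text{propensity}/\theta}$ implements the idea that sufficiently strong
and early transcription protects an allele from silencing. The scale
$\theta$ is deliberately far above basal propensities (default
$2\times10^6$ versus $a_0 s \approx 0.02$), so escape is inert in normal
regulation and matters only for an artificially induced allele
(`induce_or()`, propensity multiplied by $1+\tau$ and permission forced
to 1). A first draft of the model used $\theta$ comparable to induced
propensities; that puts a floor $1 - e^{-p/\theta}$ under every survival
probability, which distorts the deep tail of the silencing curve: zones
differ enormously in competing survivor mass (zone 5 has few, weak ORs), so
a survival floor inverts the expected ordering of ectopic-choice
frequencies between zones 4 and 5 at weak induction. With $\theta$ large,
the weak-induction behavior is governed by $\sigma(d)$ alone and the
dorsal-to-ventral ordering is preserved; strong induction
($\tau \sim 10^9$) still drives escape and near-total choice dominance in
every zone.

**NFI knockout.** Triple NFI (NFIA/B/X) loss dorsalizes the ventral MOE.
The model implements it as an effective-zone clamp: cells with
$z_c \ge 2$ regulate class II ORs as if they were zone 2, for both the
transcription permission and the silencing offset. Ventral-identity ORs are
then never transcribed — and consequently never silenced, reproducing the
loss of heterochromatin and of long-range contacts on zone 3–5 ORs —
while zone-1 cells and class I ORs are untouched.

## Default parameters

| parameter | default | meaning |
|---|---|---|
| `n_class_i`, `n_per_zone` | 115; 261/283/164/144/44 | repertoire composition (the annotated mouse OR repertoire; 1011 genes) |
| `promoter_strength` $s(z)$ | 1, 0.8, 0.6, 0.45, 0.35 | dorsal-high promoter gradient |
| `class_i_strength` | 0.5 | class I propensity (zone-1 cells only) |
| `base_rate` $a_0$ | 0.02 | propensity scale; yields ~5 transcribed ORs in dorsal and ~15–20 in ventral INPs |
| `ectopic_leak` $\varepsilon$ | 0 | permission for ORs more ventral than the cell |
| `sil_own` $\sigma_{\text{own}}$ | 0.6 | silencing floor on own-zone ORs |
| `sil_shape` $\lambda$ | 4 | growth of silencing per zone of dorsal offset |
| `escape_scale` $\theta$ | 2e6 | propensity scale of silencing escape (inert without induction) |
| `chip_noise` | 0.03 | lognormal CV of emitted per-gene densities |
| `chosen_mean` / `basal_mean` | 200 / 0.2 | UMI means of the chosen OR and of non-chosen survivors in mOSNs |
| `hk_genes`, `hk_total` | 1500, 28000 | background transcriptome for QC realism |

$a_0$, $s(z)$, $\sigma_{\text{own}}$ and $\lambda$ were chosen together, by
analysis of the closed-form choice weights, so that (i) progenitor
repertoire breadth matches the observed 5–15 co-transcribed ORs, (ii) the
mature choice is zone-appropriate in ≥90% of cells in every zone (without
which no spatial or knockout direction can be reproduced), and (iii) the
$d = 1$ step of the silencing curve remains statistically identifiable from
emitted coverage densities. $\lambda = 4$ sits near the lower end of the
range compatible with (ii): the knockout's zone-2 dorsalization requires
$e^{-\lambda}$ small enough that leaked zone-1 ORs rarely survive in
effective-zone-2 cells. The density noise CV of 3% describes deep, merged
coverage tracks where the technical per-gene error of a gene-body mean is
small; real gene-to-gene biological variability is deliberately not part of
the emission model (see *Limitations*).

## What the generator emits, and what it does not emulate

All modalities derive from one latent tissue state (per-cell transcribed,
silenced and chosen sets), so cross-modal consistency is built in:

- **UMI counts** (`emit_sc_counts()`): Poisson draws; INPs express
  transcribed ORs proportionally to propensity, iOSNs only the survivors,
  mOSNs the chosen OR at high mean plus a low post-choice baseline;
  a fixed lognormal background transcriptome and mitochondrial genes give
  QC realism; `ambient` adds uniform noise.
- **Coverage** (`emit_chip_coverage()`): a gene's expected density is the
  model's *expected* silencing frequency for the tissue's cell composition,
  plus an additive background, times lognormal noise. Using the expectation
  rather than a finite-cell average is deliberate: it makes `noise = 0` an
  exactly noiseless emission (the gradient statistic is then exactly −1),
  and it reflects that a bulk ChIP track averages over vastly more cells
  than any simulated tissue.
- **Contacts** (`emit_hic_contacts()`): Poisson counts around
  `hic_gain · q_i q_j + hic_floor` for OR-bin pairs, where `q` is the
  bin-mean silencing probability (silenced ORs aggregate, so joint
  silencing drives contact frequency, independently per gene), plus a cis
  distance-decay background and sparse trans noise.
- **3D structures** (`emit_structure()`): tethered-random-walk chromosome
  territories placed far apart; the beads of silenced ORs (both
  haplotypes) are displaced to a small random number of nuclear attractor
  points — multi-chromosomal aggregates — while unsilenced ORs stay on
  their backbone. Geometry is in particle-radius units throughout; no
  physical distances are used in any computation.
- **Spatial spots** (`emit_spatial()`): grid rows map to the five DV bands;
  each spot pools 5–30 mature neurons of its band's zone, with a
  configurable probability of drawing from an adjacent band.

The generator does **not** emulate: batch effects or replicate structure;
doublets and empty droplets; enhancer-hub (multi-enhancer) assembly or the
OR-elicited feedback (choice is a single draw); allele-level haplotype
differences in regulation (silencing is drawn per gene, displacing both
haplotype beads); read-level artifacts (mappability, GC); or histology.
Consequently, passing tests demonstrate internal consistency of the
analysis chain and the qualitative directions of the modeled biology — not
robustness to the technical structure of real datasets.

## Numerical and design choices

- **Zone rounding.** Continuous zonal indices are discretized by
  nearest-integer rounding with halves rounded up (`floor(x + 0.5)`):
  deterministic, monotone, and exact on the boundaries.
- **Bin labels.** A genomic bin carries the label set of all overlapping
  ORs. The primary label is the majority label; ties break to the more
  dorsal numeric zone, with class I outranked by numeric zones on equal
  counts. The zone-pair contact aggregation uses the full label sets by
  default (`mode = "all_labels"`), so the primary-label tie-break never
  silently shapes the headline map; `mode = "primary"` is available for
  sensitivity analysis. Unobserved pixels count as zeros — at fixed
  sequencing depth an absent trans pair is informative.
- **Aggregate calling.** OR aggregates are connected components (size ≥ 2;
  a lone OR is not a compartment) of the proximity graph at 10 particle
  radii. Edges are interchromosomal by default: compartments are
  multi-chromosomal, and on any backbone-like geometry genomically adjacent
  cluster genes are trivially proximal, which would make every OR cluster an
  "aggregate". `include_cis = TRUE` restores the permissive variant. Loci
  map to their nearest bead by genomic position, per haplotype.
- **Gradient statistic.** The DV trend is a rank correlation (Spearman by
  default, Kendall switchable) of per-gene density against zone over class
  II ORs, with a seeded permutation null (10⁴ shuffles). Class I ORs are
  excluded: they form a separate near-background category, and including
  them would manufacture trend from a categorical offset. Constant densities
  give trend 0 rather than an undefined correlation.
- **Parameter recovery.** `fit_silencing_gradient()` fits
  $\text{density} = \text{gain}\cdot p_t(z_o)\,\sigma(d)\,e(z_o) + bg$ by
  Levenberg–Marquardt least squares *on the log scale* — the emission noise
  is multiplicative lognormal, so log residuals are homoskedastic and the
  small high-$d$ densities that carry the information about $\lambda$ are
  not drowned by the large ones. Transcription parameters are taken as
  known; gain, $\sigma_{\text{own}}$ and $\lambda$ are free.
- **Rank-sum test.** Exact two-sided p by full enumeration when the smaller
  group has ≤ 8 observations and there are no ties; otherwise the normal
  approximation with tie and continuity corrections. The exact branch is
  validated against full enumeration and the approximate branch against the
  reference implementation in base R.
- **Normalization conventions.** Coverage tracks are normalized to a
  library of 10⁷ reads before densities; contact matrices to counts per
  billion, counting off-diagonal pixels twice so the symmetric total is
  exactly 10⁹; cis display blocks are capped at 150 counts per 100 kb bin
  for color scaling only (the raw block is always returned). Spot
  normalization is `log1p` of median-depth-scaled counts — a simple,
  documented stand-in for variance-stabilizing transforms, whose internals
  are out of scope here.
- **Determinism.** Every stochastic step draws from a substream seed derived
  by hashing the base seed with a stage tag (zone, stage, modality, chunk),
  so a tissue is bit-identical for a given `(params, seed)` regardless of
  which zones or stages are simulated together. Within a (zone, stage)
  block, cells are drawn vectorized in fixed order; the substream
  granularity is the block, not the single cell, trading the finest-grained
  reproducibility contract for vectorized performance. The demonstration
  pipeline writes a manifest of md5 hashes and is hash-identical across
  reruns.

## Problem sizes

The test suite exercises the full default repertoire (1011 ORs) where the
claim depends on it: parameter recovery uses tissues of 2000 mature neurons
per zone; polygenic breadth 2000 progenitors per zone; 3D comparisons 48
dorsal + 48 ventral cells; spatial assignment a 20×10 grid over 400 cells
per zone; weak-induction choice frequencies 20,000–60,000 cells per zone
(the ventral frequencies are of order 10⁻⁴ and need the depth). Unit tests
run on a 54-gene repertoire with a proportionally raised `base_rate` (0.4)
so that latent states stay non-trivial at small scale. These sizes were
chosen as the smallest that leave comfortable Monte-Carlo margins on the
directional claims.

## Limitations

- The emission models are intentionally minimal; effect sizes (e.g. the
  ~4-fold zone-1/zone-5 contact ratio in ventral tissue) are properties of
  the chosen parameters, not calibrated estimates from real data, and no
  attempt is made to fit the rheostat model to published datasets.
- The coverage emission's expectation-based density means replicate-level
  biological variability between genes of the same zone is absent; the 3%
  noise default would be optimistic for shallow or single-replicate tracks,
  and parameter recovery should be read as "identifiable under the stated
  noise model", not as a field-ready estimator.
- Silencing is independent across genes given the cell's zone; real
  compartmentalization likely induces correlated silencing within clusters.
- Stage assignment from marker scores replaces graph-based clustering of
  real single-cell data; batch integration across replicate sections is not
  modeled.
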