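---
title: "Methods: delineating and classifying single-virion genophores from long-read length distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delineating and classifying single-virion genophores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Temperate phages and their parasites, the phage-inducible chromosomal
islands (PICIs), package DNA by a headful mechanism: a terminase complex
docks at a *pac* site on a concatemeric substrate, threads DNA into a
prohead, and cuts when the head is full. Because the cut position is set by
capsid capacity rather than sequence, the packaged molecules — we call each
one a *genophore*, the single DNA molecule inside one virion — are
terminally redundant and circularly permuted. PICIs additionally remodel
the helper phage's capsid into a small-headed form whose capacity is roughly
37% of the normal head, sized to one island genome plus terminal redundancy.

Long-read sequencing of DNase-protected virion DNA reads out genophores as
single molecules, so the *length* of a read identifies the capsid it came
from, and its *alignment* identifies what was packaged: helper phage, PICI
(as monomers in small heads or multimers in normal heads), plasmid,
chromosomal DNA acquired by lateral transduction, or hybrids of element and
host DNA. `virionseq` implements this analysis end to end, together with a
generative simulator that produces labelled synthetic datasets with the same
statistical structure, so every stage is testable without external data.

## Genophore delineation by circular binary segmentation

Read lengths are binned into a `length_signal` (zero-count bins included;
the bin is the CBS "marker"). `cbs_segment()` recursively splits the bin
axis: at each step an exhaustive scan finds the arc `(i, j]` maximising the
standardised mean difference between the arc and its complement,

$$ Z_{ij} = \frac{|S_j - S_i - k\,\bar{x}\,|}{\sqrt{k\,(n-k)}}, \qquad
   k = j - i, $$

which under within-segment permutation is a monotone transform of the
two-sample *t* statistic (the total sum and sum of squares are permutation
invariant), so the permutation *p*-value is identical to that of max-|t|.
A split is accepted when its permutation *p*-value over `nperm` shuffles is
below `alpha` and both resulting pieces hold at least `min_width` markers;
accepted splits are recursed into, and a final pass merges adjacent
segments whose difference a two-sample permutation test does not support.
Defaults are `alpha = 0.01`, `min_width = 2`, `nperm = 10000`, with an
explicit permutation seed (default 1) for reproducibility. Ties in the scan
are broken leftmost; an arc and its complement carry the same statistic and
imply the same cuts.

The capsid-specific length range is then the *peak*: the maximal run of
contiguous segments, containing the highest-mean segment inside the search
window (defaults: 10–25 kb for small, 25–50 kb for normal capsids), whose
means all reach `min_mean`. If nothing in the window reaches `min_mean`,
the span of the single highest-mean segment is used — the usual situation
for normal capsids in heavily fragmented induction samples. When even that
fails, reads of 25–46 kb (inclusive) are taken as normal-capsid genophores:
the window sits above any small-capsid molecule, and longer reads (chimeras
or basecalling artifacts) are excluded.

Two resolution conventions matter:

* **Bin width.** `min_width = 2` is meaningful on a dense axis, so the
  marker default is 1-nt bins. The pipeline and the shipped analyses run at
  100-nt bins, which keeps the permutation scan at `nperm = 10000` within
  minutes on a single core without affecting medians; the bin width used is
  recorded in every report.
* **`min_mean` scaling.** The peak rule's threshold of 2 is defined per
  1-nt marker. Per-bin counts scale with bin width, so the pipeline applies
  `min_mean_per_nt * bin_width` (200 at 100-nt bins). Without this the
  fragment background itself clears the threshold and the "peak" swallows
  the whole axis.

## The ambiguity (background) model

Fragmented DNA forms a length continuum under the genophore peaks, so some
reads inside the small-capsid range are fragments of normal-capsid
genophores with an ambiguous particle-type origin; they cannot be
individually identified, only counted. `fit_background()` fits
$c(x) = a e^{b x}$ by least squares to the binned counts between 1 and
40 kb, excluding the small-capsid range, and `ambiguous_fraction()` reports
the fitted mass inside the range over the observed count, clipped to [0, 1].

The delineated range clips the peak near its inflection points, so the
peak's own tails would otherwise sit in the fit window immediately beside
the evaluation interval and inflate the background several-fold; the
excluded interval is therefore padded by 1.5 range-widths per side
(extending a ±1σ range to roughly ±4σ). With this correction the estimator
is calibrated to within ~20% on mixtures drawn from its own model class
(exponential background plus Gaussian peak). Under the full fragmentation
simulator the background is a mixture of uniform piece lengths, not an
exponential, and the estimate is only order-of-magnitude accurate — the
test suite therefore checks calibration on matched mixtures and only the
monotone response to fragmentation intensity on simulated scenarios. The
sign of `b` is left free; decay is expected but not enforced.

## Origin classification

Reads are classified from alignments (PAF or SAM) or, for error-free
synthetic reads, from the built-in exact seed-and-extend tiler
(`align_exact()`), which doubles circular references so circularly permuted
molecules tile contiguously and searches both strands. Per read, merged hit
intervals give the fraction covered by each reference category:

* a read is `hybrid_lateral` when a mobile element and the chromosome each
  cover at least `min_component` (default 0.2) and the chromosomal interval
  abuts the element's integration site (`attB`, tolerance 100 nt);
* otherwise the single category covering at least `min_primary` (default
  0.8) is assigned; anything else is `ambiguous`.

Unit copies are the total aligned length attributable to the unit divided
by the unit length — exactly 3.0 for a tandem trimer, ~1.07–1.12 for a
small-capsid island genophore. Terminal redundancy is the fractional part
of the copy number. Packaging-initiation jitter is summarised by
`pac_offset_stats()`; note that only *first* headfuls carry the initiation
jitter around *pac* — later headfuls in a series are circularly permuted by
construction — so recovering the jitter SD requires single-headful
initiations (the simulator's `max_headfuls = 1`), which is how the package
validates it.

Two packaging signatures are detected on coverage tracks:

* **Capsid switch.** Normal-capsid genophores start either at *pac* or one
  small-capacity downstream (after a small headful), producing a step up in
  the coverage of *normal-capsid reads* at `pac + small_capacity`. Pooled
  coverage of all capsids is flat — a complete series tiles the concatemer —
  so the detector must be fed the normal-capsid track. The step is called
  when the downstream/upstream mean ratio exceeds 1.05 (without switching
  the ratio stays within ~1% of unity; with `p_small = 0.5` it is typically
  1.08–1.18) and located by a single change-point scan of the binned track.
* **Lateral gradient.** In-situ packaging from an integrated element's
  *pac* site carries flanking host DNA with a frequency that decays with
  distance; `lateral_gradient()` reports binned downstream coverage and a
  Spearman trend statistic.

## The simulator as the study conditions

`scenario_preset()` fixes one parameter bundle per experimental system.
Unit genomes are 44.2 kb (phage E72m5), 42.5 kb (phage 48) and 14.8 kb
(island); capacities are 45.3/16.5 kb (E72m5 systems) and 43.8/15.9 kb
(phage 48), i.e. ~103% of the phage unit and ~37% of it for small heads.
Values the source experiments do not pin down were chosen once as
realistic defaults and are config-exposed, not tuned: initiation jitter
Normal(0, 300 nt); capacity CV 0.02 (normal) and 0.04 (small); capsid
re-draw probability 0.3 between consecutive headfuls; packaging series of
2–12 headfuls (uniform), following the behaviour reported for *pac*-type
phages; fragmentation as Poisson breaks per nt (2×10⁻⁶ for infection
lysates up to 10⁻⁵ for mitomycin-like induction, giving the observed
low/high fragment background); eight-unit concatemers; a 0.8-Mb synthetic
host backbone — long enough for 2–12-headful lateral series, small enough
for test-time alignment — with the prophage and the island integrated
~200 kb apart, packaging toward each other. Sequences are i.i.d. uniform
nucleotides from the seeded generator; every emitted dataset is
byte-identical given config and seed.

Truth labels call a read `hybrid` when element- and host-derived content
each make up at least 20% of it, matching the classifier's operational
definition; marginal flanks go to the dominant category. Fragment pieces
are re-labelled from the interval they actually cover.

What the simulator does *not* emulate — basecalling errors, quality-score
realism, chimeric sequencing artifacts, and the ONT length bias that
over-samples small genophores — bounds what green tests mean: they show the
analysis recovers the generative structure it assumes, not that it is
robust to real-data noise (real reads must be aligned externally, e.g. with
minimap2, and enter via PAF/SAM).

## Statistics and synergy models

Cliff's delta is computed by a sorted-merge equivalent of the full pairwise
comparison (tested against O(nm) brute force). Group comparisons follow the
data type: pairwise Welch *t*-tests for abundance fractions; Welch ANOVA on
log10 counts with Games–Howell pairwise comparisons (per-group variances,
Welch–Satterthwaite df, studentized-range reference) for virion and
viable-cell counts, with an optional, logged 1.5×IQR outlier exclusion (off
by default — the choice of rule is ours); Kruskal–Wallis with Dunn rank
*z*-tests (tie-corrected, Holm-adjusted) for zero-inflated transduction
counts, after substituting values below 10 TFU/ml by 10/√2. A
compact-letter display summarises pairwise significance at p < .05.

Phage–antibiotic interaction grids (percent response, viability convention)
are scored against four null models on the inhibition scale
`y = 1 − response/100`: Bliss `y_A + y_B − y_A y_B`; HSA `max(y_A, y_B)`;
Loewe by dose equivalence on 4-parameter log-logistic monotherapy curves
fitted with bounded nonlinear least squares (0–100 asymptotes), solving
`d1/D_A(E) + d2/D_B(E) = 1` per cell; and a ZIP-style score using the Bliss
expectation on the fitted (potency-shifted) curves — a simplification of
the published ZIP formulation that differs in its smoothing details. The
overall score is the mean observed-minus-expected excess × 100; positive
means synergy. With fewer than 4 dose levels per agent the curve-based
models are reported unavailable while Bliss and HSA remain.

## Numerical and design choices

* Coordinates are 0-based half-open internally and 1-based inclusive in all
  emitted files (GenBank convention).
* Permutation tests stop early once the exceedance count proves
  p ≥ alpha; the p-value is `(count + 1) / (nperm + 1)`.
* The 25–46 kb fallback window and all range selections use inclusive
  endpoints.
* Hybrids can be folded into the chromosomal category
  (`fold_hybrid_into_chromosome`) for reports that do not separate them.
* Copy shares (percent of genome copies as coverage of one reference over
  the summed coverage of all references) default to per-replicate
  computation then averaging; pooled mode is available.
* FASTQ output is written directly as four-line records because the
  installed Biostrings FASTQ writer assumes short-read line lengths;
  reading uses `readDNAStringSet(format = "fastq")` unchanged.
* Reported problem sizes: the shipped analyses and the acceptance script
  run ~5000 intact reads per capsid for length work (lengths only, no
  sequences), ~2500–5500 sequenced reads for classification, 600 series for
  the switch signature, and 2000 initiations for the lateral gradient.

## Known limitations

The ambiguity estimator inherits the exponential-background assumption;
when the true background is not exponential the fraction is indicative
only. The exact tiler requires error-free reads and is not an aligner. The
relative abundance of small versus normal particles is not estimable from
read counts (length-dependent sequencing and fragmentation bias); the
simulator's truth labels stand in for the orthogonal instrument
quantification used experimentally. Statistical testing of genophore length
ranges is deliberately limited to effect sizes (median differences and
Cliff's delta): at these sample sizes even negligible differences are
formally significant.

## A worked example

```r
library(virionseq)

cfg <- scenario_preset("infection_E72m5",
                       n_series_phage = 150, n_series_pici = 120,
                       n_lateral = 40, n_plasmid = 3)
ds <- emit_dataset(cfg, seed = 21, with_sequences = FALSE)

sig  <- length_signal(ds$reads$length, bin_width = 100,
                      range = c(1000, 60000))
segs <- cbs_segment(sig, cbs_params(nperm = 2000))
small  <- delineate_range(segs, c(10000, 25000), ds$reads,
                          min_mean = 200, capsid = "small")
normal <- delineate_range(segs, c(25000, 50000), ds$reads,
                          min_mean = 200, capsid = "normal")
small; normal

fit <- fit_background(sig, small)
obs <- sum(ds$reads$length >= small$min_length &
           ds$reads$length <= small$max_length)
ambiguous_fraction(fit, small, obs)$fraction
```
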