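---
title: "Paired primary-recurrent tumor profiling with MeD-seq and TLDA microRNA cards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired primary-recurrent tumor profiling with MeD-seq and TLDA microRNA cards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medmir)
```

## The scientific setting

Well-differentiated liposarcoma (WDLPS) recurs locally in roughly a third
of patients, and whether the recurrent tumor differs molecularly from its
primary is an open question. The natural design is a paired one: for each
patient, profile the primary tumor and its first recurrence, and ask
whether any methylation regions or microRNAs shift consistently across
pairs. This package implements that paired analysis for two platforms:

* **MeD-seq** — genome-wide CpG methylation read-out through the
  methylation-dependent restriction enzyme LpnPI. The enzyme cuts near
  methylated CpG-containing sites, producing short fragments whose
  recognition site sits a characteristic 13-17 bp from a fragment end;
  read counts at a site are therefore a proxy for its methylation.
* **TLDA cards** — microfluidic qPCR arrays reporting one Ct value per
  microRNA per sample.

Because matched patient cohorts of this kind are controlled-access, the
package ships a synthetic-data module that generates every input — genome,
annotation, methylomes, reads, Ct matrices, clinical tables — together with
a truth record, so the whole pipeline is testable offline.

## MeD-seq processing

### Positional read filter

A genuine MeD-seq fragment carries the recognition motif near one end, so
reads are retained only when the motif occurs at a 1-based offset of 13-17
(inclusive) from either end (`filter_reads()`). The distance convention is
symmetric: from the 5' side the motif's *first* base is measured, from the
3' side its *last* base. The protocol fixes only the 13-17 bp distance
from either end, not which base of the motif anchors it; the symmetric
reading is a documented choice, and the window is a parameter. Reads
shorter than `window_max + nchar(motif)` are discarded and counted.
`N` never matches the motif. The recognition motif is modeled as the CpG
dinucleotide — the methylation-dependent core of the LpnPI site — and is
configurable; the full degenerate enzyme context is deliberately not
modeled.

### Site assignment

`assign_sites()` matches retained reads exactly (both strands) against the
reference and increments the CpG site at the read's in-window motif offset.
Three classes of reads are dropped deterministically and counted:
multi-mapping reads, unmatched reads, and reads carrying *two*
window-positioned motifs (one per end) — for those the true restriction
site cannot be told from the decoy, so assignment would be a coin flip.
Externally aligned data enter through `load_alignments()` (text SAM or
BED), which applies the same offset rule per record.

### Region scoring and DMR calling

`build_regions()` materializes the three scored region classes: TSS
regions (1 kb before to 1 kb after the start, half-open, clipped at contig
edges), gene bodies (1 kb past the TSS, strand-aware, to the TES; genes
with the TES within 1 kb of the TSS yield none), and CpG islands.
`count_regions()` sums site counts per region; a site inside two
overlapping regions counts fully in both, because the three classes are
scored independently.

The group comparison is a pooled Pearson chi-square on read counts
(`chi2_counts_test()`): counts are summed within each group, and each
region (or site) is tested as a 2x2 table of count versus remaining
library total, 1 df, no continuity correction. Fold changes carry a +1
pseudocount in the counts so empty regions give finite,
direction-preserving ratios. P-values are adjusted across all tested units
by Benjamini-Hochberg (default) or Bonferroni.

`sliding_window_dmrs()` runs the same test per CpG site and bins
neighboring significant sites that share a direction (hyper/hypo in the
recurrent group) into maximal runs, allowing at most `max_gap` intervening
non-significant sites; an opposite-direction significant site always ends
a run. Each bin spans first to last significant site, reports the number
of significant member sites, a span-pooled fold change and chi-square, and
the best member site's raw/adjusted p (which keeps the adjusted value at
or above the raw one). Bins are then filtered on `min_sites` (default 4),
`min_size_bp` (default 100) and `min_fc` (default 1.5, inclusive, either
direction); a fold-change cut-off of 2 is the conventional stricter preset
for subgroup re-analyses whose call sets would otherwise swamp a
clustering. The defaults are package choices and all are exposed.

**Assumption to be aware of:** pooling counts within groups treats each
group as one library and ignores sample-to-sample (biological)
dispersion. The chi-square is exact for binomial sampling only; extra
per-sample variance inflates the statistic. The simulator's default noise
concentration (200, i.e. per-sample per-site sd about 0.03 at level 0.3)
represents technical-scale variation, under which the test is close to
nominal (measured type-I fraction about 0.05-0.06 at alpha 0.05). With
realistically heterogeneous tumors the pooled test becomes
anticonservative — an inherent limitation of pooled count testing; no
beta-binomial extension is attempted. Copy-number changes are likewise
indistinguishable from methylation changes in MeD-seq counts and are not
corrected for.

## MicroRNA processing

`normalize_ct()` censors entries above the detectability cut-off (Ct 35 by
default, the usual TLDA convention for calling a well detectable) and
expresses every value relative to the sample's median Ct over detectable
microRNAs: `-(Ct - median)`, which under qPCR doubling
chemistry is already log2 relative expression. `detection_filter()` keeps
microRNAs detected in at least 50% of *all* samples (boundary inclusive).
Missing values are never imputed.

`batch_adjust()` defaults to a deterministic per-microRNA location-scale
harmonization (each batch is centered and scaled to the microRNA's overall
mean and sd); an empirical-Bayes ComBat mode (via the sva package) is
available for complete-case rows. Because both samples of a pair always
share a batch, additive batch effects cancel in the paired differences
either way; the adjustment mainly matters for clustering. Sample exclusion
after quality review is an explicit list (`exclude_samples()`, which also
removes the pair mate), not an automated rule.

`paired_de()` tests each microRNA with a paired t-test over
pairwise-complete pairs (at least 5 by default), with BH q-values over the
tested set and significance at the dual threshold p < 0.05 *and*
q < 0.25. Degenerate difference vectors are handled by convention: zero
variance with nonzero mean reports p = 0 (flagged), all-zero differences
report p = 1 (flagged).

One property worth knowing: median normalization assumes differential
expression is roughly balanced. If many microRNAs shift in the *same*
direction, the per-sample median absorbs part of the shift and every null
microRNA inherits a small opposite bias — in simulation this pushes the
observed false-discovery proportion above the BH-controlled level. The
synthetic generator therefore plants mixed-direction effects by default,
which is also what real tumor comparisons look like.

## Clustering and pair cohesion

`hierarchical_cluster()` uses 1 minus Pearson correlation over
pairwise-complete features (the convention of classic expression
clustering tools) or completeness-rescaled Euclidean distance, with
average linkage by default; agglomeration is `stats::hclust`, which
resolves ties deterministically. Supervised clustering is the same
procedure restricted to a supplied feature list (e.g. the significant
microRNAs or DMRs). Pair cohesion is operationalized strictly: a pair
clusters together when its two samples are merged *directly with each
other* — direct siblings at their first merge (`pair_cohesion()`). Looser
readings (same subtree at some height) exist; the sibling definition is
the one every reported count uses.

## Cohort statistics

`summarize_cohort()` reports medians and interquartile ranges with the
(n + 1)-based "exclusive" quantile (`cohort_quantile()`, `stats::quantile`
type 6). With the packaged 27-pair reference table this convention gives
age 50-64 and time to recurrence 1.9-6.5 years — the values clinical
reports print — where the default type-7 interpolation gives 1.95-6.3;
both are selectable.
Localization is classed as extremity (upper/lower leg), retroperitoneum,
or other (axilla, mediastinum, esophagus, trunk). Margin codes follow the
four-level R classification (R0/R1/R2/Rx), counted separately for the
primary and the recurrent resection.

## What the synthetic data do and do not emulate

The generator reproduces the features the pipeline is sensitive to:
planted CpG sites at a controlled density with locally enriched islands
(the total expected CpG count stays at `cpg_density * length`), Beta-mixed
baseline methylomes shared across samples, per-sample Beta noise, planted
DMR intervals defined over runs of real CpG sites, Poisson read depth
proportional to methylation, 50 bp reads with the site placed in the
13-17 bp window (a random 5% of reads are off-motif background to exercise
the filter), three-batch Ct matrices with per-pair random effects and
censoring, and internally consistent clinical tables.

It does not emulate: sequencing errors or quality variation, adapter
ligation and trimming, the enzyme's real cut-site chemistry, mappability
structure of a real genome, copy-number variation, or missing-not-at-
random dropout beyond high-Ct censoring. Passing tests therefore validate
the statistical machinery and the bookkeeping, not robustness to
real-data artifacts.

Problem sizes used by the test suite and the acceptance script are chosen
to make Monte-Carlo error small while keeping runs quick: null
calibrations use 1000+ features; DMR recovery uses ten planted windows of
20 sites at mean depth 30 (and a binning gap tolerance of 1, because an
occasional near-zero-baseline site inside a window otherwise splits the
run); the observed false-discovery rate of the microRNA arm is estimated
as the mean false-discovery proportion over 100-150 replicates, since FDR
is an expectation and a single replicate with 30 true effects estimates it
with sd near 0.1.

## Numerical conventions

Coordinates are 0-based half-open internally; BED output is 0-based
half-open, FASTA/SAM/GTF are 1-based on write. Chi-square tables with an
empty count margin score 0 with p = 1. Fold changes use the +1 pseudocount
and are recurrent over primary; direction is hyper for fold > 1 (a fold of
exactly 1 cannot be significant and needs no direction). The fold-change
threshold is inclusive. All generators are pure functions of their
configuration and seed, and every pipeline output writer is byte-stable,
which the determinism checks assert end to end.
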