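---
title: "Spatial organization and splicing of intron classes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial organization and splicing of intron classes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronSpace)
```

## The scientific problem

Human introns fall on a classification continuum of six classes — major,
major-like, hybrid, minor-like, minor, and non-canonical — defined by how
closely their splice-site and branch-point motifs resemble the U2-type
(major spliceosome) versus U12-type (minor spliceosome) consensus. The rare
classes are five hundred to a thousand times less abundant than major
introns, raising two linked questions: are rare introns organized
non-randomly within the 3D genome (Hi-C compartments and subcompartments,
speckle-associated domains, lamina-associated domains), and does that
spatial position predict how efficiently they are spliced?

`intronSpace` implements the full analysis as reusable, tested components:

1. **Catalog statistics** — inter-intron distances, the abundance–distance
   log-log fit, fixed-width density bins with a cluster scan.
2. **Spatial membership** — a fractional-overlap rule assigning introns to
   feature tracks, with class-vs-baseline Fisher enrichment.
3. **Resampling nulls** — matched-size bootstrap and fractional-substitution
   ("pollution") constructions.
4. **Gene context** — expression- and essentiality-stratified enrichment.
5. **Splicing indices** — junction-read evidence and the intron-retention /
   exon-skipping indices, with rank-based group comparisons.
6. **Synthetic data** — a seeded generator that emulates every input with
   known ground truth.
7. **Orchestration** — `run_full_analysis()` drives all stages from one
   configuration. The package is driven from R: the exported functions and
   this orchestrator are the command surface, so no shell executables are
   shipped.

## Coordinates and membership semantics

All coordinates are 0-based half-open internally (BED convention); 1-based
inclusive TSV input is converted on load. An intron belongs to a feature
track when its overlap with some **single merged interval** of the track is
at least half the intron's length (inclusive threshold, configurable via
`min_overlap_frac`). Intervals of a track are merged before the test so
that fragmentation of the source file cannot change results. Within each
mutually exclusive partition (compartment A/B, subcompartments A1–B3,
nuclear bodies SPAD/LAD, 3D features), an intron passing the threshold for
two categories is resolved to the larger overlap; the only possible exact
tie is a 50/50 split, which is assigned to "neither" with a warning.
Introns passing no category are "neither" — whether that reflects absence
from the annotation or sub-threshold overlap is intentionally not
distinguished.

Inter-intron distance is the genomic gap `next.start − current.end` between
consecutive same-class introns on one chromosome, with negative gaps
(overlapping isoform introns) clamped to zero and retained; dropping such
pairs would bias medians downward for dense classes. Strand is ignored —
the quantity is genomic, not transcriptional, spacing. Gap distance (rather
than start-to-start) is used because it reproduces the ~exon-length median
expected for the dense major class.

The density cluster scan tests each 250 kb bin count against the
genome-wide class rate with an upper-tail Poisson test and
Benjamini–Hochberg adjustment across bins within class (default FDR 0.05).
The source analysis reports "statistically significant" clusters without
naming a test; Poisson/BH is this package's choice, made once, and exposed
via the `fdr` argument.

## Enrichment testing

Every enrichment is a two-sided Fisher exact test on the 2×2 table
(in/out of feature × focal/baseline class), with the abundant major class
as the default baseline. The p-value comes from the exact conditional
(hypergeometric) distribution via `stats::fisher.test`; the odds ratio
reported is the **sample (cross-product) OR**, not the conditional MLE, so
that the point estimate is the familiar ratio of observed odds. Bonferroni
adjustment multiplies by an explicit `family_size`, which is always a
caller decision and is recorded in every result: the appropriate family is
panel-dependent (the default convention is *rare classes tested ×
categories in the partition*). Tables with an empty class margin are
flagged `untestable` rather than erroring, mirroring sparse rare-class
cells in real data.

## Resampling nulls

The **bootstrap null** draws `n_boot` (default 1000) random sets of
`sample_size` baseline introns — e.g. 850 major introns, matched to the
minor-class count — without replacement within a replicate, and records the
in-feature proportion of each set. Its median estimates what any same-sized
major subset would show; a focal class whose observed proportion sits in
the far tail is enriched beyond gene-sampling effects. The observed
proportion's two-sided empirical tail uses the `(b + 1) / (n_boot + 1)`
correction.

The **pollution curve** replaces a fraction *f* of each set with focal
introns (`n_focal = round(f × n)`, ties-to-even; the baseline complement is
`n − n_focal` so every set has exactly *n* members and *f* = 1 reproduces
the focal class verbatim). The Pearson correlation of proportion with *f*
over all replicate points quantifies whether enrichment tracks class
identity.

Reproducibility: one master seed spawns deterministic per-replicate
substreams, so enlarging `n_boot` extends the replicate sequence without
reshuffling earlier draws, and identical seeds give bit-identical
distributions.

## Splicing indices

Junction evidence is extracted from coordinate-sorted alignments
(secondary, supplementary and duplicate records always excluded; a
mapping-quality floor, default MAPQ ≥ 1, removes multi-mapper records).
Per intron:

* `n5`, `n3` — reads contiguously aligned across the 5′/3′ boundary with at
  least `min_anchor` (default 2) aligned bases on each side. The classical
  one-nucleotide-overhang exclusion is extended from spliced to boundary
  reads for symmetry; both are configurable.
* `n_spliced` — gapped reads whose skip matches the intron exactly.
* `n_skip` — gapped reads whose skip contains the intron plus at least one
  whole annotated flanking exon. Whether the skipped exon must be
  constitutive is not constrained — any annotated flanking exon counts.
* `n_cryptic` — gapped reads using a non-annotated splice site within or at
  one edge of the intron.

The indices are

\[
SI_{RET} = 100 \cdot \frac{B}{B + n_{spliced}}, \quad
B = \tfrac{1}{2}(n_5 + n_3); \qquad
SI_{ES} = 100 \cdot \frac{n_{skip}}{n_{skip} + n_{spliced}}.
\]

Any cryptic evidence (`n_cryptic > 0`) **voids the boundary reads as
retention support** (B is set to 0): boundary coverage cannot then be
distinguished from a cryptic isoform. An intron with a zero denominator is
undefined and dropped downstream with a recorded reason. Replicates of one
cell line are pooled (counts summed) before index computation by default; a
per-replicate-then-average mode exists and coincides exactly with pooling
when there is a single replicate.

Analysis filters: parent gene expressed at ≥ 1 TPM (replicate mean,
inclusive), at least one supporting read, optionally only introns with
reads supporting **both** retention and canonical splicing, and seeded
subsampling of the two abundant classes to 5,000 records each. Two-group
comparisons use the Mann–Whitney U test — exact by enumeration over group
assignments for total n ≤ 20 (which handles ties correctly, where the
base-R exact path refuses), normal approximation otherwise. Multi-group
comparisons use Kruskal–Wallis followed by all-pairs Dunn z tests (tie
corrected, implemented in-package) with Benjamini–Hochberg adjustment.

Cross-cell-line analyses intersect introns sharing a nuclear-body location
across cell lines, compare the shared sets' indices between lines, and
define "improved splicing" as a strictly lower per-intron `SI_RET` in the
comparison line — no minimum effect size, since none is prescribed — with
deduplicated parent-gene lists exported for external GO tooling.

## The synthetic generator and what it does (not) emulate

`synthetic_config("calibrated")` encodes the published real-data proportions as
generative placement probabilities: compartment-A rates 0.62 (major) and
0.71 (minor), SPAD rates 0.21/0.25, LAD rates 0.19/0.14, and analogous
rates for the other classes. Class counts keep the real abundance ordering
at desk scale — 10,000 major, 2,000 major-like, 600 non-canonical, 850
minor, 120 minor-like, 100 hybrid — with the minor class pinned at its real
catalog size (850) so the matched bootstrap construction is exercised at
its published sample size; a `scale` multiplier enlarges everything
proportionally when more power is wanted. Each rare intron is placed in its
own gene (the remaining introns major), matching the observation that
rare-intron genes usually carry exactly one.

Feature tracks are built so the 50%-overlap rule recovers the drawn
membership exactly (each member intron's own interval is emitted into the
track); compartment/SPAD concordance can be imposed via `spad_in_A`, with
infeasible nesting rejected. Alignments are emitted read-by-read —
boundary, spliced, skip and cryptic reads with correct gapped CIGARs — so
the SAM/BAM parsing path is genuinely exercised, and the extractor recovers
exactly the counts written (the randomness is upstream of emission).
Junction depth defaults to 100; per-intron retention ψ and skipping σ draw
from per-class Beta distributions (concentration 30) unless supplied
explicitly.

What the generator does **not** emulate: nucleotide sequence (no splice-site
motifs, no mappability structure), multi-mapping reads, overlapping genes
and alternative isoforms, chromosome-scale spatial autocorrelation of
compartments, and the gene-level confounding between class, expression and
essentiality that motivates the bootstrap in real data (memberships are
drawn independently per intron). Passing tests therefore demonstrate
correctness of the statistical machinery and file round-trips under known
truth — not that real data meet the generator's independence assumptions.

Expression tables draw 75% of genes expressed with means comfortably above
1 TPM and the rest below, jittered log-normally across two replicates;
truth flags are re-derived from the emitted replicate means so files and
truth cannot disagree. Essentialome lists use an elevated rate for
rare-intron genes and a depleted rate for non-canonical-intron genes.

## Numerical choices and degenerate inputs

* Fractional-overlap threshold inclusive (≥), evaluated per merged interval.
* `round()` ties-to-even for substitution counts, logged per fraction.
* A class with fewer than two same-chromosome introns yields an empty
  distance summary (`n_pairs = 0`), not an error.
* The abundance–distance fit accepts two classes (R² is then exactly 1);
  zero or negative counts/medians are a domain error since log10 is
  undefined.
* Identical values across comparison groups follow the p = 1 paths without
  division errors; groups below two observations are reported untestable.
* Bootstrap/pollution draws are without replacement, so `sample_size`
  above the class size is an error, and degenerate memberships (all in /
  all out) propagate exactly.

## Problem sizes used by the test suite

The packaged checks run the calibrated preset at scale 1 (13,670 introns)
for resampling calibration, scale 3 (41,010 introns) for the end-to-end
directional pattern, and 900 introns at junction depth 200 for
splicing-index parameter recovery (median within 2 percentage points of
100ψ per stratum). These sizes were chosen as the smallest at which the
binomial/Poisson noise floors sit well inside the assertions' tolerances.

## Known limitations

* The Bonferroni family per panel is a convention, not a recovered fact;
  all results carry their family size explicitly.
* The Poisson/BH cluster scan is a stand-in for an unnamed published test.
* The exact published splicing-index formulas live in supplementary
  material of the source analysis; the implemented defaults (mean-boundary
  retention index, skip-fraction index) follow the main-text definitions
  and are configurable at the evidence level.
* With real data the pipeline consumes annotations (compartment calls,
  SPAD/LAD tracks, TPM tables) as given; it neither calls 3D features from
  contact matrices nor quantifies expression from reads.
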