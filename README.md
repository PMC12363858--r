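# intronSpace

Tools for asking where the six classes of the human intron-classification
continuum — **major, major-like, hybrid, minor-like, minor, non-canonical**
— sit within the 3D genome, and whether that position predicts how
efficiently they are spliced.

Minor (U12-type) introns number only ~850 against ~345,000 major introns,
yet their splicing is rate-limiting for the genes that carry them. The
package implements the complete analysis around that question:

* **Linear-genome statistics.** Inter-intron distances per class, the
  log–log abundance–distance fit (Pearson r on
  (log₁₀ count, log₁₀ median distance) pairs, reported as R²), and 250 kb
  density bins with an upper-tail Poisson cluster scan (BH-adjusted within
  class).
* **Spatial membership and enrichment.** An intron belongs to a 3D feature
  (compartment A/B, subcompartment A1–B3, SPAD, LAD, TAD, boundary, loop
  anchor) when ≥ 50 % of it overlaps a single merged track interval.
  Class-vs-major enrichment uses the two-sided Fisher exact test with an
  explicit Bonferroni family.
* **Resampling nulls.** A matched-size bootstrap (e.g. 1,000 random sets of
  850 major introns) and a pollution analysis that substitutes an
  increasing fraction *f* of minor for major introns; enrichment that rises
  with *f* (Pearson r over all replicate points) is tethered to intron
  identity, not set size.
* **Gene context.** Expression-stratified (TPM ≥ 1 or ≥ 20, replicate
  means) and essentiality-stratified enrichment against total/core
  essentialome gene sets.
* **Splicing indices.** From spliced alignments, per-intron junction
  evidence (boundary reads `n5`/`n3`, exact spliced reads, exon-skipping
  reads, cryptic-splice reads) and the indices
  `SI_RET = 100·B/(B + n_spliced)` with `B = (n5 + n3)/2` (cryptic evidence
  voids boundary support) and `SI_ES = 100·n_skip/(n_skip + n_spliced)`,
  compared across classes, locations and cell lines with
  Mann–Whitney / Kruskal–Wallis + Dunn (BH).
* **Synthetic studies.** A seeded generator emitting catalog BED, gene-model
  GTF, feature-track BEDs, replicate TPM tables and spliced-read SAM files
  with known ground truth, calibrated so its placement probabilities equal
  the published real-data proportions.

## Worked example

A self-contained study at a tenth of the calibrated scale:

```r
library(intronSpace)

cfg   <- synthetic_config("calibrated", scale = 0.1, depth = 60)
study <- simulate_study(cfg, tempfile("study"), seed = 42)
catalog <- study$annotation$catalog
catalog
#> intron_catalog: 1367 introns on 4 chromosomes ( synthetic:calibrated )
#>         major    major_like        hybrid    minor_like         minor non_canonical
#>          1000           200            10            12            85            60

m  <- assign_membership(catalog, study$cell_lines$SYN1$tracks)
enrichment_fisher(m, catalog, "minor", "major",
                  partition = "compartment", category = "A", family_size = 6)
#> enrichment [compartment:A]: minor 71.8% vs major 60.4%  OR=1.67  p=0.0481  p_adj=0.288 (family 6)

bs <- bootstrap_null(m, catalog, "major", partition = "compartment",
                     category = "A", sample_size = 85, n_boot = 1000,
                     seed = 42, focal_class = "minor")
sprintf("bootstrap median %.3f; observed minor %.3f; two-sided tail %.3f",
        bs$median, bs$observed_focal, bs$percentile_of_observed)
#> "bootstrap median 0.600; observed minor 0.718; two-sided tail 0.050"

ev  <- extract_junction_evidence(study$cell_lines$SYN1$sam, catalog,
                                 load_gene_models(study$paths$gene_models))
rec <- splicing_index_records(ev, catalog, expr = study$cell_lines$SYN1$expr,
                              matrix = m)
rec <- filter_for_analysis(rec, subsample = c())
cmp <- compare_distributions(rec[rec$location == "SPAD", ], "intron_class")
cmp$groups
#>                       group   n    median
#> major                 major 143  4.347826
#> major_like       major_like  42 13.867521
#> minor_like       minor_like   2 14.464286
#> minor                 minor  13  5.454545
#> non_canonical non_canonical   7 49.367089
sprintf("Kruskal-Wallis p = %.3g", cmp$p)
#> "Kruskal-Wallis p = 2.67e-17"
```

Reading the output: minor introns land in compartment A at 71.8 % against
the 60.4 % major-intron background (at this small scale the
Bonferroni-adjusted p of 0.29 is not significant — power returns at full
scale); the bootstrap median of random major subsets stays at the major
background, so the minor excess is not a set-size artefact; and within
SPADs the retention index separates the classes (non-canonical introns
retained most, major least), with minor introns spliced nearly as
efficiently as major ones.

`run_full_analysis(run_config(...))` executes every stage from file inputs
and writes all tables plus a seed/parameter manifest under an output
directory; `export_gene_lists()` emits the improved-splicing gene lists for
external GO tooling.

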