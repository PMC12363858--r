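## Junction-read evidence extraction and splicing indices (SI_RET / SI_ES).

#' Load gene models (exon intervals) for junction classification
#'
#' @param x path to a GTF file (exon features are used) or a data.frame with
#'   columns `gene_id`, `chrom`, `start`, `end` (0-based half-open) and
#'   optionally `strand`.
#' @return data.frame of exons with 0-based half-open coordinates.
#' @export
load_gene_models <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(x)))
    ex <- x
    if (!"strand" %in% names(ex)) ex$strand <- "+"
    return(ex[, c("gene_id", "chrom", "start", "end", "strand")])
  }
  gr <- rtracklayer::import(x)
  gr <- gr[gr$type == "exon"]
  data.frame(gene_id = as.character(gr$gene_id),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

# Flanking exons of each intron: the exon of the same gene ending exactly at
# the intron start (upstream in genome coordinates) and the exon starting
# exactly at the intron end.
flanking_exons <- function(catalog, gene_models) {
  r <- catalog$records
  key5 <- paste(gene_models$gene_id, gene_models$chrom, gene_models$end)
  key3 <- paste(gene_models$gene_id, gene_models$chrom, gene_models$start)
  m5 <- match(paste(r$gene_id, r$chrom, r$start), key5)
  m3 <- match(paste(r$gene_id, r$chrom, r$end), key3)
  list(e5_start = gene_models$start[m5],   # NA when no annotated flanking exon
       e3_end = gene_models$end[m3])
}

ensure_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
    return(bam)
  }
  if (!file.exists(paste0(path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", path)))
    stop("alignment file is not indexed: ", path)
  path
}

#' Extract per-intron junction read evidence from spliced alignments
#'
#' Classifies uniquely mapped primary alignments into per-intron counts:
#' \describe{
#'   \item{n5 / n3}{reads contiguously aligned across the 5'/3' intron
#'     boundary (for minus-strand introns 5' is the right-hand edge), with at
#'     least `min_anchor` aligned bases on each side of the junction —
#'     retention evidence.}
#'   \item{n_spliced}{gapped reads whose skip matches the annotated intron
#'     exactly, with both anchors >= `min_anchor` — canonical splicing.}
#'   \item{n_skip}{gapped reads whose skip contains the intron plus at least
#'     one whole annotated flanking exon — exon skipping.}
#'   \item{n_cryptic}{gapped reads using a non-annotated splice site: a skip
#'     strictly inside the intron, or anchored at exactly one annotated intron
#'     edge with the other end at a non-annotated position.}
#' }
#' Reads with fewer than `min_anchor` bases on either side of a junction are
#' excluded (the classical one-nucleotide-overhang artefact); the anchor rule
#' is applied to boundary-spanning and gapped reads alike.  Secondary,
#' supplementary and duplicate records are always dropped; `unique_only`
#' additionally applies a mapping-quality floor.
#'
#' @param alignments path to a coordinate-sorted indexed BAM, or a SAM file
#'   (converted and indexed on the fly).
#' @param catalog an `intron_catalog`.
#' @param gene_models exon table from [load_gene_models()] (used for the
#'   exon-skipping and annotated-site definitions).
#' @param min_anchor minimum aligned bases each side of a junction (default 2).
#' @param unique_only drop records below `mapq_min` (default TRUE).
#' @param mapq_min mapping-quality floor used when `unique_only` (default 1,
#'   which removes multi-mapper-flagged MAPQ-0 records).
#' @param cell_line,replicate tags carried into the output.
#' @return data.frame (`junction_evidence`): `intron_id`, `cell_line`,
#'   `replicate`, `n5`, `n3`, `n_spliced`, `n_skip`, `n_cryptic`.
#' @export
extract_junction_evidence <- function(alignments, catalog, gene_models,
                                      min_anchor = 2, unique_only = TRUE,
                                      mapq_min = 1,
                                      cell_line = NA_character_,
                                      replicate = NA_character_) {
  stopifnot(inherits(catalog, "intron_catalog"), min_anchor >= 1)
  bam <- ensure_bam(alignments)
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   mapqFilter = if (unique_only) mapq_min else 0)
  galn <- GenomicAlignments::readGAlignments(Rsamtools::BamFile(bam),
                                             param = param)
  r <- catalog$records
  n <- nrow(r)
  missing_chrom <- setdiff(unique(r$chrom),
                           as.character(GenomeInfoDb_seqlevels(galn)))
  if (length(missing_chrom))
    warning("chromosome(s) absent from alignments (zero counts): ",
            paste(missing_chrom, collapse = ", "))

  zero <- integer(n)
  out <- data.frame(intron_id = r$intron_id, cell_line = cell_line,
                    replicate = replicate, n5 = zero, n3 = zero,
                    n_spliced = zero, n_skip = zero, n_cryptic = zero,
                    stringsAsFactors = FALSE)

  if (length(galn) > 0) {
    ## aligned blocks and junction gaps, with per-read bookkeeping
    bl <- GenomicAlignments::grglist(galn)
    bl_un <- unlist(bl, use.names = FALSE)
    rid_b <- rep(seq_along(bl), lengths(bl))
    bidx <- sequence(lengths(bl))
    ju <- GenomicAlignments::junctions(galn)
    ju_un <- unlist(ju, use.names = FALSE)
    rid_j <- rep(seq_along(ju), lengths(ju))
    jidx <- sequence(lengths(ju))

    ## anchor widths flanking each junction
    if (length(ju_un) > 0) {
      bw <- GenomicRanges::width(bl_un)
      bkey <- paste(rid_b, bidx)
      left_w <- bw[match(paste(rid_j, jidx), bkey)]
      right_w <- bw[match(paste(rid_j, jidx + 1), bkey)]
      anchor_ok <- left_w >= min_anchor & right_w >= min_anchor
    } else {
      anchor_ok <- logical(0)
    }

    ## boundary (retention) evidence: a single block containing the window
    ## [edge - min_anchor, edge + min_anchor) proves contiguous alignment
    left_win <- GenomicRanges::GRanges(
      r$chrom, IRanges::IRanges(start = r$start - min_anchor + 1,
                                end = r$start + min_anchor))
    right_win <- GenomicRanges::GRanges(
      r$chrom, IRanges::IRanges(start = r$end - min_anchor + 1,
                                end = r$end + min_anchor))
    hl <- GenomicRanges::findOverlaps(left_win, bl_un, type = "within",
                                      ignore.strand = TRUE)
    hr <- GenomicRanges::findOverlaps(right_win, bl_un, type = "within",
                                      ignore.strand = TRUE)
    left_n <- tabulate(S4Vectors::queryHits(hl), nbins = n)
    right_n <- tabulate(S4Vectors::queryHits(hr), nbins = n)
    minus <- r$strand == "-"
    out$n5 <- ifelse(minus, right_n, left_n)
    out$n3 <- ifelse(minus, left_n, right_n)

    if (length(ju_un) > 0) {
      fl <- flanking_exons(catalog, gene_models)
      igr <- GenomicRanges::GRanges(
        r$chrom, IRanges::IRanges(start = r$start + 1, end = r$end))
      hits <- GenomicRanges::findOverlaps(igr, ju_un, ignore.strand = TRUE)
      qi <- S4Vectors::queryHits(hits)
      sj <- S4Vectors::subjectHits(hits)
      gs0 <- GenomicRanges::start(ju_un)[sj] - 1  # skip, 0-based half-open
      ge0 <- GenomicRanges::end(ju_un)[sj]
      s0 <- r$start[qi]
      e0 <- r$end[qi]
      aok <- anchor_ok[sj]

      exact <- gs0 == s0 & ge0 == e0
      contains <- gs0 <= s0 & ge0 >= e0
      e5s <- fl$e5_start[qi]
      e3e <- fl$e3_end[qi]
      skips <- contains & !exact &
        ((!is.na(e5s) & gs0 <= e5s) | (!is.na(e3e) & ge0 >= e3e))

      ## annotated splice positions: every catalogued intron edge
      annot_key <- c(paste(r$chrom, r$start), paste(r$chrom, r$end))
      chrom_hit <- r$chrom[qi]
      inside <- gs0 > s0 & ge0 < e0
      left_match <- gs0 == s0
      right_match <- ge0 == e0
      one_edge <- xor(left_match, right_match)
      other_pos <- ifelse(left_match, ge0, gs0)
      other_annot <- paste(chrom_hit, other_pos) %in% annot_key
      cryptics <- !exact & !skips & (inside | (one_edge & !other_annot))

      out$n_spliced <- tabulate(qi[exact & aok], nbins = n)
      out$n_skip <- tabulate(qi[skips & aok], nbins = n)
      out$n_cryptic <- tabulate(qi[cryptics & aok], nbins = n)
    }
  }
  class(out) <- c("junction_evidence", "data.frame")
  out
}

# thin indirection so the seqlevels accessor is easy to stub in tests
GenomeInfoDb_seqlevels <- function(x) GenomeInfoDb::seqlevels(x)

#' Intron-retention splicing index
#'
#' `SI_RET = 100 * B / (B + n_spliced)` with `B = (n5 + n3) / 2`, the mean of
#' the two boundary read counts.  Any cryptic-splicing evidence
#' (`n_cryptic > 0`) voids the boundary reads as retention support (`B` set
#' to 0): boundary coverage then cannot be distinguished from a cryptic
#' isoform.  The index is undefined (NA) when the denominator is zero.
#'
#' @param evidence a `junction_evidence` data.frame.
#' @return data.frame `intron_id`, `si_ret` (percentage in \[0, 100\] or NA),
#'   `category` (`retained_only`, `spliced_only`, `both`, or NA when
#'   undefined), `cryptic_veto`.
#' @export
compute_si_ret <- function(evidence) {
  b <- (evidence$n5 + evidence$n3) / 2
  veto <- evidence$n_cryptic > 0
  b[veto] <- 0
  denom <- b + evidence$n_spliced
  si <- ifelse(denom > 0, 100 * b / denom, NA_real_)
  category <- rep(NA_character_, nrow(evidence))
  category[b > 0 & evidence$n_spliced == 0] <- "retained_only"
  category[b == 0 & evidence$n_spliced > 0] <- "spliced_only"
  category[b > 0 & evidence$n_spliced > 0] <- "both"
  data.frame(intron_id = evidence$intron_id, si_ret = si,
             category = category, cryptic_veto = veto,
             stringsAsFactors = FALSE)
}

#' Exon-skipping splicing index
#'
#' `SI_ES = 100 * n_skip / (n_skip + n_spliced)`; undefined (NA) when no
#' spliced or skipping reads exist.
#'
#' @param evidence a `junction_evidence` data.frame.
#' @return data.frame `intron_id`, `si_es`.
#' @export
compute_si_es <- function(evidence) {
  denom <- evidence$n_skip + evidence$n_spliced
  si <- ifelse(denom > 0, 100 * evidence$n_skip / denom, NA_real_)
  data.frame(intron_id = evidence$intron_id, si_es = si,
             stringsAsFactors = FALSE)
}

#' Assemble full splicing-index records
#'
#' Joins the retention and skipping indices with intron class, parent-gene
#' expression and (optionally) nuclear-body location.  Evidence from several
#' replicates of one cell line is pooled (counts summed) before the indices
#' are computed; with a single replicate pooling is the identity.  Set
#' `per_replicate = TRUE` to instead compute indices per replicate and
#' average them.
#'
#' @param evidence a `junction_evidence` data.frame (possibly several
#'   replicates).
#' @param catalog an `intron_catalog`.
#' @param expr optional `expression_table` (adds `gene_mean_tpm`).
#' @param matrix optional `overlap_matrix` (adds `location` from
#'   `partition`).
#' @param partition partition used for `location` (default `nuclear_body`).
#' @param per_replicate average per-replicate indices instead of pooling
#'   counts.
#' @return data.frame (`splicing_records`) with one row per intron:
#'   `intron_id`, `intron_class`, `gene_id`, `cell_line`, counts, `si_ret`,
#'   `si_es`, `category`, `gene_mean_tpm`, `location`.
#' @export
splicing_index_records <- function(evidence, catalog, expr = NULL,
                                   matrix = NULL, partition = "nuclear_body",
                                   per_replicate = FALSE) {
  counts <- c("n5", "n3", "n_spliced", "n_skip", "n_cryptic")
  if (per_replicate) {
    rep_id <- ifelse(is.na(evidence$replicate), "rep1", evidence$replicate)
    reps <- split(evidence, rep_id)
    frags_ret <- lapply(reps, compute_si_ret)
    frags_es <- lapply(reps, compute_si_es)
    pooled <- stats::aggregate(evidence[counts],
                               by = list(intron_id = evidence$intron_id), sum)
    si_ret_tab <- do.call(rbind, frags_ret)
    si_es_tab <- do.call(rbind, frags_es)
    ret <- stats::aggregate(si_ret ~ intron_id, si_ret_tab, mean,
                            na.action = stats::na.omit)
    es <- stats::aggregate(si_es ~ intron_id, si_es_tab, mean,
                           na.action = stats::na.omit)
    base <- pooled
    base$si_ret <- ret$si_ret[match(base$intron_id, ret$intron_id)]
    base$si_es <- es$si_es[match(base$intron_id, es$intron_id)]
    cat_tab <- compute_si_ret(pooled)
    base$category <- cat_tab$category
  } else {
    base <- stats::aggregate(evidence[counts],
                             by = list(intron_id = evidence$intron_id), sum)
    frag_ret <- compute_si_ret(base)
    frag_es <- compute_si_es(base)
    base$si_ret <- frag_ret$si_ret
    base$category <- frag_ret$category
    base$si_es <- frag_es$si_es
  }
  m <- match(base$intron_id, catalog$records$intron_id)
  base$intron_class <- catalog$records$intron_class[m]
  base$gene_id <- catalog$records$gene_id[m]
  base$cell_line <- evidence$cell_line[1]
  base$gene_mean_tpm <- if (!is.null(expr))
    expr$mean_tpm[match(base$gene_id, expr$gene_id)] else NA_real_
  if (!is.null(matrix)) {
    col <- paste0("partition_", partition)
    if (!col %in% names(matrix)) stop("partition not present: ", partition)
    base$location <- matrix[[col]][match(base$intron_id, matrix$intron_id)]
  } else {
    base$location <- NA_character_
  }
  class(base) <- c("splicing_records", "data.frame")
  base
}

#' Apply the analysis filters to splicing records
#'
#' Keeps introns in genes expressed at `tpm_threshold` or above (replicate
#' mean), with at least one supporting read; optionally restricts to introns
#' with reads supporting both retention and canonical splicing (`category ==
#' "both"`, the restriction used for cross-class and cross-line index
#' comparisons); and subsamples the named abundant classes to a fixed size
#' with a seeded draw.
#'
#' @param records a `splicing_records` data.frame.
#' @param tpm_threshold minimum mean TPM (inclusive; default 1).  Records with
#'   missing `gene_mean_tpm` are removed when a threshold is applied.
#' @param require_read keep only introns with >= 1 read of any kind.
#' @param category_filter `"any"` or `"both"`.
#' @param subsample named integer vector: class -> target size (default
#'   5000 each for major and major-like).  Classes absent from the vector are
#'   kept whole; if fewer records than the target exist, all are kept with a
#'   warning.
#' @param seed seed for the subsampling draw.
#' @return Filtered `splicing_records`.
#' @export
filter_for_analysis <- function(records, tpm_threshold = 1,
                                require_read = TRUE,
                                category_filter = c("any", "both"),
                                subsample = c(major = 5000, major_like = 5000),
                                seed = 1) {
  category_filter <- match.arg(category_filter)
  keep <- rep(TRUE, nrow(records))
  if (!is.null(tpm_threshold)) {
    tpm <- records$gene_mean_tpm
    keep <- keep & !is.na(tpm) & tpm >= tpm_threshold
  }
  if (require_read) {
    total <- records$n5 + records$n3 + records$n_spliced + records$n_skip
    keep <- keep & total > 0
  }
  if (category_filter == "both")
    keep <- keep & !is.na(records$category) & records$category == "both"
  out <- records[keep, , drop = FALSE]
  if (length(subsample)) {
    keep_rows <- rep(TRUE, nrow(out))
    for (cl in names(subsample)) {
      idx <- which(out$intron_class == cl)
      target <- subsample[[cl]]
      if (length(idx) > target) {
        sel <- with_preserved_rng({
          set.seed(substream_seed(seed, match(cl, INTRON_CLASSES), tag = 7L))
          sample(idx, target)
        })
        keep_rows[setdiff(idx, sel)] <- FALSE
      } else if (length(idx) > 0 && length(idx) < target) {
        warning("subsample target ", target, " exceeds available ",
                length(idx), " records for class ", cl, "; keeping all")
      }
    }
    out <- out[keep_rows, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

## Rank-based group comparisons ----------------------------------------------

# Exact two-sided Mann-Whitney p by enumeration over group assignments.
# Handles ties correctly (permutation of the observed ranks); used for small
# samples where stats::wilcox.test refuses exact p-values with ties.
mw_exact_p <- function(x, y) {
  nx <- length(x)
  N <- nx + length(y)
  rk <- rank(c(x, y))
  W <- sum(rk[seq_len(nx)])
  mu <- nx * (N + 1) / 2
  sums <- utils::combn(rk, nx, sum)
  mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
}

#' All-pairs Dunn post hoc test
#'
#' Rank-based z statistics for all group pairs following a Kruskal-Wallis
#' test, with the usual tie correction, two-sided normal p-values and
#' Benjamini-Hochberg adjustment across pairs.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @return data.frame `group1`, `group2`, `z`, `p_raw`, `p_adj`.
#' @export
dunn_test <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  N <- length(values)
  rk <- rank(values)
  rbar <- tapply(rk, groups, mean)
  ns <- tapply(rk, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_corr
  gl <- levels(groups)
  pairs <- utils::combn(gl, 2)
  z <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(base_var * (1 / ns[[i]] + 1 / ns[[j]]))
    z[k] <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
  }
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p_raw = p,
             p_adj = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Compare splicing-index distributions between groups
#'
#' Two groups: two-sided Mann-Whitney U (exact by enumeration for total
#' n <= 20, normal approximation otherwise).  More than two groups:
#' Kruskal-Wallis followed by all-pairs Dunn with Benjamini-Hochberg
#' adjustment.  Groups with fewer than two non-missing values are reported
#' untestable and excluded from the test.
#'
#' @param records a `splicing_records` data.frame (or any data.frame with the
#'   metric column).
#' @param group name of the grouping column (e.g. `"intron_class"`,
#'   `"location"`, `"cell_line"`) or a vector of group labels.
#' @param metric `"si_ret"` or `"si_es"`.
#' @return A `group_comparison` list: `test`, `metric`, `groups` (n and
#'   median per group), `statistic`, `p`, `pairs` (Dunn table or NULL),
#'   `untestable_groups`.
#' @export
compare_distributions <- function(records, group, metric = c("si_ret", "si_es")) {
  metric <- match.arg(metric)
  g <- if (length(group) == 1 && is.character(group) &&
           group %in% names(records)) records[[group]] else group
  v <- records[[metric]]
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- as.character(g)[ok]
  sizes <- table(g)
  untestable <- names(sizes)[sizes < 2]
  keep <- !(g %in% untestable)
  v <- v[keep]; g <- g[keep]
  gl <- unique(g)
  summary_tab <- data.frame(
    group = gl,
    n = as.integer(table(factor(g, levels = gl))),
    median = vapply(gl, function(x) stats::median(v[g == x]), numeric(1)),
    stringsAsFactors = FALSE)

  if (length(gl) < 2) {
    return(structure(list(test = "none", metric = metric,
                          groups = summary_tab, statistic = NA_real_,
                          p = NA_real_, pairs = NULL,
                          untestable_groups = untestable),
                     class = "group_comparison"))
  }
  if (length(gl) == 2) {
    x <- v[g == gl[1]]; y <- v[g == gl[2]]
    if (length(v) <= 20) {
      p <- mw_exact_p(x, y)
      stat <- sum(rank(v)[g == gl[1]])
      test <- "mann_whitney_exact"
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y,
                                                alternative = "two.sided"))
      p <- wt$p.value
      stat <- unname(wt$statistic)
      test <- "mann_whitney"
    }
    return(structure(list(test = test, metric = metric, groups = summary_tab,
                          statistic = stat, p = p, pairs = NULL,
                          untestable_groups = untestable),
                     class = "group_comparison"))
  }
  kw <- stats::kruskal.test(v, factor(g))
  pairs <- dunn_test(v, g)
  structure(list(test = "kruskal_wallis_dunn", metric = metric,
                 groups = summary_tab,
                 statistic = unname(kw$statistic), p = kw$p.value,
                 pairs = pairs, untestable_groups = untestable),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("group_comparison (", x$test, ", ", x$metric, "): p = ",
      format(x$p, digits = 4), "\n", sep = "")
  print(x$groups)
  if (!is.null(x$pairs)) print(x$pairs)
  invisible(x)
}

## Cross-cell-line matched sets ----------------------------------------------

#' Introns sharing a location category across cell lines
#'
#' Builds (i) per-class sets of introns assigned to the same partition
#' category in *all* supplied cell lines, (ii) pairwise reference-vs-other
#' shared sets with counts, and (iii) Mann-Whitney comparisons of the
#' splicing index over each pairwise shared set.  Introns without a defined
#' index in a cell line are dropped from that set (counts logged).
#'
#' @param matrices named list (per cell line) of `overlap_matrix` objects
#'   over the same intron_id space.
#' @param records named list (per cell line) of `splicing_records`.
#' @param reference_cell_line name of the reference line.
#' @param partition partition defining "location" (default nuclear body).
#' @param classes intron classes to analyse (default all six).
#' @param catalog the shared `intron_catalog`.
#' @param metric `"si_ret"` or `"si_es"`.
#' @return A list: `all_lines` (data.frame class/category/n + `sets`),
#'   `pairwise` (data.frame line/class/category/n + `sets`), `comparisons`
#'   (data.frame with the Mann-Whitney p per pairwise set).
#' @export
matched_location_sets <- function(matrices, records, reference_cell_line,
                                  partition = "nuclear_body",
                                  classes = INTRON_CLASSES, catalog,
                                  metric = "si_ret") {
  stopifnot(reference_cell_line %in% names(matrices),
            reference_cell_line %in% names(records))
  lines <- names(matrices)
  col <- paste0("partition_", partition)
  loc <- lapply(matrices, function(m) {
    stats::setNames(m[[col]], m$intron_id)
  })
  has_metric <- lapply(records, function(rr) {
    stats::setNames(!is.na(rr[[metric]]), rr$intron_id)
  })
  cls_map <- stats::setNames(catalog$records$intron_class,
                             catalog$records$intron_id)
  ids_all <- Reduce(intersect, lapply(loc, names))
  categories <- sort(unique(unlist(lapply(loc, unique))))

  measured <- function(ids, line_set) {
    keep <- rep(TRUE, length(ids))
    for (ln in line_set) {
      hm <- has_metric[[ln]][ids]
      keep <- keep & !is.na(hm) & hm
    }
    dropped <- sum(!keep)
    if (dropped > 0)
      message(dropped, " intron(s) lack a defined ", metric,
              " in some cell line; excluded from the matched set")
    ids[keep]
  }

  all_sets <- list(); all_rows <- NULL
  pair_sets <- list(); pair_rows <- NULL
  comp_rows <- NULL
  others <- setdiff(lines, reference_cell_line)

  for (cl in classes) {
    ids_cl <- ids_all[cls_map[ids_all] == cl]
    for (cat in categories) {
      same_all <- ids_cl
      for (ln in lines) same_all <- same_all[loc[[ln]][same_all] == cat]
      same_all <- measured(same_all, lines)
      key <- paste(cl, cat, sep = "|")
      all_sets[[key]] <- same_all
      all_rows <- rbind(all_rows,
                        data.frame(intron_class = cl, category = cat,
                                   n = length(same_all)))
      for (ln in others) {
        ids2 <- ids_cl[loc[[reference_cell_line]][ids_cl] == cat &
                         loc[[ln]][ids_cl] == cat]
        ids2 <- measured(ids2, c(reference_cell_line, ln))
        pkey <- paste(ln, cl, cat, sep = "|")
        pair_sets[[pkey]] <- ids2
        pair_rows <- rbind(pair_rows,
                           data.frame(cell_line = ln, intron_class = cl,
                                      category = cat, n = length(ids2)))
        if (length(ids2) >= 2) {
          rr <- records[[reference_cell_line]]
          ro <- records[[ln]]
          x <- rr[[metric]][match(ids2, rr$intron_id)]
          y <- ro[[metric]][match(ids2, ro$intron_id)]
          df <- data.frame(v = c(x, y),
                           g = rep(c(reference_cell_line, ln), each = length(ids2)))
          names(df)[1] <- metric
          cmp <- compare_distributions(df, df$g, metric = metric)
          comp_rows <- rbind(comp_rows,
                             data.frame(cell_line = ln, intron_class = cl,
                                        category = cat, n = length(ids2),
                                        median_ref = stats::median(x),
                                        median_other = stats::median(y),
                                        p = cmp$p, test = cmp$test))
        }
      }
    }
  }
  list(all_lines = list(summary = all_rows, sets = all_sets),
       pairwise = list(summary = pair_rows, sets = pair_sets),
       comparisons = comp_rows,
       reference = reference_cell_line, partition = partition,
       metric = metric)
}

#' Introns with improved splicing in other cell lines
#'
#' Over a shared-location intron set, selects introns whose splicing index is
#' strictly lower in each comparison cell line than in the reference
#' (no minimum effect size), then intersects the per-line lists and
#' deduplicates parent genes — the gene lists feed external GO tooling.
#'
#' @param records_ref `splicing_records` for the reference line.
#' @param records_others named list of `splicing_records` per comparison line.
#' @param shared_ids named list (same names) of intron_id vectors: the
#'   shared-location set for each comparison.
#' @param catalog the shared `intron_catalog`.
#' @param metric `"si_ret"` (default) or `"si_es"`.
#' @return List with `per_line` (per comparison line: `intron_ids`,
#'   `gene_ids`) and `intersection` (introns improved in every line, plus
#'   deduplicated genes).
#' @export
improved_splicing_intersection <- function(records_ref, records_others,
                                           shared_ids, catalog,
                                           metric = "si_ret") {
  stopifnot(all(names(records_others) %in% names(shared_ids)))
  gene_map <- stats::setNames(catalog$records$gene_id,
                              catalog$records$intron_id)
  per_line <- lapply(names(records_others), function(ln) {
    ids <- shared_ids[[ln]]
    if (length(ids) == 0)
      return(list(intron_ids = character(0), gene_ids = character(0)))
    x <- records_ref[[metric]][match(ids, records_ref$intron_id)]
    y <- records_others[[ln]][[metric]][match(ids,
                                              records_others[[ln]]$intron_id)]
    ok <- !is.na(x) & !is.na(y) & y < x
    list(intron_ids = ids[ok],
         gene_ids = sort(unique(unname(gene_map[ids[ok]]))))
  })
  names(per_line) <- names(records_others)
  inter <- Reduce(intersect, lapply(per_line, `[[`, "intron_ids"))
  list(per_line = per_line,
       intersection = list(intron_ids = inter,
                           gene_ids = sort(unique(unname(gene_map[inter])))))
}
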