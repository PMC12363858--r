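## 3D-feature tracks, fractional-overlap membership, proportions, enrichment.

#' Construct a feature track
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) or a `GRanges`.  Intervals are sorted and merged so that no
#'   two intervals of one track overlap: the fractional-overlap rule is then
#'   evaluated against single merged intervals, making membership independent
#'   of how fragmented the source file was.
#' @param feature_type one of [feature_types()].
#' @param cell_line cell line name.
#' @return A `feature_track` list: `feature_type`, `cell_line`, `gr`
#'   (reduced `GRanges`).
#' @export
feature_track <- function(intervals, feature_type, cell_line) {
  if (!feature_type %in% FEATURE_TYPES)
    stop("unknown feature_type '", feature_type, "'; allowed: ",
         paste(FEATURE_TYPES, collapse = ", "))
  if (is.data.frame(intervals)) {
    gr <- GenomicRanges::GRanges(
      intervals$chrom,
      IRanges::IRanges(start = intervals$start + 1, end = intervals$end))
  } else {
    gr <- intervals
  }
  gr <- GenomicRanges::reduce(sort(gr), ignore.strand = TRUE)
  structure(list(feature_type = feature_type, cell_line = cell_line, gr = gr),
            class = "feature_track")
}

#' @export
print.feature_track <- function(x, ...) {
  cat("feature_track:", x$feature_type, "(", x$cell_line, ") —",
      length(x$gr), "merged intervals,",
      sum(GenomicRanges::width(x$gr)), "bp covered\n")
  invisible(x)
}

#' Load a feature track from a BED file
#'
#' @param path BED3+ file (0-based half-open); extra columns ignored.
#' @param feature_type one of [feature_types()].
#' @param cell_line cell line name.
#' @return A `feature_track` with sorted, merged intervals.
#' @export
load_feature_track <- function(path, feature_type, cell_line) {
  if (!feature_type %in% FEATURE_TYPES)
    stop("unknown feature_type '", feature_type, "'; allowed: ",
         paste(FEATURE_TYPES, collapse = ", "))
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) NULL
      else stop("malformed BED file '", path, "': ", conditionMessage(e))
    })
  if (is.null(raw) || nrow(raw) == 0) {
    warning("track '", path, "' has zero intervals")
    df <- data.frame(chrom = character(), start = numeric(), end = numeric())
    return(feature_track(df, feature_type, cell_line))
  }
  if (ncol(raw) < 3 || !is.numeric(raw[[2]]) || !is.numeric(raw[[3]]))
    stop("malformed BED file '", path, "': need chrom/start/end columns")
  tr <- feature_track(data.frame(chrom = as.character(raw[[1]]),
                                 start = as.numeric(raw[[2]]),
                                 end = as.numeric(raw[[3]])),
                      feature_type, cell_line)
  message("track ", feature_type, " (", cell_line, "): ", length(tr$gr),
          " merged intervals, ", sum(GenomicRanges::width(tr$gr)),
          " bp covered")
  tr
}

#' Assign introns to 3D features by fractional overlap
#'
#' An intron is a member of a track iff its overlap with some *single* merged
#' interval of the track is at least `min_overlap_frac` of the intron length
#' (inclusive threshold; the default 0.5 encodes the "at least 50% of the
#' intron" rule).  Within each mutually exclusive partition (compartment,
#' subcompartment, nuclear body, 3D feature), an intron passing the threshold
#' for two categories is resolved to the one with the larger overlap; an exact
#' tie — only possible at a 50/50 split — is assigned to "neither" with a
#' warning.  Introns passing no category are "neither".
#'
#' @param catalog an `intron_catalog`.
#' @param tracks list of `feature_track`s, all from one cell line.
#' @param min_overlap_frac fraction in (0, 1]; default 0.5.
#' @return An `overlap_matrix`: data.frame keyed by `intron_id` with one
#'   logical membership column per feature type present, one
#'   `partition_<name>` category column per partition populated, and
#'   attributes `cell_line`, `min_overlap_frac`, `overlap_bp` (numeric matrix
#'   of best single-interval overlaps).
#' @export
assign_membership <- function(catalog, tracks, min_overlap_frac = 0.5) {
  stopifnot(inherits(catalog, "intron_catalog"))
  if (nrow(catalog$records) == 0) stop("catalog is empty")
  if (!(min_overlap_frac > 0 && min_overlap_frac <= 1))
    stop("min_overlap_frac must lie in (0, 1]")
  if (inherits(tracks, "feature_track")) tracks <- list(tracks)
  cls <- vapply(tracks, function(t) t$cell_line, character(1))
  if (length(unique(cls)) > 1)
    stop("tracks span multiple cell lines: ", paste(unique(cls), collapse = ", "))
  types <- vapply(tracks, function(t) t$feature_type, character(1))
  if (anyDuplicated(types))
    stop("duplicate feature_type among tracks: ",
         paste(types[duplicated(types)], collapse = ", "))
  names(tracks) <- types

  igr <- catalog_granges(catalog)
  n <- length(igr)
  ilen <- GenomicRanges::width(igr)

  ov_bp <- matrix(0, nrow = n, ncol = length(tracks),
                  dimnames = list(catalog$records$intron_id, types))
  for (ty in types) {
    gr <- tracks[[ty]]$gr
    if (length(gr) == 0) next
    hits <- GenomicRanges::findOverlaps(igr, gr, ignore.strand = TRUE)
    if (length(hits) == 0) next
    pi <- GenomicRanges::pintersect(igr[S4Vectors::queryHits(hits)],
                                    gr[S4Vectors::subjectHits(hits)],
                                    ignore.strand = TRUE)
    w <- GenomicRanges::width(pi)
    best <- tapply(w, S4Vectors::queryHits(hits), max)
    ov_bp[as.integer(names(best)), ty] <- as.numeric(best)
  }
  member <- sweep(ov_bp, 1, ilen * min_overlap_frac, ">=") & ov_bp > 0

  out <- data.frame(intron_id = catalog$records$intron_id,
                    stringsAsFactors = FALSE)
  for (ty in types) out[[ty]] <- member[, ty]

  for (pname in names(PARTITIONS)) {
    cats <- PARTITIONS[[pname]]
    present <- cats[cats %in% types]
    if (length(present) == 0) next
    sub_member <- member[, present, drop = FALSE]
    sub_ov <- ov_bp[, present, drop = FALSE]
    sub_ov[!sub_member] <- -Inf
    assigned <- rep("neither", n)
    hit_any <- rowSums(sub_member) > 0
    if (any(hit_any)) {
      best_ov <- apply(sub_ov[hit_any, , drop = FALSE], 1, max)
      n_best <- rowSums(sub_ov[hit_any, , drop = FALSE] == best_ov)
      tie <- n_best > 1
      if (any(tie))
        warning(sum(tie), " intron(s) tie exactly between two '", pname,
                "' categories; assigned to 'neither'")
      pick <- names(present)[apply(sub_ov[hit_any, , drop = FALSE], 1,
                                   which.max)]
      pick[tie] <- "neither"
      assigned[hit_any] <- pick
    }
    out[[paste0("partition_", pname)]] <- assigned
  }

  attr(out, "cell_line") <- unique(cls)
  attr(out, "min_overlap_frac") <- min_overlap_frac
  attr(out, "overlap_bp") <- ov_bp
  class(out) <- c("overlap_matrix", "data.frame")
  out
}

#' Per-class proportions across a partition
#'
#' @param matrix an `overlap_matrix`.
#' @param catalog the catalog the matrix was computed from.
#' @param partition partition name (`"compartment"`, `"subcompartment"`,
#'   `"nuclear_body"`, `"feature3d"`).
#' @param by optional second partition; when given, a joint two-way
#'   cross-tabulation is returned (e.g. SPAD membership within compartment-A
#'   introns).
#' @param conditional_on for the subcompartment partition: restrict the
#'   denominator to introns assigned to the named parent category of another
#'   partition (e.g. fractions of compartment-A introns across A1/A2).
#' @return data.frame with `intron_class`, `category`, `n`, `proportion`
#'   (fractions sum to 1 within class), or a joint table when `by` is given.
#' @export
class_proportions <- function(matrix, catalog, partition, by = NULL,
                              conditional_on = NULL) {
  col <- paste0("partition_", partition)
  if (!col %in% names(matrix)) stop("partition not present: ", partition)
  cls <- catalog$records$intron_class[match(matrix$intron_id,
                                            catalog$records$intron_id)]
  keep <- rep(TRUE, nrow(matrix))
  if (!is.null(conditional_on)) {
    pcol <- paste0("partition_", conditional_on$partition)
    if (!pcol %in% names(matrix)) stop("partition not present: ",
                                       conditional_on$partition)
    keep <- matrix[[pcol]] == conditional_on$category
  }
  present <- intersect(INTRON_CLASSES, unique(cls))
  absent <- setdiff(unique(cls), present)
  if (length(absent)) warning("class(es) omitted: ", paste(absent, collapse = ", "))

  if (!is.null(by)) {
    bcol <- paste0("partition_", by)
    if (!bcol %in% names(matrix)) stop("partition not present: ", by)
    tab <- table(intron_class = cls[keep], matrix[[col]][keep],
                 matrix[[bcol]][keep])
    return(as.data.frame(tab, stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(present, function(cl) {
    v <- matrix[[col]][keep & cls == cl]
    if (length(v) == 0) return(NULL)
    tab <- table(v)
    data.frame(intron_class = cl, category = names(tab),
               n = as.integer(tab),
               proportion = as.numeric(tab) / length(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

## Shared 2x2 Fisher machinery ------------------------------------------------

# table layout: rows = (in, out), cols = (focal, baseline)
fisher_2x2 <- function(a, b, c, d, family_size = 1) {
  tab <- matrix(c(a, c, b, d), nrow = 2,
                dimnames = list(c("in", "out"), c("focal", "baseline")))
  margins_ok <- all(rowSums(tab) > 0) || TRUE  # marginal zeros handled below
  untestable <- (a + c) == 0 || (b + d) == 0
  if (untestable) {
    return(list(table = tab, odds_ratio = NA_real_, p_raw = NA_real_,
                p_adjusted = NA_real_, family_size = family_size,
                untestable = TRUE))
  }
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  or <- (a * d) / (b * c)  # sample (cross-product) odds ratio
  list(table = tab, odds_ratio = or, p_raw = p,
       p_adjusted = min(1, p * family_size), family_size = family_size,
       untestable = FALSE)
}

#' Two-sided Fisher exact test on a 2x2 enrichment table
#'
#' The table machinery behind every enrichment result: rows are in/out of the
#' feature, columns focal/baseline class.  Returns the exact conditional
#' two-sided p, the sample (cross-product) odds ratio, and the
#' Bonferroni-adjusted p (`min(1, p * family_size)`).  A zero column margin
#' flags the result untestable.
#'
#' @param in_focal,in_baseline,out_focal,out_baseline the four cell counts.
#' @param family_size Bonferroni family size (default 1).
#' @return List: `table`, `odds_ratio`, `p_raw`, `p_adjusted`, `family_size`,
#'   `untestable`.
#' @export
fisher_exact_2x2 <- function(in_focal, in_baseline, out_focal, out_baseline,
                             family_size = 1) {
  fisher_2x2(in_focal, in_baseline, out_focal, out_baseline, family_size)
}

make_enrichment_result <- function(focal_class, baseline_class, feature_label,
                                   in_focal, out_focal, in_base, out_base,
                                   family_size) {
  f <- fisher_2x2(in_focal, in_base, out_focal, out_base, family_size)
  structure(c(list(focal_class = focal_class, baseline_class = baseline_class,
                   feature = feature_label,
                   proportion_focal = if (in_focal + out_focal > 0)
                     in_focal / (in_focal + out_focal) else NA_real_,
                   proportion_baseline = if (in_base + out_base > 0)
                     in_base / (in_base + out_base) else NA_real_),
              f),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment [%s]: %s %.1f%% vs %s %.1f%%  OR=%.3g  p=%.3g  p_adj=%.3g (family %d)%s\n",
              x$feature, x$focal_class, 100 * x$proportion_focal,
              x$baseline_class, 100 * x$proportion_baseline,
              x$odds_ratio, x$p_raw, x$p_adjusted, x$family_size,
              if (x$untestable) "  [UNTESTABLE]" else ""))
  invisible(x)
}

#' Class-vs-baseline Fisher enrichment in a 3D feature
#'
#' Two-sided Fisher exact test on the 2x2 table (in/out of feature x
#' focal/baseline class), with Bonferroni adjustment by an explicit family
#' size.  The odds ratio reported is the sample (cross-product) OR; the
#' p-value comes from the exact conditional (hypergeometric) distribution.
#' When a margin is zero (e.g. no focal introns assessed) the result is
#' flagged untestable rather than erroring, mirroring sparse real-data cells.
#'
#' @param matrix an `overlap_matrix`.
#' @param catalog the catalog the matrix was computed from.
#' @param focal_class,baseline_class intron classes; baseline defaults to
#'   the abundant major class used as the background distribution.
#' @param feature_type membership column to test (e.g. `"SPAD"`).
#'   Alternatively give `partition` + `category` to test assignment to a
#'   partition category (e.g. the "neither" compartment category).
#' @param partition,category see above.
#' @param family_size Bonferroni family size (>= 1); always explicit because
#'   the family depends on the analysis panel.
#' @return An `enrichment_result`.
#' @export
enrichment_fisher <- function(matrix, catalog, focal_class,
                              baseline_class = "major", feature_type = NULL,
                              partition = NULL, category = NULL,
                              family_size = 1) {
  stopifnot(family_size >= 1)
  cls <- catalog$records$intron_class[match(matrix$intron_id,
                                            catalog$records$intron_id)]
  if (!is.null(feature_type)) {
    if (!feature_type %in% names(matrix))
      stop("feature_type not in matrix: ", feature_type)
    memb <- matrix[[feature_type]]
    label <- feature_type
  } else {
    if (is.null(partition) || is.null(category))
      stop("give either feature_type or partition + category")
    col <- paste0("partition_", partition)
    if (!col %in% names(matrix)) stop("partition not present: ", partition)
    memb <- matrix[[col]] == category
    label <- paste0(partition, ":", category)
  }
  foc <- cls == focal_class
  bas <- cls == baseline_class
  make_enrichment_result(focal_class, baseline_class, label,
                         sum(memb & foc), sum(!memb & foc),
                         sum(memb & bas), sum(!memb & bas),
                         family_size)
}

#' Export an overlap matrix as a wide TSV of boolean flags
#' @param matrix an `overlap_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_overlap_matrix <- function(matrix, path) {
  utils::write.table(as.data.frame(matrix), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
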