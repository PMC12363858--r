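## Matched-size bootstrap and fractional-substitution ("pollution") nulls.

# Derive a per-replicate substream seed from one master seed, so that growing
# n_boot extends the replicate sequence without reshuffling earlier draws.
substream_seed <- function(master, i, tag = 0L) {
  as.integer((as.numeric(master) * 48271 + as.numeric(i) * 16807 +
                as.numeric(tag) * 69621) %% 2147483647)
}

with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  expr
}

membership_vector <- function(matrix, feature_type = NULL, partition = NULL,
                              category = NULL) {
  if (!is.null(feature_type)) {
    if (!feature_type %in% names(matrix))
      stop("feature_type not in matrix: ", feature_type)
    list(memb = matrix[[feature_type]], label = feature_type)
  } else {
    if (is.null(partition) || is.null(category))
      stop("give either feature_type or partition + category")
    col <- paste0("partition_", partition)
    if (!col %in% names(matrix)) stop("partition not present: ", partition)
    list(memb = matrix[[col]] == category,
         label = paste0(partition, ":", category))
  }
}

#' Matched-size bootstrap null for feature enrichment
#'
#' Draws `n_boot` random sets of `sample_size` baseline-class introns (without
#' replacement within a replicate, with replacement across replicates) and
#' records the proportion of each set inside the feature.  This asks whether a
#' focal class's enrichment could arise from picking any same-sized subset of
#' the abundant baseline — e.g. 1,000 random sets of 850 major introns matched
#' to the minor-intron count.
#'
#' @param matrix an `overlap_matrix`.
#' @param catalog the matching `intron_catalog`.
#' @param baseline_class class to resample from (typically `"major"`).
#' @param feature_type membership column, or use `partition` + `category`.
#' @param partition,category alternative feature selector.
#' @param sample_size introns per replicate (typically the focal class size).
#' @param n_boot number of replicates (default 1000).
#' @param seed master seed; per-replicate substreams are derived from it.
#' @param focal_class optional: class whose observed proportion is located
#'   within the bootstrap distribution.
#' @return A `bootstrap_distribution` list: `proportions` (length `n_boot`),
#'   `median`, `observed_focal`, `percentile_of_observed` (two-sided empirical
#'   tail with the (b+1)/(n_boot+1) correction), plus parameters.
#' @export
bootstrap_null <- function(matrix, catalog, baseline_class,
                           feature_type = NULL, partition = NULL,
                           category = NULL, sample_size, n_boot = 1000,
                           seed = 1, focal_class = NULL) {
  sel <- membership_vector(matrix, feature_type, partition, category)
  cls <- catalog$records$intron_class[match(matrix$intron_id,
                                            catalog$records$intron_id)]
  base_memb <- sel$memb[cls == baseline_class]
  n_base <- length(base_memb)
  if (sample_size > n_base)
    stop("sample_size (", sample_size, ") exceeds baseline class size (",
         n_base, ")")
  props <- with_preserved_rng({
    vapply(seq_len(n_boot), function(i) {
      set.seed(substream_seed(seed, i, tag = 1L))
      mean(base_memb[sample.int(n_base, sample_size)])
    }, numeric(1))
  })
  observed <- NA_real_
  pctl <- NA_real_
  if (!is.null(focal_class)) {
    fm <- sel$memb[cls == focal_class]
    observed <- mean(fm)
    b_le <- sum(props <= observed)
    b_ge <- sum(props >= observed)
    pctl <- min(1, 2 * min(b_le + 1, b_ge + 1) / (n_boot + 1))
  }
  structure(list(feature = sel$label, baseline_class = baseline_class,
                 sample_size = sample_size, n_boot = n_boot,
                 proportions = props, median = stats::median(props),
                 observed_focal = observed, percentile_of_observed = pctl,
                 seed = seed),
            class = "bootstrap_distribution")
}

#' Pollution curve: fractional substitution of focal for baseline introns
#'
#' For each substitution fraction f, each replicate draws
#' `round(f * n)` focal-class introns and `n - round(f * n)` baseline introns
#' (both without replacement; rounding is ties-to-even) and records the
#' proportion of the mixed set inside the feature.  With `sample_size` equal
#' to the focal class size, f = 1 reproduces the full focal set exactly, so a
#' trend of proportion with f demonstrates that enrichment tracks class
#' identity rather than set size.
#'
#' @inheritParams bootstrap_null
#' @param focal_class class substituted in.
#' @param fractions substitution fractions (default 0.1, 0.2, ..., 1.0).
#' @param sample_size set size per replicate; defaults to the focal class
#'   size, the construction under which f = 1 is the full focal set.
#' @return A `pollution_curve` list with `points` (data.frame fraction /
#'   replicate / proportion / n_focal / n_baseline) and parameters.
#' @export
pollution_curve <- function(matrix, catalog, baseline_class, focal_class,
                            feature_type = NULL, partition = NULL,
                            category = NULL,
                            fractions = seq(0.1, 1, by = 0.1),
                            n_boot = 1000, sample_size = NULL, seed = 1) {
  sel <- membership_vector(matrix, feature_type, partition, category)
  cls <- catalog$records$intron_class[match(matrix$intron_id,
                                            catalog$records$intron_id)]
  base_memb <- sel$memb[cls == baseline_class]
  focal_memb <- sel$memb[cls == focal_class]
  n_base <- length(base_memb)
  n_focal_avail <- length(focal_memb)
  if (is.null(sample_size)) sample_size <- n_focal_avail

  n_foc <- round(fractions * sample_size)   # ties-to-even
  n_bas <- sample_size - n_foc
  if (any(n_foc > n_focal_avail))
    stop("substituted count exceeds focal class size at fraction ",
         fractions[which(n_foc > n_focal_avail)[1]])
  if (any(n_bas > n_base))
    stop("baseline draw exceeds baseline class size")

  pts <- with_preserved_rng({
    do.call(rbind, lapply(seq_along(fractions), function(k) {
      f <- fractions[k]
      prop <- vapply(seq_len(n_boot), function(i) {
        set.seed(substream_seed(seed, i, tag = 100L + k))
        got <- 0
        if (n_bas[k] > 0)
          got <- got + sum(base_memb[sample.int(n_base, n_bas[k])])
        if (n_foc[k] > 0)
          got <- got + sum(focal_memb[sample.int(n_focal_avail, n_foc[k])])
        got / sample_size
      }, numeric(1))
      data.frame(fraction = f, replicate = seq_len(n_boot), proportion = prop,
                 n_focal = n_foc[k], n_baseline = n_bas[k])
    }))
  })
  structure(list(feature = sel$label, baseline_class = baseline_class,
                 focal_class = focal_class, fractions = fractions,
                 sample_size = sample_size, n_boot = n_boot, points = pts,
                 seed = seed),
            class = "pollution_curve")
}

#' Correlation of feature proportion with substitution fraction
#'
#' Pearson correlation between the substitution fraction and the replicate
#' proportions of a pollution curve, with a two-sided p-value.  A strong
#' positive r says enrichment rises steadily as focal introns replace
#' baseline introns.
#'
#' @param curve a `pollution_curve`.
#' @return List with `r`, `p`, `n_points`, `undefined` (TRUE when the
#'   proportions have zero variance, in which case r is NA and flagged).
#' @export
pollution_correlation <- function(curve) {
  stopifnot(inherits(curve, "pollution_curve"))
  pts <- curve$points
  if (length(unique(pts$fraction)) < 2)
    stop("need points at >= 2 distinct fractions")
  if (stats::var(pts$proportion) == 0)
    return(list(r = NA_real_, p = NA_real_, n_points = nrow(pts),
                undefined = TRUE))
  ct <- stats::cor.test(pts$fraction, pts$proportion, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n_points = nrow(pts),
       undefined = FALSE)
}
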