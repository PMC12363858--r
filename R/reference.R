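## Published hg38 catalog summary statistics.

#' Published hg38 intron-class summary
#'
#' Per-class intron counts and median inter-intron distances of the published
#' hg38 (Ensembl v99) classification of the human intron complement.  These
#' are the printed real-data summary values; they serve as inputs for
#' abundance-distance fits and as the documented expected outputs for users
#' who run the pipeline on the real catalog (which is far beyond synthetic
#' desk scale).
#'
#' @return data.frame with `intron_class`, `count`, `median_distance_bp`.
#' @export
hg38_class_summary <- function() {
  data.frame(
    intron_class = c("major", "major_like", "non_canonical", "minor",
                     "minor_like", "hybrid"),
    count = c(345317, 29337, 6070, 850, 458, 373),
    median_distance_bp = c(141, 27000, 105000, 1.8e6, 4.0e6, 6.1e6),
    stringsAsFactors = FALSE)
}

#' Published real-data expectations for the calibrated synthetic preset
#'
#' The generative parameters of the `"calibrated"` preset and the matching
#' real-data observations they encode: compartment-A rates (62% major, 71%
#' minor), SPAD rates (21% / 25%), LAD rates (19% / 14%), and the pollution
#' correlation (r = 0.89) observed for minor introns in compartment A.
#'
#' @return Named list of reference values (fractions, not percentages).
#' @export
calibrated_expectations <- function() {
  list(major_A = 0.62, minor_A = 0.71,
       major_SPAD = 0.21, minor_SPAD = 0.25,
       major_LAD = 0.19, minor_LAD = 0.14,
       pollution_r_minor_A = 0.89,
       bootstrap_median_A = 0.62)
}
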