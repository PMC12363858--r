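## Gene expression (TPM) and essentialome integration.

#' Load a gene-level TPM table
#'
#' @param path headered TSV with a `gene_id` column and one column per
#'   replicate.
#' @param replicate_columns optional character vector naming the replicate
#'   columns; defaults to every non-`gene_id` column.
#' @param cell_line cell line tag.
#' @return An `expression_table`: data.frame `gene_id`, replicate columns,
#'   `mean_tpm` (arithmetic mean of replicates).
#' @export
load_expression <- function(path, replicate_columns = NULL,
                            cell_line = NA_character_) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(tab)) stop("TPM table lacks a gene_id column")
  if (is.null(replicate_columns))
    replicate_columns <- setdiff(names(tab), "gene_id")
  if (length(replicate_columns) < 1) stop("need >= 1 replicate column")
  miss <- setdiff(replicate_columns, names(tab))
  if (length(miss)) stop("replicate column(s) absent: ",
                         paste(miss, collapse = ", "))
  expression_table(tab$gene_id,
                   as.matrix(tab[, replicate_columns, drop = FALSE]),
                   cell_line)
}

#' Construct an expression table from gene ids and a replicate TPM matrix
#' @param gene_id character vector.
#' @param tpm numeric matrix, one row per gene, one column per replicate.
#' @param cell_line cell line tag.
#' @return An `expression_table`.
#' @export
expression_table <- function(gene_id, tpm, cell_line = NA_character_) {
  tpm <- as.matrix(tpm)
  if (anyDuplicated(gene_id))
    stop("duplicated gene_id: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (any(tpm < 0)) stop("negative TPM values")
  out <- data.frame(gene_id = as.character(gene_id), stringsAsFactors = FALSE)
  cn <- colnames(tpm)
  if (is.null(cn)) cn <- paste0("rep", seq_len(ncol(tpm)))
  for (j in seq_len(ncol(tpm))) out[[cn[j]]] <- tpm[, j]
  out$mean_tpm <- rowMeans(tpm)
  attr(out, "replicates") <- cn
  attr(out, "cell_line") <- cell_line
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Expressed flag per gene at a TPM threshold
#'
#' A gene is expressed when the mean of its replicate TPM values is greater
#' than or equal to the threshold (inclusive comparison).
#'
#' @param expr an `expression_table`.
#' @param threshold TPM threshold (typical values 1 and 20).
#' @return Named logical vector over the table's genes.
#' @export
expressed_genes <- function(expr, threshold = 1) {
  stats::setNames(expr$mean_tpm >= threshold, expr$gene_id)
}

# Expression flag for a vector of gene ids; genes absent from the table are
# treated as not expressed (count reported via message).
gene_expressed_lookup <- function(gene_ids, expr, threshold) {
  flags <- expressed_genes(expr, threshold)
  out <- unname(flags[gene_ids])
  n_missing <- sum(is.na(out))
  if (n_missing > 0) {
    message(n_missing, " intron gene(s) absent from the TPM table; ",
            "treated as not expressed")
    out[is.na(out)] <- FALSE
  }
  out
}

#' Expression-stratified enrichment within a 3D feature
#'
#' Among introns of each class that are members of the feature, tests whether
#' the focal class sits in expressed genes more often than the baseline class
#' (two-sided Fisher, Bonferroni by `family_size`).  Genes missing from the
#' TPM table count as not expressed.
#'
#' @inheritParams enrichment_fisher
#' @param expr an `expression_table` for the matching cell line.
#' @param threshold TPM threshold for "expressed" (inclusive; default 1).
#' @return An `enrichment_result` whose proportions are the expressed
#'   fractions within the feature-resident introns of each class.
#' @export
stratified_enrichment <- function(matrix, catalog, expr, threshold = 1,
                                  focal_class, baseline_class = "major",
                                  feature_type = NULL, partition = NULL,
                                  category = NULL, family_size = 1) {
  sel <- membership_vector(matrix, feature_type, partition, category)
  rec <- catalog$records[match(matrix$intron_id, catalog$records$intron_id), ]
  expressed <- gene_expressed_lookup(rec$gene_id, expr, threshold)
  inside <- sel$memb
  foc <- rec$intron_class == focal_class & inside
  bas <- rec$intron_class == baseline_class & inside
  make_enrichment_result(focal_class, baseline_class,
                         paste0(sel$label, " | expressed@", threshold),
                         sum(foc & expressed), sum(foc & !expressed),
                         sum(bas & expressed), sum(bas & !expressed),
                         family_size)
}

#' Load essentialome gene sets
#'
#' @param total_path one-gene-per-line file: genes essential in at least one
#'   surveyed cell line.
#' @param core_path one-gene-per-line file: genes essential in every surveyed
#'   cell line.  Must be a subset of the total essentialome; violations are
#'   reported and the offending genes added to the total so the invariant
#'   holds.
#' @return An `essentialome_sets` list with character sets `total`, `core`.
#' @export
load_essentialome <- function(total_path, core_path) {
  read_set <- function(p) {
    x <- readLines(p, warn = FALSE)
    unique(trimws(x[nzchar(trimws(x)) & !startsWith(trimws(x), "#")]))
  }
  total <- read_set(total_path)
  core <- read_set(core_path)
  stray <- setdiff(core, total)
  if (length(stray)) {
    warning("core essentialome gene(s) missing from total: ",
            paste(stray, collapse = ", "), "; added to total")
    total <- union(total, stray)
  }
  structure(list(total = total, core = core), class = "essentialome_sets")
}

#' Essentiality-conditioned enrichment
#'
#' Three comparisons around the essentialome:
#' \describe{
#'   \item{`class_vs_class`}{gene-level: are genes carrying the focal intron
#'     class more often essential than genes carrying the baseline class?
#'     A gene with several introns of a class counts once.}
#'   \item{`feature_within_scope`}{intron-level: focal vs baseline membership
#'     in a 3D feature, restricted to introns of essential-only or
#'     non-essential-only genes (or all genes).}
#'   \item{`essential_vs_all`}{intron-level, within one class: feature
#'     membership of the essential-gene subset against the full class.}
#' }
#'
#' @param catalog an `intron_catalog`.
#' @param sets an `essentialome_sets`.
#' @param matrix an `overlap_matrix` (required except for `class_vs_class`).
#' @param focal_class,baseline_class intron classes (for `essential_vs_all`
#'   only `focal_class` is used).
#' @param comparison which design to run, see above.
#' @param scope gene subset for `feature_within_scope`.
#' @param essential_set `"total"` or `"core"` essentialome.
#' @param feature_type,partition,category feature selector (as in
#'   [enrichment_fisher()]).
#' @param family_size Bonferroni family size.
#' @return An `enrichment_result` (flagged untestable when a scope subset is
#'   empty).
#' @export
essentiality_enrichment <- function(catalog, sets, matrix = NULL,
                                    focal_class, baseline_class = "major",
                                    comparison = c("class_vs_class",
                                                   "feature_within_scope",
                                                   "essential_vs_all"),
                                    scope = c("all_genes", "essential_only",
                                              "non_essential_only"),
                                    essential_set = c("total", "core"),
                                    feature_type = NULL, partition = NULL,
                                    category = NULL, family_size = 1) {
  comparison <- match.arg(comparison)
  scope <- match.arg(scope)
  essential_set <- match.arg(essential_set)
  ess <- sets[[essential_set]]
  rec <- catalog$records

  if (comparison == "class_vs_class") {
    genes_f <- unique(rec$gene_id[rec$intron_class == focal_class])
    genes_b <- unique(rec$gene_id[rec$intron_class == baseline_class])
    return(make_enrichment_result(
      focal_class, baseline_class,
      paste0("essentialome:", essential_set),
      sum(genes_f %in% ess), sum(!genes_f %in% ess),
      sum(genes_b %in% ess), sum(!genes_b %in% ess),
      family_size))
  }

  if (is.null(matrix))
    stop("an overlap_matrix is required for comparison '", comparison, "'")
  sel <- membership_vector(matrix, feature_type, partition, category)
  mrec <- rec[match(matrix$intron_id, rec$intron_id), ]
  gene_ess <- mrec$gene_id %in% ess

  if (comparison == "feature_within_scope") {
    keep <- switch(scope,
                   all_genes = rep(TRUE, nrow(mrec)),
                   essential_only = gene_ess,
                   non_essential_only = !gene_ess)
    foc <- keep & mrec$intron_class == focal_class
    bas <- keep & mrec$intron_class == baseline_class
    return(make_enrichment_result(
      focal_class, baseline_class,
      paste0(sel$label, " | ", scope, ":", essential_set),
      sum(foc & sel$memb), sum(foc & !sel$memb),
      sum(bas & sel$memb), sum(bas & !sel$memb),
      family_size))
  }

  # essential_vs_all: the essential-gene subset of a class vs the full class
  in_class <- mrec$intron_class == focal_class
  sub <- in_class & gene_ess
  make_enrichment_result(
    paste0(focal_class, ":essential"), paste0(focal_class, ":all"),
    paste0(sel$label, " | ", essential_set),
    sum(sub & sel$memb), sum(sub & !sel$memb),
    sum(in_class & sel$memb), sum(in_class & !sel$memb),
    family_size)
}
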