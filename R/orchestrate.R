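## Full-study orchestration: run every stage from one configuration.

#' Build a run configuration
#'
#' @param catalog_path intron catalog (BED dialect).
#' @param chrom_sizes_path two-column chrom sizes TSV.
#' @param gene_models_path GTF of exon models (needed for splicing stages).
#' @param cell_lines named list; each element a list with `tracks` (named
#'   list feature_type -> BED path), `tpm` (TSV path) and optionally
#'   `alignments` (SAM/BAM path).
#' @param essentialome_total,essentialome_core gene-list paths (optional).
#' @param reference_cell_line reference line for cross-line stages.
#' @param out_dir output directory.
#' @param min_overlap_frac,tpm_threshold,fdr thresholds.
#' @param n_boot,fractions,seed resampling parameters.
#' @param subsample subsampling sizes for abundant classes.
#' @return A validated `run_config` list.
#' @export
run_config <- function(catalog_path, chrom_sizes_path,
                       gene_models_path = NULL, cell_lines,
                       essentialome_total = NULL, essentialome_core = NULL,
                       reference_cell_line = names(cell_lines)[1],
                       out_dir, min_overlap_frac = 0.5, tpm_threshold = 1,
                       fdr = 0.05, n_boot = 1000,
                       fractions = seq(0.1, 1, 0.1), seed = 1,
                       subsample = c(major = 5000, major_like = 5000)) {
  cfg <- list(catalog_path = catalog_path,
              chrom_sizes_path = chrom_sizes_path,
              gene_models_path = gene_models_path, cell_lines = cell_lines,
              essentialome_total = essentialome_total,
              essentialome_core = essentialome_core,
              reference_cell_line = reference_cell_line, out_dir = out_dir,
              min_overlap_frac = min_overlap_frac,
              tpm_threshold = tpm_threshold, fdr = fdr, n_boot = n_boot,
              fractions = fractions, seed = seed, subsample = subsample)
  must_exist <- c(catalog_path, chrom_sizes_path, gene_models_path,
                  essentialome_total, essentialome_core,
                  unlist(lapply(cell_lines, function(cl)
                    c(unlist(cl$tracks), cl$tpm, cl$alignments))))
  missing <- must_exist[!vapply(must_exist, file.exists, logical(1))]
  if (length(missing))
    stop("run_config: missing input file(s): ", paste(missing, collapse = ", "))
  structure(cfg, class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis from a configuration
#'
#' Executes, per cell line, the catalog -> overlap -> resampling -> gene
#' context -> splicing -> cross-line stage sequence, writing every table as
#' TSV under the configured output directory together with a JSON manifest
#' (seed, parameters, parameter hash, per-table row counts, skipped stages).
#' Stages whose inputs are missing are skipped and recorded; a stage failure
#' marks the bundle partial and preserves the error.
#'
#' @param config a `run_config`.
#' @return A `report_bundle` list: `manifest`, `tables` (paths), in-memory
#'   `results`, and `status` (`"complete"` or `"partial"`).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list(); skipped <- list(); errors <- list()
  results <- list()

  catalog <- load_intron_catalog(config$catalog_path, "bed_zero_half_open",
                                 config$chrom_sizes_path)
  results$class_counts <- class_counts(catalog)

  ## linear-genome statistics
  dist_tab <- do.call(rbind, lapply(INTRON_CLASSES, function(cl) {
    s <- inter_intron_distances(catalog, cl)
    data.frame(intron_class = cl, n_pairs = s$n_pairs,
               median_bp = s$median_bp)
  }))
  tables$distances <- write_tsv(dist_tab,
                                file.path(config$out_dir, "distances.tsv"))
  ok <- !is.na(dist_tab$median_bp) & dist_tab$median_bp > 0 &
    results$class_counts[dist_tab$intron_class] > 0
  if (sum(ok) >= 2) {
    fit <- abundance_distance_fit(
      stats::setNames(results$class_counts[dist_tab$intron_class[ok]],
                      dist_tab$intron_class[ok]),
      stats::setNames(dist_tab$median_bp[ok], dist_tab$intron_class[ok]))
    results$abundance_distance_fit <- fit
    jsonlite::write_json(fit, file.path(config$out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA)
    tables$fit <- file.path(config$out_dir, "fit.json")
  }
  bins <- bin_intron_density(catalog)
  scan <- scan_density_clusters(bins, fdr = config$fdr)
  tables$density_scan <- write_tsv(scan,
                                   file.path(config$out_dir,
                                             "density_scan.tsv"))

  gene_models <- if (!is.null(config$gene_models_path))
    load_gene_models(config$gene_models_path) else NULL
  ess <- if (!is.null(config$essentialome_total) &&
             !is.null(config$essentialome_core))
    load_essentialome(config$essentialome_total, config$essentialome_core)
  else NULL

  matrices <- list(); all_records <- list()
  for (cl_name in names(config$cell_lines)) {
    cl <- config$cell_lines[[cl_name]]
    stage <- function(label, expr) {
      tryCatch(expr, error = function(e) {
        errors[[paste(cl_name, label, sep = ":")]] <<- conditionMessage(e)
        NULL
      })
    }
    tracks <- stage("tracks", lapply(names(cl$tracks), function(ty)
      load_feature_track(cl$tracks[[ty]], ty, cl_name)))
    if (is.null(tracks)) next
    m <- stage("membership",
               assign_membership(catalog, tracks, config$min_overlap_frac))
    if (is.null(m)) next
    matrices[[cl_name]] <- m
    tables[[paste0(cl_name, "_membership")]] <-
      write_tsv(as.data.frame(m),
                file.path(config$out_dir, paste0(cl_name, "_membership.tsv")))
    for (pn in names(PARTITIONS)) {
      col <- paste0("partition_", pn)
      if (!col %in% names(m)) next
      pr <- class_proportions(m, catalog, pn)
      tables[[paste0(cl_name, "_proportions_", pn)]] <-
        write_tsv(pr, file.path(config$out_dir,
                                paste0(cl_name, "_proportions_", pn, ".tsv")))
    }

    ## class-vs-major enrichment across partitions present
    enr_rows <- NULL
    rare <- setdiff(INTRON_CLASSES, "major")
    for (pn in names(PARTITIONS)) {
      col <- paste0("partition_", pn)
      if (!col %in% names(m)) next
      cats <- unique(m[[col]])
      fam <- length(rare) * length(cats)
      for (fc in rare) for (cat in cats) {
        er <- enrichment_fisher(m, catalog, fc, "major", partition = pn,
                                category = cat, family_size = fam)
        enr_rows <- rbind(enr_rows, data.frame(
          cell_line = cl_name, partition = pn, category = cat,
          focal_class = fc, proportion_focal = er$proportion_focal,
          proportion_baseline = er$proportion_baseline,
          odds_ratio = er$odds_ratio, p_raw = er$p_raw,
          p_adjusted = er$p_adjusted, family_size = er$family_size,
          untestable = er$untestable))
      }
    }
    if (!is.null(enr_rows))
      tables[[paste0(cl_name, "_enrichment")]] <-
        write_tsv(enr_rows, file.path(config$out_dir,
                                      paste0(cl_name, "_enrichment.tsv")))

    ## resampling nulls on the compartment partition (reference line only)
    if (cl_name == config$reference_cell_line &&
        "partition_compartment" %in% names(m)) {
      n_minor <- sum(catalog$records$intron_class == "minor")
      if (n_minor >= 2 &&
          sum(catalog$records$intron_class == "major") >= n_minor) {
        bs <- bootstrap_null(m, catalog, "major", partition = "compartment",
                             category = "A", sample_size = n_minor,
                             n_boot = config$n_boot, seed = config$seed,
                             focal_class = "minor")
        pc <- pollution_curve(m, catalog, "major", "minor",
                              partition = "compartment", category = "A",
                              fractions = config$fractions,
                              n_boot = config$n_boot, seed = config$seed)
        pr <- pollution_correlation(pc)
        results$bootstrap <- bs
        results$pollution <- list(curve = pc, correlation = pr)
        tables$resampling <- write_tsv(
          pc$points, file.path(config$out_dir, "pollution_points.tsv"))
        jsonlite::write_json(
          list(bootstrap_median = bs$median,
               observed_minor = bs$observed_focal,
               percentile_of_observed = bs$percentile_of_observed,
               pollution_r = pr$r, pollution_p = pr$p,
               n_boot = config$n_boot, seed = config$seed),
          file.path(config$out_dir, "resampling_summary.json"),
          auto_unbox = TRUE, digits = NA)
        tables$resampling_summary <-
          file.path(config$out_dir, "resampling_summary.json")
      }
    }

    ## expression context
    expr <- NULL
    if (!is.null(cl$tpm)) {
      expr <- stage("expression", load_expression(cl$tpm, cell_line = cl_name))
      if (!is.null(expr) && "partition_compartment" %in% names(m)) {
        se <- stage("stratified", stratified_enrichment(
          m, catalog, expr, threshold = config$tpm_threshold,
          focal_class = "minor", baseline_class = "major",
          partition = "compartment", category = "A", family_size = 1))
        if (!is.null(se)) results[[paste0(cl_name, "_stratified_A")]] <- se
      }
    }

    ## essentiality context (reference line)
    if (!is.null(ess) && cl_name == config$reference_cell_line &&
        "partition_compartment" %in% names(m)) {
      results$essentiality <- stage("essentiality", list(
        minor_vs_major_total = essentiality_enrichment(
          catalog, ess, comparison = "class_vs_class", focal_class = "minor"),
        minor_essential_vs_all_A = essentiality_enrichment(
          catalog, ess, m, focal_class = "minor",
          comparison = "essential_vs_all", partition = "compartment",
          category = "A")))
    }

    ## splicing stage
    if (!is.null(cl$alignments) && !is.null(gene_models)) {
      rec <- stage("splicing", {
        ev <- extract_junction_evidence(cl$alignments, catalog, gene_models,
                                        cell_line = cl_name)
        splicing_index_records(ev, catalog, expr = expr, matrix = m)
      })
      if (!is.null(rec)) {
        filtered <- filter_for_analysis(rec,
                                        tpm_threshold = if (!is.null(expr))
                                          config$tpm_threshold else NULL,
                                        subsample = config$subsample,
                                        seed = config$seed)
        all_records[[cl_name]] <- filtered
        tables[[paste0(cl_name, "_splicing")]] <-
          write_tsv(filtered, file.path(config$out_dir,
                                        paste0(cl_name, "_splicing.tsv")))
      }
    } else if (!is.null(cl$alignments) || !is.null(gene_models)) {
      skipped[[paste0(cl_name, ":splicing")]] <-
        "missing alignments or gene models"
    } else {
      skipped[[paste0(cl_name, ":splicing")]] <- "no alignments configured"
    }
  }

  ## cross-line stages
  shared_lines <- intersect(names(matrices), names(all_records))
  if (length(shared_lines) >= 2 &&
      config$reference_cell_line %in% shared_lines) {
    ml <- matched_location_sets(matrices[shared_lines],
                                all_records[shared_lines],
                                config$reference_cell_line,
                                catalog = catalog)
    results$matched_sets <- ml
    tables$matched_sets <- write_tsv(
      ml$pairwise$summary, file.path(config$out_dir, "matched_sets.tsv"))
    others <- setdiff(shared_lines, config$reference_cell_line)
    shared_neither <- lapply(others, function(ln)
      ml$pairwise$sets[[paste(ln, "minor", "neither", sep = "|")]])
    names(shared_neither) <- others
    imp <- improved_splicing_intersection(
      all_records[[config$reference_cell_line]], all_records[others],
      shared_neither, catalog)
    results$improved <- imp
  } else {
    skipped$cross_line <- "needs splicing records for >= 2 cell lines"
  }

  params_for_hash <- config[setdiff(names(config), "out_dir")]
  param_json <- file.path(config$out_dir, "parameters.json")
  jsonlite::write_json(params_for_hash, param_json, auto_unbox = TRUE,
                       force = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("intronSpace")),
    seed = config$seed, parameter_hash = unname(tools::md5sum(param_json)),
    tables = lapply(tables, function(p) {
      n <- if (grepl("\\.tsv$", p))
        length(readLines(p)) - 1L else NA_integer_
      list(path = p, rows = n)
    }),
    skipped = skipped, errors = errors)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, force = TRUE)
  structure(list(manifest = manifest, tables = tables, results = results,
                 status = if (length(errors)) "partial" else "complete"),
            class = "report_bundle")
}

#' Export improved-splicing gene lists for external GO analysis
#'
#' One plain-text file per set (each comparison line and the intersection),
#' deduplicated and sorted; empty sets produce a file with only a header
#' comment.
#'
#' @param improved output of [improved_splicing_intersection()] (or the
#'   `results$improved` slot of a `report_bundle`).
#' @param out_dir directory for the lists.
#' @param prefix filename prefix.
#' @return Named character vector of written paths.
#' @export
export_gene_lists <- function(improved, out_dir, prefix = "improved") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_set <- function(genes, path) {
    if (length(genes) == 0) {
      writeLines("# empty gene set", path)
    } else {
      writeLines(sort(unique(genes)), path)
    }
    path
  }
  paths <- c()
  for (ln in names(improved$per_line)) {
    p <- file.path(out_dir, paste0(prefix, "_", ln, ".txt"))
    paths[ln] <- write_set(improved$per_line[[ln]]$gene_ids, p)
  }
  paths["intersection"] <- write_set(
    improved$intersection$gene_ids,
    file.path(out_dir, paste0(prefix, "_intersection.txt")))
  paths
}
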