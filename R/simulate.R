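## Synthetic study generator: annotation, 3D tracks, expression, alignments.

#' Configuration for a synthetic study
#'
#' The `"calibrated"` preset encodes the published real-data
#' proportions as generative placement probabilities (compartment-A rates
#' 0.62 major / 0.71 minor, SPAD 0.21 / 0.25, LAD 0.19 / 0.14, and the
#' sibling class rates), so that pipeline runs on synthetic data reproduce
#' the direction of the real enrichment patterns with known ground truth.
#' Class counts keep the abundance ordering of the real catalog at a
#' desk-friendly scale, with the minor class pinned at 850 so the matched
#' bootstrap construction (850-intron sets) is exercised verbatim.
#'
#' @param preset `"calibrated"` (the default, encoding the published rates) or `"uniform"` (no
#'   spatial bias; all classes share the major rates).
#' @param scale multiplies all class counts (default 1).
#' @param ... overrides for any config field.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(preset = c("calibrated", "uniform"), scale = 1, ...) {
  preset <- match.arg(preset)
  cls <- INTRON_CLASSES
  comp <- rbind(major         = c(0.62, 0.28, 0.10),
                major_like    = c(0.64, 0.26, 0.10),
                hybrid        = c(0.51, 0.32, 0.17),
                minor_like    = c(0.62, 0.28, 0.10),
                minor         = c(0.71, 0.19, 0.10),
                non_canonical = c(0.50, 0.28, 0.22))
  colnames(comp) <- c("A", "B", "neither")
  nb <- rbind(major         = c(0.21, 0.19, 0.60),
              major_like    = c(0.27, 0.17, 0.56),
              hybrid        = c(0.09, 0.31, 0.60),
              minor_like    = c(0.21, 0.19, 0.60),
              minor         = c(0.25, 0.14, 0.61),
              non_canonical = c(0.17, 0.25, 0.58))
  colnames(nb) <- c("SPAD", "LAD", "neither")
  a1_given_A <- c(major = 0.73, major_like = 0.77, hybrid = 0.73,
                  minor_like = 0.73, minor = 0.73, non_canonical = 0.76)
  subB <- rbind(major         = c(0.39, 0.28, 0.33),
                major_like    = c(0.41, 0.28, 0.31),
                hybrid        = c(0.30, 0.37, 0.33),
                minor_like    = c(0.34, 0.25, 0.41),
                minor         = c(0.39, 0.28, 0.33),
                non_canonical = c(0.43, 0.33, 0.24))
  colnames(subB) <- c("B1", "B2", "B3")
  if (preset == "uniform") {
    comp <- matrix(rep(comp["major", ], each = 6), nrow = 6,
                   dimnames = dimnames(comp))
    nb <- matrix(rep(nb["major", ], each = 6), nrow = 6,
                 dimnames = dimnames(nb))
    a1_given_A[] <- a1_given_A[["major"]]
    subB <- matrix(rep(subB["major", ], each = 6), nrow = 6,
                   dimnames = dimnames(subB))
  }
  cfg <- list(
    preset = preset,
    class_counts = round(c(major = 10000, major_like = 2000, hybrid = 100,
                           minor_like = 120, minor = 850,
                           non_canonical = 600) * scale),
    one_rare_per_gene = TRUE,
    introns_per_gene = 2:8,
    exon_len = 120,
    intron_len_meanlog = log(800), intron_len_sdlog = 0.6,
    intron_len_range = c(100, 20000),
    intergenic_gap = 5000,
    n_chrom = 4, chrom_lengths = NULL,
    placement = list(compartment = comp, nuclear_body = nb,
                     a1_given_A = a1_given_A, subcompartment_B = subB),
    spad_in_A = NULL,   # NULL: SPAD membership independent of compartment
    expression = list(frac_expressed = 0.75, n_replicates = 2,
                      rep_noise_sd = 0.05,
                      expressed_meanlog = log(18), expressed_sdlog = 1),
    essentialome = list(p_essential_mig = 0.55, p_essential_default = 0.30,
                        p_essential_non_canonical = 0.15, p_core_given_total = 0.30),
    splicing = list(
      psi_mean = c(major = 0.05, major_like = 0.15, hybrid = 0.30,
                   minor_like = 0.20, minor = 0.08, non_canonical = 0.35),
      sigma_mean = c(major = 0.05, major_like = 0.12, hybrid = 0.20,
                     minor_like = 0.15, minor = 0.03, non_canonical = 0.25),
      concentration = 30),
    depth = 100, read_len = 50, cryptic_rate = 0,
    cell_lines = "SYN1")
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  bad <- vapply(cfg$placement[c("compartment", "nuclear_body")], function(m)
    any(m < 0 | m > 1) || any(abs(rowSums(m) - 1) > 1e-8), logical(1))
  if (any(bad)) stop("placement probabilities must be in [0,1] and rows sum to 1")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic annotation: gene models with class-labelled introns
#'
#' Lays out non-overlapping genes of alternating exons and introns across the
#' synthetic chromosomes.  Each rare intron is placed in its own gene (the
#' remaining introns of that gene being major), matching the observation that
#' genes carrying a rare intron usually carry exactly one; leftover major
#' introns fill major-only genes.  Class counts match the configuration
#' exactly.
#'
#' @param config a `synthetic_config`.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return List: `catalog` (an `intron_catalog`), `gene_models` (exon
#'   data.frame), `genes` (per-gene table), `truth` (per-intron class/gene).
#' @export
generate_annotation <- function(config, seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  with_preserved_rng({
    set.seed(substream_seed(seed, 1, tag = 11L))
    counts <- config$class_counts
    rare_cls <- setdiff(names(counts)[counts > 0], "major")
    rare_labels <- rep(rare_cls, counts[rare_cls])
    n_major <- if ("major" %in% names(counts)) counts[["major"]] else 0L

    ## gene composition: one rare intron per gene, padded with majors
    resample1 <- function(x) x[sample.int(length(x), 1)]
    gene_classes <- list()
    major_left <- n_major
    for (lab in rare_labels) {
      size <- resample1(config$introns_per_gene)
      n_pad <- min(size - 1, major_left)
      major_left <- major_left - n_pad
      cls_vec <- c(lab, rep("major", n_pad))
      gene_classes[[length(gene_classes) + 1]] <-
        cls_vec[sample.int(length(cls_vec))]
    }
    while (major_left > 0) {
      size <- min(resample1(config$introns_per_gene), major_left)
      gene_classes[[length(gene_classes) + 1]] <- rep("major", size)
      major_left <- major_left - size
    }
    if (!config$one_rare_per_gene && length(rare_labels) > 1) {
      # permissive mode: shuffle rare labels across genes (may co-house rares)
      flat <- unlist(gene_classes)
      flat <- flat[sample.int(length(flat))]
      gene_classes <- split(flat, rep(seq_along(gene_classes),
                                      lengths(gene_classes)))
    }
    n_gene <- length(gene_classes)
    gene_chrom_idx <- rep(seq_len(config$n_chrom), length.out = n_gene)
    chroms <- paste0("chrS", seq_len(config$n_chrom))

    draw_intron_len <- function(k) {
      L <- round(stats::rlnorm(k, config$intron_len_meanlog,
                               config$intron_len_sdlog))
      pmin(pmax(L, config$intron_len_range[1]), config$intron_len_range[2])
    }

    cursor <- stats::setNames(rep(0, config$n_chrom), chroms)
    rec <- vector("list", n_gene)
    exons <- vector("list", n_gene)
    gene_tab <- vector("list", n_gene)
    for (gi in seq_len(n_gene)) {
      cls_vec <- gene_classes[[gi]]
      k <- length(cls_vec)
      ch <- chroms[gene_chrom_idx[gi]]
      gstart <- cursor[[ch]] + config$intergenic_gap
      ilens <- draw_intron_len(k)
      estarts <- numeric(k + 1)
      istarts <- numeric(k)
      pos <- gstart
      for (j in seq_len(k + 1)) {
        estarts[j] <- pos
        pos <- pos + config$exon_len
        if (j <= k) { istarts[j] <- pos; pos <- pos + ilens[j] }
      }
      gend <- pos
      cursor[[ch]] <- gend
      gid <- sprintf("gene%05d", gi)
      strand <- if (gi %% 2 == 0) "-" else "+"
      rec[[gi]] <- data.frame(
        intron_id = sprintf("%s.i%d", gid, seq_len(k)),
        chrom = ch, start = istarts, end = istarts + ilens,
        strand = strand, gene_id = gid, intron_class = cls_vec,
        rank = seq_len(k), stringsAsFactors = FALSE)
      exons[[gi]] <- data.frame(
        gene_id = gid, chrom = ch, start = estarts,
        end = estarts + config$exon_len, strand = strand,
        stringsAsFactors = FALSE)
      gene_tab[[gi]] <- data.frame(gene_id = gid, chrom = ch,
                                   start = gstart, end = gend,
                                   strand = strand, n_introns = k,
                                   rare_class = {
                                     rc <- setdiff(unique(cls_vec), "major")
                                     if (length(rc)) rc[1] else NA_character_
                                   },
                                   stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, rec)
    gene_models <- do.call(rbind, exons)
    genes <- do.call(rbind, gene_tab)

    needed <- cursor + config$intergenic_gap
    if (is.null(config$chrom_lengths)) {
      chrom_sizes <- needed
    } else {
      chrom_sizes <- config$chrom_lengths
      short <- names(needed)[needed > chrom_sizes[names(needed)]]
      if (length(short))
        stop("configured chromosome(s) too short: ",
             paste(short, collapse = ", "), "; required ",
             paste(round(needed[short]), collapse = ", "), " bp")
    }
    catalog <- intron_catalog(records, chrom_sizes,
                              provenance = paste0("synthetic:", config$preset))
    list(catalog = catalog, gene_models = gene_models, genes = genes,
         truth = records[, c("intron_id", "gene_id", "intron_class")])
  })
}

#' Generate 3D feature tracks with class-specific placement probabilities
#'
#' Each intron independently draws a compartment category (A/B/neither), a
#' conditional subcompartment, and a nuclear-body category (SPAD/LAD/neither)
#' from its class's configured probabilities.  Track intervals are the member
#' introns' own intervals, so the 50%-overlap rule recovers the drawn
#' membership exactly.  When `spad_in_A` is set, the SPAD draw is conditioned
#' on the compartment so that P(A | SPAD) equals the configured concordance
#' while both marginal rates are preserved (an error is raised when the
#' requested nesting is infeasible).
#'
#' @param config a `synthetic_config`.
#' @param catalog catalog from [generate_annotation()].
#' @param seed integer seed.
#' @param cell_line tag for the emitted tracks.
#' @return List: `tracks` (named list of `feature_track`), `truth`
#'   (data.frame intron_id, compartment, subcompartment, nuclear_body).
#' @export
generate_feature_tracks <- function(config, catalog, seed = 1,
                                    cell_line = config$cell_lines[1]) {
  stopifnot(inherits(config, "synthetic_config"))
  r <- catalog$records
  comp_p <- config$placement$compartment
  nb_p <- config$placement$nuclear_body
  with_preserved_rng({
    set.seed(substream_seed(seed, 2, tag = 12L))
    n <- nrow(r)
    draw_cat <- function(pmat, cls) {
      u <- stats::runif(n)
      cum <- t(apply(pmat, 1, cumsum))
      cats <- colnames(pmat)
      idx <- matrix(cum[cls, ], nrow = n)
      out <- cats[1 + (u > idx[, 1]) + (u > idx[, 2])]
      out
    }
    comp <- draw_cat(comp_p, r$intron_class)

    ## nuclear body, optionally nested in compartment A
    if (is.null(config$spad_in_A)) {
      nb <- draw_cat(nb_p, r$intron_class)
    } else {
      nest <- config$spad_in_A   # target P(A | SPAD)
      pS <- nb_p[r$intron_class, "SPAD"]
      pA <- comp_p[r$intron_class, "A"]
      p_in <- pS * nest / pA
      p_out <- pS * (1 - nest) / (1 - pA)
      if (any(p_in > 1) || any(p_out > 1))
        stop("inconsistent nesting: spad_in_A = ", nest,
             " is infeasible for the configured marginal rates")
      u <- stats::runif(n)
      spad <- ifelse(comp == "A", u < p_in, u < p_out)
      pL <- nb_p[r$intron_class, "LAD"]
      lad <- !spad & stats::runif(n) < pL / (1 - pS)
      nb <- ifelse(spad, "SPAD", ifelse(lad, "LAD", "neither"))
    }

    ## subcompartment conditional on compartment
    sub <- rep("neither", n)
    inA <- comp == "A"
    a1p <- config$placement$a1_given_A[r$intron_class]
    sub[inA] <- ifelse(stats::runif(sum(inA)) < a1p[inA], "A1", "A2")
    inB <- comp == "B"
    if (any(inB)) {
      bdraw <- draw_cat(config$placement$subcompartment_B, r$intron_class)
      sub[inB] <- bdraw[inB]
    }

    truth <- data.frame(intron_id = r$intron_id, compartment = comp,
                        subcompartment = sub, nuclear_body = nb,
                        stringsAsFactors = FALSE)
    mk <- function(sel, type) {
      feature_track(r[sel, c("chrom", "start", "end")], type, cell_line)
    }
    tracks <- list(
      compartment_A = mk(comp == "A", "compartment_A"),
      compartment_B = mk(comp == "B", "compartment_B"),
      A1 = mk(sub == "A1", "A1"), A2 = mk(sub == "A2", "A2"),
      B1 = mk(sub == "B1", "B1"), B2 = mk(sub == "B2", "B2"),
      B3 = mk(sub == "B3", "B3"),
      SPAD = mk(nb == "SPAD", "SPAD"), LAD = mk(nb == "LAD", "LAD"))
    list(tracks = tracks, truth = truth)
  })
}

#' Generate a replicate TPM table with known expression truth
#'
#' Expressed genes (Bernoulli with the configured fraction) draw a mean TPM
#' comfortably above 1; unexpressed genes draw below 1.  Replicates jitter
#' the mean log-normally.  Truth flags are re-derived from the emitted
#' replicate means, so truth and files can never disagree.
#'
#' @param config a `synthetic_config`.
#' @param genes per-gene table from [generate_annotation()] (or a vector of
#'   gene ids).
#' @param seed integer seed.
#' @param cell_line tag.
#' @return List: `expr` (an `expression_table`), `truth` (gene_id,
#'   true_mean, expressed_1, expressed_20).
#' @export
generate_expression <- function(config, genes, seed = 1,
                                cell_line = config$cell_lines[1]) {
  gene_ids <- if (is.data.frame(genes)) genes$gene_id else genes
  e <- config$expression
  with_preserved_rng({
    set.seed(substream_seed(seed, 3, tag = 13L))
    ng <- length(gene_ids)
    on_flag <- stats::runif(ng) < e$frac_expressed
    mu <- ifelse(on_flag,
                 1.5 + stats::rlnorm(ng, e$expressed_meanlog, e$expressed_sdlog),
                 stats::runif(ng, 0, 0.8))
    reps <- vapply(seq_len(e$n_replicates), function(j)
      mu * exp(stats::rnorm(ng, 0, e$rep_noise_sd)), numeric(ng))
    colnames(reps) <- paste0("rep", seq_len(e$n_replicates))
    expr <- expression_table(gene_ids, reps, cell_line)
    truth <- data.frame(gene_id = gene_ids, true_mean = mu,
                        expressed_1 = expr$mean_tpm >= 1,
                        expressed_20 = expr$mean_tpm >= 20,
                        stringsAsFactors = FALSE)
    list(expr = expr, truth = truth)
  })
}

#' Generate synthetic essentialome gene lists
#'
#' Genes are drawn essential with a class-dependent probability (genes with a
#' minor/minor-like/major-like/hybrid intron use the elevated MIG-style rate,
#' non-canonical-intron genes the depleted rate, pure-major genes the
#' default); core-essential genes are a random subset of the total.
#'
#' @param config a `synthetic_config`.
#' @param genes per-gene table from [generate_annotation()].
#' @param seed integer seed.
#' @return List of character sets `total`, `core` and truth data.frame.
#' @export
generate_essentialome <- function(config, genes, seed = 1) {
  es <- config$essentialome
  with_preserved_rng({
    set.seed(substream_seed(seed, 4, tag = 14L))
    p <- ifelse(is.na(genes$rare_class), es$p_essential_default,
                ifelse(genes$rare_class == "non_canonical",
                       es$p_essential_non_canonical, es$p_essential_mig))
    total_flag <- stats::runif(nrow(genes)) < p
    total <- genes$gene_id[total_flag]
    core <- total[stats::runif(length(total)) < es$p_core_given_total]
    list(total = total, core = core,
         truth = data.frame(gene_id = genes$gene_id, essential = total_flag,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate spliced alignments with known retention and skipping truth
#'
#' Per intron with junction depth d, boundary read counts are
#' n5, n3 ~ Poisson(d * psi), canonical spliced reads
#' n_spliced ~ Poisson(d * (1 - psi) * (1 - sigma)) and exon-skipping reads
#' n_skip ~ Poisson(d * (1 - psi) * sigma); optional cryptic reads (a skip
#' strictly inside the intron) arrive at `cryptic_rate`.  Every count is
#' materialised as a coordinate-sorted single-end SAM record with correct
#' gapped-alignment encoding and generous anchors, so evidence extraction
#' recovers exactly the counts written — the randomness sits upstream of
#' emission.
#'
#' @param config a `synthetic_config`.
#' @param catalog catalog from [generate_annotation()].
#' @param gene_models exon table from [generate_annotation()].
#' @param psi,sigma optional per-intron truth vectors (named by intron_id or
#'   in catalog order); drawn from the class Beta distributions when NULL.
#' @param depth junction read depth (default from config).
#' @param out_sam output SAM path.
#' @param seed integer seed.
#' @param cell_line tag recorded in the truth table.
#' @return List: `sam` (path), `truth` (intron_id, psi, sigma and the exact
#'   emitted counts).
#' @export
simulate_alignments <- function(config, catalog, gene_models, psi = NULL,
                                sigma = NULL, depth = config$depth,
                                out_sam, seed = 1,
                                cell_line = config$cell_lines[1]) {
  r <- catalog$records
  n <- nrow(r)
  half <- config$read_len / 2
  if (half < 2) stop("read length too short for junction anchors")
  if (any(r$start < config$read_len))
    stop("intron too close to chromosome start for read emission")
  sp <- config$splicing
  with_preserved_rng({
    set.seed(substream_seed(seed, 5, tag = 15L))
    draw_beta <- function(means) {
      m <- means[r$intron_class]
      stats::rbeta(n, m * sp$concentration, (1 - m) * sp$concentration)
    }
    if (is.null(psi)) psi <- draw_beta(sp$psi_mean)
    else if (!is.null(names(psi))) psi <- unname(psi[r$intron_id])
    if (is.null(sigma)) sigma <- draw_beta(sp$sigma_mean)
    else if (!is.null(names(sigma))) sigma <- unname(sigma[r$intron_id])
    stopifnot(length(psi) == n, length(sigma) == n,
              all(psi >= 0 & psi <= 1), all(sigma >= 0 & sigma <= 1))

    n5 <- stats::rpois(n, depth * psi)
    n3 <- stats::rpois(n, depth * psi)
    n_spliced <- stats::rpois(n, depth * (1 - psi) * (1 - sigma))
    n_skip <- stats::rpois(n, depth * (1 - psi) * sigma)
    n_cryptic <- stats::rpois(n, depth * config$cryptic_rate)

    fl <- flanking_exons(catalog, gene_models)
    ilen <- r$end - r$start

    rep_rows <- function(cnt) rep(seq_len(n), cnt)
    ## boundary reads: read_len M centred on the junction; the 5' junction of
    ## a minus-strand intron is its right-hand genomic edge
    left_edge <- ifelse(r$strand == "+", r$start, r$end)
    right_edge <- ifelse(r$strand == "+", r$end, r$start)
    i5 <- rep_rows(n5)
    pos5 <- left_edge[i5] - half + 1
    cig5 <- sprintf("%dM", config$read_len)
    i3 <- rep_rows(n3)
    pos3 <- right_edge[i3] - half + 1
    ## canonical spliced reads: half M, intron N, half M
    isp <- rep_rows(n_spliced)
    possp <- r$start[isp] - half + 1
    cigsp <- sprintf("%dM%dN%dM", half, ilen[isp], half)
    ## skip reads: splice out the upstream flanking exon plus the intron
    isk <- rep_rows(n_skip)
    e5s <- fl$e5_start[isk]
    if (any(is.na(e5s)))
      stop("skip reads require an annotated upstream flanking exon")
    possk <- e5s - half + 1
    cigsk <- sprintf("%dM%dN%dM", half, r$end[isk] - e5s, half)
    ## cryptic reads: skip strictly inside the intron
    icr <- rep_rows(n_cryptic)
    gs <- r$start[icr] + 10
    ge <- r$end[icr] - 10
    poscr <- gs - half + 1
    cigcr <- sprintf("%dM%dN%dM", half, ge - gs, half)

    rows <- data.frame(
      rname = c(r$chrom[i5], r$chrom[i3], r$chrom[isp], r$chrom[isk],
                r$chrom[icr]),
      pos = c(pos5, pos3, possp, possk, poscr),
      cigar = c(rep(cig5, length(i5)), rep(cig5, length(i3)), cigsp, cigsk,
                cigcr),
      stringsAsFactors = FALSE)
    ord <- order(factor(rows$rname, levels = names(catalog$chrom_sizes)),
                 rows$pos)
    rows <- rows[ord, , drop = FALSE]
    seqstr <- strrep("A", config$read_len)
    body <- sprintf("r%07d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                    seq_len(nrow(rows)), rows$rname, as.integer(rows$pos),
                    rows$cigar, seqstr)
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", names(catalog$chrom_sizes),
                        as.integer(catalog$chrom_sizes)))
    writeLines(c(header, body), out_sam)

    truth <- data.frame(intron_id = r$intron_id, cell_line = cell_line,
                        psi = psi, sigma = sigma, n5 = n5, n3 = n3,
                        n_spliced = n_spliced, n_skip = n_skip,
                        n_cryptic = n_cryptic, stringsAsFactors = FALSE)
    list(sam = out_sam, truth = truth)
  })
}

#' Generate a complete synthetic study on disk
#'
#' Emits, under `out_dir`: the intron catalog (BED) and chromosome sizes,
#' gene models (GTF), per-cell-line feature tracks (BED), replicate TPM
#' tables (TSV), spliced alignments (SAM, optional), essentialome lists
#' (text) and a JSON truth bundle.  Everything derives from one master seed.
#'
#' @param config a `synthetic_config`.
#' @param out_dir output directory (created).
#' @param seed master seed.
#' @param with_alignments emit SAM files (TRUE) or only the count-free study
#'   (FALSE, the fast mode for purely statistical work).
#' @return List with the in-memory objects and all file paths.
#' @export
simulate_study <- function(config, out_dir, seed = 1, with_alignments = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- generate_annotation(config, seed = seed)
  catalog_bed <- file.path(out_dir, "introns.bed")
  write_catalog_bed(ann$catalog, catalog_bed)
  sizes_path <- file.path(out_dir, "chrom.sizes")
  utils::write.table(
    data.frame(names(ann$catalog$chrom_sizes),
               format_bp(ann$catalog$chrom_sizes)),
    sizes_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  gtf_path <- file.path(out_dir, "genes.gtf")
  write_gene_models_gtf(ann$gene_models, gtf_path)
  ess <- generate_essentialome(config, ann$genes, seed = seed)
  ess_total <- file.path(out_dir, "essentialome_total.txt")
  ess_core <- file.path(out_dir, "essentialome_core.txt")
  writeLines(ess$total, ess_total)
  writeLines(ess$core, ess_core)

  cell <- list()
  for (k in seq_along(config$cell_lines)) {
    cl <- config$cell_lines[k]
    cl_dir <- file.path(out_dir, cl)
    dir.create(cl_dir, showWarnings = FALSE)
    tr <- generate_feature_tracks(config, ann$catalog,
                                  seed = substream_seed(seed, k, tag = 21L),
                                  cell_line = cl)
    track_paths <- list()
    for (ty in names(tr$tracks)) {
      p <- file.path(cl_dir, paste0(ty, ".bed"))
      gr <- tr$tracks[[ty]]$gr
      utils::write.table(
        data.frame(as.character(GenomicRanges::seqnames(gr)),
                   format_bp(GenomicRanges::start(gr) - 1),
                   format_bp(GenomicRanges::end(gr))),
        p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
      track_paths[[ty]] <- p
    }
    ex <- generate_expression(config, ann$genes,
                              seed = substream_seed(seed, k, tag = 22L),
                              cell_line = cl)
    tpm_path <- file.path(cl_dir, "tpm.tsv")
    utils::write.table(
      as.data.frame(ex$expr)[, c("gene_id", attr(ex$expr, "replicates"))],
      tpm_path, sep = "\t", quote = FALSE, row.names = FALSE)
    aln <- NULL
    sam_path <- NULL
    if (with_alignments) {
      sam_path <- file.path(cl_dir, "alignments.sam")
      aln <- simulate_alignments(config, ann$catalog, ann$gene_models,
                                 out_sam = sam_path,
                                 seed = substream_seed(seed, k, tag = 23L),
                                 cell_line = cl)
    }
    cell[[cl]] <- list(tracks = tr$tracks, track_truth = tr$truth,
                       track_paths = track_paths, expr = ex$expr,
                       expr_truth = ex$truth, tpm_path = tpm_path,
                       sam = sam_path,
                       alignment_truth = if (!is.null(aln)) aln$truth)
  }
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(seed = seed, preset = config$preset,
         class_counts = as.list(config$class_counts),
         placement = lapply(config$placement, function(m)
           if (is.matrix(m)) as.data.frame(m) else as.list(m))),
    truth_path, auto_unbox = TRUE, digits = NA)
  list(config = config, seed = seed, annotation = ann, essentialome = ess,
       cell_lines = cell,
       paths = list(catalog = catalog_bed, chrom_sizes = sizes_path,
                    gene_models = gtf_path, essentialome_total = ess_total,
                    essentialome_core = ess_core, truth = truth_path,
                    out_dir = out_dir))
}

#' Write gene models as GTF exon records
#' @param gene_models exon data.frame (0-based half-open coordinates).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(gene_models, path) {
  lines <- sprintf(
    '%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1";',
    gene_models$chrom, as.integer(gene_models$start + 1),
    as.integer(gene_models$end), gene_models$strand, gene_models$gene_id,
    gene_models$gene_id)
  writeLines(lines, path)
  invisible(path)
}
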