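# Shared fixture builders and independent brute-force oracles.

# A tiny hand-built catalog on one or two chromosomes.
tiny_catalog <- function(records = NULL, sizes = c(c1 = 1e6)) {
  if (is.null(records)) {
    records <- data.frame(
      intron_id = c("i1", "i2", "i3"),
      chrom = "c1",
      start = c(100, 320, 650), end = c(200, 400, 700),
      strand = "+", gene_id = c("g1", "g1", "g2"),
      intron_class = c("minor", "major", "major"),
      stringsAsFactors = FALSE)
  }
  intron_catalog(records, sizes, provenance = "test")
}

# Build an overlap_matrix directly from given membership vectors (bypassing
# interval arithmetic) for resampling / enrichment tests.
fake_matrix <- function(intron_id, memberships, partitions = list(),
                        cell_line = "TEST") {
  out <- data.frame(intron_id = intron_id, stringsAsFactors = FALSE)
  for (nm in names(memberships)) out[[nm]] <- memberships[[nm]]
  for (nm in names(partitions)) out[[paste0("partition_", nm)]] <- partitions[[nm]]
  attr(out, "cell_line") <- cell_line
  attr(out, "min_overlap_frac") <- 0.5
  class(out) <- c("overlap_matrix", "data.frame")
  out
}

# Independent membership oracle: per-pair overlap scan with no interval
# index.  Merging is done by a simple sweep; the best single-interval overlap
# is compared against the inclusive fractional threshold.
brute_force_membership <- function(catalog, track, min_overlap_frac = 0.5) {
  gr <- track$gr
  iv <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr))
  r <- catalog$records
  vapply(seq_len(nrow(r)), function(i) {
    len <- r$end[i] - r$start[i]
    best <- 0
    for (j in seq_len(nrow(iv))) {
      if (iv$chrom[j] != r$chrom[i]) next
      ov <- min(r$end[i], iv$end[j]) - max(r$start[i], iv$start[j])
      if (ov > best) best <- ov
    }
    best >= min_overlap_frac * len && best > 0
  }, logical(1))
}

# Independent two-sided Fisher oracle: exhaustive hypergeometric enumeration
# over all tables with the observed margins.
fisher_enum_p <- function(in_focal, in_baseline, out_focal, out_baseline) {
  m <- in_focal + out_focal        # focal column total
  n <- in_baseline + out_baseline  # baseline column total
  k <- in_focal + in_baseline      # "in" row total
  ks <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(ks, m, n, k)
  p_obs <- stats::dhyper(in_focal, m, n, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Independent SAM re-scan oracle: parses SAM text directly and classifies
# every record against every intron with plain loops (no index, no early
# exit).  Only M/N/S/I/D cigar ops are handled, which covers the fixtures.
brute_force_evidence <- function(sam_path, catalog, gene_models,
                                 min_anchor = 2, mapq_min = 1) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  r <- catalog$records
  out <- data.frame(intron_id = r$intron_id, n5 = 0L, n3 = 0L,
                    n_spliced = 0L, n_skip = 0L, n_cryptic = 0L)
  annot <- unique(c(paste(r$chrom, r$start), paste(r$chrom, r$end)))
  fl5 <- integer(nrow(r)); fl3 <- integer(nrow(r))
  for (i in seq_len(nrow(r))) {
    w5 <- which(gene_models$gene_id == r$gene_id[i] &
                  gene_models$chrom == r$chrom[i] &
                  gene_models$end == r$start[i])
    w3 <- which(gene_models$gene_id == r$gene_id[i] &
                  gene_models$chrom == r$chrom[i] &
                  gene_models$start == r$end[i])
    fl5[i] <- if (length(w5)) gene_models$start[w5[1]] else NA
    fl3[i] <- if (length(w3)) gene_models$end[w3[1]] else NA
  }
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 256L) > 0 || bitwAnd(flag, 2048L) > 0 ||
        bitwAnd(flag, 1024L) > 0 || bitwAnd(flag, 4L) > 0) next
    if (as.integer(f[5]) < mapq_min) next
    chrom <- f[3]; pos0 <- as.numeric(f[4]) - 1  # 0-based block start
    ops <- regmatches(f[6], gregexpr("[0-9]+[MIDNS]", f[6]))[[1]]
    blocks <- NULL; gaps <- NULL; cur <- pos0
    blk_start <- pos0
    for (op in ops) {
      n_op <- as.numeric(sub("[MIDNS]", "", op))
      ty <- sub("[0-9]+", "", op)
      if (ty %in% c("M", "D")) cur <- cur + n_op
      if (ty == "N") {
        blocks <- rbind(blocks, c(blk_start, cur))
        gaps <- rbind(gaps, c(cur, cur + n_op))
        cur <- cur + n_op
        blk_start <- cur
      }
    }
    blocks <- rbind(blocks, c(blk_start, cur))
    for (i in seq_len(nrow(r))) {
      if (r$chrom[i] != chrom) next
      s0 <- r$start[i]; e0 <- r$end[i]
      plus <- r$strand[i] == "+"
      for (b in seq_len(nrow(blocks))) {
        bs <- blocks[b, 1]; be <- blocks[b, 2]
        if (bs <= s0 - min_anchor && be >= s0 + min_anchor) {
          if (plus) out$n5[i] <- out$n5[i] + 1L
          else out$n3[i] <- out$n3[i] + 1L
        }
        if (bs <= e0 - min_anchor && be >= e0 + min_anchor) {
          if (plus) out$n3[i] <- out$n3[i] + 1L
          else out$n5[i] <- out$n5[i] + 1L
        }
      }
      if (is.null(gaps)) next
      for (g in seq_len(nrow(gaps))) {
        gs <- gaps[g, 1]; ge <- gaps[g, 2]
        if (ge <= s0 || gs >= e0) next   # no overlap with the intron
        lw <- gaps[g, 1] - blocks[g, 1]
        rw <- blocks[g + 1, 2] - blocks[g + 1, 1]
        aok <- lw >= min_anchor && rw >= min_anchor
        if (!aok) next
        exact <- gs == s0 && ge == e0
        contains <- gs <= s0 && ge >= e0
        skip <- contains && !exact &&
          ((!is.na(fl5[i]) && gs <= fl5[i]) || (!is.na(fl3[i]) && ge >= fl3[i]))
        inside <- gs > s0 && ge < e0
        one_edge <- xor(gs == s0, ge == e0)
        other <- if (gs == s0) ge else gs
        cryptic <- !exact && !skip &&
          (inside || (one_edge && !(paste(chrom, other) %in% annot)))
        if (exact) out$n_spliced[i] <- out$n_spliced[i] + 1L
        if (skip) out$n_skip[i] <- out$n_skip[i] + 1L
        if (cryptic) out$n_cryptic[i] <- out$n_cryptic[i] + 1L
      }
    }
  }
  out
}

# Write a minimal SAM file from a data.frame of (rname, pos, cigar) rows.
write_test_sam <- function(rows, chrom_sizes, path,
                           mapq = rep(60L, nrow(rows)),
                           flag = rep(0L, nrow(rows)), read_len = NULL) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                      as.integer(chrom_sizes)))
  seq_len_of <- function(cig) {
    ops <- regmatches(cig, gregexpr("[0-9]+[MIS]", cig))[[1]]
    sum(as.numeric(sub("[MIS]", "", ops)))
  }
  ord <- order(factor(rows$rname, levels = names(chrom_sizes)), rows$pos)
  rows <- rows[ord, , drop = FALSE]
  mapq <- mapq[ord]; flag <- flag[ord]
  body <- vapply(seq_len(nrow(rows)), function(i) {
    sl <- seq_len_of(rows$cigar[i])
    sprintf("t%05d\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*", i, flag[i],
            rows$rname[i], as.integer(rows$pos[i]), mapq[i], rows$cigar[i],
            strrep("A", sl))
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# Random catalog + track fixture for the membership oracle property.
random_overlap_fixture <- function(seed, max_introns = 500, max_intervals = 50) {
  set.seed(seed)
  n_i <- sample.int(max_introns, 1)
  n_v <- sample.int(max_intervals, 1)
  sizes <- c(rc1 = 2e5, rc2 = 1e5)
  mk_iv <- function(n) {
    chrom <- sample(names(sizes), n, replace = TRUE)
    start <- floor(runif(n, 0, sizes[chrom] - 2000))
    data.frame(chrom = chrom, start = start,
               end = start + sample(10:1500, n, replace = TRUE))
  }
  iv <- mk_iv(n_i)
  cat <- intron_catalog(
    data.frame(intron_id = sprintf("r%04d", seq_len(n_i)), chrom = iv$chrom,
               start = iv$start, end = iv$end,
               strand = sample(c("+", "-"), n_i, TRUE),
               gene_id = sprintf("g%04d", seq_len(n_i)),
               intron_class = sample(intron_classes(), n_i, TRUE),
               stringsAsFactors = FALSE),
    sizes)
  track <- feature_track(mk_iv(n_v), "SPAD", "TEST")
  list(catalog = cat, track = track)
}
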