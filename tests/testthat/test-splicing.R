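# One plus-strand gene: exons [1000,1120) [1200,1320) [1400,1520),
# introns i1 = [1120,1200), i2 = [1320,1400).
splice_fixture <- function() {
  rec <- data.frame(intron_id = c("i1", "i2"), chrom = "c1",
                    start = c(1120, 1320), end = c(1200, 1400), strand = "+",
                    gene_id = "g1", intron_class = c("minor", "major"),
                    stringsAsFactors = FALSE)
  cat <- intron_catalog(rec, c(c1 = 100000))
  gm <- data.frame(gene_id = "g1", chrom = "c1",
                   start = c(1000, 1200, 1400), end = c(1120, 1320, 1520),
                   strand = "+", stringsAsFactors = FALSE)
  list(catalog = cat, gene_models = gm)
}

test_that("junction evidence classifies boundary, spliced, skip and cryptic reads", {
  fx <- splice_fixture()
  td <- withr::local_tempdir()
  sam <- file.path(td, "reads.sam")
  rows <- data.frame(
    rname = "c1",
    pos =   c(1111, 1120, 1111, 1111, 1111, 1191),
    cigar = c("20M",            # r1: spans 5' boundary of i1, anchors 10/10
              "1M80N19M",       # r2: spliced over i1 but 1-base left anchor
              "10M80N10M",      # r3: exact splice of i1
              "10M40N10M",      # r4: gap [1120,1160): cryptic (one edge)
              "10M280N10M",     # r5: skips exon2 -> n_skip for i1 and i2
              "20M"),           # r6: spans 3' boundary of i1
    stringsAsFactors = FALSE)
  write_test_sam(rows, c(c1 = 100000), sam)
  ev <- extract_junction_evidence(sam, fx$catalog, fx$gene_models,
                                  min_anchor = 2)
  i1 <- ev[ev$intron_id == "i1", ]
  i2 <- ev[ev$intron_id == "i2", ]
  expect_equal(i1$n5, 1)          # r1 only; r2 excluded by the anchor rule
  expect_equal(i1$n3, 1)          # r6
  expect_equal(i1$n_spliced, 1)   # r3
  expect_equal(i1$n_cryptic, 1)   # r4
  expect_equal(i1$n_skip, 1)      # r5
  expect_equal(i2$n_skip, 1)      # r5 also skips across i2's upstream exon
  expect_equal(i2$n_spliced, 0)

  # brute-force re-scan of the SAM text agrees exactly
  bf <- brute_force_evidence(sam, fx$catalog, fx$gene_models, min_anchor = 2)
  for (cn in c("n5", "n3", "n_spliced", "n_skip", "n_cryptic"))
    expect_equal(ev[[cn]], bf[[cn]])
})

test_that("read filters drop secondary/duplicate/low-MAPQ records", {
  fx <- splice_fixture()
  td <- withr::local_tempdir()
  sam <- file.path(td, "flags.sam")
  rows <- data.frame(rname = "c1", pos = rep(1111, 4), cigar = "20M",
                     stringsAsFactors = FALSE)
  write_test_sam(rows, c(c1 = 100000), sam,
                 mapq = c(60L, 0L, 60L, 60L),
                 flag = c(0L, 0L, 256L, 1024L))
  ev <- extract_junction_evidence(sam, fx$catalog, fx$gene_models)
  expect_equal(ev$n5[ev$intron_id == "i1"], 1)  # only the clean MAPQ-60 primary
  ev_all <- extract_junction_evidence(sam, fx$catalog, fx$gene_models,
                                      unique_only = FALSE)
  expect_equal(ev_all$n5[ev_all$intron_id == "i1"], 2)  # MAPQ 0 readmitted
})

test_that("splicing indices follow the boundary/spliced and skip/spliced formulas", {
  ev <- data.frame(intron_id = c("a", "b", "c", "d", "e"),
                   n5 = c(4, 0, 5, 5, 0), n3 = c(6, 0, 5, 5, 0),
                   n_spliced = c(10, 10, 0, 10, 0),
                   n_skip = c(2, 0, 3, 0, 0),
                   n_cryptic = c(0, 0, 0, 1, 0))
  ret <- compute_si_ret(ev)
  expect_equal(ret$si_ret[1], 100 * 5 / 15, tolerance = 1e-9)  # 33.33
  expect_equal(ret$category[1], "both")
  expect_equal(ret$si_ret[2], 0)
  expect_equal(ret$category[2], "spliced_only")
  expect_equal(ret$si_ret[3], 100)
  expect_equal(ret$category[3], "retained_only")
  # cryptic veto: boundary reads voided, intron becomes spliced_only
  expect_equal(ret$si_ret[4], 0)
  expect_equal(ret$category[4], "spliced_only")
  expect_true(ret$cryptic_veto[4])
  # zero denominator: undefined
  expect_true(is.na(ret$si_ret[5]))

  es <- compute_si_es(ev)
  expect_equal(es$si_es[1], 100 * 2 / 12)
  expect_equal(es$si_es[2], 0)
  expect_equal(es$si_es[3], 100)
  expect_true(is.na(es$si_es[5]))

  # indices stay inside [0, 100] whenever defined
  set.seed(1)
  re <- data.frame(intron_id = sprintf("r%03d", 1:200),
                   n5 = rpois(200, 3), n3 = rpois(200, 3),
                   n_spliced = rpois(200, 5), n_skip = rpois(200, 1),
                   n_cryptic = rbinom(200, 1, 0.2))
  rr <- compute_si_ret(re); ee <- compute_si_es(re)
  expect_true(all(rr$si_ret >= 0 & rr$si_ret <= 100, na.rm = TRUE))
  expect_true(all(ee$si_es >= 0 & ee$si_es <= 100, na.rm = TRUE))
})

test_that("analysis filters apply TPM, read-support, category and subsampling", {
  n <- 80
  rec <- data.frame(intron_id = sprintf("f%03d", 1:n),
                    n5 = 2, n3 = 2, n_spliced = 2, n_skip = 0, n_cryptic = 0,
                    si_ret = 50, si_es = 0,
                    category = "both",
                    intron_class = "major", gene_id = sprintf("fg%03d", 1:n),
                    cell_line = "T", gene_mean_tpm = 5,
                    location = "SPAD", stringsAsFactors = FALSE)
  rec$gene_mean_tpm[1] <- 0.8            # fails TPM >= 1
  rec$category[2] <- "spliced_only"      # fails category == both
  rec$n5[3] <- 0; rec$n3[3] <- 0; rec$n_spliced[3] <- 0  # no reads

  out <- filter_for_analysis(rec, tpm_threshold = 1, require_read = TRUE,
                             category_filter = "both",
                             subsample = c(major = 50), seed = 4)
  expect_equal(nrow(out), 50)
  expect_false(any(out$intron_id %in% c("f001", "f002", "f003")))

  # subsampling is reproducible and honours undersized classes
  out2 <- filter_for_analysis(rec, tpm_threshold = 1,
                              category_filter = "both",
                              subsample = c(major = 50), seed = 4)
  expect_identical(out$intron_id, out2$intron_id)
  expect_warning(
    filter_for_analysis(rec, tpm_threshold = 1, category_filter = "both",
                        subsample = c(major = 500), seed = 4),
    "keeping all")
})

test_that("two-group comparisons use the exact Mann-Whitney enumeration", {
  # identical groups: no evidence of difference
  d_same <- data.frame(si_ret = rep(c(1, 2, 3), 2),
                       g = rep(c("A", "B"), each = 3))
  expect_equal(compare_distributions(d_same, "g")$p, 1)

  # fully separated 4 vs 4 with within-group ties: exact p = 2/70
  d_sep <- data.frame(si_ret = c(0, 0, 0, 0, 10, 10, 10, 10),
                      g = rep(c("A", "B"), each = 4))
  expect_equal(compare_distributions(d_sep, "g")$p, 2 / 70, tolerance = 1e-9)

  # groups below the size floor are reported untestable
  d_tiny <- data.frame(si_ret = c(1, 2, 3, 4), g = c("A", "A", "A", "B"))
  cmp <- compare_distributions(d_tiny, "g")
  expect_equal(cmp$untestable_groups, "B")
  expect_equal(cmp$test, "none")
})

test_that("Dunn test matches hand-computed z statistics with BH adjustment", {
  v <- 1:9
  g <- rep(c("A", "B", "C"), each = 3)
  dt <- dunn_test(v, g)
  # no ties: var = N(N+1)/12 = 7.5; se = sqrt(7.5 * 2/3); mean ranks 2, 5, 8
  se <- sqrt(7.5 * (2 / 3))
  expect_equal(dt$z[dt$group1 == "A" & dt$group2 == "B"], -3 / se,
               tolerance = 1e-12)
  expect_equal(dt$z[dt$group1 == "A" & dt$group2 == "C"], -6 / se,
               tolerance = 1e-12)
  p_manual <- 2 * pnorm(-abs(c(-3 / se, -6 / se, -3 / se)))
  expect_equal(dt$p_raw, p_manual, tolerance = 1e-12)
  expect_equal(dt$p_adj, p.adjust(p_manual, "BH"), tolerance = 1e-12)
  # BH adjustment never decreases a p-value
  expect_true(all(dt$p_adj >= dt$p_raw - 1e-15))

  d3 <- data.frame(si_ret = v, g = g)
  cmp <- compare_distributions(d3, "g")
  expect_equal(cmp$test, "kruskal_wallis_dunn")
  expect_equal(cmp$p, kruskal.test(v, factor(g))$p.value)
})

test_that("simulated alignments round-trip exactly and recover psi/sigma", {
  cfg <- synthetic_config(scale = 0, depth = 150,
                          class_counts = c(major = 120, major_like = 0,
                                           hybrid = 0, minor_like = 0,
                                           minor = 0, non_canonical = 0))
  ann <- generate_annotation(cfg, seed = 21)
  td <- withr::local_tempdir()
  sam <- file.path(td, "sim.sam")
  psi <- rep(0.2, nrow(ann$catalog$records))
  sigma <- rep(0, nrow(ann$catalog$records))
  aln <- simulate_alignments(cfg, ann$catalog, ann$gene_models, psi = psi,
                             sigma = sigma, out_sam = sam, seed = 21)
  ev <- extract_junction_evidence(sam, ann$catalog, ann$gene_models)
  for (cn in c("n5", "n3", "n_spliced", "n_skip", "n_cryptic"))
    expect_equal(ev[[cn]], aln$truth[[cn]])

  rec <- splicing_index_records(ev, ann$catalog)
  expect_lt(abs(median(rec$si_ret, na.rm = TRUE) - 20), 2)

  # single replicate: pooled and per-replicate modes coincide exactly
  rec_pr <- splicing_index_records(ev, ann$catalog, per_replicate = TRUE)
  expect_equal(rec_pr$si_ret[match(rec$intron_id, rec_pr$intron_id)],
               rec$si_ret)
})

test_that("matched location sets and improved-splicing intersections work on toys", {
  ids <- sprintf("m%02d", 1:8)
  rec <- data.frame(intron_id = ids, chrom = "c1",
                    start = seq(1000, by = 1000, length.out = 8),
                    end = seq(1000, by = 1000, length.out = 8) + 100,
                    strand = "+", gene_id = paste0("mg", c(1:7, 7)),
                    intron_class = "minor", stringsAsFactors = FALSE)
  cat <- tiny_catalog(rec)
  loc1 <- c(rep("SPAD", 5), "LAD", "neither", "neither")
  loc2 <- c(rep("SPAD", 5), "neither", "neither", "neither")
  m1 <- fake_matrix(ids, list(), partitions = list(nuclear_body = loc1))
  m2 <- fake_matrix(ids, list(), partitions = list(nuclear_body = loc2))
  mk_rec <- function(si) data.frame(intron_id = ids, si_ret = si,
                                    stringsAsFactors = FALSE)
  r1 <- mk_rec(c(50, 10, 30, 40, 20, 5, 60, 33))
  r2 <- mk_rec(c(20, 10, 40, 35, 15, 5, 50, 33))
  ml <- matched_location_sets(list(L1 = m1, L2 = m2), list(L1 = r1, L2 = r2),
                              reference_cell_line = "L1",
                              classes = "minor", catalog = cat)
  spad_all <- ml$all_lines$sets[["minor|SPAD"]]
  expect_setequal(spad_all, ids[1:5])
  spad_pair <- ml$pairwise$sets[["L2|minor|SPAD"]]
  expect_setequal(spad_pair, ids[1:5])
  cmp <- ml$comparisons[ml$comparisons$category == "SPAD", ]
  expect_equal(cmp$n, 5)
  expect_true(cmp$p > 0 && cmp$p <= 1)

  # an intron without a defined index in one line leaves the set
  r2b <- r2; r2b$si_ret[1] <- NA
  mlb <- suppressMessages(
    matched_location_sets(list(L1 = m1, L2 = m2), list(L1 = r1, L2 = r2b),
                          reference_cell_line = "L1", classes = "minor",
                          catalog = cat))
  expect_setequal(mlb$all_lines$sets[["minor|SPAD"]], ids[2:5])

  # improved splicing: strictly lower index in the other line
  imp <- improved_splicing_intersection(
    mk_rec(c(50, 10, 30, 40, 20, 5, 60, 33)),
    list(L2 = mk_rec(c(20, 10, 40, 35, 15, 5, 50, 33)),
         L3 = mk_rec(c(45, 10, 40, 39, 25, 5, 50, 33))),
    shared_ids = list(L2 = ids[1:5], L3 = ids[1:5]),
    catalog = cat)
  expect_setequal(imp$per_line$L2$intron_ids, c("m01", "m04", "m05"))
  expect_setequal(imp$per_line$L3$intron_ids, c("m01", "m04"))
  expect_setequal(imp$intersection$intron_ids, c("m01", "m04"))
  # identical indices yield an empty improved set
  imp0 <- improved_splicing_intersection(
    r1, list(L2 = r1), shared_ids = list(L2 = ids), catalog = cat)
  expect_length(imp0$per_line$L2$intron_ids, 0)
})
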