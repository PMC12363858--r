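test_that("catalog loading handles both dialects identically and validates rows", {
  td <- withr::local_tempdir()
  sizes_path <- file.path(td, "chrom.sizes")
  writeLines(c("c1\t1000000"), sizes_path)

  bed <- file.path(td, "cat.bed")
  writeLines(c("c1\t100\t200\ti1\t0\t+\tg1\tminor",
               "c1\t320\t400\ti2\t0\t+\tg1\tmajor",
               "c1\t650\t700\ti3\t0\t-\tg2\tmajor"), bed)
  cat_bed <- suppressMessages(
    load_intron_catalog(bed, "bed_zero_half_open", sizes_path))
  expect_equal(nrow(cat_bed$records), 3)
  expect_equal(unname(class_counts(cat_bed)[c("minor", "major")]), c(1L, 2L))

  # same intervals, 1-based inclusive TSV -> identical internal coordinates
  tsv <- file.path(td, "cat.tsv")
  writeLines(c("chrom\tstart\tend\tstrand\tintron_id\tgene_id\tintron_class",
               "c1\t101\t200\t+\ti1\tg1\tminor",
               "c1\t321\t400\t+\ti2\tg1\tmajor",
               "c1\t651\t700\t-\ti3\tg2\tmajor"), tsv)
  cat_tsv <- suppressMessages(
    load_intron_catalog(tsv, "tsv_one_based_inclusive", sizes_path))
  expect_equal(cat_tsv$records[, c("chrom", "start", "end")],
               cat_bed$records[, c("chrom", "start", "end")])

  # unknown class label is rejected, naming the label
  bad <- file.path(td, "bad.bed")
  writeLines("c1\t100\t200\ti1\t0\t+\tg1\tu12", bad)
  expect_error(load_intron_catalog(bad, "bed_zero_half_open", sizes_path),
               "u12")

  # duplicate ids and out-of-bounds intervals are validation errors
  dup <- file.path(td, "dup.bed")
  writeLines(c("c1\t100\t200\ti1\t0\t+\tg1\tmajor",
               "c1\t300\t400\ti1\t0\t+\tg1\tmajor"), dup)
  expect_error(load_intron_catalog(dup, "bed_zero_half_open", sizes_path),
               "duplicate")
  oob <- file.path(td, "oob.bed")
  writeLines("c1\t999990\t1000200\ti1\t0\t+\tg1\tmajor", oob)
  expect_error(load_intron_catalog(oob, "bed_zero_half_open", sizes_path),
               "bounds")
})

test_that("inter-intron distances are sorted gaps, clamped, per chromosome", {
  cat <- tiny_catalog(data.frame(
    intron_id = c("a", "b", "c"), chrom = "c1",
    start = c(100, 320, 650), end = c(200, 400, 700), strand = "+",
    gene_id = "g1", intron_class = "major", stringsAsFactors = FALSE))
  s <- inter_intron_distances(cat, "major")
  expect_equal(s$distances, c(120, 250))
  expect_equal(s$median_bp, 185)
  expect_equal(s$n_pairs, 2)

  # single intron of a class: no pairs, median absent
  s0 <- inter_intron_distances(tiny_catalog(), "minor")
  expect_equal(s0$n_pairs, 0)
  expect_true(is.na(s0$median_bp))

  # invariant to input row order
  shuf <- tiny_catalog(data.frame(
    intron_id = c("c", "a", "b"), chrom = "c1",
    start = c(650, 100, 320), end = c(700, 200, 400), strand = "+",
    gene_id = "g1", intron_class = "major", stringsAsFactors = FALSE))
  expect_equal(inter_intron_distances(shuf, "major")$distances, s$distances)

  # overlapping isoform introns: negative gap clamped to 0 and kept
  ovl <- tiny_catalog(data.frame(
    intron_id = c("a", "b"), chrom = "c1",
    start = c(100, 150), end = c(300, 400), strand = "+",
    gene_id = "g1", intron_class = "major", stringsAsFactors = FALSE))
  expect_equal(inter_intron_distances(ovl, "major")$distances, 0)

  # pairs never span chromosomes
  two <- intron_catalog(data.frame(
    intron_id = c("a", "b"), chrom = c("c1", "c2"),
    start = c(100, 100), end = c(200, 200), strand = "+",
    gene_id = "g1", intron_class = "major", stringsAsFactors = FALSE),
    c(c1 = 1e6, c2 = 1e6))
  expect_equal(inter_intron_distances(two, "major")$n_pairs, 0)
})

test_that("abundance-distance fit matches brute-force Pearson and handles edge cases", {
  # two points determine a line exactly
  f2 <- abundance_distance_fit(c(a = 100, b = 10), c(a = 50, b = 500))
  expect_equal(f2$r_squared, 1)

  # exact power law: r = -1
  k <- 1:5
  fp <- abundance_distance_fit(setNames(10^k, letters[k]),
                               setNames(10^(-k), letters[k]))
  expect_equal(fp$r, -1)
  expect_equal(fp$r_squared, 1)

  # zero/negative inputs are a domain error
  expect_error(abundance_distance_fit(c(a = 0, b = 1), c(a = 1, b = 1)),
               "positive")

  # agreement with an independent brute-force Pearson to 1e-12
  set.seed(42)
  for (rep in 1:5) {
    x <- runif(6, 1, 1e6); y <- runif(6, 1, 1e6)
    names(x) <- names(y) <- letters[1:6]
    lx <- log10(x); ly <- log10(y)
    r_manual <- sum((lx - mean(lx)) * (ly - mean(ly))) /
      sqrt(sum((lx - mean(lx))^2) * sum((ly - mean(ly))^2))
    expect_equal(abundance_distance_fit(x, y)$r, r_manual, tolerance = 1e-12)
  }
})

test_that("density bins assign by midpoint, tile chromosomes, and conserve counts", {
  cat <- intron_catalog(data.frame(
    intron_id = c("a", "b", "c"), chrom = "c1",
    start = c(5000, 235000, 255000), end = c(15000, 245000, 265000),
    strand = "+", gene_id = "g1", intron_class = "minor",
    stringsAsFactors = FALSE), c(c1 = 500000, c2 = 300000))
  bins <- bin_intron_density(cat, 250000)
  b1 <- bins[bins$chrom == "c1" & bins$bin_start == 0, ]
  b2 <- bins[bins$chrom == "c1" & bins$bin_start == 250000, ]
  expect_equal(b1$minor, 2)   # midpoints 10k and 240k
  expect_equal(b2$minor, 1)   # midpoint 260k

  # empty chromosome still emits all-zero bins
  expect_true(all(bins$minor[bins$chrom == "c2"] == 0))
  expect_equal(sum(bins$chrom == "c2"), 2)  # 300 kb / 250 kb -> 2 bins

  # an intron spanning the bin edge is counted once, in its midpoint's bin
  span <- intron_catalog(data.frame(
    intron_id = "s", chrom = "c1", start = 240000, end = 280000,
    strand = "+", gene_id = "g1", intron_class = "major",
    stringsAsFactors = FALSE), c(c1 = 500000))
  sb <- bin_intron_density(span, 250000)
  expect_equal(sum(sb$major), 1)
  expect_equal(sb$major[sb$bin_start == 250000], 1)  # midpoint 260000

  # per-class bin sums equal catalog totals on a random catalog
  fix <- random_overlap_fixture(99)
  bb <- bin_intron_density(fix$catalog, 10000)
  expect_equal(colSums(bb[, intron_classes()]),
               class_counts(fix$catalog)[intron_classes()],
               ignore_attr = TRUE)
})

test_that("cluster scan applies the Poisson upper tail with BH per class", {
  # one chromosome of 1000 bins; class total 100 -> lambda = 0.1 per bin;
  # one bin holds 5 introns
  n_extra <- 95
  rec <- data.frame(
    intron_id = sprintf("m%03d", 1:100), chrom = "c1",
    start = c(rep(100, 5), seq(2000, by = 1000, length.out = n_extra)),
    end = c(rep(150, 5), seq(2000, by = 1000, length.out = n_extra) + 50),
    strand = "+", gene_id = sprintf("g%03d", 1:100), intron_class = "minor",
    stringsAsFactors = FALSE)
  rec$intron_id <- make.unique(rec$intron_id)
  cat <- intron_catalog(rec, c(c1 = 1e6))
  bins <- bin_intron_density(cat, 1000)
  scan <- scan_density_clusters(bins, fdr = 0.05)
  hot <- scan[scan$intron_class == "minor" & scan$bin_start == 0, ]
  # oracle: direct Poisson tail sum P(X >= 5; lambda = 0.1)
  expect_equal(hot$p, 1 - sum(dpois(0:4, 0.1)), tolerance = 1e-9)
  expect_equal(hot$p, 7.7e-8, tolerance = 0.01)
  expect_true(hot$flagged)

  # a class with zero counts is never flagged
  expect_false(any(scan$flagged[scan$intron_class == "hybrid"]))

  # uniform counts at the integer part of the rate: no flags
  urec <- data.frame(
    intron_id = sprintf("u%02d", 1:10), chrom = "c1",
    start = seq(500, by = 1000, length.out = 10),
    end = seq(500, by = 1000, length.out = 10) + 100,
    strand = "+", gene_id = "g1", intron_class = "major",
    stringsAsFactors = FALSE)
  ucat <- intron_catalog(urec, c(c1 = 10000))
  uscan <- scan_density_clusters(bin_intron_density(ucat, 1000))
  expect_false(any(uscan$flagged[uscan$intron_class == "major"]))
})
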