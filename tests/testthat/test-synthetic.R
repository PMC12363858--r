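test_that("generated annotation honours class counts, uniqueness and layout", {
  cfg <- synthetic_config(scale = 0,
                          class_counts = c(major = 400, major_like = 0,
                                           hybrid = 0, minor_like = 0,
                                           minor = 20, non_canonical = 0))
  ann <- generate_annotation(cfg, seed = 3)
  cc <- class_counts(ann$catalog)
  expect_equal(unname(cc[c("major", "minor")]), c(400L, 20L))
  expect_equal(sum(cc), 420L)

  # one rare intron per gene: 20 minor introns in 20 distinct genes
  minors <- ann$catalog$records[ann$catalog$records$intron_class == "minor", ]
  expect_equal(length(unique(minors$gene_id)), 20)

  # introns fall inside chromosome bounds and never overlap
  r <- ann$catalog$records
  for (ch in unique(r$chrom)) {
    rc <- r[r$chrom == ch, ]
    rc <- rc[order(rc$start), ]
    if (nrow(rc) > 1)
      expect_true(all(rc$start[-1] >= rc$end[-nrow(rc)]))
  }

  # determinism: same seed, identical annotation
  ann2 <- generate_annotation(cfg, seed = 3)
  expect_identical(ann$catalog$records, ann2$catalog$records)
  expect_identical(ann$gene_models, ann2$gene_models)

  # configured chromosomes too short -> error stating the requirement
  short <- synthetic_config(scale = 0,
                            class_counts = c(major = 400, major_like = 0,
                                             hybrid = 0, minor_like = 0,
                                             minor = 20, non_canonical = 0),
                            chrom_lengths = c(chrS1 = 1000, chrS2 = 1000,
                                              chrS3 = 1000, chrS4 = 1000))
  expect_error(generate_annotation(short, seed = 3), "too short")
})

test_that("feature tracks realise the configured placement probabilities", {
  cfg <- synthetic_config(scale = 0.25)
  ann <- generate_annotation(cfg, seed = 8)
  tr <- generate_feature_tracks(cfg, ann$catalog, seed = 8)
  m <- assign_membership(ann$catalog, tr$tracks)

  # the 50%-overlap rule recovers the drawn memberships exactly
  expect_identical(unname(m$partition_compartment), tr$truth$compartment)
  expect_identical(unname(m$partition_nuclear_body), tr$truth$nuclear_body)

  # realized rates within binomial error of the preset probabilities
  cls <- ann$catalog$records$intron_class
  for (cl in c("major", "minor")) {
    n_cl <- sum(cls == cl)
    p <- cfg$placement$compartment[cl, "A"]
    rate <- mean(tr$truth$compartment[cls == cl] == "A")
    expect_lt(abs(rate - p), 4 * sqrt(p * (1 - p) / n_cl))
  }

  # degenerate probabilities: all or nothing
  comp1 <- cfg$placement$compartment
  comp1["minor", ] <- c(1, 0, 0)
  nb0 <- cfg$placement$nuclear_body
  nb0[] <- rep(c(0, 0, 1), each = 6)
  cfg_deg <- synthetic_config(scale = 0.05,
                              placement = modifyList(cfg$placement,
                                                     list(compartment = comp1,
                                                          nuclear_body = nb0)))
  ann_d <- generate_annotation(cfg_deg, seed = 2)
  tr_d <- generate_feature_tracks(cfg_deg, ann_d$catalog, seed = 2)
  m_d <- assign_membership(ann_d$catalog, tr_d$tracks)
  cls_d <- ann_d$catalog$records$intron_class
  expect_true(all(m_d$partition_compartment[cls_d == "minor"] == "A"))
  expect_true(all(m_d$partition_nuclear_body == "neither"))
})

test_that("SPAD-in-A nesting is honoured and infeasible nesting errors", {
  cfg <- synthetic_config(scale = 0.5, spad_in_A = 0.9)
  ann <- generate_annotation(cfg, seed = 4)
  tr <- generate_feature_tracks(cfg, ann$catalog, seed = 4)
  spad <- tr$truth$nuclear_body == "SPAD"
  conc <- mean(tr$truth$compartment[spad] == "A")
  expect_gt(conc, 0.8)   # target P(A | SPAD) = 0.9 within sampling noise

  nb_bad <- cfg$placement$nuclear_body
  nb_bad["minor", ] <- c(0.9, 0.05, 0.05)
  cfg_bad <- synthetic_config(scale = 0.1, spad_in_A = 1,
                              placement = modifyList(
                                cfg$placement, list(nuclear_body = nb_bad)))
  ann_b <- generate_annotation(cfg_bad, seed = 4)
  expect_error(generate_feature_tracks(cfg_bad, ann_b$catalog, seed = 4),
               "infeasible")
})

test_that("expression generator hits the configured expressed fraction", {
  cfg <- synthetic_config(scale = 0.5)
  ann <- generate_annotation(cfg, seed = 6)
  ex <- generate_expression(cfg, ann$genes, seed = 6)
  frac <- mean(ex$truth$expressed_1)
  n <- nrow(ex$truth)
  expect_lt(abs(frac - 0.75), 4 * sqrt(0.75 * 0.25 / n))
  # truth flags re-derive from the emitted replicate means
  expect_identical(ex$truth$expressed_1, unname(expressed_genes(ex$expr, 1)))
  expect_identical(ex$truth$expressed_20, unname(expressed_genes(ex$expr, 20)))

  # zero replicate noise: replicates equal the mean exactly
  cfg0 <- synthetic_config(scale = 0.05,
                           expression = modifyList(cfg$expression,
                                                   list(rep_noise_sd = 0)))
  ex0 <- generate_expression(cfg0, ann$genes, seed = 6)
  expect_equal(ex0$expr$rep1, ex0$expr$rep2)
  # a gene with sub-threshold mean is never expressed at threshold 1
  expect_true(all(ex0$expr$mean_tpm[!ex0$truth$expressed_1] < 1))
})

test_that("alignment simulation matches Poisson expectations and degenerate truths", {
  cfg <- synthetic_config(scale = 0, depth = 100,
                          class_counts = c(major = 150, major_like = 0,
                                           hybrid = 0, minor_like = 0,
                                           minor = 0, non_canonical = 0))
  ann <- generate_annotation(cfg, seed = 12)
  td <- withr::local_tempdir()
  n <- nrow(ann$catalog$records)

  # psi = 0: no boundary reads at all
  a0 <- simulate_alignments(cfg, ann$catalog, ann$gene_models,
                            psi = rep(0, n), sigma = rep(0.3, n),
                            out_sam = file.path(td, "a0.sam"), seed = 1)
  expect_true(all(a0$truth$n5 == 0 & a0$truth$n3 == 0))

  # sigma = 1 with psi = 0: only skipping reads; SI_ES = 100
  a1 <- simulate_alignments(cfg, ann$catalog, ann$gene_models,
                            psi = rep(0, n), sigma = rep(1, n),
                            out_sam = file.path(td, "a1.sam"), seed = 1)
  expect_true(all(a1$truth$n_spliced == 0))
  ev <- extract_junction_evidence(file.path(td, "a1.sam"), ann$catalog,
                                 ann$gene_models)
  es <- compute_si_es(ev)
  expect_true(all(es$si_es[!is.na(es$si_es)] == 100))

  # psi = 0.2: realized mean counts near the Poisson expectations
  a2 <- simulate_alignments(cfg, ann$catalog, ann$gene_models,
                            psi = rep(0.2, n), sigma = rep(0, n),
                            out_sam = file.path(td, "a2.sam"), seed = 2)
  expect_lt(abs(mean(a2$truth$n5) - 20), 3 * sqrt(20 / n))
  expect_lt(abs(mean(a2$truth$n_spliced) - 80), 3 * sqrt(80 / n))
})

test_that("a full synthetic study is deterministic on disk", {
  cfg <- synthetic_config(scale = 0.02, depth = 30)
  td <- withr::local_tempdir()
  s1 <- simulate_study(cfg, file.path(td, "run1"), seed = 5)
  s2 <- simulate_study(cfg, file.path(td, "run2"), seed = 5)
  for (f in c("introns.bed", "genes.gtf", "chrom.sizes",
              "SYN1/alignments.sam", "SYN1/tpm.tsv", "SYN1/SPAD.bed")) {
    expect_identical(readLines(file.path(td, "run1", f)),
                     readLines(file.path(td, "run2", f)))
  }
  # emitted catalog reloads to the generated one
  reload <- suppressMessages(load_intron_catalog(
    s1$paths$catalog, "bed_zero_half_open", s1$paths$chrom_sizes))
  expect_equal(reload$records$intron_id, s1$annotation$catalog$records$intron_id)
  expect_equal(reload$records$start, s1$annotation$catalog$records$start)
})
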