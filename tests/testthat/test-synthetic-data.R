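test_that("generated catalogs satisfy the MSP structure invariants", {
  cat <- generate_catalog(n_genes = 10000, n_msp = 50, seed = 1)
  expect_s3_class(cat, "gene_catalog")
  sizes <- table(cat$msp_id)
  expect_length(sizes, 50)
  expect_true(all(sizes >= 100))
  markers <- table(cat$msp_id[cat$is_marker])
  expect_true(all(markers == 100))
  expect_true(all(cat$is_core[cat$is_marker]))
  expect_true(all(cat$length_bp > 0))
  expect_gt(sum(is.na(cat$msp_id)), 0)
})

test_that("a 100-gene single-MSP catalog is all markers; undersized requests error", {
  cat <- generate_catalog(n_genes = 100, n_msp = 1, seed = 7)
  expect_equal(sum(!is.na(cat$msp_id)), 100)
  expect_true(all(cat$is_marker))
  expect_error(generate_catalog(n_genes = 99, n_msp = 1), "cannot host")
})

test_that("generators are bit-reproducible for a fixed seed and leave the RNG alone", {
  a <- generate_catalog(500, 3, seed = 5)
  b <- generate_catalog(500, 3, seed = 5)
  expect_identical(a, b)
  msp <- sprintf("msp_%04d", 1:10)
  c1 <- generate_cohort(6, msp, seed = 9)
  c2 <- generate_cohort(6, msp, seed = 9)
  expect_identical(c1, c2)
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_catalog(200, 1, seed = 4)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("cohort designs are balanced crossovers with simplex compositions", {
  msp <- sprintf("msp_%04d", 1:20)
  co <- generate_cohort(4, msp, seed = 3)
  expect_equal(nrow(co$design), 16)
  seqs <- table(unique(co$design[, c("subject_id", "sequence")])$sequence)
  expect_lte(abs(diff(as.numeric(seqs))), 1)
  expect_true(all(co$design$visit %in% c("V2", "V4", "V5", "V7")))
  # bread determined by sequence + period
  with(co$design, expect_true(all(
    (bread == "MF") == ((sequence == "MF_first") == (period == 1)))))
  expect_true(all(abs(colSums(co$composition) - 1) < 1e-9))
  expect_true(all(co$composition > 0))

  odd <- generate_cohort(5, msp, seed = 4)
  seqs <- table(unique(odd$design[, c("subject_id", "sequence")])$sequence)
  expect_lte(abs(diff(as.numeric(seqs))), 1)
})

test_that("a single-subject cohort is a valid design but paired tests reject it", {
  co <- generate_cohort(1, sprintf("msp_%04d", 1:5), seed = 2)
  expect_equal(nrow(co$design), 4)
  expect_error(rank_interaction_test(co$composition[1, ], co$design),
               "at least 2 subjects")
})

test_that("planted effects on unknown MSPs are rejected", {
  expect_error(
    generate_cohort(4, c("msp_0001"), effects = list(planted_effect("msp_9999", 0.5)),
                    seed = 1),
    "unknown MSP")
})

test_that("planted multiplicative effects reach their Cliff's-delta target in expectation", {
  msp <- sprintf("msp_%04d", 1:50)
  target <- 0.72
  cds <- vapply(1:50, function(i) {
    co <- generate_cohort(40, msp, effects = list(planted_effect("msp_0012", target)),
                          seed = 5000 + i)
    d <- co$design
    pre <- d$sample_id[d$bread == "MF" & d$phase == "pre"]
    post <- d$sample_id[d$bread == "MF" & d$phase == "post"]
    cliffs_delta(co$composition["msp_0012", post], co$composition["msp_0012", pre])
  }, numeric(1))
  expect_lt(abs(mean(cds) - target), 0.15)
})

test_that("a null cohort plants no systematic pre/post shift", {
  msp <- sprintf("msp_%04d", 1:30)
  cds <- vapply(1:30, function(i) {
    co <- generate_cohort(20, msp, seed = 300 + i)
    d <- co$design
    pre <- d$sample_id[d$bread == "MF" & d$phase == "pre"]
    post <- d$sample_id[d$bread == "MF" & d$phase == "post"]
    cliffs_delta(co$composition["msp_0001", post], co$composition["msp_0001", pre])
  }, numeric(1))
  expect_lt(abs(mean(cds)), 0.1)
})

test_that("simulated alignments honour depth, uniqueness and the shared fraction", {
  cat <- small_msp_catalog(2)
  co <- generate_cohort(1, cat, seed = 1)
  one <- co$composition[, 1]

  aln <- simulate_alignments(one, cat, depth = 1000, shared_fraction = 0, seed = 2)
  expect_equal(nrow(aln), 1000)
  expect_true(all(lengths(aln$gene_ids) == 1))

  aln <- simulate_alignments(one, cat, depth = 10000, shared_fraction = 0.2, seed = 11)
  p_hat <- mean(lengths(aln$gene_ids) > 1)
  half <- qnorm(0.995) * sqrt(0.2 * 0.8 / 10000)
  expect_lt(abs(p_hat - 0.2), half)
  # shared candidates come from a single MSP (paralog-like)
  shared <- aln$gene_ids[lengths(aln$gene_ids) > 1]
  msps <- vapply(shared[1:50], function(g) {
    length(unique(cat$msp_id[match(g, cat$gene_id)]))
  }, numeric(1))
  expect_true(all(msps == 1))

  expect_error(simulate_alignments(one, cat, depth = 0), "positive")
  expect_error(simulate_alignments(one, cat[0, ], depth = 10), "empty catalog")
})

test_that("simulated clinical tables start postprandial curves at the fasting value", {
  des <- crossover_design(4, seed = 6)
  cl <- simulate_clinical(des, seed = 8)
  expect_true(all(cl$value >= 0))
  for (analyte in c("glucose", "insulin")) {
    fast <- cl[cl$variable == analyte & is.na(cl$time_min), ]
    t0 <- cl[cl$variable == paste0(analyte, "_pp") & cl$time_min == 0 &
               !is.na(cl$time_min), ]
    key <- paste(fast$subject_id, fast$visit)
    expect_equal(t0$value, fast$value[match(paste(t0$subject_id, t0$visit), key)])
  }
  # common time grid per series
  pp <- cl[cl$variable == "glucose_pp" & !is.na(cl$time_min), ]
  grids <- tapply(pp$time_min, paste(pp$subject_id, pp$visit),
                  function(t) paste(sort(t), collapse = ","))
  expect_length(unique(grids), 1)
})

test_that("an uncoupled clinical table shows no systematic bread effect", {
  covered <- vapply(1:20, function(i) {
    des <- crossover_design(20, seed = 400 + i)
    cl <- simulate_clinical(des, seed = 400 + i)
    ac <- arm_contrast(cl, des, "tc")
    ac$ci[1] <= 0 && ac$ci[2] >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.85)  # nominal 95% coverage of the null
})

test_that("a negative feature-to-iAUC coupling is recovered by the correlation layer", {
  msp <- sprintf("msp_%04d", 1:20)
  rhos <- vapply(1:50, function(i) {
    co <- generate_cohort(40, msp,
                          effects = list(planted_effect("msp_0003", 0.7)),
                          seed = 7000 + i)
    cl <- simulate_clinical(co$design, co$composition,
                            coupling = list(clinical_coupling("msp_0003",
                                                              "glucose_excursion",
                                                              -1.2)),
                            seed = 7000 + i)
    der <- derive_clinical(cl)
    iauc <- der[der$variable == "glucose_iauc" & is.na(der$time_min), ]
    cmat <- matrix(iauc$value, ncol = 1,
                   dimnames = list(paste(iauc$subject_id, iauc$visit, sep = "_"),
                                   "glucose_iauc"))
    cd <- feature_deltas(t(cmat), co$design)
    fd <- feature_deltas(co$composition["msp_0003", , drop = FALSE], co$design)
    dd <- delta_delta_spearman(fd, cd)
    dd$rho[1]
  }, numeric(1))
  expect_lt(mean(rhos), -0.2)
})
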