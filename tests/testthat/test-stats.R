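test_that("Bray-Curtis follows its definition and bounds", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 3, 0)), 1)       # disjoint supports
  expect_equal(bray_curtis(c(1, 0, 3), c(0, 2, 1)), 5 / 7)
  set.seed(41)
  for (i in 1:20) {
    x <- runif(10) * rbinom(10, 1, 0.7)
    y <- runif(10) * rbinom(10, 1, 0.7)
    if (sum(x + y) == 0) next
    d <- bray_curtis(x, y)
    expect_equal(d, bray_curtis(y, x))                        # symmetry
    expect_gte(d, 0); expect_lte(d, 1)
    # adding a shared constant feature decreases dissimilarity
    if (d > 0) expect_lt(bray_curtis(c(x, 5), c(y, 5)), d)
  }
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "undefined")
  expect_error(bray_curtis(c(-1, 1), c(1, 1)), "non-negative")
})

test_that("Bray-Curtis agrees with vegan's implementation", {
  set.seed(42)
  x <- runif(30); y <- runif(30)
  expect_equal(bray_curtis(x, y),
               as.numeric(vegan::vegdist(rbind(x, y), method = "bray")))
})

test_that("intra-subject Bray-Curtis shifts are computed per subject and bread", {
  cat <- sprintf("msp_%04d", 1:10)
  co <- generate_cohort(5, cat, seed = 43)
  bc <- bray_curtis_shift(co$composition, co$design)
  expect_equal(nrow(bc), 10)  # 5 subjects x 2 breads
  expect_true(all(bc$dissimilarity >= 0 & bc$dissimilarity <= 1))
  s1_mf <- co$design$sample_id[co$design$subject_id == "S001" &
                                 co$design$bread == "MF"]
  expect_equal(bc$dissimilarity[bc$subject_id == "S001" & bc$bread == "MF"],
               bray_curtis(co$composition[, s1_mf[1]], co$composition[, s1_mf[2]]))
})

test_that("the interaction test rejects degenerate input and drops incomplete subjects", {
  des <- crossover_design(6, seed = 44)
  expect_error(rank_interaction_test(rep(1, nrow(des)), des), "tied")
  v <- rnorm(nrow(des))
  v[des$subject_id == "S001" & des$visit == "V7"] <- NA
  p <- rank_interaction_test(v, des)
  expect_equal(attr(p, "n"), 5)
  expect_equal(attr(p, "n_dropped"), 1)
})

test_that("the interaction p-value is invariant under strictly monotone transforms", {
  des <- crossover_design(10, seed = 45)
  set.seed(45)
  v <- rlnorm(nrow(des))
  p1 <- as.numeric(rank_interaction_test(v, des))
  expect_equal(as.numeric(rank_interaction_test(log(v), des)), p1)
  expect_equal(as.numeric(rank_interaction_test(v^3, des)), p1)
  expect_gt(p1, 0); expect_lte(p1, 1)
})

test_that("the interaction test is calibrated under the null", {
  des <- crossover_design(40, seed = 46)
  set.seed(46)
  rej <- vapply(1:200, function(i) {
    as.numeric(rank_interaction_test(rnorm(nrow(des)), des)) < 0.05
  }, logical(1))
  half <- qnorm(0.995) * sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(mean(rej) - 0.05), half)
})

test_that("the interaction p agrees with an exact within-subject permutation oracle", {
  des <- crossover_design(8, seed = 47)
  set.seed(47)
  for (i in 1:8) {
    v <- rnorm(nrow(des)) +
      0.4 * (i %% 3) * (des$bread == "MF" & des$phase == "post")
    p_ats <- as.numeric(rank_interaction_test(v, des))
    p_perm <- oracle_interaction_perm(v, des)
    expect_lt(abs(p_ats - p_perm), 0.05)
  }
})

test_that("Wilcoxon signed-rank matches its exact small-sample distribution", {
  # 5 all-positive differences: two-sided exact p = 2/32
  expect_equal(as.numeric(wilcoxon_signed_rank(rep(0, 5), 1:5)), 0.0625)
  # antisymmetry under swapping pre and post
  set.seed(48)
  pre <- rnorm(12); post <- rnorm(12)
  expect_equal(as.numeric(wilcoxon_signed_rank(pre, post)),
               as.numeric(wilcoxon_signed_rank(post, pre)))
  # agreement with stats::wilcox.test in its exact tie-free regime
  for (i in 1:10) {
    pre <- rnorm(9); post <- rnorm(9)
    expect_equal(as.numeric(wilcoxon_signed_rank(pre, post)),
                 wilcox.test(post, pre, paired = TRUE, exact = TRUE)$p.value)
  }
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
  expect_error(wilcoxon_signed_rank(1, 2), "at least 2")
})

test_that("tied differences get mid-ranks, matching full enumeration", {
  d <- c(0.5, -0.5, 1.2, 2.0)  # one tie among |d|
  expect_equal(as.numeric(wilcoxon_signed_rank(rep(0, 4), d)),
               oracle_signed_rank(d))
  set.seed(49)
  for (i in 1:20) {
    d <- round(rnorm(sample(4:10, 1)), 1)  # rounding induces frequent ties
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(as.numeric(wilcoxon_signed_rank(rep(0, length(d)), d)),
                 oracle_signed_rank(d))
  }
})

test_that("the normal-approximation branch tracks the exact branch at its boundary", {
  set.seed(50)
  d <- rnorm(24, mean = 0.4)
  p_exact <- as.numeric(wilcoxon_signed_rank(rep(0, 24), d, exact_limit = 25))
  p_approx <- as.numeric(wilcoxon_signed_rank(rep(0, 24), d, exact_limit = 10))
  expect_lt(abs(p_exact - p_approx), 0.01)
})

test_that("Cliff's delta counts cross pairs", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cliffs_delta(c(5, 6), c(1, 2)), 1)
  expect_equal(cliffs_delta(c(1, 2, 3), c(2, 3, 4)), -5 / 9)
  set.seed(51)
  x <- rnorm(15); y <- rnorm(12)
  expect_equal(cliffs_delta(x, y), oracle_cliffs(x, y))
  expect_equal(cliffs_delta(x, y), -cliffs_delta(y, x))       # antisymmetry
  expect_gt(cliffs_delta(x + 2, y), cliffs_delta(x, y))       # location shift
  expect_error(cliffs_delta(numeric(0), y), "empty")
})

test_that("effect-size grades follow the printed magnitude thresholds", {
  expect_equal(grade_effect_size(0.72), "large")
  expect_equal(grade_effect_size(-0.27), "small")
  expect_equal(grade_effect_size(0.46), "medium")
  expect_equal(grade_effect_size(0.07), "negligible")
  expect_equal(grade_effect_size(c(0.147, 0.33, 0.474)),
               c("small", "medium", "large"))   # boundaries: < is strict
  expect_error(grade_effect_size(1.2), "<= 1")
})

test_that("Benjamini-Hochberg adjustment matches the step-up reference", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  set.seed(52)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- benjamini_hochberg(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p))
    perm <- sample(seq_along(p))
    expect_equal(benjamini_hochberg(p[perm]), q[perm])  # permutation invariance
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the differential screen reports one row per analyzable feature", {
  msp <- sprintf("msp_%04d", 1:15)
  co <- generate_cohort(10, msp, seed = 53)
  feats <- co$composition
  feats <- rbind(feats, constant = 1)  # a degenerate feature
  scr <- differential_screen(feats, co$design)
  expect_s3_class(scr, "crossover_screen")
  expect_equal(nrow(scr), 15)
  expect_equal(attr(scr, "degenerate"), "constant")
  expect_true(all(scr$q_value >= scr$p_interaction))
  expect_equal(scr$significant, scr$q_value <= 0.1)
  expect_equal(scr$grade_mf, grade_effect_size(scr$cliffs_delta_mf))
  expect_output(print(scr), "differential screen")
})

test_that("the screen flags a strongly planted feature and grades it large", {
  msp <- sprintf("msp_%04d", 1:30)
  co <- generate_cohort(30, msp,
                        effects = list(planted_effect("msp_0007", 0.8)),
                        seed = 54)
  scr <- differential_screen(co$composition, co$design)
  row <- scr[scr$feature_id == "msp_0007", ]
  expect_true(row$significant)
  expect_equal(row$grade_mf, "large")
  expect_gt(row$cliffs_delta_mf, row$cliffs_delta_ctl)
})

test_that("delta-delta Spearman recovers self-correlation and skips short pairs", {
  set.seed(55)
  fd <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("S%03d", 1:20),
                                                 c("f1", "f2")))
  cd <- fd[, "f1", drop = FALSE]
  colnames(cd) <- "same"
  out <- delta_delta_spearman(fd, cd)
  expect_equal(out$rho[out$feature == "f1"], 1)
  expect_true(out$sig_q[out$feature == "f1"])
  # monotone transform invariance of rho
  out2 <- delta_delta_spearman(fd, exp(cd))
  expect_equal(out2$rho, out$rho)
  # pairs with < 3 complete observations are skipped and reported
  cd2 <- cbind(cd, short = c(cd[1:2, 1], rep(NA, 18)))
  out3 <- delta_delta_spearman(fd, cd2)
  expect_equal(nrow(out3), 2)
  expect_length(attr(out3, "skipped"), 2)
})
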