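#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`, in `[0, 1]`: 0 for identical profiles, 1 for
#' disjoint supports.
#'
#' @param x,y non-negative abundance vectors on the same feature index.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stopf("abundances must be non-negative")
  tot <- sum(x + y)
  if (tot == 0) stopf("Bray-Curtis is undefined for two all-zero vectors")
  sum(abs(x - y)) / tot
}

#' Intra-subject Bray-Curtis shift per bread
#'
#' For each subject and each bread, the Bray-Curtis dissimilarity between the
#' pre- and post-intervention profiles of that arm — the intra-individual
#' compositional shift induced by each bread.
#'
#' @param features features x samples abundance matrix with sample ids as
#'   column names.
#' @param design a `crossover_design`.
#' @return data.frame with columns `subject_id`, `bread`, `dissimilarity`.
#' @export
bray_curtis_shift <- function(features, design) {
  design$phase <- design_phase(design)
  out <- list()
  for (subj in unique(design$subject_id)) {
    for (arm in c("MF", "CTL")) {
      pre <- design$sample_id[design$subject_id == subj & design$bread == arm &
                                design$phase == "pre"]
      post <- design$sample_id[design$subject_id == subj & design$bread == arm &
                                 design$phase == "post"]
      if (length(pre) != 1 || length(post) != 1) next
      if (!all(c(pre, post) %in% colnames(features))) next
      out[[length(out) + 1L]] <- data.frame(
        subject_id = subj, bread = arm,
        dissimilarity = bray_curtis(features[, pre], features[, post]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Rank-based bread-by-visit interaction test
#'
#' Nonparametric longitudinal test for the interaction of the factors bread
#' and visit in the fully within-subject 2x2 crossover layout. All 4n
#' observations are ranked jointly (mid-ranks); each subject contributes the
#' interaction contrast of its cell ranks, `(MF.post - MF.pre) - (CTL.post -
#' CTL.pre)`, and the ANOVA-type statistic for this rank-one hypothesis —
#' whose box-type numerator degrees of freedom equal 1 exactly — is referred
#' to an F(1, n-1) distribution, the within-subject small-sample reference.
#' The p-value is invariant under any strictly monotone transform of the
#' values. Subjects with incomplete 4-visit data are dropped and reported via
#' the `n_dropped` attribute.
#'
#' @param values numeric vector of one feature's values, aligned with the rows
#'   of `design` (or named by `design$sample_id`).
#' @param design a `crossover_design` (columns `subject_id`, `bread`, `phase`
#'   or `visit`).
#' @return the interaction p-value, with attributes `statistic`, `df`
#'   (denominator df), `n` (complete subjects) and `n_dropped`.
#' @export
rank_interaction_test <- function(values, design) {
  design$phase <- design_phase(design)
  if (!is.null(names(values))) values <- values[design$sample_id]
  stopifnot(length(values) == nrow(design))
  cell <- paste(design$bread, design$phase, sep = ".")
  wide <- tapply(values, list(design$subject_id, cell), function(v) v[1])
  need <- c("MF.pre", "MF.post", "CTL.pre", "CTL.post")
  if (!all(need %in% colnames(wide))) stopf("design must cover all four cells")
  wide <- wide[, need, drop = FALSE]
  complete <- stats::complete.cases(wide)
  n_dropped <- sum(!complete)
  wide <- wide[complete, , drop = FALSE]
  n <- nrow(wide)
  if (n < 2) stopf("need at least 2 subjects with complete 4-visit data")
  if (length(unique(as.vector(wide))) == 1) {
    stopf("degenerate data: all values tied")
  }
  r <- matrix(rank(as.vector(wide)), n, 4)
  d <- (r[, 2] - r[, 1]) - (r[, 4] - r[, 3])
  v <- stats::var(d)
  if (v == 0 && mean(d) == 0) stopf("degenerate data: interaction contrast identically zero")
  f <- if (v == 0) Inf else n * mean(d)^2 / v
  p <- stats::pf(f, 1, n - 1, lower.tail = FALSE)
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(p, statistic = unname(f), df = n - 1, n = n, n_dropped = n_dropped)
}

#' Wilcoxon signed-rank test for paired pre/post values
#'
#' Two-sided paired test. Zero differences are dropped (classic convention;
#' `zero_method = "pratt"` instead ranks them and then discards them). Ties
#' among absolute differences receive mid-ranks. For up to `exact_limit`
#' nonzero pairs the p-value is exact, computed from the full sign-assignment
#' distribution of the rank sum (by convolution, equivalent to enumerating all
#' 2^n sign patterns); above that, a normal approximation with continuity
#' correction is used. The two-sided p is twice the smaller tail, capped at 1.
#'
#' @param pre,post paired vectors (pairs with `NA` are dropped).
#' @param zero_method `"wilcox"` (drop zero differences before ranking) or
#'   `"pratt"` (rank with zeros, then drop them).
#' @param exact_limit largest number of nonzero pairs for which the exact
#'   distribution is used.
#' @return two-sided p-value with attributes `statistic` (positive-rank sum
#'   `V`) and `n` (nonzero pairs used).
#' @export
wilcoxon_signed_rank <- function(pre, post, zero_method = c("wilcox", "pratt"),
                                 exact_limit = 25) {
  zero_method <- match.arg(zero_method)
  stopifnot(length(pre) == length(post))
  ok <- stats::complete.cases(pre, post)
  d <- (post - pre)[ok]
  if (length(d) == 0 || all(d == 0)) {
    stopf("degenerate data: all paired differences are zero")
  }
  if (zero_method == "wilcox") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r <- rank(abs(d))
    r <- r[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  if (n < 2) stopf("need at least 2 nonzero paired differences")
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(r, v)
  } else {
    e <- sum(r) / 2
    s <- sqrt(sum(r^2) / 4)
    z <- (abs(v - e) - 0.5) / s
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  }
  structure(p, statistic = v, n = n)
}

# Exact two-sided p for the signed-rank sum with (mid-)ranks r and observed
# positive-rank sum v: convolve the generating polynomial over 2*r (integers),
# then take twice the smaller tail.
signed_rank_exact_p <- function(r, v) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  dist <- numeric(total + 1)  # index i holds P(2V = i - 1) * 2^n
  dist[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), dist[seq_len(total + 1 - ri)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  v2 <- as.integer(round(2 * v))
  lower <- sum(dist[seq_len(v2 + 1)])
  upper <- sum(dist[(v2 + 1):(total + 1)])
  min(1, 2 * min(lower, upper))
}

#' Cliff's delta effect size
#'
#' `(#\{x_i > y_j\} - #\{x_i < y_j\}) / (|x| |y|)` over all cross pairs: a
#' nonparametric effect size in `[-1, 1]`, 0 meaning stochastic equality and
#' +/-1 complete separation.
#'
#' @param x,y non-empty numeric vectors (`NA` dropped).
#' @return Cliff's delta in `[-1, 1]`.
#' @export
cliffs_delta <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stopf("empty input to cliffs_delta")
  mean(sign(outer(x, y, "-")))
}

#' Grade a Cliff's delta magnitude
#'
#' Standard magnitude grades: negligible if `|d| < 0.147`, small if
#' `|d| < 0.33`, medium if `|d| < 0.474`, large otherwise.
#'
#' @param delta Cliff's delta value(s) in `[-1, 1]`.
#' @return character vector of grades.
#' @export
grade_effect_size <- function(delta) {
  if (any(abs(delta) > 1, na.rm = TRUE)) stopf("|delta| must be <= 1")
  cut(abs(delta), breaks = c(-Inf, 0.147, 0.33, 0.474, Inf), right = FALSE,
      labels = c("negligible", "small", "medium", "large")) |> as.character()
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity;
#' `q >= p` element-wise and a single p-value is returned unchanged.
#'
#' @param pvalues p-values in `[0, 1]` (`NA` allowed, passed through).
#' @return q-values in the input order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Longitudinal differential screen over a feature matrix
#'
#' For each feature (MSP, functional module, CAZy family, richness, ...):
#' the rank-based bread-by-visit interaction p-value, Benjamini-Hochberg
#' q-value across all analyzable features, a significance flag at
#' `q <= q_threshold`, and per-bread post-vs-pre Wilcoxon signed-rank p-values
#' and Cliff's deltas (post distribution vs pre distribution, unpaired over
#' all cross pairs) with magnitude grades. Features on which every value is
#' tied (or that otherwise fail the degeneracy checks) are excluded before the
#' BH correction — an undefined p-value must not shrink the BH family — and
#' reported in the `degenerate` attribute.
#'
#' @param features features x samples matrix; column names must match
#'   `design$sample_id`.
#' @param design a `crossover_design`.
#' @param q_threshold significance threshold on the q-value.
#' @return a `crossover_screen` data.frame, one row per analyzable feature:
#'   `feature_id`, `p_interaction`, `q_value`, `significant`, `p_wilcoxon_mf`,
#'   `p_wilcoxon_ctl`, `cliffs_delta_mf`, `grade_mf`, `cliffs_delta_ctl`,
#'   `grade_ctl`; attribute `degenerate` lists excluded features.
#' @export
differential_screen <- function(features, design, q_threshold = 0.1) {
  if (is.null(dim(features))) {
    features <- matrix(features, nrow = 1,
                       dimnames = list("feature_1", names(features)))
  }
  if (!all(design$sample_id %in% colnames(features))) {
    stopf("feature columns do not cover the design's sample ids")
  }
  design$phase <- design_phase(design)
  feats <- rownames(features) %||% sprintf("feature_%d", seq_len(nrow(features)))

  arm_pairs <- function(arm) {
    d <- design[design$bread == arm, ]
    pre <- tapply(d$sample_id[d$phase == "pre"], d$subject_id[d$phase == "pre"],
                  function(s) s[1])
    post <- tapply(d$sample_id[d$phase == "post"], d$subject_id[d$phase == "post"],
                   function(s) s[1])
    subj <- intersect(names(pre), names(post))
    list(pre = unname(pre[subj]), post = unname(post[subj]))
  }
  mf <- arm_pairs("MF")
  ctl <- arm_pairs("CTL")

  rows <- list()
  degenerate <- character(0)
  for (i in seq_len(nrow(features))) {
    x <- features[i, design$sample_id]
    p_int <- tryCatch(rank_interaction_test(unname(x), design),
                      error = function(e) NA_real_)
    if (is.na(p_int)) {
      degenerate <- c(degenerate, feats[i])
      next
    }
    wilcox_arm <- function(pairs) {
      tryCatch(as.numeric(wilcoxon_signed_rank(features[i, pairs$pre],
                                               features[i, pairs$post])),
               error = function(e) NA_real_)
    }
    cd_mf <- cliffs_delta(features[i, mf$post], features[i, mf$pre])
    cd_ctl <- cliffs_delta(features[i, ctl$post], features[i, ctl$pre])
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = feats[i],
      p_interaction = as.numeric(p_int),
      p_wilcoxon_mf = wilcox_arm(mf),
      p_wilcoxon_ctl = wilcox_arm(ctl),
      cliffs_delta_mf = cd_mf,
      grade_mf = grade_effect_size(cd_mf),
      cliffs_delta_ctl = cd_ctl,
      grade_ctl = grade_effect_size(cd_ctl),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stopf("no analyzable features")
  res <- do.call(rbind, rows)
  res$q_value <- benjamini_hochberg(res$p_interaction)
  res$significant <- res$q_value <= q_threshold
  res <- res[, c("feature_id", "p_interaction", "q_value", "significant",
                 "p_wilcoxon_mf", "p_wilcoxon_ctl",
                 "cliffs_delta_mf", "grade_mf",
                 "cliffs_delta_ctl", "grade_ctl")]
  attr(res, "degenerate") <- degenerate
  attr(res, "q_threshold") <- q_threshold
  class(res) <- c("crossover_screen", "data.frame")
  res
}

#' @export
print.crossover_screen <- function(x, ...) {
  cat(sprintf("crossover differential screen: %d features, %d significant (q <= %g)\n",
              nrow(x), sum(x$significant), attr(x, "q_threshold")))
  if (length(attr(x, "degenerate"))) {
    cat(sprintf("  %d degenerate features excluded from the BH family\n",
                length(attr(x, "degenerate"))))
  }
  hits <- x[x$significant, , drop = FALSE]
  if (nrow(hits)) {
    hits <- hits[order(hits$q_value), ]
    print.data.frame(utils::head(hits, 10), digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.crossover_screen <- function(object, ...) {
  cat(sprintf("features analyzed: %d (degenerate excluded: %d)\n",
              nrow(object), length(attr(object, "degenerate"))))
  cat(sprintf("significant at q <= %g: %d\n", attr(object, "q_threshold"),
              sum(object$significant)))
  cat("Cliff's delta grades (multi-fiber arm):\n")
  print(table(object$grade_mf))
  invisible(object)
}

#' Per-subject post-minus-pre deltas within one arm
#'
#' @param features features x samples matrix (sample ids as column names).
#' @param design a `crossover_design`.
#' @param arm `"MF"` or `"CTL"`.
#' @return subjects x features matrix of post - pre differences.
#' @export
feature_deltas <- function(features, design, arm = "MF") {
  if (is.null(dim(features))) {
    features <- matrix(features, nrow = 1,
                       dimnames = list("feature_1", names(features)))
  }
  design$phase <- design_phase(design)
  d <- design[design$bread == arm, ]
  subj <- unique(d$subject_id)
  out <- matrix(NA_real_, length(subj), nrow(features),
                dimnames = list(subj, rownames(features)))
  for (s in subj) {
    pre <- d$sample_id[d$subject_id == s & d$phase == "pre"]
    post <- d$sample_id[d$subject_id == s & d$phase == "post"]
    if (length(pre) == 1 && length(post) == 1 &&
        all(c(pre, post) %in% colnames(features))) {
      out[s, ] <- features[, post] - features[, pre]
    }
  }
  out
}

#' Delta-delta Spearman correlations
#'
#' Correlates per-subject changes (post minus pre, typically within the
#' multi-fiber arm) of metagenomic features with those of clinical variables.
#' Each (feature, variable) pair with at least 3 complete subject pairs gets a
#' Spearman rho and p-value; q-values are Benjamini-Hochberg-adjusted across
#' all computed pairs, and two significance annotations are reported:
#' `sig_q` (q <= 0.1) and `sig_p` (raw p <= 0.05).
#'
#' @param feature_deltas subjects x features matrix (see [feature_deltas()]).
#' @param clinical_deltas subjects x variables matrix, same subjects.
#' @param q_threshold,p_threshold annotation thresholds.
#' @return long data.frame (`feature`, `variable`, `rho`, `p`, `q`, `sig_q`,
#'   `sig_p`); skipped pairs (< 3 complete observations) are listed in the
#'   `skipped` attribute.
#' @export
delta_delta_spearman <- function(feature_deltas, clinical_deltas,
                                 q_threshold = 0.1, p_threshold = 0.05) {
  subj <- intersect(rownames(feature_deltas), rownames(clinical_deltas))
  if (length(subj) == 0) stopf("no shared subjects between the delta matrices")
  fd <- feature_deltas[subj, , drop = FALSE]
  cd <- clinical_deltas[subj, , drop = FALSE]
  rows <- list()
  skipped <- character(0)
  for (f in colnames(fd)) {
    for (v in colnames(cd)) {
      ok <- stats::complete.cases(fd[, f], cd[, v])
      if (sum(ok) < 3) {
        skipped <- c(skipped, paste(f, v, sep = " ~ "))
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(fd[ok, f], cd[ok, v], method = "spearman",
                        exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, variable = v, rho = unname(ct$estimate),
        p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stopf("no correlatable pairs")
  res <- do.call(rbind, rows)
  res$q <- benjamini_hochberg(res$p)
  res$sig_q <- res$q <= q_threshold
  res$sig_p <- res$p <= p_threshold
  attr(res, "skipped") <- skipped
  res
}
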