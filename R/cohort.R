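#' Build the crossover visit design
#'
#' Two-arm, two-period crossover with four profiled visits: V2/V4 bracket the
#' first intervention period and V5/V7 the second, with a washout in between.
#' The bread received in a period is determined by the subject's randomised
#' sequence. Sequence allocation is balanced (group sizes differ by at most 1).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed for the randomised sequence allocation.
#' @return a `crossover_design` data.frame with one row per subject-visit:
#'   `subject_id`, `sequence` (`"MF_first"` / `"CTL_first"`), `visit`
#'   (`V2`,`V4`,`V5`,`V7`), `period` (1, 2), `phase` (`"pre"` / `"post"`),
#'   `bread` (`"MF"` / `"CTL"`), `sample_id`.
#' @export
crossover_design <- function(n_subjects, seed = NULL) {
  stopifnot(n_subjects >= 1)
  with_seed(seed, {
    subjects <- sprintf("S%03d", seq_len(n_subjects))
    seqs <- sample(rep(c("MF_first", "CTL_first"),
                       c(ceiling(n_subjects / 2), floor(n_subjects / 2))))
    visits <- c("V2", "V4", "V5", "V7")
    design <- data.frame(
      subject_id = rep(subjects, each = 4),
      sequence = rep(seqs, each = 4),
      visit = rep(visits, n_subjects),
      period = rep(c(1L, 1L, 2L, 2L), n_subjects),
      phase = rep(c("pre", "post", "pre", "post"), n_subjects),
      stringsAsFactors = FALSE)
    design$bread <- ifelse(
      (design$sequence == "MF_first") == (design$period == 1L), "MF", "CTL")
    design$sample_id <- paste(design$subject_id, design$visit, sep = "_")
    class(design) <- c("crossover_design", "data.frame")
    design
  })
}

# Derive the pre/post phase from visit labels when a design lacks it.
design_phase <- function(design) {
  if (!is.null(design$phase)) return(design$phase)
  ifelse(design$visit %in% c("V2", "V5"), "pre", "post")
}

#' Specify a planted effect for the cohort generator
#'
#' @param target_id MSP identifier to shift.
#' @param cliffs_delta_target signed Cliff's delta (in `[-1, 1]`) that the
#'   post-vs-pre abundance contrast of the target should reach, in expectation,
#'   in the specified arm.
#' @param arm `"MF"` or `"CTL"`.
#' @return a `planted_effect` list.
#' @export
planted_effect <- function(target_id, cliffs_delta_target, arm = "MF") {
  stopifnot(is.character(target_id), length(target_id) == 1,
            abs(cliffs_delta_target) <= 1, arm %in% c("MF", "CTL"))
  structure(list(target_id = target_id,
                 cliffs_delta_target = cliffs_delta_target,
                 direction = if (cliffs_delta_target >= 0) "increase" else "decrease",
                 arm = arm),
            class = "planted_effect")
}

#' Generate a synthetic crossover cohort with latent MSP compositions
#'
#' Draws a balanced crossover design and, for every subject-visit sample, a
#' latent MSP composition on the simplex. Log-abundances follow a log-normal
#' model: an MSP-level mean (heavy-tailed abundance distribution), a subject
#' random effect, and a visit-level noise term; compositions are renormalised
#' to sum to one. Planted effects are multiplicative shifts on a target MSP at
#' the post visit of the chosen arm; the multiplier is calibrated numerically
#' (on an independent calibration cohort, after renormalisation) so the
#' unpaired post-vs-pre Cliff's delta of the target approaches its requested
#' value in expectation.
#'
#' @param n_subjects number of subjects (>= 1; downstream paired tests need
#'   >= 2 complete subjects).
#' @param msp_ids MSP identifiers, or a `gene_catalog` whose MSPs are used.
#' @param effects list of [planted_effect()] specifications.
#' @param sd_msp standard deviation of MSP-level log-means (spread of mean
#'   abundances across MSPs, natural-log scale).
#' @param sd_subject inter-subject standard deviation of log-abundance.
#' @param sd_visit intra-subject visit-to-visit standard deviation.
#' @param seed integer seed.
#' @return a list with `design` (a `crossover_design`), `composition` (MSPs x
#'   samples matrix of relative abundances, columns summing to one) and
#'   `effects` (the effect list augmented with the calibrated multipliers).
#' @export
generate_cohort <- function(n_subjects, msp_ids, effects = list(),
                            sd_msp = 2, sd_subject = 1, sd_visit = 0.5,
                            seed = NULL) {
  stopifnot(n_subjects >= 1)
  if (inherits(msp_ids, "gene_catalog")) {
    msp_ids <- sort(unique(msp_ids$msp_id[!is.na(msp_ids$msp_id)]))
  }
  n_msp <- length(msp_ids)
  stopifnot(n_msp >= 1)
  if (inherits(effects, "planted_effect")) effects <- list(effects)
  for (ef in effects) {
    if (!ef$target_id %in% msp_ids) {
      stopf("planted effect targets unknown MSP '%s'", ef$target_id)
    }
  }

  with_seed(seed, {
    design <- crossover_design(n_subjects, seed = NULL)
    n_samples <- nrow(design)
    mu <- stats::rnorm(n_msp, 0, sd_msp)
    subj_eff <- matrix(stats::rnorm(n_msp * n_subjects, 0, sd_subject),
                       n_msp, n_subjects)
    log_a <- mu + subj_eff[, match(design$subject_id, unique(design$subject_id))] +
      matrix(stats::rnorm(n_msp * n_samples, 0, sd_visit), n_msp, n_samples)
    dimnames(log_a) <- list(msp_ids, design$sample_id)

    effects <- lapply(effects, function(ef) {
      ef$multiplier <- calibrate_multiplier(
        ef$cliffs_delta_target, which(msp_ids == ef$target_id), mu,
        sd_subject = sd_subject, sd_visit = sd_visit)
      ef
    })
    for (ef in effects) {
      hit <- design$bread == ef$arm & design$phase == "post"
      log_a[ef$target_id, hit] <- log_a[ef$target_id, hit] + log(ef$multiplier)
    }

    a <- exp(log_a)
    composition <- sweep(a, 2, colSums(a), "/")
    list(design = design, composition = composition, effects = effects)
  })
}

# Solve for the multiplicative shift whose post-vs-pre Cliff's delta on the
# renormalised target abundance matches `delta` in expectation. Uses a fixed
# calibration cohort (common random numbers across multiplier evaluations) so
# the objective is effectively smooth and monotone in log(m).
calibrate_multiplier <- function(delta, target_index, mu,
                                 sd_subject, sd_visit, n_cal = 400) {
  if (delta == 0) return(1)
  n_msp <- length(mu)
  subj <- matrix(stats::rnorm(n_msp * n_cal, 0, sd_subject), n_msp, n_cal)
  pre <- exp(mu + subj + matrix(stats::rnorm(n_msp * n_cal, 0, sd_visit), n_msp, n_cal))
  post <- exp(mu + subj + matrix(stats::rnorm(n_msp * n_cal, 0, sd_visit), n_msp, n_cal))
  t_pre <- pre[target_index, ] / colSums(pre)
  post_t <- post[target_index, ]
  post_rest <- colSums(post) - post_t
  realized <- function(log_m) {
    t_post <- post_t * exp(log_m) / (post_rest + post_t * exp(log_m))
    cliffs_delta(t_post, t_pre)
  }
  f <- function(log_m) realized(log_m) - delta
  root <- stats::uniroot(f, lower = -25, upper = 25, tol = 1e-4)
  exp(root$root)
}
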