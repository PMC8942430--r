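#' HOMA-IR insulin-resistance index
#'
#' Homeostasis model assessment of insulin resistance: fasting plasma glucose
#' (mmol/L) times fasting plasma insulin (mIU/L) divided by 22.5.
#'
#' @param glucose fasting glucose in mmol/L (> 0).
#' @param insulin fasting insulin in mIU/L (>= 0).
#' @return HOMA-IR index (vectorised).
#' @export
homa_ir <- function(glucose, insulin) {
  if (any(glucose <= 0, na.rm = TRUE)) stopf("glucose must be positive")
  if (any(insulin < 0, na.rm = TRUE)) stopf("insulin must be non-negative")
  glucose * insulin / 22.5
}

#' Friedewald LDL cholesterol
#'
#' LDL-C = TC - HDL-C - TG / 2.2, all in mmol/L (the 2.2 divisor is the
#' mmol/L form of the Friedewald formula). The formula loses validity at high
#' triglycerides; above `tg_limit` the value is still returned but a warning
#' flags it.
#'
#' @param tc total cholesterol (mmol/L).
#' @param hdl HDL cholesterol (mmol/L).
#' @param tg triglycerides (mmol/L).
#' @param tg_limit validity bound on TG (default 4.5 mmol/L).
#' @return LDL cholesterol in mmol/L (vectorised).
#' @export
friedewald_ldl <- function(tc, hdl, tg, tg_limit = 4.5) {
  if (any(c(tc, hdl, tg) < 0, na.rm = TRUE)) stopf("inputs must be non-negative")
  if (any(tg > tg_limit, na.rm = TRUE)) {
    warning(sprintf("TG above %g mmol/L: Friedewald LDL is unreliable", tg_limit),
            call. = FALSE)
  }
  tc - hdl - tg / 2.2
}

#' Postprandial curve summaries: tAUC, iAUC and peak
#'
#' Total area under the curve by the trapezoidal rule on the observed time
#' grid (no interpolation), incremental AUC as tAUC minus the baseline value
#' (at t = 0) times the total time span (net incremental convention: negative
#' excursions are allowed unless `positive_only`), and the peak concentration.
#'
#' @param times minutes from the meal, strictly increasing, starting at 0.
#' @param values analyte concentrations (>= 0), same length as `times`,
#'   at least 3 points.
#' @param positive_only if `TRUE`, truncate the baseline-subtracted curve at
#'   zero before integrating the iAUC (positive incremental convention).
#' @return named list: `tauc` (concentration x min), `iauc` (same units),
#'   `peak` (concentration units).
#' @export
postprandial_summary <- function(times, values, positive_only = FALSE) {
  if (length(times) < 3) stopf("postprandial series needs at least 3 points")
  stopifnot(length(times) == length(values))
  if (times[1] != 0) stopf("postprandial series must start at t = 0")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (any(values < 0)) stopf("concentrations must be non-negative")
  trapz <- function(t, v) sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  tauc <- trapz(times, values)
  iauc <- if (positive_only) {
    trapz(times, pmax(values - values[1], 0))
  } else {
    tauc - values[1] * (times[length(times)] - times[1])
  }
  list(tauc = tauc, iauc = iauc, peak = max(values))
}

#' Estimated group difference between breads for a clinical variable
#'
#' For each subject with all four relevant visits, the change induced by each
#' bread is `post - pre` within that arm; the estimated group difference (EGD)
#' is the mean over subjects of `(MF change) - (CTL change)`, with a 95%
#' confidence interval from the t distribution on the paired per-subject
#' differences. This paired-difference contrast deliberately replaces a
#' covariance-structured mixed model: it estimates the same bread contrast
#' without period/sequence adjustment, so exact replication of mixed-model
#' estimates is not claimed.
#'
#' @param clinical long clinical table (`subject_id`, `visit`, `variable`,
#'   `time_min`, `value`); the variable is read at `time_min` `NA` (fasting
#'   rows) unless `time_min` is given.
#' @param design a `crossover_design`.
#' @param variable which clinical variable to contrast.
#' @param conf_level confidence level for the interval.
#' @return an `arm_contrast` list: `variable`, `egd`, `ci` (length 2), `n`
#'   (complete subjects), `changes` (per-arm mean change), `cell_means`
#'   (per-arm pre/post means), `subject_diffs`.
#' @export
arm_contrast <- function(clinical, design, variable, conf_level = 0.95) {
  design$phase <- design_phase(design)
  rows <- clinical$variable == variable & is.na(clinical$time_min)
  if (!any(rows)) stopf("variable '%s' not found among fasting rows", variable)
  cl <- clinical[rows, ]
  key <- paste(cl$subject_id, cl$visit)
  val <- function(subj, visit) {
    v <- cl$value[match(paste(subj, visit), key)]
    v
  }
  subjects <- unique(design$subject_id)
  cells <- c("MF.pre", "MF.post", "CTL.pre", "CTL.post")
  mat <- matrix(NA_real_, length(subjects), 4,
                dimnames = list(subjects, cells))
  for (i in seq_along(subjects)) {
    d <- design[design$subject_id == subjects[i], ]
    for (j in seq_len(nrow(d))) {
      mat[i, paste(d$bread[j], d$phase[j], sep = ".")] <-
        val(subjects[i], d$visit[j])
    }
  }
  complete <- stats::complete.cases(mat)
  mat <- mat[complete, , drop = FALSE]
  n <- nrow(mat)
  if (n == 0) stopf("no subject has complete data for '%s'", variable)
  d_mf <- mat[, "MF.post"] - mat[, "MF.pre"]
  d_ctl <- mat[, "CTL.post"] - mat[, "CTL.pre"]
  diffs <- d_mf - d_ctl
  egd <- mean(diffs)
  ci <- if (n > 1) {
    half <- stats::qt(1 - (1 - conf_level) / 2, n - 1) * stats::sd(diffs) / sqrt(n)
    c(egd - half, egd + half)
  } else {
    c(NA_real_, NA_real_)
  }
  structure(list(variable = variable, egd = egd, ci = ci, n = n,
                 changes = c(MF = mean(d_mf), CTL = mean(d_ctl)),
                 cell_means = colMeans(mat),
                 subject_diffs = diffs,
                 conf_level = conf_level),
            class = "arm_contrast")
}

#' @export
print.arm_contrast <- function(x, ...) {
  cat(sprintf("%s: EGD = %.3f (%g%% CI %.3f to %.3f), n = %d\n",
              x$variable, x$egd, 100 * x$conf_level, x$ci[1], x$ci[2], x$n))
  cat(sprintf("  mean change: MF %+.3f, CTL %+.3f\n",
              x$changes["MF"], x$changes["CTL"]))
  invisible(x)
}

#' Derive secondary clinical variables per subject-visit
#'
#' Adds HOMA-IR, Friedewald LDL and postprandial summaries (tAUC, iAUC, peak
#' of glucose and insulin) to a long clinical table, as additional fasting-row
#' variables (`homa`, `ldl`, `glucose_tauc`, `glucose_iauc`, `glucose_peak`,
#' `insulin_tauc`, `insulin_iauc`, `insulin_peak`).
#'
#' @param clinical long clinical table (see [simulate_clinical()] for the
#'   layout): fasting variables `glucose`, `insulin`, `tc`, `hdl`, `tg` at
#'   `time_min` `NA`, postprandial series `glucose_pp`, `insulin_pp` on a
#'   common time grid.
#' @param positive_only iAUC convention, passed to [postprandial_summary()].
#' @return the clinical table with derived rows appended.
#' @export
derive_clinical <- function(clinical, positive_only = FALSE) {
  out <- list(clinical)
  keys <- unique(clinical[, c("subject_id", "visit")])
  fasting <- clinical[is.na(clinical$time_min), ]
  fkey <- paste(fasting$subject_id, fasting$visit, fasting$variable)
  fval <- function(s, v, var) fasting$value[match(paste(s, v, var), fkey)]
  for (i in seq_len(nrow(keys))) {
    s <- keys$subject_id[i]; v <- keys$visit[i]
    add <- c(homa = homa_ir(fval(s, v, "glucose"), fval(s, v, "insulin")),
             ldl = friedewald_ldl(fval(s, v, "tc"), fval(s, v, "hdl"),
                                  fval(s, v, "tg")))
    for (analyte in c("glucose", "insulin")) {
      pp <- clinical[clinical$subject_id == s & clinical$visit == v &
                       clinical$variable == paste0(analyte, "_pp") &
                       !is.na(clinical$time_min), ]
      if (nrow(pp) >= 3) {
        pp <- pp[order(pp$time_min), ]
        sm <- postprandial_summary(pp$time_min, pp$value,
                                   positive_only = positive_only)
        add <- c(add, stats::setNames(unlist(sm),
                                      paste0(analyte, c("_tauc", "_iauc", "_peak"))))
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      subject_id = s, visit = v, variable = names(add), time_min = NA_real_,
      value = unname(add), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
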