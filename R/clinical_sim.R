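#' Specify a clinical coupling to a planted metagenomic feature
#'
#' @param feature_id the planted feature (an MSP id present in the cohort's
#'   composition matrix).
#' @param variable clinical variable receiving the linear term: one of
#'   `"glucose"`, `"insulin"`, `"tc"`, `"hdl"`, `"tg"` (fasting value at the
#'   post-MF visit) or `"glucose_excursion"`, `"insulin_excursion"`
#'   (postprandial bump amplitude at the post-MF visit, so peaks and AUCs move
#'   with the feature).
#' @param coef signed coupling coefficient, in units of the clinical variable
#'   per standard deviation of the feature delta.
#' @return a `clinical_coupling` list.
#' @export
clinical_coupling <- function(feature_id, variable, coef) {
  vars <- c("glucose", "insulin", "tc", "hdl", "tg",
            "glucose_excursion", "insulin_excursion")
  if (!variable %in% vars) stopf("unknown clinical variable '%s'", variable)
  structure(list(feature_id = feature_id, variable = variable, coef = coef),
            class = "clinical_coupling")
}

#' Simulate the crossover clinical table
#'
#' Generates fasting variables (glucose, insulin, total cholesterol, HDL-C,
#' triglycerides) and unimodal postprandial glucose/insulin curves for every
#' subject-visit of a crossover design. Baselines are drawn near values
#' typical of adults at cardiometabolic risk (fasting glucose ~5.3 mM, insulin
#' ~12 mIU/L, TC ~5.1 mM, HDL-C ~1.2 mM, TG ~1.3 mM), with subject-level and
#' visit-level Gaussian noise on the measurement scale, truncated at zero.
#' The postprandial curve starts exactly at the fasting value at t = 0 and
#' follows a gamma-shaped excursion on a fixed minute grid
#' (0, 15, 30, 45, 60, 90, 120, 180, 210, 240). Couplings add a linear term
#' in the subject's standardised planted-feature delta (post - pre, MF arm)
#' to the post-MF value of the coupled variable, so delta-delta correlation
#' analyses can recover them.
#'
#' @param design a `crossover_design`.
#' @param composition MSPs x samples matrix (needed when `coupling` is
#'   non-empty, to compute the per-subject feature deltas).
#' @param coupling list of [clinical_coupling()] specifications.
#' @param time_grid postprandial minute grid.
#' @param seed integer seed.
#' @return a long clinical table: `subject_id`, `visit`, `variable`,
#'   `time_min` (`NA` on fasting rows), `value`.
#' @export
simulate_clinical <- function(design, composition = NULL, coupling = list(),
                              time_grid = c(0, 15, 30, 45, 60, 90, 120, 180, 210, 240),
                              seed = NULL) {
  design$phase <- design_phase(design)
  if (inherits(coupling, "clinical_coupling")) coupling <- list(coupling)
  z <- list()
  if (length(coupling)) {
    if (is.null(composition)) {
      stopf("composition is required to realise clinical couplings")
    }
    fd <- feature_deltas(composition, design, arm = "MF")
    for (cp in coupling) {
      if (!cp$feature_id %in% colnames(fd)) {
        stopf("coupling references unknown feature '%s'", cp$feature_id)
      }
      d <- fd[, cp$feature_id]
      s <- stats::sd(d, na.rm = TRUE)
      z[[cp$feature_id]] <- if (is.na(s) || s == 0) d * 0 else
        (d - mean(d, na.rm = TRUE)) / s
    }
  }

  base_mean <- c(glucose = 5.3, insulin = 12, tc = 5.1, hdl = 1.2, tg = 1.3)
  base_sd <- c(glucose = 0.45, insulin = 5, tc = 0.85, hdl = 0.27, tg = 0.5)
  visit_sd <- base_sd / 3
  floor_at <- c(glucose = 0.5, insulin = 0, tc = 0.5, hdl = 0.05, tg = 0.05)

  with_seed(seed, {
    subjects <- unique(design$subject_id)
    subj_base <- vapply(names(base_mean), function(v) {
      pmax(floor_at[v], stats::rnorm(length(subjects), base_mean[v], base_sd[v]))
    }, numeric(length(subjects)))
    subj_base <- matrix(subj_base, nrow = length(subjects),
                        dimnames = list(subjects, names(base_mean)))

    out <- list()
    for (i in seq_len(nrow(design))) {
      subj <- design$subject_id[i]
      visit <- design$visit[i]
      is_post_mf <- design$bread[i] == "MF" & design$phase[i] == "post"
      fast <- vapply(names(base_mean), function(v) {
        max(floor_at[[v]], subj_base[subj, v] + stats::rnorm(1, 0, visit_sd[[v]]))
      }, numeric(1))
      amp <- c(glucose = max(0.2, stats::rnorm(1, 2, 0.5)),
               insulin = max(5, stats::rnorm(1, 70, 20)))
      if (is_post_mf) {
        for (cp in coupling) {
          zi <- z[[cp$feature_id]][subj]
          if (is.na(zi)) next
          if (cp$variable %in% names(fast)) {
            fast[cp$variable] <- max(floor_at[cp$variable],
                                     fast[cp$variable] + cp$coef * zi)
          } else if (cp$variable == "glucose_excursion") {
            amp["glucose"] <- max(0.05, amp["glucose"] + cp$coef * zi)
          } else if (cp$variable == "insulin_excursion") {
            amp["insulin"] <- max(1, amp["insulin"] + cp$coef * zi)
          }
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        subject_id = subj, visit = visit, variable = names(fast),
        time_min = NA_real_, value = unname(fast), stringsAsFactors = FALSE)
      for (analyte in c("glucose", "insulin")) {
        tp <- if (analyte == "glucose") 45 else 60
        bump <- amp[analyte] * (time_grid / tp) * exp(1 - time_grid / tp)
        noise <- c(0, stats::rnorm(length(time_grid) - 1, 0,
                                   0.05 * max(amp[analyte], 1)))
        vals <- pmax(0, fast[analyte] + bump + noise)
        vals[1] <- fast[analyte]  # t = 0 equals the fasting value exactly
        out[[length(out) + 1L]] <- data.frame(
          subject_id = subj, visit = visit, variable = paste0(analyte, "_pp"),
          time_min = time_grid, value = unname(vals), stringsAsFactors = FALSE)
      }
    }
    clinical <- do.call(rbind, out)
    rownames(clinical) <- NULL
    clinical
  })
}

#' Simulate a complete synthetic crossover trial
#'
#' Convenience wrapper chaining the generators: catalog, cohort (design plus
#' latent compositions with planted effects), per-sample alignment records,
#' and the coupled clinical table. Intended for end-to-end pipeline runs at
#' desk scale.
#'
#' @param n_subjects,n_genes,n_msp cohort and catalog sizes.
#' @param depth reads per sample for the alignment simulation.
#' @param shared_fraction fraction of shared reads.
#' @param effects list of [planted_effect()].
#' @param coupling list of [clinical_coupling()].
#' @param seed integer seed driving all stages.
#' @param ... further arguments to [generate_catalog()].
#' @return list with `catalog`, `design`, `composition`, `effects`,
#'   `alignments`, `clinical`.
#' @export
simulate_trial <- function(n_subjects = 39, n_genes = 5000, n_msp = 20,
                           depth = 20000, shared_fraction = 0.1,
                           effects = list(), coupling = list(),
                           seed = NULL, ...) {
  with_seed(seed, {
    catalog <- generate_catalog(n_genes, n_msp, seed = NULL, ...)
    cohort <- generate_cohort(n_subjects, catalog, effects = effects, seed = NULL)
    alignments <- simulate_alignments(cohort$composition, catalog, depth = depth,
                                      shared_fraction = shared_fraction,
                                      seed = NULL)
    clinical <- simulate_clinical(cohort$design, cohort$composition,
                                  coupling = coupling, seed = NULL)
    list(catalog = catalog, design = cohort$design,
         composition = cohort$composition, effects = cohort$effects,
         alignments = alignments, clinical = clinical)
  })
}
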