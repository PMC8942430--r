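#' Simulate read-to-gene alignment records
#'
#' Emulates the output of mapping shotgun reads against a gene catalog at a
#' fixed sequencing depth. A read is either uniquely mapped (one candidate
#' gene) or shared (several candidate genes with tied best alignment score).
#' Shared status is drawn per read with probability `shared_fraction`; shared
#' reads land on MSP member genes and their extra candidates are drawn from the
#' same MSP (paralog-like catalog redundancy). Unique reads sample any gene
#' with probability proportional to MSP abundance times gene length within the
#' MSP; genes outside any MSP share a small background probability mass,
#' proportional to their lengths.
#'
#' @param composition MSPs x samples relative-abundance matrix (or a named
#'   vector for a single sample).
#' @param catalog a `gene_catalog`.
#' @param depth reads per sample (> 0).
#' @param shared_fraction probability that a read is shared, in `[0, 1)`.
#' @param background probability mass allotted to genes outside any MSP.
#' @param seed integer seed.
#' @return an `alignment_records` data.frame with columns `sample_id`,
#'   `read_id` and `gene_ids` (a list column; length 1 for unique reads,
#'   >= 2 for shared reads).
#' @export
simulate_alignments <- function(composition, catalog, depth,
                                shared_fraction = 0.1, background = 0.01,
                                seed = NULL) {
  if (is.null(dim(composition))) {
    composition <- matrix(composition, ncol = 1,
                          dimnames = list(names(composition), "sample_1"))
  }
  if (nrow(catalog) == 0) stopf("empty catalog")
  if (depth <= 0) stopf("depth must be positive")
  stopifnot(shared_fraction >= 0, shared_fraction < 1,
            background >= 0, background < 1)
  msp_ids <- rownames(composition)
  members <- catalog_members(catalog)
  if (!all(msp_ids %in% names(members))) {
    stopf("composition rows reference MSPs absent from the catalog")
  }

  in_msp <- !is.na(catalog$msp_id) & catalog$msp_id %in% msp_ids
  gene_msp <- catalog$msp_id
  len <- catalog$length_bp
  # within-MSP length share
  len_share <- numeric(nrow(catalog))
  if (any(in_msp)) {
    tot <- tapply(len[in_msp], gene_msp[in_msp], sum)
    len_share[in_msp] <- len[in_msp] / tot[gene_msp[in_msp]]
  }
  bg <- !in_msp
  bg_mass <- if (any(bg)) background else 0

  with_seed(seed, {
    out <- vector("list", ncol(composition))
    for (j in seq_len(ncol(composition))) {
      abund <- composition[, j]
      p <- numeric(nrow(catalog))
      p[in_msp] <- abund[gene_msp[in_msp]] * len_share[in_msp] * (1 - bg_mass)
      if (any(bg)) p[bg] <- bg_mass * len[bg] / sum(len[bg])
      if (sum(p) <= 0) stopf("sample %s has no positive sampling mass",
                             colnames(composition)[j])

      shared <- stats::runif(depth) < shared_fraction
      idx <- integer(depth)
      if (any(!shared)) {
        idx[!shared] <- sample.int(nrow(catalog), sum(!shared),
                                   replace = TRUE, prob = p)
      }
      if (any(shared)) {
        p_msp <- p
        p_msp[bg] <- 0
        if (sum(p_msp) <= 0) {
          # no MSP mass: fall back to unique records
          idx[shared] <- sample.int(nrow(catalog), sum(shared),
                                    replace = TRUE, prob = p)
          shared[shared] <- FALSE
        } else {
          idx[shared] <- sample.int(nrow(catalog), sum(shared),
                                    replace = TRUE, prob = p_msp)
        }
      }
      gene_ids <- as.list(catalog$gene_id[idx])
      if (any(shared)) {
        for (r in which(shared)) {
          mates <- members[[gene_msp[idx[r]]]]
          mates <- mates[mates != catalog$gene_id[idx[r]]]
          if (length(mates) == 0) next  # singleton cluster: stays unique
          n_extra <- 1L + stats::rbinom(1, 1, 0.3)
          n_extra <- min(n_extra, length(mates))
          gene_ids[[r]] <- c(gene_ids[[r]], sample(mates, n_extra))
        }
      }
      sample_id <- colnames(composition)[j]
      rec <- data.frame(sample_id = sample_id,
                        read_id = sprintf("%s_r%06d", sample_id, seq_len(depth)),
                        stringsAsFactors = FALSE)
      rec$gene_ids <- gene_ids
      out[[j]] <- rec
    }
    alignments <- do.call(rbind, out)
    class(alignments) <- c("alignment_records", "data.frame")
    alignments
  })
}
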