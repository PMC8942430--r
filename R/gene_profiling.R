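#' Build the raw gene count table from alignment records
#'
#' Two-pass shared-read attribution. Pass 1: every uniquely mapped read adds 1
#' to its gene. Pass 2: every shared read (several candidate genes with tied
#' best score) distributes its single count across its candidates
#' proportionally to the candidates' unique-read totals from pass 1; when all
#' candidates have zero unique counts the read is split uniformly, so reads
#' are always conserved.
#'
#' @param alignments an `alignment_records` data.frame (see
#'   [simulate_alignments()] or [read_alignments_tsv()]).
#' @param catalog a `gene_catalog`; every candidate gene must exist in it.
#' @return a genes x samples matrix of non-negative (possibly fractional)
#'   counts, with attributes `stage = "raw"` and `mapped_reads` (per-sample
#'   attributed read totals). Column sums equal the per-sample read counts.
#' @export
attribute_reads <- function(alignments, catalog) {
  if (nrow(alignments) == 0) stopf("no alignment records")
  genes <- catalog$gene_id
  all_cand <- unlist(alignments$gene_ids, use.names = FALSE)
  unknown <- setdiff(unique(all_cand), genes)
  if (length(unknown)) {
    stopf("alignment candidates absent from catalog: %s",
          paste(utils::head(unknown, 3), collapse = ", "))
  }
  samples <- unique(alignments$sample_id)
  counts <- matrix(0, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
  n_cand <- lengths(alignments$gene_ids)
  for (s in samples) {
    in_s <- alignments$sample_id == s
    uniq <- in_s & n_cand == 1L
    u <- table(factor(unlist(alignments$gene_ids[uniq], use.names = FALSE),
                      levels = genes))
    col <- as.numeric(u)
    names(col) <- genes
    for (r in which(in_s & n_cand > 1L)) {
      cand <- alignments$gene_ids[[r]]
      w <- as.numeric(u[cand])
      if (sum(w) == 0) w <- rep(1, length(cand))
      col[cand] <- col[cand] + w / sum(w)
    }
    counts[, s] <- col
  }
  attr(counts, "stage") <- "raw"
  attr(counts, "mapped_reads") <- colSums(counts)
  counts
}

#' Downsize a count table to a fixed mapped-read depth
#'
#' Rarefies each sample once to exactly `target` reads by sampling without
#' replacement from its count vector (multivariate hypergeometric draw).
#' Fractional counts left by shared-read attribution are first rounded
#' stochastically (floor plus a Bernoulli draw on the fractional part) so that
#' subsampling operates on integers. Samples whose rounded total falls below
#' the target are excluded and reported rather than kept at lower depth.
#'
#' @param counts a raw-stage genes x samples count matrix
#'   (see [attribute_reads()]).
#' @param target mapped-read depth to downsize to (> 0).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return a list with `counts` (downsized matrix, `stage = "downsized"`,
#'   retained samples only; each column sums to `target`) and `excluded`
#'   (character vector of dropped sample ids).
#' @export
downsize <- function(counts, target, seed = NULL) {
  if (target <= 0) stopf("downsizing target must be positive")
  target <- as.integer(round(target))
  with_seed(seed, {
    n <- nrow(counts)
    kept <- matrix(0, n, 0, dimnames = list(rownames(counts), NULL))
    kept_ids <- character(0)
    excluded <- character(0)
    for (j in seq_len(ncol(counts))) {
      x <- counts[, j]
      xi <- floor(x)
      frac <- x - xi
      pick <- frac > 0
      if (any(pick)) xi[pick] <- xi[pick] + stats::rbinom(sum(pick), 1, frac[pick])
      if (sum(xi) < target) {
        excluded <- c(excluded, colnames(counts)[j])
        next
      }
      kept <- cbind(kept, hyper_sample(as.integer(xi), target))
      kept_ids <- c(kept_ids, colnames(counts)[j])
    }
    colnames(kept) <- kept_ids
    attr(kept, "stage") <- "downsized"
    attr(kept, "mapped_reads") <- colSums(kept)
    attr(kept, "target") <- target
    list(counts = kept, excluded = excluded)
  })
}

# Draw k items without replacement from categories with counts x
# (multivariate hypergeometric, sequential conditional rhyper draws).
hyper_sample <- function(x, k) {
  out <- integer(length(x))
  rem <- sum(x)
  for (i in seq_along(x)) {
    if (k <= 0) break
    rem <- rem - x[i]
    d <- stats::rhyper(1, x[i], rem, k)
    out[i] <- d
    k <- k - d
  }
  out
}

#' Length-normalise a downsized count table into gene frequencies
#'
#' FPKM-style normalisation: each count is divided by the gene length in
#' kilobases and by the sample's mapped reads in millions, so frequency =
#' count / (length_bp / 1000) / (mapped / 1e6). Only frequency ratios matter
#' downstream; optionally each column can instead be rescaled to a fixed sum.
#'
#' @param counts a downsized genes x samples matrix (see [downsize()]).
#' @param catalog a `gene_catalog` providing the gene lengths.
#' @param rescale_to if non-`NULL`, rescale each column to this sum instead of
#'   applying the per-million-mapped-reads convention.
#' @return a genes x samples frequency matrix (`stage = "frequency"`).
#' @export
normalize_frequencies <- function(counts, catalog, rescale_to = NULL) {
  len <- catalog$length_bp[match(rownames(counts), catalog$gene_id)]
  if (anyNA(len)) stopf("count rows missing from catalog")
  if (any(len <= 0)) stopf("gene lengths must be positive")
  freq <- counts / (len / 1000)
  if (is.null(rescale_to)) {
    mapped <- colSums(counts)
    mapped[mapped == 0] <- 1  # all-zero column stays all-zero
    freq <- sweep(freq, 2, mapped / 1e6, "/")
  } else {
    tot <- colSums(freq)
    tot[tot == 0] <- rescale_to
    freq <- sweep(freq, 2, tot / rescale_to, "/")
  }
  attr(freq, "stage") <- "frequency"
  freq
}

#' Gene richness of downsized samples
#'
#' Number of genes detected (strictly positive count) per sample, computed on
#' the downsized table so that sequencing-depth differences do not drive the
#' comparison. Invariant under any positive per-sample rescaling, so computing
#' it before or after frequency normalisation gives the same value.
#'
#' @param counts a downsized-stage (or frequency-stage) genes x samples matrix.
#' @return named integer vector of per-sample gene counts.
#' @export
gene_richness <- function(counts) {
  stage <- attr(counts, "stage")
  if (is.null(stage) || !stage %in% c("downsized", "frequency")) {
    stopf("gene_richness requires a downsized (or frequency) matrix, not stage '%s'",
          stage %||% "unknown")
  }
  colSums(counts > 0)
}
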