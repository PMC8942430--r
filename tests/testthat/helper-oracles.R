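# Independent brute-force oracles used to check the vectorised implementations.
# These deliberately re-derive each quantity from its definition with plain
# loops and never call the code paths they are checking.

# minimal hand-built catalog (no validation; invariants are the caller's job)
manual_catalog <- function(gene_id, length_bp = 1000, msp_id = NA_character_,
                           is_marker = FALSE, is_core = FALSE,
                           ko_ids = NA_character_, cazy_families = NA_character_) {
  df <- data.frame(gene_id = gene_id, length_bp = length_bp, msp_id = msp_id,
                   is_marker = is_marker, is_core = is_core, ko_ids = ko_ids,
                   cazy_families = cazy_families, stringsAsFactors = FALSE)
  class(df) <- c("gene_catalog", "data.frame")
  df
}

# hand-built alignment records from a list of candidate-gene vectors
manual_alignments <- function(reads, sample_id = "s1") {
  df <- data.frame(sample_id = sample_id,
                   read_id = sprintf("r%04d", seq_along(reads)),
                   stringsAsFactors = FALSE)
  df$gene_ids <- lapply(reads, as.character)
  class(df) <- c("alignment_records", "data.frame")
  df
}

# Benjamini-Hochberg step-up reference: order p ascending, q_(i) = min over
# j >= i of p_(j) * n / j, capped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  q <- pmin(1, rev(cummin(rev(ranked))))
  out <- numeric(n)
  out[o] <- q
  out
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments of the
# nonzero differences (mid-ranks for tied |d|), twice the smaller tail.
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(mask) {
    pos <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    sum(r[pos])
  }, numeric(1))
  min(1, 2 * min(mean(vs <= v_obs + 1e-9), mean(vs >= v_obs - 1e-9)))
}

# Cliff's delta by explicit double loop
oracle_cliffs <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + sign(xi - yj)
  s / (length(x) * length(y))
}

# Module-carriage profile by explicit loops over samples, modules and MSPs,
# re-deriving restricted gene sets and completeness from the catalog columns.
oracle_functional <- function(msp, det, modules, catalog, threshold = 0.9) {
  out <- matrix(0, nrow(modules), ncol(msp),
                dimnames = list(modules$module_id, colnames(msp)))
  for (s in colnames(msp)) {
    detg <- rownames(det)[det[, s] > 0]
    for (mi in seq_len(nrow(modules))) {
      items <- strsplit(modules$items[mi], ";")[[1]]
      total <- 0
      for (m in rownames(msp)) {
        if (msp[m, s] <= 0) next
        memb <- catalog$gene_id[!is.na(catalog$msp_id) & catalog$msp_id == m]
        core <- catalog$gene_id[catalog$is_core & !is.na(catalog$msp_id) &
                                  catalog$msp_id == m]
        genes <- union(intersect(memb, detg), core)
        rows <- match(genes, catalog$gene_id)
        comp <- if (length(genes) == 0) {
          0
        } else if (modules$kind[mi] == "cazy") {
          fams <- unlist(strsplit(catalog$cazy_families[rows], ";"))
          as.numeric(any(items %in% fams[!is.na(fams)]))
        } else {
          kos <- unlist(strsplit(catalog$ko_ids[rows], ";"))
          sum(items %in% kos[!is.na(kos)]) / length(items)
        }
        if (comp > threshold) total <- total + msp[m, s]
      }
      out[mi, s] <- total
    }
  }
  out
}

# Random small functional-profile instance (<= 5 MSPs, <= 4 modules,
# <= 3 samples) with annotations, detections and abundances drawn at random.
random_functional_instance <- function() {
  n_msp <- sample(1:5, 1)
  n_mod <- sample(1:4, 1)
  n_smp <- sample(1:3, 1)
  genes_per <- sample(3:7, n_msp, replace = TRUE)
  kos <- sprintf("K%05d", 1:12)
  fams <- c("GH43_8", "GH30_2", "PL26")
  gene_id <- sprintf("g%03d", seq_len(sum(genes_per)))
  msp_id <- rep(sprintf("m%02d", seq_len(n_msp)), genes_per)
  catalog <- manual_catalog(
    gene_id, msp_id = msp_id,
    is_core = runif(length(gene_id)) < 0.4,
    ko_ids = ifelse(runif(length(gene_id)) < 0.8,
                    sample(kos, length(gene_id), replace = TRUE), NA_character_),
    cazy_families = ifelse(runif(length(gene_id)) < 0.3,
                           sample(fams, length(gene_id), replace = TRUE),
                           NA_character_))
  kind <- sample(c("kegg", "gmm", "cazy"), n_mod, replace = TRUE)
  items <- vapply(kind, function(k) {
    if (k == "cazy") sample(fams, 1)
    else paste(sample(kos, sample(1:4, 1)), collapse = ";")
  }, "")
  modules <- data.frame(module_id = sprintf("mod%02d", seq_len(n_mod)),
                        kind = kind, items = items, stringsAsFactors = FALSE)
  samples <- sprintf("s%d", seq_len(n_smp))
  msp <- matrix(round(runif(n_msp * n_smp), 3) *
                  (runif(n_msp * n_smp) < 0.8),
                n_msp, n_smp,
                dimnames = list(unique(msp_id), samples))
  det <- matrix(runif(length(gene_id) * n_smp) < 0.6,
                length(gene_id), n_smp,
                dimnames = list(gene_id, samples)) * 1
  list(catalog = catalog, modules = modules, msp = msp, det = det)
}

# Exact within-subject permutation p-value for the bread-by-visit interaction:
# enumerate all 2^n per-subject bread-label flips and recompute the rank
# statistic each time.
oracle_interaction_perm <- function(values, design) {
  design$phase <- ifelse(design$visit %in% c("V2", "V5"), "pre", "post")
  cell <- paste(design$bread, design$phase, sep = ".")
  wide <- tapply(values, list(design$subject_id, cell), function(v) v[1])
  wide <- wide[, c("MF.pre", "MF.post", "CTL.pre", "CTL.post")]
  n <- nrow(wide)
  stopifnot(n <= 12)
  stat <- function(w) {
    r <- matrix(rank(as.vector(w)), n, 4)
    d <- (r[, 2] - r[, 1]) - (r[, 4] - r[, 3])
    v <- var(d)
    if (v == 0) Inf else n * mean(d)^2 / v
  }
  s_obs <- stat(wide)
  ss <- vapply(0:(2^n - 1), function(mask) {
    w <- wide
    flip <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    w[flip, ] <- wide[flip, c(3, 4, 1, 2)]
    stat(w)
  }, numeric(1))
  mean(ss >= s_obs - 1e-12)
}

# tiny catalog with full MSP/marker structure for profiling tests
small_msp_catalog <- function(n_msp = 3, seed = 11) {
  generate_catalog(n_genes = n_msp * 110, n_msp = n_msp, frac_unassigned = 0,
                   core_fraction = 0.5, seed = seed)
}
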