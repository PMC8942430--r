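#' Generate a synthetic gene catalog with MSP structure
#'
#' Builds a gene catalog shaped like a non-redundant gut gene catalog organised
#' into metagenomic species (MSPs): clusters of at least 100 co-abundant genes,
#' of which exactly 100 are designated marker genes used for quantification.
#' Marker genes are always part of the MSP core (the genes assumed present in
#' every strain); a configurable fraction of catalog genes stays outside any
#' MSP, emulating unclustered catalog genes. Genes carry optional KO and CAZy
#' family annotations drawn from configurable vocabularies (each annotated gene
#' gets a single best-ranked KO, mirroring best-hit annotation).
#'
#' @param n_genes total number of catalog genes; must be at least `100 * n_msp`.
#' @param n_msp number of MSPs.
#' @param frac_unassigned target fraction of genes left outside any MSP
#'   (reduced automatically if `n_genes` is too small to honour it).
#' @param annotation_density named fractions in `[0, 1]`: `ko` is the fraction
#'   of genes with a KO annotation, `cazy` the fraction with a CAZy family.
#' @param core_fraction fraction of each MSP's genes flagged as core (never
#'   below the 100 marker genes).
#' @param ko_vocabulary,cazy_vocabulary annotation label pools. Defaults are
#'   `K00001`-style KO ids and GH/GT/PL/CE family and subfamily labels
#'   (including e.g. `GH43_8`, `GH30_2`).
#' @param seed integer seed; the catalog is bit-reproducible given the seed.
#'
#' @return a `gene_catalog`: a data.frame with columns `gene_id`, `length_bp`,
#'   `msp_id` (`NA` when unassigned), `is_marker`, `is_core`, `ko_ids` and
#'   `cazy_families` (semicolon-joined, `NA` when unannotated).
#'
#' @examples
#' cat <- generate_catalog(n_genes = 1000, n_msp = 5, seed = 1)
#' table(cat$msp_id)
#' @export
generate_catalog <- function(n_genes, n_msp,
                             frac_unassigned = 0.1,
                             annotation_density = c(ko = 0.6, cazy = 0.15),
                             core_fraction = 0.4,
                             ko_vocabulary = default_ko_vocabulary(),
                             cazy_vocabulary = default_cazy_vocabulary(),
                             seed = NULL) {
  stopifnot(n_genes >= 1, n_msp >= 1)
  if (n_genes < 100 * n_msp) {
    stopf("n_genes = %d cannot host %d MSPs of at least 100 genes each",
          n_genes, n_msp)
  }
  dens_ko <- unname(annotation_density["ko"]) %||% 0
  dens_cazy <- unname(annotation_density["cazy"]) %||% 0
  if (is.na(dens_ko)) dens_ko <- 0
  if (is.na(dens_cazy)) dens_cazy <- 0
  stopifnot(dens_ko >= 0, dens_ko <= 1, dens_cazy >= 0, dens_cazy <= 1,
            frac_unassigned >= 0, frac_unassigned < 1,
            core_fraction >= 0, core_fraction <= 1)

  with_seed(seed, {
    gene_id <- sprintf("gene_%07d", seq_len(n_genes))
    length_bp <- pmax(100L, as.integer(round(stats::rlnorm(n_genes,
                                                           meanlog = log(1000),
                                                           sdlog = 0.6))))

    n_assigned <- max(100L * n_msp, as.integer(round(n_genes * (1 - frac_unassigned))))
    n_assigned <- min(n_assigned, n_genes)
    extra <- n_assigned - 100L * n_msp
    sizes <- 100L + if (extra > 0) {
      as.integer(stats::rmultinom(1, extra, rep(1 / n_msp, n_msp)))
    } else {
      integer(n_msp)
    }

    assigned <- sample.int(n_genes, n_assigned)
    msp_id <- rep(NA_character_, n_genes)
    msp_id[assigned] <- rep(sprintf("msp_%04d", seq_len(n_msp)), times = sizes)

    is_marker <- logical(n_genes)
    is_core <- logical(n_genes)
    start <- 1L
    for (m in seq_len(n_msp)) {
      members <- assigned[start:(start + sizes[m] - 1L)]
      start <- start + sizes[m]
      markers <- sample(members, 100L)
      is_marker[markers] <- TRUE
      n_core <- max(100L, as.integer(round(core_fraction * sizes[m])))
      extra_core <- setdiff(members, markers)
      n_extra <- min(length(extra_core), n_core - 100L)
      core <- c(markers, if (n_extra > 0) sample(extra_core, n_extra))
      is_core[core] <- TRUE
    }

    ko_ids <- rep(NA_character_, n_genes)
    pick <- stats::runif(n_genes) < dens_ko
    ko_ids[pick] <- sample(ko_vocabulary, sum(pick), replace = TRUE)
    cazy_families <- rep(NA_character_, n_genes)
    pick <- stats::runif(n_genes) < dens_cazy
    cazy_families[pick] <- sample(cazy_vocabulary, sum(pick), replace = TRUE)

    catalog <- data.frame(gene_id = gene_id, length_bp = length_bp,
                          msp_id = msp_id, is_marker = is_marker,
                          is_core = is_core, ko_ids = ko_ids,
                          cazy_families = cazy_families,
                          stringsAsFactors = FALSE)
    class(catalog) <- c("gene_catalog", "data.frame")
    validate_catalog(catalog)
    catalog
  })
}

#' Default KO vocabulary for the synthetic catalog
#' @param n number of KO identifiers.
#' @return character vector of KO ids.
#' @export
default_ko_vocabulary <- function(n = 400) sprintf("K%05d", seq_len(n))

#' Default CAZy family vocabulary for the synthetic catalog
#'
#' A mix of glycoside hydrolase (GH), glycosyl-transferase (GT), polysaccharide
#' lyase (PL) and carbohydrate esterase (CE) family and subfamily labels,
#' including fiber-degradation-relevant subfamilies such as `GH43_8` and
#' `GH30_2`.
#' @return character vector of family labels.
#' @export
default_cazy_vocabulary <- function() {
  c("GH30_2", "GH43_8", "GH43_28", "GH43_33", "GH76", "GT17", "PL26",
    "GH13_29", "GH2", "GH3", "GH5_4", "GH8", "GH9", "GH10", "GH26", "GH28",
    "GH29", "GH31", "GH36", "GH51", "GH53", "GH78", "GH95", "GH97", "GH105",
    "GH115", "GT2", "GT4", "GT5", "GT35", "PL1", "PL9", "PL11", "CE1", "CE4",
    "CE6", "CE8", "CE12")
}

#' Validate a gene catalog
#'
#' Checks the catalog invariants: positive gene lengths, at least 100 genes and
#' exactly 100 markers per MSP, and markers being a subset of core genes.
#'
#' @param catalog a `gene_catalog` data.frame.
#' @return the catalog, invisibly; errors if an invariant is violated.
#' @export
validate_catalog <- function(catalog) {
  req <- c("gene_id", "length_bp", "msp_id", "is_marker", "is_core",
           "ko_ids", "cazy_families")
  miss <- setdiff(req, names(catalog))
  if (length(miss)) stopf("catalog misses columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(catalog$gene_id)) stopf("duplicated gene_id in catalog")
  if (any(catalog$length_bp <= 0)) stopf("gene lengths must be positive")
  if (any(catalog$is_marker & !catalog$is_core)) {
    stopf("marker genes must be core genes")
  }
  if (any(catalog$is_marker & is.na(catalog$msp_id))) {
    stopf("marker genes must belong to an MSP")
  }
  assigned <- !is.na(catalog$msp_id)
  if (any(assigned)) {
    sizes <- table(catalog$msp_id[assigned])
    if (any(sizes < 100)) stopf("every MSP must have at least 100 genes")
    markers <- table(factor(catalog$msp_id[assigned & catalog$is_marker],
                            levels = names(sizes)))
    if (any(markers != 100)) stopf("every MSP must have exactly 100 marker genes")
  }
  invisible(catalog)
}

# marker gene ids per MSP, as a named list
catalog_markers <- function(catalog) {
  keep <- catalog$is_marker & !is.na(catalog$msp_id)
  split(catalog$gene_id[keep], catalog$msp_id[keep])
}

# all member gene ids per MSP
catalog_members <- function(catalog) {
  keep <- !is.na(catalog$msp_id)
  split(catalog$gene_id[keep], catalog$msp_id[keep])
}

# core gene ids per MSP
catalog_core <- function(catalog) {
  keep <- catalog$is_core & !is.na(catalog$msp_id)
  split(catalog$gene_id[keep], catalog$msp_id[keep])
}

#' @export
print.gene_catalog <- function(x, ...) {
  n_msp <- length(unique(x$msp_id[!is.na(x$msp_id)]))
  cat(sprintf("gene_catalog: %d genes, %d MSPs, %d unassigned genes\n",
              nrow(x), n_msp, sum(is.na(x$msp_id))))
  cat(sprintf("  annotated: %d genes with KO, %d with CAZy family\n",
              sum(!is.na(x$ko_ids)), sum(!is.na(x$cazy_families))))
  invisible(x)
}

#' Generate synthetic functional module definitions
#'
#' Draws flat KO-set modules (emulating KEGG modules or gut metabolic modules)
#' whose KOs are sampled from the KOs actually present in a catalog, plus one
#' single-family CAZy module per requested family. Flat KO sets are used;
#' alternative-path logic is deliberately not modelled.
#'
#' @param catalog a `gene_catalog`.
#' @param n_modules number of KO-set modules.
#' @param size_range integer range of KOs per module.
#' @param kind label for the KO-set modules, `"kegg"` or `"gmm"`.
#' @param cazy_families CAZy family labels to expose as single-item modules;
#'   defaults to all families present in the catalog.
#' @param seed integer seed.
#' @return a `module_set` data.frame with columns `module_id`, `kind`, `items`
#'   (semicolon-joined).
#' @export
generate_modules <- function(catalog, n_modules = 20, size_range = c(3, 8),
                             kind = "kegg",
                             cazy_families = NULL,
                             seed = NULL) {
  kos <- split_terms(catalog$ko_ids)
  if (length(kos) < max(size_range)) {
    stopf("catalog carries too few distinct KOs (%d) for modules of size %d",
          length(kos), max(size_range))
  }
  if (is.null(cazy_families)) cazy_families <- split_terms(catalog$cazy_families)
  with_seed(seed, {
    sizes <- sample(seq(size_range[1], size_range[2]), n_modules, replace = TRUE)
    items <- vapply(sizes, function(s) paste(sample(kos, s), collapse = ";"), "")
    mods <- data.frame(
      module_id = sprintf("%s_M%04d", toupper(substr(kind, 1, 1)), seq_len(n_modules)),
      kind = kind, items = items, stringsAsFactors = FALSE)
    if (length(cazy_families)) {
      mods <- rbind(mods, data.frame(module_id = cazy_families, kind = "cazy",
                                     items = cazy_families,
                                     stringsAsFactors = FALSE))
    }
    class(mods) <- c("module_set", "data.frame")
    mods
  })
}
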