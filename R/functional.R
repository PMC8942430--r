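#' Restrict an MSP's gene content to a sample
#'
#' Step 1 of the module-carriage computation: the gene content of an MSP
#' detected in a sample is restricted to its genes also detected in that
#' sample, plus the MSP's core genes (which are assumed present in every
#' strain and are added back regardless of detection).
#'
#' @param msp_id the MSP.
#' @param detected character vector of gene ids detected in the sample.
#' @param catalog a `gene_catalog`.
#' @return character vector of gene ids:
#'   `(members(msp) intersect detected) union core(msp)`.
#' @export
restrict_gene_content <- function(msp_id, detected, catalog) {
  members <- catalog_members(catalog)[[msp_id]]
  if (is.null(members)) stopf("unknown MSP '%s'", msp_id)
  core <- catalog_core(catalog)[[msp_id]] %||% character(0)
  union(intersect(members, detected), core)
}

#' Fraction of a functional module covered by a gene set
#'
#' Step 2: for KO-set modules (KEGG modules and gut metabolic modules, treated
#' as flat KO sets) the completeness is the fraction of the module's KOs
#' covered by the KO annotations of the gene set. For a CAZy module (a single
#' family label) it is 1 if any gene in the set carries the family, else 0 —
#' which coincides with the KO-set rule on a one-item module.
#'
#' @param genes character vector of gene ids (the restricted gene content).
#' @param module one row of a `module_set` (or a list with `kind`, `items`).
#' @param catalog a `gene_catalog` providing `ko_ids` / `cazy_families`.
#' @return completeness fraction in `[0, 1]`.
#' @export
module_completeness <- function(genes, module, catalog) {
  items <- split_terms(module$items)
  if (length(items) == 0) stopf("module '%s' has no items",
                                module$module_id %||% "?")
  if (length(genes) == 0) return(0)
  rows <- match(genes, catalog$gene_id)
  if (anyNA(rows)) stopf("genes absent from catalog")
  if (identical(module$kind, "cazy")) {
    fams <- split_terms(catalog$cazy_families[rows])
    as.numeric(any(items %in% fams))
  } else {
    kos <- split_terms(catalog$ko_ids[rows])
    sum(items %in% kos) / length(items)
  }
}

#' MSP-restricted functional-module carriage profile
#'
#' Steps 3-4: an MSP detected in a sample carries a module if the completeness
#' of the module in the MSP's restricted gene content is strictly above 90%;
#' the module's abundance in the sample is the summed abundance of all
#' carrying MSPs. For single-family CAZy modules this equals the summed
#' abundance of MSPs with at least one gene annotated with the family.
#'
#' @param msp an MSPs x samples abundance matrix (post 10%-detection rule);
#'   "detected in the sample" means abundance > 0.
#' @param detections a genes x samples matrix (logical, or numeric where > 0
#'   means detected) saying which genes are detected per sample; typically the
#'   downsized count or frequency matrix.
#' @param modules a `module_set` data.frame (`module_id`, `kind`, `items`).
#' @param catalog a `gene_catalog`.
#' @param threshold carriage threshold on completeness (strict `>`).
#' @return a modules x samples abundance matrix with attribute `carriers`, a
#'   long data.frame (`sample_id`, `module_id`, `msp_id`) recording which MSPs
#'   carry which module in which sample.
#' @export
functional_profile <- function(msp, detections, modules, catalog,
                               threshold = 0.9) {
  if (is.logical(detections)) detections <- detections * 1
  if (!all(rownames(msp) %in% catalog$msp_id)) {
    stopf("abundance rows reference MSPs absent from the catalog")
  }
  if (!identical(colnames(msp), colnames(detections))) {
    stopf("sample columns of abundances and detections must match")
  }
  out <- matrix(0, nrow(modules), ncol(msp),
                dimnames = list(modules$module_id, colnames(msp)))
  carriers <- list()
  for (s in colnames(msp)) {
    det_genes <- rownames(detections)[detections[, s] > 0]
    for (m in rownames(msp)) {
      if (msp[m, s] <= 0) next
      restricted <- restrict_gene_content(m, det_genes, catalog)
      for (k in seq_len(nrow(modules))) {
        comp <- module_completeness(restricted, modules[k, ], catalog)
        if (comp > threshold) {
          out[k, s] <- out[k, s] + msp[m, s]
          carriers[[length(carriers) + 1L]] <-
            data.frame(sample_id = s, module_id = modules$module_id[k],
                       msp_id = m, stringsAsFactors = FALSE)
        }
      }
    }
  }
  attr(out, "carriers") <- if (length(carriers)) {
    do.call(rbind, carriers)
  } else {
    data.frame(sample_id = character(0), module_id = character(0),
               msp_id = character(0), stringsAsFactors = FALSE)
  }
  out
}
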