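# The screen: find clusters carrying a gene with both LuxR Pfam domains on
# the same protein, attach luxI co-occurrence, and remove clusters whose only
# biosynthetic-role gene is the luxI homolog signal synthase.

#' Construct a LuxR-BGC association
#'
#' @param record_id Record identifier.
#' @param luxr_gene_ids Non-empty character vector of qualifying LuxR genes.
#' @param luxi_gene_ids Possibly empty character vector of LuxI genes.
#' @param bgc_type Cluster type label.
#' @return A `luxr_association` object; `has_luxi` is true iff
#'   `luxi_gene_ids` is non-empty.
#' @export
luxr_association <- function(record_id, luxr_gene_ids,
                             luxi_gene_ids = character(), bgc_type = "other") {
  if (!length(luxr_gene_ids)) stop("luxr_gene_ids must be non-empty")
  structure(list(record_id = record_id,
                 luxr_gene_ids = as.character(luxr_gene_ids),
                 luxi_gene_ids = as.character(luxi_gene_ids),
                 bgc_type = bgc_type,
                 has_luxi = length(luxi_gene_ids) > 0L),
            class = "luxr_association")
}

qualifying_hits <- function(hits, cfg) {
  hits[hits$cond_evalue <= cfg$evalue_max &
       hits$model_coverage >= cfg$coverage_min, , drop = FALSE]
}

#' Find LuxR genes in one cluster record
#'
#' A gene qualifies when it has at least one qualifying hit (conditional
#' E-value at most `evalue_max` and model coverage at least `coverage_min`)
#' for the DNA-binding domain PF00196 AND at least one for the signal-binding
#' domain PF03472, both on the same protein. Genes are returned in record
#' order.
#'
#' @param record A [bgc_record()].
#' @param hits Domain-hit `data.frame` keyed by `protein_id` = gene id.
#' @param cfg A [pipeline_config()].
#' @return Character vector of qualifying gene ids (possibly empty).
#' @export
find_luxr_genes <- function(record, hits, cfg = pipeline_config()) {
  q <- qualifying_hits(hits, cfg)
  ids <- vapply(record$genes, `[[`, "", "gene_id")
  ids[vapply(ids, function(g) {
    acc <- q$pfam_acc[q$protein_id == g]
    PFAM_LUXR_DNA %in% acc && PFAM_LUXR_SIGNAL %in% acc
  }, TRUE)]
}

#' Find LuxI genes in one cluster record
#'
#' Genes with a qualifying hit for the AHL-synthase domain PF00765, in
#' record order.
#'
#' @inheritParams find_luxr_genes
#' @return Character vector of qualifying gene ids (possibly empty).
#' @export
find_luxi_genes <- function(record, hits, cfg = pipeline_config()) {
  q <- qualifying_hits(hits, cfg)
  ids <- vapply(record$genes, `[[`, "", "gene_id")
  ids[vapply(ids, function(g) {
    PFAM_LUXI %in% q$pfam_acc[q$protein_id == g]
  }, TRUE)]
}

#' Remove associations whose only biosynthetic gene is the luxI homolog
#'
#' Drops every association whose record's set of biosynthetic-role genes is
#' non-empty and exactly equals its LuxI gene set — clusters predicted solely
#' on the presence of the signal synthase, which is itself a biosynthetic
#' gene. All other associations are retained in input order; the operation
#' is idempotent.
#'
#' @param associations List of [luxr_association()] objects.
#' @param records List of [bgc_record()] objects covering every association.
#' @return Filtered list of associations.
#' @export
filter_luxi_only <- function(associations, records) {
  by_id <- setNames(records, vapply(records, `[[`, "", "record_id"))
  keep <- vapply(associations, function(a) {
    r <- by_id[[a$record_id]]
    if (is.null(r)) stop("no record for association '", a$record_id, "'")
    biosyn <- vapply(Filter(function(g) g$role == "biosynthetic", r$genes),
                     `[[`, "", "gene_id")
    !(length(biosyn) > 0L && setequal(biosyn, a$luxi_gene_ids))
  }, TRUE)
  associations[keep]
}

#' Mine LuxR-associated BGCs
#'
#' The full screen: find qualifying LuxR genes per record, keep records with
#' at least one, attach LuxI genes, then apply the luxI-only exclusion
#' filter. Deterministic; record order is preserved.
#'
#' @param records List of [bgc_record()] objects with unique ids.
#' @param hits Domain-hit `data.frame`.
#' @param cfg A [pipeline_config()].
#' @return List of [luxr_association()] objects.
#' @export
mine <- function(records, hits, cfg = pipeline_config()) {
  ids <- vapply(records, `[[`, "", "record_id")
  if (anyDuplicated(ids)) {
    stop("duplicate record_id: ", paste(unique(ids[duplicated(ids)]),
                                        collapse = ", "))
  }
  assocs <- list()
  for (r in records) {
    luxr <- find_luxr_genes(r, hits, cfg)
    if (!length(luxr)) next
    luxi <- find_luxi_genes(r, hits, cfg)
    assocs[[length(assocs) + 1L]] <-
      luxr_association(r$record_id, luxr, luxi, r$bgc_type)
  }
  filter_luxi_only(assocs, records)
}

#' Write the hit table as TSV
#'
#' Columns mirror the screen's result table: record, organism, cluster type
#' (prefixed "AHL-" when a luxI homolog is present, as a presentation flag),
#' LuxR gene ids, luxI presence, taxonomy ranks and habitat.
#'
#' @param associations List of [luxr_association()] objects.
#' @param records Matching list of [bgc_record()] objects.
#' @param path Output path.
#' @return The table, invisibly.
#' @export
write_hit_table <- function(associations, records, path) {
  by_id <- setNames(records, vapply(records, `[[`, "", "record_id"))
  rows <- lapply(associations, function(a) {
    r <- by_id[[a$record_id]]
    tax <- r$taxonomy
    data.frame(record_id = a$record_id, organism = r$organism,
               bgc_type = if (a$has_luxi) paste0("AHL-", a$bgc_type) else a$bgc_type,
               luxr_gene_ids = paste(a$luxr_gene_ids, collapse = ","),
               has_luxi = a$has_luxi,
               class = if (length(tax) >= 2) tax[2] else NA_character_,
               order = if (length(tax) >= 3) tax[3] else NA_character_,
               family = if (length(tax) >= 4) tax[4] else NA_character_,
               genus = if (length(tax) >= 5) tax[5] else NA_character_,
               habitat = r$habitat, stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record_id = character(), organism = character(),
               bgc_type = character(), luxr_gene_ids = character(),
               has_luxi = logical(), class = character(), order = character(),
               family = character(), genus = character(),
               habitat = character(), stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
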