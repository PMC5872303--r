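# Results-style tabulation of the dereplicated hit list (type, habitat,
# taxonomic class, luxI co-occurrence), per-type association enrichment, and
# the diagnostic-residue subtype of LuxR proteins.

#' Display rounding for percentages
#'
#' Percentages at or above 1% display as integers; below 1% with two
#' decimals (so a 1-in-2,000 rate displays as 0.05).
#'
#' @param x Percentages.
#' @return Character vector.
#' @export
format_pct <- function(x) {
  ifelse(x >= 1, sprintf("%d", as.integer(round(x))), sprintf("%.2f", x))
}

prop_table <- function(values) {
  if (!length(values)) return(numeric())
  tab <- table(values)
  p <- 100 * as.numeric(tab) / length(values)
  setNames(p, names(tab))[order(-p, names(tab))]
}

#' Summarize a hit list
#'
#' Tabulates luxI co-occurrence and the type / habitat / taxonomic-class
#' composition of a (typically dereplicated) association list. Raw
#' percentages are retained at full precision; `format_pct()` gives the
#' display form. Permutation-invariant in input order; an empty list yields
#' a zero report, not an error.
#'
#' @param associations List of [luxr_association()] objects.
#' @param records Matching list of [bgc_record()] objects.
#' @return A `summary_report` list: `n_hits`, `n_with_luxi`, `pct_with_luxi`,
#'   `type_proportions`, `habitat_proportions`, `class_proportions` (named
#'   percent vectors).
#' @export
tabulate_associations <- function(associations, records) {
  by_id <- setNames(records, vapply(records, `[[`, "", "record_id"))
  n <- length(associations)
  if (n == 0L) {
    return(structure(list(n_hits = 0L, n_with_luxi = 0L, pct_with_luxi = 0,
                          type_proportions = numeric(),
                          habitat_proportions = numeric(),
                          class_proportions = numeric()),
                     class = "summary_report"))
  }
  recs <- lapply(associations, function(a) {
    r <- by_id[[a$record_id]]
    if (is.null(r)) stop("no record for association '", a$record_id, "'")
    r
  })
  has_luxi <- vapply(associations, `[[`, TRUE, "has_luxi")
  types <- vapply(associations, `[[`, "", "bgc_type")
  habitats <- vapply(recs, `[[`, "", "habitat")
  classes <- vapply(recs, function(r) {
    if (length(r$taxonomy) >= 2) r$taxonomy[2] else "unknown"
  }, "")
  structure(list(n_hits = n, n_with_luxi = sum(has_luxi),
                 pct_with_luxi = 100 * mean(has_luxi),
                 type_proportions = prop_table(types),
                 habitat_proportions = prop_table(habitats),
                 class_proportions = prop_table(classes)),
            class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  cat("<summary_report> ", x$n_hits, " hits; ",
      format_pct(x$pct_with_luxi), "% with luxI\n", sep = "")
  if (length(x$type_proportions)) {
    cat("  types: ", paste0(names(x$type_proportions), " ",
                            format_pct(x$type_proportions), "%",
                            collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Per-type association frequency
#'
#' For each cluster type, the percentage of all clusters of that type that
#' are LuxR-associated: `100 * hits / total`. Types with zero total are
#' omitted; hits exceeding the total is an error.
#'
#' @param total_by_type Named numeric vector of type totals.
#' @param hits_by_type Named numeric vector of LuxR-associated counts.
#' @return Named percent vector over the types present in `total_by_type`.
#' @export
association_frequency <- function(total_by_type, hits_by_type) {
  total_by_type <- total_by_type[total_by_type > 0]
  hits <- setNames(rep(0, length(total_by_type)), names(total_by_type))
  common <- intersect(names(hits_by_type), names(hits))
  hits[common] <- hits_by_type[common]
  if (any(hits > total_by_type)) {
    bad <- names(hits)[hits > total_by_type]
    stop("hits exceed total for type(s): ", paste(bad, collapse = ", "))
  }
  100 * hits / total_by_type
}

#' Classify a LuxR protein by its two diagnostic residues
#'
#' AHL-binding and plant-responsive LuxR proteins differ at two alignment
#' positions of the signal-binding domain: characterized plant-responsive
#' regulators carry an M and a W at positions 1 and 2 respectively. The
#' query is globally aligned to its nearest reference (highest identity);
#' the residues it places at the two diagnostic columns of the reference
#' panel decide the call: a W at position 2 gives `plant_responsive_like`;
#' matching the AHL-reference consensus at both positions gives `AHL_type`;
#' anything else — including the regulator from an actinobacterial telomycin
#' cluster, which differs from both groups — is `atypical`.
#'
#' @param seq Query protein sequence.
#' @param panel A reference panel from [luxr_reference_panel()] (an aligned
#'   set with `diagnostic_cols`, `ref_class` and `ahl_consensus` attributes).
#' @return One of `"AHL_type"`, `"plant_responsive_like"`, `"atypical"`.
#' @export
classify_luxr <- function(seq, panel = luxr_reference_panel()) {
  cols <- attr(panel, "diagnostic_cols")
  ref_class <- attr(panel, "ref_class")
  ahl_cons <- attr(panel, "ahl_consensus")
  stopifnot(length(cols) == 2L, !is.null(ref_class), !is.null(ahl_cons))
  usable <- names(panel)[ref_class[names(panel)] %in% c("AHL", "plant")]
  ungapped <- gsub("-", "", panel[usable])
  pids <- vapply(ungapped, function(r) percent_identity(seq, r), 0)
  nearest <- usable[which.max(pids)]

  # residue index (ungapped) of each diagnostic column in the nearest ref
  ref_row <- strsplit(panel[[nearest]], "")[[1]]
  res_idx <- cumsum(ref_row != "-")[cols]
  if (any(ref_row[cols] == "-")) {
    warning("nearest reference is gapped at a diagnostic column")
    return("atypical")
  }

  aln <- global_align(seq, ungapped[[nearest]])
  qa <- strsplit(aln$a_aligned, "")[[1]]
  ra <- strsplit(aln$b_aligned, "")[[1]]
  rpos <- cumsum(ra != "-")
  q_res <- vapply(res_idx, function(ri) {
    hit <- which(rpos == ri & ra != "-")[1]
    qa[hit]
  }, "")
  if (all(q_res == "-")) {
    warning("query aligns with gaps at both diagnostic columns")
    return("atypical")
  }
  if (q_res[2] == "W") return("plant_responsive_like")
  if (identical(unname(q_res), unname(ahl_cons))) return("AHL_type")
  "atypical"
}

#' Load the packaged LuxR reference panel
#'
#' A synthetic stand-in for a curated reference alignment: 12 AHL-binding
#' references (LuxR, LasR, TraR, PhzR, BjaR, RpaR, YenR, EsaR, SdiA, BraR,
#' RhlR, BpsR), 2 plant-responsive references (OryR, NesR — M and W at the
#' diagnostic positions) and the outgroup GerE, which has a LuxR-type
#' DNA-binding domain but no signal-binding domain. The sequences are
#' generated, not database entries; only the diagnostic-residue structure
#' and the family relationships are modeled.
#'
#' @param path Aligned-FASTA path; defaults to the packaged panel.
#' @return Named character vector of aligned rows with attributes
#'   `diagnostic_cols`, `ref_class` (named: `"AHL"`, `"plant"`,
#'   `"outgroup"`) and `ahl_consensus`.
#' @export
luxr_reference_panel <- function(path = system.file(
    "extdata", "luxr_reference_panel_synthetic.afa", package = "luxrbgc")) {
  msa <- read_fasta(path)
  names(msa) <- sub("\\s.*", "", names(msa))  # first word of each header
  ahl <- c("LuxR", "LasR", "TraR", "PhzR", "BjaR", "RpaR", "YenR", "EsaR",
           "SdiA", "BraR", "RhlR", "BpsR")
  plant <- c("OryR", "NesR")
  ref_class <- setNames(rep("outgroup", length(msa)), names(msa))
  ref_class[intersect(ahl, names(msa))] <- "AHL"
  ref_class[intersect(plant, names(msa))] <- "plant"
  cols <- find_diagnostic_columns(msa, intersect(plant, names(msa)),
                                  intersect(ahl, names(msa)))
  cons <- vapply(cols, function(j) {
    res <- substr(msa[names(ref_class)[ref_class == "AHL"]], j, j)
    names(sort(table(res), decreasing = TRUE))[1]
  }, "")
  structure(msa, diagnostic_cols = cols, ref_class = ref_class,
            ahl_consensus = cons)
}

#' Locate the two diagnostic columns of a reference alignment
#'
#' The diagnostic positions are defined as alignment columns, anchored on
#' the plant-responsive references: the first column where every
#' plant-responsive reference has an M and the AHL consensus differs
#' (position 1), and the first later column where every plant-responsive
#' reference has a W and the AHL consensus differs (position 2).
#'
#' @param msa Named character vector of equal-length aligned rows.
#' @param plant_names,ahl_names Row names of the plant-responsive and
#'   AHL-binding references.
#' @return Integer vector of the two column indices.
#' @export
find_diagnostic_columns <- function(msa, plant_names, ahl_names) {
  L <- unique(nchar(msa))
  stopifnot(length(L) == 1L, length(plant_names) >= 1L,
            length(ahl_names) >= 1L)
  col_of <- function(target, from = 1L) {
    for (j in seq(from, L)) {
      pres <- substr(msa[plant_names], j, j)
      ares <- substr(msa[ahl_names], j, j)
      acons <- names(sort(table(ares), decreasing = TRUE))[1]
      if (all(pres == target) && acons != target) return(j)
    }
    stop("no alignment column with all plant-responsive references '",
         target, "' differing from the AHL consensus")
  }
  pos1 <- col_of("M")
  pos2 <- col_of("W", from = pos1 + 1L)
  c(pos1, pos2)
}
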