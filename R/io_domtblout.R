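# HMMER per-domain tabular output (domtblout): whitespace-delimited, 22
# fixed fields plus a free-text description, '#' comment lines.

#' Read a HMMER domtblout domain-hit table
#'
#' Expects the `hmmsearch --domtblout` dialect: target (protein) columns
#' first, query (profile) columns second. Model coverage is computed as
#' `(hmm_to - hmm_from + 1) / model_length`; Pfam accession versions
#' (`PF00196.18`) are stripped.
#'
#' @param path Path to a domtblout file.
#' @return A domain-hit `data.frame` (see [domain_hits()]); zero rows for a
#'   file of comments only.
#' @export
read_domtblout <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (!length(rows)) return(domain_hits())
  parsed <- lapply(rows, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 23) {
      stop("domtblout row at line ", i, " has ", length(f),
           " fields; expected >= 23")
    }
    f
  })
  protein_id <- vapply(parsed, `[`, "", 1L)
  pfam_acc <- sub("\\.[0-9]+$", "", vapply(parsed, `[`, "", 5L))
  qlen <- as.numeric(vapply(parsed, `[`, "", 6L))
  cond_evalue <- as.numeric(vapply(parsed, `[`, "", 12L))
  bitscore <- as.numeric(vapply(parsed, `[`, "", 14L))
  hmm_from <- as.numeric(vapply(parsed, `[`, "", 16L))
  hmm_to <- as.numeric(vapply(parsed, `[`, "", 17L))
  ali_from <- as.integer(vapply(parsed, `[`, "", 18L))
  ali_to <- as.integer(vapply(parsed, `[`, "", 19L))
  domain_hits(protein_id = protein_id, pfam_acc = pfam_acc,
              cond_evalue = cond_evalue, bitscore = bitscore,
              ali_from = ali_from, ali_to = ali_to,
              model_coverage = (hmm_to - hmm_from + 1) / qlen)
}

#' Write a domain-hit table in domtblout format
#'
#' Inverse of [read_domtblout()] for the fields the pipeline consumes;
#' a nominal model length of 200 carries the coverage fraction exactly.
#'
#' @param hits Domain-hit `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
               "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"),
             con)
  if (nrow(hits)) {
    qlen <- 200L
    hmm_to <- as.integer(round(hits$model_coverage * qlen))
    for (i in seq_len(nrow(hits))) {
      writeLines(sprintf(
        "%s - 300 %s %s.1 %d %.2g %.1f 0.1 1 1 %.6g %.6g %.1f 0.1 1 %d %d %d %d %d 0.95 -",
        hits$protein_id[i], sub("^PF", "luxr_", hits$pfam_acc[i]),
        hits$pfam_acc[i], qlen, hits$cond_evalue[i], hits$bitscore[i],
        hits$cond_evalue[i], hits$cond_evalue[i] * 10, hits$bitscore[i],
        hmm_to[i], hits$ali_from[i], hits$ali_to[i],
        hits$ali_from[i], hits$ali_to[i]), con)
    }
  }
  invisible(path)
}

#' Read protein sequences from (possibly aligned) FASTA
#'
#' @param path FASTA path; gap characters are preserved.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 60L)
  invisible(path)
}
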