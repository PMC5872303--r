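# CD-HIT-style greedy incremental clustering of LuxR protein sequences at an
# identity cutoff, with longest-sequence representatives. Identity is exact
# global-alignment identity over the shorter sequence (no k-mer pre-filter
# heuristics; exact dynamic programming is affordable at this scale).

#' Greedy identity clustering
#'
#' Sequences are sorted by decreasing length (ties broken lexicographically
#' by id). Each sequence in turn joins the first existing cluster whose
#' representative it matches at or above `cutoff` identity
#' ([percent_identity()], shorter-sequence denominator), else founds a new
#' cluster as its representative. Clusters are returned in founding order,
#' so every representative is the longest member of its cluster.
#'
#' @param seqs Named character vector of protein sequences (unique names).
#' @param cutoff Identity cutoff in `(0, 1]`; 0.9 reproduces the published
#'   dereplication.
#' @param gap_open,gap_extend Affine gap penalties for the identity
#'   alignment.
#' @return List of `identity_cluster` objects, each with
#'   `representative_id`, `member_ids` (representative first) and
#'   `pairwise_identity_to_rep`.
#' @export
greedy_cluster <- function(seqs, cutoff = 0.9, gap_open = 10,
                           gap_extend = 0.5) {
  stopifnot(length(seqs) >= 1L, cutoff > 0, cutoff <= 1)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique names")
  }
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  submat <- blosum62()
  enc <- lapply(seqs, encode_protein, alphabet = rownames(submat))
  clusters <- list()
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    placed <- FALSE
    for (k in seq_along(clusters)) {
      rep_id <- clusters[[k]]$representative_id
      pid <- encoded_identity(enc[[i]], enc[[rep_id]], submat, gap_open,
                              gap_extend)
      if (pid >= cutoff) {
        clusters[[k]]$member_ids <- c(clusters[[k]]$member_ids, id)
        clusters[[k]]$pairwise_identity_to_rep[id] <- pid
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <-
        structure(list(representative_id = id, member_ids = id,
                       pairwise_identity_to_rep = setNames(1.0, id)),
                  class = "identity_cluster")
    }
  }
  clusters
}

#' Dereplicate LuxR associations by protein identity
#'
#' Clusters the LuxR protein sequences of the associations at
#' `cfg$identity_cutoff` and retains one association — the one carrying the
#' representative (longest) LuxR sequence — per cluster.
#'
#' @param associations List of [luxr_association()] objects.
#' @param records Matching list of [bgc_record()] objects.
#' @param cfg A [pipeline_config()].
#' @return List with `clusters` (from [greedy_cluster()]), `representatives`
#'   (the retained associations, in cluster founding order) and `luxr_seqs`
#'   (named vector used for clustering, keyed by gene id).
#' @export
dereplicate <- function(associations, records, cfg = pipeline_config()) {
  if (!length(associations)) {
    return(list(clusters = list(), representatives = list(),
                luxr_seqs = character()))
  }
  by_id <- setNames(records, vapply(records, `[[`, "", "record_id"))
  seqs <- character(); assoc_of <- character()
  for (a in associations) {
    r <- by_id[[a$record_id]]
    genes <- setNames(r$genes, vapply(r$genes, `[[`, "", "gene_id"))
    # one sequence per association: its longest qualifying LuxR gene
    cand <- a$luxr_gene_ids
    lens <- vapply(cand, function(g) nchar(genes[[g]]$translation), 0L)
    pick <- cand[order(-lens, cand)][1]
    seqs[pick] <- genes[[pick]]$translation
    assoc_of[pick] <- a$record_id
  }
  clusters <- greedy_cluster(seqs, cfg$identity_cutoff, cfg$gap_open,
                             cfg$gap_extend)
  assoc_by_record <- setNames(associations,
                              vapply(associations, `[[`, "", "record_id"))
  reps <- lapply(clusters, function(cl) {
    assoc_by_record[[assoc_of[[cl$representative_id]]]]
  })
  list(clusters = clusters, representatives = reps, luxr_seqs = seqs)
}

#' Write a cluster table as TSV
#'
#' @param clusters List of `identity_cluster` objects.
#' @param path Output path.
#' @return The table, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  rows <- lapply(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    data.frame(cluster_index = k, representative_id = cl$representative_id,
               n_members = length(cl$member_ids),
               member_ids = paste(cl$member_ids, collapse = ","),
               identities = paste(sprintf("%.4f", cl$pairwise_identity_to_rep),
                                  collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_index = integer(), representative_id = character(),
               n_members = integer(), member_ids = character(),
               identities = character(), stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
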