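# Newick output with fixed 6-decimal branch lengths and integer bootstrap
# supports as internal-node labels. ape::write.tree does not control the
# number of decimals, so the serializer is written here; ape::read.tree is
# the matching reader.

#' Write a phylogenetic tree to Newick
#'
#' Branch lengths are printed with 6 decimals; internal-node labels (bootstrap
#' supports, as percentages) are printed as integers. Supports below
#' `support_min` are suppressed at rendering only — the tree object keeps
#' them — mirroring the convention of displaying only supports above 50%.
#'
#' @param tree An `ape` `phylo` object with >= 2 leaves and non-negative
#'   branch lengths; bootstrap supports, if any, in `tree$node.label`.
#' @param path Output path.
#' @param support_min Minimum support (percent) to print, or `NULL` for all.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, support_min = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf names: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  writeLines(deparse_newick(tree, support_min), path)
  invisible(path)
}

deparse_newick <- function(tree, support_min = NULL) {
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  root <- ntip + 1L
  labels <- tree$node.label
  node_txt <- function(node, edge_idx) {
    if (node <= ntip) {
      lab <- tree$tip.label[node]
    } else {
      sub <- vapply(kids[[as.character(node)]], function(e) {
        node_txt(tree$edge[e, 2], e)
      }, "")
      lab <- paste0("(", paste(sub, collapse = ","), ")")
      supp <- if (!is.null(labels)) labels[node - ntip] else ""
      if (length(supp) && !is.na(supp) && nzchar(supp)) {
        s <- suppressWarnings(as.numeric(supp))
        show <- !is.na(s) && (is.null(support_min) || s >= support_min)
        if (show) lab <- paste0(lab, as.integer(round(s)))
      }
    }
    if (!is.na(edge_idx)) {
      lab <- paste0(lab, sprintf(":%.6f", tree$edge.length[edge_idx]))
    }
    lab
  }
  paste0(node_txt(root, NA_integer_), ";")
}
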