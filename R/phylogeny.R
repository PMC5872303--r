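# LuxR tree construction: progressive multiple alignment (built-in stand-in
# for an external aligner; externally aligned FASTA is accepted anywhere an
# MSA is), complete gap deletion, p-distance, neighbor joining, bootstrap
# support and outgroup rooting. Trees are ape "phylo" objects.

#' Construct a multiple-sequence alignment object
#'
#' @param seqs Named character vector of equal-length gapped rows.
#' @return A `luxr_msa` (named character vector with class).
#' @export
luxr_msa <- function(seqs) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) stop("MSA row names must be unique")
  if (length(unique(nchar(seqs))) != 1L) {
    stop("MSA rows must have equal length")
  }
  structure(toupper(seqs), class = "luxr_msa")
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(unclass(msa), ""))
}

#' Progressive multiple alignment
#'
#' A deterministic progressive aligner: a guide tree is built by
#' average-linkage (UPGMA) clustering of k-mer distances, and profiles are
#' merged along it by global affine-gap alignment, scoring column pairs by
#' the mean pairwise substitution score (BLOSUM62 by default). Intended as a
#' dependency-free stand-in where an externally computed alignment is not
#' supplied; it does not reproduce any particular external aligner.
#'
#' @param seqs Named character vector of >= 2 ungapped protein sequences.
#' @param gap_open,gap_extend Affine gap penalties.
#' @param k k-mer size for the guide-tree distance.
#' @param submat Substitution matrix (default BLOSUM62).
#' @return A [luxr_msa()] in the input row order.
#' @export
progressive_align <- function(seqs, gap_open = 10, gap_extend = 0.5, k = 3L,
                              submat = blosum62()) {
  n <- length(seqs)
  if (n < 2L) stop("progressive alignment needs at least 2 sequences")
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  if (n == 2L) {
    aln <- global_align(seqs[[1]], seqs[[2]], gap_open, gap_extend, submat)
    return(luxr_msa(setNames(c(aln$a_aligned, aln$b_aligned), names(seqs))))
  }

  kmers <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character())
    unique(substring(s, 1:(L - k + 1), k:L))
  })
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      shared <- length(intersect(kmers[[i]], kmers[[j]]))
      denom <- min(length(kmers[[i]]), length(kmers[[j]]))
      D[i, j] <- D[j, i] <- 1 - if (denom > 0) shared / denom else 0
    }
  }
  hc <- hclust(as.dist(D), method = "average")

  alphabet <- rownames(submat)
  gap_pair <- -(gap_open / 2 + gap_extend)  # residue-vs-gap column score
  profiles <- list()
  node_msa <- function(id) {
    if (id < 0) setNames(seqs[-id], names(seqs)[-id]) else profiles[[id]]
  }
  for (step in seq_len(nrow(hc$merge))) {
    A <- node_msa(hc$merge[step, 1])
    B <- node_msa(hc$merge[step, 2])
    encA <- do.call(rbind, lapply(A, function(s) {
      idx <- match(strsplit(s, "")[[1]], alphabet)
      ifelse(is.na(idx), 0L, idx)  # gaps (and unknowns) encode as 0
    }))
    encB <- do.call(rbind, lapply(B, function(s) {
      idx <- match(strsplit(s, "")[[1]], alphabet)
      ifelse(is.na(idx), 0L, idx)
    }))
    S <- profile_score_cpp(encA, encB, submat, gap_pair)
    path <- gotoh_align_cpp(S, gap_open, gap_extend)
    expand <- function(rows, keep) {
      vapply(rows, function(s) {
        chars <- strsplit(s, "")[[1]]
        paste(ifelse(keep == 0L, "-", chars[pmax(keep, 1L)]), collapse = "")
      }, "")
    }
    profiles[[step]] <- c(expand(A, path$ai), expand(B, path$bi))
  }
  luxr_msa(profiles[[nrow(hc$merge)]][names(seqs)])
}

#' Remove every alignment column containing a gap or missing residue
#'
#' Complete-deletion filtering: a column is dropped when any row carries a
#' gap (`-`) or missing datum (`X`); remaining columns keep their order.
#'
#' @param msa A [luxr_msa()].
#' @return Filtered [luxr_msa()].
#' @export
complete_deletion <- function(msa) {
  m <- msa_matrix(msa)
  keep <- colSums(m == "-" | m == "X") == 0L
  if (!any(keep)) stop("no positions remain after complete deletion")
  luxr_msa(setNames(apply(m[, keep, drop = FALSE], 1, paste, collapse = ""),
                    names(msa)))
}

#' p-distance matrix
#'
#' Proportion of differing positions between every pair of rows of a
#' gap-free alignment (amino acid differences per site).
#'
#' @param msa A gap-free [luxr_msa()] (apply [complete_deletion()] first).
#' @return Symmetric distance matrix with zero diagonal, dimnames = row
#'   names.
#' @export
p_distance <- function(msa) {
  m <- msa_matrix(msa)
  if (any(m == "-" | m == "X")) {
    stop("p-distance requires a gap-free alignment; run complete_deletion()")
  }
  L <- ncol(m)
  if (L < 1L) stop("alignment has zero positions")
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- sum(m[i, ] != m[j, ]) / L
      }
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Classic agglomerative neighbor joining: at each step the pair minimizing
#' `Q(i, j) = (n - 2) d(i, j) - R_i - R_j` is joined (ties broken by the
#' smallest index pair), limb lengths follow the standard formulas with
#' negative lengths clamped to zero and the deficit moved to the sister limb
#' so path lengths are conserved, and the matrix is reduced by
#' `d(u, k) = (d(i, k) + d(j, k) - d(i, j)) / 2`. On an additive matrix the
#' generating tree is recovered exactly.
#'
#' @param D Symmetric distance matrix with dimnames, n >= 3.
#' @return An unrooted `phylo` tree (basal trichotomy).
#' @export
neighbor_joining <- function(D) {
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12, check.attributes = FALSE))) {
    stop("distance matrix must be symmetric")
  }
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) stop("distance matrix must have dimnames")
  sub <- labels  # newick fragment per active node

  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(li, lj)
  }
  fmt <- function(x) sprintf("%.10g", max(x, 0))

  while (nrow(D) > 3L) {
    m <- nrow(D)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    idx <- which(Q <= min(Q) + 1e-12, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    d_ij <- D[i, j]
    li <- 0.5 * d_ij + (R[i] - R[j]) / (2 * (m - 2))
    lj <- d_ij - li
    l <- clamp_pair(li, lj)
    new_sub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt(l[1]), sub[j], fmt(l[2]))
    du <- (D[i, ] + D[j, ] - d_ij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    rn <- c(rownames(D)[keep], sprintf("__u%d__", m))
    dimnames(D2) <- list(rn, rn)
    D <- D2
    sub <- c(sub[keep], new_sub)
  }

  # final three-way join: limb lengths in closed form
  dAB <- D[1, 2]; dAC <- D[1, 3]; dBC <- D[2, 3]
  la <- (dAB + dAC - dBC) / 2
  lb <- (dAB + dBC - dAC) / 2
  lc <- (dAC + dBC - dAB) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[1], fmt(la), sub[2], fmt(lb),
                 sub[3], fmt(lc))
  ape::read.tree(text = txt)
}

# non-trivial bipartitions of an (un)rooted phylo, as canonical keys:
# the side not containing the reference taxon, sorted and joined with "|"
tree_bipartitions <- function(tree, ref = NULL) {
  tips <- tree$tip.label
  if (is.null(ref)) ref <- sort(tips)[1]
  ntip <- length(tips)
  nnode <- tree$Nnode
  clades <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) clades[[i]] <- tips[i]
  # edges in ape cladewise order: process children before parents
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    clades[[p]] <- c(clades[[p]], clades[[ch]])
  }
  root <- ntip + 1L
  keys <- character()
  for (node in seq(ntip + 1L, ntip + nnode)) {
    if (node == root) next
    clade <- clades[[node]]
    if (length(clade) <= 1L || length(clade) >= ntip - 1L) next
    side <- if (ref %in% clade) setdiff(tips, clade) else clade
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for the neighbor-joining tree
#'
#' Felsenstein bootstrap: alignment columns are resampled with replacement
#' to the original length, the p-distance + neighbor-joining tree is rebuilt
#' per replicate, and each internal bipartition of the original tree is
#' scored by the percentage of replicates containing it. Seeded and
#' reproducible; row-order invariant.
#'
#' @param msa A gap-free [luxr_msa()].
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed.
#' @return A list: `tree` (the original NJ tree with supports in
#'   `node.label`, root label empty) and `supports` (named percent vector
#'   keyed by canonical bipartition).
#' @export
bootstrap_support <- function(msa, n_reps = 1000L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  msa <- luxr_msa(unclass(msa)[order(names(msa))])  # row-order invariance
  m <- msa_matrix(msa)
  L <- ncol(m)
  tree <- neighbor_joining(p_distance(msa))
  orig <- tree_bipartitions(tree)
  counts <- setNames(numeric(length(orig)), orig)
  set.seed(seed)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    mb <- m[, cols, drop = FALSE]
    msab <- luxr_msa(setNames(apply(mb, 1, paste, collapse = ""), names(msa)))
    rep_bip <- tree_bipartitions(neighbor_joining(p_distance(msab)))
    hit <- orig %in% rep_bip
    counts[hit] <- counts[hit] + 1
  }
  supports <- 100 * counts / n_reps
  tree <- apply_supports(tree, supports)
  list(tree = tree, supports = supports)
}

# write supports onto internal-node labels of a phylo (root label empty)
apply_supports <- function(tree, supports) {
  ntip <- length(tree$tip.label)
  labs <- character(tree$Nnode)
  for (node in seq(ntip + 1L, ntip + tree$Nnode)) {
    if (node == ntip + 1L) { labs[node - ntip] <- ""; next }
    key <- node_bipartition_key(tree, node)
    labs[node - ntip] <-
      if (!is.null(key) && key %in% names(supports)) {
        sprintf("%d", as.integer(round(supports[[key]])))
      } else ""
  }
  tree$node.label <- labs
  tree
}

node_bipartition_key <- function(tree, node) {
  tips <- tree$tip.label
  ntip <- length(tips)
  clades <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) clades[[i]] <- tips[i]
  for (e in rev(seq_len(nrow(tree$edge)))) {
    clades[[tree$edge[e, 1]]] <- c(clades[[tree$edge[e, 1]]],
                                   clades[[tree$edge[e, 2]]])
  }
  clade <- clades[[node]]
  if (length(clade) <= 1L || length(clade) >= ntip - 1L) return(NULL)
  ref <- sort(tips)[1]
  side <- if (ref %in% clade) setdiff(tips, clade) else clade
  paste(sort(side), collapse = "|")
}

#' Root a tree on an outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant edge; the
#' ingroup topology and all path lengths are unchanged.
#'
#' @param tree An unrooted `phylo`.
#' @param outgroup_name A leaf name.
#' @return A rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup_name) {
  tip <- which(tree$tip.label == outgroup_name)
  if (!length(tip)) stop("outgroup '", outgroup_name, "' is not a leaf")
  edge <- which(tree$edge[, 2] == tip)
  pos <- tree$edge.length[edge] / 2
  rooted <- phytools::reroot(tree, tip, position = pos)
  rooted
}
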