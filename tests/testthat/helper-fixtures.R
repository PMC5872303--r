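# shared fixtures and independent oracles

# default synthetic dataset, generated once per test run
default_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset(synth_spec())
    cache
  }
})

random_aa <- function(n, alphabet = c("A", "R", "N", "D", "C", "Q", "E", "G",
                                      "H", "I", "L", "K", "M", "F", "P", "S",
                                      "T", "W", "Y", "V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# independent brute-force affine-gap global alignment score (Gotoh recursion
# written plainly over full matrices; score only, no traceback)
bf_align_score <- function(a, b, submat, go, ge) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- matrix(-Inf, n + 1, m + 1); GA <- M; GB <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) GA[i + 1, 1] <- -(go + i * ge)
  for (j in seq_len(m)) GB[1, j + 1] <- -(go + j * ge)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- max(M[i, j], GA[i, j], GB[i, j]) + submat[x[i], y[j]]
      GA[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, GA[i, j + 1] - ge,
                              GB[i, j + 1] - go - ge)
      GB[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, GB[i + 1, j] - ge,
                              GA[i + 1, j] - go - ge)
    }
  }
  max(M[n + 1, m + 1], GA[n + 1, m + 1], GB[n + 1, m + 1])
}

# independent pairwise mismatch-count distance
bf_p_distance <- function(sa, sb) {
  xa <- strsplit(sa, "")[[1]]; xb <- strsplit(sb, "")[[1]]
  nd <- 0L
  for (k in seq_along(xa)) if (xa[k] != xb[k]) nd <- nd + 1L
  nd / length(xa)
}

# a tiny hand-built record with one dual-domain LuxR gene, one LuxI gene,
# one core biosynthetic gene
tiny_record <- function(record_id = "R1", with_core = TRUE,
                        bgc_type = "NRPS") {
  genes <- list(gene_feature("luxr1", 100, 853, 1L, random_aa(250),
                             "regulatory"),
                gene_feature("luxi1", 900, 1503, 1L, random_aa(200),
                             "biosynthetic"))
  if (with_core) {
    genes <- c(genes, list(gene_feature("core1", 1600, 2503, -1L,
                                        random_aa(300), "biosynthetic")))
  }
  bgc_record(record_id, organism = "Synthomonas testii",
             taxonomy = c("Proteobacteria", "Gammaproteobacteria",
                          "Synthomonadales", "Synthomonadaceae",
                          "Synthomonas"),
             habitat = "environmental", bgc_type = bgc_type, genes = genes,
             region_seq = paste(rep("ACGT", 700), collapse = ""),
             genome_gc = 0.67)
}

qualifying_hit <- function(protein_id, pfam_acc, cond_evalue = 1e-20,
                           model_coverage = 0.9) {
  domain_hits(protein_id = protein_id, pfam_acc = pfam_acc,
              cond_evalue = cond_evalue, bitscore = 150,
              ali_from = 5L, ali_to = 200L, model_coverage = model_coverage)
}

# reduced reference panel with attributes recomputed (for leave-one-out)
panel_without <- function(panel, drop) {
  ref_class <- attr(panel, "ref_class")
  keep <- setdiff(names(panel), drop)
  sub <- unclass(panel)[keep]
  plant <- keep[ref_class[keep] == "plant"]
  ahl <- keep[ref_class[keep] == "AHL"]
  cols <- find_diagnostic_columns(sub, plant, ahl)
  cons <- vapply(cols, function(j) {
    res <- substr(sub[ahl], j, j)
    names(sort(table(res), decreasing = TRUE))[1]
  }, "")
  structure(sub, diagnostic_cols = cols, ref_class = ref_class[keep],
            ahl_consensus = cons)
}
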