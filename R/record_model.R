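#' @useDynLib luxrbgc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames rbinom runif rnorm sd pnorm hclust as.dist cophenetic
#' @importFrom utils head tail read.table write.table
NULL

# controlled vocabularies shared across the pipeline
GENE_ROLES <- c("biosynthetic", "regulatory", "transport", "other", "unknown")
HABITATS <- c("plant_associated", "environmental", "human_associated", "other", "unknown")
TAX_RANKS <- c("phylum", "class", "order", "family", "genus")

# Pfam accessions defining the screen
PFAM_LUXR_DNA <- "PF00196"  # LuxR-type DNA-binding (GerE) domain
PFAM_LUXR_SIGNAL <- "PF03472"  # autoinducer/signal-binding domain
PFAM_LUXI <- "PF00765"  # AHL synthase

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Create a gene feature
#'
#' One CDS within a cluster region. Coordinates are 0-based, half-open, in
#' nucleotides on the region sequence; strand is +1 or -1.
#'
#' @param gene_id Unique (within record) gene identifier.
#' @param start,end 0-based half-open nucleotide coordinates, `start < end`.
#' @param strand +1 or -1.
#' @param translation Protein sequence (uppercase, 20 amino acids plus X).
#' @param role One of `"biosynthetic"`, `"regulatory"`, `"transport"`,
#'   `"other"`, `"unknown"`. Mirrors the antiSMASH `gene_kind` notion; the
#'   luxI-only exclusion filter depends on it.
#' @return A `gene_feature` object.
#' @export
gene_feature <- function(gene_id, start, end, strand = 1L,
                         translation = "", role = "unknown") {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (!(start >= 0L && start < end)) {
    stop("gene '", gene_id, "': require 0 <= start < end, got [",
         start, ", ", end, ")")
  }
  if (!strand %in% c(1L, -1L)) stop("strand must be +1 or -1")
  role <- match.arg(role, GENE_ROLES)
  translation <- toupper(translation)
  bad <- setdiff(strsplit(translation, "")[[1]], c(AA_ALPHABET, "X"))
  if (length(bad)) {
    stop("gene '", gene_id, "': illegal residue(s) in translation: ",
         paste(bad, collapse = ", "))
  }
  structure(list(gene_id = gene_id, start = start, end = end,
                 strand = as.integer(strand), translation = translation,
                 role = role),
            class = "gene_feature")
}

#' Create a BGC record
#'
#' One annotated biosynthetic gene cluster: its genes, region nucleotide
#' sequence, product-type annotation and organism metadata. Habitat is
#' consumed as curated metadata and never inferred from sequence.
#'
#' @param record_id Unique record identifier.
#' @param organism Organism name.
#' @param taxonomy Character vector of rank names, ordered phylum to genus.
#' @param habitat One of `"plant_associated"`, `"environmental"`,
#'   `"human_associated"`, `"other"`, `"unknown"`.
#' @param bgc_type Cluster type label (e.g. `"NRPS"`, `"PKS"`, `"NRPS-PKS"`).
#' @param genes List of [gene_feature()] objects.
#' @param region_seq Region nucleotide sequence over A/C/G/T/N.
#' @param genome_gc Genome-wide GC fraction in `[0, 1]`, or `NA` when unknown.
#' @return A `bgc_record` object.
#' @export
bgc_record <- function(record_id, organism = "unknown organism",
                       taxonomy = character(), habitat = "unknown",
                       bgc_type = "other", genes = list(), region_seq = "",
                       genome_gc = NA_real_) {
  stopifnot(is.character(record_id), length(record_id) == 1L, nzchar(record_id))
  habitat <- match.arg(habitat, HABITATS)
  region_seq <- toupper(region_seq)
  bad <- setdiff(strsplit(region_seq, "")[[1]], c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop("record '", record_id, "': illegal nucleotide(s): ",
         paste(unique(bad), collapse = ", "))
  }
  L <- nchar(region_seq)
  for (g in genes) {
    stopifnot(inherits(g, "gene_feature"))
    if (g$end > L) {
      stop("record '", record_id, "': gene '", g$gene_id,
           "' extends beyond region (", g$end, " > ", L, ")")
    }
  }
  if (!is.na(genome_gc) && (genome_gc < 0 || genome_gc > 1)) {
    stop("genome_gc must lie in [0, 1]")
  }
  structure(list(record_id = record_id, organism = organism,
                 taxonomy = as.character(taxonomy), habitat = habitat,
                 bgc_type = bgc_type, genes = genes, region_seq = region_seq,
                 genome_gc = genome_gc),
            class = "bgc_record")
}

#' @export
print.bgc_record <- function(x, ...) {
  cat("<bgc_record> ", x$record_id, " (", x$bgc_type, "), ",
      length(x$genes), " genes, region ", nchar(x$region_seq), " bp, ",
      x$organism, "\n", sep = "")
  invisible(x)
}

#' Create a domain-hit table
#'
#' One row per Pfam-domain match on a protein, as parsed from HMMER
#' `domtblout` output (or planted by the synthetic generator).
#'
#' @param protein_id,pfam_acc,cond_evalue,bitscore,ali_from,ali_to,model_coverage
#'   Vectors of equal length: protein identifier, Pfam accession (e.g.
#'   `"PF00196"`), conditional E-value (> 0), bit score, alignment
#'   coordinates on the protein (`ali_from <= ali_to`), and fraction of the
#'   profile model covered by the hit, in `[0, 1]`.
#' @return A `data.frame` with one row per hit.
#' @export
domain_hits <- function(protein_id = character(), pfam_acc = character(),
                        cond_evalue = numeric(), bitscore = numeric(),
                        ali_from = integer(), ali_to = integer(),
                        model_coverage = numeric()) {
  df <- data.frame(protein_id = as.character(protein_id),
                   pfam_acc = as.character(pfam_acc),
                   cond_evalue = as.numeric(cond_evalue),
                   bitscore = as.numeric(bitscore),
                   ali_from = as.integer(ali_from),
                   ali_to = as.integer(ali_to),
                   model_coverage = as.numeric(model_coverage),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$cond_evalue <= 0)) stop("cond_evalue must be > 0")
    if (any(df$ali_from > df$ali_to)) stop("require ali_from <= ali_to")
    if (any(df$model_coverage < 0 | df$model_coverage > 1)) {
      stop("model_coverage must lie in [0, 1]")
    }
  }
  df
}

#' Pipeline configuration
#'
#' Thresholds and sizes used across the pipeline. The identity cutoff (0.9),
#' bootstrap replicate count (1,000) and bootstrap display floor (50%) follow
#' the published screen; the domain-hit E-value and model-coverage thresholds
#' and the GC windowing are this package's own defaults, echoed as
#' assumptions into every run manifest.
#'
#' @param evalue_max Maximum conditional E-value for a qualifying domain hit.
#' @param coverage_min Minimum profile-model coverage for a qualifying hit.
#' @param identity_cutoff Protein identity cutoff for dereplication, `(0, 1]`.
#' @param bootstrap_reps Bootstrap replicates for branch support.
#' @param support_display_min Supports below this percentage are suppressed
#'   when rendering trees (retained in the data).
#' @param gc_window,gc_step GC sliding-window width and stride, bp.
#' @param alpha Significance level for the GC-anomaly test.
#' @param gap_open,gap_extend Affine gap penalties for protein alignment.
#' @param seed Base random seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(evalue_max = 1e-5, coverage_min = 0.35,
                            identity_cutoff = 0.9, bootstrap_reps = 1000L,
                            support_display_min = 50, gc_window = 500L,
                            gc_step = 250L, alpha = 0.05,
                            gap_open = 10, gap_extend = 0.5, seed = 1L) {
  if (!(identity_cutoff > 0 && identity_cutoff <= 1)) {
    stop("identity_cutoff must lie in (0, 1]")
  }
  if (bootstrap_reps < 1L) stop("bootstrap_reps must be >= 1")
  structure(list(evalue_max = evalue_max, coverage_min = coverage_min,
                 identity_cutoff = identity_cutoff,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 support_display_min = support_display_min,
                 gc_window = as.integer(gc_window),
                 gc_step = as.integer(gc_step), alpha = alpha,
                 gap_open = gap_open, gap_extend = gap_extend,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# defaults the paper does not fix; echoed into run manifests
CONFIG_ASSUMPTIONS <- c("evalue_max", "coverage_min", "gc_window", "gc_step",
                        "alpha", "gap_open", "gap_extend")
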