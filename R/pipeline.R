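# End-to-end pipeline: mine -> dereplicate -> classify -> GC -> phylogeny,
# with a run manifest recording the stage funnel and every assumed default.

#' Read a pipeline run configuration
#'
#' YAML or JSON with two modes: `mode: synthetic` (a [synth_spec()] under
#' `synth:`) or `mode: files` (paths under `inputs:`: `genbank`,
#' `domtblout`, optionally `alignment`). Threshold overrides live under
#' `config:` and are passed to [pipeline_config()].
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`).
#' @return A named list understood by [run_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

as_pipeline_config <- function(config) {
  do.call(pipeline_config, config$config %||% list())
}

as_synth_spec <- function(config) {
  args <- config$synth %||% list()
  for (nm in c("type_distribution", "habitat_distribution",
               "class_distribution")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  do.call(synth_spec, args)
}

#' Run the full LuxR-BGC pipeline
#'
#' Executes mining, luxI-only filtering, dereplication, classification, GC
#' profiling and (when at least 3 sequences are available) the
#' reference-anchored neighbor-joining phylogeny, writing all result
#' artifacts into `outdir`: `hits.tsv`, `clusters.tsv`, `summary.json`,
#' `gc_report.tsv`, `tree.nwk` and `manifest.json`. Identical configuration
#' and seed reproduce identical artifacts (the manifest carries the
#' timestamp). In synthetic mode the generated dataset (GenBank, domtblout,
#' FASTA, ground truth) is also written under `outdir/dataset/`.
#'
#' @param config A configuration list (see [read_run_config()]) or a path to
#'   a YAML/JSON config file.
#' @param outdir Output directory; overrides `config$outdir`.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- outdir %||% config$outdir %||% stop("no output directory given")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- as_pipeline_config(config)
  mode <- config$mode %||% "synthetic"
  log_msg <- function(...) message("[luxrbgc] ", ...)

  digests <- character()
  if (mode == "synthetic") {
    spec <- as_synth_spec(config)
    ds <- generate_dataset(spec)
    paths <- write_dataset(ds, file.path(outdir, "dataset"))
    digests <- tools::md5sum(paths)
    records <- ds$records
    hits <- ds$hits
  } else {
    for (p in c(config$inputs$genbank, config$inputs$domtblout)) {
      if (is.null(p) || !file.exists(p)) {
        stop("missing input file: ", if (is.null(p)) "(unset)" else p)
      }
    }
    digests <- tools::md5sum(c(config$inputs$genbank, config$inputs$domtblout))
    records <- read_genbank(config$inputs$genbank)
    hits <- read_domtblout(config$inputs$domtblout)
  }
  n_input <- length(records)
  log_msg("input: ", n_input, " records, ", nrow(hits), " domain hits")

  # mining funnel (pre-filter count kept for the manifest)
  assocs_raw <- list()
  for (r in records) {
    luxr <- find_luxr_genes(r, hits, cfg)
    if (length(luxr)) {
      assocs_raw[[length(assocs_raw) + 1L]] <-
        luxr_association(r$record_id, luxr, find_luxi_genes(r, hits, cfg),
                         r$bgc_type)
    }
  }
  n_luxr <- length(assocs_raw)
  assocs <- filter_luxi_only(assocs_raw, records)
  n_filtered <- length(assocs)
  log_msg("mining: ", n_luxr, " LuxR-positive, ", n_filtered,
          " after luxI-only filter")
  write_hit_table(assocs, records, file.path(outdir, "hits.tsv"))

  derep <- dereplicate(assocs, records, cfg)
  n_derep <- length(derep$representatives)
  log_msg("dereplication: ", n_derep, " clusters at identity cutoff ",
          cfg$identity_cutoff)
  write_cluster_table(derep$clusters, file.path(outdir, "clusters.tsv"))

  report <- tabulate_associations(derep$representatives, records)
  panel <- luxr_reference_panel()
  rep_seqs <- derep$luxr_seqs[vapply(derep$clusters, `[[`, "",
                                     "representative_id")]
  luxr_classes <- vapply(rep_seqs, classify_luxr, "", panel = panel)
  summary_out <- list(
    n_hits_unfiltered = n_luxr,
    n_hits_filtered = n_filtered,
    n_hits_dereplicated = n_derep,
    pct_with_luxi = report$pct_with_luxi,
    pct_with_luxi_display = format_pct(report$pct_with_luxi),
    type_proportions = as.list(report$type_proportions),
    habitat_proportions = as.list(report$habitat_proportions),
    class_proportions = as.list(report$class_proportions),
    luxr_subtype_counts = as.list(table(luxr_classes)))
  jsonlite::write_json(summary_out, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("classification: ", format_pct(report$pct_with_luxi),
          "% of dereplicated hits carry a luxI homolog")

  gc_tab <- gc_report(records, cfg)
  write.table(gc_tab, file.path(outdir, "gc_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_msg("gc: ", sum(gc_tab$anomalous, na.rm = TRUE), " of ",
          nrow(gc_tab), " regions flagged anomalous at alpha ", cfg$alpha)

  tree_note <- "ok"
  tree_seqs <- c(rep_seqs, gsub("-", "", unclass(panel)))
  if (length(tree_seqs) >= 3L && "GerE" %in% names(tree_seqs)) {
    msa <- progressive_align(tree_seqs, cfg$gap_open, cfg$gap_extend)
    msa <- complete_deletion(msa)
    bs <- bootstrap_support(msa, cfg$bootstrap_reps, cfg$seed)
    rooted <- root_with_outgroup(bs$tree, "GerE")
    write_newick(rooted, file.path(outdir, "tree.nwk"),
                 support_min = cfg$support_display_min)
    log_msg("phylogeny: ", length(tree_seqs), " sequences, ",
            nchar(msa[[1]]), " positions after complete deletion, ",
            cfg$bootstrap_reps, " bootstrap replicates")
  } else {
    tree_note <- "skipped: fewer than 3 sequences"
    log_msg("phylogeny skipped (", length(tree_seqs), " sequences)")
  }

  manifest <- list(
    mode = mode,
    config = unclass(cfg),
    assumptions = setNames(as.list(unclass(cfg)[CONFIG_ASSUMPTIONS]),
                           CONFIG_ASSUMPTIONS),
    input_digests = as.list(digests),
    counts = list(input = n_input, luxr_positive = n_luxr,
                  post_filter = n_filtered, post_dereplication = n_derep),
    phylogeny = tree_note,
    seed = cfg$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  stopifnot(n_input >= n_luxr, n_luxr >= n_filtered, n_filtered >= n_derep)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
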