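# Synthetic dataset generator. Emulates the statistical structure the screen
# assumes — antiSMASH-style cluster records carrying planted LuxR genes (with
# PF00196 + PF03472 domain-hit rows), optional LuxI genes (PF00765), luxI-only
# decoy clusters, LuxR-negative clusters, a controlled family structure of
# LuxR identities, categorical type/habitat/class composition, and region GC
# offset from a genome background — together with the ground truth needed to
# score every pipeline stage.

#' Specification for a synthetic dataset
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' three LuxR families (4, 3 and 2 members) with within-family pairwise
#' identity above 0.9 and between-family identity well below it, 47% of
#' LuxR-positive clusters carrying a luxI homolog, two luxI-only decoy
#' clusters, five LuxR-negative clusters, cluster types dominated by NRPS
#' (26%), PKS (10%) and NRPS-PKS hybrids (11%), plant-associated organisms as
#' the largest habitat group, a taxonomic class composition of 41%
#' Gammaproteobacteria / 31% Alphaproteobacteria / 26% Betaproteobacteria /
#' 2% Deltaproteobacteria, and cluster regions at GC 0.60 against a genome
#' background of 0.67.
#'
#' Categorical composition (type, habitat, class, luxI carriage) is allocated
#' by largest-remainder quota with randomized assignment, so the realized
#' composition of every dataset matches the requested distribution exactly.
#'
#' @param n_families Number of planted LuxR families.
#' @param members_per_family Integer vector of family sizes (length
#'   `n_families`).
#' @param within_identity Target pairwise identity within a family (> 0.9).
#' @param between_identity Target pairwise identity between families (< 0.9).
#' @param luxi_fraction Fraction of LuxR-positive clusters also given a LuxI
#'   gene.
#' @param luxi_only_decoys Number of clusters whose only biosynthetic-role
#'   gene is a LuxI homolog (targets of the exclusion filter).
#' @param negatives Number of clusters with no LuxR gene.
#' @param type_distribution,habitat_distribution,class_distribution Named
#'   probability vectors (each sums to 1).
#' @param region_gc,genome_gc Cluster-region and genome-background GC
#'   fractions.
#' @param protein_length Length of the root LuxR protein, residues.
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   serialized output.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_families = 3L,
                       members_per_family = c(4L, 3L, 2L),
                       within_identity = 0.95,
                       between_identity = 0.70,
                       luxi_fraction = 0.47,
                       luxi_only_decoys = 2L,
                       negatives = 5L,
                       type_distribution = c(NRPS = 0.26, PKS = 0.10,
                                             "NRPS-PKS" = 0.11,
                                             bacteriocin = 0.13,
                                             lanthipeptide = 0.08,
                                             thiopeptide = 0.07,
                                             terpene = 0.10,
                                             siderophore = 0.07,
                                             "beta-lactam" = 0.04,
                                             ectoine = 0.04),
                       habitat_distribution = c(plant_associated = 0.40,
                                                environmental = 0.30,
                                                human_associated = 0.20,
                                                other = 0.10),
                       class_distribution = c(Gammaproteobacteria = 0.41,
                                              Alphaproteobacteria = 0.31,
                                              Betaproteobacteria = 0.26,
                                              Deltaproteobacteria = 0.02),
                       region_gc = 0.60, genome_gc = 0.67,
                       protein_length = 250L, seed = 1L) {
  if (length(members_per_family) != n_families) {
    stop("members_per_family has length ", length(members_per_family),
         " but n_families is ", n_families)
  }
  if (!(between_identity > 0 && between_identity < within_identity &&
        within_identity <= 1)) {
    stop("require 0 < between_identity < within_identity <= 1")
  }
  for (d in list(type_distribution, habitat_distribution, class_distribution)) {
    if (abs(sum(d) - 1) > 1e-9) stop("distribution probabilities must sum to 1")
  }
  structure(list(n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 within_identity = within_identity,
                 between_identity = between_identity,
                 luxi_fraction = luxi_fraction,
                 luxi_only_decoys = as.integer(luxi_only_decoys),
                 negatives = as.integer(negatives),
                 type_distribution = type_distribution,
                 habitat_distribution = habitat_distribution,
                 class_distribution = class_distribution,
                 region_gc = region_gc, genome_gc = round(genome_gc, 6),
                 protein_length = as.integer(protein_length),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Mutate a protein to an exact target identity
#'
#' Substitution-only mutation: exactly `round((1 - target_identity) * L)`
#' positions are replaced by a different residue, so the realized ungapped
#' identity to the parent is controlled to within one position. Uses the
#' session RNG (seed with `set.seed()`).
#'
#' @param parent Protein sequence, length >= 50.
#' @param target_identity Target identity fraction in `(0, 1]`.
#' @return Mutated protein of the same length.
#' @export
mutate_protein <- function(parent, target_identity) {
  L <- nchar(parent)
  if (L < 50L) stop("parent must be at least 50 residues")
  if (!(target_identity > 0 && target_identity <= 1)) {
    stop("target_identity must lie in (0, 1]")
  }
  k <- as.integer(round((1 - target_identity) * L))
  if (k == 0L) return(parent)
  chars <- strsplit(parent, "")[[1]]
  pos <- sample.int(L, k)
  for (p in pos) {
    chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

random_protein <- function(L) {
  paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
}

random_dna <- function(L, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
}

# largest-remainder quota: counts per category match n * prob exactly up to
# rounding, assignment order randomized
quota_assign <- function(n, dist) {
  if (n == 0L) return(character())
  raw <- n * dist
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  sample(rep(names(dist), times = counts))
}

planted_domain_hits <- function(protein_id, accs, L) {
  n <- length(accs)
  domain_hits(protein_id = rep(protein_id, n), pfam_acc = accs,
              cond_evalue = signif(10^(-runif(n, 10, 30)), 6),
              bitscore = round(runif(n, 80, 250), 1),
              ali_from = pmax(1L, as.integer(round(runif(n, 1, L / 3)))),
              ali_to = as.integer(round(runif(n, 2 * L / 3, L))),
              model_coverage = sample(160:196, n, replace = TRUE) / 200)
}

#' Generate a synthetic dataset with ground truth
#'
#' Builds one [bgc_record()] per planted LuxR cluster, luxI-only decoy and
#' LuxR-negative cluster; plants PF00196 + PF03472 domain-hit rows on every
#' LuxR gene and PF00765 rows on every LuxI gene (all passing the default
#' thresholds); and returns the ground-truth maps needed to score mining,
#' filtering and dereplication. Family members are mutated from a family
#' founder at identity `1 - (1 - within_identity)/2`, which bounds every
#' within-family pairwise identity at or above `within_identity`; founders
#' are mutated from a common root so that between-family pairwise identities
#' fall near `between_identity`. A minority of LuxR-negative clusters carry a
#' single-domain (PF00196-only) regulator, exercising the dual-domain rule.
#'
#' @param spec A [synth_spec()].
#' @return A list with elements `records` (list of [bgc_record()]), `hits`
#'   (domain-hit `data.frame`) and `truth` (list: `family_of`,
#'   `planted_luxr_bgcs`, `planted_luxi_bgcs`, `decoy_bgcs`,
#'   `luxr_protein_of`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)

  K <- spec$n_families
  n_planted <- sum(spec$members_per_family)
  n_total <- n_planted + spec$luxi_only_decoys + spec$negatives

  # LuxR family structure: founders from a common root, members from founders
  root <- random_protein(spec$protein_length)
  luxi_root <- random_protein(200L)
  founder_id <- 1 - (1 - spec$between_identity) / 2
  member_id <- 1 - (1 - spec$within_identity) / 2
  luxr_seqs <- character(); family_of <- integer()
  for (f in seq_len(K)) {
    founder <- mutate_protein(root, founder_id)
    for (m in seq_len(spec$members_per_family[f])) {
      pid <- sprintf("luxr_F%02d_%02d", f, m)
      luxr_seqs[pid] <- mutate_protein(founder, member_id)
      family_of[pid] <- f
    }
  }

  record_ids <- sprintf("BGC%04d", seq_len(n_total))
  kind <- rep(c("planted", "decoy", "negative"),
              c(n_planted, spec$luxi_only_decoys, spec$negatives))

  # categorical metadata by quota within each stratum, so the LuxR-positive
  # population (what the downstream tables describe) matches the design
  # distribution exactly; luxI carriage by exact allocation
  stratified <- function(dist) {
    out <- character(n_total)
    for (kk in unique(kind)) {
      out[kind == kk] <- quota_assign(sum(kind == kk), dist)
    }
    out
  }
  types <- stratified(spec$type_distribution)
  habitats <- stratified(spec$habitat_distribution)
  classes <- stratified(spec$class_distribution)
  n_luxi <- as.integer(round(spec$luxi_fraction * n_planted))
  luxi_idx <- sort(sample.int(n_planted, n_luxi))

  records <- vector("list", n_total)
  hits <- domain_hits()
  luxr_protein_of <- character()
  base_seed <- spec$seed %% 2147000000L

  for (i in seq_len(n_total)) {
    set.seed((base_seed + 7919L * i) %% 2147483647L)
    rid <- record_ids[i]
    genes <- list()
    add_gene <- function(tag, aa, role) {
      # consecutive layout with 50-bp spacers and a 100-bp leading flank
      start <- if (length(genes)) genes[[length(genes)]]$end + 50L else 100L
      end <- start + 3L * (nchar(aa) + 1L)
      genes[[length(genes) + 1L]] <<-
        gene_feature(tag, start, end, sample(c(1L, -1L), 1L), aa, role)
    }

    if (kind[i] == "planted") {
      pid <- names(luxr_seqs)[i]
      luxr_protein_of[rid] <- pid
      add_gene(pid, luxr_seqs[[pid]], "regulatory")
      hits <- rbind(hits, planted_domain_hits(pid, c(PFAM_LUXR_DNA,
                                                     PFAM_LUXR_SIGNAL),
                                              nchar(luxr_seqs[[pid]])))
      if (i %in% luxi_idx) {
        lid <- sprintf("%s_luxi", rid)
        luxi <- mutate_protein(luxi_root, 0.9)
        add_gene(lid, luxi, "biosynthetic")
        hits <- rbind(hits, planted_domain_hits(lid, PFAM_LUXI, nchar(luxi)))
      }
      for (j in seq_len(sample(2:3, 1L))) {
        add_gene(sprintf("%s_core%d", rid, j), random_protein(300L),
                 "biosynthetic")
      }
      add_gene(sprintf("%s_transp", rid), random_protein(120L), "transport")
    } else if (kind[i] == "decoy") {
      pid <- sprintf("luxr_decoy_%02d", i - n_planted)
      luxr_protein_of[rid] <- pid
      dseq <- mutate_protein(root, 0.75)
      add_gene(pid, dseq, "regulatory")
      hits <- rbind(hits, planted_domain_hits(pid, c(PFAM_LUXR_DNA,
                                                     PFAM_LUXR_SIGNAL),
                                              nchar(dseq)))
      lid <- sprintf("%s_luxi", rid)
      luxi <- mutate_protein(luxi_root, 0.9)
      add_gene(lid, luxi, "biosynthetic")  # the only biosynthetic gene
      hits <- rbind(hits, planted_domain_hits(lid, PFAM_LUXI, nchar(luxi)))
      add_gene(sprintf("%s_other", rid), random_protein(150L), "other")
    } else {
      for (j in 1:2) {
        add_gene(sprintf("%s_core%d", rid, j), random_protein(300L),
                 "biosynthetic")
      }
      if (runif(1) < 0.3) {
        # single-domain (DNA-binding only) regulator: must NOT qualify
        sid <- sprintf("%s_gere", rid)
        sseq <- random_protein(210L)
        add_gene(sid, sseq, "regulatory")
        hits <- rbind(hits, planted_domain_hits(sid, PFAM_LUXR_DNA,
                                                nchar(sseq)))
      }
      add_gene(sprintf("%s_other", rid), random_protein(150L), "other")
    }

    L_region <- genes[[length(genes)]]$end + 100L
    records[[i]] <- bgc_record(
      rid,
      organism = sprintf("Synthomonas synthetica str. %s", rid),
      taxonomy = c("Proteobacteria", classes[i], "Synthomonadales",
                   "Synthomonadaceae", "Synthomonas"),
      habitat = habitats[i], bgc_type = types[i], genes = genes,
      region_seq = random_dna(L_region, spec$region_gc),
      genome_gc = spec$genome_gc)
  }

  planted_ids <- record_ids[kind == "planted"]
  truth <- list(
    family_of = family_of,
    planted_luxr_bgcs = planted_ids,
    planted_luxi_bgcs = planted_ids[seq_len(n_planted) %in% luxi_idx],
    decoy_bgcs = record_ids[kind == "decoy"],
    luxr_protein_of = luxr_protein_of)
  list(records = records, hits = hits, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Serializes the full fixture set: GenBank records, a domtblout-format hit
#' table, the LuxR protein sequences as FASTA, and the ground truth as JSON.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genbank = file.path(dir, "records.gbk"),
             domtblout = file.path(dir, "hits.domtblout"),
             fasta = file.path(dir, "luxr_proteins.faa"),
             truth = file.path(dir, "ground_truth.json"))
  write_genbank(dataset$records, paths[["genbank"]])
  write_domtblout(dataset$hits, paths[["domtblout"]])
  luxr <- luxr_sequences(dataset$records)
  write_fasta(luxr, paths[["fasta"]])
  jsonlite::write_json(dataset$truth, paths[["truth"]], auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

# all regulatory-role translations keyed by gene id (LuxR candidates)
luxr_sequences <- function(records) {
  out <- character()
  for (r in records) {
    for (g in r$genes) {
      if (g$role == "regulatory") out[g$gene_id] <- g$translation
    }
  }
  out
}
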