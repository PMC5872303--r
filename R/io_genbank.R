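# GenBank flat-file reader/writer for antiSMASH-style cluster records.
# Internal coordinates are 0-based half-open; the 1-based closed GenBank
# convention is converted exactly here and nowhere else.

#' Read BGC records from a GenBank flat file
#'
#' Parses antiSMASH-style cluster records: the cluster type is taken from a
#' `cluster` (or `region`) feature's `/product` qualifier, gene roles from a
#' `/gene_kind` qualifier, and habitat / genome GC from `source` `/note`
#' qualifiers of the form `habitat:<value>` and `genome_gc:<fraction>`.
#' Missing qualifiers map to `unknown`/`NA`, never to errors; a CDS without a
#' `/translation` is skipped with a warning.
#'
#' @param path Path to a GenBank flat file with at least one record.
#' @return A list of [bgc_record()] objects.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  starts <- grep("^LOCUS", lines)
  if (!length(starts)) stop("no LOCUS line found in '", path, "'")
  ends <- grep("^//\\s*$", lines)
  if (length(ends) < length(starts)) stop("unterminated GenBank record")
  lapply(seq_along(starts), function(k) {
    parse_genbank_record(lines[starts[k]:ends[k]], starts[k])
  })
}

parse_genbank_record <- function(lines, offset) {
  locus <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(locus) < 3 || !grepl("^[0-9]+$", locus[3])) {
    stop("malformed LOCUS line at line ", offset, ": ", lines[1])
  }
  record_id <- locus[2]

  organism <- "unknown organism"
  taxonomy <- character()
  org_i <- grep("^  ORGANISM", lines)
  feat_i <- grep("^FEATURES", lines)
  if (length(org_i)) {
    organism <- trimws(sub("^  ORGANISM", "", lines[org_i[1]]))
    j <- org_i[1] + 1L
    tax <- character()
    while (j <= length(lines) && grepl("^\\s{10,}", lines[j])) {
      tax <- c(tax, trimws(lines[j])); j <- j + 1L
    }
    tax <- sub("\\.$", "", paste(tax, collapse = " "))
    if (nzchar(tax)) taxonomy <- trimws(strsplit(tax, ";")[[1]])
  }

  # feature table
  feats <- list()
  if (length(feat_i)) {
    j <- feat_i[1] + 1L
    cur <- NULL
    while (j <= length(lines) && !grepl("^(ORIGIN|//)", lines[j])) {
      ln <- lines[j]
      if (grepl("^ {5}\\S", ln)) {  # new feature
        if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        cur <- list(key = parts[1], location = paste(parts[-1], collapse = ""),
                    quals = character())
      } else if (!is.null(cur)) {
        txt <- trimws(ln)
        if (startsWith(txt, "/")) {
          cur$quals <- c(cur$quals, txt)
        } else if (length(cur$quals)) {
          n <- length(cur$quals)
          sep <- if (grepl("^/translation=", cur$quals[n])) "" else " "
          cur$quals[n] <- paste0(cur$quals[n], sep, txt)
        } else {
          cur$location <- paste0(cur$location, txt)
        }
      }
      j <- j + 1L
    }
    if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  }

  # sequence
  seq <- ""
  ori_i <- grep("^ORIGIN", lines)
  if (length(ori_i)) {
    body <- lines[(ori_i[1] + 1L):length(lines)]
    body <- body[!grepl("^//", body)]
    seq <- toupper(paste(gsub("[^A-Za-z]", "", body), collapse = ""))
  }

  habitat <- "unknown"; genome_gc <- NA_real_; bgc_type <- "other"
  genes <- list(); n_cds <- 0L
  for (f in feats) {
    q <- parse_qualifiers(f$quals)
    if (f$key == "source") {
      if (!is.null(q$organism)) organism <- q$organism
      for (note in q[names(q) == "note"]) {
        if (startsWith(note, "habitat:")) {
          h <- sub("^habitat:", "", note)
          if (h %in% HABITATS) habitat <- h
        }
        if (startsWith(note, "genome_gc:")) {
          genome_gc <- suppressWarnings(as.numeric(sub("^genome_gc:", "", note)))
        }
      }
    } else if (f$key %in% c("cluster", "region")) {
      if (!is.null(q$product)) bgc_type <- q$product
    } else if (f$key == "CDS") {
      n_cds <- n_cds + 1L
      loc <- parse_location(f$location)
      gid <- q$locus_tag %||% q$gene %||% sprintf("%s_cds%d", record_id, n_cds)
      role <- q$gene_kind %||% "unknown"
      if (!role %in% GENE_ROLES) role <- "unknown"
      if (is.null(q$translation) || !nzchar(q$translation)) {
        warning("record '", record_id, "': CDS '", gid,
                "' has no translation; skipped")
        next
      }
      genes[[length(genes) + 1L]] <-
        gene_feature(gid, loc$start, loc$end, loc$strand,
                     gsub(" ", "", q$translation), role)
    }
  }

  bgc_record(record_id, organism = organism, taxonomy = taxonomy,
             habitat = habitat, bgc_type = bgc_type, genes = genes,
             region_seq = seq, genome_gc = genome_gc)
}

parse_qualifiers <- function(quals) {
  out <- list()
  for (qq in quals) {
    m <- regmatches(qq, regexec('^/([A-Za-z_]+)(?:=(?:"(.*)"|(\\S+)))?$', qq,
                                perl = TRUE))[[1]]
    if (length(m) < 2) next
    val <- if (nzchar(m[3])) m[3] else if (nzchar(m[4])) m[4] else ""
    out[[length(out) + 1L]] <- val
    names(out)[length(out)] <- m[2]
  }
  out
}

# GenBank 1-based closed "a..b" (optionally complement(...)) to 0-based
# half-open [a-1, b)
parse_location <- function(loc) {
  strand <- 1L
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  m <- regmatches(loc, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", loc))[[1]]
  if (length(m) != 3) stop("cannot parse feature location '", loc, "'")
  list(start = as.integer(m[2]) - 1L, end = as.integer(m[3]), strand = strand)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write BGC records to a GenBank flat file
#'
#' Inverse of [read_genbank()]: writes antiSMASH-style records whose fields
#' round-trip exactly (genome GC is carried at 6 decimal places).
#'
#' @param records List of [bgc_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(records, path) {
  if (inherits(records, "bgc_record")) records <- list(records)
  con <- file(path, "w"); on.exit(close(con))
  for (r in records) {
    L <- nchar(r$region_seq)
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   BCT 01-JAN-2016",
                       r$record_id, L), con)
    writeLines("DEFINITION  biosynthetic gene cluster region.", con)
    writeLines(sprintf("ACCESSION   %s", r$record_id), con)
    writeLines(sprintf("SOURCE      %s", r$organism), con)
    writeLines(sprintf("  ORGANISM  %s", r$organism), con)
    tax <- if (length(r$taxonomy)) paste0(paste(r$taxonomy, collapse = "; "), ".") else "."
    writeLines(paste0("            ", tax), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", L), con)
    write_qualifier(con, "organism", r$organism)
    write_qualifier(con, "note", paste0("habitat:", r$habitat))
    if (!is.na(r$genome_gc)) {
      write_qualifier(con, "note", sprintf("genome_gc:%.6f", r$genome_gc))
    }
    writeLines(sprintf("     cluster         1..%d", L), con)
    write_qualifier(con, "product", r$bgc_type)
    for (g in r$genes) {
      loc <- sprintf("%d..%d", g$start + 1L, g$end)
      if (g$strand < 0) loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      write_qualifier(con, "locus_tag", g$gene_id)
      write_qualifier(con, "gene_kind", g$role)
      write_qualifier(con, "translation", g$translation)
    }
    writeLines("ORIGIN", con)
    if (L > 0) {
      pos <- seq(1L, L, by = 60L)
      for (p in pos) {
        chunk <- substr(r$region_seq, p, min(p + 59L, L))
        tens <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
        writeLines(sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))), con)
      }
    }
    writeLines("//", con)
  }
  invisible(path)
}

write_qualifier <- function(con, name, value) {
  txt <- sprintf('/%s="%s"', name, value)
  width <- 58L
  while (nchar(txt) > width) {
    writeLines(paste0(strrep(" ", 21), substr(txt, 1, width)), con)
    txt <- substr(txt, width + 1L, nchar(txt))
  }
  writeLines(paste0(strrep(" ", 21), txt), con)
}
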