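test_that("gene and record constructors enforce their invariants", {
  expect_error(gene_feature("g", 10, 10, 1L, "MK"), "start < end")
  expect_error(gene_feature("g", 0, 9, 1L, "MKB#"), "illegal residue")
  g <- gene_feature("g", 0, 9, -1L, "MK")
  expect_identical(g$role, "unknown")
  expect_error(bgc_record("r", genes = list(g), region_seq = "ACGTA"),
               "beyond region")
  expect_error(bgc_record("r", region_seq = "ACGU"), "illegal nucleotide")
  expect_error(domain_hits("p", "PF00196", 0, 10, 1L, 5L, 0.5), "cond_evalue")
  expect_error(pipeline_config(identity_cutoff = 0), "identity_cutoff")
})

test_that("GenBank coordinates convert 1-based closed to 0-based half-open", {
  gbk <- c(
    "LOCUS       TESTREC 400 bp    DNA     linear   BCT 01-JAN-2016",
    "DEFINITION  test.",
    "SOURCE      Org x",
    "  ORGANISM  Org x",
    "            Proteobacteria; Gammaproteobacteria; O; F; G.",
    "FEATURES             Location/Qualifiers",
    "     source          1..400",
    '                     /organism="Org x"',
    "     cluster         1..400",
    '                     /product="PKS"',
    "     CDS             101..250",
    '                     /locus_tag="g1"',
    '                     /translation="MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQD"',
    "     CDS             complement(260..340)",
    '                     /translation="MKTAYIAKQRQISFVKSHFSRQLEERL"',
    "ORIGIN",
    vapply(seq(1, 400, by = 60), function(p) {
      paste0(sprintf("%9d ", p),
             paste(rep("acgtacgtac", min(6, (400 - p + 1) %/% 10)),
                   collapse = " "))
    }, ""),
    "//")
  f <- tempfile(fileext = ".gbk")
  writeLines(gbk, f)
  recs <- read_genbank(f)
  expect_length(recs, 1L)
  r <- recs[[1]]
  expect_identical(r$record_id, "TESTREC")
  expect_identical(r$bgc_type, "PKS")
  expect_identical(r$taxonomy[2], "Gammaproteobacteria")
  expect_identical(r$genes[[1]]$start, 100L)
  expect_identical(r$genes[[1]]$end, 250L)
  expect_identical(r$genes[[2]]$strand, -1L)
  # anonymous CDS gets a generated id; qualifiers absent map to unknown
  expect_identical(r$genes[[2]]$role, "unknown")
})

test_that("GenBank record counts are preserved and CDS without translation is skipped", {
  ds <- default_dataset()
  two <- ds$records[1:2]
  f <- tempfile(fileext = ".gbk")
  write_genbank(two, f)
  back <- read_genbank(f)
  expect_identical(vapply(back, function(r) length(r$genes), 0L),
                   vapply(two, function(r) length(r$genes), 0L))

  broken <- c("LOCUS       B1 100 bp DNA linear BCT 01-JAN-2016",
              "FEATURES             Location/Qualifiers",
              "     CDS             1..60",
              '                     /locus_tag="nt1"',
              "//")
  fb <- tempfile(); writeLines(broken, fb)
  expect_warning(r <- read_genbank(fb), "no translation")
  expect_length(r[[1]]$genes, 0L)

  fm <- tempfile(); writeLines(c("LOCUS", "//"), fm)
  expect_error(read_genbank(fm), "malformed LOCUS")
})

test_that("synthetic dataset round-trips through GenBank and domtblout", {
  ds <- default_dataset()
  dir <- file.path(tempdir(), "rt")
  paths <- write_dataset(ds, dir)
  back <- read_genbank(paths[["genbank"]])
  expect_equal(back, ds$records)
  h <- read_domtblout(paths[["domtblout"]])
  ord <- function(x) x[order(x$protein_id, x$pfam_acc, x$cond_evalue), ]
  expect_equal(ord(h), ord(ds$hits), ignore_attr = TRUE)
})

test_that("domtblout parsing computes model coverage and rejects short rows", {
  cmt <- tempfile(); writeLines(c("# a comment", "# another"), cmt)
  expect_identical(nrow(read_domtblout(cmt)), 0L)

  row <- paste("prot1 - 300 luxr_model PF00196.18 100 1e-20 55.0 0.1 1 1",
               "2e-20 4e-19 54.0 0.1 5 100 10 200 8 205 0.95 desc")
  f <- tempfile(); writeLines(c("# header", row), f)
  h <- read_domtblout(f)
  expect_identical(h$pfam_acc, "PF00196")
  expect_equal(h$model_coverage, 0.96)
  expect_equal(h$cond_evalue, 2e-20)

  bad <- tempfile(); writeLines("p1 - 300 q PF1 100 1e-5", bad)
  expect_error(read_domtblout(bad), "expected >= 23")
})

test_that("newick output uses 6-decimal lengths and round-trips through ape", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.2);")
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  expect_identical(readLines(f), "(A:0.100000,B:0.200000);")

  tr2 <- ape::rtree(8)
  f2 <- tempfile(); write_newick(tr2, f2)
  back <- ape::read.tree(f2)
  expect_identical(ape::dist.topo(ape::unroot(back), ape::unroot(tr2))[1], 0)
  expect_equal(sort(back$edge.length), sort(tr2$edge.length),
               tolerance = 1e-6)

  neg <- tr; neg$edge.length[1] <- -0.05
  expect_error(write_newick(neg, tempfile()), "negative branch length")
  dup <- tr; dup$tip.label <- c("A", "A")
  expect_error(write_newick(dup, tempfile()), "duplicate leaf names")
})

test_that("bootstrap supports below the display floor are suppressed only at rendering", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.1)30:0.1,(C:0.1,D:0.1)80:0.1);")
  f <- tempfile()
  write_newick(tr, f, support_min = 50)
  txt <- readLines(f)
  expect_false(grepl("30", txt))
  expect_true(grepl("80", txt))
  write_newick(tr, f)
  expect_true(grepl("30", readLines(f)))
})
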