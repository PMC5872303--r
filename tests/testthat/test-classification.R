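make_assoc_set <- function(n, n_luxi, bgc_type = "NRPS") {
  recs <- lapply(seq_len(n), function(i) {
    bgc_record(sprintf("T%03d", i), habitat = "environmental",
               taxonomy = c("Proteobacteria", "Gammaproteobacteria",
                            "O", "F", "G"),
               bgc_type = bgc_type, region_seq = "ACGT")
  })
  assocs <- lapply(seq_len(n), function(i) {
    luxr_association(sprintf("T%03d", i), "r1",
                     if (i <= n_luxi) "i1" else character(), bgc_type)
  })
  list(assocs = assocs, recs = recs)
}

test_that("the luxI co-occurrence percentage reproduces 64/137 -> 47%", {
  x <- make_assoc_set(137, 64)
  rpt <- tabulate_associations(x$assocs, x$recs)
  expect_equal(rpt$pct_with_luxi, 100 * 64 / 137)
  expect_equal(round(rpt$pct_with_luxi, 1), 46.7)
  expect_identical(format_pct(rpt$pct_with_luxi), "47")
})

test_that("tabulation is order-invariant and handles single and empty inputs", {
  x <- make_assoc_set(5, 2)
  r1 <- tabulate_associations(x$assocs, x$recs)
  set.seed(9)
  r2 <- tabulate_associations(sample(x$assocs), x$recs)
  expect_equal(r1, r2)

  single <- make_assoc_set(1, 0)
  expect_equal(tabulate_associations(single$assocs, single$recs)$type_proportions,
               c(NRPS = 100))

  empty <- tabulate_associations(list(), list())
  expect_identical(empty$n_hits, 0L)
  expect_equal(empty$pct_with_luxi, 0)
})

test_that("proportion maps sum to 100 on a generated dataset", {
  ds <- default_dataset()
  assocs <- mine(ds$records, ds$hits)
  rpt <- tabulate_associations(assocs, ds$records)
  expect_equal(sum(rpt$type_proportions), 100, tolerance = 1e-9)
  expect_equal(sum(rpt$habitat_proportions), 100, tolerance = 1e-9)
  expect_equal(sum(rpt$class_proportions), 100, tolerance = 1e-9)
})

test_that("generated composition matches the design distribution at n = 500", {
  spec <- synth_spec(n_families = 480L, members_per_family = rep(1L, 480),
                     luxi_only_decoys = 5L, negatives = 15L, seed = 33L)
  ds <- generate_dataset(spec)
  types <- vapply(ds$records, `[[`, "", "bgc_type")
  obs <- table(types)[names(spec$type_distribution)] / length(types)
  # within the binomial 95% CI of the design probabilities
  for (ty in names(spec$type_distribution)) {
    p <- spec$type_distribution[[ty]]
    half <- 1.96 * sqrt(p * (1 - p) / length(types))
    expect_lt(abs(obs[[ty]] - p), half + 1e-9)
  }
})

test_that("association frequencies reproduce the printed per-type rates", {
  af <- association_frequency(c(NRPS = 52433, ectoine = 2000, misc = 100),
                              c(NRPS = 1019, ectoine = 1))
  expect_equal(round(af[["NRPS"]], 2), 1.94)    # "about 2%"
  expect_identical(format_pct(af[["NRPS"]]), "2")
  expect_equal(af[["ectoine"]], 0.05)
  expect_identical(format_pct(af[["ectoine"]]), "0.05")
  expect_equal(af[["misc"]], 0)

  t <- c(a = 10, b = 25)
  expect_equal(unname(association_frequency(t, t)), c(100, 100))
  expect_error(association_frequency(c(a = 10), c(a = 11)), "exceed")
  # zero-total types are omitted
  expect_named(association_frequency(c(a = 10, b = 0), c(a = 1)), "a")
})

test_that("reference proteins self-classify under leave-one-out", {
  panel <- luxr_reference_panel()
  ref_class <- attr(panel, "ref_class")
  for (nm in names(panel)[ref_class %in% c("AHL", "plant")]) {
    reduced <- panel_without(panel, nm)
    got <- classify_luxr(gsub("-", "", panel[[nm]]), reduced)
    want <- if (ref_class[[nm]] == "AHL") "AHL_type" else "plant_responsive_like"
    expect_identical(got, want, label = nm)
  }
})

test_that("proteins matching neither consensus are atypical", {
  panel <- luxr_reference_panel()
  cols <- attr(panel, "diagnostic_cols")
  # take an AHL reference and overwrite both diagnostic residues
  s <- strsplit(gsub("-", "", panel[["LasR"]]), "")[[1]]
  s[cols[1]] <- "A"; s[cols[2]] <- "F"
  expect_identical(classify_luxr(paste(s, collapse = "")), "atypical")
  # the outgroup, which lacks the signal-binding domain consensus
  expect_identical(classify_luxr(gsub("-", "", panel[["GerE"]])), "atypical")
  # W at position 2 alone is decisive for the plant-responsive call
  s2 <- strsplit(gsub("-", "", panel[["LasR"]]), "")[[1]]
  s2[cols[2]] <- "W"
  expect_identical(classify_luxr(paste(s2, collapse = "")),
                   "plant_responsive_like")
})
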