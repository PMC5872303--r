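test_that("a gene qualifies only with both LuxR domains on the same protein", {
  r <- tiny_record()
  both <- rbind(qualifying_hit("luxr1", "PF00196"),
                qualifying_hit("luxr1", "PF03472"))
  expect_identical(find_luxr_genes(r, both), "luxr1")

  dna_only <- qualifying_hit("luxr1", "PF00196")
  expect_length(find_luxr_genes(r, dna_only), 0L)

  # domains split across two genes in one cluster do not qualify
  split <- rbind(qualifying_hit("luxr1", "PF00196"),
                 qualifying_hit("core1", "PF03472"))
  expect_length(find_luxr_genes(r, split), 0L)

  expect_length(find_luxr_genes(r, domain_hits()), 0L)
})

test_that("hit thresholds are enforced on E-value and model coverage", {
  r <- tiny_record()
  weak_e <- rbind(qualifying_hit("luxr1", "PF00196", cond_evalue = 1e-3),
                  qualifying_hit("luxr1", "PF03472"))
  expect_length(find_luxr_genes(r, weak_e), 0L)
  weak_cov <- rbind(qualifying_hit("luxr1", "PF00196", model_coverage = 0.2),
                    qualifying_hit("luxr1", "PF03472"))
  expect_length(find_luxr_genes(r, weak_cov), 0L)
  expect_identical(find_luxr_genes(r, weak_e,
                                   pipeline_config(evalue_max = 1e-2)),
                   "luxr1")
  expect_length(find_luxi_genes(r, qualifying_hit("luxi1", "PF00765",
                                                  cond_evalue = 1e-3)), 0L)
  expect_identical(find_luxi_genes(r, qualifying_hit("luxi1", "PF00765")),
                   "luxi1")
})

test_that("relaxing the E-value threshold never shrinks the hit set", {
  ds <- default_dataset()
  hits <- ds$hits
  # degrade a third of the hits to borderline E-values
  set.seed(3)
  k <- sample(nrow(hits), ceiling(nrow(hits) / 3))
  hits$cond_evalue[k] <- 10^runif(length(k), -6, -2)
  prev <- character()
  for (emax in c(1e-6, 1e-5, 1e-3, 1e-1)) {
    cur <- vapply(mine(ds$records, hits, pipeline_config(evalue_max = emax)),
                  `[[`, "", "record_id")
    expect_true(all(prev %in% cur), label = paste("evalue_max", emax))
    prev <- cur
  }
})

test_that("the luxI-only filter removes exactly the signal-synthase-only clusters", {
  decoy <- tiny_record("D1", with_core = FALSE)
  keeper <- tiny_record("K1", with_core = TRUE)
  hits <- rbind(qualifying_hit("luxr1", "PF00196"),
                qualifying_hit("luxr1", "PF03472"),
                qualifying_hit("luxi1", "PF00765"))
  a_decoy <- luxr_association("D1", "luxr1", "luxi1")
  a_keep <- luxr_association("K1", "luxr1", "luxi1")

  out <- filter_luxi_only(list(a_decoy, a_keep), list(decoy, keeper))
  expect_identical(vapply(out, `[[`, "", "record_id"), "K1")
  # idempotent and a subset of its input
  expect_identical(filter_luxi_only(out, list(decoy, keeper)), out)

  # association without a luxI gene is never removed
  a_solo <- luxr_association("D1", "luxr1")
  expect_length(filter_luxi_only(list(a_solo), list(decoy)), 1L)
})

test_that("mining recovers the planted ground truth exactly", {
  ds <- default_dataset()
  assocs <- mine(ds$records, ds$hits)
  got <- vapply(assocs, `[[`, "", "record_id")
  expect_setequal(got, ds$truth$planted_luxr_bgcs)  # precision = recall = 1

  with_luxi <- got[vapply(assocs, `[[`, TRUE, "has_luxi")]
  expect_setequal(with_luxi, ds$truth$planted_luxi_bgcs)

  # luxI genes are attached, and has_luxi mirrors them
  for (a in assocs) {
    expect_identical(a$has_luxi, length(a$luxi_gene_ids) > 0L)
  }
  expect_length(mine(list(), domain_hits()), 0L)
  expect_error(mine(ds$records[c(1, 1)], ds$hits), "duplicate record_id")
})

test_that("half-allocated luxI flags match the planted subset", {
  spec <- synth_spec(n_families = 8L, members_per_family = rep(5L, 8),
                     luxi_fraction = 0.5, seed = 21L)
  ds <- generate_dataset(spec)
  expect_length(ds$truth$planted_luxi_bgcs, 20L)  # round(0.5 * 40)
  assocs <- mine(ds$records, ds$hits)
  with_luxi <- vapply(assocs, `[[`, "", "record_id")[
    vapply(assocs, `[[`, TRUE, "has_luxi")]
  expect_setequal(with_luxi, ds$truth$planted_luxi_bgcs)
})

test_that("the hit table serializes with taxonomy and the AHL- type prefix", {
  ds <- default_dataset()
  assocs <- mine(ds$records, ds$hits)
  f <- tempfile(fileext = ".tsv")
  tab <- write_hit_table(assocs, ds$records, f)
  expect_identical(nrow(tab), length(assocs))
  expect_true(all(grepl("^AHL-", tab$bgc_type[tab$has_luxi])))
  expect_false(any(grepl("^AHL-", tab$bgc_type[!tab$has_luxi])))
  back <- read.delim(f)
  expect_identical(nrow(back), nrow(tab))
})
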