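test_that("progressive alignment degenerates correctly for easy inputs", {
  s <- random_aa(60)
  msa <- progressive_align(c(a = s, b = s, c = s))
  expect_false(any(grepl("-", unclass(msa))))
  expect_identical(unname(unclass(msa)), c(s, s, s))

  set.seed(6)
  x <- random_aa(50); y <- random_aa(45)
  two <- progressive_align(c(p = x, q = y))
  ref <- global_align(x, y)
  expect_identical(unname(unclass(two)), c(ref$a_aligned, ref$b_aligned))
  expect_error(progressive_align(c(only = x)), "at least 2")
})

test_that("planted families stay conserved through progressive alignment", {
  ds <- default_dataset()
  fam <- ds$truth$family_of
  prot <- sapply(ds$records[seq_along(ds$truth$planted_luxr_bgcs)],
                 function(r) r$genes[[1]]$translation)
  names(prot) <- names(fam)
  msa <- progressive_align(prot)
  m <- luxrbgc:::msa_matrix(msa)
  # expected column conservation for a family of size s mutated at rate
  # (1 - within)/2 from its founder is about (1 - (1-within)/2)^s, i.e.
  # 0.90-0.95 here; gap columns from the inter-family alignment lower it a
  # few points, so each family is checked against a small margin below that
  cons <- vapply(unique(fam), function(f) {
    rows <- m[fam[names(msa)] == f, , drop = FALSE]
    mean(apply(rows, 2, function(col) length(unique(col)) == 1L))
  }, 0)
  expect_true(all(cons > 0.85))
  expect_gte(mean(cons), 0.9)
})

test_that("complete deletion removes exactly the columns with gaps or X", {
  msa <- luxr_msa(c(a = "MK-AY", b = "MKTAY", c = "MKTAX"))
  out <- complete_deletion(msa)
  expect_identical(unname(unclass(out)), c("MKA", "MKA", "MKA"))
  clean <- luxr_msa(c(a = "MKAY", b = "MKTY"))
  expect_identical(unclass(complete_deletion(clean)), unclass(clean))
  allgap <- luxr_msa(c(a = "M-", b = "-M"))
  expect_error(complete_deletion(allgap), "no positions remain")
})

test_that("p-distance equals the brute-force mismatch proportion", {
  msa <- luxr_msa(c(a = "AAAA", b = "AAAT"))
  expect_equal(p_distance(msa)["a", "b"], 0.25)
  expect_equal(p_distance(luxr_msa(c(x = "MKTA", y = "MKTA")))["x", "y"], 0)
  expect_error(p_distance(luxr_msa(c(a = "M-", b = "MM"))), "gap-free")

  set.seed(8)
  rows <- setNames(replicate(6, random_aa(40)), letters[1:6])
  D <- p_distance(luxr_msa(rows))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(D[i, j], bf_p_distance(rows[[i]], rows[[j]]))
  }
  expect_identical(D, t(D))
})

test_that("neighbor joining recovers a known additive tree exactly", {
  # distances computed from ((A:1,B:2):1,(C:3,D:4))
  nm <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(nm, nm))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 6
  D["B", "C"] <- 6; D["B", "D"] <- 7; D["C", "D"] <- 7
  D <- D + t(D)
  tr <- neighbor_joining(D)
  expect_equal(ape::cophenetic.phylo(tr)[nm, nm], D, tolerance = 1e-9)
  truth <- ape::unroot(ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);"))
  expect_identical(ape::dist.topo(tr, truth)[1], 0)

  # 3 taxa: closed-form star limbs
  D3 <- D[1:3, 1:3]
  tr3 <- neighbor_joining(D3)
  expect_identical(tr3$Nnode, 1L)
  lens <- setNames(tr3$edge.length, tr3$tip.label[tr3$edge[, 2]])
  expect_equal(lens[["A"]], (3 + 5 - 6) / 2)
  expect_equal(lens[["B"]], (3 + 6 - 5) / 2)
  expect_equal(lens[["C"]], (5 + 6 - 3) / 2)

  asym <- D; asym[1, 2] <- 99
  expect_error(neighbor_joining(asym), "symmetric")
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining agrees with independent implementations", {
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    tr0 <- ape::rtree(n)
    D <- ape::cophenetic.phylo(tr0)
    mine <- neighbor_joining(D)
    ref <- ape::nj(D)
    expect_identical(ape::dist.topo(mine, ref)[1], 0)
    expect_equal(ape::cophenetic.phylo(mine)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
  }
  # on ultrametric distances the NJ topology matches UPGMA
  for (rep in 1:5) {
    tr0 <- ape::rcoal(7)
    D <- ape::cophenetic.phylo(tr0)
    mine <- neighbor_joining(D)
    upgma <- ape::as.phylo(hclust(as.dist(D), method = "average"))
    expect_identical(ape::dist.topo(mine, ape::unroot(upgma))[1], 0)
  }
})

test_that("bootstrap supports are seeded, bounded and family-resolving", {
  ds <- default_dataset()
  fam <- ds$truth$family_of
  prot <- sapply(ds$records[seq_along(ds$truth$planted_luxr_bgcs)],
                 function(r) r$genes[[1]]$translation)
  names(prot) <- names(fam)
  msa <- complete_deletion(progressive_align(prot))

  one <- bootstrap_support(msa, n_reps = 1, seed = 3)
  expect_true(all(one$supports %in% c(0, 100)))

  b1 <- bootstrap_support(msa, n_reps = 60, seed = 5)
  b2 <- bootstrap_support(msa, n_reps = 60, seed = 5)
  expect_identical(b1$supports, b2$supports)
  # row-order invariance
  b3 <- bootstrap_support(luxr_msa(unclass(msa)[rev(names(msa))]),
                          n_reps = 60, seed = 5)
  expect_identical(sort(b1$supports), sort(b3$supports))

  # clearly separated families: each family bipartition strongly supported
  canonical_key <- function(members, all_tips) {
    ref <- sort(all_tips)[1]
    side <- if (ref %in% members) setdiff(all_tips, members) else members
    paste(sort(side), collapse = "|")
  }
  for (f in unique(fam)) {
    members <- names(fam)[fam == f]
    if (length(members) < 2) next
    key <- canonical_key(members, names(msa))
    expect_true(key %in% names(b1$supports), label = paste("family", f))
    expect_gte(b1$supports[[key]], 95)
  }
})

test_that("outgroup rooting is a midpoint split that conserves lengths", {
  D3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  star <- neighbor_joining(D3)
  rooted <- root_with_outgroup(star, "C")
  expect_true(ape::is.rooted(rooted))
  # ((A,B),C) topology: the root splits C from the A+B clade
  kids <- rooted$edge[rooted$edge[, 1] == length(rooted$tip.label) + 1L, 2]
  expect_true(which(rooted$tip.label == "C") %in% kids)
  expect_equal(sum(rooted$edge.length), sum(star$edge.length))
  # pairwise path lengths unchanged
  expect_equal(ape::cophenetic.phylo(rooted)[c("A", "B", "C"), c("A", "B", "C")],
               ape::cophenetic.phylo(star)[c("A", "B", "C"), c("A", "B", "C")])
  # rooting then unrooting restores the original topology
  expect_identical(ape::dist.topo(ape::unroot(rooted), star)[1], 0)
  expect_error(root_with_outgroup(star, "Z"), "not a leaf")
})
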