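# Trunk/branch/private classification, Jaccard, Wagner parsimony, CCF,
# clonal architecture.

test_that("trunk/branch/private classification follows region counts", {
  m <- make_matrix(list(c(1, 1, 1), c(1, 1, 0), c(0, 0, 1)))
  lab <- classify_trunk_branch_private(m)
  expect_identical(lab$label, c("trunk", "branch", "private"))

  m2 <- make_matrix(c(rep(list(c(1, 1, 1)), 8), rep(list(c(1, 0, 0)), 2)))
  expect_equal(trunk_fraction(classify_trunk_branch_private(m2)), 0.8)

  single <- make_matrix(list(1, 1), regions = "R1")
  lab1 <- classify_trunk_branch_private(single)
  expect_true(all(lab1$label == "trunk"))
  expect_true(all(lab1$single_region_tumor))
})

test_that("mutational Jaccard index matches set arithmetic and is symmetric", {
  m <- make_matrix(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(mutational_jaccard(m)$mean_jaccard, 1)
  md <- make_matrix(list(c(1, 0), c(0, 1)))
  expect_equal(mutational_jaccard(md)$mean_jaccard, 0)
  # {a,b,c} vs {b,c,d} -> 2/4
  mh <- make_matrix(list(c(1, 0), c(1, 1), c(1, 1), c(0, 1)))
  expect_equal(mutational_jaccard(mh)$pairs$jaccard, 0.5)

  set.seed(1)
  for (i in 1:20) {
    mm <- make_matrix(lapply(1:15, function(j) rbinom(3, 1, 0.5)))
    mm <- mm[rowSums(mm) > 0, , drop = FALSE]
    if (nrow(mm) == 0) next
    ji <- mutational_jaccard(mm)$pairs
    expect_true(all(ji$jaccard >= 0 & ji$jaccard <= 1))
    # symmetry: recompute with columns permuted
    ji2 <- mutational_jaccard(mm[, c(2, 1, 3)])$pairs
    expect_setequal(round(ji$jaccard, 12), round(ji2$jaccard, 12))
  }
  expect_true(mutational_jaccard(make_matrix(list(1), "R1"))$flagged)
})

test_that("parsimony tree is exact on structured matrices", {
  # perfect phylogeny: every mutation changes exactly once
  m <- make_matrix(c(rep(list(c(1, 1, 1)), 5), rep(list(c(1, 0, 0)), 2),
                     rep(list(c(0, 1, 0)), 3)))
  tr <- build_parsimony_tree(m)
  expect_identical(tr$length, 10L)
  expect_identical(tr$trunk_count, 5)
  expect_equal(tr$trunk_count / tr$length,
               trunk_fraction(classify_trunk_branch_private(m)))

  # trunk-only: star with everything on the germline edge
  mt <- make_matrix(rep(list(c(1, 1, 1)), 7))
  trt <- build_parsimony_tree(mt)
  expect_identical(trt$length, 7L)
  expect_identical(trt$trunk_count, 7)

  expect_error(build_parsimony_tree(
    make_matrix(list(rep(1, 9)), regions = paste0("R", 1:9))), "8 regions")
})

test_that("parsimony length equals the brute-force minimum over topologies", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  for (rep in 1:40) {
    nr <- sample(2:4, 1)
    nm <- sample(3:12, 1)
    mm <- matrix(rbinom(nr * nm, 1, 0.5), nm, nr)
    mm <- mm[rowSums(mm) > 0, , drop = FALSE]
    if (!nrow(mm)) next
    colnames(mm) <- paste0("R", seq_len(nr))
    rownames(mm) <- paste0("m", seq_len(nrow(mm)))
    tr <- build_parsimony_tree(mm)

    dat <- rbind(t(mm), germline = 0)
    pd <- phangorn::phyDat(dat, type = "USER", levels = c(0, 1))
    topos <- phangorn::allTrees(nr + 1, rooted = FALSE,
                                tip.label = rownames(dat))
    oracle <- min(vapply(topos, function(tp) {
      phangorn::parsimony(tp, pd)
    }, numeric(1)))
    expect_identical(as.numeric(tr$length), oracle)
    # edge counts are a valid decomposition of the total
    expect_equal(sum(tr$edge_counts), tr$length)
    expect_true(all(tr$edge_counts >= 0))
  }
})

test_that("parsimony trees export as valid newick/phylo", {
  m <- make_matrix(list(c(1, 1, 1), c(1, 1, 0), c(0, 0, 1)))
  ph <- as_phylo(build_parsimony_tree(m))
  expect_s3_class(ph, "phylo")
  expect_setequal(ph$tip.label, colnames(m))
})

test_that("CCF follows the purity/copy-number adjustment and clamps", {
  expect_equal(estimate_ccf(0.5, 1, 2, 1)$ccf, 1)
  expect_equal(estimate_ccf(0.25, 0.5, 2, 1)$ccf, 1)
  expect_equal(estimate_ccf(0, 0.7)$ccf, 0)
  # raw value is retained before clamping
  e <- estimate_ccf(0.6, 1, 2, 1)
  expect_equal(e$ccf_raw, 1.2)
  expect_equal(e$ccf, 1)
  # multiplicity re-estimation under high VAF with extra copies
  e2 <- estimate_ccf(0.9, 1, 2, max_mult = 2)
  expect_equal(e2$multiplicity, 2)
  expect_error(estimate_ccf(0.5, 0), "purity")
})

test_that("clonal clustering separates planted populations", {
  arch1 <- cluster_clonal_architecture(rep(1, 10) + rnorm(10, 0, 0.005))
  expect_identical(arch1$k, 1L)
  expect_equal(arch1$clonal_fraction, 1)

  # two populations at CCF 1.0 and 0.4 under binomial noise at depth 180
  set.seed(31)
  alt <- c(rbinom(100, 180, 0.5 * 1.0 / 2), rbinom(50, 180, 0.5 * 0.4 / 2))
  ccf <- estimate_ccf(alt / 180, purity = 0.5)
  arch <- cluster_clonal_architecture(ccf$ccf_raw)
  expect_false(arch$fallback)
  expect_lt(abs(arch$clonal_fraction - 2 / 3), 0.05)

  small <- cluster_clonal_architecture(c(0.2, 0.9, 1.0))
  expect_true(small$fallback)
  expect_identical(small$k, 1L)
})

test_that("tumor-level merging pools read counts and evidence", {
  v <- make_variants(make_variant(region_id = "R1", t_depth = 100L,
                                  t_alt = 10L, lod = 40),
                     make_variant(region_id = "R2", t_depth = 50L,
                                  t_alt = 25L, lod = 30))
  mg <- merge_regions(v)
  expect_identical(nrow(mg), 1L)
  expect_identical(mg$t_depth, 150L)
  expect_identical(mg$t_alt, 35L)
  expect_equal(mg$t_vaf, 35 / 150)
  expect_equal(mg$lod, 70)
})
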