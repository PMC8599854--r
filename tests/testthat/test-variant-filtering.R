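# Region/tumor somatic filters, the LOD rescue rule, spectrum QC,
# cancer-gene classification, TMB.

test_that("region filters apply every rule with the documented strictness", {
  v <- make_variants(
    make_variant(pos = 1L),                                   # clean pass
    make_variant(pos = 2L, lod = 18),                         # LOD strict >
    make_variant(pos = 3L, lod = 18.0001),
    make_variant(pos = 4L, t_alt = 3L, t_vaf = 0.03),
    make_variant(pos = 5L, t_depth = 19L, t_alt = 4L, t_vaf = 0.21),
    make_variant(pos = 6L, n_depth = 9L),
    make_variant(pos = 7L, t_vaf = 0.019),
    make_variant(pos = 8L, n_vaf = 0.01),
    make_variant(pos = 9L, popfreq_exac = 0.01),
    make_variant(pos = 10L, popfreq_esp = NA_real_))          # NA freq = 0
  f <- apply_region_filters(v)
  expect_identical(f$pass,
                   c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                     FALSE, TRUE))
  expect_identical(f$fail_reasons[2], "lod")
  expect_identical(f$fail_reasons[4], "min_alt_reads")
  expect_identical(f$fail_reasons[5], "min_t_depth")
  expect_identical(f$fail_reasons[8], "max_n_vaf")
  expect_identical(f$fail_reasons[9], "max_popfreq")

  # multiple violations are all listed
  multi <- apply_region_filters(make_variant(lod = 5, t_alt = 2L,
                                             t_vaf = 0.02))
  expect_match(multi$fail_reasons, "min_alt_reads")
  expect_match(multi$fail_reasons, "lod")

  # tumor level swaps in the stricter LOD threshold
  t29 <- apply_region_filters(make_variant(lod = 29), level = "tumor")
  expect_false(t29$pass)
  t31 <- apply_region_filters(make_variant(lod = 31), level = "tumor")
  expect_true(t31$pass)
})

test_that("filtering an already-passing set is idempotent", {
  sim <- small_sim()
  f1 <- apply_region_filters(cohort_variants(sim$cohort))
  pass1 <- f1[f1$pass, names(f1) != "fail_reasons" & names(f1) != "pass"]
  f2 <- apply_region_filters(pass1)
  expect_true(all(f2$pass))
  expect_identical(pass1, f2[names(pass1)])
})

test_that("rescue admits only pure-LOD failures backed by another region", {
  v <- make_variants(
    make_variant(region_id = "A", lod = 10),                 # rescuable
    make_variant(region_id = "B", lod = 20),
    make_variant(pos = 2L, region_id = "A", lod = 10, t_depth = 15L,
                 t_alt = 4L, t_vaf = 0.27),                  # also depth
    make_variant(pos = 2L, region_id = "B", lod = 20),
    make_variant(pos = 3L, region_id = "A", lod = 10))       # single region
  f <- rescue_by_region(apply_region_filters(v))
  expect_true(f$pass[1] && f$rescued[1])
  expect_false(f$pass[3])
  expect_false(f$pass[5])

  # a supporter below LOD 18 does not rescue
  v2 <- make_variants(make_variant(region_id = "A", lod = 10),
                      make_variant(region_id = "B", lod = 17.9))
  f2 <- rescue_by_region(apply_region_filters(v2))
  expect_false(any(f2$pass))

  # support at exactly 18 counts (>= for the supporter, unlike the filter)
  v3 <- make_variants(make_variant(region_id = "A", lod = 10),
                      make_variant(region_id = "B", lod = 18.5))
  f3 <- rescue_by_region(apply_region_filters(v3))
  expect_true(f3$pass[f3$region_id == "A"])
})

test_that("rescue is monotone and never admits non-LOD failures", {
  sim <- small_sim()
  f <- apply_region_filters(cohort_variants(sim$cohort))
  r <- rescue_by_region(f)
  expect_true(all(which(f$pass) %in% which(r$pass)))
  newly <- r$rescued
  expect_true(all(f$fail_reasons[newly] == "lod"))
})

test_that("substitution spectrum collapses strands and sums to one", {
  v <- make_variants(
    make_variant(pos = 1L, ref = "C", alt = "T"),
    make_variant(pos = 2L, ref = "G", alt = "A"),   # collapses to C>T
    make_variant(pos = 3L, ref = "G", alt = "T"),   # collapses to C>A
    make_variant(pos = 4L, ref = "AC", alt = "A"))  # indel: excluded
  sp <- substitution_spectrum(v)
  hi <- sp[sp$stratum == "high_lod", ]
  expect_equal(sum(hi$proportion), 1)
  expect_equal(hi$proportion[hi$class == "C>T"], 2 / 3)
  expect_equal(hi$proportion[hi$class == "C>A"], 1 / 3)
})

test_that("FFPE-style noise inflates C>T specifically in the low-LOD stratum", {
  sim <- simulate_cohort(simulation_config(n_patients = 3,
                                           ffpe_artifact_rate = 0.4,
                                           seed = 21))
  sp <- substitution_spectrum(cohort_variants(sim$cohort),
                              by = character())
  low_ct <- sp$proportion[sp$stratum == "low_lod" & sp$class == "C>T"]
  high_ct <- sp$proportion[sp$stratum == "high_lod" & sp$class == "C>T"]
  expect_gt(low_ct, high_ct)
})

test_that("cancer-gene classification follows hotspot/TSG/CADD rules", {
  v <- make_variants(
    make_variant(pos = 1L, gene = "RB1", func_class = "stopgain",
                 cadd = NA_real_),
    make_variant(pos = 2L, gene = "GENE0002", cadd = 21),
    make_variant(pos = 3L, gene = "GENE0002", cadd = 15),
    make_variant(pos = 4L, gene = "GENE0002", cadd = NA_real_),
    make_variant(pos = 5L, gene = "RB1", func_class = "nonsynonymous",
                 cadd = 5))
  cg <- classify_cancer_gene_alterations(v)
  expect_identical(cg$cancer_gene_alteration,
                   c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(cg$alteration_basis[1:2], c("tsg_truncation", "cadd"))

  hot <- default_hotspots()
  vh <- make_variant(gene = hot$gene[1], pos = hot$pos[1], cadd = 1)
  expect_identical(classify_cancer_gene_alterations(vh)$alteration_basis,
                   "hotspot")
})

test_that("TMB counts nonsilent mutations per megabase", {
  v <- dplyr::bind_rows(lapply(1:94, function(i) {
    make_variant(pos = i,
                 func_class = c("nonsynonymous", "frameshift", "stopgain",
                                "stoploss")[1 + i %% 4])
  }))
  tm <- compute_tmb(v, capture_mb = 20)
  expect_equal(tm$tmb[!is.na(tm$region_id) & tm$region_id == "R1"], 4.70)

  syn <- make_variant(func_class = "synonymous")
  tm0 <- compute_tmb(syn, capture_mb = 20)
  expect_identical(tm0$n_nonsilent, c(0L, 0L))
  expect_identical(tm0$tmb, c(0, 0))
  # tumor-level row is the per-patient union
  expect_equal(tm$tmb[is.na(tm$region_id)], 4.70)
  expect_error(compute_tmb(v, capture_mb = 0), "capture_mb")
})
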