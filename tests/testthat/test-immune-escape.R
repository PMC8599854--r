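# Neoantigen binders, ITH inheritance, LOH enrichment, IFN-gamma loss,
# HLA-LOH calling, lost-allele binding.

neo <- function(pos, ic50, allele = "A*01:01", gene = "G1") {
  tibble::tibble(patient_id = "P01", chrom = "1", pos = pos, ref = "C",
                 alt = "A", gene = gene,
                 peptide = "AAAAAAAAA", allele = allele, ic50_nM = ic50)
}

test_that("the 500 nM binder threshold is strict", {
  calls <- dplyr::bind_rows(neo(1L, 499), neo(2L, 500), neo(3L, 500.0001))
  kept <- filter_neoantigen_binders(calls)
  expect_identical(kept$pos, 1L)
  expect_identical(nrow(filter_neoantigen_binders(calls[0, ])), 0L)
})

test_that("neoantigens inherit mutation labels for the ITH summary", {
  labels <- tibble::tibble(mutation = c("1:1:C:A", "1:2:C:A", "1:3:C:A"),
                           label = c("trunk", "trunk", "private"))
  binders <- dplyr::bind_rows(neo(1L, 100), neo(2L, 100), neo(3L, 100),
                              neo(3L, 200, allele = "B*07:02"))
  s <- neoantigen_ith_summary(binders, labels)
  expect_identical(s$n_binders, 4L)
  expect_identical(s$n_neo_mutations, 3L)
  expect_equal(s$trunk_fraction, 2 / 3)

  clonal <- tibble::tibble(mutation = labels$mutation,
                           clonal = c(TRUE, TRUE, FALSE))
  s2 <- neoantigen_ith_summary(binders, labels, clonal)
  expect_equal(s2$clonal_fraction, 2 / 3)

  expect_error(neoantigen_ith_summary(dplyr::bind_rows(neo(99L, 100)),
                                      labels), "99")
  s0 <- neoantigen_ith_summary(binders[0, ], labels)
  expect_identical(s0$n_binders, 0L)
  expect_true(is.na(s0$trunk_fraction))
})

test_that("LOH enrichment compares neoantigen genes against other genes", {
  loh <- tibble::tibble(patient_id = "P01", region_id = "R1",
                        gene = sprintf("N%02d", 1:4),
                        loh_class = "CNN_LOH")
  mutated <- tibble::tibble(patient_id = "P01", region_id = "R1",
                            gene = c(sprintf("N%02d", 1:20),
                                     sprintf("M%02d", 1:10)))
  neo_genes <- tibble::tibble(patient_id = "P01",
                              gene = sprintf("N%02d", 1:20))
  out <- loh_enrichment_comparison(loh, mutated, neo_genes)
  cnn <- out$per_sample[out$per_sample$loh_class == "CNN_LOH", ]
  expect_equal(cnn$frac_neo, 0.20)
  expect_equal(cnn$frac_other, 0)

  # identical LOH fractions in both gene classes across samples -> p = 1
  mk_loh <- function(p) {
    tibble::tibble(patient_id = p, region_id = "R1",
                   gene = c(sprintf("N%02d", 1:4), sprintf("M%02d", 1:2)),
                   loh_class = "CNN_LOH")
  }
  loh2 <- dplyr::bind_rows(lapply(c("P01", "P02", "P03"), mk_loh))
  mut2 <- dplyr::bind_rows(lapply(c("P01", "P02", "P03"), function(p) {
    dplyr::mutate(mutated, patient_id = p)
  }))
  neo2 <- dplyr::bind_rows(lapply(c("P01", "P02", "P03"), function(p) {
    dplyr::mutate(neo_genes, patient_id = p)
  }))
  out2 <- loh_enrichment_comparison(loh2, mut2, neo2)
  ps2 <- out2$per_sample[out2$per_sample$loh_class == "CNN_LOH", ]
  expect_equal(ps2$frac_neo, ps2$frac_other)   # 4/20 vs 2/10
  expect_equal(
    out2$tests$p_value[out2$tests$loh_class == "CNN_LOH"], 1)
})

test_that("planted CNN-LOH bias in neoantigen genes is detected", {
  set.seed(77)
  hits <- vapply(1:20, function(r) {
    samples <- sprintf("S%02d", 1:20)
    tabs <- lapply(samples, function(s) {
      neo_g <- sprintf("N%02d", 1:25)
      other_g <- sprintf("M%02d", 1:25)
      # CNN-LOH planted twice as often in neoantigen-associated genes
      loh_g <- c(neo_g[runif(25) < 0.30], other_g[runif(25) < 0.15])
      list(loh = tibble::tibble(patient_id = s, region_id = "R1",
                                gene = loh_g, loh_class = "CNN_LOH"),
           mut = tibble::tibble(patient_id = s, region_id = "R1",
                                gene = c(neo_g, other_g)),
           neo = tibble::tibble(patient_id = s, gene = neo_g))
    })
    out <- loh_enrichment_comparison(
      dplyr::bind_rows(lapply(tabs, `[[`, "loh")),
      dplyr::bind_rows(lapply(tabs, `[[`, "mut")),
      dplyr::bind_rows(lapply(tabs, `[[`, "neo")))
    p <- out$tests$p_value[out$tests$loh_class == "CNN_LOH"]
    isTRUE(p < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("IFN-gamma loss burden correlates with planted CNA burden", {
  calls <- dplyr::bind_rows(lapply(1:8, function(i) {
    n_loss <- i            # loss count proportional to burden
    tibble::tibble(patient_id = sprintf("P%02d", i), region_id = "R1",
                   gene = c(default_ifng_genes()[seq_len(min(n_loss, 8))],
                            sprintf("F%02d", seq_len(2 * i))),
                   mean_log2 = -0.9,
                   state = "loss")
  }))
  out <- ifng_loss_burden(calls)
  expect_equal(out$correlation$rho, 1)

  none <- dplyr::mutate(calls, state = "neutral")
  out0 <- ifng_loss_burden(none)
  expect_true(all(out0$per_sample$ifng_loss == 0))
  expect_true(is.na(out0$correlation$rho))
  expect_error(ifng_loss_burden(calls, ifng_genes = character()), "nonempty")
})

test_that("HLA-LOH calls require both the copy and the imbalance condition", {
  bins <- function(a1, a2, region = "R1", n = 10) {
    tibble::tibble(region_id = region,
                   allele = rep(c("A*01:01", "A*02:01"), each = n),
                   bin = rep(seq_len(n), 2), cn = c(a1, a2))
  }
  lost <- call_hla_loh(bins(rep(0.1, 10), rep(1.9, 10)))
  expect_true(lost$calls$lost[lost$calls$allele == "A*01:01"])
  expect_false(lost$calls$lost[lost$calls$allele == "A*02:01"])
  expect_true(lost$trunk_hla_loh)

  balanced <- call_hla_loh(bins(rep(1, 10), rep(1, 10)))
  expect_false(any(balanced$calls$lost))

  # median below 0.5 but no significant imbalance -> not lost
  set.seed(4)
  noisy <- call_hla_loh(bins(rnorm(10, 0.45, 0.6), rnorm(10, 0.65, 0.6)))
  expect_false(any(noisy$calls$lost &
                     noisy$calls$p_value > 0.01))

  # boundary: median exactly 0.5 is not lost
  half <- call_hla_loh(bins(rep(0.5, 10), rep(1.9, 10)))
  expect_false(any(half$calls$lost))

  few <- call_hla_loh(bins(rep(0.1, 3), rep(1.9, 3), n = 3))
  expect_true(all(few$calls$low_confidence))
})

test_that("lost-allele binding fraction is computed per LOH sample only", {
  calls <- tibble::tibble(region_id = c("R1", "R1", "R2", "R2"),
                          allele = rep(c("A*01:01", "A*02:01"), 2),
                          median_allele_cn = c(0.1, 1.9, 1, 1),
                          p_value = c(1e-4, 1e-4, 0.5, 0.5),
                          lost = c(TRUE, FALSE, FALSE, FALSE),
                          low_confidence = FALSE)
  binders <- dplyr::bind_rows(
    lapply(1:10, function(i) {
      neo(i, 100, allele = if (i <= 5) "A*01:01" else "A*02:01")
    }))
  out <- lost_allele_binding_fraction(binders, calls)
  expect_identical(out$region_id, "R1")
  expect_equal(out$fraction, 0.5)

  all_lost <- dplyr::mutate(binders, allele = "A*01:01")
  expect_equal(lost_allele_binding_fraction(all_lost, calls)$fraction, 1)
  none_lost <- dplyr::mutate(binders, allele = "A*02:01")
  expect_equal(lost_allele_binding_fraction(none_lost, calls)$fraction, 0)
})
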