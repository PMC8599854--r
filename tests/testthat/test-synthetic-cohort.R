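# Generator: determinism, ground-truth consistency, repertoire and survival
# models.

test_that("simulation is deterministic given the seed", {
  cfg <- simulation_config(n_patients = 2, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(cohort_variants(a$cohort), cohort_variants(b$cohort))
  expect_identical(a$cohort$bundles$P01$repertoires[["R1"]]$clones,
                   b$cohort$bundles$P01$repertoires[["R1"]]$clones)
  expect_identical(cohort_clinical(a$cohort), cohort_clinical(b$cohort))
  expect_identical(a$truth$mutations, b$truth$mutations)
})

test_that("trunk_fraction = 1 puts every mutation in all regions", {
  sim <- simulate_cohort(simulation_config(
    n_patients = 2, trunk_fraction = 1, ffpe_artifact_rate = 0, seed = 5))
  for (b in sim$cohort$bundles) {
    counts <- table(mutation_key(b$variants))
    expect_true(all(counts == length(b$regions)))
  }
})

test_that("infeasible and invalid configurations are rejected", {
  expect_error(simulation_config(n_patients = 2, region_counts = 1,
                                 trunk_fraction = 0.5), "infeasible")
  expect_error(simulation_config(trunk_fraction = 1.5))
  expect_error(simulation_config(clone_size_alpha = 0))
  expect_error(simulation_config(censoring_rate = -0.1), "censoring")
  bad_mix <- default_trunk_mix() * 2
  expect_error(simulation_config(trunk_signature_mix = bad_mix))
})

test_that("repertoire sharing controls the pairwise Jaccard index", {
  cfg1 <- simulation_config(n_patients = 1, shared_clone_fraction = 1,
                            repertoire_size = 100, seed = 3)
  set.seed(3)
  pool <- replicate(100, paste(sample(c("A", "C", "G", "T"), 30,
                                      replace = TRUE), collapse = ""))
  r1 <- simulate_repertoire(cfg1, list(patient_id = "P", region_id = "R1",
                                       shared_pool = pool))
  r2 <- simulate_repertoire(cfg1, list(patient_id = "P", region_id = "R2",
                                       shared_pool = pool))
  # identical pools: all observed clones come from the same 100 sequences
  expect_true(all(r1$clones$rearrangement %in% pool))
  expect_gt(overlap_metrics(r1, r2)$jaccard, 0.5)

  cfg0 <- simulation_config(n_patients = 1, shared_clone_fraction = 0,
                            repertoire_size = 100, seed = 3)
  u1 <- simulate_repertoire(cfg0, list(patient_id = "P", region_id = "R1",
                                       shared_pool = character()))
  u2 <- simulate_repertoire(cfg0, list(patient_id = "P", region_id = "R2",
                                       shared_pool = character()))
  expect_identical(overlap_metrics(u1, u2)$jaccard, 0)
})

test_that("steeper clone-size exponents give strictly higher clonality", {
  cfg <- simulation_config(n_patients = 1, seed = 8)
  set.seed(8)
  even <- simulate_repertoire(cfg, list(patient_id = "P", region_id = "R1",
                                        shared_pool = character(),
                                        alpha = 0.2,
                                        total_templates = 5000))
  set.seed(8)
  skew <- simulate_repertoire(cfg, list(patient_id = "P", region_id = "R1",
                                        shared_pool = character(),
                                        alpha = 2.0,
                                        total_templates = 5000))
  expect_gt(repertoire_metrics(skew)$clonality,
            repertoire_metrics(even)$clonality)
  expect_error(simulate_repertoire(cfg, list(patient_id = "P",
                                             region_id = "R1",
                                             shared_pool = character(),
                                             alpha = -1)), "alpha")
})

test_that("survival generator honors censoring and recovers planted hazards", {
  covs <- tibble::tibble(patient_id = sprintf("S%03d", 1:200),
                         cna_burden = rnorm(200))
  all_cens <- simulate_survival(covs, c(cna_burden = 0.5),
                                censoring_rate = 1, seed = 1)
  expect_true(all(all_cens$os_event == 0))
  expect_error(simulate_survival(covs, c(cna_burden = 0.5),
                                 censoring_rate = -1), "censoring_rate")
  expect_error(simulate_survival(covs, c(missing_cov = 1), 0.3, seed = 1),
               "missing_cov")

  # positive planted log-hazard on CNA burden gives HR > 1 in most fits
  hits <- vapply(1:20, function(r) {
    clin <- simulate_survival(covs, c(cna_burden = 0.5),
                              censoring_rate = 0.2, seed = 1000 + r)
    fit <- cox_univariate(
      tibble::tibble(patient = clin$patient_id, time = clin$os_months,
                     event = clin$os_event),
      setNames(covs$cna_burden, covs$patient_id))
    fit$hr > 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("no-noise mode reproduces ground truth through the pipeline", {
  sim <- simulate_cohort(simulation_config(
    n_patients = 3, noise = FALSE, seed = 17))
  co <- sim$cohort
  filt <- rescue_by_region(apply_region_filters(cohort_variants(co)))
  expect_true(all(filt$pass))

  for (b in co$bundles) {
    truth <- sim$truth$mutations[sim$truth$mutations$patient_id ==
                                   b$patient_id, ]
    m <- mutation_matrix(filt[filt$pass & filt$patient_id == b$patient_id, ],
                         regions = b$regions)
    lab <- classify_trunk_branch_private(m)
    want <- truth$compartment[match(lab$mutation, truth$mutation)]
    if (length(b$regions) == 1) {
      expect_true(all(lab$label == "trunk"))
    } else {
      expect_identical(lab$label, want)
    }

    # planted CNA / LOH events recovered exactly where present
    calls <- gene_level_cna(b$segments)
    loh <- classify_gene_loh(b$segments)
    tcna <- sim$truth$cna_events[sim$truth$cna_events$patient_id ==
                                   b$patient_id, ]
    for (i in seq_len(nrow(tcna))) {
      regs <- strsplit(tcna$regions[i], ",")[[1]]
      got <- calls[calls$gene == tcna$gene[i] & calls$region_id %in% regs, ]
      if (tcna$state[i] != "neutral") {
        expect_true(all(got$state == tcna$state[i]))
      }
      gloh <- loh[loh$gene == tcna$gene[i] & loh$region_id %in% regs, ]
      if (tcna$loh_class[i] != "none") {
        expect_true(all(gloh$loh_class == tcna$loh_class[i]))
      }
    }

    # planted HLA LOH recovered exactly
    th <- sim$truth$hla_loh[sim$truth$hla_loh$patient_id == b$patient_id, ]
    res <- call_hla_loh(b$hla_allele_cn)
    if (th$has_loh) {
      regs <- strsplit(th$regions, ",")[[1]]
      lost <- res$calls[res$calls$lost, ]
      expect_setequal(unique(lost$allele), th$lost_allele)
      expect_setequal(lost$region_id, regs)
    } else {
      expect_false(any(res$calls$lost))
    }
  }
})
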