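# End-to-end orchestration: run every analysis stage over a cohort and
# collect flat result tables suitable for write_results().

#' Run the full ITH analysis pipeline over a cohort
#'
#' Applies variant QC with rescue, trunk/branch/private classification,
#' parsimony trees, mutational and CNA Jaccard indices, tumor-level clonal
#' architecture, gene-level CNA/LOH with IFN-gamma and HLA immune-escape
#' summaries, TCR repertoire metrics and overlap, signature refitting with
#' the trunk-versus-nontrunk contrast, and survival fits for TMB and CNA
#' burden. Deterministic for a given cohort.
#'
#' @param cohort An `ith_cohort`.
#' @param thresholds A [filter_thresholds()].
#' @param capture_mb Exome footprint in Mb for TMB.
#' @param genes Gene model tibble.
#' @return Named list of result tibbles (ready for [write_results()]).
#' @export
run_ith_pipeline <- function(cohort, thresholds = filter_thresholds(),
                             capture_mb = 30, genes = default_gene_model()) {
  vars <- cohort_variants(cohort)
  filtered <- rescue_by_region(
    apply_region_filters(vars, thresholds, level = "region"))
  passing <- filtered[filtered$pass, ]

  per_tumor <- lapply(cohort$bundles, function(b) {
    pv <- passing[passing$patient_id == b$patient_id, ]
    if (!nrow(pv)) return(NULL)
    m <- mutation_matrix(pv, regions = b$regions)
    labels <- classify_trunk_branch_private(m)
    tree <- build_parsimony_tree(m)
    ji <- mutational_jaccard(m)

    merged <- merge_regions(pv)
    tl <- rescue_by_region(
      apply_region_filters(merged, thresholds, level = "tumor"),
      support = pv, support_lod = 18)
    tl_pass <- tl[tl$pass, ]
    mean_purity <- mean(b$samples$purity, na.rm = TRUE)
    arch <- NULL
    if (nrow(tl_pass) && is.finite(mean_purity)) {
      ccf <- estimate_ccf(tl_pass$t_vaf, mean_purity)
      arch <- cluster_clonal_architecture(ccf$ccf_raw)
      arch_tbl <- dplyr::mutate(arch$assignments,
                                mutation = mutation_key(tl_pass))
    } else arch_tbl <- NULL
    list(patient_id = b$patient_id, labels = labels, tree = tree, ji = ji,
         arch = arch, arch_tbl = arch_tbl)
  })
  per_tumor <- Filter(Negate(is.null), per_tumor)

  labels_tbl <- purrr::map_dfr(per_tumor, function(x) {
    dplyr::mutate(x$labels, patient_id = x$patient_id, .before = 1)
  })
  trees_tbl <- purrr::map_dfr(per_tumor, function(x) {
    tibble::tibble(patient_id = x$patient_id, newick = x$tree$newick,
                   length = x$tree$length, trunk_count = x$tree$trunk_count)
  })
  ji_tbl <- purrr::map_dfr(per_tumor, function(x) {
    if (!nrow(x$ji$pairs)) return(NULL)
    dplyr::mutate(x$ji$pairs, patient_id = x$patient_id, .before = 1)
  })
  arch_tbl <- purrr::map_dfr(per_tumor, function(x) {
    if (is.null(x$arch_tbl)) return(NULL)
    dplyr::mutate(x$arch_tbl, patient_id = x$patient_id, .before = 1)
  })

  segs <- dplyr::bind_rows(lapply(cohort$bundles, `[[`, "segments"))
  cna_calls <- gene_level_cna(segs, genes)
  burden <- cna_burden(cna_calls)
  cna_ji <- purrr::map_dfr(cohort$bundles, function(b) {
    cj <- cna_jaccard(cna_calls[cna_calls$patient_id == b$patient_id, ])
    if (!nrow(cj$pairs)) return(NULL)
    dplyr::mutate(cj$pairs, patient_id = b$patient_id, .before = 1)
  })
  loh_calls <- classify_gene_loh(segs, genes)
  ifng <- ifng_loss_burden(cna_calls)

  hla_tbl <- purrr::map_dfr(cohort$bundles, function(b) {
    if (!nrow(b$hla_allele_cn)) return(NULL)
    res <- call_hla_loh(b$hla_allele_cn)
    dplyr::mutate(res$calls, patient_id = b$patient_id, .before = 1)
  })

  tcr_metrics <- purrr::map_dfr(cohort$bundles, function(b) {
    purrr::map_dfr(b$repertoires, repertoire_metrics)
  })
  tcr_overlap <- purrr::map_dfr(cohort$bundles, function(b) {
    reps <- Filter(function(tb) tb$region_id != adjacent_lung_region(),
                   b$repertoires)
    if (length(reps) < 2) return(NULL)
    cmb <- utils::combn(length(reps), 2)
    purrr::map_dfr(seq_len(ncol(cmb)), function(q) {
      overlap_metrics(reps[[cmb[1, q]]], reps[[cmb[2, q]]])
    })
  })
  tcr_sharing <- purrr::map_dfr(cohort$bundles, function(b) {
    reps <- Filter(function(tb) tb$region_id != adjacent_lung_region(),
                   b$repertoires)
    if (length(reps) < 2) return(NULL)
    dplyr::mutate(sharing_classes(reps), patient_id = b$patient_id,
                  .before = 1)
  })

  exposures <- purrr::map_dfr(per_tumor, function(x) {
    pv <- passing[passing$patient_id == x$patient_id, ]
    cats <- build_catalog(pv, x$labels)$catalogs
    purrr::map_dfr(names(cats), function(nm) {
      if (sum(cats[[nm]]) < 1) return(NULL)
      fit <- fit_signatures(cats[[nm]])
      parts <- strsplit(nm, "/")[[1]]
      dplyr::mutate(tidy(fit), patient_id = parts[1],
                    compartment = parts[2], .before = 1)
    })
  })

  clin <- cohort_clinical(cohort)
  survival_tbl <- NULL
  if (!is.null(clin) && nrow(clin) >= 10 && sum(clin$os_event) >= 5) {
    records <- tibble::tibble(patient = clin$patient_id,
                              time = clin$os_months, event = clin$os_event)
    covs <- cohort_covariates(cohort, capture_mb)
    covs <- covs[match(clin$patient_id, covs$patient_id), ]
    survival_tbl <- purrr::map_dfr(c("tmb", "cna_burden"), function(cv) {
      x <- covs[[cv]]
      fit <- tryCatch(cox_univariate(records, x), error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      dplyr::mutate(tidy(fit), term = cv)
    })
  }

  res <- list(
    qc = dplyr::count(filtered, .data$patient_id, .data$region_id,
                      .data$pass, .data$rescued),
    tmb = compute_tmb(passing, capture_mb),
    trunk_labels = labels_tbl,
    trees = trees_tbl,
    mutational_jaccard = ji_tbl,
    clonal_architecture = arch_tbl,
    cna_burden_region = burden$per_region,
    cna_burden_tumor = burden$per_tumor,
    cna_jaccard = cna_ji,
    loh_calls = loh_calls[loh_calls$loh_class != "none", ],
    ifng_loss = ifng$per_sample,
    hla_loh = hla_tbl,
    tcr_metrics = tcr_metrics,
    tcr_overlap = tcr_overlap,
    tcr_sharing = tcr_sharing,
    signature_exposures = exposures)
  if (!is.null(survival_tbl) && nrow(survival_tbl)) {
    res$survival <- survival_tbl
  }
  res
}
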