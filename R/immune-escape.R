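# Neoantigen and immune-escape summaries: binder filtering, neoantigen ITH,
# LOH enrichment in neoantigen-associated genes, IFN-gamma pathway loss
# burden, a simplified HLA-LOH caller on binned allele-specific copy
# estimates, and the lost-allele binding fraction.

#' Filter predicted neoantigens to HLA binders
#'
#' A candidate peptide is an HLA binder iff its predicted IC50 is strictly
#' below 500 nM.
#'
#' @param calls Neoantigen tibble with an `ic50_nM` column.
#' @param ic50_cut Strict threshold in nM (default 500).
#' @return The binder subset of `calls`.
#' @export
filter_neoantigen_binders <- function(calls, ic50_cut = 500) {
  calls[!is.na(calls$ic50_nM) & calls$ic50_nM < ic50_cut, ]
}

#' Neoantigen ITH summary
#'
#' Each binder inherits the trunk/branch/private (and, when available,
#' clonal/subclonal) label of its underlying mutation; fractions are computed
#' over the distinct neoantigen-bearing mutations of the tumor.
#'
#' @param binders Binder tibble for one patient (see
#'   [filter_neoantigen_binders()]).
#' @param labels Output of [classify_trunk_branch_private()] for the same
#'   tumor.
#' @param clonal Optional tibble `mutation`, `clonal` (logical) from the
#'   clonal-architecture step.
#' @return Tibble with `n_binders`, `n_neo_mutations`, `trunk_fraction`,
#'   and `clonal_fraction` (`NA` when clonal labels are absent); fractions
#'   are `NA` when there are no binders.
#' @export
neoantigen_ith_summary <- function(binders, labels, clonal = NULL) {
  if (!nrow(binders)) {
    return(tibble::tibble(n_binders = 0L, n_neo_mutations = 0L,
                          trunk_fraction = NA_real_,
                          clonal_fraction = NA_real_))
  }
  key <- mutation_key(binders)
  unknown <- setdiff(key, labels$mutation)
  if (length(unknown)) {
    stop("binder references unlabeled mutation(s): ",
         paste(unique(unknown), collapse = "; "), call. = FALSE)
  }
  muts <- unique(key)
  lab <- labels$label[match(muts, labels$mutation)]
  clonal_fraction <- NA_real_
  if (!is.null(clonal)) {
    cl <- clonal$clonal[match(muts, clonal$mutation)]
    if (any(!is.na(cl))) clonal_fraction <- mean(cl, na.rm = TRUE)
  }
  tibble::tibble(n_binders = nrow(binders), n_neo_mutations = length(muts),
                 trunk_fraction = mean(lab == "trunk"),
                 clonal_fraction = clonal_fraction)
}

#' LOH enrichment in neoantigen-associated genes
#'
#' Per sample and LOH class, the fraction of neoantigen-associated genes
#' (genes carrying at least one binder-generating mutation) with that LOH
#' class, versus the same fraction among mutated genes not associated with
#' neoantigens; compared across samples with a two-sided paired Wilcoxon
#' signed-rank test.
#'
#' @param loh_calls Combined output of [classify_gene_loh()] across samples
#'   (`patient_id`, `region_id`, `gene`, `loh_class`).
#' @param mutated_genes Tibble `patient_id`, `region_id`, `gene` of mutated
#'   genes per sample.
#' @param neoantigen_genes Tibble `patient_id`, `gene` of neoantigen-
#'   associated genes per patient.
#' @return List with `per_sample` (tibble `patient_id`, `region_id`,
#'   `loh_class`, `frac_neo`, `frac_other`) and `tests` (tibble `loh_class`,
#'   `statistic`, `p_value`, `n_pairs`).
#' @export
loh_enrichment_comparison <- function(loh_calls, mutated_genes,
                                      neoantigen_genes) {
  per_sample <- loh_calls |>
    dplyr::distinct(.data$patient_id, .data$region_id) |>
    tidyr::crossing(loh_class = c("CNN_LOH", "CNL_LOH")) |>
    dplyr::rowwise() |>
    dplyr::mutate(res = list({
      neo <- neoantigen_genes$gene[
        neoantigen_genes$patient_id == .data$patient_id]
      mut <- mutated_genes$gene[
        mutated_genes$patient_id == .data$patient_id &
          mutated_genes$region_id == .data$region_id]
      other <- setdiff(mut, neo)
      loh <- loh_calls[loh_calls$patient_id == .data$patient_id &
                         loh_calls$region_id == .data$region_id &
                         loh_calls$loh_class == .data$loh_class, ]
      tibble::tibble(
        frac_neo = if (length(neo)) mean(neo %in% loh$gene) else NA_real_,
        frac_other = if (length(other)) mean(other %in% loh$gene)
                     else NA_real_)
    })) |>
    dplyr::ungroup() |>
    tidyr::unnest("res")
  tests <- per_sample |>
    dplyr::group_by(.data$loh_class) |>
    dplyr::reframe({
      ok <- !is.na(.data$frac_neo) & !is.na(.data$frac_other)
      x <- .data$frac_neo[ok]
      y <- .data$frac_other[ok]
      if (sum(ok) < 3 || all(x == y)) {
        tibble::tibble(statistic = NA_real_,
                       p_value = if (sum(ok) >= 1 && all(x == y)) 1
                                 else NA_real_,
                       n_pairs = sum(ok))
      } else {
        w <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
        tibble::tibble(statistic = unname(w$statistic),
                       p_value = w$p.value, n_pairs = sum(ok))
      }
    })
  list(per_sample = per_sample, tests = tests)
}

#' IFN-gamma pathway copy-number-loss burden
#'
#' Per sample, the number of IFN-gamma pathway genes with a copy-number-loss
#' call, and the Spearman correlation of that count with the sample's total
#' CNA burden across the cohort.
#'
#' @param calls Output of [gene_level_cna()] across samples.
#' @param ifng_genes Pathway gene set; defaults to [default_ifng_genes()].
#' @return List with `per_sample` (tibble `patient_id`, `region_id`,
#'   `ifng_loss`, `cna_burden`) and `correlation` (tibble `rho`, `p_value`;
#'   `NA`-flagged when undefined).
#' @export
ifng_loss_burden <- function(calls, ifng_genes = default_ifng_genes()) {
  if (!length(ifng_genes)) stop("ifng_genes must be nonempty", call. = FALSE)
  burden <- cna_burden(calls)$per_region
  losses <- calls |>
    dplyr::filter(.data$state == "loss", .data$gene %in% ifng_genes) |>
    dplyr::count(.data$patient_id, .data$region_id, name = "ifng_loss")
  per_sample <- burden |>
    dplyr::left_join(losses, by = c("patient_id", "region_id")) |>
    dplyr::mutate(ifng_loss = dplyr::coalesce(.data$ifng_loss, 0L)) |>
    dplyr::rename(cna_burden = "burden") |>
    dplyr::select("patient_id", "region_id", "ifng_loss", "cna_burden")
  correlation <- if (nrow(per_sample) >= 4 &&
                     stats::sd(per_sample$ifng_loss) > 0 &&
                     stats::sd(per_sample$cna_burden) > 0) {
    ct <- suppressWarnings(
      stats::cor.test(per_sample$ifng_loss, per_sample$cna_burden,
                      method = "spearman", alternative = "two.sided"))
    tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value)
  } else {
    tibble::tibble(rho = NA_real_, p_value = NA_real_)
  }
  list(per_sample = per_sample, correlation = correlation)
}

#' Call HLA loss of heterozygosity from binned allele copy estimates
#'
#' For each (region, HLA gene): the two alleles' binned copy estimates are
#' summarized by their medians and compared with a two-sided rank-sum test;
#' an allele is lost iff its median copy number is strictly below 0.5 and the
#' allelic-imbalance p-value is below 0.01. A tumor is trunk-HLA-LOH iff some
#' allele is lost in every region. Calls from fewer than 5 bins per allele
#' are flagged low-confidence.
#'
#' @param hla_allele_cn Tibble `region_id`, `allele`, `bin`, `cn` for one
#'   patient; allele names must pair by HLA gene (prefix before `"*"`).
#' @param cn_cut Strict median-copy threshold (default 0.5).
#' @param p_cut Imbalance p-value threshold (default 0.01).
#' @return List with `calls` (tibble `region_id`, `allele`,
#'   `median_allele_cn`, `p_value`, `lost`, `low_confidence`) and
#'   `trunk_hla_loh` (logical: some allele lost in all regions).
#' @export
call_hla_loh <- function(hla_allele_cn, cn_cut = 0.5, p_cut = 0.01) {
  x <- dplyr::mutate(hla_allele_cn,
                     hla_gene = sub("\\*.*$", "", .data$allele))
  calls <- x |>
    dplyr::group_by(.data$region_id, .data$hla_gene) |>
    dplyr::group_modify(function(d, key) {
      alleles <- unique(d$allele)
      purrr::map_dfr(alleles, function(a) {
        own <- d$cn[d$allele == a]
        hom <- d$cn[d$allele != a]
        p <- if (length(hom) && stats::sd(c(own, hom)) > 0) {
          suppressWarnings(stats::wilcox.test(own, hom)$p.value)
        } else if (length(hom)) 1 else NA_real_
        tibble::tibble(allele = a,
                       median_allele_cn = stats::median(own),
                       p_value = p,
                       low_confidence = length(own) < 5)
      })
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(lost = .data$median_allele_cn < cn_cut &
                    !is.na(.data$p_value) & .data$p_value < p_cut) |>
    dplyr::select("region_id", "allele", "median_allele_cn", "p_value",
                  "lost", "low_confidence")
  regions <- unique(hla_allele_cn$region_id)
  lost_everywhere <- calls |>
    dplyr::filter(.data$lost) |>
    dplyr::distinct(.data$allele, .data$region_id) |>
    dplyr::count(.data$allele) |>
    dplyr::filter(.data$n == length(regions))
  list(calls = calls, trunk_hla_loh = nrow(lost_everywhere) > 0,
       any_loh = any(calls$lost))
}

#' Fraction of binders presented by a lost HLA allele
#'
#' For each sample with at least one lost allele, the fraction of HLA binders
#' whose presenting allele is lost in that sample; samples without HLA LOH
#' are excluded from the output.
#'
#' @param binders Binder tibble for one patient (with an `allele` column).
#' @param hla_calls `calls` tibble from [call_hla_loh()].
#' @return Tibble `region_id`, `n_binders`, `n_lost_allele`, `fraction`.
#' @export
lost_allele_binding_fraction <- function(binders, hla_calls) {
  empty <- tibble::tibble(region_id = character(), n_binders = integer(),
                          n_lost_allele = integer(), fraction = double())
  loh_regions <- unique(hla_calls$region_id[hla_calls$lost])
  if (!length(loh_regions) || !nrow(binders)) return(empty)
  purrr::map_dfr(loh_regions, function(r) {
    lost <- hla_calls$allele[hla_calls$region_id == r & hla_calls$lost]
    n <- nrow(binders)
    if (!n) return(NULL)
    k <- sum(binders$allele %in% lost)
    tibble::tibble(region_id = r, n_binders = n, n_lost_allele = k,
                   fraction = k / n)
  })
}
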