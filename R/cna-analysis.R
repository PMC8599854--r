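# Gene-level copy-number aberration and LOH classification.
#
# Gain/loss thresholds on the length-weighted mean segment log2 ratio are
# strict: > 0.6 is gain, < -0.6 is loss, exactly +/-0.6 is neutral. A CNA
# "event" is a (gene, direction) pair throughout, which keeps burden counts
# and Jaccard indices consistent with each other.

overlap_len <- function(g_start, g_end, s_start, s_end) {
  pmax(0, pmin(g_end, s_end) - pmax(g_start, s_start) + 1)
}

#' Gene-level copy-number calls from segments
#'
#' Projects allele-specific segments onto a gene model: per (region, gene),
#' the mean log2 ratio is the segment-length-weighted mean over the gene's
#' overlapping segments, then classified by the strict +/-0.6 thresholds.
#' Genes with no overlapping segment are absent from the output. Coordinates
#' are 1-based inclusive.
#'
#' @param segments Segment tibble (`patient_id`, `region_id`, `chrom`,
#'   `start`, `end`, `log2`, `a_count`, `b_count`).
#' @param genes Gene model tibble (`gene`, `chrom`, `start`, `end`); defaults
#'   to the packaged synthetic model.
#' @param gain_cut,loss_cut Strict thresholds (defaults 0.6 / -0.6).
#' @return Tibble `patient_id`, `region_id`, `gene`, `mean_log2`, `state`
#'   (`"gain"`/`"neutral"`/`"loss"`).
#' @export
gene_level_cna <- function(segments, genes = default_gene_model(),
                           gain_cut = 0.6, loss_cut = -0.6) {
  hits <- dplyr::inner_join(
    segments, dplyr::rename(genes, g_start = "start", g_end = "end"),
    by = "chrom", relationship = "many-to-many") |>
    dplyr::mutate(ov = overlap_len(.data$g_start, .data$g_end,
                                   .data$start, .data$end)) |>
    dplyr::filter(.data$ov > 0)
  hits |>
    dplyr::group_by(.data$patient_id, .data$region_id, .data$gene) |>
    dplyr::summarise(mean_log2 = sum(.data$log2 * .data$ov) / sum(.data$ov),
                     .groups = "drop") |>
    dplyr::mutate(state = dplyr::case_when(
      .data$mean_log2 > gain_cut ~ "gain",
      .data$mean_log2 < loss_cut ~ "loss",
      TRUE ~ "neutral"))
}

#' Copy-number aberration burden
#'
#' Per region, the number of genes with a non-neutral state; per tumor, the
#' size of the union of (gene, direction) events across regions (a gene
#' gained in one region and lost in another contributes two tumor-level
#' events).
#'
#' @param calls Output of [gene_level_cna()].
#' @return List with `per_region` (tibble `patient_id`, `region_id`,
#'   `burden`) and `per_tumor` (tibble `patient_id`, `burden`).
#' @export
cna_burden <- function(calls) {
  ev <- calls[calls$state != "neutral", ]
  per_region <- calls |>
    dplyr::distinct(.data$patient_id, .data$region_id) |>
    dplyr::left_join(dplyr::count(ev, .data$patient_id, .data$region_id,
                                  name = "burden"),
                     by = c("patient_id", "region_id")) |>
    dplyr::mutate(burden = dplyr::coalesce(.data$burden, 0L))
  per_tumor <- calls |>
    dplyr::distinct(.data$patient_id) |>
    dplyr::left_join(
      ev |>
        dplyr::distinct(.data$patient_id, .data$gene, .data$state) |>
        dplyr::count(.data$patient_id, name = "burden"),
      by = "patient_id") |>
    dplyr::mutate(burden = dplyr::coalesce(.data$burden, 0L))
  list(per_region = per_region, per_tumor = per_tumor)
}

#' Pairwise CNA Jaccard index between regions
#'
#' Jaccard index over (gene, direction) event sets for each pair of regions
#' of the same tumor. Pairs where both regions are event-free have an
#' undefined index, emitted as `NA`.
#'
#' @param calls Output of [gene_level_cna()] for one patient.
#' @return List with `pairs` (tibble `region_a`, `region_b`, `jaccard`) and
#'   `mean_jaccard` (mean over defined pairs).
#' @export
cna_jaccard <- function(calls) {
  regions <- sort(unique(calls$region_id))
  if (length(regions) < 2) {
    return(list(pairs = tibble::tibble(region_a = character(),
                                       region_b = character(),
                                       jaccard = double()),
                mean_jaccard = NA_real_, flagged = TRUE))
  }
  ev <- calls[calls$state != "neutral", ]
  sets <- lapply(setNames(regions, regions), function(r) {
    e <- ev[ev$region_id == r, ]
    paste(e$gene, e$state)
  })
  cmb <- utils::combn(regions, 2)
  ji <- apply(cmb, 2, function(p) jaccard_sets(sets[[p[1]]], sets[[p[2]]]))
  pairs <- tibble::tibble(region_a = cmb[1, ], region_b = cmb[2, ],
                          jaccard = ji)
  list(pairs = pairs,
       mean_jaccard = if (all(is.na(ji))) NA_real_ else mean(ji, na.rm = TRUE),
       flagged = FALSE)
}

#' Confirm oncogene gains against sample ploidy
#'
#' Among called gains of oncogenes, only those whose integer copy number
#' exceeds the region's overall ploidy are retained as confirmed gains;
#' non-oncogene calls pass through unmodified.
#'
#' @param calls Output of [gene_level_cna()].
#' @param gene_cn Tibble `patient_id`, `region_id`, `gene`, `cn` of integer
#'   copy numbers for candidate genes.
#' @param ploidy Tibble `patient_id`, `region_id`, `ploidy`.
#' @param oncogenes Character vector of oncogene symbols; defaults to the
#'   packaged panel.
#' @return `calls` with logical `oncogene_gain_confirmed` (`NA` for rows the
#'   rule does not apply to) and demoted `state` (`"neutral"`) for rejected
#'   oncogene gains.
#' @export
oncogene_gain_filter <- function(calls, gene_cn, ploidy,
                                 oncogenes = names(default_gene_roles())[
                                   default_gene_roles() == "oncogene"]) {
  out <- calls |>
    dplyr::left_join(gene_cn, by = c("patient_id", "region_id", "gene")) |>
    dplyr::left_join(ploidy, by = c("patient_id", "region_id"))
  applies <- out$state == "gain" & out$gene %in% oncogenes
  confirmed <- applies & !is.na(out$cn) & !is.na(out$ploidy) &
    out$cn > out$ploidy
  out$oncogene_gain_confirmed <- ifelse(applies, confirmed, NA)
  out$state[applies & !confirmed] <- "neutral"
  out[c(names(calls), "oncogene_gain_confirmed")]
}

#' Gene-level LOH classification from allele counts
#'
#' Copy-number-neutral LOH (CNN-LOH) is a covering segment with allele counts
#' A = 2, B = 0; copy-number-loss LOH (CNL-LOH) is A = 1, B = 0; anything
#' else is no LOH. A gene spanning several segments takes the class of the
#' segment covering its midpoint (deterministic tiebreak).
#'
#' @param segments Segment tibble with `a_count`, `b_count`.
#' @param genes Gene model tibble; defaults to the packaged synthetic model.
#' @return Tibble `patient_id`, `region_id`, `gene`, `loh_class`
#'   (`"none"`/`"CNN_LOH"`/`"CNL_LOH"`); genes with no covering segment are
#'   absent.
#' @export
classify_gene_loh <- function(segments, genes = default_gene_model()) {
  g <- dplyr::mutate(genes, mid = floor((.data$start + .data$end) / 2))
  hits <- dplyr::inner_join(
    segments, g[c("gene", "chrom", "mid")], by = "chrom",
    relationship = "many-to-many") |>
    dplyr::filter(.data$start <= .data$mid, .data$mid <= .data$end)
  hits |>
    dplyr::mutate(loh_class = dplyr::case_when(
      .data$a_count == 2 & .data$b_count == 0 ~ "CNN_LOH",
      .data$a_count == 1 & .data$b_count == 0 ~ "CNL_LOH",
      TRUE ~ "none")) |>
    dplyr::select("patient_id", "region_id", "gene", "loh_class")
}

#' Trunk/branch status of LOH events
#'
#' An LOH event (gene, class) is trunk iff present in every region of the
#' tumor, branch otherwise; also reports the per-tumor trunk fraction of LOH
#' events.
#'
#' @param loh_calls Output of [classify_gene_loh()] for one patient with
#'   >= 2 regions.
#' @return List with `events` (tibble `gene`, `loh_class`, `n_regions`,
#'   `label`) and `trunk_fraction`.
#' @export
trunk_branch_loh <- function(loh_calls) {
  regions <- unique(loh_calls$region_id)
  stopifnot(length(regions) >= 2)
  ev <- loh_calls[loh_calls$loh_class != "none", ]
  events <- ev |>
    dplyr::distinct(.data$gene, .data$loh_class, .data$region_id) |>
    dplyr::count(.data$gene, .data$loh_class, name = "n_regions") |>
    dplyr::mutate(label = ifelse(.data$n_regions == length(regions),
                                 "trunk", "branch"))
  list(events = events,
       trunk_fraction = if (nrow(events)) mean(events$label == "trunk")
                        else NA_real_)
}
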