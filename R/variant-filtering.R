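# Somatic variant QC for FFPE multi-region exome data.
#
# Region-level calls use a log-odds (LOD) threshold of 18; merged tumor-level
# calls use 30. A call failing only the LOD rule is rescued when the identical
# mutation passes in another region of the same tumor -- FFPE artifacts are
# non-recurrent, so cross-region recurrence certifies a low-LOD call.

#' Somatic filter thresholds
#'
#' Defaults are the study thresholds for FFPE exome data: tumor depth >= 20x,
#' germline depth >= 10x, tumor VAF >= 0.02, germline VAF < 0.01, >= 4
#' alt-supporting reads, population frequency < 0.01 in all three databases,
#' and LOD strictly greater than 18 at region level (30 at tumor level).
#'
#' @param min_t_depth,min_n_depth Minimum tumor/germline depth.
#' @param min_t_vaf Minimum tumor VAF (inclusive).
#' @param max_n_vaf Germline VAF upper bound (exclusive).
#' @param min_alt_reads Minimum alt-supporting reads (inclusive).
#' @param max_popfreq Population-frequency upper bound (exclusive), applied to
#'   each of the ESP/1000-genomes/ExAC columns; missing frequencies count as 0.
#' @param lod_region,lod_tumor LOD thresholds (strictly greater than).
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_t_depth = 20, min_n_depth = 10,
                              min_t_vaf = 0.02, max_n_vaf = 0.01,
                              min_alt_reads = 4, max_popfreq = 0.01,
                              lod_region = 18, lod_tumor = 30) {
  thr <- list(min_t_depth = min_t_depth, min_n_depth = min_n_depth,
              min_t_vaf = min_t_vaf, max_n_vaf = max_n_vaf,
              min_alt_reads = min_alt_reads, max_popfreq = max_popfreq,
              lod_region = lod_region, lod_tumor = lod_tumor)
  stopifnot(all(unlist(thr) >= 0), lod_tumor >= lod_region)
  structure(thr, class = "filter_thresholds")
}

filter_reasons <- function(variants, thr, lod_threshold) {
  pf <- function(x) dplyr::coalesce(x, 0)
  v <- variants
  list(
    min_t_depth   = !(v$t_depth >= thr$min_t_depth),
    min_n_depth   = !(v$n_depth >= thr$min_n_depth),
    min_t_vaf     = !(v$t_vaf >= thr$min_t_vaf),
    max_n_vaf     = !(dplyr::coalesce(v$n_vaf, 0) < thr$max_n_vaf),
    min_alt_reads = !(v$t_alt >= thr$min_alt_reads),
    max_popfreq   = !(pf(v$popfreq_esp) < thr$max_popfreq &
                        pf(v$popfreq_1kg) < thr$max_popfreq &
                        pf(v$popfreq_exac) < thr$max_popfreq),
    lod           = !(v$lod > lod_threshold)
  )
}

#' Apply per-region somatic filters
#'
#' A variant passes iff tumor depth >= 20, germline depth >= 10, tumor VAF
#' >= 0.02, germline VAF < 0.01, alt reads >= 4, all population frequencies
#' < 0.01, and LOD strictly greater than the level-appropriate threshold
#' (18 region, 30 tumor). Every violated rule is listed for failing variants.
#'
#' @param variants Variant tibble (the MAF-like layout).
#' @param thr A [filter_thresholds()] object.
#' @param level `"region"` (LOD > 18) or `"tumor"` (LOD > 30).
#' @return Input tibble with added logical `pass` and character
#'   `fail_reasons` (`NA` for passing rows, otherwise comma-separated rules).
#' @export
apply_region_filters <- function(variants, thr = filter_thresholds(),
                                 level = c("region", "tumor")) {
  level <- match.arg(level)
  lod_thr <- if (level == "region") thr$lod_region else thr$lod_tumor
  if (!nrow(variants)) {
    return(dplyr::mutate(variants, pass = logical(0),
                         fail_reasons = character(0)))
  }
  fails <- filter_reasons(variants, thr, lod_thr)
  fail_mat <- do.call(cbind, fails)
  fail_mat[is.na(fail_mat)] <- TRUE   # unassessable rule counts as violated
  reasons <- apply(fail_mat, 1, function(r) {
    if (!any(r)) NA_character_ else paste(names(fails)[r], collapse = ",")
  })
  dplyr::mutate(variants, pass = is.na(reasons), fail_reasons = reasons)
}

#' Rescue LOD-only failures recurrent across regions
#'
#' A failing variant is rescued iff its only violated rule is the LOD rule and
#' the identical mutation (same chrom, pos, ref, alt -- gene is not consulted)
#' passed with LOD >= 18 in at least one other region of the same tumor. At
#' tumor level the supporting passes are the region-level passing calls.
#'
#' @param filtered Output of [apply_region_filters()] (region level).
#' @param support Optional tibble of supporting passing calls; defaults to the
#'   passing rows of `filtered` itself (region-level use).
#' @param support_lod Minimum LOD a supporting call must have (default 18,
#'   inclusive).
#' @return `filtered` with `pass` updated and a logical `rescued` column.
#' @export
rescue_by_region <- function(filtered, support = NULL, support_lod = 18) {
  if (!nrow(filtered)) return(dplyr::mutate(filtered, rescued = logical(0)))
  if (is.null(support)) support <- filtered[filtered$pass, ]
  support <- support[support$lod >= support_lod, ]
  supp_key <- paste(support$patient_id, mutation_key(support),
                    support$region_id, sep = "@")
  out <- dplyr::mutate(filtered, rescued = FALSE)
  cand <- which(!out$pass & out$fail_reasons == "lod")
  for (i in cand) {
    key_i <- paste(out$patient_id[i], mutation_key(out[i, ]), sep = "@")
    others <- startsWith(supp_key, paste0(key_i, "@")) &
      !endsWith(supp_key, paste0("@", out$region_id[i]))
    if (any(others)) {
      out$pass[i] <- TRUE
      out$rescued[i] <- TRUE
      out$fail_reasons[i] <- NA_character_
    }
  }
  out
}

is_snv <- function(v) {
  nchar(v$ref) == 1 & nchar(v$alt) == 1 &
    v$ref %in% BASES & v$alt %in% BASES & v$ref != v$alt
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

collapse_substitution <- function(ref, alt) {
  # pyrimidine-strand collapse: purines are reverse-complemented
  pur <- ref %in% c("A", "G")
  ref2 <- ifelse(pur, COMPLEMENT[ref], ref)
  alt2 <- ifelse(pur, COMPLEMENT[alt], alt)
  paste0(ref2, ">", alt2)
}

#' Substitution spectrum by LOD stratum
#'
#' Proportions over the six pyrimidine-collapsed substitution classes
#' (C>A, C>G, C>T, T>A, T>C, T>G), per sample and LOD stratum. FFPE artifacts
#' present as low-LOD C>T|G>A transitions, so contrasting strata around the
#' LOD cut (default 18) is the QC readout. Indels are excluded.
#'
#' @param variants Variant tibble.
#' @param lod_cut LOD value splitting the `low`/`high` strata (low: LOD <=
#'   cut).
#' @param by Grouping columns for the per-sample summary (default
#'   patient + region).
#' @return Tibble `...by, stratum, class, n, proportion`; proportions sum to 1
#'   within each (group, stratum) that has any SNV.
#' @export
substitution_spectrum <- function(variants, lod_cut = 18,
                                  by = c("patient_id", "region_id")) {
  snv <- variants[is_snv(variants), ]
  if (!nrow(snv)) {
    return(tibble::tibble(stratum = character(), class = character(),
                          n = integer(), proportion = double()))
  }
  snv$stratum <- ifelse(snv$lod <= lod_cut, "low_lod", "high_lod")
  snv$class <- collapse_substitution(snv$ref, snv$alt)
  counts <- snv |>
    dplyr::count(dplyr::across(dplyr::all_of(c(by, "stratum", "class")))) |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(c(by, "stratum"))),
      class = SUBSTITUTION_CLASSES, fill = list(n = 0L))
  counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "stratum")))) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Classify cancer-gene alterations
#'
#' A variant is a cancer-gene alteration iff it matches a known hotspot
#' (gene + position), or is a stop-gain/frameshift in a tumor suppressor gene,
#' or is a nonsynonymous mutation with CADD score strictly above 20 (missing
#' CADD is treated as not above 20).
#'
#' @param variants Variant tibble.
#' @param gene_roles Named character vector gene -> role
#'   (`"oncogene"`/`"TSG"`/`"other"`); defaults to the packaged map.
#' @param hotspots Tibble `gene`, `pos`; defaults to the packaged list.
#' @param cadd_cut CADD threshold (strictly greater than; default 20).
#' @return Input tibble with logical `cancer_gene_alteration` and character
#'   `alteration_basis` (`"hotspot"`, `"tsg_truncation"`, `"cadd"` or `NA`).
#' @export
classify_cancer_gene_alterations <- function(variants,
                                             gene_roles = default_gene_roles(),
                                             hotspots = default_hotspots(),
                                             cadd_cut = 20) {
  if (!nrow(variants)) {
    return(dplyr::mutate(variants, cancer_gene_alteration = logical(0),
                         alteration_basis = character(0)))
  }
  role <- unname(gene_roles[variants$gene])
  role[is.na(role)] <- "other"
  hot <- paste(variants$gene, variants$pos) %in% paste(hotspots$gene, hotspots$pos)
  tsg_trunc <- role == "TSG" & variants$func_class %in% c("stopgain", "frameshift")
  cadd_hit <- variants$func_class == "nonsynonymous" &
    !is.na(variants$cadd) & variants$cadd > cadd_cut
  basis <- dplyr::case_when(hot ~ "hotspot",
                            tsg_trunc ~ "tsg_truncation",
                            cadd_hit ~ "cadd",
                            TRUE ~ NA_character_)
  dplyr::mutate(variants, cancer_gene_alteration = !is.na(basis),
                alteration_basis = basis)
}

#' Nonsilent tumor mutational burden
#'
#' Counts nonsilent mutations (nonsynonymous, frameshift, stop-gain,
#' stop-loss) per megabase of capture footprint, per region and per tumor
#' (the union of distinct mutations across regions).
#'
#' @param variants Variant tibble (typically the filtered passing set).
#' @param capture_mb Capture footprint in Mb (default 30); must be positive.
#' @return Tibble `patient_id`, `region_id` (`NA` for the tumor-level union
#'   row), `n_nonsilent`, `tmb`.
#' @export
compute_tmb <- function(variants, capture_mb = 30) {
  if (!is.numeric(capture_mb) || capture_mb <= 0) {
    stop("capture_mb must be > 0", call. = FALSE)
  }
  ns <- variants[variants$func_class %in% NONSILENT_CLASSES, ]
  per_region <- ns |>
    dplyr::distinct(.data$patient_id, .data$region_id, .data$chrom,
                    .data$pos, .data$ref, .data$alt) |>
    dplyr::count(.data$patient_id, .data$region_id, name = "n_nonsilent")
  per_tumor <- ns |>
    dplyr::distinct(.data$patient_id, .data$chrom, .data$pos, .data$ref,
                    .data$alt) |>
    dplyr::count(.data$patient_id, name = "n_nonsilent") |>
    dplyr::mutate(region_id = NA_character_)
  # regions/tumors with zero nonsilent calls still get a 0 row
  frame <- dplyr::distinct(variants, .data$patient_id, .data$region_id)
  frame <- dplyr::bind_rows(frame,
                            dplyr::distinct(variants, .data$patient_id) |>
                              dplyr::mutate(region_id = NA_character_))
  frame |>
    dplyr::left_join(dplyr::bind_rows(per_region, per_tumor),
                     by = c("patient_id", "region_id")) |>
    dplyr::mutate(n_nonsilent = dplyr::coalesce(.data$n_nonsilent, 0L),
                  tmb = .data$n_nonsilent / capture_mb) |>
    dplyr::arrange(.data$patient_id, .data$region_id)
}
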