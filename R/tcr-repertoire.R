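# TCR-beta repertoire metrics and overlap.
#
# Clonality is 1 - Pielou evenness = 1 - H/ln(R) with Shannon entropy H over
# productive frequencies renormalized to sum 1 (natural log). Overlap uses
# the Jaccard index on rearrangement sets, the Morisita-Horn index on
# template counts, and the shared fraction of the top-20 most frequent
# clonotypes.

#' Per-sample repertoire metrics
#'
#' Density is templates per input nucleated cell; richness the number of
#' unique rearrangements; clonality `1 - H/ln(R)` (0 when `R = 1` by
#' convention, and 0 exactly for a perfectly even repertoire).
#'
#' @param table A [clonotype_table()].
#' @return One-row tibble `patient_id`, `region_id`, `density`, `richness`,
#'   `clonality`, `total_templates`.
#' @export
repertoire_metrics <- function(table) {
  cl <- table$clones
  stopifnot(nrow(cl) >= 1)
  R <- nrow(cl)
  p <- cl$productive_freq / sum(cl$productive_freq)
  H <- -sum(p[p > 0] * log(p[p > 0]))
  clonality <- if (R == 1) 0 else 1 - H / log(R)
  density <- if (is.na(table$input_cells) || table$input_cells <= 0) {
    NA_real_
  } else table$total_templates / table$input_cells
  tibble::tibble(patient_id = table$patient_id, region_id = table$region_id,
                 density = density, richness = R, clonality = clonality,
                 total_templates = table$total_templates)
}

top_n_rearrangements <- function(clones, n = 20) {
  # ties broken by rearrangement string order for determinism
  ord <- order(-clones$productive_freq, clones$rearrangement)
  clones$rearrangement[ord][seq_len(min(n, nrow(clones)))]
}

#' Pairwise repertoire overlap metrics
#'
#' Jaccard index on rearrangement sets; Morisita-Horn index on template
#' counts (`2 * sum(x_i y_i) / ((sum(x_i^2)/X^2 + sum(y_i^2)/Y^2) * X * Y)`);
#' and the shared proportion of the top-20 highest-frequency clonotypes
#' (denominator 20, or the smaller repertoire's size when below 20; frequency
#' ties broken by rearrangement string order).
#'
#' @param a,b [clonotype_table()] objects (both nonempty).
#' @return One-row tibble `sample_a`, `sample_b`, `jaccard`, `morisita`,
#'   `top20_shared`.
#' @export
overlap_metrics <- function(a, b) {
  stopifnot(nrow(a$clones) >= 1, nrow(b$clones) >= 1)
  ra <- a$clones$rearrangement
  rb <- b$clones$rearrangement
  jacc <- jaccard_sets(ra, rb)
  all_r <- union(ra, rb)
  x <- setNames(rep(0, length(all_r)), all_r)
  y <- x
  x[ra] <- a$clones$templates
  y[rb] <- b$clones$templates
  X <- sum(x); Y <- sum(y)
  mh <- 2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
  ta <- top_n_rearrangements(a$clones)
  tb <- top_n_rearrangements(b$clones)
  denom <- min(20, nrow(a$clones), nrow(b$clones))
  tibble::tibble(
    sample_a = paste(a$patient_id, a$region_id, sep = "/"),
    sample_b = paste(b$patient_id, b$region_id, sep = "/"),
    jaccard = jacc, morisita = mh,
    top20_shared = length(intersect(ta, tb)) / denom)
}

#' Regional sharing classes of clonotypes
#'
#' Over the union of rearrangements of all regions of one tumor: the
#' proportion present in every region (shared), in at least two but not all
#' regions (intermediate), and in exactly one (single-region). Proportions
#' sum to 1.
#'
#' @param tables List of [clonotype_table()] objects, one per region
#'   (>= 2 regions).
#' @return One-row tibble `n_regions`, `n_clonotypes`, `shared_all`,
#'   `intermediate`, `single_region`.
#' @export
sharing_classes <- function(tables) {
  if (length(tables) < 2) {
    stop("sharing classes are undefined for a single region", call. = FALSE)
  }
  sets <- lapply(tables, function(tb) unique(tb$clones$rearrangement))
  all_r <- unique(unlist(sets))
  counts <- rowSums(vapply(sets, function(s) all_r %in% s,
                           logical(length(all_r))))
  n <- length(tables)
  tibble::tibble(
    n_regions = n, n_clonotypes = length(all_r),
    shared_all = mean(counts == n),
    intermediate = mean(counts >= 2 & counts < n),
    single_region = mean(counts == 1))
}

#' Tumor versus adjacent-lung repertoire contrast
#'
#' Two-sided comparison of density, richness and clonality between tumor
#' regions and tumor-adjacent lung samples. Patient-matched pairs (tumor
#' metrics averaged per patient) are compared with a Wilcoxon signed-rank
#' test when at least 3 matched pairs exist; otherwise the groups are
#' compared unpaired with a Mann-Whitney test (the switch is reported).
#'
#' @param metrics Row-bound [repertoire_metrics()] tibble for all samples;
#'   adjacent samples carry `region_id == "adjacent_lung"`.
#' @return Tibble `metric`, `test`, `statistic`, `p_value`, `n_pairs`.
#' @export
tumor_vs_adjacent_contrast <- function(metrics) {
  adj <- metrics[metrics$region_id == adjacent_lung_region(), ]
  tum <- metrics[metrics$region_id != adjacent_lung_region(), ]
  purrr::map_dfr(c("density", "richness", "clonality"), function(m) {
    t_by_pat <- tapply(tum[[m]], tum$patient_id, mean, na.rm = TRUE)
    a_by_pat <- tapply(adj[[m]], adj$patient_id, mean, na.rm = TRUE)
    shared <- intersect(names(t_by_pat), names(a_by_pat))
    shared <- shared[!is.na(t_by_pat[shared]) & !is.na(a_by_pat[shared])]
    if (length(shared) >= 3) {
      x <- t_by_pat[shared]; y <- a_by_pat[shared]
      if (all(x == y)) {
        return(tibble::tibble(metric = m, test = "wilcoxon_signed_rank",
                              statistic = NA_real_, p_value = 1,
                              n_pairs = length(shared)))
      }
      w <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
      tibble::tibble(metric = m, test = "wilcoxon_signed_rank",
                     statistic = unname(w$statistic), p_value = w$p.value,
                     n_pairs = length(shared))
    } else {
      x <- tum[[m]][!is.na(tum[[m]])]
      y <- adj[[m]][!is.na(adj[[m]])]
      if (length(x) < 3 || length(y) < 3) {
        stop("fewer than 3 informative pairs/samples for metric ", m,
             call. = FALSE)
      }
      w <- suppressWarnings(stats::wilcox.test(x, y))
      tibble::tibble(metric = m, test = "mann_whitney",
                     statistic = unname(w$statistic), p_value = w$p.value,
                     n_pairs = NA_integer_)
    }
  })
}
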