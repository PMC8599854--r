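# 96-channel mutation catalogs and signature refitting.
#
# Catalogs count pyrimidine-strand trinucleotide substitution channels; the
# refit is a deterministic forward-selection nonnegative least-squares
# decomposition against the packaged 30-signature reference, with the usual
# 0.06 exposure cutoff.

#' Convert a trinucleotide-context string to a channel label
#'
#' Context strings have the form `"ACA>AAA"` (reference trinucleotide,
#' `">"`, alternate trinucleotide, differing at the middle base). Purine
#' reference bases are collapsed to the pyrimidine strand by
#' reverse-complementing both triplets. Invalid strings map to `NA`.
#'
#' @param tnc Character vector of context strings.
#' @return Character vector of channel labels (`"A[C>A]A"` form) or `NA`.
#' @export
tnc_to_channel <- function(tnc) {
  vapply(tnc, function(s) {
    if (is.na(s) || !grepl("^[ACGT]{3}>[ACGT]{3}$", s)) return(NA_character_)
    ref3 <- strsplit(substr(s, 1, 3), "")[[1]]
    alt3 <- strsplit(substr(s, 5, 7), "")[[1]]
    if (ref3[1] != alt3[1] || ref3[3] != alt3[3] || ref3[2] == alt3[2]) {
      return(NA_character_)
    }
    if (ref3[2] %in% c("A", "G")) {
      ref3 <- rev(unname(COMPLEMENT[ref3]))
      alt3 <- rev(unname(COMPLEMENT[alt3]))
    }
    paste0(ref3[1], "[", ref3[2], ">", alt3[2], "]", ref3[3])
  }, character(1), USE.NAMES = FALSE)
}

#' Build 96-channel catalogs by compartment
#'
#' Counts SNVs with a valid trinucleotide context into the 96 fixed channels,
#' per (patient, compartment). Compartments come from the trunk/branch/
#' private labels: `"trunk"` and `"nontrunk"` (branch + private), plus
#' `"all"`. Variants without a usable context are excluded and reported.
#'
#' @param variants Variant tibble (one or more patients) with `tnc`.
#' @param labels Output of [classify_trunk_branch_private()] covering the
#'   variants' mutations, or `NULL` for an `"all"`-only catalog.
#' @return List with `catalogs` (named list `patient/compartment` ->
#'   96-vector) and `dropped` (tibble of excluded rows and reasons).
#' @export
build_catalog <- function(variants, labels = NULL) {
  ch <- trinucleotide_channels()
  v <- variants[is_snv(variants), ]
  v <- dplyr::distinct(v, .data$patient_id, .data$chrom, .data$pos,
                       .data$ref, .data$alt, .keep_all = TRUE)
  v$channel <- tnc_to_channel(v$tnc)
  dropped <- v[is.na(v$channel), ]
  v <- v[!is.na(v$channel), ]
  v$compartment <- "all"
  if (!is.null(labels)) {
    lab <- labels$label[match(mutation_key(v), labels$mutation)]
    v2 <- v
    v2$compartment <- ifelse(lab == "trunk", "trunk", "nontrunk")
    v2 <- v2[!is.na(lab), ]
    v <- dplyr::bind_rows(v, v2)
  }
  key <- paste(v$patient_id, v$compartment, sep = "/")
  catalogs <- lapply(split(v$channel, key), function(chans) {
    counts <- table(factor(chans, levels = ch))
    setNames(as.integer(counts), ch)
  })
  list(catalogs = catalogs,
       dropped = tibble::tibble(
         mutation = if (nrow(dropped)) mutation_key(dropped) else character(),
         reason = rep("invalid_tnc", nrow(dropped))))
}

#' Refit a catalog against the reference signatures
#'
#' Deterministic forward selection: starting from an empty signature set,
#' repeatedly add the reference signature whose inclusion most reduces the
#' squared reconstruction error of the normalized catalog, refitting all
#' selected weights by nonnegative least squares each round, and stop when
#' the error improvement falls below `tol`. Weights below `cutoff` are then
#' zeroed and the survivors renormalized to the pre-cutoff total mass.
#'
#' @param catalog A 96-vector of channel counts (total >= 1).
#' @param reference 96 x 30 reference matrix; defaults to
#'   [reference_signatures()].
#' @param cutoff Exposure cutoff (default 0.06).
#' @param tol Forward-selection stopping tolerance on the improvement of the
#'   L2 reconstruction-error norm (default 1e-3).
#' @return An object of class `signature_exposure`: list with `weights`
#'   (named 30-vector), `reconstruction_error` (sum of squared differences of
#'   the normalized vectors) and `n_mutations`.
#' @export
fit_signatures <- function(catalog, reference = reference_signatures(),
                           cutoff = 0.06, tol = 1e-3) {
  total <- sum(catalog)
  if (total < 1) stop("catalog has no mutations", call. = FALSE)
  target <- catalog / total
  selected <- integer()
  weights <- numeric(0)
  err <- sqrt(sum(target^2))
  repeat {
    remaining <- setdiff(seq_len(ncol(reference)), selected)
    if (!length(remaining)) break
    trial <- vapply(remaining, function(j) {
      fit <- pracma::lsqnonneg(reference[, c(selected, j), drop = FALSE],
                               target)
      sqrt(sum((target - reference[, c(selected, j), drop = FALSE] %*%
                  fit$x)^2))
    }, numeric(1))
    best <- remaining[which.min(trial)]
    new_err <- min(trial)
    if (err - new_err < tol) break
    selected <- c(selected, best)
    err <- new_err
    weights <- pracma::lsqnonneg(reference[, selected, drop = FALSE],
                                 target)$x
  }
  w <- setNames(numeric(ncol(reference)), colnames(reference))
  if (length(selected)) w[selected] <- weights
  if (sum(w) > 1) w <- w / sum(w)   # exposures live on the simplex
  pre_mass <- sum(w)
  w[w < cutoff] <- 0
  if (sum(w) > 0) w <- w / sum(w) * pre_mass
  recon <- as.vector(reference %*% w)
  structure(list(weights = w,
                 reconstruction_error = sum((target - recon)^2),
                 n_mutations = total),
            class = "signature_exposure")
}

#' @export
print.signature_exposure <- function(x, ...) {
  nz <- sort(x$weights[x$weights > 0], decreasing = TRUE)
  cat(sprintf("<signature_exposure> %d mutations, error %.4g\n",
              x$n_mutations, x$reconstruction_error))
  if (length(nz)) {
    cat(paste(sprintf("  %s: %.3f", names(nz), nz), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
tidy.signature_exposure <- function(x, ...) {
  tibble::tibble(signature = names(x$weights), weight = unname(x$weights))
}

#' @export
glance.signature_exposure <- function(x, ...) {
  tibble::tibble(n_mutations = x$n_mutations,
                 n_signatures = sum(x$weights > 0),
                 reconstruction_error = x$reconstruction_error)
}

#' Trunk versus nontrunk signature contrast
#'
#' Pools exposures across tumors per compartment, ranks signatures by pooled
#' weight, keeps the top `top_k` and renormalizes over them to get each
#' signature's share of the top-k mass; also runs a two-sided paired
#' Wilcoxon signed-rank test on per-tumor shares of a named signature
#' between compartments (tumors missing either compartment are excluded
#' pairwise).
#'
#' @param exposures Tibble `patient_id`, `compartment`, `signature`,
#'   `weight` (e.g. from row-binding `tidy()` of per-tumor fits).
#' @param top_k Number of top signatures (default 5); if fewer are nonzero,
#'   all nonzero are used and the result is flagged.
#' @param test_signature Signature name for the across-tumor test (default
#'   `"Signature.4"`).
#' @return List with `top_shares` (tibble `compartment`, `signature`,
#'   `share`), `test` (tibble `signature`, `statistic`, `p_value`,
#'   `n_pairs`), and `flagged`.
#' @export
trunk_nontrunk_contrast <- function(exposures, top_k = 5,
                                    test_signature = "Signature.4") {
  comp <- unique(exposures$compartment)
  stopifnot(all(c("trunk", "nontrunk") %in% comp))
  n_tumors <- exposures |>
    dplyr::distinct(.data$patient_id, .data$compartment) |>
    dplyr::count(.data$compartment)
  stopifnot(all(n_tumors$n >= 3))
  pooled <- exposures |>
    dplyr::group_by(.data$compartment, .data$signature) |>
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
  flagged <- FALSE
  top_shares <- pooled |>
    dplyr::group_by(.data$compartment) |>
    dplyr::group_modify(function(d, key) {
      d <- d[d$weight > 0, ]
      k <- min(top_k, nrow(d))
      if (k < top_k) flagged <<- TRUE
      top <- d[order(-d$weight, d$signature), ][seq_len(k), ]
      top$share <- top$weight / sum(top$weight)
      top[c("signature", "share")]
    }) |>
    dplyr::ungroup()
  per_tumor <- exposures |>
    dplyr::group_by(.data$patient_id, .data$compartment) |>
    dplyr::mutate(share = .data$weight / sum(.data$weight)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$signature == test_signature) |>
    tidyr::pivot_wider(id_cols = "patient_id", names_from = "compartment",
                       values_from = "share")
  ok <- !is.na(per_tumor$trunk) & !is.na(per_tumor$nontrunk)
  x <- per_tumor$trunk[ok]
  y <- per_tumor$nontrunk[ok]
  test <- if (sum(ok) >= 3 && !all(x == y)) {
    w <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    tibble::tibble(signature = test_signature,
                   statistic = unname(w$statistic), p_value = w$p.value,
                   n_pairs = sum(ok))
  } else {
    tibble::tibble(signature = test_signature, statistic = NA_real_,
                   p_value = if (sum(ok) && all(x == y)) 1 else NA_real_,
                   n_pairs = sum(ok))
  }
  list(top_shares = top_shares, test = test, flagged = flagged)
}
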