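# ggplot2 displays for the main result types.

#' Stacked trunk/branch/private composition per tumor
#' @param labels_tbl Row-bound [classify_trunk_branch_private()] output with
#'   a `patient_id` column.
#' @return A ggplot.
#' @export
plot_trunk_composition <- function(labels_tbl) {
  ggplot2::ggplot(labels_tbl,
                  ggplot2::aes(x = .data$patient_id,
                               fill = factor(.data$label,
                                             c("trunk", "branch",
                                               "private")))) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::scale_fill_manual(
      values = c(trunk = "#2166ac", branch = "#b2772c", private = "#b2182b"),
      name = NULL) +
    ggplot2::labs(x = NULL, y = "fraction of mutations") +
    ggplot2::theme_minimal()
}

#' Substitution-spectrum bars by LOD stratum
#' @param spectrum Output of [substitution_spectrum()].
#' @return A ggplot.
#' @export
plot_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(x = .data$class, y = .data$proportion,
                               fill = .data$class)) +
    ggplot2::stat_summary(fun = mean, geom = "col") +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = NULL, y = "mean proportion") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Signature-exposure bars per compartment
#' @param exposures Tibble `patient_id`, `compartment`, `signature`,
#'   `weight`.
#' @param min_weight Hide signatures never exceeding this weight.
#' @return A ggplot.
#' @export
plot_signature_exposures <- function(exposures, min_weight = 0.05) {
  keep <- exposures |>
    dplyr::group_by(.data$signature) |>
    dplyr::filter(max(.data$weight) > min_weight) |>
    dplyr::ungroup()
  ggplot2::ggplot(keep,
                  ggplot2::aes(x = .data$patient_id, y = .data$weight,
                               fill = .data$signature)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~compartment) +
    ggplot2::labs(x = NULL, y = "exposure") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Kaplan-Meier step curves
#' @param object A `km_logrank` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_logrank <- function(object, ...) {
  curves <- dplyr::bind_rows(
    object$curves |>
      dplyr::group_by(.data$group) |>
      dplyr::slice(1) |>
      dplyr::mutate(time = 0, surv = 1) |>
      dplyr::ungroup(),
    object$curves)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$surv,
                                       color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "overall survival",
                  subtitle = sprintf("log-rank p = %.4g", object$p_value)) +
    ggplot2::theme_minimal()
}

#' Cancer-cell-fraction histogram with cluster assignment
#' @param object A `clonal_architecture` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clonal_architecture <- function(object, ...) {
  ggplot2::ggplot(object$assignments,
                  ggplot2::aes(x = .data$ccf,
                               fill = factor(.data$cluster))) +
    ggplot2::geom_histogram(bins = 40, position = "stack") +
    ggplot2::labs(x = "cancer-cell fraction", y = "mutations",
                  fill = "cluster",
                  subtitle = sprintf("clonal fraction %.2f",
                                     object$clonal_fraction)) +
    ggplot2::theme_minimal()
}
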