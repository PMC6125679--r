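#' Plot survival curves with linear-quadratic fits
#'
#' Log-scaled surviving-fraction axis; points are the measured SF per
#' dose, lines the LQ fits when supplied.
#'
#' @param curves A survival-curve tibble (see [survival_curve()]).
#' @param fits Optional named list of `lq_fit` objects (names matching
#'   the `condition` values) to overlay.
#' @return A ggplot object.
#' @export
plot_survival_curves <- function(curves, fits = NULL) {
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$dose, y = .data$sf,
                                    colour = .data$condition)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Dose (Gy)", y = "Surviving fraction",
                  colour = "Condition") +
    ggplot2::theme_classic()
  if (!is.null(curves$se) && !all(is.na(curves$se))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$sf - .data$se, 1e-6),
                   ymax = .data$sf + .data$se),
      width = 0.15
    )
  }
  if (!is.null(fits)) {
    grid <- dplyr::bind_rows(lapply(names(fits), function(nm) {
      d <- seq(0, max(curves$dose), length.out = 100)
      tibble::tibble(condition = nm, dose = d,
                     sf = sf_lq(d, fits[[nm]]$alpha, fits[[nm]]$beta))
    }))
    p <- p + ggplot2::geom_line(data = grid)
  }
  p
}

#' @rdname plot_survival_curves
#' @param object An `lq_fit` object.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @method autoplot lq_fit
#' @export
autoplot.lq_fit <- function(object, ...) {
  d <- seq(0, 10, length.out = 100)
  tibble::tibble(dose = d, sf = sf_lq(d, object$alpha, object$beta)) |>
    ggplot2::ggplot(ggplot2::aes(.data$dose, .data$sf)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Dose (Gy)", y = "Surviving fraction") +
    ggplot2::theme_classic()
}

#' Waterfall plot of screen R-scores
#'
#' Genes ordered by ascending R-score; radiosensitizing genes sit on the
#' negative side.
#'
#' @param rscores Output of [r_score()] (one run).
#' @return A ggplot object.
#' @export
plot_rscore_waterfall <- function(rscores) {
  df <- rscores |>
    dplyr::filter(.data$role == "sample") |>
    dplyr::arrange(.data$r_score) |>
    dplyr::mutate(idx = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(.data$idx, .data$r_score)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Gene rank (ascending R-score)", y = "R-score") +
    ggplot2::theme_classic()
}

#' Stacked bar chart of lineage fate percentages
#'
#' @param fates Output of [classify_lineages()], optionally with a
#'   `condition` column to facet groups side by side.
#' @return A ggplot object.
#' @export
plot_fate_summary <- function(fates) {
  if (!"condition" %in% names(fates)) fates$condition <- "all"
  df <- fates |>
    dplyr::count(.data$condition, .data$fate) |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$pct,
                                   fill = .data$fate)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of lineages", fill = "Fate") +
    ggplot2::theme_classic()
}
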