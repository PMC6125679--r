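aberration_classes <- c("chromatid_breaks", "chromatid_gaps", "chromatid_exchanges",
                        "chromosome_breaks", "chromosome_gaps", "chromosome_exchanges")

#' Summarize chromosome aberrations per metaphase
#'
#' Class-wise means and standard deviations of aberration counts per
#' metaphase, with the chromatid-type / chromosome-type dichotomy and the
#' grand total, by experimental group. Standard deviations use the sample
#' (n - 1) divisor. If a mitotic fraction is supplied, the population rate
#' per 100 cells (per-metaphase mean x mitotic fraction x 100) is added.
#'
#' @param records Tibble of metaphase records: grouping columns plus the
#'   six class-count columns `chromatid_breaks`, `chromatid_gaps`,
#'   `chromatid_exchanges`, `chromosome_breaks`, `chromosome_gaps`,
#'   `chromosome_exchanges`.
#' @param by Character vector of grouping columns present in `records`
#'   (default `condition` and, when present, `timepoint`).
#' @param mitotic_fraction Optional: a single fraction in \[0, 1\] applied
#'   to all groups, or a data frame with the grouping columns and a
#'   `mitotic_fraction` column (an external flow-cytometry measurement of
#'   the p-H3-positive fraction, not computed here).
#' @return A long tibble with one row per group x class (the six classes
#'   plus `chromatid_total`, `chromosome_total`, `total`): `mean`, `sd`,
#'   `n` and, when a mitotic fraction was given, `per_100_cells`.
#' @export
summarize_aberrations <- function(records, by = intersect(c("condition", "timepoint"),
                                                          names(records)),
                                  mitotic_fraction = NULL) {
  miss <- setdiff(aberration_classes, names(records))
  if (length(miss) > 0) stop("missing class column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0) stop("no metaphase records", call. = FALSE)
  if (length(by) == 0) {
    records$condition <- "all"
    by <- "condition"
  }

  long <- records |>
    dplyr::mutate(
      chromatid_total = .data$chromatid_breaks + .data$chromatid_gaps +
        .data$chromatid_exchanges,
      chromosome_total = .data$chromosome_breaks + .data$chromosome_gaps +
        .data$chromosome_exchanges,
      total = .data$chromatid_total + .data$chromosome_total
    ) |>
    tidyr::pivot_longer(dplyr::all_of(c(aberration_classes, "chromatid_total",
                                        "chromosome_total", "total")),
                        names_to = "class", values_to = "count")

  out <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "class")))) |>
    dplyr::summarise(mean = mean(.data$count), sd = stats::sd(.data$count),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(class = factor(.data$class,
                                 levels = c(aberration_classes, "chromatid_total",
                                            "chromosome_total", "total"))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)), .data$class) |>
    dplyr::mutate(class = as.character(.data$class))

  if (!is.null(mitotic_fraction)) {
    if (is.data.frame(mitotic_fraction)) {
      out <- dplyr::left_join(out, mitotic_fraction, by = by)
    } else {
      out$mitotic_fraction <- mitotic_fraction
    }
    out$per_100_cells <- per_100_cells(out$mean, out$mitotic_fraction)
    out$mitotic_fraction <- NULL
  }
  out
}

#' Aberrations per 100 cells of the whole population
#'
#' Scales a per-metaphase aberration rate to the whole cell population:
#' the mean number of aberrations per metaphase multiplied by the mitotic
#' (p-H3-positive) fraction, expressed per 100 cells.
#'
#' @param mean_per_metaphase Mean aberrations per metaphase (>= 0).
#' @param mitotic_fraction Fraction of mitotic cells, in \[0, 1\].
#' @return Aberrations per 100 cells (vectorised).
#' @examples
#' per_100_cells(0.8, 0.04) # 3.2
#' @export
per_100_cells <- function(mean_per_metaphase, mitotic_fraction) {
  if (any(mitotic_fraction < 0 | mitotic_fraction > 1, na.rm = TRUE)) {
    stop("`mitotic_fraction` must lie in [0, 1]", call. = FALSE)
  }
  mean_per_metaphase * mitotic_fraction * 100
}

#' Sister chromatid exchange rates
#'
#' Mean and sample standard deviation of SCE counts per metaphase by
#' condition.
#'
#' @param data Tibble with an SCE count column and a grouping column.
#' @param count Name of the count column (default `"sce"`).
#' @param by Name of the grouping column (default `"condition"`).
#' @return Tibble with `mean`, `sd` and `n` per group.
#' @export
sce_rate <- function(data, count = "sce", by = "condition") {
  miss <- setdiff(c(count, by), names(data))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(data) == 0) stop("no SCE records", call. = FALSE)
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(mean = mean(.data[[count]]), sd = stats::sd(.data[[count]]),
                     n = dplyr::n(), .groups = "drop")
}

#' Relative reporter repair efficiency
#'
#' Control-relative efficiency of a GFP-based repair reporter (DR-GFP for
#' homologous recombination, EJ5-GFP for end joining): the GFP-positive
#' percentage of a condition divided by that of its control. 1 means no
#' change; below 1 means impaired repair.
#'
#' @param gfp_condition GFP-positive percentage under the condition.
#' @param gfp_control GFP-positive percentage of the control (> 0).
#' @return Relative efficiency (vectorised over `gfp_condition`).
#' @examples
#' repair_efficiency(1, 5) # 0.2
#' @export
repair_efficiency <- function(gfp_condition, gfp_control) {
  if (any(gfp_control <= 0, na.rm = TRUE)) {
    stop("`gfp_control` must be > 0", call. = FALSE)
  }
  gfp_condition / gfp_control
}

#' Two-sided t-test between two groups
#'
#' Thin wrapper around [stats::t.test()] returning the two-sided p-value;
#' Student's pooled-variance test by default, Welch optionally.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param var_equal Assume equal variances (Student, default `TRUE`) or
#'   not (Welch).
#' @return The two-sided p-value.
#' @export
compare_groups <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("need >= 2 values per group", call. = FALSE)
  }
  stats::t.test(values_a, values_b, var.equal = var_equal,
                alternative = "two.sided")$p.value
}
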