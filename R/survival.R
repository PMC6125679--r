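#' Linear-quadratic surviving fraction
#'
#' Evaluates the linear-quadratic (LQ) dose-response
#' \eqn{SF(D) = \exp(-(\alpha D + \beta D^2))}, the standard radiobiological
#' model for clonogenic survival after ionising radiation.
#'
#' @param dose Numeric vector of doses in Gy (>= 0).
#' @param alpha Linear coefficient in Gy^-1 (>= 0).
#' @param beta Quadratic coefficient in Gy^-2 (>= 0).
#' @return Numeric vector of surviving fractions in (0, 1].
#' @examples
#' sf_lq(c(0, 2, 4), alpha = 0.25, beta = 0.03)
#' @export
sf_lq <- function(dose, alpha, beta) {
  stopifnot(is.numeric(dose), is.numeric(alpha), is.numeric(beta))
  if (any(dose < 0)) stop("`dose` must be >= 0 Gy", call. = FALSE)
  if (alpha < 0 || beta < 0) stop("`alpha` and `beta` must be >= 0", call. = FALSE)
  exp(-(alpha * dose + beta * dose^2))
}

#' Plating efficiency
#'
#' Fraction of plated single cells that grow into a countable colony:
#' the mean colony number over replicate wells divided by the number of
#' cells plated per well.
#'
#' @param colonies Integer vector of colony counts over replicate wells.
#' @param cells_plated Number of cells plated per well (> 0).
#' @return Plating efficiency as a single fraction.
#' @examples
#' plating_efficiency(c(48, 52), 500) # 0.1
#' @export
plating_efficiency <- function(colonies, cells_plated) {
  if (length(colonies) == 0) {
    stop("`colonies` is empty: at least one replicate well is required", call. = FALSE)
  }
  if (!is.numeric(colonies) || any(is.na(colonies)) || any(colonies < 0)) {
    stop("`colonies` must be non-negative counts", call. = FALSE)
  }
  if (!is.numeric(cells_plated) || length(cells_plated) != 1 || cells_plated <= 0) {
    stop("`cells_plated` must be a single count > 0", call. = FALSE)
  }
  mean(colonies) / cells_plated
}

#' Surviving fraction
#'
#' Ratio of the plating efficiency at a given dose to the plating
#' efficiency of the matched unirradiated (0 Gy) wells. Values above 1
#' (possible with noisy counts) are kept, not clipped, and trigger a
#' warning so they can be inspected.
#'
#' @param pe_dose Plating efficiency at the irradiated dose.
#' @param pe_0gy Plating efficiency at 0 Gy (> 0).
#' @return Surviving fraction (vectorised over `pe_dose`).
#' @examples
#' surviving_fraction(0.02, 0.1) # 0.2
#' @export
surviving_fraction <- function(pe_dose, pe_0gy) {
  if (!is.numeric(pe_0gy) || any(is.na(pe_0gy)) || any(pe_0gy <= 0)) {
    stop("`pe_0gy` must be > 0: a 0 Gy plating efficiency of zero makes the experiment uninterpretable",
         call. = FALSE)
  }
  sf <- pe_dose / pe_0gy
  if (any(sf > 1, na.rm = TRUE)) {
    warning("surviving fraction exceeds 1 for ", sum(sf > 1, na.rm = TRUE),
            " value(s); kept unclipped", call. = FALSE)
  }
  sf
}

#' Build survival curves from well records
#'
#' Collapses well-level colony counts into per-condition dose-response
#' points: plating efficiency per dose, surviving fraction relative to the
#' 0 Gy wells of the same condition, and a standard error from the spread
#' of per-well surviving fractions.
#'
#' @param wells A well-record table (see [read_well_records()]) with at
#'   least `dose`, `cells_plated` and `colonies` columns.
#' @param condition Column (unquoted) identifying the condition/curve;
#'   defaults to `target`.
#' @return A tibble with one row per (condition, dose): `sf`, `se`,
#'   `se0_log` (relative uncertainty of the shared 0 Gy reference, used
#'   for error propagation in [fit_linear_quadratic()]), `n_wells`, and
#'   an `over_unity` flag for SF > 1.
#' @export
survival_curve <- function(wells, condition = target) {
  condition <- rlang::enquo(condition)
  need <- c("dose", "cells_plated", "colonies")
  miss <- setdiff(need, names(wells))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)

  per_dose <- wells |>
    dplyr::mutate(.pe = .data$colonies / .data$cells_plated) |>
    dplyr::group_by(condition = !!condition, .data$dose) |>
    dplyr::summarise(
      pe = mean(.data$.pe),
      pe_sd = stats::sd(.data$.pe),
      n_wells = dplyr::n(),
      .groups = "drop"
    )

  pe0 <- per_dose |>
    dplyr::filter(.data$dose == 0) |>
    dplyr::select("condition", pe_0gy = "pe")
  if (nrow(pe0) == 0) stop("no 0 Gy wells: surviving fraction is undefined", call. = FALSE)

  # relative uncertainty of the shared 0 Gy reference: all dose points of a
  # condition divide by the same pe_0gy, so this error is common to them
  se0 <- per_dose |>
    dplyr::filter(.data$dose == 0) |>
    dplyr::transmute(.data$condition,
                     se0_log = ifelse(.data$n_wells > 1,
                                      .data$pe_sd / sqrt(.data$n_wells) / .data$pe,
                                      NA_real_))

  out <- per_dose |>
    dplyr::inner_join(pe0, by = "condition") |>
    dplyr::inner_join(se0, by = "condition") |>
    dplyr::mutate(
      sf = suppressWarnings(surviving_fraction(.data$pe, .data$pe_0gy)),
      se = ifelse(.data$n_wells > 1,
                  .data$pe_sd / .data$pe_0gy / sqrt(.data$n_wells), NA_real_),
      over_unity = .data$sf > 1
    ) |>
    dplyr::select("condition", "dose", "sf", "se", "se0_log", "n_wells",
                  "over_unity") |>
    dplyr::arrange(.data$condition, .data$dose)
  if (any(out$over_unity)) {
    warning("surviving fraction exceeds 1 for ", sum(out$over_unity),
            " point(s); kept unclipped", call. = FALSE)
  }
  out
}

#' Fit the linear-quadratic survival model
#'
#' Least-squares fit of \eqn{\ln SF = -(\alpha D + \beta D^2)} under the
#' physical constraint \eqn{\alpha, \beta \ge 0}. The log-linearisation
#' makes the LQ model linear in its parameters; the constraint is imposed
#' by active-set search over the two coefficients (at most four candidate
#' fits). Points with SF > 1 enter the fit with positive log-survival
#' rather than being clipped, which would bias \eqn{\alpha} downward.
#'
#' @param curve A survival-curve tibble (see [survival_curve()]) with
#'   `dose` and `sf` columns, or any data frame with those columns.
#' @param weights `"none"` (default) for unweighted least squares or
#'   `"inverse_se2"` to weight points by 1/se^2 (requires an `se` column).
#' @return An object of class `lq_fit`: a list with `alpha`, `beta`,
#'   `covariance` (2x2, from the linearised model; rows/columns of a
#'   coefficient pinned at the constraint boundary are zero),
#'   `residual_ss`, `n_points` and `df_residual`. Supports [tidy()],
#'   [glance()], `print()` and [ggplot2::autoplot()].
#'
#' @details
#' When the curve carries per-point standard errors (an `se` column, as
#' produced by [survival_curve()] from replicate wells), the coefficient
#' covariance is obtained by propagating those measurement errors through
#' the linear estimator (delta method on the log scale), which reflects
#' the strong dose-dependence of counting noise in clonogenic data. With
#' no `se` column the covariance falls back to the homoscedastic
#' residual-based estimate.
#' @examples
#' curve <- tibble::tibble(dose = c(0, 2, 4, 6, 8),
#'                         sf = sf_lq(c(0, 2, 4, 6, 8), 0.3, 0.03))
#' fit_linear_quadratic(curve)
#' @export
fit_linear_quadratic <- function(curve, weights = c("none", "inverse_se2")) {
  weights <- match.arg(weights)
  if (!all(c("dose", "sf") %in% names(curve))) {
    stop("`curve` must have `dose` and `sf` columns", call. = FALSE)
  }
  dose <- curve$dose
  sf <- curve$sf
  bad <- which(is.na(sf) | sf <= 0)
  if (length(bad) > 0) {
    stop("surviving fraction must be > 0 for fitting; offending dose(s): ",
         paste(dose[bad], collapse = ", "), " Gy", call. = FALSE)
  }
  if (length(unique(dose)) < 3) {
    stop("at least 3 distinct dose points (including 0 Gy) are required", call. = FALSE)
  }
  w <- rep(1, length(dose))
  if (weights == "inverse_se2") {
    if (!"se" %in% names(curve) || any(is.na(curve$se)) || any(curve$se <= 0)) {
      stop("`weights = \"inverse_se2\"` needs a positive `se` column", call. = FALSE)
    }
    # se on the SF scale; delta method gives se/sf on the log scale
    w <- (sf / curve$se)^2
  }

  y <- -log(sf)
  X <- cbind(D = dose, D2 = dose^2)

  # active-set search: fit each feasible subset, keep the lowest RSS
  fit_subset <- function(active) {
    if (length(active) == 0) {
      coefs <- c(D = 0, D2 = 0)
      rss <- sum(w * y^2)
      cov <- matrix(0, 2, 2)
      df <- length(y)
    } else {
      Xa <- X[, active, drop = FALSE]
      fit <- stats::lm.wfit(Xa, y, w)
      coefs <- c(D = 0, D2 = 0)
      coefs[active] <- fit$coefficients
      rss <- sum(w * fit$residuals^2)
      df <- length(y) - length(active)
      cov <- matrix(0, 2, 2, dimnames = list(c("D", "D2"), c("D", "D2")))
      if (df > 0) {
        sigma2 <- rss / df
        XtWX <- crossprod(Xa * sqrt(w))
        cov[active, active] <- sigma2 * solve(XtWX)
      }
    }
    list(coefs = coefs, rss = rss, cov = cov, df = df)
  }

  candidates <- list(c("D", "D2"), "D", "D2", character(0))
  best <- NULL
  best_active <- NULL
  for (active in candidates) {
    cand <- fit_subset(active)
    if (all(cand$coefs >= -1e-12)) {
      if (is.null(best) || cand$rss < best$rss - 1e-12) {
        best <- cand
        best_active <- active
      }
    }
  }
  coefs <- pmax(best$coefs, 0)

  # with per-point standard errors available, propagate them through the
  # linear estimator instead of assuming homoscedastic residuals
  has_se <- "se" %in% names(curve) &&
    all(is.finite(curve$se[dose > 0]) & curve$se[dose > 0] > 0)
  if (has_se && length(best_active) > 0) {
    se_log <- ifelse(dose > 0, curve$se / sf, 0)  # delta method, log scale
    V <- diag(se_log^2, length(se_log))
    if ("se0_log" %in% names(curve) && all(is.finite(curve$se0_log))) {
      # shared 0 Gy reference error is common to every dose > 0 point
      shared <- as.numeric(dose > 0)
      V <- V + curve$se0_log[1]^2 * tcrossprod(shared)
    }
    Xa <- X[, best_active, drop = FALSE]
    Ca <- solve(crossprod(Xa * sqrt(w)), t(Xa * w))
    cov_a <- Ca %*% V %*% t(Ca)
    cov <- matrix(0, 2, 2, dimnames = list(c("D", "D2"), c("D", "D2")))
    cov[best_active, best_active] <- cov_a
    best$cov <- cov
  }
  dimnames(best$cov) <- list(c("alpha", "beta"), c("alpha", "beta"))

  structure(
    list(
      alpha = unname(coefs["D"]),
      beta = unname(coefs["D2"]),
      covariance = best$cov,
      residual_ss = best$rss,
      n_points = length(y),
      df_residual = best$df,
      weights = weights
    ),
    class = "lq_fit"
  )
}

#' @export
print.lq_fit <- function(x, ...) {
  cat("Linear-quadratic survival fit\n")
  cat(sprintf("  alpha = %.4f Gy^-1 (se %.4f)\n", x$alpha, sqrt(x$covariance[1, 1])))
  cat(sprintf("  beta  = %.4f Gy^-2 (se %.4f)\n", x$beta, sqrt(x$covariance[2, 2])))
  cat(sprintf("  %d dose points, residual SS %.4g\n", x$n_points, x$residual_ss))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a linear-quadratic fit
#'
#' @param x An `lq_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`.
#' @method tidy lq_fit
#' @export
tidy.lq_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha, x$beta),
    std.error = sqrt(diag(x$covariance))
  )
}

#' One-row summary of a linear-quadratic fit
#'
#' @param x An `lq_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `alpha`, `beta`, `residual_ss`,
#'   `df.residual` and `nobs`.
#' @method glance lq_fit
#' @export
glance.lq_fit <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha,
    beta = x$beta,
    residual_ss = x$residual_ss,
    df.residual = x$df_residual,
    nobs = x$n_points
  )
}

#' Dose producing a target surviving fraction
#'
#' Inverts the fitted LQ curve at a target SF: the unique positive root of
#' \eqn{\beta D^2 + \alpha D + \ln(SF) = 0}, by the quadratic formula
#' (or \eqn{D = -\ln(SF)/\alpha} when \eqn{\beta = 0}).
#'
#' @param fit An `lq_fit` object, or a list with `alpha` and `beta`.
#' @param sf_target Target surviving fraction, strictly between 0 and 1.
#' @return Dose in Gy.
#' @examples
#' dose_at_sf(list(alpha = 0.5, beta = 0), 0.1) # log(10)/0.5
#' @export
dose_at_sf <- function(fit, sf_target = 0.10) {
  alpha <- fit$alpha
  beta <- fit$beta
  if (!is.numeric(sf_target) || length(sf_target) != 1 ||
      sf_target <= 0 || sf_target >= 1) {
    stop("`sf_target` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (alpha < 0 || beta < 0) stop("`alpha` and `beta` must be >= 0", call. = FALSE)
  if (alpha + beta <= 0) {
    stop("flat survival curve (alpha = beta = 0) never reaches the target SF",
         call. = FALSE)
  }
  ln_sf <- log(sf_target)
  if (beta == 0) {
    -ln_sf / alpha
  } else {
    (-alpha + sqrt(alpha^2 - 4 * beta * ln_sf)) / (2 * beta)
  }
}

#' Sensitization enhancement ratio at 10% survival (SER10)
#'
#' Ratio of the dose at which the control curve reaches a surviving
#' fraction of 0.10 to the dose at which the treated curve does. Values
#' above 1 indicate radiosensitization by the treatment.
#'
#' @param control_fit,treated_fit `lq_fit` objects (or lists with `alpha`
#'   and `beta`).
#' @param sf_target Surviving fraction at which doses are compared
#'   (default 0.10).
#' @return The dimensionless enhancement ratio.
#' @export
ser10 <- function(control_fit, treated_fit, sf_target = 0.10) {
  dose_at_sf(control_fit, sf_target) / dose_at_sf(treated_fit, sf_target)
}

#' Compare survival curves by two-way ANOVA
#'
#' Fixed-effects two-way ANOVA with survival as the dependent variable and
#' dose and condition as the two independent variables. Dose is treated as
#' categorical and the dose-by-condition interaction is included by
#' default; survival enters on the log scale by default.
#'
#' @param data Data frame of well-level surviving fractions with columns
#'   named by `sf`, `dose` and `condition`.
#' @param sf,dose,condition Column names (strings) of the response, dose
#'   and condition variables.
#' @param log_sf Analyse log(SF) (default `TRUE`) or raw SF.
#' @param interaction Include the dose-by-condition interaction (default
#'   `TRUE`).
#' @return A list with `p_condition` (condition main effect),
#'   `p_interaction` (`NA` if not fitted) and `table`, the full ANOVA
#'   table as a tibble.
#' @export
compare_curves_anova <- function(data, sf = "sf", dose = "dose",
                                 condition = "condition",
                                 log_sf = TRUE, interaction = TRUE) {
  need <- c(sf, dose, condition)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df <- data.frame(
    y = data[[sf]],
    dose = factor(data[[dose]]),
    condition = factor(data[[condition]])
  )
  if (nlevels(df$dose) < 2 || nlevels(df$condition) < 2) {
    stop("need >= 2 doses and >= 2 conditions", call. = FALSE)
  }
  cells <- table(df$dose, df$condition)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    lab <- paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
                 sep = " Gy / ", collapse = "; ")
    stop("empty design cell(s): ", lab, call. = FALSE)
  }
  if (any(cells < 2)) {
    stop("each dose-by-condition cell needs >= 2 replicates", call. = FALSE)
  }
  if (log_sf) {
    if (any(df$y <= 0)) stop("log(SF) requires all SF > 0", call. = FALSE)
    df$y <- log(df$y)
  }
  form <- if (interaction) y ~ dose * condition else y ~ dose + condition
  fit <- stats::aov(form, data = df)
  tab <- stats::summary.aov(fit)[[1]]
  table <- tibble::tibble(
    term = trimws(rownames(tab)),
    df = tab$Df,
    sumsq = tab$`Sum Sq`,
    meansq = tab$`Mean Sq`,
    statistic = tab$`F value`,
    p.value = tab$`Pr(>F)`
  )
  p_cond <- table$p.value[table$term == "condition"]
  p_int <- table$p.value[table$term == "dose:condition"]
  list(
    p_condition = if (length(p_cond)) p_cond else NA_real_,
    p_interaction = if (length(p_int)) p_int else NA_real_,
    table = table
  )
}
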