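test_that("plating efficiency is mean colonies over cells plated", {
  expect_equal(plating_efficiency(c(48, 52), 500), 0.1)
  expect_equal(plating_efficiency(c(50), 500), 0.1)
  expect_equal(plating_efficiency(0, 1000), 0)
  expect_error(plating_efficiency(numeric(0), 500), "empty")
  expect_error(plating_efficiency(c(10), 0), "cells_plated")
})

test_that("surviving fraction is the PE ratio, unclipped above 1", {
  expect_equal(surviving_fraction(0.02, 0.1), 0.2)
  expect_equal(surviving_fraction(0.1, 0.1), 1)
  expect_warning(sf <- surviving_fraction(0.12, 0.1), "exceeds 1")
  expect_equal(sf, 1.2)
  expect_error(surviving_fraction(0.05, 0), "0 Gy")
})

test_that("survival_curve collapses wells into SF points relative to 0 Gy", {
  wells <- dplyr::bind_rows(
    make_wells(n = 3, dose = 0, colonies = c(48, 50, 52)),
    make_wells(n = 3, dose = 2, colonies = c(9, 10, 11), plate = "P002"),
    make_wells(n = 3, dose = 4, colonies = c(4, 5, 6), plate = "P003")
  )
  cv <- survival_curve(wells)
  expect_equal(cv$sf[cv$dose == 0], 1)
  expect_equal(cv$sf[cv$dose == 2], (10 / 500) / (50 / 500))
  expect_equal(cv$n_wells, rep(3, 3))
  expect_false(any(cv$over_unity))
})

test_that("LQ fit recovers exact parameters from noiseless curves", {
  d <- c(0, 2, 4, 6, 8)
  fit <- fit_linear_quadratic(tibble::tibble(dose = d, sf = sf_lq(d, 0.3, 0.03)))
  expect_equal(fit$alpha, 0.3, tolerance = 1e-6)
  expect_equal(fit$beta, 0.03, tolerance = 1e-6)
  expect_lt(fit$residual_ss, 1e-12)

  # flat curve
  flat <- fit_linear_quadratic(tibble::tibble(dose = d, sf = rep(1, 5)))
  expect_equal(flat$alpha, 0)
  expect_equal(flat$beta, 0)
})

test_that("LQ fit respects the non-negativity constraint", {
  # data with upward log-survival curvature would give beta < 0 unconstrained
  d <- c(0, 2, 4, 6, 8)
  sf <- exp(-(0.5 * d - 0.02 * d^2))
  fit <- fit_linear_quadratic(tibble::tibble(dose = d, sf = sf))
  expect_gte(fit$beta, 0)
  expect_gte(fit$alpha, 0)
  # covariance symmetric PSD
  expect_equal(fit$covariance, t(fit$covariance))
  expect_true(all(eigen(fit$covariance, only.values = TRUE)$values >= -1e-12))
})

test_that("LQ fit rejects bad input", {
  expect_error(fit_linear_quadratic(tibble::tibble(dose = c(0, 2), sf = c(1, 0.5))),
               "3 distinct")
  expect_error(
    fit_linear_quadratic(tibble::tibble(dose = c(0, 2, 4), sf = c(1, 0.5, 0))),
    "4"
  )
})

test_that("tidy and glance expose the fit as tibbles", {
  d <- c(0, 2, 4, 6, 8)
  fit <- fit_linear_quadratic(tibble::tibble(dose = d, sf = sf_lq(d, 0.3, 0.03)))
  td <- tidy(fit)
  expect_equal(td$term, c("alpha", "beta"))
  expect_equal(td$estimate, c(0.3, 0.03), tolerance = 1e-6)
  gl <- glance(fit)
  expect_equal(gl$nobs, 5)
})

test_that("dose_at_sf inverts the LQ model in closed form", {
  expect_equal(dose_at_sf(list(alpha = 0.5, beta = 0), 0.1), log(10) / 0.5)
  expect_equal(dose_at_sf(list(alpha = 0.2, beta = 0.02), 0.1), 6.8376,
               tolerance = 1e-4)
  expect_error(dose_at_sf(list(alpha = 0.2, beta = 0.02), 1), "between 0 and 1")
  expect_error(dose_at_sf(list(alpha = 0, beta = 0), 0.1), "flat")
})

test_that("dose_at_sf round-trips through the forward model", {
  set.seed(1)
  for (i in 1:25) {
    alpha <- runif(1, 0.05, 0.6)
    beta <- runif(1, 0.005, 0.08)
    sft <- runif(1, 0.02, 0.8)
    d <- dose_at_sf(list(alpha = alpha, beta = beta), sft)
    expect_equal(sf_lq(d, alpha, beta), sft, tolerance = 1e-8)
  }
})

test_that("SER10 matches the quadratic-root ratio and is 1 for identical fits", {
  fit <- list(alpha = 0.2, beta = 0.02)
  expect_identical(ser10(fit, fit), 1)
  expect_equal(ser10(list(alpha = 0.2, beta = 0.02),
                     list(alpha = 0.4, beta = 0.04)),
               1.673, tolerance = 1e-3)
  # flatter treated curve: protection, SER10 < 1
  expect_lt(ser10(list(alpha = 0.2, beta = 0.02),
                  list(alpha = 0.1, beta = 0.01)), 1)
})

test_that("SER10 scale behaviour matches the closed form", {
  # beta = 0: doses scale as 1/k, so scaling both fits by k leaves SER10 at 1
  a <- list(alpha = 0.3, beta = 0)
  ak <- list(alpha = 0.6, beta = 0)
  expect_equal(ser10(a, a), ser10(ak, ak))
  expect_equal(ser10(a, ak), 2)
  # beta > 0: SER10 of a fit vs its k-scaled self differs from k
  b <- list(alpha = 0.2, beta = 0.02)
  bk <- list(alpha = 0.4, beta = 0.04)
  expect_false(isTRUE(all.equal(ser10(b, bk), 2)))
})

test_that("two-way ANOVA separates shifted curves and not duplicated ones", {
  set.seed(42)
  grid <- tidyr::expand_grid(dose = c(0, 2, 4), rep = 1:3)
  base <- sf_lq(grid$dose, 0.3, 0.03)
  a <- tibble::tibble(dose = grid$dose, condition = "A",
                      sf = base * exp(rnorm(nrow(grid), 0, 0.01)))
  # duplicated condition: no condition effect at all
  dup <- dplyr::bind_rows(a, dplyr::mutate(a, condition = "B"))
  res <- compare_curves_anova(dup)
  expect_equal(res$p_condition, 1, tolerance = 1e-6)

  # strongly shifted condition: detected
  b <- dplyr::mutate(a, condition = "B", sf = sf * 0.2)
  res2 <- compare_curves_anova(dplyr::bind_rows(a, b))
  expect_lt(res2$p_condition, 0.05)
})

test_that("ANOVA F statistics match a hand sum-of-squares decomposition", {
  # balanced 2 doses x 2 conditions x 2 replicates toy table
  df <- tibble::tibble(
    dose = rep(c(0, 2), each = 4),
    condition = rep(rep(c("A", "B"), each = 2), 2),
    sf = c(1.0, 1.2, 0.8, 1.0, 0.5, 0.7, 0.2, 0.4)
  )
  res <- compare_curves_anova(df, log_sf = FALSE)
  y <- df$sf
  gm <- mean(y)
  m_d <- tapply(y, df$dose, mean)
  m_c <- tapply(y, df$condition, mean)
  m_dc <- tapply(y, paste(df$dose, df$condition), mean)
  ss_d <- 4 * sum((m_d - gm)^2)
  ss_c <- 4 * sum((m_c - gm)^2)
  ss_cell <- 2 * sum((m_dc - gm)^2)
  ss_int <- ss_cell - ss_d - ss_c
  ss_err <- sum((y - m_dc[paste(df$dose, df$condition)])^2)
  f_c <- (ss_c / 1) / (ss_err / 4)
  f_int <- (ss_int / 1) / (ss_err / 4)
  tab <- res$table
  expect_equal(tab$statistic[tab$term == "condition"], f_c, tolerance = 1e-10)
  expect_equal(tab$statistic[tab$term == "dose:condition"], f_int,
               tolerance = 1e-10)
})

test_that("ANOVA rejects designs with empty or singleton cells", {
  df <- tibble::tibble(
    dose = c(0, 0, 2, 2, 0, 0),
    condition = c("A", "A", "A", "A", "B", "B"),
    sf = runif(6)
  )
  expect_error(compare_curves_anova(df), "empty design cell")
})
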