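#' Per-gene surviving fractions from screen well records
#'
#' Pairs each irradiated well with the 0 Gy well at the same
#' (run, plate, well) position and computes a per-well surviving fraction
#' \eqn{SF = (colonies_{IR}/cells)/(colonies_{0Gy}/cells)}. Wells whose
#' 0 Gy partner produced no colonies are dropped with a warning (their SF
#' is undefined).
#'
#' @param wells Well-record table covering both the 0 Gy and the
#'   irradiated plates, with a `role` column (joined from the plate
#'   layout or produced by [simulate_screen()]).
#' @return A tibble with one row per irradiated well: `run_id`,
#'   `plate_id`, `well_id`, `target`, `sirna_id`, `role`, `dose`, `sf`.
#' @export
screen_sf <- function(wells) {
  validate_well_records(wells)
  if (!"role" %in% names(wells)) {
    stop("`wells` needs a `role` column (join a plate layout first)", call. = FALSE)
  }
  w0 <- wells |>
    dplyr::filter(.data$dose == 0) |>
    dplyr::transmute(.data$run_id, .data$plate_id, .data$well_id,
                     pe0 = .data$colonies / .data$cells_plated)
  wd <- dplyr::filter(wells, .data$dose > 0)
  if (nrow(w0) == 0 || nrow(wd) == 0) {
    stop("both 0 Gy and irradiated wells are required", call. = FALSE)
  }
  out <- wd |>
    dplyr::inner_join(w0, by = c("run_id", "plate_id", "well_id")) |>
    dplyr::mutate(sf = (.data$colonies / .data$cells_plated) / .data$pe0)
  undefined <- !is.finite(out$sf)
  if (any(undefined)) {
    warning(sum(undefined), " well(s) dropped: 0 Gy partner had no colonies",
            call. = FALSE)
    out <- out[!undefined, ]
  }
  dplyr::select(out, "run_id", "plate_id", "well_id", "target", "sirna_id",
                "role", "dose", "sf")
}

#' Normalize surviving fractions to non-targeting controls
#'
#' Divides every well's SF by a location estimate (median by default) of
#' the non-targeting control SFs of the same run, so that the NT
#' population of each run is centred at 1 and plate-to-run throughput
#' differences cancel.
#'
#' @param sf_table Output of [screen_sf()] (needs `run_id`, `role`, `sf`).
#' @param location `"median"` (default, robust to control outliers) or
#'   `"mean"`.
#' @return The input tibble with a `normalized_sf` column.
#' @export
normalize_sf <- function(sf_table, location = c("median", "mean")) {
  location <- match.arg(location)
  need <- c("run_id", "role", "sf")
  miss <- setdiff(need, names(sf_table))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  loc_fun <- if (location == "median") stats::median else mean
  refs <- sf_table |>
    dplyr::filter(.data$role == "nt_control") |>
    dplyr::group_by(.data$run_id) |>
    dplyr::summarise(.nt_ref = loc_fun(.data$sf), .groups = "drop")
  no_nt <- setdiff(unique(sf_table$run_id), refs$run_id)
  if (length(no_nt) > 0) {
    stop("run(s) without non-targeting control wells: ",
         paste(no_nt, collapse = ", "), call. = FALSE)
  }
  if (any(refs$.nt_ref <= 0)) {
    stop("non-positive NT reference SF in run(s): ",
         paste(refs$run_id[refs$.nt_ref <= 0], collapse = ", "), call. = FALSE)
  }
  sf_table |>
    dplyr::left_join(refs, by = "run_id") |>
    dplyr::mutate(normalized_sf = .data$sf / .data$.nt_ref) |>
    dplyr::select(-".nt_ref")
}

# mean absolute deviation about the mean (the screen's spread estimator)
mad_mean <- function(x) mean(abs(x - mean(x)))

#' R-scores and ascending ranks
#'
#' Per run, scores every sample gene as
#' \deqn{R = (\mathrm{normalized\ SF} - 1) / \mathrm{MAD}(\mathrm{NT\ normalized\ SF})}
#' where MAD is the mean absolute deviation about the mean (optionally the
#' median-based form). Negative R-scores denote radiosensitization, so
#' genes are ranked in ascending R-score order (rank 1 = strongest
#' sensitizer); ties receive average ranks. Genes with several wells are
#' aggregated by their mean normalized SF before scoring. Control wells
#' are scored too but excluded from the ranking (`rank = NA`).
#'
#' @param normalized Output of [normalize_sf()].
#' @param mad `"mean"` (default; mean |x - mean(x)|) or `"median"`
#'   (median |x - median(x)|) deviation of the NT normalized SFs.
#' @return A tibble with one row per (run, target): `run_id`, `gene_id`,
#'   `role`, `normalized_sf`, `r_score`, `rank`.
#' @export
r_score <- function(normalized, mad = c("mean", "median")) {
  mad <- match.arg(mad)
  need <- c("run_id", "target", "role", "normalized_sf")
  miss <- setdiff(need, names(normalized))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  mad_fun <- if (mad == "mean") mad_mean else function(x) stats::median(abs(x - stats::median(x)))

  per_gene <- normalized |>
    dplyr::group_by(.data$run_id, gene_id = .data$target, role = .data$role) |>
    dplyr::summarise(normalized_sf = mean(.data$normalized_sf), n_wells = dplyr::n(),
                     .groups = "drop")

  spread <- normalized |>
    dplyr::filter(.data$role == "nt_control") |>
    dplyr::group_by(.data$run_id) |>
    dplyr::summarise(.mad = mad_fun(.data$normalized_sf), .n_nt = dplyr::n(),
                     .groups = "drop")
  if (any(spread$.n_nt < 2)) {
    stop("run(s) with < 2 NT wells: ",
         paste(spread$run_id[spread$.n_nt < 2], collapse = ", "), call. = FALSE)
  }
  if (any(spread$.mad == 0)) {
    stop("degenerate NT controls (zero deviation) in run(s): ",
         paste(spread$run_id[spread$.mad == 0], collapse = ", "), call. = FALSE)
  }

  per_gene |>
    dplyr::left_join(spread, by = "run_id") |>
    dplyr::mutate(r_score = (.data$normalized_sf - 1) / .data$.mad) |>
    dplyr::group_by(.data$run_id) |>
    dplyr::mutate(rank = {
      r <- rep(NA_real_, dplyr::n())
      s <- .data$role == "sample"
      r[s] <- rank(.data$r_score[s], ties.method = "average")
      r
    }) |>
    dplyr::ungroup() |>
    dplyr::select("run_id", "gene_id", "role", "normalized_sf", "r_score", "rank")
}

#' Rank product across replicate runs
#'
#' Geometric mean of each gene's ascending R-score rank across k replicate
#' runs: \eqn{RP_g = (\prod_i r_{g,i})^{1/k}}. Small rank products flag
#' genes consistently top-ranked (strongly sensitizing) in every run.
#'
#' @param rscores An R-score table covering k >= 2 runs (output of
#'   [r_score()] on multi-run data), or a list of per-run tables which are
#'   row-bound first. Only `role == "sample"` rows enter.
#' @return A tibble with one row per gene, ascending in `rp`: `gene_id`,
#'   `rp`, `n_runs`, and a `ranks` list-column of per-run ranks (named by
#'   run).
#' @export
rank_product <- function(rscores) {
  if (is.list(rscores) && !is.data.frame(rscores)) {
    rscores <- dplyr::bind_rows(rscores)
  }
  samples <- dplyr::filter(rscores, .data$role == "sample")
  runs <- unique(samples$run_id)
  k <- length(runs)
  if (k < 2) stop("rank product needs >= 2 replicate runs", call. = FALSE)
  wide <- samples |>
    dplyr::select("gene_id", "run_id", "rank") |>
    tidyr::pivot_wider(names_from = "run_id", values_from = "rank")
  rank_mat <- as.matrix(wide[, runs, drop = FALSE])
  if (anyNA(rank_mat)) {
    bad <- wide$gene_id[apply(rank_mat, 1, anyNA)]
    stop("gene(s) missing from at least one run: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    gene_id = wide$gene_id,
    rp = exp(rowMeans(log(rank_mat))),
    n_runs = k,
    ranks = lapply(seq_len(nrow(rank_mat)), function(i) rank_mat[i, ])
  ) |>
    dplyr::arrange(.data$rp, .data$gene_id)
}

#' Permutation p-values for rank products
#'
#' Significance of each gene's rank product under the null that its rank
#' in each run is an independent uniform draw on 1..n (equivalently, that
#' each run's rank column is independently permuted). When \eqn{n^k} is
#' small the null distribution is enumerated exhaustively and the p-value
#' is exact; otherwise Monte-Carlo permutations are used with the +1
#' pseudo-count correction
#' \eqn{p = (1 + \#\{RP^{perm} \le RP_g\})/(1 + B)}.
#'
#' @param rp_result Output of [rank_product()].
#' @param n_genes Number of genes ranked per run (defaults to the number
#'   of genes in `rp_result`).
#' @param n_permutations Monte-Carlo permutations (default 10000;
#'   must be >= 100).
#' @param seed Optional integer seed for the Monte-Carlo draw.
#' @param exhaustive_limit Enumerate the null exactly when
#'   `n_genes^k` does not exceed this (default 1e6).
#' @return `rp_result` with a `p_perm` column and a `p_method` attribute
#'   (`"exhaustive"` or `"permutation"`).
#' @export
rank_product_pvalues <- function(rp_result, n_genes = nrow(rp_result),
                                 n_permutations = 10000, seed = NULL,
                                 exhaustive_limit = 1e6) {
  k <- rp_result$n_runs[1]
  n <- n_genes
  log_rp_obs <- k * log(rp_result$rp)   # log of the rank product^k (= product)

  if (n^k <= exhaustive_limit) {
    # exact: enumerate all n^k equiprobable rank tuples
    tuples <- as.matrix(expand.grid(rep(list(seq_len(n)), k)))
    log_prod <- rowSums(log(tuples))
    p <- vapply(log_rp_obs, function(lo) {
      mean(log_prod <= lo + 1e-9)
    }, numeric(1))
    method <- "exhaustive"
  } else {
    if (n_permutations < 100) stop("`n_permutations` must be >= 100", call. = FALSE)
    draw <- function() {
      perm_ranks <- matrix(0, n, k)
      for (j in seq_len(k)) perm_ranks[, j] <- sample.int(n)
      rowSums(log(perm_ranks))
    }
    count <- integer(length(log_rp_obs))
    run_perms <- function() {
      for (b in seq_len(n_permutations)) {
        log_perm <- draw()
        count <<- count + (log_perm <= log_rp_obs + 1e-9)
      }
    }
    if (is.null(seed)) run_perms() else withr::with_seed(seed, run_perms())
    p <- (1 + count) / (1 + n_permutations)
    method <- "permutation"
  }
  out <- dplyr::mutate(rp_result, p_perm = p)
  attr(out, "p_method") <- method
  out
}

#' Z-factor assay quality
#'
#' Screening-window coefficient of Zhang, Chung and Oldenburg (1999):
#' \deqn{Z = 1 - 3(\sigma_+ + \sigma_-)/|\mu_+ - \mu_-|}
#' between the positive (radiosensitizing, e.g. PRKDC siRNA) and negative
#' (non-targeting) control populations on the normalized SF scale.
#' Z above 0 indicates a usable assay window; 1 is a perfect assay.
#'
#' @param neg Normalized SF values of the negative (NT) control wells.
#' @param pos Normalized SF values of the positive control wells.
#' @return A one-row tibble: `mu_pos`, `sd_pos`, `mu_neg`, `sd_neg`,
#'   `z_factor`.
#' @examples
#' z_factor(neg = c(0.95, 1.0, 1.05), pos = c(0.35, 0.4, 0.45))
#' @export
z_factor <- function(neg, pos) {
  if (length(neg) < 2 || length(pos) < 2) {
    stop("need >= 2 wells per control group", call. = FALSE)
  }
  mu_neg <- mean(neg); sd_neg <- stats::sd(neg)
  mu_pos <- mean(pos); sd_pos <- stats::sd(pos)
  if (mu_pos == mu_neg) {
    stop("control means are equal: Z-factor is undefined", call. = FALSE)
  }
  tibble::tibble(
    mu_pos = mu_pos, sd_pos = sd_pos,
    mu_neg = mu_neg, sd_neg = sd_neg,
    z_factor = 1 - 3 * (sd_pos + sd_neg) / abs(mu_pos - mu_neg)
  )
}

#' Select the top screen hits
#'
#' First `n` genes by ascending score: R-score for a primary screen
#' ranking, rank product for a secondary confirmation ranking. Ties are
#' broken by average rank (when per-run ranks are available) and then
#' lexicographic gene id, so selection is deterministic.
#'
#' @param ranking A tibble with `gene_id` and either an `rp` or an
#'   `r_score` column; the first of those present is the score.
#' @param n Number of hits to take (default 240, the size of a secondary
#'   confirmation screen).
#' @return Character vector of `n` gene ids in selection order.
#' @export
select_top_hits <- function(ranking, n = 240) {
  score_col <- intersect(c("rp", "r_score"), names(ranking))[1]
  if (is.na(score_col)) stop("`ranking` needs an `rp` or `r_score` column", call. = FALSE)
  if (n > nrow(ranking)) stop("`n` exceeds the number of genes", call. = FALSE)
  if (n == 0) return(character(0))
  avg_rank <- if ("ranks" %in% names(ranking)) {
    vapply(ranking$ranks, mean, numeric(1))
  } else if ("rank" %in% names(ranking)) {
    ranking$rank
  } else {
    rep(0, nrow(ranking))
  }
  ord <- order(ranking[[score_col]], avg_rank, ranking$gene_id)
  ranking$gene_id[ord][seq_len(n)]
}
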