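#' Configuration for a synthetic radiosensitivity screen
#'
#' Bundles and validates every knob of the screen generator. Defaults
#' describe a plate-based clonogenic screen at a single screening dose of
#' 7 Gy with HeLa-like linear-quadratic parameters; per-well cell numbers
#' and plating efficiency are not dictated by any published screen design
#' and are documented, invented defaults.
#'
#' @param n_genes Number of library genes.
#' @param wells_per_plate Total wells per plate (sample + control wells).
#' @param nt_wells_per_plate Non-targeting control wells per plate.
#' @param pos_ctrl_wells_per_plate Positive control (PRKDC-like) wells per
#'   plate.
#' @param n_plates Plates per run; derived from `n_genes` and the sample
#'   wells per plate when `NULL`.
#' @param cells_plated Cells plated per well.
#' @param base_pe Unirradiated plating efficiency, in (0, 1].
#' @param dose Screening dose in Gy.
#' @param alpha0,beta0 Baseline linear-quadratic coefficients (Gy^-1,
#'   Gy^-2) of the unperturbed cell line.
#' @param effect_model How knockdown effects act; only
#'   `"alpha_multiplier"` (a gene-specific multiplier on alpha) is
#'   implemented.
#' @param hit_fraction Fraction of genes that are true radiosensitizers.
#' @param hit_effect_range Range of alpha multipliers for hits (both >= 1);
#'   multipliers are drawn uniformly from it.
#' @param pos_ctrl_multiplier Alpha multiplier of the positive control.
#' @param plate_effect_sd Standard deviation of the log-normal
#'   multiplicative plate effect on plating efficiency (each physical
#'   plate, including each dose copy, gets its own draw).
#' @param n_replicate_runs Independent replicate runs sharing one truth
#'   table.
#' @param noise `"poisson"` (default), `"negbin"` (overdispersed, see
#'   `nb_size`), or `"none"` (counts are expectations rounded to the
#'   nearest integer).
#' @param nb_size Negative-binomial size (dispersion) parameter when
#'   `noise = "negbin"`.
#' @param seed Integer seed; identical config and seed give bit-identical
#'   output tables.
#' @return A validated `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_genes = 1000,
                              wells_per_plate = 96,
                              nt_wells_per_plate = 4,
                              pos_ctrl_wells_per_plate = 4,
                              n_plates = NULL,
                              cells_plated = 2000,
                              base_pe = 0.5,
                              dose = 7,
                              alpha0 = 0.25,
                              beta0 = 0.03,
                              effect_model = "alpha_multiplier",
                              hit_fraction = 0.05,
                              hit_effect_range = c(1.6, 2.5),
                              pos_ctrl_multiplier = 2.5,
                              plate_effect_sd = 0.1,
                              n_replicate_runs = 1,
                              noise = c("poisson", "negbin", "none"),
                              nb_size = 10,
                              seed = 1L) {
  noise <- match.arg(noise)
  check_count <- function(x, name, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
      stop("`", name, "` must be an integer >= ", min, call. = FALSE)
    }
  }
  check_count(n_genes, "n_genes")
  check_count(wells_per_plate, "wells_per_plate")
  check_count(nt_wells_per_plate, "nt_wells_per_plate")
  check_count(pos_ctrl_wells_per_plate, "pos_ctrl_wells_per_plate")
  check_count(cells_plated, "cells_plated")
  check_count(n_replicate_runs, "n_replicate_runs")
  if (!is.numeric(base_pe) || base_pe <= 0 || base_pe > 1) {
    stop("`base_pe` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(dose) || dose <= 0) stop("`dose` must be > 0 Gy", call. = FALSE)
  if (alpha0 < 0) stop("`alpha0` must be >= 0", call. = FALSE)
  if (beta0 < 0) stop("`beta0` must be >= 0", call. = FALSE)
  if (!identical(effect_model, "alpha_multiplier")) {
    stop("`effect_model` must be \"alpha_multiplier\"", call. = FALSE)
  }
  if (hit_fraction < 0 || hit_fraction > 1) {
    stop("`hit_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (length(hit_effect_range) != 2 || any(hit_effect_range < 1) ||
      hit_effect_range[1] > hit_effect_range[2]) {
    stop("`hit_effect_range` must be an increasing pair of multipliers >= 1",
         call. = FALSE)
  }
  if (pos_ctrl_multiplier < 1) stop("`pos_ctrl_multiplier` must be >= 1", call. = FALSE)
  if (plate_effect_sd < 0) stop("`plate_effect_sd` must be >= 0", call. = FALSE)
  if (noise == "negbin" && (!is.numeric(nb_size) || nb_size <= 0)) {
    stop("`nb_size` must be > 0", call. = FALSE)
  }
  samples_per_plate <- wells_per_plate - nt_wells_per_plate - pos_ctrl_wells_per_plate
  if (samples_per_plate < 1) {
    stop("`wells_per_plate` must exceed the number of control wells", call. = FALSE)
  }
  derived_plates <- ceiling(n_genes / samples_per_plate)
  if (is.null(n_plates)) {
    n_plates <- derived_plates
  } else {
    check_count(n_plates, "n_plates")
    if (n_plates < derived_plates) {
      stop("`n_plates` too small: ", n_genes, " genes need >= ", derived_plates,
           " plates of ", samples_per_plate, " sample wells", call. = FALSE)
    }
  }
  structure(
    list(n_genes = as.integer(n_genes),
         wells_per_plate = as.integer(wells_per_plate),
         nt_wells_per_plate = as.integer(nt_wells_per_plate),
         pos_ctrl_wells_per_plate = as.integer(pos_ctrl_wells_per_plate),
         n_plates = as.integer(n_plates),
         samples_per_plate = as.integer(samples_per_plate),
         cells_plated = as.integer(cells_plated),
         base_pe = base_pe, dose = dose, alpha0 = alpha0, beta0 = beta0,
         effect_model = effect_model, hit_fraction = hit_fraction,
         hit_effect_range = hit_effect_range,
         pos_ctrl_multiplier = pos_ctrl_multiplier,
         plate_effect_sd = plate_effect_sd,
         n_replicate_runs = as.integer(n_replicate_runs),
         noise = noise, nb_size = nb_size, seed = seed),
    class = "screen_sim_config"
  )
}

draw_counts <- function(mu, noise, nb_size) {
  switch(noise,
    poisson = stats::rpois(length(mu), mu),
    negbin = stats::rnbinom(length(mu), mu = mu, size = nb_size),
    none = round(mu)
  )
}

well_grid <- function(n_wells, n_cols = 12) {
  idx <- seq_len(n_wells) - 1L
  sprintf("%s%02d", LETTERS[idx %/% n_cols + 1L], idx %% n_cols + 1L)
}

#' Simulate a plate-based radiosensitivity screen
#'
#' Generates paired unirradiated and irradiated well records for every
#' library gene and control well, over one or more replicate runs sharing
#' a single ground-truth effect table. Colony counts are drawn as
#' Poisson(cells_plated x base_pe x plate_effect x SF), with SF the
#' linear-quadratic survival at the well's dose under the gene's
#' alpha multiplier; each physical plate (each dose copy of each plate in
#' each run) receives an independent log-normal plate effect on plating
#' efficiency.
#'
#' @param config A [screen_sim_config()].
#' @return A list with `wells` (a well-record tibble with a `role`
#'   column, both doses, all runs), `truth` (one row per gene and
#'   control: `gene_id`, `alpha_multiplier`, `is_hit`, `is_nt_control`,
#'   `is_pos_control`) and the `config`.
#' @export
simulate_screen <- function(config) {
  if (!inherits(config, "screen_sim_config")) {
    stop("`config` must be built with screen_sim_config()", call. = FALSE)
  }
  withr::with_seed(config$seed, simulate_screen_impl(config))
}

simulate_screen_impl <- function(cfg) {
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  n_hits <- round(cfg$hit_fraction * cfg$n_genes)
  hit_idx <- if (n_hits > 0) sort(sample.int(cfg$n_genes, n_hits)) else integer(0)
  mult <- rep(1, cfg$n_genes)
  mult[hit_idx] <- stats::runif(n_hits, cfg$hit_effect_range[1], cfg$hit_effect_range[2])

  truth <- tibble::tibble(
    gene_id = c(gene_ids, "NT", "POS"),
    alpha_multiplier = c(mult, 1, cfg$pos_ctrl_multiplier),
    is_hit = c(seq_len(cfg$n_genes) %in% hit_idx, FALSE, FALSE),
    is_nt_control = c(rep(FALSE, cfg$n_genes), TRUE, FALSE),
    is_pos_control = c(rep(FALSE, cfg$n_genes), FALSE, TRUE)
  )

  # fixed layout shared by every plate: sample wells first, then controls
  n_ctrl <- cfg$nt_wells_per_plate + cfg$pos_ctrl_wells_per_plate
  well_ids <- well_grid(cfg$wells_per_plate)
  roles <- c(rep("sample", cfg$samples_per_plate),
             rep("nt_control", cfg$nt_wells_per_plate),
             rep("pos_control", cfg$pos_ctrl_wells_per_plate))

  # gene -> (plate, well slot) assignment, identical across runs and doses
  slot_plate <- rep(seq_len(cfg$n_plates), each = cfg$samples_per_plate)
  slot_well <- rep(seq_len(cfg$samples_per_plate), times = cfg$n_plates)

  plate_tbl <- tidyr::expand_grid(
    plate = seq_len(cfg$n_plates),
    slot = seq_len(cfg$wells_per_plate)
  )
  plate_tbl$well_id <- well_ids[plate_tbl$slot]
  plate_tbl$role <- roles[plate_tbl$slot]
  # map sample slots to genes; surplus sample wells on the last plate stay empty
  gene_of <- rep(NA_character_, nrow(plate_tbl))
  sample_rows <- which(plate_tbl$role == "sample")
  gene_slot_key <- paste(slot_plate, slot_well)
  plate_key <- paste(plate_tbl$plate[sample_rows],
                     match(plate_tbl$slot[sample_rows],
                           seq_len(cfg$samples_per_plate)))
  gene_of[sample_rows] <- gene_ids[match(plate_key, gene_slot_key)]
  plate_tbl$target <- dplyr::case_when(
    plate_tbl$role == "nt_control" ~ "NT",
    plate_tbl$role == "pos_control" ~ "POS",
    TRUE ~ gene_of
  )
  plate_tbl <- plate_tbl[!is.na(plate_tbl$target), ]
  plate_tbl$sirna_id <- paste0("si_", plate_tbl$target)
  plate_tbl$alpha_multiplier <-
    truth$alpha_multiplier[match(plate_tbl$target, truth$gene_id)]

  runs <- lapply(seq_len(cfg$n_replicate_runs), function(r) {
    run_id <- sprintf("run%d", r)
    per_dose <- lapply(c(0, cfg$dose), function(d) {
      tbl <- plate_tbl
      # one physical plate per (run, plate index, dose)
      plate_effects <- exp(stats::rnorm(cfg$n_plates, 0, cfg$plate_effect_sd))
      sf_gene <- exp(-(cfg$alpha0 * tbl$alpha_multiplier * d + cfg$beta0 * d^2))
      mu <- cfg$cells_plated * cfg$base_pe * plate_effects[tbl$plate] * sf_gene
      tibble::tibble(
        run_id = run_id,
        plate_id = sprintf("P%03d", tbl$plate),
        well_id = tbl$well_id,
        target = tbl$target,
        sirna_id = tbl$sirna_id,
        dose = d,
        cells_plated = cfg$cells_plated,
        colonies = as.numeric(draw_counts(mu, cfg$noise, cfg$nb_size)),
        role = tbl$role
      )
    })
    dplyr::bind_rows(per_dose)
  })
  wells <- dplyr::bind_rows(runs)
  list(wells = wells, truth = truth, config = cfg)
}

#' Simulate a clonogenic survival experiment
#'
#' Well records for a dose-response colony formation assay: for each dose
#' and replicate well, colony counts drawn as Poisson(cells_plated x
#' base_pe x SF(D)) under the linear-quadratic model.
#'
#' @param alpha,beta Linear-quadratic coefficients (Gy^-1, Gy^-2), both
#'   >= 0.
#' @param doses Vector of doses in Gy; must include 0 (the surviving
#'   fraction is undefined without unirradiated wells).
#' @param cells_plated Cells plated per well.
#' @param n_reps Replicate wells per dose.
#' @param base_pe Unirradiated plating efficiency.
#' @param noise `"poisson"` or `"none"` (expectations rounded).
#' @param condition Label stored in the `target` column.
#' @param seed Optional integer seed.
#' @return A well-record tibble (one row per well).
#' @export
simulate_survival_experiment <- function(alpha, beta, doses,
                                         cells_plated = 500, n_reps = 3,
                                         base_pe = 0.5,
                                         noise = c("poisson", "none"),
                                         condition = "condition_a",
                                         seed = NULL) {
  noise <- match.arg(noise)
  if (alpha < 0 || beta < 0) stop("`alpha` and `beta` must be >= 0", call. = FALSE)
  if (!0 %in% doses) {
    stop("`doses` must include 0 Gy: SF is undefined without it", call. = FALSE)
  }
  if (cells_plated < 1 || n_reps < 1) {
    stop("`cells_plated` and `n_reps` must be >= 1", call. = FALSE)
  }
  gen <- function() {
    grid <- tidyr::expand_grid(dose = sort(unique(doses)), rep = seq_len(n_reps))
    mu <- cells_plated * base_pe * sf_lq(grid$dose, alpha, beta)
    tibble::tibble(
      run_id = "run1",
      plate_id = sprintf("P%03d", match(grid$dose, sort(unique(doses)))),
      well_id = well_grid(nrow(grid))[seq_len(nrow(grid))],
      target = condition,
      sirna_id = paste0("si_", condition),
      dose = grid$dose,
      cells_plated = cells_plated,
      colonies = as.numeric(draw_counts(mu, noise, NULL))
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate time-lapse lineage event logs
#'
#' Two-generation branching lineage logs with per-cell stochastic fates.
#' Each root cell may die in interphase (probability
#' `p_death_interphase`) or, having entered mitosis, die there
#' (`p_death_mitosis`); surviving mitoses polyploidize with probability
#' `p_polyploid` (half by karyokinesis without cytokinesis, half by
#' daughter fusion) and otherwise divide into two daughters, each of
#' which independently dies in interphase or mitosis with the same
#' probabilities or survives. Daughter death times are drawn from one
#' common law regardless of death type, so that when both daughters die
#' the earlier one is equally likely to be of either type — which keeps
#' the lineage-level fate probabilities in closed form (see
#' [lineage_fate_probabilities()]).
#'
#' @param n_lineages Number of lineages to generate.
#' @param p_death_interphase,p_death_mitosis,p_polyploid Per-cell event
#'   probabilities, each in \[0, 1\].
#' @param mitosis_length_mean Mean mitosis length in minutes.
#' @param observation_min Observation window in minutes (default 2880 =
#'   48 h).
#' @param seed Optional integer seed.
#' @return A list with `events` (a lineage event log, see
#'   [validate_lineage_log()]) and `truth` (realized per-lineage fate and
#'   polyploidization flag, recorded by the generator from its own
#'   draws).
#' @export
simulate_lineage_log <- function(n_lineages,
                                 p_death_interphase = 0.1,
                                 p_death_mitosis = 0.1,
                                 p_polyploid = 0.05,
                                 mitosis_length_mean = 48,
                                 observation_min = 2880,
                                 seed = NULL) {
  for (p in c(p_death_interphase, p_death_mitosis, p_polyploid)) {
    if (!is.numeric(p) || p < 0 || p > 1) {
      stop("fate probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  if (n_lineages < 1) stop("`n_lineages` must be >= 1", call. = FALSE)
  if (mitosis_length_mean <= 0) stop("`mitosis_length_mean` must be > 0", call. = FALSE)
  gen <- function() {
    out <- lapply(seq_len(n_lineages), function(i) {
      simulate_one_lineage(sprintf("L%04d", i), p_death_interphase,
                           p_death_mitosis, p_polyploid,
                           mitosis_length_mean, observation_min)
    })
    list(
      events = dplyr::bind_rows(lapply(out, `[[`, "events")),
      truth = dplyr::bind_rows(lapply(out, `[[`, "truth"))
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

simulate_one_lineage <- function(lid, p_di, p_dm, p_poly, mitosis_mean, obs) {
  ev <- list()
  add <- function(cell, parent, event, time, phase = NA_character_) {
    ev[[length(ev) + 1]] <<- tibble::tibble(
      lineage_id = lid, cell_id = cell, parent_id = parent,
      event = event, time_min = time, phase_at_death = phase
    )
  }
  mito_len <- function() stats::rgamma(1, shape = 16, rate = 16 / mitosis_mean)
  root <- paste0(lid, "_c1")
  i0 <- stats::runif(1, 600, 1200)

  if (stats::runif(1) < p_di) {
    add(root, NA_character_, "death", stats::runif(1, 0, i0), "interphase")
    fate <- "death_interphase"; poly <- FALSE
  } else if (stats::runif(1) < p_dm) {
    len <- mito_len()
    add(root, NA_character_, "condensation_start", i0)
    add(root, NA_character_, "death", i0 + stats::runif(1, 0, len), "mitosis")
    fate <- "death_mitosis"; poly <- FALSE
  } else if (stats::runif(1) < p_poly) {
    len <- mito_len()
    add(root, NA_character_, "condensation_start", i0)
    if (stats::runif(1) < 0.5) {
      # karyokinesis without cytokinesis: a single binucleated survivor
      add(root, NA_character_, "karyokinesis_complete", i0 + len)
    } else {
      # normal division followed by daughter fusion
      add(root, NA_character_, "karyokinesis_complete", i0 + 5 * len / 6)
      add(root, NA_character_, "cytokinesis_complete", i0 + len)
      d1 <- paste0(lid, "_c2")
      add(d1, root, "daughter_fusion", i0 + len + 30)
    }
    fate <- "surviving"; poly <- TRUE
  } else {
    len <- mito_len()
    t_div <- i0 + len
    add(root, NA_character_, "condensation_start", i0)
    add(root, NA_character_, "karyokinesis_complete", i0 + 5 * len / 6)
    add(root, NA_character_, "cytokinesis_complete", t_div)
    daughters <- paste0(lid, c("_c2", "_c3"))
    death_time <- c(NA_real_, NA_real_)
    death_type <- c(NA_character_, NA_character_)
    for (j in 1:2) {
      d <- daughters[j]
      u <- stats::runif(1)
      q_dm_cond <- (1 - p_di) * p_dm
      if (u < p_di || (u >= p_di && u < p_di + q_dm_cond)) {
        # one common death-time law for both death types (see docs)
        t_death <- t_div + stats::runif(1, 0, max(obs - t_div, 60))
        if (u < p_di) {
          add(d, root, "death", t_death, "interphase")
          death_type[j] <- "death_interphase"
        } else {
          add(d, root, "condensation_start", max(t_div, t_death - 4))
          add(d, root, "death", t_death, "mitosis")
          death_type[j] <- "death_mitosis"
        }
        death_time[j] <- t_death
      } else {
        dlen <- mito_len()
        di <- stats::runif(1, 600, 1200)
        if (t_div + di + dlen <= obs) {
          add(d, root, "condensation_start", t_div + di)
          add(d, root, "karyokinesis_complete", t_div + di + 5 * dlen / 6)
          add(d, root, "cytokinesis_complete", t_div + di + dlen)
        }
      }
    }
    if (all(is.na(death_time))) {
      fate <- "surviving"; poly <- FALSE
    } else {
      first <- which.min(death_time)
      fate <- death_type[first]; poly <- FALSE
    }
  }
  list(
    events = dplyr::arrange(dplyr::bind_rows(ev), .data$time_min, .data$cell_id),
    truth = tibble::tibble(lineage_id = lid, fate = fate, polyploidization = poly)
  )
}

#' Closed-form lineage fate probabilities
#'
#' Exact fate-category probabilities implied by the per-cell event
#' probabilities of [simulate_lineage_log()], obtained by enumerating the
#' two-generation branching outcomes (the common daughter death-time law
#' makes mixed-type sibling deaths split 50/50 by exchangeability).
#'
#' @inheritParams simulate_lineage_log
#' @return A one-row tibble: `p_surviving`, `p_death_interphase`,
#'   `p_death_mitosis`, `p_polyploid_given_surviving`.
#' @export
lineage_fate_probabilities <- function(p_death_interphase = 0.1,
                                       p_death_mitosis = 0.1,
                                       p_polyploid = 0.05) {
  p_di <- p_death_interphase; p_dm <- p_death_mitosis; p_poly <- p_polyploid
  q_di <- p_di
  q_dm <- (1 - p_di) * p_dm
  q_s <- 1 - q_di - q_dm
  d_branch <- (1 - p_di) * (1 - p_dm) * (1 - p_poly)
  p_poly_surv <- (1 - p_di) * (1 - p_dm) * p_poly
  p_death_i <- p_di + d_branch * (q_di^2 + q_di * q_dm + 2 * q_di * q_s)
  p_death_m <- (1 - p_di) * p_dm + d_branch * (q_dm^2 + q_di * q_dm + 2 * q_dm * q_s)
  p_surv <- p_poly_surv + d_branch * q_s^2
  tibble::tibble(
    p_surviving = p_surv,
    p_death_interphase = p_death_i,
    p_death_mitosis = p_death_m,
    p_polyploid_given_surviving = if (p_surv > 0) p_poly_surv / p_surv else NA_real_
  )
}

#' Simulate metaphase aberration counts
#'
#' Per-metaphase Poisson counts of chromatid-type and chromosome-type
#' aberrations, split across break/gap/exchange classes in configurable
#' proportions.
#'
#' @param mean_chromatid,mean_chromosome Mean aberrations per metaphase
#'   of each dichotomy arm (>= 0).
#' @param n_metaphases Number of metaphases scored.
#' @param mitotic_fraction Externally measured mitotic (p-H3-positive)
#'   fraction, in \[0, 1\]; passed through for per-100-cells scaling.
#' @param class_split Proportions of breaks, gaps and exchanges within
#'   each arm (must sum to 1).
#' @param condition,timepoint Labels stored on every record.
#' @param seed Optional integer seed.
#' @return A list with `records` (a metaphase-record tibble) and
#'   `mitotic_fraction`.
#' @export
simulate_metaphase_counts <- function(mean_chromatid, mean_chromosome,
                                      n_metaphases, mitotic_fraction,
                                      class_split = c(breaks = 0.5, gaps = 0.3,
                                                      exchanges = 0.2),
                                      condition = "condition_a",
                                      timepoint = NA_real_,
                                      seed = NULL) {
  if (mean_chromatid < 0 || mean_chromosome < 0) {
    stop("class means must be >= 0", call. = FALSE)
  }
  if (mitotic_fraction < 0 || mitotic_fraction > 1) {
    stop("`mitotic_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (n_metaphases < 1) stop("`n_metaphases` must be >= 1", call. = FALSE)
  if (length(class_split) != 3 || abs(sum(class_split) - 1) > 1e-8 ||
      any(class_split < 0)) {
    stop("`class_split` must be 3 non-negative proportions summing to 1",
         call. = FALSE)
  }
  gen <- function() {
    draw <- function(mean_arm, share) {
      stats::rpois(n_metaphases, mean_arm * share)
    }
    tibble::tibble(
      condition = condition,
      timepoint = timepoint,
      metaphase_id = seq_len(n_metaphases),
      chromatid_breaks = draw(mean_chromatid, class_split[[1]]),
      chromatid_gaps = draw(mean_chromatid, class_split[[2]]),
      chromatid_exchanges = draw(mean_chromatid, class_split[[3]]),
      chromosome_breaks = draw(mean_chromosome, class_split[[1]]),
      chromosome_gaps = draw(mean_chromosome, class_split[[2]]),
      chromosome_exchanges = draw(mean_chromosome, class_split[[3]])
    )
  }
  records <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  list(records = records, mitotic_fraction = mitotic_fraction)
}
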