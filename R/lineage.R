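lineage_events <- c("condensation_start", "karyokinesis_complete",
                    "cytokinesis_complete", "daughter_fusion", "death")
lineage_fates_levels <- c("surviving", "death_interphase", "death_mitosis")

#' Validate a lineage event log
#'
#' Checks the structural invariants of a time-lapse lineage log: known
#' event vocabulary, times non-decreasing within each cell, every
#' non-root cell carries a parent, death events carry a phase label, and
#' condensation precedes karyokinesis precedes cytokinesis for every
#' completed mitosis.
#'
#' @param events Tibble with columns `lineage_id`, `cell_id`, `parent_id`
#'   (`NA` for roots), `event`, `time_min` and `phase_at_death` (`NA`
#'   except for death events, where it is `"interphase"` or `"mitosis"`).
#' @return The input, invisibly.
#' @export
validate_lineage_log <- function(events) {
  need <- c("lineage_id", "cell_id", "parent_id", "event", "time_min",
            "phase_at_death")
  miss <- setdiff(need, names(events))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  bad <- !events$event %in% lineage_events
  if (any(bad)) {
    stop("unknown event(s): ", paste(unique(events$event[bad]), collapse = ", "),
         call. = FALSE)
  }
  deaths <- events$event == "death"
  if (any(deaths & !events$phase_at_death %in% c("interphase", "mitosis"))) {
    stop("death events must carry phase_at_death = interphase or mitosis",
         call. = FALSE)
  }
  per_cell <- split(events, paste(events$lineage_id, events$cell_id))
  for (cell in per_cell) {
    if (is.unsorted(cell$time_min)) {
      stop("event times decrease for cell ", cell$cell_id[1], " in lineage ",
           cell$lineage_id[1], call. = FALSE)
    }
    t_of <- function(ev) cell$time_min[match(ev, cell$event)]
    tc <- t_of("condensation_start")
    tk <- t_of("karyokinesis_complete")
    ty <- t_of("cytokinesis_complete")
    if (!is.na(tk) && is.na(tc)) {
      stop("karyokinesis without condensation_start for cell ", cell$cell_id[1],
           " in lineage ", cell$lineage_id[1], call. = FALSE)
    }
    if (!is.na(ty) && (is.na(tk) || ty < tk || tk < tc)) {
      stop("mitosis event order violated for cell ", cell$cell_id[1],
           " in lineage ", cell$lineage_id[1], call. = FALSE)
    }
  }
  invisible(events)
}

#' Classify lineage fates
#'
#' Applies the fate taxonomy of two-generation time-lapse lineage
#' tracking: a lineage is `surviving` when every cell in it survived and
#' a death lineage when at least one cell died, sub-classified as
#' `death_interphase` or `death_mitosis` by the phase label of the death.
#' When deaths occur in parallel branches, the earliest-initiated death
#' event (by event time; ties broken by lower cell id) determines the
#' sub-class. Polyploidization is flagged on surviving lineages that show
#' either a daughter-cell fusion or a karyokinesis never followed by
#' cytokinesis in the same cell.
#'
#' @param events A lineage event log (see [validate_lineage_log()]),
#'   covering one or more lineages.
#' @return A tibble with one row per lineage: `lineage_id`, `fate`,
#'   `polyploidization`, `scored_branch_note` (which cell's death was
#'   scored, when branches competed).
#' @export
classify_lineages <- function(events) {
  validate_lineage_log(events)
  events |>
    dplyr::group_by(.data$lineage_id) |>
    dplyr::group_modify(~ classify_one(.x)) |>
    dplyr::ungroup()
}

classify_one <- function(ev) {
  deaths <- ev[ev$event == "death", ]
  if (nrow(deaths) > 0) {
    ord <- order(deaths$time_min, deaths$cell_id)
    first <- deaths[ord[1], ]
    note <- if (nrow(deaths) > 1) {
      paste0("earliest of ", nrow(deaths), " deaths scored (cell ",
             first$cell_id, ")")
    } else NA_character_
    fate <- if (first$phase_at_death == "mitosis") "death_mitosis" else "death_interphase"
    return(tibble::tibble(fate = fate, polyploidization = FALSE,
                          scored_branch_note = note))
  }
  fusion <- any(ev$event == "daughter_fusion")
  karyo_only <- FALSE
  for (cell in split(ev, ev$cell_id)) {
    tk <- cell$time_min[match("karyokinesis_complete", cell$event)]
    ty <- cell$time_min[match("cytokinesis_complete", cell$event)]
    if (!is.na(tk) && (is.na(ty) || ty < tk)) karyo_only <- TRUE
  }
  tibble::tibble(fate = "surviving",
                 polyploidization = fusion || karyo_only,
                 scored_branch_note = NA_character_)
}

#' Mitosis length of a cell
#'
#' Time from the initiation of chromatin condensation to the completion
#' of karyokinesis and cytokinesis. For a polyploidization mitosis
#' without cytokinesis, completion is defined by karyokinesis alone. A
#' cell that died during mitosis has no defined length (`NA`).
#'
#' @param events Event log of the lineage containing the cell.
#' @param cell_id The cell to measure.
#' @return Length in minutes, or `NA` for an unresolved mitosis.
#' @examples
#' log1 <- tibble::tibble(
#'   lineage_id = "L1", cell_id = "c1", parent_id = NA_character_,
#'   event = c("condensation_start", "karyokinesis_complete",
#'             "cytokinesis_complete"),
#'   time_min = c(100, 140, 148), phase_at_death = NA_character_
#' )
#' mitosis_length(log1, "c1") # 48
#' @export
mitosis_length <- function(events, cell_id) {
  cell <- events[events$cell_id == cell_id, ]
  if (nrow(cell) == 0) stop("no events for cell ", cell_id, call. = FALSE)
  t_of <- function(ev) cell$time_min[match(ev, cell$event)]
  tc <- t_of("condensation_start")
  if (is.na(tc)) stop("cell ", cell_id, " has no condensation_start event", call. = FALSE)
  ty <- t_of("cytokinesis_complete")
  tk <- t_of("karyokinesis_complete")
  if (!is.na(ty)) return(ty - tc)
  if (!is.na(tk)) return(tk - tc)
  NA_real_
}

#' Mitosis lengths for every mitotic cell in a log
#'
#' @param events A lineage event log.
#' @return Tibble with `lineage_id`, `cell_id`, `mitosis_length` (minutes;
#'   `NA` for mitoses unresolved by death) for every cell with a
#'   condensation event.
#' @export
mitosis_lengths <- function(events) {
  events |>
    dplyr::filter(.data$event == "condensation_start") |>
    dplyr::distinct(.data$lineage_id, .data$cell_id) |>
    dplyr::rowwise() |>
    dplyr::mutate(mitosis_length = mitosis_length(
      events[events$lineage_id == .data$lineage_id, ], .data$cell_id)) |>
    dplyr::ungroup()
}

#' Summarize lineage fates
#'
#' Percentage of lineages in each fate category (summing to 100) and the
#' polyploidization percentage among surviving lineages.
#'
#' @param fates Output of [classify_lineages()].
#' @return A one-row tibble: `n_lineages`, `pct_surviving`,
#'   `pct_death_interphase`, `pct_death_mitosis`,
#'   `pct_polyploid_of_surviving`.
#' @export
summarize_fates <- function(fates) {
  if (nrow(fates) == 0) stop("no lineages to summarize", call. = FALSE)
  n <- nrow(fates)
  counts <- table(factor(fates$fate, levels = lineage_fates_levels))
  n_surv <- counts[["surviving"]]
  tibble::tibble(
    n_lineages = n,
    pct_surviving = 100 * counts[["surviving"]] / n,
    pct_death_interphase = 100 * counts[["death_interphase"]] / n,
    pct_death_mitosis = 100 * counts[["death_mitosis"]] / n,
    pct_polyploid_of_surviving =
      if (n_surv > 0) 100 * sum(fates$polyploidization) / n_surv else NA_real_
  )
}
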