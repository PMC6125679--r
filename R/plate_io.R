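#' @keywords internal
well_record_columns <- c("run_id", "plate_id", "well_id", "target",
                         "sirna_id", "dose", "cells_plated", "colonies")

layout_columns <- c("well_id", "target", "sirna_id", "role")
layout_roles <- c("sample", "nt_control", "pos_control")

delim_for <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Validate a well-record table
#'
#' Checks the invariants of the well-record dialect: required columns,
#' non-negative doses and colony counts, positive cells plated, and
#' uniqueness of (run_id, plate_id, well_id, dose).
#'
#' @param wells A data frame of well records.
#' @return The input, invisibly, typed as a tibble.
#' @export
validate_well_records <- function(wells) {
  miss <- setdiff(well_record_columns, names(wells))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  check_rows <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad)
      stop(what, " in row(s): ", paste(utils::head(rows, 5), collapse = ", "),
           if (length(rows) > 5) " ..." else "", call. = FALSE)
    }
  }
  check_rows(is.na(wells$dose) | wells$dose < 0, "negative or missing dose")
  check_rows(is.na(wells$colonies) | wells$colonies < 0,
             "negative or missing colony count")
  check_rows(is.na(wells$cells_plated) | wells$cells_plated <= 0,
             "non-positive cells_plated")
  key <- paste(wells$run_id, wells$plate_id, wells$well_id, wells$dose)
  check_rows(duplicated(key), "duplicate (run_id, plate_id, well_id, dose)")
  invisible(tibble::as_tibble(wells))
}

#' Read well-level colony count records
#'
#' Reads the flat `wells.csv` dialect exported by plate scanners: columns
#' `run_id, plate_id, well_id, target, sirna_id, dose, cells_plated,
#' colonies`. TSV is auto-detected from a `.tsv` extension. If a plate
#' layout is supplied, control roles are joined on `well_id`.
#'
#' @param path Path to a CSV/TSV file.
#' @param layout Optional plate layout (see [read_plate_layout()]) mapping
#'   `well_id` to a `role`; every well in the counts file must have a
#'   layout entry.
#' @return A validated tibble of well records (plus a `role` column when a
#'   layout is given).
#' @export
read_well_records <- function(path, layout = NULL) {
  wells <- readr::read_delim(
    path, delim = delim_for(path), show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      run_id = readr::col_character(),
      plate_id = readr::col_character(),
      well_id = readr::col_character(),
      target = readr::col_character(),
      sirna_id = readr::col_character(),
      dose = readr::col_double(),
      cells_plated = readr::col_double(),
      colonies = readr::col_double()
    )
  )
  validate_well_records(wells)
  wells <- tibble::as_tibble(wells)
  if (!is.null(layout)) {
    unknown <- setdiff(unique(wells$well_id), layout$well_id)
    if (length(unknown) > 0) {
      stop("well(s) absent from layout: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    wells <- dplyr::left_join(
      wells,
      dplyr::select(layout, "well_id", "role"),
      by = "well_id"
    )
  }
  wells
}

#' Write well records
#'
#' Inverse of [read_well_records()]: canonical column order, UTF-8,
#' newline-terminated. TSV is selected by a `.tsv` extension.
#'
#' @param wells A well-record table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_well_records <- function(wells, path) {
  validate_well_records(wells)
  out <- dplyr::select(wells, dplyr::all_of(well_record_columns))
  readr::write_delim(out, path, delim = delim_for(path), na = "")
  invisible(path)
}

#' Read a plate layout
#'
#' Reads `layout.csv`: columns `well_id, target, sirna_id, role` with
#' `role` one of `sample`, `nt_control`, `pos_control`. Control roles are
#' declared here, never inferred from target names.
#'
#' @param path Path to a CSV/TSV layout file.
#' @return A tibble with one row per well.
#' @export
read_plate_layout <- function(path) {
  layout <- readr::read_delim(path, delim = delim_for(path),
                              show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(layout_columns, names(layout))
  if (length(miss) > 0) {
    stop("layout is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- !layout$role %in% layout_roles
  if (any(bad)) {
    stop("unknown layout role(s): ", paste(unique(layout$role[bad]), collapse = ", "),
         "; expected ", paste(layout_roles, collapse = "/"), call. = FALSE)
  }
  if (!any(layout$role == "nt_control")) {
    stop("layout has no nt_control well: normalization needs >= 1 per plate",
         call. = FALSE)
  }
  tibble::as_tibble(layout)
}
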