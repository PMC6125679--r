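# in-code fixtures shared across test files

# minimal well-record tibble builder
make_wells <- function(n = 4, dose = 0, colonies = 50, cells = 500,
                       target = "GENE1", run = "run1", plate = "P001") {
  tibble::tibble(
    run_id = run,
    plate_id = plate,
    well_id = sprintf("A%02d", seq_len(n)),
    target = target,
    sirna_id = paste0("si_", target),
    dose = dose,
    cells_plated = cells,
    colonies = rep_len(colonies, n)
  )
}

# per-well screen SF table ready for normalize_sf()/r_score()
make_sf_table <- function(sample_sf, nt_sf, run = "run1", pos_sf = NULL) {
  rows <- list(
    tibble::tibble(
      run_id = run, plate_id = "P001",
      well_id = sprintf("A%02d", seq_along(sample_sf)),
      target = sprintf("G%03d", seq_along(sample_sf)),
      sirna_id = sprintf("si_G%03d", seq_along(sample_sf)),
      role = "sample", dose = 7, sf = sample_sf
    ),
    tibble::tibble(
      run_id = run, plate_id = "P001",
      well_id = sprintf("B%02d", seq_along(nt_sf)),
      target = "NT", sirna_id = "si_NT",
      role = "nt_control", dose = 7, sf = nt_sf
    )
  )
  if (!is.null(pos_sf)) {
    rows <- c(rows, list(tibble::tibble(
      run_id = run, plate_id = "P001",
      well_id = sprintf("C%02d", seq_along(pos_sf)),
      target = "POS", sirna_id = "si_POS",
      role = "pos_control", dose = 7, sf = pos_sf
    )))
  }
  dplyr::bind_rows(rows)
}

# one lineage-log row
lineage_event <- function(lineage, cell, parent, event, time, phase = NA_character_) {
  tibble::tibble(lineage_id = lineage, cell_id = cell, parent_id = parent,
                 event = event, time_min = time, phase_at_death = phase)
}

# a lineage where the root divides and both daughters divide normally
surviving_lineage <- function(lid = "L1") {
  dplyr::bind_rows(
    lineage_event(lid, "c1", NA, "condensation_start", 100),
    lineage_event(lid, "c1", NA, "karyokinesis_complete", 140),
    lineage_event(lid, "c1", NA, "cytokinesis_complete", 148),
    lineage_event(lid, "c2", "c1", "condensation_start", 900),
    lineage_event(lid, "c2", "c1", "karyokinesis_complete", 940),
    lineage_event(lid, "c2", "c1", "cytokinesis_complete", 948),
    lineage_event(lid, "c3", "c1", "condensation_start", 950),
    lineage_event(lid, "c3", "c1", "karyokinesis_complete", 990),
    lineage_event(lid, "c3", "c1", "cytokinesis_complete", 998)
  )
}

# independent one-line R-score oracle (kept separate from the package code)
rscore_oracle <- function(normalized_sf, nt_normalized_sf) {
  (normalized_sf - 1) / mean(abs(nt_normalized_sf - mean(nt_normalized_sf)))
}
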