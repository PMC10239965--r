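#' Run the simulate stage: population, corridors, outputs
#'
#' Generates a synthetic population, builds its corridors and writes
#' `corridors.csv` and `demographics.csv` (plus `archive.csv` of section
#' contours when `write_archive = TRUE` — intended for reduced-size specs)
#' into `out_dir`. Counts of subjects, ribs, stations and clamped sections
#' are reported via `message()`. Given identical `spec` and `seed` the
#' outputs are byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param spec a `population_spec` (default [default_population_spec()]).
#' @param seed RNG seed (default `spec$seed`).
#' @param write_archive logical; also write the contour archive.
#' @return Invisibly, a list with `population`, `corridors` and the written
#'   file paths.
#' @export
run_simulate <- function(out_dir, spec = default_population_spec(),
                         seed = spec$seed, write_archive = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- simulate_population(spec, seed = seed, keep_contours = write_archive)
  corridors <- build_corridors(pop$records, grid = spec$grid)
  paths <- list(
    corridors = file.path(out_dir, "corridors.csv"),
    demographics = file.path(out_dir, "demographics.csv")
  )
  write_corridor_csv(corridors, paths$corridors)
  readr::write_csv(pop$demographics, paths$demographics, progress = FALSE)
  if (write_archive) {
    paths$archive <- file.path(out_dir, "archive.csv")
    write_contour_archive(pop, paths$archive)
  }
  message(sprintf(
    "simulate: %d subjects, %d ribs, %d stations/rib, %d record rows, %d clamped station(s)",
    nrow(pop$demographics), length(spec$ribs), length(spec$grid),
    nrow(pop$records), pop$n_clamped
  ))
  invisible(list(population = pop, corridors = corridors, paths = paths))
}

#' Run the measure stage: contour archive to per-rib property CSV
#'
#' Reads a contour archive, measures every section through the hollow-section
#' geometry and writes the tidy property table (`subject`, `sex`, `rib`,
#' `station_pct`, six properties; areas in mm^2, moments in mm^4, `i_rat`
#' unitless). Invalid stations are skipped with a warning.
#'
#' @param archive_path contour archive CSV ([write_contour_archive()]).
#' @param out_path output CSV path.
#' @return Invisibly, the measured record tibble.
#' @export
run_measure <- function(archive_path, out_path) {
  records <- measure_contour_archive(read_contour_archive(archive_path))
  keep <- c("subject_id", "sex", "age", "rib", "station_pct", names(property_columns))
  readr::write_csv(records[, keep], out_path, progress = FALSE)
  message(sprintf("measure: %d record rows from %s", nrow(records), archive_path))
  invisible(records)
}

#' Run the compare stage: HBM meshes versus corridors
#'
#' Reads a corridor CSV and one or more ring-mesh JSON files, measures each
#' mesh onto the station grid, builds the comparison table and writes
#' `comparison.csv` plus the fixed-width `report.txt`. With `plots = TRUE`,
#' one corridor-overlay figure per model is written as
#' `overlay_<model>.pdf`.
#'
#' @param corridor_path corridor CSV path.
#' @param mesh_paths character vector of ring-mesh JSON paths.
#' @param out_dir output directory.
#' @param grid station grid for mesh measurement.
#' @param k corridor half-width (SDs) for overlay plots.
#' @param plots logical; write overlay figures.
#' @return Invisibly, a list with `comparison`, `records` and file paths.
#' @export
run_compare <- function(corridor_path, mesh_paths, out_dir,
                        grid = station_grid(), k = 1, plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  corridors <- read_corridor_csv(corridor_path)
  meshes <- purrr::map(mesh_paths, read_ring_mesh)
  for (mesh in meshes) {
    if (!mesh$sex %in% corridors$sex) {
      stop(sprintf("model '%s' is sex %s but the corridor file has no %s corridors",
                   mesh$model, mesh$sex, mesh$sex), call. = FALSE)
    }
  }
  records <- purrr::map_dfr(meshes, hbm_rib_to_record, grid = grid)
  comparison <- comparison_table(records, corridors)
  paths <- list(
    comparison = file.path(out_dir, "comparison.csv"),
    report = file.path(out_dir, "report.txt")
  )
  write_comparison_csv(comparison, paths$comparison)
  writeLines(format_comparison_report(comparison), paths$report)
  if (plots) {
    for (m in unique(records$model)) {
      f <- file.path(out_dir, sprintf("overlay_%s.pdf", gsub("[^A-Za-z0-9_-]", "_", m)))
      grDevices::pdf(f, width = 10, height = 7)
      print(plot_corridor_overlay(corridors, records[records$model == m, ], k = k))
      grDevices::dev.off()
      paths[[paste0("overlay_", m)]] <- f
    }
  }
  message(sprintf("compare: %d models, %d comparison rows",
                  length(mesh_paths), nrow(comparison)))
  invisible(list(comparison = comparison, records = records, paths = paths))
}
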