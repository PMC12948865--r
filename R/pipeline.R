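compartment_levels <- c("grain", "straw", "crown_root", "coarse_root",
                        "fine_root", "soil")
mass_basis_levels <- c("g_per_m2", "g_per_kg_soil")

measurement_columns <- c("plot_id", "system", "regime", "compartment",
                         "layer", "position", "delta13C_permil",
                         "c_concentration", "mass_basis", "mass_value")

check_columns <- function(tbl, required, what) {
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing required column(s): %s", what,
                  paste(missing_cols, collapse = ", ")),
          class = "rhizotrace_error_schema")
  }
}

row_err <- function(rows, msg) {
  abort(sprintf("%s (row %s)", msg,
                paste(utils::head(rows, 5), collapse = ", ")),
        class = "rhizotrace_error_schema")
}

validate_measurements <- function(tbl, what = "measurements") {
  check_columns(tbl, measurement_columns, what)
  tbl <- as_tibble(tbl)
  bad <- which(!tbl$compartment %in% compartment_levels)
  if (length(bad)) row_err(bad, sprintf("%s: unknown compartment", what))
  bad <- which(!tbl$mass_basis %in% mass_basis_levels)
  if (length(bad)) row_err(bad, sprintf("%s: unknown mass_basis", what))
  bad <- which(!is.na(tbl$delta13C_permil) & tbl$delta13C_permil <= -1000)
  if (length(bad)) {
    row_err(bad, sprintf("%s: delta13C_permil must exceed -1000 permil", what))
  }
  bad <- which(is.na(tbl$delta13C_permil))
  if (length(bad)) row_err(bad, sprintf("%s: missing delta13C_permil", what))
  bad <- which(!is.na(tbl$c_concentration) &
                 (tbl$c_concentration <= 0 | tbl$c_concentration >= 0.6))
  if (length(bad)) {
    row_err(bad, sprintf(
      "%s: c_concentration must lie in (0, 0.6) g C per g dry matter", what))
  }
  bad <- which(!is.na(tbl$mass_value) & tbl$mass_value < 0)
  if (length(bad)) row_err(bad, sprintf("%s: negative mass_value", what))
  dup <- duplicated(tbl[, c("plot_id", "compartment", "layer", "position")])
  if (any(dup)) {
    row_err(which(dup), sprintf(
      "%s: duplicate (plot_id, compartment, layer, position) record", what))
  }
  tbl
}

#' Read a measurement table
#'
#' Reads and validates the tidy long-format measurement CSV: one row per
#' plot x compartment x layer x position with columns `plot_id`, `system`,
#' `regime`, `compartment` (`grain`, `straw`, `crown_root`, `coarse_root`,
#' `fine_root`, `soil`), `layer` (depth interval label, empty for
#' aboveground compartments), `position` (`plant`, `monolith`,
#' `within_row`, `between_row`, `bulk`), `delta13C_permil`,
#' `c_concentration` (g C per g dry matter), `mass_basis` (`g_per_m2` or
#' `g_per_kg_soil`) and `mass_value`. Schema violations raise descriptive
#' errors with row numbers; duplicate records are rejected.
#'
#' @param path Path to a CSV file (RFC 4180, UTF-8, `.` decimal).
#'
#' @return A validated tibble.
#' @export
read_measurements <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           plot_id = "c", system = "c", regime = "c",
                           compartment = "c", layer = "c", position = "c",
                           .default = readr::col_guess()))
  validate_measurements(tbl, sprintf("'%s'", path))
}

reference_columns <- c("system", "regime", "compartment", "layer",
                       "delta13C_permil")

validate_references <- function(tbl, what = "references") {
  check_columns(tbl, reference_columns, what)
  tbl <- as_tibble(tbl)
  bad <- which(is.na(tbl$delta13C_permil) | tbl$delta13C_permil <= -1000)
  if (length(bad)) {
    row_err(bad, sprintf("%s: invalid natural-abundance delta13C", what))
  }
  dup <- duplicated(tbl[, c("system", "regime", "compartment", "layer")])
  if (any(dup)) {
    row_err(which(dup), sprintf(
      "%s: duplicate (system, regime, compartment, layer) reference", what))
  }
  tbl
}

#' Read a natural-abundance reference table
#'
#' One reference delta-13C per system x regime x compartment x layer,
#' measured on unlabelled material from the corresponding treatment.
#'
#' @inheritParams read_measurements
#' @return A validated tibble.
#' @export
read_references <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           system = "c", regime = "c", compartment = "c",
                           layer = "c", .default = readr::col_guess()))
  validate_references(tbl, sprintf("'%s'", path))
}

validate_geometry <- function(tbl, what = "geometry") {
  check_columns(tbl, c("layer", "thickness_m", "bulk_density_kg_m3"), what)
  tbl <- as_tibble(tbl)
  if (any(tbl$thickness_m <= 0)) {
    abort(sprintf("%s: layer thicknesses must be positive.", what),
          class = "rhizotrace_error_geometry")
  }
  if (any(tbl$bulk_density_kg_m3 < 800 | tbl$bulk_density_kg_m3 > 2000)) {
    abort(sprintf("%s: bulk densities must lie in [800, 2000] kg m^-3.",
                  what),
          class = "rhizotrace_error_geometry")
  }
  if (anyDuplicated(tbl$layer)) {
    abort(sprintf("%s: duplicated layer entries.", what),
          class = "rhizotrace_error_geometry")
  }
  tbl
}

#' Read the layer-geometry table
#'
#' Columns `layer`, `thickness_m`, `bulk_density_kg_m3`; one row per soil
#' layer. Needed to scale mass-related carbon (g C kg\eqn{^{-1}} dry soil)
#' to the soil surface area.
#'
#' @inheritParams read_measurements
#' @return A validated tibble.
#' @export
read_geometry <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(layer = "c",
                                                 .default = readr::col_guess()))
  validate_geometry(tbl, sprintf("'%s'", path))
}

#' Read an rrn copy-number table
#'
#' Long-format taxon table with columns `taxon_id`, `rank`,
#' `rrn_copy_number`, `sample_id`, `read_count`, as consumed by
#' [trophic_ratio()].
#'
#' @inheritParams read_measurements
#' @return A validated tibble.
#' @export
read_rrn_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           taxon_id = "c", rank = "c", sample_id = "c",
                           .default = readr::col_guess()))
  check_columns(tbl, c("taxon_id", "rank", "rrn_copy_number", "sample_id",
                       "read_count"), sprintf("'%s'", path))
  if (any(!is.na(tbl$rrn_copy_number) & tbl$rrn_copy_number <= 0)) {
    abort("rrn copy numbers must be positive (or NA for unmatched taxa).",
          class = "rhizotrace_error_copy_number")
  }
  tbl
}

# simple event accumulator so every clamp/exclusion ends up in the run log
new_log <- function() {
  env <- new.env(parent = emptyenv())
  env$events <- list()
  env
}
log_event <- function(log, stage, message, plot_id = NA_character_,
                      layer = NA_character_) {
  log$events[[length(log$events) + 1L]] <-
    tibble(stage = stage, plot_id = plot_id, layer = layer,
           message = message)
  invisible(log)
}
log_tbl <- function(log) {
  if (length(log$events) == 0) {
    tibble(stage = character(), plot_id = character(),
           layer = character(), message = character())
  } else {
    dplyr::bind_rows(log$events)
  }
}

#' Run the tracer mass-balance analysis on measurement tables
#'
#' Chains the full calculation: delta-13C to atom fractions and atom excess
#' against treatment- and layer-matched natural-abundance references;
#' excess-13C mass per compartment; EOM correction of topsoil fine roots by
#' the two-pool mixing model (the clean-root endmember is the same plot's
#' topsoil coarse-root measurement, justified by the homogeneous-enrichment
#' assumption); aggregation of root classes and row positions; per-layer
#' percent and quantity of carbon derived from rhizodeposition; and
#' whole-profile totals, allocation coefficients and carbon ratios per plot.
#' Whole-profile percentages are recomputed from summed excess masses, not
#' averaged across layers, since the tracer mass balance is additive.
#'
#' The run is fully deterministic for fixed inputs. Every exclusion and
#' clamp is recorded in the returned `log` tibble.
#'
#' @param measurements Measurement tibble (see [read_measurements()]).
#' @param references Natural-abundance reference tibble
#'   (see [read_references()]).
#' @param geometry Layer-geometry tibble (see [read_geometry()]).
#' @param eom_delta delta-13C of extraneous organic matter, permil.
#'   Default -29.3.
#' @param topsoil Label of the topsoil layer receiving the EOM correction.
#' @param constants An [isotope_constants()] object.
#' @param quiet Suppress clamp/exclusion warnings (they are still logged)?
#'
#' @return A list of class `rhizotrace_results` with tibbles:
#' \describe{
#'   \item{samples}{per input row: carbon per area, atom fraction, atom
#'     excess and excess-13C mass.}
#'   \item{roots}{per plot x layer x root class after EOM correction and
#'     aggregation, with `f_rbc` where applied.}
#'   \item{layers}{per plot x layer: soil and root excess, corrected root
#'     carbon, `pct_cdfr`, `qcdfr`, `relative_rhizo`, exclusion flag.}
#'   \item{profile}{per plot: whole-profile quantities, allocation
#'     coefficients (`alloc_*`), `root_to_shoot`, `below_to_above`.}
#'   \item{log}{run log of exclusions, clamps and reference pairings.}
#' }
#' @export
analyze_experiment <- function(measurements, references, geometry,
                               eom_delta = -29.3, topsoil = "0-0.25",
                               constants = isotope_constants(),
                               quiet = FALSE) {
  measurements <- validate_measurements(measurements)
  references <- validate_references(references)
  geometry <- validate_geometry(geometry)
  log <- new_log()

  data_layers <- unique(measurements$layer[!is.na(measurements$layer)])
  uncovered <- setdiff(data_layers, geometry$layer)
  if (length(uncovered) > 0) {
    abort(sprintf("Geometry does not cover layer(s): %s",
                  paste(uncovered, collapse = ", ")),
          class = "rhizotrace_error_geometry")
  }

  refs <- dplyr::rename(references, delta_ref = delta13C_permil)
  samples <- measurements |>
    dplyr::left_join(refs,
                     by = c("system", "regime", "compartment", "layer")) |>
    dplyr::left_join(geometry, by = "layer")
  unpaired <- samples |>
    dplyr::filter(is.na(delta_ref)) |>
    dplyr::distinct(system, regime, compartment, layer)
  if (nrow(unpaired) > 0) {
    abort(paste0(
      "No natural-abundance reference for treatment x layer combination(s): ",
      paste(utils::head(paste(unpaired$system, unpaired$regime,
                              unpaired$compartment, unpaired$layer,
                              sep = "/"), 6), collapse = "; ")),
      class = "rhizotrace_error_missing_reference")
  }

  samples <- samples |>
    dplyr::mutate(
      carbon_g_m2 = dplyr::case_when(
        mass_basis == "g_per_m2" ~ mass_value * c_concentration,
        mass_basis == "g_per_kg_soil" ~ area_scale(
          mass_value * c_concentration, bulk_density_kg_m3, thickness_m)
      ),
      x13 = delta_to_atom_fraction(delta13C_permil, constants),
      x13_ref = delta_to_atom_fraction(delta_ref, constants),
      atom_excess = x13 - x13_ref,
      excess_g_m2 = excess_mass(atom_excess, carbon_g_m2, x13, constants)
    )

  neg <- samples$atom_excess < 0
  if (any(neg)) {
    for (i in which(neg)) {
      log_event(log, "excess",
                sprintf("negative atom excess (%.3g) in %s retained",
                        samples$atom_excess[i], samples$compartment[i]),
                samples$plot_id[i], samples$layer[i])
    }
  }

  # EOM correction of topsoil fine roots (two-pool mixing); references
  # cancel in f_RBC, so endmember atom fractions are used directly
  x_eom <- delta_to_atom_fraction(eom_delta, constants)
  fine_top <- samples |>
    dplyr::filter(compartment == "fine_root", layer == topsoil) |>
    dplyr::summarise(x_sample = mean(x13), x_ref = mean(x13_ref),
                     sample_c = sum(carbon_g_m2), .by = plot_id)
  clean_top <- samples |>
    dplyr::filter(compartment == "coarse_root", layer == topsoil) |>
    dplyr::summarise(x_clean = mean(x13), .by = plot_id)

  if (nrow(fine_top) > 0) {
    fr <- dplyr::left_join(fine_top, clean_top, by = "plot_id")
    if (anyNA(fr$x_clean)) {
      abort(paste0(
        "Topsoil fine roots present but no topsoil coarse-root (clean-root ",
        "endmember) measurement for plot(s): ",
        paste(fr$plot_id[is.na(fr$x_clean)], collapse = ", ")),
        class = "rhizotrace_error_missing_endmember")
    }
    raw <- (fr$x_sample - x_eom) / (fr$x_clean - x_eom)
    fr$f_rbc <- withCallingHandlers(
      eom_root_fraction(fr$x_sample - fr$x_ref,
                        fr$x_clean - fr$x_ref,
                        x_eom - fr$x_ref),
      rhizotrace_warning_frbc_clamped = function(w) {
        if (quiet) invokeRestart("muffleWarning")
      }
    )
    clamped <- which(abs(fr$f_rbc - raw) > 1e-12)
    for (i in clamped) {
      log_event(log, "eom_correction",
                sprintf("raw f_RBC %.4f clamped to %.4f", raw[i],
                        fr$f_rbc[i]),
                fr$plot_id[i], topsoil)
    }
  } else {
    fr <- tibble(plot_id = character(), f_rbc = numeric(),
                 x_clean = numeric(), x_ref = numeric(),
                 sample_c = numeric())
  }

  root_samples <- samples |>
    dplyr::filter(compartment %in% c("crown_root", "coarse_root",
                                     "fine_root")) |>
    dplyr::mutate(root_class = sub("_root$", "", compartment))

  # corrected topsoil fine roots: carbon scaled by f_RBC; the excess mass is
  # recomputed from the clean-root atom excess applied to the corrected
  # carbon, since the sample's own excess still contains the EOM signal
  if (nrow(fr) > 0) {
    corr <- fr |>
      dplyr::mutate(
        carbon_corr = f_rbc * sample_c,
        excess_corr = excess_mass(x_clean - x_ref, carbon_corr, x_clean,
                                  constants)
      )
    root_samples <- root_samples |>
      dplyr::left_join(
        corr[, c("plot_id", "carbon_corr", "excess_corr", "f_rbc")],
        by = "plot_id") |>
      dplyr::mutate(
        is_fine_top = root_class == "fine" & layer == topsoil,
        carbon_g_m2 = ifelse(is_fine_top, carbon_corr, carbon_g_m2),
        excess_g_m2 = ifelse(is_fine_top, excess_corr, excess_g_m2),
        f_rbc = ifelse(is_fine_top, f_rbc, NA_real_)
      )
  } else {
    root_samples$f_rbc <- NA_real_
  }

  roots <- aggregate_roots(
    root_samples[, c("plot_id", "layer", "position", "root_class",
                     "carbon_g_m2", "excess_g_m2")],
    topsoil = topsoil
  ) |>
    dplyr::left_join(
      dplyr::distinct(root_samples[!is.na(root_samples$f_rbc),
                                   c("plot_id", "f_rbc")]),
      by = "plot_id") |>
    dplyr::mutate(f_rbc = ifelse(root_class == "fine" & layer == topsoil,
                                 f_rbc, NA_real_))

  meta <- dplyr::distinct(measurements[, c("plot_id", "system", "regime")])

  layer_roots <- roots |>
    dplyr::summarise(root_c = sum(carbon_g_m2),
                     root_excess = sum(excess_g_m2),
                     .by = c(plot_id, layer))
  soil <- samples |>
    dplyr::filter(compartment == "soil") |>
    dplyr::summarise(soil_excess = sum(excess_g_m2),
                     soil_c = sum(carbon_g_m2),
                     .by = c(plot_id, layer))

  layers <- dplyr::inner_join(layer_roots, soil,
                              by = c("plot_id", "layer")) |>
    dplyr::left_join(meta, by = "plot_id")
  pct <- withCallingHandlers(
    percent_cdfr(layers$soil_excess, layers$root_excess),
    rhizotrace_warning_undefined_partition = function(w) {
      if (quiet) invokeRestart("muffleWarning")
    }
  )
  layers$pct_cdfr <- pct
  layers$excluded <- is.na(pct) | pct < 0 | pct >= 100
  for (i in which(layers$excluded)) {
    log_event(log, "rhizodeposition",
              sprintf("layer excluded: %%CdfR %s",
                      ifelse(is.na(pct[i]), "undefined (no tracer excess)",
                             sprintf("%.2f outside [0, 100)", pct[i]))),
              layers$plot_id[i], layers$layer[i])
    if (!quiet) {
      warn(sprintf("Plot %s layer %s excluded from rhizodeposition results.",
                   layers$plot_id[i], layers$layer[i]),
           class = "rhizotrace_warning_layer_excluded")
    }
  }
  layers <- layers |>
    dplyr::mutate(
      qcdfr = ifelse(excluded, NA_real_, q_cdfr(
        ifelse(excluded, 0, pct_cdfr), root_c)),
      relative_rhizo = ifelse(excluded, NA_real_,
                              relative_rhizodeposition(qcdfr, root_c))
    ) |>
    dplyr::select(plot_id, system, regime, layer, root_c, root_excess,
                  soil_c, soil_excess, pct_cdfr, qcdfr, relative_rhizo,
                  excluded)

  aboveground <- samples |>
    dplyr::filter(compartment %in% c("grain", "straw")) |>
    dplyr::summarise(carbon = sum(carbon_g_m2),
                     .by = c(plot_id, compartment)) |>
    tidyr::pivot_wider(names_from = compartment, values_from = carbon,
                       names_glue = "{compartment}_c")

  profile <- layers |>
    dplyr::filter(!excluded) |>
    dplyr::summarise(
      root_c = sum(root_c), root_excess = sum(root_excess),
      soil_excess = sum(soil_excess),
      qcdfr_layer_sum = sum(qcdfr),
      .by = c(plot_id, system, regime)
    ) |>
    dplyr::mutate(
      pct_cdfr = percent_cdfr(soil_excess, root_excess),
      qcdfr = q_cdfr(pct_cdfr, root_c),
      relative_rhizo = relative_rhizodeposition(qcdfr, root_c)
    ) |>
    dplyr::left_join(aboveground, by = "plot_id")

  alloc <- allocation_coefficients(profile$grain_c, profile$straw_c,
                                   profile$root_c, profile$qcdfr)
  names(alloc) <- c("alloc_grain", "alloc_straw", "alloc_root",
                    "alloc_rhizo", "total_c")
  ratios <- carbon_ratios(profile$grain_c, profile$straw_c,
                          profile$root_c, profile$qcdfr)
  profile <- dplyr::bind_cols(profile, alloc, ratios)

  structure(
    list(samples = samples, roots = roots, layers = layers,
         profile = profile, log = log_tbl(log)),
    class = "rhizotrace_results"
  )
}

#' Run the pipeline from CSV inputs to CSV outputs
#'
#' File-based wrapper around [analyze_experiment()]: reads the measurement,
#' reference and geometry CSVs, runs the full calculation chain, writes the
#' per-plot layer table, per-plot profile table, treatment summary and run
#' log as CSVs into `out_dir`, and returns the results invisibly.
#' Deterministic: rerunning on the same inputs reproduces identical outputs.
#'
#' @param measurements_path,references_path,geometry_path Input CSV paths.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param summary_vars Profile columns summarised per treatment.
#' @inheritParams analyze_experiment
#'
#' @return Invisibly, the `rhizotrace_results` list with an added
#'   `treatment_summary` tibble.
#' @export
run_pipeline <- function(measurements_path, references_path, geometry_path,
                         out_dir = NULL, eom_delta = -29.3,
                         topsoil = "0-0.25",
                         constants = isotope_constants(),
                         summary_vars = c("root_c", "qcdfr", "grain_c",
                                          "straw_c", "alloc_grain",
                                          "alloc_straw", "alloc_root",
                                          "alloc_rhizo", "root_to_shoot",
                                          "below_to_above"),
                         quiet = FALSE) {
  res <- analyze_experiment(
    read_measurements(measurements_path),
    read_references(references_path),
    read_geometry(geometry_path),
    eom_delta = eom_delta, topsoil = topsoil, constants = constants,
    quiet = quiet
  )
  res$treatment_summary <- treatment_summary(res$profile, summary_vars)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(res$roots, file.path(out_dir, "root_carbon.csv"))
    readr::write_csv(res$layers, file.path(out_dir, "layer_results.csv"))
    readr::write_csv(res$profile, file.path(out_dir, "profile_results.csv"))
    readr::write_csv(res$treatment_summary,
                     file.path(out_dir, "treatment_summary.csv"))
    readr::write_csv(res$log, file.path(out_dir, "run_log.csv"))
  }
  invisible(res)
}
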