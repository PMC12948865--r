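#' Configuration of the forward experiment simulator
#'
#' Builds a validated configuration for [simulate_experiment()]. The defaults
#' describe a wheat pulse-labelling field trial at ripening: three cropping
#' systems (biodynamic `BIODYN`, mixed conventional `CONFYM`, mineral
#' conventional `CONMIN`) under two water regimes (`rainfed`, `drought`) with
#' replicate microplots, three 0.25 m soil layers, an applied tracer of
#' 36.5 g \eqn{^{13}}C m\eqn{^{-2}} of which 46% (rainfed) or 32% (drought)
#' is recovered in the plant-soil system at harvest, and rainfed allocation
#' fractions that put about 99 g C m\eqn{^{-2}} into roots and
#' 237 g C m\eqn{^{-2}} into net rhizodeposition out of roughly
#' 1060 g C m\eqn{^{-2}} net assimilated. Drought shifts allocation
#' belowground (more fine roots and rhizodeposits, less grain and straw) at
#' unchanged total assimilation.
#'
#' @param seed Integer seed; a fixed seed makes the simulated tables
#'   byte-identical across runs.
#' @param systems,regimes Character vectors of cropping-system and
#'   water-regime labels.
#' @param n_plots Replicate plots per system x regime cell.
#' @param total_assimilated_c Net assimilated carbon per plot,
#'   g C m\eqn{^{-2}}.
#' @param allocation Named list with one numeric vector per regime, each with
#'   entries `grain`, `straw`, `root`, `rhizo` summing to 1.
#' @param grain_system_effect Named multiplicative modifiers of the grain
#'   fraction per system (cell fractions are renormalised to 1).
#' @param root_layer_split Fractions of root carbon per soil layer (sum 1).
#' @param root_class_split Named list per regime, each holding `topsoil`
#'   (fractions for `crown`, `coarse`, `fine`) and `deep` (fractions for
#'   `coarse`, `fine`), each summing to 1.
#' @param rhizo_layer_split Fractions of rhizodeposition carbon per layer.
#' @param applied_tracer Applied tracer, g \eqn{^{13}}C m\eqn{^{-2}}.
#' @param recovery_fraction Named fraction of the applied tracer recovered in
#'   the plant-soil system, per regime.
#' @param natural_delta Named natural-abundance delta-13C (permil): `plant`
#'   and `soil`.
#' @param eom_delta delta-13C of extraneous organic matter, permil.
#' @param eom_contamination EOM share of topsoil fine-root sample carbon,
#'   in \[0, 1).
#' @param soil_c_g_per_kg Background soil organic C per layer,
#'   g C kg\eqn{^{-1}} dry soil.
#' @param bulk_density Soil bulk density per layer, kg m\eqn{^{-3}}.
#' @param layer_thickness Layer heights, m.
#' @param layers Layer labels (depth intervals in m).
#' @param c_concentration Named carbon concentrations (g C per g dry matter)
#'   of the plant compartments.
#' @param noise_sd_delta Additive Gaussian noise on delta-13C observations,
#'   permil (IRMS-scale precision).
#' @param noise_sd_mass Multiplicative lognormal noise (sdlog) on mass
#'   observations.
#' @param constants An [isotope_constants()] object.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       systems = c("BIODYN", "CONFYM", "CONMIN"),
                       regimes = c("rainfed", "drought"),
                       n_plots = 4L,
                       total_assimilated_c = 1060,
                       allocation = list(
                         rainfed = c(grain = 0.3104, straw = 0.3726,
                                     root = 0.0934, rhizo = 0.2236),
                         drought = c(grain = 0.2404, straw = 0.3085,
                                     root = 0.1159, rhizo = 0.3352)
                       ),
                       grain_system_effect = c(BIODYN = 0.90, CONFYM = 1.01,
                                               CONMIN = 1.09),
                       root_layer_split = c(0.70, 0.20, 0.10),
                       root_class_split = list(
                         rainfed = list(
                           topsoil = c(crown = 0.30, coarse = 0.30, fine = 0.40),
                           deep = c(coarse = 0.40, fine = 0.60)
                         ),
                         drought = list(
                           topsoil = c(crown = 0.245, coarse = 0.245, fine = 0.51),
                           deep = c(coarse = 0.30, fine = 0.70)
                         )
                       ),
                       rhizo_layer_split = c(0.70, 0.19, 0.11),
                       applied_tracer = 36.5,
                       recovery_fraction = c(rainfed = 0.46, drought = 0.32),
                       natural_delta = c(plant = -28, soil = -26),
                       eom_delta = -29.3,
                       eom_contamination = 0.2,
                       soil_c_g_per_kg = c(15, 8, 5),
                       bulk_density = c(1300, 1450, 1500),
                       layer_thickness = c(0.25, 0.25, 0.25),
                       layers = c("0-0.25", "0.25-0.5", "0.5-0.75"),
                       c_concentration = c(grain = 0.45, straw = 0.45,
                                           crown_root = 0.40,
                                           coarse_root = 0.40,
                                           fine_root = 0.40),
                       noise_sd_delta = 0.2,
                       noise_sd_mass = 0.05,
                       constants = isotope_constants()) {
  cfg <- list(
    seed = as.integer(seed), systems = systems, regimes = regimes,
    n_plots = as.integer(n_plots),
    total_assimilated_c = total_assimilated_c, allocation = allocation,
    grain_system_effect = grain_system_effect,
    root_layer_split = root_layer_split,
    root_class_split = root_class_split,
    rhizo_layer_split = rhizo_layer_split,
    applied_tracer = applied_tracer, recovery_fraction = recovery_fraction,
    natural_delta = natural_delta, eom_delta = eom_delta,
    eom_contamination = eom_contamination,
    soil_c_g_per_kg = soil_c_g_per_kg, bulk_density = bulk_density,
    layer_thickness = layer_thickness, layers = layers,
    c_concentration = c_concentration,
    noise_sd_delta = noise_sd_delta, noise_sd_mass = noise_sd_mass,
    constants = constants
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  sum_one <- function(x, what) {
    if (any(x < 0) || abs(sum(x) - 1) > 1e-9) {
      abort(sprintf("%s must be nonnegative and sum to 1 (got sum %.12f).",
                    what, sum(x)),
            class = "rhizotrace_error_config")
    }
  }
  for (rg in cfg$regimes) {
    a <- cfg$allocation[[rg]]
    if (is.null(a) || !all(c("grain", "straw", "root", "rhizo") %in% names(a))) {
      abort(sprintf("Allocation fractions missing for regime '%s'.", rg),
            class = "rhizotrace_error_config")
    }
    sum_one(a, sprintf("allocation fractions (%s)", rg))
    cs <- cfg$root_class_split[[rg]]
    if (is.null(cs)) {
      abort(sprintf("Root class split missing for regime '%s'.", rg),
            class = "rhizotrace_error_config")
    }
    sum_one(cs$topsoil, sprintf("topsoil root class split (%s)", rg))
    sum_one(cs$deep, sprintf("deep root class split (%s)", rg))
    rec <- cfg$recovery_fraction[[rg]]
    if (is.null(rec) || is.na(rec) || rec <= 0 || rec >= 1) {
      abort(sprintf("Recovery fraction for regime '%s' must be in (0, 1).", rg),
            class = "rhizotrace_error_config")
    }
  }
  sum_one(cfg$root_layer_split, "root layer split")
  sum_one(cfg$rhizo_layer_split, "rhizodeposition layer split")
  nl <- length(cfg$layers)
  if (length(cfg$root_layer_split) != nl ||
      length(cfg$rhizo_layer_split) != nl ||
      length(cfg$soil_c_g_per_kg) != nl ||
      length(cfg$bulk_density) != nl ||
      length(cfg$layer_thickness) != nl) {
    abort("Per-layer config vectors must match the number of layers.",
          class = "rhizotrace_error_config")
  }
  if (any(cfg$bulk_density < 800 | cfg$bulk_density > 2000)) {
    abort("Bulk densities must lie within [800, 2000] kg m^-3.",
          class = "rhizotrace_error_config")
  }
  if (any(cfg$layer_thickness <= 0)) {
    abort("Layer thicknesses must be positive.",
          class = "rhizotrace_error_config")
  }
  if (cfg$eom_delta <= -35 || cfg$eom_delta >= -20) {
    abort("EOM delta-13C must lie in the natural-abundance range (-35, -20).",
          class = "rhizotrace_error_config")
  }
  if (cfg$eom_contamination < 0 || cfg$eom_contamination >= 1) {
    abort("EOM contamination fraction must lie in [0, 1).",
          class = "rhizotrace_error_config")
  }
  if (cfg$noise_sd_delta < 0 || cfg$noise_sd_mass < 0) {
    abort("Noise standard deviations must be nonnegative.",
          class = "rhizotrace_error_config")
  }
  invisible(cfg)
}

# true pool carbon masses and excess 13C for one system x regime cell.
# A single atom excess chi is shared by every plant pool and the
# rhizodeposits (the mass-balance method's homogeneous/equal-enrichment
# assumptions); chi is solved in closed form so that the excess masses sum
# exactly to the recovered tracer.
sim_cell_truth <- function(cfg, system, regime) {
  cst <- cfg$constants
  frac <- cfg$allocation[[regime]]
  frac["grain"] <- frac["grain"] * cfg$grain_system_effect[[system]]
  frac <- frac / sum(frac)
  total <- cfg$total_assimilated_c

  root_total <- frac[["root"]] * total
  root_by_layer <- cfg$root_layer_split * root_total
  cs <- cfg$root_class_split[[regime]]
  nl <- length(cfg$layers)

  pools <- dplyr::bind_rows(
    tibble(compartment = c("grain", "straw"), layer = NA_character_,
           carbon_g_m2 = c(frac[["grain"]], frac[["straw"]]) * total),
    tibble(compartment = c("crown_root", "coarse_root", "fine_root"),
           layer = cfg$layers[1],
           carbon_g_m2 = cs$topsoil[c("crown", "coarse", "fine")] *
             root_by_layer[1]),
    purrr::map_dfr(seq(2, nl), function(l) {
      tibble(compartment = c("coarse_root", "fine_root"),
             layer = cfg$layers[l],
             carbon_g_m2 = cs$deep[c("coarse", "fine")] * root_by_layer[l])
    }),
    tibble(compartment = "rhizodeposition", layer = cfg$layers,
           carbon_g_m2 = cfg$rhizo_layer_split * frac[["rhizo"]] * total)
  )

  recovered <- cfg$applied_tracer * cfg$recovery_fraction[[regime]]
  x_p <- delta_to_atom_fraction(cfg$natural_delta[["plant"]], cst)
  dM <- cst$M13 - cst$M12
  chi <- recovered * mean_molar_mass(x_p, cst) /
    (cst$M13 * sum(pools$carbon_g_m2) - recovered * dM)
  x_lab <- x_p + chi

  pools$excess_g_m2 <- excess_mass(chi, pools$carbon_g_m2, x_lab, cst)

  list(pools = pools, chi = chi, x_plant = x_p, x_labelled = x_lab,
       recovered = recovered, frac = frac)
}

#' Simulate a labelled plot experiment with known ground truth
#'
#' Forward model of the pulse-labelling trial, inverse to the analysis
#' pipeline by construction: (1) the recovered tracer (applied times the
#' regime's recovery fraction) is spread over grain, straw, root classes and
#' rhizodeposits at one common atom excess, enforcing homogeneous root
#' enrichment and equal enrichment of roots and rhizodeposits; (2) the
#' rhizodeposit excess is diluted into each layer's background soil carbon,
#' with the soil delta-13C chosen so that the soil's excess-13C mass equals
#' the rhizodeposits' exactly; (3) extraneous organic matter is mixed into
#' the topsoil fine-root sample at the configured carbon fraction, the
#' sample's atom fraction being the carbon-weighted two-pool mixture of the
#' clean-root and EOM endmembers; (4) Gaussian noise is added to delta-13C
#' and multiplicative lognormal noise to mass observations; (5)
#' natural-abundance reference rows are emitted per treatment x layer.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config A [sim_config()] object.
#'
#' @return A list of class `sim_experiment`:
#' \describe{
#'   \item{measurements}{tidy measurement tibble (one row per plot x
#'     compartment x layer x position).}
#'   \item{references}{natural-abundance reference delta-13C per
#'     system x regime x compartment x layer.}
#'   \item{geometry}{layer thicknesses and bulk densities.}
#'   \item{truth}{list with `plots` (per-plot true carbon, allocation and
#'     tracer quantities), `layers` (true per-layer root and rhizodeposition
#'     carbon) and `compartments` (true carbon and excess-13C mass per
#'     pool).}
#'   \item{config}{the configuration used.}
#' }
#' @examples
#' sim <- simulate_experiment(sim_config(seed = 42, n_plots = 2))
#' head(sim$measurements)
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by sim_config().",
          class = "rhizotrace_error_config")
  }
  validate_sim_config(config)
  cfg <- config
  cst <- cfg$constants
  nl <- length(cfg$layers)
  soil_mass_kg <- cfg$bulk_density * cfg$layer_thickness # kg dry soil m^-2
  x_s <- delta_to_atom_fraction(cfg$natural_delta[["soil"]], cst)
  x_eom <- delta_to_atom_fraction(cfg$eom_delta, cst)
  dM <- cst$M13 - cst$M12
  phi <- cfg$eom_contamination

  cells <- tidyr::expand_grid(system = cfg$systems, regime = cfg$regimes)
  plot_rows <- list()
  truth_comp <- list()
  truth_plots <- list()

  for (i in seq_len(nrow(cells))) {
    sys <- cells$system[i]
    rg <- cells$regime[i]
    cell <- sim_cell_truth(cfg, sys, rg)
    pools <- cell$pools
    delta_lab <- atom_fraction_to_delta(cell$x_labelled, cst)

    pick <- function(comp, lay = NULL) {
      sel <- pools$compartment == comp &
        (if (is.null(lay)) is.na(pools$layer) else pools$layer == lay)
      pools$carbon_g_m2[sel]
    }

    rhizo_l <- pools$carbon_g_m2[pools$compartment == "rhizodeposition"]
    rhizo_excess_l <- pools$excess_g_m2[pools$compartment == "rhizodeposition"]
    m_bg <- cfg$soil_c_g_per_kg * soil_mass_kg
    m_soil <- m_bg + rhizo_l
    # soil atom fraction that makes the measured soil excess mass equal the
    # rhizodeposit excess mass: (x - x_s) m M13 / d(x) = mE, solved for x
    x_soil <- (rhizo_excess_l * cst$M12 + x_s * m_soil * cst$M13) /
      (m_soil * cst$M13 - rhizo_excess_l * dM)
    delta_soil <- atom_fraction_to_delta(x_soil, cst)

    m_fine_top <- pick("fine_root", cfg$layers[1])
    m_sample <- m_fine_top / (1 - phi)
    x_sample <- (1 - phi) * cell$x_labelled + phi * x_eom
    delta_sample <- atom_fraction_to_delta(x_sample, cst)

    cc <- cfg$c_concentration
    one_plot <- dplyr::bind_rows(
      tibble(compartment = c("grain", "straw"), layer = NA_character_,
             position = "plant", mass_basis = "g_per_m2",
             c_concentration = cc[c("grain", "straw")],
             mass_value = c(pick("grain"), pick("straw")) /
               cc[c("grain", "straw")],
             delta13C_permil = delta_lab),
      tibble(compartment = "crown_root", layer = cfg$layers[1],
             position = "monolith", mass_basis = "g_per_m2",
             c_concentration = cc[["crown_root"]],
             mass_value = pick("crown_root", cfg$layers[1]) / cc[["crown_root"]],
             delta13C_permil = delta_lab),
      tibble(compartment = "coarse_root", layer = cfg$layers[1],
             position = "monolith", mass_basis = "g_per_kg_soil",
             c_concentration = cc[["coarse_root"]],
             mass_value = pick("coarse_root", cfg$layers[1]) /
               soil_mass_kg[1] / cc[["coarse_root"]],
             delta13C_permil = delta_lab),
      tibble(compartment = "fine_root", layer = cfg$layers[1],
             position = "monolith", mass_basis = "g_per_kg_soil",
             c_concentration = cc[["fine_root"]],
             mass_value = m_sample / soil_mass_kg[1] / cc[["fine_root"]],
             delta13C_permil = delta_sample),
      purrr::map_dfr(seq(2, nl), function(l) {
        tidyr::expand_grid(
          compartment = c("coarse_root", "fine_root"),
          position = c("within_row", "between_row")
        ) |>
          dplyr::mutate(
            layer = cfg$layers[l], mass_basis = "g_per_kg_soil",
            c_concentration = unname(cc[compartment]),
            mass_value = vapply(compartment, function(co)
              pick(co, cfg$layers[l]) / soil_mass_kg[l] /
                cc[[co]], numeric(1), USE.NAMES = FALSE),
            delta13C_permil = delta_lab
          )
      }),
      tibble(compartment = "soil", layer = cfg$layers,
             position = "bulk", mass_basis = "g_per_kg_soil",
             c_concentration = m_soil / soil_mass_kg / 1000,
             mass_value = 1000,
             delta13C_permil = delta_soil)
    )

    for (p in seq_len(cfg$n_plots)) {
      pid <- sprintf("%s_%s_%d", sys, rg, p)
      plot_rows[[length(plot_rows) + 1L]] <- one_plot |>
        dplyr::mutate(plot_id = pid, system = sys, regime = rg)
      truth_comp[[length(truth_comp) + 1L]] <- pools |>
        dplyr::mutate(plot_id = pid, system = sys, regime = rg)
      truth_plots[[length(truth_plots) + 1L]] <- tibble(
        plot_id = pid, system = sys, regime = rg,
        grain_c = pick("grain"), straw_c = pick("straw"),
        root_c = sum(pools$carbon_g_m2[grepl("root$", pools$compartment)]),
        rhizo_c = sum(rhizo_l),
        alloc_grain = cell$frac[["grain"]],
        alloc_straw = cell$frac[["straw"]],
        alloc_root = cell$frac[["root"]],
        alloc_rhizo = cell$frac[["rhizo"]],
        f_rbc = 1 - phi,
        atom_excess = cell$chi,
        recovered_13c_g_m2 = cell$recovered
      )
    }
  }

  measurements <- dplyr::bind_rows(plot_rows) |>
    dplyr::select(plot_id, system, regime, compartment, layer, position,
                  delta13C_permil, c_concentration, mass_basis, mass_value)
  truth_compartments <- dplyr::bind_rows(truth_comp) |>
    dplyr::select(plot_id, system, regime, compartment, layer,
                  carbon_g_m2, excess_g_m2)
  truth_plots <- dplyr::bind_rows(truth_plots)
  truth_layers <- truth_compartments |>
    dplyr::filter(!is.na(layer)) |>
    dplyr::summarise(
      root_c = sum(carbon_g_m2[compartment != "rhizodeposition"]),
      rhizo_c = sum(carbon_g_m2[compartment == "rhizodeposition"]),
      root_excess_g_m2 = sum(excess_g_m2[compartment != "rhizodeposition"]),
      rhizo_excess_g_m2 = sum(excess_g_m2[compartment == "rhizodeposition"]),
      .by = c(plot_id, system, regime, layer)
    )

  references <- tidyr::expand_grid(
    system = cfg$systems, regime = cfg$regimes,
    tibble(
      compartment = c("grain", "straw", "crown_root",
                      rep(c("coarse_root", "fine_root", "soil"), each = nl)),
      layer = c(NA_character_, NA_character_, cfg$layers[1],
                rep(cfg$layers, times = 3))
    )
  ) |>
    dplyr::mutate(
      delta13C_permil = ifelse(compartment == "soil",
                               cfg$natural_delta[["soil"]],
                               cfg$natural_delta[["plant"]])
    )

  # measurement noise, deterministic under the config seed
  measurements <- withr::with_seed(cfg$seed, {
    m <- measurements
    if (cfg$noise_sd_delta > 0) {
      m$delta13C_permil <- m$delta13C_permil +
        rnorm(nrow(m), 0, cfg$noise_sd_delta)
    }
    if (cfg$noise_sd_mass > 0) {
      f <- exp(rnorm(nrow(m), 0, cfg$noise_sd_mass))
      is_soil <- m$compartment == "soil"
      m$mass_value[!is_soil] <- m$mass_value[!is_soil] * f[!is_soil]
      m$c_concentration[is_soil] <- m$c_concentration[is_soil] * f[is_soil]
    }
    r <- references
    if (cfg$noise_sd_delta > 0) {
      r$delta13C_permil <- r$delta13C_permil +
        rnorm(nrow(r), 0, cfg$noise_sd_delta)
    }
    list(m = m, r = r)
  })
  references <- measurements$r
  measurements <- measurements$m

  geometry <- tibble(layer = cfg$layers,
                     thickness_m = cfg$layer_thickness,
                     bulk_density_kg_m3 = cfg$bulk_density)

  structure(
    list(measurements = measurements, references = references,
         geometry = geometry,
         truth = list(plots = truth_plots, layers = truth_layers,
                      compartments = truth_compartments),
         config = cfg),
    class = "sim_experiment"
  )
}

#' Write a simulated experiment to CSV files
#'
#' Writes the measurement, reference, geometry and ground-truth tables of a
#' [simulate_experiment()] result as RFC-4180 CSVs into a directory, using
#' the same schemas that [read_measurements()] and friends consume.
#'
#' @param sim A `sim_experiment` object.
#' @param dir Output directory (created if needed).
#'
#' @return Invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    measurements = file.path(dir, "measurements.csv"),
    references = file.path(dir, "references.csv"),
    geometry = file.path(dir, "geometry.csv"),
    truth_plots = file.path(dir, "truth_plots.csv"),
    truth_layers = file.path(dir, "truth_layers.csv"),
    truth_compartments = file.path(dir, "truth_compartments.csv")
  )
  readr::write_csv(sim$measurements, paths[["measurements"]])
  readr::write_csv(sim$references, paths[["references"]])
  readr::write_csv(sim$geometry, paths[["geometry"]])
  readr::write_csv(sim$truth$plots, paths[["truth_plots"]])
  readr::write_csv(sim$truth$layers, paths[["truth_layers"]])
  readr::write_csv(sim$truth$compartments, paths[["truth_compartments"]])
  invisible(paths)
}

#' Parameter-recovery study over a measurement-noise grid
#'
#' Repeatedly simulates the experiment and runs the full analysis pipeline,
#' then summarises how well whole-profile rhizodeposition carbon, root
#' carbon and the allocation coefficients are recovered: for each noise
#' level, the mean relative bias and the RMSE of the relative error of the
#' across-plot mean estimate against the generator's truth.
#'
#' @param config Base [sim_config()]; its `noise_sd_delta` is overridden by
#'   the grid.
#' @param n_reps Replicate simulations per noise level (>= 2).
#' @param noise_sd_delta Numeric grid of delta-13C noise levels (permil).
#' @param seed Base seed for the study; per-replicate seeds are derived from
#'   it deterministically.
#'
#' @return Tibble with columns `noise_sd_delta`, `metric`, `bias`, `rmse`,
#'   `n_reps`. Bias and RMSE are on the relative-error scale (0.01 = 1%).
#' @export
recovery_study <- function(config, n_reps = 100,
                           noise_sd_delta = c(0, 0.2),
                           seed = config$seed) {
  if (n_reps < 2) {
    abort("`n_reps` must be at least 2.", class = "rhizotrace_error_config")
  }
  metrics <- c("qcdfr_profile", "root_c", "alloc_grain", "alloc_straw",
               "alloc_root", "alloc_rhizo")
  out <- purrr::map_dfr(seq_along(noise_sd_delta), function(si) {
    sdd <- noise_sd_delta[si]
    errs <- purrr::map_dfr(seq_len(n_reps), function(rep) {
      cfg <- config
      cfg$noise_sd_delta <- sdd
      cfg$seed <- as.integer(
        (seed + 7919 * rep + 104729 * si) %% 2147483629)
      sim <- simulate_experiment(cfg)
      res <- analyze_experiment(sim$measurements, sim$references,
                                sim$geometry,
                                eom_delta = cfg$eom_delta,
                                constants = cfg$constants, quiet = TRUE)
      est <- res$profile
      tru <- sim$truth$plots
      rel <- function(e, t) (mean(e) - mean(t)) / mean(t)
      tibble(
        metric = metrics,
        rel_err = c(rel(est$qcdfr, tru$rhizo_c),
                    rel(est$root_c, tru$root_c),
                    rel(est$alloc_grain, tru$alloc_grain),
                    rel(est$alloc_straw, tru$alloc_straw),
                    rel(est$alloc_root, tru$alloc_root),
                    rel(est$alloc_rhizo, tru$alloc_rhizo))
      )
    })
    errs |>
      dplyr::summarise(bias = mean(rel_err),
                       rmse = sqrt(mean(rel_err^2)),
                       .by = metric) |>
      dplyr::mutate(noise_sd_delta = sdd, n_reps = n_reps, .before = 1)
  })
  out
}
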