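# shared fixtures: tiny deterministic configs and hand-built tables

quiet_sim <- function(...) {
  simulate_experiment(sim_config(...))
}

# exact simulation: no measurement noise, no EOM contamination
exact_config <- function(seed = 1, ...) {
  sim_config(seed = seed, noise_sd_delta = 0, noise_sd_mass = 0,
             eom_contamination = 0, ...)
}

analyze_sim <- function(sim, quiet = TRUE) {
  analyze_experiment(sim$measurements, sim$references, sim$geometry,
                     eom_delta = sim$config$eom_delta,
                     constants = sim$config$constants, quiet = quiet)
}

# truth rows aligned to an estimate table by plot_id
truth_by_plot <- function(sim, profile) {
  sim$truth$plots[match(profile$plot_id, sim$truth$plots$plot_id), ]
}

# minimal hand-built root table for aggregation tests
tiny_root_table <- function() {
  tibble::tribble(
    ~plot_id, ~layer,     ~position,     ~root_class, ~carbon_g_m2, ~excess_g_m2,
    "p1",     "0-0.25",   "monolith",    "crown",      10,           0.10,
    "p1",     "0-0.25",   "monolith",    "coarse",      5,           0.05,
    "p1",     "0-0.25",   "monolith",    "fine",       16,           0.16,
    "p1",     "0.25-0.5", "within_row",  "coarse",      4,           0.04,
    "p1",     "0.25-0.5", "between_row", "coarse",      2,           0.02,
    "p1",     "0.25-0.5", "within_row",  "fine",        3,           0.03,
    "p1",     "0.25-0.5", "between_row", "fine",        1,           0.01
  )
}
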