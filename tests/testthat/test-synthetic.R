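test_that("the simulator is deterministic under a fixed seed", {
  s1 <- quiet_sim(seed = 99)
  s2 <- quiet_sim(seed = 99)
  expect_identical(s1$measurements, s2$measurements)
  expect_identical(s1$references, s2$references)
  expect_identical(s1$truth, s2$truth)
  # byte-identical CSV output
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_simulation(s1, d1)
  p2 <- write_simulation(s2, d2)
  for (i in seq_along(p1)) {
    expect_identical(readLines(p1[[i]]), readLines(p2[[i]]))
  }
  s3 <- quiet_sim(seed = 100)
  expect_false(identical(s1$measurements$delta13C_permil,
                         s3$measurements$delta13C_permil))
})

test_that("true excess masses conserve the recovered tracer", {
  sim <- exact_config(seed = 4) |> simulate_experiment()
  per_plot <- tapply(sim$truth$compartments$excess_g_m2,
                     sim$truth$compartments$plot_id, sum)
  tru <- sim$truth$plots
  expect_equal(as.vector(per_plot[tru$plot_id]), tru$recovered_13c_g_m2,
               tolerance = 1e-12)
  # recovered = applied x recovery fraction, by regime
  cfg <- sim$config
  expect_equal(unique(tru$recovered_13c_g_m2[tru$regime == "rainfed"]),
               cfg$applied_tracer * cfg$recovery_fraction[["rainfed"]])
})

test_that("roots and rhizodeposits share one atom excess per plot", {
  sim <- exact_config(seed = 8) |> simulate_experiment()
  comp <- sim$truth$compartments
  cst <- sim$config$constants
  # excess mass per unit carbon is proportional to atom excess at a common
  # enrichment; it must be identical across every pool of a plot
  ratio <- comp$excess_g_m2 / comp$carbon_g_m2
  spread <- tapply(ratio, comp$plot_id, function(r) diff(range(r)))
  expect_true(max(spread) < 1e-15)
})

test_that("zero-noise simulation is exactly inverted by the pipeline", {
  sim <- exact_config(seed = 21, n_plots = 2) |> simulate_experiment()
  res <- analyze_sim(sim)
  tru <- truth_by_plot(sim, res$profile)
  expect_equal(res$profile$qcdfr, tru$rhizo_c, tolerance = 1e-9)
  expect_equal(res$profile$root_c, tru$root_c, tolerance = 1e-9)
  expect_equal(res$profile$alloc_rhizo, tru$alloc_rhizo, tolerance = 1e-9)
  # per-layer additivity: profile qCdfR equals the sum of layer values
  expect_equal(res$profile$qcdfr_layer_sum, res$profile$qcdfr,
               tolerance = 1e-9)
  # per-layer truth as well
  lt <- sim$truth$layers
  est <- res$layers
  key <- paste(est$plot_id, est$layer)
  lt <- lt[match(key, paste(lt$plot_id, lt$layer)), ]
  expect_equal(est$qcdfr, lt$rhizo_c, tolerance = 1e-9)
})

test_that("EOM contamination is recovered as 1 - phi at zero noise", {
  for (phi in c(0.1, 0.35)) {
    sim <- sim_config(seed = 2, n_plots = 2, noise_sd_delta = 0,
                      noise_sd_mass = 0, eom_contamination = phi) |>
      simulate_experiment()
    res <- analyze_sim(sim)
    f <- res$roots$f_rbc[!is.na(res$roots$f_rbc)]
    expect_equal(f, rep(1 - phi, length(f)), tolerance = 1e-12)
    # and the corrected profile still matches truth
    tru <- truth_by_plot(sim, res$profile)
    expect_equal(res$profile$root_c, tru$root_c, tolerance = 1e-9)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(
    sim_config(allocation = list(
      rainfed = c(grain = 0.5, straw = 0.3, root = 0.1, rhizo = 0.2),
      drought = c(grain = 0.25, straw = 0.3, root = 0.1, rhizo = 0.35)
    )),
    class = "rhizotrace_error_config"
  )
  expect_error(sim_config(recovery_fraction = c(rainfed = 1.2, drought = 0.3)),
               class = "rhizotrace_error_config")
  expect_error(sim_config(bulk_density = c(100, 1450, 1500)),
               class = "rhizotrace_error_config")
  expect_error(sim_config(eom_contamination = 1),
               class = "rhizotrace_error_config")
  expect_error(simulate_experiment(list()),
               class = "rhizotrace_error_config")
})

test_that("recovery error grows with delta noise and vanishes without it", {
  cfg <- sim_config(seed = 31, n_plots = 2, noise_sd_mass = 0,
                    eom_contamination = 0)
  rs <- recovery_study(cfg, n_reps = 20, noise_sd_delta = c(0, 0.3))
  q <- rs[rs$metric == "qcdfr_profile", ]
  expect_equal(q$bias[q$noise_sd_delta == 0], 0, tolerance = 1e-9)
  expect_lt(q$rmse[q$noise_sd_delta == 0],
            q$rmse[q$noise_sd_delta == 0.3])
  expect_lte(abs(q$bias[q$noise_sd_delta == 0]),
             abs(q$bias[q$noise_sd_delta == 0.3]))
  expect_error(recovery_study(cfg, n_reps = 1),
               class = "rhizotrace_error_config")
})
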