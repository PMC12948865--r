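test_that("two-pool mixing recovers the endmember fractions", {
  # pure root, pure EOM, and midway mixtures
  expect_equal(eom_root_fraction(0.01, 0.01, 0), 1)
  expect_equal(eom_root_fraction(0, 0.01, 0), 0)
  expect_equal(eom_root_fraction(0.005, 0.01, 0), 0.5)
  expect_error(eom_root_fraction(0.005, 0.01, 0.01),
               class = "rhizotrace_error_degenerate_mixing")
})

test_that("f_RBC is invariant under a common shift of all three excesses", {
  withr::with_seed(11, {
    for (i in 1:25) {
      s <- runif(1, 0, 0.02)
      rb <- runif(1, 0.021, 0.05)
      eom <- runif(1, -0.001, 0.001)
      shift <- runif(1, -0.01, 0.01)
      expect_equal(
        eom_root_fraction(s + shift, rb + shift, eom + shift, clamp = FALSE),
        eom_root_fraction(s, rb, eom, clamp = FALSE),
        tolerance = 1e-10
      )
    }
  })
})

test_that("raw f_RBC outside [0, 1] is clamped with a warning", {
  expect_warning(
    f <- eom_root_fraction(0.012, 0.01, 0),
    class = "rhizotrace_warning_frbc_clamped"
  )
  expect_equal(f, 1)
  expect_warning(
    f2 <- eom_root_fraction(-0.001, 0.01, 0),
    class = "rhizotrace_warning_frbc_clamped"
  )
  expect_equal(f2, 0)
  # opt-out returns the raw mixing ratio
  expect_equal(eom_root_fraction(0.012, 0.01, 0, clamp = FALSE), 1.2)
})

test_that("area scaling is the product of content, density and height", {
  expect_equal(area_scale(1, 1300, 0.25), 325)
  expect_equal(area_scale(0, 1300, 0.25), 0)
  expect_equal(area_scale(2, 1300, 0.125), area_scale(1, 1300, 0.25))
  expect_error(area_scale(1, -1, 0.25), class = "rhizotrace_error_geometry")
})

test_that("root aggregation sums topsoil classes and averages row positions", {
  agg <- aggregate_roots(tiny_root_table())
  top_coarse <- agg$carbon_g_m2[agg$layer == "0-0.25" &
                                  agg$root_class == "coarse"]
  expect_equal(top_coarse, 15) # crown 10 + coarse 5
  mid_coarse <- agg$carbon_g_m2[agg$layer == "0.25-0.5" &
                                  agg$root_class == "coarse"]
  expect_equal(mid_coarse, 3) # mean(4, 2)
  mid_fine <- agg$carbon_g_m2[agg$layer == "0.25-0.5" &
                                agg$root_class == "fine"]
  expect_equal(mid_fine, 2) # mean(3, 1)
  # topsoil aggregation conserves mass
  tab <- tiny_root_table()
  expect_equal(sum(agg$carbon_g_m2[agg$layer == "0-0.25"]),
               sum(tab$carbon_g_m2[tab$layer == "0-0.25"]))
  expect_equal(sum(agg$excess_g_m2[agg$layer == "0-0.25"]),
               sum(tab$excess_g_m2[tab$layer == "0-0.25"]))
})

test_that("a lone row-position core below the topsoil is rejected", {
  tab <- tiny_root_table()
  tab <- tab[!(tab$layer == "0.25-0.5" & tab$position == "between_row" &
                 tab$root_class == "fine"), ]
  expect_error(aggregate_roots(tab),
               class = "rhizotrace_error_incomplete_design")
  expect_error(aggregate_roots(tab[0, -1]),
               class = "rhizotrace_error_schema")
})
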