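test_that("percent CdfR partitions the layer excess", {
  expect_equal(percent_cdfr(0.2, 0.2), 50)
  expect_equal(percent_cdfr(0, 0.2), 0)
  expect_equal(percent_cdfr(0.3, 0.1), 75)
  expect_warning(
    p <- percent_cdfr(0, 0),
    class = "rhizotrace_warning_undefined_partition"
  )
  expect_true(is.na(p))
})

test_that("qCdfR satisfies its defining identity across a sweep", {
  expect_equal(q_cdfr(50, 100), 100)
  expect_equal(q_cdfr(0, 100), 0)
  withr::with_seed(5, {
    pct <- runif(400, 0, 99.9)
    rc <- runif(400, 0.01, 500)
    q <- q_cdfr(pct, rc)
    expect_true(all(q >= 0))
    expect_true(max(abs(q / (q + rc) - pct / 100)) < 1e-12)
    # increasing in pct at fixed root carbon
    o <- order(pct)
    expect_true(all(diff(q_cdfr(pct[o], 100)) > 0))
  })
  expect_error(q_cdfr(100, 10),
               class = "rhizotrace_error_singular_partition")
  expect_error(q_cdfr(50, -1), class = "rhizotrace_error_negative_mass")
})

test_that("relative rhizodeposition is the belowground share", {
  expect_equal(relative_rhizodeposition(237, 99), 237 / 336)
  expect_equal(relative_rhizodeposition(0, 99), 0)
  expect_equal(relative_rhizodeposition(42, 42), 0.5)
  expect_warning(r <- relative_rhizodeposition(0, 0),
                 class = "rhizotrace_warning_undefined_partition")
  expect_true(is.na(r))
})

test_that("allocation coefficients are proportions summing to one", {
  a <- allocation_coefficients(300, 300, 100, 300)
  expect_equal(unlist(a[1, c("grain", "straw", "root", "rhizo")]),
               c(grain = 0.3, straw = 0.3, root = 0.1, rhizo = 0.3))
  expect_equal(a$total_c, 1000)
  one <- allocation_coefficients(0, 500, 0, 0)
  expect_equal(one$straw, 1)
  # permutation consistency: swapping inputs swaps outputs
  b <- allocation_coefficients(100, 300, 300, 300)
  expect_equal(b$grain, a$root)
  expect_equal(b$root, a$grain)
  withr::with_seed(3, {
    m <- matrix(runif(4 * 50, 0, 400), ncol = 4)
    cf <- allocation_coefficients(m[, 1], m[, 2], m[, 3], m[, 4])
    expect_true(max(abs(cf$grain + cf$straw + cf$root + cf$rhizo - 1)) < 1e-9)
  })
  expect_error(allocation_coefficients(0, 0, 0, 0),
               class = "rhizotrace_error_undefined_partition")
  expect_error(allocation_coefficients(-1, 2, 3, 4),
               class = "rhizotrace_error_negative_mass")
})

test_that("carbon ratios are scale-invariant", {
  r <- carbon_ratios(300, 300, 100, 300)
  expect_equal(r$root_to_shoot, 1 / 3)
  expect_equal(r$below_to_above, 400 / 600)
  expect_equal(carbon_ratios(300, 300, 0, 0)$below_to_above, 0)
  k <- 17.3
  expect_equal(carbon_ratios(k * 300, k * 300, k * 100, k * 300), r)
  expect_error(carbon_ratios(300, 0, 100, 300),
               class = "rhizotrace_error_undefined_ratio")
})

test_that("treatment summary gives group means, SEs and percent change", {
  tbl <- tibble::tibble(
    system = rep(c("A", "B"), each = 4),
    regime = rep(c("rainfed", "rainfed", "drought", "drought"), 2),
    y = c(100, 100, 150, 150, 80, 120, 100, 100)
  )
  ts <- treatment_summary(tbl, "y")
  a <- ts[ts$system == "A", ]
  expect_equal(a$mean_control, 100)
  expect_equal(a$mean_treatment, 150)
  expect_equal(a$pct_change, 50)
  expect_equal(a$se_control, 0)
  b <- ts[ts$system == "B", ]
  expect_equal(b$pct_change, 0)
  expect_equal(b$se_control, sd(c(80, 120)) / sqrt(2))
  pooled <- ts[ts$system == "all", ]
  expect_equal(pooled$n_control, 4)
  expect_equal(pooled$mean_treatment, 125)
})

test_that("degenerate treatment groups are surfaced, not silently dropped", {
  tbl <- tibble::tibble(system = "A",
                        regime = c("rainfed", "drought"),
                        y = c(1, 2))
  expect_message(ts <- treatment_summary(tbl, "y", pooled = FALSE))
  expect_true(is.na(ts$se_control))
  expect_error(
    treatment_summary(tbl[tbl$regime == "rainfed", ], "y"),
    class = "rhizotrace_error_missing_group"
  )
})
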