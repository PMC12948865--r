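test_that("delta to atom fraction follows the standard relations", {
  cst <- isotope_constants()
  # the VPDB standard itself: x13 = R_VPDB / (1 + R_VPDB)
  expect_identical(delta_to_atom_fraction(0, cst),
                   cst$R_VPDB / (1 + cst$R_VPDB))
  # hand evaluation of the two-step formula at the EOM signature
  expect_equal(delta_to_atom_fraction(-29.3, cst), 0.0107361052677461,
               tolerance = 1e-12)
  # strictly increasing in delta
  grid <- seq(-900, 5000, by = 137)
  expect_true(all(diff(delta_to_atom_fraction(grid, cst)) > 0))
})

test_that("delta <-> atom fraction invert each other to 1e-10 permil", {
  cst <- isotope_constants()
  grid <- c(seq(-900, 5000, by = 61), -50, 0, 500)
  back <- atom_fraction_to_delta(delta_to_atom_fraction(grid, cst), cst)
  expect_true(max(abs(back - grid)) < 1e-10)
  # inverse of the frozen EOM evaluation
  expect_equal(atom_fraction_to_delta(0.0107361052677461, cst), -29.3,
               tolerance = 1e-9)
})

test_that("atom fractions behave at the domain edges", {
  cst <- isotope_constants()
  # x13 -> 0+ corresponds to delta -> -1000 permil
  expect_equal(atom_fraction_to_delta(1e-15, cst), -1000, tolerance = 1e-6)
  expect_error(delta_to_atom_fraction(-1200, cst),
               class = "rhizotrace_error_invalid_delta")
  expect_error(atom_fraction_to_delta(0, cst),
               class = "rhizotrace_error_invalid_fraction")
  expect_error(atom_fraction_to_delta(1.2, cst),
               class = "rhizotrace_error_invalid_fraction")
})

test_that("atom excess is a plain antisymmetric difference", {
  expect_identical(atom_excess(0.011, 0.011), 0)
  expect_equal(atom_excess(0.02, 0.011), 0.009, tolerance = 1e-15)
  withr::with_seed(42, {
    a <- runif(50, 0.001, 0.05)
    b <- runif(50, 0.001, 0.05)
    expect_equal(atom_excess(a, b), -atom_excess(b, a))
  })
  expect_identical(attr(atom_excess(0.02, 0.011, "ref-1"), "reference_id"),
                   "ref-1")
  expect_error(atom_excess(1.5, 0.011),
               class = "rhizotrace_error_invalid_fraction")
})

test_that("excess mass matches the mass-balance equation and is linear", {
  cst <- isotope_constants()
  # hand evaluation: denominator 0.989*12 + 0.011*M13
  expect_equal(excess_mass(0.001, 100, 0.011, cst), 0.10826171716256,
               tolerance = 1e-12)
  expect_identical(excess_mass(0, 123.4, 0.011, cst), 0)
  # homogeneous of degree 1 in excess and in carbon mass
  withr::with_seed(7, {
    chi <- runif(20, 1e-5, 0.02)
    m <- runif(20, 1, 500)
    x13 <- runif(20, 0.010, 0.03)
    k <- 3.7
    expect_equal(excess_mass(k * chi, m, x13, cst),
                 k * excess_mass(chi, m, x13, cst))
    expect_equal(excess_mass(chi, k * m, x13, cst),
                 k * excess_mass(chi, m, x13, cst))
  })
  expect_error(excess_mass(0.001, -5, 0.011, cst),
               class = "rhizotrace_error_negative_mass")
})

test_that("isotope constants are validated", {
  expect_error(isotope_constants(M12 = 13, M13 = 12),
               class = "rhizotrace_error_constants")
  expect_error(isotope_constants(R_VPDB = 1.5),
               class = "rhizotrace_error_constants")
  # the alternative truncated VPDB ratio changes results reproducibly
  alt <- isotope_constants(R_VPDB = 0.011180)
  expect_lt(delta_to_atom_fraction(0, alt), delta_to_atom_fraction(0))
})
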