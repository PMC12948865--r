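test_that("trophic classification is a step function at the threshold", {
  expect_identical(classify_trophic(5.0), "copiotroph")
  expect_identical(classify_trophic(4.9), "oligotroph")
  expect_identical(classify_trophic(1), "oligotroph")
  expect_identical(classify_trophic(NA_real_), "unclassified")
  # custom threshold moves the step
  expect_identical(classify_trophic(5, threshold = 6), "oligotroph")
  expect_error(classify_trophic(0), class = "rhizotrace_error_copy_number")
})

test_that("per-sample ratios are read-weighted and rescale-invariant", {
  taxa <- tibble::tibble(
    taxon_id = c("t1", "t2", "t3", "t4"),
    rrn_copy_number = c(2, 3, 6, NA),
    sample_id = "s1",
    read_count = c(40, 20, 40, 13)
  )
  out <- trophic_ratio(taxa)
  expect_equal(out$oligotroph, 60)
  expect_equal(out$copiotroph, 40)
  expect_equal(out$oligo_to_copio, 1.5)
  expect_equal(out$copio_to_oligo, 1 / 1.5)
  expect_equal(out$n_unclassified_taxa, 1)
  # uniform read rescaling leaves the ratio unchanged
  taxa10 <- taxa
  taxa10$read_count <- taxa10$read_count * 10
  expect_equal(trophic_ratio(taxa10)$oligo_to_copio, 1.5)
  # equal reads give a unit ratio
  eq <- taxa
  eq$read_count <- c(30, 30, 60, 0)
  expect_equal(trophic_ratio(eq)$oligo_to_copio, 1)
})

test_that("samples without copiotroph reads get a missing ratio", {
  taxa <- tibble::tibble(
    taxon_id = c("t1", "t2"),
    rrn_copy_number = c(2, 3),
    sample_id = "s1",
    read_count = c(10, 5)
  )
  expect_message(out <- trophic_ratio(taxa))
  expect_true(is.na(out$oligo_to_copio))
  expect_equal(out$copio_to_oligo, 0)
})

test_that("the taxon-count option weights taxa instead of reads", {
  taxa <- tibble::tibble(
    taxon_id = c("t1", "t2", "t3"),
    rrn_copy_number = c(2, 3, 7),
    sample_id = "s1",
    read_count = c(1000, 1, 10)
  )
  out <- trophic_ratio(taxa, unit = "taxa")
  expect_equal(out$oligo_to_copio, 2)
})
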