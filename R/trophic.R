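#' Classify taxa into copiotrophic or oligotrophic lifestyles
#'
#' Fast-growing copiotrophs carry many rRNA (rrn) operon copies per genome,
#' slow-growing oligotrophs few; a taxon is labelled a copiotroph when its
#' mean rrn copy number is at or above the threshold (default 5 copies) and
#' an oligotroph below it. Taxa without a copy-number estimate (no rrnDB
#' match at any assigned rank) come back as `"unclassified"`.
#'
#' @param copy_number Mean rrn copies per genome for the lowest assigned
#'   taxonomic rank; positive, `NA` allowed for unmatched taxa.
#' @param threshold Copy-number threshold, default 5.
#'
#' @return Character vector: `"copiotroph"`, `"oligotroph"` or
#'   `"unclassified"`.
#' @examples
#' classify_trophic(c(5, 4.9, 1, NA))
#' @export
classify_trophic <- function(copy_number, threshold = 5) {
  if (any(!is.na(copy_number) & copy_number <= 0)) {
    abort("rrn copy numbers must be positive.",
          class = "rhizotrace_error_copy_number")
  }
  dplyr::case_when(
    is.na(copy_number) ~ "unclassified",
    copy_number >= threshold ~ "copiotroph",
    .default = "oligotroph"
  )
}

#' Per-sample oligotroph:copiotroph ratios
#'
#' Sums read counts (or counts taxa) per trophic class and sample, and emits
#' the community ratio in both orientations. Unclassified taxa are excluded
#' from both numerator and denominator and reported separately. A sample
#' without copiotroph (or oligotroph) reads gets a missing ratio rather than
#' an error, with a message, since such samples are data, not bugs.
#'
#' @param taxa Tibble with columns `taxon_id`, `rrn_copy_number`,
#'   `sample_id`, `read_count`.
#' @param threshold Copy-number threshold passed to [classify_trophic()].
#' @param unit `"reads"` (default) weights the ratio by read counts;
#'   `"taxa"` counts distinct taxa with at least one read instead.
#'
#' @return Tibble with one row per sample: class read/taxon totals,
#'   `n_unclassified_taxa`, `oligo_to_copio`, `copio_to_oligo`.
#' @export
trophic_ratio <- function(taxa, threshold = 5, unit = c("reads", "taxa")) {
  unit <- match.arg(unit)
  required <- c("taxon_id", "rrn_copy_number", "sample_id", "read_count")
  missing_cols <- setdiff(required, names(taxa))
  if (length(missing_cols) > 0) {
    abort(paste0("`taxa` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "rhizotrace_error_schema")
  }
  if (any(!is.na(taxa$read_count) & taxa$read_count < 0)) {
    abort("Read counts must be nonnegative.",
          class = "rhizotrace_error_schema")
  }

  classed <- dplyr::mutate(
    taxa, trophic = classify_trophic(rrn_copy_number, threshold)
  )
  weight <- if (unit == "reads") {
    function(reads) sum(reads)
  } else {
    function(reads) sum(reads > 0)
  }
  out <- classed |>
    dplyr::summarise(
      oligotroph = weight(read_count[trophic == "oligotroph"]),
      copiotroph = weight(read_count[trophic == "copiotroph"]),
      unclassified = weight(read_count[trophic == "unclassified"]),
      n_unclassified_taxa = dplyr::n_distinct(
        taxon_id[trophic == "unclassified"]),
      .by = sample_id
    ) |>
    dplyr::mutate(
      oligo_to_copio = ifelse(copiotroph > 0, oligotroph / copiotroph,
                              NA_real_),
      copio_to_oligo = ifelse(oligotroph > 0, copiotroph / oligotroph,
                              NA_real_)
    )
  if (anyNA(out$oligo_to_copio) || anyNA(out$copio_to_oligo)) {
    inform("Some samples lack reads in one trophic class; ratio set to NA.")
  }
  out
}
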