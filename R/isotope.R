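#' Isotope constants for the two-isotope carbon system
#'
#' Bundles the molar masses of the two stable carbon isotopes and the
#' \eqn{^{13}C/^{12}C} ratio of the VPDB standard. All conversions in the
#' package take their constants from one of these objects, so switching to an
#' alternative convention (e.g. a truncated `R_VPDB = 0.011180`) changes
#' results reproducibly in one place.
#'
#' @param M12 Molar mass of \eqn{^{12}C} in g mol\eqn{^{-1}}.
#' @param M13 Molar mass of \eqn{^{13}C} in g mol\eqn{^{-1}}.
#' @param R_VPDB \eqn{^{13}C/^{12}C} isotope ratio of the VPDB standard
#'   (dimensionless).
#'
#' @return An immutable object of class `isotope_constants` with elements
#'   `M12`, `M13` and `R_VPDB`.
#'
#' @examples
#' cst <- isotope_constants()
#' cst$R_VPDB
#' @export
isotope_constants <- function(M12 = 12, M13 = 13.0033548, R_VPDB = 0.0111802) {
  if (!is.numeric(M12) || !is.numeric(M13) || !is.numeric(R_VPDB) ||
      length(M12) != 1L || length(M13) != 1L || length(R_VPDB) != 1L) {
    abort("`M12`, `M13` and `R_VPDB` must be length-1 numerics.",
          class = "rhizotrace_error_constants")
  }
  if (!(M13 > M12 && M12 > 0)) {
    abort("Isotope molar masses must satisfy M13 > M12 > 0.",
          class = "rhizotrace_error_constants")
  }
  if (!(R_VPDB > 0 && R_VPDB < 1)) {
    abort("`R_VPDB` must lie strictly between 0 and 1.",
          class = "rhizotrace_error_constants")
  }
  structure(list(M12 = M12, M13 = M13, R_VPDB = R_VPDB),
            class = "isotope_constants")
}

#' @export
print.isotope_constants <- function(x, ...) {
  cat("<isotope_constants>\n",
      "  M12    = ", format(x$M12), " g/mol\n",
      "  M13    = ", format(x$M13), " g/mol\n",
      "  R_VPDB = ", format(x$R_VPDB), "\n", sep = "")
  invisible(x)
}

# mean molar mass of carbon at 13C atom fraction x13 (g/mol); the
# denominator of the excess-mass equation
mean_molar_mass <- function(x13, constants) {
  (1 - x13) * constants$M12 + x13 * constants$M13
}

#' Convert delta-13C to 13C atom fraction
#'
#' Applies the standard delta-notation relations: the sample isotope ratio is
#' \eqn{R = R_{VPDB} (\delta/1000 + 1)} and the \eqn{^{13}C} atom fraction is
#' \eqn{\chi^{13} = R/(1+R)}; the \eqn{^{12}C} fraction is its complement
#' under the binary-isotope assumption.
#'
#' @param delta delta-13C values in permil vs VPDB; must exceed -1000
#'   (delta = -1000 permil would mean zero \eqn{^{13}C}).
#' @param constants An [isotope_constants()] object.
#'
#' @return Numeric vector of \eqn{^{13}C} atom fractions, same length as
#'   `delta`. `NA` values pass through.
#'
#' @seealso [atom_fraction_to_delta()] for the inverse.
#' @examples
#' delta_to_atom_fraction(0)     # VPDB itself
#' delta_to_atom_fraction(-29.3) # typical extraneous organic matter
#' @export
delta_to_atom_fraction <- function(delta, constants = isotope_constants()) {
  stopifnot(inherits(constants, "isotope_constants"))
  bad <- !is.na(delta) & delta <= -1000
  if (any(bad)) {
    abort(
      sprintf("delta-13C values must exceed -1000 permil (got %s).",
              paste(format(delta[bad][seq_len(min(3, sum(bad)))]), collapse = ", ")),
      class = "rhizotrace_error_invalid_delta"
    )
  }
  R <- constants$R_VPDB * (delta / 1000 + 1)
  R / (1 + R)
}

#' Convert 13C atom fraction to delta-13C
#'
#' Inverse of [delta_to_atom_fraction()]:
#' \eqn{\delta = 1000 (R/R_{VPDB} - 1)} with \eqn{R = \chi^{13}/(1-\chi^{13})}.
#'
#' @param x13 \eqn{^{13}C} atom fractions, strictly inside (0, 1).
#' @inheritParams delta_to_atom_fraction
#'
#' @return Numeric vector of delta-13C values (permil vs VPDB).
#' @examples
#' atom_fraction_to_delta(delta_to_atom_fraction(-26))
#' @export
atom_fraction_to_delta <- function(x13, constants = isotope_constants()) {
  stopifnot(inherits(constants, "isotope_constants"))
  bad <- !is.na(x13) & (x13 <= 0 | x13 >= 1)
  if (any(bad)) {
    abort("13C atom fractions must lie strictly between 0 and 1.",
          class = "rhizotrace_error_invalid_fraction")
  }
  R <- x13 / (1 - x13)
  1000 * (R / constants$R_VPDB - 1)
}

#' 13C atom excess relative to a natural-abundance reference
#'
#' The atom excess is the labelled sample's \eqn{^{13}C} atom fraction minus
#' the atom fraction of its natural-abundance reference, measured on
#' unlabelled material from the corresponding treatment and soil layer.
#' Negative values (sample below its reference) are retained, not clipped:
#' clipping would bias compartment sums. Callers that need to surface such
#' cases should flag them (the pipeline logs them).
#'
#' @param labelled \eqn{^{13}C} atom fraction(s) of the labelled sample.
#' @param reference \eqn{^{13}C} atom fraction(s) of the natural-abundance
#'   reference.
#' @param reference_id Optional identifier of the reference record used;
#'   attached as attribute `reference_id` when supplied.
#'
#' @return Numeric vector of atom-excess fractions (dimensionless).
#' @examples
#' atom_excess(0.02, 0.011)
#' @export
atom_excess <- function(labelled, reference, reference_id = NULL) {
  ok <- function(x) is.na(x) | (x > 0 & x < 1)
  if (!all(ok(labelled)) || !all(ok(reference))) {
    abort("Atom fractions must lie strictly between 0 and 1.",
          class = "rhizotrace_error_invalid_fraction")
  }
  out <- labelled - reference
  if (!is.null(reference_id)) attr(out, "reference_id") <- reference_id
  out
}

#' Mass of excess 13C in a carbon pool
#'
#' Converts an atom-excess fraction and a carbon mass per area into the mass
#' of tracer-derived \eqn{^{13}C} per area:
#' \deqn{m^{E}(^{13}C) = \frac{\chi^{E}\, m(C)\, M(^{13}C)}
#'   {\chi(^{12}C) M(^{12}C) + \chi(^{13}C) M(^{13}C)}}
#' The denominator is the mean molar mass of carbon at the *measured* sample's
#' atom fractions, so `x13` must be the labelled sample's \eqn{^{13}C} atom
#' fraction, not the excess.
#'
#' @param excess Atom-excess fraction(s) \eqn{\chi^E} (dimensionless).
#' @param carbon_mass Total carbon mass of the pool, g C m\eqn{^{-2}}
#'   (nonnegative).
#' @param x13 \eqn{^{13}C} atom fraction(s) of the measured (labelled) sample.
#' @inheritParams delta_to_atom_fraction
#'
#' @return Excess \eqn{^{13}C} mass in g m\eqn{^{-2}}; linear in both
#'   `excess` and `carbon_mass`, zero when `excess` is zero.
#' @examples
#' excess_mass(0.001, 100, 0.011)
#' @export
excess_mass <- function(excess, carbon_mass, x13,
                        constants = isotope_constants()) {
  stopifnot(inherits(constants, "isotope_constants"))
  if (any(!is.na(carbon_mass) & carbon_mass < 0)) {
    abort("`carbon_mass` must be nonnegative.",
          class = "rhizotrace_error_negative_mass")
  }
  excess * carbon_mass * constants$M13 / mean_molar_mass(x13, constants)
}
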