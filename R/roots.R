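#' Root carbon fraction of a contaminated fine-root sample
#'
#' Two-pool isotope mixing correction for extraneous organic matter (EOM):
#' washed fine-root samples from the topsoil contain non-root organic carbon
#' (residues of organic amendments, litter, fauna, roots of preceding crops),
#' whose natural-abundance signature dilutes the labelled root signal. With
#' atom excesses of the total sample (\eqn{\chi^E_S}), the clean-root
#' endmember (\eqn{\chi^E_{RB}}) and the EOM endmember (\eqn{\chi^E_{EOM}}),
#' the root carbon mass fraction of the sample is
#' \deqn{f_{RBC} = \frac{\chi^E_S - \chi^E_{EOM}}
#'   {\chi^E_{RB} - \chi^E_{EOM}}.}
#' The ratio is invariant under any common shift of the three excesses, so a
#' shared reference cancels.
#'
#' Measurement noise can push the raw ratio outside \[0, 1\]; by default such
#' values are clamped with a warning carrying the raw values, since erroring
#' would discard otherwise usable replicates while silent clamping would hide
#' endmember violations.
#'
#' @param sample_excess Atom excess of the total fine-root sample.
#' @param root_excess Atom excess of the clean-root endmember.
#' @param eom_excess Atom excess of the EOM endmember.
#' @param clamp Clamp raw values outside \[0, 1\]? Default `TRUE`.
#' @param tol Smallest admissible endmember separation
#'   `|root_excess - eom_excess|`; below it the mixture is degenerate.
#'
#' @return Numeric vector of root-C mass fractions \eqn{f_{RBC}}.
#' @examples
#' eom_root_fraction(0.005, 0.01, 0)   # midway -> 0.5
#' @export
eom_root_fraction <- function(sample_excess, root_excess, eom_excess,
                              clamp = TRUE, tol = 1e-12) {
  denom <- root_excess - eom_excess
  if (any(!is.na(denom) & abs(denom) < tol)) {
    abort("Clean-root and EOM endmembers coincide: mixing model is degenerate.",
          class = "rhizotrace_error_degenerate_mixing")
  }
  raw <- (sample_excess - eom_excess) / denom
  out <- raw
  if (clamp) {
    off <- !is.na(raw) & (raw < 0 | raw > 1)
    if (any(off)) {
      warn(
        sprintf(
          "%d f_RBC value(s) outside [0, 1] clamped (raw: %s).",
          sum(off),
          paste(format(raw[off][seq_len(min(3, sum(off)))], digits = 4),
                collapse = ", ")
        ),
        class = "rhizotrace_warning_frbc_clamped",
        raw = raw[off]
      )
      out <- pmin(pmax(raw, 0), 1)
    }
  }
  out
}

#' Scale mass-related carbon to soil surface area
#'
#' Converts carbon per unit dry soil mass into carbon per soil surface area
#' for one layer: \eqn{RC_S = RC_M \, \rho \, z}, with bulk density
#' \eqn{\rho} (kg m\eqn{^{-3}}) and layer height \eqn{z} (m).
#'
#' @param mass_based Carbon content in g C kg\eqn{^{-1}} dry soil.
#' @param bulk_density Soil bulk density in kg m\eqn{^{-3}}.
#' @param thickness Layer height in m.
#'
#' @return Carbon per area in g C m\eqn{^{-2}}.
#' @examples
#' area_scale(1, 1300, 0.25)
#' @export
area_scale <- function(mass_based, bulk_density, thickness) {
  if (any(!is.na(bulk_density) & bulk_density <= 0) ||
      any(!is.na(thickness) & thickness <= 0)) {
    abort("Bulk density and layer thickness must be positive.",
          class = "rhizotrace_error_geometry")
  }
  mass_based * bulk_density * thickness
}

#' Aggregate root carbon and excess 13C over classes and positions
#'
#' Applies the sampling-scheme aggregation used at harvest: in the topsoil
#' layer the crown-root carbon (and excess) is summed into the coarse-root
#' class, while in the deeper layers, sampled by paired cores within and
#' between crop rows, the two positions are averaged per root class. Both
#' `carbon_g_m2` and `excess_g_m2` are aggregated with the same rules, which
#' conserve topsoil mass (sums) and are unbiased for the layer mean
#' (position averages).
#'
#' Any EOM correction of topsoil fine roots must be applied to the input
#' values beforehand (see [eom_root_fraction()]); this function only
#' aggregates.
#'
#' @param roots Tibble with columns `plot_id`, `layer`, `position`
#'   (`within_row`, `between_row`, or `monolith`), `root_class` (`crown`,
#'   `coarse`, `fine`), `carbon_g_m2`, `excess_g_m2`.
#' @param topsoil Label of the topsoil layer. Default `"0-0.25"`.
#'
#' @return Tibble with one row per `plot_id` x `layer` x `root_class`
#'   (classes `coarse`, `fine`) and aggregated `carbon_g_m2`, `excess_g_m2`.
#' @export
aggregate_roots <- function(roots, topsoil = "0-0.25") {
  required <- c("plot_id", "layer", "position", "root_class",
                "carbon_g_m2", "excess_g_m2")
  missing_cols <- setdiff(required, names(roots))
  if (length(missing_cols) > 0) {
    abort(paste0("`roots` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "rhizotrace_error_schema")
  }

  top <- dplyr::filter(roots, layer == topsoil)
  deep <- dplyr::filter(roots, layer != topsoil)

  # deeper layers need both row positions per class; a lone core cannot be
  # averaged into an unbiased layer value
  if (nrow(deep) > 0) {
    chk <- deep |>
      dplyr::summarise(
        ok = all(sort(unique(position)) == c("between_row", "within_row")),
        .by = c(plot_id, layer, root_class)
      )
    if (!all(chk$ok)) {
      bad <- dplyr::filter(chk, !ok)
      abort(
        paste0("Incomplete sampling design below the topsoil: need both ",
               "within_row and between_row entries for ",
               paste(utils::head(paste(bad$plot_id, bad$layer, bad$root_class,
                                       sep = "/"), 5), collapse = "; ")),
        class = "rhizotrace_error_incomplete_design"
      )
    }
    deep_agg <- deep |>
      dplyr::summarise(
        carbon_g_m2 = mean(carbon_g_m2),
        excess_g_m2 = mean(excess_g_m2),
        .by = c(plot_id, layer, root_class)
      )
  } else {
    deep_agg <- deep[, c("plot_id", "layer", "root_class",
                         "carbon_g_m2", "excess_g_m2")]
  }

  top_agg <- top |>
    dplyr::mutate(root_class = ifelse(root_class == "crown", "coarse",
                                      root_class)) |>
    dplyr::summarise(
      carbon_g_m2 = sum(carbon_g_m2),
      excess_g_m2 = sum(excess_g_m2),
      .by = c(plot_id, layer, root_class)
    )

  dplyr::bind_rows(top_agg, deep_agg) |>
    dplyr::arrange(plot_id, layer, root_class)
}
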