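#' Percent carbon derived from rhizodeposition
#'
#' Tracer mass-balance partition of a soil layer's excess \eqn{^{13}C}
#' between rhizodeposits and roots:
#' \deqn{\%CdfR = \frac{m^E(^{13}C)_{soil}}
#'   {m^E(^{13}C)_{soil} + m^E(^{13}C)_{root}} \times 100}
#' where the root excess sums all root classes present in the layer (crown,
#' coarse and fine roots in the topsoil; coarse and fine below).
#'
#' Rows where both excesses are zero (or their sum is nonpositive) carry no
#' tracer information; they return `NA` with a warning so that callers can
#' flag and exclude the plot rather than crash a whole run.
#'
#' @param soil_excess Soil excess \eqn{^{13}C} mass, g m\eqn{^{-2}}.
#' @param root_excess Root excess \eqn{^{13}C} mass (summed over classes),
#'   g m\eqn{^{-2}}.
#'
#' @return Percent of layer excess \eqn{^{13}C} attributable to
#'   rhizodeposition, in \[0, 100) for valid tracer data.
#' @examples
#' percent_cdfr(0.3, 0.1)
#' @export
percent_cdfr <- function(soil_excess, root_excess) {
  total <- soil_excess + root_excess
  und <- !is.na(total) & total <= 0
  if (any(und)) {
    warn(sprintf("%d layer(s) with nonpositive total excess 13C: %%CdfR undefined, set to NA.",
                 sum(und)),
         class = "rhizotrace_warning_undefined_partition")
  }
  out <- soil_excess / total * 100
  out[und] <- NA_real_
  out
}

#' Quantity of carbon derived from rhizodeposition
#'
#' Converts the percent partition into an absolute carbon flux using the
#' layer's corrected total root carbon \eqn{RC_S}:
#' \deqn{qCdfR = \frac{\%CdfR \cdot RC_S}{100 - \%CdfR}}
#' which satisfies the identity \eqn{qCdfR/(qCdfR + RC_S) = \%CdfR/100}.
#' The construction rests on two assumptions: the \eqn{^{13}C} enrichment of
#' the roots is homogeneous, and roots and rhizodeposits are equally
#' enriched.
#'
#' @param pct Percent carbon derived from rhizodeposition, in \[0, 100).
#' @param root_carbon Corrected total root carbon of the layer,
#'   g C m\eqn{^{-2}}.
#'
#' @return Net rhizodeposition carbon in g C m\eqn{^{-2}}.
#' @examples
#' q_cdfr(50, 100)
#' @export
q_cdfr <- function(pct, root_carbon) {
  if (any(!is.na(pct) & (pct < 0 | pct >= 100))) {
    abort("`pct` must lie in [0, 100): the partition is singular at 100%.",
          class = "rhizotrace_error_singular_partition")
  }
  if (any(!is.na(root_carbon) & root_carbon < 0)) {
    abort("`root_carbon` must be nonnegative.",
          class = "rhizotrace_error_negative_mass")
  }
  pct * root_carbon / (100 - pct)
}

#' Rhizodeposition carbon relative to total belowground carbon input
#'
#' @param q Net rhizodeposition carbon, g C m\eqn{^{-2}}.
#' @param root_carbon Root carbon, g C m\eqn{^{-2}}.
#'
#' @return Fraction `q / (q + root_carbon)` in \[0, 1\]; `NA` with a warning
#'   when both inputs are zero.
#' @examples
#' relative_rhizodeposition(237, 99) # rhizodeposits ~70.5% of belowground C
#' @export
relative_rhizodeposition <- function(q, root_carbon) {
  total <- q + root_carbon
  und <- !is.na(total) & total <= 0
  if (any(und)) {
    warn("Zero belowground carbon: relative rhizodeposition undefined, set to NA.",
         class = "rhizotrace_warning_undefined_partition")
  }
  out <- q / total
  out[und] <- NA_real_
  out
}

#' Relative carbon-allocation coefficients of the whole plant
#'
#' Expresses each destination of net assimilated carbon (grain, straw, root,
#' rhizodeposition) as its proportion of whole-plant carbon. Coefficients
#' are nonnegative and sum to one by construction.
#'
#' @param grain_c,straw_c,root_c,rhizo_c Carbon per area of each component,
#'   g C m\eqn{^{-2}}; vectors are recycled rowwise.
#'
#' @return Tibble with columns `grain`, `straw`, `root`, `rhizo` (fractions)
#'   and `total_c` (g C m\eqn{^{-2}}).
#' @examples
#' allocation_coefficients(300, 300, 100, 300)
#' @export
allocation_coefficients <- function(grain_c, straw_c, root_c, rhizo_c) {
  comps <- vctrs_recycle(grain_c, straw_c, root_c, rhizo_c)
  total <- comps[[1]] + comps[[2]] + comps[[3]] + comps[[4]]
  if (any(!is.na(total) & total <= 0)) {
    abort("Total plant carbon must be positive to form allocation coefficients.",
          class = "rhizotrace_error_undefined_partition")
  }
  neg <- vapply(comps, function(x) any(!is.na(x) & x < 0), logical(1))
  if (any(neg)) {
    abort("Allocation components must be nonnegative.",
          class = "rhizotrace_error_negative_mass")
  }
  tibble(
    grain = comps[[1]] / total,
    straw = comps[[2]] / total,
    root = comps[[3]] / total,
    rhizo = comps[[4]] / total,
    total_c = total
  )
}

# minimal common-length recycling for scalar-or-equal-length args
vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(lengths(xs))
  lapply(xs, function(x) {
    if (length(x) == n) x
    else if (length(x) == 1L) rep(x, n)
    else abort("Arguments must have length 1 or a common length.",
               class = "rhizotrace_error_length")
  })
}

#' Root-to-shoot and belowground-to-aboveground carbon ratios
#'
#' The root-to-shoot ratio divides root carbon by straw carbon; the
#' belowground-to-aboveground ratio divides root plus rhizodeposition carbon
#' by straw plus grain carbon. Both are scale-invariant.
#'
#' @inheritParams allocation_coefficients
#'
#' @return Tibble with columns `root_to_shoot` and `below_to_above`.
#' @examples
#' carbon_ratios(300, 300, 100, 300)
#' @export
carbon_ratios <- function(grain_c, straw_c, root_c, rhizo_c) {
  comps <- vctrs_recycle(grain_c, straw_c, root_c, rhizo_c)
  if (any(!is.na(comps[[2]]) & comps[[2]] <= 0) ||
      any(!is.na(comps[[1]] + comps[[2]]) & (comps[[1]] + comps[[2]]) <= 0)) {
    abort("Straw carbon and aboveground carbon must be positive for ratios.",
          class = "rhizotrace_error_undefined_ratio")
  }
  tibble(
    root_to_shoot = comps[[3]] / comps[[2]],
    below_to_above = (comps[[3]] + comps[[4]]) / (comps[[1]] + comps[[2]])
  )
}

#' Treatment-level summary of per-plot results
#'
#' Descriptive summary over replicate plots: group means and standard errors
#' per cropping system x water regime, plus the pooled summary across
#' systems, and the percent change of the drought regime relative to the
#' control. Inferential modelling (mixed models, multiple-comparison
#' adjustment) is out of scope here and left to dedicated tools.
#'
#' @param results Tibble of per-plot values with at least the grouping
#'   columns and the variables in `vars`.
#' @param vars Character vector of numeric columns to summarise.
#' @param group_col Column holding the cropping system (or other grouping)
#'   label. Default `"system"`.
#' @param regime_col Column holding the water-regime label. Default
#'   `"regime"`.
#' @param control,treatment Regime labels contrasted in the percent change.
#' @param pooled Also emit a pooled group `"all"` across systems? Default
#'   `TRUE`.
#'
#' @return Tibble with one row per group x variable: `n_control`,
#'   `mean_control`, `se_control`, `n_treatment`, `mean_treatment`,
#'   `se_treatment`, `pct_change`. Standard errors of single-plot groups are
#'   `NA` (with a message).
#' @export
treatment_summary <- function(results, vars,
                              group_col = "system", regime_col = "regime",
                              control = "rainfed", treatment = "drought",
                              pooled = TRUE) {
  missing_cols <- setdiff(c(group_col, regime_col, vars), names(results))
  if (length(missing_cols) > 0) {
    abort(paste0("`results` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "rhizotrace_error_schema")
  }
  base <- results[, c(group_col, regime_col, vars)]
  names(base)[1:2] <- c(".group", ".regime")
  if (pooled) {
    all_grp <- base
    all_grp$.group <- "all"
    base <- dplyr::bind_rows(base, all_grp)
  }
  present <- unique(base$.regime)
  if (!all(c(control, treatment) %in% present)) {
    abort(sprintf("Regime level(s) missing from data: %s",
                  paste(setdiff(c(control, treatment), present),
                        collapse = ", ")),
          class = "rhizotrace_error_missing_group")
  }

  long <- tidyr::pivot_longer(base, cols = dplyr::all_of(vars),
                              names_to = "variable", values_to = "value")
  stats_tbl <- long |>
    dplyr::summarise(
      n = sum(!is.na(value)),
      mean = mean(value, na.rm = TRUE),
      se = if (sum(!is.na(value)) >= 2) {
        stats::sd(value, na.rm = TRUE) / sqrt(sum(!is.na(value)))
      } else NA_real_,
      .by = c(.group, .regime, variable)
    )
  if (any(stats_tbl$n < 2)) {
    inform("Standard error reported as NA for group(s) with fewer than 2 plots.")
  }

  wide <- stats_tbl |>
    dplyr::filter(.regime %in% c(control, treatment)) |>
    dplyr::mutate(.regime = ifelse(.regime == control, "control", "treatment")) |>
    tidyr::pivot_wider(names_from = .regime,
                       values_from = c(n, mean, se),
                       names_glue = "{.value}_{.regime}") |>
    dplyr::mutate(pct_change = (mean_treatment - mean_control) /
                    mean_control * 100)
  names(wide)[names(wide) == ".group"] <- group_col
  wide
}
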