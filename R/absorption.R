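#' Sun et al. "all drugs" Caco-2 to jejunal permeability regression
#'
#' Constants of the published log-log regression relating Caco-2 apparent
#' permeability (1e-6 cm/s) to human jejunal effective permeability
#' (1e-4 cm/s), "all drugs" set at pH 7. Shipped as configuration so an
#' alternative transcription can be substituted.
#'
#' @return Named list with `slope`, `intercept`, `papp_unit` (cm/s value of
#'   one Papp unit) and `peff_unit` (cm/s value of one Peff unit).
#' @export
sun_regression <- function() {
  list(slope = 0.4926, intercept = -0.1454, papp_unit = 1e-6, peff_unit = 1e-4)
}

#' Aggregate apparent permeability values for one chemical
#'
#' Pools all available Caco-2 Papp values (in vitro and QSAR-predicted,
#' treated with equal weight) into a single mean.
#'
#' @param papp_values Numeric vector of Papp values (1e-6 cm/s), or a data
#'   frame with a `papp` column (e.g. one chemical's rows of [default_papp()]).
#' @return Mean Papp in 1e-6 cm/s.
#' @export
aggregate_papp <- function(papp_values) {
  if (is.data.frame(papp_values)) {
    if (!"papp" %in% names(papp_values)) {
      rlang::abort("Data frame input must have a `papp` column.", class = "bispbk_input_error")
    }
    papp_values <- papp_values$papp
  }
  if (length(papp_values) == 0) {
    rlang::abort("No Papp values available.", class = "bispbk_input_error")
  }
  if (any(papp_values <= 0)) {
    rlang::abort("All Papp values must be positive.", class = "bispbk_input_error")
  }
  average_property(papp_values)
}

#' Convert apparent to effective intestinal permeability
#'
#' Applies a log-log regression (default: [sun_regression()]) to scale a mean
#' Caco-2 apparent permeability to an in vivo effective jejunal permeability.
#'
#' @param papp_mean Mean apparent permeability, 1e-6 cm/s.
#' @param regression Regression constants, see [sun_regression()].
#' @return Effective permeability Peff, 1e-4 cm/s.
#' @export
papp_to_peff <- function(papp_mean, regression = sun_regression()) {
  if (!is.numeric(papp_mean) || any(papp_mean <= 0)) {
    rlang::abort("`papp_mean` must be positive.", class = "bispbk_input_error")
  }
  10^(regression$slope * log10(papp_mean) + regression$intercept)
}

#' First-order intestinal uptake rate from effective permeability
#'
#' Uses the cylindrical-lumen relation ka = 2 Peff / R, converting to 1/h.
#'
#' @param peff Effective permeability, 1e-4 cm/s (see [sun_regression()]
#'   units).
#' @param intestinal_radius Small-intestinal radius, cm.
#' @param peff_unit Value of one Peff unit in cm/s (default 1e-4).
#' @return Uptake rate constant ka, 1/h.
#' @export
peff_to_ka <- function(peff, intestinal_radius, peff_unit = 1e-4) {
  if (any(peff < 0)) {
    rlang::abort("`peff` must be non-negative.", class = "bispbk_input_error")
  }
  if (!is.numeric(intestinal_radius) || any(intestinal_radius <= 0)) {
    rlang::abort("`intestinal_radius` must be positive.", class = "bispbk_input_error")
  }
  2 * peff * peff_unit / intestinal_radius * 3600
}

#' Absorption parameters for a set of chemicals
#'
#' Chains Papp aggregation, the permeability regression and the uptake-rate
#' relation for every chemical in a long-format Papp table.
#'
#' @param papp_table Data frame with columns `name`, `source`, `papp`
#'   (1e-6 cm/s), e.g. [default_papp()].
#' @param physiology A physiology row (see [default_physiologies()]) supplying
#'   `intestinal_radius`.
#' @param regression Permeability regression constants.
#' @return Tibble with one row per chemical: `name`, `papp_mean`, `peff`, `ka`.
#' @export
absorption_params <- function(papp_table, physiology,
                              regression = sun_regression()) {
  papp_table |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(papp_mean = aggregate_papp(.data$papp), .groups = "drop") |>
    dplyr::mutate(
      peff = papp_to_peff(.data$papp_mean, regression),
      ka = peff_to_ka(.data$peff, physiology$intestinal_radius,
                      peff_unit = regression$peff_unit)
    )
}
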