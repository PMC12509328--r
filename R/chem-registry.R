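#' Average a set of property estimates
#'
#' Physicochemical inputs (logP, pKa, apparent permeability) are typically
#' available from several prediction sources; model robustness is improved by
#' pooling them with equal weight. This helper is the single place that
#' pooling happens.
#'
#' @param values Numeric vector of property estimates from different sources.
#' @return A single numeric value, the arithmetic mean.
#' @examples
#' average_property(c(2, 4)) # 3
#' @export
average_property <- function(values) {
  if (length(values) == 0) {
    rlang::abort("`values` must be non-empty.", class = "bispbk_input_error")
  }
  if (!is.numeric(values) || any(!is.finite(values))) {
    rlang::abort("`values` must be finite numeric.", class = "bispbk_input_error")
  }
  mean(values)
}

#' Build a chemical registry from a property table
#'
#' Validates a table of per-chemical physicochemical properties and returns a
#' registry tibble, one row per chemical. The glucuronide molar mass defaults
#' to the parent mass plus 176.12 g/mol (the glucuronic acid adduct) when the
#' `mw_glucuronide` column is absent or `NA`.
#'
#' @param data Data frame with columns `name`, `mw_parent`, `logp`, `pka` and
#'   optionally `mw_glucuronide` and `fu_parent`, `fu_glucuronide`.
#' @return A tibble, one validated row per chemical.
#' @export
load_chemical_table <- function(data) {
  required <- c("name", "mw_parent", "logp", "pka")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("Chemical table is missing column(s): ", paste(missing, collapse = ", ")),
      class = "bispbk_input_error"
    )
  }
  if (anyDuplicated(data$name)) {
    dup <- unique(data$name[duplicated(data$name)])
    rlang::abort(
      paste0("Duplicate chemical name(s): ", paste(dup, collapse = ", ")),
      class = "bispbk_input_error"
    )
  }
  if (any(!is.finite(data$mw_parent)) || any(data$mw_parent <= 0)) {
    rlang::abort("`mw_parent` must be positive and finite.", class = "bispbk_input_error")
  }
  out <- tibble::as_tibble(data)
  if (!"mw_glucuronide" %in% names(out)) {
    out$mw_glucuronide <- NA_real_
  }
  out$mw_glucuronide <- ifelse(
    is.na(out$mw_glucuronide),
    out$mw_parent + glucuronide_mass_increment(),
    out$mw_glucuronide
  )
  if (any(out$mw_glucuronide <= out$mw_parent)) {
    rlang::abort("`mw_glucuronide` must exceed `mw_parent`.", class = "bispbk_input_error")
  }
  out
}

#' Molar mass added by glucuronic acid conjugation
#'
#' @return Mass increment in g/mol for a glucuronide relative to its parent.
#' @export
glucuronide_mass_increment <- function() 176.12

#' Default chemical property table for the seven bisphenols
#'
#' Molar masses are the standard values for each parent compound; logP and pKa
#' are representative predicted values. The table is a self-contained default
#' so the whole workflow runs out of the box; users studying their own data
#' supply a table of the same shape to [load_chemical_table()].
#'
#' @return A tibble with one row per chemical (BPA, BPAF, BPB, BPE, BPF, BPM,
#'   BPS) and columns `name`, `mw_parent`, `mw_glucuronide`, `logp`, `pka`,
#'   `fu_parent`, `fu_glucuronide`.
#' @export
default_chemicals <- function() {
  load_chemical_table(tibble::tibble(
    name = c("BPA", "BPAF", "BPB", "BPE", "BPF", "BPM", "BPS"),
    mw_parent = c(228.29, 336.23, 242.31, 214.26, 200.23, 346.46, 250.27),
    logp = c(3.3, 4.5, 4.1, 3.2, 2.9, 6.2, 1.9),
    pka = c(9.6, 9.2, 9.9, 9.8, 9.9, 10.1, 8.2),
    fu_parent = c(0.04, 0.02, 0.03, 0.05, 0.06, 0.005, 0.12),
    fu_glucuronide = rep(0.15, 7)
  ))
}

#' Default apparent permeability table (synthetic)
#'
#' Long-format Caco-2 apparent permeability values per chemical and source.
#' In vitro measurements exist only for BPA, BPF and BPS; the remaining
#' entries emulate two QSAR predictors. Values are synthetic defaults of
#' realistic magnitude, not measured data.
#'
#' @return Tibble with columns `name`, `source` (`in_vitro`, `QSAR-K`,
#'   `QSAR-L`) and `papp` (1e-6 cm/s).
#' @export
default_papp <- function() {
  tibble::tribble(
    ~name, ~source, ~papp,
    "BPA", "in_vitro", 35, "BPA", "QSAR-K", 32, "BPA", "QSAR-L", 29,
    "BPAF", "QSAR-K", 26, "BPAF", "QSAR-L", 22,
    "BPB", "QSAR-K", 33, "BPB", "QSAR-L", 28,
    "BPE", "QSAR-K", 31, "BPE", "QSAR-L", 27,
    "BPF", "in_vitro", 33, "BPF", "QSAR-K", 30, "BPF", "QSAR-L", 26,
    "BPM", "QSAR-K", 20, "BPM", "QSAR-L", 9,
    "BPS", "in_vitro", 12, "BPS", "QSAR-K", 5, "BPS", "QSAR-L", 6
  )
}

#' Write / read a chemical registry as delimited text
#'
#' @param data Registry tibble from [load_chemical_table()].
#' @param path File path for the CSV.
#' @return `write_chemical_table()` returns `path` invisibly;
#'   `read_chemical_table()` returns a validated registry tibble.
#' @export
write_chemical_table <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_chemical_table
#' @export
read_chemical_table <- function(path) {
  load_chemical_table(readr::read_csv(path, show_col_types = FALSE))
}
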