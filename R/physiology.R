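#' Default organism models
#'
#' Reference physiologies for the five organism models: rat plus four human
#' standards (adult man, adult woman, male child, male toddler). Values are
#' standard reference anatomy/physiology: cardiac output follows the
#' allometric relation 15 BW^0.74 L/h, organ volumes are fractions of body
#' weight (density 1), and blood-flow fractions over the perfused
#' compartments sum to 1. Thyroid and gonadal (testes or breast) compartments
#' exist only in the human models; the `gonad` compartment is testes for male
#' physiologies and breast tissue for the woman model.
#'
#' @return Tibble, one row per organism model, with body weight `bw` (kg),
#'   `height` (cm), cardiac output `qc` (L/h), volume fractions `v_*`
#'   (fraction of bw), blood-flow fractions `q_*` (fraction of `qc`), gastric
#'   emptying half-time `gest` (h), glomerular filtration rate `gfr` (L/h),
#'   `bile_flow` (L/day), `intestinal_radius` (cm), UGT2B15 abundance
#'   `ugt_abundance` (pmol/mg) and flags `species`, `sex`, `female`.
#' @export
default_physiologies <- function() {
  phys <- tibble::tribble(
    ~label, ~species, ~sex, ~female, ~bw, ~height,
    "rat", "rat", "male", FALSE, 0.25, 22,
    "man", "human", "male", FALSE, 73, 176,
    "woman", "human", "female", TRUE, 60, 163,
    "child", "human", "male", FALSE, 32, 138,
    "toddler", "human", "male", FALSE, 12, 91
  )
  vols <- tibble::tribble(
    ~label, ~v_liver, ~v_kidney, ~v_gut, ~v_thyroid, ~v_gonad, ~v_blood, ~v_slowly, ~v_rapidly,
    "rat", 0.034, 0.0073, 0.027, 0, 0, 0.074, 0.48, 0.05,
    "man", 0.026, 0.0044, 0.017, 0.00027, 0.00049, 0.079, 0.52, 0.04,
    "woman", 0.026, 0.0044, 0.017, 0.00028, 0.0062, 0.077, 0.54, 0.04,
    "child", 0.029, 0.0050, 0.018, 0.00025, 0.00015, 0.080, 0.50, 0.05,
    "toddler", 0.033, 0.0055, 0.020, 0.00030, 0.00010, 0.080, 0.48, 0.06
  )
  flows <- tibble::tribble(
    ~label, ~q_liver, ~q_gut, ~q_kidney, ~q_thyroid, ~q_gonad, ~q_slowly, ~q_rapidly,
    "rat", 0.183, 0.150, 0.140, 0, 0, 0.227, 0.300,
    "man", 0.065, 0.160, 0.190, 0.015, 0.0005, 0.2795, 0.290,
    "woman", 0.065, 0.160, 0.190, 0.015, 0.0050, 0.2750, 0.290,
    "child", 0.065, 0.160, 0.190, 0.015, 0.0005, 0.2795, 0.290,
    "toddler", 0.065, 0.160, 0.190, 0.015, 0.0005, 0.2795, 0.290
  )
  misc <- tibble::tribble(
    ~label, ~gest, ~gfr, ~bile_flow, ~intestinal_radius, ~ugt_abundance,
    "rat", 0.25, 0.079, 0.0225, 0.18, 61.6,
    "man", 0.40, 7.5, 0.700, 1.75, 61.6,
    "woman", 0.40, 6.6, 0.700, 1.75, 61.6,
    "child", 0.35, 4.5, 0.350, 1.25, 25.0,
    "toddler", 0.30, 2.0, 0.180, 1.00, 25.0
  )
  out <- phys |>
    dplyr::left_join(vols, by = "label") |>
    dplyr::left_join(flows, by = "label") |>
    dplyr::left_join(misc, by = "label") |>
    dplyr::mutate(qc = 15 * .data$bw^0.74, .after = "height")
  validate_physiologies(out)
  out
}

physiology_flow_cols <- function() {
  c("q_liver", "q_gut", "q_kidney", "q_thyroid", "q_gonad", "q_slowly", "q_rapidly")
}

physiology_volume_cols <- function() {
  c("v_liver", "v_kidney", "v_gut", "v_thyroid", "v_gonad", "v_blood",
    "v_slowly", "v_rapidly")
}

#' Validate a physiology table
#'
#' Checks positivity of flows and volumes, that blood-flow fractions sum to
#' 1, that volume fractions sum to at most 1, and that thyroid/gonadal
#' compartments are present only for human models.
#'
#' @param phys Physiology tibble shaped like [default_physiologies()].
#' @return `phys`, invisibly; aborts on violation.
#' @export
validate_physiologies <- function(phys) {
  for (i in seq_len(nrow(phys))) {
    row <- phys[i, ]
    qs <- unlist(row[physiology_flow_cols()])
    vs <- unlist(row[physiology_volume_cols()])
    if (abs(sum(qs) - 1) > 1e-6) {
      rlang::abort(sprintf("Flow fractions of '%s' sum to %.6f, not 1.",
                           row$label, sum(qs)), class = "bispbk_input_error")
    }
    if (sum(vs) > 1) {
      rlang::abort(sprintf("Volume fractions of '%s' exceed 1.", row$label),
                   class = "bispbk_input_error")
    }
    pos <- c(row$bw, row$qc, row$gest, row$gfr, row$bile_flow,
             row$intestinal_radius)
    if (any(!is.finite(pos)) || any(pos <= 0)) {
      rlang::abort(sprintf("Non-positive physiological constant in '%s'.", row$label),
                   class = "bispbk_input_error")
    }
    if (row$species == "rat" && (row$v_thyroid > 0 || row$v_gonad > 0 ||
                                 row$q_thyroid > 0 || row$q_gonad > 0)) {
      rlang::abort("Thyroid/gonadal compartments are only present in human models.",
                   class = "bispbk_input_error")
    }
  }
  invisible(phys)
}

#' Fetch one organism model by label
#'
#' @param label One of `rat`, `man`, `woman`, `child`, `toddler`.
#' @param phys Physiology table (defaults to [default_physiologies()]).
#' @return A one-row tibble.
#' @export
get_physiology <- function(label, phys = default_physiologies()) {
  row <- phys[phys$label == label, ]
  if (nrow(row) != 1) {
    rlang::abort(paste0("Unknown physiology label: ", label),
                 class = "bispbk_input_error")
  }
  row
}
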