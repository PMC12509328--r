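#' Volume-weighted combination of partition coefficients
#'
#' Lumped compartments (slowly / rapidly perfused tissue) take the weighted
#' sum of the constituent organs' tissue:blood partition coefficients.
#'
#' @param organ_kps Named numeric vector of per-organ Kp values.
#' @param weights Named numeric vector of volume fractions over the same
#'   organs; must sum to 1.
#' @return Combined Kp (unitless).
#' @export
combine_kp <- function(organ_kps, weights) {
  if (!setequal(names(organ_kps), names(weights))) {
    rlang::abort("`organ_kps` and `weights` must share the same organ names.",
                 class = "bispbk_input_error")
  }
  weights <- weights[names(organ_kps)]
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    rlang::abort("Weights must be non-negative and sum to 1.",
                 class = "bispbk_input_error")
  }
  sum(weights * organ_kps)
}

#' Breast partition coefficient from the adipose value
#'
#' The breast compartment is parametrized as adipose tissue scaled by the
#' breast fat volume fraction (24.5%).
#'
#' @param kp_adipose Adipose tissue:blood partition coefficient.
#' @param fat_fraction Fat volume fraction of breast tissue.
#' @return Breast Kp.
#' @export
breast_kp <- function(kp_adipose, fat_fraction = 0.245) {
  if (any(kp_adipose <= 0)) {
    rlang::abort("`kp_adipose` must be positive.", class = "bispbk_input_error")
  }
  fat_fraction * kp_adipose
}

pbk_kp_compartments <- function() {
  c("gut", "liver", "kidney", "thyroid", "gonad", "slowly", "rapidly")
}

#' Assemble a complete partition set for one chemical and physiology
#'
#' Validates per-organ tissue:blood partition coefficients (parent and
#' glucuronide) plus unbound fractions against the model's compartment list.
#' The breast value (female `gonad` compartment) is derived from the adipose
#' entry via [breast_kp()] when absent.
#'
#' @param kp_table Data frame with columns `organ`, `kp_parent`,
#'   `kp_glucuronide` containing the model compartments (`gut`, `liver`,
#'   `kidney`, `thyroid`, `gonad`, `slowly`, `rapidly`) and optionally
#'   `adipose` for the breast derivation.
#' @param fu_parent,fu_glucuronide Plasma unbound fractions in (0, 1].
#' @param female Is the gonadal compartment breast tissue (derivable from
#'   adipose)?
#' @return List with `kp_parent`, `kp_glucuronide` (named vectors over
#'   compartments) and `fu_parent`, `fu_glucuronide`.
#' @export
build_partition_set <- function(kp_table, fu_parent, fu_glucuronide,
                                female = FALSE) {
  for (fu in c(fu_parent, fu_glucuronide)) {
    if (!is.finite(fu) || fu <= 0 || fu > 1) {
      rlang::abort("Unbound fractions must lie in (0, 1].",
                   class = "bispbk_input_error")
    }
  }
  get_kp <- function(col) {
    kp <- stats::setNames(kp_table[[col]], kp_table$organ)
    needed <- pbk_kp_compartments()
    if (female && !"gonad" %in% names(kp) && "adipose" %in% names(kp)) {
      kp <- c(kp, gonad = breast_kp(kp[["adipose"]]))
    }
    missing <- setdiff(needed, names(kp))
    if (length(missing) > 0) {
      rlang::abort(paste0("Missing partition coefficient(s) for: ",
                          paste(missing, collapse = ", ")),
                   class = "bispbk_input_error")
    }
    kp <- kp[needed]
    if (any(!is.finite(kp)) || any(kp <= 0)) {
      rlang::abort("All partition coefficients must be positive.",
                   class = "bispbk_input_error")
    }
    kp
  }
  list(
    kp_parent = get_kp("kp_parent"),
    kp_glucuronide = get_kp("kp_glucuronide"),
    fu_parent = fu_parent,
    fu_glucuronide = fu_glucuronide
  )
}

#' Default tissue:blood partition coefficients (synthetic)
#'
#' Per-organ Kp values for each chemical, generated from a lipophilicity
#' scaling around BPA base values: organs keep fixed relative affinities and
#' chemicals are scaled by `10^(0.25 (logP - logP_BPA))`. Glucuronides are
#' polar and get uniformly low values. These defaults are synthetic stand-ins
#' of realistic magnitude; quantitative work should supply Kp tables derived
#' from tissue-composition methods.
#'
#' @param chemicals Chemical registry, see [default_chemicals()].
#' @return Tibble with columns `name`, `organ`, `kp_parent`, `kp_glucuronide`.
#' @export
default_kp_table <- function(chemicals = default_chemicals()) {
  base <- c(gut = 1.5, liver = 1.5, kidney = 1.2, thyroid = 1.2,
            gonad = 0.9, slowly = 1.8, rapidly = 1.0, adipose = 4.0)
  gluc <- c(gut = 0.25, liver = 0.30, kidney = 0.30, thyroid = 0.25,
            gonad = 0.20, slowly = 0.20, rapidly = 0.25, adipose = 0.10)
  purrr::map_dfr(seq_len(nrow(chemicals)), function(i) {
    mult <- 10^(0.25 * (chemicals$logp[i] - 3.3))
    tibble::tibble(
      name = chemicals$name[i],
      organ = names(base),
      kp_parent = unname(base * mult),
      kp_glucuronide = unname(gluc)
    )
  })
}
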