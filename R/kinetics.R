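#' Nalimov outlier test critical values
#'
#' Small-sample critical values of the Nalimov studentised-deviation
#' statistic, tabulated at the 95% and 99% levels; intermediate sample sizes
#' are linearly interpolated. The table is configuration: an alternative
#' transcription can be passed to [nalimov_filter()].
#'
#' @return Tibble with columns `n`, `q95`, `q99`.
#' @export
nalimov_critical_table <- function() {
  tibble::tibble(
    n   = c(3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 20, 25, 30, 40, 50, 100, 200),
    q95 = c(1.409, 1.645, 1.757, 1.814, 1.848, 1.870, 1.885, 1.895, 1.904,
            1.910, 1.915, 1.919, 1.923, 1.933, 1.938, 1.942, 1.945, 1.947,
            1.953, 1.955),
    q99 = c(1.414, 1.715, 1.918, 2.051, 2.142, 2.208, 2.256, 2.294, 2.324,
            2.348, 2.368, 2.384, 2.397, 2.445, 2.472, 2.494, 2.517, 2.532,
            2.560, 2.570)
  )
}

nalimov_critical <- function(n, alpha = 0.05, table = nalimov_critical_table()) {
  col <- if (alpha <= 0.01) "q99" else "q95"
  stats::approx(table$n, table[[col]], xout = pmin(n, max(table$n)), rule = 2)$y
}

#' Nalimov outlier screening
#'
#' Iteratively removes the most extreme value while its Nalimov statistic
#' q = |x - mean| * sqrt(n/(n-1)) / sd exceeds the critical value at the
#' chosen significance level. Used on replicate measurements before kinetic
#' fitting.
#'
#' @param values Numeric vector of replicate measurements (n >= 3).
#' @param alpha Significance level (0.05 or 0.01).
#' @param critical_table Critical-value table, see [nalimov_critical_table()].
#' @return List with `retained` (values kept), `excluded` (integer indices
#'   into the original vector, in exclusion order).
#' @export
nalimov_filter <- function(values, alpha = 0.05,
                           critical_table = nalimov_critical_table()) {
  if (length(values) < 3) {
    rlang::abort("Nalimov test requires at least 3 values.", class = "bispbk_input_error")
  }
  idx <- seq_along(values)
  excluded <- integer(0)
  repeat {
    n <- length(idx)
    if (n < 3) break
    x <- values[idx]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) break
    q <- abs(x - mean(x)) / s * sqrt(n / (n - 1))
    imax <- which.max(q)
    if (q[imax] > nalimov_critical(n, alpha, critical_table)) {
      excluded <- c(excluded, idx[imax])
      idx <- idx[-imax]
    } else {
      break
    }
  }
  list(retained = values[idx], excluded = excluded)
}

#' Convert a substrate-depletion time course to rate-substrate pairs
#'
#' Each consecutive interval contributes one observation: the depletion rate
#' -dC/dt normalised by protein concentration, paired with the interval-mean
#' substrate concentration.
#'
#' @param series Data frame with columns `time_h`, `conc_uM`,
#'   `protein_mg_per_ml` (constant within a series) and optionally `replicate`.
#' @return Tibble with columns `s` (uM) and `v` (nmol/min/mg protein), plus
#'   `replicate` and `interval` identifiers.
#' @export
depletion_to_rates <- function(series) {
  required <- c("time_h", "conc_uM", "protein_mg_per_ml")
  missing <- setdiff(required, names(series))
  if (length(missing) > 0) {
    rlang::abort(paste0("Missing column(s): ", paste(missing, collapse = ", ")),
                 class = "bispbk_input_error")
  }
  if (!"replicate" %in% names(series)) series$replicate <- 1L
  series |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$time_h)
      if (nrow(df) < 2) {
        rlang::abort("Each series needs at least 2 time points.",
                     class = "bispbk_input_error")
      }
      dt <- diff(df$time_h)
      if (any(dt <= 0)) {
        rlang::abort("Time vector must be strictly increasing.",
                     class = "bispbk_input_error")
      }
      dc <- diff(df$conc_uM)
      # uM/h per (mg/mL) == nmol/h/mg; divide by 60 for nmol/min/mg
      v <- (-dc / dt) / df$protein_mg_per_ml[1] / 60
      tibble::tibble(
        interval = seq_along(v),
        s = (utils::head(df$conc_uM, -1) + utils::tail(df$conc_uM, -1)) / 2,
        v = v
      )
    }) |>
    dplyr::ungroup()
}

mm_rate <- function(s, vmax, km) vmax * s / (km + s)
si_rate <- function(s, vmax, km, ki) vmax * s / (km + s * (1 + s / ki))

new_kinetic_fit <- function(model, coefs, data, r2, converged = TRUE,
                            system = NA_character_) {
  structure(
    list(model = model, vmax = coefs[["vmax"]], km = coefs[["km"]],
         ki = if ("ki" %in% names(coefs)) coefs[["ki"]] else NA_real_,
         r2 = r2, data = data, converged = converged, system = system),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit>", x$model,
      sprintf("Vmax=%.4g nmol/min/mg, Km=%.4g uM", x$vmax, x$km),
      if (!is.na(x$ki)) sprintf("Ki=%.4g uM", x$ki) else "",
      sprintf("R2=%.4f", x$r2), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  terms <- c("vmax", "km", if (!is.na(x$ki)) "ki")
  tibble::tibble(
    term = terms,
    estimate = c(x$vmax, x$km, if (!is.na(x$ki)) x$ki),
    unit = c("nmol/min/mg", "uM", if (!is.na(x$ki)) "uM")
  )
}

#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(model = x$model, r.squared = x$r2, converged = x$converged,
                 n = nrow(x$data), system = x$system)
}

r_squared <- function(obs, fit) {
  sst <- sum((obs - mean(obs))^2)
  sse <- sum((obs - fit)^2)
  if (sst == 0) return(if (sse == 0) 1 else 0)
  1 - sse / sst
}

fit_rate_law <- function(pairs, model, system) {
  s <- pairs$s
  v <- pairs$v
  vmax0 <- max(v)
  km0 <- stats::median(s)
  # substrate inhibition is fitted on kinv = 1/Ki so the Michaelis-Menten
  # limit (Ki -> Inf) sits on the boundary kinv = 0 instead of at infinity
  starts <- if (model == "MM") {
    lapply(c(0.3, 1, 3), function(f) list(vmax = vmax0, km = km0 * f))
  } else {
    unlist(lapply(c(0.3, 1, 3), function(f) {
      lapply(c(1, 10) / max(s), function(kinv0) {
        list(vmax = vmax0, km = km0 * f, kinv = kinv0)
      })
    }), recursive = FALSE)
  }
  formula <- if (model == "MM") {
    v ~ vmax * s / (km + s)
  } else {
    v ~ vmax * s / (km + s * (1 + s * kinv))
  }
  lower <- if (model == "MM") rep(1e-12, 2) else c(1e-12, 1e-12, 0)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data.frame(s = s, v = v),
                        start = st, lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    return(new_kinetic_fit(model, c(vmax = NA_real_, km = NA_real_),
                           pairs, NA_real_, converged = FALSE, system = system))
  }
  co <- stats::coef(best$fit)
  if ("kinv" %in% names(co)) {
    co <- c(co[c("vmax", "km")], ki = unname(1 / max(co[["kinv"]], 1e-300)))
  }
  new_kinetic_fit(model, co, pairs, r_squared(v, stats::fitted(best$fit)),
                  system = system)
}

#' Fit Michaelis-Menten kinetics to rate-substrate pairs
#'
#' Least-squares fit of v = Vmax S / (Km + S) with positive-bounded
#' Levenberg-Marquardt optimisation and three Km starting values to reduce
#' local-minimum risk.
#'
#' @param pairs Data frame with columns `s` (uM) and `v` (nmol/min/mg).
#' @param system Optional in vitro system tag (`human_S9`, `rat_S9`,
#'   `human_microsome`) carried along for liver scaling.
#' @return A `kinetic_fit` object; see [tidy.kinetic_fit()].
#' @export
fit_michaelis_menten <- function(pairs, system = NA_character_) {
  if (length(unique(pairs$s)) < 3) {
    rlang::abort("Michaelis-Menten fit needs >= 3 distinct substrate levels.",
                 class = "bispbk_input_error")
  }
  fit_rate_law(pairs, "MM", system)
}

#' Fit substrate-inhibition kinetics
#'
#' Least-squares fit of v = Vmax S / (Km + S (1 + S/Ki)).
#'
#' @inheritParams fit_michaelis_menten
#' @return A `kinetic_fit` object.
#' @export
fit_substrate_inhibition <- function(pairs, system = NA_character_) {
  if (length(unique(pairs$s)) < 4) {
    rlang::abort("Substrate-inhibition fit needs >= 4 distinct substrate levels.",
                 class = "bispbk_input_error")
  }
  fit_rate_law(pairs, "SI", system)
}

#' Select the best kinetic fit by R-squared
#'
#' Ties (within `tol`) are broken toward the simpler Michaelis-Menten model.
#'
#' @param fits List of `kinetic_fit` objects.
#' @param tol R-squared difference below which fits count as tied.
#' @return The selected `kinetic_fit`.
#' @export
select_best_fit <- function(fits, tol = 1e-9) {
  fits <- Filter(function(f) isTRUE(f$converged) && is.finite(f$r2), fits)
  if (length(fits) == 0) {
    rlang::abort("All kinetic fits failed.", class = "bispbk_fit_error")
  }
  r2 <- vapply(fits, function(f) f$r2, numeric(1))
  best <- max(r2)
  candidates <- which(r2 >= best - tol)
  models <- vapply(fits[candidates], function(f) f$model, character(1))
  pick <- if ("MM" %in% models) candidates[match("MM", models)] else candidates[which.max(r2[candidates])]
  fits[[pick]]
}

#' Protein yields per gram of liver for the supported in vitro systems
#'
#' @return Named vector, mg protein per g liver.
#' @export
protein_yields <- function() {
  c(human_S9 = 107.3, rat_S9 = 143, human_microsome = 32)
}

#' Scale an in vitro Vmax to the whole liver
#'
#' Multiplies the specific Vmax (nmol/min/mg protein) by the system-matched
#' protein yield (mg/g liver) and liver mass (g).
#'
#' @param fit A `kinetic_fit` with a `system` tag, or any list with `vmax` and
#'   `system` entries.
#' @param liver_mass Liver mass, g.
#' @param system In vitro system; must match the fit's tag when both are set.
#' @param protein_yield Override yield, mg protein per g liver.
#' @return Whole-liver Vmax, nmol/min.
#' @export
scale_to_liver <- function(fit, liver_mass, system = fit$system,
                           protein_yield = NULL) {
  if (is.null(protein_yield)) {
    if (is.na(system) || !system %in% names(protein_yields())) {
      rlang::abort("Unknown in vitro system; supply `protein_yield` explicitly.",
                   class = "bispbk_input_error")
    }
    protein_yield <- protein_yields()[[system]]
  }
  if (!is.na(fit$system) && !is.na(system) && !identical(system, fit$system)) {
    rlang::abort(
      sprintf("Fit was measured in %s but scaling requested for %s.",
              fit$system, system),
      class = "bispbk_input_error"
    )
  }
  if (protein_yield <= 0 || liver_mass <= 0) {
    rlang::abort("Protein yield and liver mass must be positive.",
                 class = "bispbk_input_error")
  }
  fit$vmax * protein_yield * liver_mass
}

#' Ontogeny scaling factor for glucuronidation
#'
#' Ratio of UGT2B15 protein abundance in the age class of interest to the
#' adult abundance; applied multiplicatively to whole-liver Vmax. Child and
#' toddler models share the early-childhood abundance.
#'
#' @param abundance_age Abundance in the age class, pmol/mg microsomal protein.
#' @param abundance_adult Adult abundance, same units.
#' @return Dimensionless scaling factor SFg.
#' @export
ontogeny_sfg <- function(abundance_age, abundance_adult) {
  if (any(abundance_age <= 0) || any(abundance_adult <= 0)) {
    rlang::abort("Abundances must be positive.", class = "bispbk_input_error")
  }
  abundance_age / abundance_adult
}

#' Fit glucuronidation kinetics from a long-format depletion table
#'
#' Full chain for one or more chemicals: per-replicate finite-difference
#' rates, Nalimov screening of replicate rates within each sampling interval,
#' Michaelis-Menten and substrate-inhibition fits, and best-fit selection.
#'
#' @param depletion Long table with columns `chemical`, `replicate`, `time_h`,
#'   `conc_uM`, `protein_mg_per_ml`, `system`.
#' @param nalimov_alpha Significance level for outlier screening; `NULL`
#'   disables screening.
#' @return Named list of selected `kinetic_fit` objects, one per chemical.
#' @export
fit_glucuronidation <- function(depletion, nalimov_alpha = 0.05) {
  split(depletion, depletion$chemical) |>
    lapply(function(df) {
      system <- df$system[1]
      rates <- depletion_to_rates(df)
      if (!is.null(nalimov_alpha)) {
        rates <- rates |>
          dplyr::group_by(.data$interval) |>
          dplyr::group_modify(function(g, key) {
            if (nrow(g) >= 3) {
              keep <- setdiff(seq_len(nrow(g)), nalimov_filter(g$v, nalimov_alpha)$excluded)
              g[keep, ]
            } else g
          }) |>
          dplyr::ungroup()
      }
      fits <- list(fit_michaelis_menten(rates, system))
      if (length(unique(rates$s)) >= 4) {
        fits <- c(fits, list(fit_substrate_inhibition(rates, system)))
      }
      select_best_fit(fits)
    })
}

#' Default glucuronidation kinetic parameters (synthetic)
#'
#' Specific glucuronidation parameters per chemical and species used by the
#' default workflow. Magnitudes are physiologically plausible (fast hepatic
#' glucuronidation for most bisphenols, slow for BPS) but synthetic: real
#' analyses should fit their own depletion data via [fit_glucuronidation()].
#'
#' @return Tibble with columns `name`, `species`, `system`, `vmax`
#'   (nmol/min/mg), `km` (uM), `ki` (uM, `NA` for plain Michaelis-Menten).
#' @export
default_kinetics <- function() {
  human <- tibble::tribble(
    ~name, ~system, ~vmax, ~km,
    "BPA", "human_S9", 10, 10,
    "BPB", "human_S9", 14, 9,
    "BPE", "human_S9", 6, 12,
    "BPM", "human_S9", 12, 10,
    "BPAF", "human_microsome", 5, 12,
    "BPF", "human_microsome", 6, 12,
    "BPS", "human_microsome", 1.5, 18
  ) |> dplyr::mutate(species = "human")
  rat <- tibble::tribble(
    ~name, ~vmax, ~km,
    "BPA", 15, 10,
    "BPAF", 7, 12,
    "BPB", 18, 9,
    "BPE", 8, 12,
    "BPF", 8, 12,
    "BPM", 13, 10,
    "BPS", 2, 18
  ) |> dplyr::mutate(system = "rat_S9", species = "rat")
  dplyr::bind_rows(human, rat) |>
    dplyr::mutate(ki = NA_real_) |>
    dplyr::select("name", "species", "system", "vmax", "km", "ki")
}

#' Default UGT2B15 abundances by age class (synthetic)
#'
#' Adult and early-childhood hepatic UGT2B15 protein abundances used to form
#' the ontogeny scaling factor; child and toddler share the early-childhood
#' value. Representative magnitudes, not a transcription of any measured
#' data set.
#'
#' @return Named vector, pmol/mg microsomal protein.
#' @export
default_ugt_abundance <- function() {
  c(adult = 61.6, early_childhood = 25.0)
}
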