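#' Perturbable model parameters
#'
#' Names accepted by [set_pbk_param()] / [get_pbk_param()]: scalar bundle
#' entries (`ehcr`, `kcol`, `ka`, `vmax`, `km`, `sfg`, `fu_parent`,
#' `fu_glucuronide`), physiology constants (`bw`, `qc`, `gest`, `gfr`,
#' `bile_flow`) and the physiology's volume (`v_*`) and flow (`q_*`)
#' fraction columns.
#'
#' @param params A `pbk_params` bundle.
#' @return Character vector of perturbable parameter names.
#' @export
pbk_param_names <- function(params) {
  c("ehcr", "kcol", "ka", "vmax", "km", "sfg", "fu_parent", "fu_glucuronide",
    "bw", "qc", "gest", "gfr", "bile_flow",
    physiology_volume_cols(), physiology_flow_cols())
}

#' Get / set one parameter of a PBK bundle
#'
#' @param params A `pbk_params` bundle.
#' @param name Parameter name, see [pbk_param_names()].
#' @param value Replacement value.
#' @return `get_pbk_param()` the current value; `set_pbk_param()` the
#'   modified bundle.
#' @export
get_pbk_param <- function(params, name) {
  phys_cols <- c("bw", "qc", "gest", "gfr", "bile_flow",
                 physiology_volume_cols(), physiology_flow_cols())
  if (name %in% phys_cols) return(params$physiology[[name]])
  switch(name,
    ehcr = params$ehcr,
    kcol = params$kcol,
    ka = params$absorption$ka,
    vmax = params$kinetics$vmax,
    km = params$kinetics$km,
    sfg = params$kinetics$sfg,
    fu_parent = params$partition$fu_parent,
    fu_glucuronide = params$partition$fu_glucuronide,
    rlang::abort(paste0("Unknown parameter: ", name),
                 class = "bispbk_input_error")
  )
}

#' @rdname get_pbk_param
#' @export
set_pbk_param <- function(params, name, value) {
  phys_cols <- c("bw", "qc", "gest", "gfr", "bile_flow",
                 physiology_volume_cols(), physiology_flow_cols())
  if (name %in% phys_cols) {
    params$physiology[[name]] <- value
  } else if (name == "ehcr") {
    params$ehcr <- value
  } else if (name == "kcol") {
    params$kcol <- value
  } else if (name == "ka") {
    params$absorption$ka <- value
  } else if (name == "vmax") {
    params$kinetics$vmax <- value
  } else if (name == "km") {
    params$kinetics$km <- value
  } else if (name == "sfg") {
    params$kinetics$sfg <- value
  } else if (name == "fu_parent") {
    params$partition$fu_parent <- value
  } else if (name == "fu_glucuronide") {
    params$partition$fu_glucuronide <- value
  } else {
    rlang::abort(paste0("Unknown parameter: ", name),
                 class = "bispbk_input_error")
  }
  params
}

#' Toxicokinetic output functional
#'
#' Builds the scalar output function used by the sensitivity and uncertainty
#' analyses: peak concentration or AUC of one compartment/analyte, the AUC
#' optionally restricted to a window (e.g. 0-4 h to probe the distribution
#' and elimination phase).
#'
#' @param metric `"cmax"` or `"auc"`.
#' @param compartment,analyte Output trace to summarise.
#' @param window Upper AUC limit, h (`NULL` = full window).
#' @return Function mapping a `pbk_sim` to a scalar.
#' @export
tk_output <- function(metric = c("cmax", "auc"), compartment = "blood",
                      analyte = "parent", window = NULL) {
  metric <- match.arg(metric)
  function(sim) {
    prof <- conc_profile(sim, compartment, analyte)
    if (metric == "cmax") return(max(prof$conc_nM))
    keep <- if (is.null(window)) rep(TRUE, nrow(prof)) else prof$time_h <= window + 1e-9
    trapz(prof$time_h[keep], prof$conc_nM[keep])
  }
}

#' Local (one-at-a-time) sensitivity coefficient
#'
#' Normalised forward-difference coefficient
#' (delta output / output) / (delta parameter / parameter) with a 1%
#' perturbation; parameters with |coefficient| > 0.1 are conventionally
#' flagged sensitive. `"dose"` perturbs the administered dose.
#'
#' @param params A `pbk_params` bundle.
#' @param schedule Dose schedule.
#' @param parameter Parameter name (see [pbk_param_names()]) or `"dose"`.
#' @param output Output functional, see [tk_output()].
#' @param rel_step Relative perturbation size.
#' @param method `"forward"` or `"central"` difference.
#' @param solver Solver configuration.
#' @return Tibble with `parameter`, `coefficient`, `sensitive`.
#' @export
local_sensitivity <- function(params, schedule, parameter,
                              output = tk_output("cmax"), rel_step = 0.01,
                              method = c("forward", "central"),
                              solver = solver_config(rtol = 1e-8, dt_out = 0.02)) {
  method <- match.arg(method)
  run <- function(p, sched) output(simulate_pbk(p, sched, solver))
  perturbed <- function(delta) {
    if (parameter == "dose") {
      sched <- schedule
      sched$dose_ng_per_kg <- schedule$dose_ng_per_kg * (1 + delta)
      run(params, sched)
    } else {
      p0 <- get_pbk_param(params, parameter)
      run(set_pbk_param(params, parameter, p0 * (1 + delta)), schedule)
    }
  }
  y0 <- run(params, schedule)
  if (!is.finite(y0) || y0 == 0) {
    rlang::abort("Baseline output is zero; coefficient undefined.",
                 class = "bispbk_input_error")
  }
  coef <- if (method == "forward") {
    (perturbed(rel_step) - y0) / y0 / rel_step
  } else {
    (perturbed(rel_step) - perturbed(-rel_step)) / y0 / (2 * rel_step)
  }
  tibble::tibble(parameter = parameter, coefficient = coef,
                 sensitive = abs(coef) > 0.1)
}

#' Morris elementary-effects screening (generic)
#'
#' Classic trajectory design on a `levels`-level grid with step
#' `delta = levels / (2 (levels - 1))`, `r` trajectories. Parameters with a
#' degenerate (zero-width) range are skipped with a warning.
#'
#' @param fn Function taking a named numeric vector and returning a scalar.
#' @param lower,upper Named vectors of parameter bounds.
#' @param r Number of trajectories.
#' @param levels Number of grid levels.
#' @param seed RNG seed.
#' @return Tibble with `parameter`, `mu_star`, `sigma`, ranked by `mu_star`.
#' @export
morris_screen <- function(fn, lower, upper, r = 10, levels = 4, seed = 1) {
  stopifnot(identical(names(lower), names(upper)))
  degenerate <- upper == lower
  if (any(degenerate)) {
    rlang::warn(paste0("Skipping zero-width parameter(s): ",
                       paste(names(lower)[degenerate], collapse = ", ")))
  }
  active <- names(lower)[!degenerate]
  k <- length(active)
  delta <- levels / (2 * (levels - 1))
  grid <- seq(0, 1 - delta, length.out = levels / 2)
  set.seed(seed)
  ee <- matrix(NA_real_, nrow = r, ncol = k, dimnames = list(NULL, active))
  to_native <- function(u) {
    x <- lower
    x[active] <- lower[active] + u * (upper[active] - lower[active])
    x
  }
  for (tr in seq_len(r)) {
    base <- sample(grid, k, replace = TRUE)
    names(base) <- active
    direction <- sample(c(-1, 1), k, replace = TRUE)
    # flip directions that would leave the unit interval
    direction <- ifelse(base + direction * delta < 0 |
                          base + direction * delta > 1, -direction, direction)
    order_idx <- sample(k)
    x <- base
    y_prev <- fn(to_native(x))
    for (j in order_idx) {
      x_new <- x
      x_new[j] <- x[j] + direction[j] * delta
      y_new <- fn(to_native(x_new))
      ee[tr, j] <- (y_new - y_prev) / (direction[j] * delta)
      x <- x_new
      y_prev <- y_new
    }
  }
  tibble::tibble(
    parameter = active,
    mu_star = unname(colMeans(abs(ee))),
    sigma = unname(apply(ee, 2, stats::sd))
  ) |>
    dplyr::arrange(dplyr::desc(.data$mu_star))
}

#' Extended Fourier amplitude sensitivity test (generic)
#'
#' Classic FAST search-curve sampling with Saltelli's harmonic rule: each
#' parameter in turn is assigned the high frequency, the complementary set
#' low frequencies; first-order indices take the spectral power at the high
#' frequency and its first `M` harmonics, total-order indices the complement
#' of the low-frequency band.
#'
#' @param fn Function of a named numeric vector returning a scalar.
#' @param lower,upper Named bound vectors (>= 2 parameters).
#' @param n Samples per search curve; must exceed `4 M^2 + 1`.
#' @param M Number of harmonics.
#' @param seed RNG seed for the random phase shifts.
#' @return Tibble with `parameter`, `first_order`, `total_order`,
#'   `interaction` (total minus first).
#' @export
efast_indices <- function(fn, lower, upper, n = 1000, M = 4, seed = 1) {
  stopifnot(identical(names(lower), names(upper)))
  k <- length(lower)
  if (k < 2) {
    rlang::abort("eFAST needs at least 2 parameters.", class = "bispbk_input_error")
  }
  if (n <= 4 * M^2 + 1) {
    rlang::abort(sprintf("n must exceed 4*M^2 + 1 = %d.", 4 * M^2 + 1),
                 class = "bispbk_input_error")
  }
  set.seed(seed)
  omega_max <- floor((n - 1) / (2 * M))
  omega_comp_max <- max(1, floor(omega_max / (2 * M)))
  s <- 2 * pi * (seq_len(n) - 1) / n
  spectrum_power <- function(y) {
    co <- stats::fft(y) / n
    # one-sided power at integer frequencies 1..(n-1)/2
    2 * Mod(co[2:(floor((n - 1) / 2) + 1)])^2
  }
  purrr::map_dfr(seq_len(k), function(i) {
    omega <- rep(0, k)
    omega[i] <- omega_max
    others <- setdiff(seq_len(k), i)
    omega[others] <- rep(seq_len(omega_comp_max), length.out = k - 1)
    phase <- stats::runif(k, 0, 2 * pi)
    y <- vapply(seq_len(n), function(j) {
      u <- 0.5 + asin(sin(omega * s[j] + phase)) / pi
      x <- lower + u * (upper - lower)
      names(x) <- names(lower)
      fn(x)
    }, numeric(1))
    pw <- spectrum_power(y - mean(y))
    v_total <- sum(pw)
    v_first <- sum(pw[seq_len(M) * omega_max])
    v_comp <- sum(pw[seq_len(floor(omega_max / 2))])
    tibble::tibble(
      parameter = names(lower)[i],
      first_order = v_first / v_total,
      total_order = 1 - v_comp / v_total
    )
  }) |>
    dplyr::mutate(interaction = .data$total_order - .data$first_order)
}

#' Parameter ranges from coefficients of variation
#'
#' Builds Morris/eFAST ranges covering approximately +/- `k_sd` standard
#' deviations around the bundle's current values.
#'
#' @param params A `pbk_params` bundle.
#' @param variability Tibble with `parameter` and `cv` columns, see
#'   [default_variability()].
#' @param k_sd Half-width in standard deviations.
#' @return List with named `lower` and `upper` vectors.
#' @export
param_ranges <- function(params, variability = default_variability(),
                         k_sd = 2) {
  vals <- vapply(variability$parameter, function(nm) get_pbk_param(params, nm),
                 numeric(1))
  half <- k_sd * variability$cv * vals
  list(lower = pmax(vals - half, 1e-12), upper = vals + half)
}

#' Morris screening of a PBK model
#'
#' @param params,schedule Model bundle and dose schedule.
#' @param variability Per-parameter coefficients of variation.
#' @param output Output functional, see [tk_output()].
#' @param r,levels,seed Morris design settings.
#' @param solver Solver configuration.
#' @return Tibble as [morris_screen()].
#' @export
pbk_morris <- function(params, schedule, variability = default_variability(),
                       output = tk_output("auc", window = 4), r = 10,
                       levels = 4, seed = 1,
                       solver = solver_config(rtol = 1e-6, atol = 1e-8, dt_out = 0.05)) {
  rng <- param_ranges(params, variability)
  fn <- function(x) {
    p <- params
    for (nm in names(x)) p <- set_pbk_param(p, nm, x[[nm]])
    output(simulate_pbk(p, schedule, solver))
  }
  morris_screen(fn, rng$lower, rng$upper, r = r, levels = levels, seed = seed)
}

#' eFAST variance decomposition of a PBK model
#'
#' Run on a subset of parameters (conventionally those ranked highest by
#' Morris screening), with the AUC between 0 and 4 h as the default output.
#'
#' @param params,schedule Model bundle and dose schedule.
#' @param parameters Character vector of parameter names (>= 2).
#' @param variability Per-parameter coefficients of variation.
#' @param output Output functional.
#' @param n,M,seed eFAST settings.
#' @param solver Solver configuration.
#' @return Tibble as [efast_indices()].
#' @export
pbk_efast <- function(params, schedule, parameters,
                      variability = default_variability(),
                      output = tk_output("auc", window = 4), n = 257, M = 4,
                      seed = 1,
                      solver = solver_config(rtol = 1e-6, atol = 1e-8, dt_out = 0.05)) {
  variability <- variability[variability$parameter %in% parameters, ]
  rng <- param_ranges(params, variability)
  fn <- function(x) {
    p <- params
    for (nm in names(x)) p <- set_pbk_param(p, nm, x[[nm]])
    output(simulate_pbk(p, schedule, solver))
  }
  efast_indices(fn, rng$lower, rng$upper, n = n, M = M, seed = seed)
}

#' Default parameter variability table (placeholder)
#'
#' Coefficients of variation and distribution families for the sensitive
#' parameters resampled in the uncertainty analysis. The values are
#' placeholders of typical physiological magnitude for testing the
#' machinery; a study-specific variability table should be supplied for
#' quantitative uncertainty statements.
#'
#' @return Tibble with `parameter`, `cv`, `family` (`lognormal` or
#'   `truncnorm`).
#' @export
default_variability <- function() {
  tibble::tribble(
    ~parameter, ~cv, ~family,
    "bw", 0.15, "truncnorm",
    "qc", 0.15, "truncnorm",
    "gest", 0.30, "lognormal",
    "gfr", 0.20, "lognormal",
    "ka", 0.30, "lognormal",
    "vmax", 0.35, "lognormal",
    "km", 0.35, "lognormal",
    "sfg", 0.30, "lognormal",
    "ehcr", 0.15, "truncnorm",
    "v_liver", 0.25, "truncnorm",
    "q_liver", 0.25, "truncnorm",
    "q_slowly", 0.25, "truncnorm"
  )
}

draw_parameter <- function(value, cv, family) {
  if (cv == 0) return(value)
  if (family == "lognormal") {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(1, meanlog = log(value) - sdlog^2 / 2, sdlog = sdlog)
  } else if (family == "truncnorm") {
    # inverse-CDF draw truncated at zero
    p_lo <- stats::pnorm(0, mean = value, sd = cv * value)
    stats::qnorm(stats::runif(1, p_lo, 1), mean = value, sd = cv * value)
  } else {
    rlang::abort(paste0("Unknown distribution family: ", family),
                 class = "bispbk_input_error")
  }
}

#' Constrained Monte Carlo uncertainty propagation
#'
#' Resamples each listed parameter from its distribution, projects the draw
#' onto the physiological constraints (`ehcr` clipped to `[0, 1]`; the organ
#' volume-fraction and blood-flow-fraction vectors renormalised
#' multiplicatively to their baseline sums), simulates, and summarises the
#' selected concentration trace by first quartile, median and third quartile
#' per time point.
#'
#' @param params,schedule Model bundle and dose schedule.
#' @param distributions Tibble with `parameter`, `cv`, `family`.
#' @param n_draws Number of Monte Carlo draws.
#' @param seed RNG seed.
#' @param compartment,analyte Output trace.
#' @param solver Solver configuration (coarser defaults than a single
#'   deterministic run).
#' @return A `pbk_mc` object with `summary` (tibble: `time_h`, `q1`,
#'   `median`, `q3`), `metric_draws` (per-draw Cmax and AUC), `n_draws`,
#'   `seed`.
#' @export
monte_carlo_pbk <- function(params, schedule,
                            distributions = default_variability(),
                            n_draws = 1000, seed = 1,
                            compartment = "blood", analyte = "parent",
                            solver = solver_config(rtol = 1e-6, atol = 1e-8, dt_out = 0.05)) {
  bad <- setdiff(distributions$family, c("lognormal", "truncnorm"))
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown distribution family: ", paste(bad, collapse = ", ")),
                 class = "bispbk_input_error")
  }
  set.seed(seed)
  base_vsum <- sum(unlist(params$physiology[physiology_volume_cols()]))
  base_qsum <- sum(unlist(params$physiology[physiology_flow_cols()]))
  traces <- vector("list", n_draws)
  metric_rows <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    p <- params
    for (j in seq_len(nrow(distributions))) {
      nm <- distributions$parameter[j]
      val <- draw_parameter(get_pbk_param(params, nm), distributions$cv[j],
                            distributions$family[j])
      p <- set_pbk_param(p, nm, val)
    }
    p$ehcr <- min(1, max(0, p$ehcr))
    vsum <- sum(unlist(p$physiology[physiology_volume_cols()]))
    for (col in physiology_volume_cols()) {
      p$physiology[[col]] <- p$physiology[[col]] * base_vsum / vsum
    }
    qsum <- sum(unlist(p$physiology[physiology_flow_cols()]))
    for (col in physiology_flow_cols()) {
      p$physiology[[col]] <- p$physiology[[col]] * base_qsum / qsum
    }
    sim <- simulate_pbk(p, schedule, solver)
    prof <- conc_profile(sim, compartment, analyte)
    traces[[d]] <- prof$conc_nM
    metric_rows[[d]] <- tibble::tibble(
      draw = d, cmax_nM = max(prof$conc_nM),
      auc_nM_day = trapz(prof$time_h, prof$conc_nM) / 24
    )
    time_h <- prof$time_h
  }
  mat <- do.call(cbind, traces)
  qs <- apply(mat, 1, stats::quantile, probs = c(0.25, 0.5, 0.75), names = FALSE)
  structure(
    list(
      summary = tibble::tibble(time_h = time_h, q1 = qs[1, ],
                               median = qs[2, ], q3 = qs[3, ]),
      metric_draws = dplyr::bind_rows(metric_rows),
      n_draws = n_draws, seed = seed,
      compartment = compartment, analyte = analyte
    ),
    class = "pbk_mc"
  )
}

#' @export
print.pbk_mc <- function(x, ...) {
  cat(sprintf("<pbk_mc> %d draws (seed %d) | %s %s | median Cmax %.4g nM\n",
              x$n_draws, x$seed, x$compartment, x$analyte,
              stats::median(x$metric_draws$cmax_nM)))
  invisible(x)
}

#' @method glance pbk_mc
#' @export
glance.pbk_mc <- function(x, ...) {
  tibble::tibble(
    n_draws = x$n_draws, seed = x$seed,
    cmax_median = stats::median(x$metric_draws$cmax_nM),
    cmax_q1 = stats::quantile(x$metric_draws$cmax_nM, 0.25, names = FALSE),
    cmax_q3 = stats::quantile(x$metric_draws$cmax_nM, 0.75, names = FALSE),
    auc_median = stats::median(x$metric_draws$auc_nM_day)
  )
}
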