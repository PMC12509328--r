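test_that("Nalimov screening removes gross outliers and respects n >= 3", {
  expect_error(nalimov_filter(c(1, 2)), class = "bispbk_input_error")
  expect_length(nalimov_filter(c(5, 5, 5, 5))$excluded, 0)
  # hand computation: x = {1.0, 1.1, 0.9, 12.0}, n = 4
  # q(12) = |12 - 3.75| / 5.5019 * sqrt(4/3) = 1.732 > 1.645 (95%, n = 4)
  res <- nalimov_filter(c(1.0, 1.1, 0.9, 12.0))
  expect_equal(res$excluded, 4L)
  expect_equal(sort(res$retained), c(0.9, 1.0, 1.1))
  q_hand <- abs(12 - mean(c(1, 1.1, 0.9, 12))) / sd(c(1, 1.1, 0.9, 12)) * sqrt(4 / 3)
  expect_gt(q_hand, 1.645)
})

test_that("depletion series convert to interval rates at midpoint substrate", {
  # forced arithmetic: 10 -> 8 uM over 10 min at 1 mg/mL gives 0.2 nmol/min/mg
  series <- tibble::tibble(time_h = c(0, 10 / 60), conc_uM = c(10, 8),
                           protein_mg_per_ml = 1)
  rates <- depletion_to_rates(series)
  expect_equal(rates$v, 0.2, tolerance = 1e-12)
  expect_equal(rates$s, 9)
  # flat series gives zero rates
  flat <- tibble::tibble(time_h = 0:3, conc_uM = rep(4, 4), protein_mg_per_ml = 1)
  expect_true(all(depletion_to_rates(flat)$v == 0))
  expect_error(depletion_to_rates(series[1, ]), class = "bispbk_input_error")
  bad <- tibble::tibble(time_h = c(0, 0), conc_uM = c(1, 2), protein_mg_per_ml = 1)
  expect_error(depletion_to_rates(bad), class = "bispbk_input_error")
})

test_that("Michaelis-Menten fitting recovers exact and noisy parameters", {
  s <- c(1, 2, 5, 10, 20, 50, 100)
  exact <- tibble::tibble(s = s, v = 1 * s / (5 + s))
  fit <- fit_michaelis_menten(exact)
  expect_equal(fit$vmax, 1, tolerance = 1e-6)
  expect_equal(fit$km, 5, tolerance = 1e-6)
  expect_gt(fit$r2, 1 - 1e-10)
  # analytic property: v(S = Km) = Vmax / 2 on the fitted curve
  expect_equal(fit$vmax * fit$km / (fit$km + fit$km), fit$vmax / 2)
  # noisy data agree with a brute-force SSE grid search
  set.seed(42)
  noisy <- tibble::tibble(s = s, v = (1 * s / (5 + s)) * (1 + rnorm(7, 0, 0.05)))
  nf <- fit_michaelis_menten(noisy)
  oracle <- grid_search_mm(noisy, seq(0.8, 1.2, by = 0.002),
                           seq(3, 7, by = 0.01))
  expect_equal(nf$vmax, oracle$vmax, tolerance = 0.01)
  expect_equal(nf$km, oracle$km, tolerance = 0.01)
  expect_lte(sum((noisy$v - nf$vmax * noisy$s / (nf$km + noisy$s))^2),
             oracle$sse + 1e-12)
  expect_error(fit_michaelis_menten(tibble::tibble(s = c(5, 5, 5), v = 1:3)),
               class = "bispbk_input_error")
})

test_that("substrate-inhibition fitting recovers parameters and nests MM", {
  s <- c(1, 2, 5, 10, 20, 50, 100, 200)
  exact <- tibble::tibble(s = s, v = 2 * s / (3 + s * (1 + s / 50)))
  fit <- fit_substrate_inhibition(exact)
  expect_equal(fit$vmax, 2, tolerance = 1e-5)
  expect_equal(fit$km, 3, tolerance = 1e-5)
  expect_equal(fit$ki, 50, tolerance = 1e-4)
  # the fitted curve peaks at S = sqrt(Km * Ki)
  s_grid <- seq(1, 60, by = 0.01)
  v_grid <- fit$vmax * s_grid / (fit$km + s_grid * (1 + s_grid / fit$ki))
  expect_equal(s_grid[which.max(v_grid)], sqrt(fit$km * fit$ki), tolerance = 0.01)
  # Ki -> Inf limit reproduces the MM curve
  mm_data <- tibble::tibble(s = s, v = 1 * s / (5 + s))
  si_on_mm <- fit_substrate_inhibition(mm_data)
  mm_on_mm <- fit_michaelis_menten(mm_data)
  expect_gte(si_on_mm$r2, mm_on_mm$r2 - 1e-6)
  expect_error(fit_substrate_inhibition(exact[1:3, ]), class = "bispbk_input_error")
})

test_that("best-fit selection maximises R2 with a parsimony tie-break", {
  mk <- function(model, r2) structure(
    list(model = model, r2 = r2, converged = TRUE), class = "kinetic_fit")
  expect_equal(select_best_fit(list(mk("MM", 0.99), mk("SI", 0.95)))$model, "MM")
  expect_equal(select_best_fit(list(mk("MM", 0.90), mk("SI", 0.97)))$model, "SI")
  expect_equal(select_best_fit(list(mk("MM", 0.95), mk("SI", 0.95)))$model, "MM")
  failed <- structure(list(model = "MM", r2 = NA_real_, converged = FALSE),
                      class = "kinetic_fit")
  expect_error(select_best_fit(list(failed)), class = "bispbk_fit_error")
})

test_that("liver scaling multiplies yield and mass and checks the system tag", {
  fit <- structure(list(vmax = 1, system = "human_S9"), class = "kinetic_fit")
  expect_equal(scale_to_liver(fit, 1800), 1 * 107.3 * 1800)
  expect_error(scale_to_liver(fit, 1800, protein_yield = 0),
               class = "bispbk_input_error")
  micro <- structure(list(vmax = 1, system = "human_microsome"),
                     class = "kinetic_fit")
  expect_error(scale_to_liver(micro, 1800, system = "human_S9"),
               class = "bispbk_input_error")
})

test_that("ontogeny scaling is the abundance ratio", {
  expect_equal(ontogeny_sfg(8, 8), 1)
  expect_equal(ontogeny_sfg(2, 8), 0.25)
  expect_error(ontogeny_sfg(2, 0), class = "bispbk_input_error")
})

test_that("full chain recovers generating parameters from noiseless fixtures", {
  spec <- fixture_spec("depletion", noise_sd = 0, seed = 1, vmax = 2, km = 8,
                       chemical = "X", system = "human_S9")
  fit <- fit_glucuronidation(generate_depletion_fixture(spec))$X
  expect_lt(abs(fit$vmax - 2) / 2, 1e-3)
  expect_lt(abs(fit$km - 8) / 8, 1e-3)
})
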