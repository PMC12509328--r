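test_that("local coefficients are exact for linear and absent dependence", {
  sched <- make_schedule(5)
  # sub-saturating regime: blood Cmax is linear in the dose -> coefficient 1
  ls_dose <- local_sensitivity(man_bpa, sched, "dose",
                               tk_output("cmax", analyte = "glucuronide"),
                               solver = fast_solver)
  expect_equal(ls_dose$coefficient, 1, tolerance = 0.01)
  expect_true(ls_dose$sensitive)
  # a parameter the output does not depend on scores zero
  ls_bile <- local_sensitivity(man_bpa, sched, "bile_flow",
                               tk_output("cmax", analyte = "glucuronide"),
                               solver = fast_solver)
  expect_equal(ls_bile$coefficient, 0, tolerance = 1e-8)
  expect_error(
    local_sensitivity(man_bpa, new_schedule(0, 0, 24), "dose",
                      tk_output("cmax"), solver = fast_solver),
    class = "bispbk_input_error")
})

test_that("Morris screening ranks an additive test function correctly", {
  fn <- function(x) 1 * x[["a"]] + 4 * x[["b"]] + 0.5 * x[["c"]] + 0 * x[["d"]]
  lower <- c(a = 0, b = 0, c = 0, d = 0)
  upper <- c(a = 1, b = 1, c = 1, d = 1)
  res <- morris_screen(fn, lower, upper, r = 6, seed = 11)
  expect_equal(res$parameter[1:3], c("b", "a", "c"))
  # elementary effects of a linear function are exactly the coefficients
  expect_equal(res$mu_star[res$parameter == "b"], 4, tolerance = 1e-10)
  # the dummy parameter has no effect
  expect_equal(res$mu_star[res$parameter == "d"], 0, tolerance = 1e-12)
  # determinism under a fixed seed
  res2 <- morris_screen(fn, lower, upper, r = 6, seed = 11)
  expect_identical(res, res2)
  # degenerate ranges are skipped with a warning
  expect_warning(
    morris_screen(fn, c(lower[1:3], d = 0.5), c(upper[1:3], d = 0.5),
                  r = 2, seed = 1),
    "zero-width")
})

test_that("eFAST indices match the analytic variance decomposition", {
  fn <- function(x) 1 * x[["a"]] + 2 * x[["b"]] + 0.5 * x[["c"]]
  lower <- c(a = 0, b = 0, c = 0)
  upper <- c(a = 1, b = 1, c = 1)
  res <- efast_indices(fn, lower, upper, n = 257, seed = 2)
  analytic <- c(1, 4, 0.25) / sum(c(1, 4, 0.25))
  expect_equal(res$first_order, analytic, tolerance = 0.05)
  expect_equal(res$total_order, analytic, tolerance = 0.05)
  # additive function: negligible interaction; first-order sum bounded by 1
  expect_lt(max(abs(res$interaction)), 0.05)
  expect_lte(sum(res$first_order), 1 + 0.05)
  # a single dominant parameter takes (almost) all the variance
  fdom <- function(x) 10 * x[["a"]] + 1e-3 * x[["b"]]
  rdom <- efast_indices(fdom, lower[1:2], upper[1:2], n = 257, seed = 2)
  expect_gt(rdom$total_order[1], 0.95)
  expect_lt(rdom$first_order[2], 0.05)
  expect_error(efast_indices(fn, lower, upper, n = 30),
               class = "bispbk_input_error")
  expect_error(efast_indices(fn, lower["a"], upper["a"]),
               class = "bispbk_input_error")
})

test_that("Morris and eFAST rank a separable function identically", {
  fn <- function(x) 0.5 * x[["a"]] + 3 * x[["b"]] + 1.5 * x[["c"]]
  lower <- c(a = 0, b = 0, c = 0)
  upper <- c(a = 1, b = 1, c = 1)
  mo <- morris_screen(fn, lower, upper, r = 6, seed = 4)
  ef <- efast_indices(fn, lower, upper, n = 257, seed = 4)
  expect_equal(mo$parameter[order(-mo$mu_star)],
               ef$parameter[order(-ef$total_order)])
})

test_that("PBK Morris screening runs and flags a known-influential parameter", {
  vari <- default_variability()[c(1, 3, 6), ] # bw, gest, vmax
  res <- pbk_morris(man_bpa, make_schedule(5), vari,
                    output = tk_output("auc", analyte = "glucuronide", window = 4),
                    r = 3, seed = 5, solver = coarse_solver)
  expect_equal(nrow(res), 3)
  expect_true(all(is.finite(res$mu_star)))
  # the metabolic capacity must matter for the early glucuronide AUC
  expect_gt(res$mu_star[res$parameter == "vmax"], 0)
})

test_that("constrained Monte Carlo respects quartile order and constraints", {
  sched <- make_schedule(5)
  mc <- monte_carlo_pbk(man_bpa, sched, n_draws = 20, seed = 9,
                        analyte = "glucuronide", solver = coarse_solver)
  expect_true(all(mc$summary$q1 <= mc$summary$median + 1e-12))
  expect_true(all(mc$summary$median <= mc$summary$q3 + 1e-12))
  # single draw collapses the quartiles onto the trace
  mc1 <- monte_carlo_pbk(man_bpa, sched, n_draws = 1, seed = 9,
                         solver = coarse_solver)
  expect_equal(mc1$summary$q1, mc1$summary$median)
  expect_equal(mc1$summary$q3, mc1$summary$median)
  # zero CVs reproduce the deterministic baseline
  degen <- dplyr::mutate(default_variability(), cv = 0)
  mc0 <- monte_carlo_pbk(man_bpa, sched, degen, n_draws = 3, seed = 1,
                         analyte = "glucuronide", solver = coarse_solver)
  base <- conc_profile(simulate_pbk(man_bpa, sched, coarse_solver),
                       "blood", "glucuronide")
  expect_equal(mc0$summary$median, base$conc_nM, tolerance = 1e-10)
  # seeded reproducibility
  mc_b <- monte_carlo_pbk(man_bpa, sched, n_draws = 20, seed = 9,
                          analyte = "glucuronide", solver = coarse_solver)
  expect_identical(mc$summary, mc_b$summary)
  expect_error(
    monte_carlo_pbk(man_bpa, sched,
                    tibble::tibble(parameter = "bw", cv = 0.1, family = "cauchy"),
                    n_draws = 2),
    class = "bispbk_input_error")
})

test_that("Monte Carlo draws preserve the fraction-sum constraints", {
  # the projection used inside monte_carlo_pbk, audited directly
  set.seed(31)
  base <- man_bpa
  vsum0 <- sum(unlist(base$physiology[
    c("v_liver", "v_kidney", "v_gut", "v_thyroid", "v_gonad", "v_blood",
      "v_slowly", "v_rapidly")]))
  for (i in 1:25) {
    p <- base
    p <- set_pbk_param(p, "v_liver", get_pbk_param(p, "v_liver") * runif(1, 0.5, 1.5))
    p <- set_pbk_param(p, "ehcr", runif(1, -0.2, 1.3))
    p$ehcr <- min(1, max(0, p$ehcr))
    cols <- c("v_liver", "v_kidney", "v_gut", "v_thyroid", "v_gonad",
              "v_blood", "v_slowly", "v_rapidly")
    vsum <- sum(unlist(p$physiology[cols]))
    for (col in cols) p$physiology[[col]] <- p$physiology[[col]] * vsum0 / vsum
    expect_lt(abs(sum(unlist(p$physiology[cols])) - vsum0), 1e-9)
    expect_gte(p$ehcr, 0)
    expect_lte(p$ehcr, 1)
  }
})
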