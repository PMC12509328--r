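test_that("recirculation fit recovers the generating rate exactly", {
  truths <- c(0.1, 0.5, 0.9)
  for (truth in truths) {
    spec <- fixture_spec("rat_timecourse", seed = 7, chemical = "BPAF",
                         scenario = 1, sampling_times = c(1, 2, 4, 8, 12, 24, 48))
    obs <- generate_rat_timecourse_fixture(spec, true_ehcr = truth)
    fit <- fit_ehcr_rat(obs, default_pbk_params("BPAF", "rat", ehcr = 0.5),
                        make_schedule(1), target_time = 48)
    expect_lt(abs(fit$ehcr - truth), 0.02)
    expect_true(fit$converged)
    expect_true(fit$cmax_guard_ok)
  }
})

test_that("degenerate observations are flagged, boundary identity holds", {
  spec <- fixture_spec("rat_timecourse", seed = 2, chemical = "BPF",
                       scenario = 2, sampling_times = c(1, 2, 4, 8, 12, 24))
  obs0 <- generate_rat_timecourse_fixture(spec, true_ehcr = 0)
  fit0 <- fit_ehcr_rat(obs0, default_pbk_params("BPF", "rat", ehcr = 0.5),
                       make_schedule(2), target_time = 24)
  expect_lt(fit0$ehcr, 0.02)
  # observed zero at the target with a positive simulated floor cannot converge
  obs_bad <- obs0
  obs_bad$conc_nM[obs_bad$time_h == 24] <- 0
  obs_bad$conc_nM[1] <- obs0$conc_nM[1]
  fit_bad <- fit_ehcr_rat(obs_bad, default_pbk_params("BPF", "rat", ehcr = 0.5),
                          make_schedule(2), target_time = 24)
  expect_false(fit_bad$converged)
  expect_error(
    fit_ehcr_rat(obs0[obs0$time_h < 24, ],
                 default_pbk_params("BPF", "rat", ehcr = 0.5),
                 make_schedule(2), target_time = 24),
    class = "bispbk_input_error"
  )
})

test_that("molecular-weight calibration interpolates, clips and pins BPM", {
  chems <- default_chemicals()
  anchors <- tibble::tibble(name = c("BPAF", "BPF"), ehcr = c(0.85, 0.68))
  cal <- calibrate_ehcr_by_mw(anchors, chems$name, chems)
  # anchors reproduce themselves
  expect_equal(cal$ehcr[cal$name == "BPAF"], 0.85)
  expect_equal(cal$ehcr[cal$name == "BPF"], 0.68)
  # linear interpolation on glucuronide MW, checked by hand for BPA
  mw <- setNames(chems$mw_glucuronide, chems$name)
  slope <- (0.85 - 0.68) / (mw[["BPAF"]] - mw[["BPF"]])
  expect_equal(cal$ehcr[cal$name == "BPA"],
               unname(0.68 + slope * (mw[["BPA"]] - mw[["BPF"]])))
  # BPM is pinned to BPAF regardless of its own MW
  expect_equal(cal$ehcr[cal$name == "BPM"], 0.85)
  # extrapolations are clipped to [0, 1]
  wild <- tibble::tibble(name = c("BPF", "BPAF"), ehcr = c(0.95, 0.999))
  cal2 <- calibrate_ehcr_by_mw(wild, "BPS", chems)
  expect_lte(cal2$ehcr, 1)
  expect_error(calibrate_ehcr_by_mw(anchors[1, ], "BPA", chems),
               class = "bispbk_input_error")
})

test_that("human models inherit the sex-matched rat values", {
  tab <- default_ehcr_table()
  male <- vapply(c("man", "child", "toddler"),
                 function(m) assign_ehcr(tab, "BPA", m), numeric(1))
  expect_true(all(male == male[1]))
  # female anchors sit above the male ones
  expect_gt(assign_ehcr(tab, "BPAF", "woman"), assign_ehcr(tab, "BPAF", "man"))
  expect_error(assign_ehcr(tab, "BPA", "alien"), class = "bispbk_input_error")
  # all defaults respect the [0, 1] bound and the fitted anchors are > 0.63
  expect_true(all(tab$ehcr >= 0 & tab$ehcr <= 1))
  expect_true(all(tab$ehcr[tab$source == "anchor"] > 0.63))
})
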