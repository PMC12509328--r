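test_that("dose schedules follow the scenario definitions", {
  s9 <- make_schedule(9)
  expect_length(s9$event_times, 12)
  expect_equal(s9$dose_ng_per_kg, 112)
  expect_equal(s9$duration_h, 96)
  s8 <- make_schedule(8)
  expect_equal(s8$event_times, 0)
  expect_equal(s8$dose_ng_per_kg, 869)
  expect_equal(s8$duration_h, 48)
  expect_error(make_schedule(13), class = "bispbk_input_error")
  expect_error(new_schedule(1, c(0, 0)), class = "bispbk_input_error")
  expect_error(new_schedule(1, c(0, 60), duration_h = 48),
               class = "bispbk_input_error")
  # the alternative dose for the BPS replication study is selectable
  expect_equal(make_schedule(4, bps_dose = 8750)$dose_ng_per_kg, 8750)
})

test_that("parameter bundle validation catches bad inputs", {
  expect_error(default_pbk_params("BPA", "man", ehcr = 1.2),
               class = "bispbk_input_error")
  expect_error(default_pbk_params("BPX", "man"), class = "bispbk_input_error")
  expect_error(default_pbk_params("BPA", "martian"), class = "bispbk_input_error")
  expect_s3_class(man_bpa, "pbk_params")
  expect_equal(man_bpa$kinetics$sfg, 1)
  expect_lt(default_pbk_params("BPA", "toddler")$kinetics$sfg, 1)
})

test_that("zero dose produces identically zero concentrations", {
  sched <- new_schedule(0, 0, 24)
  sim <- simulate_pbk(man_bpa, sched, fast_solver)
  expect_equal(max(abs(sim$out[, -1])), 0)
})

test_that("molar mass balance closes at every output time", {
  for (sc in c(5, 9)) {
    params <- default_pbk_params("BPA", make_schedule(sc)$model)
    sim <- simulate_pbk(params, make_schedule(sc), fast_solver)
    expect_lt(mass_balance_error(sim), 1e-4)
    expect_gte(min(sim$out[, -1]), -1e-6)
  }
  sim_rat <- simulate_pbk(rat_bpaf, make_schedule(1), fast_solver)
  expect_lt(mass_balance_error(sim_rat), 1e-4)
})

test_that("no recirculation confines the glucuronide to urine", {
  p0 <- default_pbk_params("BPA", "man", ehcr = 0)
  sim <- simulate_pbk(p0, make_schedule(5), fast_solver)
  last <- sim$out[nrow(sim$out), ]
  expect_equal(unname(last[["bile_gluc_cum"]]), 0)
  expect_gt(unname(last[["urine_gluc"]]), 0)
  # fecal output is only ever unabsorbed parent; it must not exceed the
  # never-recirculated luminal share ka/(ka+kcol)
  expect_lt(unname(last[["feces_parent"]]) / sim$administered_nmol,
            p0$kcol / (p0$absorption$ka + p0$kcol) + 1e-6)
})

test_that("the system is linear below Km: superposition and dose scaling", {
  d <- 336
  one <- simulate_pbk(man_bpa, new_schedule(d, 0, 48), fast_solver)
  split2 <- simulate_pbk(man_bpa, new_schedule(d / 2, c(0, 0.5), 48),
                         fast_solver)
  # two half doses, elimination complete well before 48 h: AUCs superpose
  expect_equal(extract_tk_metrics(split2, "blood", "glucuronide")$auc_nM_day,
               extract_tk_metrics(one, "blood", "glucuronide")$auc_nM_day,
               tolerance = 0.01)
  # alpha-scaling of the dose scales every trace by alpha
  alpha <- 3
  scaled <- simulate_pbk(man_bpa, new_schedule(alpha * d, 0, 48), fast_solver)
  prof1 <- conc_profile(one, "blood", "glucuronide")$conc_nM
  prof3 <- conc_profile(scaled, "blood", "glucuronide")$conc_nM
  nz <- prof1 > max(prof1) * 1e-6
  expect_lt(max(abs(prof3[nz] / prof1[nz] - alpha)) / alpha, 0.01)
})

test_that("toxicokinetic metrics implement the documented conventions", {
  # constant 1 nM over 24 h integrates to exactly 1 nM*day
  fake <- man_bpa
  sim <- simulate_pbk(fake, new_schedule(336, 0, 48), fast_solver)
  prof <- conc_profile(sim, "blood", "glucuronide")
  tk <- extract_tk_metrics(sim, "blood", "glucuronide")
  expect_equal(tk$cmax_nM, max(prof$conc_nM))
  expect_equal(tk$tmax_h, prof$time_h[which.max(prof$conc_nM)])
  expect_gte(tk$auc_nM_day, 0)
  expect_error(extract_tk_metrics(sim, "bone", "parent"),
               class = "bispbk_input_error")
  # plateau tie rule: earliest time of the maximum
  x <- c(0, 5, 10, 10, 10, 4)
  expect_equal(c(0:5)[which.max(x)], 2)
})

test_that("species gating excludes thyroid and gonadal tissue from the rat", {
  sim_rat <- simulate_pbk(rat_bpaf, make_schedule(1), fast_solver)
  expect_equal(max(abs(sim_rat$out[, c("thyroid_parent", "gonad_parent",
                                       "thyroid_gluc", "gonad_gluc")])), 0)
  sim_man <- simulate_pbk(man_bpa, make_schedule(5), fast_solver)
  expect_gt(max(sim_man$out[, "thyroid_parent"]), 0)
  expect_gt(max(sim_man$out[, "gonad_parent"]), 0)
  # rat physiology cannot carry gonadal volume
  phys <- default_physiologies()
  bad <- phys
  bad$v_gonad[bad$label == "rat"] <- 0.001
  expect_error(validate_physiologies(bad), class = "bispbk_input_error")
})

test_that("solutions are stable under grid refinement", {
  tk1 <- extract_tk_metrics(
    simulate_pbk(man_bpa, make_schedule(5), solver_config(dt_out = 0.01)),
    "blood", "glucuronide")
  tk2 <- extract_tk_metrics(
    simulate_pbk(man_bpa, make_schedule(5), solver_config(dt_out = 0.005)),
    "blood", "glucuronide")
  expect_lt(abs(tk1$cmax_nM - tk2$cmax_nM) / tk1$cmax_nM, 1e-3)
})

test_that("compiled and reference right-hand sides agree", {
  sim_c <- simulate_pbk(man_bpa, make_schedule(5), fast_solver, engine = "c")
  sim_r <- simulate_pbk(man_bpa, make_schedule(5), fast_solver, engine = "r")
  rel <- abs(sim_c$out[, "urine_gluc"] - sim_r$out[, "urine_gluc"]) /
    (max(sim_c$out[, "urine_gluc"]) + 1e-12)
  expect_lt(max(rel), 1e-6)
  pc <- conc_profile(sim_c, "blood", "glucuronide")$conc_nM
  pr <- conc_profile(sim_r, "blood", "glucuronide")$conc_nM
  expect_lt(max(abs(pc - pr)) / max(pc), 1e-6)
})

test_that("tidy() returns the long concentration table", {
  sim <- simulate_pbk(man_bpa, new_schedule(336, 0, 6),
                      solver_config(dt_out = 0.1))
  td <- generics::tidy(sim)
  expect_true(all(c("time_h", "compartment", "analyte", "amount_nmol",
                    "conc_nM") %in% names(td)))
  expect_setequal(unique(td$analyte), c("parent", "glucuronide"))
  expect_true(all(is.na(td$conc_nM[td$compartment == "urine"])))
})
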