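test_that("noise-free areas equal the model expectation exactly", {
  des <- experiment_design("cd_dose_experiment", doses = 25, cds = "beta",
                          cv = 0, seed = 1)
  runs <- generate_peak_areas(des)
  rt <- retention_table(runs, letters = FALSE)
  truth <- attr(runs, "truth")
  m <- merge(as.data.frame(rt), truth, by = c("compound", "treatment"))
  expect_equal(m$percent_of_control.x, m$percent_of_control.y,
               tolerance = 1e-12)
  # replicates are identical at CV = 0
  expect_equal(runs$area_analyte[runs$replicate == 1],
               runs$area_analyte[runs$replicate == 2])
})

test_that("the same seed reproduces the run table exactly", {
  des <- experiment_design("cd_dose_experiment", seed = 99, cv = 0.05)
  r1 <- generate_peak_areas(des)
  r2 <- generate_peak_areas(des)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- generate_peak_areas(des, seed = 100)
  expect_false(identical(r1$area_analyte, r3$area_analyte))
  expect_error(generate_peak_areas(experiment_design("cd_dose_experiment")),
               "seed")
})

test_that("co-dissolved standards cancel the treatment signal completely", {
  # the three-phase design: analyte and its label share K1/K2/kb, so every
  # percent-of-control is exactly 100 whatever the host or dose
  des <- experiment_design("three_phase_cd_experiment", doses = c(5, 25),
                          cds = c("alpha", "beta", "gamma"), cv = 0,
                          seed = 5)
  runs <- generate_peak_areas(des)
  rt <- retention_table(runs, letters = FALSE)
  trt <- rt[rt$treatment != "control", ]
  expect_equal(trt$percent_of_control, rep(100, nrow(trt)),
               tolerance = 1e-9)
  # yet the absolute signal drops sharply under the strong binder, which is
  # how the failure of the conventional design stays hidden
  a_ctrl <- mean(runs$area_analyte[runs$treatment == "control" &
                                     runs$compound == "4-ethylphenol"])
  a_beta <- mean(runs$area_analyte[runs$treatment == "beta-25" &
                                     runs$compound == "4-ethylphenol"])
  expect_lt(a_beta, a_ctrl)
})

test_that("four-phase design protects the standard and exposes retention", {
  des <- experiment_design("cd_dose_experiment", doses = 25, cds = "beta",
                          cv = 0, seed = 5)
  runs <- generate_peak_areas(des)
  # standard areas identical across treatments (ampoule isolation)
  std_ctrl <- runs$area_standard[runs$treatment == "control" &
                                   runs$compound == "guaiacol"]
  std_beta <- runs$area_standard[runs$treatment == "beta-25" &
                                   runs$compound == "guaiacol"]
  expect_equal(std_ctrl, std_beta, tolerance = 1e-12)
  rt <- retention_table(runs, letters = FALSE)
  trt <- rt[rt$treatment == "beta-25", ]
  expect_true(all(trt$percent_of_control < 100))
})

test_that("generated triplicates show the requested noise level", {
  cv_target <- 0.05
  des <- experiment_design("cd_dose_experiment", doses = 25, cds = "beta",
                          replicates = 50, cv = cv_target, seed = 17)
  runs <- generate_peak_areas(des)
  cvs <- tapply(runs$area_analyte,
                paste(runs$treatment, runs$compound),
                function(a) sd(a) / mean(a))
  expect_gt(median(cvs), 0.7 * cv_target)
  expect_lt(median(cvs), 1.3 * cv_target)
  # and realistic triplicate CVs fall within the validated 0.1-9.3% band
  des3 <- experiment_design("cd_dose_experiment", doses = 25, cds = "beta",
                           replicates = 3, cv = 0.03, seed = 18)
  runs3 <- generate_peak_areas(des3)
  cvs3 <- tapply(runs3$area_analyte,
                 paste(runs3$treatment, runs3$compound),
                 function(a) 100 * sd(a) / mean(a))
  expect_gt(mean(cvs3 >= 0.1 & cvs3 <= 9.3), 0.8)
})

test_that("pipeline closure: simulated retention recovers the truth", {
  # generate -> retention_table over seeds; each seed's estimate lies
  # within 3 standard errors of the generating percentage
  compounds <- default_compounds()
  kb <- default_binding_constants()
  keep <- c("guaiacol", "4-ethylphenol", "d3-guaiacol", "d4-4-ethylphenol")
  cv <- 0.02; n_rep <- 3
  # analytic SE of the generating process: each RPA carries two independent
  # lognormal area draws (sd of log = sqrt(2)*log(1+cv)), and the percent is
  # a ratio of two independent means of n_rep such RPAs
  rel_se <- 2 * log(1 + cv) / sqrt(n_rep)
  inside <- 0L; total <- 0L
  for (s in 1:100) {
    des <- experiment_design("cd_dose_experiment", doses = 25, cds = "beta",
                            replicates = n_rep, cv = cv, seed = 1000 + s)
    runs <- generate_peak_areas(des, compounds = compounds[keep],
                                kb_table = kb)
    rt <- retention_table(runs, letters = FALSE)
    truth <- attr(runs, "truth")
    trt <- rt[rt$treatment == "beta-25", ]
    for (i in seq_len(nrow(trt))) {
      true_pct <- truth$percent_of_control[
        truth$treatment == "beta-25" & truth$compound == trt$compound[i]]
      inside <- inside + (abs(trt$percent_of_control[i] - true_pct) <=
                            3 * true_pct * rel_se)
      total <- total + 1L
    }
  }
  expect_gt(inside / total, 0.95)
})

test_that("calibration series scales linearly with the spike level", {
  cfg <- default_compounds()
  keep <- c("guaiacol", "4-methylguaiacol", "4-ethylphenol",
            "d3-guaiacol", "d3-4-methylguaiacol", "d4-4-ethylphenol")
  des <- experiment_design("calibration_series", cv = 0, seed = 2)
  runs <- generate_peak_areas(des, compounds = cfg[keep])
  fits <- calibrate(runs)
  expect_setequal(names(fits), c("guaiacol", "4-methylguaiacol",
                                 "4-ethylphenol"))
  for (f in fits) {
    expect_equal(f$r_squared, 1, tolerance = 1e-12)
    expect_equal(f$intercept, 0, tolerance = 1e-12)
  }
  truth <- attr(runs, "truth")
  expect_equal(fits[["guaiacol"]]$slope,
               truth$slope[truth$compound == "guaiacol"],
               tolerance = 1e-9)
})
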