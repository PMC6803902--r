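test_that("relative peak area is a plain area ratio", {
  expect_equal(relative_peak_area(100000, 100000), 1.0)
  expect_equal(relative_peak_area(24400, 20000), 1.22)
  # invariant under common rescaling of both areas
  expect_equal(relative_peak_area(2.7 * 24400, 2.7 * 20000), 1.22)
  expect_error(relative_peak_area(100, 0), "positive")
})

test_that("calibration fitting recovers exact lines and rejects degenerate designs", {
  fit <- fit_calibration(c(0, 1, 2), c(0, 1, 2))
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_calibration(c(1, 1), c(0.9, 1.1)), "degenerate")
  expect_error(fit_calibration(c(1, 1, 2), c(1, 1, 2)), "degenerate")
})

test_that("quantify inverts the calibration line", {
  fit <- fit_calibration(c(0.25, 0.5, 1, 2), c(0.33, 0.61, 1.18, 2.31))
  expect_equal(quantify(fit$intercept, fit), 0)
  conc <- c(0.3, 0.9, 1.7)
  expect_equal(quantify(predict(fit, conc), fit), conc, tolerance = 1e-12)
  expect_warning(quantify(fit$intercept - 1, fit), "negative")
  degenerate <- fit
  degenerate$slope <- 0
  expect_error(quantify(1, degenerate), "slope")
})

test_that("quantifying noisy synthetic levels recovers the truth within 3 CV", {
  cv <- 0.03
  cfg <- default_compounds()
  keep <- c("guaiacol", "d3-guaiacol")
  des <- experiment_design("calibration_series", cv = cv, seed = 301)
  runs <- generate_peak_areas(des, compounds = cfg[keep])
  fits <- calibrate(runs)
  fit <- fits[["guaiacol"]]
  expect_gt(fit$r_squared, 0.98)
  df <- as.data.frame(runs)
  df$rpa <- relative_peak_area(df$area_analyte, df$area_standard)
  # the blank level back-calculates slightly negative, which warns
  expect_warning(est <- quantify(df$rpa, fit), "negative")
  nz <- df$level_mg_per_L > 0
  # multiplicative area noise on analyte and standard: ~sqrt(2)*cv per RPA
  expect_true(all(abs(est[nz] - df$level_mg_per_L[nz]) /
                    df$level_mg_per_L[nz] < 3 * sqrt(2) * cv))
})

test_that("retention percentages are ratios of mean RPAs", {
  runs <- data.frame(
    compound = rep(c("a", "b"), each = 6),
    treatment = rep(rep(c("control", "beta-25"), each = 3), 2),
    replicate = rep(1:3, 4),
    area_analyte = c(100, 110, 90, 50, 55, 45,   200, 210, 190, 200, 210, 190),
    area_standard = rep(100, 12)
  )
  rt <- retention_table(runs, letters = FALSE)
  expect_equal(rt$percent_of_control[rt$compound == "a" &
                                       rt$treatment == "beta-25"], 50)
  # untreated-equivalent compound stays at exactly 100%
  expect_equal(rt$percent_of_control[rt$compound == "b" &
                                       rt$treatment == "beta-25"], 100)
  ov <- attr(rt, "overall")
  expect_equal(ov$overall_mean_percent[ov$treatment == "beta-25"], 75)
  # a treatment without control coverage fails loudly
  broken <- runs[!(runs$compound == "a" & runs$treatment == "control"), ]
  expect_error(retention_table(broken), "control.*a")
})

test_that("reference RPAs reproduce the published per-compound retention", {
  ref <- cd_retention_reference()
  runs <- data.frame(compound = ref$compound, treatment = ref$treatment,
                     replicate = 1, rpa = ref$rpa)
  rt <- retention_table(runs, letters = FALSE)
  b25 <- rt[rt$treatment == "beta-25", ]
  expect_equal(
    b25$percent_of_control[b25$compound == "4-ethylphenol"],
    100 * 0.43 / 1.85, tolerance = 1e-12)
  expect_equal(
    b25$percent_of_control[b25$compound == "4-ethylphenol"], 23.1,
    tolerance = 0.01)
})

test_that("one-way ANOVA with pairwise letters matches textbook results", {
  # identical groups: F = 0, a single shared letter
  same <- anova_compare(rep(c(1, 2, 3), 3), rep(c("A", "B", "C"), each = 3))
  expect_equal(same$f_value, 0)
  expect_true(all(same$letters == same$letters[1]))

  # two equal groups and one clearly lower one
  vals <- c(0.98, 1.00, 1.02, 0.99, 1.01, 1.00, 0.18, 0.20, 0.22)
  grp <- rep(c("ctrl", "trtA", "trtB"), each = 3)
  ac <- anova_compare(vals, grp)
  expect_lt(ac$p_value, 0.001)
  expect_equal(unname(ac$letters["ctrl"]), unname(ac$letters["trtA"]))
  expect_false(ac$letters["trtB"] %in%
                 c(ac$letters["ctrl"], ac$letters["trtA"]))
  # verified against the textbook decomposition for these numbers
  n <- 3; k <- 3
  gm <- mean(vals)
  ssb <- n * sum((tapply(vals, grp, mean) - gm)^2)
  ssw <- sum((vals - ave(vals, grp))^2)
  expect_equal(ac$f_value, (ssb / (k - 1)) / (ssw / (length(vals) - k)),
               tolerance = 1e-12)

  expect_error(anova_compare(1:3, c("A", "A", "B")), ">= 2 replicates")
})

test_that("for two groups the ANOVA F equals the squared pooled t", {
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(3, 1, 0.1); y <- rnorm(3, 0.8, 0.1)
    ac <- anova_compare(c(x, y), rep(c("A", "B"), each = 3))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(ac$f_value, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(ac$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("compact letter display separates exactly the significant pairs", {
  set.seed(31)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    means <- runif(k, 0, 2)
    sig <- matrix(FALSE, k, k)
    pairs <- which(upper.tri(sig), arr.ind = TRUE)
    on <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
    sig[on] <- TRUE
    sig <- sig | t(sig)
    names(means) <- paste0("g", seq_len(k))
    dimnames(sig) <- list(names(means), names(means))
    lett <- cdretain:::.compact_letters(sig, means)
    share <- function(a, b)
      length(intersect(strsplit(lett[a], "")[[1]],
                       strsplit(lett[b], "")[[1]])) > 0
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      if (sig[a, b]) expect_false(share(a, b)) else expect_true(share(a, b))
    }
  }
})
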