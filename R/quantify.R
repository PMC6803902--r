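#' Relative peak area
#'
#' The quantification signal of stable-isotope-dilution GC-MS: the analyte
#' peak area divided by the matched isotopically labelled standard's peak
#' area. Scale-free, so fiber-to-fiber response drift cancels.
#'
#' @param A_s Analyte peak area(s), arbitrary counts.
#' @param A_i Matched standard peak area(s); must be positive.
#' @return Numeric vector `A_s / A_i`.
#' @examples
#' relative_peak_area(24400, 20000)  # 1.22
#' @export
relative_peak_area <- function(A_s, A_i) {
  if (any(!is.finite(A_i)) || any(A_i <= 0))
    stop("standard peak area A_i must be positive", call. = FALSE)
  A_s / A_i
}

#' Fit a linear calibration function
#'
#' Ordinary least squares of relative peak area on spiked concentration,
#' `RPA = slope * conc + intercept`, with the coefficient of determination
#' reported as the squared Pearson correlation. Calibration points are
#' usually replicate-mean RPAs per spike level (see [calibrate()]).
#'
#' @param conc Spiked concentrations, mg/L; at least 3 distinct levels.
#' @param rpa Relative peak areas, same length.
#' @param compound Optional compound label carried in the result.
#' @return An object of class `calibration_fit` with elements `slope`,
#'   `intercept`, `r_squared`, `range`, `n_points`, `compound` and the
#'   underlying `lm` fit.
#' @examples
#' fit <- fit_calibration(c(0, 1, 2), c(0.02, 1.1, 2.1))
#' coef(fit)
#' @export
fit_calibration <- function(conc, rpa, compound = NULL) {
  if (length(conc) != length(rpa))
    stop("conc and rpa must have the same length", call. = FALSE)
  if (anyNA(conc) || anyNA(rpa))
    stop("calibration points must not contain NA", call. = FALSE)
  if (length(unique(conc)) < 3L)
    stop("degenerate calibration design: need >= 3 distinct concentrations",
         call. = FALSE)
  fit <- lm(rpa ~ conc)
  structure(list(
    compound = compound,
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    r_squared = cor(conc, rpa)^2,
    range = range(conc),
    n_points = length(conc),
    lm = fit
  ), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit>%s RPA = %.5g * conc + %.5g\n",
              if (!is.null(x$compound)) paste0(" ", x$compound, ":") else "",
              x$slope, x$intercept))
  cat(sprintf("  R^2 = %.5f over %g-%g mg/L (%d points)\n",
              x$r_squared, x$range[1], x$range[2], x$n_points))
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.calibration_fit <- function(object, newconc, ...) {
  if (missing(newconc)) return(fitted(object$lm))
  object$intercept + object$slope * newconc
}

#' @export
residuals.calibration_fit <- function(object, ...) residuals(object$lm)

#' @export
plot.calibration_fit <- function(x, ...) {
  d <- x$lm$model
  plot(d$conc, d$rpa, xlab = "concentration (mg/L)",
       ylab = "relative peak area",
       main = if (!is.null(x$compound)) x$compound else "calibration", ...)
  abline(x$intercept, x$slope)
  invisible(x)
}

#' Concentration from a relative peak area
#'
#' Inverts a [fit_calibration()] line: `conc = (RPA - intercept)/slope`.
#' Negative back-calculated concentrations (blank-level signals below the
#' intercept) are returned as-is with a warning, never truncated.
#'
#' @param rpa Relative peak area(s).
#' @param fit A `calibration_fit`.
#' @return Concentration(s) in mg/L.
#' @export
quantify <- function(rpa, fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope == 0)
    stop("calibration slope is zero; cannot invert", call. = FALSE)
  out <- (rpa - fit$intercept) / fit$slope
  if (any(out < 0, na.rm = TRUE))
    warning("negative back-calculated concentration(s); reported as-is",
            call. = FALSE)
  out
}

#' Fit calibration lines from a calibration run table
#'
#' Computes relative peak areas per record, averages replicates within each
#' spike level (calibration results are conventionally reported as
#' replicate means), and fits one [fit_calibration()] line per compound.
#'
#' @param runs A run table (see [generate_peak_areas()] or
#'   [read_run_table()]) with a `level_mg_per_L` column, or a data frame with
#'   columns `compound`, `level_mg_per_L`, `replicate`, `rpa`.
#' @param level_means Average replicate RPAs per level before fitting
#'   (default `TRUE`); `FALSE` fits all individual points.
#' @return Named list of `calibration_fit` objects, one per compound.
#' @export
calibrate <- function(runs, level_means = TRUE) {
  df <- as.data.frame(runs)
  if (!"rpa" %in% names(df)) {
    .check_columns(df, c("compound", "level_mg_per_L", "area_analyte",
                         "area_standard"), "calibration run table")
    df$rpa <- relative_peak_area(df$area_analyte, df$area_standard)
  } else {
    .check_columns(df, c("compound", "level_mg_per_L", "rpa"),
                   "calibration table")
  }
  out <- lapply(split(df, df$compound), function(d) {
    if (level_means) {
      agg <- aggregate(rpa ~ level_mg_per_L, data = d, FUN = mean)
      fit_calibration(agg$level_mg_per_L, agg$rpa, compound = d$compound[1L])
    } else {
      fit_calibration(d$level_mg_per_L, d$rpa, compound = d$compound[1L])
    }
  })
  out[unique(df$compound)]
}

.check_columns <- function(df, cols, what) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop(what, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Retention-of-control summary of a run table
#'
#' Summarizes a cyclodextrin treatment experiment: per compound and
#' treatment, the mean relative peak area with its standard error, and the
#' retention expressed as a percentage of the untreated control's mean RPA
#' (`100 * mean(RPA_treatment) / mean(RPA_control)`). The per-treatment
#' overall mean is the arithmetic mean of the compound percentages. When
#' every group has at least two replicates, one-way ANOVA with pairwise
#' comparisons assigns compact group letters per compound.
#'
#' @param runs Run table with columns `compound`, `treatment`, `replicate`,
#'   `area_analyte`, `area_standard` (or a precomputed `rpa` column).
#' @param control Treatment label of the control group (default
#'   `"control"`).
#' @param alpha Significance level for the letter display.
#' @param letters Compute compact letter displays (default `TRUE`; skipped
#'   automatically when replicates are insufficient).
#' @return An object of class `retention_result`: data frame with columns
#'   `compound`, `treatment`, `cd`, `dose_g_per_L`, `n`, `rpa_mean`,
#'   `rpa_se`, `percent_of_control`, `letters`, plus attribute `overall`
#'   (per-treatment mean percentage over compounds).
#' @examples
#' ref <- cd_retention_reference()
#' runs <- data.frame(compound = ref$compound, treatment = ref$treatment,
#'                    replicate = 1, rpa = ref$rpa)
#' retention_table(runs, letters = FALSE)
#' @export
retention_table <- function(runs, control = "control", alpha = 0.05,
                            letters = TRUE) {
  df <- as.data.frame(runs)
  .check_columns(df, c("compound", "treatment", "replicate"), "run table")
  if (!"rpa" %in% names(df)) {
    .check_columns(df, c("area_analyte", "area_standard"), "run table")
    df$rpa <- relative_peak_area(df$area_analyte, df$area_standard)
  }
  if (!control %in% df$treatment)
    stop("no control group '", control, "' in run table", call. = FALSE)

  has_cd <- all(c("cd", "dose_g_per_L") %in% names(df))
  groups <- unique(df[c("compound", "treatment")])
  missing_ctrl <- setdiff(unique(df$compound),
                          df$compound[df$treatment == control])
  if (length(missing_ctrl))
    stop("no control measurements for compound(s): ",
         paste(missing_ctrl, collapse = ", "), call. = FALSE)

  se <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- df[df$compound == groups$compound[i] &
              df$treatment == groups$treatment[i], , drop = FALSE]
    ctrl <- df$rpa[df$compound == groups$compound[i] &
                     df$treatment == control]
    data.frame(
      compound = groups$compound[i], treatment = groups$treatment[i],
      cd = if (has_cd) g$cd[1L] else NA_character_,
      dose_g_per_L = if (has_cd) g$dose_g_per_L[1L] else NA_real_,
      n = nrow(g), rpa_mean = mean(g$rpa), rpa_se = se(g$rpa),
      percent_of_control = 100 * mean(g$rpa) / mean(ctrl),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)

  out$letters <- NA_character_
  if (letters) {
    for (cmp in unique(out$compound)) {
      d <- df[df$compound == cmp, , drop = FALSE]
      counts <- table(d$treatment)
      if (length(counts) >= 2L && all(counts >= 2L)) {
        ac <- anova_compare(d$rpa, d$treatment, alpha = alpha)
        idx <- out$compound == cmp
        out$letters[idx] <- ac$letters[out$treatment[idx]]
      }
    }
  }

  trt <- setdiff(unique(out$treatment), control)
  overall <- data.frame(
    treatment = trt,
    overall_mean_percent = vapply(trt, function(tt)
      mean(out$percent_of_control[out$treatment == tt]), 1),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(out, class = c("retention_result", "data.frame"),
            overall = overall, control = control)
}

#' @export
print.retention_result <- function(x, digits = 4, ...) {
  cat("<retention_result> control group:", attr(x, "control"), "\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = digits)
  print.data.frame(df, row.names = FALSE, ...)
  ov <- attr(x, "overall")
  if (nrow(ov)) {
    cat("\noverall mean percent of control by treatment:\n")
    ov$overall_mean_percent <- signif(ov$overall_mean_percent, digits)
    print.data.frame(ov, row.names = FALSE)
  }
  invisible(x)
}

#' One-way ANOVA with pairwise comparisons and letter groupings
#'
#' Classic one-way analysis of variance followed by unadjusted pairwise
#' t-tests with a pooled standard deviation (Fisher's LSD), summarized as a
#' compact letter display: treatments sharing a letter are not significantly
#' different at `alpha`.
#'
#' @param values Numeric response (e.g. replicate relative peak areas).
#' @param groups Group labels, same length; at least 2 groups with at least
#'   2 replicates each.
#' @param alpha Significance level for the letter display (default 0.05).
#' @param adjust Multiplicity adjustment for the pairwise p-values, passed to
#'   [stats::pairwise.t.test()]; `"none"` by default (plain t-tests), with
#'   e.g. `"holm"` available.
#' @param pool_sd Use the pooled ANOVA standard deviation in the pairwise
#'   tests (default `TRUE`).
#' @return An object of class `anova_compare`: list with `f_value`, `df`,
#'   `p_value`, `means`, `pairwise` (p-value matrix), `letters` (named by
#'   group), `alpha`.
#' @examples
#' anova_compare(c(1.0, 1.02, 0.98, 0.2, 0.21, 0.19),
#'               rep(c("control", "treated"), each = 3))
#' @export
anova_compare <- function(values, groups, alpha = 0.05, adjust = "none",
                          pool_sd = TRUE) {
  groups <- as.character(groups)
  if (length(values) != length(groups))
    stop("values and groups must have the same length", call. = FALSE)
  counts <- table(groups)
  if (length(counts) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(counts < 2L))
    stop("every group needs >= 2 replicates; offending group(s): ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)

  fac <- factor(groups, levels = unique(groups))
  fit <- lm(values ~ fac)
  av <- anova(fit)
  f_value <- av[["F value"]][1L]
  p_value <- av[["Pr(>F)"]][1L]
  if (av[["Sum Sq"]][1L] == 0) {
    # identical group means (possibly with zero residual variance): F is 0
    f_value <- 0
    p_value <- 1
  }

  means <- tapply(values, fac, mean)
  if (all(abs(values - ave(values, fac)) < .Machine$double.eps * 100) ||
      av[["Sum Sq"]][2L] == 0) {
    # zero within-group variance: identical groups share a letter only if
    # their means coincide
    k <- length(means)
    sig <- outer(means, means, function(a, b) abs(a - b) > 0)
    pw <- matrix(NA_real_, k, k, dimnames = list(names(means), names(means)))
  } else {
    pt <- pairwise.t.test(values, fac, p.adjust.method = adjust,
                          pool.sd = pool_sd)
    k <- length(means)
    pw <- matrix(NA_real_, k, k, dimnames = list(names(means), names(means)))
    pw[rownames(pt$p.value), colnames(pt$p.value)] <- pt$p.value
    pw[upper.tri(pw)] <- t(pw)[upper.tri(pw)]
    sig <- !is.na(pw) & pw < alpha
  }
  letters <- .compact_letters(sig, means)

  structure(list(f_value = f_value, df = av$Df, p_value = p_value,
                 means = means, pairwise = pw, letters = letters,
                 alpha = alpha),
            class = "anova_compare")
}

#' @export
print.anova_compare <- function(x, ...) {
  cat(sprintf("<anova_compare> F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1L], x$df[2L], x$f_value, x$p_value))
  df <- data.frame(group = names(x$means), mean = as.numeric(x$means),
                   letters = x$letters[names(x$means)])
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

# compact letter display via insert-and-absorb on a significance matrix:
# start from one all-inclusive set, split it for every significant pair,
# absorb subsets, then label sets in order of their best (highest) mean
.compact_letters <- function(sig, means) {
  k <- length(means)
  nms <- names(means)
  sets <- list(seq_len(k))
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) for (b in seq_along(new_sets)) {
      if (a != b && keep[a] &&
          all(new_sets[[a]] %in% new_sets[[b]]) &&
          (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b))
        keep[a] <- FALSE
    }
    sets <- unique(new_sets[keep])
    sets <- sets[lengths(sets) > 0L]
  }
  ord <- order(vapply(sets, function(s) -max(means[s]), 1))
  sets <- sets[ord]
  out <- setNames(rep("", k), nms)
  for (a in seq_along(sets))
    out[sets[[a]]] <- paste0(out[sets[[a]]], letters[a])
  out
}
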