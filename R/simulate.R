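#' Describe a synthetic peak-area experiment
#'
#' Captures the structure of one of the three experimental designs the
#' synthetic-data generator emulates:
#' \describe{
#'   \item{`calibration_series`}{Spike levels 0-2 mg/L in nine steps,
#'     internal standards isolated in the ampoule; no cyclodextrin.}
#'   \item{`cd_dose_experiment`}{The four-phase retention experiment:
#'     control plus cyclodextrin doses, standards in the ampoule where
#'     dissolved hosts cannot reach them.}
#'   \item{`three_phase_cd_experiment`}{The conventional setup that fails:
#'     standards co-dissolved with the sample, inheriting their parent's
#'     binding constants, so treatment effects cancel out of the relative
#'     peak areas.}
#' }
#'
#' @param kind Design kind; see Details.
#' @param levels Spike levels in mg/L (calibration design).
#' @param doses Cyclodextrin doses in g/L (dose designs).
#' @param cds Cyclodextrin names to include.
#' @param replicates Replicate vials per condition (>= 1, default 3).
#' @param cv Multiplicative coefficient of variation of each peak area
#'   (lognormal; default 0.03, mid-range of typical HS-SPME repeatability).
#' @param response_factor Detector response in counts per mol/L on the
#'   fiber; arbitrary scale that cancels out of every relative peak area.
#' @param analyte_mg_L Analyte spike concentration for dose designs (1 mg/L).
#' @param istd_mg_L Internal-standard concentration in its own solution
#'   (10 mg/L).
#' @param noise_correlation Correlation of the lognormal noise between peak
#'   areas of the same vial (shared fiber/injection variability); 0 =
#'   independent (default).
#' @param seed Integer seed recorded in the design and used by
#'   [generate_peak_areas()].
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(kind = c("calibration_series",
                                       "cd_dose_experiment",
                                       "three_phase_cd_experiment"),
                              levels = seq(0, 2, by = 0.25),
                              doses = c(5, 25),
                              cds = c("alpha", "beta", "gamma"),
                              replicates = 3, cv = 0.03,
                              response_factor = 1e8,
                              analyte_mg_L = 1, istd_mg_L = 10,
                              noise_correlation = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (noise_correlation < 0 || noise_correlation > 1)
    stop("noise_correlation must be in [0, 1]", call. = FALSE)
  if (any(doses < 0) || any(levels < 0))
    stop("doses and levels must be >= 0", call. = FALSE)
  structure(list(kind = kind, levels = levels, doses = doses, cds = cds,
                 replicates = as.integer(replicates), cv = cv,
                 response_factor = response_factor,
                 analyte_mg_L = analyte_mg_L, istd_mg_L = istd_mg_L,
                 noise_correlation = noise_correlation, seed = seed),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> %s: %d replicate(s), CV = %g%%, seed = %s\n",
              x$kind, x$replicates, 100 * x$cv,
              if (is.null(x$seed)) "unset" else x$seed))
  if (x$kind == "calibration_series")
    cat("  levels (mg/L):", paste(x$levels, collapse = ", "), "\n")
  else
    cat("  cds:", paste(x$cds, collapse = ", "),
        "| doses (g/L):", paste(x$doses, collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic peak-area run table
#'
#' Stands in for the GC-MS instrument: phase concentrations come from the
#' equilibrium model, and each peak area is
#' `response_factor * C_f * exp(eps)` with
#' `eps ~ Normal(0, log(1 + CV)^2)`, i.e. multiplicative lognormal noise at
#' the requested coefficient of variation. Every peak area of a vial gets
#' its own noise draw (optionally correlated within the vial through
#' `noise_correlation`); an internal standard's area is drawn once per vial
#' and shared by all analytes normalized against it. Deterministic given the
#' seed.
#'
#' @param design An [experiment_design()] with its `seed` set (or pass
#'   `seed`).
#' @param compounds Named list of [compound()] objects (analytes with their
#'   `istd` reference, plus the labelled standards); default
#'   [default_compounds()].
#' @param vial A [vial_config()].
#' @param kb_table Binding constants data frame (`compound`, `cd`, `kb`),
#'   default [default_binding_constants()]; isotopologues inherit their
#'   parent's values. Ignored for the calibration design.
#' @param seed Overrides `design$seed`.
#' @return A data frame of class `run_table` with columns `vial_id`,
#'   `treatment`, `cd`, `dose_g_per_L`, `compound`, `replicate`,
#'   `area_analyte`, `area_standard` (plus `level_mg_per_L` for calibration
#'   designs), and attributes `seed`, `design`, `truth` (noise-free expected
#'   retention or calibration slope).
#' @export
generate_peak_areas <- function(design, compounds = default_compounds(),
                                vial = default_vial(), kb_table = NULL,
                                seed = design$seed) {
  stopifnot(inherits(design, "experiment_design"))
  if (is.null(seed))
    stop("seed must be set (in the design or as an argument)", call. = FALSE)
  if (is.null(names(compounds)) ||
      !all(vapply(compounds, inherits, TRUE, "compound")))
    stop("compounds must be a named list of compound objects", call. = FALSE)

  is_istd <- vapply(compounds, function(cp)
    !is.null(cp$isotopologue_of), TRUE)
  analytes <- names(compounds)[!is_istd]
  istds <- names(compounds)[is_istd]
  istd_of <- vapply(compounds[analytes], function(cp) {
    if (is.null(cp$istd)) NA_character_ else cp$istd
  }, "")
  bad <- analytes[is.na(istd_of) | !(istd_of %in% istds)]
  if (length(bad))
    stop("unknown or missing internal-standard reference for: ",
         paste(bad, collapse = ", "), call. = FALSE)

  if (design$kind == "three_phase_cd_experiment") {
    # the conventional-design experiment only ran compounds carrying their
    # own labelled analogue; a standard borrowed from another compound has
    # different binding constants and would not cancel
    own <- vapply(analytes, function(a)
      identical(compounds[[istd_of[[a]]]]$isotopologue_of, a), TRUE)
    analytes <- analytes[own]
    if (!length(analytes))
      stop("three-phase design needs analytes with their own isotopologue",
           call. = FALSE)
    istd_of <- istd_of[analytes]
    istds <- intersect(istds, unique(istd_of))
  }

  needs_kb <- design$kind != "calibration_series"
  if (needs_kb) {
    if (is.null(kb_table)) kb_table <- default_binding_constants()
    unknown <- setdiff(design$cds, unique(kb_table$cd))
    if (length(unknown))
      stop("no binding constants for cyclodextrin(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    compounds <- .apply_kb(compounds, kb_table)
  }

  mode <- if (design$kind == "three_phase_cd_experiment") "three_phase"
          else "four_phase_short_extraction"
  # the ampoule label marks where the standard's amount starts; in
  # three-phase mode the solver pools the liquids (co-dissolution)
  istd_phase <- "ampoule"

  set_conc <- function(cp, mg_L, phase) {
    compound(cp$name, molar_mass = cp$molar_mass, K1 = cp$K1, K2 = cp$K2,
             K3 = cp$K3, kb = cp$kb, conc_mg_L = mg_L, phase = phase,
             isotopologue_of = cp$isotopologue_of, istd = cp$istd,
             quant_ions = cp$quant_ions)
  }

  conditions <- switch(design$kind,
    calibration_series = data.frame(
      treatment = sprintf("cal-%g", design$levels),
      cd = NA_character_, dose_g_per_L = NA_real_,
      level_mg_per_L = design$levels, stringsAsFactors = FALSE),
    {
      grid <- expand.grid(dose_g_per_L = design$doses, cd = design$cds,
                          stringsAsFactors = FALSE)
      rbind(data.frame(treatment = "control", cd = "none",
                       dose_g_per_L = 0, level_mg_per_L = NA_real_,
                       stringsAsFactors = FALSE),
            data.frame(treatment = sprintf("%s-%g", grid$cd,
                                           grid$dose_g_per_L),
                       cd = grid$cd, dose_g_per_L = grid$dose_g_per_L,
                       level_mg_per_L = NA_real_, stringsAsFactors = FALSE))
    })

  sigma <- log(1 + design$cv)
  rho <- design$noise_correlation
  set.seed(seed)

  all_names <- c(analytes, istds)
  rows <- vector("list", nrow(conditions))
  truth <- vector("list", nrow(conditions))
  control_cf <- NULL
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    lev <- if (design$kind == "calibration_series") cond$level_mg_per_L
           else design$analyte_mg_L
    cps <- c(
      lapply(compounds[analytes], set_conc, mg_L = lev, phase = "sample"),
      lapply(compounds[istds], set_conc, mg_L = design$istd_mg_L,
             phase = istd_phase)
    )
    cd <- if (!needs_kb || cond$treatment == "control") NULL
          else cd_species(cond$cd, cond$dose_g_per_L)
    eq <- solve_equilibrium(cps, vial, cd = cd, mode = mode)
    cf <- setNames(eq$C_f, eq$compound)
    if (needs_kb && cond$treatment == "control") control_cf <- cf
    truth[[ci]] <- cf

    cond_rows <- vector("list", design$replicates)
    for (r in seq_len(design$replicates)) {
      z_vial <- rnorm(1, 0, sigma)
      z_comp <- rnorm(length(all_names), 0, sigma)
      eps <- setNames(sqrt(rho) * z_vial + sqrt(1 - rho) * z_comp,
                      all_names)
      area <- design$response_factor * cf[all_names] * exp(eps)
      cond_rows[[r]] <- data.frame(
        vial_id = sprintf("%s-r%d", cond$treatment, r),
        treatment = cond$treatment, cd = cond$cd,
        dose_g_per_L = cond$dose_g_per_L,
        level_mg_per_L = cond$level_mg_per_L,
        compound = analytes, replicate = r,
        area_analyte = as.numeric(area[analytes]),
        area_standard = as.numeric(area[istd_of]),
        stringsAsFactors = FALSE)
    }
    rows[[ci]] <- do.call(rbind, cond_rows)
  }
  out <- do.call(rbind, rows)
  if (design$kind != "calibration_series") out$level_mg_per_L <- NULL

  truth_df <- if (needs_kb) {
    do.call(rbind, lapply(seq_len(nrow(conditions)), function(ci)
      data.frame(treatment = conditions$treatment[ci], compound = analytes,
                 percent_of_control =
                   100 * truth[[ci]][analytes] / control_cf[analytes],
                 stringsAsFactors = FALSE, row.names = NULL)))
  } else {
    # noise-free RPA per mg/L at equilibrium (calibration slope truth)
    top <- truth[[which.max(conditions$level_mg_per_L)]]
    data.frame(compound = analytes,
               slope = as.numeric(top[analytes] / top[istd_of]) /
                 max(conditions$level_mg_per_L),
               stringsAsFactors = FALSE)
  }
  structure(out, class = c("run_table", "data.frame"), seed = seed,
            design = design, truth = truth_df)
}

#' @export
print.run_table <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf("<run_table> %s: %d records, seed = %s\n",
              if (!is.null(d)) d$kind else "run table", nrow(x),
              if (is.null(attr(x, "seed"))) "unknown" else attr(x, "seed")))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE, ...)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}
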