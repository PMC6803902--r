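#' Read a structured model configuration
#'
#' Reads a YAML configuration describing the vial geometry, the compound
#' table (molecular formula or molar mass, partition constants, internal
#' standard assignments, quantifier ions, optional binding constants) and
#' the cyclodextrin hosts, and builds the corresponding model objects.
#'
#' @param path Path to a YAML file; defaults to the configuration bundled
#'   with the package (eight volatile phenols, three deuterated standards,
#'   the 20 mL / 6 mL / 0.5 mL vial).
#' @return List with elements `vial` ([vial_config()]), `compounds` (named
#'   list of [compound()]), `cds` (named list of cyclodextrin descriptors
#'   with `molar_mass`), and `raw` (the parsed YAML).
#' @export
read_config <- function(path = system.file("extdata",
                                           "default_config.yaml",
                                           package = "cdretain")) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (section in c("vial", "compounds"))
    if (is.null(raw[[section]]))
      stop("config is missing the '", section, "' section", call. = FALSE)

  vial <- do.call(vial_config, lapply(raw$vial, as.numeric))

  build <- function(entry, i, isotopologue_of = NULL, parent = NULL) {
    if (is.null(entry$name))
      stop("compound entry ", i, " has no 'name'", call. = FALSE)
    args <- list(
      name = entry$name, formula = entry$formula,
      molar_mass = entry$molar_mass,
      K1 = if (!is.null(entry$K1)) as.numeric(entry$K1) else
        if (!is.null(parent)) parent$K1 else
          stop("compound '", entry$name, "' has no K1", call. = FALSE),
      kb = if (!is.null(entry$kb)) unlist(entry$kb) else
        if (!is.null(parent)) parent$kb else numeric(),
      isotopologue_of = isotopologue_of,
      istd = entry$istd,
      quant_ions = if (!is.null(entry$quant_ions))
        as.integer(unlist(entry$quant_ions)) else NULL
    )
    K2 <- if (!is.null(entry$K2)) as.numeric(entry$K2) else
      if (!is.null(parent)) parent$K2 else NULL
    K3 <- if (!is.null(entry$K3)) as.numeric(entry$K3) else
      if (!is.null(parent)) parent$K3 else NULL
    if (!is.null(K2)) args$K2 <- K2
    if (!is.null(K3)) args$K3 <- K3
    do.call(compound, args)
  }

  compounds <- list()
  for (i in seq_along(raw$compounds)) {
    cp <- build(raw$compounds[[i]], i)
    compounds[[cp$name]] <- cp
  }
  for (i in seq_along(raw$isotopologues)) {
    entry <- raw$isotopologues[[i]]
    parent <- compounds[[entry$parent]]
    if (is.null(parent))
      stop("isotopologue '", entry$name, "' references unknown parent '",
           entry$parent, "'; known compounds: ",
           paste(names(compounds), collapse = ", "), call. = FALSE)
    cp <- build(entry, i, isotopologue_of = entry$parent, parent = parent)
    compounds[[cp$name]] <- cp
  }

  cds <- list()
  for (entry in raw$cyclodextrins) {
    mm <- if (!is.null(entry$molar_mass)) as.numeric(entry$molar_mass)
          else molar_mass_from_formula(entry$formula)
    cds[[entry$name]] <- list(name = entry$name, molar_mass = mm,
                              formula = entry$formula)
  }

  list(vial = vial, compounds = compounds, cds = cds, raw = raw)
}

.default_config <- function() {
  if (is.null(.cdretain_cache$config))
    .cdretain_cache$config <- read_config()
  .cdretain_cache$config
}

#' Bundled default model configuration
#'
#' `default_compounds()` returns the eight volatile phenols (guaiacol,
#' 4-methylguaiacol, 4-ethylphenol, 4-ethylguaiacol, o-, m-, p-cresol,
#' eugenol) and their three deuterated standards with the bundled partition
#' constants; `default_vial()` the 20 mL vial with 6 mL sample and 0.5 mL
#' ampoule; `default_cds()` the alpha/beta/gamma cyclodextrin descriptors.
#'
#' @return See Description; all derived from the bundled YAML configuration
#'   (see [read_config()]).
#' @export
default_compounds <- function() .default_config()$compounds

#' @rdname default_compounds
#' @export
default_vial <- function() .default_config()$vial

#' @rdname default_compounds
#' @export
default_cds <- function() .default_config()$cds

.run_table_columns <- c("vial_id", "treatment", "compound", "replicate",
                        "area_analyte", "area_standard")

#' Read and write peak-area run tables
#'
#' Run tables are plain CSV (RFC 4180, header row, UTF-8) with columns
#' `vial_id`, `treatment`, `cd`, `dose_g_per_L`, `compound`, `replicate`,
#' `area_analyte`, `area_standard` (and `level_mg_per_L` for calibration
#' series). `write_run_table()` prints numeric columns with 17 significant
#' digits so a write/read round trip reproduces the values exactly, and can
#' write a JSON sidecar with the generating seed and design.
#'
#' @param path CSV file path.
#' @param x A run table data frame.
#' @param metadata Write `<path>.json` with seed/design metadata when the
#'   run table carries them (default `TRUE`).
#' @return `read_run_table()`: a `run_table` data frame.
#'   `write_run_table()`: `path`, invisibly.
#' @export
read_run_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, .run_table_columns, paste0("run table '", path, "'"))
  for (col in c("area_analyte", "area_standard")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop("non-numeric or missing ", col, " in '", path, "' at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  neg <- which(df$area_standard <= 0)
  if (length(neg))
    stop("non-positive area_standard in '", path, "' at row(s) ",
         paste(utils::head(neg, 5), collapse = ", "), call. = FALSE)
  meta_path <- paste0(path, ".json")
  attrs <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  structure(df, class = c("run_table", "data.frame"),
            seed = attrs$seed)
}

#' @rdname read_run_table
#' @export
write_run_table <- function(x, path, metadata = TRUE) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- NA
    out
  })
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  if (metadata && (!is.null(attr(x, "seed")) || !is.null(attr(x, "design")))) {
    meta <- list(seed = attr(x, "seed"),
                 design = unclass(attr(x, "design")),
                 package_version = as.character(utils::packageVersion("cdretain")))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a calibration table
#'
#' CSV with columns `compound`, `level_mg_per_L`, `replicate`, `rpa`.
#'
#' @param path CSV file path.
#' @return Data frame ready for [calibrate()].
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("compound", "level_mg_per_L", "replicate", "rpa"),
                 paste0("calibration table '", path, "'"))
  df
}

#' Simulate, summarize and re-fit the full retention study
#'
#' Chains the whole pipeline with the bundled configuration: derives the
#' model-consistent binding constants from the reference retention table,
#' simulates the triplicate cyclodextrin dose experiment (all three hosts at
#' 5 and 25 g/L plus control) with multiplicative peak-area noise,
#' recomputes retention-of-control from the simulated run table, and
#' re-estimates each binding constant from the simulated 25 g/L
#' percentages. The comparison against the reference percentages is exact in
#' expectation at 25 g/L (the inversion dose) and a genuine model
#' extrapolation at 5 g/L.
#'
#' @param seed Integer seed for the simulated peak areas.
#' @param cv Peak-area coefficient of variation (default 0.03).
#' @param replicates Replicates per treatment (default 3).
#' @param out_dir Optional directory; when given, the simulated run table
#'   (CSV + JSON sidecar) and the comparison table are written there.
#' @return An object of class `retention_study`: list with the simulated
#'   `runs`, the `retention` summary, the per-cell `comparison` data frame
#'   (simulated vs reference percent), the refitted constants `kb_refit`,
#'   and `overall` percentages by treatment.
#' @export
reproduce_retention_study <- function(seed = 1, cv = 0.03, replicates = 3,
                                      out_dir = NULL) {
  kb <- default_binding_constants()
  design <- experiment_design("cd_dose_experiment", doses = c(5, 25),
                              cds = c("alpha", "beta", "gamma"),
                              replicates = replicates, cv = cv, seed = seed)
  runs <- generate_peak_areas(design)
  ret <- retention_table(runs)

  ref <- cd_retention_reference()
  ref$treatment <- ifelse(ref$treatment == "control", "control",
                          ref$treatment)
  comparison <- merge(
    data.frame(compound = ret$compound, treatment = ret$treatment,
               percent_simulated = ret$percent_of_control,
               stringsAsFactors = FALSE),
    data.frame(compound = ref$compound, treatment = ref$treatment,
               percent_reference = ref$percent, stringsAsFactors = FALSE),
    by = c("compound", "treatment"))
  comparison <- comparison[comparison$treatment != "control", , drop = FALSE]
  comparison <- comparison[order(comparison$treatment, comparison$compound), ]
  rownames(comparison) <- NULL

  compounds <- default_compounds()
  trt25 <- ret[ret$dose_g_per_L == 25 & ret$treatment != "control", ,
               drop = FALSE]
  kb_refit <- do.call(rbind, lapply(seq_len(nrow(trt25)), function(i) {
    fit <- suppressWarnings(fit_binding_constant(
      trt25$percent_of_control[i], dose = 25,
      compound = compounds[[trt25$compound[i]]], cd = trt25$cd[i]))
    data.frame(compound = fit$compound, cd = fit$cd, kb_refit = fit$kb,
               stringsAsFactors = FALSE)
  }))
  kb_refit <- merge(kb_refit, kb[c("compound", "cd", "kb")],
                    by = c("compound", "cd"))
  names(kb_refit)[names(kb_refit) == "kb"] <- "kb_true"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_run_table(runs, file.path(out_dir, "simulated_runs.csv"))
    write.csv(comparison, file.path(out_dir, "retention_comparison.csv"),
              row.names = FALSE)
  }

  structure(list(runs = runs, retention = ret, comparison = comparison,
                 kb_refit = kb_refit, overall = attr(ret, "overall"),
                 seed = seed, cv = cv),
            class = "retention_study")
}

#' @export
print.retention_study <- function(x, digits = 4, ...) {
  cat(sprintf("<retention_study> seed = %d, CV = %g%%\n", x$seed,
              100 * x$cv))
  cat("\nsimulated vs reference percent of control:\n")
  cmp <- x$comparison
  cmp$percent_simulated <- signif(cmp$percent_simulated, digits)
  print.data.frame(cmp, row.names = FALSE)
  cat("\noverall mean percent by treatment (simulated):\n")
  ov <- x$overall
  ov$overall_mean_percent <- signif(ov$overall_mean_percent, digits)
  print.data.frame(ov, row.names = FALSE)
  invisible(x)
}
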