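# IUPAC 2021 standard atomic weights, abridged; D = deuterium (2H)
.atomic_masses <- c(
  C = 12.011, H = 1.008, D = 2.014, O = 15.999, N = 14.007, S = 32.06,
  P = 30.974, Cl = 35.45, Na = 22.990, K = 39.098
)

#' Molar mass from a molecular formula
#'
#' Computes the molar mass of a compound from a Hill-style molecular formula
#' such as `"C7H8O2"` (guaiacol). Deuterium is written `D`, so d3-guaiacol is
#' `"C7H5D3O2"`.
#'
#' @param formula Character vector of molecular formulas.
#' @return Numeric vector of molar masses in g/mol.
#' @examples
#' molar_mass_from_formula("C7H8O2")     # guaiacol, 124.14
#' molar_mass_from_formula("C42H70O35")  # beta-cyclodextrin, 1134.98
#' @export
molar_mass_from_formula <- function(formula) {
  stopifnot(is.character(formula))
  vapply(formula, function(f) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    tokens <- regmatches(f, list(m))[[1]]
    if (length(tokens) == 0L || paste(tokens, collapse = "") != f)
      stop("cannot parse molecular formula: '", f, "'", call. = FALSE)
    total <- 0
    for (tok in tokens) {
      el <- sub("[0-9]*$", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.numeric(n) else 1
      if (!el %in% names(.atomic_masses))
        stop("unknown element '", el, "' in formula '", f, "'", call. = FALSE)
      total <- total + n * .atomic_masses[[el]]
    }
    total
  }, numeric(1), USE.NAMES = length(formula) > 1L)
}

#' Convert between mass and molar concentration
#'
#' `convert_mass_conc()` converts mg/L to mol/L; `convert_molar_conc()` is the
#' inverse (mol/L to mg/L). All internal model computation uses mol/L; mass
#' units appear only at the interface, as in the source run tables.
#'
#' @param value Concentration (mg/L for `convert_mass_conc`, mol/L for
#'   `convert_molar_conc`).
#' @param molar_mass Molar mass in g/mol; must be positive.
#' @return Numeric vector of converted concentrations.
#' @examples
#' convert_mass_conc(124.14, 124.14)  # 1 mmol/L
#' @export
convert_mass_conc <- function(value, molar_mass) {
  if (any(!is.finite(molar_mass)) || any(molar_mass <= 0))
    stop("molar_mass must be positive", call. = FALSE)
  value / (1000 * molar_mass)
}

#' @rdname convert_mass_conc
#' @export
convert_molar_conc <- function(value, molar_mass) {
  if (any(!is.finite(molar_mass)) || any(molar_mass <= 0))
    stop("molar_mass must be positive", call. = FALSE)
  value * 1000 * molar_mass
}
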