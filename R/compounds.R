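#' Define a volatile compound and its partition/binding parameters
#'
#' A compound carries the physico-chemical parameters the multi-phase
#' equilibrium model needs: a liquid/gas partition (Henry) constant `K1 =
#' C_s/C_h` for the sample matrix, a gas/fiber distribution constant `K2 =
#' C_h/C_f` for the SPME coating, a liquid/gas constant `K3 = C_i/C_h` for the
#' internal-standard liquid (defaulting to `K1` when both liquids are the same
#' model-wine matrix), and 1:1 cyclodextrin binding constants `kb` in L/mol.
#'
#' @param name Compound identifier.
#' @param formula Molecular formula (used when `molar_mass` is missing).
#' @param molar_mass Molar mass in g/mol; derived from `formula` if `NULL`.
#' @param K1 Dimensionless liquid/gas partition constant of the sample phase
#'   (concentration in liquid over concentration in headspace).
#' @param K2 Dimensionless gas/fiber constant (headspace over fiber); small
#'   values mean strong fiber enrichment. Default `1e-5`.
#' @param K3 Dimensionless liquid/gas constant of the internal-standard
#'   liquid; defaults to `K1` (same matrix).
#' @param kb Named numeric vector of 1:1 binding constants (L/mol), one per
#'   cyclodextrin name, e.g. `c(beta = 500)`. Missing hosts bind with 0.
#' @param conc_mg_L Initial concentration in the compound's starting phase,
#'   mg/L. Stored also as `C0` in mol/L.
#' @param phase Phase the compound starts in: `"sample"` or `"ampoule"`.
#' @param isotopologue_of Name of the unlabelled parent, or `NULL`.
#' @param istd Name of the isotopically labelled standard this compound is
#'   normalized against, or `NULL` (standards themselves have none).
#' @param quant_ions Optional integer m/z values (metadata only; never used in
#'   computation).
#' @return An object of class `compound`.
#' @seealso [isotopologue()], [default_compounds()], [solve_equilibrium()]
#' @examples
#' guaiacol <- compound("guaiacol", formula = "C7H8O2", K1 = 2.2e4,
#'                      conc_mg_L = 1)
#' @export
compound <- function(name, formula = NULL, molar_mass = NULL, K1,
                     K2 = 1e-5, K3 = K1, kb = numeric(),
                     conc_mg_L = 0, phase = c("sample", "ampoule"),
                     isotopologue_of = NULL, istd = NULL,
                     quant_ions = NULL) {
  phase <- match.arg(phase)
  if (is.null(molar_mass)) {
    if (is.null(formula))
      stop("supply either molar_mass or formula for '", name, "'",
           call. = FALSE)
    molar_mass <- molar_mass_from_formula(formula)
  }
  if (!is.numeric(molar_mass) || molar_mass <= 0)
    stop("molar_mass must be positive", call. = FALSE)
  if (K1 <= 0 || K2 <= 0 || K3 <= 0)
    stop("K1, K2 and K3 must be positive for '", name, "'", call. = FALSE)
  kb <- unlist(kb)
  if (length(kb) && (is.null(names(kb)) || any(!nzchar(names(kb)))))
    stop("kb must be a named vector (cyclodextrin name -> L/mol)",
         call. = FALSE)
  if (any(kb < 0)) stop("binding constants must be >= 0", call. = FALSE)
  if (conc_mg_L < 0) stop("conc_mg_L must be >= 0", call. = FALSE)
  structure(list(
    name = name, formula = formula, molar_mass = molar_mass,
    K1 = K1, K2 = K2, K3 = K3, kb = kb,
    conc_mg_L = conc_mg_L, C0 = convert_mass_conc(conc_mg_L, molar_mass),
    phase = phase, isotopologue_of = isotopologue_of, istd = istd,
    quant_ions = quant_ions
  ), class = "compound")
}

#' Derive an isotopically labelled analogue of a compound
#'
#' Deuterated standards co-elute and partition essentially like their parent,
#' so the isotopologue inherits the parent's `K1`, `K2`, `K3` and binding
#' constants unless explicitly overridden; only the molar mass (and m/z ions)
#' differ.
#'
#' @param parent A [compound()].
#' @param name Identifier of the labelled analogue.
#' @param formula,molar_mass Molar mass of the labelled form.
#' @param ... Overrides passed to [compound()] (e.g. a different `K1`).
#' @return An object of class `compound` with `isotopologue_of` set.
#' @export
isotopologue <- function(parent, name, formula = NULL, molar_mass = NULL,
                         ...) {
  stopifnot(inherits(parent, "compound"))
  args <- list(name = name, formula = formula, molar_mass = molar_mass,
               K1 = parent$K1, K2 = parent$K2, K3 = parent$K3,
               kb = parent$kb, isotopologue_of = parent$name)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(compound, args)
}

#' @export
print.compound <- function(x, ...) {
  cat(sprintf("<compound> %s (%.2f g/mol)\n", x$name, x$molar_mass))
  cat(sprintf("  K1 = %.4g  K2 = %.4g  K3 = %.4g  phase = %s  C0 = %.4g mol/L\n",
              x$K1, x$K2, x$K3, x$phase, x$C0))
  if (length(x$kb))
    cat("  kb [L/mol]:", paste(sprintf("%s = %.4g", names(x$kb), x$kb),
                               collapse = ", "), "\n")
  if (!is.null(x$isotopologue_of))
    cat("  isotopologue of", x$isotopologue_of, "\n")
  invisible(x)
}

#' Headspace vial geometry
#'
#' Describes the four-phase extraction vessel: total vial volume, sample
#' liquid, internal-standard liquid (glass ampoule inserted in the vial, its
#' glass wall volume treated as zero), and the SPME fiber coating. The
#' headspace volume is derived as `V_total - V_s - V_i`, and the phase ratios
#' `beta_s = V_h/V_s` and `beta_i = V_h/V_i` are precomputed.
#'
#' @param V_total Total vial volume, mL (default 20).
#' @param V_s Sample liquid volume, mL (default 6).
#' @param V_i Internal-standard (ampoule) liquid volume, mL (default 0.5).
#'   May be 0 for a conventional three-phase setup.
#' @param V_f Fiber coating volume, mL (default 6.6e-4).
#' @return An object of class `vial_config` with derived `V_h`, `beta_s`,
#'   `beta_i`.
#' @examples
#' v <- vial_config()     # 20 mL vial, 6 mL sample, 0.5 mL ampoule
#' v$beta_i               # 27
#' v$beta_s               # 2.25
#' @export
vial_config <- function(V_total = 20, V_s = 6, V_i = 0.5, V_f = 6.6e-4) {
  vols <- c(V_total = V_total, V_s = V_s, V_i = V_i, V_f = V_f)
  if (any(!is.finite(vols)) || any(vols < 0))
    stop("all volumes must be finite and >= 0", call. = FALSE)
  V_h <- V_total - V_s - V_i
  if (V_h <= 0)
    stop("headspace volume V_total - V_s - V_i must be positive",
         call. = FALSE)
  if (V_s <= 0) stop("sample volume V_s must be positive", call. = FALSE)
  structure(list(
    V_total = V_total, V_s = V_s, V_i = V_i, V_f = V_f, V_h = V_h,
    beta_s = phase_ratio(V_h, V_s),
    beta_i = if (V_i > 0) phase_ratio(V_h, V_i) else NA_real_
  ), class = "vial_config")
}

#' @export
print.vial_config <- function(x, ...) {
  cat(sprintf(
    "<vial_config> V_total = %g mL, V_s = %g, V_i = %g, V_f = %g, V_h = %g\n",
    x$V_total, x$V_s, x$V_i, x$V_f, x$V_h))
  cat(sprintf("  beta_s = %.4g, beta_i = %.4g\n", x$beta_s, x$beta_i))
  invisible(x)
}

#' Headspace-to-liquid phase ratio
#'
#' The phase ratio `beta` is the headspace volume divided by a liquid phase
#' volume. Together with the Henry constant `K` it determines the headspace
#' concentration at equilibrium, `C_h = C_0/(K + beta)`.
#'
#' @param headspace_volume Headspace volume, mL (>= 0).
#' @param liquid_volume Liquid phase volume, mL (> 0).
#' @return Dimensionless phase ratio.
#' @examples
#' phase_ratio(13.5, 0.5)  # 27
#' phase_ratio(13.5, 6)    # 2.25
#' @export
phase_ratio <- function(headspace_volume, liquid_volume) {
  if (any(!is.finite(liquid_volume)) || any(liquid_volume <= 0))
    stop("liquid_volume must be positive", call. = FALSE)
  if (any(!is.finite(headspace_volume)) || any(headspace_volume < 0))
    stop("headspace_volume must be >= 0", call. = FALSE)
  headspace_volume / liquid_volume
}

#' Equilibrium headspace concentration of a two-phase system
#'
#' For a volatile solute partitioning between one liquid phase and the
#' headspace, the equilibrium headspace concentration is
#' `C_h = C_0 / (K + beta)` where `K` is the dimensionless liquid/gas Henry
#' constant and `beta` the headspace/liquid phase ratio. For strongly retained
#' solutes (`K >> beta`, e.g. guaiacol with `K ~ 2.2e4`), `C_h` is nearly
#' insensitive to `beta` — the argument for why the internal-standard volume
#' (phase ratios 6 to 139) barely shifts its headspace level.
#'
#' @param C0 Initial liquid concentration, mol/L.
#' @param K Dimensionless liquid/gas partition constant (>= 0).
#' @param beta Headspace/liquid phase ratio (>= 0; `K + beta` must be > 0).
#' @return Headspace concentration, mol/L.
#' @examples
#' headspace_fraction(1, 2.2e4, 2.25)
#' @export
headspace_fraction <- function(C0, K, beta) {
  if (any(K < 0)) stop("K must be >= 0", call. = FALSE)
  if (any(beta < 0)) stop("beta must be >= 0", call. = FALSE)
  if (any(K + beta <= 0)) stop("K + beta must be positive", call. = FALSE)
  C0 / (K + beta)
}

#' Define a cyclodextrin host
#'
#' Alpha-, beta- and gamma-cyclodextrin (6, 7 and 8 glucose units) have
#' built-in molar masses computed from their molecular formulas; custom hosts
#' need an explicit `molar_mass` or `formula`. The dose in g/L of sample phase
#' is converted to a total molar concentration.
#'
#' @param name `"alpha"`, `"beta"`, `"gamma"`, or a custom name.
#' @param dose Dose in g per litre of sample phase (>= 0).
#' @param molar_mass Molar mass in g/mol (optional for the three standard
#'   cyclodextrins).
#' @param formula Molecular formula, used when `molar_mass` is `NULL`.
#' @return An object of class `cd_species` with derived `total_molar` (mol/L).
#' @examples
#' cd_species("beta", dose = 25)  # 2.203e-2 mol/L
#' @export
cd_species <- function(name, dose, molar_mass = NULL, formula = NULL) {
  if (dose < 0) stop("dose must be >= 0", call. = FALSE)
  if (is.null(molar_mass)) {
    if (is.null(formula))
      formula <- switch(name,
        alpha = "C36H60O30", beta = "C42H70O35", gamma = "C48H80O40",
        stop("unknown cyclodextrin '", name,
             "'; supply molar_mass or formula", call. = FALSE))
    molar_mass <- molar_mass_from_formula(formula)
  }
  if (molar_mass <= 0) stop("molar_mass must be positive", call. = FALSE)
  structure(list(name = name, molar_mass = molar_mass, dose = dose,
                 total_molar = dose / molar_mass),
            class = "cd_species")
}

#' @export
print.cd_species <- function(x, ...) {
  cat(sprintf("<cd_species> %s-CD: %g g/L = %.4g mol/L (M = %.2f g/mol)\n",
              x$name, x$dose, x$total_molar, x$molar_mass))
  invisible(x)
}
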