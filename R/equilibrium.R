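#' Solve the multi-phase HS-SPME partition equilibrium
#'
#' Distributes each compound over the phases of a headspace vial at
#' equilibrium, by mass balance under Henry-law partitioning, optionally with
#' competitive 1:1 cyclodextrin complexation in the sample phase.
#'
#' Three modes are supported:
#' \describe{
#'   \item{`four_phase_equilibrium`}{Full equilibrium of sample, headspace,
#'     fiber and internal-standard (ampoule) liquid:
#'     `C_0 V_s = C_s V_s + C_i V_i + C_h V_h + C_f V_f`. The closed form is
#'     `C_h = n_0 / (K1 V_s (1 + kb h) + V_h + V_f/K2 + K3 V_i)` with `n_0`
#'     the compound's initial molar amount and `h` the free-host
#'     concentration.}
#'   \item{`four_phase_short_extraction`}{The working assumption of a short
#'     extraction: no transfer across the ampoule wall. Compounds starting in
#'     the sample never reach the ampoule liquid (`C_i = 0`), and the
#'     internal standard never reaches the sample (`C_s = 0`), so its
#'     headspace level is set by `K3` and `beta_i` alone — and cyclodextrins,
#'     confined to the sample, cannot touch it.}
#'   \item{`three_phase`}{Conventional setup: the standard is co-dissolved
#'     with the sample (liquid volume `V_s + V_i`), so dissolved
#'     cyclodextrins bind analytes and standards alike.}
#' }
#'
#' With a cyclodextrin present, each guest gains a sample-phase sink
#' `C_x = kb * h * C_s` (1:1 complex, non-volatile). Total bound host is
#' strictly increasing in free host `h`, so `h` is found by bisection of the
#' host mass balance on `[0, total_molar]` to a relative tolerance of 1e-12.
#'
#' @param compounds A [compound()] or list of compounds, each carrying its
#'   initial concentration `C0` (mol/L, relative to its starting phase) via
#'   `conc_mg_L`.
#' @param vial A [vial_config()].
#' @param cd Optional [cd_species()]; `NULL` for no host.
#' @param mode Extraction mode; see Details.
#' @param tol Relative bisection tolerance on the free-host concentration.
#' @param max_iter Maximum bisection iterations.
#' @return An object of class `equilibrium_state`: a data frame with one row
#'   per compound (`C0`, `n0`, `C_s`, `C_h`, `C_i`, `C_f`, `C_x`, `residual`)
#'   and attributes `free_host`, `total_host`, `host_residual`, `mode`,
#'   `vial`, `cd`, `iterations`.
#' @examples
#' g <- compound("guaiacol", formula = "C7H8O2", K1 = 2.2e4, conc_mg_L = 1)
#' eq <- solve_equilibrium(g, vial_config())
#' eq$C_h
#' @export
solve_equilibrium <- function(compounds, vial, cd = NULL,
                              mode = c("four_phase_equilibrium",
                                       "four_phase_short_extraction",
                                       "three_phase"),
                              tol = 1e-12, max_iter = 200L) {
  mode <- match.arg(mode)
  stopifnot(inherits(vial, "vial_config"))
  if (inherits(compounds, "compound")) compounds <- list(compounds)
  if (!length(compounds) || !all(vapply(compounds, inherits, TRUE, "compound")))
    stop("compounds must be compound objects", call. = FALSE)
  if (!is.null(cd) && !inherits(cd, "cd_species"))
    stop("cd must be a cd_species or NULL", call. = FALSE)

  nm <- vapply(compounds, `[[`, "", "name")
  K1 <- vapply(compounds, `[[`, 1, "K1")
  K2 <- vapply(compounds, `[[`, 1, "K2")
  K3 <- vapply(compounds, `[[`, 1, "K3")
  C0 <- vapply(compounds, `[[`, 1, "C0")
  ph <- vapply(compounds, `[[`, "", "phase")
  kb <- if (is.null(cd)) rep(0, length(nm)) else
    vapply(compounds, function(cp) {
      v <- unname(cp$kb[cd$name])
      if (length(v) != 1L || is.na(v)) 0 else v  # unlisted hosts bind with 0
    }, 1)

  in_ampoule <- ph == "ampoule"
  # initial molar amount; in three-phase mode the ampoule solution is simply
  # poured into the sample, so amounts are unchanged but the liquid is pooled
  n0 <- C0 * ifelse(in_ampoule, vial$V_i, vial$V_s)
  V_L <- if (mode == "three_phase") vial$V_s + vial$V_i else vial$V_s
  fib <- vial$V_f / K2

  # per-compound denominator D(z) with z = kb*h: n0 = C_h * D
  # sample-liquid capacity, ampoule capacity and binding sink depend on mode
  samp_cap <- switch(mode,
    three_phase = K1 * V_L,
    four_phase_equilibrium = K1 * vial$V_s,
    four_phase_short_extraction = ifelse(in_ampoule, 0, K1 * vial$V_s))
  amp_cap <- switch(mode,
    three_phase = rep(0, length(nm)),
    four_phase_equilibrium = K3 * vial$V_i,
    four_phase_short_extraction = ifelse(in_ampoule, K3 * vial$V_i, 0))

  C_h_of <- function(h) n0 / (samp_cap * (1 + kb * h) + vial$V_h + fib + amp_cap)

  total_host <- if (is.null(cd)) 0 else {
    # host dosed per litre of sample, diluted if liquids are pooled
    cd$total_molar * vial$V_s / V_L
  }

  iterations <- 0L
  h <- total_host
  if (total_host > 0 && any(kb > 0 & n0 > 0)) {
    # host balance: f(h) = h + sum_c kb_c h C_s_c(h) - H_tot, increasing in h
    bound <- function(h) {
      C_h <- C_h_of(h)
      C_s <- (samp_cap / V_L) * C_h  # = K1*C_h where the sample term exists
      sum(kb * h * C_s)
    }
    f <- function(h) h + bound(h) - total_host
    lo <- 0; hi <- total_host
    while ((hi - lo) > tol * total_host && iterations < max_iter) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      iterations <- iterations + 1L
    }
    if ((hi - lo) > tol * total_host)
      stop("free-host bisection did not converge: interval [", lo, ", ", hi,
           "] after ", iterations, " iterations", call. = FALSE)
    h <- (lo + hi) / 2
  }

  C_h <- C_h_of(h)
  C_s <- (samp_cap / V_L) * C_h
  C_i <- ifelse(amp_cap > 0, K3 * C_h, 0)
  C_f <- C_h / K2
  C_x <- kb * h * C_s

  V_i_eff <- if (mode == "three_phase") 0 else vial$V_i
  recovered <- C_s * V_L + C_x * V_L + C_h * vial$V_h + C_i * V_i_eff +
    C_f * vial$V_f
  residual <- ifelse(n0 > 0, abs(n0 - recovered) / n0, 0)

  host_residual <- if (total_host > 0)
    abs(h + sum(C_x) - total_host) / total_host else 0

  out <- data.frame(
    compound = nm, phase0 = ph, C0 = C0, n0 = n0,
    C_s = C_s, C_h = C_h, C_i = C_i, C_f = C_f, C_x = C_x,
    residual = residual, row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, class = c("equilibrium_state", "data.frame"),
            free_host = h, total_host = total_host,
            host_residual = host_residual, mode = mode, vial = vial, cd = cd,
            iterations = iterations)
}

#' @export
print.equilibrium_state <- function(x, digits = 4, ...) {
  cd <- attr(x, "cd")
  cat("<equilibrium_state> mode:", attr(x, "mode"),
      if (!is.null(cd)) sprintf("| %s-CD %g g/L", cd$name, cd$dose) else
        "| no cyclodextrin", "\n")
  df <- as.data.frame(x)
  df[-(1:2)] <- lapply(df[-(1:2)], signif, digits = digits)
  print.data.frame(df, row.names = FALSE, ...)
  if (attr(x, "total_host") > 0)
    cat(sprintf("free host: %.6g mol/L of %.6g total (%d bisection steps)\n",
                attr(x, "free_host"), attr(x, "total_host"),
                attr(x, "iterations")))
  invisible(x)
}

#' @export
summary.equilibrium_state <- function(object, ...) {
  tot <- object$C_s + object$C_x  # per litre of liquid
  v <- attr(object, "vial")
  mode <- attr(object, "mode")
  V_L <- if (mode == "three_phase") v$V_s + v$V_i else v$V_s
  frac <- function(amount) ifelse(object$n0 > 0, amount / object$n0, NA)
  out <- data.frame(
    compound = object$compound,
    headspace = frac(object$C_h * v$V_h),
    liquid_free = frac(object$C_s * V_L),
    complexed = frac(object$C_x * V_L),
    ampoule = frac(object$C_i * (if (mode == "three_phase") 0 else v$V_i)),
    fiber = frac(object$C_f * v$V_f),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("summary.equilibrium_state", "data.frame"))
}

#' @export
print.summary.equilibrium_state <- function(x, digits = 4, ...) {
  cat("phase fractions of each compound's initial amount\n")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], signif, digits = digits)
  print.data.frame(df, row.names = FALSE, ...)
  invisible(x)
}
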