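# small builders used across the test files

make_guest <- function(name = "guest", K1 = 2.2e4, K2 = 1e-5, K3 = K1,
                       kb = numeric(), conc_mg_L = 1, phase = "sample") {
  compound(name, molar_mass = 124.14, K1 = K1, K2 = K2, K3 = K3, kb = kb,
           conc_mg_L = conc_mg_L, phase = phase)
}

std_vial <- function() vial_config(V_total = 20, V_s = 6, V_i = 0.5,
                                   V_f = 6.6e-4)

# independent brute-force search for the free-host concentration: evaluate
# the host balance on a fine grid, then refine around the sign change
grid_free_host <- function(compounds, vial, cd,
                           mode = "four_phase_short_extraction",
                           n_grid = 1e6) {
  K1 <- vapply(compounds, `[[`, 1, "K1")
  K2 <- vapply(compounds, `[[`, 1, "K2")
  kb <- vapply(compounds, function(cp) {
    v <- cp$kb[[cd$name]]
    if (is.null(v)) 0 else v
  }, 1)
  C0 <- vapply(compounds, `[[`, 1, "C0")
  n0 <- C0 * vial$V_s
  H <- cd$total_molar
  f <- function(h) {
    bound <- vapply(h, function(hh) {
      Ch <- n0 / (K1 * vial$V_s * (1 + kb * hh) + vial$V_h +
                    vial$V_f / K2)
      sum(kb * hh * K1 * Ch)
    }, 1)
    h + bound - H
  }
  lo <- 0; hi <- H
  for (pass in 1:3) {
    h <- seq(lo, hi, length.out = n_grid)
    v <- f(h)
    i <- max(which(v <= 0))
    lo <- h[i]
    hi <- h[min(i + 1L, length(h))]
  }
  (lo + hi) / 2
}

# closed-form 1:1 binding with host and guest depletion (single guest):
# complex concentration x solves a*x^2 - (a*(H + C0) + 1)*x + a*H*C0 = 0
# with a = kb * K1 * V_s / D0, D0 the guest's cd-free denominator
quadratic_single_guest <- function(guest, vial, cd,
                                   mode = "four_phase_short_extraction") {
  kb <- guest$kb[[cd$name]]
  D0 <- guest$K1 * vial$V_s + vial$V_h + vial$V_f / guest$K2 +
    (if (mode == "four_phase_equilibrium") guest$K3 * vial$V_i else 0)
  a <- kb * guest$K1 * vial$V_s / D0
  H <- cd$total_molar
  C0 <- guest$C0
  b <- -(a * (H + C0) + 1)
  cc <- a * H * C0
  # numerically stable smaller root
  q <- -(b - sqrt(b^2 - 4 * a * cc)) / 2
  x <- cc / q
  list(C_x = x, C_h = (C0 - x) * vial$V_s / D0, free_host = H - x)
}
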