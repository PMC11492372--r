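# Independent re-derivation of every model formula, written as straight-line
# arithmetic from the documented equations. These functions share no code
# with the package and serve as the second route in the dual-route
# equivalence tests.

o_kB <- 1.380649e-23
o_e <- 1.602176634e-19
o_NAv <- 6.02214076e23
o_Rgas <- 8.31446261815324
o_F <- 96485.33212
o_eps <- 78.41 * 8.8541878128e-12

# Debye activity coefficients, one per species.
o_fa <- function(conc, z, radii, temperature = 298) {
  kT <- o_kB * temperature
  B <- sqrt(2 * o_e^2 * o_NAv * 1000 / (o_eps * kT))
  A <- B * o_e^2 / (log(10) * 8 * pi * o_eps * kT)
  I <- 0.5 * sum(conc * z^2)
  rbar <- sum(radii) / length(radii)
  10^(-A * z^2 * sqrt(I) / (1 + B * rbar * sqrt(I)))
}

o_Pbs <- function(r_maj, r_min, r_np, L_C = 1e-9) (r_min / r_maj) * (L_C / r_np)

o_Vbs <- function(a_np, a_res, P, z_maj, temperature = 298) {
  -sign(z_maj) * (o_Rgas * temperature / o_F) * P *
    log((a_np / a_res) * (1 / a_res))
}

o_Ibs <- function(V) 1.75e-8 * V + 7.0e-11

o_vbs <- function(V, mu, z_maj, L_Au = 5e-9) sign(z_maj) * mu * V / L_Au

o_nbs <- function(I, v, A) I / (A * v)

# baseline chain for a symmetric binary electrolyte at per-ion conc c (mol/L)
o_baseline_naf <- function(c, r_np = 2.3e-9, temperature = 298) {
  conc <- c(c, c); z <- c(1, -1); radii <- c(0.116e-9, 0.119e-9)
  f <- o_fa(conc, z, radii, temperature)
  a <- conc * f
  a_np <- a[1]           # majority = Na (smaller radius), cations only
  a_res <- a[1] + a[2]
  P <- o_Pbs(0.116e-9, 0.119e-9, r_np)
  V <- o_Vbs(a_np, a_res, P, +1, temperature)
  I <- o_Ibs(V)
  mu <- 5.19e-8
  v <- o_vbs(V, mu, +1)
  A <- pi * r_np^2
  list(V = V, I = I, v = v, n = o_nbs(I, v, A), A = A, V_total = A * 55e-9)
}

o_dnV <- function(n_bs, V_an, V_total) -n_bs * V_an / V_total
o_dnE <- function(z, V_total, kappa = 1.15) -kappa * z * o_e / V_total
o_dv <- function(v_bs, n_bs, dn) v_bs * ((n_bs / (n_bs + dn))^2 - 1)
o_dI <- function(A, n_bs, v_bs, dn) {
  n_ps <- n_bs + dn
  v_ps <- v_bs + o_dv(v_bs, n_bs, dn)
  A * (n_ps * v_ps - n_bs * v_bs)
}
o_nan <- function(z, V_total) z * o_e / V_total
o_van <- function(t_ic, L = 55e-9) L / t_ic
o_Ian <- function(z, t_ic, A, V_total, L = 55e-9) {
  o_nan(z, V_total) * A * o_van(t_ic, L)
}
o_Vps <- function(dn, n_an, V_total, C_EDL) -V_total * (dn + n_an) / C_EDL

o_mob <- function(t_ic, V_bs, L = 55e-9, L_Au = 5e-9) {
  L * L_Au / (abs(V_bs) * t_ic)
}
o_diff <- function(mu, z, temperature = 298) {
  mu * o_kB * temperature / (abs(z) * o_e)
}

# secant-fit capacitance oracle: slope of V_total*n_bs vs V_bs over the
# standard sweep of a NaF-type composition
o_CEDL_naf <- function(r_np = 2.3e-9, n_pts = 20) {
  totals <- 10^seq(log10(2e-7), log10(2e-1), length.out = n_pts)
  V <- Q <- numeric(n_pts)
  for (i in seq_len(n_pts)) {
    b <- o_baseline_naf(totals[i] / 2, r_np)
    V[i] <- b$V
    Q[i] <- b$V_total * b$n
  }
  xm <- mean(V); ym <- mean(Q)
  abs(sum((V - xm) * (Q - ym)) / sum((V - xm)^2))
}
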