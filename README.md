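# poresignal

Forward and inverse modelling of resistive-pulse signals in metal-layered
solid-state nanopores.

A nanopore through a silicon nitride membrane capped with a thin gold layer
reads out two channels at once: the transmembrane ionic current and the
potential of the electrical double layer (EDL) at the metal. With
electrolyte only, both settle to a *baseline state* (V_bs, I_bs) set by the
electrolyte composition and the pore geometry; when a single molecule or
nanoparticle translocates, both channels spike (V_ps, I_ps) in proportion
to the analyte's size and charge, and the spike duration t_ic (full
duration at half-maximum of the current trace) carries its mobility.
`poresignal` is for experimentalists and modellers who want to predict
those signals from first inputs, and to invert measured signal sets to
recover what went through the pore.

## The model in brief

Baseline state (per-species Debye activities a = c·f, size-partition
coefficient P_bs from the Knudsen-coefficient ratio of the ion pair):

    V_bs = -sgn(z_maj) · (RT/F) · P_bs · ln[(a_np / a_res) · (c° / a_res)]
    I_bs = G · V_bs + I_0                    (linear device response)
    v_bs = sgn(z_maj) · μ_ion · V_bs / L_Au
    n_bs = I_bs / (A · v_bs)                 (continuity, I = n A v)
    C_EDL = d(V_total · n_bs) / dV_bs        (sweep slope)

Perturbed state for an analyte of radius r and valence z:

    Δn_bs = -n_bs·V_analyte/V_total  -  κ·z·e/V_total     (blockade + screening)
    ΔI_bs = -A · v_bs · (n_bs/n_ps) · Δn_bs
    I_ps  = ΔI_bs + I_analyte,   I_analyte = (z·e/V_total)·A·(L/t_ic)  (negligible)
    V_ps  = -V_total · (Δn_bs + z·e/V_total) / C_EDL

Kinetics from one event: μ = L·L_Au/(|V_bs|·t_ic), D = μ·k_B·T/(|z|·e).
The inverse fit minimises the mean squared relative error of (I_ps, V_ps)
over an exhaustive (r, z) grid with continuous refinement of r. The methods
vignette (`vignettes/poresignal-model.Rmd`) derives and motivates every
piece, including the calibration constants and the screening factor κ.

## Worked example

Predict the baseline for 1 mM NaF in a 2.3 nm pore, the signals of a
ceria-like nanoparticle (bare radius 1.27 nm, charge +112), then recover
the particle from 50 noisy synthetic events:

```r
library(poresignal)

sol <- electrolyte(Na = 1e-3, F = 1e-3)
po  <- nanopore(2.3)

baseline_state(sol, po)
#> <baseline_state> V_bs = -63.7 mV, I_bs = -1.04 nA, n_bs = 9.51e+07 C/m^3, C_EDL = 9.9e-17 F

predict_signals(sol, po, analyte("ceria", 1.27, 112, use_stokes = FALSE))[, 3:4]
#> # A tibble: 1 × 2
#>   I_ps_nA V_ps_mV
#>     <dbl>   <dbl>
#> 1  -0.342    35.4

ev <- simulate_events(sol, po, analyte("ceria", 1.27, 112, use_stokes = FALSE),
                      n_events = 50, noise_rel = 0.05, seed = 1)
fit <- fit_analyte(ev, sol, po, fit_spec(use_stokes = FALSE))
glance(fit)
#> # A tibble: 1 × 5
#>   r_hat_nm z_hat residual n_events degenerate
#>      <dbl> <int>    <dbl>    <int> <lgl>
#> 1     1.25   112  0.00420       50 FALSE
```

Reading the numbers: the baseline EDL potential is negative (polarity
opposite to the Na⁺ majority ion) with a ~1 nA baseline current; the
positively charged particle pulls the current signal down by ~0.34 nA while
pushing the EDL potential up, and the grid fit recovers the generating
radius within 2% and the charge exactly from 5%-noise events.

A thin CLI wraps the same functions for shell use
(`inst/cli/poresignal-cli.R`: `predict-baseline`, `predict-signals`,
`simulate`, `extract-events`, `fit`).

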