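# Shared fixtures: standard electrolytes, pores and analytes.

naf <- function(c = 1e-3) electrolyte(Na = c, F = c)
kcl <- function(c = 1e-3) electrolyte(K = c, Cl = c)
nacl <- function(c = 1e-3) electrolyte(Na = c, Cl = c)
lif <- function(c = 1e-3) electrolyte(Li = c, F = c)

pore23 <- function() nanopore(2.3)

std_analytes <- function() {
  tab <- ion_table()
  lapply(c("OA", "HQ", "AA", "CA"), function(nm) {
    row <- tab[tab$name == nm, ]
    analyte(nm, row$radius_nm, row$valence)
  })
}

conc_sweep <- 10^seq(-7, -1, by = 1)
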