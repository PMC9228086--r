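# shared generators for property-style tests

# random landscape with one endergonic-reversible and one exergonic-
# irreversible channel (the mechanism's canonical shape); barrier ordering
# between the two channels is left free. Ranges bracket the reported cage
# kinetics: endergonic halide products a few kcal/mol up, reverse barriers
# of order 7-19, forward barriers 3-25, hydroxylation reverse barriers > 30.
random_bifurcated_landscape <- function() {
  p_rev <- runif(1, 1, 12)
  ts_rev <- p_rev + runif(1, 6, 20)        # reverse barrier 6..20 (< 30)
  p_irr <- runif(1, -45, -31)
  ts_irr <- runif(1, 2, 26)                # reverse barrier >= 33 (> 30)
  energy_landscape("synth", "synth", data.frame(
    name = c("X", "OH"), ligand = c("Cl", "OH"),
    position = c("equatorial", "distal"),
    ts_energy = c(ts_rev, ts_irr),
    product_energy = c(p_rev, p_irr),
    reversible = c(TRUE, FALSE), stringsAsFactors = FALSE))
}

# random valid bde_table rows with plain positive energies (no ordering)
random_free_table <- function() {
  ligs <- c("OH", "Cl", "Br", "F", "OTf")
  rads <- c("trityl", "PP", "PM")
  cx <- data.frame(radical = rep(rads, each = length(ligs)),
                   ligand = rep(ligs, times = length(rads)),
                   bde_kcal_mol = round(runif(15, 20, 110), 1),
                   stringsAsFactors = FALSE)
  metal <- data.frame(complex = "1Cl", ligand = c("OH", "Cl"),
                      bde_kcal_mol = round(runif(2, 50, 90), 1),
                      stringsAsFactors = FALSE)
  bde_table(cx, metal, check_order = FALSE)
}
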