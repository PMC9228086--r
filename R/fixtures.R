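#' Packaged bond-energy table
#'
#' The homolytic C-X bond dissociation energies of the three carbon radicals
#' with the five ligands (15 values) together with the diabatic Fe-OH (75.0)
#' and Fe-Cl (63.8 kcal/mol) bond energies of the 1Cl reactant complex.
#'
#' @return A [bde_table()].
#' @export
#' @examples
#' cx_bde(hx_bde_table(), "trityl", "Cl") # 46.2
hx_bde_table <- function() {
  read_bde_table(hx_extdata("bde_table1.tsv"))
}

#' Packaged orbital gap set for the 1Cl reactant complex
#'
#' Pair splittings of 88.8 (equatorial sigma/sigma* x2-y2, the weaker
#' three-electron bond, feeding the halide channel) and 99.2 kcal/mol
#' (pi*yz/pi**yz, feeding the hydroxyl channel). Excitation terms are unset
#' until calibrated with [calibrate_excitation_terms()].
#'
#' @return An [orbital_gap_set()].
#' @export
hx_orbital_gaps <- function() {
  doc <- jsonlite::fromJSON(hx_extdata("orbital_gaps_1Cl.json"))
  orbital_gap_set(pi_gap = doc$pi_gap, sigma_gap = doc$sigma_gap,
                  exc_pi_to_pixy = doc$exc_pi_to_pixy %||% NA_real_,
                  exc_sigma_to_pixy = doc$exc_sigma_to_pixy %||% NA_real_,
                  calibrated = isTRUE(doc$calibrated))
}

#' Packaged energy landscapes
#'
#' Loads one of the packaged stationary-point landscapes by system id. Use
#' [hx_landscape_ids()] to list them. Energies are adiabatic (DeltaE + ZPE,
#' solvent included) relative to each landscape's reactant complex; values
#' that are not available in print are synthetic stand-ins, flagged in the
#' sidecar `landscapes/provenance.json`.
#'
#' @param id System id such as `"1Cl_trityl"` or `"1Br_PM"`.
#' @return An [energy_landscape()].
#' @export
#' @examples
#' hx_landscape("1Cl_trityl")
hx_landscape <- function(id) {
  dir <- hx_extdata("landscapes")
  cands <- c(file.path(dir, paste0(id, ".json")),
             file.path(dir, paste0(id, "_synthetic.json")))
  path <- cands[file.exists(cands)][1]
  if (is.na(path)) {
    stop(sprintf("no packaged landscape '%s'; available: %s", id,
                 paste(hx_landscape_ids(), collapse = ", ")), call. = FALSE)
  }
  read_landscape(path)
}

#' @rdname hx_landscape
#' @export
hx_landscape_ids <- function() {
  f <- list.files(hx_extdata("landscapes"), pattern = "\\.json$")
  f <- setdiff(f, "provenance.json")
  sort(sub("(_synthetic)?\\.json$", "", f))
}

#' Packaged second-coordination-sphere perturbation barrier sets
#'
#' OH and halide rebound barriers (and reaction energies) for 1Cl + trityl
#' with the full ligand scaffold and with sterics, hydrogen bonding, or both
#' removed. The winning-channel gaps are as reported; absolute truncated
#' barriers are synthetic stand-ins (see the file header).
#'
#' @return A `data.frame` with columns `variant`, `channel`,
#'   `barrier_kcal_mol`, `reaction_energy_kcal_mol`.
#' @export
hx_truncation_barriers <- function() {
  utils::read.delim(hx_extdata("truncation_barriers.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE)
}

hx_extdata <- function(...) {
  path <- system.file("extdata", ..., package = "haloselect")
  if (!nzchar(path)) {
    stop(sprintf("packaged data file not found: %s",
                 file.path(...)), call. = FALSE)
  }
  path
}
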