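#' Radical descriptors
#'
#' A radical descriptor records the short id used to key bond-energy tables,
#' a free-text name, and whether the radical carbon is secondary or tertiary.
#' The 2/3 degree distinction drives the selectivity logic: secondary radicals
#' form substantially stronger C-X bonds than stabilised tertiary ones.
#'
#' @param id Short unique label, e.g. `"trityl"`.
#' @param name Free-text description.
#' @param order `"secondary"` or `"tertiary"`.
#' @return A one-row `data.frame` with columns `id`, `name`, `order`.
#' @export
#' @examples
#' radical_descriptor("PM", "phenylmethylmethyl radical", "secondary")
radical_descriptor <- function(id, name, order = c("secondary", "tertiary")) {
  order <- match.arg(order)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  data.frame(id = id, name = name, order = order, stringsAsFactors = FALSE)
}

#' Built-in radical registry
#'
#' The three carbon radicals the packaged energetics cover: the tertiary
#' tri(p-chlorophenyl)methyl radical (`trityl`) and the secondary
#' diphenylmethyl (`PP`) and phenylmethylmethyl (`PM`) radicals.
#'
#' @return A `data.frame` of radical descriptors.
#' @export
default_radicals <- function() {
  rbind(
    radical_descriptor("trityl", "tri(p-chlorophenyl)methyl radical", "tertiary"),
    radical_descriptor("PP", "diphenylmethyl radical", "secondary"),
    radical_descriptor("PM", "phenylmethylmethyl radical", "secondary")
  )
}

#' Complex descriptors
#'
#' Describes a cis-Fe(III) complex by the ligand sitting in the equatorial
#' plane (cis to the axial nitrogen donor) and the distal ligand, plus which
#' second-coordination-sphere variant is meant (full ligand scaffold, or
#' truncations with sterics and/or hydrogen bonding removed).
#'
#' @param id Short label, e.g. `"1Cl"`.
#' @param equatorial_ligand,distal_ligand One of `"OH"`, `"Cl"`, `"Br"`,
#'   `"F"`, `"OTf"`.
#' @param second_sphere One of `"full"`, `"no_sterics"`, `"no_hbonds"`,
#'   `"neither"`.
#' @return A one-row `data.frame`.
#' @export
complex_descriptor <- function(id, equatorial_ligand, distal_ligand,
                               second_sphere = c("full", "no_sterics",
                                                 "no_hbonds", "neither")) {
  second_sphere <- match.arg(second_sphere)
  equatorial_ligand <- match.arg(equatorial_ligand, LIGANDS)
  distal_ligand <- match.arg(distal_ligand, LIGANDS)
  data.frame(id = id, equatorial_ligand = equatorial_ligand,
             distal_ligand = distal_ligand, second_sphere = second_sphere,
             stringsAsFactors = FALSE)
}

#' Built-in complex registry
#'
#' The halide (or triflate) sits in the equatorial plane and the hydroxo
#' ligand along the molecular z-axis for the `1X` complexes; `2Cl` carries
#' chloride in both positions and `2OH` is the positional isomer of `1Cl`
#' with hydroxide equatorial and chloride distal.
#'
#' @return A `data.frame` of complex descriptors.
#' @export
default_complexes <- function() {
  rbind(
    complex_descriptor("1Cl", "Cl", "OH"),
    complex_descriptor("1Br", "Br", "OH"),
    complex_descriptor("1F", "F", "OH"),
    complex_descriptor("1OTf", "OTf", "OH"),
    complex_descriptor("2Cl", "Cl", "Cl"),
    complex_descriptor("2OH", "OH", "Cl")
  )
}

#' Construct a bond-energy table
#'
#' Holds homolytic C-X/C-OH bond dissociation energies keyed by
#' (radical id, ligand) and diabatic metal-ligand bond energies keyed by
#' (complex id, ligand), all in kcal/mol. Diabatic metal bond energies are
#' computed on frozen fragments and are deliberately kept on a different
#' scale from adiabatic landscape energies; the two are never mixed.
#'
#' @param cx `data.frame` with columns `radical`, `ligand`, `bde_kcal_mol`.
#' @param metal `data.frame` with columns `complex`, `ligand`, `bde_kcal_mol`.
#' @param radicals Optional radical registry (see [default_radicals()]).
#' @param check_order If `TRUE`, verify the physical ligand ordering
#'   C-F > C-OH > C-Cl > C-Br for every radical with all four entries.
#' @return An object of class `bde_table`.
#' @export
bde_table <- function(cx, metal = NULL, radicals = default_radicals(),
                      check_order = TRUE) {
  req <- c("radical", "ligand", "bde_kcal_mol")
  if (!is.data.frame(cx) || !all(req %in% names(cx))) {
    stop("`cx` must be a data.frame with columns radical, ligand, bde_kcal_mol",
         call. = FALSE)
  }
  if (nrow(cx) == 0L) stop("bond-energy table is empty", call. = FALSE)
  bad <- setdiff(unique(cx$ligand), LIGANDS)
  if (length(bad)) {
    stop(sprintf("unknown ligand(s) in C-X section: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(cx$bde_kcal_mol)) || any(cx$bde_kcal_mol <= 0)) {
    stop("all C-X bond energies must be strictly positive", call. = FALSE)
  }
  if (anyDuplicated(cx[c("radical", "ligand")])) {
    stop("duplicate (radical, ligand) keys in C-X section", call. = FALSE)
  }
  if (is.null(metal)) {
    metal <- data.frame(complex = character(), ligand = character(),
                        bde_kcal_mol = numeric(), stringsAsFactors = FALSE)
  }
  if (nrow(metal)) {
    bad <- setdiff(unique(metal$ligand), LIGANDS)
    if (length(bad)) {
      stop(sprintf("unknown ligand(s) in metal section: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    if (any(!is.finite(metal$bde_kcal_mol)) || any(metal$bde_kcal_mol <= 0)) {
      stop("all metal-ligand bond energies must be strictly positive",
           call. = FALSE)
    }
    if (anyDuplicated(metal[c("complex", "ligand")])) {
      stop("duplicate (complex, ligand) keys in metal section", call. = FALSE)
    }
  }
  out <- structure(
    list(cx = cx[order(cx$radical, cx$ligand), , drop = FALSE],
         metal = metal[order(metal$complex, metal$ligand), , drop = FALSE],
         radicals = radicals),
    class = "bde_table")
  rownames(out$cx) <- NULL
  rownames(out$metal) <- NULL
  if (check_order) validate_bde_ordering(out)
  out
}

# physical ligand ordering: C-F > C-OH > C-Cl > C-Br whenever all present
validate_bde_ordering <- function(table) {
  want <- c("F", "OH", "Cl", "Br")
  for (r in unique(table$cx$radical)) {
    sub <- table$cx[table$cx$radical == r, ]
    if (all(want %in% sub$ligand)) {
      v <- vapply(want, function(l) sub$bde_kcal_mol[sub$ligand == l][1L],
                  numeric(1))
      if (any(diff(v) >= 0)) {
        stop(sprintf(
          "radical '%s' violates the C-F > C-OH > C-Cl > C-Br ordering", r),
          call. = FALSE)
      }
    }
  }
  invisible(table)
}

#' @export
print.bde_table <- function(x, ...) {
  cat("Bond-energy table (kcal/mol)\n")
  cat(sprintf("  %d C-X entries over %d radicals; %d metal-ligand entries\n",
              nrow(x$cx), length(unique(x$cx$radical)), nrow(x$metal)))
  invisible(x)
}

#' Look up a homolytic C-X bond energy
#'
#' @param table A [bde_table()].
#' @param radical,ligand Key.
#' @return Energy in kcal/mol.
#' @export
cx_bde <- function(table, radical, ligand) {
  i <- which(table$cx$radical == radical & table$cx$ligand == ligand)
  if (length(i) != 1L) {
    stop(sprintf("no C-X bond energy for (radical=%s, ligand=%s)",
                 radical, ligand), call. = FALSE)
  }
  table$cx$bde_kcal_mol[i]
}

#' Look up a diabatic metal-ligand bond energy
#'
#' @param table A [bde_table()].
#' @param complex,ligand Key.
#' @return Energy in kcal/mol.
#' @export
metal_bde <- function(table, complex, ligand) {
  i <- which(table$metal$complex == complex & table$metal$ligand == ligand)
  if (length(i) != 1L) {
    stop(sprintf("no metal-ligand bond energy for (complex=%s, ligand=%s)",
                 complex, ligand), call. = FALSE)
  }
  table$metal$bde_kcal_mol[i]
}

#' Read a bond-energy table from TSV
#'
#' The file holds two tab-separated sections: a C-X section with header
#' `radical  ligand  bde_kcal_mol`, then (optionally, after a blank line) a
#' metal section with header `complex  ligand  bde_kcal_mol`. Lines starting
#' with `#` are comments.
#'
#' @param path File path.
#' @inheritParams bde_table
#' @return A [bde_table()].
#' @export
read_bde_table <- function(path, radicals = default_radicals(),
                           check_order = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("empty bond-energy table file: %s", path),
                           call. = FALSE)
  hdr <- which(vapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    length(f) >= 3L && f[2] == "ligand" && f[3] == "bde_kcal_mol"
  }, logical(1)))
  if (!length(hdr) || hdr[1] != 1L) {
    stop(sprintf("schema error in %s: first line must be the header %s",
                 path, "'radical\tligand\tbde_kcal_mol'"), call. = FALSE)
  }
  parse_section <- function(block, keycol, start_line) {
    out <- lapply(seq_along(block), function(i) {
      f <- strsplit(block[i], "\t", fixed = TRUE)[[1]]
      if (length(f) != 3L) {
        stop(sprintf("schema error at data row %d: expected 3 columns, got %d",
                     start_line + i, length(f)), call. = FALSE)
      }
      v <- suppressWarnings(as.numeric(f[3]))
      if (is.na(v)) {
        stop(sprintf("schema error at data row %d, column bde_kcal_mol: '%s'",
                     start_line + i, f[3]), call. = FALSE)
      }
      stats::setNames(data.frame(f[1], f[2], v, stringsAsFactors = FALSE),
                      c(keycol, "ligand", "bde_kcal_mol"))
    })
    do.call(rbind, out)
  }
  if (length(hdr) > 1L) {
    cxb <- lines[2:(hdr[2] - 1L)]
    mtb <- lines[(hdr[2] + 1L):length(lines)]
  } else {
    cxb <- lines[-1L]
    mtb <- character()
  }
  cx <- parse_section(cxb, "radical", 1L)
  metal <- if (length(mtb)) parse_section(mtb, "complex", hdr[2]) else NULL
  bde_table(cx, metal, radicals = radicals, check_order = check_order)
}

#' Write a bond-energy table to TSV
#'
#' Writers are bit-stable: fixed key order (alphabetical within section) and
#' fixed decimal formatting (up to 6 decimal places, trailing zeros trimmed
#' to at least one decimal). Tables whose energies carry at most 6 decimals
#' round-trip losslessly.
#'
#' @param table A [bde_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bde_table <- function(table, path) {
  fmt <- function(x) sub("0+$", "", sprintf("%.6f", x)) |>
    (\(s) ifelse(grepl("\\.$", s), paste0(s, "0"), s))()
  lines <- c("radical\tligand\tbde_kcal_mol",
             sprintf("%s\t%s\t%s", table$cx$radical, table$cx$ligand,
                     fmt(table$cx$bde_kcal_mol)))
  if (nrow(table$metal)) {
    lines <- c(lines, "",
               "complex\tligand\tbde_kcal_mol",
               sprintf("%s\t%s\t%s", table$metal$complex, table$metal$ligand,
                       fmt(table$metal$bde_kcal_mol)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Diabatic driving force for a ligand transfer
#'
#' The difference between the (diabatic) metal-ligand bond broken and the
#' carbon-ligand bond formed, `metal_bde - cx_bde` in kcal/mol. Positive
#' values mean the bond being broken is stronger than the bond being formed,
#' i.e. the transfer is endergonic on the diabatic scale. Note this sign
#' convention is opposite to the adiabatic landscape convention (where a
#' product below the reactant is negative); the two scales are never mixed.
#'
#' @param metal_bde Diabatic Fe-L bond energy, kcal/mol, positive.
#' @param cx_bde Homolytic C-L bond energy, kcal/mol, positive.
#' @return Driving force in kcal/mol.
#' @export
#' @examples
#' driving_force(63.8, 46.2) # 17.6, chlorine transfer
#' driving_force(75.0, 59.2) # 15.8, hydroxyl transfer
driving_force <- function(metal_bde, cx_bde) {
  stopifnot_scalar_number(metal_bde, "metal_bde")
  stopifnot_scalar_number(cx_bde, "cx_bde")
  if (metal_bde <= 0 || cx_bde <= 0) {
    stop("bond energies must be strictly positive", call. = FALSE)
  }
  metal_bde - cx_bde
}

#' Resonance energy of the valence-bond crossing point
#'
#' Taken as one-half of the weakest bond that is broken or formed in the
#' transfer, applied literally: if the bond being formed is stronger than the
#' bond being broken, the broken bond (then the weakest) still sets B.
#'
#' @param bond_energies Non-empty numeric vector of positive bond energies
#'   (kcal/mol), broken and formed.
#' @return Resonance energy B in kcal/mol.
#' @export
#' @examples
#' resonance_energy(c(63.8, 46.2)) # 23.1
resonance_energy <- function(bond_energies) {
  if (!is.numeric(bond_energies) || length(bond_energies) == 0L) {
    stop("`bond_energies` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(bond_energies)) || any(bond_energies <= 0)) {
    stop("all bond energies must be strictly positive", call. = FALSE)
  }
  min(bond_energies) / 2
}

#' Orbital pair gaps and excitation terms feeding the VB promotion gap
#'
#' `pi_gap` is the splitting of the pi*yz/pi**yz pair (breaks during OH
#' transfer, the Fe-O bond lying along the molecular z-axis); `sigma_gap` is
#' the splitting of the sigma/sigma* x2-y2 pair (the equatorial three-electron
#' bond that breaks during halide transfer). The excitation terms (promotion
#' of the odd electron into pi*xy) are not tabulated for the reactant
#' complexes and are treated as calibration parameters; `calibrated` is TRUE
#' whenever either was fitted rather than supplied.
#'
#' @param pi_gap,sigma_gap Positive pair splittings, kcal/mol.
#' @param exc_pi_to_pixy,exc_sigma_to_pixy Excitation terms, kcal/mol, or
#'   `NA` if not yet calibrated.
#' @param calibrated Logical flag.
#' @return An object of class `orbital_gap_set`.
#' @export
orbital_gap_set <- function(pi_gap, sigma_gap,
                            exc_pi_to_pixy = NA_real_,
                            exc_sigma_to_pixy = NA_real_,
                            calibrated = FALSE) {
  stopifnot_scalar_number(pi_gap, "pi_gap")
  stopifnot_scalar_number(sigma_gap, "sigma_gap")
  if (pi_gap <= 0 || sigma_gap <= 0) {
    stop("orbital pair gaps must be strictly positive", call. = FALSE)
  }
  structure(list(pi_gap = pi_gap, sigma_gap = sigma_gap,
                 exc_pi_to_pixy = exc_pi_to_pixy,
                 exc_sigma_to_pixy = exc_sigma_to_pixy,
                 calibrated = isTRUE(calibrated)),
            class = "orbital_gap_set")
}

#' @export
print.orbital_gap_set <- function(x, ...) {
  cat(sprintf("Orbital gap set: pi %.1f, sigma %.1f kcal/mol; exc (pi->pixy %s, sigma->pixy %s); calibrated: %s\n",
              x$pi_gap, x$sigma_gap,
              ifelse(is.na(x$exc_pi_to_pixy), "unset",
                     sprintf("%.1f", x$exc_pi_to_pixy)),
              ifelse(is.na(x$exc_sigma_to_pixy), "unset",
                     sprintf("%.1f", x$exc_sigma_to_pixy)),
              x$calibrated))
  invisible(x)
}
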