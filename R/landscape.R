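#' Construct a stationary-point energy landscape
#'
#' A landscape holds the adiabatic (DeltaE + ZPE) energies of the stationary
#' points of one rebound system, relative to its reactant complex (pinned at
#' exactly 0): for every transfer channel a transition-state energy and a
#' product-complex energy, plus channel metadata (ligand transferred,
#' equatorial or distal position, and an annotated reversibility flag).
#' `reactant_offset` places the reactant complex of this landscape relative
#' to an external reference (used for positional isomers, whose reactant is
#' less stable than the parent complex); it does not enter the within-
#' landscape kinetics.
#'
#' @param complex,radical System id, e.g. `"1Cl"`, `"trityl"`.
#' @param channels `data.frame` with columns `name`, `ligand`, `position`
#'   (`"equatorial"` or `"distal"`), `ts_energy`, `product_energy`,
#'   `reversible` (logical annotation).
#' @param reactant_offset Energy of this landscape's reactant complex
#'   relative to an external reference, kcal/mol.
#' @return An object of class `energy_landscape`.
#' @export
energy_landscape <- function(complex, radical, channels, reactant_offset = 0) {
  req <- c("name", "ligand", "position", "ts_energy", "product_energy",
           "reversible")
  if (!is.data.frame(channels) || !all(req %in% names(channels))) {
    stop("`channels` must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(channels) == 0L) stop("landscape has no channels", call. = FALSE)
  channels <- channels[req]
  x <- structure(list(complex = complex, radical = radical,
                      reactant_offset = reactant_offset,
                      channels = channels),
                 class = "energy_landscape")
  validate_landscape(x)
}

#' Validate an energy landscape
#'
#' Checks the single-step profile invariants: the reactant sits at exactly 0
#' (implicit), every channel has finite TS and product energies, ligands are
#' known, positions valid, and every TS satisfies the sanity bound
#' `ts_energy >= max(0, product_energy) - 0.5` kcal/mol.
#'
#' @param x An `energy_landscape`.
#' @return `x` invisibly; errors on violation.
#' @export
validate_landscape <- function(x) {
  ch <- x$channels
  if (anyDuplicated(ch$name)) stop("duplicate channel names", call. = FALSE)
  bad <- setdiff(unique(ch$ligand), LIGANDS)
  if (length(bad)) {
    stop(sprintf("unknown ligand(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (!all(ch$position %in% c("equatorial", "distal"))) {
    stop("channel position must be 'equatorial' or 'distal'", call. = FALSE)
  }
  if (any(!is.finite(ch$ts_energy)) || any(!is.finite(ch$product_energy))) {
    stop("every channel needs finite ts_energy and product_energy",
         call. = FALSE)
  }
  viol <- ch$ts_energy < pmax(0, ch$product_energy) - 0.5
  if (any(viol)) {
    stop(sprintf("channel(s) %s violate ts_energy >= max(0, product) - 0.5",
                 paste(ch$name[viol], collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("Energy landscape %s x %s (reactant at 0.0%s)\n",
              x$complex, x$radical,
              if (x$reactant_offset != 0)
                sprintf(", offset %+.1f vs reference", x$reactant_offset)
              else ""))
  print(x$channels, row.names = FALSE)
  invisible(x)
}

landscape_id <- function(x) paste0(x$complex, "_", x$radical)

#' Read an energy landscape from its JSON document
#'
#' @param path File path to a landscape JSON document (see
#'   [write_landscape()] for the dialect).
#' @return An [energy_landscape()].
#' @export
read_landscape <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(doc$system) || is.null(doc$channels)) {
    stop(sprintf("schema error in %s: need 'system' and 'channels'", path),
         call. = FALSE)
  }
  energy_landscape(doc$system$complex, doc$system$radical,
                   as.data.frame(doc$channels),
                   reactant_offset = doc$reactant_offset %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an energy landscape as a JSON document
#'
#' The writer is bit-stable: fixed key order and energies formatted with one
#' decimal place (the precision of the underlying electronic-structure data).
#'
#' @param x An [energy_landscape()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(x, path) {
  ch <- x$channels
  chan_json <- vapply(seq_len(nrow(ch)), function(i) {
    sprintf(paste0('    {"name": "%s", "ligand": "%s", "position": "%s", ',
                   '"ts_energy": %.1f, "product_energy": %.1f, ',
                   '"reversible": %s}'),
            ch$name[i], ch$ligand[i], ch$position[i],
            ch$ts_energy[i], ch$product_energy[i],
            tolower(as.character(ch$reversible[i])))
  }, character(1))
  lines <- c(
    "{",
    sprintf('  "system": {"complex": "%s", "radical": "%s"},',
            x$complex, x$radical),
    sprintf('  "reactant_offset": %.1f,', x$reactant_offset),
    '  "channels": [',
    paste0(chan_json, c(rep(",", nrow(ch) - 1L), "")),
    "  ]",
    "}")
  writeLines(lines, path)
  invisible(path)
}
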