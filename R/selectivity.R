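#' Kinetic selectivity call for a rebound landscape
#'
#' Runs the rebound network and maps the species fractions at the horizon to
#' a product call. The mechanism this encodes: an endergonic halide channel
#' with a small reverse barrier equilibrates with the reactant inside the
#' solvent cage and is non-productive, so an irreversible (strongly
#' exergonic) hydroxylation wins even where its forward barrier is higher;
#' when the carbon radical forms a strong C-X bond the halide channel becomes
#' exergonic and irreversible and the outcome reverts to kinetic (barrier)
#' control.
#'
#' Calls: the leading product maps to `hydroxylation` (OH ligand) or
#' `halogenation` (halide/OTf) when its fraction reaches `margin`;
#' `competitive` when no channel reaches the margin or when the two leading
#' transition states of opposing type lie within `barrier_tie` kcal/mol
#' (inside the accuracy of the underlying electronic-structure energies);
#' `no_productive_reaction` when every channel is endergonic and reversible
#' (cage equilibrium with nothing to trap it).
#'
#' @param landscape An [energy_landscape()].
#' @param temperature Kelvin.
#' @param horizon Seconds (or `"auto"`, see [simulate_network()]).
#' @param margin Fraction a product must reach for a unique call.
#' @param barrier_tie Barrier difference (kcal/mol) under which opposing
#'   channels are reported competitive regardless of fractions.
#' @param reversibility_ceiling See [build_network()].
#' @param sink_rate Optional first-order radical loss, 1/s.
#' @return An object of class `selectivity_report`: list with `system`,
#'   `call`, `fractions` (at horizon), `asymptotic`, `bep`, `notes`.
#' @export
#' @examples
#' selectivity_call(hx_landscape("1Cl_trityl"))$call # hydroxylation
selectivity_call <- function(landscape, temperature = default_temperature(),
                             horizon = default_horizon(), margin = 0.9,
                             barrier_tie = 0.5, reversibility_ceiling = 30,
                             sink_rate = 0) {
  validate_landscape(landscape)
  ch <- landscape$channels
  rates <- build_network(landscape, temperature, reversibility_ceiling)
  notes <- character()

  frozen <- all(rates$k_f < 1e-30)
  if (frozen) {
    warning("all forward rates are numerically zero at this temperature; ",
            "kinetics are frozen", call. = FALSE)
    notes <- c(notes, "all forward rates are numerically zero (frozen kinetics)")
    frac <- stats::setNames(c(1, numeric(nrow(rates))),
                            c("reactant", rates$name))
    asym <- frac
  } else {
    tc <- simulate_network(rates, horizon, sink_rate = sink_rate)
    frac <- horizon_fractions(tc)
    asym <- tc$asymptotic
  }

  call_of <- function(lig) if (lig == "OH") "hydroxylation" else "halogenation"
  prod_frac <- frac[rates$name]
  all_dead_end <- all(rates$reversible & rates$product_energy > 0)
  if (frozen || all_dead_end) {
    call <- "no_productive_reaction"
    if (all_dead_end) {
      notes <- c(notes,
                 "every channel is endergonic and reversible: cage equilibrium returns all population to the reactant")
    }
  } else {
    lead <- which.max(prod_frac)
    # opposing-call channels too close in barrier to distinguish?
    types <- vapply(rates$ligand, call_of, character(1))
    tie <- FALSE
    if (length(unique(types)) > 1L) {
      b_by_type <- tapply(rates$barrier_f, types, min)
      tie <- abs(diff(range(b_by_type))) < barrier_tie
    }
    if (prod_frac[lead] >= margin && !tie) {
      call <- call_of(rates$ligand[lead])
    } else {
      call <- "competitive"
      if (tie) notes <- c(notes, sprintf(
        "lowest opposing barriers within %.1f kcal/mol", barrier_tie))
    }
  }

  bep <- if (nrow(ch) >= 2L) {
    bep_check(ch$ts_energy, ch$product_energy)
  } else NA_character_

  structure(list(system = list(complex = landscape$complex,
                               radical = landscape$radical),
                 call = call,
                 fractions = frac,
                 asymptotic = asym,
                 bep = bep,
                 temperature = temperature,
                 horizon = horizon,
                 notes = notes),
            class = "selectivity_report")
}

#' @export
print.selectivity_report <- function(x, ...) {
  cat(sprintf("%s x %s -> %s (BEP %s)\n", x$system$complex, x$system$radical,
              x$call, ifelse(is.na(x$bep), "n/a", x$bep)))
  cat("  fractions at horizon:",
      paste(sprintf("%s %.3f", names(x$fractions), x$fractions),
            collapse = ", "), "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Bell-Evans-Polanyi compliance of a set of channels
#'
#' Within a family, BEP expects the more exothermic reaction to have the
#' lower barrier. The flag is `inverted` iff the channel with the lowest
#' barrier does not also have the most exergonic reaction energy; exact ties
#' (in barriers or energies) count as compliant.
#'
#' @param barriers Forward barriers, kcal/mol (length >= 2).
#' @param reaction_energies Reaction energies on the adiabatic convention
#'   (product below reactant = negative), same length.
#' @return `"compliant"` or `"inverted"`.
#' @export
#' @examples
#' bep_check(c(13.2, 23.6), c(6.0, -20.0)) # inverted
bep_check <- function(barriers, reaction_energies) {
  if (length(barriers) < 2L || length(reaction_energies) != length(barriers)) {
    stop("bep_check needs >= 2 channels with matching reaction energies",
         call. = FALSE)
  }
  tol <- 1e-9
  lead <- which(barriers <= min(barriers) + tol)
  # compliant if any lowest-barrier channel is also (tied-)most exergonic
  if (any(reaction_energies[lead] <= min(reaction_energies) + tol)) {
    "compliant"
  } else {
    "inverted"
  }
}

#' Equatorial versus distal transfer preference
#'
#' Compares the transition-state energies of the equatorial and distal
#' channels of one landscape; the preference follows the energies, not the
#' channel labels.
#'
#' @param landscape An [energy_landscape()] containing at least one channel
#'   in each position.
#' @return List with `preferred` (`"equatorial"`, `"distal"` or `"tie"`),
#'   `gap` (kcal/mol, nonnegative) and the two barrier values.
#' @export
#' @examples
#' position_compare(hx_landscape("2Cl_trityl")) # equatorial by 10.2
position_compare <- function(landscape) {
  validate_landscape(landscape)
  ch <- landscape$channels
  b_eq <- ch$ts_energy[ch$position == "equatorial"]
  b_di <- ch$ts_energy[ch$position == "distal"]
  if (!length(b_eq) || !length(b_di)) {
    stop("landscape must contain both an equatorial and a distal channel",
         call. = FALSE)
  }
  b_eq <- min(b_eq); b_di <- min(b_di)
  gap <- abs(b_eq - b_di)
  preferred <- if (gap < 1e-9) "tie" else if (b_eq < b_di) "equatorial"
               else "distal"
  list(preferred = preferred, gap = gap,
       equatorial_barrier = b_eq, distal_barrier = b_di)
}

#' Competitiveness of hydroxo/halide positional isomerisation
#'
#' An isomerisation that swaps the equatorial halide and distal hydroxide
#' competes with direct transfer when its cost is within `margin` of the
#' lowest direct barrier. The isomer's own selectivity is evaluated on its
#' landscape (whose `reactant_offset` records how much less stable the
#' isomeric reactant complex is than the parent).
#'
#' @param direct An [energy_landscape()] for the parent complex.
#' @param isomer An [energy_landscape()] for the isomerised complex.
#' @param cost Isomerisation cost, kcal/mol, `>= 0`.
#' @param margin Competitiveness margin, kcal/mol.
#' @param ... Passed to [selectivity_call()] for the isomer.
#' @return List with `competitive`, `post_isomerization_call`, `cost`,
#'   `min_direct_barrier`, `isomer_offset`.
#' @export
isomerization_competitiveness <- function(direct, isomer, cost, margin = 0.5,
                                          ...) {
  if (!is.numeric(cost) || cost < 0) {
    stop("isomerisation cost must be >= 0", call. = FALSE)
  }
  validate_landscape(direct)
  validate_landscape(isomer)
  min_direct <- min(direct$channels$ts_energy)
  rep <- selectivity_call(isomer, ...)
  list(competitive = cost <= min_direct + margin,
       post_isomerization_call = rep$call,
       cost = cost,
       min_direct_barrier = min_direct,
       isomer_offset = isomer$reactant_offset)
}

#' Second-coordination-sphere perturbation ledger
#'
#' Summarises, for each variant of the ligand scaffold (full, no sterics, no
#' H-bonds, neither), which transfer channel has the lowest barrier and by
#' how much. Hydrogen bonds to the hydroxo group and steric bulk around the
#' substrate approach both raise the OH rebound barrier selectively, so their
#' removal flips the preference channel by channel.
#'
#' @param barrier_sets `data.frame` with columns `variant` (exactly the four
#'   values `full`, `no_sterics`, `no_hbonds`, `neither`), `channel` (`OH` or
#'   `X`), `barrier_kcal_mol` and optionally `reaction_energy_kcal_mol`.
#' @return An object of class `perturbation_ledger`: `data.frame` with one
#'   row per variant (`oh_barrier`, `x_barrier`, `lowest`, `gap`, `bep`).
#' @export
#' @examples
#' perturbation_ledger(hx_truncation_barriers())
perturbation_ledger <- function(barrier_sets = hx_truncation_barriers()) {
  want <- c("full", "no_sterics", "no_hbonds", "neither")
  if (!setequal(unique(barrier_sets$variant), want)) {
    stop("barrier_sets must contain exactly the variants ",
         paste(want, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(want, function(v) {
    sub <- barrier_sets[barrier_sets$variant == v, ]
    oh <- sub$barrier_kcal_mol[sub$channel == "OH"]
    x <- sub$barrier_kcal_mol[sub$channel == "X"]
    if (length(oh) != 1L || length(x) != 1L) {
      stop(sprintf("variant '%s' must supply one OH and one X barrier", v),
           call. = FALSE)
    }
    bep <- if ("reaction_energy_kcal_mol" %in% names(barrier_sets)) {
      bep_check(c(oh, x),
                c(sub$reaction_energy_kcal_mol[sub$channel == "OH"],
                  sub$reaction_energy_kcal_mol[sub$channel == "X"]))
    } else NA_character_
    data.frame(variant = v, oh_barrier = oh, x_barrier = x,
               lowest = if (abs(oh - x) < 1e-9) "tie"
                        else if (oh < x) "OH" else "X",
               gap = abs(oh - x), bep = bep, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("perturbation_ledger", "data.frame"))
}
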