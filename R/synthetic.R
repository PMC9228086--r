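#' Configuration for the synthetic-data generator
#'
#' The generator emulates the structure of the packaged thermochemistry: per
#' ligand class, C-X bond energies are drawn from ranges bracketing the
#' packaged values by +/- 15 kcal/mol, subject to the physical orderings
#' C-F > C-OH > C-Cl > C-Br within each radical and 2-degree > 3-degree for
#' the same ligand. Energies are rounded to 0.1 kcal/mol (the precision of
#' the underlying electronic-structure data), which also makes the TSV
#' round-trip exact. The seed fully determines the output; scenario indices
#' give independent streams.
#'
#' @param seed Integer seed.
#' @param n_scenarios Number of scenarios callers intend to draw.
#' @param cx_ranges Named list of `c(lo, hi)` per ligand.
#' @param metal_ranges Named list of `c(lo, hi)` for `OH` and halides.
#' @param noise_sd Gaussian noise scale (kcal/mol) for perturbed landscapes.
#' @param enforce_order Apply the ordering constraints.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_scenarios = 100L,
                             cx_ranges = list(
                               F = c(68.2, 110.8),
                               OH = c(44.2, 88.3),
                               Cl = c(31.2, 78.7),
                               Br = c(19.3, 67.8),
                               OTf = c(32.0, 83.1)),
                             metal_ranges = list(
                               OH = c(60.0, 90.0),
                               Cl = c(48.8, 78.8),
                               Br = c(48.8, 78.8),
                               F = c(48.8, 78.8),
                               OTf = c(48.8, 78.8)),
                             noise_sd = 1.0,
                             enforce_order = TRUE) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  for (r in cx_ranges) {
    if (length(r) != 2L || r[1] >= r[2] || r[1] <= 0) {
      stop("each range must be c(lo, hi) with 0 < lo < hi", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_scenarios = as.integer(n_scenarios),
                 cx_ranges = cx_ranges, metal_ranges = metal_ranges,
                 noise_sd = noise_sd, enforce_order = isTRUE(enforce_order)),
            class = "generator_config")
}

scenario_seed <- function(config, scenario) {
  (config$seed * 48271L + scenario * 7919L) %% 2147483562L + 1L
}

#' Sample a physically ordered bond-energy table
#'
#' Rejection-samples uniform energies within the configured ranges until the
#' enabled ordering constraints hold; errors if the ranges make the
#' constraints infeasible (no accepted draw in `max_tries`).
#'
#' @param config A [generator_config()].
#' @param scenario Scenario index (independent stream per index).
#' @param max_tries Rejection cap per table.
#' @return A [bde_table()].
#' @export
#' @examples
#' tbl <- sample_bde_table(generator_config(seed = 1))
sample_bde_table <- function(config = generator_config(), scenario = 1L,
                             max_tries = 10000L) {
  set.seed(scenario_seed(config, scenario))
  rads <- default_radicals()
  ligs <- names(config$cx_ranges)
  ord_ok <- function(v) !config$enforce_order ||
    (v["F"] > v["OH"] && v["OH"] > v["Cl"] && v["Cl"] > v["Br"])
  # one radical row: uniform per ligand above `floor` (the tertiary value for
  # secondary radicals), rejected until the ligand ordering holds
  draw_row <- function(floor = NULL) {
    for (try in seq_len(max_tries)) {
      v <- vapply(ligs, function(l) {
        lo <- config$cx_ranges[[l]][1]
        hi <- config$cx_ranges[[l]][2]
        if (!is.null(floor) && config$enforce_order &&
            l %in% c("F", "OH", "Cl", "Br")) {
          lo <- max(lo, floor[l] + 0.1)
        }
        if (lo >= hi) return(NA_real_) # no room above the floor
        stats::runif(1, lo, hi)
      }, numeric(1))
      if (anyNA(v)) return(NULL) # redraw the whole table
      v <- round(v, 1)
      if (ord_ok(v)) return(v)
    }
    stop(sprintf(
      "generation error: no row satisfying the ligand ordering in %d tries",
      max_tries), call. = FALSE)
  }
  tert <- rads$id[rads$order == "tertiary"]
  rows <- NULL
  for (attempt in seq_len(max_tries)) {
    cand <- list()
    cand[[tert]] <- draw_row()
    ok <- TRUE
    for (s in rads$id[rads$order == "secondary"]) {
      row <- draw_row(floor = cand[[tert]])
      if (is.null(row)) { ok <- FALSE; break }
      cand[[s]] <- row
    }
    if (ok) { rows <- cand; break }
  }
  if (is.null(rows)) {
    stop(sprintf(
      "generation error: ordering constraints unsatisfiable in %d attempts; ranges are likely infeasible",
      max_tries), call. = FALSE)
  }
  rows <- rows[rads$id]
  cx <- do.call(rbind, lapply(names(rows), function(rid) {
    data.frame(radical = rid, ligand = ligs,
               bde_kcal_mol = unname(rows[[rid]]),
               stringsAsFactors = FALSE)
  }))
  metal <- data.frame(
    complex = "1Cl",
    ligand = c("OH", "Cl"),
    bde_kcal_mol = round(c(
      stats::runif(1, config$metal_ranges$OH[1], config$metal_ranges$OH[2]),
      stats::runif(1, config$metal_ranges$Cl[1], config$metal_ranges$Cl[2])),
      1),
    stringsAsFactors = FALSE)
  bde_table(cx, metal, radicals = rads, check_order = config$enforce_order)
}

# diabatic -> adiabatic bridging defaults, anchored on the printed 1Cl/trityl
# pairs (Cl: 17.6 diabatic vs +5.5 adiabatic; OH: 15.8 vs -20.0) and, for the
# halide slope, on the strongly exergonic 2-degree halide products.
VB_PRODUCT_MODEL <- list(
  oh_relaxation = 35.8,
  x_relaxation = 12.1,
  x_ref_bde = 46.2,
  x_ref_product = 5.5,
  x_slope = -32.5 / 17.5
)

vb_product_energy <- function(channel, dErp, cx, model = VB_PRODUCT_MODEL) {
  if (channel == "OH_transfer") {
    dErp - model$oh_relaxation
  } else {
    model$x_ref_product + model$x_slope * (cx - model$x_ref_bde)
  }
}

#' Sample (or derive) an energy landscape for a system
#'
#' `via = "direct"` perturbs the packaged landscape for the system with
#' seeded Gaussian noise of scale `config$noise_sd` on every transition-state
#' and product energy (a surrogate for electronic-structure error), then
#' restores the single-step sanity bound by lifting any TS below
#' `max(0, product)`. `via = "vb_model"` chains the valence-bond barrier
#' model into a landscape: transition states are clamped VB estimates and
#' product energies come from the diabatic driving force through the
#' package's bridging model (ligand-specific relaxation for OH; an anchored
#' linear response in the C-X bond strength for halides, see the methods
#' vignette).
#'
#' @param table A [bde_table()] (used by `vb_model`).
#' @param gaps A calibrated [orbital_gap_set()] (used by `vb_model`).
#' @param system `c(complex, radical)`, e.g. `c("1Cl", "PM")`.
#' @param via `"vb_model"` or `"direct"`.
#' @param config A [generator_config()] (noise scale, seed).
#' @param scenario Scenario index for the noise stream.
#' @param complexes Complex registry.
#' @return An [energy_landscape()].
#' @export
sample_landscape <- function(table = hx_bde_table(),
                             gaps = calibrate_excitation_terms(),
                             system, via = c("vb_model", "direct"),
                             config = generator_config(),
                             scenario = 1L,
                             complexes = default_complexes()) {
  via <- match.arg(via)
  cid <- system[1]; rid <- system[2]
  if (via == "direct") {
    base <- hx_landscape(paste0(cid, "_", rid))
    set.seed(scenario_seed(config, scenario))
    ch <- base$channels
    if (config$noise_sd > 0) {
      ch$ts_energy <- ch$ts_energy +
        stats::rnorm(nrow(ch), 0, config$noise_sd)
      ch$product_energy <- ch$product_energy +
        stats::rnorm(nrow(ch), 0, config$noise_sd)
      ch$ts_energy <- pmax(ch$ts_energy, 0, ch$product_energy)
    }
    return(energy_landscape(cid, rid, ch,
                            reactant_offset = base$reactant_offset))
  }
  cd <- complexes[complexes$id == cid, ]
  if (nrow(cd) != 1L) stop(sprintf("unknown complex '%s'", cid), call. = FALSE)
  specs <- list(
    list(name = cd$equatorial_ligand, channel = "X_transfer",
         ligand = cd$equatorial_ligand, position = "equatorial",
         gap = gaps$sigma_gap, exc = gaps$exc_sigma_to_pixy),
    list(name = "OH", channel = "OH_transfer", ligand = cd$distal_ligand,
         position = "distal", gap = gaps$pi_gap, exc = gaps$exc_pi_to_pixy))
  ch <- do.call(rbind, lapply(specs, function(s) {
    m <- metal_bde(table, cid, s$ligand)
    cx <- cx_bde(table, rid, s$ligand)
    est <- vb_barrier(vb_channel_input(s$channel, m, cx, s$gap, s$exc,
                                       label = c(cid, rid)))
    product <- vb_product_energy(s$channel, est$decomposition$driving_force,
                                 cx)
    ts <- max(est$barrier_clamped, 0, product)
    data.frame(name = s$name, ligand = s$ligand, position = s$position,
               ts_energy = ts, product_energy = product,
               reversible = (ts - product) < 30, stringsAsFactors = FALSE)
  }))
  energy_landscape(cid, rid, ch)
}

#' Locate the selectivity phase boundary along the C-X bond strength
#'
#' Sweeps the homolytic C-X bond energy of the halide channel at a fixed
#' C-OH bond energy, building a two-channel landscape at each point through
#' the VB model (see [sample_landscape()]'s `vb_model` route) and calling
#' [selectivity_call()]. Weak C-X bonds (stabilised tertiary radicals) leave
#' the halide channel endergonic/reversible and the call is hydroxylation;
#' strong C-X bonds (secondary radicals) make it exergonic, fast and
#' irreversible and the call flips to halogenation. Returns the bracketing
#' interval of the flip; an absent flip is reported as an open interval, not
#' an error. The call sequence must be monotone along the sweep
#' (hydroxylation, then possibly competitive, then halogenation); a
#' non-monotone sequence is an error.
#'
#' @param cx_grid Increasing grid of C-X bond energies, kcal/mol.
#' @param cx_oh Fixed C-OH bond energy, kcal/mol.
#' @param ligand Halide ligand being swept.
#' @param table,gaps Thermochemistry and calibrated gaps (for the metal bond
#'   energies and promotion terms).
#' @param complex Complex id whose metal bond energies are used.
#' @param temperature,horizon,margin Passed to [selectivity_call()]. The
#'   barrier-tie window is disabled along the sweep (`barrier_tie = 0`):
#'   the two transition states inevitably cross somewhere along a continuous
#'   sweep, and flagging that crossing as competitive regardless of the
#'   kinetic outcome would puncture the phase map where the populations are
#'   in fact unanimous.
#' @param method `"grid"` brackets the flip on the supplied grid;
#'   `"bisect"` refines it by bisection to `tol`.
#' @param tol Bisection tolerance, kcal/mol.
#' @return List with `lower`, `upper` (bracket of the first halogenation
#'   call; `NA` and `open = TRUE` when the call never flips in range),
#'   `calls` (per grid point), `grid`, `method`.
#' @export
phase_boundary <- function(cx_grid, cx_oh = 59.2, ligand = "Cl",
                           table = hx_bde_table(),
                           gaps = calibrate_excitation_terms(),
                           complex = "1Cl",
                           temperature = default_temperature(),
                           horizon = default_horizon(), margin = 0.9,
                           method = c("grid", "bisect"), tol = 0.1) {
  method <- match.arg(method)
  if (is.unsorted(cx_grid, strictly = FALSE)) {
    stop("`cx_grid` must be a monotone increasing sweep", call. = FALSE)
  }
  m_x <- metal_bde(table, complex, ligand)
  m_oh <- metal_bde(table, complex, "OH")

  land_at <- function(b) {
    est_x <- vb_barrier(vb_channel_input("X_transfer", m_x, b,
                                         gaps$sigma_gap,
                                         gaps$exc_sigma_to_pixy))
    est_oh <- vb_barrier(vb_channel_input("OH_transfer", m_oh, cx_oh,
                                          gaps$pi_gap, gaps$exc_pi_to_pixy))
    p_x <- vb_product_energy("X_transfer", est_x$decomposition$driving_force, b)
    p_oh <- vb_product_energy("OH_transfer",
                              est_oh$decomposition$driving_force, cx_oh)
    ch <- data.frame(
      name = c(ligand, "OH"), ligand = c(ligand, "OH"),
      position = c("equatorial", "distal"),
      ts_energy = c(max(est_x$barrier_clamped, 0, p_x),
                    max(est_oh$barrier_clamped, 0, p_oh)),
      product_energy = c(p_x, p_oh),
      reversible = c(TRUE, FALSE), stringsAsFactors = FALSE)
    energy_landscape(complex, sprintf("sweep_%.1f", b), ch)
  }
  call_at <- function(b) {
    selectivity_call(land_at(b), temperature = temperature,
                     horizon = horizon, margin = margin,
                     barrier_tie = 0)$call
  }

  calls <- vapply(cx_grid, call_at, character(1))
  rank <- c(hydroxylation = 0, no_productive_reaction = 0, competitive = 1,
            halogenation = 2)[calls]
  if (any(diff(rank) < 0)) {
    stop("selectivity call is not monotone along the sweep", call. = FALSE)
  }
  flip <- which(calls == "halogenation")
  if (!length(flip)) {
    return(list(lower = utils::tail(cx_grid, 1), upper = NA_real_,
                open = TRUE, calls = calls, grid = cx_grid, method = method))
  }
  if (flip[1] == 1L) {
    return(list(lower = NA_real_, upper = cx_grid[1], open = TRUE,
                calls = calls, grid = cx_grid, method = method))
  }
  lower <- cx_grid[flip[1] - 1L]
  upper <- cx_grid[flip[1]]
  if (method == "bisect") {
    while (upper - lower > tol) {
      mid <- (lower + upper) / 2
      if (call_at(mid) == "halogenation") upper <- mid else lower <- mid
    }
  }
  list(lower = lower, upper = upper, open = FALSE, calls = calls,
       grid = cx_grid, method = method)
}
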