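#' Eyring rate constant from an activation energy
#'
#' `k = (kB T / h) exp(-barrier / (R T))`, with the barrier in kcal/mol. The
#' landscape energies are DeltaE + ZPE values and are used directly as
#' activation energies (an approximation: activation entropies beyond the
#' universal prefactor are neglected). Negative barriers are a domain error;
#' clamping exergonic crossings at zero is the caller's responsibility (see
#' [build_network()] and `barrier_clamped` in [vb_barrier()]).
#'
#' @param barrier Activation energy, kcal/mol, `>= 0`.
#' @param temperature Kelvin, `> 0`.
#' @return First-order rate constant, 1/s.
#' @export
#' @examples
#' eyring_rate(0, 298.15) # the prefactor kB*T/h, ~6.21e12 1/s
eyring_rate <- function(barrier, temperature = default_temperature()) {
  if (any(!is.finite(barrier)) || any(barrier < 0)) {
    stop("negative or non-finite barrier; clamp exergonic barriers at 0 ",
         "before converting to rates", call. = FALSE)
  }
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("temperature must be positive (kelvin)", call. = FALSE)
  }
  (KB_J * temperature / H_J) * exp(-barrier / (R_KCAL * temperature))
}

#' Build the rebound rate network from an energy landscape
#'
#' Converts each channel of a landscape into Eyring forward and reverse rate
#' constants. The effective transition-state energy is
#' `max(ts_energy, 0, product_energy)` so that forward and reverse barriers
#' are both non-negative and detailed balance
#' `k_f / k_r = exp(-product_energy / RT)` holds exactly for reversible
#' channels. A channel is reversible iff its reverse barrier
#' (`ts - product`) is below the reversibility ceiling: barriers above ~30
#' kcal/mol are not crossed on any laboratory timescale, making such channels
#' operationally irreversible; those channels get `k_r = 0`.
#'
#' @param landscape An [energy_landscape()].
#' @param temperature Kelvin.
#' @param reversibility_ceiling Reverse-barrier ceiling, kcal/mol.
#' @param source `"dft"` uses the landscape transition-state energies as
#'   stored; `"vb"` replaces them with clamped VB estimates computed from
#'   `table` and `gaps`.
#' @param table,gaps Only for `source = "vb"`.
#' @return An object of class `rate_set`: a `data.frame` of channels with
#'   `k_f`, `k_r`, `barrier_f`, `barrier_r`, `product_energy`, `reversible`,
#'   plus the temperature and landscape id as attributes.
#' @export
build_network <- function(landscape, temperature = default_temperature(),
                          reversibility_ceiling = 30,
                          source = c("dft", "vb"), table = NULL, gaps = NULL) {
  source <- match.arg(source)
  validate_landscape(landscape)
  ch <- landscape$channels
  if (source == "vb") {
    if (is.null(table) || is.null(gaps)) {
      stop("source = 'vb' needs `table` and `gaps`", call. = FALSE)
    }
    for (i in seq_len(nrow(ch))) {
      channel <- if (ch$ligand[i] == "OH") "OH_transfer" else "X_transfer"
      gap <- if (channel == "OH_transfer") gaps$pi_gap else gaps$sigma_gap
      exc <- if (channel == "OH_transfer") gaps$exc_pi_to_pixy
             else gaps$exc_sigma_to_pixy
      est <- vb_barrier(vb_channel_input(
        channel, metal_bde(table, landscape$complex, ch$ligand[i]),
        cx_bde(table, landscape$radical, ch$ligand[i]), gap, exc))
      ch$ts_energy[i] <- est$barrier_clamped
    }
  }
  if (any(ch$product_energy > ch$ts_energy + 1e-9)) {
    bad <- ch$name[ch$product_energy > ch$ts_energy + 1e-9]
    stop(sprintf("landscape inconsistency: product above its own TS in %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  ts_eff <- pmax(ch$ts_energy, 0, ch$product_energy)
  barrier_f <- ts_eff
  barrier_r <- ts_eff - ch$product_energy
  reversible <- barrier_r < reversibility_ceiling
  k_f <- eyring_rate(barrier_f, temperature)
  k_r <- ifelse(reversible, eyring_rate(barrier_r, temperature), 0)
  out <- data.frame(name = ch$name, ligand = ch$ligand,
                    position = ch$position, barrier_f = barrier_f,
                    barrier_r = barrier_r, product_energy = ch$product_energy,
                    reversible = reversible, k_f = k_f, k_r = k_r,
                    stringsAsFactors = FALSE)
  structure(out, class = c("rate_set", "data.frame"),
            temperature = temperature,
            landscape_id = landscape_id(landscape),
            reversibility_ceiling = reversibility_ceiling)
}

#' Assemble a rate set directly from rate constants
#'
#' Mainly for tests and synthetic scenarios where no landscape exists.
#'
#' @param k_f,k_r Numeric vectors of forward/reverse rate constants (1/s);
#'   `k_r = 0` marks an irreversible channel.
#' @param name Channel names.
#' @param ligand Ligand labels (default `"X"`).
#' @param temperature Kelvin, recorded as metadata.
#' @return A `rate_set`.
#' @export
rate_set <- function(k_f, k_r = rep(0, length(k_f)),
                     name = paste0("ch", seq_along(k_f)),
                     ligand = rep("Cl", length(k_f)),
                     temperature = default_temperature()) {
  if (any(k_f < 0) || any(k_r < 0)) stop("rates must be nonnegative",
                                         call. = FALSE)
  out <- data.frame(name = name, ligand = ligand,
                    position = rep("equatorial", length(k_f)),
                    barrier_f = NA_real_, barrier_r = NA_real_,
                    product_energy = NA_real_, reversible = k_r > 0,
                    k_f = k_f, k_r = k_r, stringsAsFactors = FALSE)
  structure(out, class = c("rate_set", "data.frame"),
            temperature = temperature, landscape_id = "ad_hoc",
            reversibility_ceiling = NA_real_)
}

# stable characteristic roots of the reduced (reactant, reversible-product)
# system; the slow root comes from Vieta (det/lambda_fast) because det can
# sit many orders of magnitude below tr^2 and the textbook quadratic loses it
three_state_roots <- function(k1f, k1r, k2f) {
  tr <- -(k1f + k2f) - k1r
  det <- k2f * k1r
  disc <- (k1f + k2f - k1r)^2 + 4 * k1r * k1f # = tr^2 - 4*det
  l1 <- (tr - sqrt(disc)) / 2
  l2 <- if (l1 != 0) det / l1 else 0
  c(fast = l1, slow = l2)
}

# slowest relevant relaxation rate of a rate_set (for horizon = "auto")
slowest_rate <- function(rates, sink_rate = 0) {
  if (nrow(rates) <= 2L && sum(rates$k_r > 0) <= 1L && sink_rate == 0) {
    ord <- order(rates$k_r == 0)
    r <- rates[ord, ]
    k2f <- if (nrow(r) == 2L) r$k_f[2] else 0
    l <- three_state_roots(r$k_f[1], r$k_r[1], k2f)
    l <- abs(l[l != 0])
    if (length(l)) return(min(l))
    return(NA_real_)
  }
  ev <- eigen(rate_matrix(rates, sink_rate), only.values = TRUE)$values
  lam <- abs(Re(ev))
  # drop the conserved (numerically-zero) modes
  lam <- lam[lam > 1e-13 * max(lam, 1)]
  if (length(lam)) min(lam) else NA_real_
}

# rate matrix for x' = A x over species (reactant, products...)
rate_matrix <- function(rates, sink_rate = 0) {
  n <- nrow(rates)
  A <- matrix(0, n + 1L + (sink_rate > 0), n + 1L + (sink_rate > 0))
  A[1, 1] <- -(sum(rates$k_f) + sink_rate)
  for (i in seq_len(n)) {
    A[1, i + 1L] <- rates$k_r[i]
    A[i + 1L, 1] <- rates$k_f[i]
    A[i + 1L, i + 1L] <- -rates$k_r[i]
  }
  if (sink_rate > 0) A[n + 2L, 1] <- sink_rate
  A
}

#' Asymptotic product fractions of the rebound network
#'
#' Closed-form long-time limit of the first-order network with all population
#' starting in the reactant. If at least one channel is irreversible, every
#' reversible channel and the reactant drain to zero and the irreversible
#' products split in proportion to their forward rate constants (the net flux
#' into product i is `k_f[i] * integral(reactant)`, and reversible channels
#' carry no net asymptotic flux). If no channel is irreversible the network
#' relaxes to its equilibrium distribution, `1 : k_f/k_r` across reactant and
#' products.
#'
#' @param rates A `rate_set`.
#' @param sink_rate Optional first-order loss from the reactant (radical
#'   decomposition); treated as an extra irreversible channel `lost`.
#' @return Named vector of asymptotic fractions (reactant first).
#' @export
asymptotic_fractions <- function(rates, sink_rate = 0) {
  nm <- c("reactant", rates$name, if (sink_rate > 0) "lost")
  k_f <- c(rates$k_f, if (sink_rate > 0) sink_rate)
  k_r <- c(rates$k_r, if (sink_rate > 0) 0)
  irr <- k_r == 0 & k_f > 0
  frac <- numeric(length(k_f))
  if (any(irr)) {
    frac[irr] <- k_f[irr] / sum(k_f[irr])
    out <- c(0, frac)
  } else {
    w <- ifelse(k_f > 0, k_f / pmax(k_r, .Machine$double.xmin), 0)
    out <- c(1, w) / (1 + sum(w))
  }
  stats::setNames(out, nm)
}

#' Simulate the rebound network to a time horizon
#'
#' Integrates the linear first-order network (all population starting in the
#' reactant complex) with a stiff-capable integrator ([deSolve::lsoda()]) on
#' a fixed grid of `n_points` log-spaced time points. Species fractions are
#' conserved (sum to 1) by construction; the integration tolerances keep the
#' defect below 1e-6 and integration failure is an error with diagnostics,
#' never a silent truncation.
#'
#' @param rates A `rate_set` from [build_network()] or [rate_set()].
#' @param horizon Final time in seconds, or `"auto"` to integrate to ~30
#'   relaxation times of the slowest nonzero mode (effectively the asymptote).
#' @param n_points Number of output time points (log-spaced, plus t = 0).
#' @param atol,rtol Solver tolerances.
#' @param sink_rate Optional first-order loss from the reactant (1/s).
#' @return An object of class `time_course`: list with `time`, `fractions`
#'   (matrix, one column per species), `asymptotic` (see
#'   [asymptotic_fractions()]) and `meta`.
#' @export
simulate_network <- function(rates, horizon = default_horizon(),
                             n_points = 200, atol = 1e-12, rtol = 1e-9,
                             sink_rate = 0) {
  stopifnot(inherits(rates, "rate_set"))
  A <- rate_matrix(rates, sink_rate)
  if (identical(horizon, "auto")) {
    lam <- slowest_rate(rates, sink_rate)
    horizon <- if (is.finite(lam) && lam > 0) 30 / lam else 1
  }
  stopifnot_scalar_number(horizon, "horizon")
  if (horizon <= 0) stop("horizon must be positive", call. = FALSE)
  if (all(abs(A) < 1e-300)) {
    warning("all rate constants are zero at this temperature; ",
            "kinetics are frozen", call. = FALSE)
  }
  nsp <- nrow(A)
  x0 <- c(1, numeric(nsp - 1L))
  times <- c(0, 10^seq(log10(horizon) - 12, log10(horizon),
                       length.out = n_points - 1L))
  sol <- deSolve::lsoda(
    y = x0, times = times,
    func = function(t, y, p) list(as.vector(A %*% y)),
    parms = NULL, atol = atol, rtol = rtol, maxsteps = 100000)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    stop(sprintf("ODE solver failed (istate = %d) for landscape %s; ",
                 diagn[1], attr(rates, "landscape_id")), call. = FALSE)
  }
  if (nrow(sol) < length(times)) {
    stop("ODE solver returned a truncated solution; diagnostics: ",
         paste(utils::capture.output(deSolve::diagnostics(sol)),
               collapse = "\n"), call. = FALSE)
  }
  frac <- unname(sol[, -1, drop = FALSE])
  colnames(frac) <- c("reactant", rates$name, if (sink_rate > 0) "lost")
  structure(list(
    time = times, fractions = frac,
    asymptotic = asymptotic_fractions(rates, sink_rate),
    meta = list(landscape_id = attr(rates, "landscape_id"),
                temperature = attr(rates, "temperature"),
                horizon = horizon, atol = atol, rtol = rtol,
                sink_rate = sink_rate)),
    class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  end <- x$fractions[nrow(x$fractions), ]
  cat(sprintf("Time course for %s (%.4g s, %.2f K)\n", x$meta$landscape_id,
              x$meta$horizon, x$meta$temperature))
  cat("  fractions at horizon:",
      paste(sprintf("%s %.4f", names(end), end), collapse = ", "), "\n")
  invisible(x)
}

#' Fractions at the simulation horizon
#'
#' @param tc A `time_course`.
#' @return Named numeric vector of species fractions at the final time point.
#' @export
horizon_fractions <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  f <- tc$fractions[nrow(tc$fractions), ]
  stats::setNames(as.numeric(f), colnames(tc$fractions))
}

#' Closed-form solution of the three-state rebound system
#'
#' Analytic eigen-solution for reactant + one reversible channel + one
#' irreversible channel (or simpler degenerate cases), used as the
#' independent oracle against the ODE path. The reduced 2x2 system in
#' (reactant, reversible product) is diagonalised exactly; the irreversible
#' product follows by conservation.
#'
#' @param rates A `rate_set` with at most two channels, at most one of them
#'   reversible.
#' @param times Numeric vector of times (s).
#' @return Matrix of fractions, columns `reactant`, then the channels.
#' @export
analytic_three_state <- function(rates, times) {
  stopifnot(inherits(rates, "rate_set"))
  if (nrow(rates) > 2L || sum(rates$k_r > 0) > 1L) {
    stop("analytic solution covers at most two channels with at most one ",
         "reversible; use simulate_network()", call. = FALSE)
  }
  # order: reversible channel (if any) first
  ord <- order(rates$k_r == 0)
  r <- rates[ord, ]
  k1f <- r$k_f[1]; k1r <- r$k_r[1]
  k2f <- if (nrow(r) == 2L) r$k_f[2] else 0
  # reduced system in (reactant, channel-1 product):
  #   M = [ a b ; c d ], a = -(k1f+k2f), b = k1r, c = k1f, d = -k1r
  a <- -(k1f + k2f); c <- k1f
  roots <- three_state_roots(k1f, k1r, k2f)
  l1 <- unname(roots["fast"]); l2 <- unname(roots["slow"])
  if (abs(l1 - l2) < 1e-14 * max(abs(l1), 1e-300)) {
    l2 <- l2 * (1 - 1e-9) # degenerate pair: nudge to keep the form generic
  }
  Rfrac <- if (l1 == l2) {
    exp(l1 * times)
  } else {
    ((a - l2) * exp(l1 * times) + (l1 - a) * exp(l2 * times)) / (l1 - l2)
  }
  P1 <- if (l1 == l2) {
    c * times * exp(l1 * times)
  } else {
    c * (exp(l1 * times) - exp(l2 * times)) / (l1 - l2)
  }
  Rfrac <- pmin(pmax(Rfrac, 0), 1)
  P1 <- pmin(pmax(P1, 0), 1)
  P2 <- pmax(1 - Rfrac - P1, 0)
  m <- cbind(reactant = Rfrac, P1, P2)
  colnames(m) <- c("reactant", r$name[1],
                   if (nrow(r) == 2L) r$name[2] else "unused")
  if (nrow(r) == 1L) m <- m[, 1:2, drop = FALSE]
  m[, c("reactant", rates$name), drop = FALSE]
}

#' Feasibility of the back reaction for each channel
#'
#' A product complex can revert to the reactant complex (e.g. a ferrous
#' complex plus alkyl halide undergoing back electron transfer with homolytic
#' C-X cleavage) when the reverse barrier is surmountable at the run
#' temperature. Feasible iff `ts - product <= threshold` (boundary included).
#'
#' @param landscape An [energy_landscape()].
#' @param temperature Kelvin (recorded; the rule itself is a barrier cutoff).
#' @param threshold Feasibility threshold, kcal/mol.
#' @return `data.frame` with `name`, `ligand`, `reverse_barrier`, `feasible`.
#' @export
reverse_feasibility <- function(landscape,
                                temperature = default_temperature(),
                                threshold = 25) {
  validate_landscape(landscape)
  ch <- landscape$channels
  rb <- pmax(ch$ts_energy, 0, ch$product_energy) - ch$product_energy
  data.frame(name = ch$name, ligand = ch$ligand, reverse_barrier = rb,
             feasible = rb <= threshold, stringsAsFactors = FALSE)
}
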