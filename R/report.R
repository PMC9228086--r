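#' Run configuration
#'
#' Bundles the knobs of a reproduction run. The defaults are the conditions
#' of the packaged study: 363.15 K, a 12 h horizon, the 30 kcal/mol
#' reversibility ceiling and 25 kcal/mol reverse-feasibility threshold, a
#' 0.9 fraction margin for a unique selectivity call and a 0.5 kcal/mol
#' barrier tie window.
#'
#' @param temperature Kelvin.
#' @param horizon Seconds.
#' @param margin,barrier_tie Selectivity-call thresholds.
#' @param reversibility_ceiling,feasibility_threshold kcal/mol.
#' @param atol,rtol ODE tolerances.
#' @param seed Integer seed (the reproduction itself is deterministic; the
#'   seed feeds any synthetic stages).
#' @param format Report format, `"json"` or `"text"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(temperature = default_temperature(),
                       horizon = default_horizon(), margin = 0.9,
                       barrier_tie = 0.5, reversibility_ceiling = 30,
                       feasibility_threshold = 25, atol = 1e-12, rtol = 1e-9,
                       seed = 1L, format = c("json", "text")) {
  format <- match.arg(format)
  structure(list(temperature = temperature, horizon = horizon,
                 margin = margin, barrier_tie = barrier_tie,
                 reversibility_ceiling = reversibility_ceiling,
                 feasibility_threshold = feasibility_threshold,
                 atol = atol, rtol = rtol, seed = as.integer(seed),
                 format = format),
            class = "run_config")
}

#' Serialise / deserialise a run configuration
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config` returns a [run_config()]; the writer returns
#'   `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  doc <- jsonlite::fromJSON(path)
  do.call(run_config, doc)
}

#' Reproduce the packaged analysis end to end
#'
#' Runs every stage of the analysis over the packaged fixtures and compares
#' each result with the packaged expected values: the six VB barriers from a
#' single calibrated gap set (two fitted excitation terms, four out-of-sample
#' predictions), the two diabatic driving forces, the kinetic selectivity
#' call for every packaged landscape, the BEP flags, the equatorial/distal
#' comparison for the dichloride, and the second-sphere perturbation ledger.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage log lines.
#' @return An object of class `reproduction_report`: list of stage results,
#'   each with a `pass` flag, plus `ok` (all stages pass).
#' @export
run_reproduction <- function(config = run_config(), quiet = FALSE) {
  log_line <- function(...) if (!quiet) message(sprintf(...))
  expected <- jsonlite::fromJSON(hx_extdata("expected_reproduction.json"))
  tbl <- hx_bde_table()
  gaps <- calibrate_excitation_terms()
  log_line("stage=calibration source=packaged-anchors sigma_exc=%.2f pi_exc=%.2f",
           gaps$exc_sigma_to_pixy, gaps$exc_pi_to_pixy)

  systems <- data.frame(complex = "1Cl",
                        radical = c("trityl", "PP", "PM"),
                        stringsAsFactors = FALSE)
  barriers <- predict_barrier_table(tbl, gaps, systems)
  key <- paste(barriers$complex, barriers$radical, barriers$channel, sep = ".")
  bar_pass <- vapply(names(expected$vb_barriers), function(k) {
    abs(barriers$barrier[key == k] - expected$vb_barriers[[k]]) <=
      expected$vb_barrier_tolerance
  }, logical(1))
  log_line("stage=vb_barriers source=packaged-table n=%d pass=%d/%d",
           nrow(barriers), sum(bar_pass), length(bar_pass))

  dF <- c(Cl = driving_force(metal_bde(tbl, "1Cl", "Cl"),
                             cx_bde(tbl, "trityl", "Cl")),
          OH = driving_force(metal_bde(tbl, "1Cl", "OH"),
                             cx_bde(tbl, "trityl", "OH")))
  dF_pass <- all(abs(dF - unlist(expected$driving_forces)[names(dF)]) < 1e-9)
  log_line("stage=driving_forces Cl=%.1f OH=%.1f pass=%s", dF["Cl"], dF["OH"],
           dF_pass)

  calls <- vapply(names(expected$selectivity_calls), function(id) {
    selectivity_call(hx_landscape(id), temperature = config$temperature,
                     horizon = config$horizon, margin = config$margin,
                     barrier_tie = config$barrier_tie,
                     reversibility_ceiling = config$reversibility_ceiling)$call
  }, character(1))
  call_pass <- calls == unlist(expected$selectivity_calls)[names(calls)]
  log_line("stage=selectivity source=packaged-landscapes pass=%d/%d",
           sum(call_pass), length(call_pass))

  beps <- vapply(names(expected$bep_flags), function(id) {
    l <- hx_landscape(id)
    bep_check(l$channels$ts_energy, l$channels$product_energy)
  }, character(1))
  bep_pass <- beps == unlist(expected$bep_flags)[names(beps)]

  pos <- position_compare(hx_landscape("2Cl_trityl"))
  pos_pass <- pos$preferred == expected$position_2Cl$preferred &&
    abs(pos$gap - expected$position_2Cl$gap) < 1e-9

  ledg <- perturbation_ledger(hx_truncation_barriers())
  ledg_pass <- all(
    ledg$lowest == unlist(expected$perturbation_lowest)[ledg$variant],
    abs(ledg$gap - unlist(expected$perturbation_gaps)[ledg$variant]) < 1e-9,
    ledg$bep[ledg$variant == "neither"] == expected$perturbation_bep$neither)
  log_line("stage=ledgers bep_pass=%s position_pass=%s perturbation_pass=%s",
           all(bep_pass), pos_pass, ledg_pass)

  structure(list(
    config = config,
    calibrated_gaps = gaps,
    vb_barriers = list(table = barriers, pass = bar_pass),
    driving_forces = list(values = dF, pass = dF_pass),
    selectivity = list(calls = calls, pass = call_pass),
    bep = list(flags = beps, pass = bep_pass),
    position = c(pos, list(pass = pos_pass)),
    perturbation = list(ledger = ledg, pass = ledg_pass),
    ok = all(bar_pass, dF_pass, call_pass, bep_pass, pos_pass, ledg_pass)),
    class = "reproduction_report")
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}

format_report_text <- function(report) {
  b <- report$vb_barriers$table
  c("haloselect reproduction report (format v1)",
    sprintf("temperature %.2f K, horizon %.0f s", report$config$temperature,
            report$config$horizon),
    "",
    "VB barriers (kcal/mol):",
    sprintf("  %-6s %-7s %-12s %6.1f  (dErp %5.1f, B %5.1f)",
            b$complex, b$radical, b$channel, b$barrier, b$dErp, b$B),
    sprintf("  anchors + predictions pass: %d/%d",
            sum(report$vb_barriers$pass), length(report$vb_barriers$pass)),
    "",
    sprintf("Driving forces: Cl %.1f, OH %.1f (pass: %s)",
            report$driving_forces$values["Cl"],
            report$driving_forces$values["OH"], report$driving_forces$pass),
    "",
    "Selectivity calls:",
    sprintf("  %-12s %-22s pass=%s", names(report$selectivity$calls),
            report$selectivity$calls, report$selectivity$pass),
    "",
    sprintf("BEP flags: %s (pass: %s)",
            paste(names(report$bep$flags), report$bep$flags, collapse = ", "),
            all(report$bep$pass)),
    sprintf("2Cl position: %s by %.1f kcal/mol (pass: %s)",
            report$position$preferred, report$position$gap,
            report$position$pass),
    "",
    "Second-sphere perturbation ledger:",
    sprintf("  %-10s OH %5.1f  X %5.1f  lowest %-3s gap %4.1f  BEP %s",
            report$perturbation$ledger$variant,
            report$perturbation$ledger$oh_barrier,
            report$perturbation$ledger$x_barrier,
            report$perturbation$ledger$lowest,
            report$perturbation$ledger$gap,
            report$perturbation$ledger$bep),
    "",
    sprintf("overall: %s", if (report$ok) "PASS" else "FAIL"))
}

#' Write a reproduction report
#'
#' JSON (machine) or plain-text (human) forms, both versioned and
#' deterministic (two runs with the same config produce byte-identical
#' files).
#'
#' @param report A `reproduction_report`.
#' @param path Output path.
#' @param format `"json"` or `"text"` (default: the config's format).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = report$config$format) {
  if (format == "text") {
    writeLines(format_report_text(report), path)
  } else {
    doc <- list(
      format_version = 1L,
      config = unclass(report$config),
      calibrated_excitation = list(
        sigma = report$calibrated_gaps$exc_sigma_to_pixy,
        pi = report$calibrated_gaps$exc_pi_to_pixy),
      vb_barriers = report$vb_barriers$table,
      vb_pass = as.list(report$vb_barriers$pass),
      driving_forces = as.list(report$driving_forces$values),
      selectivity_calls = as.list(report$selectivity$calls),
      selectivity_pass = as.list(report$selectivity$pass),
      bep_flags = as.list(report$bep$flags),
      position_2Cl = report$position[c("preferred", "gap", "pass")],
      perturbation_ledger = report$perturbation$ledger,
      ok = report$ok)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = 8,
                         pretty = TRUE)
  }
  invisible(path)
}
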