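calibrated <- calibrate_excitation_terms()
table1 <- hx_bde_table()

test_that("calibration reproduces both full-system anchor barriers", {
  expect_true(calibrated$calibrated)
  x <- vb_barrier(vb_channel_input("X_transfer", 63.8, 46.2,
                                   calibrated$sigma_gap,
                                   calibrated$exc_sigma_to_pixy))
  oh <- vb_barrier(vb_channel_input("OH_transfer", 75.0, 59.2,
                                    calibrated$pi_gap,
                                    calibrated$exc_pi_to_pixy))
  expect_equal(x$barrier, 25.4, tolerance = 0.05 / 25.4)
  expect_equal(oh$barrier, 23.5, tolerance = 0.05 / 23.5)
})

test_that("one calibrated gap set predicts the secondary-radical barriers", {
  systems <- data.frame(complex = "1Cl", radical = c("trityl", "PP", "PM"))
  b <- predict_barrier_table(table1, calibrated, systems)
  expect_equal(nrow(b), 6L)
  got <- function(r, ch) b$barrier[b$radical == r & b$channel == ch]
  expect_equal(got("PP", "X_transfer"), 16.3, tolerance = 0.5 / 16.3)
  expect_equal(got("PM", "X_transfer"), 7.9, tolerance = 0.5 / 7.9)
  expect_equal(got("PP", "OH_transfer"), 15.1, tolerance = 0.5 / 15.1)
  expect_equal(got("PM", "OH_transfer"), 9.4, tolerance = 0.5 / 9.4)
  # deterministic ordering and empty-input behaviour
  expect_identical(b$radical, rep(c("trityl", "PP", "PM"), each = 2L))
  empty <- predict_barrier_table(table1, calibrated,
                                 data.frame(complex = character(),
                                            radical = character()))
  expect_equal(nrow(empty), 0L)
  expect_error(
    predict_barrier_table(table1, calibrated,
                          data.frame(complex = "9Zz", radical = "trityl")),
    "9Zz")
})

test_that("barrier differences across substrates equal driving-force shifts", {
  # with the gap terms shared, DeltaE^(PP) - DeltaE^(PM) must equal the
  # change in (dErp/2 - B); the printed barriers satisfy this to <= 0.2
  systems <- data.frame(complex = "1Cl", radical = c("PP", "PM"))
  b <- predict_barrier_table(table1, calibrated, systems)
  for (ch in c("X_transfer", "OH_transfer")) {
    sub <- b[b$channel == ch, ]
    lhs <- diff(sub$barrier)
    rhs <- diff(sub$dErp / 2 - sub$B)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  # and against the printed values themselves
  printed <- c(PP_X = 16.3, PM_X = 7.9, PP_OH = 15.1, PM_OH = 9.4)
  expect_lt(abs((printed["PP_X"] - printed["PM_X"]) -
                  (b$dErp[b$radical == "PP" & b$channel == "X_transfer"] / 2 -
                     b$B[b$radical == "PP" & b$channel == "X_transfer"] -
                     b$dErp[b$radical == "PM" & b$channel == "X_transfer"] / 2 +
                     b$B[b$radical == "PM" & b$channel == "X_transfer"])), 0.2)
})

test_that("the barrier rises with driving force and falls with resonance", {
  # vary the metal bond above the fixed C-X bond: dErp sweeps, B is pinned
  cx <- 40
  barriers <- vapply(seq(45, 90, by = 2.5), function(m) {
    vb_barrier(vb_channel_input("X_transfer", m, cx, 88.8, 30))$barrier
  }, numeric(1))
  expect_true(all(diff(barriers) > 0))
  # decomposition identity: barrier = gap_term + dErp/2 - B, exactly
  set.seed(21)
  for (i in 1:25) {
    m <- runif(1, 30, 100); cxv <- runif(1, 30, 100)
    est <- vb_barrier(vb_channel_input("OH_transfer", m, cxv, 99.2, 36.4))
    expect_equal(est$barrier,
                 est$decomposition$gap_term +
                   est$decomposition$driving_force / 2 -
                   est$decomposition$resonance_B, tolerance = 1e-12)
    expect_gte(est$barrier_clamped, 0)
  }
  # cancellation case: equal bonds give barrier = gap_term - b/2 exactly
  b <- 50
  est <- vb_barrier(vb_channel_input("X_transfer", b, b, 88.8, 30))
  expect_equal(est$barrier, est$decomposition$gap_term - b / 2)
  expect_equal(est$decomposition$driving_force, 0)
})

test_that("a missing excitation term is an explicit uncalibrated error", {
  raw <- hx_orbital_gaps()
  expect_false(raw$calibrated)
  expect_true(raw$sigma_gap < raw$pi_gap) # the sigma pair is the weaker bond
  inp <- vb_channel_input("X_transfer", 63.8, 46.2, raw$sigma_gap,
                          raw$exc_sigma_to_pixy)
  expect_error(vb_barrier(inp), "uncalibrated")
})

test_that("calibration is idempotent and anchor-order independent", {
  gaps <- hx_orbital_gaps()
  anchors <- list(
    vb_channel_input("X_transfer", 63.8, 46.2, gaps$sigma_gap),
    vb_channel_input("OH_transfer", 75.0, 59.2, gaps$pi_gap))
  g1 <- calibrate_excitation_terms(anchors, c(25.4, 23.5), gaps)
  g2 <- calibrate_excitation_terms(rev(anchors), c(23.5, 25.4), gaps)
  expect_equal(g1$exc_sigma_to_pixy, g2$exc_sigma_to_pixy)
  expect_equal(g1$exc_pi_to_pixy, g2$exc_pi_to_pixy)
  # fixed point: anchors computed from a complete set return that set
  b_x <- vb_barrier(vb_channel_input("X_transfer", 63.8, 46.2, g1$sigma_gap,
                                     g1$exc_sigma_to_pixy))$barrier
  b_oh <- vb_barrier(vb_channel_input("OH_transfer", 75.0, 59.2, g1$pi_gap,
                                      g1$exc_pi_to_pixy))$barrier
  g3 <- calibrate_excitation_terms(anchors, c(b_x, b_oh), g1)
  expect_equal(g3$exc_sigma_to_pixy, g1$exc_sigma_to_pixy, tolerance = 1e-10)
  expect_equal(g3$exc_pi_to_pixy, g1$exc_pi_to_pixy, tolerance = 1e-10)
})

test_that("predictions are invariant to the crossing-fraction choice", {
  gaps <- hx_orbital_gaps()
  systems <- data.frame(complex = "1Cl", radical = c("PP", "PM"))
  preds <- lapply(c(0.25, 1 / 3, 0.5), function(f) {
    anchors <- list(
      vb_channel_input("X_transfer", 63.8, 46.2, gaps$sigma_gap),
      vb_channel_input("OH_transfer", 75.0, 59.2, gaps$pi_gap))
    g <- calibrate_excitation_terms(anchors, c(25.4, 23.5), gaps,
                                    crossing_fraction = f)
    predict_barrier_table(table1, g, systems, crossing_fraction = f)$barrier
  })
  expect_equal(preds[[1]], preds[[2]], tolerance = 1e-10)
  expect_equal(preds[[2]], preds[[3]], tolerance = 1e-10)
})

test_that("barrier tables are written with one-decimal formatting", {
  systems <- data.frame(complex = "1Cl", radical = "trityl")
  b <- predict_barrier_table(table1, calibrated, systems)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_barrier_table(b, f)
  lines <- readLines(f)
  expect_equal(length(lines), 3L)
  expect_match(lines[2], "^1Cl\ttrityl\tX_transfer\tCl\t25\\.4\t17\\.6\t23\\.1\t39\\.7\tTRUE$")
})
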