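test_that("Eyring rates match the closed form and the ratio identity", {
  # prefactor limit: kB*T/h at zero barrier (constants evaluated inline)
  kB <- 1.380649e-23; h <- 6.62607015e-34; Rk <- 1.987204e-3
  expect_equal(eyring_rate(0, 298.15), kB * 298.15 / h, tolerance = 1e-12)
  expect_equal(eyring_rate(0, 298.15), 6.21e12, tolerance = 1e-3)
  # the 13.2 kcal/mol halogen-transfer barrier at the run temperature
  expect_equal(eyring_rate(13.2, 363.15),
               (kB * 363.15 / h) * exp(-13.2 / (Rk * 363.15)),
               tolerance = 1e-12)
  set.seed(31)
  for (i in 1:20) {
    b1 <- runif(1, 0, 30); b2 <- runif(1, 0, 30); T <- runif(1, 250, 400)
    expect_equal(eyring_rate(b1, T) / eyring_rate(b2, T),
                 exp((b2 - b1) / (Rk * T)), tolerance = 1e-9)
  }
  expect_error(eyring_rate(-0.1), "negative")
  expect_error(eyring_rate(5, -10), "temperature")
})

test_that("build_network classifies reversibility from reverse barriers", {
  # chloride transfer equilibrates in the cage; hydroxylation cannot revert
  rates <- build_network(hx_landscape("1Cl_trityl"), 363.15)
  cl <- rates[rates$name == "Cl", ]; oh <- rates[rates$name == "OH", ]
  expect_true(cl$reversible)
  expect_equal(cl$barrier_r, 24.6 - 5.5)
  expect_false(oh$reversible)
  expect_equal(oh$barrier_r, 23.2 + 20.0)
  expect_identical(oh$k_r, 0)
  # thermoneutral single channel: k_f equals k_r exactly
  land <- energy_landscape("1Cl", "trityl", data.frame(
    name = "X", ligand = "Cl", position = "equatorial",
    ts_energy = 10, product_energy = 0, reversible = TRUE))
  r <- build_network(land, 363.15)
  expect_identical(r$k_f, r$k_r)
  # strongly exergonic secondary-radical channels are irreversible
  r_pm <- build_network(hx_landscape("1Cl_PM"), 363.15)
  expect_false(any(r_pm$reversible))
  # a product above its own TS is a landscape inconsistency
  bad <- hx_landscape("1Cl_trityl")
  bad$channels$product_energy[1] <- bad$channels$ts_energy[1] + 0.3
  expect_error(build_network(bad, 363.15), "inconsistency")
})

test_that("detailed balance holds for every reversible channel", {
  Rk <- 1.987204e-3
  set.seed(32)
  for (i in 1:50) {
    p <- runif(1, -5, 12)
    ts <- max(0, p) + runif(1, 0.2, 15)
    land <- energy_landscape("s", "s", data.frame(
      name = "X", ligand = "Cl", position = "equatorial",
      ts_energy = ts, product_energy = p, reversible = TRUE))
    T <- runif(1, 270, 400)
    r <- build_network(land, T)
    expect_true(r$reversible)
    expect_equal(r$k_f / r$k_r, exp(-p / (Rk * T)), tolerance = 1e-9)
  }
})

test_that("the network simulator conserves mass and hits known limits", {
  # single irreversible channel: everything ends in the product
  tc <- simulate_network(rate_set(k_f = 2.5), horizon = "auto")
  expect_equal(unname(horizon_fractions(tc)["ch1"]), 1, tolerance = 1e-6)
  # two irreversible channels with equal barriers: a clean 0.5/0.5 split
  land <- energy_landscape("s", "s", data.frame(
    name = c("A", "B"), ligand = c("Cl", "OH"),
    position = c("equatorial", "distal"),
    ts_energy = c(12, 12), product_energy = c(-40, -40),
    reversible = c(FALSE, FALSE)))
  tc <- simulate_network(build_network(land, 363.15), horizon = "auto")
  f <- horizon_fractions(tc)
  expect_equal(unname(f["A"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(f["B"]), 0.5, tolerance = 1e-6)
  # conservation across random bifurcated landscapes
  set.seed(33)
  for (i in 1:100) {
    land <- random_bifurcated_landscape()
    tc <- simulate_network(build_network(land, 363.15), horizon = "auto")
    expect_lt(max(abs(rowSums(tc$fractions) - 1)), 1e-6)
  }
})

test_that("irreversible hydroxylation wins even against a faster halide", {
  # the 1Br landscape: Br transfer is 10 kcal/mol faster but endergonic and
  # reversible, so the asymptotic product is still the alcohol
  rates <- build_network(hx_landscape("1Br_trityl"), 363.15)
  expect_lt(rates$barrier_f[rates$name == "Br"],
            rates$barrier_f[rates$name == "OH"])
  tc <- simulate_network(rates, horizon = "auto")
  f <- horizon_fractions(tc)
  expect_gt(unname(f["OH"]), 0.999)
  # ODE path against the closed-form solution: tight at the endpoint, and
  # within solver accuracy across the whole transient
  an <- analytic_three_state(rates, tc$time)
  expect_lt(max(abs(f - an[nrow(an), colnames(tc$fractions)])), 1e-4)
  expect_lt(max(abs(tc$fractions - an[, colnames(tc$fractions)])), 1e-3)
  expect_equal(unname(tc$asymptotic["OH"]), 1)
})

test_that("asymptotic fractions follow flux partitioning and equilibrium", {
  # two irreversible channels split in proportion to forward rates
  r <- rate_set(k_f = c(3, 1))
  expect_equal(unname(asymptotic_fractions(r)), c(0, 0.75, 0.25))
  # all-reversible network relaxes to its equilibrium distribution
  r2 <- rate_set(k_f = c(2, 4), k_r = c(1, 8))
  expect_equal(unname(asymptotic_fractions(r2)),
               c(1, 2, 0.5) / 3.5, tolerance = 1e-12)
  tc <- simulate_network(r2, horizon = "auto")
  expect_equal(unname(horizon_fractions(tc)), unname(asymptotic_fractions(r2)),
               tolerance = 1e-6)
})

test_that("an optional first-order sink drains the reactant", {
  r <- rate_set(k_f = 1, k_r = 2) # reversible, endergonic-ish channel
  tc <- simulate_network(r, horizon = "auto", sink_rate = 0.5)
  f <- horizon_fractions(tc)
  expect_equal(unname(f["lost"]), 1, tolerance = 1e-4)
  expect_lt(max(abs(rowSums(tc$fractions) - 1)), 1e-6)
})

test_that("reverse feasibility applies the barrier threshold inclusively", {
  fz <- reverse_feasibility(hx_landscape("1Br_trityl"), threshold = 25)
  expect_true(fz$feasible[fz$name == "Br"])     # reverse barrier 7.2
  expect_equal(fz$reverse_barrier[fz$name == "Br"], 13.2 - 6.0)
  expect_false(fz$feasible[fz$name == "OH"])    # reverse barrier 43.6
  # boundary convention: exactly at the threshold is feasible
  land <- energy_landscape("s", "s", data.frame(
    name = "X", ligand = "Cl", position = "equatorial",
    ts_energy = 20, product_energy = -5, reversible = TRUE))
  expect_true(reverse_feasibility(land, threshold = 25)$feasible)
})
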