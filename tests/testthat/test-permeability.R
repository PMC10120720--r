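test_that("cumulative_basolateral_amount credits withdrawn mass back", {
  g <- transwell_geometry(sample_volume = 5e-5)
  # single sample: Q = C Vb
  q1 <- cumulative_basolateral_amount(0.02, 0, g)
  expect_equal(q1$amount, 0.02 * 1.5e-3)
  # hand arithmetic from the three-sample series
  q <- cumulative_basolateral_amount(c(0, 0.01, 0.02), c(0, 15, 30), g)
  expect_equal(q$amount[3], 0.02 * 1.5e-3 + (0 + 0.01) * 5e-5)
  expect_equal(q$amount[3], 3.05e-5)
  # all-zero series
  expect_equal(cumulative_basolateral_amount(rep(0, 4), c(0, 15, 30, 45),
                                             g)$amount, rep(0, 4))
  expect_error(cumulative_basolateral_amount(c(0, 1), c(15, 10), g),
               "increasing")
})

test_that("apparent_permeability inverts a constructed constant flux", {
  pe_true <- 5.0e-6; area <- 1.12; c0 <- 2
  slope <- pe_true * 60 / 1000 * area * c0      # umol/min
  tt <- seq(0, 60, by = 15)
  Q <- data.frame(time = tt, amount = slope * tt)
  res <- apparent_permeability(Q, c0 = c0, area = area)
  expect_equal(res$pe_app, pe_true, tolerance = 1e-12)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)

  # constant Q -> zero permeability
  Qc <- data.frame(time = tt, amount = rep(3e-5, length(tt)))
  expect_equal(apparent_permeability(Qc, c0 = c0, area = area)$pe_app, 0)

  # Pe scales as 1/C0 at fixed flux
  res2 <- apparent_permeability(Q, c0 = 2 * c0, area = area)
  expect_equal(res2$pe_app, res$pe_app / 2, tolerance = 1e-12)

  expect_error(apparent_permeability(Q[1:2, ], c0 = c0), ">= 3 points")
  expect_error(apparent_permeability(Q, c0 = 0), "c0")
})

test_that("sampling correction makes Pe schedule-invariant for constant flux", {
  pe_true <- 4.8e-6; area <- 1.12; c0 <- 2
  g <- transwell_geometry()
  flux <- pe_true * 60 / 1000 * area * c0       # umol/min
  simulate_series <- function(times) {
    # receiver concentration series under withdrawals, constant influx
    n_b <- 0; conc <- numeric(length(times)); t_prev <- 0
    for (i in seq_along(times)) {
      n_b <- n_b + flux * (times[i] - t_prev)
      conc[i] <- n_b / g$basolateral_volume
      n_b <- n_b - conc[i] * g$sample_volume
      t_prev <- times[i]
    }
    conc
  }
  pe_of <- function(times) {
    conc <- simulate_series(times)
    Q <- cumulative_basolateral_amount(conc, times, g)
    apparent_permeability(Q, c0 = c0, area = area)$pe_app
  }
  expect_equal(pe_of(seq(0, 60, 15)), pe_true, tolerance = 1e-10)
  expect_equal(pe_of(c(0, 5, 20, 33, 60)), pe_true, tolerance = 1e-10)
})

test_that("simulator round trip recovers Pe within the stated bands", {
  cfg <- simulation_config(seed = 5, noise_model = "none")
  assay <- simulate_transwell(cfg)
  pe <- assay_permeability(assay)
  truth <- attr(assay, "truth")
  pe_c14 <- pe$pe_app[pe$channel == "C14"][1]
  pe_h3 <- pe$pe_app[pe$channel == "H3"][1]
  # sucrose: near-constant C0 regime
  expect_lt(abs(pe_c14 / truth[["C14"]] - 1), 0.02)
  # ROH: small finite-sink deviation allowed
  expect_lt(abs(pe_h3 / truth[["H3"]] - 1), 0.05)
})

test_that("mass_balance closes exactly on noiseless simulations", {
  assay <- simulate_transwell(simulation_config(seed = 2,
                                                noise_model = "none"))
  mb <- mass_balance(assay)
  expect_true(all(abs(mb$fraction_recovered - 1) < 1e-9))
  expect_true(all(mb[, c("apical_end", "apical_sampled", "basolateral",
                         "lysate")] >= 0))
})

test_that("mass_balance stays near closure under counting noise", {
  fr <- vapply(1:25, function(s) {
    assay <- simulate_transwell(simulation_config(
      seed = s, noise_model = "gaussian_cv", noise_scale = 0.02))
    mean(mass_balance(assay)$fraction_recovered)
  }, numeric(1))
  expect_gt(mean(fr), 0.97)
  expect_lt(mean(fr), 1.03)
})

test_that("mass_balance reports which compartment is missing", {
  assay <- simulate_transwell(simulation_config(seed = 2,
                                                noise_model = "none"))
  assay$data <- assay$data[assay$data$compartment != "lysate", ]
  expect_error(mass_balance(assay), "lysate")
})

test_that("normalize_basolateral collapses proportional curves", {
  tt <- seq(0, 60, 15)
  base <- 1e-4 * tt
  c0s <- c(0.1, 0.4, 2)
  curves <- lapply(c0s, function(c0) base * c0)
  normed <- mapply(normalize_basolateral, curves, c0s)
  expect_lt(max(abs(normed[, 1] - normed[, 2])), 1e-9)
  expect_lt(max(abs(normed[, 1] - normed[, 3])), 1e-9)
  # reference equal to the series -> all ones
  expect_equal(normalize_basolateral(rep(2, 4), 2), rep(1, 4))
  # non-proportional references do not collapse
  cell_conc <- c(9, 36, 320)
  normed2 <- mapply(normalize_basolateral, curves, cell_conc)
  expect_gt(max(abs(normed2[, 1] - normed2[, 3])), 1e-9)
  expect_error(normalize_basolateral(base, 0), "reference")
})

test_that("transwell_geometry validates fields", {
  expect_error(transwell_geometry(membrane_area = 0), "> 0")
  expect_error(transwell_geometry(sample_volume = 2e-3), "smaller")
})
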