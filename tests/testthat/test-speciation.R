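test_that("solve_binary matches the closed form, the oracle and edge cases", {
  # 2 uM ROH + 2 uM RBP at KD 0.1: the published partitioning
  res <- solve_binary(2, 2, 0.1)
  expect_equal(unname(res["free"]), 0.4)
  expect_equal(unname(res["bound"]), 1.6)

  # no protein: everything free
  expect_equal(solve_binary(2, 0, 0.1), c(free = 2, bound = 0))

  # symmetric unit case: bound = (3 - sqrt(5))/2, frozen from the bisection
  # oracle on the scalar residual
  res <- solve_binary(1, 1, 1)
  expect_equal(unname(res["bound"]), 0.38196601125010515, tolerance = 1e-12)
  expect_equal(unname(res["bound"]), oracle_binary_bound(1, 1, 1),
               tolerance = 1e-10)
  expect_equal(unname(res["free"]), 1 - unname(res["bound"]))

  # random cases vs bisection oracle
  set.seed(42)
  for (i in 1:25) {
    L <- runif(1, 0.01, 10); P <- runif(1, 0.01, 10); kd <- runif(1, 0.01, 1)
    expect_equal(unname(solve_binary(L, P, kd)["bound"]),
                 oracle_binary_bound(L, P, kd), tolerance = 1e-9)
  }

  # infinite KD abolishes the complex
  expect_equal(unname(solve_binary(2, 2, Inf)["bound"]), 0)
  expect_error(solve_binary(-1, 2, 0.1), "finite and >= 0")
  expect_error(solve_binary(2, 2, 0), "kd must be > 0")
})

test_that("solve_ternary reproduces the published carrier distribution", {
  st <- solve_ternary(equilibrium_system(2, 2, 4, 0.1, 0.25))
  expect_equal(st$free_roh, 0.14, tolerance = 0.01 / 0.14)
  expect_lt(abs(st$free_roh - 0.14), 0.01)
  expect_lt(abs(st$holo_rbp - 0.18), 0.01)
  expect_lt(abs(st$ternary - 1.68), 0.01)
  expect_speciation_invariants(st)
})

test_that("solve_ternary degenerates to solve_binary without TTR", {
  st <- solve_ternary(equilibrium_system(2, 2, 0, 0.1, 0.25))
  bin <- solve_binary(2, 2, 0.1)
  expect_equal(st$free_roh, unname(bin["free"]), tolerance = 1e-9)
  expect_equal(st$holo_rbp, unname(bin["bound"]), tolerance = 1e-9)
  expect_equal(st$ternary, 0)
})

test_that("mutant variants abolish the ternary complex", {
  for (v in c("muRBP", "muTTR")) {
    st <- solve_ternary(equilibrium_system(2, 2, 4, variant = v))
    expect_equal(st$ternary, 0)
    expect_equal(st$free_roh, 0.4, tolerance = 1e-9)
    expect_equal(st$holo_rbp, 1.6, tolerance = 1e-9)
  }
})

test_that("solve_ternary matches the bisection oracle on random systems", {
  systems <- random_equilibrium_systems(60, seed = 7)
  for (sys in systems) {
    st <- solve_ternary(sys)
    orc <- oracle_ternary(sys$total_roh, sys$total_rbp, sys$total_ttr,
                          sys$kd_roh_rbp, sys$kd_holo_ttr)
    expect_lt(abs(st$free_roh - orc$free_roh), 1e-6)
    expect_lt(abs(st$ternary - orc$ternary), 1e-6)
    expect_speciation_invariants(st)
  }
})

test_that("free ROH decreases and ternary increases with added TTR", {
  ttrs <- c(0, 0.5, 1, 2, 4, 8, 16)
  sts <- lapply(ttrs, function(T)
    solve_ternary(equilibrium_system(2, 2, T, 0.1, 0.25)))
  free <- vapply(sts, `[[`, 0, "free_roh")
  tern <- vapply(sts, `[[`, 0, "ternary")
  expect_true(all(diff(free) <= 1e-12))
  expect_true(all(diff(tern) >= -1e-12))
})

test_that("the ternary solution is continuous in the TTR -> 0 limit", {
  bin <- solve_binary(2, 2, 0.1)
  for (T in 10^(-c(3, 5, 7))) {
    st <- solve_ternary(equilibrium_system(2, 2, T, 0.1, 0.25))
    expect_equal(st$free_roh, unname(bin["free"]), tolerance = 10 * T)
  }
})

test_that("fraction_free gives the published percentages and errors on 0", {
  st_rbp <- solve_ternary(equilibrium_system(2, 2, 0))
  expect_equal(fraction_free(st_rbp), 20)
  st_ttr <- solve_ternary(equilibrium_system(2, 2, 4))
  expect_lt(abs(fraction_free(st_ttr) - 7), 0.5)
  st_none <- solve_ternary(equilibrium_system(2, 0, 0))
  expect_equal(fraction_free(st_none), 100)
  expect_error(fraction_free(st_rbp, total_roh = 0), "total_roh")
})

test_that("speciation_table reproduces all delivery-mode rows", {
  tab <- speciation_table()
  expect_equal(nrow(tab), 5)
  ref <- data.frame(
    mode = c("free", "ROH-RBP", "ROH-muRBP", "ROH-RBP-TTR", "ROH-RBP-muTTR"),
    free_roh = c(2, 0.4, 0.4, 0.13, 0.4),
    roh_rbp = c(0, 1.6, 1.6, 0.18, 1.6),
    roh_rbp_ttr = c(0, 0, 0, 1.68, 0))
  expect_equal(tab$mode, ref$mode)
  # full-precision solve rounds to 0.13; printed tables round up to 0.14
  expect_true(all(abs(tab$free_roh - ref$free_roh) <= 0.011))
  expect_true(all(abs(tab$roh_rbp - ref$roh_rbp) <= 0.011))
  expect_true(all(abs(tab$roh_rbp_ttr - ref$roh_rbp_ttr) <= 0.011))
})

test_that("equilibrium_system validates its inputs", {
  expect_error(equilibrium_system(-1, 2, 4), "non-negative")
  expect_error(equilibrium_system(2, 2, 4, kd_roh_rbp = 0), "kd_roh_rbp")
  expect_error(equilibrium_system(2, 2, 4, kd_holo_ttr = -1), "kd_holo_ttr")
})
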