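# Independent oracles used across the suite. These deliberately avoid the
# package's solution path: everything here is plain nested bisection on the
# mass-action residuals.

# Bisection solve of the coupled ROH/RBP/TTR equilibria. Unknowns: free ROH r
# (outer) and holo-RBP h (inner). No quadratic shortcuts.
oracle_ternary <- function(total_roh, total_rbp, total_ttr, kd1, kd2,
                           tol = 1e-13, iters = 200L) {
  if (total_roh == 0) {
    return(list(free_roh = 0, holo_rbp = 0, ternary = 0,
                apo_rbp = total_rbp, free_ttr = total_ttr))
  }
  species_given_free <- function(r) {
    # inner bisection: g(h) = h + apo(h) + ternary(h) - total_rbp, increasing
    ternary_of <- function(h) {
      if (total_ttr == 0 || !is.finite(kd2)) return(0)
      # x satisfies x = h (total_ttr - x) / kd2
      h * total_ttr / (kd2 + h)
    }
    g <- function(h) {
      apo <- h * kd1 / r
      apo + h + ternary_of(h) - total_rbp
    }
    lo <- 0; hi <- total_rbp
    if (total_rbp == 0) { h <- 0 } else {
      for (i in seq_len(iters)) {
        mid <- (lo + hi) / 2
        if (g(mid) > 0) hi <- mid else lo <- mid
      }
      h <- (lo + hi) / 2
    }
    x <- ternary_of(h)
    list(holo = h, ternary = x, apo = h * kd1 / r,
         free_ttr = total_ttr - x)
  }
  f <- function(r) {
    s <- species_given_free(r)
    r + s$holo + s$ternary - total_roh
  }
  lo <- total_roh * 1e-16; hi <- total_roh
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  r <- (lo + hi) / 2
  s <- species_given_free(r)
  list(free_roh = r, holo_rbp = s$holo, ternary = s$ternary,
       apo_rbp = s$apo, free_ttr = s$free_ttr)
}

# Bisection solve of the scalar 1:1 binding residual (oracle for the
# closed-form quadratic): bound b solves (L - b)(P - b)/b = kd.
oracle_binary_bound <- function(L, P, kd, iters = 200L) {
  if (L == 0 || P == 0) return(0)
  f <- function(b) (L - b) * (P - b) - kd * b
  lo <- 0; hi <- min(L, P)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

expect_speciation_invariants <- function(st, tol = 1e-9) {
  sys <- st$system
  expect_true(all(unlist(st[c("free_roh", "apo_rbp", "holo_rbp",
                              "free_ttr", "ternary")]) >= -1e-12))
  expect_equal(st$free_roh + st$holo_rbp + st$ternary, sys$total_roh,
               tolerance = tol)
  expect_equal(st$apo_rbp + st$holo_rbp + st$ternary, sys$total_rbp,
               tolerance = tol)
  expect_equal(st$free_ttr + st$ternary, sys$total_ttr, tolerance = tol)
  if (st$holo_rbp > 0)
    expect_equal(st$free_roh * st$apo_rbp / st$holo_rbp, sys$kd_roh_rbp,
                 tolerance = 1e-6)
  if (st$ternary > 0 && is.finite(sys$kd_holo_ttr))
    expect_equal(st$holo_rbp * st$free_ttr / st$ternary, sys$kd_holo_ttr,
                 tolerance = 1e-6)
}
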