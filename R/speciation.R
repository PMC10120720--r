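#' Equilibrium system of retinol and its serum carriers
#'
#' Bundles the total concentrations of retinol (ROH), retinol binding protein 4
#' (RBP) and transthyretin (TTR) together with the two dissociation constants
#' that govern their coupled equilibria:
#' \deqn{ROH + RBP \rightleftharpoons ROH{-}RBP \quad (K_D^{(1)})}
#' \deqn{ROH{-}RBP + TTR \rightleftharpoons ROH{-}RBP{-}TTR \quad (K_D^{(2)})}
#' TTR binds only the holo (ROH-loaded) form of RBP, never apo-RBP and never
#' free ROH. TTR is treated as a single binding entity at its molar
#' concentration, with no tetramer-site multiplicity.
#'
#' Binding-deficient mutants are expressed through the `variant` argument:
#' `"muRBP"` (L63R/L64S RBP, no TTR binding) and `"muTTR"` (I84A TTR, no RBP
#' binding) both abolish the second equilibrium, modelled as
#' `kd_holo_ttr = Inf` (zero ternary complex).
#'
#' @param total_roh Total retinol, uM.
#' @param total_rbp Total RBP, uM.
#' @param total_ttr Total TTR, uM.
#' @param kd_roh_rbp Dissociation constant of the ROH-RBP complex, uM
#'   (default 0.1, the measured value for recombinant human RBP).
#' @param kd_holo_ttr Dissociation constant of holo-RBP binding to TTR, uM
#'   (default 0.25). May be `Inf` to abolish TTR binding.
#' @param variant One of `"wt"`, `"muRBP"`, `"muTTR"`. The mutant variants
#'   force `kd_holo_ttr = Inf`.
#' @return An object of class `"equilibrium_system"`.
#' @examples
#' equilibrium_system(2, 2, 4)
#' equilibrium_system(2, 2, 4, variant = "muTTR")
#' @export
equilibrium_system <- function(total_roh, total_rbp, total_ttr,
                               kd_roh_rbp = 0.1, kd_holo_ttr = 0.25,
                               variant = c("wt", "muRBP", "muTTR")) {
  variant <- match.arg(variant)
  for (nm in c("total_roh", "total_rbp", "total_ttr")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
      stop(nm, " must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(kd_roh_rbp) || length(kd_roh_rbp) != 1L ||
      is.na(kd_roh_rbp) || kd_roh_rbp <= 0)
    stop("kd_roh_rbp must be > 0", call. = FALSE)
  if (!is.numeric(kd_holo_ttr) || length(kd_holo_ttr) != 1L ||
      is.na(kd_holo_ttr) || kd_holo_ttr <= 0)
    stop("kd_holo_ttr must be > 0 (use Inf to abolish binding)", call. = FALSE)
  if (variant != "wt") kd_holo_ttr <- Inf
  structure(
    list(total_roh = total_roh, total_rbp = total_rbp, total_ttr = total_ttr,
         kd_roh_rbp = kd_roh_rbp, kd_holo_ttr = kd_holo_ttr,
         variant = variant),
    class = "equilibrium_system")
}

#' @export
print.equilibrium_system <- function(x, ...) {
  cat("Equilibrium system (uM): ROH", x$total_roh, "| RBP", x$total_rbp,
      "| TTR", x$total_ttr, "\n  KD(ROH-RBP) =", x$kd_roh_rbp,
      "uM; KD(holoRBP-TTR) =", x$kd_holo_ttr, "uM; variant =", x$variant, "\n")
  invisible(x)
}

#' Closed-form 1:1 binding equilibrium
#'
#' Solves the single-site binding quadratic for a ligand L and protein P with
#' dissociation constant \eqn{K_D}: the bound complex is
#' \deqn{B = \frac{(L_t + P_t + K_D) - \sqrt{(L_t + P_t + K_D)^2 - 4 L_t P_t}}{2},}
#' the physically valid root (non-negative and no larger than either total).
#'
#' @param total_ligand,total_protein Totals, uM (>= 0).
#' @param kd Dissociation constant, uM (> 0; `Inf` yields zero complex).
#' @return Named numeric vector `c(free = , bound = )`, uM.
#' @examples
#' solve_binary(2, 2, 0.1)   # free 0.4, bound 1.6
#' @export
solve_binary <- function(total_ligand, total_protein, kd) {
  if (any(!is.finite(c(total_ligand, total_protein))) ||
      total_ligand < 0 || total_protein < 0)
    stop("totals must be finite and >= 0", call. = FALSE)
  if (is.na(kd) || kd <= 0) stop("kd must be > 0", call. = FALSE)
  if (!is.finite(kd)) return(c(free = total_ligand, bound = 0))
  s <- total_ligand + total_protein + kd
  disc <- s * s - 4 * total_ligand * total_protein
  # disc >= kd^2 > 0 algebraically; clamp against roundoff
  bound <- (s - sqrt(max(disc, 0))) / 2
  bound <- min(max(bound, 0), total_ligand, total_protein)
  c(free = total_ligand - bound, bound = bound)
}

# Given free ROH r > 0, the RBP/TTR sub-equilibrium reduces to a quadratic in
# the holo-RBP concentration h:
#   h^2 (K1/r + 1) + h (K1 K2 / r + K2 + T - R) - R K2 = 0
# obtained from h = r a / K1 (a = apo-RBP), x = h T / (K2 + h) (x = ternary)
# and the RBP balance a + h + x = R. The positive root is unique.
.holo_given_free <- function(r, total_rbp, total_ttr, k1, k2) {
  if (total_rbp == 0) return(0)
  if (!is.finite(k2) || total_ttr == 0) {
    # no ternary complex: a + h = R with h = r a / k1
    return(total_rbp * (r / k1) / (1 + r / k1))
  }
  A <- k1 / r + 1
  B <- k1 * k2 / r + k2 + total_ttr - total_rbp
  C <- -total_rbp * k2
  h <- (-B + sqrt(B * B - 4 * A * C)) / (2 * A)
  min(max(h, 0), total_rbp)
}

.speciation_given_free <- function(r, sys) {
  h <- .holo_given_free(r, sys$total_rbp, sys$total_ttr,
                        sys$kd_roh_rbp, sys$kd_holo_ttr)
  x <- if (is.finite(sys$kd_holo_ttr) && sys$total_ttr > 0)
    h * sys$total_ttr / (sys$kd_holo_ttr + h) else 0
  list(free_roh = r, holo_rbp = h, ternary = x,
       apo_rbp = sys$total_rbp - h - x,
       free_ttr = sys$total_ttr - x)
}

#' Solve the coupled ROH/RBP/TTR speciation equilibria
#'
#' Distributes total ROH, RBP and TTR into the five species free ROH, apo-RBP,
#' ROH-RBP (holo), free TTR and the ternary ROH-RBP-TTR complex, assuming
#' simultaneous equilibrium of both binding reactions.
#'
#' The two coupled mass-action equations are reduced to a single scalar
#' residual in free ROH, \eqn{f(r) = r + h(r) + x(r) - ROH_{tot}}, which is
#' strictly increasing on \eqn{(0, ROH_{tot}]}; it is solved by safeguarded
#' bracketing ([stats::uniroot()]) to an absolute tolerance of 1e-12 uM.
#' The scheme is deterministic. With `total_ttr = 0` (or an infinite second
#' \eqn{K_D}) the solution reduces exactly to [solve_binary()].
#'
#' @param system An [equilibrium_system()].
#' @param tol Absolute tolerance on free ROH, uM.
#' @return An object of class `"speciation_state"`: a list with fields
#'   `free_roh`, `apo_rbp`, `holo_rbp`, `free_ttr`, `ternary` (all uM),
#'   the originating `system`, and `residuals` (mass-balance and mass-action
#'   relative residuals).
#' @examples
#' solve_ternary(equilibrium_system(2, 2, 4))  # Table-style 0.13/0.18/1.68
#' @export
solve_ternary <- function(system, tol = 1e-12) {
  stopifnot(inherits(system, "equilibrium_system"))
  R <- system$total_roh
  if (R == 0) {
    st <- .speciation_given_free(0, system)
    st$free_roh <- 0
  } else if (system$total_rbp == 0) {
    st <- list(free_roh = R, holo_rbp = 0, ternary = 0,
               apo_rbp = 0, free_ttr = system$total_ttr)
  } else {
    f <- function(r) {
      s <- .speciation_given_free(r, system)
      s$free_roh + s$holo_rbp + s$ternary - R
    }
    # f(0+) = -R < 0, f(R) >= 0: bracket is (0, R]. Bisect to machine
    # precision -- the residual slope can be steep for tight binding, so a
    # looser interval tolerance would leak into the mass balances.
    lo <- R * 1e-18; hi <- R
    for (i in 1:2000) {
      mid <- (lo + hi) / 2
      if (mid <= lo || mid >= hi) break
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    r <- (lo + hi) / 2
    if (abs(f(r)) > 1e-6 * max(R, 1))
      stop("speciation solver did not converge: residual ",
           format(f(r)), " uM at free ROH ", format(r), call. = FALSE)
    st <- .speciation_given_free(r, system)
  }
  out <- structure(
    c(st, list(system = system)),
    class = "speciation_state")
  out$residuals <- speciation_residuals(out)
  out
}

#' Mass-balance and mass-action residuals of a speciation state
#'
#' @param state A `"speciation_state"`.
#' @return Named numeric vector of relative residuals (dimensionless):
#'   `roh_balance`, `rbp_balance`, `ttr_balance`, `kd1`, `kd2`. Mass-action
#'   residuals are `NA` when their denominator is zero.
#' @export
speciation_residuals <- function(state) {
  sys <- state$system
  rel <- function(lhs, total) if (total > 0) (lhs - total) / total else lhs
  kd1 <- if (state$holo_rbp > 0 && sys$total_rbp > 0)
    (state$free_roh * state$apo_rbp / state$holo_rbp - sys$kd_roh_rbp) /
      sys$kd_roh_rbp else NA_real_
  kd2 <- if (state$ternary > 0 && is.finite(sys$kd_holo_ttr))
    (state$holo_rbp * state$free_ttr / state$ternary - sys$kd_holo_ttr) /
      sys$kd_holo_ttr else NA_real_
  c(roh_balance = rel(state$free_roh + state$holo_rbp + state$ternary,
                      sys$total_roh),
    rbp_balance = rel(state$apo_rbp + state$holo_rbp + state$ternary,
                      sys$total_rbp),
    ttr_balance = rel(state$free_ttr + state$ternary, sys$total_ttr),
    kd1 = kd1, kd2 = kd2)
}

#' @export
print.speciation_state <- function(x, digits = 2, ...) {
  cat("Speciation (uM):\n")
  v <- c("free ROH" = x$free_roh, "apo-RBP" = x$apo_rbp,
         "ROH-RBP" = x$holo_rbp, "free TTR" = x$free_ttr,
         "ROH-RBP-TTR" = x$ternary)
  print(round(v, digits))
  invisible(x)
}

#' @export
as.data.frame.speciation_state <- function(x, ...) {
  data.frame(free_roh = x$free_roh, apo_rbp = x$apo_rbp,
             holo_rbp = x$holo_rbp, free_ttr = x$free_ttr,
             ternary = x$ternary)
}

#' Percentage of total ROH that is unbound
#'
#' @param state A `"speciation_state"`.
#' @param total_roh Total ROH, uM; defaults to the total recorded in the state.
#' @return Percent free ROH, `100 * free_roh / total_roh`.
#' @examples
#' fraction_free(solve_ternary(equilibrium_system(2, 2, 0)))  # 20
#' @export
fraction_free <- function(state, total_roh = state$system$total_roh) {
  stopifnot(inherits(state, "speciation_state"))
  if (!is.numeric(total_roh) || length(total_roh) != 1L || total_roh <= 0)
    stop("total_roh must be > 0", call. = FALSE)
  100 * state$free_roh / total_roh
}

#' Speciation table for a set of delivery modes
#'
#' Builds a table of free / RBP-bound / ternary ROH for the standard delivery
#' modes used in BMEC accumulation and permeability assays: protein-free ROH,
#' ROH-RBP, ROH-muRBP, ROH-RBP-TTR and ROH-RBP-muTTR.
#'
#' @param total_roh Total ROH, uM (recycled across modes).
#' @param total_rbp,total_ttr Protein totals, uM, applied where the mode
#'   includes that protein.
#' @param kd_roh_rbp,kd_holo_ttr Dissociation constants, uM.
#' @param modes Character vector of delivery modes.
#' @param digits Rounding applied for presentation (values are solved at full
#'   precision and rounded only here).
#' @return A data.frame with one row per mode: columns `total_roh`, `mode`,
#'   `free_roh`, `roh_rbp`, `roh_rbp_ttr`.
#' @export
speciation_table <- function(total_roh = 2, total_rbp = 2, total_ttr = 4,
                             kd_roh_rbp = 0.1, kd_holo_ttr = 0.25,
                             modes = c("free", "ROH-RBP", "ROH-muRBP",
                                       "ROH-RBP-TTR", "ROH-RBP-muTTR"),
                             digits = 2) {
  rows <- lapply(modes, function(m) {
    sys <- switch(m,
      "free" = equilibrium_system(total_roh, 0, 0, kd_roh_rbp, kd_holo_ttr),
      "ROH-RBP" = equilibrium_system(total_roh, total_rbp, 0,
                                     kd_roh_rbp, kd_holo_ttr),
      "ROH-muRBP" = equilibrium_system(total_roh, total_rbp, 0,
                                       kd_roh_rbp, kd_holo_ttr,
                                       variant = "muRBP"),
      "ROH-RBP-TTR" = equilibrium_system(total_roh, total_rbp, total_ttr,
                                         kd_roh_rbp, kd_holo_ttr),
      "ROH-RBP-muTTR" = equilibrium_system(total_roh, total_rbp, total_ttr,
                                           kd_roh_rbp, kd_holo_ttr,
                                           variant = "muTTR"),
      stop("unknown delivery mode: ", m, call. = FALSE))
    st <- solve_ternary(sys)
    data.frame(total_roh = total_roh, mode = m,
               free_roh = round(st$free_roh, digits),
               roh_rbp = round(st$holo_rbp, digits),
               roh_rbp_ttr = round(st$ternary, digits))
  })
  do.call(rbind, rows)
}
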