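#' Simulation configuration
#'
#' Central configuration of the synthetic-data generator. A single integer
#' seed fixes all randomness end-to-end. Noise models:
#' \describe{
#'   \item{`none`}{deterministic forward model.}
#'   \item{`gaussian_cv`}{multiplicative Gaussian noise with coefficient of
#'     variation `noise_scale` applied to concentrations.}
#'   \item{`poisson_counts`}{physically motivated counting noise — each
#'     observation is converted to DPM through the inverse radiometry chain
#'     and replaced with a Poisson draw; `noise_scale` is ignored.}
#' }
#'
#' @param seed Integer seed.
#' @param noise_model `"none"`, `"gaussian_cv"` or `"poisson_counts"`.
#' @param noise_scale CV for `gaussian_cv` (default 0.05, a typical assay CV).
#' @param accumulation List: `params` ([kinetic_params()]), `cf` (uM vector,
#'   default `c(0.1, 0.4, 2)`), `times` (min, default `seq(5, 120, by = 5)`),
#'   `replicates` (default 3). Defaults follow the fitted free-ROH assay:
#'   Kp = 90, k1 = 0.02/min, Kp* = 70, k1* = 0.01/min, ccell* = 36 uM.
#' @param transwell List: `pe` named cm/s per channel (default
#'   `c(H3 = 4.8e-6, C14 = 0.6e-6)`), `c0` named uM per channel (default
#'   `c(H3 = 2, C14 = 1)`), `geometry` ([transwell_geometry()]), `times`
#'   (basolateral schedule, default `seq(0, 60, by = 15)`),
#'   `apical_times` (default `c(0, 60)`), `cell_exchange` (named:
#'   `uptake_cl`, `efflux_frac` — see [simulate_transwell()]), `replicates`
#'   (default 3).
#' @param tracer A [tracer_spec()].
#' @param geometry A [cell_geometry()] (used when emitting DPM-level output;
#'   default 1e5 cells).
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1,
                              noise_model = c("none", "gaussian_cv",
                                              "poisson_counts"),
                              noise_scale = 0.05,
                              accumulation = list(),
                              transwell = list(),
                              tracer = tracer_spec(),
                              geometry = cell_geometry(n_cells = 1e5)) {
  noise_model <- match.arg(noise_model)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  if (noise_scale < 0) stop("noise_scale must be >= 0", call. = FALSE)
  acc <- utils::modifyList(
    list(params = kinetic_params(Kp = 90, k1 = 0.02, Kp_star = 70,
                                 k1_star = 0.01, ccell_star = 36),
         cf = c(0.1, 0.4, 2),
         times = seq(5, 120, by = 5),
         replicates = 3L),
    accumulation)
  tw <- utils::modifyList(
    list(pe = c(H3 = 4.8e-6, C14 = 0.6e-6),
         c0 = c(H3 = 2, C14 = 1),
         geometry = transwell_geometry(),
         times = seq(0, 60, by = 15),
         apical_times = c(0, 60),
         cell_exchange = c(uptake_cl = 0, efflux_frac = 0.5),
         replicates = 3L),
    transwell)
  structure(list(seed = as.integer(seed), noise_model = noise_model,
                 noise_scale = noise_scale, accumulation = acc,
                 transwell = tw, tracer = tracer, geometry = geometry),
            class = "simulation_config")
}

.apply_noise <- function(conc, config, amount_scale) {
  switch(config$noise_model,
    none = conc,
    gaussian_cv = conc * (1 + config$noise_scale *
                            stats::rnorm(length(conc))),
    poisson_counts = {
      # amount_scale converts uM to umol (a volume in L); DPM round-trip
      dpm <- amount_to_dpm(conc * amount_scale * 1e-6, config$tracer)
      # rpois overflows above ~2e9; use the normal approximation there
      big <- dpm > 1e9
      noisy <- numeric(length(dpm))
      noisy[!big] <- stats::rpois(sum(!big), dpm[!big])
      noisy[big] <- round(stats::rnorm(sum(big), dpm[big], sqrt(dpm[big])))
      dpm_to_total_amount(noisy, config$tracer) * 1e6 / amount_scale
    })
}

#' Simulate cellular-accumulation time courses
#'
#' Forward model of the biphasic accumulation kinetics: for each fluid
#' concentration and replicate, cellular concentrations are evaluated with
#' [predict_biphasic()] on the configured time grid and noise is applied per
#' the configuration (at the DPM level for `poisson_counts`, through the
#' inverse radiometry chain). Deterministic under a fixed seed.
#'
#' @param config A [simulation_config()].
#' @return Named list of [timecourse()] objects (one per `cf`), with the true
#'   parameters attached as attribute `"truth"`.
#' @examples
#' tcs <- simulate_accumulation(simulation_config(seed = 7))
#' @export
simulate_accumulation <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  acc <- config$accumulation
  cell_vol_total <- cell_volume(config$geometry) *
    max(config$geometry$n_cells, 1)
  withr_seed(config$seed, {
    out <- lapply(acc$cf, function(cf) {
      times <- rep(acc$times, times = acc$replicates)
      reps <- rep(seq_len(acc$replicates), each = length(acc$times))
      clean <- predict_biphasic(acc$params, cf, times)
      noisy <- pmax(.apply_noise(clean, config, cell_vol_total), 0)
      timecourse(cf, times, noisy, replicate = reps,
                 label = paste0("free_", cf, "uM"))
    })
    names(out) <- paste0("cf_", acc$cf)
    attr(out, "truth") <- acc$params
    out
  })
}

#' Write simulated accumulation data as CSV
#'
#' Emits the long CSV schema read by the analysis stages:
#' `time_min, replicate, ccell_uM, label, cf_uM`.
#'
#' @param tcs List of [timecourse()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_accumulation_csv <- function(tcs, path) {
  rows <- do.call(rbind, lapply(tcs, function(tc)
    data.frame(time_min = tc$time, replicate = tc$replicate,
               ccell_uM = tc$ccell, label = attr(tc, "label"),
               cf_uM = attr(tc, "cf"))))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read accumulation time courses from CSV
#'
#' Expects columns `time_min, replicate, ccell_uM, label, cf_uM` (comma
#' separated, header row, '.' decimal). One [timecourse()] is built per
#' distinct `label`.
#'
#' @param path CSV path.
#' @return Named list of [timecourse()] objects.
#' @export
read_accumulation_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_min", "replicate", "ccell_uM", "label", "cf_uM")
  if (!all(req %in% names(d)))
    stop("accumulation CSV must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(d, d$label), function(g)
    timecourse(g$cf_uM[1], g$time_min, g$ccell_uM,
               replicate = g$replicate, label = g$label[1]))
  out
}

# One Transwell replicate for one channel, integrated with fixed-step RK4
# (0.1-min steps) between sampling events. State = amounts (umol) in apical,
# cell, basolateral. Transfer:
#   paracellular / lumped transcellular: rate cl = Pe * A * 60 / 1000 (L/min)
#   apical -> basolateral driven by (C_a - C_b)
#   optional cell compartment: apical -> cell at uptake_cl (L/min), cell ->
#   basolateral first-order at rate that routes efflux_frac of uptake onward.
.simulate_transwell_channel <- function(pe, c0, geom, times, apical_times,
                                        cell_exchange, dt = 0.1) {
  cl <- pe * geom$membrane_area * 60 / 1000          # L/min
  up_cl <- cell_exchange[["uptake_cl"]]              # L/min apical->cell
  k_out <- cell_exchange[["efflux_frac"]] * 0.05     # /min cell->baso
  va <- geom$apical_volume
  vb <- geom$basolateral_volume
  vs <- geom$sample_volume
  N <- c(a = c0 * va, c = 0, b = 0)                  # umol
  deriv <- function(N, va) {
    Ca <- N[["a"]] / va; Cb <- N[["b"]] / vb
    j_ab <- cl * (Ca - Cb)
    j_ac <- up_cl * Ca
    j_cb <- k_out * N[["c"]]
    c(a = -j_ab - j_ac, c = j_ac - j_cb, b = j_ab + j_cb)
  }
  step <- function(N, va, h) {
    k1 <- deriv(N, va)
    k2 <- deriv(N + h / 2 * k1, va)
    k3 <- deriv(N + h / 2 * k2, va)
    k4 <- deriv(N + h * k3, va)
    N + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  events <- sort(unique(c(times, apical_times)))
  rows <- list(); drawn_a <- 0
  t_now <- 0
  for (ev in events) {
    while (t_now < ev - 1e-9) {
      h <- min(dt, ev - t_now)
      N <- step(N, va, h)
      t_now <- t_now + h
    }
    if (ev %in% times) {                             # basolateral draw
      Cb <- N[["b"]] / vb
      rows[[length(rows) + 1]] <-
        data.frame(time = ev, compartment = "basolateral", conc_uM = Cb)
      N[["b"]] <- N[["b"]] - Cb * vs                 # replaced with buffer
    }
    if (ev %in% apical_times) {                      # apical draw, no refill
      Ca <- N[["a"]] / va
      rows[[length(rows) + 1]] <-
        data.frame(time = ev, compartment = "apical", conc_uM = Ca)
      N[["a"]] <- N[["a"]] - Ca * vs
      va <- va - vs
      drawn_a <- drawn_a + 1
    }
  }
  meas <- do.call(rbind, rows)
  meas$amount_umol <- NA_real_
  lys <- data.frame(time = max(events), compartment = "lysate",
                    conc_uM = NA_real_, amount_umol = N[["c"]])
  rbind(meas, lys)
}

#' Simulate a dual-tracer Transwell permeability assay
#'
#' Three-compartment (apical, cell, basolateral) mass-action transfer
#' integrated with a fixed-step 4th-order Runge-Kutta scheme at 0.1-min
#' steps; sampling events are handled exactly at the scheduled times.
#' Basolateral draws are replaced with buffer; apical draws are not (volume
#' shrinks). The sucrose channel is direct apical-to-basolateral paracellular
#' flux; the tracer-of-interest channel may additionally route through a
#' lumped first-order cell compartment (`uptake_cl` L/min into the cell,
#' with a fraction passed on basolaterally), a deliberately simple stand-in
#' that produces the observed basolateral lag without full biphasic cell
#' dynamics. Total mass is conserved exactly before noise.
#'
#' @param config A [simulation_config()]; the `transwell` block provides true
#'   Pe values, geometry and schedules.
#' @return A [transwell_assay()] with attribute `"truth"` (the configured Pe
#'   per channel).
#' @examples
#' a <- simulate_transwell(simulation_config(seed = 3))
#' assay_permeability(a)
#' @export
simulate_transwell <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  tw <- config$transwell
  if (max(tw$times) > max(tw$apical_times))
    stop("basolateral schedule exceeds assay duration (last apical sample)",
         call. = FALSE)
  withr_seed(config$seed, {
    rows <- list()
    for (ch in names(tw$pe)) {
      for (rp in seq_len(tw$replicates)) {
        ex <- if (ch == "C14") c(uptake_cl = 0, efflux_frac = 0)
              else tw$cell_exchange
        sim <- .simulate_transwell_channel(
          tw$pe[[ch]], tw$c0[[ch]], tw$geometry, tw$times, tw$apical_times,
          ex)
        is_conc <- !is.na(sim$conc_uM)
        sim$conc_uM[is_conc] <-
          pmax(.apply_noise(sim$conc_uM[is_conc], config,
                            tw$geometry$basolateral_volume), 0)
        is_amt <- !is.na(sim$amount_umol)
        sim$amount_umol[is_amt] <-
          pmax(.apply_noise(sim$amount_umol[is_amt] /
                              tw$geometry$basolateral_volume, config,
                            tw$geometry$basolateral_volume) *
                 tw$geometry$basolateral_volume, 0)
        sim$channel <- ch
        sim$replicate <- rp
        rows[[length(rows) + 1]] <- sim
      }
    }
    d <- do.call(rbind, rows)
    out <- transwell_assay(d, geometry = tw$geometry, c0 = tw$c0)
    attr(out, "truth") <- tw$pe
    out
  })
}

#' Write a Transwell assay as CSV
#'
#' Schema: `time_min, compartment, channel, replicate, conc_uM, amount_umol`.
#'
#' @param assay A [transwell_assay()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transwell_csv <- function(assay, path) {
  d <- assay$data
  out <- data.frame(time_min = d$time, compartment = d$compartment,
                    channel = d$channel, replicate = d$replicate,
                    conc_uM = d$conc_uM, amount_umol = d$amount_umol)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Transwell assay from CSV
#'
#' @param path CSV with columns `time_min, compartment, channel, replicate`
#'   and `conc_uM` / `amount_umol`.
#' @param geometry A [transwell_geometry()].
#' @param c0 Optional named nominal loading concentrations per channel, uM.
#' @return A [transwell_assay()].
#' @export
read_transwell_csv <- function(path, geometry = transwell_geometry(),
                               c0 = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(d)[names(d) == "time_min"] <- "time"
  transwell_assay(d, geometry = geometry, c0 = c0)
}

#' Random equilibrium systems for property testing
#'
#' Reproducible batch of random [equilibrium_system()] objects spanning the
#' given concentration ranges, always including the degenerate edges (zero
#' TTR and zero RBP) as the first two entries when `n >= 2`.
#'
#' @param n Number of systems (>= 1).
#' @param seed Integer seed.
#' @param ranges List with elements `roh`, `rbp`, `ttr`, `kd1`, `kd2`, each a
#'   length-2 range. Defaults: totals in \[0.01, 10\] uM, K_Ds in
#'   \[0.01, 1\] uM.
#' @return List of `equilibrium_system` objects.
#' @export
random_equilibrium_systems <- function(n, seed = 1, ranges = list()) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("n must be >= 1", call. = FALSE)
  r <- utils::modifyList(
    list(roh = c(0.01, 10), rbp = c(0.01, 10), ttr = c(0.01, 10),
         kd1 = c(0.01, 1), kd2 = c(0.01, 1)), ranges)
  withr_seed(seed, {
    sys <- lapply(seq_len(n), function(i) {
      equilibrium_system(stats::runif(1, r$roh[1], r$roh[2]),
                         stats::runif(1, r$rbp[1], r$rbp[2]),
                         stats::runif(1, r$ttr[1], r$ttr[2]),
                         stats::runif(1, r$kd1[1], r$kd1[2]),
                         stats::runif(1, r$kd2[1], r$kd2[2]))
    })
    if (n >= 2) {
      sys[[1]]$total_ttr <- 0    # degenerate edges included by contract
      sys[[2]]$total_rbp <- 0
    }
    sys
  })
}
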