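#' Kinetic parameters for cellular retinol accumulation
#'
#' Parameters of the partitioning model of retinol accumulation in BMEC
#' monolayers. The primary phase is first-order partitioning with coefficient
#' `Kp` (uM cell per uM fluid) and rate `k1` (1/min). A secondary uptake
#' mechanism with coefficient `Kp_star` and rate `k1_star` is triggered once
#' the accumulated cellular concentration crosses the threshold `ccell_star`
#' (uM), which happens after the concentration-dependent lag time computed by
#' [lag_time()]. The monophasic model is the restriction `Kp_star = 0`.
#'
#' @param Kp Primary partition coefficient, uM/uM (>= 0).
#' @param k1 Primary rate constant, 1/min (>= 0).
#' @param Kp_star Secondary partition coefficient, uM/uM (>= 0; 0 disables
#'   the secondary phase).
#' @param k1_star Secondary rate constant, 1/min (>= 0).
#' @param ccell_star Trigger threshold on cellular concentration, uM (>= 0).
#' @return Object of class `"kinetic_params"`.
#' @examples
#' kinetic_params(Kp = 90, k1 = 0.02)                       # monophasic
#' kinetic_params(90, 0.02, Kp_star = 70, k1_star = 0.01,
#'                ccell_star = 36)                          # biphasic
#' @export
kinetic_params <- function(Kp, k1, Kp_star = 0, k1_star = 0, ccell_star = 0) {
  v <- c(Kp = Kp, k1 = k1, Kp_star = Kp_star, k1_star = k1_star,
         ccell_star = ccell_star)
  if (any(!is.finite(v)) || any(v < 0))
    stop("all kinetic parameters must be finite and >= 0", call. = FALSE)
  structure(as.list(v), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "Kinetic parameters: Kp=%.4g uM/uM, k1=%.4g /min, Kp*=%.4g, k1*=%.4g, ccell*=%.4g uM\n",
    x$Kp, x$k1, x$Kp_star, x$k1_star, x$ccell_star))
  invisible(x)
}

#' Accumulation time course
#'
#' One accumulation curve: cellular concentrations observed at given times for
#' one bulk fluid concentration. The fluid concentration is assumed constant
#' over the assay. Replicates are stored long (one row per observation).
#'
#' @param cf Bulk fluid ROH concentration, uM (> 0).
#' @param time Observation times, min (>= 0).
#' @param ccell Accumulated cellular concentrations, uM (>= 0), same length
#'   as `time`.
#' @param replicate Optional replicate ids (defaults to 1).
#' @param label Delivery-mode tag, e.g. `"free"`, `"ROH-RBP"`.
#' @return Object of class `"timecourse"`: a data.frame with columns `time`,
#'   `ccell`, `replicate` and attributes `cf`, `label`.
#' @export
timecourse <- function(cf, time, ccell, replicate = 1L, label = "free") {
  if (!is.numeric(cf) || length(cf) != 1L || is.na(cf) || cf <= 0)
    stop("cf must be > 0 uM", call. = FALSE)
  if (length(time) != length(ccell))
    stop("time and ccell lengths differ", call. = FALSE)
  if (any(time < 0) || any(ccell < 0))
    stop("time and ccell must be >= 0", call. = FALSE)
  df <- data.frame(time = as.numeric(time), ccell = as.numeric(ccell),
                   replicate = rep_len(replicate, length(time)))
  structure(df, cf = cf, label = label,
            class = c("timecourse", "data.frame"))
}

#' Monophasic accumulation model
#'
#' \deqn{c_{cell}(t) = c_f K_p (1 - e^{-k_1 t})}
#'
#' @param params A [kinetic_params()] (only `Kp`, `k1` are used).
#' @param cf Fluid concentration, uM.
#' @param t Times, min (vectorised).
#' @return Predicted cellular concentration, uM.
#' @export
predict_monophasic <- function(params, cf, t) {
  stopifnot(inherits(params, "kinetic_params"), all(t >= 0))
  cf * params$Kp * (1 - exp(-params$k1 * t))
}

#' Lag time before the secondary uptake phase
#'
#' The secondary mechanism triggers when the primary phase alone reaches the
#' threshold `ccell_star`:
#' \deqn{t_{lag} = -\ln(1 - c^*_{cell} / (K_p c_f)) / k_1.}
#' When the primary asymptote \eqn{K_p c_f} never reaches the threshold the
#' trigger never fires and `Inf` is returned (a value, not an error).
#'
#' @param params A [kinetic_params()] with `Kp`, `k1` > 0.
#' @param cf Fluid concentration, uM.
#' @return Lag time in min, or `Inf` if the threshold is never crossed.
#' @examples
#' lag_time(kinetic_params(90, 0.02, ccell_star = 36), cf = 2)  # ~11.16 min
#' @export
lag_time <- function(params, cf) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$Kp <= 0 || params$k1 <= 0)
    stop("lag_time requires Kp > 0 and k1 > 0", call. = FALSE)
  if (params$ccell_star <= 0) return(0)
  arg <- 1 - params$ccell_star / (params$Kp * cf)
  if (arg <= 0) return(Inf)
  -log(arg) / params$k1
}

#' Biphasic accumulation model with triggered secondary uptake
#'
#' The primary partitioning term plus, once the lag time has elapsed, a
#' second exponential phase:
#' \deqn{c_{cell}(t) = c_f K_p (1 - e^{-k_1 t}) +
#'   c_f K_p^* (1 - e^{-k_1^* (t - t_{lag})}) \cdot 1\{t \ge t_{lag}\}.}
#' The secondary term is zero before the trigger and when the trigger never
#' fires, so the curve is continuous at \eqn{t_{lag}} (with a kink in slope;
#' no smoothing is applied).
#'
#' @inheritParams predict_monophasic
#' @return Predicted cellular concentration, uM.
#' @export
predict_biphasic <- function(params, cf, t) {
  stopifnot(inherits(params, "kinetic_params"), all(t >= 0))
  base <- cf * params$Kp * (1 - exp(-params$k1 * t))
  if (params$Kp_star <= 0 || params$Kp <= 0 || params$k1 <= 0) return(base)
  tl <- lag_time(params, cf)
  if (!is.finite(tl)) return(base)
  extra <- ifelse(t >= tl,
                  cf * params$Kp_star * (1 - exp(-params$k1_star * (t - tl))),
                  0)
  base + extra
}

.predict_model <- function(params, cf, t, model) {
  if (model == "monophasic") predict_monophasic(params, cf, t)
  else predict_biphasic(params, cf, t)
}

.params_from_vec <- function(th, model) {
  if (model == "monophasic")
    kinetic_params(Kp = th[1], k1 = th[2])
  else
    kinetic_params(Kp = th[1], k1 = th[2], Kp_star = th[3],
                   k1_star = th[4], ccell_star = th[5])
}

.sse <- function(th, tcs, model) {
  # optim's finite-difference gradient can step ndeps below the box; clamp
  # rather than error so the objective is defined everywhere
  if (any(!is.finite(th))) return(1e300)
  p <- .params_from_vec(pmax(th, 0), model)
  s <- 0
  for (tc in tcs) {
    pred <- .predict_model(p, attr(tc, "cf"), tc$time, model)
    s <- s + sum((tc$ccell - pred)^2)
  }
  s
}

# Data-driven starting point: Kp from the late-time normalized level, k1 from
# a coarse grid, secondary phase seeded at mid-range values.
.heuristic_start <- function(tcs, model, cmax) {
  norm_late <- vapply(tcs, function(tc) {
    cf <- attr(tc, "cf")
    idx <- tc$time >= stats::quantile(tc$time, 0.6)
    mean(tc$ccell[idx]) / cf
  }, numeric(1))
  Kp0 <- max(min(norm_late), 1e-2)
  if (model == "monophasic") {
    Kp0 <- max(mean(norm_late), 1e-2)
    c(Kp0, 0.02)
  } else {
    c(Kp0, 0.02, max(max(norm_late) - Kp0, 1), 0.01, 0.5 * cmax)
  }
}

#' Fit accumulation time courses by least squares
#'
#' Minimises the pooled sum of squared residuals
#' \eqn{\sum (c_{cell,obs} - c_{cell,pred})^2} over all supplied curves with a
#' single shared parameter set (global fit): the curves are linked through the
#' \eqn{c_f}-dependence of the lag time. Replicates enter as individual
#' observations (no pre-averaging). Optimisation uses bounded Nelder-Mead /
#' L-BFGS-B multistart (one data-driven start plus `n_starts` seeded random
#' starts), deterministic for a given `seed`.
#'
#' @param timecourses A [timecourse()] or list of them.
#' @param model `"monophasic"` (2 parameters) or `"biphasic"` (5 parameters).
#' @param n_starts Number of random multistarts in addition to the
#'   data-driven start (default 10).
#' @param seed Integer seed for the random starts (default 1).
#' @param per_curve If `TRUE`, fit each curve separately and return a list of
#'   fits instead of one global fit.
#' @param bounds Named list overriding the default box bounds
#'   (`Kp`, `Kp_star` in \[0, 1e4\]; `k1`, `k1_star` in \[1e-5, 1\];
#'   `ccell_star` in \[0, max observed\]).
#' @return Object of class `"fit_result"`: `params` ([kinetic_params()]),
#'   `sse`, `n_obs`, `n_params`, `se` (approximate standard errors from the
#'   Gauss-Newton J'J at the optimum), `converged`, `model`, `starts` (the
#'   multistart log), and the data used.
#' @export
fit_accumulation <- function(timecourses, model = c("biphasic", "monophasic"),
                             n_starts = 10, seed = 1, per_curve = FALSE,
                             bounds = NULL) {
  model <- match.arg(model)
  if (inherits(timecourses, "timecourse")) timecourses <- list(timecourses)
  stopifnot(length(timecourses) >= 1,
            all(vapply(timecourses, inherits, TRUE, "timecourse")))
  if (per_curve) {
    fits <- lapply(timecourses, fit_accumulation, model = model,
                   n_starts = n_starts, seed = seed, per_curve = FALSE,
                   bounds = bounds)
    names(fits) <- vapply(timecourses, attr, "", "label")
    return(fits)
  }
  n_obs <- sum(vapply(timecourses, nrow, 0L))
  n_par <- if (model == "monophasic") 2L else 5L
  for (tc in timecourses) {
    if (length(unique(tc$time)) < 2)
      stop("each curve needs >= 2 distinct time points", call. = FALSE)
  }
  if (model == "biphasic" && n_obs < 5)
    stop("biphasic fit needs >= 5 observations", call. = FALSE)
  if (n_obs <= n_par)
    stop("need more observations than parameters", call. = FALSE)

  cmax <- max(vapply(timecourses, function(tc) max(tc$ccell), numeric(1)))
  lower <- c(Kp = 0, k1 = 1e-5, Kp_star = 0, k1_star = 1e-5,
             ccell_star = 0)[seq_len(n_par)]
  upper <- c(Kp = 1e4, k1 = 1, Kp_star = 1e4, k1_star = 1,
             ccell_star = max(cmax, 1e-6))[seq_len(n_par)]
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      if (nm %in% names(lower)) {
        lower[nm] <- bounds[[nm]][1]; upper[nm] <- bounds[[nm]][2]
      }
    }
  }

  starts <- list(.heuristic_start(timecourses, model, cmax))
  if (n_starts > 0) {
    rs <- withr_seed(seed, {
      lapply(seq_len(n_starts), function(i) {
        th <- c(Kp = exp(stats::runif(1, log(1), log(500))),
                k1 = exp(stats::runif(1, log(1e-3), log(0.3))),
                Kp_star = exp(stats::runif(1, log(1), log(500))),
                k1_star = exp(stats::runif(1, log(1e-3), log(0.3))),
                ccell_star = stats::runif(1, 0, cmax))
        unname(th[seq_len(n_par)])
      })
    })
    starts <- c(starts, rs)
  }
  starts <- lapply(starts, function(s) pmin(pmax(s, lower), upper))

  obj <- function(th) .sse(th, timecourses, model)
  run_one <- function(st) {
    f1 <- suppressWarnings(stats::optim(
      st, obj, method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(maxit = 500,
                     parscale = pmax(abs(st), lower + 1e-3))))
    f2 <- suppressWarnings(stats::optim(
      pmin(pmax(f1$par, lower), upper), obj, method = "Nelder-Mead",
      control = list(maxit = 2000, reltol = 1e-12)))
    par <- pmin(pmax(f2$par, lower), upper)
    list(par = par, value = obj(par),
         convergence = min(f1$convergence, f2$convergence))
  }
  cands <- lapply(starts, run_one)
  vals <- vapply(cands, `[[`, numeric(1), "value")
  best <- cands[[which.min(vals)]]
  # one polishing pass from the winner
  pol <- run_one(best$par)
  if (pol$value < best$value) best <- pol

  params <- .params_from_vec(best$par, model)
  sse <- best$value
  se <- .fit_se(best$par, timecourses, model, sse, n_obs, n_par, lower, upper)
  structure(list(params = params, sse = sse, n_obs = n_obs, n_params = n_par,
                 se = se, converged = best$convergence == 0, model = model,
                 starts = list(n_starts = length(starts), seed = seed,
                               sse = sort(vals)),
                 data = timecourses),
            class = "fit_result")
}

# Approximate standard errors from the numeric Gauss-Newton J'J. Parameters
# pinned at a bound get NA.
.fit_se <- function(th, tcs, model, sse, n_obs, n_par, lower, upper) {
  predv <- function(p) {
    kp <- .params_from_vec(p, model)
    unlist(lapply(tcs, function(tc)
      .predict_model(kp, attr(tc, "cf"), tc$time, model)))
  }
  J <- matrix(NA_real_, n_obs, n_par)
  h <- pmax(abs(th) * 1e-6, 1e-9)
  for (j in seq_len(n_par)) {
    up <- th; up[j] <- th[j] + h[j]
    dn <- th; dn[j] <- max(th[j] - h[j], lower[j])
    J[, j] <- (predv(up) - predv(dn)) / (up[j] - dn[j])
  }
  sigma2 <- sse / max(n_obs - n_par, 1)
  se <- rep(NA_real_, n_par)
  cv <- try(solve(crossprod(J)), silent = TRUE)
  if (!inherits(cv, "try-error")) {
    d <- diag(cv)
    ok <- d > 0
    se[ok] <- sqrt(sigma2 * d[ok])
  }
  at_bound <- th <= lower + 1e-12 | th >= upper - 1e-12
  se[at_bound] <- NA_real_
  names(se) <- c("Kp", "k1", "Kp_star", "k1_star",
                 "ccell_star")[seq_len(n_par)]
  se
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: SSE = %.6g over %d observations (%d parameters)%s\n",
              x$model, x$sse, x$n_obs, x$n_params,
              if (x$converged) "" else " [did not converge]"))
  print(x$params)
  invisible(x)
}

#' Compare nested monophasic and biphasic fits
#'
#' Extra-sum-of-squares F test of the monophasic model (restriction
#' `Kp_star = 0`) against the full biphasic model fitted to the same data,
#' plus the AIC difference. `preferred` is `"biphasic"` iff the F test
#' rejects at level `alpha`.
#'
#' @param fit_mono,fit_bi [fit_accumulation()] results for the monophasic and
#'   biphasic models on the same observations.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `"model_comparison"` with `f_statistic`,
#'   `p_value`, `delta_aic` (AIC_mono - AIC_bi; positive favours biphasic)
#'   and `preferred`.
#' @export
compare_models <- function(fit_mono, fit_bi, alpha = 0.05) {
  stopifnot(inherits(fit_mono, "fit_result"), inherits(fit_bi, "fit_result"))
  if (fit_mono$model != "monophasic" || fit_bi$model != "biphasic")
    stop("arguments must be a monophasic and a biphasic fit, in that order",
         call. = FALSE)
  if (fit_mono$n_obs != fit_bi$n_obs)
    stop("fits are not on identical data (n_obs differs)", call. = FALSE)
  n <- fit_bi$n_obs
  df1 <- fit_bi$n_params - fit_mono$n_params
  df2 <- n - fit_bi$n_params
  if (df2 <= 0) stop("no residual degrees of freedom", call. = FALSE)
  # the restricted model cannot fit better; guard roundoff
  sse_r <- max(fit_mono$sse, fit_bi$sse)
  sse_f <- fit_bi$sse
  f <- if (sse_f <= 0) Inf else ((sse_r - sse_f) / df1) / (sse_f / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  aic <- function(sse, k) n * log(max(sse, 1e-300) / n) + 2 * k
  d_aic <- aic(sse_r, fit_mono$n_params) - aic(sse_f, fit_bi$n_params)
  structure(list(f_statistic = f, p_value = p, delta_aic = d_aic,
                 alpha = alpha,
                 preferred = if (is.finite(p) && p < alpha) "biphasic"
                             else "monophasic"),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "Extra-sum-of-squares F = %.4g, p = %.3g; dAIC = %.4g; preferred: %s\n",
    x$f_statistic, x$p_value, x$delta_aic, x$preferred))
  invisible(x)
}

#' Contribution of free retinol to protein-bound accumulation
#'
#' For each time point, the cellular accumulation observed with protein-free
#' ROH (at the free concentration present in a protein-bound preparation) is
#' divided by the total accumulation observed for the protein-bound sample.
#' Replicates are averaged per time point; the two curves are linearly
#' interpolated onto the coarser of the two time grids restricted to the
#' overlapping time range. Ratios at times where the denominator is zero
#' (typically t = 0) are returned as `NA`.
#'
#' @param free_tc [timecourse()] measured with protein-free ROH.
#' @param bound_tc [timecourse()] measured with the protein-bound preparation.
#' @return data.frame with columns `time`, `ratio` (free/bound, uncapped) and
#'   `percent` (100 x ratio, capped at 100 for reporting).
#' @export
free_contribution_fraction <- function(free_tc, bound_tc) {
  stopifnot(inherits(free_tc, "timecourse"), inherits(bound_tc, "timecourse"))
  avg <- function(tc) {
    ag <- stats::aggregate(ccell ~ time, data = as.data.frame(tc), FUN = mean)
    ag[order(ag$time), ]
  }
  fa <- avg(free_tc); ba <- avg(bound_tc)
  t0 <- max(min(fa$time), min(ba$time))
  t1 <- min(max(fa$time), max(ba$time))
  if (t0 > t1) stop("time ranges do not overlap", call. = FALSE)
  grid_of <- function(a) a$time[a$time >= t0 & a$time <= t1]
  gf <- grid_of(fa); gb <- grid_of(ba)
  grid <- if (length(gf) <= length(gb)) gf else gb
  fv <- stats::approx(fa$time, fa$ccell, xout = grid)$y
  bv <- stats::approx(ba$time, ba$ccell, xout = grid)$y
  ratio <- ifelse(bv > 0, fv / bv, NA_real_)
  data.frame(time = grid, ratio = ratio,
             percent = pmin(100 * ratio, 100))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
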