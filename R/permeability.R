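#' Transwell insert geometry
#'
#' Defaults match a 12-well Transwell permeability assay: 1.12 cm^2 membrane,
#' 550 uL apical donor volume, 1500 uL basolateral receiver volume. Samples
#' drawn from the basolateral chamber are replaced with the same volume of
#' buffer; apical draws are not replaced.
#'
#' @param membrane_area Insert membrane area, cm^2.
#' @param apical_volume Apical chamber volume, L.
#' @param basolateral_volume Basolateral chamber volume, L.
#' @param sample_volume Volume withdrawn per basolateral sample, L. The
#'   default (3e-5 L) keeps the total withdrawn over four 15-min draws plus
#'   t = 0 at 10 percent of the basolateral bulk volume.
#' @return Object of class `"transwell_geometry"`.
#' @export
transwell_geometry <- function(membrane_area = 1.12,
                               apical_volume = 5.5e-4,
                               basolateral_volume = 1.5e-3,
                               sample_volume = 3e-5) {
  v <- c(membrane_area, apical_volume, basolateral_volume, sample_volume)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all geometry fields must be > 0", call. = FALSE)
  if (sample_volume >= basolateral_volume)
    stop("sample_volume must be smaller than basolateral_volume",
         call. = FALSE)
  structure(list(membrane_area = membrane_area,
                 apical_volume = apical_volume,
                 basolateral_volume = basolateral_volume,
                 sample_volume = sample_volume),
            class = "transwell_geometry")
}

#' Sampling-corrected cumulative basolateral amount
#'
#' Basolateral samples are replaced with fresh buffer, so the measured
#' concentration series under-counts mass already withdrawn. The cumulative
#' amount that has crossed into the basolateral chamber by sample k is
#' \deqn{Q(t_k) = C_k V_b + \sum_{j<k} C_j v_s,}
#' i.e. the amount currently in the chamber plus everything removed in prior
#' draws. With a constant underlying flux this correction exactly undoes the
#' withdrawals, so the fitted slope is schedule-invariant.
#'
#' @param conc Basolateral concentrations at the sampling times, uM.
#' @param times Sampling times, min, sorted increasing.
#' @param geometry A [transwell_geometry()].
#' @param sample_volume Withdrawn volume per draw, L; defaults to the
#'   geometry's value.
#' @return data.frame with columns `time` (min) and `amount` (umol).
#' @export
cumulative_basolateral_amount <- function(conc, times,
                                          geometry = transwell_geometry(),
                                          sample_volume =
                                            geometry$sample_volume) {
  stopifnot(inherits(geometry, "transwell_geometry"),
            length(conc) == length(times))
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (sample_volume >= geometry$basolateral_volume)
    stop("sample_volume must be smaller than basolateral_volume",
         call. = FALSE)
  withdrawn <- c(0, cumsum(conc * sample_volume))[seq_along(conc)]
  data.frame(time = times,
             amount = conc * geometry$basolateral_volume + withdrawn)
}

#' Apparent permeability from cumulative receiver amounts
#'
#' Ordinary least-squares slope of the cumulative basolateral amount Q versus
#' time over the regression window, divided by membrane area and donor
#' concentration:
#' \deqn{P_{e,app} = \frac{dQ/dt}{A \cdot C_0}}
#' with units converted from umol/min/(cm^2 uM) to cm/s (x 1000/60: 1 L =
#' 1000 cm^3, 1 min = 60 s). The default window starts at the first non-zero
#' sampling time, excluding t = 0 to skip the initial lag before basolateral
#' accumulation becomes linear.
#'
#' @param Q data.frame with columns `time` (min) and `amount` (umol), e.g.
#'   from [cumulative_basolateral_amount()].
#' @param c0 Donor (apical) reference concentration, uM; the measured t = 0
#'   apical concentration when available, else the nominal loading.
#' @param area Membrane area, cm^2.
#' @param window Length-2 numeric, time window (min) for the regression;
#'   default `c(min positive time, Inf)`.
#' @return Object of class `"permeability_result"`: `pe_app` (cm/s), `slope`
#'   (umol/min), `intercept`, `c0`, `r_squared`, `n_points`, `window`.
#' @export
apparent_permeability <- function(Q, c0, area = 1.12, window = NULL) {
  stopifnot(is.data.frame(Q), all(c("time", "amount") %in% names(Q)))
  if (!is.numeric(c0) || length(c0) != 1L || is.na(c0) || c0 <= 0)
    stop("c0 must be > 0 uM", call. = FALSE)
  if (is.null(window)) {
    tpos <- Q$time[Q$time > 0]
    if (!length(tpos)) stop("no positive-time points", call. = FALSE)
    window <- c(min(tpos), Inf)
  }
  sel <- Q$time >= window[1] & Q$time <= window[2]
  if (sum(sel) < 3)
    stop("regression window must contain >= 3 points", call. = FALSE)
  fit <- stats::lm(amount ~ time, data = Q[sel, ])
  slope <- unname(stats::coef(fit)["time"])          # umol / min
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((Q$amount[sel] - mean(Q$amount[sel]))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  pe <- slope / (area * c0) * 1000 / 60              # L/(min cm^2) -> cm/s
  structure(list(pe_app = max(pe, 0), slope = slope,
                 intercept = unname(stats::coef(fit)[1]), c0 = c0,
                 r_squared = min(max(r2, 0), 1), n_points = sum(sel),
                 window = window),
            class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf(
    "Pe_app = %.3g cm/s (slope %.3g umol/min, C0 %.3g uM, R^2 %.4f, n=%d)\n",
    x$pe_app, x$slope, x$c0, x$r_squared, x$n_points))
  invisible(x)
}

#' Transwell assay container
#'
#' Long-format measurements of a dual-tracer Transwell permeability assay.
#' Each row is one measurement: a chamber concentration or a lysate amount at
#' a sampling time for one isotope channel and replicate.
#'
#' @param data data.frame with columns `time` (min), `compartment`
#'   (`"apical"`, `"basolateral"`, `"lysate"`), `channel` (e.g. `"H3"`,
#'   `"C14"`), `replicate`, and `conc_uM` (chamber rows, uM) or `amount_umol`
#'   (either may be NA where the other applies; lysate rows must carry
#'   `amount_umol`).
#' @param geometry A [transwell_geometry()].
#' @param c0 Named numeric of nominal loading concentrations per channel, uM
#'   (fallback when no measured t = 0 apical concentration exists).
#' @return Object of class `"transwell_assay"`.
#' @export
transwell_assay <- function(data, geometry = transwell_geometry(),
                            c0 = NULL) {
  req <- c("time", "compartment", "channel", "replicate")
  if (!all(req %in% names(data)))
    stop("data must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!any(c("conc_uM", "amount_umol") %in% names(data)))
    stop("data must carry conc_uM and/or amount_umol", call. = FALSE)
  if (!"conc_uM" %in% names(data)) data$conc_uM <- NA_real_
  if (!"amount_umol" %in% names(data)) data$amount_umol <- NA_real_
  bad <- setdiff(unique(data$compartment),
                 c("apical", "basolateral", "lysate"))
  if (length(bad))
    stop("unknown compartment(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(data = data, geometry = geometry, c0 = c0),
            class = "transwell_assay")
}

.assay_c0 <- function(assay, channel, replicate) {
  d <- assay$data
  sel <- d$channel == channel & d$replicate == replicate &
    d$compartment == "apical" & d$time == 0 & !is.na(d$conc_uM)
  if (any(sel)) return(mean(d$conc_uM[sel]))
  if (!is.null(assay$c0) && channel %in% names(assay$c0))
    return(assay$c0[[channel]])
  stop("no t=0 apical concentration and no nominal c0 for channel ",
       channel, call. = FALSE)
}

#' Apparent permeability for every channel and replicate of an assay
#'
#' Applies [cumulative_basolateral_amount()] and [apparent_permeability()] to
#' each (channel, replicate) of a [transwell_assay()], using the measured
#' t = 0 apical concentration as C0 (nominal fallback).
#'
#' @param assay A [transwell_assay()].
#' @param window Regression window passed to [apparent_permeability()].
#' @return data.frame with one row per channel x replicate: `channel`,
#'   `replicate`, `pe_app` (cm/s), `r_squared`, `c0`; plus per-channel mean
#'   and sd in the `"summary"` attribute.
#' @export
assay_permeability <- function(assay, window = NULL) {
  stopifnot(inherits(assay, "transwell_assay"))
  d <- assay$data
  bl <- d[d$compartment == "basolateral" & !is.na(d$conc_uM), ]
  combos <- unique(bl[, c("channel", "replicate")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    ch <- combos$channel[i]; rp <- combos$replicate[i]
    b <- bl[bl$channel == ch & bl$replicate == rp, ]
    b <- b[order(b$time), ]
    Q <- cumulative_basolateral_amount(b$conc_uM, b$time, assay$geometry)
    pr <- apparent_permeability(Q, c0 = .assay_c0(assay, ch, rp),
                                area = assay$geometry$membrane_area,
                                window = window)
    data.frame(channel = ch, replicate = rp, pe_app = pr$pe_app,
               r_squared = pr$r_squared, c0 = pr$c0)
  })
  res <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(res, res$channel), function(g)
    data.frame(channel = g$channel[1], mean_pe = mean(g$pe_app),
               sd_pe = stats::sd(g$pe_app), n = nrow(g))))
  attr(res, "summary") <- summ
  res
}

#' Mass-balance closure of a Transwell assay
#'
#' Fraction of the initially loaded tracer recovered at assay end:
#' \deqn{\frac{N_{apical,end} + N_{apical,sampled} + Q_{basolateral}(end) +
#'   N_{lysate}}{N_{loaded}}}
#' where apical draws (not replaced) are credited back at the concentration
#' observed when drawn, the basolateral term is the sampling-corrected
#' cumulative amount, and the lysate term is the cell-associated amount.
#' Actual end-of-assay apical volume (initial minus draws) is used.
#'
#' @param assay A [transwell_assay()]. Needs apical concentrations at 0 and
#'   the final time, the basolateral series, and a lysate `amount_umol` row
#'   per channel/replicate.
#' @param apical_sample_volume Volume per apical draw, L; defaults to the
#'   geometry's basolateral sample volume.
#' @return data.frame per channel x replicate with components
#'   `apical_end`, `apical_sampled`, `basolateral`, `lysate`, `loaded`
#'   (umol) and `fraction_recovered`.
#' @export
mass_balance <- function(assay,
                         apical_sample_volume = assay$geometry$sample_volume) {
  stopifnot(inherits(assay, "transwell_assay"))
  d <- assay$data
  g <- assay$geometry
  combos <- unique(d[d$compartment == "basolateral",
                     c("channel", "replicate")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    ch <- combos$channel[i]; rp <- combos$replicate[i]
    sub <- d[d$channel == ch & d$replicate == rp, ]
    ap <- sub[sub$compartment == "apical" & !is.na(sub$conc_uM), ]
    bl <- sub[sub$compartment == "basolateral" & !is.na(sub$conc_uM), ]
    ly <- sub[sub$compartment == "lysate" & !is.na(sub$amount_umol), ]
    missing <- c(if (!nrow(ap)) "apical", if (!nrow(bl)) "basolateral",
                 if (!nrow(ly)) "lysate")
    if (length(missing))
      stop("mass_balance: missing compartment(s) for channel ", ch,
           " replicate ", rp, ": ", paste(missing, collapse = ", "),
           call. = FALSE)
    ap <- ap[order(ap$time), ]
    c0 <- ap$conc_uM[ap$time == 0][1]
    if (is.na(c0)) stop("mass_balance: no t=0 apical sample", call. = FALSE)
    loaded <- c0 * g$apical_volume
    # apical draws happen at every apical sampling time (t=0 included), and
    # are not replaced; remaining volume shrinks accordingly
    n_draws <- nrow(ap)
    v_end <- g$apical_volume - n_draws * apical_sample_volume
    apical_sampled <- sum(ap$conc_uM) * apical_sample_volume
    apical_end <- ap$conc_uM[nrow(ap)] * v_end
    bl <- bl[order(bl$time), ]
    Q <- cumulative_basolateral_amount(bl$conc_uM, bl$time, g)
    baso <- Q$amount[nrow(Q)]
    lys <- sum(ly$amount_umol)
    data.frame(channel = ch, replicate = rp, apical_end = apical_end,
               apical_sampled = apical_sampled, basolateral = baso,
               lysate = lys, loaded = loaded,
               fraction_recovered =
                 (apical_end + apical_sampled + baso + lys) / loaded)
  })
  do.call(rbind, rows)
}

#' Normalize a basolateral accumulation series
#'
#' Element-wise division of a basolateral concentration (or amount) series by
#' a scalar reference: the apical chamber t = 0 concentration, or the
#' accumulated cellular concentration. Curves driven by a flux proportional
#' to C0 collapse onto one another after apical normalization; normalization
#' by a non-proportional cellular concentration does not collapse them.
#'
#' @param series Numeric series to normalize.
#' @param reference Positive scalar reference.
#' @return `series / reference`.
#' @export
normalize_basolateral <- function(series, reference) {
  if (!is.numeric(reference) || length(reference) != 1L ||
      is.na(reference) || reference <= 0)
    stop("reference must be a single value > 0", call. = FALSE)
  series / reference
}
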