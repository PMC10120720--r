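test_that("predict_monophasic follows the partitioning form", {
  p <- kinetic_params(Kp = 90, k1 = 0.02)
  expect_equal(predict_monophasic(p, 2, 0), 0)
  # asymptote Kp * cf
  expect_equal(predict_monophasic(p, 2, 1e6), 180, tolerance = 1e-9)
  # hand evaluation: cf=0.4 -> 36 (1 - e^-1)
  expect_equal(predict_monophasic(p, 0.4, 50), 36 * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(predict_monophasic(p, 0.4, 50), 22.7545, tolerance = 1e-4)
})

test_that("lag_time crosses the threshold or never fires", {
  expect_equal(lag_time(kinetic_params(90, 0.02, ccell_star = 0), 2), 0)
  tl <- lag_time(kinetic_params(90, 0.02, ccell_star = 36), 2)
  expect_equal(tl, -log(1 - 36 / 180) / 0.02, tolerance = 1e-12)
  expect_equal(tl, 11.157, tolerance = 1e-4)
  # threshold above the primary asymptote: trigger never fires
  expect_identical(lag_time(kinetic_params(90, 0.02, ccell_star = 36), 0.1),
                   Inf)
  expect_error(lag_time(kinetic_params(0, 0.02, ccell_star = 1), 2), "Kp")
})

test_that("predict_biphasic adds a delayed second phase", {
  p <- kinetic_params(90, 0.02, Kp_star = 70, k1_star = 0.01,
                      ccell_star = 36)
  p0 <- kinetic_params(90, 0.02)
  tt <- seq(0, 120, by = 0.5)

  # Kp_star = 0 collapses to the monophasic curve
  expect_equal(predict_biphasic(p0, 2, tt), predict_monophasic(p0, 2, tt))

  # continuity at the trigger: value equals the left limit (= ccell_star)
  tl <- lag_time(p, 2)
  eps <- 1e-9
  expect_equal(predict_biphasic(p, 2, tl), 36, tolerance = 1e-6)
  expect_equal(predict_biphasic(p, 2, tl + eps),
               predict_biphasic(p, 2, tl - eps), tolerance = 1e-6)

  # hand evaluation at t = t_lag + 60
  t1 <- tl + 60
  expect_equal(predict_biphasic(p, 2, t1),
               180 * (1 - exp(-0.02 * t1)) + 140 * (1 - exp(-0.6)),
               tolerance = 1e-12)
  # 180 (1 - e^-1.4231) = 136.63 and 140 (1 - e^-0.6) = 63.17
  expect_equal(predict_biphasic(p, 2, t1), 199.79, tolerance = 1e-4)

  # biphasic >= monophasic, both non-decreasing
  expect_true(all(predict_biphasic(p, 2, tt) >=
                    predict_monophasic(p, 2, tt) - 1e-12))
  expect_true(all(diff(predict_biphasic(p, 2, tt)) >= -1e-12))
  expect_true(all(diff(predict_monophasic(p, 2, tt)) >= -1e-12))

  # never-trigger concentration stays monophasic throughout
  expect_equal(predict_biphasic(p, 0.1, tt), predict_monophasic(p0, 0.1, tt))
})

test_that("normalized curves coincide before the trigger and split after", {
  p <- kinetic_params(90, 0.02, Kp_star = 70, k1_star = 0.01,
                      ccell_star = 36)
  cfs <- c(0.4, 2)
  tls <- vapply(cfs, function(cf) lag_time(p, cf), 0)
  tt <- seq(0, min(tls) - 1e-6, length.out = 50)
  norm <- vapply(cfs, function(cf) predict_biphasic(p, cf, tt) / cf,
                 numeric(length(tt)))
  expect_lt(max(abs(norm[, 1] - norm[, 2])), 1e-9)
  t_post <- max(tls) + 30
  expect_gt(abs(predict_biphasic(p, 2, t_post) / 2 -
                  predict_biphasic(p, 0.4, t_post) / 0.4), 1)
})

test_that("fit_accumulation recovers monophasic parameters exactly", {
  p <- kinetic_params(Kp = 90, k1 = 0.02)
  tt <- seq(5, 120, by = 5)
  tcs <- lapply(c(0.1, 0.4, 2), function(cf)
    timecourse(cf, tt, predict_monophasic(p, cf, tt)))
  fit <- fit_accumulation(tcs, model = "monophasic", n_starts = 4, seed = 1)
  expect_lt(abs(fit$params$Kp / 90 - 1), 1e-3)
  expect_lt(abs(fit$params$k1 / 0.02 - 1), 1e-3)
  expect_lt(fit$sse, 1e-8)
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$se[c("Kp", "k1")])))
})

test_that("fit_accumulation input contracts hold", {
  p <- kinetic_params(90, 0.02)
  tc1 <- timecourse(2, c(0, 10), c(0, 10))
  expect_error(fit_accumulation(list(tc1), model = "biphasic"),
               ">= 5 observations")
  expect_error(timecourse(0, 1:3, 1:3), "cf")
  expect_error(fit_accumulation(timecourse(2, c(5, 5), c(1, 1)),
                                model = "monophasic"), "distinct time")
})

test_that("per-curve fitting returns one fit per curve", {
  p <- kinetic_params(90, 0.02)
  tt <- seq(5, 120, by = 5)
  tcs <- lapply(c(0.4, 2), function(cf)
    timecourse(cf, tt, predict_monophasic(p, cf, tt),
               label = paste0("cf", cf)))
  fits <- fit_accumulation(tcs, model = "monophasic", per_curve = TRUE,
                           n_starts = 2)
  expect_named(fits, c("cf0.4", "cf2"))
  for (f in fits) expect_lt(abs(f$params$Kp / 90 - 1), 0.01)
})

test_that("compare_models applies the extra-sum-of-squares F test", {
  p <- kinetic_params(90, 0.02, Kp_star = 70, k1_star = 0.01,
                      ccell_star = 36)
  tt <- seq(5, 120, by = 5)
  tcs <- lapply(c(0.4, 2), function(cf)
    timecourse(cf, tt, predict_biphasic(p, cf, tt)))
  fb <- fit_accumulation(tcs, "biphasic", n_starts = 6, seed = 2)
  fm <- fit_accumulation(tcs, "monophasic", n_starts = 6, seed = 2)
  cmp <- compare_models(fm, fb)
  expect_s3_class(cmp, "model_comparison")
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
  expect_equal(cmp$preferred, "biphasic")
  expect_gt(cmp$delta_aic, 0)

  # identical SSE -> F = 0, monophasic retained
  fm2 <- fm; fm2$sse <- fb$sse
  cmp0 <- compare_models(fm2, fb)
  expect_equal(cmp0$f_statistic, 0)
  expect_equal(cmp0$preferred, "monophasic")

  expect_error(compare_models(fb, fb), "monophasic and a biphasic")
})

test_that("free_contribution_fraction computes interpolated ratios", {
  tt <- seq(0, 120, by = 5)
  p <- kinetic_params(90, 0.02, Kp_star = 70, k1_star = 0.01,
                      ccell_star = 36)
  bound <- timecourse(2, tt, predict_biphasic(p, 2, tt))

  # identical curves -> 100% everywhere (t = 0 is 0/0 -> NA)
  r <- free_contribution_fraction(bound, bound)
  expect_true(is.na(r$percent[r$time == 0]))
  expect_true(all(abs(r$percent[r$time > 0] - 100) < 1e-9))

  # half curve -> 50%
  half <- timecourse(1, tt, predict_biphasic(p, 2, tt) / 2)
  r2 <- free_contribution_fraction(half, bound)
  expect_true(all(abs(r2$percent[r2$time > 0] - 50) < 1e-9))

  # analytic ratio of two known curves, free on a finer grid
  tf <- seq(0, 120, by = 1)
  pf_ <- kinetic_params(90, 0.02)
  free <- timecourse(0.4, tf, predict_monophasic(pf_, 0.4, tf))
  r3 <- free_contribution_fraction(free, bound)
  expect_equal(r3$time, tt)  # coarser grid wins
  want <- predict_monophasic(pf_, 0.4, tt) / predict_biphasic(p, 2, tt)
  expect_equal(r3$ratio[-1], want[-1], tolerance = 1e-9)
  expect_true(all(r3$percent <= 100, na.rm = TRUE))
})
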