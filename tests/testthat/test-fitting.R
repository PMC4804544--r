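test_that("observation series validate their structure and arm metadata", {
  s <- observation_series(c(0, 3, 7), c(100, 150, 220), sds = c(5, 8, 11))
  expect_s3_class(s, "observation_series")
  expect_identical(attr(s, "group"), "control")
  expect_error(observation_series(c(0, 3, 3), c(1, 2, 3)), "increasing")
  expect_error(observation_series(c(0, 3), c(100, -1)), "positive")
  expect_error(observation_series(c(0, 3), c(1, 2), group = "treatment"),
               "regimen")
})

test_that("residuals vanish at the generating truth and reject unknown parameters", {
  truth <- growth_params(lambda1 = 0.15, c = 3, d = 0.005)
  s <- generate_series(truth, twice_weekly(), init = c(V = 200, K = 400),
                       noise_cv = 0)
  r <- growth_residuals(c(lambda1 = 0.15, c = 3, d = 0.005, K0 = 400), s,
                        fixed = truth)
  expect_lt(max(abs(r)), 1e-6)
  expect_length(r, nrow(s))
  expect_error(growth_residuals(c(lambda0 = 1), s, fixed = truth), "unknown")
  # local convexity probe: moving c off the truth increases the cost
  r_up <- growth_residuals(c(lambda1 = 0.15, c = 3.3, d = 0.005, K0 = 400),
                           s, fixed = truth)
  expect_gt(sum(r_up^2), sum(r^2))
  # SD weighting rescales by the per-time uncertainty, relative by volume
  s_sd <- observation_series(s$time, s$volume, sds = rep(2, nrow(s)))
  rw <- growth_residuals(c(lambda1 = 0.15, c = 3.3, d = 0.005, K0 = 400),
                         s_sd, fixed = truth, weighting = "sd")
  expect_equal(rw, r_up / 2, tolerance = 1e-12)
  rr <- growth_residuals(c(lambda1 = 0.15, c = 3.3, d = 0.005, K0 = 400),
                         s, fixed = truth, weighting = "relative")
  expect_equal(rr, r_up / s$volume, tolerance = 1e-12)
})

test_that("control-stage fit recovers the generating parameters from clean data", {
  truth <- growth_params(lambda1 = 0.15, c = 3, d = 0.005)
  s <- generate_series(truth, twice_weekly(), init = c(V = 200, K = 400),
                       noise_cv = 0)
  fit <- fit_control(s)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates$lambda1 - 0.15) / 0.15, 0.01)
  expect_lt(abs(fit$estimates$c - 3) / 3, 0.01)
  expect_lt(abs(fit$estimates$d - 0.005) / 0.005, 0.01)
  expect_lt(abs(fit$estimates$K0 - 400) / 400, 0.01)
  expect_gte(fit$estimates$K0, s$volume[1])
  expect_lt(fit$rmse, 1e-3)
  expect_lt(fit$foo, 1)
  # the solver's objective never increases across iterations
  expect_true(all(diff(fit$rsstrace) <= 1e-12))
  # refitting from the returned solution barely moves the objective
  cfg <- fit_config(free = fit$free,
                    initial = unlist(fit$estimates[c("lambda1", "c", "d", "K0")]),
                    lower = c(lambda1 = 0, c = 1e-8, d = 0, K0 = s$volume[1]),
                    upper = c(lambda1 = Inf, c = Inf, d = Inf, K0 = Inf))
  refit <- fit_control(s, config = cfg)
  expect_lt(abs(refit$objective - fit$objective),
            1e-6 * (1 + fit$objective))
})

test_that("fits with fewer observations than free parameters warn", {
  truth <- growth_params()
  s <- generate_series(truth, c(0, 4, 8), init = c(V = 200, K = 625),
                       noise_cv = 0)
  w <- capture_warnings(fit <- fit_control(s))
  expect_match(w, "under-determined", all = FALSE)
  expect_false(fit$converged)
})

test_that("treatment-stage fit honours the two-stage protocol on clean data", {
  control_truth <- growth_params(lambda1 = 0.15, c = 3, d = 0.005)
  ctrl <- generate_series(control_truth, twice_weekly(),
                          init = c(V = 200, K = 400), noise_cv = 0)
  cfit <- fit_control(ctrl)
  reg <- ref_regimen()
  pk <- ref_pk()
  # treated truth: stimulation reduced 30 %, abnormal vasculature switched on
  treat_truth <- growth_params(lambda1 = 0.15, c = 2.1, d = 0.005,
                               beta = 14, p = 6)
  obs <- seq(1, 29, by = 3.5)
  ts <- generate_series(treat_truth, obs, init = c(V = 230, K = 460),
                        regimen = reg, pk = pk, noise_cv = 0)
  tfit <- fit_treatment(ts, cfit, pk)
  expect_true(tfit$converged)
  # d stays pinned to the control estimate
  expect_identical(tfit$estimates$d, cfit$estimates$d)
  # near-perfect fit, with the growth rate at or below the control estimate
  expect_lt(tfit$rmse, 1)
  expect_lte(tfit$estimates$lambda1, cfit$estimates$lambda1 + 1e-12)
  # K0 was free because the first observation coincides with the first dose
  expect_true("K0" %in% tfit$free)
  # an explicit config equal to the default reproduces the same fit
  manual <- fit_config(
    free = c("lambda1", "c", "beta", "p", "K0"),
    initial = c(lambda1 = cfit$estimates$lambda1, c = cfit$estimates$c,
                beta = 1, p = 0,
                K0 = ts$volume[1] * cfit$estimates$K0 / cfit$estimates$V0),
    lower = c(lambda1 = 0, c = 1e-8, beta = 0, p = 0, K0 = ts$volume[1]),
    upper = c(lambda1 = cfit$estimates$lambda1, c = Inf, beta = Inf,
              p = Inf, K0 = Inf))
  tfit2 <- fit_treatment(ts, cfit, pk, config = manual)
  expect_equal(tfit2$estimates, tfit$estimates, tolerance = 1e-10)
})

test_that("a zero-dose treatment arm behaves like a control fit", {
  control_truth <- growth_params(lambda1 = 0.15, c = 3, d = 0.005)
  ctrl <- generate_series(control_truth, twice_weekly(),
                          init = c(V = 200, K = 400), noise_cv = 0)
  cfit <- fit_control(ctrl)
  sham <- make_regimen(5, 0.025, numeric(0))
  ts <- observation_series(ctrl$time, ctrl$volume, group = "treatment",
                           regimen = sham)
  tfit <- fit_treatment(ts, cfit, ref_pk())
  # with no drug on board the control-stage estimates already fit the data
  expect_lt(tfit$rmse, 1e-3)
  expect_equal(tfit$estimates$lambda1, cfit$estimates$lambda1,
               tolerance = 1e-4)
  expect_equal(tfit$estimates$c, cfit$estimates$c, tolerance = 1e-4)
})

test_that("goodness-of-fit metrics follow their definitions", {
  s <- observation_series(c(0, 7), c(50, 150))
  fake <- structure(list(residuals = c(3, -4), foo = 0, series = s),
                    class = "fit_result")
  g <- goodness_of_fit(fake)
  expect_equal(g$rmse, sqrt((9 + 16) / 2), tolerance = 1e-9)  # 3.5355
  expect_equal(g$nrmse, 100 * g$rmse / 100, tolerance = 1e-9)
  # NRMSE is invariant to a change of volume units
  s_l <- observation_series(c(0, 7), c(50, 150) / 1000)
  fake_l <- structure(list(residuals = c(3, -4) / 1000, foo = 0,
                           series = s_l), class = "fit_result")
  expect_equal(goodness_of_fit(fake_l)$nrmse, g$nrmse, tolerance = 1e-12)
  # zero observed range leaves NRMSE undefined
  s0 <- observation_series(c(0, 7), c(100, 100))
  fake0 <- structure(list(residuals = c(0, 0), foo = 0, series = s0),
                     class = "fit_result")
  expect_warning(g0 <- goodness_of_fit(fake0), "zero range")
  expect_true(is.na(g0$nrmse))
  expect_equal(g0$rmse, 0)
})
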