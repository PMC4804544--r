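#' Tumour-volume observation series
#'
#' The unit of fitting: a time series of (mean) tumour volumes, optionally
#' with per-time standard deviations, from a control (untreated) or
#' treatment arm of a xenograft experiment.  A treatment series must carry
#' the dosing regimen that generated it.
#'
#' @param times Observation times (day), strictly increasing.
#' @param volumes Mean tumour volumes (mm^3), strictly positive.
#' @param sds Optional standard deviations (mm^3).
#' @param group `"control"` or `"treatment"`.
#' @param regimen A [make_regimen()] object (required for treatment series).
#' @return An object of class `observation_series`: data frame with columns
#'   `time`, `volume` and (optionally) `sd`, carrying `group` and `regimen`
#'   attributes.
#' @export
observation_series <- function(times, volumes, sds = NULL,
                               group = c("control", "treatment"),
                               regimen = NULL) {
  group <- match.arg(group)
  times <- as.numeric(times)
  volumes <- as.numeric(volumes)
  if (length(times) != length(volumes) || length(times) == 0L) {
    stop("'times' and 'volumes' must be non-empty and of equal length")
  }
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (any(!is.finite(volumes)) || any(volumes <= 0)) {
    stop("'volumes' must be positive and finite")
  }
  if (!is.null(sds)) {
    sds <- as.numeric(sds)
    if (length(sds) != length(times)) stop("'sds' length mismatch")
    if (any(sds < 0, na.rm = TRUE)) stop("'sds' must be non-negative")
  }
  if (group == "treatment" && !inherits(regimen, "regimen")) {
    stop("a treatment series must carry a 'regimen'")
  }
  df <- data.frame(time = times, volume = volumes)
  if (!is.null(sds)) df$sd <- sds
  structure(df, class = c("observation_series", "data.frame"),
            group = group, regimen = regimen)
}

#' @export
print.observation_series <- function(x, ...) {
  cat(sprintf("Observation series (%s arm): %d time-points, %.4g-%.4g day, %.4g-%.4g mm^3\n",
              attr(x, "group"), nrow(x), min(x$time), max(x$time),
              min(x$volume), max(x$volume)))
  NextMethod()
}

#' Fitting configuration
#'
#' Names the free parameters and supplies the initial point, box bounds and
#' termination tolerance for the bounded least-squares fits.  Normally
#' constructed internally by [fit_control()] / [fit_treatment()]; supply
#' one explicitly to override their defaults.
#'
#' @param free Character vector of free parameter names (growth coefficients
#'   and/or `"K0"`).
#' @param initial Named numeric vector of starting values covering `free`.
#' @param lower,upper Named numeric bounds; must bracket `initial`.
#' @param function_tolerance Relative termination tolerance on the sum of
#'   squares (default 1e-6).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(free, initial, lower, upper,
                       function_tolerance = 1e-6) {
  free <- as.character(free)
  for (nm in c("initial", "lower", "upper")) {
    v <- get(nm)
    if (!all(free %in% names(v))) {
      stop("'", nm, "' must supply a value for every free parameter")
    }
  }
  initial <- initial[free]; lower <- lower[free]; upper <- upper[free]
  if (any(initial < lower - 1e-12) || any(initial > upper + 1e-12)) {
    stop("bounds must bracket the initial point")
  }
  if (function_tolerance <= 0) stop("'function_tolerance' must be positive")
  structure(list(free = free, initial = initial, lower = lower,
                 upper = upper, function_tolerance = function_tolerance),
            class = "fit_config")
}

#' Model-minus-observed residuals for a candidate parameter set
#'
#' Simulates the growth model (with the series' regimen, for a treatment
#' arm) from `V0` equal to the first observed volume and `K0` taken from the
#' candidate, and returns the differences between predicted and observed
#' volumes at every observation time.  Residuals are unweighted by default,
#' matching the calibration cost of record; for data whose measurement error
#' scales with tumour size (as cohort mean +/- SD xenograft series do), the
#' `"sd"` weighting divides by the reported per-time SDs and the
#' `"relative"` weighting divides by the observed volumes (a constant-CV
#' error model that needs no SD column).
#'
#' @param candidate Named numeric vector overriding entries of `fixed`
#'   (any of `lambda1`, `lambda2`, `c`, `d`, `alpha`, `beta`, `p`) and
#'   optionally `K0`.  When `K0` is absent, the initial carrying capacity
#'   defaults to `V0 / ratio` with the reference ratio `V0/K0 = 200/625`.
#' @param series An [observation_series()].
#' @param fixed [growth_params()] providing every coefficient not in
#'   `candidate`.
#' @param pk [pk_params()]; required for treatment series.
#' @param weighting `"none"` (raw mm^3 differences), `"sd"` (divide by the
#'   series SDs) or `"relative"` (divide by the observed volumes).
#' @param rel_tol,abs_tol Integration tolerances.
#' @param plasma_density Plasma density (kg/ml) for concentration units.
#' @return Numeric vector of residuals (mm^3), one per observation.
#' @export
growth_residuals <- function(candidate, series, fixed = growth_params(),
                             pk = NULL, weighting = c("none", "sd", "relative"),
                             rel_tol = 1e-8, abs_tol = 1e-10,
                             plasma_density = 1.025e-3) {
  stopifnot(inherits(series, "observation_series"))
  weighting <- match.arg(weighting)
  gp <- unclass(fixed)
  extra <- setdiff(names(candidate), c(names(gp), "K0"))
  if (length(extra) > 0L) {
    stop("unknown candidate parameter(s): ", paste(extra, collapse = ", "))
  }
  for (nm in intersect(names(candidate), names(gp))) {
    gp[[nm]] <- unname(candidate[[nm]])
  }
  gp <- validate_growth_params(gp)
  V0 <- series$volume[1L]
  K0 <- if ("K0" %in% names(candidate)) unname(candidate[["K0"]]) else
    V0 * 625 / 200
  pred <- predict_volumes(gp, V0, K0, series, pk, rel_tol, abs_tol,
                          plasma_density)
  r <- pred - series$volume
  if (weighting == "sd") {
    if (is.null(series$sd)) stop("SD-weighted residuals require series SDs")
    if (any(series$sd <= 0)) stop("SD-weighted residuals require positive SDs")
    r <- r / series$sd
  } else if (weighting == "relative") {
    r <- r / series$volume
  }
  r
}

predict_volumes <- function(gp, V0, K0, series, pk, rel_tol, abs_tol,
                            plasma_density) {
  regimen <- attr(series, "regimen")
  treated <- identical(attr(series, "group"), "treatment") &&
    !is.null(regimen) && regimen$n > 0L
  if (treated && is.null(pk)) {
    stop("treatment series require 'pk' parameters")
  }
  if (treated) {
    conc_fn <- make_conc_fn(regimen, hybrid_constants(pk), plasma_density)
    breaks <- regimen_breaks(regimen)
  } else {
    conc_fn <- function(t) rep(0, length(t))
    breaks <- numeric(0)
  }
  times <- series$time
  if (length(times) == 1L) return(V0)
  states <- integrate_states(gp, c(V = V0, K = K0), times, conc_fn, breaks,
                             rel_tol = rel_tol, abs_tol = abs_tol)
  states$V[match(times, states$time)]
}

#' Calibrate the free-growth model to a control series
#'
#' Stage one of the two-stage calibration: bounded nonlinear least squares
#' (Levenberg-Marquardt, [minpack.lm::nls.lm()]) over the four parameters
#' `(lambda1, c, d, K0)` against an untreated tumour-volume series.  By
#' default the growth coefficients start from the reference set and `K0`
#' starts at `V0 / (200/625)`; lower bounds impose non-negativity and
#' `K0 >= V0`, which excludes biologically irrelevant untreated trajectories
#' with an initial decreasing section.
#'
#' @param series A control [observation_series()].
#' @param config Optional [fit_config()] overriding the defaults.
#' @param weighting Residual weighting passed to [growth_residuals()]
#'   (`"none"`, `"sd"` or `"relative"`).  The default `"none"` is the
#'   calibration cost of record; `"relative"` is statistically preferable
#'   when volumes span orders of magnitude with size-proportional error.
#' @param fixed [growth_params()] supplying the non-free coefficients and
#'   the default initial point.
#' @param rel_tol,abs_tol Integration tolerances used inside the residual
#'   evaluations.
#' @return An object of class `fit_result`: list with `estimates` (named
#'   list: full growth parameters plus `K0` and `V0`), `free`, `residuals`,
#'   `rmse`, `nrmse` (percent of the observed range), `foo` (first-order
#'   optimality: infinity norm of the projected gradient of the half sum of
#'   squares), `converged`, `objective` and the underlying solver report.
#' @seealso [fit_treatment()], [goodness_of_fit()]
#' @export
fit_control <- function(series, config = NULL, fixed = growth_params(),
                        weighting = "none", rel_tol = 1e-8, abs_tol = 1e-10) {
  stopifnot(inherits(series, "observation_series"))
  if (!identical(attr(series, "group"), "control")) {
    stop("fit_control expects a control series")
  }
  V0 <- series$volume[1L]
  if (is.null(config)) {
    config <- fit_config(
      free = c("lambda1", "c", "d", "K0"),
      initial = c(lambda1 = fixed$lambda1, c = fixed$c, d = fixed$d,
                  K0 = V0 * 625 / 200),
      lower = c(lambda1 = 0, c = 1e-8, d = 0, K0 = V0),
      upper = c(lambda1 = Inf, c = Inf, d = Inf, K0 = Inf))
  }
  run_fit(series, config, fixed, pk = NULL, weighting = weighting,
          rel_tol = rel_tol, abs_tol = abs_tol, plasma_density = 1.025e-3)
}

#' Calibrate the treatment model to a treated series
#'
#' Stage two: bounded least squares over `(lambda1, c, beta, p, K0)` with the
#' inhibition coefficient `d` held fixed at the control-stage estimate
#' (endogenous inhibition is taken to be unaffected by anti-VEGF treatment).
#' The initial `lambda1` and `c` come from the control fit (or from
#' `warm_start`, for dose-escalation chains where each arm starts from the
#' nearest lower dose level); `beta` and `p` start from the reference values
#' 1 and 0.  The upper bound of `lambda1` is the control estimate, admitting
#' a direct antitumour effect but not a treatment-accelerated tumour.  `K0`
#' is free only when the first observation coincides with the first dose
#' time (instantaneous-effect convention); otherwise it is fixed at
#' `V0 / ratio` with the control-fit `V0/K0` ratio.
#'
#' @param series A treatment [observation_series()] (carrying its regimen).
#' @param control_fit The `fit_result` of [fit_control()] on the matching
#'   control arm.
#' @param pk [pk_params()] for the drug.
#' @param config Optional [fit_config()] overriding the defaults.
#' @param warm_start Optional `fit_result` of the nearest lower dose level,
#'   used for the initial `lambda1`, `c`, `beta`, `p`.
#' @param plasma_density Plasma density (kg/ml).
#' @inheritParams fit_control
#' @return A `fit_result` (see [fit_control()]).
#' @export
fit_treatment <- function(series, control_fit, pk, config = NULL,
                          warm_start = NULL, weighting = "none",
                          plasma_density = 1.025e-3,
                          rel_tol = 1e-8, abs_tol = 1e-10) {
  stopifnot(inherits(series, "observation_series"),
            inherits(control_fit, "fit_result"))
  if (!identical(attr(series, "group"), "treatment")) {
    stop("fit_treatment expects a treatment series")
  }
  if (!control_fit$converged) {
    stop("the control-stage fit did not converge; refusing to chain")
  }
  regimen <- attr(series, "regimen")
  V0 <- series$volume[1L]
  est <- control_fit$estimates
  ws <- if (is.null(warm_start)) NULL else warm_start$estimates
  lam1_0 <- if (is.null(ws)) est$lambda1 else ws$lambda1
  c_0 <- if (is.null(ws)) est$c else ws$c
  beta_0 <- if (is.null(ws)) 1 else ws$beta
  p_0 <- if (is.null(ws)) 0 else ws$p
  K0_default <- V0 * est$K0 / est$V0
  K0_free <- regimen$n > 0L &&
    isTRUE(abs(series$time[1L] - regimen$events$t_D[1L]) < 1e-9)

  fixed <- growth_params(lambda1 = lam1_0, c = c_0, d = est$d,
                         alpha = est$alpha, beta = beta_0, p = p_0,
                         v_star = est$v_star)
  if (is.null(config)) {
    free <- c("lambda1", "c", "beta", "p", if (K0_free) "K0")
    initial <- c(lambda1 = lam1_0, c = c_0, beta = beta_0, p = p_0,
                 K0 = max(K0_default, V0))
    lower <- c(lambda1 = 0, c = 1e-8, beta = 0, p = 0, K0 = V0)
    upper <- c(lambda1 = est$lambda1, c = Inf, beta = Inf, p = Inf, K0 = Inf)
    config <- fit_config(free, initial[free], lower[free], upper[free])
  }
  extra <- if (K0_free) NULL else c(K0 = K0_default)
  run_fit(series, config, fixed, pk = pk, weighting = weighting,
          rel_tol = rel_tol, abs_tol = abs_tol,
          plasma_density = plasma_density, pinned = extra)
}

## Shared bounded-LS driver.  `pinned` holds parameters outside `config$free`
## that must still reach the residual function (e.g. a fixed K0).
run_fit <- function(series, config, fixed, pk, rel_tol, abs_tol,
                    plasma_density, pinned = NULL, weighting = "none") {
  stopifnot(inherits(config, "fit_config"))
  if (nrow(series) < length(config$free)) {
    warning("fewer observations (", nrow(series), ") than free parameters (",
            length(config$free), "): the fit is under-determined")
  }
  resid_fn <- function(par) {
    growth_residuals(c(par, pinned), series, fixed = fixed, pk = pk,
                     weighting = weighting, rel_tol = rel_tol,
                     abs_tol = abs_tol, plasma_density = plasma_density)
  }
  sol <- minpack.lm::nls.lm(
    par = config$initial, lower = config$lower, upper = config$upper,
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      ftol = config$function_tolerance, maxiter = 150))
  par <- stats::coef(sol)
  ## never report an out-of-bounds point
  par <- pmin(pmax(par, config$lower), config$upper)
  rw <- resid_fn(par)
  foo <- projected_gradient_norm(resid_fn, par, rw, config$lower, config$upper)
  ## goodness-of-fit metrics are always reported on the raw mm^3 residuals,
  ## whatever weighting the optimization used
  r <- if (identical(weighting, "none")) rw else {
    growth_residuals(c(par, pinned), series, fixed = fixed, pk = pk,
                     weighting = "none", rel_tol = rel_tol,
                     abs_tol = abs_tol, plasma_density = plasma_density)
  }
  est <- unclass(fixed)
  for (nm in intersect(names(par), names(est))) est[[nm]] <- unname(par[[nm]])
  V0 <- series$volume[1L]
  est$K0 <- if ("K0" %in% names(par)) unname(par[["K0"]]) else
    if ("K0" %in% names(pinned)) unname(pinned[["K0"]]) else V0 * 625 / 200
  est$V0 <- V0
  rng <- diff(range(series$volume))
  rmse <- sqrt(mean(r^2))
  structure(list(
    estimates = est, free = config$free, residuals = r,
    rmse = rmse,
    nrmse = if (rng > 0) 100 * rmse / rng else NA_real_,
    foo = foo,
    converged = sol$info %in% 1:4,
    objective = sol$deviance, rsstrace = sol$rsstrace,
    niter = sol$niter, info = sol$info, message = sol$message,
    config = config, series = series, resid_fn = resid_fn),
    class = "fit_result")
}

## Infinity norm of the projected gradient g = J^T r of 0.5 * sum(r^2),
## with the Jacobian taken by finite differences of the residual vector
## (so a near-zero residual yields a near-zero gradient regardless of
## curvature).  Components pushing against an active box bound are zeroed.
projected_gradient_norm <- function(resid_fn, par, r, lower, upper) {
  g <- vapply(seq_along(par), function(j) {
    h <- max(1e-7, 1e-7 * abs(par[j]))
    pj <- par
    if (par[j] + h <= upper[j]) {
      pj[j] <- par[j] + h
      sum((resid_fn(pj) - r) / h * r)
    } else {
      pj[j] <- par[j] - h
      sum((r - resid_fn(pj)) / h * r)
    }
  }, numeric(1))
  tol <- 1e-8 * pmax(1, abs(par))
  at_lower <- par - lower <= tol
  at_upper <- upper - par <= tol
  g[at_lower & g > 0] <- 0
  g[at_upper & g < 0] <- 0
  if (length(g) == 0L) return(0)
  max(abs(g))
}

#' Goodness-of-fit metrics
#'
#' Root-mean-square error, its normalization by the observed volume range,
#' and the first-order optimality measure of a completed fit:
#' `rmse = sqrt(sum(r^2)/n)`, `nrmse = 100 * rmse / diff(range(volumes))`,
#' `foo = ` infinity norm of the projected gradient of half the sum of
#' squared residuals at the solution.
#'
#' @param result A `fit_result`.
#' @param series The fitted [observation_series()]; defaults to the series
#'   stored in `result`.
#' @return Named list `(rmse, nrmse, foo)`; `nrmse` is `NA` (with a
#'   warning) when the observed volumes have zero range.
#' @export
goodness_of_fit <- function(result, series = NULL) {
  stopifnot(inherits(result, "fit_result"))
  if (is.null(series)) series <- result$series
  r <- result$residuals
  rmse <- sqrt(mean(r^2))
  rng <- diff(range(series$volume))
  if (rng <= 0) {
    warning("observed volumes have zero range: NRMSE is undefined")
    nrmse <- NA_real_
  } else {
    nrmse <- 100 * rmse / rng
  }
  list(rmse = rmse, nrmse = nrmse, foo = result$foo)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Bounded least-squares fit (", paste(x$free, collapse = ", "), ")\n",
      sep = "")
  est <- unlist(x$estimates[c("lambda1", "c", "d", "beta", "p", "K0")])
  print(signif(est, 5))
  cat(sprintf("RMSE %.4g mm^3 | NRMSE %.3g %% | first-order optimality %.3g | %s (%d iterations)\n",
              x$rmse, x$nrmse, x$foo,
              if (x$converged) "converged" else "NOT converged", x$niter))
  invisible(x)
}
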