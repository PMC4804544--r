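#' Generate a synthetic xenograft observation series
#'
#' Emulates the statistical structure of small-cohort mouse xenograft
#' experiments: the truth trajectory is simulated from known parameters,
#' each virtual animal observes it under multiplicative lognormal
#' measurement noise with a given coefficient of variation, and the series
#' reports the per-time cohort mean and standard deviation.  Lognormal
#' (rather than additive Gaussian) noise keeps volumes positive and scales
#' the error with tumour size, as caliper measurements do; the noise is
#' mean-preserving (`meanlog = log(V) - sigma^2/2`).
#'
#' The generator assumes a single truth per arm: the ODE model describes a
#' homogeneous tumour, so inter-animal parameter heterogeneity, dropout and
#' measurement bias are deliberately not modelled.
#'
#' @param truth [growth_params()] generating the underlying trajectory.
#' @param obs_times Observation times (day), strictly increasing; typically
#'   twice-weekly.
#' @param init Named vector `c(V =, K =)` of true initial volumes (mm^3).
#' @param regimen Optional [make_regimen()]; when given (with `pk`) the arm
#'   is a treatment arm and the series carries the regimen.
#' @param pk [pk_params()]; required with a regimen.
#' @param n_animals Cohort size (>= 1).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise (0 gives noise-free means and zero SDs).
#' @param seed Optional integer seed making the draw reproducible.
#' @param plasma_density Plasma density (kg/ml).
#' @return An [observation_series()] with per-time means and SDs.
#' @examples
#' s <- generate_series(growth_params(), obs_times = seq(0, 14, 3.5),
#'                      noise_cv = 0.05, n_animals = 10, seed = 1)
#' s
#' @export
generate_series <- function(truth, obs_times, init = c(V = 200, K = 625),
                            regimen = NULL, pk = NULL, n_animals = 10,
                            noise_cv = 0.05, seed = NULL,
                            plasma_density = 1.025e-3) {
  stopifnot(inherits(truth, "growth_params"))
  obs_times <- as.numeric(obs_times)
  if (any(diff(obs_times) <= 0)) stop("'obs_times' must be strictly increasing")
  if (n_animals < 1L) stop("'n_animals' must be at least 1")
  if (noise_cv < 0) stop("'noise_cv' must be non-negative")
  group <- if (!is.null(regimen) && regimen$n > 0L) "treatment" else "control"

  if (!is.null(regimen) && is.null(pk)) stop("a 'regimen' requires 'pk'")
  conc_fn <- if (!is.null(regimen) && regimen$n > 0L) {
    make_conc_fn(regimen, hybrid_constants(pk), plasma_density)
  } else {
    function(t) rep(0, length(t))
  }
  states <- integrate_states(truth, init, obs_times, conc_fn,
                             regimen_breaks(regimen))
  v_true <- states$V[match(obs_times, states$time)]

  if (noise_cv == 0) {
    return(observation_series(obs_times, v_true,
                              sds = rep(0, length(obs_times)),
                              group = group, regimen = regimen))
  }
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(log1p(noise_cv^2))
  draws <- matrix(
    stats::rlnorm(length(obs_times) * n_animals,
                  meanlog = rep(log(v_true) - sigma^2 / 2, each = n_animals),
                  sdlog = sigma),
    nrow = n_animals)
  means <- colMeans(draws)
  sds <- if (n_animals > 1L) apply(draws, 2L, stats::sd) else
    rep(0, length(obs_times))
  observation_series(obs_times, means, sds = sds, group = group,
                     regimen = regimen)
}

#' Read and write observation series as CSV
#'
#' CSV columns are `time_day`, `volume_mm3` and optionally `sd_mm3`.  The
#' round trip is lossless to full double precision; files with missing or
#' non-numeric fields or non-increasing times are rejected with the
#' offending line numbers.
#'
#' @param series An [observation_series()].
#' @param path CSV file path.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "observation_series"))
  df <- data.frame(time_day = series$time, volume_mm3 = series$volume)
  if (!is.null(series$sd)) df$sd_mm3 <- series$sd
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @param group,regimen Arm metadata attached to the series on reading (the
#'   CSV holds only the measurements).
#' @return `read_series` returns an [observation_series()].
#' @export
read_series <- function(path, group = c("control", "treatment"),
                        regimen = NULL) {
  group <- match.arg(group)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_day", "volume_mm3")
  if (!all(need %in% names(df))) {
    stop("'", path, "' must contain columns ", paste(need, collapse = ", "))
  }
  for (col in intersect(c("time_day", "volume_mm3", "sd_mm3"), names(df))) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(vals))
    if (length(bad) > 0L) {
      stop("non-numeric or missing '", col, "' in '", path, "' at line(s) ",
           paste(bad + 1L, collapse = ", "))  # +1 for the header line
    }
    df[[col]] <- vals
  }
  nonmono <- which(diff(df$time_day) <= 0)
  if (length(nonmono) > 0L) {
    stop("times in '", path, "' are not strictly increasing at line(s) ",
         paste(nonmono + 2L, collapse = ", "))
  }
  observation_series(df$time_day, df$volume_mm3,
                     sds = if ("sd_mm3" %in% names(df)) df$sd_mm3 else NULL,
                     group = group, regimen = regimen)
}
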