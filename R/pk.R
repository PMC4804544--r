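#' Two-compartment pharmacokinetic parameters
#'
#' Micro-constants of the two-compartment model with first-order elimination
#' from the central compartment (plasma plus well-perfused organs) and
#' first-order exchange with a peripheral compartment.  Defaults are the
#' mouse bevacizumab values used by the package's worked examples.
#'
#' @param Vc Central-compartment volume (ml).
#' @param k12 Central-to-peripheral transfer rate (day^-1).
#' @param k21 Peripheral-to-central transfer rate (day^-1).
#' @param ke Elimination rate from the central compartment (day^-1).
#' @return An object of class `pk_params`.
#' @seealso [hybrid_constants()]
#' @export
pk_params <- function(Vc = 7.975, k12 = 0.7536, k21 = 0.3144, ke = 0.3888) {
  pk <- list(Vc = Vc, k12 = k12, k21 = k21, ke = ke)
  for (f in names(pk)) {
    x <- pk[[f]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop("pk_params field '", f, "' must be a single positive number")
    }
  }
  S <- k12 + k21 + ke
  if (S^2 <= 4 * k21 * ke) {
    stop("(k12 + k21 + ke)^2 must exceed 4 k21 ke for distinct real ",
         "hybrid rates")
  }
  structure(pk, class = "pk_params")
}

#' Hybrid (macro) constants of the bi-exponential disposition
#'
#' Converts micro-constants to the macro form of the two-compartment model:
#' hybrid rates `a` (fast) and `b` (slow) are the roots of
#' \eqn{x^2 - (k_{12}+k_{21}+k_e)x + k_{21}k_e = 0}, computed as
#' \deqn{b = \tfrac12\left(S - \sqrt{S^2 - 4 k_{21} k_e}\right), \quad
#'       a = k_{21} k_e / b, \quad S = k_{12}+k_{21}+k_e,}
#' with coefficients
#' \deqn{A = \frac{1}{V_c}\frac{a - k_{21}}{a - b}, \quad
#'       B = \frac{1}{V_c}\frac{b - k_{21}}{b - a}.}
#' They satisfy `a + b = S`, `a * b = k21 * ke` and `A + B = 1/Vc`.
#'
#' @param pk A [pk_params()] object.
#' @return An object of class `hybrid_constants`: list with `a`, `b`
#'   (day^-1) and `A`, `B` (ml^-1).
#' @examples
#' hybrid_constants(pk_params())
#' @export
hybrid_constants <- function(pk) {
  stopifnot(inherits(pk, "pk_params"))
  S <- pk$k12 + pk$k21 + pk$ke
  disc <- S^2 - 4 * pk$k21 * pk$ke
  if (disc <= 0) stop("non-positive discriminant: no distinct real hybrid rates")
  b <- 0.5 * (S - sqrt(disc))
  a <- pk$k21 * pk$ke / b
  A <- (1 / pk$Vc) * (a - pk$k21) / (a - b)
  B <- (1 / pk$Vc) * (b - pk$k21) / (b - a)
  structure(list(a = a, b = b, A = A, B = B), class = "hybrid_constants")
}

#' @export
print.hybrid_constants <- function(x, ...) {
  cat(sprintf("Hybrid constants: a = %.6g, b = %.6g day^-1; A = %.6g, B = %.6g ml^-1\n",
              x$a, x$b, x$A, x$B))
  invisible(x)
}

#' Intravenous-infusion dosing regimen
#'
#' Builds the ordered list of infusion events for a weight-based dosing
#' schedule: each event delivers an absolute dose `D = dosage * weight` (mg)
#' at a constant rate `D / duration` over the infusion window
#' `[t_D, t_D + duration]` (zero-order absorption).
#'
#' @param dosage Per-weight dose level (mg/kg).
#' @param weight Host body mass (kg).
#' @param days Administration time-points (day); must be distinct.
#' @param duration Infusion duration (day), strictly positive.  The default
#'   1/48 day is a 30-minute infusion.
#' @return An object of class `regimen`: list with `events` (data frame with
#'   columns `t_D`, `D`, `duration`, sorted by `t_D`), `dosage`, `weight`
#'   and `n` (number of infusions).
#' @examples
#' make_regimen(5, 0.025, c(1, 4, 8, 11, 15, 18, 22, 25, 29))
#' @export
make_regimen <- function(dosage, weight, days, duration = 1 / 48) {
  if (!is.numeric(dosage) || length(dosage) != 1L || dosage < 0) {
    stop("'dosage' must be a single non-negative number")
  }
  if (!is.numeric(weight) || length(weight) != 1L || weight <= 0) {
    stop("'weight' must be a single positive number")
  }
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop("'duration' must be a single positive number")
  }
  days <- as.numeric(days)
  if (anyDuplicated(days)) stop("duplicate administration days in 'days'")
  days <- sort(days)
  events <- data.frame(t_D = days, D = rep(dosage * weight, length(days)),
                       duration = rep(duration, length(days)))
  structure(list(events = events, dosage = dosage, weight = weight,
                 n = nrow(events)),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("Infusion regimen: %d dose(s) of %.4g mg (%.4g mg/kg x %.4g kg), duration %.4g day\n",
              x$n, x$dosage * x$weight, x$dosage, x$weight,
              if (x$n > 0) x$events$duration[1] else NA_real_))
  if (x$n > 0) cat("  days:", paste(x$events$t_D, collapse = ", "), "\n")
  invisible(x)
}

#' Plasma concentration after a single infusion
#'
#' Closed-form central-compartment concentration for one zero-order infusion
#' of dose `D` (mg) over `[t_D, t_D + duration]`.  While the infusion runs
#' (elapsed time \eqn{e = t - t_D \le T}):
#' \deqn{I(t) = \frac{D}{T}\left[\frac{A}{a}(1 - e^{-a e})
#'   + \frac{B}{b}(1 - e^{-b e})\right]}
#' and post-infusion (\eqn{e > T}):
#' \deqn{I(t) = \frac{D}{T}\left[\frac{A}{a}(1 - e^{-a T}) e^{-a (e - T)}
#'   + \frac{B}{b}(1 - e^{-b T}) e^{-b (e - T)}\right].}
#' The two branches agree at \eqn{e = T}; the curve is continuous,
#' non-negative, and decays to zero.  For `t < t_D` the concentration is 0.
#'
#' @param t Time-point(s) (day); vectorized.
#' @param t_D Administration time (day).
#' @param D Absolute dose (mg).
#' @param duration Infusion duration (day).
#' @param consts A [hybrid_constants()] object.
#' @return Concentration(s) in mg/ml.
#' @export
infusion_concentration <- function(t, t_D, D, duration, consts) {
  stopifnot(inherits(consts, "hybrid_constants"))
  if (duration <= 0) stop("'duration' must be positive")
  if (D < 0) stop("'D' must be non-negative")
  ## Unified form covering both branches: during the infusion the washout
  ## factor is 1; afterwards the elapsed-in-infusion time is capped at the
  ## duration, reproducing the post-infusion bi-exponential exactly.
  e <- t - t_D
  rate <- D / duration
  a <- consts$a; b <- consts$b; A <- consts$A; B <- consts$B
  em <- pmin(e, duration)
  ep <- pmax(e - duration, 0)
  out <- rate * (A / a * (1 - exp(-a * em)) * exp(-a * ep) +
                 B / b * (1 - exp(-b * em)) * exp(-b * ep))
  out[e < 0] <- 0
  out
}

## Fast closure t (day) -> concentration (mg/kg) for a regimen, used inside
## ODE right-hand sides: no per-call validation or method dispatch.
make_conc_fn <- function(regimen, consts, plasma_density) {
  if (is.null(regimen) || regimen$n == 0L) {
    return(function(t) rep(0, length(t)))
  }
  tD <- regimen$events$t_D
  rate <- regimen$events$D / regimen$events$duration
  TT <- regimen$events$duration
  a <- consts$a; b <- consts$b
  Aa <- consts$A / a; Bb <- consts$B / b
  one_t <- function(t) {
    e <- t - tD
    live <- e > 0
    if (!any(live)) return(0)
    e <- e[live]
    em <- pmin(e, TT[live])
    ep <- e - em
    sum(rate[live] * (Aa * (1 - exp(-a * em)) * exp(-a * ep) +
                      Bb * (1 - exp(-b * em)) * exp(-b * ep)))
  }
  function(t) {
    if (length(t) == 1L) one_t(t) / plasma_density
    else vapply(t, one_t, numeric(1)) / plasma_density
  }
}

#' Plasma concentration under a multi-dose regimen
#'
#' Superposition of [infusion_concentration()] over every event of the
#' regimen: the PK system is linear, so the total concentration is the sum
#' of the single-dose solutions of all doses started at or before `t`.
#' Overlapping infusion windows are permitted.
#'
#' @param t Time-point(s) (day); vectorized.
#' @param regimen A [make_regimen()] object.
#' @param consts A [hybrid_constants()] object.
#' @return Concentration(s) in mg/ml.
#' @export
regimen_concentration <- function(t, regimen, consts) {
  stopifnot(inherits(regimen, "regimen"))
  if (regimen$n == 0L) return(rep(0, length(t)))
  ev <- regimen$events
  total <- rep(0, length(t))
  for (i in seq_len(nrow(ev))) {
    total <- total + infusion_concentration(t, ev$t_D[i], ev$D[i],
                                            ev$duration[i], consts)
  }
  total
}

#' Convert plasma concentration to growth-model units
#'
#' The growth model consumes drug concentration in mg per kg of plasma while
#' the compartment model yields mg per ml; dividing by the plasma mass
#' density converts between the two.  The default density 1.025e-3 kg/ml
#' (1.025 g/ml) is the standard figure for human blood plasma.
#'
#' @param conc Concentration(s) in mg/ml.
#' @param plasma_density Plasma mass density (kg/ml), strictly positive.
#' @return Concentration(s) in mg/kg.
#' @export
to_growth_units <- function(conc, plasma_density = 1.025e-3) {
  if (!is.numeric(plasma_density) || length(plasma_density) != 1L ||
      !is.finite(plasma_density) || plasma_density <= 0) {
    stop("'plasma_density' must be a single positive number")
  }
  conc / plasma_density
}

#' Read PK parameters and regimens from file
#'
#' `read_pk_params` expects keys `Vc`, `k12`, `k21`, `ke`;
#' `read_regimen` expects keys `dosage` (mg/kg), `weight` (kg),
#' `infusion_duration` (day) and `times` (list of administration days).
#' Both accept flat JSON objects or CSV (wide one-row or `name,value`
#' format; for a CSV regimen the `times` entry may be a single
#' semicolon-separated string, e.g. `"1;4;8"`).
#'
#' @param path File path ending in `.csv` or `.json`.
#' @return A [pk_params()] or [make_regimen()] object.
#' @export
read_pk_params <- function(path) {
  vals <- read_flat_record(path)
  need <- c("Vc", "k12", "k21", "ke")
  missing <- setdiff(need, names(vals))
  if (length(missing) > 0L) {
    stop("PK parameter file is missing key(s): ", paste(missing, collapse = ", "))
  }
  pk_params(Vc = as.numeric(vals$Vc), k12 = as.numeric(vals$k12),
            k21 = as.numeric(vals$k21), ke = as.numeric(vals$ke))
}

#' @rdname read_pk_params
#' @export
read_regimen <- function(path) {
  vals <- read_flat_record(path)
  need <- c("dosage", "weight", "infusion_duration", "times")
  missing <- setdiff(need, names(vals))
  if (length(missing) > 0L) {
    stop("regimen file is missing key(s): ", paste(missing, collapse = ", "))
  }
  times <- vals$times
  if (is.character(times)) {
    times <- as.numeric(strsplit(times, "[;,[:space:]]+")[[1]])
  }
  make_regimen(dosage = as.numeric(vals$dosage),
               weight = as.numeric(vals$weight),
               days = times,
               duration = as.numeric(vals$infusion_duration))
}

#' @rdname read_pk_params
#' @param regimen A `regimen` object to serialize (JSON only).
#' @export
write_regimen <- function(regimen, path) {
  stopifnot(inherits(regimen, "regimen"))
  rec <- list(dosage = regimen$dosage, weight = regimen$weight,
              infusion_duration = if (regimen$n > 0) regimen$events$duration[1] else 1 / 48,
              times = regimen$events$t_D)
  ext <- tolower(tools::file_ext(path))
  if (ext != "json") stop("regimens are serialized as JSON")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
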