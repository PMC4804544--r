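#' One-at-a-time parameter perturbation
#'
#' Perturbs a single growth parameter by a signed percentage, simulates free
#' growth from the standard anchor state, detects the plateau and reports
#' its value and timing together with the percentage variation of the
#' plateau value relative to the unperturbed reference run.
#'
#' @param params Reference [growth_params()].
#' @param target Name of the parameter to perturb (`"lambda1"`, `"c"` or
#'   `"d"`; any growth parameter is accepted).
#' @param pct Signed perturbation in percent (e.g. `20`, `-20`).
#' @param opts [solver_options()] used for the simulations.
#' @param init Anchor initial state (mm^3).
#' @param span Simulation span (day); must be long enough for the plateau
#'   to be attained.
#' @param rule Plateau-detection rule passed to [detect_plateau()].
#' @param reference Optional precomputed reference run (the value returned
#'   by `vascgro:::run_to_plateau`); avoids re-simulating the reference
#'   across a table of perturbations.
#' @return A one-row data frame with columns `parameter`, `perturbation`
#'   (percent), `value` (the perturbed numeric value), `t_plateau` (day),
#'   `plateau_value` (mm^3, the detected shared integer) and
#'   `plateau_variation` (percent vs reference).  The variation is computed
#'   from the unrounded converged levels (the terminal simulated volumes),
#'   not from the integerized detection values, so it is insensitive to the
#'   integer-part detection device.
#' @seealso [oat_table()] for the full perturbation table.
#' @export
one_at_a_time <- function(params, target, pct, opts = solver_options(),
                          init = c(V = 200, K = 625), span = c(0, 400),
                          rule = "first", reference = NULL) {
  stopifnot(inherits(params, "growth_params"))
  if (!target %in% setdiff(names(params), "v_star")) {
    stop("unknown perturbation target '", target, "'")
  }
  perturbed <- unclass(params)
  perturbed[[target]] <- perturbed[[target]] * (1 + pct / 100)
  perturbed <- tryCatch(validate_growth_params(perturbed), error = function(e) {
    stop("perturbing '", target, "' by ", pct, " % yields invalid parameters: ",
         conditionMessage(e))
  })
  if (is.null(reference)) {
    reference <- run_to_plateau(params, init, span, opts, rule)
  }
  if (!reference$plateau$attained) stop("reference run did not attain a plateau")
  run <- run_to_plateau(perturbed, init, span, opts, rule)
  if (!run$plateau$attained) {
    warning("perturbed run ('", target, "' ", pct,
            " %) did not attain a plateau within the span")
  }
  data.frame(parameter = target, perturbation = pct,
             value = perturbed[[target]],
             t_plateau = run$plateau$t_plateau,
             plateau_value = run$plateau$plateau_value,
             plateau_variation = 100 * (run$level - reference$level) /
               reference$level)
}

## Free-growth run long enough to plateau: detection result plus the
## unrounded converged level (terminal simulated volume).
run_to_plateau <- function(params, init, span, opts, rule = "first") {
  traj <- simulate_tumour(params, init = init, span = span, opts = opts)
  list(plateau = detect_plateau(traj, rule = rule),
       level = traj$V[nrow(traj)])
}

#' Full one-at-a-time perturbation table
#'
#' Runs [one_at_a_time()] for each target/percentage combination, sharing a
#' single reference simulation, and prepends the reference row.
#'
#' @inheritParams one_at_a_time
#' @param targets Parameters to perturb.
#' @param pcts Signed percentages applied to every target.
#' @return A data frame, one row per run; the reference row carries
#'   `perturbation = 0` and `plateau_variation = 0`.
#' @examples
#' \donttest{
#' oat_table(growth_params(), pcts = c(20, -20))
#' }
#' @export
oat_table <- function(params = growth_params(),
                      targets = c("lambda1", "c", "d"),
                      pcts = c(20, -20), opts = solver_options(),
                      init = c(V = 200, K = 625), span = c(0, 400),
                      rule = "first") {
  reference <- run_to_plateau(params, init, span, opts, rule)
  if (!reference$plateau$attained) stop("reference run did not attain a plateau")
  ref_row <- data.frame(parameter = "reference", perturbation = 0,
                        value = NA_real_,
                        t_plateau = reference$plateau$t_plateau,
                        plateau_value = reference$plateau$plateau_value,
                        plateau_variation = 0)
  rows <- lapply(targets, function(tg) {
    do.call(rbind, lapply(pcts, function(pc) {
      one_at_a_time(params, tg, pc, opts = opts, init = init, span = span,
                    rule = rule, reference = reference)
    }))
  })
  out <- rbind(ref_row, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Plateau volume over a (c, d) grid
#'
#' Evaluates the analytic steady state [steady_state_volume()] on the
#' Cartesian product of stimulation and inhibition coefficient values; no
#' simulation is involved.  The plateau depends on `c` and `d` only through
#' the ratio `c/d` (for fixed `alpha`), increases in `c` and decreases in
#' `d`.
#'
#' @param c_values,d_values Positive numeric grids.
#' @param params [growth_params()] supplying `alpha` and `v_star`.
#' @return Matrix of plateau volumes (mm^3) with rows indexed by `c_values`
#'   and columns by `d_values`.
#' @export
plateau_surface <- function(c_values, d_values, params = growth_params()) {
  stopifnot(inherits(params, "growth_params"))
  if (any(c_values <= 0) || any(d_values <= 0)) {
    stop("'c_values' and 'd_values' must be strictly positive")
  }
  out <- outer(c_values, d_values, function(cc, dd) {
    params$v_star + (cc / (params$alpha * dd))^(3 / 2)
  })
  dimnames(out) <- list(format(c_values, trim = TRUE),
                        format(d_values, trim = TRUE))
  out
}

#' Biologically admissible bounds on the angiogenic coefficients
#'
#' Derives the range of the stimulation coefficient `c` and the inhibition
#' coefficient `d` that keeps an untreated virtual tumour biologically
#' plausible, from two requirements:
#'
#' * the plateau volume must not exceed `plateau_cap` (inverting the steady
#'   state for one coefficient with the other held at its reference value):
#'   `c_max = alpha * d * (cap - v_star)^(2/3)` and
#'   `d_min = c / (alpha * (cap - v_star)^(2/3))`;
#' * the carrying capacity must be non-decreasing at the anchor state
#'   (no self-regressing vasculature without treatment), i.e.
#'   `dK/dt >= 0` at `(V0, K0)`, giving
#'   `c_min = alpha * d * (K0 - v_star) / (V0 - v_star)^(1/3)` and
#'   `d_max = c * (V0 - v_star)^(1/3) / (alpha * (K0 - v_star))`.
#'
#' The cap is reduced by `v_star` for exactness; at caps of order 1e6 mm^3
#' the difference from using the cap alone is far below printed precision.
#'
#' @param params Reference [growth_params()].
#' @param plateau_cap Largest admissible plateau volume (mm^3).
#' @param anchor Named vector `c(V =, K =)`: the initial state at which the
#'   monotonicity constraint is imposed.
#' @return An object of class `parameter_bounds`: list with `c_range`,
#'   `d_range` (each `c(min, max)`), `plateau_cap` and `anchor`.
#' @examples
#' valid_parameter_bounds(growth_params())
#' @export
valid_parameter_bounds <- function(params = growth_params(),
                                   plateau_cap = 1e6,
                                   anchor = c(V = 200, K = 625)) {
  stopifnot(inherits(params, "growth_params"))
  V0 <- anchor[["V"]]; K0 <- anchor[["K"]]
  if (V0 <= params$v_star || K0 <= params$v_star) {
    stop("anchor state must lie above v_star")
  }
  if (plateau_cap <= K0) stop("'plateau_cap' must exceed the anchor K")
  cap_u <- (plateau_cap - params$v_star)^(2 / 3)
  u0 <- V0 - params$v_star
  k0 <- K0 - params$v_star
  c_max <- params$alpha * params$d * cap_u
  d_min <- params$c / (params$alpha * cap_u)
  c_min <- params$alpha * params$d * k0 / u0^(1 / 3)
  d_max <- params$c * u0^(1 / 3) / (params$alpha * k0)
  if (c_min >= c_max || d_min >= d_max) {
    stop("degenerate anchor/cap combination: empty admissible range")
  }
  structure(list(c_range = c(min = c_min, max = c_max),
                 d_range = c(min = d_min, max = d_max),
                 plateau_cap = plateau_cap, anchor = anchor),
            class = "parameter_bounds")
}

#' @export
print.parameter_bounds <- function(x, ...) {
  cat(sprintf("Admissible coefficient ranges (plateau cap %.3g mm^3, anchor V = %g, K = %g):\n",
              x$plateau_cap, x$anchor[["V"]], x$anchor[["K"]]))
  cat(sprintf("  c in [%.4g, %.4g]\n", x$c_range[["min"]], x$c_range[["max"]]))
  cat(sprintf("  d in [%.4g, %.4g]\n", x$d_range[["min"]], x$d_range[["max"]]))
  invisible(x)
}
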