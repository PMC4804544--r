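#' Right-hand sides of the vascular tumour growth system
#'
#' `rhs_treated` evaluates the rates of change of tumour volume `V` and
#' carrying capacity `K` under an antiangiogenic drug concentration `conc`
#' (mg/kg in plasma):
#'
#' \deqn{dV/dt = -\lambda_1 (V - V^*) \ln\frac{V - V^*}{K - V^*}}
#' \deqn{dK/dt = -\lambda_2 (K - V^*)
#'   + c \frac{(\beta + (V - V^*)^p)(V - V^*)}{\alpha(\beta + (V - V^*)^p) + I}
#'   - d (K - V^*) (V - V^*)^{2/3}}
#'
#' where \eqn{V^*} is the avascular floor: only the part of the tumour grown
#' after the angiogenic switch secretes angiogenic factors, so as
#' \eqn{I \to \infty} the system relaxes to \eqn{(V^*, V^*)} rather than
#' collapsing to zero.  `rhs_untreated` is the `I = 0` special case, in which
#' the stimulation term reduces to \eqn{(c/\alpha)(V - V^*)}.
#'
#' The convention \eqn{x^0 = 1} (including at \eqn{x = 0}) applies to the
#' \eqn{(V-V^*)^p} factor, so with `p = 0` the abnormality factor is
#' \eqn{\beta + 1} exactly.
#'
#' @param state Named numeric vector or list with elements `V` and `K`
#'   (mm^3).  Both must exceed `params$v_star` by more than `eps`: the model
#'   is only defined in the vascular phase, and the logarithm requires
#'   positive arguments.  States outside that domain raise an error rather
#'   than being clamped, so solver excursions are not silently masked.
#' @param params A [growth_params()] object.
#' @param conc Drug concentration in plasma (mg/kg), non-negative scalar.
#' @param eps Domain-guard floor (mm^3) on `V - v_star` and `K - v_star`.
#' @return Named numeric vector `c(dV, dK)` in mm^3/day.
#' @examples
#' gp <- growth_params()
#' rhs_untreated(c(V = 200, K = 625), gp)
#' rhs_treated(c(V = 200, K = 625), gp, conc = 10)
#' @export
rhs_treated <- function(state, params, conc = 0, eps = 1e-12) {
  stopifnot(inherits(params, "growth_params"))
  V <- state[["V"]]
  K <- state[["K"]]
  if (!is.numeric(conc) || length(conc) != 1L || !is.finite(conc) || conc < 0) {
    stop("'conc' must be a single non-negative finite number")
  }
  u <- V - params$v_star
  k <- K - params$v_star
  if (!is.finite(u) || !is.finite(k) || u <= eps || k <= eps) {
    stop("state outside the vascular regime: V and K must exceed v_star = ",
         format(params$v_star), " mm^3 (got V = ", format(V), ", K = ",
         format(K), ")")
  }
  abnorm <- params$beta + u^params$p   # R's ^ gives x^0 == 1, incl. 0^0
  dV <- -params$lambda1 * u * log(u / k)
  dK <- -params$lambda2 * k +
    params$c * abnorm * u / (params$alpha * abnorm + conc) -
    params$d * k * u^(2 / 3)
  c(dV = dV, dK = dK)
}

#' @rdname rhs_treated
#' @export
rhs_untreated <- function(state, params, eps = 1e-12) {
  rhs_treated(state, params, conc = 0, eps = eps)
}

#' Analytic steady-state (plateau) tumour volume
#'
#' The untreated system has the stable equilibrium
#' \deqn{V_{SS} = V^* + \left(\frac{c}{\alpha d}\right)^{3/2},}
#' the post-vascular dormancy volume at which endogenous angiogenic
#' stimulation and inhibition balance.  It depends only on `c`, `d`, `alpha`
#' and `v_star`; the growth rate `lambda1` sets how fast the plateau is
#' approached but not its value.
#'
#' @param params A [growth_params()] object with `d > 0` (otherwise no
#'   finite plateau exists and an error is raised).
#' @return Plateau volume (mm^3).
#' @examples
#' steady_state_volume(growth_params())  # ~17347 mm^3
#' @export
steady_state_volume <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  if (params$d <= 0) {
    stop("'d' must be strictly positive: with d = 0 the carrying capacity ",
         "is unbounded and no finite plateau exists")
  }
  params$v_star + (params$c / (params$alpha * params$d))^(3 / 2)
}
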