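# The cell model: stochastic event equations and intrinsic-state updates.
#
# Proliferation, mortality and migration are Bernoulli events per hourly
# step; differentiation is a continuous maturity increment. All chance
# functions are vectorized over cells.

#' Logistic cycle bias
#'
#' Concentrates the proliferation probability toward the end of the cell
#' cycle: `Omega(t) = 1 / (1 + exp(-k * (t - T_cyc)))` where `t` is hours
#' since the last division.
#'
#' @param t Hours since last division (vectorized).
#' @param params Parameter set (`k_omega`, `T_cyc`).
#' @return Bias values in `(0, 1)`.
#' @export
omega_bias <- function(t, params) {
  1 / (1 + exp(-params$k_omega * (t - params$T_cyc)))
}

#' Per-step proliferation chance
#'
#' `clamp(Omega(clock) * aP * fP * gP0, 0, 1)`.
#'
#' @param fP Controller proliferation intensity in `[0, 1]`.
#' @param clock Hours since last division.
#' @param params Parameter set.
#' @return Probability vector.
#' @export
proliferation_chance <- function(fP, clock, params) {
  if (params$gP0 < 0 || params$aP < 0) stop("negative rate parameter")
  pmin(1, pmax(0, omega_bias(clock, params) * params$aP * fP * params$gP0))
}

#' Per-step mortality chance
#'
#' `clamp((1 + aPM * deltaP) * aM * fM * gM0, 0, 1)`; `deltaP` is the
#' transient mitotic-damage flag of one daughter cell.
#'
#' @param fM Controller mortality intensity in `[0, 1]`.
#' @param deltaP Mitotic-damage flag, 0 or 1.
#' @param params Parameter set.
#' @return Probability vector.
#' @export
mortality_chance <- function(fM, deltaP, params) {
  if (params$gM0 < 0 || params$aM < 0) stop("negative rate parameter")
  pmin(1, pmax(0, (1 + params$aPM * deltaP) * params$aM * fM * params$gM0))
}

#' Per-step migration chance
#'
#' The identity: the controller output is itself the chance.
#'
#' @param fMi Controller migration intensity in `[0, 1]`.
#' @return `fMi` unchanged.
#' @export
migration_chance <- function(fMi) fMi

#' Differentiation maturity increment
#'
#' Maturity advances at rate `aD * fD * rD0` per hour, where `fD` is the
#' early- or late-differentiation controller output depending on whether
#' maturity is below or above the threshold `Mt`; the result is capped
#' at 1.
#'
#' @param maturity Current maturity in `[0, 1]`.
#' @param fD_early,fD_late Controller differentiation intensities.
#' @param params Parameter set (`aD`, `rD0`, `Mt`).
#' @param dt Time step (h).
#' @return Updated maturity vector.
#' @export
differentiation_step <- function(maturity, fD_early, fD_late, params,
                                 dt = 1) {
  fD <- ifelse(maturity < params$Mt, fD_early, fD_late)
  pmin(1, maturity + params$aD * fD * params$rD0 * dt)
}

#' Internal-pH relaxation toward the ambient pH
#'
#' The internal pH moves toward the ambient value by at most `r_r * dt`
#' per step, never overshooting. The controller's alkalinity input is the
#' remaining gap `max(ambient - internal, 0)`.
#'
#' @param internal,ambient pH values (internal vectorized).
#' @param r_r Recovery rate (pH units/h).
#' @param dt Time step (h).
#' @return Updated internal pH vector.
#' @export
relax_internal_ph <- function(internal, ambient, r_r, dt = 1) {
  if (dt <= 0) stop("dt must be positive")
  gap <- ambient - internal
  internal + sign(gap) * pmin(abs(gap), r_r * dt)
}

#' DNA-damage update
#'
#' DNA damage is a crisp absorbing state: at initialization each cell is
#' damaged with base chance `gC` (cell passaging); afterwards one step of
#' exposure to an ambient pH at or above `pH_t` damages the cell
#' deterministically. Damage never reverts.
#'
#' @param damage Current damage flags (0/1), vectorized.
#' @param ambient_ph Ambient pH (scalar).
#' @param params Parameter set (`gC`, `pH_t`).
#' @param is_init `TRUE` only for the initialization draw.
#' @return Updated damage flags.
#' @export
check_dna_damage <- function(damage, ambient_ph, params, is_init = FALSE) {
  n <- length(damage)
  if (is_init) {
    hit <- stats::runif(n) < params$gC
    return(as.integer(damage == 1L | hit))
  }
  if (ambient_ph >= params$pH_t) return(rep(1L, n))
  as.integer(damage)
}
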