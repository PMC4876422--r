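# Constitutive law: dynamic conductivity as a function of three subsidiary
# state variables, their per-step update rules, and the capacitive current
# density.  All functions are vectorised over elements.

#' Field-determined target level of poration
#'
#' Linear ramp between the two field-magnitude limits: the level of
#' poration that the local field sustains, clamped to \[0, 1\] (values at
#' exactly `Emin`/`Emax` map to 0/1 inclusively).
#'
#' @param Emag local electric field magnitude(s), V/m, non-negative.
#' @param params [tissue_parameters()].
#' @return Dimensionless value(s) in \[0, 1\], non-decreasing in `Emag`.
#' @examples
#' p <- tissue_parameters()
#' target_poration(c(0, 20000, 30000, 40000, 50000), p)
#' @export
target_poration <- function(Emag, params) {
  if (any(Emag < 0)) stop("Emag must be non-negative")
  pmin(pmax((Emag - params$Emin) / (params$Emax - params$Emin), 0), 1)
}

#' Advance the level of poration over one time step
#'
#' Pore creation is fast relative to any resolved time step: when the
#' field-determined target exceeds the previous level, the level jumps to
#' the target within the step.  When the target falls below (field removed
#' or reduced), the level relaxes exponentially toward the target with the
#' poration relaxation time `tauRelax` (pore resealing).
#'
#' @param pPrev previous level(s) of poration, in \[0, 1\].
#' @param Emag local field magnitude(s), V/m.
#' @param dt time step, s, positive.
#' @param params [tissue_parameters()].
#' @return Updated level(s), guaranteed to stay in \[0, 1\].
#' @export
update_poration <- function(pPrev, Emag, dt, params) {
  if (any(pPrev < 0 | pPrev > 1)) stop("pPrev must lie in [0, 1]")
  if (any(dt <= 0)) stop("dt must be positive")
  pT <- target_poration(Emag, params)
  ifelse(pT >= pPrev, pT, pT + (pPrev - pT) * exp(-dt / params$tauRelax))
}

#' Advance a damage indicator over one time step
#'
#' Damage indicators grow proportionally to the local field magnitude while
#' a pulse is applied (`dPrev + alpha * Emag * dt`) and decay exponentially
#' between pulses (`dPrev * exp(-dt / tauDecay)`).  The same rule serves the
#' poration damage indicator (`alpha = alphaP`, decay `tauRelax`) and the
#' thermal damage indicator (`alpha = alphaT`, decay `tauT`).
#'
#' @param dPrev previous indicator value(s), non-negative (units: s, since
#'   alpha carries m/V and Emag V/m).
#' @param Emag local field magnitude(s), V/m.
#' @param dt time step, s.
#' @param pulseOn logical flag: is a pulse being applied during this step?
#' @param alpha accumulation rate, m/V.
#' @param tauDecay decay time constant between pulses, s.
#' @return Updated indicator value(s), non-negative.
#' @export
update_damage <- function(dPrev, Emag, dt, pulseOn, alpha, tauDecay) {
  if (any(dPrev < 0)) stop("damage indicator must be non-negative")
  if (any(dt <= 0)) stop("dt must be positive")
  if (isTRUE(pulseOn)) dPrev + alpha * Emag * dt
  else dPrev * exp(-dt / tauDecay)
}

#' Tissue conductivity from the subsidiary variables
#'
#' The linear poration part interpolates between `sigma0` and `sigmaMax`
#' with the level of poration; it is multiplied by two saturating
#' enhancement terms, one shaped by the measured current within the first
#' pulse (pore growth, amplitude `Apg`) and one by the rising current
#' envelope across a pulse train (thermal, amplitude `AT`):
#' \deqn{\sigma = [\sigma_0 + (\sigma_{MAX}-\sigma_0)p]\,
#'   [1 + A_{pg}(1 - e^{-d_p/\tau_{pg}})]\,[1 + A_T(1 - e^{-d_T/\tau_T})]}
#' so that \eqn{\sigma(0,0,0)=\sigma_0}, \eqn{\sigma} is non-decreasing in
#' each argument, and bounded by
#' \eqn{\sigma_{MAX}(1+A_{pg})(1+A_T)}.
#'
#' @param p level(s) of poration in \[0, 1\].
#' @param dP poration damage indicator(s), non-negative.
#' @param dT thermal damage indicator(s), non-negative.
#' @param params [tissue_parameters()].
#' @return Conductivity value(s), S/m.
#' @examples
#' conductivity(0, 0, 0, tissue_parameters())  # sigma0
#' conductivity(1, 0, 0, tissue_parameters())  # sigmaMax
#' @export
conductivity <- function(p, dP, dT, params) {
  (params$sigma0 + (params$sigmaMax - params$sigma0) * p) *
    (1 + params$Apg * (1 - exp(-dP / params$tauPg))) *
    (1 + params$AT * (1 - exp(-dT / params$tauT)))
}

#' Capacitive current density (first-order RC filter)
#'
#' Charging/discharging of membrane and interface capacitance is lumped
#' into a per-element RC filter on the local potential.  A potential step
#' of height \eqn{\Delta U} produces a current-density spike of initial
#' magnitude \eqn{A_C \Delta U / R} that decays with the time constant
#' \eqn{RC}; a potential constant for much longer than \eqn{RC} yields zero.
#'
#' @param uLocal current local (element) potential(s), V.
#' @param capMemory filtered potential state(s) from the previous step, V.
#' @param dt time step, s, positive.
#' @param Edir unit vector(s) along the local field (n x 3 matrix or
#'   length-3 vector); the density is directed along `Edir` with the sign
#'   of `uLocal - capMemory`.
#' @param params [tissue_parameters()].
#' @return A list with `jCap` (n x 3 current density, A/m^2), `capMemory`
#'   (updated filter state, V) and `magnitude` (signed scalar density).
#' @export
capacitive_current_density <- function(uLocal, capMemory, dt, Edir, params) {
  if (any(dt <= 0)) stop("dt must be positive")
  f <- exp(-dt / (params$R * params$C))
  delta <- uLocal - capMemory
  signed <- params$AC * delta * f / params$R
  if (is.null(dim(Edir))) Edir <- matrix(Edir, nrow = length(uLocal),
                                         ncol = 3, byrow = TRUE)
  list(jCap = Edir * signed,
       capMemory = uLocal + (capMemory - uLocal) * f,
       magnitude = signed)
}

#' Virgin tissue state for a mesh
#'
#' Per-element subsidiary variables and capacitive filter memory, all at
#' their resting values (p = 0, damages = 0, sigma = sigma0).
#'
#' @param nElements number of mesh elements.
#' @param params [tissue_parameters()].
#' @param t simulation time attached to the state, s.
#' @return An object of class `tissue_state`.
#' @export
tissue_state <- function(nElements, params, t = 0) {
  z <- numeric(nElements)
  structure(list(p = z, dP = z, dT = z,
                 sigma = rep(params$sigma0, nElements),
                 Emag = z,
                 jCond = matrix(0, nElements, 3),
                 jCap = matrix(0, nElements, 3),
                 capMemory = z, t = t),
            class = "tissue_state")
}

# Candidate state for a Newton iterate: subsidiary variables recomputed
# from the previous committed state and the current-iterate field, plus
# the analytic derivative d(sigma)/d(Emag) needed by the Jacobian.  The
# poration ramp's clamp points use one-sided (zero) derivatives.
state_candidate <- function(statePrev, Emag, dt, pulseOn, params) {
  p <- update_poration(statePrev$p, Emag, dt, params)
  dP <- update_damage(statePrev$dP, Emag, dt, pulseOn, params$alphaP,
                      params$tauRelax)
  dT <- update_damage(statePrev$dT, Emag, dt, pulseOn, params$alphaT,
                      params$tauT)
  L <- params$sigma0 + (params$sigmaMax - params$sigma0) * p
  Fpg <- 1 + params$Apg * (1 - exp(-dP / params$tauPg))
  Ft <- 1 + params$AT * (1 - exp(-dT / params$tauT))
  sigma <- L * Fpg * Ft

  # dp/dE: linear ramp slope where the target is active and not clamped
  pT <- target_poration(Emag, params)
  ramp <- as.numeric(Emag > params$Emin & Emag < params$Emax) /
    (params$Emax - params$Emin)
  dpdE <- ifelse(pT >= statePrev$p, ramp,
                 ramp * (1 - exp(-dt / params$tauRelax)))
  dLdE <- (params$sigmaMax - params$sigma0) * dpdE
  if (isTRUE(pulseOn)) {
    dFpgdE <- params$Apg * exp(-dP / params$tauPg) / params$tauPg *
      params$alphaP * dt
    dFtdE <- params$AT * exp(-dT / params$tauT) / params$tauT *
      params$alphaT * dt
  } else {
    dFpgdE <- 0
    dFtdE <- 0
  }
  dsdE <- dLdE * Fpg * Ft + L * dFpgdE * Ft + L * Fpg * dFtdE

  list(p = p, dP = dP, dT = dT, sigma = sigma, dsdE = dsdE)
}
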