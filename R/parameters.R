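#' Tissue model parameters
#'
#' Container for the fourteen constitutive constants of the dynamic
#' conductivity model plus the adaptive time-step bounds.  The defaults are
#' the fitted beef-liver values for a two-needle electrode geometry:
#' conduction interpolates linearly between `sigma0` and `sigmaMax` with the
#' level of poration, which in turn tracks the local field between `Emin`
#' and `Emax`; two slower multiplicative terms (pore growth, Joule heating)
#' are driven by accumulated damage indicators; and a lumped RC term
#' produces capacitive charging spikes at pulse edges.
#'
#' @param sigma0 baseline (virgin) tissue conductivity, S/m.
#' @param sigmaMax fully porated tissue conductivity, S/m.
#' @param Emin,Emax field magnitudes bounding the linear poration ramp, V/m.
#' @param tauRelax poration relaxation (pore resealing) time constant, s.
#' @param Apg dimensionless amplitude of the pore-growth conductivity term.
#' @param tauPg saturation constant of the pore-growth term, s.
#' @param AT dimensionless amplitude of the thermal conductivity term.
#' @param tauT thermal diffusion time constant, s.
#' @param alphaP poration damage accumulation rate, m/V.
#' @param alphaT thermal damage accumulation rate, m/V.
#' @param AC capacitive current amplitude, 1/m^2.
#' @param R lumped resistance of the capacitive branch, Ohm.
#' @param C lumped capacitance of the capacitive branch, F.
#' @param dtMin,dtMax adaptive time-step bounds, s.
#' @return An object of class `tissue_parameters` (a validated named list).
#' @examples
#' p <- tissue_parameters()
#' p$sigma0          # 0.065 S/m
#' p$R * p$C         # RC time constant, 1.8e-6 s
#' @export
tissue_parameters <- function(sigma0 = 0.065, sigmaMax = 0.1483,
                              Emin = 20000, Emax = 40000,
                              tauRelax = 100e-6,
                              Apg = 0.35, tauPg = 15e-6,
                              AT = 0.125, tauT = 1.75,
                              alphaP = 0.0015, alphaT = 25.0,
                              AC = 0.0005, R = 15, C = 1.2e-7,
                              dtMin = 2e-6, dtMax = 0.99) {
  p <- list(sigma0 = sigma0, sigmaMax = sigmaMax, Emin = Emin, Emax = Emax,
            tauRelax = tauRelax, Apg = Apg, tauPg = tauPg, AT = AT,
            tauT = tauT, alphaP = alphaP, alphaT = alphaT, AC = AC,
            R = R, C = C, dtMin = dtMin, dtMax = dtMax)
  p <- lapply(p, parse_quantity)
  class(p) <- "tissue_parameters"
  validate_tissue_parameters(p)
  p
}

#' @export
print.tissue_parameters <- function(x, ...) {
  cat("Dynamic tissue conductivity parameters\n")
  cat(sprintf("  sigma0 = %g S/m, sigmaMax = %g S/m\n", x$sigma0, x$sigmaMax))
  cat(sprintf("  poration ramp: %g - %g V/m, tauRelax = %g s\n",
              x$Emin, x$Emax, x$tauRelax))
  cat(sprintf("  pore growth: Apg = %g, tauPg = %g s, alphaP = %g m/V\n",
              x$Apg, x$tauPg, x$alphaP))
  cat(sprintf("  thermal: AT = %g, tauT = %g s, alphaT = %g m/V\n",
              x$AT, x$tauT, x$alphaT))
  cat(sprintf("  capacitive: AC = %g 1/m^2, R = %g Ohm, C = %g F (RC = %g s)\n",
              x$AC, x$R, x$C, x$R * x$C))
  cat(sprintf("  time step: %g s to %g s\n", x$dtMin, x$dtMax))
  invisible(x)
}

validate_tissue_parameters <- function(p) {
  stopifnot(is.list(p))
  need <- c("sigma0", "sigmaMax", "Emin", "Emax", "tauRelax", "Apg", "tauPg",
            "AT", "tauT", "alphaP", "alphaT", "AC", "R", "C", "dtMin", "dtMax")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing parameter fields: ", paste(miss, collapse = ", "))
  if (!(p$sigma0 > 0 && p$sigmaMax > p$sigma0)) {
    stop("require sigmaMax > sigma0 > 0")
  }
  if (!(p$Emin > 0 && p$Emax > p$Emin)) stop("require Emax > Emin > 0")
  if (any(c(p$tauRelax, p$tauPg, p$tauT, p$R, p$C) <= 0)) {
    stop("time constants, R and C must be positive")
  }
  if (p$Apg < 0 || p$AT < 0) stop("Apg and AT must be non-negative")
  if (!(p$dtMax >= p$dtMin && p$dtMin > 0)) stop("require dtMax >= dtMin > 0")
  invisible(p)
}

#' Read or write a tissue parameter set
#'
#' Parameter sets round-trip through a YAML file whose keys match the field
#' names of [tissue_parameters()].  Values may be plain SI numbers or
#' strings with unit suffixes (`"100 us"`, `"0.065 S/m"`, `"15 Ohm"`),
#' normalised to strict SI on read.  Unknown keys are rejected.
#'
#' @param path file path.
#' @param params a `tissue_parameters` object (for writing).
#' @return `read_parameters()` returns a `tissue_parameters` object.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$parameters)) raw <- raw$parameters
  known <- names(formals(tissue_parameters))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown parameter keys: ", paste(unknown, collapse = ", "))
  }
  do.call(tissue_parameters, raw)
}

#' @rdname read_parameters
#' @export
write_parameters <- function(params, path) {
  validate_tissue_parameters(params)
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' Packaged default parameter file
#'
#' Path to the packaged YAML parameter set holding the fitted beef-liver
#' defaults (identical to the defaults of [tissue_parameters()]).
#' @return A file path.
#' @export
default_parameter_file <- function() {
  system.file("extdata", "default_parameters.yaml", package = "porodyn",
              mustWork = TRUE)
}

#' Solver controls
#'
#' Numerical controls for the Newton solve and the adaptive time-step
#' schedule.  The step schedule keeps `dtMin` steps inside a refinement
#' window after every pulse edge (where the capacitive term changes on the
#' RC scale) and grows steps geometrically elsewhere, capped at `dtMax` and
#' at the next pulse edge.
#'
#' @param newtonTol relative residual tolerance for stopping Newton
#'   iteration (default `1e-9`).
#' @param newtonMaxIter maximum Newton iterations per time step.
#' @param dtMin,dtMax time-step bounds, s; defaults come from `params`.
#' @param edgeRefinementWindow time span after each pulse edge kept at
#'   `dtMin`, s.
#' @param growthFactor geometric step enlargement factor (> 1).
#' @param params optional [tissue_parameters()] supplying `dtMin`/`dtMax`.
#' @return An object of class `solver_controls`.
#' @export
solver_controls <- function(newtonTol = 1e-9, newtonMaxIter = 25,
                            dtMin = NULL, dtMax = NULL,
                            edgeRefinementWindow = 10e-6,
                            growthFactor = 2,
                            params = NULL) {
  if (is.null(dtMin)) dtMin <- if (is.null(params)) 2e-6 else params$dtMin
  if (is.null(dtMax)) dtMax <- if (is.null(params)) 0.99 else params$dtMax
  if (newtonTol <= 0) stop("newtonTol must be positive")
  if (growthFactor <= 1) stop("growthFactor must exceed 1")
  if (!(dtMax >= dtMin && dtMin > 0)) stop("require dtMax >= dtMin > 0")
  structure(list(newtonTol = newtonTol, newtonMaxIter = newtonMaxIter,
                 dtMin = dtMin, dtMax = dtMax,
                 edgeRefinementWindow = edgeRefinementWindow,
                 growthFactor = growthFactor),
            class = "solver_controls")
}
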