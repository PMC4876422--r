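# Inverse calibration: fit the saturated conductivity sigmaMax per
# sequence against a measured current waveform (Run1), and evaluate a
# shared parameter set across sequences (Run2).

#' Fit the saturated conductivity to a measured current waveform
#'
#' Bounded scalar minimisation of the average absolute current deviation
#' ([fit_metrics()]) over `sigmaMax`, all other parameters held fixed.
#' The measured voltage trace drives the simulation as the Dirichlet
#' boundary condition; traces are expected preprocessed (down-sampled,
#' replicate-averaged).  Brent-style search via [stats::optimize()] with an
#' absolute tolerance of 1e-4 S/m.
#'
#' @param measuredVoltage voltage [ep_trace()] (the drive).
#' @param measuredCurrent current [ep_trace()] (the target).
#' @param mesh an `ep_mesh`.
#' @param params [tissue_parameters()]; its `sigmaMax` is ignored.
#' @param bounds search interval for `sigmaMax`, S/m; must lie above
#'   `sigma0`.  Default is the fitted range of the reference experiment.
#' @param controls [solver_controls()].
#' @param tol optimiser tolerance, S/m.
#' @return A list of class `sigma_fit`: `sigmaMax` (S/m), `metrics`
#'   ([fit_metrics()] at the optimum), `atBound` (logical warning flag).
#' @export
fit_sigma_max <- function(measuredVoltage, measuredCurrent, mesh,
                          params = tissue_parameters(),
                          bounds = c(0.125, 0.1675),
                          controls = solver_controls(params = params),
                          tol = 1e-4) {
  stopifnot(inherits(measuredVoltage, "ep_trace"),
            inherits(measuredCurrent, "ep_trace"))
  if (bounds[1] <= params$sigma0) {
    stop("bounds must lie strictly above sigma0")
  }
  objective <- function(s) {
    p <- params
    p$sigmaMax <- s
    sim <- run_simulation(mesh, measuredVoltage, p, controls)
    fit_metrics(measuredCurrent, sim)$avgDeltaI
  }
  opt <- stats::optimize(objective, interval = bounds, tol = tol)
  atBound <- min(opt$minimum - bounds[1], bounds[2] - opt$minimum) < 2 * tol
  if (atBound) {
    warning("fitted sigmaMax lies at a search bound; no interior minimum ",
            "found in [", bounds[1], ", ", bounds[2], "]")
  }
  p <- params
  p$sigmaMax <- opt$minimum
  sim <- run_simulation(mesh, measuredVoltage, p, controls)
  structure(list(sigmaMax = opt$minimum,
                 metrics = fit_metrics(measuredCurrent, sim),
                 atBound = atBound),
            class = "sigma_fit")
}

#' @export
print.sigma_fit <- function(x, ...) {
  cat(sprintf("fitted sigmaMax = %.5g S/m%s\n", x$sigmaMax,
              if (x$atBound) " (at search bound)" else ""))
  print(x$metrics)
  invisible(x)
}

#' Per-sequence calibration (Run1)
#'
#' Fits `sigmaMax` independently for each sequence's replicate-averaged
#' voltage/current pair, with all other parameters shared.
#'
#' @param experiments a list; each entry a list with elements `voltage` and
#'   `current` ([ep_trace()] objects) and optionally `label`.
#' @param mesh an `ep_mesh`.
#' @param params,bounds,controls,tol passed to [fit_sigma_max()].
#' @return A `calibration_result`: data frame `table` (one row per
#'   sequence with fitted sigmaMax and metrics), `sigmaMaxMean`, and
#'   `runLabel = "Run1"`.
#' @export
calibrate_run1 <- function(experiments, mesh, params = tissue_parameters(),
                           bounds = c(0.125, 0.1675),
                           controls = solver_controls(params = params),
                           tol = 1e-4) {
  rows <- lapply(seq_along(experiments), function(i) {
    e <- experiments[[i]]
    fit <- fit_sigma_max(e$voltage, e$current, mesh, params, bounds,
                         controls, tol)
    data.frame(sequence = e$label %||% i,
               sigmaMax = fit$sigmaMax,
               i_max_A = fit$metrics$iMax,
               avg_dI_A = fit$metrics$avgDeltaI,
               rel_deviation = fit$metrics$relDeviation)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, sigmaMaxMean = mean(tab$sigmaMax),
                 runLabel = "Run1"),
            class = "calibration_result")
}

#' Shared-parameter evaluation (Run2)
#'
#' Re-simulates every sequence with one shared `sigmaMax` (typically the
#' mean of the per-sequence Run1 optima) and reports the fit metrics; no
#' optimisation is performed.
#'
#' @param experiments as in [calibrate_run1()].
#' @param sharedSigmaMax the shared saturated conductivity, S/m.
#' @param mesh an `ep_mesh`.
#' @param params [tissue_parameters()].
#' @param controls [solver_controls()].
#' @return A `calibration_result` with `runLabel = "Run2"`.
#' @export
evaluate_run2 <- function(experiments, sharedSigmaMax, mesh,
                          params = tissue_parameters(),
                          controls = solver_controls(params = params)) {
  p <- params
  p$sigmaMax <- sharedSigmaMax
  rows <- lapply(seq_along(experiments), function(i) {
    e <- experiments[[i]]
    sim <- run_simulation(mesh, e$voltage, p, controls)
    m <- fit_metrics(e$current, sim)
    data.frame(sequence = e$label %||% i,
               sigmaMax = sharedSigmaMax,
               i_max_A = m$iMax,
               avg_dI_A = m$avgDeltaI,
               rel_deviation = m$relDeviation)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, sigmaMaxMean = sharedSigmaMax,
                 runLabel = "Run2"),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("%s calibration over %d sequence(s); mean sigmaMax = %.5g S/m\n",
              x$runLabel, nrow(x$table), x$sigmaMaxMean))
  print(x$table, row.names = FALSE)
  invisible(x)
}
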