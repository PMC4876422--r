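# Seeded synthetic-experiment generator: oscilloscope-like voltage/current
# trace pairs with known ground-truth parameters, standing in for wet-lab
# acquisitions so every downstream stage is testable offline.

#' Synthetic experiment specification
#'
#' @param sequence sequence number 1-9 (see [pulse_sequence_table()]) or a
#'   [pulse_train()].
#' @param trueParams ground-truth [tissue_parameters()] used to simulate
#'   the current.
#' @param replicates number of replicate acquisitions (default 5, as in
#'   the reference experiment).
#' @param noiseSigma additive Gaussian current noise, as a fraction of the
#'   maximum simulated current (default 0.01).
#' @param voltageJitter per-replicate fractional plateau-amplitude spread
#'   (default 0.005, keeping applied voltages within ~1% of one another).
#' @param sigma0Jitter optional per-replicate fractional spread of the
#'   baseline conductivity emulating tissue heterogeneity (default 0, off).
#' @param seed integer RNG seed; identical seeds regenerate identical
#'   traces.
#' @param samplingInterval oscilloscope sampling interval, s; default
#'   `span / 5e5`, dense enough that down-sampling in groups of 1000 is
#'   meaningful.
#' @param pulseCount optional pulse-count override for shortened runs.
#' @return An object of class `synthetic_experiment_spec`.
#' @export
synthetic_experiment <- function(sequence = 1,
                                 trueParams = tissue_parameters(),
                                 replicates = 5, noiseSigma = 0.01,
                                 voltageJitter = 0.005, sigma0Jitter = 0,
                                 seed = 1, samplingInterval = NULL,
                                 pulseCount = NULL) {
  if (replicates < 1) stop("replicates must be at least 1")
  if (noiseSigma < 0) stop("noiseSigma must be non-negative")
  train <- if (inherits(sequence, "pulse_train")) sequence
           else sequence_pulse_train(sequence, pulseCount = pulseCount)
  structure(list(train = train, trueParams = trueParams,
                 replicates = replicates, noiseSigma = noiseSigma,
                 voltageJitter = voltageJitter, sigma0Jitter = sigma0Jitter,
                 seed = as.integer(seed),
                 samplingInterval = samplingInterval),
            class = "synthetic_experiment_spec")
}

#' Generate a synthetic experiment
#'
#' Per replicate: the trapezoidal voltage train is scaled by a seeded
#' plateau-amplitude factor, the current response is simulated with the
#' ground-truth parameters on the supplied mesh, interpolated onto the
#' dense oscilloscope sampling grid, and additive Gaussian noise
#' (`noiseSigma * I_max`) is applied per sample.  Regenerating with the
#' same seed reproduces identical traces.
#'
#' @param spec a [synthetic_experiment()].
#' @param mesh an `ep_mesh` on which the truth is simulated.
#' @param controls [solver_controls()].
#' @return A list of class `synthetic_experiment` with one entry per
#'   replicate, each a list `(voltage, current)` of [ep_trace()] objects;
#'   attributes `truth` (the simulation of replicate 1's drive) and `spec`.
#' @export
generate_experiment <- function(spec, mesh,
                                controls = solver_controls(params = spec$trueParams)) {
  stopifnot(inherits(spec, "synthetic_experiment_spec"))
  train <- spec$train
  span <- pulse_train_span(train)
  si <- spec$samplingInterval %||% (span / 5e5)
  si <- min(si, train$riseTime / 2)
  grid <- seq(train$startTime, train$startTime + span, by = si)

  with_local_seed(spec$seed, {
    ampFac <- 1 + spec$voltageJitter * stats::rnorm(spec$replicates)
    sigFac <- 1 + spec$sigma0Jitter * stats::rnorm(spec$replicates)
    if (spec$voltageJitter == 0) ampFac[] <- 1
    if (spec$sigma0Jitter == 0) sigFac[] <- 1
    reps <- vector("list", spec$replicates)
    truth <- NULL
    for (r in seq_len(spec$replicates)) {
      tr <- train
      tr$peakVoltage <- train$peakVoltage * ampFac[r]
      p <- spec$trueParams
      p$sigma0 <- p$sigma0 * sigFac[r]
      sim <- if (r > 1 && ampFac[r] == ampFac[1] && sigFac[r] == sigFac[1]) {
        truth  # identical drive and tissue: reuse the simulation
      } else {
        run_simulation(mesh, tr, p, controls)
      }
      if (r == 1) truth <- sim
      vGrid <- pulse_voltage(tr, grid)
      iGrid <- stats::approx(sim$times, sim$current, xout = grid,
                             rule = 2)$y
      noise <- if (spec$noiseSigma > 0) {
        stats::rnorm(length(grid), sd = spec$noiseSigma * max(abs(iGrid)))
      } else 0
      reps[[r]] <- list(
        voltage = ep_trace(grid, vGrid, "voltage",
                        meta = list(replicate = r, synthetic = TRUE)),
        current = ep_trace(grid, iGrid + noise, "current",
                        meta = list(replicate = r, synthetic = TRUE)))
    }
    structure(reps, class = "synthetic_experiment", truth = truth,
              spec = spec)
  })
}

#' Preprocess a synthetic (or measured) replicate set
#'
#' The acquisition pipeline applied to the reference measurements:
#' down-sample each replicate's voltage and current in groups, then average
#' across replicates.
#'
#' @param reps a list of `(voltage, current)` replicate pairs (e.g. from
#'   [generate_experiment()]).
#' @param groupSize down-sampling group size (default 1000).
#' @return A list `(voltage, current)` of averaged [ep_trace()] objects.
#' @export
preprocess_replicates <- function(reps, groupSize = 1000) {
  v <- lapply(reps, function(r) downsample(r$voltage, groupSize))
  i <- lapply(reps, function(r) downsample(r$current, groupSize))
  if (length(reps) == 1) return(list(voltage = v[[1]], current = i[[1]]))
  list(voltage = average_replicates(v), current = average_replicates(i))
}
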