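# Shared fixtures, built once per test run.  Meshes are deliberately small:
# the box meshes represent the plate-capacitor verification geometry (the
# uniform field is exact on them at any resolution), the needle mesh is the
# coarse two-needle geometry used for solver-behaviour checks.

fix <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    cache[[name]] <- switch(name,
      params = tissue_parameters(),
      frozen = porodyn:::frozen_sigma_parameters(tissue_parameters()),
      box_small = build_box_geometry(lengths = c(0.01, 0.01, 0.01),
                                     n = c(2, 2, 2)),
      box_mid = build_box_geometry(lengths = c(0.01, 0.01, 0.01),
                                   n = c(4, 4, 4)),
      needle = build_two_needle_geometry(targetEdgeLength = 4e-3),
      stop("unknown fixture: ", name))
    cache[[name]]
  }
})

# One-pulse 500 V trapezoid (Sequence-1-like first pulse).
one_pulse <- function(peak = 500, duration = 100e-6) {
  pulse_train(peak, duration, 4762, pulseCount = 1)
}

# Synthetic replicate set plus its down-sampled, replicate-averaged pair.
make_synth_pair <- function(mesh, seed = 1, noiseSigma = 0.01,
                            replicates = 2, trueParams = tissue_parameters(),
                            train = one_pulse()) {
  spec <- synthetic_experiment(sequence = train, trueParams = trueParams,
                               replicates = replicates,
                               noiseSigma = noiseSigma, seed = seed,
                               samplingInterval = pulse_train_span(train) / 5e4)
  reps <- generate_experiment(spec, mesh)
  pre <- preprocess_replicates(reps, groupSize = 1000)
  list(reps = reps, voltage = pre$voltage, current = pre$current,
       truth = attr(reps, "truth"))
}
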