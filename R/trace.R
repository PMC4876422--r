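# Pulse-train synthesis and oscilloscope-trace processing.

#' Pulse-train specification
#'
#' A train of identical trapezoidal voltage pulses.  A pulse occupies the
#' interval `[t0, t0 + pulseDuration]`: it ramps linearly from 0 to
#' `peakVoltage` over the first `riseTime`, holds the plateau, and ramps
#' back to 0 over the final `fallTime`.  Pulse starts are spaced by
#' `1/repetitionFrequency`, so the nominal span from the first rise to the
#' last fall is `(pulseCount - 1)/repetitionFrequency + pulseDuration`.
#'
#' @param peakVoltage plateau voltage, V.
#' @param pulseDuration duration of one pulse (rise start to fall end), s.
#' @param repetitionFrequency pulse repetition frequency, Hz.
#' @param pulseCount number of pulses (>= 1).
#' @param riseTime,fallTime linear ramp durations, s.
#' @param startTime time of the first pulse's rise start, s.
#' @return An object of class `pulse_train`.
#' @examples
#' seq1 <- pulse_train(500, 100e-6, 4762, 8)
#' pulse_train_span(pulse_train(500, 1000e-6, 1, 8))  # 7.001 s
#' @export
pulse_train <- function(peakVoltage, pulseDuration, repetitionFrequency,
                        pulseCount = 8, riseTime = 2e-6, fallTime = 2e-6,
                        startTime = 0) {
  if (pulseCount < 1) stop("pulseCount must be at least 1")
  if (riseTime + fallTime > pulseDuration) {
    stop("riseTime + fallTime must not exceed pulseDuration")
  }
  if (pulseCount > 1 && 1 / repetitionFrequency < pulseDuration) {
    stop("pulses overlap: 1/repetitionFrequency < pulseDuration")
  }
  structure(list(peakVoltage = peakVoltage, pulseDuration = pulseDuration,
                 repetitionFrequency = repetitionFrequency,
                 pulseCount = pulseCount, riseTime = riseTime,
                 fallTime = fallTime, startTime = startTime),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf(
    "Pulse train: %d x %g V, %g us pulses at %g Hz (span %g s)\n",
    x$pulseCount, x$peakVoltage, x$pulseDuration * 1e6,
    x$repetitionFrequency, pulse_train_span(x)))
  invisible(x)
}

#' Nominal span and edge times of a pulse train
#'
#' `pulse_train_span()` returns the time from the first rise start to the
#' last fall end.  `pulse_edges()` returns the sorted times of every rise
#' start, rise end, fall start and fall end.
#'
#' @param train a [pulse_train()].
#' @return A scalar time (s), or a sorted numeric vector of edge times.
#' @export
pulse_train_span <- function(train) {
  (train$pulseCount - 1) / train$repetitionFrequency + train$pulseDuration
}

#' @rdname pulse_train_span
#' @export
pulse_edges <- function(train) {
  t0 <- train$startTime +
    (seq_len(train$pulseCount) - 1) / train$repetitionFrequency
  sort(unique(c(t0, t0 + train$riseTime,
                t0 + train$pulseDuration - train$fallTime,
                t0 + train$pulseDuration)))
}

#' Instantaneous applied voltage of a pulse train
#'
#' @param train a [pulse_train()].
#' @param t time(s), s.
#' @return Voltage(s), V.
#' @export
pulse_voltage <- function(train, t) {
  rel <- t - train$startTime
  period <- 1 / train$repetitionFrequency
  k <- floor(rel / period)
  k <- pmin(pmax(k, 0), train$pulseCount - 1)
  tau <- rel - k * period  # time within the pulse window
  v <- numeric(length(t))
  inPulse <- tau >= 0 & tau <= train$pulseDuration & rel >= 0
  up <- inPulse & tau < train$riseTime
  dn <- inPulse & tau > train$pulseDuration - train$fallTime
  flat <- inPulse & !up & !dn
  v[up] <- train$peakVoltage * tau[up] / train$riseTime
  v[flat] <- train$peakVoltage
  v[dn] <- train$peakVoltage * (train$pulseDuration - tau[dn]) / train$fallTime
  v
}

#' Time-series trace
#'
#' A sampled voltage or current time series: strictly increasing times and
#' matching values, with free-form acquisition metadata.
#'
#' @param times sample times, s, strictly increasing.
#' @param values sampled values, V or A.
#' @param kind `"voltage"` or `"current"`.
#' @param meta optional named list of acquisition metadata.
#' @return An object of class `ep_trace`.
#' @export
ep_trace <- function(times, values, kind = c("voltage", "current"),
                     meta = list()) {
  kind <- match.arg(kind)
  if (length(times) != length(values)) {
    stop("times and values must have equal length")
  }
  if (length(times) == 0) stop("empty trace")
  if (anyNA(times) || anyNA(values)) stop("trace contains NaN/NA values")
  d <- diff(times)
  if (any(d <= 0)) {
    stop("trace times must be strictly increasing (first violation at row ",
         which(d <= 0)[1] + 1, ")")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 kind = kind, meta = meta),
            class = "ep_trace")
}

#' @export
print.ep_trace <- function(x, ...) {
  cat(sprintf("%s trace: %d samples over [%g, %g] s\n",
              x$kind, length(x$times), x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

#' Sample a pulse train into a voltage trace
#'
#' @param train a [pulse_train()].
#' @param samplingInterval sample spacing, s; must resolve the ramps
#'   (`<= riseTime / 2`).
#' @param until end of the sampled window, s; defaults to the nominal span.
#' @return A voltage [ep_trace()].
#' @export
make_pulse_train_trace <- function(train, samplingInterval, until = NULL) {
  if (samplingInterval > train$riseTime / 2) {
    stop("samplingInterval must be at most riseTime / 2")
  }
  tEnd <- until %||% (train$startTime + pulse_train_span(train))
  times <- seq(train$startTime, tEnd, by = samplingInterval)
  ep_trace(times, pulse_voltage(train, times), kind = "voltage",
        meta = list(source = "pulse_train"))
}

#' Read or write a two-column trace file
#'
#' Delimited text with two columns (time \[s\], value); comma or tab
#' auto-detected; an optional header row is preserved in `meta$header`.
#'
#' @param path file path.
#' @param kind trace kind for the returned object.
#' @param x an `ep_trace` (for writing).
#' @param digits significant digits written.
#' @return `read_trace()` returns an [ep_trace()] object.
#' @export
read_trace <- function(path, kind = c("voltage", "current")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("trace file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  hasHeader <- is.na(suppressWarnings(as.numeric(strsplit(first, sep)[[1]][1])))
  df <- utils::read.table(path, sep = sep, header = hasHeader,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("trace file must have two columns: ", path)
  meta <- list(path = path)
  if (hasHeader) meta$header <- colnames(df)
  tms <- as.numeric(df[[1]])
  if (anyNA(tms) || anyNA(as.numeric(df[[2]]))) {
    stop("trace file contains non-numeric or NaN entries: ", path)
  }
  d <- diff(tms)
  if (any(d <= 0)) {
    stop("non-monotone time column in ", path, " at row ",
         which(d <= 0)[1] + 1 + hasHeader)
  }
  ep_trace(tms, as.numeric(df[[2]]), kind = kind, meta = meta)
}

#' @rdname read_trace
#' @export
write_trace <- function(x, path, digits = 15) {
  stopifnot(inherits(x, "ep_trace"))
  df <- data.frame(time = format(x$times, digits = digits, trim = TRUE),
                   value = format(x$values, digits = digits, trim = TRUE))
  names(df) <- c("time", x$kind)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Down-sample a trace by group averaging
#'
#' Consecutive non-overlapping groups of `groupSize` samples are replaced
#' by their average, in both time and value; a trailing partial group is
#' averaged as well, so the output has `ceiling(n / groupSize)` samples.
#'
#' @param x an [ep_trace()].
#' @param groupSize number of raw samples per output sample (default 1000,
#'   the acquisition down-sampling used for the reference measurements).
#' @return A down-sampled [ep_trace()].
#' @export
downsample <- function(x, groupSize = 1000) {
  stopifnot(inherits(x, "ep_trace"))
  if (groupSize < 1) stop("groupSize must be at least 1")
  if (groupSize == 1) return(x)
  n <- length(x$times)
  g <- ceiling(seq_len(n) / groupSize)
  tm <- as.numeric(tapply(x$times, g, mean))
  vl <- as.numeric(tapply(x$values, g, mean))
  ep_trace(tm, vl, kind = x$kind,
        meta = c(x$meta, list(downsampledBy = groupSize)))
}

#' Average replicate traces
#'
#' Replicates are aligned by linear interpolation onto the first trace's
#' time grid restricted to the span common to all replicates, then averaged
#' pointwise.  The pointwise standard deviation is returned alongside.
#'
#' @param traces a list of at least two [ep_trace()] objects with overlapping
#'   time spans.
#' @return The mean [ep_trace()]; the pointwise standard deviation is attached
#'   as the `"sd"` attribute (a numeric vector).
#' @export
average_replicates <- function(traces) {
  if (length(traces) < 2) stop("need at least 2 replicate traces")
  lapply(traces, function(x) stopifnot(inherits(x, "ep_trace")))
  lo <- max(vapply(traces, function(x) x$times[1], 0))
  hi <- min(vapply(traces, function(x) x$times[length(x$times)], 0))
  if (lo >= hi) stop("replicate traces have disjoint time spans")
  grid <- traces[[1]]$times
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) < 2) stop("common time span too short to align replicates")
  vals <- vapply(traces, function(x) {
    stats::approx(x$times, x$values, xout = grid)$y
  }, numeric(length(grid)))
  out <- ep_trace(grid, rowMeans(vals), kind = traces[[1]]$kind,
               meta = list(replicates = length(traces)))
  attr(out, "sd") <- apply(vals, 1, stats::sd)
  out
}

#' Reference pulse sequences
#'
#' The nine delivered pulse sequences of the beef-liver reference
#' experiment: peak voltages 500/750/1000 V, pulse durations 100/1000 us,
#' repetition frequencies 4762 Hz ("high") or 1 Hz ("low"), eight pulses
#' each.
#'
#' @return A data frame with columns `sequence`, `peak_voltage_V`,
#'   `pulse_duration_us`, `repetition_frequency_Hz`, `pulse_count`.
#' @export
pulse_sequence_table <- function() {
  utils::read.csv(system.file("extdata", "pulse_sequences.csv",
                              package = "porodyn", mustWork = TRUE))
}

#' Build a pulse train for one reference sequence
#'
#' @param n sequence number, 1-9 (see [pulse_sequence_table()]).
#' @param pulseCount optionally override the number of pulses (for
#'   shortened simulations).
#' @param riseTime,fallTime ramp durations passed to [pulse_train()].
#' @return A [pulse_train()].
#' @export
sequence_pulse_train <- function(n, pulseCount = NULL, riseTime = 2e-6,
                                 fallTime = 2e-6) {
  tab <- pulse_sequence_table()
  row <- tab[tab$sequence == n, ]
  if (nrow(row) != 1) stop("unknown sequence number: ", n)
  pulse_train(row$peak_voltage_V, row$pulse_duration_us * 1e-6,
              row$repetition_frequency_Hz,
              pulseCount %||% row$pulse_count,
              riseTime = riseTime, fallTime = fallTime)
}
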