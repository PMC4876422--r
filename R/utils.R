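# Internal helpers: unit-suffixed quantity parsing and local RNG scoping.

# Multiplicative factors to strict SI for the unit suffixes accepted in
# configuration files (Design: configs carry V, us, Hz, S/m etc.; the
# package itself is strict SI internally).
.unit_factors <- c(
  "s" = 1, "ms" = 1e-3, "us" = 1e-6, "µs" = 1e-6, "ns" = 1e-9,
  "V" = 1, "kV" = 1e3, "mV" = 1e-3,
  "V/m" = 1, "kV/m" = 1e3, "kV/cm" = 1e5,
  "Hz" = 1, "kHz" = 1e3, "MHz" = 1e6,
  "S/m" = 1, "mS/m" = 1e-3,
  "Ohm" = 1, "ohm" = 1, "Ω" = 1,
  "F" = 1, "uF" = 1e-6, "nF" = 1e-9, "pF" = 1e-12,
  "m" = 1, "cm" = 1e-2, "mm" = 1e-3, "um" = 1e-6,
  "m/V" = 1, "1/m2" = 1, "m-2" = 1, "1/m^2" = 1, "A" = 1
)

# Parse a scalar quantity that is either numeric or a string like "100 us",
# "0.99 s", "15 Ohm".  Decimal point only; unknown units are an error.
parse_quantity <- function(x, what = "value") {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  if (!is.character(x) || length(x) != 1L) {
    stop("cannot parse ", what, ": expected a number or 'number unit' string")
  }
  s <- trimws(x)
  m <- regmatches(s, regexec("^([-+0-9.eE]+)\\s*(.*)$", s))[[1]]
  if (length(m) != 3L || is.na(suppressWarnings(as.numeric(m[2])))) {
    stop("cannot parse ", what, ": '", x, "' is not a quantity")
  }
  val <- as.numeric(m[2])
  unit <- m[3]
  if (nzchar(unit)) {
    if (!unit %in% names(.unit_factors)) {
      stop("unknown unit '", unit, "' in ", what, " ('", x, "')")
    }
    val <- val * .unit_factors[[unit]]
  }
  val
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards (keeps generator output reproducible without
# clobbering the global stream).
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Row-wise Euclidean norms of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

# Vectorised cross product of rows of two n x 3 matrices.
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
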