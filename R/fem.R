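# Quasi-static nonlinear solve of the charge-conservation equation
# div(sigma(E) grad u) = div(j_cap) with Newton iteration, plus the
# adaptive time-step schedule and the time-marching driver.

# Sparse global stiffness for per-element conductivities (uses the cached
# unit-conductivity element blocks).
assemble_stiffness <- function(mesh, sigma) {
  vals <- mesh$K0 * sigma  # recycles sigma down the M rows of each column
  Matrix::sparseMatrix(i = mesh$rows, j = mesh$cols, x = as.vector(vals),
                       dims = c(mesh$nNodes, mesh$nNodes))
}

# Load vector from an element-wise constant capacitive current density:
# f_i = sum_e V_e (j_e . grad(phi_i)).
assemble_cap_source <- function(mesh, jCap) {
  fmat <- mesh$vol * (mesh$Gx * jCap[, 1] + mesh$Gy * jCap[, 2] +
                        mesh$Gz * jCap[, 3])
  as.numeric(Matrix::sparseMatrix(i = as.vector(mesh$tets),
                                  j = rep(1L, length(mesh$tets)),
                                  x = as.vector(fmat),
                                  dims = c(mesh$nNodes, 1L)))
}

electrode_nodes <- function(mesh, tag) {
  sort(unique(as.vector(mesh$tri[mesh$triTag == tag, , drop = FALSE])))
}

#' Solve the potential for one time step
#'
#' Newton solve of the weak form of the charge-conservation equation with
#' the dynamic conductivity and the capacitive source: `ELECTRODE_A` is
#' held at `appliedVoltage` and `ELECTRODE_B` at 0 V (Dirichlet), the outer
#' boundary carries zero normal current density (natural Neumann).  The
#' conductivity is re-evaluated from the current-iterate field within every
#' Newton iteration; after convergence the subsidiary variables are
#' committed from the converged field without a convergence loop of their
#' own.  The capacitive density is refreshed from the current-iterate
#' element potential each iteration (Picard; its Jacobian contribution is
#' negligible at the model's amplitude).
#'
#' @param mesh an `ep_mesh`.
#' @param state the committed `tissue_state` from the previous step.
#' @param appliedVoltage electrode A potential, V.
#' @param dt time step since the previous state, s.
#' @param controls [solver_controls()].
#' @param params [tissue_parameters()].
#' @param pulseOn logical: is a pulse applied during this step (switches
#'   damage indicators between growth and decay)?
#' @param uInit optional warm-start nodal potential.
#' @return A `field_solution`: nodal potential `u`, per-element `Emag`,
#'   the updated `state`, `time`, `newtonIterations` and the residual
#'   history.
#' @export
solve_potential <- function(mesh, state, appliedVoltage, dt,
                            controls = solver_controls(params = params),
                            params = tissue_parameters(),
                            pulseOn = TRUE, uInit = NULL) {
  if (!is.finite(appliedVoltage)) stop("appliedVoltage must be finite")
  N <- mesh$nNodes
  M <- nrow(mesh$tets)
  dirA <- electrode_nodes(mesh, "ELECTRODE_A")
  dirB <- electrode_nodes(mesh, "ELECTRODE_B")
  if (!length(dirA) || !length(dirB)) {
    stop("singular system: mesh has no Dirichlet (electrode) nodes")
  }
  dir <- c(dirA, dirB)
  free <- setdiff(seq_len(N), dir)

  u <- if (is.null(uInit)) numeric(N) else uInit
  u[dirA] <- appliedVoltage
  u[dirB] <- 0

  # boundary-load scale for the relative residual
  ub <- numeric(N); ub[dirA] <- appliedVoltage

  # Capacitive-density direction frozen at the previous committed step's
  # total current direction (explicit): near pulse edges the in-iterate
  # field direction is ill-defined where |E| ~ 0 and would chatter.
  jPrev <- state$jCond + state$jCap
  jPrevNorm <- row_norms(jPrev)
  havePrev <- jPrevNorm > 1e-300
  dirPrev <- jPrev / pmax(jPrevNorm, 1e-300)

  # residual and state evaluation at a trial potential
  evalAt <- function(u) {
    U4 <- matrix(u[mesh$tets], M, 4)
    gx <- rowSums(mesh$Gx * U4)
    gy <- rowSums(mesh$Gy * U4)
    gz <- rowSums(mesh$Gz * U4)
    Emag <- sqrt(gx^2 + gy^2 + gz^2)
    cand <- state_candidate(state, Emag, dt, pulseOn, params)
    safeE <- pmax(Emag, 1e-300)
    Edir <- cbind(-gx, -gy, -gz) / safeE
    Edir[Emag == 0, ] <- 0
    Edir[havePrev, ] <- dirPrev[havePrev, , drop = FALSE]
    cap <- capacitive_current_density(rowMeans(U4), state$capMemory, dt,
                                      Edir, params)
    A <- assemble_stiffness(mesh, cand$sigma)
    f <- assemble_cap_source(mesh, cap$jCap)
    r <- as.numeric(A %*% u) - f
    scale <- max(sqrt(sum((A %*% ub)[free]^2)), sqrt(sum(f[free]^2)), 1e-300)
    list(rel = sqrt(sum(r[free]^2)) / scale, r = r, cand = cand, cap = cap,
         gx = gx, gy = gy, gz = gz, safeE = safeE)
  }

  resHist <- numeric(0)
  iter <- 0L
  ev <- evalAt(u)
  repeat {
    resHist <- c(resHist, ev$rel)
    if (ev$rel <= controls$newtonTol) break
    if (iter >= controls$newtonMaxIter) {
      cond <- simpleError(sprintf(
        "Newton did not converge in %d iterations (last relative residual %.3g)",
        controls$newtonMaxIter, ev$rel))
      cond$residuals <- resHist
      stop(cond)
    }
    # Jacobian: sigma-part plus rank-one d(sigma)/dE blocks
    wgt <- mesh$Gx * ev$gx + mesh$Gy * ev$gy + mesh$Gz * ev$gz  # G^T grad u
    coefA <- mesh$vol * wgt                                     # K0 u
    coefB <- (ev$cand$dsdE / ev$safeE) * wgt
    jvals <- mesh$K0 * ev$cand$sigma
    for (a in 1:4) for (b in 1:4) {
      idx <- (a - 1) * 4 + b
      jvals[, idx] <- jvals[, idx] + coefA[, a] * coefB[, b]
    }
    J <- Matrix::sparseMatrix(i = mesh$rows, j = mesh$cols,
                              x = as.vector(jvals), dims = c(N, N))
    du <- as.numeric(Matrix::solve(J[free, free, drop = FALSE], -ev$r[free]))
    # backtracking line search: the poration ramp's clamps and the steep
    # pore-growth slope can make the full step overshoot
    lambda <- 1
    repeat {
      uTry <- u
      uTry[free] <- u[free] + lambda * du
      evTry <- evalAt(uTry)
      if (evTry$rel < ev$rel || lambda <= 1 / 64) break
      lambda <- lambda / 2
    }
    u <- uTry
    ev <- evTry
    iter <- iter + 1L
  }
  cand <- ev$cand
  cap <- ev$cap

  # commit state from the converged field
  U4 <- matrix(u[mesh$tets], M, 4)
  gx <- rowSums(mesh$Gx * U4); gy <- rowSums(mesh$Gy * U4)
  gz <- rowSums(mesh$Gz * U4)
  Evec <- cbind(-gx, -gy, -gz)
  newState <- state
  newState$p <- cand$p
  newState$dP <- cand$dP
  newState$dT <- cand$dT
  newState$sigma <- cand$sigma
  newState$Emag <- row_norms(Evec)
  newState$jCond <- Evec * cand$sigma
  newState$jCap <- cap$jCap
  newState$capMemory <- cap$capMemory
  newState$t <- state$t + dt

  structure(list(u = u, Emag = newState$Emag, state = newState,
                 time = newState$t, newtonIterations = iter,
                 residuals = resHist, appliedVoltage = appliedVoltage),
            class = "field_solution")
}

#' Adaptive time-step schedule for a pulse train
#'
#' Every pulse rise/fall edge is hit exactly; steps stay at `dtMin` inside
#' the refinement window after each edge (where the capacitive term varies
#' on the RC scale) and grow geometrically by `growthFactor` elsewhere,
#' capped at `dtMax` and truncated to land on the next edge.
#'
#' @param train a [pulse_train()].
#' @param controls [solver_controls()].
#' @param until optional end time, s (defaults to the last fall edge).
#' @return Sorted vector of solution times, starting at the train's start
#'   time; step sizes lie in `[dtMin, dtMax]`.
#' @export
schedule_time_steps <- function(train, controls = solver_controls(),
                                until = NULL) {
  edges <- pulse_edges(train)
  if (!is.null(until)) {
    edges <- c(edges[edges < until], until)
  }
  dtMin <- controls$dtMin; dtMax <- controls$dtMax
  win <- controls$edgeRefinementWindow; gf <- controls$growthFactor
  times <- edges[1]
  for (i in seq_len(length(edges) - 1)) {
    a <- edges[i]; b <- edges[i + 1]
    t <- a
    h <- dtMin
    while (t < b - 1e-15 * max(abs(b), 1)) {
      h <- if (t - a < win - 1e-15) dtMin else min(h * gf, dtMax)
      rem <- b - t
      if (rem <= h + dtMin) h <- rem  # avoid a trailing sliver below dtMin
      t <- min(t + h, b)
      times <- c(times, t)
    }
    times[length(times)] <- b  # land on the edge exactly
  }
  unique(times)
}

#' Constant-step counterfactual
#'
#' Number of steps a constant `dt` would need to cover a pulse train's
#' nominal span — the cost the adaptive schedule avoids.
#'
#' @param train a [pulse_train()].
#' @param dt constant step size, s (default the minimum step).
#' @return Integer step count.
#' @export
constant_step_count <- function(train, dt = 2e-6) {
  ceiling(pulse_train_span(train) / dt - 1e-9)
}

#' Run a time-dependent simulation
#'
#' Marches the dynamic model over the adaptive schedule (for a
#' [pulse_train()] drive) or over the trace's own time grid (for a
#' measured/synthetic voltage [ep_trace()] drive, interpolated linearly).
#' Each step solves the nonlinear potential problem, commits the state,
#' and records the simulated electrode current.
#'
#' @param mesh an `ep_mesh`.
#' @param drive a [pulse_train()] or a voltage [ep_trace()].
#' @param params [tissue_parameters()].
#' @param controls [solver_controls()].
#' @param until optional end time, s.
#' @param snapshotEvery keep a full state snapshot every this many steps
#'   (0 = none).
#' @param electrodeTag electrode over which the current is summed.
#' @return A `simulation_result` with fields `times`, `appliedVoltage`,
#'   `current` (the simulated current, A), `iterations`, `state` (final),
#'   `snapshots`.
#' @export
run_simulation <- function(mesh, drive, params = tissue_parameters(),
                           controls = solver_controls(params = params),
                           until = NULL, snapshotEvery = 0,
                           electrodeTag = "ELECTRODE_A") {
  if (inherits(drive, "pulse_train")) {
    times <- schedule_time_steps(drive, controls, until = until)
    volts <- pulse_voltage(drive, times)
  } else if (inherits(drive, "ep_trace")) {
    times <- drive$times
    if (!is.null(until)) times <- times[times <= until]
    volts <- stats::approx(drive$times, drive$values, xout = times)$y
  } else {
    stop("drive must be a pulse_train or a voltage trace")
  }
  nT <- length(times)
  peak <- max(abs(volts))
  state <- tissue_state(nrow(mesh$tets), params, t = times[1])
  current <- numeric(nT)
  iters <- integer(nT)
  snapshots <- list()
  u <- NULL
  sols_t <- times
  for (k in 2:nT) {
    dt <- times[k] - times[k - 1]
    on <- peak > 0 && max(abs(volts[k]), abs(volts[k - 1])) > 1e-9 * peak
    sol <- solve_potential(mesh, state, volts[k], dt, controls, params,
                           pulseOn = on, uInit = u)
    state <- sol$state
    u <- sol$u
    current[k] <- electrode_current(sol, mesh, electrodeTag)
    iters[k] <- sol$newtonIterations
    if (snapshotEvery > 0 && (k - 1) %% snapshotEvery == 0) {
      snapshots[[length(snapshots) + 1]] <- sol
    }
  }
  structure(list(times = sols_t, appliedVoltage = volts, current = current,
                 iterations = iters, state = state, snapshots = snapshots,
                 mesh = mesh),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "Simulation: %d steps over [%g, %g] s, peak current %.4g A, median Newton iterations %g\n",
    length(x$times) - 1, x$times[1], x$times[length(x$times)],
    max(abs(x$current)), stats::median(x$iterations[-1])))
  invisible(x)
}

#' One-dimensional plate-capacitor oracle
#'
#' Analytic verification harness: a parallel-plate configuration in which
#' the field is uniform (`E = U / gap`), evolved with the identical
#' constitutive update code but without any finite-element solve.  Serves
#' as the independent reference that the FEM must match on a box mesh.
#'
#' @param drive a [pulse_train()] or voltage [ep_trace()].
#' @param gap plate separation, m.
#' @param area plate area, m^2.
#' @param params [tissue_parameters()].
#' @param controls [solver_controls()].
#' @param until optional end time, s.
#' @return A `simulation_result` (with an additional `state_trace` data
#'   frame of per-step `p`, `sigma`, `Emag`).
#' @export
plate_oracle <- function(drive, gap, area, params = tissue_parameters(),
                         controls = solver_controls(params = params),
                         until = NULL) {
  if (gap <= 0 || area <= 0) stop("gap and area must be positive")
  if (inherits(drive, "pulse_train")) {
    times <- schedule_time_steps(drive, controls, until = until)
    volts <- pulse_voltage(drive, times)
  } else {
    times <- drive$times
    if (!is.null(until)) times <- times[times <= until]
    volts <- stats::approx(drive$times, drive$values, xout = times)$y
  }
  nT <- length(times)
  peak <- max(abs(volts))
  state <- tissue_state(1L, params, t = times[1])
  current <- numeric(nT)
  stTrace <- data.frame(time = times, p = 0, sigma = params$sigma0, Emag = 0)
  for (k in 2:nT) {
    dt <- times[k] - times[k - 1]
    on <- peak > 0 && max(abs(volts[k]), abs(volts[k - 1])) > 1e-9 * peak
    Emag <- abs(volts[k]) / gap
    cand <- state_candidate(state, Emag, dt, on, params)
    cap <- capacitive_current_density(volts[k] / 2, state$capMemory, dt,
                                      c(1, 0, 0), params)
    jTot <- cand$sigma * Emag + cap$magnitude
    current[k] <- abs(jTot) * area
    state$p <- cand$p; state$dP <- cand$dP; state$dT <- cand$dT
    state$sigma <- cand$sigma; state$Emag <- Emag
    state$capMemory <- cap$capMemory
    state$t <- times[k]
    stTrace$p[k] <- cand$p
    stTrace$sigma[k] <- cand$sigma
    stTrace$Emag[k] <- Emag
  }
  structure(list(times = times, appliedVoltage = volts, current = current,
                 iterations = rep(0L, nT), state = state,
                 state_trace = stTrace, snapshots = list(), mesh = NULL),
            class = "simulation_result")
}

#' Export a simulation result to CSV
#'
#' One row per time step: `time`, `applied_voltage`, `current`,
#' `newton_iterations`.
#'
#' @param result a `simulation_result`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_simulation_csv <- function(result, path) {
  utils::write.csv(data.frame(time = result$times,
                              applied_voltage = result$appliedVoltage,
                              current = result$current,
                              newton_iterations = result$iterations),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
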