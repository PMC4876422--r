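# Tetrahedral mesh construction: graded rectilinear grids split uniformly
# into six tetrahedra per hexahedron (Kuhn split, conforming across faces),
# with tagged electrode and outer boundary triangles.

SURFACE_TAGS <- c("ELECTRODE_A", "ELECTRODE_B", "OUTER")

# Cell widths covering `len`, starting near h0 at the fine end and growing
# geometrically (capped at hmax), scaled to sum to len exactly.
grade_widths <- function(len, h0, hmax, ratio = 2, fine_at = c("a", "b")) {
  fine_at <- match.arg(fine_at)
  if (len <= 0) return(numeric(0))
  if (len <= h0 * 1.5) return(len)
  w <- c()
  h <- h0
  while (sum(w) < len) {
    w <- c(w, h)
    h <- min(h * ratio, hmax)
  }
  w <- w * (len / sum(w))
  if (fine_at == "b") rev(w) else w
}

uniform_widths <- function(len, h) {
  if (len <= 0) return(numeric(0))
  n <- max(1L, round(len / h))
  rep(len / n, n)
}

# Axis breakpoints from a list of segments, each a width vector; endpoints
# of segments are reproduced exactly (no floating drift across keys).
axis_points <- function(keys, widthList) {
  pts <- keys[1]
  for (i in seq_along(widthList)) {
    w <- widthList[[i]]
    if (length(w)) {
      seg <- keys[i] + cumsum(w)
      seg[length(seg)] <- keys[i + 1]
      pts <- c(pts, seg)
    } else if (keys[i + 1] > keys[i]) {
      pts <- c(pts, keys[i + 1])
    }
  }
  pts
}

# Split a structured hex grid (graded axis points xs, ys, zs with a logical
# keep-mask over cells) into tetrahedra.  The same vertex ordering is used
# in every cell, which makes the six-tet Kuhn split face-conforming.
hexgrid_to_tets <- function(xs, ys, zs, keep) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  nid <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * as.integer(nx * ny)
  cells <- which(keep, arr.ind = TRUE)  # (i, j, k) of kept cells
  i <- cells[, 1]; j <- cells[, 2]; k <- cells[, 3]
  v <- cbind(nid(i,     j,     k),     nid(i + 1L, j,     k),
             nid(i + 1L, j + 1L, k),   nid(i,     j + 1L, k),
             nid(i,     j,     k + 1L), nid(i + 1L, j,     k + 1L),
             nid(i + 1L, j + 1L, k + 1L), nid(i,   j + 1L, k + 1L))
  # Kuhn split along the 0-6 diagonal (1-based columns: 1..8)
  pat <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
               c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  tets <- do.call(rbind, lapply(seq_len(6), function(r) v[, pat[r, ], drop = FALSE]))
  # node coordinates for the full grid, then drop unused nodes
  coords <- cbind(rep(xs, times = ny * nz),
                  rep(rep(ys, each = nx), times = nz),
                  rep(zs, each = nx * ny))
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nx * ny * nz)
  remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4)
  list(nodes = coords[used, , drop = FALSE], tets = tets)
}

# Geometry precomputation: volumes, P1 basis gradients, stiffness blocks,
# boundary triangle extraction with owners, areas and outward normals.
finalize_mesh <- function(nodes, tets, tagger, meta = list()) {
  M <- nrow(tets)
  p1 <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4], , drop = FALSE] - p1
  v6 <- rowSums(e1 * row_cross(e2, e3))
  flip <- v6 < 0
  if (any(flip)) {
    tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
    tmp <- e2[flip, , drop = FALSE]
    e2[flip, ] <- e3[flip, , drop = FALSE]
    e3[flip, ] <- tmp
    v6 <- abs(v6)
  }
  scale <- max(row_norms(e1))^3
  bad <- which(v6 <= 1e-12 * scale)
  if (length(bad)) {
    stop("degenerate (zero-volume) tetrahedron at element index ", bad[1])
  }
  g2 <- row_cross(e2, e3) / v6
  g3 <- row_cross(e3, e1) / v6
  g4 <- row_cross(e1, e2) / v6
  g1 <- -(g2 + g3 + g4)
  Gx <- cbind(g1[, 1], g2[, 1], g3[, 1], g4[, 1])
  Gy <- cbind(g1[, 2], g2[, 2], g3[, 2], g4[, 2])
  Gz <- cbind(g1[, 3], g2[, 3], g3[, 3], g4[, 3])
  vol <- v6 / 6

  # unit-conductivity element stiffness, flattened 4x4 blocks (j fast)
  K0 <- matrix(0, M, 16)
  rows <- matrix(0L, M, 16)
  cols <- matrix(0L, M, 16)
  for (a in 1:4) for (b in 1:4) {
    idx <- (a - 1) * 4 + b
    K0[, idx] <- vol * (Gx[, a] * Gx[, b] + Gy[, a] * Gy[, b] +
                          Gz[, a] * Gz[, b])
    rows[, idx] <- tets[, a]
    cols[, idx] <- tets[, b]
  }

  # boundary faces: tet faces appearing exactly once
  faceIdx <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  faces <- do.call(rbind, lapply(1:4, function(f) tets[, faceIdx[f, ], drop = FALSE]))
  owner <- rep(seq_len(M), times = 4)
  skey <- apply(faces, 1, function(r) paste(sort(r), collapse = "-"))
  cnt <- table(skey)
  isBnd <- cnt[skey] == 1L
  tri <- faces[isBnd, , drop = FALSE]
  triOwner <- owner[isBnd]

  q1 <- nodes[tri[, 1], , drop = FALSE]
  q2 <- nodes[tri[, 2], , drop = FALSE]
  q3 <- nodes[tri[, 3], , drop = FALSE]
  cr <- row_cross(q2 - q1, q3 - q1)
  triArea <- row_norms(cr) / 2
  triNormal <- cr / (2 * triArea)
  triCent <- (q1 + q2 + q3) / 3
  tetCent <- (p1 + nodes[tets[, 2], , drop = FALSE] +
                nodes[tets[, 3], , drop = FALSE] +
                nodes[tets[, 4], , drop = FALSE]) / 4
  outwards <- rowSums(triNormal * (triCent - tetCent[triOwner, , drop = FALSE]))
  triNormal[outwards < 0, ] <- -triNormal[outwards < 0, , drop = FALSE]

  if (is.function(tagger)) {
    triTag <- tagger(triCent)
  } else {
    # named character vector keyed by sorted node triple "a-b-c"
    bkey <- apply(tri, 1, function(r) paste(sort(r), collapse = "-"))
    triTag <- unname(tagger[bkey])
    triTag[is.na(triTag)] <- "OUTER"
  }
  if (!all(triTag %in% SURFACE_TAGS)) stop("tagger produced an unknown tag")

  structure(list(nodes = nodes, tets = tets, vol = vol,
                 Gx = Gx, Gy = Gy, Gz = Gz, K0 = K0,
                 rows = as.integer(rows), cols = as.integer(cols),
                 tri = tri, triTag = triTag, triOwner = triOwner,
                 triArea = triArea, triNormal = triNormal,
                 nNodes = nrow(nodes), meta = meta),
            class = "ep_mesh")
}

#' @export
print.ep_mesh <- function(x, ...) {
  cat(sprintf("Tetrahedral mesh: %d nodes, %d tets, %d boundary triangles\n",
              x$nNodes, nrow(x$tets), nrow(x$tri)))
  for (tag in SURFACE_TAGS) {
    cat(sprintf("  %s: %d triangles, area %.4g m^2\n", tag,
                sum(x$triTag == tag), sum(x$triArea[x$triTag == tag])))
  }
  invisible(x)
}

#' Validate mesh invariants
#'
#' Checks positive element volumes (consistent orientation), node indices
#' in range, absence of orphan nodes, and that every boundary triangle
#' carries exactly one known tag.
#'
#' @param mesh an `ep_mesh`.
#' @return The mesh, invisibly; errors describe the first violation.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "ep_mesh"))
  if (any(mesh$tets < 1 | mesh$tets > mesh$nNodes)) {
    stop("tet node index out of range")
  }
  if (any(mesh$vol <= 0)) {
    stop("non-positive volume at element ", which(mesh$vol <= 0)[1])
  }
  orphan <- setdiff(seq_len(mesh$nNodes), unique(as.vector(mesh$tets)))
  if (length(orphan)) stop("orphan node referenced by no element: ", orphan[1])
  if (!all(mesh$triTag %in% SURFACE_TAGS)) stop("unknown surface tag present")
  if (length(mesh$triTag) != nrow(mesh$tri)) stop("tag/triangle length mismatch")
  invisible(mesh)
}

#' Total tagged surface area
#'
#' @param mesh an `ep_mesh`.
#' @param tag one of `"ELECTRODE_A"`, `"ELECTRODE_B"`, `"OUTER"`.
#' @return Area in m^2.
#' @export
electrode_area <- function(mesh, tag) {
  if (!tag %in% SURFACE_TAGS) stop("unknown tag: ", tag)
  sum(mesh$triArea[mesh$triTag == tag])
}

#' Two-needle-electrode geometry
#'
#' Box of tissue with two parallel needle electrodes inserted from the top
#' face, insulated except over an exposed segment of the shaft.  Needles
#' are modelled as square-section bores with side `pi * d / 4`
#' (perimeter-matched to the cylindrical needle, so the tagged lateral
#' electrode area equals the cylinder area `pi * d * L`); the flat exposed
#' tip face is part of the electrode.  Bore walls over the exposed length
#' are tagged `ELECTRODE_A` / `ELECTRODE_B`; the insulated shaft and all
#' remaining boundary are tagged `OUTER` (zero normal current).
#'
#' @param electrodeDiameter needle diameter, m (default 1.2 mm).
#' @param centreSpacing centre-to-centre electrode distance, m (default
#'   10 mm).
#' @param exposedLength exposed (bare) electrode length, m (default 10 mm).
#' @param domainSize edge length of the cubic tissue domain, m (default
#'   60 mm).
#' @param targetEdgeLength target element edge length near the electrodes,
#'   m; elements coarsen geometrically toward the outer boundary.
#' @return A validated `ep_mesh`.
#' @examples
#' \donttest{
#' m <- build_two_needle_geometry(targetEdgeLength = 4e-3)
#' electrode_area(m, "ELECTRODE_A")  # ~ pi * 1.2e-3 * 10e-3
#' }
#' @export
build_two_needle_geometry <- function(electrodeDiameter = 1.2e-3,
                                      centreSpacing = 10e-3,
                                      exposedLength = 10e-3,
                                      domainSize = 60e-3,
                                      targetEdgeLength = 4e-3) {
  d <- electrodeDiameter; cs <- centreSpacing; L <- exposedLength
  D <- domainSize; h <- targetEdgeLength
  if (cs <= d) stop("infeasible geometry: centreSpacing <= electrodeDiameter ",
                    "(overlapping bores)")
  s <- pi * d / 4  # square bore side, perimeter-matched to the cylinder
  if (D / 2 - (cs / 2 + s / 2) < 2 * cs) {
    stop("infeasible geometry: domainSize too small for a margin of ",
         "2 * centreSpacing around the electrodes")
  }
  if (D < 2 * L) stop("infeasible geometry: domainSize too small for the ",
                      "exposed electrode length")
  hmax <- D / 4
  xc <- c(-cs / 2, cs / 2)

  keysX <- c(-D / 2, xc[1] - s / 2, xc[1] + s / 2, xc[2] - s / 2,
             xc[2] + s / 2, D / 2)
  segX <- list(grade_widths(keysX[2] - keysX[1], h, hmax, fine_at = "b"),
               uniform_widths(s, min(h, s)),
               uniform_widths(keysX[4] - keysX[3], h),
               uniform_widths(s, min(h, s)),
               grade_widths(keysX[6] - keysX[5], h, hmax, fine_at = "a"))
  xs <- axis_points(keysX, segX)

  keysY <- c(-D / 2, -s / 2, s / 2, D / 2)
  segY <- list(grade_widths(keysY[2] - keysY[1], h, hmax, fine_at = "b"),
               uniform_widths(s, min(h, s)),
               grade_widths(keysY[4] - keysY[3], h, hmax, fine_at = "a"))
  ys <- axis_points(keysY, segY)

  zTip <- D / 2 - L / 2
  zTop <- zTip + L
  keysZ <- c(0, zTip, zTop, D)
  segZ <- list(grade_widths(zTip, h, hmax, fine_at = "b"),
               uniform_widths(L, 1.25 * h),
               grade_widths(D - zTop, h, hmax, fine_at = "a"))
  zs <- axis_points(keysZ, segZ)

  nx <- length(xs) - 1; ny <- length(ys) - 1; nz <- length(zs) - 1
  cx <- (xs[-1] + xs[-length(xs)]) / 2
  cy <- (ys[-1] + ys[-length(ys)]) / 2
  cz <- (zs[-1] + zs[-length(zs)]) / 2
  inBore <- function(px, py) {
    (abs(px - xc[1]) < s / 2 | abs(px - xc[2]) < s / 2) & abs(py) < s / 2
  }
  keep <- array(TRUE, dim = c(nx, ny, nz))
  bore2d <- outer(cx, cy, inBore)
  for (k in seq_len(nz)) if (cz[k] > zTip) keep[, , k] <- !bore2d

  grid <- hexgrid_to_tets(xs, ys, zs, keep)
  tol <- 1e-9 * D
  tagger <- function(cent) {
    tag <- rep("OUTER", nrow(cent))
    for (e in 1:2) {
      inFoot <- abs(cent[, 1] - xc[e]) <= s / 2 + tol &
        abs(cent[, 2]) <= s / 2 + tol &
        cent[, 3] >= zTip - tol & cent[, 3] <= zTop + tol
      tag[inFoot] <- SURFACE_TAGS[e]
    }
    tag
  }
  mesh <- finalize_mesh(grid$nodes, grid$tets, tagger,
                        meta = list(geometry = "two_needle",
                                    electrodeDiameter = d,
                                    centreSpacing = cs, exposedLength = L,
                                    domainSize = D, targetEdgeLength = h,
                                    boreSide = s, zTip = zTip, zTop = zTop))
  validate_mesh(mesh)
}

#' Box (plate-capacitor) geometry
#'
#' Rectangular box meshed uniformly; the two faces at `x = 0` and
#' `x = lengths[1]` are tagged as electrodes (a parallel-plate
#' configuration with gap `lengths[1]` and plate area
#' `lengths[2] * lengths[3]`), the rest of the boundary as `OUTER`.
#' Used as the verification geometry against the one-dimensional analytic
#' oracle ([plate_oracle()]), where the uniform field is represented
#' exactly by linear elements.
#'
#' @param lengths box edge lengths `c(lx, ly, lz)`, m.
#' @param n cell counts per direction `c(nx, ny, nz)`.
#' @return A validated `ep_mesh`.
#' @export
build_box_geometry <- function(lengths = c(0.01, 0.01, 0.01),
                               n = c(4, 4, 4)) {
  stopifnot(length(lengths) == 3, length(n) == 3, all(lengths > 0),
            all(n >= 1))
  xs <- seq(0, lengths[1], length.out = n[1] + 1)
  ys <- seq(0, lengths[2], length.out = n[2] + 1)
  zs <- seq(0, lengths[3], length.out = n[3] + 1)
  keep <- array(TRUE, dim = n)
  grid <- hexgrid_to_tets(xs, ys, zs, keep)
  tol <- 1e-9 * max(lengths)
  tagger <- function(cent) {
    tag <- rep("OUTER", nrow(cent))
    tag[abs(cent[, 1]) < tol] <- "ELECTRODE_A"
    tag[abs(cent[, 1] - lengths[1]) < tol] <- "ELECTRODE_B"
    tag
  }
  mesh <- finalize_mesh(grid$nodes, grid$tets, tagger,
                        meta = list(geometry = "box", lengths = lengths,
                                    n = n))
  validate_mesh(mesh)
}

#' Mesh refinement convergence harness
#'
#' Builds the requested geometry at a sequence of halved target edge
#' lengths, solves the linear baseline problem (virgin conductivity,
#' field-independent), and reports the electrode current at each
#' resolution together with its relative change between levels.
#'
#' @param geometry `"box"` or `"two_needle"`.
#' @param targetEdgeLength coarsest edge length, m (two-needle) or coarsest
#'   cell count (box, cells per direction).
#' @param levels number of refinement levels (>= 2).
#' @param voltage applied voltage, V.
#' @param params [tissue_parameters()].
#' @return A data frame with columns `level`, `tets`, `current_A`,
#'   `rel_change`.
#' @export
mesh_convergence_study <- function(geometry = c("box", "two_needle"),
                                   targetEdgeLength = 4e-3, levels = 2,
                                   voltage = 500,
                                   params = tissue_parameters()) {
  geometry <- match.arg(geometry)
  frozen <- frozen_sigma_parameters(params)
  out <- data.frame()
  cur <- NA_real_
  for (lv in seq_len(levels)) {
    mesh <- if (geometry == "two_needle") {
      build_two_needle_geometry(targetEdgeLength = targetEdgeLength / 2^(lv - 1))
    } else {
      nc <- as.integer(2^(lv - 1) * max(2, round(0.01 / targetEdgeLength)))
      build_box_geometry(n = rep(nc, 3))
    }
    st <- tissue_state(nrow(mesh$tets), frozen)
    sol <- solve_potential(mesh, st, voltage, dt = frozen$dtMin,
                           controls = solver_controls(params = frozen),
                           params = frozen)
    I <- electrode_current(sol, mesh, "ELECTRODE_A", method = "reaction")
    out <- rbind(out, data.frame(level = lv, tets = nrow(mesh$tets),
                                 current_A = abs(I),
                                 rel_change = abs(abs(I) - cur) / abs(I)))
    cur <- abs(I)
  }
  out
}

# Parameters with the field dependence switched off (ramp far above any
# attainable field), so sigma stays at sigma0 and the problem is linear.
frozen_sigma_parameters <- function(params = tissue_parameters()) {
  params$Emin <- 1e12
  params$Emax <- 2e12
  params$Apg <- 0
  params$AT <- 0
  params$AC <- 0
  params
}
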