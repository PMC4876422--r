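# Gmsh MSH (ASCII 2.2 and 4.1) import/export.  Surface tags map to the
# physical group names "electrode_a", "electrode_b" and "outer"; the tissue
# volume carries the physical name "tissue".

.msh_phys <- c(ELECTRODE_A = "electrode_a", ELECTRODE_B = "electrode_b",
               OUTER = "outer")

#' Read a Gmsh MSH mesh
#'
#' Supports ASCII MSH versions 2.2 and 4.1.  Surface triangles belonging to
#' the physical groups `electrode_a` / `electrode_b` / `outer` are mapped to
#' the corresponding tags; boundary triangles not listed in the file are
#' tagged `OUTER`.  Both electrode groups must be present.  Node numbering
#' is remapped to a dense internal index regardless of file numbering.
#'
#' @param path path to an ASCII `.msh` file.
#' @return A validated `ep_mesh`.
#' @export
read_mesh_msh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  lines <- readLines(path)
  sec <- function(name) {
    a <- which(lines == paste0("$", name))
    b <- which(lines == paste0("$End", name))
    if (length(a) != 1 || length(b) != 1) return(NULL)
    lines[(a + 1):(b - 1)]
  }
  fmt <- sec("MeshFormat")
  if (is.null(fmt)) stop("not an MSH file (no $MeshFormat): ", path)
  ver <- strsplit(trimws(fmt[1]), "\\s+")[[1]][1]
  physRaw <- sec("PhysicalNames")
  phys <- list()  # key "dim:tag" -> name
  if (!is.null(physRaw) && length(physRaw) > 1) {
    for (ln in physRaw[-1]) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      phys[[paste0(f[1], ":", f[2])]] <- gsub('"', "", paste(f[-(1:2)],
                                                             collapse = " "))
    }
  }
  parsed <- switch(ver,
    "2.2" = parse_msh2(sec, phys),
    "4.1" = parse_msh4(sec, phys),
    stop("unsupported MSH version '", ver, "' (ASCII 2.2 or 4.1 expected)"))

  surfNames <- tolower(parsed$triName)
  wanted <- unname(.msh_phys)
  if (!all(c("electrode_a", "electrode_b") %in% surfNames)) {
    stop("missing physical groups: MSH file must name surface groups ",
         "'electrode_a' and 'electrode_b'")
  }
  keep <- surfNames %in% wanted
  tagOf <- names(.msh_phys)[match(surfNames[keep], .msh_phys)]
  triKeys <- apply(parsed$tris[keep, , drop = FALSE], 1,
                   function(r) paste(sort(r), collapse = "-"))
  tagMap <- stats::setNames(tagOf, triKeys)
  mesh <- finalize_mesh(parsed$nodes, parsed$tets, tagMap,
                        meta = list(geometry = "msh", path = path,
                                    version = ver))
  validate_mesh(mesh)
}

parse_msh2 <- function(sec, phys) {
  nodeRaw <- sec("Nodes")
  if (is.null(nodeRaw)) stop("MSH file has no $Nodes section")
  nN <- as.integer(nodeRaw[1])
  ntab <- matrix(as.numeric(unlist(strsplit(trimws(nodeRaw[1 + seq_len(nN)]),
                                            "\\s+"))), ncol = 4, byrow = TRUE)
  remap <- integer(max(ntab[, 1]))
  remap[ntab[, 1]] <- seq_len(nN)
  nodes <- ntab[, 2:4, drop = FALSE]

  elRaw <- sec("Elements")
  if (is.null(elRaw)) stop("MSH file has no $Elements section")
  nE <- as.integer(elRaw[1])
  tris <- list(); triName <- character(0); tets <- list()
  for (ln in elRaw[1 + seq_len(nE)]) {
    f <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    type <- f[2]; ntags <- f[3]
    physTag <- if (ntags >= 1) f[4] else NA
    conn <- f[(4 + ntags):length(f)]
    if (type == 2) {
      tris[[length(tris) + 1]] <- remap[conn]
      nm <- phys[[paste0("2:", physTag)]]
      triName <- c(triName, if (is.null(nm)) "" else nm)
    } else if (type == 4) {
      tets[[length(tets) + 1]] <- remap[conn]
    }
  }
  if (!length(tets)) stop("MSH file contains no tetrahedra")
  list(nodes = nodes,
       tets = do.call(rbind, tets),
       tris = if (length(tris)) do.call(rbind, tris) else matrix(0L, 0, 3),
       triName = triName)
}

parse_msh4 <- function(sec, phys) {
  entRaw <- sec("Entities")
  entPhys <- list()  # "dim:tag" -> physical tag
  if (!is.null(entRaw)) {
    counts <- as.numeric(strsplit(trimws(entRaw[1]), "\\s+")[[1]])
    i <- 2
    # points: tag x y z numPhys phys...
    for (k in seq_len(counts[1])) i <- i + 1
    for (k in seq_len(counts[2])) i <- i + 1  # curves (ignored)
    for (dimIdx in 3:4) {
      dim <- dimIdx - 1
      for (k in seq_len(counts[dimIdx])) {
        f <- as.numeric(strsplit(trimws(entRaw[i]), "\\s+")[[1]])
        nPhys <- f[8]
        if (!is.na(nPhys) && nPhys >= 1) {
          entPhys[[paste0(dim, ":", f[1])]] <- f[9]
        }
        i <- i + 1
      }
    }
  }
  nodeRaw <- sec("Nodes")
  if (is.null(nodeRaw)) stop("MSH file has no $Nodes section")
  hdr <- as.numeric(strsplit(trimws(nodeRaw[1]), "\\s+")[[1]])
  nBlocks <- hdr[1]; nN <- hdr[2]
  ids <- integer(0); xyz <- list()
  i <- 2
  for (b in seq_len(nBlocks)) {
    bh <- as.numeric(strsplit(trimws(nodeRaw[i]), "\\s+")[[1]])
    nb <- bh[4]; i <- i + 1
    bids <- as.integer(nodeRaw[i:(i + nb - 1)]); i <- i + nb
    for (k in seq_len(nb)) {
      xyz[[length(xyz) + 1]] <- as.numeric(strsplit(trimws(nodeRaw[i]),
                                                    "\\s+")[[1]])[1:3]
      i <- i + 1
    }
    ids <- c(ids, bids)
  }
  nodes <- do.call(rbind, xyz)
  remap <- integer(max(ids))
  remap[ids] <- seq_len(nN)

  elRaw <- sec("Elements")
  if (is.null(elRaw)) stop("MSH file has no $Elements section")
  ehdr <- as.numeric(strsplit(trimws(elRaw[1]), "\\s+")[[1]])
  nBlocks <- ehdr[1]
  tris <- list(); triName <- character(0); tets <- list()
  i <- 2
  for (b in seq_len(nBlocks)) {
    bh <- as.numeric(strsplit(trimws(elRaw[i]), "\\s+")[[1]])
    dim <- bh[1]; etag <- bh[2]; type <- bh[3]; nb <- bh[4]
    i <- i + 1
    for (k in seq_len(nb)) {
      f <- as.numeric(strsplit(trimws(elRaw[i]), "\\s+")[[1]])
      conn <- remap[f[-1]]
      if (type == 2) {
        tris[[length(tris) + 1]] <- conn
        pt <- entPhys[[paste0("2:", etag)]]
        nm <- if (is.null(pt)) NULL else phys[[paste0("2:", pt)]]
        triName <- c(triName, if (is.null(nm)) "" else nm)
      } else if (type == 4) {
        tets[[length(tets) + 1]] <- conn
      }
      i <- i + 1
    }
  }
  if (!length(tets)) stop("MSH file contains no tetrahedra")
  list(nodes = nodes,
       tets = do.call(rbind, tets),
       tris = if (length(tris)) do.call(rbind, tris) else matrix(0L, 0, 3),
       triName = triName)
}

#' Write a mesh to Gmsh MSH format
#'
#' Writes ASCII MSH version 2.2 (default) or 4.1 with physical surface
#' groups `electrode_a`, `electrode_b`, `outer` and volume group `tissue`.
#'
#' @param mesh an `ep_mesh`.
#' @param path output path.
#' @param version `"2.2"` or `"4.1"`.
#' @return The path, invisibly.
#' @export
write_mesh_msh <- function(mesh, path, version = c("2.2", "4.1")) {
  version <- match.arg(version)
  stopifnot(inherits(mesh, "ep_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  fmtNodes <- apply(mesh$nodes, 1, function(r) paste(format(r, digits = 17),
                                                     collapse = " "))
  tagNum <- match(mesh$triTag, names(.msh_phys))  # 1..3
  if (version == "2.2") {
    w("$MeshFormat", "2.2 0 8", "$EndMeshFormat")
    w("$PhysicalNames", "4",
      paste0('2 1 "', .msh_phys[1], '"'),
      paste0('2 2 "', .msh_phys[2], '"'),
      paste0('2 3 "', .msh_phys[3], '"'),
      '3 4 "tissue"',
      "$EndPhysicalNames")
    w("$Nodes", as.character(mesh$nNodes),
      paste(seq_len(mesh$nNodes), fmtNodes), "$EndNodes")
    nT <- nrow(mesh$tri); nE <- nrow(mesh$tets)
    triLn <- paste(seq_len(nT), 2, 2, tagNum, tagNum,
                   mesh$tri[, 1], mesh$tri[, 2], mesh$tri[, 3])
    tetLn <- paste(nT + seq_len(nE), 4, 2, 4, 4,
                   mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                   mesh$tets[, 4])
    w("$Elements", as.character(nT + nE), triLn, tetLn, "$EndElements")
  } else {
    bb <- c(apply(mesh$nodes, 2, min), apply(mesh$nodes, 2, max))
    bbs <- paste(format(bb, digits = 17), collapse = " ")
    w("$MeshFormat", "4.1 0 8", "$EndMeshFormat")
    w("$PhysicalNames", "4",
      paste0('2 1 "', .msh_phys[1], '"'),
      paste0('2 2 "', .msh_phys[2], '"'),
      paste0('2 3 "', .msh_phys[3], '"'),
      '3 4 "tissue"',
      "$EndPhysicalNames")
    w("$Entities", "0 0 3 1",
      paste("1", bbs, "1 1"), paste("2", bbs, "1 2"), paste("3", bbs, "1 3"),
      paste("1", bbs, "1 4"),
      "$EndEntities")
    w("$Nodes",
      paste(1, mesh$nNodes, 1, mesh$nNodes),
      paste(3, 1, 0, mesh$nNodes),
      as.character(seq_len(mesh$nNodes)), fmtNodes,
      "$EndNodes")
    nT <- nrow(mesh$tri); nE <- nrow(mesh$tets)
    blocks <- character(0)
    eid <- 0L
    for (g in 1:3) {
      idx <- which(tagNum == g)
      if (!length(idx)) next
      blocks <- c(blocks, paste(2, g, 2, length(idx)),
                  paste(eid + seq_along(idx), mesh$tri[idx, 1],
                        mesh$tri[idx, 2], mesh$tri[idx, 3]))
      eid <- eid + length(idx)
    }
    blocks <- c(blocks, paste(3, 1, 4, nE),
                paste(eid + seq_len(nE), mesh$tets[, 1], mesh$tets[, 2],
                      mesh$tets[, 3], mesh$tets[, 4]))
    nBlocks <- sum(tabulate(tagNum, 3) > 0) + 1
    w("$Elements", paste(nBlocks, nT + nE, 1, nT + nE), blocks,
      "$EndElements")
  }
  invisible(path)
}
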