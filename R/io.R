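#' Save / load a voxel grid
#'
#' The container is a gzip-compressed JSON document holding the shape,
#' spacing and run-length-encoded phase and mask arrays (x-fastest order).
#' The round trip is lossless on all fields.
#'
#' @param grid A [voxel_grid()].
#' @param path File path (conventionally `.vgz`).
#' @return `save_grid` returns `path` invisibly; `load_grid` the grid.
#' @export
save_grid <- function(grid, path) {
  validate_grid(grid)
  doc <- list(
    format = "chambergrow-voxel-grid",
    version = 1L,
    shape = grid$shape,
    spacing = grid$spacing,
    phase = rle_encode(as.vector(grid$phase)),
    design_mask = rle_encode(as.integer(grid$design_mask)),
    roi_mask = rle_encode(as.integer(grid$roi_mask))
  )
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' @rdname save_grid
#' @export
load_grid <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(readLines(gzfile(path), warn = FALSE)),
    error = function(e) stop("corrupt grid container: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!identical(doc$format, "chambergrow-voxel-grid")) {
    stop("not a chambergrow grid container", call. = FALSE)
  }
  if (!identical(as.integer(doc$version), 1L)) {
    stop("unsupported grid container version ", doc$version, call. = FALSE)
  }
  shp <- as.integer(doc$shape)
  n <- prod(shp)
  dec <- function(r, what) {
    v <- rle_decode(r)
    if (length(v) != n) stop("corrupt grid container: ", what,
                             " has wrong length", call. = FALSE)
    v
  }
  voxel_grid(array(as.integer(dec(doc$phase, "phase")), shp),
             spacing = doc$spacing,
             design_mask = array(dec(doc$design_mask, "design_mask") == 1L, shp),
             roi_mask = array(dec(doc$roi_mask, "roi_mask") == 1L, shp))
}

rle_encode <- function(v) {
  r <- rle(v)
  list(lengths = r$lengths, values = r$values)
}

rle_decode <- function(r) {
  inverse.rle(structure(list(lengths = as.integer(r$lengths),
                             values = as.integer(r$values)), class = "rle"))
}

#' Export a grid as a legacy-VTK rectilinear grid
#'
#' Writes an ASCII VTK file with the phase as cell data plus any supplied
#' per-element fields, readable by ParaView and other VTK viewers.
#'
#' @param grid A [voxel_grid()].
#' @param path Output path (conventionally `.vtk`).
#' @param cell_fields Named list of numeric arrays/vectors with one value
#'   per voxel (grid shape or its flattened length).
#' @return `path`, invisibly.
#' @export
export_vtk <- function(grid, path, cell_fields = list()) {
  validate_grid(grid)
  shp <- grid$shape
  n <- prod(shp)
  for (nm in names(cell_fields)) {
    if (length(cell_fields[[nm]]) != n) {
      stop("cell field '", nm, "' does not match the grid shape", call. = FALSE)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0",
     "chambergrow voxel model",
     "ASCII",
     "DATASET RECTILINEAR_GRID",
     sprintf("DIMENSIONS %d %d %d", shp[1] + 1L, shp[2] + 1L, shp[3] + 1L))
  coord <- function(axis, nm) {
    wl(sprintf("%s_COORDINATES %d double", nm, shp[axis] + 1L),
       paste(format(0:shp[axis] * grid$spacing, scientific = TRUE), collapse = " "))
  }
  coord(1, "X"); coord(2, "Y"); coord(3, "Z")
  wl(sprintf("CELL_DATA %d", n),
     "SCALARS phase int 1",
     "LOOKUP_TABLE default")
  writeLines(paste(as.vector(grid$phase)), con)
  for (nm in names(cell_fields)) {
    wl(sprintf("SCALARS %s double 1", gsub("[^A-Za-z0-9_]", "_", nm)),
       "LOOKUP_TABLE default")
    writeLines(format(as.vector(cell_fields[[nm]]), digits = 17), con)
  }
  invisible(path)
}

#' Export one phase as a binary STL surface
#'
#' Triangulates the exposed voxel faces of the selected phase (two
#' triangles per face, outward-oriented) into a watertight surface whose
#' area is exactly the exposed-face count times the face area.
#'
#' @param grid A [voxel_grid()].
#' @param path Output `.stl` path.
#' @param phase Phase name to export, default `"IMPLANT"`.
#' @return `path` invisibly, with attributes `n_triangles` and `area`.
#' @export
export_stl <- function(grid, path, phase = "IMPLANT") {
  code <- phase_codes()[[match.arg(phase, names(phase_codes()))]]
  tri <- voxel_surface_triangles(grid$phase == code, grid$spacing)
  if (nrow(tri$v1) == 0) stop("phase ", phase, " has no voxels", call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "chambergrow voxel surface"))
  writeBin(header[1:80], con)
  n <- nrow(tri$v1)
  writeBin(as.integer(n), con, size = 4, endian = "little")
  ## per triangle: normal, 3 vertices (12 float32 = 48 bytes) + 2 attr bytes
  block <- rbind(t(tri$normal), t(tri$v1), t(tri$v2), t(tri$v3))
  fraw <- writeBin(as.numeric(block), raw(), size = 4, endian = "little")
  body <- rbind(matrix(fraw, nrow = 48L), matrix(as.raw(0), 2L, n))
  writeBin(as.vector(body), con)
  out <- invisible(path)
  attr(out, "n_triangles") <- nrow(tri$v1)
  attr(out, "area") <- nrow(tri$v1) / 2 * grid$spacing^2
  out
}

## triangulate exposed faces of a logical voxel mask; outward normals.
## returns matrices v1, v2, v3 (n x 3, meters) and normal (n x 3)
voxel_surface_triangles <- function(mask, h) {
  shp <- dim(mask)
  empty <- matrix(numeric(0), 0, 3)
  v1 <- v2 <- v3 <- nl <- list()
  ids <- which(mask)
  if (!length(ids)) return(list(v1 = empty, v2 = empty, v3 = empty,
                                normal = empty))
  for (axis in 1:3) for (sgn in c(-1L, 1L)) {
    nb <- shift_array(mask, axis, -sgn)   # neighbour in +sgn dir shifted back
    exposed <- ids[!nb[ids]]
    if (!length(exposed)) next
    lo <- (arrayInd(exposed, shp) - 1L) * h
    q <- face_quads(lo, axis, sgn, h)     # list of 4 corner matrices (CCW)
    n <- matrix(0, length(exposed), 3); n[, axis] <- sgn
    v1 <- c(v1, list(q[[1]], q[[1]]))
    v2 <- c(v2, list(q[[2]], q[[3]]))
    v3 <- c(v3, list(q[[3]], q[[4]]))
    nl <- c(nl, list(n, n))
  }
  list(v1 = do.call(rbind, v1), v2 = do.call(rbind, v2),
       v3 = do.call(rbind, v3), normal = do.call(rbind, nl))
}

## corner coordinates of the faces of voxels with lower corners `lo`
## (n x 3) facing direction (axis, sgn); returns 4 corner matrices in
## counter-clockwise order seen from outside
face_quads <- function(lo, axis, sgn, h) {
  o <- setdiff(1:3, axis)
  uv <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  corners <- lapply(1:4, function(q) {
    p <- lo
    p[, axis] <- lo[, axis] + if (sgn > 0) h else 0
    p[, o[1]] <- lo[, o[1]] + uv[q, 1] * h
    p[, o[2]] <- lo[, o[2]] + uv[q, 2] * h
    p
  })
  nrm <- cross3(corners[[2]][1, ] - corners[[1]][1, ],
                corners[[3]][1, ] - corners[[1]][1, ])
  if (nrm[axis] * sgn < 0) corners <- corners[c(1, 4, 3, 2)]
  corners
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Read a binary STL file
#'
#' Minimal reader for surfaces written by [export_stl()] (used for
#' validation and round-trip checks).
#'
#' @param path STL file path.
#' @return List with `normal`, `v1`, `v2`, `v3` matrices (n x 3).
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  dat <- matrix(NA_real_, 12, n)
  for (t in seq_len(n)) {
    dat[, t] <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "raw", 2)
  }
  list(normal = t(dat[1:3, , drop = FALSE]),
       v1 = t(dat[4:6, , drop = FALSE]),
       v2 = t(dat[7:9, , drop = FALSE]),
       v3 = t(dat[10:12, , drop = FALSE]))
}

#' Check an STL surface for watertightness
#'
#' A closed, consistently oriented triangulation has every directed edge
#' matched by exactly one reverse edge, and its signed volume equals the
#' enclosed solid volume. Both are checked; the signed volume is returned.
#'
#' @param stl A list as returned by [read_stl()].
#' @return `list(watertight = logical, volume = signed volume in m^3)`.
#' @export
stl_watertight <- function(stl) {
  key <- function(p) paste(format(p[, 1], digits = 12),
                           format(p[, 2], digits = 12),
                           format(p[, 3], digits = 12), sep = ",")
  a <- key(stl$v1); b <- key(stl$v2); c <- key(stl$v3)
  fwd <- c(paste(a, b), paste(b, c), paste(c, a))
  rev <- c(paste(b, a), paste(c, b), paste(a, c))
  tf <- table(fwd)
  tr <- table(rev)
  matched <- identical(sort(names(tf)), sort(names(tr))) &&
    all(tf == tr[names(tf)])
  vol <- sum(stl$v1[, 1] * (stl$v2[, 2] * stl$v3[, 3] - stl$v3[, 2] * stl$v2[, 3]) -
             stl$v2[, 1] * (stl$v1[, 2] * stl$v3[, 3] - stl$v3[, 2] * stl$v1[, 3]) +
             stl$v3[, 1] * (stl$v1[, 2] * stl$v2[, 3] - stl$v2[, 2] * stl$v1[, 3])) / 6
  list(watertight = matched, volume = vol)
}
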