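#' Voxel grid container
#'
#' A regular lattice of cubic elements (default edge 50 um), each labeled
#' with a phase code (see [phase_codes()]), plus two boolean masks: the
#' design region (the healing-chamber trough, whose voxels may swap between
#' cancellous bone and implant during the design loop) and the cylindrical
#' region of interest (ROI) in which the healthy-bone fraction is evaluated.
#'
#' @param phase Integer 3D array of phase codes.
#' @param spacing Voxel edge length in m.
#' @param design_mask,roi_mask Logical arrays of the same shape as `phase`.
#'
#' @return A `voxel_grid` object with fields `shape`, `spacing`, `phase`,
#'   `design_mask`, `roi_mask`.
#' @export
voxel_grid <- function(phase, spacing = 50e-6,
                       design_mask = NULL, roi_mask = NULL) {
  stopifnot(is.array(phase), length(dim(phase)) == 3L)
  storage.mode(phase) <- "integer"
  shp <- dim(phase)
  if (is.null(design_mask)) design_mask <- array(FALSE, shp)
  if (is.null(roi_mask)) roi_mask <- array(FALSE, shp)
  g <- structure(list(shape = shp, spacing = spacing, phase = phase,
                      design_mask = design_mask, roi_mask = roi_mask),
                 class = "voxel_grid")
  validate_grid(g)
  g
}

validate_grid <- function(g) {
  stopifnot(inherits(g, "voxel_grid"))
  if (!all(dim(g$design_mask) == g$shape) || !all(dim(g$roi_mask) == g$shape)) {
    stop("mask shape does not match phase array", call. = FALSE)
  }
  if (!is.numeric(g$spacing) || g$spacing <= 0) {
    stop("spacing must be a positive length", call. = FALSE)
  }
  if (!all(g$phase %in% 0:3)) {
    stop("unknown phase code in grid", call. = FALSE)
  }
  dph <- g$phase[g$design_mask]
  if (length(dph) && !all(dph %in% c(PH_CANCELLOUS, PH_IMPLANT))) {
    stop("design-region voxels must be cancellous bone or implant",
         call. = FALSE)
  }
  invisible(g)
}

#' @export
print.voxel_grid <- function(x, ...) {
  tab <- tabulate(x$phase + 1L, nbins = 4L)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, h = %g um\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing * 1e6))
  cat(sprintf("  void %d | cancellous %d | cortical %d | implant %d\n",
              tab[1], tab[2], tab[3], tab[4]))
  cat(sprintf("  design region %d voxels, ROI %d voxels\n",
              sum(x$design_mask), sum(x$roi_mask)))
  invisible(x)
}

#' Tabulate a voxel grid
#'
#' One row per voxel with 0-based lattice indices, center coordinates (m),
#' phase label and mask membership. Mainly for inspection and plotting of
#' small grids; the solver works on the arrays directly.
#'
#' @param grid A [voxel_grid()].
#' @return A tibble with columns `i`, `j`, `k`, `x`, `y`, `z`, `phase`,
#'   `design`, `roi`.
#' @export
grid_tibble <- function(grid) {
  shp <- grid$shape
  idx <- arrayInd(seq_len(prod(shp)), shp) - 1L
  codes <- phase_codes()
  tibble::tibble(
    i = idx[, 1], j = idx[, 2], k = idx[, 3],
    x = (idx[, 1] + 0.5) * grid$spacing,
    y = (idx[, 2] + 0.5) * grid$spacing,
    z = (idx[, 3] + 0.5) * grid$spacing,
    phase = names(codes)[match(as.vector(grid$phase), codes)],
    design = as.vector(grid$design_mask),
    roi = as.vector(grid$roi_mask)
  )
}

## linear (1-based, x-fastest) index helpers
lin_index <- function(i, j, k, shp) {
  1L + i + shp[1] * (j + shp[2] * k)
}

## 6-neighbour shift of a logical/any array along axis by +-1, FALSE/0 padded
shift_array <- function(a, axis, by) {
  shp <- dim(a)
  out <- array(vector(typeof(a), 1L), shp)
  src <- dst <- lapply(shp, seq_len)
  n <- shp[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) { dst[[axis]] <- (1 + by):n; src[[axis]] <- 1:(n - by) }
  else if (by < 0) { dst[[axis]] <- 1:(n + by); src[[axis]] <- (1 - by):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

## count of 6-neighbours of each voxel satisfying a logical array
count_face_neighbors <- function(mask) {
  out <- array(0L, dim(mask))
  for (axis in 1:3) for (by in c(-1L, 1L)) {
    out <- out + shift_array(mask, axis, by)
  }
  out
}
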