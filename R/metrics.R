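#' Candidate evaluation parameters
#'
#' @param healthy_low,healthy_high Bounds (microstrain, inclusive) of the
#'   healthy-bone strain window; defaults 400 and 1500 microstrain, the
#'   strain range of normal physical activity.
#' @param denominator `"bone_in_roi"` (default): healthy bone voxels over
#'   all bone voxels in the ROI; `"total_roi"`: over all ROI voxels.
#' @return An `evaluation_params` object.
#' @export
evaluation_params <- function(healthy_low = 400, healthy_high = 1500,
                              denominator = c("bone_in_roi", "total_roi")) {
  denominator <- match.arg(denominator)
  if (!(0 < healthy_low && healthy_low < healthy_high)) {
    stop("need 0 < healthy_low < healthy_high", call. = FALSE)
  }
  structure(list(healthy_low = healthy_low, healthy_high = healthy_high,
                 denominator = denominator),
            class = "evaluation_params")
}

#' Healthy-bone volume fraction in the ROI
#'
#' Fraction of region-of-interest bone voxels whose equivalent strain lies
#' inside the healthy window (both ends inclusive).
#'
#' @param grid A [voxel_grid()].
#' @param solution A `field_solution` computed on `grid`.
#' @param params An [evaluation_params()] object.
#' @return Fraction in `[0, 1]`.
#' @export
healthy_fraction <- function(grid, solution, params = evaluation_params()) {
  bone <- grid$phase == PH_CANCELLOUS | grid$phase == PH_CORTICAL
  roi_bone <- which(grid$roi_mask & bone)
  if (!length(roi_bone)) stop("ROI contains no bone voxels", call. = FALSE)
  eps <- rep(NA_real_, prod(grid$shape))
  eps[solution$elem] <- solution$eqv_strain_micro
  e <- eps[roi_bone]
  if (anyNA(e)) stop("solution does not cover every ROI bone voxel", call. = FALSE)
  healthy <- sum(e >= params$healthy_low & e <= params$healthy_high)
  denom <- switch(params$denominator,
                  bone_in_roi = length(roi_bone),
                  total_roi = sum(grid$roi_mask))
  healthy / denom
}

#' Bone-implant contact area
#'
#' Number of lattice faces shared between a bone voxel (cancellous or
#' cortical) and an implant voxel (6-connectivity), times the face area.
#'
#' @param grid A [voxel_grid()].
#' @return Contact area in m^2.
#' @export
contact_area <- function(grid) {
  bone <- grid$phase == PH_CANCELLOUS | grid$phase == PH_CORTICAL
  impl <- grid$phase == PH_IMPLANT
  faces <- 0L
  for (axis in 1:3) {
    faces <- faces + sum(bone & shift_array(impl, axis, 1L)) +
                     sum(bone & shift_array(impl, axis, -1L))
  }
  faces * grid$spacing^2
}

#' Select the best design candidate
#'
#' The candidate with the greatest healthy-bone fraction; ties broken by
#' earliest iteration, then by larger contact area.
#'
#' @param history A `design_history` from [run_design()].
#' @return A one-row tibble (`iteration`, `healthy_fraction`,
#'   `contact_area`, `changes`) with the reconstructed candidate grid as
#'   attribute `"grid"`.
#' @export
select_best <- function(history) {
  stopifnot(inherits(history, "design_history"))
  tb <- history$table
  if (!nrow(tb)) stop("empty design history", call. = FALSE)
  ord <- order(-tb$healthy_fraction, tb$iteration, -tb$contact_area)
  best <- tb[ord[1L], ]
  out <- best
  attr(out, "grid") <- snapshot_grid(history, best$iteration)
  out
}
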