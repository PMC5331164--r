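#' Parameters of the synthetic implant-in-bone model
#'
#' Describes a voxelized stand-in for a solid cylindrical screwed implant
#' placed in a rectangular bone block: an axisymmetric core with annular
#' thread rings (a ring per pitch, approximating the helix), a cortical
#' crest layer over a cancellous body, and rectangular circumferential
#' troughs cut into the core between adjacent threads. The troughs are the
#' healing chamber: they start filled with cancellous bone and form the
#' design region in which the remodeling loop may swap bone and implant.
#'
#' All lengths are in meters and must be (near-)integer multiples of
#' `spacing`. The default configuration is a miniature (~2.4 x 2.4 x 3.6 mm)
#' model of 48 x 48 x 72 voxels at 50 um: small enough to iterate on a
#' single CPU while retaining crest/body stratification, three thread
#' rings and two trough bands.
#'
#' @param spacing Voxel edge (m), default 50 um.
#' @param block_size Bone block dimensions c(x, y, z) (m).
#' @param abutment_height Height of the implant abutment protruding above
#'   the bone crest (m); the grid is `block_size[3] + abutment_height` tall.
#' @param cortical_thickness Thickness of the cortical crest layer (m).
#' @param core_radius Implant core radius (m).
#' @param implant_length Embedded implant length, tip to bone crest (m).
#' @param thread_pitch Axial spacing between thread rings (m).
#' @param thread_depth Radial protrusion of a thread ring beyond the core (m).
#' @param thread_height Axial extent of a thread ring (m).
#' @param trough_depth Radial depth of the circumferential trough cut into
#'   the core (m); default half the thread pitch.
#' @param trough_height Axial extent of each trough band (m); default the
#'   inter-thread gap minus one voxel margin on each side.
#' @param roi_margin Radial margin of the cylindrical ROI beyond the outer
#'   thread radius (m); default 10 voxels.
#'
#' @return An `implant_params` object (a validated list).
#' @export
implant_params <- function(spacing = 50e-6,
                           block_size = c(2.4e-3, 2.4e-3, 2.8e-3),
                           abutment_height = 0.8e-3,
                           cortical_thickness = 0.3e-3,
                           core_radius = 0.45e-3,
                           implant_length = 2.0e-3,
                           thread_pitch = 0.6e-3,
                           thread_depth = 0.15e-3,
                           thread_height = 0.1e-3,
                           trough_depth = thread_pitch / 2,
                           trough_height = NULL,
                           roi_margin = 10 * spacing) {
  vox <- function(len, what) {
    n <- len / spacing
    if (abs(n - round(n)) > 1e-6) {
      stop(what, " (", len, " m) is not a multiple of the voxel spacing",
           call. = FALSE)
    }
    as.integer(round(n))
  }
  p <- list(spacing = spacing,
            nx = vox(block_size[1], "block x"),
            ny = vox(block_size[2], "block y"),
            nz_bone = vox(block_size[3], "block z"),
            nz_abut = vox(abutment_height, "abutment height"),
            t_cort = vox(cortical_thickness, "cortical thickness"),
            r_core = vox(core_radius, "core radius"),
            l_impl = vox(implant_length, "implant length"),
            pitch = vox(thread_pitch, "thread pitch"),
            d_thr = vox(thread_depth, "thread depth"),
            h_thr = vox(thread_height, "thread height"),
            d_tro = vox(trough_depth, "trough depth"),
            roi_margin = vox(roi_margin, "roi margin"))
  gap <- p$pitch - p$h_thr
  p$h_tro <- if (is.null(trough_height)) max(gap - 2L, 0L)
             else vox(trough_height, "trough height")
  p$nz <- p$nz_bone + p$nz_abut
  class(p) <- "implant_params"
  validate_implant_params(p)
  p
}

validate_implant_params <- function(p) {
  with(p, {
    if (any(c(nx, ny, nz_bone, r_core, l_impl, pitch) <= 0)) {
      stop("all principal dimensions must be positive", call. = FALSE)
    }
    if (d_tro >= r_core) {
      stop("trough depth must be smaller than the implant core radius",
           call. = FALSE)
    }
    if (d_tro > 0 && h_tro > pitch - h_thr) {
      stop("trough does not fit between adjacent threads", call. = FALSE)
    }
    if (t_cort >= nz_bone) {
      stop("cortical crest thicker than the bone block", call. = FALSE)
    }
    if (l_impl > nz_bone) {
      stop("implant longer than the bone block", call. = FALSE)
    }
  })
  invisible(p)
}

## analytic phase classification of one voxel center, in voxel units.
## shared by the builder; the test oracle re-implements it independently.
classify_voxel_centers <- function(p) {
  shp <- c(p$nx, p$ny, p$nz)
  cx <- p$nx / 2; cy <- p$ny / 2
  xi <- (seq_len(p$nx) - 0.5) - cx
  yj <- (seq_len(p$ny) - 0.5) - cy
  zk <- seq_len(p$nz) - 0.5            # z in voxel units from block bottom
  r2 <- outer(xi^2, yj^2, `+`)          # nx x ny, radial distance squared
  r <- sqrt(r2)

  z_tip <- p$nz_bone - p$l_impl
  thread_z <- thread_ring_starts(p)

  phase <- array(PH_VOID, shp)
  design <- array(FALSE, shp)

  in_core_xy <- r <= p$r_core
  in_thread_xy <- r <= p$r_core + p$d_thr
  in_trough_xy <- r <= p$r_core & r > p$r_core - p$d_tro

  trough_z <- trough_band_starts(p)

  for (k in seq_len(p$nz)) {
    z <- zk[k]
    sl <- matrix(PH_VOID, p$nx, p$ny)
    if (z < p$nz_bone) {
      sl[] <- if (z > p$nz_bone - p$t_cort) PH_CORTICAL else PH_CANCELLOUS
    }
    if (z > z_tip) {
      if (z < p$nz_bone) {
        ## embedded body: core, plus thread rings at their bands
        sl[in_core_xy] <- PH_IMPLANT
        for (zt in thread_z) {
          if (z > zt && z < zt + p$h_thr) sl[in_thread_xy] <- PH_IMPLANT
        }
        ## troughs carve bone back into the core between threads
        for (zt in trough_z) {
          if (z > zt && z < zt + p$h_tro) {
            sl[in_trough_xy] <- PH_CANCELLOUS
            design[, , k] <- design[, , k] | in_trough_xy
          }
        }
      } else {
        ## abutment above the crest
        sl[in_core_xy] <- PH_IMPLANT
      }
    }
    phase[, , k] <- sl
  }
  list(phase = phase, design = design, r = r, z_tip = z_tip)
}

## axial start (voxel units) of each annular thread ring, tip to crest
thread_ring_starts <- function(p) {
  if (p$d_thr == 0L || p$h_thr == 0L) return(integer(0))
  z_tip <- p$nz_bone - p$l_impl
  z <- z_tip + seq.int(p$pitch %/% 2L, by = p$pitch,
                       length.out = max(0L, p$l_impl %/% p$pitch + 1L))
  z[z + p$h_thr <= p$nz_bone - p$t_cort]
}

## axial start of each trough band: centered in every inter-thread gap
trough_band_starts <- function(p) {
  if (p$d_tro == 0L || p$h_tro == 0L) return(integer(0))
  tz <- thread_ring_starts(p)
  if (length(tz) < 2L) return(integer(0))
  gap_lo <- tz[-length(tz)] + p$h_thr
  gap_hi <- tz[-1L]
  mid <- (gap_lo + gap_hi) / 2
  as.integer(round(mid - p$h_tro / 2))
}

#' Build the synthetic voxelized implant-in-bone model
#'
#' Discretizes the parameterized screw stand-in onto the voxel lattice by
#' classifying each voxel center analytically: bone block (cortical crest
#' over cancellous body), implant core with annular thread rings and
#' abutment, rectangular circumferential troughs marked as the design
#' region and initially filled with cancellous bone, and a cylindrical ROI
#' shell around the implant.
#'
#' @param params An [implant_params()] object.
#' @param materials Named material list as from [default_materials()];
#'   only checked for completeness here.
#' @return A [voxel_grid()].
#' @export
build_synthetic_model <- function(params, materials = default_materials()) {
  stopifnot(inherits(params, "implant_params"))
  cls <- classify_voxel_centers(params)
  material_by_phase(materials, unique(as.vector(cls$phase)))

  p <- params
  roi <- array(FALSE, dim(cls$phase))
  r_out <- p$r_core + p$d_thr + p$roi_margin
  in_roi_xy <- cls$r <= r_out
  k_lo <- max(1L, as.integer(floor(cls$z_tip)) + 1L)
  for (k in k_lo:p$nz_bone) roi[, , k] <- in_roi_xy
  roi[cls$phase == PH_IMPLANT] <- FALSE
  roi[cls$phase == PH_VOID] <- FALSE

  voxel_grid(cls$phase, spacing = p$spacing,
             design_mask = cls$design, roi_mask = roi)
}
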