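#' Phase labels of the voxel model
#'
#' Every voxel of the model carries one of four integer phase codes:
#' `0` void, `1` cancellous (trabecular) bone, `2` cortical bone,
#' `3` implant alloy (Ti6Al4V). The helper returns the named code vector.
#'
#' @return Named integer vector of phase codes.
#' @export
phase_codes <- function() {
  c(VOID = 0L, CANCELLOUS = 1L, CORTICAL = 2L, IMPLANT = 3L)
}

PH_VOID <- 0L
PH_CANCELLOUS <- 1L
PH_CORTICAL <- 2L
PH_IMPLANT <- 3L

#' Define an isotropic linear-elastic material
#'
#' @param phase Phase name, one of `"CANCELLOUS"`, `"CORTICAL"`, `"IMPLANT"`.
#' @param young_modulus Young's modulus in Pa; must be positive.
#' @param poisson_ratio Poisson ratio; must lie in `[0, 0.5)`.
#'
#' @return A `material_spec` object.
#' @export
material_spec <- function(phase, young_modulus, poisson_ratio) {
  phase <- match.arg(phase, c("CANCELLOUS", "CORTICAL", "IMPLANT"))
  stopifnot(is.numeric(young_modulus), length(young_modulus) == 1L,
            is.finite(young_modulus), young_modulus > 0,
            is.numeric(poisson_ratio), length(poisson_ratio) == 1L,
            poisson_ratio >= 0, poisson_ratio < 0.5)
  structure(list(phase = phase,
                 young_modulus = young_modulus,
                 poisson_ratio = poisson_ratio),
            class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec> %s: E = %.4g GPa, nu = %.3g\n",
              x$phase, x$young_modulus / 1e9, x$poisson_ratio))
  invisible(x)
}

#' Default material set
#'
#' Elastic constants commonly used for implant-in-jaw simulation: type IV
#' (posterior maxilla) cancellous bone E = 0.69 GPa, cortical bone
#' E = 13.7 GPa (both nu = 0.3), and Ti6Al4V E = 110 GPa, nu = 0.35.
#'
#' @return A named list of [material_spec()] objects, one per solid phase.
#' @export
default_materials <- function() {
  list(
    CANCELLOUS = material_spec("CANCELLOUS", 0.69e9, 0.30),
    CORTICAL   = material_spec("CORTICAL",   13.7e9, 0.30),
    IMPLANT    = material_spec("IMPLANT",    110.0e9, 0.35)
  )
}

## material lookup by integer phase code; errors if a present phase is missing
material_by_phase <- function(materials, phases_present) {
  codes <- phase_codes()
  out <- vector("list", 3L)
  for (ph in setdiff(phases_present, PH_VOID)) {
    nm <- names(codes)[match(ph, codes)]
    m <- materials[[nm]]
    if (is.null(m)) {
      stop("no material defined for phase ", nm, call. = FALSE)
    }
    out[[ph]] <- m
  }
  out
}
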