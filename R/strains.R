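#' Per-element strain and stress recovery
#'
#' Evaluates the small-strain tensor at each non-void element centroid from
#' the trilinear shape-function gradients, then the scalar remodeling
#' stimulus: the equivalent strain
#' \deqn{\varepsilon_{eqv} = \frac{1}{1+\nu'}\,\frac{1}{\sqrt{2}}
#'   \sqrt{(\varepsilon_1-\varepsilon_2)^2 + (\varepsilon_2-\varepsilon_3)^2
#'   + (\varepsilon_3-\varepsilon_1)^2}}
#' with \eqn{\nu'} either the element material's Poisson ratio (default) or
#' a fixed 0.5, and the von Mises equivalent stress. On the regular
#' trilinear element the centroid value equals the Gauss-point average for
#' linear fields.
#'
#' @param grid A [voxel_grid()].
#' @param system The `fem_system` the displacements were solved on.
#' @param u Displacement vector from [solve_elasticity()].
#' @param nu_prime `"material"` (default) or `"half"` for \eqn{\nu' = 0.5}.
#' @return A `field_solution`: `elem` (1-based linear element ids of
#'   non-void voxels), `strain` (n x 6, order xx, yy, zz, xy, yz, zx with
#'   engineering shear), `eqv_strain_micro` (microstrain, >= 0),
#'   `eqv_stress` (Pa, >= 0), and the displacement vector.
#' @export
compute_strains <- function(grid, system, u,
                            nu_prime = c("material", "half")) {
  nu_prime <- match.arg(nu_prime)
  shp <- grid$shape
  elem <- which(grid$phase != PH_VOID)
  ph <- as.vector(grid$phase)[elem]

  ## element -> 8 node ids (0-based), x-fastest local order
  ijk <- arrayInd(elem, shp) - 1L
  s <- hex8_sign()
  n8 <- matrix(0L, length(elem), 8L)
  for (a in 1:8) {
    n8[, a] <- node_id(ijk[, 1] + (s[a, 1] + 1) %/% 2,
                       ijk[, 2] + (s[a, 2] + 1) %/% 2,
                       ijk[, 3] + (s[a, 3] + 1) %/% 2, shp)
  }
  rank_of <- node_rank_map(system)
  r8 <- matrix(rank_of[n8 + 1L], nrow(n8), 8L)
  if (anyNA(r8)) stop("solution/grid mismatch: non-void element with inactive node",
                      call. = FALSE)

  ## gather 24 dofs per element and apply the centroid B matrix
  U <- matrix(0, length(elem), 24L)
  for (a in 1:8) for (d in 1:3) {
    U[, 3L * (a - 1L) + d] <- u[3L * r8[, a] + d]
  }
  B0 <- hex8_B(0, 0, 0, grid$spacing)
  eps <- U %*% t(B0)            # n x 6, engineering shear in cols 4:6

  ## stress via the element material, and both equivalent scalars
  mats <- material_by_phase(system$materials, unique(ph))
  n <- length(elem)
  sig <- matrix(0, n, 6L)
  nu_el <- numeric(n)
  for (code in unique(ph)) {
    m <- mats[[code]]
    sel <- ph == code
    sig[sel, ] <- eps[sel, , drop = FALSE] %*% t(elastic_D(m$young_modulus,
                                                           m$poisson_ratio))
    nu_el[sel] <- m$poisson_ratio
  }
  if (nu_prime == "half") nu_el[] <- 0.5

  eqv_strain <- equivalent_strain(eps, nu_el)
  eqv_stress <- von_mises_stress(sig)

  structure(list(elem = elem,
                 phase = ph,
                 strain = eps,
                 eqv_strain_micro = eqv_strain * 1e6,
                 eqv_stress = eqv_stress,
                 u = u,
                 nu_prime = nu_prime),
            class = "field_solution")
}

## scalar invariant (1/(1+nu')) * (1/sqrt2) * sqrt(sum (eps_i - eps_j)^2)
## over principal strains; computed via the deviatoric identity so no
## per-element eigendecomposition is needed. eps has engineering shear.
equivalent_strain <- function(eps, nu_prime) {
  exy <- eps[, 4] / 2; eyz <- eps[, 5] / 2; ezx <- eps[, 6] / 2
  q <- (eps[, 1] - eps[, 2])^2 + (eps[, 2] - eps[, 3])^2 +
       (eps[, 3] - eps[, 1])^2 + 6 * (exy^2 + eyz^2 + ezx^2)
  sqrt(pmax(q, 0) / 2) / (1 + nu_prime)
}

von_mises_stress <- function(sig) {
  q <- (sig[, 1] - sig[, 2])^2 + (sig[, 2] - sig[, 3])^2 +
       (sig[, 3] - sig[, 1])^2 + 6 * (sig[, 4]^2 + sig[, 5]^2 + sig[, 6]^2)
  sqrt(pmax(q, 0) / 2)
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("<field_solution> %d elements; eqv strain %.1f-%.1f ue (median %.1f)\n",
              length(x$elem), min(x$eqv_strain_micro), max(x$eqv_strain_micro),
              stats::median(x$eqv_strain_micro)))
  invisible(x)
}

#' Tabulate a field solution
#'
#' @param x A `field_solution`.
#' @param ... Unused.
#' @return A tibble with one row per non-void element: linear element id,
#'   phase label, equivalent strain (microstrain) and von Mises stress (Pa).
#' @method tidy field_solution
#' @export
tidy.field_solution <- function(x, ...) {
  codes <- phase_codes()
  tibble::tibble(elem = x$elem,
                 phase = names(codes)[match(x$phase, codes)],
                 eqv_strain_micro = x$eqv_strain_micro,
                 eqv_stress = x$eqv_stress)
}
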