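#' Element stiffness of a cubic trilinear hexahedron
#'
#' Stiffness matrix of an 8-node cube of edge `h` with isotropic elasticity
#' `(E, nu)`, integrated with full 2x2x2 Gauss quadrature. Local node order
#' is x-fastest (then y, then z); DOFs are `(ux, uy, uz)` per node.
#'
#' @param E Young's modulus (Pa).
#' @param nu Poisson ratio.
#' @param h Element edge length (m).
#' @return A 24 x 24 symmetric matrix.
#' @export
hex8_stiffness <- function(E, nu, h) {
  D <- elastic_D(E, nu)
  g <- 1 / sqrt(3)
  Ke <- matrix(0, 24, 24)
  for (xi in c(-g, g)) for (et in c(-g, g)) for (ze in c(-g, g)) {
    B <- hex8_B(xi, et, ze, h)
    Ke <- Ke + crossprod(B, D %*% B) * (h / 2)^3
  }
  (Ke + t(Ke)) / 2
}

## isotropic constitutive matrix, engineering shear strain convention
elastic_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

## strain-displacement matrix at natural coords for the regular cube,
## strain order (xx, yy, zz, xy, yz, zx) with engineering shear
hex8_B <- function(xi, et, ze, h) {
  s <- hex8_sign()
  dN <- cbind(0.125 * s[, 1] * (1 + et * s[, 2]) * (1 + ze * s[, 3]),
              0.125 * (1 + xi * s[, 1]) * s[, 2] * (1 + ze * s[, 3]),
              0.125 * (1 + xi * s[, 1]) * (1 + et * s[, 2]) * s[, 3]) * (2 / h)
  B <- matrix(0, 6, 24)
  for (a in 1:8) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- dN[a, 1]
    B[2, c0 + 2] <- dN[a, 2]
    B[3, c0 + 3] <- dN[a, 3]
    B[4, c0 + 1] <- dN[a, 2]; B[4, c0 + 2] <- dN[a, 1]
    B[5, c0 + 2] <- dN[a, 3]; B[5, c0 + 3] <- dN[a, 2]
    B[6, c0 + 1] <- dN[a, 3]; B[6, c0 + 3] <- dN[a, 1]
  }
  B
}

hex8_sign <- function() {
  cbind(c(-1, 1, -1, 1, -1, 1, -1, 1),
        c(-1, -1, 1, 1, -1, -1, 1, 1),
        c(-1, -1, -1, -1, 1, 1, 1, 1))
}

#' Assemble the global stiffness operator of a voxel grid
#'
#' Builds the sparse symmetric stiffness over 3 DOFs per node of non-void
#' elements. Bone and implant elements share nodes on the conformal lattice,
#' which reproduces a bonded (perfectly rigid) interface. Void voxels
#' contribute nothing and their isolated nodes carry no DOFs.
#'
#' @param grid A [voxel_grid()].
#' @param materials Named material list; an error is raised if a phase
#'   present in the grid has no material.
#' @return A `fem_system` object: sparse `K` (class `dgCMatrix`), 0-based
#'   `active_nodes`, the node-dimension `nnode_dim`, spacing, and the grid
#'   shape. DOF `3*a + d` (0-based) belongs to axis `d` of `active_nodes[a+1]`.
#' @export
assemble_stiffness <- function(grid, materials = default_materials()) {
  validate_grid(grid)
  phases <- sort(unique(as.vector(grid$phase)))
  if (identical(phases, PH_VOID) || length(phases) == 0) {
    stop("grid has no non-void elements", call. = FALSE)
  }
  mats <- material_by_phase(materials, phases)
  ke <- vector("list", 3L)
  for (ph in setdiff(phases, PH_VOID)) {
    m <- mats[[ph]]
    ke[[ph]] <- hex8_stiffness(m$young_modulus, m$poisson_ratio, grid$spacing)
  }
  raw <- assemble_voxel_stiffness(as.vector(grid$phase), grid$shape, ke)
  ndof <- as.integer(raw$ndof)
  K <- Matrix::sparseMatrix(i = raw$i, p = as.integer(raw$p),
                            x = raw$x, dims = c(ndof, ndof),
                            index1 = FALSE)
  structure(list(K = K,
                 active_nodes = raw$active_nodes,
                 shape = grid$shape,
                 spacing = grid$spacing,
                 materials = materials),
            class = "fem_system")
}

#' Boundary conditions for the voxel model
#'
#' @param fixed A list of constraints, each `list(nodes = <0-based node
#'   ids>, axes = <subset of 1:3>)`; the listed displacement components are
#'   set to zero.
#' @param loaded_nodes 0-based node ids receiving the external load.
#' @param total_load Total force vector (N), split over `loaded_nodes`
#'   according to `load_weights` (uniform by default).
#' @param load_weights Optional positive weights, one per loaded node
#'   (normalized internally); use lattice-consistent weights (1/4 corner,
#'   1/2 edge, 1 interior) to represent an exactly uniform surface pressure.
#' @return A `boundary_conditions` object.
#' @export
boundary_conditions <- function(fixed, loaded_nodes, total_load,
                                load_weights = NULL) {
  stopifnot(is.list(fixed), length(fixed) >= 1L,
            length(loaded_nodes) >= 1L,
            is.numeric(total_load), length(total_load) == 3L)
  for (f in fixed) {
    stopifnot(length(f$nodes) >= 1L, all(f$axes %in% 1:3))
  }
  if (!is.null(load_weights)) {
    stopifnot(length(load_weights) == length(loaded_nodes),
              all(load_weights > 0))
  }
  structure(list(fixed = fixed,
                 loaded_nodes = as.integer(loaded_nodes),
                 total_load = as.numeric(total_load),
                 load_weights = load_weights),
            class = "boundary_conditions")
}

## 0-based lattice node id from 0-based (i, j, k) on the node lattice
node_id <- function(i, j, k, shape) {
  nnx <- shape[1] + 1L; nny <- shape[2] + 1L
  as.integer(i + nnx * (j + nny * k))
}

## decompose 0-based node ids into (i, j, k)
node_ijk <- function(ids, shape) {
  nnx <- shape[1] + 1L; nny <- shape[2] + 1L
  i <- ids %% nnx
  j <- (ids %/% nnx) %% nny
  k <- ids %/% (nnx * nny)
  cbind(i = i, j = j, k = k)
}

#' Default load case of the implant model
#'
#' Mesial and distal bone faces (the two y-extreme node planes) are fully
#' constrained; a compressive axial force is split uniformly over the nodes
#' of the implant's top (abutment) surface.
#'
#' @param grid A [voxel_grid()].
#' @param axial_force Compressive force magnitude (N), applied along -z.
#'   The default 3 N is the miniature-model equivalent of a full-scale
#'   100 N bite load: it puts the nominal cancellous strain
#'   F / (A_block * E) near the middle of the physiological window.
#' @return A [boundary_conditions()] object.
#' @export
default_bc <- function(grid, axial_force = 3) {
  shp <- grid$shape
  ## nodes of the y = 0 and y = ny planes that touch non-void voxels
  nonvoid <- grid$phase != PH_VOID
  face_nodes <- function(jval) {
    jj <- if (jval == 0L) 1L else shp[2]
    touch <- which(nonvoid[, jj, ], arr.ind = TRUE)   # (i, k) of voxels
    if (nrow(touch) == 0) return(integer(0))
    i0 <- touch[, 1] - 1L; k0 <- touch[, 2] - 1L
    ii <- c(i0, i0 + 1L, i0, i0 + 1L)
    kk <- c(k0, k0, k0 + 1L, k0 + 1L)
    unique(node_id(ii, rep(jval, length(ii)), kk, shp))
  }
  fixed <- list(
    list(nodes = face_nodes(0L), axes = 1:3),
    list(nodes = face_nodes(shp[2]), axes = 1:3)
  )
  if (!length(fixed[[1]]$nodes) || !length(fixed[[2]]$nodes)) {
    stop("constrained faces touch no non-void voxel", call. = FALSE)
  }
  ## nodes of top faces of implant voxels in the top voxel layer
  top <- which(grid$phase[, , shp[3]] == PH_IMPLANT, arr.ind = TRUE)
  if (nrow(top) == 0) {
    stop("no implant voxels on the loaded top surface", call. = FALSE)
  }
  i0 <- top[, 1] - 1L; j0 <- top[, 2] - 1L
  ii <- c(i0, i0 + 1L, i0, i0 + 1L)
  jj <- c(j0, j0, j0 + 1L, j0 + 1L)
  loaded <- unique(node_id(ii, jj, rep(shp[3], length(ii)), shp))
  boundary_conditions(fixed, loaded, c(0, 0, -abs(axial_force)))
}

#' Solve the constrained elastic equilibrium
#'
#' Applies the Dirichlet constraints by reduction to the free DOFs and
#' solves `K u = f`. Systems below `direct_limit` DOFs use a sparse
#' Cholesky factorization; larger systems use Jacobi-preconditioned
#' conjugate gradients to a relative residual of `tol`.
#'
#' @param system A `fem_system` from [assemble_stiffness()].
#' @param bc A [boundary_conditions()] object.
#' @param tol Relative residual tolerance of the iterative solver.
#' @param direct_limit DOF count below which a direct solve is used.
#' @param u0 Optional warm-start displacement (full active-DOF vector).
#' @param max_iter Iteration cap of the CG solver.
#' @return Numeric vector of nodal displacements over all active DOFs
#'   (fixed DOFs hold 0), with attributes `relres` and `iterations`.
#' @export
solve_elasticity <- function(system, bc, tol = 1e-9, direct_limit = 3e4,
                             u0 = NULL, max_iter = 10000) {
  K <- system$K
  ndof <- nrow(K)
  rank_of <- node_rank_map(system)

  fixed_dofs <- integer(0)
  for (f in bc$fixed) {
    r <- rank_of[f$nodes + 1L]
    if (anyNA(r)) {
      stop("a constrained node carries no DOF (void-attached)", call. = FALSE)
    }
    fixed_dofs <- c(fixed_dofs, as.vector(outer(3L * r, f$axes - 1L, `+`)))
  }
  fixed_dofs <- sort(unique(fixed_dofs)) + 1L   # 1-based
  if (!length(fixed_dofs)) stop("no constraints given", call. = FALSE)

  lr <- rank_of[bc$loaded_nodes + 1L]
  if (anyNA(lr)) {
    stop("a loaded node carries no DOF (void-attached)", call. = FALSE)
  }
  w <- bc$load_weights
  if (is.null(w)) w <- rep(1, length(lr))
  w <- w / sum(w)
  f <- numeric(ndof)
  for (d in 1:3) {
    if (bc$total_load[d] != 0) {
      f[3L * lr + d] <- f[3L * lr + d] + bc$total_load[d] * w
    }
  }

  free <- setdiff(seq_len(ndof), fixed_dofs)
  Kff <- K[free, free, drop = FALSE]
  b <- f[free]
  u <- numeric(ndof)

  if (!any(b != 0)) {
    attr(u, "relres") <- 0
    attr(u, "iterations") <- 0L
    return(u)
  }

  if (length(free) <= direct_limit) {
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE,
                           super = TRUE)
    x <- as.vector(Matrix::solve(ch, b))
    it <- NA_integer_
  } else {
    x0 <- if (!is.null(u0)) u0[free] else NULL
    cg <- pcg_jacobi(Kff, b, tol = tol, max_iter = max_iter, x0 = x0)
    x <- cg$x
    it <- cg$iterations
  }
  u[free] <- x
  r <- b - as.vector(Kff %*% x)
  relres <- sqrt(sum(r^2)) / sqrt(sum(b^2))
  if (!is.finite(relres) || relres > 1e-6) {
    stop(sprintf("elastic solve did not converge (relres %.3g); %s",
                 relres, "check that constraints suppress rigid-body modes"),
         call. = FALSE)
  }
  attr(u, "relres") <- relres
  attr(u, "iterations") <- it
  u
}

## map 0-based lattice node id -> active node rank (0-based), NA if inactive
node_rank_map <- function(system) {
  shp <- system$shape
  nnode <- prod(shp + 1L)
  m <- rep(NA_integer_, nnode)
  m[system$active_nodes + 1L] <- seq_along(system$active_nodes) - 1L
  m
}

## Jacobi-preconditioned conjugate gradients on an SPD dgCMatrix; the
## iteration itself runs in compiled code
pcg_jacobi <- function(A, b, tol = 1e-9, max_iter = 10000, x0 = NULL) {
  d <- Matrix::diag(A)
  if (any(d <= 0)) stop("system matrix is not positive definite", call. = FALSE)
  if (is.null(x0)) x0 <- numeric(length(b))
  pcg_csc(A@p, A@i, A@x, b, d, x0, tol, as.integer(max_iter))
}
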