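## Independent oracles used across the test files. These deliberately avoid
## the package's own code paths: dense assembly with 3x3x3 quadrature and
## its own shape-function code, plain-loop voxel classification, and
## exhaustive neighbour scans.

## ---- dense single-element stiffness, 3x3x3 Gauss, independent coding ----
oracle_hex_Ke <- function(E, nu, h) {
  ## Gauss-Legendre 3-point rule
  gp <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gw <- c(5 / 9, 8 / 9, 5 / 9)
  ## node corner coordinates in the same local order as the package
  corners <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1))) * h
  D <- matrix(0, 6, 6)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D[1:3, 1:3] <- lam; diag(D)[1:3] <- diag(D)[1:3] + 2 * mu
  D[4, 4] <- D[5, 5] <- D[6, 6] <- mu
  Ke <- matrix(0, 24, 24)
  for (a in 1:3) for (b in 1:3) for (c in 1:3) {
    xi <- (gp[a] + 1) / 2 * h; et <- (gp[b] + 1) / 2 * h; ze <- (gp[c] + 1) / 2 * h
    ## trilinear shape gradients in physical coords, by direct product rule
    dN <- matrix(0, 8, 3)
    for (n in 1:8) {
      fx <- if (corners[n, 1] > 0) xi / h else 1 - xi / h
      fy <- if (corners[n, 2] > 0) et / h else 1 - et / h
      fz <- if (corners[n, 3] > 0) ze / h else 1 - ze / h
      gx <- if (corners[n, 1] > 0) 1 / h else -1 / h
      gy <- if (corners[n, 2] > 0) 1 / h else -1 / h
      gz <- if (corners[n, 3] > 0) 1 / h else -1 / h
      dN[n, ] <- c(gx * fy * fz, fx * gy * fz, fx * fy * gz)
    }
    B <- matrix(0, 6, 24)
    for (n in 1:8) {
      col <- 3 * (n - 1)
      B[1, col + 1] <- dN[n, 1]
      B[2, col + 2] <- dN[n, 2]
      B[3, col + 3] <- dN[n, 3]
      B[4, col + 1] <- dN[n, 2]; B[4, col + 2] <- dN[n, 1]
      B[5, col + 2] <- dN[n, 3]; B[5, col + 3] <- dN[n, 2]
      B[6, col + 1] <- dN[n, 3]; B[6, col + 3] <- dN[n, 1]
    }
    wt <- gw[a] * gw[b] * gw[c] * (h / 2)^3
    Ke <- Ke + t(B) %*% D %*% B * wt
  }
  Ke
}

## ---- dense global stiffness over all lattice nodes -----------------------
## returns the full (3 * nnodes) dense matrix; void elements skipped
oracle_dense_K <- function(grid, materials = default_materials()) {
  shp <- grid$shape
  h <- grid$spacing
  nn <- prod(shp + 1L)
  K <- matrix(0, 3 * nn, 3 * nn)
  codes <- phase_codes()
  kes <- list()
  for (k in 0:(shp[3] - 1)) for (j in 0:(shp[2] - 1)) for (i in 0:(shp[1] - 1)) {
    ph <- grid$phase[i + 1, j + 1, k + 1]
    if (ph == 0L) next
    nm <- names(codes)[match(ph, codes)]
    key <- as.character(ph)
    if (is.null(kes[[key]])) {
      m <- materials[[nm]]
      kes[[key]] <- oracle_hex_Ke(m$young_modulus, m$poisson_ratio, h)
    }
    nodes <- integer(8)
    q <- 1
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      nodes[q] <- (i + dx) + (shp[1] + 1) * ((j + dy) + (shp[2] + 1) * (k + dz))
      q <- q + 1
    }
    dofs <- as.vector(t(outer(3 * nodes, 0:2, `+`))) + 1
    K[dofs, dofs] <- K[dofs, dofs] + kes[[key]]
  }
  K
}

## dense constrained solve; fixed_dofs / loaded are 1-based global dof ids
oracle_dense_solve <- function(K, f, fixed_dofs) {
  n <- nrow(K)
  free <- setdiff(seq_len(n), fixed_dofs)
  ## drop dofs of fully inactive (void-surrounded) nodes: zero rows
  act <- free[colSums(abs(K[, free, drop = FALSE])) > 0]
  u <- numeric(n)
  u[act] <- solve(K[act, act], f[act])
  u
}

## translate a package solution (active-dof vector) into the oracle's
## all-node dof numbering for comparison
expand_u <- function(system, u) {
  nn <- prod(system$shape + 1L)
  out <- numeric(3 * nn)
  dofs <- as.vector(t(outer(3 * system$active_nodes, 0:2, `+`))) + 1
  out[dofs] <- u
  out
}

## ---- independent voxel classification for small screw configs -----------
## plain-loop reimplementation of the geometric rules from their statement:
## bone block with cortical crest, implant core + annular rings + abutment,
## rectangular troughs between adjacent rings marked as design region.
oracle_classify <- function(p) {
  shp <- c(p$nx, p$ny, p$nz)
  phase <- array(0L, shp)
  design <- array(FALSE, shp)
  z_tip <- p$nz_bone - p$l_impl
  rings <- c()
  if (p$d_thr > 0 && p$h_thr > 0) {
    z <- z_tip + p$pitch %/% 2
    while (z + p$h_thr <= p$nz_bone - p$t_cort) {
      rings <- c(rings, z)
      z <- z + p$pitch
    }
  }
  troughs <- c()
  if (p$d_tro > 0 && p$h_tro > 0 && length(rings) >= 2) {
    for (q in 1:(length(rings) - 1)) {
      mid <- (rings[q] + p$h_thr + rings[q + 1]) / 2
      troughs <- c(troughs, round(mid - p$h_tro / 2))
    }
  }
  for (i in 1:p$nx) for (j in 1:p$ny) for (k in 1:p$nz) {
    x <- i - 0.5 - p$nx / 2
    y <- j - 0.5 - p$ny / 2
    z <- k - 0.5
    r <- sqrt(x^2 + y^2)
    ph <- 0L
    if (z < p$nz_bone) {
      ph <- if (z > p$nz_bone - p$t_cort) 2L else 1L
    }
    if (z > z_tip) {
      if (z < p$nz_bone) {
        if (r <= p$r_core) ph <- 3L
        for (zr in rings) {
          if (z > zr && z < zr + p$h_thr && r <= p$r_core + p$d_thr) ph <- 3L
        }
        for (zt in troughs) {
          if (z > zt && z < zt + p$h_tro &&
              r <= p$r_core && r > p$r_core - p$d_tro) {
            ph <- 1L
            design[i, j, k] <- TRUE
          }
        }
      } else if (r <= p$r_core) {
        ph <- 3L
      }
    }
    phase[i, j, k] <- ph
  }
  list(phase = phase, design = design)
}

## ---- exhaustive neighbour / face scans ----------------------------------
oracle_interface_elements <- function(grid) {
  shp <- grid$shape
  out <- integer(0)
  for (id in which(grid$design_mask & grid$phase == 1L)) {
    ijk <- arrayInd(id, shp)
    touch <- FALSE
    for (d in 1:3) for (s in c(-1, 1)) {
      q <- ijk
      q[d] <- q[d] + s
      if (q[d] >= 1 && q[d] <= shp[d] &&
          grid$phase[q[1], q[2], q[3]] == 3L) touch <- TRUE
    }
    if (touch) out <- c(out, id)
  }
  out
}

oracle_contact_faces <- function(grid) {
  shp <- grid$shape
  cnt <- 0L
  for (id in which(grid$phase == 1L | grid$phase == 2L)) {
    ijk <- arrayInd(id, shp)
    for (d in 1:3) for (s in c(-1, 1)) {
      q <- ijk
      q[d] <- q[d] + s
      if (q[d] >= 1 && q[d] <= shp[d] &&
          grid$phase[q[1], q[2], q[3]] == 3L) cnt <- cnt + 1L
    }
  }
  cnt
}

## ---- small fixtures ------------------------------------------------------
small_params <- function(...) {
  defaults <- list(block_size = c(0.8e-3, 0.8e-3, 1.0e-3),
                   abutment_height = 0.2e-3,
                   cortical_thickness = 0.15e-3,
                   core_radius = 0.2e-3,
                   implant_length = 0.7e-3,
                   thread_pitch = 0.3e-3,
                   thread_depth = 0.1e-3,
                   thread_height = 0.05e-3,
                   trough_depth = 0.15e-3)
  args <- utils::modifyList(defaults, list(...))
  do.call(implant_params, args)
}

## homogeneous block grid of one phase
block_grid <- function(nx, ny, nz, phase = 1L, spacing = 50e-6) {
  voxel_grid(array(as.integer(phase), c(nx, ny, nz)), spacing = spacing)
}

## synthetic frozen field solution covering the non-void elements of a grid
fake_solution <- function(grid, eps_micro, stress = NULL) {
  elem <- which(grid$phase != 0L)
  eps <- rep_len(eps_micro, length(elem))
  sg <- if (is.null(stress)) eps * 1e-6 * 1e9 else rep_len(stress, length(elem))
  structure(list(elem = elem,
                 phase = as.vector(grid$phase)[elem],
                 strain = matrix(0, length(elem), 6),
                 eqv_strain_micro = eps,
                 eqv_stress = sg,
                 u = NULL, nu_prime = "material"),
            class = "field_solution")
}

## uniaxial-compression boundary conditions of a homogeneous block with
## frictionless lateral faces and lattice-consistent top loading; the pins
## suppress the in-plane rigid modes without disturbing the uniform state
uniaxial_bc <- function(grid, pressure) {
  shp <- grid$shape
  nnx <- shp[1] + 1L; nny <- shp[2] + 1L; nnz <- shp[3] + 1L
  nid <- function(i, j, k) i + nnx * (j + nny * k)
  bot <- as.vector(outer(0:(nnx - 1), 0:(nny - 1),
                         function(i, j) nid(i, j, 0L)))
  top <- as.vector(outer(0:(nnx - 1), 0:(nny - 1),
                         function(i, j) nid(i, j, nnz - 1L)))
  wt <- as.vector(outer(ifelse(c(0:(nnx - 1)) %in% c(0, nnx - 1), 0.5, 1),
                        ifelse(c(0:(nny - 1)) %in% c(0, nny - 1), 0.5, 1)))
  area <- (shp[1] * grid$spacing) * (shp[2] * grid$spacing)
  ctr <- nid((nnx - 1L) %/% 2L, (nny - 1L) %/% 2L, 0L)
  ctr2 <- nid((nnx - 1L) %/% 2L + 1L, (nny - 1L) %/% 2L, 0L)
  boundary_conditions(
    fixed = list(list(nodes = bot, axes = 3L),
                 list(nodes = ctr, axes = 1:2),
                 list(nodes = ctr2, axes = 2L)),
    loaded_nodes = top,
    total_load = c(0, 0, -pressure * area),
    load_weights = wt
  )
}

## flood fill: keep only non-void voxels face-connected to the j = 1 layer
prune_disconnected <- function(ph) {
  shp <- dim(ph)
  seen <- array(FALSE, shp)
  queue <- which(ph != 0L & slice.index(ph, 2) == 1L)
  seen[queue] <- TRUE
  while (length(queue)) {
    nxt <- integer(0)
    for (id in queue) {
      for (nb in face_neighbor_ids(id, shp)) {
        if (!seen[nb] && ph[nb] != 0L) { seen[nb] <- TRUE; nxt <- c(nxt, nb) }
      }
    }
    queue <- nxt
  }
  ph[!seen] <- 0L
  ph
}
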