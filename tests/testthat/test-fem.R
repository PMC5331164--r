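test_that("single-element stiffness matches the dense quadrature oracle", {
  for (mat in default_materials()) {
    Ke <- hex8_stiffness(mat$young_modulus, mat$poisson_ratio, 50e-6)
    Ko <- oracle_hex_Ke(mat$young_modulus, mat$poisson_ratio, 50e-6)
    expect_equal(Ke, Ko, tolerance = 1e-12)
    expect_equal(max(abs(Ke - t(Ke))), 0)
    ## rigid translations produce no force
    for (d in 1:3) {
      rt <- rep(0, 24); rt[seq(d, 24, by = 3)] <- 1
      expect_lt(max(abs(Ke %*% rt)), max(abs(Ke)) * 1e-12)
    }
  }
})

test_that("assembled operator is symmetric and matches the dense oracle", {
  set.seed(42)
  g <- voxel_grid(array(sample(0:3, 27, replace = TRUE, prob = c(.2, .4, .2, .2)),
                        c(3, 3, 3)))
  while (all(g$phase == 0L)) g$phase[1] <- 1L
  sys <- assemble_stiffness(g)
  K <- as.matrix(sys$K)
  expect_equal(max(abs(K - t(K))), 0)
  Kd <- oracle_dense_K(g)
  dofs <- as.vector(t(outer(3 * sys$active_nodes, 0:2, `+`))) + 1
  expect_equal(K, Kd[dofs, dofs], tolerance = 1e-12)
  ## missing material for a present phase errors
  mats <- default_materials(); mats$IMPLANT <- NULL
  if (any(g$phase == 3L)) expect_error(assemble_stiffness(g, mats), "material")
})

test_that("a floating connected body has exactly six rigid-body modes", {
  g <- block_grid(2, 2, 2, phase = 1L)
  sys <- assemble_stiffness(g)
  ev <- eigen(as.matrix(sys$K), symmetric = TRUE, only.values = TRUE)$values
  scale <- max(ev)
  expect_equal(sum(abs(ev) < scale * 1e-9), 6)
})

test_that("zero load gives zero displacement", {
  g <- block_grid(3, 3, 3)
  sys <- assemble_stiffness(g)
  bc <- uniaxial_bc(g, 0)
  u <- solve_elasticity(sys, bc)
  expect_equal(max(abs(u)), 0)
})

test_that("homogeneous block under uniaxial stress matches sigma L / E", {
  g <- block_grid(4, 4, 6)
  mat <- default_materials()$CANCELLOUS
  sys <- assemble_stiffness(g)
  sigma <- 1e6
  bc <- uniaxial_bc(g, sigma)
  u <- solve_elasticity(sys, bc)
  L <- g$shape[3] * g$spacing
  expected <- -sigma * L / mat$young_modulus
  ## mean axial displacement of the top-face nodes
  rank_of <- node_rank_map(sys)
  nnz_top <- bc$loaded_nodes
  uz_top <- u[3 * rank_of[nnz_top + 1] + 3]
  expect_equal(mean(uz_top), expected, tolerance = 1e-6)
  ## per-element equivalent strain is sigma / E (nu factors cancel)
  sol <- compute_strains(g, sys, u)
  expect_equal(sol$eqv_strain_micro,
               rep(sigma / mat$young_modulus * 1e6, length(sol$elem)),
               tolerance = 1e-6)
  ## 1 MPa on 0.69 GPa cancellous bone is ~1449 microstrain
  expect_equal(mean(sol$eqv_strain_micro), 1449.28, tolerance = 1e-4)
  ## equivalent stress is the applied stress
  expect_equal(sol$eqv_stress, rep(sigma, length(sol$elem)), tolerance = 1e-6)
})

test_that("sparse path equals dense oracle on random mixed-phase grids", {
  set.seed(7)
  for (rep in 1:5) {
    ph <- array(sample(0:3, 27, replace = TRUE, prob = c(.15, .45, .2, .2)),
                c(3, 3, 3))
    ph[, 1, ] <- 1L   # keep the constrained face solid and connected
    ph[, 2, ][ph[, 2, ] == 0L] <- 1L
    ph[, 3, ][ph[, 3, ] == 0L] <- 1L
    g <- voxel_grid(ph)
    sys <- assemble_stiffness(g)
    shp <- g$shape
    nnx <- shp[1] + 1L; nny <- shp[2] + 1L
    yface <- function(jv) {
      as.vector(outer(0:shp[1], 0:shp[3],
                      function(i, k) i + nnx * (jv + nny * k)))
    }
    f0 <- yface(0L)
    loaded <- yface(shp[2])
    loaded <- loaded[!is.na(node_rank_map(sys)[loaded + 1])]
    bc <- boundary_conditions(list(list(nodes = f0, axes = 1:3)),
                              loaded, c(0.5, 0.2, -1.0))
    u <- solve_elasticity(sys, bc, direct_limit = 1e9)
    u_cg <- solve_elasticity(sys, bc, direct_limit = 0, tol = 1e-12)
    expect_equal(max(abs(u - u_cg)) / max(abs(u)), 0, tolerance = 1e-8)

    ## dense oracle on the all-node numbering
    Kd <- oracle_dense_K(g)
    nn <- prod(shp + 1L)
    fd <- numeric(3 * nn)
    w <- 1 / length(loaded)
    fd[3 * loaded + 1] <- 0.5 * w
    fd[3 * loaded + 2] <- 0.2 * w
    fd[3 * loaded + 3] <- -1.0 * w
    fixed <- as.vector(t(outer(3 * f0, 0:2, `+`))) + 1
    ud <- oracle_dense_solve(Kd, fd, fixed)
    expect_equal(expand_u(sys, u), ud, tolerance = 1e-8)
  }
})

test_that("patch test: imposed linear field reproduces constant strain", {
  g <- block_grid(3, 4, 3, phase = 2L)
  sys <- assemble_stiffness(g)
  shp <- g$shape
  A <- matrix(c(2e-4, 3e-5, -1e-5,
                5e-5, -1e-4, 2e-5,
                -2e-5, 4e-5, 1.5e-4), 3, 3, byrow = TRUE)
  nodes <- node_ijk(sys$active_nodes, shp)
  xyz <- nodes * g$spacing
  u_exact <- xyz %*% t(A)
  ## fix all boundary nodes to the linear field, solve for the interior
  bdry <- nodes[, 1] == 0 | nodes[, 1] == shp[1] |
          nodes[, 2] == 0 | nodes[, 2] == shp[2] |
          nodes[, 3] == 0 | nodes[, 3] == shp[3]
  K <- sys$K
  ndof <- nrow(K)
  fix_dofs <- as.vector(t(outer(3 * (which(bdry) - 1L), 0:2, `+`))) + 1
  u <- numeric(ndof)
  u[fix_dofs] <- t(u_exact[bdry, ])
  free <- setdiff(seq_len(ndof), fix_dofs)
  rhs <- -as.vector(K[free, fix_dofs] %*% u[fix_dofs])
  u[free] <- as.vector(Matrix::solve(K[free, free], rhs))
  expect_equal(u, as.vector(t(u_exact)), tolerance = 1e-10)
  sol <- compute_strains(g, sys, u)
  Asym <- (A + t(A)) / 2
  exp_eps <- c(Asym[1, 1], Asym[2, 2], Asym[3, 3],
               2 * Asym[1, 2], 2 * Asym[2, 3], 2 * Asym[3, 1])
  for (cc in 1:6) {
    expect_equal(sol$strain[, cc], rep(exp_eps[cc], length(sol$elem)),
                 tolerance = 1e-10)
  }
})

test_that("external work equals strain energy on a solved system", {
  g <- build_synthetic_model(small_params())
  sys <- assemble_stiffness(g)
  bc <- default_bc(g, axial_force = 0.5)
  u <- solve_elasticity(sys, bc, tol = 1e-12)
  rank_of <- node_rank_map(sys)
  f <- numeric(nrow(sys$K))
  lr <- rank_of[bc$loaded_nodes + 1]
  f[3 * lr + 3] <- bc$total_load[3] / length(lr)
  W_ext <- sum(f * u)
  W_int <- as.numeric(u %*% (sys$K %*% u))
  expect_equal(W_ext, W_int, tolerance = 1e-8)
})

test_that("strain invariants behave: rigid motion and hydrostatic states", {
  g <- block_grid(2, 2, 2)
  sys <- assemble_stiffness(g)
  nodes <- node_ijk(sys$active_nodes, g$shape)
  ## rigid translation: zero strain everywhere
  u <- rep(c(1e-6, -2e-6, 3e-6), length(sys$active_nodes))
  sol <- compute_strains(g, sys, u)
  expect_lt(max(abs(sol$strain)), 1e-15)
  expect_lt(max(sol$eqv_strain_micro), 1e-9)
  ## pure hydrostatic strain: deviatoric equivalent strain is zero
  xyz <- nodes * g$spacing
  uh <- as.vector(t(xyz * 1e-4))
  solh <- compute_strains(g, sys, uh)
  expect_equal(max(solh$eqv_strain_micro), 0, tolerance = 1e-9)
  expect_gt(max(abs(solh$strain)), 0)
})

test_that("nu-prime convention switch scales the equivalent strain", {
  g <- block_grid(3, 3, 3)
  sys <- assemble_stiffness(g)
  bc <- uniaxial_bc(g, 1e6)
  u <- solve_elasticity(sys, bc)
  nu <- default_materials()$CANCELLOUS$poisson_ratio
  s_mat <- compute_strains(g, sys, u, nu_prime = "material")
  s_half <- compute_strains(g, sys, u, nu_prime = "half")
  expect_equal(s_half$eqv_strain_micro * 1.5,
               s_mat$eqv_strain_micro * (1 + nu), tolerance = 1e-12)
})
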