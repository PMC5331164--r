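test_that("interface selection matches the exhaustive adjacency scan", {
  ## design region fully implant: empty selection
  ph <- array(3L, c(3, 3, 3))
  g <- voxel_grid(ph, design_mask = array(TRUE, c(3, 3, 3)))
  expect_length(interface_bone_elements(g), 0)
  ## single bone voxel surrounded by implant: selected
  ph[2, 2, 2] <- 1L
  g <- voxel_grid(ph, design_mask = array(TRUE, c(3, 3, 3)))
  expect_equal(interface_bone_elements(g), lin_index(1L, 1L, 1L, c(3L, 3L, 3L)))
  ## screw model trough vs brute force
  gm <- build_synthetic_model(small_params())
  expect_identical(interface_bone_elements(gm), oracle_interface_elements(gm))
  expect_gt(length(interface_bone_elements(gm)), 0)
})

test_that("physiological strains with uniform stress change nothing", {
  g <- build_synthetic_model(small_params())
  sol <- fake_solution(g, 800, stress = 1e6)   # PW, Gamma = 0 everywhere
  p <- remodeling_params(seed = 1)
  set.seed(p$seed)
  out <- apply_remodeling_step(g, sol, p)
  expect_equal(out$changes, 0)
  expect_identical(out$grid$phase, g$phase)
})

test_that("disuse strains convert the whole interface shell", {
  g <- build_synthetic_model(small_params())
  sol <- fake_solution(g, 10)    # all below eps_du: f* = -1 everywhere
  p <- remodeling_params(seed = 1)
  shell <- interface_bone_elements(g)
  set.seed(p$seed)
  out <- apply_remodeling_step(g, sol, p)
  expect_equal(out$changes, length(shell))
  expect_true(all(out$grid$phase[shell] == 3L))
  ## nothing outside the design region changed
  expect_identical(out$grid$phase[!g$design_mask], g$phase[!g$design_mask])
})

test_that("mixed-window sweep matches a scripted step-by-step replay", {
  ## a 5x1x5 slab: design column of bone flanked by implant on the left
  ph <- array(1L, c(5, 1, 5))
  ph[1, 1, ] <- 3L
  design <- array(FALSE, c(5, 1, 5))
  design[2:4, 1, ] <- TRUE
  design_ph <- ph; g <- voxel_grid(design_ph, design_mask = design)
  ## frozen strains: bottom row disuse, middle physiological, top overuse
  eps <- array(800, c(5, 1, 5))
  eps[, 1, 1] <- 50       # DW -> remove
  eps[, 1, 5] <- 3500     # OW -> add
  sol <- fake_solution(g, as.vector(eps)[g$phase != 0L], stress = 1e6)
  p <- remodeling_params(seed = 42, n_act = 1)
  set.seed(p$seed)
  out <- apply_remodeling_step(g, sol, p)

  ## independent replay of the stated sweep rules
  set.seed(p$seed)
  shp <- c(5L, 1L, 5L)
  iface <- oracle_interface_elements(g)
  fs <- numeric(length(iface))
  for (q in seq_along(iface)) {
    e <- eps[iface[q]]
    fs[q] <- if (e < 100) -1 else if (e >= 3000) 1 else 0  # Gamma uniform -> 0
  }
  draws <- stats::runif(length(fs))
  act <- ifelse(fs < 0 & draws < abs(fs), "REMOVE",
                ifelse(fs > 0 & draws < fs, "ADD", "NONE"))
  phase2 <- ph
  born <- rep(FALSE, prod(shp))
  rem <- iface[act == "REMOVE"]
  phase2[rem] <- 3L
  born[rem] <- TRUE
  for (id in iface[act == "ADD"]) {
    ijk <- arrayInd(id, shp)
    nbs <- integer(0)
    for (d in c(3, 1)) for (s in c(-1, 1)) {   # candidates, any order
      q2 <- ijk; q2[d] <- q2[d] + s
      if (q2[d] >= 1 && q2[d] <= shp[d]) {
        lid <- lin_index(q2[1] - 1L, q2[2] - 1L, q2[3] - 1L, shp)
        if (design[lid] && phase2[lid] == 3L && !born[lid]) nbs <- c(nbs, lid)
      }
    }
    if (length(nbs)) phase2[min(nbs)] <- 1L
  }
  expect_identical(out$grid$phase, phase2)
})

test_that("activation count repeats sweeps against the frozen solution", {
  g <- build_synthetic_model(small_params())
  sol <- fake_solution(g, 10)
  p2 <- remodeling_params(seed = 1, n_act = 2)
  set.seed(p2$seed)
  out2 <- apply_remodeling_step(g, sol, p2)
  ## two disuse sweeps peel two shells: equal to two single sweeps
  p1 <- remodeling_params(seed = 1, n_act = 1)
  set.seed(p1$seed)
  s1 <- apply_remodeling_step(g, sol, p1)
  set.seed(p1$seed)
  s2 <- apply_remodeling_step(s1$grid, sol, p1)
  expect_identical(out2$grid$phase, s2$grid$phase)
  expect_equal(out2$changes, s1$changes + s2$changes)
})

test_that("design loop conserves the design region and is reproducible", {
  p <- small_params()
  g <- build_synthetic_model(p)
  rp <- remodeling_params(seed = 7)
  bc <- default_bc(g, axial_force = 1.0)
  h1 <- run_design(g, bc, rp, max_iter = 3)
  h2 <- run_design(g, bc, rp, max_iter = 3)
  expect_identical(h1$snapshots, h2$snapshots)
  expect_equal(h1$table, h2$table)
  design_n <- sum(g$design_mask)
  for (s in h1$snapshots) {
    ## conservation: design voxels remain bone or implant, never void
    expect_true(all(s[g$design_mask] %in% c(1L, 3L)))
    ## immutability outside the design region
    expect_identical(s[!g$design_mask], g$phase[!g$design_mask])
  }
  ## history indices strictly increasing from 0, metrics attached
  expect_equal(h1$table$iteration, seq_len(nrow(h1$table)) - 1L)
  expect_true(all(h1$table$healthy_fraction >= 0 &
                  h1$table$healthy_fraction <= 1))
  ## a different seed gives a different trajectory (stochastic mode)
  h3 <- run_design(g, bc, remodeling_params(seed = 8), max_iter = 3)
  expect_false(identical(h1$snapshots, h3$snapshots))
})

test_that("max_iter = 0 records only the initial design with its metrics", {
  g <- build_synthetic_model(small_params())
  h <- run_design(g, default_bc(g, 1.0), remodeling_params(seed = 1),
                  max_iter = 0)
  expect_equal(nrow(h$table), 1)
  expect_equal(h$table$iteration, 0L)
  expect_identical(h$snapshots[[1]], g$phase)
  expect_gt(h$table$contact_area, 0)
})

test_that("zero load fills the design region shell by shell", {
  g <- build_synthetic_model(small_params())
  h <- run_design(g, default_bc(g, 0), remodeling_params(seed = 1),
                  max_iter = 20)
  tb <- h$table
  ## monotone filling: bone count strictly decreases to zero
  expect_true(all(diff(tb$design_bone) < 0))
  expect_equal(tb$design_bone[nrow(tb)], 0)
  ## converted counts equal the exhaustively computed interface shells
  cur <- g
  for (r in 2:nrow(tb)) {
    shell <- oracle_interface_elements(cur)
    expect_equal(tb$changes[r], length(shell))
    cur$phase[shell] <- 3L
  }
  ## the number of iterations is bounded by the trough thickness
  expect_lte(max(tb$iteration), max(g$shape))
})

test_that("tidy, glance and autoplot expose the history", {
  g <- build_synthetic_model(small_params())
  h <- run_design(g, default_bc(g, 1.0), remodeling_params(seed = 2),
                  max_iter = 2)
  tb <- tidy(h)
  expect_s3_class(tb, "tbl_df")
  expect_named(tb, c("iteration", "healthy_fraction", "contact_area",
                     "changes", "design_bone"))
  gl <- glance(h)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$best_healthy_fraction,
               max(tb$healthy_fraction))
  pl <- autoplot(h)
  expect_s3_class(pl, "ggplot")
})
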