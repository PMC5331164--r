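#' Interface bone elements of the healing chamber
#'
#' Design-region cancellous-bone voxels with at least one face-adjacent
#' (6-connectivity) implant voxel — the bone surface of the current
#' chamber, where the remodeling law acts.
#'
#' @param grid A [voxel_grid()].
#' @return Increasing 1-based linear element indices.
#' @export
interface_bone_elements <- function(grid) {
  impl_nb <- count_face_neighbors(grid$phase == PH_IMPLANT) > 0L
  which(grid$design_mask & grid$phase == PH_CANCELLOUS & impl_nb)
}

## inverse-distance-weighted neighbourhood mean of bone equivalent stress,
## evaluated for every bone voxel at once via lattice shifts. Returns the
## nonuniformity Gamma (0 where the neighbourhood mean is zero, e.g. an
## unloaded model, or where the element is not bone).
gamma_field <- function(grid, solution, params) {
  shp <- grid$shape
  h <- grid$spacing
  bone <- grid$phase == PH_CANCELLOUS | grid$phase == PH_CORTICAL
  sig <- array(0, shp)
  sig[solution$elem] <- solution$eqv_stress
  sigb <- array(0, shp); sigb[bone] <- sig[bone]
  boneN <- array(0, shp); boneN[bone] <- 1

  rad <- params$sensing_radius / h
  rmax <- floor(rad)
  wsum <- array(0, shp)
  ssum <- array(0, shp)
  for (di in -rmax:rmax) for (dj in -rmax:rmax) for (dk in -rmax:rmax) {
    d <- sqrt(di^2 + dj^2 + dk^2)
    if (d == 0 || d > rad) next
    w <- 1 / (d * h)
    sh <- shift_array(boneN, 1L, di)
    sh <- shift_array(sh, 2L, dj)
    sh <- shift_array(sh, 3L, dk)
    s2 <- shift_array(sigb, 1L, di)
    s2 <- shift_array(s2, 2L, dj)
    s2 <- shift_array(s2, 3L, dk)
    wsum <- wsum + w * sh
    ssum <- ssum + w * s2
  }
  gam <- array(0, shp)
  ok <- bone & wsum > 0
  m <- ssum[ok] / wsum[ok]
  g <- numeric(sum(ok))
  pos <- m > 0
  g[pos] <- (sig[ok][pos] - m[pos]) / m[pos]
  gam[ok] <- g
  gam
}

#' Apply one remodeling update to the design region
#'
#' Executes `n_act` decision sweeps against a frozen field solution. In a
#' sweep, every interface bone element gets an `f*` from its frozen
#' equivalent strain and nonuniformity, and an action is drawn; removals
#' (bone -> implant) are applied first, then each adding element converts
#' its lowest-linear-index face-adjacent design-region implant voxel back
#' to cancellous bone. Implant voxels created by a removal in the current
#' sweep are not eligible ADD targets in that sweep. Only design-region
#' voxels ever change.
#'
#' @param grid A [voxel_grid()].
#' @param solution The `field_solution` computed on `grid` (kept frozen for
#'   all sweeps).
#' @param params A [remodeling_params()] object. The caller owns the RNG
#'   state (see [run_design()]).
#' @return `list(grid = updated grid, changes = total voxel conversions)`.
#' @export
apply_remodeling_step <- function(grid, solution, params) {
  shp <- grid$shape
  nvox <- prod(shp)
  eps <- rep(NA_real_, nvox)
  eps[solution$elem] <- solution$eqv_strain_micro
  gam <- gamma_field(grid, solution, params)
  fg <- array(f_gamma(as.vector(gam), params$gamma_scale), shp)

  phase <- grid$phase
  changes <- 0L
  for (sweep in seq_len(params$n_act)) {
    g2 <- grid; g2$phase <- phase
    ids <- interface_bone_elements(g2)
    if (!length(ids)) break
    if (anyNA(eps[ids])) {
      stop("solution/grid mismatch: interface element without a strain",
           call. = FALSE)
    }
    fs <- remodeling_probability(eps[ids], fg[ids], params)
    act <- decide(fs, params)

    rem <- ids[act == "REMOVE"]
    phase[rem] <- PH_IMPLANT
    changes <- changes + length(rem)
    born_implant <- logical(nvox)
    born_implant[rem] <- TRUE

    for (id in ids[act == "ADD"]) {
      nb <- face_neighbor_ids(id, shp)
      cand <- nb[grid$design_mask[nb] & phase[nb] == PH_IMPLANT &
                 !born_implant[nb]]
      if (length(cand)) {
        tgt <- min(cand)
        phase[tgt] <- PH_CANCELLOUS
        changes <- changes + 1L
      }
    }
  }
  grid$phase <- phase
  list(grid = grid, changes = changes)
}

## 1-based linear ids of the up-to-6 face neighbours of one voxel
face_neighbor_ids <- function(id, shp) {
  ijk <- arrayInd(id, shp)
  i <- ijk[1]; j <- ijk[2]; k <- ijk[3]
  out <- integer(0)
  if (i > 1) out <- c(out, id - 1L)
  if (i < shp[1]) out <- c(out, id + 1L)
  if (j > 1) out <- c(out, id - shp[1])
  if (j < shp[2]) out <- c(out, id + shp[1])
  if (k > 1) out <- c(out, id - shp[1] * shp[2])
  if (k < shp[3]) out <- c(out, id + shp[1] * shp[2])
  out
}

#' Run the healing-chamber design loop
#'
#' Alternates finite-element solve, candidate evaluation and remodeling
#' update. Iteration 0 is the initial rectangular-trough design; every
#' subsequent iteration's geometry is a candidate, each evaluated with a
#' fresh solve on its own geometry. The loop stops at `max_iter`, when a
#' step changes nothing, or when the design region is entirely implant.
#'
#' @param grid The initial model from [build_synthetic_model()].
#' @param bc Boundary conditions; default [default_bc()].
#' @param params [remodeling_params()]; `params$seed` seeds the RNG.
#' @param eval_params [evaluation_params()].
#' @param max_iter Maximum number of remodeling iterations (>= 0).
#' @param materials Material set.
#' @param verbose Print one line per iteration.
#' @return A `design_history` object: a tibble of per-iteration metrics
#'   (`iteration`, `healthy_fraction`, `contact_area`, `changes`,
#'   `design_bone`) plus immutable phase snapshots.
#' @export
run_design <- function(grid, bc = default_bc(grid),
                       params = remodeling_params(),
                       eval_params = evaluation_params(),
                       max_iter = 20L,
                       materials = default_materials(),
                       verbose = FALSE) {
  validate_grid(grid)
  stopifnot(max_iter >= 0)
  set.seed(params$seed)
  design_n <- sum(grid$design_mask)

  rows <- list()
  snaps <- list()
  u_prev <- NULL
  iter <- 0L
  changes <- 0L
  repeat {
    sys <- assemble_stiffness(grid, materials)
    u <- tryCatch(
      solve_elasticity(sys, bc, u0 = u_prev),
      error = function(e) stop("FE solve failed at iteration ", iter, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    u_prev <- u
    sol <- compute_strains(grid, sys, u)
    hf <- healthy_fraction(grid, sol, eval_params)
    ca <- contact_area(grid)
    nbone <- sum(grid$phase[grid$design_mask] == PH_CANCELLOUS)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      iteration = iter, healthy_fraction = hf, contact_area = ca,
      changes = changes, design_bone = nbone)
    snaps[[length(snaps) + 1L]] <- grid$phase
    if (verbose) {
      message(sprintf("iter %d: healthy %.3f, contact %.3f mm2, changes %d, design bone %d",
                      iter, hf, ca * 1e6, changes, nbone))
    }
    if (iter >= max_iter || nbone == 0L) break
    step <- apply_remodeling_step(grid, sol, params)
    if (step$changes == 0L) break
    grid <- step$grid
    changes <- step$changes
    iter <- iter + 1L
  }

  structure(list(table = do.call(rbind, rows),
                 snapshots = snaps,
                 initial_grid = snaps[[1L]],
                 grid0 = {
                   g0 <- grid; g0$phase <- snaps[[1L]]; g0
                 },
                 shape = grid$shape,
                 spacing = grid$spacing,
                 design_mask = grid$design_mask,
                 roi_mask = grid$roi_mask,
                 params = params,
                 eval_params = eval_params),
            class = "design_history")
}

#' Reconstruct the voxel grid of one recorded candidate
#'
#' @param history A `design_history`.
#' @param iteration Iteration index present in the history.
#' @return A [voxel_grid()].
#' @export
snapshot_grid <- function(history, iteration) {
  pos <- match(iteration, history$table$iteration)
  if (is.na(pos)) stop("iteration ", iteration, " not in history", call. = FALSE)
  voxel_grid(history$snapshots[[pos]], spacing = history$spacing,
             design_mask = history$design_mask, roi_mask = history$roi_mask)
}

#' @export
print.design_history <- function(x, ...) {
  tb <- x$table
  cat(sprintf("<design_history> %d candidates (iterations %d..%d)\n",
              nrow(tb), min(tb$iteration), max(tb$iteration)))
  best <- select_best(x)
  cat(sprintf("  best: iteration %d, healthy fraction %.3f, contact area %.3f mm2\n",
              best$iteration, best$healthy_fraction, best$contact_area * 1e6))
  invisible(x)
}

#' Per-iteration candidate metrics
#'
#' @param x A `design_history`.
#' @param ... Unused.
#' @return The metrics tibble, one row per recorded candidate.
#' @method tidy design_history
#' @export
tidy.design_history <- function(x, ...) x$table

#' One-row summary of a design run
#'
#' @param x A `design_history`.
#' @param ... Unused.
#' @return A tibble with the iteration count, final design-region bone
#'   count, and the best candidate's index, healthy fraction and contact
#'   area together with the initial design's values.
#' @method glance design_history
#' @export
glance.design_history <- function(x, ...) {
  tb <- x$table
  best <- select_best(x)
  tibble::tibble(
    n_candidates = nrow(tb),
    final_design_bone = tb$design_bone[nrow(tb)],
    best_iteration = best$iteration,
    best_healthy_fraction = best$healthy_fraction,
    best_contact_area = best$contact_area,
    initial_healthy_fraction = tb$healthy_fraction[1L],
    initial_contact_area = tb$contact_area[1L]
  )
}

#' Plot the candidate metrics of a design run
#'
#' Healthy-bone fraction and bone-implant contact area per iteration, with
#' the selected best candidate marked.
#'
#' @param object A `design_history`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot design_history
#' @export
autoplot.design_history <- function(object, ...) {
  tb <- object$table
  best <- select_best(object)
  long <- rbind(
    data.frame(iteration = tb$iteration, value = tb$healthy_fraction,
               metric = "healthy bone fraction"),
    data.frame(iteration = tb$iteration, value = tb$contact_area * 1e6,
               metric = "contact area (mm²)")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = best$iteration, linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "design iteration", y = NULL,
                  title = "Healing-chamber design candidates",
                  subtitle = sprintf("best candidate: iteration %d",
                                     best$iteration)) +
    ggplot2::theme_minimal()
}
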