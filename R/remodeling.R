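#' Remodeling parameters
#'
#' The Mechanostat-style strain windows and the stochastic decision
#' machinery. Below `eps_du` (disuse window) resorption is certain
#' (`f* = -1`); at or above `eps_ol` (overuse window) formation is certain
#' (`f* = +1`); inside the physiological window `[eps_pl, eps_pu)` the
#' outcome is governed by the local stress nonuniformity through
#' `f(Gamma)`; the two intermediate ranges blend linearly.
#'
#' The numeric defaults (100 / 400 / 1500 / 3000 microstrain) place the
#' physiological window on the 400-1500 microstrain healthy-bone range and
#' are substitutes for values the surface-remodeling literature does not
#' pin down uniquely; all four are plain arguments so users can match a
#' specific source.
#'
#' @param eps_du,eps_pl,eps_pu,eps_ol Window thresholds in microstrain;
#'   must satisfy `0 < eps_du < eps_pl < eps_pu < eps_ol`.
#' @param sensing_radius Radius (m) of the stress-sensing neighbourhood.
#' @param gamma_scale Nonuniformity scale at which `f(Gamma)` saturates.
#' @param n_act Activation count: decision sweeps per mechanical solve.
#' @param seed RNG seed used by [run_design()].
#' @param decision_mode `"stochastic"` (draw with probability `|f*|`) or
#'   `"deterministic"` (act iff `|f*| >= 0.5`).
#' @return A `remodeling_params` object.
#' @export
remodeling_params <- function(eps_du = 100, eps_pl = 400,
                              eps_pu = 1500, eps_ol = 3000,
                              sensing_radius = 150e-6,
                              gamma_scale = 1,
                              n_act = 1L,
                              seed = 1L,
                              decision_mode = c("stochastic", "deterministic")) {
  decision_mode <- match.arg(decision_mode)
  if (!(0 < eps_du && eps_du < eps_pl && eps_pl < eps_pu && eps_pu < eps_ol)) {
    stop("thresholds must satisfy 0 < eps_du < eps_pl < eps_pu < eps_ol",
         call. = FALSE)
  }
  stopifnot(sensing_radius > 0, gamma_scale > 0, n_act >= 1)
  structure(list(eps_du = eps_du, eps_pl = eps_pl,
                 eps_pu = eps_pu, eps_ol = eps_ol,
                 sensing_radius = sensing_radius,
                 gamma_scale = gamma_scale,
                 n_act = as.integer(n_act),
                 seed = as.integer(seed),
                 decision_mode = decision_mode),
            class = "remodeling_params")
}

#' Local stress nonuniformity
#'
#' Relative deviation of an element's equivalent stress from the
#' inverse-distance-weighted mean of the bone stresses in its sensing
#' neighbourhood (the element itself excluded):
#' `Gamma = (sigma_c - <sigma>_w) / <sigma>_w`.
#'
#' @param sigma_c Equivalent stress of the element (Pa).
#' @param neighbor_stresses Stresses of bone elements within the sensing
#'   radius (Pa).
#' @param distances Matching center-to-center distances (m), all > 0.
#' @return The dimensionless nonuniformity.
#' @export
nonuniformity <- function(sigma_c, neighbor_stresses, distances) {
  if (length(neighbor_stresses) == 0) {
    stop("empty sensing neighbourhood (isolated element)", call. = FALSE)
  }
  stopifnot(length(neighbor_stresses) == length(distances), all(distances > 0))
  w <- 1 / distances
  m <- sum(w * neighbor_stresses) / sum(w)
  if (m <= 0) stop("neighbourhood mean stress is zero", call. = FALSE)
  (sigma_c - m) / m
}

#' Resorption/formation probability from nonuniformity
#'
#' Piecewise-linear saturation: `f = clamp(Gamma / Gamma_u, -1, 1)`.
#' Positive nonuniformity (element more stressed than its surroundings)
#' favours formation, negative favours resorption.
#'
#' @param gamma Nonuniformity value(s).
#' @param gamma_scale Saturation scale `Gamma_u > 0`.
#' @return Value(s) in `[-1, 1]`.
#' @export
f_gamma <- function(gamma, gamma_scale) {
  stopifnot(gamma_scale > 0)
  pmin(pmax(gamma / gamma_scale, -1), 1)
}

#' Remodeling probability f*
#'
#' The five-branch window law: `-1` in the disuse window, a linear blend
#' from `-1` to `f(Gamma)` over `[eps_du, eps_pl)`, `f(Gamma)` in the
#' physiological window, a linear blend from `f(Gamma)` to `+1` over
#' `[eps_pu, eps_ol)`, and `+1` in the overuse window. Negative values are
#' resorption (element removal) probabilities, positive values formation.
#'
#' @param eps_c Equivalent strain(s) in microstrain.
#' @param f_g Value(s) of `f(Gamma)` for the same element(s); recycled.
#' @param params A [remodeling_params()] object.
#' @return `f*` value(s) in `[-1, 1]`, vectorized over `eps_c`.
#' @export
remodeling_probability <- function(eps_c, f_g, params) {
  stopifnot(inherits(params, "remodeling_params"))
  n <- length(eps_c)
  f_g <- rep_len(f_g, n)
  out <- numeric(n)
  du <- params$eps_du; pl <- params$eps_pl
  pu <- params$eps_pu; ol <- params$eps_ol

  low <- eps_c < du
  blo <- eps_c >= du & eps_c < pl
  mid <- eps_c >= pl & eps_c < pu
  bhi <- eps_c >= pu & eps_c < ol
  high <- eps_c >= ol

  out[low] <- -1
  t <- (eps_c[blo] - du) / (pl - du)
  out[blo] <- -(1 - t) + t * f_g[blo]
  out[mid] <- f_g[mid]
  s <- (eps_c[bhi] - pu) / (ol - pu)
  out[bhi] <- (1 - s) * f_g[bhi] + s
  out[high] <- 1
  out
}

#' Turn f* values into remodeling actions
#'
#' Stochastic mode draws one uniform variate per element (in input order)
#' and acts with probability `|f*|`; deterministic mode acts iff
#' `|f*| >= 0.5`. Negative `f*` yields `"REMOVE"`, positive `"ADD"`.
#'
#' @param f_star Values in `[-1, 1]`.
#' @param params A [remodeling_params()]; `decision_mode` selects the rule.
#' @return Character vector of `"ADD"`, `"REMOVE"`, `"NONE"`.
#' @export
decide <- function(f_star, params) {
  if (any(f_star < -1 - 1e-12) || any(f_star > 1 + 1e-12)) {
    stop("f* out of [-1, 1]", call. = FALSE)
  }
  act <- if (params$decision_mode == "stochastic") {
    stats::runif(length(f_star)) < abs(f_star)
  } else {
    abs(f_star) >= 0.5
  }
  out <- rep("NONE", length(f_star))
  out[act & f_star < 0] <- "REMOVE"
  out[act & f_star > 0] <- "ADD"
  out
}
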