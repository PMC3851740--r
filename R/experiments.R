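## defaults shared by the simulation drivers
default_sim_config <- function() {
  list(psi_leaf = -2.0, psi_soil = 0, WUE = 250, target_dP = 0.7,
       e_leaf = 1e-3,    # reference transpiration per leaf area, mol m-2 s-1
       temperature = 293.15, c_sink = 300)
}

## reference scales for one tree: xylem scale from the leaf-area based
## transpiration under the isohydric rule, phloem scale from the turgor
## calibration with root unloading.
reference_scales <- function(tree, unloading = "root", n_nodes = 81L,
                             config = default_sim_config()) {
  grid <- transport_grid(tree, n_nodes = n_nodes)
  E <- leaf_area(tree) * config$e_leaf * MOLAR_MASS_WATER / 1000
  K_x <- calibrate_xylem_scale(grid, E, psi_leaf = config$psi_leaf,
                               psi_soil = config$psi_soil)
  bnd <- transport_boundary(E, loading_from_transpiration(E, config$WUE),
                            unloading = unloading,
                            psi_soil = config$psi_soil,
                            temperature = config$temperature,
                            c_sink = config$c_sink)
  K_p <- calibrate_phloem_scale(grid, bnd, K_x, target_dP = config$target_dP)
  list(grid = grid, boundary = bnd, K_x = K_x, K_p = K_p, E = E,
       config = config)
}

#' Axial pressure and concentration gradients (simulation 1)
#'
#' Solves the calibrated steady state for one tree and summarises where
#' the xylem water-potential drop and the phloem turgor drop concentrate
#' along the path.
#'
#' @param tree A [tree_spec()] object (the worked example is a 10 m pine
#'   with 2 cm maximum sapwood depth).
#' @param unloading `"root"` or `"uniform"`.
#' @param n_nodes Grid resolution.
#' @param config Simulation constants, see `default_sim_config`
#'   (leaf water potential -2 MPa, WUE 250, turgor target 0.7 MPa).
#' @return List of class `axial_experiment`: the `transport_state`, plus
#'   `profiles` (normalised to the basal value of each quantity) and
#'   summary scalars `turgor_drop_basal_fraction` (fraction of the total
#'   phloem turgor drop occurring in the basal half of the path),
#'   `xylem_gradient_apical`, `xylem_gradient_basal` (water-potential drop
#'   per metre over the apical/basal 10% of the path).
#' @export
run_axial_profile_experiment <- function(tree, unloading = "root",
                                         n_nodes = 121L,
                                         config = default_sim_config()) {
  sc <- reference_scales(tree, unloading = unloading, n_nodes = n_nodes,
                         config = config)
  st <- solve_steady_state(sc$grid, sc$boundary, sc$K_x, sc$K_p)
  nd <- st$nodes
  nb <- nrow(nd)
  profiles <- data.frame(x = nd$x,
                         psi_rel = nd$psi_x / nd$psi_x[nb],
                         P_rel = nd$P_p / nd$P_p[nb],
                         c_rel = nd$c / nd$c[nb])
  ## path-position helpers (x runs apex -> base)
  val_at <- function(v, xq) stats::approx(nd$x, v, xout = xq)$y
  x_mid <- (tree$L0 + tree$L) / 2
  dP_tot <- nd$P_p[1] - nd$P_p[nb]
  basal_frac <- (val_at(nd$P_p, x_mid) - nd$P_p[nb]) / dP_tot
  span <- tree$L - tree$L0
  x_ap <- tree$L0 + 0.1 * span
  x_ba <- tree$L - 0.1 * span
  grad_apical <- (val_at(nd$psi_x, x_ap) - nd$psi_x[1]) / (0.1 * span)
  grad_basal <- (nd$psi_x[nb] - val_at(nd$psi_x, x_ba)) / (0.1 * span)
  structure(list(state = st, profiles = profiles,
                 turgor_drop_basal_fraction = basal_frac,
                 xylem_gradient_apical = grad_apical,
                 xylem_gradient_basal = grad_basal,
                 scales = list(K_x = sc$K_x, K_p = sc$K_p), tree = tree),
            class = "axial_experiment")
}

#' Optimal axial allocation of phloem tissue (simulation 2)
#'
#' Redistributes the summed phloem cross-section as `A_p_tot(x)
#' proportional to x^theta` at fixed whole-tree phloem volume, re-solves
#' the calibrated steady state for each `theta` on a coarse grid, and
#' refines the turgor-minimising exponent by golden-section search.
#'
#' @param tree A [tree_spec()] object.
#' @param unloading `"root"` or `"uniform"`.
#' @param theta_grid Coarse scan grid; must span at least `[-1, 0.5]`.
#' @param refine_tol Golden-section half-width stopping tolerance on theta.
#' @param n_nodes Grid resolution.
#' @param config Simulation constants.
#' @param scales Optional precomputed `list(K_x =, K_p =)` to bypass
#'   calibration (used to check scale invariance of the optimum).
#' @return List of class `allocation_search`: `theta_opt`, `dP_opt`,
#'   `grid` (data.frame theta/dP/converged), `volume_residual` (max
#'   relative deviation of the reallocated phloem volume from the
#'   reference).
#' @export
optimize_phloem_allocation <- function(tree, unloading = "root",
                                       theta_grid = seq(-1, 0.5,
                                                        length.out = 13L),
                                       refine_tol = 0.005, n_nodes = 81L,
                                       config = default_sim_config(),
                                       scales = NULL) {
  if (min(theta_grid) > -1 || max(theta_grid) < 0.5)
    stop("theta_grid must span at least [-1, 0.5]")
  sc <- reference_scales(tree, unloading = unloading, n_nodes = n_nodes,
                         config = config)
  if (!is.null(scales)) { sc$K_x <- scales$K_x; sc$K_p <- scales$K_p }
  V_ref <- sc$grid$V_p
  vol_res <- 0
  dP_of <- function(theta) {
    g <- transport_grid(tree, n_nodes = n_nodes, theta = theta)
    vol_res <<- max(vol_res, abs(g$V_p / V_ref - 1))
    tryCatch(solve_steady_state(g, sc$boundary, sc$K_x, sc$K_p)$dP,
             transport_nonconvergence = function(e) NA_real_)
  }
  dP <- vapply(theta_grid, dP_of, numeric(1))
  if (all(is.na(dP))) stop("no theta on the grid admits a steady state")
  i <- which.min(dP)
  lo <- theta_grid[max(i - 1L, 1L)]
  hi <- theta_grid[min(i + 1L, length(theta_grid))]
  ## golden-section refinement of the unimodal minimum
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- dP_of(x1); f2 <- dP_of(x2)
  while ((b - a) > refine_tol) {
    if (is.na(f1)) { a <- x1 }
    if (is.na(f2)) { b <- x2 }
    if (!is.na(f1) && !is.na(f2)) {
      if (f1 < f2) { b <- x2; x2 <- x1; f2 <- f1
                     x1 <- b - gr * (b - a); f1 <- dP_of(x1) }
      else { a <- x1; x1 <- x2; f1 <- f2
             x2 <- a + gr * (b - a); f2 <- dP_of(x2) }
    } else {
      x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
      f1 <- dP_of(x1); f2 <- dP_of(x2)
    }
  }
  theta_opt <- (a + b) / 2
  structure(list(theta_opt = theta_opt, dP_opt = dP_of(theta_opt),
                 grid = data.frame(theta = theta_grid, dP = dP,
                                   converged = !is.na(dP)),
                 volume_residual = vol_res, unloading = unloading),
            class = "allocation_search")
}

#' @export
print.allocation_search <- function(x, ...) {
  cat(sprintf(
    "optimal phloem allocation (%s unloading): A_p_tot ~ x^%.3f (dP = %.4g MPa)\n",
    x$unloading, x$theta_opt, x$dP_opt))
  invisible(x)
}

#' Turgor difference versus tree height (simulation 3)
#'
#' For each height, sets the transpiration by the isohydric rule (leaf
#' water potential fixed), the photosynthesis/loading by the water-use
#' efficiency, and the conductances by the structural scaling with the
#' absolute scales calibrated once on a reference tree; then solves for
#' the leaf-to-root turgor difference. Non-converging heights (the phloem
#' cannot transport the assimilated sugars) and heights where gravity
#' makes the isohydric transpiration nonpositive are flagged, not dropped.
#'
#' @param params A [scaling_params()] object.
#' @param heights Tree heights to sweep (m).
#' @param r_sw_max Heartwood scenario of the tree family.
#' @param unloading `"root"` or `"uniform"`.
#' @param kp_multipliers Scenario multipliers on the calibrated phloem
#'   conductance scale.
#' @param reference_L Height of the calibration tree (m).
#' @param n_nodes Grid resolution.
#' @param config Simulation constants.
#' @return data.frame of class `height_sweep`: `L`, `kp_mult`, `E`
#'   (m^3 s^-1), `A_co2` (mol CO2 s^-1, equal to `E/WUE` in moles),
#'   `loading`, `dP` (MPa, NA when not converged), `converged`,
#'   `feasible`, `scenario`, `unloading`.
#' @export
run_height_sweep <- function(params,
                             heights = c(2, 3, 5, 7, 10, 15, 20, 30, 40, 50),
                             r_sw_max = 0.02, unloading = "root",
                             kp_multipliers = c(0.5, 1, 2),
                             reference_L = 10, n_nodes = 61L,
                             config = default_sim_config()) {
  ref_tree <- tree_spec(params, L = reference_L, r_sw_max = r_sw_max)
  sc <- reference_scales(ref_tree, unloading = "root", n_nodes = n_nodes,
                         config = config)
  rows <- list()
  for (L in heights) {
    tr <- tree_spec(params, L = L, r_sw_max = r_sw_max)
    g <- transport_grid(tr, n_nodes = n_nodes)
    E <- isohydric_transpiration(g, sc$K_x, psi_leaf = config$psi_leaf,
                                 psi_soil = config$psi_soil)
    feasible <- E > 0
    for (m in kp_multipliers) {
      if (!feasible) {
        rows[[length(rows) + 1L]] <-
          data.frame(L = L, kp_mult = m, E = NA_real_, A_co2 = NA_real_,
                     loading = NA_real_, dP = NA_real_, converged = FALSE,
                     feasible = FALSE)
        next
      }
      loading <- loading_from_transpiration(E, config$WUE)
      bnd <- transport_boundary(E, loading, unloading = unloading,
                                psi_soil = config$psi_soil,
                                temperature = config$temperature,
                                c_sink = config$c_sink)
      dP <- tryCatch(solve_steady_state(g, bnd, sc$K_x, sc$K_p * m)$dP,
                     transport_nonconvergence = function(e) NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(L = L, kp_mult = m, E = E,
                   A_co2 = E * WATER_MOLARITY / config$WUE,
                   loading = loading, dP = dP, converged = !is.na(dP),
                   feasible = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  out$scenario <- if (is.finite(r_sw_max))
    sprintf("sapwood depth %.3g m", r_sw_max) else "no heartwood"
  out$unloading <- unloading
  class(out) <- c("height_sweep", "data.frame")
  out
}
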