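## gravitational pressure gradient of water, MPa per metre of height
RHO_G <- 1000 * 9.81 / 1e6
## molar volume bookkeeping
MOLAR_MASS_WATER <- 0.018      # kg/mol
WATER_MOLARITY <- 1000 / 0.018 # mol/m3

#' Dynamic viscosity of pure water
#'
#' Empirical correlation `2.414e-5 * 10^(247.8/(T - 140))` Pa s, accurate
#' to ~1% between 0 and 70 degrees C.
#'
#' @param temperature Temperature (K).
#' @return Viscosity (Pa s).
#' @export
viscosity_water <- function(temperature = 293.15) {
  2.414e-5 * 10^(247.8 / (temperature - 140))
}

#' Viscosity of sucrose solution
#'
#' Concentration-dependent phloem sap viscosity: an exponential-in-mass-
#' fraction correlation for aqueous sucrose,
#' `eta = eta_water(T) * exp(a * b * w / (1 - b * w))` with
#' `w = M*c / (1000 + M*c)` the sucrose mass fraction. Strictly increasing
#' and convex in `c`, equal to the water viscosity at `c = 0`, and rising
#' steeply at high concentrations — the feedback that can choke phloem
#' transport.
#'
#' @param c Sucrose concentration (mol m^-3), nonnegative.
#' @param temperature Temperature (K).
#' @param a,b Correlation parameters.
#' @param M_sucrose Sucrose molar mass (kg/mol).
#' @return Viscosity (Pa s).
#' @examples
#' sucrose_viscosity(0) / viscosity_water() # 1
#' @export
sucrose_viscosity <- function(c, temperature = 293.15, a = 4.68, b = 0.956,
                              M_sucrose = 0.342) {
  if (any(c < 0)) stop("concentration must be nonnegative")
  w <- M_sucrose * c / (1000 + M_sucrose * c)
  viscosity_water(temperature) * exp(a * b * w / (1 - b * w))
}

#' Discretised transport path for the Munch model
#'
#' Builds the node/segment geometry and the relative conductance profiles
#' for a tree's root-to-apex transport path. Nodes are log-spaced in
#' distance from the apex over `[L0, L]`; per-segment relative xylem and
#' phloem conductivities come from [axial_profiles()] evaluated at segment
#' midpoints. The summed phloem cross-section can be redistributed as
#' `A_p_tot(x)` proportional to `x^theta`, rescaled so the whole-tree
#' phloem volume is conserved; the per-area conduit properties (taper,
#' conduit fraction) keep their baseline profiles.
#'
#' @param tree A [tree_spec()] object.
#' @param n_nodes Number of nodes (>= 9).
#' @param theta Optional reallocation exponent for the phloem
#'   cross-section; `NULL` keeps the measured allometric profile.
#' @return List of class `transport_grid`: node vectors `x`, `z`, segment
#'   vectors `x_mid`, `ds`, `dz`, `k_x_rel`, `k_p_rel`, `A_p_tot`, scalars
#'   `V_p` (m^3), `K_x_tot_rel`, `K_p_tot_rel`, and `tree`.
#' @export
transport_grid <- function(tree, n_nodes = 81L, theta = NULL) {
  stopifnot(inherits(tree, "tree_spec"))
  if (n_nodes < 2L) stop("n_nodes must be at least 2")
  x <- exp(seq(log(tree$L0), log(tree$L), length.out = n_nodes)) # apex->base
  z <- tree$L - x
  xm <- sqrt(x[-1] * x[-n_nodes])
  ds <- diff(x)
  dz <- -diff(z)            # height gained going up each segment (positive)
  p <- tree$params
  d <- diameter_at_distance(xm, p)
  sw <- sapwood_partition(d, tree)
  n <- furcation_number(xm, tree)
  k_x <- n * sw$A_sw * prop_at(d, p, "rho_c_x") * prop_at(d, p, "r_x")^2
  A_p_base <- n * prop_at(d, p, "A_p")
  V_ref <- sum(A_p_base * ds)
  A_p <- if (is.null(theta)) A_p_base else {
    shape <- xm^theta
    shape * V_ref / sum(shape * ds)
  }
  k_p <- A_p * prop_at(d, p, "rho_c_p") * prop_at(d, p, "r_p")^2
  structure(list(x = x, z = z, x_mid = xm, ds = ds, dz = dz,
                 k_x_rel = k_x, k_p_rel = k_p, A_p_tot = A_p,
                 V_p = V_ref * 1e-6,
                 K_x_tot_rel = 1 / sum(ds / k_x),
                 K_p_tot_rel = 1 / sum(ds / k_p),
                 theta = theta, tree = tree),
            class = "transport_grid")
}

#' Boundary conditions for the steady-state transport model
#'
#' @param E Transpiration rate (m^3 water s^-1), extracted at the apex.
#' @param loading_rate Sucrose loading into the phloem at the apex
#'   (mol s^-1); at steady state total unloading equals it.
#' @param unloading `"root"` (all unloading at the base) or `"uniform"`
#'   (equal unloading per metre of path).
#' @param psi_soil Soil water potential (MPa).
#' @param temperature Temperature (K).
#' @param c_sink Sugar concentration at the unloading end of the path
#'   (mol m^-3). The model prescribes loading/unloading *rates*, which fixes
#'   all concentration differences but not the absolute level; the level is
#'   pinned at the sink, where unloading kinetics would set it.
#' @param viscosity Function `(c, temperature) -> Pa s` for phloem sap.
#' @param gravity Logical; include the hydrostatic gradient.
#' @return List of class `transport_boundary`.
#' @export
transport_boundary <- function(E, loading_rate,
                               unloading = c("root", "uniform"),
                               psi_soil = 0, temperature = 293.15,
                               c_sink = 300, viscosity = sucrose_viscosity,
                               gravity = TRUE) {
  unloading <- match.arg(unloading)
  if (E < 0 || loading_rate < 0) stop("E and loading_rate must be >= 0")
  if (c_sink <= 0) stop("c_sink must be positive")
  structure(list(E = E, loading_rate = loading_rate, unloading = unloading,
                 psi_soil = psi_soil, temperature = temperature,
                 c_sink = c_sink, viscosity = viscosity, gravity = gravity),
            class = "transport_boundary")
}

## xylem water potentials at the nodes, apex last? (x is apex->base; node 1
## is the apex). All transpiration leaves at the apex, so every segment
## carries flux E upward.
xylem_potentials <- function(grid, boundary, K_x_scale) {
  n <- length(grid$x)
  rg <- if (boundary$gravity) RHO_G else 0
  psi <- numeric(n)
  psi[n] <- boundary$psi_soil
  for (j in (n - 1L):1L) {
    K_seg <- K_x_scale * grid$k_x_rel[j] / grid$ds[j]
    psi[j] <- psi[j + 1L] - boundary$E / K_seg - rg * grid$dz[j]
  }
  psi
}

## sugar flux carried by each segment (positive toward the base)
segment_sugar_flux <- function(grid, boundary) {
  n_seg <- length(grid$ds)
  if (boundary$unloading == "root") rep(boundary$loading_rate, n_seg)
  else {
    s <- c(0, cumsum(grid$ds))
    s_mid <- (s[-1] + s[-length(s)]) / 2
    boundary$loading_rate * (1 - s_mid / s[length(s)])
  }
}

#' Solve the coupled xylem-phloem steady state
#'
#' Munch pressure flow on a discretised path: xylem potentials follow from
#' the series xylem resistances with all transpiration extracted at the
#' apex; phloem turgor couples to the xylem through water-potential
#' equilibrium at every node (`P = psi_x + R T c`, van 't Hoff); phloem
#' volume flow down each segment is `K_p_seg * (dP + rho g dz) / eta_rel(c)`
#' (gravity aids downward phloem flow) and carries the known steady-state
#' sugar flux with the segment-midpoint concentration. Concentrations are solved
#' segment by segment from the sink upward; each segment's balance is a
#' scalar root-find, taken on the physical (low-concentration) branch. If
#' the viscosity build-up makes a segment's maximum transportable sugar
#' flux fall below the required flux, no steady state exists and a
#' diagnostic `transport_nonconvergence` error reports the failing
#' position and concentration.
#'
#' @param grid A [transport_grid()].
#' @param boundary A [transport_boundary()].
#' @param K_x_scale,K_p_scale Absolute conductance scales
#'   (m^3 s^-1 MPa^-1 per relative-conductivity unit per metre).
#' @param tol Root-finding tolerance on nodal concentrations (mol m^-3).
#' @return Object of class `transport_state`: data.frame `nodes` (`x`,
#'   `z`, `psi_x`, `P_p`, `c`), data.frame `segments` (`x_mid`,
#'   `F_sugar`, `Q_water`), scalars `dP` (leaf minus root turgor, MPa),
#'   `residual` (max relative momentum residual), `converged`.
#' @export
solve_steady_state <- function(grid, boundary, K_x_scale, K_p_scale,
                               tol = 1e-11) {
  stopifnot(inherits(grid, "transport_grid"),
            inherits(boundary, "transport_boundary"))
  n <- length(grid$x)
  RT <- 8.314 * boundary$temperature / 1e6  # MPa per mol/m3
  rg <- if (boundary$gravity) RHO_G else 0
  eta_w <- viscosity_water(boundary$temperature)
  eta_rel <- function(cc) boundary$viscosity(cc, boundary$temperature) / eta_w
  psi <- xylem_potentials(grid, boundary, K_x_scale)
  Fseg <- segment_sugar_flux(grid, boundary)
  cc <- numeric(n)
  cc[n] <- boundary$c_sink
  for (j in (n - 1L):1L) {
    cl <- cc[j + 1L]
    dpsi <- psi[j] - psi[j + 1L]
    G <- K_p_scale * grid$k_p_rel[j] / grid$ds[j]
    drive <- function(cu) dpsi + RT * (cu - cl) + rg * grid$dz[j]
    h <- function(cu) G * drive(cu) * (cu + cl) / 2 /
      eta_rel((cu + cl) / 2) - Fseg[j]
    if (Fseg[j] <= 0) {
      cc[j] <- cl - (dpsi + rg * grid$dz[j]) / RT
      next
    }
    ## h rises from <=0, peaks, then collapses as viscosity explodes;
    ## the physical solution is the first (lowest-concentration) root.
    peak <- stats::optimize(h, c(cl, 5e4), maximum = TRUE)
    if (peak$objective < 0) {
      cond <- simpleError(sprintf(
        "no steady state: viscosity limits sugar flux at x = %.3g m (flux deficit %.3g mol/s, c = %.4g mol/m3)",
        grid$x_mid[j], -peak$objective, peak$maximum))
      cond$x <- grid$x_mid[j]
      cond$residual <- -peak$objective
      cond$max_c <- max(cc[(j + 1L):n])
      class(cond) <- c("transport_nonconvergence", class(cond))
      stop(cond)
    }
    cc[j] <- stats::uniroot(h, c(cl, peak$maximum), tol = tol)$root
  }
  P <- psi + RT * cc
  c_mid <- (cc[-n] + cc[-1]) / 2
  Q <- ifelse(Fseg > 0, Fseg / c_mid, 0)
  G <- K_p_scale * grid$k_p_rel / grid$ds
  drive_all <- (P[-n] - P[-1]) + rg * grid$dz
  flux_chk <- G * drive_all * c_mid / eta_rel(c_mid)
  residual <- if (boundary$loading_rate > 0)
    max(abs(flux_chk - Fseg)) / boundary$loading_rate else max(abs(flux_chk))
  structure(list(nodes = data.frame(x = grid$x, z = grid$z, psi_x = psi,
                                    P_p = P, c = cc),
                 segments = data.frame(x_mid = grid$x_mid, F_sugar = Fseg,
                                       Q_water = Q),
                 dP = P[1] - P[n], residual = residual, converged = TRUE,
                 boundary = boundary),
            class = "transport_state")
}

#' @export
print.transport_state <- function(x, ...) {
  cat(sprintf(
    "steady state: %d nodes, leaf-root turgor difference %.4g MPa,\n  c %.4g -> %.4g mol/m3, momentum residual %.2g\n",
    nrow(x$nodes), x$dP, x$nodes$c[1], x$nodes$c[nrow(x$nodes)],
    x$residual))
  invisible(x)
}

#' Leaf area of a tree (pipe model)
#'
#' Leaf area proportional to basal sapwood cross-sectional area.
#'
#' @param tree A [tree_spec()] object.
#' @return Leaf area (m^2).
#' @export
leaf_area <- function(tree) {
  d_base <- diameter_at_distance(tree$L, tree$params)
  sapwood_partition(d_base, tree)$A_sw * 1e-6 * tree$params$C_ls
}

#' Absolute xylem conductance scale from a reference transpiration
#'
#' Chooses the absolute scale of the relative xylem conductivity profile so
#' that the tree transpires `E_target` while holding the leaf water
#' potential at `psi_leaf` (isohydric behaviour):
#' `E = K_x_tot * (psi_soil - psi_leaf - rho g z_apex)`.
#'
#' @param grid A [transport_grid()].
#' @param E_target Transpiration (m^3 s^-1).
#' @param psi_leaf,psi_soil Water potentials (MPa).
#' @param gravity Include the gravitational head.
#' @return Scale factor (m^3 s^-1 MPa^-1 per relative unit).
#' @export
calibrate_xylem_scale <- function(grid, E_target, psi_leaf = -2,
                                  psi_soil = 0, gravity = TRUE) {
  z_apex <- grid$z[1]
  head <- psi_soil - psi_leaf - (if (gravity) RHO_G else 0) * z_apex
  if (head <= 0) stop("leaf water potential unreachable: gravity exceeds it")
  E_target / (head * grid$K_x_tot_rel)
}

#' Isohydric transpiration rate for a grid and xylem scale
#'
#' @inheritParams calibrate_xylem_scale
#' @param K_x_scale Absolute xylem conductance scale.
#' @return Transpiration (m^3 s^-1); zero or negative means the height is
#'   infeasible under the isohydric rule.
#' @export
isohydric_transpiration <- function(grid, K_x_scale, psi_leaf = -2,
                                    psi_soil = 0, gravity = TRUE) {
  z_apex <- grid$z[1]
  head <- psi_soil - psi_leaf - (if (gravity) RHO_G else 0) * z_apex
  K_x_scale * grid$K_x_tot_rel * head
}

#' Phloem loading rate implied by transpiration
#'
#' Photosynthesis is proportional to transpiration through the water-use
#' efficiency (mol H2O per mol CO2); fixed carbon is exported as sucrose
#' (12 CO2 per sucrose).
#'
#' @param E Transpiration (m^3 s^-1).
#' @param WUE Water-use efficiency (mol H2O / mol CO2).
#' @param co2_per_sucrose Carbons per sucrose molecule.
#' @return Sucrose loading rate (mol s^-1).
#' @export
loading_from_transpiration <- function(E, WUE = 250, co2_per_sucrose = 12) {
  E * WATER_MOLARITY / WUE / co2_per_sucrose
}

#' Calibrate the absolute phloem conductance scale
#'
#' Finds the multiplicative phloem conductance scale at which the
#' steady-state leaf-to-root turgor difference equals `target_dP`
#' (bisection on the log scale). The turgor difference decreases
#' monotonically with the scale; below a critical scale the viscosity
#' build-up prevents any steady state, which bounds the search from below.
#'
#' @param grid A [transport_grid()].
#' @param boundary A [transport_boundary()].
#' @param K_x_scale Absolute xylem conductance scale.
#' @param target_dP Target leaf-root turgor difference (MPa).
#' @param tol Tolerance on the achieved difference (MPa).
#' @param bracket Log10 search bracket for the scale.
#' @return The phloem conductance scale (same units as `K_x_scale`).
#' @export
calibrate_phloem_scale <- function(grid, boundary, K_x_scale,
                                   target_dP = 0.7, tol = 1e-3,
                                   bracket = c(-18, -2)) {
  dP_at <- function(lg) {
    tryCatch(solve_steady_state(grid, boundary, K_x_scale, 10^lg)$dP,
             transport_nonconvergence = function(e) NA_real_)
  }
  lo <- bracket[1]
  while (is.na(dP_at(lo)) && lo < bracket[2]) lo <- lo + 0.5
  if (lo >= bracket[2]) stop("no solvable phloem scale in the bracket")
  v_lo <- dP_at(lo); v_hi <- dP_at(bracket[2])
  if (v_lo < target_dP || v_hi > target_dP)
    stop(sprintf(
      "target turgor difference %.3g MPa unreachable (attainable range %.3g..%.3g)",
      target_dP, v_hi, v_lo))
  f <- function(lg) {
    v <- dP_at(lg)
    if (is.na(v)) target_dP * 10 else v - target_dP
  }
  lg <- stats::uniroot(f, c(lo, bracket[2]), tol = 1e-8)$root
  achieved <- dP_at(lg)
  if (is.na(achieved) || abs(achieved - target_dP) > tol)
    stop("phloem calibration did not reach the target within tolerance")
  10^lg
}
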