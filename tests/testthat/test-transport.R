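make_boundary <- function(E, loading, ...) {
  transport_boundary(E = E, loading_rate = loading, ...)
}

test_that("sucrose viscosity behaves like the published correlation", {
  expect_equal(sucrose_viscosity(0), viscosity_water())
  ## direct evaluation at sucrose mass fraction 0.2
  w <- 0.2
  c20 <- 1000 * w / (0.342 * (1 - w))
  expect_equal(sucrose_viscosity(c20) / viscosity_water(),
               exp(4.68 * 0.956 * w / (1 - 0.956 * w)), tolerance = 1e-12)
  expect_equal(sucrose_viscosity(c20) / viscosity_water(), 3.023,
               tolerance = 1e-3)
  cs <- seq(0, 3000, by = 100)
  expect_true(all(diff(sucrose_viscosity(cs)) > 0))
  expect_error(sucrose_viscosity(-1), "nonnegative")
})

test_that("zero loading and zero transpiration give hydrostatic equilibrium", {
  tr <- pine_tree(10, r_sw_max = 0.02)
  g <- transport_grid(tr, n_nodes = 41)
  bnd <- make_boundary(0, 0, c_sink = 400)
  st <- solve_steady_state(g, bnd, K_x_scale = 1e-10, K_p_scale = 1e-10)
  rho_g <- 1000 * 9.81 / 1e6
  expect_equal(st$nodes$c, rep(400, 41), tolerance = 1e-9)
  expect_equal(st$nodes$psi_x, -rho_g * st$nodes$z, tolerance = 1e-12)
  expect_equal(diff(st$nodes$P_p), -rho_g * diff(st$nodes$z),
               tolerance = 1e-9)
  expect_equal(st$dP, -rho_g * st$nodes$z[1], tolerance = 1e-9)
})

test_that("a single segment matches the algebraic one-segment solution", {
  tr <- tree_spec(pine, L = 6, L0 = 2)
  g <- transport_grid(tr, n_nodes = 2)
  E <- 2e-7; loading <- 4e-6
  bnd <- make_boundary(E, loading, c_sink = 300)
  Kx <- 1e-9; Kp <- 3e-10
  st <- solve_steady_state(g, bnd, Kx, Kp)
  ## independent algebra: with one segment the upper concentration solves
  ## loading = G*(dpsi + RT*(cu - cl) + rho*g*dz) * c_mid / eta_rel(c_mid),
  ## taken on the low-concentration branch
  rho_g <- 1000 * 9.81 / 1e6
  RT <- 8.314 * 293.15 / 1e6
  dz <- g$dz[1]
  psi_apex <- 0 - E / (Kx * g$k_x_rel[1] / g$ds[1]) - rho_g * dz
  G <- Kp * g$k_p_rel[1] / g$ds[1]
  eta_rel <- function(cc) sucrose_viscosity(cc) / viscosity_water()
  f <- function(cc) {
    cm <- (cc + 300) / 2
    G * (psi_apex - 0 + RT * (cc - 300) + rho_g * dz) * cm / eta_rel(cm) -
      loading
  }
  c_peak <- stats::optimize(f, c(300, 5e4), maximum = TRUE)$maximum
  cu <- stats::uniroot(f, c(300, c_peak), tol = 1e-10)$root
  expect_equal(st$nodes$c[1], cu, tolerance = 1e-6)
  expect_equal(st$dP, (psi_apex + RT * cu) - (0 + RT * 300),
               tolerance = 1e-6)
  ## spelled as a pressure drop: dP = loading*eta/(G*c_mid) - gravity assist
  cm <- (cu + 300) / 2
  expect_equal(st$dP, loading * eta_rel(cm) / (G * cm) - rho_g * dz,
               tolerance = 1e-6)
})

test_that("the xylem sub-problem equals the series-resistor closed form", {
  tr <- pine_tree(10, r_sw_max = 0.02)
  g <- transport_grid(tr, n_nodes = 81)
  E <- 5e-7
  bnd <- make_boundary(E, 1e-6, psi_soil = -0.3)
  Kx <- 2e-9
  st <- solve_steady_state(g, bnd, Kx, 1e-9)
  rho_g <- 1000 * 9.81 / 1e6
  expect_equal(st$nodes$psi_x[1],
               -0.3 - E / (Kx * g$K_x_tot_rel) - rho_g * g$z[1],
               tolerance = 1e-10)
})

test_that("water and sugar are conserved at steady state", {
  tr <- pine_tree(10, r_sw_max = 0.02)
  g <- transport_grid(tr, n_nodes = 61)
  loading <- 5e-6
  for (mode in c("root", "uniform")) {
    bnd <- make_boundary(4e-7, loading, unloading = mode)
    st <- solve_steady_state(g, bnd, 1e-9, 1e-9)
    expect_lt(st$residual, 1e-8)
    ## van 't Hoff equilibrium at every node
    RT <- 8.314 * 293.15 / 1e6
    expect_equal(st$nodes$P_p - RT * st$nodes$c, st$nodes$psi_x,
                 tolerance = 1e-12)
    ## sugar: flux into the top segment equals the loading minus what is
    ## unloaded above it; at the base everything loaded has been unloaded
    expect_equal(st$segments$F_sugar[1], loading *
                   (if (mode == "root") 1 else
                      1 - (g$ds[1] / 2) / sum(g$ds)), tolerance = 1e-12)
    ## phloem water uptake at the apex carries the sugar flux at the
    ## segment concentration
    c_mid <- (st$nodes$c[1] + st$nodes$c[2]) / 2
    expect_equal(st$segments$Q_water[1],
                 st$segments$F_sugar[1] / c_mid, tolerance = 1e-12)
  }
})

test_that("the solution converges under grid refinement", {
  tr <- pine_tree(10, r_sw_max = 0.02)
  dP <- sapply(c(61, 121), function(nn) {
    g <- transport_grid(tr, n_nodes = nn)
    bnd <- make_boundary(4e-7, 8e-6)
    solve_steady_state(g, bnd, 1e-9, 1e-9)$dP
  })
  expect_lt(abs(dP[2] / dP[1] - 1), 0.01)
})

test_that("turgor difference decreases monotonically with phloem conductance", {
  tr <- pine_tree(10, r_sw_max = 0.02)
  g <- transport_grid(tr, n_nodes = 61)
  bnd <- make_boundary(4e-7, 8e-6)
  scales <- 1e-9 * 10^seq(0, 1, length.out = 5)
  dP <- sapply(scales, function(kp)
    solve_steady_state(g, bnd, 1e-9, kp)$dP)
  expect_true(all(diff(dP) < 0))
})

test_that("an unsustainable sugar flux raises a diagnostic error", {
  tr <- pine_tree(10, r_sw_max = 0.02)
  g <- transport_grid(tr, n_nodes = 41)
  bnd <- make_boundary(4e-7, 8e-6)
  expect_error(solve_steady_state(g, bnd, 1e-9, 1e-14),
               class = "transport_nonconvergence")
  err <- tryCatch(solve_steady_state(g, bnd, 1e-9, 1e-14),
                  transport_nonconvergence = function(e) e)
  expect_true(is.finite(err$max_c))
  expect_true(err$x >= tr$L0 && err$x <= tr$L)
})

test_that("phloem calibration hits the target turgor difference", {
  tr <- pine_tree(10, r_sw_max = 0.02)
  g <- transport_grid(tr, n_nodes = 61)
  bnd <- make_boundary(4e-7, 8e-6)
  Kx <- 1e-9
  Kp <- calibrate_phloem_scale(g, bnd, Kx, target_dP = 0.7)
  st <- solve_steady_state(g, bnd, Kx, Kp)
  expect_equal(st$dP, 0.7, tolerance = 1e-3)
  ## calibrating to the model's own value returns scale ~= the same scale
  Kp2 <- calibrate_phloem_scale(g, bnd, Kx, target_dP = st$dP)
  expect_equal(Kp2 / Kp, 1, tolerance = 1e-3)
  ## in the weak-feedback regime doubling the scale about halves the
  ## frictional part of the drop
  bnd_w <- make_boundary(0, 8e-6, gravity = FALSE,
                         viscosity = function(c, temperature)
                           viscosity_water(temperature))
  d1 <- solve_steady_state(g, bnd_w, Kx, 1e-8)$dP
  d2 <- solve_steady_state(g, bnd_w, Kx, 2e-8)$dP
  expect_equal(d2 / d1, 0.5, tolerance = 0.05)
})

test_that("an unreachable calibration target errors out", {
  tr <- pine_tree(10, r_sw_max = 0.02)
  g <- transport_grid(tr, n_nodes = 41)
  bnd <- make_boundary(4e-7, 8e-6)
  expect_error(calibrate_phloem_scale(g, bnd, 1e-9, target_dP = -5),
               "unreachable")
})
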