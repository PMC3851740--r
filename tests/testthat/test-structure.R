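test_that("stem taper evaluates and inverts correctly", {
  expect_equal(diameter_at_distance(1, pine), 15.8)
  expect_equal(diameter_at_distance(10, pine), 15.8 * 10^0.97)
  one <- scaling_params("custom", gamma = 1, delta = 1,
                        alpha = rep(1, 8), beta = rep(1, 8),
                        C_ls = 1, rho_SLA = 1, rho_N_leaf = 1)
  x <- c(0.3, 2, 7)
  expect_equal(diameter_at_distance(x, one), x)
  expect_equal(distance_at_diameter(diameter_at_distance(x, pine), pine), x)
  expect_error(diameter_at_distance(-1, pine), "positive")
})

test_that("tissue properties follow alpha * d^beta", {
  expect_equal(tissue_property(10, 0.75, 1.27), 0.75 * 10^1.27) # ~13.97 mm2
  expect_equal(tissue_property(10, 0.75, 1.27), 13.97, tolerance = 1e-3)
  expect_equal(tissue_property(10, 22.1, -0.80), 3.503, tolerance = 1e-3)
  expect_equal(tissue_property(c(2, 20), 5, 0), c(5, 5)) # beta = 0: constant
  expect_error(tissue_property(0, 1, 1), "positive")
})

test_that("sapwood partition is an annulus with a continuous transition", {
  no_hw <- pine_tree(10)
  d <- c(5, 40, 150)
  sw <- sapwood_partition(d, no_hw)
  expect_equal(sw$A_sw, 0.82 * d^1.98)
  expect_equal(sw$A_hw, rep(0, 3))

  hw <- pine_tree(10, r_sw_max = 0.02)
  ## transition diameter: A_x = pi * (20 mm)^2
  d_star <- (pi * 20^2 / 0.82)^(1 / 1.98)
  expect_equal(d_star, 40.62, tolerance = 1e-3)
  expect_equal(sapwood_partition(d_star, hw)$A_hw, 0, tolerance = 1e-9)
  ## and the corresponding distance from the apex is ~2.6 m
  expect_equal(distance_at_diameter(d_star, pine), 2.65, tolerance = 0.01)
  ## continuity across the transition
  lo <- sapwood_partition(d_star * (1 - 1e-7), hw)$A_sw
  hi <- sapwood_partition(d_star * (1 + 1e-7), hw)$A_sw
  expect_equal(lo, hi, tolerance = 1e-5)
  ## deep in the heartwood zone the annulus formula holds
  r <- sqrt(0.82 * 150^1.98 / pi)
  expect_equal(sapwood_partition(150, hw)$A_sw, pi * (r^2 - (r - 20)^2))
})

test_that("furcation number is anchored at the base and matches Eq-form", {
  tr <- pine_tree(10)
  expect_equal(furcation_number(10, tr), 1)
  expect_equal(furcation_number(1, tr), 10^(0.97 * 1.98), tolerance = 1e-12)
  expect_error(furcation_number(0.01, tr), "within")
  expect_error(furcation_number(11, tr), "within")
  hw <- pine_tree(10, r_sw_max = 0.02)
  expect_equal(furcation_number(10, hw), 1)
})

test_that("pipe model conserves summed sapwood area along the tree", {
  for (rsw in c(Inf, 0.02)) {
    tr <- pine_tree(12, r_sw_max = rsw)
    pr <- axial_profiles(tr, n_grid = 200)
    base <- pr$A_sw_tot[nrow(pr)]
    expect_lt(max(abs(pr$A_sw_tot - base)) / base, 1e-10)
  }
})

test_that("an effectively infinite sapwood cap reproduces the no-heartwood profile", {
  a <- axial_profiles(pine_tree(10), n_grid = 64)
  b <- axial_profiles(pine_tree(10, r_sw_max = 1e6), n_grid = 64)
  for (col in setdiff(names(a), c("x"))) {
    expect_equal(b[[col]], a[[col]], tolerance = 1e-12)
  }
})

test_that("phloem-to-xylem area ratio at a position is height invariant (no hw)", {
  p10 <- axial_profiles(pine_tree(10), n_grid = 1024)
  p20 <- axial_profiles(pine_tree(20), n_grid = 1024)
  x0 <- 1
  r10 <- stats::approx(p10$x, p10$A_p_tot / p10$A_x_tot, xout = x0)$y
  r20 <- stats::approx(p20$x, p20$A_p_tot / p20$A_x_tot, xout = x0)$y
  expect_equal(r10, r20, tolerance = 1e-5)
})

test_that("axial exponents match the analytic pipe-model values", {
  tr <- pine_tree(10)
  ## conductivity taper: k_x ~ x^(2 * delta * beta5) exactly
  expect_equal(axial_exponent(tr, "k_x")$exponent, 2 * 0.97 * 0.25,
               tolerance = 1e-9)
  ## summed phloem area: exponent delta * (beta2 - beta1)
  expect_equal(axial_exponent(tr, "A_p_tot")$exponent, 0.97 * (1.27 - 1.98),
               tolerance = 1e-9)
  ## summed xylem area is constant: log-log slope 0
  expect_equal(axial_exponent(tr, "A_x_tot")$exponent, 0, tolerance = 1e-10)
})

test_that("heartwood formation flattens the axial phloem-area profile", {
  e_no <- axial_exponent(pine_tree(10), "A_p_tot")$exponent
  e_hw <- axial_exponent(pine_tree(10, r_sw_max = 0.02), "A_p_tot")$exponent
  expect_gt(e_hw, e_no)  # -0.46 vs -0.69: less apex-concentrated
  expect_lt(e_hw, 0)
})
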