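## independent adaptive-quadrature oracle built directly from the scaling
## definitions (not from axial_profiles)
oracle_totals <- function(params, L, L0 = 0.1) {
  g <- params$gamma; dl <- params$delta
  a <- params$alpha; b <- params$beta
  d_at <- function(x) g * x^dl
  A_x <- function(x) a[["A_x"]] * d_at(x)^b[["A_x"]]
  A_p <- function(x) a[["A_p"]] * d_at(x)^b[["A_p"]]
  n <- function(x) A_x(L) / A_x(x)
  qu <- function(f) stats::integrate(f, L0, L, rel.tol = 1e-10)$value
  list(
    V_x = qu(function(x) n(x) * A_x(x)) * 1e-6,
    V_p = qu(function(x) n(x) * A_p(x)) * 1e-6,
    N_x = qu(function(x) n(x) * A_x(x) * 1e-6 * params$wood_density * 1000 *
               a[["rho_N_x"]] * d_at(x)^b[["rho_N_x"]] / 100),
    N_p = qu(function(x) n(x) * A_p(x) * 1e-6 * params$phloem_density * 1000 *
               a[["rho_N_p"]] * d_at(x)^b[["rho_N_p"]] / 100),
    K_x = 1 / qu(function(x) 1 / (n(x) * A_x(x) *
                                    (a[["r_x"]] * d_at(x)^b[["r_x"]])^2 *
                                    a[["rho_c_x"]] * d_at(x)^b[["rho_c_x"]])),
    K_p = 1 / qu(function(x) 1 / (n(x) * A_p(x) *
                                    (a[["r_p"]] * d_at(x)^b[["r_p"]])^2 *
                                    a[["rho_c_p"]] * d_at(x)^b[["rho_c_p"]])))
}

test_that("closed forms agree with independent adaptive quadrature", {
  tr <- pine_tree(10)
  cf <- whole_tree_closed_form(tr)
  or <- oracle_totals(pine, 10)
  expect_equal(cf$V_x_tot, or$V_x, tolerance = 1e-4)
  expect_equal(cf$V_p_tot, or$V_p, tolerance = 1e-4)
  expect_equal(cf$N_x_tot, or$N_x, tolerance = 1e-4)
  expect_equal(cf$N_p_tot, or$N_p, tolerance = 1e-4)
  expect_equal(cf$K_x_tot, or$K_x, tolerance = 1e-4)
  expect_equal(cf$K_p_tot, or$K_p, tolerance = 1e-4)
})

test_that("quadrature summaries match the closed forms to <0.1% (no hw)", {
  for (L in c(1, 3, 10, 30)) {
    for (sp in list(pine, aspen)) {
      tr <- tree_spec(sp, L = L)
      cf <- unlist(whole_tree_closed_form(tr)[1, summary_cols <- c(
        "V_x_tot", "V_sw_tot", "V_p_tot", "N_x_tot", "N_p_tot",
        "N_leaf_tot", "K_x_tot", "K_p_tot")])
      nm <- unlist(whole_tree_numeric(tr)[1, summary_cols])
      expect_lt(max(abs(nm / cf - 1)), 1e-3)
    }
  }
})

test_that("closed forms are linear in the xylem area base", {
  p2 <- pine; p2$alpha[["A_x"]] <- 2 * p2$alpha[["A_x"]]
  a <- whole_tree_closed_form(pine_tree(10))
  b <- whole_tree_closed_form(tree_spec(p2, L = 10))
  expect_equal(b$V_x_tot, 2 * a$V_x_tot, tolerance = 1e-12)
  expect_equal(b$V_p_tot, a$V_p_tot, tolerance = 1e-12) # phloem untouched
})

test_that("closed forms vanish in the degenerate limit L -> L0", {
  tr <- tree_spec(pine, L = 0.1 + 1e-9, L0 = 0.1)
  cf <- whole_tree_closed_form(tr)
  expect_lt(cf$V_x_tot, 1e-10)
  expect_lt(cf$V_p_tot, 1e-10)
  expect_lt(cf$N_x_tot, 1e-6)
})

test_that("the closed form refuses heartwood scenarios", {
  expect_error(whole_tree_closed_form(pine_tree(10, r_sw_max = 0.02)),
               "no-heartwood")
})

test_that("every whole-tree total increases strictly with height", {
  Ls <- c(2, 5, 10, 20, 40)
  for (rsw in c(Inf, 0.02)) {
    vals <- sapply(Ls, function(L) {
      unlist(whole_tree_numeric(tree_spec(pine, L = L, r_sw_max = rsw,
                                          hw_nitrogen_fraction = 1))[
        1, c("V_x_tot", "V_sw_tot", "V_p_tot", "N_x_tot", "N_p_tot",
             "N_leaf_tot", "K_x_tot", "K_p_tot")])
    })
    expect_true(all(apply(vals, 1, function(v) all(diff(v) > 0))))
  }
})

test_that("capped sapwood reduces sapwood volume below the no-hw xylem volume", {
  no_hw <- whole_tree_closed_form(pine_tree(10))
  hw <- whole_tree_numeric(pine_tree(10, r_sw_max = 0.02))
  expect_lt(hw$V_sw_tot, no_hw$V_x_tot)
  expect_lt(hw$V_sw_tot, hw$V_x_tot)
})

test_that("summaries are continuous in r_sw_max at the sapwood transition", {
  ## for L = 10 pine the basal xylem radius is ~71.7 mm; at r_sw_max just
  ## above it the tree is heartwood-free
  r_base <- sqrt(0.82 * (15.8 * 10^0.97)^1.98 / pi) / 1000
  lo <- whole_tree_numeric(pine_tree(10, r_sw_max = r_base * (1 - 1e-6)))
  hi <- whole_tree_numeric(pine_tree(10, r_sw_max = r_base * (1 + 1e-6)))
  expect_equal(lo$V_sw_tot, hi$V_sw_tot, tolerance = 1e-4)
  expect_equal(lo$K_x_tot, hi$K_x_tot, tolerance = 1e-4)
})

test_that("the exponent fitter is exact on exact power laws", {
  ## leaf nitrogen (no hw) is an exact power law L^(delta*beta1)
  f <- scaling_exponent(pine, "N_leaf_tot", fit_range = c(1, 25))
  expect_equal(f$exponent, 0.97 * 1.98, tolerance = 1e-9)
  expect_error(scaling_exponent(pine, "V_x_tot", n_heights = 5),
               "at least 8")
})

test_that("height-scaling exponents reproduce the headline values", {
  e_vx <- scaling_exponent(pine, "V_x_tot", fit_range = c(1, 25))$exponent
  expect_gt(e_vx, 2.9); expect_lt(e_vx, 2.96)
  e_sw <- scaling_exponent(pine, "V_sw_tot", fit_range = c(10, 100),
                           r_sw_max = 0.02)$exponent
  expect_gt(e_sw, 1.95); expect_lt(e_sw, 2.06)
})

test_that("a zero-amplitude sensitivity sweep collapses onto the base curve", {
  env <- sensitivity_sweep(pine, n_draws = 1, seed = 1,
                           heights = c(2, 5, 10, 20),
                           scale_range = c(1, 1),
                           r_sw_range = c(0.02, 0.02))
  expect_equal(env$min, env$max, tolerance = 1e-12)
  expect_equal(env$min, env$base, tolerance = 1e-12)
})

test_that("sensitivity envelopes contain the base curve and are reproducible", {
  env <- sensitivity_sweep(pine, n_draws = 25, seed = 7,
                           heights = c(2, 5, 10, 20, 40))
  expect_true(all(env$min <= env$base + 1e-9))
  expect_true(all(env$max >= env$base - 1e-9))
  expect_true(all(env$min <= env$max))
  ## normalisation: curves equal 1 at the reference height by construction;
  ## the envelope must straddle 1 wherever the reference height is in range
  env2 <- sensitivity_sweep(pine, n_draws = 25, seed = 7,
                            heights = c(2, 5, 10, 20, 40))
  expect_identical(env$min, env2$min)
  expect_identical(env$max, env2$max)
})
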