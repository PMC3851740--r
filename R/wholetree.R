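## exact integral of x^p over [lo, hi], handling the logarithmic case
pwint <- function(p, lo, hi) {
  if (abs(p + 1) < 1e-12) log(hi / lo)
  else (hi^(p + 1) - lo^(p + 1)) / (p + 1)
}

summary_names <- c("V_x_tot", "V_sw_tot", "V_p_tot", "N_x_tot", "N_p_tot",
                   "N_leaf_tot", "K_x_tot", "K_p_tot", "A_leaf")

#' Whole-tree totals from the closed-form integrals (no heartwood)
#'
#' Integrates the axial profiles analytically over `[L0, L]` for the
#' scenario in which all xylem conducts. Under the pipe model the summed
#' sapwood area `n * A_x` is constant along the tree, so the xylem volume
#' is simply that constant times the path length; phloem, nitrogen and
#' conductance integrals are power-law integrals in closed form.
#'
#' Units: volumes m^3, nitrogen grams, leaf area m^2; conductances are in
#' relative units (conduit bases are only defined up to a common factor)
#' and are comparable across heights and between xylem and phloem.
#'
#' @param tree A [tree_spec()] object with `r_sw_max = Inf`.
#' @return A one-row data.frame of class `whole_tree_summary` with columns
#'   `V_x_tot`, `V_sw_tot`, `V_p_tot`, `N_x_tot`, `N_p_tot`, `N_leaf_tot`,
#'   `K_x_tot`, `K_p_tot`, `A_leaf` plus scenario metadata.
#' @export
whole_tree_closed_form <- function(tree) {
  stopifnot(inherits(tree, "tree_spec"))
  if (is.finite(tree$r_sw_max))
    stop("closed forms hold only for the no-heartwood scenario; ",
         "use whole_tree_numeric() for finite r_sw_max")
  p <- tree$params
  L <- tree$L; L0 <- tree$L0
  g <- p$gamma; dl <- p$delta; a <- p$alpha; b <- p$beta
  db1 <- dl * b[["A_x"]]
  C1 <- a[["A_x"]] * g^b[["A_x"]]          # mm2 at x = 1 m
  C2 <- a[["A_p"]] * g^b[["A_p"]]
  sw_line <- C1 * L^db1                    # n*A_x, constant (mm2)

  V_x <- sw_line * (L - L0) * 1e-6
  V_p <- C2 * L^db1 * pwint(dl * b[["A_p"]] - db1, L0, L) * 1e-6
  N_x <- sw_line * 1e-6 * p$wood_density * 1000 *
    (a[["rho_N_x"]] * g^b[["rho_N_x"]] / 100) *
    pwint(dl * b[["rho_N_x"]], L0, L)
  N_p <- C2 * L^db1 * 1e-6 * p$phloem_density * 1000 *
    (a[["rho_N_p"]] * g^b[["rho_N_p"]] / 100) *
    pwint(dl * (b[["rho_N_p"]] + b[["A_p"]] - b[["A_x"]]), L0, L)
  A_leaf <- sw_line * 1e-6 * p$C_ls
  N_leaf <- A_leaf * p$rho_SLA * p$rho_N_leaf / 100

  qx <- dl * (b[["rho_c_x"]] + 2 * b[["r_x"]])
  kx0 <- sw_line * a[["rho_c_x"]] * a[["r_x"]]^2 *
    g^(b[["rho_c_x"]] + 2 * b[["r_x"]])
  K_x <- kx0 / pwint(-qx, L0, L)
  qp <- dl * (b[["A_p"]] - b[["A_x"]] + b[["rho_c_p"]] + 2 * b[["r_p"]])
  kp0 <- C2 * L^db1 * a[["rho_c_p"]] * a[["r_p"]]^2 *
    g^(b[["rho_c_p"]] + 2 * b[["r_p"]])
  K_p <- kp0 / pwint(-qp, L0, L)

  out <- data.frame(V_x_tot = V_x, V_sw_tot = V_x, V_p_tot = V_p,
                    N_x_tot = N_x, N_p_tot = N_p, N_leaf_tot = N_leaf,
                    K_x_tot = K_x, K_p_tot = K_p, A_leaf = A_leaf,
                    scenario = "no heartwood", method = "closed form")
  class(out) <- c("whole_tree_summary", "data.frame")
  out
}

#' Whole-tree totals by quadrature of the axial profiles
#'
#' Composite trapezoidal integration of [axial_profiles()] line densities
#' over `[L0, L]` on a log-spaced grid, with grid doubling until all
#' totals change by less than `tol` (relative) or the refinement cap is
#' hit. Works for any heartwood scenario; conductances come from series
#' resistance `1/K = integral dx / k(x)`.
#'
#' In the capped-sapwood scenario `V_x_tot` integrates the full xylem
#' cross-section (sapwood plus heartwood) and `V_sw_tot` the conducting
#' sapwood only; leaf area follows basal sapwood area.
#'
#' @param tree A [tree_spec()] object.
#' @param n_grid Starting number of grid points.
#' @param tol Relative refinement tolerance.
#' @param max_doublings Refinement cap.
#' @return As [whole_tree_closed_form()].
#' @export
whole_tree_numeric <- function(tree, n_grid = 513L, tol = 1e-4,
                               max_doublings = 5L) {
  stopifnot(inherits(tree, "tree_spec"))
  trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  eval_at <- function(ng) {
    pr <- axial_profiles(tree, n_grid = ng, spacing = "log")
    p <- tree$params
    A_sw_base <- pr$A_sw[nrow(pr)] * 1e-6
    A_leaf <- A_sw_base * p$C_ls
    c(V_x_tot = trapz(pr$x, pr$A_x_tot) * 1e-6,
      V_sw_tot = trapz(pr$x, pr$A_sw_tot) * 1e-6,
      V_p_tot = trapz(pr$x, pr$A_p_tot) * 1e-6,
      N_x_tot = trapz(pr$x, pr$N_line_x),
      N_p_tot = trapz(pr$x, pr$N_line_p),
      N_leaf_tot = A_leaf * p$rho_SLA * p$rho_N_leaf / 100,
      K_x_tot = 1 / trapz(pr$x, 1 / pr$k_x),
      K_p_tot = 1 / trapz(pr$x, 1 / pr$k_p),
      A_leaf = A_leaf)
  }
  cur <- eval_at(n_grid)
  for (i in seq_len(max_doublings)) {
    n_grid <- 2L * (n_grid - 1L) + 1L
    nxt <- eval_at(n_grid)
    if (max(abs(nxt / cur - 1)) < tol) {
      cur <- nxt
      out <- as.data.frame(as.list(cur))
      out$scenario <- if (is.finite(tree$r_sw_max))
        sprintf("sapwood depth %.3g m", tree$r_sw_max) else "no heartwood"
      out$method <- "quadrature"
      class(out) <- c("whole_tree_summary", "data.frame")
      return(out)
    }
    cur <- nxt
  }
  stop("quadrature did not reach tolerance ", tol,
       " within the refinement cap")
}

#' Height-scaling exponent of a whole-tree quantity
#'
#' Builds trees of increasing height with fixed parameters and scenario,
#' extracts one whole-tree total, and fits `quantity ~ prefactor * L^E` by
#' log-log OLS over a stated height range. Whole-tree scaling is close to
#' but not exactly allometric, so the fitted exponent depends (weakly for
#' the no-heartwood scenario, strongly for capped sapwood) on the range,
#' which is therefore recorded in the result.
#'
#' @param params A [scaling_params()] object.
#' @param quantity One of the whole-tree summary columns.
#' @param fit_range Height range (m), fitted over `n_heights` log-spaced
#'   heights (>= 8).
#' @param n_heights Number of heights.
#' @param L0 Apex cutoff (m).
#' @param r_sw_max,hw_nitrogen_fraction Heartwood scenario, see
#'   [tree_spec()].
#' @return List of class `exponent_fit`: `quantity`, `prefactor`,
#'   `exponent`, `fit_range`, `n_heights`, `scenario`.
#' @examples
#' scaling_exponent(scaling_params("pine"), "V_x_tot")$exponent # ~ 2.93
#' @export
scaling_exponent <- function(params, quantity, fit_range = c(1, 25),
                             n_heights = 16L, L0 = 0.1, r_sw_max = Inf,
                             hw_nitrogen_fraction = 0) {
  stopifnot(inherits(params, "scaling_params"))
  if (n_heights < 8L) stop("need at least 8 heights")
  if (!quantity %in% summary_names) stop("unknown quantity: ", quantity)
  heights <- exp(seq(log(fit_range[1]), log(fit_range[2]),
                     length.out = n_heights))
  vals <- vapply(heights, function(L) {
    tr <- tree_spec(params, L = L, L0 = L0, r_sw_max = r_sw_max,
                    hw_nitrogen_fraction = hw_nitrogen_fraction)
    s <- if (is.finite(r_sw_max)) whole_tree_numeric(tr)
         else whole_tree_closed_form(tr)
    s[[quantity]]
  }, numeric(1))
  if (any(vals <= 0)) stop("quantity must stay positive over the fit range")
  fit <- stats::lm(log(vals) ~ log(heights))
  out <- list(quantity = quantity,
              prefactor = exp(unname(stats::coef(fit)[1])),
              exponent = unname(stats::coef(fit)[2]),
              fit_range = fit_range, n_heights = n_heights,
              scenario = if (is.finite(r_sw_max))
                sprintf("sapwood depth %.3g m", r_sw_max) else "no heartwood")
  class(out) <- "exponent_fit"
  out
}

#' @export
print.exponent_fit <- function(x, ...) {
  cat(sprintf("%s ~ %.3g * L^%.4g  (heights %.3g-%.3g m, %s)\n",
              x$quantity, x$prefactor, x$exponent,
              x$fit_range[1], x$fit_range[2], x$scenario))
  invisible(x)
}

#' Sensitivity envelopes of the height scaling
#'
#' Monte-Carlo sweep over the scaling exponents: `beta1..beta6` and
#' `delta` are each drawn uniformly between `scale_range[1]` and
#' `scale_range[2]` times their base values, and the maximum sapwood depth
#' is drawn log-uniformly over `r_sw_range`. Each draw's whole-tree
#' quantities are computed over `heights` and normalised to their value at
#' the reference height; the envelope is the pointwise min/max across
#' draws.
#'
#' @param params Base [scaling_params()].
#' @param n_draws Number of random parameter combinations (>= 1).
#' @param seed Integer seed; the sweep is reproducible for a fixed seed.
#' @param heights Heights (m) at which curves are evaluated.
#' @param L_ref Reference height for normalisation (m).
#' @param scale_range Multiplicative perturbation range for the exponents.
#' @param r_sw_range Sapwood-depth range (m), sampled log-uniformly.
#' @param quantities Summary columns to track.
#' @param L0 Apex cutoff (m).
#' @return List of class `sensitivity_envelope`: arrays `min`, `max`
#'   (quantity x height), the `base` curves (unperturbed exponents at the
#'   centre of the sapwood-depth range), `heights`, `n_draws`, `seed`.
#' @export
sensitivity_sweep <- function(params, n_draws = 1000L, seed = 1L,
                              heights = exp(seq(log(1), log(50),
                                                length.out = 12L)),
                              L_ref = 10, scale_range = c(0.75, 1.25),
                              r_sw_range = c(0.02, 2),
                              quantities = c("V_sw_tot", "V_p_tot",
                                             "N_x_tot", "N_p_tot",
                                             "N_leaf_tot", "K_x_tot",
                                             "K_p_tot"),
                              L0 = 0.1) {
  stopifnot(inherits(params, "scaling_params"), n_draws >= 1L)
  set.seed(seed)
  curve_for <- function(p, r_sw) {
    vapply(c(heights, L_ref), function(L) {
      tr <- tree_spec(p, L = L, L0 = L0, r_sw_max = r_sw,
                      hw_nitrogen_fraction = 1)
      unlist(whole_tree_numeric(tr, n_grid = 257L, tol = 1e-3,
                                max_doublings = 3L)[quantities])
    }, numeric(length(quantities)))
  }
  normalise <- function(m) m[, seq_along(heights), drop = FALSE] /
    m[, length(heights) + 1L]
  ## base curve: unperturbed exponents at the centre of the swept
  ## sapwood-depth range
  base_curve <- normalise(curve_for(params, sqrt(prod(r_sw_range))))
  lo <- hi <- NULL
  for (i in seq_len(n_draws)) {
    p <- params
    p$beta[1:6] <- p$beta[1:6] *
      stats::runif(6, scale_range[1], scale_range[2])
    p$delta <- p$delta * stats::runif(1, scale_range[1], scale_range[2])
    r_sw <- exp(stats::runif(1, log(r_sw_range[1]), log(r_sw_range[2])))
    m <- normalise(curve_for(p, r_sw))
    lo <- if (is.null(lo)) m else pmin(lo, m)
    hi <- if (is.null(hi)) m else pmax(hi, m)
  }
  dimnames(lo) <- dimnames(hi) <- dimnames(base_curve) <-
    list(quantities, signif(heights, 4))
  structure(list(min = lo, max = hi, base = base_curve, heights = heights,
                 L_ref = L_ref, n_draws = n_draws, seed = seed),
            class = "sensitivity_envelope")
}
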