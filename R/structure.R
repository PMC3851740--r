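#' Diameter at a given distance from the apex
#'
#' Stem taper: `d = gamma * x^delta`, `x` in metres, `d` in millimetres.
#'
#' @param x Distance from the branch/stem apex (m), positive.
#' @param params A [scaling_params()] object.
#' @return Diameter (mm).
#' @examples
#' diameter_at_distance(1, scaling_params("pine")) # 15.8 mm
#' @export
diameter_at_distance <- function(x, params) {
  stopifnot(inherits(params, "scaling_params"))
  if (any(!is.finite(x)) || any(x <= 0))
    stop("x must be positive (distance from apex in metres)")
  params$gamma * x^params$delta
}

#' Distance from apex at a given diameter (inverse taper)
#'
#' @param d Diameter (mm), positive.
#' @inheritParams diameter_at_distance
#' @return Distance from apex (m).
#' @export
distance_at_diameter <- function(d, params) {
  stopifnot(inherits(params, "scaling_params"))
  if (any(!is.finite(d)) || any(d <= 0)) stop("d must be positive")
  (d / params$gamma)^(1 / params$delta)
}

#' Tissue property from the diameter power law
#'
#' Evaluates `base * d^exponent`; the generic building block behind all the
#' diameter allometries.
#'
#' @param d Diameter (mm), positive.
#' @param base,exponent Power-law base and exponent.
#' @return Property value in the base's units.
#' @examples
#' tissue_property(10, 0.75, 1.27) # pine phloem area at d = 10 mm
#' @export
tissue_property <- function(d, base, exponent) {
  if (any(!is.finite(d)) || any(d <= 0)) stop("d must be positive")
  base * d^exponent
}

## named accessors for the eight scaled properties
prop_at <- function(d, params, what) {
  tissue_property(d, params$alpha[[what]], params$beta[[what]])
}

#' Sapwood/heartwood partition of the xylem cross-section
#'
#' The xylem is treated as a circular cross-section of area `A_x(d)`; its
#' equivalent radius is `sqrt(A_x / pi)`. Conducting sapwood is the
#' outermost annulus of radial depth `r_sw_max`; anything deeper is
#' heartwood. With `r_sw_max = Inf` all xylem is sapwood.
#'
#' @param d Diameter over bark (mm).
#' @param tree A [tree_spec()] object.
#' @return A data.frame with columns `A_sw` and `A_hw` (mm^2).
#' @export
sapwood_partition <- function(d, tree) {
  stopifnot(inherits(tree, "tree_spec"))
  A_x <- prop_at(d, tree$params, "A_x")
  if (!is.finite(tree$r_sw_max)) return(data.frame(A_sw = A_x, A_hw = 0 * A_x))
  r_xyl <- sqrt(A_x / pi) / 1000                 # m
  ann <- pi * (r_xyl^2 - pmax(r_xyl - tree$r_sw_max, 0)^2) * 1e6
  A_sw <- pmin(A_x, ann)
  data.frame(A_sw = A_sw, A_hw = A_x - A_sw)
}

#' Furcation number at a distance from the apex
#'
#' Number of parallel branch axes at distance `x` from the apex, from
#' conservation of sapwood cross-sectional area across branching junctions
#' (pipe model): `n(x) = A_sw(d(L)) / A_sw(d(x))`, normalised so that
#' `n(L) = 1` at the tree base. Without heartwood this reduces to the
#' closed form `(L/x)^(delta*beta1)`.
#'
#' @param x Distance from apex (m), within `[L0, L]`.
#' @param tree A [tree_spec()] object.
#' @return Real-valued furcation number, >= 1.
#' @examples
#' tr <- tree_spec(scaling_params("pine"), L = 10)
#' furcation_number(1, tr) # ~ 10^(0.97*1.98) = 83.3
#' @export
furcation_number <- function(x, tree) {
  stopifnot(inherits(tree, "tree_spec"))
  eps <- 1e-9
  if (any(x < tree$L0 - eps) || any(x > tree$L + eps))
    stop("x must lie within [L0, L]")
  x <- pmin(pmax(x, tree$L0), tree$L)
  base_sw <- sapwood_partition(diameter_at_distance(tree$L, tree$params),
                               tree)$A_sw
  base_sw / sapwood_partition(diameter_at_distance(x, tree$params), tree)$A_sw
}

#' Axial profiles of summed tissue properties
#'
#' Evaluates, on a grid of distances from the apex, the per-axis tissue
#' properties and their crown-wide totals: summed xylem/sapwood/phloem
#' cross-sectional areas, nitrogen line densities, and relative hydraulic
#' conductivities under Hagen-Poiseuille proportionality
#' (`k = n * A * rho_c * r^2`; absolute units arbitrary because conduit
#' bases are relative).
#'
#' Nitrogen line densities convert tissue mass fractions (%) to grams of N
#' per metre of transport path using the tissue densities in
#' `tree$params`; heartwood contributes a fraction
#' `tree$hw_nitrogen_fraction` of the sapwood concentration.
#'
#' @param tree A [tree_spec()] object.
#' @param n_grid Number of grid points (>= 16).
#' @param spacing `"log"` (default; equidistributes relative error of the
#'   power laws) or `"linear"` (equal weight per metre of path, used for
#'   axial exponent fits).
#' @return A data.frame of class `axial_profile` with columns `x`, `d`,
#'   `A_x`, `A_p`, `A_sw`, `A_hw`, `n`, `A_x_tot`, `A_sw_tot`, `A_p_tot`,
#'   `N_line_x`, `N_line_p`, `k_x`, `k_p`.
#' @export
axial_profiles <- function(tree, n_grid = 200L, spacing = c("log", "linear")) {
  stopifnot(inherits(tree, "tree_spec"))
  spacing <- match.arg(spacing)
  if (n_grid < 16L) stop("n_grid must be at least 16")
  x <- if (spacing == "log")
    exp(seq(log(tree$L0), log(tree$L), length.out = n_grid))
  else seq(tree$L0, tree$L, length.out = n_grid)
  p <- tree$params
  d <- diameter_at_distance(x, p)
  sw <- sapwood_partition(d, tree)
  n <- furcation_number(x, tree)
  A_x <- prop_at(d, p, "A_x")
  A_p <- prop_at(d, p, "A_p")
  ## N line densities: mm2 -> m2, kg -> g, % -> fraction
  N_line_x <- n * (sw$A_sw + tree$hw_nitrogen_fraction * sw$A_hw) * 1e-6 *
    p$wood_density * 1000 * prop_at(d, p, "rho_N_x") / 100
  N_line_p <- n * A_p * 1e-6 * p$phloem_density * 1000 *
    prop_at(d, p, "rho_N_p") / 100
  k_x <- n * sw$A_sw * prop_at(d, p, "rho_c_x") * prop_at(d, p, "r_x")^2
  k_p <- n * A_p * prop_at(d, p, "rho_c_p") * prop_at(d, p, "r_p")^2
  out <- data.frame(x = x, d = d, A_x = A_x, A_p = A_p,
                    A_sw = sw$A_sw, A_hw = sw$A_hw, n = n,
                    A_x_tot = n * A_x, A_sw_tot = n * sw$A_sw,
                    A_p_tot = n * A_p,
                    N_line_x = N_line_x, N_line_p = N_line_p,
                    k_x = k_x, k_p = k_p)
  class(out) <- c("axial_profile", "data.frame")
  attr(out, "tree") <- tree
  out
}

#' Fitted axial scaling exponent of a profile quantity
#'
#' Log-log OLS exponent of one summed profile quantity against distance
#' from the apex. The fit grid is linearly spaced so every metre of
#' transport path carries equal weight; for quantities that are exact power
#' laws the grid choice is irrelevant, for heartwood-affected profiles it
#' is part of the definition of the summary exponent.
#'
#' @param tree A [tree_spec()] object.
#' @param quantity Profile column to fit (e.g. `"A_p_tot"`, `"k_x"`).
#' @param n_grid Number of fit points.
#' @return A list with `exponent`, `prefactor` and the fitted range.
#' @examples
#' tr <- tree_spec(scaling_params("pine"), L = 10)
#' axial_exponent(tr, "A_p_tot")$exponent # ~ -0.69
#' @export
axial_exponent <- function(tree, quantity, n_grid = 256L) {
  prof <- axial_profiles(tree, n_grid = n_grid, spacing = "linear")
  if (!quantity %in% names(prof)) stop("unknown profile quantity: ", quantity)
  y <- prof[[quantity]]
  if (any(y <= 0)) stop("quantity must be positive to fit a log-log slope")
  fit <- stats::lm(log(y) ~ log(x), data = data.frame(x = prof$x, y = y))
  list(quantity = quantity, exponent = unname(stats::coef(fit)[2]),
       prefactor = exp(unname(stats::coef(fit)[1])),
       range = c(tree$L0, tree$L))
}
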