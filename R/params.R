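#' Scaling parameters for one species
#'
#' Bundles the power-law bases and exponents that describe how vascular
#' tissue properties vary with branch/stem diameter, together with the stem
#' taper and the leaf constants needed for whole-tree totals.
#'
#' The taper relation is `d = gamma * x^delta`, with `x` the distance from
#' the branch/stem apex in metres and `d` the diameter in millimetres.
#' Every other property is `alpha_i * d^beta_i` with `d` in millimetres:
#'
#' * `i = 1`: xylem cross-sectional area (mm^2)
#' * `i = 2`: phloem (inner, living bark) cross-sectional area (mm^2)
#' * `i = 3`: xylem nitrogen concentration (% of dry mass)
#' * `i = 4`: phloem nitrogen concentration (% of dry mass)
#' * `i = 5`: xylem conduit radius (relative units)
#' * `i = 6`: phloem conduit radius (relative units)
#' * `i = 7`: fraction of xylem area occupied by conduit lumina (relative)
#' * `i = 8`: fraction of phloem area occupied by conduit lumina (relative)
#'
#' Bases for `i = 5..8` are only defined up to a common factor; all
#' conductivities derived from them are relative. The defaults for
#' `"pine"` (Pinus sylvestris) and `"aspen"` (Populus tremula) are the
#' field-measured values for Southern-Finland trees plus literature conduit
#' taper (`beta5 = beta6 = 0.25`) and constant conduit fraction
#' (`beta7 = beta8 = 0`).
#'
#' @param species `"pine"` or `"aspen"` to load the built-in parameter set,
#'   or `"custom"` together with explicit values.
#' @param gamma,delta Stem taper base (mm at `x` = 1 m) and exponent.
#' @param alpha,beta Numeric vectors of length 8, bases and exponents for
#'   the diameter scaling of the eight tissue properties above.
#' @param C_ls Leaf area per unit basal sapwood area (m^2 m^-2).
#' @param rho_SLA Leaf dry mass per unit leaf area (g m^-2).
#' @param rho_N_leaf Leaf nitrogen concentration (% of dry mass).
#' @param wood_density Xylem tissue density (kg m^-3), used to convert
#'   nitrogen mass fractions into absolute nitrogen amounts.
#' @param phloem_density Phloem tissue density (kg m^-3).
#' @return An object of class `scaling_params`.
#' @examples
#' p <- scaling_params("pine")
#' p$gamma # 15.8 mm at 1 m from the apex
#' @export
scaling_params <- function(species = c("pine", "aspen", "custom"),
                           gamma = NULL, delta = NULL,
                           alpha = NULL, beta = NULL,
                           C_ls = NULL, rho_SLA = NULL, rho_N_leaf = NULL,
                           wood_density = 400, phloem_density = 1000) {
  species <- match.arg(species)
  defaults <- list(
    pine = list(gamma = 15.8, delta = 0.97,
                alpha = c(0.82, 0.75, 2.02, 1.4, 1, 1, 1, 1),
                beta = c(1.98, 1.27, -0.61, -0.22, 0.25, 0.25, 0, 0),
                C_ls = 3400, rho_SLA = 300, rho_N_leaf = 1.2),
    aspen = list(gamma = 15.6, delta = 0.97,
                 alpha = c(0.71, 0.99, 0.68, 22.1, 1, 1, 1, 1),
                 beta = c(2.00, 1.31, -0.34, -0.80, 0.25, 0.25, 0, 0),
                 C_ls = 2700, rho_SLA = 80, rho_N_leaf = 2.4))
  base <- if (species == "custom") list() else defaults[[species]]
  pick <- function(user, field, fallback = NULL) {
    if (!is.null(user)) user
    else if (!is.null(base[[field]])) base[[field]]
    else fallback
  }
  p <- list(species = species,
            gamma = pick(gamma, "gamma"), delta = pick(delta, "delta"),
            alpha = pick(alpha, "alpha"), beta = pick(beta, "beta"),
            C_ls = pick(C_ls, "C_ls"), rho_SLA = pick(rho_SLA, "rho_SLA"),
            rho_N_leaf = pick(rho_N_leaf, "rho_N_leaf"),
            wood_density = wood_density, phloem_density = phloem_density)
  if (is.null(p$gamma) || is.null(p$delta) || is.null(p$alpha) ||
      is.null(p$beta))
    stop("custom scaling_params need gamma, delta, alpha and beta")
  if (length(p$alpha) != 8L || length(p$beta) != 8L)
    stop("alpha and beta must have length 8")
  if (p$gamma <= 0 || p$alpha[1] <= 0 || p$alpha[2] <= 0)
    stop("gamma, alpha[1] and alpha[2] must be positive")
  names(p$alpha) <- names(p$beta) <- c("A_x", "A_p", "rho_N_x", "rho_N_p",
                                       "r_x", "r_p", "rho_c_x", "rho_c_p")
  class(p) <- "scaling_params"
  p
}

#' @export
print.scaling_params <- function(x, ...) {
  cat("Vascular scaling parameters (", x$species, ")\n", sep = "")
  cat(sprintf("  taper: d = %.3g mm * x[m]^%.3g\n", x$gamma, x$delta))
  m <- rbind(base = x$alpha, exponent = x$beta)
  print(round(m, 4))
  cat(sprintf("  C_ls %.4g m2/m2, rho_SLA %.4g g/m2, rho_N_leaf %.3g %%\n",
              x$C_ls, x$rho_SLA, x$rho_N_leaf))
  invisible(x)
}

#' One tree instance
#'
#' Combines a species parameter set with a tree height, an apical
#' integration cutoff, and the heartwood scenario. `r_sw_max = Inf`
#' corresponds to the no-heartwood scenario (all xylem conducts);
#' `r_sw_max = 0.02` restricts conducting sapwood to the outermost 2 cm of
#' the xylem. `hw_nitrogen_fraction` is the heartwood nitrogen
#' concentration expressed as a fraction of the sapwood concentration
#' (0 = nitrogen-free heartwood, 1 = same as sapwood).
#'
#' @param params A [scaling_params()] object.
#' @param L Tree height (m).
#' @param L0 Distance from the apex at which whole-tree integrals start
#'   (m); below this the allometries are not trusted. Default 0.1 m.
#' @param r_sw_max Maximum sapwood depth (m), measured radially inward from
#'   the xylem surface. `Inf` disables heartwood formation.
#' @param hw_nitrogen_fraction Heartwood N concentration relative to
#'   sapwood, in \[0, 1\].
#' @return An object of class `tree_spec`.
#' @examples
#' tree_spec(scaling_params("pine"), L = 10)
#' tree_spec(scaling_params("pine"), L = 10, r_sw_max = 0.02)
#' @export
tree_spec <- function(params, L, L0 = 0.1, r_sw_max = Inf,
                      hw_nitrogen_fraction = 0) {
  stopifnot(inherits(params, "scaling_params"))
  if (!is.finite(L) || L <= 0) stop("L must be a positive height in metres")
  if (L0 <= 0 || L0 >= L) stop("need 0 < L0 < L")
  if (r_sw_max <= 0) stop("r_sw_max must be positive (Inf for no heartwood)")
  if (hw_nitrogen_fraction < 0 || hw_nitrogen_fraction > 1)
    stop("hw_nitrogen_fraction must lie in [0, 1]")
  structure(list(params = params, L = L, L0 = L0, r_sw_max = r_sw_max,
                 hw_nitrogen_fraction = hw_nitrogen_fraction),
            class = "tree_spec")
}

#' @export
print.tree_spec <- function(x, ...) {
  hw <- if (is.finite(x$r_sw_max))
    sprintf("sapwood depth capped at %.3g m", x$r_sw_max) else "no heartwood"
  cat(sprintf("tree_spec: %s, L = %.3g m (L0 = %.3g m), %s\n",
              x$params$species, x$L, x$L0, hw))
  invisible(x)
}
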