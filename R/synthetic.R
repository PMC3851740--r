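#' Measured diameter-scaling coefficients for the four study species
#'
#' Power-law coefficients `P = B * d^E` (d in mm) relating branch/stem
#' properties to diameter for birch, pine, spruce and aspen, together with
#' the coefficient of determination of the original fits and the sample
#' sizes. Distance from apex is included as `x_apex` with `P` in mm.
#' These drive the synthetic measurement generator and serve as recovery
#' truth for the allometric fitters.
#'
#' @param species One of `"birch"`, `"pine"`, `"spruce"`, `"aspen"`.
#' @return A data.frame with columns `response`, `base`, `exponent`,
#'   `r_squared`, `n`.
#' @export
measurement_coefficients <- function(species = c("pine", "aspen", "birch",
                                                 "spruce")) {
  species <- match.arg(species)
  tab <- list(
    birch = list(A_b = c(0.45, 1.60, 0.98, 553),
                 A_x = c(0.67, 2.01, 0.999, 555),
                 A_p = c(0.32, 1.59, 0.99, 10),
                 rho_N_x = c(0.11, 0.21, 0.099, 4),
                 rho_N_p = c(7.1, -0.59, 0.86, 12),
                 x_apex = c(115, 1.00, 0.97, 370)),
    pine = list(A_b = c(0.38, 1.61, 0.88, 2050),
                A_x = c(0.82, 1.98, 0.999, 2052),
                A_p = c(0.75, 1.27, 0.98, 62),
                rho_N_x = c(2.02, -0.61, 0.86, 27),
                rho_N_p = c(1.4, -0.22, 0.73, 28),
                x_apex = c(61, 1.029, 0.97, 1168)),
    spruce = list(A_b = c(0.52, 1.59, 0.97, 1371),
                  A_x = c(0.55, 2.05, 0.999, 1372),
                  A_p = c(0.0086, 2.35, 0.93, 10),
                  rho_N_x = c(0.15, -0.021, 0.0033, 8),
                  rho_N_p = c(0.87, -0.10, 0.0387, 9),
                  x_apex = c(85, 0.98, 0.96, 1144)),
    aspen = list(A_b = c(0.61, 1.53, 0.97, 399),
                 A_x = c(0.71, 2.00, 0.999, 401),
                 A_p = c(0.99, 1.3, 0.94, 37),
                 rho_N_x = c(0.68, -0.34, 0.80, 9),
                 rho_N_p = c(22, -0.79, 0.90, 13),
                 x_apex = c(73, 1.05, 0.97, 483)))
  m <- do.call(rbind, tab[[species]])
  data.frame(response = rownames(m), base = m[, 1], exponent = m[, 2],
             r_squared = m[, 3], n = m[, 4], row.names = NULL)
}

#' Multiplicative noise level implied by a reported R-squared
#'
#' For a power law fitted on the log scale to log-uniform diameters on
#' `d_range`, the residual log-variance that reproduces a coefficient of
#' determination `r2` is `E^2 * var(log d) * (1/r2 - 1)`. Returns the
#' lognormal `sdlog` for the multiplicative noise factor.
#'
#' @param exponent Power-law exponent of the response.
#' @param r2 Target coefficient of determination, in (0, 1].
#' @param d_range Diameter range (mm) sampled log-uniformly.
#' @return Lognormal standard deviation (sdlog) of the noise factor.
#' @export
noise_sdlog_for_r2 <- function(exponent, r2, d_range = c(0.9, 276.2)) {
  if (any(r2 <= 0) || any(r2 > 1)) stop("r2 must be in (0, 1]")
  var_ld <- diff(log(d_range))^2 / 12
  sqrt(pmax(exponent^2 * var_ld * (1 / r2 - 1), 0))
}

#' Generate a synthetic branch/stem measurement table
#'
#' Emulates the statistical structure of a harvested-tree segment dataset:
#' diameters drawn log-uniformly over `d_range` (the measured distribution
#' is strongly right-skewed), each response generated from its species
#' power law `B * d^E` times a multiplicative lognormal factor with median
#' 1. The per-response noise levels default to the values implied by the
#' reported fit R-squared of each relation (see [noise_sdlog_for_r2()]);
#' pass `noise_cv = 0` for noiseless data.
#'
#' Whole-bark nitrogen concentration is generated from the living-bark law
#' damped by a periderm dilution factor of 0.9 (no fitted relation is
#' available for it); under-bark diameter is derived from the over-bark
#' diameter and the generated bark area. Consistency (`A_p <= A_b`,
#' nitrogen fractions inside (0, 100)) is enforced by adjusting the bark
#' area and clipping the fractions; the responses used for fit-recovery
#' (`A_x`, `A_p`, `rho_N_*`, `x_apex`) are left exactly on their laws.
#'
#' @param n Number of segment records (>= 1).
#' @param species Species label, see [measurement_coefficients()].
#' @param d_range Diameter range (mm), min > 0.
#' @param noise_cv Either `NULL` (default: per-response noise implied by the
#'   reported R-squared), a single coefficient of variation applied to all
#'   responses, or a named vector with entries among
#'   `A_b, A_x, A_p, rho_N_x, rho_N_p, x_apex`.
#' @param seed Optional integer; fixing it makes the dataset reproducible.
#' @return A data.frame with one row per segment: `species`,
#'   `d_over_bark`, `d_under_bark` (mm), `A_x`, `A_b`, `A_p` (mm^2),
#'   `x_apex` (mm), `rho_N_x`, `rho_N_p`, `rho_N_bark` (%).
#' @examples
#' seg <- generate_segments(100, "pine", seed = 1)
#' head(seg)
#' @export
generate_segments <- function(n, species = "pine", d_range = c(0.9, 276.2),
                              noise_cv = NULL, seed = NULL) {
  if (length(n) != 1L || n < 1) stop("n must be a positive count")
  if (length(d_range) != 2L || d_range[1] <= 0 || d_range[2] <= d_range[1])
    stop("d_range must be an increasing positive pair (mm)")
  if (!is.null(noise_cv) && any(noise_cv < 0))
    stop("noise_cv must be nonnegative")
  co <- measurement_coefficients(species)
  rownames(co) <- co$response
  if (!is.null(seed)) set.seed(seed)

  sdlog <- if (is.null(noise_cv)) {
    stats::setNames(noise_sdlog_for_r2(co$exponent, co$r_squared, d_range),
                    co$response)
  } else if (is.null(names(noise_cv))) {
    stats::setNames(rep(sqrt(log(1 + noise_cv[1]^2)), nrow(co)), co$response)
  } else {
    s <- stats::setNames(rep(0, nrow(co)), co$response)
    bad <- setdiff(names(noise_cv), co$response)
    if (length(bad)) stop("unknown response in noise_cv: ",
                          paste(bad, collapse = ", "))
    s[names(noise_cv)] <- sqrt(log(1 + noise_cv^2))
    s
  }

  d <- exp(stats::runif(n, log(d_range[1]), log(d_range[2])))
  gen <- function(resp) {
    co[resp, "base"] * d^co[resp, "exponent"] *
      exp(stats::rnorm(n, 0, sdlog[[resp]]))
  }
  A_x <- gen("A_x"); A_p <- gen("A_p")
  ## the bark contains the phloem: raise A_b where the independently
  ## generated laws would cross (they do at small d, where the phloem and
  ## bark relations were fitted on different subsamples)
  A_b <- pmax(gen("A_b"), A_p)
  rho_N_x <- pmin(pmax(gen("rho_N_x"), 1e-3), 99.9)
  rho_N_p <- pmin(pmax(gen("rho_N_p"), 1e-3), 99.9)
  rho_N_bark <- pmin(pmax(0.9 * rho_N_p *
                            exp(stats::rnorm(n, 0, sdlog[["rho_N_p"]] / 3)),
                          1e-3), 99.9)
  x_apex <- gen("x_apex")
  d_under <- sqrt(pmax(d^2 - 4 * A_b / pi, (0.2 * d)^2))
  data.frame(species = species, d_over_bark = d, d_under_bark = d_under,
             A_x = A_x, A_b = A_b, A_p = A_p, x_apex = x_apex,
             rho_N_x = rho_N_x, rho_N_p = rho_N_p, rho_N_bark = rho_N_bark)
}

#' Write / read a segment measurement table
#'
#' Plain CSV with the [generate_segments()] column layout.
#'
#' @param segments A segment data.frame.
#' @param path File path.
#' @return `read_segments` returns the data.frame; `write_segments` its
#'   path, invisibly.
#' @export
write_segments <- function(segments, path) {
  utils::write.csv(segments, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
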