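#' Fit a diameter power law to segment measurements
#'
#' Fits `P = B * d^E` for one response column against diameter. Two
#' estimators are exposed because they answer to different residual
#' assumptions and give somewhat different exponents on real data:
#'
#' * `"raw"` (default): nonlinear least squares on the raw scale
#'   (Levenberg-Marquardt via \pkg{minpack.lm}), initialised from the
#'   log-scale estimate. Appropriate when absolute errors are homoscedastic.
#' * `"ln"`: ordinary least squares of `log(P)` on `log(d)`. Appropriate
#'   for multiplicative errors; this is also the scale on which species are
#'   compared.
#'
#' R-squared is reported on the fitted scale (raw for `"raw"`, log for
#' `"ln"`); the p-value is the t-test of the exponent.
#'
#' @param data Segment data.frame (e.g. from [generate_segments()]).
#' @param response Name of the response column.
#' @param method `"raw"` or `"ln"`.
#' @param diameter Name of the diameter column (mm).
#' @return An object of class `power_law_fit`: list with `base`,
#'   `exponent`, `r_squared`, `n`, `p_value`, `method`, `response`.
#' @examples
#' seg <- generate_segments(500, "pine", noise_cv = 0, seed = 1)
#' fit_power_law(seg, "A_x") # recovers (0.82, 1.98)
#' @export
fit_power_law <- function(data, response, method = c("raw", "ln"),
                          diameter = "d_over_bark") {
  method <- match.arg(method)
  if (!response %in% names(data)) stop("no column called ", response)
  d <- data[[diameter]]
  y <- data[[response]]
  keep <- is.finite(d) & is.finite(y)
  d <- d[keep]; y <- y[keep]
  if (length(y) < 3L) stop("need at least 3 records")
  if (any(d <= 0) || any(y <= 0))
    stop("diameters and responses must be positive")

  ## noiseless round-trips are a designed use case; keep summary() quiet
  ## about them
  quiet_summary <- function(obj) withCallingHandlers(
    summary(obj),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  lnfit <- stats::lm(log(y) ~ log(d))
  B0 <- exp(unname(stats::coef(lnfit)[1]))
  E0 <- unname(stats::coef(lnfit)[2])
  if (method == "ln") {
    sm <- quiet_summary(lnfit)
    out <- list(base = B0, exponent = E0, r_squared = sm$r.squared,
                n = length(y), p_value = sm$coefficients[2, 4],
                method = "ln-ols", response = response)
  } else {
    nls_fit <- tryCatch(
      minpack.lm::nlsLM(y ~ B * d^E, start = list(B = B0, E = E0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(nls_fit, "error")) {
      cond <- simpleError(paste0("raw-scale fit did not converge: ",
                                 conditionMessage(nls_fit)))
      cond$fallback <- list(base = B0, exponent = E0)
      class(cond) <- c("power_law_nonconvergence", class(cond))
      stop(cond)
    }
    cf <- stats::coef(nls_fit)
    r2 <- 1 - sum(stats::residuals(nls_fit)^2) / sum((y - mean(y))^2)
    out <- list(base = unname(cf["B"]), exponent = unname(cf["E"]),
                r_squared = r2, n = length(y),
                p_value = quiet_summary(nls_fit)$coefficients["E", 4],
                method = "raw-nonlinear", response = response)
  }
  class(out) <- "power_law_fit"
  out
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("%s: P = %.4g * d^%.4g  (R2 = %.4g, n = %d, p = %.3g, %s)\n",
              x$response, x$base, x$exponent, x$r_squared, x$n, x$p_value,
              x$method))
  invisible(x)
}

#' Fit all standard responses for one or more species tables
#'
#' Convenience wrapper producing a coefficient table shaped like a
#' measured-properties summary: one row per response and species.
#'
#' @param data Segment data.frame with a `species` column.
#' @param responses Response columns to fit.
#' @param method Passed to [fit_power_law()].
#' @return data.frame with `species`, `response`, `base`, `exponent`,
#'   `r_squared`, `p_value`, `n`.
#' @export
fit_allometry_table <- function(data,
                                responses = c("A_b", "A_x", "A_p",
                                              "rho_N_x", "rho_N_p", "x_apex"),
                                method = "raw") {
  rows <- list()
  for (sp in unique(data$species)) {
    sub <- data[data$species == sp, , drop = FALSE]
    for (resp in intersect(responses, names(sub))) {
      f <- fit_power_law(sub, resp, method = method)
      rows[[length(rows) + 1L]] <-
        data.frame(species = sp, response = resp, base = f$base,
                   exponent = f$exponent, r_squared = f$r_squared,
                   p_value = f$p_value, n = f$n)
    }
  }
  do.call(rbind, rows)
}

#' Compare diameter-scaling exponents between species
#'
#' Analysis of covariance on the log scale: fits a single linear model
#' `log(P) ~ species * log(d)` and reports all pairwise differences of the
#' species slopes (the power-law exponents) with t-test p-values
#' (unadjusted, plus a Holm-adjusted column).
#'
#' @param data Segment data.frame holding >= 2 species, each with >= 3
#'   records.
#' @param response Response column to compare.
#' @param diameter Diameter column (mm).
#' @return data.frame of class `slope_comparison` with columns `contrast`,
#'   `slope_difference`, `se`, `p_value`, `p_holm`.
#' @export
compare_species_slopes <- function(data, response,
                                   diameter = "d_over_bark") {
  sp <- factor(data$species)
  if (nlevels(sp) < 2L)
    stop("need at least two species to compare slopes")
  if (any(table(sp) < 3L)) stop("each species needs at least 3 records")
  df <- data.frame(ld = log(data[[diameter]]), ly = log(data[[response]]),
                   species = sp)
  if (any(!is.finite(df$ld)) || any(!is.finite(df$ly)))
    stop("diameters and responses must be positive")
  fit <- stats::lm(ly ~ species * ld, data = df)
  tr <- emmeans::emtrends(fit, "species", var = "ld")
  ctr <- summary(emmeans::contrast(tr, method = "pairwise", adjust = "none"))
  out <- data.frame(contrast = as.character(ctr$contrast),
                    slope_difference = ctr$estimate, se = ctr$SE,
                    p_value = ctr$p.value,
                    p_holm = stats::p.adjust(ctr$p.value, "holm"))
  class(out) <- c("slope_comparison", "data.frame")
  out
}
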