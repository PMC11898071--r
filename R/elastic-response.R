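# Young's modulus from a uniaxial tension -> mean-box-length series. The
# simulation producing <L>(sigma) is out of scope; the estimator and its
# synthetic exerciser are here.

#' Default uniaxial stress schedule
#'
#' The reference loading protocol: 0.1 MPa (the unstressed reference
#' defining L0), then 0.5-MPa steps up to 3 MPa, then 1-MPa steps to
#' 10 MPa.
#'
#' @return numeric vector of stresses (MPa), strictly increasing.
#' @export
schedule_default <- function() c(0.1, seq(0.5, 3, by = 0.5), seq(4, 10, by = 1))

#' Construct a stress-strain series
#'
#' @param sigma applied tensions (MPa), strictly increasing, starting at
#'   0.1 MPa (the reference state whose mean box length defines L0).
#' @param L mean box lengths along the stressed direction (nm).
#' @param se optional per-point standard errors of `L` (nm).
#' @return class `stress_strain`: data frame with columns `sigma`, `L`
#'   (and `se` if given).
#' @export
stress_strain_series <- function(sigma, L, se = NULL) {
  if (length(sigma) != length(L)) stop("sigma and L lengths differ")
  if (any(diff(sigma) <= 0)) stop("sigma must be strictly increasing")
  if (abs(sigma[1L] - 0.1) > 1e-9)
    stop("the series must start at the 0.1 MPa reference state")
  out <- data.frame(sigma = sigma, L = L)
  if (!is.null(se)) out$se <- se
  structure(out, class = c("stress_strain", "data.frame"))
}

#' Young's modulus from a stress-strain series
#'
#' Converts the series to relative strain `eps = (L - L0) / L0` with L0 the
#' mean length at the 0.1 MPa reference (that point stays in the
#' regression), fits `eps ~ sigma` by (weighted, if per-point errors are
#' given) least squares with a free intercept, and returns `Y = 1 / slope`
#' with the propagated standard error. The intercept and its error are kept
#' as a diagnostic: a large intercept signals a reference-state offset.
#'
#' @param series a [stress_strain_series()] (>= 4 points).
#' @return class `youngs_fit`: list with `Y` (MPa), `se` (MPa), `slope`,
#'   `intercept`, `intercept_se`, the underlying `lm` fit and the data.
#' @examples
#' s <- simulate_stress_strain(stress_strain_spec(Y_true = 200, noise_sd = 0))
#' young_modulus(s)$Y  # 200
#' @export
young_modulus <- function(series) {
  if (nrow(series) < 4L) stop("need at least 4 stress points")
  L0 <- series$L[which.min(abs(series$sigma - 0.1))]
  df <- data.frame(sigma = series$sigma, eps = (series$L - L0) / L0)
  w <- if (!is.null(series$se)) (L0 / series$se)^2 else NULL
  fit <- stats::lm(eps ~ sigma, data = df, weights = w)
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm["sigma", "Estimate"]
  if (slope <= 0) stop("no elastic response detected (non-positive slope)")
  se_slope <- sm["sigma", "Std. Error"]
  structure(list(Y = 1 / slope, se = se_slope / slope^2,
                 slope = slope, slope_se = se_slope,
                 intercept = sm["(Intercept)", "Estimate"],
                 intercept_se = sm["(Intercept)", "Std. Error"],
                 fit = fit, data = df, L0 = L0),
            class = "youngs_fit")
}

#' @export
print.youngs_fit <- function(x, ...) {
  cat(sprintf("Young's modulus: Y = %.4g +/- %.2g MPa\n", x$Y, x$se))
  invisible(x)
}

#' @export
summary.youngs_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  strain-stress slope %.4g +/- %.2g 1/MPa\n",
              object$slope, object$slope_se))
  cat(sprintf("  intercept %.3g +/- %.2g (diagnostic; ~0 for a clean series)\n",
              object$intercept, object$intercept_se))
  cat(sprintf("  L0 = %.4g nm, %d points\n", object$L0, nrow(object$data)))
  invisible(object)
}

#' @export
coef.youngs_fit <- function(object, ...) {
  c(Y = object$Y, slope = object$slope, intercept = object$intercept)
}

#' @export
predict.youngs_fit <- function(object, sigma, ...) {
  strain <- object$intercept + object$slope * sigma
  object$L0 * (1 + strain)
}

#' @export
residuals.youngs_fit <- function(object, ...) stats::residuals(object$fit)

#' @export
plot.youngs_fit <- function(x, ...) {
  graphics::plot(x$data$sigma, x$data$eps, xlab = expression(sigma ~ (MPa)),
                 ylab = expression(epsilon), ...)
  graphics::abline(x$intercept, x$slope, col = 2)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("Y = %.3g ± %.2g MPa", x$Y, x$se))
  invisible(x)
}
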