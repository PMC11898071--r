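# Water mobility: NPT-safe trajectory unwrapping (toroidal scheme), mean
# squared displacement and Einstein-relation diffusion estimates,
# displacement distributions at fixed lag, and maximum-likelihood fits of
# one- or two-population Brownian mixtures to displacement magnitudes.

#' Unwrap a trajectory by the toroidal scheme
#'
#' Computes the displacement between consecutive frames as the minimum-image
#' difference in the *current* frame's box and accumulates it. Under a
#' constant box this reduces to classical unwrapping; under a fluctuating
#' (barostat) box it avoids the spurious drift that position-based
#' unwrapping schemes accumulate. Requires every true inter-frame
#' displacement to stay below half the concurrent box length per axis.
#'
#' @param traj a `labeled_trajectory` with at least one frame.
#' @return an object of class `unwrapped_trajectory`: list with `time`,
#'   `box`, `coords` (continuous coordinates, nm), `labels` and a
#'   `provenance` flag naming the scheme.
#' @export
unwrap <- function(traj) {
  nf <- n_frames(traj)
  out <- vector("list", nf)
  out[[1L]] <- traj$coords[[1L]]
  if (nf > 1L) {
    for (f in 2L:nf) {
      box <- traj$box[f, ]
      d <- min_image(traj$coords[[f]], traj$coords[[f - 1L]], box)
      bad <- which(abs(d) >= matrix(box / 2, nrow(d), 3L, byrow = TRUE) - 1e-12,
                   arr.ind = TRUE)
      if (nrow(bad))
        stop("minimum-image displacement at frame ", f, ", site ", bad[1L, 1L],
             " reaches half the box length; frames too far apart to unwrap")
      out[[f]] <- out[[f - 1L]] + d
    }
  }
  structure(list(time = traj$time, box = traj$box, coords = out,
                 labels = traj$labels, provenance = "toroidal"),
            class = "unwrapped_trajectory")
}

#' Mean squared displacement with multiple time origins
#'
#' `MSD(lag) = < |r(t0 + lag) - r(t0)|^2 >` averaged over the selected sites
#' and over time origins spaced by `origin_stride` frames.
#'
#' @param unwrapped an `unwrapped_trajectory` from [unwrap()].
#' @param sel site selection (indices or population name resolved against
#'   the stored labels).
#' @param max_lag maximal lag in frames (default: all available).
#' @param origin_stride origin spacing in frames.
#' @return class `msd_curve`: data frame with `lag` (ps), `msd` (nm^2),
#'   `n_origins`.
#' @export
msd <- function(unwrapped, sel = NULL, max_lag = NULL, origin_stride = 1L) {
  nf <- length(unwrapped$coords)
  if (nf < 2L) stop("need at least 2 frames")
  if (is.null(sel)) sel <- seq_len(nrow(unwrapped$coords[[1L]]))
  if (is.character(sel)) sel <- which(unwrapped$labels$role == "water_O")
  if (is.null(max_lag)) max_lag <- nf - 1L
  if (max_lag > nf - 1L) stop("max_lag exceeds the trajectory length")
  dt <- unwrapped$time[2L] - unwrapped$time[1L]
  lags <- 0:max_lag
  msd_v <- numeric(length(lags)); nor <- integer(length(lags))
  xs <- lapply(unwrapped$coords, function(x) x[sel, , drop = FALSE])
  for (i in seq_along(lags)) {
    lg <- lags[i]
    if (lg == 0L) { msd_v[i] <- 0; nor[i] <- nf; next }
    origins <- seq(1L, nf - lg, by = origin_stride)
    acc <- 0
    for (t0 in origins) {
      d <- xs[[t0 + lg]] - xs[[t0]]
      acc <- acc + mean(rowSums(d * d))
    }
    msd_v[i] <- acc / length(origins)
    nor[i] <- length(origins)
  }
  structure(data.frame(lag = lags * dt, msd = msd_v, n_origins = nor),
            class = c("msd_curve", "data.frame"))
}

#' @export
plot.msd_curve <- function(x, ...) {
  graphics::plot(x$lag, x$msd, type = "b", xlab = "lag (ps)",
                 ylab = expression(MSD ~ (nm^2)), ...)
  invisible(x)
}

#' Diffusion coefficient from the Einstein relation
#'
#' Least-squares slope of MSD versus lag over a fit window, `D = slope / 6`
#' (3-D). Warns -- without failing -- when a quadratic term is significant at
#' two standard errors over the window (MSD detectably nonlinear, as happens
#' at short lags in crowded systems); a negative slope is clipped to zero
#' with a warning.
#'
#' @param curve an `msd_curve`.
#' @param window length-2 lag window (ps); default: the last half of the
#'   curve.
#' @return list of class `diffusion_estimate`: `D` (cm^2/s), `se`, `window`,
#'   `nonlinear` flag.
#' @export
diffusion_coefficient <- function(curve, window = NULL) {
  if (is.null(window)) window <- c(max(curve$lag) / 2, max(curve$lag))
  pts <- curve[curve$lag >= window[1L] & curve$lag <= window[2L], , drop = FALSE]
  if (nrow(pts) < 4L) stop("fit window must contain at least 4 points")
  fit <- stats::lm(msd ~ lag, data = pts)
  slope <- stats::coef(fit)[["lag"]]
  # suppress lm's "essentially perfect fit" chatter on noiseless curves
  se <- suppressWarnings(summary(fit)$coefficients["lag", "Std. Error"])
  nonlinear <- FALSE
  if (nrow(pts) >= 5L) {
    fq <- stats::lm(msd ~ lag + I(lag^2), data = pts)
    cq <- suppressWarnings(summary(fq)$coefficients)
    if ("I(lag^2)" %in% rownames(cq) && is.finite(cq["I(lag^2)", "Std. Error"]) &&
        cq["I(lag^2)", "Std. Error"] > 0 &&
        abs(cq["I(lag^2)", "Estimate"]) > 2 * cq["I(lag^2)", "Std. Error"]) {
      nonlinear <- TRUE
      warning("MSD is detectably nonlinear over the fit window")
    }
  }
  if (slope < 0) {
    warning("negative MSD slope; D clipped at 0")
    slope <- 0
  }
  structure(list(D = slope / 6 * D_NM2PS_TO_CM2S,
                 se = se / 6 * D_NM2PS_TO_CM2S,
                 window = window, nonlinear = nonlinear),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D = %.4g +/- %.2g cm^2/s (window %g..%g ps)%s\n", x$D, x$se,
              x$window[1L], x$window[2L],
              if (x$nonlinear) " [nonlinear MSD]" else ""))
  invisible(x)
}

#' Displacement magnitudes at a fixed lag
#'
#' `|r(t0 + t) - r(t0)|` for every selected molecule and every time origin.
#' Origins default to non-overlapping spacing (stride = lag) to limit
#' correlation between samples.
#'
#' @param unwrapped an `unwrapped_trajectory`.
#' @param sel site selection.
#' @param t lag (ps); must be a multiple of the frame spacing.
#' @param origin_stride origin spacing in frames; default: the lag itself.
#' @return a `displacement_sample` (fields `r`, `t`, `molecule`, `origin`).
#' @export
displacement_distribution <- function(unwrapped, sel = NULL, t,
                                      origin_stride = NULL) {
  nf <- length(unwrapped$coords)
  dt <- unwrapped$time[2L] - unwrapped$time[1L]
  lg <- t / dt
  if (abs(lg - round(lg)) > 1e-9) stop("t must be a multiple of the frame spacing")
  lg <- as.integer(round(lg))
  if (lg < 1L || lg > nf - 1L) stop("lag outside the trajectory")
  if (is.null(sel)) sel <- seq_len(nrow(unwrapped$coords[[1L]]))
  if (is.null(origin_stride)) origin_stride <- lg
  origins <- seq(1L, nf - lg, by = origin_stride)
  rs <- vector("list", length(origins))
  for (i in seq_along(origins)) {
    t0 <- origins[i]
    d <- unwrapped$coords[[t0 + lg]][sel, , drop = FALSE] -
         unwrapped$coords[[t0]][sel, , drop = FALSE]
    rs[[i]] <- sqrt(rowSums(d * d))
  }
  structure(list(r = unlist(rs), t = t,
                 molecule = rep(sel, length(origins)),
                 origin = rep(origins, each = length(sel))),
            class = "displacement_sample")
}

#' @export
print.displacement_sample <- function(x, ...) {
  cat("Displacement sample: n =", length(x$r), "at lag t =", x$t, "ps\n")
  cat("  mean r =", signif(mean(x$r), 4), "nm; mean r^2 =",
      signif(mean(x$r^2), 4), "nm^2\n")
  invisible(x)
}

# negative log-likelihood of the radial mixture in transformed parameters
# theta = (log Dnm_1, ..., log Dnm_k, logit w_1..k-1); Dnm in nm^2/ps.
.mix_nll <- function(theta, r, t, k, convention) {
  Dnm <- exp(theta[seq_len(k)])
  w <- if (k == 1L) 1 else {
    z <- c(theta[(k + 1L):(2L * k - 1L)], 0)
    ez <- exp(z - max(z)); ez / sum(ez)
  }
  dens <- dbrownian_r(r, D = Dnm * D_NM2PS_TO_CM2S, w = w, t = t,
                      convention = convention)
  -sum(log(pmax(dens, 1e-300)))
}

#' Fit a Brownian mixture to displacement magnitudes
#'
#' Maximum-likelihood fit of a one- or two-population Brownian propagator
#' mixture to radial displacement magnitudes at a fixed lag. A single
#' Brownian population rarely represents gel water: the short-displacement
#' tail demands a second, slow population of molecules bound to the chains.
#' The fit reports both populations' diffusion coefficients and weights,
#' ordered fast to slow, with standard errors from the observed information
#' (delta method), so the single- versus two-population comparison can be
#' made by likelihood ratio.
#'
#' Optimisation is multi-start (default 5 seeded starts over dispersed
#' initial D ratios) to dodge local optima. A binned least-squares mode
#' (`method = "ls"`) is available for figure-style comparisons, as is a
#' per-coordinate (non-radial) density convention.
#'
#' @param sample a `displacement_sample`.
#' @param n_components 1 or 2.
#' @param convention `"radial"` (default; includes the 4 pi r^2 Jacobian)
#'   or `"per_coordinate"`.
#' @param method `"ml"` (maximum likelihood) or `"ls"` (least squares on a
#'   100-bin histogram density).
#' @param n_starts number of optimiser starts.
#' @param seed seed for the start dispersion.
#' @return an object of class `brownian_mixture` with components `D`
#'   (cm^2/s, fast first), `w`, `se_D`, `se_w`, `logLik`, `n`, `t`,
#'   `convention`, `method`, `convergence`.
#' @examples
#' sp <- brownian_spec(data.frame(D = c(1.93e-5, 2.30e-6), weight = c(0.85, 0.15)),
#'                     n_walkers = 5000)
#' s <- displacement_samples(sp, t = 30)
#' fit <- fit_brownian(s, n_components = 2)
#' coef(fit)
#' @export
fit_brownian <- function(sample, n_components = 2L,
                         convention = c("radial", "per_coordinate"),
                         method = c("ml", "ls"), n_starts = 5L, seed = 1L) {
  convention <- match.arg(convention)
  method <- match.arg(method)
  k <- as.integer(n_components)
  stopifnot(k %in% c(1L, 2L))
  r <- sample$r[sample$r > 0]
  n <- length(r)
  if (n < 10L) stop("too few displacement magnitudes to fit")
  t <- sample$t
  D0 <- mean(r^2) / (6 * t)  # moment estimate, nm^2/ps
  if (method == "ls") return(.fit_brownian_ls(r, t, k, convention, D0))
  if (k == 1L) {
    starts <- list(log(D0))
  } else {
    ratios <- with_seed(seed, {
      base <- c(3, 10, 30, 100, 300)
      if (n_starts <= length(base)) base[seq_len(n_starts)]
      else c(base, stats::runif(n_starts - length(base), 3, 300))
    })
    starts <- lapply(ratios, function(rt) {
      c(log(D0 * 1.5), log(D0 * 1.5 / rt), stats::qlogis(0.8) - 0)
    })
  }
  best <- NULL
  for (st in starts) {
    opt <- try(stats::optim(st, .mix_nll, r = r, t = t, k = k,
                            convention = convention, method = "BFGS",
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value - 1e-9) best <- opt
  }
  if (is.null(best))
    stop("Brownian mixture fit failed to converge after ", length(starts),
         " starts; inspect the sample (n = ", n, ", t = ", t, " ps)")
  H <- stats::optimHess(best$par, .mix_nll, r = r, t = t, k = k,
                        convention = convention)
  cov_theta <- try(solve(H), silent = TRUE)
  if (inherits(cov_theta, "try-error") || any(!is.finite(cov_theta)))
    cov_theta <- matrix(NA_real_, length(best$par), length(best$par))
  Dnm <- exp(best$par[seq_len(k)])
  if (k == 1L) {
    w <- 1
    se_D <- sqrt(diag(cov_theta))[1L] * Dnm   # delta method on log scale
    se_w <- 0
  } else {
    z <- best$par[3L]
    w1 <- stats::plogis(z)
    w <- c(w1, 1 - w1)
    # delta method: d(D_i)/d(theta_i) = D_i; d(w1)/dz = w1(1-w1)
    J <- matrix(0, 3L, 3L)
    J[1L, 1L] <- Dnm[1L]; J[2L, 2L] <- Dnm[2L]; J[3L, 3L] <- w1 * (1 - w1)
    cov_p <- J %*% cov_theta %*% t(J)
    se_D <- sqrt(pmax(diag(cov_p)[1:2], 0))
    se_w <- sqrt(max(diag(cov_p)[3L], 0))
    se_w <- c(se_w, se_w)
  }
  ord <- order(-Dnm)
  obj <- list(D = (Dnm * D_NM2PS_TO_CM2S)[ord], w = w[ord],
              se_D = (se_D * D_NM2PS_TO_CM2S)[ord],
              se_w = if (k == 1L) 0 else se_w[ord],
              logLik = -best$value, n = n, t = t,
              convention = convention, method = method,
              convergence = best$convergence)
  class(obj) <- "brownian_mixture"
  obj
}

# binned least-squares mode: fit the model density to a histogram
.fit_brownian_ls <- function(r, t, k, convention, D0) {
  h <- graphics::hist(r, breaks = 100, plot = FALSE)
  mid <- h$mids; dens <- h$density
  ssr_fun <- function(theta) {
    w <- if (k == 1L) 1 else {
      w1 <- stats::plogis(theta[3L]); c(w1, 1 - w1)
    }
    sum((dens - dbrownian_r(mid, D = exp(theta[seq_len(k)]) * D_NM2PS_TO_CM2S,
                            w = w, t = t, convention = convention))^2)
  }
  st <- if (k == 1L) log(D0) else c(log(D0 * 1.5), log(D0 / 10), stats::qlogis(0.8))
  opt <- stats::optim(st, ssr_fun, method = "BFGS", control = list(maxit = 500))
  Dnm <- exp(opt$par[seq_len(k)])
  w <- if (k == 1L) 1 else { w1 <- stats::plogis(opt$par[3L]); c(w1, 1 - w1) }
  ord <- order(-Dnm)
  structure(list(D = (Dnm * D_NM2PS_TO_CM2S)[ord], w = w[ord],
                 se_D = rep(NA_real_, k), se_w = rep(NA_real_, k),
                 logLik = NA_real_, SSR = opt$value, n = length(r), t = t,
                 convention = convention, method = "ls",
                 convergence = opt$convergence),
            class = "brownian_mixture")
}

#' @export
print.brownian_mixture <- function(x, ...) {
  cat("Brownian mixture fit (", length(x$D), " component(s), ", x$method,
      ", ", x$convention, " convention), n = ", x$n, ", t = ", x$t, " ps\n",
      sep = "")
  for (i in seq_along(x$D))
    cat(sprintf("  D%d = %.4g cm^2/s (se %.2g), w%d = %.3f (se %.2g)\n",
                i, x$D[i], x$se_D[i], i, x$w[i], x$se_w[i]))
  if (is.finite(x$logLik)) cat("  logLik =", signif(x$logLik, 8), "\n")
  invisible(x)
}

#' @export
summary.brownian_mixture <- function(object, ...) {
  print(object)
  cat("  weighted mean D =", signif(weighted_D(object), 5), "cm^2/s\n")
  invisible(object)
}

#' @export
coef.brownian_mixture <- function(object, ...) {
  stats::setNames(c(object$D, object$w),
                  c(paste0("D", seq_along(object$D)),
                    paste0("w", seq_along(object$w))))
}

#' @export
logLik.brownian_mixture <- function(object, ...) {
  val <- object$logLik
  attr(val, "df") <- 2L * length(object$D) - 1L
  attr(val, "nobs") <- object$n
  class(val) <- "logLik"
  val
}

#' @export
predict.brownian_mixture <- function(object, r, type = c("density", "cdf"), ...) {
  type <- match.arg(type)
  f <- if (type == "density") dbrownian_r else pbrownian_r
  f(r, D = object$D, w = object$w, t = object$t, convention = object$convention)
}

#' @export
plot.brownian_mixture <- function(x, sample = NULL, ...) {
  if (!is.null(sample)) {
    h <- graphics::hist(sample$r, breaks = 80, freq = FALSE,
                        xlab = "r (nm)", main = "Displacement distribution", ...)
    rr <- seq(0, max(sample$r), length.out = 400)
  } else {
    sig <- sqrt(2 * max(x$D) * D_CM2S_TO_NM2PS * x$t)
    rr <- seq(0, 4 * sig, length.out = 400)
    graphics::plot(rr, predict(x, rr), type = "n", xlab = "r (nm)",
                   ylab = "p(r)", main = "Fitted displacement density", ...)
  }
  graphics::lines(rr, predict(x, rr), col = 2, lwd = 2)
  invisible(x)
}

#' @export
simulate.brownian_mixture <- function(object, nsim = 1, seed = NULL, ...) {
  sp <- brownian_spec(data.frame(D = object$D, weight = object$w),
                      n_walkers = nsim, seed = seed %||% 1L)
  displacement_samples(sp, t = object$t)
}

#' Posterior fast/slow population assignment
#'
#' Given a two-component fit, computes each molecule's posterior probability
#' of belonging to the fast component (responsibilities multiplied across
#' that molecule's displacement observations) and labels it by the maximum.
#' The fraction labelled fast approximates the fitted fast weight.
#'
#' @param sample a `displacement_sample` carrying `molecule` ids.
#' @param fit a two-component `brownian_mixture`.
#' @return data frame with `molecule`, `p_fast`, `label` ("fast"/"slow").
#' @export
assign_populations <- function(sample, fit) {
  if (length(fit$D) != 2L)
    stop("population assignment requires a two-component fit")
  d1 <- fit$w[1L] * dbrownian_r(sample$r, fit$D[1L], 1, sample$t, fit$convention)
  d2 <- fit$w[2L] * dbrownian_r(sample$r, fit$D[2L], 1, sample$t, fit$convention)
  l1 <- log(pmax(d1, 1e-300)); l2 <- log(pmax(d2, 1e-300))
  s1 <- rowsum(l1, sample$molecule); s2 <- rowsum(l2, sample$molecule)
  p <- 1 / (1 + exp(s2 - s1))
  data.frame(molecule = as.integer(rownames(s1)),
             p_fast = as.numeric(p),
             label = ifelse(p >= 0.5, "fast", "slow"))
}

#' Population-weighted mean diffusion coefficient
#'
#' The overall diffusion coefficient implied by a mixture fit: the average
#' of the component coefficients weighted by their population fractions.
#'
#' @param fit a `brownian_mixture`.
#' @return numeric, cm^2/s.
#' @examples
#' # 85/15 fast/slow mixture:
#' # 0.85 * 1.93e-5 + 0.15 * 2.30e-6 = 1.675e-5
#' @export
weighted_D <- function(fit) sum(fit$w * fit$D)
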