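# Ground-truth generators: Brownian walkers (single or mixed populations),
# reference lattices (simple cubic, ice-like, ideal gas), and noisy linear
# stress-strain series. Every generator is reproducible under its seed and
# records its ground truth so downstream estimators can be validated.

# 1 cm^2/s = 100 nm^2/ps; diffusion coefficients cross this boundary a lot.
D_CM2S_TO_NM2PS <- 100
D_NM2PS_TO_CM2S <- 0.01

#' Specification of Brownian walker dynamics
#'
#' @param components data frame (or list coercible to one) with columns `D`
#'   (diffusion coefficient, cm^2/s) and `weight` (population fraction,
#'   summing to 1).
#' @param n_walkers number of walkers.
#' @param dt frame spacing (ps).
#' @param n_frames number of frames.
#' @param box length-3 box (nm) or NULL for unbounded walkers.
#' @param breathing fractional sinusoidal box-length modulation amplitude
#'   (one period over the trajectory), mimicking NPT barostat fluctuation;
#'   wrapped positions are affinely rescaled with the box.
#' @param seed RNG seed.
#' @export
brownian_spec <- function(components, n_walkers = 1000L, dt = 1, n_frames = 31L,
                          box = NULL, breathing = 0, seed = 1L) {
  components <- as.data.frame(components)
  stopifnot(all(c("D", "weight") %in% names(components)))
  if (any(components$D < 0)) stop("diffusion coefficients must be >= 0")
  if (abs(sum(components$weight) - 1) > 1e-9) stop("component weights must sum to 1")
  if (dt <= 0 || n_frames < 1L) stop("dt must be > 0 and n_frames >= 1")
  structure(list(components = components, n_walkers = as.integer(n_walkers),
                 dt = dt, n_frames = as.integer(n_frames), box = box,
                 breathing = breathing, seed = as.integer(seed)),
            class = "brownian_spec")
}

#' Generate a Brownian-walker trajectory
#'
#' Walkers are assigned to mixture components by weight; each frame adds
#' independent Gaussian steps of per-axis variance `2 * D * dt`. If a box is
#' given the stored coordinates are wrapped (and affinely rescaled when box
#' breathing is on); the pre-wrap ground-truth path and the per-walker
#' component ids are kept as attributes `true_coords` and `component`.
#'
#' @param spec a [brownian_spec()].
#' @return a [labeled_trajectory()] of `water_O` sites.
#' @export
brownian_trajectory <- function(spec) {
  nw <- spec$n_walkers
  nf <- spec$n_frames
  comp_n <- nrow(spec$components)
  sd_step <- sqrt(2 * spec$components$D * D_CM2S_TO_NM2PS * spec$dt)
  res <- with_seed(spec$seed, {
    comp <- if (comp_n == 1L) rep(1L, nw) else
      sample.int(comp_n, nw, replace = TRUE, prob = spec$components$weight)
    x0 <- if (is.null(spec$box)) matrix(0, nw, 3L) else
      cbind(runif(nw, 0, spec$box[1L]), runif(nw, 0, spec$box[2L]),
            runif(nw, 0, spec$box[3L]))
    true <- vector("list", nf)
    true[[1L]] <- x0
    for (f in seq_len(nf - 1L)) {
      step <- matrix(stats::rnorm(nw * 3L, 0, sd_step[comp]), nw, 3L)
      true[[f + 1L]] <- true[[f]] + step
    }
    list(comp = comp, true = true)
  })
  if (is.null(spec$box)) {
    span <- range(unlist(res$true))
    L <- rep(diff(span) + 2, 3L)
    shift <- -span[1L] + 1
    box <- matrix(L, nf, 3L, byrow = TRUE)
    coords <- lapply(res$true, function(x) x + shift)
    res$true <- coords
  } else {
    s <- 1 + spec$breathing * sin(2 * pi * (seq_len(nf) - 1L) / nf)
    box <- outer(s, spec$box)
    coords <- lapply(seq_len(nf), function(f) res$true[[f]] * s[f])
  }
  lab <- site_labels(rep("O", nw), rep("water_O", nw))
  out <- labeled_trajectory(coords, box = box, labels = lab,
                            time = (seq_len(nf) - 1L) * spec$dt)
  attr(out, "true_coords") <- res$true
  attr(out, "component") <- res$comp
  out
}

#' Draw radial displacement magnitudes from a Brownian mixture
#'
#' Samples i.i.d. displacement magnitudes from the mixture of 3-D Gaussian
#' propagators
#' \deqn{p(r) = \sum_i w_i \, 4\pi r^2 (4\pi D_i t)^{-3/2} e^{-r^2/(4 D_i t)},}
#' the distribution of the distance travelled in time `t` by a particle
#' diffusing with coefficient `D_i`.
#'
#' @param spec a [brownian_spec()]; `n_walkers` sets the sample size.
#' @param t lag time (ps), > 0.
#' @return a `displacement_sample`: list with `r` (nm), `t`, `molecule` ids
#'   and the ground-truth `component` assignment.
#' @examples
#' sp <- brownian_spec(data.frame(D = 1.93e-5, weight = 1), n_walkers = 1000)
#' s <- displacement_samples(sp, t = 30)
#' mean(s$r^2) / (6 * 30) * 0.01  # ~ 1.93e-5 cm^2/s
#' @export
displacement_samples <- function(spec, t) {
  if (t <= 0) stop("t must be > 0")
  n <- spec$n_walkers
  comp_n <- nrow(spec$components)
  sig <- sqrt(2 * spec$components$D * D_CM2S_TO_NM2PS * t)  # per-axis sd, nm
  res <- with_seed(spec$seed, {
    comp <- if (comp_n == 1L) rep(1L, n) else
      sample.int(comp_n, n, replace = TRUE, prob = spec$components$weight)
    dx <- matrix(stats::rnorm(3L * n, 0, sig[comp]), n, 3L)
    list(comp = comp, r = sqrt(rowSums(dx^2)))
  })
  structure(list(r = res$r, t = t, molecule = seq_len(n), component = res$comp),
            class = "displacement_sample")
}

#' Mixture density and distribution of radial Brownian displacements
#'
#' Closed forms for the radial (Maxwell-type) displacement-magnitude
#' distribution of a Brownian mixture; used as the fit model and as an
#' independent check on the sampler.
#'
#' @param r displacement magnitudes (nm).
#' @param D diffusion coefficients (cm^2/s), one per component.
#' @param w component weights.
#' @param t lag time (ps).
#' @param convention `"radial"` (includes the 4 pi r^2 Jacobian) or
#'   `"per_coordinate"` (half-normal magnitude of a 1-D Gaussian step).
#' @return density (`dbrownian_r`) or CDF (`pbrownian_r`) values.
#' @export
dbrownian_r <- function(r, D, w = rep(1 / length(D), length(D)), t,
                        convention = c("radial", "per_coordinate")) {
  convention <- match.arg(convention)
  sig2 <- 2 * D * D_CM2S_TO_NM2PS * t  # per-axis variance, nm^2
  out <- numeric(length(r))
  for (i in seq_along(D)) {
    out <- out + w[i] * switch(convention,
      radial = sqrt(2 / pi) * r^2 / sig2[i]^1.5 * exp(-r^2 / (2 * sig2[i])),
      per_coordinate = sqrt(2 / (pi * sig2[i])) * exp(-r^2 / (2 * sig2[i])))
  }
  out
}

#' @rdname dbrownian_r
#' @export
pbrownian_r <- function(r, D, w = rep(1 / length(D), length(D)), t,
                        convention = c("radial", "per_coordinate")) {
  convention <- match.arg(convention)
  sig <- sqrt(2 * D * D_CM2S_TO_NM2PS * t)
  out <- numeric(length(r))
  for (i in seq_along(D)) {
    z <- r / sig[i]
    out <- out + w[i] * switch(convention,
      radial = stats::pchisq(z^2, df = 3),
      per_coordinate = 2 * stats::pnorm(z) - 1)
  }
  out
}

#' Reference lattice and gas configurations
#'
#' Single-frame oxygen configurations with known structure, used as targets
#' for the structure-factor and rdf machinery: a simple-cubic lattice
#' (rdf/S(k) peaks at the spacing and its reciprocal), an ice-like lattice
#' (wurtzite-topology tetrahedral network whose six-ring correlation shell
#' sits at `nn * sqrt(8/3)`; the default `nn = 0.297` nm places it at the
#' 4.85 A reference periodicity, with the crystallographic ice value 0.276
#' nm available by argument), and an ideal gas (uniform random points).
#'
#' @param kind `"sc"`, `"ice_like"` or `"ideal_gas"`.
#' @param box requested length-3 box (nm); for lattices the returned box is
#'   rounded to a whole number of cells.
#' @param spacing simple-cubic lattice spacing (nm).
#' @param nn nearest-neighbour O-O distance of the ice-like lattice (nm).
#' @param n number of ideal-gas particles.
#' @param seed RNG seed (ideal gas only).
#' @return a single-frame [labeled_trajectory()] of `water_O` sites.
#' @export
lattice_config <- function(kind = c("sc", "ice_like", "ideal_gas"), box,
                           spacing = 0.31, nn = 0.297, n = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "sc") {
    reps <- floor(box / spacing)
    if (any(reps < 1)) stop("box too small for the requested spacing")
    pts <- as.matrix(expand.grid(
      (seq_len(reps[1L]) - 0.5) * spacing,
      (seq_len(reps[2L]) - 0.5) * spacing,
      (seq_len(reps[3L]) - 0.5) * spacing))
    box_out <- reps * spacing
  } else if (kind == "ice_like") {
    a <- nn * sqrt(8 / 3)
    cell <- c(a, a * sqrt(3), a * sqrt(8 / 3))
    frac <- rbind(c(0, 0, 0), c(0, 1 / 3, 1 / 2), c(0, 0, 3 / 8), c(0, 1 / 3, 7 / 8),
                  c(1 / 2, 1 / 2, 0), c(1 / 2, 5 / 6, 1 / 2),
                  c(1 / 2, 1 / 2, 3 / 8), c(1 / 2, 5 / 6, 7 / 8))
    reps <- pmax(1L, round(box / cell))
    base <- sweep(frac, 2L, cell, "*")
    shifts <- as.matrix(expand.grid((seq_len(reps[1L]) - 1L) * cell[1L],
                                    (seq_len(reps[2L]) - 1L) * cell[2L],
                                    (seq_len(reps[3L]) - 1L) * cell[3L]))
    pts <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(s)
      sweep(base, 2L, shifts[s, ], "+")))
    box_out <- reps * cell
  } else {
    if (is.null(n) || n < 1L) stop("ideal_gas requires n >= 1")
    pts <- with_seed(seed, cbind(runif(n, 0, box[1L]), runif(n, 0, box[2L]),
                                 runif(n, 0, box[3L])))
    box_out <- box
  }
  lab <- site_labels(rep("O", nrow(pts)), rep("water_O", nrow(pts)))
  labeled_trajectory(pts, box = box_out, labels = lab, time = 0)
}

#' Specification of a synthetic uniaxial stress-strain experiment
#'
#' @param Y_true ground-truth Young's modulus (MPa), > 0.
#' @param L0 unstressed box side (nm).
#' @param sigma stress schedule (MPa); defaults to [schedule_default()] and
#'   must start at 0.1 MPa (the reference state defining L0).
#' @param noise_sd Gaussian noise s.d. added to each mean box length (nm).
#' @param seed RNG seed.
#' @export
stress_strain_spec <- function(Y_true, L0 = 25, sigma = schedule_default(),
                               noise_sd = 0, seed = 1L) {
  if (Y_true <= 0) stop("Y_true must be positive")
  if (abs(sigma[1L] - 0.1) > 1e-12) stop("stress schedule must start at 0.1 MPa")
  structure(list(Y_true = Y_true, L0 = L0, sigma = sigma,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "stress_strain_spec")
}

#' Generate a noisy linear stress-strain series
#'
#' `<L>(sigma) = L0 * (1 + (sigma - 0.1) / Y_true) + noise`, evaluated on
#' the stress schedule. Strain is referenced to the 0.1 MPa ambient state
#' whose mean length defines `L0`, matching the estimator's convention, so
#' with zero noise [young_modulus()] inverts the generator exactly.
#'
#' @param spec a [stress_strain_spec()].
#' @return a [stress_strain_series()] with the ground truth in attribute
#'   `Y_true`.
#' @export
simulate_stress_strain <- function(spec) {
  L <- spec$L0 * (1 + (spec$sigma - 0.1) / spec$Y_true)
  if (spec$noise_sd > 0)
    L <- L + with_seed(spec$seed, stats::rnorm(length(L), 0, spec$noise_sd))
  out <- stress_strain_series(sigma = spec$sigma, L = L)
  attr(out, "Y_true") <- spec$Y_true
  out
}
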