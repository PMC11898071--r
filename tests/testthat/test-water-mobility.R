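test_that("toroidal unwrapping undoes wrapping and survives box breathing", {
  # walker crossing the +x boundary at constant velocity: linear when unwrapped
  lab <- site_labels("O", "water_O")
  x <- seq(1.5, 4.3, by = 0.2)  # crosses L = 2 repeatedly
  tr <- labeled_trajectory(lapply(x, function(v) matrix(c(v, 1, 1), 1, 3)),
                           box = c(2, 2, 2), labels = lab,
                           time = seq_along(x) - 1)
  uw <- unwrap(tr)
  path <- vapply(uw$coords, function(m) m[1, 1], numeric(1))
  expect_equal(diff(path), rep(0.2, length(x) - 1), tolerance = 1e-12)

  # static site in a breathing box: zero accumulated displacement
  boxes <- cbind(2 + 0.2 * sin(1:8), 2, 2)
  st <- labeled_trajectory(replicate(8, matrix(c(1, 1, 1), 1, 3),
                                     simplify = FALSE),
                           box = boxes, labels = lab, time = 0:7)
  us <- unwrap(st)
  expect_equal(us$coords[[8]], us$coords[[1]], tolerance = 1e-12)

  # generator ground truth at constant box, recovered to 1e-12
  sp <- brownian_spec(data.frame(D = 1e-5, weight = 1), n_walkers = 60,
                      n_frames = 25, box = c(2, 2, 2), seed = 8)
  bt <- brownian_trajectory(sp)
  uw2 <- unwrap(bt)
  truth <- attr(bt, "true_coords")
  for (f in c(2, 13, 25))
    expect_equal(uw2$coords[[f]] - uw2$coords[[1]],
                 truth[[f]] - truth[[1]], tolerance = 1e-12)

  # an inter-frame jump at half the box is rejected with a location
  jump <- labeled_trajectory(list(matrix(c(0.2, 1, 1), 1, 3),
                                  matrix(c(1.2, 1, 1), 1, 3)),
                             box = c(2, 2, 2), labels = lab, time = 0:1)
  expect_error(unwrap(jump), "frame 2")
})

test_that("MSD reproduces ballistic, frozen and Brownian ground truths", {
  lab <- site_labels("O", "water_O")
  v <- 0.05
  tr <- labeled_trajectory(lapply(0:20, function(f) matrix(c(1 + v * f, 1, 1), 1, 3)),
                           box = c(50, 50, 50), labels = lab, time = 0:20)
  curve <- msd(unwrap(tr))
  expect_equal(curve$msd, (v * curve$lag)^2, tolerance = 1e-10)
  expect_equal(curve$msd[1], 0)
  expect_true(all(diff(curve$n_origins[-1]) <= 0))
  expect_warning(diffusion_coefficient(curve), "nonlinear")

  frozen <- labeled_trajectory(replicate(6, matrix(1, 4, 3), simplify = FALSE),
                               box = c(3, 3, 3),
                               labels = site_labels(rep("O", 4), rep("water_O", 4)),
                               time = 0:5)
  expect_true(all(msd(unwrap(frozen))$msd == 0))

  # Brownian at the bulk-water coefficient: slope/6 recovers D within 3 se
  D <- 4.0e-5
  sp <- brownian_spec(data.frame(D = D, weight = 1), n_walkers = 3000,
                      n_frames = 41, dt = 1, seed = 12)
  uw <- unwrap(brownian_trajectory(sp))
  est <- suppressWarnings(
    diffusion_coefficient(msd(uw, origin_stride = 10), window = c(5, 40)))
  expect_lt(abs(est$D - D), 3 * max(est$se, 0.01 * D))
  expect_error(msd(uw, max_lag = 100), "exceeds")
})

test_that("diffusion fits are exact on exact lines and guard degenerate input", {
  lag <- 0:20
  line <- structure(data.frame(lag = lag, msd = 6 * 2e-3 * lag,
                               n_origins = 50),
                    class = c("msd_curve", "data.frame"))
  est <- diffusion_coefficient(line)
  expect_equal(est$D, 2e-5, tolerance = 1e-12)
  expect_equal(est$se, 0, tolerance = 1e-12)

  down <- structure(data.frame(lag = lag, msd = -0.01 * lag, n_origins = 50),
                    class = c("msd_curve", "data.frame"))
  expect_warning(est2 <- diffusion_coefficient(down), "clipped")
  expect_equal(est2$D, 0)
  expect_error(diffusion_coefficient(line, window = c(0, 2)), "4 points")

  # two-population trajectory: the single fitted D lies between the two
  sp <- brownian_spec(data.frame(D = c(2e-5, 2e-6), weight = c(.5, .5)),
                      n_walkers = 2000, n_frames = 31, seed = 13)
  est3 <- diffusion_coefficient(msd(unwrap(brownian_trajectory(sp))))
  expect_gt(est3$D, 2e-6); expect_lt(est3$D, 2e-5)
})

test_that("displacement distributions match their generator", {
  sp <- brownian_spec(data.frame(D = 1.5e-5, weight = 1), n_walkers = 400,
                      n_frames = 61, dt = 1, seed = 14)
  uw <- unwrap(brownian_trajectory(sp))
  s <- displacement_distribution(uw, t = 30)
  # non-overlapping origins: 2 origins x 400 molecules
  expect_length(s$r, 800L)
  expect_lt(abs(mean(s$r^2) - 6 * 1.5e-5 * 100 * 30),
            3 * sd(s$r^2) / sqrt(length(s$r)))
  frozen <- labeled_trajectory(replicate(4, matrix(1, 2, 3), simplify = FALSE),
                               box = c(3, 3, 3),
                               labels = site_labels(rep("O", 2), rep("water_O", 2)),
                               time = 0:3)
  expect_true(all(displacement_distribution(unwrap(frozen), t = 2)$r == 0))
  expect_error(displacement_distribution(uw, t = 30.5), "multiple")

  # chi-square goodness of fit against the closed-form density
  big <- displacement_samples(brownian_spec(data.frame(D = 1.5e-5, weight = 1),
                                            n_walkers = 2e4, seed = 15), t = 30)
  qs <- quantile(big$r, probs = seq(0, 1, length.out = 21))
  qs[1] <- 0; qs[21] <- Inf
  obs <- table(cut(big$r, qs))
  pr <- diff(pbrownian_r(c(0, qs[2:20], 1e9), D = 1.5e-5, w = 1, t = 30))
  expect_gt(chisq.test(as.integer(obs), p = pr, rescale.p = TRUE)$p.value, 0.01)
})

test_that("the two-population fit recovers mixture parameters", {
  sp <- brownian_spec(data.frame(D = c(1.93e-5, 2.30e-6), weight = c(.85, .15)),
                      n_walkers = 5e4, seed = 16)
  s <- displacement_samples(sp, t = 30)
  fit <- fit_brownian(s, n_components = 2)
  expect_equal(sum(fit$w), 1, tolerance = 1e-12)
  expect_true(all(diff(fit$D) < 0))  # ordered fast -> slow
  expect_lt(abs(fit$D[1] - 1.93e-5), 3 * fit$se_D[1])
  expect_lt(abs(fit$D[2] - 2.30e-6), 3 * fit$se_D[2])
  expect_lt(abs(fit$w[1] - 0.85), 0.02)

  # one-component fit has w = 1 and a likelihood the mixture dominates
  f1 <- fit_brownian(s, n_components = 1)
  expect_equal(f1$w, 1)
  expect_gt(fit$logLik, f1$logLik)

  # single-population data: two-component fit degenerates harmlessly
  s1 <- displacement_samples(brownian_spec(data.frame(D = 1e-5, weight = 1),
                                           n_walkers = 2e4, seed = 17), t = 30)
  f2 <- fit_brownian(s1, n_components = 2)
  deg <- min(f2$w) < 0.02 ||
    abs(f2$D[1] - f2$D[2]) < 4 * sqrt(sum(f2$se_D^2))
  expect_true(deg)

  # binned least-squares mode lands near the same parameters
  fls <- fit_brownian(s, n_components = 2, method = "ls")
  expect_equal(fls$D[1], fit$D[1], tolerance = 0.1)
  expect_equal(fls$w[1], fit$w[1], tolerance = 0.05)
})

test_that("fitted D and weights are unbiased across replicate samples", {
  reps <- 12
  D_true <- c(1.93e-5, 2.30e-6); w_true <- c(0.85, 0.15)
  Dm <- matrix(0, reps, 2); wm <- numeric(reps)
  for (i in seq_len(reps)) {
    s <- displacement_samples(brownian_spec(data.frame(D = D_true, weight = w_true),
                                            n_walkers = 1e5, seed = 100 + i),
                              t = 30)
    f <- fit_brownian(s, n_components = 2, n_starts = 3)
    Dm[i, ] <- f$D; wm[i] <- f$w[1]
  }
  expect_lt(abs(median(Dm[, 1]) / D_true[1] - 1), 0.02)
  expect_lt(abs(median(Dm[, 2]) / D_true[2] - 1), 0.02)
  expect_lt(abs(median(wm) - w_true[1]), 0.01)
})

test_that("posterior assignment separates well-resolved populations", {
  sp <- brownian_spec(data.frame(D = c(1e-5, 1e-7), weight = c(.5, .5)),
                      n_walkers = 4000, seed = 18)
  s <- displacement_samples(sp, t = 30)
  fit <- fit_brownian(s, n_components = 2, n_starts = 3)
  pa <- assign_populations(s, fit)
  truth <- ifelse(s$component == 1L, "fast", "slow")
  expect_gt(mean(pa$label[order(pa$molecule)] == truth[order(s$molecule)]), 0.99)
  frac_fast <- mean(pa$label == "fast")
  expect_lt(abs(frac_fast - fit$w[1]), 3 * sqrt(0.25 / nrow(pa)) + 0.01)
  expect_error(assign_populations(s, fit_brownian(s, n_components = 1)),
               "two-component")

  # indistinguishable components: posteriors collapse to the weights
  same <- list(D = c(1e-5, 1e-5), w = c(0.7, 0.3), t = 30,
               convention = "radial")
  class(same) <- "brownian_mixture"
  pa2 <- assign_populations(s, same)
  expect_equal(unique(round(pa2$p_fast, 10)), 0.7)
})

test_that("the weighted mean coefficient is a plain mixture average", {
  mk <- function(D, w) structure(list(D = D, w = w), class = "brownian_mixture")
  expect_equal(weighted_D(mk(c(1.93e-5, 2.30e-6), c(0.85, 0.15))), 1.675e-5,
               tolerance = 1e-8)
  expect_equal(weighted_D(mk(3.3e-6, 1)), 3.3e-6)
  expect_equal(weighted_D(mk(c(4, 2), c(0.5, 0.5))), 3)
})

test_that("MSD of a mixed population is the weight-split sum of its parts", {
  sp <- brownian_spec(data.frame(D = c(2e-5, 2e-6), weight = c(.6, .4)),
                      n_walkers = 1500, n_frames = 21, seed = 19)
  bt <- brownian_trajectory(sp)
  uw <- unwrap(bt)
  comp <- attr(bt, "component")
  all_msd <- msd(uw)$msd
  m1 <- msd(uw, sel = which(comp == 1L))$msd
  m2 <- msd(uw, sel = which(comp == 2L))$msd
  f1 <- mean(comp == 1L)
  expect_equal(all_msd, f1 * m1 + (1 - f1) * m2, tolerance = 1e-10)
})
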