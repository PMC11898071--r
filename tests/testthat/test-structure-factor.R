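test_that("rho_k matches exact limits and the direct lattice sum", {
  kv <- rbind(c(0.5, 0, 0), c(0.3, 0.4, 0), c(1, 2, 3) * 0.2)
  one <- water_box_toy(1)
  expect_equal(Mod(rho_k(one, select_population(one, "water_oxygens"), kv)),
               rep(1, 3), tolerance = 1e-12)

  # N coincident particles: |rho| = N
  lab <- site_labels(rep("O", 7), rep("water_O", 7))
  tr <- labeled_trajectory(matrix(1.234, 7, 3), box = c(3, 3, 3), labels = lab)
  expect_equal(Mod(rho_k(tr, 1:7, kv)), rep(7, 3), tolerance = 1e-9)

  # sc lattice: reciprocal vectors coherent, others destructive
  sc <- lattice_config("sc", box = c(2.28, 2.28, 2.28), spacing = 0.285)
  sel <- select_population(sc, "water_oxygens")
  k_on <- matrix(c(2 * pi / 2.85, 0, 0), 1)
  k_off <- matrix(c(2 * pi / 2.85 * 0.5, 0, 0), 1)
  expect_equal(Mod(rho_k(sc, sel, k_on)), length(sel), tolerance = 1e-8)
  expect_lt(Mod(rho_k(sc, sel, k_off)), 1e-8)
  expect_error(rho_k(sc, integer(0), k_on), "empty")
})

test_that("shell-binned S(k) equals the brute-force double sum", {
  set.seed(42)
  n <- 25
  co <- cbind(runif(n, 0, 2), runif(n, 0, 2), runif(n, 0, 2))
  tr <- labeled_trajectory(co, box = c(2, 2, 2),
                           labels = site_labels(rep("O", n), rep("water_O", n)))
  kv <- hydroglucan:::make_kvecs(c(2, 2, 2), 1.2)
  rho <- rho_k(tr, 1:n, kv$k)
  s_fast <- Re(rho * Conj(rho)) / n
  s_brute <- vapply(seq_len(nrow(kv$k)), function(i)
    brute_sk(tr$coords[[1]], kv$k[i, ]), numeric(1))
  expect_equal(s_fast, s_brute, tolerance = 1e-10)

  # global translation leaves S(k) unchanged
  tr2 <- labeled_trajectory(co + matrix(c(0.7, -0.3, 1.1), n, 3, byrow = TRUE),
                            box = c(2, 2, 2),
                            labels = tr$labels)
  rho2 <- rho_k(tr2, 1:n, kv$k)
  expect_equal(Re(rho2 * Conj(rho2)) / n, s_fast, tolerance = 1e-10)
})

test_that("disordered and crystalline reference systems bracket S(k)", {
  gas <- lattice_config("ideal_gas", box = c(2.5, 2.5, 2.5), n = 2000, seed = 8)
  sk <- structure_factor(gas, "water_oxygens", kmax = 3, dk = 0.1, stride = 1)
  hi <- sk[sk$k >= 1.5, ]
  # S ~ 1 with sampling error ~ sqrt(2/n_vectors) per shell
  se <- sqrt(2 / sum(hi$n_vectors))
  expect_lt(abs(weighted.mean(hi$S, hi$n_vectors) - 1), 3 * se + 0.05)

  sc <- lattice_config("sc", box = c(2.28, 2.28, 2.28), spacing = 0.285)
  sk2 <- structure_factor(sc, "water_oxygens", kmax = 3, dk = 0.02, stride = 1)
  peak_shell <- sk2$k[which.max(sk2$S)]
  expect_equal(peak_shell, 2 * pi / 2.85, tolerance = 0.02)
})

test_that("complementary clustered populations share a prepeak that pooling dims", {
  # alternating 1-nm slabs of two oxygen populations along x: each population
  # is modulated with period 2 nm; their union is nearly homogeneous
  set.seed(11)
  L <- 8; nslab <- 500
  xa <- c(); xb <- c()
  for (s in 0:3) {
    xa <- c(xa, runif(nslab, 2 * s, 2 * s + 1))
    xb <- c(xb, runif(nslab, 2 * s + 1, 2 * s + 2))
  }
  co <- rbind(cbind(xa, runif(4 * nslab, 0, L), runif(4 * nslab, 0, L)),
              cbind(xb, runif(4 * nslab, 0, L), runif(4 * nslab, 0, L)))
  lab <- site_labels(rep("O", 8 * nslab),
                     rep(c("water_O", "poly_hydroxyl_O"), each = 4 * nslab),
                     polymer = rep(c("none", "callose"), each = 4 * nslab),
                     chain = rep(c(NA, 1L), each = 4 * nslab),
                     ring = rep(c(NA, 1L), each = 4 * nslab))
  tr <- labeled_trajectory(co, box = c(L, L, L), labels = lab)
  dk <- 0.01
  ska <- structure_factor(tr, "water_oxygens", kmax = 0.6, dk = dk, stride = 1)
  skb <- structure_factor(tr, "poly_oxygens", kmax = 0.6, dk = dk, stride = 1)
  skp <- structure_factor(tr, "all_oxygens", kmax = 0.6, dk = dk, stride = 1)
  k0 <- 2 * pi / 20  # domain period 2 nm = 20 A
  pa <- find_prepeak(ska, k_upper = 0.5)
  pb <- find_prepeak(skb, k_upper = 0.5)
  expect_lt(abs(pa$k - k0), 2.5 * dk)  # within the smoothing window
  expect_lt(abs(pb$k - k0), 2.5 * dk)
  at_k0 <- function(sk) sk$S[which.min(abs(sk$k - k0))]
  expect_lt(at_k0(skp), min(at_k0(ska), at_k0(skb)))
})

test_that("prepeak detection finds constructed bumps and rejects monotone S(k)", {
  k <- seq(0.05, 3, by = 0.02)
  bump <- 1 + 2 * exp(-((k - 0.3) / 0.05)^2)
  res <- structure(data.frame(k = k, S = bump, n_vectors = 1),
                   class = c("sf_result", "data.frame"))
  pk <- find_prepeak(res)
  expect_lt(abs(pk$k - 0.3), 0.021)  # within one shell of the bump centre

  mono <- structure(data.frame(k = k, S = 3 * exp(-k), n_vectors = 1),
                    class = c("sf_result", "data.frame"))
  expect_null(find_prepeak(mono))
  few <- structure(data.frame(k = c(0.1, 0.5), S = c(1, 1), n_vectors = 1),
                   class = c("sf_result", "data.frame"))
  expect_error(find_prepeak(few), "5 shells")
})

test_that("tighter domain spacing moves the prepeak to higher k", {
  set.seed(12)
  make_slabs <- function(period, L = 8, n_per = 320) {
    ns <- L / period
    x <- unlist(lapply(0:(ns - 1), function(s)
      runif(n_per, period * s, period * s + period / 2)))
    cbind(x, runif(length(x), 0, L), runif(length(x), 0, L))
  }
  for (period in c(2, 1)) {
    co <- make_slabs(period)
    tr <- labeled_trajectory(co, box = c(8, 8, 8),
                             labels = site_labels(rep("O", nrow(co)),
                                                  rep("water_O", nrow(co))))
    sk <- structure_factor(tr, "water_oxygens", kmax = 1.2, dk = 0.01, stride = 1)
    pk <- find_prepeak(sk, k_upper = 1.1)
    if (period == 2) k_wide <- pk$k else k_tight <- pk$k
  }
  expect_gt(k_tight, k_wide)
  expect_equal(k_tight / k_wide, 2, tolerance = 0.2)
})
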