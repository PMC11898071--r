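# Shared fixtures and independent oracles, built in code at test time.

# n water molecules (O,H,H) on a coarse grid inside `box`.
water_box_toy <- function(n = 3, box = c(3, 3, 3), spacing = 0.6) {
  per <- ceiling(n^(1 / 3))
  idx <- (as.matrix(expand.grid(seq_len(per), seq_len(per), seq_len(per))) - 0.5) *
    spacing
  o <- idx[seq_len(n), , drop = FALSE]
  co <- matrix(0, 3 * n, 3)
  co[seq(1, 3 * n, 3), ] <- o
  co[seq(2, 3 * n, 3), ] <- sweep(o, 2, c(0.1, 0, 0), "+")
  co[seq(3, 3 * n, 3), ] <- sweep(o, 2, c(-0.033, 0.094, 0), "+")
  lab <- site_labels(rep(c("O", "H", "H"), n),
                     rep(c("water_O", "water_H", "water_H"), n))
  labeled_trajectory(co, box = box, labels = lab)
}

# a single isolated glucan chain in a generous box (no periodic contacts)
single_chain_traj <- function(rings = 3, polymer = "callose", box = 6) {
  sp <- network_spec(rings_per_chain = rings, chains_per_axis = 1,
                     box_side = box, polymer = polymer, axes = "x")
  ch <- build_chain(sp)
  labeled_trajectory(ch$coords + 1, box = rep(box, 3), labels = ch$labels)
}

# brute-force structure factor: S(k) = (1/N) sum_jl cos(k . (r_j - r_l))
brute_sk <- function(coords, kvec_invA) {
  k <- kvec_invA * 10
  ph <- as.numeric(coords %*% k)
  (sum(cos(ph))^2 + sum(sin(ph))^2) / nrow(coords)
}

# donor O at `origin`, its H 0.96 A away along +x, acceptor placed so that
# the O-O distance is `doo_A` (Angstrom) and the O-H-O angle at H is
# `angle_deg`; returns a 3 x 3 coordinate matrix (nm): donor O, H, acceptor O.
hb_triplet <- function(doo_A, angle_deg, origin = c(1, 1, 1)) {
  a <- 0.096
  d <- doo_A / 10
  th <- angle_deg * pi / 180
  disc <- d^2 - (a * sin(th))^2
  stopifnot(disc > 0)
  b <- a * cos(th) + sqrt(disc)  # H-acceptor distance
  h <- origin + c(a, 0, 0)
  u <- c(-cos(th), sin(th), 0)   # unit vector from H at `th` to H->donor (-x)
  acc <- h + b * u
  rbind(origin, h, acc)
}

# minimal hbond_census object from hand-constructed record tables
census_from_records <- function(records_list) {
  structure(list(records = records_list, frames = seq_along(records_list),
                 counts = NULL, n_frames = length(records_list),
                 n_rings = 0L, n_hb = list(donated = NA, accepted = NA)),
            class = "hbond_census")
}

# random water-like gas: oxygens on a jittered grid (keeps every foreign
# O-H separation above the covalent 1.2 A threshold, so assignments stay
# unambiguous while many O-O pairs fall inside the 3.2 A bonding range),
# two hydrogens 0.96 A from each O in random directions.
rand_water_gas <- function(n, box = c(3, 3, 3), seed = 1) {
  set.seed(seed)
  a <- 0.33
  per <- pmax(1L, floor(box / a))
  stopifnot(prod(per) >= n)
  g <- as.matrix(expand.grid(seq_len(per[1]), seq_len(per[2]), seq_len(per[3])))
  g <- g[sample(nrow(g), n), , drop = FALSE]
  o <- sweep((g - 0.5), 2, box / per, "*") +
    matrix(runif(3 * n, -0.045, 0.045), n, 3)
  dir1 <- matrix(rnorm(3 * n), n, 3); dir1 <- dir1 / sqrt(rowSums(dir1^2))
  dir2 <- matrix(rnorm(3 * n), n, 3); dir2 <- dir2 / sqrt(rowSums(dir2^2))
  co <- matrix(0, 3 * n, 3)
  co[seq(1, 3 * n, 3), ] <- o
  co[seq(2, 3 * n, 3), ] <- o + 0.096 * dir1
  co[seq(3, 3 * n, 3), ] <- o + 0.096 * dir2
  lab <- site_labels(rep(c("O", "H", "H"), n),
                     rep(c("water_O", "water_H", "water_H"), n))
  labeled_trajectory(co, box = box, labels = lab)
}

sorted_records <- function(rec) {
  rec <- rec[order(rec$donor_h, rec$acceptor_o), ]
  rownames(rec) <- NULL
  rec
}
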