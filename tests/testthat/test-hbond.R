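water_pair_traj <- function(doo_A, angle_deg, box = c(5, 5, 5)) {
  tri <- hb_triplet(doo_A, angle_deg)
  # donor water (O,H,H), acceptor water (O,H,H): extra hydrogens point away
  co <- rbind(tri[1, ], tri[2, ], tri[1, ] + c(-0.033, -0.09, 0),
              tri[3, ], tri[3, ] + c(0.09, 0.03, 0), tri[3, ] + c(0, 0.05, 0.08))
  lab <- site_labels(rep(c("O", "H", "H"), 2),
                     rep(c("water_O", "water_H", "water_H"), 2))
  labeled_trajectory(co, box = box, labels = lab)
}

test_that("the geometric criterion applies strict distance and angle cuts", {
  expect_equal(nrow(detect_hbonds(water_pair_traj(3.0, 170))), 1L)
  expect_equal(nrow(detect_hbonds(water_pair_traj(3.3, 180))), 0L)
  expect_equal(nrow(detect_hbonds(water_pair_traj(3.0, 139))), 0L)
  # both boundaries are exclusive
  expect_equal(nrow(detect_hbonds(water_pair_traj(3.0, 140 - 1e-4))), 0L)
  expect_equal(nrow(detect_hbonds(water_pair_traj(3.0, 140 + 1e-3))), 1L)
  expect_equal(nrow(detect_hbonds(water_pair_traj(3.2 - 1e-4, 170))), 1L)
  expect_equal(nrow(detect_hbonds(water_pair_traj(3.2 + 1e-4, 170))), 0L)

  rec <- detect_hbonds(water_pair_traj(3.0, 170))
  expect_equal(rec$dist, 3.0, tolerance = 1e-9)
  expect_equal(rec$angle, 170, tolerance = 1e-9)
  expect_equal(rec$category, "ww")
})

test_that("covalent assignment errors on malformed or ambiguous hydrogens", {
  lab <- site_labels(c("O", "H", "H"), c("water_O", "water_H", "water_H"))
  lost <- labeled_trajectory(rbind(c(1, 1, 1), c(1.5, 1, 1), c(1, 1.09, 1)),
                             box = c(4, 4, 4), labels = lab)
  expect_error(detect_hbonds(lost), "water hydrogen site 2")

  lab2 <- site_labels(c("O", "O", "H"), c("water_O", "water_O", "water_H"))
  amb <- labeled_trajectory(rbind(c(1, 1, 1), c(1.2, 1, 1), c(1.1, 1, 1)),
                            box = c(4, 4, 4), labels = lab2)
  expect_error(detect_hbonds(amb), "ambiguous")

  # carbon-bound chain hydrogens are quietly skipped as non-donors
  expect_s3_class(detect_hbonds(single_chain_traj(2)), "data.frame")
})

test_that("cell-list and all-pairs detection agree exactly", {
  for (seed in 1:8) {
    tr <- rand_water_gas(300, box = c(2.6, 2.9, 3.1), seed = seed)
    expect_identical(sorted_records(detect_hbonds(tr, method = "cell")),
                     sorted_records(detect_hbonds(tr, method = "brute")))
  }
  big <- rand_water_gas(1500, box = c(4.2, 4.2, 4.2), seed = 99)
  expect_identical(sorted_records(detect_hbonds(big, method = "cell")),
                   sorted_records(detect_hbonds(big, method = "brute")))
})

test_that("the census is invariant under global translation", {
  tr <- rand_water_gas(200, box = c(2.5, 2.5, 2.5), seed = 3)
  sh <- labeled_trajectory(tr$coords[[1]] +
                             matrix(c(1.2, -0.7, 0.4), n_sites(tr), 3, byrow = TRUE),
                           box = tr$box[1, ], labels = tr$labels)
  a <- sorted_records(detect_hbonds(tr))
  b <- sorted_records(detect_hbonds(sh))
  expect_equal(a[c("donor_o", "donor_h", "acceptor_o", "category")],
               b[c("donor_o", "donor_h", "acceptor_o", "category")])
  expect_equal(a$dist, b$dist, tolerance = 1e-9)
})

# one saturated glucose ring: its ring oxygen accepts one bond from a water,
# its C2 hydroxyl donates one bond to a second water and accepts bonds from
# two further waters
saturated_ring_traj <- function() {
  ch <- build_chain(network_spec(rings_per_chain = 1))
  co <- ch$coords + 2          # ring centred away from the origin
  lab <- ch$labels
  o2 <- which(lab$attach == 2L)
  h2 <- o2 + 3L                # template order: O2,Omid,O6 then their H's
  add_water <- function(o_pos, h1_target) {
    u <- (h1_target - o_pos); u <- u / sqrt(sum(u^2))
    rbind(o_pos, o_pos + 0.1 * u, o_pos + 0.1 * c(u[2], -u[1], u[3]))
  }
  # donor waters aimed at O2 from two well-separated directions
  w1 <- add_water(co[o2, ] + c(0, 0.30, 0), co[o2, ])
  w2 <- add_water(co[o2, ] + c(0, 0, 0.30), co[o2, ])
  # acceptor water along the O2-H2 axis (receives the hydroxyl's proton)
  uax <- (co[h2, ] - co[o2, ]); uax <- uax / sqrt(sum(uax^2))
  wa_o <- co[o2, ] + 0.29 * uax
  w3 <- rbind(wa_o, wa_o + 0.1 * c(uax[2], -uax[1], uax[3]),
              wa_o + 0.1 * c(uax[3], uax[2], -uax[1]))
  co_all <- rbind(co, w1, w2, w3)
  lab_all <- rbind(lab, site_labels(rep(c("O", "H", "H"), 3),
                                    rep(c("water_O", "water_H", "water_H"), 3)))
  labeled_trajectory(co_all, box = c(6, 6, 6), labels = lab_all)
}

test_that("classification routes donors and acceptors to the right categories", {
  tr <- saturated_ring_traj()
  cen <- hbond_census(tr)
  rec <- cen$records[[1]]
  expect_gte(sum(rec$category == "water_to_poly"), 2L)
  expect_equal(sum(rec$category == "poly_to_water"), 1L)
  # per-glucose aggregates: one ring, one frame
  expect_equal(cen$n_hb$donated, 1.0)
  expect_gte(cen$n_hb$accepted, 2 * cen$n_hb$donated)

  # intrachain vs interchain: a donating hydroxyl pair on one chain or two
  tri <- hb_triplet(3.0, 170)
  hyd_pair <- function(chains) {
    co <- rbind(tri[1, ], tri[2, ], tri[3, ])
    lab <- site_labels(c("O", "H", "O"),
                       c("poly_hydroxyl_O", "poly_H", "poly_hydroxyl_O"),
                       polymer = "callose", chain = chains[c(1, 1, 2)],
                       ring = c(1L, 1L, 2L), attach = c(2L, NA, 4L))
    detect_hbonds(labeled_trajectory(co, box = c(5, 5, 5), labels = lab))
  }
  expect_equal(hyd_pair(c(1L, 1L))$category, "intrachain")
  expect_equal(hyd_pair(c(1L, 2L))$category, "interchain")
})

test_that("wire lengths equal exhaustive path enumeration", {
  # chain of 3 waters along 4 hydroxyls: one maximal wire of length 3
  mk_lab <- function(n_poly, n_wat) {
    site_labels(rep("O", n_poly + n_wat),
                c(rep("poly_hydroxyl_O", n_poly), rep("water_O", n_wat)),
                polymer = c(rep("callose", n_poly), rep("none", n_wat)),
                chain = c(rep(1L, n_poly), rep(NA, n_wat)),
                ring = c(seq_len(n_poly), rep(NA, n_wat)))
  }
  lab <- mk_lab(4, 3)
  rec <- data.frame(
    donor_o = c(1L, 2L, 3L, 5L, 6L, 7L),
    donor_h = NA_integer_,
    acceptor_o = c(5L, 6L, 7L, 2L, 3L, 4L),
    dist = 2.9, angle = 165,
    category = rep(c("poly_to_water", "water_to_poly"), each = 3))
  wl <- wire_lengths(census_from_records(list(rec)), lab)
  expect_equal(as.integer(names(wl)), 3L)
  expect_equal(unname(as.integer(wl)), 1L)

  # no water->poly bonds: no wires at all
  rec0 <- rec[rec$category == "poly_to_water", ]
  expect_equal(length(wire_lengths(census_from_records(list(rec0)), lab)), 0L)

  # random sparse wiring vs an independent exhaustive enumeration
  set.seed(14)
  for (rep_i in 1:5) {
    n_p <- 8L; n_w <- 6L
    lab2 <- mk_lab(n_p, n_w)
    wat_ids <- n_p + seq_len(n_w)
    in_h <- sample(n_p, n_w, replace = TRUE)   # hydroxyl donating to water
    out_h <- sample(n_p, n_w, replace = TRUE)  # hydroxyl accepting from water
    keep <- in_h != out_h
    rec2 <- rbind(
      data.frame(donor_o = in_h[keep], donor_h = NA_integer_,
                 acceptor_o = wat_ids[keep], dist = 2.9, angle = 160,
                 category = "poly_to_water"),
      data.frame(donor_o = wat_ids[keep], donor_h = NA_integer_,
                 acceptor_o = out_h[keep], dist = 2.9, angle = 160,
                 category = "water_to_poly"))
    got <- wire_lengths(census_from_records(list(rec2)), lab2)
    # oracle: depth-first enumeration of maximal simple paths on the
    # hydroxyl->hydroxyl edge list
    edges <- data.frame(from = in_h[keep], to = out_h[keep])
    lens <- integer(0)
    extend <- function(path_nodes, used) {
      nxt <- which(edges$from == path_nodes[length(path_nodes)] & !used &
                     !(edges$to %in% path_nodes))
      if (!length(nxt)) {
        if (sum(used) > 0) lens <<- c(lens, sum(used))
        return(invisible())
      }
      for (e in nxt) {
        u2 <- used; u2[e] <- TRUE
        extend(c(path_nodes, edges$to[e]), u2)
      }
    }
    srcs <- setdiff(unique(edges$from), unique(edges$to))
    if (!length(srcs)) srcs <- unique(edges$from)
    for (s in srcs) extend(s, rep(FALSE, nrow(edges)))
    expect_equal(as.vector(got), as.vector(table(lens)))
  }
})

test_that("bridging waters span two chains, not two bonds", {
  lab <- site_labels(rep("O", 12),
                     c(rep("poly_hydroxyl_O", 2), rep("water_O", 10)),
                     polymer = c("callose", "callose", rep("none", 10)),
                     chain = c(1L, 2L, rep(NA, 10)),
                     ring = c(1L, 1L, rep(NA, 10)))
  rec <- data.frame(
    donor_o    = c(3L, 1L, 4L, 4L, 2L, 5L),
    donor_h    = NA_integer_,
    acceptor_o = c(1L, 3L, 1L, 1L, 4L, 2L),
    dist = 3.0, angle = 160,
    category = c("water_to_poly", "poly_to_water", "water_to_poly",
                 "water_to_poly", "poly_to_water", "water_to_poly"))
  br <- bridging_waters(census_from_records(list(rec)), lab)
  # water 3 touches only chain 1; water 4 touches chains 1 and 2 (two bonds
  # to chain 1 alone would not count); water 5 touches only chain 2
  expect_equal(br$ids, 4L)
  expect_equal(br$count, 1L)
  expect_equal(br$fraction, 0.1)

  # constructed 20 % bridging fixture: 2 of 10 waters span two chains
  rec2 <- data.frame(
    donor_o    = c(3L, 3L, 4L, 4L),
    donor_h    = NA_integer_,
    acceptor_o = c(1L, 2L, 1L, 2L),
    dist = 3.0, angle = 160, category = "water_to_poly")
  br2 <- bridging_waters(census_from_records(list(rec2)), lab)
  expect_equal(br2$fraction, 0.2)
})
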