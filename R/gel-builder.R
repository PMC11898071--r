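# Synthetic gel-network construction: a geometric implementation of the
# sample-preparation protocol (chain replication, 3-axis lattice placement,
# lattice solvation, random dilution cascade). Geometry only, no energetics.

# Run an expression with a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic gel network
#'
#' Defaults reproduce the reference construction: 48 rings per chain, 64
#' chains per axis on an 8 x 8 square lattice, a cubic box of 25 nm side,
#' and a rise of 0.52 nm per ring (so a 48-ring chain spans about 25 nm).
#'
#' @param rings_per_chain number of glucose rings per chain.
#' @param chains_per_axis chains inserted along each axis; must be a perfect
#'   square (placed on a sqrt(n) x sqrt(n) lattice).
#' @param box_side cubic box edge (nm).
#' @param polymer `"callose"` (1,3-linked; hydroxyls at C2/C4/C6) or
#'   `"cellulose"` (1,4-linked; hydroxyls at C2/C3/C6).
#' @param rise rise per ring along the chain axis (nm).
#' @param axes which Cartesian axes receive chains.
#' @param lattice_offset transverse lattice offset between successive axes,
#'   as a fraction of the lattice cell. The default of one third keeps the
#'   centre lines of all three axis families a third of a cell apart;
#'   multiples of one half would bring the first and third family back into
#'   register and make crossing chains intersect.
#' @param seed RNG seed for the random chain-origin shifts.
#' @return a list of class `network_spec`.
#' @export
network_spec <- function(rings_per_chain = 48L, chains_per_axis = 64L,
                         box_side = 25, polymer = c("callose", "cellulose"),
                         rise = 0.52, axes = c("x", "y", "z"),
                         lattice_offset = 1 / 3, seed = 1L) {
  polymer <- match.arg(polymer)
  g <- sqrt(chains_per_axis)
  if (g != round(g)) stop("chains_per_axis must be a perfect square")
  if (rings_per_chain < 1L) stop("rings_per_chain must be >= 1")
  if (rise * rings_per_chain > 2 * box_side)
    stop("chain longer than twice the box side; reduce rise or rings")
  axes <- match.arg(axes, c("x", "y", "z"), several.ok = TRUE)
  structure(list(rings_per_chain = as.integer(rings_per_chain),
                 chains_per_axis = as.integer(chains_per_axis),
                 box_side = box_side, polymer = polymer, rise = rise,
                 axes = axes, lattice_offset = lattice_offset,
                 seed = as.integer(seed)),
            class = "network_spec")
}

# Coarse single-residue template: ring heavy atoms on a (puckered) hexagon of
# radius 0.15 nm normal to the chain axis, hydroxyl oxygens on radial stubs.
# The placement fixes the intra-ring hydroxyl pair distances the rdf analyses
# probe: callose O2-O4 = 4.80 A, O2-O6 = 3.35 A, O4-O6 = 4.35 A;
# cellulose O2-O3 = 2.77 A. Not force-field relaxed, not chemically accurate.
residue_template <- function(polymer = "callose") {
  ang <- c(0, 60, 120, 180, 240, 300) * pi / 180  # C1 C2 C3 C4 C5 Oring
  puck <- c(0.03, -0.03, 0.03, -0.03, 0.03, -0.03)
  hex <- cbind(puck, 0.15 * cos(ang), 0.15 * sin(ang))
  c6 <- c(0.05, 0.25 * cos(285 * pi / 180), 0.25 * sin(285 * pi / 180))
  o_glyc <- c(0.26, 0.12, 0)
  radial <- function(x, rho, deg) c(x, rho * cos(deg * pi / 180), rho * sin(deg * pi / 180))
  o2 <- radial(0, 0.277, 60)
  o6 <- radial(0.10, 0.16, 330)
  if (polymer == "callose") {
    o_mid <- radial(0, 0.277, 180)   # O4
    attach_mid <- 4L
  } else {
    o_mid <- radial(0, 0.277, 120)   # O3
    attach_mid <- 3L
  }
  stretch <- function(o, f) c(o[1], o[2] * f, o[3] * f)
  h2 <- stretch(o2, (0.277 + 0.096) / 0.277)
  h_mid <- stretch(o_mid, (0.277 + 0.096) / 0.277)
  h6 <- stretch(o6, (0.16 + 0.096) / 0.16)
  hc <- rbind(hex[1, ] + c(0.1, 0, 0), hex[2, ] - c(0.1, 0, 0),
              hex[3, ] + c(0.1, 0, 0), hex[4, ] - c(0.1, 0, 0),
              hex[5, ] + c(0.1, 0, 0),
              c6 + c(0.1, 0, 0),
              radial(0.05, 0.35, 285))
  coords <- rbind(hex[1:5, ], c6, hex[6, ], o_glyc, o2, o_mid, o6,
                  h2, h_mid, h6, hc)
  list(coords = coords,
       element = c(rep("C", 6), "O", "O", "O", "O", "O", rep("H", 10)),
       role = c(rep("poly_C", 6), "poly_ring_O", "poly_glycosidic_O",
                rep("poly_hydroxyl_O", 3), rep("poly_H", 10)),
       attach = c(rep(NA_integer_, 8), 2L, attach_mid, 6L, rep(NA_integer_, 10)))
}

#' Build one linear glucan chain
#'
#' Purely geometric replication of the single-residue template along +x with
#' a fixed rise per ring, terminated by a complementary -OH group (one
#' oxygen, one hydrogen) at the reducing end and a lone -H at the other.
#' Atom count is `21 * rings + 3`.
#'
#' @param spec a [network_spec()]; only the ring count, rise and polymer
#'   fields are used.
#' @return list with `coords` (matrix, nm) and `labels` (chain id 1).
#' @examples
#' ch <- build_chain(network_spec(rings_per_chain = 1))
#' nrow(ch$coords)  # 24
#' @export
build_chain <- function(spec) {
  tpl <- residue_template(spec$polymer)
  n <- spec$rings_per_chain
  per <- nrow(tpl$coords)  # 21
  coords <- matrix(0, per * n + 3L, 3L)
  element <- character(per * n + 3L)
  role <- character(per * n + 3L)
  attach <- rep(NA_integer_, per * n + 3L)
  ring <- rep(NA_integer_, per * n + 3L)
  for (j in seq_len(n)) {
    idx <- (j - 1L) * per + seq_len(per)
    ctr <- c((j - 0.5) * spec$rise, 0, 0)
    coords[idx, ] <- sweep(tpl$coords, 2L, ctr, "+")
    element[idx] <- tpl$element
    role[idx] <- tpl$role
    attach[idx] <- tpl$attach
    ring[idx] <- j
  }
  # terminal -OH after the last ring, lone -H before the first
  last_ctr <- c((n - 0.5) * spec$rise, 0, 0)
  first_ctr <- c(0.5 * spec$rise, 0, 0)
  ti <- per * n + 1:3
  coords[ti[1L], ] <- last_ctr + c(0.26, 0.27, 0.10)
  coords[ti[2L], ] <- last_ctr + c(0.26, 0.345, 0.10)
  coords[ti[3L], ] <- first_ctr + c(-0.26, 0.12, 0)
  element[ti] <- c("O", "H", "H")
  role[ti] <- c("poly_hydroxyl_O", "poly_H", "poly_H")
  ring[ti] <- c(n, n, 1L)
  labels <- site_labels(element, role, polymer = spec$polymer,
                        chain = 1L, ring = ring, attach = attach)
  list(coords = coords, labels = labels)
}

#' Place a 3-axis network of chains in a cubic box
#'
#' Inserts `chains_per_axis` chains aligned along each requested axis, on
#' square lattices in the transverse plane (successive axes offset by half a
#' lattice cell to avoid close contacts), each chain's origin shifted along
#' its own axis by a seeded uniform random distance in `[0, L)`. Chains wrap
#' through the periodic boundaries, so the cell faces are not discontinuity
#' surfaces. The default spec yields 192 chains and 9216 rings.
#'
#' @param spec a [network_spec()].
#' @param min_separation optional minimum transverse chain-lattice spacing
#'   (nm); an error is raised if the lattice cell is smaller (guaranteed
#'   clashes).
#' @return a single-frame [labeled_trajectory()].
#' @export
place_network <- function(spec, min_separation = 0) {
  g <- as.integer(sqrt(spec$chains_per_axis))
  L <- spec$box_side
  cell <- L / g
  if (cell < min_separation)
    stop("chain lattice spacing ", signif(cell, 4),
         " nm is below the required separation ", min_separation, " nm")
  ch <- build_chain(spec)
  per_chain <- nrow(ch$coords)
  n_chains <- spec$chains_per_axis * length(spec$axes)
  coords <- matrix(0, per_chain * n_chains, 3L)
  chain_id <- rep(seq_len(n_chains), each = per_chain)
  shifts <- with_seed(spec$seed, runif(n_chains, 0, L))
  # cyclic permutations mapping the template's +x axis onto x, y, z
  perms <- list(x = c(1L, 2L, 3L), y = c(3L, 1L, 2L), z = c(2L, 3L, 1L))
  cidx <- 0L
  for (a in seq_along(spec$axes)) {
    axis <- spec$axes[a]
    off <- (a - 1L) * spec$lattice_offset * cell
    for (i in seq_len(g)) for (j in seq_len(g)) {
      cidx <- cidx + 1L
      x <- ch$coords
      x[, 1L] <- x[, 1L] + shifts[cidx]
      x[, 2L] <- x[, 2L] + (i - 0.5) * cell + off
      x[, 3L] <- x[, 3L] + (j - 0.5) * cell + off
      rows <- (cidx - 1L) * per_chain + seq_len(per_chain)
      coords[rows, ] <- x[, perms[[axis]], drop = FALSE]
    }
  }
  labels <- ch$labels[rep(seq_len(per_chain), n_chains), ]
  labels$chain <- chain_id
  rownames(labels) <- NULL
  labeled_trajectory(coords, box = rep(L, 3L), labels = labels, time = 0)
}

#' Count glucose rings in a trajectory
#' @param traj a `labeled_trajectory`.
#' @return list with `n_chains` and `n_rings`.
#' @export
network_counts <- function(traj) {
  lab <- traj$labels
  poly <- lab$polymer != "none"
  ch <- unique(lab$chain[poly])
  nr <- sum(vapply(ch, function(cc)
    max(lab$ring[poly & lab$chain == cc], na.rm = TRUE), numeric(1)))
  list(n_chains = length(ch), n_rings = as.integer(nr))
}

#' Fill a configuration with lattice water
#'
#' Places water molecules on a simple-cubic lattice whose default spacing
#' matches the liquid-water number density (33.37 molecules/nm^3, spacing
#' 0.3104 nm), removes lattice sites within an exclusion radius of any
#' polymer heavy atom, then randomly thins (seeded) to an exact target
#' count. The target may also be given as a water weight percentage, which
#' is converted by the closed-form mass balance of [waters_for_wt_pct()].
#'
#' @param traj a single-frame `labeled_trajectory` (may be polymer-free).
#' @param target either `list(count = n)` or `list(wt_pct = w)`.
#' @param spacing water lattice spacing (nm); default density-matched.
#' @param exclusion_radius exclusion radius around polymer heavy atoms (nm).
#' @param seed RNG seed for the thinning.
#' @return a single-frame `labeled_trajectory` with the water appended.
#' @export
solvate_lattice <- function(traj, target, spacing = NULL,
                            exclusion_radius = 0.25, seed = 1L) {
  stopifnot(inherits(traj, "labeled_trajectory"), n_frames(traj) == 1L)
  if (exclusion_radius < 0) stop("exclusion_radius must be >= 0")
  box <- traj$box[1L, ]
  if (is.null(spacing)) spacing <- (1 / 33.37)^(1 / 3)
  if (spacing <= 0) stop("spacing must be positive")
  npts <- pmax(1L, floor(box / spacing))
  grids <- lapply(1:3, function(k) (seq_len(npts[k]) - 0.5) * (box[k] / npts[k]))
  keep <- array(TRUE, dim = npts)
  heavy <- which(traj$labels$polymer != "none" & traj$labels$element != "H")
  if (length(heavy) && exclusion_radius > 0) {
    cellw <- box / npts
    xs <- traj$coords[[1L]][heavy, , drop = FALSE]
    for (m in seq_along(heavy)) {
      p <- xs[m, ]
      rng <- lapply(1:3, function(k) {
        lo <- floor((p[k] - exclusion_radius) / cellw[k] - 0.5)
        hi <- ceiling((p[k] + exclusion_radius) / cellw[k] + 0.5)
        ((lo:hi) %% npts[k]) + 1L
      })
      cand <- as.matrix(expand.grid(rng[[1L]], rng[[2L]], rng[[3L]]))
      pts <- cbind(grids[[1L]][cand[, 1L]], grids[[2L]][cand[, 2L]],
                   grids[[3L]][cand[, 3L]])
      d <- min_image_dist(p, pts, box)
      hit <- cand[d < exclusion_radius, , drop = FALSE]
      if (nrow(hit)) keep[hit] <- FALSE
    }
  }
  avail <- which(keep, arr.ind = TRUE)
  n_avail <- nrow(avail)
  n_target <- if (!is.null(target$count)) {
    as.integer(target$count)
  } else if (!is.null(target$wt_pct)) {
    nr <- network_counts(traj)$n_rings
    if (nr == 0L) stop("wt_pct target requires a polymer network in the frame")
    waters_for_wt_pct(target$wt_pct, nr)
  } else stop("target must be list(count=) or list(wt_pct=)")
  if (n_target > n_avail)
    stop("target of ", n_target, " waters exceeds the ", n_avail,
         " available lattice sites")
  sel <- if (n_target < n_avail)
    with_seed(seed, sort(sample.int(n_avail, n_target))) else seq_len(n_avail)
  opts <- cbind(grids[[1L]][avail[sel, 1L]], grids[[2L]][avail[sel, 2L]],
                grids[[3L]][avail[sel, 3L]])
  # rigid water geometry: O-H 0.1 nm, H-O-H 109.47 deg, fixed orientation
  h1 <- c(0.1, 0, 0)
  h2 <- c(0.1 * cos(109.47 * pi / 180), 0.1 * sin(109.47 * pi / 180), 0)
  nw <- nrow(opts)
  wc <- matrix(0, 3L * nw, 3L)
  wc[seq(1L, 3L * nw, 3L), ] <- opts
  wc[seq(2L, 3L * nw, 3L), ] <- sweep(opts, 2L, h1, "+")
  wc[seq(3L, 3L * nw, 3L), ] <- sweep(opts, 2L, h2, "+")
  wlab <- site_labels(rep(c("O", "H", "H"), nw),
                      rep(c("water_O", "water_H", "water_H"), nw))
  labeled_trajectory(rbind(traj$coords[[1L]], wc), box = box,
                     labels = rbind(traj$labels, wlab), time = traj$time[1L])
}

# Group water sites into molecules: each water oxygen owns the water
# hydrogens that follow it in site order (the builder and readers emit
# O,H,H triples).
water_molecules <- function(labels) {
  o <- which(labels$role == "water_O")
  h <- which(labels$role == "water_H")
  lapply(o, function(i) c(i, h[h > i & h <= i + 2L]))
}

#' Progressive random removal of water
#'
#' Emulates the cascade used to span the concentration series: at each step
#' a given fraction of the surviving water molecules is removed at random
#' (oxygen and both hydrogens together).
#'
#' @param traj a `labeled_trajectory` containing water.
#' @param fractions removal fractions in (0, 1), applied in sequence.
#' @param seed RNG seed.
#' @return a list of trajectories with strictly decreasing water counts.
#' @export
dilution_cascade <- function(traj, fractions, seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions < 1))
  mols <- water_molecules(traj$labels)
  if (!length(mols)) stop("trajectory contains no water molecules")
  out <- vector("list", length(fractions))
  cur <- traj
  with_seed(seed, {
    for (s in seq_along(fractions)) {
      mols <- water_molecules(cur$labels)
      n_rm <- max(1L, round(fractions[s] * length(mols)))
      drop_sites <- unlist(mols[sample.int(length(mols), n_rm)])
      keep <- setdiff(seq_len(n_sites(cur)), drop_sites)
      cur <- labeled_trajectory(lapply(cur$coords, function(x) x[keep, , drop = FALSE]),
                                box = cur$box, labels = cur$labels[keep, ],
                                time = cur$time)
      rownames(cur$labels) <- NULL
      out[[s]] <- cur
    }
  })
  out
}
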