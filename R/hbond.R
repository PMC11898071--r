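# Geometric hydrogen-bond census. A triplet O-H...O is a hydrogen bond if
# the O-O distance is strictly less than 3.2 A and the O-H-O angle at the
# hydrogen is strictly wider than 140 degrees (both boundaries exclusive --
# the documented convention). Each donor hydrogen participates in at most
# one bond per frame: the widest-angle acceptor wins, distance breaking ties.

HB_DIST_A <- 3.2
HB_ANGLE_DEG <- 140
COVALENT_OH_NM <- 0.12

# Candidate O-O pairs closer than cutoff (nm), by cell lists. Falls back to
# the all-pairs path when the box holds fewer than 3 cells per axis (cell
# aliasing); results are identical either way. Returns a 2-column matrix of
# indices into `coords` rows (i < j).
oo_pairs_cell <- function(coords, box, cutoff) {
  n <- nrow(coords)
  if (n < 2L) return(matrix(integer(), 0L, 2L))
  ncell <- floor(box / cutoff)
  if (any(ncell < 3L)) return(oo_pairs_brute(coords, box, cutoff))
  cw <- box / ncell
  ci <- pmin(floor(sweep(coords, 2L, cw, "/")), matrix(ncell - 1L, n, 3L, byrow = TRUE))
  key <- ci[, 1L] + ncell[1L] * (ci[, 2L] + ncell[2L] * ci[, 3L])
  cells <- split(seq_len(n), key)
  coord_of <- function(k) c(k %% ncell[1L],
                            (k %/% ncell[1L]) %% ncell[2L],
                            k %/% (ncell[1L] * ncell[2L]))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[offs[, 3L] > 0L | (offs[, 3L] == 0L & (offs[, 2L] > 0L |
            (offs[, 2L] == 0L & offs[, 1L] >= 0L))), , drop = FALSE]
  res <- vector("list", length(cells) * nrow(offs))
  m <- 0L
  for (ck in names(cells)) {
    a <- cells[[ck]]
    cc <- coord_of(as.numeric(ck))
    for (o in seq_len(nrow(offs))) {
      if (all(offs[o, ] == 0L)) {
        if (length(a) < 2L) next
        pr <- t(utils::combn(a, 2L))
      } else {
        nb <- (cc + offs[o, ]) %% ncell
        nk <- as.character(nb[1L] + ncell[1L] * (nb[2L] + ncell[2L] * nb[3L]))
        b <- cells[[nk]]
        if (is.null(b)) next
        pr <- cbind(rep(a, each = length(b)), rep(b, length(a)))
      }
      m <- m + 1L
      res[[m]] <- pr
    }
  }
  pr <- do.call(rbind, res[seq_len(m)])
  if (is.null(pr) || !nrow(pr)) return(matrix(integer(), 0L, 2L))
  d <- min_image(coords[pr[, 1L], , drop = FALSE],
                 coords[pr[, 2L], , drop = FALSE], box)
  keep <- rowSums(d * d) < cutoff^2
  pr <- pr[keep, , drop = FALSE]
  cbind(pmin(pr[, 1L], pr[, 2L]), pmax(pr[, 1L], pr[, 2L]))
}

oo_pairs_brute <- function(coords, box, cutoff) {
  n <- nrow(coords)
  if (n < 2L) return(matrix(integer(), 0L, 2L))
  dm <- pair_dist_matrix(coords, coords, box)
  hit <- which(dm < cutoff & upper.tri(dm), arr.ind = TRUE)
  cbind(hit[, 1L], hit[, 2L])
}

# Covalent O-H assignment by proximity: each hydrogen belongs to the nearest
# oxygen within 1.2 A. A water hydrogen with no such oxygen is a malformed
# input (error naming the site); a polymer hydrogen with none is carbon-bound
# and silently skipped as a non-donor. Two oxygens within 1.2 A of one
# hydrogen is ambiguous and errors rather than guessing.
assign_covalent <- function(coords, box, labels) {
  h_ids <- which(labels$element == "H")
  o_ids <- which(labels$element == "O")
  if (!length(h_ids) || !length(o_ids))
    return(data.frame(h = integer(), o = integer()))
  dm <- pair_dist_matrix(coords[h_ids, , drop = FALSE],
                         coords[o_ids, , drop = FALSE], box)
  res_h <- integer(); res_o <- integer()
  for (m in seq_along(h_ids)) {
    win <- which(dm[m, ] < COVALENT_OH_NM)
    if (length(win) == 0L) {
      if (labels$role[h_ids[m]] == "water_H")
        stop("water hydrogen site ", h_ids[m], " has no oxygen within 1.2 A")
      next
    }
    if (length(win) > 1L)
      stop("ambiguous covalent assignment: hydrogen site ", h_ids[m],
           " has ", length(win), " oxygens within 1.2 A")
    res_h <- c(res_h, h_ids[m]); res_o <- c(res_o, o_ids[win])
  }
  data.frame(h = res_h, o = res_o)
}

#' Detect hydrogen bonds in one frame
#'
#' Applies the geometric criterion (O-O distance < 3.2 A, O-H-O angle at the
#' hydrogen > 140 degrees, both strict) to all donor-hydrogen/acceptor
#' triplets under minimum-image distances. Neighbour search uses cell lists;
#' `method = "brute"` forces the all-pairs path (identical results, used as
#' an internal cross-check).
#'
#' @param traj a `labeled_trajectory`.
#' @param frame frame index.
#' @param method `"cell"` or `"brute"`.
#' @param dist_cut O-O distance cutoff (A).
#' @param angle_cut O-H-O angle cutoff (degrees).
#' @return data frame with one row per bond: `donor_o`, `donor_h`,
#'   `acceptor_o` (site ids), `dist` (O-O, A), `angle` (degrees), and the
#'   `category` column added by [classify_hbonds()].
#' @export
detect_hbonds <- function(traj, frame = 1L, method = c("cell", "brute"),
                          dist_cut = HB_DIST_A, angle_cut = HB_ANGLE_DEG) {
  method <- match.arg(method)
  x <- traj$coords[[frame]]
  box <- traj$box[frame, ]
  labels <- traj$labels
  cov <- assign_covalent(x, box, labels)
  o_ids <- which(labels$element == "O")
  empty <- data.frame(donor_o = integer(), donor_h = integer(),
                      acceptor_o = integer(), dist = numeric(),
                      angle = numeric())
  if (!nrow(cov) || length(o_ids) < 2L)
    return(classify_hbonds(empty, labels))
  oc <- x[o_ids, , drop = FALSE]
  pairs <- if (method == "cell") oo_pairs_cell(oc, box, dist_cut / 10)
           else oo_pairs_brute(oc, box, dist_cut / 10)
  if (!nrow(pairs)) return(classify_hbonds(empty, labels))
  # adjacency: for each oxygen, the oxygens within the cutoff
  pi1 <- o_ids[pairs[, 1L]]; pi2 <- o_ids[pairs[, 2L]]
  nbr <- split(c(pi2, pi1), c(pi1, pi2))
  rec <- vector("list", nrow(cov))
  for (m in seq_len(nrow(cov))) {
    od <- cov$o[m]; hh <- cov$h[m]
    acc <- nbr[[as.character(od)]]
    if (is.null(acc)) next
    v1 <- min_image(x[od, ], x[hh, ], box)
    v2 <- min_image(x[acc, , drop = FALSE],
                    matrix(x[hh, ], length(acc), 3L, byrow = TRUE), box)
    cosang <- (v2 %*% t(v1))[, 1L] /
      (sqrt(sum(v1 * v1)) * sqrt(rowSums(v2 * v2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    doo <- min_image_dist(x[od, ], x[acc, , drop = FALSE], box) * 10
    ok <- which(ang > angle_cut & doo < dist_cut)
    if (!length(ok)) next
    best <- ok[order(-ang[ok], doo[ok])][1L]
    rec[[m]] <- data.frame(donor_o = od, donor_h = hh,
                           acceptor_o = acc[best],
                           dist = doo[best], angle = ang[best])
  }
  rec <- rec[!vapply(rec, is.null, logical(1L))]
  out <- if (length(rec)) do.call(rbind, rec) else empty
  rownames(out) <- NULL
  classify_hbonds(out, labels)
}

#' Classify hydrogen-bond records by donor/acceptor roles
#'
#' Categories: `ww` (water-water), `poly_to_water` (donated by a saccharide
#' hydroxyl to water), `water_to_poly` (donated by water to a saccharide
#' oxygen), `intrachain` and `interchain` (both partners on chains, same or
#' different chain id). Every record lands in exactly one category.
#'
#' @param records data frame from [detect_hbonds()].
#' @param labels the trajectory's label table.
#' @return `records` with a `category` column.
#' @export
classify_hbonds <- function(records, labels) {
  if (!nrow(records)) {
    records$category <- character(0)
    return(records)
  }
  d_poly <- labels$polymer[records$donor_o] != "none"
  a_poly <- labels$polymer[records$acceptor_o] != "none"
  same_chain <- labels$chain[records$donor_o] == labels$chain[records$acceptor_o]
  records$category <- ifelse(!d_poly & !a_poly, "ww",
                      ifelse(d_poly & !a_poly, "poly_to_water",
                      ifelse(!d_poly & a_poly, "water_to_poly",
                      ifelse(same_chain, "intrachain", "interchain"))))
  records
}

#' Hydrogen-bond census over a trajectory
#'
#' Runs [detect_hbonds()] on a set of frames and aggregates: counts per
#' category and the average number of water-polysaccharide bonds per glucose
#' unit, split into bonds donated by the chains to water and accepted by the
#' chains from water (hydroxyls alone can donate; every chain oxygen can
#' accept).
#'
#' @param traj a `labeled_trajectory`.
#' @param frames frame indices (default: all).
#' @param method passed to [detect_hbonds()].
#' @return an object of class `hbond_census`: list with `records` (one data
#'   frame per frame), `counts` (category totals), `n_frames`, `n_rings`,
#'   and `n_hb` (per-glucose donated/accepted averages).
#' @export
hbond_census <- function(traj, frames = seq_len(n_frames(traj)),
                         method = c("cell", "brute")) {
  method <- match.arg(method)
  recs <- lapply(frames, function(f) detect_hbonds(traj, f, method = method))
  all_rec <- do.call(rbind, recs)
  cats <- c("ww", "poly_to_water", "water_to_poly", "intrachain", "interchain")
  counts <- stats::setNames(integer(length(cats)), cats)
  tb <- table(all_rec$category)
  counts[names(tb)] <- as.integer(tb)
  nr <- network_counts(traj)$n_rings
  n_hb <- if (nr > 0L) {
    list(donated = counts[["poly_to_water"]] / (nr * length(frames)),
         accepted = counts[["water_to_poly"]] / (nr * length(frames)))
  } else list(donated = NA_real_, accepted = NA_real_)
  structure(list(records = recs, frames = frames, counts = counts,
                 n_frames = length(frames), n_rings = nr, n_hb = n_hb),
            class = "hbond_census")
}

#' @export
print.hbond_census <- function(x, ...) {
  cat("H-bond census over", x$n_frames, "frame(s):",
      sum(x$counts), "bonds\n")
  print(x$counts)
  if (!is.na(x$n_hb$donated))
    cat(sprintf("  n_HB per glucose: donated %.3f, accepted %.3f\n",
                x$n_hb$donated, x$n_hb$accepted))
  invisible(x)
}

#' @export
summary.hbond_census <- function(object, ...) {
  print(object)
  per_frame <- vapply(object$records, nrow, integer(1L))
  cat("  bonds per frame: min", min(per_frame), "mean",
      signif(mean(per_frame), 4), "max", max(per_frame), "\n")
  invisible(object)
}

#' Water-mediated hydrogen-bond wire lengths
#'
#' A water molecule that simultaneously accepts a hydrogen bond from one
#' saccharide hydroxyl and donates one to another chain oxygen forms a link
#' of an alternating water-polysaccharide wire. This builds the directed
#' graph whose nodes are chain oxygens and whose edges are such waters, and
#' reports the lengths (in water units) of all maximal paths.
#'
#' @param census an `hbond_census`.
#' @param labels the trajectory's label table.
#' @param frame which census frame to analyse (position in `census$frames`).
#' @return integer vector: a histogram `table()` of maximal wire lengths
#'   (empty if no water links exist).
#' @export
wire_lengths <- function(census, labels, frame = 1L) {
  rec <- census$records[[frame]]
  ptw <- rec[rec$category == "poly_to_water", , drop = FALSE]
  wtp <- rec[rec$category == "water_to_poly", , drop = FALSE]
  if (!nrow(ptw) || !nrow(wtp)) return(table(integer()))
  # edges: poly oxygen donating to water w -> poly oxygen accepting from w
  waters <- intersect(ptw$acceptor_o, wtp$donor_o)
  if (!length(waters)) return(table(integer()))
  edges <- do.call(rbind, lapply(waters, function(w) {
    from <- ptw$donor_o[ptw$acceptor_o == w]
    to <- wtp$acceptor_o[wtp$donor_o == w]
    expand.grid(from = from, to = to, water = w)
  }))
  adj <- split(seq_len(nrow(edges)), edges$from)
  sources <- setdiff(unique(edges$from), unique(edges$to))
  starts <- if (length(sources)) sources else unique(edges$from)
  lengths_out <- integer(0)
  walk <- function(node, used_edges, used_nodes, depth) {
    out_e <- setdiff(adj[[as.character(node)]] %||% integer(0), used_edges)
    out_e <- out_e[!(edges$to[out_e] %in% used_nodes)]
    if (!length(out_e)) {
      if (depth > 0L) lengths_out <<- c(lengths_out, depth)
      return(invisible())
    }
    for (e in out_e)
      walk(edges$to[e], c(used_edges, e), c(used_nodes, edges$to[e]), depth + 1L)
  }
  for (s in starts) walk(s, integer(0), s, 0L)
  table(lengths_out)
}

#' Waters hydrogen-bonded to two or more distinct chains
#'
#' A water molecule is bridging if its polysaccharide-involving hydrogen
#' bonds (donated or accepted) span at least two chain ids. Such waters tie
#' chains together and contribute to the cohesion of the gel at low water
#' content.
#'
#' @param census an `hbond_census`.
#' @param labels the trajectory's label table.
#' @param frame which census frame to analyse.
#' @return list with `count`, `fraction` (of all water molecules) and the
#'   bridging water oxygen `ids`.
#' @export
bridging_waters <- function(census, labels, frame = 1L) {
  rec <- census$records[[frame]]
  n_water <- sum(labels$role == "water_O")
  poly_rec <- rec[rec$category %in% c("poly_to_water", "water_to_poly"), ,
                  drop = FALSE]
  if (!nrow(poly_rec) || n_water == 0L)
    return(list(count = 0L, fraction = 0, ids = integer(0)))
  wat <- ifelse(poly_rec$category == "poly_to_water",
                poly_rec$acceptor_o, poly_rec$donor_o)
  pol <- ifelse(poly_rec$category == "poly_to_water",
                poly_rec$donor_o, poly_rec$acceptor_o)
  chains <- labels$chain[pol]
  nch <- vapply(split(chains, wat), function(z) length(unique(z)), integer(1L))
  ids <- as.integer(names(nch)[nch >= 2L])
  list(count = length(ids), fraction = length(ids) / n_water, ids = ids)
}
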