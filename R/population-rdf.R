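# Radial distribution functions over selected oxygen subpopulations,
# including frame-dependent restricted populations (water H-bonded to the
# chains), and the decomposition of the ~4.8 A hydroxyl-hydroxyl peak by
# pair category. Radial arguments are in Angstrom; coordinates stay in nm.

#' Radial distribution function between two site populations
#'
#' Histograms minimum-image pair distances from a reference to a target
#' population. Two normalisations are provided: `"bulk_density"` divides
#' each shell by the ideal-gas expectation `4 pi r^2 dr * rho_target *
#' N_ref` per frame (the textbook g(r), which tends to 1 at large r for
#' homogeneous populations), and `"shell_count"` reports the raw average
#' number of target sites per reference per shell. For restricted,
#' non-isotropic populations (e.g. only waters H-bonded to the chains) the
#' radial variable is a 1-D projection and g(r) need not approach 1;
#' `shell_count` is the honest default there.
#'
#' @param traj a `labeled_trajectory`.
#' @param ref,target site selections: an index vector, a population name,
#'   or a list of per-frame index vectors (one per analysed frame).
#' @param r_max histogram range (A); must be below half the smallest box
#'   edge.
#' @param dr bin width (A).
#' @param mode `"bulk_density"` or `"shell_count"`.
#' @param frames frame indices to average over.
#' @return class `rdf_result`: data frame with `r` (bin centers, A), `g`,
#'   `count`; attributes `mode`, `ref`, `target`.
#' @export
rdf <- function(traj, ref, target, r_max = 12, dr = 0.05,
                mode = c("bulk_density", "shell_count"),
                frames = seq_len(n_frames(traj))) {
  mode <- match.arg(mode)
  resolve <- function(sel, f, fi) {
    if (is.character(sel)) select_population(traj, sel)
    else if (is.list(sel)) sel[[fi]]
    else sel
  }
  nm <- function(sel) if (is.character(sel)) sel else
    attr(sel, "name") %||% "custom"
  edges <- seq(0, r_max, by = dr)
  nb <- length(edges) - 1L
  counts <- numeric(nb); expected <- numeric(nb)
  tot_ref <- 0L
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    box <- traj$box[f, ]
    if (r_max / 10 >= min(box) / 2)
      stop("r_max = ", r_max, " A reaches half the box; reduce it")
    rs <- resolve(ref, f, fi); ts <- resolve(target, f, fi)
    if (!length(rs) || !length(ts))
      stop("empty reference or target selection in frame ", f,
           "; rdf needs at least one site on each side")
    dm <- pair_dist_matrix(traj$coords[[f]][rs, , drop = FALSE],
                           traj$coords[[f]][ts, , drop = FALSE], box) * 10
    same <- outer(rs, ts, "==")
    d <- dm[!same]
    h <- graphics::hist(d[d < r_max], breaks = edges, plot = FALSE)
    counts <- counts + h$counts
    tot_ref <- tot_ref + length(rs)
    if (mode == "bulk_density") {
      vol_A3 <- prod(box) * 1e3
      rho_t <- length(ts) / vol_A3
      rc <- (edges[-1L] + edges[-length(edges)]) / 2
      expected <- expected + length(rs) * 4 * pi * rc^2 * dr * rho_t
    }
  }
  rc <- (edges[-1L] + edges[-length(edges)]) / 2
  g <- if (mode == "bulk_density") counts / pmax(expected, .Machine$double.xmin)
       else counts / tot_ref
  structure(data.frame(r = rc, g = g, count = counts),
            class = c("rdf_result", "data.frame"),
            mode = mode, ref = nm(ref), target = nm(target))
}

#' @export
print.rdf_result <- function(x, ...) {
  cat("rdf ", attr(x, "ref"), " -> ", attr(x, "target"), " (",
      attr(x, "mode"), "), ", nrow(x), " bins up to ",
      signif(max(x$r), 4), " A\n", sep = "")
  invisible(x)
}

#' @export
plot.rdf_result <- function(x, ...) {
  graphics::plot(x$r, x$g, type = "l", xlab = "r (Å)",
                 ylab = if (attr(x, "mode") == "bulk_density") "g(r)"
                        else "shell count", ...)
  invisible(x)
}

#' Per-frame selection of waters hydrogen-bonded to the chains
#'
#' Builds, for each censused frame, the selection of water oxygens carrying
#' at least one hydrogen bond to a polysaccharide oxygen (donated or
#' accepted). The result is a per-frame selection list directly usable as
#' the `ref` or `target` of [rdf()].
#'
#' @param traj the `labeled_trajectory` the census came from.
#' @param census an [hbond_census()] over frames of `traj`.
#' @return list of integer vectors, one per census frame.
#' @export
hbonded_water_selection <- function(traj, census) {
  if (any(census$frames > n_frames(traj)))
    stop("census frames do not match the trajectory")
  lab <- traj$labels
  lapply(census$records, function(rec) {
    pw <- rec[rec$category == "poly_to_water", "acceptor_o"]
    wp <- rec[rec$category == "water_to_poly", "donor_o"]
    ids <- sort(unique(c(pw, wp)))
    ids[lab$role[ids] == "water_O"]
  })
}

.pair_categories <- c("same_ring_C2_C4", "same_ring_C4_C6",
                      "neighbor_ring_C2_C4", "other_intrachain", "interchain")

#' Decompose hydroxyl-pair distances in a radial window by category
#'
#' Classifies every hydroxyl-oxygen pair whose minimum-image distance falls
#' in the window (default 4.55-5.15 A, bracketing the ~4.8 A peak) by the
#' structural relation of its members: same-ring C2-C4, same-ring C4-C6,
#' neighbouring-ring C2-C4, any other intrachain pair, or interchain.
#' Same-ring classification takes precedence over neighbour-ring, which
#' takes precedence over the generic categories. Chain-terminal hydroxyls
#' (no carbon attachment) are excluded.
#'
#' @param traj a `labeled_trajectory`.
#' @param window length-2 distance window (A).
#' @param frame frame index.
#' @return class `pair_breakdown`: data frame with `category`, `n`,
#'   `fraction` (fractions sum to 1 over the window).
#' @export
peak_category_breakdown <- function(traj, window = c(4.55, 5.15), frame = 1L) {
  lab <- traj$labels
  hyd <- which(lab$role == "poly_hydroxyl_O")
  if (!length(hyd)) stop("no hydroxyl oxygens in the trajectory")
  if (all(is.na(lab$attach[hyd])))
    stop("hydroxyl oxygens carry no carbon-attachment labels")
  hyd <- hyd[!is.na(lab$attach[hyd])]
  box <- traj$box[frame, ]
  dm <- pair_dist_matrix(traj$coords[[frame]][hyd, , drop = FALSE],
                         traj$coords[[frame]][hyd, , drop = FALSE], box) * 10
  hit <- which(dm > window[1L] & dm < window[2L] & upper.tri(dm), arr.ind = TRUE)
  cats <- character(nrow(hit))
  if (nrow(hit)) {
    i <- hyd[hit[, 1L]]; j <- hyd[hit[, 2L]]
    same_chain <- lab$chain[i] == lab$chain[j]
    same_ring <- same_chain & lab$ring[i] == lab$ring[j]
    nbr_ring <- same_chain & abs(lab$ring[i] - lab$ring[j]) == 1L
    aset <- paste(pmin(lab$attach[i], lab$attach[j]),
                  pmax(lab$attach[i], lab$attach[j]), sep = "-")
    cats <- ifelse(same_ring & aset == "2-4", "same_ring_C2_C4",
            ifelse(same_ring & aset == "4-6", "same_ring_C4_C6",
            ifelse(nbr_ring & aset == "2-4", "neighbor_ring_C2_C4",
            ifelse(same_chain, "other_intrachain", "interchain"))))
  }
  n <- vapply(.pair_categories, function(cc) sum(cats == cc), integer(1L))
  out <- data.frame(category = .pair_categories, n = as.integer(n),
                    fraction = if (sum(n)) n / sum(n) else rep(0, length(n)))
  rownames(out) <- NULL
  structure(out, class = c("pair_breakdown", "data.frame"),
            window = window, n_pairs = sum(n))
}
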