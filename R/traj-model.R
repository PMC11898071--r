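# Core data model: labeled trajectories, site labels, selections, composition.

#' Molar masses used throughout the package (g/mol)
#'
#' Water and anhydroglucose-residue molar masses used by
#' [composition_summary()] and the solvation mass balance. The per-chain
#' terminal correction (+18 g/mol) is deliberately ignored; at 48 rings per
#' chain the error is below 0.03 %.
#' @name molar-masses
#' @keywords internal
M_WATER <- 18.0153
M_RING  <- 162.141

.role_levels <- c("water_O", "water_H", "poly_hydroxyl_O", "poly_ring_O",
                  "poly_glycosidic_O", "poly_C", "poly_H")

#' Construct a site-label table
#'
#' One row per site. Water sites must have `polymer = "none"`; the carbon
#' attachment is defined only for hydroxyl oxygens.
#'
#' @param element character, one of `"O"`, `"H"`, `"C"`.
#' @param role character, one of `r paste(.role_levels, collapse = ", ")`.
#' @param polymer character, `"callose"`, `"cellulose"` or `"none"`.
#' @param chain integer chain id (NA for water).
#' @param ring integer ring index within the chain, 1-based (NA for water).
#' @param attach integer carbon attachment (2, 3, 4 or 6) for hydroxyl
#'   oxygens, NA otherwise.
#' @return a `data.frame` with the six columns above.
#' @export
site_labels <- function(element, role, polymer = "none", chain = NA_integer_,
                        ring = NA_integer_, attach = NA_integer_) {
  n <- length(role)
  lab <- data.frame(
    element = rep_len(as.character(element), n),
    role    = rep_len(as.character(role), n),
    polymer = rep_len(as.character(polymer), n),
    chain   = rep_len(as.integer(chain), n),
    ring    = rep_len(as.integer(ring), n),
    attach  = rep_len(as.integer(attach), n),
    stringsAsFactors = FALSE
  )
  validate_labels(lab)
  lab
}

validate_labels <- function(lab) {
  stopifnot(is.data.frame(lab))
  need <- c("element", "role", "polymer", "chain", "ring", "attach")
  if (!all(need %in% names(lab)))
    stop("labels must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(lab$role), .role_levels)
  if (length(bad))
    stop("unknown site roles: ", paste(bad, collapse = ", "))
  water <- lab$role %in% c("water_O", "water_H")
  if (any(lab$polymer[water] != "none"))
    stop("water sites must have polymer = 'none'")
  if (any(!is.na(lab$attach) & lab$role != "poly_hydroxyl_O"))
    stop("carbon attachment is defined only for hydroxyl oxygens")
  invisible(lab)
}

#' Construct a labeled trajectory
#'
#' The substrate of every analysis in the package: an ordered sequence of
#' frames (time, orthorhombic box, N x 3 coordinates in nm) plus an immutable
#' per-site label table. Coordinates are wrapped into `[0, L)` per axis on
#' ingest; unwrapping is an explicit, separate operation ([unwrap()]) so that
#' every analysis states its periodic-image convention.
#'
#' @param coords a single N x 3 matrix or a list of N x 3 matrices (nm),
#'   one per frame.
#' @param box a length-3 vector (constant box) or an `n_frames` x 3 matrix of
#'   per-frame box edge lengths (nm). Orthorhombic only.
#' @param labels a label table from [site_labels()].
#' @param time numeric frame times in ps, strictly increasing.
#' @return an object of class `labeled_trajectory` with elements `time`,
#'   `box` (matrix), `coords` (list of wrapped matrices) and `labels`.
#' @examples
#' lab <- site_labels("O", "water_O")
#' tr <- labeled_trajectory(matrix(c(1, 1, 1), 1, 3), box = c(3, 3, 3), labels = lab)
#' n_frames(tr)
#' @export
labeled_trajectory <- function(coords, box, labels, time = NULL) {
  if (is.matrix(coords)) coords <- list(coords)
  stopifnot(length(coords) >= 1L)
  nf <- length(coords)
  if (is.null(dim(box))) box <- matrix(box, nf, 3L, byrow = TRUE)
  box <- as.matrix(box)
  if (nrow(box) == 1L && nf > 1L) box <- box[rep(1L, nf), , drop = FALSE]
  if (nrow(box) != nf || ncol(box) != 3L)
    stop("box must be a length-3 vector or an n_frames x 3 matrix")
  if (any(box <= 0)) stop("box lengths must be positive (orthorhombic only)")
  n <- nrow(coords[[1L]])
  validate_labels(labels)
  if (nrow(labels) != n)
    stop("labels (", nrow(labels), " rows) do not match coordinates (N = ", n, ")")
  if (is.null(time)) time <- seq_len(nf) - 1
  if (length(time) != nf) stop("time must have one entry per frame")
  if (nf > 1L && any(diff(time) <= 0)) stop("frame times must be strictly increasing")
  for (f in seq_len(nf)) {
    x <- as.matrix(coords[[f]])
    if (nrow(x) != n || ncol(x) != 3L)
      stop("frame ", f, ": coordinate dimensions differ from frame 1")
    coords[[f]] <- wrap_coords(x, box[f, ])
  }
  structure(list(time = as.numeric(time), box = box, coords = coords,
                 labels = labels),
            class = "labeled_trajectory")
}

#' @export
print.labeled_trajectory <- function(x, ...) {
  cat("Labeled trajectory:", n_sites(x), "sites,", n_frames(x), "frame(s)\n")
  cat("  time range (ps): ", x$time[1L], "..", x$time[n_frames(x)], "\n", sep = "")
  cat("  box, frame 1 (nm): ", paste(signif(x$box[1L, ], 4), collapse = " x "), "\n", sep = "")
  tab <- table(x$labels$role)
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames / sites in a trajectory
#' @param traj a `labeled_trajectory`.
#' @export
n_frames <- function(traj) length(traj$coords)

#' @rdname n_frames
#' @export
n_sites <- function(traj) nrow(traj$labels)

#' Extract a subset of frames
#' @param x a `labeled_trajectory`.
#' @param i frame indices.
#' @param ... unused.
#' @export
`[.labeled_trajectory` <- function(x, i, ...) {
  structure(list(time = x$time[i], box = x$box[i, , drop = FALSE],
                 coords = x$coords[i], labels = x$labels),
            class = "labeled_trajectory")
}

.population_names <- c("water_oxygens", "poly_oxygens", "all_oxygens",
                       "poly_hydroxyl_oxygens")

#' Select a named oxygen population
#'
#' The analyses distinguish three oxygen populations: water oxygens,
#' polysaccharide oxygens, and their (disjoint) union. Hydroxyl oxygens of
#' the chains are additionally selectable on their own, and an arbitrary
#' predicate on the label table is accepted for custom selections. Whether
#' ring and glycosidic oxygens belong to the "polysaccharide oxygen"
#' population is a convention; here they do, with the hydroxyl-only
#' selection available separately.
#'
#' @param traj a `labeled_trajectory`.
#' @param name one of `"water_oxygens"`, `"poly_oxygens"`, `"all_oxygens"`,
#'   `"poly_hydroxyl_oxygens"`, or a function taking the label table and
#'   returning a logical vector.
#' @return an integer vector of site indices (1-based) with attributes
#'   `name`.
#' @examples
#' lab <- site_labels(rep(c("O", "H", "H"), 3), rep(c("water_O", "water_H", "water_H"), 3))
#' tr <- labeled_trajectory(matrix(runif(27), 9, 3), box = c(2, 2, 2), labels = lab)
#' select_population(tr, "water_oxygens")  # 1, 4, 7
#' @export
select_population <- function(traj, name) {
  lab <- traj$labels
  if (is.function(name)) {
    keep <- name(lab)
    stopifnot(is.logical(keep), length(keep) == nrow(lab))
    ids <- which(keep)
    nm <- "custom"
  } else {
    keep <- switch(name,
      water_oxygens = lab$role == "water_O",
      poly_oxygens = lab$role %in% c("poly_hydroxyl_O", "poly_ring_O",
                                     "poly_glycosidic_O"),
      all_oxygens = lab$element == "O",
      poly_hydroxyl_oxygens = lab$role == "poly_hydroxyl_O",
      stop("unknown population '", name, "'; valid names: ",
           paste(.population_names, collapse = ", "),
           ", or a predicate function")
    )
    ids <- which(keep)
    nm <- name
  }
  structure(ids, name = nm)
}

#' Composition arithmetic for water/glucan mixtures
#'
#' Converts molecule counts into the two composition measures used for the
#' sample series: the water weight percentage and the number of water
#' molecules per glucose ring. Molar masses are fixed at 18.0153 g/mol
#' (water) and 162.141 g/mol (anhydroglucose residue).
#'
#' @param n_water number of water molecules.
#' @param n_rings number of glucose rings (> 0).
#' @return a list with `water_wt_pct` and `waters_per_ring`.
#' @examples
#' composition_summary(478307, 9216)  # ~85 wt %, 51.9 waters per ring
#' @export
composition_summary <- function(n_water, n_rings) {
  if (n_water < 0 || n_rings <= 0)
    stop("n_water must be >= 0 and n_rings > 0")
  m_w <- n_water * M_WATER
  m_p <- n_rings * M_RING
  list(water_wt_pct = 100 * m_w / (m_w + m_p),
       waters_per_ring = n_water / n_rings)
}

#' Water count for a target water weight percentage
#'
#' Closed-form mass balance inverse of [composition_summary()]:
#' `n_w = (wt / (100 - wt)) * (m_ring * n_rings) / m_water`, rounded to the
#' nearest whole molecule.
#'
#' @param wt_pct target water weight percentage in (0, 100).
#' @param n_rings number of glucose rings.
#' @export
waters_for_wt_pct <- function(wt_pct, n_rings) {
  if (wt_pct <= 0 || wt_pct >= 100) stop("wt_pct must be in (0, 100)")
  round((wt_pct / (100 - wt_pct)) * (M_RING * n_rings) / M_WATER)
}
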