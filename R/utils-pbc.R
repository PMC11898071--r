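# Periodic-boundary helpers for orthorhombic boxes. All coordinates in nm.

#' Wrap coordinates into the primary cell
#'
#' Maps every coordinate into `[0, L)` per axis for an orthorhombic box.
#'
#' @param x numeric matrix, N x 3 (nm).
#' @param box numeric length-3 vector of box edge lengths (nm).
#' @return matrix of the same shape with all entries in `[0, L)`.
#' @keywords internal
wrap_coords <- function(x, box) {
  stopifnot(is.matrix(x), ncol(x) == 3L, length(box) == 3L, all(box > 0))
  sweep(x, 2L, box, function(a, L) a - floor(a / L) * L)
}

#' Minimum-image displacement
#'
#' Componentwise displacement `a - b` folded into `[-L/2, L/2)`.
#'
#' @param a,b N x 3 matrices or length-3 vectors (nm).
#' @param box length-3 box (nm).
#' @keywords internal
min_image <- function(a, b, box) {
  d <- a - b
  if (is.null(dim(d))) d <- matrix(d, ncol = 3L)
  sweep(d, 2L, box, function(v, L) v - round(v / L) * L)
}

#' Minimum-image distances between one point and many
#' @keywords internal
min_image_dist <- function(p, pts, box) {
  d <- min_image(pts, matrix(p, nrow(pts), 3L, byrow = TRUE), box)
  sqrt(rowSums(d * d))
}

# All minimum-image pair distances between two coordinate sets (small N only).
# Returns an n_a x n_b matrix.
pair_dist_matrix <- function(a, b, box) {
  n_a <- nrow(a); n_b <- nrow(b)
  out <- matrix(0, n_a, n_b)
  for (k in 1:3) {
    d <- outer(a[, k], b[, k], "-")
    d <- d - round(d / box[k]) * box[k]
    out <- out + d * d
  }
  sqrt(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
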