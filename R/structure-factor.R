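# Per-population static structure factors on box-commensurate wavevectors,
# shell-binned over |k|, with low-k prepeak detection. Wavevector magnitudes
# are quoted in 1/Angstrom (the field's convention); coordinates stay in nm.

# Integer-triple wavevectors commensurate with an orthorhombic box:
# k = 2*pi*(nx/Lx, ny/Ly, nz/Lz), 0 < |k| <= kmax. Inversion symmetry makes
# k and -k redundant for S(k), so only a half space is enumerated.
make_kvecs <- function(box_nm, kmax_inv_A) {
  kmax <- kmax_inv_A * 10  # 1/nm
  nmax <- floor(kmax * box_nm / (2 * pi))
  if (any(nmax < 1))
    stop("kmax too small: no commensurate wavevector fits the box")
  gx <- seq.int(-nmax[1L], nmax[1L]); gy <- seq.int(-nmax[2L], nmax[2L])
  gz <- seq.int(0L, nmax[3L])  # half space: nz > 0, or nz == 0 and (ny, nx) lexic.
  tr <- as.matrix(expand.grid(nx = gx, ny = gy, nz = gz))
  keep <- tr[, 3L] > 0L | (tr[, 3L] == 0L & (tr[, 2L] > 0L |
            (tr[, 2L] == 0L & tr[, 1L] > 0L)))
  tr <- tr[keep, , drop = FALSE]
  k <- sweep(tr, 2L, 2 * pi / box_nm, "*")          # 1/nm
  kmag <- sqrt(rowSums(k * k))
  sel <- kmag <= kmax + 1e-12
  # both components and magnitudes in 1/A, the package-wide k convention
  list(k = k[sel, , drop = FALSE] / 10, kmag = kmag[sel] / 10)
}

#' Collective density Fourier amplitude
#'
#' Computes `rho_k = sum_j exp(i k . r_j)` over a site selection, as an
#' exact complex sum.
#'
#' @param traj a `labeled_trajectory`.
#' @param sel integer site selection (see [select_population()]); must be
#'   non-empty.
#' @param kvecs M x 3 matrix of wavevectors in 1/Angstrom.
#' @param frame frame index.
#' @return complex vector of length M.
#' @export
rho_k <- function(traj, sel, kvecs, frame = 1L) {
  if (!length(sel)) stop("empty selection: rho_k needs at least one site")
  kvecs <- matrix(as.numeric(kvecs), ncol = 3L)
  r <- traj$coords[[frame]][sel, , drop = FALSE]
  phase <- (kvecs * 10) %*% t(r)   # k in 1/nm times r in nm
  rowSums(exp(1i * phase))
}

#' Static structure factor per oxygen population
#'
#' `S(k) = <|rho_k|^2> / N` averaged over frames (taken as independent
#' configurations) and over all commensurate wavevectors falling in each
#' `|k|` shell. For fluctuating (NPT-style) boxes the commensurate integer
#' grid is regenerated per frame while the shell edges stay fixed in 1/A,
#' so shell membership may vary across frames; this is the documented
#' contract for barostat trajectories.
#'
#' @param traj a `labeled_trajectory`.
#' @param sel site selection, or a population name passed to
#'   [select_population()].
#' @param kmax maximum `|k|` (1/A).
#' @param dk shell width (1/A).
#' @param stride frame stride (default 10).
#' @return an object of class `sf_result`: data frame columns `k`
#'   (shell centers, 1/A), `S`, `n_vectors`, plus attributes `population`
#'   and `N`.
#' @export
structure_factor <- function(traj, sel, kmax = 3.0, dk = 0.02, stride = 10L) {
  if (is.character(sel)) sel <- select_population(traj, sel)
  if (!length(sel)) stop("empty selection")
  frames <- seq(1L, n_frames(traj), by = stride)
  if (!length(frames)) stop("no frames after stride")
  edges <- seq(0, kmax, by = dk)
  if (edges[length(edges)] < kmax) edges <- c(edges, edges[length(edges)] + dk)
  nsh <- length(edges) - 1L
  ssum <- numeric(nsh); cnt <- integer(nsh)
  n_alpha <- length(sel)
  for (f in frames) {
    kv <- make_kvecs(traj$box[f, ], kmax)
    rho <- rho_k(traj, sel, kv$k, frame = f)
    s <- Re(rho * Conj(rho)) / n_alpha
    sh <- findInterval(kv$kmag, edges, rightmost.closed = TRUE)
    ok <- sh >= 1L & sh <= nsh
    ssum <- ssum + unname(tapply2(s[ok], sh[ok], nsh))
    cnt <- cnt + unname(tapply2(rep(1L, sum(ok)), sh[ok], nsh))
  }
  keep <- cnt > 0L
  out <- data.frame(k = (edges[-length(edges)] + edges[-1L])[keep] / 2,
                    S = ssum[keep] / cnt[keep],
                    n_vectors = cnt[keep])
  structure(out, class = c("sf_result", "data.frame"),
            population = attr(sel, "name") %||% "custom", N = n_alpha,
            kmax = kmax, dk = dk)
}

# fast fixed-length group sum
tapply2 <- function(x, g, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- rowsum(as.numeric(x), g)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

#' @export
print.sf_result <- function(x, ...) {
  cat("Structure factor, population '", attr(x, "population"), "' (N = ",
      attr(x, "N"), ")\n", sep = "")
  cat("  ", nrow(x), " shells, k in [", signif(min(x$k), 3), ", ",
      signif(max(x$k), 3), "] 1/A\n", sep = "")
  invisible(x)
}

#' @export
plot.sf_result <- function(x, ...) {
  graphics::plot(x$k, x$S, type = "l", xlab = "k (1/Å)", ylab = "S(k)",
                 main = paste0("S(k): ", attr(x, "population")), ...)
  graphics::abline(h = 1, lty = 3, col = "grey")
  invisible(x)
}

#' Locate the low-k prepeak of a structure factor
#'
#' Finds the largest local maximum of S(k) strictly below `k_upper` after
#' 3-point moving-average smoothing. The default upper bound is the main
#' liquid-water structure peak `k_nn = 2 pi / 2.85 A^-1`; a prepeak below it
#' signals nanoscale water/polymer domain alternation.
#'
#' @param result an `sf_result`.
#' @param k_upper upper bound (1/A); defaults to `2 * pi / 2.85`.
#' @return `list(k, height)` of the prepeak, or `NULL` if S(k) is monotone
#'   below `k_upper`.
#' @export
find_prepeak <- function(result, k_upper = 2 * pi / 2.85) {
  sub <- result[result$k < k_upper, , drop = FALSE]
  if (nrow(sub) < 5L)
    stop("fewer than 5 shells below k_upper = ", signif(k_upper, 4),
         "; refine dk or extend the grid")
  s <- sub$S
  sm <- stats::filter(s, rep(1 / 3, 3L), sides = 2L)
  sm[1L] <- mean(s[1:2]); sm[length(s)] <- mean(s[(length(s) - 1L):length(s)])
  sm <- as.numeric(sm)
  i <- which(diff(sign(diff(sm))) < 0) + 1L  # interior local maxima
  if (!length(i)) return(NULL)
  best <- i[which.max(sm[i])]
  list(k = sub$k[best], height = sub$S[best])
}
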