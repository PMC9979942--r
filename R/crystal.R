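#' Gaussian description of a crystal in reciprocal space
#'
#' Holds the reciprocal unit cell and the parameters that broaden its
#' lattice points into Gaussian peaks: the intrinsic reciprocal peak shape
#' (shape transform of the finite crystal), isotropic mosaicity (rotational
#' disorder, tangential broadening) and scalar strain (relative cell-size
#' variation, radial broadening), plus the linear scale factor and B factor
#' used when intensities are predicted.
#'
#' @param R 3x3 reciprocal unit-cell matrix whose *columns* are the
#'   reciprocal basis vectors (nm^-1 per Miller index unit), so a peak sits
#'   at `x = R %*% c(h, k, l)`. The text dialects serialize R row-wise as
#'   three basis vectors; [read_geometry()]-style readers transpose.
#' @param shape_cov 3x3 PSD reciprocal peak-shape covariance (nm^-2).
#' @param mosaicity Standard deviation of rotational disorder (radians).
#' @param strain Standard deviation of relative cell-size variation.
#' @param scale_a Linear intensity scale factor (> 0).
#' @param b_factor B factor (nm^2): Gaussian intensity decay
#'   `exp(-B |x|^2 / 2)` with resolution.
#' @return Object of class `crystal_model`.
#' @examples
#' cr <- crystal_model(R = diag(3) / 8, shape_cov = diag(3) * 1e-6,
#'                     mosaicity = 1e-3, strain = 5e-4)
#' reciprocal_peak(cr, c(1, 2, 0))
#' @export
crystal_model <- function(R, shape_cov = diag(3) * 1e-6, mosaicity = 0,
                          strain = 0, scale_a = 1, b_factor = 0) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3L, 3L)))
  if (abs(det(R)) < 1e-300) stop("reciprocal cell matrix must be nonsingular")
  shape_cov <- as.matrix(shape_cov)
  ev <- eigen((shape_cov + t(shape_cov)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (any(ev < -1e-12 * max(sum(ev), 1e-300))) {
    stop("shape_cov must be positive semidefinite")
  }
  stopifnot(mosaicity >= 0, strain >= 0, scale_a > 0)
  structure(list(R = R, shape_cov = (shape_cov + t(shape_cov)) / 2,
                 mosaicity = mosaicity, strain = strain,
                 scale_a = scale_a, b_factor = b_factor),
            class = "crystal_model")
}

#' @export
print.crystal_model <- function(x, ...) {
  cat("Crystal model\n")
  cat("  reciprocal cell (columns, nm^-1):\n")
  print(signif(x$R, 6))
  cat(sprintf("  mosaicity = %g rad, strain = %g\n", x$mosaicity, x$strain))
  cat(sprintf("  scale a = %g, B = %g nm^2\n", x$scale_a, x$b_factor))
  invisible(x)
}

#' Reciprocal-space positions of Miller indices
#'
#' @param crystal A [crystal_model()].
#' @param hkl Length-3 integer vector or n x 3 matrix of Miller indices.
#' @return 3-vector or n x 3 matrix of positions (nm^-1).
#' @export
reciprocal_position <- function(crystal, hkl) {
  if (is.matrix(hkl)) {
    t(crystal$R %*% t(hkl))
  } else {
    drop(crystal$R %*% as.numeric(hkl))
  }
}

#' Gaussian kernel of one reciprocal lattice peak
#'
#' Mean `x = R hkl`; covariance is the sum of the shape-transform
#' covariance, the tangential mosaic broadening
#' `mosaicity^2 (|x|^2 I - x x')` and the radial strain broadening
#' `strain^2 x x'`. Both disorder terms vanish at the origin. The mosaic
#' term is the second-moment linearization of an isotropic small-angle
#' rotation distribution, valid for mosaicity << 1 rad.
#'
#' @param crystal A [crystal_model()].
#' @param hkl Length-3 Miller index.
#' @return A [gauss_kernel()] with weight 1.
#' @export
reciprocal_peak <- function(crystal, hkl) {
  x <- reciprocal_position(crystal, hkl)
  xx <- outer(x, x)
  cov <- crystal$shape_cov +
    crystal$mosaicity^2 * (sum(x^2) * diag(3) - xx) +
    crystal$strain^2 * xx
  gauss_kernel(1, x, psd_clip(cov))
}

#' Independent parameter count of a crystal kernel
#'
#' Nine for the reciprocal unit cell, six for the symmetric peak-shape
#' covariance and one each for mosaicity and strain; the linear scale and
#' B factor are counted only when scaling is included.
#'
#' @param crystal A [crystal_model()] (structural count; values unused).
#' @param include_scaling Count scale and B factor too?
#' @return Integer: 17, or 19 with scaling.
#' @export
crystal_dof_count <- function(crystal = NULL, include_scaling = FALSE) {
  n <- 9L + 6L + 1L + 1L
  if (include_scaling) n <- n + 2L
  n
}

# --- vectorized Ewald-offset statistics ------------------------------------
#
# For an n x 3 matrix of reciprocal peak positions X, computes for each row:
#   u       outgoing/radial unit direction through the closest point of the
#           Ewald sphere (the planar-slab normal and approximate w_max)
#   delta   signed radial offset of the peak from the sphere (nm^-1)
#   sig2    projected variance u' (cov_peak + cov_delta_k) u
#   maha    Mahalanobis distance sqrt(delta^2 * u' Sigma^-1 u) from the
#           product-overlap exponent
# The per-row 3x3 inverse uses the cofactor form; entries are kept as
# column vectors throughout.
ewald_offset_stats <- function(crystal, beam, X, mosaicity = NULL,
                               strain = NULL) {
  if (!is.matrix(X)) X <- matrix(X, ncol = 3L)
  sm <- if (is.null(mosaicity)) crystal$mosaicity else mosaicity
  ss <- if (is.null(strain)) crystal$strain else strain
  nu0 <- beam$nu0
  win <- beam$w_in
  v1 <- X[, 1] + nu0 * win[1]
  v2 <- X[, 2] + nu0 * win[2]
  v3 <- X[, 3] + nu0 * win[3]
  r <- sqrt(v1^2 + v2^2 + v3^2)
  r <- pmax(r, 1e-300)
  u1 <- v1 / r; u2 <- v2 / r; u3 <- v3 / r
  delta <- r - nu0
  # Sigma_total entries: shape + mosaic + strain + delta-k
  s2 <- X[, 1]^2 + X[, 2]^2 + X[, 3]^2
  sh <- crystal$shape_cov
  d1 <- u1 - win[1]; d2 <- u2 - win[2]; d3 <- u3 - win[3]
  bb <- nu0^2 * beam$bandwidth^2
  dv <- nu0^2 * beam$divergence^2
  a11 <- sh[1, 1] + sm^2 * (s2 - X[, 1]^2) + ss^2 * X[, 1]^2 +
    bb * d1^2 + dv * (1 - win[1]^2)
  a22 <- sh[2, 2] + sm^2 * (s2 - X[, 2]^2) + ss^2 * X[, 2]^2 +
    bb * d2^2 + dv * (1 - win[2]^2)
  a33 <- sh[3, 3] + sm^2 * (s2 - X[, 3]^2) + ss^2 * X[, 3]^2 +
    bb * d3^2 + dv * (1 - win[3]^2)
  a12 <- sh[1, 2] + (ss^2 - sm^2) * X[, 1] * X[, 2] +
    bb * d1 * d2 - dv * win[1] * win[2]
  a13 <- sh[1, 3] + (ss^2 - sm^2) * X[, 1] * X[, 3] +
    bb * d1 * d3 - dv * win[1] * win[3]
  a23 <- sh[2, 3] + (ss^2 - sm^2) * X[, 2] * X[, 3] +
    bb * d2 * d3 - dv * win[2] * win[3]
  # projected variance along u
  sig2 <- a11 * u1^2 + a22 * u2^2 + a33 * u3^2 +
    2 * (a12 * u1 * u2 + a13 * u1 * u3 + a23 * u2 * u3)
  # cofactor inverse quadratic form u' Sigma^-1 u
  A11 <- a22 * a33 - a23^2
  A22 <- a11 * a33 - a13^2
  A33 <- a11 * a22 - a12^2
  A12 <- a13 * a23 - a12 * a33
  A13 <- a12 * a23 - a13 * a22
  A23 <- a12 * a13 - a11 * a23
  dets <- a11 * A11 + a12 * A12 + a13 * A13
  q <- (A11 * u1^2 + A22 * u2^2 + A33 * u3^2 +
          2 * (A12 * u1 * u2 + A13 * u1 * u3 + A23 * u2 * u3)) / dets
  maha <- sqrt(pmax(0, delta^2 * q))
  list(u = cbind(u1, u2, u3), delta = delta, sig2 = sig2, maha = maha,
       s2 = s2)
}

# strict significance test shared by the exhaustive and region-growing
# traversals: within the resolution sphere and within sigma_cutoff
excitation_test <- function(crystal, beam, H, sigma_cutoff, d_min) {
  X <- reciprocal_position(crystal, H)
  st <- ewald_offset_stats(crystal, beam, X)
  (st$s2 <= (1 / d_min)^2) & (st$maha < sigma_cutoff)
}

#' Reflections excited by a beam
#'
#' Finds every Miller index inside the resolution sphere whose Mahalanobis
#' distance from the diffraction condition -- the exponent of the
#' incoherent product overlap between the reciprocal peak kernel and the
#' diffraction-vector (Ewald) kernel, evaluated at the peak's closest
#' approach to the sphere -- is below `sigma_cutoff`. The region-growing
#' traversal walks the integer lattice with 26-neighbour connectivity from
#' seeds on the Ewald sphere and prunes cells that cannot intersect the
#' diffraction condition; it is an acceleration, not an approximation, and
#' returns the same set as exhaustive enumeration.
#'
#' @param crystal A [crystal_model()].
#' @param beam A [beam_model()].
#' @param sigma_cutoff Positive Mahalanobis cutoff (larger values integrate
#'   reflections further from the diffraction condition: overprediction).
#' @param d_min Resolution limit (nm); reflections with `|x| > 1/d_min` are
#'   excluded.
#' @param method `"region"` (region growing) or `"exhaustive"`.
#' @param include_origin Keep (0,0,0) (the direct beam)? Default `FALSE`.
#' @return `data.frame` with columns `h`, `k`, `l`, `maha` (distance from
#'   the diffraction condition), ordered lexicographically.
#' @export
excited_reflections <- function(crystal, beam, sigma_cutoff = 3,
                                d_min = 0.4,
                                method = c("region", "exhaustive"),
                                include_origin = FALSE) {
  stopifnot(sigma_cutoff > 0, d_min > 0)
  method <- match.arg(method)
  q_max <- 1 / d_min
  Rinv <- solve(crystal$R)
  # index bounds of the resolution sphere: |h_i| <= q_max * ||row_i(R^-1)||
  hb <- ceiling(q_max * sqrt(rowSums(Rinv^2))) + 1L
  H <- if (method == "exhaustive") {
    as.matrix(expand.grid(h = -hb[1]:hb[1], k = -hb[2]:hb[2],
                          l = -hb[3]:hb[3]))
  } else {
    region_grow_indices(crystal, beam, sigma_cutoff, q_max, hb)
  }
  X <- reciprocal_position(crystal, H)
  st <- ewald_offset_stats(crystal, beam, X)
  keep <- (st$s2 <= q_max^2) & (st$maha < sigma_cutoff)
  if (!include_origin) keep <- keep & rowSums(H != 0) > 0
  out <- data.frame(h = H[keep, 1], k = H[keep, 2], l = H[keep, 3],
                    maha = st$maha[keep])
  out <- out[order(out$h, out$k, out$l), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# quasi-uniform directions on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# region-growing traversal of the integer lattice. Cells are admitted for
# traversal with a relaxed cutoff: the strict cutoff plus the worst-case
# Mahalanobis change over one lattice step, bounded by the cell diagonal in
# reciprocal length over the smallest shape-covariance standard deviation.
region_grow_indices <- function(crystal, beam, sigma_cutoff, q_max, hb) {
  lam_min <- min(eigen(crystal$shape_cov, symmetric = TRUE,
                       only.values = TRUE)$values)
  if (lam_min <= 0) {
    stop("region growing requires a nonsingular shape covariance; ",
         "use method = \"exhaustive\"")
  }
  step_q <- sqrt(3) * sqrt(max(colSums(crystal$R^2)))
  margin <- step_q / sqrt(lam_min)
  relaxed <- sigma_cutoff + margin
  q_relaxed <- q_max + step_q

  dims <- 2L * hb + 1L
  visited <- array(FALSE, dim = dims)
  idx_of <- function(H) {
    ((H[, 3] + hb[3]) * dims[2] + (H[, 2] + hb[2])) * dims[1] +
      (H[, 1] + hb[1]) + 1L
  }
  # seeds: lattice points nearest to the Ewald sphere along many directions
  W <- fibonacci_sphere(256L)
  Xs <- beam$nu0 * sweep(W, 2, beam$w_in)
  Hs <- t(round(solve(crystal$R) %*% t(Xs)))
  ok <- abs(Hs[, 1]) <= hb[1] & abs(Hs[, 2]) <= hb[2] & abs(Hs[, 3]) <= hb[3]
  Hs <- unique(Hs[ok, , drop = FALSE])
  storage.mode(Hs) <- "integer"

  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(nb != 0) > 0, , drop = FALSE]
  storage.mode(nb) <- "integer"

  accepted <- matrix(integer(0), ncol = 3L)
  frontier <- Hs
  visited[idx_of(frontier)] <- TRUE
  while (nrow(frontier) > 0) {
    X <- reciprocal_position(crystal, frontier)
    st <- ewald_offset_stats(crystal, beam, X)
    live <- (st$s2 <= q_relaxed^2) & (st$maha < relaxed)
    accepted <- rbind(accepted, frontier[live, , drop = FALSE])
    grow <- frontier[live, , drop = FALSE]
    if (nrow(grow) == 0) break
    cand <- grow[rep(seq_len(nrow(grow)), each = nrow(nb)), , drop = FALSE] +
      nb[rep(seq_len(nrow(nb)), times = nrow(grow)), , drop = FALSE]
    inb <- abs(cand[, 1]) <= hb[1] & abs(cand[, 2]) <= hb[2] &
      abs(cand[, 3]) <= hb[3]
    cand <- cand[inb, , drop = FALSE]
    if (nrow(cand) == 0) break
    ii <- idx_of(cand)
    first <- !duplicated(ii)
    cand <- cand[first, , drop = FALSE]
    ii <- ii[first]
    new <- !visited[ii]
    cand <- cand[new, , drop = FALSE]
    if (nrow(cand) > 0) visited[ii[new]] <- TRUE
    frontier <- cand
  }
  colnames(accepted) <- c("h", "k", "l")
  accepted
}
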