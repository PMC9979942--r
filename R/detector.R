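#' Rigid detector panel
#'
#' A panel maps fast-scan/slow-scan pixel coordinates to lab-frame
#' positions via `position = origin + D %*% c(fs, ss)`. Pixel indices are
#' 0-based with pixel centres at half-integer offsets; the lab frame is
#' right-handed with the beam along +z by default and the interaction point
#' at the origin.
#'
#' @param D 3x2 matrix of lab displacements per fs/ss pixel step (m/pixel);
#'   columns must be linearly independent.
#' @param origin Lab position (m) of the corner of pixel (0, 0).
#' @param n_fs,n_ss Pixel counts (>= 1).
#' @param gain Detector response in counts per wavenumber per photon (> 0).
#' @param name Panel identifier used in geometry files and image sets.
#' @return Object of class `panel`.
#' @examples
#' p <- panel(D = cbind(c(75e-6, 0, 0), c(0, 75e-6, 0)),
#'            origin = c(-7.5e-3, -7.5e-3, 0.1), n_fs = 200, n_ss = 200)
#' pixel_direction(p, 99.5, 99.5)
#' @export
panel <- function(D, origin, n_fs, n_ss, gain = 1, name = "panel0") {
  D <- as.matrix(D)
  stopifnot(all(dim(D) == c(3L, 2L)))
  cr <- c(D[2, 1] * D[3, 2] - D[3, 1] * D[2, 2],
          D[3, 1] * D[1, 2] - D[1, 1] * D[3, 2],
          D[1, 1] * D[2, 2] - D[2, 1] * D[1, 2])
  if (sqrt(sum(cr^2)) < 1e-30) stop("panel basis columns must be independent")
  stopifnot(n_fs >= 1, n_ss >= 1, gain > 0, length(origin) == 3L)
  structure(list(D = D, origin = as.numeric(origin),
                 n_fs = as.integer(n_fs), n_ss = as.integer(n_ss),
                 gain = gain, name = as.character(name)),
            class = "panel")
}

#' @export
print.panel <- function(x, ...) {
  cat(sprintf("Panel '%s': %d x %d px, gain %g\n",
              x$name, x$n_fs, x$n_ss, x$gain))
  invisible(x)
}

#' Detector built from rigid panels
#'
#' @param panels List of [panel()] objects with unique names.
#' @return Object of class `detector_geometry`.
#' @export
detector_geometry <- function(panels) {
  if (inherits(panels, "panel")) panels <- list(panels)
  nm <- vapply(panels, function(p) p$name, character(1))
  if (anyDuplicated(nm)) stop("panel names must be unique")
  names(panels) <- nm
  structure(list(panels = panels), class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat("Detector with", length(x$panels), "panel(s)\n")
  for (p in x$panels) print(p)
  invisible(x)
}

# lab position of sampling points (pixel centres at fs + 0.5, ss + 0.5 when
# integer indices are supplied to the exported helpers)
panel_position <- function(p, fs, ss) {
  cbind(p$origin[1] + p$D[1, 1] * fs + p$D[1, 2] * ss,
        p$origin[2] + p$D[2, 1] * fs + p$D[2, 2] * ss,
        p$origin[3] + p$D[3, 1] * fs + p$D[3, 2] * ss)
}

#' Outgoing direction sampled by a pixel
#'
#' Normalized direction from the interaction point (lab origin) to the
#' pixel-centre position `origin + D %*% c(fs + 0.5, ss + 0.5)`.
#'
#' @param p A [panel()].
#' @param fs,ss 0-based pixel indices (vectors allowed; fractional values
#'   address sub-pixel positions directly).
#' @return Unit 3-vector, or n x 3 matrix for vector input.
#' @export
pixel_direction <- function(p, fs, ss) {
  v <- panel_position(p, fs + 0.5, ss + 0.5)
  r <- sqrt(rowSums(v^2))
  if (any(r < 1e-12)) stop("pixel coincides with the interaction point")
  out <- v / r
  if (nrow(out) == 1L) drop(out) else out
}

#' Derivatives of the pixel direction w.r.t. detector coordinates
#'
#' The derivative of the normed directionality vector:
#' `dw/dfs = (I - w w') D[,1] / |v|` and likewise for ss. These are the
#' pixel-edge vectors projected onto the unit sphere; they set the solid
#' angle and the detector point-spread covariance.
#'
#' @inheritParams pixel_direction
#' @return List with n x 3 matrices `d_fs` and `d_ss`.
#' @export
direction_derivatives <- function(p, fs, ss) {
  v <- panel_position(p, fs + 0.5, ss + 0.5)
  r <- sqrt(rowSums(v^2))
  w <- v / r
  proj <- function(col) {
    dv <- matrix(col, nrow = nrow(v), ncol = 3L, byrow = TRUE)
    (dv - w * rowSums(w * dv)) / r
  }
  list(d_fs = proj(p$D[, 1]), d_ss = proj(p$D[, 2]))
}

#' Solid angle subtended by a pixel
#'
#' Length of the cross product of the pixel sides projected onto the unit
#' sphere, `|dw/dfs x dw/dss|` (steradians).
#'
#' @inheritParams pixel_direction
#' @return Positive scalar or vector.
#' @export
solid_angle <- function(p, fs, ss) {
  d <- direction_derivatives(p, fs, ss)
  a <- d$d_fs
  b <- d$d_ss
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  out <- sqrt(rowSums(cr^2))
  if (length(out) == 1L) drop(out) else out
}

#' Detector point-spread (smoothing) covariance in direction space
#'
#' Gaussian point-spread covariance used to smooth the predicted flux
#' density analytically without changing the total flux of the pattern:
#' `sigma_plus^2 (d_fs d_fs' + d_ss d_ss')` with `sigma_plus = 0.5 /
#' oversample` pixel extents. The constant 1/2 minimizes the maximum
#' Kullback-Leibler divergence between the properly pixel-integrated
#' Gaussian and the variance-inflated Gaussian sampled at pixel centres
#' (see [kl_smoothing_study()]). Oversampling by an integer factor `s`
#' divides the extent, i.e. the covariance entries by `s^2`.
#'
#' @inheritParams pixel_direction
#' @param oversample Integer sub-pixel oversampling factor (>= 1).
#' @return 3x3 PSD matrix of rank <= 2 (direction space, dimensionless);
#'   multiply by `nu^2` to move to reciprocal space. For vector input a
#'   list of matrices.
#' @export
smoothing_covariance <- function(p, fs, ss, oversample = 1L) {
  stopifnot(oversample >= 1)
  d <- direction_derivatives(p, fs, ss)
  sp2 <- (0.5 / oversample)^2
  one <- function(i) {
    a <- d$d_fs[i, ]
    b <- d$d_ss[i, ]
    sp2 * (outer(a, a) + outer(b, b))
  }
  n <- nrow(d$d_fs)
  if (n == 1L) one(1L) else lapply(seq_len(n), one)
}

#' Numerical study of the KL-optimal smoothing constant
#'
#' Reproduces in one dimension the minimax calibration of the detector
#' point-spread width: the exact pixel-integrated Gaussian (error-function
#' form) is compared with the variance-inflated Gaussian density sampled at
#' pixel centres (not renormalized -- it is a flux estimate), the
#' Kullback-Leibler divergence `sum P log(P/Q)` is maximized over sub-pixel
#' offset and peak width, and the smoothing width minimizing that worst
#' case is returned. The worst case sits in the narrow-peak limit with the
#' peak just inside a pixel edge, where the minimax width is 1/2 pixel.
#'
#' @param sigma_plus_grid Candidate smoothing widths (pixel units).
#' @param sigma_grid Peak widths to maximize over (pixel units); should
#'   reach well below one pixel.
#' @param offset_grid Sub-pixel peak offsets in (0, 0.5\].
#' @return List with `sigma_plus` (the minimax width), `max_kl` (its worst
#'   KL), and the full `profile` (data.frame of width vs worst KL).
#' @export
kl_smoothing_study <- function(sigma_plus_grid = seq(0.3, 0.75, by = 0.005),
                               sigma_grid = exp(seq(log(1e-3), log(3),
                                                    length.out = 40)),
                               offset_grid = c(seq(0.005, 0.12, by = 0.005),
                                               seq(0.15, 0.5, by = 0.05))) {
  half <- 80L
  i <- seq(-half, half)
  kl_one <- function(sp, sigma, mu) {
    P <- stats::pnorm(i + 1, mu, sigma) - stats::pnorm(i, mu, sigma)
    Q <- stats::dnorm(i + 0.5, mu, sqrt(sigma^2 + sp^2))
    ok <- P > 1e-300
    sum(P[ok] * log(P[ok] / Q[ok]))
  }
  worst <- vapply(sigma_plus_grid, function(sp) {
    m <- -Inf
    for (s in sigma_grid) for (mu in offset_grid) {
      m <- max(m, kl_one(sp, s, mu))
    }
    m
  }, numeric(1))
  best <- which.min(worst)
  list(sigma_plus = sigma_plus_grid[best], max_kl = worst[best],
       profile = data.frame(sigma_plus = sigma_plus_grid, max_kl = worst))
}
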