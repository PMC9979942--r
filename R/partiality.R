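#' Outgoing direction of maximal flux for a reflection
#'
#' Maximizes the angular flux density (the incoherent overlap between the
#' diffraction-vector kernel and the reciprocal peak kernel) over the unit
#' sphere of outgoing directions. Initialized at the direction through the
#' peak's closest approach to the Ewald sphere and refined with BFGS in a
#' local two-angle chart, followed by Newton polish steps until the
#' spherical gradient of the log flux is below `tol` (in units of the local
#' angular peak width).
#'
#' @param crystal A [crystal_model()].
#' @param beam A [beam_model()].
#' @param hkl Miller index, not (0, 0, 0).
#' @param tol Stationarity tolerance for the scaled spherical gradient.
#' @param maxit Maximum polish iterations.
#' @return Unit 3-vector `w_max`, with attributes `flux` (the maximal
#'   angular flux density) and `grad_norm` (achieved scaled gradient).
#' @export
optimal_direction <- function(crystal, beam, hkl, tol = 1e-8,
                              maxit = 60L) {
  hkl <- as.numeric(hkl)
  if (all(hkl == 0)) stop("the direct beam (0,0,0) has no optimal direction")
  x <- reciprocal_position(crystal, hkl)
  v <- x + beam$nu0 * beam$w_in
  r <- sqrt(sum(v^2))
  w0 <- if (r > 1e-12) v / r else c(1, 0, 0)
  # local angular scale: projected sigma of the joint kernel over nu0
  st <- ewald_offset_stats(crystal, beam, matrix(x, 1))
  ang <- sqrt(st$sig2[1]) / beam$nu0
  # orthonormal chart around the current direction
  chart <- function(w) {
    a <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a - sum(a * w) * w
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(w[2] * e1[3] - w[3] * e1[2],
            w[3] * e1[1] - w[1] * e1[3],
            w[1] * e1[2] - w[2] * e1[1])
    cbind(e1, e2)
  }
  logf <- function(w) {
    log(max(hkl_direction_terms(crystal, beam, hkl,
                                matrix(w, 1))$incoh, 1e-300))
  }
  # robust first stage: BFGS in the chart anchored at the initial guess
  E0 <- chart(w0)
  to_w <- function(t) {
    wt <- w0 + E0 %*% t
    as.numeric(wt / sqrt(sum(wt^2)))
  }
  opt <- stats::optim(c(0, 0), function(t) -logf(to_w(t)),
                      method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500,
                                     parscale = rep(max(ang, 1e-7), 2)))
  w <- to_w(opt$par)
  # Newton polish on a local chart until the scaled spherical gradient
  # of the log flux is stationary
  for (it in seq_len(maxit)) {
    E <- chart(w)
    f0 <- function(t) {
      wt <- w + E %*% t
      logf(wt / sqrt(sum(wt^2)))
    }
    # gradient with a fine step (the curvature bias of the central
    # difference would otherwise dominate the stationarity measure),
    # Hessian with a moderate one
    hg <- ang / 100
    g <- c((f0(c(hg, 0)) - f0(c(-hg, 0))) / (2 * hg),
           (f0(c(0, hg)) - f0(c(0, -hg))) / (2 * hg))
    h <- ang / 4
    gn <- sqrt(sum(g^2)) * ang  # dimensionless: gradient x angular width
    if (gn < tol) {
      out <- w
      attr(out, "flux") <- exp(logf(w))
      attr(out, "grad_norm") <- gn
      return(out)
    }
    H <- matrix(0, 2, 2)
    f00 <- f0(c(0, 0))
    H[1, 1] <- (f0(c(h, 0)) - 2 * f00 + f0(c(-h, 0))) / h^2
    H[2, 2] <- (f0(c(0, h)) - 2 * f00 + f0(c(0, -h))) / h^2
    H[1, 2] <- H[2, 1] <-
      (f0(c(h, h)) - f0(c(h, -h)) - f0(c(-h, h)) + f0(c(-h, -h))) /
      (4 * h^2)
    step <- tryCatch(-solve(H, g), error = function(e) g * ang^2)
    if (!all(is.finite(step))) step <- g * ang^2
    # backtracking line search along the proposed step
    accepted <- FALSE
    for (bt in 0:8) {
      wn <- w + chart(w) %*% (step / 2^bt)
      wn <- as.numeric(wn / sqrt(sum(wn^2)))
      if (logf(wn) >= f00) {
        w <- wn
        accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      if (gn < sqrt(tol)) {
        # flat to finite-difference precision: accept the iterate
        out <- w
        attr(out, "flux") <- exp(logf(w))
        attr(out, "grad_norm") <- gn
        return(out)
      }
      stop("optimal_direction stalled away from stationarity; best ",
           "direction (", paste(signif(w, 8), collapse = ", "), ")")
    }
  }
  stop("optimal_direction did not reach stationarity; best direction (",
       paste(signif(w, 8), collapse = ", "), ")")
}

#' Closed-form integrated intensity factor of a reflection
#'
#' The angular integral of the flux density over a whole reflection,
#' reduced to one dimension: near the reflection the density of Ewald
#' spheres is approximated as a planar Gaussian slab orthogonal to the
#' optimal outgoing direction `w_max`, and both the slab and the peak
#' kernel are projected onto `w_max`. The factor is
#' `phi(delta; 0, sigma_proj^2) / nu0^2`, where `delta` is the projected
#' offset of the peak centre from the slab centre and `sigma_proj^2` the
#' projected variance of peak plus diffraction-vector kernels (the slab
#' width `d` enters through the latter).
#'
#' @param crystal A [crystal_model()].
#' @param beam A [beam_model()].
#' @param hkl Miller index.
#' @param w_max Optional precomputed optimal direction; the closed-form
#'   closest-approach direction is used when `NULL`.
#' @param tangential_order 1 for the pure planar projection; 3 (default)
#'   additionally applies a 3-point Gauss-Hermite correction along each
#'   tangential principal axis of the footprint. The correction accounts
#'   for the variation of the Ewald slab width across wide (mosaic)
#'   footprints in strongly polychromatic beams, and for the sphere
#'   curvature; it reduces exactly to the planar form when the
#'   diffraction-vector covariance is constant over the footprint.
#' @return Scalar factor (>= 0); multiply by
#'   `J0 |F|^2 a exp(-B|x|^2/2) C g nu_bar` for the predicted reading.
#' @export
integrated_intensity_factor <- function(crystal, beam, hkl, w_max = NULL,
                                        tangential_order = 3L) {
  x <- reciprocal_position(crystal, hkl)
  st <- ewald_offset_stats(crystal, beam, matrix(x, 1))
  ang_extent <- sqrt(st$sig2[1]) / beam$nu0
  if (ang_extent > 0.3) {
    warning("peak angular extent ", signif(ang_extent, 3),
            " rad exceeds the small-peak regime")
  }
  if (is.null(w_max)) {
    u <- st$u[1, ]
  } else {
    u <- as.numeric(w_max)
  }
  mu_dk <- beam$nu0 * (u - beam$w_in)
  delta <- sum(u * (x - mu_dk))
  dk <- delta_k_kernel(beam, u)
  pk <- reciprocal_peak(crystal, hkl)
  Sig <- pk$cov + dk$cov
  sig2 <- drop(t(u) %*% Sig %*% u)
  if (sig2 <= 0) stop("degenerate projected variance for reflection ",
                      paste(hkl, collapse = " "))
  planar <- stats::dnorm(delta, 0, sqrt(sig2)) / beam$nu0^2
  if (tangential_order < 3L) return(planar)
  # tangential footprint of the integrand: conditional 2x2 covariance of
  # the frozen-kernel tangent-plane Gaussian, used as the Gauss-Hermite
  # proposal for the importance-weighted correction
  E <- local_tangent_chart(u)
  B <- cbind(u, E)
  Sb <- t(B) %*% Sig %*% B
  P <- tryCatch(solve(Sb), error = function(e) NULL)
  if (is.null(P)) return(planar)
  Tcov <- tryCatch(solve(P[2:3, 2:3]), error = function(e) NULL)
  if (is.null(Tcov)) return(planar)
  cc <- drop(t(B) %*% (mu_dk - x))
  tstar <- -drop(Tcov %*% (P[2:3, ] %*% cc))
  ed <- eigen((Tcov + t(Tcov)) / 2, symmetric = TRUE)
  sd1 <- sqrt(max(ed$values[1], 0))
  sd2 <- sqrt(max(ed$values[2], 0))
  nodes <- c(-sqrt(3), 0, sqrt(3))
  wts <- c(1 / 6, 2 / 3, 1 / 6)
  g_over_phi <- function(t2) {
    # t2: tangential offset in the chart (nm^-1)
    wdir <- drop(u + (E %*% t2) / beam$nu0)
    wdir <- wdir / sqrt(sum(wdir^2))
    p_t <- beam$nu0 * (wdir - beam$w_in)
    dk_t <- delta_k_kernel(beam, wdir)
    Sig_t <- pk$cov + dk_t$cov
    g <- gauss_density(p_t - x, c(0, 0, 0), Sig_t)
    tt <- t2 - tstar
    q <- drop(t(tt) %*% solve(Tcov, tt))
    phi2 <- exp(-q / 2) / (2 * pi * sqrt(max(det(Tcov), 1e-300)))
    g / phi2
  }
  acc <- 0
  for (i in 1:3) for (j in 1:3) {
    t2 <- tstar + ed$vectors[, 1] * (nodes[i] * sd1) +
      ed$vectors[, 2] * (nodes[j] * sd2)
    acc <- acc + wts[i] * wts[j] * g_over_phi(t2)
  }
  acc / beam$nu0^2
}

# orthonormal tangent basis at a unit vector
local_tangent_chart <- function(w) {
  a <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * w) * w
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(w[2] * e1[3] - w[3] * e1[2],
          w[3] * e1[1] - w[1] * e1[3],
          w[1] * e1[2] - w[2] * e1[1])
  cbind(e1, e2)
}

#' Predicted integrated reading of a reflection
#'
#' `J0 * |F|^2 * a * exp(-B |x|^2 / 2) * C(w_max) * factor * g * nu_bar`:
#' the closed-form intensity factor scaled by incident flux, structure
#' factor, linear scale, B-factor decay, polarization and the
#' energy-integrating detector response.
#'
#' @inheritParams integrated_intensity_factor
#' @param F2 Structure-factor modulus squared (>= 0).
#' @param gain Detector counts per wavenumber per photon.
#' @return Predicted counts.
#' @export
predicted_intensity <- function(crystal, beam, hkl, F2, gain = 1,
                                w_max = NULL) {
  stopifnot(F2 >= 0)
  x <- reciprocal_position(crystal, hkl)
  if (is.null(w_max)) {
    v <- x + beam$nu0 * beam$w_in
    w_max <- v / sqrt(sum(v^2))
  }
  fac <- integrated_intensity_factor(crystal, beam, hkl, w_max)
  nu <- reflection_wavenumber_stats(crystal, beam, hkl, w_max)
  beam$flux * F2 * crystal$scale_a *
    exp(-crystal$b_factor * sum(x^2) / 2) *
    polarization_factor(beam, w_max) * fac * gain * nu$mean
}

#' Wavenumber statistics of a whole reflection
#'
#' Mean and variance of the wavenumber of the photons in one integrated
#' reflection, evaluated at the optimal outgoing direction (the analogues
#' of the per-pixel statistics).
#'
#' @inheritParams integrated_intensity_factor
#' @return List with `mean` (nm^-1) and `var` (nm^-2).
#' @export
reflection_wavenumber_stats <- function(crystal, beam, hkl, w_max = NULL) {
  x <- reciprocal_position(crystal, hkl)
  if (is.null(w_max)) {
    v <- x + beam$nu0 * beam$w_in
    w_max <- v / sqrt(sum(v^2))
  }
  t <- hkl_direction_terms(crystal, beam, hkl,
                           matrix(as.numeric(w_max), 1))
  list(mean = t$nu_bar, var = t$nu_var)
}

#' Partiality of reflections
#'
#' Ratio of the integrated intensity factor at the current orientation to
#' its maximum over rigid reorientations of the crystal. The maximum is
#' attained when the geodesic rotation centres the peak in the Ewald slab
#' (projected offset zero) with unchanged covariance magnitudes, so the
#' partiality is the closed form `exp(-delta^2 / (2 sigma_proj^2))` in
#' \[0, 1\]. Reflections outside the sphere of radius `2 nu0` can never
#' diffract and get partiality 0 with attribute `unreachable`.
#'
#' @param crystal A [crystal_model()].
#' @param beam A [beam_model()].
#' @param hkl Length-3 Miller index or n x 3 matrix.
#' @return Numeric vector of partialities with attribute `unreachable`
#'   (logical vector).
#' @export
partiality <- function(crystal, beam, hkl) {
  H <- if (is.matrix(hkl)) hkl else matrix(as.numeric(hkl), ncol = 3L)
  X <- reciprocal_position(crystal, H)
  st <- ewald_offset_stats(crystal, beam, X)
  p <- exp(-st$delta^2 / (2 * st$sig2))
  unreach <- sqrt(st$s2) > 2 * beam$nu0
  p[unreach] <- 0
  attr(p, "unreachable") <- unreach
  p
}

#' Per-reflection prediction table
#'
#' Closed-form predictions for a set of reflections of one crystal:
#' intensity factor, partiality, wavenumber statistics and the optimal
#' outgoing direction (closest-approach closed form).
#'
#' @param crystal A [crystal_model()].
#' @param beam A [beam_model()].
#' @param hkl n x 3 matrix or data.frame with columns h, k, l.
#' @param crystal_id Identifier column for the output table.
#' @return `data.frame` with columns `crystal_id, h, k, l, factor,
#'   partiality, nu_mean, nu_var, wx, wy, wz`.
#' @export
predict_reflections <- function(crystal, beam, hkl, crystal_id = 1L) {
  H <- if (is.data.frame(hkl)) as.matrix(hkl[, c("h", "k", "l")]) else hkl
  if (!is.matrix(H)) H <- matrix(as.numeric(H), ncol = 3L)
  X <- reciprocal_position(crystal, H)
  st <- ewald_offset_stats(crystal, beam, X)
  p <- exp(-st$delta^2 / (2 * st$sig2))
  fac <- stats::dnorm(st$delta, 0, sqrt(st$sig2)) / beam$nu0^2
  # wavenumber stats at the closest-approach direction, per reflection
  nu_mean <- numeric(nrow(H))
  nu_var <- numeric(nrow(H))
  for (i in seq_len(nrow(H))) {
    t <- hkl_direction_terms(crystal, beam, H[i, ],
                             matrix(st$u[i, ], 1))
    nu_mean[i] <- t$nu_bar
    nu_var[i] <- t$nu_var
  }
  data.frame(crystal_id = crystal_id, h = H[, 1], k = H[, 2], l = H[, 3],
             factor = fac, partiality = p, nu_mean = nu_mean,
             nu_var = nu_var, wx = st$u[, 1], wy = st$u[, 2],
             wz = st$u[, 3])
}
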