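# shared fixtures and independent numerical oracles

rand_cov3 <- function(scale = 1) {
  A <- matrix(rnorm(9), 3)
  scale * (crossprod(A) + 0.3 * diag(3))
}

rand_kernel <- function(scale = 1) {
  gauss_kernel(runif(1, 0.5, 2), rnorm(3), rand_cov3(scale))
}

# tensor-product Gauss-Legendre quadrature of f over a box
# centre +- hw (vectorized integrand over an n x 3 matrix)
gl_quad3 <- function(f, centre, hw, n = 64L) {
  if (requireNamespace("pracma", quietly = TRUE)) {
    gl <- pracma::gaussLegendre(n, -1, 1)
    xs <- gl$x
    ws <- gl$w
  } else {
    # fallback: composite Simpson nodes
    xs <- seq(-1, 1, length.out = n + 1)
    h <- xs[2] - xs[1]
    ws <- h / 3 * c(1, rep(c(4, 2), length.out = n - 1), 1)
  }
  G <- as.matrix(expand.grid(x = centre[1] + hw[1] * xs,
                             y = centre[2] + hw[2] * xs,
                             z = centre[3] + hw[3] * xs))
  W <- as.vector(outer(outer(ws, ws), ws)) * prod(hw)
  sum(W * f(G))
}

# quadrature box that safely contains the mass of both kernels
joint_box <- function(a, b, nsig = 9) {
  lo <- pmin(a$mean, b$mean)
  hi <- pmax(a$mean, b$mean)
  sd <- sqrt(pmax(diag(a$cov), diag(b$cov)))
  list(centre = (lo + hi) / 2, hw = (hi - lo) / 2 + nsig * sd)
}

# orthonormal tangent chart at a unit vector
tangent_chart <- function(w) {
  a <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * w) * w
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(w[2] * e1[3] - w[3] * e1[2],
          w[3] * e1[1] - w[1] * e1[3],
          w[1] * e1[2] - w[2] * e1[1])
  cbind(e1, e2)
}

# dense angular quadrature of the incoherent flux density over a cap
# around w0; independent check of the closed-form integrated factor.
# The grid is aligned to the principal axes of the projected angular
# covariance so that strongly anisotropic (mosaic) peaks are resolved in
# both directions.
angular_quadrature_factor <- function(crystal, beam, hkl, w0,
                                      nsig = 8, n = 201L) {
  E <- tangent_chart(w0)
  pk <- reciprocal_peak(crystal, hkl)
  dk <- delta_k_kernel(beam, w0)
  Sig <- (pk$cov + dk$cov) / beam$nu0^2
  M <- t(E) %*% Sig %*% E
  ed <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ax <- E %*% ed$vectors
  hw <- nsig * sqrt(pmax(ed$values, 1e-16))
  s1 <- seq(-hw[1], hw[1], length.out = n)
  s2 <- seq(-hw[2], hw[2], length.out = n)
  G <- expand.grid(s = s1, t = s2)
  W <- matrix(w0, nrow(G), 3, byrow = TRUE) +
    outer(G$s, ax[, 1]) + outer(G$t, ax[, 2])
  W <- W / sqrt(rowSums(W^2))
  terms <- stillgauss:::hkl_direction_terms(crystal, beam, hkl, W)
  sum(terms$incoh) * (s1[2] - s1[1]) * (s2[2] - s2[1])
}

# exact solid angle of a planar triangle seen from the origin
# (Van Oosterom & Strackee construction)
triangle_solid_angle <- function(R1, R2, R3) {
  r1 <- sqrt(sum(R1^2)); r2 <- sqrt(sum(R2^2)); r3 <- sqrt(sum(R3^2))
  num <- abs(det(cbind(R1, R2, R3)))
  den <- r1 * r2 * r3 + sum(R1 * R2) * r3 + sum(R1 * R3) * r2 +
    sum(R2 * R3) * r1
  2 * atan2(num, den)
}

# a crystal whose (1,0,0) reflection lies exactly on the Ewald sphere in
# the direction w_out, plus a panel centred on the diffracted ray
on_sphere_fixture <- function(beam, theta = 0.25, mosaicity = 4e-3,
                              strain = 5e-4, shape_sigma = 2e-3,
                              pixel = 1e-4, npix = 200L, dist = 0.08) {
  w <- c(sin(theta), 0, cos(theta))
  x <- beam$nu0 * (w - beam$w_in)
  R <- diag(3) / 8
  R[, 1] <- x
  crystal <- crystal_model(R = R, shape_cov = diag(3) * shape_sigma^2,
                           mosaicity = mosaicity, strain = strain)
  ctr <- dist * w / w[3]
  p <- panel(D = cbind(c(pixel, 0, 0), c(0, pixel, 0)),
             origin = c(ctr[1] - npix / 2 * pixel,
                        ctr[2] - npix / 2 * pixel, dist),
             n_fs = npix, n_ss = npix)
  list(crystal = crystal, panel = p, w = w, x = x,
       detector = detector_geometry(p))
}

# random crystal in a random orientation on the synthetic base cell
rand_crystal <- function(mosaicity = 2.6e-3, strain = 5e-4,
                         cell_nm = 8, shape_sigma = 7.5e-4) {
  Q <- stillgauss:::random_rotation(1)[[1]]
  crystal_model(R = Q %*% (diag(3) / cell_nm),
                shape_cov = diag(3) * shape_sigma^2,
                mosaicity = mosaicity, strain = strain)
}
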