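#' Gaussian description of the illumination
#'
#' Collects the source parameters of a still-diffraction experiment: mean
#' wavenumber, relative bandwidth, divergence, beam direction, polarization
#' and flux. The wavenumber convention is `nu = 1/lambda` without a factor
#' of 2*pi; all reciprocal-space quantities are in nm^-1.
#'
#' @param nu0 Mean wavenumber (nm^-1). Give either `nu0` or `wavelength`.
#' @param wavelength Mean wavelength (nm); used as `nu0 = 1/wavelength`.
#' @param bandwidth Relative standard deviation of the wavenumber
#'   distribution (dimensionless).
#' @param divergence Standard deviation of the incidence angle (radians).
#' @param w_in Mean unit beam direction (default along +z).
#' @param polarization_p Degree of polarization in \[0, 1\].
#' @param pol_normal Unit normal of the polarization plane; must be
#'   orthogonal to `w_in` (the beam lies in its own polarization plane).
#' @param flux Incident flux J0 (photons per area; arbitrary units).
#' @return Object of class `beam_model`.
#' @examples
#' beam_model(wavelength = 0.13, bandwidth = 1e-3, divergence = 1e-4)
#' @export
beam_model <- function(nu0 = NULL, wavelength = NULL, bandwidth = 0,
                       divergence = 0, w_in = c(0, 0, 1),
                       polarization_p = 0, pol_normal = c(0, 1, 0),
                       flux = 1) {
  if (is.null(nu0)) {
    if (is.null(wavelength)) stop("give either nu0 or wavelength")
    nu0 <- 1 / wavelength
  }
  w_in <- as.numeric(w_in)
  pol_normal <- as.numeric(pol_normal)
  stopifnot(length(w_in) == 3L, length(pol_normal) == 3L)
  if (abs(sqrt(sum(w_in^2)) - 1) > 1e-9) stop("|w_in| must be 1")
  if (abs(sqrt(sum(pol_normal^2)) - 1) > 1e-9) stop("|pol_normal| must be 1")
  if (abs(sum(w_in * pol_normal)) > 1e-6) {
    stop("pol_normal must be orthogonal to w_in")
  }
  stopifnot(nu0 > 0, bandwidth >= 0, divergence >= 0,
            polarization_p >= 0, polarization_p <= 1, flux >= 0)
  structure(list(nu0 = nu0, bandwidth = bandwidth, divergence = divergence,
                 w_in = w_in, polarization_p = polarization_p,
                 pol_normal = pol_normal, flux = flux),
            class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat("Beam model\n")
  cat(sprintf("  nu0 = %g nm^-1 (lambda = %g nm)\n", x$nu0, 1 / x$nu0))
  cat(sprintf("  bandwidth = %g, divergence = %g rad\n",
              x$bandwidth, x$divergence))
  cat(sprintf("  polarization p = %g, flux = %g\n", x$polarization_p, x$flux))
  invisible(x)
}

#' Covariance of the incident wavevector distribution
#'
#' Transverse divergence ring plus radial wavelength broadening, under the
#' assumption that the angular distribution is isotropic and uncorrelated
#' with the wavelength:
#' `nu0^2 * (divergence^2 (I - w w') + bandwidth^2 w w')`.
#'
#' @param beam A [beam_model()].
#' @return 3x3 PSD matrix (nm^-2).
#' @export
cov_kin <- function(beam) {
  P <- outer(beam$w_in, beam$w_in)
  beam$nu0^2 * (beam$divergence^2 * (diag(3) - P) + beam$bandwidth^2 * P)
}

#' Covariance of the outgoing wavevector distribution
#'
#' The outgoing wave at a fixed detector direction is not affected by
#' divergence and only carries the wavelength distribution along `w_out`:
#' the radial bandwidth component of [cov_kin()] rotated onto `w_out`.
#'
#' @param beam A [beam_model()].
#' @param w_out Unit outgoing direction.
#' @return 3x3 PSD matrix of rank <= 1 (nm^-2).
#' @export
cov_kout <- function(beam, w_out) {
  w_out <- as.numeric(w_out)
  if (abs(sqrt(sum(w_out^2)) - 1) > 1e-9) stop("|w_out| must be 1")
  beam$nu0^2 * beam$bandwidth^2 * outer(w_out, w_out)
}

#' Gaussian kernel of the diffraction vector distribution
#'
#' Distribution of `delta_k = k_out - k_in` for a fixed outgoing direction.
#' The wavelength is preserved by diffraction, so the radial (bandwidth)
#' components of `k_out` and `k_in` are perfectly correlated and partially
#' cancel: with a shared relative wavenumber deviation the bandwidth part of
#' the difference is the rank-1 matrix
#' `nu0^2 bandwidth^2 (w_out - w_in)(w_out - w_in)'`
#' (the correlated difference of the two rank-1 radial factors). The
#' divergence part enters only through `k_in`, is independent, and is added
#' by covariance addition. The mean is `nu0 (w_out - w_in)`, which lies on
#' the Ewald sphere of radius `nu0` centred at `-nu0 w_in`; the weight is 1.
#'
#' @param beam A [beam_model()].
#' @param w_out Unit outgoing direction.
#' @return A [gauss_kernel()].
#' @export
delta_k_kernel <- function(beam, w_out) {
  w_out <- as.numeric(w_out)
  if (abs(sqrt(sum(w_out^2)) - 1) > 1e-9) stop("|w_out| must be 1")
  d <- w_out - beam$w_in
  Pin <- outer(beam$w_in, beam$w_in)
  cov <- beam$nu0^2 * (beam$bandwidth^2 * outer(d, d) +
                         beam$divergence^2 * (diag(3) - Pin))
  gauss_kernel(1, beam$nu0 * d, cov)
}

#' Polarization correction factor
#'
#' Standard partially-polarized Thomson factor
#' `C = p (1 - (w_out . n)^2) + (1 - p) (1 + (w_out . w_in)^2) / 2`,
#' where `n` is the normal of the polarization plane. With this convention
#' `C(w_in) = 1`, and the correction of the mean beam direction is applied
#' to the whole (small) angular distribution.
#'
#' @param beam A [beam_model()].
#' @param w_out Unit outgoing direction, or an n x 3 matrix of directions.
#' @return Scalar (or vector) in (0, 1\].
#' @export
polarization_factor <- function(beam, w_out) {
  if (is.matrix(w_out)) {
    cn <- drop(w_out %*% beam$pol_normal)
    cw <- drop(w_out %*% beam$w_in)
  } else {
    cn <- sum(w_out * beam$pol_normal)
    cw <- sum(w_out * beam$w_in)
  }
  beam$polarization_p * (1 - cn^2) +
    (1 - beam$polarization_p) * (1 + cw^2) / 2
}

#' Independent parameter count of a source kernel
#'
#' Three parameters for the mean direction and six for a possibly
#' correlated distribution of illumination angles and wavelengths.
#'
#' @return Integer 9.
#' @export
source_dof_count <- function() {
  3L + 6L
}
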