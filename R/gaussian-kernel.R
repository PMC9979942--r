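#' Gaussian kernels in reciprocal space
#'
#' A Gaussian kernel is the universal carrier of the diffraction model: a
#' nonnegative weight, a 3-vector mean (reciprocal length, nm^-1) and a 3x3
#' symmetric positive-semidefinite covariance (nm^-2). Kernels are not
#' normalized to one -- the weight is the total mass, so a kernel integrates
#' to its weight over all space. Weights carry physical units implicitly;
#' the algebra never attaches units, callers do.
#'
#' @param weight Nonnegative scalar mass.
#' @param mean Numeric 3-vector.
#' @param cov 3x3 symmetric positive-semidefinite matrix. Rank-deficient
#'   covariances are permitted (e.g. the rank-1 wavelength covariance of a
#'   polychromatic beam); operations that require a density
#'   ([kernel_evaluate()], [kernel_product()]) reject them.
#' @return An object of class `gauss_kernel` with fields `weight`, `mean`,
#'   `cov`.
#' @examples
#' k <- gauss_kernel(1, c(0, 0, 0), diag(3))
#' kernel_evaluate(k, c(0, 0, 0)) # (2*pi)^(-3/2)
#' @export
gauss_kernel <- function(weight = 1, mean = c(0, 0, 0), cov = diag(3)) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  stopifnot(length(mean) == 3L, all(dim(cov) == c(3L, 3L)))
  if (!is.finite(weight) || weight < 0) {
    stop("kernel weight must be a finite nonnegative scalar")
  }
  sc <- max(abs(cov), 1e-300)
  if (max(abs(cov - t(cov))) > 1e-12 * sc) {
    stop("kernel covariance must be symmetric (relative tolerance 1e-12)")
  }
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  tr <- sum(diag(cov))
  if (any(ev < -1e-12 * max(tr, 1e-300))) {
    stop("kernel covariance must be positive semidefinite")
  }
  structure(list(weight = weight, mean = mean, cov = cov),
            class = "gauss_kernel")
}

#' @export
print.gauss_kernel <- function(x, ...) {
  cat("Gaussian kernel\n")
  cat("  weight:", format(x$weight), "\n")
  cat("  mean:  ", paste(format(x$mean, digits = 6), collapse = "  "), "\n")
  cat("  cov eigenvalues:",
      paste(format(eigen(x$cov, symmetric = TRUE,
                         only.values = TRUE)$values, digits = 6),
            collapse = "  "), "\n")
  invisible(x)
}

#' Ordered collection of Gaussian kernels
#'
#' Represents a density expressed as a sum of Gaussian kernels. An empty
#' mixture represents zero density. Evaluation and the pairwise integrals
#' distribute over the members.
#'
#' @param kernels List of [gauss_kernel()] objects (possibly empty).
#' @return Object of class `gauss_mixture`.
#' @export
gauss_mixture <- function(kernels = list()) {
  stopifnot(is.list(kernels))
  for (k in kernels) stopifnot(inherits(k, "gauss_kernel"))
  structure(list(kernels = kernels), class = "gauss_mixture")
}

#' @export
print.gauss_mixture <- function(x, ...) {
  cat("Gaussian mixture of", length(x$kernels), "kernel(s)\n")
  invisible(x)
}

# symmetric PSD square root via eigendecomposition; eigenvalues clipped at 0
# below -1e-12 * trace so numerical noise cannot produce complex roots
sym_sqrt <- function(S) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  e$vectors %*% (lam^0.5 * t(e$vectors))
}

# re-symmetrize and clip tiny negative eigenvalues
psd_clip <- function(S) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  e$vectors %*% (lam * t(e$vectors))
}

# density normalization constant and quadratic form via Cholesky;
# on failure report the null direction for the error message
chol_or_null <- function(S, what = "covariance") {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    e <- eigen(S, symmetric = TRUE)
    null_dir <- e$vectors[, which.min(e$values)]
    stop(sprintf(
      "degenerate %s: singular along direction (%.4g, %.4g, %.4g)",
      what, null_dir[1], null_dir[2], null_dir[3]))
  }
  R
}

# weight-free Gaussian density phi(x; mean, cov); x is a length-3 vector or
# an n x 3 matrix
gauss_density <- function(x, mean, cov) {
  R <- chol_or_null(cov)
  X <- if (is.matrix(x)) x else matrix(x, ncol = 3L)
  z <- backsolve(R, t(X) - mean, transpose = TRUE)
  exp(-0.5 * colSums(z^2)) / ((2 * pi)^1.5 * prod(diag(R)))
}

#' Evaluate a Gaussian kernel (or mixture) at points
#'
#' @param k A [gauss_kernel()] or [gauss_mixture()].
#' @param x Length-3 vector or n x 3 matrix of evaluation points.
#' @return Nonnegative density value(s); a kernel integrates to its weight.
#' @export
kernel_evaluate <- function(k, x) {
  if (inherits(k, "gauss_mixture")) {
    n <- if (is.matrix(x)) nrow(x) else 1L
    out <- numeric(n)
    for (kk in k$kernels) out <- out + kernel_evaluate(kk, x)
    return(out)
  }
  k$weight * gauss_density(x, k$mean, k$cov)
}

#' Pointwise product of two Gaussian kernels
#'
#' The product of two Gaussian densities is a scaled Gaussian: the new mean
#' is the precision-weighted mean, the new covariance the inverse summed
#' precision, and the weight picks up the Gaussian overlap factor
#' `phi(mean_a; mean_b, cov_a + cov_b)`. The returned kernel evaluates to
#' `kernel_evaluate(a, x) * kernel_evaluate(b, x)` everywhere.
#'
#' The implementation uses the solve-based form `cov_a (cov_a+cov_b)^-1
#' cov_b`, which only requires the summed covariance to be nonsingular, so a
#' single rank-deficient factor is tolerated.
#'
#' @param a,b [gauss_kernel()] objects.
#' @return A [gauss_kernel()].
#' @export
kernel_product <- function(a, b) {
  S <- a$cov + b$cov
  R <- chol_or_null(S, "joint covariance (cov_a + cov_b)")
  Sinv_d <- backsolve(R, backsolve(R, a$mean - b$mean, transpose = TRUE))
  mean_p <- b$mean + drop(b$cov %*% Sinv_d)
  cov_p <- psd_clip(a$cov - a$cov %*% backsolve(
    R, backsolve(R, a$cov, transpose = TRUE)))
  w <- a$weight * b$weight * gauss_density(a$mean, b$mean, S)
  gauss_kernel(w, mean_p, cov_p)
}

#' Convolution of two Gaussian kernels
#'
#' Means add, covariances add, weights multiply. Degenerate (including
#' all-zero) covariances are allowed.
#'
#' @param a,b [gauss_kernel()] objects.
#' @return A [gauss_kernel()].
#' @export
kernel_convolve <- function(a, b) {
  gauss_kernel(a$weight * b$weight, a$mean + b$mean, a$cov + b$cov)
}

#' Covariance of a fully correlated difference
#'
#' For two distributions that are perfectly correlated (correlation 1), the
#' covariance of their difference is formed from the difference of the
#' symmetric PSD square roots: `S = sqrtm(cov_out) - sqrtm(cov_in)`,
#' returning `S %*% t(S)` re-symmetrized and clipped to PSD. In one
#' dimension this is the familiar `(sigma_out - sigma_in)^2`; for matrices
#' sharing an eigenbasis it acts eigenvalue-wise as
#' `(sqrt(lambda_out) - sqrt(lambda_in))^2`.
#'
#' @param cov_out,cov_in_parallel 3x3 PSD matrices.
#' @return 3x3 PSD matrix.
#' @export
correlated_difference_cov <- function(cov_out, cov_in_parallel) {
  S <- sym_sqrt(cov_out) - sym_sqrt(cov_in_parallel)
  psd_clip(S %*% t(S))
}

#' Incoherent overlap integral of two kernels or mixtures
#'
#' The integral over all space of the pointwise product of the two
#' densities, i.e. the weight of [kernel_product()]. This is the default
#' (incoherent) flux integral of the diffraction model: densities are the
#' squared amplitudes of contributions with random relative phase, so the
#' squaring happens before the integration. Strictly positive and symmetric
#' in its arguments; mixtures distribute as the sum over kernel pairs.
#'
#' @param a,b [gauss_kernel()] or [gauss_mixture()] objects.
#' @return Scalar overlap.
#' @export
integrate_product_incoherent <- function(a, b) {
  if (inherits(a, "gauss_mixture") || inherits(b, "gauss_mixture")) {
    ka <- if (inherits(a, "gauss_mixture")) a$kernels else list(a)
    kb <- if (inherits(b, "gauss_mixture")) b$kernels else list(b)
    tot <- 0
    for (i in ka) for (j in kb) tot <- tot + integrate_product_incoherent(i, j)
    return(tot)
  }
  a$weight * b$weight * gauss_density(a$mean, b$mean, a$cov + b$cov)
}

# amplitude-overlap term: integral of sqrt(phi_a * phi_b), closed form
amplitude_overlap <- function(a, b) {
  S <- a$cov + b$cov
  R <- chol_or_null(S, "joint covariance (cov_a + cov_b)")
  d <- a$mean - b$mean
  z <- backsolve(R, d, transpose = TRUE)
  da <- det(a$cov)
  db <- det(b$cov)
  sqrt(a$weight * b$weight) * 2^1.5 * (da * db)^0.25 /
    prod(diag(R)) * exp(-sum(z^2) / 4)
}

#' Coherent overlap integral of two kernels or mixtures
#'
#' Coherent contributions add in amplitude before squaring: the amplitude of
#' a kernel is the square root of its density, amplitudes are multiplied and
#' integrated over all space, and the result is squared. For two single
#' Gaussian kernels this differs from [integrate_product_incoherent()] only
#' by the mean-independent scale factor
#' `2^3 (2*pi)^(3/2) sqrt(det(cov_a) det(cov_b)) / sqrt(det(cov_a+cov_b))`;
#' for mixtures the amplitudes of the members interfere, so the coherent
#' result is not the sum of pairwise incoherent overlaps.
#'
#' @param a,b [gauss_kernel()] or [gauss_mixture()] objects.
#' @return Scalar overlap.
#' @export
integrate_product_coherent <- function(a, b) {
  ka <- if (inherits(a, "gauss_mixture")) a$kernels else list(a)
  kb <- if (inherits(b, "gauss_mixture")) b$kernels else list(b)
  amp <- 0
  for (i in ka) for (j in kb) amp <- amp + amplitude_overlap(i, j)
  amp^2
}

#' Project a Gaussian kernel onto a direction
#'
#' One-dimensional marginal along a unit vector `w`: mean `w'mu`, variance
#' `w' cov w`, weight preserved. Degenerate covariances are allowed.
#'
#' @param k A [gauss_kernel()].
#' @param w Unit 3-vector (checked to 1e-9).
#' @return List with `mean`, `var`, `weight`.
#' @export
kernel_project <- function(k, w) {
  w <- as.numeric(w)
  if (abs(sqrt(sum(w^2)) - 1) > 1e-9) {
    stop("projection direction must be a unit vector")
  }
  list(mean = sum(w * k$mean),
       var = max(0, drop(t(w) %*% k$cov %*% w)),
       weight = k$weight)
}
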