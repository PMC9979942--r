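test_that("kernel evaluation matches the closed form and conserves mass", {
  k <- gauss_kernel(1, c(0, 0, 0), diag(3))
  expect_equal(kernel_evaluate(k, c(0, 0, 0)), (2 * pi)^(-1.5))
  set.seed(1)
  k2 <- gauss_kernel(2, rnorm(3), rand_cov3())
  expect_equal(kernel_evaluate(k2, k2$mean),
               2 / sqrt(det(2 * pi * k2$cov)))
  # grid quadrature recovers the weight as total mass
  k3 <- rand_kernel()
  mass <- gl_quad3(function(X) kernel_evaluate(k3, X), k3$mean,
                   rep(9 * sqrt(max(diag(k3$cov))), 3))
  expect_equal(mass, k3$weight, tolerance = 1e-3)
})

test_that("degenerate covariances are rejected with the null direction", {
  S <- diag(c(1, 1, 0))
  k <- gauss_kernel(1, c(0, 0, 0), S)
  expect_error(kernel_evaluate(k, c(0, 0, 0)), "singular along direction")
  expect_error(kernel_product(k, k), "singular along direction")
})

test_that("kernel product equals the pointwise product everywhere", {
  a <- gauss_kernel(1, c(0, 0, 0), diag(3))
  p <- kernel_product(a, a)
  expect_equal(p$mean, c(0, 0, 0))
  expect_equal(p$cov, diag(3) / 2)
  b <- gauss_kernel(1, c(2, 0, 0), diag(3))
  p2 <- kernel_product(a, b)
  expect_equal(p2$mean, c(1, 0, 0))
  expect_equal(p2$cov, diag(3) / 2)
  set.seed(2)
  for (rep in 1:5) {
    ka <- rand_kernel()
    kb <- rand_kernel()
    pr <- kernel_product(ka, kb)
    X <- matrix(rnorm(300), ncol = 3)
    expect_equal(kernel_evaluate(pr, X),
                 kernel_evaluate(ka, X) * kernel_evaluate(kb, X),
                 tolerance = 1e-10)
  }
  # weight linearity
  a2 <- a
  a2$weight <- 2
  expect_equal(kernel_product(a2, b)$weight, 2 * kernel_product(a, b)$weight)
})

test_that("convolution adds means and covariances and is associative", {
  set.seed(3)
  a <- rand_kernel()
  zero <- gauss_kernel(1, c(0, 0, 0), matrix(0, 3, 3))
  id <- kernel_convolve(a, zero)
  expect_equal(id$mean, a$mean)
  expect_equal(id$cov, a$cov)
  i1 <- gauss_kernel(1, c(1, 0, 0), diag(3) * 4)
  i2 <- gauss_kernel(1, c(0, 2, 0), diag(3) * 9)
  expect_equal(kernel_convolve(i1, i2)$cov, diag(3) * 13)
  b <- rand_kernel()
  cc <- rand_kernel()
  ab <- kernel_convolve(a, b)
  ba <- kernel_convolve(b, a)
  expect_equal(ab$mean, ba$mean, tolerance = 1e-12)
  expect_equal(kernel_convolve(ab, cc)$cov,
               kernel_convolve(a, kernel_convolve(b, cc))$cov,
               tolerance = 1e-12)
  # 1-D marginal of the convolution matches direct grid convolution
  grid <- seq(-30, 30, by = 0.01)
  m1 <- dnorm(grid, a$mean[1], sqrt(a$cov[1, 1]))
  m2 <- dnorm(grid, b$mean[1], sqrt(b$cov[1, 1]))
  direct <- convolve(m1, rev(m2), type = "open") * 0.01
  dgrid <- seq(2 * grid[1], 2 * grid[length(grid)], by = 0.01)
  conv <- kernel_convolve(a, b)
  expected <- dnorm(dgrid, conv$mean[1], sqrt(conv$cov[1, 1]))
  expect_lt(max(abs(direct[seq_along(dgrid)] - expected)), 1e-4)
})

test_that("correlated difference of covariances follows the sqrt rule", {
  S <- rand_cov3()
  expect_equal(correlated_difference_cov(S, S), matrix(0, 3, 3),
               tolerance = 1e-12)
  out <- diag(c(4, 0, 0))
  inn <- diag(c(1, 0, 0))
  expect_equal(correlated_difference_cov(out, inn), diag(c(1, 0, 0)))
  # commuting pair: eigenvalue-wise (sqrt difference)^2, checked against
  # a shared-draw Monte Carlo of correlated Gaussian pairs
  set.seed(4)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  lo <- c(4, 2, 1)
  li <- c(1, 0.5, 0.25)
  So <- Q %*% (lo * t(Q))
  Si <- Q %*% (li * t(Q))
  got <- correlated_difference_cov(So, Si)
  want <- Q %*% ((sqrt(lo) - sqrt(li))^2 * t(Q))
  expect_equal(got, want, tolerance = 1e-10)
  z <- matrix(rnorm(3 * 3e5), ncol = 3)
  xo <- z %*% stillgauss:::sym_sqrt(So)
  xi <- z %*% stillgauss:::sym_sqrt(Si)
  emp <- cov(xo - xi)
  expect_lt(max(abs(emp - want)) / max(abs(want)), 0.025)
  # always PSD
  for (rep in 1:20) {
    D <- correlated_difference_cov(rand_cov3(), rand_cov3())
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-12 * sum(diag(D)))
  }
})

test_that("incoherent overlap equals the product weight and the integral", {
  a <- gauss_kernel(1, c(0, 0, 0), diag(3))
  expect_equal(integrate_product_incoherent(a, a), (4 * pi)^(-1.5))
  set.seed(5)
  for (rep in 1:5) {
    ka <- rand_kernel()
    kb <- rand_kernel()
    inc <- integrate_product_incoherent(ka, kb)
    expect_gt(inc, 0)
    expect_identical(inc, integrate_product_incoherent(kb, ka))
    expect_equal(inc, kernel_product(ka, kb)$weight, tolerance = 1e-14)
    # translation invariance: depends on means only via the difference
    shift <- rnorm(3)
    ka2 <- ka
    kb2 <- kb
    ka2$mean <- ka$mean + shift
    kb2$mean <- kb$mean + shift
    expect_equal(integrate_product_incoherent(ka2, kb2), inc,
                 tolerance = 1e-12)
    # quadrature oracle; the box is centred on the product support
    pr <- kernel_product(ka, kb)
    q <- gl_quad3(function(X) {
      kernel_evaluate(ka, X) * kernel_evaluate(kb, X)
    }, pr$mean, 10 * sqrt(diag(pr$cov)) + 0.1)
    expect_equal(q / inc, 1, tolerance = 1e-6)
  }
})

test_that("coherent overlap has the integrate-then-square ordering", {
  a <- gauss_kernel(1, c(0, 0, 0), diag(3))
  # identical standard kernels: the amplitude overlap integral is 1
  expect_equal(integrate_product_coherent(a, a), 1)
  set.seed(6)
  for (rep in 1:20) {
    ka <- rand_kernel()
    kb <- rand_kernel()
    ratio <- integrate_product_coherent(ka, kb) /
      integrate_product_incoherent(ka, kb)
    S <- ka$cov + kb$cov
    want <- 2^3 * (2 * pi)^1.5 * sqrt(det(ka$cov) * det(kb$cov)) /
      sqrt(det(S))
    expect_equal(ratio, want, tolerance = 1e-10)
  }
  # two-kernel mixtures interfere: verified against quadrature of the
  # squared summed amplitudes
  for (rep in 1:3) {
    ma <- gauss_mixture(list(rand_kernel(), rand_kernel()))
    mb <- gauss_mixture(list(rand_kernel(), rand_kernel()))
    coh <- integrate_product_coherent(ma, mb)
    inc_sum <- integrate_product_incoherent(ma, mb)
    amp <- 0
    for (ka in ma$kernels) for (kb in mb$kernels) {
      wide_a <- gauss_kernel(1, ka$mean, 2 * ka$cov)
      wide_b <- gauss_kernel(1, kb$mean, 2 * kb$cov)
      pr <- kernel_product(wide_a, wide_b)
      amp <- amp + gl_quad3(function(X) {
        sqrt(kernel_evaluate(ka, X) * kernel_evaluate(kb, X))
      }, pr$mean, 10 * sqrt(diag(pr$cov)) + 0.1, n = 72L)
    }
    expect_equal(coh, amp^2, tolerance = 1e-4)
    expect_false(isTRUE(all.equal(coh, inc_sum, tolerance = 1e-3)))
  }
})

test_that("mixture operations distribute over kernel pairs", {
  set.seed(7)
  ks <- replicate(4, rand_kernel(), simplify = FALSE)
  ma <- gauss_mixture(ks[1:2])
  mb <- gauss_mixture(ks[3:4])
  pairwise <- sum(vapply(ks[1:2], function(a) {
    sum(vapply(ks[3:4], function(b) integrate_product_incoherent(a, b),
               numeric(1)))
  }, numeric(1)))
  expect_equal(integrate_product_incoherent(ma, mb), pairwise)
  X <- matrix(rnorm(30), ncol = 3)
  expect_equal(kernel_evaluate(ma, X),
               kernel_evaluate(ks[[1]], X) + kernel_evaluate(ks[[2]], X))
  expect_equal(kernel_evaluate(gauss_mixture(), X), numeric(10))
})

test_that("1-D projection preserves weight and matches sampling", {
  k <- gauss_kernel(3, c(1, 2, 3), diag(3) * 4)
  pr <- kernel_project(k, c(0, 0, 1))
  expect_equal(pr$var, 4)
  expect_equal(pr$weight, 3)
  # eigenvector direction gives the eigenvalue
  set.seed(8)
  S <- rand_cov3()
  e <- eigen(S, symmetric = TRUE)
  k2 <- gauss_kernel(1, rnorm(3), S)
  pr2 <- kernel_project(k2, e$vectors[, 2])
  expect_equal(pr2$var, e$values[2])
  expect_error(kernel_project(k2, c(1, 1, 0)), "unit vector")
  # sampling oracle
  Z <- matrix(rnorm(3 * 2e5), ncol = 3) %*% stillgauss:::sym_sqrt(S)
  w <- e$vectors[, 1]
  expect_equal(var(drop(Z %*% w)), drop(t(w) %*% S %*% w),
               tolerance = 0.02)
})
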