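test_that("sinc grid follows the printed map", {
  sg <- build_sinc_grid(1, 1, 1, h = log(3))
  expect_equal(sg$z_pts[sg$i0], 0)                     # z_0 = 0 exactly
  expect_equal(sg$z_pts[sg$i0 + 1], 1)                 # 2(-1+3)/(1+3) = 1
  sg2 <- build_sinc_grid(4, 8, 8)
  phi <- function(z) log((2 * 4 + z) / (2 * 4 - z))
  l <- seq.int(-8, 8)
  expect_equal(phi(sg2$z_pts), l * sg2$h, tolerance = 1e-12)
  expect_true(all(diff(sg2$z_pts) > 0))
  expect_true(all(sg2$phi_prime > 0))                  # positive form
  expect_error(build_sinc_grid(1, 40, 40, h = 5), "grid error|collide")
})

test_that("I^(-1) entries match the sine-integral closed form", {
  I5 <- build_Im1(5)
  expect_equal(diag(I5), rep(0.5, 5))
  expect_equal(I5[2, 1], 0.5 + Si_quadrature(pi) / pi, tolerance = 1e-10)
  expect_equal(I5[1, 2], 0.5 - Si_quadrature(pi) / pi, tolerance = 1e-10)
  expect_equal(I5[2, 1], 1.08949, tolerance = 1e-5)
  ## Toeplitz structure and full Si-based oracle
  m <- 12L
  I12 <- build_Im1(m)
  d <- outer(seq_len(m), seq_len(m), "-")
  oracle <- matrix(Si_quadrature(pi * as.vector(d)) / pi + 0.5, m, m)
  expect_lt(max(abs(I12 - oracle)), 1e-10)
})

test_that("kernel transform matches quadrature of the defining integral", {
  set.seed(12)
  maxerr <- 0
  for (i in 1:20) {
    u <- complex(real = runif(1, 0.05, 2), imaginary = runif(1, -2, 2))
    v <- complex(real = runif(1, 0.05, 2), imaginary = runif(1, -2, 2))
    g <- laplace_kernel_G(u, v)
    maxerr <- max(maxerr, Mod(g - G_quadrature(u, v)) / Mod(g))
  }
  expect_lt(maxerr, 1e-6)
  ## printed-example magnitude; the quadrature fixes the sign convention
  expect_equal(laplace_kernel_G(1, 1), pi / 4 - 1i * pi / 4,
               tolerance = 1e-12)
  ## homogeneity: g is homogeneous of degree -1, so G(cu, cv) = c G(u, v)
  u <- 0.7 + 0.2i; v <- 1.1 - 0.4i
  expect_equal(laplace_kernel_G(2 * u, 2 * v), 2 * laplace_kernel_G(u, v),
               tolerance = 1e-12)
  ## conjugate-pair inputs stay finite (removable u = iv handled)
  expect_true(is.finite(Mod(laplace_kernel_G(1 + 1i, 1 - 1i))))
  expect_equal(laplace_kernel_G(1e-14 + 1i, 1 - 1e-14i), 1 - 1e-14i,
               tolerance = 1e-6)
  expect_error(laplace_kernel_G(-1, 1), "domain")
})

test_that("operator build satisfies its structural contracts", {
  sg <- build_sinc_grid(4, 8, 8)
  ops <- build_operators(sg)
  m <- sg$m
  Dinv <- diag(1 / sg$phi_prime)
  expect_equal(ops$A1, sg$h * ops$Im1 %*% Dinv, tolerance = 1e-12)
  expect_equal(ops$A2, sg$h * t(ops$Im1) %*% Dinv, tolerance = 1e-12)
  ## A2 differs from t(A1) by the diagonal right-factor
  expect_equal(ops$A2 %*% diag(sg$phi_prime),
               t(ops$A1 %*% diag(sg$phi_prime)), tolerance = 1e-12)
  expect_lt(max(Mod(ops$X1 %*% (ops$S1 * ops$X1inv) - ops$A1)) /
              max(abs(ops$A1)), 1e-8)
  ## eigenvalues in the right half plane (required for the G domain)
  for (mm in c(9L, 17L, 33L, 65L)) {
    sgm <- build_sinc_grid(4, (mm - 1) %/% 2, (mm - 1) %/% 2)
    expect_true(all(Re(eigen(build_operators(sgm)$A1, only.values = TRUE)
                       $values) > 0))
  }
})

test_that("separated convolution: linearity and structural exactness", {
  sg <- build_sinc_grid(4, 4, 4)
  ops <- build_operators(sg)
  m <- sg$m
  set.seed(31)
  U1 <- matrix(complex(real = rnorm(m^2), imaginary = rnorm(m^2)), m)
  U2 <- matrix(complex(real = rnorm(m^2), imaginary = rnorm(m^2)), m)
  expect_equal(separate_convolve(matrix(0 + 0i, m, m), ops, 1L),
               matrix(0 + 0i, m, m))
  for (q in 1:4) {
    r12 <- separate_convolve(2 * U1 - 3i * U2, ops, q)
    expect_lt(max(Mod(r12 - (2 * separate_convolve(U1, ops, q) -
                             3i * separate_convolve(U2, ops, q)))), 1e-10)
  }
  ## separable-kernel identity: with G(u,v) = F1(u) F2(v) the separated
  ## procedure must equal sequential 1D operator applications exactly
  F1 <- function(s) s / (1 + s); F2 <- function(s) s / (1 + 2 * s)
  ops2 <- ops
  ops2$Gvals[[1]] <- outer(F1(ops$S1), F2(ops$S1))
  ops2$Gvals[[2]] <- outer(F1(ops$S1), F2(ops$S2))
  M1 <- ops$X1 %*% (F1(ops$S1) * ops$X1inv)
  M2a <- ops$X1 %*% (F2(ops$S1) * ops$X1inv)
  M2b <- ops$X2 %*% (F2(ops$S2) * ops$X2inv)
  expect_lt(max(Mod(separate_convolve(U1, ops2, 1L) - M1 %*% U1 %*% t(M2a))),
            1e-8)
  expect_lt(max(Mod(separate_convolve(U1, ops2, 2L) - M1 %*% U1 %*% t(M2b))),
            1e-8)
  expect_error(separate_convolve(U1[1:3, 1:3], ops, 1L), "contract")
})

test_that("full sinc convolution approximates the true Cauchy convolution", {
  R <- 4
  Ufun <- function(k1, k2) {
    k <- k1 + 1i * k2
    v <- exp(-Mod(k)^2 / 2) * (1 + 0.3i * k)
    v[Mod(k) > R] <- 0
    v
  }
  for (cc in list(list(N = 16L, tol = 0.02), list(N = 32L, tol = 0.005))) {
    sg <- build_sinc_grid(R, cc$N / 2, cc$N / 2)
    ops <- build_operators(sg)
    z <- sg$z_pts
    K <- outer(z, z, function(a, b) complex(real = a, imaginary = b))
    U <- Ufun(Re(K), Im(K))
    r <- eitdbar:::sinc_convolve(U, ops)
    for (ij in list(c(sg$i0, sg$i0), c(sg$i0 + 1, sg$i0),
                    c(sg$i0 + 2, sg$i0 - 1))) {
      o <- cauchy_conv_polar(z[ij[1]], z[ij[2]], Ufun, R)
      expect_lt(Mod(r[ij[1], ij[2]] - o) / Mod(o), cc$tol)
    }
  }
})

test_that("D-bar operator: identity at t = 0, real-linear but not complex-linear", {
  sg <- build_sinc_grid(4, 4, 4)
  ops <- build_operators(sg)
  kg <- k_grid(sg$z_pts, 4)
  m <- sg$m
  tz <- structure(list(values = matrix(0 + 0i, m, m), grid = kg,
                       gamma_best = 1), class = "eit_scattering")
  v <- rnorm(2 * m^2)
  expect_equal(dbar_apply(v, 0.3 + 0.1i, tz, sg, ops), v)
  ## nonzero t: F(a mu) = a F(mu) + (1-a) mu-part fails for a = i
  set.seed(7)
  tv <- matrix(complex(real = rnorm(m^2, sd = .3),
                       imaginary = rnorm(m^2, sd = .3)), m)
  tv[!kg$mask] <- 0
  tnz <- structure(list(values = tv, grid = kg, gamma_best = 1),
                   class = "eit_scattering")
  Fop <- eitdbar:::dbar_operator(0.2 + 0i, tnz, sg, ops)
  mu <- matrix(complex(real = rnorm(m^2), imaginary = rnorm(m^2)), m)
  ## real-linear: F(a mu) - a F(mu) + (a-1) ... check via K = F - I part
  Kpart <- function(x) Fop(x) - x
  expect_lt(max(Mod(Kpart(2.5 * mu) - 2.5 * Kpart(mu))), 1e-10)
  expect_gt(max(Mod(Kpart(1i * mu) - 1i * Kpart(mu))), 1e-6)
  expect_lt(max(Mod(Kpart(1i * mu) + 1i * Kpart(mu))), 1e-10)  # conjugation
})

test_that("operator at mu = 1 matches the true integral of the D-bar kernel", {
  ## r(s) = conv(1/k, T) evaluated by the independent polar oracle
  R <- 4
  sg <- build_sinc_grid(R, 16, 16)
  ops <- build_operators(sg)
  kg <- k_grid(sg$z_pts, R)
  a <- 0.5; s_in <- 1.5
  x <- 0.3 + 0.2i
  tfun <- function(k1, k2) {
    k <- k1 + 1i * k2
    v <- vapply(k, function(kk) if (Mod(kk) > R || kk == 0) 0 + 0i else
      t_analytic_inclusion(kk, a, s_in), complex(1))
    matrix(v, nrow = NROW(k1))
  }
  z <- sg$z_pts
  K <- outer(z, z, function(p, q) complex(real = p, imaginary = q))
  tv <- tfun(Re(K), Im(K))
  tR <- structure(list(values = tv, grid = kg, gamma_best = 1),
                  class = "eit_scattering")
  Fop <- eitdbar:::dbar_operator(x, tR, sg, ops)
  one <- matrix(1 + 0i, sg$m, sg$m)
  r_sinc <- pi * (one - Fop(one))        # (1/pi) r = 1 - F(1)
  Ufun <- function(k1, k2) {
    k <- k1 + 1i * k2
    tt <- tfun(k1, k2)
    ex <- exp(-2i * (Re(x) * k1 - Im(x) * k2))
    out <- tt * ex / (4 * pi * Conj(k))
    out[k == 0] <- 0
    out
  }
  for (ij in list(c(sg$i0, sg$i0), c(sg$i0 + 3, sg$i0 - 2))) {
    o <- cauchy_conv_polar(z[ij[1]], z[ij[2]], Ufun, R)
    expect_lt(Mod(r_sinc[ij[1], ij[2]] - o) / Mod(o), 0.05)
  }
})

test_that("GMRES solve equals the dense collocation solve (m <= 16)", {
  sg <- build_sinc_grid(4, 4, 4)         # m = 9
  ops <- build_operators(sg)
  kg <- k_grid(sg$z_pts, 4)
  m <- sg$m
  set.seed(13)
  tv <- matrix(complex(real = rnorm(m^2, sd = .5),
                       imaginary = rnorm(m^2, sd = .5)), m)
  tv[!kg$mask] <- 0; tv[kg$k == 0] <- 0
  tR <- structure(list(values = tv, grid = kg, gamma_best = 1),
                  class = "eit_scattering")
  x <- 0.4 - 0.2i
  n2 <- 2 * m^2
  ## dense real matrix of the operator, column by column
  A <- matrix(0, n2, n2)
  for (j in seq_len(n2)) {
    e <- numeric(n2); e[j] <- 1
    A[, j] <- dbar_apply(e, x, tR, sg, ops)
  }
  b <- eitdbar:::stack_mu(matrix(1 + 0i, m, m))
  dense <- solve(A, b)
  sol <- solve_dbar_at(x, tR, sg, ops, tol = 1e-12, maxit = 500L)
  expect_true(sol$converged)
  expect_lt(max(abs(eitdbar:::stack_mu(sol$mu) - dense)), 1e-6)
})

test_that("solve_dbar_at: trivial kernel, Born linearity, convergence flag", {
  sg <- build_sinc_grid(4, 4, 4)
  ops <- build_operators(sg)
  kg <- k_grid(sg$z_pts, 4)
  m <- sg$m
  tz <- structure(list(values = matrix(0 + 0i, m, m), grid = kg,
                       gamma_best = 1), class = "eit_scattering")
  s0 <- solve_dbar_at(0 + 0i, tz, sg, ops)
  expect_true(s0$converged)
  expect_lte(s0$iterations, 1L)
  expect_equal(s0$mu, matrix(1 + 0i, m, m))
  ## small-||t|| linearity: ||mu - 1|| scales with ||t|| within 5 %
  set.seed(17)
  tv <- matrix(complex(real = rnorm(m^2, sd = .2),
                       imaginary = rnorm(m^2, sd = .2)), m)
  tv[!kg$mask] <- 0; tv[kg$k == 0] <- 0
  mk <- function(sc) structure(list(values = sc * tv, grid = kg,
                                    gamma_best = 1),
                               class = "eit_scattering")
  d1 <- solve_dbar_at(0.1 + 0i, mk(1e-3), sg, ops, tol = 1e-10)$mu - 1
  d2 <- solve_dbar_at(0.1 + 0i, mk(2e-3), sg, ops, tol = 1e-10)$mu - 1
  expect_lt(max(Mod(d2 - 2 * d1)) / max(Mod(d2)), 0.05)
  ## non-convergence is flagged, not raised
  s_bad <- solve_dbar_at(0 + 0i, mk(1), sg, ops, tol = 1e-14, maxit = 2L)
  expect_false(s_bad$converged)
  expect_gt(s_bad$residual, 0)
  expect_error(solve_dbar_at(2 + 0i, tz, sg, ops), "disk")
})

test_that("reconstruction: homogeneous identity, symmetry, chirality", {
  sg <- build_sinc_grid(4, 8, 8)
  ops <- build_operators(sg)
  kg <- k_grid(sg$z_pts, 4)
  m <- sg$m
  xg <- image_grid(17L)
  tz <- structure(list(values = matrix(0 + 0i, m, m), grid = kg,
                       gamma_best = 424), class = "eit_scattering")
  flat <- reconstruct_image(tz, xg, sg, ops, gamma_best = 424)
  expect_true(all(abs(flat$gamma[xg$mask] - 424) < 1e-8))
  expect_true(all(is.na(flat$gamma[!xg$mask])))
  ## radially symmetric target -> radially symmetric image (90 deg turns)
  ds <- analytic_inclusion_dataset(16L, 0.5, 2)
  fit <- fit_reference(ds, NULL, reference = "analytic")
  tR <- scattering_transform(fit$dmap, kg, ds$layout)
  img <- reconstruct_image(tR, xg, sg, ops, gamma_best = fit$gamma_best)
  g <- img$gamma
  for (rot in 1:3) {
    gr <- t(apply(g, 2, rev))[, ]          # 90 degree rotation
    expect_lt(max(abs(g - gr), na.rm = TRUE) /
                diff(range(g, na.rm = TRUE)), 0.05)
    g <- gr
  }
  expect_lt(img$meta$max_rel_imag, 1e-2)   # real output for noiseless data
})

test_that("an off-axis target reconstructs at the true angle", {
  ## pins the e_{-k} phase convention (chirality)
  cfg <- rt_config(image_n = 32L, kgrid_n = 16L)
  ph <- make_rotating_target(4L)
  ph$inclusions[[1]]$center <- 0.45 * c(cos(pi / 3), sin(pi / 3))
  ds <- simulate_dataset(cfg, ph)
  img <- dbar_reconstruct(ds, cfg)
  q <- quarter_amplitude(img$gamma - img$meta$gamma_best, img$xgrid)
  ang <- atan2(q$cog[2], q$cog[1])
  expect_lt(abs(ang - pi / 3), 0.2)
  expect_gt(sqrt(sum(q$cog^2)), 0.25)
})
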