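## Shared oracles and lazily built fixtures.  Everything here is
## independent of the implementation paths it is used to check.

## Analytic Dirichlet-to-Neumann eigenvalues of the unit disk with a
## centered circular inclusion: radius a, conductivity s_in inside, s_out
## outside (separation of variables; eigenfunctions e^{i n theta}).
dn_eigen_inclusion <- function(n, a, s_in, s_out = 1) {
  mu <- (s_in - s_out) / (s_in + s_out)
  n * s_out * (1 + mu * a^(2 * n)) / (1 - mu * a^(2 * n))
}

## Closed-form Born scattering transform of the centered inclusion for a
## delta-DN map diagonal with eigenvalues d_n: t(k) = 2 pi sum_n
## a_n(conj k) a_n(k) d_n  (independent boundary-integral evaluation).
t_analytic_inclusion <- function(k, a, s_in, gamma_ratio = 1, nmax = 40) {
  s <- 0 + 0i
  for (n in seq_len(nmax)) {
    d_n <- gamma_ratio * dn_eigen_inclusion(n, a, s_in) - n
    s <- s + a_coeff(n, Conj(k)) * a_coeff(n, k) * d_n
  }
  2 * pi * s
}

## Synthetic "measured" voltages for the centered-inclusion disk, computed
## from the analytic DN map (no FEM): physical conductivity
## gamma = gscale * sigma with sigma the unit-background profile.
analytic_inclusion_dataset <- function(L, a, s_in, gscale = 1000, M = 1) {
  lay <- electrode_layout(L, r = 1)
  th <- lay$theta
  V <- sapply(seq_len(L - 1), function(j) {
    jj <- if (j <= L / 2) j else j - L / 2
    f <- if (j < L / 2) cos(jj * th)
         else if (j == L / 2) cos(pi * seq_len(L))
         else sin(jj * th)
    lay$r * M * f / (lay$A * gscale * dn_eigen_inclusion(jj, a, s_in))
  })
  patt <- trig_patterns(L, M)
  structure(list(V = V, T = patt$T, patterns = patt, layout = lay,
                 meta = list()), class = "eit_voltages")
}

## True 2D convolution of the Cauchy kernel 1/k against U over the box
## [-2R,2R]^2, by polar coordinates about the evaluation point (the
## substitution removes the singularity; plain midpoint quadrature).
cauchy_conv_polar <- function(s1, s2, Ufun, R, nphi = 240, nrho = 360) {
  rmax <- sqrt(2) * 4 * R
  phis <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
  rhos <- (seq_len(nrho) - 0.5) * rmax / nrho
  acc <- 0 + 0i
  for (p in phis) {
    k1 <- s1 - rhos * cos(p); k2 <- s2 - rhos * sin(p)
    acc <- acc + sum(Ufun(k1, k2)) * (rmax / nrho) * (2 * pi / nphi) *
      exp(-1i * p)
  }
  acc
}

## 1D quadrature oracle for the kernel transform G(u, v): polar reduction
## of the defining double integral (valid for Re(u), Re(v) > 0).
G_quadrature <- function(u, v) {
  f <- function(phi) exp(-1i * phi) / (cos(phi) / u + sin(phi) / v)
  re <- stats::integrate(function(p) Re(f(p)), 0, pi / 2,
                         rel.tol = 1e-12)$value
  im <- stats::integrate(function(p) Im(f(p)), 0, pi / 2,
                         rel.tol = 1e-12)$value
  complex(real = re, imaginary = im)
}

## Independent sine integral via adaptive quadrature.
Si_quadrature <- function(x) {
  vapply(x, function(xi) {
    if (xi == 0) return(0)
    stats::integrate(function(t) ifelse(t == 0, 1, sin(t) / t), 0, xi,
                     rel.tol = 1e-13, subdivisions = 400L)$value
  }, numeric(1))
}

## ---- lazily built shared fixtures (expensive FEM solves) ----------------
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

## small rotating-target configuration used across tests
rt_config <- function(...) {
  default_config(L = 16L, forward_elements = 6400L, image_n = 64L, ...)
}

fix_hom16 <- function() fixture("hom16", function() {
  simulate_dataset(rt_config(), phantom_spec(1000))
})

fix_refmesh16 <- function() fixture("refmesh16", function() {
  fm <- make_disk_mesh(1, 6400, sectors = 16L)
  make_disk_mesh(1, 6400, rotate = pi / (16 * fm$n_rings), sectors = 16L)
})

expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}
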