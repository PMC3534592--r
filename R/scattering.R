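## Truncated Born-approximate scattering transform t_R^exp evaluated on a
## k-plane grid from the delta-DN matrix.

#' Scattering series coefficient a_n(z)
#'
#' \eqn{a_n(z) = (iz)^n / n!} for \eqn{n \ge 0}, 0 for \eqn{n < 0}.
#' Evaluated in log space for stability at large n.
#'
#' @param n integer order (vectorized over \code{z}).
#' @param z complex point(s).
#' @return complex vector.
#' @export
a_coeff <- function(n, z) {
  if (n < 0) return(rep(0 + 0i, length(z)))
  if (n == 0) return(rep(1 + 0i, length(z)))
  iz <- 1i * z
  out <- rep(0 + 0i, length(z))
  nz <- which(iz != 0)
  if (length(nz)) {
    ## (iz)^n/n! = exp(n log(iz) - lgamma(n+1)); principal log, exact phase
    out[nz] <- exp(n * log(iz[nz]) - lgamma(n + 1))
  }
  out
}

#' k-plane evaluation grid
#'
#' Tensor grid of 1D points (typically sinc points, so the scattering
#' transform is sampled exactly where the D-bar solver collocates) with the
#' truncation mask \eqn{|k| \le R}.
#'
#' @param pts1d strictly increasing 1D points in \code{(-2R, 2R)}; must
#'   contain 0.
#' @param R truncation radius.
#' @return object of class \code{eit_kgrid} with complex matrix \code{k},
#'   logical \code{mask} and \code{R}.
#' @export
k_grid <- function(pts1d, R) {
  if (R <= 0) stopf("truncation radius must be positive")
  if (!any(pts1d == 0)) stopf("k-grid must contain 0")
  k <- outer(pts1d, pts1d, function(a, b) complex(real = a, imaginary = b))
  structure(list(k = k, pts1d = pts1d, mask = Mod(k) <= R, R = R),
            class = "eit_kgrid")
}

#' Approximate scattering transform from the delta-DN matrix
#'
#' Evaluates the truncated double series over the trigonometric-pattern
#' matrix elements of \eqn{\delta L} at every masked k-grid point:
#' \deqn{t(k) = c \, \pi \frac{r}{A^2} \sum_{m,n} w_m w_n a_m(\bar k) a_n(k)
#'   [\delta L_{m,n} + \delta L_{m+L/2,n+L/2}
#'    + i(\delta L_{m,n+L/2} - \delta L_{m+L/2,n})]}
#' with weights \eqn{w_{L/2} = \sqrt 2} on the half-order boundary terms
#' (the cos(L\eqn{\theta}/2) pattern carries norm \eqn{\sqrt L} instead of
#' \eqn{\sqrt{L/2}}), and zero outside \eqn{|k| > R}.  \code{calibration}
#' is an exposed multiplicative constant (default 1); the series is linear
#' in \eqn{\delta L}.
#'
#' @param dmap an \code{eit_deltadn} built from gamma_best-normalized data.
#' @param grid an \code{eit_kgrid}.
#' @param layout an \code{eit_layout} (supplies L, r, A).
#' @param calibration multiplicative calibration constant.
#' @return object of class \code{eit_scattering} with complex matrix
#'   \code{values}, the \code{grid} and \code{gamma_best}.
#' @export
scattering_transform <- function(dmap, grid, layout = dmap$layout_ref,
                                 calibration = 1) {
  dL <- dmap$dL
  L <- nrow(dL) + 1L
  if (is.null(layout)) stopf("layout required (none stored in dmap)")
  if (layout$L != L) stopf("dmap built for L=%d but layout has L=%d", L,
                           layout$L)
  half <- L %/% 2L
  kv <- grid$k[grid$mask]
  if (max(Mod(kv)) > 0) {
    ## overflow guard for the series terms (iz)^n/n!
    peak <- max(Mod(kv))^half / gamma(half + 1)
    if (!is.finite(peak) || peak > 1e12)
      stopf("truncation radius too large for L=%d electrodes; reduce R", L)
  }
  ## per-order coefficient vectors at all masked points
  Abar <- matrix(sapply(1:half, function(m) a_coeff(m, Conj(kv))),
                 nrow = length(kv))                         # a_m(conj k)
  Areg <- matrix(sapply(1:half, function(n) a_coeff(n, kv)),
                 nrow = length(kv))                         # a_n(k)
  w <- c(rep(1, half - 1L), sqrt(2))
  tv <- rep(0 + 0i, length(kv))
  for (m in 1:half) {
    for (n in 1:half) {
      br <- dL[m, n] +
        (if (m < half && n < half) dL[m + half, n + half] else 0) +
        1i * ((if (n < half) dL[m, n + half] else 0) -
              (if (m < half) dL[m + half, n] else 0))
      tv <- tv + w[m] * w[n] * Abar[, m] * Areg[, n] * br
    }
  }
  tv <- calibration * pi * layout$r / layout$A^2 * tv
  values <- matrix(0 + 0i, nrow(grid$k), ncol(grid$k))
  values[grid$mask] <- tv
  values[grid$k == 0] <- 0 + 0i   # convention: t(0) = 0
  structure(list(values = values, grid = grid, gamma_best = dmap$gamma_best,
                 calibration = calibration), class = "eit_scattering")
}

#' Conjugate-symmetrize a scattering transform
#'
#' A real conductivity implies \eqn{t(-k) = \overline{t(k)}}; measured
#' transforms violate this only through noise and discretization error.
#' Averaging \eqn{t(k)} with \eqn{\overline{t(-k)}} projects onto the
#' physical symmetry class and halves the noise variance.  Requires a grid
#' symmetric about the origin.
#'
#' @param t an \code{eit_scattering} on a symmetric grid.
#' @return an \code{eit_scattering}.
#' @export
symmetrize_scattering <- function(t) {
  p <- t$grid$pts1d
  if (max(abs(p + rev(p))) > 1e-9 * max(abs(p)))
    stopf("symmetrization requires a grid symmetric about 0")
  n <- nrow(t$values)
  out <- t
  out$values <- (t$values + Conj(t$values[n:1, n:1])) / 2
  out
}

#' Truncate a scattering transform to a smaller radius
#'
#' Zeroes values with \eqn{|k| > R_{new}} and updates the mask.
#'
#' @param t an \code{eit_scattering}.
#' @param R_new new truncation radius (0 < R_new, <= grid extent).
#' @return an \code{eit_scattering}.
#' @export
truncate_scattering <- function(t, R_new) {
  if (R_new <= 0) stopf("truncation radius must be positive")
  ext <- max(abs(Re(t$grid$k)), abs(Im(t$grid$k)))
  if (R_new > ext + 1e-12) stopf("R_new exceeds the grid extent")
  out <- t
  out$grid$R <- R_new
  out$grid$mask <- Mod(t$grid$k) <= R_new
  out$values[!out$grid$mask] <- 0 + 0i
  out
}

#' @export
print.eit_scattering <- function(x, ...) {
  cat(sprintf("<eit_scattering> %d x %d grid, R = %g, max|t| = %.4g\n",
              nrow(x$values), ncol(x$values), x$grid$R, max(Mod(x$values))))
  invisible(x)
}
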