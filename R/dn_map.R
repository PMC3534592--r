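## Discrete Neumann-to-Dirichlet / Dirichlet-to-Neumann maps, the delta-DN
## matrix, and the best homogeneous conductivity fit.

#' Discrete Neumann-to-Dirichlet map from normalized data
#'
#' Entries \eqn{R(m,n) = (t^m/A, v^n)_L} with the discrete inner product
#' \eqn{(u,w)_L = \sum_l \bar u(\theta_l) w(\theta_l)} (the conjugate is a
#' no-op for the real trigonometric patterns).
#'
#' @param t L x (L-1) matrix of normalized currents.
#' @param v L x (L-1) matrix of normalized voltages (columns sum to zero).
#' @param A electrode area (m^2).
#' @param layout optional \code{eit_layout} carried for provenance.
#' @return object of class \code{eit_ndmap} with field \code{R}.
#' @export
build_nd_map <- function(t, v, A, layout = NULL) {
  if (!all(dim(t) == dim(v))) stopf("shape mismatch between t and v")
  if (nrow(t) != ncol(t) + 1L) stopf("expected L rows and L-1 columns")
  if (max(abs(colSums(v))) > 1e-8 * max(abs(v), 1e-300))
    stopf("voltage columns must sum to zero (normalize first)")
  R <- crossprod(t, v) / A
  structure(list(R = R, A = A, layout_ref = layout), class = "eit_ndmap")
}

#' Homogeneous-disk Neumann-to-Dirichlet map (diagonal approximation)
#'
#' The diagonal matrix with entries \eqn{1/(Am)} for \eqn{m \le L/2} and
#' \eqn{1/(A(m-L/2))} for \eqn{m > L/2}; zeros elsewhere.  This is the
#' continuum approximation for unit conductivity in units where the domain
#' radius equals \code{A}; the pipeline's default homogeneous reference is a
#' FEM solve instead (see \code{\link{fit_reference}}).
#'
#' @param L electrode count (even).
#' @param A electrode area.
#' @return an \code{eit_ndmap}.
#' @export
homogeneous_nd <- function(L, A) {
  if (L %% 2 != 0) stopf("unsupported: L must be even")
  m <- seq_len(L - 1)
  d <- ifelse(m <= L / 2, 1 / m, 1 / (m - L / 2)) / A
  structure(list(R = diag(d, L - 1), A = A, layout_ref = NULL),
            class = "eit_ndmap")
}

#' Dirichlet-to-Neumann matrix from an ND map
#'
#' \eqn{L_{\gamma,r} = R_{\gamma,r}^{-1}}, with a conditioning guard: warn
#' above condition number 1e8, fail above 1e12.
#'
#' @param nd an \code{eit_ndmap} (or plain square matrix).
#' @return the (L-1) x (L-1) DN matrix.
#' @export
dn_from_nd <- function(nd) {
  R <- if (inherits(nd, "eit_ndmap")) nd$R else nd
  kap <- kappa(R, exact = FALSE)
  if (!is.finite(kap) || kap > 1e12)
    stopf("degenerate data: ND map condition number %.3g exceeds 1e12", kap)
  if (kap > 1e8)
    warning(sprintf("ND map poorly conditioned (kappa = %.3g)", kap),
            call. = FALSE)
  solve(R)
}

#' Difference of DN matrices
#'
#' \eqn{\delta L_{\gamma,r} = L_{\gamma,r} - L_{1,r}} (elementwise), packaged
#' with the fitted homogeneous conductivity.
#'
#' @param L_gamma DN matrix from measured data (gamma_best-normalized).
#' @param L_1 homogeneous reference DN matrix.
#' @param gamma_best best homogeneous conductivity (mS/m).
#' @param layout optional \code{eit_layout}.
#' @return object of class \code{eit_deltadn} with fields \code{dL},
#'   \code{gamma_best}, \code{layout_ref}.
#' @export
delta_dn <- function(L_gamma, L_1, gamma_best = 1, layout = NULL) {
  if (!all(dim(L_gamma) == dim(L_1))) stopf("shape mismatch")
  structure(list(dL = L_gamma - L_1, gamma_best = gamma_best,
                 layout_ref = layout), class = "eit_deltadn")
}

#' @export
print.eit_deltadn <- function(x, ...) {
  cat(sprintf("<eit_deltadn> %d x %d, gamma_best = %.4g mS/m, |dL|_F = %.4g\n",
              nrow(x$dL), ncol(x$dL), x$gamma_best, norm(x$dL, "F")))
  invisible(x)
}

#' Best homogeneous conductivity fit
#'
#' Least squares through the origin for \eqn{\rho V^{(1)} \approx U}:
#' \eqn{\rho_{best} = \sum V^{(1)} U / \sum (V^{(1)})^2}, and
#' \eqn{\gamma_{best} = 1/\rho_{best}}.
#'
#' @param U matrix of measured voltages.
#' @param V1 matrix of homogeneous reference voltages at unit conductivity.
#' @return list with \code{gamma_best}, \code{rho_best}.
#' @export
gamma_best <- function(U, V1) {
  if (!all(dim(U) == dim(V1))) stopf("shape mismatch")
  denom <- sum(V1^2)
  if (denom == 0) stopf("degenerate reference: sum(V1^2) = 0")
  rho <- sum(V1 * U) / denom
  list(gamma_best = 1 / rho, rho_best = rho)
}

#' Homogeneous reference and delta-DN construction
#'
#' Builds the full inverse-problem input from a measured dataset: fits
#' \eqn{\gamma_{best}}, solves the homogeneous reference with the same CEM
#' forward model on a *different* (inverse-side) mesh, normalizes the
#' measured voltages by \eqn{\gamma_{best}} and returns the
#' \code{eit_deltadn} difference map in normalized units.
#'
#' The reference is solved at conductivity \eqn{\gamma_{best}} (not at
#' 1 mS/m) so that the contact-impedance term of the CEM matches the data;
#' the resulting DN matrix is scaled to unit conductivity afterwards.  An
#' \code{analytic} mode replaces the FEM reference by the continuum diagonal
#' map (no contact impedance, for tests).
#'
#' @param dataset an \code{eit_voltages} (possibly noisy).
#' @param ref_mesh inverse-side \code{eit_mesh}; must not be the forward
#'   mesh (inverse-crime guard).
#' @param forward_mesh optional: the mesh that generated the data, only used
#'   to assert the meshes differ.
#' @param reference "fem" or "analytic".
#' @return list with \code{dmap} (an \code{eit_deltadn}), \code{gamma_best},
#'   \code{L_gamma}, \code{L_1}, \code{V1}.
#' @export
fit_reference <- function(dataset, ref_mesh, forward_mesh = NULL,
                          reference = c("fem", "analytic")) {
  reference <- match.arg(reference)
  layout <- dataset$layout
  if (!is.null(forward_mesh) &&
      nrow(forward_mesh$nodes) == nrow(ref_mesh$nodes) &&
      isTRUE(all.equal(forward_mesh$nodes, ref_mesh$nodes)))
    stopf("inverse crime: reference mesh must differ from the forward mesh")
  ## Measured data: the recorded currents are known exactly (an imperfect
  ## but self-aware current source), so the voltage responses to the
  ## *clean* normalized trigonometric patterns are recovered by least
  ## squares over the recorded pattern basis; the remaining noise
  ## sensitivity is second order.  With clean recorded currents this
  ## reduces exactly to the plain normalization.
  Trec <- if (!is.null(dataset$T)) dataset$T else dataset$patterns$T
  tcl <- trig_patterns(layout$L, M = 1)$T
  tcl <- sweep(tcl, 2L, sqrt(colSums(tcl^2)), "/")   # clean orthonormal t
  X <- qr.solve(Trec, tcl)
  Vresp <- dataset$V %*% X                   # responses to the clean t^j
  v_meas <- sweep(Vresp, 2L, colMeans(Vresp), "-")
  if (reference == "fem") {
    ## provisional reference at a nominal conductivity, then refit at
    ## gamma_best so the contact-impedance term matches the data
    hom <- function(g) solve_forward_cem(
      ref_mesh, phantom_spec(g), layout, dataset$patterns)
    g0 <- 1000
    V1 <- hom(g0)$V * g0          # voltages scaled to unit conductivity
    nrm1 <- sqrt(colSums(dataset$patterns$T^2))
    U_cl <- sweep(v_meas, 2L, nrm1, "*")   # back to full pattern amplitude
    gb <- gamma_best(U_cl, V1)$gamma_best
    ref <- hom(gb)
    V1 <- ref$V * gb
    gb <- gamma_best(U_cl, V1)$gamma_best
    nv1 <- normalize_patterns(dataset$patterns, ref$V)
    R1 <- build_nd_map(nv1$t, nv1$v * gb, layout$A, layout)
  } else {
    m <- seq_len(layout$L - 1)
    d <- ifelse(m <= layout$L / 2, 1 / m, 1 / (m - layout$L / 2)) *
      layout$r / layout$A^2      # continuum ND at unit conductivity
    R1 <- structure(list(R = diag(d, layout$L - 1), A = layout$A,
                         layout_ref = layout), class = "eit_ndmap")
    ## analytic reference voltages for the gamma_best fit
    th <- layout$theta
    V1 <- sapply(seq_len(layout$L - 1), function(j) {
      jj <- if (j <= layout$L / 2) j else j - layout$L / 2
      f <- if (j < layout$L / 2) cos(jj * th)
           else if (j == layout$L / 2) cos(pi * seq_len(layout$L))
           else sin(jj * th)
      layout$r * dataset$patterns$M * f / (jj * layout$A)
    })
    nrm1 <- sqrt(colSums(dataset$patterns$T^2))
    gb <- gamma_best(sweep(v_meas, 2L, nrm1, "*"), V1)$gamma_best
  }
  ## gamma_best-normalized measured data -> dimensionless conductivity ~ 1
  Rg <- build_nd_map(tcl, v_meas * gb, layout$A, layout)
  L_gamma <- dn_from_nd(Rg)
  L_1 <- dn_from_nd(R1)
  dmap <- delta_dn(L_gamma, L_1, gamma_best = gb, layout = layout)
  list(dmap = dmap, gamma_best = gb, L_gamma = L_gamma, L_1 = L_1, V1 = V1)
}
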