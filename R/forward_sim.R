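## Synthetic EIT measurement generation: structured disk meshes, electrode
## layouts, trigonometric current patterns, complete electrode model (CEM)
## finite element solves, and measurement noise.

#' Structured triangulation of a disk
#'
#' Builds a conforming triangular mesh of the disk of the given radius from
#' concentric rings (ring j carries \code{sectors}*j nodes), the classic
#' hexagonal-sector construction generalized to an arbitrary sector count.
#' Matching \code{sectors} to the electrode count makes the discretization
#' error commute with the electrode rotation symmetry, which is what lets
#' the delta-DN construction cancel it against a same-resolution reference
#' mesh.  All boundary nodes lie exactly on the circle.  The number
#' of rings is chosen so the element count is as close as possible to
#' \code{target_elements} (always within 30\%).
#'
#' @param radius disk radius (length units of the domain).
#' @param target_elements desired number of triangles (>= 100).
#' @param rotate rigid rotation angle (radians) applied to all nodes; used
#'   to build an inverse-side mesh that differs from the forward mesh while
#'   matching its resolution (so the O(h^2) discretization bias largely
#'   cancels in the delta-DN map).
#' @param sectors angular sector count (ring j carries sectors*j nodes).
#' @return an object of class \code{eit_mesh} with \code{nodes} (n x 2),
#'   \code{elements} (e x 3, counter-clockwise), \code{boundary_edges}
#'   (ordered closed loop, b x 2) and \code{boundary_nodes}.
#' @export
make_disk_mesh <- function(radius, target_elements, rotate = 0,
                           sectors = 6L) {
  if (!is.numeric(radius) || radius <= 0) stopf("radius must be positive")
  if (target_elements < 100) stopf("target_elements must be >= 100")
  S <- as.integer(sectors)
  if (S < 3L) stopf("sectors must be >= 3")
  n_r <- max(4L, as.integer(round(sqrt(target_elements / S))))
  nodes <- matrix(0, nrow = 1 + S * n_r * (n_r + 1) / 2, ncol = 2)
  ring_start <- integer(n_r + 1L)  # 1-based index of first node of ring j
  ring_start[1L] <- 1L             # ring 0 = center node
  idx <- 2L
  for (j in seq_len(n_r)) {
    ring_start[j + 1L] <- idx
    ang <- 2 * pi * (0:(S * j - 1)) / (S * j) + rotate
    rr <- radius * j / n_r
    nodes[idx:(idx + S * j - 1), ] <- cbind(rr * cos(ang), rr * sin(ang))
    idx <- idx + S * j
  }
  ring_index <- function(j, t) {      # node id of ring j, position t (mod Sj)
    if (j == 0L) return(1L)
    ring_start[j + 1L] + (t %% (S * j))
  }
  elems <- vector("list", n_r)
  for (j in seq_len(n_r)) {
    tri <- matrix(0L, nrow = S * (2L * j - 1L), ncol = 3L)
    row <- 1L
    for (s in 0:(S - 1L)) {
      for (t in 0:(j - 1L)) {  # "up" triangles: two outer nodes, one inner
        o1 <- ring_index(j, j * s + t)
        o2 <- ring_index(j, j * s + t + 1L)
        i1 <- ring_index(j - 1L, (j - 1L) * s + t)
        tri[row, ] <- c(o1, o2, i1); row <- row + 1L
      }
      if (j >= 2L) {
        for (t in 0:(j - 2L)) {  # "down" triangles: two inner, one outer
          i1 <- ring_index(j - 1L, (j - 1L) * s + t)
          i2 <- ring_index(j - 1L, (j - 1L) * s + t + 1L)
          o2 <- ring_index(j, j * s + t + 1L)
          tri[row, ] <- c(i1, o2, i2); row <- row + 1L
        }
      }
    }
    elems[[j]] <- tri
  }
  elements <- do.call(rbind, elems)
  ## enforce counter-clockwise orientation (positive signed area)
  a <- signed_areas(nodes, elements)
  flip <- a < 0
  if (any(flip)) {
    tmp <- elements[flip, 2L]
    elements[flip, 2L] <- elements[flip, 3L]
    elements[flip, 3L] <- tmp
  }
  nb <- S * n_r
  bnd <- ring_start[n_r + 1L] + 0:(nb - 1L)
  boundary_edges <- cbind(bnd, c(bnd[-1L], bnd[1L]))
  structure(list(nodes = nodes, elements = elements,
                 boundary_edges = boundary_edges, boundary_nodes = bnd,
                 radius = radius, n_rings = n_r, sectors = S,
                 rotate = rotate),
            class = "eit_mesh")
}

signed_areas <- function(nodes, elements) {
  p1 <- nodes[elements[, 1L], , drop = FALSE]
  p2 <- nodes[elements[, 2L], , drop = FALSE]
  p3 <- nodes[elements[, 3L], , drop = FALSE]
  0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
         (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
}

#' @export
print.eit_mesh <- function(x, ...) {
  cat(sprintf("<eit_mesh> radius %g: %d nodes, %d elements, %d boundary nodes\n",
              x$radius, nrow(x$nodes), nrow(x$elements),
              length(x$boundary_nodes)))
  invisible(x)
}

#' Electrode layout on a circular boundary
#'
#' \code{L} electrodes counter-clockwise with the first at 3 o'clock,
#' centers \eqn{\theta_l = 2\pi l / L}, l = 1..L.
#'
#' @param L electrode count (even, >= 4).
#' @param r domain radius (m).
#' @param width electrode arc width (m); default covers half the
#'   inter-electrode spacing.
#' @param A electrode area used to convert currents to current densities in
#'   the ND-map normalization (m^2); default the per-electrode boundary strip
#'   \eqn{(2\pi r/L) \times 1} of unit height, never inferred silently
#'   elsewhere.
#' @param z_contact contact impedance (Ohm m^2), uniform.
#' @return object of class \code{eit_layout}.
#' @export
electrode_layout <- function(L, r = 1, width = NULL, A = NULL,
                             z_contact = 0.01) {
  if (L %% 2 != 0 || L < 4) stopf("L must be even and >= 4")
  if (r <= 0) stopf("radius must be positive")
  if (is.null(width)) width <- 0.5 * 2 * pi * r / L
  if (is.null(A)) A <- (2 * pi * r / L) * 1
  if (width * L >= 2 * pi * r) stopf("electrodes overlap: width*L >= 2*pi*r")
  theta <- 2 * pi * seq_len(L) / L
  structure(list(L = as.integer(L), theta = theta, r = r, A = A,
                 width = width, z_contact = rep(z_contact, L)),
            class = "eit_layout")
}

#' @export
print.eit_layout <- function(x, ...) {
  cat(sprintf("<eit_layout> L=%d, r=%g m, width=%g m, A=%g m^2, z=%g Ohm m^2\n",
              x$L, x$r, x$width, x$A, x$z_contact[1]))
  invisible(x)
}

#' Trigonometric current patterns
#'
#' The L-1 trigonometric patterns of amplitude \code{M}: column j is
#' \eqn{M\cos(j\theta_l)} for j < L/2, \eqn{M\cos(\pi l)} for j = L/2 and
#' \eqn{M\sin((j-L/2)\theta_l)} for j > L/2, with \eqn{\theta_l = 2\pi l/L}.
#' Columns conserve current (sum to zero) and are mutually orthogonal.
#'
#' @param L electrode count (even, >= 4).
#' @param M current amplitude (mA).
#' @return object of class \code{eit_patterns} with fields \code{T}
#'   (L x (L-1)), \code{M}, \code{L}, \code{normalized}.
#' @export
trig_patterns <- function(L, M = 1) {
  if (L %% 2 != 0 || L < 4) stopf("unsupported configuration: L must be even")
  if (M <= 0) stopf("amplitude M must be positive")
  theta <- 2 * pi * seq_len(L) / L
  Tm <- matrix(0, L, L - 1)
  for (j in seq_len(L - 1)) {
    Tm[, j] <- if (j < L / 2) M * cos(j * theta)
               else if (j == L / 2) M * cos(pi * seq_len(L))
               else M * sin((j - L / 2) * theta)
  }
  structure(list(T = Tm, M = M, L = as.integer(L), normalized = FALSE),
            class = "eit_patterns")
}

#' Normalize current patterns and voltages
#'
#' \eqn{t^j = T^j/\|T^j\|} (Euclidean norm over electrodes) and
#' \eqn{v^j = (V^j - \bar V^j)/\|T^j\|}; every normalized voltage column
#' sums to zero.
#'
#' @param patterns an \code{eit_patterns} object (or plain L x (L-1) matrix).
#' @param V matrix of measured voltages, same shape as the currents.
#' @return list with matrices \code{t} and \code{v} and the norms used.
#' @export
normalize_patterns <- function(patterns, V) {
  Tm <- if (inherits(patterns, "eit_patterns")) patterns$T else patterns
  if (!all(dim(Tm) == dim(V))) stopf("current/voltage shape mismatch")
  nrm <- sqrt(colSums(Tm^2))
  if (any(nrm < 1e-300)) stopf("degenerate pattern: zero-norm current column")
  v <- sweep(V, 2L, colMeans(V), "-")
  list(t = sweep(Tm, 2L, nrm, "/"), v = sweep(v, 2L, nrm, "/"), norms = nrm)
}

## ---- phantoms ------------------------------------------------------------

#' Phantom specification
#'
#' @param background_sigma background conductivity (mS/m).
#' @param inclusions list of inclusions; each a list with \code{shape}
#'   ("circle" or "ellipse"), \code{center} (relative to unit disk),
#'   \code{radius} (circle) or \code{semi_axes} + \code{angle} (ellipse),
#'   and \code{sigma} (mS/m).  A \code{fun} inclusion carries a function
#'   \code{sigma_fun(x1, x2)} for smooth phantoms.
#' @return object of class \code{eit_phantom}.
#' @export
phantom_spec <- function(background_sigma, inclusions = list()) {
  if (background_sigma <= 0) stopf("conductivities must be positive")
  for (inc in inclusions) {
    if (!identical(inc$shape, "fun") && !is.null(inc$sigma) &&
        inc$sigma <= 0)
      stopf("conductivities must be positive")
  }
  structure(list(background_sigma = background_sigma,
                 inclusions = inclusions), class = "eit_phantom")
}

#' Chest phantom (two elliptical lungs, one circular heart)
#'
#' Conductivities are 1000/1500/500 mS/m (background/heart/lungs) for the
#' simulated variant and 424/750/240 mS/m for the experimental-tank variant.
#' The geometry (never printed for the reference experiments) is a fixed
#' visually plausible configuration on the unit disk and can be overridden
#' downstream through the config file.
#'
#' @param variant "simulated" or "experimental".
#' @return an \code{eit_phantom}.
#' @export
make_chest_phantom <- function(variant = c("simulated", "experimental")) {
  variant <- match.arg(variant)
  cond <- if (variant == "simulated") c(bg = 1000, heart = 1500, lung = 500)
          else c(bg = 424, heart = 750, lung = 240)
  inclusions <- list(
    list(shape = "ellipse", center = c(-0.45, -0.15),
         semi_axes = c(0.24, 0.42), angle = -20 * pi / 180,
         sigma = unname(cond["lung"]), label = "lung_right"),
    list(shape = "ellipse", center = c(0.45, -0.15),
         semi_axes = c(0.24, 0.42), angle = 20 * pi / 180,
         sigma = unname(cond["lung"]), label = "lung_left"),
    list(shape = "circle", center = c(0.07, 0.42), radius = 0.2,
         sigma = unname(cond["heart"]), label = "heart"))
  phantom_spec(unname(cond["bg"]), inclusions)
}

#' Rotating circular target phantom
#'
#' One circular target of diameter 0.05 of the tank diameter with
#' conductivity twice the homogeneous background, at one of nine radial
#' displacements along \eqn{\theta = 0}: index 0 is the medium center, index
#' 8 the outermost position with boundary clearance at least one target
#' radius.
#'
#' @param position_index integer 0..8.
#' @param layout an \code{eit_layout} (sets the relative geometry; the
#'   phantom is expressed on the unit disk).
#' @param background_sigma background conductivity (mS/m).
#' @return an \code{eit_phantom}.
#' @export
make_rotating_target <- function(position_index, layout = NULL,
                                 background_sigma = 1000) {
  if (length(position_index) != 1 || position_index < 0 || position_index > 8)
    stopf("position_index must be in 0..8")
  rho <- 0.05          # target radius on the unit disk (0.05 of the diameter)
  c_max <- 0.9         # outermost center: clearance 0.075 >= rho
  cx <- c_max * position_index / 8
  phantom_spec(background_sigma, list(
    list(shape = "circle", center = c(cx, 0), radius = rho,
         sigma = 2 * background_sigma, label = "target")))
}

## TRUE where the points (x, y) (unit-disk coordinates) lie inside inclusion
point_in_inclusion <- function(inc, x, y) {
  dx <- x - inc$center[1]; dy <- y - inc$center[2]
  if (inc$shape == "circle") {
    dx^2 + dy^2 <= inc$radius^2
  } else if (inc$shape == "ellipse") {
    ca <- cos(inc$angle); sa <- sin(inc$angle)
    u <- ca * dx + sa * dy; v <- -sa * dx + ca * dy
    (u / inc$semi_axes[1])^2 + (v / inc$semi_axes[2])^2 <= 1
  } else stopf("unknown inclusion shape '%s'", inc$shape)
}

#' Sample a phantom on points of the unit disk
#'
#' @param phantom an \code{eit_phantom}.
#' @param x,y coordinates scaled to the unit disk.
#' @return conductivity values (mS/m).
#' @export
phantom_sigma <- function(phantom, x, y) {
  sig <- rep(phantom$background_sigma, length(x))
  for (inc in phantom$inclusions) {
    if (identical(inc$shape, "fun")) {
      sig <- inc$sigma_fun(x, y)
    } else {
      inside <- point_in_inclusion(inc, x, y)
      sig[inside] <- inc$sigma
    }
  }
  sig
}

## ---- complete electrode model forward solver ------------------------------

## Exact integrals of the P1 basis over the part of each boundary edge
## covered by each electrode.  Returns triplet lists for the three CEM
## boundary blocks.  Arc-length parametrization along the circular boundary.
cem_boundary_blocks <- function(mesh, layout) {
  nb <- mesh$boundary_nodes
  ang <- atan2(mesh$nodes[nb, 2], mesh$nodes[nb, 1]) %% (2 * pi)
  edges <- mesh$boundary_edges
  e_ang1 <- atan2(mesh$nodes[edges[, 1], 2], mesh$nodes[edges[, 1], 1]) %% (2 * pi)
  e_ang2 <- e_ang1 + 2 * pi / length(nb)   # uniform boundary spacing
  r <- layout$r
  half <- layout$width / (2 * r)           # angular half width
  ii <- jj <- ll <- integer(0)
  kk_mass <- numeric(0)                    # phi_i phi_j entries (4 per piece)
  ci <- numeric(0); cl <- integer(0); cn <- integer(0)
  dl <- numeric(0); dL_idx <- integer(0)
  Kmi <- Kmj <- integer(0); Kmx <- numeric(0)
  for (l in seq_len(layout$L)) {
    a0 <- layout$theta[l] - half; b0 <- layout$theta[l] + half
    for (shift in c(-2 * pi, 0, 2 * pi)) {  # handle wrap-around
      a <- a0 + shift; b <- b0 + shift
      ov_lo <- pmax(a, e_ang1); ov_hi <- pmin(b, e_ang2)
      hit <- which(ov_hi > ov_lo + 1e-14)
      for (e in hit) {
        n1 <- edges[e, 1]; n2 <- edges[e, 2]
        dphi <- e_ang2[e] - e_ang1[e]
        ta <- (ov_lo[e] - e_ang1[e]) / dphi
        tb <- (ov_hi[e] - e_ang1[e]) / dphi
        len <- r * dphi                    # full edge arc length
        ## \int phi_a phi_b ds over t in [ta,tb], phi_1 = 1-t, phi_2 = t
        I11 <- len * ((tb - ta) - (tb^2 - ta^2) + (tb^3 - ta^3) / 3)
        I12 <- len * ((tb^2 - ta^2) / 2 - (tb^3 - ta^3) / 3)
        I22 <- len * (tb^3 - ta^3) / 3
        J1 <- len * ((tb - ta) - (tb^2 - ta^2) / 2)
        J2 <- len * (tb^2 - ta^2) / 2
        Kmi <- c(Kmi, n1, n1, n2, n2); Kmj <- c(Kmj, n1, n2, n1, n2)
        Kmx <- c(Kmx, I11, I12, I12, I22)
        ci <- c(ci, J1, J2); cn <- c(cn, n1, n2); cl <- c(cl, l, l)
        dl <- c(dl, len * (tb - ta)); dL_idx <- c(dL_idx, l)
      }
    }
  }
  list(Kmi = Kmi, Kmj = Kmj, Kmx = Kmx, cn = cn, cl = cl, ci = ci,
       dL_idx = dL_idx, dl = dl)
}

#' Complete electrode model forward solve
#'
#' Solves the generalized Laplace equation \eqn{\nabla\cdot(\gamma\nabla u)=0}
#' with the complete electrode model for every current pattern, by P1 finite
#' elements.  Conductivity is piecewise constant per element, sampled from
#' the phantom at the element centroid (after scaling to the unit disk).
#' Units: conductivity mS/m, currents mA, voltages V, contact impedance
#' Ohm m^2 (unit electrode height).
#'
#' @param mesh an \code{eit_mesh} covering the disk of the layout radius.
#' @param phantom an \code{eit_phantom} (unit-disk coordinates).
#' @param layout an \code{eit_layout}.
#' @param patterns an \code{eit_patterns}.
#' @return object of class \code{eit_voltages}: fields \code{V} (L x (L-1),
#'   mean-shifted to sum to zero), \code{T} applied currents, \code{layout},
#'   \code{patterns}, and solver metadata.
#' @export
solve_forward_cem <- function(mesh, phantom, layout, patterns) {
  if (abs(mesh$radius - layout$r) > 1e-9 * layout$r)
    stopf("mesh radius (%g) does not match layout radius (%g)",
          mesh$radius, layout$r)
  Tm <- if (inherits(patterns, "eit_patterns")) patterns$T else patterns
  if (nrow(Tm) != layout$L) stopf("pattern rows != electrode count")
  if (max(abs(colSums(Tm))) > 1e-9 * max(abs(Tm)))
    stopf("current patterns do not conserve current")
  nn <- nrow(mesh$nodes); L <- layout$L
  ## element conductivities at centroids (unit-disk coordinates)
  cx <- (mesh$nodes[mesh$elements[, 1], 1] + mesh$nodes[mesh$elements[, 2], 1] +
         mesh$nodes[mesh$elements[, 3], 1]) / 3 / layout$r
  cy <- (mesh$nodes[mesh$elements[, 1], 2] + mesh$nodes[mesh$elements[, 2], 2] +
         mesh$nodes[mesh$elements[, 3], 2]) / 3 / layout$r
  sig <- phantom_sigma(phantom, cx, cy)
  if (any(!is.finite(sig)) || any(sig <= 0))
    stopf("solver error: non-positive conductivity in phantom sample")
  ## P1 stiffness, vectorized
  el <- mesh$elements
  x1 <- mesh$nodes[el[, 1], 1]; y1 <- mesh$nodes[el[, 1], 2]
  x2 <- mesh$nodes[el[, 2], 1]; y2 <- mesh$nodes[el[, 2], 2]
  x3 <- mesh$nodes[el[, 3], 1]; y3 <- mesh$nodes[el[, 3], 2]
  area <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  b1 <- (y2 - y3) / (2 * area); b2 <- (y3 - y1) / (2 * area)
  b3 <- (y1 - y2) / (2 * area)
  c1 <- (x3 - x2) / (2 * area); c2 <- (x1 - x3) / (2 * area)
  c3 <- (x2 - x1) / (2 * area)
  bs <- cbind(b1, b2, b3); cs <- cbind(c1, c2, c3)
  ne <- nrow(el)
  ii <- jj <- integer(9 * ne); xx <- numeric(9 * ne)
  pos <- 1L
  for (a in 1:3) for (b in 1:3) {
    idx <- pos:(pos + ne - 1L)
    ii[idx] <- el[, a]; jj[idx] <- el[, b]
    xx[idx] <- sig * area * (bs[, a] * bs[, b] + cs[, a] * cs[, b])
    pos <- pos + ne
  }
  ## CEM boundary terms; 1/z in mS/m^2 (z in Ohm m^2, unit height)
  bb <- cem_boundary_blocks(mesh, layout)
  zinv <- 1000 / layout$z_contact  # per-electrode, mS units
  Kb <- zinv[1] * bb$Kmx           # uniform z (per-electrode uniform here)
  K <- Matrix::sparseMatrix(i = c(ii, bb$Kmi), j = c(jj, bb$Kmj),
                            x = c(xx, Kb), dims = c(nn, nn))
  Cm <- Matrix::sparseMatrix(i = bb$cn, j = bb$cl, x = -zinv[bb$cl] * bb$ci,
                             dims = c(nn, L))
  Dd <- numeric(L)
  for (k in seq_along(bb$dL_idx))
    Dd[bb$dL_idx[k]] <- Dd[bb$dL_idx[k]] + zinv[bb$dL_idx[k]] * bb$dl[k]
  if (any(Dd <= 0)) stopf("solver error: electrode %d not attached to mesh",
                          which(Dd <= 0)[1])
  ## assemble [[K, C, 0], [C', D, 1], [0, 1', 0]] with sum(U)=0 grounding
  Dm <- Matrix::sparseMatrix(i = seq_len(L), j = seq_len(L), x = Dd)
  one <- Matrix::Matrix(1, L, 1, sparse = TRUE)
  zero_n <- Matrix::Matrix(0, nn, 1, sparse = TRUE)
  A <- rbind(cbind(K, Cm, zero_n),
             cbind(Matrix::t(Cm), Dm, one),
             cbind(Matrix::t(zero_n), Matrix::t(one),
                   Matrix::Matrix(0, 1, 1, sparse = TRUE)))
  rhs <- rbind(matrix(0, nn, ncol(Tm)), Tm, matrix(0, 1, ncol(Tm)))
  sol <- tryCatch(Matrix::solve(A, rhs),
                  error = function(e) stopf("solver error: %s", conditionMessage(e)))
  U <- as.matrix(sol[nn + seq_len(L), , drop = FALSE])
  U <- sweep(U, 2L, colMeans(U), "-")
  structure(list(V = U, T = Tm, patterns = patterns, layout = layout,
                 noise_seed = NULL,
                 meta = list(mesh_elements = nrow(mesh$elements),
                             mesh_nodes = nn, phantom = phantom)),
            class = "eit_voltages")
}

#' @export
print.eit_voltages <- function(x, ...) {
  cat(sprintf("<eit_voltages> %d electrodes x %d patterns%s\n",
              nrow(x$V), ncol(x$V),
              if (!is.null(x$noise_seed)) sprintf(" (noise seed %d)",
                                                  x$noise_seed) else ""))
  invisible(x)
}

#' Add uniform noise to a dataset
#'
#' Adds i.i.d. uniform noise on \code{[-amplitude, +amplitude]} to the
#' injected currents (default; the noise amplitude of the reference
#' protocol is quoted in mA) or to the measured voltages.  Reproducible
#' under a fixed seed; the caller's RNG state is untouched.
#'
#' Current-side noise models an imperfect current source: the perturbed
#' patterns are mean-centered per pattern (charge conservation), recorded
#' as the dataset's currents, and -- when the dataset carries its forward
#' model (any dataset from \code{\link{simulate_dataset}}) -- the voltages
#' are re-solved so they correspond to the currents actually injected.
#' Voltage-side noise is plain additive measurement noise.
#'
#' @param dataset an \code{eit_voltages}.
#' @param amplitude noise amplitude, same units as the target quantity.
#' @param seed integer seed.
#' @param target "currents" or "voltages".
#' @return a new \code{eit_voltages}.
#' @export
add_noise <- function(dataset, amplitude, seed = 1L,
                      target = c("currents", "voltages")) {
  target <- match.arg(target)
  if (amplitude < 0) stopf("noise amplitude must be >= 0")
  if (amplitude == 0) return(dataset)
  out <- dataset
  if (target == "currents") {
    eps <- with_seed(seed, matrix(runif(length(dataset$T), -amplitude,
                                        amplitude), nrow(dataset$T)))
    eps <- sweep(eps, 2L, colMeans(eps))   # keep columns current-conserving
    out$T <- dataset$T + eps
    if (!is.null(dataset$meta$forward_mesh) &&
        !is.null(dataset$meta$phantom)) {
      resolved <- solve_forward_cem(dataset$meta$forward_mesh,
                                    dataset$meta$phantom, dataset$layout,
                                    out$T)
      out$V <- resolved$V
    }
  } else {
    eps <- with_seed(seed, matrix(runif(length(dataset$V), -amplitude,
                                        amplitude), nrow(dataset$V)))
    out$V <- dataset$V + eps
  }
  out$noise_seed <- as.integer(seed)
  out$noise_amplitude <- amplitude
  out$noise_target <- target
  out
}
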