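## High-level pipeline: configuration defaults, simulation, and the full
## D-bar reconstruction chain (normalize -> delta-DN -> scattering ->
## sinc-convolution solve -> conductivity image).

#' Default run configuration
#'
#' All tunable parameters of the pipeline with the reference experimental
#' defaults: 32 electrodes, 1 mA trigonometric patterns, unit-radius
#' dimensionless tank (set \code{r = 0.15} for the physical saline tank),
#' truncation radius 4, k-grid level 16 (17 x 17 sinc points), 64 x 64
#' image.
#'
#' @param ... overrides, e.g. \code{default_config(L = 16, kgrid_n = 32)}.
#' @return a named list of class \code{eit_config}.
#' @export
default_config <- function(...) {
  cfg <- list(
    L = 32L,             # electrode count
    r = 1,               # domain radius (m); 0.15 for the saline tank
    M = 1,               # current amplitude (mA)
    A = NULL,            # electrode area (m^2); NULL = (2 pi r / L) * 1
    width = NULL,        # electrode arc width (m); NULL = half spacing
    z_contact = 0.01,    # contact impedance (Ohm m^2)
    forward_elements = 6400L,   # forward FEM element target
    ref_elements = NULL, # inverse-side reference mesh; NULL = 0.9 * forward
    reference = "fem",   # homogeneous reference: "fem" or "analytic"
    R_trunc = 4,         # scattering truncation radius (noiseless cap)
    R_noise_rule = TRUE, # shrink R with declared noise: 2.3*(-ln delta)^(1/3)
    kgrid_n = 16L,       # k-plane discretization level (m = n + 1 points)
    h = NULL,            # sinc step; NULL = pi / sqrt(m / 2)
    tol = 1e-5,          # GMRES relative tolerance
    maxit = 200L,        # GMRES iteration cap
    image_n = 64L,       # image pixels per side
    calibration = 1,     # scattering-series calibration constant
    symmetrize = TRUE,   # enforce t(-k) = conj(t(k)) (real conductivity)
    noise_amplitude = 0, # uniform noise amplitude (mA by default target)
    noise_target = "currents",
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  for (k in c("L", "r", "M", "z_contact", "forward_elements", "R_trunc",
              "kgrid_n", "tol", "maxit", "image_n"))
    if (cfg[[k]] <= 0) stopf("config value '%s' must be positive", k)
  structure(cfg, class = "eit_config")
}

config_layout <- function(cfg) {
  electrode_layout(cfg$L, r = cfg$r, width = cfg$width, A = cfg$A,
                   z_contact = cfg$z_contact)
}

#' Simulate a measurement dataset for a phantom
#'
#' Builds the forward mesh and layout from the config, solves the CEM
#' forward problem for all trigonometric patterns, and applies the
#' configured measurement noise.
#'
#' @param cfg an \code{\link{default_config}} list.
#' @param phantom an \code{eit_phantom}.
#' @return an \code{eit_voltages} (with the forward mesh attached in
#'   \code{meta} for inverse-crime checks).
#' @export
simulate_dataset <- function(cfg, phantom) {
  layout <- config_layout(cfg)
  mesh <- make_disk_mesh(cfg$r, cfg$forward_elements, sectors = cfg$L)
  patt <- trig_patterns(cfg$L, cfg$M)
  ds <- solve_forward_cem(mesh, phantom, layout, patt)
  ds$meta$forward_mesh <- mesh
  if (cfg$noise_amplitude > 0)
    ds <- add_noise(ds, cfg$noise_amplitude, seed = cfg$seed,
                    target = cfg$noise_target)
  ds
}

#' Full D-bar reconstruction of a dataset
#'
#' Chains the inverse pipeline: homogeneous reference fit and delta-DN
#' construction, truncated scattering transform on the sinc tensor grid,
#' and the per-pixel sinc-convolution D-bar solve.
#'
#' @param dataset an \code{eit_voltages}.
#' @param cfg a config list.
#' @return an \code{eit_image}; the fitted \code{gamma_best}, the
#'   scattering transform and the delta-DN map ride along in \code{meta}.
#' @export
dbar_reconstruct <- function(dataset, cfg = default_config()) {
  if (nrow(dataset$V) != cfg$L)
    stopf("dataset has %d electrodes but config L = %d", nrow(dataset$V),
          cfg$L)
  patt <- dataset$patterns
  if (!is_trig_protocol(dataset))
    stopf(paste("unsupported protocol: the D-bar chain requires",
                "trigonometric current patterns"))
  ## inverse-side reference mesh: same resolution class as the forward mesh
  ## but rotated by half a boundary-node spacing -- a different mesh (no
  ## inverse crime) whose discretization bias nearly cancels in delta-L
  ref_target <- if (is.null(cfg$ref_elements)) cfg$forward_elements
                else cfg$ref_elements
  tmp <- make_disk_mesh(cfg$r, ref_target, sectors = cfg$L)
  ref_mesh <- make_disk_mesh(cfg$r, ref_target,
                             rotate = pi / (cfg$L * tmp$n_rings),
                             sectors = cfg$L)
  fit <- fit_reference(dataset, ref_mesh,
                       forward_mesh = dataset$meta$forward_mesh,
                       reference = cfg$reference)
  ## truncation radius is the regularization dial of the D-bar method: with
  ## declared measurement noise of relative size delta it shrinks like
  ## (-ln delta)^(1/3) (capped by the configured noiseless radius)
  R_use <- cfg$R_trunc
  if (isTRUE(cfg$R_noise_rule) && !is.null(dataset$noise_amplitude) &&
      dataset$noise_amplitude > 0) {
    delta <- dataset$noise_amplitude / dataset$patterns$M
    R_use <- min(R_use, 2.3 * (-log(delta))^(1 / 3))
  }
  sg <- build_sinc_grid(R_use, cfg$kgrid_n %/% 2L, cfg$kgrid_n %/% 2L,
                        h = cfg$h)
  kg <- k_grid(sg$z_pts, R_use)
  tR <- scattering_transform(fit$dmap, kg, dataset$layout,
                             calibration = cfg$calibration)
  if (isTRUE(cfg$symmetrize)) tR <- symmetrize_scattering(tR)
  ops <- build_operators(sg)
  xg <- image_grid(cfg$image_n)
  img <- reconstruct_image(tR, xg, sg, ops, gamma_best = fit$gamma_best,
                           tol = cfg$tol, maxit = cfg$maxit)
  img$meta$gamma_best <- fit$gamma_best
  img$meta$scattering <- tR
  img$meta$dmap <- fit$dmap
  img$meta$config <- cfg
  img
}

## TRUE when the dataset's current patterns are (close to) the L-1
## mutually orthogonal trigonometric patterns.
is_trig_protocol <- function(dataset) {
  Tm <- if (inherits(dataset$patterns, "eit_patterns")) dataset$patterns$T
        else dataset$patterns
  L <- nrow(Tm)
  if (ncol(Tm) != L - 1) return(FALSE)
  ref <- trig_patterns(L, M = 1)$T
  ## compare up to a positive per-dataset amplitude
  sc <- sqrt(sum(Tm^2) / sum(ref^2))
  max(abs(Tm - sc * ref)) < 0.25 * sc   # tolerant to additive noise
}

#' Rasterize a phantom on an image grid
#'
#' @param phantom an \code{eit_phantom}.
#' @param xgrid an \code{\link{image_grid}}.
#' @return matrix of true conductivity (mS/m), NA outside the disk.
#' @export
phantom_image <- function(phantom, xgrid) {
  g <- matrix(NA_real_, xgrid$n, xgrid$n)
  idx <- which(xgrid$mask)
  g[idx] <- phantom_sigma(phantom, xgrid$X1[idx], xgrid$X2[idx])
  g
}
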