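## GREIT-style figures of merit, convergence diagnostics, degree of truth.
## All measures operate on difference images (reconstruction minus fitted
## background) on the pixel grid of the reconstruction; radii are
## normalized to the medium radius 1.

#' Quarter-amplitude set of a difference image
#'
#' Binary mask of pixels at or above one fourth of the image maximum,
#' its amplitude-weighted center of gravity and the radial distance of the
#' COG from the medium center.
#'
#' @param img n x n difference image (NA outside the disk), positive max.
#' @param xgrid the \code{\link{image_grid}} the image lives on.
#' @return object of class \code{eit_qset}: \code{mask} (logical n x n,
#'   FALSE outside the disk), \code{cog} (length-2), \code{r_q},
#'   \code{A_q} (pixel count).
#' @export
quarter_amplitude <- function(img, xgrid) {
  mx <- max(img, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0)
    stopf("empty-set error: image has no positive values")
  mask <- !is.na(img) & img >= mx / 4
  w <- img[mask]
  cog <- c(sum(w * xgrid$X1[mask]), sum(w * xgrid$X2[mask])) / sum(w)
  structure(list(mask = mask, cog = cog, r_q = sqrt(sum(cog^2)),
                 A_q = sum(mask)), class = "eit_qset")
}

#' Ground-truth circular target description
#'
#' @param center target center (unit-disk coordinates).
#' @param radius target radius (fraction of medium radius).
#' @param sigma_t,sigma_r target and background conductivity (mS/m).
#' @param xgrid \code{\link{image_grid}} used to count target pixels.
#' @return object of class \code{eit_truth} with \code{r_t} and \code{A_t}
#'   (pixel count of the target disk).
#' @export
target_truth <- function(center, radius, sigma_t, sigma_r, xgrid) {
  if (sigma_t <= 0 || sigma_r <= 0) stopf("conductivities must be positive")
  d2 <- (xgrid$X1 - center[1])^2 + (xgrid$X2 - center[2])^2
  A_t <- sum(d2 <= radius^2 & xgrid$mask)
  structure(list(center = center, radius = radius, sigma_t = sigma_t,
                 sigma_r = sigma_r, r_t = sqrt(sum(center^2)), A_t = A_t),
            class = "eit_truth")
}

#' Amplitude response
#'
#' \eqn{AR = \sum_k [\gamma]_k / (A_t (\sigma_t - \sigma_r)/\sigma_r)},
#' divided by \code{norm_const}.  The normalization constant is calibrated
#' once per pipeline configuration so that AR = 1 for a centered circular
#' target of contrast 2 (see \code{\link{calibrate_ar}}).
#'
#' @param img difference image.
#' @param truth an \code{eit_truth}.
#' @param norm_const calibration constant (default 1 = uncalibrated).
#' @return scalar AR.
#' @export
amplitude_response <- function(img, truth, norm_const = 1) {
  if (truth$sigma_t == truth$sigma_r)
    stopf("undefined-contrast error: sigma_t == sigma_r")
  if (truth$A_t == 0) stopf("target covers no pixels on this grid")
  raw <- sum(img, na.rm = TRUE) /
    (truth$A_t * (truth$sigma_t - truth$sigma_r) / truth$sigma_r)
  raw / norm_const
}

#' AR self-calibration constant
#'
#' Returns the un-normalized amplitude response of the supplied centered
#' contrast-2 reconstruction, to be used as \code{norm_const} for the
#' pipeline configuration it was computed under.
#'
#' @param img difference image of the centered contrast-2 target.
#' @param truth the matching \code{eit_truth}.
#' @return scalar normalization constant.
#' @export
calibrate_ar <- function(img, truth) amplitude_response(img, truth, 1)

#' Position error
#'
#' Signed \eqn{PE = r_t - r_q}, radii normalized to the medium radius.
#'
#' @param qset an \code{eit_qset}.
#' @param truth an \code{eit_truth}.
#' @return scalar PE.
#' @export
position_error <- function(qset, truth) truth$r_t - qset$r_q

#' Ringing
#'
#' \eqn{RNG = A_{out}/A_{in}} where \eqn{A_{out}} is the amplitude-weighted
#' opposite-sign (negative) content outside the circle C centered at the
#' quarter-amplitude COG with area equal to \eqn{A_q}, and \eqn{A_{in}} the
#' positive amplitude content inside C.
#'
#' @param img difference image.
#' @param qset its \code{eit_qset}.
#' @param xgrid the image grid.
#' @return scalar RNG >= 0.
#' @export
ringing <- function(img, qset, xgrid) {
  if (qset$A_q == 0) stopf("degenerate error: empty quarter-amplitude set")
  pix_area <- (2 / xgrid$n)^2
  rC <- sqrt(qset$A_q * pix_area / pi)
  d2 <- (xgrid$X1 - qset$cog[1])^2 + (xgrid$X2 - qset$cog[2])^2
  inC <- d2 <= rC^2 & !is.na(img)
  outC <- d2 > rC^2 & !is.na(img)
  A_in <- sum(pmax(img[inC], 0))
  if (A_in == 0) stopf("degenerate error: no positive content in main lobe")
  A_out <- sum(pmax(-img[outC], 0))
  A_out / A_in
}

#' Resolution
#'
#' \eqn{RES = A_q / A_0}: pixel count of the quarter-amplitude set over the
#' pixel count of the whole reconstructed (disk) image.  \code{sqrt = TRUE}
#' applies the square-root variant used by some GREIT implementations.
#'
#' @param qset an \code{eit_qset}.
#' @param xgrid the image grid.
#' @param sqrt_variant take the square root of the ratio.
#' @return scalar in [0, 1].
#' @export
resolution <- function(qset, xgrid, sqrt_variant = FALSE) {
  A0 <- sum(xgrid$mask)
  if (A0 == 0) stopf("empty image domain")
  res <- qset$A_q / A0
  if (sqrt_variant) sqrt(res) else res
}

#' Shape deformation
#'
#' Fraction of the quarter-amplitude set lying outside the circle C
#' centered at its COG with area \eqn{A_q}.
#'
#' @param qset an \code{eit_qset}.
#' @param xgrid the image grid.
#' @return scalar in [0, 1].
#' @export
shape_deformation <- function(qset, xgrid) {
  if (qset$A_q == 0) stopf("degenerate error: empty quarter-amplitude set")
  pix_area <- (2 / xgrid$n)^2
  rC <- sqrt(qset$A_q * pix_area / pi)
  d2 <- (xgrid$X1 - qset$cog[1])^2 + (xgrid$X2 - qset$cog[2])^2
  sum(qset$mask & d2 > rC^2) / qset$A_q
}

#' Convergence table over k-grid sizes
#'
#' \eqn{E_i = \sup |\gamma_{true} - \gamma_i|} over disk pixels (excluding
#' a configurable boundary rim where the constant-near-boundary assumption
#' makes the error uninformative) and \eqn{CR_i = E_i/E_{i+1}}.
#'
#' @param images list of \code{eit_image}s (or plain matrices) on a common
#'   grid, ordered by increasing k-grid size.
#' @param truth_img matrix of the true conductivity on the same grid.
#' @param xgrid the image grid.
#' @param rim_pixels boundary rim width excluded from the sup (default 2).
#' @return list with \code{E} and \code{CR}.
#' @export
convergence_table <- function(images, truth_img, xgrid, rim_pixels = 2) {
  if (length(images) < 2) stopf("need at least two images")
  n <- xgrid$n
  rad <- sqrt(xgrid$X1^2 + xgrid$X2^2)
  keep <- xgrid$mask & rad <= 1 - rim_pixels * (2 / n)
  E <- vapply(images, function(im) {
    g <- if (inherits(im, "eit_image")) im$gamma else im
    if (!all(dim(g) == dim(truth_img))) stopf("contract error: grid mismatch")
    max(abs(truth_img[keep] - g[keep]), na.rm = TRUE)
  }, numeric(1))
  CR <- E[-length(E)] / E[-1]
  list(E = E, CR = CR)
}

#' Degree of truth
#'
#' \eqn{DT = (\max\gamma_{rec} - \min\gamma_{rec}) /
#' (\max\gamma - \min\gamma)}.
#'
#' @param img reconstructed image (matrix or \code{eit_image}).
#' @param truth_img true conductivity on a common support.
#' @return scalar DT.
#' @export
degree_of_truth <- function(img, truth_img) {
  g <- if (inherits(img, "eit_image")) img$gamma else img
  tr <- range(truth_img, na.rm = TRUE)
  if (diff(tr) == 0) stopf("undefined-DT error: constant truth image")
  diff(range(g, na.rm = TRUE)) / diff(tr)
}

#' Relative extremum errors (percent)
#'
#' \eqn{|\max\gamma_{rec} - \max\gamma|/\max\gamma} and likewise for the
#' minimum, in percent.
#'
#' @param img reconstructed image.
#' @param truth_img true conductivity.
#' @return named vector \code{c(err_max, err_min)} in percent.
#' @export
rel_extremum_errors <- function(img, truth_img) {
  g <- if (inherits(img, "eit_image")) img$gamma else img
  c(err_max = 100 * abs(max(g, na.rm = TRUE) - max(truth_img, na.rm = TRUE)) /
      max(truth_img, na.rm = TRUE),
    err_min = 100 * abs(min(g, na.rm = TRUE) - min(truth_img, na.rm = TRUE)) /
      min(truth_img, na.rm = TRUE))
}

#' All five GREIT measures for one image
#'
#' @param img difference image (reconstruction minus fitted background).
#' @param truth an \code{eit_truth}.
#' @param xgrid the image grid.
#' @param norm_const AR calibration constant.
#' @return named numeric vector AR, PE, RNG, RES, SD.
#' @export
greit_measures <- function(img, truth, xgrid, norm_const = 1) {
  q <- quarter_amplitude(img, xgrid)
  c(AR = amplitude_response(img, truth, norm_const),
    PE = position_error(q, truth),
    RNG = ringing(img, q, xgrid),
    RES = resolution(q, xgrid),
    SD = shape_deformation(q, xgrid))
}
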