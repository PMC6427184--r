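## The three information channels (gray, Canny edge, phase-angle
## reconstruction) and the similarity measures NCC, MI, PSNR (with MSE as
## support).  Images are M x N numeric matrices with intensities in [0, 1].

#' Canny edge channel
#'
#' Binary edge map: Gaussian smoothing, Sobel gradient magnitude,
#' non-maximum suppression along the gradient direction, and
#' double-threshold hysteresis with both thresholds given as fractions of
#' the maximum gradient magnitude.  A constant image returns an all-zero
#' map.
#'
#' @param img image matrix.
#' @param lowFrac,highFrac hysteresis thresholds as fractions of the maximum
#'   gradient magnitude, `0 <= lowFrac < highFrac <= 1`.
#' @param sigma Gaussian smoothing standard deviation in pixels.
#' @return a same-size matrix with values in {0, 1}.
#' @export
edgeChannel <- function(img, lowFrac = 0.1, highFrac = 0.2, sigma = sqrt(2)) {
  .check_image(img)
  if (!(lowFrac >= 0 && lowFrac < highFrac && highFrac <= 1))
    stop("need 0 <= lowFrac < highFrac <= 1")
  cpp_canny(img, sigma, lowFrac, highFrac)
}

#' Phase-angle reconstruction channel
#'
#' Takes the 2-D discrete Fourier transform, keeps only the phase angle
#' (all magnitudes set to 1), inverse-transforms, takes the real part and
#' min-max rescales to [0, 1].  The result preserves edge/structure layout
#' while discarding contrast, so translated inputs give translated outputs
#' (up to boundary wrap) and positive affine intensity changes barely
#' affect it.
#'
#' @param img image matrix.
#' @return a same-size matrix in [0, 1] (all zeros for a degenerate
#'   constant reconstruction).
#' @export
phaseChannel <- function(img) {
  .check_image(img)
  F <- stats::fft(img)
  # zero coefficients carry no phase; keeping them at zero means a constant
  # image reconstructs as a constant (mapped to 0 by the degenerate rescale)
  # rather than as a spurious delta from their arbitrary zero phase
  unit <- ifelse(Mod(F) > 1e-12 * max(Mod(F)), exp(1i * Arg(F)), 0 + 0i)
  rec <- Re(stats::fft(unit, inverse = TRUE)) / length(img)
  rng <- range(rec)
  if (rng[2] - rng[1] < 1e-15) return(matrix(0, nrow(img), ncol(img)))
  (rec - rng[1]) / (rng[2] - rng[1])
}

#' Normalized cross-correlation
#'
#' Pearson correlation of pixel intensities (the mean-and-variance
#' normalized form, so the value lies in [-1, 1]).  By convention a
#' constant image - for which the measure is undefined - yields 0.
#'
#' @param A,B image matrices of identical size.
#' @return value in [-1, 1].
#' @export
ncc <- function(A, B) {
  .check_pair(A, B)
  cpp_ncc(A, B)
}

#' Mutual information
#'
#' Intensities are quantized into `bins` equal-width bins over [0, 1]; the
#' joint histogram gives the joint and marginal distributions and
#' `MI = sum p_AB * log2(p_AB / (p_A p_B))` (bits), with `0 log 0 = 0`.
#' Symmetric, nonnegative, bounded by min of the marginal entropies.
#'
#' @param A,B image matrices of identical size.
#' @param bins number of histogram bins (default 256, the 8-bit level
#'   count).
#' @return MI in bits (>= 0).
#' @export
mutualInformation <- function(A, B, bins = 256) {
  .check_pair(A, B)
  cpp_mi(A, B, as.integer(bins))
}

#' Mean squared error
#' @param A,B image matrices of identical size.
#' @return mean of squared intensity differences.
#' @export
mse <- function(A, B) {
  .check_pair(A, B)
  cpp_mse(A, B)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` with peak 1 for [0, 1]-scaled intensities
#' (identical to the 8-bit 255-scale value since numerator and denominator
#' rescale together).  Identical images return `Inf`.
#'
#' @param A,B image matrices of identical size.
#' @return PSNR in dB; `Inf` when MSE is 0.
#' @export
psnr <- function(A, B) {
  m <- mse(A, B)
  if (m == 0) Inf else 10 * log10(1 / m)
}

.check_pair <- function(A, B) {
  .check_image(A); .check_image(B)
  if (!identical(dim(A), dim(B))) stop("images must have identical dimensions")
  invisible(NULL)
}
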