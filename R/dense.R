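## Dense candidate generation: direct search over the rigid 3-parameter
## space (theta, tv, th) maximizing a similarity measure between the
## reference image and the warped sensed image.  Deterministic two-stage
## search: exhaustive coarse grid, then Nelder-Mead refinement from the
## best grid node.

#' Dense-search configuration
#'
#' @param thetaRange rotation bounds in degrees (length 2).
#' @param tRange translation bounds in pixels (length 2, shared by tv, th).
#' @param thetaStep coarse grid step in degrees.
#' @param tStep coarse grid step in pixels.
#' @param refine run Nelder-Mead refinement from the best grid node.
#' @param miBins joint-histogram bins used when the measure is MI (64 by
#'   default: small images populate a 256-bin joint histogram too sparsely
#'   for a stable objective).
#' @param masked restrict the measure to the valid warp overlap (default).
#'   With `FALSE` the measure is taken over the full frame with
#'   out-of-frame fill 0, which can create spurious optima when large
#'   displacements align fill regions with dark image areas.
#' @param minOverlap minimum valid-overlap fraction for a candidate
#'   parameter vector; smaller overlaps score `-Inf` (guards the masked
#'   objective against the small-overlap bias).
#' @return a list of class `denseSearchConfig`.
#' @export
denseSearchConfig <- function(thetaRange = c(-30, 30), tRange = c(-30, 30),
                              thetaStep = 1, tStep = 2, refine = TRUE,
                              miBins = 64, masked = TRUE, minOverlap = 0.5) {
  stopifnot(length(thetaRange) == 2, length(tRange) == 2,
            thetaStep > 0, tStep > 0, minOverlap > 0, minOverlap <= 1)
  structure(list(thetaRange = thetaRange, tRange = tRange,
                 thetaStep = thetaStep, tStep = tStep, refine = refine,
                 miBins = miBins, masked = masked, minOverlap = minOverlap),
            class = "denseSearchConfig")
}

.rigid_mat <- function(p) {
  t <- p[1] * pi / 180
  ct <- cos(t); st <- sin(t)
  matrix(c(ct, -st, p[2], st, ct, p[3], 0, 0, 1), 3, 3)
}

.dense_objective <- function(R, S, measure, miBins, masked = TRUE,
                             minOverlap = 0.5) {
  force(R); force(S)
  M <- nrow(R); N <- ncol(R)
  if (masked) {
    score <- switch(measure,
      NCC = function(w) cpp_ncc_masked(R, w$image, w$mask),
      MI = function(w) cpp_mi_masked(R, w$image, w$mask, miBins),
      PSNR = function(w) {
        m <- cpp_mse_masked(R, w$image, w$mask)
        if (m == 0) Inf else 10 * log10(1 / m)
      },
      stop("unknown measure: ", measure))
    function(p) {
      w <- cpp_warp(S, .rigid_mat(p), M, N, TRUE)
      if (mean(w$mask) < minOverlap) return(-Inf)
      score(w)
    }
  } else {
    score <- switch(measure,
      NCC = function(w) cpp_ncc(R, w$image),
      MI = function(w) cpp_mi(R, w$image, miBins),
      PSNR = function(w) {
        m <- cpp_mse(R, w$image)
        if (m == 0) Inf else 10 * log10(1 / m)
      },
      stop("unknown measure: ", measure))
    function(p) score(cpp_warp(S, .rigid_mat(p), M, N, TRUE))
  }
}

#' Dense rigid registration
#'
#' Finds the rigid parameters maximizing `measure(R, warp(S, T(p)))` by an
#' exhaustive coarse grid over the configured bounds followed by local
#' Nelder-Mead refinement (which never regresses below the best grid
#' node).  The objective uses bilinear resampling; by default the measure
#' is restricted to the valid warp overlap with a minimum-overlap guard
#' (see [denseSearchConfig()]), the full-frame fill-0 objective being
#' available with `masked = FALSE`.
#'
#' @param R,S reference and sensed image matrices.
#' @param measure "MI", "NCC" or "PSNR".  PSNR is intensity-sensitive: it is
#'   a poor choice under illumination differences (a warning is the
#'   caller's responsibility; the search itself runs regardless).
#' @param search a [denseSearchConfig()].
#' @return the recovered [RigidParams-class] with attributes `value` (the
#'   similarity at the optimum) and `gridValue` (at the best grid node).
#' @export
registerDense <- function(R, S, measure = c("NCC", "MI", "PSNR"),
                          search = denseSearchConfig()) {
  measure <- match.arg(measure)
  .check_pair(R, S)
  if (min(dim(R)) < 8) stop("images must be at least 8 x 8")
  if (stats::sd(R) == 0 || stats::sd(S) == 0)
    stop("degenerate constant image: dense registration undefined")
  obj <- .dense_objective(R, S, measure, search$miBins, search$masked,
                          search$minOverlap)

  thetas <- seq(search$thetaRange[1], search$thetaRange[2],
                by = search$thetaStep)
  ts <- seq(search$tRange[1], search$tRange[2], by = search$tStep)
  best <- -Inf; best_p <- c(0, 0, 0)
  for (th in thetas) {
    for (tv in ts) {
      for (tr in ts) {
        v <- obj(c(th, tv, tr))
        if (v > best) { best <- v; best_p <- c(th, tv, tr) }
      }
    }
  }
  grid_value <- best
  p <- best_p
  if (search$refine && is.finite(best)) {
    lo <- c(search$thetaRange[1], search$tRange[1], search$tRange[1])
    hi <- c(search$thetaRange[2], search$tRange[2], search$tRange[2])
    fence <- function(q) {
      if (any(q < lo - 2) || any(q > hi + 2)) return(Inf)  # stay near bounds
      -obj(q)
    }
    op <- stats::optim(best_p, fence, method = "Nelder-Mead",
                       control = list(maxit = 400, reltol = 1e-10))
    if (-op$value >= grid_value) { p <- op$par; best <- -op$value }
  }
  theta <- p[1]
  if (theta <= -180) theta <- theta + 360
  if (theta > 180) theta <- theta - 360
  out <- rigidParams(theta, p[2], p[3])
  attr(out, "value") <- best
  attr(out, "gridValue") <- grid_value
  attr(out, "measure") <- measure
  out
}
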