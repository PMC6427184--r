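## Ground-truth evaluation: the reference image is warped by the composite
## of the true transformation and the inverse of the estimated one; a
## perfect estimate gives back the reference image, and the average
## absolute intensity difference (AAID) scores the residual misalignment,
## globally and on an even spatial partition.

#' Ground-truth composite warp of the reference image
#'
#' Maps each reference pixel through `Ttrue %*% solve(Tc)` (row-vector
#' convention) and resamples: the result equals the reference image exactly
#' when the estimate matches the truth.
#'
#' @param R reference image matrix.
#' @param tTrue,tEst the true and estimated [ProjectiveTransform-class]s.
#' @param interpolation "bilinear" (default) or "nearest".
#' @return the warped reference image matrix (fill 0 outside the frame).
#' @export
referenceWarp <- function(R, tTrue, tEst,
                          interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  composite <- composeTransforms(tTrue, invertTransform(tEst))
  warpImage(R, invertTransform(composite), dim(R), interpolation)$image
}

#' Average absolute intensity difference
#'
#' `AAID = mean(|A - B|)` over all pixels (fill-0 pixels included);
#' symmetric and zero iff the images are identical.
#'
#' @param A,B image matrices of identical size.
#' @param scale8bit report on the 0-255 display scale instead of [0, 1].
#' @return a nonnegative value.
#' @export
aaid <- function(A, B, scale8bit = FALSE) {
  .check_pair(A, B)
  out <- mean(abs(A - B))
  if (scale8bit) out * 255 else out
}

#' Spatially partitioned AAID
#'
#' Divides the image evenly into `rows x cols` parts (remainder pixels go
#' to the trailing parts) and computes the AAID in each; the global AAID
#' equals the pixel-count-weighted mean of the parts, which the report's
#' validity enforces.
#'
#' @param A,B image matrices of identical size.
#' @param rows,cols partition grid (default 5 x 5).
#' @param scale8bit report on the 0-255 scale.
#' @return an [EvaluationReport-class].
#' @export
partitionAAID <- function(A, B, rows = 5, cols = 5, scale8bit = FALSE) {
  .check_pair(A, B)
  M <- nrow(A); N <- ncol(A)
  if (M < rows || N < cols) stop("image smaller than the partition grid")
  rb <- as.integer(c(1L + (0:(rows - 1)) * (M %/% rows), M + 1L))
  cb <- as.integer(c(1L + (0:(cols - 1)) * (N %/% cols), N + 1L))
  part <- matrix(0, rows, cols)
  counts <- matrix(0, rows, cols)
  D <- abs(A - B)
  if (scale8bit) D <- D * 255
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      blk <- D[rb[i]:(rb[i + 1] - 1), cb[j]:(cb[j + 1] - 1)]
      part[i, j] <- mean(blk)
      counts[i, j] <- length(blk)
    }
  }
  new("EvaluationReport", aaid = sum(part * counts) / sum(counts),
      partition = part, counts = counts, rowBreaks = rb, colBreaks = cb)
}

#' @describeIn partitionAAID Global AAID stored in a report.
#' @param report an [EvaluationReport-class].
#' @export
reportAAID <- function(report) report@aaid

#' @describeIn partitionAAID The per-part AAID grid.
#' @export
reportPartition <- function(report) report@partition

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: AAID = %.6f over a %dx%d partition\n",
              object@aaid, nrow(object@partition), ncol(object@partition)))
  print(round(object@partition, 5))
})

#' Evaluate an estimated transformation against ground truth
#'
#' Convenience wrapper: composite-warps the reference image and reports
#' the global and partitioned AAID.
#'
#' @param R reference image matrix.
#' @param tTrue,tEst true and estimated [ProjectiveTransform-class]s.
#' @param rows,cols partition grid.
#' @param interpolation resampling for the composite warp.
#' @param scale8bit report on the 0-255 scale.
#' @return an [EvaluationReport-class].
#' @export
evaluateRegistration <- function(R, tTrue, tEst, rows = 5, cols = 5,
                                 interpolation = "bilinear",
                                 scale8bit = FALSE) {
  Rc <- referenceWarp(R, tTrue, tEst, interpolation)
  partitionAAID(R, Rc, rows, cols, scale8bit)
}
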