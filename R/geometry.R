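## Projective-transform algebra on the row-vector convention
## [g h s] = [v w 1] %*% T, point (v, w) = (column, row), 0-based.  All
## third-party code in this package uses the same convention; any future
## column-vector routine must transpose at the boundary.

#' Construct a projective transformation
#'
#' @param m a 3x3 invertible matrix acting on row homogeneous vectors; it is
#'   canonically normalized to `t33 = 1` when `t33 != 0`.
#' @return a [ProjectiveTransform-class].
#' @export
projectiveTransform <- function(m) {
  m <- as.matrix(m)
  t <- new("ProjectiveTransform", matrix = m)
  normalizeTransform(t)
}

#' @describeIn transformMatrix The 3x3 matrix of a transformation.
#' @param x a [ProjectiveTransform-class].
#' @export
setMethod("transformMatrix", "ProjectiveTransform", function(x) x@matrix)

#' @name transformMatrix
#' @title Transformation matrix accessor
NULL

setMethod("show", "ProjectiveTransform", function(object) {
  k <- if (isSimilarityTransform(object)) "similarity"
       else if (isAffineTransform(object)) "affine" else "projective"
  cat("ProjectiveTransform (row-vector convention,", k, "):\n")
  print(round(object@matrix, 6))
})

#' Identity transformation
#' @return the identity [ProjectiveTransform-class].
#' @export
identityTransform <- function() projectiveTransform(diag(3))

#' Translation transformation
#' @param a,b translations along the first (v) and second (w) coordinate.
#' @return a [ProjectiveTransform-class] with `t31 = a`, `t32 = b`.
#' @export
translationTransform <- function(a, b) {
  m <- diag(3); m[3, 1] <- a; m[3, 2] <- b
  projectiveTransform(m)
}

#' Transform-family predicates
#'
#' Affine transforms have zero perspective entries (`t13 = t23 = 0`);
#' similarity transforms additionally satisfy `t11 = t22`, `t12 = -t21`.
#'
#' @param t a [ProjectiveTransform-class].
#' @param tol entrywise tolerance.
#' @return logical.
#' @export
isAffineTransform <- function(t, tol = 1e-9) {
  m <- t@matrix
  abs(m[1, 3]) <= tol && abs(m[2, 3]) <= tol
}

#' @rdname isAffineTransform
#' @export
isSimilarityTransform <- function(t, tol = 1e-9) {
  m <- t@matrix
  isAffineTransform(t, tol) && abs(m[1, 1] - m[2, 2]) <= tol &&
    abs(m[1, 2] + m[2, 1]) <= tol
}

#' Normalize the scale freedom of a transformation
#'
#' Divides the matrix by `t33` whenever `t33 != 0`; otherwise the matrix is
#' returned unchanged with a warning (the canonical gauge does not exist).
#'
#' @param t a [ProjectiveTransform-class].
#' @return the normalized [ProjectiveTransform-class].
#' @export
normalizeTransform <- function(t) {
  m <- t@matrix
  if (abs(m[3, 3]) > 1e-12) m <- m / m[3, 3]
  else warning("t33 = 0: transformation left unnormalized")
  new("ProjectiveTransform", matrix = m)
}

#' Invert a transformation
#'
#' @param t a [ProjectiveTransform-class].
#' @return the inverse, renormalized to `t33 = 1` where possible.
#' @export
invertTransform <- function(t) {
  projectiveTransform(solve(t@matrix))
}

#' Compose transformations
#'
#' Row-vector order: applying `t1` then `t2` corresponds to right-multiplying
#' by `t1 %*% t2`, so `transformPoints(composeTransforms(t1, t2), p)` equals
#' `transformPoints(t2, transformPoints(t1, p))`.
#'
#' @param t1,t2 [ProjectiveTransform-class] objects.
#' @return the composite [ProjectiveTransform-class].
#' @export
composeTransforms <- function(t1, t2) {
  projectiveTransform(t1@matrix %*% t2@matrix)
}

#' Map points through a transformation
#'
#' @param t a [ProjectiveTransform-class].
#' @param points n x 2 matrix (or length-2 vector) of (v, w) coordinates.
#' @return n x 2 matrix of mapped (g, h) coordinates; rows mapping to the
#'   line at infinity (homogeneous coordinate ~ 0) are NaN and flagged in
#'   the `"atInfinity"` attribute.
#' @export
transformPoints <- function(t, points) {
  p <- rbind(points)
  if (ncol(p) != 2) stop("points must be n x 2")
  h <- cbind(p, 1) %*% t@matrix
  bad <- abs(h[, 3]) < 1e-12
  out <- h[, 1:2, drop = FALSE] / h[, 3]
  out[bad, ] <- NaN
  attr(out, "atInfinity") <- bad
  out
}

#' Rigid-motion parameters
#'
#' @param theta rotation angle in degrees, anticlockwise positive, in
#'   (-180, 180].
#' @param tv,th translations in pixels along the first and second coordinate.
#' @return a [RigidParams-class].
#' @export
rigidParams <- function(theta, tv, th) {
  new("RigidParams", theta = as.numeric(theta), tv = as.numeric(tv),
      th = as.numeric(th))
}

setMethod("show", "RigidParams", function(object) {
  cat(sprintf("RigidParams: theta = %.4f deg, (tv, th) = (%.4f, %.4f) px\n",
              object@theta, object@tv, object@th))
})

#' Rigid parameters to a projective matrix
#'
#' The unit-scale similarity form on row vectors: rows
#' `[cos t, sin t, 0; -sin t, cos t, 0; tv, th, 1]` (rotation applied before
#' translation).
#'
#' @param p a [RigidParams-class].
#' @return the equivalent [ProjectiveTransform-class].
#' @export
rigidToMatrix <- function(p) {
  t <- p@theta * pi / 180
  m <- rbind(c(cos(t), sin(t), 0),
             c(-sin(t), cos(t), 0),
             c(p@tv, p@th, 1))
  projectiveTransform(m)
}

#' Projective matrix to rigid parameters
#'
#' Exact inverse of [rigidToMatrix()] on the rigid subgroup.
#'
#' @param t a [ProjectiveTransform-class] that is a unit-scale similarity.
#' @param tol tolerance for the rigidity check.
#' @return a [RigidParams-class].
#' @export
matrixToRigid <- function(t, tol = 1e-6) {
  m <- t@matrix
  if (!isSimilarityTransform(t, tol)) stop("not a similarity transform")
  s <- sqrt(m[1, 1]^2 + m[1, 2]^2)
  if (abs(s - 1) > tol) stop("similarity has non-unit scale ", s)
  theta <- atan2(m[1, 2], m[1, 1]) * 180 / pi
  if (theta <= -180) theta <- theta + 360
  rigidParams(theta, m[3, 1], m[3, 2])
}

#' Warp an image by inverse mapping
#'
#' For each output pixel (v, w), the source position is
#' `transformPoints(t, c(v, w))` and the intensity is resampled from `src`
#' by the chosen interpolation.  Out-of-frame sources fill with 0 and get
#' mask 0.  Warping the sensed image by the estimated reference-to-sensed
#' transformation therefore registers it into the reference frame.
#'
#' @param src source image (M x N numeric matrix in [0, 1]).
#' @param t a [ProjectiveTransform-class] mapping output coordinates to
#'   source coordinates.
#' @param outDim integer (M, N) output size; defaults to `dim(src)`.
#' @param interpolation "bilinear" (default) or "nearest".
#' @return list with `image` (the warped matrix) and `mask` (binary
#'   validity matrix).
#' @export
warpImage <- function(src, t, outDim = dim(src),
                      interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  .check_image(src)
  cpp_warp(src, t@matrix, as.integer(outDim[1]), as.integer(outDim[2]),
           interpolation == "bilinear")
}

.check_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) stop("image must be a numeric matrix")
  if (any(!is.finite(img))) stop("image intensities must be finite")
  invisible(img)
}

## ---- estimation ------------------------------------------------------------

.as_points <- function(p, name) {
  p <- rbind(p)
  if (ncol(p) != 2 || anyNA(p)) stop(name, " must be a finite n x 2 matrix")
  p
}

.collinear_triple <- function(p, tol = 1e-8) {
  n <- nrow(p)
  cmb <- utils::combn(n, 3)
  for (k in seq_len(ncol(cmb))) {
    a <- p[cmb[1, k], ]; b <- p[cmb[2, k], ]; c <- p[cmb[3, k], ]
    area2 <- abs((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    scale <- max(1, max(abs(rbind(a, b, c))))
    if (area2 <= tol * scale^2) return(TRUE)
  }
  FALSE
}

#' Exact 4-point projective estimation
#'
#' Solves the 8-equation linear system for the unique transformation
#' (with `t33 = 1`) mapping four reference points to four sensed points
#' exactly; no three reference points may be collinear.
#'
#' @param refPts,senPts 4 x 2 matrices of (v, w) coordinates in the
#'   reference and sensed frames.
#' @return the [ProjectiveTransform-class].
#' @export
estimateProjectiveExact <- function(refPts, senPts) {
  refPts <- .as_points(refPts, "refPts"); senPts <- .as_points(senPts, "senPts")
  if (nrow(refPts) != 4 || nrow(senPts) != 4)
    stop("exact estimation needs exactly 4 correspondences")
  if (.collinear_triple(refPts))
    stop("degenerate configuration: three reference points are collinear")
  # unknowns (t11,t21,t31,t12,t22,t32,t13,t23), t33 = 1
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    v <- refPts[i, 1]; w <- refPts[i, 2]
    g <- senPts[i, 1]; h <- senPts[i, 2]
    A[2 * i - 1, ] <- c(v, w, 1, 0, 0, 0, -g * v, -g * w)
    A[2 * i, ]     <- c(0, 0, 0, v, w, 1, -h * v, -h * w)
    b[2 * i - 1] <- g
    b[2 * i] <- h
  }
  x <- tryCatch(solve(A, b),
                error = function(e) stop("degenerate configuration: ",
                                         conditionMessage(e)))
  projectiveTransform(rbind(c(x[1], x[4], x[7]),
                            c(x[2], x[5], x[8]),
                            c(x[3], x[6], 1)))
}

.hartley_norm <- function(p) {
  ctr <- colMeans(p)
  d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  # row-convention similarity: p_norm = (p - ctr) * s
  N <- rbind(c(s, 0, 0), c(0, s, 0), c(-s * ctr[1], -s * ctr[2], 1))
  list(N = N, pts = sweep(p, 2, ctr) * s)
}

#' Least-squares projective estimation
#'
#' Normalized direct linear transform (Hartley normalization, SVD solution
#' of the homogeneous system) followed by Levenberg-Marquardt refinement of
#' the summed squared reprojection distance (default), or of the literal
#' sum of Euclidean distances via Nelder-Mead when `cost = "euclidean"`.
#' On noise-free consistent correspondences the DLT already recovers the
#' transformation exactly.
#'
#' @param refPts,senPts n x 2 matrices, n >= 4.
#' @param refine logical; run the iterative geometric refinement.
#' @param cost "squared" (default) or "euclidean".
#' @param maxIter maximum refinement iterations.
#' @return the estimated [ProjectiveTransform-class].
#' @export
estimateProjectiveLS <- function(refPts, senPts, refine = TRUE,
                                 cost = c("squared", "euclidean"),
                                 maxIter = 100) {
  cost <- match.arg(cost)
  refPts <- .as_points(refPts, "refPts"); senPts <- .as_points(senPts, "senPts")
  n <- nrow(refPts)
  if (n < 4 || nrow(senPts) != n) stop("need n >= 4 matched correspondences")
  nr <- .hartley_norm(refPts); ns <- .hartley_norm(senPts)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    v <- nr$pts[i, 1]; w <- nr$pts[i, 2]
    g <- ns$pts[i, 1]; h <- ns$pts[i, 2]
    A[2 * i - 1, ] <- c(v, w, 1, 0, 0, 0, -g * v, -g * w, -g)
    A[2 * i, ]     <- c(0, 0, 0, v, w, 1, -h * v, -h * w, -h)
  }
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] / sv$d[1] < 1e-10)
    stop("degenerate configuration: rank-deficient correspondence system")
  x <- sv$v[, 9]
  Ht <- rbind(c(x[1], x[4], x[7]), c(x[2], x[5], x[8]), c(x[3], x[6], x[9]))
  # denormalize: actual = Nref %*% Ht %*% solve(Nsen)
  Tm <- nr$N %*% Ht %*% solve(ns$N)
  est <- projectiveTransform(Tm)
  if (!refine) return(est)

  par0 <- as.vector(est@matrix)[-9]  # 8 free entries, t33 fixed at 1
  proj <- function(par) {
    m <- matrix(c(par, 1), 3, 3)
    h <- cbind(refPts, 1) %*% m
    h[, 1:2, drop = FALSE] / h[, 3]
  }
  if (cost == "squared") {
    res_fn <- function(par) as.vector(proj(par) - senPts)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = res_fn,
                         control = minpack.lm::nls.lm.control(maxiter = maxIter)),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("refinement failed; returning the DLT solution")
      return(est)
    }
    par <- fit$par
  } else {
    obj <- function(par) sum(sqrt(rowSums((proj(par) - senPts)^2)))
    op <- stats::optim(par0, obj, method = "Nelder-Mead",
                       control = list(maxit = maxIter * 20,
                                      reltol = 1e-12))
    if (op$convergence != 0)
      warning("euclidean-cost refinement did not converge; result may be the DLT solution refined partially")
    par <- op$par
  }
  projectiveTransform(matrix(c(par, 1), 3, 3))
}

#' Serialize / deserialize a transformation
#'
#' JSON block with the nine row-major entries and a
#' `"convention": "row-vector"` tag; loading refuses files without the tag.
#'
#' @param t a [ProjectiveTransform-class].
#' @param path file path; omit in `transformToJSON` to get the string.
#' @return `transformFromJSON` returns the [ProjectiveTransform-class].
#' @export
transformToJSON <- function(t, path = NULL) {
  x <- list(convention = "row-vector",
            matrix = as.vector(t(t@matrix)))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname transformToJSON
#' @param json a JSON string (alternative to `path`).
#' @export
transformFromJSON <- function(path = NULL, json = NULL) {
  x <- jsonlite::fromJSON(if (is.null(json)) path else json)
  if (!identical(x$convention, "row-vector"))
    stop("refusing to load a transform without the \"row-vector\" convention tag")
  projectiveTransform(matrix(unlist(x$matrix), 3, 3, byrow = TRUE))
}
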