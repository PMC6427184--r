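#' @import methods
NULL

#' Frame of discernment
#'
#' An ordered set of at least two distinct hypothesis labels.  In this
#' package the hypotheses are candidate image transformations, one per
#' keypoint detector (sparse mode) or per similarity measure (dense mode).
#' The construction order is fixed and used for the canonical bitmask
#' encoding of subsets.
#'
#' @slot elements character vector of distinct labels, length >= 2.
#' @export
setClass("FrameOfDiscernment",
  representation(elements = "character"),
  validity = function(object) {
    e <- object@elements
    if (length(e) < 2) return("a frame of discernment needs at least 2 elements")
    if (anyDuplicated(e)) return("frame elements must be pairwise distinct")
    if (length(e) > 30) return("at most 30 elements supported (bitmask encoding)")
    TRUE
  })

#' Basic belief assignment (mass function)
#'
#' Nonnegative masses over non-empty subsets of a frame of discernment,
#' summing to 1 (tolerance 1e-9).  Subsets are stored as integer bitmasks
#' over the frame's element order.  A BBA whose focal elements are all
#' singletons is called Bayesian.
#'
#' @slot fod the [FrameOfDiscernment-class] the masses live on.
#' @slot subsets integer bitmasks of the focal-candidate subsets (may include
#'   zero-mass entries; entries are distinct and non-zero).
#' @slot masses numeric masses aligned with `subsets`.
#' @export
setClass("BBA",
  representation(fod = "FrameOfDiscernment", subsets = "integer",
                 masses = "numeric"),
  validity = function(object) {
    msg <- .validate_masses(object, allow_empty = FALSE)
    if (is.null(msg)) TRUE else msg
  })

#' Unnormalized BBA (conjunctive-combination intermediate)
#'
#' As [BBA-class] but the empty set may carry mass: the conflict mass K of a
#' conjunctive combination.  Masses including the empty-set entry sum to 1.
#'
#' @slot fod,subsets,masses as in [BBA-class]; `subsets` may contain 0 (the
#'   empty set).
#' @export
setClass("UnnormalizedBBA",
  representation(fod = "FrameOfDiscernment", subsets = "integer",
                 masses = "numeric"),
  validity = function(object) {
    msg <- .validate_masses(object, allow_empty = TRUE)
    if (is.null(msg)) TRUE else msg
  })

.mass_tol <- 1e-9

.validate_masses <- function(object, allow_empty) {
  s <- object@subsets
  m <- object@masses
  if (length(s) != length(m)) return("subsets and masses differ in length")
  if (anyDuplicated(s)) return("duplicate subset entries")
  if (any(!is.finite(m))) return("masses must be finite")
  if (any(m < -.mass_tol)) return("masses must be nonnegative")
  full <- bitwShiftL(1L, length(object@fod@elements)) - 1L
  if (any(s < 0L | s > full)) return("subset outside the frame of discernment")
  if (!allow_empty && any(s == 0L & m > .mass_tol))
    return("the empty set cannot carry mass")
  if (abs(sum(m) - 1) > .mass_tol)
    return(sprintf("masses sum to %.12f, not 1", sum(m)))
  NULL
}

#' Projective transformation (row-vector convention)
#'
#' A 3x3 invertible matrix acting on row homogeneous coordinates
#' `[v w 1] %*% T = [g h s]`, mapping a reference-frame point (v, w) to the
#' sensed-frame point (g/s, h/s).  (v, w) = (column, row), 0-based, pixel
#' centers on integers.  Canonically normalized to `t33 = 1` whenever
#' `t33 != 0`.
#'
#' @slot matrix the 3x3 transformation matrix.
#' @export
setClass("ProjectiveTransform",
  representation(matrix = "matrix"),
  validity = function(object) {
    m <- object@matrix
    if (!is.numeric(m) || !identical(dim(m), c(3L, 3L)))
      return("transformation must be a numeric 3x3 matrix")
    if (any(!is.finite(m))) return("transformation entries must be finite")
    if (abs(det(m)) <= 1e-12) return("transformation matrix is singular")
    TRUE
  })

#' Rigid motion parameters
#'
#' Rotation angle `theta` in degrees (anticlockwise positive) plus the
#' translations `tv` and `th` in pixels along the first and second
#' coordinate; converts losslessly to a [ProjectiveTransform-class] with
#' unit scale (rotation applied before translation).
#'
#' @slot theta rotation in degrees, in (-180, 180].
#' @slot tv,th translations in pixels.
#' @export
setClass("RigidParams",
  representation(theta = "numeric", tv = "numeric", th = "numeric"),
  validity = function(object) {
    if (length(object@theta) != 1 || length(object@tv) != 1 ||
        length(object@th) != 1)
      return("theta, tv, th must be scalars")
    if (!is.finite(object@theta) || object@theta <= -180 || object@theta > 180)
      return("theta must lie in (-180, 180]")
    if (!is.finite(object@tv) || !is.finite(object@th))
      return("translations must be finite")
    TRUE
  })

#' Synthetic registration scenario
#'
#' A fully reproducible recipe for a (reference, sensed) image pair with a
#' known ground-truth transformation: texture generator settings, the true
#' transform, the additive Gaussian noise variance, the noise seed, and the
#' interpolation used when generating the sensed image.
#'
#' @slot name scenario identifier.
#' @slot textureKind one of the [makeTextureImage()] kinds.
#' @slot size integer (M, N) image size.
#' @slot textureSeed seed for the texture generator.
#' @slot trueTransform the ground-truth [ProjectiveTransform-class].
#' @slot noiseVariance variance of zero-mean Gaussian noise on the [0,1]
#'   scale (0 = noise-free).
#' @slot noiseSeed seed for the noise draw.
#' @slot interpolation "bilinear" or "nearest".
#' @slot mode intended registration mode, "dense" or "sparse".
#' @export
setClass("Scenario",
  representation(name = "character", textureKind = "character",
                 size = "integer", textureSeed = "integer",
                 trueTransform = "ProjectiveTransform",
                 noiseVariance = "numeric", noiseSeed = "integer",
                 interpolation = "character", mode = "character"),
  validity = function(object) {
    if (length(object@size) != 2 || any(object@size < 8))
      return("size must be two integers >= 8")
    if (object@noiseVariance < 0) return("noiseVariance must be >= 0")
    if (!object@interpolation %in% c("bilinear", "nearest"))
      return("interpolation must be 'bilinear' or 'nearest'")
    if (!object@mode %in% c("dense", "sparse"))
      return("mode must be 'dense' or 'sparse'")
    TRUE
  })

#' Fused registration result
#'
#' Everything the evidential registration chain produces: the candidate
#' transformations with their provenance labels, the per-channel NCC table,
#' the three channel BBAs and the combined BBA, the combination rule used,
#' the combined transformation, and the registered sensed image with its
#' validity mask.
#'
#' @slot candidates list of [ProjectiveTransform-class] candidates.
#' @slot labels provenance labels (detector or measure names).
#' @slot channelNCC Q x 3 matrix of NCC values (columns gray, edge, phase).
#' @slot bbaG,bbaE,bbaP,bbaC the gray/edge/phase channel BBAs and the
#'   combined BBA.
#' @slot rule "dempster" or "pcr6".
#' @slot transform the combined [ProjectiveTransform-class].
#' @slot registered registered sensed image (matrix in [0,1]).
#' @slot mask binary validity mask of the warp.
#' @export
setClass("RegistrationResult",
  representation(candidates = "list", labels = "character",
                 channelNCC = "matrix", bbaG = "BBA", bbaE = "BBA",
                 bbaP = "BBA", bbaC = "BBA", rule = "character",
                 transform = "ProjectiveTransform", registered = "matrix",
                 mask = "matrix"))

#' Registration evaluation report
#'
#' The global average absolute intensity difference (AAID) between the
#' reference image and its ground-truth-composite warp, plus the per-part
#' AAID over an even spatial partition (5x5 by default).  The global value
#' equals the pixel-count-weighted mean of the partition entries.
#'
#' @slot aaid global AAID.
#' @slot partition rows x cols matrix of per-part AAID values.
#' @slot counts pixel count of each part.
#' @slot rowBreaks,colBreaks part boundary indices (1-based, inclusive
#'   starts; last entry is M+1 / N+1).
#' @export
setClass("EvaluationReport",
  representation(aaid = "numeric", partition = "matrix", counts = "matrix",
                 rowBreaks = "integer", colBreaks = "integer"),
  validity = function(object) {
    if (any(object@partition < -1e-12)) return("AAID entries must be >= 0")
    wm <- sum(object@partition * object@counts) / sum(object@counts)
    if (abs(wm - object@aaid) > 1e-9)
      return("global AAID inconsistent with the weighted partition mean")
    TRUE
  })
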