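## Sparse candidate generation: keypoint detection behind a pluggable
## detector registry, Lowe-ratio descriptor matching, RANSAC/MSAC mismatch
## removal and least-squares transform estimation.
##
## Three classical detector families are built in, each wrapped by an
## adapter that normalizes to the package's (v, w) 0-based coordinate
## convention:
##   harris    - Harris corner response on the smoothed structure tensor
##   shitomasi - Shi-Tomasi minimum-eigenvalue corners
##   dog       - difference-of-Gaussians blob extrema across a small
##               scale stack
## All three share an oriented, L2-normalized intensity-patch descriptor
## (dominant-gradient-orientation frame), compared by Euclidean distance.

.detector_registry <- new.env(parent = emptyenv())

#' Register a keypoint detector
#'
#' A detector function receives `(img, params)` and returns a keypoint set
#' (see [detectFeatures()]); registering under an existing name replaces
#' the previous detector.
#'
#' @param name detector name.
#' @param fun detector function.
#' @export
registerDetector <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .detector_registry)
  invisible(name)
}

#' Names of all registered detectors
#' @return character vector.
#' @export
detectorNames <- function() sort(ls(.detector_registry))

#' Detect keypoints with descriptors
#'
#' Runs the named registered detector; deterministic for fixed input and
#' parameters.  The result is a list with `detector`, `location` (n x 2
#' matrix of (v, w) positions), `scale`, `orientation` (radians),
#' `descriptors` (n x d matrix, rows L2-normalized) and `metric`
#' ("euclidean").
#'
#' @param img image matrix.
#' @param detector one of [detectorNames()].
#' @param params optional named list of detector parameters
#'   (`maxKeypoints`, `responseFrac`, `sigma` ...).
#' @return a keypoint set (possibly with zero rows).
#' @export
detectFeatures <- function(img, detector, params = list()) {
  .check_image(img)
  if (!exists(detector, envir = .detector_registry))
    stop("unknown detector: ", detector,
         " (registered: ", paste(detectorNames(), collapse = ", "), ")")
  fun <- get(detector, envir = .detector_registry)
  ks <- fun(img, params)
  ks$detector <- detector
  ks
}

## ---- shared detector machinery --------------------------------------------

.gradients <- function(img, sigma = 1) {
  sm <- cpp_gaussian_blur(img, sigma)
  M <- nrow(sm); N <- ncol(sm)
  gx <- matrix(0, M, N); gy <- matrix(0, M, N)
  gx[, 2:(N - 1)] <- (sm[, 3:N] - sm[, 1:(N - 2)]) / 2
  gy[2:(M - 1), ] <- (sm[3:M, ] - sm[1:(M - 2), ]) / 2
  list(gx = gx, gy = gy, sm = sm)
}

# 3x3-neighborhood local maxima above frac * an upper response quantile
# (quantile, not max: a single strong structure such as the zero-fill frame
# boundary of a warped image must not starve texture keypoints), excluding a
# border margin
.local_maxima <- function(resp, frac, border, maxn) {
  M <- nrow(resp); N <- ncol(resp)
  pos <- resp[resp > 0]
  if (length(pos) == 0) return(cbind(v = integer(0), w = integer(0)))
  thr <- max(frac * stats::quantile(pos, 0.98, names = FALSE), 1e-12)
  core <- resp[2:(M - 1), 2:(N - 1)]
  is_max <- core >= thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & core >= resp[2:(M - 1) + dr, 2:(N - 1) + dc]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(cbind(v = integer(0), w = integer(0)))
  r <- idx[, 1] + 1; c <- idx[, 2] + 1
  keep <- r > border & r <= M - border & c > border & c <= N - border
  r <- r[keep]; c <- c[keep]
  if (length(r) == 0) return(cbind(v = integer(0), w = integer(0)))
  o <- order(resp[cbind(r, c)], decreasing = TRUE)
  o <- o[seq_len(min(maxn, length(o)))]
  cbind(v = c[o] - 1L, w = r[o] - 1L)  # 0-based (column, row)
}

# dominant gradient orientation: peak of a 36-bin magnitude-weighted
# orientation histogram over a (2r+1)^2 window
.dominant_orientation <- function(gx, gy, v, w, radius) {
  M <- nrow(gx); N <- ncol(gx)
  r0 <- max(1, w + 1 - radius); r1 <- min(M, w + 1 + radius)
  c0 <- max(1, v + 1 - radius); c1 <- min(N, v + 1 + radius)
  px <- gx[r0:r1, c0:c1]; py <- gy[r0:r1, c0:c1]
  mag <- sqrt(px^2 + py^2)
  if (sum(mag) <= 0) return(0)
  ang <- atan2(py, px)
  bin <- pmin(36L, 1L + as.integer(floor((ang + pi) / (2 * pi) * 36)))
  hist <- vapply(1:36, function(b) sum(mag[bin == b]), 0)
  peak <- which.max(hist)
  (peak - 0.5) / 36 * 2 * pi - pi
}

# oriented 8x8 normalized patch descriptor sampled at `spacing` px
.patch_descriptor <- function(sm, v, w, orientation, spacing) {
  g <- seq(-3.5, 3.5, by = 1) * spacing
  grid <- as.matrix(expand.grid(x = g, y = g))
  ca <- cos(orientation); sa <- sin(orientation)
  xs <- v + grid[, 1] * ca - grid[, 2] * sa
  ys <- w + grid[, 1] * sa + grid[, 2] * ca
  vals <- .bilinear_sample(sm, xs, ys)
  vals <- vals - mean(vals)
  nrm <- sqrt(sum(vals^2))
  if (nrm > 0) vals / nrm else vals
}

# vectorized bilinear sampling with edge clamping; x = column, y = row,
# 0-based
.bilinear_sample <- function(img, x, y) {
  M <- nrow(img); N <- ncol(img)
  x <- pmin(pmax(x, 0), N - 1)
  y <- pmin(pmax(y, 0), M - 1)
  x0 <- pmin(floor(x), N - 2); y0 <- pmin(floor(y), M - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1)
  (1 - fy) * ((1 - fx) * img[i00] + fx * img[cbind(y0 + 1, x0 + 2)]) +
    fy * ((1 - fx) * img[cbind(y0 + 2, x0 + 1)] +
          fx * img[cbind(y0 + 2, x0 + 2)])
}

.corner_detector <- function(type) {
  force(type)
  function(img, params) {
    p <- utils::modifyList(list(sigmaD = 1.5, sigmaI = 2.5, k = 0.04,
                                responseFrac = 0.01, maxKeypoints = 400,
                                border = 12, spacing = 2, orient = FALSE),
                           params)
    gr <- .gradients(img, p$sigmaD)
    Sxx <- cpp_gaussian_blur(gr$gx^2, p$sigmaI)
    Syy <- cpp_gaussian_blur(gr$gy^2, p$sigmaI)
    Sxy <- cpp_gaussian_blur(gr$gx * gr$gy, p$sigmaI)
    resp <- if (type == "harris") {
      Sxx * Syy - Sxy^2 - p$k * (Sxx + Syy)^2
    } else {  # Shi-Tomasi minimum eigenvalue
      (Sxx + Syy) / 2 - sqrt(((Sxx - Syy) / 2)^2 + Sxy^2)
    }
    resp[resp < 0] <- 0
    loc <- .local_maxima(resp, p$responseFrac, p$border, p$maxKeypoints)
    .describe_keypoints(img, gr, loc, scale = rep(1, nrow(loc)), p$spacing,
                        orient = p$orient)
  }
}

.dog_detector <- function(img, params) {
  p <- utils::modifyList(list(sigma0 = 1.6, nScales = 4, responseFrac = 0.1,
                              maxKeypoints = 400, border = 12,
                              orient = FALSE), params)
  sigmas <- p$sigma0 * 2^(seq(0, p$nScales) / 2)
  blurred <- lapply(sigmas, function(s) cpp_gaussian_blur(img, s))
  loc <- NULL; scl <- numeric(0)
  for (k in seq_len(p$nScales - 1) + 1) {   # interior scales only
    dog <- abs(blurred[[k + 1]] - blurred[[k]])
    dlo <- abs(blurred[[k]] - blurred[[k - 1]])
    cand <- .local_maxima(dog, p$responseFrac, p$border, p$maxKeypoints)
    if (nrow(cand) > 0) {
      # keep scale-space maxima: response at this scale >= neighbor scale
      ok <- dog[cbind(cand[, 2] + 1, cand[, 1] + 1)] >=
            dlo[cbind(cand[, 2] + 1, cand[, 1] + 1)]
      cand <- cand[ok, , drop = FALSE]
      loc <- rbind(loc, cand)
      scl <- c(scl, rep(sigmas[k], nrow(cand)))
    }
  }
  if (is.null(loc)) loc <- cbind(v = integer(0), w = integer(0))
  if (nrow(loc) > p$maxKeypoints) {
    loc <- loc[seq_len(p$maxKeypoints), , drop = FALSE]
    scl <- scl[seq_len(p$maxKeypoints)]
  }
  gr <- .gradients(img, 1)
  .describe_keypoints(img, gr, loc, scale = scl, spacing = pmax(1.5, scl),
                      orient = p$orient)
}

# Upright patches are the default: dominant-orientation estimates are
# noise-sensitive, and a wrong frame costs far more matches than modest
# view rotation does.  Pass orient = TRUE (detector param) for rotation
# invariance when views differ by large rotations.
.describe_keypoints <- function(img, gr, loc, scale, spacing,
                                descSigma = 2, orient = FALSE) {
  n <- nrow(loc)
  if (length(spacing) == 1) spacing <- rep(spacing, max(n, 1))
  dimg <- cpp_gaussian_blur(img, descSigma)  # noise-robust descriptor base
  orientation <- numeric(n)
  desc <- matrix(0, n, 64)
  for (i in seq_len(n)) {
    if (orient)
      orientation[i] <- .dominant_orientation(gr$gx, gr$gy, loc[i, 1],
                                              loc[i, 2], radius = 7)
    desc[i, ] <- .patch_descriptor(dimg, loc[i, 1], loc[i, 2],
                                   orientation[i], spacing[i])
  }
  list(location = loc, scale = scale, orientation = orientation,
       descriptors = desc, metric = "euclidean")
}

registerDetector("harris", .corner_detector("harris"))
registerDetector("shitomasi", .corner_detector("shitomasi"))
registerDetector("dog", .dog_detector)

## ---- matching --------------------------------------------------------------

#' Match keypoints with the Lowe ratio test
#'
#' Nearest-neighbor descriptor matching: a reference keypoint is matched to
#' its nearest sensed keypoint iff nearest / second-nearest distance is at
#' most `ratio`; ties on distance break toward the lower sensed index.  The
#' result is made one-to-one by greedy best-distance-first resolution.
#'
#' @param ref,sen keypoint sets from [detectFeatures()] with the same
#'   descriptor metric.
#' @param ratio ratio-test threshold in (0, 1].
#' @return list with `refIdx`, `senIdx`, `distance` (parallel vectors) and
#'   `inlier` (all TRUE; filled by [removeMismatches()]).
#' @export
matchFeatures <- function(ref, sen, ratio = 0.8) {
  if (!identical(ref$metric, sen$metric))
    stop("descriptor metrics differ between keypoint sets")
  nr <- nrow(ref$descriptors); ns <- nrow(sen$descriptors)
  if (nr == 0 || ns == 0) stop("empty keypoint set")
  D2 <- outer(rowSums(ref$descriptors^2), rowSums(sen$descriptors^2), "+") -
    2 * ref$descriptors %*% t(sen$descriptors)
  D2[D2 < 0] <- 0
  cand <- NULL
  single <- ns < 2
  if (single)
    warning("fewer than 2 sensed keypoints: ratio test degenerates to nearest")
  for (i in seq_len(nr)) {
    d <- sqrt(D2[i, ])
    o <- order(d, seq_along(d))  # ties toward the lower sensed index
    best <- o[1]
    if (!single) {
      if (d[o[2]] <= 0) next                     # indistinguishable pair
      if (d[best] / d[o[2]] > ratio) next
    }
    cand <- rbind(cand, c(i, best, d[best]))
  }
  if (is.null(cand))
    return(list(refIdx = integer(0), senIdx = integer(0),
                distance = numeric(0), inlier = logical(0)))
  # greedy one-to-one by ascending distance
  cand <- cand[order(cand[, 3], cand[, 2]), , drop = FALSE]
  used <- logical(ns)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used[cand[k, 2]]) { keep[k] <- TRUE; used[cand[k, 2]] <- TRUE }
  }
  cand <- cand[keep, , drop = FALSE]
  list(refIdx = as.integer(cand[, 1]), senIdx = as.integer(cand[, 2]),
       distance = cand[, 3], inlier = rep(TRUE, nrow(cand)))
}

## ---- robust model fitting --------------------------------------------------

#' Remove mismatches with RANSAC or MSAC
#'
#' Samples minimal 4-match subsets, fits the exact projective solution and
#' scores the consensus by inlier count (RANSAC) or by the truncated squared
#' reprojection loss (MSAC).  The winning model's inliers (reprojection
#' distance within `thresholdPx`) are re-fit by [estimateProjectiveLS()].
#' Deterministic for a fixed `seed`.
#'
#' @param matches a match set from [matchFeatures()].
#' @param ref,sen the keypoint sets the match indices refer to.
#' @param method "MSAC" (default) or "RANSAC".
#' @param thresholdPx inlier reprojection threshold in pixels.
#' @param maxIter number of sampling iterations.
#' @param seed RNG seed for the sampler.
#' @return list with `matches` (the input with `inlier` flags updated),
#'   `transform` (the LS re-fit), `nInliers`, and `ok` (FALSE when no model
#'   reached 4 inliers).
#' @export
removeMismatches <- function(matches, ref, sen, method = c("MSAC", "RANSAC"),
                             thresholdPx = 2, maxIter = 2000, seed = 1) {
  method <- match.arg(method)
  n <- length(matches$refIdx)
  if (n < 4) stop("mismatch removal needs at least 4 matches")
  rp <- ref$location[matches$refIdx, , drop = FALSE]
  sp <- sen$location[matches$senIdx, , drop = FALSE]
  storage.mode(rp) <- "double"; storage.mode(sp) <- "double"
  thr2 <- thresholdPx^2

  best_cost <- Inf; best_inl <- NULL
  rph <- cbind(rp, 1)
  .with_seed(seed, {
    for (it in seq_len(maxIter)) {
      s <- sample.int(n, 4)
      t4 <- tryCatch(estimateProjectiveExact(rp[s, ], sp[s, ]),
                     error = function(e) NULL)
      if (is.null(t4)) next
      h <- rph %*% t4@matrix
      bad <- abs(h[, 3]) < 1e-12
      d2 <- rowSums((h[, 1:2, drop = FALSE] / h[, 3] - sp)^2)
      d2[bad] <- Inf
      cost <- if (method == "MSAC") sum(pmin(d2, thr2)) else -sum(d2 <= thr2)
      if (cost < best_cost) {
        best_cost <- cost
        best_inl <- d2 <= thr2
      }
    }
  })
  if (is.null(best_inl) || sum(best_inl) < 4)
    return(list(matches = matches, transform = NULL, nInliers = 0, ok = FALSE))
  fit <- estimateProjectiveLS(rp[best_inl, , drop = FALSE],
                              sp[best_inl, , drop = FALSE])
  matches$inlier <- best_inl
  list(matches = matches, transform = fit, nInliers = sum(best_inl), ok = TRUE)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# geometric-gated re-matching: with a provisional transform, each reference
# keypoint is matched to the descriptor-nearest sensed keypoint within
# `gatePx` of its predicted position (one-to-one, best distance first)
.guided_match <- function(ref, sen, t, gatePx = 5) {
  pred <- transformPoints(t, ref$location)
  cand <- NULL
  for (i in seq_len(nrow(ref$location))) {
    d2pos <- rowSums(sweep(sen$location, 2, pred[i, ])^2)
    near <- which(d2pos <= gatePx^2)
    if (length(near) == 0) next
    dd <- sqrt(rowSums(sweep(sen$descriptors[near, , drop = FALSE], 2,
                             ref$descriptors[i, ])^2))
    j <- near[which.min(dd)]
    cand <- rbind(cand, c(i, j, min(dd)))
  }
  if (is.null(cand))
    return(list(refIdx = integer(0), senIdx = integer(0),
                distance = numeric(0), inlier = logical(0)))
  cand <- cand[order(cand[, 3], cand[, 2]), , drop = FALSE]
  used <- logical(nrow(sen$location))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand)))
    if (!used[cand[k, 2]]) { keep[k] <- TRUE; used[cand[k, 2]] <- TRUE }
  cand <- cand[keep, , drop = FALSE]
  list(refIdx = as.integer(cand[, 1]), senIdx = as.integer(cand[, 2]),
       distance = cand[, 3], inlier = rep(TRUE, nrow(cand)))
}

# local area scale (sqrt |Jacobian|) of the mapping at the frame corners
# and center must stay within [lo, hi]: same-scene views do not magnify
# fourfold, and runaway projective fits do
.plausible_transform <- function(t, dims, lo = 0.25, hi = 4) {
  m <- t@matrix
  pts <- rbind(c(0, 0), c(dims[2] - 1, 0), c(0, dims[1] - 1),
               c(dims[2] - 1, dims[1] - 1),
               c((dims[2] - 1) / 2, (dims[1] - 1) / 2))
  h <- cbind(pts, 1) %*% m
  if (any(abs(h[, 3]) < 1e-9)) return(FALSE)
  for (i in seq_len(nrow(pts))) {
    v <- pts[i, 1]; w <- pts[i, 2]; D <- h[i, 3]
    # Jacobian of (g, h) = ([v w 1] m)_{1,2} / D at (v, w)
    dg_dv <- (m[1, 1] - h[i, 1] / D * m[1, 3]) / D
    dg_dw <- (m[2, 1] - h[i, 1] / D * m[2, 3]) / D
    dh_dv <- (m[1, 2] - h[i, 2] / D * m[1, 3]) / D
    dh_dw <- (m[2, 2] - h[i, 2] / D * m[2, 3]) / D
    jd <- abs(dg_dv * dh_dw - dg_dw * dh_dv)
    if (!is.finite(jd) || jd < lo^2 || jd > hi^2) return(FALSE)
  }
  TRUE
}

#' Sparse registration pipeline
#'
#' Detect, match, remove mismatches, and least-squares fit.  A second,
#' geometry-guided round then re-matches keypoints within a small gate of
#' the positions predicted by the first fit and refits; the refined
#' estimate is kept when it explains at least as many inliers.  Returns
#' the estimated reference-to-sensed transformation.
#'
#' @param R,S reference and sensed image matrices.
#' @param detector one of [detectorNames()].
#' @param ratio ratio-test threshold.
#' @param method,thresholdPx,maxIter,seed passed to [removeMismatches()].
#' @param guided run the guided second round (default TRUE).
#' @param gatePx geometric gate radius for the guided round, pixels.
#' @param verifyNCC minimum valid-overlap gray NCC between the reference
#'   and the registered sensed image for a fit to be accepted; the round
#'   (initial or guided) with the higher score wins, and a best score
#'   below the threshold is a verification failure (a correct fit scores
#'   near 1 on clean pairs and well above 0.8 at the supported noise
#'   levels, while a wrong consensus model scores near 0).
#' @param params detector parameters.
#' @param verbose log stage counts.
#' @return the estimated [ProjectiveTransform-class]; stage failures raise
#'   stage-labeled errors.
#' @export
registerSparse <- function(R, S, detector, ratio = 0.8, method = "MSAC",
                           thresholdPx = 2, maxIter = 2000, seed = 1,
                           guided = TRUE, gatePx = 5, verifyNCC = 0.5,
                           params = list(), verbose = FALSE) {
  kr <- detectFeatures(R, detector, params)
  ks <- detectFeatures(S, detector, params)
  if (nrow(kr$location) == 0 || nrow(ks$location) == 0)
    stop("[detect] no keypoints found by ", detector)
  m <- matchFeatures(kr, ks, ratio)
  if (length(m$refIdx) < 4)
    stop("[match] fewer than 4 ratio-test matches for ", detector)
  rm <- removeMismatches(m, kr, ks, method = method, thresholdPx = thresholdPx,
                         maxIter = maxIter, seed = seed)
  if (!rm$ok)
    stop("[consensus] no model with >= 4 inliers for ", detector)
  # verification score: gray NCC over the valid warp overlap, provided the
  # overlap covers at least half the frame (a degenerate fit can score a
  # high NCC over a tiny surviving overlap) and the transform is
  # plausible for same-scene alignment (local area scale within [1/4, 4]
  # across the frame)
  score <- function(t) {
    if (!.plausible_transform(t, dim(R))) return(-1)
    w <- warpImage(S, t, dim(R))
    if (mean(w$mask) < 0.5) return(-1)
    cpp_ncc_masked(R, w$image, w$mask)
  }
  sc1 <- score(rm$transform)
  if (guided) {
    g <- .guided_match(kr, ks, rm$transform, gatePx)
    if (length(g$refIdx) >= 4) {
      rm2 <- tryCatch(
        removeMismatches(g, kr, ks, method = method,
                         thresholdPx = max(thresholdPx, 3),
                         maxIter = min(maxIter, 500), seed = seed + 1),
        error = function(e) NULL)
      if (!is.null(rm2) && rm2$ok && score(rm2$transform) > sc1) {
        rm <- rm2
        sc1 <- score(rm2$transform)
      }
    }
  }
  if (sc1 < verifyNCC)
    stop("[verify] registered-image NCC ", round(sc1, 3), " below ",
         verifyNCC, " for ", detector)
  if (verbose)
    message(sprintf("%s: %d/%d keypoints, %d matches, %d inliers, NCC %.3f",
                    detector, nrow(kr$location), nrow(ks$location),
                    length(m$refIdx), rm$nInliers, sc1))
  rm$transform
}
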