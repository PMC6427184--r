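## Deterministic synthetic fixtures: textured reference images, sensed
## images derived through a known transformation (optionally noisy), and
## the packaged scenario suite used by the acceptance experiments.  All
## randomness is seeded and the global RNG state is left untouched.

#' Deterministic textured test image
#'
#' All kinds have broad-band spatial structure so that corners, edges and
#' phase content exist.  `blobs` sums random Gaussian blobs over fine
#' smoothed noise; `checker` is a checkerboard with per-cell intensity
#' jitter (to break the translation periodicity) plus fine texture;
#' `gradient_blobs` adds a linear illumination ramp to `blobs`;
#' `hestain_like` mixes a few large bright blobs with many small dark ones
#' at different scales, mimicking stained-tissue texture.
#'
#' @param kind one of "blobs", "checker", "gradient_blobs", "hestain_like".
#' @param size integer (M, N), both >= 64.
#' @param seed RNG seed; the same (kind, size, seed) always returns the
#'   identical image.
#' @return an M x N matrix in [0, 1].
#' @export
makeTextureImage <- function(kind = c("blobs", "checker", "gradient_blobs",
                                      "hestain_like"),
                             size = c(128, 128), seed = 1) {
  kind <- match.arg(kind)
  if (length(size) != 2 || any(size < 64)) stop("size must be >= 64 x 64")
  M <- as.integer(size[1]); N <- as.integer(size[2])
  .with_seed(seed, {
    img <- switch(kind,
      blobs = .tex_blobs(M, N),
      checker = .tex_checker(M, N),
      gradient_blobs = {
        b <- .tex_blobs(M, N)
        ramp <- matrix(seq(0, 0.3, length.out = N), M, N, byrow = TRUE)
        b * 0.7 + ramp
      },
      hestain_like = .tex_hestain(M, N))
    rng <- range(img)
    (img - rng[1]) / (rng[2] - rng[1])
  })
}

.blob_field <- function(M, N, n, sigRange, ampRange) {
  rows <- matrix(0:(M - 1), M, N)
  cols <- matrix(0:(N - 1), M, N, byrow = TRUE)
  acc <- matrix(0, M, N)
  for (i in seq_len(n)) {
    cy <- stats::runif(1, 0, M - 1); cx <- stats::runif(1, 0, N - 1)
    s <- stats::runif(1, sigRange[1], sigRange[2])
    a <- stats::runif(1, ampRange[1], ampRange[2])
    acc <- acc + a * exp(-((rows - cy)^2 + (cols - cx)^2) / (2 * s^2))
  }
  acc
}

.fine_noise <- function(M, N, sigma = 1, amp = 0.15) {
  amp * cpp_gaussian_blur(matrix(stats::rnorm(M * N), M, N), sigma)
}

.tex_blobs <- function(M, N) {
  .blob_field(M, N, 60, c(3, 12), c(-1, 1)) + .fine_noise(M, N)
}

.tex_checker <- function(M, N) {
  cell <- 16L
  ri <- (0:(M - 1)) %/% cell
  ci <- (0:(N - 1)) %/% cell
  nr <- max(ri) + 1; nc <- max(ci) + 1
  jitter <- matrix(stats::runif(nr * nc, -0.18, 0.18), nr, nc)
  base <- outer(ri, ci, function(a, b) ifelse((a + b) %% 2 == 0, 0.3, 0.7))
  base <- base + jitter[cbind(rep(ri + 1, length(ci)),
                              rep(ci + 1, each = length(ri)))]
  # note: outer() above already gives M x N; add jitter by cell index
  base + .fine_noise(M, N, sigma = 1, amp = 0.08)
}

.tex_hestain <- function(M, N) {
  big <- .blob_field(M, N, 25, c(6, 14), c(0.3, 0.8))
  small <- .blob_field(M, N, 120, c(1.5, 3), c(-0.9, -0.3))
  0.65 + 0.3 * big + 0.5 * small + .fine_noise(M, N, sigma = 0.8, amp = 0.1)
}

#' Derive a sensed image from a reference and a known transformation
#'
#' The sensed image is the reference warped into the sensed frame by the
#' inverse of the true transformation (so registering it back to the
#' reference must recover the truth), then corrupted by independent
#' zero-mean Gaussian pixel noise of the given variance on the [0, 1]
#' scale and clipped to [0, 1].
#'
#' @param R reference image matrix.
#' @param tTrue the true reference-to-sensed [ProjectiveTransform-class].
#' @param noiseVariance Gaussian noise variance (0 = noise-free).
#' @param seed seed for the noise draw.
#' @param interpolation resampling used for the pair generation.
#' @return the sensed image matrix.
#' @export
derivePair <- function(R, tTrue, noiseVariance = 0, seed = 1,
                       interpolation = "bilinear") {
  .check_image(R)
  S <- warpImage(R, invertTransform(tTrue), dim(R), interpolation)$image
  if (noiseVariance > 0) {
    .with_seed(seed, {
      S <- S + matrix(stats::rnorm(length(S), 0, sqrt(noiseVariance)),
                      nrow(S), ncol(S))
    })
    S <- pmin(pmax(S, 0), 1)
  }
  S
}

#' Build a scenario
#'
#' @param name scenario identifier.
#' @param textureKind,size,textureSeed texture recipe.
#' @param trueTransform ground-truth [ProjectiveTransform-class].
#' @param noiseVariance,noiseSeed noise recipe.
#' @param interpolation pair-generation resampling.
#' @param mode intended registration mode ("dense" or "sparse").
#' @return a [Scenario-class].
#' @export
scenario <- function(name, textureKind, size, textureSeed, trueTransform,
                     noiseVariance = 0, noiseSeed = 1,
                     interpolation = "bilinear", mode = "dense") {
  new("Scenario", name = name, textureKind = textureKind,
      size = as.integer(size), textureSeed = as.integer(textureSeed),
      trueTransform = trueTransform, noiseVariance = noiseVariance,
      noiseSeed = as.integer(noiseSeed), interpolation = interpolation,
      mode = mode)
}

setMethod("show", "Scenario", function(object) {
  cat(sprintf("Scenario '%s': %s %dx%d (seed %d), noise var %.3g, %s mode\n",
              object@name, object@textureKind, object@size[1], object@size[2],
              object@textureSeed, object@noiseVariance, object@mode))
})

#' Regenerate the image pair of a scenario
#'
#' @param sc a [Scenario-class].
#' @return list with `R`, `S` and `tTrue`; bit-identical on every call.
#' @export
scenarioPair <- function(sc) {
  R <- makeTextureImage(sc@textureKind, sc@size, sc@textureSeed)
  S <- derivePair(R, sc@trueTransform, sc@noiseVariance, sc@noiseSeed,
                  sc@interpolation)
  list(R = R, S = S, tTrue = sc@trueTransform)
}

#' Scenario serialization
#'
#' @param sc a [Scenario-class].
#' @param path optional file path.
#' @return `scenarioFromJSON` returns the [Scenario-class].
#' @export
scenarioToJSON <- function(sc, path = NULL) {
  x <- list(name = sc@name, textureKind = sc@textureKind, size = sc@size,
            textureSeed = sc@textureSeed,
            trueTransform = list(convention = "row-vector",
                                 matrix = as.vector(t(sc@trueTransform@matrix))),
            noiseVariance = sc@noiseVariance, noiseSeed = sc@noiseSeed,
            interpolation = sc@interpolation, mode = sc@mode)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname scenarioToJSON
#' @param json a JSON string (alternative to `path`).
#' @export
scenarioFromJSON <- function(path = NULL, json = NULL) {
  x <- jsonlite::fromJSON(if (is.null(json)) path else json)
  if (!identical(x$trueTransform$convention, "row-vector"))
    stop("transform convention tag missing")
  scenario(x$name, x$textureKind, unlist(x$size), x$textureSeed,
           projectiveTransform(matrix(unlist(x$trueTransform$matrix), 3, 3,
                                      byrow = TRUE)),
           x$noiseVariance, x$noiseSeed, x$interpolation, x$mode)
}

#' Packaged scenario suite
#'
#' Twenty scenarios over four base textures (128 x 128): per texture, the
#' rigid design theta = 10 deg, (tv, th) = (-10, 5) at noise variance 0 and
#' 0.01; the rigid design theta = -10 deg, (tv, th) = (-10, 5) at noise
#' 0.01; and one mild random projective scenario (rotation within +/- 5
#' deg, translation within +/- 8 px, perspective entries within +/- 5e-4)
#' at noise 0 and 0.01.  Rigid scenarios are flagged for the dense mode,
#' projective ones for the sparse mode.
#'
#' @param seed master seed; all per-scenario seeds derive from it.
#' @return list of [Scenario-class] objects (length 20).
#' @export
scenarioSuite <- function(seed = 1) {
  textures <- c("blobs", "checker", "gradient_blobs", "hestain_like")
  size <- c(128L, 128L)
  base <- (abs(seed) %% 100000L) * 10007L
  out <- list()
  add <- function(sc) out[[length(out) + 1]] <<- sc
  for (k in seq_along(textures)) {
    tex <- textures[k]
    tseed <- base + k * 101L
    rigidT <- rigidToMatrix(rigidParams(10, -10, 5))
    add(scenario(paste0(tex, "_rigid10_clean"), tex, size, tseed, rigidT,
                 0, 1L, mode = "dense"))
    add(scenario(paste0(tex, "_rigid10_noisy"), tex, size, tseed, rigidT,
                 0.01, base + k * 7L + 1L, mode = "dense"))
    rigidN <- rigidToMatrix(rigidParams(-10, -10, 5))
    add(scenario(paste0(tex, "_rigidm10_noisy"), tex, size, tseed, rigidN,
                 0.01, base + k * 7L + 2L, mode = "dense"))
    projT <- .random_mild_projective(base + k * 13L)
    add(scenario(paste0(tex, "_proj_clean"), tex, size, tseed, projT,
                 0, 1L, mode = "sparse"))
    add(scenario(paste0(tex, "_proj_noisy"), tex, size, tseed, projT,
                 0.01, base + k * 7L + 3L, mode = "sparse"))
  }
  out
}

# mild projective ground truth: small rotation and translation with tiny
# perspective terms, centered so the frame overlap stays large
.random_mild_projective <- function(seed) {
  .with_seed(seed, {
    th <- stats::runif(1, -5, 5)
    tv <- stats::runif(1, -8, 8)
    tr <- stats::runif(1, -8, 8)
    p13 <- stats::runif(1, -5e-4, 5e-4)
    p23 <- stats::runif(1, -5e-4, 5e-4)
    m <- rigidToMatrix(rigidParams(th, tv, tr))@matrix
    m[1, 3] <- p13
    m[2, 3] <- p23
    projectiveTransform(m)
  })
}
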