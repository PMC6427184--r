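## The evidential fusion chain: per-candidate NCC on three information
## channels, the e^x - 1 belief stretch, combination by Dempster or PCR6,
## and the mass-weighted combined transformation.

#' Per-candidate channel similarities
#'
#' Each candidate transformation warps the sensed image into the reference
#' frame; NCC is then computed between channels extracted independently
#' from the reference image and from each warped image: gray against gray,
#' Canny edges against Canny edges, phase reconstruction against phase
#' reconstruction.
#'
#' @param R,S reference and sensed image matrices.
#' @param transforms list of at least two invertible
#'   [ProjectiveTransform-class] candidates.
#' @param edgeParams named list of [edgeChannel()] parameters.
#' @return list with `ncc` (Q x 3 matrix, columns G/E/P), `warped` (list of
#'   warp results) and `kept` (indices of surviving candidates; candidates
#'   whose warp fails are dropped with a warning).
#' @export
candidateSimilarities <- function(R, S, transforms, edgeParams = list()) {
  .check_pair(R, S)
  if (length(transforms) < 2) stop("need at least 2 candidate transformations")
  Rg <- R
  Re_ <- do.call(edgeChannel, c(list(Rg), edgeParams))
  Rp <- phaseChannel(Rg)
  kept <- integer(0); warped <- list(); rows <- NULL
  for (i in seq_along(transforms)) {
    w <- tryCatch(warpImage(S, transforms[[i]], dim(R)),
                  error = function(e) NULL)
    if (is.null(w)) {
      warning("candidate ", i, " dropped: warp failed")
      next
    }
    Sg <- w$image
    Se <- do.call(edgeChannel, c(list(Sg), edgeParams))
    Sp <- phaseChannel(Sg)
    rows <- rbind(rows, c(G = cpp_ncc_masked(Rg, Sg, w$mask),
                          E = cpp_ncc_masked(Re_, Se, w$mask),
                          P = cpp_ncc_masked(Rp, Sp, w$mask)))
    kept <- c(kept, i)
    warped[[length(warped) + 1]] <- w
  }
  if (length(kept) < 2)
    stop("fewer than 2 candidates survived warping: fusion impossible")
  rownames(rows) <- NULL
  list(ncc = rows, warped = warped, kept = kept)
}

#' Build the three channel BBAs from NCC values
#'
#' Per channel, NCC values are clamped to [0, 1] (negative correlation
#' carries no evidence of a correct transformation), stretched by
#' `y = exp(x) - 1` to enlarge their differences, and normalized into a
#' Bayesian BBA over the candidates.  A channel whose clamped values are
#' all zero carries no evidence and falls back to the uniform BBA with a
#' warning.
#'
#' @param nccMatrix Q x 3 matrix of NCC values (columns gray, edge, phase).
#' @param labels candidate labels (frame elements); defaults to
#'   "T1".."TQ".
#' @return list with elements `G`, `E`, `P`: Bayesian [BBA-class]s on the
#'   shared candidate frame.
#' @export
buildChannelBBAs <- function(nccMatrix, labels = NULL) {
  nccMatrix <- rbind(nccMatrix)
  Q <- nrow(nccMatrix)
  if (Q < 2) stop("need at least 2 candidates")
  if (ncol(nccMatrix) != 3) stop("nccMatrix must have 3 channel columns")
  if (is.null(labels)) labels <- paste0("T", seq_len(Q))
  fod <- frameOfDiscernment(labels)
  one <- function(x, channel) {
    y <- expm1(pmax(pmin(x, 1), 0))
    s <- sum(y)
    if (s <= 0) {
      warning("zero-evidence ", channel,
              " channel: falling back to the uniform BBA")
      y <- rep(1, Q); s <- Q
    }
    makeBBA(fod, stats::setNames(y / s, labels))
  }
  list(G = one(nccMatrix[, 1], "gray"),
       E = one(nccMatrix[, 2], "edge"),
       P = one(nccMatrix[, 3], "phase"))
}

#' Fuse the three channel BBAs
#'
#' Dempster's rule is applied sequentially (it is associative, so the order
#' is immaterial); PCR6 combines all three sources jointly by the n-source
#' redistribution.
#'
#' @param mG,mE,mP channel [BBA-class]s on an identical frame.
#' @param rule "dempster" or "pcr6".
#' @return the combined [BBA-class].
#' @export
fuseBBAs <- function(mG, mE, mP, rule = c("dempster", "pcr6")) {
  rule <- match.arg(rule)
  .check_same_fod(mG, mE, mP)
  if (rule == "dempster") {
    out <- tryCatch(combineDempster(combineDempster(mG, mE), mP),
                    error = function(e)
                      stop("total conflict under Dempster's rule; ",
                           "use rule = \"pcr6\"", call. = FALSE))
    out
  } else {
    combinePCR6(list(mG, mE, mP))
  }
}

#' Combined transformation from fused masses
#'
#' The combined inverse matrix is the mass-weighted entrywise sum of the
#' candidates' inverse matrices (each first normalized to `t33 = 1`, the
#' package's canonical gauge); the result is inverted and renormalized.
#' Defined for Bayesian fused masses only.
#'
#' @param mc the combined Bayesian [BBA-class]; its frame elements must
#'   correspond one-to-one, in order, with `transforms`.
#' @param transforms list of candidate [ProjectiveTransform-class]s.
#' @return the combined [ProjectiveTransform-class].
#' @export
combinedTransform <- function(mc, transforms) {
  if (!isBayesian(mc))
    stop("the combined transformation is defined for Bayesian masses only")
  els <- frameElements(mc)
  if (length(transforms) != length(els))
    stop("number of candidates must match the frame size")
  inv_sum <- matrix(0, 3, 3)
  for (i in seq_along(els)) {
    w <- massOf(mc, els[i])
    inv_sum <- inv_sum + w * invertTransform(transforms[[i]])@matrix
  }
  if (abs(det(inv_sum)) <= 1e-12)
    stop("mass-weighted inverse sum is singular")
  projectiveTransform(solve(inv_sum))
}

setMethod("show", "RegistrationResult", function(object) {
  cat("RegistrationResult (", object@rule, " rule, ",
      length(object@candidates), " candidates)\n", sep = "")
  cat("  candidates:", paste(object@labels, collapse = ", "), "\n")
  cat("  combined masses:\n")
  m <- massValues(object@bbaC)
  for (k in names(m)) cat(sprintf("    m(%s) = %.5f\n", k, m[[k]]))
  cat("  combined transform:\n")
  print(round(object@transform@matrix, 6))
})

#' Accessors for registration results
#'
#' @param x a [RegistrationResult-class].
#' @return `fusedTransform`: the combined [ProjectiveTransform-class];
#'   `registeredImage`: the registered sensed image matrix;
#'   `candidateTransforms`: named list of candidates; `channelNCC`: the
#'   Q x 3 NCC table; `fusedBBA`: the combined [BBA-class].
#' @export
fusedTransform <- function(x) x@transform

#' @rdname fusedTransform
#' @export
registeredImage <- function(x) x@registered

#' @rdname fusedTransform
#' @export
candidateTransforms <- function(x) stats::setNames(x@candidates, x@labels)

#' @rdname fusedTransform
#' @export
channelNCC <- function(x) x@channelNCC

#' @rdname fusedTransform
#' @export
fusedBBA <- function(x) x@bbaC

#' Full evidential registration
#'
#' Runs every configured candidate generator (sparse detectors or dense
#' similarity measures), measures each candidate on the three information
#' channels, builds and fuses the channel BBAs, forms the combined
#' transformation and warps the sensed image with it.
#'
#' @param R,S reference and sensed image matrices.
#' @param mode "sparse" (keypoint detectors) or "dense" (similarity
#'   measures).
#' @param candidates character vector of generators: detector names for
#'   sparse mode (default `c("harris", "shitomasi", "dog")`), measure names
#'   for dense mode (default `c("MI", "PSNR", "NCC")`).
#' @param rule combination rule, "dempster" or "pcr6".
#' @param search dense-mode [denseSearchConfig()].
#' @param seed seed for the sparse consensus sampler.
#' @param sparseOpts named list of extra [registerSparse()] arguments.
#' @return a [RegistrationResult-class]; generators that fail are dropped
#'   with a warning, and fewer than two surviving candidates is an error.
#' @export
registerFused <- function(R, S, mode = c("dense", "sparse"),
                          candidates = NULL, rule = c("dempster", "pcr6"),
                          search = denseSearchConfig(), seed = 1,
                          sparseOpts = list()) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  if (is.null(candidates))
    candidates <- if (mode == "dense") c("MI", "PSNR", "NCC")
                  else c("harris", "shitomasi", "dog")
  if (length(candidates) < 2) stop("need at least 2 candidate generators")
  transforms <- list(); labels <- character(0)
  for (g in candidates) {
    t <- tryCatch({
      if (mode == "dense") rigidToMatrix(registerDense(R, S, g, search))
      else do.call(registerSparse, c(list(R, S, detector = g, seed = seed),
                                     sparseOpts))
    }, error = function(e) {
      warning("[", g, "] candidate failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(t)) {
      transforms[[length(transforms) + 1]] <- t
      labels <- c(labels, g)
    }
  }
  if (length(transforms) < 2)
    stop("[candidates] fewer than 2 candidate transformations available")
  cs <- candidateSimilarities(R, S, transforms)
  transforms <- transforms[cs$kept]
  labels <- labels[cs$kept]
  bbas <- buildChannelBBAs(cs$ncc, labels)
  mc <- fuseBBAs(bbas$G, bbas$E, bbas$P, rule)
  tc <- combinedTransform(mc, transforms)
  w <- warpImage(S, tc, dim(R))
  new("RegistrationResult", candidates = transforms, labels = labels,
      channelNCC = cs$ncc, bbaG = bbas$G, bbaE = bbas$E, bbaP = bbas$P,
      bbaC = mc, rule = rule, transform = tc, registered = w$image,
      mask = w$mask)
}
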