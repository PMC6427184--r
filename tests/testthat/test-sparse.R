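test_that("detectors run deterministically and respect degenerate inputs", {
  flat <- matrix(0.5, 96, 96)
  for (d in c("harris", "shitomasi", "dog"))
    expect_lte(nrow(detectFeatures(flat, d)$location), 2)

  img <- fixture_image()
  for (d in c("harris", "shitomasi", "dog")) {
    k1 <- detectFeatures(img, d)
    k2 <- detectFeatures(img, d)
    expect_identical(k1$location, k2$location)
    expect_identical(k1$descriptors, k2$descriptors)
    expect_gt(nrow(k1$location), 10)
    # keypoints spread over the frame, not clustered in one quadrant
    v <- k1$location[, 1]; w <- k1$location[, 2]
    expect_gt(length(unique(paste(v > 64, w > 64))), 2)
  }
  expect_error(detectFeatures(img, "sift9000"), "unknown detector")
})

test_that("checkerboard corners are covered by every detector family", {
  cell <- 16L
  base <- outer(0:95, 0:95, function(i, j)
    ifelse((i %/% cell + j %/% cell) %% 2 == 0, 0.25, 0.75))
  set.seed(4)
  img <- pmin(pmax(base + 0.02 * matrix(rnorm(96^2), 96, 96), 0), 1)
  for (d in c("harris", "shitomasi", "dog")) {
    kp <- detectFeatures(img, d)$location
    # interior cell corners at multiples of 16 within the border margin
    corners <- expand.grid(v = seq(16, 80, 16), w = seq(16, 80, 16))
    covered <- mapply(function(cv, cw)
      any((kp[, 1] - cv)^2 + (kp[, 2] - cw)^2 <= 6^2),
      corners$v, corners$w)
    expect_gt(mean(covered), 0.6)
  }
})

test_that("ratio-test matching recovers planted pairs and rejects ties", {
  set.seed(17)
  n <- 60
  loc <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  desc <- loc / 100 + matrix(rnorm(2 * n, 0, 1e-3), n, 2)
  mk <- function(loc, desc) list(location = loc, scale = rep(1, nrow(loc)),
                                 orientation = rep(0, nrow(loc)),
                                 descriptors = desc, metric = "euclidean")
  perm <- sample(n)
  m <- matchFeatures(mk(loc, desc), mk(loc[perm, ], desc[perm, ]), 0.8)
  recovered <- mean(perm[m$senIdx] == m$refIdx)
  expect_gte(recovered, 0.95)
  expect_gte(length(m$refIdx) / n, 0.9)
  # one-to-one: no sensed index repeats
  expect_false(anyDuplicated(m$senIdx) > 0)

  # two equidistant sensed descriptors force a rejection at any ratio < 1
  ref1 <- mk(rbind(c(0, 0)), rbind(c(0.5, 0.5)))
  sen2 <- mk(rbind(c(0, 0), c(1, 1)), rbind(c(0.6, 0.5), c(0.4, 0.5)))
  m2 <- matchFeatures(ref1, sen2, 0.99)
  expect_equal(length(m2$refIdx), 0)
  expect_error(matchFeatures(mk(loc, desc),
                             list(location = loc, descriptors = desc,
                                  metric = "hamming")), "metric")
})

test_that("consensus filtering rejects planted outliers and refits", {
  set.seed(23)
  Tt <- mild_projective()
  mk <- function(loc) list(location = loc, scale = rep(1, nrow(loc)),
                           orientation = rep(0, nrow(loc)),
                           descriptors = matrix(0, nrow(loc), 2),
                           metric = "euclidean")
  n_in <- 28; n_out <- 12
  refp <- cbind(runif(n_in + n_out, 5, 120), runif(n_in + n_out, 5, 120))
  senp <- transformPoints(Tt, refp)
  senp[n_in + seq_len(n_out), ] <- cbind(runif(n_out, 0, 127),
                                         runif(n_out, 0, 127)) # outliers
  matches <- list(refIdx = seq_len(n_in + n_out),
                  senIdx = seq_len(n_in + n_out),
                  distance = rep(0, n_in + n_out),
                  inlier = rep(TRUE, n_in + n_out))
  for (seed in 1:5) {
    rm <- removeMismatches(matches, mk(refp), mk(senp), method = "MSAC",
                           thresholdPx = 2, maxIter = 2000, seed = seed)
    expect_true(rm$ok)
    expect_true(all(which(rm$matches$inlier) <= n_in))
    expect_gte(rm$nInliers, n_in - 1)
    err <- sqrt(rowSums((transformPoints(rm$transform,
                                         refp[seq_len(n_in), ]) -
                         senp[seq_len(n_in), ])^2))
    expect_lt(mean(err), 0.5)
  }
  # determinism for a fixed seed
  r1 <- removeMismatches(matches, mk(refp), mk(senp), seed = 3)
  r2 <- removeMismatches(matches, mk(refp), mk(senp), seed = 3)
  expect_equal(transformMatrix(r1$transform), transformMatrix(r2$transform))
  expect_error(removeMismatches(list(refIdx = 1:3, senIdx = 1:3,
                                     distance = rep(0, 3),
                                     inlier = rep(TRUE, 3)),
                                mk(refp), mk(senp)), "at least 4")
})

test_that("the sparse pipeline self-registers and recovers a known mild
           projective transform", {
  img <- fixture_image()
  for (d in c("harris", "dog")) {
    est <- registerSparse(img, img, d)
    expect_lt(max(abs(transformMatrix(est) - diag(3))), 1e-3)
  }
  Tt <- mild_projective()
  S <- derivePair(img, Tt, 0)
  for (d in c("harris", "shitomasi", "dog")) {
    est <- registerSparse(img, S, d)
    rep <- evaluateRegistration(img, Tt, est)
    expect_lt(reportAAID(rep), 0.02)
  }
})

test_that("under Gaussian noise at least one detector family still
           registers the pair", {
  img <- fixture_image()
  S <- derivePair(img, rigid_true(), 0.01, seed = 5)
  # rigid 10-degree pairs go to the dense mode; for the sparse smoke check
  # use the mild projective design
  Sp <- derivePair(img, mild_projective(), 0.01, seed = 5)
  ok <- 0
  for (d in c("harris", "shitomasi", "dog")) {
    est <- tryCatch(registerSparse(img, Sp, d), error = function(e) NULL)
    if (!is.null(est) &&
        reportAAID(evaluateRegistration(img, mild_projective(), est)) < 0.1)
      ok <- ok + 1
  }
  expect_gte(ok, 1)
})
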