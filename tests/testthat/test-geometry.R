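test_that("point mapping follows the row-vector convention", {
  I <- identityTransform()
  pts <- cbind(c(0, 5, -3), c(0, 2, 7))
  expect_equal(unname(transformPoints(I, pts)[, 1:2]), unname(pts))

  tr <- translationTransform(4, -2)
  expect_equal(unname(transformPoints(tr, c(1, 1))[1, ]), c(5, -1))

  q <- rigidToMatrix(rigidParams(90, 0, 0))
  expect_equal(unname(transformPoints(q, c(1, 0))[1, ]), c(0, 1),
               tolerance = 1e-12)
})

test_that("compose, invert and normalize satisfy the group identities", {
  set.seed(2)
  Tm <- projectiveTransform(rbind(c(1.2, 0.1, 1e-4),
                                  c(-0.2, 0.9, 2e-4),
                                  c(5, -3, 1)))
  expect_equal(transformMatrix(composeTransforms(Tm, invertTransform(Tm))),
               diag(3), tolerance = 1e-9)
  expect_equal(transformMatrix(invertTransform(translationTransform(3, -7))),
               transformMatrix(translationTransform(-3, 7)), tolerance = 1e-12)
  expect_equal(transformMatrix(projectiveTransform(2 * diag(3))), diag(3))
  # composition order: apply T1 then T2 == right-multiply T1 %*% T2
  T2 <- rigidToMatrix(rigidParams(10, 2, -1))
  p <- cbind(runif(5, 0, 50), runif(5, 0, 50))
  expect_equal(transformPoints(composeTransforms(Tm, T2), p),
               transformPoints(T2, transformPoints(Tm, p)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(projectiveTransform(matrix(0, 3, 3)), "singular")
})

test_that("rigid parameter conversion round-trips exactly", {
  p <- rigidParams(0, -10, 5)
  m <- transformMatrix(rigidToMatrix(p))
  expect_equal(m[3, 1:2], c(-10, 5))
  expect_equal(m[1:2, 1:2], diag(2))
  expect_equal(transformMatrix(rigidToMatrix(rigidParams(0, 0, 0))), diag(3))
  for (th in c(-90, -10, 0, 10, 90)) {
    rp <- rigidParams(th, 3.5, -2.25)
    back <- matrixToRigid(rigidToMatrix(rp))
    expect_equal(back@theta, th, tolerance = 1e-10)
    expect_equal(back@tv, 3.5, tolerance = 1e-10)
    expect_equal(back@th, -2.25, tolerance = 1e-10)
  }
  expect_error(rigidParams(200, 0, 0), "-180")
  expect_error(matrixToRigid(projectiveTransform(diag(c(2, 2, 1)))), "scale")
})

test_that("warping is exact on lattice-preserving maps and bounded on
           interpolating round-trips", {
  img <- fixture_image()
  w <- warpImage(img, identityTransform())
  expect_equal(w$image, img)
  expect_equal(w$mask, matrix(1, 128, 128))

  sh <- warpImage(img, translationTransform(3, 2), interpolation = "nearest")
  expect_equal(sh$image[1:120, 1:120], img[3:122, 4:123])
  expect_equal(unique(as.vector(sh$mask[, 126:128])), 0)

  Tt <- rigid_true()
  fwd <- warpImage(img, Tt)$image
  back <- warpImage(fwd, invertTransform(Tt))$image
  interior <- 25:104
  expect_lt(mean(abs(back[interior, interior] - img[interior, interior])),
            0.02)
})

test_that("exact 4-point estimation solves the correspondence system", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)) * 100
  expect_equal(transformMatrix(estimateProjectiveExact(sq, sq)), diag(3),
               tolerance = 1e-9)
  shifted <- sweep(sq, 2, c(7, -3), "+")
  expect_equal(transformMatrix(estimateProjectiveExact(sq, shifted)),
               transformMatrix(translationTransform(7, -3)), tolerance = 1e-9)
  set.seed(11)
  for (rep in 1:10) {
    Tt <- projectiveTransform(rbind(
      c(1 + rnorm(1, 0, 0.2), rnorm(1, 0, 0.2), runif(1, -1e-3, 1e-3)),
      c(rnorm(1, 0, 0.2), 1 + rnorm(1, 0, 0.2), runif(1, -1e-3, 1e-3)),
      c(runif(1, -20, 20), runif(1, -20, 20), 1)))
    pts <- cbind(runif(4, 0, 100), runif(4, 0, 100))
    est <- estimateProjectiveExact(pts, transformPoints(Tt, pts))
    expect_equal(transformMatrix(est), transformMatrix(Tt), tolerance = 1e-8)
  }
  collinear <- rbind(c(0, 0), c(1, 1), c(2, 2), c(5, 0))
  expect_error(estimateProjectiveExact(collinear, collinear), "degenerate")
  expect_error(estimateProjectiveExact(sq[1:3, ], sq[1:3, ]), "exactly 4")
})

test_that("least-squares estimation recovers exactly without noise and
           degrades gracefully with it", {
  set.seed(21)
  Tt <- projectiveTransform(rbind(c(1.05, 0.08, 2e-4),
                                  c(-0.04, 0.98, -1e-4),
                                  c(6, -2, 1)))
  pts4 <- cbind(runif(4, 0, 120), runif(4, 0, 120))
  expect_equal(transformMatrix(estimateProjectiveLS(pts4,
                                                    transformPoints(Tt, pts4))),
               transformMatrix(estimateProjectiveExact(pts4,
                                                       transformPoints(Tt, pts4))),
               tolerance = 1e-8)
  pts <- cbind(runif(20, 0, 120), runif(20, 0, 120))
  sen <- transformPoints(Tt, pts)
  expect_equal(transformMatrix(estimateProjectiveLS(pts, sen)),
               transformMatrix(Tt), tolerance = 1e-6)
  # invariance to a global pixel-coordinate translation of both sets
  est1 <- estimateProjectiveLS(pts, sen)
  est2 <- estimateProjectiveLS(sweep(pts, 2, c(50, 50), "+"),
                               sweep(sen, 2, c(50, 50), "+"))
  p0 <- cbind(runif(6, 0, 120), runif(6, 0, 120))
  expect_equal(transformPoints(est2, p0 + 50) - 50, transformPoints(est1, p0),
               tolerance = 1e-6, ignore_attr = TRUE)
  # Gaussian coordinate noise: mean reprojection error stays near the noise
  errs <- replicate(5, {
    noisy <- sen + matrix(rnorm(40, 0, 0.5), 20, 2)
    est <- estimateProjectiveLS(pts, noisy)
    mean(sqrt(rowSums((transformPoints(est, pts) - sen)^2)))
  })
  expect_lt(mean(errs), 1.5)
})

test_that("transform JSON serialization enforces the convention tag", {
  Tt <- mild_projective()
  js <- transformToJSON(Tt)
  expect_match(js, "row-vector")
  expect_equal(transformMatrix(transformFromJSON(json = js)),
               transformMatrix(Tt), tolerance = 1e-12)
  expect_error(transformFromJSON(json = '{"matrix":[1,0,0,0,1,0,0,0,1]}'),
               "convention")
})
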