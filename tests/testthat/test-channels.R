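test_that("Canny edge channel is binary, empty on constant images, and
           localizes a step edge", {
  flat <- matrix(0.5, 64, 64)
  expect_equal(edgeChannel(flat), matrix(0, 64, 64))

  step <- cbind(matrix(0.2, 64, 32), matrix(0.8, 64, 32))
  e <- edgeChannel(step)
  expect_true(all(e %in% c(0, 1)))
  # a connected vertical line near the step, nothing far from it
  marked_cols <- which(colSums(e) > 0)
  expect_true(all(abs(marked_cols - 32.5) <= 4))
  expect_gte(sum(e[, 30:35]), 50)  # near-full-height line
  expect_equal(sum(e[, c(1:24, 41:64)]), 0)

  img <- fixture_image()
  e2 <- edgeChannel(img)
  expect_true(all(e2 %in% c(0, 1)))
  expect_gt(sum(e2), 0)
  expect_error(edgeChannel(img, lowFrac = 0.3, highFrac = 0.2), "lowFrac")
})

test_that("phase channel keeps structure, discards contrast, and commutes
           with cyclic translation", {
  img <- fixture_image()
  ph <- phaseChannel(img)
  expect_equal(dim(ph), dim(img))
  expect_true(all(ph >= 0 & ph <= 1))

  # Fourier shift theorem: a cyclic shift of the input shifts the output
  sh <- img[c(11:128, 1:10), ]
  ph_sh <- phaseChannel(sh)
  expect_gt(ncc(ph_sh, ph[c(11:128, 1:10), ]), 0.999)

  # positive affine intensity change barely affects the reconstruction
  ph2 <- phaseChannel(0.5 * img + 0.2)
  expect_gte(ncc(ph, ph2), 0.99)

  expect_equal(phaseChannel(matrix(0.7, 32, 32)), matrix(0, 32, 32))
})

test_that("NCC is the Pearson correlation with the constant-image
           convention", {
  img <- fixture_image()
  expect_equal(ncc(img, img), 1, tolerance = 1e-12)
  expect_equal(ncc(img, 1 - img), -1, tolerance = 1e-12)
  expect_equal(ncc(img, matrix(0.3, 128, 128)), 0)
  # affine intensity rescaling invariance (positive gain)
  expect_equal(ncc(img, 0.25 * img + 0.1), 1, tolerance = 1e-9)
  # independent white noise decorrelates at n = 256^2
  set.seed(31)
  A <- matrix(runif(256^2), 256, 256)
  B <- matrix(runif(256^2), 256, 256)
  expect_lt(abs(ncc(A, B)), 0.05)
  expect_equal(ncc(A, B), ncc(B, A))
  expect_error(ncc(A, matrix(0, 8, 8)), "identical dimensions")
})

test_that("mutual information matches closed-form entropies", {
  flat <- matrix(0.5, 64, 64)
  img <- fixture_image(size = c(64, 64), seed = 3)
  expect_equal(mutualInformation(flat, img), 0)
  # binary checkerboard: MI(A, A) = H(A) = 1 bit
  A <- outer(1:64, 1:64, function(i, j) (i + j) %% 2)
  expect_equal(mutualInformation(A, A), 1)
  # symmetry and the upper entropy bound
  set.seed(5)
  B <- matrix(runif(64^2), 64, 64)
  expect_equal(mutualInformation(img, B), mutualInformation(B, img))
  hA <- mutualInformation(img, img)  # self-MI equals histogram entropy
  expect_lte(mutualInformation(img, B), hA + 1e-9)
  expect_gte(mutualInformation(img, B), 0)
})

test_that("PSNR matches closed forms and orders degradations", {
  expect_equal(psnr(matrix(0, 16, 16), matrix(1, 16, 16)), 0)
  img <- fixture_image()
  expect_equal(psnr(img, img), Inf)
  A <- matrix(0.2, 32, 32)
  expect_equal(psnr(A, A + 0.5), 10 * log10(1 / 0.25), tolerance = 1e-12)
  expect_equal(psnr(A, A + 0.5), 6.0206, tolerance = 1e-4)
})

test_that("all three measures peak at the identical image within a
           perturbation family", {
  img <- fixture_image(size = c(96, 96), seed = 12)
  set.seed(8)
  for (eps in c(0.02, 0.05, 0.1)) {
    pert <- pmin(pmax(img + matrix(rnorm(96^2, 0, eps), 96, 96), 0), 1)
    expect_lt(ncc(img, pert), 1)
    expect_lt(mutualInformation(img, pert), mutualInformation(img, img))
    expect_lt(psnr(img, pert), Inf)
  }
})
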