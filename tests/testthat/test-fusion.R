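test_that("candidate similarities separate correct from wrong
           transformations on the three channels", {
  img <- fixture_image()
  Tt <- rigid_true()
  S <- derivePair(img, Tt, 0)
  wrong <- translationTransform(50, 0)
  cs <- candidateSimilarities(img, S, list(Tt, wrong))
  expect_equal(cs$kept, 1:2)
  expect_gte(cs$ncc[1, "G"], 0.9)
  expect_lt(cs$ncc[2, "G"], 0.5)
  expect_gt(cs$ncc[1, "G"], cs$ncc[2, "G"])
  expect_gt(cs$ncc[1, "E"], cs$ncc[2, "E"])
  expect_gt(cs$ncc[1, "P"], cs$ncc[2, "P"])
  expect_error(candidateSimilarities(img, S, list(Tt)), "at least 2")
})

test_that("an edge-free smooth fixture triggers the zero-evidence
           convention on the edge channel", {
  ramp <- matrix(seq(0, 1, length.out = 96), 96, 96)
  expect_equal(sum(edgeChannel(ramp)), 0)
  S <- derivePair(ramp, translationTransform(2, 0), 0)
  cs <- candidateSimilarities(ramp, S,
                              list(translationTransform(2, 0),
                                   translationTransform(4, 0)))
  expect_equal(unname(cs$ncc[, "E"]), c(0, 0))
  expect_warning(buildChannelBBAs(cs$ncc), "zero-evidence")
})

test_that("the exponential stretch produces the documented masses", {
  b <- buildChannelBBAs(cbind(c(0.5, 0.3, 0.9), c(0.5, 0.3, 0.9),
                              c(0.5, 0.3, 0.9)))
  expect_equal(round(unname(massValues(b$G)[c("T1", "T2", "T3")]), 5),
               c(0.26390, 0.14232, 0.59377))
  expect_true(isBayesian(b$G))
  expect_equal(sum(b$G@masses), 1, tolerance = 1e-12)
  # symmetry at equal similarity
  b2 <- buildChannelBBAs(cbind(c(0.4, 0.4), c(0.4, 0.4), c(0.4, 0.4)))
  expect_equal(unname(massValues(b2$E)), c(0.5, 0.5))
  # negative values clamp to zero evidence
  b3 <- buildChannelBBAs(cbind(c(0.8, -0.2), c(0.8, -0.2), c(0.8, -0.2)))
  expect_equal(unname(massValues(b3$P)["T1"]), 1)
  expect_equal(massOf(b3$P, "T2"), 0)
})

test_that("channel fusion follows the chosen combination rule", {
  fod <- frameOfDiscernment(c("a", "b"))
  one <- makeBBA(fod, c(a = 1))
  expect_equal(massOf(fuseBBAs(one, one, one, "dempster"), "a"), 1)
  expect_equal(massOf(fuseBBAs(one, one, one, "pcr6"), "a"), 1)

  mG <- makeBBA(fod, c(a = 0.6, b = 0.4))
  mE <- makeBBA(fod, c(a = 0.7, b = 0.3))
  mP <- makeBBA(fod, c(a = 0.5, b = 0.5))
  d <- fuseBBAs(mG, mE, mP, "dempster")
  # Bayesian Dempster = normalized product of singleton masses
  expect_equal(massOf(d, "a"), 0.21 / 0.27, tolerance = 1e-9)
  expect_equal(massOf(d, "a"), 0.7778, tolerance = 1e-4)
  p <- fuseBBAs(mG, mE, mP, "pcr6")
  expect_equal(sum(p@masses), 1, tolerance = 1e-9)
  expect_gt(massOf(p, "a"), massOf(p, "b"))
  # n-source PCR6 oracle cross-check
  expect_bba_matches_table(p, oracle_pcr6(list(bba_to_table(mG),
                                               bba_to_table(mE),
                                               bba_to_table(mP))))
  expect_error(fuseBBAs(makeBBA(fod, c(a = 1)), makeBBA(fod, c(b = 1)),
                        makeBBA(fod, c(a = 1)), "dempster"), "pcr6")
})

test_that("the combined transformation averages inverses by mass", {
  fod <- frameOfDiscernment(c("T1", "T2"))
  t1 <- translationTransform(2, 0)
  t2 <- translationTransform(4, 0)
  mc <- makeBBA(fod, c(T1 = 0.5, T2 = 0.5))
  tc <- combinedTransform(mc, list(t1, t2))
  expect_equal(transformMatrix(tc),
               transformMatrix(translationTransform(3, 0)), tolerance = 1e-12)
  # one-hot masses return the selected candidate exactly
  hot <- makeBBA(fod, c(T2 = 1))
  expect_equal(transformMatrix(combinedTransform(hot, list(t1, t2))),
               transformMatrix(t2), tolerance = 1e-12)
  # identical candidates are a fixed point for any masses
  mcu <- makeBBA(fod, c(T1 = 0.3, T2 = 0.7))
  expect_equal(transformMatrix(combinedTransform(mcu, list(t1, t1))),
               transformMatrix(t1), tolerance = 1e-12)
  # non-Bayesian masses are rejected
  nb <- makeBBA(fod, c(T1 = 0.5, "T1|T2" = 0.5))
  expect_error(combinedTransform(nb, list(t1, t2)), "Bayesian")
})

test_that("the combined transformation is equivariant under candidate
           relabeling and stays in the inverse-matrix hull", {
  set.seed(77)
  fod3 <- frameOfDiscernment(c("T1", "T2", "T3"))
  for (rep in 1:10) {
    ts <- lapply(1:3, function(i) {
      m <- rigidToMatrix(rigidParams(runif(1, -10, 10), runif(1, -5, 5),
                                     runif(1, -5, 5)))@matrix
      m[1, 3] <- runif(1, -2e-4, 2e-4)
      projectiveTransform(m)
    })
    w <- rgamma(3, 1) + 0.05; w <- w / sum(w)
    mc <- makeBBA(fod3, setNames(w, c("T1", "T2", "T3")))
    tc <- combinedTransform(mc, ts)
    perm <- sample(3)
    mcp <- makeBBA(fod3, setNames(w[perm], c("T1", "T2", "T3")))
    tcp <- combinedTransform(mcp, ts[perm])
    expect_equal(transformMatrix(tcp), transformMatrix(tc), tolerance = 1e-9)
    inv <- sapply(ts, function(t) transformMatrix(invertTransform(t)))
    tci <- as.vector(transformMatrix(invertTransform(tc)))
    expect_true(all(tci >= apply(inv, 1, min) - 1e-9))
    expect_true(all(tci <= apply(inv, 1, max) + 1e-9))
  }
})

test_that("the fused registration pipeline produces consistent results
           under both rules on an easy pair", {
  img <- fixture_image(size = c(96, 96), seed = 20)
  Tt <- rigidToMatrix(rigidParams(4, -3, 2))
  S <- derivePair(img, Tt, 0)
  cfg <- denseSearchConfig(c(-8, 8), c(-8, 8), 2, 2)
  rd <- registerFused(img, S, mode = "dense", rule = "dempster", search = cfg)
  rp <- registerFused(img, S, mode = "dense", rule = "pcr6", search = cfg)
  expect_s4_class(rd, "RegistrationResult")
  expect_equal(sum(massValues(fusedBBA(rd))), 1, tolerance = 1e-9)
  expect_true(isBayesian(fusedBBA(rd)))
  ad <- reportAAID(evaluateRegistration(img, Tt, fusedTransform(rd)))
  ap <- reportAAID(evaluateRegistration(img, Tt, fusedTransform(rp)))
  expect_lt(ad, 0.03)
  expect_lt(ap, 0.03)
  expect_lt(abs(ad - ap) / max(ad, ap), 0.2)
  expect_equal(dim(registeredImage(rd)), dim(img))
  expect_named(candidateTransforms(rd))
})
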