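test_that("BBA construction validates the mass axioms and stores exactly", {
  fod <- frameOfDiscernment(c("T1", "T2", "T3"))
  b <- makeBBA(fod, c(T1 = 0.3, T2 = 0.3, T3 = 0.4))
  expect_true(isBayesian(b))
  expect_equal(unname(massValues(b)[c("T1", "T2", "T3")]), c(0.3, 0.3, 0.4))

  fod2 <- frameOfDiscernment(c("T1", "T2"))
  v <- makeBBA(fod2, c("T1|T2" = 1.0))
  expect_false(isBayesian(v))
  expect_equal(massOf(v, c("T1", "T2")), 1)

  expect_error(makeBBA(fod2, c(T1 = 0.6, T2 = 0.6)), "sum")
  expect_error(makeBBA(fod2, c(T1 = -0.1, T2 = 1.1)), "nonnegative")
  expect_error(makeBBA(fod2, c(T1 = 0.5, T9 = 0.5)), "not in the frame")
  expect_error(frameOfDiscernment("only_one"), "at least 2")
  expect_error(frameOfDiscernment(c("a", "a")), "distinct")
})

test_that("belief and plausibility enumerate focal elements correctly", {
  fod <- frameOfDiscernment(c("a", "b", "c"))
  m <- makeBBA(fod, c(a = 0.5, "a|b" = 0.3, "a|b|c" = 0.2))
  expect_equal(belief(m, c("a", "b", "c")), 1)
  expect_equal(plausibility(m, c("a", "b", "c")), 1)
  expect_equal(belief(m, c("a", "b")), 0.8)
  expect_equal(belief(m, "c"), 0)
  expect_equal(plausibility(m, "b"), 0.5)
  # Bayesian: Pl = Bel = m on singletons
  bb <- makeBBA(fod, c(a = 0.2, b = 0.3, c = 0.5))
  for (el in c("a", "b", "c")) {
    expect_equal(plausibility(bb, el), belief(bb, el))
    expect_equal(belief(bb, el), massOf(bb, el))
  }
  expect_error(belief(m, "z"), "not in the frame")
})

test_that("conjunctive rule produces the worked conflict decomposition", {
  fod <- frameOfDiscernment(c("a", "b"))
  m1 <- makeBBA(fod, c(a = 0.6, b = 0.4))
  m2 <- makeBBA(fod, c(a = 0.7, b = 0.3))
  conj <- combineConjunctive(m1, m2)
  expect_equal(massOf(conj, "a"), 0.42)
  expect_equal(massOf(conj, "b"), 0.12)
  expect_equal(conflictMass(conj), 0.46)
  expect_equal(sum(conj@masses), 1)
  # vacuous neutral element
  v <- vacuousBBA(fod)
  cv <- combineConjunctive(v, m2)
  expect_equal(massOf(cv, "a"), 0.7)
  expect_equal(conflictMass(cv), 0)
  cvv <- combineConjunctive(v, v)
  expect_equal(massOf(cvv, c("a", "b")), 1)
})

test_that("Dempster's rule normalizes conflict and fails at total conflict", {
  fod <- frameOfDiscernment(c("a", "b"))
  m1 <- makeBBA(fod, c(a = 0.6, b = 0.4))
  m2 <- makeBBA(fod, c(a = 0.7, b = 0.3))
  d <- combineDempster(m1, m2)
  expect_equal(massOf(d, "a"), 0.42 / 0.54, tolerance = 1e-12)
  expect_equal(massOf(d, "b"), 0.12 / 0.54, tolerance = 1e-12)
  expect_equal(massOf(combineDempster(vacuousBBA(fod), m2), "a"), 0.7)
  expect_error(combineDempster(makeBBA(fod, c(a = 1)),
                               makeBBA(fod, c(b = 1))), "conflict")
  fod3 <- frameOfDiscernment(c("a", "b", "x"))
  expect_error(combineDempster(m1, makeBBA(fod3, c(a = 1))), "same frame")
})

test_that("PCR6 reproduces hand-computed redistributions", {
  fod <- frameOfDiscernment(c("a", "b"))
  m1 <- makeBBA(fod, c(a = 0.6, b = 0.4))
  m2 <- makeBBA(fod, c(a = 0.7, b = 0.3))
  p <- combinePCR6(list(m1, m2))
  # a: 0.42 + 0.6^2*0.3/0.9 + 0.7^2*0.4/1.1 ; b: the complement
  expect_equal(massOf(p, "a"), 0.42 + 0.36 * 0.3 / 0.9 + 0.49 * 0.4 / 1.1,
               tolerance = 1e-12)
  expect_equal(massOf(p, "a"), 0.71818, tolerance = 1e-5)
  expect_equal(massOf(p, "b"), 0.28182, tolerance = 1e-5)
  # total conflict splits evenly
  p2 <- combinePCR6(list(makeBBA(fod, c(a = 1)), makeBBA(fod, c(b = 1))))
  expect_equal(massOf(p2, "a"), 0.5)
  expect_equal(massOf(p2, "b"), 0.5)
  # conflict-free pair equals the conjunctive result
  u1 <- makeBBA(fod, c(a = 1))
  expect_equal(massOf(combinePCR6(list(u1, u1)), "a"), 1)
  expect_error(combinePCR6(list(m1)), "at least two")
})

test_that("combination rules agree with brute-force oracles on random BBAs", {
  set.seed(421)
  for (rep in 1:60) {
    q <- sample(2:4, 1)
    fod <- frameOfDiscernment(paste0("T", seq_len(q)))
    m1 <- random_bba(fod)
    m2 <- random_bba(fod)
    t1 <- bba_to_table(m1); t2 <- bba_to_table(m2)
    expect_bba_matches_table(combineConjunctive(m1, m2),
                             oracle_conjunctive(t1, t2))
    K <- table_lookup(oracle_conjunctive(t1, t2), character(0))
    if (K < 1 - 1e-6) {
      d12 <- combineDempster(m1, m2)
      expect_bba_matches_table(d12, oracle_dempster(t1, t2))
      # commutativity
      d21 <- combineDempster(m2, m1)
      expect_equal(massValues(d12), massValues(d21), tolerance = 1e-12)
      # associativity with a third source
      m3 <- random_bba(fod)
      lhs <- tryCatch(combineDempster(combineDempster(m1, m2), m3),
                      error = function(e) NULL)
      rhs <- tryCatch(combineDempster(m1, combineDempster(m2, m3)),
                      error = function(e) NULL)
      if (!is.null(lhs) && !is.null(rhs))
        expect_equal(massValues(lhs), massValues(rhs), tolerance = 1e-9)
    }
    p12 <- combinePCR6(list(m1, m2))
    expect_bba_matches_table(p12, oracle_pcr6(list(t1, t2)))
    expect_equal(massValues(p12), massValues(combinePCR6(list(m2, m1))),
                 tolerance = 1e-12)
    expect_equal(sum(p12@masses), 1, tolerance = 1e-9)
  }
})

test_that("Bayesian inputs stay Bayesian through every rule", {
  set.seed(99)
  for (rep in 1:20) {
    fod <- frameOfDiscernment(paste0("T", 1:3))
    m1 <- random_bba(fod, bayesian = TRUE)
    m2 <- random_bba(fod, bayesian = TRUE)
    expect_true(isBayesian(combineDempster(m1, m2)))
    expect_true(isBayesian(combinePCR6(list(m1, m2))))
    # Pl >= Bel on arbitrary subsets of a general BBA
    m <- random_bba(fod)
    for (A in list("T1", c("T1", "T3"), c("T2", "T3")))
      expect_gte(plausibility(m, A) - belief(m, A), -1e-12)
  }
})

test_that("pignistic transform splits compound masses evenly", {
  fod <- frameOfDiscernment(c("a", "b", "c"))
  m <- makeBBA(fod, c(a = 0.5, "a|b" = 0.3, "a|b|c" = 0.2))
  bp <- pignistic(m)
  expect_equal(unname(bp), c(0.5 + 0.15 + 0.2 / 3, 0.15 + 0.2 / 3, 0.2 / 3),
               tolerance = 1e-12)
  expect_equal(sum(bp), 1)
  # Bayesian fixed point and vacuous uniformity
  bb <- makeBBA(fod, c(a = 0.2, b = 0.3, c = 0.5))
  expect_equal(unname(pignistic(bb)), c(0.2, 0.3, 0.5))
  expect_equal(unname(pignistic(vacuousBBA(fod))), rep(1 / 3, 3))
})

test_that("BBA JSON serialization round-trips with pipe-joined keys", {
  fod <- frameOfDiscernment(c("T1", "T2", "T3"))
  m <- makeBBA(fod, c(T1 = 0.25, "T1|T3" = 0.5, "T1|T2|T3" = 0.25))
  js <- bbaToJSON(m)
  expect_match(js, "T1\\|T3")
  m2 <- bbaFromJSON(json = js)
  expect_equal(massValues(m2), massValues(m))
  expect_equal(frameElements(m2), frameElements(m))
})
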