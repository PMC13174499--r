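test_that("a pass-through chain carries the tracer pattern unchanged", {
  res <- solveSteadyState(testNet, passThroughLactateConfig(),
                          tracerSpec("glucose", "U", enrichment = 1))
  expect_true(converged(res))
  expect_equal(mids(res)$lactate, c(0, 0, 0, 1), tolerance = 1e-9)
})

test_that("aKGDH releases the [1-13C]glutamine label before succinate", {
  res <- solveSteadyState(testNet, oxidativeOnlyConfig(),
                          tracerSpec("glutamine", 1, enrichment = 1))
  m <- mids(res)$succinate
  expect_equal(m[1], 1, tolerance = 1e-9)
  expect_equal(m[2], 0, tolerance = 1e-12)
})

test_that("fully reductive glutamine carboxylation yields M5 citrate, M2 acetyl and M3 OAA", {
  res <- solveSteadyState(testNet, reductiveOnlyConfig(),
                          tracerSpec("glutamine", "U", enrichment = 1))
  m <- mids(res)
  expect_equal(m$citrate[6], 1, tolerance = 1e-9)
  expect_equal(m$acetylCoA_chromatin[3], 1, tolerance = 1e-9)
  expect_equal(m$oxaloacetate[4], 1, tolerance = 1e-9)
})

test_that("collapseToMid counts labeled carbons", {
  # all mass on pattern (1,1,0) of a 3-carbon pool
  iso <- numeric(8); iso[4] <- 1
  expect_equal(collapseToMid(iso), c(0, 0, 1, 0))
  # uniform over the 4 patterns of a 2-carbon pool: binomial shape
  expect_equal(collapseToMid(rep(0.25, 4)), c(0.25, 0.5, 0.25))
  set.seed(2)
  x <- randomSimplex(16)
  expect_equal(sum(collapseToMid(x)), 1, tolerance = 1e-12)
})

test_that("every steady-state MID is simplex-valued", {
  for (preset in c("ESC", "E6.5_EPI")) {
    res <- solveSteadyState(testNet, conditionPreset(preset),
                            testTracers$gln_u13)
    expect_true(converged(res))
    for (m in mids(res)) {
      expect_true(all(m >= -1e-12))
      expect_equal(sum(m), 1, tolerance = 1e-9)
    }
  }
})

test_that("the fixed point does not depend on the initial state", {
  cfg <- conditionPreset("EpiLC_d2")
  tol <- 1e-12
  a <- solveSteadyState(testNet, cfg, testTracers$glc_u13, tol = tol,
                        init = "unlabeled")
  b <- solveSteadyState(testNet, cfg, testTracers$glc_u13, tol = tol,
                        init = "labeled")
  dev <- max(mapply(function(x, y) max(abs(x - y)),
                    isotopomers(a), isotopomers(b)))
  expect_lt(dev, 10 * tol)
})

test_that("tracer purity acts linearly on a pass-through pool", {
  cfg <- passThroughLactateConfig()
  p <- 0.7
  mPure <- mids(solveSteadyState(testNet, cfg,
                                 tracerSpec("glucose", "U",
                                            enrichment = 1)))$lactate
  mNone <- mids(solveSteadyState(testNet, allUnlabeledConfig(),
                                 testTracers$glc_u13))$lactate
  mMix <- mids(solveSteadyState(testNet, cfg,
                                tracerSpec("glucose", "U",
                                           enrichment = p)))$lactate
  expect_equal(mMix, p * mPure + (1 - p) * mNone, tolerance = 1e-9)
})

test_that("symmetric pools are invariant under their two-fold rotation", {
  res <- solveSteadyState(testNet, conditionPreset("EpiLC_d1"),
                          testTracers$gln_u13)
  for (pool in c("succinate", "fumarate")) {
    iso <- isotopomers(res)[[pool]]
    perm <- symmetryPermutation(testNet, pool)
    lut <- midflux:::.permLUT(perm)
    expect_equal(iso, iso[lut], tolerance = 1e-12)
  }
})

test_that("a cycle with no labeled entry stays unlabeled", {
  res <- solveSteadyState(testNet, allUnlabeledConfig(),
                          testTracers$gln_u13)
  for (m in mids(res)) expect_equal(m[1], 1, tolerance = 1e-12)
})

test_that("non-convergence is flagged, not thrown", {
  res <- solveSteadyState(testNet, conditionPreset("ESC"),
                          testTracers$gln_u13, maxIter = 3L)
  expect_false(converged(res))
  expect_gt(res@residual, 1e-12)
})

test_that("tidy MID tables round-trip through CSV with schema validation", {
  res <- solveSteadyState(testNet, conditionPreset("ESC"),
                          testTracers$glc_u13)
  tab <- asTidyMid(res, sample_id = "s1", condition = "ESC",
                   tracer = "glc_u13")
  expect_silent(validateMidTable(tab, net = testNet))
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeMidTable(tab, tmp)
  tab2 <- readMidTable(tmp, net = testNet)
  expect_equal(tab2$value, tab$value, tolerance = 1e-12)
  bad <- tab
  bad$value[1] <- bad$value[1] + 0.5
  expect_error(validateMidTable(bad), "sum to 1")
})
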