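test_that("default network has the expected pools, carbon counts and symmetries", {
  nc <- nCarbons(testNet)
  expected <- c(pyruvate = 3, lactate = 3, alanine = 3, acetylCoA_mito = 2,
                acetylCoA_chromatin = 2, citrate = 6, aKG = 5,
                glutamate = 5, glutamine = 5, succinate = 4, fumarate = 4,
                malate = 4, oxaloacetate = 4, aspartate = 4, CO2 = 1)
  expect_true(all(names(expected) %in% names(nc)))
  expect_equal(nc[names(expected)], expected,
               ignore_attr = FALSE, tolerance = 0)
  expect_equal(symmetryPermutation(testNet, "succinate"), 4:1)
  expect_equal(symmetryPermutation(testNet, "fumarate"), 4:1)
  expect_equal(symmetryPermutation(testNet, "citrate"), 1:6)
})

test_that("the default network passes carbon balance and all carbon-fate constraints", {
  rep <- validateNetwork(testNet)
  expect_true(all(rep$reactions$pass))
  expect_true(all(rep$symmetry$pass))
  expect_equal(rep$constraints$pass, rep(TRUE, 8))
  expect_true(rep$pass)
})

test_that("ACLY inverts citrate synthase on labeling patterns", {
  set.seed(11)
  for (i in 1:20) {
    ac <- sample(c(TRUE, FALSE), 2, replace = TRUE)
    oaa <- sample(c(TRUE, FALSE), 4, replace = TRUE)
    cit <- applyAtomMap(testNet, "cs",
                        list(acetylCoA_mito = ac, oxaloacetate = oaa),
                        "citrate")
    expect_equal(applyAtomMap(testNet, "acly", list(citrate = cit),
                              "acetylCoA_chromatin"), ac)
    expect_equal(applyAtomMap(testNet, "acly", list(citrate = cit),
                              "oxaloacetate"), oaa)
  }
})

test_that("atom-map defects are reported per reaction, not thrown", {
  # PDH releasing C2 instead of C1 breaks the [1-13C]pyruvate logic (C3)
  bad <- testNet
  m <- bad@reactions$pdh$map
  m$prod[m$sub_carbon == 1] <- "acetylCoA_mito"
  m$prod_carbon[m$sub_carbon == 1] <- 1L
  m$prod[m$sub_carbon == 2] <- "CO2"
  m$prod_carbon[m$sub_carbon == 2] <- 1L
  bad@reactions$pdh$map <- m
  rep <- validateNetwork(bad)
  expect_false(rep$constraints$pass[rep$constraints$constraint == "C3"])
  expect_false(rep$pass)

  # dropping one carbon from the map is a carbon-balance failure
  bad2 <- testNet
  bad2@reactions$ldh$map <- bad2@reactions$ldh$map[-1, ]
  rep2 <- validateNetwork(bad2)
  expect_false(rep2$reactions$pass[rep2$reactions$reaction == "ldh"])
  expect_false(rep2$pass)
  expect_s3_class(rep2$reactions, "data.frame")
})

test_that("knockdown at zero efficiency is the identity", {
  cfg <- defaultFluxConfig()
  kd <- applyKnockdown(cfg, c("pc", "malic_enzyme"), 0)
  expect_equal(sourceFractions(kd), sourceFractions(cfg))
})

test_that("full knockdown renormalizes the remaining sources proportionally", {
  cfg <- defaultFluxConfig()
  cfg@fractions$oxaloacetate <- c(pc = 0.4, mdh_from_malate = 0.5,
                                  acly_oaa_arm = 0.1)
  kd <- applyKnockdown(cfg, "pc", 1)
  expect_equal(unname(sourceFractions(kd)$oxaloacetate),
               c(0, 5 / 6, 1 / 6), tolerance = 1e-12)
})

test_that("knockdown validates inputs and preserves simplex structure", {
  cfg <- defaultFluxConfig()
  expect_error(applyKnockdown(cfg, "not_a_source", 0.5), "not_a_source")
  expect_error(applyKnockdown(cfg, "pc", 1.5), "efficiency")
  set.seed(4)
  for (eff in c(0.1, 0.5, 0.9)) {
    kd <- applyKnockdown(cfg, c("pc", "malic_enzyme"), eff)
    for (f in sourceFractions(kd)) {
      expect_true(all(f >= 0))
      expect_equal(sum(f), 1, tolerance = 1e-9)
    }
  }
  expect_equal(knockdownTargets(c("Pcx", "Me1", "Me2")),
               c("pc", "malic_enzyme"))
  expect_error(knockdownTargets("Idh1"), "Idh1")
})

test_that("network and flux config survive a JSON round trip", {
  tmp <- withr::local_tempfile(fileext = ".json")
  writeCarbonNetwork(testNet, tmp)
  net2 <- readCarbonNetwork(tmp)
  expect_true(validateNetwork(net2)$pass)
  expect_equal(nCarbons(net2), nCarbons(testNet))
  expect_equal(names(net2@reactions), names(testNet@reactions))

  tmp2 <- withr::local_tempfile(fileext = ".json")
  cfg <- conditionPreset("EpiLC_d1")
  writeFluxConfig(cfg, tmp2)
  cfg2 <- readFluxConfig(tmp2)
  expect_equal(sourceFractions(cfg2), sourceFractions(cfg),
               tolerance = 1e-12)
  expect_equal(cfg2@tracerPurity, cfg@tracerPurity)
})
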