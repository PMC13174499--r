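test_that("preset registry covers the study conditions and knockdowns", {
  expect_setequal(listPresets(),
                  c("ESC", "EpiLC_d1", "EpiLC_d2", "EpiLC_d3", "EpiSC",
                    "E3.5_ICM", "E3.5_TE", "E6.5_EPI", "E6.5_EC",
                    "Neg", "Pcx_KD", "Me1_KD", "Me2_KD", "TripleKD"))
  expect_error(conditionPreset("nope"), "unknown preset")
  # knockdown presets are exactly apply_knockdown of Neg at efficiency 0.9
  neg <- conditionPreset("Neg")
  expect_equal(sourceFractions(conditionPreset("TripleKD")),
               sourceFractions(applyKnockdown(neg, c("pc", "malic_enzyme"),
                                              0.9)))
  expect_equal(sourceFractions(conditionPreset("Pcx_KD")),
               sourceFractions(applyKnockdown(neg, "pc", 0.9)))
})

test_that("preset ordering contract holds under noise-free simulation", {
  akgGln <- function(p) sourceFractions(conditionPreset(p))$aKG[["glutamine"]]
  expect_gt(akgGln("EpiLC_d1"), akgGln("ESC"))
  pcOf <- function(p) sourceFractions(conditionPreset(p))$oxaloacetate[["pc"]]
  stems <- c("ESC", "EpiLC_d1", "EpiLC_d2", "EpiLC_d3", "EpiSC")
  expect_equal(names(which.max(vapply(stems, pcOf, numeric(1)))),
               "EpiLC_d1")
  for (p in listPresets())
    expect_gt(sourceFractions(conditionPreset(p))$citrate[["idh1_reductive"]],
              0)
  # second-turn ratio: post-implantation EPI below blastocyst ICM
  str <- function(p) {
    tab <- asTidyMid(solveSteadyState(testNet, conditionPreset(p),
                                      testTracers$gln_u13))
    secondTurnRatio(tab, "glutamate")$value
  }
  expect_lt(str("E6.5_EPI"), str("E3.5_ICM"))
})

test_that("chromatin acetyl sourcing: glutamine beats glucose with a growing gap", {
  stems <- c("ESC", "EpiLC_d1", "EpiLC_d2", "EpiLC_d3", "EpiSC")
  gap <- vapply(stems, function(p) {
    cfg <- conditionPreset(p)
    q <- mids(solveSteadyState(testNet, cfg,
                               testTracers$gln_u13))$acetylCoA_chromatin[3]
    g <- mids(solveSteadyState(testNet, cfg,
                               testTracers$glc_u13))$acetylCoA_chromatin[3]
    expect_gt(q, g)
    q - g
  }, numeric(1))
  expect_true(all(diff(gap) > 0))
})

test_that("MID generation is deterministic and schema-valid", {
  a <- generateMidDataset("ESC", tracers = "gln_u13", nReplicates = 3,
                          pools = c("aKG", "citrate"), seed = 13)
  b <- generateMidDataset("ESC", tracers = "gln_u13", nReplicates = 3,
                          pools = c("aKG", "citrate"), seed = 13)
  expect_identical(a, b)
  expect_silent(validateMidTable(a, net = testNet))
  expect_equal(length(unique(a$sample_id)), 3)
  expect_error(generateMidDataset("nope", seed = 1), "unknown preset")
})

test_that("infinite concentration is the exact mode", {
  exact <- generateMidDataset("ESC", tracers = "gln_u13", nReplicates = 2,
                              concentration = Inf, pools = "aKG", seed = 1)
  truth <- convolveNA(
    mids(solveSteadyState(testNet, conditionPreset("ESC"),
                          testTracers$gln_u13))$aKG,
    buildCorrectionMatrix(5, 0.0107))
  for (d in split(exact, exact$sample_id))
    expect_equal(d$value[order(d$mass_shift)], truth, tolerance = 1e-12)
})

test_that("Dirichlet replicate noise stays on the simplex and scales with concentration", {
  tab <- generateMidDataset("EpiLC_d1", tracers = "gln_u13",
                            nReplicates = 6, concentration = 500,
                            pools = "aKG", seed = 3)
  sums <- tapply(tab$value, tab$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(tab$value >= 0))
  spread <- function(conc) {
    t2 <- generateMidDataset("EpiLC_d1", tracers = "gln_u13",
                             nReplicates = 6, concentration = conc,
                             pools = "aKG", seed = 5)
    stats::sd(t2$value[t2$mass_shift == 5])
  }
  expect_gt(spread(50), spread(5000))
})

test_that("embryo and histone generators are deterministic given a seed", {
  e1 <- generateEmbryoDataset("E3.5", nEmbryos = 1, pools = "citrate",
                              seed = 9)
  e2 <- generateEmbryoDataset("E3.5", nEmbryos = 1, pools = "citrate",
                              seed = 9)
  expect_identical(e1, e2)
  h1 <- generateHistoneDataset("ESC", nReplicates = 2, seed = 9)
  h2 <- generateHistoneDataset("ESC", nReplicates = 2, seed = 9)
  expect_identical(h1, h2)
  expect_true(all(h1$auc >= 0))
})
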