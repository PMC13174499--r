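.midRow <- function(sample, pool, mid, tracer = "glc_u13") {
  data.frame(sample_id = sample, condition = "c", tracer = tracer,
             pool = pool, mass_shift = seq_along(mid) - 1L, value = mid,
             value_kind = "fraction", stringsAsFactors = FALSE)
}

test_that("fractional labeling extracts the requested isotopologue per sample", {
  tab <- rbind(.midRow("s1", "lactate", c(0.2, 0, 0, 0.8)),
               .midRow("s2", "lactate", c(1, 0, 0, 0)))
  out <- fractionalLabeling(tab, "lactate", 3)
  expect_equal(out$value[match(c("s1", "s2"), out$sample_id)], c(0.8, 0))
  expect_equal(fractionalLabeling(tab, "lactate", 0)$value[
    out$sample_id == "s2"], 1)
  expect_error(fractionalLabeling(tab, "lactate", 4), "out of range")
  expect_error(fractionalLabeling(tab, "citrate", 2), "citrate")
})

test_that("normalized fractions divide per sample and flag zero denominators", {
  tab <- rbind(.midRow("s1", "malate", c(0.9, 0, 0, 0.1)),
               .midRow("s1", "pyruvate", c(0.5, 0, 0, 0.5)),
               .midRow("s2", "malate", c(0.9, 0, 0, 0.1)),
               .midRow("s2", "pyruvate", c(1, 0, 0, 0)))
  expect_message(out <- pcIndex(tab), "undefined")
  expect_equal(out$value[out$sample_id == "s1"], 0.2)
  expect_true(is.na(out$value[out$sample_id == "s2"]))
  expect_false(out$defined[out$sample_id == "s2"])
})

test_that("pc index vanishes without a PC route in a single-turn configuration", {
  cfg <- defaultFluxConfig()
  cfg <- setSourceFraction(cfg, "oxaloacetate", "pc", 0)
  cfg <- setSourceFraction(cfg, "aKG", "unlabeled", 1)
  tab <- asTidyMid(solveSteadyState(testNet, cfg, testTracers$glc_u13),
                   tracer = "glc_u13")
  expect_equal(pcIndex(tab)$value, 0, tolerance = 1e-9)
})

test_that("total carbon contribution follows the printed formula", {
  expect_equal(totalCarbonContribution(c(1, 0, 0)), 0)
  expect_equal(totalCarbonContribution(c(0, 0, 1)), 1)
  mid <- c(0.5, 0, 0.5)  # citrate with half M0, half M2
  expect_equal(totalCarbonContribution(mid, n = 6), 1 / 6)
  # invariant to uniform intensity rescaling
  expect_equal(totalCarbonContribution(mid * 1e4, n = 6), 1 / 6)
  expect_error(totalCarbonContribution(c(0, 0, 0)), "zero")
})

test_that("each flux-ratio index increases with its governing source fraction", {
  sweepIndex <- function(pool, source, indexFn, tracer, pts) {
    vapply(pts, function(v) {
      cfg <- setSourceFraction(defaultFluxConfig(), pool, source, v)
      tab <- asTidyMid(solveSteadyState(testNet, cfg, tracer))
      indexFn(tab)$value
    }, numeric(1))
  }
  pts <- seq(0, 0.6, length.out = 5)
  expect_true(all(diff(sweepIndex("oxaloacetate", "pc", pcIndex,
                                  testTracers$glc_u13, pts)) > 0))
  expect_true(all(diff(sweepIndex("pyruvate", "malic_enzyme", meIndex,
                                  testTracers$gln_u13, pts)) > 0))
  expect_true(all(diff(sweepIndex("citrate", "idh1_reductive",
                                  reductiveIndex, testTracers$gln_u13,
                                  pts)) > 0))
})

test_that("second-turn ratio falls as the oxidative return path is diluted", {
  vals <- vapply(c(0.05, 0.2, 0.35), function(u) {
    cfg <- setSourceFraction(conditionPreset("ESC"), "aKG", "unlabeled", u)
    tab <- asTidyMid(solveSteadyState(testNet, cfg, testTracers$gln_u13))
    secondTurnRatio(tab, "aKG")$value
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("acetyl sourcing summary separates tracer contributions", {
  cfg <- reductiveOnlyConfig()
  res <- list(
    glucose = solveSteadyState(testNet, cfg,
                               tracerSpec("glucose", "U", enrichment = 1)),
    glutamine = solveSteadyState(testNet, cfg,
                                 tracerSpec("glutamine", "U",
                                            enrichment = 1)))
  out <- acetylSourcingSummary(res)
  chromQ <- out$table$m2[out$table$tracer == "glutamine" &
                           out$table$pool == "acetylCoA_chromatin"]
  chromG <- out$table$m2[out$table$tracer == "glucose" &
                           out$table$pool == "acetylCoA_chromatin"]
  expect_equal(chromQ, 1, tolerance = 1e-9)
  expect_equal(chromG, 0, tolerance = 1e-9)
  expect_equal(unname(out$difference["acetylCoA_chromatin"]), 1,
               tolerance = 1e-9)

  unlab <- setSourceFraction(cfg, "acetylCoA_chromatin", "unlabeled", 1)
  resU <- list(glutamine = solveSteadyState(
    testNet, unlab, tracerSpec("glutamine", "U", enrichment = 1)))
  expect_equal(acetylSourcingSummary(resU)$table$m2[2], 0,
               tolerance = 1e-9)
  expect_error(acetylSourcingSummary(list()), "named")
})

test_that("a single free fraction is recovered from noise-free data", {
  cfgTrue <- setSourceFraction(conditionPreset("ESC"), "aKG", "glutamine",
                               0.63)
  obs <- do.call(rbind, lapply(c("glc_u13", "gln_u13"), function(tn)
    asTidyMid(solveSteadyState(testNet, cfgTrue, testTracers[[tn]]),
              tracer = tn)))
  fit <- recoverFluxFractions(obs, testNet, conditionPreset("ESC"),
                              "aKG.glutamine")
  expect_false(fit$nonIdentifiable)
  expect_lt(abs(fit$estimates[["aKG.glutamine"]] - 0.63), 1e-3)
})

test_that("an all-unlabeled observation drives the tracer-fed fraction to zero", {
  obs <- .midRow("s1", "aKG", c(1, 0, 0, 0, 0, 0), tracer = "gln_u13")
  fit <- recoverFluxFractions(obs, testNet, conditionPreset("ESC"),
                              "aKG.glutamine")
  expect_lt(fit$estimates[["aKG.glutamine"]], 1e-3)
})

test_that("a parameter with no effect on the observed pools is flagged non-identifiable", {
  obs <- .midRow("s1", "lactate", c(0.3, 0, 0, 0.7), tracer = "glc_u13")
  fit <- recoverFluxFractions(obs, testNet, conditionPreset("ESC"),
                              "acetylCoA_chromatin.acly_acetyl_arm")
  expect_true(fit$nonIdentifiable)
  expect_true(is.na(fit$estimates[[1]]))
})
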