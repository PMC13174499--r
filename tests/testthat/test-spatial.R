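.pix <- function(embryo, x, y, pool, shifts, intensity) {
  data.frame(embryo_id = embryo, x = x, y = y, pool = pool,
             mass_shift = shifts, intensity = intensity,
             stringsAsFactors = FALSE)
}

test_that("pixel aggregation averages annotated pixels and drops the rest", {
  pixels <- rbind(.pix("e1", 0, 0, "citrate", 0, 10),
                  .pix("e1", 1, 0, "citrate", 0, 30),
                  .pix("e1", 5, 5, "citrate", 0, 999))  # unannotated
  ann <- data.frame(embryo_id = "e1", x = c(0, 1), y = c(0, 0),
                    lineage = "ICM")
  agg <- aggregatePixels(pixels, ann)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$mean_intensity, 20)
  expect_equal(agg$n_pixels, 2)
  # permuting pixel order changes nothing
  agg2 <- aggregatePixels(pixels[c(3, 1, 2), ], ann)
  expect_equal(agg2$mean_intensity, agg$mean_intensity)
})

test_that("annotated groups without pixel data are omitted with a warning", {
  pixels <- .pix("e1", 0, 0, "citrate", 0, 10)
  ann <- data.frame(embryo_id = "e1", x = c(0, 9), y = c(0, 9),
                    lineage = c("ICM", "TE"))
  expect_warning(agg <- aggregatePixels(pixels, ann), "omitting")
  expect_equal(unique(agg$lineage), "ICM")
})

test_that("fractional enrichment normalizes within (embryo, lineage, pool)", {
  agg <- data.frame(embryo_id = "e1", lineage = "ICM", pool = "citrate",
                    mass_shift = 0:2,
                    mean_intensity = c(80, 0, 20))
  out <- clusterFractionEnrichment(agg)
  expect_equal(out$fraction, c(0.8, 0, 0.2))
  agg$mean_intensity <- c(5, 5, 5)
  expect_equal(clusterFractionEnrichment(agg)$fraction, rep(1 / 3, 3))
  agg$mean_intensity <- 0
  expect_message(out0 <- clusterFractionEnrichment(agg), "undefined")
  expect_true(all(is.na(out0$fraction)))
  expect_false(any(out0$defined))
})

test_that("embryo layouts are disjoint and the annotation mirrors the regions", {
  lay <- embryoLayout("E3.5", 40)
  expect_false(anyDuplicated(lay[, c("x", "y")]) > 0)
  expect_true(all(table(lay$lineage) >= 200))
  ds <- generateEmbryoDataset("E3.5", nEmbryos = 1, noiseCv = 0,
                              pools = "citrate", seed = 2)
  merged <- merge(unique(ds$pixels[, c("embryo_id", "x", "y")]),
                  ds$annotation, by = c("embryo_id", "x", "y"))
  expect_equal(nrow(merged), nrow(ds$annotation))
  # zero noise: every pixel of a lineage is identical
  sub <- ds$pixels[ds$pixels$mass_shift == 0, ]
  icm <- merge(sub, ds$annotation[ds$annotation$lineage == "ICM", ],
               by = c("embryo_id", "x", "y"))
  expect_equal(length(unique(icm$intensity)), 1)
  expect_error(generateEmbryoDataset("E3.5", layout = rbind(lay, lay[1, ]),
                                     seed = 1), "overlap")
})

test_that("aggregation and enrichment recover the generator's lineage MIDs", {
  ds <- generateEmbryoDataset("E3.5", nEmbryos = 1, noiseCv = 0.05,
                              pools = c("citrate", "glutamate"), seed = 4)
  enr <- clusterFractionEnrichment(aggregatePixels(ds$pixels,
                                                   ds$annotation))
  for (lin in c("ICM", "TE")) for (pool in c("citrate", "glutamate")) {
    got <- enr[enr$lineage == lin & enr$pool == pool, ]
    got <- got$fraction[order(got$mass_shift)]
    expect_lt(max(abs(got - ds$truth[[lin]][[pool]])), 0.02)
  }
})

test_that("post-implantation lineages carry higher M5 glutamine than blastocyst ones", {
  early <- generateEmbryoDataset("E3.5", nEmbryos = 1, noiseCv = 0.05,
                                 pools = "glutamine", seed = 6)
  late <- generateEmbryoDataset("E6.5", nEmbryos = 1, noiseCv = 0.05,
                                pools = "glutamine", seed = 6)
  m5 <- function(ds) {
    enr <- clusterFractionEnrichment(aggregatePixels(ds$pixels,
                                                     ds$annotation))
    tapply(enr$fraction[enr$mass_shift == 5],
           enr$lineage[enr$mass_shift == 5], mean)
  }
  expect_gt(min(m5(late)), max(m5(early)))
})
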