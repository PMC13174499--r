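# Synthetic-data generators: condition presets (flux routings calibrated to
# the qualitative ordering contract of the pluripotency transition and
# embryo stages), replicate-level MID tables with Dirichlet noise, stylized
# embryo pixel grids, and histone peptide observations. Every stage of the
# pipeline is testable from these generators alone.

# Stem-cell presets: glycolytic cells whose glutamine anaplerosis spikes at
# the ESC -> EpiLC day-1 transition, whose PC entry and malic-enzyme
# activity peak at EpiLC day 1, with reductive carboxylation active
# throughout and a chromatin acetyl-CoA pool increasingly fed by the
# ACLY acetyl arm toward primed pluripotency.
.stemPreset <- function(g, me, pc, csOx, akgOx, akgGln, acly, export,
                        pdh = 0.40) {
  idh1 <- 1 - csOx
  fluxConfig(list(
    pyruvate = c(glycolysis_tracer = g, lactate_uptake = 0.05,
                 malic_enzyme = me, unlabeled = 1 - g - 0.05 - me),
    lactate = c(ldh_from_pyruvate = 0.85, exogenous_tracer = 0.05,
                unlabeled = 0.10),
    alanine = c(alt_from_pyruvate = 0.85, unlabeled = 0.15),
    glutamine = c(exogenous_tracer = 1, unlabeled = 0),
    acetylCoA_mito = c(pdh = pdh, unlabeled = 1 - pdh),
    oxaloacetate = c(pc = pc, mdh_from_malate = 0.90 - pc,
                     acly_oaa_arm = 0.10),
    citrate = c(cs_oxidative = csOx, idh1_reductive = idh1),
    aKG = c(oxidative_from_citrate = akgOx, glutamine = akgGln,
            unlabeled = 1 - akgOx - akgGln),
    glutamate = c(glutamine = 0.50, akg_exchange = 0.40, unlabeled = 0.10),
    succinate = c(akgdh = 0.80, unlabeled = 0.20),
    fumarate = c(sdh = 1),
    malate = c(fh = 0.55, mdh_from_oaa = 0.30, unlabeled = 0.15),
    aspartate = c(oaa_exchange = 0.80, unlabeled = 0.20),
    acetylCoA_chromatin = c(acly_acetyl_arm = acly, pdh_export = export,
                            unlabeled = 1 - acly - export)))
}

.embryoPreset <- function(glnExo, akgOx, akgGln, g, lacUp, csOx, succDil) {
  fluxConfig(list(
    pyruvate = c(glycolysis_tracer = g, lactate_uptake = lacUp,
                 malic_enzyme = 0.05, unlabeled = 1 - g - lacUp - 0.05),
    lactate = c(ldh_from_pyruvate = 0.70, exogenous_tracer = 0.20,
                unlabeled = 0.10),
    alanine = c(alt_from_pyruvate = 0.85, unlabeled = 0.15),
    glutamine = c(exogenous_tracer = glnExo, unlabeled = 1 - glnExo),
    acetylCoA_mito = c(pdh = 0.50, unlabeled = 0.50),
    oxaloacetate = c(pc = 0.10, mdh_from_malate = 0.80,
                     acly_oaa_arm = 0.10),
    citrate = c(cs_oxidative = csOx, idh1_reductive = 1 - csOx),
    aKG = c(oxidative_from_citrate = akgOx, glutamine = akgGln,
            unlabeled = 1 - akgOx - akgGln),
    glutamate = c(glutamine = 0.50, akg_exchange = 0.40, unlabeled = 0.10),
    succinate = c(akgdh = 1 - succDil, unlabeled = succDil),
    fumarate = c(sdh = 1),
    malate = c(fh = 0.55, mdh_from_oaa = 0.30, unlabeled = 0.15),
    aspartate = c(oaa_exchange = 0.80, unlabeled = 0.20),
    acetylCoA_chromatin = c(acly_acetyl_arm = 0.55, pdh_export = 0.10,
                            unlabeled = 0.35)))
}

.buildPresets <- function() {
  stems <- list(
    #                     g    me    pc  csOx akgOx akgGln acly export
    ESC      = .stemPreset(0.70, 0.08, 0.12, 0.52, 0.20, 0.42, 0.58, 0.08),
    EpiLC_d1 = .stemPreset(0.62, 0.18, 0.30, 0.70, 0.08, 0.79, 0.59, 0.07),
    EpiLC_d2 = .stemPreset(0.66, 0.12, 0.20, 0.63, 0.12, 0.71, 0.64, 0.06),
    EpiLC_d3 = .stemPreset(0.68, 0.10, 0.15, 0.58, 0.12, 0.68, 0.68, 0.05),
    EpiSC    = .stemPreset(0.70, 0.08, 0.12, 0.58, 0.12, 0.70, 0.72, 0.04))
  embryos <- list(
    #                        glnExo akgOx akgGln   g  lacUp csOx succDil
    E3.5_ICM = .embryoPreset(0.60, 0.25, 0.45, 0.55, 0.25, 0.70, 0.15),
    E3.5_TE  = .embryoPreset(0.60, 0.22, 0.40, 0.55, 0.25, 0.70, 0.25),
    E6.5_EPI = .embryoPreset(0.85, 0.10, 0.60, 0.65, 0.10, 0.65, 0.30),
    E6.5_EC  = .embryoPreset(0.85, 0.16, 0.55, 0.60, 0.15, 0.65, 0.20))
  neg <- stems$EpiLC_d1
  kds <- list(
    Neg = neg,
    Pcx_KD = applyKnockdown(neg, "pc", 0.9),
    Me1_KD = applyKnockdown(neg, "malic_enzyme", 0.9),
    Me2_KD = applyKnockdown(neg, "malic_enzyme", 0.9),
    TripleKD = applyKnockdown(neg, c("pc", "malic_enzyme"), 0.9))
  c(stems, embryos, kds)
}

.presetCache <- new.env(parent = emptyenv())

#' Condition presets
#'
#' Named flux configurations emulating the study conditions: the
#' pluripotency transition (`ESC`, `EpiLC_d1`, `EpiLC_d2`, `EpiLC_d3`,
#' `EpiSC`), embryo lineages (`E3.5_ICM`, `E3.5_TE`, `E6.5_EPI`,
#' `E6.5_EC`) and the CRISPRi knockdown panel (`Neg`, `Pcx_KD`, `Me1_KD`,
#' `Me2_KD`, `TripleKD`; knockdowns are [applyKnockdown()] of `Neg` at
#' efficiency 0.9). Numeric values are calibration choices anchored to the
#' reported fractional labelings; the binding contract is the qualitative
#' ordering between conditions, documented in the package vignette.
#'
#' @param name preset name (see [listPresets()])
#' @return a [FluxConfig-class]
#' @export
conditionPreset <- function(name) {
  if (is.null(.presetCache$presets))
    .presetCache$presets <- .buildPresets()
  cfg <- .presetCache$presets[[name]]
  if (is.null(cfg))
    stop(sprintf("unknown preset '%s'; see listPresets()", name))
  cfg
}

#' @rdname conditionPreset
#' @export
listPresets <- function() {
  if (is.null(.presetCache$presets))
    .presetCache$presets <- .buildPresets()
  names(.presetCache$presets)
}

# Dirichlet draw around a MID; zero components stay exactly zero
.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) return(alpha / sum(alpha))
  g / sum(g)
}

#' Generate a replicate-level tidy MID dataset
#'
#' For each preset x tracer, solves the steady state, convolves natural
#' abundance onto every pool MID (the forward model of what a spectrometer
#' reports), and draws each replicate from
#' `Dirichlet(concentration * trueMID)` — simplex-respecting replicate
#' noise. `concentration = Inf` is the exact mode: replicates equal the
#' convolved truth.
#'
#' @param presets character vector of preset names
#' @param tracers character vector of tracer names from [standardTracers()]
#' @param nReplicates replicates per preset x tracer
#' @param concentration Dirichlet concentration (default 500; `Inf` = exact)
#' @param p13 natural 13C abundance used in the forward convolution
#' @param pools pools to report (default: all measurable pools)
#' @param seed integer seed; regeneration with the same seed is identical
#' @param net network (default [buildDefaultNetwork()])
#' @return a tidy MID table with `value_kind = "measured_fraction"`
#' @export
generateMidDataset <- function(presets, tracers = names(standardTracers()),
                               nReplicates = 3, concentration = 500,
                               p13 = 0.0107, pools = NULL, seed = 1L,
                               net = buildDefaultNetwork()) {
  if (nReplicates < 1) stop("nReplicates must be >= 1")
  if (concentration <= 0) stop("concentration must be positive")
  allTracers <- standardTracers()
  unknown <- setdiff(tracers, names(allTracers))
  if (length(unknown))
    stop(sprintf("unknown tracer(s): %s", paste(unknown, collapse = ", ")))
  models <- list()
  .withSeed(seed, function() {
    rows <- list()
    for (preset in presets) {
      cfg <- conditionPreset(preset)
      for (tr in tracers) {
        res <- solveSteadyState(net, cfg, allTracers[[tr]])
        m <- mids(res)
        if (!is.null(pools)) m <- m[intersect(pools, names(m))]
        for (pool in names(m)) {
          n <- length(m[[pool]]) - 1
          key <- as.character(n)
          if (is.null(models[[key]]))
            models[[key]] <<- buildCorrectionMatrix(n, p13)
          truth <- convolveNA(m[[pool]], models[[key]])
          for (r in seq_len(nReplicates)) {
            val <- if (is.finite(concentration))
              .rdirichlet(concentration * truth) else truth
            rows[[length(rows) + 1]] <- data.frame(
              sample_id = sprintf("%s_%s_r%d", preset, tr, r),
              condition = preset, tracer = tr, pool = pool,
              mass_shift = 0:n, value = val,
              value_kind = "measured_fraction", stringsAsFactors = FALSE)
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Stylized embryo section layouts
#'
#' Geometric lineage regions on an integer pixel grid (0-based, origin
#' top-left): the E3.5 blastocyst is an ICM disk inside a TE ring; the
#' E6.5 conceptus is stacked EPI and EC bands separated by an unannotated
#' gap. Regions are disjoint by construction.
#'
#' @param stage `"E3.5"` or `"E6.5"`
#' @param size grid side length in pixels (default 40 gives >= 200 pixels
#'   per lineage)
#' @return data.frame with columns `x`, `y`, `lineage`
#' @export
embryoLayout <- function(stage = c("E3.5", "E6.5"), size = 40L) {
  stage <- match.arg(stage)
  grid <- expand.grid(x = 0:(size - 1), y = 0:(size - 1))
  cx <- (size - 1) / 2
  if (stage == "E3.5") {
    r <- sqrt((grid$x - cx)^2 + (grid$y - cx)^2)
    icm <- r <= 0.205 * size
    te <- r > 0.30 * size & r <= 0.45 * size
    out <- rbind(
      data.frame(grid[icm, ], lineage = "ICM"),
      data.frame(grid[te, ], lineage = "TE"))
  } else {
    band <- grid$x >= 0.125 * size & grid$x < 0.875 * size
    epi <- band & grid$y < 0.45 * size
    ec <- band & grid$y >= 0.55 * size
    out <- rbind(
      data.frame(grid[epi, ], lineage = "EPI"),
      data.frame(grid[ec, ], lineage = "EC"))
  }
  rownames(out) <- NULL
  out
}

# lineage label -> condition preset name, per stage
.LINEAGE_PRESETS <- list(
  "E3.5" = c(ICM = "E3.5_ICM", TE = "E3.5_TE"),
  "E6.5" = c(EPI = "E6.5_EPI", EC = "E6.5_EC"))

#' Generate a synthetic embryo imaging dataset
#'
#' Produces pixel-level isotopologue intensities and the matching lineage
#' annotation for stylized embryo sections: per lineage, the preset flux
#' routing is solved under the tracer, natural abundance is convolved on,
#' and each pixel's intensity for isotopologue `i` is
#' `totalIntensity * mid_i` under multiplicative log-normal noise.
#'
#' @param stage `"E3.5"` or `"E6.5"`
#' @param tracer tracer name from [standardTracers()]
#' @param nEmbryos number of embryos (each embryo is one replicate unit)
#' @param pools metabolite panel (default: the imaging panel)
#' @param noiseCv log-normal coefficient of variation per pixel
#' @param totalIntensity expected per-pixel summed intensity scale
#' @param p13 natural 13C abundance for the forward convolution
#' @param size grid side length passed to [embryoLayout()]
#' @param layout optional custom layout data.frame (`x`, `y`, `lineage`);
#'   overlapping lineage regions are an error
#' @param presetsByLineage optional named map lineage -> preset name
#' @param seed integer seed
#' @param net network
#' @return list with `pixels` (pixel table), `annotation` (lineage
#'   annotation) and `truth` (the convolved lineage MIDs the generator
#'   drew from)
#' @export
generateEmbryoDataset <- function(stage = c("E3.5", "E6.5"),
                                  tracer = "gln_u13", nEmbryos = 3,
                                  pools = c("lactate", "citrate",
                                            "glutamate", "aspartate",
                                            "succinate", "glutamine"),
                                  noiseCv = 0.1, totalIntensity = 1000,
                                  p13 = 0.0107, size = 40L, layout = NULL,
                                  presetsByLineage = NULL, seed = 1L,
                                  net = buildDefaultNetwork()) {
  stage <- match.arg(stage)
  if (is.null(layout)) layout <- embryoLayout(stage, size)
  if (anyDuplicated(layout[, c("x", "y")]))
    stop("lineage regions overlap")
  if (is.null(presetsByLineage))
    presetsByLineage <- .LINEAGE_PRESETS[[stage]]
  lineages <- unique(layout$lineage)
  miss <- setdiff(lineages, names(presetsByLineage))
  if (length(miss))
    stop(sprintf("no preset mapped for lineage(s): %s",
                 paste(miss, collapse = ", ")))
  tr <- standardTracers()[[tracer]]
  if (is.null(tr)) stop(sprintf("unknown tracer '%s'", tracer))

  truth <- lapply(lineages, function(lin) {
    res <- solveSteadyState(net, conditionPreset(presetsByLineage[[lin]]),
                            tr)
    m <- mids(res)[pools]
    lapply(m, function(mid)
      convolveNA(mid, buildCorrectionMatrix(length(mid) - 1, p13)))
  })
  names(truth) <- lineages

  sdlog <- if (noiseCv > 0) sqrt(log(1 + noiseCv^2)) else 0
  .withSeed(seed, function() {
    pixelRows <- list()
    annRows <- list()
    for (e in seq_len(nEmbryos)) {
      eid <- sprintf("embryo_%02d", e)
      annRows[[e]] <- data.frame(embryo_id = eid, layout,
                                 stringsAsFactors = FALSE)
      for (lin in lineages) {
        px <- layout[layout$lineage == lin, , drop = FALSE]
        for (pool in pools) {
          mid <- truth[[lin]][[pool]]
          for (i in seq_along(mid)) {
            base <- totalIntensity * mid[i]
            noise <- if (sdlog > 0)
              stats::rlnorm(nrow(px), -sdlog^2 / 2, sdlog) else
              rep(1, nrow(px))
            pixelRows[[length(pixelRows) + 1]] <- data.frame(
              embryo_id = eid, x = px$x, y = px$y, pool = pool,
              mass_shift = i - 1L, intensity = base * noise,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    list(pixels = do.call(rbind, pixelRows),
         annotation = do.call(rbind, annRows), truth = truth)
  })
}

#' The acetyl-peptide panel of the histone labeling model
#' @return data.frame with columns `peptide`, `n_sites`
#' @export
histonePeptidePanel <- function() {
  data.frame(
    peptide = c("H3K9ac|H3K14ac", "H3K18ac|H3K23ac", "H3K27ac",
                "H4K5ac|H4K8ac|H4K12ac|H4K16ac"),
    n_sites = c(1L, 1L, 1L, 4L),
    stringsAsFactors = FALSE)
}

#' Generate histone peptide labeling observations
#'
#' For each preset x tracer, solves the steady state, takes the M2 fraction
#' of the chromatin acetyl-CoA pool, and simulates labeled/unlabeled AUC
#' observations for the acetyl-peptide panel via
#' [simulateHistoneLabeling()].
#'
#' @param presets character vector of preset names; a name may carry the
#'   suffix `"-Q"` (e.g. `"EpiSC-Q"`) for the glutamine-withdrawal variant
#'   of the preset (see [withdrawGlutamine()])
#' @param tracers tracer names (default glucose and glutamine)
#' @param turnover fraction of peptide acetyl groups replaced during the
#'   labeling window
#' @param nReplicates replicates per combination
#' @param noiseCv multiplicative AUC noise
#' @param peptides peptide panel (default [histonePeptidePanel()])
#' @param seed integer seed
#' @param net network
#' @return data.frame with columns `condition`, `tracer`, `peptide`,
#'   `n_sites`, `replicate`, `labeled_acetyl_count`, `auc`
#' @export
generateHistoneDataset <- function(presets,
                                   tracers = c("glc_u13", "gln_u13"),
                                   turnover = 0.35, nReplicates = 3,
                                   noiseCv = 0.1,
                                   peptides = histonePeptidePanel(),
                                   seed = 1L,
                                   net = buildDefaultNetwork()) {
  allTracers <- standardTracers()
  unknown <- setdiff(tracers, names(allTracers))
  if (length(unknown))
    stop(sprintf("unknown tracer(s): %s", paste(unknown, collapse = ", ")))
  rows <- list()
  counter <- 0L
  for (preset in presets) {
    base <- sub("-Q$", "", preset)
    cfg <- conditionPreset(base)
    if (grepl("-Q$", preset)) cfg <- withdrawGlutamine(cfg)
    for (tr in tracers) {
      res <- solveSteadyState(net, cfg, allTracers[[tr]])
      m2 <- mids(res)$acetylCoA_chromatin[3]
      for (k in seq_len(nrow(peptides))) {
        counter <- counter + 1L
        obs <- simulateHistoneLabeling(
          poolM2 = m2, turnover = turnover,
          nSites = peptides$n_sites[k], nReplicates = nReplicates,
          noiseCv = noiseCv, seed = (seed * 1009L + counter) %% 2147483647L)
        rows[[length(rows) + 1]] <- data.frame(
          condition = preset, tracer = tr, peptide = peptides$peptide[k],
          n_sites = peptides$n_sites[k], obs, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
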