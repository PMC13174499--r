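# MID-level tracing statistics: fractional labelings, the named flux-ratio
# indices, total carbon contribution, acetyl-CoA sourcing summaries and
# inversion of the forward model (mixing-fraction recovery).
# All ratios are computed per sample and only then aggregated; undefined
# ratios (zero denominators) propagate as NA with a flagged count, never as
# silent zeros.

.fractionPerSample <- function(table, pool, k) {
  validateMidTable(table)
  sub <- table[table$pool == pool, , drop = FALSE]
  if (!nrow(sub)) stop(sprintf("pool '%s' absent from table", pool))
  maxShift <- max(sub$mass_shift)
  if (k > maxShift || k < 0)
    stop(sprintf("mass shift %d out of range for pool '%s' (0..%d)",
                 k, pool, maxShift))
  sub <- sub[sub$mass_shift == k, , drop = FALSE]
  out <- sub[, c("sample_id", "condition", "tracer")]
  out$value <- sub$value
  rownames(out) <- NULL
  out
}

#' Fractional labeling of one isotopologue
#'
#' Returns `m_k` for a pool, per sample (e.g. fractional labeling of M3
#' lactate under a \[U-13C\]glucose tracer).
#'
#' @param table a tidy MID table (see [asTidyMid()])
#' @param pool metabolite pool
#' @param k mass shift
#' @return data.frame with columns `sample_id`, `condition`, `tracer`,
#'   `value`
#' @export
fractionalLabeling <- function(table, pool, k) {
  .fractionPerSample(table, pool, k)
}

#' Ratio of two fractional labelings, per sample
#'
#' Computes `m_numK(numPool) / m_denK(denPool)` within each sample. Samples
#' with a zero denominator get `NA` with `defined = FALSE`; a message
#' reports how many were undefined.
#'
#' @param table a tidy MID table
#' @param numPool,numK numerator pool and mass shift
#' @param denPool,denK denominator pool and mass shift
#' @return data.frame with columns `sample_id`, `condition`, `tracer`,
#'   `value`, `defined`
#' @export
normalizedFraction <- function(table, numPool, numK, denPool, denK) {
  num <- .fractionPerSample(table, numPool, numK)
  den <- .fractionPerSample(table, denPool, denK)
  m <- merge(num, den, by = c("sample_id", "condition", "tracer"),
             suffixes = c(".num", ".den"))
  m$defined <- m$value.den > 0
  m$value <- ifelse(m$defined, m$value.num / m$value.den, NA_real_)
  if (any(!m$defined))
    message(sprintf("%d sample(s) with zero denominator flagged undefined",
                    sum(!m$defined)))
  m[, c("sample_id", "condition", "tracer", "value", "defined")]
}

#' Named flux-ratio indices
#'
#' Convenience wrappers around [normalizedFraction()] for the ratios used
#' as relative-activity readouts:
#' * `pcIndex`: M3 malate / M3 pyruvate (\[U-13C\]glucose) — pyruvate
#'   carboxylase activity;
#' * `meIndex`: M3 pyruvate / M4 malate (\[U-13C\]glutamine) — malic enzyme
#'   activity;
#' * `reductiveIndex`: M5 citrate / M5 aKG (\[U-13C\]glutamine) — reductive
#'   carboxylation;
#' * `secondTurnRatio`: M3 / M5 of aKG or glutamate — progression of
#'   glutamine carbon into a second TCA turn;
#' * `pcEntryRatio`: M1 malate / M1 pyruvate (\[1-13C\]pyruvate) — PC entry
#'   versus PDH loss;
#' * `dilutionIndex`: M4 succinate / M5 glutamate — dilution downstream of
#'   aKG.
#'
#' @param table a tidy MID table
#' @param pool for `secondTurnRatio`: `"aKG"` or `"glutamate"`
#' @return data.frame as returned by [normalizedFraction()]
#' @name fluxIndices
NULL

#' @rdname fluxIndices
#' @export
pcIndex <- function(table) normalizedFraction(table, "malate", 3,
                                              "pyruvate", 3)

#' @rdname fluxIndices
#' @export
meIndex <- function(table) normalizedFraction(table, "pyruvate", 3,
                                              "malate", 4)

#' @rdname fluxIndices
#' @export
reductiveIndex <- function(table) normalizedFraction(table, "citrate", 5,
                                                     "aKG", 5)

#' @rdname fluxIndices
#' @export
secondTurnRatio <- function(table, pool = c("aKG", "glutamate")) {
  pool <- match.arg(pool)
  normalizedFraction(table, pool, 3, pool, 5)
}

#' @rdname fluxIndices
#' @export
pcEntryRatio <- function(table) normalizedFraction(table, "malate", 1,
                                                   "pyruvate", 1)

#' @rdname fluxIndices
#' @export
dilutionIndex <- function(table) normalizedFraction(table, "succinate", 4,
                                                    "glutamate", 5)

#' Total carbon contribution of a tracer to a metabolite
#'
#' The enrichment-weighted average `sum(i * m_i) / (n * sum(m_i))`: the
#' fraction of the metabolite's carbon atoms that carry the label.
#'
#' @param mid numeric MID vector `m_0..m_n` (fractions or intensities)
#' @param n the metabolite's carbon count (defaults to `length(mid) - 1`)
#' @return a fraction in \[0, 1\]
#' @examples
#' totalCarbonContribution(c(0.5, 0, 0.5), n = 6)  # padded below
#' @export
totalCarbonContribution <- function(mid, n = length(mid) - 1) {
  if (any(mid < 0)) stop("MID must be non-negative")
  if (all(mid == 0)) stop("MID is all zero")
  if (length(mid) > n + 1) stop("MID longer than n + 1")
  i <- seq_along(mid) - 1
  sum(i * mid) / (n * sum(mid))
}

#' Acetyl-CoA sourcing summary across tracers
#'
#' Tabulates the M2 fraction of the mitochondrial and chromatin acetyl-CoA
#' pools under each supplied tracer simulation, and the
#' glutamine-minus-glucose difference when both tracers are present —
#' the contrast behind the question of which nutrient feeds histone
#' acetylation.
#'
#' @param results named list of [SimulationResult-class] objects, names
#'   identifying the tracer (e.g. `glucose`, `glutamine`)
#' @return a list with `table` (data.frame: tracer, pool, m2) and
#'   `difference` (named numeric, glutamine minus glucose per pool, or
#'   `NULL` if either tracer is missing)
#' @export
acetylSourcingSummary <- function(results) {
  if (!length(results) || is.null(names(results)))
    stop("results must be a named list of SimulationResult objects")
  pools <- c("acetylCoA_mito", "acetylCoA_chromatin")
  tab <- do.call(rbind, lapply(names(results), function(tr) {
    m <- mids(results[[tr]])
    miss <- setdiff(pools, names(m))
    if (length(miss))
      stop(sprintf("tracer '%s': missing pool(s) %s", tr,
                   paste(miss, collapse = ", ")))
    data.frame(tracer = tr, pool = pools,
               m2 = vapply(pools, function(p) m[[p]][3], numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  diff <- NULL
  if (all(c("glucose", "glutamine") %in% tab$tracer)) {
    q <- tab[tab$tracer == "glutamine", ]
    g <- tab[tab$tracer == "glucose", ]
    diff <- stats::setNames(q$m2[match(pools, q$pool)] -
                              g$m2[match(pools, g$pool)], pools)
  }
  list(table = tab, difference = diff)
}

# mean observed MID per (tracer, pool), as named list tracer -> pool -> mid
.observedMids <- function(observed) {
  validateMidTable(observed)
  out <- list()
  for (tr in unique(observed$tracer)) {
    sub <- observed[observed$tracer == tr, , drop = FALSE]
    out[[tr]] <- lapply(split(sub, sub$pool), function(d) {
      agg <- tapply(d$value, d$mass_shift, mean)
      as.vector(agg[order(as.integer(names(agg)))])
    })
  }
  out
}

.applyFreeParams <- function(cfg, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop(sprintf("free parameter '%s' must be 'pool.source'", nm))
    cfg <- setSourceFraction(cfg, parts[1], parts[2], params[[nm]])
  }
  cfg
}

#' Recover flux mixing fractions from observed MIDs
#'
#' Inverts the forward model: finds the free source fractions minimizing
#' the sum of squared differences between simulated and observed
#' (natural-abundance-corrected) MIDs across all tracers present in the
#' observation table. The remaining sources of each touched pool are
#' renormalized proportionally. Deterministic: a fixed multi-start grid
#' feeds bounded quasi-Newton refinement. If the objective is flat across
#' the whole grid the request is flagged non-identifiable and no arbitrary
#' answer is returned.
#'
#' @param observed tidy MID table of corrected fractions; its `tracer`
#'   column must use the names of [standardTracers()]
#' @param net a [CarbonNetwork-class]
#' @param baseCfg the [FluxConfig-class] defining all non-free fractions
#' @param freeParams character vector of `"pool.source"` names to estimate
#' @param bounds length-2 numeric bounds for every free fraction
#' @param gridStep grid spacing for the multi-start sweep; defaults to 0.1
#'   for up to two free parameters and 0.25 beyond that (full factorial)
#' @param tol steady-state solver tolerance used inside the objective
#' @return list with `estimates` (named numeric), `objective` (residual sum
#'   of squares at the optimum), `nonIdentifiable` (logical flag) and
#'   `gridObjectiveRange`
#' @export
recoverFluxFractions <- function(observed, net, baseCfg, freeParams,
                                 bounds = c(0, 1), gridStep = NULL,
                                 tol = 1e-10) {
  obs <- .observedMids(observed)
  tracers <- standardTracers()
  unknown <- setdiff(names(obs), names(tracers))
  if (length(unknown))
    stop(sprintf("unknown tracer name(s) in observed table: %s",
                 paste(unknown, collapse = ", ")))
  d <- length(freeParams)
  if (d < 1) stop("freeParams must name at least one 'pool.source'")
  if (is.null(gridStep)) gridStep <- if (d <= 2) 0.1 else 0.25

  objective <- function(theta) {
    names(theta) <- freeParams
    cfg <- tryCatch(.applyFreeParams(baseCfg, theta),
                    error = function(e) NULL)
    if (is.null(cfg)) return(1e6)
    sse <- 0
    for (tr in names(obs)) {
      res <- solveSteadyState(net, cfg, tracers[[tr]], tol = tol)
      sim <- mids(res)
      for (pool in names(obs[[tr]])) {
        o <- obs[[tr]][[pool]]
        s <- sim[[pool]]
        if (length(s) != length(o))
          stop(sprintf("pool '%s': observed MID length %d, expected %d",
                       pool, length(o), length(s)))
        sse <- sse + sum((s - o)^2)
      }
    }
    sse
  }

  gridPts <- seq(bounds[1], bounds[2], by = gridStep)
  grid <- as.matrix(expand.grid(rep(list(gridPts), d)))
  gridVals <- apply(grid, 1, objective)
  rng <- range(gridVals)
  if (diff(rng) < 1e-10) {
    return(list(estimates = stats::setNames(rep(NA_real_, d), freeParams),
                objective = NA_real_, nonIdentifiable = TRUE,
                gridObjectiveRange = rng))
  }
  starts <- grid[order(gridVals)[seq_len(min(3, nrow(grid)))], ,
                 drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], objective, method = "L-BFGS-B",
                        lower = bounds[1], upper = bounds[2],
                        control = list(factr = 1e4))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(estimates = stats::setNames(as.vector(best$par), freeParams),
       objective = best$value, nonIdentifiable = FALSE,
       gridObjectiveRange = rng)
}
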