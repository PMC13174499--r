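#' Monte-Carlo ancestry oracle for pool MIDs
#'
#' An independent stochastic check on [solveSteadyState()]: for each pool it
#' samples `nMolecules` molecule ancestries by recursing through the source
#' decomposition (choosing a source by its fraction, recursing into
#' substrate pools independently for bimolecular reactions, stopping at a
#' tracer or unlabeled injection or at `maxDepth`, where the molecule is
#' returned unlabeled), applying atom maps and symmetry scrambling along the
#' path, and tallies the empirical MID. Deterministic given `seed`.
#'
#' @param net a [CarbonNetwork-class]
#' @param cfg a [FluxConfig-class]
#' @param tracer a [TracerSpec-class]
#' @param nMolecules molecules sampled per pool
#' @param maxDepth ancestry recursion cap
#' @param seed integer seed (a single seeded generator drives the whole
#'   call; the global RNG state is restored afterwards)
#' @return named list of empirical MID vectors, one per pool
#' @examples
#' net <- buildDefaultNetwork()
#' mc <- monteCarloOracle(net, defaultFluxConfig(),
#'                        tracerSpec("glutamine", "U"),
#'                        nMolecules = 5000, seed = 1)
#' round(mc$aKG, 2)
#' @export
monteCarloOracle <- function(net, cfg, tracer, nMolecules = 2e5,
                             maxDepth = 200L, seed = 1L) {
  if (nMolecules < 1) stop("nMolecules must be >= 1")
  if (maxDepth < 1) stop("maxDepth must be >= 1")
  validObject(cfg); validObject(tracer)
  nc <- nCarbons(net)
  pools <- names(cfg@fractions)
  purity <- if (is.na(tracer@enrichment)) cfg@tracerPurity else
    tracer@enrichment
  poolId <- stats::setNames(seq_along(pools) - 1L, pools)

  spec <- lapply(pools, function(pool) {
    n <- nc[[pool]]
    perm <- symmetryPermutation(net, pool)
    lut <- if (any(perm != seq_len(n))) .permLUT(perm) - 1L else integer(0)
    srcs <- lapply(names(cfg@fractions[[pool]]), function(src) {
      route <- .SOURCE_ROUTES[[pool]][[src]]
      frac <- cfg@fractions[[pool]][[src]]
      base <- list(frac = frac, kind = 0L, pattern = 0L, purity = 0,
                   subs = integer(0), msub = integer(0), mcar = integer(0))
      if (route$kind == "inject") {
        base$kind <- 1L
        if (tracer@nutrient %in% route$nutrients) {
          base$pattern <- as.integer(sum(2L^(which(tracer@pattern) - 1L)))
          base$purity <- purity
        }
      } else if (route$kind == "reaction") {
        r <- net@reactions[[route$reaction]]
        if (is.null(r))
          stop(sprintf("source '%s.%s' needs reaction '%s', absent from the network",
                       pool, src, route$reaction))
        base$kind <- 2L
        base$subs <- vapply(r$inputs, function(s)
          if (s == "CO2") -1L else poolId[[s]], integer(1))
        rows <- r$map[r$map$prod == route$output, , drop = FALSE]
        rows <- rows[order(rows$prod_carbon), , drop = FALSE]
        base$msub <- match(rows$sub, r$inputs) - 1L
        base$mcar <- rows$sub_carbon - 1L
      }
      base
    })
    list(n = as.integer(n), sym_lut = as.integer(lut), sources = srcs)
  })

  counts <- .withSeed(seed, function() {
    .mc_oracle_cpp(spec, cfg@co2LabeledFraction, as.integer(nMolecules),
                   as.integer(maxDepth))
  })
  stats::setNames(lapply(counts, function(ct) ct / sum(ct)), pools)
}

# run fn under a local RNG state seeded with `seed`, restoring the caller's
.withSeed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  fn()
}
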