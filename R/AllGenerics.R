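#' Pool names of a network or result
#' @param x a `CarbonNetwork` or `SimulationResult`
#' @return character vector of pool names
#' @export
setGeneric("poolNames", function(x) standardGeneric("poolNames"))

#' Carbon counts per pool
#' @param x a `CarbonNetwork` or `SimulationResult`
#' @return named integer vector
#' @export
setGeneric("nCarbons", function(x) standardGeneric("nCarbons"))

#' Per-pool source fractions of a flux configuration
#' @param x a `FluxConfig`
#' @return named list of named numeric simplex vectors
#' @export
setGeneric("sourceFractions", function(x) standardGeneric("sourceFractions"))

#' Positional isotopomer distributions of a simulation
#' @param x a `SimulationResult`
#' @return named list of probability vectors over `2^n` labeling patterns
#' @export
setGeneric("isotopomers", function(x) standardGeneric("isotopomers"))

#' Mass isotopologue distributions (MIDs)
#'
#' Collapses positional isotopomer distributions to MIDs, the observable all
#' tracing statistics consume: `m_i` is the fraction of molecules carrying
#' `i` heavy carbons.
#'
#' @param x a `SimulationResult`
#' @return named list; element `[[pool]]` is the numeric vector `m_0..m_n`
#' @export
setGeneric("mids", function(x) standardGeneric("mids"))

#' Convergence flag of a steady-state solve
#' @param x a `SimulationResult`
#' @return logical
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

setMethod("poolNames", "CarbonNetwork", function(x) x@metabolites$name)
setMethod("nCarbons", "CarbonNetwork", function(x) {
  stats::setNames(as.integer(x@metabolites$n_carbons), x@metabolites$name)
})
setMethod("poolNames", "SimulationResult", function(x) names(x@isotopomers))
setMethod("nCarbons", "SimulationResult", function(x) x@poolCarbons)
setMethod("sourceFractions", "FluxConfig", function(x) x@fractions)
setMethod("isotopomers", "SimulationResult", function(x) x@isotopomers)
setMethod("converged", "SimulationResult", function(x) x@converged)

setMethod("mids", "SimulationResult", function(x) {
  out <- lapply(names(x@isotopomers), function(pool) {
    collapseToMid(x@isotopomers[[pool]])
  })
  stats::setNames(out, names(x@isotopomers))
})

setMethod("show", "CarbonNetwork", function(object) {
  cat(sprintf("CarbonNetwork with %d metabolite pools, %d reactions\n",
              nrow(object@metabolites), length(object@reactions)))
  sym <- object@metabolites$name[object@metabolites$symmetry != "none"]
  cat("  pools: ", paste(sprintf("%s(%d)", object@metabolites$name,
                                 object@metabolites$n_carbons),
                         collapse = ", "), "\n", sep = "")
  if (length(sym))
    cat("  two-fold rotation symmetry: ", paste(sym, collapse = ", "),
        "\n", sep = "")
  cat("  reactions: ", paste(names(object@reactions), collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "FluxConfig", function(object) {
  cat(sprintf("FluxConfig over %d pools (tracer purity %.3g, CO2 labeled %.3g)\n",
              length(object@fractions), object@tracerPurity,
              object@co2LabeledFraction))
  for (pool in names(object@fractions)) {
    f <- object@fractions[[pool]]
    cat(sprintf("  %-20s %s\n", pool,
                paste(sprintf("%s=%.3g", names(f), f), collapse = " ")))
  }
})

setMethod("show", "TracerSpec", function(object) {
  lab <- which(object@pattern)
  desc <- if (length(lab) == length(object@pattern)) "U-13C" else
    paste0("[", paste(lab, collapse = ","), "-13C]")
  cat(sprintf("TracerSpec: %s %s (enrichment %s)\n", desc, object@nutrient,
              ifelse(is.na(object@enrichment), "config default",
                     format(object@enrichment))))
})

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d pools, %s after %d iterations (residual %.3g)\n",
              length(object@isotopomers),
              if (object@converged) "converged" else "NOT converged",
              object@iterations, object@residual))
})

setMethod("show", "CorrectionModel", function(object) {
  cat(sprintf("CorrectionModel: n = %d carbons, p13 = %.4g\n",
              object@nCarbons, object@p13))
})
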