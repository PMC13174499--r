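# Flux routing configuration: each pool's sources and how each source maps
# onto the network (a reaction + output pool, a tracer injection point, or
# unlabeled dilution). Mixing weights, not absolute fluxes: the model's
# observables are steady-state labeling fractions, which only depend on the
# normalized source composition of each pool.

# source -> route registry; `nutrients` lists which supplemented tracers a
# given injection point accepts (glucose enters at the pyruvate level).
.SOURCE_ROUTES <- list(
  pyruvate = list(
    glycolysis_tracer = list(kind = "inject",
                             nutrients = c("glucose", "pyruvate")),
    lactate_uptake = list(kind = "reaction", reaction = "ldh_reverse",
                          output = "pyruvate"),
    malic_enzyme = list(kind = "reaction", reaction = "me",
                        output = "pyruvate"),
    unlabeled = list(kind = "unlabeled")),
  lactate = list(
    ldh_from_pyruvate = list(kind = "reaction", reaction = "ldh",
                             output = "lactate"),
    exogenous_tracer = list(kind = "inject", nutrients = "lactate"),
    unlabeled = list(kind = "unlabeled")),
  alanine = list(
    alt_from_pyruvate = list(kind = "reaction", reaction = "alt",
                             output = "alanine"),
    unlabeled = list(kind = "unlabeled")),
  glutamine = list(
    exogenous_tracer = list(kind = "inject", nutrients = "glutamine"),
    unlabeled = list(kind = "unlabeled")),
  acetylCoA_mito = list(
    pdh = list(kind = "reaction", reaction = "pdh",
               output = "acetylCoA_mito"),
    unlabeled = list(kind = "unlabeled")),
  oxaloacetate = list(
    pc = list(kind = "reaction", reaction = "pc", output = "oxaloacetate"),
    mdh_from_malate = list(kind = "reaction", reaction = "mdh",
                           output = "oxaloacetate"),
    acly_oaa_arm = list(kind = "reaction", reaction = "acly",
                        output = "oxaloacetate")),
  citrate = list(
    cs_oxidative = list(kind = "reaction", reaction = "cs",
                        output = "citrate"),
    idh1_reductive = list(kind = "reaction", reaction = "idh1_red",
                          output = "citrate")),
  aKG = list(
    oxidative_from_citrate = list(kind = "reaction", reaction = "idh_ox",
                                  output = "aKG"),
    glutamine = list(kind = "reaction", reaction = "glnakg",
                     output = "aKG"),
    unlabeled = list(kind = "unlabeled")),
  glutamate = list(
    glutamine = list(kind = "reaction", reaction = "gls",
                     output = "glutamate"),
    akg_exchange = list(kind = "reaction", reaction = "trans_akg_glu",
                        output = "glutamate"),
    unlabeled = list(kind = "unlabeled")),
  succinate = list(
    akgdh = list(kind = "reaction", reaction = "akgdh",
                 output = "succinate"),
    unlabeled = list(kind = "unlabeled")),
  fumarate = list(
    sdh = list(kind = "reaction", reaction = "sdh", output = "fumarate")),
  malate = list(
    fh = list(kind = "reaction", reaction = "fh", output = "malate"),
    mdh_from_oaa = list(kind = "reaction", reaction = "mdh_reverse",
                        output = "malate"),
    unlabeled = list(kind = "unlabeled")),
  aspartate = list(
    oaa_exchange = list(kind = "reaction", reaction = "trans_oaa_asp",
                        output = "aspartate"),
    unlabeled = list(kind = "unlabeled")),
  acetylCoA_chromatin = list(
    acly_acetyl_arm = list(kind = "reaction", reaction = "acly",
                           output = "acetylCoA_chromatin"),
    pdh_export = list(kind = "reaction", reaction = "acetyl_export",
                      output = "acetylCoA_chromatin"),
    unlabeled = list(kind = "unlabeled")))

#' Construct a flux configuration
#'
#' @param fractions named list: `fractions[[pool]]` is a named non-negative
#'   vector of source fractions summing to 1. Valid sources per pool are
#'   those of [sourceRegistry()].
#' @param tracerPurity default tracer isotopic purity (fraction).
#' @param co2LabeledFraction labeled fraction of the infinite CO2 pool.
#' @return a validated [FluxConfig-class]
#' @export
fluxConfig <- function(fractions, tracerPurity = 0.99,
                       co2LabeledFraction = 0) {
  for (pool in names(fractions)) {
    routes <- .SOURCE_ROUTES[[pool]]
    if (is.null(routes)) stop(sprintf("unknown pool '%s'", pool))
    bad <- setdiff(names(fractions[[pool]]), names(routes))
    if (length(bad))
      stop(sprintf("pool '%s': unknown source(s) %s", pool,
                   paste(bad, collapse = ", ")))
  }
  missing <- setdiff(names(.SOURCE_ROUTES), names(fractions))
  if (length(missing))
    stop(sprintf("missing pool(s): %s", paste(missing, collapse = ", ")))
  new("FluxConfig", fractions = fractions, tracerPurity = tracerPurity,
      co2LabeledFraction = co2LabeledFraction)
}

#' The source registry: valid sources per pool
#' @return named list; element `[[pool]]` names that pool's valid sources
#' @export
sourceRegistry <- function() {
  lapply(.SOURCE_ROUTES, names)
}

#' A neutral template flux configuration
#'
#' A generic highly glycolytic stem-cell-like routing, useful as a starting
#' point for constructing custom configurations with [setSourceFraction()].
#' Condition-calibrated configurations live in [conditionPreset()].
#'
#' @param tracerPurity,co2LabeledFraction passed to [fluxConfig()]
#' @return a [FluxConfig-class]
#' @export
defaultFluxConfig <- function(tracerPurity = 0.99, co2LabeledFraction = 0) {
  fluxConfig(list(
    pyruvate = c(glycolysis_tracer = 0.70, lactate_uptake = 0.05,
                 malic_enzyme = 0.10, unlabeled = 0.15),
    lactate = c(ldh_from_pyruvate = 0.90, exogenous_tracer = 0.05,
                unlabeled = 0.05),
    alanine = c(alt_from_pyruvate = 0.85, unlabeled = 0.15),
    glutamine = c(exogenous_tracer = 1, unlabeled = 0),
    acetylCoA_mito = c(pdh = 0.45, unlabeled = 0.55),
    oxaloacetate = c(pc = 0.15, mdh_from_malate = 0.75,
                     acly_oaa_arm = 0.10),
    citrate = c(cs_oxidative = 0.60, idh1_reductive = 0.40),
    aKG = c(oxidative_from_citrate = 0.15, glutamine = 0.60,
            unlabeled = 0.25),
    glutamate = c(glutamine = 0.50, akg_exchange = 0.40, unlabeled = 0.10),
    succinate = c(akgdh = 0.80, unlabeled = 0.20),
    fumarate = c(sdh = 1),
    malate = c(fh = 0.55, mdh_from_oaa = 0.30, unlabeled = 0.15),
    aspartate = c(oaa_exchange = 0.80, unlabeled = 0.20),
    acetylCoA_chromatin = c(acly_acetyl_arm = 0.65, pdh_export = 0.06,
                            unlabeled = 0.29)),
    tracerPurity = tracerPurity, co2LabeledFraction = co2LabeledFraction)
}

#' Set one source fraction, renormalizing the rest of the pool
#'
#' Fixes `pool`'s `source` fraction at `value` and rescales the remaining
#' sources of that pool proportionally so the pool still sums to 1. If the
#' remaining sources currently sum to 0, the balance is assigned to the
#' pool's `unlabeled` source.
#'
#' @param cfg a `FluxConfig`
#' @param pool pool name
#' @param source source name within the pool
#' @param value new fraction in \[0, 1\]
#' @return the modified `FluxConfig`
#' @export
setSourceFraction <- function(cfg, pool, source, value) {
  f <- cfg@fractions[[pool]]
  if (is.null(f)) stop(sprintf("unknown pool '%s'", pool))
  if (!source %in% names(f))
    stop(sprintf("unknown source '%s' in pool '%s'", source, pool))
  if (value < 0 || value > 1) stop("value must be in [0, 1]")
  rest <- setdiff(names(f), source)
  restSum <- sum(f[rest])
  if (restSum > 0) {
    f[rest] <- f[rest] * (1 - value) / restSum
  } else if ((1 - value) > 0) {
    if (!"unlabeled" %in% rest)
      stop(sprintf("pool '%s' has no mass to renormalize", pool))
    f["unlabeled"] <- 1 - value
  }
  f[source] <- value
  cfg@fractions[[pool]] <- f
  validObject(cfg)
  cfg
}

#' Knock down flux sources
#'
#' Models CRISPRi repression of the enzymes behind one or more sources: each
#' targeted source fraction is multiplied by `1 - efficiency` and the
#' affected pool is renormalized, so the removed flux is absorbed
#' proportionally by the remaining sources. Gene-level shorthand:
#' Pcx targets `pc`; Me1 and Me2 target `malic_enzyme`.
#'
#' @param cfg a `FluxConfig`
#' @param targets character vector of source names (e.g. `c("pc",
#'   "malic_enzyme")` for the triple Pcx/Me1/Me2 knockdown)
#' @param efficiency knockdown efficiency in \[0, 1\]
#' @return the perturbed `FluxConfig`
#' @examples
#' cfg <- defaultFluxConfig()
#' kd <- applyKnockdown(cfg, c("pc", "malic_enzyme"), efficiency = 0.9)
#' sourceFractions(kd)$oxaloacetate
#' @export
applyKnockdown <- function(cfg, targets, efficiency) {
  if (length(efficiency) != 1 || efficiency < 0 || efficiency > 1)
    stop("efficiency must be a single value in [0, 1]")
  allSources <- unique(unlist(lapply(cfg@fractions, names)))
  unknown <- setdiff(targets, allSources)
  if (length(unknown))
    stop(sprintf("unknown knockdown target(s): %s",
                 paste(unknown, collapse = ", ")))
  for (pool in names(cfg@fractions)) {
    f <- cfg@fractions[[pool]]
    hit <- intersect(names(f), targets)
    if (!length(hit)) next
    f[hit] <- f[hit] * (1 - efficiency)
    s <- sum(f)
    if (s <= 0)
      stop(sprintf("knockdown removes all flux into pool '%s'", pool))
    cfg@fractions[[pool]] <- f / s
  }
  validObject(cfg)
  cfg
}

#' Map knockdown gene names to flux sources
#' @param genes character vector among `"Pcx"`, `"Me1"`, `"Me2"`
#' @return character vector of source names
#' @export
knockdownTargets <- function(genes) {
  map <- c(Pcx = "pc", Me1 = "malic_enzyme", Me2 = "malic_enzyme")
  unknown <- setdiff(genes, names(map))
  if (length(unknown))
    stop(sprintf("unknown gene(s): %s", paste(unknown, collapse = ", ")))
  unique(unname(map[genes]))
}

#' Glutamine-withdrawal scenario
#'
#' Emulates acute glutamine deprivation: the glutamine-fed source fraction of
#' each pool (the glutamine pool's exogenous supply, and the `glutamine`
#' sources of aKG and glutamate) is moved into that pool's `unlabeled`
#' source. The gap left by glutamine is filled by unlabeled carbon (other
#' amino-acid catabolism), not by proportionally more cycling, so routing
#' through the remaining sources is unchanged.
#'
#' @param cfg a `FluxConfig`
#' @return the deprived `FluxConfig`
#' @export
withdrawGlutamine <- function(cfg) {
  moves <- list(glutamine = "exogenous_tracer", aKG = "glutamine",
                glutamate = "glutamine")
  for (pool in names(moves)) {
    f <- cfg@fractions[[pool]]
    src <- moves[[pool]]
    if (!all(c(src, "unlabeled") %in% names(f))) next
    f["unlabeled"] <- f["unlabeled"] + f[src]
    f[src] <- 0
    cfg@fractions[[pool]] <- f
  }
  validObject(cfg)
  cfg
}

#' Construct a tracer specification
#'
#' @param nutrient one of `"glucose"`, `"pyruvate"`, `"lactate"`,
#'   `"glutamine"`. Glucose is specified at the pyruvate level (3 carbons).
#' @param labeled integer positions of 13C carbons, or `"U"` for uniform
#'   labeling
#' @param enrichment tracer purity override (`NA` = use the FluxConfig
#'   default)
#' @return a [TracerSpec-class]
#' @examples
#' tracerSpec("glutamine", "U")
#' tracerSpec("pyruvate", 1)
#' @export
tracerSpec <- function(nutrient, labeled = "U", enrichment = NA_real_) {
  n <- .TRACER_POOL_CARBONS[[nutrient]]
  if (is.null(n)) stop(sprintf("unknown nutrient '%s'", nutrient))
  pat <- logical(n)
  if (identical(labeled, "U")) pat[] <- TRUE else {
    labeled <- as.integer(labeled)
    if (any(labeled < 1 | labeled > n)) stop("labeled positions out of range")
    pat[labeled] <- TRUE
  }
  new("TracerSpec", nutrient = nutrient, pattern = pat,
      enrichment = as.numeric(enrichment))
}

#' The five standard tracers of the tracing design
#'
#' \[U-13C\]glucose, \[U-13C\]lactate, \[U-13C\]glutamine, \[1-13C\]pyruvate
#' and \[1-13C\]glutamine.
#'
#' @return named list of [TracerSpec-class] objects with names
#'   `glc_u13`, `lac_u13`, `gln_u13`, `pyr_1c13`, `gln_1c13`
#' @export
standardTracers <- function() {
  list(glc_u13 = tracerSpec("glucose", "U"),
       lac_u13 = tracerSpec("lactate", "U"),
       gln_u13 = tracerSpec("glutamine", "U"),
       pyr_1c13 = tracerSpec("pyruvate", 1),
       gln_1c13 = tracerSpec("glutamine", 1))
}
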