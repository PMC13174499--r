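#' @import methods
NULL

.SIMPLEX_TOL <- 1e-9

#' CarbonNetwork: an atom-mapped central-carbon network
#'
#' Holds the metabolite pools (with carbon counts and molecular symmetries)
#' and the reactions connecting them, each with an explicit carbon atom map.
#' The atom map of a reaction is a bijection between substrate carbon slots
#' and product carbon slots; CO2 may appear on either side and is treated as
#' an infinite pool.
#'
#' @slot metabolites data.frame with columns `name`, `n_carbons`, `symmetry`
#'   (`"none"` or `"two_fold_rotation"`).
#' @slot reactions named list; each element has `name`, `inputs` (ordered
#'   substrate pool names), `outputs` (ordered product pool names, `"CO2"`
#'   allowed) and `map`, a data.frame with columns `sub`, `sub_carbon`,
#'   `prod`, `prod_carbon` covering every substrate carbon exactly once.
#'
#' @seealso [buildDefaultNetwork()], [validateNetwork()]
#' @export
setClass("CarbonNetwork",
  representation(metabolites = "data.frame", reactions = "list"))

setValidity("CarbonNetwork", function(object) {
  met <- object@metabolites
  need <- c("name", "n_carbons", "symmetry")
  if (!all(need %in% names(met)))
    return("metabolites must have columns name, n_carbons, symmetry")
  if (anyDuplicated(met$name)) return("duplicated metabolite names")
  if (any(met$n_carbons < 1)) return("n_carbons must be >= 1")
  if (!all(met$symmetry %in% c("none", "two_fold_rotation")))
    return("unknown symmetry kind")
  for (r in object@reactions) {
    msg <- .checkAtomMap(object, r)
    if (!isTRUE(msg)) return(sprintf("reaction '%s': %s", r$name, msg))
  }
  # symmetry permutations must be involutions
  for (i in seq_len(nrow(met))) {
    p <- .symmetryPerm(met$symmetry[i], met$n_carbons[i])
    if (!identical(p[p], seq_len(met$n_carbons[i])))
      return(sprintf("symmetry permutation for '%s' is not an involution",
                     met$name[i]))
  }
  TRUE
})

# carbon balance + bijectivity of one atom map; returns TRUE or message
.checkAtomMap <- function(net, r) {
  met <- net@metabolites
  nc <- function(p) if (p == "CO2") 1L else met$n_carbons[match(p, met$name)]
  if (!all(c("name", "inputs", "outputs", "map") %in% names(r)))
    return("missing fields")
  pools <- setdiff(c(r$inputs, r$outputs), "CO2")
  if (!all(pools %in% met$name))
    return(sprintf("unknown pool(s): %s",
                   paste(setdiff(pools, met$name), collapse = ", ")))
  m <- r$map
  subSlots <- unlist(lapply(r$inputs, function(p) paste(p, seq_len(nc(p)))))
  prodSlots <- unlist(lapply(r$outputs, function(p) paste(p, seq_len(nc(p)))))
  got <- paste(m$sub, m$sub_carbon)
  if (!setequal(got, subSlots) || anyDuplicated(got))
    return("map does not cover every substrate carbon exactly once")
  gotP <- paste(m$prod, m$prod_carbon)
  if (!setequal(gotP, prodSlots) || anyDuplicated(gotP))
    return("map is not a bijection onto product carbon slots")
  if (length(subSlots) != length(prodSlots)) return("carbon imbalance")
  TRUE
}

.symmetryPerm <- function(kind, n) {
  if (kind == "two_fold_rotation") rev(seq_len(n)) else seq_len(n)
}

#' FluxConfig: normalized source fractions per metabolite pool
#'
#' A flux routing is parameterised as, for each pool, a simplex of source
#' fractions (mixing weights standing in for relative fluxes): each source is
#' either a reaction drawing on upstream pools, a tracer injection point, or
#' an unlabeled dilution.
#'
#' @slot fractions named list; element `fractions[[pool]]` is a named
#'   non-negative numeric vector summing to 1.
#' @slot tracerPurity default isotopic purity applied to tracer injections
#'   (fraction in \[0, 1\]).
#' @slot co2LabeledFraction labeled fraction of the (infinite) CO2 pool.
#'
#' @seealso [fluxConfig()], [defaultFluxConfig()], [conditionPreset()]
#' @export
setClass("FluxConfig",
  representation(fractions = "list", tracerPurity = "numeric",
                 co2LabeledFraction = "numeric"))

setValidity("FluxConfig", function(object) {
  for (pool in names(object@fractions)) {
    f <- object@fractions[[pool]]
    if (is.null(names(f)) || any(!nzchar(names(f))))
      return(sprintf("pool '%s': sources must be named", pool))
    if (any(f < 0))
      return(sprintf("pool '%s': negative source fraction", pool))
    if (abs(sum(f) - 1) > .SIMPLEX_TOL)
      return(sprintf("pool '%s': source fractions sum to %.12g, not 1",
                     pool, sum(f)))
  }
  p <- object@tracerPurity
  if (length(p) != 1 || p < 0 || p > 1)
    return("tracerPurity must be a single value in [0, 1]")
  cf <- object@co2LabeledFraction
  if (length(cf) != 1 || cf < 0 || cf > 1)
    return("co2LabeledFraction must be a single value in [0, 1]")
  TRUE
})

#' TracerSpec: a positional 13C labeling pattern for a supplemented nutrient
#'
#' @slot nutrient nutrient name; one of `"glucose"`, `"pyruvate"`,
#'   `"lactate"`, `"glutamine"`. Glucose is specified at the pyruvate level
#'   (three carbons): glycolytic cleavage of a uniformly labeled hexose
#'   yields two uniformly labeled trioses.
#' @slot pattern logical vector, one flag per carbon (TRUE = 13C).
#' @slot enrichment tracer purity override; `NA` uses the FluxConfig default.
#'
#' @seealso [tracerSpec()], [standardTracers()]
#' @export
setClass("TracerSpec",
  representation(nutrient = "character", pattern = "logical",
                 enrichment = "numeric"))

setValidity("TracerSpec", function(object) {
  if (length(object@nutrient) != 1) return("nutrient must be a single name")
  if (!object@nutrient %in% names(.TRACER_POOL_CARBONS))
    return(sprintf("unknown nutrient '%s'", object@nutrient))
  if (length(object@pattern) != .TRACER_POOL_CARBONS[[object@nutrient]])
    return("pattern length must equal the nutrient's carbon count")
  e <- object@enrichment
  if (length(e) != 1 || (!is.na(e) && (e < 0 || e > 1)))
    return("enrichment must be NA or in [0, 1]")
  TRUE
})

# carbons of the pool a tracer feeds (glucose enters at the pyruvate level)
.TRACER_POOL_CARBONS <- c(glucose = 3L, pyruvate = 3L, lactate = 3L,
                          glutamine = 5L)

#' SimulationResult: steady-state positional isotopomer distributions
#'
#' @slot isotopomers named list; element `[[pool]]` is the probability vector
#'   over the `2^n` binary labeling patterns of that pool's carbons (pattern
#'   index = 1 + sum of `2^(i-1)` over labeled carbons `i`).
#' @slot poolCarbons named integer vector of carbon counts.
#' @slot converged logical convergence flag.
#' @slot iterations number of fixed-point sweeps performed.
#' @slot residual final max-norm change between sweeps.
#'
#' @seealso [solveSteadyState()], [mids()], [collapseToMid()]
#' @export
setClass("SimulationResult",
  representation(isotopomers = "list", poolCarbons = "integer",
                 converged = "logical", iterations = "integer",
                 residual = "numeric"))

setValidity("SimulationResult", function(object) {
  if (!identical(sort(names(object@isotopomers)),
                 sort(names(object@poolCarbons))))
    return("isotopomers and poolCarbons must cover the same pools")
  for (pool in names(object@isotopomers)) {
    x <- object@isotopomers[[pool]]
    if (length(x) != 2^object@poolCarbons[[pool]])
      return(sprintf("pool '%s': wrong state-space size", pool))
    if (any(x < -.SIMPLEX_TOL))
      return(sprintf("pool '%s': negative probability", pool))
    if (object@converged && abs(sum(x) - 1) > 1e-6)
      return(sprintf("pool '%s': probabilities sum to %.12g", pool, sum(x)))
  }
  TRUE
})

#' CorrectionModel: binomial natural-abundance convolution operator
#'
#' Column `j` (for `j` true labels, 0-based) is the binomial distribution of
#' additional apparent labels among the `n - j` remaining carbons at natural
#' 13C abundance `p13`: entry `(i, j) = C(n-j, i-j) p13^(i-j) (1-p13)^(n-i)`
#' for `i >= j`, else 0. Columns are stochastic by construction.
#'
#' @slot nCarbons number of carbons of the metabolite.
#' @slot p13 natural 13C abundance fraction.
#' @slot matrix the `(n+1) x (n+1)` lower-triangular operator.
#'
#' @seealso [buildCorrectionMatrix()], [convolveNA()], [correctNA()]
#' @export
setClass("CorrectionModel",
  representation(nCarbons = "integer", p13 = "numeric", matrix = "matrix"))

setValidity("CorrectionModel", function(object) {
  n <- object@nCarbons
  if (length(n) != 1 || n < 1) return("nCarbons must be >= 1")
  if (object@p13 < 0 || object@p13 >= 1) return("p13 must be in [0, 1)")
  m <- object@matrix
  if (!all(dim(m) == n + 1)) return("matrix must be (n+1) x (n+1)")
  if (any(abs(colSums(m) - 1) > 1e-12)) return("columns must sum to 1")
  if (any(m[upper.tri(m)] != 0)) return("matrix must be lower-triangular")
  TRUE
})
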