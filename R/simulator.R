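# Steady-state positional isotopomer solver. State space: for a pool with n
# carbons, a probability vector over the 2^n binary labeling patterns
# (pattern integer p has bit i-1 set iff carbon i is 13C; R index = p + 1).
# The steady state is the fixed point of
#   x(pool) = sum_sources f_source * T_source(x)
# where T applies the source reaction's atom map; bimolecular reactions take
# the product distribution of their substrates (independence, exact in this
# well-mixed pool model); tracer sources inject the tracer pattern at purity
# p and the unlabeled pattern at 1 - p; symmetric pools are symmetrized
# after every sweep.

.patternBits <- function(n) {
  p <- 0:(2^n - 1)
  vapply(seq_len(n), function(i) bitwAnd(bitwShiftR(p, i - 1L), 1L),
         integer(2^n))
}

# index permutation of pattern space induced by a carbon permutation
.permLUT <- function(perm) {
  n <- length(perm)
  bits <- .patternBits(n)            # 2^n x n
  out <- integer(2^n)
  for (i in seq_len(n)) out <- out + bits[, i] * 2L^(perm[i] - 1L)
  out + 1L
}

# transfer matrix (2^n_out x prod 2^n_sub) for one reaction/output pair
.transferMatrix <- function(net, r, output) {
  nc <- nCarbons(net)
  ncOf <- function(p) if (p == "CO2") 1L else nc[[p]]
  ns <- vapply(r$inputs, ncOf, integer(1))
  offsets <- c(0L, cumsum(ns))[seq_along(ns)]
  N <- 2L^sum(ns)
  jp <- 0:(N - 1)
  rows <- r$map[r$map$prod == output, , drop = FALSE]
  out <- integer(N)
  for (k in seq_len(nrow(rows))) {
    s <- match(rows$sub[k], r$inputs)
    bit <- bitwAnd(bitwShiftR(jp, offsets[s] + rows$sub_carbon[k] - 1L), 1L)
    out <- out + bit * 2L^(rows$prod_carbon[k] - 1L)
  }
  M <- matrix(0, nrow = 2L^ncOf(output), ncol = N)
  M[cbind(out + 1L, jp + 1L)] <- 1
  M
}

# resolve every source of every pool into an executable update rule
.buildPlan <- function(net, cfg, tracer) {
  nc <- nCarbons(net)
  purity <- if (is.na(tracer@enrichment)) cfg@tracerPurity else
    tracer@enrichment
  co2dist <- c(1 - cfg@co2LabeledFraction, cfg@co2LabeledFraction)
  plan <- list()
  for (pool in names(cfg@fractions)) {
    if (!pool %in% names(nc))
      stop(sprintf("config pool '%s' is not in the network", pool))
    n <- nc[[pool]]
    f <- cfg@fractions[[pool]]
    srcs <- list()
    for (src in names(f)) {
      route <- .SOURCE_ROUTES[[pool]][[src]]
      e0 <- c(1, numeric(2^n - 1))
      if (route$kind == "unlabeled") {
        srcs[[src]] <- list(frac = f[[src]], kind = "const", dist = e0)
      } else if (route$kind == "inject") {
        if (tracer@nutrient %in% route$nutrients) {
          idx <- sum(2L^(which(tracer@pattern) - 1L)) + 1L
          d <- numeric(2^n)
          d[idx] <- purity
          d[1] <- d[1] + 1 - purity
        } else d <- e0
        srcs[[src]] <- list(frac = f[[src]], kind = "const", dist = d)
      } else {
        r <- net@reactions[[route$reaction]]
        if (is.null(r))
          stop(sprintf("source '%s.%s' needs reaction '%s', absent from the network",
                       pool, src, route$reaction))
        srcs[[src]] <- list(frac = f[[src]], kind = "reaction",
                            subs = r$inputs,
                            M = .transferMatrix(net, r, route$output))
      }
    }
    perm <- symmetryPermutation(net, pool)
    plan[[pool]] <- list(n = n, sources = srcs,
                         permLUT = if (any(perm != seq_len(n)))
                           .permLUT(perm) else NULL)
  }
  list(pools = plan, co2dist = co2dist)
}

.jointDist <- function(subs, state, co2dist) {
  d <- NULL
  for (s in subs) {
    ds <- if (s == "CO2") co2dist else state[[s]]
    d <- if (is.null(d)) ds else as.vector(outer(d, ds))
  }
  d
}

#' Solve the steady-state labeling of a network under a tracer
#'
#' Iterates the pool-mixing fixed point from a chosen initial state until
#' the maximum-norm change between sweeps falls below `tol` or `maxIter` is
#' reached. Non-convergence is reported through the `converged` flag, not an
#' exception.
#'
#' @param net a [CarbonNetwork-class]
#' @param cfg a [FluxConfig-class] valid on `net`
#' @param tracer a [TracerSpec-class]
#' @param tol convergence tolerance on the max-norm change per sweep
#' @param maxIter maximum number of sweeps
#' @param init `"unlabeled"` (default) or `"labeled"` starting state
#' @return a [SimulationResult-class]
#' @examples
#' net <- buildDefaultNetwork()
#' res <- solveSteadyState(net, defaultFluxConfig(),
#'                         tracerSpec("glutamine", "U"))
#' round(mids(res)$citrate, 3)
#' @export
solveSteadyState <- function(net, cfg, tracer, tol = 1e-12,
                             maxIter = 10000L,
                             init = c("unlabeled", "labeled")) {
  init <- match.arg(init)
  validObject(cfg); validObject(tracer)
  plan <- .buildPlan(net, cfg, tracer)
  pools <- names(plan$pools)
  state <- lapply(plan$pools, function(p) {
    d <- numeric(2^p$n)
    d[if (init == "unlabeled") 1L else 2^p$n] <- 1
    d
  })
  iter <- 0L
  resid <- Inf
  while (iter < maxIter) {
    iter <- iter + 1L
    newState <- state
    for (pool in pools) {
      p <- plan$pools[[pool]]
      acc <- numeric(2^p$n)
      for (s in p$sources) {
        if (s$frac == 0) next
        acc <- acc + s$frac * (if (s$kind == "const") s$dist else
          as.vector(s$M %*% .jointDist(s$subs, state, plan$co2dist)))
      }
      if (!is.null(p$permLUT)) acc <- (acc + acc[p$permLUT]) / 2
      newState[[pool]] <- acc
    }
    resid <- max(vapply(pools, function(pool)
      max(abs(newState[[pool]] - state[[pool]])), numeric(1)))
    state <- newState
    if (resid < tol) break
  }
  new("SimulationResult", isotopomers = state,
      poolCarbons = stats::setNames(
        vapply(plan$pools, `[[`, integer(1), "n"), pools),
      converged = resid < tol, iterations = iter, residual = resid)
}

#' Collapse a positional isotopomer distribution to its MID
#'
#' @param iso probability vector over the `2^n` labeling patterns
#' @return numeric vector `m_0..m_n`: the fraction of molecules carrying
#'   each number of heavy carbons
#' @examples
#' # all mass on the pattern (1,1,0) -> m_2 = 1
#' collapseToMid(c(0, 0, 0, 1, 0, 0, 0, 0))
#' @export
collapseToMid <- function(iso) {
  n <- round(log2(length(iso)))
  if (2^n != length(iso)) stop("length must be a power of two")
  counts <- rowSums(.patternBits(n))
  as.vector(vapply(0:n, function(k) sum(iso[counts == k]), numeric(1)))
}

#' Tidy MID table from a simulation result
#'
#' Converts a [SimulationResult-class] into the long-format interchange
#' table used by the diagnostics and statistics stages: one row per
#' `(sample_id, condition, tracer, pool, mass_shift)`.
#'
#' @param result a `SimulationResult`
#' @param sample_id,condition,tracer identifying labels for the rows
#' @param pools optional subset of pools to include
#' @param value_kind value-kind flag, default `"fraction"`
#' @return data.frame with columns `sample_id`, `condition`, `tracer`,
#'   `pool`, `mass_shift`, `value`, `value_kind`
#' @export
asTidyMid <- function(result, sample_id = "sim", condition = "sim",
                      tracer = "tracer", pools = NULL,
                      value_kind = "fraction") {
  m <- mids(result)
  if (!is.null(pools)) {
    missing <- setdiff(pools, names(m))
    if (length(missing))
      stop(sprintf("pool(s) not in result: %s",
                   paste(missing, collapse = ", ")))
    m <- m[pools]
  }
  do.call(rbind, lapply(names(m), function(pool) {
    data.frame(sample_id = sample_id, condition = condition,
               tracer = tracer, pool = pool,
               mass_shift = seq_along(m[[pool]]) - 1L,
               value = m[[pool]], value_kind = value_kind,
               stringsAsFactors = FALSE)
  }))
}

#' Validate a tidy MID table
#'
#' Checks the schema (columns, mass-shift ranges against a network) and,
#' for fraction-valued rows, the per-(sample, tracer, pool) simplex
#' constraint.
#'
#' @param table a tidy MID data.frame
#' @param net optional `CarbonNetwork` to check mass shifts against
#' @param tol simplex tolerance
#' @return invisibly `TRUE`; stops with a message otherwise
#' @export
validateMidTable <- function(table, net = NULL, tol = 1e-6) {
  need <- c("sample_id", "condition", "tracer", "pool", "mass_shift",
            "value", "value_kind")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  if (any(table$mass_shift < 0)) stop("negative mass shift")
  if (!is.null(net)) {
    nc <- nCarbons(net)
    unknown <- setdiff(unique(table$pool), names(nc))
    if (length(unknown))
      stop(sprintf("unknown pool(s): %s", paste(unknown, collapse = ", ")))
    bad <- table$mass_shift > nc[table$pool]
    if (any(bad)) stop("mass shift exceeds the pool's carbon count")
  }
  isFrac <- table$value_kind %in% c("fraction", "measured_fraction")
  if (any(table$value[isFrac] < -tol)) stop("negative fraction value")
  if (any(isFrac)) {
    key <- interaction(table$sample_id[isFrac], table$tracer[isFrac],
                       table$pool[isFrac], drop = TRUE)
    sums <- tapply(table$value[isFrac], key, sum)
    if (any(abs(sums - 1) > tol))
      stop("fractions do not sum to 1 for some (sample, tracer, pool)")
  }
  invisible(TRUE)
}
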