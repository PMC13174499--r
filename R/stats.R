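# Group-comparison statistics matching the conventions of tracing-study reporting:
# Kruskal-Wallis with Dunn's post hoc z-tests and Benjamini-Hochberg
# adjustment, and one-way ANOVA with Tukey's HSD. Omnibus and pairwise
# machinery come from stats (kruskal.test, aov, TukeyHSD, p.adjust);
# Dunn's rank-sum z-tests are computed here with mid-rank tie correction.

.checkGroups <- function(groups, minPer = 2) {
  if (!is.list(groups) || is.null(names(groups)) || length(groups) < 2)
    stop("groups must be a named list with >= 2 groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  small <- names(groups)[vapply(groups, length, integer(1)) < minPer]
  if (length(small))
    stop(sprintf("group(s) with fewer than %d values: %s", minPer,
                 paste(small, collapse = ", ")))
  groups
}

#' Kruskal-Wallis omnibus with Dunn's post hoc test and BH adjustment
#'
#' Nonparametric comparison across conditions: Kruskal-Wallis on the
#' pooled ranks, then Dunn's z-tests on mean rank differences for all
#' pairs (mid-ranks with tie correction), with Benjamini-Hochberg
#' adjustment across the pairwise family.
#'
#' @param groups named list of numeric vectors (one per condition); `NA`s
#'   are dropped
#' @return list with `statistic` (`"kruskal_wallis_dunn_bh"`), `omnibusP`,
#'   `pairwise` (data.frame: group1, group2, z, p, p_adjusted, method) and
#'   `groups`
#' @examples
#' g <- list(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5), c = c(8, 9, 10, 11))
#' compareGroupsKwDunnBH(g)$omnibusP
#' @export
compareGroupsKwDunnBH <- function(groups) {
  groups <- .checkGroups(groups)
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                   levels = names(groups))
  kw <- stats::kruskal.test(values, labels)
  N <- length(values)
  r <- rank(values)
  meanRank <- tapply(r, labels, mean)
  n <- tapply(r, labels, length)
  ties <- table(values)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / n[[a]] + 1 / n[[b]]))
    z[k] <- if (se > 0) (meanRank[[a]] - meanRank[[b]]) / se else 0
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         z = z, p = p,
                         p_adjusted = stats::p.adjust(p, "BH"),
                         method = "dunn_bh", stringsAsFactors = FALSE)
  list(statistic = "kruskal_wallis_dunn_bh",
       omnibusP = unname(kw$p.value), pairwise = pairwise,
       groups = groups)
}

#' One-way ANOVA with Tukey's honest significant difference
#'
#' @param groups named list of numeric vectors; `NA`s are dropped. All
#'   values identical (zero pooled variance) is an error.
#' @return list with `statistic` (`"anova_tukey_hsd"`), `omnibusP`, `F`,
#'   `pairwise` (data.frame: group1, group2, diff, p_adjusted, method) and
#'   `groups`
#' @examples
#' g <- list(a = rnorm(5), b = rnorm(5, 2))
#' compareGroupsAnovaTukey(g)$F
#' @export
compareGroupsAnovaTukey <- function(groups) {
  groups <- .checkGroups(groups)
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                   levels = names(groups))
  pooledVar <- sum(tapply(values, labels, function(v)
    sum((v - mean(v))^2)))
  if (pooledVar == 0) stop("zero pooled variance: groups are constant")
  fit <- stats::aov(values ~ labels)
  tab <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit)$labels
  pairNames <- strsplit(rownames(tuk), "-", fixed = TRUE)
  pairwise <- data.frame(
    group1 = vapply(pairNames, `[`, "", 2),
    group2 = vapply(pairNames, `[`, "", 1),
    diff = -tuk[, "diff"],
    p_adjusted = tuk[, "p adj"],
    method = "tukey_hsd", stringsAsFactors = FALSE)
  rownames(pairwise) <- NULL
  list(statistic = "anova_tukey_hsd",
       omnibusP = tab[["Pr(>F)"]][1], F = tab[["F value"]][1],
       pairwise = pairwise, groups = groups)
}

#' Compare a diagnostic index across conditions
#'
#' Convenience wrapper: splits a per-sample index table (as returned by
#' [normalizedFraction()] and friends) by condition, drops undefined
#' samples with a logged count, and runs the requested test.
#'
#' @param index data.frame with columns `condition`, `value` and
#'   optionally `defined`
#' @param test `"kw_dunn_bh"` or `"anova_tukey"`
#' @return as [compareGroupsKwDunnBH()] / [compareGroupsAnovaTukey()]
#' @export
compareIndexAcrossConditions <- function(index,
                                         test = c("kw_dunn_bh",
                                                  "anova_tukey")) {
  test <- match.arg(test)
  if ("defined" %in% names(index)) {
    drop <- !index$defined
    if (any(drop))
      message(sprintf("excluding %d undefined sample(s) from group tests",
                      sum(drop)))
    index <- index[!drop, , drop = FALSE]
  }
  groups <- split(index$value, index$condition, drop = TRUE)
  if (test == "kw_dunn_bh") compareGroupsKwDunnBH(groups) else
    compareGroupsAnovaTukey(groups)
}
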