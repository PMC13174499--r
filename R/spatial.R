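# Spatial (pixel-to-lineage) stage: aggregate pixel-level isotopologue
# signals into per-(embryo, lineage) means and compute cell-type fractional
# enrichment. Pixels are integer grid coordinates (origin top-left,
# 0-based); annotations are exact pixel matches and unannotated pixels are
# dropped. Embryos are the unit of replication: nothing here pools pixels
# across embryos.

.checkPixelTable <- function(pixels) {
  need <- c("embryo_id", "x", "y", "pool", "mass_shift", "intensity")
  miss <- setdiff(need, names(pixels))
  if (length(miss))
    stop(sprintf("pixel table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (any(pixels$intensity < 0)) stop("negative pixel intensity")
  key <- paste(pixels$embryo_id, pixels$x, pixels$y, pixels$pool,
               pixels$mass_shift)
  if (anyDuplicated(key))
    stop("duplicated (embryo, pixel, pool, mass_shift) rows")
  invisible(TRUE)
}

.checkAnnotation <- function(ann) {
  need <- c("embryo_id", "x", "y", "lineage")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop(sprintf("annotation missing column(s): %s",
                 paste(miss, collapse = ", ")))
  invisible(TRUE)
}

#' Aggregate pixel signals to embryo-by-lineage means
#'
#' Joins the pixel table with the lineage annotation on exact
#' `(embryo_id, x, y)` and averages intensities over the annotated pixels
#' of each `(embryo, lineage, pool, mass_shift)` group. Pixels without an
#' annotation are dropped (extracellular or unassigned clusters); annotated
#' positions without pixel data produce a warning and are omitted.
#'
#' @param pixels data.frame with columns `embryo_id`, `x`, `y`, `pool`,
#'   `mass_shift`, `intensity`
#' @param ann data.frame with columns `embryo_id`, `x`, `y`, `lineage`
#' @return data.frame with columns `embryo_id`, `lineage`, `pool`,
#'   `mass_shift`, `mean_intensity`, `n_pixels`
#' @export
aggregatePixels <- function(pixels, ann) {
  .checkPixelTable(pixels)
  .checkAnnotation(ann)
  merged <- merge(pixels, ann[, c("embryo_id", "x", "y", "lineage")],
                  by = c("embryo_id", "x", "y"))
  annotatedGroups <- unique(ann[, c("embryo_id", "lineage")])
  seen <- unique(merged[, c("embryo_id", "lineage")])
  lost <- !paste(annotatedGroups$embryo_id, annotatedGroups$lineage) %in%
    paste(seen$embryo_id, seen$lineage)
  if (any(lost))
    warning(sprintf("omitting %d annotated (embryo, lineage) group(s) with no pixel data",
                    sum(lost)))
  if (!nrow(merged)) stop("no annotated pixels")
  agg <- stats::aggregate(intensity ~ embryo_id + lineage + pool + mass_shift,
                          data = merged, FUN = mean)
  names(agg)[names(agg) == "intensity"] <- "mean_intensity"
  cnt <- stats::aggregate(intensity ~ embryo_id + lineage + pool + mass_shift,
                          data = merged, FUN = length)
  agg$n_pixels <- cnt$intensity[match(
    paste(agg$embryo_id, agg$lineage, agg$pool, agg$mass_shift),
    paste(cnt$embryo_id, cnt$lineage, cnt$pool, cnt$mass_shift))]
  agg[order(agg$embryo_id, agg$lineage, agg$pool, agg$mass_shift), ]
}

#' Cell-type fractional enrichment from aggregated intensities
#'
#' Converts mean isotopologue intensities into a MID-like enrichment
#' vector per `(embryo, lineage, pool)`: each isotopologue's share of the
#' metabolite's summed intensity in that cell type. Metabolites with zero
#' total intensity in a lineage are flagged undefined (`NA`), not zeroed.
#'
#' @param aggregated output of [aggregatePixels()]
#' @return data.frame with columns `embryo_id`, `lineage`, `pool`,
#'   `mass_shift`, `fraction`, `defined`
#' @export
clusterFractionEnrichment <- function(aggregated) {
  need <- c("embryo_id", "lineage", "pool", "mass_shift", "mean_intensity")
  miss <- setdiff(need, names(aggregated))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  key <- paste(aggregated$embryo_id, aggregated$lineage, aggregated$pool)
  totals <- tapply(aggregated$mean_intensity, key, sum)
  tot <- as.vector(totals[key])
  out <- aggregated[, c("embryo_id", "lineage", "pool", "mass_shift")]
  out$defined <- tot > 0
  out$fraction <- ifelse(out$defined, aggregated$mean_intensity / tot,
                         NA_real_)
  if (any(!out$defined))
    message(sprintf("%d all-zero (embryo, lineage, pool) group(s) flagged undefined",
                    sum(tapply(!out$defined, key, any))))
  out[, c("embryo_id", "lineage", "pool", "mass_shift", "fraction",
          "defined")]
}
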