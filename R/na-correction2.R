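# Table-level wrappers for the natural-abundance operators.

#' Natural-abundance correct a tidy MID table
#'
#' Applies [correctNA()] to every `(sample_id, tracer, pool)` group of a
#' measured table and returns corrected fractions
#' (`value_kind = "fraction"`).
#'
#' @param table tidy MID table of measured fractions or intensities
#' @param p13 natural 13C abundance
#' @return the corrected tidy MID table
#' @export
correctMidTable <- function(table, p13 = 0.0107) {
  validateMidTable(table)
  key <- interaction(table$sample_id, table$tracer, table$pool, drop = TRUE)
  models <- new.env(parent = emptyenv())
  out <- lapply(split(table, key), function(d) {
    d <- d[order(d$mass_shift), , drop = FALSE]
    n <- nrow(d) - 1
    k <- as.character(n)
    if (is.null(models[[k]])) models[[k]] <- buildCorrectionMatrix(n, p13)
    d$value <- correctNA(d$value, models[[k]])
    d$value_kind <- "fraction"
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
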