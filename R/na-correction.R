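# Natural 13C abundance handling, carbon-only: forward convolution (for
# generating synthetic "measured" data) and the inverse correction of
# measured MIDs by non-negativity-constrained least squares.

#' Build a natural-abundance correction model
#'
#' Constructs the `(n+1) x (n+1)` binomial convolution operator for a
#' metabolite with `n` carbons: column `j` (0-based, `j` true labels) is the
#' binomial distribution of additional apparent labels among the `n - j`
#' remaining carbons at natural 13C abundance `p13`.
#'
#' @param nCarbons number of carbons (>= 1)
#' @param p13 natural 13C abundance fraction (default 0.0107)
#' @return a [CorrectionModel-class]
#' @examples
#' buildCorrectionMatrix(2, 0.0107)@matrix
#' @export
buildCorrectionMatrix <- function(nCarbons, p13 = 0.0107) {
  if (nCarbons < 1) stop("nCarbons must be >= 1")
  if (p13 < 0 || p13 >= 1) stop("p13 must be in [0, 1)")
  n <- as.integer(nCarbons)
  m <- matrix(0, n + 1, n + 1)
  for (j in 0:n) {
    i <- j:n
    m[i + 1, j + 1] <- stats::dbinom(i - j, n - j, p13)
  }
  new("CorrectionModel", nCarbons = n, p13 = p13, matrix = m)
}

#' Convolve natural abundance onto a theoretical MID
#'
#' Forward model: what a mass spectrometer would report for a molecule
#' population with true MID `mid`, given that every 12C carbon independently
#' has probability `p13` of being a natural 13C.
#'
#' @param mid numeric MID vector `m_0..m_n`
#' @param model a [CorrectionModel-class] with matching `n`
#' @return the convolved MID (sums to the same total)
#' @export
convolveNA <- function(mid, model) {
  if (length(mid) != model@nCarbons + 1)
    stop("MID length does not match the correction model")
  as.vector(model@matrix %*% mid)
}

#' Correct a measured MID for natural abundance
#'
#' Solves `matrix %*% x = measured` for `x >= 0` by non-negative least
#' squares and renormalizes the solution to sum 1. The constrained solve
#' guarantees a simplex-valued result even on noisy inputs, where naive
#' matrix inversion can produce negative fractions.
#'
#' @param measured measured MID (fractions or raw intensities)
#' @param model a [CorrectionModel-class] with matching `n`
#' @return the corrected MID, non-negative and summing to 1
#' @examples
#' mod <- buildCorrectionMatrix(2)
#' x <- c(0.3, 0.3, 0.4)
#' correctNA(convolveNA(x, mod), mod)
#' @export
correctNA <- function(measured, model) {
  if (length(measured) != model@nCarbons + 1)
    stop("MID length does not match the correction model")
  if (all(measured == 0)) stop("measured vector is all zero")
  if (any(measured < 0)) stop("measured intensities must be non-negative")
  x <- pracma::lsqnonneg(model@matrix, measured)$x
  s <- sum(x)
  if (s <= 0) stop("correction produced an all-zero solution")
  x / s
}
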