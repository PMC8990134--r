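# ---------------------------------------------------------------------------
# Mutual information by adaptive partitioning of the rank space
# (Darbellay-Vajda): recursively quarter a cell while a chi-square test
# rejects uniformity of the four quadrant counts. After rank transformation
# the marginals are uniform, so the independence expectation of a cell is the
# product of its side fractions.
# ---------------------------------------------------------------------------

#' Mutual information between two series, in bits
#'
#' Adaptive-partitioning estimator: both variables are rank-transformed, the
#' unit square is split recursively into four equal quadrants while a
#' chi-square test (alpha = 0.05, 3 df) rejects uniformity of the quadrant
#' counts and at least `min_cell` points remain per prospective quadrant; MI
#' is summed over the final cells and floored at zero.
#'
#' @param x,y Numeric vectors of equal length (`n >= 500` recommended for
#'   stable estimates).
#' @param min_cell Minimum expected points per quadrant to allow a further
#'   split (default 8).
#' @return Estimated mutual information in bits (>= 0). Returns 0 for
#'   constant inputs.
#' @export
mutual_information <- function(x, y, min_cell = 8) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 8) return(0)
  if (stats::sd(x) < 1e-14 || stats::sd(y) < 1e-14) return(0)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  crit <- stats::qchisq(0.95, df = 3)
  mi <- 0
  # stack of cells: x0, x1, y0, y1 (rank-space bounds) and point indices
  stack <- list(list(x0 = 0, x1 = n, y0 = 0, y1 = n, idx = seq_len(n)))
  while (length(stack) > 0) {
    cell <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    idx <- cell$idx
    nc <- length(idx)
    if (nc == 0) next
    xm <- (cell$x0 + cell$x1) / 2
    ym <- (cell$y0 + cell$y1) / 2
    splittable <- nc >= 4 * min_cell &&
      (cell$x1 - cell$x0) > 2 && (cell$y1 - cell$y0) > 2
    if (splittable) {
      lx <- rx[idx] <= xm
      ly <- ry[idx] <= ym
      counts <- c(sum(lx & ly), sum(lx & !ly), sum(!lx & ly), sum(!lx & !ly))
      expd <- nc / 4
      chi2 <- sum((counts - expd)^2) / expd
      if (chi2 > crit) {
        stack[[length(stack) + 1]] <- list(x0 = cell$x0, x1 = xm,
                                           y0 = cell$y0, y1 = ym,
                                           idx = idx[lx & ly])
        stack[[length(stack) + 1]] <- list(x0 = cell$x0, x1 = xm,
                                           y0 = ym, y1 = cell$y1,
                                           idx = idx[lx & !ly])
        stack[[length(stack) + 1]] <- list(x0 = xm, x1 = cell$x1,
                                           y0 = cell$y0, y1 = ym,
                                           idx = idx[!lx & ly])
        stack[[length(stack) + 1]] <- list(x0 = xm, x1 = cell$x1,
                                           y0 = ym, y1 = cell$y1,
                                           idx = idx[!lx & !ly])
        next
      }
    }
    p <- nc / n
    px <- (cell$x1 - cell$x0) / n
    py <- (cell$y1 - cell$y0) / n
    mi <- mi + p * log2(p / (px * py))
  }
  max(mi, 0)
}
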