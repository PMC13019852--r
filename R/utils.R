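#' Derive per-stage seeds from a master seed
#'
#' A single master seed is fanned out deterministically so stages can be rerun
#' in isolation with the same stream. Derived seeds stay below 2^31.
#'
#' @param master_seed integer master seed.
#' @param stage character stage label.
#' @return integer seed for the stage.
#' @export
stage_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 7919 + h * 104729) %% 2147483647)
}

# standard error of the mean
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Raster a filled disk into a logical matrix
#'
#' Pixel (i, j) is inside when its centre lies within `radius` of (cy, cx),
#' 0-based row-major convention with half-open pixel grid.
#'
#' @param nrow,ncol raster dimensions in pixels.
#' @param cy,cx centre (row, column), 1-based pixel centres.
#' @param radius radius in pixels.
#' @return logical matrix.
#' @keywords internal
disk_mask <- function(nrow, ncol, cy, cx, radius) {
  if (radius < 0.5) {
    m <- matrix(FALSE, nrow, ncol)
    ri <- round(cy); ci <- round(cx)
    if (ri >= 1 && ri <= nrow && ci >= 1 && ci <= ncol) m[ri, ci] <- TRUE
    return(m)
  }
  rows <- matrix(seq_len(nrow), nrow, ncol)
  cols <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  (rows - cy)^2 + (cols - cx)^2 <= radius^2
}
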