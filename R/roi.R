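#' Representative ROI time series by correlation-strength weighting
#'
#' Collapses a block of voxel time series within a region of interest into one
#' representative series. Each voxel's strength is the sum of its Pearson
#' correlations with every other voxel in the block (self-correlations
#' excluded); strengths are floored at zero, normalized to sum to one, and the
#' representative is the weight-sum of the voxel series.
#'
#' @param block `n_voxels x n_samples` numeric matrix; no constant rows.
#' @return List with `series` (length `n_samples`), `weights` (sum 1),
#'   `strengths`, and the voxel correlation matrix `corr`.
#' @export
roiRepresentative <- function(block) {
  if (!is.matrix(block)) block <- matrix(block, nrow = 1)
  if (ncol(block) < 2) stop("need at least 2 samples", call. = FALSE)
  v <- apply(block, 1, stats::var)
  if (any(v == 0)) stop("constant voxel row: correlation undefined", call. = FALSE)
  nv <- nrow(block)
  if (nv == 1L)
    return(list(series = as.numeric(block[1, ]), weights = 1,
                strengths = 1, corr = matrix(1, 1, 1)))
  cm <- cor(t(block))
  strengths <- rowSums(cm) - 1            # exclude the self term
  floored <- pmax(strengths, 0)
  if (any(strengths < 0))
    warning("negative voxel strengths floored at 0 before normalization")
  if (sum(floored) <= 0)
    stop("total voxel strength is non-positive; block has no coherent signal",
         call. = FALSE)
  w <- floored / sum(floored)
  list(series = as.numeric(crossprod(block, w)), weights = w,
       strengths = strengths, corr = cm)
}

#' Windowed representative ROI time series
#'
#' Recomputes [roiRepresentative()] independently within each analysis window,
#' so the voxel weighting can track nonstationary changes in which voxels
#' dominate the region.
#'
#' @param block `n_voxels x n_samples` matrix.
#' @param starts 1-based window start samples.
#' @param width Window width in samples.
#' @return List of per-window results as in [roiRepresentative()], plus
#'   `starts` and `width`.
#' @export
roiRepresentativeWindowed <- function(block, starts, width) {
  if (!is.matrix(block)) block <- matrix(block, nrow = 1)
  if (any(starts < 1) || any(starts + width - 1 > ncol(block)))
    stop("windows must fit within the recording", call. = FALSE)
  wins <- lapply(starts, function(s0)
    roiRepresentative(block[, s0:(s0 + width - 1), drop = FALSE]))
  list(windows = wins, starts = starts, width = as.integer(width))
}
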