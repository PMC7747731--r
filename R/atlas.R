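#' Build a probabilistic atlas by majority voting
#'
#' Accumulates, per voxel and label, the number of subjects carrying that
#' label across a list of spatially aligned label maps, and assigns each voxel
#' the label with the highest count (majority voting). Background participates
#' in the vote: a voxel whose background count exceeds or ties every label
#' count stays background, so fringe voxels covered by only a minority of
#' subjects do not inflate the fused subunits. Ties between labels break
#' toward the smallest label id.
#'
#' @param label_maps list of aligned 3-D integer label arrays (0 background,
#'   1..L subunits).
#' @param label_names names of labels 1..L (defaults to the four hypothalamic
#'   subunits when L = 4).
#' @return A [ProbabilisticAtlas-class].
#' @export
buildProbabilisticAtlas <- function(label_maps, label_names = NULL) {
  if (length(label_maps) < 1) stop("need at least one label map")
  dims <- lapply(label_maps, dim)
  for (d in dims[-1])
    if (!identical(d, dims[[1]])) stop("grid mismatch across label maps")
  L <- max(1L, max(vapply(label_maps, max, numeric(1))))
  if (is.null(label_names))
    label_names <- if (L == 4) .subunitNames else paste0("label", seq_len(L))
  counts <- array(0L, c(dims[[1]], L))
  nvox <- prod(dims[[1]])
  for (m in label_maps) {
    lab <- as.integer(m)
    sel <- lab > 0
    idx <- which(sel) + (lab[sel] - 1L) * nvox
    counts[idx] <- counts[idx] + 1L
  }
  cmat <- matrix(counts, nvox, L)
  winner <- max.col(cmat, ties.method = "first")
  best <- cmat[cbind(seq_len(nvox), winner)]
  bg <- length(label_maps) - rowSums(cmat)
  winner[best == 0L | bg >= best] <- 0L
  new("ProbabilisticAtlas", counts = counts,
      labelMap = array(as.integer(winner), dims[[1]]),
      nSubjects = length(label_maps), labelNames = label_names)
}

#' Threshold a probabilistic atlas
#'
#' Sets voxels whose winning label count is below `min_count` to background,
#' yielding a more conservative atlas mask.
#'
#' @param atlas a [ProbabilisticAtlas-class].
#' @param min_count minimal subject count (0..n_subjects).
#' @return 3-D integer label array.
#' @export
thresholdAtlas <- function(atlas, min_count) {
  if (min_count < 0 || min_count > atlas@nSubjects)
    stop("min_count must lie in [0, n_subjects]")
  lm <- atlas@labelMap
  nvox <- length(lm)
  win <- as.integer(lm)
  has <- win > 0L
  wc <- integer(nvox)
  wc[has] <- atlas@counts[which(has) + (win[has] - 1L) * nvox]
  lm[has & wc < min_count] <- 0L
  lm
}

#' Dice overlap coefficient
#'
#' 2 |A intersect B| / (|A| + |B|) for two binary masks on the same grid. Two
#' empty masks are defined as perfectly overlapping (Dice 1, reported).
#'
#' @param a,b logical (or 0/1) arrays of identical dimension.
#' @return Scalar in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  a <- a > 0; b <- b > 0
  .stopIfGridMismatch(dim(a), dim(b), what = "masks")
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    message("diceCoefficient: both masks empty, defining Dice = 1")
    return(1)
  }
  2 * sum(a & b) / denom
}

#' Validate a parcellation against the atlas
#'
#' Computes one Dice coefficient per anatomical subunit between the subject's
#' label region and the atlas max-count region.
#'
#' @param subject_labels 3-D integer label array aligned with the atlas.
#' @param atlas a [ProbabilisticAtlas-class].
#' @return `data.frame` with columns `label`, `name`, `dice`,
#'   `missing_in_subject`, `missing_in_atlas`.
#' @export
validateAgainstAtlas <- function(subject_labels, atlas) {
  .stopIfGridMismatch(dim(subject_labels), dim(atlas@labelMap),
                      what = "subject and atlas label maps")
  L <- dim(atlas@counts)[4]
  rows <- lapply(seq_len(L), function(l) {
    a <- subject_labels == l
    b <- atlas@labelMap == l
    data.frame(label = l, name = atlas@labelNames[l],
               dice = diceCoefficient(a, b),
               missing_in_subject = !any(a), missing_in_atlas = !any(b))
  })
  do.call(rbind, rows)
}
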