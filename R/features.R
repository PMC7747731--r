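#' Build the standardized clustering feature matrix
#'
#' Assembles one row per in-mask voxel: the voxel's world coordinates (mm,
#' via the affine) followed by its ODF spherical-harmonic coefficients. Every
#' column is standardized to mean 0 / SD 1 so that voxel size and coefficient
#' scale do not bias the clustering metric; constant columns (SD = 0, e.g. the
#' unit-mass l = 0 coefficient) are set to all-zeros and reported. The two
#' blocks enter the k-means distance with weights `w_spatial` and `w_odf`
#' (default 0.5 each).
#'
#' @param mask 3-D logical array of clustered voxels.
#' @param odfs an [OdfField-class] covering the mask.
#' @param affine 4x4 voxel-to-world matrix.
#' @param w_spatial,w_odf block weights, summing to 1.
#' @return A [FeatureMatrix-class].
#' @export
buildFeatures <- function(mask, odfs, affine, w_spatial = 0.5, w_odf = 0.5) {
  .stopIfGridMismatch(dim(mask), odfs@dim, what = "mask and ODF field")
  if (abs(w_spatial + w_odf - 1) > 1e-12) stop("block weights must sum to 1")
  vox <- which(mask, arr.ind = TRUE)
  odf_lin <- (odfs@voxels[, 3] - 1L) * prod(odfs@dim[1:2]) +
    (odfs@voxels[, 2] - 1L) * odfs@dim[1] + odfs@voxels[, 1]
  row_of <- match((vox[, 3] - 1L) * prod(odfs@dim[1:2]) +
                    (vox[, 2] - 1L) * odfs@dim[1] + vox[, 1], odf_lin)
  if (anyNA(row_of)) stop("ODF field does not cover the mask")
  pos <- .voxelToWorld(vox, affine)
  x <- cbind(pos, odfs@coefficients[row_of, , drop = FALSE])
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  const <- scl <= .Machine$double.eps * 100
  if (any(const))
    message(sprintf("buildFeatures: %d constant columns zeroed", sum(const)))
  xs <- sweep(x, 2, ctr, `-`)
  xs <- sweep(xs, 2, ifelse(const, 1, scl), `/`)
  xs[, const] <- 0
  scl[const] <- 0
  colnames(xs) <- c("x", "y", "z", paste0("sh", seq_len(ncol(x) - 3L)))
  new("FeatureMatrix", x = xs, center = ctr, scale = scl,
      wSpatial = w_spatial, wOdf = w_odf, voxels = vox,
      dim = dim(mask), affine = affine)
}
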