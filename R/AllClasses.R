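#' @import methods
NULL

#' Gradient table for a diffusion acquisition
#'
#' One b-value and one unit gradient direction per acquired volume, following
#' the FSL text convention (`bvals` a single row, `bvecs` three rows). Volumes
#' with `bval == 0` carry an all-zero direction.
#'
#' @slot bvals numeric vector of b-values (s/mm^2), one per volume.
#' @slot bvecs numeric matrix, volumes x 3, unit direction per nonzero-b volume.
#' @export
setClass("GradientTable",
  representation(bvals = "numeric", bvecs = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@bvals) != nrow(object@bvecs))
      msg <- c(msg, "bvals and bvecs describe different numbers of volumes")
    if (ncol(object@bvecs) != 3L)
      msg <- c(msg, "bvecs must have 3 columns")
    nz <- object@bvals > 0
    if (any(nz)) {
      nrm <- sqrt(rowSums(object@bvecs[nz, , drop = FALSE]^2))
      if (any(abs(nrm - 1) > 1e-6))
        msg <- c(msg, "nonzero-b directions must be unit-norm (within 1e-6)")
    }
    if (any(!nz)) {
      if (any(abs(object@bvecs[!nz, , drop = FALSE]) > 0))
        msg <- c(msg, "b = 0 volumes must have all-zero directions")
    }
    if (length(msg)) msg else TRUE
  })

#' Multi-tensor phantom specification
#'
#' Describes a small voxel grid carrying ground-truth subunit labels, one set
#' of diffusion-tensor compartments per labelled region, an isotropic CSF rim
#' and an isotropic background, from which noise-free DWI signal is simulated
#' under the multi-tensor model S(b,g) = S0 * sum_i f_i exp(-b g' D_i g).
#'
#' @slot dim integer grid shape (3).
#' @slot voxelSize voxel edge length in mm (isotropic).
#' @slot labels 3-D integer array, 0 background, 1..n_regions subunits.
#' @slot regions named list, one entry per label id, each a list of
#'   compartments `list(orientation =, fraction =, evals =)` with eigenvalues
#'   in mm^2/s.
#' @slot csfMask 3-D logical array marking the CSF rim.
#' @slot csfDiffusivity,backgroundDiffusivity isotropic diffusivities (mm^2/s).
#' @slot S0 non-diffusion-weighted signal level (arbitrary units).
#' @slot snr default signal-to-noise ratio S0/sigma for Rician noise.
#' @slot seed default random seed.
#' @export
setClass("PhantomSpec",
  representation(dim = "integer", voxelSize = "numeric", labels = "array",
                 regions = "list", csfMask = "array",
                 csfDiffusivity = "numeric", backgroundDiffusivity = "numeric",
                 S0 = "numeric", snr = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@labels), object@dim))
      msg <- c(msg, "labels array does not match grid dim")
    if (!identical(dim(object@csfMask), object@dim))
      msg <- c(msg, "csfMask does not match grid dim")
    ids <- sort(unique(as.integer(object@labels[object@labels > 0])))
    if (length(object@regions) < length(ids))
      msg <- c(msg, "regions must define parameters for every label id")
    for (r in object@regions) {
      fr <- vapply(r, function(cp) cp$fraction, numeric(1))
      if (abs(sum(fr) - 1) > 1e-9)
        msg <- c(msg, "compartment volume fractions must sum to 1 (within 1e-9)")
      ev <- unlist(lapply(r, function(cp) cp$evals))
      if (any(ev <= 0)) msg <- c(msg, "tensor eigenvalues must be positive")
    }
    if (any(object@csfMask & object@labels > 0))
      msg <- c(msg, "CSF rim must be disjoint from labelled regions")
    for (id in ids) {
      if (!.isConnected6(object@labels == id))
        msg <- c(msg, sprintf("region %d is not 6-connected", id))
    }
    if (length(msg)) msg else TRUE
  })

#' Synthetic diffusion-weighted subject
#'
#' A simulated acquisition: 4-D DWI array (possibly empty when only geometry
#' and covariates were generated), gradient table, voxel-to-world affine,
#' ground-truth label map, CSF probability map, and subject covariates.
#'
#' @slot dwi 4-D numeric array (x, y, z, volume); may have zero extent.
#' @slot gtab a [GradientTable-class].
#' @slot affine 4x4 voxel-to-world matrix (mm).
#' @slot labels 3-D integer ground-truth label array.
#' @slot csf 3-D CSF probability array in [0, 1].
#' @slot covariates named list (bmi, age, sex, fitness, icv, ...).
#' @export
setClass("SyntheticSubject",
  representation(dwi = "array", gtab = "GradientTable", affine = "matrix",
                 labels = "array", csf = "array", covariates = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@dwi) && any(object@dwi < 0))
      msg <- c(msg, "DWI signal must be non-negative")
    if (length(object@dwi) &&
        !identical(dim(object@dwi)[1:3], dim(object@labels)))
      msg <- c(msg, "DWI grid does not match label map")
    if (any(object@csf < 0 | object@csf > 1))
      msg <- c(msg, "CSF probabilities must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Diffusion-tensor fit result
#'
#' Per-voxel eigenvalues (sorted decreasing), principal eigenvector, and FA/MD
#' maps on the full grid (NA outside the fitted mask).
#'
#' @slot evals n_voxels x 3 matrix, lambda1 >= lambda2 >= lambda3 (mm^2/s).
#' @slot evecs n_voxels x 3 matrix of unit principal eigenvectors.
#' @slot fa,md 3-D arrays (NA outside mask).
#' @slot voxels n_voxels x 3 integer matrix of 1-based voxel indices.
#' @slot mask 3-D logical array of fitted voxels.
#' @export
setClass("TensorFit",
  representation(evals = "matrix", evecs = "matrix", fa = "array",
                 md = "array", voxels = "matrix", mask = "array"),
  validity = function(object) {
    msg <- character()
    fam <- object@fa[object@mask]
    if (any(fam < -1e-9 | fam > 1 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "FA must lie in [0, 1]")
    mdv <- rowMeans(object@evals)
    if (any(abs(mdv - object@md[object@mask]) > 1e-12, na.rm = TRUE))
      msg <- c(msg, "MD must equal the eigenvalue mean")
    if (length(msg)) msg else TRUE
  })

#' Field of spherical-harmonic ODF coefficients
#'
#' Per-voxel coefficient vectors of a real, symmetric (even-order-only)
#' spherical-harmonic expansion of the diffusion ODF. With `lmax = 6` each
#' voxel carries (lmax+1)(lmax+2)/2 = 28 coefficients. ODFs are unit mass:
#' the l = 0 coefficient equals 1/(2*sqrt(pi)).
#'
#' @slot coefficients n_voxels x R matrix of SH coefficients.
#' @slot lmax maximum (even) spherical-harmonic order.
#' @slot basis character identifier of the basis convention.
#' @slot voxels n_voxels x 3 integer matrix of 1-based voxel indices.
#' @slot dim grid shape the voxel indices refer to.
#' @export
setClass("OdfField",
  representation(coefficients = "matrix", lmax = "integer", basis = "character",
                 voxels = "matrix", dim = "integer"),
  validity = function(object) {
    msg <- character()
    R <- (object@lmax + 1) * (object@lmax + 2) / 2
    if (ncol(object@coefficients) != R)
      msg <- c(msg, sprintf("expected %d coefficients for lmax = %d", R, object@lmax))
    if (nrow(object@coefficients) != nrow(object@voxels))
      msg <- c(msg, "one coefficient row per voxel required")
    if (nrow(object@coefficients) &&
        any(abs(object@coefficients[, 1] - 1 / (2 * sqrt(pi))) > 1e-6))
      msg <- c(msg, "l = 0 coefficient must equal 1/(2*sqrt(pi)) (unit-mass ODF)")
    if (length(msg)) msg else TRUE
  })

#' Standardized clustering feature matrix
#'
#' One row per in-mask voxel: a 3-column spatial block (world mm before
#' standardization) followed by an R-column ODF coefficient block, both
#' column-standardized to mean 0 / SD 1, with block weights used by the
#' weighted k-means distance.
#'
#' @slot x n_voxels x (3 + R) standardized feature matrix.
#' @slot center,scale per-column standardization parameters.
#' @slot wSpatial,wOdf block weights (sum to 1).
#' @slot voxels n_voxels x 3 integer voxel indices; @slot dim grid shape.
#' @slot affine 4x4 voxel-to-world matrix.
#' @export
setClass("FeatureMatrix",
  representation(x = "matrix", center = "numeric", scale = "numeric",
                 wSpatial = "numeric", wOdf = "numeric", voxels = "matrix",
                 dim = "integer", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (abs(object@wSpatial + object@wOdf - 1) > 1e-12)
      msg <- c(msg, "block weights must sum to 1")
    live <- object@scale > 0
    if (nrow(object@x) > 1 && any(live)) {
      mu <- colMeans(object@x[, live, drop = FALSE])
      sd_ <- apply(object@x[, live, drop = FALSE], 2, stats::sd)
      if (any(abs(mu) > 1e-8) || any(abs(sd_ - 1) > 1e-8))
        msg <- c(msg, "non-constant columns must be standardized to mean 0, SD 1")
    }
    if (length(msg)) msg else TRUE
  })

#' Weighted k-means clustering result
#'
#' @slot labels integer vector of per-voxel cluster labels in 1..k.
#' @slot centroids k x (3 + R) matrix in standardized feature space.
#' @slot centroidMm k x 3 matrix of centroid world coordinates (mm).
#' @slot objective final within-cluster weighted sum of squared distances.
#' @slot objectiveTrace per-iteration objective values.
#' @slot iterations Lloyd iterations used.
#' @slot db Davies-Bouldin score (NA until computed).
#' @slot anatomicalMap named character: cluster id -> anatomical subunit, or
#'   a single "unclassifiable"; empty until labelling is applied.
#' @slot voxels,dim voxel bookkeeping; @slot wSpatial,wOdf metric weights.
#' @slot seed seed used for initialization (NA if externally initialized).
#' @export
setClass("ClusterResult",
  representation(labels = "integer", centroids = "matrix", centroidMm = "matrix",
                 objective = "numeric", objectiveTrace = "numeric",
                 iterations = "integer", db = "numeric",
                 anatomicalMap = "character", voxels = "matrix", dim = "integer",
                 wSpatial = "numeric", wOdf = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    k <- nrow(object@centroids)
    if (!all(seq_len(k) %in% object@labels))
      msg <- c(msg, "every cluster must be nonempty")
    if (length(object@labels) != nrow(object@voxels))
      msg <- c(msg, "one label per voxel required")
    if (length(msg)) msg else TRUE
  })

#' Probabilistic subunit atlas
#'
#' Voxelwise per-label subject counts plus the majority-vote (max-count)
#' label map.
#'
#' @slot counts 4-D integer array (x, y, z, label).
#' @slot labelMap 3-D integer max-count label map (0 where no votes).
#' @slot nSubjects number of fused subjects.
#' @slot labelNames names of label ids 1..L.
#' @export
setClass("ProbabilisticAtlas",
  representation(counts = "array", labelMap = "array", nSubjects = "integer",
                 labelNames = "character"),
  validity = function(object) {
    msg <- character()
    tot <- apply(object@counts, 1:3, sum)
    if (any(tot > object@nSubjects))
      msg <- c(msg, "per-voxel label counts cannot exceed the number of subjects")
    if (!identical(dim(object@counts)[1:3], dim(object@labelMap)))
      msg <- c(msg, "counts and label map grids differ")
    if (length(msg)) msg else TRUE
  })
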