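#' @include AllClasses.R
NULL

#' Accessors for hypoparc objects
#'
#' `bvals()` and `bvecs()` return the gradient table columns; `nVolumes()` the
#' number of acquired volumes. `odfCoefficients()` returns the voxel x
#' coefficient matrix of an [OdfField-class]. `clusterLabels()` returns
#' per-voxel cluster assignments, `centroids()` the standardized centroids,
#' `anatomicalMap()` the cluster-to-subunit mapping. `labelMap()` materializes
#' a result as a 3-D integer array; `voxelIndices()` the n x 3 voxel index
#' matrix.
#'
#' @param x an object.
#' @param ... passed to methods.
#' @return The extracted component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bvals", function(x) standardGeneric("bvals"))
#' @rdname accessors
#' @export
setGeneric("bvecs", function(x) standardGeneric("bvecs"))
#' @rdname accessors
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))
#' @rdname accessors
#' @export
setGeneric("odfCoefficients", function(x) standardGeneric("odfCoefficients"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname accessors
#' @export
setGeneric("anatomicalMap", function(x) standardGeneric("anatomicalMap"))
#' @rdname accessors
#' @export
setGeneric("labelMap", function(x, ...) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setGeneric("voxelIndices", function(x) standardGeneric("voxelIndices"))

#' @rdname accessors
setMethod("bvals", "GradientTable", function(x) x@bvals)
#' @rdname accessors
setMethod("bvecs", "GradientTable", function(x) x@bvecs)
#' @rdname accessors
setMethod("nVolumes", "GradientTable", function(x) length(x@bvals))
#' @rdname accessors
setMethod("odfCoefficients", "OdfField", function(x) x@coefficients)
#' @rdname accessors
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)
#' @rdname accessors
setMethod("centroids", "ClusterResult", function(x) x@centroids)
#' @rdname accessors
setMethod("anatomicalMap", "ClusterResult", function(x) x@anatomicalMap)
#' @rdname accessors
setMethod("voxelIndices", "ClusterResult", function(x) x@voxels)
#' @rdname accessors
setMethod("voxelIndices", "OdfField", function(x) x@voxels)
#' @rdname accessors
setMethod("voxelIndices", "FeatureMatrix", function(x) x@voxels)

#' @rdname accessors
#' @param anatomical if `TRUE`, relabel clusters to the fixed anatomical ids
#'   1 = anterior-superior, 2 = anterior-inferior, 3 = intermediate,
#'   4 = posterior (requires a prior [labelClustersAnatomically()] call).
setMethod("labelMap", "ClusterResult", function(x, anatomical = FALSE) {
  out <- array(0L, x@dim)
  lab <- x@labels
  if (anatomical) {
    if (!length(x@anatomicalMap))
      stop("no anatomical mapping present; run labelClustersAnatomically() first")
    if (identical(unname(x@anatomicalMap), "unclassifiable"))
      stop("cluster configuration was unclassifiable; no anatomical label map")
    ids <- match(x@anatomicalMap, .subunitNames)
    lab <- ids[x@labels]
  }
  out[cbind(x@voxels)] <- as.integer(lab)
  out
})
#' @rdname accessors
setMethod("labelMap", "ProbabilisticAtlas", function(x, ...) x@labelMap)

setMethod("show", "GradientTable", function(object) {
  nz <- object@bvals > 0
  shells <- sort(unique(round(object@bvals[nz])))
  cat(sprintf("GradientTable: %d volumes (%d b=0, %d diffusion-weighted)\n",
              length(object@bvals), sum(!nz), sum(nz)))
  cat("  shells (s/mm^2):", paste(shells, collapse = ", "), "\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s grid at %.2f mm, %d regions, %d tissue voxels, %d CSF rim voxels\n",
              paste(object@dim, collapse = "x"), object@voxelSize,
              length(object@regions), sum(object@labels > 0), sum(object@csfMask)))
  cat(sprintf("  S0 = %g, default SNR = %g\n", object@S0, object@snr))
})

setMethod("show", "SyntheticSubject", function(object) {
  cat(sprintf("SyntheticSubject: %s grid, %d volumes%s\n",
              paste(dim(object@labels), collapse = "x"), nVolumes(object@gtab),
              if (length(object@dwi)) "" else " (DWI not simulated)"))
  if (length(object@covariates))
    cat("  covariates:", paste(names(object@covariates), collapse = ", "), "\n")
})

setMethod("show", "TensorFit", function(object) {
  cat(sprintf("TensorFit: %d voxels; FA %.3f-%.3f, MD %.2e-%.2e mm^2/s\n",
              nrow(object@evals), min(object@fa, na.rm = TRUE),
              max(object@fa, na.rm = TRUE), min(object@md, na.rm = TRUE),
              max(object@md, na.rm = TRUE)))
})

setMethod("show", "OdfField", function(object) {
  cat(sprintf("OdfField: %d voxels, lmax = %d (%d SH coefficients), basis '%s'\n",
              nrow(object@coefficients), object@lmax,
              ncol(object@coefficients), object@basis))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d voxels x (3 spatial + %d ODF) standardized features, weights %.2f/%.2f\n",
              nrow(object@x), ncol(object@x) - 3L, object@wSpatial, object@wOdf))
})

setMethod("show", "ClusterResult", function(object) {
  k <- nrow(object@centroids)
  cat(sprintf("ClusterResult: k = %d over %d voxels, objective %.4f, %d iterations%s\n",
              k, length(object@labels), object@objective, object@iterations,
              if (is.na(object@db)) "" else sprintf(", DB = %.4f", object@db)))
  if (length(object@anatomicalMap))
    cat("  anatomical labels:", paste(object@anatomicalMap, collapse = ", "), "\n")
})

setMethod("show", "ProbabilisticAtlas", function(object) {
  cat(sprintf("ProbabilisticAtlas: %s grid, %d labels, %d subjects fused\n",
              paste(dim(object@labelMap), collapse = "x"),
              dim(object@counts)[4], object@nSubjects))
})
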