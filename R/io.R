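# Thin NIfTI-1 wrappers around RNifti, keeping a plain-array-plus-affine
# contract at the module boundaries.

#' Read and write NIfTI-1 volumes
#'
#' `readNiftiVolume()` returns a list with the data `array` and the 4x4
#' voxel-to-world `affine`; `writeNiftiVolume()` writes an array with a given
#' affine (sform and qform set identically).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param x numeric/integer array (3-D or 4-D).
#' @param affine 4x4 voxel-to-world matrix (mm, 0-based voxel convention).
#' @param datatype storage datatype passed to RNifti (default `"auto"`).
#' @return `readNiftiVolume()`: list(data, affine); `writeNiftiVolume()`: the
#'   path, invisibly.
#' @export
readNiftiVolume <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))
  list(data = data, affine = unclass(aff)[1:4, 1:4])
}

#' @rdname readNiftiVolume
#' @export
writeNiftiVolume <- function(x, affine, path, datatype = "auto") {
  img <- RNifti::asNifti(x)
  xf <- structure(affine, code = 2L)
  RNifti::sform(img) <- xf
  RNifti::qform(img) <- xf
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# Write a subject covariate table as TSV with the canonical header.
writeCovariatesTsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readCovariatesTsv <- function(path) {
  if (!file.exists(path)) stop("covariates file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
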