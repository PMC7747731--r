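#' Refine a hypothalamus mask by CSF and FA exclusion
#'
#' Removes partial-volume and white-matter contamination from a binary
#' hypothalamus mask: voxels with CSF probability strictly greater than
#' `csf_thresh` (default 15%, excluding third-ventricle contamination) or FA
#' strictly greater than `fa_thresh` (default 0.55, excluding fornix and optic
#' tract) are dropped. Thresholds are inclusive-keep. Counts removed per
#' criterion are reported via `message()`.
#'
#' @param mask 3-D logical (or 0/1) array.
#' @param csf_prob 3-D CSF probability array in [0, 1].
#' @param fa_map 3-D FA array (NA treated as not-computed and kept).
#' @param csf_thresh CSF probability threshold (default 0.15).
#' @param fa_thresh FA threshold (default 0.55).
#' @return 3-D logical array, the refined mask.
#' @export
refineMask <- function(mask, csf_prob, fa_map, csf_thresh = 0.15,
                       fa_thresh = 0.55) {
  mask <- mask > 0
  .stopIfGridMismatch(dim(mask), dim(csf_prob), dim(fa_map),
                      what = "mask, CSF and FA maps")
  csf_ok <- csf_prob <= csf_thresh
  fa_ok <- is.na(fa_map) | fa_map <= fa_thresh
  out <- mask & csf_ok & fa_ok
  message(sprintf("refineMask: removed %d voxels by CSF > %g, %d by FA > %g (of %d)",
                  sum(mask & !csf_ok), csf_thresh,
                  sum(mask & csf_ok & !fa_ok), fa_thresh, sum(mask)))
  if (!any(out)) stop("mask fully excluded by thresholds")
  out
}
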