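#' Assemble and validate a single-subject pipeline configuration
#'
#' Collects file paths and parameters for [runSubject()]. All referenced input
#' paths must exist. Parameters mirror the CLI flags of `inst/cli/hypoparc.R`.
#'
#' @param dwi,bvals,bvecs,mask,csf input file paths (NIfTI-1 / FSL text).
#' @param out_dir output directory (`NULL` for in-memory results only).
#' @param hemisphere tag recorded in outputs ("left"/"right").
#' @param b_target,b_tol shell extraction parameters (s/mm^2).
#' @param lmax,reg_lambda CSA ODF parameters.
#' @param bootstrap use residual-bootstrap averaged ODFs; `n_samples`
#'   replicates.
#' @param n_samples bootstrap replicates (default 50).
#' @param csf_thresh,fa_thresh mask refinement thresholds.
#' @param k number of clusters, or `"auto"` for Davies-Bouldin selection.
#' @param k_range candidate k values when `k = "auto"`.
#' @param n_init_runs spatial initialization runs (default 5000).
#' @param w_spatial,w_odf block weights (default 0.5/0.5).
#' @param seed integer seed controlling all randomness.
#' @return A validated `list` of class `"PipelineConfig"`.
#' @export
makePipelineConfig <- function(dwi, bvals, bvecs, mask, csf, out_dir = NULL,
                               hemisphere = "left", b_target = 1000,
                               b_tol = 100, lmax = 6L, reg_lambda = 0.006,
                               bootstrap = FALSE, n_samples = 50L,
                               csf_thresh = 0.15, fa_thresh = 0.55,
                               k = "auto", k_range = 2:6, n_init_runs = 5000L,
                               w_spatial = 0.5, w_odf = 0.5, seed = 1L) {
  cfg <- list(dwi = dwi, bvals = bvals, bvecs = bvecs, mask = mask, csf = csf,
              out_dir = out_dir, hemisphere = hemisphere, b_target = b_target,
              b_tol = b_tol, lmax = as.integer(lmax), reg_lambda = reg_lambda,
              bootstrap = bootstrap, n_samples = as.integer(n_samples),
              csf_thresh = csf_thresh, fa_thresh = fa_thresh, k = k,
              k_range = as.integer(k_range),
              n_init_runs = as.integer(n_init_runs), w_spatial = w_spatial,
              w_odf = w_odf, seed = as.integer(seed))
  for (p in c("dwi", "bvals", "bvecs", "mask", "csf"))
    if (!file.exists(cfg[[p]]))
      stop(sprintf("input '%s' not found: %s", p, cfg[[p]]))
  if (!identical(cfg$k, "auto") && (!is.numeric(cfg$k) || cfg$k < 1))
    stop("k must be \"auto\" or a positive integer")
  if (cfg$lmax %% 2 != 0) stop("lmax must be even")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the parcellation pipeline for one subject
#'
#' End-to-end orchestration: shell extraction, tensor fit (FA/MD), CSF/FA mask
#' refinement, CSA ODF estimation (optionally bootstrap-averaged), feature
#' standardization, position-averaged initialization, weighted k-means (with
#' Davies-Bouldin selection when `k = "auto"`), and anatomical labelling.
#' When `out_dir` is set, writes the refined mask, FA/MD maps, the anatomical
#' label map (uncompressed `.nii`, 1 = anterior-superior, 2 =
#' anterior-inferior, 3 = intermediate, 4 = posterior) and a JSON summary with
#' the full provenance (parameters, seed, package version).
#'
#' @param config a `PipelineConfig` from [makePipelineConfig()].
#' @return (invisibly) `list(labels, result, odfs, tensor, mask, summary,
#'   paths)`.
#' @export
runSubject <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  vols <- stage("read", {
    dwi <- readNiftiVolume(config$dwi)
    gtab <- readBvalsBvecs(config$bvals, config$bvecs)
    mask <- readNiftiVolume(config$mask)
    csf <- readNiftiVolume(config$csf)
    list(dwi = dwi$data, affine = dwi$affine, gtab = gtab,
         mask = mask$data > 0, csf = csf$data)
  })
  shell <- stage("extract_shell",
                 extractShell(vols$dwi, vols$gtab, config$b_target, config$b_tol))
  tensor <- stage("fit_tensor", fitTensor(shell$dwi, shell$gtab, vols$mask))
  refined <- stage("refine_mask",
                   refineMask(vols$mask, vols$csf, tensor@fa,
                              config$csf_thresh, config$fa_thresh))
  odfs <- stage("fit_odf", {
    if (config$bootstrap)
      bootstrapOdf(shell$dwi, shell$gtab, refined, lmax = config$lmax,
                   reg_lambda = config$reg_lambda,
                   n_samples = config$n_samples, seed = config$seed)
    else
      fitCsaOdf(shell$dwi, shell$gtab, refined, lmax = config$lmax,
                reg_lambda = config$reg_lambda)
  })
  features <- stage("build_features",
                    buildFeatures(refined, odfs, vols$affine,
                                  config$w_spatial, config$w_odf))
  result <- stage("cluster", {
    if (identical(config$k, "auto")) {
      sel <- selectK(features, config$k_range, n_runs = config$n_init_runs,
                     seed = config$seed)
      res <- sel$results[[as.character(sel$best_k)]]
      attr(res, "scores") <- sel$scores
      res
    } else {
      init <- initCentroids(features, config$k, n_runs = config$n_init_runs,
                            seed = config$seed)
      weightedKmeans(features, config$k, init, seed = config$seed)
    }
  })
  scores <- attr(result, "scores")
  k_used <- nrow(result@centroids)
  labels_out <- NULL
  if (k_used == 4) {
    result <- stage("label_anatomically", labelClustersAnatomically(result))
    if (!identical(unname(result@anatomicalMap), "unclassifiable"))
      labels_out <- labelMap(result, anatomical = TRUE)
  }
  if (is.null(labels_out)) labels_out <- labelMap(result)
  summary <- list(
    hemisphere = config$hemisphere, chosen_k = k_used,
    db_scores = as.list(scores),
    db = if (is.na(result@db)) NULL else result@db,
    anatomical_map = as.list(result@anatomicalMap),
    centroid_mm = apply(result@centroidMm, 1, function(r)
      round(r, 3), simplify = FALSE),
    voxel_counts = as.list(table(result@labels)),
    parameters = config[setdiff(names(config),
                                c("dwi", "bvals", "bvecs", "mask", "csf",
                                  "out_dir"))],
    seed = config$seed,
    software = list(package = "hypoparc",
                    version = as.character(utils::packageVersion("hypoparc"))))
  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    pre <- file.path(config$out_dir, config$hemisphere)
    paths <- c(labels = paste0(pre, "_labels.nii"),
               fa = paste0(pre, "_fa.nii.gz"),
               md = paste0(pre, "_md.nii.gz"),
               mask = paste0(pre, "_mask_refined.nii.gz"),
               summary = paste0(pre, "_summary.json"))
    writeNiftiVolume(labels_out, vols$affine, paths["labels"], datatype = "int16")
    fa0 <- tensor@fa; fa0[is.na(fa0)] <- 0
    md0 <- tensor@md; md0[is.na(md0)] <- 0
    writeNiftiVolume(fa0, vols$affine, paths["fa"], datatype = "float")
    writeNiftiVolume(md0, vols$affine, paths["md"], datatype = "float")
    writeNiftiVolume(array(as.integer(refined), dim(refined)), vols$affine,
                     paths["mask"], datatype = "int16")
    jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(list(labels = labels_out, result = result, odfs = odfs,
                 tensor = tensor, mask = refined, affine = vols$affine,
                 summary = summary, paths = paths))
}

#' Run the cohort-level pipeline: atlas, validation, statistics
#'
#' Fuses per-subject anatomical label maps (already on a shared grid) into a
#' majority-voting probabilistic atlas, computes per-subject per-subunit Dice
#' validation against the atlas, assembles the per-subject per-subunit
#' MD/FA/volume table, applies the residual-approach ICV correction to the
#' subunit volumes when ICVs are supplied, compares subunits with three
#' one-way ANOVAs (volume, FA, MD; Tukey HSD, alpha 0.017), and — when
#' covariates are supplied — fits the BMI regression on subunit MD.
#'
#' @param subject_results list of [runSubject()] results (>= 2), each with an
#'   anatomical 4-label map on the shared grid.
#' @param covariates optional `data.frame` with one row per subject: `bmi`,
#'   `age`, `sex`, `fitness`, `icv`.
#' @return `list(atlas, dice (subjects x subunits data.frame), measures
#'   (long data.frame), anovas, regression)`.
#' @export
runCohort <- function(subject_results, covariates = NULL) {
  if (length(subject_results) < 2)
    stop("atlas construction needs at least 2 subjects")
  maps <- lapply(subject_results, `[[`, "labels")
  atlas <- buildProbabilisticAtlas(maps)
  dice <- do.call(rbind, lapply(seq_along(maps), function(s) {
    v <- validateAgainstAtlas(maps[[s]], atlas)
    cbind(subject = s, v)
  }))
  measures <- do.call(rbind, lapply(seq_along(subject_results), function(s) {
    r <- subject_results[[s]]
    vox_mm3 <- if (!is.null(r$affine)) abs(det(r$affine[1:3, 1:3])) else 1
    do.call(rbind, lapply(1:4, function(l) {
      sel <- r$labels == l
      data.frame(subject = s, label = l, name = .subunitNames[l],
                 volume = sum(sel) * vox_mm3,
                 md = mean(r$tensor@md[sel], na.rm = TRUE),
                 fa = mean(r$tensor@fa[sel], na.rm = TRUE),
                 n_voxels = sum(sel))
    }))
  }))
  if (!is.null(covariates) && !is.null(covariates$icv) &&
      nrow(covariates) == length(subject_results)) {
    # residual-approach ICV correction of subunit volumes, per subunit
    for (l in 1:4) {
      sel <- measures$label == l
      measures$volume[sel] <- icvCorrect(measures$volume[sel],
                                         covariates$icv[measures$subject[sel]])
    }
  }
  anovas <- list(
    volume = anovaTukey(measures$volume, measures$name),
    fa = anovaTukey(measures$fa, measures$name),
    md = anovaTukey(measures$md, measures$name))
  regression <- NULL
  if (!is.null(covariates)) {
    if (nrow(covariates) != length(subject_results))
      stop("covariates must have one row per subject")
    wide <- stats::reshape(
      measures[, c("subject", "name", "md")],
      idvar = "subject", timevar = "name", direction = "wide")
    names(wide) <- sub("^md\\.", "md_", gsub("-", "_", names(wide)))
    # measured MDs replace any generator-supplied md_*/vol_* columns
    keep <- !grepl("^(md|vol)_", names(covariates))
    tab <- cbind(covariates[, keep, drop = FALSE],
                 wide[order(wide$subject), -1])
    regression <- fitBmiModel(tab)
  }
  list(atlas = atlas, dice = dice, measures = measures, anovas = anovas,
       regression = regression)
}
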