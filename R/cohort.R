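#' Generate a multi-subject phantom cohort with covariates
#'
#' Produces `n_subjects` variants of a base phantom. Across subjects the
#' anterior-superior tensor eigenvalues are scaled by a standardized latent
#' factor `z_md` (coefficient of variation 8% on MD; the other subunits get
#' independent 4% jitter), the subunit partition cuts are jittered by +/- 1
#' voxel (emulating segmentation variability for atlas experiments), and BMI
#' is generated as a linear function of the standardized true
#' anterior-superior MD and cardiovascular fitness plus Gaussian noise:
#'
#'   BMI = 26.5 + 4.2 (beta_md z_md + beta_fitness z_fit) + e
#'
#' with e ~ Normal(0, noise_sd^2) in kg/m^2. When `noise_sd` is `NULL` it is
#' completed to 4.2 sqrt(1 - beta_md^2 - beta_fitness^2), so that the
#' population standardized regression coefficient of BMI on anterior-superior
#' MD is exactly `beta_md`. Sex is Bernoulli(0.5) with zero true effect; age
#' is uniform 22-36 with zero effect; ICV ~ Normal(1.5e6, 1.2e5) mm^3.
#'
#' @param n_subjects cohort size (>= 10).
#' @param effect list with `beta_md`, `beta_fitness` (standardized slopes) and
#'   `noise_sd` (kg/m^2, or `NULL` for the unit-variance completion).
#' @param base_spec a [PhantomSpec-class] defining the shared geometry.
#' @param seed integer seed.
#' @param simulate if `TRUE`, simulate (noisy) DWI per subject; otherwise
#'   subjects carry geometry + covariates only (empty DWI array).
#' @param gtab gradient table used when `simulate = TRUE`.
#' @param snr SNR for the simulated data (default `base_spec@snr`).
#' @return List of [SyntheticSubject-class]; assemble the per-subject
#'   covariate/measurement table with [cohortTable()].
#' @examples
#' cohort <- makeCohort(12, seed = 3)
#' head(cohortTable(cohort))
#' @export
makeCohort <- function(n_subjects,
                       effect = list(beta_md = 0.3, beta_fitness = -0.29,
                                     noise_sd = NULL),
                       base_spec = defaultPhantomSpec(), seed = 1L,
                       simulate = FALSE,
                       gtab = makeGradientTable(90, 6, 1000, seed = seed),
                       snr = base_spec@snr) {
  if (n_subjects < 10) stop("cohort too small for regression (need n_subjects >= 10)")
  beta_md <- effect$beta_md %||% 0.3
  beta_fit <- effect$beta_fitness %||% 0
  bmi_scale <- 4.2
  noise_sd <- effect$noise_sd
  if (is.null(noise_sd)) {
    resid_var <- 1 - beta_md^2 - beta_fit^2
    if (resid_var < 0) stop("standardized effects imply variance > 1; give noise_sd")
    noise_sd <- bmi_scale * sqrt(resid_var)
  }
  .withSeed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      z_md <- stats::rnorm(1)
      z_other <- stats::rnorm(3)
      z_fit <- stats::rnorm(1)
      scales <- c(1 + 0.08 * z_md, 1 + 0.04 * z_other)
      scales <- pmax(scales, 0.5)
      spec <- base_spec
      for (id in 1:4) {
        spec@regions[[as.character(id)]] <- lapply(
          spec@regions[[as.character(id)]], function(cp) {
            cp$evals <- cp$evals * scales[id]
            cp
          })
      }
      # jitter the subunit geometry: each lobe centre moves by +/- 1 voxel
      # along one random axis; rare jitters that pinch a region are redrawn
      for (try in 1:20) {
        jit <- matrix(0, 4, 3)
        jit[cbind(1:4, sample(3, 4, replace = TRUE))] <-
          sample(c(-1, 0, 1), 4, replace = TRUE)
        geom <- tryCatch(
          defaultPhantomSpec(dim = base_spec@dim,
                             voxel_size = base_spec@voxelSize,
                             lobe_centers = .defaultLobeCenters + jit,
                             S0 = base_spec@S0, snr = snr, seed = seed + s),
          error = function(e) NULL)
        if (!is.null(geom)) break
      }
      if (is.null(geom)) stop("could not draw a valid jittered geometry")
      spec@labels <- geom@labels
      spec@csfMask <- geom@csfMask
      true_md <- vapply(1:4, function(id) {
        cps <- spec@regions[[as.character(id)]]
        sum(vapply(cps, function(cp) cp$fraction * mean(cp$evals), numeric(1)))
      }, numeric(1))
      vols <- vapply(1:4, function(id) sum(spec@labels == id), numeric(1)) *
        base_spec@voxelSize^3
      bmi <- 26.5 + bmi_scale * (beta_md * z_md + beta_fit * z_fit) +
        stats::rnorm(1, 0, noise_sd)
      cov <- list(subject = sprintf("sub-%03d", s), bmi = bmi,
                  age = round(stats::runif(1, 22, 36)),
                  sex = if (stats::runif(1) < 0.5) "male" else "female",
                  fitness = 100 + 15 * z_fit,
                  icv = stats::rnorm(1, 1.5e6, 1.2e5),
                  md_anterior_superior = true_md[1],
                  md_anterior_inferior = true_md[2],
                  md_intermediate = true_md[3],
                  md_posterior = true_md[4],
                  vol_anterior_superior = vols[1],
                  vol_anterior_inferior = vols[2],
                  vol_intermediate = vols[3],
                  vol_posterior = vols[4])
      if (simulate) {
        subj <- simulateSignal(spec, gtab)
        subj <- addRicianNoise(subj, snr,
                               seed = sample.int(.Machine$integer.max, 1))
        initialize(subj, covariates = cov)
      } else {
        csfprob <- array(0, spec@dim)
        csfprob[spec@csfMask] <- 0.9
        csfprob[spec@labels > 0] <- 0.02
        new("SyntheticSubject", dwi = array(0, c(0, 0, 0, 0)), gtab = gtab,
            affine = phantomAffine(spec), labels = spec@labels,
            csf = csfprob, covariates = cov)
      }
    })
  })
}

#' Assemble the per-subject covariate table of a cohort
#'
#' @param cohort list of [SyntheticSubject-class] from [makeCohort()].
#' @return `data.frame` with one row per subject: BMI, age, sex, fitness, ICV,
#'   and per-subunit true MD (mm^2/s) and volume (mm^3).
#' @export
cohortTable <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s)
    as.data.frame(s@covariates, stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic subject to disk in standard formats
#'
#' Writes the DWI as NIfTI-1 plus FSL `bvals`/`bvecs` text files, the
#' ground-truth label map, an input hypothalamus mask (tissue plus CSF rim, as
#' a manual segmentation would over-include), and the CSF probability map, all
#' sharing the DWI affine.
#'
#' @param subject a [SyntheticSubject-class] with simulated DWI.
#' @param dir output directory (created if needed).
#' @param gzip write `.nii.gz` (default) or plain `.nii`.
#' @return Named character vector of the written paths.
#' @export
writeSyntheticSubject <- function(subject, dir, gzip = TRUE) {
  if (!length(subject@dwi)) stop("subject carries no simulated DWI")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  paths <- c(dwi = file.path(dir, paste0("dwi", ext)),
             bvals = file.path(dir, "bvals"),
             bvecs = file.path(dir, "bvecs"),
             mask = file.path(dir, paste0("mask", ext)),
             truth = file.path(dir, paste0("truth", ext)),
             csf = file.path(dir, paste0("csf", ext)))
  writeNiftiVolume(subject@dwi, subject@affine, paths["dwi"])
  writeBvalsBvecs(subject@gtab, paths["bvals"], paths["bvecs"])
  mask <- (subject@labels > 0) | (subject@csf >= 0.5)
  writeNiftiVolume(array(as.integer(mask), dim(mask)), subject@affine, paths["mask"])
  writeNiftiVolume(subject@labels, subject@affine, paths["truth"])
  writeNiftiVolume(subject@csf, subject@affine, paths["csf"])
  paths
}
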