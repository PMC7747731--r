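test_that("the spherical-harmonic basis is orthonormal and correctly sized", {
  # Gauss-Legendre in cos(theta) x uniform azimuth integrates the products
  gl <- pracma::gaussLegendre(64, -1, 1)
  nphi <- 128
  phi <- 2 * pi * (seq_len(nphi) - 0.5) / nphi
  grid <- expand.grid(ct = gl$x, phi = phi)
  st <- sqrt(1 - grid$ct^2)
  dirs <- cbind(st * cos(grid$phi), st * sin(grid$phi), grid$ct)
  w <- rep(gl$w, nphi) * (2 * pi / nphi)
  B <- hypoparc:::shBasis(dirs, 6)
  expect_equal(ncol(B), 28)   # (lmax+1)(lmax+2)/2
  G <- t(B) %*% (B * w)
  expect_lt(max(abs(G - diag(28))), 1e-10)
  expect_equal(hypoparc:::shBasis(rbind(c(0, 0, 1)), 0)[1, 1],
               1 / (2 * sqrt(pi)))
})

test_that("shell extraction keeps b=0 plus in-tolerance volumes in order", {
  fx <- .fx()
  # multi-shell table: replicate the 96-volume table at three b-values
  gt3 <- new("GradientTable",
             bvals = c(bvals(fx$gtab),
                       replace(bvals(fx$gtab), bvals(fx$gtab) > 0, 2000),
                       replace(bvals(fx$gtab), bvals(fx$gtab) > 0, 3000)),
             bvecs = rbind(bvecs(fx$gtab), bvecs(fx$gtab), bvecs(fx$gtab)))
  dwi3 <- array(0, c(dim(fx$subjNF@dwi)[1:3], nVolumes(gt3)))
  dwi3[, , , seq_len(96)] <- fx$subjNF@dwi
  sh <- extractShell(dwi3, gt3, 1000, 100)
  expect_equal(nVolumes(sh$gtab), 96 + 12)   # 90 dirs + 3 x 6 b0
  expect_equal(sum(bvals(sh$gtab) == 1000), 90)
  # already single-shell -> identity
  sh1 <- extractShell(fx$subjNF@dwi, fx$gtab, 1000, 100)
  expect_identical(sh1$dwi, fx$subjNF@dwi)
  expect_identical(bvals(sh1$gtab), bvals(fx$gtab))
  # tol = 0 on jittered b-values keeps exact matches only (brute-force count)
  set.seed(4)
  jit <- bvals(fx$gtab)
  nz <- which(jit > 0)
  jit[nz[1:40]] <- jit[nz[1:40]] - 5
  gtj <- new("GradientTable", bvals = jit, bvecs = bvecs(fx$gtab))
  shj <- extractShell(fx$subjNF@dwi, gtj, 1000, 0)
  expect_equal(sum(bvals(shj$gtab) > 0), sum(jit == 1000))
  shj2 <- extractShell(fx$subjNF@dwi, gtj, 995, 0)
  expect_equal(sum(bvals(shj2$gtab) > 0), 40)
  expect_error(extractShell(fx$subjNF@dwi, gtj, 990, 0),
               "insufficient directions")
})

test_that("tensor fit recovers isotropic and anisotropic ground truth", {
  gtab <- makeGradientTable(30, 3, 1000, seed = 2)
  iso <- miniSpec(list(stick(c(1, 0, 0), evals = rep(0.9e-3, 3))))
  si <- simulateSignal(iso, gtab)
  tf <- fitTensor(si@dwi, gtab, iso@labels > 0)
  expect_lt(max(tf@fa[iso@labels > 0]), 1e-6)
  expect_equal(unname(tf@md[iso@labels > 0][1]), 0.9e-3, tolerance = 1e-9)

  ori <- c(1, 2, 2) / 3
  ani <- miniSpec(list(stick(ori)))
  sa <- simulateSignal(ani, gtab)
  tfa <- fitTensor(sa@dwi, gtab, ani@labels > 0)
  # closed-form FA for (1.7, 0.2, 0.2)
  ev <- c(1.7, 0.2, 0.2) * 1e-3
  fa_true <- sqrt(0.5 * sum((ev - ev[c(2, 3, 1)])^2) / sum(ev^2))
  expect_equal(unname(tfa@fa[ani@labels > 0][1]), fa_true, tolerance = 1e-6)
  expect_equal(unname(tfa@md[ani@labels > 0][1]), 0.7e-3, tolerance = 1e-9)
  expect_lt(max(axisAngle(tfa@evecs, matrix(ori, nrow(tfa@evecs), 3,
                                            byrow = TRUE))), 1)
})

test_that("noise-free tensor WLS agrees with an OLS log-linear oracle", {
  gtab <- makeGradientTable(45, 3, 1000, seed = 5)
  spec <- miniSpec(list(stick(c(1, 2, 0) / sqrt(5))))
  subj <- simulateSignal(spec, gtab)
  mask <- spec@labels > 0
  tf <- fitTensor(subj@dwi, gtab, mask)
  # independent oracle: lm() on log signal, first in-mask voxel
  v <- which(mask)[1]
  S <- apply(subj@dwi, 4, function(a) a[v])
  X <- hypoparc:::.tensorDesign(gtab)
  beta <- unname(coef(lm(log(S) ~ X - 1)))
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  expect_equal(sort(eigen(D, symmetric = TRUE)$values, decreasing = TRUE),
               unname(tf@evals[1, ]), tolerance = 1e-8)
})

test_that("FA is invariant to global signal scaling", {
  fx <- .fx()
  tf1 <- fitTensor(fx$subjNF@dwi, fx$gtab, fx$mask)
  tf2 <- fitTensor(fx$subjNF@dwi * 3.7, fx$gtab, fx$mask)
  expect_equal(tf1@fa[fx$mask], tf2@fa[fx$mask], tolerance = 1e-10)
})

test_that("CSA ODFs are unit mass, isotropic where diffusion is isotropic,
           and peak along the simulated fiber", {
  gtab <- makeGradientTable(90, 6, 1000, seed = 1)
  iso <- miniSpec(list(stick(c(1, 0, 0), evals = rep(0.9e-3, 3))))
  oi <- fitCsaOdf(simulateSignal(iso, gtab)@dwi, gtab, iso@labels > 0)
  co <- odfCoefficients(oi)
  expect_equal(ncol(co), 28)
  expect_true(all(abs(co[, 1] - 1 / (2 * sqrt(pi))) < 1e-6))
  expect_lt(max(rowSums(co[, -1]^2) / co[, 1]^2), 1e-3)

  ori <- c(2, -1, 2) / 3
  ani <- miniSpec(list(stick(ori)))
  oa <- fitCsaOdf(simulateSignal(ani, gtab)@dwi, gtab, ani@labels > 0)
  pk <- odfPeak(oa)
  expect_lt(max(axisAngle(pk, matrix(ori, nrow(pk), 3, byrow = TRUE))), 5)
  # peak agrees with the tensor principal eigenvector
  tfa <- fitTensor(simulateSignal(ani, gtab)@dwi, gtab, ani@labels > 0)
  expect_lt(max(axisAngle(pk, tfa@evecs)), 5)
  expect_error(fitCsaOdf(simulateSignal(ani, gtab)@dwi, gtab,
                         ani@labels > 0, lmax = 5), "even")
})

test_that("CSA fit refuses underdetermined problems", {
  gtab <- makeGradientTable(20, 2, 1000, seed = 1)  # 20 dirs < 28 coefficients
  spec <- miniSpec(list(stick(c(1, 0, 0))))
  subj <- simulateSignal(spec, gtab)
  expect_error(fitCsaOdf(subj@dwi, gtab, spec@labels > 0),
               "fewer directions")
})

test_that("bootstrap ODFs equal the deterministic fit on zero-residual data and are seed-stable", {
  gtab <- makeGradientTable(60, 4, 1000, seed = 2)
  # isotropic signal: ln(-ln E) is constant, exactly representable at l = 0,
  # so the unregularized SH fit has zero residuals
  spec <- miniSpec(list(stick(c(0, 1, 1) / sqrt(2), evals = rep(0.9e-3, 3))))
  subj <- simulateSignal(spec, gtab)
  mask <- spec@labels > 0
  det <- fitCsaOdf(subj@dwi, gtab, mask, reg_lambda = 0)
  bs1 <- bootstrapOdf(subj@dwi, gtab, mask, n_samples = 10, seed = 3,
                      reg_lambda = 0)
  expect_lt(max(abs(odfCoefficients(bs1) - odfCoefficients(det))), 1e-6)
  aniso <- simulateSignal(miniSpec(list(stick(c(0, 1, 1) / sqrt(2)))), gtab)
  noisy <- addRicianNoise(aniso, 20, seed = 4)
  b1 <- bootstrapOdf(noisy@dwi, gtab, mask, n_samples = 5, seed = 7)
  b2 <- bootstrapOdf(noisy@dwi, gtab, mask, n_samples = 5, seed = 7)
  expect_identical(odfCoefficients(b1), odfCoefficients(b2))
  expect_error(bootstrapOdf(subj@dwi, gtab, mask, n_samples = 0), "n_samples")
})

test_that("bootstrap coefficient variance shrinks as SNR grows", {
  gtab <- makeGradientTable(60, 4, 1000, seed = 2)
  spec <- miniSpec(list(stick(c(1, 0, 0))))
  subj <- simulateSignal(spec, gtab)
  mask <- spec@labels > 0
  # spread of bootstrap-mean coefficients across noise realizations
  spread <- vapply(c(10, 40), function(snr) {
    reps <- vapply(1:8, function(r) {
      noisy <- addRicianNoise(subj, snr, seed = 100 + r)
      odfCoefficients(bootstrapOdf(noisy@dwi, gtab, mask, n_samples = 5,
                                   seed = r))[1, 2]
    }, numeric(1))
    var(reps)
  }, numeric(1))
  # variance ~ 1/SNR^2: a 4x SNR increase should cut variance far more than 2x
  expect_gt(spread[1] / spread[2], 4)
})
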