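# Shared phantom fixtures, built once per session.

.fx <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gtab <- makeGradientTable(90, 6, 1000, seed = 1)
      spec <- defaultPhantomSpec()
      subjNF <- simulateSignal(spec, gtab)
      mask <- spec@labels > 0
      cache <<- list(gtab = gtab, spec = spec, subjNF = subjNF, mask = mask,
                     truth = spec@labels)
    }
    cache
  }
})

# A small one-region phantom with arbitrary compartments: 5x5x5 grid, the
# central 3x3x3 block is "region 1", surrounded by background (no CSF rim).
miniSpec <- function(compartments, S0 = 1000, background_d = 0.8e-3) {
  labels <- array(0L, c(5L, 5L, 5L))
  labels[2:4, 2:4, 2:4] <- 1L
  new("PhantomSpec", dim = c(5L, 5L, 5L), voxelSize = 1.25, labels = labels,
      regions = list("1" = compartments), csfMask = array(FALSE, c(5L, 5L, 5L)),
      csfDiffusivity = 3.0e-3, backgroundDiffusivity = background_d,
      S0 = S0, snr = 20, seed = 1)
}

stick <- function(orientation, evals = c(1.7, 0.2, 0.2) * 1e-3, fraction = 1)
  list(orientation = orientation / sqrt(sum(orientation^2)),
       fraction = fraction, evals = evals)

# Dice per true subunit for an anatomically labelled ClusterResult.
subunitDice <- function(result, truth) {
  lm4 <- labelMap(result, anatomical = TRUE)
  vapply(1:4, function(l)
    diceCoefficient(lm4 == l, truth == l), numeric(1))
}

# angle (degrees) between unit vectors, sign-invariant
axisAngle <- function(a, b)
  acos(pmin(1, abs(rowSums(a * b)))) * 180 / pi
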