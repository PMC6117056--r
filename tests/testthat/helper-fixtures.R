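# Small fixture builders shared across test files. Everything is
# generated in code; nothing is read from disk except temp files the
# tests themselves write.

noiselessCT <- function(target = 0.30, gradient = 0, seed = 11, ...) {
  generateCTPhantom(ctPhantomConfig(
    lavFractionTarget = target, gradientStrength = gradient,
    parenchymaHUSD = 0, emphysemaHUSD = 0, globalHUOffset = 0,
    seed = seed, ...))
}

noiselessOEMRI <- function(amplitude = 0.22, gradient = 0, seed = 1, ...) {
  generateOEMRIPhantom(oemriPhantomConfig(
    enhancementAmplitudeMean = amplitude, enhancementGradient = gradient,
    noiseSD = 0, seed = seed, ...))
}

# Independent oracle: per-voxel loop computing per-partition total and
# LAV counts straight from the arrays, no vectorized pipeline involved.
naivePartitionCounts <- function(volume, mask, scheme) {
  n <- scheme@nTotal
  tot <- integer(n); lav <- integer(n)
  for (i in seq_along(scheme@voxelIndex)) {
    p <- scheme@assignment[i]
    v <- scheme@voxelIndex[i]
    tot[p] <- tot[p] + 1L
    if (mask[v]) lav[p] <- lav[p] + 1L
  }
  list(total = tot, lav = lav)
}
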