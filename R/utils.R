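## Internal helpers shared by the CT and MRI partitioning paths.

# Equal-count quota vector: total items into n partitions, base size
# floor(total/n), remainder assigned to the earliest partitions.
partitionQuotas <- function(total, n) {
  stopifnot(total >= n, n >= 1)
  base <- total %/% n
  rem <- total %% n
  as.integer(base + (seq_len(n) <= rem))
}

# Sample standard deviation (n-1 denominator); population (n) available
# since the denominator convention is configurable upstream.
sampleSD <- function(x, denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  if (denominator == "sample") return(stats::sd(x))
  sqrt(mean((x - mean(x))^2))
}

# Weighted inverse-CDF draw of indices 1..length(w) for uniforms u.
# Deterministic in (w, u): with a fixed uniform sequence, tilting w toward
# the tail moves every draw monotonically toward the tail (common random
# numbers), which is what makes the gradient dial act smoothly.
weightedInverseCDF <- function(w, u) {
  cw <- cumsum(w)
  tot <- cw[length(cw)]
  if (tot <= 0) stop("all sampling weights are zero")
  findInterval(u * tot, cw, left.open = TRUE) + 1L
}

# Canonical ordering of lung voxels: slice-major (cranial first), then
# row-major in-slice (column index fastest is R's native order within a
# slice; we fix it explicitly so results are reproducible across layouts).
orderedLungVoxels <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  # array index -> (x, y, z); order by z, then y, then x
  z <- (idx - 1L) %/% (d[1] * d[2])
  rest <- (idx - 1L) %% (d[1] * d[2])
  y <- rest %/% d[1]
  x <- rest %% d[1]
  idx[order(z, y, x)]
}

jsonWrite <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
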