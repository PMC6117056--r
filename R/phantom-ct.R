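#' Configuration for the synthetic CT emphysema phantom
#'
#' Builds and validates the parameter set for [generateCTPhantom()]. The
#' phantom places a pair of ellipsoidal lungs and a cylindrical trachea in
#' a HU-valued voxel grid, then seeds spherical emphysema clusters inside
#' the lung until a target low-attenuation fraction is realized, with the
#' cluster-center density optionally tilted along the cranial-caudal axis.
#'
#' @param gridShape integer(3), voxels per axis (x, y, z); z is
#'   cranial-caudal with index 1 cranial.
#' @param voxelSpacing numeric(3), mm per axis.
#' @param lavFractionTarget target emphysema fraction of the lung, in
#'   `[0, 1]`.
#' @param gradientStrength cranial-caudal tilt of the cluster-center
#'   sampling density, in `[-1, 1]`; 0 is homogeneous, positive is
#'   caudal-dominant.
#' @param clusterRadiusMM emphysema cluster radius in mm.
#' @param parenchymaHUMean,parenchymaHUSD normal-parenchyma HU Gaussian.
#' @param emphysemaHUMean,emphysemaHUSD emphysema HU Gaussian; the mean
#'   must be below -960 HU (and the parenchyma mean above) so that the
#'   noiseless phantom is exactly separable at the threshold.
#' @param globalHUOffset additive HU miscalibration applied to the whole
#'   volume (what tracheal-air calibration must undo).
#' @param seed integer; identical config and seed give a bit-identical
#'   phantom.
#' @return a named list of class `CTPhantomConfig`.
#' @export
ctPhantomConfig <- function(gridShape = c(24L, 24L, 30L),
                            voxelSpacing = c(2, 2, 2),
                            lavFractionTarget = 0.25,
                            gradientStrength = 0,
                            clusterRadiusMM = 2.5,
                            parenchymaHUMean = -860, parenchymaHUSD = 35,
                            emphysemaHUMean = -985, emphysemaHUSD = 8,
                            globalHUOffset = 0,
                            seed = 1L) {
  cfg <- list(
    gridShape = as.integer(gridShape), voxelSpacing = as.numeric(voxelSpacing),
    lavFractionTarget = lavFractionTarget,
    gradientStrength = gradientStrength,
    clusterRadiusMM = clusterRadiusMM,
    parenchymaHUMean = parenchymaHUMean, parenchymaHUSD = parenchymaHUSD,
    emphysemaHUMean = emphysemaHUMean, emphysemaHUSD = emphysemaHUSD,
    globalHUOffset = globalHUOffset,
    seed = as.integer(seed)
  )
  if (length(cfg$gridShape) != 3L || any(cfg$gridShape < 8L))
    stop("gridShape must be three values, each at least 8 voxels")
  if (cfg$lavFractionTarget < 0 || cfg$lavFractionTarget > 1)
    stop("lavFractionTarget must lie in [0, 1]")
  if (abs(cfg$gradientStrength) > 1)
    stop("gradientStrength must lie in [-1, 1]")
  if (cfg$clusterRadiusMM <= 0) stop("clusterRadiusMM must be positive")
  if (!(cfg$emphysemaHUMean < -960 && -960 < cfg$parenchymaHUMean))
    stop("need emphysemaHUMean < -960 < parenchymaHUMean")
  if (any(c(cfg$parenchymaHUSD, cfg$emphysemaHUSD) < 0))
    stop("HU standard deviations must be non-negative")
  class(cfg) <- "CTPhantomConfig"
  cfg
}

# Lung/trachea geometry: two ellipsoids flanking a central tracheal
# cylinder that descends through the upper 40% of the lung extent.
phantomGeometry <- function(gridShape) {
  nx <- gridShape[1]; ny <- gridShape[2]; nz <- gridShape[3]
  x <- (seq_len(nx) - 0.5) / nx
  y <- (seq_len(ny) - 0.5) / ny
  z <- (seq_len(nz) - 0.5) / nz
  X <- array(rep(x, times = ny * nz), dim = gridShape)
  Y <- array(rep(rep(y, each = nx), times = nz), dim = gridShape)
  Z <- array(rep(z, each = nx * ny), dim = gridShape)
  inEllipsoid <- function(cx, cy, cz, rx, ry, rz)
    ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 + ((Z - cz) / rz)^2 <= 1
  lungL <- inEllipsoid(0.30, 0.5, 0.5, 0.17, 0.33, 0.42)
  lungR <- inEllipsoid(0.70, 0.5, 0.5, 0.17, 0.33, 0.42)
  trachea <- (((X - 0.5) / 0.05)^2 + ((Y - 0.5) / 0.05)^2 <= 1) &
    Z >= 0.08 & Z <= 0.45
  lung <- (lungL | lungR) & !trachea
  list(lung = lung, trachea = trachea)
}

#' Generate a synthetic CT emphysema phantom with ground truth
#'
#' Emphysema is laid down as spherical clusters whose centers are sampled
#' from the lung-voxel distribution tilted linearly along the
#' cranial-caudal axis by `gradientStrength` (density clipped at zero).
#' Clusters are added, overlap counted once, until the realized
#' emphysema-label fraction is within 0.5 percentage points of
#' `lavFractionTarget`; a cluster whose addition would overshoot the band
#' is rejected and resampled. HU values are then drawn from the
#' parenchyma/emphysema Gaussian mixture, the trachea is filled with air
#' (-1000 HU, 2 HU jitter), non-lung background with soft-tissue HU, and
#' the whole volume is shifted by `globalHUOffset`.
#'
#' @param config a [ctPhantomConfig()].
#' @return list with components `volume` (a [CTVolume-class]) and
#'   `truth` (a [PhantomTruth-class]).
#' @examples
#' ph <- generateCTPhantom(ctPhantomConfig(lavFractionTarget = 0.2, seed = 3))
#' ph$volume
#' trueLavFraction(ph$truth)
#' @export
generateCTPhantom <- function(config) {
  stopifnot(inherits(config, "CTPhantomConfig"))
  geom <- phantomGeometry(config$gridShape)
  lung <- geom$lung; trachea <- geom$trachea
  d <- config$gridShape

  lungSlices <- apply(lung, 3, any)
  if (sum(lungSlices) < 12L)
    stop("degenerate grid: fewer than 12 slices contain lung")

  lungIdx <- orderedLungVoxels(lung)
  nLung <- length(lungIdx)
  zOf <- ((lungIdx - 1L) %/% (d[1] * d[2])) + 1L
  yOf <- (((lungIdx - 1L) %% (d[1] * d[2])) %/% d[1]) + 1L
  xOf <- ((lungIdx - 1L) %% d[1]) + 1L

  withr::with_seed(config$seed, {
    label <- rep(FALSE, nLung)
    target <- config$lavFractionTarget
    tol <- 0.005
    if (target > tol) {
      # Cranial-caudal center density: per-slice lung voxel count tilted
      # linearly by gradientStrength, clipped >= 0, then converted into
      # per-slice emphysema quotas (a stratified realization of the same
      # density: i.i.d. center draws leave the heterogeneity dial too
      # noisy at desk-scale grids). Each cluster is centered on a random
      # unlabeled voxel of the slice with the largest relative deficit;
      # overlap between clusters counts once.
      zLung <- sort(unique(zOf))
      nSlices <- length(zLung)
      nPerZ <- tabulate(match(zOf, zLung), nbins = nSlices)
      u <- if (nSlices > 1)
        2 * (zLung - zLung[1]) / (zLung[nSlices] - zLung[1]) - 1
      else 0
      wz <- nPerZ * pmax(1 + config$gradientStrength * u, 0)
      nTarget <- target * nLung
      quota <- nTarget * wz / sum(wz)
      # a slice cannot hold more emphysema than lung; redistribute excess
      for (pass in 1:3) {
        excess <- sum(pmax(quota - nPerZ, 0))
        if (excess == 0) break
        quota <- pmin(quota, nPerZ)
        room <- nPerZ - quota
        quota <- quota + excess * room / sum(room)
      }
      sliceOf <- match(zOf, zLung)
      bySlice <- split(seq_len(nLung), sliceOf)
      rVox <- config$clusterRadiusMM / config$voxelSpacing
      # nominal cluster volume in voxels (full ellipsoid on the grid)
      off <- expand.grid(x = -ceiling(rVox[1]):ceiling(rVox[1]),
                         y = -ceiling(rVox[2]):ceiling(rVox[2]),
                         z = -ceiling(rVox[3]):ceiling(rVox[3]))
      ballSize <- sum((off$x / rVox[1])^2 + (off$y / rVox[2])^2 +
                        (off$z / rVox[3])^2 <= 1)
      if (ballSize > 2 * tol * nLung + 1)
        stop(sprintf(paste0(
          "unreachable target fraction %.3f: one %.1f mm cluster holds ",
          "%d voxels, more than the 0.5 percentage-point tolerance band ",
          "(%.1f voxels) allows"), target, config$clusterRadiusMM,
          ballSize, 2 * tol * nLung))
      curz <- numeric(nSlices)
      # In-slice pick: a per-slice randomized golden-ratio sequence over
      # the slice's row-major voxel order, so emphysema spreads evenly
      # along the order used to split boundary slices between partitions
      # (a purely random pick leaves the partition split of a boundary
      # slice hypergeometrically noisy and drowns weak gradients).
      phi <- (sqrt(5) - 1) / 2
      sliceOffset <- stats::runif(nSlices)
      slicePick <- integer(nSlices)
      pickVoxel <- function(zi) {
        vox <- bySlice[[zi]]
        for (try in seq_len(length(vox))) {
          slicePick[zi] <<- slicePick[zi] + 1L
          q <- (sliceOffset[zi] + slicePick[zi] * phi) %% 1
          ci <- vox[ceiling(q * length(vox))]
          if (!label[ci]) return(ci)
        }
        free <- vox[!label[vox]]
        if (!length(free)) NA_integer_ else free[1]
      }
      guard <- 0L
      # cluster pass: fill the slice with the largest relative deficit
      # until one cluster short of the target
      repeat {
        placed <- sum(label)
        if (placed >= nTarget - ballSize) break
        deficit <- (quota - curz) / pmax(nPerZ, 1)
        zi <- which.max(deficit)
        ci <- pickVoxel(zi)
        if (is.na(ci)) { quota[zi] <- curz[zi]; next }
        inBall <- (((xOf - xOf[ci]) / rVox[1])^2 +
                   ((yOf - yOf[ci]) / rVox[2])^2 +
                   ((zOf - zOf[ci]) / rVox[3])^2) <= 1
        gain <- inBall & !label
        if (placed + sum(gain) > nTarget + tol * nLung) {
          guard <- guard + 1L
          if (guard > 500L)
            stop(sprintf(paste0(
              "unreachable target fraction %.3f: cluster radius %.1f mm ",
              "adds more voxels than the 0.5 percentage-point tolerance ",
              "band allows"), target, config$clusterRadiusMM))
          next
        }
        guard <- 0L
        label <- label | inBall
        curz <- curz + tabulate(sliceOf[gain], nbins = nSlices)
      }
      # micro-lesion pass: single-voxel fill of the residual per-slice
      # deficits, so every slice meets its quota and the whole-lung
      # fraction lands on the target exactly (emphysema also has a
      # fine-grain component below the nominal cluster size)
      while (sum(label) < round(nTarget)) {
        deficit <- (quota - curz) / pmax(nPerZ, 1)
        zi <- which.max(deficit)
        ci <- pickVoxel(zi)
        if (is.na(ci)) { quota[zi] <- curz[zi]; next }
        label[ci] <- TRUE
        curz[zi] <- curz[zi] + 1
      }
    }

    hu <- array(0, dim = d)
    hu[!lung & !trachea] <- stats::rnorm(sum(!lung & !trachea), 40, 15)
    pIdx <- lungIdx[!label]; eIdx <- lungIdx[label]
    hu[pIdx] <- stats::rnorm(length(pIdx), config$parenchymaHUMean,
                             config$parenchymaHUSD)
    if (length(eIdx))
      hu[eIdx] <- stats::rnorm(length(eIdx), config$emphysemaHUMean,
                               config$emphysemaHUSD)
    hu[trachea] <- stats::rnorm(sum(trachea), -1000, 2)
    hu <- hu + config$globalHUOffset
  })

  vol <- methods::new("CTVolume", hu = hu, spacing = config$voxelSpacing,
                      lungMask = lung, tracheaMask = trachea,
                      calibrationShift = 0)

  labelArr <- array(FALSE, dim = d)
  labelArr[lungIdx[label]] <- TRUE
  scheme <- partitionIsovolumetric(vol)
  perPart <- vapply(seq_len(scheme@nTotal), function(p) {
    vx <- scheme@voxelIndex[scheme@assignment == p]
    mean(labelArr[vx])
  }, numeric(1))
  truth <- methods::new("PhantomTruth",
    emphysemaLabel = labelArr,
    lavFractionWhole = sum(label) / nLung,
    lavFractionPerPartition = perPart)
  list(volume = vol, truth = truth)
}
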