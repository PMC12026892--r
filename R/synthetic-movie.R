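# Voxel-centre coordinate vectors (micrometres) for a volume of given
# dims; centre of voxel i is at (i - 0.5) * pitch.
voxelCenters <- function(dims, voxelSize) {
  list(x = (seq_len(dims[1]) - 0.5) * voxelSize[1],
       y = (seq_len(dims[2]) - 0.5) * voxelSize[2],
       z = (seq_len(dims[3]) - 0.5) * voxelSize[3])
}

.boxRange <- function(centers, lo, hi) {
  i <- which(centers >= lo & centers <= hi)
  if (length(i) == 0L) integer(0) else i
}

# Paint an ellipsoid (set voxels to `value`) into vol; returns vol.
addEllipsoid <- function(vol, center, radii, value, vc) {
  ix <- .boxRange(vc$x, center[1] - radii[1], center[1] + radii[1])
  iy <- .boxRange(vc$y, center[2] - radii[2], center[2] + radii[2])
  iz <- .boxRange(vc$z, center[3] - radii[3], center[3] + radii[3])
  if (!length(ix) || !length(iy) || !length(iz)) return(vol)
  qx <- ((vc$x[ix] - center[1]) / radii[1])^2
  qy <- ((vc$y[iy] - center[2]) / radii[2])^2
  qz <- ((vc$z[iz] - center[3]) / radii[3])^2
  q <- outer(outer(qx, qy, "+"), qz, "+")
  sub <- vol[ix, iy, iz, drop = FALSE]
  sub[q <= 1] <- value
  vol[ix, iy, iz] <- sub
  vol
}

# Add an anisotropy-aware Gaussian blob (separable, truncated at 4 sigma).
addBlob <- function(vol, center, sigma, peak, vc) {
  sigma <- rep(sigma, length.out = 3)
  ix <- .boxRange(vc$x, center[1] - 4 * sigma[1], center[1] + 4 * sigma[1])
  iy <- .boxRange(vc$y, center[2] - 4 * sigma[2], center[2] + 4 * sigma[2])
  iz <- .boxRange(vc$z, center[3] - 4 * sigma[3], center[3] + 4 * sigma[3])
  if (!length(ix) || !length(iy) || !length(iz)) return(vol)
  ex <- exp(-0.5 * ((vc$x[ix] - center[1]) / sigma[1])^2)
  ey <- exp(-0.5 * ((vc$y[iy] - center[2]) / sigma[2])^2)
  ez <- exp(-0.5 * ((vc$z[iz] - center[3]) / sigma[3])^2)
  vol[ix, iy, iz] <- vol[ix, iy, iz] + peak * outer(outer(ex, ey), ez)
  vol
}

# Peak value such that the blob's voxel-summed intensity equals `total`.
blobPeakForIntegral <- function(total, sigma, voxelSize) {
  sigma <- rep(sigma, length.out = 3)
  total * prod(voxelSize) / ((2 * pi)^1.5 * prod(sigma))
}

.defaultProfile <- function(span) {
  # interphase-like rise and fall of nucleoplasmic concentration
  function(t) 0.5 + 0.5 * sin(pi * pmin(pmax(t / span, 0), 1))
}

#' Simulate a two-channel 4D embryo movie with ground truth
#'
#' Renders ellipsoidal nuclei whose nucleoplasmic intensity follows a
#' configurable time profile, Gaussian-blob transcription-factor hubs
#' born/dying inside each nucleus (channel 1), and one diffraction-
#' limited MS2 spot per nucleus whose integrated intensity follows the
#' burst model (channel 2). Poisson-Gaussian camera noise is applied
#' last. Every rendered event is recorded in the returned ground truth.
#'
#' Hub lifetimes at movie level are exponential with mean
#' \code{hubs$meanLifetime}, and births follow a Poisson process at rate
#' density x nuclear volume / mean lifetime, so the per-frame hub count
#' per nucleus is Poisson with mean density x nuclear volume at every
#' frame (stationarity by memorylessness).
#'
#' @param cfg a [simulationConfig()].
#' @param dims volume dimensions (nx, ny, nz) in voxels; must not
#'   exceed 256 x 256 x 64.
#' @return list with \code{movie} (a \linkS4class{HubMovie}),
#'   \code{truth} (nuclei, hub inventory, MS2 tables), and the config.
#' @export
simulateEmbryoMovie <- function(cfg, dims = c(96L, 96L, 24L)) {
  validateSimulationConfig(cfg)
  if (prod(dims) > 256 * 256 * 64)
    stop("configuration error: volume exceeds the 256x256x64 voxel bound",
         call. = FALSE)
  set.seed(cfg$seed)
  vs <- cfg$voxelSize
  vc <- voxelCenters(dims, vs)
  ext <- dims * vs
  dt <- cfg$frameInterval / 60
  nT <- cfg$nFrames
  tmin <- (seq_len(nT) - 1L) * dt
  nuc <- cfg$nucleus

  # --- nucleus placement with overlap rejection -------------------------
  nN <- nuc$n
  margin <- nuc$radii + 0.2
  centers <- matrix(NA_real_, nN, 3)
  tries <- 0L
  i <- 1L
  while (i <= nN) {
    cand <- c(stats::runif(1, margin[1], ext[1] - margin[1]),
              stats::runif(1, margin[2], ext[2] - margin[2]),
              stats::runif(1, margin[3], ext[3] - margin[3]))
    ok <- TRUE
    if (i > 1L) {
      d <- sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                           matrix(cand, i - 1L, 3, byrow = TRUE))^2))
      ok <- all(d > 1.9 * max(nuc$radii[1:2]))
    }
    if (ok) { centers[i, ] <- cand; i <- i + 1L } else tries <- tries + 1L
    if (tries > 500L)
      stop("nucleus placement failed: volume too crowded for ", nN,
           " nuclei", call. = FALSE)
  }
  # constant-velocity drift at the configured speed, random headings
  theta <- stats::runif(nN, 0, 2 * pi)
  vel <- cbind(cos(theta), sin(theta), 0) * nuc$driftSpeed  # um/min

  profile <- nuc$intensityProfile
  if (is.null(profile)) profile <- .defaultProfile(max(tmin) + dt)
  nucVol <- 4 / 3 * pi * prod(nuc$radii)

  # --- ground-truth hub events (birth-death process per nucleus) --------
  lam <- cfg$hubs$density * nucVol            # stationary mean count
  span <- max(tmin)
  hubTab <- list()
  hid <- 0L
  for (n in seq_len(nN)) {
    births <- numeric(0)
    m0 <- stats::rpois(1, lam)
    births <- c(births, rep(0, m0))           # standing crop at t = 0
    if (cfg$hubs$meanLifetime > 0 && lam > 0) {
      rate <- lam / cfg$hubs$meanLifetime
      t <- stats::rexp(1, rate)
      while (t < span) { births <- c(births, t); t <- t + stats::rexp(1, rate) }
    }
    for (b in births) {
      life <- stats::rexp(1, 1 / cfg$hubs$meanLifetime)
      # position fixed relative to the (drifting) nucleus centre
      u <- stats::runif(3, -1, 1)
      while (sum(u^2) > 1) u <- stats::runif(3, -1, 1)
      hid <- hid + 1L
      hubTab[[hid]] <- data.frame(
        hub_id = hid, nucleus_id = n, birth_min = b,
        death_min = min(b + life, span),
        rel_x = u[1] * 0.75 * nuc$radii[1],
        rel_y = u[2] * 0.75 * nuc$radii[2],
        rel_z = u[3] * 0.75 * nuc$radii[3],
        amplitude = max(0.2, stats::rnorm(1, cfg$hubs$intensityMean,
                                          cfg$hubs$intensitySd)))
    }
  }
  hubTab <- if (length(hubTab)) do.call(rbind, hubTab) else
    data.frame(hub_id = integer(0), nucleus_id = integer(0),
               birth_min = numeric(0), death_min = numeric(0),
               rel_x = numeric(0), rel_y = numeric(0), rel_z = numeric(0),
               amplitude = numeric(0))
  hubTab$birth_frame <- as.integer(ceiling(hubTab$birth_min / dt - 1e-9))
  hubTab$death_frame <- pmin(as.integer(floor(hubTab$death_min / dt + 1e-9)),
                             nT - 1L)

  # --- MS2 loci: fixed offset from nucleus centre, bursting trace -------
  m <- cfg$ms2
  ms2Off <- matrix(0, nN, 3)
  ms2Trace <- matrix(0, nT, nN)
  burstTruthAll <- list()
  for (n in seq_len(nN)) {
    u <- stats::runif(3, -1, 1); u <- u / sqrt(sum(u^2))
    ms2Off[n, ] <- u * 0.3 * nuc$radii
    # per-nucleus burst phase jitter (Inf = auto: half the spacing)
    jit <- if (is.finite(m$phaseJitter)) m$phaseJitter else m$interBurst / 2
    phase <- if (jit > 0) stats::runif(1, 0, jit) else 0
    starts <- seq(m$firstBurst + phase, by = m$interBurst,
                  length.out = max(1, floor((span - m$firstBurst) /
                                              m$interBurst) + 1))
    starts <- round(starts[starts <= span] / dt) * dt
    tr <- numeric(nT)
    for (s in starts)
      tr <- tr + burstWaveform(tmin, s, m$riseRate, m$amplitude,
                               m$plateau, m$decayRate)
    ms2Trace[, n] <- tr
    bt <- burstTruth(starts, m$riseRate, m$amplitude, m$plateau, m$decayRate)
    bt$nucleus_id <- rep(n, nrow(bt))
    burstTruthAll[[n]] <- bt
  }

  # --- render ----------------------------------------------------------
  arr <- array(0, dim = c(dims, 2L, nT))
  base <- nuc$baseIntensity
  sigHub <- cfg$hubs$sigma
  sigSpot <- c(0.12, 0.12, 0.18)
  nucTruth <- list()
  inv <- list()
  for (f in seq_len(nT)) {
    t <- tmin[f]
    ch1 <- array(0, dims)
    ch2 <- array(0, dims)
    nucInt <- base * profile(t)
    for (n in seq_len(nN)) {
      ctr <- centers[n, ] + vel[n, ] * t
      ctr <- pmin(pmax(ctr, margin), ext - margin)
      ch1 <- addEllipsoid(ch1, ctr, nuc$radii, nucInt, vc)
      ch2 <- addEllipsoid(ch2, ctr, nuc$radii, 0.4 * nucInt, vc)
      nucTruth[[length(nucTruth) + 1L]] <- data.frame(
        nucleus_id = n, frame = f - 1L, t_min = t, x = ctr[1], y = ctr[2],
        z = ctr[3], intensity = nucInt)
      live <- hubTab[hubTab$nucleus_id == n &
                       hubTab$birth_frame <= f - 1L &
                       hubTab$death_frame >= f - 1L, , drop = FALSE]
      if (nrow(live)) {
        for (j in seq_len(nrow(live))) {
          pos <- ctr + c(live$rel_x[j], live$rel_y[j], live$rel_z[j])
          ch1 <- addBlob(ch1, pos, sigHub, live$amplitude[j] * nucInt, vc)
          inv[[length(inv) + 1L]] <- data.frame(
            hub_id = live$hub_id[j], nucleus_id = n, frame = f - 1L,
            x = pos[1], y = pos[2], z = pos[3],
            amplitude = live$amplitude[j])
        }
      }
      if (ms2Trace[f, n] > 0) {
        pos <- ctr + ms2Off[n, ]
        ch2 <- addBlob(ch2, pos,  sigSpot,
                       blobPeakForIntegral(ms2Trace[f, n], sigSpot, vs), vc)
      }
    }
    arr[, , , 1L, f] <- ch1
    arr[, , , 2L, f] <- ch2
  }

  # --- camera noise last ------------------------------------------------
  nz <- cfg$noise
  if (nz$background > 0) arr <- arr + nz$background
  if (is.finite(nz$gain) && nz$gain > 0)
    arr <- array(stats::rpois(length(arr), nz$gain * arr) / nz$gain,
                 dim = dim(arr))
  if (nz$readSd > 0)
    arr <- arr + array(stats::rnorm(length(arr), 0, nz$readSd),
                       dim = dim(arr))
  arr[arr < 0] <- 0

  ms2Truth <- do.call(rbind, lapply(seq_len(nN), function(n) {
    ctr <- t(vapply(seq_len(nT), function(f) {
      p <- centers[n, ] + vel[n, ] * tmin[f]
      pmin(pmax(p, margin), ext - margin) + ms2Off[n, ]
    }, numeric(3)))
    data.frame(nucleus_id = n, frame = seq_len(nT) - 1L, t_min = tmin,
               x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
               intensity = ms2Trace[, n])
  }))

  list(movie = HubMovie(arr, voxelSize = vs,
                        frameInterval = cfg$frameInterval),
       truth = list(
         nuclei = do.call(rbind, nucTruth),
         hubs = hubTab,
         hub_inventory = if (length(inv)) do.call(rbind, inv) else
           data.frame(hub_id = integer(0), nucleus_id = integer(0),
                      frame = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), amplitude = numeric(0)),
         ms2 = ms2Truth,
         bursts = do.call(rbind, burstTruthAll)),
       config = cfg)
}
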