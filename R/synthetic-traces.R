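#' Simulation configuration for synthetic movies and traces
#'
#' Bundles and validates every knob of the synthetic-data generator.
#' Defaults emulate the acquisition conditions the analysis assumes:
#' one volume per 11.56 s, z-planes every 0.3 um, blastoderm-scale
#' nuclei, sub-nuclear hubs, and a single bursting MS2 locus per
#' nucleus. All durations other than \code{frameInterval} are minutes;
#' all lengths are micrometres.
#'
#' @param seed integer RNG seed.
#' @param frameInterval seconds between volumes (default 11.56).
#' @param nFrames number of frames.
#' @param voxelSize (dx, dy, dz) micrometres (default 0.104, 0.104, 0.3).
#' @param nucleus list: \code{n} nuclei; \code{radii} ellipsoid semi-axes
#'   (um); \code{driftSpeed} um/min; \code{intensityProfile} optional
#'   function(t_min) -> nucleoplasm intensity (default a rise-and-fall
#'   interphase profile); \code{baseIntensity} scale.
#' @param hubs list: \code{density} hubs per um^3; \code{sigma} blob
#'   standard deviation (um); \code{intensityMean}, \code{intensitySd}
#'   peak amplitude of a hub blob relative to the nucleoplasm;
#'   \code{meanLifetime} minutes (movie-level hub lifetimes are
#'   exponential so the stationary count is exactly density x volume);
#'   \code{dwellMixture} list(weights, means, sds) in minutes for the
#'   three-component dwell-time mixture used at trace level.
#' @param ms2 list: burst model \code{firstBurst} (min, first start),
#'   \code{interBurst} (min between burst starts), \code{riseRate}
#'   (intensity/min), \code{amplitude} (peak), \code{plateau} (min),
#'   \code{decayRate} (1/min); \code{nBursts} bursts per trace; coupling
#'   controls: \code{coupling} one of "none", "lag", "arrival" (mutually
#'   exclusive modes); \code{lag} imposed trace lag in minutes (positive
#'   = hub follows MS2); \code{arrivalLead}, \code{dwellAfter} minutes
#'   for arrival coupling; \code{smoothSigma} minutes for the lag-mode
#'   hub trace smoothing.
#' @param noise list: \code{gain} photons per intensity unit (Poisson
#'   shot noise; \code{Inf} disables), \code{readSd} additive Gaussian
#'   sd, \code{background} offset, \code{traceSd} additive sd on
#'   trace-level series.
#' @return a validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1L,
                             frameInterval = 11.56,
                             nFrames = 120L,
                             voxelSize = c(0.104, 0.104, 0.3),
                             nucleus = list(),
                             hubs = list(),
                             ms2 = list(),
                             noise = list()) {
  nucleus <- utils::modifyList(list(
    n = 4L, radii = c(2.6, 2.6, 3.2), driftSpeed = 0.3,
    intensityProfile = NULL, baseIntensity = 100), nucleus)
  hubs <- utils::modifyList(list(
    density = 0.05, sigma = 0.2, intensityMean = 1.2, intensitySd = 0.25,
    meanLifetime = 1.0,
    dwellMixture = list(weights = c(0.5, 0.35, 0.15),
                        means = c(0.4, 1.35, 10.04),
                        sds = c(0.15, 0.5, 2.0))), hubs)
  ms2 <- utils::modifyList(list(
    firstBurst = 2, interBurst = 8, riseRate = 600, amplitude = 600,
    plateau = 1.0, decayRate = 2.0, nBursts = Inf, phaseJitter = Inf,
    coupling = "none", lag = 0, arrivalLead = 1.5, dwellAfter = 2.0,
    smoothSigma = 0.2), ms2)
  noise <- utils::modifyList(list(
    gain = 5, readSd = 2, background = 10, traceSd = 0), noise)

  cfg <- list(seed = as.integer(seed), frameInterval = frameInterval,
              nFrames = as.integer(nFrames), voxelSize = voxelSize,
              nucleus = nucleus, hubs = hubs, ms2 = ms2, noise = noise)
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
  cfg
}

#' Validate a SimulationConfig
#'
#' Checks positivity of rates and sizes, that mixture weights sum to 1,
#' and that coupling offsets fit inside the inter-burst spacing (hub ON
#' windows of consecutive bursts must not overlap).
#' @param cfg a SimulationConfig.
#' @return invisibly \code{TRUE}; stops with a configuration error otherwise.
#' @export
validateSimulationConfig <- function(cfg) {
  fail <- function(...) stop("configuration error: ", ..., call. = FALSE)
  if (cfg$frameInterval <= 0) fail("frame_interval must be > 0")
  if (cfg$nFrames < 1L) fail("n_frames must be >= 1")
  if (any(cfg$voxelSize <= 0)) fail("voxel sizes must be positive")
  if (any(cfg$nucleus$radii <= 0)) fail("nucleus radii must be positive")
  mx <- cfg$hubs$dwellMixture
  if (length(mx$weights) != 3L || length(mx$means) != 3L ||
      length(mx$sds) != 3L) fail("dwell mixture needs 3 components")
  if (any(mx$weights < 0) || abs(sum(mx$weights) - 1) > 1e-8)
    fail("mixture weights must be non-negative and sum to 1")
  if (any(mx$means <= 0)) fail("mixture means must be positive")
  if (any(mx$sds < 0)) fail("mixture sds must be non-negative")
  with(cfg$ms2, {
    if (interBurst <= 0 || riseRate <= 0 || amplitude <= 0 ||
        decayRate <= 0 || plateau < 0)
      fail("burst model parameters must be positive")
    if (!coupling %in% c("none", "lag", "arrival"))
      fail("coupling must be one of none/lag/arrival")
    if (coupling == "arrival") {
      dt_min <- cfg$frameInterval / 60
      if (arrivalLead < 0 || dwellAfter < 0)
        fail("coupling offsets must be non-negative")
      if (arrivalLead + dwellAfter + dt_min >= interBurst)
        fail("coupling offsets larger than inter-burst spacing: ",
             "hub ON windows of consecutive bursts would overlap")
    }
  })
  if (cfg$hubs$density < 0 || cfg$hubs$sigma <= 0)
    fail("hub density must be >= 0 and blob sigma > 0")
  invisible(TRUE)
}

#' Sample dwell times from a truncated three-component Gaussian mixture
#'
#' Draws durations (minutes) from a mixture of three Gaussians truncated
#' at zero: negative draws are rejected and redrawn within their
#' component.
#'
#' @param mixture list with \code{weights}, \code{means}, \code{sds}
#'   (each length 3; minutes).
#' @param n number of samples (>= 1).
#' @param seed integer seed; identical seeds give identical samples.
#' @return numeric vector of n positive durations.
#' @export
sampleDwellTimes <- function(mixture, n, seed = NULL) {
  stopifnot(n >= 1)
  if (length(mixture$means) != 3L || any(mixture$means <= 0) ||
      any(mixture$weights < 0) || abs(sum(mixture$weights) - 1) > 1e-8)
    stop("configuration error: mixture needs 3 positive-mean components ",
         "with non-negative weights summing to 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(3L, n, replace = TRUE, prob = mixture$weights)
  out <- stats::rnorm(n, mixture$means[comp], mixture$sds[comp])
  bad <- which(out <= 0)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- stats::rnorm(length(bad), mixture$means[comp[bad]],
                             mixture$sds[comp[bad]])
    bad <- bad[out[bad] <= 0]
    guard <- guard + 1L
  }
  if (length(bad) > 0L) out[bad] <- mixture$means[comp[bad]]
  out
}

# Deterministic burst waveform: linear rise at riseRate to amplitude,
# plateau, exponential decay. Analytic amplitude/output/loading rate
# make it a closed-form oracle for burst calling.
burstWaveform <- function(t, start, riseRate, amplitude, plateau,
                          decayRate) {
  rise <- amplitude / riseRate
  dt <- t - start
  v <- numeric(length(t))
  up <- dt >= 0 & dt < rise
  v[up] <- riseRate * dt[up]
  fl <- dt >= rise & dt < rise + plateau
  v[fl] <- amplitude
  dn <- dt >= rise + plateau
  v[dn] <- amplitude * exp(-decayRate * (dt[dn] - rise - plateau))
  v
}

# Ground-truth burst bookkeeping: end = time the decay falls to 5% of
# amplitude; output = closed-form integral from start to end.
burstTruth <- function(starts, riseRate, amplitude, plateau, decayRate) {
  if (length(starts) == 0L)
    return(data.frame(index = integer(0), start_min = numeric(0),
                      end_min = numeric(0), duration_min = numeric(0),
                      amplitude = numeric(0), output = numeric(0),
                      loading_rate = numeric(0), is_first = logical(0)))
  rise <- amplitude / riseRate
  tail <- log(20) / decayRate
  end <- starts + rise + plateau + tail
  output <- 0.5 * amplitude * rise + amplitude * plateau +
    amplitude / decayRate * (1 - 0.05)
  data.frame(index = seq_along(starts), start_min = starts, end_min = end,
             duration_min = end - starts, amplitude = amplitude,
             output = output, loading_rate = riseRate,
             is_first = seq_along(starts) == 1L)
}

#' Simulate paired MS2 / hub-intensity traces with ground truth
#'
#' Generates a nascent-transcription intensity trace from the burst
#' model on the acquisition frame grid, plus a hub signal at the locus
#' under one of three coupling modes:
#' \describe{
#'   \item{none}{hub presence drawn as dwell-mixture ON intervals with
#'     exponential gaps, independent of bursts.}
#'   \item{lag}{hub intensity is a smoothed copy of the MS2 trace
#'     shifted by \code{ms2$lag} minutes (positive = hub follows MS2),
#'     plus optional noise.}
#'   \item{arrival}{hub presence switches ON \code{arrivalLead} minutes
#'     before each non-first burst start and OFF \code{dwellAfter}
#'     minutes after that burst start; events are snapped to the frame
#'     grid.}
#' }
#'
#' @param cfg a [simulationConfig()].
#' @return list with \code{trace} (data.frame: frame, t_min, ms2,
#'   hub_intensity, hub_present), \code{truth} (bursts, hub events,
#'   imposed lag), and the echoed \code{config}.
#' @export
simulateTraces <- function(cfg) {
  validateSimulationConfig(cfg)
  set.seed(cfg$seed)
  dt <- cfg$frameInterval / 60
  tmin <- (seq_len(cfg$nFrames) - 1L) * dt
  m <- cfg$ms2

  starts <- seq(m$firstBurst, by = m$interBurst,
                length.out = max(1, min(m$nBursts,
                  floor((max(tmin) - m$firstBurst) / m$interBurst) + 1)))
  starts <- starts[starts <= max(tmin)]
  # snap burst starts to the frame grid so event times are realisable
  starts <- round(starts / dt) * dt
  if (m$coupling == "arrival" && length(starts) > 1L) {
    # keep only bursts whose full hub window [start - lead, start + dwell]
    # fits inside the trace, so no ground-truth event is truncated
    keep <- c(TRUE, vapply(starts[-1], function(s)
      s - m$arrivalLead >= 0 && s + m$dwellAfter <= max(tmin),
      logical(1)))
    starts <- starts[keep]
  }
  ms2 <- numeric(cfg$nFrames)
  for (s in starts)
    ms2 <- ms2 + burstWaveform(tmin, s, m$riseRate, m$amplitude,
                               m$plateau, m$decayRate)
  bursts <- burstTruth(starts, m$riseRate, m$amplitude, m$plateau,
                       m$decayRate)

  hubI <- numeric(cfg$nFrames)
  hubP <- logical(cfg$nFrames)
  hubEvents <- data.frame(on_frame = integer(0), off_frame = integer(0),
                          on_min = numeric(0), off_min = numeric(0),
                          burst_index = integer(0))
  if (m$coupling == "lag") {
    sm <- smoothTrace(ms2, sigma = m$smoothSigma / dt)
    lagFrames <- round(m$lag / dt)
    hubI <- shiftTrace(sm, lagFrames)
    hubP <- hubI > 0.05 * max(hubI)
  } else if (m$coupling == "arrival") {
    for (k in seq_along(starts)[-1]) {
      onF <- as.integer(round((starts[k] - m$arrivalLead) / dt))
      offF <- as.integer(round((starts[k] + m$dwellAfter) / dt))
      onF <- max(0L, onF); offF <- min(cfg$nFrames - 1L, offF)
      hubP[(onF + 1L):(offF + 1L)] <- TRUE
      hubEvents <- rbind(hubEvents, data.frame(
        on_frame = onF, off_frame = offF, on_min = onF * dt,
        off_min = offF * dt, burst_index = k))
    }
    hubI <- ifelse(hubP, cfg$hubs$intensityMean, 0)
  } else {
    # uncoupled ON/OFF process: dwell-mixture ON durations separated by
    # exponential OFF gaps with the same mean lifetime
    t <- stats::rexp(1, rate = 1 / cfg$hubs$meanLifetime)
    while (t < max(tmin)) {
      d <- sampleDwellTimes(cfg$hubs$dwellMixture, 1)
      onF <- as.integer(round(t / dt))
      offF <- as.integer(min(round((t + d) / dt), cfg$nFrames - 1L))
      if (onF <= offF && onF < cfg$nFrames) {
        hubP[(onF + 1L):(offF + 1L)] <- TRUE
        hubEvents <- rbind(hubEvents, data.frame(
          on_frame = onF, off_frame = offF, on_min = onF * dt,
          off_min = offF * dt, burst_index = NA_integer_))
      }
      t <- t + d + stats::rexp(1, rate = 1 / cfg$hubs$meanLifetime)
    }
    hubI <- ifelse(hubP, cfg$hubs$intensityMean, 0)
  }

  if (cfg$noise$traceSd > 0) {
    ms2 <- ms2 + stats::rnorm(cfg$nFrames, 0, cfg$noise$traceSd)
    hubI <- hubI + stats::rnorm(cfg$nFrames, 0, cfg$noise$traceSd)
  }

  list(trace = data.frame(frame = seq_len(cfg$nFrames) - 1L, t_min = tmin,
                          ms2 = ms2, hub_intensity = hubI,
                          hub_present = hubP),
       truth = list(bursts = bursts, hub_events = hubEvents,
                    lag_min = if (m$coupling == "lag") m$lag else NA_real_),
       config = cfg)
}

#' Gaussian smoothing of a 1D trace
#'
#' @param x numeric vector.
#' @param sigma kernel standard deviation in samples; values below 0.3
#'   return \code{x} unchanged.
#' @return smoothed vector (edges handled by replication).
#' @export
smoothTrace <- function(x, sigma) {
  if (sigma < 0.3 || length(x) < 3L) return(x)
  kr <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-kr:kr, sd = sigma)
  k <- k / sum(k)
  xp <- c(rep(x[1], kr), x, rep(x[length(x)], kr))
  as.numeric(stats::filter(xp, k, sides = 2))[(kr + 1):(kr + length(x))]
}

# integer shift with edge replication; positive k delays the signal
shiftTrace <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  if (k > 0) c(rep(x[1], min(k, n)), x[seq_len(max(0, n - k))])
  else c(x[(-k + 1):n], rep(x[n], min(-k, n)))
}
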