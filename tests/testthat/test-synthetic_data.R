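test_that("dwell-time sampling honours the mixture and the seed", {
  # degenerate mixture: single zero-variance component
  mx <- list(weights = c(1, 0, 0), means = c(5, 6, 7), sds = c(0, 0, 0))
  expect_equal(sampleDwellTimes(mx, 50, seed = 1), rep(5, 50))

  # sample mean within 3 s.e. of the closed-form mixture mean
  mx <- list(weights = c(0.5, 0.3, 0.2), means = c(0.5, 1.35, 10.04),
             sds = c(0.05, 0.1, 0.5))
  n <- 1e4
  d <- sampleDwellTimes(mx, n, seed = 42)
  mixMean <- sum(mx$weights * mx$means)
  mixVar <- sum(mx$weights * (mx$sds^2 + mx$means^2)) - mixMean^2
  expect_lt(abs(mean(d) - mixMean), 3 * sqrt(mixVar / n))
  expect_lt(abs(stats::var(d) - mixVar), 4 * mixVar / sqrt(n) * 3)
  expect_true(all(d > 0))

  # determinism
  expect_identical(sampleDwellTimes(mx, 100, seed = 9),
                   sampleDwellTimes(mx, 100, seed = 9))

  # configuration errors
  bad <- list(weights = c(0.5, 0.5, 0), means = c(-1, 2, 3),
              sds = c(1, 1, 1))
  expect_error(sampleDwellTimes(bad, 10, 1), "configuration error")
})

test_that("simulation config validates its invariants", {
  expect_error(simulationConfig(frameInterval = 0), "frame_interval")
  expect_error(
    simulationConfig(hubs = list(dwellMixture = list(
      weights = c(0.5, 0.4, 0.4), means = c(1, 2, 3), sds = c(1, 1, 1)))),
    "sum to 1")
  # arrival coupling offsets must fit within the inter-burst spacing
  expect_error(
    simulationConfig(ms2 = list(coupling = "arrival", arrivalLead = 5,
                                dwellAfter = 5, interBurst = 8)),
    "overlap")
  expect_silent(simulationConfig(ms2 = list(coupling = "arrival",
                                            arrivalLead = 2, dwellAfter = 2,
                                            interBurst = 8)))
})

test_that("trace simulator reproduces the burst waveform and couplings", {
  # zero noise, one burst: trace equals the deterministic waveform
  cfg <- simulationConfig(seed = 1, nFrames = 120,
                          ms2 = list(firstBurst = 2, interBurst = 50,
                                     nBursts = 1, riseRate = 600,
                                     amplitude = 600, plateau = 1,
                                     decayRate = 2))
  s <- simulateTraces(cfg)
  w <- HubKinetics:::burstWaveform(s$trace$t_min,
                                   s$truth$bursts$start_min[1],
                                   600, 600, 1, 2)
  expect_equal(s$trace$ms2, w)

  # imposed lag 0 with lag coupling: hub trace equals smoothed MS2 trace
  cfgL <- simulationConfig(seed = 2, nFrames = 200,
                           ms2 = list(coupling = "lag", lag = 0,
                                      smoothSigma = 0.2))
  sL <- simulateTraces(cfgL)
  sm <- smoothTrace(sL$trace$ms2, 0.2 / (11.56 / 60))
  expect_equal(sL$trace$hub_intensity, sm)

  # arrival coupling: ground-truth lead equals the configured value for
  # every non-first burst, up to frame-grid snapping
  lead <- 20.95
  cfgA <- simulationConfig(seed = 3, nFrames = 950,
                           ms2 = list(coupling = "arrival",
                                      arrivalLead = lead, dwellAfter = 23.16,
                                      interBurst = 46, firstBurst = 2,
                                      riseRate = 600, amplitude = 600,
                                      plateau = 1.5, decayRate = 2))
  sA <- simulateTraces(cfgA)
  ev <- sA$truth$hub_events
  expect_gt(nrow(ev), 0)
  dt <- 11.56 / 60
  for (i in seq_len(nrow(ev))) {
    bStart <- sA$truth$bursts$start_min[ev$burst_index[i]]
    expect_lt(abs((bStart - ev$on_min[i]) - lead), dt / 2 + 1e-9)
  }

  # determinism
  s2 <- simulateTraces(cfg)
  expect_identical(s$trace, s2$trace)
})

test_that("embryo movie renders nuclei, hubs and MS2 spots faithfully", {
  vsz <- c(0.15, 0.15, 0.3)
  base <- simulationConfig(seed = 5, nFrames = 3, voxelSize = vsz,
    nucleus = list(n = 2, radii = c(1.6, 1.6, 2.0), driftSpeed = 0,
                   intensityProfile = function(t) 1),
    hubs = list(density = 0),
    ms2 = list(firstBurst = 100),   # no bursts in span
    noise = list(gain = Inf, readSd = 0, background = 0))
  sim <- simulateEmbryoMovie(base, dims = c(64L, 64L, 20L))
  ch1 <- intensities(sim$movie)[, , , 1, 1]
  # noise off, hubs off: channel 1 is exactly nuclei on empty background
  expect_setequal(unique(as.numeric(ch1)), c(0, 100))
  vin <- sum(ch1 > 0) * prod(vsz)
  expect_lt(abs(vin - 2 * 4 / 3 * pi * prod(c(1.6, 1.6, 2.0))) / vin, 0.1)

  # MS2 spot integrated intensity matches the burst amplitude
  cfgM <- simulationConfig(seed = 6, nFrames = 8, voxelSize = vsz,
    nucleus = list(n = 1, radii = c(1.8, 1.8, 2.2), driftSpeed = 0,
                   intensityProfile = function(t) 1),
    hubs = list(density = 0),
    ms2 = list(firstBurst = 0, interBurst = 50, riseRate = 1e5,
               amplitude = 2000, plateau = 2, decayRate = 2,
               phaseJitter = 0),
    noise = list(gain = Inf, readSd = 0, background = 0))
  simM <- simulateEmbryoMovie(cfgM, dims = c(48L, 48L, 20L))
  f <- 4   # mid-plateau frame
  ch2 <- intensities(simM$movie)[, , , 2, f]
  bg <- 0.4 * 100  # nuclear background in channel 2
  spot <- sum(ch2[ch2 > bg + 1e-9] - bg)
  trueI <- simM$truth$ms2$intensity[simM$truth$ms2$frame == f - 1]
  expect_lt(abs(spot - trueI) / trueI, 0.05)

  # hub count per nucleus per frame has mean density x nuclear volume
  dens <- 0.06
  cfgH <- simulationConfig(seed = 7, nFrames = 40, voxelSize = vsz,
    nucleus = list(n = 2, radii = c(1.8, 1.8, 2.2), driftSpeed = 0),
    hubs = list(density = dens, meanLifetime = 0.8),
    ms2 = list(firstBurst = 1000),
    noise = list(gain = Inf, readSd = 0, background = 0))
  simH <- simulateEmbryoMovie(cfgH, dims = c(64L, 64L, 20L))
  nucVol <- 4 / 3 * pi * prod(c(1.8, 1.8, 2.2))
  perFrame <- table(factor(simH$truth$hub_inventory$frame, 0:39),
                    factor(simH$truth$hub_inventory$nucleus_id, 1:2))
  counts <- as.numeric(perFrame)
  expFf <- dens * nucVol
  # Poisson counts: mean within 4 s.e. (correlated frames, generous)
  expect_lt(abs(mean(counts) - expFf), 4 * sqrt(expFf / 20))

  # conservation: every inventory entry maps to a ground-truth hub
  # whose [birth, death] covers its frame
  inv <- simH$truth$hub_inventory
  hub <- simH$truth$hubs
  m <- match(inv$hub_id, hub$hub_id)
  expect_true(all(inv$frame >= hub$birth_frame[m] &
                    inv$frame <= hub$death_frame[m]))
  expect_true(all(hub$death_min >= hub$birth_min))

  # seed determinism of the full movie
  simH2 <- simulateEmbryoMovie(cfgH, dims = c(64L, 64L, 20L))
  expect_identical(intensities(simH$movie), intensities(simH2$movie))
})
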