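fi <- 11.56
dt <- fi / 60

test_that("burst calling matches closed-form trapezoid waveforms", {
  # rise and plateau chosen as exact grid multiples
  rise <- 5 * dt; plateau <- 8 * dt
  A <- 600; rho <- A / rise; decay <- 2
  tmin <- (0:399) * dt
  starts <- c(10, 150, 290) * dt
  tr <- rowSums(vapply(starts, function(s)
    HubKinetics:::burstWaveform(tmin, s, rho, A, plateau, decay),
    numeric(400)))
  bs <- callBursts(tr, fi, burstParams(smoothSigma = 0))
  expect_equal(nrow(bs), 3)
  expect_equal(bs$start_min, starts)
  expect_equal(bs$amplitude, rep(A, 3))
  expect_equal(bs$loading_rate, rep(rho, 3))
  # duration: truth ends when the decay reaches 5% of amplitude
  truthDur <- rise + plateau + log(20) / decay
  expect_true(all(abs(bs$duration_min - truthDur) <= dt + 1e-9))
  # output: closed-form area of rise + plateau + truncated decay
  truthOut <- 0.5 * A * rise + A * plateau + A * (1 - 0.05) / decay
  expect_true(all(abs(bs$output - truthOut) / truthOut < 0.02))
  expect_equal(bs$is_first, c(TRUE, FALSE, FALSE))

  # two separated bursts: frequency = 2 / span
  bs2 <- callBursts(tr[1:280], fi, burstParams(smoothSigma = 0))
  expect_equal(nrow(bs2), 2)
  expect_equal(burstFrequency(bs2, 280 * dt), 2 / (280 * dt))

  # flat trace: no bursts; empty list has frequency 0
  expect_equal(nrow(callBursts(rep(3, 100), fi)), 0)
  expect_equal(burstFrequency(NULL, 10), 0)

  # output additivity: trace integral equals the summed burst outputs
  # plus a small inter-burst residual (decay tails below 5%)
  tot <- sum((tr[-1] + tr[-length(tr)]) / 2) * dt
  expect_lt(abs(tot - sum(bs$output)) / tot, 0.06)
})

test_that("burst calling recovers generator bursts under noise", {
  matched <- 0L; total <- 0L
  for (s in 1:25) {
    cfg <- simulationConfig(seed = s, nFrames = 400,
      ms2 = list(firstBurst = 2, interBurst = 12, riseRate = 600,
                 amplitude = 600, plateau = 1.5, decayRate = 2),
      noise = list(traceSd = 30))
    st <- simulateTraces(cfg)
    bs <- callBursts(st$trace$ms2, fi)
    for (i in seq_len(nrow(st$truth$bursts))) {
      tb <- st$truth$bursts[i, ]
      if (tb$end_min > max(st$trace$t_min)) next
      total <- total + 1L
      if (nrow(bs) && max(vapply(seq_len(nrow(bs)), function(j)
        intervalJaccard(tb$start_min, tb$end_min, bs$start_min[j],
                        bs$end_min[j]), numeric(1))) > 0.5)
        matched <- matched + 1L
    }
  }
  expect_gte(matched / total, 0.95)
})

test_that("burst-hub linking recovers imposed arrival and dwell times", {
  res <- arrivalRecovery(lead = 1.5, dwell = 2.0, seed = 3,
                         interBurst = 8, nFrames = 400)
  expect_gt(length(res$leads), 5)
  expect_true(all(abs(res$leads - 1.5) <= dt + 1e-9))
  expect_true(all(abs(res$dwells - 2.0) <= dt + 1e-9))

  # no hubs ever: all links false, leads undefined
  cfg <- simulationConfig(seed = 4, nFrames = 200,
                          hubs = list(density = 0, meanLifetime = 1e-9))
  s <- simulateTraces(cfg)
  bs <- callBursts(s$trace$ms2, fi)
  recs <- data.frame(frame = s$trace$frame, hub_present = FALSE,
                     overlap_mean_intensity = NA_real_,
                     sphere_mean_intensity = 0)
  lk <- linkBurstsToHubs(bs, extractRuns(recs, fi), recs)
  expect_false(any(lk$hub_present_at_start))
  expect_true(all(is.na(lk$arrival_lead_min)))

  # threshold monotonicity: high-mode presence is a subset of any-mode
  rH <- arrivalRecovery(1.5, 2.0, 5, 8, 400)
  recs2 <- data.frame(frame = 0:399,
                      hub_present = seq_len(400) %in%
                        (rH$links$start_frame + 1),
                      overlap_mean_intensity = stats::runif(400, 1, 3),
                      sphere_mean_intensity = 1)
  runs2 <- extractRuns(recs2, fi)
  lkAny <- linkBurstsToHubs(rH$bursts, runs2, recs2, mode = "any")
  lkHigh <- linkBurstsToHubs(rH$bursts, runs2, recs2, mode = "high",
                             highThreshold = 2)
  expect_true(all(!lkHigh$high_hub_at_start | lkAny$hub_present_at_start))
  lkTop <- linkBurstsToHubs(rH$bursts, runs2, recs2, mode = "high",
                            highThreshold = 99)
  expect_false(any(lkTop$high_hub_at_start))
  expect_equal(lkTop$hub_present_at_start, lkAny$hub_present_at_start)
})

test_that("high-intensity threshold is the mean ventral hub intensity", {
  hubs <- data.frame(mean_intensity = c(2, 4))
  expect_equal(highIntensityThreshold(hubs), 3)
  expect_equal(highIntensityThreshold(hubs[1, , drop = FALSE]), 2)
  expect_equal(highIntensityThreshold(rbind(hubs, hubs)), 3)  # duplication
})

test_that("cross-correlation peaks at the imposed lag, antisymmetrically", {
  cfg <- simulationConfig(seed = 6, nFrames = 300,
                          ms2 = list(coupling = "lag", lag = 0))
  s <- simulateTraces(cfg)
  # self-correlation: peak at lag 0 with value 1
  cc <- crossCorrelate(s$trace$ms2, s$trace$ms2, fi, maxLag = 3)
  expect_equal(cc$peak_lag_min, 0)
  expect_equal(cc$peak_value, 1, tolerance = 1e-6)
  expect_true(all(cc$value >= -1 & cc$value <= 1))

  # imposed delay: recovered to one frame; swapping negates the lag
  cfgD <- simulationConfig(seed = 7, nFrames = 400,
                           ms2 = list(coupling = "lag", lag = 6 * dt))
  sD <- simulateTraces(cfgD)
  ccD <- crossCorrelate(sD$trace$ms2, sD$trace$hub_intensity, fi,
                        maxLag = 4)
  expect_lt(abs(ccD$peak_lag_min - 6 * dt), dt + 1e-9)
  ccR <- crossCorrelate(sD$trace$hub_intensity, sD$trace$ms2, fi,
                        maxLag = 4)
  expect_equal(ccR$peak_lag_min, -ccD$peak_lag_min)

  # anti-correlated traces: negative value at lag 0
  x <- sin(seq(0, 20, length.out = 200))
  ccA <- crossCorrelate(x, -x, fi)
  expect_lt(ccA$value[ccA$lag_min == 0], -0.9)

  # zero-variance trace: undefined with a warning
  expect_warning(ccZ <- crossCorrelate(rep(1, 50), stats::runif(50), fi),
                 "zero-variance")
  expect_true(is.na(ccZ$peak_lag_min))
})

test_that("Mann-Whitney comparisons match exhaustive pair counting", {
  set.seed(41)
  # identical groups: not significant
  g <- stats::rnorm(20)
  same <- groupCompare(g, g)
  expect_equal(same$stars, "ns")
  expect_gt(same$p_value, 0.5)

  # disjoint support, n = 20 each: U = 0, p < 0.001
  a <- stats::runif(20, 0, 1); b <- stats::runif(20, 2, 3)
  disj <- groupCompare(a, b)
  expect_equal(disj$U, 0)
  expect_lt(disj$p_value, 0.001)
  expect_equal(disj$stars, "***")

  # U equals brute-force pair counting for n <= 12 (with ties)
  for (i in 1:10) {
    x <- sample(1:6, sample(3:12, 1), replace = TRUE)
    y <- sample(1:6, sample(3:12, 1), replace = TRUE)
    expect_equal(groupCompare(x, y)$U, bruteU(x, y))
  }
})

test_that("burst-parameter correlations reproduce the two-pass Pearson", {
  set.seed(51)
  n <- 30
  dwell <- stats::runif(n, 0.5, 5)
  bursts <- data.frame(burst_index = 1:n, amplitude = 3 * dwell + 1,
                       loading_rate = stats::rnorm(n, 10),
                       output = 2 * dwell + stats::rnorm(n, 0, 0.2),
                       duration_min = stats::runif(n, 0.5, 2))
  links <- data.frame(burst_index = 1:n, dwell_after_min = dwell,
                      pre_burst_intensity = stats::rnorm(n, 1.5, 0.2))
  cs <- correlateBurstParams(bursts, links, "dwell_after")
  # exact linear coupling: r2 = 1 and the slope is recovered
  ampRow <- cs[cs$parameter == "amplitude", ]
  expect_equal(ampRow$r2, 1.0)
  expect_equal(ampRow$slope, 3.0)
  # r2 equals the squared two-pass Pearson coefficient
  outRow <- cs[cs$parameter == "output", ]
  expect_equal(outRow$r2, twoPassPearson(dwell, bursts$output)^2)
  # shuffled predictor: correlation collapses
  linksS <- links
  set.seed(52)
  linksS$dwell_after_min <- sample(dwell)
  csS <- correlateBurstParams(bursts, linksS, "dwell_after")
  expect_lt(csS[csS$parameter == "amplitude", "r2"], 0.3)
})
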