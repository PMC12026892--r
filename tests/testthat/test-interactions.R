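test_that("sphere metrics match the exhaustive voxel oracle", {
  vsz <- c(0.104, 0.104, 0.3)
  dims <- c(30L, 30L, 12L)
  set.seed(21)
  for (i in 1:20) {
    lab <- array(as.integer(stats::runif(prod(dims)) < 0.15), dims)
    nv <- array(stats::runif(prod(dims)), dims)
    pos <- c(stats::runif(2, 0.4, 2.6), stats::runif(1, 0.5, 3.1))
    sm <- sphereMetrics(nv, lab, pos, vsz, 0.5)
    member <- bruteSphere(dims, vsz, pos, 0.5)
    expect_identical(sm$sphere_voxels, sum(member))
    expect_equal(sm$sphere_mean_intensity, mean(nv[member]))
    ov <- member & (as.vector(lab) > 0)
    expect_equal(sm$overlap_volume_um3, sum(ov) * prod(vsz))
    expect_equal(sm$hub_present, any(ov))
    if (any(ov)) expect_equal(sm$overlap_mean_intensity, mean(nv[ov]))
  }

  # no hubs anywhere
  sm0 <- sphereMetrics(array(1, dims), array(0L, dims), c(1.5, 1.5, 1.8),
                       vsz, 0.5)
  expect_false(sm0$hub_present)
  expect_equal(sm0$overlap_volume_um3, 0)
  expect_true(is.na(sm0$overlap_mean_intensity))

  # a tiny hub 1.1 um away cannot overlap a 0.5 um sphere
  lab <- array(0L, dims)
  lab[cbind(15, 15, 6)] <- 1L
  hubPos <- (c(15, 15, 6) - 0.5) * vsz
  sm1 <- sphereMetrics(array(1, dims), lab,
                       hubPos + c(1.1, 0, 0), vsz, 0.5)
  expect_false(sm1$hub_present)

  # occupied sphere volume approaches 4/3 pi r^3 as voxels shrink
  fine <- c(0.02, 0.02, 0.02)
  df <- c(60L, 60L, 60L)
  smF <- sphereMetrics(array(1, df), array(1L, df), c(0.6, 0.6, 0.6),
                       fine, 0.5)
  expect_lt(abs(smF$overlap_volume_um3 - 4 / 3 * pi * 0.5^3),
            4 * pi * 0.25 * max(fine))   # one voxel shell
})

test_that("hub-contact runs respect strict presence and gap tolerance", {
  fi <- 11.56
  rec <- data.frame(frame = 0:4,
                    hub_present = c(TRUE, TRUE, TRUE, FALSE, TRUE),
                    overlap_mean_intensity = c(1.5, 1.6, 1.4, NA, 2.0))
  runs <- extractRuns(rec, fi, gapTolerance = 0L)
  expect_equal(nrow(runs), 2)
  expect_equal(runs$duration_min, c(3, 1) * fi / 60)

  # tolerance 1 bridges the single absent frame
  runs1 <- extractRuns(rec, fi, gapTolerance = 1L)
  expect_equal(nrow(runs1), 1)
  expect_equal(runs1$duration_min, 5 * fi / 60)

  # all-absent series
  recA <- data.frame(frame = 0:4, hub_present = FALSE)
  expect_equal(nrow(extractRuns(recA, fi)), 0)

  # total run time never exceeds the observation span
  set.seed(5)
  recR <- data.frame(frame = 0:199,
                     hub_present = stats::runif(200) < 0.4)
  runsR <- extractRuns(recR, fi)
  expect_lte(sum(runsR$duration_min), 200 * fi / 60)
})

test_that("the dwell-time mixture fit recovers separable components", {
  # three near-point-masses: means recovered to <1%
  set.seed(31)
  x <- c(rnorm(300, 0.3, 0.005), rnorm(300, 1.35, 0.005),
         rnorm(300, 10.04, 0.005))
  fit <- fitDwellMixture(x, seed = 1)
  expect_lt(max(abs(mixtureMeans(fit) - c(0.3, 1.35, 10.04)) /
                  c(0.3, 1.35, 10.04)), 0.01)
  expect_true(all(diff(mixtureMeans(fit)) > 0))
  expect_equal(sum(mixtureWeights(fit)), 1.0)

  # class assignment follows the responsibilities
  expect_equal(as.integer(table(fit@classes)), c(300, 300, 300))

  # determinism under a fixed seed
  fit2 <- fitDwellMixture(x, seed = 1)
  expect_identical(mixtureMeans(fit), mixtureMeans(fit2))

  # identical durations: variance floor keeps the fit finite, flagged
  expect_message(fitC <- fitDwellMixture(rep(2, 50), seed = 1),
                 "degenerate")
  expect_true(all(is.finite(mixtureMeans(fitC))))

  # parameter recovery on a sampled separable mixture (n = 2000),
  # cross-checked against an independent EM implementation (mclust)
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  mx <- list(weights = c(0.4, 0.35, 0.25), means = c(0.3, 1.35, 10.04),
             sds = c(0.06, 0.27, 2.0))
  d <- sampleDwellTimes(mx, 2000, seed = 17)
  fitS <- fitDwellMixture(d, seed = 17)
  expect_lt(max(abs(mixtureMeans(fitS) - mx$means) / mx$means), 0.05)
  mc <- Mclust(d, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(mixtureMeans(fitS), sort(unname(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("survival curves equal the sorted empirical 1-CDF", {
  s <- survivalCurve(c(1, 2, 3))
  expect_equal(s$survival[s$duration_min == 0], 1)
  expect_equal(s$survival[s$duration_min == 2], 2 / 3)

  set.seed(7)
  d <- stats::rexp(500, 0.5)
  sc <- survivalCurve(d)
  # oracle: sort-based empirical survival
  for (t in stats::quantile(d, c(0.1, 0.5, 0.9))) {
    i <- max(which(sc$duration_min <= t))
    expect_equal(sc$survival[i], sum(sort(d) >= sc$duration_min[i]) / 500)
  }
  expect_true(all(diff(sc$survival) <= 0))
})
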