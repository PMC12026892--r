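vsz <- c(0.104, 0.104, 0.3)

makeSpotNucleus <- function(spotPos = NULL, amp = 3000,
                            dims = c(48L, 48L, 20L), bg = 40) {
  vc <- HubKinetics:::voxelCenters(dims, vsz)
  ctr <- dims * vsz / 2
  vol <- HubKinetics:::addEllipsoid(array(0, dims), ctr, c(1.8, 1.8, 2.2),
                                    bg, vc)
  mask <- vol > 0
  if (!is.null(spotPos)) {
    peak <- HubKinetics:::blobPeakForIntegral(amp, c(0.12, 0.12, 0.18), vsz)
    vol <- HubKinetics:::addBlob(vol, spotPos, c(0.12, 0.12, 0.18), peak, vc)
  }
  list(vol = vol, mask = mask, ctr = ctr)
}

test_that("MS2 candidate detection localizes diffraction-limited spots", {
  # blank nucleus: no candidates
  blank <- makeSpotNucleus(NULL)
  expect_equal(nrow(detectMS2Candidates(blank$vol, blank$mask, vsz)), 0)

  # uniform field (zero-variance DoG response): defined as no candidates
  flat <- array(5, c(20, 20, 8))
  expect_equal(nrow(detectMS2Candidates(flat, array(TRUE, dim(flat)), vsz)),
               0)

  # single spot: one candidate, weighted centroid within half a voxel
  pos <- makeSpotNucleus(NULL)$ctr + c(0.4, -0.3, 0.3)
  one <- makeSpotNucleus(pos)
  cand <- detectMS2Candidates(one$vol, one$mask, vsz)
  expect_equal(nrow(cand), 1)
  err <- abs(c(cand$x, cand$y, cand$z) - pos)
  expect_true(all(err <= vsz / 2 + 1e-9))
})

test_that("locus selection takes the brightest candidate with stable ties", {
  cand <- data.frame(label = 1:2, voxels = c(4L, 6L), x = 0, y = 0, z = 0,
                     integrated_intensity = c(10, 7), peak_filtered = 1)
  expect_equal(selectLocusSpot(cand)$label, 1L)
  expect_null(selectLocusSpot(cand[0, ]))
  expect_null(selectLocusSpot(NULL))
  tie <- transform(cand, integrated_intensity = c(9, 9))
  expect_equal(selectLocusSpot(tie)$label, 2L)   # larger voxel count wins
})

test_that("temporal linking keeps segments and reports gaps", {
  det <- data.frame(frame = 0:9, x = 1, y = 1, z = 1, intensity = 5)
  tr <- trackMS2(det)
  expect_equal(unique(tr$segment), 1L)

  # single-frame dropout: one gap, detections still one locus
  det2 <- det[det$frame != 4, ]
  tr2 <- trackMS2(det2)
  expect_equal(unique(tr2$segment), c(1L, 2L))
  expect_equal(sum(diff(tr2$frame) > 1), 1)

  # jump beyond the step limit starts a new segment
  det3 <- det
  det3$x[6:10] <- 5
  tr3 <- trackMS2(det3, maxStep = 1)
  expect_equal(max(tr3$segment), 2L)
})

test_that("gap filling is exact under nucleus translation and scaling", {
  nuc <- data.frame(frame = 0:9, x = 5, y = 5, z = 3,
                    eq_radius_x = 2, eq_radius_y = 2, eq_radius_z = 2.4)
  det <- data.frame(frame = c(0, 1, 5, 6), x = 6, y = 5.5, z = 3,
                    intensity = c(5, 5, 5, 5))
  raw <- trackMS2(det)
  # static nucleus: interpolation between identical positions is identical
  filled <- fillTrack(raw, nuc, extrapolateFrames = 20L)
  expect_equal(unique(filled$x), 6)
  expect_equal(unique(filled$y), 5.5)
  expect_equal(sum(filled$status == "interpolated"), 3)
  expect_equal(sum(filled$status == "detected"), 4)

  # rigid nucleus translation with the spot riding along (fixed
  # nucleus-relative position): interpolated positions translate too
  nucT <- nuc
  nucT$x <- nuc$x + 0.5 * nuc$frame    # rigid translation
  detT <- det
  detT$x <- det$x + 0.5 * det$frame
  filledT <- fillTrack(trackMS2(detT, maxStep = 3), nucT,
                       extrapolateFrames = 20L)
  gap <- filledT$status == "interpolated"
  expect_equal(filledT$x[gap], 6 + 0.5 * filledT$frame[gap])
  expect_equal(filledT$y[gap], rep(5.5, 3))

  # only 5 earlier frames exist: 5 extrapolated frames, not 20
  det5 <- data.frame(frame = 5:7, x = 6, y = 5, z = 3, intensity = 1)
  filled5 <- fillTrack(trackMS2(det5), nuc, extrapolateFrames = 20L)
  expect_equal(sum(filled5$status == "extrapolated"), 5)
  ext <- filled5$frame[filled5$status == "extrapolated"]
  expect_true(all(ext < 5))   # extrapolation strictly precedes detection

  # status accounting: every covered frame has exactly one status
  expect_equal(nrow(filled5), length(unique(filled5$frame)))
  expect_true(all(filled5$status %in%
                    c("detected", "interpolated", "extrapolated")))

  # isotropic size change: gaps interpolate in nucleus-relative
  # coordinates and map back through each frame's radius
  nucS <- nuc
  nucS[, c("eq_radius_x", "eq_radius_y", "eq_radius_z")] <-
    nuc[, c("eq_radius_x", "eq_radius_y", "eq_radius_z")] *
    (1 + 0.05 * nuc$frame)
  filledS <- fillTrack(raw, nucS, extrapolateFrames = 0L)
  rAt <- function(f) (6 - 5) / nucS$eq_radius_x[match(f, nucS$frame)]
  for (f in 2:4) {
    w <- (f - 1) / (5 - 1)
    relExp <- (1 - w) * rAt(1) + w * rAt(5)
    expect_equal(filledS$x[filledS$frame == f],
                 5 + relExp * nucS$eq_radius_x[match(f, nucS$frame)])
  }
})

test_that("manual edits override automatic tracking reproducibly", {
  det <- data.frame(frame = 0:4, x = 1, y = 1, z = 1, intensity = 5)
  raw <- trackMS2(det)
  edits <- data.frame(frame = c(2, 7), x = c(1.5, 2), y = 1, z = 1,
                      intensity = c(NA, 9))
  fixed <- applyTrackEdits(raw, edits)
  expect_equal(fixed$x[fixed$frame == 2], 1.5)
  expect_equal(fixed$intensity[fixed$frame == 2], 5)  # kept from auto
  expect_equal(fixed$x[fixed$frame == 7], 2)          # added detection
  expect_equal(fixed$intensity[fixed$frame == 7], 9)
  expect_equal(applyTrackEdits(raw, NULL), raw)       # no edits, no-op
})
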