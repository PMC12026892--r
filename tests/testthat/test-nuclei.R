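vsz <- c(0.15, 0.15, 0.3)

# 2D slice with filled circles of radius r at given centres (um)
makeSlice <- function(centers, r = 1.2, dims = c(64L, 64L), value = 100) {
  x <- (seq_len(dims[1]) - 0.5) * vsz[1]
  y <- (seq_len(dims[2]) - 0.5) * vsz[2]
  sl <- matrix(0, dims[1], dims[2])
  for (i in seq_len(nrow(centers)))
    sl <- sl + value * (outer((x - centers[i, 1])^2,
                              (y - centers[i, 2])^2, "+") <= r^2)
  pmin(sl, value)
}

test_that("slice segmentation finds separated and touching nuclei", {
  two <- makeSlice(rbind(c(2.5, 2.5), c(7, 7)))
  lab <- segmentNucleiSlice(two, vsz)
  expect_equal(max(lab), 2)

  blank <- matrix(0, 64, 64)
  expect_equal(max(segmentNucleiSlice(blank, vsz)), 0)

  # touching circles are split by the seeded watershed
  touching <- makeSlice(rbind(c(3.8, 4.8), c(6.1, 4.8)))
  labT <- segmentNucleiSlice(touching, vsz, minSep = 1.0)
  expect_equal(max(labT), 2)
})

test_that("stitching merges overlapping slices and interpolates gaps", {
  sl <- makeSlice(rbind(c(2.5, 2.5), c(7, 7)))
  lab2d <- segmentNucleiSlice(sl, vsz)
  # identical labelling on every slice: one 3D label per column
  vol <- stitchAndInterpolate(replicate(6, lab2d, simplify = FALSE))
  ids <- setdiff(unique(as.integer(vol)), 0L)
  expect_length(ids, 2)
  for (z in 2:6) expect_equal(vol[, , z], vol[, , 1])

  # deleting one interior slice: interpolated volume within 10%
  slices <- replicate(6, lab2d, simplify = FALSE)
  slicesGap <- slices
  slicesGap[[3]] <- matrix(0L, 64, 64)
  v1 <- stitchAndInterpolate(slices)
  v2 <- stitchAndInterpolate(slicesGap)
  expect_lt(abs(sum(v2 > 0) - sum(v1 > 0)) / sum(v1 > 0), 0.1)
  expect_length(setdiff(unique(as.integer(v2)), 0L), 2)

  # zero-overlap regions stacked in z are never merged
  a <- matrix(0L, 64, 64); a[5:15, 5:15] <- 1L
  b <- matrix(0L, 64, 64); b[40:50, 40:50] <- 1L
  v3 <- stitchAndInterpolate(list(a, matrix(0L, 64, 64),
                                  matrix(0L, 64, 64), b), maxGap = 2L)
  expect_length(setdiff(unique(as.integer(v3)), 0L), 2)
})

test_that("greedy nearest-neighbour tracking follows drifting nuclei", {
  # static nuclei: track ids equal frame-1 assignment throughout
  mk <- function(shift) {
    sl <- makeSlice(rbind(c(2.5 + shift, 2.5), c(7, 7 - shift)))
    lab2d <- segmentNucleiSlice(sl, vsz)
    stitchAndInterpolate(replicate(4, lab2d, simplify = FALSE))
  }
  static <- replicate(3, mk(0), simplify = FALSE)
  tr <- trackNuclei(static, vsz)
  expect_equal(sort(unique(tr$nucleus_id)), 1:2)
  expect_equal(nrow(tr), 6)

  # sub-threshold drift: 100% correct linkage against generated motion
  drifting <- lapply(c(0, 0.3, 0.6, 0.9), mk)  # 0.3 um/frame < 2 um max
  trD <- trackNuclei(drifting, vsz)
  expect_equal(length(unique(trD$nucleus_id)), 2)
  # the drifting nucleus moves +x, its partner -y; check monotone paths
  n1 <- trD[trD$nucleus_id == trD$nucleus_id[which.min(trD$x)], ]
  expect_true(all(diff(n1$x[order(n1$frame)]) > 0.1))

  # tracking is invariant to a permutation of input label numbering
  perm <- lapply(drifting, function(v) {
    w <- v
    w[v == 1L] <- 2L
    w[v == 2L] <- 1L
    w
  })
  trP <- trackNuclei(perm, vsz)
  key <- function(d) d[order(d$frame, round(d$x, 6)),
                       c("frame", "x", "y", "z", "voxels")]
  expect_equal(key(trP), key(trD), ignore_attr = TRUE)
  # same partition into tracks (ids may differ)
  grpSize <- function(d) sort(as.integer(table(d$nucleus_id)))
  expect_equal(grpSize(trP), grpSize(trD))
})

test_that("nucleus time series recover intensity and analytic volume", {
  dims <- c(48L, 48L, 22L)
  vc <- HubKinetics:::voxelCenters(dims, vsz)
  radii <- c(1.8, 1.8, 2.2)
  vol <- HubKinetics:::addEllipsoid(array(0, dims), dims * vsz / 2, radii,
                                    7.5, vc)
  lab <- array(as.integer(vol > 0), dims)
  mv <- HubMovie(array(vol, c(dims, 1, 1)), voxelSize = vsz)
  tr <- trackNuclei(list(lab), vsz)
  ts <- nucleusTimeseries(tr, list(lab), mv)
  # uniform intensity c: mean exactly c
  expect_equal(ts$mean_intensity, 7.5)
  # volume within one voxel-shell of 4/3 pi abc
  vTrue <- 4 / 3 * pi * prod(radii)
  surf <- 4 * pi * (prod(radii)^(2 / 3))      # ~ surface area
  shell <- surf * max(vsz)
  expect_lt(abs(ts$volume_um3 - vTrue), shell)
  # label conservation: every foreground voxel in exactly one nucleus
  expect_equal(sum(lab > 0) * prod(vsz), ts$volume_um3)
})
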