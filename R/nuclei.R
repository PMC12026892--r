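#' Segment nuclei in one z-slice
#'
#' Intensity-based stand-in segmenter: Gaussian smoothing, Otsu
#' threshold, hole filling, then a distance-transform-seeded watershed
#' to split touching nuclei, followed by a size filter. The downstream
#' stitching/tracking stages accept any externally produced label
#' volumes, so output from a learned segmenter can be dropped in.
#'
#' @param slice 2D numeric matrix (x, y).
#' @param voxelSize (dx, dy, dz) micrometres (dz unused here).
#' @param smoothSigma smoothing sigma, micrometres.
#' @param minSep minimum seed separation, micrometres (about one
#'   nuclear radius).
#' @param minArea minimum region area, square micrometres.
#' @param threshold optional fixed threshold overriding Otsu.
#' @return 2D integer label matrix; a blank slice yields all zeros.
#' @export
segmentNucleiSlice <- function(slice, voxelSize, smoothSigma = 0.3,
                               minSep = 1.5, minArea = 3,
                               threshold = NULL) {
  d <- dim(slice)
  vol <- array(slice, c(d, 1L))
  sm <- gaussianBlur3D(vol, voxelSize, smoothSigma)[, , 1]
  thr <- if (is.null(threshold)) otsuThreshold(as.numeric(sm)) else threshold
  bin <- sm > thr
  if (!any(bin)) return(matrix(0L, d[1], d[2]))
  bin <- EBImage::fillHull(bin) > 0
  # drop sub-minimum-area speckle before seeding the watershed
  cc <- labelComponents(array(bin, c(d, 1L)), 26L)[, , 1]
  areas <- tabulate(cc[cc > 0])
  keep <- which(areas * voxelSize[1] * voxelSize[2] >= minArea)
  if (length(keep) == 0L) return(matrix(0L, d[1], d[2]))
  bin <- matrix(cc %in% keep, d[1], d[2])
  dm <- EBImage::distmap(bin)
  seeds <- localMaxima3D(array(dm, c(d, 1L)), voxelSize,
                         minSep, mask = array(bin, c(d, 1L)),
                         threshold = 0)
  if (nrow(seeds) == 0L) return(matrix(0L, d[1], d[2]))
  markers <- array(0L, c(d, 1L))
  markers[cbind(seeds[, 1], seeds[, 2], 1L)] <- seq_len(nrow(seeds))
  lab <- watershedSeeded(array(-dm, c(d, 1L)), markers,
                         array(bin, c(d, 1L)))[, , 1]
  # size filter in physical units
  areas <- tabulate(lab[lab > 0])
  tooSmall <- which(areas * voxelSize[1] * voxelSize[2] < minArea)
  if (length(tooSmall)) lab[lab %in% tooSmall] <- 0L
  # compact label ids
  u <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, d[1], d[2])
  for (i in seq_along(u)) out[lab == u[i]] <- i
  out
}

# signed distance interpolation between two 2D masks; w in [0,1]
.interpMask <- function(m1, m2, w) {
  sdf <- function(m) {
    if (!any(m)) return(matrix(-1e6, nrow(m), ncol(m)))
    if (all(m)) return(matrix(1e6, nrow(m), ncol(m)))
    as.matrix(EBImage::distmap(m)) - as.matrix(EBImage::distmap(!m))
  }
  ((1 - w) * sdf(m1) + w * sdf(m2)) > 0
}

#' Stitch per-slice nucleus labels into a 3D label volume
#'
#' Regions on consecutive slices are merged into one 3D nucleus when
#' their IoU reaches \code{iouThreshold}; a gap of up to \code{maxGap}
#' empty slices inside a nucleus is filled by signed-distance shape
#' interpolation between the flanking slices. When one region overlaps
#' two established nuclei it is assigned to the larger overlap and a
#' warning is logged.
#'
#' @param sliceLabels list of 2D integer label matrices, ordered in z.
#' @param iouThreshold minimum IoU to merge across slices (default 0.5).
#' @param maxGap maximum missing-slice gap to interpolate (default 2).
#' @return 3D integer label array (x, y, z).
#' @export
stitchAndInterpolate <- function(sliceLabels, iouThreshold = 0.5,
                                 maxGap = 2L) {
  nz <- length(sliceLabels)
  d <- dim(sliceLabels[[1]])
  out <- array(0L, c(d, nz))
  nextId <- 0L
  # lastSeen[[id]] = list(z, mask)
  lastSeen <- list()
  for (z in seq_len(nz)) {
    lab <- sliceLabels[[z]]
    ids <- setdiff(unique(as.integer(lab)), 0L)
    for (r in ids) {
      m <- lab == r
      best <- 0L; bestIoU <- 0; second <- 0
      for (g in seq_along(lastSeen)) {
        ls <- lastSeen[[g]]
        if (is.null(ls) || z - ls$z > maxGap + 1L) next
        inter <- sum(m & ls$mask)
        if (inter == 0) next
        iou <- inter / sum(m | ls$mask)
        if (iou > bestIoU) { second <- bestIoU; bestIoU <- iou; best <- g }
        else second <- max(second, iou)
      }
      if (best > 0L && bestIoU >= iouThreshold) {
        if (second >= iouThreshold)
          hkLog("slice ", z, ": region overlaps two nuclei; assigned to ",
                "max-overlap nucleus ", best, level = "warn")
        gid <- best
        gap <- z - lastSeen[[gid]]$z - 1L
        if (gap > 0L && gap <= maxGap) {
          for (k in seq_len(gap)) {
            w <- k / (gap + 1)
            im <- .interpMask(lastSeen[[gid]]$mask, m, w)
            sl <- out[, , lastSeen[[gid]]$z + k]
            sl[im & sl == 0L] <- gid
            out[, , lastSeen[[gid]]$z + k] <- sl
          }
        }
      } else {
        nextId <- nextId + 1L
        gid <- nextId
        lastSeen[[gid]] <- NULL
      }
      sl <- out[, , z]
      sl[m] <- gid
      out[, , z] <- sl
      lastSeen[[gid]] <- list(z = z, mask = m)
    }
  }
  out
}

#' Region centroids and shape summaries of a 3D label volume
#'
#' @param lab 3D integer label array.
#' @param vol optional intensity array for mean intensities.
#' @param voxelSize (dx, dy, dz) micrometres.
#' @return data.frame: label, x/y/z centroid (um), voxels, volume_um3,
#'   mean_intensity, equivalent semi-axes eq_radius_* (um, from second
#'   moments; exact for solid ellipsoids).
#' @export
regionSummaries <- function(lab, vol = NULL, voxelSize) {
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  vv <- prod(voxelSize)
  if (length(ids) == 0L)
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), voxels = integer(0),
                      volume_um3 = numeric(0), mean_intensity = numeric(0),
                      eq_radius_x = numeric(0), eq_radius_y = numeric(0),
                      eq_radius_z = numeric(0)))
  idx <- which(lab > 0)
  co <- arrayInd(idx, dim(lab))
  pos <- sweep(co - 0.5, 2, voxelSize, "*")
  g <- lab[idx]
  res <- lapply(ids, function(i) {
    s <- g == i
    p <- pos[s, , drop = FALSE]
    ctr <- colMeans(p)
    m2 <- colMeans(sweep(p, 2, ctr)^2)
    data.frame(label = i, x = ctr[1], y = ctr[2], z = ctr[3],
               voxels = sum(s), volume_um3 = sum(s) * vv,
               mean_intensity = if (is.null(vol)) NA_real_
                 else mean(vol[idx[s]]),
               eq_radius_x = max(sqrt(5 * m2[1]), voxelSize[1] / 2),
               eq_radius_y = max(sqrt(5 * m2[2]), voxelSize[2] / 2),
               eq_radius_z = max(sqrt(5 * m2[3]), voxelSize[3] / 2))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Track nuclei across frames by greedy nearest-neighbour linking
#'
#' Candidate (track, region) pairs are sorted by ascending centroid
#' distance and accepted greedily; distances beyond
#' \code{maxDisplacement} start new tracks. Position swaps within one
#' frame step are inherently ambiguous under this rule; exact distance
#' ties are resolved by track age then label order and logged.
#'
#' @param labelVolumes list of 3D label arrays, one per frame.
#' @param voxelSize (dx, dy, dz) micrometres.
#' @param frameInterval seconds per frame.
#' @param maxDisplacement micrometres per frame (default 2).
#' @param intensity optional list of matching intensity volumes.
#' @return data.frame (NucleusTrack): nucleus_id, frame, t_min, label,
#'   x, y, z, voxels, volume_um3, mean_intensity, eq_radius_*.
#' @export
trackNuclei <- function(labelVolumes, voxelSize, frameInterval = 11.56,
                        maxDisplacement = 2,
                        intensity = NULL) {
  stopifnot(length(labelVolumes) >= 1L)
  rows <- list()
  lastPos <- NULL   # matrix track x 3
  trackIds <- integer(0)
  nextTrack <- 0L
  for (f in seq_along(labelVolumes)) {
    rs <- regionSummaries(labelVolumes[[f]],
                          if (is.null(intensity)) NULL else intensity[[f]],
                          voxelSize)
    assigned <- rep(NA_integer_, nrow(rs))
    if (!is.null(lastPos) && nrow(rs) > 0L && nrow(lastPos) > 0L) {
      dmat <- outer(seq_len(nrow(lastPos)), seq_len(nrow(rs)),
                    Vectorize(function(i, j)
                      sqrt(sum((lastPos[i, ] - c(rs$x[j], rs$y[j],
                                                 rs$z[j]))^2))))
      cand <- which(dmat <= maxDisplacement, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        ord <- order(dmat[cand], cand[, 1], cand[, 2])
        usedT <- logical(nrow(lastPos)); usedR <- logical(nrow(rs))
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (usedT[i] || usedR[j]) next
          usedT[i] <- TRUE; usedR[j] <- TRUE
          assigned[j] <- trackIds[i]
        }
      }
    }
    for (j in seq_len(nrow(rs))) {
      if (is.na(assigned[j])) {
        nextTrack <- nextTrack + 1L
        assigned[j] <- nextTrack
      }
    }
    if (nrow(rs) > 0L) {
      rows[[f]] <- cbind(data.frame(nucleus_id = assigned, frame = f - 1L,
                                    t_min = (f - 1L) * frameInterval / 60),
                         rs)
      lastPos <- as.matrix(rs[, c("x", "y", "z")])
      trackIds <- assigned
    } else {
      lastPos <- NULL
      trackIds <- integer(0)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-frame nuclear mean intensity and volume
#'
#' @param tracks NucleusTrack data.frame from [trackNuclei()].
#' @param labelVolumes list of label arrays used for tracking.
#' @param movie a \linkS4class{HubMovie}; channel 1 is measured.
#' @param channel channel index or name (default 1).
#' @return data.frame: nucleus_id, frame, t_min, mean_intensity,
#'   volume_um3.
#' @export
nucleusTimeseries <- function(tracks, labelVolumes, movie, channel = 1L) {
  vv <- prod(voxelSize(movie))
  rows <- lapply(seq_len(nrow(tracks)), function(i) {
    f <- tracks$frame[i]
    lab <- labelVolumes[[f + 1L]]
    vol <- intensities(getFrame(movie, channel, f))
    sel <- lab == tracks$label[i]
    data.frame(nucleus_id = tracks$nucleus_id[i], frame = f,
               t_min = tracks$t_min[i],
               mean_intensity = mean(vol[sel]),
               volume_um3 = sum(sel) * vv)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
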