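#' Detect MS2 spot candidates in a nucleus
#'
#' Median filter, difference-of-Gaussians band-pass, then a percentile
#' threshold on the filtered in-mask voxel distribution; connected
#' components above the threshold become candidates with an
#' intensity-weighted centroid (weights from the filtered image) and an
#' integrated raw intensity. A zero-variance filtered distribution
#' (e.g. a uniform field) yields no candidates by definition. Sigma
#' values and the percentile may be tuned per nucleus; all values used
#' are recorded on the result.
#'
#' @param vol 3D numeric array (channel 2).
#' @param mask logical nucleus mask (non-empty).
#' @param voxelSize (dx, dy, dz) micrometres.
#' @param sigma1,sigma2 DoG scales in micrometres (sigma1 < sigma2).
#' @param percentile threshold percentile of the filtered in-mask
#'   distribution (default 99.5).
#' @param medianRadius median-filter half-widths in voxels.
#' @return data.frame of candidates: label, voxels, x, y, z (um,
#'   weighted centroid), integrated_intensity, peak_filtered.
#' @export
detectMS2Candidates <- function(vol, mask, voxelSize, sigma1 = 0.1,
                                sigma2 = 0.3, percentile = 99.5,
                                medianRadius = c(1L, 1L, 0L)) {
  stopifnot(any(mask))
  # pad outside the nucleus with the in-mask mean before filtering, so
  # the bright-interior/dark-exterior edge neither biases the median
  # nor rings in the DoG
  volPad <- vol
  volPad[!mask] <- mean(vol[mask])
  med <- medianFilter3D(volPad, boxOffsets(medianRadius[1],
                                           medianRadius[2],
                                           medianRadius[3]))
  dog <- dogFilter3D(med, voxelSize, sigma1, sigma2)
  inMask <- dog[mask]
  empty <- data.frame(label = integer(0), voxels = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      integrated_intensity = numeric(0),
                      peak_filtered = numeric(0))
  # zero-variance band-pass response (flat nucleus): no candidates;
  # judged relative to the image scale so float noise does not count
  if (stats::sd(inMask) <= 1e-9 * max(abs(med[mask]), 1e-12))
    return(empty)
  thr <- stats::quantile(inMask, percentile / 100, names = FALSE)
  bin <- dog > thr & mask
  if (!any(bin)) return(empty)
  lab <- labelComponents(bin, 26L)
  ids <- seq_len(attr(lab, "max"))
  idx <- which(lab > 0L)
  co <- arrayInd(idx, dim(vol))
  pos <- sweep(co - 0.5, 2, voxelSize, "*")
  g <- lab[idx]
  out <- do.call(rbind, lapply(ids, function(i) {
    s <- g == i
    w <- dog[idx[s]]
    w <- pmax(w, 0)
    if (sum(w) == 0) w <- rep(1, sum(s))
    ctr <- colSums(pos[s, , drop = FALSE] * w) / sum(w)
    data.frame(label = i, voxels = sum(s), x = ctr[1], y = ctr[2],
               z = ctr[3], integrated_intensity = sum(vol[idx[s]]),
               peak_filtered = max(dog[idx[s]]))
  }))
  rownames(out) <- NULL
  attr(out, "params") <- list(sigma1 = sigma1, sigma2 = sigma2,
                              percentile = percentile,
                              medianRadius = medianRadius)
  out
}

#' Select the locus spot among candidates
#'
#' The nascent-transcription spot is taken to be the candidate with the
#' highest integrated intensity; exact ties are broken by larger voxel
#' count, then lower label id, and logged.
#'
#' @param candidates data.frame from [detectMS2Candidates()].
#' @return one-row data.frame, or \code{NULL} when no candidates.
#' @export
selectLocusSpot <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(NULL)
  o <- order(-candidates$integrated_intensity, -candidates$voxels,
             candidates$label)
  if (nrow(candidates) > 1L &&
      candidates$integrated_intensity[o[1]] ==
        candidates$integrated_intensity[o[2]])
    hkLog("MS2 candidate intensity tie; larger-volume candidate chosen",
          level = "warn")
  candidates[o[1], , drop = FALSE]
}

#' Link per-frame spot selections into a raw track
#'
#' Nearest-neighbour linking in time: consecutive detections within
#' \code{maxStep} micrometres continue the current segment; larger
#' jumps or missing frames leave gaps (the new detection continues the
#' same locus track, since there is one locus per nucleus).
#'
#' @param selections data.frame with columns frame, x, y, z, intensity
#'   (one row per frame with a detection; frames with none omitted).
#' @param maxStep maximum per-frame displacement, micrometres.
#' @return data.frame: frame, x, y, z, intensity, segment (integer id
#'   of the contiguous linked segment).
#' @export
trackMS2 <- function(selections, maxStep = 1.0) {
  stopifnot(nrow(selections) >= 1L)
  sel <- selections[order(selections$frame), , drop = FALSE]
  seg <- integer(nrow(sel))
  seg[1] <- 1L
  if (nrow(sel) > 1L) {
    for (i in 2:nrow(sel)) {
      d <- sqrt(sum((c(sel$x[i], sel$y[i], sel$z[i]) -
                       c(sel$x[i - 1], sel$y[i - 1], sel$z[i - 1]))^2))
      contiguous <- sel$frame[i] == sel$frame[i - 1] + 1L
      seg[i] <- if (contiguous && d <= maxStep) seg[i - 1] else seg[i - 1] + 1L
    }
  }
  sel$segment <- seg
  rownames(sel) <- NULL
  sel
}

#' Apply manual tracking corrections to a raw MS2 track
#'
#' Reproducible replacement for ad-hoc manual curation: an edits table
#' (frame, x, y, z, optionally intensity) overrides or adds the
#' selection at those frames after automatic tracking and before gap
#' filling. Every applied edit is logged.
#'
#' @param raw data.frame from [trackMS2()].
#' @param edits data.frame with columns frame, x, y, z and optionally
#'   intensity; may be read from a CSV with [readTable()].
#' @return corrected track data.frame, re-sorted by frame.
#' @export
applyTrackEdits <- function(raw, edits) {
  if (is.null(edits) || nrow(edits) == 0L) return(raw)
  stopifnot(all(c("frame", "x", "y", "z") %in% names(edits)))
  for (i in seq_len(nrow(edits))) {
    j <- which(raw$frame == edits$frame[i])
    row <- data.frame(frame = edits$frame[i], x = edits$x[i],
                      y = edits$y[i], z = edits$z[i],
                      intensity = if ("intensity" %in% names(edits) &&
                                      !is.na(edits$intensity[i]))
                        edits$intensity[i]
                      else if (length(j)) raw$intensity[j] else NA_real_)
    if (length(j)) {
      raw[j, c("frame", "x", "y", "z", "intensity")] <- row
      hkLog("edit applied: frame ", row$frame, " position overridden")
    } else {
      raw <- merge(raw, row, all = TRUE)
      hkLog("edit applied: frame ", row$frame, " detection added")
    }
  }
  raw <- raw[order(raw$frame), , drop = FALSE]
  if ("segment" %in% names(raw))
    raw$segment[is.na(raw$segment)] <- 0L
  rownames(raw) <- NULL
  raw
}

#' Fill an MS2 track by interpolation and pre-appearance extrapolation
#'
#' Positions are first expressed in nucleus-relative coordinates
#' \code{r = (position - nucleus centroid) / equivalent radius} per
#' axis. Gaps between detections are filled by linear interpolation of
#' \code{r} over time and mapped back through each frame's nucleus
#' geometry, so the fill is exact under rigid nucleus translation and
#' isotropic size change. Up to \code{extrapolateFrames} frames before
#' the first detection are filled by holding the first detected
#' \code{r} fixed (motion- and size-corrected extrapolation).
#'
#' @param raw data.frame from [trackMS2()].
#' @param nucleus data.frame for one nucleus with columns frame, x, y,
#'   z, eq_radius_x/y/z (from [trackNuclei()]).
#' @param extrapolateFrames frames to extrapolate before first
#'   detection (default 20; fewer when the nucleus record is shorter).
#' @return data.frame (MS2Track): frame, x, y, z, intensity, status in
#'   detected/interpolated/extrapolated.
#' @export
fillTrack <- function(raw, nucleus, extrapolateFrames = 20L) {
  nuc <- nucleus[order(nucleus$frame), , drop = FALSE]
  geom <- function(f) {
    i <- match(f, nuc$frame)
    if (is.na(i)) return(NULL)
    list(ctr = c(nuc$x[i], nuc$y[i], nuc$z[i]),
         rad = c(nuc$eq_radius_x[i], nuc$eq_radius_y[i], nuc$eq_radius_z[i]))
  }
  toRel <- function(p, g) (p - g$ctr) / g$rad
  toAbs <- function(r, g) r * g$rad + g$ctr

  det <- raw[order(raw$frame), , drop = FALSE]
  rel <- matrix(NA_real_, nrow(det), 3)
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    g <- geom(det$frame[i])
    if (is.null(g)) next
    rel[i, ] <- toRel(c(det$x[i], det$y[i], det$z[i]), g)
    keep[i] <- TRUE
  }
  det <- det[keep, , drop = FALSE]
  rel <- rel[keep, , drop = FALSE]
  if (nrow(det) == 0L)
    stop("nucleus track does not cover any detection frame", call. = FALSE)

  first <- det$frame[1]
  last <- det$frame[nrow(det)]
  preFrames <- nuc$frame[nuc$frame < first]
  preFrames <- sort(utils::tail(sort(preFrames), extrapolateFrames))
  frames <- c(preFrames, first:last)
  out <- data.frame(frame = frames, x = NA_real_, y = NA_real_,
                    z = NA_real_, intensity = NA_real_,
                    status = NA_character_)
  for (k in seq_along(frames)) {
    f <- frames[k]
    g <- geom(f)
    if (is.null(g)) {
      hkLog("nucleus absent at frame ", f, "; frame left uncovered",
            level = "warn")
      next
    }
    i <- match(f, det$frame)
    if (!is.na(i)) {
      out[k, c("x", "y", "z")] <- toAbs(rel[i, ], g)
      out$intensity[k] <- det$intensity[i]
      out$status[k] <- "detected"
    } else if (f < first) {
      out[k, c("x", "y", "z")] <- toAbs(rel[1, ], g)
      out$intensity[k] <- 0
      out$status[k] <- "extrapolated"
    } else {
      lo <- max(which(det$frame < f))
      hi <- min(which(det$frame > f))
      w <- (f - det$frame[lo]) / (det$frame[hi] - det$frame[lo])
      r <- (1 - w) * rel[lo, ] + w * rel[hi, ]
      out[k, c("x", "y", "z")] <- toAbs(r, g)
      out$intensity[k] <- (1 - w) * det$intensity[lo] +
        w * det$intensity[hi]
      out$status[k] <- "interpolated"
    }
  }
  out <- out[!is.na(out$status), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "first_detection_frame") <- first
  out
}
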