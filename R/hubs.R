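#' Normalize a nucleus to its mean intensity
#'
#' Divides channel-1 voxel values by the mean over the nucleus mask so
#' local transcription-factor enrichment is expressed relative to the
#' nucleoplasmic background: the masked mean of the output is exactly 1,
#' and the result is invariant to rescaling of the raw intensities.
#'
#' @param vol 3D numeric array (channel 1).
#' @param mask logical array, the nucleus mask (non-empty).
#' @return list: \code{data} (normalized array, zero outside the mask)
#'   and \code{mask}.
#' @export
normalizeNucleus <- function(vol, mask) {
  stopifnot(any(mask))
  mu <- mean(vol[mask])
  if (!is.finite(mu) || mu == 0)
    stop("degenerate input: nucleus mean intensity is zero", call. = FALSE)
  out <- array(0, dim(vol))
  out[mask] <- vol[mask] / mu
  list(data = out, mask = mask)
}

#' Hub detection parameters
#'
#' Footprints are given in micrometres and converted per-axis to voxels,
#' so the ~3x coarser z sampling is respected.
#'
#' @param medianRadius median filter footprint half-width in voxels
#'   (x, y, z); default c(1, 1, 0), a 3x3x1 kernel.
#' @param erosionRadius grayscale erosion ball radius, micrometres.
#' @param residualThreshold fixed residual threshold; \code{NULL} (the
#'   default) uses Otsu on the in-mask residual distribution.
#' @param minSeparation local-maxima minimum separation, micrometres.
#' @param minVoxels minimum hub size in voxels.
#' @return named list of parameters.
#' @export
hubParams <- function(medianRadius = c(1L, 1L, 0L), erosionRadius = 0.15,
                      residualThreshold = NULL, minSeparation = 0.3,
                      minVoxels = 4L) {
  list(medianRadius = as.integer(medianRadius),
       erosionRadius = erosionRadius,
       residualThreshold = residualThreshold,
       minSeparation = minSeparation, minVoxels = as.integer(minVoxels))
}

#' Detect transcription-factor hubs in a normalized nucleus
#'
#' Morphological recipe: median filter to suppress noise; grayscale
#' erosion then morphological reconstruction by dilation (seed = eroded
#' image, mask = median-filtered image) to estimate the smooth
#' background; residual = median-filtered minus reconstructed, which
#' isolates compact bright features; threshold the residual to a binary
#' mask; local maxima of the residual (minimum physical separation)
#' seed a marker-controlled watershed on the inverted residual,
#' separating closely associated hubs that connected components would
#' fuse; finally a voxel-count size filter.
#'
#' @param normalized result of [normalizeNucleus()] (or a list with
#'   \code{data} and \code{mask}).
#' @param voxelSize (dx, dy, dz) micrometres.
#' @param params a [hubParams()] list.
#' @return integer hub label array; attributes \code{"params"} (full
#'   provenance) and \code{"threshold"} (residual threshold used).
#'   Zero hubs is a valid result.
#' @export
detectHubs <- function(normalized, voxelSize, params = hubParams()) {
  vol <- normalized$data
  mask <- normalized$mask
  med <- medianFilter3D(vol, boxOffsets(params$medianRadius[1],
                                        params$medianRadius[2],
                                        params$medianRadius[3]))
  ero <- erode3D(med, ballOffsets(params$erosionRadius, voxelSize))
  rec <- reconstructByDilation(ero, med)
  resid <- med - rec
  resid[!mask] <- 0
  thr <- params$residualThreshold
  if (is.null(thr)) {
    rv <- resid[mask]
    rv <- rv[rv > 0]
    thr <- if (length(rv) < 10L) Inf else otsuThreshold(rv)
  }
  bin <- resid > thr & mask
  lab <- array(0L, dim(vol))
  if (any(bin)) {
    peaks <- localMaxima3D(resid, voxelSize, params$minSeparation,
                           mask = bin, threshold = thr)
    if (nrow(peaks) > 0L) {
      markers <- array(0L, dim(vol))
      markers[peaks] <- seq_len(nrow(peaks))
      lab <- watershedSeeded(-resid, markers, bin)
    } else {
      lab <- labelComponents(bin, 26L)
      attr(lab, "max") <- NULL
    }
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < params$minVoxels)
    if (length(drop)) lab[lab %in% drop] <- 0L
    u <- sort(unique(lab[lab > 0L]))
    if (length(u)) {
      relab <- array(0L, dim(vol))
      for (i in seq_along(u)) relab[lab == u[i]] <- i
      lab <- relab
    }
  }
  attr(lab, "params") <- params
  attr(lab, "threshold") <- thr
  lab
}

#' Hub region properties
#'
#' Per hub label: voxel count, physical volume, integrated and mean
#' normalized intensity, and intensity-weighted-free centroid in
#' micrometres (integrated = sum over voxels; mean = integrated /
#' count; volume = count x voxel volume).
#'
#' @param lab hub label array from [detectHubs()].
#' @param normalized normalized nucleus (list with \code{data}).
#' @param voxelSize (dx, dy, dz) micrometres.
#' @param frame 0-based frame index recorded in the output.
#' @param nucleusId nucleus id recorded in the output.
#' @return data.frame (HubRegion): hub_id, frame, nucleus_id, voxels,
#'   volume_um3, integrated_intensity, mean_intensity, x, y, z.
#' @export
hubRegionprops <- function(lab, normalized, voxelSize, frame = 0L,
                           nucleusId = 1L) {
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  vv <- prod(voxelSize)
  if (length(ids) == 0L)
    return(data.frame(hub_id = integer(0), frame = integer(0),
                      nucleus_id = integer(0), voxels = integer(0),
                      volume_um3 = numeric(0),
                      integrated_intensity = numeric(0),
                      mean_intensity = numeric(0), x = numeric(0),
                      y = numeric(0), z = numeric(0)))
  idx <- which(lab > 0L)
  co <- arrayInd(idx, dim(lab))
  pos <- sweep(co - 0.5, 2, voxelSize, "*")
  vals <- normalized$data[idx]
  g <- lab[idx]
  out <- do.call(rbind, lapply(ids, function(i) {
    s <- g == i
    integ <- sum(vals[s])
    ctr <- colMeans(pos[s, , drop = FALSE])
    data.frame(hub_id = i, frame = as.integer(frame),
               nucleus_id = as.integer(nucleusId), voxels = sum(s),
               volume_um3 = sum(s) * vv, integrated_intensity = integ,
               mean_intensity = integ / sum(s),
               x = ctr[1], y = ctr[2], z = ctr[3])
  }))
  rownames(out) <- NULL
  out
}

#' Nucleus-level hub statistics and correlations
#'
#' Per nucleus and frame: hub count, hub density (count per cubic
#' micrometre of nuclear volume), mean hub intensity, and the nuclear
#' mean intensity; plus Pearson correlation summaries of hub density
#' vs. nuclear intensity and mean hub intensity vs. nuclear intensity
#' across all frames and nuclei.
#'
#' @param hubTable HubRegion data.frame (possibly several frames/nuclei).
#' @param nucleusSeries data.frame with nucleus_id, frame,
#'   mean_intensity, volume_um3 (from [nucleusTimeseries()]).
#' @return list: \code{stats} (per nucleus-frame HubNucleusStats) and
#'   \code{correlations} (data.frame with r2, p per relationship).
#' @export
hubNucleusStats <- function(hubTable, nucleusSeries) {
  key <- paste(nucleusSeries$nucleus_id, nucleusSeries$frame)
  stats <- do.call(rbind, lapply(seq_len(nrow(nucleusSeries)), function(i) {
    sel <- hubTable$nucleus_id == nucleusSeries$nucleus_id[i] &
      hubTable$frame == nucleusSeries$frame[i]
    n <- sum(sel)
    data.frame(nucleus_id = nucleusSeries$nucleus_id[i],
               frame = nucleusSeries$frame[i],
               hub_count = n,
               hub_density = n / nucleusSeries$volume_um3[i],
               mean_hub_intensity = if (n) mean(hubTable$mean_intensity[sel])
                 else NA_real_,
               mean_nuclear_intensity = nucleusSeries$mean_intensity[i])
  }))
  corRow <- function(x, y, name) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(relationship = name, r2 = NA_real_, p = NA_real_,
                        n = sum(ok)))
    ct <- stats::cor.test(x[ok], y[ok])
    data.frame(relationship = name, r2 = unname(ct$estimate)^2,
               p = ct$p.value, n = sum(ok))
  }
  correlations <- rbind(
    corRow(stats$hub_density, stats$mean_nuclear_intensity,
           "density_vs_nuclear_intensity"),
    corRow(stats$mean_hub_intensity, stats$mean_nuclear_intensity,
           "hub_intensity_vs_nuclear_intensity"))
  rownames(stats) <- NULL
  list(stats = stats, correlations = correlations)
}
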