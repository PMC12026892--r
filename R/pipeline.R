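#' Run the full analysis pipeline on a movie
#'
#' End-to-end driver used by the command-line interface: per-frame
#' per-slice nucleus segmentation, z-stitching with gap interpolation,
#' nearest-neighbour nucleus tracking, nuclear normalization, hub
#' detection and region properties, MS2 spot detection/selection/
#' tracking with interpolation and pre-appearance extrapolation,
#' interaction-sphere metrics, hub-contact runs, burst calling, and
#' burst-hub linking. All stage parameters are recorded with the
#' outputs; given the same movie and parameters the emitted tables are
#' identical across runs.
#'
#' @param movie a \linkS4class{HubMovie} (channel 1 = transcription
#'   factor, channel 2 = MS2).
#' @param outDir optional directory; when given, tables and the config
#'   are written there.
#' @param nucleusParams,hubParams,ms2Params,burstParams stage parameter
#'   lists (see [hubParams()], [burstParams()]); nucleusParams may set
#'   smoothSigma, minSep, minArea, iouThreshold, maxGap,
#'   maxDisplacement; ms2Params may set sigma1, sigma2, percentile,
#'   maxStep, extrapolateFrames.
#' @param sphereRadius interaction sphere radius, micrometres.
#' @param gapTolerance absent-frame tolerance inside a hub run.
#' @param config optional config object echoed into the output.
#' @return named list of tables: nuclei, hubs, ms2, interactions, runs,
#'   bursts, links.
#' @export
runPipeline <- function(movie, outDir = NULL,
                        nucleusParams = list(), hubParams = NULL,
                        ms2Params = list(), burstParams = NULL,
                        sphereRadius = 0.5, gapTolerance = 0L,
                        config = NULL) {
  np <- utils::modifyList(list(smoothSigma = 0.3, minSep = 1.5,
                               minArea = 3, iouThreshold = 0.5,
                               maxGap = 2L, maxDisplacement = 2,
                               minVolume = 4), nucleusParams)
  hp <- if (is.null(hubParams)) HubKinetics::hubParams() else hubParams
  mp <- utils::modifyList(list(sigma1 = 0.1, sigma2 = 0.3,
                               percentile = 99.5, maxStep = 1.0,
                               extrapolateFrames = 20L), ms2Params)
  bp <- if (is.null(burstParams)) HubKinetics::burstParams() else
    burstParams
  vs <- voxelSize(movie)
  fi <- frameInterval(movie)
  nT <- nFrames(movie)

  # --- nuclei ----------------------------------------------------------
  hkLog("segmenting nuclei in ", nT, " frames")
  labelVolumes <- vector("list", nT)
  ch1Frames <- vector("list", nT)
  for (f in seq_len(nT)) {
    vol <- intensities(getFrame(movie, 1L, f - 1L))
    ch1Frames[[f]] <- vol
    nz <- dim(vol)[3]
    # one Otsu threshold per volume: slices without nuclei then stay empty
    thr <- otsuThreshold(as.numeric(vol))
    slices <- lapply(seq_len(nz), function(z)
      segmentNucleiSlice(vol[, , z], vs, smoothSigma = np$smoothSigma,
                         minSep = np$minSep, minArea = np$minArea,
                         threshold = thr))
    lab <- stitchAndInterpolate(slices, np$iouThreshold, np$maxGap)
    # reject 3D fragments far below nuclear volume
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes * prod(vs) < np$minVolume)
    if (length(drop)) lab[lab %in% drop] <- 0L
    labelVolumes[[f]] <- lab
  }
  tracks <- trackNuclei(labelVolumes, vs, frameInterval = fi,
                        maxDisplacement = np$maxDisplacement,
                        intensity = ch1Frames)
  nucSeries <- nucleusTimeseries(tracks, labelVolumes, movie, 1L)

  # --- hubs + MS2 per nucleus/frame ------------------------------------
  hubRows <- list()
  ms2Sel <- list()
  normCache <- vector("list", nT)   # per frame: list(norm per nucleus label)
  labCache <- vector("list", nT)
  for (f in seq_len(nT)) {
    lab <- labelVolumes[[f]]
    ch1 <- ch1Frames[[f]]
    ch2 <- intensities(getFrame(movie, 2L, f - 1L))
    tf <- tracks[tracks$frame == f - 1L, , drop = FALSE]
    normCache[[f]] <- list()
    labCache[[f]] <- list()
    for (i in seq_len(nrow(tf))) {
      mask <- lab == tf$label[i]
      if (!any(mask)) next
      nrm <- normalizeNucleus(ch1, mask)
      hl <- detectHubs(nrm, vs, hp)
      nid <- tf$nucleus_id[i]
      normCache[[f]][[as.character(nid)]] <- nrm$data
      labCache[[f]][[as.character(nid)]] <- hl
      hr <- hubRegionprops(hl, nrm, vs, frame = f - 1L, nucleusId = nid)
      if (nrow(hr)) hubRows[[length(hubRows) + 1L]] <- hr
      cand <- detectMS2Candidates(ch2, mask, vs, sigma1 = mp$sigma1,
                                  sigma2 = mp$sigma2,
                                  percentile = mp$percentile)
      spot <- selectLocusSpot(cand)
      if (!is.null(spot)) {
        bgMed <- stats::median(ch2[mask])
        ms2Sel[[length(ms2Sel) + 1L]] <- data.frame(
          nucleus_id = nid, frame = f - 1L, x = spot$x, y = spot$y,
          z = spot$z, intensity = spot$integrated_intensity,
          intensity_corrected = spot$integrated_intensity -
            bgMed * spot$voxels)
      }
    }
  }
  hubTable <- if (length(hubRows)) do.call(rbind, hubRows) else
    hubRegionprops(array(0L, c(1, 1, 1)), list(data = array(0, c(1, 1, 1))),
                   vs)
  ms2Sel <- if (length(ms2Sel)) do.call(rbind, ms2Sel) else NULL

  # --- per-nucleus traces, interactions, bursts ------------------------
  interRows <- list(); runRows <- list(); burstRows <- list()
  linkRows <- list(); ms2Rows <- list()
  dtMin <- fi / 60
  for (nid in unique(tracks$nucleus_id)) {
    nuc <- tracks[tracks$nucleus_id == nid, , drop = FALSE]
    det <- if (is.null(ms2Sel)) NULL else
      ms2Sel[ms2Sel$nucleus_id == nid, , drop = FALSE]
    if (is.null(det) || nrow(det) == 0L) next
    raw <- trackMS2(det, maxStep = mp$maxStep)
    filled <- fillTrack(raw, nuc, extrapolateFrames = mp$extrapolateFrames)
    filled$nucleus_id <- nid
    filled$t_min <- filled$frame * dtMin
    ms2Rows[[length(ms2Rows) + 1L]] <- filled
    recs <- do.call(rbind, lapply(seq_len(nrow(filled)), function(k) {
      f <- filled$frame[k] + 1L
      nrm <- normCache[[f]][[as.character(nid)]]
      hl <- labCache[[f]][[as.character(nid)]]
      if (is.null(nrm) || is.null(hl) ||
          !all(is.finite(c(filled$x[k], filled$y[k], filled$z[k]))))
        return(NULL)
      sm <- sphereMetrics(nrm, hl, c(filled$x[k], filled$y[k],
                                     filled$z[k]), vs, sphereRadius)
      cbind(data.frame(nucleus_id = nid, frame = filled$frame[k],
                       t_min = filled$t_min[k]), sm)
    }))
    if (is.null(recs) || nrow(recs) == 0L) next
    interRows[[length(interRows) + 1L]] <- recs
    runs <- extractRuns(recs, frameInterval = fi,
                        gapTolerance = gapTolerance)
    if (nrow(runs)) {
      runs$nucleus_id <- nid
      runRows[[length(runRows) + 1L]] <- runs
    }
    # burst calling on the filled intensity trace
    grid <- data.frame(frame = min(filled$frame):max(filled$frame))
    tr <- merge(grid, filled[, c("frame", "intensity")], all.x = TRUE)
    tr$intensity[is.na(tr$intensity)] <- 0
    if (nrow(tr) >= 5L) {
      bs <- callBursts(tr$intensity, frameInterval = fi, params = bp)
      if (nrow(bs)) {
        # shift frames back to absolute indexing
        off <- min(filled$frame)
        bs$start_frame <- bs$start_frame + off
        bs$peak_frame <- bs$peak_frame + off
        bs$end_frame <- bs$end_frame + off
        bs$start_min <- bs$start_frame * dtMin
        bs$end_min <- bs$end_frame * dtMin
        bs$nucleus_id <- nid
        burstRows[[length(burstRows) + 1L]] <- bs
        lk <- linkBurstsToHubs(bs, runs, recs, mode = "any",
                               frameInterval = fi)
        lk$nucleus_id <- nid
        linkRows[[length(linkRows) + 1L]] <- lk
      }
    }
  }
  bind <- function(x) if (length(x)) do.call(rbind, x) else NULL
  tables <- list(nuclei = nucSeries, tracks = tracks, hubs = hubTable,
                 ms2 = bind(ms2Rows), interactions = bind(interRows),
                 runs = bind(runRows), bursts = bind(burstRows),
                 links = bind(linkRows))
  if (!is.null(outDir)) {
    writeTables(tables[!vapply(tables, is.null, logical(1))], outDir)
    if (!is.null(config)) writeRunConfig(config, outDir)
  }
  tables
}
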