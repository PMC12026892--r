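#' Write a HubMovie to disk
#'
#' Movies are stored as a multi-page TIFF with pages ordered
#' (t, c, z) — i.e. TZCYX on disk with z fastest within a channel — plus
#' a JSON sidecar (\code{<path>.meta.json}) carrying voxel size, frame
#' interval and channel names, so physical units survive the round trip.
#'
#' @param movie a \linkS4class{HubMovie}.
#' @param path output TIFF path.
#' @return invisibly, \code{path}.
#' @export
writeMovie <- function(movie, path) {
  stopifnot(is(movie, "HubMovie"))
  d <- dim(movie@data)
  mx <- max(movie@data, 1e-12)
  pages <- list()
  for (f in seq_len(d[5]))
    for (ch in seq_len(d[4]))
      for (z in seq_len(d[3]))
        # tiff stores 2D matrices row-major as (row = y, col = x)
        pages[[length(pages) + 1L]] <-
          t(movie@data[, , z, ch, f]) / mx
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(voxel_size_um = movie@voxelSize,
               frame_interval_s = movie@frameInterval,
               channel_names = movie@channelNames,
               dims_xyz = d[1:3], n_channels = d[4], n_frames = d[5],
               intensity_scale = mx, page_order = "TZCYX")
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie written by [writeMovie()]
#'
#' Voxel size is taken from the JSON sidecar; if that is absent it must
#' be supplied via \code{voxelSize}, otherwise reading fails (physical-
#' unit metrics would be silently wrong).
#'
#' @param path TIFF path.
#' @param voxelSize fallback (dx, dy, dz) micrometres when no sidecar.
#' @param frameInterval fallback seconds per volume.
#' @param channelMap optional integer permutation applied to channels
#'   (e.g. \code{c(2, 1)} swaps a two-channel movie).
#' @return a \linkS4class{HubMovie}, frames ordered by time.
#' @export
readMovie <- function(path, voxelSize = NULL, frameInterval = NULL,
                      channelMap = NULL) {
  metaPath <- paste0(path, ".meta.json")
  meta <- if (file.exists(metaPath))
    jsonlite::read_json(metaPath, simplifyVector = TRUE) else NULL
  if (is.null(meta) && is.null(voxelSize))
    stop("voxel size missing from both metadata and config; refusing to ",
         "guess physical units", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.null(meta)) {
    d <- as.integer(meta$dims_xyz); nc <- meta$n_channels
    nt <- meta$n_frames; sc <- meta$intensity_scale
    vs <- meta$voxel_size_um
    fi <- if (is.null(frameInterval)) meta$frame_interval_s else frameInterval
    cn <- meta$channel_names
  } else {
    stop("cannot infer volume layout without the metadata sidecar",
         call. = FALSE)
  }
  if (!is.null(voxelSize)) vs <- voxelSize
  arr <- array(0, dim = c(d, nc, nt))
  k <- 1L
  for (f in seq_len(nt))
    for (ch in seq_len(nc))
      for (z in seq_len(d[3])) {
        arr[, , z, ch, f] <- t(pages[[k]]) * sc
        k <- k + 1L
      }
  if (!is.null(channelMap)) {
    stopifnot(length(channelMap) == nc)
    arr <- arr[, , , channelMap, , drop = FALSE]
    cn <- cn[channelMap]
  }
  HubMovie(arr, voxelSize = vs, frameInterval = fi, channelNames = cn)
}

# column dictionaries for each record kind; every emitted table keeps
# durations in minutes (explicit _min suffix) and lengths in micrometres
.tableSchemas <- list(
  nuclei = c("nucleus_id", "frame", "t_min", "x", "y", "z", "volume_um3",
             "mean_intensity", "eq_radius_x", "eq_radius_y", "eq_radius_z"),
  hubs = c("hub_id", "frame", "nucleus_id", "voxels", "volume_um3",
           "integrated_intensity", "mean_intensity", "x", "y", "z"),
  interactions = c("nucleus_id", "frame", "t_min", "sphere_mean_intensity",
                   "overlap_volume_um3", "overlap_mean_intensity",
                   "hub_present", "high_hub_present", "truncated"),
  bursts = c("nucleus_id", "burst_index", "start_min", "end_min",
             "duration_min", "amplitude", "output", "loading_rate",
             "is_first"),
  ms2 = c("nucleus_id", "frame", "t_min", "x", "y", "z", "intensity",
          "intensity_corrected", "status"),
  runs = c("nucleus_id", "run_id", "start_frame", "end_frame",
           "duration_min", "class", "mean_overlap_intensity"),
  stats = c("name", "group_a", "group_b", "statistic", "p_value", "stars"))

#' Write record tables as CSV
#'
#' One CSV per record kind with a fixed, documented column set (see
#' \code{HubKinetics:::.tableSchemas}); an empty record set produces a
#' header-only file. Values round-trip at full double precision.
#'
#' @param records named list of data.frames; names must be schema kinds.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeTables <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (kind in names(records)) {
    df <- records[[kind]]
    if (kind %in% names(.tableSchemas)) {
      sch <- .tableSchemas[[kind]]
      if (is.null(df) || nrow(df) == 0L) {
        df <- as.data.frame(stats::setNames(
          replicate(length(sch), numeric(0), simplify = FALSE), sch))
      } else {
        missing <- setdiff(sch, names(df))
        for (mcol in missing) df[[mcol]] <- NA
        df <- df[, c(sch, setdiff(names(df), sch)), drop = FALSE]
      }
    }
    p <- file.path(dir, paste0(kind, ".csv"))
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     p, row.names = FALSE, quote = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a table written by [writeTables()]
#' @param path CSV path.
#' @return data.frame.
#' @export
readTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize a run configuration next to its results
#'
#' Every run directory gets the exact config (including seed) that
#' produced it, as YAML.
#'
#' @param cfg a SimulationConfig or plain named list.
#' @param dir run directory.
#' @return invisibly the file path.
#' @export
writeRunConfig <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- unclass(cfg)
  # functions are not serialisable; record their deparsed body
  x <- rapply(x, function(e)
    if (is.function(e)) paste(deparse(e), collapse = "\n") else e,
    how = "replace")
  p <- file.path(dir, "config.yaml")
  yaml::write_yaml(x, p)
  invisible(p)
}

#' Read a configuration file (YAML or JSON)
#' @param path file path.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

# lightweight run logging
.hkLogLevel <- new.env(parent = emptyenv())
assign("level", "info", envir = .hkLogLevel)

#' Set the package log level
#' @param level one of "debug", "info", "warn", "quiet".
#' @export
setLogLevel <- function(level = c("info", "debug", "warn", "quiet")) {
  assign("level", match.arg(level), envir = .hkLogLevel)
  invisible(level)
}

hkLog <- function(..., level = "info") {
  ranks <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (ranks[[level]] >= ranks[[get("level", envir = .hkLogLevel)]])
    message("[", level, "] ", ...)
  invisible(NULL)
}
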