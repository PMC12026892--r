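#' @import methods
NULL

#' VolumeFrame: one 3D intensity volume at one time point
#'
#' A single-channel, single-time-point 3D grid with its physical voxel
#' size. Arrays are stored column-major as (x, y, z).
#'
#' @slot data 3D numeric array of non-negative intensities.
#' @slot voxelSize numeric (dx, dy, dz) in micrometres.
#' @slot channel integer channel id (1-based).
#' @slot frame integer frame index (0-based, as in all emitted tables).
#' @slot time acquisition time in seconds.
#' @export
setClass("VolumeFrame",
  representation(data = "array", voxelSize = "numeric", channel = "integer",
                 frame = "integer", time = "numeric"))

setValidity("VolumeFrame", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive values")
  if (any(object@data < 0, na.rm = TRUE)) return("intensities must be >= 0")
  TRUE
})

#' Construct a VolumeFrame
#' @param data 3D numeric array.
#' @param voxelSize (dx, dy, dz) micrometres.
#' @param channel channel id.
#' @param frame 0-based frame index.
#' @param time acquisition time, seconds.
#' @return a \linkS4class{VolumeFrame}.
#' @export
VolumeFrame <- function(data, voxelSize, channel = 1L, frame = 0L,
                        time = 0) {
  new("VolumeFrame", data = data, voxelSize = as.numeric(voxelSize),
      channel = as.integer(channel), frame = as.integer(frame),
      time = as.numeric(time))
}

#' HubMovie: a two-channel 4D acquisition
#'
#' In-memory container for a time-lapse volumetric movie: a 5D array
#' with dimensions (x, y, z, channel, frame) plus acquisition metadata.
#'
#' @slot data 5D numeric array (x, y, z, channel, frame).
#' @slot voxelSize numeric (dx, dy, dz) micrometres.
#' @slot frameInterval seconds between volumes.
#' @slot channelNames character vector naming the channels.
#' @export
setClass("HubMovie",
  representation(data = "array", voxelSize = "numeric",
                 frameInterval = "numeric", channelNames = "character"))

setValidity("HubMovie", function(object) {
  d <- dim(object@data)
  if (length(d) != 5L) return("data must be a 5D (x,y,z,c,t) array")
  if (length(object@channelNames) != d[4])
    return("channelNames length must match channel dimension")
  if (object@frameInterval <= 0) return("frameInterval must be positive")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive values")
  TRUE
})

#' Construct a HubMovie
#' @param data 5D array (x, y, z, channel, frame).
#' @param voxelSize (dx, dy, dz) micrometres.
#' @param frameInterval seconds per volume.
#' @param channelNames channel labels; defaults \code{c("tf", "ms2")[...]}.
#' @return a \linkS4class{HubMovie}.
#' @export
HubMovie <- function(data, voxelSize, frameInterval = 11.56,
                     channelNames = NULL) {
  nc <- dim(data)[4]
  if (is.null(channelNames))
    channelNames <- if (nc == 2L) c("tf", "ms2") else paste0("ch", seq_len(nc))
  new("HubMovie", data = data, voxelSize = as.numeric(voxelSize),
      frameInterval = as.numeric(frameInterval),
      channelNames = channelNames)
}

#' @describeIn HubMovie-class number of frames
#' @param x a HubMovie.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname HubMovie-class
#' @export
setMethod("nFrames", "HubMovie", function(x) dim(x@data)[5])

#' @describeIn HubMovie-class number of channels
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname HubMovie-class
#' @export
setMethod("nChannels", "HubMovie", function(x) dim(x@data)[4])

#' Physical voxel size accessor
#' @param x a HubMovie or VolumeFrame.
#' @return numeric (dx, dy, dz) in micrometres.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "HubMovie", function(x) x@voxelSize)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "VolumeFrame", function(x) x@voxelSize)

#' Frame interval accessor (seconds)
#' @param x a HubMovie.
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname frameInterval
#' @export
setMethod("frameInterval", "HubMovie", function(x) x@frameInterval)

#' Extract one channel/frame as a VolumeFrame
#'
#' @param x a \linkS4class{HubMovie}.
#' @param channel channel index or name.
#' @param frame 0-based frame index.
#' @return a \linkS4class{VolumeFrame}.
#' @export
setGeneric("getFrame", function(x, channel, frame) standardGeneric("getFrame"))
#' @rdname getFrame
#' @export
setMethod("getFrame", "HubMovie", function(x, channel, frame) {
  if (is.character(channel)) channel <- match(channel, x@channelNames)
  stopifnot(!is.na(channel), frame >= 0, frame < nFrames(x))
  VolumeFrame(x@data[, , , channel, frame + 1L, drop = TRUE],
              voxelSize = x@voxelSize, channel = as.integer(channel),
              frame = as.integer(frame),
              time = frame * x@frameInterval)
})

#' Intensity array accessor
#' @param x a VolumeFrame or HubMovie.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname intensities
#' @export
setMethod("intensities", "VolumeFrame", function(x) x@data)
#' @rdname intensities
#' @export
setMethod("intensities", "HubMovie", function(x) x@data)

setMethod("show", "HubMovie", function(object) {
  d <- dim(object@data)
  cat("HubMovie:", d[1], "x", d[2], "x", d[3], "voxels,",
      d[4], "channel(s) [", paste(object@channelNames, collapse = ", "),
      "],", d[5], "frame(s)\n")
  cat("  voxel size (um):", paste(signif(object@voxelSize, 4),
                                  collapse = " x "),
      "| frame interval:", object@frameInterval, "s\n")
})

setMethod("show", "VolumeFrame", function(object) {
  d <- dim(object@data)
  cat("VolumeFrame:", d[1], "x", d[2], "x", d[3],
      "voxels, channel", object@channel, "frame", object@frame,
      sprintf("(t = %.2f s)\n", object@time))
})

#' DwellMixtureFit: three-component Gaussian mixture over dwell times
#'
#' Result of [fitDwellMixture()]. Components are relabelled so means are
#' ascending (short < mid < long).
#'
#' @slot weights,means,sds numeric length-3 parameters (minutes).
#' @slot responsibilities n x 3 matrix of posterior membership.
#' @slot classes factor of hardened assignments (short/mid/long).
#' @slot logLik final log-likelihood.
#' @slot converged logical.
#' @slot seed integer seed used for the k-means initialisation.
#' @export
setClass("DwellMixtureFit",
  representation(weights = "numeric", means = "numeric", sds = "numeric",
                 responsibilities = "matrix", classes = "factor",
                 logLik = "numeric", converged = "logical", seed = "integer"))

setValidity("DwellMixtureFit", function(object) {
  if (abs(sum(object@weights) - 1) > 1e-6) return("weights must sum to 1")
  if (is.unsorted(object@means)) return("means must be ascending")
  TRUE
})

setMethod("show", "DwellMixtureFit", function(object) {
  cat("Three-component Gaussian mixture fit (dwell times, minutes)\n")
  tab <- data.frame(component = c("short", "mid", "long"),
                    weight = round(object@weights, 3),
                    mean = round(object@means, 3),
                    sd = round(object@sds, 3))
  print(tab, row.names = FALSE)
  cat("converged:", object@converged,
      "| logLik:", round(object@logLik, 2), "\n")
})

#' Mixture parameter accessors
#' @param x a DwellMixtureFit.
#' @return numeric length-3 vector (short, mid, long).
#' @export
setGeneric("mixtureMeans", function(x) standardGeneric("mixtureMeans"))
#' @rdname mixtureMeans
#' @export
setMethod("mixtureMeans", "DwellMixtureFit", function(x) x@means)
#' @rdname mixtureMeans
#' @export
setGeneric("mixtureWeights", function(x) standardGeneric("mixtureWeights"))
#' @rdname mixtureMeans
#' @export
setMethod("mixtureWeights", "DwellMixtureFit", function(x) x@weights)
#' @rdname mixtureMeans
#' @export
setGeneric("mixtureSds", function(x) standardGeneric("mixtureSds"))
#' @rdname mixtureMeans
#' @export
setMethod("mixtureSds", "DwellMixtureFit", function(x) x@sds)
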