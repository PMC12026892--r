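#' @useDynLib HubKinetics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Ellipsoidal footprint offsets in physical units
#'
#' Builds the integer voxel-offset matrix whose members lie within
#' \code{radius} micrometres of the origin, given an anisotropic voxel
#' size. Used to express morphological footprints in micrometres rather
#' than voxels, so the z axis (typically ~3x coarser) is handled
#' correctly. The origin is always included.
#'
#' @param radius radius in micrometres.
#' @param voxelSize numeric length-3 \code{(dx, dy, dz)} in micrometres.
#' @return integer matrix with columns \code{dx, dy, dz} (voxel offsets).
#' @export
ballOffsets <- function(radius, voxelSize) {
  stopifnot(radius >= 0, length(voxelSize) == 3, all(voxelSize > 0))
  r <- pmax(0L, as.integer(floor(radius / voxelSize)))
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (g$dx * voxelSize[1])^2 + (g$dy * voxelSize[2])^2 +
    (g$dz * voxelSize[3])^2
  m <- as.matrix(g[d2 <= radius^2 + 1e-9, , drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' Rectangular footprint offsets
#'
#' @param rx,ry,rz half-widths in voxels along each axis.
#' @return integer offset matrix.
#' @export
boxOffsets <- function(rx = 1L, ry = 1L, rz = 0L) {
  m <- as.matrix(expand.grid(dx = -rx:rx, dy = -ry:ry, dz = -rz:rz))
  storage.mode(m) <- "integer"
  m
}

.asVol <- function(x) {
  if (is.null(dim(x))) stop("expected a 3D array")
  d <- dim(x)
  if (length(d) == 2L) dim(x) <- c(d, 1L)
  x
}

.rankFilter <- function(vol, offsets, type) {
  vol <- .asVol(vol)
  out <- cpp_rank_filter(as.numeric(vol), as.integer(dim(vol)), offsets, type)
  array(out, dim(vol))
}

#' 3D median filter
#' @param vol 3D numeric array.
#' @param offsets footprint offset matrix (see [ballOffsets()]).
#' @return filtered array of the same shape.
#' @export
medianFilter3D <- function(vol, offsets = boxOffsets(1L, 1L, 0L))
  .rankFilter(vol, offsets, 2L)

#' Grayscale erosion
#' @inheritParams medianFilter3D
#' @export
erode3D <- function(vol, offsets) .rankFilter(vol, offsets, 0L)

#' Grayscale dilation
#' @inheritParams medianFilter3D
#' @export
dilate3D <- function(vol, offsets) .rankFilter(vol, offsets, 1L)

#' Morphological reconstruction by dilation
#'
#' Grayscale reconstruction of \code{mask} from \code{seed}
#' (seed <= mask enforced by clipping), 6-connected.
#' @param seed,mask 3D numeric arrays of identical shape.
#' @return reconstructed array.
#' @export
reconstructByDilation <- function(seed, mask) {
  seed <- .asVol(seed); mask <- .asVol(mask)
  stopifnot(identical(dim(seed), dim(mask)))
  out <- cpp_reconstruct_dilation(as.numeric(seed), as.numeric(mask),
                                  as.integer(dim(seed)))
  array(out, dim(seed))
}

#' Separable Gaussian blur with physical-unit sigma
#'
#' @param vol 3D numeric array.
#' @param voxelSize voxel size (dx, dy, dz) in micrometres.
#' @param sigma isotropic standard deviation in micrometres; converted
#'   per-axis to voxels. Axes where sigma is below 0.3 voxels are left
#'   unsmoothed.
#' @return blurred array.
#' @export
gaussianBlur3D <- function(vol, voxelSize, sigma) {
  vol <- .asVol(vol)
  out <- as.numeric(vol)
  for (ax in 0:2) {
    sv <- sigma / voxelSize[ax + 1]
    if (sv < 0.3 || dim(vol)[ax + 1] == 1L) next
    kr <- max(1L, as.integer(ceiling(3 * sv)))
    k <- stats::dnorm(-kr:kr, sd = sv)
    k <- k / sum(k)
    out <- cpp_convolve_axis(out, as.integer(dim(vol)), k, ax)
  }
  array(out, dim(vol))
}

#' Difference-of-Gaussians band-pass filter
#' @inheritParams gaussianBlur3D
#' @param sigma1,sigma2 inner and outer scales in micrometres
#'   (\code{sigma1 < sigma2}).
#' @export
dogFilter3D <- function(vol, voxelSize, sigma1, sigma2) {
  stopifnot(sigma1 < sigma2)
  gaussianBlur3D(vol, voxelSize, sigma1) -
    gaussianBlur3D(vol, voxelSize, sigma2)
}

#' Connected-component labelling of a 3D mask
#' @param mask logical 3D array.
#' @param connectivity 6 or 26.
#' @return integer label array; attribute \code{"max"} holds the label count.
#' @export
labelComponents <- function(mask, connectivity = 26L) {
  mask <- .asVol(mask)
  lab <- cpp_label(as.logical(mask), as.integer(dim(mask)),
                   as.integer(connectivity))
  n <- attr(lab, "max")
  lab <- array(lab, dim(mask))
  attr(lab, "max") <- n
  lab
}

#' Local maxima with a physical minimum-separation
#'
#' A voxel is a local maximum when it attains the maximum of \code{vol}
#' over the separation footprint, lies inside \code{mask}, and exceeds
#' \code{threshold}. Plateaus are collapsed to one representative voxel
#' per connected plateau component.
#'
#' @param vol 3D numeric array.
#' @param voxelSize voxel size in micrometres.
#' @param minSep minimum separation radius in micrometres.
#' @param mask logical array restricting the search (default everywhere).
#' @param threshold minimum value for a maximum (default \code{-Inf}).
#' @return integer matrix of 1-based voxel coordinates (x, y, z).
#' @export
localMaxima3D <- function(vol, voxelSize, minSep, mask = NULL,
                          threshold = -Inf) {
  vol <- .asVol(vol)
  off <- ballOffsets(minSep, voxelSize)
  dil <- dilate3D(vol, off)
  isMax <- (vol >= dil) & (vol > threshold)
  if (!is.null(mask)) isMax <- isMax & mask
  if (!any(isMax)) {
    return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  }
  lab <- labelComponents(isMax, 26L)
  n <- attr(lab, "max")
  idx <- which(lab > 0)
  co <- arrayInd(idx, dim(vol))
  groups <- split(seq_along(idx), lab[idx])
  out <- matrix(0L, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_len(n)) {
    sel <- groups[[as.character(i)]]
    # plateau representative: member closest to the plateau centroid
    cm <- colMeans(co[sel, , drop = FALSE])
    d2 <- rowSums((co[sel, , drop = FALSE] -
                     matrix(cm, length(sel), 3, byrow = TRUE))^2)
    out[i, ] <- as.integer(co[sel[which.min(d2)], ])
  }
  out
}

#' Marker-controlled 3D watershed
#'
#' Floods \code{priority} in ascending order from integer markers,
#' restricted to \code{mask} (6-connectivity, deterministic FIFO
#' tie-breaking).
#'
#' @param priority 3D numeric array (lower values flooded first).
#' @param markers integer array of seed labels (0 = unlabelled).
#' @param mask logical array limiting the flood.
#' @return integer label array.
#' @export
watershedSeeded <- function(priority, markers, mask) {
  priority <- .asVol(priority)
  stopifnot(identical(dim(priority), dim(markers)),
            identical(dim(priority), dim(mask)))
  lab <- cpp_watershed(as.numeric(priority), as.integer(markers),
                       as.logical(mask), as.integer(dim(priority)))
  array(lab, dim(priority))
}

#' Otsu threshold of a value distribution
#'
#' Maximises between-class variance over a 256-bin histogram of the
#' supplied values. Operates on raw voxel values (any range), so it can
#' binarise residual images whose values are not confined to [0, 1].
#'
#' @param x numeric vector.
#' @param nbins histogram bins.
#' @return threshold value; values strictly above it are foreground.
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L || diff(range(x)) == 0) return(suppressWarnings(max(x, -Inf)))
  h <- hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1L),
            plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  muT <- mu[length(mu)]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- 0
  mids[which.max(sigmaB)]
}
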