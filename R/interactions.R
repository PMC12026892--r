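#' Hub metrics inside the interaction sphere around the MS2 locus
#'
#' Sphere membership is defined on voxel centres: a voxel belongs to
#' the sphere when its centre lies within \code{radius} micrometres of
#' the MS2 weighted centroid (physical distance, anisotropy-aware).
#' Reported metrics: mean normalized channel-1 intensity over member
#' voxels; hub overlap volume (member voxels carrying a hub label,
#' times voxel volume); and the mean channel-1 intensity over those
#' overlap voxels (\code{NA} when there is no overlap). Spheres
#' truncated by the volume edge are computed over in-bounds members and
#' flagged.
#'
#' @param normalizedVol normalized channel-1 array (see
#'   [normalizeNucleus()]).
#' @param hubLabels hub label array from [detectHubs()].
#' @param position MS2 position (x, y, z) in micrometres.
#' @param voxelSize (dx, dy, dz) micrometres.
#' @param radius sphere radius in micrometres (default 0.5).
#' @return one-row data.frame (InteractionRecord core):
#'   sphere_mean_intensity, overlap_volume_um3, overlap_mean_intensity,
#'   hub_present, truncated, sphere_voxels.
#' @export
sphereMetrics <- function(normalizedVol, hubLabels, position, voxelSize,
                          radius = 0.5) {
  d <- dim(normalizedVol)
  stopifnot(length(position) == 3L, all(is.finite(position)))
  # bounding box of candidate voxels (1-based indices)
  lo <- pmax(1L, as.integer(floor((position - radius) / voxelSize + 0.5)))
  hi <- pmin(d, as.integer(ceiling((position + radius) / voxelSize + 0.5)))
  truncated <- any((position - radius) / voxelSize + 0.5 < 1) ||
    any((position + radius) / voxelSize + 0.5 > d)
  if (any(lo > hi))
    return(data.frame(sphere_mean_intensity = NA_real_,
                      overlap_volume_um3 = 0,
                      overlap_mean_intensity = NA_real_,
                      hub_present = FALSE, truncated = TRUE,
                      sphere_voxels = 0L))
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  dx2 <- ((ix - 0.5) * voxelSize[1] - position[1])^2
  dy2 <- ((iy - 0.5) * voxelSize[2] - position[2])^2
  dz2 <- ((iz - 0.5) * voxelSize[3] - position[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  member <- d2 <= radius^2
  if (!any(member))
    return(data.frame(sphere_mean_intensity = NA_real_,
                      overlap_volume_um3 = 0,
                      overlap_mean_intensity = NA_real_,
                      hub_present = FALSE, truncated = truncated,
                      sphere_voxels = 0L))
  subI <- normalizedVol[ix, iy, iz, drop = FALSE]
  subL <- hubLabels[ix, iy, iz, drop = FALSE]
  ov <- member & subL > 0L
  vv <- prod(voxelSize)
  data.frame(sphere_mean_intensity = mean(subI[member]),
             overlap_volume_um3 = sum(ov) * vv,
             overlap_mean_intensity = if (any(ov)) mean(subI[ov])
               else NA_real_,
             hub_present = any(ov), truncated = truncated,
             sphere_voxels = sum(member))
}

#' Extract contiguous hub-contact runs from an interaction series
#'
#' Maximal runs of frames with a hub present in the interaction sphere;
#' up to \code{gapTolerance} absent frames may be bridged inside a run
#' (default 0: "consistently present" read strictly). Durations are in
#' minutes: (end - start + 1) x frame interval.
#'
#' @param records data.frame with columns frame and hub_present,
#'   time-ordered; optionally overlap_mean_intensity.
#' @param frameInterval seconds per frame.
#' @param gapTolerance frames of absence tolerated within a run.
#' @return data.frame (InteractionRun): run_id, start_frame, end_frame,
#'   duration_min, mean_overlap_intensity.
#' @export
extractRuns <- function(records, frameInterval = 11.56, gapTolerance = 0L) {
  stopifnot(!is.unsorted(records$frame))
  present <- which(records$hub_present)
  empty <- data.frame(run_id = integer(0), start_frame = integer(0),
                      end_frame = integer(0), duration_min = numeric(0),
                      mean_overlap_intensity = numeric(0))
  if (length(present) == 0L) return(empty)
  f <- records$frame[present]
  brk <- c(TRUE, diff(f) > gapTolerance + 1L)
  runId <- cumsum(brk)
  out <- do.call(rbind, lapply(unique(runId), function(r) {
    ff <- f[runId == r]
    sel <- records$frame >= min(ff) & records$frame <= max(ff) &
      records$hub_present
    mi <- if ("overlap_mean_intensity" %in% names(records))
      mean(records$overlap_mean_intensity[sel], na.rm = TRUE) else NA_real_
    data.frame(run_id = r, start_frame = min(ff), end_frame = max(ff),
               duration_min = (max(ff) - min(ff) + 1L) * frameInterval / 60,
               mean_overlap_intensity = mi)
  }))
  rownames(out) <- NULL
  out
}

# log-likelihood of a 1D Gaussian mixture
.gmmLogLik <- function(x, w, mu, sd) {
  dens <- vapply(1:3, function(k) w[k] * stats::dnorm(x, mu[k], sd[k]),
                 numeric(length(x)))
  sum(log(pmax(rowSums(dens), 1e-300)))
}

#' Fit a three-component Gaussian mixture to dwell times
#'
#' Expectation-maximization on the raw duration samples, initialised
#' from a fixed-seed k-means partition. Component variances are floored
#' (relative to the data spread) so point masses do not collapse the
#' likelihood; components are relabelled so means are ascending (short
#' < mid < long) and each duration is assigned to the component with
#' the largest responsibility.
#'
#' @param durations numeric vector of dwell times, minutes (>= 3 values).
#' @param seed integer seed for the k-means initialisation.
#' @param maxIter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @return a \linkS4class{DwellMixtureFit}.
#' @export
fitDwellMixture <- function(durations, seed = 1L, maxIter = 500L,
                            tol = 1e-8) {
  x <- as.numeric(durations)
  stopifnot(length(x) >= 3L)
  n <- length(x)
  varFloor <- max(1e-6, 1e-4 * stats::var(x))
  if (!is.finite(varFloor) || varFloor == 0) varFloor <- 1e-6

  set.seed(seed)
  runEM <- function(cluster) {
    mu <- vapply(1:3, function(k) mean(x[cluster == k]), numeric(1))
    w <- as.numeric(table(factor(cluster, 1:3))) / n
    w <- pmax(w, 1e-6); w <- w / sum(w)
    sd2 <- vapply(1:3, function(k) {
      v <- stats::var(x[cluster == k])
      if (!is.finite(v) || v < varFloor) varFloor else v
    }, numeric(1))
    mu[!is.finite(mu)] <- mean(x)
    ll <- -Inf
    converged <- FALSE
    resp <- matrix(1 / 3, n, 3)
    for (it in seq_len(maxIter)) {
      dens <- vapply(1:3, function(k)
        w[k] * stats::dnorm(x, mu[k], sqrt(sd2[k])), numeric(n))
      tot <- pmax(rowSums(dens), 1e-300)
      resp <- dens / tot
      nk <- colSums(resp)
      w <- nk / n
      mu <- colSums(resp * x) / pmax(nk, 1e-12)
      sd2 <- vapply(1:3, function(k)
        max(sum(resp[, k] * (x - mu[k])^2) / max(nk[k], 1e-12), varFloor),
        numeric(1))
      llNew <- sum(log(tot))
      if (is.finite(ll) && abs(llNew - ll) <= tol * (abs(ll) + 1)) {
        ll <- llNew
        converged <- TRUE
        break
      }
      ll <- llNew
    }
    list(w = w, mu = mu, sd2 = sd2, resp = resp, ll = ll,
         converged = converged)
  }

  # multiple deterministic initialisations: k-means on the raw and on
  # the log scale (dwell mixtures separate multiplicatively), plus
  # quantile thirds; the best final likelihood wins
  inits <- list()
  if (length(unique(x)) >= 3L) {
    inits$raw <- stats::kmeans(x, centers = 3L, nstart = 5L)$cluster
    if (all(x > 0))
      inits$log <- stats::kmeans(log(x), centers = 3L, nstart = 5L)$cluster
    q <- stats::quantile(x, c(1 / 3, 2 / 3), names = FALSE)
    inits$quantile <- 1L + (x > q[1]) + (x > q[2])
  } else {
    inits$flat <- rep(1:3, length.out = n)[order(order(x))]
  }
  fits <- lapply(inits, runEM)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]
  w <- best$w; mu <- best$mu; sd2 <- best$sd2
  resp <- best$resp; ll <- best$ll; converged <- best$converged
  o <- order(mu)
  mu <- mu[o]; w <- w[o]; sd2 <- sd2[o]
  resp <- resp[, o, drop = FALSE]
  cls <- factor(c("short", "mid", "long")[max.col(resp, ties.method = "first")],
                levels = c("short", "mid", "long"))
  if (length(unique(round(mu, 8))) < 3L)
    hkLog("dwell mixture degenerate: effective component count < 3",
          level = "warn")
  new("DwellMixtureFit", weights = w, means = mu, sds = sqrt(sd2),
      responsibilities = resp, classes = cls, logLik = ll,
      converged = converged, seed = as.integer(seed))
}

#' Empirical survival curve of interaction durations
#'
#' \code{S(t)} = fraction of runs with duration >= t, evaluated on the
#' sorted unique durations (right-continuous step function);
#' \code{S(0) = 1}.
#'
#' @param durations numeric vector of run durations, minutes (>= 1).
#' @return data.frame: duration_min (grid, starting at 0), survival.
#' @export
survivalCurve <- function(durations) {
  stopifnot(length(durations) >= 1L)
  grid <- c(0, sort(unique(durations)))
  surv <- vapply(grid, function(t) mean(durations >= t), numeric(1))
  data.frame(duration_min = grid, survival = surv)
}
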