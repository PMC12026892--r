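#' Burst-calling parameters
#'
#' @param smoothSigma Gaussian smoothing sigma in frames (0 disables
#'   smoothing); default 1.5.
#' @param thresholdK derivative thresholds are +/- thresholdK x MAD of
#'   the smoothed derivative (default 2), with a small floor so
#'   noiseless traces (MAD 0) still threshold sensibly.
#' @param baselineWindow rolling-minimum window for the per-trace
#'   baseline, frames (default 20).
#' @param endFraction a burst ends when the background-subtracted
#'   intensity falls to this fraction of its amplitude (default 0.05).
#' @param minDuration minimum burst length in frames (default 2).
#' @param startFloorFraction intensity must exceed this fraction of the
#'   trace's dynamic range at the derivative crossing (default 0.02).
#' @return named parameter list.
#' @export
burstParams <- function(smoothSigma = 1.5, thresholdK = 2,
                        baselineWindow = 20L, endFraction = 0.05,
                        minDuration = 2L, startFloorFraction = 0.02) {
  list(smoothSigma = smoothSigma, thresholdK = thresholdK,
       baselineWindow = as.integer(baselineWindow),
       endFraction = endFraction, minDuration = as.integer(minDuration),
       startFloorFraction = startFloorFraction)
}

# centered rolling minimum
.rollMin <- function(x, w) {
  n <- length(x)
  half <- w %/% 2L
  vapply(seq_len(n), function(i)
    min(x[max(1L, i - half):min(n, i + half)]), numeric(1))
}

#' Call transcriptional bursts from an MS2 intensity trace
#'
#' The trace is Gaussian-smoothed and its discrete time-derivative
#' computed. A burst starts when the derivative crosses its positive
#' threshold while the background-subtracted intensity is above a small
#' floor; the onset time is refined by intersecting the rising tangent
#' (at the derivative peak) with the baseline, which recovers the true
#' onset exactly for linear rises. The burst ends at the first frame
#' where the background-subtracted intensity returns to within
#' \code{endFraction} of its amplitude above baseline. Bursts shorter
#' than \code{minDuration} frames are discarded.
#'
#' Per burst: amplitude (peak smoothed intensity minus pre-burst
#' baseline), duration, output (trapezoidal time-integral of the
#' background-subtracted intensity over the burst, in intensity x
#' minutes), and loading rate (amplitude / rise time from onset to
#' peak).
#'
#' @param trace numeric MS2 intensity vector (>= 5 frames).
#' @param frameInterval seconds per frame.
#' @param params a [burstParams()] list.
#' @return data.frame (Burst): burst_index, start_frame, peak_frame,
#'   end_frame, start_min, end_min, duration_min, amplitude, output,
#'   loading_rate, is_first. Empty for a flat trace.
#' @export
callBursts <- function(trace, frameInterval = 11.56,
                       params = burstParams()) {
  stopifnot(length(trace) >= 5L)
  dt <- frameInterval / 60
  n <- length(trace)
  s <- if (params$smoothSigma > 0)
    smoothTrace(trace, params$smoothSigma) else as.numeric(trace)
  base <- .rollMin(s, params$baselineWindow)
  b <- s - base
  empty <- data.frame(burst_index = integer(0), start_frame = integer(0),
                      peak_frame = integer(0), end_frame = integer(0),
                      start_min = numeric(0), end_min = numeric(0),
                      duration_min = numeric(0), amplitude = numeric(0),
                      output = numeric(0), loading_rate = numeric(0),
                      is_first = logical(0))
  rng <- max(b)
  if (rng <= 0) return(empty)
  deriv <- c(0, diff(s)) / dt
  mad <- stats::mad(deriv)
  thrUp <- max(params$thresholdK * mad, 0.01 * max(abs(deriv)))
  floorI <- params$startFloorFraction * rng

  bursts <- list()
  i <- 2L
  while (i <= n) {
    if (deriv[i] > thrUp && b[i] > floorI) {
      # ride the rise to the derivative peak
      p <- i
      while (p < n && deriv[p + 1L] >= deriv[p]) p <- p + 1L
      # tangent onset: exact for linear rises
      onset <- (p - 1L) * dt - b[p] / deriv[p]
      startF <- max(0L, min(as.integer(round(onset / dt)), p - 1L))
      if (length(bursts) &&
          startF <= bursts[[length(bursts)]]$end_frame)
        startF <- bursts[[length(bursts)]]$end_frame + 1L
      # peak of the smoothed signal while the burst persists
      j <- p
      peakF <- p
      amp <- b[p]
      endF <- NA_integer_
      while (j < n) {
        j <- j + 1L
        if (b[j] > amp) { amp <- b[j]; peakF <- j }
        if (b[j] <= params$endFraction * amp &&
            s[j] <= base[j] + params$endFraction * amp + 1e-12) {
          endF <- j
          break
        }
        # a fresh rise after a decline starts a new burst
        if (deriv[j] > thrUp && b[j] < 0.5 * amp && j > peakF + 1L) {
          endF <- j - 1L
          break
        }
      }
      if (is.na(endF)) endF <- n
      startIdx <- startF + 1L
      lenF <- endF - startIdx + 1L
      if (lenF >= params$minDuration) {
        seg <- b[startIdx:endF]
        output <- sum((seg[-1] + seg[-length(seg)]) / 2) * dt
        rise <- (peakF - startIdx) * dt
        bursts[[length(bursts) + 1L]] <- data.frame(
          burst_index = length(bursts) + 1L,
          start_frame = startIdx - 1L, peak_frame = peakF - 1L,
          end_frame = endF - 1L,
          start_min = (startIdx - 1L) * dt, end_min = (endF - 1L) * dt,
          duration_min = (endF - startIdx) * dt,
          amplitude = amp, output = output,
          loading_rate = if (rise > 0) amp / rise else NA_real_,
          is_first = length(bursts) == 0L)
      }
      i <- endF + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(bursts)) return(empty)
  out <- do.call(rbind, bursts)
  rownames(out) <- NULL
  out
}

#' Burst frequency
#' @param bursts Burst data.frame.
#' @param span observed trace span in minutes (> 0).
#' @return bursts per minute (0 for an empty list).
#' @export
burstFrequency <- function(bursts, span) {
  stopifnot(span > 0)
  if (is.null(bursts)) return(0)
  nrow(bursts) / span
}

#' High-intensity hub threshold
#'
#' The threshold separating ordinary from high-intensity hubs: the
#' arithmetic mean of the mean intensities of the supplied (ventral)
#' hubs.
#'
#' @param hubTable HubRegion data.frame with a mean_intensity column
#'   (>= 1 hub).
#' @return threshold value.
#' @export
highIntensityThreshold <- function(hubTable) {
  stopifnot(nrow(hubTable) >= 1L)
  mean(hubTable$mean_intensity)
}

#' Link bursts to hub presence at the locus
#'
#' For each called burst, looks up the interaction record at the
#' burst-start frame: whether any hub is present (\code{mode = "any"}),
#' or whether additionally its overlap mean intensity meets
#' \code{highThreshold} (\code{mode = "high"}); the arrival lead (burst
#' start minus first frame of the containing hub run) and the dwell
#' after start (last frame of that run minus burst start), both in
#' minutes and defined only when a hub is present at the start. First
#' bursts are flagged so arrival-lead summaries can exclude them.
#'
#' @param bursts Burst data.frame from [callBursts()].
#' @param runs InteractionRun data.frame from [extractRuns()].
#' @param records InteractionRecord data.frame (frame, hub_present,
#'   overlap_mean_intensity, sphere_mean_intensity).
#' @param mode "any" or "high".
#' @param highThreshold intensity threshold for \code{mode = "high"}
#'   (see [highIntensityThreshold()]).
#' @param frameInterval seconds per frame.
#' @param preWindow frames before the start over which the pre-burst
#'   mean sphere intensity is computed (default 5).
#' @return data.frame (BurstHubLink): burst_index, start_frame,
#'   hub_present_at_start, high_hub_at_start, arrival_lead_min,
#'   dwell_after_min, pre_burst_intensity, is_first.
#' @export
linkBurstsToHubs <- function(bursts, runs, records, mode = c("any", "high"),
                             highThreshold = NULL,
                             frameInterval = 11.56, preWindow = 5L) {
  mode <- match.arg(mode)
  if (mode == "high" && is.null(highThreshold))
    stop("mode = \"high\" requires highThreshold", call. = FALSE)
  dt <- frameInterval / 60
  out <- lapply(seq_len(nrow(bursts)), function(i) {
    f <- bursts$start_frame[i]
    rec <- records[records$frame == f, , drop = FALSE]
    present <- nrow(rec) == 1L && isTRUE(rec$hub_present)
    high <- present && !is.na(rec$overlap_mean_intensity) &&
      !is.null(highThreshold) &&
      rec$overlap_mean_intensity >= highThreshold
    usePresent <- if (mode == "high") high else present
    lead <- dwell <- NA_real_
    if (usePresent) {
      r <- runs[runs$start_frame <= f & runs$end_frame >= f, , drop = FALSE]
      if (nrow(r) >= 1L) {
        lead <- (f - r$start_frame[1]) * dt
        dwell <- (r$end_frame[1] - f) * dt
      }
    }
    pre <- records[records$frame >= f - preWindow & records$frame < f, ,
                   drop = FALSE]
    data.frame(burst_index = bursts$burst_index[i], start_frame = f,
               hub_present_at_start = present, high_hub_at_start = high,
               arrival_lead_min = lead, dwell_after_min = dwell,
               pre_burst_intensity = if (nrow(pre))
                 mean(pre$sphere_mean_intensity, na.rm = TRUE) else NA_real_,
               is_first = bursts$is_first[i])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cross-correlate paired MS2 and hub-intensity traces
#'
#' Both traces are Gaussian-smoothed and z-score normalized
#' (population sd); the normalized cross-correlation is evaluated over
#' integer lags within \code{maxLag}, each sum divided by n - |lag| to
#' correct the finite overlap, and clamped to [-1, 1]. Sign convention:
#' a positive peak lag means the hub signal follows the MS2 signal in
#' time. The estimator is antisymmetric under swapping the traces.
#'
#' @param ms2,hub equal-length numeric traces (>= 10 frames).
#' @param frameInterval seconds per frame.
#' @param maxLag maximum lag in minutes (default a quarter of the
#'   trace).
#' @param smoothSigma smoothing sigma in frames (default 1.5; 0
#'   disables).
#' @return list of class \code{"CrossCorrResult"}: lag_min, value,
#'   peak_lag_min, peak_value; all NA (with a warning) when either
#'   trace has zero variance.
#' @export
crossCorrelate <- function(ms2, hub, frameInterval = 11.56, maxLag = NULL,
                           smoothSigma = 1.5) {
  stopifnot(length(ms2) == length(hub), length(ms2) >= 10L)
  dt <- frameInterval / 60
  n <- length(ms2)
  if (smoothSigma > 0) {
    ms2 <- smoothTrace(ms2, smoothSigma)
    hub <- smoothTrace(hub, smoothSigma)
  }
  sdM <- stats::sd(ms2) * sqrt((n - 1) / n)
  sdH <- stats::sd(hub) * sqrt((n - 1) / n)
  if (sdM == 0 || sdH == 0) {
    warning("zero-variance trace: cross-correlation undefined")
    return(structure(list(lag_min = NA_real_, value = NA_real_,
                          peak_lag_min = NA_real_, peak_value = NA_real_),
                     class = "CrossCorrResult"))
  }
  zm <- (ms2 - mean(ms2)) / sdM
  zh <- (hub - mean(hub)) / sdH
  K <- if (is.null(maxLag)) floor(n / 4) else
    min(n - 2L, as.integer(round(maxLag / dt)))
  lags <- -K:K
  vals <- vapply(lags, function(k) {
    if (k >= 0) sum(zm[seq_len(n - k)] * zh[seq_len(n - k) + k]) / (n - k)
    else sum(zm[seq_len(n + k) - k] * zh[seq_len(n + k)]) / (n + k)
  }, numeric(1))
  best <- which(vals == max(vals))
  best <- best[which.min(abs(lags[best]))]   # ties: smallest |lag|
  vals <- pmin(1, pmax(-1, vals))            # clamp reported curve
  structure(list(lag_min = lags * dt, value = vals,
                 peak_lag_min = lags[best] * dt, peak_value = vals[best]),
            class = "CrossCorrResult")
}

#' @export
print.CrossCorrResult <- function(x, ...) {
  cat("Cross-correlation (positive lag = hub follows MS2)\n")
  cat(sprintf("  peak lag: %.4f min (value %.3f), %d lags evaluated\n",
              x$peak_lag_min, x$peak_value, length(x$lag_min)))
  invisible(x)
}

.starCode <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Compare two groups with a Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) with normal
#' approximation and tie correction; significance stars follow the
#' conventional coding * p<0.05, ** p<0.01, *** p<0.001.
#'
#' @param a,b numeric vectors (each >= 2 values).
#' @return data.frame (GroupStats): n_a, n_b, U, p_value, stars.
#' @export
groupCompare <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  wt <- stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE,
                           correct = TRUE)
  data.frame(n_a = length(a), n_b = length(b),
             U = unname(wt$statistic), p_value = wt$p.value,
             stars = .starCode(wt$p.value))
}

#' Correlate burst parameters with a hub predictor
#'
#' Pearson correlation (r-squared and p) and least-squares line of each
#' burst parameter against a per-burst predictor: the hub dwell after
#' burst start, or the pre-burst mean intensity in the interaction
#' sphere.
#'
#' @param bursts Burst data.frame.
#' @param links BurstHubLink data.frame aligned by burst_index.
#' @param predictor "dwell_after" or "pre_burst_intensity".
#' @param parameters burst columns to correlate.
#' @return data.frame: parameter, n, r2, p_value, slope, intercept,
#'   stars.
#' @export
correlateBurstParams <- function(bursts, links,
                                 predictor = c("dwell_after",
                                               "pre_burst_intensity"),
                                 parameters = c("amplitude", "loading_rate",
                                                "output", "duration_min")) {
  predictor <- match.arg(predictor)
  m <- merge(bursts, links, by = "burst_index")
  x <- if (predictor == "dwell_after") m$dwell_after_min else
    m$pre_burst_intensity
  out <- lapply(parameters, function(pn) {
    y <- m[[pn]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(parameter = pn, n = sum(ok), r2 = NA_real_,
                        p_value = NA_real_, slope = NA_real_,
                        intercept = NA_real_, stars = NA_character_))
    ct <- stats::cor.test(x[ok], y[ok])
    fit <- stats::lm(y[ok] ~ x[ok])
    data.frame(parameter = pn, n = sum(ok), r2 = unname(ct$estimate)^2,
               p_value = ct$p.value,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               stars = .starCode(ct$p.value))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
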