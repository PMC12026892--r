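# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures on disk.

fixtureVoxel <- c(0.104, 0.104, 0.3)

# A synthetic nucleus volume: unit-intensity ellipsoid with k planted
# isotropic Gaussian blobs (amplitude `amp`, sigma `sigma` um), blob
# centres separated by at least `minSep` um.
makeBlobNucleus <- function(k, seed, dims = c(56L, 56L, 22L),
                            voxelSize = fixtureVoxel, radii = c(2.3, 2.3, 2.6),
                            amp = 1.0, sigma = 0.2, minSep = 1.0) {
  set.seed(seed)
  vc <- HubKinetics:::voxelCenters(dims, voxelSize)
  ctr <- dims * voxelSize / 2
  vol <- HubKinetics:::addEllipsoid(array(0, dims), ctr, radii, 1.0, vc)
  mask <- vol > 0
  pos <- matrix(NA_real_, k, 3)
  if (k > 0) {
    for (i in seq_len(k)) {
      repeat {
        u <- stats::runif(3, -1, 1)
        if (sum(u^2) > 1) next
        p <- ctr + u * 0.55 * radii
        if (i > 1) {
          d <- sqrt(rowSums((pos[seq_len(i - 1), , drop = FALSE] -
                               matrix(p, i - 1, 3, byrow = TRUE))^2))
          if (min(d) < minSep) next
        }
        pos[i, ] <- p
        break
      }
    }
    for (i in seq_len(k))
      vol <- HubKinetics:::addBlob(vol, pos[i, ], sigma, amp, vc)
  }
  list(vol = vol, mask = mask, pos = pos, voxelSize = voxelSize,
       dims = dims)
}

# Exhaustive every-voxel sphere membership: the independent oracle for
# sphereMetrics.
bruteSphere <- function(dims, voxelSize, position, radius = 0.5) {
  co <- arrayInd(seq_len(prod(dims)), dims)
  pc <- sweep(co - 0.5, 2, voxelSize, "*")
  rowSums(sweep(pc, 2, position)^2) <= radius^2
}

# Brute-force Mann-Whitney U: count pairs (a_i > b_j) + half-ties.
bruteU <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# Two-pass Pearson correlation (independent of stats::cor).
twoPassPearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Interval Jaccard between two [start, end] intervals in minutes.
intervalJaccard <- function(s1, e1, s2, e2) {
  lo <- max(s1, s2); hi <- min(e1, e2)
  if (hi <= lo) return(0)
  (hi - lo) / (max(e1, e2) - min(s1, s2))
}

# Arrival-coupled single-nucleus trace run through burst calling and
# linking; returns the per-burst leads/dwells for non-first bursts.
arrivalRecovery <- function(lead, dwell, seed, interBurst, nFrames,
                            burstParams = HubKinetics::burstParams()) {
  cfg <- simulationConfig(seed = seed, nFrames = nFrames,
    ms2 = list(coupling = "arrival", arrivalLead = lead,
               dwellAfter = dwell, interBurst = interBurst,
               firstBurst = 2, riseRate = 600, amplitude = 600,
               plateau = 1.5, decayRate = 2))
  s <- simulateTraces(cfg)
  bs <- callBursts(s$trace$ms2, params = burstParams)
  recs <- data.frame(frame = s$trace$frame,
                     hub_present = s$trace$hub_present,
                     overlap_mean_intensity =
                       ifelse(s$trace$hub_present, 1.2, NA),
                     sphere_mean_intensity = s$trace$hub_intensity)
  runs <- extractRuns(recs, 11.56, 0L)
  lk <- linkBurstsToHubs(bs, runs, recs)
  ok <- !lk$is_first & lk$hub_present_at_start
  list(leads = lk$arrival_lead_min[ok], dwells = lk$dwell_after_min[ok],
       links = lk, bursts = bs, truth = s$truth)
}
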