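# HubKinetics

Quantitative analysis of transcription factor hubs and transcriptional
bursting in two-channel 4D live-imaging data of early embryos.

## The problem

Morphogen transcription factors such as Dorsal in the *Drosophila*
blastoderm concentrate in sub-nuclear microenvironments ("hubs").
Two-channel volumetric time-lapse imaging records a tagged
transcription factor alongside nascent transcription at a reporter
locus, visualised as a single diffraction-limited spot by the MS2/MCP
system. Relating the two signals requires a long measurement chain,
and this package implements all of it for R users working with such
data:

- **Nuclei** — per-slice segmentation (a simple intensity-based
  stand-in with a drop-in interface for learned segmenters),
  z-stitching with gap interpolation, and greedy nearest-neighbour
  tracking through interphase.
- **Hubs** — nucleoplasm-normalized detection by median filter,
  grayscale erosion + morphological reconstruction, residual
  thresholding and marker-controlled 3D watershed; per-hub volume,
  integrated and mean intensity; hub density and intensity statistics
  per nucleus.
- **MS2 locus** — median + difference-of-Gaussians spot detection with
  a percentile threshold, brightest-spot selection, temporal linking,
  and gap interpolation / 20-frame pre-appearance extrapolation in
  nucleus-relative coordinates (exact under nucleus translation and
  isotropic growth).
- **Interactions** — hub overlap volume and intensity inside a 0.5 µm
  sphere around the locus; contiguous hub-contact runs; survival
  curves; three-component Gaussian-mixture classification of dwell
  times into short-, mid- and long-lived contacts.
- **Bursts** — derivative-based burst calling on smoothed MS2 traces
  with amplitude, duration, output, loading rate and frequency;
  burst–hub linking (hub present at burst start, arrival lead, dwell
  after start, high-intensity-hub splits); lag-resolved
  cross-correlation of MS2 and hub-intensity traces; Mann-Whitney and
  Pearson group statistics.
- **Synthetic data** — a first-class, ground-truthed generator of
  intensity traces and full two-channel movies (ellipsoidal nuclei,
  Gaussian-blob hubs with birth/death dynamics, a bursting MS2 spot,
  Poisson–Gaussian camera noise), so the entire pipeline is testable
  without any imaging download.

The core statistic for dwell-time classification is a three-component
Gaussian mixture over run durations *d* (minutes),

p(d) = Σₖ wₖ N(d; μₖ, σₖ²),  k ∈ {short, mid, long}, μ₁ < μ₂ < μ₃,

fitted by EM with multiple deterministic initialisations and a
variance floor; bursts are segmented from the smoothed trace
derivative with a tangent-refined onset, so a linear rise of slope ρ
reaching amplitude A yields loading rate exactly ρ = A / rise-time.

## Worked example

Simulate a paired trace in which hub presence switches on 8.38 min
before each non-first burst and off 13.02 min after the burst start,
then recover those numbers with the analysis chain:

```r
library(HubKinetics)

cfg <- simulationConfig(seed = 42, nFrames = 520,
  ms2 = list(coupling = "arrival", arrivalLead = 8.38, dwellAfter = 13.02,
             interBurst = 23, firstBurst = 2, riseRate = 600,
             amplitude = 600, plateau = 1.5, decayRate = 2))
s    <- simulateTraces(cfg)
bs   <- callBursts(s$trace$ms2, frameInterval = 11.56)
recs <- data.frame(frame = s$trace$frame,
                   hub_present = s$trace$hub_present,
                   overlap_mean_intensity = ifelse(s$trace$hub_present, 1.2, NA),
                   sphere_mean_intensity = s$trace$hub_intensity)
runs <- extractRuns(recs, frameInterval = 11.56)
lk   <- linkBurstsToHubs(bs, runs, recs)
ok   <- !lk$is_first & lk$hub_present_at_start
cat(sprintf("arrival lead %.3f min, dwell after start %.3f min\n",
            mean(lk$arrival_lead_min[ok]), mean(lk$dwell_after_min[ok])))
```

```
arrival lead 8.285 min, dwell after start 13.101 min
```

Both recovered means sit within half a frame interval (11.56 s ≈
0.193 min) of the imposed values; the residual offset is the frame-grid
quantization of the hub ON/OFF events. Dwell-time classification works
the same way:

```r
mx  <- list(weights = c(0.4, 0.35, 0.25), means = c(0.3, 1.35, 10.04),
            sds = c(0.045, 0.2, 1.5))
fit <- fitDwellMixture(sampleDwellTimes(mx, 2000, seed = 1), seed = 1)
fit
```

```
Three-component Gaussian mixture fit (dwell times, minutes)
 component weight  mean    sd
     short  0.413 0.302 0.047
       mid  0.331 1.349 0.211
      long  0.256 9.951 1.497
converged: TRUE | logLik: -1641.32
```

Movie-level analysis goes through `simulateEmbryoMovie()` (or
`readMovie()` for your own TIFF + metadata sidecar) and
`runPipeline()`, which emits the nuclei/hubs/ms2/interactions/runs/
bursts/links CSV tables plus the exact config that produced them. The
same stages are exposed as a command line via
`inst/cli/hubkinetics.R` (`simulate`, `segment-nuclei`, `detect-hubs`,
`track-ms2`, `interactions`, `bursts`, `report`).

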