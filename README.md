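# mitoquant

Quantification of mitotic fidelity assays: kinetochore SAC signals,
kinetochore–microtubule turnover, Cyclin B1 degradation kinetics,
mitotic timing, drug dose–response, and CRISPR-screen hit selection.

## The problem

Cells that depend on the kinesin KIF18A die in mitosis when the motor is
inhibited: kinetochore–microtubule (K-MT) attachments destabilize, the
spindle assembly checkpoint (SAC) fires modestly at many kinetochores,
and cells whose metaphase-to-anaphase transition is already slow —
because of weak basal APC/C activity or persistent SAC signaling —
arrest and die. Dissecting that axis takes several quantitative assays,
each with its own analysis conventions. `mitoquant` implements those
analyses as a tested R package for cell-biology groups running the
assays:

- **3D kinetochore quantification** — segment spots in multi-channel
  z-stacks, subtract the median non-kinetochore background, flag merged
  spots (volume > Q3 + 1.5·IQR), pole-coincident spots, and cells with
  aberrant kinetochore counts, and call MAD1-positive kinetochores above
  the 90th/95th/99th percentile of the DMSO reference distribution.
- **Spindle geometry** — locate poles, project kinetochores onto the
  spindle axis, classify central (≤ 5 µm from the midline) vs polar.
- **Photoactivation turnover** — fit
  `I(t) = f·2^(−t/t½_fast) + (1−f)·2^(−t/t½_slow)` to
  contralateral-corrected decay of a photoactivated tubulin band; the
  slow half-life reports K-MT stability, and
  `t½(treated)/t½(control)` summarizes destabilization. Poleward flux
  is the drift velocity of the band's smoothed intensity maximum.
- **Cyclin B1 kinetics** — detect the metaphase inflection anchor,
  normalize to 100% there, report the interpolated 50% crossing as the
  degradation half-life and the steepest 3-frame slope (relative to the
  mitotic maximum) as the maximum degradation rate.
- **Timing and fates** — NEBD-to-anaphase durations with censoring for
  death/slippage, fate proportions, OLS R² for sensitivity predictors.
- **Dose–response** — `%Viability = (S_sample − S_DMN)/(S_DMSO − S_DMN)
  × 100`, `%Toxicity = 100 − %Viability`, viability rescue, 4-parameter
  logistic (variable-slope) fits, and the >40% / <20% toxicity
  sensitivity classification.
- **Screen hits** — Δβ gating outside mean ± 1.5 SD with an FDR cutoff,
  plus Fisher-exact gene-set enrichment.

A seeded synthetic-data generator (volumes with planted artifacts,
decay traces, Cyclin traces, plates, screen tables) provides ground
truth for every stage, so the package is fully testable offline.

## Worked example

```r
library(mitoquant)

## one synthetic metaphase cell with planted artifacts
cfg <- synthConfig(seed = 7, sac_positive_rate = 0.2,
                   artifact_rates = list(fused_pair = 0.1,
                                         pole_coincident = 0.05))
out <- makeKinetochoreVolume(cfg)
qc  <- qcConfig(threshold = attr(out$truth, "suggested_threshold"))
seg <- segmentSpots(out$volume, "reference", qc)
bg  <- c(reference = estimateBackground(out$volume, seg$labels, "reference"),
         sac       = estimateBackground(out$volume, seg$labels, "sac"))
spots <- quantifySpots(seg$spots, out$volume, seg$labels, bg)
frame <- locatePoles(out$volume)
spots <- qcFilterSpots(spots, qc, frame)
frame
#> SpindleFrame
#>   pole A (z,y,x um): 3.499, 1.468, 4.517
#>   pole B (z,y,x um): 3.499, 11.47, 4.518
#>   length: 9.999 um
sum(!spots$qc_pass)   # artifacts flagged among 46 components
#> [1] 6
table(classifyRegion(axisPosition(spots, frame)))
#> central   polar
#>      45       1

## K-MT turnover: two-phase decay and the treated/control ratio
fit <- fitTwoPhase(correctContralateral(
  makePhotoactivationSeries(1.5, 10, 0.7, noise_sd = 0, seed = 7)))
fit
#> TwoPhaseFit: f_fast = 0.700, t1/2 fast = 1.5 min, t1/2 slow (K-MT) = 10 min
#>   rss = 1.703e-31 over 37 frames; converged: TRUE
ctl <- fitTwoPhase(correctContralateral(
  makePhotoactivationSeries(1.5, 16.9, 0.7, noise_sd = 0, seed = 8)))
slowHalfLifeRatio(fit, ctl)
#> ratio 0.59 -> 41% destabilization

## endpoint toxicity and the sensitivity call
vm <- viabilityMetrics(signal_sample = 0.62, signal_dmso = 1.40,
                       signal_dmn = 0.35)
c(vm$toxicity, classifySensitivity(vm$toxicity))
#> viability 25.7%, toxicity 74.3% -> "sensitive"
```

The flagged components are the planted fused pairs and pole-coincident
spots; the decay fit returns the planted parameters to numerical
precision on a noiseless trace; a slow-half-life ratio of 0.59
corresponds to a 41% K-MT destabilization; toxicity above 40% classifies
the line as drug-sensitive.

A command-line front end covering the same steps ships in
`inst/exec/mitoquant` (`mitoquant simulate|spots|pa-fit|cyclin|timing|
dose|screen`). The methods vignette
(`vignettes/mitoquant-methods.Rmd`) documents every model, convention
and default.

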