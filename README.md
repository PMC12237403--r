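# GLIMtools

Quantitative analysis of intra-Golgi secretory transport from fluorescence
microscopy of nocodazole-induced Golgi ministacks.

## The problem and the method

The Golgi stack is only 200–400 nm thick and randomly oriented, so where a
secretory cargo sits *within* a stack cannot be read off a conventional
image directly. Nocodazole-induced Golgi ministacks are small, uniform and
rotationally symmetric, which makes a numerical treatment possible. GLIM
(Golgi localization by imaging centers of mass) images three channels per
ministack — the cis marker GM130, the trans marker GalT-mCherry, and the
cargo under test — computes each channel's sub-pixel, chromatic-corrected
center of mass, and places the cargo on the cis-to-trans axis by the
**localization quotient**

> LQ = (a · b) / (b · b),  with a = cargo − GM130, b = GalT − GM130

the signed projection of the cargo's displacement onto the stack axis in
units of the axis length. GM130 defines LQ = 0, GalT-mCherry defines
LQ = 1; one LQ unit corresponds to 274 nm. LQs map onto Golgi regions:
ERES/ERGIC (LQ < −0.25), cis (−0.25 ≤ LQ < 0.25), medial
(0.25 ≤ LQ < 0.75), trans (0.75 ≤ LQ < 1.25), TGN (LQ ≥ 1.25).

For a cargo released synchronously from the ER (RUSH assay), the LQ versus
chase time t follows first-order kinetics

> LQ(t) = y₀ − A·exp(−ln2 · t / t_intra)

where y₀ is the LQ of the Golgi exit site and t_intra the half-range
(intra-Golgi transport) time. Its derivative gives the instantaneous
transport velocity, most usefully expressed at a fixed axial position:

> dLQ/dt = ln2 · (y₀ − LQ) / t_intra    (× 274 for nm/min)

The package also estimates **Golgi residence times** by fitting
Golgi-intensity decays to y = y₀ + A₁·exp(−x/t₁) with t₁⁄₂ = 0.693·t₁
(fits require adjusted R² ≥ 0.80 and acquisition length ≥ 1.33·t₁⁄₂), and
performs **side / en-face averaging**: registration and averaging of many
ministack images guided by giantin double puncta or rings, with axial
Gaussian peak fitting (Xc) to measure inter-marker distances such as the
~300 nm GM130-to-GalT spacing.

A synthetic-image module simulates ministack fields, bead calibration
fields, kinetic series, decay traces/movies and side/en-face views with
known ground truth, so the entire pipeline is testable end to end.

## Worked example

```r
library(GLIMtools)

## simulate a wide-field ministack image and measure LQs
cfg <- simulationConfig(nStacks = 25, cargoLqTrue = 0.4, seed = 7)
sim <- simulateMinistackField(cfg)
lqs <- measureMinistacks(sim$image, cargoId = "SBP-GFP-demo")
ok  <- lqs$pass_qc
sprintf("mean LQ = %.3f ± %.3f (SEM), region: %s",
        mean(lqs$lq[ok]), sd(lqs$lq[ok]) / sqrt(sum(ok)),
        classifyRegion(mean(lqs$lq[ok])))
#> "mean LQ = 0.404 ± 0.009 (SEM), region: MEDIAL"

## fit intra-Golgi transport kinetics and derive the velocity
ser <- simulateLQSeries(1.0, 1.2, 8, c(5, 10, 15, 20, 30, 40, 50, 60),
                        seed = 7)
fit <- fitIntraGolgiKinetics(ser)
fit
#> KineticFit [simulated]: LQ(t) = 1.002 - 1.175 exp(-ln2 t / 8.07),
#>   adj R2 = 0.999 (n = 8)
velocityAtLQ(fit@tIntraMin, fit@y0, 0.40)
#> 0.052 LQ/min = 14.2 nm/min

## published fit parameters ship with the package
sbp <- subset(rushKineticParams(), reporter == "SBP-GFP")
velocityAtLQ(sbp$t_intra_min, sbp$y0, 0.40)
#> 0.022 LQ/min, 6.1 nm/min

## Golgi residence time with QC gates
tr <- simulateDecayTrace(10, 100, 23.1, durationMin = 90, dtMin = 2,
                         noiseSd = 3, seed = 7)
fitGolgiDecay(tr)
#> DecayFit [simulated]: t1/2 = 17.74 min, adj R2 = 0.988, accepted
```

The measured mean LQ (0.404 ± 0.009) recovers the simulated ground truth
(0.4) and lands in the medial region; the kinetic fit recovers
(y₀, A, t_intra) = (1.0, 1.2, 8 min) from noisy data; the velocity at
LQ = 0.40 converts to nm/min through the 274 nm/LQ calibration; and the
decay fit passes both acceptance gates.

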