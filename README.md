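# uscontour

Semi-automatic extraction of smooth closed organ contours from grayscale
ultrasound images, guided by a few operator-supplied points near the
boundary.

Ultrasound images suffer speckle, shadowing and missing edges, so fully
automatic segmentation is brittle; clinically, a radiologist can cheaply
click a handful of points near the organ boundary. `uscontour` turns the
image plus those clicks into an *explicit* parametric contour

    f(t) = ( (2 O_x(t) + 1) / (2 O_x(t) + 2),
             (2 O_y(t) + 1) / (2 O_y(t) + 2) ),   t in [0, 1),

where `O_x`, `O_y` are the outputs of a small three-layer network (sigmoid
hidden layer, shifted-ELU output) driven by the *projection index* `t`:
the normalised arc-length position of a click on a closed polygonal
principal curve. The pipeline:

1. **Data sequence** — Z-score filtering of the clicks and histogram
   equalization; neutrosophic channel mapping (true/indeterminate/false
   memberships, the indeterminacy channel being the normalised gradient);
   an indeterminacy-adaptive Gaussian filter; mean-shift clustering of
   the clicks with the adaptive bandwidth `h = mean(Ic) * range(Tc')`;
   the modes become the vertices of a closed principal curve and each
   click is projected onto it to get `t`.
2. **Weight search** — a memory-based quantum-inspired differential
   evolution (superior-blended mutation with schedule
   `lambda = ((g_max - g)/g_max)^2`, Levy-flight perturbation `g^-ap`,
   Lehmer-mean adaptation of F and CR) seeds the network weights.
3. **Training** — full-batch momentum descent with a Caputo-type
   fractional gradient scaling `(|w - w0| + delta)^(1-nu) / Gamma(2-nu)`
   and L2 regularization (reference configuration: learning rate 0.4, momentum
   0.9, 1000 epochs, 10 hidden units).
4. **Contour** — the closed-form curve is sampled, rasterized (even-odd
   fill) and scored by Dice (DSC), Jaccard (OMG) and accuracy (ACC).

A speckle phantom generator with exact ground truth, salt-and-pepper
robustness sweeps (SNR 1/0.8/0.7/0.6 with the histogram-overlap damage
measure) and the four-way ablation battery (classic mean shift / plain DE
/ integer-order training) make every stage testable without clinical
data. Everything the package reads or writes is plain text: ASCII PGM
images, CSV point sets, JSON reports.

## Worked example

```r
library(uscontour)

## a 600 x 450 speckle phantom: 3-lobed organ, 24 jittered boundary clicks
ph  <- generatePhantom(phantomSpec(fourierCoeffs = list(c(0.1, 3, 0.5)),
                                   seed = 1))
run <- segmentImage(phantomImage(ph), phantomPriors(ph),
                    pipelineConfig(seed = 1))
computeMetrics(run$mask, phantomMask(ph))
```

```
$dsc
[1] 0.9515704

$omg
[1] 0.9076149

$acc
[1] 0.9889778
```

The fitted contour overlaps the true boundary at Dice 0.952 — roughly a
5 px boundary error on a 100 px-radius organ — and `run$report$formula`
holds the full closed-form expression for `x(t)` and `y(t)` with the
trained coefficients inlined, evaluable with `evalContourFormula()`:

```r
substr(run$report$formula[["x"]], 1, 80)
#> [1] "((((2*(ifelse((((1/(1+exp(-(2.4327154059197178*t+-2.0544908221871103))))*-0.2815"
```

A thin command-line front-end over the same functions lives at
`inst/scripts/uscontour.R` (`synth`, `segment`, `evaluate`, `sweep`,
`ablate` subcommands).

## Acceptance script

`scripts/acceptance.R` regenerates a phantom from the given seed, runs the
full four-stage segmentation against it, reports the overlap metrics on
stderr and writes the acceptance JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/contour-extraction.Rmd` documents the model, its assumptions,
every tunable parameter, the numerical design choices (channel
normalisation, target conditioning, the training loss scale, the
parameter-seam anchor, the evolutionary-search repairs) and what the
phantom generator does and does not emulate.
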