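---
title: "Point-guided parametric contour extraction for ultrasound images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-guided parametric contour extraction for ultrasound images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uscontour)
```

## The problem and the model

Ultrasound organ boundaries are corrupted by speckle, attenuation shadows
and missing edges, so fully automatic segmentation is unreliable and
clinical workflows often fall back on a radiologist clicking a handful of
points near the boundary. `uscontour` turns such a point set plus the
grayscale image into a smooth, closed, *explicit* parametric contour

$$f(t) = \left( \frac{2\,O_x(t) + 1}{2\,O_x(t) + 2},\;
                \frac{2\,O_y(t) + 1}{2\,O_y(t) + 2} \right),
  \qquad t \in [0, 1),$$

where $O_x, O_y$ are the two outputs of a three-layer network (sigmoid
hidden layer, shifted-ELU output) whose only input is the *projection
index* $t$ — the normalised arc-length position of a point on a closed
polygonal principal curve. The trained weights and thresholds *are* the
contour: `contourFormula()` renders the fitted curve as a plain-text
expression in `t`, and a test pins that the rendered formula reproduces
`contourPoint()` to 1e-12.

The pipeline has four stages:

1. **Data sequence.** The prior clicks are Z-score filtered (outlier
   clicks removed per coordinate at 3 standard deviations) and the image
   is histogram-equalized. The image is mapped to neutrosophic channels —
   true $T_c$ (bright), false $F_c = 1 - T_c$ (dark) and indeterminate
   $I_c$ (normalised Sobel gradient magnitude, the edge/noise channel) —
   and $T_c$ is smoothed by a Gaussian whose per-pixel width follows
   $\sigma_I = a I_c + b$. Mean shift with the adaptive bandwidth
   $h = \bar I_c \cdot \mathrm{range}(T_c')$ (scaled to pixels) clusters
   the clicks; the cluster modes are the vertices of the closed principal
   curve, ordered by polar angle about their centroid. Every click is
   projected to its nearest vertex or segment, yielding the sorted data
   sequence $(t_n, x_n, y_n)$.
2. **Weight search.** A memory-based differential evolution searches the
   42-dimensional flattened parameter vector of the 1-10-2 network,
   minimising the model error on the data sequence, to give training a
   good basin.
3. **Training.** Full-batch gradient descent with momentum on the
   sum-squared error, with a Caputo-type fractional scaling of the
   gradient, $(|w - w_0| + \delta)^{1-\nu} / \Gamma(2-\nu)$, and L2
   regularization.
4. **Contour.** The closed-form curve is sampled at 1000 parameters,
   rasterized by even-odd fill at pixel centers, and compared to ground
   truth by Dice (DSC), Jaccard (OMG) and pixel accuracy (ACC).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `zThreshold` | 3 | z-score cut for outlier clicks (dimensionless) |
| `nsA`, `nsB` | 10, 0.25 | $\sigma_I = a I_c + b$ of the indeterminacy filter; the literature leaves these free, so they are configuration values |
| `nsM` | 5 px | filter window size |
| `sH` | 40 px | bridge from the dimensionless bandwidth of the uncertain domain to pixels |
| `hMin` | 2 px | bandwidth floor (phantom interiors can have near-zero indeterminacy) |
| `hidden` | 10 | hidden units, the reference configuration of the method |
| `lr`, `momentum`, `epochs` | 0.4, 0.9, 1000 | the reference SGD configuration |
| `nu` | 0.9 | fractional order; `nu = 1` is exactly plain backpropagation |
| `l2` | 1e-4 | weight decay |
| `wrapPad` | 0.04 | seam handling, see below |
| `nSamples` | 1000 | contour sampling density |

## Numerical choices

**Channel normalisation.** The membership definitions are implemented as
$T_c = (g - g_{\min})/(g_{\max} - g_{\min})$ so that $T_c + F_c = 1$ and
both lie in $[0, 1]$; the variant with $g + g_{\min}$ in the numerator
breaks the membership range whenever $g_{\min} > 0$ and is treated as a
typo.

**Target normalisation.** The coordinate map $c = (2O+1)/(2O+2)$ is
heavily asymmetric: $c = 0.95$ needs $O = 9$ where $dc/dO \approx 0.005$,
while $c = 0.3$ sits at $O \approx -0.29$ with $dc/dO \approx 1$. Targets
are therefore min-max normalised into $[0.3, 0.7]$ per axis (the margin is
configurable), where the map is well conditioned; the affine map is stored
in the model and inverted when the contour is evaluated.

**Training loss scale.** The reference learning rate (0.4, momentum 0.9,
1000 epochs) converges only when the descent direction is the gradient of
the classic sum-squared error $\tfrac12\sum_n\|c(t_n) - c^*_n\|^2$; with
the per-sample mean loss the steps are $N$ times smaller and the same
budget stalls an order of magnitude short. The step is therefore
`gradScale` (default 24, the default click count) times the mean-sample
gradient — exactly the textbook sum-loss step at the nominal click count,
but independent of how many clicks the operator actually supplies (a
plain sum loss was measured to diverge at this learning rate once the
data sequence grows dense). `modelError()` reports the per-sample
normalisation; the two scalings have identical minimisers. Training also
returns the lowest-error epoch alongside the final one; the pipeline uses
that checkpoint, since momentum can overshoot late in the fixed budget.

**Evolutionary search.** The printed algorithm overloads one symbol for
the mutation blend, a Levy-updated state and a selection-updated state.
The package keeps them apart: the mutation base is the
$\lambda$-schedule blend of a random and a "superior" individual; a
single persistent *base individual* (initialised to the best of the
random population) is updated greedily by the crossover/selection step
and is the anchor that new mutants are blended toward, with the Levy step
$g^{-ap}$ perturbing only its trial copy. With a single scalar mutation
factor the printed Lehmer-mean memory update degenerates — the Lehmer
mean of copies of $F$ is just $F$, leaving a decaying random walk that
collapses the mutation factor and freezes the search — so the memories
$u_F, u_{CR}$ seed per-candidate values, $F_i \sim
\mathrm{Cauchy}(u_F, 0.1)$ truncated to $(0, 1]$ and $CR_i \sim
\mathcal N(u_{CR}, 0.1)$ clipped to $[0, 1]$, and the successful values
feed the Lehmer update. The acceptance suite requires this configuration
to solve the 5-dimensional sphere benchmark (fitness below $10^{-2}$) in
at least 19 of 20 seeded runs; the literal per-index readings stalled
well short of that during development and were abandoned.

**The parameter seam.** The network is not periodic in $t$, and the
points clustered around the first vertex all receive $t = 0$ (they sit in
that vertex's partition region), so the final stretch of the parameter
range carries no data and the fitted curve can swing far from the organ
there — even an otherwise excellent fit. The pipeline therefore
duplicates the data rows with $t$ below `wrapPad` at $t + 1$ before
training (periodic continuation), pinning the closure. Wide two-sided
padding stretches the fixed 10-unit capacity over a longer domain and
costs more than this one-sided anchor.

**Convergence and ties.** Mean-shift iterations stop when the shift norm
falls below 1e-3 px (200 iteration cap); modes closer than half a
bandwidth merge, weighted by member count. Projection ties go to the
lower-index element in curve order $v_0, s_0, v_1, \dots$. Fitness ties
in the evolutionary search favour the newer candidate.

## What the phantom generator does and does not emulate

`generatePhantom()` draws a star-shaped organ cross-section
$r(\theta) = r_0 (1 + \sum_k A_k \cos(k\theta + \phi_k))$, fills inside
and outside with contrasting means, multiplies by unit-mean gamma speckle
(shape 8 by default — a standard first-order speckle surrogate),
optionally attenuates angular shadow sectors, and jitters `nPrior = 24`
uniform boundary samples with 2 px isotropic Gaussian noise to emulate
radiologist clicks. Defaults use the 600 x 450 px working resolution of
the clinical protocol the package models. What it does **not** emulate:
physics-based wave propagation, depth-dependent attenuation, anisotropic
speckle correlation, neighbouring organs, or operator click bias toward
high-contrast edge segments. A green end-to-end test therefore
establishes that the mathematics of the pipeline recovers known smooth
boundaries under speckle-like noise — not clinical performance.

The test suite runs most phantoms at 200 x 150 px (radius 50) to stay
inside its time budget; the full-resolution defaults are exercised by the
end-to-end accuracy checks.

## Degenerate inputs

Constant images are rejected at channel mapping (no intensity range);
fewer than 3 prior points, all-outlier point sets, collinear cluster
modes, and contours that collapse below 1 px$^2$ of area raise stage-named
errors. A bandwidth that underflows (zero indeterminacy everywhere) is
clamped to `hMin` with a message. Non-finite objective values during the
evolutionary search mark the candidate infeasible rather than aborting.

## Known limitations

- The polar-angle vertex ordering assumes a star-shaped outline (true of
  prostate and kidney cross-sections, not of strongly folded shapes).
- t-parameterisation inherits the polygon's piecewise-linear arc length,
  so very coarse vertex sets warp the target functions.
- With 10 hidden units the fit floor on jittered 24-point star data is a
  few pixels RMS; tighter contours need more clicks, not more epochs.
- The ablation battery reproduces the *direction* of the reference
  component comparison on phantoms; absolute clinical numbers require the
  original (private) hospital data.
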