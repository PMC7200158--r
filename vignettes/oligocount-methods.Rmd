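---
title: "Models and methods in oligocount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in oligocount}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligocount)
```

oligocount implements the quantitative machinery behind a study of
DIX-domain self-association in Wnt signalling: how strongly the Axin
DIX-type domain (DAX) self-associates, what helix the Dishevelled DIX
filament forms, and how many Dishevelled molecules sit in a
diffraction-limited membrane spot. This vignette explains each model,
its assumptions, the tunable parameters, and the choices made where the
methods left room for interpretation.

## The isodesmic oligomerization model

SEC-MALS reports one average mass for a self-associating protein, not a
dissociation constant. The isodesmic (equal-K) model closes that gap:
every monomer-addition step $A_n + A_1 \rightleftharpoons A_{n+1}$ is
assigned the same dissociation constant $K$, so with monomer
concentration $m$ the oligomer concentrations are
$c_n = m\,(m/K)^{n-1}$ up to a truncation order $N$. Two observations
determine the two unknowns:

* protomer conservation, $\sum_{n} n\,c_n = c_\mathrm{tot}$;
* the number-average species mass,
  $M_1 \sum_n n\,c_n \big/ \sum_n c_n = M_\mathrm{avg}$.

$K$ is reported as monomer squared over dimer, $K_D = m^2/c_2$.

`solve_isodesmic()` reduces the system to one dimension: with
$x = m/K$, the mass constraint
$\sum_n n x^{n-1} / \sum_n x^{n-1} = M_\mathrm{avg}/M_1$ depends on $x$
alone and is strictly increasing in $x$ (from 1 towards $N$), so a
bracketed root find on $x$ is guaranteed a unique solution; $m$ then
follows from conservation and $K = m/x$. The bracket is expanded
upward as needed because for small $N$ the solution can sit at
$x \ge 1$ (at $N = 2$ and $M_\mathrm{avg} = 1.5\,M_1$ it is exactly
$x = 1$). The root is polished to machine precision and the solution is
rejected if the reproduced average mass differs from the observation by
more than one part in $10^8$.

Parameter choices:

* **Protomer mass.** The worked equations of the source analysis use a
  10 kDa protomer even though the construct's sequence mass is 9.9 kDa;
  `solve_isodesmic()` takes the mass as a parameter and the analysis
  scripts use 10 kDa for the dissociation-constant table and 9.9 kDa
  for protomers-per-oligomer conversions, matching that convention.
* **Mass average.** The constraint uses the *number*-average mass over
  species, which is what the worked equations encode. SEC-MALS
  instruments conventionally report weight-average masses; a
  `mass_average = "weight"` flag implements that variant, but the
  number average is the default because it is the published model. The
  two give very different constants (the weight-average reading of the
  same inputs more than doubles $K_D$), which is worth keeping in mind
  when comparing against instrument output.
* **Truncation.** `convergence_table()` shows $K_D$ as a function of
  $N$; for the study's inputs (710 nM protomer, 15 kDa average) the
  estimate rises from 237 nM at $N = 2$ and settles by $N \approx 9$
  within a nanomolar of the closed-form infinite limit
  $K = c_\mathrm{tot}(1 - x)^2/x$ with $x = 1 - M_1/M_\mathrm{avg}$
  (`infinite_limit_kd()`), about 947 nM.

At the solution for the study's inputs, the monomer holds about 44% of
protomers (67% of species) — close to, but not exactly, the "roughly
40% monomer" the source text quotes without stating its basis; the
package computes both fractions rather than hard-coding either.

`fit_kd_to_series()` generalizes the single-point inversion to a
concentration series by least squares on predicted versus observed
average masses, with $K$ optimized on a log scale; with a single row it
reproduces `solve_isodesmic()`.

## Helical geometry

The filament model is pure arithmetic: per-protomer twist
$\Delta\phi = 48.0^\circ$ and rise $\Delta z = 13.5$ Å give a pitch of
$\Delta z \cdot 360 / \Delta\phi = 101.25$ Å and $7.5$ protomers per
turn. `build_double_helix()` places strand-A centroids at
$(R\cos i\Delta\phi,\, R\sin i\Delta\phi,\, i\Delta z)$ and generates
the antiparallel strand B by a two-fold rotation about an in-plane
axis. Three parameters are schematic rather than measured: the radius
(default 20 Å), the dyad phase (default 0°), and the handedness
(default right), none of which is printed in the source structure
analysis; the builder exposes all three and the documentation flags
them as illustrative. `export_centroids()` writes one CA pseudo-atom
per protomer (chains A/B) so the model can be opened in any structure
viewer.

## The TIRF copy-number pipeline

The pipeline estimates how many GFP-tagged molecules occupy each
diffraction-limited spot in a short movie, without trusting absolute
intensity calibration. Stages, with defaults matching the imaging
analysis it re-implements:

1. **Rolling-ball background subtraction** (`rolling_ball_subtract()`,
   5 px ball). Implemented as grayscale morphological opening with a
   disc; features narrower than the disc survive. The opening reaches
   slightly into a PSF-sized spot's own tails, costing roughly 8% of
   peak amplitude at $\sigma = 1$ px — a known, multiplicative bias
   discussed below.
2. **Time averaging** (`time_average()`, centred window of 5,
   edge-truncated), reducing shot noise about $\sqrt{5}$-fold for
   slowly moving spots at the cost of a small bleaching bias within
   the window.
3. **Spot detection** (`detect_spots()`, $\alpha = 0.05$, PSF
   $\sigma = 1$ px). Candidates are local maxima of the matched-filter
   amplitude field (per-pixel least-squares amplitude of a fixed-width
   Gaussian over a flat local background). Because selecting maxima
   biases any plain amplitude z-test anticonservative, the detection
   p-value is taken against the empirical distribution of local-maximum
   amplitudes on a matched-filtered pure-noise reference built once per
   PSF width from a fixed-seed white-noise frame — so on featureless
   frames the false-positive fraction tracks $\alpha$ by construction.
   Survivors are refined by least-squares Gaussian fits with $\sigma$
   fixed (damped Gauss-Newton); when the single-spot residual shows a
   secondary peak, a two-component fit is attempted, and detections
   closer than $2\sigma$ merge to the brighter one.
4. **Trajectory linking** (`link_trajectories()`, maximum closed gap 4
   frames). Frame-to-frame matching minimizes total squared
   displacement under a displacement gate (default 2 px, sized for
   near-stationary membrane spots), solved exactly per connected
   component of the candidate graph with an augmented-matrix linear
   assignment. Gap closing joins track ends to later starts within the
   gap limit and a diffusive displacement budget
   ($\mathrm{gate}\times\sqrt{\mathrm{gap}+1}$), greedily by ascending
   displacement.
5. **Selection and sampling.** Trajectories with at least 10 detected
   frames are kept (length counts detections, not closed gaps — the
   stricter reading of "10 frames or longer", configurable), and each
   contributes one sample: the integrated intensity
   $2\pi\sigma^2 A$ at its first detected frame. Integrated volume is
   used rather than peak amplitude because it is the quantity
   proportional to emitted photons; this is configurable in spirit by
   consuming the fitted amplitudes directly.
6. **Mixture modelling** (`select_gmm()`). The sample distribution is
   fit with 1-D Gaussian mixtures for $k = 1..k_\mathrm{max}$, each the
   best of 100 seeded EM replicates (k-means++-style initialization,
   500-iteration cap, variances floored at $10^{-6}$ times the sample
   variance), selecting $k$ by BIC (or AIC); component counts whose
   replicates all collapse are excluded, mirroring the ill-conditioned
   handling of the original analysis.
7. **Calibration** (`calibrate()`). With sorted component means, the
   single-fluorophore intensity is $g = \mu_{(2)} - \mu_{(1)}$ and the
   implied background offset $b = \mu_{(1)} - g$; spot intensities
   normalize to copy numbers as $(I - b)/g$, and `fraction_within()`
   reports the fraction within a chosen multiple (default 10) of a
   single fluorophore. The threshold is applied to normalized values,
   i.e. after background subtraction.

The spacing-based calibration is deliberately robust to two failure
modes: a multiplicative intensity bias (background subtraction,
bleaching within the averaging window) shifts all component means by
the same factor and largely cancels in the normalized copy numbers; and
missing the monomer population entirely still leaves $g$ equal to the
spacing of adjacent copy-number components. In end-to-end simulations
at the default conditions the recovered $g$ sits 10–15% below truth —
the same direction and rough size of bias the original analysis reports
for its single-GFP estimate on live cells — while the fraction of spots
within 10× of one fluorophore is recovered to within a few hundredths.

## Resampling statistics

Field-level comparisons use: `rank_sum_test()`, a two-sided
Mann-Whitney U (exact enumeration when the pooled sample is at most 12
without ties, otherwise the tie-corrected normal approximation);
`bootstrap_diff_means()`, which resamples each condition at its own
size and reports the empirical middle-95% interval of the difference of
means, flagging significance when the interval excludes zero; and
`ratio_of_means_bootstrap()`, which bootstraps each group mean, fits a
Gaussian to each bootstrap distribution and propagates the standard
deviations into a first-order standard error for the ratio of means.
All three take explicit seeds and leave the caller's RNG untouched.

## The synthetic-data generators

`simulate_tirf_stack()` produces movies with known truth: spots with
copy numbers drawn from an explicit probability vector (so ground-truth
summaries like the fraction within 10× are exact), pixel-integrated
Gaussian PSFs scaled so one unbleached fluorophore integrates to
exactly $g$ counts, per-fluorophore binary survival bleaching (no
blinking — omitted for identifiability at this scale), a linear
background gradient, Poisson shot noise followed by Gaussian read noise
at unit gain, and Gaussian random-walk motion. Defaults encode the
study conditions the pipeline is tested against: 512×512 px, 40 frames,
150 spots, copy numbers 1..12 with a decreasing probability vector
putting 97.5% of spots at or below 10 copies, $g = 120$ counts,
bleaching 0.02/frame, background 50 counts with a 10% gradient, read
noise 3 counts, diffusion 0.05 px/frame.

What the generator does *not* emulate — fluorophore blinking and
maturation, cell-shaped backgrounds, focus drift, camera gain
structure — bounds what passing tests show: they validate the
pipeline's statistical machinery under a faithful noise model, not its
behaviour on any particular microscope. `simulate_mals_series()`
(lognormal mass noise on the isodesmic forward model) and
`simulate_mgv_fields()` (normal per-field mean gray values with a
configurable fractional effect) play the same role for the equilibrium
fitting and the resampling statistics.

## Numerical and scale choices

Root finding uses machine-precision brackets ($x \in [10^{-12},
\infty)$ expanded as needed); EM convergence is declared at a relative
log-likelihood change of $10^{-8}$; assignment ties are broken by the
solver's deterministic scan order; degenerate inputs (constant frames,
empty trajectories, infeasible masses) raise informative errors rather
than producing numbers. Stochastic functions accept one integer seed
each, and `child_seed()` derives distinct per-stage seeds from a single
run seed so an entire analysis is reproducible from one number; all
seeded runs are byte-identical on re-execution.

The end-to-end simulation checks run at the study's native scale
(512×512 px, 40 frames, 150 spots), which keeps the full test suite in
the minutes range; the statistical power checks use 40 fields per
condition and 1000–5000 bootstrap resamples, sizes chosen to make the
asserted outcomes near-certain under the stated effect sizes.

## Known limitations

* The isodesmic model assumes length-independent addition constants; a
  cooperative (nucleation-elongation) mechanism would need a different
  closure and is out of scope.
* The helix builder is schematic between the measured twist/rise: the
  radius and inter-strand phase are presentation parameters.
* The detection null reference assumes approximately white,
  homoscedastic noise after preprocessing; strongly structured
  backgrounds would mis-calibrate $\alpha$.
* The two-component overlap fit caps at two spots per local cluster;
  denser fields need a true multi-emitter fitter.
* Copy numbers are reported on the scale of the calibrated
  single-fluorophore unit; absolute molecule counts inherit its 10–15%
  downward bias and the ~10% GFP maturation shortfall noted in the
  source analysis, which the package does not correct for.
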