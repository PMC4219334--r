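# nngibbs — Gibbs nearest-neighbor interaction analysis for spatial point patterns

`nngibbs` quantifies the spatial relationship between two sets of point-like
objects — virus particles and endosomes in a confocal image, receptor and
clathrin localizations in a PALM point cloud, cells in a tissue — going
beyond colocalization counts. It infers the effective interaction potential
that best explains where one set sits relative to the other, and tests
whether the inferred interaction is statistically significant given the
number of objects and the space they can occupy.

It is aimed at microscopists and image analysts who have either images of
blob-like objects (a spot detector is included) or object coordinates from
any segmentation or single-molecule localization pipeline.

## The model

Let $X = \{x_i\}_{i=1}^N$ be the dependent set and $Y = \{y_j\}_{j=1}^M$ the
reference set, and $d_i$ the distance from $x_i$ to its nearest neighbor in
$Y$. The *context* $q(d)$ is the NN-distance density that uniform, random,
independent placement of $X$ would produce — it absorbs the influence of
$Y$'s layout and the region's shape, including masks. The observed distances
are modeled by a Gibbs nearest-neighbor model:

$$ p(D \mid q) = Z^{-N} \prod_{i=1}^{N} q(d_i)\, e^{-\phi(d_i)} , $$

where $\phi(d)$ is the interaction potential and $Z$ the partition function.
Parametric potentials $\phi(d) = \varepsilon f((d-t)/\sigma)$ carry an
interaction strength $\varepsilon$ ($0$ for independent patterns), a length
scale $\sigma$, and a hard core $t$ (the colocalization-threshold analogue);
shapes $f$ include step, Hernquist, linear (two types) and Plummer wells, and
a penalized piecewise-linear non-parametric potential handles unknown shapes.
Parameters are estimated by minimizing the $\ell^2$ difference between the
kernel-smoothed observed distance density and the model density
$q e^{-\phi}/Z$; significance is assessed by a Monte Carlo rank test against
$K$ uniform null placements. The methods vignette
(`vignettes/interaction-analysis.Rmd`) derives the pipeline, defaults, and
limitations in detail.

## Worked example

Simulate a reference set of 100 points on a 500×500 px region, draw 1000
dependent points attracted to it through a Plummer potential with
$\varepsilon = 2$, $\sigma = 10$ px, then recover the interaction and test
it:

```r
library(nngibbs)
reg <- region(c(0, 499, 0, 499))
y   <- generate_reference(100, reg, seed = 101)
x   <- generate_interacting(y, 1000, potential("plummer", 2, 10), reg,
                            seed = 201)
fit <- ia_fit(x, y, reg, potential = "plummer", spacing = 0.5)
fit
#> Gibbs nearest-neighbor interaction fit
#>   N = 1000 points vs M = 100 reference points
#> Potential: plummer, epsilon = 1.848, sigma = 9.918, t = 0
#>   residual (L2) = 0.0001488

tst <- ia_test(x, y, reg, shape = "plummer", K = 199, seed = 1,
               context = fit$context)
tst
#> Monte Carlo test of 'no interaction'
#>   statistic: L2(observed, context) = 0.001146
#>   rank 200 of 199 null samples (rejection threshold: rank > 190 at alpha = 0.05)
#>   => interaction significant: null hypothesis rejected
```

The fit recovers the generating strength ($\hat\varepsilon = 1.85$ vs. 2)
and length scale ($\hat\sigma = 9.9$ px vs. 10); the observed pattern ranks
above all 199 null replicates, so independence is rejected at
$\alpha = 0.05$. `plot(fit)` overlays the observed, context and model
densities; `plot(fit, "potential")` draws $\hat\phi(d)$; `summary`, `coef`,
`predict`, `residuals` and `simulate` behave as for any fitted model object.

Images enter the same pipeline through `detect_spots()` (band-pass
restoration, percentile candidate selection, sub-pixel centroid refinement,
moment-based false-positive rejection), and coordinate CSV files through
`read_coordinates()`. A command-line launcher `exec/nngibbs` exposes
`detect`, `analyze`, `test` and `simulate` subcommands for shell use.

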