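---
title: "Separating site signal from season: constrained PLS-DA for confounded metabolomics designs"
author: "terroirPLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating site signal from season: constrained PLS-DA for confounded metabolomics designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terroirPLS)
```

## The problem

Untargeted metabolomics studies of perennial crops sampled over several
growing seasons face a structural confounder: year-to-year climatic
variation (the *vintage* effect) is usually the largest source of variance
in the feature table, dwarfing the site-specific (*terroir*) differences the
study is actually after. An unconstrained discriminant model — PLS-DA with
the site as the class — will happily build latent components that mix site
and season, because nothing in the objective stops season-correlated
variation from entering the score space. The model may classify well, but
its loadings (and therefore any candidate markers read off them) confound
the two sources.

`terroirPLS` implements a constrained variant, **oCPLS2-DA** (orthogonal
constrained PLS2 discriminant analysis), in which every latent score is
forced orthogonal to a nuisance block $Z$ built from the confounder's
dummy codes. The package covers the full modelling protocol around it:
preprocessing (internal-standard and median fold change normalization, log
transform, centering/autoscaling), post-transformation of fitted models to
$N-1$ predictive components, OPLS-DA, $N$-fold full cross-validation with
$Q^2$, permutation testing, component selection, per-feature split-plot
ANOVA screening, correlation-loading marker extraction, and a synthetic
generator that emulates the study design (7 vineyards in 3 macrozones,
3 vintages, 3 developmental stages, 3 replicate pools; 189 samples).

## The model

PLS2-DA regresses the centered dummy class matrix $Y_c$ ($n \times N$) on
the centered feature matrix $X$ ($n \times p$) through $A$ latent
components. Per component NIPALS iterates

$$w = X^\top u / (u^\top u), \quad w \leftarrow w / \lVert w \rVert, \quad
  t = Xw, \quad c = Y^\top t / (t^\top t), \quad u = Yc / (c^\top c)$$

to a fixed point (relative score change below $10^{-10}$, at most 500
iterations; the iteration is seeded at its analytical fixed point, the
dominant singular pair of $X^\top Y_c$, so it converges immediately except
near eigenvalue ties). $X$ is then deflated by $t p^\top$ with
$p = X^\top t/(t^\top t)$, and $Y$ by $t c^\top$.

**The constraint.** oCPLS2-DA inserts one step: after every weight update,
$w$ is replaced by $Qw$, where $Q$ projects onto the null space of
$A_0 = X_{\text{current}}^\top Z$ and is recomputed from the deflated $X$
at every component (deflation changes the forbidden span). The
pseudo-inverse inside $Q$ uses a cutoff of $10^{-12}$ times the largest
singular value of $A_0^\top A_0$, because $Z$ keeps all dummy columns and
is rank-deficient by construction (rank $c-1$ for $c$ levels; no reference
level is dropped, so all levels are treated symmetrically). The result is
that every score satisfies $t^\top Z = 0$ to machine precision: the latent
space carries *no linear information* about the confounder (regressing any
column of $Z$ on the scores gives $R^2 < 10^{-10}$). If the class
direction lies entirely inside the forbidden span, the projected weight
vanishes and the fit aborts with a "class structure confounded with
constraint" error — the honest outcome when class and confounder are not
separable.

An empty constraint reduces the algorithm, bitwise, to plain PLS2-DA: both
run through one code path.

**Alternative estimator.** Pre-projecting $X$ onto the orthocomplement of
$Z$ before an ordinary PLS-DA fit also removes the confounder but strips
confounder-correlated variance from the loadings too; it is a different
estimator. It is available as `projectOutConstraint()` for comparison; the
weight-step constraint is the default.

## Post-transformation

A fitted model with $A$ components spreads class discrimination over all
of them. `postTransform()` rotates the weight matrix by an orthogonal
$G$ derived from the SVD of $M = Y_c^\top T$: right singular vectors with
nonzero singular value (rank of $M$ is at most $N-1$) span the predictive
block, ordered by decreasing singular value; an orthonormal basis of the
null space of $M$ spans the response-orthogonal block, ordered by
decreasing score variance. Weights, loadings, scores and Y-loadings rotate
by the same $G$; because $G$ is orthogonal, the regression coefficients
$B = W(P^\top W)^{-1}C^\top$ — hence all fitted and predicted responses —
are unchanged (verified to $10^{-10}$ in the tests). The $(t_1, t_2)$
predictive scores are the plot-ready coordinates of the usual 2-D score
scatter. The rank of $M$ is decided at $10^{-10}$ times its largest
singular value, separating structural zeros from round-off.

## Validation protocol

* **Full cross-validation.** Every sample is held out exactly once across
  $N$ folds ($N = 6, 7, 8$). Fold assignment is deterministic and
  stratified: samples are sorted by (class, stable index) and dealt
  round-robin (venetian blinds); a seed only shuffles within class.
  $Q^2 = 1 - \mathrm{PRESS}/\mathrm{SS}$, with both terms accumulated over
  held-out samples under training-fold preprocessing and $Y$ centering.
  All preprocessing parameters — the MFC reference profile, centers,
  scales, and the constraint block — are re-estimated inside each training
  fold and applied to the held-out rows, so no information leaks from test
  to train. $Q^2$ is computed directly for the full model (not
  accumulated per component), since the protocol reports a single value
  per model.
* **Permutation test.** Class labels are permuted (the constraint labels
  stay attached to the samples), $Q^2_{7\text{-fold}}$ is recomputed per
  permutation, and $p = (1 + \#\{Q^2_{\text{perm}} \ge
  Q^2_{\text{obs}}\})/(n_{\text{perm}} + 1)$ — the add-one estimator, so
  $p > 0$ always. The protocol default is 400 permutations (200 is the
  usual choice for large model batteries; both are plain arguments).
* **Component selection.** $A$ is the first local maximum of
  $Q^2(A)$ under 7-fold CV, subject to passing the permutation test; if
  the first maximum fails, later maxima are tried, and a model with no
  passing maximum is rejected outright. A strictly increasing $Q^2$
  sequence selects the ceiling with a warning.
* **Reliability rule.** A screened model is flagged reliable only when
  $Q^2_{7\text{-fold}} > 0.5$ *and* the permutation test passes.

## Preprocessing

The LC-MS-style chain is median fold change normalization → natural log
($x \mapsto \ln(x + \varepsilon)$, $\varepsilon = 1$ raw unit by default) →
mean centering. The GC-MS-style chain is internal-standard normalization
(monoterpenes and sesquiterpenes over α-copaene, norisoprenoids over
d3-β-ionone, everything else over d13-hexanol) → autoscaling (sample
standard deviation, $n-1$ denominator). The log base is immaterial after
centering or autoscaling; natural log is used. MFC's reference profile is
the per-feature median over the table's samples. A single MFC pass against
a re-estimated reference is not exactly idempotent (the reference drifts
by estimator noise), so the estimated reference is returned and reused —
renormalizing against the *stored* reference yields factors of exactly 1,
and the cross-validation code normalizes held-out samples against the
training-fold reference for the same reason.

## Split-plot ANOVA screen

Sampling is nested in year (restricted randomization), so the univariate
screen uses a split-plot decomposition: year and replicate are whole-plot
factors tested against the year × replicate whole-plot error stratum, the
producer (vineyard) is the subplot factor tested against the residual. The
model is additive — `y ~ year + replicate + producer` with the whole-plot
error stratum — because those are the three design factors; a
year:producer interaction is available behind a flag but off by default.
Fits go through `stats::aov` with an `Error()` stratum; an independently
coded cell-means oracle in the test suite confirms the SS/MS/F/p values to
$10^{-10}$ on balanced designs. No multiple-testing correction is applied
by default (the screen reports raw significance fractions, with
Benjamini–Hochberg behind a flag).

## The synthetic generator

`confoundedScenario()` emulates the study conditions on the log scale:

$$x = \text{baseline} + \text{stage} + \text{vintage} + \text{macrozone}
      + \text{vineyard} + \mathcal{N}(0, \sigma_\epsilon),$$

exponentiated to positive intensities, with per-sample dilution factors
(log-uniform in $[0.5, 2]$) applied so MFC normalization has real work to
do. Two structural choices matter:

* **Group-coherent effects.** Features belong to chemical-class-like
  groups (8 by default) with per-feature loadings centred at 1. The
  vintage effect and the shared part of the site effect act on group-level
  activities, not independently per feature. This reproduces the
  correlated covariance structure of real metabolomes — climate shifts
  whole compound classes coherently — and it is precisely what makes an
  unconstrained model confound site with season: their variation occupies
  the same feature-space directions. With feature-independent effects, a
  balanced design gives supervised PLS-DA nothing to confound. It also
  makes PCA cluster by vintage, the hallmark of the confounded regime.
* **Nested site effects.** Each macrozone has a shared group-level effect
  plus feature-specific effects, and vineyards draw independent
  feature-specific effects nested within their macrozone, so both the
  macrozone and the vineyard level are learnable.

Default effect sizes (log scale): vintage group-activity sd 1.0, shared
macrozone sd 1/3 (the *strong-vintage* preset fixes vintage = 3 × site),
feature-specific macrozone and vineyard sd 0.1, replicate noise sd 0.4,
monotone per-feature stage trends with sd 0.6 and random sign. Carrier
fractions: 67 % of features respond to vintage, 70 % to site, 60 % to
stage. These were chosen once as a realistic confounded regime — the
per-feature site effect is deliberately *below* the replicate noise, so no
single feature is a strong marker and the class structure is only
recoverable multivariately — and the generator's truth record stores every
drawn effect so recovery tests query the truth rather than re-deriving it.
What the generator does **not** emulate: missing values, chromatographic
drift, heteroscedastic noise, and realistic metabolite correlation
networks beyond the group structure; a pass on synthetic data therefore
validates the algorithms and the protocol, not instrument-specific
robustness.

## Matched-dimension comparison

When the two methods are compared on the confounded scenario, both are
given the same latent budget $A = N - 1 = 2$ — the minimal predictive
dimension for $N$ classes and the dimension in which post-transformed
models are interpreted. At matched dimension the constrained model
classifies held-out samples at ≥ 0.9 accuracy while plain PLS-DA pays a
clear price for the vintage variance in its score space. Given unlimited
components, PLS-DA instead spends 2–3 *extra* components modelling the
vintage and eventually reaches similar accuracy — at the cost of a larger,
less interpretable model whose scores carry substantial vintage
information (score-on-vintage $R^2$ well above 0; the constrained model's
is below $10^{-10}$). Both facets are reported by `compareConfounding()`.

## Worked example

```{r example, eval = FALSE}
library(terroirPLS)

sc <- confoundedScenario("strong_vintage", seed = 1)

## preprocessing: MFC -> log -> center
norm <- medianFoldChangeNormalize(sc$table)
cen <- meanCenter(logTransform(norm$table))
X <- intensities(cen$table)

## constrained fit: macrozone class, vintage constraint
m <- fitOCPLSDA(X, sc$design$macrozone, sc$design$vintage, A = 3)
constraintOrthogonality(m)     # ~1e-16

## rotate to 2 predictive components and extract markers
pt <- postTransform(m, sc$design$macrozone)
pq <- correlationLoadings(pt, X, sc$design$macrozone)
head(extractMarkers(pq, threshold = 0.5))

## full protocol in one call
run <- runTwoLevelAnalysis(sc$table, n_permutations = 199, seed = 1)
run$level1$report
```

## Numerical choices and limitations

* Component signs follow a fixed convention (largest-magnitude weight
  entry positive), so outputs are reproducible across platforms.
* Ties in classification are broken in favour of the earlier class in
  first-appearance order.
* Degenerate inputs fail loudly: single-class responses, single-level
  constraints, components beyond the rank of $X$, zero-variance features
  under autoscaling, folds that lose a class, and confounded class
  structure all raise informative errors rather than returning silently
  wrong results.
* The marker threshold default is 0.5 for screening; 0.75 is the
  conventional "strong correlation" cutoff for single-feature association
  models. Both are plain arguments, as the appropriate value is
  study-specific.
* Multiple simultaneous constraint blocks are supported only by column
  concatenation; continuous-covariate constraints are accepted (any
  centered matrix) but are untested territory.
* Problem sizes in the test suite (a few dozen to 551 features, 63–189
  samples, 19–199 permutations) were chosen to exercise every code path at
  the study's design scale while keeping a full run inside a few minutes.
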