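---
title: "Models and methods behind transectvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind transectvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`transectvar` assesses the methodology of repeated video-transect surveys
of reef fish: how much of the observed variation in counts, diversity and
assemblage structure is attributable to space (islands, locations,
transects), to observers, and to the irreducible sampling variability of
closely repeated passes — and how transect length, number of repeats,
counting metric and data treatment change that balance.  This vignette
explains the models, the synthetic-data generator, and the numerical and
design choices, in that order.

## The survey design and its model

The reference design is balanced and hierarchical: 2 islands, 5 locations
per island, 3 fixed transects per location (50 m long, 5 m strip), each
covered back to back 6 times by each of 3 observers — 18 temporally
ordered passes per transect and 540 observations in total.  Throughout,
Island is a fixed factor; Location (nested in Island), Transect (nested
in Location) and Observer (crossed) are random, together with the
Observer×Location and Observer×Transect interactions.

For a univariate response $y$ (species density, Shannon diversity, or a
single species' count) the mixed model is

$$y = \mu + \text{Island} + u_{L} + u_{T} + u_{O} + u_{OL} + u_{OT} + \varepsilon,$$

with independent Gaussian random effects of variances $\sigma^2_r$ and
residual variance $\sigma^2_\varepsilon$.  The intraclass correlation of
factor $r$ is $ICC_r = \sigma^2_r / (\sum_r \sigma^2_r +
\sigma^2_\varepsilon)$, and the *sampling variability* — counting and
detection errors, observer effects and instantaneous fish displacement,
i.e. everything replication within a transect must average over — is
summarised as $ICC_{Sampling} = ICC_\varepsilon + ICC_{OT} + ICC_{OL}$.
Counts are modelled with zero-inflated COM-Poisson mixed models (log
link): the COM-Poisson pmf $\propto \lambda^y / (y!)^\nu$ covers
underdispersion ($\nu > 1$) as well as overdispersion ($\nu < 1$), which
matters because reef fish assemblages typically contain both schooling
(overdispersed) and territorial (underdispersed) species.

The multivariate analogue partitions a dissimilarity matrix with
PERMANOVA over the same terms plus an Island×Observer interaction, and
expresses each term as a component of variation $\sigma'_r =
\mathrm{sign}(\hat\sigma^2_r)\sqrt{|\hat\sigma^2_r|}$ obtained by
equating mean squares to their expectations.

## The synthetic-data generator

No field data accompany the package, so `simulate_study()` generates
surveys with the structure the models assume, plus the misbehaviours the
diagnostics are meant to detect.  For species $s$ on pass $i$ of transect
$j$ the latent log mean is

$$\eta = \beta_{0,s} + \beta_{I,s} + u_{L} + u_{T} + u_{O} + u_{OL} + u_{OT} + e_{i},$$

where the $u$ terms are Gaussian with the configured variances and
$e_i$ follows a stationary AR(1) along the 18 ordered passes of the
transect (marginal variance $\sigma^2_{residual}$, coefficient
$\rho_s$).  True abundance is COM-Poisson with dispersion $\nu_s$,
rate-parameterized as $\mu^{\nu_s}$ with $\mu = e^\eta$ so that the
latent scale is the log-*mean* scale assumed by the log-link GLMMs (the
rate parameterization with rate $e^\eta$ itself would make the mean
$e^{\eta/\nu_s}$, exploding for overdispersed species).  Structural
zeros are drawn per (species, location); schooling multiplies $\mu$ by a
Gamma($k$, $k$) clump factor (mean 1, `schooling_k = Inf` disables);
detection thins the true count binomially with probability
$d_s (1 - \text{sens}_s \cdot \text{turbidity})$, tilted on the log-odds
scale by $\gamma_s(\text{order} - 9.5)$ so that $\gamma_s < 0$ produces
deterrence and $\gamma_s > 0$ attraction.  Detected individuals are split
into timestamped events with short presence intervals, which makes
MinCount (maximum simultaneous count) genuinely smaller than MaxCount
and supports distance-window splitting from the timestamps.

Defaults were fixed once, as plausible field conditions: latent variance
components (0.30 location, 0.20 transect, 0.01 observer, 0.03
observer×location, 0.08 observer×transect, 0.25 residual) ordered as
location > transect ≫ observer, with observer interactions in between;
base log-abundances $N(0.5, 1.1^2)$ giving a realistic rare-to-common
gradient; one third of species underdispersed ($\nu \in [1.2, 2]$) and
two thirds overdispersed ($\nu \in [0.45, 0.9]$); detectability
$U(0.5, 1)$; 30% of species attracted or deterred with
$|\gamma| \in [0.05, 0.25]$ log-odds per pass (the literature gives no
quantitative effect sizes for attraction/deterrence; these are
order-of-magnitude choices); 40% of species with $\rho \in [0.2, 0.6]$;
20% schooling; pass durations $N(276, 42^2)$ seconds.  Draws are
organised in seed-derived substreams per species (record-level
attributes first), so adding a species never reshuffles earlier draws
and every output is bit-reproducible from the seed.

What the generator does *not* emulate: spatially explicit fish movement,
habitat structure within transects, observer learning over days,
distance-estimation error, or species misidentification.  Passing tests
therefore demonstrate that the estimators recover the structure they
assume and detect the injected violations — not that real surveys meet
those assumptions.

## Core data operations

Detections carry timestamps; assuming constant swim speed within a pass
(the observers' instruction), distance along the transect is
$d = (t_{start}/\text{duration}) \cdot L$.  Windows are closed intervals
and an event is windowed by its *start* time (the moment the fish is
first counted); the canonical five windows on a 50 m transect are
centred: 0–50, 5–45, 10–40, 15–35, 20–30 m.  MaxCount sums event counts;
MinCount is the interval-stabbing maximum (evaluated at event starts,
which is exact for closed intervals).  The logarithm transform is
$\log(1+y)$ because counts contain zeros; Shannon diversity uses the
natural log (base configurable) and is defined as 0 for empty or
single-species rows.  The long-format CSV dialect is one detection per
row with pass-level columns repeated; passes without detections keep one
row with an empty species field so the design round-trips.

## Variance partitioning

**Expected mean squares.** For balanced designs the coefficient of each
variance component in each term's expected mean square is built by the
Cornfield–Tukey rules: component $t$ enters $E[MS_u]$ iff $t$'s
subscripts contain $u$'s and every *live* (non-bracketed) extra
subscript of $t$ is random, with coefficient $N/\text{cells}(t)$ — a
fixed extra subscript contributes a finite-population multiplier of
zero (the restricted convention).  Pseudo-F denominators are solved from
this table; where no single mean square matches (Island and Location in
the full design) a quasi-F linear combination is used, e.g.
$F_{Location} = MS_L / (MS_T + MS_{LO} - MS_{TO})$.

**PERMANOVA.** Sums of squares come from the Gower-centred inner-product
matrix $G = (I - \tfrac{1}{n}J)(-\tfrac{1}{2}D^{(2)})(I - \tfrac{1}{n}J)$
and sequential orthogonal projections onto the term cell spaces (QR of
the cumulative indicator matrices, whose rank increments must equal the
EMS degrees of freedom — this doubles as a balance check).  On a
single-variable Euclidean matrix this reproduces classical ANOVA exactly,
which the tests exploit as an oracle.  Components of variation may be
negative; they are reported signed ($\sigma'$), and the percentage of
variation truncates negative components to zero by default (reproducing
non-negative printed percentages) with the untruncated alternative
available.

**Permutation tests.** P-values use permutation of residuals under a
reduced model (Freedman–Lane): for term $t$ the reduced model drops $t$
*and* every term whose cell space contains $t$ (a nested sub-term would
absorb the tested effect), and $y^* = H_{red}y + P(I - H_{red})y$.  The
permutation $P$ moves whole exchangeable units — the cells of the
coarsest purely-nested positive-weight denominator term (whole transects
when testing Location; rows when the denominator is the residual) —
within strata given by the factors the term is nested in.  Everything is
evaluated directly on $G$ (no per-permutation eigendecomposition), with
$p = (b+1)/(m+1)$; an exhaustive mode enumerates all unit permutations
on small designs, where it matches relabeling enumeration exactly.  For
terms tested by quasi-F no exact permutation strategy exists; the
Freedman–Lane approximation is the accepted compromise.

**GLMM route.** The COM-Poisson mixed models are fitted by Laplace
approximation via `glmmTMB` (family `compois`, mean-parameterized;
the reported $\nu$ is the reciprocal of glmmTMB's dispersion), with an
intercept-only zero-inflation component on the logit scale — no
covariate structure is assumed for the zero part.  Model comparison
across Poisson, NB2 and COM-Poisson uses AIC.  ICCs for GLMMs are
computed on the latent (link) scale from the random-effect variances;
this is the standard convention for variance partitioning with
`glmmTMB`-style output and is a caveat, not an identity, for the data
scale.  The package's own `com_poisson_logpmf()`/`rcompois()` (series
normalization with log-sum-exp, truncation at a relative tolerance of
1e-12, cap of 1e4 terms, CDF-inversion sampling) exist for the generator
and as an independent check; they are deliberately not used in the
fitting path.

## Independence diagnostics

The per-transect ACF uses the full-series mean and denominator (the
biased estimator); constant series are flagged undefined, never reported
as zero, and the mean ACF averages only defined transects.  The
order-effect model is a binomial GLMM with a Gaussian random intercept
per transect, fitted on series with at least one presence; $\beta$ is
tested by Wald z (likelihood-ratio optionally), and complete separation
is flagged rather than reported as a finite estimate.  The partial
Mantel correlogram uses exact integer lag classes 1..17 within transects
only (between-transect pairs carry no temporal order), partials out
transect dummies and observer sharing by linear residualization, and
reports the statistic on the similarity scale so positive lag-1 values
mean adjacent passes resemble each other.  Significance is by restricted
permutation of pass order within transects, one-sided for positive
dependence, Holm-corrected across lags.

## Pooling, precision, multSE

Pooling draws two *disjoint* subsets per level (a shared observation
would bias dissimilarity downward), averages raw counts, transforms
afterwards (fourth root by default; the reverse order is behind a flag),
and histograms Bray–Curtis values in bins of width 0.05 — the histogram
bin width and the disjointness are package choices, as is treating
both-empty pairs as a separate undefined category rather than imputing.

Univariate precision subsamples $k$ of the 18 passes per transect
without replacement (bootstrap behind a flag), computes
$(sd/\sqrt{k})/\text{mean}$, excludes and counts zero-mean draws (the
ratio is undefined there; silent NaN-dropping would bias curves), and
forms 95% intervals from the pooled standard deviation of the
per-transect estimates.  Total swim distance is repeats × length;
turbidity terciles split the rank-ordered transects with stable ties.
The multivariate pseudo standard error is $\sqrt{MS_{residual}/k}$ under
the reduced spatial model (no observer factor); in the balanced design
that residual is exactly the within-transect mean square, so it is
computed directly from pairwise dissimilarities and coincides with
classical ANOVA on Euclidean single-variable data.

## Numerical choices and degenerate inputs

Constant responses return all-zero components; all-zero ICC inputs are
flagged undefined; dissimilarities between two all-zero profiles are NA
and refuse to enter PERMANOVA (they signal the design error the pooling
module quantifies); CAP clips $m$ to the available positive-eigenvalue
axes with a warning and defaults to $m = 8$; PCO reports negative
eigenvalues but excludes them from scores.  Held-out CAP projections use
the standard double-centring of the new point against the training
row/grand means.  Permutation p-values are never 0 by construction.

## Problem sizes

The test suite and acceptance script run on a single CPU in a few
minutes, which the package treats as its reference scale: parameter
recovery uses 150 replicate surveys for the linear mixed models, 6–20
replicate fits for the COM-Poisson models, 100 null replicates for the
order-effect size check, and 10 replicates at 72 observations for the
correlogram power checks; Monte-Carlo loops use 50–400 draws and 99–199
permutations.  The full-study analyses use the complete 540-observation
design.  All of these are configurable upward (the field-scale defaults
are $10^4$ permutations/draws).

## Known limitations

Unbalanced designs are rejected rather than approximated (the
video-analyst factor of unbalanced real surveys is supported only as a
balanced crossed factor on synthetic data); the EMS machinery assumes
every listed term's cells are equireplicated.  Quasi-F permutation
p-values are approximate.  The COM-Poisson mean parameterization is
exact only asymptotically ($\lambda^{1/\nu}$ correction of order
$(\nu-1)/2\nu$).  ICCs for count models live on the latent scale.  The
generator's trait defaults are stylised; analyses of real surveys should
replace them with data.
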