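---
title: "Methods: sigma-profile neural-network modelling of DES viscosity"
author: "desvisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sigma-profile neural-network modelling of DES viscosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desvisc)
```

## The modelling problem

Deep eutectic solvents (DESs) — here always mixtures of the hydrogen-bond
acceptor choline chloride ([Ch]Cl) with a hydrogen-bond donor such as
glycerol, urea or a carboxylic acid — are attractive green solvents whose
main practical drawback is high viscosity. Dilution with a cosolvent
(water, methanol, isopropanol, DMSO) can change viscosity by orders of
magnitude, so a predictive model must handle composition, temperature and
molecular structure jointly.

`desvisc` implements a quantitative structure–property (QSPR) pipeline
that predicts $\log_{10} \eta$ (viscosity in mPa·s) of a DES or
DES + cosolvent mixture from nine inputs: eight molecular descriptors
derived from COSMO-type sigma-profiles, plus temperature in kelvin.
Modelling the logarithm rather than the raw viscosity homogenizes the
error weight between low- and high-viscosity measurements.

## From sigma-profiles to descriptors

A sigma-profile $p(\sigma)A$ tabulates a molecule's COSMO surface area
against the screening charge density $\sigma$, conventionally on 31 points
over $[-0.03, +0.03]$ e/Å² (the package accepts 31–61 points). Profiles
are consumed as plain two-column text files in the open-database dialect;
no quantum-chemistry computation happens in the package.

The profile span is partitioned into eight contiguous regions and the
area under the curve in each region, computed by the trapezoidal rule,
gives the descriptors $S_1 \ldots S_8$. Region edges falling between grid
points are handled by linear interpolation of the area density, so the
eight areas partition the total area exactly (a tested invariant). The
chemical reading runs from the negative end (positively charged,
hydrogen-donating surface) to the positive end: $S_1, S_2$ strong HBD,
$S_3$ weak HBD, $S_4, S_5$ nonpolar, $S_6$ weak HBA, $S_7, S_8$ strong
HBA.

**Design choice — region edges.** The literature this discretization
follows does not fix printable numerical edges, so the package defaults
to eight equal-width intervals of 0.0075 e/Å² over $[-0.03, 0.03]$. This
reproduces the standard grouping above and places the conventional
hydrogen-bonding threshold $|\sigma| \approx 0.0075$–0.0082 e/Å² exactly
at the $S_3/S_4$ and $S_5/S_6$ edges. `region_scheme()` accepts custom
edges; analyses that must match a specific published descriptor table
should supply that table's edges. Units are carried as labels only; no
conversion is attempted.

Mixture descriptors follow the standard molar-weighted mixing rule
$S_i^{mix} = \sum_j x_j S_i^j$. It is linear, hence associative and
permutation-invariant, which the property tests exercise. DES
compositions are written as acceptor:donor molar ratios (e.g. 1:2) with
an optional cosolvent mole fraction; `ratio_to_fractions()` encodes that
convention.

## The network and its trainer

The predictor is a feed-forward network with tanh hidden layers and a
linear output unit, the reference architecture being 9-19-16-1 (527
weights). Inputs and response are min-max scaled to $[-1, 1]$; scaling
the targets as well is the natural companion of tanh hidden units and is
recorded in the model object so either convention is reproducible.
Temperature enters in kelvin, unscaled before the min-max map — no log or
offset transform.

Training minimizes the Bayesian-regularized objective
$F = \beta E_D + \alpha E_W$ ($E_D$ the sum of squared errors on the
scaled targets, $E_W$ the sum of squared weights) with a
Levenberg–Marquardt inner loop on the Gauss–Newton approximation
$H = 2\beta J^\top J + 2\alpha I$. The hyperparameters are re-estimated
each outer iteration through the evidence framework:
$\gamma = N_w - 2\alpha\,\mathrm{tr}(H^{-1})$ (the effective number of
parameters), $\alpha = \gamma / 2E_W$, $\beta = (n-\gamma)/2E_D$. A
near-singular $H$ is ridge-stabilized (a warning is raised), $\gamma$ is
clamped to $[0, N_w]$, and a model that exhausts its iteration budget is
returned with a warning rather than an error. A fixed-penalty variant
(`method = "l2"`) is provided for comparisons; with a vanishing penalty
and no hidden layer it reproduces ordinary least squares, which anchors
the trainer against a closed-form oracle in the tests.

Weight initialization is symmetric uniform scaled by fan-in
($\pm 1/\sqrt{m}$), driven by the mandatory seed; given seed, data and
configuration the whole weight history is bit-reproducible. Defaults:
150 outer iterations, relative objective tolerance $10^{-9}$, initial
damping $5 \times 10^{-3}$ varied by factors of 10.

**Architecture search.** `architecture_search()` retrains one model per
candidate (the full reference grid is 25 single-layer plus $25 \times 25
= 625$ two-layer candidates) and ranks by RMSE on the pooled train + test
records. Because "one of the lowest RMSEs" is not a sharp criterion, the
selection rule is: fewest weights among all candidates within 1%
(configurable) relative RMSE of the best.

## Data handling and splits

Records carry the system identity (acceptor, donor, cosolvent, molar
composition), temperature, viscosity and provenance; validation rejects
non-positive viscosities and mole fractions off by more than $10^{-6}$,
renormalizes smaller discrepancies, and warns outside the
283.15–373.15 K window typical of the experimental databases.

The three-way split mirrors ordered-response external validation: all
records are sorted by $\log_{10}\eta$ and every 9th (starting at the
9th — the natural reading of "one out of every nine"; the phase is
configurable) becomes the *external* test set, about 11% spanning the
whole response range. The remainder is shuffled with a seed and the
training set is sized at 80% *of the total*, leaving roughly 9% as the
internal test set. Whether sorting should be done jointly or per system
is ambiguous in the source methodology; joint sorting is used.

## Validation toolkit

* **Fit statistics** ($R^2$, RMSE, AARD) are computed on
  $\log_{10}\eta$. AARD divides by the experimental $\log_{10}\eta$, which
  is near zero for viscosities around 1 mPa·s; points with
  $|\log_{10}\eta| < 10^{-9}$ are excluded from AARD with a logged count.
  More broadly, AARD on the log scale is denominator-sensitive: a handful
  of records near 1 mPa·s can dominate it even when the absolute errors
  are uniformly small, so RMSE and $R^2$ are the more stable headline
  numbers on synthetic datasets whose response crosses zero.
* **Residual concentration** reports the fraction of residuals inside a
  closed band ($|r| \le 0.05$ by default).
* **Leave-one-system-out CV**: each DES system (at the granularity of the
  dataset's `system_id`, so a water-diluted series is distinct from its
  parent DES) is held out in turn, the model refit, and $R^2$ evaluated
  on the held-out system; $Q^2$ is the unweighted mean (the plain reading
  of "an average of the internal fits"; weighting by system size is a
  defensible alternative). Systems with fewer than two records or a
  constant response are excluded with a warning.
* **Applicability domain** (Williams plot): leverages
  $h_i = v_i (V^\top V)^{-1} v_i^\top$ are computed on the scaled
  9-feature training design without an intercept ($d^* = 9$), matching
  the stated $p \times d^*$ dimensions. The critical leverage uses the
  canonical rule $h^* = 3(d^*+1)/p$, which the source methodology cites
  rather than prints. Standardized residuals divide by the *training*
  residual standard deviation for all splits, so external points are
  judged on the training error scale. A point is inside the domain when
  $h < h^*$ and $|\mathrm{SDR}| < 3$; coverage is the percentage inside
  over all records. A rank-deficient design falls back to the
  pseudo-inverse (leverages then sum to the design rank); an exactly
  zero-residual fit sets all SDR to zero rather than failing.
* **PaD contributions**: exact chain-rule gradients of the output with
  respect to each input (through the scalers and tanh layers) are
  squared, summed over the training records and normalized to percent:
  $C_j = 100 \sum_i g_{ij}^2 / \sum_k \sum_i g_{ik}^2$. Squared-sum
  aggregation is the common convention where the source methodology
  prints no formula; gradients are taken in the scaled space so the
  ranking is invariant to input units, and the normalization runs over
  $S_1 \ldots S_8$ only by default (temperature is a state variable, not
  a structural descriptor), with an option to include it.

## The synthetic-data generator

Real viscosity databases and curated sigma-profile tables are not
redistributed here, so every end-to-end test runs on synthetic data with
the structure the model assumes:

* **Profiles** are sums of 2–4 Gaussian peaks on the 31-point grid: a
  dominant nonpolar band near $\sigma = 0$, a donor-side peak below
  $-0.0075$, an acceptor-side peak above $+0.0075$; the acceptor salt has
  a strong positive-side peak (chloride-like) and cosolvents are the same
  shape at 25–45% of the surface area (small molecules).
* **Viscosities** follow a Vogel–Fulcher–Tammann law
  $\log_{10}\eta = A(S) + B(S)/(T - T_0(S))$ with $A$, $B$, $T_0$ affine
  in the mixture descriptors. VFT keeps the temperature curvature of
  real DES data; coefficients are drawn once per seed, constrained so
  that $B > 0$ (viscosity falls with temperature) with positive
  descriptor loadings (dilution by a low-area cosolvent lowers $B$, hence
  the viscosity), and affinely calibrated so the noise-free viscosities
  span 0.39–4722 mPa·s, the realistic experimental span. The calibrated
  coefficients are returned as ground truth for oracle tests.
* **Noise** is multiplicative lognormal on $\eta$ — Gaussian with
  $\sigma = 0.02$ on $\log_{10}\eta$, the scale the model fits on. The
  0.02 default is of the order of inter-laboratory scatter in viscosity
  compilations.

What the generator does **not** emulate: the strongly uneven record
counts per system of real compilations, correlated (non-i.i.d.)
measurement errors within a temperature series, chemically structured
descriptor correlations, or literature unit mistakes. Passing the
recovery tests therefore demonstrates that the pipeline is correctly
implemented and can recover a smooth descriptor–temperature law at
realistic noise; it does not certify accuracy on any particular
experimental dataset.

## Problem sizes and numerical choices

The test-suite recovery study uses ~1,500 records (8 donors, ratios
1:2/1:3/1:4, two cosolvents at four dilutions, temperatures every 5 K),
the 9-19-16-1 architecture and 150 training iterations — the same order
as the reference experimental study — and checks held-out $R^2 > 0.98$
and AARD $< 5$%. Smaller study sizes (4–8 systems, 3–5 hidden units, 15–120
iterations) are used where the point under test is structural rather
than statistical, and the leave-one-system-out demonstration runs on a
reduced study so that the ~16 refits stay fast. Ties in the
response sort are broken by original record order; the ordered-response
stride starts at the $k$-th sorted record; all tolerances quoted above
(quadrature $10^{-9}$ relative, forward-pass oracle $10^{-12}$, leverage
oracle $10^{-10}$, gradient–finite-difference $10^{-6}$) are regression-tested.

## Known limitations

* AARD on the log scale degrades near $\eta = 1$ mPa·s (see above);
  seed-to-seed spread of synthetic AARD is dominated by how many records
  land near that singularity.
* Bayesian-regularization internals of the historical reference trainer
  are proprietary; this implementation follows the published evidence
  framework, so a published weight table is reproduced by importing it
  (`import_weight_table()`), not by retraining.
* Leverage-based applicability domains measure distance in descriptor
  space only; chemically novel compounds can have unremarkable leverage
  and still be mispredicted.
* The architecture search retrains each candidate once per seed set;
  ranking very similar architectures is therefore seed-noisy at small
  sample sizes, which the 1% simplicity tolerance partly absorbs.
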