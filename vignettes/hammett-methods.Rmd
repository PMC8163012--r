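---
title: "Robust global Hammett regression and additive substituent constants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust global Hammett regression and additive substituent constants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hammettr)
```

## The model

The Hammett linear free-energy relationship separates what a chemical
transformation does from what the substituents on the reactant do. For a
reaction $j$ and a substituent set $s$, hammettr models the response as

$$ y_{s,j} = c_j + \rho_j\,\sigma_s $$

where $y$ is either a decadic log rate constant or an activation energy in
kcal/mol, $\rho_j$ is the reaction constant (susceptibility of reaction $j$
to substituent effects, including temperature and solvent), $\sigma_s$ is the
substituent constant, and $c_j$ is the response of the unsubstituted
(reference) compound in reaction $j$. We keep $c_j$ explicit rather than
folding it into the response normalization so that tables in which the
unsubstituted compound was never measured still fit cleanly.

The bilinear form has a two-parameter gauge freedom: $\rho \to a\rho$,
$\sigma \to \sigma/a$ and $\sigma \to \sigma + e$, $c_j \to c_j - \rho_j e$
leave every prediction unchanged. We pin it by fixing $\rho = 1$ for one
anchor reaction (lexicographically first by default; the choice only sets
the scale, not the fit) and $\sigma = 0$ for the reference substituent set.

With barriers as the response the sign convention inverts relative to rate
constants: under $\rho_j > 0$ a negative $\sigma$ (or per-group $\alpha$,
below) marks an electron-withdrawing group, which stabilizes the negatively
charged transition state of an S$_\mathrm{N}$2 reaction and lowers its
barrier. The package never converts between the two response types; it only
records which one a table carries.

## Reference-free global fitting

The classic sequential recipe (implemented as `original_hammett_fit()` for
comparison) fixes a reference reaction, reads $\sigma$ off its series, and
then alternates between regressing new reactions on the known $\sigma$ set
and extending $\sigma$ with the new reaction's scale. Its outcome depends on
the reference and on the expansion order; with $N_R$ reactions up to $N_R!$
distinct parameter sets exist (`enumeration_bound()`), about $10^8$ for 12
reactions.

`fit_sigma_hammett()` instead estimates everything at once:

1. **Pairwise slopes.** For every reaction pair with at least two common
   substituent sets, the slope of $y_{\cdot,j}$ against $y_{\cdot,i}$
   estimates $\rho_j/\rho_i$. We use the Theil–Sen estimator — the median of
   all pairwise-point slopes — whose ~29% breakdown point buys robustness to
   anomalous series without any outlier labeling.
2. **One global solve.** The log-slopes form an overdetermined system
   $\log\rho_j - \log\rho_i = \log m_{ij}$ over the reaction graph, solved by
   least squares weighted by the pair support (number of common sets), then
   rescaled to the anchor. Every pair informs every $\rho$, so no single
   reference biases the result; a disconnected reaction graph is reported as
   an error naming the components. Slopes are required positive by default
   (true for barrier and rate data alike in the regimes modeled here); a
   sign-propagation mode over a maximum-support spanning tree handles mixed
   signs when explicitly enabled.
3. **Inversion and averaging.** With $\rho$ fixed, offsets and substituent
   constants alternate: $c_j$ as the median over sets of
   $y_{s,j} - \rho_j\sigma_s$ (median for robustness), $\sigma_s$ as the
   unweighted mean over reactions of $(y_{s,j} - c_j)/\rho_j$ (a
   $\rho^2$-weighted mean is available as an option). Each iteration re-pins
   the gauge: the update map is exactly invariant along the gauge orbit, and
   without pinning the median/mean disagreement on noisy data drifts the
   iterates along that orbit indefinitely. Because the median step is
   piecewise constant the iteration can also fall into a tiny period-2
   cycle; updates are damped after 30 iterations and a detected 2-cycle is
   resolved by its midpoint. Stopping: maximum parameter change below
   1e-10, or 200 iterations (then flagged unconverged on the result rather
   than raised, so that noisy-but-useful fits are not aborted).

On noiseless, fully observed synthetic tables this recovers $\rho$,
$\sigma$, $c$ to better than 1e-8 after gauge alignment, and the fit is
invariant to row order and to reaction relabeling (given the anchor).

## Additive decomposition of molecular sigma

For multi-substituted scaffolds, $\sigma_s$ describes the joint effect of
all groups. Three nested decompositions expose individual contributions,
all gauged by a baseline group (default `"H"`) with $\alpha = 0$:

* **Categorical (dummy encoding)** — `fit_categorical()`:
  $\sigma_s = \sum_p \alpha_{g_p(s),p}$, one term per (group, position);
  $N_P N_G$ parameters. Needs no geometry; rank deficiency is reported with
  the unresolvable pairs, never silently regularized.
* **Distance decay** — `fit_distance_decay()`:
  $\sigma_s = \sum_p \alpha_{g_p(s)}\, f(d_p)$ with $f(d) = d^{-\gamma}$
  (power) or $e^{-d/\lambda}$ (exponential); $N_G + 1$ parameters. The decay
  constant is profiled: for a fixed $\gamma$ (or $\lambda$) the alphas are a
  linear least-squares solve, and the constant is optimized from a
  multistart grid $\{0.25, 0.5, 1, 2, 4\}$ (Å scale), refined within a
  physical window $[0.1, 8]$. The window matters: on degenerate small
  samples the profile likelihood can run off to extreme exponents with
  compensating huge alphas. With one position or all-equal distances the
  constant is not identifiable (a pure scale); it is fixed at 1 and flagged.
* **Three-body (Axilrod–Teller–Muto form)** — `fit_atm()`: adds
  $\sum_{p<q}\beta_{\{g_p,g_q\}}\,
  (1 + 3\cos\theta_p\cos\theta_q\cos\theta_C)/(d_{pC}d_{qC}d_{pq})^3$
  over position pairs, with the interior angles of the
  (position, position, reaction-center) triangle; one $\beta$ per unordered
  group pair including same-group pairs, $N_G + (N_G^2+N_G)/2 + 1$
  parameters. Collinear triangles are a geometry error. Since the decay
  model is the three-body model with all $\beta = 0$, the three-body SSE
  never exceeds the decay SSE (up to solver tolerance), and on data
  generated without pair terms the fitted $\beta$ vanish.

A note on parameter counts: `count_parameters()` implements the closed
forms above. Under the same-group-pair convention the cost of adding one
group to the three-body model is $1 + N_G + 1$ (one alpha, one pair with
each old group, the new same-group pair) — the commonly quoted $1 + N_G$
increment and a total of 20 for five groups correspond to dropping the
same-group pair and are internally inconsistent with the closed form; the
package keeps the closed form and documents the discrepancy here.

Decomposition inputs are molecular $\sigma$ values from a prior global fit
(two-stage). `fit_alpha_hammett()` bundles the stages into one predictive
model, $\hat y = c_j + \rho_j \hat\sigma(s)$, which — unlike the plain
global fit — extrapolates to substituent sets never observed. Its `joint`
mode alternates between per-reaction regressions of $y$ on $\hat\sigma$ and
refits of the decomposition against pooled inverted sigmas, initialized
from the two-stage fit where possible and from a neutral gauge otherwise.
Two safeguards make the joint mode usable on very small samples (its main
purpose, e.g. as a delta-ML baseline): per-reaction slopes are partially
pooled toward the consensus $\rho$ with a prior weight of four
pseudo-observations, and reactions absent from a training split predict
with the geometric-mean $\rho$ and mean offset (flagged on the output).

## Machine learning layer

`krr_train()`/`krr_predict()` implement kernel ridge regression,
$(K + \lambda I)a = y$, over one-hot composition encodings: one indicator
block per scaffold position plus reaction-descriptor blocks (nucleophile
and leaving group when reaction ids are splittable, else one reaction-id
block). The representation deliberately carries no Cartesian information so
that the comparison with the categorical Hammett models is information-fair.
The default kernel is Laplacian, $\exp(-\lVert x-x'\rVert_1/w)$, natural
for binary fingerprints; Gaussian is selectable. Hyperparameters come from
an exhaustive k-fold cross-validated grid search (`grid_search_cv()`,
5 folds, seeded shuffle-then-contiguous-split, ties broken toward the
smoother model: larger regularization, then larger width). Default grids:
width $2^{-2}\ldots 2^6$, regularization $10^{-10}\ldots 10^{-2}$ by
decades.

`delta_train()` learns only the residuals of the additive Hammett baseline;
predictions add the baseline back. The residual surface is smoother than
the raw response, so the delta model's learning curve
(`learning_curve()`) starts at a far lower error than plain KRR and the
two meet once the sample is large enough that both are limited by the same
irreducible noise.

## The synthetic world

`generate_hammett_data()` and the presets state a concrete,
fully-ground-truthed world; every fitting stage has an exact recovery test
against it.

* `make_sn2_like()`: a computational S$_\mathrm{N}$2 campaign on a
  two-carbon scaffold. Twelve reactions — every ordered
  nucleophile/leaving-group pair from {H, F, Cl, Br} with distinct members —
  five groups {H, NO2, CN, NH2, CH3} on four positions, R1/R2 at 1.5 Å from
  the reacting carbon and R3/R4 at 2.5 Å on the neighbor carbon, power-law
  decay with $\gamma = 2$. True alphas (kcal/mol, barrier convention):
  NO2 $-3.5$ < CN $-2.5$ < H $0$ < CH3 $+1.0$ < NH2 $+2.2$, i.e. the
  electron-withdrawing order NO2 > CN > H > CH3 > NH2. Reaction constants
  are log-uniform on $[0.5, 2]$ and offsets uniform on $[8, 30]$ kcal/mol,
  which together with the alphas spans barriers of roughly 3–40 kcal/mol.
  Full enumeration gives $5^4 = 625$ substituent sets; sampled subsets
  always include the all-H set, since the unsubstituted compound anchors
  the sigma gauge (an intercept-free additive decomposition cannot absorb
  a gauge shift).
* `make_single_substituent_like()`: experimental-style single-position
  series (log$_{10}$ k response, ~10 groups, no decay), with an optional
  injected anomalous series that is linear in the reaction index — the
  un-physical, non-Arrhenius pattern that shows up at the top of the
  robust fit's residual ranking.

Noise is additive Gaussian; `noise_sd = 0.3` kcal/mol is the scale used in
the robustness and learning-curve studies, commensurate with the numerical
error of the level of theory such campaigns are computed at. Outliers are,
by default, whole substituent-set series (every record of a chosen set
shifted by `outlier_shift` times a random sign): real anomalies are
compound series, and set-level selection keeps the contamination of every
pairwise reaction scatter equal to the nominal fraction. A record-level
mode exists; note that uniformly contaminated records contaminate
$1-(1-f)^2$ of each pairwise scatter, nearly twice the nominal fraction.
Missingness is uniform over (reaction, set) cells with regeneration (up to
10 attempts) if it disconnects the reaction graph.

**What the generator does not emulate:** quantum-chemical energetics (its
magnitudes are phenomenological), resonance effects (substituent constants
here are purely inductive/additive — resonance-capable scales are out of
scope), correlated errors between reactions sharing a nucleophile, and
solvent or steric extensions. A green recovery test therefore establishes
correctness of the estimators under the stated model, not chemical accuracy
on real campaigns.

## Robustness: what the Theil–Sen step does and does not buy

With set-level outliers at fraction $f$, each pairwise scatter has $f$
contaminated points and hence $1-(1-f)^2$ contaminated pairwise slopes —
36% at $f = 0.2$, already past the point where the slope median is
anchored by clean pairs alone. Moreover, when the shift magnitude is
comparable to the per-reaction signal spread, contaminated slopes pile up
near $\pm 1$ and bias the median toward 1, compressing the fitted
$\rho$-ratios; this bias does not vanish with more data. In that regime the
honest statement — and what the tests assert — is relative: the Theil–Sen
pipeline's worst ratio error stays several-fold smaller than an
ordinary-least-squares control's on every seed, but it is not below 5%.
Absolute 5%-level accuracy under contamination requires either a smaller
outlier fraction (scatter contamination below ~29%) or shifts well clear of
the signal range.

## Numerical and design choices

* Substituent-set keys join group labels with `"|"` in position order;
  labels may not contain the separator.
* The rho solve drops the anchor column and solves the support-weighted
  system by QR; the anchor entry is set to exactly 1 afterwards.
* Convergence of the sigma/offset alternation: tolerance 1e-10 on the max
  parameter change, cap 200 iterations, damping 0.5 after iteration 30,
  2-cycle midpoint resolution, gauge pinned every iteration (see above).
* Learning curves hold out a fixed seeded 20% of records; every subsample
  is seeded; failed fits on degenerate subsamples (e.g. a disconnected
  reaction graph for the pure global method) are recorded as missing
  repeats, not errors. "Converged curves" in the acceptance suite means
  the delta-ML/plain-KRR gap at the largest training size is below 5% of
  the error level there — the log-scale reading of learning-curve
  convergence, robust to the deflated repeat variance that a shared
  holdout produces.
* All randomness flows through one seeded, state-restoring RNG helper; no
  function touches the global RNG state.
* Parameter files are JSON at 17 significant digits (exact double round
  trip); tables and geometries are plain CSV; run configuration is YAML
  with flags taking precedence.

## Known limitations

* The alternating sigma/offset refinement is a fixed-point scheme, not a
  joint M-estimator; its median step makes the exact solution
  configuration-dependent at the 1e-3 level on noisy data (well below
  statistical error in all tested regimes).
* The joint additive fit is an alternating least-squares heuristic; with
  pathological tiny samples it can converge to visibly suboptimal baselines
  (bounded by the partial pooling and the decay window, but not guaranteed
  optimal).
* Signed reaction constants are supported only through the spanning-tree
  sign propagation; worlds where many true slopes are near zero will
  defeat it.
* The three-body functional form fixes the classic triple-dipole angular
  shape; it is a modeling choice, not a fitted family.
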