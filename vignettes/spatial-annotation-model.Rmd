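---
title: "Marker-informed spatial annotation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-informed spatial annotation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spanr)
```

## The problem

Spatially resolved transcriptomics (SRT) measures gene expression at known
tissue locations — per spot on barcoded arrays (ST, 10x Visium), per cell on
imaging platforms (osmFISH-like). Assigning each spot or cell to a known
cell or domain type is a first analysis step. Two sources of information are
usually exploited separately: *marker genes* (genes known a priori to be
over-expressed in particular types) and *spatial coherence* (neighbouring
locations tend to share a type). This package implements SPAN, a
probabilistic model that uses both at once: a negative-binomial (NB) mixture
over marker-gene counts, with a hidden Markov random field (HMRF) prior on
the latent label field.

## The mixture model

Let $Y$ be the $N \times G$ raw count matrix restricted to $G$ marker genes,
and $\rho$ the $G \times K$ binary indicator with $\rho_{gk} = 1$ when gene
$g$ marks type $k$. Conditional on spot $i$ having type $z_i = k$,

$$y_{ig} \mid z_i = k \sim \mathrm{NB}(\mu_{igk}, \phi_{igk}), \qquad
\log \mu_{igk} = \log s_i + \delta_{gk}\rho_{gk} + \beta_{g0} +
\textstyle\sum_p \beta_{gp} x_{ip},$$

with $s_i$ a size factor (total marker count over the median total),
$\beta_{g0}$ the base expression of gene $g$, $\delta_{gk} > 0$ the log fold
change a marker contributes in the type it marks, and $x_{ip}$ optional
covariates such as one-hot batch indicators. We use the inverse-dispersion
("size") convention $\mathrm{Var} = \mu + \mu^2/\phi$, following the
CellAssign lineage of count models; this is a fixed convention of the
package, deliberately not configurable, to avoid silent mismatches between
components that would interpret a "dispersion" differently.

The inverse-dispersion is tied to the mean through a radial-basis expansion
$\phi_{igk} = \sum_{j=1}^{B} a_j \exp(-b_j (\mu_{igk} - x_j)^2)$ with $B =
10$ centres fixed on an equal-spaced grid from 0 to the maximum observed
count; only the non-negative amplitudes $a_j$ and widths $b_j$ are learned.
The sum is floored at $10^{-6}$ so the mass function stays defined when a
mean falls far from every centre. Centres are treated as fixed design
points, not parameters: learning them adds little flexibility beyond what
$a, b$ provide and makes the objective multimodal.

Two MAP priors regularise the fit: $\delta_{gk} \sim
\text{log-normal}(\bar\delta = 0, \sigma^2 = 1)$ on marked entries only
($\delta$ is inert where $\rho_{gk} = 0$, so penalising it there would be
meaningless), and a symmetric Dirichlet$(\alpha = 0.01)$ on the mixing
weights $\pi$, initialised uniform at $1/K$. By default the weights *stay*
at that initialisation: estimating $\pi$ jointly with diffuse early
responsibilities creates a rich-get-richer feedback (small $\pi_k$ shrinks
$\gamma_{ik}$, which shrinks $\pi_k$ further) that the sparse
$\alpha < 1$ prior amplifies, and on weakly separated data it can empty a
component entirely. `mixture_control(estimate_pi = TRUE)` restores joint
estimation, implemented by gradient on a softmax reparameterisation with
the weights floored at $10^{-8}$ (the closed-form Dirichlet-MAP update is
ill-defined near the boundary when $\alpha < 1$).

Estimation is EM: the E-step is the exact Bayes posterior over types
(computed in log space with log-sum-exp), the M-step is *partial* — 30 Adam
steps at learning rate 0.01 on the penalised expected complete-data
log-likelihood $Q$, with positivity enforced by reparameterisation
($\delta = e^{\text{raw}}$, $a, b$ via softplus). Initialisation is
moment-based and deterministic: each marker's $\delta_{gk}$ is seeded from
the log ratio of its depth-normalised expression averaged over the top
$N/K$ spots (the expected size of one group) to the average over the rest,
clipped to $[0.1, 3]$, and $\beta_{g0}$ at the log rest-mean. A random
fold-change initialisation was tried first and discarded: on weakly
separated data EM happily converges to self-consistent wrong labelings
seeded by an unlucky draw, whereas the moment seed starts every marker on
the correct side of its own evidence. The M-step keeps the best
iterate visited, so $Q$ never decreases across an M-step even though Adam
itself is not monotone. EM stops when the relative change in $Q$ falls
below $10^{-4}$ or after 50 iterations. This "loose EM" is also the
spatially unaware pretraining stage of the full model; pretraining to full
convergence is unnecessary because the spatial phase re-estimates the same
parameters against hard labels.

## The label field

The latent labels $z$ follow a Potts-like HMRF on a spot neighbourhood
graph: up to normalisation,

$$\log p(z) = \sum_k \eta_k n_k - \sum_{k < l} \zeta_{kl} n_{kl},$$

where $n_k$ counts spots of type $k$, $n_{kl}$ counts neighbour pairs with
discordant types $(k, l)$, $\eta$ are external fields and $\zeta_{kl} > 0$
symmetric interaction penalties. The per-spot conditional depends only on
the neighbour type counts $u_i(l)$:
$\mathrm{logit}_k = \eta_k - \sum_{l \neq k} \zeta_{kl} u_i(l)$.

$\Phi = \{\eta, \zeta\}$ is estimated by maximum pseudolikelihood (the
product of per-spot conditionals), by 50 Adam steps at rate 0.01. Three
numerical choices matter here:

* **Identifiability.** The conditionals are invariant to shifting all
  $\eta_k$ by a constant, so $\eta_1 \equiv 0$.
* **Degeneracy.** On a perfectly smooth labelling the pseudolikelihood is
  strictly increasing in $\zeta$, which would diverge. A small ridge penalty
  ($10^{-3}$ on the raw parameters) plus a hard cap $\zeta_{\max} = 20$
  keeps the optimisation stable while preserving effectively infinite
  smoothing — at $\zeta = 20$ a single discordant neighbour already
  outweighs any realistic likelihood difference.
* **Symmetry.** $\zeta$ is parameterised by its upper triangle through a
  softplus, mirrored down, so symmetry and positivity hold after every
  optimiser step by construction.

## The integrated procedure

1. Pretrain the mixture (EM as above); initialise $z^{(0)}$ at the
   responsibility argmax.
2. Iterate: (a) update the mixture parameters by Adam on the conditional
   likelihood of the current hard labels (same MAP priors, mixing weights
   frozen — the final model has no $\pi$ term); (b) re-estimate
   $\Phi$ by pseudolikelihood; (c) run one ICM sweep, visiting spots in
   ascending index order and setting each to the type maximising
   data log-likelihood plus spatial conditional given the neighbours'
   *current* labels.
3. Stop when at most 0.1% of labels changed in a sweep, or after 20
   iterations.

Sequential (rather than synchronous) ICM updates were chosen because they
guarantee each accepted label weakly increases its local objective, which
makes the sweep's behaviour testable spot by spot and avoids the
oscillations synchronous updates can produce on bipartite-ish grids. Ties
go to the smallest type index. The per-spot softmax scores of the final
sweep are reported as a posterior for downstream use; they condition on the
final neighbour labels, so they are a local approximation, not a joint
posterior. If a type empties out during ICM it is kept (its parameters
remain anchored by the marker prior) and a warning is raised; re-seeding
clusters mid-run would break determinism and the monotone-sweep contract.

The whole fit is a deterministic function of the data and one integer seed,
which controls only parameter initialisation (the fold-change draws).

## The synthetic-data generator

The simulator emulates the group-structured count generator of the Splatter
family, reduced to the features the model exercises: gene base means
$\lambda_g \sim \Gamma(0.6, 0.3)$; per group, a `de_prob = 0.1` fraction of
genes receives a log-normal DE factor $f_{gk} = e^{N(0, \sigma^2)}$; spot
library sizes $L_i \sim \text{logN}(\log 2000, 0.35)$; expected counts
$L_i\,\lambda_g f_{g z_i} / \sum_g \lambda_g f_{g z_i}$; counts NB with
inverse-dispersion 2. BCV trends, dropout and trajectory paths are omitted
— they are features of real platforms the model does not model either, so
the tests say nothing about them. Markers are the genes with $f_{gk} > 1.5$
(strict), mirroring common DE-based marker derivation; `sigma` is the
difficulty dial, with $\sigma \in [0.2, 0.6]$ spanning hard to easy
regimes.

Types are laid out as contiguous horizontal bands on a near-square grid,
emulating layered cortical tissue. Three perturbations reproduce common
real-data pathologies: *spatial noise* (disjoint cross-group spot pairs
swap expression and labels in place, roughening the map while conserving
composition), *marker corruption* (replacing markers with randomly-typed
non-DE genes, or moving markers to a wrong type), and *batch effects*
(per-batch per-gene log-normal factors applied to the means, with batch
identity exported as a one-hot covariate).

What passing on these data does **not** show: robustness to zero inflation,
segmentation errors, spot-level cell-type mixtures (deconvolution is out of
scope), or non-layered spatial geometries beyond what the spatial-noise
scenario probes.

## Problem sizes used in the checks

The package's end-to-end checks run at a deliberate desk scale: 900 spots
on a 30×30 banded grid with K = 4 types. Label/fold-change recovery uses
1000 simulated genes at $\sigma = 0.5$, which yields a marker panel of
roughly 80 genes at the 1.5 threshold. The spatial-noise check uses 2500
genes at $\sigma = 0.3$ — the moderate-signal regime with around 20 markers
per type, where spatial information has visible value. The marker-corruption
check runs at $\sigma = 0.25$: corrupting markers must have measurable
cost for the experiment to mean anything, and at $\sigma = 0.3$ the model
is robust enough that a 10% fake-marker rate leaves accuracy at its
ceiling, while much below $\sigma = 0.25$ the derived panels get so small
that some spots have zero marker counts altogether (an invalid model
input). Ten seeds per scenario give stable success counts without
excessive runtime.

## Known limitations

* Types absent from the marker table cannot be discovered; every spot is
  forced into one of the K given types.
* First-order neighbourhoods only; no second-order or longer-range
  interactions.
* The ICM phase finds a local optimum of a non-convex objective; a poor
  pretraining fit on very weak signal (few markers, small N) can collapse a
  cluster, which the fit reports via a warning rather than repairing
  silently.
* Label matching for anonymous-cluster baselines is exact only up to 9
  classes (exhaustive assignment enumeration).
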