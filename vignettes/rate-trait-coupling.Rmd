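---
title: "Linking substitution rate categories to trait variance on a phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking substitution rate categories to trait variance on a phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`cnelink` asks, for one conserved non-coding element (CNE) at a time,
whether lineages in which the element's nucleotide substitution rate has
shifted are also lineages in which a continuous trait evolves at a
different rate. Both signals are tied to a single latent *conservation
state* per branch, taking values background (1), conserved (2), or
accelerated (3).

**State process.** States evolve root-to-tips along the tree as a Markov
chain with transition matrix

$$\Phi = \begin{pmatrix} 1-c & c & 0\\ 0 & 1-a & a\\ 0 & b & 1-b \end{pmatrix},$$

with $(a, b, c) \in (0,1)^3$. The structural zeros encode the biology of
ascertained CNEs: an element seen to be broadly conserved does not return
to the background regime, and cannot jump from background straight to
accelerated; because $b > 0$, a burst of acceleration on an internal
branch may revert to conservation. The root state prior is $(0.5, 0.5, 0)$
— candidate elements were ascertained as conserved somewhere, so the root
is either background or conserved, never accelerated.

**Sequence.** Given a neutral rate matrix $Q$ (with stationary
distribution $\pi$, both estimated elsewhere, e.g. from fourfold
degenerate sites, and supplied as input), a branch of length $t_j$ in
state $z_j$ transmits each alignment column independently with transition
matrix $e^{Q r_{z_j} t_j}$, where $r = (1, r_2, r_3)$ are the per-state
rate multipliers. Gaps, `N`, and IUPAC ambiguity codes are treated as
missing data (an ambiguity code carries little information at these
scales and a uniform missing treatment keeps the emission contract
simple).

**Trait.** The trait follows Brownian motion with branch-specific
variance: $y_j \mid y_{pa(j)} \sim \mathrm{Normal}(y_{pa(j)},\,
t_j v_{z_j})$ with per-state variance multipliers $v = (\sigma^2,
\beta_2\sigma^2, \beta_3\sigma^2)$. The parameter of scientific interest
is $\log(\beta_3/\beta_2)$: positive values mean faster sequence
evolution coincides with faster trait evolution, negative values the
opposite. The ratio rather than $\beta_2$ or $\beta_3$ alone is reported
because roughly half the nodes of a tree are unobserved and paths may mix
hidden stretches of either regime, so only the contrast is well
identified.

**Priors.** $r_2 \sim \mathrm{Gamma}(\text{shape }5, \text{scale }0.04)$
(mean 0.2), $r_3 \sim \mathrm{Gamma}(10, 0.2)$ (mean 2);
$\log\sigma^2 \sim \mathrm{N}(0, 2)$, $\log\beta_2, \log\beta_3 \sim
\mathrm{N}(0, 1)$ (second arguments are variances throughout, so
$\log(\beta_3/\beta_2) \sim \mathrm{N}(0,2)$ a priori); $a, b, c \sim
\mathrm{Beta}(1,1)$; root trait $\sim \mathrm{N}(0,1)$. All are
configurable through `model_priors()`.

# Inference

One Gibbs sweep executes five steps in order:

1. **Trait block** — 500 inner Metropolis iterations; each is, with
   probability 0.6, a Gaussian random walk on one of $\log\sigma^2$,
   $\log\beta_2$, $\log\beta_3$ (chosen uniformly), otherwise a random
   walk on one uniformly chosen latent trait value (ancestral nodes and
   any leaf without an observed trait — such leaves are treated exactly
   like internal nodes, the natural marginalization).
2. **Ancestral nucleotides** — the pruning recursion computes per-node,
   per-site partial likelihoods given the current states, then root
   sites are drawn $\propto \pi_x \cdot \text{partial}$ and interior
   sites root-to-tips from their exact conditionals. Missing leaf cells
   are imputed in the same pass.
3. **Conservation states** — a tips-to-root pass accumulates, for each
   branch and candidate state, the log joint of sequence and trait
   emissions below it (log-sum-exp over children through $\Phi$),
   then states are drawn root-to-tips from the exact joint conditional.
   Root nucleotide and trait terms do not depend on the root state and
   cancel from its conditional.
4. **Rate multipliers** — one log-scale Gaussian random-walk Metropolis
   step each for $r_2$ and $r_3$, scored against the fully imputed
   alignment (per-edge nucleotide transition counts make this a 16-term
   dot product per edge) plus the Gamma priors.
5. **Transition parameters** — the Beta(1,1) priors on $a$, $b$, $c$ are
   conjugate to the observed parent-child state transition counts, so
   these are exact Beta draws.

## Numerical choices

* Pruning runs in linear space with per-node, per-site rescaling by the
  maximum partial; scale logs accumulate so likelihoods of hundreds of
  sites on 100+ taxon trees cannot underflow.
* Branch transition matrices are computed from a one-time
  eigendecomposition of $Q$ (validated at build time against a
  scaling-and-squaring matrix exponential, with automatic fallback if
  $Q$ is defective); matrices are cached per (branch, state) and
  invalidated only when $r_2$ or $r_3$ changes.
* Tiny negative entries from the eigendecomposition are clamped to zero
  and rows renormalized; log-transition matrices are floored at
  `1e-300`.
* Zero-length branches are rejected at parse time rather than clamped:
  the branch trait variance $t\,v$ degenerates at $t = 0$, so users must
  pre-collapse zero branches.
* Proposal scales (the model itself is silent on them) default to s.d.
  0.3 on all log-parameter walks and, for latent trait values,
  $0.5\sqrt{\tilde t\,\sigma^2}$ with $\tilde t$ the median branch
  length — a walk tied to the model's own diffusion scale. The 60/40
  split in Step 1 is an independent Bernoulli coin per inner iteration,
  and one parameter or one latent node moves per iteration, keeping
  acceptance ratios simple.

## Chains, convergence, ranking

`run_chains()` runs (by default) 3 chains of 10,000 sweeps from
overdispersed starts — each chain initializes its parameters from
independent prior draws and its states from a fresh simulation under the
drawn $\Phi$ — discards the first half, and computes split-chain
Gelman-Rubin statistics for all monitored scalars (the classic statistic
drives the convergence flag at threshold 1.01; a rank-normalized variant
is reported alongside for robustness). Burn-in fraction, thinning and
initialization are explicit configuration with these defaults.

Element ranking uses the Savage-Dickey density ratio: the null model
($\beta_2 = \beta_3 = 1$) is nested at $(\log\beta_2, \log\beta_3) =
(0,0)$, so the Bayes factor in favour of the full model is the prior
density at the origin — exactly $1/(2\pi)$ — divided by the posterior
density there, estimated by a bivariate Gaussian product-kernel KDE with
Scott's bandwidth over samples pooled across chains (pooling maximizes
effective sample size once the convergence screen passes). Reported
labels are "very strong" at BF ≥ 30 and "overwhelming" at BF ≥ 100,
boundaries inclusive. In ranked output, non-converged elements are
excluded to a side table by default; in simulation studies the
false-positive rate is likewise computed among replicates passing the
screen, with failures tallied separately.

# The simulator

`sim_z()`, `sim_X()` and `sim_y()` generate states, alignments and traits
from the generative model itself; `sim_study_replicate()` composes them.
In prior mode every parameter is drawn from the priors above (whether the
transition probabilities should also be drawn was an open choice; the
default draws them, and any parameter can be fixed through
`sim_config()`). False-positive scenarios fix $\beta_2 = \beta_3 = 1$ and
bypass the state process for the sequence, applying one uniform rate
multiplier to every branch — 1 (neutral), 0.2 (conserved, the prior mean
of $r_2$), or 0.5 (barely conserved); the trait is then plain Brownian
motion with a prior-drawn $\sigma^2$, or can be fixed to a supplied
vector as in mammal-tree scenarios. Generating truth (states, ancestral
sequences and traits, parameters) is always returned alongside the leaf
data.

What the simulator deliberately does *not* emulate: indels and alignment
error, rate variation across sites, non-Brownian trait dynamics
(Ornstein-Uhlenbeck or Lévy-type jumps), and misspecification of the
neutral model. Passing calibration studies therefore demonstrates
correctness of the inference machinery under the model's own assumptions,
not robustness of the model on real data.

# Calibration studies and problem sizes

The package's central validation is simulate-then-infer calibration on a
fully bifurcating ultrametric tree with 128 tips and all branch lengths
0.1 (root-to-tip 0.7, comparable to deep mammalian divergences), with
80 bp elements — the median mammalian CNE length. Over prior-drawn
replicates, the mean squared error of the posterior median of
$\log(\beta_3/\beta_2)$ and the empirical coverage of the 80% credible
interval are the calibration measures, computed over *all* replicates
(the recovery study measures the estimator as a whole); over null
replicates ($\beta_2 = \beta_3 = 1$), the false-positive rate at
Bayes-factor cutoffs, computed among replicates passing the convergence
screen (mirroring how a real ranking would treat non-converged fits). The background substitution model for these studies is the
bundled GTR model (`neutral_model_gtr()`: unequal frequencies and
transition bias, a more generic stand-in for a mammalian neutral model
than Jukes-Cantor).

The shipped test suite and the acceptance script run these studies at
30 prior replicates (2 chains of 2,500 sweeps per fit) and 50 null
replicates per scenario (2 chains of 4,000 sweeps; null fits lean harder
on the convergence screen and on Bayes-factor stability). The chains mix
quickly on 80 bp elements, and the calibration aggregates are stable well
before the default 3 × 10,000 protocol that a real analysis would use. These sizes are the package's
own choice of demonstration scale; rerunning with `run_config()` defaults
reproduces the full protocol.

The prior-recovery check uses an element with every alignment cell
missing and no observed traits, under which the posterior provably equals
the prior: marginal Kolmogorov-Smirnov checks on heavily thinned draws of
all eight parameters then validate every sampler component jointly. A
"getting-it-right" successive-conditional test (alternating one sampler
sweep with a redraw of the data given the current parameters and latents)
guards the same invariance from a second direction.

# Known limitations

* Branch lengths do not inform the state process: $\Phi$ applies per
  edge regardless of edge length, so long branches are not more likely
  to switch state.
* $\beta_2$ and $\beta_3$ are only weakly identified individually;
  inference should focus on their ratio.
* The "barely conserved" regime ($r \approx 0.5$) conflates $r_2$ and
  $r_3$ and mixes poorly — reflected in elevated Bayes-factor cutoffs
  needed to control false positives there.
* Very short elements (tens of bp) on small trees carry little
  information about state placement; the convergence screen exists
  precisely to flag such fits.
* One rate per branch and site-independence are assumed for the
  sequence process; no indel model.
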