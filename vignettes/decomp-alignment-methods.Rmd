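---
title: "Reward-ranked alignment of a decomposed diffusion model: methods and design"
author: "DecompAlign authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-ranked alignment of a decomposed diffusion model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DecompAlign)
```

## The problem

Structure-based drug design (SBDD) conditions a generative model on a
protein binding pocket $P = \{(x_i^P, v_i^P)\}$ and asks it for ligands
$M = \{(x_i^M, v_i^M, b_{ij}^M)\}$ — atoms with 3D coordinates
$x \in \mathbb{R}^3$, types $v$ over a small element vocabulary, and
bonds $b$ over five categories (non-bonded, single, double, triple,
aromatic) — that bind the pocket and are drug-like. Models trained by
likelihood alone drift from what a medicinal chemist wants, so this
package implements a *post hoc alignment* cycle: generate $K$ candidates
per target, score them with a multi-objective reward, keep the best,
repair its geometry relative to the pocket, and fine-tune the generator
on the curated winners. The same reward also drives pure inference-time
*Best-of-N* selection, which skips fine-tuning entirely.

Everything runs at desk scale against a synthetic toy world, so the
machinery — ranking, relocation, decomposition, diffusion, fine-tuning,
evaluation — is exercised end-to-end without external datasets, trained
checkpoints or a docking installation.

## The multi-objective reward

Each candidate is scored on three axes:

* **QED** (quantitative estimate of drug-likeness), already in $[0,1]$;
* **SA** (synthetic accessibility), raw scale 1 (easy) to 10 (hard),
  normalized here as $(10 - s)/9$ so that higher is better — the
  convention of the SBDD benchmarking literature;
* **docking score**, lower better, min–max normalized *within the
  $K$ candidates of one target* and inverted:
  $d_i \mapsto (\max d - d_i)/(\max d - \min d)$, so the best candidate
  of a cohort gets 1 and the worst 0. A flat cohort maps to 0.5
  everywhere, which keeps it rankable by the other two objectives
  without dividing by zero.

The reward is the weighted sum
$r = w_\mathrm{QED}\,\mathrm{QED} + w_\mathrm{SA}\,\mathrm{SA_{norm}} +
w_\mathrm{dock}\,\mathrm{dock_{norm}}$ with non-negative tunable
weights. The package default is $(1, 0, 0)$: aligning on drug-likeness
alone was the best-performing configuration in the study this design
follows, and it makes the desk-scale alignment experiment directly
interpretable (the reward *is* QED).

A molecule counts toward the **success rate** when
$\mathrm{QED} > 0.25$, $\mathrm{SA_{norm}} > 0.59$ and docking score
$< -8.18$, all inequalities strict.

### Native QED and SA

No R package in this stack provides QED or SA, so both are implemented
natively on the package's own molecular graph:

* `computeQED()` combines eight descriptors (MW, Crippen ALOGP, HBA,
  HBD, TPSA, rotatable bonds, aromatic rings, structural alerts)
  through the published asymmetric-double-sigmoid desirability
  functions and mean-optimal weights. The descriptor layer is a
  faithful subset of the published definitions for H/C/N/O/S and
  halogens; on fixture drugs whose descriptors coincide with the
  reference implementation the final QED agrees to $10^{-6}$
  (benzene, ethane, ibuprofen), while molecules exercising the
  differing corner definitions (rotatable-bond strictness, acceptor
  SMARTS, the alert catalogue) agree to better than 0.17 with rank
  order preserved.
* `computeSARaw()` is a calibrated complexity estimator on the 1–10
  scale built from ring count and fusion, macrocycles, heteroatom
  load, sp3 branching, stereo-prone centres and size. The
  fragment-frequency database of the classic contribution method is a
  large binary artifact that cannot be shipped as text, so these
  closed-form terms stand in for it; the calibration places simple
  drug-like molecules in the 1–3 band and correlates with the
  reference scores on the fixture drugs.

Because relocation (below) is a rigid translation, QED and SA are
identical whether computed on the as-generated or the relocated ligand;
the question of which the reward "should" use is therefore moot here.

## Best-of-K curation and data preparation

For each target the pipeline generates $K = 10$ candidates, drops
samples that fail reconstruction-style validity (connected graph, at
least two heavy atoms, resolvable valences), scores the survivors and
keeps the reward argmax (ties break to the lowest index, making
curation deterministic). Targets with no valid candidate are skipped
and logged, never fatal.

Generated ligands frequently sit away from the pocket, which breaks
any machinery that extracts pocket-proximal substructure. Two repairs
are applied to each winner:

1. **Center-of-mass relocation**: the docking pose is stripped of
   non-heavy atoms (read: hydrogens — the only sub-carbon element in
   scope), and the ligand is rigidly translated so its center of mass
   lands on the cleaned pose's center of mass. True mass weighting is
   the default; an unweighted-centroid mode exists behind a flag since
   "center of mass" is used loosely in parts of the field. Relocation
   preserves every internal distance and is idempotent.
2. **Adaptive arm/scaffold decomposition**: the ligand graph is cut at
   acyclic single bonds that join ring systems, or join a ring system
   to a chain of at least two atoms. A fragment becomes an *arm* when
   one of its atoms lies within `cutoff` of a pocket atom while lying
   within `radius` of the fragment's own centroid; all remaining
   fragments together form the single (possibly empty) *scaffold* set.
   If no fragment qualifies, both thresholds are relaxed jointly by
   their step sizes and the test retried, at most `maxRelaxations`
   times; if that still fails, the whole ligand becomes one arm. The
   defaults (cutoff 4 Å, radius 6 Å, steps 0.5 Å, 8 relaxations) are
   chosen so that ligands seated in the toy pocket decompose without
   relaxation and ligands a few Å off need one or two rounds. This
   decomposition is a documented simplification: the full-scale
   pipeline adjusts the equivalent thresholds of an external
   sub-pocket tool whose internals are proprietary to that tool; only
   the graph-cut-plus-proximity rule is specified here. Joint
   relaxation of both parameters (rather than one at a time) is this
   package's choice, flagged as such.

The curated records — relocated winner, pocket, decomposition, priors —
form the fine-tuning batch $\mathcal{B}$ of size $b \le B$ (default
$B = 128$; $b$ is simply the number of successfully curated targets).

## The decomposed diffusion model

Fragments carry data-dependent priors $O_P = \{\mu_{1:K}, \Sigma_{1:K},
H\}$: per-fragment position mean and covariance estimated by maximum
likelihood from the member atoms ($\Sigma$ regularized by
$10^{-3}\,\mathring{A}^2\, I$, so single-atom fragments remain
non-degenerate), and the atom-to-fragment assignment $H$. Positions are
shifted to the prior-centered frame $\tilde{x}_i = x_i -
\mu_{\mathrm{frag}(i)}$ before diffusing; the shift is exactly
invertible.

### Forward processes

With schedule $\{\lambda_t\}$, $\alpha_t = 1 - \lambda_t$,
$\bar\alpha_t = \prod_{s \le t}\alpha_s$:

* **Positions** support two conditional kernels, selected by a mode
  flag. The `"ddpm"` default applies mean shrinkage,
  $\tilde{x}_t \mid \tilde{x}_{t-1} \sim \mathcal{N}(\sqrt{\alpha_t}\,
  \tilde{x}_{t-1}, \lambda_t \Sigma)$, giving the marginal
  $\mathcal{N}(\sqrt{\bar\alpha_t}\,\tilde{x}_0, (1-\bar\alpha_t)\Sigma)$
  — the form the $\bar\alpha$ bookkeeping implies. The `"as-printed"`
  mode omits the shrinkage,
  $\tilde{x}_t \mid \tilde{x}_{t-1} \sim \mathcal{N}(\tilde{x}_{t-1},
  \lambda_t \Sigma)$, with marginal variance $\sum_{s\le t}\lambda_s\,
  \Sigma$. Both are implemented and tested against their analytic
  marginals; which one a source formula "means" when it defines
  $\bar\alpha$ but writes the kernel without $\sqrt{\alpha_t}$ is left
  undecided.
* **Categories** (atom types over $K_a$ elements, bond types over
  $K_b = 5$) mix with the uniform distribution:
  $p_t = (1-\lambda_t)p_{t-1} + \lambda_t/K$, closed form
  $p_t = \bar\alpha_t p_0 + (1-\bar\alpha_t)/K$. The reverse-time
  posterior is the standard uniform-noise discrete-diffusion
  coefficient,
  $c(p_t, p_0) \propto (\alpha_t p_t + (1-\alpha_t)/K) \odot
  (\bar\alpha_{t-1} p_0 + (1-\bar\alpha_{t-1})/K)$, verified against
  exhaustive Bayes for $K \le 5$.

**Schedule.** The default is a linear ramp over $T = 100$ steps with
endpoints $0.001$ to $0.2$, which drives $\bar\alpha_T$ to about
$5\times10^{-5}$. A generative schedule must essentially destroy the
signal by $t = T$, otherwise sampling "from noise" starts from the
wrong distribution; the classic $10^{-4}$–$0.02$ endpoints accomplish
that only over 1000 steps and would retain 37% of the signal at desk
scale, so the endpoints are rescaled rather than the step count
inflated. Both endpoints and $T$ are configurable.

### Losses

At a uniformly drawn $t$ the model predicts $(\hat{x}_0, \hat{v}_0,
\hat{b}_0)$ from the noisy state and the loss is

$$L_t = \underbrace{\lVert x_0 - \hat{x}_0\rVert^2}_{L_t(x)} +
\gamma_v \underbrace{\mathrm{KL}\!\left(c(v_t, v_0)\,\|\,c(v_t,
\hat{v}_0)\right)}_{L_t(v)} + \gamma_b \underbrace{\mathrm{KL}\!\left(
c(b_t, b_0)\,\|\,c(b_t, \hat{b}_0)\right)}_{L_t(b)},$$

summed over atoms and atom pairs (summation rather than averaging is a
package choice; the loss weights default to $\gamma_v = \gamma_b = 100$,
the convention of decomposed-diffusion training at full scale). All
terms are non-negative and vanish exactly at a perfect prediction.

### The desk-scale denoiser

The denoiser behind the prediction contract is deliberately small — a
distance-featurized predictor with ~40 parameters, not an equivariant
GNN, and no architectural fidelity to any published network is claimed.
Its heads:

* position: $\hat{x}_0 = g(t)\,\tilde{x}_t + h\,m(x_t)$ with gain
  $g(t) = w_0 + w_1\sqrt{\bar\alpha_t} + w_2\bar\alpha_t$ and a
  fixed-strength geometric relaxation message $m$: each atom is nudged
  toward its (up to) three nearest neighbours with a restoring force at
  the 1.5 Å reference bond length and softly repelled from
  second-neighbour-range crowding, so relaxed point sets arrange into
  chains and rings rather than close-packed blobs.
* atom types: per-atom softmax over log of the noisy type state, a
  global composition bias, and a pocket-proximity feature (polar
  elements preferentially face the pocket surface).
* bond types: per-pair softmax over log of the noisy bond state, a
  category bias, and two radial-basis distance features (a covalent
  window near 1.45 Å and a mid-range window near 2.5 Å).

Two further design points matter in practice. First, the geometric
features of both categorical heads (pair distances, pocket proximity)
are computed from the model's *own denoised positions* with gradients
stopped, not from the raw noisy positions: training states carry
noise-inflated distances, and a head trained on those would
systematically over-predict bonds at stretched separations when the
sampler later feeds it clean geometry. Second, every categorical head
weight that must behave differently at clean and corrupted states —
the trust placed in the noisy category state ($a_v$, $a_b$) and the
bias calibration — carries a companion weight on the noise-level
feature $1-\sqrt{\bar\alpha_t}$, so that marginal calibration at
heavily corrupted states lands in the time-dependent terms instead of
leaking into the head's behaviour near $t = 0$. Without this, a
fine-tuned static trust weight locks the ancestral chain onto its
random initial categories during generation.

A fresh model is seeded to play the role of the *pre-trained
checkpoint* the full-scale alignment method starts from: the atom head
follows the toy grammar's element composition, the bond head encodes
the geometric bond prior, and the position gain is the identity-style
$\sqrt{\bar\alpha_t}$. The relaxation strength $h$ is excluded from
fine-tuning by default: it is an architectural constant of the sampler,
and the single-step reconstruction objective would otherwise train it
away even though generation quality depends on it (the two objectives
genuinely pull in opposite directions for this term).

Gradients of all trainable parameters are analytic (chain rule through
the posterior and softmax) and are verified against central finite
differences in the test-suite.

### Sampling

Generation runs the reverse chain $t = T..1$ from prior noise
(positions $\mathcal{N}(0, \Sigma_{\mathrm{frag}})$ in the shifted
frame, categories uniform): positions follow the stochastic reverse
kernel of the chosen mode, categories are sampled ancestrally from the
posterior at the model's prediction, and the final state is discretized
by argmax, dropping non-bonded pairs and un-shifting by the priors.
Outputs may fail chemical validity — that is a legal outcome, filtered
downstream exactly like reconstruction failures at full scale; only a
fraction of fresh-model draws pass the filter, which is why every
evaluation reports the valid count alongside the raw draw count.
Untrained-sample clouds centre on the fragment priors (a property the
test-suite checks directly).

### Fine-tuning

`finetuneDenoiser()` runs plain SGD on $\mathbb{E}_t[L_t]$ over the
curated batch (records cycled, $t$ uniform per step). The conservative
full-scale regime (learning rate $10^{-6}$, 1000 iterations) is the
default; the desk-scale experiments use $10^{-3}$ and 2000 iterations,
which the ~30-parameter model needs to move appreciably. One caveat
documented rather than hidden: with a handful of parameters the model
cannot memorize a record the way a multi-million-parameter network can,
so the single-record overfit experiment reduces the evaluation loss
several-fold (to its conditional-mean floor) rather than by orders of
magnitude; the test asserts a three-fold reduction.

## Best-of-N

`bestOfN()` draws $N$ candidates, filters invalid ones, scores the
valid cohort (docking normalization over those $N$ valid draws,
mirroring the per-cohort convention) and returns the reward argmax
without touching model state. Summaries over BoN winners are computed
winners-only — the statistics the strategy is judged by — with the
all-samples summary alongside for contrast. For a fixed reward
distribution $\mathbb{E}[\max\text{ of }N]$ is non-decreasing in $N$;
the test-suite verifies the trend over $N \in \{1, 5, 10, 20\}$ with
200 Monte-Carlo repetitions and a one-sided one-standard-error
tolerance.

## Evaluation metrics

* `summarizeMetrics()`: per-metric means and medians, plus the success
  rate with the *valid-molecule* denominator (the raw generation count
  is carried alongside; whether reconstruction failures belong in the
  denominator is ambiguous at full scale, so the choice is explicit
  here).
* `accumulatedScore()`: the equal-weight summary
  $\mathrm{QED} + \mathrm{SA} + \mathrm{Vina}/(-10)$, the docking score
  divided by $-10$ so typical affinities land in $[0, 1]$. Values are
  kept unrounded internally and conventionally printed at 3 decimals.
* `bondDistanceJSD()`: Jensen–Shannon divergence between bond-length
  distributions of a generated and a reference set for one bond query
  (element pair unordered, one bond category). Lengths are histogrammed
  on fixed 0.02 Å bins over [0.8, 3.0] Å with out-of-range values
  clipped to the edge bins, and the divergence uses base-2 logarithms
  so the metric lives in $[0, 1]$; zero-count bins need no pseudo-counts
  because the JSD mixture handles them ($0\log 0 := 0$). Published
  values of this metric are not bit-comparable without knowing the
  original binning, which is why the binning here is explicit and
  configurable.

## The toy world

The synthetic module emulates exactly what the pipeline needs and no
more:

* **Pockets**: a hemispherical shell of ~60 C/N/O pseudo-atoms at
  radius 7 ± 0.5 Å around an empty cavity, deterministically placed
  (Fibonacci lattice plus a seeded rotation) — geometry enough for
  proximity rules and a contact score, with no claim to protein
  realism.
* **Ligands**: one or two ring units (benzene, pyridine,
  cyclopentane) joined by a three-carbon linker, plus up to three
  heteroatom substituents; idealized geometry with 0.03 Å jitter and a
  random rigid rotation. Sizes span 9–16 heavy atoms. All products are
  valence-valid and connected; the "dumbbell" variant returns its
  ground-truth 2-arm/1-scaffold partition for decomposition tests.
* **Surrogate docking**: a smooth contact potential (Gaussian well at
  3.5 Å, quadratic clash below 2.5 Å) summed over ligand–pocket
  heavy-atom pairs and scaled by a calibration constant (0.15), chosen
  so that the $-8.18$ success threshold is reachable but not trivial
  for seated toy ligands. The score is invariant under joint rigid
  motion and sensitive to ligand-only translation.
* **Perturbation sampler**: seeded coordinate jitter (scale
  proportional to the diversity temperature) with occasional element
  swaps at terminal atoms, plus a configurable fraction of deliberately
  disconnected outputs — the planted test hook for the validity filter.

What the toy world does *not* model: real protein chemistry, rotamers,
conformational strain, aromatic perception subtleties, or any
physically meaningful binding energetics. Passing tests therefore
demonstrate that the alignment machinery is correct and productive
under controlled conditions, not that it improves real docking
campaigns.

## Desk-scale experiment sizes

The alignment experiment in the test-suite uses 8 targets, $K = 10$,
weights $(1,0,0)$, fine-tuning at $10^{-3}$ for 2000 iterations, and 50
evaluation draws before and after — sizes chosen so the full cycle
completes in minutes while keeping the Monte-Carlo error of the QED
comparison small relative to the tolerance band (the test computes that
error from the evaluation sets themselves). The BoN trend uses 200 repetitions per
$N$. Forward-process moment checks use $10^5$ draws. These are the
package's reference experiment sizes; all of them scale up by
configuration.

## Known limitations

* The denoiser is a statistical toy: it captures composition,
  bond-distance statistics and coarse geometry, not chemistry. Its
  alignment gains are correspondingly modest and partly absorbed by
  sampling noise.
* Aromaticity is carried as a bond category, never perceived;
  heteroaromatic edge cases follow fixed conventions (documented in
  the descriptor code) rather than a perception algorithm.
* Arm re-orientation toward the pose (beyond rigid CoM translation) is
  out of scope, as is any alpha-sphere-style pocket detection.
* The external-command docking adapter is provided but deliberately
  untested here; the surrogate is the reference scorer throughout.
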