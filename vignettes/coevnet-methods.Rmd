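---
title: "Coevolutionary contact prediction with raw feature triplets: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coevolutionary contact prediction with raw feature triplets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Residues that are close in a protein's 3D structure constrain each other's
evolution: substitutions at one position are compensated at its spatial
neighbors. Given a deep multiple sequence alignment (MSA) of homologs, this
leaves a statistical fingerprint — correlated columns — from which residue
contact maps can be inferred. `coevnet` implements a complete desk-scale
pipeline for this inference:

1. **MSA statistics** — sequence weighting at 80% identity and the effective
   sequence number `Neff`;
2. **a triplet of raw coevolutionary features** — the covariance tensor
   (COV), a ridge-regularized precision matrix (PRE), and pseudolikelihood
   Potts couplings (PLM), each an `L x L x 441` tensor over the 21-state
   residue alphabet (20 amino acids + gap);
3. **a four-branch residual network** that maps the three tensors to a
   12-bin discretized distance distribution (distogram) per residue pair,
   from which the contact map is the probability mass below 8 Å;
4. **CASP-style evaluation** — top-`L/k` precision at medium (12–23) and
   long (≥ 24) sequence separations;
5. **a Potts-model simulator** that generates toy chains with known contact
   maps and samples matching synthetic MSAs, so that every stage is testable
   end to end with no external databases, structures, or pretrained weights.

The central design idea the package follows is to feed the network the *raw*
coupling tensors rather than classical post-processed pair scores
(Frobenius norm + average product correction): the post-processing discards
the sign and state-pair structure of the potentials, and the network can
learn a better reduction itself. The classical scores are retained as an
unsupervised baseline.

# Models

## Sequence weighting and Neff

Sequence redundancy is corrected by cluster weighting: sequence $n$ receives
weight $w_n = 1/\#\{m : S_{mn} \ge 0.8\}$ (the count includes $n$ itself),
where $S_{mn}$ is the fraction of identical positions over the full
alignment length, gap–gap positions counting as matches. Then

$$N_{\mathrm{eff}} = \frac{1}{L}\sum_n w_n .$$

Two readings of the printed weighting formula are possible — whether the
inner sum includes the self term, and whether identity normalizes by
alignment length or by non-gap columns. We take the cluster-size reading
(self term is the leading 1, so duplicating any sequence leaves
$N_{\mathrm{eff}}$ exactly unchanged) and full-length normalization with
gap=gap matching, which is the simplest testable convention; both choices
are isolated behind `pairwise_identity()` and `msa_weights()`. The
deep-search decision predicate `needs_deeper_search()` is strict:
`Neff < 128` triggers a deeper search stage (the external search tools
themselves are out of scope).

## The covariance feature (COV)

With weighted single-site frequencies $f_i(a)$ and pair frequencies
$f_{ij}(a,b)$,

$$S_{ij}^{ab} = f_{ij}(a,b) - f_i(a)\,f_j(b),$$

a `21L x 21L` block matrix capturing marginal — possibly transitive —
dependency. Frequencies default to uniform sequence weights for the plain
covariance reading; Neff-style weights are available and are what
`coev_features()` uses throughout, matching standard direct-coupling
practice. An optional pseudocount mixes frequencies toward uniform; the
default is 0 so that the exact margin identities (block rows and columns of
$S$ summing to zero) hold, which the tests assert.

## The precision feature (PRE)

PRE is the minimizer of the ridge-regularized Gaussian negative
log-likelihood

$$G(\Theta) = \mathrm{tr}(S\Theta) - \log\det\Theta + \rho\,\|\Theta\|_F^2,
\qquad \rho = e^{-6}.$$

No algorithm is dictated by the objective, and we solve it in closed form:
if $S = U\Lambda U^\top$, the unique positive-definite stationary point is
$\Theta = U\,\mathrm{diag}(\theta_k)\,U^\top$ with $\theta_k$ the positive
root of $2\rho\theta^2 + \lambda_k\theta - 1 = 0$. This is exact,
deterministic and $O((21L)^3)$; the test suite verifies it against an
independent L-BFGS minimizer of $G$ started from the identity, and checks
the stationarity residual $\|S - \Theta^{-1} + 2\rho\Theta\|_\infty$
directly.

Finite-MSA covariance matrices are rank-deficient, so a shrinkage step
$S \leftarrow (1-\gamma)S + \gamma\,\overline{\mathrm{diag}(S)}\,I$ with
$\gamma = 0.1$ is applied by default before solving; $\rho$ alone already
guarantees a positive-definite solution, but shrinkage stabilizes the
spectrum. It is exposed as a parameter (`shrinkage = 0` reproduces the bare
objective). The feature fed to the network is $\Theta$ itself; a sign
ambiguity exists in the literature (the precision matrix is sometimes
quoted as the *negative* inverse covariance) and is immaterial downstream
because the network is sign-agnostic after its learned reduction.

## The pseudolikelihood feature (PLM)

The Potts model assigns a sequence probability through per-site
conditionals

$$P(\sigma_l = q \mid \sigma_{\setminus l}) =
\frac{\exp\!\big(h_l(q) + \sum_{k \ne l} J_{lk}(q, \sigma_k)\big)}
     {\sum_{q'=1}^{21} \exp\!\big(h_l(q') + \sum_{k \ne l} J_{lk}(q', \sigma_k)\big)},$$

and pseudolikelihood maximization fits $(h, J)$ by minimizing the weighted
sum of the conditional negative log-likelihoods plus L2 penalties
$\lambda_h\|h\|^2 + \lambda_J\sum_{i<j}\|J_{ij}\|^2$. Defaults
$\lambda_h = 0.01$, $\lambda_J = 0.2\,(L-1)$ follow the convention of the
standard pseudolikelihood DCA implementations. The optimizer is L-BFGS-B
from a zero start (the objective is smooth and convex in each conditional;
a zero start makes the fit deterministic), with a gradient tolerance of
`pgtol = 1e-4` and an iteration cap. The couplings are kept block-symmetric
by construction ($J_{ij} = J_{ji}^\top$, shared between the two conditionals
they enter), so no post-hoc symmetrization step is needed. The **raw**
symmetrized coupling tensor is the network feature.

Internally weights are rescaled by their maximum before entering the
objective, which makes the fit invariant to multiplying all weights by a
constant (asserted by a test) while coinciding with the usual convention
(max weight = 1) whenever at least one sequence is unique.

The analytic gradient is exposed through `plm_objective()` and is checked
against central finite differences at every test run.

## Classical pair scores (baseline only)

`frobenius_score()` reduces each coupling (or covariance, or precision)
block to $\|J_{ij}\|_F$ — over the 20×20 gap-free sub-block by default —
deliberately ignoring the sign of the potentials, and `apc_correct()`
subtracts the average-product background
$\mathrm{corrected}_{ij} = \mathrm{raw}_{ij} - \bar r_i \bar r_j / \bar r$
(means over off-diagonal entries). The exact algebraic form of the
published post-processing pair is not available to us in full; we implement
the standard Frobenius+APC reading that the main-text description matches.
These scores are used for the raw-vs-processed comparison and as the
unsupervised baseline, never as network input.

## The network

Each feature tensor enters its own branch: a 1×1 convolution reducing 441
channels to `channels_hidden`, instance normalization, then
`blocks_per_branch` residual blocks. A residual block is
conv3×3 → instance norm → ReLU → dropout(0.2) → conv3×3 → instance norm,
with an identity skip and post-addition ReLU — the canonical basic block,
chosen because the published architecture names instance normalization but
does not pin the block internals. Branch outputs are concatenated
(3 × `channels_hidden` channels) and fused by the same reduction + blocks
pattern, ending in a 1×1 projection to 12 channels and a per-pixel softmax.
The output is symmetrized by averaging the $(i,j)$ and $(j,i)$
distributions, which preserves the per-pair probability simplex.

Distances are discretized into 12 bins — below 5 Å, ten 1-Å bins spanning
5–15 Å, and at or above 15 Å, half-open on the right — so the first four
bins tile exactly the `d < 8 Å` contact region and the contact probability
is their summed mass. Training minimizes the distance-bin negative
log-likelihood (or, as an ablation arm, the binary cross-entropy of the
derived contact probability at the 8 Å cut) with Adam, one protein per
batch, dropout active only in training, random square crops when a map
exceeds `crop_size` (default 128, i.e. never at desk scale), and diagonal
pairs excluded from the loss.

Because the three tensors live on very different numeric scales (covariance
entries are bounded by 1/4; precision entries grow like the inverse
shrinkage), each input tensor is z-scaled by its global mean and standard
deviation on entry to the network. This is a scalar affine map per tensor —
it does not touch the pairwise structure and commutes with the
transposition symmetry.

The published-scale profile (24 blocks per branch, 64 channels, 100 epochs
on thousands of real domains) is constructible via `net_config()`, but the
package's working profile is deliberately small — 2 blocks per branch, 2
fusion blocks, 16 channels — which trains in seconds per epoch on one CPU.
Layer composition, backpropagation bookkeeping and Adam are plain R; the
arithmetic-heavy primitives (the im2col 3×3 convolution, 1×1 convolution
and instance normalization, forward and backward) are small compiled
routines on BLAS matrix products. The whole computational graph is
verified against central finite differences in the test suite, for both
loss functions.

# The synthetic benchmark

The simulator replaces the external training corpus. It emulates, in order:

- **structures**: self-avoiding random chains with consecutive-site
  distance 3.8 units, excluded volume at one bond length, and a radial
  confinement ("compactness") term pulling sites toward the origin with
  force growing linearly in the radius. The default compactness 0.35 was
  calibrated once so that a 50-residue chain has an overall contact density
  of roughly 0.1–0.25 and long-range (|i−j| ≥ 24) contacts are sparse —
  a handful per 30-residue chain — mirroring the sparsity that makes
  long-range precision a discriminating metric on real proteins. Chains of
  length ≥ 30 are regenerated (bounded retries, derived seeds) until at
  least one long-range contact exists.
- **couplings**: every contacting pair receives a coupling block
  $s\,P_\pi$ — strength $s$ (default 1.5) on a permutation $\pi$ of paired
  states, so each state at $i$ favors exactly one partner state at $j$;
  non-contact blocks are exactly zero, fields are i.i.d. normal with
  standard deviation 0.3 (weak, protein-like conservation without freezing
  columns). The permutations come from a small family (default 4) drawn
  from a dedicated `pattern_seed` shared across proteins — emulating the
  universality of real contact energetics, where the same few interaction
  classes (hydrophobic packing, salt bridges, hydrogen bonding) recur in
  every protein. The family size matters in both directions: a single
  universal pattern lets the Potts system order globally (Gibbs chains
  freeze into near-identical sequences and Neff collapses), while a fresh
  random pattern per pair leaves no fixed low-dimensional channel subspace
  for a learned reduction to align with, so no generalizing network can be
  trained. A handful of shared patterns frustrates the chain (healthy
  Neff, diverse sampling) while keeping the informative subspace fixed and
  learnable.
- **alignments**: $N$ independent single-site Gibbs chains whose kernel is
  exactly the Potts conditional above, initialized uniformly, read out
  after 200 burn-in sweeps. Independent chains match the exchangeable-
  sequence assumption implicit in pseudolikelihood fitting; the package
  does not model phylogeny, and that is the main feature of real MSAs the
  simulator deliberately omits (real homolog sets are tree-correlated,
  which depresses effective depth and biases weights). Sampling is
  vectorized across chains with the Gumbel-argmax trick; blocks that are
  identically zero are skipped, which makes a sweep linear in the number of
  planted contacts.

What passing tests on this benchmark do show: the feature extractors
recover planted direct couplings, the network learns to read raw tensors,
distance supervision and feature ensembling behave as designed. What they
do not show: performance on real proteins, whose MSAs are shallower,
phylogenetically structured, and whose contacts are not generated by a
permutation-block Potts model.

## Standard benchmark conditions

The package's standard desk-scale study, used by the acceptance checks and
`scripts/acceptance.R`:

- **planted-coupling recovery**: L = 30, N = 2000 sequences,
  coupling strength 1.5, five seeds; top-K APC-corrected scores (K = number
  of planted pairs) are compared against the planted map for PLM, PRE and
  COV.
- **end-to-end training**: one fixed synthetic corpus of 75 proteins
  (60 train / 15 held out), L = 32, N = 100 sequences per alignment, PLM
  capped at 40 iterations during corpus building; the desk network profile
  trained for 5 epochs at learning rate 2e-3 on random 24 x 24 crops; five
  *training* seeds vary initialization, shuffling and dropout over the
  fixed corpus (varying the corpus itself would test the generator, not
  the learner, at five times the cost). Held-out long-range top-L/5
  precision is compared against the random-ranking null (the long-range
  native contact density) and across feature subsets and loss functions.
  L = 32 rather than 30 because the number of eligible long-range pairs
  (36 versus 21) sets the ratio between a perfect ranking and the null;
  at L = 30 that ratio is only 3.5, leaving no room between "null" and
  "perfect" for a learned model to demonstrate anything.

These sizes are the package's chosen working point: large enough that the
planted signal dominates sampling noise, small enough to run on a laptop
CPU in minutes.

# Evaluation conventions

Contacts are defined strictly below 8.0 Å between C-beta atoms (C-alpha for
glycine); `read_structure_cb()` falls back to C-alpha with a warning when
C-beta is missing elsewhere. Unordered pairs are counted once (i < j).
Depth is `floor(L/k)` with a minimum of 1; when fewer eligible pairs exist
than the nominal depth, the denominator is the number evaluated. Ties in
predicted probability break deterministically by ascending (i, j). Pairs
with unresolved coordinates are excluded from both numerator and
denominator. Precision is not monotone in depth and the tests only assert
prefix nesting of the ranked lists, plus the property that zeroing a
top-ranked true contact can never raise any precision.

# Numerical choices and degenerate inputs

- Frequencies, covariance and pseudolikelihood computations share one
  one-hot encoding; all invariants (simplex sums, marginalization, block
  symmetry) are asserted at `1e-9`.
- `compute_pre()` symmetrizes its input eigendecomposition and its output,
  so floating-point asymmetry cannot accumulate.
- All-zero pair-score matrices APC-correct to zeros with a warning.
- Softmax evaluations subtract the per-pair maximum before exponentiating.
- Distogram probabilities are floored at `1e-12` (NLL) / `1e-9` (BCE)
  inside the losses.
- Excluded pairs in a score map are floored to the minimum eligible score
  rather than removed, so the matrix shape is stable for plotting and IO.
- Every stochastic stage takes an explicit seed; nested seeds derive from
  the master seed via an integer mixing function (`derive_seed()`), and all
  RNG use is wrapped so the caller's RNG state is never disturbed.

# Known limitations

- At desk scale the distance-supervised and binary-supervised models are
  often indistinguishable on long-range top-L precision: the depth-L list
  is much longer than the handful of planted long-range contacts, so both
  models saturate it. The distance-loss advantage the architecture is
  built around is a large-scale effect; here it shows up as parity, not
  loss.

- No phylogenetic simulation; see above.
- The PLM optimizer caps iterations rather than iterating to machine
  precision; features extracted at the cap are slightly under-converged,
  which is deliberate (the network consumes them robustly and corpus
  building must stay fast).
- The desk-scale network is far below the published-scale capacity; its
  held-out precision on the synthetic benchmark is a sanity floor, not an
  estimate of real-data performance.
- Single-domain evaluation only; no domain parsing, no Z-score aggregation
  across targets.
- A3M support covers the common HHblits dialect (lowercase insertions
  removed, `.` dropped); exotic dialect extensions are not handled.
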