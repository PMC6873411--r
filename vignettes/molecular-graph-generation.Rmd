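---
title: "Non-autoregressive molecular graph generation with a conditional graph VAE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-autoregressive molecular graph generation with a conditional graph VAE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`molgvae` trains a variational autoencoder that emits an entire molecular
graph in a single decoder pass — no node-by-node iteration. A molecule with
up to $m$ heavy atoms is a padded undirected graph: node $i$ carries a
$p$-dimensional vector $\mathbf{v}^i$, the concatenation of three one-hot
blocks (atom type, formal charge, explicit-hydrogen count), and each node
pair $(i,j)$ carries a $q$-dimensional one-hot bond vector
$\mathbf{e}^{i,j} = \mathbf{e}^{j,i}$ over $\{$single, double, triple,
none$\}$, so $q = 4$. Molecules are kekulized on input, so no aromatic bond
type exists. Padding nodes are one-hot on the reserved "none" atom type
(charge 0, H-count 0), and the diagonal and all edges incident to a "none"
node are one-hot on the "none" bond, so every tensor cell is defined and the
losses need no masking. The shipped presets couple $m$, $p$ and $q$: the
small-organic preset (`qm9`) uses atom types $\{$C, N, O, F, none$\}$,
charges $\{-1,0,1\}$, H-counts $\{0,\dots,3\}$ and $m = 14$ (five plus the
9-atom maximum of that corpus), hence $p = 12$; the drug-like preset
(`zinc`) uses ten atom types and $m = 43$, hence $p = 17$.

Conditioning uses a property vector $\mathbf{y}$ of dimension $l = 2$:
molecular weight and the Wildman–Crippen LogP. Both priors are Gaussian:
$p(\mathbf{z}) = \mathcal{N}(\mathbf{0}, \mathbf{I})$ over the
$d$-dimensional latent space (default $d = 100$) and
$p(\mathbf{y}) = \mathcal{N}(\hat{\mu}_y, \hat{\Sigma}_y)$ with moments
estimated from the training set after each property is normalized to mean 0
and standard deviation 1.

Four networks are trained jointly:

* **encoder** $q_\phi(\mathbf{z}\mid\mathcal{G},\mathbf{y})$ — a message
  passing neural network (MPNN) producing $\mu_z$ and a strictly positive
  variance vector $\sigma^2_z$;
* **decoder** $p_\theta(\mathcal{G}\mid\mathbf{z},\mathbf{y})$ — a
  fully-connected network emitting all $mp + m(m-1)q/2$ raw values at once,
  softmaxed per node block and per unordered pair and mirrored into a
  symmetric *probabilistic graph*;
* **reward network** $r$ — an MPNN with sigmoid output approximating the
  non-differentiable chemical-validity reward $R$;
* **predictor network** $f$ — an MPNN with $l$ linear outputs regressing
  $\mathbf{y}$.

All MPNNs share one architecture (three message passing layers with 50
hidden units, a 100-dimensional node aggregation layer, two 100-unit tanh
head layers) but no weights. Messages between nodes $i$ and $j$ are
per-bond-type linear transforms of the neighbor state, convex-combined by
the *non-"none"* edge-type probabilities, so "none" edges carry no message
and one-hot and soft graphs travel the same code path; the state update is a
GRU-style gate, and the readout sums over nodes, which makes every network
invariant to node permutation (asserted by tests). The property vector is
injected into the encoder by concatenation to the graph readout — the
simplest conditioning consistent with the encoder's contract.

## The three auxiliary objectives

**Approximate graph matching.** The exact reconstruction likelihood of a
permutation-invariant graph requires a matching procedure that costs
$O(m^4)$. The reconstruction term is instead approximated by squared
distances between four permutation-invariant *count profiles* of the input
graph and its probabilistic reconstruction: atom-type counts, bond-type
counts, atom–bond pair counts, and atom–bond–atom triple counts. Three
conventions are fixed project-wide and documented here because the algebra
does not force them:

* Pair sums run over *ordered* pairs $i \neq j$, so each undirected bond
  counts twice; this only rescales terms and makes the atom–bond–atom term
  symmetric automatically.
* "Discarding the non-atom and non-bond types" zeroes the "none" atom
  column and drops the "none" bond channel. The pair and triple terms use
  the atom-type block only. In the first (atom-count) term the charge and
  H-count blocks are retained but weighted by each node's non-"none"
  probability, so padding nodes contribute no counts while the term remains
  differentiable.
* The four terms carry equal weight.

Under these conventions the loss is zero for any node permutation of the
same molecule, and the documented worked example (two bare carbons joined by
a single versus a double bond) evaluates to exactly $0+8+8+8 = 24$. The
approximation has a known collision mode — distinct non-isomorphic graphs
can share a profile — which is accepted as the price of $O(m^2)$ cost.

**Reinforcement learning.** The decoder is treated as a deterministic
policy whose action is the probabilistic graph; its reward is the chemical
validity of the argmax decoding, judged by the external function $R$
(below). Because $R$ is not differentiable, the reward network $r$ learns to
imitate it on three streams per batch — the data graphs, the
reconstructions, and decoder outputs from prior draws of
$(\mathbf{z},\mathbf{y})$ — with binary cross-entropy, and the VAE
minimizes $-\log r(\cdot)$ on its reconstruction and prior outputs. Reward
outputs are clamped to $[10^{-7}, 1-10^{-7}]$ before any logarithm.

**Auxiliary property prediction.** The predictor $f$ learns
$\|\mathbf{y} - f(\mathcal{G})\|^2$ on the data graphs; the VAE receives the
same penalty on its soft outputs, gated by $R$ of the argmax decoding so
that only chemically meaningful outputs are pushed toward their conditioning
values. $R$ is used here purely as a 0/1 label on a non-differentiable side
path; every term that backpropagates into the decoder flows through the
continuous probabilistic graph (one posterior draw and one prior draw per
example — single-sample estimates of the expectations).

The combined objectives are
$\mathcal{J}_1 = \mathcal{L}_\mathrm{VAE} + \beta_1 \mathcal{L}_\mathrm{RL}(\phi,\theta) + \beta_2 \mathcal{L}_Y(\phi,\theta)$
for the encoder/decoder and
$\mathcal{J}_2 = \beta_1 \mathcal{L}_\mathrm{RL}(r) + \beta_2 \mathcal{L}_Y(f)$
for the auxiliary networks, with $\beta_1 = \beta_2 = 1$ by default.
Setting $\beta_1 = \beta_2 = 0$ recovers the plain VAE (ablation "A1");
$\beta_1 = 1, \beta_2 = 0$ keeps only the reward pathway ("A2").

## Training loop

Per iteration a batch (default 20) is sampled; the encoder/decoder take one
RMSProp step (learning rate $5\times10^{-4}$) on $\mathcal{J}_1$; then the
VAE outputs are recomputed without gradient under the refreshed parameters
and the reward/predictor networks take one step on $\mathcal{J}_2$. Only
the simultaneity of the two updates is inherent to the method; the
"$\mathcal{J}_1$ first, then $\mathcal{J}_2$ on refreshed outputs" order is
this package's choice and is deterministic given the run seed. Gradient
isolation — a $\mathcal{J}_1$ step never touches $r$ or $f$, and vice versa
— is enforced by updating disjoint parameter sets and asserted by tests.
Gradients are clipped at global norm 10 (a numerical guard against early
RL-loss spikes), weights use Glorot-uniform initialization, and there is no
KL annealing and no validation split.

One detail deserves a flag: the default reparameterization draws
$\mathbf{z} = \mu_z + \epsilon \odot \sigma^2_z$ — the noise is scaled by
the *variance*, not the standard deviation. This unusual form is the one
the method family states and is kept deliberately rather than silently
corrected; the conventional $\epsilon \odot \sigma_z$ form is available
behind `train_config(use_sigma = TRUE)`.

## Validity, canonicalization, properties

The external reward $R(\mathcal{G})$ implements a sanitization check: every
atom's explicit valence (sum of bond orders plus the explicit-H count) must
not exceed the maximum allowed valence for its element and formal charge
(e.g. C 4, N 3 / N$^+$ 4, O 2 / O$^-$ 1, halogens 1, S $\{2,4,6\}$), with
the remaining valence filled by implicit hydrogens — the same semantics
mainstream cheminformatics sanitizers apply, cross-checked in the test suite
against an independent toolkit on correct and deliberately corrupted graphs.
Under-valent atoms are therefore tolerated (as radicals), the empty graph is
invalid, and a disconnected graph is judged as a whole — every fragment must
pass. Whether a disconnected-but-valid decoding should instead keep only its
largest fragment is not fixed by the method; whole-graph judgment is the
default and `decode_graph(largest_fragment = TRUE)` provides the
alternative.

Argmax decoding breaks ties toward the lowest vocabulary index, making
decoding deterministic. Decoded graphs are serialized as fully bracketed
SMILES (every atom carries its total hydrogen count and charge), so the
string pins down the molecule exactly even for radicals; canonicalization,
molecular weight and Wildman–Crippen LogP are delegated to Open Babel
(via ChemmineOB). Canonical SMILES double as the identity keys for
uniqueness and novelty.

## Generation and evaluation

Generation draws $\mathbf{y}_*$ from the estimated prior (or, for a target
condition $y^k = \tau$, from the exact Gaussian conditional — conditional
mean $\mu_{-k} + \Sigma_{-k,k}\Sigma_{k,k}^{-1}(\tau - \mu_k)$, conditional
covariance $\Sigma_{-k,-k} - \Sigma_{-k,k}\Sigma_{k,k}^{-1}\Sigma_{k,-k}$,
with coordinate $k$ set to the normalized $\tau$ exactly), draws
$\mathbf{z}_* \sim \mathcal{N}(\mathbf{0},\mathbf{I})$, runs the decoder and
discretizes by argmax. No post-processing (spanning trees, beam search) is
applied, and generation never fails: invalid graphs flow through to the
metrics.

The report computes Validity (valid fraction of all samples), Uniqueness
(distinct canonical keys over valid samples), Novelty (valid samples absent
from the training keys) and their geometric mean. Novelty's denominator
includes duplicate valid graphs — the literal reading of "fraction of valid
graphs not included in the training set"; `novelty_over_unique = TRUE`
switches to the unique-valid denominator used by some other toolkits.
Conditional summaries (property mean ± sd) are computed over valid *unique*
molecules; the alternative (all valid) is equally defensible, and the choice
is flagged here because the method description leaves it open. Display
rounding is three decimals; internal values keep full precision.

## The synthetic fixture generator

Testing a generative pipeline needs training data, and the package must be
testable offline, so `make_fixture_set()` grows random molecules directly in
graph space: random bond trees over $\{$C, N, O, F$\}$ (element frequencies
roughly organic-like: C 70%, O 14%, N 12%, F 4%), bond orders sampled
(80/15/5%) subject to valence bookkeeping, up to two ring closures per
molecule, an occasional ammonium/alkoxide zwitterion pair (5%) to exercise
the charge paths, and hydrogen counts set to the remaining valence. Every
emitted molecule is therefore valid and featurizable by construction;
uniqueness is enforced via canonical keys, and the whole set is
deterministic given a seed. The induced property distribution is whatever
the sampler produces — no attempt is made to mimic the exact MolWt/LogP
distribution of any public corpus, and the prior-estimation code consumes it
identically to real data.

What fixture-based tests do show: that the losses, gradients, training loop,
conditioning and metrics behave as specified, and that the validity reward
measurably steers the decoder (reconstruction loss falls epoch over epoch;
validity of generated samples rises over training; adding the RL objective
raises validity relative to the plain VAE). What they cannot show:
corpus-scale metric values, which depend on 100,000-molecule training sets
and longer schedules. The full protocol for a corpus-scale run is: download the public QM9/ZINC sets, sample 100,000 unique molecules,
train 50 epochs with the default configuration, sample 10,000 molecules,
and evaluate — the code path is identical, only the inputs and durations
change.

## Problem sizes and numerical choices

The shipped test and acceptance runs use sizes chosen to exercise real
learning dynamics on a single CPU: a 1,000-molecule fixture set trained for
20 epochs (batch 20) with 500-sample generation for the main benchmark, and
250 molecules for 8 epochs for the A1-versus-A2 ablation direction. Unit
tests use reduced network widths; the acceptance run uses the full default
architecture.

Numerical details, all asserted or exercised by tests: probability simplexes
are validated to $10^{-5}$; the encoder's log-variance head is clamped to
$[-10, 10]$ before exponentiation; reward outputs are clamped by $10^{-7}$
before logs; LeakyReLU uses slope 0.01; RMSProp uses decay 0.9 and epsilon
$10^{-8}$; the gradient clip is global norm 10. Reverse-mode gradients of
every primitive and of both full objectives are verified against central
finite differences. Degenerate inputs are defined rather than special-cased:
the empty graph has reward 0, an all-"none" probabilistic graph decodes to
the empty graph, a zero-variance property makes prior fitting fail loudly,
and evaluation of an empty sample is an error while a sample with no valid
graphs reports zero for all metrics.

## Known limitations

* The count-profile reconstruction loss cannot distinguish graphs that share
  all four profiles; the model can therefore be rewarded for reconstructing
  a profile-equivalent but non-isomorphic molecule.
* Stereochemistry, isotopes, and aromatic (non-kekulized) bond types are out
  of scope; molecules that cannot be kekulized are skipped on input.
* The dense $m \times m$ pair representation scales quadratically; the
  design targets small drug-like molecules, not macromolecules.
* Validity is a valence check: it accepts radicals and strained rings that a
  chemist might reject on stability grounds.
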