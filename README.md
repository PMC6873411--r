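# molgvae

Non-autoregressive molecular graph generation in R: a conditional graph
variational autoencoder trained with three auxiliary objectives —
approximate graph matching, reinforcement learning against a
chemical-validity reward, and auxiliary property prediction — plus the
generation and evaluation protocol that goes with it (validity, uniqueness,
novelty, G-mean, and property-conditioned sampling on MolWt/LogP).

## Who this is for

People building or studying generative models for small drug-like
molecules who want a one-shot (non-autoregressive) graph decoder: the whole
molecule — atom types, formal charges, explicit hydrogen counts, and the
full bond tensor — is emitted in a single decoder pass and discretized by
argmax, with no node-by-node iteration. The package is a complete,
self-contained implementation: data model, networks (with their own
reverse-mode autodiff and compiled message-passing kernels), training loop,
conditional generation, metrics, a synthetic fixture generator for offline
testing, and a command-line interface.

## The model in brief

A molecule with up to *m* heavy atoms is a padded graph: node vectors
**v**<sup>i</sup> ∈ {0,1}<sup>p</sup> concatenate one-hot blocks for atom
type, formal charge and explicit-H count; edge vectors
**e**<sup>i,j</sup> = **e**<sup>j,i</sup> ∈ {0,1}<sup>q</sup> range over
{single, double, triple, none} (molecules are kekulized, so q = 4). An MPNN
encoder q<sub>φ</sub>(**z**|𝒢, **y**) and a fully connected decoder
p<sub>θ</sub>(𝒢|**z**, **y**) — emitting all mp + m(m−1)q/2 values at once
with node-wise and edge-wise softmax — form a conditional VAE over a
property vector **y** = (MolWt, LogP) with Gaussian priors p(**z**) =
N(**0**, **I**) and p(**y**) = N(μ̂<sub>y</sub>, Σ̂<sub>y</sub>) estimated
from the training set.

Training minimizes two objectives simultaneously:

* **J₁** (encoder/decoder): an approximate reconstruction loss — squared
  distances between permutation-invariant count profiles (atom types, bond
  types, atom–bond pairs, atom–bond–atom triples) instead of O(m⁴) graph
  matching — plus the KL term, plus β₁·(−log r) on reconstruction and
  prior samples (r is an MPNN reward network approximating the
  non-differentiable validity check R), plus β₂·R-gated squared property
  error through an MPNN predictor f.
* **J₂** (reward/predictor): binary cross-entropy of r against R on data,
  reconstruction and prior streams, plus the predictor's squared error on
  the data graphs.

Conditional generation samples **y**★ from the exact Gaussian conditional
p(**y** | y<sup>k</sup> = τ) and decodes **z**★ ~ N(**0**, **I**).

See the methods vignette (`vignettes/molecular-graph-generation.Rmd`) for
the conventions, numerical choices, and limitations.

## Worked example

```r
library(molgvae)

# a synthetic training set: unique, valid, kekulizable molecules over
# {C, N, O, F} with <= 9 heavy atoms and computed MolWt/LogP
make_fixture_set(6, seed = 42)
#> [1] "C1OC=N1"          "CC(C(C#C)F)(CN)N" "FC1CC1"           "CO"
#> [5] "CCC=C(OC(C)C)C"   "OOF"

g <- featurize("C1OC=N1", vocab_preset("qm9"))
g
#> <molecular_graph> 4 heavy atoms, 4 bonds, m = 14
compute_properties(g)
#>    molwt     logp
#> 57.05132 -0.56200

ds  <- fixture_dataset(200, seed = 7)
fit <- train_model(ds, train_config(epochs = 5, batch_size = 20, seed = 7))
round(fit$log[, c("epoch", "recon", "kl", "rl_vae", "rl_reward")], 1)
#>   epoch   recon    kl rl_vae rl_reward
#> 1     1 25339.4 673.7    8.7      26.6
#> 2     2  1769.6 249.1    2.0      27.2
#> 3     3  1358.1 193.3   31.3      38.7
#> 4     4  1159.9 170.4   38.3      35.2
#> 5     5  1093.0 145.6   57.6      28.2

gen <- generate_molecules(fit$model, 200, seed = 11)
evaluate_generation(gen, canonicalize_smiles(ds$smiles))
#> <generation_report> n = 200
#>   validity 0.260  uniqueness 0.288  novelty 1.000  G-mean 0.422  unique 15
#>   molwt 79.08 +/- 10.08
#>   logp 1.34 +/- 0.76
```

The reconstruction term collapses within the first epochs while the
reward-network loss stays active — the RL pathway keeps pushing the decoder
toward chemically valid graphs long after the count profiles are matched;
validity keeps rising with more data and epochs (the acceptance run below
trains 1,000 molecules for 20 epochs). Conditioned generation targets a
property value:

```r
gen_c <- generate_molecules(fit$model, 100, condition = c(molwt = 80), seed = 3)
conditional_report(gen_c, canonicalize_smiles(ds$smiles))
```

A command-line interface wraps the same functions:

```sh
inst/cli/molgvae fixtures --n 1000 --seed 7 --out train.smi
inst/cli/molgvae train    --data train.smi --epochs 20 --seed 7 --out model.rds
inst/cli/molgvae generate --model model.rds --n 500 --condition molwt=100 \
                          --seed 7 --out gen.smi
inst/cli/molgvae evaluate --generated gen.smi --train train.smi --out report.json
```

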