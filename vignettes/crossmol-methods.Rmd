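---
title: "Methods: knowledge-augmented sequence-graph cross-attention for molecular property prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge-augmented sequence-graph cross-attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmol)
```

# The problem and the model

Predicting physicochemical and biological properties (solubility,
blood-brain-barrier permeability, toxicity, target activity) from a
molecular structure is a central task in computational drug discovery.  A
molecule arrives as a SMILES string; two complementary views of it exist:
the *sequence* view (the SMILES text itself, whose recurring substrings
correlate with substructures) and the *graph* view (atoms and bonds).
`crossmol` implements a dual-branch architecture that encodes both views
and fuses them:

1. **Knowledge-augmented graph branch.**  The molecular graph is augmented
   with *virtual knowledge nodes*: every atom receives five directed
   property→atom edges from discretised periodic-table properties
   (periodicity, metallicity, group, radius group, weight group), and every
   matched functional group (hydroxyl, amino, carboxyl, ...) becomes a
   virtual node with a directed edge to each member atom.  Virtual nodes
   create short paths between atoms that share chemistry but are far apart
   in the bond graph.  A dual-channel attention message-passing network
   (AMPNN) encodes the augmented graph: channel 1 carries knowledge-edge
   messages, channel 2 carries bond messages; each channel scores incoming
   edges GAT-style — `LeakyReLU(a^T [W h_u || W h_v])`, softmax-normalised
   over the receiver's channel neighbourhood — gates a linear transform of
   the (fixed) edge state by the attention coefficient through a logistic
   sigmoid, and modulates it elementwise by the sender state.  Channel
   aggregates (sum by default, mean available) drive a GRU update of the
   node state.  After K rounds, a Set2Set readout (LSTM-driven attention
   pooling, permutation-invariant) produces one graph vector, linearly
   mapped from 2F back to F.

2. **Sequence branch.**  A frequent-consecutive-subsequence (FCS)
   vocabulary is mined from the training SMILES by frequency-thresholded
   iterative adjacent-pair merging (BPE-style) over *atomic units* — `Cl`,
   `Br` and bracket atoms are pre-grouped so no token ever splits an
   element symbol.  Strings are segmented by greedy left-to-right longest
   match; segmentation is lossless by construction.  A transformer encoder
   (8 heads, learned positional embeddings, GELU feed-forward, post-norm)
   produces contextual token states and a mean-pooled sequence vector.

3. **Fusion and decoding.**  Cross-attention uses the token states as
   queries and affine projections of the graph vector as a one-element
   key/value memory, scaled by `sqrt(C/d)` (C = width, d = heads).  The
   attended states are mean-pooled and a residual from the pooled token
   states is added (see *Design choices*).  A three-layer feed-forward
   decoder emits per-task outputs: sigmoid probabilities for
   classification, unbounded reals for regression.  Losses are masked mean
   binary cross-entropy and RMSE.

# Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `model_dim` | 128 | shared feature width of both branches (stated experimental setup) |
| `n_heads` | 8 | attention heads, transformer and fusion (stated setup) |
| `n_layers` | 4 | transformer depth; unstated upstream, standard small-encoder choice |
| `rounds` (K) | 3 | message-passing rounds; deeper graph networks over-smooth |
| `set2set_steps` | 3 | readout processing steps |
| `aggregate` | sum | channel aggregation (`mean` available) |
| `lr` | 1e-4 | Adam initial learning rate (stated setup) |
| `batch_size` | 64 | molecules per optimisation step (stated setup) |
| `max_epochs` / `patience` | 100 / 15 | early stopping on the validation metric |
| `seeds` | 10 | seeds aggregated in a report (stated setup) |
| `min_freq` / `max_token_len` / `max_vocab` | 5 / 8 / 1024 | FCS mining: tokens stay medium-sized, frequent, bounded |
| `n_bins` | 5 | quantile bins for element radius/weight groups |
| `split` | scaffold | Bemis-Murcko scaffold split, 80/10/10 (MoleculeNet convention) |

# Design choices where the design was open

- **Fusion residual.**  With a one-element graph memory the cross-attention
  softmax is identically 1, so the attended output depends only on the
  graph projection — the sequence encoder would receive no gradient, and
  end-to-end training of both branches (which the architecture requires)
  would be impossible.  `cross_attend()` is kept as the pure attention
  operation; the model adds the standard residual from the pooled token
  states around it.  The query/key projections inside the fusion block
  still see zero gradient under a one-token memory; an optional multi-token
  (node-level) memory would activate them but is off by default.
- **Message semantics.**  The per-edge message is
  `sigmoid(alpha * (he W)) ⊙ h_sender`: a gated transform of the edge state
  modulated by the *sender* state, so messages carry neighbour information.
  Edge states are initialised once (bond-feature projection for bonds,
  relation-type embedding for knowledge edges) and held fixed across
  rounds.
- **Virtual node sharing.**  Atoms with the same property label point to
  one shared virtual node per molecule, so the graph grows by the number of
  *distinct* labels plus matches, not 5 x atoms.  Each functional-group
  occurrence is its own virtual node.  Property nodes connect only to their
  own atom, not to its bond neighbours.
- **Aromaticity is notation-derived.**  Lowercase atoms and `:` bonds are
  aromatic; Kekulé-form rings are left as drawn.  Hydrogen counts, ring
  perception and topology agree with RDKit on the development corpus;
  re-perception of aromaticity from Kekulé forms is out of scope.
- **Tokenised vocabulary is mined per training split**, so evaluation
  molecules containing unseen atomic units are dropped from
  validation/test with a warning rather than leaking corpus statistics.
- **Readout over atoms only.**  Virtual nodes carry knowledge, not
  molecular identity, and are excluded from Set2Set pooling.
- **Regression outputs are unbounded** (log-solubility-style targets are
  unbounded), decoded without a squashing nonlinearity.

# Numerical choices

- Classification probabilities are clamped to `[1e-7, 1 - 1e-7]` before the
  logs; a fully masked batch yields loss 0 with a warning.
- Attention softmaxes subtract the per-row (or per-receiver-group) maximum
  before exponentiation; empty neighbourhoods contribute a zero message
  rather than NaN.
- LeakyReLU slope 0.2; logistic sigmoid as the gating nonlinearity; GELU in
  the transformer feed-forward; Glorot-uniform initialisation; layer
  normalisation with variance floor 1e-5.
- Vocabulary-mining ties (equal pair frequency) break lexicographically on
  the merged string, so mining is deterministic.
- All stochastic components (splits, initialisation, minibatch order,
  dropout, fixture sampling) draw from R's RNG under the caller's seed;
  a fixed seed reproduces a run bit-for-bit on one machine.

# The autodiff engine

No automatic-differentiation framework is available to R in this stack, so
the package includes a small reverse-mode tape over dense matrices
(`R/autograd.R`): operators record parent links and a backward closure,
and `ag_backward()` replays the tape in reverse creation order.  Every
operator is validated against central finite differences in the test
suite, and an end-to-end gradient check covers the composed model.  Adam
follows the standard bias-corrected update.

# What the synthetic fixtures emulate — and what they do not

`generate_fixture()` decorates ~10 small ring/chain cores (benzene,
cyclohexane, pyridine, furan, thiophene, THF, piperidine, short chains)
with functional-group fragments drawn from the same table the knowledge
base matches, then labels molecules either by the *presence of a target
group* (classification; established with the package's own substructure
matcher, so implied chemistry such as a carboxyl containing a hydroxyl is
labelled consistently) or by an *additive per-group score* plus Gaussian
noise (regression, sigma = 0.25 by default).  Class balance is held near
0.5 by quota sampling.

The fixtures make the tasks learnable exactly through the features the
architecture claims to exploit, which is what the learning smoke test
establishes: the assembled model can extract a functional-group signal
end-to-end on CPU.  They do **not** emulate real chemical space: no
stereochemistry, no charged drug-like scaffolds, no label noise from assay
variability, no activity cliffs, and far less structural diversity than
MoleculeNet sets.  A green smoke test is evidence of correct wiring and
optimisation, not of benchmark-level accuracy; published benchmark numbers
are not reproducible at desk scale and are not claimed.

# Scaled test dimensions

The test suite trains at width 32 (one transformer layer, K = 2) rather
than the 128-wide default: the pure-R engine runs ~25 ms per molecule
forward+backward at that size, which keeps the 200-molecule smoke test
inside a CPU budget of minutes.  The wiring, losses and optimiser are
identical at every width.

# Known limitations

- SMILES coverage is the organic subset plus bracket atoms; isotopes and
  stereo descriptors parse but are ignored; aromaticity is not
  re-perceived from Kekulé notation.
- Bond conjugation flags are a documented approximation, not a resonance
  analysis.
- One molecule is encoded at a time (no padded batching); throughput is
  CPU-bound and suits small datasets, not 40k-molecule benchmarks.
- The functional-group pattern language is a restricted SMARTS subset
  (element lists, degree, charge, bond orders, explicit H); recursive or
  ring-membership SMARTS constraints are not supported.
- Hyperparameter random search is exposed as configuration, not automated.
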