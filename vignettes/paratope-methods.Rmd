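---
title: "Methods: sequence-based paratope prediction and interface analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based paratope prediction and interface analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paratope)
```

This vignette documents the scientific model behind the package, the
parameters that matter, the numerical and design decisions taken where the
problem left them open, what the synthetic data generator does and does not
emulate, and the known limitations.

## Ground-truth labeling

An antibody residue belongs to the paratope iff at least one of its
non-hydrogen atoms lies within a distance cutoff of any non-hydrogen atom
of the bound antigen; epitope labels mirror this on the antigen side.

* `cutoff` — contact distance in Ångström, default **4.5**, the standard
  heavy-atom contact criterion for antibody–antigen interfaces.
* `boundary_inclusive` — default **TRUE**: "within 4.5 Å" is read as
  `d <= 4.5`. The choice only matters for atoms exactly on the boundary,
  but it is exposed as a flag so either convention can be forced.
* `exclude_hydrogen` — default **TRUE**. Hydrogens are rarely resolved and
  never part of the heavy-atom criterion; deuterium is treated as hydrogen.
  Detection uses the element column when present and falls back to the
  legacy atom-name convention (strip leading digits, first letter).

Further conventions, chosen where crystallographic practice is silent:

* **Altloc resolution** keeps the highest-occupancy conformer, ties broken
  by altloc identifier order. (Parsers that silently keep conformer "A"
  can keep the *lower*-occupancy atom; we resolve this in-package.)
* **Residue order** follows author-assigned numbering with insertion codes
  breaking ties lexicographically (100 < 100A < 101).
* **Nonstandard residues** are retained and mapped to `X` (with a warning)
  so structure-derived label tracks stay aligned with sequence-model
  tracks. Residues with zero resolved heavy atoms keep label 0 rather than
  being dropped, preserving sequence/label alignment.
* Only residues resolved in the crystal are labeled; unresolved residues of
  the construct simply do not appear in the track.

Internally the labeler computes squared distances with a Gram-matrix
expansion; the test suite checks it against an exhaustive all-pairs scan on
every generated complex, plus monotonicity in the cutoff and invariance to
added hydrogens.

## Embedding backends

Each residue is represented by the column-wise concatenation of one block
per backend. Backends declare a name, a dimension and a pairing mode:

* *single-sequence* backends receive the heavy+light concatenation in
  paired mode (the two chains joined with no separator token; a linker is
  deliberately not inserted because no convention exists);
* *paired-aware* backends receive each chain separately.

Backend order in the concatenation is **alphabetical by name** — an
arbitrary but fixed and recorded convention, stored in the `block_index`
attribute together with each block's column range.

The **synthetic backend** exists so that the entire pipeline is testable
without downloading pretrained models. Its residue vector is a
deterministic hash of (amino acid, ±2 sequence window, chain tag, backend
name, seed) mapped to standard-normal values. Three properties are by
construction:

* determinism — identical inputs give bit-identical matrices;
* no cross-chain leakage — context windows truncate at chain boundaries,
  so the heavy-chain rows of a paired embedding equal the single-chain
  embedding exactly (a tested invariant);
* `X` embeds as the mean over the 20 standard-residue substitutions at the
  same context.

A planted signal spec (`dims`, `beta`) shifts the chosen dimensions by
`beta` at positions flagged as paratope-like, giving synthetic datasets a
linear signal of known strength. Default synthetic dimensions are small
(8–64) to keep tests fast; real adapters would declare their true
dimensions and must pass the same `adapter_contract_check()`.

PCA reduction of embeddings is not part of any default pipeline: reduced
embeddings measurably hurt paratope prediction, so the package does not
encourage them.

## The classifier and its training protocol

`paratope_mlp()` fits a fully connected network
`d -> 2000 -> 1000 -> 500 -> 1`. The hidden activation is ReLU — the
conventional default, configurable in principle through the architecture;
the output is logistic. Defaults follow the reference training protocol:

| parameter | default | notes |
|---|---|---|
| `hidden` | 2000, 1000, 500 | width of the three hidden layers |
| `dropout` | 0.4 | applied to all hidden layers, training only |
| `mask_rate` | 0.4 | fraction of input coordinates zeroed per residue per step |
| `learning_rate` | 1e-5 | Adam |
| `batch_size` | 16 | **sequences** per batch; loss averaged over all residues in the batch |
| `weight_decay` | 1e-5 | L2, applied to weights only, biases excluded |
| `patience` / `max_epochs` | 10 / 300 | early stopping on validation PR AUC |

Decisions taken where the protocol was underspecified:

* "Masking 40 % of the input embeddings" is implemented as independent
  per-coordinate Bernoulli zeroing (per residue, per step), with no
  inverse-rate rescaling — it is input corruption, not dropout. Coarser
  granularities (whole residues, whole backend blocks) would be natural
  variants; per-coordinate was chosen as the least structured assumption.
* Batches are formed at sequence level because the batch size counts
  sequences; residue-level batching would change the effective loss
  weighting between short and long sequences.
* The selection metric is validation PR AUC computed **per protein and
  then averaged**, matching the evaluation convention; the checkpoint kept
  is the argmax-metric epoch, never the last epoch (a contract enforced by
  a rigged-metric test).
* Probabilities are clamped to `[1e-7, 1 − 1e-7]` inside the loss.
* Inputs are not normalised before the MLP; embeddings enter as produced.
* Inference applies neither dropout nor masking and is fully
  deterministic.

All randomness (initialisation, shuffling, dropout, masking) is governed
by the `seed` argument; an identical (data, config, seed) triple reproduces
the history and weights exactly. The global RNG state is restored on exit.

### Settings for the small synthetic demonstrations

The defaults above are tuned for real embedding dimensions (thousands) and
datasets of hundreds of complexes. The package's own demonstrations, tests
and acceptance script run a deliberately small problem: 40 sequences of
length 90–130, 24 synthetic dimensions, hidden widths 64/32 (32/16 for the
null runs). At that scale a learning rate of 1e-5 barely moves the weights
within 300 epochs, and a slow warm-up interacts badly with patience-10
early stopping: if the random initialisation happens to score well on the
tiny validation set, training can stop before learning begins. The small
fixtures therefore use `learning_rate = 3e-3`, at which learning reliably
outpaces the patience window across seeds. The full-width 2000/1000/500
architecture is still constructed and forward-passed (and its closed-form
parameter count `(d+1)·2000 + 2001·1000 + 1001·500 + 501` reported) to
exercise the production configuration.

## Evaluation conventions

Metrics are computed per complex and averaged unweighted across complexes
(the "per-protein" convention); a pooled-residue computation gives
different numbers on unbalanced data, and a constructed counterexample in
the tests keeps the two from being conflated.

* Binarization at 0.5 uses `>=` (ties count positive).
* PR AUC uses precision–recall **step summation** (average-precision
  style); trapezoidal interpolation is optimistic in PR space. Published
  baselines may interpolate differently, so PR AUC comparisons are only
  guaranteed self-consistent.
* ROC AUC is the Mann–Whitney concordance probability with tie correction,
  checked against exhaustive pair counting.
* Complexes with a single label class are excluded from AUC averages and
  counted in the report; degenerate F1/MCC denominators return 0 with a
  warning.

## Two-arm asymmetry and the upper bound

Curation applies four filters in order: protein/peptide antigen; both
heavy and light chains present (excludes nanobodies); exactly two arms;
identical arms (heavy, light and antigen sequences match). Counts are
reported per antibody after each stage. Filter 4 can be relaxed to a
Levenshtein-distance threshold (`max_arm_distance`) for sensitivity
analyses of near-identical arms.

Paratope sets use (amino acid, position) members, e.g. `L63`; because
curated arms have identical sequences, position-only membership coincides
and is available as an option. Sequential sequence positions are the
numbering frame. Normalized asymmetry for two empty sets raises an error
rather than silently returning 0 — curated paratopes are never empty, so a
0 would mask upstream problems. Arm pairing follows metadata row order.
The Pearson correlation between normalized paratope and epitope asymmetry
uses the standard two-sided t approximation.

`arm_upper_bound()` scores one arm's labels against the other (F1, MCC).
On identical tracks with both classes present it returns (1, 1); the tests
verify symmetry under argument swap.

## Downstream operators

* `paratope_size()` — the sum of probabilities, additive over chains;
  single-chain sizes are not comparable with paired-chain sizes. A
  thresholded-count variant is monotone non-increasing in the threshold
  and is left to the caller via `binarize()`.
* `pooled_embedding()` — unweighted mean, or weights
  `w_i = p_i / sum(p)`; invariant to uniform rescaling of `p`, lies in the
  convex hull of residue vectors, errors when `sum(p) = 0`.
* `combine_tracks()` — substitutes a region-restricted track into a
  full-length track on a supplied mask. Region membership (e.g. CDR±2) is
  annotation the caller provides; the package deliberately does not
  implement antibody numbering, keeping the combiner agnostic to how the
  mask was built. Raw probabilities are substituted with no boundary
  rescaling.

## Shapley attribution

`exact_shapley()` enumerates all `2^n` coalitions (refusing `n > 12`);
absent features take baseline values. `approx_shapley()` averages marginal
contributions over sampled permutations and converges to the exact values
with the same baseline; it satisfies efficiency exactly by construction.
The baseline is the mean feature vector of a user-supplied background set
(the training features by default).

Backend importance sums **absolute** Shapley values per block (raw mode)
or averages them (mean mode), then normalizes to sum to 1. Absolute values
keep importance non-negative so the normalization is well defined; a
`signed` option exposes the alternative. Aggregation across
residues/sequences/positions averages the normalized profiles over the
profiles in which each backend appears, then renormalizes.

## What the synthetic generator does and does not emulate

`generate_training_set()` emulates the statistical shape of the real
problem: ~1:10 positive prevalence over the variable region, positives
clustered in three CDR-like windows covering ~30 % of each sequence
(within-window positive probability `prevalence / window_frac`), and a
label signal carried linearly by a subset of embedding dimensions.
`generate_toy_complex()` and `generate_two_arm_complex()` emit
standards-conformant PDB text with single-atom antigen decoys so the
brute-force distance oracle stays auditable.

It does **not** emulate: real antibody geometry or side-chain chemistry,
the nonlinear and distributed way real PLM embeddings encode paratope
propensity, sequence-family structure (germline relatedness between
sequences), or inter-annotator noise in structural labels. Passing tests
on these fixtures therefore demonstrates the correctness of the machinery
— labeling, training protocol, selection, metrics, attribution — not the
accuracy a pretrained-embedding model would reach on real complexes.
Reproducing published benchmark accuracy requires the six real PLM
adapters and curated structure datasets, both out of scope here.

## Problem sizes

The test suite and acceptance script use: 200 generated complexes of 10–50
residues for the labeling oracle; null metric simulations at n = 10 000;
the 40-sequence planted fixture (β = 4, prevalence 0.12) plus eight
40-sequence null fixtures (β = 0); exact Shapley up to 8 features with a
500-permutation sampling check; and two-arm recovery at k ∈ {0, 1, 2, 4}
over 25 residues. These sizes were chosen so each statistical check has
comfortable resolution while a full run stays in the minutes range on one
CPU core.

## Known limitations

* No pretrained PLM adapters are bundled; the adapter contract and the
  synthetic backend define the interface real adapters must satisfy.
* The labeler requires resolved structures; it does not repair missing
  residues, model protonation, or predict structures.
* Exact Shapley is exponential by nature; per-dimension attribution over
  thousands of real embedding dimensions must use the sampling estimator
  with a modest permutation budget.
* `curate_two_arm_dataset()` reproduces filtering logic, not any specific
  database snapshot; retained counts depend on the metadata supplied.
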