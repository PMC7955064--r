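---
title: "Likelihood-guided affinity maturation from phage display repertoires: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-guided affinity maturation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phagelm)
```

# The problem

Phage display panning enriches antigen-binding antibody variants out of a
combinatorial library, and deep sequencing of the panning output gives a
snapshot of which sequences survived selection. Read frequency, however, is
a noisy proxy for affinity: amplification bias, display level and sampling
all distort it. `phagelm` implements an alternative prioritization: fit an
autoregressive LSTM language model to the enriched repertoire, and rank
candidate sequences — including sequences never observed in the library —
by their negative log-likelihood (NLL) under that model. The package covers
the full path from reads to ranked candidates, plus a synthetic panning
simulator with a known ground-truth binding model so that every stage can
be validated by parameter recovery.

The concrete system modeled throughout is a synthetic heavy-chain (VH)
library against the hapten kynurenine: 17 diversified CDR positions
(antibody numbering 28–100c), five of them restricted by special degenerate
codons, the rest NNK. Only the 17 diversified residues enter the model; the
constant frameworks are treated as anchors.

# Library model

A `library_design` is an ordered list of positions, each with an IUPAC
degenerate codon. `expand_degenerate_codon()` enumerates the codon's
concrete expansion against the standard genetic code and records *codon
multiplicity* per residue — under NNK, leucine is encoded by 3 of the 31
non-stop codons, so its theoretical frequency is 3/31, not 1/20.

**Stop policy.** NNK includes the amber stop TAG. The production host for
such libraries is typically an amber-suppressor strain (TAG read as Gln),
but the theoretical position distributions are most naturally stop-free, so
the default policy `exclude_and_renormalize` drops stops and renormalizes;
`amber_as_Q` is available when suppression should be modeled explicitly.
The bundled 17-position design gives a theoretical diversity of
20^12 × 3 × 2^4 = 1.96608 × 10^17, computed exactly in arbitrary precision
and reported rounded half-away-from-zero to one significant figure
(2 × 10^17). Positions labels ("100a") are opaque ordered text; no
Kabat/IMGT numbering engine is involved, because the method only needs the
fixed-length residue vector.

**Open choice — NNK weighting.** Whether theoretical distributions should
weight NNK residues by codon multiplicity or uniformly is not decidable
from the headline figures alone; codon weighting is the physically correct
model of an NNK synthesis and is the default, with
`theoretical_distribution(..., weighting = "uniform")` as the alternative.

# Read processing

`merge_read_pair()` joins a forward read to the reverse-complement of its
mate at the longest exact suffix–prefix overlap of at least `min_overlap`
bases (default 10); a `max_mismatch` option exists but defaults to 0, since
the simulator's reads are exact and real pipelines typically precede this
step with quality trimming that is out of scope here. Merged DNA is
translated in the three forward frames (`translate_frames()`; stops as
`*`, N-containing codons as `X`).

**Anchor extraction instead of BLAST.** The reference workflow identified
VH sequences with BLAST-based tools. For a fixed-framework synthetic
library this is unnecessary: `extract_vectors()` matches the constant
framework template exactly (diversified slots wildcarded) and pulls the 17
residues out by position. Frameshifted or indel-containing reads simply
fail to match; reads with `*` or `X` in a diversified slot are rejected.
This keeps the pipeline deterministic and dependency-free. The bundled
template is a synthetic VH3-style scaffold (the real clone's framework is
unpublished) and is labelled synthetic in the fixture itself; every
consistency between scaffold and design (restricted positions, parental
residues) is preserved.

**Enrichment ratios.** `enrichment_ratio()` divides per-position residue
frequencies after panning by frequencies before. For the primary library
the "before" is the theoretical design distribution (the reference
analysis does the same); an observed-vs-observed mode is available by
passing any other frequency matrix. Cells are classified enriched
(ER ≥ 1.2), neutral (0.8 < ER < 1.2) or intolerant (ER ≤ 0.8); boundary
values are assigned to the outer classes so that the three classes
partition all 340 cells (17 positions × 20 residues). A residue observed
after but absent before gets `Inf` and a flag rather than an error.

**Training-set rule.** Training sequences are chosen by a cap-driven count
threshold: the smallest count c\* such that at most `cap` (default 1000)
sequences have count ≥ c\*, keeping all of them. This depends only on the
count multiset and reproduces both phrasings used for the reference data
("read counts over three", 959 sequences, cap 1000) without hard-coding a
threshold. A methods sentence in the source text refers to occurrence
"higher in round 2 than in 3" although only rounds 0–2 exist; we read this
as a slip for the count-threshold rule and implement only the latter.

# The LSTM

The vocabulary has exactly 22 tokens: the 20 amino-acid letters, a start
token `B`, and a padding token. Sequences are one-hot encoded with the
start token prepended. One LSTM layer with N blocks computes, at each
step,

$$z_t = \tanh(W_z x_t + R_z h_{t-1} + b_z)$$
$$i_t = \sigma(W_i x_t + R_i h_{t-1} + b_i), \quad
  f_t = \sigma(W_f x_t + R_f h_{t-1} + b_f), \quad
  o_t = \sigma(W_o x_t + R_o h_{t-1} + b_o)$$
$$c_t = z_t * i_t + c_{t-1} * f_t, \qquad h_t = o_t * \tanh(c_t)$$

with elementwise products; a dense layer shared across time maps the last
layer's output to 22 scores and a softmax turns them into next-token
probabilities. Training minimizes categorical cross-entropy (natural log)
under teacher forcing with Adam at learning rate 0.01 (β₁ = 0.9,
β₂ = 0.999, ε = 1e-8 — standard defaults; only the learning rate is
prescribed). The cell, backpropagation through time and Adam are
implemented directly in vectorized base R: no deep-learning framework
exists in the target environment, the sequences are short (18 steps) and
fully batched, and having the backward pass in-package lets the test suite
check it against finite differences.

Choices the reference leaves open, fixed here:

* **Loss scale and logs** — natural log throughout; learning curves report
  the per-position mean (a uniform model scores ln 22 ≈ 3.09 per
  position), while `nll()` sums over the K residue positions, matching the
  printed NLL range of roughly 9–11 for 17 positions.
* **Start token and padding in the loss** — the start token is input-only
  and never a target; sequences are fixed-length here so the padding token
  exists in the vocabulary but carries no loss. Predicted mass on B/pad is
  *not* renormalized away during scoring (a plain softmax head).
* **Initialization** — Glorot-uniform weights from the seeded generator;
  forget-gate biases start at 1 (standard practice for stable early
  training); everything else at 0.
* **Dropout** — inverted dropout on each LSTM layer's output, fresh masks
  per epoch and time step, training only.
* **Optimization regime** — full-batch gradients: the training sets are
  ≤ 1000 sequences, so full-batch Adam is cheap, removes mini-batch
  ordering as a source of nondeterminism, and makes seeded runs
  bit-reproducible on one platform.
* **Best epoch** — weights are snapshotted at the epoch minimizing
  validation loss (no retraining); `cross_validate()` scores each
  architecture by the mean over folds of that minimum, ties broken toward
  fewer parameters.

# Generation and prioritization

`sample_sequences()` starts from `B` and draws K residues sequentially
from the temperature-adjusted softmax. The reference text prints the
temperature factor as dividing `exp(y)` in numerator and denominator —
where it would cancel; the surrounding text (T > 1 diversifies, T < 1
sharpens) requires the standard form `exp(y/T)`, which is what is
implemented. The start and padding tokens are excluded from the sampling
support and the residue probabilities renormalized, so samples are always
exactly K residues; `temperature = 0` is exact greedy decoding.

Generated duplicates are collapsed to unique vectors before ranking (the
reference is silent; its evaluated candidates are distinct), and the
position-novelty filter removes sequences with a residue at a position
where no training sequence ever had it. Candidate groups follow the
published scheme: the 10 lowest-NLL generated sequences; one sequence per
value of the NLL grid 10.0–25.5 in 0.5 steps (32 values) chosen as the
unused sequence nearest the grid value (nearest-with-no-replacement is our
choice of matching rule, ties toward lower NLL); and the 10 most frequent
NGS sequences, count ties broken lexicographically.

# The panning simulator

The simulator exists to make the pipeline testable without the study's raw
sequencing data. Its stated world:

* **Library** — `n_library = 1e5` i.i.d. draws from the codon-weighted
  design distribution (the real library has ~4 × 10^10 transformants; 1e5
  is the desk-scale stand-in that still leaves most variants unique, as in
  the real data where unique/total > 0.97).
* **Selection** — a variant with additive position-weight energy E
  survives a round with weight ε + exp(−βE), β = 1, ε = 1e-6. Boltzmann
  retention was chosen over a logistic model for analytic transparency; ε
  models nonspecific carryover so no variant has zero survival. An
  optional pairwise-coupling table can probe epistasis but is off by
  default.
* **Ground truth for recovery tests** — five strongly favorable residues
  at ΔE = −2 (including a tryptophan at position 28, echoing the strongest
  published enrichment signal, T28W) and five unfavorable at ΔE = +2.
  ΔE = ±2 under β = 1 gives per-round weight ratios of e² ≈ 7.4, the
  regime where two rounds of selection produce clear but not saturated
  enrichment.
* **Sequencing** — `depth = 1e5` multinomial reads per round (the real
  rounds have 1–3 × 10^6 reads; 1e5 preserves the count-threshold behavior
  at desk scale), rendered on request as overlapping 220-nt paired reads
  over the 360-nt amplicon, with optional per-base substitution errors.
* **Rounds** — two, as in the reference experiment.

What the simulator does **not** emulate: amplification bias between
rounds, display-level differences, washing kinetics, chimeric reads,
quality-score structure, barcode demultiplexing, and (by default) epistatic
fitness. A green parameter-recovery test therefore establishes that the
statistical machinery — enrichment analysis, the cap rule, LSTM fitting,
NLL ranking — recovers a known positional selection signal from multinomial
data of realistic size; it does not establish robustness to those real-data
artifacts, nor that NLL would correlate with affinity for any particular
antigen.

On this stated world, the headline recovery test (seeded) trains the
2-layer × 64-block model on the cap-1000 subset of simulated round-2
counts and checks Spearman correlation ≥ 0.5 between NLL and true energy
over 500 held-out variants spanning the energy range; observed values are
around 0.9, with favorable residues classified enriched (ER ≫ 1.2) and
unfavorable ones intolerant.

# Evaluation arithmetic

`group_stats()` summarizes measured dissociation constants per candidate
group; the median of an even group is the mean of the central pair, and
quartiles use the inclusive linear-interpolation convention (R quantile
type 7; the reference does not state its convention, so the type is an
argument). `fold_improvement()` is parent K_D over best model-derived
K_D — about 1833 on the bundled table, matching the published "over
1800-fold". `nll_affinity_fit()` regresses log10(K_D) on NLL by OLS; on
the bundled 20-candidate table R² ≈ 0.26. The published R² of 0.52 was
computed on a 42-candidate set that is not printed anywhere, so it is
documented as non-reproducible and excluded from acceptance.

# Numerical conventions

* Probabilities are floored at 1e-12 inside loss/NLL, with a warning.
* All count tie-breaks are lexicographic on the vector string;
  deterministic outputs are sorted by decreasing count then vector.
* Every simulator/training/sampling entry point takes an explicit integer
  seed; multi-stage runs derive stage seeds deterministically from the
  master seed.
* Exact integer arithmetic (decimal-string bignum) is used for theoretical
  diversity, since 1.96608 × 10^17 exceeds exact double integer range in
  general-design cases.

# Known limitations

* The merge step is exact-overlap only; it is not a general-purpose
  paired-end assembler (no quality-aware consensus).
* Full-batch training is quadratic-memory in nothing but linear in
  sequences, yet very large training sets (≫ 10^4) would warrant
  mini-batching that is not implemented.
* The CLI covers the documented workflow but is intentionally thin; the
  R API is the primary interface.
* The NLL–affinity link is a modeling assumption validated here only in
  simulation and by the bundled measured table.
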