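---
title: "Two-stage CAZyme annotation from protein language model embeddings"
author: "cazkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage CAZyme annotation from protein language model embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cazkit)
```

## The problem and the model

Carbohydrate-active enzymes (CAZymes) — glycoside hydrolases (GH),
glycosyltransferases (GT), carbohydrate esterases (CE) and polysaccharide
lyases (PL) — drive glycan synthesis and breakdown in microbial
communities, but a large fraction of metagenomic proteins carrying these
activities escape homology-based annotation: remote homologs conserve fold
and mechanism while their sequences diverge past the reach of alignment
tools. Protein language model (pLM) embeddings summarize a sequence as a
fixed-length numeric vector that captures this deeper structure, and a
classifier over embeddings can therefore recover CAZymes that alignment
misses.

`cazkit` implements that idea as a two-stage classifier over per-protein
embedding vectors:

1. **Gate** (`train_gate`): a random forest (200 trees by default, seeded)
   votes CAZyme versus non-CAZyme. The score of a query is its CAZyme vote
   fraction, a probability-like quantity in $[0,1]$ suitable for
   thresholding and for ROC / precision–recall construction.
2. **Family assignment** (`train_family`): a feed-forward network maps the
   embedding $x \in \mathbb{R}^D$ through two ReLU hidden layers
   ($D \to h_1 \to h_2 \to K$, defaults $h_1 = 256$, $h_2 = 512$) to a
   softmax over the $K$ family/subfamily labels. The label space is always
   derived from the training data (a `family_ontology`), never hard-coded.

The loss is weighted cross-entropy
$\ell(x, c) = -w_c \log p_c(x)$ with $w_c \propto 1/n_c$, the inverse of
the training count of family $c$. Rare families — for CAZymes, notably the
carbohydrate esterases, a few percent of the catalog — would otherwise be
drowned out by the heavily represented GH/GT families. We normalize the
weights to mean 1; the inverse-frequency rule fixes only their ratios, and
mean-1 normalization keeps loss magnitudes comparable across ontologies of
different sizes.

`annotate` chains the stages: every query receives a gate score; only
gate-positives (score $\ge \tau$, default $\tau = 0.5$, exposed as a
parameter) are passed to the family network. Output rows carry
`id`, `gate_score`, `is_cazyme`, `family`, `family_probability`, with
family fields present exactly when the gate fired.

## Training-set curation

The curation module reproduces the protocol used to build the training
sets around such a classifier:

* **Length filter** (`filter_records`): sequences of more than 5,000
  residues are removed; the bound is strict, so a sequence of exactly
  5,000 residues is kept.
* **Deduplication** (`deduplicate`): one representative per identical
  sequence (100% identity); we keep the lexicographically smallest id for
  determinism and merge the duplicates' labels.
* **Redundancy reduction** (`cluster_identity`): greedy longest-first
  clustering at 60% identity — the strategy of the standard external
  clusterer — so that no two representatives share more than 60% identity.
  Identity is matches divided by alignment length from a global alignment
  (BLOSUM62, via Biostrings); both the threshold and the identity function
  are arguments, so an external clusterer can be plugged in unchanged.
* **Negative purge** (`purge_homologs`): any putative non-CAZyme that
  registers a homology hit against the positive set is discarded, and a
  search failure aborts the run — negatives are never silently kept. The
  built-in search is a shared exact 8-mer screen followed by local
  alignment confirmation at $\ge 30\%$ identity over $\ge 50\%$ query
  coverage. These cutoffs are deliberately permissive (cheap to trip, so
  the purge errs toward removing negatives) and configurable; an external
  sensitive aligner can replace the whole search through the same
  function contract.

Ambiguity letters (B, Z, J, U, O) are retained in stored sequences but
folded to X for identity computation.

## The embedding store and embedder contract

Embeddings live in HDF5 files, one float32 dataset per protein keyed by
id — the layout produced by common embedding pipelines — with an alternate
single-matrix layout behind a flag. Reading validates that all vectors
share one dimension and names the offending id otherwise.

The embedder itself is a contract (`make_embedder`): any deterministic
function from a sequence to either a per-protein vector or a per-residue
$L \times D$ matrix. Per-residue output is pooled by the arithmetic mean
over residues (`pool_residue_embeddings`), the usual convention for
deriving per-protein vectors from per-residue pLM output; sum and max
pooling are available because the choice is a convention, not a law.
`embed_records` never skips a record silently: failures are recorded per
id and the run errors unless partial output was explicitly allowed.
Sequences longer than the curation cap are rejected so inference inputs
match the training distribution.

## Hyperparameter search

`train_family` tunes $h_1$, $h_2$, batch size and learning rate by random
search (20 candidates by default; $h_1, h_2 \in [128, 1024]$, batch
$\in [32, 512]$, learning rate log-uniform on $[10^{-4}, 10^{-2}]$) under
a successive-halving schedule: candidates are trained to epoch
checkpoints ("rungs") at $g, g\eta, g\eta^2, \dots$ up to the epoch budget
(default grace $g = 5$, reduction factor $\eta = 2$, budget 100), and at
each rung only the best $1/\eta$ fraction by validation loss continues.
With 8 candidates and $\eta = 2$ the rung occupancy is 8, 4, 2, 1. We run
the halving synchronously: the asynchronous variant exists to keep
parallel workers busy and selects the same survivors at this scale, while
the synchronous form is exactly reproducible from one seed. Each
candidate's minibatch shuffle is seeded per epoch from (seed, candidate,
epoch), so a candidate paused at a rung resumes bit-identically.

The final model is the fully trained survivor with the best validation
accuracy; the per-candidate search report (hyperparameters, epochs
survived, final metrics) is attached to the returned model.

Fixed choices the training text leaves open, recorded in the model
manifest: ReLU activations, softmax output, Adam optimizer
($\beta_1 = 0.9$, $\beta_2 = 0.999$), He initialization. Argmax ties at
prediction break toward the lowest class index, for determinism.

## Benchmarking harness

`precision_recall_f1` implements the standard formulas with the 0/0 → 0
convention on empty denominators, so degenerate classes remain scorable.
`confusion_and_micro_accuracy` pools all classes (trace over total).
`roc_pr_curves` sweeps every distinct score as a threshold (ties grouped,
one point per distinct value, endpoints included) and integrates by
trapezoid. It accepts either polarity — classifier scores where larger is
more positive, or e-values where smaller is — and imputes the worst
possible score for truth ids missing from a third-party hit file, so
curves always cover the full evaluation universe rather than only the
queries the other tool happened to report.

## Interpretability probes

`nearest_neighbors` is an exact Euclidean search against a reference
embedding set (no approximate mode), with ties broken by reference order
and optional self-exclusion.

`sliding_window_probe` asks *where in the sequence* the classification
signal lives: for each window of 10 residues (width and stride are
parameters; coordinates are 0-based half-open throughout), every canonical
residue is replaced by its most distant BLOSUM62 substitution — the
row-minimum of the substitution matrix, ties alphabetical — the mutant is
re-embedded, and the family network's probability for the target class is
recorded against the unmutated baseline. We chose the single
most-distant substitution per residue as the strongest perturbation
consistent with a "more distant substitutions" design; windows whose
perturbation produces the sharpest probability drops are the regions the
embedding depends on. An identity-substitution mode serves as a negative
control (its trace must sit exactly at baseline), and non-canonical
residues are either left unperturbed (default, counted) or treated as X.
The BLOSUM62 table comes from Biostrings and is structurally checked at
load (symmetry; self-scores dominate their row).

## Differential abundance and prioritization

The gene-catalog workflow (`diff_abundance`) runs in an enforced order —
each later stage rejects input the earlier stages should have handled:

1. **Prevalence filter**: genes detected in fewer than 10% of samples are
   removed (strict: exactly 10% is kept).
2. **Zero imputation**: each remaining zero becomes half its gene's
   minimum nonzero value; an all-zero gene at this stage is an error, and
   downstream stages refuse matrices that still contain zeros.
3. **logFC**: $\log_2$ of disease-group mean over control-group mean on
   the imputed counts.
4. **Per-gene model**: counts are $\log_2$-transformed and z-scored
   within the gene (sample standard deviation, $n-1$); an OLS model of
   the z-scores on the disease indicator plus covariates is fit per gene
   (`stats::lm`), and the reported p-value is the two-sided t-test on the
   disease coefficient. Covariates adjust, they are not reported.
   Collinear designs and missing metadata are errors — no silent
   imputation. Zero-variance genes are dropped with a note rather than
   emitting NaN statistics.
5. **BH correction** (`stats::p.adjust`), significance at q ≤ 0.25.
6. **Volcano labels**: ordered disjunctions of (logFC, p) clauses, with
   presets reproducing the labeling criteria used for the Crohn's disease
   and IgG4-related disease catalogs.

`prioritize` ranks predicted CAZymes by the mean of (a) the percentile
rank of the gene's logFC among all tested genes — $(r-1)/(n-1)$ with
average ranks for ties, so the range is exactly $[0,1]$ — and (b) the
predicted family probability. A gene at the top of both scales has
priority 1.

## What the synthetic generators emulate — and what they do not

All tests and the acceptance script run on synthetic data from the
`simulate_*` generators, which are deterministic from their seed:

* `simulate_embeddings`: families as isotropic Gaussian clusters whose
  means sit on a sphere scaled so every pair is at least the requested
  number of within-class standard deviations apart (a heavier-tailed t
  option exists). This is the minimal structure under which both stages
  should succeed; it does **not** reproduce real pLM geometry —
  anisotropy, nested family/subfamily structure, or the correlation
  between sequence length and embedding norm. Passing tests show the
  machinery is correct, not that any particular accuracy will transfer to
  real catalogs.
* `simulate_sequences`: i.i.d. uniform residues with planted structure —
  mutated copies of seeds (for clustering), spliced shared segments (for
  the homology purge), fixed-position motifs (for the probe). Real
  proteins have composition bias and domain structure; random sequences
  make the planted signal the *only* signal, which is exactly what a
  recovery test needs.
* `simulate_counts`: negative-binomial counts (dispersion 0.1) with
  lognormal gene abundances, lognormal per-sample depth factors, a
  configurable fraction of genes carrying a multiplicative disease
  effect (as a fixed log2 fold change, or calibrated per gene in units
  of its log2-scale standard deviation), optional covariate effects, and
  a planted low-prevalence subset. The truth table records every planted
  feature, so downstream recovery is scored without re-deriving ground
  truth.

Study-scale problem sizes used by the test suite and acceptance script,
chosen as representative desk-scale versions of the analysis: two-stage
recovery on 20 families × 60 sequences at dimension 64 and 6σ separation;
imbalance experiments with one family 50× rarer than five common ones;
null calibration on 2,000 genes at n = 30 + 30; power on 200 planted
standardized effects of 1.5 at n = 40 per group.

One calibration note: the Kolmogorov–Smirnov uniformity check on null
p-values assumes independent tests. Shared per-sample depth factors
correlate all genes within a sample, which leaves each gene's p-value
marginally uniform but makes the 2,000 p-values strongly dependent — the
KS statistic then rejects even though the per-gene test is calibrated.
The null-calibration scenario therefore simulates independent features
(no depth variation); scenarios that measure effect recovery keep the
depth factors. In real catalogs the same dependence is one reason a
library-size normalization step usually precedes this kind of model.

## Numerical choices and degenerate inputs

* Weighted cross-entropy clamps $p = 0$ at a configurable
  $\varepsilon = 10^{-12}$ (logged), never returning infinity.
* Softmax subtracts the row maximum before exponentiation.
* The percentile rank of a single gene is defined as 1.
* 0/0 → 0 for precision, recall and F1.
* A single-family ontology yields a network that predicts that family
  with probability 1 (softmax over one class) — degenerate but valid.
* Every training or simulation entry point run twice with the same seed
  produces byte-identical output; this is asserted by the test suite.

## Known limitations

* The built-in negative-purge search is a k-mer screen with alignment
  confirmation, tuned for desk-scale sets; at catalog scale an external
  sensitive aligner should be plugged into the `purge_homologs` contract.
* The greedy clusterer performs all-pairs alignments against cluster
  representatives and is quadratic in the worst case; it is meant for
  fixture- and validation-scale inputs, with the external-tool adapter
  for production use.
* The family network trains on CPU in plain R; at the scale of millions
  of training sequences a GPU implementation behind the same interfaces
  would be the practical choice.
* No taxonomy assignment: the pipeline annotates function only.
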