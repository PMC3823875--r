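---
title: "Kernel-fusion drug repositioning: model, protocols and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-fusion drug repositioning: model, protocols and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Drug repositioning asks which approved drugs might treat which further
diseases. `predr` treats this as supervised link prediction on the bipartite
drug–disease graph of known (gold-standard) treatment associations. The
premise is that similar drugs treat similar diseases, with drug similarity
read off three complementary layers:

* **structure** — binary substructure fingerprints (à la PubChem's 881 keys),
* **activity** — the drug's target proteins, compared by sequence,
* **phenotype** — binary side-effect annotation profiles (à la SIDER).

Diseases are compared by a precomputed phenotype similarity matrix (à la the
OMIM text-mining similarity); computing that matrix is out of scope — it is an
input.

### Drug similarities

For binary profiles (chemical and side-effect), similarity is a *weighted
cosine*: with feature frequencies $h_k$ (column sums) and their population
standard deviation $\sigma_h$,

$$ w_k = \exp\!\left(-\frac{h_k^2}{d\,\sigma_h^2}\right), \qquad
   S(d,d') = \frac{\sum_k w_k x_k x'_k}
   {\sqrt{\sum_k w_k x_k^2}\,\sqrt{\sum_k w_k x'^2_k}} $$

so rare features count more than ubiquitous ones. The smoothing parameter $d$
(dimensionless) defaults to 10. When all features are equally frequent
($\sigma_h = 0$) the weights are uniform and the measure reduces to plain
cosine similarity. The exact algebraic form of the weight is a design choice
of this package: any strictly decreasing function of $h_k$ honours the
rare-features-are-informative rationale, and the chosen Gaussian-in-$h_k$
form keeps the similarity a Gram matrix of rescaled vectors, hence positive
semidefinite. Zero profiles (a drug with no annotated features) get
similarity 0 to everything and 1 to themselves, with a warning — inventing
similarity for them would be worse.

Target-based similarity compares two drugs' target sets $T(d)$, $T(d')$ by
normalized Smith–Waterman sequence similarity
$\mathrm{sw}(p,p')/\sqrt{\mathrm{sw}(p,p)\,\mathrm{sw}(p',p')}$, aggregated
over all cross pairs. The default aggregator is the **maximum** (best-match:
two drugs are similar if *any* of their targets are similar), with `mean` as
an option. Alignment defaults mirror the classic MATLAB toolbox settings:
BLOSUM50 with a linear gap cost of 8 per residue (`gap_open = gap_extend =
8`; a gap of length $k$ costs `gap_open + (k-1) * gap_extend`). The
aggregated matrix need not be positive semidefinite, so it is re-normalized
by its diagonal, $K'_{ij} = K_{ij}/\sqrt{K_{ii}K_{jj}}$ (idempotent), and any
remaining negative spectrum is clipped by `psd_repair()` before SVM training.
Whether to clip or to let the solver face an indefinite matrix is left
configurable (`repair =` argument); clipping is the default because the SVM
dual is only convex for PSD kernels, and the spectral clip is the nearest PSD
matrix in Frobenius norm.

### The pair kernel and the classifier

A (drug, disease) pair kernel is the Kronecker product
$k\big((d,q),(d',q')\big) = K_{dr}(d,d') \cdot K_{di}(q,q')$: two pairs are
similar only when drugs *and* diseases are simultaneously similar. The full
Kronecker Gram over all drug × disease pairs is never materialized (it is
quadratic in #drugs × #diseases); Gram blocks are evaluated lazily for the
pair lists actually needed. The "Comb" variant fuses the three drug kernels
by an unweighted arithmetic mean before pairing (weights are configurable;
no kernel-weight learning is attempted).

Known associations are positives; all other pairs are unlabeled. Balanced
training sets are built by sampling negatives uniformly without replacement
from the unlabeled pairs, one negative per positive, deterministically given
a seed. A soft-margin SVM is trained on the precomputed pair Gram. The
penalty $C$ is chosen by a 3-fold cross-validated grid search once, before
evaluation folds are run — re-tuning inside every fold is available
(`select_per_fold = TRUE`) but is not the default protocol.

**Numerical note on the solver.** Training with a precomputed kernel is done
by factoring the PSD Gram $G = VV^\top$ (eigendecomposition, tiny negative
eigenvalues clipped) and fitting a linear SVM on the rows of $V$ — the exact
same dual problem, and one factorization serves every train/validation split
of a cross-validation because a row subset of $V$ factors the corresponding
Gram submatrix. The stored dual coefficients and intercept are oriented so
positive margins mean predicted association, and prediction uses the pair
kernel directly. The default penalty grid is $2^{-5}, 2^{-3}, \dots, 2^{1}$:
the pair kernel is bounded in $[0,1]$ with unit diagonal, so margins live on
an $O(1)$ scale and small penalties cover the optimum; very large $C$ values
were observed to both degrade validation AUC and stall the solver, and the
grid is an explicit argument everywhere if a wider sweep is wanted.

### Evaluation protocols

* **Stratified 10-fold CV** over labeled pairs (positives + sampled
  negatives). Both per-fold means and pooled (concatenated-score) metrics are
  reported, since pooling conventions differ across studies. The CV unit is
  the pair, not the drug — the per-drug regime is covered separately by LODO.
* **Leave-one-drug-out (LODO)**: each drug's pairs are removed from training
  entirely (from the positives *and* from the negative-sampling candidates,
  so nothing about the held-out drug leaks), the model is retrained, and the
  drug's known diseases are ranked against its other diseases. Per-drug AUCs
  are macro-averaged; a pooled micro-AUC is also reported. Drugs whose
  positives cover every disease are skipped with a warning.
* **Metrics**: AUC with midrank tie handling (= Mann–Whitney); AUPR from the
  precision–recall step curve with no linear interpolation (which would be
  optimistic); accuracy/sensitivity/specificity/precision/F at the threshold
  maximizing F, with F ties broken toward higher sensitivity because
  repositioning favours recall.
* **Trivial-prediction filter**: a positive (d, q) is "trivial" when another
  positive (d', q) exists whose drug has maximum normalized Smith–Waterman
  target similarity ≥ 0.8 to d — the association is explainable by a
  near-identical target. The filter removes edges, not drugs, keeps the
  lexicographically smaller drug's edge on symmetric conflicts (deterministic,
  minimal removal), and returns a removal log.

### Descriptive analyses

`drug_network_distances()` computes shortest paths between drugs in the
bipartite graph (distance 2 ⇔ the drugs share a disease).
`similarity_profile_correlation()` correlates a drug similarity source with
disease-profile similarity (the aggregate phenotype similarity of the
diseases two drugs treat) — overall and on cumulative tails $s \ge$ cutoff
at cutoffs {0, 0.2, 0.4, 0.6, 0.8}. Tails rather than disjoint bins are used
because the tail PCC is the better-conditioned statistic at high cutoffs
where few pairs remain; this is flagged in the output metadata. P-values use
the exact t-transform of $r$ with $n-2$ degrees of freedom, unadjusted.
`rank_novel_predictions()` scores all non-positive pairs and returns the top
100 by default, deterministically tie-broken by (drug id, disease id).

## The synthetic benchmark

No real dataset is bundled; `generate_benchmark()` produces all inputs with
a planted "similar drugs treat similar diseases" structure. Drugs and
diseases fall into latent classes (contiguous near-equal blocks). Each class
has a prototype chemical fingerprint, a prototype side-effect profile
(prototype bits set with probability 0.2 — a realistic sparse fingerprint
density) and a prototype protein sequence (i.i.d. uniform over the 20
residues). Drugs inherit their class prototypes with independent bit flips
(`bit_noise`) and, for each of their 1–3 targets, point substitutions at
`mutation_rate` (no indels, keeping alignment scores well-behaved). Disease
phenotype similarity is a within/between block matrix (0.7 / 0.2) plus
symmetric Gaussian noise (sd 0.05), clipped to [0, 1] with unit diagonal.
Associations are independent Bernoulli draws: probability 0.5 when drug and
disease classes match, 0.02 otherwise. Defaults — 60 drugs, 40 diseases, 4
classes, 200 chemical and 100 side-effect features, `bit_noise` 0.1,
sequence length 120, `mutation_rate` 0.05 — are sized so that the full
evaluation suite completes in minutes on one CPU while leaving the planted
signal clearly recoverable but not saturated.

What the generator does *not* emulate: the heavy-tailed degree distributions
of real drug–disease networks, correlated fingerprint bits, shared targets
across drugs (every drug gets private mutated copies of its class
prototype), and any realistic marginal statistics of the public datasets.
Passing tests on this benchmark therefore demonstrate that the machinery
recovers a planted multi-source signal and that the protocols are leak-free
and deterministic — not that the package reproduces published real-data
accuracies, which require the external benchmark files as inputs.

### Problem sizes used by the test suite

The acceptance-style checks run at sizes chosen to keep the whole suite
within a few minutes of CPU: the signal-recovery and leakage checks use the
default 60 × 40 benchmark; the noise-monotonicity experiment uses 40 drugs ×
24 diseases, 5-fold CV, five replicate benchmarks per noise level, in a
fingerprint-dominant configuration (`pheno_within = 0.45`, `pheno_between =
0.35`, `mutation_rate = 0.3`) — with the default strongly informative
phenotype and target kernels, fusion masks fingerprint corruption almost
entirely, so the regime where fingerprints are load-bearing is the one where
the monotonicity claim is actually testable; the trivial-filter experiment
uses 30 drugs × 20 diseases with `mutation_rate = 0` (same-class drugs then
carry literally identical targets, making "trivial" exactly decidable) and a
within-class association probability of 0.3, which puts the trivial fraction
near one half, and averages over five replicate benchmarks because
single-benchmark AUCs at this size fluctuate by ±0.1.

## Known limitations

* The weighted-cosine weight function and the set aggregator are reasonable
  reconstructions of under-specified conventions; both are pluggable.
* Negative "gold standards" are sampled from unlabeled pairs, so some
  sampled negatives are unknown true positives; this depresses measured
  AUC/AUPR slightly and is inherent to the protocol.
* The fused kernel uses fixed (default uniform) weights; no multiple-kernel
  learning.
* LODO retrains one model per drug; on benchmarks much larger than the
  default its cost grows linearly in the number of drugs.
* P-values in the correlation analysis are not corrected for multiplicity,
  matching the descriptive use they serve.
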