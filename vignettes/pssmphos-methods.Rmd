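---
title: "Methods: evolutionary-profile phosphosite classification in pssmphos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary-profile phosphosite classification in pssmphos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pssmphos)
```

## The model

`pssmphos` treats phosphosite prediction as a per-residue binary
classification problem over evolutionary profiles. The only feature source
is the PSI-BLAST position-specific scoring matrix (PSSM): for a protein of
length $L$, an $L \times 20$ matrix of integer log-odds scores whose row
$i$ describes how well each amino acid is tolerated at position $i$ across
the protein's evolutionary lineage. The working hypothesis is that
conservation patterns in a window around a phosphorylated residue differ
systematically from those around non-phosphorylated residues of the same
type, and that this difference survives even when kinase identity is
unknown — which is what makes the approach applicable to the ~80% of
annotated phosphosites lacking kinase annotation.

A candidate site at position $p$ is encoded by flattening the $W$ PSSM
rows centred on $p$ into a vector of length $k = 20W$. Rows falling
outside $[1, L]$ contribute 20 zeros each; zero is the neutral value in
log-odds space, so terminal sites are neither attracted to nor repelled
from either class by the padding itself.

Three independent classifiers are trained (serine, threonine, tyrosine),
for each of the window sizes $W \in \{7, 9, 11, 13, 15\}$. Each is a
C-support-vector classifier with a radial basis function kernel,
$C = 1$ and $\gamma = 1/k$, producing hard labels only: the system is a
discrete classifier and each configuration occupies a single point
$(\mathrm{FPR}, \mathrm{Sn})$ in ROC space.

### Assumptions

* Positive annotations are trustworthy; absence of annotation is weak
  evidence of absence. This asymmetry drives the negative-labeling rule
  below.
* Profile rows carry the discriminative signal; the raw sequence enters
  only through which residues are candidates.
* Sites are conditionally independent given their windows — no
  protein-level pooling beyond the window.

## Dataset construction

**Negative rule.** A non-annotated S/T/Y residue is labeled negative only
if its distance to *every* annotated phosphosite of the protein (of any
residue type) exceeds 50 positions; otherwise it is excluded from both
classes. "Distance of 50" is read symmetrically as $|\Delta| \le 50
\Rightarrow$ excluded, which matches both the "distance" and the "window
of size 50" phrasings of the rule. Exclusion by sites of any residue type
is deliberate: clustering of phosphosites is not type-specific.

**Corpus scope.** Only proteins with at least one positive annotation
contribute instances (a phosphoprotein corpus); this is configurable
(`phosphoproteins_only = FALSE`) for users who want negatives from
unannotated proteins.

**Balancing.** With $p$ positives and $n$ negatives, the target ratio $f$
negatives-per-positive is met by the stride rule $r = \max(1, \lfloor
n/(f p) \rfloor)$, keeping negatives at 0-based indices $0, r, 2r, \dots$
($\lceil n/r \rceil$ of them). Two consequences worth knowing:

* the realized ratio can exceed $f$ by up to a factor of ~2 when $r$ is
  small (flooring), exactly as in the original protocol — e.g. $n/p = 5.6$
  with $f = 2$ gives $r = 2$ and a realized ratio of 2.8;
* selection is deterministic and order-preserving, so the whole pipeline
  is reproducible byte-for-byte.

**Folds.** The classical protocol says only "divided into three equal
sets". We stratify by class and seed the shuffle: stratification prevents
degenerate single-class folds at small $n$ (a real risk for tyrosine), and
seeding makes every report reproducible. Fold sizes differ by at most one
per class.

## Numerical choices

**Feature scaling (a deliberate deviation).** The classical description
feeds PSSM scores to the SVM without mentioning scaling, and this
package's first implementation did the same. That mode is numerically
degenerate: integer log-odds entries have per-entry variance near 10, so
squared Euclidean distances between two window vectors concentrate around
$2 \cdot \mathrm{Var} \cdot k \approx 3600$ and, at $\gamma = 1/k$, every
off-diagonal kernel entry is $\approx e^{-20}$. The Gram matrix is then
indistinguishable from the identity, every training point becomes a
bounded support vector, and held-out decisions collapse to the majority
class — we measured exactly this (sensitivity pinned at 0 or 100 across
all ratios, Mcc $\approx 0$ even at large planted effect sizes).
Consequently the default is the standard libsvm preprocessing: per-feature
min-max scaling to $[-1, 1]$, with the scaling parameters estimated on the
training set, stored in the model bundle, and applied to every query.
`model_config(..., scale = FALSE)` restores the raw mode for anyone who
wants to reproduce the degenerate behaviour.

**SVM solver.** No SVM package is assumed to be installed; the package
implements sequential minimal optimization for the C-SVC dual in C++
(maximal-violating-pair working-set selection with a second-order choice
of the second index, stopping tolerance $10^{-3}$, full precomputed kernel
in single precision). The test suite cross-checks decision values against
an independent libsvm-backed implementation on a fixed fixture and
requires agreement to within 0.01, with identical hard labels away from
the decision boundary. Training is deterministic given the data order.

**Degenerate metrics.** Rates with empty denominators are reported as 0
and flagged (`undefined`); Mcc is defined as 0 whenever a factor of its
denominator vanishes. Percentages are carried at full precision
internally and rounded half-up only for display (2 decimals in grid
tables, 1 decimal for Q3, matching the conventions of published
comparison tables).

**Fold combination.** Cross-validation reports the arithmetic mean of
each metric across folds ("averaging the performance of the three sets");
pooling the confusion counts first is available via `combine = "pooled"`,
since the two differ when folds are unbalanced. Which of the two the
original tables used is not stated; averaging is the default because it
is the literal reading.

**Q3.** The benchmark score is read as sensitivity on the annotated
positive set: correct positive predictions / annotated positives. This is
the only reading under which a system's Q3 equals its benchmark Sn, which
is the observed relationship in the published comparison tables
(e.g. 152/211 = 72.0%, 57/85 = 67.1%, 74/97 = 76.3%).

**Released models.** The per-(residue, $W$) bundle written by the `train`
command is retrained on the full balanced set after cross-validation; the
original description ambiguously reuses "a model file stored in the
cross-validation phase", and `cross_validate()` keeps its per-fold models
(`fold_models`) for anyone preferring that path.

## The synthetic phosphoproteome generator

Real corpora require PSI-BLAST against a large sequence database plus a
curated phosphosite database, neither of which is available in a
self-contained build. The generator (`sim_config()`,
`simulate_phosphoproteome()`) emulates the statistical features the
classifier actually consumes:

* **Profiles:** i.i.d. integer background scores, discrete uniform on
  $[-5, 5]$ (mean 0, bounded, integer — a valid blastpgp-style matrix).
* **Signal:** an additive mean shift `effect_size` applied to all 20
  columns of the `signal_width` (default 7) rows centred on each planted
  positive — conservation rendered as a localized, symmetric profile
  perturbation. Fractional effect sizes are realized stochastically so the
  mean shift is exact in expectation while scores stay integers.
* **Imbalance:** each protein is laid out as one exclusion block of
  $2 \cdot 50 + 1$ residues per planted site followed by a negative region
  whose expected S/T/Y content delivers the configured
  negatives-per-positive (default 5.6, the serine-like regime; threonine
  and tyrosine corpora run closer to 25). S/T/Y-free padding keeps
  lengths within bounds without perturbing the label counts. When the
  planted residue types are drawn proportionally to the amino-acid
  composition, the realized per-residue imbalance matches the target for
  every type.
* **Gold labels:** the generator records the true label of every S/T/Y
  site, computed by brute force from the planted positions, so the
  pipeline's labeling can be checked for exact agreement
  (`gold_check()`).

What the generator does **not** emulate: kinase motifs (deliberately — the
method under study is kinase-agnostic), correlated profile columns,
composition biases around real phosphosites, disorder context, or
redundancy between homologous proteins. A green end-to-end test therefore
establishes that the pipeline recovers a planted conservation signal under
realistic imbalance — not that the method attains any particular accuracy
on biological data.

**Calibration of the trend fixture.** The ratio-trend acceptance property
(sensitivity rising and specificity falling as the negative share
shrinks across $f = 2 \to 1.5 \to 1 \to 0.5$) is only meaningful if the
classifier operates away from saturation. The fixture's effect size was
therefore calibrated to the published serine operating point at ratio 1:1
(accuracy $\approx 75\%$, Mcc $\approx 0.5$): `effect_size = 0.5` with
`signal_width = 7` lands there (measured 75.7% / 0.51), whereas e.g.
`effect_size = 3` drives every ratio to 100%/100% and erases the
trade-off. The calibration target is the published operating regime, not
the trend itself.

## Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `W` | 15 for prediction; grid 7–15 | window size (residues); larger windows capture wider conservation context, at $20W$ features; 15 is the published optimum before cost explodes |
| `distance` | 50 | exclusion radius (residues) of the negative rule |
| ratio `factor` | 1 | negatives per positive after thinning; 1:1 is the published optimum |
| `C` | 1 | SVC box constraint |
| `gamma` | $1/k$ | RBF width; libsvm's classical default |
| `scale` | `TRUE` | per-feature min-max to $[-1,1]$; see above |
| `folds` | 3 | cross-validation folds |
| `effect_size` | 3 (generator) | mean log-odds shift at signal rows; 0 = null data, 6 = strong recovery regime, 0.5 = published-like operating point |
| `imbalance` | 5.6 | expected negatives per positive after labeling |

## Known limitations

* The SMO solver precomputes the full kernel; memory is $O(n^2)$ floats,
  comfortable to $n \approx 10^4$ instances, which covers per-residue
  balanced corpora of the size used here but not the unbalanced serine
  corpus of a full proteome. Chunked kernels would be the next step.
* Hard labels only: no probability calibration, no ranking within a
  protein.
* The negative rule guarantees nothing about future annotations: some
  negatives are unannotated positives, an irreducible label noise this
  method (like the original) simply tolerates via the SVM's soft margin.
* Benchmark comparison numbers for other predictors are reference data,
  not computations of this package.
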