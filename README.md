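# pssmphos

Kinase-independent prediction of protein phosphorylation sites from
evolutionary information alone.

## The problem

Phosphorylation of serine (S), threonine (T) and tyrosine (Y) residues is
the most common post-translational modification and a central switch in
eukaryotic signalling. Most sequence-based predictors of phosphosites are
trained on kinase-annotated sites, yet only a small fraction of known
phosphosites carry a kinase annotation — such predictors discard most of
the available data and generalize poorly outside their kinase cliques.
`pssmphos` implements the alternative: classify candidate S/T/Y sites
using *only* the evolutionary conservation profile of the protein, i.e.
the position-specific scoring matrix (PSSM) produced by iterative profile
search (PSI-BLAST against a non-redundant database).

It is aimed at computational biologists who want a transparent,
self-contained reference implementation of this classical approach —
including its dataset construction rules and evaluation protocol — and a
synthetic-data harness that makes every stage testable without PSI-BLAST,
a sequence database, or a phosphosite corpus.

## The method

For a protein of length *L*, the PSSM is an *L* × 20 integer matrix of
log-odds scores. A candidate site at position *p* is encoded by
concatenating the *W* score rows centred on *p* (rows outside the sequence
contribute zeros) into a feature vector of length *k* = 20·*W*, for
*W* ∈ {7, 9, 11, 13, 15}.

**Labels.** Annotated sites are positive. A non-annotated S/T/Y residue is
*negative* only if it lies more than 50 residues from every annotated
phosphosite of its protein; nearer sites are *excluded* from both classes
(they are too likely to be unannotated positives).

**Class balance.** Negatives outnumber positives roughly 5–25×. With *p*
positives and *n* negatives, a target ratio *f* negatives-per-positive
(*f* ∈ {2, 1.5, 1, 0.5}) is achieved by keeping every *r*-th negative,
*r* = max(1, ⌊*n*/(*f·p*)⌋), starting from the first; positives are never
subsampled.

**Classifier.** One binary SVM per residue type and window size — an RBF
kernel C-SVC with *C* = 1 and *γ* = 1/*k*, emitting hard labels
(+1 phosphosite / −1 not). Because no SVM implementation is available in
the target environment, the package ships its own SMO solver (in C++),
validated against libsvm-based implementations. Features are min-max
scaled to [−1, 1] per feature by default (see the methods vignette for
why raw integer scores break the RBF kernel at γ = 1/k).

**Assessment.** Stratified 3-fold cross-validation reporting
Ac = (TP+TN)/total, Sn = TP/(TP+FN), Sp = TN/(TN+FP),
Mcc = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)) and FPR = FP/(FP+TN);
each (residue, W, ratio) cell is a hard classifier and hence one point
(FPR, Sn) in ROC space. On an independent benchmark the headline number is
the Q3 score: the fraction of annotated positive sites predicted positive.

## Worked example

```r
library(pssmphos)

## 1. simulate a small phosphoproteome (40 proteins, realistic signal)
cfg <- sim_config(n_proteins = 40, effect_size = 0.5, imbalance = 5.6,
                  seed = 101)
sim <- simulate_phosphoproteome(cfg, dir = "fixture")
site_count_summary(sim$profiles, sim$annotations)
#>   residue positive negative excluded
#> 1       S       27      136      378
#> 2       T       25      120      300
#> 3       Y        6       62      146

## 2. windowed instances for serine, W = 9, balanced ~1:1
built <- build_instances(sim$profiles, sim$annotations, residue = "S", W = 9)
plan  <- balance_plan(n_instances(built$positives),
                      n_instances(built$negatives), factor = 1)
plan
#> <balance_plan> p=27 n=136 factor=1 -> keep every 5-th (28 kept)
train_set <- merge_instances(built$positives, balance(built$negatives, plan))

## 3. three-fold CV with the standard RBF SVM (C = 1, gamma = 1/180)
cv <- cross_validate(train_set, model_config("S", W = 9), folds = 3,
                     seed = 101)
cv$overall
#> <metrics_report> Ac=61.60% Sn=25.93% Sp=96.30% Mcc=0.30 FPR=0.04

## 4. persist per-residue models, then predict all S/T/Y sites of a protein
for (res in c("S", "T", "Y")) {
  b  <- build_instances(sim$profiles, sim$annotations, residue = res, W = 9)
  pl <- balance_plan(n_instances(b$positives), n_instances(b$negatives), 1)
  m  <- train_model(merge_instances(b$positives, balance(b$negatives, pl)),
                    model_config(res, W = 9))
  save_bundle(m, file.path("fixture", bundle_filename(res, 9)))
}
head(predict_protein(sim$profiles[[1]], "fixture", W = 9), 4)
#>    protein_id position residue label W
#> 14    SYN0001        7       T    -1 9
#> 15    SYN0001        8       T    -1 9
#> 1     SYN0001       14       S    -1 9
#> 16    SYN0001       16       T    -1 9
```

Reading the numbers: the toy corpus has 27 positive serines against 136
negatives (5.0:1 imbalance); stride-5 thinning leaves 28 negatives. At
this deliberately weak effect size the cross-validated classifier is
conservative — sensitivity 25.9% at specificity 96.3% (Mcc 0.30), the
high-specificity corner of ROC space, exactly the regime seen at
negative-heavy training ratios on real corpora. The prediction table has
one row per candidate site; label −1 means "not a phosphosite".

The small `fixture/` directory written above also contains blastpgp-style
`.pssm` files, a FASTA and the annotation TSV, so the same analysis can be
driven from the shell:

```sh
Rscript inst/cli/pssmphos.R simulate --out fixture --seed 101 --n-proteins 40
Rscript inst/cli/pssmphos.R cv --profiles fixture \
    --annotations fixture/annotations.tsv --out cvout \
    --residues S --windows 9,15 --ratios 2,1.5,1,0.5 --seed 101
```

For real proteins, generate the PSSM externally (the exact command is
rendered by `blastpgp_command("P16386.seq", "P16386.pssm")`) and feed the
resulting file to `parse_pssm()` / the `predict` subcommand.

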