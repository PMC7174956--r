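# stackDBP

Prediction of DNA-binding proteins (DBPs) from evolutionary profiles with a
two-stage stacked ensemble, in R.

DNA-binding proteins regulate transcription, replication, recombination and
repair; recognising them from sequence alone is a standard binary
classification task in protein bioinformatics. The strongest sequence-only
predictors work from profile hidden Markov models (HHsuite `.hhm` files,
built externally by iterative HHblits searches) rather than from the raw
sequence. stackDBP implements such a predictor end to end, for
bioinformaticians who have per-protein `.hhm` profiles and labels and want a
reproducible, testable pipeline.

## Method

From the L×20 match-emission block of each profile, scores x (in units of
−1000·log₂ p, `*` marking negligible probability) are normalized entrywise:

    f(x) = 0        if x = *
    f(x) = 2^(−x/1000)  otherwise

giving h ∈ [0,1]^(L×20). Each protein becomes a 420-dimensional vector:

* **AAC** (20): column means x_j = (1/L) Σ_i h_ij — the average
  evolutionary propensity toward amino-acid type j;
* **TPC** (400): y_ij = Σ_k h_ki·h_(k+1)j / Σ_j' Σ_k h_ki·h_(k+1)j' —
  a row-normalized first-order sequence-order summary over consecutive
  positions (zero-evidence rows stay all-zero).

Classification is stacked generalization: base classifiers (default SM1 =
KNN, logistic regression, decision tree, RBF-SVM; SM2–SM5 variants and
custom sets available) emit **out-of-fold** positive-class probabilities on
stratified folds, and a gradient-boosted decision tree (GBDT)
meta-classifier combines them. Evaluation offers the field's jackknife
(leave-one-out), stratified k-fold with pooled out-of-fold metrics, and
independent-test protocols, reporting OA, SN, SP, MCC (square-root
denominator; zero when a denominator factor vanishes) and trapezoidal
ROC/AUC.

A synthetic profile generator (`generateDataset()`) emits parseable `.hhm`
files from class-biased Dirichlet emission models with a controllable
`separation` knob, so the whole pipeline is testable offline; see the
vignette in `vignettes/` for its semantics and limits.

## Worked example

```r
library(stackDBP)

cfg <- SimulationConfig(nPos = 50, nNeg = 50, separation = 0.5, seed = 1)
ds  <- generateDataset(cfg, "profiles")       # writes .hhm files + labels.tsv
fm  <- batchEncode(ds)                        # 100 x 420 feature matrix

report <- kfoldEvaluate(StackConfig("SM1", seed = 1), fm, k = 10)
report
```

```
EvaluationReport [kfold(k=10, seed=1)]
  counts: TP=45 FP=4 TN=46 FN=5
  OA=91.00% SN=90.00% SP=92.00% MCC=0.8202 AUC=0.9648
```

The counts are the pooled out-of-fold confusion table over all 100
proteins; OA/SN/SP are overall accuracy, sensitivity (positive = DBP) and
specificity; MCC is the Matthews correlation and AUC the area under the
pooled ROC curve. A model for new proteins is then trained on everything:

```r
model <- trainStacked(StackConfig("SM1", seed = 1), fm)
predictProba(model, fm[1:3])   # positive-class probabilities
#> [1] 0.9930 0.9896 0.9930
```

The same pipeline runs from the shell via `inst/scripts/stackdbp.R`
(`simulate`, `extract-features`, `train`, `predict`, `evaluate`), each
command writing a JSON run manifest next to its output.

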