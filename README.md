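# mkscreen

Ligand-based virtual screening for compounds that promote megakaryocyte
(MK) differentiation and platelet production — the drug class sought for
treating radiation-induced thrombocytopenia. Given a small set of known
inducers and a large set of inactives, the package trains a hybrid
neural-network classifier on molecular fingerprints and ranks unlabeled
compound libraries by predicted activity.

## The method

Training data for this activity is tiny and imbalanced (tens of inducers
against hundreds of inactives), so the pipeline prepares it before any
model sees it:

1. **SMILES enumeration** — each molecule admits many valid SMILES
   spellings; emitting randomized spellings of every inducer expands the
   minority class k-fold (default 20×, e.g. 38 → 760 records) without
   inventing chemistry.
2. **Tanimoto / MaxMin balancing** — within each class, greedy MaxMin
   selection on the distance *d* = 1 − *T<sub>c</sub>* (Tanimoto
   coefficient *T<sub>c</sub>* = |A∩B| / |A∪B| over fingerprint bits) keeps
   the *n* most mutually dissimilar molecules (default 500 per class),
   removing augmentation and dataset redundancy.
3. **Dual fingerprints** — MACCS keys (166 public keys in the conventional
   167-slot vector) and Morgan/circular fingerprints (radius 2, 2048 bits).

Three classifiers share one protocol (binary cross-entropy, Adam with
learning rate 10⁻³, 20 epochs, batch 32, stratified 80/20 split, three
replicates whose sigmoid outputs are averaged):

* **CNN** — embedding of the 167 MACCS bits → 1-D convolution (330
  filters, window 16, stride 1) → global max pooling → dense-128 ReLU →
  sigmoid;
* **DNN** — Morgan bits → dense 2048/64/16 ReLU stack → sigmoid;
* **HCD** — both trunks minus their heads, concatenated (128 + 16 = 144)
  under a single sigmoid, trained end to end.

Evaluation reports ACC, PRE, recall, F-value, the Matthews correlation
coefficient

> MCC = (TP·TN − FN·FP) / √((TP+FN)(TN+FP)(TP+FP)(TN+FN)),

and the ROC / precision-recall curves with their areas. Screening assigns
each library compound the replicate-mean score in [0, 1]; compounds scoring
**strictly above 0.5** are called active, and the library is returned
ranked. A seeded synthetic-library generator with a planted catechol-ester
substructure rule makes the whole pipeline testable without any external
dataset.

## Worked example

Train a small hybrid model on a synthetic planted-rule library and screen
a spiked library:

```r
library(mkscreen)

lib <- generate_library(n_pos = 60, n_neg = 60, seed = 7)
sp  <- split_dataset(labels = lib$label, fraction = 0.8, seed = 7)
train <- lib[sp$train, ]; test <- lib[sp$test, ]
class(train) <- class(test) <- c("compound_set", "data.frame")

model <- activity_model(train, arch = "hcd",
                        config = train_config(epochs = 10, replicates = 1,
                                              seed = 7))
print(model)
#> activity_model (HCD): 1 replicate(s), trained on 96 molecules
#>   protocol: 10 epochs, batch 32, Adam lr 0.001, dropout 0.2
#>   final training loss (mean over replicates): 0.0020

evaluate_model(model, test)
#> metric_report (threshold 0.50): n = 24
#>   ACC 1.000  PRE 1.000  recall 1.000  F-value 1.000  MCC 1.000
#>   AUROC 1.000  AUPRC 1.000

scr  <- generate_screening_library(n = 50, spiked_actives = 5, seed = 7)
hits <- screen_library(model, scr$library)
head(as.data.frame(hits), 4)
#>      id                                                smiles     score active rank
#> 1 lib27           C(=O)Oc1ccc(O)c(O)c1C1CCNCC1CCOc1ccc(Cl)cc1 0.9999879   TRUE    1
#> 2 lib23           C1CCCC1c1ccc(Cl)cc1C(=O)Oc1ccc(O)c(O)c1CCOC 0.9999117   TRUE    2
#> 3 lib13                CCOCc1ccc(O)c(O)c1C(=O)Oc1ccc(O)c(O)c1 0.9994450   TRUE    3
#> 4 lib30 C=Cc1ccccc1C1CCCCC1C(=O)Oc1ccc(O)c(O)c1c1ccc2ccccc2c1 0.9980665   TRUE    4

sum(scr$truth %in% hits$id[1:5])
#> [1] 4
```

The 24-molecule held-out set is classified perfectly (the planted rule is
noise-free and perfectly informative — see the methods vignette for what
this does and does not demonstrate). The four top-ranked library compounds
are spiked actives, the fifth spike ranks sixth, and the intervening
compounds at ranks 5 and 7 are decoys carrying a bare catechol without the
ester linkage — exactly the near-motif chemistry the generator plants to
keep the task non-trivial.

A shell interface wrapping the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/mkscreen.R simulate --out data --seed 1
Rscript inst/cli/mkscreen.R prepare  --pos data/pos.smi --neg data/neg.smi \
                                     --out prep --seed 1
Rscript inst/cli/mkscreen.R train    --pos prep/pos_selected.smi \
                                     --neg prep/neg_selected.smi \
                                     --out run --seed 1
Rscript inst/cli/mkscreen.R screen   --model run/model.rds \
                                     --library data/library.smi \
                                     --out hits.csv
```

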