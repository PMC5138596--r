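# rgenescan

Identification of resistance (R) genes — genes whose protein products carry
immune or defense function — from protein sequences, by supervised
classification on physicochemical sequence descriptors. The package is
aimed at researchers who have a curated positive set (R-gene products), a
negative set (unrelated protein families), and a proteome to screen, and
who want a reproducible, testable pipeline rather than a web form.

## What it implements

* **188-D descriptor** (`extract_188()`): 20 amino-acid-composition
  percentages plus, for each of 8 physicochemical properties that partition
  the alphabet into three groups, 21 composition/transition/distribution
  (CTD) features:
  `C_j = 100 n_j / L`,
  `T_jk = 100 (N_jk + N_kj) / (L - 1)`,
  and per group the positions of the first/25%/50%/75%/last occurrence as
  `100 * pos / L`. Total dimension `20 + 8×21 = 188`.
* **Pse-AAC** (`extract_pseaac()`): type-I pseudo amino acid composition,
  `p_u = f_u / (Σf + ωΣe)` for `u ≤ 20` and
  `p_{20+j} = ω e_j / (Σf + ωΣe)`, with lag-`j` correlation factors
  `e_j = mean_i Θ(r_i, r_{i+j})` over standardized hydrophobicity,
  hydrophilicity and side-chain-mass scales. Defaults `λ = 10`, `ω = 0.05`
  give a 30-component probability vector.
* **Redundancy removal** (`cluster_greedy()`, `dereplicate()`): greedy
  incremental clustering at an identity threshold (default 0.70), identity =
  identical aligned positions / shorter length.
* **Class balancing** (`under_sample()`, `weighted_sample()`): random
  under-sampling with a majority hold-out, or per-instance class weights
  (inverse-frequency, or fixed such as 10/7).
* **Classification + evaluation** (`train_model()`, `cross_validate()`):
  seeded Random Forest (100 trees, `mtry = √p`) with SVM/naive-Bayes
  baselines behind one interface; SN, SP, Acc,
  `MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, and ROC area by
  the rank statistic; stratified k-fold CV with pooled scoring.
* **Synthetic data** (`generate_dataset()`,
  `generate_redundant_families()`): two sequence classes whose emission
  distributions differ by a tunable total-variation `effect`, plus
  mutated-family fixtures — every stage is testable offline.
* **Pipeline** (`run_pipeline()` and the `inst/cli/rgenescan.R` script):
  curate → extract → balance → train → evaluate → predict, with seeds and a
  config hash recorded in every run directory.

## Worked example

Simulate two classes with a modest compositional signal, extract 188-D
features, balance, cross-validate, and screen the whole set:

```r
library(rgenescan)

d     <- generate_dataset(generator_config(n_pos = 60, n_neg = 80,
                                           effect = 0.1, seed = 42))
feats <- extract_188_batch(d$records)
ds    <- labeled_dataset(feats, d$labels$label)
bal   <- under_sample(ds, seed = 42)        # 60/60 train, 20-negative hold-out

cross_validate(bal$train, learner_spec("random_forest"), k = 10, seed = 42)
#> Evaluation (cv10, n = 120):
#>   SN = 0.9000  SP = 0.9167  Acc = 90.8333%  MCC = 0.8168  ROC area = 0.9754

model <- train_model(bal$train, seed = 42)
preds <- predict_model(model, feats)
summarize_predictions(preds)$pct_formatted
#> [1] "43.5714"
```

Reading the numbers: of 120 balanced training instances under 10-fold CV,
90.0% of true positives and 91.67% of true negatives are recovered (54 + 55
of 120 correct, hence Acc 90.83%); MCC 0.82 indicates strong agreement well
above chance, and the ROC area 0.975 says positives outrank negatives in
97.5% of cross-class pairs. Scoring all 140 generated records labels
43.5714% of them R-gene. At `effect = 0` the same pipeline stays at chance
— the null check that guards against feature or fold leakage.

The same workflow runs from a shell:

```sh
Rscript inst/cli/rgenescan.R simulate --n-pos 60 --n-neg 80 --effect 0.1 --seed 42 --out demo
Rscript inst/cli/rgenescan.R extract --fasta demo.fasta --method ctd188 --out demo.features.tsv
Rscript inst/cli/rgenescan.R run --pos positives.fasta --neg negatives.fasta \
    --query proteome.fasta --method ctd188 --sampling under --cv 10 --seed 42 --out-dir run1
```

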