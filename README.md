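# foldstack

Consensus RNA secondary-structure prediction from the outputs of several
folding algorithms.

Individual structure predictors — thermodynamic folders, probabilistic
grammars, deep networks — disagree substantially on the same sequences
even when their average accuracies are similar, because each captures
only part of the folding rules. `foldstack` treats those programs as
*base learners*: their predicted structures for a sequence of length $n$
are stacked into a binary array $A \in \{0,1\}^{l \times n \times n}$ of
contact maps, and a small trainable ensemble turns the stack into one
consensus structure that is typically better than every member.

Two ensembles are implemented:

- an **attention network**: channel attention over the learner axis
  ($F_p = \sigma(\mathrm{MLP}(\mathrm{avgpool}\,A) +
  \mathrm{MLP}(\mathrm{maxpool}\,A))$), spatial attention over the
  pairing matrix (a learned $7{\times}7$ convolution over channel-pooled
  descriptors, $F_d = \sigma(\mathrm{Conv}[\mathrm{avg};\mathrm{max}])$),
  and a linear channel head giving per-pair probabilities
  $Y_{ij} = \sigma(\sum_c w_c A''_{c,ij} + b)$ — a few hundred parameters
  in total;
- a **lite** variant: one softmax-normalized weight per learner,
  $Y = \sum_v \pi(v)\,A_v$.

Both are trained with positively re-weighted binary cross-entropy
(positive-class weight 300 by default, Adam, batch 4) against known
structures, with analytic gradients written out in R and verified against
finite differences. Probability maps are decoded into valid structures —
canonical (A-U, G-C) plus wobble (G-U) pairs only, symmetric, minimum
pairing distance $|i-j| \ge 4$, at most one partner per base — by
symmetrizing and masking the map ($\phi(Y) = \tfrac12(Y + Y^\top)\odot M$)
and solving the sparsity-penalized matching problem
$\max_{\hat Y}\ \langle \hat Y, \phi(Y)\rangle - \rho\|\hat Y\|_1$,
either exactly (blossom maximum-weight matching, in C++) or by an
iterative relaxation with feasibility rounding.

Around this core the package provides FASTA / dot-bracket / CT / BPSEQ
readers and writers (pseudoknot bracket layers included), base-pair
evaluation metrics (precision, recall, F1, and INF — numerically the
Matthews correlation coefficient), Jaccard concordance and error-map PCA
across algorithms, ROC curves, an exhaustive search over base-learner
combinations, and a synthetic structure generator plus base-learner
simulator so everything is trainable and testable without any external
prediction tool. See the methods vignette
(`vignettes/ensemble-methods.Rmd`) for models, assumptions and design
choices.

## Worked example

Simulate 60 structures with four diverse fallible learners (sensitivity
0.8, 8 spurious pairs per 100 nt, distinct error biases), train the lite
ensemble on 48, and evaluate on the held-out 12:

```r
library(foldstack)

panel <- default_learner_panel(sensitivity = 0.8, false_pair_rate = 8)
cfg <- synthetic_structure_config(n_range = c(40, 80))
examples <- lapply(1:60, function(k) {
  rec <- generate_structure(cfg, seed = 100 + k, id = sprintf("rna%02d", k))
  stack <- simulate_stack(rec$structure, rec$sequence, panel, seed = 200 + k)
  training_example(stack, rec$structure, rec$sequence)
})

fit <- train_ensemble(examples[1:48], examples[49:60],
                      cfg = train_config(epochs = 15, learning_rate = 0.05,
                                         seed = 1, val_every = 5),
                      variant = "lite")
round(lite_softmax(fit$params$raw_weights), 3)
#> [1] 0.377 0.287 0.136 0.200

f1 <- function(pred, truth) pair_metrics(confusion(pred, truth))$f1
test <- examples[49:60]
sapply(1:4, function(v) {
  median(sapply(test, function(e)
    f1(contact_map_from_matrix(e$stack$maps[[v]]), e$truth)))
})
#> [1] 0.7157191 0.7084942 0.8117647 0.7602627

median(sapply(test, function(e)
  f1(decode(ensemble_predict(e$stack, fit$params), e$seq), e$truth)))
#> [1] 0.9396051
```

The learned weights favor the less biased learners, and the decoded
consensus reaches a median F1 of 0.94 on held-out structures where the
best single learner reaches 0.81: pairs supported by several learners are
kept, isolated spurious pairs are voted away, and the matching step
enforces a valid structure.

The same pipeline is available from the shell via the bundled CLI
(`inst/cli/foldstack`): `simulate`, `train`, `predict`, `evaluate`,
`concord` and `combinations` subcommands, each writing a resolved-config
snapshot with all seeds next to its outputs.

```sh
Rscript inst/cli/foldstack simulate --out data --n 50 --seed 1
Rscript inst/cli/foldstack train --data data --out run --variant lite --epochs 20 --lr 0.05 --seed 1
Rscript inst/cli/foldstack predict --data data --checkpoint run/checkpoint.json --out pred
Rscript inst/cli/foldstack evaluate --pred pred --truth data/truth --out eval.tsv
```

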