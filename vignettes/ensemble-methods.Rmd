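---
title: "Ensembling RNA secondary-structure predictions: models, training and decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensembling RNA secondary-structure predictions: models, training and decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An RNA secondary structure is a set of base pairs: position $i$ pairs with
position $j$, each position pairs at most once, and (in this package's
representation) the structure is the binary symmetric contact map $Z \in
\{0,1\}^{n \times n}$ with $Z_{ij} = 1$ iff $i$ and $j$ pair. Many
prediction algorithms exist — thermodynamic folding, probabilistic
grammars, deep networks — and their outputs disagree substantially on the
same sequences even when their headline accuracies are similar. Each
algorithm captures part of the folding rules; an ensemble that learns how
much to trust each *base learner*, and where, can beat every individual
member, and is far less prone to overfitting than a full structure
predictor because it has only a handful of parameters.

`foldstack` implements two such ensembles over a stack of base-learner
contact maps $A \in \{0,1\}^{l \times n \times n}$ ($l$ learners), plus
everything needed to use and evaluate them: structure file I/O,
hard-constraint decoding, evaluation metrics, concordance analysis, a
combination search over learner subsets, and a simulator that stands in
for the external prediction tools.

## The attention ensemble

The full model applies two attention stages in sequence, following the
channel-then-spatial design of convolutional block attention (CBAM), and a
linear channel-reduction head:

1. **Channel attention over learners.** Each learner's matrix is pooled
   over both spatial dimensions by average and max; both pooled vectors
   pass through a shared two-layer perceptron ($l \to l/r \to l$, ReLU
   hidden layer) and are summed and squashed:
   $F_p = \sigma(\mathrm{MLP}(\mathrm{avgpool}(A)) +
   \mathrm{MLP}(\mathrm{maxpool}(A)))$, giving one weight in $(0,1)$ per
   learner: $A'_c = F_p[c]\,A_c$. The reduction ratio defaults to $r = 1$:
   with a typical $l = 4$ there is no dimension worth bottlenecking (the
   conventional $r = 16$ of image-scale CBAM would be impossible).
2. **Spatial attention over the pairing matrix.** The rescaled stack is
   pooled along the learner axis (average and max) into a two-channel
   $n \times n$ descriptor, convolved with a learned $7 \times 7$ kernel
   (same-padding, so the map keeps its shape for any $n$), and squashed:
   $F_d = \sigma(\mathrm{Conv}_{7\times7}([\mathrm{avg}; \mathrm{max}]))$,
   then $A''_c = F_d \odot A'_c$. The $7 \times 7$ receptive field spans
   helix-sized neighborhoods: true pairs come in diagonal runs (stems),
   spurious pairs tend to be isolated, and this stage is what lets the
   model suppress the latter.
3. **Channel head.** The refined stack must become a single per-pair
   probability for the loss and the decoder. A learned linear mix across
   channels with a sigmoid, $Y_{ij} = \sigma(\sum_c w_c A''_{c,ij} + b)$,
   is the minimal end-to-end-differentiable choice. The head initializes
   at $w_c = 4$, $b = -2$, i.e. a soft vote count, which is already a
   sensible ensemble before any training.

No residual connection from $A$ to $A''$ is used; the head sees only the
attention-refined stack. The whole model has $2l^2 + 2l + 99 + l + 1$
parameters (217 for $l = 4$).

**The lite ensemble** replaces all of this with one raw weight per
learner, softmax-normalized so the weights are positive and sum to one,
and predicts the weighted sum $Y = \sum_v \pi(v) A_v$. Because $\pi$ is a
simplex point and the $A_v$ are binary, $Y$ is already in $[0,1]$ and no
squashing is applied. This variant is convex-ish, nearly free to train,
and remarkably competitive.

## Training

Both variants minimize positively re-weighted binary cross-entropy over
the cells of the contact map. A structure of length $n$ has roughly $n/2$
positive cells among $n^2$, so positive cells are up-weighted by
`pos_weight` (default 300) inside the loss; training uses Adam (default
learning rate $10^{-3}$, exposed in `train_config()`), batches of 4 with
zero-padding to the batch maximum and validity masks so padding
contributes exactly nothing to any loss or gradient, and per-epoch
shuffling driven by the seed. Gradients are analytic (hand-derived
backpropagation through both attention stages, the convolution and the
head) and are checked against central finite differences in the test
suite at tolerance $10^{-4}$; the implementation is pure R with
vectorized matrix arithmetic.

Model selection follows validation F1: after every `val_every` epochs the
current model's probability maps are decoded with the default decoder and
the median F1 over the validation set is recorded; the returned checkpoint
is the best-validation epoch. F1 was chosen as the selection metric
because it is the evaluation metric used everywhere else; cell-wise
accuracy is uninformative at this class imbalance. Probabilities exactly 0
or 1 (possible for the lite variant on unanimous cells) are clamped at
$10^{-7}$ inside the loss.

Sequences longer than `max_len` (default 500) are excluded from training
with a warning rather than truncated. Crossing (pseudoknotted) pairs in
ground truth are kept as positives by default; `load_dataset(...,
drop_pseudoknots = TRUE)` (CLI flag `--drop-pseudoknots`) reproduces the
pseudoknot-free regime by greedily removing crossing pairs.

## Constrained decoding

A probability map is not a structure: decoded output must satisfy four
hard constraints — (1) only canonical (A-U, G-C) plus wobble (G-U) pairs,
(2) symmetry, (3) a minimum pairing distance $|i - j| \ge 4$ (three
unpaired bases is the smallest sterically plausible hairpin loop), and
(4) at most one partner per base. Decoding proceeds as:

1. the constraint mask $M$ from the sequence (rules 1 and 3; residues
   outside ACGU can never pair);
2. the symmetrization $\phi(Y) = \tfrac12 (Y + Y^\top) \odot M$;
3. a confidence floor: entries of $\phi(Y)$ not exceeding the threshold
   $P$ (default 0.5) are zeroed;
4. the sparsity-penalized matching problem
   $\max_{\hat Y} \langle \hat Y, \phi(Y) \rangle - \rho \|\hat Y\|_1$
   subject to row sums $\le 1$, entries in $[0,1]$, symmetry;
5. thresholding at $P$ (strict inequality) and a final assertion of all
   four constraints.

The penalty $\|\hat Y\|_1$ is read as the entrywise sum — the
interpretation under which $\rho$ literally controls sparsity and the
optimization becomes a maximum-weight matching on the graph of positions
with edges $\{(i,j): \phi(Y)_{ij} > \rho\}$ and weights
$\phi(Y)_{ij} - \rho$. Two solvers are provided:

- **exact** (default): the blossom method (Galil's $O(V^3)$ primal-dual
  algorithm), implemented in C++. It returns a certified-optimal binary
  assignment and is fast far beyond the package's length limit.
- **relaxation**: projected gradient ascent on the box/row-sum polytope
  for a fixed iteration budget (default 200), then feasibility rounding
  (greedy matching in ascent-score and in weight order) and a bounded
  alternating-path/cycle local search. This is the iterative style of
  post-processing used by end-to-end structure predictors; the exact
  solver doubles as its benchmark. Plain thresholding of the relaxed
  solution is unreliable — the fractional matching polytope has
  half-integral vertices whose $0.5$ entries a strict threshold discards —
  which is why the rounding and local-search stages exist.

A design note on ordering: applied literally, "solve the matching, then
threshold" makes the threshold inert for the exact solver (its output is
already binary), and with $\rho = 0$ every strictly positive entry —
sigmoid outputs are never zero — would be eligible for pairing, so decoded
structures would approach perfect matchings of the allowed-pair graph.
The confidence floor in step 3 resolves this: both solvers prune the same
low-confidence cells, the threshold retains its meaning for soft
solutions, $\rho$ and $P$ keep their separate roles (objective trade-off
vs. confidence), and decoding the ground-truth matrix remains an exact
fixed point. Defaults are $\rho = 0$, $P = 0.5$; both are exposed.

## The simulator: what it emulates and what it does not

The synthetic generator emits pseudoknot-free nested structures from a
stochastic grammar: helices open at random positions; a helix stacks
another pair with probability `stem_extension_prob` (0.75, mean stem
length 4); a closed helix opens a multi-branch loop with probability
`branch_prob` (0.15), continues through a 1-3 nt bulge/interior loop when
the enclosed region is too large for a plausible hairpin, and otherwise
closes a hairpin of at least `min_loop` (3) unpaired bases. Paired
positions get Watson-Crick complements, or G-U wobble with probability
`gu_fraction` (0.15); loops are uniform random. Generated structures are
40-80 nt by default, with roughly half of the positions paired —
consistent with real structured RNAs of this size. Every generated or
simulated structure satisfies all four hard constraints by construction.

Simulated base learners keep each true pair with probability
`sensitivity` and add Poisson(`false_pair_rate`·n/100) spurious pairs
drawn from the constraint-allowed, currently-unpaired cells, with
sampling skewed by a per-learner bias (uniform, register-shift,
long-range or short-range). The default panel (four learners, sensitivity
0.8, 8 false pairs per 100 nt, distinct biases) reproduces the
concordance regime observed between real algorithms — mean pairwise
Jaccard distance around 0.6, within the 0.3-0.65 band reported for real
predictor panels — which is the property that makes ensembling
worthwhile. What the simulator does *not* emulate: family-dependent
accuracy, shared systematic errors between learners trained on the same
data, pseudoknotted truths, and length-dependent degradation. Passing
tests on synthetic stacks therefore demonstrates the machinery — that the
ensembles learn to exploit learner agreement and context — not
benchmark-level accuracy on real RNA families.

## Evaluation conventions

Counts are taken over unordered position pairs $i < j$ (universe size
$n(n-1)/2$), never the full matrix: symmetric cells would double every
count and the diagonal cannot pair. This inflates neither precision nor
recall but does set the magnitude of TN and hence of INF (interaction
network fidelity), which equals the Matthews correlation coefficient over
this universe — an identity the test suite verifies against an
independently computed correlation on 1000 random count vectors. Scoring
is exact-match only (no one-position slip tolerance). All 0/0 ratios
(empty prediction and/or empty truth, empty Jaccard union) are defined as
0 and flagged. ROC curves pool the masked upper-triangle scores of all
sequences and sweep one threshold.

The per-algorithm error-map PCA flattens each prediction's squared-error
map against truth (upper triangle), concatenates over sequences into one
feature vector per algorithm, and takes the first two principal
components; algorithms with similar error structure land together, and the
embedding's distances rank-correlate with the Jaccard concordance matrix
on simulated panels.

## Experiment sizes and numerical choices

The bundled experiments (test suite and `scripts/acceptance.R`) use 300
simulated structures of 40-80 nt with a 240/60 train/test split, 20
training epochs (learning rate 0.05 for lite, 0.01 for the attention
network, validation every 5 epochs), and the default decoder. These sizes
were chosen so the full suite runs comfortably on one CPU core while the
measured effects (ensemble gain over the best single learner,
oracle-weight recovery above 0.9) remain unambiguous. The combination
search demonstration uses a heterogeneous four-learner panel (sensitivity
0.90/0.80/0.70/0.55) because ranking subsets by strength requires a
strongest learner to exist. Tie-breaks worth knowing: channel max-pooling
routes gradients to the first maximal channel; thresholding is strictly
greater-than; the dot-bracket writer assigns crossing pairs to the first
non-crossing bracket layer.

## Known limitations

- Training is pure R; it is comfortable at the bundled scales (seconds to
  a couple of minutes) but not meant for thousands of long sequences.
- The attention network's benefit over the lite variant depends on
  spatial error structure; when learner errors are isolated pairs and
  truths share no systematic context, lite can match or beat it (a
  pattern also visible on the simulated benchmark).
- The relaxation solver's local search is bounded; on large dense score
  matrices it can stop around 97-99% of the exact optimum. The exact
  solver is the default everywhere.
- Checkpoints store learner names and refuse mismatched stacks, but
  cannot detect two different tools writing files under the same learner
  name.
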