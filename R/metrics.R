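# Base-pair evaluation metrics, prediction concordance, ROC analysis,
# ensemble-combination search and error-map PCA.
#
# The evaluation universe is the set of unordered position pairs i < j
# (n(n-1)/2 cells), not the full n^2 matrix: symmetric cells would double
# every count and the diagonal can never pair. This choice affects TN and
# therefore the magnitude of INF; it is applied consistently everywhere.

.pair_keys <- function(cm) {
  if (nrow(cm$pairs) == 0L) return(character(0))
  paste(cm$pairs[, 1L], cm$pairs[, 2L], sep = "_")
}

#' Confusion counts between a predicted and a true structure
#'
#' Counted over unordered position pairs `i < j`: TP are predicted pairs
#' present in the truth, FP predicted but absent, FN true but missed, and
#' TN the remaining `n(n-1)/2 - TP - FP - FN` cells.
#'
#' @param pred Predicted `contact_map`.
#' @param truth Ground-truth `contact_map` of the same length.
#' @return Named list with integer `TP`, `FP`, `TN`, `FN` and `n`.
#' @export
confusion <- function(pred, truth) {
  stopifnot(inherits(pred, "contact_map"), inherits(truth, "contact_map"),
            pred$n == truth$n)
  kp <- .pair_keys(pred)
  kt <- .pair_keys(truth)
  tp <- length(intersect(kp, kt))
  fp <- length(kp) - tp
  fn <- length(kt) - tp
  universe <- pred$n * (pred$n - 1) / 2
  list(TP = tp, FP = fp, FN = fn, TN = as.integer(universe - tp - fp - fn),
       n = pred$n)
}

#' Precision, recall and F1 from confusion counts
#'
#' Standard formulas; any ratio with a zero denominator is reported as 0
#' and flagged via the `degenerate` field.
#'
#' @param counts List with `TP`, `FP`, `FN` (e.g. from [confusion()]).
#' @return List with `precision`, `recall`, `f1`, `degenerate`.
#' @export
pair_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       degenerate = (tp + fp == 0) || (tp + fn == 0))
}

#' Interaction network fidelity (INF)
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TN+FP)(TP+FN)(TN+FN))`, numerically
#' identical to the Matthews correlation coefficient over the pair
#' universe; 0 when any factor of the denominator vanishes.
#'
#' @param counts List with `TP`, `FP`, `TN`, `FN`.
#' @return Scalar in `[-1, 1]`.
#' @export
inf_score <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  denom <- (tp + fp) * (tn + fp) * (tp + fn) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Jaccard distance between two structures
#'
#' `(|A U B| - |A n B|) / |A U B|` over the two pair sets; 0 when both
#' structures are empty.
#'
#' @param A,B `contact_map` objects of the same length.
#' @return Scalar in `[0, 1]`.
#' @export
jaccard_distance <- function(A, B) {
  ka <- .pair_keys(A)
  kb <- .pair_keys(B)
  u <- length(union(ka, kb))
  if (u == 0L) return(0)
  (u - length(intersect(ka, kb))) / u
}

#' Pairwise concordance matrix between prediction algorithms
#'
#' Entry (a, b) is the mean over sequences of the Jaccard distance between
#' algorithm a's and algorithm b's predicted structures.
#'
#' @param predictions Named list: algorithm name -> list of `contact_map`s
#'   (same sequences, same order, for every algorithm).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pairwise_concordance <- function(predictions) {
  algos <- names(predictions)
  stopifnot(length(algos) >= 2L)
  ns <- lengths(predictions)
  stopifnot(length(unique(ns)) == 1L)
  m <- matrix(0, length(algos), length(algos), dimnames = list(algos, algos))
  for (a in seq_along(algos)) {
    for (b in seq_along(algos)) {
      if (b <= a) next
      d <- mean(vapply(seq_len(ns[1L]), function(k) {
        jaccard_distance(predictions[[a]][[k]], predictions[[b]][[k]])
      }, numeric(1L)))
      m[a, b] <- m[b, a] <- d
    }
  }
  m
}

#' ROC curve over pooled pairing scores
#'
#' Pools the upper-triangle cells of the score matrices (restricted to
#' constraint-allowed cells when sequences are supplied), labels them by the
#' truth contact maps, and sweeps the threshold.
#'
#' @param Y_list List of score matrices.
#' @param truth_list List of `contact_map`s matching `Y_list`.
#' @param seqs Optional list of `rna_sequence`s; when given, only cells
#'   allowed by the constraint mask enter the pool.
#' @return List with `fpr`, `tpr` (threshold sweep) and `auc`
#'   (trapezoidal area).
#' @export
roc_points <- function(Y_list, truth_list, seqs = NULL) {
  stopifnot(length(Y_list) == length(truth_list))
  scores <- numeric(0)
  labels <- numeric(0)
  for (k in seq_along(Y_list)) {
    Y <- Y_list[[k]]
    Z <- cm_matrix(truth_list[[k]])
    keep <- upper.tri(Y)
    if (!is.null(seqs)) keep <- keep & build_mask(seqs[[k]]) == 1
    scores <- c(scores, Y[keep])
    labels <- c(labels, Z[keep])
  }
  if (length(unique(labels)) < 2L) {
    stop("ROC requires both positive and negative cells in the pool")
  }
  r <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                 direction = "<", levels = c(0, 1))
  list(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities),
       auc = as.numeric(pROC::auc(r)))
}

#' Per-sequence evaluation table
#'
#' @param preds List of predicted `contact_map`s.
#' @param truths List of ground-truth `contact_map`s.
#' @param ids Optional sequence identifiers.
#' @return Data frame with one row per sequence (id, TP, FP, TN, FN,
#'   precision, recall, f1, inf).
#' @export
evaluate_structures <- function(preds, truths, ids = NULL) {
  stopifnot(length(preds) == length(truths))
  if (is.null(ids)) ids <- sprintf("seq_%04d", seq_along(preds))
  rows <- lapply(seq_along(preds), function(k) {
    cts <- confusion(preds[[k]], truths[[k]])
    pm <- pair_metrics(cts)
    data.frame(id = ids[k], TP = cts$TP, FP = cts$FP, TN = cts$TN,
               FN = cts$FN, precision = pm$precision, recall = pm$recall,
               f1 = pm$f1, inf = inf_score(cts))
  })
  do.call(rbind, rows)
}

#' Exhaustive search over base-learner combinations
#'
#' For every nonempty subset of the learners, trains a lite ensemble on the
#' training split and evaluates decoded predictions on the evaluation
#' split, reporting mean and median F1 per subset and the best F1 by
#' ensemble size.
#'
#' @param examples List of `training_example` objects (full learner stacks).
#' @param train_idx,eval_idx Integer indices splitting `examples`.
#' @param cfg A `train_config` for the per-subset lite training.
#' @param decoder A `decoder_config` for evaluation decoding.
#' @param force Allow more than 10 learners (2^l subsets) when TRUE.
#' @return A list of class `combination_report` with data frames `subsets`
#'   (subset, size, mean_f1, median_f1) and `by_size` (size, best_f1).
#' @export
combination_search <- function(examples, train_idx, eval_idx,
                               cfg = train_config(epochs = 30L,
                                                  learning_rate = 0.05,
                                                  val_every = 1000L),
                               decoder = decoder_config(), force = FALSE) {
  lnames <- examples[[1L]]$stack$learner_names
  l <- length(lnames)
  if (l > 10L && !force) {
    stop("more than 10 learners means over 1000 subsets; pass force = TRUE to proceed")
  }
  subsets <- unlist(lapply(seq_len(l), function(k) {
    asplit(utils::combn(l, k), 2L)
  }), recursive = FALSE)
  rows <- lapply(subsets, function(idx) {
    idx <- as.integer(idx)
    sub_train <- lapply(examples[train_idx], function(e) {
      training_example(subset_stack(e$stack, idx), e$truth, e$seq)
    })
    fit <- train_ensemble(sub_train, val_set = NULL, cfg = cfg,
                          variant = "lite", decoder = decoder)
    f1s <- vapply(examples[eval_idx], function(e) {
      stack <- subset_stack(e$stack, idx)
      Y <- ensemble_predict(stack, fit$params)
      pred <- decode(Y, e$seq, decoder)
      pair_metrics(confusion(pred, e$truth))$f1
    }, numeric(1L))
    data.frame(subset = paste(lnames[idx], collapse = "+"),
               size = length(idx), mean_f1 = mean(f1s),
               median_f1 = median(f1s))
  })
  subsets_df <- do.call(rbind, rows)
  by_size <- do.call(rbind, lapply(sort(unique(subsets_df$size)), function(s) {
    data.frame(size = s,
               best_f1 = max(subsets_df$median_f1[subsets_df$size <= s]))
  }))
  structure(list(subsets = subsets_df, by_size = by_size),
            class = "combination_report")
}

#' @export
print.combination_report <- function(x, ...) {
  cat(sprintf("<combination_report> %d subsets\n", nrow(x$subsets)))
  print(utils::head(x$subsets[order(-x$subsets$median_f1), ], 10L))
  invisible(x)
}

#' Two-dimensional PCA embedding of per-algorithm error maps
#'
#' For each algorithm, the squared-error maps of its predictions against
#' the ground truth (upper-triangle cells, concatenated over sequences)
#' form one feature vector; PCA across algorithms yields a 2-D layout in
#' which algorithms with similar error structure cluster.
#'
#' @param predictions Named list: algorithm -> list of `contact_map`s.
#' @param truths List of ground-truth `contact_map`s.
#' @return Data frame with `algorithm`, `pc1`, `pc2`.
#' @export
pca_error_embedding <- function(predictions, truths) {
  algos <- names(predictions)
  stopifnot(length(algos) >= 2L)
  feats <- t(vapply(algos, function(a) {
    unlist(lapply(seq_along(truths), function(k) {
      D <- (cm_matrix(predictions[[a]][[k]]) - cm_matrix(truths[[k]]))^2
      D[upper.tri(D)]
    }))
  }, numeric(sum(vapply(truths, function(tr) tr$n * (tr$n - 1) / 2, numeric(1L))))))
  pc <- prcomp(feats, center = TRUE, scale. = FALSE)
  scores <- pc$x
  pc2 <- if (ncol(scores) >= 2L) scores[, 2L] else rep(0, length(algos))
  data.frame(algorithm = algos, pc1 = scores[, 1L], pc2 = pc2)
}
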