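# Independent oracles and fixture builders used across the suite.

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rna_sequence(paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                     collapse = ""), id = "rand")
}

# Random valid contact map over n positions (crossing pairs allowed):
# repeatedly draw index pairs at distance >= min_dist on free positions.
random_contact_map <- function(n, n_pairs = NULL, min_dist = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_pairs)) n_pairs <- sample.int(max(1L, n %/% 3L), 1L)
  used <- logical(n)
  pairs <- NULL
  for (tries in seq_len(200L)) {
    if (!is.null(pairs) && nrow(pairs) >= n_pairs) break
    ij <- sort(sample.int(n, 2L)) - 1L
    if (ij[2L] - ij[1L] < min_dist) next
    if (used[ij[1L] + 1L] || used[ij[2L] + 1L]) next
    used[ij + 1L] <- TRUE
    pairs <- rbind(pairs, ij)
  }
  contact_map(pairs, n = n)
}

# Brute-force maximum-weight matching by recursive enumeration of all
# matchings. Independent of the package's solvers.
brute_force_matching <- function(phiY, rho = 0) {
  w <- which(upper.tri(phiY) & phiY > rho, arr.ind = TRUE)
  if (nrow(w) == 0L) {
    return(list(weight = 0, pairs = matrix(integer(0), ncol = 2L)))
  }
  ei <- w[, 1L]
  ej <- w[, 2L]
  wt <- phiY[w] - rho
  n <- nrow(phiY)
  m <- length(wt)
  best <- 0
  best_take <- logical(m)
  take <- logical(m)
  used <- logical(n)
  rec <- function(k, acc) {
    if (k > m) {
      if (acc > best) {
        best <<- acc
        best_take <<- take
      }
      return(invisible())
    }
    rec(k + 1L, acc)
    a <- ei[k]; b <- ej[k]
    if (!used[a] && !used[b]) {
      used[a] <<- used[b] <<- TRUE
      take[k] <<- TRUE
      rec(k + 1L, acc + wt[k])
      used[a] <<- used[b] <<- FALSE
      take[k] <<- FALSE
    }
  }
  rec(1L, 0)
  list(weight = best, pairs = cbind(ei[best_take] - 1L, ej[best_take] - 1L))
}

# Matthews correlation coefficient computed independently, as the Pearson
# correlation of the reconstructed binary prediction/label vectors.
mcc_oracle <- function(tp, fp, tn, fn) {
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  if (length(unique(pred)) < 2L || length(unique(truth)) < 2L) return(0)
  suppressWarnings(stats::cor(pred, truth))
}

# Brute-force confusion counts by enumerating every upper-triangle cell.
confusion_oracle <- function(pred, truth) {
  P <- cm_matrix(pred)
  Z <- cm_matrix(truth)
  tp <- fp <- tn <- fn <- 0L
  n <- nrow(P)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (P[i, j] == 1 && Z[i, j] == 1) tp <- tp + 1L
      else if (P[i, j] == 1) fp <- fp + 1L
      else if (Z[i, j] == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

# Jaccard distance by explicit set enumeration over matrix cells.
jaccard_oracle <- function(A, B) {
  a <- cm_matrix(A)
  b <- cm_matrix(B)
  un <- sum((a + b) > 0 & upper.tri(a))
  it <- sum(a == 1 & b == 1 & upper.tri(a))
  if (un == 0L) 0 else (un - it) / un
}

# Small bundle of simulated training examples shared by trainer tests.
make_examples <- function(n_examples, n_range = c(30L, 50L), seed = 1L,
                          profiles = default_learner_panel()) {
  cfg <- synthetic_structure_config(n_range = n_range)
  lapply(seq_len(n_examples), function(k) {
    rec <- generate_structure(cfg, seed = seed * 10000L + k,
                              id = sprintf("ex%03d", k))
    st <- simulate_stack(rec$structure, rec$sequence, profiles,
                         seed = seed * 20000L + k)
    training_example(st, rec$structure, rec$sequence)
  })
}
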