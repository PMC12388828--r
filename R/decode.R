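# Constrained decoding of pair-probability maps.
#
# A raw pairing-score matrix Y is turned into a hard-constraint-satisfying
# structure in four steps: (1) a sequence-derived constraint mask (canonical
# + wobble pairs only, minimum pairing distance); (2) the symmetrization
# transform phi(Y) = (Y + t(Y))/2 * M; (3) a sparsity-penalized matching
# optimization enforcing the one-partner-per-base rule; (4) thresholding.

.allowed_pair_types <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Build the hard-constraint mask for a sequence
#'
#' `M[i, j] = 1` iff bases i and j may pair: the pair type is Watson-Crick
#' (A-U, G-C) or wobble (G-U), and the bases are at least four positions
#' apart (`|i - j| >= 4`). Non-ACGU residues never pair. The mask is
#' symmetric with a zero diagonal.
#'
#' @param seq An `rna_sequence`.
#' @return Binary `n` x `n` matrix.
#' @export
build_mask <- function(seq) {
  chars <- seq_chars(seq)
  n <- seq$n
  type <- matrix(paste0(rep(chars, times = n), rep(chars, each = n)), n, n)
  M <- matrix(0, n, n)
  M[type %in% .allowed_pair_types] <- 1
  dist_ok <- abs(row(M) - col(M)) >= 4
  M * dist_ok
}

#' Symmetrize and mask a pairing-score matrix
#'
#' Computes `phi(Y) = (Y + t(Y)) / 2 * M` elementwise: the output is
#' symmetric and zero wherever the constraint mask is zero.
#'
#' @param Y Numeric `n` x `n` score matrix (need not be symmetric).
#' @param M Constraint mask from [build_mask()].
#' @return Symmetric masked score matrix.
#' @export
phi_transform <- function(Y, M) {
  stopifnot(is.matrix(Y), all(dim(Y) == dim(M)))
  0.5 * (Y + t(Y)) * M
}

#' Decoder configuration
#'
#' @param rho Sparsity penalty `>= 0`: a pair enters the solution only if
#'   its symmetrized score exceeds `rho`, and each selected pair's objective
#'   contribution is `phi - rho`.
#' @param threshold Confidence threshold `P` in (0, 1); entries must be
#'   strictly greater than `P` to become pairs.
#' @param solver `"exact"` (blossom maximum-weight matching) or
#'   `"relaxation"` (projected gradient ascent with a fixed iteration
#'   budget, followed by feasibility rounding and a short local search).
#' @param relax_steps Iteration budget for the relaxation solver.
#' @param relax_lr Step size for the relaxation solver.
#' @return A list of class `decoder_config`.
#' @export
decoder_config <- function(rho = 0, threshold = 0.5,
                           solver = c("exact", "relaxation"),
                           relax_steps = 200L, relax_lr = 0.2) {
  solver <- match.arg(solver)
  stopifnot(rho >= 0, threshold > 0, threshold < 1, relax_steps >= 1)
  structure(list(rho = rho, threshold = threshold, solver = solver,
                 relax_steps = as.integer(relax_steps), relax_lr = relax_lr),
            class = "decoder_config")
}

.candidate_edges <- function(phiY, rho) {
  w <- which(upper.tri(phiY) & phiY > rho, arr.ind = TRUE)
  list(i = w[, 1L] - 1L, j = w[, 2L] - 1L,
       wt = phiY[w] - rho)
}

#' Matching objective value
#'
#' The sparsity-penalized linear objective `sum(Yhat * phi) - rho * sum(Yhat)`
#' evaluated over unordered position pairs (upper triangle).
#'
#' @param Yhat Assignment matrix (binary or soft, symmetric).
#' @param phiY Symmetrized masked scores.
#' @param rho Sparsity penalty.
#' @return Scalar objective value.
#' @export
matching_objective <- function(Yhat, phiY, rho = 0) {
  ut <- upper.tri(Yhat)
  sum(Yhat[ut] * phiY[ut]) - rho * sum(Yhat[ut])
}

.solve_exact <- function(phiY, rho) {
  n <- nrow(phiY)
  ed <- .candidate_edges(phiY, rho)
  out <- matrix(0, n, n)
  if (length(ed$i) == 0L) return(out)
  mate <- max_weight_matching_cpp(ed$i, ed$j, ed$wt, n)
  v <- which(mate >= 0L) # 1-based positions with a partner
  if (length(v) > 0L) {
    out[cbind(v, mate[v] + 1L)] <- 1
  }
  out
}

# Greedy feasibility rounding: take candidate edges in decreasing score
# order, keeping an edge when both endpoints are still free.
.greedy_matching <- function(ord, ei, ej, n) {
  used <- logical(n)
  take <- logical(length(ord))
  for (k in ord) {
    a <- ei[k] + 1L; b <- ej[k] + 1L
    if (!used[a] && !used[b]) {
      used[a] <- used[b] <- TRUE
      take[k] <- TRUE
    }
  }
  take
}

# Local search by bounded alternating-path augmentation. The symmetric
# difference of a matching with an improving alternating path or cycle is a
# better matching; paths (and drop-initiated cycles) with up to `max_add`
# added edges are searched depth-first and the best improvement of each
# pass is applied, until a local optimum or the pass cap is reached.
.improve_matching <- function(take, ei, ej, wt, n, max_add = NULL,
                              max_pass = 20L) {
  m <- length(wt)
  if (is.null(max_add)) max_add <- if (n <= 24L) 4L else 2L
  adj <- vector("list", n)
  for (k in seq_len(m)) {
    adj[[ei[k] + 1L]] <- c(adj[[ei[k] + 1L]], k)
    adj[[ej[k] + 1L]] <- c(adj[[ej[k] + 1L]], k)
  }
  other_end <- function(k, v) if (ei[k] + 1L == v) ej[k] + 1L else ei[k] + 1L
  partner_edge <- integer(n)
  set_partner <- function() {
    partner_edge <<- integer(n)
    for (k in which(take)) {
      partner_edge[ei[k] + 1L] <<- k
      partner_edge[ej[k] + 1L] <<- k
    }
  }
  set_partner()
  best_gain <- 0
  best_flip <- NULL
  # u is an exposed path end; the next edge must be an addition. `cyc_root`
  # closes drop-initiated alternating cycles.
  dfs <- function(u, gain, visited, flips, depth, cyc_root) {
    for (k in adj[[u]]) {
      if (take[k]) next
      x <- other_end(k, u)
      if (x == cyc_root) {
        g2 <- gain + wt[k]
        if (g2 > best_gain + 1e-12) {
          best_gain <<- g2
          best_flip <<- c(flips, k)
        }
        next
      }
      if (visited[x]) next
      g2 <- gain + wt[k]
      ex <- partner_edge[x]
      if (ex == 0L) {
        if (g2 > best_gain + 1e-12) {
          best_gain <<- g2
          best_flip <<- c(flips, k)
        }
      } else {
        g3 <- g2 - wt[ex]
        y <- other_end(ex, x)
        if (g3 > best_gain + 1e-12) {
          best_gain <<- g3
          best_flip <<- c(flips, k, ex)
        }
        if (depth < max_add && !visited[y]) {
          visited[x] <- visited[y] <- TRUE
          dfs(y, g3, visited, c(flips, k, ex), depth + 1L, cyc_root)
        }
      }
    }
  }
  for (pass in seq_len(max_pass)) {
    best_gain <- 0
    best_flip <- NULL
    for (v in seq_len(n)) {
      ev <- partner_edge[v]
      visited <- logical(n)
      if (ev == 0L) {
        visited[v] <- TRUE
        dfs(v, 0, visited, integer(0), 1L, 0L)
      } else {
        w2 <- other_end(ev, v)
        if (w2 > v) {
          visited[v] <- visited[w2] <- TRUE
          dfs(w2, -wt[ev], visited, ev, 1L, v)
          dfs(v, -wt[ev], visited, ev, 1L, w2)
        }
      }
    }
    if (is.null(best_flip)) break
    take[best_flip] <- !take[best_flip]
    set_partner()
  }
  take
}

.solve_relaxation <- function(phiY, rho, steps, lr) {
  n <- nrow(phiY)
  ed <- .candidate_edges(phiY, rho)
  out <- matrix(0, n, n)
  if (length(ed$i) == 0L) return(out)
  grad <- phiY - rho
  grad[phiY <= rho] <- 0
  X <- matrix(0, n, n)
  for (s in seq_len(steps)) {
    X <- X + lr * grad
    X[X < 0] <- 0
    X[X > 1] <- 1
    rs <- rowSums(X)
    over <- rs > 1
    if (any(over)) X[over, ] <- X[over, , drop = FALSE] / rs[over]
    X <- 0.5 * (X + t(X))
  }
  # feasibility rounding: greedy both in ascent-score order and in raw
  # weight order, local search on each, keep the better matching
  sc <- X[cbind(ed$i + 1L, ed$j + 1L)]
  take_a <- .greedy_matching(order(sc, ed$wt, decreasing = TRUE),
                             ed$i, ed$j, n)
  take_a <- .improve_matching(take_a, ed$i, ed$j, ed$wt, n)
  take_w <- .greedy_matching(order(ed$wt, sc, decreasing = TRUE),
                             ed$i, ed$j, n)
  take_w <- .improve_matching(take_w, ed$i, ed$j, ed$wt, n)
  take <- if (sum(ed$wt[take_a]) >= sum(ed$wt[take_w])) take_a else take_w
  sel <- which(take)
  if (length(sel) > 0L) {
    out[cbind(ed$i[sel] + 1L, ed$j[sel] + 1L)] <- 1
    out[cbind(ed$j[sel] + 1L, ed$i[sel] + 1L)] <- 1
  }
  out
}

#' Solve the sparsity-penalized matching problem
#'
#' Maximizes `<Yhat, phi(Y)> - rho * |Yhat|` over symmetric assignment
#' matrices with entries in `[0, 1]` and row sums at most one (each base
#' pairs with at most one partner). The exact solver reduces the problem to
#' maximum-weight matching on the graph of position pairs with
#' `phi(Y) > rho` (edge weight `phi - rho`) and solves it with the blossom
#' method; the relaxation solver performs projected gradient ascent for a
#' fixed budget and rounds to feasibility.
#'
#' @param phiY Symmetric nonnegative score matrix from [phi_transform()].
#' @param cfg A `decoder_config`.
#' @return Symmetric assignment matrix (binary for both solvers' final
#'   output).
#' @export
solve_matching <- function(phiY, cfg = decoder_config()) {
  stopifnot(is.matrix(phiY), nrow(phiY) == ncol(phiY))
  if (max(abs(phiY - t(phiY))) > 1e-9) {
    stop("solve_matching requires a symmetric input; run phi_transform first")
  }
  if (any(phiY < 0)) stop("solve_matching requires nonnegative scores")
  switch(cfg$solver,
    exact = .solve_exact(phiY, cfg$rho),
    relaxation = .solve_relaxation(phiY, cfg$rho, cfg$relax_steps, cfg$relax_lr))
}

#' Threshold a soft assignment into a contact map
#'
#' Entries strictly greater than `threshold` become pairs.
#'
#' @param Yhat Symmetric assignment matrix.
#' @param threshold Threshold `P`.
#' @return A `contact_map`.
#' @export
binarize <- function(Yhat, threshold = 0.5) {
  Z <- matrix(0, nrow(Yhat), ncol(Yhat))
  Z[Yhat > threshold] <- 1
  contact_map_from_matrix(Z)
}

#' Decode a pair-probability map into a valid structure
#'
#' Full decoding pipeline: constraint mask, symmetrization, confidence
#' floor at `threshold` (entries of `phi(Y)` not exceeding the threshold
#' cannot become pairs), matching optimization, thresholding. The result is
#' verified against all four hard constraints; a violation is a programming
#' error and raises an exception.
#'
#' @param Y Numeric `n` x `n` pairing-score matrix.
#' @param seq The `rna_sequence` decoded against.
#' @param cfg A `decoder_config`.
#' @return A `contact_map` satisfying all hard constraints.
#' @export
decode <- function(Y, seq, cfg = decoder_config()) {
  stopifnot(is.matrix(Y), nrow(Y) == seq$n, ncol(Y) == seq$n)
  M <- build_mask(seq)
  phiY <- phi_transform(Y, M)
  phiY[phiY <= cfg$threshold] <- 0
  Yhat <- solve_matching(phiY, cfg)
  cm <- binarize(Yhat, cfg$threshold)
  viol <- constraint_violations(cm, seq)
  if (viol > 0L) stop(sprintf("decoded structure violates %d hard constraint(s)", viol))
  cm
}

#' Count hard-constraint violations of a structure
#'
#' Checks the four decoding constraints: allowed pair types (canonical plus
#' wobble, non-ACGU residues never pair), minimum pairing distance
#' `|i - j| >= 4`, symmetry, and at most one partner per base. The latter
#' two hold for every well-formed `contact_map`; they are re-checked from
#' the matrix view for completeness.
#'
#' @param cm A `contact_map`.
#' @param seq The corresponding `rna_sequence`.
#' @return Integer count of violations (0 for a valid structure).
#' @export
constraint_violations <- function(cm, seq) {
  stopifnot(cm$n == seq$n)
  Z <- cm_matrix(cm)
  v <- 0L
  if (!isTRUE(all.equal(Z, t(Z)))) v <- v + 1L
  if (any(rowSums(Z) > 1)) v <- v + sum(rowSums(Z) > 1)
  M <- build_mask(seq)
  v + sum(Z == 1 & M == 0) / 2L
}
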