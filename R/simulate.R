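# Synthetic structures and simulated base learners.
#
# The generator emits pseudoknot-free nested structures from a stochastic
# stem/loop grammar; the simulator degrades a ground-truth contact map into
# the output of a fallible base learner with a configurable sensitivity,
# false-pair rate and error bias, so that ensembles can be trained and
# evaluated without any external prediction tool.

#' Configuration for the synthetic structure generator
#'
#' @param n_range Length 2 integer vector, inclusive range of sequence lengths.
#' @param min_loop Minimum number of unpaired bases in a hairpin loop
#'   (>= 3, so every generated pair satisfies the minimum pairing distance
#'   `j - i >= 4`).
#' @param stem_extension_prob Probability that a helix grows by one more
#'   stacked pair.
#' @param branch_prob Probability that a closed helix opens into a
#'   multi-branch loop instead of a hairpin.
#' @param gu_fraction Fraction of pairs drawn as G-U wobble pairs instead of
#'   Watson-Crick pairs.
#' @return A list of class `synthetic_structure_config`.
#' @export
synthetic_structure_config <- function(n_range = c(40L, 80L), min_loop = 3L,
                                       stem_extension_prob = 0.75,
                                       branch_prob = 0.15,
                                       gu_fraction = 0.15) {
  stopifnot(length(n_range) == 2L, n_range[1L] >= 5L, n_range[2L] >= n_range[1L],
            min_loop >= 3L,
            stem_extension_prob >= 0, stem_extension_prob <= 1,
            branch_prob >= 0, branch_prob <= 1,
            gu_fraction >= 0, gu_fraction <= 1)
  structure(list(n_range = as.integer(n_range), min_loop = as.integer(min_loop),
                 stem_extension_prob = stem_extension_prob,
                 branch_prob = branch_prob, gu_fraction = gu_fraction),
            class = "synthetic_structure_config")
}

# a helix closing (a, b) is geometrically possible iff b - a >= min_loop + 1
.gen_helix <- function(a, b, cfg, pairs) {
  pairs[[length(pairs) + 1L]] <- c(a, b)
  inner <- b - a - 1L
  if (b - 1L - (a + 1L) >= cfg$min_loop + 1L &&
      runif(1L) < cfg$stem_extension_prob) {
    return(.gen_helix(a + 1L, b - 1L, cfg, pairs))
  }
  if (inner >= 2L * (cfg$min_loop + 2L) + 1L && runif(1L) < cfg$branch_prob) {
    # multi-branch loop: several helices may open in the enclosed region
    return(.gen_region(a + 1L, b - 1L, cfg, pairs, open_prob = 0.6))
  }
  if (inner >= cfg$min_loop + 8L) {
    # enclosed region too large for a plausible hairpin loop: continue the
    # stem after a bulge / interior loop of 1-3 unpaired bases per side
    g1 <- sample.int(3L, 1L)
    g2 <- sample.int(3L, 1L)
    return(.gen_helix(a + g1 + 1L, b - g2 - 1L, cfg, pairs))
  }
  pairs # hairpin: inner >= min_loop unpaired bases by construction
}

.gen_region <- function(a, b, cfg, pairs, open_prob) {
  pos <- a
  while (pos <= b) {
    if (b - pos >= cfg$min_loop + 1L && runif(1L) < open_prob) {
      e <- pos + cfg$min_loop + 1L +
        floor(runif(1L) * (b - pos - cfg$min_loop))
      pairs <- .gen_helix(pos, as.integer(e), cfg, pairs)
      pos <- as.integer(e) + 1L
    } else {
      pos <- pos + 1L
    }
  }
  pairs
}

.pair_alphabet <- c("AU", "UA", "GC", "CG")
.wobble_alphabet <- c("GU", "UG")

#' Generate a random nested RNA structure with a compatible sequence
#'
#' Structures are produced by a stochastic grammar: helices open at random
#' positions, are stacked with probability `stem_extension_prob`, and close
#' either into hairpins of at least `min_loop` unpaired bases or (with
#' probability `branch_prob`) into multi-branch loops. Paired positions
#' receive Watson-Crick complementary bases (G-U wobble with probability
#' `gu_fraction`); loop bases are uniform random. Every emitted pair
#' therefore satisfies all decoding hard constraints.
#'
#' @param cfg A `synthetic_structure_config`.
#' @param seed Optional integer; when given, output is reproducible.
#' @param id Identifier for the generated sequence.
#' @return A `structure_record` with `source = "ground_truth"`.
#' @export
generate_structure <- function(cfg = synthetic_structure_config(), seed = NULL,
                               id = "synthetic") {
  if (!is.null(seed)) set.seed(seed)
  n <- if (cfg$n_range[1L] == cfg$n_range[2L]) cfg$n_range[1L] else
    sample(cfg$n_range[1L]:cfg$n_range[2L], 1L)
  pairs <- .gen_region(0L, n - 1L, cfg, list(), open_prob = 0.5)
  chars <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  for (p in pairs) {
    ab <- if (runif(1L) < cfg$gu_fraction) {
      sample(.wobble_alphabet, 1L)
    } else {
      sample(.pair_alphabet, 1L)
    }
    ab <- strsplit(ab, "")[[1L]]
    chars[p[1L] + 1L] <- ab[1L]
    chars[p[2L] + 1L] <- ab[2L]
  }
  seq <- rna_sequence(paste(chars, collapse = ""), id = id)
  structure_record(seq, contact_map(do.call(rbind, pairs), n = n),
                   source = "ground_truth")
}

#' Error profile of a simulated base learner
#'
#' @param name Learner name.
#' @param sensitivity Probability that a true pair is reported.
#' @param false_pair_rate Expected number of spurious pairs per 100 nt.
#' @param bias_mode Which spurious pairs this learner favors: `"none"`
#'   (uniform), `"shift"` (register shifts of true pairs by one position),
#'   `"long_range"` (large `j - i`), or `"short_range"` (small `j - i`).
#'   Learners with different biases make partially independent errors, the
#'   regime in which ensembling pays off.
#' @param seed_offset Integer offset added to the stack-level seed so each
#'   learner has its own reproducible random substream.
#' @return A list of class `learner_profile`.
#' @export
learner_profile <- function(name, sensitivity = 0.8, false_pair_rate = 8,
                            bias_mode = c("none", "shift", "long_range", "short_range"),
                            seed_offset = 0L) {
  bias_mode <- match.arg(bias_mode)
  stopifnot(sensitivity >= 0, sensitivity <= 1, false_pair_rate >= 0)
  structure(list(name = as.character(name), sensitivity = sensitivity,
                 false_pair_rate = false_pair_rate, bias_mode = bias_mode,
                 seed_offset = as.integer(seed_offset)),
            class = "learner_profile")
}

#' Simulate one base learner's prediction for a known structure
#'
#' Each true pair is kept independently with probability
#' `profile$sensitivity`. Spurious pairs are then drawn (count ~
#' Poisson(`false_pair_rate * n / 100`)) from the constraint-allowed pairs
#' whose endpoints are still unpaired, with sampling weights set by
#' `profile$bias_mode`; a greedy rejection step preserves the one-partner
#' rule, so the simulated output is always a valid, constraint-satisfying
#' contact map.
#'
#' @param truth Ground-truth `contact_map`.
#' @param seq The `rna_sequence` the structure belongs to.
#' @param profile A `learner_profile`.
#' @param seed Optional integer seed for reproducibility.
#' @return A `contact_map`.
#' @export
simulate_learner <- function(truth, seq, profile, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- seq$n
  stopifnot(truth$n == n)
  tp <- truth$pairs
  keep <- if (nrow(tp) > 0L) runif(nrow(tp)) < profile$sensitivity else logical(0)
  kept <- tp[keep, , drop = FALSE]
  used <- logical(n)
  if (nrow(kept) > 0L) used[c(kept[, 1L], kept[, 2L]) + 1L] <- TRUE

  n_spur <- rpois(1L, profile$false_pair_rate * n / 100)
  out <- kept
  if (n_spur > 0L) {
    M <- build_mask(seq)
    cand <- which(M == 1 & upper.tri(M), arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      ci <- cand[, 1L] - 1L
      cj <- cand[, 2L] - 1L
      free <- !(used[ci + 1L] | used[cj + 1L])
      ci <- ci[free]; cj <- cj[free]
      if (length(ci) > 0L) {
        w <- switch(profile$bias_mode,
          none = rep(1, length(ci)),
          long_range = (cj - ci)^2,
          short_range = 1 / (cj - ci)^2,
          shift = {
            w0 <- rep(1, length(ci))
            if (nrow(tp) > 0L) {
              key <- paste(ci, cj)
              shifted <- c(paste(tp[, 1L] + 1L, tp[, 2L]), paste(tp[, 1L] - 1L, tp[, 2L]),
                           paste(tp[, 1L], tp[, 2L] + 1L), paste(tp[, 1L], tp[, 2L] - 1L))
              w0[key %in% shifted] <- 50
            }
            w0
          })
        ord <- sample.int(length(ci), prob = w)
        added <- 0L
        for (k in ord) {
          if (added >= n_spur) break
          if (used[ci[k] + 1L] || used[cj[k] + 1L]) next
          out <- rbind(out, c(ci[k], cj[k]))
          used[c(ci[k], cj[k]) + 1L] <- TRUE
          added <- added + 1L
        }
      }
    }
  }
  contact_map(out, n = n)
}

#' Assemble a stack of simulated learner predictions
#'
#' One `simulate_learner()` call per profile, each on its own random
#' substream `seed + seed_offset`, so adding or removing a learner never
#' perturbs the draws of the others.
#'
#' @param truth Ground-truth `contact_map`.
#' @param seq The `rna_sequence`.
#' @param profiles List of `learner_profile` objects.
#' @param seed Integer base seed.
#' @return A `learner_stack`.
#' @export
simulate_stack <- function(truth, seq, profiles, seed = 1L) {
  maps <- lapply(profiles, function(p) {
    simulate_learner(truth, seq, p, seed = seed + p$seed_offset)
  })
  learner_stack(maps, vapply(profiles, function(p) p$name, character(1L)))
}

#' Default panel of four diverse simulated learners
#'
#' Four learners with distinct error biases (uniform, register shift,
#' long-range, short-range), mirroring the partially independent error modes
#' of real prediction algorithms.
#'
#' @param sensitivity Shared sensitivity.
#' @param false_pair_rate Shared spurious-pair rate per 100 nt.
#' @return List of four `learner_profile` objects.
#' @export
default_learner_panel <- function(sensitivity = 0.8, false_pair_rate = 8) {
  modes <- c("none", "shift", "long_range", "short_range")
  lapply(seq_along(modes), function(k) {
    learner_profile(paste0("sim_", modes[k]), sensitivity = sensitivity,
                    false_pair_rate = false_pair_rate, bias_mode = modes[k],
                    seed_offset = (k - 1L) * 1000L)
  })
}

# ---------------------------------------------------------------------------
# learner_stack type
# ---------------------------------------------------------------------------

#' Stack per-learner contact maps into the ensemble input
#'
#' @param maps List of `contact_map` objects (or binary matrices) of common
#'   dimension, one per learner.
#' @param learner_names Character vector of learner names.
#' @return An object of class `learner_stack` with fields `learner_names`,
#'   `maps` (list of binary n x n matrices), `l` and `n`.
#' @export
learner_stack <- function(maps, learner_names = NULL) {
  stopifnot(length(maps) >= 1L)
  if (is.null(learner_names)) learner_names <- paste0("learner_", seq_along(maps))
  stopifnot(length(learner_names) == length(maps))
  mats <- lapply(maps, function(m) {
    if (inherits(m, "contact_map")) m <- cm_matrix(m)
    contact_map_from_matrix(m) # validates symmetry, diag, one-partner
    m
  })
  ns <- vapply(mats, nrow, integer(1L))
  if (length(unique(ns)) != 1L) stop("all learner maps must have the same dimension")
  structure(list(learner_names = as.character(learner_names), maps = mats,
                 l = length(mats), n = ns[1L]),
            class = "learner_stack")
}

#' @export
print.learner_stack <- function(x, ...) {
  cat(sprintf("<learner_stack> l=%d learners, n=%d: %s\n", x$l, x$n,
              paste(x$learner_names, collapse = ", ")))
  invisible(x)
}

#' Subset the learners of a stack
#' @param stack A `learner_stack`.
#' @param idx Integer or character vector selecting learners.
#' @return A `learner_stack` over the selected learners.
#' @export
subset_stack <- function(stack, idx) {
  if (is.character(idx)) idx <- match(idx, stack$learner_names)
  stopifnot(!anyNA(idx), length(idx) >= 1L)
  learner_stack(stack$maps[idx], stack$learner_names[idx])
}

#' Build a learner stack from prediction files
#'
#' @param seq The `rna_sequence` the predictions refer to.
#' @param files Named character vector mapping learner name to file path
#'   (dot-bracket, CT, or BPSEQ; format guessed from the extension).
#' @return A `learner_stack` with slices in the order of `files`.
#' @export
stack_from_files <- function(seq, files) {
  stopifnot(length(files) >= 1L)
  if (is.null(names(files)) || any(!nzchar(names(files)))) {
    stop("`files` must be a named vector: learner name -> path")
  }
  maps <- vector("list", length(files))
  for (k in seq_along(files)) {
    rec <- read_structure_file(files[[k]])
    if (rec$sequence$n != seq$n) {
      stop(sprintf("learner '%s': structure length %d does not match sequence length %d",
                   names(files)[k], rec$sequence$n, seq$n))
    }
    maps[[k]] <- rec$structure
  }
  learner_stack(maps, names(files))
}

# ---------------------------------------------------------------------------
# Dataset simulation (used by the CLI `simulate` subcommand)
# ---------------------------------------------------------------------------

#' Simulate a full benchmark dataset on disk
#'
#' Writes `sequences.fasta`, ground-truth BPSEQ files under `truth/`,
#' per-learner dot-bracket predictions under `learners/<name>/`, and a
#' `manifest.txt` recording every profile parameter and seed.
#'
#' @param dir Output directory.
#' @param n_structures Number of structures to generate.
#' @param cfg A `synthetic_structure_config`.
#' @param profiles List of `learner_profile` objects.
#' @param seed Integer master seed.
#' @return Invisibly, the list of generated `structure_record`s.
#' @export
simulate_dataset <- function(dir, n_structures = 50L,
                             cfg = synthetic_structure_config(),
                             profiles = default_learner_panel(), seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  for (p in profiles) {
    dir.create(file.path(dir, "learners", p$name), recursive = TRUE,
               showWarnings = FALSE)
  }
  records <- vector("list", n_structures)
  for (k in seq_len(n_structures)) {
    id <- sprintf("synth_%04d", k)
    rec <- generate_structure(cfg, seed = seed + k, id = id)
    records[[k]] <- rec
    writeLines(write_bpseq(rec), file.path(dir, "truth", paste0(id, ".bpseq")))
    for (p in profiles) {
      pred <- simulate_learner(rec$structure, rec$sequence, p,
                               seed = seed + k + p$seed_offset)
      db <- write_dot_bracket(pred)
      writeLines(c(paste0(">", id), rec$sequence$residues, db),
                 file.path(dir, "learners", p$name, paste0(id, ".db")))
    }
  }
  write_fasta(lapply(records, function(r) r$sequence),
              file.path(dir, "sequences.fasta"))
  manifest <- c(
    sprintf("seed=%d", seed),
    sprintf("n_structures=%d", n_structures),
    sprintf("n_range=%d..%d", cfg$n_range[1L], cfg$n_range[2L]),
    sprintf("min_loop=%d", cfg$min_loop),
    sprintf("stem_extension_prob=%g", cfg$stem_extension_prob),
    sprintf("branch_prob=%g", cfg$branch_prob),
    sprintf("gu_fraction=%g", cfg$gu_fraction),
    vapply(profiles, function(p) {
      sprintf("learner=%s sensitivity=%g false_pair_rate=%g bias_mode=%s seed_offset=%d",
              p$name, p$sensitivity, p$false_pair_rate, p$bias_mode, p$seed_offset)
    }, character(1L)))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(records)
}
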