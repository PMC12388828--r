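#' @useDynLib foldstack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median prcomp quantile rbinom rpois runif setNames
#' @importFrom utils write.table read.table head tail
NULL

# ---------------------------------------------------------------------------
# Domain types: rna_sequence, contact_map, structure_record
# ---------------------------------------------------------------------------

#' Create an RNA sequence object
#'
#' Residues are uppercased and DNA thymine is mapped to uracil. Residues
#' outside A/C/G/U (other IUPAC codes, e.g. N or R) are kept but flagged:
#' such positions are excluded from base pairing by the constraint mask.
#'
#' @param residues Character scalar, the nucleotide sequence.
#' @param id Character scalar identifier.
#' @return An object of class `rna_sequence` with fields `id`, `residues`
#'   (normalized) and `n` (length).
#' @examples
#' rna_sequence("ggtacc", id = "s1")
#' @export
rna_sequence <- function(residues, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1L)
  res <- toupper(gsub("[[:space:]]", "", residues))
  res <- chartr("T", "U", res)
  n <- nchar(res)
  if (n < 1L) stop("sequence must contain at least one residue")
  chars <- strsplit(res, "", fixed = TRUE)[[1L]]
  nonstd <- !(chars %in% c("A", "C", "G", "U"))
  if (any(nonstd)) {
    warning(sprintf("sequence '%s': %d non-ACGU residue(s) kept but barred from pairing",
                    id, sum(nonstd)))
  }
  structure(list(id = as.character(id), residues = res, n = n),
            class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence> %s (%d nt)\n", x$id, x$n))
  invisible(x)
}

seq_chars <- function(seq) strsplit(seq$residues, "", fixed = TRUE)[[1L]]

#' Create a contact map from a pair list
#'
#' A contact map is the set of base pairs of one structure, equivalently a
#' binary symmetric `n` x `n` matrix with zero diagonal and row sums at most
#' one. Pairs use 0-based indices with `i < j`; the matrix view and the
#' pair-set view are kept consistent by construction.
#'
#' @param pairs Two-column matrix (or empty) of 0-based index pairs.
#' @param n Sequence length.
#' @return An object of class `contact_map` with fields `n` and `pairs`
#'   (canonically ordered integer matrix with columns `i`, `j`).
#' @examples
#' contact_map(rbind(c(0, 5), c(1, 4)), n = 6)
#' @export
contact_map <- function(pairs = NULL, n) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, n >= 1L)
  if (is.null(pairs) || NROW(pairs) == 0L) {
    p <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
    return(structure(list(n = n, pairs = p), class = "contact_map"))
  }
  p <- matrix(as.integer(pairs), ncol = 2L)
  ii <- pmin(p[, 1L], p[, 2L])
  jj <- pmax(p[, 1L], p[, 2L])
  if (any(ii == jj)) stop("a base cannot pair with itself")
  if (any(ii < 0L) || any(jj >= n)) stop("pair index out of range [0, n)")
  idx <- c(ii, jj)
  if (anyDuplicated(idx)) stop("a base may pair with at most one partner")
  o <- order(ii, jj)
  p <- cbind(i = ii[o], j = jj[o])
  structure(list(n = n, pairs = p), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> n=%d, %d pair(s)\n", x$n, nrow(x$pairs)))
  invisible(x)
}

#' Number of pairs in a contact map
#' @param cm A `contact_map`.
#' @return Integer pair count.
#' @export
n_pairs <- function(cm) nrow(cm$pairs)

#' Matrix view of a contact map
#'
#' @param cm A `contact_map`.
#' @return A binary symmetric `n` x `n` matrix.
#' @export
cm_matrix <- function(cm) {
  Z <- matrix(0, cm$n, cm$n)
  if (nrow(cm$pairs) > 0L) {
    Z[cbind(cm$pairs[, 1L] + 1L, cm$pairs[, 2L] + 1L)] <- 1
    Z[cbind(cm$pairs[, 2L] + 1L, cm$pairs[, 1L] + 1L)] <- 1
  }
  Z
}

#' Contact map from a binary matrix
#'
#' @param Z Binary symmetric matrix with zero diagonal and row sums <= 1.
#' @return A `contact_map`.
#' @export
contact_map_from_matrix <- function(Z) {
  stopifnot(is.matrix(Z), nrow(Z) == ncol(Z))
  if (any(Z != 0 & Z != 1)) stop("matrix must be binary")
  if (!isTRUE(all.equal(Z, t(Z)))) stop("matrix must be symmetric")
  if (any(diag(Z) != 0)) stop("matrix diagonal must be zero")
  if (any(rowSums(Z) > 1)) stop("each base may pair with at most one partner")
  w <- which(Z == 1 & upper.tri(Z), arr.ind = TRUE)
  contact_map(cbind(w[, 1L] - 1L, w[, 2L] - 1L), n = nrow(Z))
}

#' Test two contact maps for equality of their pair sets
#' @param a,b `contact_map` objects.
#' @return Logical.
#' @export
cm_equal <- function(a, b) {
  a$n == b$n && nrow(a$pairs) == nrow(b$pairs) && all(a$pairs == b$pairs)
}

#' Bundle a sequence with a structure and a provenance tag
#'
#' @param sequence An `rna_sequence`.
#' @param structure A `contact_map` of the same length.
#' @param source Provenance tag, e.g. `"ground_truth"`, a learner name, or
#'   `"ensemble"`.
#' @return An object of class `structure_record`.
#' @export
structure_record <- function(sequence, structure, source = "ground_truth") {
  stopifnot(inherits(sequence, "rna_sequence"), inherits(structure, "contact_map"))
  if (structure$n != sequence$n) {
    stop(sprintf("structure length %d does not match sequence length %d",
                 structure$n, sequence$n))
  }
  structure(list(sequence = sequence, structure = structure,
                 source = as.character(source)),
            class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat(sprintf("<structure_record> %s (%d nt, %d pairs, source=%s)\n",
              x$sequence$id, x$sequence$n, n_pairs(x$structure), x$source))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Dot-bracket notation
# ---------------------------------------------------------------------------

.db_openers <- c("(", "[", "{", "<", LETTERS)
.db_closers <- c(")", "]", "}", ">", letters)

#' Parse a dot-bracket (Vienna) structure string
#'
#' Matched brackets are base pairs, dots are unpaired positions. Additional
#' bracket alphabets (`[]`, `{}`, `<>`, `Aa`, `Bb`, ...) encode pseudoknot
#' layers; each alphabet is matched with its own stack, so crossing pairs
#' between layers are supported.
#'
#' @param db Character scalar of length `n` over `.()[]{}<>` and letter pairs.
#' @param seq An `rna_sequence` of the same length, or a plain integer length.
#' @return A `contact_map`.
#' @examples
#' parse_dot_bracket("((..))", 6)
#' @export
parse_dot_bracket <- function(db, seq) {
  n <- if (inherits(seq, "rna_sequence")) seq$n else as.integer(seq)
  db <- trimws(db)
  if (nchar(db) != n) {
    stop(sprintf("structure string length %d does not match sequence length %d",
                 nchar(db), n))
  }
  chars <- strsplit(db, "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% c(".", "-", .db_openers, .db_closers))
  if (any(bad)) {
    stop(sprintf("invalid dot-bracket character '%s' at position %d",
                 chars[which(bad)[1L]], which(bad)[1L]))
  }
  stacks <- vector("list", length(.db_openers))
  pairs <- vector("list", 0L)
  for (pos in seq_along(chars)) {
    ch <- chars[pos]
    k <- match(ch, .db_openers)
    if (!is.na(k)) {
      stacks[[k]] <- c(stacks[[k]], pos)
      next
    }
    k <- match(ch, .db_closers)
    if (!is.na(k)) {
      st <- stacks[[k]]
      if (length(st) == 0L) {
        stop(sprintf("unbalanced brackets: unmatched '%s' at position %d", ch, pos))
      }
      opener <- st[length(st)]
      stacks[[k]] <- st[-length(st)]
      pairs[[length(pairs) + 1L]] <- c(opener - 1L, pos - 1L)
    }
  }
  left <- which(lengths(stacks) > 0L)
  if (length(left) > 0L) {
    k <- left[1L]
    pos <- stacks[[k]][length(stacks[[k]])]
    stop(sprintf("unbalanced brackets: unmatched '%s' at position %d",
                 .db_openers[k], pos))
  }
  contact_map(do.call(rbind, pairs), n = n)
}

# TRUE where pair p = (i,j) crosses q = (k,l): i < k < j < l or k < i < l < j
.crosses <- function(p, q) {
  (p[1L] < q[1L] & q[1L] < p[2L] & p[2L] < q[2L]) ||
    (q[1L] < p[1L] & p[1L] < q[2L] & q[2L] < p[2L])
}

#' Write a contact map in dot-bracket notation
#'
#' Nested pairs use `()`. Crossing (pseudoknotted) pairs are assigned
#' greedily to the first additional bracket layer whose pairs they do not
#' cross. The output always re-parses to the identical pair set.
#'
#' @param cm A `contact_map`.
#' @return Character scalar of length `cm$n`.
#' @examples
#' write_dot_bracket(contact_map(rbind(c(0, 5), c(1, 4)), 6))
#' @export
write_dot_bracket <- function(cm) {
  out <- rep(".", cm$n)
  if (nrow(cm$pairs) == 0L) return(paste(out, collapse = ""))
  layers <- list()
  assign_layer <- integer(nrow(cm$pairs))
  for (r in seq_len(nrow(cm$pairs))) {
    p <- cm$pairs[r, ]
    placed <- FALSE
    for (k in seq_along(layers)) {
      lay <- layers[[k]]
      ok <- TRUE
      for (rr in seq_len(nrow(lay))) {
        if (.crosses(p, lay[rr, ])) { ok <- FALSE; break }
      }
      if (ok) {
        layers[[k]] <- rbind(lay, p)
        assign_layer[r] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      layers[[length(layers) + 1L]] <- matrix(p, ncol = 2L)
      assign_layer[r] <- length(layers)
    }
  }
  if (length(layers) > length(.db_openers)) {
    stop("structure requires more pseudoknot layers than available bracket alphabets")
  }
  for (r in seq_len(nrow(cm$pairs))) {
    k <- assign_layer[r]
    out[cm$pairs[r, 1L] + 1L] <- .db_openers[k]
    out[cm$pairs[r, 2L] + 1L] <- .db_closers[k]
  }
  paste(out, collapse = "")
}

# ---------------------------------------------------------------------------
# CT and BPSEQ formats
# ---------------------------------------------------------------------------

.split_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\r?\n")[[1L]]
  }
  text <- sub("\r$", "", text)
  text[nzchar(trimws(text))]
}

.check_pair_columns <- function(idx, pair, n, fmt) {
  if (!identical(idx, seq_len(n))) {
    stop(sprintf("%s: residue indices must be contiguous 1..n", fmt))
  }
  if (any(pair < 0L | pair > n)) {
    stop(sprintf("%s: pair index out of range", fmt))
  }
  if (any(pair == idx)) {
    stop(sprintf("%s: base %d pairs with itself", fmt, idx[which(pair == idx)[1L]]))
  }
  paired <- which(pair > 0L)
  if (any(pair[pair[paired]] != paired)) {
    bad <- paired[pair[pair[paired]] != paired][1L]
    stop(sprintf("%s: asymmetric record, base %d pairs with %d but not vice versa",
                 fmt, bad, pair[bad]))
  }
}

#' Parse a BPSEQ-format structure
#'
#' Three whitespace-separated columns per row: 1-based index, base, 1-based
#' partner index (0 if unpaired).
#'
#' @param text Character scalar (whole file) or vector of lines.
#' @param id Identifier for the resulting sequence.
#' @return A `structure_record` with `source = "file"`.
#' @export
parse_bpseq <- function(text, id = "bpseq") {
  lines <- .split_lines(text)
  lines <- lines[!grepl("^\\s*#", lines)]
  if (length(lines) == 0L) stop("BPSEQ: empty input")
  fields <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(fields) != 3L)) stop("BPSEQ: expected 3 columns per row")
  m <- do.call(rbind, fields)
  idx <- as.integer(m[, 1L])
  pair <- as.integer(m[, 3L])
  n <- length(idx)
  .check_pair_columns(idx, pair, n, "BPSEQ")
  seq <- rna_sequence(paste(m[, 2L], collapse = ""), id = id)
  paired <- which(pair > idx)
  cm <- contact_map(cbind(paired - 1L, pair[paired] - 1L), n = n)
  structure_record(seq, cm, source = "file")
}

#' Parse a CT-format structure
#'
#' A header line whose first field is the residue count, followed by
#' six-column rows: index, base, previous index, next index, 1-based partner
#' (0 if unpaired), and the index again.
#'
#' @inheritParams parse_bpseq
#' @return A `structure_record` with `source = "file"`.
#' @export
parse_ct <- function(text, id = NULL) {
  lines <- .split_lines(text)
  if (length(lines) < 2L) stop("CT: empty input")
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- suppressWarnings(as.integer(header[1L]))
  if (is.na(n) || n < 1L) stop("CT: header must start with the residue count")
  if (is.null(id)) id <- if (length(header) > 1L) header[2L] else "ct"
  body <- lines[-1L]
  if (length(body) != n) {
    stop(sprintf("CT: header declares %d residues but %d rows follow", n, length(body)))
  }
  fields <- strsplit(trimws(body), "\\s+")
  if (any(lengths(fields) < 6L)) stop("CT: expected 6 columns per row")
  m <- do.call(rbind, lapply(fields, function(f) f[1:6]))
  idx <- as.integer(m[, 1L])
  pair <- as.integer(m[, 5L])
  .check_pair_columns(idx, pair, n, "CT")
  seq <- rna_sequence(paste(m[, 2L], collapse = ""), id = id)
  paired <- which(pair > idx)
  cm <- contact_map(cbind(paired - 1L, pair[paired] - 1L), n = n)
  structure_record(seq, cm, source = "file")
}

#' Serialize a structure record to BPSEQ text
#' @param record A `structure_record`.
#' @return Character scalar (no trailing newline).
#' @export
write_bpseq <- function(record) {
  n <- record$sequence$n
  partner <- integer(n)
  p <- record$structure$pairs
  if (nrow(p) > 0L) {
    partner[p[, 1L] + 1L] <- p[, 2L] + 1L
    partner[p[, 2L] + 1L] <- p[, 1L] + 1L
  }
  paste(sprintf("%d %s %d", seq_len(n), seq_chars(record$sequence), partner),
        collapse = "\n")
}

#' Serialize a structure record to CT text
#' @param record A `structure_record`.
#' @return Character scalar (no trailing newline).
#' @export
write_ct <- function(record) {
  n <- record$sequence$n
  partner <- integer(n)
  p <- record$structure$pairs
  if (nrow(p) > 0L) {
    partner[p[, 1L] + 1L] <- p[, 2L] + 1L
    partner[p[, 2L] + 1L] <- p[, 1L] + 1L
  }
  i <- seq_len(n)
  body <- sprintf("%d %s %d %d %d %d", i, seq_chars(record$sequence),
                  i - 1L, ifelse(i == n, 0L, i + 1L), partner, i)
  paste(c(sprintf("%d %s", n, record$sequence$id), body), collapse = "\n")
}

# ---------------------------------------------------------------------------
# FASTA and file-level helpers
# ---------------------------------------------------------------------------

#' Read a multi-record FASTA file of RNA sequences
#'
#' Case is normalized and T is mapped to U. Duplicate ids raise a warning.
#'
#' @param path Path to a FASTA file.
#' @return List of `rna_sequence` objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqtype = "AA")
  if (length(recs) == 0L) stop(sprintf("FASTA file is empty: %s", path))
  ids <- names(recs)
  if (anyDuplicated(ids)) {
    warning(sprintf("duplicate FASTA ids: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  lapply(seq_along(recs), function(k) rna_sequence(as.character(recs[[k]]), id = ids[k]))
}

#' Write RNA sequences to a FASTA file
#' @param seqs List of `rna_sequence` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  seqinr::write.fasta(sequences = lapply(seqs, function(s) s$residues),
                      names = vapply(seqs, function(s) s$id, character(1L)),
                      file.out = path, as.string = TRUE, nbchar = 80)
  invisible(path)
}

#' Read a structure file, guessing the format from its extension
#'
#' `.ct` is parsed as CT, `.bpseq` as BPSEQ; anything else is treated as a
#' dot-bracket file (a `>id` header line, the sequence line, then the
#' structure line).
#'
#' @param path Path to a structure file.
#' @param format One of `"auto"`, `"db"`, `"ct"`, `"bpseq"`.
#' @return A `structure_record`.
#' @export
read_structure_file <- function(path, format = c("auto", "db", "ct", "bpseq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("structure file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ct = "ct", bpseq = "bpseq", "db")
  }
  text <- readLines(path, warn = FALSE)
  id <- tools::file_path_sans_ext(basename(path))
  switch(format,
    ct = parse_ct(text, id = id),
    bpseq = parse_bpseq(text, id = id),
    db = {
      lines <- .split_lines(text)
      if (length(lines) < 2L) stop(sprintf("dot-bracket file too short: %s", path))
      if (startsWith(lines[1L], ">")) {
        id <- sub("^>\\s*", "", lines[1L])
        lines <- lines[-1L]
      }
      if (length(lines) < 2L) stop(sprintf("dot-bracket file needs sequence and structure lines: %s", path))
      seq <- rna_sequence(lines[1L], id = id)
      db <- strsplit(trimws(lines[2L]), "\\s+")[[1L]][1L]
      structure_record(seq, parse_dot_bracket(db, seq), source = "file")
    })
}

#' Write structure records to a directory, one file per record
#'
#' CT and BPSEQ files use their native 1-based conventions; dot-bracket
#' files contain a `>id` header, the sequence and the structure string.
#'
#' @param records List of `structure_record` objects.
#' @param format One of `"db"`, `"ct"`, `"bpseq"`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of paths written.
#' @export
write_outputs <- function(records, format = c("db", "ct", "bpseq"), dir) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- switch(format, db = "db", ct = "ct", bpseq = "bpseq")
  paths <- character(length(records))
  for (k in seq_along(records)) {
    rec <- records[[k]]
    text <- switch(format,
      db = paste0(">", rec$sequence$id, "\n", rec$sequence$residues, "\n",
                  write_dot_bracket(rec$structure)),
      ct = write_ct(rec),
      bpseq = write_bpseq(rec))
    paths[k] <- file.path(dir, paste0(rec$sequence$id, ".", ext))
    writeLines(text, paths[k])
  }
  invisible(paths)
}
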