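# The ensemble "structure module": sequential channel attention over the
# learner axis, spatial attention over the pairing matrix, and a linear
# channel-reduction head producing a per-pair probability map. A simplified
# variant learns one softmax-normalized weight per base learner and takes
# the weighted sum of their contact maps.
#
# The networks are deliberately tiny (a few hundred parameters for typical
# ensemble sizes), which is what makes ensembling attractive against
# overfit-prone full structure predictors; they are implemented directly in
# R with analytic gradients (see train.R).

.sigmoid <- function(x) 1 / (1 + exp(-x))

.as_maps <- function(A) {
  if (inherits(A, "learner_stack")) A$maps else A
}

#' Initialize attention-ensemble parameters
#'
#' Parameters comprise a shared two-layer perceptron for channel attention
#' (`l -> l/r -> l`, reduction ratio `r`), a 7x7 convolution kernel over the
#' two-channel spatial descriptor, and a linear channel-reduction head. The
#' default reduction ratio is 1 (no bottleneck): with typical ensemble sizes
#' of about four learners there is no dimension to reduce.
#'
#' @param l Number of base learners (channels).
#' @param r Channel-attention reduction ratio; hidden width is
#'   `max(1, floor(l / r))`.
#' @param learner_names Learner names recorded for checkpoint compatibility
#'   checks.
#' @param seed Integer seed for the random initialization.
#' @return A list of class `cbam_params`.
#' @export
init_cbam_params <- function(l, r = 1, learner_names = paste0("learner_", seq_len(l)),
                             seed = 1L) {
  stopifnot(l >= 1, r >= 1, length(learner_names) == l)
  set.seed(seed)
  h <- max(1L, as.integer(floor(l / r)))
  structure(list(
    W1 = matrix(rnorm(h * l, sd = 0.3), h, l),
    b1 = numeric(h),
    W2 = matrix(rnorm(l * h, sd = 0.3), l, h),
    b2 = numeric(l),
    conv = array(rnorm(2 * 7 * 7, sd = 0.05), dim = c(2L, 7L, 7L)),
    conv_b = 0,
    head_w = rep(4, l),
    head_b = -2,
    l = as.integer(l), r = r, h = h,
    learner_names = as.character(learner_names),
    seed = as.integer(seed), variant = "attention", version = "1"
  ), class = "cbam_params")
}

#' Initialize lite-ensemble parameters
#'
#' One real-valued raw weight per learner; the softmax of the raw weights is
#' the learner weighting, so the normalized weights are strictly positive
#' and sum to one.
#'
#' @param l Number of base learners.
#' @param learner_names Learner names recorded for compatibility checks.
#' @return A list of class `lite_params` with zero-initialized raw weights
#'   (uniform softmax).
#' @export
init_lite_params <- function(l, learner_names = paste0("learner_", seq_len(l))) {
  stopifnot(l >= 1, length(learner_names) == l)
  structure(list(raw_weights = numeric(l), l = as.integer(l),
                 learner_names = as.character(learner_names),
                 variant = "lite", version = "1"),
            class = "lite_params")
}

.mlp_forward <- function(par, s) {
  pre <- drop(par$W1 %*% s) + par$b1
  hid <- pmax(pre, 0)
  list(out = drop(par$W2 %*% hid) + par$b2, pre = pre, hid = hid)
}

#' Channel attention over the learner axis
#'
#' Average- and max-pools each learner's matrix over both spatial
#' dimensions, passes both pooled descriptors through a shared two-layer
#' perceptron, and squashes the sum through a sigmoid, yielding one
#' attention factor per learner in (0, 1). Each learner channel is then
#' rescaled by its factor.
#'
#' @param A A `learner_stack` or list of `l` matrices.
#' @param par A `cbam_params` object.
#' @param n_real Side length of the real (non-padding) top-left block;
#'   defaults to the full matrix size. Pooling statistics are computed over
#'   the real block only, so padded and unpadded inputs agree.
#' @return List with `Fp` (length-`l` attention vector) and `A_prime`
#'   (list of rescaled matrices).
#' @export
rss_pattern_block <- function(A, par, n_real = NULL) {
  maps <- .as_maps(A)
  l <- length(maps)
  stopifnot(l == par$l)
  n <- nrow(maps[[1L]])
  if (is.null(n_real)) n_real <- n
  s_avg <- vapply(maps, sum, numeric(1L)) / (n_real^2)
  s_max <- vapply(maps, max, numeric(1L))
  Fp <- .sigmoid(.mlp_forward(par, s_avg)$out + .mlp_forward(par, s_max)$out)
  A_prime <- lapply(seq_len(l), function(c) Fp[c] * maps[[c]])
  list(Fp = Fp, A_prime = A_prime)
}

.shift_mat <- function(X, du, dv) {
  n <- nrow(X)
  out <- matrix(0, n, n)
  ri <- max(1L, 1L - du):min(n, n - du)
  ci <- max(1L, 1L - dv):min(n, n - dv)
  if (length(ri) > 0L && length(ci) > 0L) {
    out[ri, ci] <- X[ri + du, ci + dv]
  }
  out
}

.conv7_forward <- function(Pavg, Pmax, kernel, bias) {
  n <- nrow(Pavg)
  S <- matrix(bias, n, n)
  for (du in -3:3) {
    for (dv in -3:3) {
      k1 <- kernel[1L, du + 4L, dv + 4L]
      k2 <- kernel[2L, du + 4L, dv + 4L]
      if (k1 != 0) S <- S + k1 * .shift_mat(Pavg, du, dv)
      if (k2 != 0) S <- S + k2 * .shift_mat(Pmax, du, dv)
    }
  }
  S
}

#' Spatial attention over the pairing matrix
#'
#' Average- and max-pools the channel-rescaled stack along the learner axis
#' into a two-channel spatial descriptor, convolves it with a 7x7 kernel
#' (same-padding), and squashes through a sigmoid into a spatial attention
#' map in (0, 1) that multiplies every channel. The 7x7 receptive field
#' spans helix-sized neighborhoods, letting the model favor pairs supported
#' by stacked neighbors over isolated ones.
#'
#' @param A_prime List of channel-rescaled matrices.
#' @param par A `cbam_params` object.
#' @return List with `Fd` (spatial attention matrix) and `A_dprime`
#'   (list of rescaled matrices).
#' @export
domain_focus_block <- function(A_prime, par) {
  maps <- .as_maps(A_prime)
  l <- length(maps)
  Pavg <- Reduce(`+`, maps) / l
  Pmax <- Reduce(pmax, maps)
  Fd <- .sigmoid(.conv7_forward(Pavg, Pmax, par$conv, par$conv_b))
  A_dprime <- lapply(maps, function(m) Fd * m)
  list(Fd = Fd, A_dprime = A_dprime)
}

#' Linear channel-reduction head
#'
#' Combines the refined learner channels into a single per-pair pairing
#' probability: `Y[i, j] = sigmoid(sum_c w[c] * A''[c][i, j] + b)`.
#'
#' @param A_dprime List of refined matrices.
#' @param par A `cbam_params` object.
#' @return `n` x `n` probability matrix with entries in (0, 1).
#' @export
channel_head <- function(A_dprime, par) {
  maps <- .as_maps(A_dprime)
  logit <- Reduce(`+`, lapply(seq_along(maps), function(c) par$head_w[c] * maps[[c]]))
  .sigmoid(logit + par$head_b)
}

#' Full attention-ensemble forward pass
#'
#' Channel attention, then spatial attention, then the channel-reduction
#' head. Pure function of the stack and parameters.
#'
#' @param stack A `learner_stack`.
#' @param par A `cbam_params` object.
#' @param n_real Optional real (non-padding) block size; see
#'   [rss_pattern_block()].
#' @return `n` x `n` pair-probability matrix.
#' @export
ensemble_forward <- function(stack, par, n_real = NULL) {
  cb <- rss_pattern_block(stack, par, n_real = n_real)
  df <- domain_focus_block(cb$A_prime, par)
  channel_head(df$A_dprime, par)
}

#' Numerically stabilized softmax of the lite raw weights
#'
#' @param raw Numeric vector of raw (pre-softmax) weights.
#' @return Simplex vector: strictly positive, sums to one.
#' @export
lite_softmax <- function(raw) {
  e <- exp(raw - max(raw))
  e / sum(e)
}

#' Lite weighted combination of learner contact maps
#'
#' `Y = sum_v pi[v] * A[v]`. Because `pi` lies on the simplex and the
#' learner maps are binary, every entry of `Y` already lies in `[0, 1]`
#' with no extra squashing.
#'
#' @param stack A `learner_stack`.
#' @param pi Simplex weight vector of length `stack$l` (e.g. from
#'   [lite_softmax()]).
#' @return `n` x `n` pair-probability matrix.
#' @export
lite_combine <- function(stack, pi) {
  stopifnot(length(pi) == stack$l)
  Reduce(`+`, lapply(seq_len(stack$l), function(v) pi[v] * stack$maps[[v]]))
}

#' Predict a pair-probability map with either ensemble variant
#'
#' @param stack A `learner_stack`.
#' @param par `cbam_params` or `lite_params`.
#' @return `n` x `n` probability matrix.
#' @export
ensemble_predict <- function(stack, par) {
  check_stack_compat(par, stack)
  if (inherits(par, "lite_params")) {
    lite_combine(stack, lite_softmax(par$raw_weights))
  } else {
    ensemble_forward(stack, par)
  }
}

# ---------------------------------------------------------------------------
# Checkpoints
# ---------------------------------------------------------------------------

#' Save ensemble parameters to a JSON checkpoint
#'
#' The checkpoint records a version tag, the variant, the learner names and
#' ensemble size, the reduction ratio and seed where applicable, and all
#' learned values, in a plain-text portable format.
#'
#' @param par `cbam_params` or `lite_params`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_params <- function(par, path) {
  x <- unclass(par)
  x$conv <- if (!is.null(x$conv)) as.numeric(x$conv)
  x$W1 <- if (!is.null(x$W1)) list(dim = dim(par$W1), data = as.numeric(par$W1))
  x$W2 <- if (!is.null(x$W2)) list(dim = dim(par$W2), data = as.numeric(par$W2))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load ensemble parameters from a JSON checkpoint
#'
#' @param path Checkpoint path written by [save_params()].
#' @return `cbam_params` or `lite_params`, according to the stored variant.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$variant) || is.null(x$version)) {
    stop("not a valid checkpoint: missing variant/version tag")
  }
  if (x$variant == "lite") {
    par <- init_lite_params(x$l, x$learner_names)
    par$raw_weights <- as.numeric(x$raw_weights)
    return(par)
  }
  par <- init_cbam_params(x$l, r = x$r, learner_names = x$learner_names,
                          seed = x$seed)
  par$W1 <- matrix(x$W1$data, x$W1$dim[1L], x$W1$dim[2L])
  par$W2 <- matrix(x$W2$data, x$W2$dim[1L], x$W2$dim[2L])
  par$b1 <- as.numeric(x$b1)
  par$b2 <- as.numeric(x$b2)
  par$conv <- array(as.numeric(x$conv), dim = c(2L, 7L, 7L))
  par$conv_b <- as.numeric(x$conv_b)
  par$head_w <- as.numeric(x$head_w)
  par$head_b <- as.numeric(x$head_b)
  par
}

#' Check that a checkpoint matches a learner stack
#'
#' Refuses to combine parameters with a stack whose learner names or order
#' disagree with those recorded at training time.
#'
#' @param par `cbam_params` or `lite_params`.
#' @param stack A `learner_stack`.
#' @return Invisibly `TRUE`; raises an error on mismatch.
#' @export
check_stack_compat <- function(par, stack) {
  if (!identical(par$learner_names, stack$learner_names)) {
    stop(sprintf("checkpoint learner set (%s) does not match stack (%s)",
                 paste(par$learner_names, collapse = ","),
                 paste(stack$learner_names, collapse = ",")))
  }
  invisible(TRUE)
}
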