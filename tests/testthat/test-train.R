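test_that("weighted BCE matches hand-computed values", {
  # single positive cell at p = 0.5 with weight 300
  expect_equal(weighted_bce(matrix(0.5), matrix(1), pos_weight = 300),
               300 * log(2), tolerance = 1e-9)
  # single negative cell at p = 0.5, weight irrelevant
  expect_equal(weighted_bce(matrix(0.5), matrix(0), pos_weight = 300),
               log(2), tolerance = 1e-9)
  # near-perfect fit after clamping (realistically sparse positives)
  Z <- matrix(0, 10, 10)
  Z[1, 6] <- Z[6, 1] <- 1
  expect_message(l <- weighted_bce(Z, Z, pos_weight = 300), "clamping")
  expect_lt(l, 1e-5)
  expect_gte(l, 0)
})

test_that("BCE gradient at a positive cell is -w/p (finite differences)", {
  set.seed(4)
  for (k in 1:10) {
    p <- runif(1, 0.05, 0.95)
    w <- sample(c(1, 50, 300), 1)
    eps <- 1e-7
    fd <- (weighted_bce(matrix(p + eps), matrix(1), pos_weight = w) -
             weighted_bce(matrix(p - eps), matrix(1), pos_weight = w)) / (2 * eps)
    expect_equal(fd, -w / p, tolerance = 1e-4)
  }
})

test_that("padding never changes a per-example loss", {
  examples <- make_examples(6L, n_range = c(20L, 40L), seed = 6)
  # batch_size 1: no padding at all
  b1 <- make_batches(examples, 1L, seed = 3)
  expect_true(all(vapply(b1, function(b) b[[1L]]$n_real == nrow(b[[1L]]$Z),
                         logical(1L))))
  # batch_size 3: padded examples must reproduce the unpadded losses
  b3 <- make_batches(examples, 3L, seed = 3)
  par <- init_cbam_params(4L, learner_names = examples[[1L]]$stack$learner_names,
                          seed = 2)
  for (batch in b3) {
    for (ex in batch) {
      padded <- foldstack:::.attention_grad(ex$maps, ex$Z, ex$mask, par,
                                            300, ex$n_real)
      n <- ex$n_real
      plain <- foldstack:::.attention_grad(ex$stack$maps, cm_matrix(ex$truth),
                                           matrix(1, n, n), par, 300, n)
      expect_equal(padded$loss, plain$loss, tolerance = 1e-10)
    }
  }
})

test_that("batching pads to the batch maximum and shuffles reproducibly", {
  examples <- make_examples(4L, n_range = c(30L, 45L), seed = 8)
  b <- make_batches(examples, 2L, seed = 5)
  for (batch in b) {
    n_pad <- nrow(batch[[1L]]$Z)
    for (ex in batch) {
      expect_equal(nrow(ex$Z), n_pad)
      expect_equal(sum(ex$mask), ex$n_real^2)
    }
  }
  b2 <- make_batches(examples, 2L, seed = 5)
  expect_identical(lapply(b, function(x) lapply(x, `[[`, "n_real")),
                   lapply(b2, function(x) lapply(x, `[[`, "n_real")))
})

test_that("analytic gradients agree with finite differences for both variants", {
  ex <- make_examples(1L, n_range = c(16L, 22L), seed = 12)[[1L]]
  n <- ex$truth$n
  Z <- cm_matrix(ex$truth)
  mask <- matrix(1, n, n)
  par <- init_cbam_params(4L, learner_names = ex$stack$learner_names, seed = 5)
  gr <- foldstack:::.attention_grad(ex$stack$maps, Z, mask, par, 300, n)
  eps <- 1e-6
  set.seed(31)
  for (f in foldstack:::.attention_fields) {
    idx <- seq_along(par[[f]])
    if (length(idx) > 8L) idx <- sample(idx, 8L)
    for (i in idx) {
      up <- par; up[[f]][i] <- up[[f]][i] + eps
      dn <- par; dn[[f]][i] <- dn[[f]][i] - eps
      fd <- (foldstack:::.attention_grad(ex$stack$maps, Z, mask, up, 300, n)$loss -
               foldstack:::.attention_grad(ex$stack$maps, Z, mask, dn, 300, n)$loss) /
        (2 * eps)
      expect_equal(gr$grads[[f]][i], fd, tolerance = 1e-4)
    }
  }
  lp <- init_lite_params(4L, ex$stack$learner_names)
  lp$raw_weights <- c(0.4, -0.1, 0.2, 0)
  gl <- foldstack:::.lite_grad(ex$stack$maps, Z, mask, lp, 300)
  for (i in 1:4) {
    up <- lp; up$raw_weights[i] <- up$raw_weights[i] + eps
    dn <- lp; dn$raw_weights[i] <- dn$raw_weights[i] - eps
    fd <- (foldstack:::.lite_grad(ex$stack$maps, Z, mask, up, 300)$loss -
             foldstack:::.lite_grad(ex$stack$maps, Z, mask, dn, 300)$loss) / (2 * eps)
    expect_equal(gl$grads$raw_weights[i], fd, tolerance = 1e-4)
  }
})

test_that("training is deterministic and the loss descends", {
  examples <- make_examples(20L, n_range = c(25L, 40L), seed = 14)
  cfg <- train_config(epochs = 5L, learning_rate = 0.01, seed = 9,
                      val_every = 5L)
  fit1 <- train_ensemble(examples[1:16], examples[17:20], cfg = cfg,
                         variant = "attention")
  fit2 <- train_ensemble(examples[1:16], examples[17:20], cfg = cfg,
                         variant = "attention")
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$params, fit2$params)
  expect_lt(fit1$history$loss[5L], fit1$history$loss[1L])
  # lite variant descends too
  fitl <- train_ensemble(examples[1:16], examples[17:20],
                         cfg = train_config(epochs = 5L, learning_rate = 0.05,
                                            seed = 9, val_every = 5L),
                         variant = "lite")
  expect_lt(fitl$history$loss[5L], fitl$history$loss[1L])
})

test_that("training rejects empty data and warns on degenerate labels", {
  expect_error(train_ensemble(list(), cfg = train_config(epochs = 1L)), "empty")
  ex <- make_examples(2L, seed = 15)
  empty_truth <- lapply(ex, function(e) {
    training_example(e$stack, contact_map(NULL, e$truth$n), e$seq)
  })
  expect_warning(train_ensemble(empty_truth,
                                cfg = train_config(epochs = 1L),
                                variant = "lite"),
                 "degenerate")
  short <- make_examples(2L, n_range = c(20L, 30L), seed = 15)
  long <- make_examples(2L, n_range = c(40L, 45L), seed = 16)
  expect_warning(
    fit <- train_ensemble(c(short, long),
                          cfg = train_config(epochs = 1L, max_len = 38L),
                          variant = "lite"),
    "max_len")
})

test_that("a lite ensemble trained with an oracle learner recovers it", {
  cfg <- synthetic_structure_config(n_range = c(30L, 50L))
  noise <- list(
    learner_profile("na", 0.35, 20, "none", 1000L),
    learner_profile("nb", 0.35, 20, "long_range", 2000L),
    learner_profile("nc", 0.35, 20, "short_range", 3000L))
  examples <- lapply(1:15, function(k) {
    rec <- generate_structure(cfg, seed = 500 + k)
    maps <- c(list(rec$structure),
              lapply(noise, function(p) {
                simulate_learner(rec$structure, rec$sequence, p,
                                 seed = 600 + k + p$seed_offset)
              }))
    st <- learner_stack(maps, c("oracle", "na", "nb", "nc"))
    training_example(st, rec$structure, rec$sequence)
  })
  fit <- train_ensemble(examples,
                        cfg = train_config(epochs = 40L, learning_rate = 0.05,
                                           seed = 3, val_every = 1000L),
                        variant = "lite")
  w <- lite_softmax(fit$params$raw_weights)
  expect_gt(w[1L], 0.9)
})
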