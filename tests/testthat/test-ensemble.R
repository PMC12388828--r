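test_that("channel attention matches its closed form and zero-propagates", {
  l <- 4L
  par <- init_cbam_params(l, seed = 1)
  # hand-set identity MLP: two layers that compose to the identity on
  # nonnegative inputs (ReLU transparent)
  par$W1 <- diag(l); par$b1 <- numeric(l)
  par$W2 <- diag(l); par$b2 <- numeric(l)
  maps <- lapply(seq_len(l), function(c) matrix(c / 10, 5, 5))
  out <- rss_pattern_block(maps, par)
  expect_equal(out$Fp, 1 / (1 + exp(-2 * (1:4) / 10)), tolerance = 1e-12)
  expect_equal(out$A_prime[[2L]], out$Fp[2L] * maps[[2L]])
  # all-zero input with zero biases: descriptors are 0, output is 0
  zeros <- lapply(seq_len(l), function(c) matrix(0, 5, 5))
  out0 <- rss_pattern_block(zeros, par)
  expect_equal(out0$Fp, rep(0.5, l)) # sigmoid(2 * MLP(0)) = sigmoid(0)
  expect_true(all(vapply(out0$A_prime, function(m) all(m == 0), logical(1L))))
  # sigmoid range
  par2 <- init_cbam_params(l, seed = 9)
  st <- make_examples(1L, seed = 3)[[1L]]$stack
  Fp <- rss_pattern_block(st, par2)$Fp
  expect_true(all(Fp > 0 & Fp < 1))
})

test_that("spatial attention matches its closed form with a delta kernel", {
  par <- init_cbam_params(1L, seed = 2)
  par$conv[] <- 0
  alpha <- 0.7; beta <- -0.4
  par$conv[1, 4, 4] <- alpha # centered delta on the average-pool channel
  par$conv[2, 4, 4] <- beta
  par$conv_b <- 0
  A_prime <- list(matrix(runif(36), 6, 6))
  out <- domain_focus_block(A_prime, par)
  # single channel: avg pool = max pool = the map itself
  expect_equal(out$Fd, 1 / (1 + exp(-(alpha + beta) * A_prime[[1L]])),
               tolerance = 1e-12)
  expect_equal(out$A_dprime[[1L]], out$Fd * A_prime[[1L]])
  # zero input, zero bias -> Fd = 0.5 everywhere, refined output 0
  z <- domain_focus_block(list(matrix(0, 6, 6)), par)
  expect_true(all(z$Fd == 0.5))
  expect_true(all(z$A_dprime[[1L]] == 0))
})

test_that("channel head squashes a linear channel mix", {
  par <- init_cbam_params(2L, seed = 3)
  par$head_w <- c(1, 0)
  par$head_b <- 0
  A_dprime <- list(matrix(c(0, 1, 1, 0), 2, 2), matrix(runif(4), 2, 2))
  Y <- channel_head(A_dprime, par)
  expect_true(all(Y %in% (1 / (1 + exp(-c(0, 1))))))
  # zero input -> constant sigmoid(bias)
  par$head_b <- -1.3
  Y0 <- channel_head(list(matrix(0, 3, 3), matrix(0, 3, 3)), par)
  expect_true(all(abs(Y0 - 1 / (1 + exp(1.3))) < 1e-12))
})

test_that("forward pass is pure and permutation-equivariant", {
  ex <- make_examples(1L, seed = 5)[[1L]]
  par <- init_cbam_params(4L, learner_names = ex$stack$learner_names, seed = 4)
  Y1 <- ensemble_forward(ex$stack, par)
  expect_identical(Y1, ensemble_forward(ex$stack, par))
  expect_true(all(Y1 > 0 & Y1 < 1))
  # permuting learners together with the parameters leaves Y unchanged
  perm <- c(3L, 1L, 4L, 2L)
  st_p <- learner_stack(ex$stack$maps[perm], ex$stack$learner_names[perm])
  par_p <- par
  par_p$W1 <- par$W1[, perm]
  par_p$W2 <- par$W2[perm, ]
  par_p$b2 <- par$b2[perm]
  par_p$head_w <- par$head_w[perm]
  par_p$learner_names <- par$learner_names[perm]
  expect_equal(ensemble_forward(st_p, par_p), Y1, tolerance = 1e-12)
})

test_that("with neutral attention the network reduces to a squashed vote count", {
  # force both attention stages to identity and compare against a hand
  # vote-counting oracle on a 5x5 toy
  l <- 3L
  par <- init_cbam_params(l, seed = 6)
  par$W1 <- matrix(0, l, l); par$b1 <- rep(20, l) # MLP output saturates
  par$W2 <- matrix(0, l, l); par$b2 <- rep(20, l) # -> Fp ~ 1 for all channels
  par$conv[] <- 0; par$conv_b <- 20               # -> Fd ~ 1 everywhere
  par$head_w <- rep(1, l); par$head_b <- 0
  maps <- list(matrix(0, 5, 5), matrix(0, 5, 5), matrix(0, 5, 5))
  maps[[1L]][1, 5] <- maps[[1L]][5, 1] <- 1
  maps[[2L]][1, 5] <- maps[[2L]][5, 1] <- 1
  maps[[3L]][2, 4] <- maps[[3L]][4, 2] <- 1
  Y <- channel_head(domain_focus_block(rss_pattern_block(maps, par)$A_prime,
                                       par)$A_dprime, par)
  votes <- maps[[1L]] + maps[[2L]] + maps[[3L]]
  expect_equal(Y, 1 / (1 + exp(-votes)), tolerance = 1e-6)
})

test_that("lite softmax is stabilized, normalized and uniform at zero", {
  expect_equal(lite_softmax(c(0, 0, 0, 0)), rep(0.25, 4))
  big <- lite_softmax(c(1000, 0))
  expect_true(all(is.finite(big)))
  expect_gt(big[1L], 0.999)
  set.seed(8)
  for (k in 1:20) {
    p <- lite_softmax(rnorm(sample(2:9, 1), sd = 10))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
  }
})

test_that("lite combination is an affine, monotone vote average", {
  ex <- make_examples(1L, seed = 9)[[1L]]
  st <- ex$stack
  Y <- lite_combine(st, c(1, 0, 0, 0))
  expect_identical(Y, st$maps[[1L]])
  # agreement cell with equal weights
  l3 <- learner_stack(st$maps[1:3], st$learner_names[1:3])
  pi3 <- c(0.2, 0.3, 0.5)
  Y3 <- lite_combine(l3, pi3)
  both <- st$maps[[1L]] == 1 & st$maps[[3L]] == 1 & st$maps[[2L]] == 0
  if (any(both)) expect_true(all(abs(Y3[both] - 0.7) < 1e-12))
  expect_true(all(Y3 >= 0 & Y3 <= 1))
  # monotonicity: shifting weight toward a learner that contains a pair
  # never lowers that entry
  w1 <- lite_combine(l3, c(0.2, 0.3, 0.5))
  w2 <- lite_combine(l3, c(0.4, 0.3 * 0.75, 0.5 * 0.75))
  gain <- l3$maps[[1L]] == 1
  expect_true(all(w2[gain] >= w1[gain] - 1e-12))
  expect_equal(lite_combine(l3, c(0.5, 0.5, 0)),
               0.5 * st$maps[[1L]] + 0.5 * st$maps[[2L]])
})

test_that("checkpoints round-trip and refuse mismatched learner sets", {
  ex <- make_examples(1L, seed = 10)[[1L]]
  par <- init_cbam_params(4L, learner_names = ex$stack$learner_names, seed = 3)
  f <- tempfile(fileext = ".json")
  save_params(par, f)
  back <- load_params(f)
  expect_equal(back$W1, par$W1)
  expect_equal(back$conv, par$conv)
  expect_equal(ensemble_forward(ex$stack, back), ensemble_forward(ex$stack, par))
  lp <- init_lite_params(4L, ex$stack$learner_names)
  lp$raw_weights <- c(0.1, -0.2, 0.3, 0)
  save_params(lp, f)
  back2 <- load_params(f)
  expect_equal(back2$raw_weights, lp$raw_weights)
  wrong <- learner_stack(ex$stack$maps, paste0("other_", 1:4))
  expect_error(ensemble_predict(wrong, back2), "does not match")
  expect_error(load_params(tempfile()), "not found")
})
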