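test_that("confusion counts match the hand-enumerated example and sum to the universe", {
  truth <- contact_map(rbind(c(1, 10), c(2, 9)), 12)
  pred <- contact_map(rbind(c(1, 10), c(3, 8)), 12)
  cts <- confusion(pred, truth)
  expect_equal(cts[c("TP", "FP", "FN", "TN")],
               list(TP = 1L, FP = 1L, FN = 1L, TN = 63L))
  expect_equal(cts$TP + cts$FP + cts$FN + cts$TN, 12 * 11 / 2)
  same <- confusion(truth, truth)
  expect_equal(same$FP + same$FN, 0L)
  none <- confusion(contact_map(NULL, 12), truth)
  expect_equal(none$TP, 0L)
  expect_equal(none$FN, 2L)
})

test_that("confusion agrees with a cell-enumeration oracle on random pairs", {
  set.seed(51)
  for (k in 1:50) {
    n <- sample(10:40, 1)
    a <- random_contact_map(n)
    b <- random_contact_map(n)
    expect_identical(confusion(a, b)[c("TP", "FP", "TN", "FN")],
                     confusion_oracle(a, b))
  }
})

test_that("precision/recall/F1 follow the formulas with 0/0 -> 0 conventions", {
  pm <- pair_metrics(list(TP = 1, FP = 1, FN = 1))
  expect_equal(pm[c("precision", "recall", "f1")],
               list(precision = 0.5, recall = 0.5, f1 = 0.5))
  perfect <- pair_metrics(list(TP = 7, FP = 0, FN = 0))
  expect_equal(perfect$f1, 1)
  degen <- pair_metrics(list(TP = 0, FP = 0, FN = 0))
  expect_equal(c(degen$precision, degen$recall, degen$f1), c(0, 0, 0))
  expect_true(degen$degenerate)
})

test_that("INF matches the worked example and equals an independent MCC", {
  expect_equal(inf_score(list(TP = 3, FP = 1, FN = 1, TN = 20)),
               59 / sqrt(4 * 21 * 4 * 21), tolerance = 1e-12)
  expect_equal(inf_score(list(TP = 5, FP = 0, FN = 0, TN = 10)), 1)
  expect_equal(inf_score(list(TP = 0, FP = 0, FN = 3, TN = 10)), 0)
  set.seed(52)
  for (k in 1:200) {
    cts <- list(TP = sample(0:30, 1), FP = sample(0:30, 1),
                TN = sample(1:200, 1), FN = sample(0:30, 1))
    m <- mcc_oracle(cts$TP, cts$FP, cts$TN, cts$FN)
    expect_equal(inf_score(cts), m, tolerance = 1e-12)
  }
})

test_that("Jaccard distance matches set enumeration and the metric axioms", {
  a <- contact_map(rbind(c(1, 5), c(2, 8)), 10)
  b <- contact_map(rbind(c(1, 5), c(3, 9)), 10)
  expect_equal(jaccard_distance(a, b), 2 / 3)
  expect_equal(jaccard_distance(a, a), 0)
  disjoint <- contact_map(rbind(c(0, 7)), 10)
  expect_equal(jaccard_distance(b, disjoint), 1)
  expect_equal(jaccard_distance(contact_map(NULL, 5), contact_map(NULL, 5)), 0)
  set.seed(53)
  for (k in 1:60) {
    n <- sample(10:30, 1)
    x <- random_contact_map(n); y <- random_contact_map(n); z <- random_contact_map(n)
    expect_equal(jaccard_distance(x, y), jaccard_oracle(x, y))
    expect_equal(jaccard_distance(x, y), jaccard_distance(y, x))
    # triangle inequality
    expect_lte(jaccard_distance(x, z),
               jaccard_distance(x, y) + jaccard_distance(y, z) + 1e-12)
  }
})

test_that("pairwise concordance equals a direct loop and is symmetric", {
  set.seed(54)
  preds <- list(
    alg1 = lapply(1:20, function(k) random_contact_map(25)),
    alg2 = lapply(1:20, function(k) random_contact_map(25)),
    alg3 = lapply(1:20, function(k) random_contact_map(25)))
  J <- pairwise_concordance(preds)
  expect_equal(diag(J), c(alg1 = 0, alg2 = 0, alg3 = 0))
  expect_equal(J, t(J), tolerance = 1e-15)
  direct <- mean(vapply(1:20, function(k) {
    jaccard_distance(preds$alg1[[k]], preds$alg2[[k]])
  }, numeric(1L)))
  expect_equal(J["alg1", "alg2"], direct)
})

test_that("ROC area is 1 for perfect scores, 0.5 for constant scores", {
  set.seed(55)
  truths <- lapply(1:5, function(k) random_contact_map(20, min_dist = 4L))
  perfect <- lapply(truths, cm_matrix)
  expect_equal(roc_points(perfect, truths)$auc, 1)
  flat <- lapply(truths, function(x) matrix(0.5, 20, 20))
  expect_equal(roc_points(flat, truths)$auc, 0.5)
  # 3-point toy with hand-ordered scores: cells (1,2): score .5 label 1,
  # (1,3): .9 label 0, (2,3): .2 label 0
  Y <- matrix(0, 3, 3)
  Y[1, 2] <- 0.5; Y[1, 3] <- 0.9; Y[2, 3] <- 0.2
  tr <- contact_map(rbind(c(0, 1)), 3)
  r <- roc_points(list(Y), list(tr))
  # hand-computed staircase: (0,0) -> (0.5,0) -> (0.5,1) -> (1,1), area 0.5
  expect_equal(r$auc, 0.5)
  expect_error(roc_points(flat, lapply(1:5, function(k) contact_map(NULL, 20))),
               "positive and negative")
})

test_that("error-map PCA places identical algorithms together and truth at zero", {
  set.seed(56)
  cfg <- synthetic_structure_config(n_range = c(30L, 40L))
  recs <- lapply(1:10, function(k) generate_structure(cfg, seed = 900 + k))
  truths <- lapply(recs, function(r) r$structure)
  noisy <- lapply(recs, function(r) {
    simulate_learner(r$structure, r$sequence,
                     learner_profile("x", 0.6, 10, "long_range"), seed = 1)
  })
  preds <- list(exact1 = truths, exact2 = truths, noisy = noisy)
  emb <- pca_error_embedding(preds, truths)
  expect_equal(emb$pc1[1L], emb$pc1[2L], tolerance = 1e-9)
  expect_equal(emb$pc2[1L], emb$pc2[2L], tolerance = 1e-9)
  d12 <- 0
  d13 <- sqrt((emb$pc1[1L] - emb$pc1[3L])^2 + (emb$pc2[1L] - emb$pc2[3L])^2)
  expect_gt(d13, d12)
})

test_that("PCA distances rank-correlate with Jaccard concordance across biases", {
  cfg <- synthetic_structure_config(n_range = c(40L, 60L))
  profs <- list(learner_profile("u", 0.8, 12, "none", 0L),
                learner_profile("l", 0.8, 12, "long_range", 1000L),
                learner_profile("s", 0.8, 12, "short_range", 2000L))
  recs <- lapply(1:40, function(k) generate_structure(cfg, seed = 2500 + k))
  preds <- lapply(profs, function(p) {
    lapply(seq_along(recs), function(k) {
      simulate_learner(recs[[k]]$structure, recs[[k]]$sequence, p,
                       seed = 300 + k + p$seed_offset)
    })
  })
  names(preds) <- vapply(profs, function(p) p$name, character(1L))
  truths <- lapply(recs, function(r) r$structure)
  J <- pairwise_concordance(preds)
  emb <- pca_error_embedding(preds, truths)
  pcd <- as.matrix(dist(emb[, c("pc1", "pc2")]))
  ut <- upper.tri(J)
  expect_gt(suppressWarnings(cor(J[ut], pcd[ut], method = "spearman")), 0)
})

test_that("combination search covers all subsets with nondecreasing best-by-size", {
  profs <- list(learner_profile("strong", 0.9, 4, "none", 0L),
                learner_profile("weak", 0.5, 14, "short_range", 1000L),
                learner_profile("fair", 0.7, 10, "long_range", 2000L))
  examples <- make_examples(24L, n_range = c(30L, 50L), seed = 60,
                            profiles = profs)
  rep <- combination_search(examples, 1:18, 19:24,
                            cfg = train_config(epochs = 15L,
                                               learning_rate = 0.05,
                                               seed = 2, val_every = 1000L))
  expect_equal(nrow(rep$subsets), 7L) # 2^3 - 1
  expect_true(all(diff(rep$by_size$best_f1) >= 0))
  # a subset containing an oracle learner is near-perfect
  oracle_examples <- lapply(examples, function(e) {
    maps <- c(list(e$truth), e$stack$maps[2:3])
    training_example(learner_stack(maps, c("oracle", "weak", "fair")),
                     e$truth, e$seq)
  })
  rep2 <- combination_search(oracle_examples, 1:18, 19:24,
                             cfg = train_config(epochs = 25L,
                                                learning_rate = 0.05,
                                                seed = 2, val_every = 1000L))
  best <- max(rep2$subsets$median_f1)
  expect_gt(best, 0.98)
  expect_error(combination_search(make_examples(
    2L, seed = 61,
    profiles = lapply(1:11, function(k) learner_profile(paste0("p", k), 0.8, 8,
                                                        "none", k * 100L))),
    1L, 2L), "force")
})
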