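make_toy_table <- function(features, labels, traj = seq_along(labels),
                           kind = "gccd") {
  feature_table(features,
                data.frame(trajectory_id = traj,
                           frame_index = seq_along(labels),
                           label = labels, stringsAsFactors = FALSE),
                kind)
}

test_that("pairwise distances match a brute-force double loop", {
  set.seed(10)
  X <- matrix(rnorm(10 * 6), nrow = 10)
  tab <- make_toy_table(X, rep(c("glycosylated", "aglycosylated"), 5))
  Dm <- pairwise_distances(tab)
  expect_equal(diag(Dm), rep(0, 10), ignore_attr = TRUE)
  for (i in 1:10) for (j in 1:10) {
    expect_equal(Dm[i, j], sqrt(sum((X[i, ] - X[j, ])^2)), tolerance = 1e-12)
  }
  # unit basis vectors are sqrt(2) apart
  e <- diag(2)
  tab2 <- make_toy_table(e, c("glycosylated", "aglycosylated"))
  expect_equal(pairwise_distances(tab2)[1, 2], sqrt(2))
})

test_that("k-NN prediction is a majority vote with stable ties", {
  X <- matrix(c(0, 0, 1, 1, 0.1, 0.1), ncol = 2, byrow = TRUE)
  train <- make_toy_table(X[1:2, ], c("glycosylated", "aglycosylated"))
  test <- make_toy_table(X[3, , drop = FALSE], "glycosylated")
  expect_equal(knn_predict(train, test, 1), "glycosylated")
  # identical vector, k = 1: picks that item's label
  test2 <- make_toy_table(X[2, , drop = FALSE], "glycosylated")
  expect_equal(knn_predict(train, test2, 1), "aglycosylated")
  # single-class training data always predicts that class
  train1 <- make_toy_table(matrix(rnorm(12), 6), rep("glycosylated", 6))
  testn <- make_toy_table(matrix(rnorm(4), 2), rep("aglycosylated", 2))
  expect_equal(unname(knn_predict(train1, testn, 3)), rep("glycosylated", 2))
  expect_error(knn_predict(train1, testn, 4), "odd")
  expect_error(knn_predict(train1, testn, 7), "exceeds")
})

test_that("k-NN agrees with an exhaustive-sort reference on random data", {
  set.seed(22)
  Xtr <- matrix(rnorm(50 * 4), nrow = 50)
  ytr <- sample(c("glycosylated", "aglycosylated"), 50, replace = TRUE)
  Xte <- matrix(rnorm(20 * 4), nrow = 20)
  train <- make_toy_table(Xtr, ytr)
  test <- make_toy_table(Xte, rep("glycosylated", 20))
  for (k in c(1, 5, 9)) {
    pred <- knn_predict(train, test, k)
    ref <- vapply(seq_len(20), function(i) {
      d <- sqrt(colSums((t(Xtr) - Xte[i, ])^2))
      votes <- ytr[order(d)[1:k]]
      names(which.max(table(votes)))
    }, "")
    expect_equal(unname(pred), unname(ref))
  }
})

test_that("grid search scores nine validation splits and breaks ties low", {
  sets <- make_fixture_trajectories(n_frames = 6, class_effect = 0.5,
                                    noise_sd = 0.05, seed = 3)
  train_sets <- sets[1:6]                   # 3 glyco + 3 aglyco
  grid <- epsilon_grid(0.2, 4, 0.1)
  sigmas <- c(0.125, 0.25)
  tabs <- summarize_frames(train_sets, grid, sigmas)
  sel <- grid_search(tabs, sigmas, ks = c(3, 5))
  expect_equal(nrow(sel$accuracies), 4L)    # 2 sigmas x 2 ks
  expect_true(all(sel$accuracies$mean_accuracy >= 0 &
                    sel$accuracies$mean_accuracy <= 1))
  # separable fixtures: every pair is perfect, tie -> smallest sigma and k
  expect_equal(sel$sigma, 0.125)
  expect_equal(sel$k, 3)
  expect_equal(max(sel$accuracies$mean_accuracy), 1)
  expect_error(grid_search(tabs, c(0.125, 0.9), c(3)), "missing")
  expect_error(grid_search(tabs, sigmas, c(2, 3)), "odd")
})

test_that("evaluation runs 16 leakage-free train/test splits", {
  sets <- make_fixture_trajectories(n_frames = 4, class_effect = 0.5,
                                    noise_sd = 0.05, seed = 9)
  grid <- epsilon_grid(0.2, 4, 0.1)
  tabs <- summarize_frames(sets, grid, sigmas = 0.25)
  res <- evaluate_splits(tabs, sigmas = 0.25, ks = 3)
  expect_equal(nrow(res$splits), 16L)
  expect_equal(sort(unique(res$splits$glyco)), 0:3)
  expect_equal(sort(unique(res$splits$aglyco)), 0:3)
  expect_equal(res$mean_accuracy, mean(res$splits$accuracy))
  # determinism: identical inputs give identical outputs
  res2 <- evaluate_splits(tabs, sigmas = 0.25, ks = 3)
  expect_identical(res, res2)
})

test_that("split construction requires both classes in numbers", {
  sets <- make_fixture_trajectories(n_frames = 2, seed = 1)[1:3]
  grid <- epsilon_grid(0.2, 4, 0.1)
  tabs <- summarize_frames(sets, grid, sigmas = 0.25)
  expect_error(evaluate_splits(tabs, 0.25, 3), "two trajectories")
})

test_that("embeddings recover exact low-dimensional structure", {
  # three collinear summaries embed with ~zero distortion
  X <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  tab <- make_toy_table(X, rep("unlabeled", 3))
  mds <- embed_summaries(tab, "mds")
  emb_d <- as.matrix(dist(mds$coordinates))
  expect_equal(emb_d, as.matrix(dist(X)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # PCA on rank-2 data explains everything with two components
  set.seed(13)
  basis <- matrix(rnorm(2 * 8), nrow = 2)
  scores <- matrix(rnorm(20 * 2), ncol = 2)
  tab2 <- make_toy_table(scores %*% basis, rep("unlabeled", 20))
  pca <- embed_summaries(tab2, "pca")
  expect_equal(sum(pca$explained_variance_ratio), 1, tolerance = 1e-10)
  expect_lte(sum(pca$explained_variance_ratio), 1 + 1e-12)
  expect_error(embed_summaries(make_toy_table(X[1:2, ], rep("unlabeled", 2)),
                               "mds"), "too few")
})
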