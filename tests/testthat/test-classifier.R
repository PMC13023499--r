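test_that("standardization follows its affine contract", {
  set.seed(91)
  X <- matrix(rnorm(200, 5, 3), 50, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  Z <- standardize(X)
  expect_equal(unname(colMeans(Z)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 4), tolerance = 1e-9)
  # idempotence
  Z2 <- standardize(Z)
  expect_equal(as.vector(Z2), as.vector(Z), tolerance = 1e-9)
  # applying train-row statistics to shifted data moves every value by the
  # shift in z units (affine contract)
  tr <- 1:30
  Zt <- standardize(X, stats_from = tr)
  shifted <- sweep(sweep(X + 2, 2, attr(Zt, "center")), 2,
                   attr(Zt, "scale"), "/")
  expected <- matrix(rep(2 / attr(Zt, "scale"), each = 50), 50, 4)
  expect_equal(as.vector(shifted - Zt), as.vector(expected), tolerance = 1e-9)
  Xc <- X; Xc[, 2] <- 7
  expect_error(standardize(Xc), "f2")
})

test_that("clustering recovers well-separated blobs exactly", {
  set.seed(92)
  X <- rbind(matrix(rnorm(60, 0, 1), ncol = 2),
             matrix(rnorm(60, 20, 1), ncol = 2))
  truth <- rep(1:2, each = 30)
  for (lk in c("average", "single", "complete")) {
    cl <- agglomerative_cluster(X, lk, 2)
    expect_equal(canon_partition(cl$labels), canon_partition(truth))
    # top merge dwarfs the second on separated data
    h <- sort(cl$heights, decreasing = TRUE)
    expect_gt(h[1] / h[2], 2)
  }
  # identical points merge at distance 0 first
  cl3 <- agglomerative_cluster(matrix(c(1, 1, 1, 1, 5, 5), ncol = 2,
                                      byrow = TRUE), "single", 2)
  expect_equal(sort(cl3$heights)[1], 0)
  expect_error(agglomerative_cluster(matrix(1, 1, 1), n_clusters = 2),
               "fewer rows")
})

test_that("all three linkages match a brute-force reference merge-for-merge", {
  set.seed(93)
  for (lk in c("single", "complete", "average")) {
    # chain plus random instances
    chain <- matrix(c(0, 1.0, 2.1, 3.3, 4.6), ncol = 1)
    X5 <- matrix(rnorm(12), ncol = 2)
    for (X in list(chain, X5)) {
      ref <- brute_linkage(X, lk)
      cl <- agglomerative_cluster(X, lk, 2)
      expect_equal(sort(cl$heights), sort(ref$heights), tolerance = 1e-9)
      n <- nrow(X)
      ours2 <- canon_partition(cl$labels)
      ref2 <- canon_partition(ref$partitions[[n - 2]])
      expect_equal(ours2, ref2)
    }
  }
})

test_that("cluster naming follows mean FAA and ignores index order", {
  labels <- rep(c(1L, 2L), each = 10)
  p_faa <- c(rnorm(10, 0.5, 0.05), rnorm(10, -0.5, 0.05))
  cls <- label_clusters_by_faa(labels, p_faa)
  expect_equal(cls, rep(c(1L, 2L), each = 10))
  # swapping cluster indices leaves classes unchanged
  cls_swapped <- label_clusters_by_faa(3L - labels, p_faa)
  expect_equal(cls_swapped, cls)
  expect_message(label_clusters_by_faa(labels, rep(0.2, 20)), "equal")
  expect_error(label_clusters_by_faa(rep(1L, 20), p_faa), "two clusters")
})

test_that("coincidence rates behave on perfect, random, and flipped labels", {
  p <- c(rep(0.4, 50), rep(-0.4, 50))
  perfect <- c(rep(1L, 50), rep(2L, 50))
  expect_equal(coincidence_rate(perfect, p),
               c(class1_pct = 100, class2_pct = 100))
  flipped <- 3L - perfect
  expect_equal(coincidence_rate(flipped, p),
               c(class1_pct = 0, class2_pct = 0))
  set.seed(94)
  pr <- sample(1:2, 1000, replace = TRUE)
  pb <- rep(c(0.3, -0.3), 500)
  cc <- coincidence_rate(pr, pb)
  expect_true(all(abs(cc - 50) < 6))
  # empty class is missing, zero FAA counts as Class 2
  expect_true(is.na(coincidence_rate(rep(1L, 4), c(1, -1, 1, -1))[["class2_pct"]]))
  expect_equal(coincidence_rate(c(2L, 2L), c(0, 0))[["class2_pct"]], 100)
})

test_that("FAA columns are firewalled out of the classifier features", {
  expect_error(fit_emotion_model(data.frame(), c("Mean_Tn", "P_Asym")),
               "may not enter")
  expect_error(loto_cv(data.frame(), c("MI_Asym")), "may not enter")
})

test_that("the fitted model depends only on training rows", {
  s <- tiny_session(n_trials = 4, duration = 120, kappa = 0.9, seed = 95)
  tab <- build_feature_table(s)
  feats <- c("Mean_Tn", "Std_Tn", "TVSymp")
  train <- tab[tab$trial != 4, ]
  test <- tab[tab$trial == 4, ]
  m1 <- fit_emotion_model(train, feats)
  # mutate the held-out rows arbitrarily; the trained model must not move
  test_mutated <- test
  test_mutated[, feats] <- test_mutated[, feats] * 100 + 7
  m2 <- fit_emotion_model(train, feats)
  expect_identical(m1$center, m2$center)
  expect_identical(m1$train_classes, m2$train_classes)
  expect_equal(m1$svm$coefs, m2$svm$coefs)
  expect_equal(m1$svm$SV, m2$svm$SV)
  # predictions on the original held-out rows are unchanged as well
  expect_identical(predict(m1, test), predict(m2, test))
})

test_that("LOTO-CV performance rises strongly with coupling", {
  s <- tiny_session(n_trials = 12, duration = 120, kappa = 0.9, seed = 96,
                    noise_sd = list(eeg = 0.3, eda = 0.005, drift = 0.02,
                                    latent = 0.12))
  tab <- build_feature_table(s)
  rk <- mi_feature_ranking(tab, "P_Asym", group_by = c("participant", "task"))
  cv <- loto_cv(tab, select_top_features(rk, 6))
  expect_s3_class(cv, "cv_report")
  expect_equal(nrow(cv$per_trial), 12L)
  expect_true(all(cv$per_trial$class1_pct >= 0 & cv$per_trial$class1_pct <= 100,
                  na.rm = TRUE))
  expect_gt(cv$overall, 70)
  # zero coupling: EDA carries no FAA information; the coincidence collapses
  # far below the strongly coupled level (the per-class metric is not
  # centred at 50 when classes are arbitrary, so "chance" is a broad band)
  s0 <- tiny_session(n_trials = 12, duration = 120, kappa = 0, seed = 97)
  tab0 <- build_feature_table(s0)
  cv0 <- loto_cv(tab0, c("Mean_Tn", "Std_Tn", "SCR_Ampl", "TVSymp"))
  expect_lt(cv0$overall, 70)
  expect_lt(cv0$overall, cv$overall - 25)
})
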