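test_that("the bench yields one out-of-fold record per case and classifier", {
  coded <- tiny_coded(n = 100, seed = 41)
  rec <- run_cv_bench(coded, k_folds = 5, seed = 2,
                      hyperparams = list(NN = list(size = 2, decay = 1,
                                                   maxit = 50)))
  expect_equal(nrow(rec), 100 * 6)
  expect_equal(as.integer(table(rec$classifier)), rep(100L, 6))
  key <- paste(rec$case_id, rec$classifier)
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(rec$score >= 0 & rec$score <= 1, na.rm = TRUE))
  expect_true(all(rec$predicted == (rec$score >= 0.5), na.rm = TRUE))
  # out-of-fold discipline: a case's fold matches the fold assignment map
  fold_map <- attr(rec, "fold")
  expect_equal(unname(fold_map[rec$case_id]), rec$fold)
})

test_that("a perfectly separable outcome is learned exactly by LR", {
  withr::local_seed(7)
  n <- 120
  X <- cbind(sig = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
             noise = rnorm(n))
  rownames(X) <- paste0("c", seq_len(n))
  coded <- structure(list(case_id = rownames(X), classifier_matrix = X,
                          binary_matrix = (X > 0) * 1L,
                          outcome = as.integer(X[, "sig"] > 0)),
                     class = "coded_cohort")
  rec <- run_cv_bench(coded, classifiers = c("LR", "DT"), k_folds = 5,
                      seed = 3)
  m <- traditional_metrics(rec)
  expect_equal(m$accuracy[m$classifier == "LR"], 1.0)
  expect_equal(m$auc[m$classifier == "LR"], 1.0)
})

test_that("the bench is deterministic given the seed", {
  coded <- tiny_coded(n = 100, seed = 43)
  hp <- list(NN = list(size = 2, decay = 1, maxit = 50))
  r1 <- run_cv_bench(coded, k_folds = 5, seed = 11, hyperparams = hp)
  r2 <- run_cv_bench(coded, k_folds = 5, seed = 11, hyperparams = hp)
  expect_identical(r1$score, r2$score)
  r3 <- run_cv_bench(coded, k_folds = 5, seed = 12, hyperparams = hp)
  expect_false(identical(r1$fold, r3$fold))
})

test_that("KNN prediction honors its distance metrics", {
  Xtr <- rbind(c(0, 0), c(0, 1), c(5, 5), c(5, 6))
  ytr <- c(0, 0, 1, 1)
  Xte <- rbind(c(0, 0.4), c(5, 5.4))
  expect_equal(knn_predict(Xtr, ytr, Xte, k = 2, metric = "manhattan"),
               c(0, 1))
  expect_equal(knn_predict(Xtr, ytr, Xte, k = 4, metric = "euclidean"),
               c(0.5, 0.5))
  # hamming counts unequal coordinates
  expect_equal(knn_predict(rbind(c(0, 0), c(1, 1)), c(0, 1),
                           rbind(c(0, 1)), k = 1, metric = "hamming"), 0)
})

test_that("grid search picks the best configuration with small-model ties", {
  coded <- tiny_coded(n = 120, seed = 47)
  # single-point grid -> that point
  g1 <- grid_search(coded, "KNN",
                    grid = data.frame(k = 7, metric = "manhattan"),
                    k_folds = 3, seed = 5, mode = "pooled")
  expect_equal(g1$k, 7)
  # the chosen K must match brute-force evaluation of both grid points
  grid2 <- data.frame(k = c(1, 35), metric = "manhattan")
  g2 <- grid_search(coded, "KNN", grid = grid2, k_folds = 3, seed = 5,
                    mode = "pooled")
  res <- attr(g2, "grid_results")
  expect_equal(g2$k, res$k[which.max(res$cv_accuracy)])
  expect_equal(g2$cv_accuracy, max(res$cv_accuracy))
  # tie goes to the smaller model: duplicate configuration
  g3 <- grid_search(coded, "KNN",
                    grid = data.frame(k = c(9, 9), metric = "manhattan"),
                    k_folds = 3, seed = 5, mode = "pooled")
  expect_equal(g3$k, 9)
  res3 <- attr(g3, "grid_results")
  expect_equal(res3$cv_accuracy[1], res3$cv_accuracy[2])
})

test_that("nested grid search runs and returns a grid member", {
  coded <- tiny_coded(n = 100, seed = 53)
  g <- grid_search(coded, "NN",
                   grid = data.frame(size = c(1, 3), decay = 1),
                   k_folds = 3, seed = 5, mode = "nested", inner_folds = 2)
  expect_true(g$size %in% c(1, 3))
  expect_true(g$cv_accuracy >= 0 && g$cv_accuracy <= 1)
})

test_that("traditional metrics match hand arithmetic on a toy confusion", {
  # TP=3 FP=1 FN=1 TN=5
  rec <- data.frame(
    case_id = 1:10, classifier = "LR", fold = 1,
    score = c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.15, 0.1, 0.05),
    predicted = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
    truth = c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  )
  m <- traditional_metrics(rec)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  # rank AUC equals the Mann-Whitney probability
  truth <- rec$truth; s <- rec$score
  pairs <- expand.grid(i = which(truth == 1), j = which(truth == 0))
  auc_brute <- mean(ifelse(s[pairs$i] > s[pairs$j], 1,
                           ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
  expect_equal(m$auc, auc_brute)
})

test_that("rank-based AUC matches the pROC reference", {
  withr::local_seed(17)
  rec <- data.frame(case_id = 1:80, classifier = "LR", fold = 1,
                    score = round(runif(80), 2),  # ties on purpose
                    truth = rbinom(80, 1, 0.4))
  rec$predicted <- as.integer(rec$score >= 0.5)
  ref <- as.numeric(pROC::auc(rec$truth, rec$score, quiet = TRUE,
                              direction = "<"))
  expect_equal(traditional_metrics(rec)$auc, ref, tolerance = 1e-12)
})

test_that("AUC is invariant to monotone score transformations", {
  withr::local_seed(13)
  rec <- data.frame(case_id = 1:50, classifier = "NB", fold = 1,
                    score = runif(50), truth = rbinom(50, 1, 0.5))
  rec$predicted <- as.integer(rec$score >= 0.5)
  a1 <- traditional_metrics(rec)$auc
  rec2 <- rec; rec2$score <- plogis(5 * rec$score - 2)
  rec2$predicted <- rec$predicted
  expect_equal(traditional_metrics(rec2)$auc, a1)
})

test_that("degenerate truth yields explicit undefined metrics with reasons", {
  rec <- data.frame(case_id = 1:6, classifier = "DT", fold = 1,
                    score = c(0.1, 0.2, 0.3, 0.2, 0.1, 0.4),
                    predicted = 0, truth = 0)
  m <- traditional_metrics(rec)
  expect_equal(m$accuracy, 1.0)
  expect_true(is.na(m$recall))
  expect_true(is.na(m$f1))
  expect_true(is.na(m$auc))
  expect_match(m$note, "recall undefined")
  # all predictions correct -> every defined metric is 1
  rec2 <- data.frame(case_id = 1:6, classifier = "LR", fold = 1,
                     score = c(0.9, 0.8, 0.9, 0.1, 0.2, 0.1),
                     predicted = c(1, 1, 1, 0, 0, 0),
                     truth = c(1, 1, 1, 0, 0, 0))
  m2 <- traditional_metrics(rec2)
  expect_equal(unlist(m2[c("accuracy", "precision", "recall", "f1", "auc")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1, auc = 1))
})

test_that("a failing classifier is recorded and the bench continues", {
  coded <- tiny_coded(n = 100, seed = 59)
  # constant feature matrix breaks LDA (zero within-group variance)
  coded$classifier_matrix[] <- 1
  rec <- run_cv_bench(coded, classifiers = c("LDA", "DT"), k_folds = 5,
                      seed = 3)
  fails <- attr(rec, "failures")
  expect_gt(length(fails), 0)
  expect_true(all(vapply(fails, `[[`, character(1), "classifier") == "LDA"))
  # DT rows survive with valid predictions
  expect_false(anyNA(rec$score[rec$classifier == "DT"]))
})
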