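#' @title Six-classifier cross-validation bench
#' @description Internal backbone shared by [run_cv_bench()] and
#'   [grid_search()]. The bench trains each classifier on k-1 folds and
#'   keeps the held-out probability for every case, linked back to its
#'   case id, so downstream evaluation can stratify per-case correctness
#'   by difficulty bin.
#' @name classifier_bench
NULL

CLASSIFIERS <- c("LR", "LDA", "KNN", "DT", "NB", "NN")

default_hyperparams <- function() {
  list(
    KNN = list(k = 27L, metric = "manhattan", p = 2),
    NN  = list(size = 15L, decay = 1, maxit = 300L),
    DT  = list(cp = 0.01),
    LR = list(), LDA = list(), NB = list()
  )
}

# stratified fold assignment, deterministic given the current RNG state
make_folds <- function(outcome, k) {
  fold <- integer(length(outcome))
  for (cls in unique(outcome)) {
    idx <- which(outcome == cls)
    if (length(idx) < k)
      stop("need at least ", k, " cases per class for ", k, "-fold CV")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# z-score columns using training-fold statistics only
standardize_pair <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(train = sweep(sweep(train, 2L, mu), 2L, sdv, `/`),
       test  = sweep(sweep(test,  2L, mu), 2L, sdv, `/`))
}

# ---- individual classifier backends ----------------------------------------
# Each returns the held-out probability of class 1.

fit_predict_one <- function(name, Xtr, ytr, Xte, hp) {
  switch(name,
    LR = {
      df <- data.frame(Xtr); df$.y <- ytr
      fit <- suppressWarnings(
        stats::glm(.y ~ ., data = df, family = stats::binomial()))
      suppressWarnings(
        stats::predict(fit, newdata = data.frame(Xte), type = "response"))
    },
    LDA = {
      fit <- MASS::lda(Xtr, grouping = factor(ytr, levels = c(0, 1)))
      stats::predict(fit, Xte)$posterior[, "1"]
    },
    KNN = knn_predict(Xtr, ytr, Xte, k = hp$k, metric = hp$metric, p = hp$p),
    DT = {
      df <- data.frame(Xtr); df$.y <- factor(ytr, levels = c(0, 1))
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          cp = if (is.null(hp$cp)) 0.01 else hp$cp)
      stats::predict(fit, newdata = data.frame(Xte), type = "prob")[, "1"]
    },
    NB = {
      fit <- e1071::naiveBayes(Xtr, factor(ytr, levels = c(0, 1)))
      stats::predict(fit, Xte, type = "raw")[, "1"]
    },
    NN = {
      fit <- nnet::nnet(Xtr, ytr, size = hp$size, decay = hp$decay,
                        maxit = if (is.null(hp$maxit)) 200L else hp$maxit,
                        entropy = TRUE, trace = FALSE, MaxNWts = 5000L)
      drop(stats::predict(fit, Xte))
    },
    stop("unknown classifier: ", name)
  )
}

#' K-nearest-neighbor probability prediction with a choice of metric
#'
#' Plain vote-share KNN supporting the Minkowski family plus Hamming
#' distance (count of unequal coordinates). Returns the fraction of the
#' \code{k} nearest training cases labeled 1; distance ties are broken by
#' training-set order.
#'
#' @param Xtr,ytr training feature matrix and 0/1 labels.
#' @param Xte test feature matrix.
#' @param k number of neighbors.
#' @param metric \code{"minkowski"}, \code{"manhattan"} or
#'   \code{"hamming"} (\code{"euclidean"} = minkowski with \code{p = 2}).
#' @param p Minkowski order.
#' @return Probability vector for the test cases.
#' @export
knn_predict <- function(Xtr, ytr, Xte, k = 5L,
                        metric = c("minkowski", "manhattan", "hamming",
                                   "euclidean"),
                        p = 2) {
  metric <- match.arg(metric)
  k <- min(as.integer(k), nrow(Xtr))
  D <- matrix(0, nrow(Xte), nrow(Xtr))
  for (j in seq_len(ncol(Xtr))) {
    diffs <- abs(outer(Xte[, j], Xtr[, j], `-`))
    D <- D + switch(metric,
                    manhattan = diffs,
                    hamming   = (diffs > 1e-12) * 1,
                    euclidean = diffs^2,
                    minkowski = diffs^p)
  }
  vapply(seq_len(nrow(Xte)), function(i) {
    nb <- order(D[i, ])[seq_len(k)]
    mean(ytr[nb])
  }, numeric(1))
}

#' Run the classifier bench with out-of-fold prediction tracking
#'
#' Trains each requested classifier under stratified k-fold
#' cross-validation and records, for every case, the probability assigned
#' by the one model that never saw it. Continuous features are z-scored
#' with training-fold statistics for LR, LDA, KNN and the neural network;
#' the decision tree and naive Bayes consume raw values. Fold assignment
#' and all stochastic classifiers are deterministic given \code{seed}.
#'
#' @param coded a [code_cohort()] result (or any list with
#'   \code{classifier_matrix}, \code{outcome}, \code{case_id}).
#' @param classifiers subset of \code{c("LR","LDA","KNN","DT","NB","NN")}
#'   (logistic regression, linear discriminant analysis, K-nearest
#'   neighbors, decision tree, naive Bayes, neural network).
#' @param k_folds number of folds (default 10).
#' @param seed integer seed.
#' @param hyperparams named list of per-classifier settings; see
#'   \code{cdistrat:::default_hyperparams()} for the defaults.
#' @param threshold decision threshold on the class-1 probability.
#' @return data.frame of class \code{"prediction_records"} with columns
#'   \code{case_id}, \code{classifier}, \code{fold}, \code{score},
#'   \code{predicted}, \code{truth}. A classifier that fails on a fold
#'   leaves \code{NA} scores for that fold's cases and an entry in the
#'   \code{"failures"} attribute; the bench keeps running.
#' @export
run_cv_bench <- function(coded, classifiers = CLASSIFIERS, k_folds = 10L,
                         seed = 1L, hyperparams = list(), threshold = 0.5) {
  X <- coded$classifier_matrix
  y <- coded$outcome
  ids <- coded$case_id
  stopifnot(!anyNA(X), all(y %in% c(0, 1)))
  classifiers <- match.arg(classifiers, CLASSIFIERS, several.ok = TRUE)
  hp <- utils::modifyList(default_hyperparams(), hyperparams)

  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  fold <- make_folds(y, k_folds)

  scaled <- c("LR", "LDA", "KNN", "NN")
  out <- vector("list", length(classifiers) * k_folds)
  failures <- list()
  i <- 0L
  for (f in seq_len(k_folds)) {
    te <- which(fold == f); tr <- which(fold != f)
    std <- standardize_pair(X[tr, , drop = FALSE], X[te, , drop = FALSE])
    for (cl in classifiers) {
      i <- i + 1L
      Xtr <- if (cl %in% scaled) std$train else X[tr, , drop = FALSE]
      Xte <- if (cl %in% scaled) std$test  else X[te, , drop = FALSE]
      set.seed((seed + 7L * f + 131L * match(cl, CLASSIFIERS)) %% .Machine$integer.max)
      sc <- tryCatch(fit_predict_one(cl, Xtr, y[tr], Xte, hp[[cl]]),
                     error = function(e) {
                       failures[[length(failures) + 1L]] <<-
                         list(classifier = cl, fold = f,
                              message = conditionMessage(e))
                       rep(NA_real_, length(te))
                     })
      out[[i]] <- data.frame(case_id = ids[te], classifier = cl, fold = f,
                             score = as.numeric(sc),
                             predicted = as.integer(sc >= threshold),
                             truth = y[te], stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, out)
  rec <- rec[order(match(rec$classifier, CLASSIFIERS),
                   match(rec$case_id, ids)), ]
  rownames(rec) <- NULL
  attr(rec, "failures") <- failures
  attr(rec, "fold") <- stats::setNames(fold, ids)
  class(rec) <- c("prediction_records", "data.frame")
  rec
}

#' Hyperparameter grid search by cross-validated accuracy
#'
#' Evaluates every grid configuration for the KNN or neural-network
#' classifier and returns the one with the highest mean cross-validated
#' accuracy. Ties go to the smaller model (fewer neighbors / fewer hidden
#' units), then to grid order. Two modes are provided: \code{"pooled"}
#' scores each configuration by one k-fold CV over the full data (a single
#' grid-search pass), and \code{"nested"} scores it by inner 5-fold CVs
#' run inside each outer training fold only, which keeps the outer test
#' folds untouched by selection.
#'
#' @param coded a [code_cohort()] result.
#' @param classifier \code{"KNN"} or \code{"NN"}.
#' @param grid data.frame of configurations — columns \code{k},
#'   \code{metric}, optionally \code{p} for KNN; \code{size}, \code{decay}
#'   for NN. Defaults to the full search grids
#'   ([default_grid()]).
#' @param k_folds outer folds.
#' @param seed integer seed.
#' @param mode \code{"nested"} or \code{"pooled"}.
#' @param inner_folds inner folds for nested mode.
#' @return One-row data.frame: the chosen configuration plus its
#'   \code{cv_accuracy}; full per-configuration results in attribute
#'   \code{"grid_results"}.
#' @export
grid_search <- function(coded, classifier = c("KNN", "NN"), grid = NULL,
                        k_folds = 10L, seed = 1L,
                        mode = c("nested", "pooled"), inner_folds = 5L) {
  classifier <- match.arg(classifier)
  mode <- match.arg(mode)
  if (is.null(grid)) grid <- default_grid(classifier)
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  needed <- if (classifier == "KNN") c("k", "metric") else c("size", "decay")
  if (!all(needed %in% names(grid)))
    stop(classifier, " grid needs columns: ", paste(needed, collapse = ", "))

  X <- coded$classifier_matrix; y <- coded$outcome
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  eval_config <- function(cfg, idx, folds) {
    hp <- as.list(cfg)
    if (classifier == "KNN" && is.null(hp$p)) hp$p <- 2
    if (classifier == "NN" && is.null(hp$maxit)) hp$maxit <- 200L
    correct <- 0L; total <- 0L
    for (f in unique(folds)) {
      tr <- idx[folds != f]; te <- idx[folds == f]
      std <- standardize_pair(X[tr, , drop = FALSE], X[te, , drop = FALSE])
      set.seed((seed + 977L * f) %% .Machine$integer.max)
      sc <- fit_predict_one(classifier, std$train, y[tr], std$test, hp)
      correct <- correct + sum((sc >= 0.5) == y[te])
      total <- total + length(te)
    }
    correct / total
  }

  acc <- numeric(nrow(grid))
  if (mode == "pooled") {
    folds <- make_folds(y, k_folds)
    for (g in seq_len(nrow(grid)))
      acc[g] <- eval_config(grid[g, , drop = FALSE], seq_along(y), folds)
  } else {
    outer_folds <- make_folds(y, k_folds)
    accs <- matrix(0, nrow(grid), k_folds)
    for (f in seq_len(k_folds)) {
      tr <- which(outer_folds != f)
      inner <- make_folds(y[tr], inner_folds)
      for (g in seq_len(nrow(grid)))
        accs[g, f] <- eval_config(grid[g, , drop = FALSE], tr, inner)
    }
    acc <- rowMeans(accs)
  }

  size_col <- if (classifier == "KNN") grid$k else grid$size
  ord <- order(-acc, size_col, seq_len(nrow(grid)))
  best <- grid[ord[1L], , drop = FALSE]
  best$cv_accuracy <- acc[ord[1L]]
  rownames(best) <- NULL
  results <- grid
  results$cv_accuracy <- acc
  attr(best, "grid_results") <- results
  best
}

#' @rdname grid_search
#' @export
default_grid <- function(classifier = c("KNN", "NN")) {
  classifier <- match.arg(classifier)
  if (classifier == "KNN") {
    expand.grid(k = 1:40, metric = c("minkowski", "hamming", "manhattan"),
                stringsAsFactors = FALSE)
  } else {
    expand.grid(size = c(1L, 5L, 10L, 15L, 20L, 25L, 30L),
                decay = c(0.01, 0.1, 0.5, 1, 2))
  }
}

#' Traditional whole-sample metrics per classifier
#'
#' Computes accuracy, precision, recall, F1 and AUC from the out-of-fold
#' prediction records. AUC is the rank-based (Mann--Whitney) probability
#' that a random death case scores above a random survivor, with ties
#' counted half. A metric whose denominator is empty (e.g. recall with no
#' positive cases) is reported as \code{NA} with the reason in
#' \code{note}.
#'
#' @param records a [run_cv_bench()] result.
#' @param truth optional named 0/1 vector (names = case ids) overriding the
#'   recorded truth.
#' @return data.frame of class \code{"metric_block"}: one row per
#'   classifier with \code{accuracy}, \code{precision}, \code{recall},
#'   \code{f1}, \code{auc}, \code{note}.
#' @export
traditional_metrics <- function(records, truth = NULL) {
  stopifnot(is.data.frame(records),
            all(c("case_id", "classifier", "score", "predicted") %in%
                  names(records)))
  if (!is.null(truth)) {
    if (is.null(names(truth))) stop("`truth` must be named by case_id")
    miss <- setdiff(records$case_id, names(truth))
    if (length(miss)) stop("truth missing for case(s): ",
                           paste(utils::head(miss, 5), collapse = ", "))
    records$truth <- as.integer(truth[as.character(records$case_id)])
  }
  if (!"truth" %in% names(records)) stop("records carry no truth column")

  per_class <- lapply(split(records, records$classifier), function(r) {
    y <- r$truth; yhat <- r$predicted; s <- r$score
    ok <- !is.na(s)
    y <- y[ok]; yhat <- yhat[ok]; s <- s[ok]
    tp <- sum(y == 1 & yhat == 1); fp <- sum(y == 0 & yhat == 1)
    fn <- sum(y == 1 & yhat == 0); tn <- sum(y == 0 & yhat == 0)
    notes <- character(0)
    accuracy <- (tp + tn) / length(y)
    precision <- if (tp + fp > 0) tp / (tp + fp) else {
      notes <- c(notes, "precision undefined: no positive predictions")
      NA_real_
    }
    recall <- if (tp + fn > 0) tp / (tp + fn) else {
      notes <- c(notes, "recall undefined: no positive cases")
      NA_real_
    }
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else {
        notes <- c(notes, "F1 undefined")
        NA_real_
      }
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    auc <- if (n1 > 0 && n0 > 0) {
      rk <- rank(s)                 # midranks handle ties
      (sum(rk[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    } else {
      notes <- c(notes, "AUC undefined: one class absent")
      NA_real_
    }
    data.frame(classifier = r$classifier[1L], accuracy = accuracy,
               precision = precision, recall = recall, f1 = f1, auc = auc,
               note = paste(notes, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_class)
  out <- out[order(match(out$classifier, CLASSIFIERS)), ]
  rownames(out) <- NULL
  class(out) <- c("metric_block", "data.frame")
  out
}
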