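# small deterministic records fixture: two classifiers, hand-set correctness
toy_records <- function(correct_a, correct_b, bins) {
  n <- length(bins)
  truth <- rep(0L, n)
  rbind(
    data.frame(case_id = seq_len(n), classifier = "A", fold = 1,
               score = 0.2, predicted = ifelse(correct_a, 0L, 1L),
               truth = truth),
    data.frame(case_id = seq_len(n), classifier = "B", fold = 1,
               score = 0.2, predicted = ifelse(correct_b, 0L, 1L),
               truth = truth)
  )
}

toy_scores <- function(bins) {
  data.frame(case_id = seq_along(bins), cdi = bins, se = 0.3, bin = bins)
}

test_that("stratified accuracy aggregates correctness per bin and classifier", {
  bins <- rep(c(-0.5, 0, 0.5), each = 4)
  ca <- c(TRUE, TRUE, TRUE, TRUE,  TRUE, FALSE, FALSE, TRUE,  rep(TRUE, 4))
  cb <- c(TRUE, FALSE, TRUE, FALSE, rep(FALSE, 4), TRUE, TRUE, FALSE, TRUE)
  rep_ <- stratified_accuracy(toy_records(ca, cb, bins), toy_scores(bins))
  expect_s3_class(rep_, "stratified_report")
  # ordered positive -> negative
  expect_equal(unique(rep_$bin), c(0.5, 0, -0.5))
  expect_equal(rep_$accuracy[rep_$bin == 0 & rep_$classifier == "A"], 0.5)
  expect_equal(rep_$accuracy[rep_$bin == 0 & rep_$classifier == "B"], 0)
  # a bin answered correctly by everyone reads 100%
  expect_equal(rep_$accuracy[rep_$bin == 0.5 & rep_$classifier == "A"], 1)
  expect_equal(sum(rep_$n_cases[rep_$classifier == "A"]), length(bins))
})

test_that("count-weighted bin accuracies reproduce overall accuracy exactly", {
  coded <- tiny_coded(n = 200, seed = 61)
  fit <- cdi_irt(coded$binary_matrix)
  sc <- cdi_scores(fit, min_count = 20)
  rec <- run_cv_bench(coded, k_folds = 5, seed = 7,
                      hyperparams = list(NN = list(size = 2, decay = 1,
                                                   maxit = 50)))
  rep_ <- stratified_accuracy(rec, sc)
  m <- traditional_metrics(rec)
  for (cl in unique(rep_$classifier)) {
    sub <- rep_[rep_$classifier == cl, ]
    expect_equal(sum(sub$accuracy * sub$n_cases) / sum(sub$n_cases),
                 m$accuracy[m$classifier == cl], tolerance = 1e-12)
  }
  # single-bin degenerate input collapses to the traditional accuracy
  sc1 <- sc; sc1$bin <- 0
  rep1 <- stratified_accuracy(rec, sc1)
  expect_equal(rep1$accuracy[rep1$classifier == "LR"],
               m$accuracy[m$classifier == "LR"], tolerance = 1e-12)
  # a record without a score is an error
  expect_error(stratified_accuracy(rec, sc[-1, ]), "missing")
})

test_that("difficulty descriptives match closed forms", {
  # constant CDI: zero association by convention
  d0 <- cdi_descriptives(rep(0.3, 50), rep(c(0, 1), 25))
  expect_equal(d0$r, 0)
  expect_equal(d0$t, 0)
  # CDI identical to the outcome: maximal point-biserial for the sizes
  y <- rep(c(0, 1), c(30, 20))
  d1 <- cdi_descriptives(as.numeric(y), y)
  expect_equal(d1$r, 1)
  # analytic point-biserial for separated Gaussians
  withr::local_seed(15)
  n <- 6000
  y2 <- rbinom(n, 1, 0.5)
  cdi <- rnorm(n, ifelse(y2 == 1, 0.4, -0.4), 0.7)
  d2 <- cdi_descriptives(cdi, y2)
  p <- mean(y2)
  s_pop <- sd(cdi) * sqrt((n - 1) / n)
  r_expected <- (mean(cdi[y2 == 1]) - mean(cdi[y2 == 0])) *
    sqrt(p * (1 - p)) / s_pop
  expect_equal(d2$r, r_expected, tolerance = 1e-6)
  expect_lt(abs(d2$r - 0.8 * sqrt(0.25) / sqrt(0.7^2 + 0.16)), 0.05)
  # pooled-variance t with df = n - 2
  expect_equal(d2$df, n - 2)
  tt <- t.test(cdi[y2 == 1], cdi[y2 == 0], var.equal = TRUE)
  expect_equal(d2$t, unname(tt$statistic))
  # one empty group -> undefined with reason
  d3 <- cdi_descriptives(rnorm(10), rep(0, 10))
  expect_true(is.na(d3$r))
  expect_match(d3$note, "empty")
})

test_that("effect-model Wald statistics match a brute-force ML oracle", {
  # two bins x two classifiers, aggregated binomial counts
  cells <- expand.grid(bin = c(0, 1), classifier = c("A", "B"))
  cells$n <- c(40, 50, 40, 50)
  cells$k <- c(22, 41, 30, 35)
  # expand to per-case records
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    correct <- rep(c(1L, 0L), c(cells$k[i], cells$n[i] - cells$k[i]))
    data.frame(case_id = paste0(i, "_", seq_len(cells$n[i])),
               classifier = cells$classifier[i],
               predicted = correct, truth = 1L,
               bin = cells$bin[i])
  }))
  rows$predicted <- ifelse(rows$predicted == 1, 1L, 0L)
  rows$truth <- 1L
  scores <- data.frame(case_id = rows$case_id, cdi = rows$bin, se = 0.3,
                       bin = rows$bin)
  em <- fit_effect_model(rows[c("case_id", "classifier", "predicted",
                                "truth")], scores)

  # independent oracle: numeric ML fit of the same saturated model
  nll <- function(beta) {
    X <- cbind(1, c(1, -1, 1, -1), c(1, 1, -1, -1),
               c(1, -1, -1, 1)) # sum-to-zero coding, bins (0,1) x cls (A,B)
    eta <- drop(X %*% beta)
    -sum(cells$k * eta - cells$n * log1p(exp(eta)))
  }
  opt <- optim(rep(0, 4), nll, hessian = TRUE, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000))
  V <- solve(opt$hessian)
  wald_or <- function(i) opt$par[i]^2 / V[i, i]
  # order of terms in the fit: bin, classifier, interaction
  expect_equal(em$tests$wald_chisq[em$tests$effect == "bin"],
               wald_or(2), tolerance = 1e-3)
  expect_equal(em$tests$wald_chisq[em$tests$effect == "classifier"],
               wald_or(3), tolerance = 1e-3)
  expect_equal(em$tests$wald_chisq[em$tests$effect == "bin:classifier"],
               wald_or(4), tolerance = 1e-3)
  # saturated model: fitted cell means equal observed proportions
  expect_equal(em$cells$fitted, em$cells$prob, tolerance = 1e-8)
})

test_that("sign conventions of the sum-coded oracle match the model frame", {
  # sanity companion for the oracle above: same data through glm directly
  cells <- data.frame(bin = factor(c(0, 1, 0, 1)),
                      classifier = factor(c("A", "A", "B", "B")),
                      k = c(22, 41, 30, 35), n = c(40, 50, 40, 50))
  fit <- glm(cbind(k, n - k) ~ bin * classifier, data = cells,
             family = binomial(),
             contrasts = list(bin = contr.sum, classifier = contr.sum))
  W <- (coef(fit) / sqrt(diag(vcov(fit))))^2
  expect_equal(length(W), 4L)
})

test_that("estimated marginal means agree with the emmeans reference", {
  withr::local_seed(37)
  bins <- rep(c(-0.5, 0, 0.5), each = 40)
  ca <- runif(120) < plogis(0.4 + 0.6 * abs(bins))
  cb <- runif(120) < plogis(0.1 + 0.6 * abs(bins))
  recs <- toy_records(ca, cb, bins)
  em <- fit_effect_model(recs, toy_scores(bins))

  dat <- data.frame(correct = as.integer(recs$predicted == recs$truth),
                    bin = relevel(factor(rep(bins, 2)), "0"),
                    classifier = factor(recs$classifier))
  g <- glm(correct ~ bin * classifier, dat, family = binomial())
  ref_bin <- suppressMessages(summary(emmeans::emmeans(g, ~ bin)))
  ref_cls <- suppressMessages(summary(emmeans::emmeans(g, ~ classifier)))
  expect_equal(
    em$emm$bin$logit[match(ref_bin$bin, em$emm$bin$level)],
    ref_bin$emmean, tolerance = 1e-6)
  expect_equal(
    em$emm$classifier$logit[match(ref_cls$classifier,
                                  em$emm$classifier$level)],
    ref_cls$emmean, tolerance = 1e-6)
  expect_equal(
    em$emm$bin$se[match(ref_bin$bin, em$emm$bin$level)],
    ref_bin$SE, tolerance = 1e-6)
})

test_that("complete separation triggers the ridge path with a flag", {
  bins <- rep(c(0, 1), each = 30)
  ca <- c(rep(TRUE, 15), rep(FALSE, 15), rep(TRUE, 30))   # 100% in bin 1
  cb <- c(rep(TRUE, 20), rep(FALSE, 10), rep(TRUE, 20), rep(FALSE, 10))
  em <- fit_effect_model(toy_records(ca, cb, bins), toy_scores(bins))
  expect_true(em$separation)
  expect_true(all(is.finite(em$coefficients)))
  expect_true(any(em$cells$separated))
})

test_that("pairwise comparisons find no pairs among identical classifiers", {
  bins <- rep(c(-0.5, 0, 0.5), each = 20)
  withr::local_seed(23)
  ca <- runif(60) < 0.7
  em <- fit_effect_model(toy_records(ca, ca, bins), toy_scores(bins))
  pr <- pairwise_comparisons(em, alpha = 0.001)
  # classifier contrasts all null
  expect_false(any(pr$scope == "classifier"))
  all_ct <- attr(pr, "all")
  cls_ct <- all_ct[all_ct$scope == "classifier", ]
  expect_equal(cls_ct$z, 0, tolerance = 1e-8)
})

test_that("a large uniform classifier gap is detected by the pairwise tests", {
  withr::local_seed(29)
  bins <- rep(c(-0.5, 0, 0.5), each = 1500)
  pa <- plogis(1.0)   # ~0.73
  pb <- plogis(0.0)   # 0.50, logit gap 1.0
  ca <- runif(length(bins)) < pa
  cb <- runif(length(bins)) < pb
  em <- fit_effect_model(toy_records(ca, cb, bins), toy_scores(bins))
  pr <- pairwise_comparisons(em, alpha = 0.001)
  expect_true(any(pr$scope == "classifier" & pr$higher == "A" &
                    pr$lower == "B"))
  # classifier main effect significant, interaction not, at alpha 0.001
  t <- em$tests
  expect_lt(t$p[t$effect == "classifier"], 0.001)
  expect_gt(t$p[t$effect == "bin:classifier"], 0.001)
})

test_that("hard-bin chi-squares match hand computations and report direction", {
  # 2x2 table (20,10 / 10,20) -> Pearson chi-square 6.667 without correction
  n <- 60
  feature <- rep(c(0, 1), each = 30)
  correct <- c(rep(c(1, 0), c(20, 10)), rep(c(1, 0), c(10, 20)))
  coded <- structure(list(
    case_id = as.character(seq_len(n)),
    binary_matrix = matrix(feature, ncol = 1,
                           dimnames = list(as.character(seq_len(n)), "f1")),
    classifier_matrix = matrix(0, n, 1), outcome = rep(0L, n)),
    class = "coded_cohort")
  rec <- data.frame(case_id = as.character(seq_len(n)), classifier = "NN",
                    fold = 1, score = 0.2,
                    predicted = ifelse(correct == 1, 0L, 1L),
                    truth = 0L)
  scores <- data.frame(case_id = as.character(seq_len(n)), cdi = 0, se = 0.3,
                       bin = 0)
  tab <- hard_bin_feature_chisq(coded, rec, scores, 0, "NN")
  expect_equal(tab$chisq[tab$feature == "f1"], 60 * (20 * 20 - 10 * 10)^2 /
                 (30 * 30 * 30 * 30), tolerance = 1e-10)
  expect_equal(tab$chisq[tab$feature == "f1"], 20 / 3, tolerance = 1e-10)
  expect_match(tab$direction[tab$feature == "f1"], "in-range")

  # a feature identical to correctness: chi-square = n (phi = 1)
  coded$binary_matrix <- cbind(coded$binary_matrix,
                               f2 = as.integer(correct == 1))
  tab2 <- hard_bin_feature_chisq(coded, rec, scores, 0, "NN")
  expect_equal(tab2$chisq[tab2$feature == "f2"], n, tolerance = 1e-10)
  # constant feature skipped with reason
  coded$binary_matrix <- cbind(coded$binary_matrix, f3 = 1L)
  tab3 <- hard_bin_feature_chisq(coded, rec, scores, 0, "NN")
  expect_true(is.na(tab3$chisq[tab3$feature == "f3"]))
  expect_match(tab3$note[tab3$feature == "f3"], "constant")
})

test_that("features independent of correctness show near-nominal rejection", {
  withr::local_seed(31)
  ps <- replicate(50, {
    n <- 80
    feature <- rbinom(n, 1, 0.5)
    correct <- rbinom(n, 1, 0.7)
    coded <- structure(list(
      case_id = as.character(seq_len(n)),
      binary_matrix = matrix(feature, ncol = 1,
                             dimnames = list(as.character(seq_len(n)),
                                             "f1")),
      classifier_matrix = matrix(0, n, 1), outcome = rep(0L, n)),
      class = "coded_cohort")
    rec <- data.frame(case_id = as.character(seq_len(n)),
                      classifier = "NN", fold = 1, score = 0.2,
                      predicted = ifelse(correct == 1, 0L, 1L), truth = 0L)
    scores <- data.frame(case_id = as.character(seq_len(n)), cdi = 0,
                         se = 0.3, bin = 0)
    hard_bin_feature_chisq(coded, rec, scores, 0, "NN")$p[1]
  })
  expect_lt(mean(ps < 0.05, na.rm = TRUE), 0.16)  # near nominal alpha 0.05
})
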