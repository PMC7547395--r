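#' Accuracy stratified by difficulty bin
#'
#' The central report of the method: instead of one scalar accuracy per
#' classifier, accuracy is computed within each difficulty stratum, so
#' classifiers can be compared on the easy (peripheral) and hard (central)
#' cases separately.
#'
#' @param records out-of-fold [run_cv_bench()] predictions.
#' @param scores a [cdi_scores()] table (binned, post-collapse).
#' @return data.frame of class \code{"stratified_report"} in long format:
#'   \code{bin}, \code{classifier}, \code{n_cases}, \code{accuracy}
#'   (proportion in [0, 1]), ordered from the most positive to the most
#'   negative bin center. The count-weighted mean of a classifier's bin
#'   accuracies equals its overall accuracy exactly.
#' @seealso [print.stratified_report()] renders the familiar wide
#'   percentage table; [plot.stratified_report()] draws accuracy against
#'   bin.
#' @export
stratified_accuracy <- function(records, scores) {
  stopifnot(is.data.frame(records), is.data.frame(scores),
            all(c("case_id", "bin") %in% names(scores)))
  idx <- match(as.character(records$case_id), as.character(scores$case_id))
  if (anyNA(idx))
    stop("case(s) present in records but missing a difficulty score: ",
         paste(utils::head(unique(records$case_id[is.na(idx)]), 5),
               collapse = ", "))
  records$bin <- scores$bin[idx]
  records$correct <- as.integer(records$predicted == records$truth)

  agg <- stats::aggregate(correct ~ bin + classifier, data = records,
                          FUN = function(x) c(n = length(x), acc = mean(x)))
  out <- data.frame(bin = agg$bin, classifier = agg$classifier,
                    n_cases = agg$correct[, "n"],
                    accuracy = agg$correct[, "acc"])
  out <- out[order(-out$bin, match(out$classifier, CLASSIFIERS)), ]
  rownames(out) <- NULL
  class(out) <- c("stratified_report", "data.frame")
  out
}

# wide bin x classifier view used by print/export (accuracy in percent)
widen_report <- function(report, digits = 1) {
  bins <- sort(unique(report$bin), decreasing = TRUE)
  cls <- unique(report$classifier)
  cls <- cls[order(match(cls, CLASSIFIERS))]
  wide <- data.frame(
    n_cases = vapply(bins, function(b)
      report$n_cases[report$bin == b][1L], numeric(1)),
    cdi_bin = bins)
  for (cl in cls) {
    wide[[cl]] <- vapply(bins, function(b) {
      a <- report$accuracy[report$bin == b & report$classifier == cl]
      if (length(a)) round(100 * a, digits) else NA_real_
    }, numeric(1))
  }
  wide
}

#' @export
print.stratified_report <- function(x, ...) {
  cat("Mortality-prediction accuracy stratified by difficulty bin (%)\n")
  print(widen_report(x), row.names = FALSE)
  invisible(x)
}

#' @export
#' @rdname stratified_accuracy
#' @param x a \code{stratified_report}.
#' @param ... passed to [graphics::matplot()].
plot.stratified_report <- function(x, ...) {
  wide <- widen_report(x)
  cls <- setdiff(names(wide), c("n_cases", "cdi_bin"))
  graphics::matplot(wide$cdi_bin, as.matrix(wide[cls]), type = "b",
                    pch = seq_along(cls), lty = 1,
                    xlab = "CDI bin", ylab = "Accuracy (%)", ...)
  graphics::legend("bottomright", legend = cls, pch = seq_along(cls),
                   col = seq_along(cls), lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Export the stratified report as a wide CSV
#'
#' One row per bin ordered positive to negative, a column per classifier,
#' accuracies as percentages to one decimal.
#'
#' @param report a [stratified_accuracy()] result.
#' @param path output CSV path.
#' @export
write_stratified_report <- function(report, path) {
  utils::write.csv(widen_report(report), path, row.names = FALSE)
  invisible(path)
}

#' Descriptive statistics of the difficulty index against the outcome
#'
#' Range, mean and SD of the CDI; group means by outcome; the
#' point-biserial correlation between CDI and the 0/1 outcome (identical
#' to the Pearson correlation) with its test; and the pooled-variance
#' two-sample t-test between outcome groups (df = n - 2).
#'
#' @param cdi numeric difficulty scores (or a [cdi_scores()] table).
#' @param outcome 0/1 outcome vector, same length/order.
#' @return List of class \code{"cdi_descriptives"}.
#' @export
cdi_descriptives <- function(cdi, outcome) {
  if (is.data.frame(cdi)) cdi <- cdi$cdi
  stopifnot(length(cdi) == length(outcome), all(outcome %in% c(0, 1)))
  g0 <- cdi[outcome == 0]; g1 <- cdi[outcome == 1]
  out <- list(
    n = length(cdi), range = range(cdi),
    mean = mean(cdi), sd = stats::sd(cdi),
    mean_no_death = if (length(g0)) mean(g0) else NA_real_,
    sd_no_death = if (length(g0) > 1) stats::sd(g0) else NA_real_,
    mean_death = if (length(g1)) mean(g1) else NA_real_,
    sd_death = if (length(g1) > 1) stats::sd(g1) else NA_real_,
    r = NA_real_, r_p = NA_real_, t = NA_real_, df = NA_integer_,
    t_p = NA_real_, note = ""
  )
  if (length(g0) == 0L || length(g1) == 0L) {
    out$note <- "one outcome group empty: r and t undefined"
  } else if (stats::sd(cdi) == 0) {
    # degenerate: no variance anywhere, zero association by convention
    out$r <- 0; out$r_p <- 1; out$t <- 0
    out$df <- length(cdi) - 2L; out$t_p <- 1
    out$note <- "CDI constant: zero association"
  } else {
    ct <- stats::cor.test(cdi, outcome)
    out$r <- unname(ct$estimate); out$r_p <- ct$p.value
    # pooled-variance two-sample t with df = n - 2, computed directly so a
    # zero pooled variance (perfectly separated groups) stays well defined
    n0 <- length(g0); n1 <- length(g1)
    df <- n0 + n1 - 2L
    sp2 <- ((n0 - 1) * stats::var(g0) + (n1 - 1) * stats::var(g1)) / df
    out$df <- df
    if (sp2 == 0) {
      out$t <- Inf * sign(mean(g1) - mean(g0))
      out$t_p <- 0
      out$note <- "zero within-group variance: t unbounded"
    } else {
      out$t <- (mean(g1) - mean(g0)) / sqrt(sp2 * (1 / n0 + 1 / n1))
      out$t_p <- 2 * stats::pt(-abs(out$t), df)
    }
  }
  class(out) <- "cdi_descriptives"
  out
}

#' @export
print.cdi_descriptives <- function(x, ...) {
  cat(sprintf("CDI descriptives (n = %d)\n", x$n))
  cat(sprintf("  range %.2f to %+.2f; mean %.2f (SD %.2f)\n",
              x$range[1], x$range[2], x$mean, x$sd))
  cat(sprintf("  no death %.2f (SD %.2f); death %.2f (SD %.2f)\n",
              x$mean_no_death, x$sd_no_death, x$mean_death, x$sd_death))
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  if (!is.na(x$r))
    cat(sprintf("  point-biserial r = %.3f (p = %.3g); t(%d) = %.2f (p = %.3g)\n",
                x$r, x$r_p, x$df, x$t, x$t_p))
  invisible(x)
}

# ---- fixed-effects binomial model on correctness ---------------------------

# ridge-penalized binomial IRLS on aggregated cell counts; used when the
# plain fit hits complete separation in a cell
ridge_irls <- function(Xm, k, n, lambda = 1e-4, max_iter = 200L) {
  beta <- rep(0, ncol(Xm))
  for (it in seq_len(max_iter)) {
    eta <- drop(Xm %*% beta)
    p <- stats::plogis(eta)
    W <- pmax(n * p * (1 - p), 1e-10)
    z <- eta + (k - n * p) / W
    A <- crossprod(Xm * W, Xm) + diag(lambda, ncol(Xm))
    beta_new <- solve(A, crossprod(Xm * W, z))
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(Xm %*% beta)
  p <- stats::plogis(eta)
  W <- pmax(n * p * (1 - p), 1e-10)
  V <- solve(crossprod(Xm * W, Xm) + diag(lambda, ncol(Xm)))
  list(coefficients = drop(beta), vcov = V)
}

#' Fixed-effects logistic model of correctness by bin and classifier
#'
#' Fits the binomial logit model \code{correct ~ bin * classifier} to the
#' per-(case, classifier) correctness indicators — all effects fixed, the
#' dependent variable binomial, predictors linked through the logit, and
#' the difficulty-bin reference category set to 0 (the hardest stratum).
#' Because every classifier scores every case and the model is saturated,
#' the fit operates on the aggregated bin x classifier success counts,
#' which is the identical likelihood. Omnibus Wald chi-square tests (with
#' equivalent F statistics) for the bin main effect, classifier main
#' effect, and their interaction use sum-to-zero contrasts, the
#' Type-III convention of repeated-measure GLM software.
#'
#' Cells with 0\% or 100\% correctness have infinite sample logits; they
#' are flagged, and the model is refitted with a small ridge penalty
#' (\code{lambda}) so every reported coefficient is finite. The flag is
#' carried on the returned object.
#'
#' @param records out-of-fold [run_cv_bench()] predictions.
#' @param scores a binned [cdi_scores()] table.
#' @param lambda ridge used only under complete separation.
#' @return Object of class \code{"effect_model"}: \code{tests} (data.frame
#'   effect / wald_chisq / df / f_value / df2 / p), \code{cells} (per
#'   bin x classifier counts, observed proportions, fitted logits and
#'   standard errors), \code{emm} (estimated marginal means per factor on
#'   both scales), \code{coefficients}, \code{vcov}, \code{separation}.
#' @export
fit_effect_model <- function(records, scores, lambda = 1e-4) {
  idx <- match(as.character(records$case_id), as.character(scores$case_id))
  if (anyNA(idx)) stop("records contain cases without difficulty scores")
  dat <- data.frame(
    correct = as.integer(records$predicted == records$truth),
    bin = factor(scores$bin[idx]),
    classifier = factor(records$classifier)
  )
  dat <- dat[!is.na(dat$correct), ]
  if (nlevels(droplevels(dat$bin)) < 2L)
    stop("need at least 2 difficulty bins after collapsing")
  if (nlevels(droplevels(dat$classifier)) < 2L)
    stop("need at least 2 classifiers")
  dat$bin <- droplevels(dat$bin)
  dat$classifier <- droplevels(dat$classifier)
  # reference category 0 for the bin factor
  if ("0" %in% levels(dat$bin)) dat$bin <- stats::relevel(dat$bin, "0")

  agg <- stats::aggregate(correct ~ bin + classifier, dat,
                          FUN = function(x) c(k = sum(x), n = length(x)))
  cells <- data.frame(bin = agg$bin, classifier = agg$classifier,
                      successes = agg$correct[, "k"],
                      n = agg$correct[, "n"])
  cells$prob <- cells$successes / cells$n
  cells$separated <- cells$prob %in% c(0, 1)

  ctr <- list(bin = stats::contr.sum, classifier = stats::contr.sum)
  Xm <- stats::model.matrix(~ bin * classifier, cells, contrasts.arg = ctr)
  term_of <- attr(Xm, "assign")

  separation <- any(cells$separated)
  if (!separation) {
    fit <- stats::glm(cbind(successes, n - successes) ~ bin * classifier,
                      data = cells, family = stats::binomial(),
                      contrasts = ctr)
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
  } else {
    rf <- ridge_irls(Xm, cells$successes, cells$n, lambda)
    beta <- stats::setNames(rf$coefficients, colnames(Xm))
    V <- rf$vcov
  }

  term_labels <- c("bin", "classifier", "bin:classifier")
  n_obs <- nrow(dat)
  p_coef <- length(beta)
  tests <- do.call(rbind, lapply(seq_along(term_labels), function(t) {
    ii <- which(term_of == t)
    b <- beta[ii]
    W <- drop(t(b) %*% solve(V[ii, ii, drop = FALSE]) %*% b)
    df1 <- length(ii)
    df2 <- n_obs - p_coef
    data.frame(effect = term_labels[t], wald_chisq = W, df = df1,
               f_value = W / df1, df2 = df2,
               p = stats::pchisq(W, df1, lower.tail = FALSE))
  }))

  # fitted cell logits and their SEs (saturated: equal observed logits
  # unless the ridge is active)
  eta <- drop(Xm %*% beta)
  se_eta <- sqrt(rowSums((Xm %*% V) * Xm))
  cells$logit <- eta
  cells$se_logit <- se_eta
  cells$fitted <- stats::plogis(eta)

  # estimated marginal means: average cell logits over the other factor
  emm_of <- function(fac) {
    lv <- levels(cells[[fac]])
    L <- t(vapply(lv, function(l) {
      rows <- which(cells[[fac]] == l)
      colMeans(Xm[rows, , drop = FALSE])
    }, numeric(ncol(Xm))))
    est <- drop(L %*% beta)
    se <- sqrt(rowSums((L %*% V) * L))
    data.frame(level = lv, logit = est, se = se,
               accuracy = stats::plogis(est))
  }

  structure(
    list(tests = tests,
         cells = cells,
         emm = list(bin = emm_of("bin"), classifier = emm_of("classifier")),
         coefficients = beta, vcov = V, X = Xm,
         separation = separation, lambda = if (separation) lambda else 0,
         n_obs = n_obs),
    class = "effect_model"
  )
}

#' @export
print.effect_model <- function(x, ...) {
  cat("Fixed-effects binomial logit model: correct ~ bin * classifier\n")
  if (x$separation)
    cat("  note: complete separation in ", sum(x$cells$separated),
        " cell(s); ridge penalty ", x$lambda, " applied\n", sep = "")
  t <- x$tests
  t$wald_chisq <- round(t$wald_chisq, 2)
  t$f_value <- round(t$f_value, 2)
  t$p <- signif(t$p, 3)
  print(t, row.names = FALSE)
  invisible(x)
}

#' All pairwise Wald comparisons of estimated marginal and cell means
#'
#' Contrasts every pair of difficulty-bin marginal means, every pair of
#' classifier marginal means, and — for the interaction — every classifier
#' pair within each bin, on the logit scale with Wald z tests. Pairs
#' significant at \code{alpha} are returned with the higher-accuracy
#' member listed first.
#'
#' @param model a [fit_effect_model()] result.
#' @param alpha significance level (default 0.001, a conservative guard
#'   against type-I error inflation across the many contrasts).
#' @return data.frame of the significant pairs: \code{scope} (\code{bin},
#'   \code{classifier}, or \code{cells:<bin>}), \code{higher},
#'   \code{lower}, \code{diff_logit}, \code{z}, \code{p}. All contrasts
#'   (not only the significant ones) are in attribute \code{"all"}.
#' @export
pairwise_comparisons <- function(model, alpha = 0.001) {
  stopifnot(inherits(model, "effect_model"))
  beta <- model$coefficients; V <- model$vcov
  Xm <- model$X; cells <- model$cells

  row_for <- function(fac, lv) {
    rows <- which(cells[[fac]] == lv)
    colMeans(Xm[rows, , drop = FALSE])
  }
  contrast <- function(L1, L2, scope, name1, name2) {
    d <- L1 - L2
    est <- drop(crossprod(d, beta))
    se <- sqrt(drop(t(d) %*% V %*% d))
    z <- if (se > 0) est / se else 0
    hi <- if (est >= 0) name1 else name2
    lo <- if (est >= 0) name2 else name1
    data.frame(scope = scope, higher = hi, lower = lo,
               diff_logit = abs(est), z = abs(z),
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }

  res <- list()
  for (fac in c("bin", "classifier")) {
    lv <- levels(cells[[fac]])
    for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j)
      res[[length(res) + 1L]] <-
        contrast(row_for(fac, lv[i]), row_for(fac, lv[j]), fac,
                 lv[i], lv[j])
  }
  # per-bin classifier contrasts (interaction cells)
  for (b in levels(cells$bin)) {
    lv <- levels(cells$classifier)
    for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
      r1 <- which(cells$bin == b & cells$classifier == lv[i])
      r2 <- which(cells$bin == b & cells$classifier == lv[j])
      res[[length(res) + 1L]] <-
        contrast(Xm[r1, ], Xm[r2, ], paste0("cells:", b), lv[i], lv[j])
    }
  }
  all <- do.call(rbind, res)
  rownames(all) <- NULL
  sig <- all[all$p < alpha, , drop = FALSE]
  rownames(sig) <- NULL
  attr(sig, "all") <- all
  sig
}

#' Post-hoc feature inspection of a hard bin
#'
#' For the cases one classifier faced inside one difficulty bin, crosses
#' each feature's in/out-of-range coding with classification correctness
#' in a 2x2 table and reports the Pearson chi-square (df = 1, no
#' continuity correction) per feature, ordered by p, with the direction of
#' association (which coding level went with being classified correctly).
#' Features constant within the bin are skipped with a reason. An FDR
#' (Benjamini--Hochberg) column accompanies the unadjusted p values.
#'
#' @param coded the [code_cohort()] result (for the binary matrix).
#' @param records out-of-fold [run_cv_bench()] predictions.
#' @param scores binned [cdi_scores()] table.
#' @param bin_center which bin to inspect (e.g. 0).
#' @param classifier_name which classifier's correctness to cross.
#' @return data.frame: \code{feature}, \code{chisq}, \code{df}, \code{p},
#'   \code{p_fdr}, \code{direction}, \code{note}; skipped features keep
#'   \code{NA} statistics.
#' @export
hard_bin_feature_chisq <- function(coded, records, scores, bin_center = 0,
                                   classifier_name = "NN") {
  stopifnot(inherits(coded, "coded_cohort"))
  rec <- records[records$classifier == classifier_name, ]
  idx <- match(as.character(rec$case_id), as.character(scores$case_id))
  rec$bin <- scores$bin[idx]
  rec <- rec[!is.na(rec$bin) & rec$bin == bin_center, ]
  if (nrow(rec) == 0L)
    stop("no cases for classifier ", classifier_name, " in bin ", bin_center)
  mi <- match(as.character(rec$case_id), coded$case_id)
  B <- coded$binary_matrix[mi, , drop = FALSE]
  correct <- as.integer(rec$predicted == rec$truth)

  rows <- lapply(colnames(B), function(f) {
    x <- B[, f]
    if (length(unique(x)) < 2L || length(unique(correct)) < 2L) {
      return(data.frame(feature = f, chisq = NA_real_, df = NA_integer_,
                        p = NA_real_, direction = NA_character_,
                        note = if (length(unique(x)) < 2L)
                          "feature constant within bin" else
                          "correctness constant within bin",
                        stringsAsFactors = FALSE))
    }
    tab <- table(factor(x, levels = 0:1), factor(correct, levels = 0:1))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    p_correct_out <- tab["1", "1"] / sum(tab["1", ])
    p_correct_in <- tab["0", "1"] / sum(tab["0", ])
    data.frame(feature = f, chisq = unname(ct$statistic),
               df = unname(ct$parameter), p = ct$p.value,
               direction = if (p_correct_out >= p_correct_in)
                 "out-of-range associated with correct" else
                 "in-range associated with correct",
               note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(is.na(out$p), out$p), ]
  rownames(out) <- NULL
  out[c("feature", "chisq", "df", "p", "p_fdr", "direction", "note")]
}
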