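#' Validate a raw cohort table
#'
#' A raw cohort is a plain \code{data.frame} with one row per case, a unique
#' \code{case_id} column, a binary \code{outcome} column (1 = death in
#' hospital, never missing), and any number of raw feature columns
#' (continuous or categorical; missing values allowed). All cohort-coding
#' functions accept and return this shape, so pipelines compose with
#' ordinary data-frame tools.
#'
#' @param df a data.frame containing \code{case_id}, \code{outcome} and
#'   feature columns.
#' @return \code{df}, invisibly classed \code{c("raw_cohort", "data.frame")}.
#' @export
as_raw_cohort <- function(df) {
  stopifnot(is.data.frame(df))
  if (!all(c("case_id", "outcome") %in% names(df)))
    stop("cohort needs `case_id` and `outcome` columns")
  if (anyDuplicated(df$case_id))
    stop("`case_id` must be unique")
  if (anyNA(df$outcome) || !all(df$outcome %in% c(0, 1)))
    stop("`outcome` must be 0/1 and never missing")
  if (!inherits(df, "raw_cohort")) class(df) <- c("raw_cohort", class(df))
  df
}

feature_columns <- function(cohort) {
  setdiff(names(cohort), c("case_id", "outcome"))
}

#' Read / write a cohort CSV
#'
#' One row per case; reserved columns \code{case_id} and \code{outcome};
#' missing values are empty cells or \code{NA} tokens.
#'
#' @param path CSV file path.
#' @return \code{read_cohort()}: a validated raw cohort data.frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  as_raw_cohort(df)
}

#' @rdname read_cohort
#' @param cohort a raw cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Drop cases with too many missing features
#'
#' Keeps only cases for which the fraction of non-missing feature values is
#' at least \code{min_fraction} (default: three quarters of the features of
#' interest must be available). Row order is preserved.
#'
#' @param cohort raw cohort data.frame.
#' @param min_fraction required availability fraction in (0, 1]; the
#'   boundary counts as available enough (18/24 = 0.75 is retained at the
#'   default).
#' @return The filtered cohort.
#' @export
apply_inclusion <- function(cohort, min_fraction = 0.75) {
  cohort <- as_raw_cohort(cohort)
  stopifnot(min_fraction > 0, min_fraction <= 1)
  feats <- feature_columns(cohort)
  if (length(feats) == 0L) stop("cohort has no feature columns")
  avail <- rowMeans(!is.na(cohort[feats]))
  keep <- avail >= min_fraction
  if (!any(keep))
    stop("no case meets the availability threshold of ", min_fraction)
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  as_raw_cohort(out)
}

#' Impute missing feature values by chained equations
#'
#' Single-imputation chained equations: numeric columns with missing entries
#' are initialized at their observed means, then repeatedly re-imputed by
#' stochastic linear regression on all other feature columns (prediction
#' plus a residual draw, which preserves spread rather than shrinking
#' imputed values to the conditional mean). Categorical (non-numeric)
#' columns are imputed by a draw from their observed empirical
#' distribution. Observed entries are never altered, and the result is
#' deterministic given \code{seed}.
#'
#' @param cohort raw cohort data.frame.
#' @param seed integer seed controlling the residual draws.
#' @param n_sweeps number of full passes over the incomplete columns.
#' @return The cohort with no missing feature values.
#' @export
impute_chained <- function(cohort, seed = 1L, n_sweeps = 10L) {
  cohort <- as_raw_cohort(cohort)
  feats <- feature_columns(cohort)
  X <- cohort[feats]
  n_miss <- vapply(X, function(x) sum(is.na(x)), integer(1))
  if (all(n_miss == 0L)) return(cohort)
  all_na <- names(n_miss)[n_miss == nrow(X)]
  if (length(all_na))
    stop("all-missing column(s): ", paste(all_na, collapse = ", "))

  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  numeric_col <- vapply(X, is.numeric, logical(1))
  miss_idx <- lapply(X, function(x) which(is.na(x)))

  # initialization: mean (numeric) or empirical draw (categorical)
  for (j in seq_along(X)) {
    mi <- miss_idx[[j]]
    if (!length(mi)) next
    obs <- X[[j]][-mi]
    X[[j]][mi] <- if (numeric_col[j]) mean(obs)
                  else sample(obs, length(mi), replace = TRUE)
  }

  # numeric design matrix for the regression sweeps (categoricals enter as
  # integer codes; crude but standard for a chained-equations backbone)
  as_design <- function(X) {
    M <- vapply(X, function(x) {
      if (is.numeric(x)) as.numeric(x) else as.numeric(as.factor(x))
    }, numeric(nrow(X)))
    matrix(M, nrow = nrow(X))
  }

  incomplete <- which(vapply(miss_idx, length, integer(1)) > 0L)
  for (sweep in seq_len(n_sweeps)) {
    for (j in incomplete) {
      mi <- miss_idx[[j]]
      if (!numeric_col[j]) {
        # categorical: redraw from the observed distribution each sweep
        X[[j]][mi] <- sample(X[[j]][-mi], length(mi), replace = TRUE)
        next
      }
      D <- as_design(X[-j])
      # drop constant predictors to keep the regression well posed
      keep <- apply(D, 2L, function(c) stats::sd(c) > 0)
      y <- X[[j]]
      if (!any(keep)) {
        obs_sd <- stats::sd(y[-mi])
        X[[j]][mi] <- mean(y[-mi]) + stats::rnorm(length(mi), 0, obs_sd)
        next
      }
      D <- D[, keep, drop = FALSE]
      fit <- stats::lm.fit(cbind(1, D[-mi, , drop = FALSE]), y[-mi])
      sigma <- sqrt(sum(fit$residuals^2) /
                      max(1L, length(fit$residuals) - fit$rank))
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      pred <- drop(cbind(1, D[mi, , drop = FALSE]) %*% beta)
      X[[j]][mi] <- pred + stats::rnorm(length(mi), 0, sigma)
    }
  }
  cohort[feats] <- X
  as_raw_cohort(cohort)
}

#' Draw a balanced or imbalanced analysis sample
#'
#' Both designs keep every death case (\code{outcome == 1}) exactly once and
#' undersample the survivors without replacement: the balanced design draws
#' as many no-death cases as there are deaths (1:1, total \eqn{2d}); the
#' imbalanced design draws twice as many (1:2, total \eqn{3d}). Deterministic
#' given \code{seed}.
#'
#' @param cohort raw cohort data.frame.
#' @param design \code{"balanced"} or \code{"imbalanced"}.
#' @param seed integer seed for the survivor draw.
#' @return The sampled cohort (deaths first, then sampled survivors).
#' @export
design_sample <- function(cohort, design = c("balanced", "imbalanced"),
                          seed = 1L) {
  cohort <- as_raw_cohort(cohort)
  design <- match.arg(design)
  mult <- if (design == "balanced") 1L else 2L
  deaths <- which(cohort$outcome == 1)
  survivors <- which(cohort$outcome == 0)
  d <- length(deaths)
  if (d == 0L) stop("cohort has no death cases")
  need <- mult * d
  if (length(survivors) < need)
    stop("need ", need, " no-death cases for the ", design,
         " design, have ", length(survivors))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  picked <- sort(sample(survivors, need))
  out <- cohort[c(deaths, picked), , drop = FALSE]
  rownames(out) <- NULL
  as_raw_cohort(out)
}

#' Dichotomize raw features into the binary response matrix
#'
#' Each feature is mapped through its [feature_spec()] to the 0/1
#' disease-promoting indicator: out of the normal range, above the
#' threshold, or a member of the positive codes codes 1; anything else
#' (including exact range endpoints) codes 0.
#'
#' @param cohort raw cohort data.frame (impute first if it has missing
#'   values; missing raw values propagate to NA indicators).
#' @param specs a [feature_spec_list()] covering every feature column.
#' @return Integer matrix, cases x items, rownames \code{case_id}.
#' @export
dichotomize <- function(cohort, specs) {
  cohort <- as_raw_cohort(cohort)
  stopifnot(inherits(specs, "feature_spec_list"))
  feats <- feature_columns(cohort)
  missing_spec <- setdiff(feats, names(specs))
  if (length(missing_spec))
    stop("no feature spec for: ", paste(missing_spec, collapse = ", "))
  M <- vapply(feats, function(f) apply_spec(specs[[f]], cohort[[f]]),
              integer(nrow(cohort)))
  M <- matrix(M, nrow = nrow(cohort),
              dimnames = list(cohort$case_id, feats))
  M
}

#' Code a cohort end to end
#'
#' Convenience wrapper running the cohort-coding stage in its canonical
#' order: inclusion filter, chained-equation imputation, then
#' dichotomization. Returns both consumer views of the same imputed values
#' — the 0/1 response matrix for the difficulty model and the
#' original-valued (imputed) feature matrix for the classifiers — in
#' identical row order.
#'
#' @param cohort raw cohort data.frame.
#' @param specs a [feature_spec_list()].
#' @param min_fraction availability threshold for [apply_inclusion()].
#' @param seed imputation seed.
#' @param n_sweeps imputation sweeps.
#' @return A list of class \code{"coded_cohort"}: \code{case_id},
#'   \code{binary_matrix}, \code{classifier_matrix} (numeric matrix),
#'   \code{outcome}.
#' @export
code_cohort <- function(cohort, specs, min_fraction = 0.75, seed = 1L,
                        n_sweeps = 10L) {
  cohort <- apply_inclusion(cohort, min_fraction)
  cohort <- impute_chained(cohort, seed = seed, n_sweeps = n_sweeps)
  feats <- feature_columns(cohort)
  bin <- dichotomize(cohort, specs)
  num <- vapply(cohort[feats], function(x) {
    if (is.numeric(x)) as.numeric(x) else as.numeric(as.factor(x))
  }, numeric(nrow(cohort)))
  num <- matrix(num, nrow = nrow(cohort),
                dimnames = list(cohort$case_id, feats))
  structure(
    list(case_id = as.character(cohort$case_id), binary_matrix = bin,
         classifier_matrix = num, outcome = as.integer(cohort$outcome)),
    class = "coded_cohort"
  )
}

#' @export
print.coded_cohort <- function(x, ...) {
  cat("<coded_cohort> ", length(x$case_id), " cases x ",
      ncol(x$binary_matrix), " features; deaths: ", sum(x$outcome), "\n",
      sep = "")
  invisible(x)
}

#' Export a coded cohort as two CSVs
#'
#' Writes the binary response matrix and the imputed classifier matrix with
#' a shared \code{case_id} order (plus the outcome column in each).
#'
#' @param coded a \code{coded_cohort}.
#' @param binary_path,classifier_path output CSV paths.
#' @export
write_coded_cohort <- function(coded, binary_path, classifier_path) {
  stopifnot(inherits(coded, "coded_cohort"))
  bdf <- data.frame(case_id = coded$case_id, coded$binary_matrix,
                    outcome = coded$outcome, check.names = FALSE)
  cdf <- data.frame(case_id = coded$case_id, coded$classifier_matrix,
                    outcome = coded$outcome, check.names = FALSE)
  utils::write.csv(bdf, binary_path, row.names = FALSE)
  utils::write.csv(cdf, classifier_path, row.names = FALSE)
  invisible(c(binary_path, classifier_path))
}

# --- seed plumbing -----------------------------------------------------------
# Stage seeds are isolated: each stochastic stage installs its own RNG state
# and restores the caller's afterwards, so changing one stage's seed cannot
# perturb another's draws.

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
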