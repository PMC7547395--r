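#' Default synthetic item set for an ICU-style cohort
#'
#' Twenty-four items mirroring a severity-score feature panel: slopes drawn
#' once (fixed here, not re-randomized per call) log-normally around 1,
#' locations spread over the latent range, and one deliberately
#' near-zero-slope item emulating a non-discriminatory feature such as
#' urine output (slope 0.15). Each item carries a synthetic "normal range"
#' on a raw measurement scale so that dichotomization is exactly
#' invertible.
#'
#' @return data.frame: \code{item}, \code{a}, \code{b}, \code{low},
#'   \code{high} (raw-scale normal range), \code{units}.
#' @export
default_item_bank <- function() {
  # fixed panel: reproducible without touching the RNG
  a <- c(1.62, 0.74, 1.11, 0.93, 2.10, 0.55, 1.35, 0.87, 1.02, 0.68,
         1.48, 0.79, 1.22, 0.61, 1.83, 0.95, 1.07, 0.71, 1.29, 0.84,
         2.45, 0.52, 1.16, 0.15)
  b <- c(-1.6, -1.2, -0.9, -0.6, -0.4, -0.2, 0.0, 0.1, 0.3, 0.5,
         0.7, 0.9, 1.1, 1.4, -1.4, -1.0, -0.7, -0.3, 0.2, 0.6,
         0.05, 1.2, -0.5, -2.23)
  data.frame(
    item = sprintf("feat%02d", seq_along(a)),
    a = a, b = b,
    low = 10 * seq_along(a), high = 10 * seq_along(a) + 5,
    units = "synthetic", stringsAsFactors = FALSE
  )
}

#' Configure the synthetic-cohort generator
#'
#' The generator emulates the statistical structure the difficulty model
#' assumes: a latent standard-normal "unhealthiness" trait drives
#' out-of-range binary indicators through 2PL item curves, raw continuous
#' values are emitted consistently with those indicators (truncated
#' normals inside the normal range when in range; a two-sided truncated
#' mixture outside it when out of range, so dichotomization recovers the
#' indicators exactly), and mortality follows a logistic link on the
#' trait.
#'
#' @param n_cases cohort size.
#' @param items item bank as from [default_item_bank()] (columns
#'   \code{item}, \code{a}, \code{b}, \code{low}, \code{high}).
#' @param link_slope slope \code{c} of the outcome link
#'   \eqn{P(death) = logis(c\theta + c_0)}.
#' @param link_intercept intercept \eqn{c_0} (0 gives a ~50\% death rate).
#' @param missing_rate completely-at-random missingness applied to the raw
#'   feature values, in [0, 1).
#' @param low_mix_weight probability an out-of-range value falls below the
#'   range rather than above it. The default 0.2 emulates the typical
#'   clinical-lab pattern where derangement is predominantly one-sided
#'   (e.g. urea or white-cell count elevated in the critically ill), which
#'   gives raw values the monotone relation to unhealthiness that real
#'   cohorts show; 0.5 would make raw values uninformative for linear
#'   classifiers while leaving the binary indicators unchanged.
#' @return List of class \code{"generator_config"}.
#' @export
generator_config <- function(n_cases = 8000L, items = default_item_bank(),
                             link_slope = 1.0, link_intercept = 0,
                             missing_rate = 0, low_mix_weight = 0.2) {
  stopifnot(n_cases > 0, missing_rate >= 0, missing_rate < 1,
            all(c("item", "a", "b", "low", "high") %in% names(items)),
            all(items$low <= items$high),
            low_mix_weight >= 0, low_mix_weight <= 1)
  structure(list(n_cases = as.integer(n_cases), items = items,
                 link_slope = link_slope, link_intercept = link_intercept,
                 missing_rate = missing_rate,
                 low_mix_weight = low_mix_weight),
            class = "generator_config")
}

# truncated-normal draw on (lo, hi) by inverse CDF
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  # clamp away from 0/1 so qnorm stays finite
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic cohort with known ground truth
#'
#' @param config a [generator_config()].
#' @param seed integer seed; the draw is fully deterministic given it.
#' @return List of class \code{"synthetic_cohort"}:
#'   \code{cohort} (a raw cohort data.frame ready for [code_cohort()]),
#'   \code{specs} (the matching [feature_spec_list()]),
#'   \code{truth} (list: \code{theta} per case, \code{items} with the true
#'   a/b, \code{u} the latent indicator matrix, and the link parameters).
#'   The truth is for validation only; the pipeline never sees it.
#' @export
generate_cohort <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  it <- config$items
  n <- config$n_cases
  m <- nrow(it)
  theta <- stats::rnorm(n)
  U <- sim_responses(it$a, it$b, theta, item_names = it$item)

  # raw-value emission: in-range draws live inside [low, high]; out-of-range
  # draws come from a two-sided truncated mixture strictly outside it
  X <- matrix(NA_real_, n, m, dimnames = list(NULL, it$item))
  for (j in seq_len(m)) {
    lo <- it$low[j]; hi <- it$high[j]
    mid <- (lo + hi) / 2; span <- max(hi - lo, 1e-6)
    inr <- U[, j] == 0
    X[inr, j] <- rtruncnorm1(sum(inr), mid, span / 4, lo, hi)
    n_out <- sum(!inr)
    if (n_out) {
      below <- stats::runif(n_out) < config$low_mix_weight
      v <- numeric(n_out)
      v[below] <- rtruncnorm1(sum(below), lo - span / 2, span / 4,
                              -Inf, lo - 1e-9)
      v[!below] <- rtruncnorm1(sum(!below), hi + span / 2, span / 4,
                               hi + 1e-9, Inf)
      X[!inr, j] <- v
    }
  }

  outcome <- as.integer(
    stats::runif(n) < stats::plogis(config$link_slope * theta +
                                      config$link_intercept))

  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    X[drop] <- NA_real_
  }

  cohort <- data.frame(case_id = sprintf("case%06d", seq_len(n)),
                       X, outcome = outcome, check.names = FALSE,
                       stringsAsFactors = FALSE)
  specs <- feature_spec_list(lapply(seq_len(m), function(j)
    feature_spec(it$item[j], "range", low = it$low[j], high = it$high[j],
                 units = it$units[j])))

  structure(list(
    cohort = as_raw_cohort(cohort), specs = specs,
    truth = list(theta = theta, items = it, u = U,
                 link_slope = config$link_slope,
                 link_intercept = config$link_intercept, seed = seed)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$cohort), " cases x ",
      nrow(x$truth$items), " features; deaths: ", sum(x$cohort$outcome),
      "\n", sep = "")
  invisible(x)
}

#' Calibrate the outcome link to a target point-biserial correlation
#'
#' Root-finds the link slope \code{c} so that the expected point-biserial
#' correlation between the estimated difficulty score and the 0/1 outcome
#' matches \code{target_r}. Uses common random numbers: one Monte-Carlo
#' pool of latent traits, responses and EAP scores (computed from the true
#' item parameters) is drawn once, outcomes are re-thresholded from a
#' fixed uniform draw for each candidate slope, so the correlation is a
#' smooth monotone function of the slope and the root is sharp.
#'
#' @param items item bank (columns \code{a}, \code{b}).
#' @param target_r target correlation (e.g. 0.37).
#' @param intercept link intercept held fixed during calibration.
#' @param n_mc Monte-Carlo pool size.
#' @param seed integer seed for the pool.
#' @param interval search interval for the slope.
#' @return The calibrated slope (numeric scalar) with the achieved
#'   correlation in attribute \code{"achieved_r"}.
#' @export
calibrate_link_slope <- function(items = default_item_bank(),
                                 target_r = 0.37, intercept = 0,
                                 n_mc = 20000L, seed = 1L,
                                 interval = c(0.05, 8)) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  theta <- stats::rnorm(n_mc)
  U <- sim_responses(items$a, items$b, theta)
  sc <- score_eap(U, items$a, items$b, quadrature_grid())
  uu <- stats::runif(n_mc)
  r_of <- function(cc) {
    y <- as.integer(uu < stats::plogis(cc * theta + intercept))
    if (stats::sd(y) == 0) return(0)
    stats::cor(sc$theta, y)
  }
  f <- function(cc) r_of(cc) - target_r
  root <- stats::uniroot(f, interval = interval, tol = 1e-4)$root
  structure(root, achieved_r = r_of(root))
}

#' Draw a balanced/imbalanced design pair from one generated pool
#'
#' Generates one cohort pool and applies [design_sample()] twice — 1:1 and
#' 1:2 death:no-death — so the death cases are identical across the pair,
#' matching how paired analysis samples are drawn from one source
#' population.
#'
#' @param config a [generator_config()]; \code{n_cases} is the pool size
#'   and must leave enough survivors for the 1:2 draw.
#' @param seed integer seed (generation and both draws derive from it).
#' @return List with \code{balanced} and \code{imbalanced} raw cohorts,
#'   plus \code{pool} (the full generated object with its ground truth).
#' @export
make_design_pair <- function(config = generator_config(), seed = 1L) {
  gen <- generate_cohort(config, seed = seed)
  list(
    balanced = design_sample(gen$cohort, "balanced", seed = seed + 1L),
    imbalanced = design_sample(gen$cohort, "imbalanced", seed = seed + 2L),
    pool = gen
  )
}

#' Write the synthetic bundle to disk
#'
#' Cohort CSV, feature-spec YAML and a ground-truth sidecar JSON (the
#' sidecar is for validation only and is never fed to the pipeline).
#'
#' @param gen a [generate_cohort()] result.
#' @param cohort_path,specs_path,truth_path output paths.
#' @export
write_synthetic_cohort <- function(gen, cohort_path, specs_path,
                                   truth_path) {
  stopifnot(inherits(gen, "synthetic_cohort"))
  write_cohort(gen$cohort, cohort_path)
  write_feature_specs(gen$specs, specs_path)
  tr <- gen$truth
  jsonlite::write_json(
    list(theta = tr$theta, items = tr$items,
         link_slope = tr$link_slope, link_intercept = tr$link_intercept,
         seed = tr$seed),
    truth_path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(c(cohort_path, specs_path, truth_path))
}
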