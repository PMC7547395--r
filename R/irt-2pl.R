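#' Item characteristic curve of the two-parameter logistic model
#'
#' Probability that a case at latent position \code{theta} shows the
#' disease-promoting level of an item with discrimination \code{a} and
#' location \code{b}:
#' \deqn{P(u = 1 \mid \theta) = \frac{1}{1 + e^{-a(\theta - b)}}.}
#' The curve passes through 0.5 at \code{theta = b} and is strictly
#' increasing in \code{theta} when \code{a > 0}. Vectorized over all three
#' arguments with the usual recycling.
#'
#' @param a discrimination (slope), unitless.
#' @param b location on the latent scale (curve inflection point).
#' @param theta latent trait value(s).
#' @return Probabilities in (0, 1).
#' @examples
#' icc_2pl(1, 0, 0)            # 0.5 at the inflection
#' icc_2pl(2, 1, 0)            # 1 / (1 + e^2)
#' @export
icc_2pl <- function(a, b, theta) {
  stopifnot(all(is.finite(a)), all(is.finite(b)), all(is.finite(theta)))
  stats::plogis(a * (theta - b))
}

#' Likelihood of a response pattern
#'
#' The probability of observing the 0/1 pattern \code{u} at latent value
#' \code{theta}, i.e. the product over items of
#' \eqn{P_i^{u_i} (1 - P_i)^{1 - u_i}} with \eqn{P_i} the item
#' characteristic curve. Summed over all \eqn{2^n} patterns this is 1 at
#' every \code{theta}.
#'
#' @param u 0/1 response vector, one entry per item.
#' @param a,b item parameter vectors, same length as \code{u}.
#' @param theta a single latent value.
#' @return A probability in (0, 1].
#' @export
pattern_likelihood <- function(u, a, b, theta) {
  if (length(u) != length(a) || length(a) != length(b))
    stop("u, a, b must have equal length")
  stopifnot(all(u %in% c(0, 1)), length(theta) == 1L)
  p <- icc_2pl(a, b, theta)
  prod(ifelse(u == 1, p, 1 - p))
}

#' Gauss-type quadrature grid for the latent standard-normal population
#'
#' Equally spaced nodes with standard-normal weights renormalized to sum to
#' one. This grid carries the model's population assumption: cases are
#' placed on a latent N(0, 1) "unhealthiness" continuum, and both the
#' marginal likelihood and the posterior case scores integrate over it.
#'
#' @param n number of nodes (default 61).
#' @param range node range on the latent scale (default \code{c(-6, 6)}).
#' @return List of class \code{"quadrature_grid"} with \code{nodes} and
#'   \code{weights}.
#' @export
quadrature_grid <- function(n = 61L, range = c(-6, 6)) {
  stopifnot(n >= 3L, length(range) == 2L, range[1] < range[2])
  nodes <- seq(range[1], range[2], length.out = n)
  w <- stats::dnorm(nodes)
  structure(list(nodes = nodes, weights = w / sum(w)),
            class = "quadrature_grid")
}

# cases x nodes log-likelihood matrix; NA responses contribute nothing.
loglik_matrix <- function(U, a, b, nodes) {
  if (length(a) == 0L)                # no items: flat likelihood (prior only)
    return(matrix(0, nrow(U), length(nodes)))
  eta <- outer(a, nodes) - a * b      # items x nodes: a_i * (node_k - b_i)
  logP <- stats::plogis(eta, log.p = TRUE)
  logQ <- stats::plogis(-eta, log.p = TRUE)
  obs <- !is.na(U)
  U0 <- ifelse(obs, U, 0)
  # sum_i [ u log P + (1-u) log Q ] restricted to observed entries
  U0 %*% logP + (obs - U0) %*% logQ
}

rowlogsumexp <- function(M) {
  m <- apply(M, 1L, max)
  m + log(rowSums(exp(M - m)))
}

#' Fit the 2PL difficulty model by marginal maximum likelihood
#'
#' Fits the two-parameter logistic model to a cases x items 0/1 response
#' matrix with the Bock--Aitkin EM algorithm: the E-step places each case's
#' posterior mass on a fixed quadrature grid under the standard-normal
#' population prior, and the M-step refits each item's logistic curve to
#' the expected node-level response counts by Newton iterations with
#' step-halving. The latent scale is identified by the fixed N(0, 1) prior;
#' no constraint is placed on item slopes, so reverse-indicating features
#' (negative slopes) are allowed. Slopes are bounded at \eqn{|a| \le 10}
#' and locations at \eqn{|b| \le 6} to keep quasi-Guttman items finite.
#'
#' Items with fitted \eqn{|a| < 0.35} are flagged as non-discriminatory.
#' Standard errors come from the per-item observed information at the
#' solution (delta method for \code{b}).
#'
#' @param M integer cases x items matrix with entries 0/1 (column names are
#'   the item names). Every column must contain both responses.
#' @param grid a [quadrature_grid()].
#' @param tol EM convergence tolerance: maximum absolute change of any item
#'   parameter between iterations.
#' @param max_iter maximum EM iterations; hitting it leaves a non-converged
#'   flag on the fit (reported by \code{print()}/\code{summary()}) rather
#'   than failing.
#' @param min_cases minimum cohort size for a stable fit.
#' @return An object of class \code{"cdi_irt"} with components
#'   \code{items} (data.frame: item, a, b, se_a, se_b, flagged),
#'   \code{scores} (data.frame: case_id, cdi, se — expected-a-posteriori
#'   case scores), \code{loglik} (marginal log-likelihood trace),
#'   \code{converged}, \code{n_iter}, \code{grid}, \code{responses}.
#' @seealso [predict.cdi_irt()] to score new response patterns,
#'   [assign_bins()] for difficulty strata, [simulate.cdi_irt()].
#' @export
cdi_irt <- function(M, grid = quadrature_grid(), tol = 1e-4,
                    max_iter = 500L, min_cases = 100L) {
  M <- as.matrix(M)
  storage.mode(M) <- "double"
  if (is.null(colnames(M)))
    colnames(M) <- paste0("item", seq_len(ncol(M)))
  if (!all(M[!is.na(M)] %in% c(0, 1)))
    stop("response matrix must be 0/1")
  if (nrow(M) < min_cases)
    stop("need at least ", min_cases, " cases, have ", nrow(M))
  csum <- colSums(M, na.rm = TRUE)
  cobs <- colSums(!is.na(M))
  const <- csum == 0 | csum == cobs
  if (any(const))
    stop("constant item column(s): ",
         paste(colnames(M)[const], collapse = ", "),
         " — every item needs both responses")
  stopifnot(inherits(grid, "quadrature_grid"))

  nodes <- grid$nodes
  logw <- log(grid$weights)
  n_items <- ncol(M)

  # start values: a = 1, b from the probit approximation to the marginal
  # proportion out-of-range (logistic scale factor 1.702)
  p0 <- csum / cobs
  a <- rep(1, n_items)
  b <- pmax(-4, pmin(4, -stats::qnorm(p0) * sqrt(1 + 1.702^2)))

  ll_trace <- numeric(0)
  converged <- FALSE
  X <- cbind(1, nodes)
  for (iter in seq_len(max_iter)) {
    LL <- loglik_matrix(M, a, b, nodes)
    LW <- sweep(LL, 2L, logw, `+`)
    lse <- rowlogsumexp(LW)
    ll_trace <- c(ll_trace, sum(lse))
    post <- exp(LW - lse)                      # cases x nodes
    nk <- colSums(post)                        # expected cases per node
    obs <- !is.na(M)
    U0 <- ifelse(obs, M, 0)
    rik <- crossprod(post, U0)                 # nodes x items expected 1s
    nik <- crossprod(post, obs * 1)            # nodes x items exposure

    a_new <- a; b_new <- b
    for (j in seq_len(n_items)) {
      cf <- mstep_logistic(X, rik[, j], nik[, j],
                           c(-a[j] * b[j], a[j]))
      aj <- cf[2L]; bj <- -cf[1L] / cf[2L]
      # bound the parameters; quasi-Guttman items would otherwise diverge
      if (!is.finite(bj)) bj <- 0
      aj <- max(-10, min(10, aj))
      bj <- max(-6, min(6, bj))
      a_new[j] <- aj; b_new[j] <- bj
    }
    delta <- max(abs(c(a_new - a, b_new - b)))
    a <- a_new; b <- b_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter,
            " iterations (max parameter change ",
            format(delta, digits = 3), ")")

  # standard errors from the expected information at the solution
  se_a <- se_b <- rep(NA_real_, n_items)
  LL <- loglik_matrix(M, a, b, nodes)
  LW <- sweep(LL, 2L, logw, `+`)
  lse <- rowlogsumexp(LW)
  post <- exp(LW - lse)
  obs <- !is.na(M)
  nik <- crossprod(post, obs * 1)
  for (j in seq_len(n_items)) {
    p <- stats::plogis(drop(X %*% c(-a[j] * b[j], a[j])))
    wts <- nik[, j] * p * (1 - p)
    I <- crossprod(X * wts, X)
    V <- tryCatch(solve(I), error = function(e) matrix(NA_real_, 2, 2))
    se_a[j] <- sqrt(V[2, 2])
    g <- c(-1 / a[j], (-a[j] * b[j]) / a[j]^2)   # d b / d (c0, c1)
    se_b[j] <- sqrt(drop(t(g) %*% V %*% g))
  }

  theta <- drop(post %*% nodes)
  se_theta <- sqrt(pmax(0, drop(post %*% nodes^2) - theta^2))
  ids <- rownames(M)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(M)))

  structure(
    list(
      items = data.frame(item = colnames(M), a = a, b = b,
                         se_a = se_a, se_b = se_b,
                         flagged = abs(a) < 0.35, row.names = NULL),
      scores = data.frame(case_id = ids, cdi = theta, se = se_theta,
                          row.names = NULL),
      loglik = ll_trace, converged = converged, n_iter = length(ll_trace),
      grid = grid, responses = M, call = match.call()
    ),
    class = "cdi_irt"
  )
}

# M-step inner solver: weighted Bernoulli logistic regression of expected
# successes r (exposure n) on the node design X, Newton with step-halving.
mstep_logistic <- function(X, r, n, start, max_newton = 50L, tol = 1e-10) {
  cf <- start
  obj <- function(cf) {
    eta <- drop(X %*% cf)
    sum(r * eta - n * log1p(exp(eta)))
  }
  f0 <- obj(cf)
  for (it in seq_len(max_newton)) {
    eta <- drop(X %*% cf)
    p <- stats::plogis(eta)
    gr <- drop(crossprod(X, r - n * p))
    W <- n * p * (1 - p)
    H <- crossprod(X * W, X)
    step <- tryCatch(solve(H, gr), error = function(e) gr * 0)
    if (all(step == 0)) break
    lambda <- 1
    repeat {
      cf_try <- cf + lambda * step
      f1 <- obj(cf_try)
      if (is.finite(f1) && f1 >= f0 - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-8) { cf_try <- cf; f1 <- f0; break }
    }
    moved <- max(abs(cf_try - cf))
    cf <- cf_try; f0 <- f1
    if (moved < tol) break
  }
  cf
}

#' @export
print.cdi_irt <- function(x, ...) {
  cat("Two-parameter logistic difficulty model (marginal ML)\n")
  cat(sprintf("  %d cases x %d items; log-likelihood %.2f (%d EM iterations%s)\n",
              nrow(x$responses), nrow(x$items),
              x$loglik[length(x$loglik)], x$n_iter,
              if (x$converged) "" else ", NOT converged"))
  nf <- sum(x$items$flagged)
  if (nf) cat(sprintf("  %d item(s) flagged non-discriminatory (|a| < 0.35)\n",
                      nf))
  invisible(x)
}

#' @export
summary.cdi_irt <- function(object, ...) {
  out <- list(items = object$items,
              loglik = object$loglik[length(object$loglik)],
              n_iter = object$n_iter, converged = object$converged,
              n_cases = nrow(object$responses),
              cdi = summary(object$scores$cdi),
              cdi_sd = stats::sd(object$scores$cdi))
  class(out) <- "summary.cdi_irt"
  out
}

#' @export
print.summary.cdi_irt <- function(x, ...) {
  cat("Two-parameter logistic difficulty model\n")
  cat(sprintf("  %d cases; marginal log-likelihood %.2f; %s in %d iterations\n",
              x$n_cases, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat("\nItem parameters:\n")
  it <- x$items
  it$a <- round(it$a, 3); it$b <- round(it$b, 3)
  it$se_a <- round(it$se_a, 3); it$se_b <- round(it$se_b, 3)
  print(it, row.names = FALSE)
  cat(sprintf("\nCase difficulty scores: mean %.3f, SD %.3f\n",
              mean(x$cdi), x$cdi_sd))
  invisible(x)
}

#' @export
coef.cdi_irt <- function(object, ...) {
  m <- as.matrix(object$items[c("a", "b")])
  rownames(m) <- object$items$item
  m
}

#' @export
logLik.cdi_irt <- function(object, ...) {
  structure(object$loglik[length(object$loglik)],
            df = 2L * nrow(object$items), class = "logLik")
}

#' Expected-a-posteriori case scores for response patterns
#'
#' Scores 0/1 response patterns on the latent difficulty scale as the
#' posterior mean of \eqn{\theta} under the standard-normal population
#' prior (EAP), with the posterior standard deviation as the per-case
#' standard error. Missing responses simply drop out of the likelihood.
#'
#' @param object a fitted [cdi_irt()] model.
#' @param newdata optional cases x items 0/1 matrix (columns matching the
#'   fitted items); defaults to the training responses.
#' @param ... unused.
#' @return data.frame with \code{case_id}, \code{cdi}, \code{se}.
#' @export
predict.cdi_irt <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  U <- as.matrix(newdata)
  if (!is.null(colnames(U)) && !identical(colnames(U), object$items$item)) {
    if (!all(object$items$item %in% colnames(U)))
      stop("newdata is missing fitted items")
    U <- U[, object$items$item, drop = FALSE]
  }
  if (ncol(U) != nrow(object$items))
    stop("newdata has ", ncol(U), " items; model has ", nrow(object$items))
  sc <- score_eap(U, object$items$a, object$items$b, object$grid)
  ids <- rownames(U)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(U)))
  data.frame(case_id = ids, cdi = sc$theta, se = sc$se, row.names = NULL)
}

#' @rdname predict.cdi_irt
#' @param U cases x items 0/1 matrix (a single pattern may be given as a
#'   vector).
#' @param a,b item parameter vectors.
#' @param grid a [quadrature_grid()].
#' @return \code{score_eap()}: data.frame with \code{theta} and \code{se}.
#' @export
score_eap <- function(U, a, b, grid = quadrature_grid()) {
  if (is.null(dim(U))) U <- matrix(U, nrow = 1L)
  U <- as.matrix(U); storage.mode(U) <- "double"
  if (ncol(U) != length(a) || length(a) != length(b))
    stop("pattern length must match the number of items")
  LL <- loglik_matrix(U, a, b, grid$nodes)
  LW <- sweep(LL, 2L, log(grid$weights), `+`)
  post <- exp(LW - rowlogsumexp(LW))
  theta <- drop(post %*% grid$nodes)
  se <- sqrt(pmax(0, drop(post %*% grid$nodes^2) - theta^2))
  data.frame(theta = theta, se = se)
}

#' @export
residuals.cdi_irt <- function(object, ...) {
  # raw response residuals u - P(theta_hat) at the EAP estimates
  eta <- sweep(outer(object$scores$cdi, object$items$b, `-`), 2L,
               object$items$a, `*`)
  object$responses - stats::plogis(eta)
}

#' Plot fitted item characteristic curves
#'
#' @param x a fitted [cdi_irt()] model.
#' @param items indices or names of items to draw (default all).
#' @param theta_range latent range for the curves.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cdi_irt <- function(x, items = NULL, theta_range = c(-4, 4), ...) {
  it <- x$items
  if (!is.null(items)) {
    idx <- if (is.character(items)) match(items, it$item) else items
    it <- it[idx, , drop = FALSE]
  }
  th <- seq(theta_range[1], theta_range[2], length.out = 201)
  P <- vapply(seq_len(nrow(it)),
              function(j) icc_2pl(it$a[j], it$b[j], th), numeric(length(th)))
  graphics::matplot(th, P, type = "l", lty = 1, ylim = c(0, 1),
                    xlab = expression(theta~("unhealthiness")),
                    ylab = "P(out of range)", ...)
  graphics::abline(h = 0.5, lty = 3, col = "grey60")
  invisible(x)
}

#' Simulate response matrices from a fitted model
#'
#' Draws latent traits from the standard-normal population and responses
#' from the fitted item curves — the parametric-bootstrap companion to
#' [cdi_irt()].
#'
#' @param object a fitted \code{cdi_irt} model.
#' @param nsim number of replicate matrices.
#' @param seed optional integer seed.
#' @param n_cases cases per replicate (default: the fitted cohort size).
#' @param ... unused.
#' @return A list of \code{nsim} response matrices, each with attribute
#'   \code{"theta"} (the latent draws).
#' @export
simulate.cdi_irt <- function(object, nsim = 1, seed = NULL,
                             n_cases = nrow(object$responses), ...) {
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  lapply(seq_len(nsim), function(s) {
    theta <- stats::rnorm(n_cases)
    sim_responses(object$items$a, object$items$b, theta,
                  item_names = object$items$item)
  })
}

# Bernoulli draws from item curves; shared with the synthetic-cohort module.
sim_responses <- function(a, b, theta, item_names = NULL) {
  n <- length(theta); m <- length(a)
  P <- stats::plogis(sweep(outer(theta, b, `-`), 2L, a, `*`))
  U <- matrix(as.integer(stats::runif(n * m) < P), n, m)
  colnames(U) <- if (is.null(item_names)) paste0("item", seq_len(m)) else
    item_names
  attr(U, "theta") <- theta
  U
}

#' Assign difficulty-strata bins
#'
#' Bins are 0.5-wide (by default) half-open intervals
#' \eqn{[c - w/2,\; c + w/2)} of the difficulty scale, centered on multiples
#' of the width with the first bin centered at 0.0 (the hardest cases).
#' A score exactly on an edge belongs to the interval whose lower edge it
#' is, so 0.25 falls in bin 0.5 and -0.25 falls in bin 0.0.
#'
#' @param theta numeric difficulty scores (CDIs).
#' @param width bin width (> 0), default 0.5.
#' @return Numeric vector of bin centers.
#' @export
assign_bins <- function(theta, width = 0.5) {
  stopifnot(width > 0)
  width * floor(theta / width + 0.5)
}

#' Collapse sparse extreme bins inward
#'
#' Strata at the far ends of the difficulty distribution can be too small
#' to compare; each extreme bin with fewer than \code{min_count} members is
#' merged into its inward neighbor (taking the neighbor's label), repeating
#' until every remaining extreme bin is large enough. Interior bins are
#' never merged.
#'
#' @param bins numeric bin-center labels, as from [assign_bins()].
#' @param min_count minimum cases an extreme bin must hold (default 30).
#' @param width spacing between adjacent bin centers.
#' @return Relabeled bin vector.
#' @export
collapse_sparse_bins <- function(bins, min_count = 30L, width = 0.5) {
  if (length(bins) < min_count)
    stop("fewer cases (", length(bins), ") than min_count (", min_count, ")")
  repeat {
    lv <- sort(unique(bins))
    if (length(lv) <= 1L) break
    cnt <- table(factor(bins, levels = lv))
    if (cnt[[1L]] < min_count) {
      bins[bins == lv[1L]] <- lv[2L]
    } else if (cnt[[length(lv)]] < min_count) {
      bins[bins == lv[length(lv)]] <- lv[length(lv) - 1L]
    } else break
  }
  bins
}

#' Score, bin and collapse in one step
#'
#' Builds the per-case score table the evaluation stage consumes: the EAP
#' difficulty score, its standard error, and the (collapsed) difficulty
#' bin.
#'
#' @param fit a fitted [cdi_irt()] model.
#' @param width bin width.
#' @param min_count sparse-bin threshold for [collapse_sparse_bins()];
#'   \code{NULL} skips collapsing.
#' @return data.frame of class \code{"cdi_scores"}: \code{case_id},
#'   \code{cdi}, \code{se}, \code{bin}.
#' @export
cdi_scores <- function(fit, width = 0.5, min_count = 30L) {
  stopifnot(inherits(fit, "cdi_irt"))
  sc <- fit$scores
  sc$bin <- assign_bins(sc$cdi, width)
  if (!is.null(min_count))
    sc$bin <- collapse_sparse_bins(sc$bin, min_count, width)
  class(sc) <- c("cdi_scores", "data.frame")
  sc
}
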