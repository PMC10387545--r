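#' Item parameter set
#'
#' Constructs the parameter container for a set of polytomous (or dichotomous)
#' Rasch items. Each item is described by its ordered-category transition
#' locations ("thresholds", tau) on the logit metric; the item location
#' (difficulty, delta) is the arithmetic mean of its thresholds. A dichotomous
#' item has a single threshold equal to its location.
#'
#' Threshold ordering is deliberately *not* enforced: diagnosing disordered
#' thresholds is part of the analysis (see [threshold_order()]), so the
#' container must be able to hold them.
#'
#' @param thresholds named list of numeric threshold vectors, one per item
#'   (tau_i1..tau_im, logits). Names are the item ids.
#' @param se optional list of per-threshold standard errors (same shapes).
#' @param model_form `"dichotomous"`, `"rating_scale"` or `"partial_credit"`.
#'   Defaults to `"dichotomous"` when every item has one threshold, else
#'   `"partial_credit"`.
#' @return An object of class `rasch_items`: a list with one element per item,
#'   each holding `item_id`, `thresholds`, `location`, `threshold_se`.
#' @examples
#' it <- rasch_items(list(easy = -1, hard = 1.5))
#' it2 <- rasch_items(list(A = c(-1, 0, 1), B = c(-2, -0.5, 1.2)))
#' @export
rasch_items <- function(thresholds, se = NULL, model_form = NULL) {
  if (!is.list(thresholds) || length(thresholds) == 0)
    stop("'thresholds' must be a non-empty named list of numeric vectors")
  ids <- names(thresholds)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("'thresholds' must have unique non-empty names (item ids)")
  if (is.null(model_form)) {
    model_form <- if (all(lengths(thresholds) == 1L)) "dichotomous" else "partial_credit"
  }
  model_form <- match.arg(model_form, c("dichotomous", "rating_scale", "partial_credit"))
  out <- lapply(seq_along(thresholds), function(i) {
    tau <- as.numeric(thresholds[[i]])
    if (length(tau) < 1L || any(!is.finite(tau)))
      stop("item '", ids[i], "': thresholds must be finite and non-empty")
    tse <- if (!is.null(se)) as.numeric(se[[i]]) else rep(NA_real_, length(tau))
    list(item_id = ids[i], thresholds = tau, location = mean(tau),
         threshold_se = tse, model_form = model_form)
  })
  names(out) <- ids
  structure(out, class = "rasch_items", model_form = model_form)
}

#' @export
print.rasch_items <- function(x, ...) {
  cat("Rasch item parameters (", attr(x, "model_form"), "), ",
      length(x), " items\n", sep = "")
  print(as.data.frame(x), digits = 3)
  invisible(x)
}

#' @export
as.data.frame.rasch_items <- function(x, ...) {
  do.call(rbind, lapply(x, function(it) {
    data.frame(item = it$item_id,
               step = seq_along(it$thresholds),
               tau = it$thresholds,
               se = it$threshold_se,
               location = it$location,
               row.names = NULL)
  }))
}

#' @export
coef.rasch_items <- function(object, ...) {
  vapply(object, function(it) it$location, numeric(1))
}

item_maxima <- function(items) vapply(items, function(it) length(it$thresholds), integer(1))

# cumulative threshold sums, eta_k = sum_{j<=k} tau_j, with eta_0 = 0
cum_thresholds <- function(tau) c(0, cumsum(tau))

check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) == 0 || any(!is.finite(theta)))
    stop("person ability 'theta' must be finite numeric")
  invisible(theta)
}

#' Partial credit model category probabilities
#'
#' Probability of each response category 0..m for one item under the
#' polytomous Rasch model, P(X = k) proportional to exp(k*theta - sum_{j<=k}
#' tau_j). The dichotomous model is the special case m = 1, and the rating
#' scale model the special case where all items share one threshold-offset
#' pattern. Computation is done in log space (log-sum-exp normalisation), so
#' extreme abilities or thresholds do not overflow.
#'
#' @param theta numeric vector of person abilities (logits).
#' @param item a single element of a [rasch_items()] object, or a numeric
#'   vector of thresholds.
#' @return A matrix `length(theta)` x `(m + 1)` of category probabilities;
#'   rows sum to one. Column names are the categories `0..m`.
#' @examples
#' category_probability(0, c(-1, 1))
#' @export
category_probability <- function(theta, item) {
  tau <- if (is.list(item)) item$thresholds else as.numeric(item)
  if (length(tau) < 1L || any(!is.finite(tau)))
    stop("item thresholds must be finite and non-empty")
  check_theta(theta)
  exp(pcm_logprob(theta, tau))
}

# log category probabilities, length(theta) x (m+1)
pcm_logprob <- function(theta, tau) {
  m <- length(tau)
  eta <- cum_thresholds(tau)                       # length m+1
  lin <- outer(theta, 0:m) - rep(eta, each = length(theta))
  mx <- lin[cbind(seq_along(theta), max.col(lin, ties.method = "first"))]
  lse <- mx + log(rowSums(exp(lin - mx)))
  out <- lin - lse
  colnames(out) <- as.character(0:m)
  out
}

#' Model-expected item score
#'
#' Expected category value E = sum_k k P(X = k) for each ability in `theta`.
#' Strictly increasing in theta and bounded in (0, m).
#'
#' @inheritParams category_probability
#' @return numeric vector of expectations, one per ability.
#' @export
expected_score <- function(theta, item) {
  p <- category_probability(theta, item)
  drop(p %*% (0:(ncol(p) - 1L)))
}

#' Model variance of the item score
#'
#' W = sum_k k^2 P(k) - E^2, the binomial/multinomial variance of the observed
#' category around its expectation; the weight used by information-weighted
#' (INFIT) fit statistics. Strictly positive for finite theta.
#'
#' @inheritParams category_probability
#' @return numeric vector of variances, one per ability.
#' @export
score_variance <- function(theta, item) {
  p <- category_probability(theta, item)
  k <- 0:(ncol(p) - 1L)
  e <- drop(p %*% k)
  drop(p %*% k^2) - e^2
}

# third central moment of the category score; derivative of W wrt theta.
score_third_moment <- function(theta, tau) {
  p <- exp(pcm_logprob(theta, tau))
  k <- 0:(ncol(p) - 1L)
  e <- drop(p %*% k)
  drop(p %*% k^3) - 3 * e * drop(p %*% k^2) + 2 * e^3
}
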