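# Residual-based homogeneity and monotonicity diagnostics.

#' Standardized response residuals
#'
#' Cellwise model expectation E, variance W and standardized residual
#' z = (x - E)/sqrt(W), evaluated at each person's estimated ability.
#' Persons with extreme raw scores are excluded (their cells carry no
#' residual variance under the model at the boundary).
#'
#' @param object a [rasch_fit()].
#' @param ... unused.
#' @return matrix of standardized residuals (non-extreme persons x items)
#'   with attributes `expected` and `variance` (same shape).
#' @export
residuals.rasch_fit <- function(object, ...) {
  res_matrices(object)
}

res_matrices <- function(fit) {
  keep <- !fit$persons$extreme
  x <- unclass(fit$responses)[keep, , drop = FALSE]
  th <- fit$persons$estimate[keep]
  E <- W <- Z <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  for (i in seq_len(ncol(x))) {
    it <- fit$items[[colnames(x)[i]]]
    E[, i] <- expected_score(th, it)
    W[, i] <- score_variance(th, it)
    Z[, i] <- (x[, i] - E[, i]) / sqrt(W[, i])
  }
  E[is.na(x)] <- NA; W[is.na(x)] <- NA; Z[is.na(x)] <- NA
  # estimation-adjusted residual variance: evaluating residuals at the
  # estimated ability deflates their variance by roughly W/I_n (I_n = test
  # information for person n); mean squares computed against V are centred
  # at 1 under fit.
  info <- rowSums(W, na.rm = TRUE)
  V <- W * (1 - W / info)
  V[is.na(x)] <- NA
  structure(Z, expected = E, variance = W, adj_variance = V, theta = th,
            persons = fit$persons$person_id[keep])
}

#' Class intervals on the ability estimate
#'
#' Splits non-extreme persons into `G` groups of (as nearly as possible)
#' equal size, ordered on the ability estimate. The default
#' `G = min(10, max(2, floor(n / 50)))` gives 3 intervals around n = 188,
#' matching common practice for samples of that size. Intervals that would
#' hold fewer than 2 persons are merged with a neighbour (with a warning).
#'
#' @param fit a [rasch_fit()].
#' @param G number of class intervals, or `NULL` for the default rule.
#' @return integer vector of interval labels (1..G) for non-extreme persons,
#'   with attribute `breaks`.
#' @export
class_intervals <- function(fit, G = NULL) {
  keep <- !fit$persons$extreme
  th <- fit$persons$estimate[keep]
  n <- length(th)
  if (is.null(G)) G <- min(10L, max(2L, n %/% 50L))
  G <- max(2L, as.integer(G))
  # equal-count split on theta-hat; rank ties broken by stable order
  g <- as.integer(cut(rank(th, ties.method = "first"),
                      breaks = seq(0, n, length.out = G + 1), labels = FALSE))
  tab <- tabulate(g, G)
  while (any(tab < 2L) && G > 2L) {
    warning("class interval with <2 persons merged with neighbour")
    small <- which(tab < 2L)[1]
    nb <- if (small == G) small - 1L else small + 1L
    g[g == small] <- nb
    g <- as.integer(factor(g))
    G <- max(g); tab <- tabulate(g, G)
  }
  structure(g, G = max(g))
}

#' Smith's sample-size-corrected INFIT critical interval
#'
#' The 5% Type-I critical interval for the INFIT mean square is
#' `1 +/- 2/sqrt(n)`: the conventional fixed 0.7-1.3 band retains a 5%
#' error rate only around n = 45; at n = 200 the corrected band is
#' 0.86-1.14. Bounds are rounded to 2 decimals for reporting.
#'
#' @param n sample size (>= 1).
#' @param rounded round bounds to 2 decimals (reporting convention).
#' @return numeric vector `c(lower, upper)`.
#' @examples
#' smith_interval(200)  # 0.86 1.14
#' smith_interval(45)   # 0.70 1.30
#' @export
smith_interval <- function(n, rounded = TRUE) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("n must be >= 1")
  half <- 2 / sqrt(n)
  out <- c(lower = 1 - half, upper = 1 + half)
  if (rounded) out <- round(out, 2)
  out
}

# Wilson-Hilferty standardization of a mean-square with k contributing cells
wh_standardize <- function(ms, k) {
  ((ms)^(1 / 3) - (1 - 2 / (9 * k))) / sqrt(2 / (9 * k))
}

#' Item fit statistics
#'
#' For every item: OUTFIT (unweighted mean square of standardized
#' residuals), INFIT (information-weighted mean square, sum(W z^2)/sum(W)),
#' a standardized fit residual (cube-root standardization of the mean
#' square), the class-interval chi-square (observed vs expected interval
#' score sums, df = G - 1) and a one-way ANOVA F of the residuals across
#' class intervals. Expected value of the mean squares under fit is 1.0.
#'
#' Flags: INFIT outside Smith's corrected interval at the analysed sample
#' size; chi-square and F at Bonferroni-adjusted alpha (family = items).
#'
#' @param fit a [rasch_fit()].
#' @param G class interval count (NULL = default rule of [class_intervals()]).
#' @param alpha nominal significance level before Bonferroni adjustment.
#' @param bonferroni divide alpha by the number of items tested.
#' @return data.frame of class `item_fit`: one row per item with columns
#'   `infit_mnsq`, `outfit_mnsq`, `fit_residual`, `chi_square`, `chi_df`,
#'   `chi_p`, `anova_f`, `anova_p`, flags, plus attributes `total_chisq`,
#'   `total_df`, `total_p` (pooled item-trait interaction) and
#'   `smith_bounds`.
#' @export
item_fit <- function(fit, G = NULL, alpha = 0.05, bonferroni = TRUE) {
  z <- res_matrices(fit)
  E <- attr(z, "expected"); V <- attr(z, "adj_variance")
  if (nrow(z) < 3L) stop("too few non-extreme persons for fit statistics")
  ci <- class_intervals(fit, G)
  Gn <- attr(ci, "G")
  x <- unclass(fit$responses)[!fit$persons$extreme, , drop = FALSE]
  I <- ncol(z)
  n_used <- nrow(z)
  thr <- if (bonferroni) alpha / I else alpha
  sb <- smith_interval(n_used, rounded = FALSE)

  rows <- lapply(seq_len(I), function(i) {
    ok <- !is.na(z[, i])
    ri <- x[ok, i] - E[ok, i]; vi <- V[ok, i]; gi <- ci[ok]
    k <- length(ri)
    outfit <- mean(ri^2 / vi)
    infit <- sum(ri^2) / sum(vi)
    fres <- wh_standardize(outfit, k)
    # chi-square across class intervals on score sums
    chi <- 0
    for (g in unique(gi)) {
      sel <- gi == g
      chi <- chi + sum(ri[sel])^2 / sum(vi[sel])
    }
    chi_df <- length(unique(gi)) - 1L
    chi_p <- stats::pchisq(chi, chi_df, lower.tail = FALSE)
    zi <- z[ok, i]
    av <- tryCatch(stats::anova(stats::lm(zi ~ factor(gi))),
                   error = function(e) NULL)
    f <- if (!is.null(av)) av$`F value`[1] else NA_real_
    fp <- if (!is.null(av)) av$`Pr(>F)`[1] else NA_real_
    data.frame(item = colnames(z)[i],
               location = fit$items[[colnames(z)[i]]]$location,
               n = k, infit_mnsq = infit, outfit_mnsq = outfit,
               fit_residual = fres, chi_square = chi, chi_df = chi_df,
               chi_p = chi_p, anova_f = f,
               anova_df1 = chi_df, anova_df2 = k - chi_df - 1L, anova_p = fp,
               infit_flag = infit < sb[1] | infit > sb[2],
               chi_flag = chi_p < thr,
               anova_flag = !is.na(fp) & fp < thr,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("item_fit", "data.frame")
  attr(out, "G") <- Gn
  attr(out, "smith_bounds") <- smith_interval(n_used)
  attr(out, "total_chisq") <- sum(out$chi_square)
  attr(out, "total_df") <- sum(out$chi_df)
  attr(out, "total_p") <- stats::pchisq(sum(out$chi_square), sum(out$chi_df),
                                        lower.tail = FALSE)
  out
}

#' Person fit
#'
#' Per-person standardized fit residual: the cube-root (Wilson-Hilferty)
#' standardization of the person's mean squared standardized residual over
#' their observed items. Values outside +/-2.5 are flagged as misfitting.
#' Persons with a single observed item are left unflagged (no information).
#'
#' @param fit a [rasch_fit()].
#' @param bound flag bound (default 2.5).
#' @return data.frame: `person_id`, `n_items`, `mean_square`,
#'   `fit_residual`, `flag`. Extreme persons are excluded.
#' @export
person_fit <- function(fit, bound = 2.5) {
  z <- res_matrices(fit)
  E <- attr(z, "expected"); V <- attr(z, "adj_variance")
  x <- unclass(fit$responses)[!fit$persons$extreme, , drop = FALSE]
  k <- rowSums(!is.na(z))
  ms <- rowMeans((x - E)^2 / V, na.rm = TRUE)
  fres <- wh_standardize(ms, k)
  out <- data.frame(person_id = attr(z, "persons"), n_items = k,
                    mean_square = ms, fit_residual = fres,
                    flag = k > 1L & abs(fres) > bound,
                    row.names = NULL)
  out
}

#' Threshold ordering diagnosis
#'
#' A polytomous item's thresholds are disordered when some transition
#' location is below an earlier one, i.e. the category order is not an
#' order on the latent trait. Testletized (summed) items are exempt from
#' interpretation: a given super-item score arises from many member-response
#' combinations, so disordering there only reflects the absorbed dependency.
#'
#' @param items a [rasch_items()] or [rasch_fit()].
#' @param testletized character vector of item ids that are testlets/super
#'   items (their status is reported as `"not interpretable"`).
#' @return data.frame: `item`, `status` (`ordered`/`disordered`/
#'   `not interpretable`), `offending` (comma-list of transitions k with
#'   tau_k+1 < tau_k).
#' @export
threshold_order <- function(items, testletized = character(0)) {
  if (inherits(items, "rasch_fit")) {
    if (attr(items$responses, "provenance") == "testletized" &&
        length(testletized) == 0)
      testletized <- names(items$items)
    items <- items$items
  }
  rows <- lapply(items, function(it) {
    tau <- it$thresholds
    off <- if (length(tau) > 1) which(diff(tau) < 0) + 1L else integer(0)
    status <- if (it$item_id %in% testletized) "not interpretable"
              else if (length(off)) "disordered" else "ordered"
    data.frame(item = it$item_id, status = status,
               offending = paste(off, collapse = ","), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Rescore an item by collapsing categories
#'
#' Applies an order-preserving mapping of the item's categories onto a
#' contiguous `0..m'` range (e.g. collapsing a disordered adjacent pair).
#' Counts are conserved; the mapping is recorded in the returned matrix's
#' `rescore_log` attribute and provenance becomes `"rescored"`.
#'
#' @param responses a [response_matrix()].
#' @param item item id or column index.
#' @param mapping integer vector of length `item_max + 1`: new category for
#'   each old category `0..m`. Must be non-decreasing, onto `0..max(mapping)`.
#' @return the rescored [response_matrix()].
#' @examples
#' rm <- response_matrix(matrix(c(0, 1, 2, 3, 4, 2), 3, 2), item_max = c(4, 4))
#' rescore_item(rm, 1, c(0, 1, 1, 2, 3))
#' @export
rescore_item <- function(responses, item, mapping) {
  responses <- as_response_matrix(responses)
  i <- if (is.character(item)) match(item, colnames(responses)) else as.integer(item)
  if (is.na(i) || i < 1 || i > ncol(responses)) stop("unknown item: ", item)
  im <- item_max_of(responses)
  mapping <- as.integer(mapping)
  if (length(mapping) != im[i] + 1L)
    stop("mapping must give a new category for each of 0..", im[i])
  if (any(diff(mapping) < 0)) stop("mapping must be order-preserving (non-decreasing)")
  if (mapping[1] != 0L || !all(seq(0, max(mapping)) %in% mapping))
    stop("mapping must be onto a contiguous 0..m' range starting at 0")
  x <- unclass(responses)
  x[, i] <- mapping[x[, i] + 1L]
  im[i] <- max(mapping)
  out <- response_matrix(x, item_max = im, provenance = "rescored")
  attr(out, "rescore_log") <- c(attr(responses, "rescore_log"),
                                stats::setNames(list(mapping), colnames(x)[i]))
  out
}
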