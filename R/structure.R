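# Local item dependency, testlets, explained common variance and the
# unidimensionality t-test.

#' Residual correlations between items
#'
#' Pairwise correlations of the standardized residuals over co-observed
#' persons: the partial correlation between items after conditioning on the
#' trait. Under local independence these hover around a slightly negative
#' average (the residuals share the estimated trait), so dependency is
#' judged relative to the average off-diagonal correlation, not zero.
#'
#' @param fit a [rasch_fit()].
#' @param offset flag margin above the average (default 0.2; see
#'   [flag_lid()]).
#' @param min_n pairs with fewer co-observations get a `low_n` flag.
#' @return list of class `residual_cor`: `matrix` (symmetric, diagonal NA),
#'   `average` (mean off-diagonal), `pairs` (data.frame with `cor`, `n`,
#'   `margin`, `flag`, `low_n`), `offset`.
#' @export
residual_cor <- function(fit, offset = 0.2, min_n = 10) {
  z <- res_matrices(fit)
  if (ncol(z) < 3L) stop("residual correlations need at least 3 items")
  R <- suppressWarnings(stats::cor(z, use = "pairwise.complete.obs"))
  diag(R) <- NA
  nobs <- crossprod(!is.na(z))
  avg <- mean(R[upper.tri(R)], na.rm = TRUE)
  ut <- which(upper.tri(R), arr.ind = TRUE)
  pairs <- data.frame(item1 = colnames(z)[ut[, 1]], item2 = colnames(z)[ut[, 2]],
                      cor = R[ut], n = nobs[ut],
                      margin = R[ut] - avg,
                      flag = !is.na(R[ut]) & (R[ut] >= avg + offset),
                      low_n = nobs[ut] < min_n,
                      row.names = NULL)
  structure(list(matrix = R, average = avg, pairs = pairs, offset = offset),
            class = "residual_cor")
}

#' @export
print.residual_cor <- function(x, ...) {
  cat("Residual correlations: average off-diagonal =", round(x$average, 3), "\n")
  fl <- x$pairs[x$pairs$flag, , drop = FALSE]
  if (nrow(fl)) {
    cat("Locally dependent pairs (cor >= average +", x$offset, "):\n")
    print(fl[, c("item1", "item2", "cor", "n")], digits = 3, row.names = FALSE)
  } else cat("No locally dependent pairs flagged.\n")
  invisible(x)
}

#' Flag locally dependent item pairs
#'
#' A pair is flagged when its residual correlation is at least `offset`
#' (default 0.2) above the average off-diagonal residual correlation. With
#' few items the average is typically negative, so even small positive
#' correlations can signal dependency.
#'
#' @param report a `residual_cor` object (or a [rasch_fit()], for
#'   convenience).
#' @param offset threshold margin above the average.
#' @return data.frame of flagged pairs (subset of `report$pairs`).
#' @export
flag_lid <- function(report, offset = 0.2) {
  if (inherits(report, "rasch_fit")) report <- residual_cor(report, offset)
  p <- report$pairs
  p$flag <- !is.na(p$cor) & (p$cor >= report$average + offset)
  p[p$flag, , drop = FALSE]
}

#' Group items into testlets / super items
#'
#' Each group of items is summed into one larger polytomous item (maximum =
#' sum of member maxima). This absorbs local dependency without altering
#' the items or, for complete data, any person's total raw score. Groups
#' based on a priori domains are "testlets"; post hoc groupings driven by
#' observed residual correlations are "super items" -- the mechanics are
#' identical. A person's super-item score is missing if any member is
#' missing. Singleton groups pass through unchanged; ungrouped items are
#' kept as singletons.
#'
#' @param responses a [response_matrix()].
#' @param map named list of character vectors of item ids (the partition);
#'   groups must be disjoint.
#' @return a [response_matrix()] with provenance `"testletized"` and
#'   attribute `testlet_map`.
#' @examples
#' rm <- response_matrix(cbind(A = c(0, 2, 1), B = c(1, 2, 0), C = c(0, 1, 1)),
#'                       item_max = c(2, 2, 2))
#' make_testlets(rm, list(AB = c("A", "B")))
#' @export
make_testlets <- function(responses, map) {
  responses <- as_response_matrix(responses)
  ids <- colnames(responses)
  grouped <- unlist(map, use.names = FALSE)
  if (anyDuplicated(grouped)) stop("overlapping testlet groups")
  unknown <- setdiff(grouped, ids)
  if (length(unknown)) stop("unknown item(s) in testlet map: ",
                            paste(unknown, collapse = ", "))
  singles <- setdiff(ids, grouped)
  full <- c(map, stats::setNames(as.list(singles), singles))
  # keep original column order by first member
  ord <- order(vapply(full, function(g) match(g[1], ids), integer(1)))
  full <- full[ord]
  x <- unclass(responses)
  im <- item_max_of(responses)
  cols <- lapply(full, function(g) {
    sub <- x[, g, drop = FALSE]
    out <- rowSums(sub)              # NA if any member missing
    as.integer(out)
  })
  newx <- do.call(cbind, cols)
  colnames(newx) <- names(full)
  new_max <- vapply(full, function(g) sum(im[match(g, ids)]), numeric(1))
  out <- response_matrix(newx, item_max = new_max, provenance = "testletized")
  attr(out, "testlet_map") <- full
  attr(out, "truth") <- attr(responses, "truth")
  out
}

#' Explained common variance (ECV)
#'
#' Bi-factor-style summary of how much person variance the general
#' dimension retains across testlets. Each testlet's persons are estimated
#' from its member items on the common (anchored) calibration; the common
#' variance is the average between-testlet covariance of those estimates
#' (measurement errors of disjoint testlets are independent), and each
#' testlet's specific variance is its error-corrected variance in excess of
#' the common part. `ECV = V_common / (V_common + mean specific variance)`.
#' Interpretation bands: < 0.7 multidimensional, > 0.9 unidimensional,
#' between the two undetermined.
#'
#' This is a variance-decomposition approximation computed from the
#' package's own estimates (commercial implementations do not publish their
#' algorithm); it respects the 0.7/0.9 banding semantics and is labelled as
#' an approximation in reports.
#'
#' @param responses a [response_matrix()] (pre-testletization).
#' @param map testlet map as in [make_testlets()].
#' @param bands numeric length-2: the multidimensional / unidimensional
#'   cutpoints.
#' @return list of class `rasch_ecv`: `ecv`, `band`, `specific_variances`,
#'   `general_variance`.
#' @export
explained_common_variance <- function(responses, map, bands = c(0.7, 0.9)) {
  responses <- as_response_matrix(responses)
  grouped <- unlist(map, use.names = FALSE)
  singles <- setdiff(colnames(responses), grouped)
  full <- c(map, stats::setNames(lapply(singles, identity), singles))
  if (length(full) < 2L) stop("ECV undefined with a single testlet")
  fit_g <- rasch_fit(responses, model = "pcm", se = FALSE)
  full <- lapply(full, function(g) intersect(g, colnames(fit_g$responses)))
  full <- full[lengths(full) > 0]
  ids <- names(full)
  est <- matrix(NA_real_, nrow(fit_g$responses), length(ids),
                dimnames = list(rownames(fit_g$responses), ids))
  err <- numeric(length(ids))
  for (k in seq_along(ids)) {
    sub <- subset_responses(fit_g$responses, items = full[[k]])
    pm <- person_measures(sub, fit_g$items[full[[k]]])
    est[pm$person_id, k] <- pm$estimate
    err[k] <- mean(pm$se^2)
  }
  # common variance: covariance shared between testlet estimates
  # (measurement errors of different testlets are independent)
  cv <- stats::cov(est, use = "pairwise.complete.obs")
  vg <- mean(cv[upper.tri(cv)])
  s_t <- pmax(0, diag(cv) - err - vg)
  names(s_t) <- ids
  ecv <- if (vg <= 0) 0 else min(1, vg / (vg + mean(s_t)))
  band <- if (ecv < bands[1]) "multidimensional"
          else if (ecv > bands[2]) "unidimensional" else "undetermined"
  structure(list(ecv = ecv, band = band, specific_variances = s_t,
                 general_variance = max(vg, 0), bands = bands),
            class = "rasch_ecv")
}

#' @export
print.rasch_ecv <- function(x, ...) {
  cat("Explained common variance (approximate bi-factor decomposition)\n")
  cat("ECV =", round(x$ecv, 3), "->", x$band,
      "(bands:", paste(x$bands, collapse = "/"), ")\n")
  invisible(x)
}

#' Unidimensionality t-test
#'
#' Principal-component split of the residual correlation matrix: items
#' loading positively vs negatively on the first component form two
#' subsets; each person is estimated from each subset (on the common,
#' anchored metric) and the per-person difference is tested with
#' `t = (thetaA - thetaB) / sqrt(seA^2 + seB^2)`. The scale is taken as
#' unidimensional when the percentage of significant tests (|t| > 1.96) is
#' at most `threshold` (default 5%), or when the Clopper-Pearson lower
#' bound of that percentage is.
#'
#' @param fit a [rasch_fit()].
#' @param threshold percent of significant t-tests tolerated.
#' @return list of class `unidim_test`: `percent_significant`, `ci_lower`,
#'   `verdict`, `subsets`, `loadings`, `n`.
#' @export
unidim_ttest <- function(fit, threshold = 5) {
  z <- res_matrices(fit)
  if (ncol(z) < 2L) stop("unidimensionality t-test needs at least 2 items")
  if (ncol(z) < 4L)
    warning("fewer than 4 items: the subset contrast has little power")
  R <- suppressWarnings(stats::cor(z, use = "pairwise.complete.obs"))
  R[!is.finite(R)] <- 0; diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  load <- ev$vectors[, 1]
  names(load) <- colnames(z)
  if (sum(load > 0) == 0 || sum(load < 0) == 0) {
    # degenerate all-one-sign loading: split on the largest |loading|s
    if (all(load == 0)) stop("degenerate loading pattern: empty subset")
    ord <- order(-abs(load))
    pos <- names(load)[ord[seq_len(floor(length(load) / 2))]]
    neg <- setdiff(names(load), pos)
  } else {
    pos <- names(load)[load > 0]
    neg <- names(load)[load < 0]
  }
  if (length(pos) < 2L || length(neg) < 2L)
    warning("subset with fewer than 2 items; t-test has little power")
  keep <- !fit$persons$extreme
  subA <- subset_responses(fit$responses, persons = which(keep), items = pos)
  subB <- subset_responses(fit$responses, persons = which(keep), items = neg)
  pa <- person_measures(subA, fit$items[pos])
  pb <- person_measures(subB, fit$items[neg])
  common <- intersect(pa$person_id, pb$person_id)
  ia <- match(common, pa$person_id); ib <- match(common, pb$person_id)
  tstat <- (pa$estimate[ia] - pb$estimate[ib]) /
    sqrt(pa$se[ia]^2 + pb$se[ib]^2)
  nsig <- sum(abs(tstat) > 1.96)
  n <- length(tstat)
  pct <- 100 * nsig / n
  ci_lo <- if (nsig == 0) 0 else 100 * stats::qbeta(0.025, nsig, n - nsig + 1)
  verdict <- if (pct <= threshold || ci_lo <= threshold)
    "unidimensional" else "multidimensional"
  structure(list(percent_significant = pct, ci_lower = ci_lo,
                 verdict = verdict, subsets = list(positive = pos, negative = neg),
                 loadings = load, n = n, t = tstat),
            class = "unidim_test")
}

#' @export
print.unidim_test <- function(x, ...) {
  cat("Unidimensionality t-test (PCA split of residuals)\n")
  cat("subsets:", paste(x$subsets$positive, collapse = "+"), "vs",
      paste(x$subsets$negative, collapse = "+"), "\n")
  cat(round(x$percent_significant, 1), "% of ", x$n,
      " t-tests significant (CI lower bound ",
      round(x$ci_lower, 1), "%) -> ", x$verdict, "\n", sep = "")
  invisible(x)
}
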