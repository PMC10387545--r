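# Reliability, targeting, the ordinal-to-interval transformation table and
# test equating.

#' Reliability: person separation index, alpha, separation, strata
#'
#' The person separation index (PSI) is reliability on the logit metric:
#' `(observed variance of theta-hat - mean squared SE) / observed
#' variance`, over non-extreme persons. Cronbach's alpha is computed from
#' the raw item scores on complete cases. For normally distributed samples
#' PSI and alpha are similar; skewed samples usually pull PSI below alpha.
#' `separation = sqrt(PSI / (1 - PSI))` and the number of statistically
#' distinct ability strata is `(4 * separation + 1) / 3`. Individual-use
#' reliability requires about 0.9.
#'
#' @param fit a [rasch_fit()] (or a `person_measures` data.frame plus
#'   `responses`).
#' @param responses only needed when `fit` is a `person_measures` object.
#' @return list of class `rasch_reliability`: `psi`, `alpha`,
#'   `alpha_n_complete`, `separation`, `strata`, `individual_use`,
#'   `n_nonextreme`.
#' @export
reliability <- function(fit, responses = NULL) {
  if (inherits(fit, "rasch_fit")) {
    persons <- fit$persons
    responses <- fit$responses
  } else persons <- fit
  if (nrow(persons[!persons$extreme, ]) < 2L)
    stop("need at least 2 non-extreme persons")
  pm <- persons[!persons$extreme, ]
  v <- stats::var(pm$estimate)
  psi <- if (v <= 0) NA_real_ else (v - mean(pm$se^2)) / v
  if (!is.na(psi)) psi <- max(psi, 0)
  # Cronbach's alpha on complete cases, raw scores
  x <- unclass(responses)
  cc <- stats::complete.cases(x)
  alpha <- NA_real_
  if (sum(cc) >= 2L) {
    xc <- x[cc, , drop = FALSE]
    vt <- stats::var(rowSums(xc))
    if (vt > 0) {
      k <- ncol(xc)
      alpha <- k / (k - 1) * (1 - sum(apply(xc, 2, stats::var)) / vt)
    }
  }
  sep <- if (is.na(psi) || psi >= 1) NA_real_ else sqrt(psi / (1 - psi))
  strata <- if (is.na(sep)) NA_real_ else (4 * sep + 1) / 3
  out <- list(psi = psi, alpha = alpha, alpha_n_complete = sum(cc),
              separation = sep, strata = strata,
              individual_use = !is.na(psi) && psi >= 0.9,
              n_nonextreme = nrow(pm))
  if (is.na(psi))
    warning("zero person variance: PSI undefined (homogeneous sample)")
  class(out) <- "rasch_reliability"
  out
}

#' @export
print.rasch_reliability <- function(x, ...) {
  cat("Reliability: PSI =", round(x$psi, 3),
      " alpha =", round(x$alpha, 3),
      "(", x$alpha_n_complete, "complete cases )\n")
  cat("separation =", round(x$separation, 2),
      " strata =", round(x$strata, 2),
      if (x$individual_use) " [suitable for individual use]" else "", "\n")
  invisible(x)
}

#' Number of ability strata from a separation index
#'
#' `(4 * separation + 1) / 3`: how many statistically distinct levels of
#' the trait the scale resolves.
#'
#' @param separation separation index (>= 0).
#' @export
strata_count <- function(separation) {
  stopifnot(is.numeric(separation), all(separation >= 0))
  (4 * separation + 1) / 3
}

#' Targeting summary and Wright map data
#'
#' How well the item (threshold) locations cover the person distribution
#' on the shared logit metric. Reports distribution summaries, the
#' person-item mean offset (a warning is attached beyond +/-1 logit:
#' off-target, which depresses reliability) and binned counts for the
#' Wright map (persons on one side, thresholds on the other).
#'
#' @param fit a [rasch_fit()].
#' @param binwidth Wright map bin width in logits (default 0.25).
#' @return list of class `rasch_targeting`: `person_mean`, `person_sd`,
#'   `item_mean`, `threshold_range`, `offset`, `off_target`, `bins`
#'   (data.frame mid/persons/thresholds).
#' @export
targeting <- function(fit, binwidth = 0.25) {
  pm <- fit$persons[!fit$persons$extreme, ]
  thr <- unlist(lapply(fit$items, function(it) it$thresholds))
  pmean <- mean(pm$estimate); imean <- mean(coef(fit$items))
  offset <- pmean - imean
  lo <- floor(min(pm$estimate, thr) / binwidth) * binwidth
  hi <- ceiling(max(pm$estimate, thr) / binwidth) * binwidth
  breaks <- seq(lo, hi + binwidth, by = binwidth)
  bins <- data.frame(
    mid = breaks[-length(breaks)] + binwidth / 2,
    persons = as.integer(table(cut(pm$estimate, breaks, right = FALSE))),
    thresholds = as.integer(table(cut(thr, breaks, right = FALSE))))
  structure(list(person_mean = pmean, person_sd = stats::sd(pm$estimate),
                 item_mean = imean,
                 threshold_range = range(thr), offset = offset,
                 off_target = abs(offset) > 1, bins = bins,
                 binwidth = binwidth),
            class = "rasch_targeting")
}

#' @export
print.rasch_targeting <- function(x, ...) {
  cat("Targeting: person mean", round(x$person_mean, 2),
      "(SD", round(x$person_sd, 2), "), item mean", round(x$item_mean, 2), "\n")
  cat("person-item offset:", round(x$offset, 2), "logits",
      if (x$off_target) "[off-target]" else "[well targeted]", "\n")
  invisible(x)
}

#' Wright map
#'
#' Back-to-back histogram of person abilities (left) and item thresholds
#' (right) on the common logit metric.
#'
#' @param x a [rasch_fit()].
#' @param binwidth bin width in logits.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.rasch_fit <- function(x, binwidth = 0.25, ...) {
  tg <- targeting(x, binwidth)
  b <- tg$bins
  old <- graphics::par(no.readonly = TRUE); on.exit(graphics::par(old))
  graphics::par(mar = c(4, 4, 3, 1))
  lim <- max(b$persons, b$thresholds)
  graphics::barplot(-b$persons, horiz = TRUE, names.arg = sprintf("%.2f", b$mid),
                    xlim = c(-lim, lim), col = "steelblue", border = NA,
                    las = 1, cex.names = 0.6,
                    main = "Wright map", xlab = "persons | thresholds", ...)
  graphics::barplot(b$thresholds, horiz = TRUE, add = TRUE, col = "tomato",
                    border = NA, axes = FALSE)
  invisible(tg)
}

#' Ordinal-to-interval transformation table
#'
#' For a complete-data administration, the total raw score is sufficient
#' for the person estimate, so every raw score maps to one interval-level
#' logit estimate. The table gives, per raw score `0..max`, the weighted
#' likelihood estimate, its SE, and a linear rescaling in which raw 0 and
#' raw max hit the target range endpoints exactly (default 0-100; reports
#' conventionally show one decimal). The logit and rescaled columns are
#' strictly increasing: the transformation preserves raw-score ordering.
#'
#' @param items a [rasch_items()] or [rasch_fit()].
#' @param range numeric length-2 target range (low, high).
#' @return data.frame of class `transformation_table`: `raw_score`,
#'   `logit`, `se`, `rescaled`.
#' @export
transformation_table <- function(items, range = c(0, 100)) {
  if (inherits(items, "rasch_fit")) items <- items$items
  tau <- lapply(items, function(it) it$thresholds)
  M <- sum(lengths(tau))
  sol <- t(vapply(0:M, function(r) wle_solve(r, tau), numeric(2)))
  logit <- sol[, 1]; se <- sol[, 2]
  resc <- range[1] + (logit - logit[1]) / (logit[M + 1] - logit[1]) *
    (range[2] - range[1])
  out <- data.frame(raw_score = 0:M, logit = logit, se = se, rescaled = resc)
  class(out) <- c("transformation_table", "data.frame")
  attr(out, "range") <- range
  out
}

#' @export
print.transformation_table <- function(x, ...) {
  cat("Raw score to interval-scale transformation (range ",
      paste(attr(x, "range"), collapse = "-"), ")\n", sep = "")
  y <- data.frame(raw_score = x$raw_score, logit = round(x$logit, 3),
                  se = round(x$se, 3), rescaled = sprintf("%.1f", x$rescaled))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Equate tests via total scores
#'
#' Places two or more scales measuring one construct on a common metric by
#' treating each scale's total score as one large polytomous item and
#' fitting those scale-items to the Rasch model in the usual way. The
#' thresholds of the fitted scale-items must be ordered for equating;
#' disorder aborts with a diagnostic. The cross-walk maps each raw total of
#' each scale to the common logit and, by interpolation in the other
#' scale's transformation table, to the equivalent raw total of every other
#' scale.
#'
#' @param scale_totals matrix/data.frame of per-person scale totals, one
#'   column per scale.
#' @param scale_max integer vector of maximum totals (default observed max).
#' @param range rescaling range for the per-scale transformation tables.
#' @return list of class `rasch_equating`: `items` (scale-item parameters),
#'   `tables` (per-scale transformation tables), `crosswalk` (data.frame
#'   mapping every score of every scale to the common logit and the
#'   equivalent score on each other scale).
#' @export
equate_tests <- function(scale_totals, scale_max = NULL, range = c(0, 100)) {
  rm <- response_matrix(scale_totals, item_max = scale_max)
  if (ncol(rm) < 2L) stop("equating needs at least 2 scales")
  fit <- rasch_fit(rm, model = "pcm", se = FALSE)
  disord <- threshold_order(fit$items)
  bad <- disord$item[disord$status == "disordered"]
  if (length(bad))
    stop("equating refused: disordered thresholds for scale(s) ",
         paste(bad, collapse = ", "),
         " (transitions ", paste(disord$offending[disord$status == "disordered"],
                                 collapse = "; "), ")")
  tabs <- lapply(names(fit$items), function(s)
    transformation_table(fit$items[s], range = range))
  names(tabs) <- names(fit$items)
  cross <- list()
  for (s in names(fit$items)) {
    tb <- tabs[[s]]
    for (s2 in setdiff(names(fit$items), s)) {
      tb2 <- tabs[[s2]]
      cross[[paste(s, s2)]] <- data.frame(
        scale = s, raw_score = tb$raw_score, logit = tb$logit,
        to_scale = s2,
        equivalent_score = stats::approx(tb2$logit, tb2$raw_score,
                                         xout = tb$logit, rule = 2)$y,
        row.names = NULL)
    }
  }
  structure(list(items = fit$items, tables = tabs,
                 crosswalk = do.call(rbind, c(cross, list(make.row.names = FALSE))),
                 fit = fit),
            class = "rasch_equating")
}

#' @export
print.rasch_equating <- function(x, ...) {
  cat("Test equating:", length(x$items), "scales fitted as polytomous items\n")
  print(round(coef(x$items), 3))
  invisible(x)
}
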