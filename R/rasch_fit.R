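#' Fit the polytomous Rasch model
#'
#' The main entry point: estimates item thresholds by conditional maximum
#' likelihood (see [estimate_items()]) and person abilities by weighted
#' likelihood (see [person_measures()]), returning a fitted-model object on
#' which the whole requirement battery operates ([item_fit()],
#' [person_fit()], [residual_cor()], [unidim_ttest()], [dif_anova()],
#' [reliability()], [targeting()], [transformation_table()]).
#'
#' @param responses a [response_matrix()] (or plain integer matrix) of
#'   ordered categories, persons x items, `NA` = missing.
#' @param model `"pcm"` (partial credit: item-specific threshold spacings),
#'   `"rsm"` (rating scale: shared spacings) or `"auto"` (choose by the
#'   conditional likelihood-ratio test, see [rsm_vs_pcm()]).
#' @param anchor optional [rasch_items()] anchor; fixed parameters define
#'   the metric (no re-centering).
#' @param se compute item-parameter standard errors.
#' @param alpha significance level for the `"auto"` model choice.
#' @return An object of class `rasch_fit` with components `items`
#'   ([rasch_items()]), `persons` (person measures), `responses`, `model`,
#'   `lr_test` (when `model = "auto"`), and `call`.
#' @examples
#' sim <- simulate_responses(sim_design(150, spread_items(6, 3), seed = 42))
#' fit <- rasch_fit(sim)
#' fit
#' coef(fit)
#' @export
rasch_fit <- function(responses, model = c("pcm", "rsm", "auto"),
                      anchor = NULL, se = TRUE, alpha = 0.05) {
  model <- match.arg(model)
  cl <- match.call()
  responses <- as_response_matrix(responses)
  responses <- collapse_unused_categories(drop_degenerate(responses))
  lr <- NULL
  if (model == "auto") {
    lr <- tryCatch(suppressWarnings(rsm_vs_pcm(responses)), error = function(e) NULL)
    model <- if (!is.null(lr) && !is.na(lr$p.value) && lr$p.value >= alpha)
      "rsm" else "pcm"
  }
  items <- estimate_items(responses, model_form = model, anchor = anchor, se = se)
  persons <- person_measures(responses, items)
  structure(list(call = cl, responses = responses, items = items,
                 persons = persons, model = model, lr_test = lr,
                 anchored = !is.null(anchor)),
            class = "rasch_fit")
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat("Rasch model fit (", x$model, ", conditional ML)\n", sep = "")
  cat(nrow(x$responses), "persons,", ncol(x$responses), "items;",
      sum(is.na(x$responses)), "missing cells\n")
  cat("item locations (logits):\n")
  print(round(coef(x$items), 3))
  conv <- attr(x$items, "convergence")
  if (!is.null(conv) && !isTRUE(conv$converged))
    cat("NOTE: estimation convergence not confirmed (|grad| =",
        signif(conv$grad_norm, 3), ")\n")
  invisible(x)
}

#' @export
coef.rasch_fit <- function(object, what = c("items", "thresholds", "persons"), ...) {
  what <- match.arg(what)
  switch(what,
         items = coef(object$items),
         thresholds = object$items,
         persons = stats::setNames(object$persons$estimate, object$persons$person_id))
}

#' @export
logLik.rasch_fit <- function(object, ...) {
  structure(attr(object$items, "logLik_cond"),
            df = attr(object$items, "npar"),
            class = "logLik")
}

#' @export
summary.rasch_fit <- function(object, ...) {
  ifit <- item_fit(object)
  pfit <- person_fit(object)
  rel <- reliability(object)
  tg <- targeting(object)
  out <- list(fit = object, item_fit = ifit, person_fit_summary =
                c(mean = mean(pfit$fit_residual, na.rm = TRUE),
                  sd = stats::sd(pfit$fit_residual, na.rm = TRUE),
                  flagged = sum(pfit$flag, na.rm = TRUE)),
              reliability = rel, targeting = tg,
              thresholds = threshold_order(object$items))
  class(out) <- "summary.rasch_fit"
  out
}

#' @export
print.summary.rasch_fit <- function(x, digits = 3, ...) {
  print(x$fit)
  cat("\nItem fit:\n")
  print(x$item_fit, digits = digits)
  cat("\nPerson fit residual: mean", round(x$person_fit_summary["mean"], 3),
      "sd", round(x$person_fit_summary["sd"], 3), "; |>2.5| flagged:",
      x$person_fit_summary["flagged"], "\n")
  cat("\nReliability: PSI", round(x$reliability$psi, 3),
      "alpha", round(x$reliability$alpha, 3),
      "strata", round(x$reliability$strata, 2), "\n")
  cat("Targeting: person mean", round(x$targeting$person_mean, 3),
      "(item mean 0 by constraint); offset",
      round(x$targeting$offset, 3), "logits\n")
  dis <- x$thresholds$status == "disordered"
  if (any(dis)) cat("Disordered thresholds:",
                    paste(x$thresholds$item[dis], collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.rasch_fit <- function(object, newtheta = NULL,
                              type = c("expected", "probability"), ...) {
  type <- match.arg(type)
  th <- if (is.null(newtheta)) object$persons$estimate else newtheta
  if (type == "expected") {
    sapply(object$items, function(it) expected_score(th, it))
  } else {
    lapply(object$items, function(it) category_probability(th, it))
  }
}

#' @export
simulate.rasch_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  th <- object$persons$estimate
  lapply(seq_len(nsim), function(s) {
    X <- sapply(object$items, function(it) {
      p <- category_probability(th, it)
      u <- stats::runif(length(th))
      max.col(u < t(apply(p, 1, cumsum)), ties.method = "first") - 1L
    })
    X[is.na(unclass(object$responses))] <- NA_integer_
    response_matrix(X, item_max = item_maxima(object$items))
  })
}

#' Likelihood-ratio test of rating scale vs. partial credit parameterisation
#'
#' Both models are fitted by conditional maximum likelihood (so the test is
#' free of the trait distribution) and compared with
#' `-2 (logL_RSM - logL_PCM)` on `(I - 1)(m - 1)` degrees of freedom. A
#' significant result means the threshold spacings differ across items and
#' the partial credit parameterisation is needed.
#'
#' @param responses a [response_matrix()].
#' @param alpha significance level for the recommendation.
#' @return list of class `rasch_lr_test`: `statistic`, `df`, `p.value`,
#'   `recommended` (`"pcm"` or `"rsm"`), `skipped` (with reason when the
#'   test cannot run: single item, or unequal category counts, which force
#'   the PCM).
#' @export
rsm_vs_pcm <- function(responses, alpha = 0.05) {
  responses <- as_response_matrix(responses)
  responses <- collapse_unused_categories(drop_degenerate(responses))
  im <- item_max_of(responses)
  skip <- NULL
  if (ncol(responses) < 2L)
    skip <- "single-item instrument: the two parameterisations coincide"
  else if (length(unique(im)) != 1L)
    skip <- "unequal category counts across items: PCM forced"
  else if (im[1] < 2L)
    skip <- "dichotomous items: the two parameterisations coincide"
  if (!is.null(skip)) {
    warning("RSM vs PCM test skipped: ", skip)
    out <- list(statistic = NA_real_, df = NA_integer_, p.value = NA_real_,
                recommended = "pcm", skipped = skip)
    class(out) <- "rasch_lr_test"
    return(out)
  }
  pcm <- estimate_items(responses, "pcm", se = FALSE)
  rsm <- estimate_items(responses, "rsm", se = FALSE)
  stat <- -2 * (attr(rsm, "logLik_cond") - attr(pcm, "logLik_cond"))
  df <- (ncol(responses) - 1L) * (im[1] - 1L)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  out <- list(statistic = stat, df = df, p.value = p,
              recommended = if (p < alpha) "pcm" else "rsm", skipped = NULL)
  class(out) <- "rasch_lr_test"
  out
}

#' @export
print.rasch_lr_test <- function(x, ...) {
  cat("Likelihood-ratio test: rating scale vs partial credit (conditional)\n")
  if (!is.null(x$skipped)) {
    cat("skipped:", x$skipped, "\n")
  } else {
    cat("LR =", round(x$statistic, 2), " df =", x$df,
        " p =", signif(x$p.value, 3), "\n")
  }
  cat("recommended parameterisation:", x$recommended, "\n")
  invisible(x)
}
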