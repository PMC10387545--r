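# Group invariance: DIF by two-way ANOVA of residuals, item splitting and
# the anchored substantive-DIF effect-size decision.

#' Differential item functioning by ANOVA of residuals
#'
#' For every item, a two-way ANOVA of the standardized residuals on the
#' person grouping and the ability class interval (sequential
#' `z ~ interval + group + interval:group`). The group main effect tests
#' uniform DIF (a constant shift at equal trait level); the interaction
#' tests non-uniform DIF (a trait-dependent shift). Flags use
#' Bonferroni-adjusted alpha; by convention the adjustment family is
#' items x factors for a screening pass.
#'
#' @param fit a [rasch_fit()].
#' @param factors data.frame (or single factor/vector) of person groupings,
#'   rows aligned with the response matrix.
#' @param G class interval count (`NULL` = default rule).
#' @param alpha nominal level; `family` divides it (defaults to
#'   items x factors).
#' @param min_group_n groups smaller than this trigger a warning.
#' @return data.frame of class `dif_result`: per item x factor, uniform
#'   (`uniform_f`, `uniform_p`) and non-uniform (`nonuniform_f`,
#'   `nonuniform_p`) statistics with Bonferroni flags.
#' @export
dif_anova <- function(fit, factors, G = NULL, alpha = 0.05,
                      min_group_n = 10, family = NULL) {
  if (!is.data.frame(factors)) {
    factors <- data.frame(group = factors)
  }
  if (nrow(factors) != nrow(fit$responses))
    stop("factors must have one row per person in the response matrix")
  z <- res_matrices(fit)
  keep <- !fit$persons$extreme
  factors <- factors[keep, , drop = FALSE]
  ci <- factor(class_intervals(fit, G))
  if (is.null(family)) family <- ncol(z) * ncol(factors)
  thr <- alpha / family
  rows <- list()
  for (f in names(factors)) {
    g <- factor(factors[[f]])
    if (nlevels(droplevels(g)) < 2L)
      stop("factor '", f, "' has a single group")
    if (any(table(g) < min_group_n))
      warning("factor '", f, "': group(s) with fewer than ", min_group_n,
              " persons")
    for (i in seq_len(ncol(z))) {
      ok <- !is.na(z[, i]) & !is.na(g)
      av <- tryCatch(
        stats::anova(stats::lm(z[ok, i] ~ ci[ok] + g[ok] + ci[ok]:g[ok])),
        error = function(e) NULL)
      up <- nup <- NA_real_; uf <- nf <- NA_real_
      if (!is.null(av) && nrow(av) >= 4) {
        uf <- av$`F value`[2]; up <- av$`Pr(>F)`[2]
        nf <- av$`F value`[3]; nup <- av$`Pr(>F)`[3]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        item = colnames(z)[i], factor = f,
        uniform_f = uf, uniform_p = up,
        nonuniform_f = nf, nonuniform_p = nup,
        uniform_flag = !is.na(up) & up < thr,
        nonuniform_flag = !is.na(nup) & nup < thr,
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha_adjusted") <- thr
  class(out) <- c("dif_result", "data.frame")
  out
}

#' Split an item by a person grouping
#'
#' Replaces one DIF-flagged item column by one column per group (structural
#' missing elsewhere), so each group gets its own item parameters while all
#' other items are untouched. Per-person observed counts are unchanged and
#' the original matrix is recoverable by summing the split columns.
#'
#' @param responses a [response_matrix()].
#' @param item item id or index to split.
#' @param groups factor/vector of group membership, one per person.
#' @param split_groups groups receiving their own column; default: every
#'   group separately. E.g. `list(illiterate = "illiterate", rest =
#'   c("primary", "secondary+"))` splits one group against the pooled rest.
#' @return a [response_matrix()] with provenance `"split"`; the new columns
#'   are named `item@groupname`.
#' @export
split_item <- function(responses, item, groups, split_groups = NULL) {
  responses <- as_response_matrix(responses)
  i <- if (is.character(item)) match(item, colnames(responses)) else as.integer(item)
  if (is.na(i)) stop("unknown item: ", item)
  if (!is.factor(groups)) groups <- factor(groups)   # keep declared levels
  if (length(groups) != nrow(responses))
    stop("groups must have one entry per person")
  if (is.null(split_groups))
    split_groups <- stats::setNames(as.list(levels(groups)), levels(groups))
  x <- unclass(responses)
  im <- item_max_of(responses)
  id <- colnames(x)[i]
  newcols <- lapply(names(split_groups), function(gname) {
    sel <- groups %in% split_groups[[gname]]
    if (!any(sel & !is.na(x[, i])))
      stop("group '", gname, "' has no observations on item ", id)
    col <- rep(NA_integer_, nrow(x))
    col[sel] <- x[sel, i]
    col
  })
  newx <- cbind(x[, seq_len(i - 1L), drop = FALSE],
                do.call(cbind, newcols),
                x[, setdiff(seq_len(ncol(x)), seq_len(i)), drop = FALSE])
  colnames(newx) <- c(colnames(x)[seq_len(i - 1L)],
                      paste0(id, "@", names(split_groups)),
                      colnames(x)[setdiff(seq_len(ncol(x)), seq_len(i))])
  new_im <- c(im[seq_len(i - 1L)], rep(im[i], length(split_groups)),
              im[setdiff(seq_len(ncol(x)), seq_len(i))])
  out <- response_matrix(newx, item_max = new_im, provenance = "split")
  attr(out, "split_info") <- list(item = id, groups = split_groups)
  out
}

#' Substantive DIF test
#'
#' A statistically flagged DIF may be practically negligible. This test
#' compares person estimates from the unsplit and the split solution, both
#' placed on one metric by anchoring through items free of DIF: the split
#' solution is estimated freely, and the unsplit solution is shifted so the
#' anchor items' mean location matches. A paired t-test on the per-person
#' estimate differences decides significance; the effect size is the
#' absolute mean difference standardized by the SD of the unsplit person
#' estimates. Verdict: `"no DIF"` when not significant; when significant,
#' `"substantive (use split)"` if the effect size is >= 0.1 and
#' `"non-substantive (retain unsplit)"` otherwise. Effects above 0.015 are
#' reported as non-negligible measurement bias even when below 0.1.
#'
#' @param responses a [response_matrix()].
#' @param item item id to split.
#' @param groups person grouping (factor/vector).
#' @param anchor_items character vector of non-DIF item ids used for
#'   anchoring (must be non-empty).
#' @param split_groups as in [split_item()].
#' @param es_substantive,es_nonnegligible the 0.1 / 0.015 effect-size
#'   bounds.
#' @return list of class `substantive_dif`: `t`, `p`, `effect_size`,
#'   `verdict`, `mean_difference`, `non_negligible`.
#' @export
substantive_dif <- function(responses, item, groups, anchor_items,
                            split_groups = NULL,
                            es_substantive = 0.1, es_nonnegligible = 0.015) {
  responses <- as_response_matrix(responses)
  anchor_items <- setdiff(anchor_items, item)
  if (length(anchor_items) == 0)
    stop("no non-DIF anchor item available: review the solutions manually")
  if (!all(anchor_items %in% colnames(responses)))
    stop("anchor items not found in responses")
  split_rm <- split_item(responses, item, groups, split_groups)
  fit_split <- rasch_fit(split_rm, model = "pcm", se = FALSE)
  fit_unsplit <- rasch_fit(responses, model = "pcm", se = FALSE)
  # shift the unsplit metric so the anchor locations agree with the split fit
  anchor_ok <- intersect(anchor_items,
                         intersect(names(fit_split$items), names(fit_unsplit$items)))
  shift <- mean(vapply(anchor_ok, function(a) fit_split$items[[a]]$location,
                       numeric(1))) -
           mean(vapply(anchor_ok, function(a) fit_unsplit$items[[a]]$location,
                       numeric(1)))
  shifted <- lapply(fit_unsplit$items, function(it) it$thresholds + shift)
  items_shifted <- rasch_items(shifted,
                               model_form = attr(fit_unsplit$items, "model_form"))
  p_unsplit <- person_measures(fit_unsplit$responses, items_shifted)
  p_split <- fit_split$persons
  common <- intersect(p_unsplit$person_id, p_split$person_id)
  d <- p_split$estimate[match(common, p_split$person_id)] -
       p_unsplit$estimate[match(common, p_unsplit$person_id)]
  tt <- stats::t.test(d)
  es <- abs(mean(d)) / stats::sd(p_unsplit$estimate)
  sig <- tt$p.value < 0.05
  verdict <- if (!sig) "no DIF"
             else if (es >= es_substantive) "substantive (use split)"
             else "non-substantive (retain unsplit)"
  structure(list(t = unname(tt$statistic), p = tt$p.value, effect_size = es,
                 mean_difference = mean(d), verdict = verdict,
                 non_negligible = sig && es > es_nonnegligible,
                 anchor_items = anchor_ok, n = length(d)),
            class = "substantive_dif")
}

#' @export
print.substantive_dif <- function(x, ...) {
  cat("Substantive DIF test (anchored split vs unsplit person estimates)\n")
  cat("paired t =", round(x$t, 2), " p =", signif(x$p, 3),
      " effect size =", round(x$effect_size, 3), "\n")
  cat("verdict:", x$verdict, "\n")
  invisible(x)
}

# deviating group for auto-splitting: largest |mean residual| on the item
deviating_group <- function(fit, item, groups) {
  z <- res_matrices(fit)
  keep <- !fit$persons$extreme
  g <- factor(groups[keep])
  mz <- tapply(z[, item], g, mean, na.rm = TRUE)
  names(which.max(abs(mz)))
}
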