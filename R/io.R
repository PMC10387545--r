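# CSV/JSON input-output: response and covariate readers with a data-quality
# log, report writers, and the item-parameter anchor-file format.

#' Read a response matrix from CSV
#'
#' Expects a header row, a person-id column (default the first column, or
#' one named `person`/`person_id`), and integer category columns. Cells
#' equal to `missing_code` (plus empty cells and `NA`) are recorded missing.
#' Parse problems (out-of-range categories, duplicate ids, non-integer
#' values) are reported as itemized errors. A data-quality log (category
#' usage per item, missingness per person and item) is attached as
#' attribute `quality`.
#'
#' @param path CSV file.
#' @param missing_code value denoting a missing response (default 9 is a
#'   common convention; empty cells and `NA` always count as missing).
#' @param item_max optional per-item maxima (default: observed).
#' @return a [response_matrix()].
#' @export
read_responses <- function(path, missing_code = NA, item_max = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("input error: need a person id column plus items")
  idcol <- match(c("person", "person_id"), names(df))
  idcol <- idcol[!is.na(idcol)][1]
  if (is.na(idcol)) idcol <- 1L
  ids <- as.character(df[[idcol]])
  if (anyDuplicated(ids))
    stop("input error: duplicate person ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  x <- as.matrix(df[-idcol])
  errs <- character(0)
  for (j in seq_len(ncol(x))) {
    v <- suppressWarnings(as.numeric(x[, j]))
    chr <- !is.na(x[, j]) & x[, j] != "" & is.na(v)
    if (any(chr))
      errs <- c(errs, paste0("item '", colnames(x)[j], "': non-numeric value(s) ",
                             paste(unique(x[chr, j]), collapse = ",")))
    nonint <- !is.na(v) & v != round(v)
    if (any(nonint))
      errs <- c(errs, paste0("item '", colnames(x)[j], "': non-integer value(s)"))
  }
  if (length(errs)) stop("input error:\n  ", paste(errs, collapse = "\n  "))
  xm <- matrix(suppressWarnings(as.integer(x)), nrow(x), ncol(x),
               dimnames = list(ids, colnames(x)))
  if (!is.na(missing_code)) xm[xm == missing_code] <- NA_integer_
  if (any(xm < 0, na.rm = TRUE))
    stop("input error: negative categories present (wrong missing code?)")
  out <- response_matrix(xm, item_max = item_max)
  im <- item_max_of(out)
  usage <- lapply(seq_len(ncol(out)), function(i)
    tabulate(unclass(out)[, i] + 1L, nbins = im[i] + 1L))
  names(usage) <- colnames(out)
  attr(out, "quality") <- list(
    category_usage = usage,
    missing_per_item = colSums(is.na(out)),
    missing_per_person = rowSums(is.na(out)))
  out
}

#' Read a person covariate table from CSV
#'
#' First column (or `person`/`person_id`) is the person id; the rest are
#' covariates, returned as character/factor columns.
#'
#' @param path CSV file.
#' @return data.frame with rownames = person ids.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  idcol <- match(c("person", "person_id"), names(df))
  idcol <- idcol[!is.na(idcol)][1]
  if (is.na(idcol)) idcol <- 1L
  ids <- as.character(df[[idcol]])
  if (anyDuplicated(ids)) stop("input error: duplicate person ids in covariates")
  out <- df[-idcol]
  rownames(out) <- ids
  out
}

#' Write a response matrix (with covariates) to CSV
#'
#' @param responses a [response_matrix()].
#' @param path output CSV.
#' @export
write_responses <- function(responses, path) {
  df <- data.frame(person = rownames(responses),
                   as.data.frame(unclass(responses)), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export / import item parameters (anchor-file format)
#'
#' CSV with columns `item_id`, `step`, `value`, `se`: the interchange
#' format for anchored estimation across samples or time points.
#'
#' @param items a [rasch_items()].
#' @param path CSV file.
#' @export
write_items <- function(items, path) {
  df <- as.data.frame(items)
  utils::write.csv(data.frame(item_id = df$item, step = df$step,
                              value = df$tau, se = df$se),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_items
#' @export
read_items <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "step", "value")
  if (!all(need %in% names(df)))
    stop("input error: anchor file needs columns ", paste(need, collapse = ", "))
  df <- df[order(match(df$item_id, unique(df$item_id)), df$step), ]
  th <- split(df$value, factor(df$item_id, levels = unique(df$item_id)))
  se <- if ("se" %in% names(df))
    split(df$se, factor(df$item_id, levels = unique(df$item_id))) else NULL
  rasch_items(th, se = se)
}

protocol_report_list <- function(x) {
  iters <- lapply(x$iterations, function(it) {
    list(label = it$label, n_items = it$n_items, item_set = it$item_set,
         item_fit_mean_residual = it$item_fit_mean_residual,
         item_fit_sd_residual = it$item_fit_sd_residual,
         person_fit_mean_residual = it$person_fit_mean_residual,
         person_fit_sd_residual = it$person_fit_sd_residual,
         persons_misfitting = it$persons_misfitting,
         total_chisq = it$total_chisq, total_chisq_df = it$total_chisq_df,
         total_chisq_p = it$total_chisq_p,
         psi = it$psi, alpha = it$alpha,
         percent_t_significant = it$percent_t_significant,
         unidim_verdict = it$unidim_verdict,
         lid_average = it$lid_average,
         lid_flags = it$lid_flags,
         item_fit = it$item_fit)
  })
  cfg <- x$config
  list(config = cfg[setdiff(names(cfg), "testlet_map")],
       methods_checklist = list(
         model_parameterisation = x$final_fit$model,
         estimation = "conditional maximum likelihood (items); weighted likelihood (persons)",
         lid_rule = paste0("residual correlation >= average + ", cfg$lid_offset),
         fit_rules = paste0("chi-square/ANOVA at Bonferroni-adjusted ", cfg$alpha,
                            "; INFIT at Smith's corrected interval"),
         person_fit_bound = cfg$person_fit_bound,
         dif_analysis = "two-way ANOVA of residuals (uniform + non-uniform)",
         dif_factors = cfg$dif_factors, causal_factors = cfg$causal_factors,
         unidimensionality = paste0("PCA-split t-tests, threshold ",
                                    cfg$unidim_threshold, "%"),
         ecv_note = "ECV is a variance-decomposition approximation"),
       iterations = iters,
       decisions = x$decisions,
       threshold_report = x$threshold_report,
       dif = x$dif,
       ecv = if (!is.null(x$ecv)) list(ecv = x$ecv$ecv, band = x$ecv$band) else NULL,
       unidimensionality = if (!is.null(x$unidim))
         list(percent = x$unidim$percent_significant,
              ci_lower = x$unidim$ci_lower, verdict = x$unidim$verdict) else NULL,
       reliability = unclass(x$reliability),
       targeting = x$targeting[c("person_mean", "person_sd", "item_mean",
                                 "offset", "off_target")],
       wright_map = x$targeting$bins,
       transformation = x$transformation,
       verdict = x$verdict)
}

#' Write protocol artifacts
#'
#' Writes the machine-readable JSON report (every number in the
#' human-readable summary appears here), a Markdown summary, and CSV tables
#' (item fit per iteration, residual correlations, DIF, transformation,
#' Wright map bins).
#'
#' @param x a `rasch_protocol` from [run_protocol()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "rasch_protocol"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  rep <- protocol_report_list(x)
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(rep, jp, auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE, force = TRUE)
  paths <- c(paths, jp)
  mp <- file.path(dir, "report.md")
  md <- c("# Rasch analysis report", "",
          paste0("Verdict: ", x$verdict), "",
          "## Iterations", "",
          utils::capture.output(print(x)), "",
          "## Decisions", paste0("- ", x$decisions))
  writeLines(md, mp); paths <- c(paths, mp)
  for (nm in names(x$iterations)) {
    fp <- file.path(dir, paste0("item_fit_", nm, ".csv"))
    utils::write.csv(x$iterations[[nm]]$item_fit, fp, row.names = FALSE)
    paths <- c(paths, fp)
  }
  last_rc <- x$iterations[[length(x$iterations)]]$residual_cor
  if (!is.null(last_rc)) {
    fp <- file.path(dir, "residual_correlations.csv")
    utils::write.csv(data.frame(item = rownames(last_rc$matrix),
                                round(last_rc$matrix, 4), check.names = FALSE),
                     fp, row.names = FALSE)
    paths <- c(paths, fp)
  }
  if (!is.null(x$dif)) {
    fp <- file.path(dir, "dif.csv")
    utils::write.csv(x$dif, fp, row.names = FALSE); paths <- c(paths, fp)
  }
  if (!is.null(x$transformation)) {
    fp <- file.path(dir, "transformation_table.csv")
    utils::write.csv(x$transformation, fp, row.names = FALSE); paths <- c(paths, fp)
  }
  fp <- file.path(dir, "wright_map.csv")
  utils::write.csv(x$targeting$bins, fp, row.names = FALSE)
  paths <- c(paths, fp)
  invisible(paths)
}
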