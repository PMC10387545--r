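#' Simulation design for truth-tagged polytomous Rasch data
#'
#' Describes a data-generating design under the partial credit model with
#' controllable violations of the measurement requirements: local item
#' dependency (LID), uniform/non-uniform differential item functioning (DIF),
#' multidimensionality, off-targeting and MCAR missingness. The generated
#' data carry a truth record so every downstream detector can be scored.
#'
#' @param n_persons number of persons.
#' @param items a [rasch_items()] object (the generating parameters).
#' @param theta_mean,theta_sd latent trait distribution (logits).
#' @param lid_links data.frame with columns `source`, `dependent`, `d`
#'   (dependence probability in `[0,1]`): with probability `d` the dependent
#'   item's response is replaced by the source item's response.
#' @param dif_specs data.frame with columns `item`, `factor`, `group`,
#'   `shift` (logits added to the item location for persons in `group`) and
#'   optionally `slope` (multiplier on theta for that group before response
#'   generation: non-uniform DIF; default 1).
#' @param dimension_map integer/character vector assigning each item to a
#'   dimension (default: all on one dimension).
#' @param dim_cor correlation between dimensions (bivariate+ normal theta).
#' @param missing_rate probability a cell is missing completely at random.
#' @param covariates data.frame of person covariates (factors used by
#'   `dif_specs`), or NULL.
#' @param seed integer seed; a fixed seed makes the output bit-identical.
#' @return A list of class `sim_design`.
#' @seealso [simulate_responses()], [whodas_like_data()]
#' @export
sim_design <- function(n_persons, items, theta_mean = 0, theta_sd = 1,
                       lid_links = NULL, dif_specs = NULL,
                       dimension_map = NULL, dim_cor = 1,
                       missing_rate = 0, covariates = NULL, seed = 1L) {
  if (!inherits(items, "rasch_items") || length(items) == 0)
    stop("invalid design: 'items' must be a non-empty rasch_items object")
  if (!is.numeric(n_persons) || n_persons < 1)
    stop("invalid design: n_persons must be positive")
  if (missing_rate < 0 || missing_rate > 1) stop("invalid design: missing_rate in [0,1]")
  if (abs(dim_cor) > 1) stop("invalid design: dim_cor in [-1,1]")
  if (!is.null(lid_links) && length(lid_links$d) &&
      (any(lid_links$d < 0) || any(lid_links$d > 1)))
    stop("invalid design: dependence probability d in [0,1]")
  if (is.null(dimension_map)) dimension_map <- rep(1L, length(items))
  if (length(dimension_map) != length(items))
    stop("invalid design: every item needs exactly one dimension")
  structure(list(n_persons = as.integer(n_persons), items = items,
                 theta_mean = theta_mean, theta_sd = theta_sd,
                 lid_links = lid_links, dif_specs = dif_specs,
                 dimension_map = dimension_map, dim_cor = dim_cor,
                 missing_rate = missing_rate, covariates = covariates,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Simulate responses from a design
#'
#' Draws each response from the partial credit category distribution at the
#' person's ability (on the item's dimension, location-shifted for the
#' person's DIF group), then applies LID links, then MCAR missingness.
#'
#' @param design a [sim_design()].
#' @return A [response_matrix()] with attribute `truth`: a list holding the
#'   person abilities (per dimension), generating item parameters and the
#'   injected violations.
#' @examples
#' it <- rasch_items(list(A = c(-1, 1), B = c(-0.5, 0.5)))
#' d <- sim_design(50, it, seed = 7)
#' x <- simulate_responses(d)
#' @export
simulate_responses <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  n <- design$n_persons
  items <- design$items
  I <- length(items)
  dims <- as.integer(factor(design$dimension_map))
  ndim <- max(dims)

  # latent trait: equicorrelated multivariate normal across dimensions
  if (ndim == 1L) {
    theta <- matrix(stats::rnorm(n, design$theta_mean, design$theta_sd), n, 1)
  } else {
    r <- design$dim_cor
    common <- stats::rnorm(n)
    theta <- sapply(seq_len(ndim), function(d)
      design$theta_mean + design$theta_sd *
        (sqrt(abs(r)) * sign(r)^(d > 1) * common + sqrt(1 - abs(r)) * stats::rnorm(n)))
    theta <- matrix(theta, n, ndim)
  }

  covs <- design$covariates
  X <- matrix(NA_integer_, n, I, dimnames = list(NULL, names(items)))
  for (i in seq_len(I)) {
    th <- theta[, dims[i]]
    shift <- numeric(n)
    if (!is.null(design$dif_specs)) {
      sp <- design$dif_specs[design$dif_specs$item == names(items)[i], , drop = FALSE]
      for (s in seq_len(nrow(sp))) {
        g <- covs[[sp$factor[s]]] == sp$group[s]
        shift[g] <- shift[g] + sp$shift[s]
        if (!is.null(sp$slope) && !is.na(sp$slope[s]) && sp$slope[s] != 1)
          th[g] <- th[g] * sp$slope[s]
      }
    }
    p <- category_probability(th - shift, items[[i]])
    u <- stats::runif(n)
    X[, i] <- max.col(u < t(apply(p, 1, cumsum)), ties.method = "first") - 1L
  }

  if (!is.null(design$lid_links)) {
    for (l in seq_len(NROW(design$lid_links))) {
      src <- design$lid_links$source[l]; dep <- design$lid_links$dependent[l]
      d <- design$lid_links$d[l]
      copy <- stats::runif(n) < d
      mi <- length(items[[dep]]$thresholds)
      X[copy, dep] <- pmin(X[copy, src], mi)
    }
  }

  if (design$missing_rate > 0) {
    drop_cells <- matrix(stats::runif(n * I) < design$missing_rate, n, I)
    # keep at least one observed response per person
    all_gone <- rowSums(!drop_cells) == 0L
    drop_cells[all_gone, 1L] <- FALSE
    X[drop_cells] <- NA_integer_
  }

  out <- response_matrix(X, item_max = item_maxima(items))
  attr(out, "truth") <- list(theta = theta, dimension_map = dims,
                             items = items, lid_links = design$lid_links,
                             dif_specs = design$dif_specs,
                             covariates = covs, seed = design$seed)
  out
}

#' Evenly spread item bank
#'
#' Convenience generator of `I` items with `m + 1` categories whose
#' locations are evenly spaced over `loc_range` and whose step offsets
#' share one centred pattern spanning `step_span` logits. Thresholds span
#' roughly `loc_range + step_span/2` either side of zero.
#'
#' @param I number of items.
#' @param m number of thresholds per item (categories - 1).
#' @param loc_range range of item locations (logits).
#' @param step_span spread of the within-item step offsets (logits).
#' @return a [rasch_items()] object.
#' @export
spread_items <- function(I = 11, m = 4, loc_range = c(-1.5, 1.5), step_span = 2.5) {
  locs <- seq(loc_range[1], loc_range[2], length.out = I)
  steps <- seq(-step_span / 2, step_span / 2, length.out = m)
  th <- lapply(seq_len(I), function(i) locs[i] + steps)
  names(th) <- paste0("I", seq_len(I))
  rasch_items(th, model_form = if (m == 1) "dichotomous" else "partial_credit")
}

#' Synthetic stroke-rehabilitation fixture (WHODAS-12-like structure)
#'
#' Generates a synthetic dataset emulating the structure of a WHODAS-12
#' administration to stroke inpatients: 188 persons, the 11 analysable items
#' (the work item is omitted because of structural missingness) scored 0-4,
#' grouped into six ICF domains, with within-domain local dependency, an
#' extra dependency between the household-responsibilities item and the
#' self-care domain, two correlated latent components (physical activities
#' vs. cognitive/social), a small education DIF on the cognitive/social
#' items, and person covariates: grouped age, gender, education (including
#' an illiterate category) and grouped days-since-stroke.
#'
#' This is synthetic data: it mimics the dependency/dimensionality structure
#' of such a sample, not any real patients.
#'
#' @param seed integer seed.
#' @param n number of persons (default 188).
#' @return list with elements `responses` (a [response_matrix()] carrying the
#'   simulation truth record), `covariates` (data.frame), `domains` (a priori
#'   testlet map, list of item-id vectors) and `components` (the two-component
#'   map).
#' @export
whodas_like_data <- function(seed = 1L, n = 188L) {
  ids <- c("D1.1", "D1.4", "D2.1", "D2.5", "D3.1", "D3.2",
           "D4.1", "D4.2", "D5.1", "D6.1", "D6.5")
  # item locations loosely spanning the +-1 logit band typical of this scale
  locs <- c(0.9, 0.35, -0.05, -0.45, -0.3, 0.0, 0.45, 0.8, -1.05, -0.35, -0.3)
  steps <- c(-1.8, -0.6, 0.6, 1.8)
  th <- lapply(locs, function(l) l + steps)
  names(th) <- ids
  items <- rasch_items(th)
  domains <- list(understanding = c("D1.1", "D1.4"), mobility = c("D2.1", "D2.5"),
                  self_care = c("D3.1", "D3.2"), getting_along = c("D4.1", "D4.2"),
                  life_activities = "D5.1", participation = c("D6.1", "D6.5"))
  cognitive <- c("D1.1", "D1.4", "D4.1", "D4.2", "D6.1", "D6.5")
  dim_map <- ifelse(ids %in% cognitive, "cognitive_social", "activities")
  components <- split(ids, dim_map)

  set.seed(seed + 1L)
  covariates <- data.frame(
    person = paste0("P", seq_len(n)),
    age_group = sample(c("<65", "65+"), n, replace = TRUE),
    gender = sample(c("male", "female"), n, replace = TRUE, prob = c(0.54, 0.46)),
    education = sample(c("illiterate", "primary", "secondary+"), n,
                       replace = TRUE, prob = c(0.2, 0.5, 0.3)),
    duration_group = sample(c("<=30d", ">30d"), n, replace = TRUE),
    stringsAsFactors = FALSE)

  lid <- data.frame(
    source = c("D1.1", "D2.1", "D3.1", "D4.1", "D6.1", "D3.2"),
    dependent = c("D1.4", "D2.5", "D3.2", "D4.2", "D6.5", "D5.1"),
    d = c(0.35, 0.35, 0.35, 0.45, 0.35, 0.3))
  dif <- data.frame(item = cognitive, factor = "education", group = "illiterate",
                    shift = 0.35, slope = 1)

  design <- sim_design(n, items, theta_mean = 0, theta_sd = 1.4,
                       lid_links = lid, dif_specs = dif,
                       dimension_map = dim_map, dim_cor = 0.65,
                       covariates = covariates, seed = seed)
  responses <- simulate_responses(design)
  rownames(responses) <- covariates$person
  list(responses = responses, covariates = covariates,
       domains = domains, components = components)
}
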