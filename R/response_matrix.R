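#' Person x item response matrix
#'
#' Validates and annotates a matrix of integer ordered-category responses.
#' Rows are persons, columns items; `NA` marks a missing response. The
#' per-item maximum category `item_max` defaults to the observed maximum.
#'
#' @param x integer matrix (or data.frame) of responses in `0..item_max`.
#' @param item_max integer vector of per-item maximum categories.
#' @param person_ids,item_ids optional identifiers; default to dimnames or
#'   `P1..Pn` / `I1..Ik`.
#' @param provenance one of `"raw"`, `"rescored"`, `"testletized"`, `"split"`.
#' @return An integer matrix of class `response_matrix` with attributes
#'   `item_max` and `provenance`.
#' @examples
#' rm <- response_matrix(matrix(c(0, 1, 2, 1), 2, 2), item_max = c(2, 2))
#' @export
response_matrix <- function(x, item_max = NULL, person_ids = NULL,
                            item_ids = NULL, provenance = "raw") {
  provenance <- match.arg(provenance, c("raw", "rescored", "testletized", "split"))
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (nrow(x) < 1L || ncol(x) < 1L) stop("response matrix must be non-empty")
  if (is.null(item_ids)) item_ids <- colnames(x)
  if (is.null(item_ids)) item_ids <- paste0("I", seq_len(ncol(x)))
  if (is.null(person_ids)) person_ids <- rownames(x)
  if (is.null(person_ids)) person_ids <- paste0("P", seq_len(nrow(x)))
  if (anyDuplicated(person_ids)) stop("duplicate person ids")
  if (anyDuplicated(item_ids)) stop("duplicate item ids")
  dimnames(x) <- list(person_ids, item_ids)
  obs_max <- suppressWarnings(apply(x, 2, max, na.rm = TRUE))
  if (is.null(item_max)) item_max <- obs_max
  item_max <- as.integer(item_max)
  if (length(item_max) == 1L) item_max <- rep(item_max, ncol(x))
  if (length(item_max) != ncol(x)) stop("'item_max' must have one entry per item")
  if (any(x < 0L, na.rm = TRUE)) stop("negative response categories found")
  bad <- which(obs_max > item_max)
  if (length(bad))
    stop("responses above item_max for item(s): ", paste(item_ids[bad], collapse = ", "))
  if (any(rowSums(!is.na(x)) == 0L))
    stop("person(s) with no observed responses: ",
         paste(person_ids[rowSums(!is.na(x)) == 0L], collapse = ", "))
  names(item_max) <- item_ids
  structure(x, item_max = item_max, provenance = provenance,
            class = c("response_matrix", "matrix", "array"))
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("Response matrix: ", nrow(x), " persons x ", ncol(x), " items (",
      attr(x, "provenance"), ")\n", sep = "")
  cat("item_max:", paste(attr(x, "item_max"), collapse = " "), "\n")
  cat("missing cells:", sum(is.na(x)), "\n")
  invisible(x)
}

item_max_of <- function(responses) {
  im <- attr(responses, "item_max")
  if (is.null(im)) im <- apply(responses, 2, max, na.rm = TRUE)
  as.integer(im)
}

# Items with fewer than 2 observed categories carry no information.
degenerate_items <- function(responses) {
  n_cat <- apply(responses, 2, function(col) length(unique(col[!is.na(col)])))
  which(n_cat < 2L)
}

# Subset persons/items, preserving attributes.
subset_responses <- function(responses, persons = NULL, items = NULL) {
  im <- item_max_of(responses)
  prov <- attr(responses, "provenance")
  x <- unclass(responses)
  if (is.null(persons)) persons <- seq_len(nrow(x))
  if (is.null(items)) items <- seq_len(ncol(x))
  if (is.character(items)) items <- match(items, colnames(x))
  x <- x[persons, items, drop = FALSE]
  keep <- rowSums(!is.na(x)) > 0L
  x <- x[keep, , drop = FALSE]
  response_matrix(x, item_max = im[items], provenance = prov)
}
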