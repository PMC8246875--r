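#' Ordinal response matrix
#'
#' Container for a subjects-by-items matrix of ordinal category codes, the
#' input to every fitting and selection function in the package. Codes are
#' 0-based internally: item `i` with `m_i + 1` ordered categories takes values
#' in `{0, ..., m_i}`; `NA` marks a missing cell.
#'
#' By default each item must use every category `0..m_i` at least once in the
#' data. Unobserved intermediate categories leave thresholds without data
#' support, so loading stops with a message pointing at
#' [recode_categories()]; no silent collapsing is done. Simulated data may
#' instead declare the intended category counts via `n_categories`, in which
#' case coverage is not enforced (a rare category can be absent by chance).
#'
#' @param x integer matrix (or data frame) of category codes, one row per
#'   subject, one column per item. `NA` = missing.
#' @param one_based if `TRUE`, codes in `x` start at 1 and are shifted down.
#' @param n_categories optional integer vector of category counts per item
#'   (`m_i + 1`). When supplied, the per-item maxima are taken from it rather
#'   than from the data and category coverage is not enforced.
#' @param subject_ids,item_ids optional labels; default to dimnames of `x` or
#'   `S1..SN` / `I1..IP`.
#' @return An object of class `"response_matrix"`: a list with elements
#'   `values` (integer matrix with `NA` for missing), `m` (per-item top
#'   category, so `m + 1` categories), `subject_ids`, `item_ids`.
#' @examples
#' x <- matrix(c(0L, 1L, 1L, 0L, 1L, 1L), nrow = 3)
#' r <- response_matrix(x)
#' r$m
#' @export
response_matrix <- function(x, one_based = FALSE, n_categories = NULL,
                            subject_ids = NULL, item_ids = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("`x` must be a matrix or data frame of category codes")
  storage <- suppressWarnings(as.numeric(x))
  if (anyNA(storage) && !all(is.na(x) == is.na(storage))) {
    bad <- which(is.na(storage) & !is.na(x))[1L]
    stop(sprintf("non-numeric response at row %d, column %d",
                 (bad - 1L) %% nrow(x) + 1L, (bad - 1L) %/% nrow(x) + 1L))
  }
  v <- matrix(storage, nrow(x), ncol(x))
  nonint <- which(!is.na(v) & v != round(v))
  if (length(nonint)) {
    stop(sprintf("non-integer response code at row %d, column %d",
                 (nonint[1L] - 1L) %% nrow(v) + 1L,
                 (nonint[1L] - 1L) %/% nrow(v) + 1L))
  }
  v <- matrix(as.integer(round(v)), nrow(v), ncol(v))
  if (one_based) v <- v - 1L
  N <- nrow(v); P <- ncol(v)
  if (N < 1L || P < 1L) stop("need at least one subject and one item")

  if (is.null(item_ids)) item_ids <- colnames(x)
  if (is.null(item_ids)) item_ids <- paste0("I", seq_len(P))
  if (is.null(subject_ids)) subject_ids <- rownames(x)
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(N))

  for (i in seq_len(P)) {
    obs <- v[, i][!is.na(v[, i])]
    if (!length(obs)) stop(sprintf("item %s has no observed responses", item_ids[i]))
    if (min(obs) < 0L)
      stop(sprintf("item %s has negative codes; is the file 1-based? (see `one_based`)",
                   item_ids[i]))
  }

  if (is.null(n_categories)) {
    m <- apply(v, 2L, function(col) max(col, na.rm = TRUE))
    for (i in seq_len(P)) {
      if (m[i] < 1L)
        stop(sprintf("item %s is constant (a single observed category); drop or recode it",
                     item_ids[i]))
      seen <- unique(v[, i][!is.na(v[, i])])
      missing_cat <- setdiff(0:m[i], seen)
      if (length(missing_cat)) {
        hint <- if (0L %in% missing_cat && min(seen) >= 1L)
          " (codes start at 1: see `one_based`)" else
          "; merge sparse categories with recode_categories() before fitting"
        stop(sprintf("item %s never uses category %s%s",
                     item_ids[i], paste(missing_cat, collapse = ", "), hint))
      }
    }
  } else {
    if (length(n_categories) == 1L) n_categories <- rep(n_categories, P)
    if (length(n_categories) != P) stop("`n_categories` must have one entry per item")
    m <- as.integer(n_categories) - 1L
    if (any(m < 1L)) stop("every item needs at least 2 categories")
    for (i in seq_len(P)) {
      if (max(v[, i], na.rm = TRUE) > m[i])
        stop(sprintf("item %s has codes above its declared top category %d",
                     item_ids[i], m[i]))
    }
  }

  dimnames(v) <- list(subject_ids, item_ids)
  structure(list(values = v, m = as.integer(m),
                 subject_ids = as.character(subject_ids),
                 item_ids = as.character(item_ids)),
            class = "response_matrix")
}

#' Coerce to a response matrix
#'
#' @param x a `response_matrix`, matrix or data frame.
#' @param ... passed to [response_matrix()] for matrix input.
#' @return a `response_matrix`.
#' @export
as_response_matrix <- function(x, ...) {
  if (inherits(x, "response_matrix")) return(x)
  response_matrix(x, ...)
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("Response matrix: %d subjects x %d items\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("Categories per item: %s\n",
              paste(unique(x$m + 1L), collapse = "/")))
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat(sprintf("Missing cells: %d\n", nmiss))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

# subset items, keeping declared category counts
subset_items <- function(resp, items) {
  idx <- resolve_items(resp, items)
  structure(list(values = resp$values[, idx, drop = FALSE],
                 m = resp$m[idx],
                 subject_ids = resp$subject_ids,
                 item_ids = resp$item_ids[idx]),
            class = "response_matrix")
}

# items given as integer indices or item id strings -> integer indices
resolve_items <- function(resp, items) {
  if (is.character(items)) {
    idx <- match(items, resp$item_ids)
    if (anyNA(idx)) stop("unknown item id(s): ",
                         paste(items[is.na(idx)], collapse = ", "))
    return(idx)
  }
  idx <- as.integer(items)
  if (any(idx < 1L | idx > ncol(resp$values)))
    stop("item index out of range 1..", ncol(resp$values))
  if (anyDuplicated(idx)) stop("duplicated item indices")
  idx
}

#' Merge or relabel response categories of one item
#'
#' Sparse categories (e.g. a rarely used top category) leave thresholds poorly
#' determined; the usual remedy before a Rasch fit is to merge them with a
#' neighbouring category. `merge_map` sends each old 0-based code to a new
#' one; the new codes must cover a contiguous range `0..m'` so that the
#' recoded item is again a valid ordinal item.
#'
#' @param responses a [response_matrix()] (or coercible).
#' @param item item id or index to recode.
#' @param merge_map named integer vector, names = old codes, values = new
#'   codes, e.g. `c("0" = 0, "1" = 1, "2" = 2, "3" = 2)` to merge the top two
#'   of four categories.
#' @return a new `response_matrix` with the item's category count reduced (or
#'   unchanged for an identity map). Response counts are conserved: every old
#'   response maps to exactly one new code.
#' @examples
#' x <- matrix(c(0L, 1L, 2L, 3L, 0L, 1L, 1L, 2L), ncol = 2)
#' r <- response_matrix(x)
#' r2 <- recode_categories(r, 1, c("0" = 0, "1" = 1, "2" = 2, "3" = 2))
#' r2$m
#' @export
recode_categories <- function(responses, item, merge_map) {
  resp <- as_response_matrix(responses)
  idx <- resolve_items(resp, item)
  if (length(idx) != 1L) stop("recode one item at a time")
  if (is.null(names(merge_map))) stop("`merge_map` must be named by old codes")
  old <- suppressWarnings(as.integer(names(merge_map)))
  new <- as.integer(merge_map)
  if (anyNA(old)) stop("`merge_map` names must be integer codes")
  if (anyDuplicated(old)) stop("duplicate old codes in `merge_map`")
  tgt <- sort(unique(new))
  if (!identical(tgt, seq.int(0L, max(new))))
    stop("new codes must form a contiguous 0-based range 0..",
         max(new), "; got {", paste(tgt, collapse = ","), "}")
  col <- resp$values[, idx]
  obs <- col[!is.na(col)]
  if (length(setdiff(unique(obs), old)))
    stop("`merge_map` does not cover observed code(s): ",
         paste(setdiff(unique(obs), old), collapse = ", "))
  lut <- new[match(col, old)]
  v <- resp$values
  v[, idx] <- lut
  m <- resp$m
  m[idx] <- max(new)
  if (m[idx] < 1L) stop("recoding collapsed item to a single category")
  structure(list(values = v, m = m, subject_ids = resp$subject_ids,
                 item_ids = resp$item_ids),
            class = "response_matrix")
}

#' Read a response matrix from CSV
#'
#' Expected layout: a header row of item ids and one row of integer codes per
#' subject; empty cells are missing. An optional subject-id column can be
#' named via `subject_col`.
#'
#' @param path CSV file path.
#' @param one_based set `TRUE` for files coded `1..m+1` (shifted to `0..m`).
#' @param subject_col optional name of a column holding subject ids.
#' @param n_categories optional declared category counts (see
#'   [response_matrix()]).
#' @return a [response_matrix()].
#' @export
read_responses <- function(path, one_based = FALSE, subject_col = NULL,
                           n_categories = NULL) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, fill = FALSE,
                    stringsAsFactors = FALSE),
    error = function(e) stop("could not parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  subject_ids <- NULL
  if (!is.null(subject_col)) {
    if (!subject_col %in% names(df))
      stop("no column named '", subject_col, "' in ", path)
    subject_ids <- as.character(df[[subject_col]])
    df[[subject_col]] <- NULL
  }
  response_matrix(df, one_based = one_based, n_categories = n_categories,
                  subject_ids = subject_ids)
}

#' Write a response matrix to CSV
#'
#' Inverse of [read_responses()]: header of item ids, one row per subject,
#' empty cells for missing responses.
#'
#' @param responses a [response_matrix()].
#' @param path output file path.
#' @param one_based write codes shifted up to start at 1.
#' @param subject_col if non-`NULL`, prepend a subject-id column of this name.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path, one_based = FALSE,
                            subject_col = NULL) {
  resp <- as_response_matrix(responses)
  v <- resp$values
  if (one_based) v <- v + 1L
  df <- as.data.frame(v)
  names(df) <- resp$item_ids
  if (!is.null(subject_col)) {
    df <- cbind(stats::setNames(data.frame(resp$subject_ids,
                                           stringsAsFactors = FALSE),
                                subject_col), df)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
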