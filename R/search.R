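#' One backward-elimination step
#'
#' Scores every itemset obtainable by dropping a single item from `s_in` with
#' [ipoq_ll()] and returns the best. Exact score ties are broken by removing
#' the lowest item index.
#'
#' @param responses a [response_matrix()] (or coercible).
#' @param s_in current included itemset (ids or indices), at least 2 items.
#' @param lambda_theta,lambda_in,lambda_out penalty weights (see
#'   [ipoq_ll()]).
#' @param warm optional `ipoq_ll` object for the parent split; its fitted
#'   parameters warm-start every candidate fit.
#' @return list with `score` (the winning [ipoq_ll()] object), `removed`
#'   (item id), and `candidates` (data frame of all evaluated moves).
#' @export
one_step_backward <- function(responses, s_in, lambda_theta = 0.05,
                              lambda_in = 50, lambda_out = 0.05,
                              warm = NULL) {
  resp <- as_response_matrix(responses)
  idx <- sort(resolve_items(resp, s_in))
  if (length(idx) < 2L)
    stop("backward elimination needs at least 2 included items")
  scores <- lapply(idx, function(drop_i)
    ipoq_ll(resp, setdiff(idx, drop_i), lambda_theta = lambda_theta,
            lambda_in = lambda_in, lambda_out = lambda_out, warm = warm))
  vals <- vapply(scores, function(s) s$ipoq_ll, numeric(1))
  best <- which.max(vals)  # first maximum = lowest removed index on ties
  list(score = scores[[best]], removed = resp$item_ids[idx[best]],
       candidates = data.frame(removed = resp$item_ids[idx],
                               ipoq_ll = vals, stringsAsFactors = FALSE))
}

#' One forward-selection step
#'
#' Scores every itemset obtainable by adding a single currently excluded item
#' to `s_in` and returns the best; exact ties are broken by adding the lowest
#' item index.
#'
#' @inheritParams one_step_backward
#' @return list with `score`, `added` (item id) and `candidates`.
#' @export
one_step_forward <- function(responses, s_in, lambda_theta = 0.05,
                             lambda_in = 50, lambda_out = 0.05,
                             warm = NULL) {
  resp <- as_response_matrix(responses)
  idx <- sort(resolve_items(resp, s_in))
  pool <- setdiff(seq_len(ncol(resp$values)), idx)
  if (!length(pool)) stop("forward selection needs a non-empty excluded set")
  scores <- lapply(pool, function(add_i)
    ipoq_ll(resp, sort(c(idx, add_i)), lambda_theta = lambda_theta,
            lambda_in = lambda_in, lambda_out = lambda_out, warm = warm))
  vals <- vapply(scores, function(s) s$ipoq_ll, numeric(1))
  best <- which.max(vals)
  list(score = scores[[best]], added = resp$item_ids[pool[best]],
       candidates = data.frame(added = resp$item_ids[pool],
                               ipoq_ll = vals, stringsAsFactors = FALSE))
}

#' Stepwise itemset selection by IPOQ-LL
#'
#' Starting from the full survey, alternates backward elimination with
#' forward selection: after each backward step a forward step is attempted,
#' and accepted when it strictly improves the best score recorded at the
#' resulting size (by more than `improve_tol`); an accepted forward step earns
#' one further forward attempt. This lets the search partially recover when
#' backward elimination discards an item too greedily. The best itemset seen
#' at every size is recorded, and the size whose best IPOQ-LL is the overall
#' maximum is the suggested instrument (the criterion's stopping rule); the
#' full per-size trajectory is returned so a fixed instrument length can also
#' be read off.
#'
#' The search is deterministic for given responses and penalties: candidate
#' fits are warm-started from the parent split but always polished to full
#' optimizer tolerance.
#'
#' @inheritParams one_step_backward
#' @param min_size smallest included-set size to explore (default 1).
#' @param improve_tol minimal strict improvement for accepting a forward
#'   step; guards against remove/re-add cycles driven by optimizer noise.
#' @param verbose log per-step progress (size and IPOQ-LL) to stderr.
#' @return object of class `"ipoq_search"`: list with
#'   * `best_by_size`: data frame (`size`, `ipoq_ll`, `iq_ll`, `oq_ll`,
#'     `items` as semicolon-joined ids),
#'   * `move_log`: data frame of moves (`step`, `action`, `item`, `size`,
#'     `ipoq_ll`),
#'   * `optimum`: list(`items`, `size`, `ipoq_ll`) at the global maximum,
#'   * `scores`: the best [ipoq_ll()] object per size.
#' @examples
#' \donttest{
#' sim <- sim_inhomogeneous(seed = 1)
#' tr <- ipoq_search(sim$responses)
#' tr$optimum$items     # the high-discrimination block
#' plot(tr)
#' }
#' @export
ipoq_search <- function(responses, lambda_theta = 0.05, lambda_in = 50,
                        lambda_out = 0.05, min_size = 1L,
                        improve_tol = 1e-6, verbose = FALSE) {
  resp <- as_response_matrix(responses)
  P <- ncol(resp$values)
  if (P < 2L) stop("need at least 2 items to search")
  if (min_size < 1L || min_size > P) stop("`min_size` must be in 1..P")

  best <- vector("list", P)      # per-size best ipoq_ll objects
  move_log <- list()
  visited <- new.env(parent = emptyenv())
  step <- 0L

  key <- function(idx) paste(idx, collapse = ",")
  record <- function(sc) {
    k <- length(sc$index_in)
    if (is.null(best[[k]]) || sc$ipoq_ll > best[[k]]$ipoq_ll)
      best[[k]] <<- sc
  }
  log_move <- function(action, item, sc) {
    step <<- step + 1L
    move_log[[step]] <<- data.frame(step = step, action = action,
                                    item = item,
                                    size = length(sc$index_in),
                                    ipoq_ll = sc$ipoq_ll,
                                    stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("step %3d: %s %-6s -> size %2d, IPOQ-LL %.3f",
                      step, action, item, length(sc$index_in), sc$ipoq_ll))
  }

  current <- ipoq_ll(resp, seq_len(P), lambda_theta = lambda_theta,
                     lambda_in = lambda_in, lambda_out = lambda_out)
  record(current)
  assign(key(current$index_in), TRUE, envir = visited)
  if (verbose)
    message(sprintf("full set: size %2d, IPOQ-LL %.3f", P, current$ipoq_ll))

  guard <- 0L
  while (length(current$index_in) > min_size) {
    guard <- guard + 1L
    if (guard > 20L * P) {
      warning("stepwise search exceeded its move budget; returning trajectory so far")
      break
    }
    bk <- one_step_backward(resp, current$index_in, lambda_theta = lambda_theta,
                            lambda_in = lambda_in, lambda_out = lambda_out,
                            warm = current)
    record(bk$score)
    log_move("remove", bk$removed, bk$score)
    current <- bk$score
    assign(key(current$index_in), TRUE, envir = visited)

    # forward recovery: up to two strictly improving additions
    for (attempt in 1:2) {
      if (!length(current$index_out)) break
      fw <- one_step_forward(resp, current$index_in,
                             lambda_theta = lambda_theta,
                             lambda_in = lambda_in, lambda_out = lambda_out,
                             warm = current)
      sz <- length(fw$score$index_in)
      prev_best <- if (is.null(best[[sz]])) -Inf else best[[sz]]$ipoq_ll
      if (fw$score$ipoq_ll > prev_best + improve_tol &&
          !exists(key(fw$score$index_in), envir = visited)) {
        record(fw$score)
        log_move("add", fw$added, fw$score)
        current <- fw$score
        assign(key(current$index_in), TRUE, envir = visited)
      } else break
    }
  }

  sizes <- which(!vapply(best, is.null, logical(1)))
  tab <- data.frame(
    size = sizes,
    ipoq_ll = vapply(sizes, function(k) best[[k]]$ipoq_ll, numeric(1)),
    iq_ll = vapply(sizes, function(k) best[[k]]$iq_ll, numeric(1)),
    oq_ll = vapply(sizes, function(k) best[[k]]$oq_ll, numeric(1)),
    items = vapply(sizes, function(k) paste(best[[k]]$s_in, collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$size), , drop = FALSE]
  opt_size <- tab$size[which.max(tab$ipoq_ll)]
  structure(list(
    best_by_size = tab,
    move_log = do.call(rbind, move_log),
    optimum = list(items = best[[opt_size]]$s_in, size = opt_size,
                   ipoq_ll = best[[opt_size]]$ipoq_ll),
    scores = stats::setNames(best[sizes], sizes),
    penalties = list(lambda_theta = lambda_theta, lambda_in = lambda_in,
                     lambda_out = lambda_out),
    min_size = min_size
  ), class = "ipoq_search")
}

#' @export
print.ipoq_search <- function(x, ...) {
  cat(sprintf("Stepwise IPOQ-LL search over sizes %d..%d\n",
              min(x$best_by_size$size), max(x$best_by_size$size)))
  cat(sprintf("Maximum IPOQ-LL %.3f at %d included items:\n  %s\n",
              x$optimum$ipoq_ll, x$optimum$size,
              paste(x$optimum$items, collapse = ", ")))
  invisible(x)
}

#' @export
summary.ipoq_search <- function(object, ...) {
  cat("Best itemset per size:\n")
  print(object$best_by_size, row.names = FALSE)
  invisible(object$best_by_size)
}

#' Trajectory plot of a stepwise search
#'
#' Best IPOQ-LL per included-set size, with the global maximum marked — the
#' usual way to read off where the criterion peaks and how flat the
#' neighbourhood is.
#'
#' @param x an [ipoq_search()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ipoq_search <- function(x, ...) {
  tab <- x$best_by_size
  graphics::plot(tab$size, tab$ipoq_ll, type = "b", pch = 16,
                 xlab = "included items", ylab = "IPOQ-LL", ...)
  graphics::abline(v = x$optimum$size, lty = 3)
  invisible(x)
}

#' Best recorded itemset of a given size
#'
#' Reads the per-size bookkeeping of a search trajectory, e.g. to pin the
#' instrument to the length of an existing questionnaire for a like-for-like
#' comparison.
#'
#' @param trajectory an [ipoq_search()] object.
#' @param size included-set size; must have been visited by the search.
#' @return character vector of item ids.
#' @export
best_itemset <- function(trajectory, size) {
  stopifnot(inherits(trajectory, "ipoq_search"))
  row <- trajectory$best_by_size[trajectory$best_by_size$size == size, ]
  if (!nrow(row)) stop("size ", size, " was not visited by the search")
  strsplit(row$items, ";", fixed = TRUE)[[1]]
}

#' Exhaustive IPOQ-LL search
#'
#' Scores every non-empty included itemset (or every itemset of a fixed
#' `size`) and returns the maximizer. Cost grows as `2^P - 1`, so the number
#' of items is capped at 20; beyond that use [ipoq_search()].
#'
#' @inheritParams one_step_backward
#' @param size optional fixed included-set size.
#' @return list with `items` (ids), `ipoq_ll`, and `scores` (data frame over
#'   all evaluated itemsets).
#' @export
ipoq_exhaustive <- function(responses, size = NULL, lambda_theta = 0.05,
                            lambda_in = 50, lambda_out = 0.05) {
  resp <- as_response_matrix(responses)
  P <- ncol(resp$values)
  if (P > 20L)
    stop("exhaustive search over ", P,
         " items is infeasible (2^P - 1 subsets); use ipoq_search()")
  sizes <- if (is.null(size)) seq_len(P) else size
  if (any(sizes < 1L | sizes > P)) stop("`size` must be in 1..P")
  subsets <- unlist(lapply(sizes, function(k)
    utils::combn(P, k, simplify = FALSE)), recursive = FALSE)
  vals <- vapply(subsets, function(s)
    ipoq_ll(resp, s, lambda_theta = lambda_theta, lambda_in = lambda_in,
            lambda_out = lambda_out)$ipoq_ll, numeric(1))
  best <- which.max(vals)
  list(items = resp$item_ids[subsets[[best]]], ipoq_ll = vals[best],
       scores = data.frame(
         items = vapply(subsets, function(s)
           paste(resp$item_ids[s], collapse = ";"), character(1)),
         size = lengths(subsets), ipoq_ll = vals,
         stringsAsFactors = FALSE))
}
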