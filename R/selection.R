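# Exhaustive item-combination search per subscale.
#
# Every combination of k items from a subscale's pool (k = 1..|pool|) is
# scored by cross-validated model-zoo selection; the best combination per k
# forms an improvement curve over item counts, from which the working number
# of items is chosen at a pronounced elbow or, failing that, as the fewest
# items whose metric exceeds 0.8.

#' All item combinations of a given size
#'
#' @param pool integer item ids.
#' @param k combination size, `1 <= k <= length(pool)`.
#' @return list of sorted id vectors in lexicographic order.
#' @export
enumerate_combos <- function(pool, k) {
  pool <- sort(as.integer(pool))
  if (length(k) != 1 || k < 1 || k > length(pool)) {
    stop("k must lie in [1, |pool|]")
  }
  m <- utils::combn(pool, k)
  lapply(seq_len(ncol(m)), function(i) m[, i])
}

#' Define a per-subscale prediction task
#'
#' The target is derived from the scoring module on the same responses: for
#' `"classification"` the binary presence of the constitution (GTC via its
#' compound rule; tendency counts as absent), for `"score"` the subscale's
#' converted score. Predictors are the raw item responses of the subscale's
#' member pool — the search sees items, never derived scores.
#'
#' @param responses a `ccmq_responses` matrix.
#' @param spec a [ccmq_spec].
#' @param subscale subscale name.
#' @param target `"classification"` or `"score"`.
#' @param criteria classification boundaries, see [bc_criteria].
#' @param pool optional candidate pool (defaults to the subscale's members).
#' @return an object of class `ccmq_task`.
#' @export
prediction_task <- function(responses, spec, subscale,
                            target = c("classification", "score"),
                            criteria = bc_criteria(), pool = NULL) {
  target <- match.arg(target)
  if (!subscale %in% names(spec$subscales)) {
    stop("unknown subscale: ", subscale)
  }
  pool <- sort(as.integer(pool %||% spec$subscales[[subscale]]))
  if (!all(pool %in% spec$items)) stop("pool contains unknown item ids")
  scores <- score_all(responses, spec)
  if (target == "classification") {
    cls <- classify_bc(scores, criteria)
    y <- as.integer(cls[[subscale]] == "present")
    if (length(unique(y)) < 2) {
      stop(sprintf("subscale %s: classification target has a single class",
                   subscale))
    }
  } else {
    y <- scores[[subscale]]
  }
  structure(list(subscale = subscale,
                 kind = if (target == "classification") "classification"
                        else "regression",
                 pool = pool,
                 X = unclass(responses)[, as.character(pool), drop = FALSE],
                 y = y, n = nrow(responses)),
            class = "ccmq_task")
}

# Per-fold out-of-fold metric for one family on the given columns.
cv_family_metric <- function(task, cols, family, folds, seed) {
  k <- max(folds)
  vapply(seq_len(k), function(f) {
    tr <- folds != f; te <- !tr
    pred <- fit_predict(family, task$X[tr, cols, drop = FALSE], task$y[tr],
                        task$X[te, cols, drop = FALSE], task = task$kind,
                        seed = derive_seed(seed, f))
    if (task$kind == "classification") auc(task$y[te], pred)
    else r_squared(task$y[te], pred)
  }, 0)
}

#' Cross-validated zoo evaluation of one item combination
#'
#' Each active family is scored by k-fold out-of-fold AUC (classification,
#' stratified folds) or R^2 (regression). The returned metric is the mean
#' out-of-fold metric of the winning family, where families within one
#' standard error of the best are resolved toward the lowest complexity rank
#' (performance-versus-complexity balance).
#'
#' @param task a [prediction_task].
#' @param combo item ids (subset of the task pool).
#' @param zoo registry from [model_zoo]; defaults to the task's default zoo.
#' @param cv_folds number of folds (default 5).
#' @param seed master seed; folds and per-fold learner seeds derive from it,
#'   so the same seed gives identical results.
#' @return list with `metric`, `family`, and per-family `details`.
#' @export
evaluate_combo <- function(task, combo, zoo = NULL, cv_folds = 5L, seed = 1L) {
  if (!all(combo %in% task$pool)) stop("combo contains items outside the pool")
  zoo <- zoo %||% model_zoo(task$kind)
  cols <- match(as.integer(combo), task$pool)
  folds <- make_folds(task$y, cv_folds,
                      stratify = task$kind == "classification",
                      seed = derive_seed(seed, 0))
  if (task$kind == "classification") {
    per_fold_pos <- tabulate(folds[task$y == 1L], nbins = cv_folds)
    per_fold_neg <- tabulate(folds[task$y == 0L], nbins = cv_folds)
    if (any(per_fold_pos == 0) || any(per_fold_neg == 0)) {
      stop("single-class fold: too few members of one class for ",
           cv_folds, "-fold stratification")
    }
  }
  fold_metrics <- lapply(zoo$family, function(fam) {
    cv_family_metric(task, cols, fam, folds, seed)
  })
  means <- vapply(fold_metrics, mean, 0)
  ses <- vapply(fold_metrics, function(m) stats::sd(m) / sqrt(length(m)), 0)
  best <- which.max(means)
  eligible <- which(means >= means[best] - ses[best])
  pick <- eligible[which.min(zoo$complexity[eligible])]
  list(metric = means[pick], family = zoo$family[pick],
       details = data.frame(family = zoo$family, mean = means, se = ses,
                            complexity = zoo$complexity))
}

#' Best item combination for every combination size
#'
#' Exhaustively evaluates all `C(|pool|, k)` combinations for each k and
#' keeps the argmax by cross-validated metric; ties resolve to the
#' lexicographically smallest combination (the enumeration order). All
#' combinations share one fold assignment derived from `seed`, so metrics
#' are comparable across combinations and the search is reproducible.
#'
#' @param task a [prediction_task].
#' @param zoo registry from [model_zoo].
#' @param cv_folds folds (default 5). @param seed master seed.
#' @param max_k largest combination size to search (default `|pool|`).
#' @return object of class `ccmq_selection`: data frame `table` with one row
#'   per k (`k`, `combo`, `family`, `metric`, `delta`) plus `combos` (list of
#'   id vectors) and the search settings.
#' @export
best_per_k <- function(task, zoo = NULL, cv_folds = 5L, seed = 1L,
                       max_k = NULL) {
  zoo <- zoo %||% model_zoo(task$kind)
  max_k <- min(max_k %||% length(task$pool), length(task$pool))
  rows <- vector("list", max_k)
  best_combos <- vector("list", max_k)
  for (k in seq_len(max_k)) {
    combos <- enumerate_combos(task$pool, k)
    best_metric <- -Inf; best_combo <- NULL; best_family <- NA_character_
    for (cb in combos) {
      ev <- evaluate_combo(task, cb, zoo, cv_folds, seed)
      if (ev$metric > best_metric) {  # strict: first (lexicographic) wins ties
        best_metric <- ev$metric; best_combo <- cb; best_family <- ev$family
      }
    }
    rows[[k]] <- data.frame(k = k,
                            combo = paste(best_combo, collapse = ","),
                            family = best_family, metric = best_metric)
    best_combos[[k]] <- best_combo
  }
  tab <- do.call(rbind, rows)
  tab$delta <- c(NA, diff(tab$metric))
  structure(list(table = tab, combos = best_combos, subscale = task$subscale,
                 kind = task$kind, cv_folds = cv_folds, seed = seed),
            class = "ccmq_selection")
}

#' @export
print.ccmq_selection <- function(x, ...) {
  cat(sprintf("Best combinations per item count - %s (%s target)\n",
              x$subscale, x$kind))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Choose the number of items from an improvement curve
#'
#' Improvement deltas are `metric(k) - metric(k - 1)`. If the largest delta
#' is pronounced — at least `elbow_ratio` times the runner-up delta (and
#' positive) — its k is the elbow and is selected. Otherwise the smallest k
#' whose metric exceeds `threshold` is chosen; if none does, all items are
#' kept with a warning.
#'
#' @param selection a `ccmq_selection` from [best_per_k] (or its `table`).
#' @param threshold metric threshold for the fallback rule (default 0.8).
#' @param elbow_ratio dominance factor a pronounced elbow requires
#'   (default 2).
#' @return list with `selected_k`, `rule` (`"elbow"` or `"threshold"`),
#'   `combo` and `family` when available.
#' @export
select_num_items <- function(selection, threshold = 0.8, elbow_ratio = 2) {
  tab <- if (inherits(selection, "ccmq_selection")) selection$table
         else selection
  if (is.null(tab) || nrow(tab) == 0) stop("empty selection table")
  deltas <- tab$delta[-1]
  rule <- "threshold"
  selected_k <- NA_integer_
  if (length(deltas) >= 2) {
    ord <- order(deltas, decreasing = TRUE)
    top <- deltas[ord[1]]; second <- deltas[ord[2]]
    if (top > 0 && (second <= 0 || top >= elbow_ratio * second)) {
      rule <- "elbow"
      selected_k <- tab$k[which.max(tab$delta[-1]) + 1]
    }
  }
  if (rule == "threshold") {
    over <- which(tab$metric > threshold)
    if (length(over)) {
      selected_k <- tab$k[min(over)]
    } else {
      selected_k <- tab$k[nrow(tab)]
      warning(sprintf("no combination exceeds metric %.2f; keeping all %d items",
                      threshold, selected_k))
    }
  }
  row <- which(tab$k == selected_k)
  out <- list(selected_k = selected_k, rule = rule,
              metric = tab$metric[row], family = tab$family[row])
  if (inherits(selection, "ccmq_selection")) {
    out$combo <- selection$combos[[row]]
  }
  out
}

#' Held-out performance report for a chosen combination
#'
#' Fits the chosen family on a training split and reports every applicable
#' statistic on the held-out split: AUC, accuracy and F1 (classification,
#' scores thresholded at 0.5) or R^2, RMSE and MAPE (regression).
#'
#' @param task a [prediction_task].
#' @param combo item ids to use as predictors.
#' @param family zoo family identifier.
#' @param seed split/learner seed.
#' @param holdout_frac held-out fraction (default 0.25; split is stratified
#'   for classification).
#' @return data frame with `task`, `n_test` and the metric columns.
#' @export
holdout_report <- function(task, combo, family, seed = 1L,
                           holdout_frac = 0.25) {
  if (!all(combo %in% task$pool)) stop("combo contains items outside the pool")
  cols <- match(as.integer(combo), task$pool)
  set.seed(derive_seed(seed, 77))
  n <- task$n
  if (task$kind == "classification") {
    te <- logical(n)
    for (cls in 0:1) {
      idx <- which(task$y == cls)
      te[sample(idx, max(1, round(length(idx) * holdout_frac)))] <- TRUE
    }
  } else {
    te <- logical(n)
    te[sample.int(n, max(2, round(n * holdout_frac)))] <- TRUE
  }
  if (sum(te) < 2 || sum(!te) < 2) stop("degenerate holdout split")
  pred <- fit_predict(family, task$X[!te, cols, drop = FALSE], task$y[!te],
                      task$X[te, cols, drop = FALSE], task = task$kind,
                      seed = derive_seed(seed, 78))
  y_te <- task$y[te]
  if (task$kind == "classification") {
    if (length(unique(y_te)) < 2) stop("degenerate holdout split")
    data.frame(task = "classification", n_test = sum(te),
               auc = auc(y_te, pred),
               accuracy = accuracy(y_te, as.integer(pred > 0.5)),
               f1 = f1_score(y_te, as.integer(pred > 0.5)))
  } else {
    data.frame(task = "regression", n_test = sum(te),
               r2 = r_squared(y_te, pred), rmse = rmse(y_te, pred),
               mape = as.numeric(mape(y_te, pred)))
  }
}
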