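# Synthetic prediction task over explicit predictors and target.
make_task <- function(X, y, kind) {
  colnames(X) <- seq_len(ncol(X))
  structure(list(subscale = "SYN", kind = kind,
                 pool = seq_len(ncol(X)), X = X, y = y, n = nrow(X)),
            class = "ccmq_task")
}

test_that("combination enumeration is exhaustive and lexicographic", {
  combos <- enumerate_combos(1:8, 2)
  expect_length(combos, 28)
  expect_equal(combos[[1]], c(1, 2))
  expect_equal(combos[[28]], c(7, 8))
  expect_length(enumerate_combos(1:8, 8), 1)
  expect_error(enumerate_combos(1:8, 0), "\\[1, \\|pool\\|\\]")
  expect_error(enumerate_combos(1:8, 9), "\\[1, \\|pool\\|\\]")
  # unsorted pool input still yields sorted combinations
  expect_equal(enumerate_combos(c(5, 3, 9), 2),
               list(c(3, 5), c(3, 9), c(5, 9)))
})

test_that("prediction tasks derive targets from the scoring module", {
  sim <- simulate_responses(sim_config(n = 400, seed = 6))
  spec <- sim_responses_spec <- load_spec()
  task <- prediction_task(sim$responses, spec, "QDC", "classification")
  expect_equal(task$pool, sort(spec$subscales$QDC))
  expect_setequal(unique(task$y), 0:1)
  scores <- score_all(sim$responses, spec)
  cls <- classify_bc(scores)
  expect_equal(task$y, as.integer(cls$QDC == "present"))  # tendency -> 0
  treg <- prediction_task(sim$responses, spec, "QDC", "score")
  expect_equal(treg$y, scores$QDC)
  expect_error(prediction_task(sim$responses, spec, "XXX"), "unknown subscale")
})

test_that("cross-validated evaluation is reproducible and honest on nulls", {
  set.seed(77)
  n <- 2000
  X <- matrix(sample(1:5, n * 4, TRUE), ncol = 4)
  y <- rbinom(n, 1, 0.3)  # labels independent of all items
  task <- make_task(X, y, "classification")
  ev1 <- evaluate_combo(task, 1:2, seed = 5)
  ev2 <- evaluate_combo(task, 1:2, seed = 5)
  expect_identical(ev1$metric, ev2$metric)
  expect_identical(ev1$family, ev2$family)
  expect_gt(ev1$metric, 0.45); expect_lt(ev1$metric, 0.55)  # null band

  # a perfectly informative predictor dominates a regression target
  yreg <- as.numeric(X[, 3])
  treg <- make_task(X, yreg, "regression")
  expect_gte(evaluate_combo(treg, 3, seed = 1)$metric, 0.99)
  expect_error(evaluate_combo(treg, 9, seed = 1), "outside the pool")
  # single-class targets cannot be stratified
  task_bad <- make_task(X[1:50, ], c(1, rep(0, 49)), "classification")
  expect_error(evaluate_combo(task_bad, 1:2, seed = 1), "single-class fold")
})

test_that("one-standard-error rule prefers the simpler family on ties", {
  set.seed(3)
  n <- 1200
  X <- matrix(sample(1:5, n * 2, TRUE), ncol = 2)
  y <- rbinom(n, 1, plogis(X[, 1] - 3))  # both families near-equivalent
  task <- make_task(X, y, "classification")
  ev <- evaluate_combo(task, 1:2, seed = 2)
  within_1se <- with(ev$details,
                     mean[family == ev$family] >= max(mean) - se[which.max(mean)])
  expect_true(within_1se)
  simpler <- with(ev$details, complexity[family == ev$family] <=
                    complexity[which.max(mean)])
  expect_true(simpler)
})

test_that("best_per_k searches exhaustively and tracks improvements", {
  set.seed(21)
  n <- 900
  X <- matrix(sample(1:5, n * 3, TRUE), ncol = 3)
  y <- X[, 2] + 0.8 * X[, 3] + rnorm(n, sd = 0.7)
  task <- make_task(X, y, "regression")
  sel <- best_per_k(task, seed = 4)
  expect_equal(sel$table$k, 1:3)
  expect_equal(sel$combos[[1]], 2)          # strongest single predictor
  expect_setequal(sel$combos[[2]], c(2, 3)) # planted pair
  expect_true(is.na(sel$table$delta[1]))
  expect_equal(sel$table$delta[-1], diff(sel$table$metric))
  # nested information: the full pool is never much worse than any k
  expect_gte(sel$table$metric[3], max(sel$table$metric) - 0.02)
  # two-item pool yields exactly rows k = 1, 2
  t2 <- make_task(X[, 1:2], y, "regression")
  expect_equal(best_per_k(t2, seed = 4)$table$k, 1:2)
})

test_that("item-count selection applies the elbow and threshold rules", {
  tab <- data.frame(k = 1:4, metric = c(0.70, 0.88, 0.89, 0.895),
                    family = "nb")
  tab$delta <- c(NA, diff(tab$metric))
  out <- select_num_items(tab, threshold = 0.8, elbow_ratio = 2)
  expect_equal(out$selected_k, 2)   # 0.18 dominates the runner-up 0.01
  expect_equal(out$rule, "elbow")

  tab <- data.frame(k = 1:4, metric = c(0.75, 0.78, 0.82, 0.84),
                    family = "nb")
  tab$delta <- c(NA, diff(tab$metric))
  out <- select_num_items(tab)
  expect_equal(out$selected_k, 3)   # smooth curve: first metric above 0.8
  expect_equal(out$rule, "threshold")

  tab <- data.frame(k = 1, metric = 0.85, family = "nb", delta = NA)
  out <- select_num_items(tab)
  expect_equal(out$selected_k, 1)   # single-item pool
  expect_equal(out$rule, "threshold")

  tab <- data.frame(k = 1:3, metric = c(0.55, 0.58, 0.60), family = "nb")
  tab$delta <- c(NA, diff(tab$metric))
  expect_warning(out <- select_num_items(tab), "keeping all")
  expect_equal(out$selected_k, 3)

  expect_error(select_num_items(tab[0, ]), "empty")
})

test_that("holdout reports cover the metric suite deterministically", {
  set.seed(8)
  n <- 1200
  X <- matrix(sample(1:5, n * 3, TRUE), ncol = 3)
  y <- as.integer(X[, 1] >= 4)
  task <- make_task(X, y, "classification")
  r1 <- holdout_report(task, 1, "logistic", seed = 9)
  expect_equal(r1$auc, 1)  # perfectly informative predictor
  expect_identical(r1, holdout_report(task, 1, "logistic", seed = 9))
  expect_named(r1, c("task", "n_test", "auc", "accuracy", "f1"))

  yreg <- as.numeric(X[, 2])
  treg <- make_task(X, yreg, "regression")
  r2 <- holdout_report(treg, 2, "linear", seed = 9)
  expect_gte(r2$r2, 0.99)
  expect_named(r2, c("task", "n_test", "r2", "rmse", "mape"))
  # permuted labels stay in the null band
  yperm <- sample(y)
  rnull <- holdout_report(make_task(X, yperm, "classification"),
                          1, "logistic", seed = 10)
  expect_gt(rnull$auc, 0.42); expect_lt(rnull$auc, 0.58)
})
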