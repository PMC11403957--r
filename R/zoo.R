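# Candidate learner registry for the combination search.
#
# A deterministic stand-in for automated pipeline search: a small, ordered
# zoo of learner families is cross-validated for every item combination and
# the winner is chosen by out-of-fold AUC (classification) or R^2
# (regression), with a one-standard-error simplicity rule — among families
# within one SE of the best, the lowest complexity rank wins. The default
# families (Gaussian naive Bayes and logistic regression for
# classification; linear and quadratic-expansion linear for regression)
# pair a low- and a higher-capacity model at well under a millisecond per
# fit, which keeps the exhaustive search over all item subsets tractable on
# one core; k-nearest-neighbours, random forest (ranger) and a small
# multilayer perceptron (nnet) are registered but off by default.
#
# Gaussian naive Bayes and k-NN regression are implemented vectorized here:
# at ~50k cross-validation fits per pipeline run the per-fit overhead of the
# generic implementations dominates the entire analysis, and both are
# cross-checked against independent reference implementations in the test
# suite.

#' Learner-family registry
#'
#' @param task `"classification"` or `"regression"`.
#' @param families optional character subset to activate, in the registry's
#'   identifiers; defaults to the fast core families.
#' @return data frame with `family` and `complexity` (rank, lower = simpler).
#' @export
model_zoo <- function(task = c("classification", "regression"),
                      families = NULL) {
  task <- match.arg(task)
  reg <- if (task == "classification") {
    data.frame(family = c("nb", "logistic", "knn", "rf", "mlp"),
               complexity = 1:5)
  } else {
    data.frame(family = c("linear", "poly2", "knn", "rf", "mlp"),
               complexity = 1:5)
  }
  families <- families %||% reg$family[1:2]
  unknown <- setdiff(families, reg$family)
  if (length(unknown)) stop("unknown model families: ",
                            paste(unknown, collapse = ", "))
  out <- reg[reg$family %in% families, , drop = FALSE]
  attr(out, "task") <- task
  out
}

# Gaussian naive Bayes, vectorized over the test set.
nb_fit_predict <- function(Xtr, ytr, Xte) {
  lp <- matrix(0, nrow(Xte), 2)
  for (c in 0:1) {
    Z <- Xtr[ytr == c, , drop = FALSE]
    mu <- colMeans(Z)
    v <- pmax(apply(Z, 2, stats::var), 1e-9)
    lp[, c + 1] <- log(nrow(Z) / nrow(Xtr)) +
      colSums(stats::dnorm(t(Xte), mu, sqrt(v), log = TRUE))
  }
  1 / (1 + exp(lp[, 1] - lp[, 2]))  # P(y = 1 | x)
}

# k-NN prediction: mean response over the neighbourhood of the k nearest
# training points, ties at the boundary distance included (deterministic,
# no index-order dependence). Likert predictors collapse to few distinct
# cells, which is exploited by aggregating training rows per cell; the
# boundary-tie rule makes the collapsed and direct paths exactly equivalent.
knn_reg_predict <- function(Xtr, ytr, Xte, k) {
  k <- min(k, nrow(Xtr))
  p <- ncol(Xtr)
  small_int <- p <= 15 && all(Xtr == round(Xtr)) && all(Xtr >= 0) &&
    max(Xtr) <= 9 && all(Xte == round(Xte)) && all(Xte >= 0) && max(Xte) <= 9
  if (small_int) {
    pow <- 10^(seq_len(p) - 1)
    key_tr <- drop(Xtr %*% pow)
    key_te <- drop(Xte %*% pow)
    ucells <- !duplicated(key_tr)
    U <- Xtr[ucells, , drop = FALSE]
    ukey <- key_tr[ucells]
    grp <- match(key_tr, ukey)
    w <- tabulate(grp, nbins = length(ukey))
    s <- drop(rowsum(ytr, grp, reorder = FALSE))
    vkey <- unique(key_te)
    V <- Xte[match(vkey, key_te), , drop = FALSE]
    d2 <- outer(rowSums(V^2), rep(1, nrow(U))) +
      outer(rep(1, nrow(V)), rowSums(U^2)) - 2 * tcrossprod(V, U)
    storage.mode(d2) <- "integer"  # squared Likert distances are integers
    pred_cell <- vapply(seq_len(nrow(V)), function(r) {
      dr <- d2[r, ]
      o <- order(dr, method = "radix")
      m <- sum(cumsum(w[o]) < k) + 1L
      sel <- dr <= dr[o[m]]
      sum(s[sel]) / sum(w[sel])
    }, 0)
    pred_cell[match(key_te, vkey)]
  } else {
    d2 <- outer(rowSums(Xte^2), rep(1, nrow(Xtr))) +
      outer(rep(1, nrow(Xte)), rowSums(Xtr^2)) - 2 * tcrossprod(Xte, Xtr)
    apply(d2, 1, function(r) {
      thr <- sort.int(r, partial = k)[k]
      mean(ytr[r <= thr])
    })
  }
}

quad_expand <- function(X) {
  p <- ncol(X)
  out <- cbind(X, X^2)
  if (p > 1) {
    for (i in seq_len(p - 1)) out <- cbind(out, X[, i] * X[, (i + 1):p])
  }
  out
}

#' Fit one learner family and predict continuous scores
#'
#' Classification families return the positive-class probability (the score
#' ranked by AUC); regression families the predicted response.
#'
#' @param family registry identifier, see [model_zoo].
#' @param Xtr,ytr training predictors/response. @param Xte test predictors.
#' @param task `"classification"` or `"regression"`.
#' @param seed integer controlling any internal randomness (k-NN tie
#'   breaking, forest bootstraps, perceptron initialization).
#' @param knn_k neighbourhood size (default 25).
#' @return numeric score vector over the rows of `Xte`.
#' @export
fit_predict <- function(family, Xtr, ytr, Xte,
                        task = c("classification", "regression"),
                        seed = 1L, knn_k = 25L) {
  task <- match.arg(task)
  Xtr <- as.matrix(Xtr); Xte <- as.matrix(Xte)
  if (task == "classification") {
    switch(family,
      nb = nb_fit_predict(Xtr, ytr, Xte),
      logistic = {
        fit <- suppressWarnings(
          stats::glm.fit(cbind(1, Xtr), ytr,
                         family = stats::binomial()))
        drop(stats::plogis(cbind(1, Xte) %*% fit$coefficients))
      },
      # positive-class fraction among the k nearest neighbours; Likert
      # predictors produce distance-tie groups far beyond what class::knn
      # tolerates, so the same vectorized neighbour routine as the
      # regression family is used (deterministic index-order ties)
      knn = knn_reg_predict(Xtr, as.numeric(ytr), Xte, knn_k),
      rf = {
        fit <- ranger::ranger(y = factor(ytr, levels = 0:1),
                              x = as.data.frame(Xtr), num.trees = 100,
                              probability = TRUE, num.threads = 1,
                              seed = seed)
        predict(fit, as.data.frame(Xte), num.threads = 1)$predictions[, "1"]
      },
      mlp = {
        set.seed(seed)
        fit <- nnet::nnet(Xtr, ytr, size = 3, decay = 0.01, maxit = 200,
                          trace = FALSE)
        drop(predict(fit, Xte))
      },
      stop("unknown classification family: ", family))
  } else {
    switch(family,
      linear = {
        fit <- stats::lm.fit(cbind(1, Xtr), ytr)
        co <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
        drop(cbind(1, Xte) %*% co)
      },
      poly2 = {
        fit <- stats::lm.fit(cbind(1, quad_expand(Xtr)), ytr)
        co <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
        drop(cbind(1, quad_expand(Xte)) %*% co)
      },
      knn = knn_reg_predict(Xtr, ytr, Xte, knn_k),
      rf = {
        fit <- ranger::ranger(y = ytr, x = as.data.frame(Xtr),
                              num.trees = 100, num.threads = 1, seed = seed)
        predict(fit, as.data.frame(Xte), num.threads = 1)$predictions
      },
      mlp = {
        set.seed(seed)
        fit <- nnet::nnet(Xtr, ytr / 100, size = 3, decay = 0.01,
                          maxit = 200, linout = TRUE, trace = FALSE)
        drop(predict(fit, Xte)) * 100
      },
      stop("unknown regression family: ", family))
  }
}

#' Cross-validation fold assignment
#'
#' Stratified assignment keeps the class ratio near-constant across folds so
#' every fold contains both classes whenever each class has at least `k`
#' members.
#'
#' @param y response vector.
#' @param k number of folds.
#' @param stratify stratify on `y` as a class label?
#' @param seed fold-shuffling seed.
#' @return integer fold id (1..k) per observation.
#' @export
make_folds <- function(y, k = 5L, stratify = FALSE, seed = 1L) {
  n <- length(y)
  if (k < 2 || k > n) stop("fold count must be in [2, n]")
  set.seed(seed)
  folds <- integer(n)
  if (stratify) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    folds <- sample(rep_len(seq_len(k), n))
  }
  folds
}
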