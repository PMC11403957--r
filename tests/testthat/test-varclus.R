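test_that("second eigenvalue matches closed forms", {
  m <- correlation_model(matrix(c(1, 1, 1, 1), 2, dimnames = list(1:2, 1:2)))
  expect_equal(second_eigenvalue(c(1, 2), m), 0)
  m <- correlation_model(diag(2), item_ids = 1:2)
  expect_equal(second_eigenvalue(c(1, 2), m), 1)
  # equicorrelation: eigenvalues 1 + (p-1)rho and (p-1)-fold 1 - rho
  R <- block_corr(3, within = 0.5)
  expect_equal(second_eigenvalue(1:3, correlation_model(R)), 0.5)
  expect_equal(second_eigenvalue(5, correlation_model(block_corr(c(3, 3)))), 0)
  expect_error(second_eigenvalue(integer(0), m), "empty")
})

test_that("splitting separates orthogonal blocks exactly", {
  R <- block_corr(c(3, 3), within = 0.9, between = 0)
  m <- correlation_model(R)
  kids <- split_cluster(1:6, m)
  expect_setequal(kids[[1]], 1:3)
  expect_setequal(kids[[2]], 4:6)
  # two uncorrelated items -> two singletons
  kids <- split_cluster(1:2, correlation_model(diag(2), item_ids = 1:2))
  expect_equal(lengths(kids), c(1, 1))
  expect_error(split_cluster(3, m), "singleton")
})

test_that("fully symmetric clusters split deterministically", {
  m <- correlation_model(block_corr(5, within = 0.6))
  k1 <- split_cluster(1:5, m)
  k2 <- split_cluster(1:5, m)
  expect_identical(k1, k2)
  expect_setequal(unlist(k1), 1:5)
  expect_true(all(lengths(k1) >= 1))
})

test_that("hierarchy spans K = 1..p with refinement and trace conservation", {
  m <- block_model(c(4, 3, 3), n = 800, seed = 21)
  h <- build_hierarchy(m)
  p <- 10
  expect_length(h$partitions, p)
  expect_setequal(unlist(h$partitions[[1]]), 1:p)
  expect_equal(lengths(h$partitions[[p]]), rep(1, p))
  expect_true(all(h$split_trace$second_eigenvalue >= 0))
  for (K in 2:p) {
    part <- h$partitions[[K]]
    expect_length(part, K)
    expect_setequal(unlist(part), 1:p)
    expect_equal(anyDuplicated(unlist(part)), 0)
    # refinement: every cluster at K is inside one cluster at K - 1
    parent <- h$partitions[[K - 1]]
    for (cl in part) {
      holders <- vapply(parent, function(pc) all(cl %in% pc), TRUE)
      expect_equal(sum(holders), 1)
    }
    # trace conservation: eigenvalues of each submatrix sum to its size
    for (cl in part) {
      if (length(cl) > 1) {
        ev <- eigen(m$corr[as.character(cl), as.character(cl)],
                    symmetric = TRUE, only.values = TRUE)$values
        expect_equal(sum(ev), length(cl))
      }
    }
  }
  # the split cluster at each step had the maximal second eigenvalue
  for (K in 2:p) {
    prev <- h$partitions[[K - 1]]
    sev <- vapply(prev, function(cl)
      if (length(cl) < 2) -Inf else second_eigenvalue(cl, m), 0)
    split_members <- as.integer(strsplit(h$split_trace$split_cluster[K - 1],
                                         " ")[[1]])
    hit <- which(vapply(prev, function(cl) setequal(cl, split_members), TRUE))
    expect_equal(sev[hit], max(sev))
  }
})

test_that("near-degenerate models reach both endpoint partitions", {
  R <- matrix(0.999, 3, 3); diag(R) <- 1; dimnames(R) <- list(1:3, 1:3)
  h <- build_hierarchy(correlation_model(R))
  expect_length(h$partitions[[1]][[1]], 3)
  expect_equal(lengths(h$partitions[[3]]), rep(1, 3))
})

test_that("representative ratio picks the item with weakest outside loading", {
  # two 2-item clusters; item cross-correlations asymmetric
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.9; R[3, 4] <- R[4, 3] <- 0.9
  R[1, 3] <- R[3, 1] <- 0.1; R[1, 4] <- R[4, 1] <- 0.1
  R[2, 3] <- R[3, 2] <- 0.3; R[2, 4] <- R[4, 2] <- 0.3
  dimnames(R) <- list(1:4, 1:4)
  m <- correlation_model(R)
  part <- list(c(1, 2), c(3, 4))
  reps <- representative_items(part, m)

  # brute-force oracle: loadings = |corr with each cluster's first PC|
  pc <- function(mem) {
    e <- eigen(R[mem, mem], symmetric = TRUE)
    v <- abs(e$vectors[, 1])
    list(v = v, lam = e$values[1], mem = mem)
  }
  load_on <- function(j, cl) {
    drop(R[j, cl$mem] %*% cl$v) / sqrt(cl$lam)
  }
  c1 <- pc(1:2); c2 <- pc(3:4)
  ratio1 <- abs(load_on(1, c1)) / abs(load_on(1, c2))
  ratio2 <- abs(load_on(2, c1)) / abs(load_on(2, c2))
  expect_gt(ratio1, ratio2)  # item 1 has the smaller cross-loading
  expect_equal(reps$item[1], 1)
  expect_equal(reps$ratio[1], max(ratio1, ratio2))

  # singleton cluster represents itself
  part <- list(c(1, 2), 3, 4)
  reps <- representative_items(part, m)
  expect_equal(reps$item[reps$cluster == 2], 3)

  # K = 1 fallback: largest own loading wins
  reps <- representative_items(list(1:4), m)
  expect_length(reps$item, 1)
  expect_true(reps$item %in% 1:4)

  # exact tie -> lowest item id (fully exchangeable cluster pair)
  Rt <- block_corr(c(2, 2), within = 0.8, between = 0.1)
  rt <- representative_items(list(c(1, 2), c(3, 4)), correlation_model(Rt))
  expect_equal(rt$item, c(1, 3))
})

test_that("explained variance summaries match hand arithmetic", {
  R <- block_corr(c(3, 3), within = 0.9, between = 0)
  m <- correlation_model(R)
  # all singletons -> everything explained
  part <- as.list(1:6)
  es <- explained_summary(part, 1:6, m)
  expect_equal(es$average_explained, 1)
  # 3-item equicorrelated rho = 0.9: (1 + 0.81 + 0.81)/3
  part <- list(1:3, 4:6)
  es <- explained_summary(part, c(1, 4), m)
  expect_equal(es$within_explained[1], (1 + 0.81 + 0.81) / 3)
  # mutually uncorrelated cluster: only the representative's own term
  m0 <- correlation_model(diag(4), item_ids = 1:4)
  es <- explained_summary(list(1:4), 2, m0)
  expect_equal(es$within_explained[1], 1 / 4)
  expect_error(explained_summary(list(1:3, 4:6), c(1, 1), m),
               "outside its cluster")
  # pc_share variant: first-PC share of an equicorrelated cluster
  es <- explained_summary(list(1:3, 4:6), c(1, 4), m, method = "pc_share")
  expect_equal(es$within_explained[1], (1 + 2 * 0.9) / 3)
})

test_that("partition selection takes the least K reaching the target", {
  m <- block_model(c(4, 3, 3), n = 1500, seed = 3)
  h <- build_hierarchy(m)
  sel <- select_partition(h, m, threshold = 0.8)
  expect_gte(sel$representatives$average_explained, 0.8)
  if (sel$selected_K > 1) {
    expect_lt(sel$curve$average_explained[sel$selected_K - 1], 0.8)
  }
  expect_equal(sel$curve$K, 1:10)
  expect_equal(sel$curve$average_explained[10], 1)
  # threshold 1 on noisy data forces K = p
  expect_equal(select_partition(h, m, threshold = 1)$selected_K, 10)
  expect_error(select_partition(h, m, threshold = 0), "\\(0, 1\\]")
  expect_error(select_partition(h, m, threshold = 1.5), "\\(0, 1\\]")
})

test_that("planted blocks are recovered at the true cluster count", {
  m <- block_model(c(6, 6, 7, 7), within = 0.7, between = 0.05,
                   n = 2000, seed = 8)
  h <- build_hierarchy(m)
  lab <- partition_labels(h$partitions[[4]], 26)
  expect_equal(mclust::adjustedRandIndex(lab, attr(m, "blocks")), 1)
})
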