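# Shared fixtures, built in code.

# Block-structured correlation matrix: `sizes` blocks with correlation
# `within` inside and `between` across blocks.
block_corr <- function(sizes, within = 0.7, between = 0.05) {
  p <- sum(sizes)
  blocks <- rep(seq_along(sizes), sizes)
  R <- matrix(between, p, p)
  for (b in seq_along(sizes)) R[blocks == b, blocks == b] <- within
  diag(R) <- 1
  dimnames(R) <- list(1:p, 1:p)
  attr(R, "blocks") <- blocks
  R
}

# Sampled correlation model over a block construct.
block_model <- function(sizes, within = 0.7, between = 0.05,
                        n = 2000, seed = 1) {
  R <- block_corr(sizes, within, between)
  set.seed(seed)
  X <- MASS::mvrnorm(n, rep(0, ncol(R)), R)
  colnames(X) <- colnames(R)
  m <- correlation_model(X)
  attr(m, "blocks") <- attr(R, "blocks")
  m
}

# Cluster labels (one per item id 1..p) from a partition.
partition_labels <- function(partition, p) {
  lab <- integer(p)
  for (i in seq_along(partition)) lab[partition[[i]]] <- i
  lab
}

# Pairwise brute-force AUC oracle: ties count one half.
brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Independent truth-table oracle for the nine-type classification of one
# respondent's converted scores (named vector).
classify_oracle_row <- function(s) {
  out <- character(9)
  names(out) <- bc_types()
  biased_ok <- TRUE
  for (b in biased_types()) if (s[[b]] >= 30) biased_ok <- FALSE
  out["GTC"] <- if (s[["GTC"]] >= 60 && biased_ok) "present" else "absent"
  for (b in biased_types()) {
    v <- s[[b]]
    out[b] <- if (v > 40) "present" else if (v >= 30 && v <= 40) "tendency"
              else "absent"
  }
  out
}

# Copy of a simulation config with a different size and seed.
within_n <- function(cfg, n, seed) {
  cfg$n <- as.integer(n)
  cfg$seed <- as.integer(seed)
  cfg
}

# Small respondent-by-item matrix of constant responses.
constant_responses <- function(spec, n, value = 3L) {
  response_matrix(matrix(value, n, length(spec$items),
                         dimnames = list(NULL, spec$items)), spec)
}
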