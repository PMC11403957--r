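# Divisive principal-component variable clustering.
#
# Starting from all items in one cluster, the cluster whose correlation
# submatrix has the largest second eigenvalue is split in two at each step,
# producing one partition for every cluster count K = 1..p. Splitting
# assigns members to the first two principal components by larger squared
# correlation, followed by nearest-component reassignment until stable. Each
# cluster is then summarized by a representative item: the member maximizing
# the ratio of its loading on the cluster's own first principal component to
# its largest loading on any other cluster's first principal component. The
# working partition is the smallest K whose representative items explain, on
# average, at least 80% of the within-cluster variance.

EIG_TOL <- 1e-10

#' Build a correlation model over items
#'
#' @param x either a respondent-by-item matrix of (standardizable) responses,
#'   or a ready-made correlation matrix (square, symmetric, unit diagonal).
#' @param item_ids optional item identifiers; defaults to column names.
#' @return an object of class `ccmq_corr` with fields `p`, `corr`,
#'   `item_ids`.
#' @export
correlation_model <- function(x, item_ids = NULL) {
  x <- as.matrix(x)
  is_corr <- nrow(x) == ncol(x) &&
    max(abs(x - t(x))) < 1e-8 && max(abs(diag(x) - 1)) < 1e-8
  corr <- if (is_corr) (x + t(x)) / 2 else stats::cor(x)
  p <- ncol(corr)
  if (p == 0) stop("empty correlation model")
  if (anyNA(corr)) stop("undefined correlations (constant item?)")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix is not positive semidefinite")
  ids <- item_ids %||% colnames(corr) %||% as.character(seq_len(p))
  ids <- as.integer(ids)
  dimnames(corr) <- list(ids, ids)
  structure(list(p = p, corr = corr, item_ids = ids), class = "ccmq_corr")
}

# Eigendecomposition of a cluster's correlation submatrix (ids -> positions).
cluster_eigen <- function(members, model) {
  idx <- match(members, model$item_ids)
  if (anyNA(idx)) stop("cluster contains unknown item ids")
  sub <- model$corr[idx, idx, drop = FALSE]
  eigen((sub + t(sub)) / 2, symmetric = TRUE)
}

# First principal component of a cluster, sign-fixed so the loading sum is
# positive (first nonzero loading positive when the sum is zero).
cluster_pc1 <- function(members, model) {
  if (length(members) == 1) {
    return(list(lambda = 1, v = stats::setNames(1, members)))
  }
  e <- cluster_eigen(members, model)
  v <- e$vectors[, 1]
  s <- sum(v)
  if (abs(s) < EIG_TOL) s <- v[which(abs(v) > EIG_TOL)[1]]
  if (s < 0) v <- -v
  list(lambda = max(e$values[1], 0), v = stats::setNames(v, members))
}

# Correlation of every model item with a cluster's first principal
# component: R[, members] %*% v / sqrt(lambda).
component_correlations <- function(pc, members, model) {
  idx <- match(members, model$item_ids)
  if (pc$lambda < EIG_TOL) return(stats::setNames(rep(0, model$p),
                                                  model$item_ids))
  drop(model$corr[, idx, drop = FALSE] %*% pc$v) / sqrt(pc$lambda)
}

#' Second eigenvalue of a cluster's correlation submatrix
#'
#' The divisive criterion: a cluster is unidimensional when this is small.
#' Singleton clusters return 0.
#'
#' @param cluster integer item ids.
#' @param model a [correlation_model].
#' @return second-largest eigenvalue (non-negative up to numerical noise).
#' @export
second_eigenvalue <- function(cluster, model) {
  if (length(cluster) == 0) stop("empty cluster")
  if (length(cluster) == 1) return(0)
  ev <- cluster_eigen(cluster, model)$values
  max(ev[2], 0)
}

#' Split a cluster in two along its first two principal components
#'
#' Members are assigned to whichever of the cluster's first two principal
#' components they have the larger squared correlation with; assignments are
#' then iteratively refined by recomputing each child's first principal
#' component and reassigning every member to the nearer child, until stable
#' or `max_iter` sweeps. Degenerate geometry (a tied or vanishing second
#' eigenvalue, or an assignment that empties one side) falls back to
#' splitting off the lowest-index member as a singleton, which keeps the
#' procedure deterministic on fully symmetric input.
#'
#' @param cluster integer item ids, at least 2.
#' @param model a [correlation_model].
#' @param max_iter reassignment sweep cap (default 20).
#' @return list of two disjoint non-empty id vectors covering `cluster`;
#'   the child containing the smallest id comes first.
#' @export
split_cluster <- function(cluster, model, max_iter = 20) {
  if (length(cluster) < 2) stop("cannot split a singleton cluster")
  cluster <- sort(cluster)
  anchor_split <- function() list(cluster[1], cluster[-1])

  e <- cluster_eigen(cluster, model)
  lam <- pmax(e$values, 0)
  degenerate <- lam[2] < EIG_TOL ||
    (length(lam) > 2 && lam[2] - lam[3] < EIG_TOL)
  if (degenerate && length(cluster) == 2) return(anchor_split())
  if (lam[2] < EIG_TOL) return(anchor_split())

  fix_sign <- function(v) {
    s <- sum(v); if (abs(s) < EIG_TOL) s <- v[which(abs(v) > EIG_TOL)[1]]
    if (s < 0) -v else v
  }
  # initial assignment: squared loadings on the varimax-rotated first two
  # components (rotation polarizes the loadings toward one component each,
  # as in classic divisive variable clustering)
  L2 <- cbind(fix_sign(e$vectors[, 1]) * sqrt(lam[1]),
              fix_sign(e$vectors[, 2]) * sqrt(lam[2]))
  rot <- tryCatch(L2 %*% stats::varimax(L2, normalize = FALSE)$rotmat,
                  error = function(e) L2)
  r1 <- rot[, 1]; r2 <- rot[, 2]
  assign1 <- r1^2 >= r2^2 - EIG_TOL  # ties go to the first component
  if (all(assign1) || !any(assign1)) return(anchor_split())

  g1 <- cluster[assign1]; g2 <- cluster[!assign1]
  for (it in seq_len(max_iter)) {
    pc1 <- cluster_pc1(g1, model); pc2 <- cluster_pc1(g2, model)
    c1 <- component_correlations(pc1, g1, model)[as.character(cluster)]
    c2 <- component_correlations(pc2, g2, model)[as.character(cluster)]
    new1 <- c1^2 >= c2^2 - EIG_TOL
    if (all(new1) || !any(new1)) break  # keep last non-degenerate assignment
    ng1 <- cluster[new1]; ng2 <- cluster[!new1]
    if (identical(ng1, g1)) break
    g1 <- ng1; g2 <- ng2
  }
  # cohesion repair: a child's first component underrepresents minority item
  # groups, which component-based reassignment can tear across the boundary;
  # mean squared correlation with each child's members pulls such groups
  # back together (the centroid-flavored assignment of classic variable
  # clustering)
  idx <- match(cluster, model$item_ids)
  R2 <- model$corr[idx, idx, drop = FALSE]^2
  diag(R2) <- 0
  in1 <- cluster %in% g1
  for (it in seq_len(max_iter)) {
    moved <- FALSE
    for (j in seq_along(cluster)) {  # sequential sweep: no swap oscillation
      n1 <- sum(in1) - in1[j]; n2 <- sum(!in1) - !in1[j]
      if ((in1[j] && n1 == 0) || (!in1[j] && n2 == 0)) next  # keep non-empty
      m1 <- sum(R2[j, in1])
      m2 <- sum(R2[j, !in1])
      pref1 <- m1 / max(n1, 1) >= m2 / max(n2, 1) - EIG_TOL
      if (pref1 != in1[j]) { in1[j] <- pref1; moved <- TRUE }
    }
    if (!moved) break
  }
  g1 <- cluster[in1]; g2 <- cluster[!in1]
  if (min(g2) < min(g1)) list(g2, g1) else list(g1, g2)
}

#' Build the full divisive cluster hierarchy
#'
#' One divisive pass: at each step the cluster with the largest second
#' eigenvalue (lowest index on ties) is split, yielding a partition for
#' every cluster count K in 1..p — a deterministic realization of sweeping
#' the second-eigenvalue threshold through all values. Clusters are kept
#' ordered by their smallest member id.
#'
#' @param model a [correlation_model].
#' @return an object of class `ccmq_varclus`: `partitions` (list indexed by
#'   K of lists of item-id vectors) and `split_trace` (data frame with the
#'   split cluster and its second eigenvalue at each step).
#' @export
build_hierarchy <- function(model) {
  p <- model$p
  if (p == 0) stop("empty model")
  current <- list(sort(model$item_ids))
  partitions <- vector("list", p)
  partitions[[1]] <- current
  trace <- data.frame(K = integer(0), split_cluster = character(0),
                      second_eigenvalue = numeric(0))
  for (K in seq_len(p - 1) + 1) {
    sev <- vapply(current, function(cl) {
      if (length(cl) < 2) -Inf else second_eigenvalue(cl, model)
    }, 0)
    pick <- which.max(sev)  # ties: lowest cluster index
    kids <- split_cluster(current[[pick]], model)
    trace <- rbind(trace, data.frame(
      K = K, split_cluster = paste(current[[pick]], collapse = " "),
      second_eigenvalue = max(sev[pick], 0)))
    current <- append(current[-pick], kids)
    current <- current[order(vapply(current, min, 0))]
    partitions[[K]] <- current
  }
  structure(list(item_ids = model$item_ids, partitions = partitions,
                 split_trace = trace), class = "ccmq_varclus")
}

#' @export
print.ccmq_varclus <- function(x, ...) {
  cat(sprintf("Divisive variable-clustering hierarchy over %d items (K = 1..%d)\n",
              length(x$item_ids), length(x$partitions)))
  invisible(x)
}

# |correlation| of every item with every cluster's first PC: p x K matrix.
partition_loadings <- function(partition, model) {
  pcs <- lapply(partition, cluster_pc1, model = model)
  sapply(seq_along(partition), function(i) {
    abs(component_correlations(pcs[[i]], partition[[i]], model))
  })
}

#' Representative items for every cluster of a partition
#'
#' For member j of cluster i the selection ratio is
#' `r = lambda_ij / lambda_j^max,other`: the loading of j on its own
#' cluster's first principal component over its largest loading on any other
#' cluster's first principal component (absolute values; loadings are
#' eigenvector entries scaled by the square root of the eigenvalue, i.e.
#' item-component correlations). The member with the highest ratio
#' represents the cluster; exact ties break to the lowest item id. With a
#' single cluster there is no "other" loading and the member with the
#' largest own loading is chosen.
#'
#' @param partition list of disjoint item-id vectors covering the model.
#' @param model a [correlation_model].
#' @return data frame with columns `cluster`, `item`, `ratio`, `own_loading`.
#' @export
representative_items <- function(partition, model) {
  K <- length(partition)
  L <- partition_loadings(partition, model)  # p x K, |corr| with each PC1
  rows <- lapply(seq_len(K), function(i) {
    members <- sort(partition[[i]])
    pos <- match(members, model$item_ids)
    own <- L[pos, i]
    if (K == 1) {
      j <- which.max(own)
      return(data.frame(cluster = i, item = members[j], ratio = NA_real_,
                        own_loading = own[j]))
    }
    other <- apply(L[pos, -i, drop = FALSE], 1, max)
    ratio <- ifelse(other < EIG_TOL, Inf, own / other)
    best <- which(ratio >= max(ratio) - EIG_TOL)[1]  # tie: lowest item id
    data.frame(cluster = i, item = members[best], ratio = ratio[best],
               own_loading = own[best])
  })
  do.call(rbind, rows)
}

#' Representative item of one cluster
#'
#' @param cluster item ids of the cluster (must be one of the partition's
#'   clusters).
#' @param partition the full partition the cluster belongs to.
#' @param model a [correlation_model].
#' @return list with `item` and `ratio`.
#' @export
representative_item <- function(cluster, partition, model) {
  hit <- which(vapply(partition, function(cl) setequal(cl, cluster), TRUE))
  if (length(hit) != 1) stop("cluster is not part of the partition")
  reps <- representative_items(partition, model)
  list(item = reps$item[hit], ratio = reps$ratio[hit])
}

#' Within-cluster variance explained by the representative items
#'
#' Under the default method the variance of member j "explained by the
#' representative item" is their squared correlation (the representative
#' itself contributing 1), averaged within each cluster; `average_explained`
#' is the mean over clusters. The alternative `"pc_share"` method uses the
#' first principal component's variance share of each cluster instead.
#'
#' @param partition list of item-id vectors.
#' @param representatives data frame from [representative_items] (or one
#'   representative id per cluster).
#' @param model a [correlation_model].
#' @param method `"squared_correlation"` (default) or `"pc_share"`.
#' @return object of class `ccmq_repset`: `K`, `clusters`,
#'   `representatives`, per-cluster `within_explained`, `average_explained`.
#' @export
explained_summary <- function(partition, representatives, model,
                              method = c("squared_correlation", "pc_share")) {
  method <- match.arg(method)
  rep_ids <- if (is.data.frame(representatives)) representatives$item
             else as.integer(representatives)
  if (length(rep_ids) != length(partition)) {
    stop("need exactly one representative per cluster")
  }
  within <- vapply(seq_along(partition), function(i) {
    members <- partition[[i]]
    if (!rep_ids[i] %in% members) stop("representative outside its cluster")
    if (method == "pc_share") {
      if (length(members) == 1) return(1)
      return(cluster_pc1(members, model)$lambda / length(members))
    }
    pos <- match(members, model$item_ids)
    rp <- match(rep_ids[i], model$item_ids)
    mean(model$corr[pos, rp]^2)
  }, 0)
  structure(list(K = length(partition), clusters = partition,
                 representatives = if (is.data.frame(representatives))
                   representatives else
                   data.frame(cluster = seq_along(partition), item = rep_ids),
                 within_explained = within,
                 average_explained = mean(within), method = method),
            class = "ccmq_repset")
}

#' @export
print.ccmq_repset <- function(x, ...) {
  cat(sprintf("K = %d clusters; representatives: %s\n", x$K,
              paste(sort(x$representatives$item), collapse = " ")))
  cat(sprintf("average within-cluster variance explained: %.3f (%s)\n",
              x$average_explained, x$method))
  invisible(x)
}

#' Select the least number of clusters reaching a variance-explained target
#'
#' Walks the hierarchy from K = 1 upward and returns the smallest K whose
#' representative items explain on average at least `threshold` of the
#' within-cluster variance (default 0.8), along with the full K-versus-
#' average-explained curve.
#'
#' @param hierarchy a `ccmq_varclus` from [build_hierarchy].
#' @param model the [correlation_model] the hierarchy was built from.
#' @param threshold target average explained fraction in (0, 1].
#' @param method passed to [explained_summary].
#' @return list with `selected_K`, `representatives` (`ccmq_repset` at the
#'   selected K) and `curve` (data frame `K`, `average_explained`).
#' @export
select_partition <- function(hierarchy, model, threshold = 0.8,
                             method = c("squared_correlation", "pc_share")) {
  method <- match.arg(method)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]")
  }
  p <- length(hierarchy$partitions)
  avg <- numeric(p)
  repsets <- vector("list", p)
  for (K in seq_len(p)) {
    part <- hierarchy$partitions[[K]]
    reps <- representative_items(part, model)
    repsets[[K]] <- explained_summary(part, reps, model, method)
    avg[K] <- repsets[[K]]$average_explained
  }
  hit <- which(avg >= threshold)
  selected <- if (length(hit)) min(hit) else p
  list(selected_K = selected, representatives = repsets[[selected]],
       curve = data.frame(K = seq_len(p), average_explained = avg))
}
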