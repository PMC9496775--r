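#' Mutual reachability distances
#'
#' Given a point matrix, computes the pairwise mutual reachability distance
#' `d_mreach(a, b) = max(core(a), core(b), d(a, b))` where the core distance
#' of a point is the distance to its `min_samples`-th nearest neighbor (the
#' point itself counts as its own 0-th neighbor, matching the reference
#' HDBSCAN implementations). Density-based clustering on this metric makes
#' sparse regions "further away" than their raw geometry suggests.
#'
#' @param x numeric matrix, one row per point.
#' @param min_samples neighbor rank defining the core distance.
#' @param metric `"euclidean"` or `"cosine"` (cosine distance
#'   `1 - cos(a, b)`).
#' @return List with `dist` (raw distance matrix), `core` (core distances)
#'   and `mreach` (mutual reachability matrix, zero diagonal).
#' @export
mutual_reachability <- function(x, min_samples = 5L, metric = "euclidean") {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- switch(metric,
    euclidean = as.matrix(stats::dist(x)),
    cosine = {
      norms <- sqrt(rowSums(x^2))
      norms[norms == 0] <- 1
      s <- tcrossprod(x / norms)
      m <- 1 - pmin(pmax(s, -1), 1)
      diag(m) <- 0
      m
    },
    stop("unknown metric: ", metric)
  )
  # row-sorted distances include the 0 self-distance in position 1, so the
  # min_samples-th neighbor (self included) sits at position min_samples
  core <- apply(d, 1L, function(row) sort(row)[min(min_samples, n)])
  mreach <- pmax(d, outer(core, core, pmax))
  diag(mreach) <- 0
  list(dist = d, core = core, mreach = mreach)
}

# Prim's algorithm on a dense symmetric weight matrix.
# Returns edges (from, to, weight) of a minimum spanning tree.
prim_mst <- function(w) {
  n <- nrow(w)
  in_tree <- rep(FALSE, n)
  best_w <- rep(Inf, n)
  best_from <- rep(NA_integer_, n)
  in_tree[1L] <- TRUE
  best_w_upd <- w[1L, ]
  upd <- best_w_upd < best_w
  best_w[upd] <- best_w_upd[upd]
  best_from[upd] <- 1L
  edges <- matrix(0, nrow = n - 1L, ncol = 3L,
                  dimnames = list(NULL, c("from", "to", "weight")))
  for (e in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best_w[cand])]
    edges[e, ] <- c(best_from[v], v, best_w[v])
    in_tree[v] <- TRUE
    upd <- !in_tree & w[v, ] < best_w
    best_w[upd] <- w[v, upd]
    best_from[upd] <- v
  }
  edges
}

# Single-linkage dendrogram from MST edges (scipy-style): leaves are 1..n,
# internal nodes n+1..2n-1 in order of increasing merge distance.
# Returns left/right child ids, merge heights and subtree sizes per
# internal node.
single_linkage_tree <- function(edges, n) {
  ord <- order(edges[, "weight"])
  parent <- seq_len(2L * n - 1L)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  node_of <- seq_len(n)          # current dendrogram node of each component
  sizes <- c(rep(1L, n), integer(n - 1L))
  left <- integer(n - 1L); right <- integer(n - 1L); height <- numeric(n - 1L)
  nxt <- n
  for (e in ord) {
    a <- find(edges[e, "from"]); b <- find(edges[e, "to"])
    na <- node_of[a]; nb <- node_of[b]
    nxt <- nxt + 1L
    left[nxt - n] <- na; right[nxt - n] <- nb
    height[nxt - n] <- edges[e, "weight"]
    sizes[nxt] <- sizes[na] + sizes[nb]
    parent[b] <- a
    node_of[a] <- nxt
  }
  list(left = left, right = right, height = height, sizes = sizes, n = n)
}

# All leaf points (1..n) under a dendrogram node.
tree_leaves <- function(tree, node) {
  n <- tree$n
  stack <- node
  out <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= n) out <- c(out, v) else {
      stack <- c(stack, tree$left[v - n], tree$right[v - n])
    }
  }
  out
}

# Condense the single-linkage hierarchy: splits into two components of at
# least min_cluster_size each survive as cluster splits; smaller components
# are points "falling out" of their cluster at lambda = 1/distance.
# Returns a data.frame(parent, child, lambda, size): child <= n are points,
# child > n condensed clusters; the root cluster has id n + 1.
condense_tree <- function(tree, min_cluster_size) {
  n <- tree$n
  rows_parent <- integer(0); rows_child <- integer(0)
  rows_lambda <- numeric(0); rows_size <- integer(0)
  add_row <- function(p, c, l, s) {
    rows_parent[length(rows_parent) + 1L] <<- p
    rows_child[length(rows_child) + 1L] <<- c
    rows_lambda[length(rows_lambda) + 1L] <<- l
    rows_size[length(rows_size) + 1L] <<- s
  }
  next_id <- n + 1L
  root_cond <- next_id
  next_id <- next_id + 1L
  # stack of (dendrogram node, condensed cluster it belongs to)
  stack <- list(c(2L * n - 1L, root_cond))
  while (length(stack)) {
    item <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- item[1L]; cond <- item[2L]
    dist <- tree$height[node - n]
    lambda <- if (dist > 0) 1 / dist else Inf
    l <- tree$left[node - n]; r <- tree$right[node - n]
    ls <- tree$sizes[l]; rs <- tree$sizes[r]
    if (ls >= min_cluster_size && rs >= min_cluster_size) {
      for (ch in c(l, r)) {
        new_id <- next_id; next_id <- next_id + 1L
        add_row(cond, new_id, lambda, tree$sizes[ch])
        if (ch <= n) {
          # a cluster that is a single point cannot arise (size >= 2)
          add_row(new_id, ch, lambda, 1L)
        } else {
          stack[[length(stack) + 1L]] <- c(ch, new_id)
        }
      }
    } else if (ls < min_cluster_size && rs < min_cluster_size) {
      for (p in tree_leaves(tree, l)) add_row(cond, p, lambda, 1L)
      for (p in tree_leaves(tree, r)) add_row(cond, p, lambda, 1L)
    } else {
      small <- if (ls < min_cluster_size) l else r
      big <- if (ls < min_cluster_size) r else l
      for (p in tree_leaves(tree, small)) add_row(cond, p, lambda, 1L)
      if (big <= n) {
        add_row(cond, big, lambda, 1L)
      } else {
        stack[[length(stack) + 1L]] <- c(big, cond)
      }
    }
  }
  data.frame(parent = rows_parent, child = rows_child,
             lambda = rows_lambda, size = rows_size)
}

# Excess-of-mass stability per condensed cluster:
# sum over members of (lambda_leave - lambda_birth).
compute_stability <- function(condensed, root_id) {
  clusters <- sort(unique(condensed$parent))
  births <- setNames(rep(0, length(clusters)), clusters)
  is_cluster_child <- condensed$child %in% clusters
  births[as.character(condensed$child[is_cluster_child])] <-
    condensed$lambda[is_cluster_child]
  stab <- vapply(clusters, function(cl) {
    rows <- condensed$parent == cl
    sum((condensed$lambda[rows] - births[as.character(cl)]) *
          condensed$size[rows])
  }, numeric(1))
  setNames(stab, clusters)
}

# Excess-of-mass cluster selection (allow_single_cluster = FALSE): a cluster
# is selected when its own stability exceeds the summed stability of its
# selected subtree; the root is never selected.
select_clusters_eom <- function(condensed, stability, root_id) {
  clusters <- as.integer(names(stability))
  children_of <- split(condensed$child[condensed$child %in% clusters],
                       condensed$parent[condensed$child %in% clusters])
  stab_hat <- stability
  selected <- setNames(rep(FALSE, length(clusters)), names(stability))
  descendants <- function(cl) {
    out <- integer(0)
    stack <- children_of[[as.character(cl)]]
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      out <- c(out, v)
      stack <- c(stack, children_of[[as.character(v)]])
    }
    out
  }
  for (cl in sort(clusters[clusters != root_id], decreasing = TRUE)) {
    kids <- children_of[[as.character(cl)]]
    child_stab <- if (length(kids)) sum(stab_hat[as.character(kids)]) else 0
    if (length(kids) && stability[as.character(cl)] < child_stab) {
      stab_hat[as.character(cl)] <- child_stab
    } else {
      selected[as.character(cl)] <- TRUE
      if (length(kids)) selected[as.character(descendants(cl))] <- FALSE
    }
  }
  as.integer(names(selected)[selected])
}

#' Density-based clustering with HDBSCAN
#'
#' A full implementation of hierarchical density-based clustering: core
#' distances, mutual reachability, minimum spanning tree, single-linkage
#' hierarchy, condensation at `min_cluster_size`, and excess-of-mass
#' cluster selection. Points not falling in any selected cluster receive
#' the noise label `-1` ("Topic -1" downstream); clusters are renumbered
#' `1..C` by decreasing size. Matches the reference implementation
#' (scikit-learn / McInnes et al.) with `allow_single_cluster = FALSE`.
#'
#' @param emb numeric matrix (or `nt_embedding`), one row per document.
#' @param min_cluster_size smallest subtree that survives condensation
#'   (default 10).
#' @param min_samples neighbor rank for core distances (default:
#'   `min_cluster_size`).
#' @param metric `"euclidean"` (default) or `"cosine"`.
#' @return An `nt_clustering`: list with `labels` (integer, `-1` = noise),
#'   `sizes` (named, decreasing), `strengths` (membership probabilities in
#'   `[0, 1]`, 0 for noise), `n_noise`, and the intermediate `condensed`
#'   tree for inspection.
#' @export
hdbscan_cluster <- function(emb, min_cluster_size = 10L,
                            min_samples = min_cluster_size,
                            metric = "euclidean") {
  x <- as.matrix(emb)
  n <- nrow(x)
  stopifnot(n >= 2L, min_cluster_size >= 2L, min_samples >= 1L)
  labels <- rep(-1L, n)
  strengths <- rep(0, n)
  if (n < min_cluster_size) {
    warning("fewer points (", n, ") than min_cluster_size (",
            min_cluster_size, "); labeling everything noise")
    return(new_clustering(labels, strengths, rownames(x), condensed = NULL))
  }
  mr <- mutual_reachability(x, min_samples = min_samples, metric = metric)
  edges <- prim_mst(mr$mreach)
  tree <- single_linkage_tree(edges, n)
  condensed <- condense_tree(tree, min_cluster_size)
  root_id <- n + 1L
  stability <- compute_stability(condensed, root_id)
  chosen <- select_clusters_eom(condensed, stability, root_id)
  if (length(chosen)) {
    clusters <- as.integer(names(stability))
    parent_of <- setNames(condensed$parent[match(clusters, condensed$child)],
                          clusters)
    point_rows <- condensed$child <= n
    leaf_parent <- condensed$parent[point_rows]
    leaf_point <- condensed$child[point_rows]
    leaf_lambda <- condensed$lambda[point_rows]
    raw <- rep(-1L, n)
    lambda_p <- rep(0, n)
    for (i in seq_along(leaf_point)) {
      q <- leaf_parent[i]
      while (q != root_id && !(q %in% chosen)) q <- parent_of[as.character(q)]
      if (q != root_id) {
        raw[leaf_point[i]] <- q
        lambda_p[leaf_point[i]] <- leaf_lambda[i]
      }
    }
    # renumber 1..C by decreasing size (ties: smaller internal id first)
    tab <- table(raw[raw != -1L])
    ord <- names(tab)[order(-as.integer(tab), as.integer(names(tab)))]
    for (new in seq_along(ord)) {
      members <- raw == as.integer(ord[new])
      labels[members] <- new
      lmax <- max(lambda_p[members][is.finite(lambda_p[members])], 0)
      strengths[members] <-
        if (lmax <= 0) 1 else pmin(lambda_p[members], lmax) / lmax
    }
  }
  new_clustering(labels, strengths, rownames(x), condensed)
}

new_clustering <- function(labels, strengths, ids, condensed) {
  sz <- table(factor(labels[labels != -1L]))
  out <- list(labels = labels,
              sizes = setNames(as.integer(sz), names(sz)),
              strengths = strengths,
              n_noise = sum(labels == -1L),
              doc_ids = ids,
              condensed = condensed)
  class(out) <- "nt_clustering"
  out
}

#' @export
print.nt_clustering <- function(x, ...) {
  cat(sprintf("<nt_clustering> %d clusters (%s), %d noise of %d points\n",
              length(x$sizes), paste(x$sizes, collapse = ", "),
              x$n_noise, length(x$labels)))
  invisible(x)
}

#' Hard topic assignment from a clustering
#'
#' HDBSCAN assignments are hard: the cluster label is the topic id, with
#' `-1` the virtual topic of unassigned documents. Membership strengths are
#' reported in the clustering but do not alter assignment.
#'
#' @param clustering an `nt_clustering`.
#' @return Integer vector of per-document topic ids (`-1, 1, 2, ...`).
#' @export
assign_topics <- function(clustering) {
  stopifnot(inherits(clustering, "nt_clustering"))
  clustering$labels
}
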