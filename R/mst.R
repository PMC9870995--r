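#' Maximum-coupling spanning tree of a connectivity matrix
#'
#' Builds the spanning tree that retains the strongest functional
#' connections: Kruskal's algorithm on edges sorted by decreasing coupling
#' (equivalently, a minimum spanning tree over inverted weights, the usual
#' convention when "link weight" means distance). Ties are broken
#' deterministically by lexicographic edge order (lower channel index first),
#' so equal-weight matrices always yield the same tree.
#'
#' @param cm an `eeg_connectivity`, or a plain symmetric numeric matrix.
#' @return an object of class `mst_tree` with `nodes` (labels) and `edges`
#'   (data frame `i`, `j`, `weight`, 1-based node indices, `i < j`).
#' @export
build_mst <- function(cm) {
  if (inherits(cm, "eeg_connectivity")) {
    w <- cm$values
    labels <- cm$labels
  } else {
    w <- as.matrix(cm)
    labels <- rownames(w) %||% paste0("ch", seq_len(nrow(w)))
  }
  n <- nrow(w)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  if (ncol(w) != n) stop("matrix must be square", call. = FALSE)
  ut <- w[upper.tri(w)]
  lt <- t(w)[upper.tri(w)]
  if (any(!is.finite(ut)) || any(!is.finite(lt)))
    stop("non-finite off-diagonal connectivity values", call. = FALSE)
  if (any(abs(ut - lt) > 1e-9))
    stop("connectivity matrix must be symmetric", call. = FALSE)

  idx <- which(upper.tri(w), arr.ind = TRUE)
  ord <- order(-ut, idx[, 1], idx[, 2])
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  ei <- integer(n - 1); ej <- integer(n - 1); ew <- numeric(n - 1)
  k <- 0L
  for (e in ord) {
    a <- find(idx[e, 1]); b <- find(idx[e, 2])
    if (a != b) {
      parent[a] <- b
      k <- k + 1L
      ei[k] <- idx[e, 1]; ej[k] <- idx[e, 2]; ew[k] <- ut[e]
      if (k == n - 1L) break
    }
  }
  structure(list(nodes = labels,
                 edges = data.frame(i = ei, j = ej, weight = ew)),
            class = "mst_tree")
}

#' @export
print.mst_tree <- function(x, ...) {
  cat(sprintf("<mst_tree> %d nodes, %d edges\n", length(x$nodes),
              nrow(x$edges)))
  invisible(x)
}

tree_adjacency <- function(t) {
  n <- length(t$nodes)
  adj <- vector("list", n)
  for (k in seq_len(nrow(t$edges))) {
    i <- t$edges$i[k]; j <- t$edges$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# hop distances from one node by BFS
tree_bfs <- function(adj, from, n) {
  d <- rep(NA_integer_, n)
  d[from] <- 0L
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) if (is.na(d[u])) {
      d[u] <- d[v] + 1L
      queue <- c(queue, u)
    }
  }
  d
}

#' Global MST topology measures
#'
#' The six normalized tree measures:
#' \describe{
#'   \item{kmax}{highest node degree / (n-1).}
#'   \item{leaf_fraction}{number of degree-1 nodes / n.}
#'   \item{diameter}{largest hop distance between any two nodes / M.}
#'   \item{ecc_mean}{mean over nodes of the largest hop distance to any
#'     other node / M.}
#'   \item{bc_max}{highest betweenness centrality, normalized by
#'     (n-1)(n-2)/2 so the hub of a star scores 1 and every leaf 0.}
#'   \item{tree_hierarchy}{L / (2 M bc_max) with L the leaf count.}
#' }
#' Here M = n - 1, which is simultaneously the edge count of the tree and
#' the maximum attainable leaf number (the star); the two published readings
#' of M coincide for every tree, not only at n = 64.
#'
#' @param t an `mst_tree` (or an `eeg_connectivity`, in which case the tree
#'   is built first).
#' @return named list of the six measures, all in `[0, 1]`.
#' @export
mst_metrics <- function(t) {
  if (inherits(t, "eeg_connectivity")) t <- build_mst(t)
  stopifnot(inherits(t, "mst_tree"))
  n <- length(t$nodes)
  if (n < 3) stop("betweenness undefined for fewer than 3 nodes", call. = FALSE)
  M <- n - 1
  adj <- tree_adjacency(t)
  deg <- lengths(adj)
  leaves <- sum(deg == 1)

  ecc <- vapply(seq_len(n), function(v) max(tree_bfs(adj, v, n)), integer(1))
  diam <- max(ecc)

  # betweenness on a tree: pairs (s, t) separated by v = all pairs among
  # the other n-1 nodes minus pairs inside a single branch hanging off v
  bc <- vapply(seq_len(n), function(v) {
    total <- (n - 1) * (n - 2) / 2
    seen <- rep(FALSE, n)
    seen[v] <- TRUE
    within <- 0
    for (u in adj[[v]]) {
      if (seen[u]) next
      # size of the component containing u once v is removed
      comp <- 0L
      queue <- u
      seen[u] <- TRUE
      while (length(queue)) {
        x <- queue[1]; queue <- queue[-1]
        comp <- comp + 1L
        for (y in adj[[x]]) if (!seen[y]) {
          seen[y] <- TRUE
          queue <- c(queue, y)
        }
      }
      within <- within + comp * (comp - 1) / 2
    }
    (total - within) / total
  }, numeric(1))
  bc_max <- max(bc)

  list(kmax = max(deg) / M,
       leaf_fraction = leaves / n,
       diameter = diam / M,
       bc_max = bc_max,
       ecc_mean = mean(ecc) / M,
       tree_hierarchy = leaves / (2 * M * bc_max))
}
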