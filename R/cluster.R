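#' Jaccard similarity between sample band profiles
#'
#' For each sample pair, over the bands where both samples are scored
#' (non-NA): J = a / (a + b + c) with a = shared presences and b, c the
#' presences unique to each sample. When a + b + c = 0 (no presences at
#' all among co-scored bands) J is 1 by convention: two blank profiles are
#' indistinguishable. A sample pair with zero co-scored bands is an error.
#'
#' @param bm A `band_matrix` with at least 2 samples.
#' @return Symmetric numeric matrix with unit diagonal, dimnames = samples.
#' @export
jaccard_similarity <- function(bm) {
  v <- bm$values
  n <- ncol(v)
  if (n < 2) stop("need at least 2 samples")
  sim <- diag(1, n)
  dimnames(sim) <- list(bm$samples, bm$samples)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(v[, i]) & !is.na(v[, j])
      if (!any(ok)) {
        stop("samples '", bm$samples[i], "' and '", bm$samples[j],
             "' share no co-scored bands")
      }
      x <- v[ok, i]
      y <- v[ok, j]
      a <- sum(x == 1 & y == 1)
      bc <- sum(x != y)
      sim[i, j] <- sim[j, i] <- if (a + bc == 0) 1 else a / (a + bc)
    }
  }
  sim
}

#' UPGMA dendrogram from a similarity matrix
#'
#' Distances are taken as d = 1 - similarity. Standard unweighted
#' pair-group agglomeration: repeatedly merge the closest pair of clusters,
#' with new distances the size-weighted arithmetic mean of member
#' distances. Node heights follow the ultrametric convention
#' height = d_merge / 2, so the cophenetic distance between two leaves is
#' twice the height of their lowest common ancestor. Ties between equally
#' close cluster pairs break to the pair containing the lexicographically
#' smallest member id (then the smallest partner), making the merge order
#' and the Newick output reproducible.
#'
#' @param sim Symmetric similarity matrix in \[0, 1\] with unit diagonal and
#'   dimnames.
#' @return An object of class `upgma_tree`: list with `merge` (hclust-style
#'   merge matrix), `height` (merge heights, = d/2), `labels`, `n_leaves`.
#' @export
upgma <- function(sim) {
  if (!isSymmetric(unname(sim), tol = 1e-12)) {
    stop("similarity matrix must be symmetric")
  }
  labels <- rownames(sim)
  if (is.null(labels)) stop("similarity matrix needs dimnames")
  n <- nrow(sim)
  if (n < 2) stop("need at least 2 samples")
  d <- 1 - sim
  diag(d) <- Inf
  # active clusters: id (negative leaf index or positive merge index),
  # member leaf indices, smallest member label
  active <- lapply(seq_len(n), function(i) {
    list(id = -i, members = i, min_label = labels[i])
  })
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(active)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        dij <- d[i, j]
        key <- sort(c(active[[i]]$min_label, active[[j]]$min_label))
        if (is.null(best) || dij < best$d - 1e-15 ||
            (abs(dij - best$d) <= 1e-15 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = dij, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    ni <- length(active[[i]]$members)
    nj <- length(active[[j]]$members)
    # left child = cluster containing the lexicographically smallest id,
    # so leaf order and Newick output are reproducible
    if (active[[i]]$min_label <= active[[j]]$min_label) {
      merge[step, ] <- c(active[[i]]$id, active[[j]]$id)
    } else {
      merge[step, ] <- c(active[[j]]$id, active[[i]]$id)
    }
    height[step] <- best$d / 2
    new_cl <- list(id = step,
                   members = c(active[[i]]$members, active[[j]]$members),
                   min_label = min(active[[i]]$min_label,
                                   active[[j]]$min_label))
    # size-weighted average distances to the remaining clusters
    keep <- setdiff(seq_len(m), c(i, j))
    if (length(keep) > 0) {
      new_d <- (ni * d[i, keep] + nj * d[j, keep]) / (ni + nj)
      d_new <- matrix(Inf, m - 1, m - 1)
      d_new[seq_along(keep), seq_along(keep)] <- d[keep, keep]
      d_new[m - 1, seq_along(keep)] <- new_d
      d_new[seq_along(keep), m - 1] <- new_d
      d <- d_new
    }
    active <- c(active[keep], list(new_cl))
  }
  structure(list(merge = merge, height = height, labels = labels,
                 n_leaves = n),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA dendrogram over", x$n_leaves, "samples; root height",
      format(max(x$height), digits = 4), "\n")
  invisible(x)
}

#' Convert a UPGMA tree to an hclust object
#'
#' @param x An `upgma_tree`.
#' @param ... Unused.
#' @return An object of class `hclust` (heights are the halved cophenetic
#'   merge distances).
#' @export
as.hclust.upgma_tree <- function(x, ...) {
  order <- tree_leaf_order(x)
  structure(list(merge = x$merge, height = x$height, order = order,
                 labels = x$labels, method = "upgma",
                 call = match.call(), dist.method = "1 - Jaccard"),
            class = "hclust")
}

tree_leaf_order <- function(tree) {
  leaves_of <- function(node) {
    if (node < 0) return(-node)
    c(leaves_of(tree$merge[node, 1]), leaves_of(tree$merge[node, 2]))
  }
  leaves_of(nrow(tree$merge))
}

fmt_num <- function(x) {
  format(x, trim = TRUE, scientific = FALSE, digits = 10)
}

#' Newick string for a UPGMA tree
#'
#' Branch lengths are parent height minus child height (leaves have height
#' 0), so root-to-leaf path lengths equal half the cophenetic distances.
#'
#' @param tree An `upgma_tree`.
#' @param path Optional file to write the Newick string to.
#' @return The Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  node_str <- function(node, parent_height) {
    if (node < 0) {
      paste0(tree$labels[-node], ":", fmt_num(parent_height))
    } else {
      h <- tree$height[node]
      inner <- paste(node_str(tree$merge[node, 1], h),
                     node_str(tree$merge[node, 2], h), sep = ",")
      paste0("(", inner, "):", fmt_num(parent_height - h))
    }
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  nwk <- paste0("(",
                node_str(tree$merge[root, 1], h), ",",
                node_str(tree$merge[root, 2], h),
                ");")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Cut a UPGMA dendrogram into k clusters
#'
#' Removes the k-1 highest merges. Cluster ids are assigned in order of each
#' cluster's lexicographically smallest sample id. If the cut is ambiguous
#' because the (k-1)-th and k-th highest merges are at exactly the same
#' height, an error lists the tied heights.
#'
#' @param tree An `upgma_tree`.
#' @param k Number of clusters, 1..n_leaves.
#' @return Named integer vector: sample id -> cluster id.
#' @export
cut_clusters <- function(tree, k) {
  n <- tree$n_leaves
  if (k < 1 || k > n) stop("k must be in 1..", n)
  h <- tree$height
  if (k > 1 && k < n && isTRUE(all.equal(h[n - k], h[n - k + 1]))) {
    stop("cut into k = ", k, " clusters is ambiguous: tied merge heights ",
         fmt_num(h[n - k]), " and ", fmt_num(h[n - k + 1]))
  }
  # union-find over the first n-k merges
  comp <- seq_len(n)
  find <- function(i) {
    while (comp[i] != i) i <- comp[i]
    i
  }
  cluster_of_node <- integer(n - 1)
  for (step in seq_len(max(0, n - k))) {
    pick <- function(node) {
      if (node < 0) find(-node) else find(cluster_of_node[node])
    }
    a <- pick(tree$merge[step, 1])
    b <- pick(tree$merge[step, 2])
    comp[b] <- a
    cluster_of_node[step] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  reps <- vapply(split(tree$labels, roots), min, character(1))
  ids <- setNames(seq_along(sort(reps)), sort(reps))
  out <- ids[reps[as.character(roots)]]
  setNames(as.integer(out), tree$labels)
}

#' Write a similarity matrix as TSV
#'
#' @param sim Similarity matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_similarity_tsv <- function(sim, path) {
  df <- data.frame(sample = rownames(sim), sim, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
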