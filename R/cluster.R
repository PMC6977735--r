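#' Hierarchical clustering of samples on expression or methylation features
#'
#' Dissimilarity is 1 minus the Pearson correlation over pairwise-complete
#' features (the common clustering convention for expression heat maps), or
#' Euclidean distance over the shared features of each sample pair rescaled
#' by completeness (`sqrt(n_features / n_shared)`), followed by
#' agglomeration with the chosen linkage. Supervised clustering is this same
#' procedure restricted to a supplied feature subset — subset the matrix rows
#' before calling.
#'
#' @param mat Numeric matrix, rows features, columns samples (named);
#'   `NA` entries are allowed and handled pairwise.
#' @param distance `"pearson"` (default) or `"euclidean"`.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An object of class `cluster_tree` wrapping the `hclust` result
#'   (fields labels, merge, height).
#' @export
hierarchical_cluster <- function(mat, distance = c("pearson", "euclidean"),
                                 linkage = c("average", "complete", "single")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (is.null(colnames(mat))) stop("`mat` needs sample column names", call. = FALSE)
  n <- ncol(mat)
  if (n < 2L) stop("at least two samples are required", call. = FALSE)
  obs <- !is.na(mat)
  shared <- crossprod(obs)
  off <- shared[upper.tri(shared)]
  if (any(off < 2L)) {
    idx <- which(upper.tri(shared) & shared < 2L, arr.ind = TRUE)[1, ]
    stop(sprintf("distance undefined: samples %s and %s share fewer than 2 features",
                 colnames(mat)[idx[1]], colnames(mat)[idx[2]]), call. = FALSE)
  }
  if (distance == "pearson") {
    d <- 1 - suppressWarnings(stats::cor(mat, use = "pairwise.complete.obs"))
    if (any(is.na(d))) {
      stop("distance undefined: constant sample over a shared feature set",
           call. = FALSE)
    }
  } else {
    d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        k <- obs[, i] & obs[, j]
        d[i, j] <- d[j, i] <-
          sqrt(sum((mat[k, i] - mat[k, j])^2) * nrow(mat) / sum(k))
      }
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  structure(list(hclust = hc, labels = hc$labels, merge = hc$merge,
                 height = hc$height), class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("cluster_tree: %d leaves, %d merges (method %s)\n",
              length(x$labels), nrow(x$merge), x$hclust$method))
  invisible(x)
}

#' Count tumor pairs that cluster together
#'
#' A pair is cohesive when its primary and recurrent samples are merged
#' directly with each other, i.e. are siblings at their first merge in the
#' tree — the strict reading of a pair clustering together in a tree
#' figure.
#'
#' @param tree A `cluster_tree` from [hierarchical_cluster()].
#' @param pair_map data.frame(pair_id, primary, recurrent) of leaf labels.
#' @return list(count, cohesive_pairs).
#' @export
pair_cohesion <- function(tree, pair_map) {
  i <- match(pair_map$primary, tree$labels)
  j <- match(pair_map$recurrent, tree$labels)
  if (any(is.na(i)) || any(is.na(j))) {
    stop("input error: pair sample missing from the tree", call. = FALSE)
  }
  sib <- vapply(seq_len(nrow(pair_map)), function(k) {
    any(tree$merge[, 1] == -i[k] & tree$merge[, 2] == -j[k]) ||
      any(tree$merge[, 1] == -j[k] & tree$merge[, 2] == -i[k])
  }, TRUE)
  list(count = sum(sib), cohesive_pairs = pair_map$pair_id[sib])
}

#' Write a cluster tree as Newick with merge heights as branch lengths
#' @param tree A `cluster_tree`.
#' @param path Output file.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree$hclust), file = path)
  invisible(path)
}
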