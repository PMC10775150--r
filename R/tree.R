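#' @include AllClasses.R
NULL

.treeSSE <- function(y) sum((y - mean(y))^2)

.bestSplit <- function(X, y, min_leaf) {
  n <- length(y)
  baseSSE <- .treeSSE(y)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    vals <- sort(unique(x))
    if (length(vals) < 2L) next
    thresholds <- (vals[-length(vals)] + vals[-1L]) / 2
    for (thr in thresholds) {
      left <- x <= thr
      nl <- sum(left)
      if (nl < min_leaf || n - nl < min_leaf) next
      sse <- .treeSSE(y[left]) + .treeSSE(y[!left])
      gain <- baseSSE - sse
      # ties -> first feature in column order, then smaller threshold;
      # both are the iteration order, so strict improvement is required
      if (gain > 1e-12 && (is.null(best) || gain > best$gain + 1e-12))
        best <- list(feature = j, threshold = thr, gain = gain)
    }
  }
  best
}

.growTree <- function(X, y, depth, max_depth, min_leaf) {
  node <- list(n = length(y), mean = mean(y), sse = .treeSSE(y),
               depth = depth)
  if (depth >= max_depth || length(y) < 2L * min_leaf ||
      node$sse < 1e-12) {
    node$leaf <- TRUE
    return(node)
  }
  sp <- .bestSplit(X, y, min_leaf)
  if (is.null(sp)) {
    node$leaf <- TRUE
    return(node)
  }
  node$leaf <- FALSE
  node$feature <- colnames(X)[sp$feature]
  node$featureIndex <- sp$feature
  node$threshold <- sp$threshold
  left <- X[, sp$feature] <= sp$threshold
  node$left <- .growTree(X[left, , drop = FALSE], y[left],
                         depth + 1L, max_depth, min_leaf)
  node$right <- .growTree(X[!left, , drop = FALSE], y[!left],
                          depth + 1L, max_depth, min_leaf)
  node
}

#' CART regression tree over descriptors
#'
#' Grows a binary regression tree by variance reduction: candidate
#' thresholds are the midpoints of sorted adjacent distinct feature
#' values; the split maximizing the decrease in total within-node sum of
#' squared errors wins, with ties broken by the first feature in column
#' order and then the smaller threshold. Growth stops at
#' \code{max_depth}, when a child would fall below \code{min_leaf}
#' samples, or when no split reduces the SSE. Left children satisfy
#' feature <= threshold.
#'
#' An optional classification mode thresholds the response first
#' (selective vs unselective at \code{class_cutoff}) and grows the same
#' tree on the 0/1 indicator.
#'
#' @param X numeric descriptor matrix or data.frame with column names.
#' @param y numeric response (e.g. ddG in kcal/mol).
#' @param max_depth maximum depth, default 3.
#' @param min_leaf minimum samples per leaf, default 5.
#' @param class_cutoff optional ddG cutoff for classification mode.
#' @return nested-list tree of class \code{"stericselTree"}; internal
#'   nodes carry \code{feature}, \code{threshold}, \code{left},
#'   \code{right}; every node carries \code{n}, \code{mean},
#'   \code{sse}, \code{depth}.
#' @export
regressionTree <- function(X, y, max_depth = 3L, min_leaf = 5L,
                           class_cutoff = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) != nrow(X)) stop("X and y sizes disagree")
  if (length(y) < 2L * min_leaf)
    stop("need at least 2 * min_leaf samples")
  if (!is.null(class_cutoff)) y <- as.numeric(y <= class_cutoff)
  tree <- .growTree(X, y, 0L, max_depth, min_leaf)
  class(tree) <- "stericselTree"
  tree
}

#' Predict from a regression tree
#'
#' @param object a \code{"stericselTree"}.
#' @param newdata matrix or data.frame with the columns used at fit
#'   time.
#' @param ... unused.
#' @return numeric vector of leaf means.
#' @method predict stericselTree
#' @export
predict.stericselTree <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  one <- function(node, row) {
    while (!node$leaf) {
      node <- if (X[row, node$feature] <= node$threshold)
        node$left else node$right
    }
    node$mean
  }
  vapply(seq_len(nrow(X)), function(i) one(object, i), numeric(1))
}

#' @export
print.stericselTree <- function(x, ...) {
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(sprintf("%sleaf: mean = %.3f (n = %d)\n", pad, node$mean,
                  node$n))
    } else {
      cat(sprintf("%s%s <= %.4g ? (n = %d)\n", pad, node$feature,
                  node$threshold, node$n))
      rec(node$left, indent + 1L)
      rec(node$right, indent + 1L)
    }
  }
  rec(x, 0L)
  invisible(x)
}

#' Total SSE of tree predictions on a dataset
#'
#' @param tree a \code{"stericselTree"}.
#' @param X,y data the tree is evaluated on.
#' @return sum of squared errors.
#' @export
treeSSE <- function(tree, X, y) {
  sum((y - predict.stericselTree(tree, X))^2)
}

#' Export a tree as nested JSON
#'
#' @param tree a \code{"stericselTree"}.
#' @param path output path.
#' @return \code{path} invisibly.
#' @export
writeTreeJson <- function(tree, path) {
  strip <- function(node) {
    if (node$leaf)
      list(leaf = TRUE, mean = node$mean, n = node$n)
    else
      list(leaf = FALSE, feature = node$feature,
           threshold = node$threshold, n = node$n,
           left = strip(node$left), right = strip(node$right))
  }
  jsonlite::write_json(strip(tree), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
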