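#' @include AllClasses.R metrics.R
NULL

#' Principal-component chemical space map
#'
#' PCA on z-scored columns (descriptors carry incomparable units), with
#' a deterministic sign convention: the largest-magnitude element of
#' each loading vector is positive. Zero-variance columns are dropped
#' with a message. Explained variance is reported as percentages over
#' all retained PCs (summing to 100).
#'
#' @param X numeric matrix or data.frame of descriptors.
#' @param n_components number of PCs kept in the scores, default 2.
#' @return a \linkS4class{ChemSpaceMap}.
#' @export
pcaMap <- function(X, n_components = 2L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need more than one row for PCA")
  if (anyNA(X)) stop("missing values not allowed")
  sdv <- apply(X, 2L, stats::sd)
  drop <- sdv <= 1e-12
  if (any(drop))
    message(sum(drop), " zero-variance column(s) dropped: ",
            paste(colnames(X)[drop], collapse = ", "))
  X <- X[, !drop, drop = FALSE]
  mu <- colMeans(X); sdv <- sdv[!drop]
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  expl <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  rot <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  n_components <- min(n_components, ncol(scores))
  new("ChemSpaceMap",
      loadings = rot,
      scores = scores[, seq_len(n_components), drop = FALSE],
      explained = expl,
      columns = colnames(X),
      scaling = list(center = mu, scale = sdv))
}

#' K-means clustering with per-cluster response ranges
#'
#' Lloyd's algorithm, best of \code{n_init} seeded random
#' initializations by within-cluster sum of squares (inertia). An
#' emptied cluster is re-seeded at the point farthest from its assigned
#' centroid. Labels are 1-based. When a response vector is supplied,
#' per-cluster [min, max] response ranges are reported alongside the
#' counts, mirroring range annotations on selectivity maps.
#'
#' @param X numeric matrix of coordinates (e.g. PC scores or the raw
#'   descriptor block).
#' @param k number of clusters, default 5.
#' @param n_init random restarts, default 10.
#' @param seed integer seed, default 2023.
#' @param response optional numeric response per row.
#' @param max_iter Lloyd iteration cap per start, default 100.
#' @return list with \code{labels}, \code{k}, \code{inertia},
#'   \code{centers} and (when a response is given) \code{ranges}, a
#'   data.frame with cluster, n, min, max.
#' @export
kmeansCluster <- function(X, k = 5L, n_init = 10L, seed = 2023L,
                          response = NULL, max_iter = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("k must not exceed the number of points")
  best <- NULL
  starts <- .withSeed(seed, lapply(seq_len(n_init), function(i)
    sample.int(n, k)))
  for (init in starts) {
    centers <- X[init, , drop = FALSE]
    labels <- rep(0L, n)
    for (it in seq_len(max_iter)) {
      d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centers) +
        outer(rep(1, n), rowSums(centers^2))
      newLabels <- max.col(-d2, ties.method = "first")
      # empty cluster: re-seed at the point farthest from its centroid
      for (c in seq_len(k)) {
        if (!any(newLabels == c)) {
          far <- which.max(d2[cbind(seq_len(n), newLabels)])
          centers[c, ] <- X[far, ]
          newLabels[far] <- c
        }
      }
      if (identical(newLabels, labels)) break
      labels <- newLabels
      for (c in seq_len(k))
        centers[c, ] <- colMeans(X[labels == c, , drop = FALSE])
    }
    inertia <- sum((X - centers[labels, , drop = FALSE])^2)
    if (is.null(best) || inertia < best$inertia - 1e-12)
      best <- list(labels = labels, inertia = inertia, centers = centers)
  }
  out <- list(labels = best$labels, k = as.integer(k),
              inertia = best$inertia, centers = best$centers)
  if (!is.null(response))
    out$ranges <- clusterResponseRanges(best$labels, response)
  out
}

#' Per-cluster response ranges
#'
#' Exact [min, max] of the response within each cluster, formatted the
#' way selectivity ranges are annotated on chemical-space maps.
#'
#' @param labels integer cluster labels (1-based).
#' @param response numeric response per sample.
#' @return data.frame with cluster, n, min, max and a formatted
#'   \code{range} string.
#' @export
clusterResponseRanges <- function(labels, response) {
  if (length(labels) != length(response))
    stop("labels and response must have equal length")
  cl <- sort(unique(labels))
  out <- data.frame(
    cluster = cl,
    n = vapply(cl, function(c) sum(labels == c), integer(1)),
    min = vapply(cl, function(c) min(response[labels == c]), numeric(1)),
    max = vapply(cl, function(c) max(response[labels == c]), numeric(1)))
  out$range <- sprintf("%.2f to %.2f", out$min, out$max)
  out
}
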