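#' @include AllClasses.R
NULL

#' Response-equidistant train/test split
#'
#' Selects \code{round(fraction * n)} training samples at equally spaced
#' response targets spanning [min(y), max(y)] inclusive: for each target
#' in order, the unassigned sample with minimal |y - target| is chosen
#' (ties go to the smaller y, then the smaller index). The minimum and
#' maximum of y always end up in training, so the model never
#' extrapolates on its own test set.
#'
#' A constant response carries no ordering information; the split then
#' falls back to index-stratified selection with a warning.
#'
#' @param y numeric response vector (length >= 4).
#' @param train_fraction fraction in (0, 1), default 0.5.
#' @return list with \code{method}, \code{train}, \code{test} (integer
#'   index vectors) and \code{params}.
#' @export
yEquidistantSplit <- function(y, train_fraction = 0.5) {
  n <- length(y)
  if (n < 4L) stop("need at least 4 samples to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  nTrain <- round(train_fraction * n)
  nTrain <- max(1L, min(n - 1L, nTrain))
  if (max(y) - min(y) < 1e-12) {
    warning("constant response; falling back to index-stratified split")
    train <- unique(round(seq(1L, n, length.out = nTrain)))
  } else {
    targets <- seq(min(y), max(y), length.out = nTrain)
    assigned <- rep(FALSE, n)
    train <- integer(nTrain)
    for (t in seq_len(nTrain)) {
      cand <- which(!assigned)
      dist <- abs(y[cand] - targets[t])
      o <- cand[order(dist, y[cand], cand)]
      train[t] <- o[1L]
      assigned[train[t]] <- TRUE
    }
    train <- sort(train)
  }
  list(method = "y_equidistant",
       train = train,
       test = setdiff(seq_len(n), train),
       params = list(train_fraction = train_fraction, n_train = nTrain))
}

#' Kennard-Stone maximin train/test split
#'
#' Classic deterministic coverage design on z-scored features: seed the
#' training set with the pair at maximal Euclidean distance, then
#' repeatedly add the point whose minimum distance to the selected set
#' is largest (ties go to the smaller index). Duplicate rows are allowed
#' (their distance is zero); a matrix whose rows are all identical has
#' no geometry to split on and is an error.
#'
#' @param X numeric feature matrix (rows = samples, n >= 4, complete).
#' @param train_fraction fraction in (0, 1) of rows selected for
#'   training.
#' @param zscore z-score columns before computing distances, default
#'   TRUE.
#' @return list with \code{method}, \code{train} (in selection order),
#'   \code{test} and \code{params}.
#' @export
kennardStoneSplit <- function(X, train_fraction = 0.5, zscore = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 samples to split")
  if (anyNA(X)) stop("missing values not allowed")
  if (train_fraction <= 0 || train_fraction > 1)
    stop("train_fraction must be in (0, 1]")
  nTrain <- max(2L, min(n, round(train_fraction * n)))
  if (zscore) {
    sdv <- apply(X, 2L, stats::sd)
    keep <- sdv > 1e-12
    if (!any(keep)) stop("all rows identical: Kennard-Stone undefined")
    X <- scale(X[, keep, drop = FALSE])
  }
  D <- as.matrix(stats::dist(X))
  if (max(D) < 1e-12) stop("all rows identical: Kennard-Stone undefined")
  # seed pair at maximal distance; ties -> smallest (i, j)
  hit <- which(D == max(D), arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  sel <- as.integer(hit[1L, ])
  while (length(sel) < nTrain) {
    rest <- setdiff(seq_len(n), sel)
    minD <- apply(D[rest, sel, drop = FALSE], 1L, min)
    best <- rest[order(-minD, rest)][1L]
    sel <- c(sel, best)
  }
  list(method = "kennard_stone",
       train = sel,
       test = setdiff(seq_len(n), sel),
       params = list(train_fraction = train_fraction, n_train = nTrain))
}
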