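#' @include AllClasses.R sisso-fit.R
NULL

# run expr with a local RNG seed, leaving the global stream untouched
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.olsFitPredict <- function(Xtr, ytr, Xte) {
  A <- cbind(1, Xtr)
  fit <- tryCatch(qr.solve(A, ytr), error = function(e) NULL)
  if (is.null(fit) || qr(A)$rank < ncol(A))
    fit <- as.numeric(MASS::ginv(A) %*% ytr)
  as.numeric(cbind(1, Xte) %*% fit)
}

#' Leave-one-out cross-validated Q-squared for a fixed feature set
#'
#' Refits ordinary least squares with each sample left out in turn
#' (the feature set itself is held fixed, not re-selected per fold) and
#' returns \eqn{Q^2 = 1 - \mathrm{PRESS}/\mathrm{TSS}}. A singular
#' leave-one-out design is handled by the Moore-Penrose pseudoinverse
#' with a message.
#'
#' @param X numeric matrix of the model's feature values (see
#'   \code{\link{modelFeatureValues}} for a fitted nonlinear model).
#' @param y response vector.
#' @return Q-squared (can be negative; never exceeds 1).
#' @export
loocvQ2 <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= ncol(X) + 1L) stop("need n > p + 1 for leave-one-out")
  press <- 0
  sing <- 0L
  for (i in seq_len(n)) {
    A <- cbind(1, X[-i, , drop = FALSE])
    qrA <- qr(A)
    if (qrA$rank < ncol(A)) {
      beta <- as.numeric(MASS::ginv(A) %*% y[-i])
      sing <- sing + 1L
    } else beta <- qr.coef(qrA, y[-i])
    pred <- sum(c(1, X[i, ]) * beta)
    press <- press + (y[i] - pred)^2
  }
  if (sing > 0L)
    message(sing, " leave-one-out fold(s) were singular; pseudoinverse used")
  1 - press / sum((y - mean(y))^2)
}

#' Pooled k-fold cross-validated R-squared
#'
#' One seeded shuffle assigns samples to k folds of near-equal size;
#' out-of-fold predictions from the fixed feature set are pooled and
#' \eqn{R^2 = 1 - \sum(y - \hat y)^2 / \sum(y - \bar y)^2} is computed
#' on the pool. With k = n this reproduces the leave-one-out
#' \code{\link{loocvQ2}}.
#'
#' @param X numeric feature matrix (fixed model form).
#' @param y response vector.
#' @param k number of folds, default 5.
#' @param seed integer seed for the fold shuffle, default 2023.
#' @return pooled cross-validated R-squared.
#' @export
kfoldR2 <- function(X, y, k = 5L, seed = 2023L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k) stop("need at least k samples")
  perm <- .withSeed(seed, sample.int(n))
  folds <- rep_len(seq_len(k), n)[order(perm)]
  pred <- numeric(n)
  for (f in seq_len(k)) {
    te <- which(folds == f)
    pred[te] <- .olsFitPredict(X[-te, , drop = FALSE], y[-te],
                               X[te, , drop = FALSE])
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Feature values of a fitted nonlinear model on raw descriptors
#'
#' Evaluates the model's expression trees (after applying the stored
#' base scaling) and returns the n x d feature-value matrix, e.g. for
#' cross-validating the selected feature set.
#'
#' @param model a \linkS4class{SissoModel}.
#' @param newdata matrix or data.frame of raw base descriptors.
#' @return numeric matrix with the canonical strings as column names.
#' @export
modelFeatureValues <- function(model, newdata) {
  stopifnot(is(model, "SissoModel"))
  X <- as.matrix(newdata)
  need <- names(model@baseScaling$mean)
  miss <- setdiff(need, colnames(X))
  if (length(miss))
    stop("missing base descriptor(s): ", paste(miss, collapse = ", "))
  Xz <- scale(X[, need, drop = FALSE],
              center = model@baseScaling$mean,
              scale = model@baseScaling$sd)
  F <- vapply(model@exprs, function(e) evalFeatureExpr(e, Xz),
              numeric(nrow(X)))
  F <- matrix(F, nrow = nrow(X))
  colnames(F) <- model@featureNames
  F
}

#' External / held-out validation metrics
#'
#' Predicts the external set and reports \code{r2_test} as the squared
#' Pearson correlation between predicted and observed (the convention of
#' external-validation plots in this literature), \code{r2_test_alt}
#' as 1 - SSE/SST, and \code{rmse_test} in response units.
#'
#' @param model a \linkS4class{SissoModel}, a
#'   \code{\link{fitLinearSubset}} result, or any object with a
#'   \code{predict} method/closure over raw descriptors.
#' @param newdata raw base-descriptor matrix or data.frame.
#' @param y observed response.
#' @return list with \code{r2_test}, \code{r2_test_alt},
#'   \code{rmse_test}, \code{n}.
#' @export
externalValidate <- function(model, newdata, y) {
  pred <- if (is(model, "SissoModel")) {
    predict(model, newdata)
  } else if (is.list(model) && is.function(model$predict)) {
    model$predict(newdata)
  } else stop("model must be a SissoModel or carry a predict closure")
  if (length(pred) != length(y))
    stop("prediction/observation length mismatch")
  r2 <- if (stats::sd(pred) < 1e-300 || stats::sd(y) < 1e-300) 0
        else stats::cor(pred, y)^2
  list(r2_test = r2,
       r2_test_alt = 1 - sum((y - pred)^2) / sum((y - mean(y))^2),
       rmse_test = sqrt(mean((y - pred)^2)),
       n = length(y))
}
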