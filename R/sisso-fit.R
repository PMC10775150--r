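#' @include AllClasses.R sisso-features.R reaction.R
NULL

#' Sure-independence screening
#'
#' Ranks features by absolute Pearson correlation with a target (usually
#' the residual of the current model) and returns the indices of the top
#' k. Ties are broken by lower complexity, then lexicographic canonical
#' string. Zero-variance features are excluded.
#'
#' @param values numeric feature matrix (columns = features).
#' @param target numeric vector (response or residual).
#' @param k number of features to keep.
#' @param complexity optional integer vector for tie-breaking.
#' @param strings optional character vector for tie-breaking.
#' @return integer vector of column indices, best first.
#' @export
sisScreen <- function(values, target, k, complexity = NULL,
                      strings = NULL) {
  p <- ncol(values)
  if (is.null(complexity)) complexity <- rep(1L, p)
  if (is.null(strings)) strings <- colnames(values)
  if (is.null(strings)) strings <- as.character(seq_len(p))
  r <- suppressWarnings(as.numeric(stats::cor(values, target)))
  ok <- which(is.finite(r))
  if (length(ok) < min(k, 1L)) stop("no finite-correlation features to screen")
  ord <- ok[order(-abs(r[ok]), complexity[ok], strings[ok])]
  utils::head(ord, k)
}

# exhaustive best subset of size d by explained sum of squares,
# using the Gram matrix G = t(Fz) %*% Fz and b = t(Fz) %*% yc.
# Returns list(idx, explained) or NULL if no valid subset.
.bestSubsetByGram <- function(G, b, yty, d, maxSubsets = 5e6,
                              detTol = 1e-9) {
  m <- length(b)
  if (m < d) return(NULL)
  if (choose(m, d) > maxSubsets)
    stop("exhaustive subset search over ", m, " features at dimension ",
         d, " exceeds maxSubsets; reduce sisSize or maxDimension")
  scale <- mean(diag(G))
  upper <- yty * (1 + 1e-6)
  if (d == 1L) {
    g <- diag(G)
    expl <- ifelse(g > detTol * scale, b^2 / g, -Inf)
    expl[expl > upper] <- -Inf
    i <- which.max(expl)
    if (!is.finite(expl[i])) return(NULL)
    return(list(idx = i, explained = expl[i]))
  }
  cmb <- utils::combn(m, d)
  if (d == 2L) {
    i <- cmb[1, ]; j <- cmb[2, ]
    a <- G[cbind(i, i)]; c2 <- G[cbind(j, j)]; g12 <- G[cbind(i, j)]
    det <- a * c2 - g12^2
    b1 <- b[i]; b2 <- b[j]
    expl <- (b1^2 * c2 - 2 * b1 * b2 * g12 + b2^2 * a) / det
    expl[!(det > detTol * scale^2) | expl > upper] <- -Inf
  } else if (d == 3L) {
    i <- cmb[1, ]; j <- cmb[2, ]; k <- cmb[3, ]
    a <- G[cbind(i, i)]; bb <- G[cbind(j, j)]; cc <- G[cbind(k, k)]
    dd <- G[cbind(i, j)]; e <- G[cbind(i, k)]; f <- G[cbind(j, k)]
    det <- a * (bb * cc - f^2) - dd * (dd * cc - f * e) +
      e * (dd * f - bb * e)
    A11 <- bb * cc - f^2
    A22 <- a * cc - e^2
    A33 <- a * bb - dd^2
    A12 <- -(dd * cc - e * f)
    A13 <- dd * f - e * bb
    A23 <- -(a * f - dd * e)
    b1 <- b[i]; b2 <- b[j]; b3 <- b[k]
    expl <- (b1^2 * A11 + b2^2 * A22 + b3^2 * A33 +
               2 * (b1 * b2 * A12 + b1 * b3 * A13 + b2 * b3 * A23)) / det
    expl[!(det > detTol * scale^3) | expl > upper] <- -Inf
  } else {
    expl <- rep(-Inf, ncol(cmb))
    for (s in seq_len(ncol(cmb))) {
      S <- cmb[, s]
      GS <- G[S, S]
      detS <- det(GS)
      if (!(detS > detTol * scale^d)) next
      beta <- tryCatch(solve(GS, b[S]), error = function(e) NULL)
      if (is.null(beta)) next
      ex <- sum(beta * b[S])
      if (is.finite(ex) && ex <= upper) expl[s] <- ex
    }
  }
  s <- which.max(expl)
  if (!is.finite(expl[s])) return(NULL)
  list(idx = cmb[, s], explained = expl[s])
}

.degenerateModel <- function(y, baseScaling, provenance) {
  new("SissoModel", exprs = list(), featureNames = character(),
      coefficients = numeric(), intercept = mean(y),
      baseScaling = baseScaling, dimension = 0L,
      metrics = list(r2_train = 0,
                     rmse_train = sqrt(mean((y - mean(y))^2)),
                     n = length(y)),
      provenance = provenance)
}

#' Fit sparse nonlinear models by screening and exhaustive subset search
#'
#' The base descriptors are z-scored and expanded with
#' \code{\link{expandFeatures}}. Round i screens the pool against the
#' residual of the best (i-1)-term model (round 1 screens against the
#' centered response) and adds the top \code{sisSize} features to the
#' candidate union, skipping near-duplicates (|r| above the config
#' threshold) of features already in the union. The best model of each
#' dimension d is then found by exhaustive ordinary least squares over
#' all d-subsets of the union. The whole search is deterministic.
#'
#' @param x a \linkS4class{ModelMatrix}, or a numeric base-descriptor
#'   matrix with named columns.
#' @param y response vector (ignored when \code{x} is a ModelMatrix).
#' @param config a \linkS4class{SissoConfig}.
#' @return list of \linkS4class{SissoModel}, element d holding the best
#'   d-term model, for d = 1 .. maxDimension. A constant response
#'   returns a single 0-term model with R2 = 0 by convention.
#' @export
fitSisso <- function(x, y = NULL, config = sissoConfig()) {
  if (is(x, "ModelMatrix")) {
    y <- response(x)
    X <- featureMatrix(x)
  } else X <- as.matrix(x)
  validObject(config)
  n <- nrow(X)
  D <- config@maxDimension
  if (n <= D + 1L) stop("need more rows than maxDimension + 1")

  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  keepCols <- sdv > 1e-12
  if (!all(keepCols))
    message(sum(!keepCols), " zero-variance base column(s) dropped")
  X <- X[, keepCols, drop = FALSE]
  mu <- mu[keepCols]; sdv <- sdv[keepCols]
  Xz <- scale(X, center = mu, scale = sdv)
  baseScaling <- list(mean = mu, sd = sdv)
  provenance <- list(rung = config@rung, sisSize = config@sisSize,
                     maxDimension = D, operators = config@operators,
                     n = n)

  if (stats::sd(y) < 1e-12) {
    return(list(.degenerateModel(y, baseScaling, provenance)))
  }

  pool <- expandFeatures(Xz, config)
  af <- activeFeatures(pool)
  F <- af$values
  fmu <- colMeans(F)
  fsd <- apply(F, 2L, stats::sd)
  Fz <- scale(F, center = fmu, scale = fsd)

  yc <- y - mean(y)
  tss <- sum(yc^2)

  union <- integer()       # indices into the active set
  models <- vector("list", D)
  residual <- yc
  for (d in seq_len(D)) {
    ranked <- sisScreen(F, residual, ncol(F), af$complexity, af$strings)
    added <- 0L
    for (cand in ranked) {
      if (added >= config@sisSize) break
      if (cand %in% union) next
      if (length(union)) {
        rr <- suppressWarnings(abs(stats::cor(Fz[, cand], Fz[, union])))
        if (any(rr > config@dedupR, na.rm = TRUE)) next
      }
      union <- c(union, cand)
      added <- added + 1L
    }
    G <- crossprod(Fz[, union, drop = FALSE])
    b <- as.numeric(crossprod(Fz[, union, drop = FALSE], yc))
    best <- .bestSubsetByGram(G, b, tss, d, config@maxSubsets)
    if (is.null(best)) {
      # no non-singular d-subset: keep the previous model for this slot
      models[[d]] <- models[[max(1L, d - 1L)]]
      next
    }
    S <- union[best$idx]
    betaZ <- solve(G[best$idx, best$idx, drop = FALSE], b[best$idx])
    coefFeat <- betaZ / fsd[S]
    intercept <- mean(y) - sum(coefFeat * fmu[S])
    fitted <- intercept + F[, S, drop = FALSE] %*% coefFeat
    rss <- sum((y - fitted)^2)
    r2 <- 1 - rss / tss
    exprs <- lapply(af$index[S], function(i) .extractExpr(pool, i))
    models[[d]] <- new("SissoModel",
      exprs = exprs,
      featureNames = pool$strings[af$index[S]],
      coefficients = as.numeric(coefFeat),
      intercept = intercept,
      baseScaling = baseScaling,
      dimension = as.integer(d),
      metrics = list(r2_train = r2, rmse_train = sqrt(rss / n), n = n),
      provenance = c(provenance,
                     list(pool_size = ncol(F),
                          union_size = length(union))))
    residual <- as.numeric(y - fitted)
  }
  models
}

#' Predict from a fitted sparse nonlinear model
#'
#' Evaluates the stored expression trees on raw (un-z-scored) base
#' descriptors using the scaling recorded at fit time, then applies the
#' stored linear coefficients. Deterministic; a missing base descriptor
#' column is a named error.
#'
#' @param object a \linkS4class{SissoModel}.
#' @param newdata matrix or data.frame of raw base descriptors.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
setMethod("predict", "SissoModel", function(object, newdata, ...) {
  X <- as.matrix(newdata)
  need <- names(object@baseScaling$mean)
  miss <- setdiff(need, colnames(X))
  if (length(miss))
    stop("missing base descriptor(s): ", paste(miss, collapse = ", "))
  Xz <- scale(X[, need, drop = FALSE],
              center = object@baseScaling$mean,
              scale = object@baseScaling$sd)
  yhat <- rep(object@intercept, nrow(X))
  for (i in seq_len(object@dimension))
    yhat <- yhat + object@coefficients[i] *
      evalFeatureExpr(object@exprs[[i]], Xz)
  as.numeric(yhat)
})

#' Best purely linear subset model
#'
#' Exhaustive ordinary least squares over all d-subsets of the raw base
#' descriptor columns (no nonlinear expansion), best by RMSE. The
#' baseline the nonlinear models are compared against.
#'
#' @param x a \linkS4class{ModelMatrix} or numeric matrix with named
#'   columns.
#' @param y response (ignored for a ModelMatrix).
#' @param d subset size.
#' @param maxSubsets search cap, default 5e6.
#' @return list with \code{columns}, \code{coefficients} (raw scale),
#'   \code{intercept}, \code{r2_train}, \code{rmse_train} and a
#'   \code{predict(newdata)} closure.
#' @export
fitLinearSubset <- function(x, y = NULL, d = 3L, maxSubsets = 5e6) {
  if (is(x, "ModelMatrix")) {
    y <- response(x)
    X <- featureMatrix(x)
  } else X <- as.matrix(x)
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  keep <- sdv > 1e-12
  X <- X[, keep, drop = FALSE]; mu <- mu[keep]; sdv <- sdv[keep]
  if (ncol(X) < d) stop("fewer usable columns than subset size d")
  Xz <- scale(X, center = mu, scale = sdv)
  yc <- y - mean(y)
  tss <- sum(yc^2)
  G <- crossprod(Xz)
  b <- as.numeric(crossprod(Xz, yc))
  best <- .bestSubsetByGram(G, b, tss, d, maxSubsets)
  if (is.null(best)) stop("no non-singular linear subset found")
  S <- best$idx
  betaZ <- solve(G[S, S, drop = FALSE], b[S])
  coefRaw <- betaZ / sdv[S]
  intercept <- mean(y) - sum(coefRaw * mu[S])
  cols <- colnames(X)[S]
  fitted <- intercept + X[, S, drop = FALSE] %*% coefRaw
  rss <- sum((y - fitted)^2)
  list(columns = cols,
       coefficients = stats::setNames(as.numeric(coefRaw), cols),
       intercept = intercept,
       r2_train = 1 - rss / tss,
       rmse_train = sqrt(rss / n),
       predict = function(newdata) {
         Xn <- as.matrix(newdata)[, cols, drop = FALSE]
         as.numeric(intercept + Xn %*% coefRaw)
       })
}

#' Export / import a fitted model as JSON
#'
#' The JSON carries the canonical feature strings, the expression trees,
#' coefficients, intercept, base-descriptor scaling and training
#' metrics; \code{readSissoModel} restores a fully functional model.
#'
#' @param model a \linkS4class{SissoModel}.
#' @param path output JSON path.
#' @return \code{path} invisibly (write) / a \linkS4class{SissoModel}
#'   (read).
#' @export
writeSissoModel <- function(model, path) {
  stopifnot(is(model, "SissoModel"))
  payload <- list(
    featureNames = model@featureNames,
    exprs = model@exprs,
    coefficients = model@coefficients,
    intercept = model@intercept,
    baseScaling = list(
      columns = names(model@baseScaling$mean),
      mean = unname(model@baseScaling$mean),
      sd = unname(model@baseScaling$sd)),
    dimension = model@dimension,
    metrics = model@metrics,
    provenance = model@provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.rebuildExpr <- function(e) {
  if (e$kind == "var") return(list(kind = "var", name = e$name))
  list(kind = "op", op = e$op, args = lapply(e$args, .rebuildExpr))
}

#' @rdname writeSissoModel
#' @export
readSissoModel <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  bs <- list(
    mean = stats::setNames(as.numeric(unlist(p$baseScaling$mean)),
                           unlist(p$baseScaling$columns)),
    sd = stats::setNames(as.numeric(unlist(p$baseScaling$sd)),
                         unlist(p$baseScaling$columns)))
  new("SissoModel",
      exprs = lapply(p$exprs, .rebuildExpr),
      featureNames = as.character(unlist(p$featureNames)),
      coefficients = as.numeric(unlist(p$coefficients)),
      intercept = as.numeric(p$intercept),
      baseScaling = bs,
      dimension = as.integer(p$dimension),
      metrics = lapply(p$metrics, function(v)
        if (is.numeric(v) || is.character(v)) v else unlist(v)),
      provenance = p$provenance)
}
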