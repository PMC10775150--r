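#' @include AllClasses.R
NULL

#' Construct a SISSO configuration
#'
#' @param rung operator-expansion depth, default 2.
#' @param operators operator subset; default
#'   \code{c("add","sub","mul","div","sq","inv","sqrt","abs")}. The
#'   exponential family is deliberately absent by default (purely
#'   algebraic expansion); pass e.g. \code{c(..., "exp")} is not
#'   supported.
#' @param sisSize screened pool size per round, default 50.
#' @param maxDimension largest model size searched, default 4.
#' @param dedupR absolute correlation above which two features count as
#'   duplicates, default 0.9999.
#' @param maxFeatures cap on the expanded feature count, default 2e5.
#' @param maxSubsets cap on the exhaustive subset search, default 5e6.
#' @return a \linkS4class{SissoConfig}.
#' @export
sissoConfig <- function(rung = 2L,
                        operators = c("add", "sub", "mul", "div",
                                      "sq", "inv", "sqrt", "abs"),
                        sisSize = 50L, maxDimension = 4L,
                        dedupR = 0.9999, maxFeatures = 200000L,
                        maxSubsets = 5e6) {
  new("SissoConfig", rung = as.integer(rung), operators = operators,
      sisSize = as.integer(sisSize),
      maxDimension = as.integer(maxDimension), dedupR = dedupR,
      maxFeatures = as.integer(maxFeatures), maxSubsets = maxSubsets)
}

# deterministic near-collinearity keys: sign-normalized z-scored column
# projected onto two fixed vectors. Identical keys => candidate exact
# duplicates (verified by correlation before dropping).
.collinearKeys <- function(V) {
  n <- nrow(V)
  mu <- colMeans(V)
  Vc <- sweep(V, 2L, mu)
  sdv <- sqrt(colSums(Vc^2) / n)
  Z <- sweep(Vc, 2L, pmax(sdv, 1e-300), `/`)
  # sign normalization: flip so the projection onto w1 is positive
  w1 <- sin(seq_len(n)); w2 <- cos(0.7 * seq_len(n))
  k1 <- colSums(Z * w1)
  flip <- ifelse(k1 < 0, -1, 1)
  # resolve k1 ~ 0 by the second projection
  k2 <- colSums(Z * w2)
  flip[abs(k1) < 1e-9] <- ifelse(k2[abs(k1) < 1e-9] < 0, -1, 1)
  k1 <- k1 * flip; k2 <- k2 * flip
  list(key = paste(round(k1, 6), round(k2, 6)), sd = sdv)
}

.emptyPool <- function(n) {
  list(values = matrix(numeric(0), nrow = n, ncol = 0),
       strings = character(), complexity = integer(),
       rung = integer(), op = character(),
       arg1 = integer(), arg2 = integer(), varname = character(),
       keys = character(), active = logical(),
       dropped_nonfinite = 0L, dropped_duplicate = 0L)
}

.appendPool <- function(pool, values, strings, complexity, rung, op,
                        arg1, arg2, varname, dedupR,
                        pairwise_limit = 3000L) {
  if (!length(strings)) return(pool)
  n <- nrow(values)
  # drop non-finite columns
  finite <- colSums(!is.finite(values)) == 0L
  pool$dropped_nonfinite <- pool$dropped_nonfinite + sum(!finite)
  # drop zero-variance columns
  if (any(finite)) {
    rng <- apply(values[, finite, drop = FALSE], 2L, function(v)
      max(v) - min(v))
    zv <- finite
    zv[finite] <- rng <= 1e-12
    finite <- finite & !zv
  }
  keep <- which(finite)
  if (!length(keep)) return(pool)
  # order candidates by (complexity, string) so dedup keeps the simpler
  keep <- keep[order(complexity[keep], strings[keep])]
  values <- values[, keep, drop = FALSE]
  strings <- strings[keep]; complexity <- complexity[keep]
  rung <- rung[keep]; op <- op[keep]
  arg1 <- arg1[keep]; arg2 <- arg2[keep]; varname <- varname[keep]

  # canonical-string dedup against pool and within batch
  dupStr <- duplicated(c(pool$strings, strings))[
    length(pool$strings) + seq_along(strings)]
  # exact-collinearity dedup via projection keys
  ck <- .collinearKeys(values)
  dupKey <- duplicated(c(pool$keys, ck$key))[
    length(pool$keys) + seq_along(strings)]
  drop <- dupStr | dupKey
  pool$dropped_duplicate <- pool$dropped_duplicate + sum(drop)
  if (all(drop)) return(pool)
  sel <- which(!drop)
  pool$values <- cbind(pool$values, values[, sel, drop = FALSE])
  pool$strings <- c(pool$strings, strings[sel])
  pool$complexity <- c(pool$complexity, complexity[sel])
  pool$rung <- c(pool$rung, rung[sel])
  pool$op <- c(pool$op, op[sel])
  pool$arg1 <- c(pool$arg1, arg1[sel])
  pool$arg2 <- c(pool$arg2, arg2[sel])
  pool$varname <- c(pool$varname, varname[sel])
  pool$keys <- c(pool$keys, ck$key[sel])
  pool$active <- c(pool$active, rep(TRUE, length(sel)))

  # full near-duplicate sweep only at tractable pool sizes; duplicates
  # are deactivated (hidden from screening and the model search), never
  # deleted, so expression-DAG argument indices stay valid
  p <- length(pool$strings)
  if (p <= pairwise_limit && dedupR < 1) {
    C <- suppressWarnings(stats::cor(pool$values))
    C[!is.finite(C)] <- 0
    for (j in seq_len(p)) {
      if (!pool$active[j]) next
      earlier <- which(pool$active[seq_len(j - 1L)])
      if (length(earlier) && any(abs(C[earlier, j]) > dedupR)) {
        pool$active[j] <- FALSE
        pool$dropped_duplicate <- pool$dropped_duplicate + 1L
      }
    }
  }
  pool
}

#' Expand base descriptors into a nonlinear feature pool
#'
#' Applies the operator set \{+, -, x, /, x^2, 1/x, sqrt(x), |x|\}
#' layer-by-layer up to the configured rung, starting from the base
#' columns. Features are deduplicated by canonical string (commutative
#' operands sorted) and by exact collinearity; columns producing any
#' non-finite value (division by zero, square root of a negative) are
#' dropped and counted. A near-duplicate sweep at |r| > \code{dedupR}
#' runs whenever the pool is small enough for the quadratic pass;
#' above that size, near-duplicates are pruned later within the
#' screened pools (where the exhaustive model search operates).
#'
#' The input matrix is expected z-scored; \code{\link{fitSisso}} does
#' this automatically.
#'
#' @param X numeric matrix of z-scored base descriptors with column
#'   names.
#' @param config a \linkS4class{SissoConfig}.
#' @return a feature pool: list with \code{values} (matrix),
#'   \code{strings} (canonical forms), \code{complexity}, \code{rung}
#'   and the internal expression DAG.
#' @export
expandFeatures <- function(X, config = sissoConfig()) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  validObject(config)
  if (any(!is.finite(X))) stop("base matrix must be finite")
  n <- nrow(X)
  ops <- config@operators
  pool <- .emptyPool(n)
  p0 <- ncol(X)
  pool <- .appendPool(pool, X, colnames(X), rep(1L, p0), rep(0L, p0),
                      rep("var", p0), rep(0L, p0), rep(0L, p0),
                      colnames(X), config@dedupR)

  unary <- intersect(ops, c("sq", "inv", "sqrt", "abs"))
  binary <- intersect(ops, c("add", "sub", "mul", "div"))

  for (r in seq_len(config@rung)) {
    act <- which(pool$active)
    m <- length(act)
    newIdx <- act[pool$rung[act] == r - 1L]
    if (!length(newIdx)) break
    # candidate count estimate against the cap (before computing values)
    nPairsNew <- choose(m, 2) - choose(m - length(newIdx), 2)
    est <- length(unary) * length(newIdx) +
      length(intersect(binary, c("add", "sub", "mul"))) * nPairsNew +
      ("div" %in% binary) * 2 * nPairsNew
    if (length(pool$strings) + est > config@maxFeatures)
      stop("feature expansion overflow: ~", est, " rung-", r,
           " candidates exceed maxFeatures = ", config@maxFeatures,
           "; reduce the rung, the operator set, or the base columns")

    V <- pool$values; S <- pool$strings
    CP <- pool$complexity; RG <- pool$rung

    cand <- list()
    addCand <- function(values, strings, comp, op, a1, a2, vn = NA_character_) {
      cand[[length(cand) + 1L]] <<- list(
        values = values, strings = strings, comp = comp,
        op = op, a1 = a1, a2 = a2,
        vn = rep(vn, length(strings)))
    }

    # operator domains: sqrt needs non-negative input; abs is the
    # identity on one-signed input; inverse and division require a
    # one-signed (never zero-crossing) denominator -- 1/x across a sign
    # change is unbounded and discontinuous, so such features are
    # leverage artifacts rather than smooth descriptor transforms
    colMin <- apply(V, 2L, min)
    colMax <- apply(V, 2L, max)
    oneSigned <- colMin * colMax > 0

    # unary ops on the newest layer
    for (u in unary) {
      idx <- newIdx
      if (u == "sqrt") idx <- idx[colMin[idx] >= 0]
      if (u == "abs") idx <- idx[colMin[idx] < 0]
      if (u == "inv") idx <- idx[oneSigned[idx]]
      if (!length(idx)) next
      vals <- switch(u,
        sq = V[, idx, drop = FALSE]^2,
        inv = 1 / V[, idx, drop = FALSE],
        sqrt = sqrt(V[, idx, drop = FALSE]),
        abs = abs(V[, idx, drop = FALSE]))
      addCand(vals, paste0(u, "(", S[idx], ")"), CP[idx] + 1L,
              rep(u, length(idx)), idx, rep(0L, length(idx)))
    }

    # binary ops: all active pairs touching the newest layer
    if (length(binary) && m >= 2L) {
      ii <- act[rep(seq_len(m - 1L), times = (m - 1L):1L)]
      jj <- act[sequence((m - 1L):1L) + rep(seq_len(m - 1L),
                                            times = (m - 1L):1L)]
      touch <- RG[ii] == r - 1L | RG[jj] == r - 1L
      ii <- ii[touch]; jj <- jj[touch]
      if (length(ii)) {
        si <- S[ii]; sj <- S[jj]
        lo <- ifelse(si <= sj, si, sj)
        hi <- ifelse(si <= sj, sj, si)
        comp <- CP[ii] + CP[jj] + 1L
        if ("add" %in% binary)
          addCand(V[, ii, drop = FALSE] + V[, jj, drop = FALSE],
                  paste0("(", lo, "+", hi, ")"), comp,
                  rep("add", length(ii)), ii, jj)
        if ("mul" %in% binary)
          addCand(V[, ii, drop = FALSE] * V[, jj, drop = FALSE],
                  paste0("(", lo, "*", hi, ")"), comp,
                  rep("mul", length(ii)), ii, jj)
        if ("sub" %in% binary)
          addCand(V[, ii, drop = FALSE] - V[, jj, drop = FALSE],
                  paste0("(", si, "-", sj, ")"), comp,
                  rep("sub", length(ii)), ii, jj)
        if ("div" %in% binary) {
          dok <- oneSigned[jj]
          if (any(dok))
            addCand(V[, ii[dok], drop = FALSE] / V[, jj[dok], drop = FALSE],
                    paste0("(", si[dok], "/", sj[dok], ")"), comp[dok],
                    rep("div", sum(dok)), ii[dok], jj[dok])
          dok <- oneSigned[ii]
          if (any(dok))
            addCand(V[, jj[dok], drop = FALSE] / V[, ii[dok], drop = FALSE],
                    paste0("(", sj[dok], "/", si[dok], ")"), comp[dok],
                    rep("div", sum(dok)), jj[dok], ii[dok])
        }
      }
    }
    if (!length(cand)) next
    values <- do.call(cbind, lapply(cand, `[[`, "values"))
    strings <- unlist(lapply(cand, `[[`, "strings"))
    comp <- unlist(lapply(cand, `[[`, "comp"))
    op <- unlist(lapply(cand, `[[`, "op"))
    a1 <- unlist(lapply(cand, `[[`, "a1"))
    a2 <- unlist(lapply(cand, `[[`, "a2"))
    vn <- unlist(lapply(cand, `[[`, "vn"))
    pool <- .appendPool(pool, values, strings, comp,
                        rep(r, length(strings)), op, a1, a2, vn,
                        config@dedupR)
    if (length(pool$strings) > config@maxFeatures)
      stop("feature expansion overflow: pool size ",
           length(pool$strings), " exceeds maxFeatures = ",
           config@maxFeatures)
  }
  colnames(pool$values) <- pool$strings
  pool
}

# extract a self-contained expression tree for pool feature idx
.extractExpr <- function(pool, idx) {
  if (pool$op[idx] == "var")
    return(list(kind = "var", name = pool$varname[idx]))
  a1 <- .extractExpr(pool, pool$arg1[idx])
  if (pool$op[idx] %in% c("sq", "inv", "sqrt", "abs"))
    return(list(kind = "op", op = pool$op[idx], args = list(a1)))
  a2 <- .extractExpr(pool, pool$arg2[idx])
  list(kind = "op", op = pool$op[idx], args = list(a1, a2))
}

#' Active features of an expanded pool
#'
#' Returns the usable (non-duplicate) features of a pool produced by
#' \code{\link{expandFeatures}}.
#'
#' @param pool a feature pool.
#' @return list with \code{values}, \code{strings}, \code{complexity},
#'   \code{rung} and \code{index} (positions in the full pool).
#' @export
activeFeatures <- function(pool) {
  idx <- which(pool$active)
  list(values = pool$values[, idx, drop = FALSE],
       strings = pool$strings[idx],
       complexity = pool$complexity[idx],
       rung = pool$rung[idx],
       index = idx)
}

#' Evaluate a feature expression tree on (z-scored) base descriptors
#'
#' @param expr expression tree (as stored in a
#'   \linkS4class{SissoModel}).
#' @param X matrix or data.frame of z-scored base descriptor columns.
#' @return numeric vector of feature values.
#' @export
evalFeatureExpr <- function(expr, X) {
  if (expr$kind == "var") {
    if (!expr$name %in% colnames(X))
      stop("missing base descriptor: ", expr$name)
    return(as.numeric(X[, expr$name]))
  }
  a <- evalFeatureExpr(expr$args[[1L]], X)
  switch(expr$op,
    sq = a^2,
    inv = 1 / a,
    sqrt = sqrt(a),
    abs = abs(a),
    add = a + evalFeatureExpr(expr$args[[2L]], X),
    sub = a - evalFeatureExpr(expr$args[[2L]], X),
    mul = a * evalFeatureExpr(expr$args[[2L]], X),
    div = a / evalFeatureExpr(expr$args[[2L]], X),
    stop("unknown operator: ", expr$op))
}

#' Canonical string of a feature expression tree
#'
#' Commutative operands are sorted, so algebraically identical trees
#' print identically.
#'
#' @param expr expression tree.
#' @return character scalar.
#' @export
featureExprString <- function(expr) {
  if (expr$kind == "var") return(expr$name)
  if (expr$op %in% c("sq", "inv", "sqrt", "abs"))
    return(paste0(expr$op, "(", featureExprString(expr$args[[1L]]), ")"))
  a <- featureExprString(expr$args[[1L]])
  b <- featureExprString(expr$args[[2L]])
  sym <- c(add = "+", sub = "-", mul = "*", div = "/")[[expr$op]]
  if (expr$op %in% c("add", "mul") && b < a) { tmp <- a; a <- b; b <- tmp }
  paste0("(", a, sym, b, ")")
}
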