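test_that("rung-1 expansion enumerates the documented feature set", {
  X <- baseMatrix(10, 2)
  pool <- expandFeatures(X, sissoConfig(rung = 1,
                                        operators = c("add", "mul")))
  expect_setequal(activeFeatures(pool)$strings,
                  c("x1", "x2", "(x1+x2)", "(x1*x2)"))

  # a perfectly collinear base column is pruned to one survivor
  X2 <- cbind(x = X[, 1], x2 = 2 * X[, 1])
  pool2 <- expandFeatures(X2, sissoConfig(rung = 0))
  expect_equal(length(activeFeatures(pool2)$strings), 1L)
})

test_that("full-operator rung-1 count matches a brute-force enumerator", {
  # positive base columns so every operator domain is open
  X <- baseMatrix(12, 5, seed = 3, positive = TRUE)
  pool <- expandFeatures(X, sissoConfig(rung = 1))
  got <- sort(activeFeatures(pool)$strings)

  # independent enumeration under the same documented rules:
  # vars; sq/inv/sqrt on any (abs is the identity on one-signed input);
  # +, *, - on unordered pairs; / on ordered pairs (one-signed input)
  v <- colnames(X)
  exp_strings <- c(v,
                   paste0("sq(", v, ")"), paste0("inv(", v, ")"),
                   paste0("sqrt(", v, ")"))
  for (i in 1:4) for (j in (i + 1):5) {
    a <- sort(c(v[i], v[j]))
    exp_strings <- c(exp_strings,
                     paste0("(", a[1], "+", a[2], ")"),
                     paste0("(", a[1], "*", a[2], ")"),
                     paste0("(", v[i], "-", v[j], ")"),
                     paste0("(", v[i], "/", v[j], ")"),
                     paste0("(", v[j], "/", v[i], ")"))
  }
  expect_setequal(got, sort(unique(exp_strings)))
})

test_that("division and inverse require one-signed denominators", {
  X <- baseMatrix(30, 2, seed = 5)  # sign-crossing z-like columns
  pool <- expandFeatures(X, sissoConfig(rung = 1,
                                        operators = c("div", "inv")))
  expect_false(any(grepl("inv\\(x", activeFeatures(pool)$strings)))
  expect_false(any(grepl("/", activeFeatures(pool)$strings)))
})

test_that("expansion overflow raises an instructive error", {
  X <- baseMatrix(20, 8, seed = 2)
  expect_error(
    expandFeatures(X, sissoConfig(rung = 2, maxFeatures = 500L)),
    "overflow")
})

test_that("screening ranks by |r| with complexity tie-breaks", {
  set.seed(11)
  n <- 200
  F <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(NULL, sprintf("f%02d", 1:20)))
  y <- F[, 3]
  top <- sisScreen(F, y, 5)
  expect_equal(top[1], 3L)
  expect_equal(abs(cor(F[, 3], y)), 1)

  # planted r = 0.9 feature outranks noise
  yp <- 0.9 * scale(F[, 7]) + sqrt(1 - 0.81) * scale(rnorm(n))
  expect_equal(sisScreen(F, as.numeric(yp), 1), 7L)

  # identical |r|, different complexity: the simpler wins
  F2 <- cbind(a = F[, 1], b = F[, 1])
  expect_equal(sisScreen(F2, F[, 1], 2, complexity = c(5L, 1L),
                         strings = c("a", "b")),
               c(2L, 1L))

  # top-1 equals the brute-force |r| maximizer on a big pool
  Fbig <- matrix(rnorm(50 * 3000), 50, 3000)
  colnames(Fbig) <- sprintf("g%04d", 1:3000)
  yy <- rnorm(50)
  brute <- which.max(abs(cor(Fbig, yy)))
  expect_equal(sisScreen(Fbig, yy, 1), as.integer(brute))
})

test_that("noiseless planted targets are recovered exactly", {
  X <- baseMatrix(60, 5, seed = 7)
  X <- scale(X); attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL

  # single product term
  y1 <- as.numeric(X[, 1] * X[, 2])
  m1 <- fitSisso(X, y1, sissoConfig(rung = 1, maxDimension = 1,
                                    sisSize = 20))[[1]]
  expect_equal(m1@featureNames, "(x1*x2)")
  expect_equal(m1@metrics$r2_train, 1, tolerance = 1e-10)

  # linear plus square
  y2 <- as.numeric(2 * X[, 1] + 3 * X[, 2]^2)
  m2 <- fitSisso(X, y2, sissoConfig(rung = 1, maxDimension = 2,
                                    sisSize = 20))[[2]]
  expect_setequal(m2@featureNames, c("x1", "sq(x2)"))
  co <- m2@coefficients[order(m2@featureNames)]
  expect_equal(unname(co), c(3, 2), tolerance = 1e-8)
  expect_equal(m2@metrics$r2_train, 1, tolerance = 1e-10)

  # constant response: 0-term model, R2 = 0 by convention, no crash
  m0 <- fitSisso(X, rep(2.5, 60), sissoConfig(rung = 1))[[1]]
  expect_equal(m0@dimension, 0L)
  expect_equal(m0@metrics$r2_train, 0)
  expect_equal(predict(m0, X), rep(2.5, 60))
})

test_that("training RMSE never increases with model dimension", {
  set.seed(21)
  X <- baseMatrix(80, 5, seed = 21)
  y <- X[, 1] + 0.5 * X[, 2] * X[, 3] + rnorm(80, sd = 0.3)
  ms <- fitSisso(X, y, sissoConfig(rung = 1, maxDimension = 3,
                                   sisSize = 15))
  rmse <- sapply(ms, function(m) m@metrics$rmse_train)
  expect_true(all(diff(rmse) <= 1e-12))
})

test_that("predictions are consistent, portable, and deterministic", {
  X <- baseMatrix(60, 4, seed = 9)
  y <- as.numeric(1 + 2 * scale(X[, 1]) * scale(X[, 2]))
  m <- fitSisso(X, y, sissoConfig(rung = 1, maxDimension = 1,
                                  sisSize = 10))[[1]]
  # training rows re-predicted reproduce stored fitted values
  expect_equal(predict(m, X), y, tolerance = 1e-10)

  # external row evaluated by hand through the stored pipeline
  newrow <- matrix(c(0.3, -1.1, 0.2, 0.5), 1,
                   dimnames = list(NULL, colnames(X)))
  z <- (newrow - m@baseScaling$mean) / m@baseScaling$sd
  hand <- m@intercept + m@coefficients[1] * z[1] * z[2]
  expect_equal(predict(m, newrow), as.numeric(hand), tolerance = 1e-10)

  # missing descriptor is a named error
  expect_error(predict(m, newrow[, 1:2, drop = FALSE]), "x")

  # byte-identical model JSON across reruns
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  writeSissoModel(m, f1)
  m2 <- fitSisso(X, y, sissoConfig(rung = 1, maxDimension = 1,
                                   sisSize = 10))[[1]]
  writeSissoModel(m2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # JSON round trip restores a working model
  mr <- readSissoModel(f1)
  expect_equal(predict(mr, X), predict(m, X), tolerance = 1e-12)
  expect_equal(mr@featureNames, m@featureNames)
})

test_that("canonical strings normalize commutative operand order", {
  e1 <- list(kind = "op", op = "mul", args = list(
    list(kind = "var", name = "b"), list(kind = "var", name = "a")))
  expect_equal(featureExprString(e1), "(a*b)")
  e2 <- list(kind = "op", op = "sub", args = list(
    list(kind = "var", name = "b"), list(kind = "var", name = "a")))
  expect_equal(featureExprString(e2), "(b-a)")
})
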