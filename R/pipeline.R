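#' @include fixtures.R sisso-fit.R splits.R metrics.R chemspace.R tree.R
NULL

#' Replicated planted-benchmark evaluation
#'
#' Runs the full modeling workflow once per seed on the planted
#' catalyst x substrate benchmark: generate the benchmark, split 50%
#' (or as configured) by the response-equidistant rule, fit the
#' nonlinear model by screening + exhaustive subset search, and fit the
#' best purely linear subset model of the same size on the raw base
#' descriptors. Reports per-seed training R2, leave-one-out Q2 of the
#' selected feature set, held-out test R2 (squared Pearson correlation)
#' and the linear baseline's training R2.
#'
#' @param seeds integer vector of benchmark seeds, default 1:20.
#' @param train_fraction response-equidistant training fraction,
#'   default 0.5.
#' @param rung,sisSize,dimension nonlinear search settings, defaults
#'   2 / 50 / 3.
#' @param ... passed to \code{\link{makePlantedBenchmark}}.
#' @return data.frame with one row per seed: \code{seed},
#'   \code{r2_train_sisso}, \code{q2_loocv}, \code{r2_test_sisso},
#'   \code{r2_train_linear}.
#' @export
plantedBenchmarkStudy <- function(seeds = 1:20, train_fraction = 0.5,
                                  rung = 2L, sisSize = 50L,
                                  dimension = 3L, ...) {
  cfg <- sissoConfig(rung = rung, sisSize = sisSize,
                     maxDimension = dimension)
  res <- lapply(seeds, function(s) {
    bench <- makePlantedBenchmark(seed = s, ...)
    X <- featureMatrix(bench$matrix)
    y <- response(bench$matrix)
    sp <- yEquidistantSplit(y, train_fraction)
    Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
    Xte <- X[sp$test, , drop = FALSE]; yte <- y[sp$test]
    models <- fitSisso(Xtr, ytr, cfg)
    m <- models[[dimension]]
    lin <- fitLinearSubset(Xtr, ytr, d = dimension)
    data.frame(
      seed = s,
      r2_train_sisso = m@metrics$r2_train,
      q2_loocv = loocvQ2(modelFeatureValues(m, Xtr), ytr),
      r2_test_sisso = externalValidate(m, Xte, yte)$r2_test,
      r2_train_linear = lin$r2_train)
  })
  do.call(rbind, res)
}

.configHash <- function(config) {
  config$output_dir <- NULL  # hash the science, not the artifact path
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  # small deterministic rolling hash; enough to stamp outputs
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Default pipeline configuration
#'
#' @param output_dir artifact directory.
#' @param seed global seed.
#' @return nested configuration list accepted by
#'   \code{\link{runPipeline}}.
#' @export
defaultPipelineConfig <- function(output_dir = tempfile("stericsel_run_"),
                                  seed = 1L) {
  list(
    output_dir = output_dir,
    seed = seed,
    benchmark = list(n_catalysts = 18L, n_substrates = 5L,
                     n_withheld = 4L, signal_fraction = 0.95,
                     linear_share = 0.35),
    split = list(method = "yequidistant", fraction = 0.5),
    sisso = list(rung = 2L, sis = 50L, dim = 3L),
    linear = list(dim = 3L),
    chemspace = list(k = 5L, n_init = 10L, n_components = 2L,
                     kmeans_on = "parameters"),
    tree = list(max_depth = 3L, min_leaf = 5L))
}

#' Read a pipeline configuration from YAML
#'
#' Missing sections inherit the defaults of
#' \code{\link{defaultPipelineConfig}}. Referenced input files (when the
#' config points at CSV tables instead of the synthetic benchmark) are
#' checked for existence at validation time.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- defaultPipelineConfig()
  for (k in names(base))
    if (is.null(cfg[[k]])) cfg[[k]] <- base[[k]]
    else if (is.list(base[[k]]))
      for (kk in names(base[[k]]))
        if (is.null(cfg[[k]][[kk]])) cfg[[k]][[kk]] <- base[[k]][[kk]]
  if (!is.null(cfg$inputs)) {
    for (f in unlist(cfg$inputs))
      if (!file.exists(f)) stop("config input file not found: ", f)
  }
  cfg
}

#' Run the end-to-end modeling pipeline
#'
#' Orchestrates the workflow: assemble the reaction model matrix (from
#' CSV inputs named in \code{config$inputs}, or from the synthetic
#' planted benchmark), split train/test, fit the best linear subset
#' model and the nonlinear screened model, cross-validate, build the
#' principal-component chemical space map with K-means cluster
#' selectivity ranges, grow a regression tree over the base descriptors,
#' and write every artifact plus a human-readable report into
#' \code{config$output_dir}. Deterministic under a fixed config; the
#' config hash and package version are stamped into every JSON artifact.
#'
#' @param config nested list, see \code{\link{defaultPipelineConfig}},
#'   or a YAML path.
#' @return invisibly, a list with the fitted objects and the metrics.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  for (sec in c("output_dir", "seed", "split", "sisso", "tree"))
    if (is.null(config[[sec]]))
      stop("pipeline config is missing the '", sec, "' section")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(package = "stericsel",
                version = as.character(utils::packageVersion("stericsel")),
                config_hash = .configHash(config))
  outj <- function(x, name) jsonlite::write_json(
    c(stamp, x), file.path(config$output_dir, name),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  log <- character()
  say <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
    message(line)
  }

  # stage 1: model matrix
  if (!is.null(config$inputs)) {
    rx <- readReactionTable(config$inputs$reactions)
    ct <- readDescriptorTable(config$inputs$catalyst_descriptors)
    st <- readDescriptorTable(config$inputs$substrate_descriptors)
    mm <- buildModelMatrix(rx, ct, st)
    say("matrix: %d reactions x %d descriptors from CSV inputs",
        nrow(featureMatrix(mm)), ncol(featureMatrix(mm)))
  } else {
    bench <- do.call(makePlantedBenchmark,
                     c(config$benchmark, list(seed = config$seed)))
    mm <- bench$matrix
    say("matrix: %d synthetic reactions x %d descriptors (seed %d)",
        nrow(featureMatrix(mm)), ncol(featureMatrix(mm)), config$seed)
  }
  X <- featureMatrix(mm); y <- response(mm)
  utils::write.csv(data.frame(catalyst_id = mm@catalystId,
                              substrate_id = mm@substrateId,
                              ddg_kcal_mol = y, X,
                              check.names = FALSE),
                   file.path(config$output_dir, "matrix.csv"),
                   row.names = FALSE)

  # stage 2: split
  sp <- if (identical(config$split$method, "kennardstone"))
    kennardStoneSplit(X, config$split$fraction)
  else yEquidistantSplit(y, config$split$fraction)
  say("split: %s, %d train / %d test", sp$method, length(sp$train),
      length(sp$test))
  outj(sp, "split.json")
  Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
  Xte <- X[sp$test, , drop = FALSE]; yte <- y[sp$test]

  # stage 3: linear baseline
  lin <- fitLinearSubset(Xtr, ytr, d = config$linear$dim)
  linExt <- externalValidate(lin, Xte, yte)
  say("linear %d-term: train R2 = %.3f, test R2 = %.3f",
      config$linear$dim, lin$r2_train, linExt$r2_test)
  outj(list(columns = lin$columns, coefficients = lin$coefficients,
            intercept = lin$intercept, r2_train = lin$r2_train,
            rmse_train = lin$rmse_train, r2_test = linExt$r2_test),
       "linear_model.json")

  # stage 4: nonlinear model
  cfgS <- sissoConfig(rung = config$sisso$rung,
                      sisSize = config$sisso$sis,
                      maxDimension = config$sisso$dim)
  models <- fitSisso(Xtr, ytr, cfgS)
  m <- models[[length(models)]]
  Ftr <- modelFeatureValues(m, Xtr)
  ext <- externalValidate(m, Xte, yte)
  metrics <- list(
    r2_train = m@metrics$r2_train,
    rmse_train = m@metrics$rmse_train,
    q2_loocv = loocvQ2(Ftr, ytr),
    r2_fivefold = kfoldR2(Ftr, ytr, k = 5L, seed = config$seed),
    r2_test = ext$r2_test,
    rmse_test = ext$rmse_test,
    r2_train_linear = lin$r2_train,
    r2_test_linear = linExt$r2_test)
  say(paste0("nonlinear %d-term: train R2 = %.3f, Q2 = %.3f, ",
             "fivefold R2 = %.3f, test R2 = %.3f"),
      m@dimension, metrics$r2_train, metrics$q2_loocv,
      metrics$r2_fivefold, metrics$r2_test)
  writeSissoModel(m, file.path(config$output_dir, "sisso_model.json"))
  outj(metrics, "metrics.json")

  # stage 5: chemical space deconvolution on the model's parameters
  F <- modelFeatureValues(m, X)
  map <- pcaMap(F, n_components = config$chemspace$n_components)
  kmX <- if (identical(config$chemspace$kmeans_on, "scores"))
    map@scores else scale(F)
  km <- kmeansCluster(kmX, k = config$chemspace$k,
                      n_init = config$chemspace$n_init,
                      seed = config$seed, response = y)
  say("chemspace: PC1+PC2 explain %.1f%%; k = %d clusters",
      sum(map@explained[1:min(2, length(map@explained))]), km$k)
  outj(list(explained_pct = map@explained,
            loadings = as.data.frame(map@loadings),
            scores = as.data.frame(map@scores),
            labels = km$labels, inertia = km$inertia,
            ranges = km$ranges), "chemspace.json")

  # stage 6: regression tree over the base descriptors
  tr <- regressionTree(X, y, max_depth = config$tree$max_depth,
                       min_leaf = config$tree$min_leaf)
  say("tree: root %s, SSE %.3f -> %.3f",
      if (tr$leaf) "(leaf)" else sprintf("%s <= %.3g", tr$feature,
                                         tr$threshold),
      tr$sse, treeSSE(tr, X, y))
  writeTreeJson(tr, file.path(config$output_dir, "tree.json"))

  writeLines(c(sprintf("stericsel %s run %s", stamp$version,
                       stamp$config_hash), log),
             file.path(config$output_dir, "report.txt"))
  invisible(list(matrix = mm, split = sp, linear = lin, models = models,
                 metrics = metrics, map = map, clusters = km, tree = tr))
}
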