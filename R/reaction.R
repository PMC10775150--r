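#' @include AllClasses.R geometry-io.R
NULL

#' Convert a diastereomeric ratio to an activation free-energy difference
#'
#' Transition-state arithmetic: \eqn{\Delta\Delta G^\ddagger = -RT
#' \ln(\mathrm{syn}/\mathrm{anti})} with R = 1.98720425e-3 kcal/(mol K),
#' so a syn-major ratio gives a negative value (more negative = more
#' syn-selective). Fully selective ratios (syn = 0 or anti = 0) return
#' signed infinities; treat them as censored bounds, not measurements.
#'
#' @param syn,anti non-negative counts or fractions, syn + anti > 0.
#'   Vectorized.
#' @param temperature Kelvin, default 298.15.
#' @return ddG in kcal/mol (may be +/- Inf for censored ratios).
#' @export
#' @examples
#' ddgFromDr(97, 3)   # about -2.06 kcal/mol
ddgFromDr <- function(syn, anti, temperature = 298.15) {
  if (any(syn < 0) || any(anti < 0))
    stop("syn and anti must be non-negative")
  if (any(syn + anti <= 0)) stop("syn + anti must be positive")
  if (any(temperature <= 0)) stop("temperature must be positive (K)")
  -.Rgas * temperature * log(syn / anti)
}

#' Convert an activation free-energy difference to a syn fraction
#'
#' Exact inverse of \code{\link{ddgFromDr}}: returns
#' syn / (syn + anti).
#'
#' @param ddg kcal/mol, finite. Vectorized.
#' @param temperature Kelvin, default 298.15.
#' @return syn fraction in (0, 1).
#' @export
drFromDdg <- function(ddg, temperature = 298.15) {
  if (any(temperature <= 0)) stop("temperature must be positive (K)")
  ratio <- exp(-ddg / (.Rgas * temperature))
  ratio / (1 + ratio)
}

#' Read a reaction table from CSV
#'
#' Required columns: \code{catalyst_id}, \code{substrate_id},
#' \code{syn}, \code{anti}. Optional: \code{temperature_K} (default
#' 298.15 when absent and \code{strict = FALSE}; required when
#' \code{strict = TRUE}) and \code{ddg_kcal_mol} (used verbatim when
#' present, otherwise derived via \code{\link{ddgFromDr}}). Fully
#' selective ratios are flagged \code{censored} and carry infinite ddG
#' bounds; they are excluded from regression by default downstream.
#'
#' @param path CSV file path.
#' @param strict require an explicit temperature column.
#' @return data.frame with catalyst_id, substrate_id, syn, anti,
#'   temperature_K, ddg_kcal_mol, censored.
#' @export
readReactionTable <- function(path, strict = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("catalyst_id", "substrate_id", "syn", "anti")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("reaction table missing column(s): ", paste(miss, collapse = ", "))
  if (!"temperature_K" %in% names(df)) {
    if (strict)
      stop("strict mode: reaction table must carry a temperature_K column")
    df$temperature_K <- 298.15
  }
  if (!"ddg_kcal_mol" %in% names(df))
    df$ddg_kcal_mol <- ddgFromDr(df$syn, df$anti, df$temperature_K)
  df$censored <- !is.finite(df$ddg_kcal_mol)
  df[c("catalyst_id", "substrate_id", "syn", "anti", "temperature_K",
       "ddg_kcal_mol", "censored")]
}

#' Read a descriptor table from CSV
#'
#' First column \code{entity_id}, remaining columns numeric descriptors.
#' Duplicate entity ids are an error. A \code{provenance} attribute
#' tags every column as computed or ingested (electronic descriptors
#' such as NBO charges and NMR shifts are always ingested, never
#' computed here).
#'
#' @param path CSV file path.
#' @param provenance optional named character vector
#'   (column -> "computed" or "ingested"); defaults to "ingested" for
#'   every column.
#' @return data.frame with rownames = entity ids and a
#'   \code{provenance} attribute.
#' @export
readDescriptorTable <- function(path, provenance = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "entity_id")
    stop("descriptor table must start with an 'entity_id' column")
  if (anyDuplicated(df$entity_id))
    stop("duplicate entity ids in descriptor table")
  ids <- df$entity_id
  df <- df[, -1L, drop = FALSE]
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("all descriptor columns must be numeric")
  rownames(df) <- ids
  if (is.null(provenance))
    provenance <- stats::setNames(rep("ingested", ncol(df)), names(df))
  attr(df, "provenance") <- provenance
  df
}

#' Assemble the combinatorial catalyst x substrate model matrix
#'
#' Inner-joins reaction records with catalyst- and substrate-descriptor
#' tables. Columns are prefixed \code{cat_} and \code{sub_}; a name
#' collision after prefixing is a hard error. Reactions with any missing
#' descriptor, unresolvable id, or (by default) censored ddG are dropped
#' with a logged count. Optional z-scoring stores means and scales in
#' the matrix metadata.
#'
#' @param reactions data.frame from \code{\link{readReactionTable}} (or
#'   equivalent with ddg_kcal_mol).
#' @param catalyst_table,substrate_table data.frames with entity
#'   rownames (see \code{\link{readDescriptorTable}}).
#' @param drop_censored exclude infinite-ddG records, default TRUE.
#' @param zscore z-score feature columns, default FALSE.
#' @return a \linkS4class{ModelMatrix}.
#' @export
buildModelMatrix <- function(reactions, catalyst_table, substrate_table,
                             drop_censored = TRUE, zscore = FALSE) {
  catNames <- paste0("cat_", colnames(catalyst_table))
  subNames <- paste0("sub_", colnames(substrate_table))
  allNames <- c(catNames, subNames)
  if (anyDuplicated(allNames))
    stop("descriptor column collision after role prefixing: ",
         paste(unique(allNames[duplicated(allNames)]), collapse = ", "))
  n0 <- nrow(reactions)
  keep <- reactions$catalyst_id %in% rownames(catalyst_table) &
    reactions$substrate_id %in% rownames(substrate_table)
  if (drop_censored && "censored" %in% names(reactions))
    keep <- keep & !reactions$censored
  keep <- keep & is.finite(reactions$ddg_kcal_mol)
  rx <- reactions[keep, , drop = FALSE]
  cx <- as.matrix(catalyst_table[rx$catalyst_id, , drop = FALSE])
  sx <- as.matrix(substrate_table[rx$substrate_id, , drop = FALSE])
  X <- cbind(cx, sx)
  colnames(X) <- c(catNames, subNames)
  complete <- stats::complete.cases(X)
  rx <- rx[complete, , drop = FALSE]
  X <- X[complete, , drop = FALSE]
  dropped <- n0 - nrow(X)
  if (!nrow(X))
    stop("model matrix assembly produced no complete reactions")
  if (dropped > 0)
    message(dropped, " reaction(s) dropped (missing descriptors, ",
            "unresolved ids, or censored ratios)")
  scaling <- NULL
  if (zscore) {
    mu <- colMeans(X)
    sdv <- apply(X, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    X <- scale(X, center = mu, scale = sdv)
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
    scaling <- list(center = mu, scale = sdv)
  }
  new("ModelMatrix", features = X,
      response = rx$ddg_kcal_mol,
      catalystId = as.character(rx$catalyst_id),
      substrateId = as.character(rx$substrate_id),
      meta = list(dropped = dropped, scaling = scaling))
}

#' Construct a ModelMatrix from in-memory pieces
#'
#' Convenience constructor used by the synthetic generators and tests.
#'
#' @param features numeric matrix with named columns.
#' @param response numeric ddG vector.
#' @param catalystId,substrateId character ids per row (optional).
#' @param meta list of metadata.
#' @return a \linkS4class{ModelMatrix}.
#' @export
newModelMatrix <- function(features, response,
                           catalystId = rep(NA_character_, nrow(features)),
                           substrateId = rep(NA_character_, nrow(features)),
                           meta = list()) {
  new("ModelMatrix", features = as.matrix(features),
      response = as.numeric(response),
      catalystId = as.character(catalystId),
      substrateId = as.character(substrateId), meta = meta)
}
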