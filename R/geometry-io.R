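#' @include AllClasses.R vdw.R
NULL

#' Gas constant in kcal mol^-1 K^-1
#' @keywords internal
.Rgas <- 1.98720425e-3

#' Boltzmann weights of a set of conformer energies
#'
#' Computes normalized Boltzmann probabilities
#' \eqn{w_i \propto \exp(-E_i / RT)} with
#' \eqn{R = 1.98720425 \times 10^{-3}} kcal mol\eqn{^{-1}} K\eqn{^{-1}}.
#' Energies are shifted by their minimum before exponentiation, so the
#' weights are invariant under adding a constant to all energies and
#' numerically safe for large absolute energies.
#'
#' @param energies numeric vector, kcal/mol (relative energies fine).
#' @param temperature numeric scalar, Kelvin (> 0).
#' @return numeric vector of probabilities summing to 1.
#' @export
#' @examples
#' boltzmannWeights(c(0, 1), 298.15)  # ~ c(0.844, 0.156)
boltzmannWeights <- function(energies, temperature = 298.15) {
  if (!length(energies) || any(!is.finite(energies)))
    stop("energies must be a non-empty vector of finite values")
  if (length(temperature) != 1L || !is.finite(temperature) ||
      temperature <= 0)
    stop("temperature must be a single positive number (K)")
  w <- exp(-(energies - min(energies)) / (.Rgas * temperature))
  w / sum(w)
}

newConformer <- function(elements, coords, energy = 0, label = "conf",
                         radii = NULL, vdw_table = defaultVdwRadii()) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (is.null(radii)) radii <- lookupRadii(elements, vdw_table)
  new("Conformer", elements = elements, coords = coords,
      radii = as.numeric(radii), energy = as.numeric(energy),
      label = as.character(label))
}

#' Build a conformer ensemble
#'
#' Assembles conformers into an ensemble and computes Boltzmann weights
#' at the given temperature. All conformers must share atom count and
#' element order.
#'
#' @param conformers list of \linkS4class{Conformer}.
#' @param temperature Kelvin, default 298.15.
#' @return a \linkS4class{ConformerEnsemble}.
#' @export
newEnsemble <- function(conformers, temperature = 298.15) {
  e <- vapply(conformers, function(cf) cf@energy, numeric(1))
  new("ConformerEnsemble", conformers = conformers,
      temperature = temperature,
      weights = boltzmannWeights(e, temperature))
}

#' Read a multi-frame XYZ file as a conformer ensemble
#'
#' Standard XYZ blocks (atom count line, comment line, atom lines). The
#' comment line of every frame must contain an energy token
#' \code{E=<float>}; energies are kcal/mol unless
#' \code{energy_unit = "hartree"}, in which case they are converted
#' (x 627.5095). All frames must have identical atom ordering.
#'
#' @param path file path.
#' @param temperature Kelvin for Boltzmann weighting, default 298.15.
#' @param energy_unit "kcal/mol" (default) or "hartree".
#' @param vdw_table named radius vector, see \code{\link{defaultVdwRadii}}.
#' @return a \linkS4class{ConformerEnsemble}.
#' @export
readXYZEnsemble <- function(path, temperature = 298.15,
                            energy_unit = c("kcal/mol", "hartree"),
                            vdw_table = defaultVdwRadii()) {
  energy_unit <- match.arg(energy_unit)
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) > 1 & lines == "" &
                     seq_along(lines) == length(lines))]  # trailing blank
  confs <- list()
  i <- 1L; frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      stop(sprintf("frame %d: malformed atom count line '%s'", frame,
                   lines[i]))
    if (i + 1L + nat > length(lines))
      stop(sprintf("frame %d: truncated (expected %d atom lines)", frame,
                   nat))
    comment <- lines[i + 1L]
    m <- regmatches(comment,
                    regexpr("E=\\s*[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?",
                            comment))
    if (!length(m))
      stop(sprintf("frame %d: no parseable 'E=<float>' token in comment line",
                   frame))
    energy <- as.numeric(sub("E=\\s*", "", m))
    if (energy_unit == "hartree") energy <- energy * 627.5095
    at <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(at), "\\s+")
    if (any(vapply(toks, length, integer(1)) < 4L))
      stop(sprintf("frame %d: malformed atom line", frame))
    el <- vapply(toks, `[[`, character(1), 1L)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop(sprintf("frame %d: non-numeric coordinates", frame))
    confs[[frame]] <- newConformer(el, xyz, energy,
                                   label = sprintf("frame%03d", frame),
                                   vdw_table = vdw_table)
    i <- i + 2L + nat
  }
  if (!length(confs)) stop("no frames found in ", path)
  el0 <- confs[[1L]]@elements
  for (k in seq_along(confs))
    if (!identical(confs[[k]]@elements, el0))
      stop(sprintf("frame %d: atom ordering differs from frame 1", k))
  newEnsemble(confs, temperature)
}

#' Write a conformer ensemble as multi-frame XYZ
#'
#' Emits the dialect \code{\link{readXYZEnsemble}} reads: the comment
#' line carries \code{E=<energy kcal/mol>}. Coordinates are written with
#' enough digits for a 1e-6 Angstrom round trip.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeXYZEnsemble <- function(ensemble, path) {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in ensemble@conformers) {
    writeLines(as.character(length(cf@elements)), con)
    writeLines(sprintf("%s E=%.10g", cf@label, cf@energy), con)
    writeLines(sprintf("%-3s %14.8f %14.8f %14.8f", cf@elements,
                       cf@coords[, 1], cf@coords[, 2], cf@coords[, 3]),
               con)
  }
  invisible(path)
}

#' Read a single-conformer SDF (V2000) file
#'
#' Parses the first molecule block of a V2000 SDF file. The conformer
#' energy is taken from the named data property (default
#' \code{"ENERGY"}, kcal/mol); if absent, energy 0 is assigned.
#'
#' @param path file path.
#' @param energy_property SDF data field holding the energy.
#' @param vdw_table named radius vector.
#' @return a \linkS4class{Conformer}.
#' @export
readSDFConformer <- function(path, energy_property = "ENERGY",
                             vdw_table = defaultVdwRadii()) {
  lines <- readLines(path)
  if (length(lines) < 4L) stop("not a valid SDF file: ", path)
  counts <- lines[4L]
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  if (is.na(natoms) || natoms < 1L)
    stop("malformed V2000 counts line in ", path)
  at <- lines[5:(4 + natoms)]
  xyz <- cbind(as.numeric(substr(at, 1, 10)),
               as.numeric(substr(at, 11, 20)),
               as.numeric(substr(at, 21, 30)))
  el <- trimws(substr(at, 31, 34))
  energy <- 0
  tag <- paste0("^>\\s*<", energy_property, ">")
  hit <- grep(tag, lines)
  if (length(hit))
    energy <- as.numeric(trimws(lines[hit[1L] + 1L]))
  label <- trimws(lines[1L])
  if (!nzchar(label)) label <- basename(path)
  newConformer(el, xyz, energy, label = label, vdw_table = vdw_table)
}

#' Define the two axial pocket frames of a bimetallic core
#'
#' Each frame is centered on one metal atom with its axis pointing away
#' from the other metal, i.e. into that metal's axial pocket. The two
#' axes of one conformer are exactly antiparallel.
#'
#' @param conformer a \linkS4class{Conformer}.
#' @param metal_indices integer pair of atom indices of the two metal
#'   atoms (checked to be Rh by default).
#' @param metal_element expected element symbol, default \code{"Rh"};
#'   set to \code{NULL} to skip the check.
#' @return list of two \linkS4class{PocketFrame} objects (site 1, site 2).
#' @export
definePocketFrames <- function(conformer, metal_indices,
                               metal_element = "Rh") {
  stopifnot(is(conformer, "Conformer"), length(metal_indices) == 2L)
  i <- metal_indices[1L]; j <- metal_indices[2L]
  if (i == j) stop("metal indices must be distinct")
  if (!is.null(metal_element)) {
    el <- conformer@elements[c(i, j)]
    if (any(el != metal_element))
      stop(sprintf("atoms %d,%d are (%s,%s); expected %s", i, j, el[1],
                   el[2], metal_element))
  }
  a <- conformer@coords[i, ]; b <- conformer@coords[j, ]
  v <- a - b
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("metal atoms are coincident; no axis defined")
  u <- v / nv
  list(new("PocketFrame", center = a, axis = u, siteId = 1L),
       new("PocketFrame", center = b, axis = -u, siteId = 2L))
}

#' Weighted ensemble statistic
#'
#' MIN and MAX ignore the weights except that zero-weight entries are
#' excluded; MEAN is the weighted mean; SIGMA is the weighted population
#' standard deviation \eqn{\sqrt{\sum w_i (v_i - \bar v)^2}}.
#'
#' @param values numeric vector.
#' @param weights probability vector of the same length (>= 0, sums
#'   to 1).
#' @param stat one of \code{"MIN"}, \code{"MAX"}, \code{"MEAN"},
#'   \code{"SIGMA"}.
#' @return numeric scalar.
#' @export
#' @examples
#' weightedStat(c(1, 2, 4), c(0.5, 0.25, 0.25), "SIGMA")  # 1.2247
weightedStat <- function(values, weights,
                         stat = c("MIN", "MAX", "MEAN", "SIGMA")) {
  stat <- match.arg(stat)
  if (length(values) != length(weights))
    stop("values and weights must have equal length")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be probabilities summing to 1")
  keep <- weights > 0
  if (!any(keep)) stop("no entries remain after zero-weight exclusion")
  v <- values[keep]; w <- weights[keep]
  switch(stat,
    MIN = min(v),
    MAX = max(v),
    MEAN = sum(w * v),
    SIGMA = {
      m <- sum(w * v)
      sqrt(sum(w * (v - m)^2))
    })
}
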