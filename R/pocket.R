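#' @include AllClasses.R geometry-io.R
NULL

#' Construct a cavity specification
#'
#' @param probeOffset distance d (Angstrom) from the binding metal to
#'   the probe-sphere center along the pocket axis; default 2.0.
#' @param cavityRadius probe-sphere radius R (Angstrom); default 4.0.
#' @param proximalCutoff axial distance p (Angstrom) from the binding
#'   metal separating the proximal from the distal region; default 2.0.
#' @param gridSpacing voxel spacing h (Angstrom); default 0.2.
#' @return a \linkS4class{CavitySpec}.
#' @export
cavitySpec <- function(probeOffset = 2.0, cavityRadius = 4.0,
                       proximalCutoff = 2.0, gridSpacing = 0.2) {
  new("CavitySpec", probeOffset = probeOffset, cavityRadius = cavityRadius,
      proximalCutoff = proximalCutoff, gridSpacing = gridSpacing)
}

# orthonormal basis (u, v, w) with w = axis
.pocketBasis <- function(axis) {
  w <- axis / sqrt(sum(axis^2))
  e <- diag(3)[, which.min(abs(w))]
  u <- c(w[2] * e[3] - w[3] * e[2],
         w[3] * e[1] - w[1] * e[3],
         w[1] * e[2] - w[2] * e[1])
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  cbind(u, v, w)
}

#' Axial-pocket cavity volume and proximal/distal partition
#'
#' Places a probe sphere of radius R at distance d from the binding
#' metal along the pocket axis and measures the volume of the sphere not
#' occupied by any atom's van der Waals sphere, on a cubic grid of
#' spacing h expressed in the pocket frame. The open volume is reported
#' as the analytic sphere volume times the open-voxel fraction, so an
#' unobstructed cavity is exact and the proximal + distal parts sum to
#' the total by construction. Grid points whose axial distance from the
#' binding metal is at most p are proximal.
#'
#' If the whole probe sphere lies inside a single atom, all volumes are
#' zero and the result carries \code{occluded = TRUE} (with a warning),
#' not an error.
#'
#' @param conformer a \linkS4class{Conformer}.
#' @param frame the \linkS4class{PocketFrame} of the site.
#' @param spec a \linkS4class{CavitySpec}.
#' @return list with \code{V_CAVITY}, \code{proxV_CAVITY},
#'   \code{distV_CAVITY} (Angstrom^3), \code{distV_pct} (percent of
#'   V_CAVITY; 0 if V_CAVITY is 0) and \code{occluded}.
#' @export
cavityVolume <- function(conformer, frame, spec) {
  stopifnot(is(conformer, "Conformer"), is(frame, "PocketFrame"),
            is(spec, "CavitySpec"))
  validObject(spec)
  d <- spec@probeOffset; R <- spec@cavityRadius
  p <- spec@proximalCutoff; h <- spec@gridSpacing
  c0 <- frame@center + d * frame@axis
  B <- .pocketBasis(frame@axis)

  # fully-occluded short circuit: probe sphere inside one atom
  dc <- sqrt(rowSums((conformer@coords -
                        matrix(c0, nrow(conformer@coords), 3,
                               byrow = TRUE))^2))
  if (any(dc + R <= conformer@radii)) {
    warning("probe sphere entirely inside an atom; cavity reported as zero")
    return(list(V_CAVITY = 0, proxV_CAVITY = 0, distV_CAVITY = 0,
                distV_pct = 0, occluded = TRUE))
  }

  s <- seq(-R + h / 2, R, by = h)
  g <- expand.grid(u = s, v = s, w = s)
  inside <- g$u^2 + g$v^2 + g$w^2 <= R^2
  g <- g[inside, , drop = FALSE]
  nProbe <- nrow(g)
  # world coordinates of grid points
  P <- as.matrix(g) %*% t(B)
  P <- sweep(P, 2L, c0, `+`)

  open <- rep(TRUE, nProbe)
  near <- which(dc <= R + conformer@radii)
  for (a in near) {
    ctr <- conformer@coords[a, ]
    r2 <- conformer@radii[a]^2
    d2 <- (P[, 1] - ctr[1])^2 + (P[, 2] - ctr[2])^2 + (P[, 3] - ctr[3])^2
    open <- open & (d2 > r2)
  }
  vSphere <- 4 / 3 * pi * R^3
  # axial distance from the binding metal of each grid point: d + w
  prox <- (d + g$w) <= p
  V <- vSphere * sum(open) / nProbe
  proxV <- vSphere * sum(open & prox) / nProbe
  distV <- vSphere * sum(open & !prox) / nProbe
  list(V_CAVITY = V, proxV_CAVITY = proxV, distV_CAVITY = distV,
       distV_pct = if (V > 0) 100 * distV / V else 0,
       occluded = FALSE)
}

#' Entry / proximal window open area
#'
#' The measurement window is the disc of radius R centered on the pocket
#' axis, perpendicular to it, at axial distance d (\code{plane =
#' "ENTRY"}) or p (\code{plane = "PROXIMAL"}) from the binding metal.
#' Returns the area of the disc not covered by the circular
#' cross-sections of atom van der Waals spheres that intersect the
#' window plane, estimated on a 2-D grid of spacing h as the analytic
#' disc area times the open fraction.
#'
#' @inheritParams cavityVolume
#' @param plane \code{"ENTRY"} or \code{"PROXIMAL"}.
#' @return open window area in Angstrom^2.
#' @export
entrySurfaceArea <- function(conformer, frame, spec,
                             plane = c("ENTRY", "PROXIMAL")) {
  stopifnot(is(conformer, "Conformer"), is(frame, "PocketFrame"),
            is(spec, "CavitySpec"))
  validObject(spec)
  plane <- match.arg(plane)
  q <- if (plane == "ENTRY") spec@probeOffset else spec@proximalCutoff
  R <- spec@cavityRadius; h <- spec@gridSpacing
  B <- .pocketBasis(frame@axis)
  cq <- frame@center + q * frame@axis

  s <- seq(-R + h / 2, R, by = h)
  g <- expand.grid(u = s, v = s)
  g <- g[g$u^2 + g$v^2 <= R^2, , drop = FALSE]
  nDisc <- nrow(g)

  # atoms whose spheres cut the plane
  rel <- sweep(conformer@coords, 2L, frame@center, `-`)
  ax <- as.numeric(rel %*% frame@axis)
  dz <- ax - q
  cut <- which(abs(dz) < conformer@radii)
  open <- rep(TRUE, nDisc)
  for (a in cut) {
    rc2 <- conformer@radii[a]^2 - dz[a]^2
    # in-plane center of the cross-section, in (u, v) coordinates
    relA <- conformer@coords[a, ] - cq
    au <- sum(relA * B[, 1]); av <- sum(relA * B[, 2])
    open <- open & ((g$u - au)^2 + (g$v - av)^2 > rc2)
  }
  pi * R^2 * sum(open) / nDisc
}

.cavityDescriptors <- function(conformer, frame, spec) {
  vol <- cavityVolume(conformer, frame, spec)
  R <- spec@cavityRadius
  window <- pi * R^2
  esa <- entrySurfaceArea(conformer, frame, spec, "ENTRY")
  proxEsa <- entrySurfaceArea(conformer, frame, spec, "PROXIMAL")
  c(V_CAVITY = vol$V_CAVITY, proxV_CAVITY = vol$proxV_CAVITY,
    distV_CAVITY = vol$distV_CAVITY, distV_pct = vol$distV_pct,
    ESA = esa, proxESA = proxEsa,
    ESA_pct = 100 * esa / window, proxESA_pct = 100 * proxEsa / window)
}

#' Ensemble-aggregated pocket descriptor row
#'
#' Computes the cavity and window descriptors for every conformer at
#' both axial sites and reduces them to ensemble aggregates. The
#' reduction order is fixed: per-conformer per-site values are first
#' reduced across the two sites (min for the MIN aggregate, max for MAX,
#' across-site mean for MEAN and SIGMA), then the Boltzmann-weighted
#' ensemble statistic is taken with \code{\link{weightedStat}}.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param metal_indices integer pair locating the two metal atoms
#'   (identical across conformers).
#' @param spec a \linkS4class{CavitySpec}.
#' @param metal_element element symbol expected at the metal indices,
#'   default "Rh".
#' @return one-row data.frame with columns
#'   \code{<descriptor>_<MIN|MAX|MEAN|SIGMA>} for V_CAVITY,
#'   proxV_CAVITY, distV_CAVITY, distV_pct, ESA, proxESA, ESA_pct and
#'   proxESA_pct.
#' @export
ensemblePocketRow <- function(ensemble, metal_indices, spec,
                              metal_element = "Rh") {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  descNames <- c("V_CAVITY", "proxV_CAVITY", "distV_CAVITY", "distV_pct",
                 "ESA", "proxESA", "ESA_pct", "proxESA_pct")
  k <- nConformers(ensemble)
  perSite <- array(NA_real_, dim = c(k, 2L, length(descNames)),
                   dimnames = list(NULL, NULL, descNames))
  for (ci in seq_len(k)) {
    cf <- ensemble@conformers[[ci]]
    frames <- definePocketFrames(cf, metal_indices, metal_element)
    for (si in 1:2)
      perSite[ci, si, ] <- .cavityDescriptors(cf, frames[[si]], spec)
  }
  w <- ensemble@weights
  out <- numeric(0)
  for (dn in descNames) {
    m <- perSite[, , dn, drop = FALSE]
    dim(m) <- c(k, 2L)
    siteMin <- pmin(m[, 1], m[, 2])
    siteMax <- pmax(m[, 1], m[, 2])
    siteMean <- (m[, 1] + m[, 2]) / 2
    out[paste0(dn, "_MIN")] <- weightedStat(siteMin, w, "MIN")
    out[paste0(dn, "_MAX")] <- weightedStat(siteMax, w, "MAX")
    out[paste0(dn, "_MEAN")] <- weightedStat(siteMean, w, "MEAN")
    out[paste0(dn, "_SIGMA")] <- weightedStat(siteMean, w, "SIGMA")
  }
  as.data.frame(as.list(out))
}
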