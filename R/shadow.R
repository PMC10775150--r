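#' @include AllClasses.R geometry-io.R
NULL

#' Construct a shadow specification
#'
#' @param nDirections deterministic Fibonacci-sphere direction count,
#'   default 20000 (must be >= 1000).
#' @param centerAtom index of the atom rays emanate from, default 1.
#' @param sphereRadius \code{NA} for the encompassing-sphere rule used
#'   by the G\% surface descriptor, or a fixed radius in Angstrom.
#' @param exclude atom indices that do not shield (e.g. a co-computed
#'   scaffold), default none.
#' @return a \linkS4class{ShadowSpec}.
#' @export
shadowSpec <- function(nDirections = 20000L, centerAtom = 1L,
                       sphereRadius = NA_real_, exclude = integer()) {
  new("ShadowSpec", nDirections = as.integer(nDirections),
      centerAtom = as.integer(centerAtom),
      sphereRadius = as.numeric(sphereRadius),
      exclude = as.integer(exclude))
}

#' Deterministic Fibonacci-sphere directions
#'
#' Quasi-uniform unit vectors by the golden-angle spiral; fully
#' deterministic, so shielding percentages are reproducible without a
#' random seed.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

.shadowMask <- function(conformer, spec) {
  ctr <- conformer@coords[spec@centerAtom, ]
  U <- fibonacciSphere(spec@nDirections)
  idx <- setdiff(seq_along(conformer@elements),
                 c(spec@centerAtom, spec@exclude))
  shield <- rep(FALSE, nrow(U))
  for (a in idx) {
    rel <- conformer@coords[a, ] - ctr
    d2 <- sum(rel^2)
    r <- conformer@radii[a]
    if (d2 <= r^2)
      stop(sprintf("center atom engulfed by atom %d's vdW sphere", a))
    t <- as.numeric(U %*% rel)
    shield <- shield | (t > 0 & (d2 - t^2) <= r^2)
  }
  shield
}

#' G percent: shielded fraction of directions around a center atom
#'
#' Percentage of deterministic unit directions from the center atom
#' whose ray intersects at least one other atom's van der Waals sphere
#' (the Guzei-Wendt solid-angle shielding measure, evaluated by
#' quasi-uniform ray sampling).
#'
#' @param conformer a \linkS4class{Conformer}.
#' @param spec a \linkS4class{ShadowSpec}.
#' @return shielding percentage in [0, 100].
#' @export
gPercent <- function(conformer, spec = shadowSpec()) {
  stopifnot(is(conformer, "Conformer"), is(spec, "ShadowSpec"))
  validObject(spec)
  if (spec@centerAtom > length(conformer@elements))
    stop("centerAtom index out of range")
  100 * mean(.shadowMask(conformer, spec))
}

#' G percent surface: absolute unshielded area
#'
#' Contextualizes \code{\link{gPercent}} to an encompassing sphere:
#' returns \eqn{(1 - G\%/100) \cdot 4\pi R_s^2}, the absolute area of
#' the sphere left unhindered by ligand shadow cones. By default
#' \eqn{R_s} is the encompassing radius, the maximum over atoms of
#' (distance from the center atom + vdW radius); a fixed radius can be
#' set in the spec.
#'
#' @inheritParams gPercent
#' @return unshielded area in Angstrom^2.
#' @export
gPercentSurface <- function(conformer, spec = shadowSpec()) {
  g <- gPercent(conformer, spec)
  Rs <- spec@sphereRadius
  if (is.na(Rs)) {
    ctr <- conformer@coords[spec@centerAtom, ]
    d <- sqrt(rowSums(sweep(conformer@coords, 2L, ctr, `-`)^2))
    Rs <- max(d + conformer@radii)
  }
  (1 - g / 100) * 4 * pi * Rs^2
}

#' Ensemble flexibility of catalyst hindrance
#'
#' Boltzmann-weighted population standard deviation of the per-conformer
#' \code{\link{gPercentSurface}} values: large values flag ensembles
#' whose accessible reactive space varies strongly across conformers.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param spec a \linkS4class{ShadowSpec}.
#' @return weighted sigma in Angstrom^2.
#' @export
gSurfaceSigma <- function(ensemble, spec = shadowSpec()) {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  v <- vapply(ensemble@conformers, gPercentSurface, numeric(1),
              spec = spec)
  weightedStat(v, ensemble@weights, "SIGMA")
}

#' Sterimol L, B1 and B5 of a substituent
#'
#' The axis runs from the first attachment atom toward the second; the
#' substituent is every atom except the first (dummy/attachment) atom.
#' L is the maximum over substituent atoms of (axial projection from the
#' attachment atom + vdW radius); B5 is the maximum perpendicular extent
#' (radial distance from the axis + vdW radius); B1 is the minimum over
#' in-plane directions of the maximum signed half-width, computed by a
#' dense angular scan. Convention: L is measured from the attachment
#' atom's center and no legacy +0.40 Angstrom correction is applied.
#'
#' @param conformer a \linkS4class{Conformer}.
#' @param attach integer pair: (attachment/dummy atom, first substituent
#'   atom defining the axis direction).
#' @param scan_step angular scan step for B1 in degrees (<= 0.5,
#'   default 0.2).
#' @return list with \code{L}, \code{B1}, \code{B5} (Angstrom) and
#'   \code{L_over_B1}.
#' @export
sterimol <- function(conformer, attach, scan_step = 0.2) {
  stopifnot(is(conformer, "Conformer"), length(attach) == 2L)
  if (attach[1L] == attach[2L]) stop("attachment atoms must be distinct")
  if (scan_step > 0.5) stop("scan_step must be <= 0.5 degrees")
  o <- conformer@coords[attach[1L], ]
  v <- conformer@coords[attach[2L], ] - o
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("degenerate axis: attachment atoms coincide")
  w <- v / nv
  sub <- setdiff(seq_along(conformer@elements), attach[1L])
  rel <- sweep(conformer@coords[sub, , drop = FALSE], 2L, o, `-`)
  r <- conformer@radii[sub]
  ax <- as.numeric(rel %*% w)
  L <- max(ax + r)
  B <- .pocketBasis(w)  # columns u, v, w
  pu <- as.numeric(rel %*% B[, 1])
  pv <- as.numeric(rel %*% B[, 2])
  B5 <- max(sqrt(pu^2 + pv^2) + r)
  ang <- seq(0, 360 - scan_step, by = scan_step) * pi / 180
  # width(phi) = max_i (p_i . u_phi + r_i); B1 = min_phi width(phi)
  W <- outer(cos(ang), pu) + outer(sin(ang), pv)  # n_ang x n_atoms
  W <- sweep(W, 2L, r, `+`)
  B1 <- min(apply(W, 1L, max))
  list(L = L, B1 = B1, B5 = B5, L_over_B1 = L / B1)
}

#' Molecular sphericity from the van der Waals union
#'
#' Volume V of the union of van der Waals spheres is obtained by voxel
#' counting at the given spacing; surface area A by deterministic
#' Fibonacci sampling of each sphere's surface, counting the fraction of
#' sample points not buried inside any other sphere. Sphericity is
#' \eqn{\Psi = \pi^{1/3} (6V)^{2/3} / A}: 1 for a single sphere,
#' smaller for elongated shapes.
#'
#' @param conformer a \linkS4class{Conformer}.
#' @param grid_spacing voxel spacing in Angstrom, default 0.1.
#' @param n_surface_points surface samples per atom, default 2000.
#' @return list with \code{volume} (Angstrom^3), \code{surface_area}
#'   (Angstrom^2) and \code{psi}.
#' @export
sphericity <- function(conformer, grid_spacing = 0.1,
                       n_surface_points = 2000L) {
  stopifnot(is(conformer, "Conformer"))
  if (grid_spacing <= 0) stop("grid_spacing must be > 0")
  X <- conformer@coords; r <- conformer@radii
  n <- nrow(X)
  h <- grid_spacing

  lo <- apply(X - r, 2L, min) - h
  hi <- apply(X + r, 2L, max) + h
  gx <- seq(lo[1] + h / 2, hi[1], by = h)
  gy <- seq(lo[2] + h / 2, hi[2], by = h)
  gz <- seq(lo[3] + h / 2, hi[3], by = h)
  # count voxels inside any sphere, sweeping z-slabs to bound memory
  nopen <- 0
  gxy <- expand.grid(x = gx, y = gy)
  for (z in gz) {
    inside <- rep(FALSE, nrow(gxy))
    for (a in seq_len(n)) {
      dz2 <- (z - X[a, 3])^2
      if (dz2 > r[a]^2) next
      inside <- inside |
        ((gxy$x - X[a, 1])^2 + (gxy$y - X[a, 2])^2 <= r[a]^2 - dz2)
    }
    nopen <- nopen + sum(inside)
  }
  V <- nopen * h^3

  U <- fibonacciSphere(n_surface_points)
  A <- 0
  for (a in seq_len(n)) {
    P <- sweep(U * r[a], 2L, X[a, ], `+`)
    exposed <- rep(TRUE, nrow(P))
    for (b in seq_len(n)) {
      if (b == a) next
      d2 <- (P[, 1] - X[b, 1])^2 + (P[, 2] - X[b, 2])^2 +
        (P[, 3] - X[b, 3])^2
      exposed <- exposed & (d2 >= r[b]^2)
    }
    A <- A + 4 * pi * r[a]^2 * mean(exposed)
  }
  psi <- pi^(1 / 3) * (6 * V)^(2 / 3) / A
  list(volume = V, surface_area = A, psi = psi)
}
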