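# shared fixture builders; everything is generated in code

# conformer with a manual radius override
conf <- function(elements, coords, energy = 0, radii = NULL,
                 label = "fix") {
  stericsel:::newConformer(elements, coords, energy, label = label,
                           radii = radii)
}

# a pocket frame without needing metal atoms in the structure
frameAt <- function(center = c(0, 0, 0), axis = c(0, 0, 1), site = 1L) {
  new("PocketFrame", center = as.numeric(center),
      axis = axis / sqrt(sum(axis^2)), siteId = site)
}

# Rh-Rh core plus n random carbon blockers near the +z pocket
randomPocketConformer <- function(seed, n_blockers = 5) {
  set.seed(seed)
  el <- c("Rh", "Rh", rep("C", n_blockers))
  xyz <- rbind(c(0, 0, 1.2), c(0, 0, -1.2),
               cbind(runif(n_blockers, -3, 3),
                     runif(n_blockers, -3, 3),
                     runif(n_blockers, 1.5, 6)))
  conf(el, xyz)
}

# uniform Monte-Carlo estimate of the open cavity volume
mcCavityVolume <- function(conformer, frame, spec, n = 1e6, seed = 42) {
  set.seed(seed)
  R <- spec@cavityRadius
  c0 <- frame@center + spec@probeOffset * frame@axis
  dir <- matrix(rnorm(3 * n), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  P <- dir * (R * runif(n)^(1 / 3))
  P <- sweep(P, 2L, c0, `+`)
  open <- rep(TRUE, n)
  for (a in seq_len(nrow(conformer@coords))) {
    d2 <- (P[, 1] - conformer@coords[a, 1])^2 +
      (P[, 2] - conformer@coords[a, 2])^2 +
      (P[, 3] - conformer@coords[a, 3])^2
    open <- open & d2 > conformer@radii[a]^2
  }
  4 / 3 * pi * R^3 * mean(open)
}

# rigid motion: random rotation + translation applied to a conformer
rigidMove <- function(conformer, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  tr <- rnorm(3, sd = 5)
  moved <- conformer
  moved@coords <- conformer@coords %*% t(Q) +
    matrix(tr, nrow(conformer@coords), 3, byrow = TRUE)
  list(conformer = moved, Q = Q, t = tr)
}

# standardized base matrix for model-engine tests
baseMatrix <- function(n, p, seed = 1, positive = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  if (positive) X <- abs(X) + 0.5
  X
}
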