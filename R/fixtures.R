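#' @include AllClasses.R geometry-io.R reaction.R metrics.R
NULL

#' Toy paddlewheel-like catalyst ensemble
#'
#' Builds a deterministic dirhodium-like test structure: two Rh
#' pseudo-atoms at (0, 0, +/-1.2) Angstrom and four ligand arms at 90
#' degree azimuthal spacing, each a short chain of bulky spheres rooted
#' on an equatorial belt and tilted by \code{cone_angle} toward the +z
#' axial pocket (0 = equatorial/open, larger = arms folded over the
#' pocket, the "chiral crown" archetype). Conformers jitter the arm
#' azimuths and tilts by a seeded uniform wobble; the first conformer is
#' the unjittered reference and energies grow with the squared angular
#' deviation, so wobble 0 gives identical conformers with equal weights.
#'
#' With \code{mirror_arms = TRUE} a mirrored set of arms shields the -z
#' pocket equally, making the two axial sites symmetric.
#'
#' @param arm_length arm chain length in Angstrom, default 4.
#' @param arm_bulk_radius vdW radius assigned to arm spheres, default
#'   1.5.
#' @param cone_angle tilt from the equatorial plane toward +z, degrees,
#'   default 45.
#' @param n_conformers number of conformers, default 3.
#' @param wobble_deg per-conformer uniform angular jitter, default 5.
#' @param seed integer seed, default 1.
#' @param n_arm_atoms spheres per arm, default 3.
#' @param arm_base_radius equatorial belt radius (Angstrom), default 2.
#' @param mirror_arms also shield the -z pocket, default FALSE.
#' @param temperature Kelvin for Boltzmann weighting, default 298.15.
#' @return a \linkS4class{ConformerEnsemble}; atoms 1 and 2 are the Rh
#'   pair for \code{\link{definePocketFrames}}.
#' @export
makeToyCatalyst <- function(arm_length = 4, arm_bulk_radius = 1.5,
                            cone_angle = 45, n_conformers = 3L,
                            wobble_deg = 5, seed = 1L,
                            n_arm_atoms = 3L, arm_base_radius = 2,
                            mirror_arms = FALSE,
                            temperature = 298.15) {
  if (n_conformers < 1L) stop("n_conformers must be >= 1")
  if (wobble_deg < 0) stop("wobble_deg must be >= 0")
  deg <- pi / 180
  armSpec <- expand.grid(phi = c(0, 90, 180, 270),
                         updown = if (mirror_arms) c(1, -1) else 1)
  buildConf <- function(dphi, dtilt, label, energy) {
    el <- c("Rh", "Rh")
    xyz <- rbind(c(0, 0, 1.2), c(0, 0, -1.2))
    radii <- rep(defaultVdwRadii()[["Rh"]], 2L)
    for (a in seq_len(nrow(armSpec))) {
      phi <- (armSpec$phi[a] + dphi[a]) * deg
      alpha <- (cone_angle + dtilt[a]) * deg
      s <- armSpec$updown[a]
      dir <- c(cos(phi) * cos(alpha), sin(phi) * cos(alpha),
               s * sin(alpha))
      base <- c(arm_base_radius * cos(phi), arm_base_radius * sin(phi), 0)
      for (i in seq_len(n_arm_atoms)) {
        pos <- base + dir * (arm_length * i / n_arm_atoms)
        el <- c(el, "C")
        xyz <- rbind(xyz, pos)
        radii <- c(radii, arm_bulk_radius)
      }
    }
    newConformer(el, xyz, energy, label = label, radii = radii)
  }
  nArms <- nrow(armSpec)
  confs <- .withSeed(seed, {
    lapply(seq_len(n_conformers), function(ci) {
      if (ci == 1L) {
        dphi <- rep(0, nArms); dtilt <- rep(0, nArms)
      } else {
        dphi <- stats::runif(nArms, -wobble_deg, wobble_deg)
        dtilt <- stats::runif(nArms, -wobble_deg, wobble_deg)
      }
      energy <- 0.005 * sum(dphi^2 + dtilt^2)
      buildConf(dphi, dtilt, sprintf("conf%02d", ci), energy)
    })
  })
  newEnsemble(confs, temperature)
}

#' Planted-signal catalyst x substrate reaction benchmark
#'
#' Emulates the statistical structure of a combinatorial selectivity
#' campaign: per-entity descriptor columns are drawn i.i.d. standard
#' normal (then exactly standardized across the final reaction rows, so
#' planted expressions live on the same scale the fitting pipeline
#' sees), all catalyst x substrate pairs are formed, a few rows are
#' withheld, and the response is one linear catalyst term plus two
#' catalyst x substrate product interactions plus Gaussian noise. The
#' coefficients are scaled so a stated fraction of the response variance
#' is systematic, with a stated share carried by the linear term; the
#' remainder splits evenly between the two interactions.
#'
#' Because products of independent standard normals are uncorrelated
#' with the linear features, the best purely linear model can explain at
#' most the linear share (plus sampling noise) -- the mechanism behind
#' the linear-vs-nonlinear performance gap this benchmark is built to
#' exhibit.
#'
#' @param n_catalysts default 18.
#' @param n_substrates default 5.
#' @param n_cat_desc catalyst-role descriptor count, default 4.
#' @param n_sub_desc substrate-role descriptor count, default 3.
#' @param signal_fraction systematic share of response variance in
#'   (0, 1), default 0.95.
#' @param linear_share share of total variance carried by the linear
#'   term, default 0.35 (must be < signal_fraction).
#' @param n_withheld rows removed from the full combinatorial pairing,
#'   default 4 (18 x 5 - 4 = 86 rows).
#' @param seed integer seed.
#' @param coefficients optional length-3 override (linear, interaction1,
#'   interaction2); when supplied, shares are ignored and
#'   \code{noise_sd} must be given.
#' @param noise_sd optional noise standard deviation override.
#' @return list with \code{matrix} (a \linkS4class{ModelMatrix}) and
#'   \code{truth} (planted canonical strings, coefficients, noise_sd,
#'   withheld row ids).
#' @export
makePlantedBenchmark <- function(n_catalysts = 18L, n_substrates = 5L,
                                 n_cat_desc = 4L, n_sub_desc = 3L,
                                 signal_fraction = 0.95,
                                 linear_share = 0.35,
                                 n_withheld = 4L, seed = 1L,
                                 coefficients = NULL, noise_sd = NULL) {
  if (is.null(coefficients)) {
    if (signal_fraction <= 0 || signal_fraction >= 1)
      stop("signal_fraction must be in (0, 1)")
    if (linear_share <= 0 || linear_share >= signal_fraction)
      stop("linear_share must be in (0, signal_fraction)")
    inter <- (signal_fraction - linear_share) / 2
    coefficients <- c(sqrt(linear_share), sqrt(inter), sqrt(inter))
    noise_sd <- sqrt(1 - signal_fraction)
  } else if (is.null(noise_sd))
    stop("noise_sd must be given with explicit coefficients")
  if (n_cat_desc < 3L || n_sub_desc < 2L)
    stop("need >= 3 catalyst and >= 2 substrate descriptors for the planted form")
  nTotal <- n_catalysts * n_substrates
  if (n_withheld < 0L || n_withheld >= nTotal - 4L)
    stop("n_withheld out of range")

  out <- .withSeed(seed, {
    catX <- matrix(stats::rnorm(n_catalysts * n_cat_desc),
                   n_catalysts, n_cat_desc,
                   dimnames = list(sprintf("C%02d", seq_len(n_catalysts)),
                                   paste0("d", seq_len(n_cat_desc))))
    subX <- matrix(stats::rnorm(n_substrates * n_sub_desc),
                   n_substrates, n_sub_desc,
                   dimnames = list(sprintf("S%d", seq_len(n_substrates)),
                                   paste0("d", seq_len(n_sub_desc))))
    pairs <- expand.grid(cat = rownames(catX), sub = rownames(subX),
                         stringsAsFactors = FALSE)
    withheld <- if (n_withheld > 0L) sample.int(nrow(pairs), n_withheld)
                else integer()
    keep <- setdiff(seq_len(nrow(pairs)), withheld)
    X <- cbind(catX[pairs$cat[keep], , drop = FALSE],
               subX[pairs$sub[keep], , drop = FALSE])
    colnames(X) <- c(paste0("cat_", colnames(catX)),
                     paste0("sub_", colnames(subX)))
    # exact row-level standardization (affine per column, so the
    # entity structure is preserved)
    X <- scale(X)
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
    eps <- stats::rnorm(nrow(X), 0, noise_sd)
    y <- coefficients[1] * X[, "cat_d1"] +
      coefficients[2] * X[, "cat_d2"] * X[, "sub_d1"] +
      coefficients[3] * X[, "cat_d3"] * X[, "sub_d2"] + eps
    list(X = X, y = as.numeric(y),
         cat = pairs$cat[keep], sub = pairs$sub[keep],
         withheld = paste(pairs$cat[withheld], pairs$sub[withheld],
                          sep = ":"),
         signal = y - eps)
  })
  mm <- newModelMatrix(out$X, out$y, out$cat, out$sub,
                       meta = list(generator = "planted_benchmark",
                                   seed = seed))
  truth <- list(
    features = c("cat_d1", "(cat_d2*sub_d1)", "(cat_d3*sub_d2)"),
    coefficients = coefficients,
    noise_sd = noise_sd,
    signal_fraction = signal_fraction,
    linear_share = linear_share,
    withheld = out$withheld,
    signal = out$signal)
  list(matrix = mm, truth = truth)
}
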