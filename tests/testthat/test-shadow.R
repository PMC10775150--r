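test_that("shielding percentage matches the closed-form shadow cone", {
  lone <- conf("Rh", rbind(c(0, 0, 0)))
  expect_equal(gPercent(lone, shadowSpec(2000L, 1L)), 0)

  # one r = 1.2 atom at 2.4 A: shielded fraction (1 - cos(asin(0.5)))/2
  cone <- conf(c("Rh", "H"), rbind(c(0, 0, 0), c(0, 0, 2.4)))
  exact1 <- 100 * (1 - cos(asin(0.5))) / 2
  expect_lt(abs(gPercent(cone, shadowSpec(20000L, 1L)) - exact1), 0.1)

  # two opposed, non-overlapping cones add
  two <- conf(c("Rh", "H", "H"),
              rbind(c(0, 0, 0), c(0, 0, 2.4), c(0, 0, -2.4)))
  expect_lt(abs(gPercent(two, shadowSpec(20000L, 1L)) - 2 * exact1), 0.2)

  engulfed <- conf(c("Rh", "C"), rbind(c(0, 0, 0), c(0.5, 0, 0)))
  expect_error(gPercent(engulfed, shadowSpec(2000L, 1L)), "engulfed")
})

test_that("shielding is rotation-invariant and monotone in added atoms", {
  cf <- randomPocketConformer(9)
  spec <- shadowSpec(20000L, 1L)
  g0 <- gPercent(cf, spec)
  g1 <- gPercent(rigidMove(cf, seed = 5)$conformer, spec)
  expect_lt(abs(g0 - g1), 0.2)

  grown <- conf(c(cf@elements, "C"), rbind(cf@coords, c(-2, -2, 0.5)))
  expect_gte(gPercent(grown, spec) + 1e-9, g0)
})

test_that("G%-surface contextualizes shielding to the encompassing sphere", {
  lone <- conf("C", rbind(c(0, 0, 0)))
  r <- defaultVdwRadii()[["C"]]
  expect_equal(gPercentSurface(lone, shadowSpec(2000L, 1L)),
               4 * pi * r^2, tolerance = 1e-9)

  cone <- conf(c("Rh", "H"), rbind(c(0, 0, 0), c(0, 0, 2.4)))
  g <- gPercent(cone, shadowSpec(20000L, 1L))
  expect_equal(gPercentSurface(cone, shadowSpec(20000L, 1L, sphereRadius = 5)),
               (1 - g / 100) * 100 * pi, tolerance = 0.01 * 100 * pi)

  # six wide spheres on the axes tile every direction
  caged <- conf(c("Rh", rep("C", 6)),
                rbind(c(0, 0, 0), 3 * rbind(diag(3), -diag(3))),
                radii = c(2.1, rep(2.9, 6)))
  expect_equal(gPercentSurface(caged, shadowSpec(2000L, 1L)), 0)
})

test_that("hindrance flexibility sigma composes from per-conformer surfaces", {
  rigid <- makeToyCatalyst(n_conformers = 3L, wobble_deg = 0)
  expect_equal(gSurfaceSigma(rigid, shadowSpec(2000L, 1L)), 0,
               tolerance = 1e-9)

  flex <- makeToyCatalyst(n_conformers = 3L, wobble_deg = 20, seed = 2)
  spec <- shadowSpec(5000L, 1L)
  vals <- sapply(conformers(flex), gPercentSurface, spec = spec)
  expect_equal(gSurfaceSigma(flex, spec),
               weightedStat(vals, weights(flex), "SIGMA"),
               tolerance = 1e-12)
})

test_that("Sterimol follows the stated convention exactly", {
  hh <- conf(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  st <- sterimol(hh, c(1, 2))
  expect_equal(st$L, 1.94)
  expect_equal(st$B1, 1.20)
  expect_equal(st$B5, 1.20)

  # a single on-axis substituent atom: B1 = B5 = its radius
  onax <- conf(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 1.3)))
  st2 <- sterimol(onax, c(1, 2))
  expect_equal(st2$B1, defaultVdwRadii()[["O"]])
  expect_equal(st2$B5, defaultVdwRadii()[["O"]])

  # a linear rod grows L but not B1; dense-scan B1 matches a finer scan
  rod3 <- conf(c("C", "C", "C"),
               rbind(c(0, 0, 0), c(0, 0, 1.5), c(0.3, 0, 3.0)))
  rod2 <- conf(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 1.5)))
  s3 <- sterimol(rod3, c(1, 2))
  s2 <- sterimol(rod2, c(1, 2))
  expect_gt(s3$L, s2$L)
  fine <- sterimol(rod3, c(1, 2), scan_step = 0.1)
  expect_equal(s3$B1, fine$B1, tolerance = 1e-3)

  # invariants over random substituents
  for (s in 1:5) {
    set.seed(s)
    cf <- conf(rep("C", 6), rbind(c(0, 0, 0), c(0, 0, 1.5),
                                  matrix(rnorm(12, sd = 2), 4)))
    st <- sterimol(cf, c(1, 2))
    expect_lte(st$B1, st$B5 + 1e-9)
    mv <- rigidMove(cf, seed = s + 50)
    stm <- sterimol(mv$conformer, c(1, 2))
    expect_equal(stm$L, st$L, tolerance = 1e-6)
    expect_equal(stm$B5, st$B5, tolerance = 1e-6)
  }
  expect_error(sterimol(hh, c(1, 1)), "distinct")
})

test_that("sphericity matches analytic unions and orders shapes", {
  one <- conf("C", rbind(c(0, 0, 0)))
  s1 <- sphericity(one, 0.1)
  expect_equal(s1$psi, 1, tolerance = 0.02)

  r <- defaultVdwRadii()[["C"]]
  tangent <- conf(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 2 * r)))
  s2 <- sphericity(tangent, 0.1)
  expect_equal(s2$psi, 2^(-1 / 3), tolerance = 0.02)
  # analytic union values for two tangent equal spheres
  expect_equal(s2$volume, 2 * 4 / 3 * pi * r^3, tolerance = 0.02)
  expect_equal(s2$surface_area, 2 * 4 * pi * r^2, tolerance = 0.02)

  # psi is internally consistent with its own V and A
  expect_equal(s2$psi, pi^(1 / 3) * (6 * s2$volume)^(2 / 3) / s2$surface_area,
               tolerance = 1e-12)

  # an extended rod is less spherical than a compact cluster
  rod <- conf(rep("C", 5), cbind(0, 0, seq(0, 4) * 2.2))
  compact <- conf(rep("C", 5),
                  rbind(c(0, 0, 0), c(2.2, 0, 0), c(0, 2.2, 0),
                        c(0, 0, 2.2), c(1.1, 1.1, 1.1)))
  expect_lt(sphericity(rod, 0.15)$psi, sphericity(compact, 0.15)$psi)
})
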