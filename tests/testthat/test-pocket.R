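test_that("an unobstructed probe sphere returns the analytic volume", {
  far <- conf("C", rbind(c(100, 100, 100)))
  spec <- cavitySpec(probeOffset = 2, cavityRadius = 3,
                     proximalCutoff = 2, gridSpacing = 0.15)
  v <- cavityVolume(far, frameAt(), spec)
  expect_equal(v$V_CAVITY, 4 / 3 * pi * 27, tolerance = 0.005)
  expect_false(v$occluded)
  expect_equal(v$proxV_CAVITY + v$distV_CAVITY, v$V_CAVITY,
               tolerance = 1e-9)
})

test_that("a fully engulfing blocker zeroes the cavity with a warning", {
  big <- conf("C", rbind(c(0, 0, 2)), radii = 50)
  spec <- cavitySpec()
  expect_warning(v <- cavityVolume(big, frameAt(), spec), "inside")
  expect_true(v$occluded)
  expect_equal(v$V_CAVITY, 0)
  expect_equal(v$distV_pct, 0)
})

test_that("grid cavity volume agrees with a Monte-Carlo oracle", {
  spec <- cavitySpec(gridSpacing = 0.15)
  for (s in 1:5) {
    cf <- randomPocketConformer(s)
    fr <- definePocketFrames(cf, c(1, 2))[[1]]
    vg <- cavityVolume(cf, fr, spec)$V_CAVITY
    vmc <- mcCavityVolume(cf, fr, spec, n = 1e6, seed = 100 + s)
    expect_equal(vg, vmc, tolerance = 0.02)
  }
})

test_that("cavity descriptors are invariant under rigid motion", {
  spec <- cavitySpec(gridSpacing = 0.15)
  cf <- randomPocketConformer(3)
  fr <- definePocketFrames(cf, c(1, 2))[[1]]
  v0 <- cavityVolume(cf, fr, spec)
  e0 <- entrySurfaceArea(cf, fr, spec, "ENTRY")
  mv <- rigidMove(cf, seed = 11)
  fr2 <- definePocketFrames(mv$conformer, c(1, 2))[[1]]
  v1 <- cavityVolume(mv$conformer, fr2, spec)
  e1 <- entrySurfaceArea(mv$conformer, fr2, spec, "ENTRY")
  expect_lt(abs(v1$V_CAVITY - v0$V_CAVITY), 0.005 * v0$V_CAVITY + 1e-9)
  expect_lt(abs(e1 - e0), 0.005 * e0 + 1e-9)
})

test_that("halving the grid spacing changes the volume by under 1%", {
  cf <- randomPocketConformer(7)
  fr <- definePocketFrames(cf, c(1, 2))[[1]]
  v1 <- cavityVolume(cf, fr, cavitySpec(gridSpacing = 0.2))$V_CAVITY
  v2 <- cavityVolume(cf, fr, cavitySpec(gridSpacing = 0.1))$V_CAVITY
  expect_lt(abs(v1 - v2), 0.01 * v2)
})

test_that("adding a blocker never increases volume or window area", {
  spec <- cavitySpec(gridSpacing = 0.2)
  cf <- randomPocketConformer(5)
  fr <- definePocketFrames(cf, c(1, 2))[[1]]
  v0 <- cavityVolume(cf, fr, spec)$V_CAVITY
  e0 <- entrySurfaceArea(cf, fr, spec, "ENTRY")
  grown <- conf(c(cf@elements, "C"),
                rbind(cf@coords, c(0.5, 0.3, 3.0)),
                radii = c(cf@radii, 1.7))
  v1 <- cavityVolume(grown, fr, spec)$V_CAVITY
  e1 <- entrySurfaceArea(grown, fr, spec, "ENTRY")
  expect_lte(v1, v0 + 1e-9)
  expect_lte(e1, e0 + 1e-9)
})

test_that("window areas match the analytic disc cases", {
  spec <- cavitySpec(probeOffset = 2, cavityRadius = 4,
                     proximalCutoff = 2, gridSpacing = 0.05)
  far <- conf("C", rbind(c(100, 100, 100)))
  expect_equal(entrySurfaceArea(far, frameAt(), spec, "ENTRY"), 16 * pi,
               tolerance = 1e-9)

  # one r = 1 atom centered on the window plane, inside the disc
  one <- conf("C", rbind(c(1.5, 0, 2)), radii = 1.0)
  expect_equal(entrySurfaceArea(one, frameAt(), spec, "ENTRY"), 15 * pi,
               tolerance = 0.005)

  blocked <- conf("C", rbind(c(0, 0, 2)), radii = 30)
  expect_equal(entrySurfaceArea(blocked, frameAt(), spec, "ENTRY"), 0)
})

test_that("ensemble pocket rows reduce per-conformer, per-site values", {
  spec <- cavitySpec(gridSpacing = 0.25, cavityRadius = 3.0,
                     probeOffset = 2, proximalCutoff = 1.5)

  # symmetric single conformer: MIN = MAX = MEAN, SIGMA = 0
  sym <- makeToyCatalyst(n_conformers = 1L, wobble_deg = 0,
                         mirror_arms = TRUE)
  row <- ensemblePocketRow(sym, c(1, 2), spec)
  for (d in c("V_CAVITY", "proxESA", "distV_pct")) {
    expect_equal(row[[paste0(d, "_MIN")]], row[[paste0(d, "_MAX")]],
                 tolerance = 1e-9)
    expect_equal(row[[paste0(d, "_SIGMA")]], 0, tolerance = 1e-12)
  }

  # compositional oracle: aggregates equal direct per-conformer calls
  ens <- makeToyCatalyst(n_conformers = 2L, wobble_deg = 25, seed = 4)
  row2 <- ensemblePocketRow(ens, c(1, 2), spec)
  w <- weights(ens)
  perConf <- sapply(conformers(ens), function(cf) {
    frs <- definePocketFrames(cf, c(1, 2))
    sapply(1:2, function(s)
      entrySurfaceArea(cf, frs[[s]], spec, "PROXIMAL"))
  })  # 2 sites x 2 conformers
  siteMax <- apply(perConf, 2L, max)
  siteMean <- colMeans(perConf)
  expect_equal(row2$proxESA_MAX, max(siteMax), tolerance = 1e-9)
  expect_equal(row2$proxESA_MEAN, sum(w * siteMean), tolerance = 1e-9)
  expect_equal(row2$proxESA_SIGMA,
               sqrt(sum(w * (siteMean - sum(w * siteMean))^2)),
               tolerance = 1e-9)
  expect_equal(row2$distV_pct_MIN,
               min(sapply(conformers(ens), function(cf) {
                 frs <- definePocketFrames(cf, c(1, 2))
                 min(sapply(1:2, function(s)
                   cavityVolume(cf, frs[[s]], spec)$distV_pct))
               })), tolerance = 1e-9)

  # MIN <= MEAN <= MAX across every descriptor
  nm <- sub("_MIN$", "", grep("_MIN$", names(row2), value = TRUE))
  for (d in nm) {
    expect_lte(row2[[paste0(d, "_MIN")]],
               row2[[paste0(d, "_MEAN")]] + 1e-9)
    expect_lte(row2[[paste0(d, "_MEAN")]],
               row2[[paste0(d, "_MAX")]] + 1e-9)
  }
})

test_that("cavity specifications validate their geometry", {
  expect_error(cavitySpec(probeOffset = -1), "probeOffset")
  expect_error(cavitySpec(proximalCutoff = 7), "proximalCutoff")
  expect_error(cavitySpec(gridSpacing = 2), "gridSpacing")
})
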