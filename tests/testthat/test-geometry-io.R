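R_KCAL <- 1.98720425e-3

test_that("Boltzmann weights match the closed form and its symmetries", {
  expect_equal(boltzmannWeights(rep(5, 4), 500), rep(0.25, 4))

  # energies differing by RT ln 2 force a 2:1 split
  T <- 298.15
  expect_equal(boltzmannWeights(c(0, R_KCAL * T * log(2)), T),
               c(2 / 3, 1 / 3), tolerance = 1e-12)

  # hand evaluation of exp(-dE/RT)
  w <- exp(-1 / (R_KCAL * 298.15))
  expect_equal(boltzmannWeights(c(0, 1), 298.15),
               c(1, w) / (1 + w), tolerance = 1e-12)
  expect_equal(round(boltzmannWeights(c(0, 1), 298.15), 4),
               c(0.8439, 0.1561))

  # shift invariance and ordering over random cases
  for (s in 1:10) {
    set.seed(s)
    e <- rnorm(6, sd = 2)
    w1 <- boltzmannWeights(e, 300)
    expect_equal(sum(w1), 1, tolerance = 1e-12)
    expect_equal(w1, boltzmannWeights(e + 123.4, 300), tolerance = 1e-12)
    expect_equal(order(e), order(-w1))
  }
  expect_error(boltzmannWeights(c(0, NA), 300), "finite")
  expect_error(boltzmannWeights(c(0, 1), -5), "positive")
})

test_that("multi-frame XYZ round-trips and weights come from the energies", {
  p <- tempfile(fileext = ".xyz")
  writeLines(c(
    "2", "frame one E=0.0",
    "Rh   0.0 0.0 1.2", "C  1.0 0.0 2.0",
    "2", "frame two E=0.5",
    "Rh   0.001 0.0 1.2", "C  1.0 0.2 2.0",
    "2", "frame three E=1.0",
    "Rh   0.0 0.1 1.2", "C  1.1 0.0 2.0"), p)
  ens <- readXYZEnsemble(p, temperature = 298.15)
  expect_s4_class(ens, "ConformerEnsemble")
  expect_equal(nConformers(ens), 3L)
  f <- exp(-c(0, 0.5, 1) / (R_KCAL * 298.15))
  expect_equal(weights(ens), f / sum(f), tolerance = 1e-12)

  # degenerate cases
  p1 <- tempfile(fileext = ".xyz")
  writeLines(c("1", "only E=-3.2", "C 0 0 0"), p1)
  expect_equal(weights(readXYZEnsemble(p1)), 1.0)
  p2 <- tempfile(fileext = ".xyz")
  writeLines(c("1", "a E=7", "C 0 0 0", "1", "b E=7", "C 0 0 1"), p2)
  expect_equal(weights(readXYZEnsemble(p2)), c(0.5, 0.5))

  # round trip: coordinates to 1e-6, energies to 1e-9
  out <- tempfile(fileext = ".xyz")
  writeXYZEnsemble(ens, out)
  back <- readXYZEnsemble(out)
  for (i in 1:3) {
    expect_equal(conformers(back)[[i]]@coords, conformers(ens)[[i]]@coords,
                 tolerance = 1e-6)
    expect_equal(conformers(back)[[i]]@energy, conformers(ens)[[i]]@energy,
                 tolerance = 1e-9)
  }
})

test_that("XYZ reader rejects malformed input with frame context", {
  bad1 <- tempfile(fileext = ".xyz")
  writeLines(c("2", "no energy token here", "C 0 0 0", "C 0 0 1"), bad1)
  expect_error(readXYZEnsemble(bad1), "frame 1.*E=")

  bad2 <- tempfile(fileext = ".xyz")
  writeLines(c("1", "a E=0", "C 0 0 0", "1", "b E=0", "N 0 0 0"), bad2)
  expect_error(readXYZEnsemble(bad2), "frame 2.*ordering")

  bad3 <- tempfile(fileext = ".xyz")
  writeLines(c("1", "a E=0", "Zz 0 0 0"), bad3)
  expect_error(readXYZEnsemble(bad3), "radius.*Zz")

  bad4 <- tempfile(fileext = ".xyz")
  writeLines(c("3", "a E=0", "C 0 0 0"), bad4)
  expect_error(readXYZEnsemble(bad4), "frame 1")
})

test_that("hartree energies convert on read", {
  p <- tempfile(fileext = ".xyz")
  writeLines(c("1", "a E=0.001", "C 0 0 0", "1", "b E=0.0", "C 0 0 1"), p)
  ens <- readXYZEnsemble(p, energy_unit = "hartree")
  expect_equal(energies(ens), c(0.6275095, 0), tolerance = 1e-9)
})

test_that("SDF V2000 single conformers parse with a named energy field", {
  p <- tempfile(fileext = ".sdf")
  writeLines(c(
    "ethane-ish", " builder", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    0.0000    0.0000    1.5400 C   0  0",
    "  1  2  1  0",
    "M  END",
    "> <ENERGY>", "2.5", "", "$$$$"), p)
  cf <- readSDFConformer(p)
  expect_equal(cf@energy, 2.5)
  expect_equal(cf@elements, c("C", "C"))
  expect_equal(cf@coords[2, 3], 1.54)
})

test_that("pocket frames center on each metal and point apart", {
  cf <- conf(c("Rh", "Rh"), rbind(c(0, 0, -1.2), c(0, 0, 1.2)))
  fr <- definePocketFrames(cf, c(1, 2))
  expect_equal(fr[[1]]@center, c(0, 0, -1.2))
  expect_equal(fr[[1]]@axis, c(0, 0, -1))
  expect_equal(fr[[2]]@axis, c(0, 0, 1))

  cfx <- conf(c("Rh", "Rh"), rbind(c(0, 0, 0), c(2.4, 0, 0)))
  frx <- definePocketFrames(cfx, c(1, 2))
  expect_equal(frx[[1]]@axis, c(-1, 0, 0))
  expect_equal(frx[[2]]@axis, c(1, 0, 0))

  # antiparallel for arbitrary placements
  for (s in 1:5) {
    set.seed(s)
    cfr <- conf(c("Rh", "Rh", "C"), matrix(rnorm(9, sd = 3), 3))
    fra <- definePocketFrames(cfr, c(1, 2))
    expect_equal(sum(fra[[1]]@axis * fra[[2]]@axis), -1, tolerance = 1e-9)
  }

  bad <- conf(c("C", "Rh"), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(definePocketFrames(bad, c(1, 2)), "expected Rh")
  co <- conf(c("Rh", "Rh"), rbind(c(1, 1, 1), c(1, 1, 1)))
  expect_error(definePocketFrames(co, c(1, 2)), "coincident")
})

test_that("weighted statistics follow the population-sigma convention", {
  expect_equal(weightedStat(c(1, 3), c(0.5, 0.5), "SIGMA"), 1.0)
  for (st in c("MIN", "MAX", "MEAN"))
    expect_equal(weightedStat(c(4, 9), c(1, 0), st), 4)
  expect_equal(weightedStat(c(4, 9), c(1, 0), "SIGMA"), 0)
  expect_equal(weightedStat(c(1, 2, 4), c(0.5, 0.25, 0.25), "MEAN"), 2.0)
  expect_equal(weightedStat(c(1, 2, 4), c(0.5, 0.25, 0.25), "SIGMA"),
               sqrt(1.5), tolerance = 1e-12)
  expect_error(weightedStat(numeric(), numeric(), "MIN"))
  expect_error(weightedStat(c(1, 2), c(0.4, 0.4), "MIN"), "probabilities")
})

test_that("vdW table covers the required elements and accepts overrides", {
  tab <- defaultVdwRadii()
  expect_true(all(c("H", "C", "N", "O", "F", "S", "Cl", "Br", "I", "Rh")
                  %in% names(tab)))
  expect_true(all(tab > 0))
  p <- tempfile(fileext = ".csv")
  write.csv(data.frame(element = c("C", "Xx"),
                       radius_angstrom = c(1.9, 1.1)), p,
            row.names = FALSE)
  tab2 <- readVdwTable(p)
  expect_equal(unname(tab2["C"]), 1.9)
  expect_equal(unname(tab2["Xx"]), 1.1)
  expect_equal(unname(tab2["H"]), unname(tab["H"]))
})
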