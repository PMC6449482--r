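# Flat-bottom restraints: the penalty law, construction helpers, additivity.

test_that("the flat-bottom parabola obeys its closed form", {
  expect_equal(pin_energy(0.9, d = 1, k = 10), 0)
  expect_equal(pin_energy(1.5, d = 1, k = 10), 10 * 0.5^2)
  expect_equal(pin_energy(2.5, d = 2.5, k = 10), 0)
  # continuity at the window edge and strict growth outside, for the
  # half-widths used throughout (1.0 default pins, 2.0 sensor pins,
  # 2.5 bedplate pins)
  for (d in c(1, 2, 2.5)) {
    eps <- 1e-9
    expect_lt(pin_energy(d + eps, d, 10), 1e-15)
    devs <- seq(d, d + 3, by = 0.1)
    e <- pin_energy(devs, d, 10)
    expect_true(all(diff(e) > 0))
    expect_equal(e, 10 * pmax(devs - d, 0)^2)
  }
  expect_error(pin_energy(-0.1), "non-negative")
})

test_that("pins are built from template correspondences", {
  s <- build_system(segment_spec("A", rep("ALA", 5)))
  xyz <- to_cartesian(s)
  ca <- which(s$atoms$name == "CA")
  pins <- make_pins_from_template(s, xyz[ca, ], ca, d = 2.5)
  expect_length(pins, 5)
  expect_true(all(vapply(pins, `[[`, numeric(1), "d") == 2.5))
  expect_length(make_pins_from_template(s, xyz[integer(0), , drop = FALSE],
                                        integer(0)), 0)
  # at the template, total pin energy is zero
  expect_equal(restraint_energy(s, restraint_set(pins = pins))$total, 0)
  # missing correspondence is rejected with the orphans listed
  bad <- xyz[ca, ]
  bad[2, ] <- NA
  expect_error(make_pins_from_template(s, bad, ca), "correspondence")
})

test_that("helix restraints cover (i, i+4) pairs and score geometry", {
  s <- build_system(segment_spec("H", rep("ALA", 10)))
  keys <- names(s$torsions)
  helical <- c(stats::setNames(rep(-57, 9), keys[endsWith(keys, ":phi")]),
               stats::setNames(rep(-47, 10), keys[endsWith(keys, ":psi")]))
  h <- make_helix_restraints(s, "H", 1:10)
  expect_equal(nrow(h$pairs), 6)  # n - 4
  # ideal helix: restraint energy ~ 0
  s_hel <- set_torsions(s, helical)
  e_hel <- restraint_energy(s_hel, restraint_set(helices = list(h)))$total
  expect_lt(e_hel, 0.1)
  # fully extended strand: violated
  e_ext <- restraint_energy(s, restraint_set(helices = list(h)))$total
  expect_gt(e_ext, 1)
  expect_error(make_helix_restraints(s, "H", 1:4), "at least 5")
})

test_that("set energy is the sum of its members", {
  s <- two_segment_system()
  set.seed(5)
  keys <- names(s$torsions)
  s <- set_torsions(s, stats::setNames(stats::runif(length(keys), -150, 150),
                                       keys))
  xyz <- to_cartesian(s)
  ca <- which(s$atoms$name == "CA")
  set <- restraint_set(
    pins = make_pins_from_template(s, xyz[ca, ] + 1.1, ca, d = 0.5),
    distances = list(distance_restraint(1, 20, 0, 2, 10),
                     distance_restraint(3, 30, 5, 50, 10)),
    torsion_windows = list(torsion_window_restraint("A:2:phi", 0, 5, 0.1)),
    helices = list(make_helix_restraints(s, "A", 1:5)))
  got <- restraint_energy(s, set, breakdown = TRUE)
  expect_gte(got$total, 0)
  expect_equal(sum(got$per_restraint$energy), got$total, tolerance = 1e-10)
  expect_equal(nrow(got$per_restraint), n_restraints(set))
  # single violated pin equals its own closed form
  one <- restraint_set(pins = set$pins[1])
  dev <- sqrt(sum((xyz[set$pins[[1]]$atom, ] - set$pins[[1]]$anchor)^2))
  expect_equal(restraint_energy(s, one)$total, pin_energy(dev, 0.5, 10),
               tolerance = 1e-10)
  # audit dump covers every restraint
  expect_equal(nrow(restraint_table(set)), n_restraints(set))
})

test_that("torsion windows wrap the circle correctly", {
  s <- build_system(segment_spec("A", c("ALA", "ALA", "ALA")))
  s <- set_torsions(s, c("A:2:phi" = 178))
  tw <- torsion_window_restraint("A:2:phi", -178, half_width = 5, k = 0.1)
  # 178 vs -178 is a 4-degree separation: inside the window
  expect_equal(restraint_energy(s, restraint_set(torsion_windows = list(tw)))$total, 0)
  tw2 <- torsion_window_restraint("A:2:phi", -170, half_width = 5, k = 0.1)
  # separation 12, window 5: penalty 0.1 * 7^2
  expect_equal(restraint_energy(s, restraint_set(torsion_windows = list(tw2)))$total,
               0.1 * 7^2, tolerance = 1e-9)
})
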