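# Synthetic toy channel: geometry invariants, state correspondence,
# determinism, derived generators.

test_that("the gate ring sits at the state's nominal radius", {
  spec <- default_spec()
  sc <- generate_toy_channel(spec, "closed")
  xc <- to_cartesian(sc)
  for (m in 1:4) {
    i <- atom_index(sc, paste0("S6.", m), 100 * m + 50 + spec$s6_len, "CA")
    expect_equal(sqrt(sum(xc[i, 1:2]^2)), spec$closed_radius,
                 tolerance = 0.1 / spec$closed_radius)
  }
  so <- generate_toy_channel(spec, "open")
  xo <- to_cartesian(so)
  ro <- sapply(1:4, function(m) {
    i <- atom_index(so, paste0("S6.", m), 100 * m + 50 + spec$s6_len, "CA")
    sqrt(sum(xo[i, 1:2]^2))
  })
  expect_true(all(ro > spec$closed_radius + 2))
  expect_error(toy_channel_spec(open_radius = 2, closed_radius = 3),
               "open_radius > closed_radius")
})

test_that("only the state-dependent segments differ between states", {
  spec <- default_spec()
  so <- generate_toy_channel(spec, "open")
  sc <- generate_toy_channel(spec, "closed")
  xo <- to_cartesian(so)
  xc <- to_cartesian(sc)
  # atom correspondence is the identity
  expect_identical(so$atoms$name, sc$atoms$name)
  expect_identical(so$atoms$segment, sc$atoms$segment)
  conserved <- c(paste0("S5.", 1:4), "BP1", "BP2")
  for (sg in conserved) {
    rows <- which(so$atoms$segment == sg)
    expect_identical(xo[rows, ], xc[rows, ])
  }
  for (sg in c(paste0("S6.", 1:4), "AID", "IIS0")) {
    rows <- which(so$atoms$segment == sg)
    expect_gt(max(abs(xo[rows, ] - xc[rows, ])), 0.5)
  }
  corr <- toy_correspondence(spec)
  expect_equal(nrow(corr), nrow(so$atoms))
})

test_that("the AID helix slides along its own axis between states", {
  spec <- default_spec()
  so <- generate_toy_channel(spec, "open")
  sc <- generate_toy_channel(spec, "closed")
  xo <- to_cartesian(so)
  xc <- to_cartesian(sc)
  aid <- which(so$atoms$segment == "AID" & so$atoms$name == "CA")
  d <- colMeans(xc[aid, ]) - colMeans(xo[aid, ])
  ax <- svd(sweep(xo[aid, ], 2, colMeans(xo[aid, ])))$v[, 1]
  along <- abs(sum(d * ax))
  trans <- sqrt(sum((d - sum(d * ax) * ax)^2))
  expect_gt(along, 2)
  expect_gt(along / trans, 2)
})

test_that("generation is reproducible and exports identical PDB", {
  spec <- mini_spec()
  s1 <- generate_toy_channel(spec, "open")
  s2 <- generate_toy_channel(spec, "open")
  expect_identical(to_cartesian(s1), to_cartesian(s2))
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s1, p1)
  write_pdb(s2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("mismatched-sequence generation flags exactly the substitutions", {
  spec <- mini_spec()
  g0 <- generate_mismatched_sequence(spec, 0, seed = 1)
  expect_true(all(g0$map$match))
  expect_equal(g0$map$model_rindex, g0$map$template_rindex)
  g3 <- generate_mismatched_sequence(spec, 3, seed = 1)
  expect_equal(sum(!g3$map$match), 3)
  g3b <- generate_mismatched_sequence(spec, 3, seed = 2)
  expect_false(identical(which(!g3$map$match), which(!g3b$map$match)))
  expect_error(generate_mismatched_sequence(spec, 10000), "more substitutions")
})

test_that("the standing scaffold is satisfied at the canonical states", {
  spec <- default_spec()
  for (st in c("open", "closed")) {
    s <- generate_toy_channel(spec, st)
    rs <- toy_connectivity_restraints(s)
    expect_lt(restraint_energy(s, rs)$total, 5)
  }
})
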