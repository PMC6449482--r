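# Universal P-loop nomenclature and Kabsch superposition.

test_that("the shipped label map reproduces the published anchors", {
  map <- label_map()
  expect_equal(label_to_resid(universal_label(1, "i", 24), map), 402L)
  expect_equal(label_to_resid(universal_label(1, "i", 28), map), 406L)
  expect_equal(label_to_resid(universal_label(1, "o", 6), map), 276L)
  expect_equal(label_to_resid(universal_label(1, "o", 2), map), 272L)
  expect_equal(label_to_resid(universal_label(4, "k", 11), map), 1401L)
  expect_equal(label_to_resid(universal_label(4, "k", 7), map), 1397L)
  expect_equal(label_to_resid(universal_label(2, "i", 20), map), 746L)
  expect_error(label_to_resid(universal_label(1, "k", 99), map), "outside")
})

test_that("label mapping is a bijection over every declared range", {
  map <- label_map()
  for (row in seq_len(nrow(map))) {
    for (ix in map$index_origin[row]:map$index_max[row]) {
      lb <- universal_label(map$repeat_[row], map$segment[row], ix)
      resid <- label_to_resid(lb, map)
      back <- resid_to_label(resid, map)
      expect_equal(format(back), format(lb))
    }
  }
  # the steered ranges resolve to the expected counts: 9 positions x 4
  # repeats for the S4-S5 linker, 16 for a single S6 C-part
  n_k <- sum(vapply(1:4, function(rp) length(3:11), integer(1)))
  expect_equal(n_k, 36)
  resids <- unlist(lapply(1:4, function(rp)
    vapply(3:11, function(ix)
      label_to_resid(universal_label(rp, "k", ix), map), integer(1))))
  expect_equal(length(unique(resids)), 36)
  expect_length(21:36, 16)
})

test_that("label selections resolve alpha carbons on the toy channel", {
  spec <- mini_spec()
  s <- generate_toy_channel(spec, "open")
  map <- toy_label_map(spec)
  sel <- select_by_labels(s, 1:2, "o", 1:6, map)
  expect_length(sel, 12)
  expect_true(all(s$atoms$name[sel] == "CA"))
  expect_true(all(s$atoms$segment[sel] %in% c("S5.1", "S5.2")))
  sel_i <- select_by_labels(s, 2, "i", 2:4, map)
  expect_equal(s$atoms$resid[sel_i], c(252L, 253L, 254L))
  expect_length(select_by_labels(s, integer(0), "o", 1:6, map), 0)
  expect_error(select_by_labels(s, 1, "o", 1:99, map), "unresolvable")
})

test_that("superposition recovers synthetic rigid motions", {
  set.seed(12)
  a <- matrix(rnorm(60, sd = 5), ncol = 3)
  expect_lt(superpose(a, a)$rmsd, 1e-9)
  R <- axis_rot(stats::rnorm(3), 37 * pi / 180)
  b <- sweep(a %*% t(R), 2, c(4, -2, 7), `+`)
  sp <- superpose(b, a)
  expect_lt(sp$rmsd, 1e-6)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  # invariance to pre-composed rigid motions of the mobile set
  R2 <- axis_rot(stats::rnorm(3), 1.1)
  b2 <- sweep(b %*% t(R2), 2, c(-3, 1, 2), `+`)
  expect_lt(abs(superpose(b2, a)$rmsd - sp$rmsd), 1e-8)
  # rotation stays proper on chiral sets (no reflection shortcut)
  chiral <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                  c(1, 1, 2), c(2, 1, 1))
  mirror <- chiral %*% diag(c(-1, 1, 1))
  spm <- superpose(mirror, chiral)
  expect_equal(det(spm$rotation), 1, tolerance = 1e-9)
  expect_gt(spm$rmsd, 0.1)  # a mirror image cannot be superposed properly
  expect_error(superpose(a[1:2, ], a[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate")
})

test_that("per-atom deviations report known displacements after fitting", {
  set.seed(3)
  helixA <- matrix(rnorm(30, sd = 3), ncol = 3)
  helixB <- matrix(rnorm(30, sd = 3), ncol = 3) + 15
  ref <- rbind(helixA, helixB)
  mob <- ref
  mob[11:20, 1] <- mob[11:20, 1] + 2.0  # shift helix B by exactly 2 A
  sp <- superpose(mob, ref, selection = 1:10)
  expect_lt(sp$rmsd, 1e-9)
  expect_equal(mean(sp$deviations[11:20]), 2.0, tolerance = 0.05)
})
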