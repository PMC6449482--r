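# Molecular data model: building, forward kinematics, editing.

test_that("building threads sequences through the topology library", {
  s <- build_system(segment_spec("A", "ALA"))
  expect_equal(nrow(s$residues), 1)
  expect_equal(length(s$roots), 1)
  expect_equal(sum(s$atoms$name == "CB"), 1)

  s10 <- build_system(segment_spec("H", rep("ALA", 10)))
  expect_equal(nrow(s10$residues), 10)
  expect_equal(length(s10$roots), 1)
  # phi/psi flexible by default, omega frozen
  expect_true(all(s10$torsion_flexible[s10$torsion_class == "backbone"]))
  expect_false(any(s10$torsion_flexible[s10$torsion_class == "omega"]))
  # torsion count: 9 phi + 10 psi + 9 omega
  expect_equal(length(s10$torsions), 28)

  expect_error(build_system(segment_spec("A", c("ALA", "XXX"))), "XXX")
  expect_error(segment_spec("A", character(0)), "empty")
})

test_that("forward kinematics is exact, local and idempotent", {
  s <- two_segment_system()
  # all-trans: backbone dihedrals measured from Cartesian equal 180
  expect_equal(measure_torsion(s, "A:2:phi"), 180, tolerance = 1e-6)
  expect_equal(measure_torsion(s, "A:1:psi"), 180, tolerance = 1e-6)

  # round-trip: set arbitrary values, measure them back
  vals <- c("A:2:phi" = -57.3, "A:2:psi" = -47.1, "A:3:chi1" = 63.2,
            "B:3:chi2" = -171.4)
  s <- set_torsions(s, vals)
  for (k in names(vals))
    expect_equal(measure_torsion(s, k), unname(vals[k]), tolerance = 1e-6)

  # idempotence: rebuilding without changes moves nothing
  x1 <- to_cartesian(s)
  x2 <- to_cartesian(s)
  expect_identical(x1, x2)
  fresh <- clone_system(s)
  fresh$cache <- new.env(parent = emptyenv())
  expect_lt(max(abs(to_cartesian(fresh) - x1)), 1e-9)

  # rigidity: bond lengths equal topology values under random coordinates
  set.seed(4)
  keys <- names(s$torsions)
  s2 <- set_torsions(s, stats::setNames(stats::runif(length(keys), -180, 180),
                                        keys))
  xyz <- to_cartesian(s2)
  at <- s2$atoms
  ok <- !is.na(at$parent) & !is.na(at$blen)
  d <- sqrt(rowSums((xyz[at$parent[ok], ] - xyz[at$idx[ok], ])^2))
  expect_lt(max(abs(d - at$blen[ok])), 1e-6)

  # locality: rotating one chi moves only atoms distal to that torsion.
  # Oracle: dependents from an independent parent-tree walk.
  x0 <- to_cartesian(s)
  s3 <- set_torsions(s, c("B:1:chi2" = 95))
  moved <- which(rowSums(abs(to_cartesian(s3) - x0)) > 1e-9)
  par <- s$atoms$parent
  drivers <- which(!is.na(s$atoms$tor) & s$atoms$tor == "B:1:chi2")
  dep <- drivers
  repeat {
    nxt <- which(par %in% dep & !(seq_along(par) %in% dep))
    if (!length(nxt)) break
    dep <- c(dep, nxt)
  }
  expect_setequal(moved, dep)

  # rigid-body property: translating a root translates exactly
  s4 <- set_root(s, "A", pos = s$roots$A$pos + c(1, 2, 3))
  delta <- to_cartesian(s4) - x0
  rows <- which(s$atoms$segment == "A")
  expect_lt(max(abs(sweep(delta[rows, ], 2, c(1, 2, 3)))), 1e-9)
  expect_lt(max(abs(delta[-rows, ])), 1e-9)
})

test_that("all-trans assignment touches exactly the requested residues", {
  s <- two_segment_system()
  set.seed(9)
  keys <- residue_torsions(s, seq_len(nrow(s$residues)), "chi")
  s <- set_torsions(s, stats::setNames(stats::runif(length(keys), -170, 170),
                                       keys))
  before <- get_torsions(s)
  s2 <- set_all_trans(s, c(2L, 7L))
  after <- get_torsions(s2)
  ch2 <- residue_torsions(s, 2L, "chi")
  ch7 <- residue_torsions(s, 7L, "chi")
  expect_true(all(abs(after[c(ch2, ch7)]) == 180))
  untouched <- setdiff(names(before), c(ch2, ch7))
  expect_identical(before[untouched], after[untouched])
  # identity on the empty set
  expect_identical(get_torsions(set_all_trans(s, integer(0))), before)
  expect_error(set_all_trans(s, 99L), "outside")
})

test_that("mutations replace sidechains without touching the backbone", {
  s <- build_system(segment_spec("A", c("ALA", "GLY", "ALA"), 1))
  x0 <- to_cartesian(s)
  m <- apply_mutation(s, "A", 2, "SER")
  expect_true("OG" %in% m$atoms$name[m$atoms$resid == 2])
  ca0 <- x0[atom_index(s, "A", 2, "CA"), ]
  ca1 <- to_cartesian(m)[atom_index(m, "A", 2, "CA"), ]
  expect_lt(max(abs(ca0 - ca1)), 1e-9)
  # mutation locality: other residues' atoms bit-identical
  for (r in c(1, 3)) {
    i0 <- which(s$atoms$resid == r)
    i1 <- which(m$atoms$resid == r)
    expect_equal(to_cartesian(m)[i1, ], x0[i0, ])
  }
})

test_that("protonation variants set the documented formal charges", {
  s <- build_system(segment_spec("A", c("GLY", "ARG", "GLY"), 1))
  m <- apply_mutation(s, "A", 2, "HIS", variant = "HIP-like")
  expect_equal(sum(m$atoms$formal[m$atoms$resid == 2]), 1L)
  m2 <- apply_mutation(s, "A", 2, "HIS", variant = "HID-like")
  expect_equal(sum(m2$atoms$formal[m2$atoms$resid == 2]), 0L)
})

test_that("vicinal disulfides bond the sulfurs and unpin the alpha carbons", {
  s <- build_system(segment_spec("A", c("GLY", "CYS", "CYS", "GLY"), 516))
  m <- apply_mutation(s, "A", 517, "CYS", variant = "CYS-disulfide",
                      disulfide_partner = list(segment = "A", resid = 518))
  sg1 <- atom_index(m, "A", 517, "SG")
  sg2 <- atom_index(m, "A", 518, "SG")
  expect_true(any(apply(m$extra_bonds, 1, function(b)
    setequal(b, c(sg1, sg2)))))
  # no thiol hydrogens on the oxidized pair
  expect_false(any(m$atoms$name == "HG" & m$atoms$resid %in% c(517, 518)))
  # both cysteines excluded from pin sets
  pins <- make_pins_from_template(m, to_cartesian(m))
  pinned_res <- m$atoms$rindex[vapply(pins, `[[`, integer(1), "atom")]
  cys <- c(locate_residue(m, "A", 517), locate_residue(m, "A", 518))
  expect_length(intersect(pinned_res, cys), 0)
  # flexible bond angles registered at the cysteines
  expect_true(any(grepl("517:SG", names(m$angles))))
  # geometric reachability is enforced
  far <- build_system(list(segment_spec("A", c("GLY", "CYS"), 1),
                           segment_spec("B", c("CYS", "GLY"), 10)))
  far <- set_root(far, "B", pos = c(50, 0, 0))
  expect_error(
    apply_mutation(far, "A", 2, "CYS", variant = "CYS-disulfide",
                   disulfide_partner = list(segment = "B", resid = 10)),
    "unreachable")
})

test_that("topology library round-trips through its JSON schema", {
  topo <- default_topology()
  path <- withr::local_tempfile(fileext = ".json")
  write_topology_json(topo, path)
  back <- read_topology_json(path)
  expect_setequal(topology_residues(back), topology_residues(topo))
  s1 <- build_system(segment_spec("A", c("ARG", "TRP")), topo)
  s2 <- build_system(segment_spec("A", c("ARG", "TRP")), back)
  expect_equal(to_cartesian(s1), to_cartesian(s2), tolerance = 1e-12)
})
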