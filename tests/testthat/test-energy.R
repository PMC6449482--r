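# Nonbonded energy: closed forms, brute-force oracle, cutoff behaviour.

test_that("pair energy matches closed forms", {
  opts_inf <- nonbonded_options(cutoff = Inf)
  # Lennard-Jones minimum: at r = rmin_i + rmin_j the energy is -sqrt(ei*ej)
  a <- list(q = 0, eps = 0.12, rmin2 = 1.9, ionized = FALSE)
  b <- list(q = 0, eps = 0.22, rmin2 = 1.7, ionized = FALSE)
  expect_equal(pair_energy(a, b, a$rmin2 + b$rmin2, opts_inf),
               -sqrt(a$eps * b$eps), tolerance = 1e-12)
  # Coulomb with distance-dependent dielectric eps(r) = 4r: two unit
  # charges at 10 A give 332.06/(4*10*10), not truncated for an ionized pair
  ci <- list(q = 1, eps = 0, rmin2 = 1.8, ionized = TRUE)
  expect_equal(pair_energy(ci, ci, 10, nonbonded_options(cutoff = 9)),
               332.06 / (4 * 10 * 10), tolerance = 1e-12)
  # symmetry
  expect_equal(pair_energy(a, b, 3.1), pair_energy(b, a, 3.1))
  expect_error(pair_energy(a, b, 0), "positive")
})

test_that("shifted-force truncation is continuous and differentiable at the cutoff", {
  a <- list(q = 0.3, eps = 0.1, rmin2 = 1.8, ionized = FALSE)
  opts <- nonbonded_options(cutoff = 9, shift_mode = "shifted_force")
  expect_equal(pair_energy(a, a, 9, opts), 0, tolerance = 1e-12)
  expect_equal(pair_energy(a, a, 9.5, opts), 0)
  h <- 1e-4
  deriv <- (pair_energy(a, a, 9 - h, opts) -
              pair_energy(a, a, 9 - 2 * h, opts)) / h
  expect_lt(abs(deriv), 1e-6)
  # shifted_energy removes the value but not the slope
  opts_e <- nonbonded_options(cutoff = 9, shift_mode = "shifted_energy")
  expect_equal(pair_energy(a, a, 9, opts_e), 0, tolerance = 1e-12)
})

test_that("system energy equals an independent all-pairs brute force", {
  set.seed(1)
  s <- two_segment_system()
  # a mildly perturbed, non-clashing conformation so absolute 1e-8
  # comparisons are meaningful
  keys <- names(s$torsions)
  s <- set_torsions(s, stats::setNames(
    180 - stats::runif(length(keys), 0, 40), keys))
  s <- set_root(s, "B", pos = c(14, 3, 2), euler = c(20, -15, 30))
  expect_lt(abs(nonbonded_energy(s, breakdown = FALSE)$total), 1e4)
  xyz <- to_cartesian(s)
  at <- s$atoms
  n <- nrow(at)
  expect_lte(n, 100)

  # independent oracle: double loop with BFS bonded separations
  adj <- vector("list", n)
  for (i in which(!is.na(at$parent))) {
    p <- at$parent[i]
    adj[[i]] <- c(adj[[i]], p)
    adj[[p]] <- c(adj[[p]], i)
  }
  sepf <- function(a, b) {
    if (b %in% adj[[a]]) return(1)
    n2 <- unique(unlist(adj[adj[[a]]]))
    if (b %in% n2) return(2)
    if (b %in% unique(unlist(adj[n2]))) return(3)
    99
  }
  brute <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sp <- sepf(i, j)
    if (sp <= 2) next
    sc <- if (sp == 3) 0.5 else 1
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    rm <- at$rmin2[i] + at$rmin2[j]
    s6 <- (rm / r)^6
    brute <- brute + sc * (sqrt(at$eps[i] * at$eps[j]) * (s6^2 - 2 * s6) +
                             332.06 * at$q[i] * at$q[j] / (4 * r^2))
  }
  got <- nonbonded_energy(s, nonbonded_options(cutoff = Inf),
                          breakdown = TRUE)
  expect_lt(abs(got$total - brute), 1e-8)
  # decomposition identity
  expect_lt(abs(sum(got$per_pair$E_total) - got$total), 1e-8)
})

test_that("isolated distant atoms contribute nothing", {
  s <- build_system(list(segment_spec("A", "ALA", 1),
                         segment_spec("B", "ALA", 1),
                         segment_spec("C", "ALA", 1)))
  s <- set_root(s, "B", pos = c(100, 0, 0))
  s <- set_root(s, "C", pos = c(0, 100, 0))
  e <- nonbonded_energy(s, nonbonded_options(cutoff = 9), breakdown = TRUE)
  inter <- e$per_pair[e$per_pair$rindex_i != e$per_pair$rindex_j, ]
  expect_equal(nrow(inter), 0)
})

test_that("total energy is invariant under rigid motion of the whole system", {
  s <- two_segment_system()
  s <- set_root(s, "B", pos = c(12, 2, 1))
  e0 <- nonbonded_energy(s, breakdown = FALSE)$total
  set.seed(8)
  R <- axis_rot(c(1, 2, 3), 0.7)
  t <- c(5, -3, 2)
  s2 <- s
  for (seg in names(s$roots)) {
    rt <- s$roots[[seg]]
    Rs <- euler_to_rot(rt$euler)
    s2 <- set_root(s2, seg, pos = as.numeric(R %*% rt$pos + t),
                   euler = rad2deg(rot_to_euler(R %*% Rs)))
  }
  e1 <- nonbonded_energy(s2, breakdown = FALSE)$total
  expect_lt(abs(e1 - e0), 1e-8)
})

test_that("group filter restricts pairs and preserves the decomposition", {
  s <- two_segment_system()
  s <- set_root(s, "B", pos = c(7, 1, 0))
  full <- nonbonded_energy(s, nonbonded_options(cutoff = Inf))
  filt <- nonbonded_energy(s, nonbonded_options(cutoff = Inf),
                           group_filter = list("alpha1", "beta_subunit"),
                           groups_as = "group")
  res <- s$residues
  cross <- res$group[full$per_pair$rindex_i] != res$group[full$per_pair$rindex_j]
  expect_equal(filt$total, sum(full$per_pair$E_total[cross]),
               tolerance = 1e-10)
  expect_equal(sum(filt$per_pair$E_total), filt$total, tolerance = 1e-10)
})
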