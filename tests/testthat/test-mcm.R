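# Monte Carlo minimization engine: moves, minimization, convergence rule,
# the grid-search oracle, and seed determinism.

test_that("proposals are reproducible and cover all coordinate classes", {
  s <- two_segment_system()
  cfg <- mcm_config()
  set.seed(101)
  p1 <- propose_move(s, cfg)
  set.seed(101)
  p2 <- propose_move(s, cfg)
  expect_identical(get_torsions(p1$system), get_torsions(p2$system))
  expect_identical(p1$system$roots, p2$system$roots)
  # coverage: over many proposals every coordinate class is hit
  set.seed(7)
  classes <- character(0)
  for (i in 1:300) classes <- c(classes, propose_move(s, cfg)$key$type)
  expect_true(all(c("torsion", "root_pos", "root_euler", "segment") %in%
                    classes))
  frozen <- set_flexible(s, torsions = character(0), roots = character(0),
                         angles = character(0))
  expect_error(propose_move(frozen, cfg), "no flexible")
})

test_that("local minimization is monotone and honors its iteration cap", {
  s <- two_segment_system()
  s <- set_root(s, "B", pos = c(12, 2, 1))
  fit <- local_minimize(s, NULL, 100)
  expect_lte(fit$energy, fit$start_energy)
  # zero-iteration call returns the input unchanged
  f0 <- local_minimize(s, NULL, 0)
  expect_equal(f0$energy, f0$start_energy)
  expect_identical(to_cartesian(f0$system), to_cartesian(s))
  # after a few restarts the minimizer settles: a further restart at the
  # minimum changes (almost) nothing
  prev <- fit
  d <- Inf
  for (k in 1:5) {
    nxt <- local_minimize(prev$system, NULL, 100)
    d <- prev$energy - nxt$energy
    prev <- nxt
    if (d < 0.5) break
  }
  expect_lt(d, 0.5)
})

test_that("a single analytic well is found to high precision", {
  s <- build_system(segment_spec("A", c("ALA", "ALA")))
  s <- set_flexible(s, torsions = "A:2:phi", roots = character(0))
  well <- function(sys) 2 * (wrap_angle(sys$torsions[["A:2:phi"]] - 0.8))^2
  fit <- local_minimize(s, NULL, 200, nonbonded = FALSE, extra_energy = well)
  expect_equal(fit$system$torsions[["A:2:phi"]], 0.8, tolerance = 1e-3)
})

test_that("the convergence rule fires exactly per injected energy sequences", {
  # improvement resets the window; the rule fires at the first index where
  # `window` consecutive minimizations brought no new lowest energy
  expect_equal(convergence_index(c(5, 4, 3, 3, 3, 3, 3, 3), window = 5), 8)
  expect_equal(convergence_index(rep(1, 6), window = 5), 6)
  expect_equal(convergence_index(c(5, 4, 3, 2, 1, 0), window = 5), NA_integer_)
  expect_equal(convergence_index(c(3, 3, 3, 3, 2, 2, 2, 2, 2, 2), window = 5),
               10)
})

test_that("a flat landscape converges after exactly the window length", {
  s <- build_system(segment_spec("A", c("ALA", "ALA")))
  s <- set_flexible(s, torsions = c("A:1:psi", "A:2:phi"),
                    roots = character(0))
  flat <- function(sys) 0
  cfg <- mcm_config(rng_seed = 5, convergence_window = 5,
                    max_minimizations = 100, max_min_iterations = 5)
  tr <- run_mcm(s, NULL, cfg, nonbonded = FALSE, extra_energy = flat)
  expect_true(tr$converged)
  # first minimization sets the lowest; five more without improvement
  expect_equal(tr$n_minimizations, 6)
  # downhill candidates are always accepted
  expect_true(all(tr$proposals$accepted[tr$proposals$energy <
                                          cummin(tr$proposals$energy) + 1e-12]))
})

test_that("MCM attains the exhaustive-grid optimum of a 2-torsion landscape", {
  s <- build_system(segment_spec("A", c("ALA", "ALA")))
  s <- set_flexible(s, torsions = c("A:1:psi", "A:2:phi"),
                    roots = character(0))
  well <- function(th) 1.2 * cos(3 * th) + 0.7 * cos(th - 0.5) +
    0.25 * sin(2 * th)
  pot <- function(sys) well(sys$torsions[["A:1:psi"]]) +
    well(sys$torsions[["A:2:phi"]] + 1.0)
  # independent oracle: exhaustive 1-degree grid (the two torsions are
  # independent, so the grid minimum separates)
  g <- seq(-179, 180, by = 1) * pi / 180
  grid_min <- min(well(g)) + min(well(g + 1.0))
  cfg <- mcm_config(rng_seed = 42, convergence_window = 60,
                    max_minimizations = 500, max_min_iterations = 80)
  tr <- run_mcm(s, NULL, cfg, nonbonded = FALSE, extra_energy = pot)
  expect_lt(abs(tr$lowest$energy - grid_min), 1e-3)
  expect_true(tr$lowest$energy <= min(tr$proposals$energy) + 1e-12)
})

test_that("identical seeds give bit-identical trajectories", {
  s <- two_segment_system()
  s <- set_root(s, "B", pos = c(7, 1, 0))
  cfg <- mcm_config(rng_seed = 77, convergence_window = 3,
                    max_minimizations = 6, max_min_iterations = 10)
  t1 <- run_mcm(s, NULL, cfg)
  t2 <- run_mcm(s, NULL, cfg)
  expect_identical(t1$proposals, t2$proposals)
  expect_identical(to_cartesian(t1$lowest$system),
                   to_cartesian(t2$lowest$system))
})

test_that("a null steer leaves the system near its start", {
  s <- two_segment_system()
  s <- set_root(s, "B", pos = c(7, 1, 0))
  s <- local_minimize(s, NULL, 100)$system
  xyz <- to_cartesian(s)
  ca <- which(s$atoms$name == "CA")
  sched <- steer_schedule(ca, xyz[ca, ], xyz[ca, ], half_width = 0.3, k = 10,
                          n_stages = 3)
  cfg <- mcm_config(rng_seed = 9, convergence_window = 4,
                    max_minimizations = 8, steered_max_min_iterations = 20,
                    stage_accept = 2, stage_proposals = 4)
  res <- run_steered(s, sched, NULL, cfg, stability_minimizations = 0)
  x1 <- to_cartesian(res$steered_system)
  expect_lt(sqrt(mean(rowSums((x1[ca, ] - xyz[ca, ])^2))), 0.5)
  expect_error(run_steered(s, steer_schedule(99999L,
                                             matrix(0, 1, 3),
                                             matrix(0, 1, 3)), NULL, cfg),
               "outside")
})

test_that("trajectory logs serialize as JSONL", {
  s <- build_system(segment_spec("A", c("ALA", "ALA")))
  s <- set_flexible(s, torsions = c("A:1:psi", "A:2:phi"),
                    roots = character(0))
  cfg <- mcm_config(rng_seed = 1, convergence_window = 3,
                    max_minimizations = 5, max_min_iterations = 5)
  tr <- run_mcm(s, NULL, cfg, nonbonded = FALSE,
                extra_energy = function(sys) 0)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_trajectory_jsonl(tr, path)
  lines <- readLines(path)
  expect_length(lines, tr$n_minimizations)
  rec <- jsonlite::fromJSON(lines[1])
  expect_setequal(names(rec), c("n_min", "energy", "accepted",
                                "lowest_so_far"))
})
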