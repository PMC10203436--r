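# Metropolis rule, single-move attempts, sweeps, determinism, conservation.

test_that("metropolis rule accepts downhill moves unconditionally", {
  set.seed(1)
  expect_true(all(replicate(50, metropolis_accept(-0.3))))
  expect_true(all(replicate(50, metropolis_accept(2, work = -2))))   # exponent 0
  expect_true(all(replicate(50, metropolis_accept(1, work = -3))))
})

test_that("two-state occupation sampled through the rule obeys detailed balance", {
  # toy system with E1 - E0 = 1: occupancy ratio must approach exp(-1)
  set.seed(123)
  state <- 0L
  n1 <- 0L
  n <- 40000L
  for (i in seq_len(n)) {
    dE <- if (state == 0L) 1 else -1
    if (metropolis_accept(dE)) state <- 1L - state
    n1 <- n1 + state
  }
  p1 <- n1 / n
  want <- exp(-1) / (1 + exp(-1))
  # 3 sigma for the iid count, doubled for the short autocorrelation time
  tol <- 6 * sqrt(want * (1 - want) / n)
  expect_lt(abs(p1 - want), tol)
})

test_that("frozen configuration: zero-width proposals always accepted", {
  m <- equilibrated_vesicle()
  st <- cmc_state(integer(nrow(m$positions)))
  cfg <- sim_config(sweeps = 1, step = 0)
  set.seed(5)
  r <- run_sweep(m, st, model_params(), cfg)
  expect_equal(unname(r$stats[1, "acc_move"]), 1)
  expect_equal(r$mesh$positions, m$positions)
})

test_that("a fully stretched vertex can never move", {
  m <- stretched_patch()
  st <- cmc_state(integer(nrow(m$positions)))
  cfg <- sim_config(sweeps = 1, step = 0.15)
  cen <- which.min(colSums((t(m$positions) - colMeans(m$positions))^2))
  expect_length(mesh_adjacency(m)[[cen]], 6L)
  set.seed(31)
  acc <- replicate(1000, attempt_vertex_move(m, st, model_params(), cfg,
                                             vertex = cen)$accepted)
  expect_false(any(acc))
})

test_that("invalid flips are rejected before any energy evaluation", {
  m <- build_vesicle(1)   # equatorial ring vertices have degree 4, poles 5
  st <- cmc_state(integer(7))
  cfg <- sim_config(sweeps = 1)
  # flipping a pole-equator edge would drop the equator vertex below 3
  res <- attempt_bond_flip(m, st, model_params(), cfg, edge = c(1L, 2L))
  expect_false(res$accepted)
  expect_true(res$reason %in% c("degree", "duplicate-edge", "length"))
})

test_that("an uphill flip of a bound CMC pair is accepted at the Boltzmann rate", {
  p <- flippable_patch()
  iv <- interior_vertices(p)
  adj <- mesh_adjacency(p)
  v1 <- iv[1]; v2 <- intersect(adj[[v1]], iv)[1]
  lab <- integer(nrow(p$positions)); lab[c(v1, v2)] <- 1L
  st <- cmc_state(lab, species_table(c0 = 1))
  pr <- model_params(kappa = 0, w = 2)
  cfg <- sim_config(sweeps = 1, lmin = 0.5, lmax = 1.7)
  set.seed(17)
  n <- 4000
  acc <- logical(n)
  for (i in seq_len(n))
    acc[i] <- attempt_bond_flip(p, st, pr, cfg, edge = c(v1, v2))$accepted
  want <- exp(-2)
  se3 <- 3 * sqrt(want * (1 - want) / n)
  expect_lt(abs(mean(acc) - want), se3)
})

test_that("sweeps preserve labels, Euler relation and edge bounds", {
  m <- build_vesicle(5)
  sp <- species_table(c0 = c(0.8, -0.6), f = c(0.5, 0))
  st <- plant_labels(m, "two-species-random", rho = c(0.1, 0.1), species = sp,
                     seed = 3)
  counts0 <- table(st$labels)
  pr <- model_params(kappa = 20, w = 2)
  cfg <- sim_config(sweeps = 40, cadence = 40, seed = 21)
  r <- run_simulation(m, st, pr, cfg)
  expect_true(r$mesh$closed)
  V <- nrow(r$mesh$positions)
  expect_equal(V - nrow(r$mesh$edges) + nrow(r$mesh$triangles), 2L)
  expect_identical(table(r$state$labels), counts0)
  el <- edge_lengths(r$mesh)
  expect_true(all(el > 1 & el < 1.7))
})

test_that("equal seeds give bit-identical trajectories", {
  m <- build_vesicle(4)
  st <- plant_labels(m, "random", rho = 0.1,
                     species = species_table(c0 = 1, f = 1), seed = 5)
  pr <- model_params(kappa = 20, w = 1)
  cfg <- sim_config(sweeps = 30, cadence = 10, seed = 99)
  r1 <- run_simulation(m, st, pr, cfg)
  r2 <- run_simulation(m, st, pr, cfg)
  expect_identical(r1$mesh$positions, r2$mesh$positions)
  expect_identical(r1$mesh$triangles, r2$mesh$triangles)
  expect_identical(r1$measures, r2$measures)
})

test_that("zero sweeps yield the initial snapshot only", {
  m <- build_vesicle(3)
  st <- cmc_state(integer(nrow(m$positions)))
  r <- run_simulation(m, st, model_params(), sim_config(sweeps = 0, seed = 1))
  expect_equal(nrow(r$measures), 1L)
  expect_equal(r$measures$sweep, 0L)
  expect_identical(r$mesh$positions, m$positions)
})

test_that("a passive quenched run settles near the analytic sphere minimum", {
  m <- build_vesicle(7)   # V = 247
  st <- cmc_state(integer(nrow(m$positions)))
  pr <- model_params(kappa = 20, beta = 6)   # low temperature: quenched minimum
  cfg <- sim_config(sweeps = 500, cadence = 500, seed = 13)
  r <- run_simulation(m, st, pr, cfg)
  e <- r$measures$e_bend[2]
  expect_gt(e, 8 * pi * 20 * 0.97)       # bounded below by the sphere value
  expect_lt(e, 8 * pi * 20 * 1.6)        # quenched minimum plus small excess
})
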