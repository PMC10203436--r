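# Bending, binding and adhesion energies, and incremental-delta consistency.

bare <- function(mesh) cmc_state(integer(nrow(mesh$positions)))

test_that("bare-sphere bending energy approaches 8 pi kappa, radius-free", {
  pr <- model_params(kappa = 20)
  for (R in c(5, 10)) {
    s <- make_sphere_mesh(6, radius = R)
    expect_lt(abs(bending_energy(s, bare(s), pr) - 8 * pi * 20) / (8 * pi * 20),
              0.03)
  }
  # doubling the radius changes the energy by well under 0.5%
  s <- make_sphere_mesh(6, radius = 7)
  e1 <- bending_energy(s, bare(s), pr)
  s$positions <- s$positions * 2
  e2 <- bending_energy(s, bare(s), pr)
  expect_lt(abs(e2 - e1) / e1, 0.005)
})

test_that("flat patch has zero bending energy", {
  p <- make_plane_patch(7)
  expect_lt(abs(bending_energy(p, bare(p), model_params())), 1e-10)
})

test_that("a fully covered sphere at R = 2/C0 has almost no bending energy", {
  C0 <- 0.25
  s <- make_sphere_mesh(7, radius = 2 / C0)
  e_cov <- bending_energy(s, cmc_state(rep(1L, nrow(s$positions)),
                                       species_table(c0 = C0)),
                          model_params())
  e_bare <- bending_energy(s, bare(s), model_params())
  expect_lt(e_cov / e_bare, 0.03)
})

test_that("binding energy counts CMC-CMC bonds once, bare never binds", {
  p <- make_plane_patch(7)
  sp <- species_table(c0 = 1)
  # single isolated CMC
  lab <- integer(nrow(p$positions))
  lab[interior_vertices(p)[1]] <- 1L
  expect_equal(binding_energy(p, cmc_state(lab, sp), model_params(w = 2)), 0)
  # two adjacent CMCs, w = 2 -> one bond
  iv <- interior_vertices(p)
  adj <- mesh_adjacency(p)
  v1 <- iv[1]; v2 <- intersect(adj[[v1]], iv)[1]
  lab2 <- integer(nrow(p$positions)); lab2[c(v1, v2)] <- 1L
  expect_equal(binding_energy(p, cmc_state(lab2, sp), model_params(w = 2)), -2)
  # 7-vertex hexagonal patch on the triangular lattice: 12 internal bonds
  cen <- which.min(colSums((t(p$positions) - colMeans(p$positions))^2))
  st_hex <- plant_labels(p, "hexagonal-patch", center = cen, species = sp)
  expect_equal(sum(st_hex$labels), 7)
  expect_equal(binding_energy(p, st_hex, model_params(w = 1)), -12)
})

test_that("binding is invariant under species relabelling when w is", {
  m <- build_vesicle(4)
  sp <- species_table(c0 = c(0.8, -0.8))
  st <- plant_labels(m, "two-species-random", rho = c(0.1, 0.1), species = sp,
                     seed = 8)
  pr <- model_params(w = matrix(c(2, 0.5, 0.5, 2), 2))
  e1 <- binding_energy(m, st, pr)
  swapped <- st
  swapped$labels <- c(0L, 2L, 1L)[st$labels + 1L]
  expect_equal(binding_energy(m, swapped, pr), e1)
})

test_that("adhesion energy counts vertices inside the band", {
  m <- place_on_wall(equilibrated_vesicle(), z0 = 0)
  k <- sum(abs(m$positions[, 3]) <= 1)
  expect_gt(k, 0)
  pr <- model_params(w_ad = 0.25, z0 = 0, wall = TRUE)
  expect_equal(adhesion_energy(m, params = pr), -0.25 * k)
  # vesicle entirely above the band
  m2 <- m; m2$positions[, 3] <- m2$positions[, 3] + 5
  expect_equal(adhesion_energy(m2, params = pr), 0)
  expect_equal(adhesion_energy(m, params = model_params(w_ad = 0, wall = TRUE)), 0)
})

test_that("bending energy is invariant under rigid motions", {
  m <- equilibrated_vesicle()
  pr <- model_params(kappa = 20)
  e0 <- bending_energy(m, bare(m), pr)
  th <- 0.7; ph <- 1.3
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3)
  m2 <- m
  m2$positions <- m$positions %*% (Rz %*% Rx) +
    matrix(c(3, -2, 11), nrow(m$positions), 3, byrow = TRUE)
  expect_lt(abs(bending_energy(m2, bare(m2), pr) - e0) / e0, 1e-10)
})

test_that("incremental delta equals the full recomputation difference", {
  m <- equilibrated_vesicle()
  st <- plant_labels(m, "random", rho = 0.2,
                     species = species_table(c0 = 0.8), seed = 6)
  pr <- model_params(kappa = 20, w = 2, w_ad = 0.25,
                     z0 = min(m$positions[, 3]), wall = TRUE)
  set.seed(99)
  etot <- function(mm) sum(total_energy(mm, st, pr)[1:3])
  e0 <- etot(m)
  for (i in 1:120) {
    v <- sample(nrow(m$positions), 1)
    np <- m$positions[v, ] + runif(3, -0.12, 0.12)
    dE <- local_energy_delta(m, st, pr,
                             list(type = "move", vertex = v, new_position = np))
    m2 <- m; m2$positions[v, ] <- np
    expect_lt(abs((etot(m2) - e0) - dE) / max(1, abs(dE)), 1e-8)
  }
  # null move
  expect_equal(local_energy_delta(m, st, pr,
                                  list(type = "move", vertex = 3,
                                       new_position = m$positions[3, ])), 0)
})

test_that("flip delta matches recomputation and the binding change is +-w", {
  # pure binding change on a flat patch: kappa = 0 isolates the bond term
  p <- flippable_patch()
  iv <- interior_vertices(p)
  adj <- mesh_adjacency(p)
  v1 <- iv[1]; v2 <- intersect(adj[[v1]], iv)[1]
  lab <- integer(nrow(p$positions)); lab[c(v1, v2)] <- 1L
  st <- cmc_state(lab, species_table(c0 = 1))
  pr0 <- model_params(kappa = 0, w = 2)
  dE <- local_energy_delta(p, st, pr0, list(type = "flip", edge = c(v1, v2)))
  expect_equal(dE, 2)            # the CMC bond is broken exactly
  # and with the CMCs on the opposite diagonal the bond is created
  common <- intersect(mesh_adjacency(p)[[v1]], mesh_adjacency(p)[[v2]])
  lab2 <- integer(nrow(p$positions)); lab2[common] <- 1L
  st2 <- cmc_state(lab2, species_table(c0 = 1))
  expect_equal(local_energy_delta(p, st2, pr0,
                                  list(type = "flip", edge = c(v1, v2))), -2)
  # full-recompute agreement with bending on
  m <- equilibrated_vesicle()
  stm <- plant_labels(m, "random", rho = 0.2,
                      species = species_table(c0 = 0.8), seed = 6)
  prm <- model_params(kappa = 20, w = 2)
  e0 <- sum(total_energy(m, stm, prm)[1:3])
  checked <- 0L
  for (i in seq_len(nrow(m$edges))) {
    dE <- local_energy_delta(m, stm, prm,
                             list(type = "flip", edge = m$edges[i, ]))
    if (is.na(dE)) next
    fl <- bond_flip(m, m$edges[i, ])
    e1 <- sum(total_energy(fl$mesh, stm, prm)[1:3])
    expect_lt(abs((e1 - e0) - dE) / max(1, abs(dE)), 1e-8)
    checked <- checked + 1L
    if (checked >= 10L) break
  }
  expect_gt(checked, 0L)
})
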