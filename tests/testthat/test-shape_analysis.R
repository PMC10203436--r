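# Cluster statistics, gyration spectrum, perimeter, segregation, phases,
# hole area.

test_that("cluster finding agrees with the flood-fill oracle", {
  m <- build_vesicle(5)
  for (seed in 1:5) {
    st <- plant_labels(m, "random", rho = 0.25,
                       species = species_table(c0 = 1), seed = seed)
    got <- canon_clusters(find_clusters(m, st))
    want <- canon_clusters(oracle_clusters(m, st$labels))
    expect_identical(got, want)
  }
  # no CMC -> empty list
  expect_identical(find_clusters(m, cmc_state(integer(nrow(m$positions)))),
                   list())
})

test_that("planted caps form the expected clusters", {
  m <- make_sphere_mesh(6, radius = 10)
  st <- plant_labels(m, "cap", size = 20, species = species_table(c0 = 1))
  cl <- find_clusters(m, st)
  expect_length(cl, 1L)
  expect_length(cl[[1]], 20L)
  # second cap at the opposite pole, separated by bare membrane
  south <- which.min(m$positions[, 3])
  st2 <- st
  st2$labels[c(south, mesh_adjacency(m)[[south]])] <- 1L
  expect_length(find_clusters(m, st2), 2L)
})

test_that("mean cluster size and its restricted variant", {
  fake <- lapply(c(1, 1, 2, 8, 40), seq_len)
  expect_equal(mean_cluster_size(fake), mean(c(1, 1, 2, 8, 40)))
  expect_equal(mean_cluster_size(fake, restrict_below = 10), 3)
  expect_equal(mean_cluster_size(list(1L, 5L, 9L)), 1)   # all singletons
  expect_equal(mean_cluster_size(list(seq_len(450))), 450)
  expect_true(is.na(mean_cluster_size(list())))
  expect_true(is.na(mean_cluster_size(fake, restrict_below = 1)))
})

test_that("gyration spectrum matches closed forms", {
  # 4 points at (+-1,0,0), (0,+-2,0): spectrum (0, 1/2, 2)
  pts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 2, 0), c(0, -2, 0))
  expect_equal(gyration_eigenvalues(pts), c(0, 0.5, 2))
  # collinear points: two zero eigenvalues
  line <- make_gyration_pointsets("line", 2000, L = 4, seed = 2)
  lam <- gyration_eigenvalues(line)
  expect_equal(lam[1:2], c(0, 0))
  expect_lt(abs(lam[3] - 16 / 12) / (16 / 12), 0.05)
  # sphere shell: isotropic spectrum R^2/3
  sh <- make_gyration_pointsets("sphere-shell", 20000, R = 3, seed = 3)
  lam <- gyration_eigenvalues(sh)
  expect_lt(max(abs(lam - 3)) / 3, 0.02)
  # trace identity on random clouds
  set.seed(11)
  for (i in 1:5) {
    X <- matrix(rnorm(300), ncol = 3)
    lam <- gyration_eigenvalues(X)
    msd <- mean(rowSums(sweep(X, 2, colMeans(X))^2))
    expect_lt(abs(sum(lam) - msd) / msd, 1e-10)
  }
})

test_that("boundary perimeter per CMC counts CMC-bare edges", {
  p <- make_plane_patch(11)
  cen <- which.min(colSums((t(p$positions) - colMeans(p$positions))^2))
  st <- plant_labels(p, "hexagonal-patch", center = cen,
                     species = species_table(c0 = 1))
  expect_equal(cluster_perimeter(p, st), 18 / 7)
  # a second, identical patch leaves the mean unchanged: pick a deep-interior
  # degree-6 vertex (whole neighbour ring interior) away from the first patch
  adj <- mesh_adjacency(p)
  iv <- interior_vertices(p)
  deep <- iv[vapply(iv, function(v) all(adj[[v]] %in% iv), logical(1))]
  d <- colSums((t(p$positions[deep, ]) - p$positions[cen, ])^2)
  cen2 <- deep[which.max(d)]
  st2 <- st
  st2$labels[c(cen2, adj[[cen2]])] <- 1L
  expect_length(find_clusters(p, st2), 2L)
  expect_equal(cluster_perimeter(p, st2), 18 / 7)
  # all-CMC surface has no boundary at all
  m <- build_vesicle(3)
  st_all <- cmc_state(rep(1L, nrow(m$positions)), species_table(c0 = 1))
  expect_equal(cluster_perimeter(m, st_all), 0)
  # geometric variant scales with the lattice constant
  expect_equal(cluster_perimeter(p, st, geometric = TRUE), 1.2 * 18 / 7)
})

test_that("segregation factor spans phase separation to alternation", {
  m <- build_vesicle(4)
  sp2 <- species_table(c0 = c(1, 1))
  # single species everywhere: complete phase separation
  expect_equal(segregation_factor(m, cmc_state(rep(1L, nrow(m$positions)), sp2)), 1)
  # alternating colouring of an isolated 6-ring: S = -1
  p <- make_plane_patch(9)
  cen <- which.min(colSums((t(p$positions) - colMeans(p$positions))^2))
  ring <- mesh_adjacency(p)[[cen]]
  # order the ring by angle around the centre so neighbours alternate
  relv <- sweep(p$positions[ring, 1:2], 2, p$positions[cen, 1:2])
  ring <- ring[order(atan2(relv[, 2], relv[, 1]))]
  lab <- integer(nrow(p$positions))
  lab[ring] <- rep(c(1L, 2L), 3)
  expect_equal(segregation_factor(p, cmc_state(lab, sp2)), -1)
  # random equal mixture: near zero
  set.seed(1)
  s_vals <- vapply(1:10, function(seed) {
    st <- cmc_state(sample(c(1L, 2L), nrow(m$positions), replace = TRUE), sp2)
    segregation_factor(m, st)
  }, numeric(1))
  expect_lt(abs(mean(s_vals)), 0.05)
  # no CMC-CMC edge: undefined
  st1 <- cmc_state(integer(nrow(m$positions)), sp2)
  expect_true(is.na(segregation_factor(m, st1)))
  # invariant under global relabelling
  st <- plant_labels(m, "two-species-random", rho = c(0.2, 0.2), species = sp2,
                     seed = 4)
  sw <- st; sw$labels <- c(0L, 2L, 1L)[st$labels + 1L]
  expect_equal(segregation_factor(m, sw), segregation_factor(m, st))
})

test_that("phase classification follows the ordered decision list", {
  cl <- function(...) classify_phase(list(...))
  # all-singleton gas state
  expect_equal(cl(mean_cluster_size_small = 1, mean_cluster_size = 1,
                  perimeter = NA, lambda1_sq = 100, lambda2_sq = 100), "gas")
  expect_equal(cl(mean_cluster_size_small = 50, mean_cluster_size = 50,
                  perimeter = 0.2, lambda1_sq = 500, lambda2_sq = 600),
               "pearling")
  expect_equal(cl(mean_cluster_size_small = 5, mean_cluster_size = 300,
                  perimeter = 2.5, lambda1_sq = 30, lambda2_sq = 200), "flat")
  expect_equal(cl(mean_cluster_size_small = 5, mean_cluster_size = 300,
                  perimeter = 2.5, lambda1_sq = 70, lambda2_sq = 120),
               "elongated")
  expect_equal(cl(mean_cluster_size_small = 5, mean_cluster_size = 300,
                  perimeter = 2.5, lambda1_sq = 70, lambda2_sq = 200), "buds")
  expect_equal(cl(mean_cluster_size_small = 5, mean_cluster_size = 300,
                  perimeter = 1.0, lambda1_sq = 70, lambda2_sq = 200), "mixed")
  # idempotent / total
  x <- list(mean_cluster_size_small = 5, mean_cluster_size = 300,
            perimeter = 1, lambda1_sq = 70, lambda2_sq = 200)
  expect_identical(classify_phase(x), classify_phase(x))
  other <- classify_phase(list(mean_cluster_size_small = NA,
                               mean_cluster_size = NA, perimeter = NA,
                               lambda1_sq = 1, lambda2_sq = 2))
  expect_equal(as.character(other), "other")
})

test_that("hole area reproduces planar polygons and ignores orientation", {
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(hole_area(square, 1:4), 1)
  expect_equal(hole_area(square, 4:1), 1)
  th <- 2 * pi * (0:5) / 6
  hexa <- cbind(cos(th), sin(th), 5)   # off the origin plane: translation-safe
  expect_equal(hole_area(hexa, 1:6), 3 * sqrt(3) / 2)
  expect_error(hole_area(square, c(1, 2)), "at least 3")
  expect_error(hole_area(square, c(1, 2, 2)), "distinct|at least 3")
})
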