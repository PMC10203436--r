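# Deterministic generators of test inputs: analytic meshes with known
# curvature, planted CMC label patterns, and point sets with closed-form
# gyration spectra.

#' Triangulated sphere with analytic curvature
#'
#' Subdivided icosahedron projected onto a sphere of the given radius: every
#' vertex has analytic mean curvature `h = 1/R`.  `V = 10 * nshell^2 + 2`.
#'
#' @param nshell subdivision order (>= 1).
#' @param radius sphere radius (lmin units).
#' @return a closed `vesicle_mesh`.
#' @export
make_sphere_mesh <- function(nshell, radius = 10) {
  if (nshell < 1) stop("nshell must be >= 1")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  sub <- subdivide_triangulation(v, f, as.integer(nshell))
  r0 <- sqrt(rowSums(sub$positions^2))
  pos <- sub$positions * (radius / r0)
  tri <- sub$triangles
  if (cpp_signed_volume(pos, tri) < 0) tri <- tri[, c(1L, 3L, 2L)]
  vesicle_mesh(pos, tri)
}

#' Triangulated cylinder patch with analytic curvature
#'
#' Open cylindrical tube of `n_axial` vertex rings wrapped by `n_radial`
#' vertices; interior vertices have analytic mean curvature `h = 1/(2R)`.
#' Rings are offset by half a step for near-equilateral triangles.
#'
#' @param n_axial number of rings along the axis (>= 3).
#' @param n_radial number of vertices around the circumference (>= 3).
#' @param radius cylinder radius.
#' @return an open `vesicle_mesh` (boundary at the two end rings).
#' @export
make_cylinder_patch <- function(n_axial, n_radial, radius = 5) {
  if (n_axial < 3 || n_radial < 3) stop("need n_axial >= 3 and n_radial >= 3")
  dtheta <- 2 * pi / n_radial
  dz <- radius * dtheta * sqrt(3) / 2    # near-equilateral triangles
  pos <- matrix(0, n_axial * n_radial, 3)
  idx <- function(i, j) (i - 1L) * n_radial + ((j - 1L) %% n_radial) + 1L
  for (i in seq_len(n_axial)) {
    th <- dtheta * (seq_len(n_radial) - 1 + 0.5 * (i %% 2))
    rows <- idx(i, seq_len(n_radial))
    pos[rows, ] <- cbind(radius * cos(th), radius * sin(th), (i - 1) * dz)
  }
  tri <- list()
  for (i in seq_len(n_axial - 1L)) {
    for (j in seq_len(n_radial)) {
      if (i %% 2 == 1L) {
        tri[[length(tri) + 1L]] <- c(idx(i, j), idx(i, j + 1L), idx(i + 1L, j))
        tri[[length(tri) + 1L]] <- c(idx(i, j + 1L), idx(i + 1L, j + 1L), idx(i + 1L, j))
      } else {
        tri[[length(tri) + 1L]] <- c(idx(i, j), idx(i, j + 1L), idx(i + 1L, j + 1L))
        tri[[length(tri) + 1L]] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i + 1L, j))
      }
    }
  }
  tri <- do.call(rbind, tri)
  # orient faces outward (normals away from the axis)
  a <- pos[tri[, 1], ]; b <- pos[tri[, 2], ]; c3 <- pos[tri[, 3], ]
  n <- cbind((b[, 2] - a[, 2]) * (c3[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (c3[, 2] - a[, 2]),
             (b[, 3] - a[, 3]) * (c3[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (c3[, 3] - a[, 3]),
             (b[, 1] - a[, 1]) * (c3[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c3[, 1] - a[, 1]))
  cen <- (a + b + c3) / 3
  flip <- rowSums(n[, 1:2] * cen[, 1:2]) < 0
  tri[flip, ] <- tri[flip, c(1L, 3L, 2L)]
  vesicle_mesh(pos, tri)
}

#' Flat triangulated patch
#'
#' `n x n` triangular lattice in the z = 0 plane; interior vertices have
#' degree 6 and zero curvature.
#'
#' @param n lattice size (>= 3).
#' @param spacing lattice constant.
#' @return an open `vesicle_mesh`.
#' @export
make_plane_patch <- function(n, spacing = 1.2) {
  if (n < 3) stop("n must be >= 3")
  ij <- expand.grid(i = 0:(n - 1L), j = 0:(n - 1L))
  pos <- cbind(spacing * (ij$i + ij$j / 2), spacing * ij$j * sqrt(3) / 2, 0)
  idx <- function(i, j) j * n + i + 1L
  tri <- list()
  for (j in 0:(n - 2L)) for (i in 0:(n - 2L)) {
    tri[[length(tri) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i, j + 1L))
    tri[[length(tri) + 1L]] <- c(idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  }
  vesicle_mesh(pos, do.call(rbind, tri))
}

#' Interior vertices of an open patch
#'
#' Vertices not touching any boundary edge; useful to restrict curvature
#' checks to where the analytic value applies.
#'
#' @param mesh an open `vesicle_mesh`.
#' @return integer vertex indices.
#' @export
interior_vertices <- function(mesh) {
  einfo <- cpp_edges(mesh$triangles, nrow(mesh$positions))
  bnd <- unique(c(einfo$edges[einfo$ntri == 1L, ]))
  setdiff(seq_len(nrow(mesh$positions)), bnd)
}

#' Plant a deterministic CMC label pattern
#'
#' Supported kinds: `"cap"` (graph-geodesic ball of `size` vertices around the
#' topmost vertex), `"ring"` (band of polar angle in `[theta]` degrees),
#' `"hexagonal-patch"` (a centre vertex plus its first neighbour ring),
#' `"stripes"` (alternating polar bands of `size` degrees), `"random"`
#' (fraction `rho` of vertices, species 1), and `"two-species-random"`
#' (disjoint fractions `rho` = c(rho1, rho2)).  All kinds are deterministic
#' given `seed`.
#'
#' @param mesh a `vesicle_mesh`.
#' @param kind pattern kind.
#' @param size vertex count (cap) or band width in degrees (stripes).
#' @param theta length-2 polar-angle interval in degrees (ring).
#' @param rho density (random) or per-species densities (two-species-random).
#' @param center centre vertex for `"hexagonal-patch"`; defaults to the
#'   vertex nearest the centroid of an open patch, or the topmost vertex.
#' @param species a [species_table()] for the resulting state.
#' @param seed RNG seed for the random kinds.
#' @return a `cmc_state`.
#' @export
plant_labels <- function(mesh, kind = c("cap", "ring", "hexagonal-patch",
                                        "stripes", "random",
                                        "two-species-random"),
                         size = 7, theta = c(60, 90), rho = 0.1, center = NULL,
                         species = species_table(), seed = 1) {
  kind <- match.arg(kind)
  V <- nrow(mesh$positions)
  labels <- integer(V)
  adj <- NULL
  if (kind %in% c("cap", "hexagonal-patch")) adj <- mesh_adjacency(mesh)
  if (kind == "cap") {
    if (size > V) stop("requested cap larger than the mesh")
    pole <- if (is.null(center)) which.max(mesh$positions[, 3]) else as.integer(center)
    # breadth-first rings; the last partial ring filled nearest-first
    sel <- pole
    frontier <- pole
    visited <- logical(V); visited[pole] <- TRUE
    while (length(sel) < size) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!visited[nxt]]
      if (length(nxt) == 0L) break
      visited[nxt] <- TRUE
      if (length(sel) + length(nxt) > size) {
        d <- colSums((t(mesh$positions[nxt, , drop = FALSE]) -
                        mesh$positions[pole, ])^2)
        nxt <- nxt[order(d)][seq_len(size - length(sel))]
      }
      sel <- c(sel, nxt)
      frontier <- nxt
    }
    labels[sel] <- 1L
  } else if (kind == "hexagonal-patch") {
    if (is.null(center)) {
      cen <- colMeans(mesh$positions)
      center <- which.min(colSums((t(mesh$positions) - cen)^2))
    }
    labels[c(center, adj[[center]])] <- 1L
  } else if (kind %in% c("ring", "stripes")) {
    cen <- colMeans(mesh$positions)
    rel <- sweep(mesh$positions, 2, cen)
    pol <- acos(pmin(1, pmax(-1, rel[, 3] / sqrt(rowSums(rel^2))))) * 180 / pi
    if (kind == "ring") {
      labels[pol >= theta[1] & pol <= theta[2]] <- 1L
    } else {
      labels[(pol %/% size) %% 2 == 0] <- 1L
    }
  } else if (kind == "random") {
    k <- round(rho * V)
    if (k > V) stop("rho too large")
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    labels[sample.int(V, k)] <- 1L
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  } else {
    ks <- round(rho * V)
    if (sum(ks) > V) stop("species fractions exceed 1")
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    pick <- sample.int(V, sum(ks))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    labels[pick[seq_len(ks[1])]] <- 1L
    if (length(ks) > 1L && ks[2] > 0)
      labels[pick[ks[1] + seq_len(ks[2])]] <- 2L
  }
  cmc_state(labels, species)
}

#' Point sets with closed-form gyration spectra
#'
#' `"sphere-shell"`: uniform on a sphere of radius `R` (spectrum
#' `R^2/3` per axis); `"line"`: uniform on a segment of length `L` along z
#' (spectrum `(0, 0, L^2/12)`); `"ellipsoid"`: uniform-angle surface
#' parametrization with semi-axes `a, b, c`.
#'
#' @param kind one of `"sphere-shell"`, `"line"`, `"ellipsoid"`.
#' @param n number of points.
#' @param R,L,axes shape parameters.
#' @param seed RNG seed.
#' @return n x 3 coordinate matrix.
#' @export
make_gyration_pointsets <- function(kind = c("sphere-shell", "line", "ellipsoid"),
                                    n, R = 1, L = 1, axes = c(1, 2, 3),
                                    seed = 1) {
  kind <- match.arg(kind)
  if (n < 1) stop("n must be >= 1")
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  if (kind == "line") {
    return(cbind(0, 0, runif(n, -L / 2, L / 2)))
  }
  u <- runif(n, -1, 1)            # cos(polar), uniform on the sphere
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  dirs <- cbind(s * cos(phi), s * sin(phi), u)
  if (kind == "sphere-shell") return(R * dirs)
  sweep(dirs, 2, axes, `*`)
}

#' Translate a vesicle onto an adhesive wall
#'
#' Rigidly shifts the mesh so that its lowest vertex sits at the wall height
#' `z0` (inside the adhesion band), the starting condition for spreading runs.
#'
#' @param mesh a `vesicle_mesh`.
#' @param z0 wall height.
#' @return the translated `vesicle_mesh`.
#' @export
place_on_wall <- function(mesh, z0 = 0) {
  mesh$positions[, 3] <- mesh$positions[, 3] - min(mesh$positions[, 3]) + z0
  mesh
}
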