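# Triangulated closed-surface data structure and topology moves.
# All coordinates are dimensionless, in units of the hard-core edge length
# lmin = 1; the vesicle is a closed, outward-oriented, genus-0 triangulation.

#' Construct a vesicle mesh object
#'
#' Wraps a vertex position matrix and a triangle index matrix into a
#' `vesicle_mesh`: the edge list, manifoldness and (for closed surfaces) the
#' Euler relation are derived and checked on construction.
#'
#' @param positions numeric matrix (V x 3) of vertex coordinates, in units of
#'   the minimal edge length.
#' @param triangles integer matrix (T x 3) of 1-based vertex triples with
#'   consistent (outward, for closed surfaces) orientation.
#' @param validate check manifoldness and the Euler relation (default `TRUE`).
#' @return An object of class `vesicle_mesh` with elements `positions`,
#'   `triangles`, `edges` (E x 2, each row sorted), and `closed`.
#' @export
vesicle_mesh <- function(positions, triangles, validate = TRUE) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(positions) != 3L) stop("positions must have 3 columns")
  if (ncol(triangles) != 3L) stop("triangles must have 3 columns")
  einfo <- cpp_edges(triangles, nrow(positions))
  mesh <- structure(
    list(positions = positions, triangles = triangles,
         edges = einfo$edges, closed = einfo$closed),
    class = "vesicle_mesh")
  if (validate) {
    if (mesh$closed) {
      V <- nrow(positions); E <- nrow(mesh$edges); Tn <- nrow(triangles)
      if (V - E + Tn != 2L)
        stop("closed mesh violates the Euler relation V - E + T = 2 (genus != 0?)")
    }
    deg <- tabulate(c(mesh$edges), nbins = nrow(positions))
    if (mesh$closed && any(deg < 3L)) stop("vertex degree below 3")
  }
  mesh
}

#' @export
print.vesicle_mesh <- function(x, ...) {
  cat(sprintf("vesicle_mesh: %d vertices, %d edges, %d triangles (%s)\n",
              nrow(x$positions), nrow(x$edges), nrow(x$triangles),
              if (x$closed) "closed" else "open patch"))
  el <- edge_lengths(x)
  cat(sprintf("  edge length: %.3f-%.3f (mean %.3f)\n",
              min(el), max(el), mean(el)))
  invisible(x)
}

#' Edge lengths of a mesh
#' @param mesh a `vesicle_mesh`.
#' @return numeric vector, one length per edge.
#' @export
edge_lengths <- function(mesh) {
  d <- mesh$positions[mesh$edges[, 1], , drop = FALSE] -
       mesh$positions[mesh$edges[, 2], , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' Vertex adjacency list
#' @param mesh a `vesicle_mesh`.
#' @return list of integer vectors; element `i` holds the neighbours of
#'   vertex `i`.
#' @export
mesh_adjacency <- function(mesh) {
  V <- nrow(mesh$positions)
  adj <- split(c(mesh$edges[, 2], mesh$edges[, 1]),
               factor(c(mesh$edges[, 1], mesh$edges[, 2]), levels = seq_len(V)))
  lapply(adj, as.integer)
}

# Subdivide each face of a base triangulation into n^2 triangles, merging
# shared boundary vertices exactly (ids keyed symbolically, not by rounding).
subdivide_triangulation <- function(verts, faces, n) {
  nface <- nrow(faces)
  maxv <- nface * (n + 1L) * (n + 2L) / 2L
  coords <- matrix(0, maxv, 3L)
  keys <- new.env(hash = TRUE, parent = emptyenv())
  nv <- 0L
  getid <- function(key, coord) {
    id <- keys[[key]]
    if (!is.null(id)) return(id)
    nv <<- nv + 1L
    coords[nv, ] <<- coord
    keys[[key]] <- nv
    nv
  }
  tris <- matrix(0L, nface * n * n, 3L)
  ntri <- 0L
  for (fc in seq_len(nface)) {
    a <- faces[fc, 1L]; b <- faces[fc, 2L]; cc <- faces[fc, 3L]
    idx <- matrix(NA_integer_, n + 1L, n + 1L)   # idx[i+1, j+1]; i wt of b, j wt of cc
    for (i in 0:n) for (j in 0:(n - i)) {
      k <- n - i - j   # weight of a
      coord <- (k * verts[a, ] + i * verts[b, ] + j * verts[cc, ]) / n
      key <-
        if (k == n) paste0("v", a)
        else if (i == n) paste0("v", b)
        else if (j == n) paste0("v", cc)
        else if (j == 0) edge_key(a, b, k, i)
        else if (i == 0) edge_key(a, cc, k, j)
        else if (k == 0) edge_key(b, cc, i, j)
        else paste0("f", fc, "_", i, "_", j)
      idx[i + 1L, j + 1L] <- getid(key, coord)
    }
    for (i in 0:(n - 1L)) for (j in 0:(n - 1L - i)) {
      ntri <- ntri + 1L
      tris[ntri, ] <- c(idx[i + 1L, j + 1L], idx[i + 2L, j + 1L], idx[i + 1L, j + 2L])
      if (j < n - 1L - i) {
        ntri <- ntri + 1L
        tris[ntri, ] <- c(idx[i + 2L, j + 1L], idx[i + 2L, j + 2L], idx[i + 1L, j + 2L])
      }
    }
  }
  list(positions = coords[seq_len(nv), , drop = FALSE],
       triangles = tris[seq_len(ntri), , drop = FALSE])
}

# canonical id of an interior point along edge (u, v) carrying barycentric
# weights (wu, wv); keyed by the weight of the larger-id endpoint so both
# faces sharing the edge agree on the id
edge_key <- function(u, v, wu, wv) {
  s <- min(u, v); t <- max(u, v)
  wt <- if (t == v) wv else wu
  paste0("e", s, "_", t, "_", wt)
}

#' Build the initial quasi-spherical vesicle
#'
#' Constructs a closed triangulated vesicle by subdividing each face of a
#' pentagonal dipyramid into `nshell^2` triangles, giving exactly
#' `V = 5 * nshell^2 + 2` vertices (so `nshell = 30` gives the reference
#' vesicle with 4502 vertices).  All edges of the faceted surface are exactly
#' equal, and the mesh is uniformly scaled so that the mean edge length equals
#' `target_edge_length`; Monte-Carlo equilibration rounds the shape.
#'
#' @param nshell positive integer subdivision order.
#' @param target_edge_length initial edge length, strictly between `lmin` and
#'   `lmax`.  The default 1.35 is the mean edge length of the equilibrated
#'   fluid membrane under the default bounds, so the surface area is
#'   conserved from the first sweep.
#' @param lmin,lmax hard edge-length bounds (defaults 1 and 1.7).
#' @return a closed, outward-oriented `vesicle_mesh`.
#' @export
build_vesicle <- function(nshell, target_edge_length = 1.35,
                          lmin = 1, lmax = 1.7) {
  if (!is.numeric(nshell) || length(nshell) != 1L || nshell < 1 ||
      nshell != round(nshell))
    stop("nshell must be a positive integer")
  if (!(target_edge_length > lmin && target_edge_length < lmax))
    stop(sprintf("target_edge_length must lie strictly in (%g, %g)", lmin, lmax))
  nshell <- as.integer(nshell)
  # pentagonal dipyramid with unit edges (2 poles + 5 equatorial vertices)
  re <- 1 / (2 * sin(pi / 5))
  hz <- sqrt(1 - re^2)
  ang <- 2 * pi * (0:4) / 5
  verts <- rbind(c(0, 0, hz),
                 cbind(re * cos(ang), re * sin(ang), 0),
                 c(0, 0, -hz))
  eq <- 2:6
  nxt <- c(3:6, 2L)
  faces <- rbind(cbind(1L, eq, nxt),      # northern faces
                 cbind(7L, nxt, eq))      # southern faces
  sub <- subdivide_triangulation(verts, faces, nshell)
  scale <- target_edge_length * nshell    # base edges have length 1
  pos <- sub$positions * scale
  if (cpp_signed_volume(pos, sub$triangles) < 0)
    sub$triangles <- sub$triangles[, c(1L, 3L, 2L)]
  mesh <- vesicle_mesh(pos, sub$triangles)
  el <- edge_lengths(mesh)
  bad <- which(el <= lmin | el >= lmax)
  if (length(bad))
    stop(sprintf("edge %d-%d (length %.4f) violates the bounds (%g, %g)",
                 mesh$edges[bad[1], 1], mesh$edges[bad[1], 2], el[bad[1]],
                 lmin, lmax))
  stopifnot(nrow(mesh$positions) == 5L * nshell^2 + 2L)
  mesh
}

#' Per-vertex discrete geometry
#'
#' Computes, for one vertex or all vertices, the barycentric area share
#' (one third of each incident triangle), the signed mean curvature
#' `h = (C1 + C2)/2` from the cotangent mean-curvature vector
#' (sign taken against the outward normal, so a sphere has `h = 1/R > 0`),
#' and the area-weighted outward unit normal.  On open patches the curvature
#' of boundary vertices is undefined and reported as `NA`.
#'
#' @param mesh a `vesicle_mesh`.
#' @param vertex optional vertex index; if omitted, all vertices are returned.
#' @return For a single vertex, a list with `area`, `h`, `normal`; otherwise a
#'   list of vectors `area`, `h` and a V x 3 `normal` matrix.
#' @export
vertex_geometry <- function(mesh, vertex = NULL) {
  g <- cpp_geometry(mesh$positions, mesh$triangles)
  if (is.null(vertex)) return(g)
  v <- as.integer(vertex)
  if (v < 1L || v > nrow(mesh$positions)) stop("vertex out of range")
  list(area = g$area[v], h = g$h[v], normal = g$normal[v, ])
}

#' Flip the shared edge of two adjacent triangles
#'
#' Replaces the edge by the opposite diagonal of the quadrilateral formed by
#' its two incident triangles, keeping the outward orientation and all vertex,
#' edge and triangle counts.  The move is refused (mesh returned unchanged,
#' `accepted = FALSE`) if the new edge would violate the length bounds, would
#' duplicate an existing edge, or would drop an endpoint below degree 3.
#'
#' @param mesh a `vesicle_mesh`.
#' @param edge length-2 integer vector naming the edge's endpoints.
#' @param lmin,lmax edge-length bounds used to validate the new diagonal.
#' @return list with `mesh`, logical `accepted` and a `reason` string.
#' @export
bond_flip <- function(mesh, edge, lmin = 1, lmax = 1.7) {
  res <- cpp_flip_edge(mesh$positions, mesh$triangles,
                       as.integer(edge[1]), as.integer(edge[2]), lmin, lmax)
  if (!res$ok)
    return(list(mesh = mesh, accepted = FALSE, reason = res$reason))
  list(mesh = vesicle_mesh(mesh$positions, res$triangles),
       accepted = TRUE, reason = "ok", new_edge = res$new_edge)
}

#' Constraint predicate for a proposed vertex displacement
#'
#' Checks, in order: that every incident edge stays strictly inside
#' `(lmin, lmax)`; that the vertex does not cross the hard floor `z0 - lmin`
#' when a wall is configured; and that no non-neighbour vertex comes within
#' the hard-core distance `lmin` (self-avoidance).
#'
#' @param mesh a `vesicle_mesh`.
#' @param vertex vertex index.
#' @param new_position length-3 numeric.
#' @param wall optional wall height `z0`; `NULL` for no wall.
#' @param lmin,lmax edge-length bounds.
#' @return list with logical `accept` and `reason` in
#'   `"ok"`, `"edge-length"`, `"wall"`, `"self-avoidance"`.
#' @export
check_move_constraints <- function(mesh, vertex, new_position, wall = NULL,
                                   lmin = 1, lmax = 1.7) {
  reason <- cpp_check_constraints(mesh$positions, mesh$triangles,
                                  as.integer(vertex), as.numeric(new_position),
                                  lmin, lmax, !is.null(wall),
                                  if (is.null(wall)) 0 else wall)
  list(accept = identical(reason, "ok"), reason = reason)
}

#' Total surface area and enclosed volume
#' @param mesh a `vesicle_mesh`.
#' @return named numeric vector with `area` and (for closed meshes) the
#'   signed enclosed `volume`.
#' @export
mesh_area_volume <- function(mesh) {
  c(area = cpp_total_area(mesh$positions, mesh$triangles),
    volume = if (mesh$closed)
      cpp_signed_volume(mesh$positions, mesh$triangles) else NA_real_)
}
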