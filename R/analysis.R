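# Snapshot statistics: CMC clustering, gyration-tensor shape descriptors,
# cluster boundary perimeter, segregation factor, phase classification and
# neck ("hole") area.

#' Connected CMC clusters
#'
#' Maximal edge-connected components of CMC-occupied vertices (any species;
#' connectivity ignores the species so mixed patches form one cluster).
#' Bare vertices belong to no cluster.
#'
#' @param mesh a `vesicle_mesh`.
#' @param state a `cmc_state`.
#' @return list of integer vertex-index vectors, one per cluster.
#' @export
find_clusters <- function(mesh, state) {
  ids <- cpp_clusters(mesh$triangles, state$labels, nrow(mesh$positions))
  if (!any(ids > 0L)) return(list())
  unname(split(seq_along(ids)[ids > 0L], ids[ids > 0L]))
}

#' Mean CMC cluster size
#'
#' Arithmetic mean of cluster sizes, `N_vertex / N_clusters`; with
#' `restrict_below` only clusters strictly smaller than that size enter
#' (the variant used to separate the gas phase).
#'
#' @param clusters list of clusters from [find_clusters()].
#' @param restrict_below optional size cut-off (exclusive).
#' @return mean size, or `NA` if no (eligible) cluster exists.
#' @export
mean_cluster_size <- function(clusters, restrict_below = NULL) {
  sizes <- lengths(clusters)
  if (!is.null(restrict_below)) sizes <- sizes[sizes < restrict_below]
  if (length(sizes) == 0L) return(NA_real_)
  mean(sizes)
}

#' Gyration tensor eigenvalues
#'
#' Eigenvalues (ascending) of the 3x3 position covariance about the centre of
#' mass, `R_G = (1/N) sum_i r_i r_i^T`.  Their sum equals the mean squared
#' distance from the centre of mass.
#'
#' @param positions N x 3 coordinate matrix.
#' @return numeric vector `(lambda1_sq, lambda2_sq, lambda3_sq)`, ascending.
#' @export
gyration_eigenvalues <- function(positions) {
  positions <- as.matrix(positions)
  cen <- sweep(positions, 2, colMeans(positions))
  G <- crossprod(cen) / nrow(positions)
  sort(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
}

#' Mean CMC-bare boundary perimeter per CMC
#'
#' For each cluster `i` of size `N_i > 1`, `lp_i` counts the mesh edges
#' joining a cluster vertex to a bare vertex; the measure is the mean of
#' `lp_i / N_i` over those clusters.  With `geometric = TRUE` the boundary
#' edges are summed by their Euclidean length instead of counted.
#'
#' @param mesh a `vesicle_mesh`.
#' @param state a `cmc_state`.
#' @param clusters optional precomputed [find_clusters()] result.
#' @param geometric sum geometric edge lengths instead of counting edges.
#' @return mean perimeter per CMC, or `NA` if no cluster larger than 1 exists.
#' @export
cluster_perimeter <- function(mesh, state, clusters = NULL, geometric = FALSE) {
  if (is.null(clusters)) clusters <- find_clusters(mesh, state)
  sizes <- lengths(clusters)
  keep <- which(sizes > 1L)
  if (length(keep) == 0L) return(NA_real_)
  ids <- cpp_clusters(mesh$triangles, state$labels, nrow(mesh$positions))
  l1 <- state$labels[mesh$edges[, 1]]
  l2 <- state$labels[mesh$edges[, 2]]
  boundary <- (l1 > 0L) != (l2 > 0L)   # exactly one endpoint is CMC
  clust_of_edge <- ifelse(l1 > 0L, ids[mesh$edges[, 1]], ids[mesh$edges[, 2]])
  wt <- if (geometric) edge_lengths(mesh) else rep(1, nrow(mesh$edges))
  lp <- vapply(keep, function(ci)
    sum(wt[boundary & clust_of_edge == ci]), numeric(1))
  mean(lp / sizes[keep])
}

#' Segregation factor of a CMC mixture
#'
#' `S = 2 * P(CMC neighbour is of the same species) - 1` over all mesh edges
#' joining two CMC vertices: 1 for complete phase separation, 0 for a
#' well-mixed state, -1 for perfect alternation.
#'
#' @param mesh a `vesicle_mesh`.
#' @param state a `cmc_state`.
#' @param per_cluster also return the factor restricted to each cluster.
#' @return `S` in `[-1, 1]`, or `NA` if there is no CMC-CMC edge; with
#'   `per_cluster = TRUE`, a list with `total` and the per-cluster vector.
#' @export
segregation_factor <- function(mesh, state, per_cluster = FALSE) {
  l1 <- state$labels[mesh$edges[, 1]]
  l2 <- state$labels[mesh$edges[, 2]]
  cc <- l1 > 0L & l2 > 0L
  seg <- function(sel) {
    if (!any(sel)) return(NA_real_)
    2 * mean(l1[sel] == l2[sel]) - 1
  }
  total <- seg(cc)
  if (!per_cluster) return(total)
  ids <- cpp_clusters(mesh$triangles, state$labels, nrow(mesh$positions))
  eid <- ids[mesh$edges[, 1]]   # both endpoints share the cluster when cc
  ncl <- max(ids)
  per <- vapply(seq_len(ncl), function(ci) seg(cc & eid == ci), numeric(1))
  list(total = total, per_cluster = per)
}

#' Phase-classification thresholds
#'
#' The decision thresholds of the phase classifier, calibrated at the
#' reference vesicle size of 4502 vertices; they are configuration, not
#' constants, and are not rescaled automatically for smaller meshes.
#'
#' @param gas_mean_size gas/buds boundary on the restricted mean cluster size.
#' @param pearling_perimeter upper perimeter-per-CMC bound of pearled clusters.
#' @param flat_lambda1 upper bound on `lambda1^2` for flat (pancake) shapes.
#' @param elongated_lambda2 `(lo, hi)` window on `lambda2^2` for elongated
#'   shapes.
#' @param buds_perimeter lower perimeter bound of the pure-buds phase.
#' @param reference_vertices vesicle size at which the defaults were set.
#' @return list of thresholds.
#' @export
phase_thresholds <- function(gas_mean_size = 1.5, pearling_perimeter = 0.375,
                             flat_lambda1 = 50, elongated_lambda2 = c(80, 150),
                             buds_perimeter = 1.875,
                             reference_vertices = 4502) {
  list(gas_mean_size = gas_mean_size, pearling_perimeter = pearling_perimeter,
       flat_lambda1 = flat_lambda1, elongated_lambda2 = elongated_lambda2,
       buds_perimeter = buds_perimeter, reference_vertices = reference_vertices)
}

#' Classify the vesicle phase from shape measures
#'
#' Ordered decision list: gas (small restricted mean cluster size), pearling
#' (very small boundary perimeter per CMC), flat (small `lambda1^2`),
#' elongated (`lambda2^2` window), buds (large perimeter per CMC), else mixed.
#' Undefined measures yield `"other"` with a `reason` attribute.
#'
#' @param measures list/one-row data.frame with `mean_cluster_size_small`,
#'   `perimeter`, `lambda1_sq`, `lambda2_sq` (as produced by
#'   [shape_measures()]).
#' @param thresholds a [phase_thresholds()] list.
#' @return character phase label.
#' @export
classify_phase <- function(measures, thresholds = phase_thresholds()) {
  n_small <- measures$mean_cluster_size_small
  lp <- measures$perimeter
  l1 <- measures$lambda1_sq
  l2 <- measures$lambda2_sq
  if (is.null(n_small) || is.na(n_small)) {
    # no small clusters at all: fall back to the unrestricted mean
    n_small <- measures$mean_cluster_size
  }
  if (is.null(n_small) || is.na(n_small))
    return(structure("other", reason = "no CMC clusters"))
  if (n_small < thresholds$gas_mean_size) return("gas")
  if (!is.na(lp) && lp < thresholds$pearling_perimeter) return("pearling")
  if (!is.na(l1) && l1 < thresholds$flat_lambda1) return("flat")
  if (!is.na(l2) && l2 > thresholds$elongated_lambda2[1] &&
      l2 < thresholds$elongated_lambda2[2]) return("elongated")
  if (!is.na(lp) && lp >= thresholds$buds_perimeter) return("buds")
  "mixed"
}

#' Cross-sectional area of a neck/hole polygon
#'
#' Magnitude of the polygon vector area `(1/2) |sum_k x_k x x_{k+1}|` of the
#' closed loop of vertices bounding a neck; exact for planar loops and
#' well-defined for near-planar necks.  The loop is provided by the user
#' (e.g. picked in a viewer); there is no automatic neck detection.
#'
#' @param positions N x 3 coordinate matrix.
#' @param loop ordered vertex indices (length >= 3, distinct) tracing the
#'   hole edge.
#' @return area in lmin^2.
#' @export
hole_area <- function(positions, loop) {
  loop <- as.integer(loop)
  if (length(loop) < 3L || anyDuplicated(loop))
    stop("loop must contain at least 3 distinct vertex indices")
  P <- as.matrix(positions)[loop, , drop = FALSE]
  Q <- P[c(2:nrow(P), 1L), , drop = FALSE]
  cr <- cbind(P[, 2] * Q[, 3] - P[, 3] * Q[, 2],
              P[, 3] * Q[, 1] - P[, 1] * Q[, 3],
              P[, 1] * Q[, 2] - P[, 2] * Q[, 1])
  0.5 * sqrt(sum(colSums(cr)^2))
}

measure_columns <- function() {
  c("mean_cluster_size", "mean_cluster_size_small", "n_clusters",
    "lambda1_sq", "lambda2_sq", "lambda3_sq", "perimeter", "segregation",
    "phase")
}

#' All shape measures of one snapshot
#'
#' @param mesh a `vesicle_mesh`.
#' @param state a `cmc_state`.
#' @param params optional `model_params` (unused by the measures themselves;
#'   accepted for interface symmetry).
#' @param thresholds [phase_thresholds()] used by the classifier.
#' @param small_cutoff cluster-size cut-off of the restricted mean (exclusive).
#' @return named list: cluster statistics, ordered gyration eigenvalues,
#'   boundary perimeter per CMC, segregation factor and the phase label.
#' @export
shape_measures <- function(mesh, state, params = NULL,
                           thresholds = phase_thresholds(),
                           small_cutoff = 10) {
  clusters <- find_clusters(mesh, state)
  lam <- gyration_eigenvalues(mesh$positions)
  out <- list(
    mean_cluster_size = mean_cluster_size(clusters),
    mean_cluster_size_small = mean_cluster_size(clusters, small_cutoff),
    n_clusters = length(clusters),
    lambda1_sq = lam[1], lambda2_sq = lam[2], lambda3_sq = lam[3],
    perimeter = cluster_perimeter(mesh, state, clusters),
    segregation = segregation_factor(mesh, state))
  out$phase <- as.character(classify_phase(out, thresholds))
  out
}
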