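# Discretized vesicle energy: bending + nearest-neighbour binding + wall
# adhesion, with incremental evaluation for single Monte-Carlo moves.

# shared plumbing: pull species columns in engine order
species_args <- function(state) {
  sp <- state$species
  list(c0 = as.numeric(sp$c0), f = as.numeric(sp$f),
       inhibitor = as.logical(sp$inhibitor), aligned = as.logical(sp$aligned))
}

energy_terms <- function(mesh, state, params, lmin = 1) {
  sa <- species_args(state)
  wm <- binding_matrix(params, nrow(state$species))
  cpp_energy_terms(mesh$positions, mesh$triangles, state$labels,
                   sa$c0, sa$f, sa$inhibitor, sa$aligned, wm,
                   params$kappa, params$w_ad, params$z0, isTRUE(params$wall),
                   lmin)
}

#' Bending energy
#'
#' Discretized Helfrich energy
#' `sum_i kappa/2 * (2 h_i - C0(label_i))^2 * A_i` with `C0 = 0` on bare
#' vertices, `h_i` the signed mean curvature and `A_i` the barycentric vertex
#' area.  On open patches, boundary vertices (whose curvature is undefined)
#' are excluded.
#'
#' @param mesh a `vesicle_mesh`.
#' @param state a `cmc_state`.
#' @param params a `model_params`.
#' @return energy in kBT.
#' @export
bending_energy <- function(mesh, state, params) {
  unname(energy_terms(mesh, state, params)["bending"])
}

#' Nearest-neighbour binding energy
#'
#' `-w[label_i, label_j]` summed once per mesh edge joining two CMC vertices;
#' edges touching bare membrane contribute nothing.
#'
#' @inheritParams bending_energy
#' @return energy in kBT (non-positive for attractive `w > 0`).
#' @export
binding_energy <- function(mesh, state, params) {
  unname(energy_terms(mesh, state, params)["binding"])
}

#' Wall adhesion energy
#'
#' `-w_ad` per vertex within `lmin` of the wall plane `z = z0` (adhesion is
#' energetically favourable).  Vertices below `z0 - lmin` cannot exist: moves
#' crossing the hard floor are rejected by the engine.
#'
#' @inheritParams bending_energy
#' @param lmin adhesion band half-width (the minimal edge length).
#' @return energy in kBT.
#' @export
adhesion_energy <- function(mesh, state = NULL, params, lmin = 1) {
  if (!isTRUE(params$wall) || params$w_ad == 0) return(0)
  z <- mesh$positions[, 3]
  -params$w_ad * sum(abs(z - params$z0) <= lmin)
}

#' Total energy with breakdown
#'
#' @inheritParams bending_energy
#' @return named numeric vector `bending`, `binding`, `adhesion`, `total`.
#' @export
total_energy <- function(mesh, state, params) {
  e <- energy_terms(mesh, state, params)
  c(e, total = unname(sum(e)))
}

#' Incremental energy difference of a single move
#'
#' Computes the energy change of a vertex displacement or a bond flip from
#' the local neighbourhood only (the moved vertex and its 1-ring, whose
#' curvatures and areas are the only ones that change; for a flip, the four
#' quad vertices plus the swapped binding bond).  Satisfies
#' `total_energy(after) - total_energy(before) == delta` to numerical
#' round-off.
#'
#' @inheritParams bending_energy
#' @param move either `list(type = "move", vertex = i, new_position = xyz)`
#'   or `list(type = "flip", edge = c(a, b))`.
#' @param lmin,lmax edge bounds used to validate a flip.
#' @return energy difference in kBT (`NA` with a reason attribute for an
#'   infeasible flip).
#' @export
local_energy_delta <- function(mesh, state, params, move,
                               lmin = 1, lmax = 1.7) {
  sa <- species_args(state)
  wm <- binding_matrix(params, nrow(state$species))
  if (identical(move$type, "move")) {
    cpp_move_delta(mesh$positions, mesh$triangles, state$labels,
                   sa$c0, sa$f, sa$inhibitor, sa$aligned, wm,
                   params$kappa, params$w_ad, params$z0, isTRUE(params$wall),
                   lmin, as.integer(move$vertex), as.numeric(move$new_position))
  } else if (identical(move$type, "flip")) {
    res <- cpp_flip_delta(mesh$positions, mesh$triangles, state$labels,
                          sa$c0, sa$f, sa$inhibitor, sa$aligned, wm,
                          params$kappa, params$w_ad, params$z0,
                          isTRUE(params$wall), lmin, lmax,
                          as.integer(move$edge[1]), as.integer(move$edge[2]))
    if (!res$ok) return(structure(NA_real_, reason = res$reason))
    res$delta
  } else stop("move$type must be 'move' or 'flip'")
}
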