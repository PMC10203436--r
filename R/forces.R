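# Active protrusive forces exerted by CMCs: magnitude (with neighbour
# inhibition), direction (outward normal or Vicsek-aligned within the
# cluster), and the Monte-Carlo work term.

#' Active force magnitude at a vertex
#'
#' Bare or passive vertices return 0.  With `inhibition = "proportional"`
#' the force is scaled by the fraction of neighbours that are not inhibitors;
#' with `"disabling"` any inhibiting neighbour suppresses the force entirely.
#'
#' @param mesh a `vesicle_mesh`.
#' @param state a `cmc_state`.
#' @param params a `model_params`.
#' @param vertex vertex index; omit for all vertices at once.
#' @return force magnitude(s) in kBT/lmin.
#' @export
force_magnitude <- function(mesh, state, params, vertex = NULL) {
  sa <- species_args(state)
  fm <- cpp_force_magnitudes(mesh$triangles, state$labels, sa$c0, sa$f,
                             sa$inhibitor, sa$aligned,
                             inhibition_code(params), nrow(mesh$positions))
  if (is.null(vertex)) fm else fm[as.integer(vertex)]
}

#' Active force direction at a vertex
#'
#' For a normal-force species (or `s = 0`) this is the outward vertex normal.
#' For an aligned species it is the normalized Vicsek-like average
#' `normalize(n_i + s * sum_j n_j)` over CMC vertices `j` of the same
#' connected cluster within Euclidean distance `r` of vertex `i`.  If the sum
#' cancels, the outward normal is used as fallback.
#'
#' @inheritParams force_magnitude
#' @return a unit 3-vector, or the V x 3 matrix of directions (zero rows for
#'   bare vertices) if `vertex` is omitted.
#' @export
force_direction <- function(mesh, state, params, vertex = NULL) {
  sa <- species_args(state)
  D <- cpp_force_directions(mesh$positions, mesh$triangles, state$labels,
                            sa$c0, sa$f, sa$inhibitor, sa$aligned,
                            params$s, params$r)
  if (is.null(vertex)) D else D[as.integer(vertex), ]
}

#' Monte-Carlo work of the active force over a displacement
#'
#' `W = -f * (direction . displacement)`: motion along the force direction is
#' energetically favoured.  Enters the Metropolis exponent together with the
#' energy difference.
#'
#' @param direction unit 3-vector of the force.
#' @param f_i force magnitude (kBT/lmin); 0 for bare/passive vertices.
#' @param displacement 3-vector of the proposed vertex displacement.
#' @return work in kBT.
#' @export
work_term <- function(direction, f_i, displacement) {
  if (f_i == 0) return(0)
  -f_i * sum(as.numeric(direction) * as.numeric(displacement))
}
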