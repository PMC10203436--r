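# Closed-form force balance for the tube-transition boundary and the
# effective-parameter mapping of CMC mixtures.

#' Pulling force of a hemispherical CMC cap
#'
#' A hemispherical cap of radius `2/C0` minimizes bending and maximizes the
#' pulling force; its total force is
#' `F_pull = f * (1/2) * 2 pi (2/C0)^2 / s0`, the per-protein force times the
#' number of proteins in the cap, with the factor 1/2 from the hemispherical
#' geometry.
#'
#' @param f active force per CMC (kBT/lmin).
#' @param c0 spontaneous curvature (1/lmin), must be > 0.
#' @param s0 mean membrane area per vertex (lmin^2), must be > 0.
#' @return total pulling force (kBT/lmin).
#' @export
cap_pulling_force <- function(f, c0, s0) {
  if (any(c0 <= 0)) stop("c0 must be > 0 (no finite cap otherwise)")
  if (any(s0 <= 0)) stop("s0 must be > 0")
  f * 0.5 * 2 * pi * (2 / c0)^2 / s0
}

#' Restoring force of a membrane tube
#'
#' Classic tether force `2 pi kappa / r_tube` at the tube radius `r_tube =
#' 2/C0` set by the cap, i.e. `pi kappa C0`.
#'
#' @param kappa bending modulus (kBT).
#' @param c0 spontaneous curvature (1/lmin).
#' @return restoring force (kBT/lmin).
#' @export
tube_restoring_force <- function(kappa, c0) {
  pi * kappa * c0
}

#' Critical force of the tube transition
#'
#' Balancing [cap_pulling_force()] against [tube_restoring_force()] gives the
#' cubic boundary `f* = A C0^3` with prefactor `A = kappa * s0 / 4`.
#'
#' @param kappa bending modulus (kBT).
#' @param s0 mean area per vertex (lmin^2), measured on an equilibrated
#'   passive vesicle.
#' @param c0 spontaneous curvature (1/lmin).
#' @return list with `f_star` (critical force per CMC) and the prefactor `A`.
#' @export
critical_force <- function(kappa, s0, c0) {
  if (any(kappa <= 0) || any(s0 <= 0) || any(c0 <= 0))
    stop("kappa, s0 and c0 must be positive")
  A <- kappa * s0 / 4
  list(f_star = A * c0^3, A = A)
}

#' Effective parameters of a CMC mixture
#'
#' Maps a two-species (or general) mixture onto the single-species phase
#' diagram: the effective spontaneous curvature is the unweighted per-CMC mean
#' of `C0` and the effective force the per-CMC mean of `f`.  The revised
#' variant drops concave CMCs that are sequestered inside internalized sacks,
#' i.e. keeps only concave CMCs adjacent to at least one convex CMC (plus all
#' convex CMCs).
#'
#' @param state a `cmc_state`.
#' @param mesh a `vesicle_mesh`; required for `revised = TRUE`.
#' @param revised exclude sack-interior concave CMCs from the curvature mean.
#' @return list with `c0_eff` and `f_eff`.
#' @export
effective_mixture <- function(state, mesh = NULL, revised = FALSE) {
  lab <- state$labels
  cmc <- which(lab > 0L)
  if (length(cmc) == 0L) return(list(c0_eff = NA_real_, f_eff = NA_real_))
  c0v <- state$species$c0[lab[cmc]]
  fv <- state$species$f[lab[cmc]]
  f_eff <- mean(fv)
  if (!revised) return(list(c0_eff = mean(c0v), f_eff = f_eff))
  if (is.null(mesh)) stop("revised mapping needs the mesh adjacency")
  convex <- c0v > 0
  keep <- convex
  if (any(!convex)) {
    is_convex_vertex <- logical(length(lab))
    is_convex_vertex[cmc[convex]] <- TRUE
    adj <- mesh_adjacency(mesh)
    has_convex_nbr <- vapply(cmc, function(v) any(is_convex_vertex[adj[[v]]]),
                             logical(1))
    keep <- convex | has_convex_nbr
  }
  list(c0_eff = mean(c0v[keep]), f_eff = f_eff)
}

#' Tube-transition boundary curve
#'
#' Tabulates the critical force `f*(C0) = A C0^3` for a grid of spontaneous
#' curvatures.
#'
#' @param kappa bending modulus (kBT).
#' @param s0 mean area per vertex (lmin^2).
#' @param c0 vector of spontaneous curvatures.
#' @return data.frame with columns `c0`, `f_star`; the prefactor `A` is
#'   attached as an attribute.
#' @export
tube_boundary_curve <- function(kappa, s0, c0 = seq(0.1, 1, by = 0.05)) {
  cf <- critical_force(kappa, s0, c0)
  structure(data.frame(c0 = c0, f_star = cf$f_star), A = cf$A)
}
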