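# Per-vertex protein occupation and model parameters.

#' Species parameter table
#'
#' One row per curved-membrane-component (CMC) species.  Species id 0 is the
#' bare membrane and is implicit: it has zero spontaneous curvature, no force
#' and never binds.
#'
#' @param c0 spontaneous curvature per species (1/lmin units; convex > 0).
#' @param f active force magnitude per species (kBT/lmin; 0 = passive).
#' @param inhibitor logical: does this species inhibit its neighbours' force?
#' @param aligned logical: does this species use the Vicsek-aligned force
#'   direction instead of the local outward normal?
#' @return data.frame with columns `species`, `c0`, `f`, `inhibitor`,
#'   `aligned`.
#' @export
species_table <- function(c0 = 1, f = 0, inhibitor = FALSE, aligned = FALSE) {
  K <- max(length(c0), length(f), length(inhibitor), length(aligned))
  data.frame(species = seq_len(K),
             c0 = rep_len(as.numeric(c0), K),
             f = rep_len(as.numeric(f), K),
             inhibitor = rep_len(as.logical(inhibitor), K),
             aligned = rep_len(as.logical(aligned), K))
}

#' Per-vertex CMC occupation state
#'
#' @param labels integer vector, one entry per mesh vertex: 0 for bare
#'   membrane, `1..K` for a CMC of that species.
#' @param species a [species_table()].
#' @return object of class `cmc_state`.
#' @export
cmc_state <- function(labels, species = species_table()) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 0L))
    stop("labels must be non-negative integers")
  if (max(labels, 0L) > nrow(species))
    stop("label exceeds the number of species in the table")
  structure(list(labels = labels, species = species), class = "cmc_state")
}

#' @export
print.cmc_state <- function(x, ...) {
  V <- length(x$labels)
  cat(sprintf("cmc_state: %d vertices, %d species\n", V, nrow(x$species)))
  for (k in seq_len(nrow(x$species))) {
    n <- sum(x$labels == k)
    cat(sprintf("  species %d: %d vertices (rho = %.1f%%), C0 = %g, f = %g%s%s\n",
                k, n, 100 * n / V, x$species$c0[k], x$species$f[k],
                if (x$species$inhibitor[k]) ", inhibitor" else "",
                if (x$species$aligned[k]) ", aligned" else ""))
  }
  invisible(x)
}

#' Global and per-species CMC densities
#' @param state a `cmc_state`.
#' @return named vector: `rho` (total) followed by one density per species.
#' @export
cmc_density <- function(state) {
  V <- length(state$labels)
  per <- vapply(seq_len(nrow(state$species)),
                function(k) sum(state$labels == k) / V, numeric(1))
  c(rho = sum(per), setNames(per, paste0("rho", seq_along(per))))
}

#' Energy and force model parameters
#'
#' @param kappa bending modulus (kBT).
#' @param w CMC-CMC binding energy per bond (kBT): either a scalar (uniform
#'   binding among all species) or a symmetric K x K matrix; bare membrane
#'   never binds.
#' @param w_ad adhesion energy per vertex within `lmin` of the wall (kBT).
#' @param z0 wall height; `wall = TRUE` switches the wall on.
#' @param wall logical, adhesive wall at `z = z0` present?
#' @param s alignment weight of the Vicsek-like force interaction.
#' @param r alignment range (lmin units, Euclidean).
#' @param inhibition force-inhibition mode: `"none"`, `"proportional"`
#'   (force scaled by the fraction of non-inhibiting neighbours) or
#'   `"disabling"` (any inhibiting neighbour kills the force).
#' @param beta inverse temperature (1/kBT); 1 by default, exposed to scan a
#'   temperature axis.
#' @return object of class `model_params`.
#' @export
model_params <- function(kappa = 20, w = 1, w_ad = 0, z0 = 0, wall = FALSE,
                         s = 0, r = 0,
                         inhibition = c("none", "proportional", "disabling"),
                         beta = 1) {
  inhibition <- match.arg(inhibition)
  if (kappa < 0) stop("kappa must be >= 0")
  if (s < 0 || r < 0) stop("alignment s and r must be >= 0")
  if (is.matrix(w) && !isSymmetric(unname(w)))
    stop("binding matrix w must be symmetric")
  structure(list(kappa = kappa, w = w, w_ad = w_ad, z0 = z0, wall = wall,
                 s = s, r = r, inhibition = inhibition, beta = beta),
            class = "model_params")
}

# Expand the binding specification to a K x K matrix (kBT per bond).
binding_matrix <- function(params, K) {
  w <- params$w
  if (is.matrix(w)) {
    if (nrow(w) != K || ncol(w) != K)
      stop(sprintf("binding matrix must be %d x %d", K, K))
    return(w)
  }
  matrix(as.numeric(w), K, K)
}

# map inhibition mode to the engine's integer code
inhibition_code <- function(params) {
  match(params$inhibition, c("none", "proportional", "disabling")) - 1L
}

#' Simulation run control
#'
#' @param sweeps number of Monte-Carlo sweeps (one sweep = V vertex-move
#'   attempts followed by E bond-flip attempts).
#' @param step half-width of the uniform cubic vertex displacement
#'   (lmin units, must lie in (0, lmin)).
#' @param cadence sweeps between recorded snapshots/measures.
#' @param lmin,lmax hard edge-length bounds.
#' @param seed optional RNG seed recorded with the run.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(sweeps, step = 0.15, cadence = max(1L, sweeps %/% 100L),
                       lmin = 1, lmax = 1.7, seed = NULL) {
  if (sweeps < 0) stop("sweeps must be >= 0")
  if (!(step >= 0 && step < lmin)) stop("step half-width must lie in [0, lmin)")
  if (!(lmax > lmin)) stop("lmax must exceed lmin")
  structure(list(sweeps = as.integer(sweeps), step = step,
                 cadence = as.integer(cadence), lmin = lmin, lmax = lmax,
                 seed = seed),
            class = "sim_config")
}
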