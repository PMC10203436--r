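# shared test fixtures and independent oracles

# flat lattice stretched to just under lmax: the interior vertex is pinned,
# since any displacement lengthens the edge to the opposite ring neighbour
# (in plane) or to all six (out of plane) beyond the bound
stretched_patch <- function() make_plane_patch(5, spacing = 1.6995)

# plane patch squashed so that opposite quad diagonals fit inside the edge
# bounds (flips become geometrically feasible)
flippable_patch <- function(n = 6, spacing = 0.9) make_plane_patch(n, spacing)

# brute-force flood fill over CMC vertices; independent of the engine's BFS
oracle_clusters <- function(mesh, labels) {
  V <- nrow(mesh$positions)
  adj <- mesh_adjacency(mesh)
  seen <- logical(V)
  out <- list()
  for (s in seq_len(V)) {
    if (labels[s] == 0L || seen[s]) next
    comp <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      comp <- c(comp, v)
      for (u in adj[[v]]) if (labels[u] > 0L && !seen[u]) {
        seen[u] <- TRUE
        queue <- c(queue, u)
      }
    }
    out[[length(out) + 1L]] <- sort(comp)
  }
  out
}

# canonicalize a cluster list for comparison
canon_clusters <- function(cl) {
  cl <- lapply(cl, sort)
  cl[order(vapply(cl, min, integer(1)))]
}

# small equilibrated vesicle shared by the energy/MC tests (built once)
equilibrated_vesicle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- build_vesicle(5)
      st <- cmc_state(integer(nrow(m$positions)))
      set.seed(4242)
      r <- run_simulation(m, st, model_params(kappa = 20),
                          sim_config(sweeps = 150, cadence = 150))
      cache <<- r$mesh
    }
    cache
  }
})
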