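# Metropolis Monte-Carlo driver: vertex moves and bond flips with the active
# work term, hard constraints, sweeps and trajectories.

#' Metropolis acceptance rule
#'
#' Accepts with probability `min(1, exp(-beta * (delta_e + work)))`, consuming
#' exactly one uniform draw from R's seeded generator per call.
#'
#' @param delta_e energy difference of the proposed move (kBT).
#' @param work active work term of the move (kBT).
#' @param beta inverse temperature.
#' @return logical.
#' @export
metropolis_accept <- function(delta_e, work = 0, beta = 1) {
  x <- -beta * (delta_e + work)
  u <- runif(1)
  x >= 0 || u < exp(x)
}

#' Attempt a single vertex displacement
#'
#' Proposes a uniform displacement in a cube of half-width `config$step`
#' (or applies `displacement` if given), rejects on any hard-constraint
#' violation, and otherwise applies the Metropolis rule to the local energy
#' difference plus the active work term.
#'
#' @param mesh a `vesicle_mesh`.
#' @param state a `cmc_state`.
#' @param params a `model_params`.
#' @param config a `sim_config`.
#' @param vertex vertex index.
#' @param displacement optional fixed displacement (bypasses the random
#'   proposal; useful for tests).
#' @return list with `accepted`, `reason`, and the (possibly updated) `mesh`.
#' @export
attempt_vertex_move <- function(mesh, state, params, config, vertex,
                                displacement = NULL) {
  v <- as.integer(vertex)
  if (is.null(displacement))
    displacement <- config$step * (2 * runif(3) - 1)
  newpos <- mesh$positions[v, ] + displacement
  chk <- check_move_constraints(mesh, v, newpos,
                                wall = if (isTRUE(params$wall)) params$z0 else NULL,
                                lmin = config$lmin, lmax = config$lmax)
  if (!chk$accept)
    return(list(accepted = FALSE, reason = chk$reason, mesh = mesh))
  dE <- local_energy_delta(mesh, state, params,
                           list(type = "move", vertex = v, new_position = newpos),
                           lmin = config$lmin, lmax = config$lmax)
  fm <- force_magnitude(mesh, state, params, v)
  W <- if (fm > 0)
    work_term(force_direction(mesh, state, params, v), fm, displacement)
  else 0
  if (metropolis_accept(dE, W, params$beta)) {
    mesh$positions[v, ] <- newpos
    list(accepted = TRUE, reason = "ok", mesh = mesh, delta_e = dE, work = W)
  } else {
    list(accepted = FALSE, reason = "metropolis", mesh = mesh,
         delta_e = dE, work = W)
  }
}

#' Attempt a single bond flip
#'
#' Validity-checks the flip (length bounds on the new diagonal, no duplicate
#' edge, degrees stay >= 3), then applies the Metropolis rule to the local
#' bending + binding energy difference.  No work term: a flip displaces no
#' vertex.
#'
#' @inheritParams attempt_vertex_move
#' @param edge length-2 vector of edge endpoints.
#' @return list with `accepted`, `reason`, and the (possibly updated) `mesh`.
#' @export
attempt_bond_flip <- function(mesh, state, params, config, edge) {
  dE <- local_energy_delta(mesh, state, params,
                           list(type = "flip", edge = edge),
                           lmin = config$lmin, lmax = config$lmax)
  if (is.na(dE))
    return(list(accepted = FALSE, reason = attr(dE, "reason"), mesh = mesh))
  if (metropolis_accept(dE, 0, params$beta)) {
    res <- bond_flip(mesh, edge, config$lmin, config$lmax)
    list(accepted = TRUE, reason = "ok", mesh = res$mesh, delta_e = dE)
  } else {
    list(accepted = FALSE, reason = "metropolis", mesh = mesh, delta_e = dE)
  }
}

# shared call into the compiled sweep engine
run_engine <- function(mesh, state, params, config, nsweeps) {
  sa <- species_args(state)
  wm <- binding_matrix(params, nrow(state$species))
  cpp_run_sweeps(mesh$positions, mesh$triangles, state$labels,
                 sa$c0, sa$f, sa$inhibitor, sa$aligned, wm,
                 params$kappa, params$w_ad, params$z0, isTRUE(params$wall),
                 params$s, params$r, inhibition_code(params), params$beta,
                 config$lmin, config$lmax, config$step, as.integer(nsweeps))
}

#' Run one Monte-Carlo sweep
#'
#' One sweep = V vertex-move attempts on uniformly random vertices followed by
#' E bond-flip attempts on uniformly random edges.  Uses R's RNG: call
#' `set.seed()` first for a reproducible trajectory.
#'
#' @inheritParams attempt_vertex_move
#' @return list with the updated `mesh` and a one-row `stats` matrix
#'   (energies, area, acceptance fractions).
#' @export
run_sweep <- function(mesh, state, params, config) {
  res <- run_engine(mesh, state, params, config, 1L)
  list(mesh = vesicle_mesh(res$positions, res$triangles), stats = res$stats)
}

#' Run a full Monte-Carlo simulation
#'
#' Executes `config$sweeps` sweeps, recording a snapshot and the shape/energy
#' measures every `config$cadence` sweeps.  When `out_dir` is given, VTU
#' snapshots, the measure table (CSV) and an echo of the configuration are
#' written there.  A run can be resumed by passing the mesh/state of a
#' previous snapshot (e.g. from [read_vtu()]).
#'
#' @inheritParams attempt_vertex_move
#' @param out_dir optional output directory for VTU/CSV output.
#' @param keep_snapshots keep all snapshot meshes in memory (default: only
#'   measures and the final mesh).
#' @return object of class `vesicle_sim`: final `mesh` and `state`, the
#'   per-snapshot `measures` data.frame, per-sweep `sweep_stats`, and the
#'   run configuration.
#' @export
run_simulation <- function(mesh, state, params, config, out_dir = NULL,
                           keep_snapshots = FALSE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config_echo(file.path(out_dir, "config.txt"), params, config, state)
  }
  snap_ids <- if (config$sweeps > 0)
    unique(c(seq(config$cadence, config$sweeps, by = config$cadence), config$sweeps))
  else integer(0)
  measures <- list()
  snapshots <- list()
  stats_all <- list()
  record <- function(mesh, state, sweep) {
    sm <- shape_measures(mesh, state, params)
    row <- cbind(data.frame(sweep = sweep), as.data.frame(sm[measure_columns()]))
    e <- total_energy(mesh, state, params)
    av <- mesh_area_volume(mesh)
    row$e_bend <- e[["bending"]]; row$e_bind <- e[["binding"]]
    row$e_adh <- e[["adhesion"]]
    row$area <- av[["area"]]; row$volume <- av[["volume"]]
    measures[[length(measures) + 1L]] <<- row
    if (keep_snapshots)
      snapshots[[length(snapshots) + 1L]] <<- list(sweep = sweep, mesh = mesh,
                                                   state = state)
    if (!is.null(out_dir))
      write_vtu(file.path(out_dir, sprintf("snapshot_%06d.vtu", sweep)),
                mesh, state, params)
  }
  record(mesh, state, 0L)
  done <- 0L
  for (s in snap_ids) {
    res <- run_engine(mesh, state, params, config, s - done)
    done <- s
    mesh <- vesicle_mesh(res$positions, res$triangles, validate = FALSE)
    stats_all[[length(stats_all) + 1L]] <- res$stats
    record(mesh, state, s)
  }
  measures <- do.call(rbind, measures)
  sweep_stats <- if (length(stats_all)) as.data.frame(do.call(rbind, stats_all))
  else NULL
  if (!is.null(sweep_stats)) sweep_stats$sweep <- seq_len(nrow(sweep_stats))
  if (!is.null(out_dir))
    write_measures_csv(file.path(out_dir, "measures.csv"), measures)
  structure(list(mesh = mesh, state = state, params = params, config = config,
                 measures = measures, sweep_stats = sweep_stats,
                 snapshots = if (keep_snapshots) snapshots else NULL),
            class = "vesicle_sim")
}

#' @export
print.vesicle_sim <- function(x, ...) {
  cat(sprintf("vesicle_sim: %d sweeps on %d vertices (%d snapshots)\n",
              x$config$sweeps, nrow(x$mesh$positions), nrow(x$measures)))
  last <- x$measures[nrow(x$measures), ]
  cat(sprintf("  final: E_bend = %.1f, E_bind = %.1f, E_adh = %.1f kBT, area = %.1f\n",
              last$e_bend, last$e_bind, last$e_adh, last$area))
  cat(sprintf("  phase: %s\n", last$phase))
  invisible(x)
}

#' @export
summary.vesicle_sim <- function(object, ...) {
  m <- object$measures
  tail_third <- m[m$sweep > max(m$sweep) * 2 / 3, , drop = FALSE]
  out <- list(
    sweeps = object$config$sweeps,
    vertices = nrow(object$mesh$positions),
    acceptance_move = if (!is.null(object$sweep_stats))
      mean(object$sweep_stats$acc_move, na.rm = TRUE) else NA_real_,
    acceptance_flip = if (!is.null(object$sweep_stats))
      mean(object$sweep_stats$acc_flip, na.rm = TRUE) else NA_real_,
    area_drift = max(abs(m$area - m$area[1])) / m$area[1],
    steady_state = colMeans(tail_third[, c("mean_cluster_size", "lambda1_sq",
                                           "lambda2_sq", "perimeter",
                                           "segregation", "e_bend")],
                            na.rm = TRUE),
    final_phase = m$phase[nrow(m)])
  class(out) <- "summary.vesicle_sim"
  out
}

#' @export
print.summary.vesicle_sim <- function(x, ...) {
  cat(sprintf("Monte-Carlo run: %d sweeps, %d vertices\n", x$sweeps, x$vertices))
  cat(sprintf("  acceptance: moves %.2f, flips %.2f\n",
              x$acceptance_move, x$acceptance_flip))
  cat(sprintf("  max relative area drift: %.2f%%\n", 100 * x$area_drift))
  cat("  steady-state means (final third):\n")
  print(round(x$steady_state, 3))
  cat(sprintf("  final phase: %s\n", x$final_phase))
  invisible(x)
}

#' Plot the measure time series of a run
#'
#' Base-graphics panel of energies, area and the shape measures versus sweep.
#'
#' @param x a `vesicle_sim`.
#' @param which character vector of measure columns to show.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.vesicle_sim <- function(x, which = c("e_bend", "area", "mean_cluster_size",
                                          "lambda1_sq"), ...) {
  m <- x$measures
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (col in which) {
    graphics::plot(m$sweep, m[[col]], type = "l", xlab = "sweep", ylab = col, ...)
  }
  invisible(x)
}
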