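# Tape-style configuration parsing and VTU/PLY/CSV snapshot input-output.
# All writers are atomic (temp file + rename).

tape_defaults <- function() {
  list(f = 1, w = 1, kappa = 20, rho = 0.1, c0 = 1,
       f2 = 0, rho2 = 0, c02 = 0,
       w_ad = 0, z0 = 0, wall = 0,
       s = 0, r = 0, inhibition = "none", binding = "universal",
       aligned = 0, aligned2 = 0, inhibitor = 0, inhibitor2 = 0,
       nshell = 30, mcsweeps = 50000, iterations = 100, seed = 1,
       step = 0.15, lmin = 1, lmax = 1.7, beta = 1, out = "")
}

#' Read a tape-style run configuration
#'
#' Plain-text `key=value` lines (`#` starts a comment; blank lines ignored).
#' Unknown keys are rejected with a named error; unspecified keys take the
#' defaults (f = 1, w = 1, kappa = 20, rho = 10\%, C0 = 1, no wall).  A second
#' CMC species is configured through `rho2`, `c02`, `f2`, `aligned2`,
#' `inhibitor2`; `binding=exclusive` restricts binding to like species.
#'
#' @param path tape file path.
#' @return list with `config` (a [sim_config()]), `params` (a
#'   [model_params()]), `species` (a [species_table()]), `rho` (per-species
#'   densities), `nshell`, and the resolved `values`.
#' @export
read_tape <- function(path) {
  if (!file.exists(path)) stop("tape file not found: ", path)
  vals <- tape_defaults()
  lines <- readLines(path, warn = FALSE)
  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[ln])
    line <- trimws(line)
    if (line == "") next
    if (!grepl("=", line, fixed = TRUE))
      stop(sprintf("malformed tape line %d (expected key=value): '%s'", ln, line))
    key <- tolower(trimws(sub("=.*$", "", line)))
    val <- trimws(sub("^[^=]*=", "", line))
    if (!key %in% names(vals))
      stop(sprintf("unknown tape key '%s' on line %d", key, ln))
    if (key %in% c("inhibition", "binding", "out")) {
      vals[[key]] <- val
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num))
        stop(sprintf("non-numeric value for '%s' on line %d: '%s'", key, ln, val))
      vals[[key]] <- num
    }
  }
  if (!vals$inhibition %in% c("none", "proportional", "disabling"))
    stop("inhibition must be none, proportional or disabling")
  if (!vals$binding %in% c("universal", "exclusive"))
    stop("binding must be universal or exclusive")
  if (vals$rho < 0 || vals$rho2 < 0 || vals$rho + vals$rho2 > 1)
    stop("densities must be non-negative and sum to at most 1")
  if (vals$nshell < 1) stop("nshell must be >= 1")
  two <- vals$rho2 > 0
  species <- species_table(
    c0 = if (two) c(vals$c0, vals$c02) else vals$c0,
    f = if (two) c(vals$f, vals$f2) else vals$f,
    inhibitor = if (two) c(vals$inhibitor > 0, vals$inhibitor2 > 0)
                else vals$inhibitor > 0,
    aligned = if (two) c(vals$aligned > 0, vals$aligned2 > 0)
              else vals$aligned > 0)
  K <- nrow(species)
  wmat <- if (identical(vals$binding, "exclusive")) diag(vals$w, K, K)
  else matrix(vals$w, K, K)
  params <- model_params(kappa = vals$kappa, w = wmat, w_ad = vals$w_ad,
                         z0 = vals$z0, wall = vals$wall > 0 || vals$w_ad > 0,
                         s = vals$s, r = vals$r,
                         inhibition = vals$inhibition, beta = vals$beta)
  config <- sim_config(sweeps = vals$mcsweeps, step = vals$step,
                       cadence = max(1L, as.integer(vals$mcsweeps) %/%
                                       max(1L, as.integer(vals$iterations))),
                       lmin = vals$lmin, lmax = vals$lmax,
                       seed = as.integer(vals$seed))
  list(config = config, params = params, species = species,
       rho = if (two) c(vals$rho, vals$rho2) else vals$rho,
       nshell = as.integer(vals$nshell), values = vals)
}

# echo of the resolved configuration, sufficient to reproduce a run
write_config_echo <- function(path, params, config, state) {
  lines <- c(
    sprintf("kappa=%g", params$kappa),
    sprintf("w_ad=%g", params$w_ad), sprintf("z0=%g", params$z0),
    sprintf("wall=%d", as.integer(isTRUE(params$wall))),
    sprintf("s=%g", params$s), sprintf("r=%g", params$r),
    sprintf("inhibition=%s", params$inhibition),
    sprintf("beta=%g", params$beta),
    sprintf("mcsweeps=%d", config$sweeps), sprintf("step=%g", config$step),
    sprintf("lmin=%g", config$lmin), sprintf("lmax=%g", config$lmax),
    sprintf("seed=%s", if (is.null(config$seed)) "NA" else config$seed),
    sprintf("# species: %s",
            paste(sprintf("c0=%g f=%g", state$species$c0, state$species$f),
                  collapse = " | ")))
  atomic_write(path, function(con) writeLines(lines, con))
}

atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  con <- file(tmp, "w")
  ok <- FALSE
  tryCatch({ writer(con); ok <- TRUE }, finally = {
    close(con)
    if (ok) file.rename(tmp, path) else unlink(tmp)
  })
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a snapshot as a VTU (VTK XML UnstructuredGrid) file
#'
#' Triangles as cells; per-vertex point-data arrays: species label, mean
#' curvature `h`, vertex area `A`, cluster id, the active force vector and
#' its projection on the outward normal.  Positions round-trip bit-exactly
#' through [read_vtu()].
#'
#' @param path output path.
#' @param mesh a `vesicle_mesh`.
#' @param state optional `cmc_state` (bare state assumed if omitted).
#' @param params optional `model_params` (used for the force arrays).
#' @export
write_vtu <- function(path, mesh, state = NULL, params = NULL) {
  V <- nrow(mesh$positions)
  Tn <- nrow(mesh$triangles)
  if (is.null(state)) state <- cmc_state(integer(V))
  if (is.null(params)) params <- model_params()
  geom <- cpp_geometry(mesh$positions, mesh$triangles)
  cl <- cpp_clusters(mesh$triangles, state$labels, V)
  fm <- force_magnitude(mesh, state, params)
  dir <- force_direction(mesh, state, params)
  force <- dir * fm
  fdn <- rowSums(force * geom$normal)
  da <- function(name, values, ncomp = 1L, type = "Float64") {
    vals <- if (ncomp == 1L) fmt_num(values)
    else apply(values, 1L, function(r) paste(fmt_num(r), collapse = " "))
    if (type == "Int32") vals <- as.character(values)
    c(sprintf('      <DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">',
              type, name, ncomp),
      paste0("        ", vals),
      "      </DataArray>")
  }
  lines <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    "  <UnstructuredGrid>",
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', V, Tn),
    "      <Points>",
    sprintf('      <DataArray type="Float64" Name="Position" NumberOfComponents="3" format="ascii">'),
    paste0("        ",
           apply(mesh$positions, 1L, function(r) paste(fmt_num(r), collapse = " "))),
    "      </DataArray>",
    "      </Points>",
    "      <PointData>",
    da("species", state$labels, type = "Int32"),
    da("h", geom$area * 0 + ifelse(is.na(geom$h), 0, geom$h)),
    da("A", geom$area),
    da("cluster", cl, type = "Int32"),
    da("force", force, ncomp = 3L),
    da("force_dot_normal", fdn),
    "      </PointData>",
    "      <Cells>",
    '      <DataArray type="Int32" Name="connectivity" format="ascii">',
    paste0("        ",
           apply(mesh$triangles - 1L, 1L, paste, collapse = " ")),
    "      </DataArray>",
    '      <DataArray type="Int32" Name="offsets" format="ascii">',
    paste0("        ", paste(seq_len(Tn) * 3L, collapse = " ")),
    "      </DataArray>",
    '      <DataArray type="UInt8" Name="types" format="ascii">',
    paste0("        ", paste(rep(5L, Tn), collapse = " ")),
    "      </DataArray>",
    "      </Cells>",
    "    </Piece>",
    "  </UnstructuredGrid>",
    "</VTKFile>")
  atomic_write(path, function(con) writeLines(lines, con))
}

#' Read a VTU snapshot back
#'
#' @param path a VTU file written by [write_vtu()] (or any ascii triangle
#'   UnstructuredGrid with the same arrays).
#' @param species a [species_table()] to attach to the restored state.
#' @return list with `mesh` (a `vesicle_mesh`) and `state` (a `cmc_state`).
#' @export
read_vtu <- function(path, species = species_table()) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (inherits(piece, "xml_missing")) stop("malformed VTU: no <Piece> element")
  get_array <- function(xpath, what) {
    node <- xml2::xml_find_first(doc, xpath)
    if (inherits(node, "xml_missing"))
      stop(sprintf("malformed VTU: missing %s", what))
    scan(text = xml2::xml_text(node), quiet = TRUE)
  }
  pts <- get_array(".//Points/DataArray", "<Points>")
  conn <- get_array(".//Cells/DataArray[@Name='connectivity']", "connectivity")
  pos <- matrix(pts, ncol = 3L, byrow = TRUE)
  tri <- matrix(as.integer(conn), ncol = 3L, byrow = TRUE) + 1L
  lab_node <- xml2::xml_find_first(doc, ".//PointData/DataArray[@Name='species']")
  labels <- if (inherits(lab_node, "xml_missing")) integer(nrow(pos))
  else as.integer(scan(text = xml2::xml_text(lab_node), quiet = TRUE))
  list(mesh = vesicle_mesh(pos, tri),
       state = cmc_state(labels, species))
}

#' Write a snapshot as ascii PLY
#'
#' @param path output path.
#' @param mesh a `vesicle_mesh`.
#' @param state optional `cmc_state`; species labels stored as a vertex
#'   property.
#' @export
write_ply <- function(path, mesh, state = NULL) {
  V <- nrow(mesh$positions)
  Tn <- nrow(mesh$triangles)
  labels <- if (is.null(state)) integer(V) else state$labels
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", V),
              "property double x", "property double y", "property double z",
              "property int species",
              sprintf("element face %d", Tn),
              "property list uchar int vertex_indices",
              "end_header")
  vlines <- paste(fmt_num(mesh$positions[, 1]), fmt_num(mesh$positions[, 2]),
                  fmt_num(mesh$positions[, 3]), labels)
  flines <- paste(3L, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                  mesh$triangles[, 3] - 1L)
  atomic_write(path, function(con) writeLines(c(header, vlines, flines), con))
}

#' Read an ascii PLY snapshot
#' @param path PLY file written by [write_ply()].
#' @param species a [species_table()] for the restored state.
#' @return list with `mesh` and `state`.
#' @export
read_ply <- function(path, species = species_table()) {
  lines <- readLines(path, warn = FALSE)
  endh <- match("end_header", lines)
  if (is.na(endh)) stop("malformed PLY: no end_header")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vdat <- read.table(text = lines[endh + seq_len(nv)])
  fdat <- read.table(text = lines[endh + nv + seq_len(nf)])
  list(mesh = vesicle_mesh(unname(as.matrix(vdat[, 1:3])),
                           unname(as.matrix(fdat[, 2:4])) + 1L),
       state = cmc_state(as.integer(vdat[, 4]), species))
}

#' Write the per-snapshot measure table as CSV
#'
#' One row per snapshot: sweep, energies, area, volume, cluster statistics,
#' gyration eigenvalues, perimeter, segregation and phase label.  Values
#' round-trip at full precision.
#'
#' @param path output path.
#' @param measures the `measures` data.frame of a `vesicle_sim`.
#' @export
write_measures_csv <- function(path, measures) {
  atomic_write(path, function(con)
    write.csv(format(measures, digits = 17, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, quote = FALSE))
}

#' Read a measure table written by [write_measures_csv()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_measures_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
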