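# Run configuration, result bundles and plain-text writers (legacy ASCII VTK,
# unit-suffixed CSV curve tables).

run_config_defaults <- function() {
  list(
    variants = c("no_soc", "with_soc", "protrusions_small",
                 "protrusions_extended"),
    geometry = list(),
    materials = list(),
    mesh = list(target_edge_length = 0.9),
    load_cases = list(list(sector_center_angle = 90, peak_pressure = 0.3),
                      list(sector_center_angle = 45, peak_pressure = 0.3)),
    solver = list(tol = 1e-8, max_iter = 80, small_strain = FALSE),
    zones = list(band = "growth_plate_band"),
    out_dir = "epimech-run",
    seed = 1L
  )
}

#' Read and validate a run configuration
#'
#' YAML configuration for [run_simulation()]. Unknown top-level keys are
#' rejected; missing keys take the documented defaults, and the fully resolved
#' configuration is snapshotted into the output directory for provenance.
#'
#' @param path YAML file; alternatively pass a list via `config`.
#' @param config optional list overriding `path`.
#' @return validated configuration list.
#' @export
read_run_config <- function(path = NULL, config = NULL) {
  if (is.null(config)) config <- yaml::read_yaml(path)
  def <- run_config_defaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  # named option groups merge key-by-key; list-valued keys (variants, load
  # cases) replace wholesale
  cfg <- def
  for (key in names(config)) {
    if (key %in% c("geometry", "mesh", "solver", "materials", "zones") &&
        is.list(config[[key]])) {
      cfg[[key]] <- utils::modifyList(def[[key]], config[[key]])
    } else {
      cfg[[key]] <- config[[key]]
    }
  }
  bad <- setdiff(cfg$variants, variant_ids())
  if (length(bad) > 0)
    stop("unknown variant(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (lc in cfg$load_cases)
    if (!is.list(lc) || is.null(lc$peak_pressure))
      stop("each load case needs at least peak_pressure", call. = FALSE)
  cfg
}

#' Run the full simulation pipeline
#'
#' For each (variant, load case) pair: build geometry, mesh (meshes are shared
#' between variants with identical polygons, e.g. with/without ossification
#' center), solve, post-process, and export displacement and stress fields
#' (VTK), zone summaries (CSV), convergence logs and a config snapshot. Any
#' stage failure aborts the run with a stage-named error.
#'
#' @param config a list or validated configuration (see [read_run_config()]).
#' @param quiet suppress progress messages.
#' @return a `result_bundle`: summary data.frame plus per-run solutions,
#'   invisibly.
#' @export
run_simulation <- function(config = list(), quiet = FALSE) {
  cfg <- read_run_config(config = config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(out, "config-snapshot.yaml"))
  params <- do.call(epiphysis_params, cfg$geometry)
  say <- function(...) if (!quiet) message(...)

  meshes <- list()
  summary_rows <- list()
  runs <- list()
  for (v in cfg$variants) {
    gkey <- if (v %in% c("no_soc", "with_soc")) "soc" else v
    if (is.null(meshes[[gkey]])) {
      say("meshing geometry for ", gkey)
      geo <- build_geometry(params, v)
      meshes[[gkey]] <- tryCatch(
        generate_mesh(geo, cfg$mesh$target_edge_length),
        error = function(e) stop("stage mesh (", v, "): ",
                                 conditionMessage(e), call. = FALSE))
    }
    mesh <- meshes[[gkey]]
    mat <- do.call(material_map, c(list(variant = v), cfg$materials))
    bc <- boundary_conditions(mesh, "epiphysis")
    band <- zone_elements(mesh, label = "growth_plate_band")
    for (i in seq_along(cfg$load_cases)) {
      lcspec <- cfg$load_cases[[i]]
      lc <- do.call(load_case, lcspec)
      say(sprintf("solving %s, load case %d (theta %g, %g MPa)", v, i,
                  lc$sector_center_angle, lc$peak_pressure))
      sol <- tryCatch(
        solve_elasticity(mesh, mat, bc, lc,
                         small_strain = isTRUE(cfg$solver$small_strain),
                         tol = cfg$solver$tol,
                         max_iter = cfg$solver$max_iter),
        error = function(e) stop("stage solve (", v, ", load case ", i, "): ",
                                 conditionMessage(e), call. = FALSE))
      sf <- scalar_measures(second_pk_stress(sol, mesh, mat))
      zs <- zone_summary(sf, band)
      defl <- deflection(sol, mesh, lc)
      tagrun <- sprintf("%s_lc%d", v, i)
      for (r in seq_len(nrow(zs)))
        summary_rows[[length(summary_rows) + 1L]] <-
          data.frame(variant = v, load_case = i,
                     theta = lc$sector_center_angle,
                     peak_pressure = lc$peak_pressure, zone = "band",
                     measure = zs$measure[r], peak = zs$peak[r],
                     mean = zs$mean[r], deflection_mm = defl)
      write_vtk(file.path(out, paste0(tagrun, ".vtk")), mesh,
                point_data = list(displacement = sol$u),
                cell_data = sf[c("S11", "S22", "S12", "S33", "hydrostatic",
                                 "min_principal", "tau_oct")])
      write_vtk(file.path(out, paste0(tagrun, "_deformed.vtk")), mesh,
                coords = deformed_coordinates(mesh, sol),
                cell_data = sf[c("hydrostatic", "min_principal", "tau_oct")])
      clog <- sol$log
      clog[] <- lapply(clog, function(x)
        if (is.double(x)) sprintf("%.17g", x) else x)
      utils::write.csv(clog,
                       file.path(out, paste0(tagrun, "_convergence.csv")),
                       row.names = FALSE, quote = FALSE)
      runs[[tagrun]] <- list(variant = v, lc = lc, sol = sol, mesh_key = gkey)
    }
  }
  summary <- do.call(rbind, summary_rows)
  fmt <- summary
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], function(x) sprintf("%.17g", x))
  utils::write.csv(fmt, file.path(out, "summary.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(structure(list(summary = summary, runs = runs, meshes = meshes,
                           config = cfg, out_dir = out),
                      class = "result_bundle"))
}

#' Write a mesh with fields as legacy ASCII VTK
#'
#' Quadratic triangles (VTK cell type 22) with optional per-node point data
#' and per-element cell data; numbers are written with 17 significant digits
#' so files round-trip exactly.
#'
#' @param path output file.
#' @param mesh a `planar_mesh`.
#' @param point_data named list of per-node vectors or 2-column matrices
#'   (written as 3-vectors with zero z).
#' @param cell_data named list/data.frame of per-element vectors.
#' @param coords optional node coordinates overriding the reference ones
#'   (e.g. deformed coordinates).
#' @export
write_vtk <- function(path, mesh, point_data = list(), cell_data = list(),
                      coords = NULL) {
  nodes <- if (is.null(coords)) mesh$nodes else coords
  if (nrow(nodes) != nrow(mesh$nodes)) stop("coords size mismatch")
  for (nm in names(point_data))
    if (NROW(point_data[[nm]]) != nrow(nodes))
      stop("point data '", nm, "' has wrong length", call. = FALSE)
  for (nm in names(cell_data))
    if (NROW(cell_data[[nm]]) != nrow(mesh$tri))
      stop("cell data '", nm, "' has wrong length", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(x) sprintf("%.17g", x)
  w("# vtk DataFile Version 3.0")
  w("epimech planar mesh")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", nrow(nodes))
  writeLines(paste(num(nodes[, 1]), num(nodes[, 2]), "0"), con)
  m <- nrow(mesh$tri)
  w("CELLS %d %d", m, m * 7)
  writeLines(paste(6, mesh$tri[, 1] - 1, mesh$tri[, 2] - 1, mesh$tri[, 3] - 1,
                   mesh$tri[, 4] - 1, mesh$tri[, 5] - 1, mesh$tri[, 6] - 1),
             con)
  w("CELL_TYPES %d", m)
  writeLines(rep("22", m), con)
  lab <- as.integer(factor(mesh$label, levels = sort(unique(mesh$label))))
  w("CELL_DATA %d", m)
  w("SCALARS subdomain int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(lab), con)
  for (nm in names(cell_data)) {
    w("SCALARS %s double 1", nm)
    w("LOOKUP_TABLE default")
    writeLines(num(cell_data[[nm]]), con)
  }
  if (length(point_data) > 0) {
    w("POINT_DATA %d", nrow(nodes))
    for (nm in names(point_data)) {
      pd <- point_data[[nm]]
      if (is.matrix(pd)) {
        w("VECTORS %s double", nm)
        writeLines(paste(num(pd[, 1]), num(pd[, 2]), "0"), con)
      } else {
        w("SCALARS %s double 1", nm)
        w("LOOKUP_TABLE default")
        writeLines(num(pd), con)
      }
    }
  }
  invisible(path)
}

#' Write a mesh as XML VTU (ASCII appended data)
#'
#' Unstructured-grid XML flavour of [write_vtk()], with the same quadratic
#' triangles and optional cell/point data.
#' @inheritParams write_vtk
#' @export
write_vtu <- function(path, mesh, point_data = list(), cell_data = list(),
                      coords = NULL) {
  nodes <- if (is.null(coords)) mesh$nodes else coords
  m <- nrow(mesh$tri); n <- nrow(nodes)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste(sprintf("%.17g", nodes[, 1]),
                   sprintf("%.17g", nodes[, 2]), "0"), con)
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$tri - 1L, 1, paste, collapse = " "), con)
  w('</DataArray><DataArray type="Int64" Name="offsets" format="ascii">')
  w(paste(seq_len(m) * 6L, collapse = " "))
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(22L, m), collapse = " "))
  w('</DataArray></Cells>')
  w('<CellData>')
  for (nm in names(cell_data)) {
    w('<DataArray type="Float64" Name="%s" format="ascii">', nm)
    w(num(cell_data[[nm]]))
    w('</DataArray>')
  }
  w('</CellData>')
  w('<PointData>')
  for (nm in names(point_data)) {
    pd <- point_data[[nm]]
    if (is.matrix(pd)) {
      w('<DataArray type="Float64" Name="%s" NumberOfComponents="3" format="ascii">', nm)
      writeLines(paste(sprintf("%.17g", pd[, 1]),
                       sprintf("%.17g", pd[, 2]), "0"), con)
    } else {
      w('<DataArray type="Float64" Name="%s" format="ascii">', nm)
      w(num(pd))
    }
    w('</DataArray>')
  }
  w('</PointData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}

#' Dump mesh nodes and elements to CSV
#'
#' Writes `<prefix>_nodes.csv` (id, x, y) and `<prefix>_elements.csv`
#' (id, n1..n6, label).
#' @param mesh a `planar_mesh`.
#' @param prefix output path prefix.
#' @export
write_mesh_csv <- function(mesh, prefix) {
  nd <- data.frame(id = seq_len(nrow(mesh$nodes)),
                   x = sprintf("%.17g", mesh$nodes[, 1]),
                   y = sprintf("%.17g", mesh$nodes[, 2]))
  utils::write.csv(nd, paste0(prefix, "_nodes.csv"), row.names = FALSE,
                   quote = FALSE)
  el <- data.frame(id = seq_len(nrow(mesh$tri)), n1 = mesh$tri[, 1],
                   n2 = mesh$tri[, 2], n3 = mesh$tri[, 3],
                   n4 = mesh$tri[, 4], n5 = mesh$tri[, 5],
                   n6 = mesh$tri[, 6], label = mesh$label)
  utils::write.csv(el, paste0(prefix, "_elements.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(prefix)
}

#' Read back a legacy ASCII VTK file written by [write_vtk()]
#'
#' Minimal reader for round-trip checks: returns points and connectivity.
#' @param path VTK file.
#' @export
read_vtk <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)[1]
  np <- as.integer(strsplit(ln[ip], " ")[[1]][2])
  pts <- do.call(rbind, lapply(strsplit(ln[ip + seq_len(np)], " "),
                               function(x) as.numeric(x[1:2])))
  ic <- grep("^CELLS", ln)[1]
  nc <- as.integer(strsplit(ln[ic], " ")[[1]][2])
  cells <- do.call(rbind, lapply(strsplit(ln[ic + seq_len(nc)], " "),
                                 function(x) as.integer(x[-1]) + 1L))
  list(points = pts, cells = cells)
}

#' Write a force or load-deformation curve as a unit-suffixed CSV
#'
#' Metadata (instrument constants, generator ground truth) goes into `#`
#' comment lines of the form `# key: value` above the header.
#' @param obj a `force_curve` or `load_deformation_record`.
#' @param path output CSV.
#' @export
write_curve_table <- function(obj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c()
  if (inherits(obj, "force_curve")) {
    meta <- c(k_N_per_m = obj$k_N_per_m, R_um = obj$R_um,
              direction = obj$direction, instrument = obj$instrument)
    df <- data.frame(z_um = obj$z_um, force_nN = obj$force_nN)
  } else if (inherits(obj, "load_deformation_record")) {
    df <- data.frame(time_s = obj$time_s, position_mm = obj$position_mm,
                     load_N = obj$load_N)
  } else stop("unsupported object", call. = FALSE)
  gt <- obj$meta
  gt$dims <- NULL; gt$delta_true <- NULL; gt$force_true <- NULL
  meta <- c(meta, unlist(gt))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm,
                       if (is.numeric(meta[[nm]]))
                         sprintf("%.17g", as.numeric(meta[[nm]]))
                       else as.character(meta[[nm]])), con)
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(lapply(df, function(x)
    if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)),
    sep = ",")), con)
  invisible(path)
}

#' Read a unit-suffixed curve table
#'
#' Columns must carry unit suffixes (`_s`, `_mm`, `_N`, `_um`, `_nN`, `_nm`);
#' a file with `z_um` plus `force_nN` or `deflection_nm` becomes a
#' `force_curve` (spring constant and radius from the metadata block), one
#' with `position_mm` and `load_N` becomes a `load_deformation_record`.
#'
#' @param path CSV file with optional `# key: value` metadata lines.
#' @return a `force_curve` or `load_deformation_record`.
#' @export
read_curve_table <- function(path) {
  ln <- readLines(path)
  metal <- grep("^#", ln, value = TRUE)
  meta <- list()
  for (l in metal) {
    kv <- sub("^#\\s*", "", l)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    num <- suppressWarnings(as.numeric(val))
    meta[[trimws(key)]] <- if (!is.na(num)) num else val
  }
  body <- ln[!grepl("^#", ln)]
  body <- body[nzchar(body)]
  if (length(body) < 2) stop("parse error: empty data section", call. = FALSE)
  header <- strsplit(body[1], ",")[[1]]
  ok_suffix <- grepl("_(s|mm|N|um|nN|nm)$", header)
  if (!all(ok_suffix))
    stop("parse error: column(s) without a recognised unit suffix: ",
         paste(header[!ok_suffix], collapse = ", "), call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  names(df) <- header
  if (all(c("position_mm", "load_N") %in% header)) {
    structure(list(time_s = df$time_s, position_mm = df$position_mm,
                   load_N = df$load_N, meta = meta),
              class = "load_deformation_record")
  } else if ("z_um" %in% header &&
             any(c("force_nN", "deflection_nm") %in% header)) {
    if (is.null(meta$k_N_per_m) || is.null(meta$R_um))
      stop("parse error: force curve needs k_N_per_m and R_um metadata",
           call. = FALSE)
    force_curve(z = df$z_um, force = df$force_nN,
                deflection = df$deflection_nm,
                k = meta$k_N_per_m, R = meta$R_um,
                direction = if (is.null(meta$direction)) "retract"
                            else meta$direction,
                instrument = if (is.null(meta$instrument)) "afm"
                             else meta$instrument,
                meta = meta)
  } else {
    stop("parse error: unrecognised column set (missing column?): ",
         paste(header, collapse = ", "), call. = FALSE)
  }
}
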