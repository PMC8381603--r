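## File interfaces: VTK unstructured grids (.vtu, ASCII XML), optional
## Abaqus-flavoured .inp export, contour stacks as CSV/JSON, transforms as
## JSON, run configurations as YAML.

#' Write a hex mesh (plus optional fields) as a VTK unstructured grid
#'
#' ASCII XML .vtu with hexahedra (VTK type 12); surface/node sets are stored
#' as point-data membership arrays and per-element vectors (e.g. fiber
#' directions) as cell data.
#'
#' @param mesh A `hex_mesh`.
#' @param file Output path.
#' @param cell_data Named list of per-element vectors (length nE) or
#'   matrices (nE x 3).
#' @param point_data Named list of per-node vectors or n x 3 matrices.
#' @return The path, invisibly.
#' @export
write_vtu <- function(mesh, file, cell_data = list(), point_data = list()) {
  n <- nrow(mesh$nodes); e <- nrow(mesh$elements)
  for (s in names(mesh$surfaces)) {
    memb <- integer(n)
    memb[unique(as.integer(mesh$surfaces[[s]]))] <- 1L
    point_data[[paste0("set_", s)]] <- memb
  }
  for (s in names(mesh$node_sets)) {
    memb <- integer(n)
    memb[mesh$node_sets[[s]]] <- 1L
    point_data[[paste0("nodeset_", s)]] <- memb
  }
  num <- function(x) paste(formatC(x, format = "g", digits = 9), collapse = " ")
  da <- function(name, x, comps) {
    sprintf(paste0('<DataArray type="Float64" Name="%s" ',
                   'NumberOfComponents="%d" format="ascii">%s</DataArray>'),
            name, comps, num(t(x)))
  }
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="%d" NumberOfCells="%d">', n, e)
  writeLines(paste0('<Points>', da("Points", mesh$nodes, 3), '</Points>'),
             con)
  w('<Cells>')
  writeLines(paste0('<DataArray type="Int64" Name="connectivity" format="ascii">',
                    paste(t(mesh$elements) - 1L, collapse = " "),
                    '</DataArray>'), con)
  writeLines(paste0('<DataArray type="Int64" Name="offsets" format="ascii">',
                    paste(seq_len(e) * 8L, collapse = " "), '</DataArray>'),
             con)
  writeLines(paste0('<DataArray type="UInt8" Name="types" format="ascii">',
                    paste(rep(12L, e), collapse = " "), '</DataArray>'), con)
  w('</Cells>')
  w('<PointData>')
  for (nm in names(point_data)) {
    x <- point_data[[nm]]
    writeLines(da(nm, if (is.matrix(x)) x else cbind(x),
                  if (is.matrix(x)) 3L else 1L), con)
  }
  w('</PointData>')
  w('<CellData>')
  for (nm in names(cell_data)) {
    x <- cell_data[[nm]]
    writeLines(da(nm, if (is.matrix(x)) x else cbind(x),
                  if (is.matrix(x)) 3L else 1L), con)
  }
  w('</CellData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(file)
}

#' Read a hex mesh written by [write_vtu()]
#' @param file Path to an ASCII .vtu produced by this package.
#' @return A `hex_mesh` (surface facet sets are reconstructed from the
#'   membership arrays and the element faces).
#' @export
read_vtu <- function(file) {
  doc <- xml2::read_xml(file)
  get_arr <- function(xp) {
    nd <- xml2::xml_find_first(doc, xp)
    as.numeric(strsplit(trimws(xml2::xml_text(nd)), "\\s+")[[1]])
  }
  pts <- matrix(get_arr(".//Points/DataArray"), ncol = 3, byrow = TRUE)
  conn <- get_arr(".//Cells/DataArray[@Name='connectivity']")
  elems <- matrix(as.integer(conn) + 1L, ncol = 8, byrow = TRUE)
  pd <- xml2::xml_find_all(doc, ".//PointData/DataArray")
  sets <- list()
  for (nd in pd) {
    nm <- xml2::xml_attr(nd, "Name")
    if (startsWith(nm, "set_") || startsWith(nm, "nodeset_")) {
      v <- as.numeric(strsplit(trimws(xml2::xml_text(nd)), "\\s+")[[1]])
      sets[[nm]] <- which(v > 0.5)
    }
  }
  mesh <- structure(list(nodes = pts, elements = elems,
                         surfaces = list(), node_sets = list(),
                         meta = list(kind = "vtu_import")),
                    class = "hex_mesh")
  ## rebuild facet sets: boundary faces all of whose nodes are in the set
  faces <- rbind(c(1,4,3,2), c(5,6,7,8), c(1,2,6,5),
                 c(2,3,7,6), c(3,4,8,7), c(4,1,5,8))
  all_faces <- do.call(rbind, lapply(seq_len(nrow(elems)), function(e)
    t(apply(faces, 1, function(fc) elems[e, fc]))))
  key <- apply(all_faces, 1, function(f) paste(sort(f), collapse = "-"))
  boundary <- all_faces[key %in% names(which(table(key) == 1)), , drop = FALSE]
  for (nm in names(sets)) {
    if (startsWith(nm, "set_")) {
      inset <- matrix(boundary %in% sets[[nm]], nrow(boundary))
      mesh$surfaces[[sub("^set_", "", nm)]] <-
        boundary[rowSums(inset) == 4L, , drop = FALSE]
    } else {
      mesh$node_sets[[sub("^nodeset_", "", nm)]] <- sets[[nm]]
    }
  }
  mesh
}

#' Export a hex mesh in Abaqus .inp flavour
#'
#' Nodes, C3D8 elements and surface definitions, for cross-checking in
#' external FE tools.
#' @param mesh A `hex_mesh`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_inp <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.9g, %.9g, %.9g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines("*ELEMENT, TYPE=C3D8, ELSET=WALL", con)
  writeLines(apply(cbind(seq_len(nrow(mesh$elements)), mesh$elements), 1,
                   paste, collapse = ", "), con)
  for (s in names(mesh$surfaces)) {
    writeLines(sprintf("*NSET, NSET=%s", toupper(s)), con)
    ids <- sort(unique(as.integer(mesh$surfaces[[s]])))
    for (chunk in split(ids, ceiling(seq_along(ids) / 12)))
      writeLines(paste(chunk, collapse = ", "), con)
  }
  invisible(file)
}

#' Write a contour stack as CSV
#'
#' Long format with columns slice_z, contour_id ("endo"/"epi"), point, x, y.
#' @param stack A `contour_stack`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_contours_csv <- function(stack, file) {
  rows <- list()
  for (s in stack$slices) for (cid in c("endo", "epi")) {
    p <- s[[cid]]
    rows[[length(rows) + 1L]] <- data.frame(
      slice_z = s$slice_z, contour_id = cid, point = seq_len(nrow(p)),
      x = p[, 1], y = p[, 2])
  }
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' Read a contour stack from CSV
#' @param file Path written by [write_contours_csv()].
#' @param in_plane_spacing,slice_thickness Metadata (mm).
#' @return A `contour_stack`.
#' @export
read_contours_csv <- function(file, in_plane_spacing = 1.4,
                              slice_thickness = 2.5) {
  d <- utils::read.csv(file)
  slices <- lapply(sort(unique(d$slice_z)), function(z) {
    sl <- d[d$slice_z == z, ]
    mk <- function(cid) {
      p <- sl[sl$contour_id == cid, ]
      unname(as.matrix(p[order(p$point), c("x", "y")]))
    }
    list(slice_z = z, endo = mk("endo"), epi = mk("epi"))
  })
  contour_stack(slices, in_plane_spacing, slice_thickness)
}

#' Write a contour stack as JSON
#' @param stack A `contour_stack`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_contours_json <- function(stack, file) {
  jsonlite::write_json(list(
    in_plane_spacing = stack$in_plane_spacing,
    slice_thickness = stack$slice_thickness,
    slices = lapply(stack$slices, function(s)
      list(slice_z = s$slice_z, endo = s$endo, epi = s$epi))),
    file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' Read a contour stack from JSON
#' @param file Path written by [write_contours_json()].
#' @return A `contour_stack`.
#' @export
read_contours_json <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  slices <- lapply(seq_along(j$slices$slice_z), function(i)
    list(slice_z = j$slices$slice_z[i],
         endo = as.matrix(j$slices$endo[[i]]),
         epi = as.matrix(j$slices$epi[[i]])))
  contour_stack(slices, j$in_plane_spacing, j$slice_thickness)
}

#' Write a rigid transform as a JSON 4x4 matrix
#' @param transform A `rigid_transform`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_transform_json <- function(transform, file) {
  M <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = M), file, digits = NA)
  invisible(file)
}

#' Default run configuration
#'
#' Nested list of all tunable parameters (shape, material, boundary
#' conditions, solver, mask, Bayesian optimization), round-trippable through
#' YAML.
#' @return A named list.
#' @export
default_config <- function() {
  list(shape = unclass(coarse_lv_spec()),
       material = unclass(material_params()),
       boundary = unclass(boundary_conditions()),
       solver = lapply(unclass(solver_settings()), identity),
       mask = list(spacing = 2, threshold = 0.25, closing_diameter = 6),
       bo = list(beta = 10, beta_scale = "sqrt", n_iterations = 10,
                 init_params = list(c(0, 1), c(1, 0), c(1, 1)),
                 acquisition_grid = 101, noise_floor = 1e-4, seed = 1))
}

#' Read a YAML run configuration (missing fields filled with defaults)
#' @param file YAML path.
#' @return A config list.
#' @export
read_config <- function(file) {
  utils::modifyList(default_config(), yaml::read_yaml(file))
}

#' Write a run configuration as YAML
#' @param config A config list.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(config, file)
  invisible(file)
}

config_objects <- function(cfg) {
  bo_ip <- do.call(rbind, lapply(cfg$bo$init_params, unlist))
  list(spec = do.call(lv_shape_spec, cfg$shape),
       mat = do.call(material_params, cfg$material),
       bc = do.call(boundary_conditions, cfg$boundary),
       solver = do.call(solver_settings, cfg$solver[
         intersect(c("n_increments", "settle_increments", "damping",
                     "mass_safety", "checkpoint_fractions",
                     "ke_check_interval", "ke_tolerance"),
                   names(cfg$solver))]),
       bo = bo_settings(beta = cfg$bo$beta,
                        beta_scale = cfg$bo$beta_scale %||% "sqrt",
                        n_iterations = cfg$bo$n_iterations,
                        init_params = bo_ip,
                        acquisition_grid = cfg$bo$acquisition_grid,
                        noise_floor = cfg$bo$noise_floor,
                        seed = cfg$bo$seed))
}
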