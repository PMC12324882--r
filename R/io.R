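# File interchange: VTK XML (ASCII) unstructured-grid / poly-data writers
# and readers for field, wall and centerline data, plus CSV tables.

fmt_num <- function(x) {
  paste(format(x, digits = 17, trim = TRUE, scientific = TRUE),
        collapse = " ")
}

vtk_data_array <- function(x, name, type = "Float64") {
  ncomp <- if (is.matrix(x)) ncol(x) else 1L
  vals <- if (is.matrix(x)) as.vector(t(x)) else x
  txt <- if (type %in% c("Int64", "UInt8")) {
    paste(format(vals, trim = TRUE, scientific = FALSE), collapse = " ")
  } else {
    fmt_num(vals)
  }
  sprintf(
    '<DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
    type, name, ncomp, txt)
}

#' Write a VTK XML unstructured grid (.vtu)
#'
#' ASCII, inline data. Connectivity is written 0-based as VTK expects.
#'
#' @param points n x 3 matrix of point coordinates.
#' @param cells List of 1-based point-index vectors.
#' @param types Integer VTK cell type per cell (10 tet, 12 hex, 13 wedge...).
#' @param file Output path.
#' @param cell_data Named list of per-cell numeric vectors or n x k matrices.
#' @return `file`, invisibly.
#' @export
write_vtu <- function(points, cells, types, file, cell_data = list()) {
  conn <- unlist(cells) - 1L
  offs <- cumsum(lengths(cells))
  cd <- paste(vapply(names(cell_data), function(nm) {
    vtk_data_array(cell_data[[nm]], nm)
  }, character(1)), collapse = "\n")
  xml <- sprintf(
'<?xml version="1.0"?>
<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">
<UnstructuredGrid>
<Piece NumberOfPoints="%d" NumberOfCells="%d">
<Points>
%s
</Points>
<Cells>
%s
%s
%s
</Cells>
<CellData>
%s
</CellData>
</Piece>
</UnstructuredGrid>
</VTKFile>',
    nrow(points), length(cells),
    vtk_data_array(points, "Points"),
    vtk_data_array(conn, "connectivity", "Int64"),
    vtk_data_array(offs, "offsets", "Int64"),
    vtk_data_array(as.integer(types), "types", "UInt8"),
    cd)
  writeLines(xml, file)
  invisible(file)
}

read_vtk_array <- function(node) {
  vals <- scan(text = xml2::xml_text(node), what = double(), quiet = TRUE)
  ncomp <- as.integer(xml2::xml_attr(node, "NumberOfComponents") %||% "1")
  if (is.na(ncomp)) ncomp <- 1L
  if (ncomp > 1L) matrix(vals, ncol = ncomp, byrow = TRUE) else vals
}

#' Read a VTK XML unstructured grid (.vtu)
#'
#' @param file Path to an ASCII-format .vtu file.
#' @return A list: `points` (n x 3), `cells` (list of 1-based indices),
#'   `types`, `cell_data` (named list).
#' @export
read_vtu <- function(file) {
  doc <- xml2::read_xml(file)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  by_name <- setNames(as.list(arrays), xml2::xml_attr(arrays, "Name"))
  pts <- read_vtk_array(by_name[["Points"]])
  conn <- as.integer(read_vtk_array(by_name[["connectivity"]])) + 1L
  offs <- as.integer(read_vtk_array(by_name[["offsets"]]))
  types <- as.integer(read_vtk_array(by_name[["types"]]))
  starts <- c(1L, utils::head(offs, -1L) + 1L)
  cells <- purrr::map2(starts, offs, function(a, b) conn[a:b])
  skip <- c("Points", "connectivity", "offsets", "types")
  cd <- by_name[setdiff(names(by_name), skip)]
  list(points = pts, cells = cells, types = types,
       cell_data = lapply(cd, read_vtk_array))
}

#' Write a VTK XML poly-data file (.vtp)
#'
#' @param points n x 3 matrix.
#' @param prims List of 1-based point-index vectors (polygons or polylines).
#' @param file Output path.
#' @param primitive `"polys"` or `"lines"`.
#' @param cell_data,point_data Named lists of numeric vectors/matrices.
#' @return `file`, invisibly.
#' @export
write_vtp <- function(points, prims, file, primitive = c("polys", "lines"),
                      cell_data = list(), point_data = list()) {
  primitive <- match.arg(primitive)
  tag <- if (primitive == "polys") "Polys" else "Lines"
  counts <- sprintf('NumberOfVerts="0" NumberOfLines="%d" NumberOfStrips="0" NumberOfPolys="%d"',
                    if (primitive == "lines") length(prims) else 0L,
                    if (primitive == "polys") length(prims) else 0L)
  conn <- unlist(prims) - 1L
  offs <- cumsum(lengths(prims))
  cd <- paste(vapply(names(cell_data), function(nm) {
    vtk_data_array(cell_data[[nm]], nm)
  }, character(1)), collapse = "\n")
  pd <- paste(vapply(names(point_data), function(nm) {
    vtk_data_array(point_data[[nm]], nm)
  }, character(1)), collapse = "\n")
  xml <- sprintf(
'<?xml version="1.0"?>
<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">
<PolyData>
<Piece NumberOfPoints="%d" %s>
<Points>
%s
</Points>
<%s>
%s
%s
</%s>
<CellData>
%s
</CellData>
<PointData>
%s
</PointData>
</Piece>
</PolyData>
</VTKFile>',
    nrow(points), counts,
    vtk_data_array(points, "Points"),
    tag,
    vtk_data_array(conn, "connectivity", "Int64"),
    vtk_data_array(offs, "offsets", "Int64"),
    tag, cd, pd)
  writeLines(xml, file)
  invisible(file)
}

#' Read a VTK XML poly-data file (.vtp)
#'
#' @param file Path to an ASCII-format .vtp file.
#' @return A list: `points`, `prims` (list of 1-based index vectors),
#'   `cell_data`, `point_data`.
#' @export
read_vtp <- function(file) {
  doc <- xml2::read_xml(file)
  pts <- read_vtk_array(
    xml2::xml_find_first(doc, ".//Points/DataArray"))
  geom <- xml2::xml_find_first(doc, ".//Polys")
  if (is.na(xml2::xml_name(geom, ns = character()))) {
    geom <- xml2::xml_find_first(doc, ".//Lines")
  }
  conn <- as.integer(read_vtk_array(
    xml2::xml_find_first(geom, './/DataArray[@Name="connectivity"]'))) + 1L
  offs <- as.integer(read_vtk_array(
    xml2::xml_find_first(geom, './/DataArray[@Name="offsets"]')))
  starts <- c(1L, utils::head(offs, -1L) + 1L)
  prims <- purrr::map2(starts, offs, function(a, b) conn[a:b])
  grab <- function(xpath) {
    nodes <- xml2::xml_find_all(doc, xpath)
    setNames(lapply(nodes, read_vtk_array), xml2::xml_attr(nodes, "Name"))
  }
  list(points = pts, prims = prims,
       cell_data = grab(".//CellData/DataArray"),
       point_data = grab(".//PointData/DataArray"))
}

# --- derived mesh quantities -------------------------------------------------

tet_volume_centroid <- function(p0, p1, p2, p3) {
  v <- abs(sum((p1 - p0) * crossprod_vec(p2 - p0, p3 - p0))) / 6
  list(volume = v, centroid = (p0 + p1 + p2 + p3) / 4)
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Tetrahedral decompositions (1-based local indices).
cell_tet_split <- function(type, nv) {
  switch(as.character(type),
    "10" = list(c(1, 2, 3, 4)),
    "13" = list(c(1, 2, 3, 4), c(2, 3, 5, 4), c(3, 4, 5, 6)),
    "12" = list(c(1, 2, 4, 5), c(2, 3, 4, 7), c(2, 4, 5, 7),
                c(4, 5, 7, 8), c(2, 5, 6, 7)),
    abort(sprintf("unsupported VTK cell type %s.", type)))
}

#' Cell volumes and centroids from connectivity
#'
#' Decomposes tetrahedra, wedges and hexahedra into tetrahedra and sums
#' their volumes; centroids are volume-weighted.
#'
#' @param points n x 3 point matrix.
#' @param cells List of 1-based point-index vectors.
#' @param types VTK cell types (10, 12, 13).
#' @return Tibble (cell, x, y, z, volume).
#' @export
cell_geometry <- function(points, cells, types) {
  out <- purrr::map_dfr(seq_along(cells), function(i) {
    ids <- cells[[i]]
    tets <- cell_tet_split(types[i], length(ids))
    v <- 0; cxyz <- c(0, 0, 0)
    for (tt in tets) {
      tv <- tet_volume_centroid(points[ids[tt[1]], ], points[ids[tt[2]], ],
                                points[ids[tt[3]], ], points[ids[tt[4]], ])
      v <- v + tv$volume
      cxyz <- cxyz + tv$volume * tv$centroid
    }
    tibble(cell = i, x = cxyz[1] / v, y = cxyz[2] / v, z = cxyz[3] / v,
           volume = v)
  })
  out
}

#' Face-adjacency neighbour pairs from connectivity
#'
#' Two cells are neighbours when they share at least `min_shared` points
#' (3 = a face for tets/wedges/hexes).
#'
#' @param cells List of 1-based point-index vectors.
#' @param min_shared Minimum shared points.
#' @return Tibble (cell, nbr), both directions.
#' @export
cell_neighbors_from_cells <- function(cells, min_shared = 3L) {
  inc <- tibble(point = unlist(cells),
                cell = rep(seq_along(cells), lengths(cells)))
  pairs <- dplyr::inner_join(inc, inc, by = "point",
                             relationship = "many-to-many") |>
    filter(.data$cell.x != .data$cell.y) |>
    dplyr::count(.data$cell.x, .data$cell.y) |>
    filter(.data$n >= min_shared)
  tibble(cell = pairs$cell.x, nbr = pairs$cell.y)
}

# --- time-series round trips -------------------------------------------------

#' Write a flow-field time series as VTK files plus a manifest
#'
#' One .vtu per snapshot (cell data: velocity, optional vorticity, volume,
#' centroid, segment codes) and a JSON manifest listing files, times and the
#' segment code book.
#'
#' @param field Long flow-field tibble.
#' @param mesh A mesh list with `points`, `cells`, `cell_types` (e.g. a
#'   [make_cylinder_mesh()]).
#' @param dir Output directory (created if needed).
#' @param name Base name for the files.
#' @return Path of the manifest JSON, invisibly.
#' @export
write_flow_series <- function(field, mesh, dir, name = "flow") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  times <- sort(unique(field$time))
  seg_levels <- sort(unique(field[["segment"]] %||% "volume"))
  files <- character(length(times))
  for (i in seq_along(times)) {
    df <- field |> filter(.data$time == times[i]) |> arrange(.data$cell)
    cd <- list(velocity = cbind(df$vx, df$vy, df$vz),
               volume = df$volume,
               centroid = cbind(df$x, df$y, df$z),
               segment_code = match(df$segment, seg_levels))
    if (all(c("wx", "wy", "wz") %in% names(df))) {
      cd$vorticity <- cbind(df$wx, df$wy, df$wz)
    }
    files[i] <- sprintf("%s_%03d.vtu", name, i - 1L)
    write_vtu(mesh$points, mesh$cells, mesh$cell_types,
              file.path(dir, files[i]), cell_data = cd)
  }
  manifest <- file.path(dir, paste0(name, "_series.json"))
  jsonlite::write_json(
    list(kind = "flow_series", files = files, times = times,
         segment_levels = seg_levels),
    manifest, auto_unbox = FALSE, digits = NA)
  invisible(manifest)
}

#' Read a flow-field time series written by [write_flow_series()]
#'
#' Velocity/vorticity arrays are taken from the files (the array name is
#' configurable); volumes and centroids use the stored arrays when present
#' and are otherwise derived from the connectivity via [cell_geometry()].
#'
#' @param manifest Path to the series manifest JSON.
#' @param velocity_array Name of the velocity cell array.
#' @return A long flow-field tibble.
#' @export
read_flow_field <- function(manifest, velocity_array = "velocity") {
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  purrr::map_dfr(seq_along(man$files), function(i) {
    v <- read_vtu(file.path(dir, man$files[i]))
    cd <- v$cell_data
    vel <- cd[[velocity_array]]
    if (is.null(vel)) abort(sprintf("array '%s' not found.", velocity_array))
    geo <- if (!is.null(cd$volume) && !is.null(cd$centroid)) {
      tibble(cell = seq_len(length(cd$volume)), x = cd$centroid[, 1],
             y = cd$centroid[, 2], z = cd$centroid[, 3], volume = cd$volume)
    } else {
      cell_geometry(v$points, v$cells, v$types)
    }
    seg <- if (!is.null(cd$segment_code) && !is.null(man$segment_levels)) {
      man$segment_levels[as.integer(cd$segment_code)]
    } else {
      "volume"
    }
    geo |>
      mutate(time = man$times[i], segment = seg,
             vx = vel[, 1], vy = vel[, 2], vz = vel[, 3]) |>
      (\(df) if (!is.null(cd$vorticity)) {
        mutate(df, wx = cd$vorticity[, 1], wy = cd$vorticity[, 2],
               wz = cd$vorticity[, 3])
      } else df)()
  })
}

#' Write a wall shear series as .vtp files plus a manifest
#'
#' @param wall Long wall-series tibble.
#' @param mesh Mesh providing `points` and `wall_polys`.
#' @param dir Output directory.
#' @param name Base name.
#' @return Manifest path, invisibly.
#' @export
write_wall_series <- function(wall, mesh, dir, name = "wall") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  times <- sort(unique(wall$time))
  seg_levels <- sort(unique(wall[["segment"]] %||% "wall"))
  files <- character(length(times))
  for (i in seq_along(times)) {
    df <- wall |> filter(.data$time == times[i]) |> arrange(.data$element)
    files[i] <- sprintf("%s_%03d.vtp", name, i - 1L)
    write_vtp(mesh$points, mesh$wall_polys, file.path(dir, files[i]),
              primitive = "polys",
              cell_data = list(
                wss = cbind(df$taux, df$tauy, df$tauz),
                area = df$area,
                segment_code = match(df$segment, seg_levels)))
  }
  manifest <- file.path(dir, paste0(name, "_series.json"))
  jsonlite::write_json(
    list(kind = "wall_series", files = files, times = times,
         segment_levels = seg_levels),
    manifest, auto_unbox = FALSE, digits = NA)
  invisible(manifest)
}

#' Read a wall shear series written by [write_wall_series()]
#'
#' @param manifest Path to the manifest JSON.
#' @param wss_array Name of the wall-shear cell array.
#' @return A long wall-series tibble.
#' @export
read_wall_series <- function(manifest, wss_array = "wss") {
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  purrr::map_dfr(seq_along(man$files), function(i) {
    v <- read_vtp(file.path(dir, man$files[i]))
    cd <- v$cell_data
    tau <- cd[[wss_array]]
    if (is.null(tau)) abort(sprintf("array '%s' not found.", wss_array))
    seg <- if (!is.null(cd$segment_code) && !is.null(man$segment_levels)) {
      man$segment_levels[as.integer(cd$segment_code)]
    } else {
      "wall"
    }
    tibble(element = seq_len(nrow(tau)), time = man$times[i],
           taux = tau[, 1], tauy = tau[, 2], tauz = tau[, 3],
           area = cd$area, segment = seg)
  })
}

# --- centerlines and tables --------------------------------------------------

#' Write a centerline as VTK poly-data with a radius point array
#' @param curve A [centerline()] tibble.
#' @param file Output .vtp path.
#' @return `file`, invisibly.
#' @export
write_centerline_vtp <- function(curve, file) {
  pd <- list(arc_length = curve$arc_length)
  if (!is.null(curve[["radius"]])) pd$radius <- curve$radius
  write_vtp(cbind(curve$x, curve$y, curve$z),
            list(seq_len(nrow(curve))), file, primitive = "lines",
            point_data = pd)
  invisible(file)
}

#' Read a centerline from VTK poly-data
#' @param file A .vtp path with a polyline and optional radius array.
#' @param label Segment label for the result.
#' @return A [centerline()] tibble.
#' @export
read_centerline_vtp <- function(file, label = "segment") {
  v <- read_vtp(file)
  ord <- v$prims[[1]]
  centerline(v$points[ord, 1], v$points[ord, 2], v$points[ord, 3],
             radius = v$point_data$radius[ord], label = label)
}

#' Write / read a centerline as CSV (x, y, z, radius, label)
#' @param curve A [centerline()] tibble.
#' @param file CSV path.
#' @return `file` (write) or a centerline tibble (read).
#' @export
write_centerline_csv <- function(curve, file) {
  readr::write_csv(curve, file)
  invisible(file)
}

#' @rdname write_centerline_csv
#' @export
read_centerline_csv <- function(file) {
  df <- readr::read_csv(file, show_col_types = FALSE)
  centerline(df$x, df$y, df$z, radius = df[["radius"]],
             label = df$label[1] %||% "segment")
}

#' Write / read a tidy segment table as CSV
#' @param table Tidy segment table tibble.
#' @param file CSV path.
#' @return `file` (write) or a tibble (read).
#' @export
write_segment_table <- function(table, file) {
  readr::write_csv(table, file)
  invisible(file)
}

#' @rdname write_segment_table
#' @export
read_segment_table <- function(file) {
  readr::read_csv(file, show_col_types = FALSE)
}

#' Write / read a waveform as a (time, flow) CSV
#' @param wave A [waveform_spec()].
#' @param file CSV path.
#' @param n_steps Samples over one cycle.
#' @return `file` (write) or a tibble (read).
#' @export
write_waveform_csv <- function(wave, file, n_steps = 101L) {
  readr::write_csv(waveform_table(wave, n_steps), file)
  invisible(file)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(file) {
  readr::read_csv(file, show_col_types = FALSE)
}
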