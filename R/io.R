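## File formats: ASCII VTU (XML unstructured grid) for meshes and fields,
## a JSON + CSV pair for sparse cDTI datasets, and JSON/YAML run
## configuration with validated defaults.  No binary payloads: everything is
## plain text and round-trips losslessly at full double precision.

fmt_num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)

#' Write a tetrahedral mesh (with fields) as ASCII VTU
#'
#' Tetrahedra are written as VTK cell type 10; the labeled surface triangles
#' are appended as cell type 5 with the cell-data array `surface_label`
#' (0 = volume, 1 = endo, 2 = epi, 3 = base) so that the labels survive a
#' round trip.  The apex region is stored as the point-data mask
#' `apex_region`.
#'
#' @param mesh a [tet_mesh()].
#' @param path output file path (.vtu).
#' @param point_data named list of per-node scalars (length n) or vectors
#'   (n x 3) written as PointData arrays.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list()) {
  n <- nrow(mesh$nodes)
  labs <- c(endo = 1L, epi = 2L, base = 3L)
  tris <- do.call(rbind, mesh$surfaces[names(labs)])
  tri_lab <- rep(labs, vapply(mesh$surfaces[names(labs)], nrow, 0L))
  m_tet <- nrow(mesh$tets)
  m_tri <- nrow(tris)
  pd <- point_data
  pd$apex_region <- as.integer(seq_len(n) %in% mesh$apex_region)
  for (nm in names(mesh$point_data)) {
    if (!nm %in% names(pd)) pd[[nm]] <- mesh$point_data[[nm]]
  }

  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">',
            n, m_tet + m_tri))
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$nodes, 1L, function(r) paste(fmt_num(r), collapse = " ")), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$tets - 1L, 1L, paste, collapse = " "), con)
  if (m_tri > 0L) writeLines(apply(tris - 1L, 1L, paste, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int64" Name="offsets" format="ascii">')
  offs <- cumsum(c(rep(4L, m_tet), rep(3L, m_tri)))
  writeLines(paste(offs, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(c(rep(10L, m_tet), rep(5L, m_tri)), collapse = " "), con)
  w('        </DataArray>')
  w('      </Cells>')
  w('      <CellData>')
  w('        <DataArray type="Int32" Name="surface_label" format="ascii">')
  writeLines(paste(c(rep(0L, m_tet), tri_lab), collapse = " "), con)
  w('        </DataArray>')
  w('      </CellData>')
  w('      <PointData>')
  for (nm in names(pd)) {
    v <- pd[[nm]]
    if (is.null(dim(v))) {
      w(sprintf('        <DataArray type="Float64" Name="%s" format="ascii">', nm))
      writeLines(paste(fmt_num(as.numeric(v)), collapse = " "), con)
    } else {
      w(sprintf(paste0('        <DataArray type="Float64" Name="%s" ',
                       'NumberOfComponents="%d" format="ascii">'), nm, ncol(v)))
      writeLines(apply(v, 1L, function(r) paste(fmt_num(r), collapse = " ")), con)
    }
    w('        </DataArray>')
  }
  w('      </PointData>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Read an ASCII VTU mesh written by [write_vtu()]
#'
#' @param path input file path.
#' @return a [tet_mesh()]; PointData arrays are returned in `point_data`.
#' @export
read_vtu <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("reading VTU requires the 'xml2' package")
  }
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "VTKFile") {
    stop("unsupported format: expected a VTU (VTKFile) document; ",
         "supported formats: ASCII .vtu")
  }
  piece <- xml2::xml_find_first(doc, ".//Piece")
  num <- function(node) scan(text = xml2::xml_text(node), quiet = TRUE)
  pts <- num(xml2::xml_find_first(piece, ".//Points/DataArray"))
  nodes <- matrix(pts, ncol = 3L, byrow = TRUE)
  cells <- xml2::xml_find_all(piece, ".//Cells/DataArray")
  names(cells) <- xml2::xml_attr(cells, "Name")
  conn <- as.integer(num(cells[["connectivity"]])) + 1L
  offs <- as.integer(num(cells[["offsets"]]))
  types <- as.integer(num(cells[["types"]]))
  starts <- c(1L, utils::head(offs, -1L) + 1L)
  lab_arr <- xml2::xml_find_first(
    piece, ".//CellData/DataArray[@Name='surface_label']")
  cell_lab <- if (!inherits(lab_arr, "xml_missing")) {
    as.integer(num(lab_arr))
  } else rep(0L, length(types))
  tets <- do.call(rbind, lapply(which(types == 10L), function(i) {
    conn[starts[i]:(starts[i] + 3L)]
  }))
  tri_of <- function(lab) {
    ix <- which(types == 5L & cell_lab == lab)
    if (length(ix) == 0L) return(matrix(integer(), 0L, 3L))
    do.call(rbind, lapply(ix, function(i) conn[starts[i]:(starts[i] + 2L)]))
  }
  surfaces <- list(endo = tri_of(1L), epi = tri_of(2L), base = tri_of(3L))
  pd_nodes <- xml2::xml_find_all(piece, ".//PointData/DataArray")
  point_data <- list()
  for (nd in pd_nodes) {
    nm <- xml2::xml_attr(nd, "Name")
    nc <- xml2::xml_attr(nd, "NumberOfComponents")
    v <- num(nd)
    point_data[[nm]] <- if (is.na(nc)) v else matrix(v, ncol = as.integer(nc),
                                                    byrow = TRUE)
  }
  apex <- which(point_data$apex_region > 0)
  point_data$apex_region <- NULL
  tet_mesh(nodes, tets, surfaces, apex, point_data = point_data)
}

#' Write a sparse cDTI dataset as a JSON + CSV pair
#'
#' The CSV has one row per voxel sample with the documented schema
#' `slice_id, x, y, z, t, c, l, Dxx, Dxy, Dxz, Dyy, Dyz, Dzz` (plus the
#' local frame axes `et?`/`el?` so the shape-adapted frames round-trip); the
#' JSON side-car carries slice positions, thickness, and provenance.
#'
#' @param dataset a `sparse_cdti`.
#' @param path base path; `.json` and `.csv` suffixes are appended.
#' @param provenance optional named list stored in the JSON header.
#' @return character vector of the two file paths, invisibly.
#' @export
write_cdti_dataset <- function(dataset, path, provenance = list()) {
  csv_path <- paste0(path, ".csv")
  json_path <- paste0(path, ".json")
  rows <- lapply(seq_along(dataset$slices), function(si) {
    sl <- dataset$slices[[si]]
    cbind(data.frame(slice_id = si), sl$samples,
          as.data.frame(sl$tensors),
          data.frame(etx = sl$frames$e_t[, 1L], ety = sl$frames$e_t[, 2L],
                     etz = sl$frames$e_t[, 3L],
                     elx = sl$frames$e_l[, 1L], ely = sl$frames$e_l[, 2L],
                     elz = sl$frames$e_l[, 3L]))
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, csv_path, row.names = FALSE)
  meta <- list(
    format = "cardiofiber-sparse-cdti-v1",
    n_slices = length(dataset$slices),
    slice_z = vapply(dataset$slices, `[[`, 0, "z"),
    thickness = dataset$meta$thickness,
    in_plane_spacing = dataset$meta$in_plane_spacing,
    csv = basename(csv_path),
    provenance = provenance)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(json_path, csv_path))
}

#' Read a sparse cDTI dataset written by [write_cdti_dataset()]
#'
#' @param path the `.json` side-car path (or the base path without suffix).
#' @return a `sparse_cdti`.
#' @export
read_cdti_dataset <- function(path) {
  json_path <- if (grepl("\\.json$", path)) path else paste0(path, ".json")
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  csv_path <- file.path(dirname(json_path), meta$csv)
  tab <- utils::read.csv(csv_path)
  need <- c("slice_id", "x", "y", "z", "t", "c", "l",
            "Dxx", "Dxy", "Dxz", "Dyy", "Dyz", "Dzz")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("dataset CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  slices <- lapply(sort(unique(tab$slice_id)), function(si) {
    rows <- tab[tab$slice_id == si, , drop = FALSE]
    e_t <- as.matrix(rows[, c("etx", "ety", "etz")])
    e_l <- as.matrix(rows[, c("elx", "ely", "elz")])
    fr <- orthonormal_frames(e_t, e_l)
    list(z = rows$z[1L], thickness = meta$thickness,
         samples = rows[, c("x", "y", "z", "t", "c", "l")],
         tensors = as.matrix(rows[, c("Dxx", "Dxy", "Dxz", "Dyy", "Dyz", "Dzz")]),
         frames = fr)
  })
  structure(list(slices = slices,
                 meta = list(n_slices = length(slices),
                             thickness = meta$thickness,
                             in_plane_spacing = meta$in_plane_spacing)),
            class = "sparse_cdti")
}

## configuration schema: known keys and their defaults (printed parameter
## values); nested sections validated recursively
config_defaults <- function() {
  list(
    mesh = list(endo_radii = c(20, 20, 45), epi_radii = c(30, 30, 55),
                truncation_height = 10, edge_length = 3, apex_diameter = 2),
    truth = list(helix_profile = c(60, -60), transverse_profile = c(0, 0),
                 perturbation_sigma = 0, perturbation_corr_length = 10),
    acquisition = list(bvals = c(100, 200, 450), ndirs = c(3, 3, 12),
                       S0 = 1, snr = 20, n_averages = 8,
                       noise_model = "rician"),
    slices = list(n_slices = 9, thickness = 8, in_plane_spacing = 2),
    hfc = list(h_t = 0.4, h_c = 0.05, h_l = 0.2, optimize = FALSE),
    pgd = list(n_modes = 6, n_svd = 6, grid_t = 14, grid_c = 24, grid_l = 10),
    pod = list(n_modes = 8, grid_t = 20, grid_c = 200, grid_l = 120),
    material = list(a_iso = 0.0943, b_iso = 5.874, a_f = 0.311, b_f = 11.271,
                    a_s = 0.0431, b_s = 9.772, a_fs = 0.0254, b_fs = 2.405,
                    A = 1, D = 0.1, T_max = 0.1, Ca0 = 4.35, Ca0_max = 4.35,
                    B = 4750, l0 = 0.75, l_r = 1.835, t0 = 150,
                    m = 300, b = -0.38, n = 0.7))
}

#' Load and validate a run configuration
#'
#' JSON (or YAML, when the `yaml` package is available) configuration with
#' schema validation: unknown keys raise an error naming the key path, and
#' all omitted keys receive the package defaults (the printed model
#' parameter values).  The returned object carries a provenance block
#' (source file, md5, seed) echoed into every output.
#'
#' @param path configuration file (`.json`, `.yaml`, `.yml`), or NULL for
#'   pure defaults.
#' @param seed integer seed recorded in the provenance block.
#' @return named list of validated settings with attribute `provenance`.
#' @export
load_config <- function(path = NULL, seed = NULL) {
  defaults <- config_defaults()
  user <- list()
  if (!is.null(path)) {
    if (grepl("\\.ya?ml$", path)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("YAML configuration requires the 'yaml' package; use JSON")
      }
      user <- yaml::read_yaml(path)
    } else {
      user <- jsonlite::read_json(path, simplifyVector = TRUE)
    }
  }
  merge_checked <- function(def, usr, prefix = "") {
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown) > 0L) {
      stop("unknown configuration key: ", prefix, unknown[1L])
    }
    for (nm in names(usr)) {
      if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
        if (!is.list(usr[[nm]])) {
          stop("configuration key ", prefix, nm, " must be a section")
        }
        def[[nm]] <- merge_checked(def[[nm]], usr[[nm]],
                                   paste0(prefix, nm, "."))
      } else {
        v <- usr[[nm]]
        if (is.character(def[[nm]]) != is.character(v)) {
          stop("type mismatch for configuration key ", prefix, nm)
        }
        def[[nm]] <- v
      }
    }
    def
  }
  cfg <- merge_checked(defaults, user)
  if (length(cfg$acquisition$bvals) != length(cfg$acquisition$ndirs)) {
    stop("acquisition.bvals and acquisition.ndirs must have equal length")
  }
  attr(cfg, "provenance") <- list(
    source = if (is.null(path)) "defaults" else normalizePath(path),
    md5 = if (is.null(path)) NA_character_ else unname(tools::md5sum(path)),
    seed = seed,
    package = tryCatch(as.character(utils::packageVersion("cardiofiber")),
                       error = function(e) NA_character_),
    r_version = R.version.string)
  cfg
}
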