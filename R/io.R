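#' Read and write wire paths as CSV
#'
#' One row per segment endpoint pair is impractical for polylines, so the
#' CSV layout is one row per node (`x,y,z`) plus the columns `seg_a`,
#' `seg_b`, `current` holding the segment table (padded with `NA` when
#' there are fewer segments than nodes, and vice versa).
#'
#' @param path A [wire_path()].
#' @param file File path.
#' @return `read_wirepath_csv` returns a [wire_path()];
#'   `write_wirepath_csv` returns `file` invisibly.
#' @export
write_wirepath_csv <- function(path, file) {
  stopifnot(inherits(path, "wire_path"))
  n <- max(nrow(path$nodes), nrow(path$segments))
  pad <- function(v) c(v, rep(NA, n - length(v)))
  df <- data.frame(x = pad(path$nodes[, 1]), y = pad(path$nodes[, 2]),
                   z = pad(path$nodes[, 3]),
                   seg_a = pad(path$segments[, 1]), seg_b = pad(path$segments[, 2]),
                   current = pad(path$segment_current))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_wirepath_csv
#' @export
read_wirepath_csv <- function(file) {
  df <- read.csv(file)
  nodes <- as.matrix(df[!is.na(df$x), c("x", "y", "z")])
  segs <- as.matrix(df[!is.na(df$seg_a), c("seg_a", "seg_b")])
  wire_path(nodes, segs, df$current[!is.na(df$current)])
}

#' Write a wire path as a legacy VTK polyline
#'
#' ASCII legacy VTK `POLYDATA` with one `LINES` entry per segment and the
#' signed segment current attached as `CELL_DATA`.
#'
#' @param path A [wire_path()].
#' @param file Output file (conventionally `.vtk`).
#' @return `file`, invisibly.
#' @export
write_wirepath_vtk <- function(path, file) {
  stopifnot(inherits(path, "wire_path"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "wire path", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(path$nodes))), con)
  writeLines(apply(path$nodes, 1, paste, collapse = " "), con)
  ns <- nrow(path$segments)
  writeLines(sprintf("LINES %d %d", ns, 3L * ns), con)
  writeLines(sprintf("2 %d %d", path$segments[, 1] - 1L, path$segments[, 2] - 1L), con)
  writeLines(c(sprintf("CELL_DATA %d", ns), "SCALARS current double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(format(path$segment_current, digits = 17), con)
  invisible(file)
}

#' Write and read tetrahedral meshes as legacy VTK unstructured grids
#'
#' ASCII legacy VTK `UNSTRUCTURED_GRID` of tetrahedra (cell type 10) with
#' the tissue label written as integer `CELL_DATA` (`tissue` array; the
#' label dictionary is stored in a comment-free sidecar order: levels are
#' written alphabetically). The reader restores labels through the same
#' alphabetical dictionary.
#'
#' @param mesh A [tetra_mesh()].
#' @param file File path (conventionally `.vtk`).
#' @param conductivity Conductivity table used by the reader.
#' @return `write_mesh_vtk` returns `file` invisibly; `read_mesh_vtk`
#'   returns a [tetra_mesh()].
#' @export
write_mesh_vtk <- function(mesh, file) {
  stopifnot(inherits(mesh, "tetra_mesh"))
  con <- file(file, "w")
  on.exit(close(con))
  lev <- sort(unique(mesh$tissue_label))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("tetra mesh | labels:", paste(lev, collapse = " ")),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(mesh$nodes))), con)
  writeLines(apply(mesh$nodes, 1, paste, collapse = " "), con)
  nt <- nrow(mesh$tets)
  writeLines(sprintf("CELLS %d %d", nt, 5L * nt), con)
  writeLines(paste("4", mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                   mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(rep("10", nt), con)
  writeLines(c(sprintf("CELL_DATA %d", nt), "SCALARS tissue int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(mesh$tissue_label, lev)), con)
  invisible(file)
}

#' @rdname write_mesh_vtk
#' @export
read_mesh_vtk <- function(file, conductivity = tissue_conductivities()) {
  ln <- readLines(file)
  lev <- strsplit(sub(".*labels: ", "", ln[2]), " ")[[1]]
  ip <- grep("^POINTS", ln)[1]
  np <- as.integer(strsplit(ln[ip], " ")[[1]][2])
  nodes <- matrix(scan(text = ln[(ip + 1):(ip + np)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", ln)[1]
  nt <- as.integer(strsplit(ln[ic], " ")[[1]][2])
  cells <- matrix(scan(text = ln[(ic + 1):(ic + nt)], quiet = TRUE),
                  ncol = 5, byrow = TRUE)
  il <- grep("^LOOKUP_TABLE", ln)[1]
  labs <- as.integer(ln[(il + 1):(il + nt)])
  tetra_mesh(nodes, cells[, 2:5] + 1L, lev[labs], conductivity)
}

#' Write and read tetrahedral meshes in Gmsh 2.2 ASCII format
#'
#' Minimal Gmsh `$MeshFormat 2.2` I/O: tetrahedra (element type 4) with the
#' physical tag carrying the tissue label index; the label dictionary is
#' stored in `$PhysicalNames`.
#'
#' @param mesh A [tetra_mesh()].
#' @param file File path (conventionally `.msh`).
#' @param conductivity Conductivity table used by the reader.
#' @return `write_mesh_msh` returns `file` invisibly; `read_mesh_msh`
#'   returns a [tetra_mesh()].
#' @export
write_mesh_msh <- function(mesh, file) {
  stopifnot(inherits(mesh, "tetra_mesh"))
  con <- file(file, "w")
  on.exit(close(con))
  lev <- sort(unique(mesh$tissue_label))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$PhysicalNames", as.character(length(lev)),
               sprintf('3 %d "%s"', seq_along(lev), lev),
               "$EndPhysicalNames",
               "$Nodes", as.character(nrow(mesh$nodes))), con)
  writeLines(paste(seq_len(nrow(mesh$nodes)),
                   apply(mesh$nodes, 1, paste, collapse = " ")), con)
  writeLines(c("$EndNodes", "$Elements", as.character(nrow(mesh$tets))), con)
  tag <- match(mesh$tissue_label, lev)
  writeLines(paste(seq_len(nrow(mesh$tets)), 4L, 2L, tag, tag,
                   mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                   mesh$tets[, 4]), con)
  writeLines("$EndElements", con)
  invisible(file)
}

#' @rdname write_mesh_msh
#' @export
read_mesh_msh <- function(file, conductivity = tissue_conductivities()) {
  ln <- readLines(file)
  blk <- function(tag) {
    i <- match(paste0("$", tag), ln)
    n <- as.integer(ln[i + 1L])
    ln[(i + 2L):(i + 1L + n)]
  }
  pn <- blk("PhysicalNames")
  lev <- sub('.*"(.*)"', "\\1", pn)
  names(lev) <- vapply(strsplit(pn, " "), `[`, "", 2)
  nd <- matrix(scan(text = blk("Nodes"), quiet = TRUE), ncol = 4, byrow = TRUE)
  el <- strsplit(blk("Elements"), " +")
  el <- el[vapply(el, `[`, "", 2) == "4"]
  em <- t(vapply(el, function(x) as.integer(x[c(4, 6, 7, 8, 9)]), integer(5)))
  tetra_mesh(nd[order(nd[, 1]), 2:4], em[, 2:5], lev[as.character(em[, 1])],
             conductivity)
}

#' Write per-node or per-cell fields onto a legacy VTK mesh file
#'
#' Appends `POINT_DATA`/`CELL_DATA` vector or scalar arrays to a mesh
#' written by [write_mesh_vtk()]; used to export the solved potential and
#' E-fields next to the mesh they live on.
#'
#' @param mesh A [tetra_mesh()].
#' @param file Output `.vtk` file.
#' @param point_data Named list of per-node vectors/matrices.
#' @param cell_data Named list of per-tet vectors/matrices.
#' @return `file`, invisibly.
#' @export
write_mesh_fields_vtk <- function(mesh, file, point_data = list(),
                                  cell_data = list()) {
  write_mesh_vtk(mesh, file)
  con <- file(file, "a")
  on.exit(close(con))
  emit <- function(dat) {
    for (nm in names(dat)) {
      v <- dat[[nm]]
      if (is.null(dim(v))) {
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(format(v, digits = 17), con)
      } else {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(apply(v, 1, paste, collapse = " "), con)
      }
    }
  }
  # CELL_DATA section already open from the tissue labels
  emit(cell_data)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(mesh$nodes)), con)
    emit(point_data)
  }
  invisible(file)
}

#' Read and write field maps as NIfTI
#'
#' The Bz volume is written as a NIfTI image whose affine encodes the grid
#' spacing and origin; the validity mask goes to a second file with suffix
#' `_mask`. `read_field_map` restores both (a missing mask file means all
#' voxels valid).
#'
#' @param map A [field_map()].
#' @param file Output path (`.nii` or `.nii.gz`).
#' @return `write_field_map` returns `file` invisibly; `read_field_map`
#'   returns a [field_map()].
#' @export
write_field_map <- function(map, file) {
  stopifnot(inherits(map, "field_map"))
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(map$spacing)
  aff[1:3, 4] <- map$origin
  bz <- map$bz
  bz[!map$mask] <- NA_real_
  img <- RNifti::asNifti(bz)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, file)
  mfile <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", file)
  RNifti::writeNifti(RNifti::`sform<-`(RNifti::asNifti(array(as.integer(map$mask), map$dims)),
                                       structure(aff, code = 2L)), mfile)
  invisible(file)
}

#' @rdname write_field_map
#' @export
read_field_map <- function(file) {
  img <- RNifti::readNifti(file)
  aff <- RNifti::xform(img)
  dims <- dim(img)
  spacing <- diag(aff)[1:3]
  origin <- aff[1:3, 4]
  mfile <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", file)
  mask <- if (file.exists(mfile)) array(RNifti::readNifti(mfile) > 0, dims)
  else array(TRUE, dims)
  bz <- array(as.numeric(img), dims)
  field_map(origin, spacing, dims, bz = bz, mask = mask)
}

#' Write a metric result as a JSON record
#'
#' @param result A `metric_result` from [ec_metric()].
#' @param file Output path.
#' @param meta Named list of extra fields (coil model, orientation, ...).
#' @return `file`, invisibly.
#' @export
write_metric_json <- function(result, file, meta = list()) {
  stopifnot(inherits(result, "metric_result"))
  rec <- c(meta, list(ec = result$ec, patch_area = result$patch_area,
                      n_triangles = length(result$per_triangle)))
  jsonlite::write_json(rec, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
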