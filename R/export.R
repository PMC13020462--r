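## Readers/writers: legacy-VTK unstructured meshes with fields, ASCII STL
## surfaces, delimited results tables and planar sensitivity grids.

#' Write a mesh (with optional fields) as legacy ASCII VTK
#'
#' Unstructured-grid export readable by ParaView/VisIt/meshio.  Cell data
#' always includes the integer-coded region label; additional per-node
#' (`point_data`) and per-element (`cell_data`) scalar fields can be
#' attached (complex fields are exported as their magnitude).
#'
#' @param mesh A `tet_mesh`.
#' @param path Output file path (.vtk).
#' @param point_data,cell_data Named lists of numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  stopifnot(inherits(mesh, "tet_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("labeled tetrahedral thorax mesh")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  wl("POINTS ", n, " double")
  utils::write.table(format(mesh$nodes, digits = 12, trim = TRUE,
                            scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  wl("CELLS ", m, " ", 5 * m)
  utils::write.table(cbind(4L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  wl("CELL_TYPES ", m)
  writeLines(rep("10", m), con)

  reg_levels <- sort(unique(mesh$region))
  cell_data <- c(list(region_code = match(mesh$region, reg_levels)),
                 cell_data)
  wl("CELL_DATA ", m)
  for (nm in names(cell_data)) {
    v <- cell_data[[nm]]
    if (is.complex(v)) v <- Mod(v)
    wl("SCALARS ", nm, " double 1")
    wl("LOOKUP_TABLE default")
    writeLines(format(v, digits = 10, trim = TRUE), con)
  }
  if (length(point_data)) {
    wl("POINT_DATA ", n)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.complex(v)) v <- Mod(v)
      wl("SCALARS ", nm, " double 1")
      wl("LOOKUP_TABLE default")
      writeLines(format(v, digits = 10, trim = TRUE), con)
    }
  }
  invisible(path)
}

#' Read a labeled tetrahedral mesh from legacy ASCII VTK
#'
#' Reads an unstructured grid of tetrahedra (cell type 10) with an
#' optional `region_code`/`region` cell field, as written by
#' [write_vtk()].  The boundary is recomputed; all boundary faces are
#' labeled `outer` unless electrode disks are supplied.
#'
#' @param path VTK file.
#' @param region_labels Optional character vector decoding `region_code`.
#' @param patch_disks Optional data frame (`label`, `cx`, `cy`, `cz`,
#'   `nx`, `ny`, `nz`, `radius`): boundary faces whose centroid lies on
#'   the disk plane (normal `n`) within `radius` of the centre are
#'   labeled `electrode_<label>`.
#' @return A `tet_mesh` (without a structured locator; point location
#'   falls back to a bounding-box search).
#' @export
read_vtk_mesh <- function(path, region_labels = NULL, patch_disks = NULL) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- scan(text = lines[(ip + 1):length(lines)], n = 3 * n,
              quiet = TRUE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  m <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cl <- scan(text = lines[(ic + 1):length(lines)], n = 5 * m, quiet = TRUE)
  cl <- matrix(cl, ncol = 5, byrow = TRUE)
  if (any(cl[, 1] != 4)) stop("only tetrahedral cells are supported")
  elems <- cl[, 2:5] + 1L
  region <- rep("soft_tissue", m)
  ir <- grep("^SCALARS region_code", lines)
  if (length(ir)) {
    codes <- scan(text = lines[(ir[1] + 2):length(lines)], n = m,
                  quiet = TRUE)
    region <- if (!is.null(region_labels)) region_labels[codes]
              else paste0("region_", codes)
  }
  elems <- orient_tets(nodes, elems)
  faces <- boundary_faces(elems, n)
  patch <- rep("outer", nrow(faces))
  if (!is.null(patch_disks)) {
    fcen <- tri_centroids(nodes, faces)
    for (i in seq_len(nrow(patch_disks))) {
      nv <- c(patch_disks$nx[i], patch_disks$ny[i], patch_disks$nz[i])
      nv <- nv / sqrt(sum(nv^2))
      dx <- fcen[, 1] - patch_disks$cx[i]
      dy <- fcen[, 2] - patch_disks$cy[i]
      dz <- fcen[, 3] - patch_disks$cz[i]
      out <- dx * nv[1] + dy * nv[2] + dz * nv[3]
      inplane2 <- pmax(dx^2 + dy^2 + dz^2 - out^2, 0)
      sel <- abs(out) <= 1e-7 + 1e-4 * patch_disks$radius[i] &
        inplane2 <= patch_disks$radius[i]^2
      patch[sel] <- paste0("electrode_", patch_disks$label[i])
    }
  }
  new_tet_mesh(nodes, elems, region, faces, patch,
               refinement_level = "normal", structured = NULL)
}

#' Read an ASCII STL surface
#'
#' Minimal reader for user-supplied surface shells.  Returns the unique
#' vertices, triangle index matrix, total surface area and (for a closed,
#' consistently oriented shell) the enclosed volume by the divergence
#' theorem.
#'
#' @param path ASCII STL file.
#' @return List with `vertices`, `faces`, `area`, `volume`.
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (!length(vl)) stop("no vertices found; only ASCII STL is supported")
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  if (nrow(nums) %% 3 != 0) stop("malformed STL: vertex count not divisible by 3")
  key <- apply(round(nums, 12), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- nums[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  area <- sum(tri_areas(verts, faces))
  v1 <- verts[faces[, 1], , drop = FALSE]
  v2 <- verts[faces[, 2], , drop = FALSE]
  v3 <- verts[faces[, 3], , drop = FALSE]
  vol <- sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
               v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
               v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
  list(vertices = verts, faces = faces, area = area, volume = abs(vol))
}

#' Write a sweep results table
#'
#' Tab-separated table carrying the sweep points, configuration columns
#' and the configuration hash (identical configurations produce
#' bit-identical tables).
#'
#' @param sweep A `sweep_result` (or plain data frame).
#' @param path Output path.
#' @param config Optional `run_config` whose hash is embedded.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(sweep, path, config = NULL) {
  pts <- if (inherits(sweep, "sweep_result")) sweep$points else sweep
  if (inherits(sweep, "sweep_result")) {
    for (nm in names(sweep$meta)) {
      v <- sweep$meta[[nm]]
      if (is.atomic(v) && length(v) == 1) pts[[nm]] <- v
    }
  }
  if (!is.null(config)) pts$config_hash <- config_hash(config)
  utils::write.table(pts, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a planar sensitivity map as a delimited grid
#'
#' @param map Output of [planar_sensitivity_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_planar_map <- function(map, path) {
  utils::write.table(map$grid, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
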