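## Deterministic graded tetrahedral meshing.
##
## The torso is meshed on a structured elliptic-cylindrical lattice
## (radial fraction s, cross-section arc length u, height z) whose cells
## are split into tetrahedra by the Freudenthal 6-tet subdivision; the
## degenerate ring around the axis is meshed with 3-tet wedges.  Using the
## same index-space split in every cell makes the face diagonals agree
## between neighbours, so the mesh is conforming, and the construction
## contains no randomness at all, so meshing is bitwise deterministic.
## Refinement levels rescale the volumetric element-size budget only; the
## fine surface band around the electrode patches is held fixed so that
## refinement studies measure volumetric discretisation error.

MESH_LEVELS <- c(coarser = 2.2, coarse = 1.5, normal = 1.0, fine = 0.7)

## Target spacing field induced by refinement windows: inside a window the
## spacing is the window's h, away from it the spacing grows linearly at
## rate (ratio - 1) per unit distance, capped at h_base.  The minimum over
## windows handles overlapping windows of different fineness.
window_h_fun <- function(windows, h_base, ratio = 1.45, period = NULL) {
  g <- ratio - 1
  function(x) {
    h <- rep(h_base, length(x))
    if (!is.null(windows) && nrow(windows) > 0)
      for (i in seq_len(nrow(windows))) {
        dx <- abs(x - windows$center[i])
        if (!is.null(period)) dx <- pmin(dx %% period, period - dx %% period)
        d <- pmax(0, dx - windows$halfwidth[i])
        h <- pmin(h, windows$h[i] + d * g)
      }
    h
  }
}

## Gap spacings between two fixed anchors: march with the anticipatory
## spacing field, then rescale to fit the gap exactly.
gap_spacings <- function(a, b, hf) {
  len <- b - a
  if (len <= 1e-12) return(numeric(0))
  x <- a
  sp <- numeric(0)
  repeat {
    h <- hf(x)
    if (b - x <= 1.5 * h) { sp <- c(sp, b - x); break }
    sp <- c(sp, h)
    x <- x + h
  }
  sp * len / sum(sp)
}

## Segment structure shared by the periodic and non-periodic builders:
## window edges are fixed anchors, window interiors are meshed uniformly
## (n = round(len/h), so the in-window node pattern does not depend on
## the volumetric budget h_base), gaps are graded.
segmented_grid <- function(brk, windows, hf) {
  pts <- brk[1]
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    if (b - a <= 1e-12) next
    mid <- (a + b) / 2
    hw <- Inf
    if (!is.null(windows) && nrow(windows) > 0)
      for (j in seq_len(nrow(windows))) {
        lo <- windows$lo[j]; hi <- windows$hi[j]
        if (mid >= lo - 1e-12 && mid <= hi + 1e-12)
          hw <- min(hw, windows$h[j])
      }
    sp <- if (is.finite(hw)) {
      n <- max(1L, round((b - a) / hw))
      rep((b - a) / n, n)
    } else gap_spacings(a, b, hf)
    pts <- c(pts, a + cumsum(sp))
  }
  pts
}

## Graded 1-D grid on [0, L] with fixed uniform refinement windows.
graded_grid <- function(L, h_base, windows = NULL, ratio = 1.45) {
  if (is.null(windows) || nrow(windows) == 0) {
    n <- max(1L, ceiling(L / h_base))
    return(seq(0, L, length.out = n + 1L))
  }
  hf <- window_h_fun(windows, h_base, ratio)
  w <- data.frame(lo = pmax(0, windows$center - windows$halfwidth),
                  hi = pmin(L, windows$center + windows$halfwidth),
                  h = windows$h)
  w <- w[w$hi - w$lo > 1e-12, , drop = FALSE]
  brk <- sort(unique(c(0, L, w$lo, w$hi)))
  pts <- segmented_grid(brk, w, hf)
  pts[length(pts)] <- L
  pts[c(TRUE, diff(pts) > 1e-9)]
}

## Periodic graded grid on [0, P) (cell-boundary positions).
graded_grid_periodic <- function(P, h_base, windows = NULL, ratio = 1.45) {
  if (is.null(windows) || nrow(windows) == 0) {
    n <- max(8L, ceiling(P / h_base))
    return(seq(0, P, length.out = n + 1L)[-(n + 1L)])
  }
  hf <- window_h_fun(windows, h_base, ratio, period = P)
  ## unroll on [start, start + P) anchored at the first window edge
  start <- min(windows$center - windows$halfwidth)
  lo <- windows$center - windows$halfwidth
  hi <- windows$center + windows$halfwidth
  shift <- function(x) start + ((x - start) %% P)
  w <- data.frame(lo = shift(lo), h = windows$h)
  w$hi <- w$lo + (hi - lo)
  brk <- sort(unique(c(start, start + P,
                       pmin(w$lo, start + P), pmin(w$hi, start + P))))
  pts <- segmented_grid(brk, w, hf)
  pts <- sort(unique(round(pts[-length(pts)], 10)) %% P)
  pts[c(TRUE, diff(pts) > 1e-9)]
}

## Freudenthal 6-tet split of hex cells given the 8 corner-node id vectors
## (c000 ... c111, bit order (i, j, k)).  Returns an (6 m) x 4 matrix.
split_hexes <- function(c000, c100, c010, c110, c001, c101, c011, c111) {
  rbind(cbind(c000, c100, c110, c111),
        cbind(c000, c100, c101, c111),
        cbind(c000, c010, c110, c111),
        cbind(c000, c010, c011, c111),
        cbind(c000, c001, c101, c111),
        cbind(c000, c001, c011, c111))
}

## 3-tet split of the axis wedges (a = axis edge, b = theta_j, c = theta_j+1
## ring nodes; 0/1 = lower/upper z), conforming with split_hexes.
split_wedges <- function(a0, a1, b0, b1, c0, c1) {
  rbind(cbind(a0, b0, c0, c1),
        cbind(a0, b0, c1, b1),
        cbind(a0, b1, c1, a1))
}

## Interior sample points of each tetrahedron (the 4-point quadrature
## rule), used for partial-volume material averaging at the interfaces.
tet_sample_points <- function(nodes, elems) {
  aa <- 0.5854102; bb <- 0.1381966
  v <- lapply(1:4, function(p) nodes[elems[, p], , drop = FALSE])
  lapply(1:4, function(p) {
    s <- v[[1]] * bb + v[[2]] * bb + v[[3]] * bb + v[[4]] * bb
    s + v[[p]] * (aa - bb)
  })
}

## Classify the 4 interior sample points of every element and store them
## as integer codes (partial-volume composition).  "outside" cannot occur
## for mapped cells; airway samples keep their own code (insulating).
attach_region_samples <- function(mesh, geom) {
  levels <- c("soft_tissue", "lung_left", "lung_right", "heart", "rib",
              "fluid", "airway")
  sp <- tet_sample_points(mesh$nodes, mesh$elems)
  codes <- vapply(sp, function(p) {
    lab <- classify_points(geom, p)
    lab[lab == "outside"] <- "soft_tissue"
    match(lab, levels)
  }, integer(nrow(mesh$elems)))
  mesh$region_levels <- levels
  mesh$region_samples <- codes
  mesh
}

tet_volumes <- function(nodes, elems) {
  p1 <- nodes[elems[, 1], , drop = FALSE]
  d1 <- nodes[elems[, 2], , drop = FALSE] - p1
  d2 <- nodes[elems[, 3], , drop = FALSE] - p1
  d3 <- nodes[elems[, 4], , drop = FALSE] - p1
  (d1[, 1] * (d2[, 2] * d3[, 3] - d2[, 3] * d3[, 2]) -
     d1[, 2] * (d2[, 1] * d3[, 3] - d2[, 3] * d3[, 1]) +
     d1[, 3] * (d2[, 1] * d3[, 2] - d2[, 2] * d3[, 1])) / 6
}

orient_tets <- function(nodes, elems) {
  v <- tet_volumes(nodes, elems)
  neg <- v < 0
  if (any(neg)) {
    tmp <- elems[neg, 3]
    elems[neg, 3] <- elems[neg, 4]
    elems[neg, 4] <- tmp
  }
  elems
}

## Boundary faces: triangles that appear in exactly one tetrahedron.
boundary_faces <- function(elems, n_nodes) {
  fc <- rbind(elems[, c(1, 2, 3)], elems[, c(1, 2, 4)],
              elems[, c(1, 3, 4)], elems[, c(2, 3, 4)])
  a <- pmin(fc[, 1], fc[, 2], fc[, 3])
  c_ <- pmax(fc[, 1], fc[, 2], fc[, 3])
  b <- as.numeric(fc[, 1]) + fc[, 2] + fc[, 3] - a - c_
  key <- (a * (n_nodes + 1) + b) * (n_nodes + 1) + c_
  o <- order(key)
  ks <- key[o]
  n <- length(ks)
  dup <- c(FALSE, ks[-1] == ks[-n]) | c(ks[-1] == ks[-n], FALSE)
  fc[o[!dup], , drop = FALSE]
}

tri_centroids <- function(nodes, faces) {
  (nodes[faces[, 1], , drop = FALSE] + nodes[faces[, 2], , drop = FALSE] +
     nodes[faces[, 3], , drop = FALSE]) / 3
}

tri_areas <- function(nodes, faces) {
  u <- nodes[faces[, 2], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  v <- nodes[faces[, 3], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

new_tet_mesh <- function(nodes, elems, region, faces, face_patch,
                         refinement_level, structured) {
  m <- list(nodes = nodes, elems = elems, region = region,
            elem_vol = tet_volumes(nodes, elems),
            faces = faces, face_patch = face_patch,
            refinement_level = refinement_level,
            structured = structured)
  class(m) <- "tet_mesh"
  if (any(m$elem_vol <= 0)) {
    bad <- which(m$elem_vol <= 0)[1]
    stop("meshing failure: degenerate (sliver) element in region '",
         region[bad], "'")
  }
  m
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("Labeled tetrahedral mesh ('%s'): %d nodes, %d tets, %d boundary tris\n",
              x$refinement_level, nrow(x$nodes), nrow(x$elems), nrow(x$faces)))
  v <- region_volumes(x)
  for (nm in names(v)) cat(sprintf("  %-12s %8.3f L\n", nm, 1e3 * v[[nm]]))
  invisible(x)
}

#' Generate a labeled tetrahedral mesh of the thorax
#'
#' Meshes the synthetic thorax on a graded structured lattice.  Cells are
#' concentrated radially towards the surface and, when an electrode array
#' is present, in bands around the electrode columns and rows so that the
#' 1 cm patches are resolved by ~2 mm surface elements at every refinement
#' level.  Elements are labeled by classifying their centroids with
#' [classify_points()]; airway-lumen elements are removed from the
#' conductive domain and the triangles exposed by their removal form the
#' insulating `airway_wall` patch.
#'
#' The refinement levels scale the volumetric element-size budget by
#' 2.2 : 1.5 : 1.0 : 0.7 (coarser : coarse : normal : fine).
#'
#' @param geom A `thorax_geometry` (with electrodes placed, normally).
#' @param refinement_level One of `"coarser"`, `"coarse"`, `"normal"`,
#'   `"fine"`.
#' @param h_normal Volumetric target element size at the `normal` level (m).
#' @param h_band Surface element size inside the electrode bands (m),
#'   identical at all levels.
#' @param h_surface Radial spacing of the first layer under the surface (m).
#' @param z_refine Optional extra vertical refinement windows (data frame
#'   with `center`, `halfwidth`, `h`), e.g. across the band a fluid front
#'   traverses during a volume sweep; merged with the electrode-row bands.
#' @return A `tet_mesh`.
#' @export
generate_mesh <- function(geom,
                          refinement_level = c("normal", "coarser",
                                               "coarse", "fine"),
                          h_normal = 0.014, h_band = 0.002,
                          h_surface = 0.0025, z_refine = NULL) {
  refinement_level <- match.arg(refinement_level)
  stopifnot(inherits(geom, "thorax_geometry"))
  h_base <- h_normal * MESH_LEVELS[[refinement_level]]
  a <- geom$torso$a; b <- geom$torso$b; H <- geom$torso$h
  P <- geom$arc$perimeter

  uw <- zw <- NULL
  if (!is.null(geom$electrodes)) {
    el <- geom$electrodes
    r <- el$diameter / 2
    ucs <- unique(vapply(el$centers_uz, `[`, 0, 1))
    zcs <- unique(vapply(el$centers_uz, `[`, 0, 2))
    ## nested fixed windows: the whole near-electrode discretisation is
    ## identical at every refinement level, so refinement only changes
    ## the far field
    hws <- c(r + 2 * h_band, r + 0.013, r + 0.025)
    hns <- c(h_band, 0.0035, 0.0055)
    uw <- data.frame(center = rep(ucs, each = 3),
                     halfwidth = rep(hws, length(ucs)),
                     h = rep(hns, length(ucs)))
    zw <- data.frame(center = rep(zcs, each = 3),
                     halfwidth = rep(hws, length(zcs)),
                     h = rep(hns, length(zcs)))
  }
  if (!is.null(z_refine))
    zw <- if (is.null(zw)) z_refine
          else rbind(zw, z_refine[, c("center", "halfwidth", "h")])
  u_grid <- graded_grid_periodic(P, h_base, uw)
  z_grid <- graded_grid(H, h_base, zw)

  ## radial grid: fine under the surface, growing inwards; the stack down
  ## to ~35 mm depth is capped at a fixed 11 mm so it is identical at all
  ## refinement levels (the far interior follows the level budget)
  R_ref <- sqrt(a * b)
  d <- 0; hs <- h_surface
  repeat {
    depth <- d[length(d)]
    cap <- if (depth < 0.035) 0.011 else h_base
    nxt <- depth + min(hs, cap)
    if (nxt >= R_ref - 0.6 * max(h_base, 0.011)) break
    d <- c(d, nxt)
    hs <- min(hs * 1.45, cap)
  }
  s_grid <- sort(c(0, 1 - d / R_ref))

  ns <- length(s_grid); nu <- length(u_grid); nz <- length(z_grid)
  t_grid <- geom$arc$t_of_u(u_grid)

  ## nodes: axis nodes (one per z), then rings for s_grid[2..ns]
  n_ring <- (ns - 1L) * nu * nz
  nodes <- matrix(0, nz + n_ring, 3)
  nodes[seq_len(nz), 3] <- z_grid
  ring_id <- function(i, j, k)  # i: ring layer 1..ns-1, j wraps
    nz + (i - 1L) + (ns - 1L) * (((j - 1L) %% nu) + nu * (k - 1L))  + 1L
  ii <- rep(seq_len(ns - 1L), times = nu * nz)
  jj <- rep(rep(seq_len(nu), each = ns - 1L), times = nz)
  kk <- rep(seq_len(nz), each = (ns - 1L) * nu)
  s_v <- s_grid[ii + 1L]
  nodes[nz + seq_len(n_ring), ] <- cbind(s_v * a * cos(t_grid[jj]),
                                         s_v * b * sin(t_grid[jj]),
                                         z_grid[kk])

  ## wedge ring around the axis
  cj <- rep(seq_len(nu), times = nz - 1L)
  ck <- rep(seq_len(nz - 1L), each = nu)
  wedges <- split_wedges(a0 = cj * 0 + ck,          # axis node ids = k
                         a1 = cj * 0 + ck + 1L,
                         b0 = ring_id(1L, cj, ck),
                         b1 = ring_id(1L, cj, ck + 1L),
                         c0 = ring_id(1L, cj + 1L, ck),
                         c1 = ring_id(1L, cj + 1L, ck + 1L))
  wcell <- rep(1L + ((cj - 1L) + nu * (ck - 1L)) * (ns - 1L), 3L)

  ## hex cells between rings
  hi <- rep(seq_len(ns - 2L), times = nu * (nz - 1L))
  hj <- rep(rep(seq_len(nu), each = ns - 2L), times = nz - 1L)
  hk <- rep(seq_len(nz - 1L), each = (ns - 2L) * nu)
  hexes <- split_hexes(c000 = ring_id(hi,      hj,      hk),
                       c100 = ring_id(hi + 1L, hj,      hk),
                       c010 = ring_id(hi,      hj + 1L, hk),
                       c110 = ring_id(hi + 1L, hj + 1L, hk),
                       c001 = ring_id(hi,      hj,      hk + 1L),
                       c101 = ring_id(hi + 1L, hj,      hk + 1L),
                       c011 = ring_id(hi,      hj + 1L, hk + 1L),
                       c111 = ring_id(hi + 1L, hj + 1L, hk + 1L))
  hcell <- rep((hi + 1L) + ((hj - 1L) + nu * (hk - 1L)) * (ns - 1L), 6L)

  elems <- rbind(wedges, hexes)
  cell_of_elem <- c(wcell, hcell)
  elems <- orient_tets(nodes, elems)

  cen <- (nodes[elems[, 1], ] + nodes[elems[, 2], ] +
            nodes[elems[, 3], ] + nodes[elems[, 4], ]) / 4
  region <- classify_points(geom, cen)
  region[region == "outside"] <- "soft_tissue"  # mapped cells are inside

  keep <- region != "airway"
  elems <- elems[keep, , drop = FALSE]
  region <- region[keep]
  cell_of_elem <- cell_of_elem[keep]

  ## drop nodes orphaned by airway-lumen removal
  used <- sort(unique(as.vector(elems)))
  if (length(used) < nrow(nodes)) {
    remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
    elems <- matrix(remap[elems], ncol = 4)
    nodes <- nodes[used, , drop = FALSE]
  }

  faces <- boundary_faces(elems, nrow(nodes))
  fcen <- tri_centroids(nodes, faces)
  ## a face is on the lateral surface iff all three nodes sit exactly on
  ## the ellipse (s = 1); centroids of such faces sag slightly inside
  rho_n <- sqrt((nodes[, 1] / a)^2 + (nodes[, 2] / b)^2)
  on_surf <- rho_n > 1 - 1e-8
  lateral <- on_surf[faces[, 1]] & on_surf[faces[, 2]] & on_surf[faces[, 3]]
  on_cap <- nodes[, 3] < 1e-9 | nodes[, 3] > H - 1e-9
  caps <- on_cap[faces[, 1]] & on_cap[faces[, 2]] & on_cap[faces[, 3]]
  patch <- rep("airway_wall", nrow(faces))
  patch[caps] <- "outer"
  patch[lateral & !caps] <- "outer"

  if (!is.null(geom$electrodes)) {
    el <- geom$electrodes
    r <- el$diameter / 2
    t_f <- atan2(fcen[, 2] / b, fcen[, 1] / a) %% (2 * pi)
    u_f <- geom$arc$u_of_t(t_f)
    for (lb in names(el$centers_uz)) {
      cz <- el$centers_uz[[lb]]
      du <- arc_diff(u_f, cz[1] %% P, P)
      dz <- fcen[, 3] - cz[2]
      sel <- lateral & !caps & (du^2 + dz^2 <= r^2)
      patch[sel] <- paste0("electrode_", lb)
    }
  }

  mesh <- new_tet_mesh(nodes, elems, region, faces, patch, refinement_level,
               structured = list(type = "torso", a = a, b = b,
                                 u_of_t = geom$arc$u_of_t,
                                 perimeter = P,
                                 s_grid = s_grid, u_grid = u_grid,
                                 z_grid = z_grid,
                                 cell_of_elem = cell_of_elem,
                                 cell_dims = c(ns - 1L, nu, nz)))
  attach_region_samples(mesh, geom)
}

#' Structured box mesh with surface electrode disks
#'
#' Mesh of the box `[0,lx] x [0,ly] x [0,lz]` used for analytic validation
#' (half-space point-electrode formula, homogeneous-bar resistance).
#' Electrode disks live on the top face `z = lz`; alternatively
#' `end_electrodes = TRUE` turns the whole faces `z = lz` / `z = 0` into
#' patches `electrode_A` / `electrode_B`.
#'
#' @param lx,ly,lz Box dimensions (m).
#' @param h_base Volumetric target element size (m).
#' @param electrodes `NULL` or a data frame with columns `label`, `cx`,
#'   `cy`, `radius` describing disks on the top face.
#' @param h_band In-plane element size near the disks (m).
#' @param h_top Vertical spacing of the first element layer under the top
#'   face (m).
#' @param end_electrodes Use the entire top/bottom faces as electrodes A/B.
#' @param region_label Region label given to every element.
#' @return A `tet_mesh`.
#' @export
box_mesh <- function(lx, ly, lz, h_base, electrodes = NULL,
                     h_band = 0.002, h_top = NULL, end_electrodes = FALSE,
                     region_label = "soft_tissue") {
  xw <- yw <- NULL
  if (!is.null(electrodes)) {
    hw <- electrodes$radius + 2 * h_band
    xw <- data.frame(center = electrodes$cx, halfwidth = hw, h = h_band)
    yw <- data.frame(center = electrodes$cy, halfwidth = hw, h = h_band)
  }
  x_grid <- graded_grid(lx, h_base, xw)
  y_grid <- graded_grid(ly, h_base, yw)
  if (is.null(h_top)) h_top <- h_base
  ## vertical grid graded from h_top at the top face to h_base at depth
  d <- 0; hs <- h_top
  repeat {
    nxt <- d[length(d)] + hs
    if (nxt >= lz - 0.6 * h_base) break
    d <- c(d, nxt)
    hs <- min(hs * 1.45, h_base)
  }
  z_grid <- sort(c(0, lz - d))

  nx <- length(x_grid); ny <- length(y_grid); nzg <- length(z_grid)
  nid <- function(i, j, k) i + nx * ((j - 1L) + ny * (k - 1L))
  nodes <- cbind(rep(x_grid, times = ny * nzg),
                 rep(rep(y_grid, each = nx), times = nzg),
                 rep(z_grid, each = nx * ny))
  ci <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nzg - 1L))
  cj <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nzg - 1L)
  ck <- rep(seq_len(nzg - 1L), each = (nx - 1L) * (ny - 1L))
  elems <- split_hexes(c000 = nid(ci,      cj,      ck),
                       c100 = nid(ci + 1L, cj,      ck),
                       c010 = nid(ci,      cj + 1L, ck),
                       c110 = nid(ci + 1L, cj + 1L, ck),
                       c001 = nid(ci,      cj,      ck + 1L),
                       c101 = nid(ci + 1L, cj,      ck + 1L),
                       c011 = nid(ci,      cj + 1L, ck + 1L),
                       c111 = nid(ci + 1L, cj + 1L, ck + 1L))
  cell_of_elem <- rep(ci + (nx - 1L) * ((cj - 1L) + (ny - 1L) * (ck - 1L)), 6L)
  elems <- orient_tets(nodes, elems)
  region <- rep(region_label, nrow(elems))

  faces <- boundary_faces(elems, nrow(nodes))
  fcen <- tri_centroids(nodes, faces)
  patch <- rep("outer", nrow(faces))
  top <- fcen[, 3] > lz - 1e-9
  bottom <- fcen[, 3] < 1e-9
  if (end_electrodes) {
    patch[top] <- "electrode_A"
    patch[bottom] <- "electrode_B"
  } else if (!is.null(electrodes)) {
    for (i in seq_len(nrow(electrodes))) {
      sel <- top & ((fcen[, 1] - electrodes$cx[i])^2 +
                      (fcen[, 2] - electrodes$cy[i])^2 <=
                      electrodes$radius[i]^2)
      patch[sel] <- paste0("electrode_", electrodes$label[i])
    }
  }
  new_tet_mesh(nodes, elems, region, faces, patch,
               refinement_level = "normal",
               structured = list(type = "box",
                                 x_grid = x_grid, y_grid = y_grid,
                                 z_grid = z_grid,
                                 cell_of_elem = cell_of_elem,
                                 cell_dims = c(nx - 1L, ny - 1L, nzg - 1L)))
}

#' Per-region volumes of a labeled mesh
#'
#' Exact sums of the (positive) element volumes per region label.  All six
#' standard thorax labels are always reported (0 when absent).
#'
#' @param mesh A `tet_mesh`.
#' @return Named numeric vector of volumes (m^3).
#' @export
region_volumes <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  std <- c("soft_tissue", "lung_left", "lung_right", "heart", "rib", "fluid")
  v <- tapply(mesh$elem_vol, mesh$region, sum)
  out <- stats::setNames(rep(0, length(union(std, names(v)))),
                         union(std, names(v)))
  out[names(v)] <- as.numeric(v)
  out
}

#' @rdname region_volumes
#' @param labels Region label or set of labels (must exist in the standard
#'   label set or in the mesh).
#' @export
region_volume <- function(mesh, labels) {
  v <- region_volumes(mesh)
  unknown <- setdiff(labels, names(v))
  if (length(unknown))
    stop("unknown region label(s): ", paste(unknown, collapse = ", "))
  sum(v[labels])
}

## -- electrode patch helpers ------------------------------------------------

patch_face_ids <- function(mesh, patch) which(mesh$face_patch == patch)

patch_area <- function(mesh, patch) {
  ids <- patch_face_ids(mesh, patch)
  if (!length(ids)) return(0)
  sum(tri_areas(mesh$nodes, mesh$faces[ids, , drop = FALSE]))
}

patch_nodes <- function(mesh, patch) {
  ids <- patch_face_ids(mesh, patch)
  sort(unique(as.vector(mesh$faces[ids, , drop = FALSE])))
}

## Is a boundary patch edge-connected?
patch_connected <- function(mesh, patch) {
  ids <- patch_face_ids(mesh, patch)
  if (length(ids) <= 1) return(length(ids) == 1)
  f <- mesh$faces[ids, , drop = FALSE]
  n <- nrow(f)
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  fid <- rep(seq_len(n), 3L)
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  sp <- split(fid, ek)
  for (grp in sp) if (length(grp) > 1) {
    r <- find(grp[1])
    for (g in grp[-1]) { r2 <- find(g); if (r2 != r) comp[r2] <- r }
  }
  length(unique(vapply(seq_len(n), find, 0L))) == 1
}

## -- point location ---------------------------------------------------------

## Map physical points to structured cell indices (torso or box).
structured_cell_coords <- function(mesh, pts) {
  st <- mesh$structured
  if (st$type == "torso") {
    s <- sqrt((pts[, 1] / st$a)^2 + (pts[, 2] / st$b)^2)
    t <- atan2(pts[, 2] / st$b, pts[, 1] / st$a) %% (2 * pi)
    u <- st$u_of_t(t)
    i <- findInterval(s, st$s_grid, all.inside = TRUE)
    j <- findInterval(u, st$u_grid)  # 0 handled below; periodic
    j[j == 0L] <- length(st$u_grid)
    k <- findInterval(pts[, 3], st$z_grid, all.inside = TRUE)
    list(i = i, j = j, k = k, dims = st$cell_dims, periodic_j = TRUE,
         inside = s <= 1 + 1e-9 & pts[, 3] >= min(st$z_grid) - 1e-9 &
           pts[, 3] <= max(st$z_grid) + 1e-9)
  } else {
    i <- findInterval(pts[, 1], st$x_grid, all.inside = TRUE)
    j <- findInterval(pts[, 2], st$y_grid, all.inside = TRUE)
    k <- findInterval(pts[, 3], st$z_grid, all.inside = TRUE)
    ins <- pts[, 1] >= st$x_grid[1] - 1e-9 &
      pts[, 1] <= st$x_grid[length(st$x_grid)] + 1e-9 &
      pts[, 2] >= st$y_grid[1] - 1e-9 &
      pts[, 2] <= st$y_grid[length(st$y_grid)] + 1e-9 &
      pts[, 3] >= st$z_grid[1] - 1e-9 &
      pts[, 3] <= st$z_grid[length(st$z_grid)] + 1e-9
    list(i = i, j = j, k = k, dims = st$cell_dims, periodic_j = FALSE,
         inside = ins)
  }
}

## CSR-style index from cell id to element ids.
cell_index <- function(mesh) {
  nc <- prod(mesh$structured$cell_dims)
  o <- order(mesh$structured$cell_of_elem)
  ptr <- c(0L, cumsum(tabulate(mesh$structured$cell_of_elem, nbins = nc)))
  list(order = o, ptr = ptr, ncell = nc)
}

point_in_tet <- function(nodes, tet, p, tol = 1e-9) {
  A <- t(nodes[tet[2:4], , drop = FALSE]) - nodes[tet[1], ]
  rhs <- p - nodes[tet[1], ]
  lam <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(lam)) return(FALSE)
  all(lam >= -tol) && sum(lam) <= 1 + tol
}

#' Locate the mesh element containing each point
#'
#' Uses the structured lattice to find the candidate cell, then tests the
#' cell's tetrahedra (and, as a fallback, the neighbouring cells').
#' Returns `NA` for points outside the conductive domain.
#'
#' @param mesh A `tet_mesh`.
#' @param pts n x 3 matrix of points (m).
#' @return Integer vector of element ids (NA outside).
#' @export
locate_elements <- function(mesh, pts) {
  pts <- as.matrix(pts)
  cc <- structured_cell_coords(mesh, pts)
  ci <- cell_index(mesh)
  dims <- cc$dims
  out <- rep(NA_integer_, nrow(pts))
  cand_cells <- function(i, j, k, ring) {
    di <- seq(max(1L, i - ring), min(dims[1], i + ring))
    dj <- (seq(j - ring, j + ring) - 1L)
    dj <- if (cc$periodic_j) (dj %% dims[2]) + 1L
          else dj[dj >= 0 & dj < dims[2]] + 1L
    dk <- seq(max(1L, k - ring), min(dims[3], k + ring))
    g <- expand.grid(di, unique(dj), dk)
    g[, 1] + dims[1] * ((g[, 2] - 1L) + dims[2] * (g[, 3] - 1L))
  }
  for (n in seq_len(nrow(pts))) {
    if (!cc$inside[n]) next
    p <- pts[n, ]
    for (ring in 0:1) {
      cells <- cand_cells(cc$i[n], cc$j[n], cc$k[n], ring)
      hit <- NA_integer_
      for (cl in cells) {
        if (cl < 1 || cl > ci$ncell) next
        rng <- seq_len(ci$ptr[cl + 1L] - ci$ptr[cl]) + ci$ptr[cl]
        for (e in ci$order[rng]) {
          if (point_in_tet(mesh$nodes, mesh$elems[e, ], p)) { hit <- e; break }
        }
        if (!is.na(hit)) break
      }
      if (!is.na(hit)) { out[n] <- hit; break }
    }
  }
  out
}
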