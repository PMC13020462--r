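## Tetrapolar transfer impedance and reciprocity sensitivity.
##
## Two routes to the transfer impedance: the voltage route
## Z = (V_C - V_D) / I0 read off the floating sense patches of the drive
## solve, and the lead-field volume integral Z = sum_e z_e vol_e with the
## volume impedance density z = (1/kappa) J_AB . J_CD / I0^2 computed from
## the drive and sense (reciprocal) lead fields.  For the symmetric
## discrete system the two agree to solver precision, which the dual-route
## tests exploit.

new_impedance_result <- function(Z, method, meta = list()) {
  structure(list(Z = Z, method = method, meta = meta),
            class = "impedance_result")
}

#' @export
print.impedance_result <- function(x, ...) {
  cat(sprintf("Transfer impedance (%s method): |Z| = %.4f Ohm\n",
              x$method, Mod(x$Z)))
  invisible(x)
}

#' Transfer impedance from the sense-patch voltage difference
#'
#' `Z = (V_C - V_D) / I0` using the equipotential values of the floating
#' sense patches of a drive-pair solution.  In complex mode the complex
#' impedance is carried in `Z_complex` and `Z` is its magnitude.
#'
#' @param sol A `field_solution` for the drive injection, solved on a mesh
#'   where the sense patches exist (they float automatically).
#' @param sense_pos,sense_neg Sense electrode labels (default C, D).
#' @return An `impedance_result`.
#' @export
transfer_impedance_voltage <- function(sol, sense_pos = "C",
                                       sense_neg = "D") {
  stopifnot(inherits(sol, "field_solution"))
  pC <- paste0("electrode_", sense_pos)
  pD <- paste0("electrode_", sense_neg)
  for (p in c(pC, pD)) if (!(p %in% names(sol$patch_V)))
    stop("sense patch '", p, "' missing from the solution")
  Zc <- (sol$patch_V[[pC]] - sol$patch_V[[pD]]) / sol$spec$I0
  Z <- if (sol$spec$mode == "complex") Mod(Zc) else as.numeric(Zc)
  new_impedance_result(Z, "voltage",
                       meta = list(Z_complex = Zc,
                                   frequency = sol$spec$frequency,
                                   mode = sol$spec$mode))
}

#' Volume impedance density from two lead fields
#'
#' Per element, `z = (1/kappa) * (J_AB . J_CD) / I0^2` (non-conjugated dot
#' product), in Ohm/m^3.  Its volume integral is the transfer impedance;
#' the sign of z is not definite: regions where the two lead fields
#' oppose contribute negatively.
#'
#' @param sol_drive,sol_sense `field_solution`s for the drive (A-B) and
#'   sense (C-D) injections on the same mesh with the same current.
#' @return A `sensitivity_field` with per-element `z`, element volumes and
#'   metadata.
#' @export
sensitivity_field <- function(sol_drive, sol_sense) {
  stopifnot(inherits(sol_drive, "field_solution"),
            inherits(sol_sense, "field_solution"))
  msh1 <- sol_drive$system$mesh
  msh2 <- sol_sense$system$mesh
  if (!identical(dim(msh1$elems), dim(msh2$elems)) ||
      !isTRUE(all.equal(msh1$nodes, msh2$nodes)))
    stop("drive and sense solutions live on different meshes")
  if (sol_drive$spec$I0 != sol_sense$spec$I0)
    stop("drive and sense solves must use the same injected current")
  I0 <- sol_drive$spec$I0
  dot <- sol_drive$J[, 1] * sol_sense$J[, 1] +
    sol_drive$J[, 2] * sol_sense$J[, 2] +
    sol_drive$J[, 3] * sol_sense$J[, 3]
  z <- dot / (sol_drive$system$kappa * I0^2)
  fld <- list(z = z, vol = msh1$elem_vol, region = msh1$region, I0 = I0,
              mode = sol_drive$spec$mode,
              frequency = sol_drive$spec$frequency,
              mesh = msh1)
  class(fld) <- "sensitivity_field"
  fld
}

#' Transfer impedance by the sensitivity volume integral
#'
#' `Z = sum_e z_e vol_e` over the conductive domain.
#'
#' @param field A `sensitivity_field`.
#' @return An `impedance_result` (`Z` is the magnitude in complex mode).
#' @export
transfer_impedance_integral <- function(field) {
  stopifnot(inherits(field, "sensitivity_field"))
  Zc <- sum(field$z * field$vol)
  Z <- if (field$mode == "complex") Mod(Zc) else as.numeric(Zc)
  new_impedance_result(Z, "integral",
                       meta = list(Z_complex = Zc, frequency = field$frequency,
                                   mode = field$mode))
}

#' Regional contribution to the transfer impedance
#'
#' Sum of `z * vol` over the elements of the given region label(s);
#' contributions over any partition of the regions sum exactly to the
#' integral-method impedance.
#'
#' @param field A `sensitivity_field`.
#' @param labels Region label or character vector of labels; an empty set
#'   gives 0.
#' @return Contribution (Ohm); complex in complex mode.
#' @export
regional_contribution <- function(field, labels) {
  stopifnot(inherits(field, "sensitivity_field"))
  if (length(labels) == 0) return(0)
  known <- union(unique(field$region),
                 c("soft_tissue", "lung_left", "lung_right", "heart",
                   "rib", "fluid"))
  unknown <- setdiff(labels, known)
  if (length(unknown))
    stop("unknown region label(s): ", paste(unknown, collapse = ", "))
  sel <- field$region %in% labels
  val <- sum(field$z[sel] * field$vol[sel])
  if (field$mode == "complex") val else as.numeric(val)
}

#' Planar sensitivity map at a depth beneath the electrode plane
#'
#' Samples the volume impedance density on a regular grid in the frontal
#' (coronal) plane parallel to the electrode plane at the given depth
#' beneath it.  The electrode plane is the tangent plane of the torso
#' surface at the array centre; the in-plane axes are the vertical (z) and
#' the horizontal tangent.
#'
#' @param field A `sensitivity_field` computed on a torso mesh.
#' @param geom The `thorax_geometry` the mesh was generated from (supplies
#'   the electrode array).
#' @param depth Depth beneath the electrode plane (m), non-negative.
#' @param spacing Grid spacing (m), default 5 mm.
#' @param half_extent Half-width of the sampling grid in the plane (m).
#' @return A list with `grid` (data frame: in-plane coordinates `h`, `v`,
#'   3D point, `z` value, NA outside the mesh) and `planar_average`
#'   (mean z over in-mesh samples, Ohm/m^3).
#' @export
planar_sensitivity_map <- function(field, geom, depth, spacing = 0.005,
                                   half_extent = 0.12) {
  stopifnot(inherits(field, "sensitivity_field"))
  if (is.null(geom$electrodes))
    stop("geometry carries no electrode array")
  el <- geom$electrodes
  a <- geom$torso$a; b <- geom$torso$b
  P <- geom$arc$perimeter
  t_c <- geom$arc$t_of_u(el$u_center %% P)
  z_c <- mean(vapply(el$centers_uz, `[`, 0, 2))
  p0 <- c(a * cos(t_c), b * sin(t_c), z_c)
  ## inward unit normal of the elliptic cylinder at t_c
  nrm <- c(cos(t_c) / a, sin(t_c) / b, 0)
  nrm <- -nrm / sqrt(sum(nrm^2))
  e_v <- c(0, 0, 1)
  e_h <- c(-nrm[2], nrm[1], 0)  # horizontal tangent
  origin <- p0 + depth * nrm
  hs <- seq(-half_extent, half_extent, by = spacing)
  vs <- seq(-half_extent, half_extent, by = spacing)
  gr <- expand.grid(h = hs, v = vs)
  pts <- cbind(origin[1] + gr$h * e_h[1],
               origin[2] + gr$h * e_h[2],
               origin[3] + gr$v)
  eid <- locate_elements(field$mesh, pts)
  zval <- rep(NA_real_, nrow(pts))
  zsrc <- if (field$mode == "complex") Re(field$z) else field$z
  zval[!is.na(eid)] <- zsrc[eid[!is.na(eid)]]
  if (all(is.na(zval)))
    stop("sampling plane at depth ", depth, " m lies outside the mesh")
  list(grid = data.frame(h = gr$h, v = gr$v, x = pts[, 1], y = pts[, 2],
                         zc = pts[, 3], z = zval),
       planar_average = mean(zval, na.rm = TRUE),
       depth = depth, origin = origin, normal = nrm)
}

#' Closed-form half-space tetrapolar impedance for point electrodes
#'
#' For point electrodes on the surface of a homogeneous half-space of
#' resistivity `rho`, superposition of the two point-source potentials
#' `V(r) = rho * I / (2 * pi * r)` gives
#' `Z = (rho / 2 pi) (1/r_AC - 1/r_BC - 1/r_AD + 1/r_BD)`
#' with current driven A->B and voltage sensed C-D.  Used as the analytic
#' validation oracle for the FEM pipeline.
#'
#' @param A,B,C,D Electrode positions, length-2 or length-3 numeric
#'   (coplanar points on the surface).
#' @param rho Resistivity (Ohm m).
#' @return Impedance (Ohm).
#' @export
halfspace_point_electrode_Z <- function(A, B, C, D, rho) {
  pts <- list(A = A, B = B, C = C, D = D)
  pts <- lapply(pts, function(p) if (length(p) == 2) c(p, 0) else p)
  d <- function(p, q) sqrt(sum((p - q)^2))
  for (i in 1:3) for (j in (i + 1):4)
    if (d(pts[[i]], pts[[j]]) < 1e-12)
      stop("coincident electrode positions")
  (rho / (2 * pi)) * (1 / d(pts$A, pts$C) - 1 / d(pts$B, pts$C) -
                        1 / d(pts$A, pts$D) + 1 / d(pts$B, pts$D))
}
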