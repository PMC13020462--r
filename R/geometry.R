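#' Parametric thorax geometry
#'
#' `thorax_params()` collects the parameters of the simplified parametric
#' thorax: a vertical elliptic-cylinder torso containing two truncated
#' ellipsoidal lungs, an ellipsoidal heart placed between the lungs and left
#' of the midline, 12 pairs of curved rib bars embedded in the soft tissue,
#' and a trachea/main-bronchi airway tree whose lumen is electrically
#' excluded from the conductive domain.
#'
#' All lengths are metres, volumes cubic metres.  The coordinate convention
#' is: z vertical and increasing towards the head, the anterior (chest)
#' surface faces +y, the patient's left is +x.  The torso occupies
#' `0 <= z <= torso_height`.
#'
#' The default targets pin the realized solid volumes to a total thorax
#' volume of 23.4 L and a total inflated-lung volume of 4.84 L;
#' [build_geometry()] rescales the torso and lung semi-axes to hit these
#' targets (lungs to within the numerical-quadrature tolerance).
#'
#' @param torso_semi_axis_x,torso_semi_axis_y Semi-axes of the elliptical
#'   torso cross-section (m).
#' @param torso_height Torso height (m).
#' @param lungs A list with components `left` and `right`, each a list with
#'   `center` (length-3 numeric), `semi` (semi-axes, length-3), and
#'   `base_frac` (the lung solid is the ellipsoid truncated below at
#'   `center[3] - base_frac * semi[3]`; the truncation plane is the lung
#'   base / lower margin).
#' @param heart_center,heart_semi_axes Centre and semi-axes of the heart
#'   ellipsoid (m).
#' @param heart_clearance Dilation factor applied to the heart ellipsoid
#'   when it is subtracted from the lung solids (cardiac notch), so that
#'   heart and lungs never overlap.
#' @param ribs_enabled Include rib bars?
#' @param rib_count_pairs Number of rib pairs (default 12).
#' @param rib_cross_section_radius Radius of the rib bar cross-section (m).
#' @param rib_shell_frac Ribs run along the ellipse scaled by this factor
#'   relative to the torso surface.
#' @param rib_z_range Height range spanned by the rib stack (m).
#' @param airways_enabled Include the airway tree (lumen removed from the
#'   conductive domain, walls insulating)?
#' @param airway_trachea_radius,airway_bronchus_radius Airway radii (m).
#' @param target_thorax_volume,target_lung_volume_total Volume targets (m^3).
#' @return An object of class `thorax_params`.
#' @seealso [build_geometry()]
#' @export
thorax_params <- function(torso_semi_axis_x = 0.149,
                          torso_semi_axis_y = 0.100,
                          torso_height = 0.50,
                          lungs = NULL,
                          heart_center = c(0.022, 0.012, 0.26),
                          heart_semi_axes = c(0.045, 0.055, 0.065),
                          heart_clearance = 1.08,
                          ribs_enabled = TRUE,
                          rib_count_pairs = 12L,
                          rib_cross_section_radius = 0.005,
                          rib_shell_frac = 0.90,
                          rib_z_range = c(0.17, 0.47),
                          airways_enabled = TRUE,
                          airway_trachea_radius = 0.008,
                          airway_bronchus_radius = 0.006,
                          target_thorax_volume = 23.4e-3,
                          target_lung_volume_total = 4.84e-3) {
  if (is.null(lungs)) {
    ## half-ellipsoids: truncated at the equator, so the base (resting on
    ## the diaphragm) is the widest section and the apex tapers upwards
    lungs <- list(
      left  = list(center = c( 0.062, -0.005, 0.22),
                   semi = c(0.062, 0.082, 0.24), base_frac = 0),
      right = list(center = c(-0.062, -0.005, 0.22),
                   semi = c(0.062, 0.082, 0.24), base_frac = 0)
    )
  }
  p <- list(torso_semi_axis_x = torso_semi_axis_x,
            torso_semi_axis_y = torso_semi_axis_y,
            torso_height = torso_height,
            lungs = lungs,
            heart_center = heart_center,
            heart_semi_axes = heart_semi_axes,
            heart_clearance = heart_clearance,
            ribs_enabled = isTRUE(ribs_enabled),
            rib_count_pairs = as.integer(rib_count_pairs),
            rib_cross_section_radius = rib_cross_section_radius,
            rib_shell_frac = rib_shell_frac,
            rib_z_range = rib_z_range,
            airways_enabled = isTRUE(airways_enabled),
            airway_trachea_radius = airway_trachea_radius,
            airway_bronchus_radius = airway_bronchus_radius,
            target_thorax_volume = target_thorax_volume,
            target_lung_volume_total = target_lung_volume_total)
  lens <- c(torso_semi_axis_x, torso_semi_axis_y, torso_height,
            unlist(lapply(lungs, function(l) l$semi)),
            heart_semi_axes, rib_cross_section_radius,
            airway_trachea_radius, airway_bronchus_radius,
            target_thorax_volume, target_lung_volume_total)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all lengths and volume targets must be positive and finite")
  class(p) <- "thorax_params"
  p
}

ellipsoid_volume <- function(semi) 4 / 3 * pi * prod(semi)

## Volume of an ellipsoid with vertical semi-axis c truncated below at
## z = cz - base_frac * c  (closed form).
truncated_ellipsoid_volume <- function(semi, base_frac) {
  f <- function(u) u - u^3 / 3
  pi * semi[1] * semi[2] * semi[3] * (f(1) - f(-base_frac))
}

lung_base_z <- function(lung) lung$center[3] - lung$base_frac * lung$semi[3]

## -- point membership predicates (vectorised over an n x 3 matrix) ---------

in_ellipsoid <- function(pts, center, semi) {
  ((pts[, 1] - center[1]) / semi[1])^2 +
    ((pts[, 2] - center[2]) / semi[2])^2 +
    ((pts[, 3] - center[3]) / semi[3])^2 <= 1
}

in_torso <- function(geom, pts) {
  (pts[, 1] / geom$torso$a)^2 + (pts[, 2] / geom$torso$b)^2 <= 1 &
    pts[, 3] >= 0 & pts[, 3] <= geom$torso$h
}

## Lung solid: ellipsoid, truncated below at the base plane, with the
## dilated heart subtracted (cardiac notch).
in_lung <- function(geom, pts, side) {
  lung <- geom$lungs[[side]]
  ok <- in_ellipsoid(pts, lung$center, lung$semi) & pts[, 3] >= lung$z_base
  if (any(ok)) {
    hs <- geom$heart$semi * geom$heart$clearance
    ok[ok] <- !in_ellipsoid(pts[ok, , drop = FALSE], geom$heart$center, hs)
  }
  ok
}

in_heart <- function(geom, pts) in_ellipsoid(pts, geom$heart$center, geom$heart$semi)

## Ribs: tubes of radius r following the ellipse scaled by shell_frac, at
## rib_count_pairs evenly spaced heights, with gaps at the sternum (around
## the anterior midline) and the spine (posterior midline).
in_rib <- function(geom, pts) {
  if (!geom$ribs$enabled) return(rep(FALSE, nrow(pts)))
  a <- geom$torso$a * geom$ribs$shell_frac
  b <- geom$torso$b * geom$ribs$shell_frac
  r <- geom$ribs$radius
  xs <- pts[, 1] / a
  ys <- pts[, 2] / b
  rho <- sqrt(xs^2 + ys^2)
  ## first-order distance from the scaled ellipse: (rho - 1) / |grad rho|
  gn <- sqrt((xs / a)^2 + (ys / b)^2) / pmax(rho, 1e-12)
  d_shell <- (rho - 1) / pmax(gn, 1e-12)
  zk <- geom$ribs$heights
  dz_sp <- if (length(zk) > 1) zk[2] - zk[1] else Inf
  idx <- pmin(pmax(round((pts[, 3] - zk[1]) / dz_sp), 0), length(zk) - 1)
  d_z <- pts[, 3] - (zk[1] + idx * dz_sp)
  near <- d_shell^2 + d_z^2 <= r^2
  ## angular gaps: sternum around t = 90 deg (anterior), spine around -90 deg
  t <- atan2(ys, xs) * 180 / pi
  gap <- (t > geom$ribs$arc_lat_deg & t < 180 - geom$ribs$arc_lat_deg) |
    (t < -geom$ribs$arc_lat_deg & t > -(180 - geom$ribs$arc_lat_deg))
  near & !gap
}

## Airway tree: union of cylinders around line segments.
in_airway <- function(geom, pts) {
  if (!geom$airways$enabled) return(rep(FALSE, nrow(pts)))
  inside <- rep(FALSE, nrow(pts))
  for (seg in geom$airways$segments) {
    p0 <- seg$from; p1 <- seg$to; r <- seg$radius
    d <- p1 - p0
    L2 <- sum(d^2)
    t <- ((pts[, 1] - p0[1]) * d[1] + (pts[, 2] - p0[2]) * d[2] +
            (pts[, 3] - p0[3]) * d[3]) / L2
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1] - (p0[1] + t * d[1])
    dy <- pts[, 2] - (p0[2] + t * d[2])
    dz <- pts[, 3] - (p0[3] + t * d[3])
    inside <- inside | (dx^2 + dy^2 + dz^2 <= r^2)
  }
  inside
}

in_fluid <- function(geom, pts, side) {
  fl <- geom$fluid[[side]]
  if (is.null(fl) || fl$target_volume <= 0) return(rep(FALSE, nrow(pts)))
  in_lung(geom, pts, side) & pts[, 3] < fl$cut_height
}

#' Classify points into thorax regions
#'
#' Assigns each point one of the region labels `airway` (non-conductive
#' lumen), `fluid`, `heart`, `lung_left`, `lung_right`, `rib`,
#' `soft_tissue`, or `outside`.  Fluid takes precedence over lung, the
#' organs over ribs, ribs over soft tissue.
#'
#' @param geom A `thorax_geometry`.
#' @param pts Numeric matrix (n x 3) of points (m).
#' @return Character vector of region labels.
#' @export
classify_points <- function(geom, pts) {
  pts <- as.matrix(pts)
  lab <- rep("outside", nrow(pts))
  keep <- in_torso(geom, pts)
  lab[keep] <- "soft_tissue"
  sub <- pts[keep, , drop = FALSE]
  sl <- rep("soft_tissue", nrow(sub))
  sl[in_rib(geom, sub)] <- "rib"
  sl[in_lung(geom, sub, "left")] <- "lung_left"
  sl[in_lung(geom, sub, "right")] <- "lung_right"
  sl[in_heart(geom, sub)] <- "heart"
  for (side in c("left", "right")) {
    fl <- geom$fluid[[side]]
    if (!is.null(fl) && fl$target_volume > 0) {
      lung_lab <- paste0("lung_", side)
      sl[sl == lung_lab & sub[, 3] < fl$cut_height] <- "fluid"
    }
  }
  sl[in_airway(geom, sub)] <- "airway"
  lab[keep] <- sl
  lab
}

## Deterministic midpoint-grid volume quadrature of a lung solid.
lung_volume_quadrature <- function(geom, side, h = 0.0025) {
  lung <- geom$lungs[[side]]
  lo <- lung$center - lung$semi
  hi <- lung$center + lung$semi
  lo[3] <- max(lo[3], lung$z_base)
  gx <- seq(lo[1] + h / 2, hi[1], by = h)
  gy <- seq(lo[2] + h / 2, hi[2], by = h)
  gz <- seq(lo[3] + h / 2, hi[3], by = h)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz, KEEP.OUT.ATTRS = FALSE))
  inside <- in_lung(geom, pts, side)
  list(volume = sum(inside) * h^3, z = pts[inside, 3], cell = h^3)
}

## Ellipse perimeter parameterisation: arc length u as a function of the
## parameter angle t for (a cos t, b sin t), plus the inverse.
ellipse_arclength_tables <- function(a, b, n = 4096L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)
  speed <- sqrt((a * sin(t))^2 + (b * cos(t))^2)
  u <- c(0, cumsum((speed[-1] + speed[-length(speed)]) / 2 * diff(t)))
  list(perimeter = u[length(u)],
       u_of_t = stats::approxfun(t, u, rule = 2),
       t_of_u = stats::approxfun(u, t, rule = 2))
}

## Signed circular difference on the perimeter.
arc_diff <- function(u1, u2, perimeter) {
  ((u1 - u2 + perimeter / 2) %% perimeter) - perimeter / 2
}

#' Build the synthetic thorax geometry
#'
#' Constructs the labeled solid model from a [thorax_params()] object.  The
#' torso semi-axes are rescaled (preserving their ratio) so that the torso
#' volume `pi * a * b * h` equals `target_thorax_volume` exactly, and the
#' horizontal lung semi-axes are rescaled so that the total lung solid
#' volume (after truncation at the base plane and subtraction of the
#' dilated heart) matches `target_lung_volume_total` to the quadrature
#' tolerance.
#'
#' @param params A `thorax_params` object.
#' @param quad_h Grid step of the deterministic volume quadrature used for
#'   the lung auto-scaling (m).
#' @return An object of class `thorax_geometry`.
#' @examples
#' geom <- build_geometry(thorax_params())
#' geom$volumes$thorax   # 0.0234 m^3
#' @export
build_geometry <- function(params = thorax_params(), quad_h = 0.0025) {
  stopifnot(inherits(params, "thorax_params"))
  ## pin torso volume exactly
  s_t <- sqrt(params$target_thorax_volume /
                (pi * params$torso_semi_axis_x * params$torso_semi_axis_y *
                   params$torso_height))
  a <- params$torso_semi_axis_x * s_t
  b <- params$torso_semi_axis_y * s_t
  h <- params$torso_height

  geom <- list(
    params = params,
    torso = list(a = a, b = b, h = h),
    lungs = lapply(params$lungs, function(l) {
      l$z_base <- lung_base_z(l); l
    }),
    heart = list(center = params$heart_center, semi = params$heart_semi_axes,
                 clearance = params$heart_clearance),
    ribs = list(enabled = params$ribs_enabled,
                n_pairs = params$rib_count_pairs,
                radius = params$rib_cross_section_radius,
                shell_frac = params$rib_shell_frac,
                heights = seq(params$rib_z_range[1], params$rib_z_range[2],
                              length.out = params$rib_count_pairs),
                arc_lat_deg = 82),
    airways = list(enabled = params$airways_enabled, segments = list()),
    fluid = list(left = NULL, right = NULL),
    electrodes = NULL
  )
  class(geom) <- "thorax_geometry"

  ## airway tree: trachea entering at the top, splitting into two bronchi
  if (params$airways_enabled) {
    carina <- c(0, -0.010, 0.36)
    geom$airways$segments <- list(
      list(from = c(0, -0.010, h), to = carina,
           radius = params$airway_trachea_radius),
      list(from = carina, to = c( 0.045, -0.005, 0.31),
           radius = params$airway_bronchus_radius),
      list(from = carina, to = c(-0.045, -0.005, 0.31),
           radius = params$airway_bronchus_radius)
    )
  }

  ## feasibility: lungs must fit inside the torso envelope
  for (side in c("left", "right")) {
    lung <- geom$lungs[[side]]
    th <- seq(0, 2 * pi, length.out = 73)[-73]
    ph <- seq(-pi / 2, pi / 2, length.out = 37)
    sp <- expand.grid(th = th, ph = ph)
    bdry <- cbind(lung$center[1] + lung$semi[1] * cos(sp$ph) * cos(sp$th),
                  lung$center[2] + lung$semi[2] * cos(sp$ph) * sin(sp$th),
                  lung$center[3] + lung$semi[3] * sin(sp$ph))
    bdry <- bdry[bdry[, 3] >= lung$z_base, , drop = FALSE]
    if (!all(in_torso(geom, bdry)))
      stop("infeasible parameters: ", side,
           " lung protrudes outside the torso envelope")
    if (sign(lung$center[1]) * lung$center[1] - lung$semi[1] < 0)
      stop("infeasible parameters: ", side, " lung crosses the midline ",
           "(lungs would overlap)")
  }
  if (!all(abs(geom$heart$center[1:2]) + geom$heart$semi[1:2] * 1.0 <
             c(a, b)))
    stop("infeasible parameters: heart protrudes outside the torso")

  ## auto-scale horizontal lung semi-axes to the total lung volume target
  vol_at <- function(s) {
    g2 <- geom
    for (side in c("left", "right")) {
      g2$lungs[[side]]$semi[1:2] <- geom$lungs[[side]]$semi[1:2] * s
    }
    sum(vapply(c("left", "right"), function(sd)
      lung_volume_quadrature(g2, sd, h = quad_h)$volume, 0))
  }
  target <- params$target_lung_volume_total
  f <- function(s) vol_at(s) - target
  root <- stats::uniroot(f, interval = c(0.6, 1.4), tol = 1e-5)
  for (side in c("left", "right"))
    geom$lungs[[side]]$semi[1:2] <- geom$lungs[[side]]$semi[1:2] * root$root

  geom$arc <- ellipse_arclength_tables(a, b)
  geom$volumes <- list(
    thorax = pi * a * b * h,
    lung_left = lung_volume_quadrature(geom, "left", h = quad_h)$volume,
    lung_right = lung_volume_quadrature(geom, "right", h = quad_h)$volume,
    heart = ellipsoid_volume(geom$heart$semi)
  )
  dev <- abs(geom$volumes$lung_left + geom$volumes$lung_right - target) /
    target
  if (dev > 0.02)
    stop("lung auto-scaling failed to reach the volume target (deviation ",
         signif(dev * 100, 3), "%)")
  geom
}

#' @export
print.thorax_geometry <- function(x, ...) {
  cat("Synthetic thorax geometry\n")
  cat(sprintf("  torso: %.3f x %.3f m semi-axes, height %.3f m, volume %.2f L\n",
              x$torso$a, x$torso$b, x$torso$h, 1e3 * x$volumes$thorax))
  cat(sprintf("  lungs: %.2f L (left) + %.2f L (right)\n",
              1e3 * x$volumes$lung_left, 1e3 * x$volumes$lung_right))
  cat(sprintf("  heart: %.2f L; ribs: %s; airways: %s\n",
              1e3 * x$volumes$heart,
              if (x$ribs$enabled) sprintf("%d pairs", x$ribs$n_pairs) else "off",
              if (x$airways$enabled) "on" else "off"))
  for (side in c("left", "right")) {
    fl <- x$fluid[[side]]
    if (!is.null(fl) && fl$target_volume > 0)
      cat(sprintf("  fluid (%s lung): %.0f mL up to z = %.3f m\n",
                  side, 1e6 * fl$realized_volume, fl$cut_height))
  }
  if (!is.null(x$electrodes))
    cat(sprintf("  electrodes: %s side, offset %.3f m, separation %.3f m\n",
                x$electrodes$side, x$electrodes$vertical_offset,
                x$electrodes$separation))
  invisible(x)
}

#' Height of the lower lung margin
#'
#' The lung base plane height for one side; the electrode reference
#' position aligns the bottom electrode pair with this height.
#'
#' @param geom A `thorax_geometry`.
#' @param side `"left"` or `"right"`.
#' @return Height (m).
#' @export
lung_base_height <- function(geom, side = c("right", "left")) {
  side <- match.arg(side)
  geom$lungs[[side]]$z_base
}

#' Carve a gravity-pooled fluid region into a lung
#'
#' The fluid region is the intersection of the lung solid with the
#' half-space below a horizontal cut plane; the cut height is found by
#' bisection on the lung volume-below-height curve so that the realized
#' fluid volume matches the target to within 1 %.  The lung's air region
#' shrinks by the same volume.  A zero target leaves the geometry
#' unchanged.
#'
#' @param geom A `thorax_geometry`.
#' @param side Which lung (`"left"`/`"right"`).
#' @param target_volume Fluid volume target (m^3).
#' @param quad_h Quadrature grid step (m).
#' @param max_iter Bisection iteration cap.
#' @return The modified `thorax_geometry`; `geom$fluid[[side]]` carries
#'   `target_volume`, `realized_volume` and `cut_height`.
#' @export
carve_fluid_region <- function(geom, side = c("right", "left"),
                               target_volume, quad_h = 0.002,
                               max_iter = 60L) {
  side <- match.arg(side)
  stopifnot(inherits(geom, "thorax_geometry"))
  if (target_volume == 0) {
    geom$fluid[[side]] <- NULL
    return(geom)
  }
  if (target_volume < 0) stop("target_volume must be non-negative")
  lung <- geom$lungs[[side]]
  quad <- lung_volume_quadrature(geom, side, h = quad_h)
  if (target_volume > 0.9 * quad$volume)
    stop("fluid target (", signif(target_volume * 1e3, 4),
         " L) exceeds 90% of the ", side, " lung volume (",
         signif(quad$volume * 1e3, 4), " L)")
  ## piecewise-linear volume-below-height: each quadrature cell contributes
  ## the fraction of its vertical extent below the cut plane
  v_below <- function(hcut)
    sum(pmin(pmax((hcut - (quad$z - quad_h / 2)) / quad_h, 0), 1)) * quad$cell
  lo <- lung$z_base
  hi <- lung$center[3] + lung$semi[3]
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (v_below(mid) < target_volume) lo <- mid else hi <- mid
  }
  cut <- (lo + hi) / 2
  realized <- v_below(cut)
  if (abs(realized - target_volume) / target_volume > 0.01)
    stop("fluid bisection did not reach the 1% volume tolerance")
  geom$fluid[[side]] <- list(side = side, target_volume = target_volume,
                             realized_volume = realized, cut_height = cut)
  geom
}

#' Place a tetrapolar electrode array on the chest surface
#'
#' Four circular electrode patches are placed at the corners of a square in
#' the unrolled surface metric (arc length along the torso cross-section x
#' height).  The array is centred laterally above the chosen lung; at
#' `vertical_offset = 0` the bottom electrode pair is level with the lower
#' margin of that lung (the reference position).
#'
#' The default corner assignment drives current through the left vertical
#' edge of the square (A bottom, B top) and senses across the right
#' vertical edge (C bottom, D top); it can be overridden through
#' `corner_assignment`.
#'
#' @param geom A `thorax_geometry`.
#' @param side Chest side (`"right"`/`"left"`).
#' @param vertical_offset Vertical shift of the whole array above the
#'   reference position (m).
#' @param separation Centre-to-centre distance of adjacent electrodes (m);
#'   default 0.08.
#' @param diameter Electrode diameter (m); default 0.01.
#' @param corner_assignment Named character vector mapping the labels
#'   A,B,C,D to corners `"bottom_left"`, `"top_left"`, `"bottom_right"`,
#'   `"top_right"`.
#' @return The modified `thorax_geometry` with `geom$electrodes` set.
#' @export
place_electrode_array <- function(geom, side = c("right", "left"),
                                  vertical_offset = 0,
                                  separation = 0.08, diameter = 0.01,
                                  corner_assignment = c(
                                    A = "bottom_left", B = "top_left",
                                    C = "bottom_right", D = "top_right")) {
  side <- match.arg(side)
  stopifnot(inherits(geom, "thorax_geometry"))
  if (separation <= 0 || diameter <= 0)
    stop("separation and diameter must be positive")
  if (!setequal(names(corner_assignment), c("A", "B", "C", "D")) ||
      !setequal(unname(corner_assignment),
                c("bottom_left", "top_left", "bottom_right", "top_right")))
    stop("corner_assignment must map A,B,C,D onto the four square corners")

  lung <- geom$lungs[[side]]
  a <- geom$torso$a
  ## lateral centre: the anterior surface point above the lung centre
  t_c <- acos(pmin(pmax(lung$center[1] / a, -1), 1))  # sin(t_c) >= 0: anterior
  u_c <- geom$arc$u_of_t(t_c)
  z_bot <- lung$z_base + vertical_offset
  z_top <- z_bot + separation
  r <- diameter / 2
  if (z_bot - r < 0 || z_top + r > geom$torso$h)
    stop("electrode patch falls off the torso surface (z range [",
         signif(z_bot - r, 3), ", ", signif(z_top + r, 3), "] m)")

  corners <- list(bottom_left  = c(u_c - separation / 2, z_bot),
                  top_left     = c(u_c - separation / 2, z_top),
                  bottom_right = c(u_c + separation / 2, z_bot),
                  top_right    = c(u_c + separation / 2, z_top))
  centers <- lapply(corner_assignment, function(cn) corners[[cn]])
  names(centers) <- names(corner_assignment)

  P <- geom$arc$perimeter
  ## all four centres must project onto the anterior surface
  for (lb in names(centers)) {
    t_i <- geom$arc$t_of_u(centers[[lb]][1] %% P)
    if (sin(t_i) <= 0)
      stop("electrode ", lb, " does not project onto the anterior surface")
  }
  ## no patch overlap
  labs <- names(centers)
  for (i in seq_along(labs)) for (j in seq_len(i - 1L)) {
    du <- arc_diff(centers[[i]][1], centers[[j]][1], P)
    dz <- centers[[i]][2] - centers[[j]][2]
    if (sqrt(du^2 + dz^2) < diameter)
      stop("electrode patches ", labs[i], " and ", labs[j], " overlap")
  }

  pts3d <- lapply(centers, function(cz) {
    t_i <- geom$arc$t_of_u(cz[1] %% P)
    c(geom$torso$a * cos(t_i), geom$torso$b * sin(t_i), cz[2])
  })
  geom$electrodes <- list(side = side, vertical_offset = vertical_offset,
                          separation = separation, diameter = diameter,
                          corner_assignment = corner_assignment,
                          centers_uz = centers, centers_xyz = pts3d,
                          u_center = u_c)
  geom
}
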