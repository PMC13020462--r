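## Experiment drivers: vertical electrode sweep, fluid-volume sweep,
## frequency sweep, mesh convergence study, and their summary statistics.
##
## All drivers share one workhorse, thorax_impedance(), which places
## (or reuses) the electrode array, meshes, solves the drive and sense
## lead fields and returns the integral-method transfer impedance.  The
## meshing and the direct solver are deterministic, so every sweep is
## bitwise reproducible for a fixed configuration.

#' Relabel a mesh after a geometry change that preserves the solids
#'
#' Re-classifies the element centroids under a modified geometry (e.g.
#' after carving a different fluid volume).  Valid only for geometry
#' changes that do not move region boundaries across the airway lumen
#' (which has been removed from the mesh).
#'
#' @param mesh A `tet_mesh` generated from a compatible geometry.
#' @param geom The modified `thorax_geometry`.
#' @return The mesh with updated region labels.
#' @export
relabel_mesh <- function(mesh, geom) {
  cen <- (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 2], ] +
            mesh$nodes[mesh$elems[, 3], ] + mesh$nodes[mesh$elems[, 4], ]) / 4
  region <- classify_points(geom, cen)
  region[region %in% c("outside", "airway")] <- "soft_tissue"
  mesh$region <- region
  attach_region_samples(mesh, geom)
}

#' Transfer impedance of one thorax configuration
#'
#' Convenience wrapper: meshes the geometry (the electrode array must be
#' placed), solves both lead fields and returns the integral-method
#' impedance together with the sensitivity field.
#'
#' @param geom A `thorax_geometry` with electrodes placed.
#' @param spec A [solve_spec()].
#' @param refinement_level Mesh refinement level.
#' @param mesh Optional pre-generated mesh to reuse (it is relabeled under
#'   `geom`).
#' @return A list with `Z` (magnitude, Ohm), `Z_complex`, `field` (the
#'   `sensitivity_field`), `sol_drive`, `sol_sense` and `mesh`.
#' @export
thorax_impedance <- function(geom, spec = solve_spec(),
                             refinement_level = "normal", mesh = NULL) {
  if (is.null(geom$electrodes)) stop("place an electrode array first")
  if (is.null(mesh)) mesh <- generate_mesh(geom, refinement_level)
  else mesh <- relabel_mesh(mesh, geom)
  sys <- assemble_system(mesh, spec = spec)
  sAB <- solve_injection(sys, "A", "B", spec)
  sCD <- solve_injection(sys, "C", "D", spec)
  fld <- sensitivity_field(sAB, sCD)
  Zi <- transfer_impedance_integral(fld)
  list(Z = Mod(Zi$meta$Z_complex), Z_complex = Zi$meta$Z_complex,
       field = fld, sol_drive = sAB, sol_sense = sCD, mesh = mesh)
}

new_sweep_result <- function(kind, points, meta = list()) {
  structure(list(kind = kind, points = points, meta = meta),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep over %s (%d points)\n", x$kind, nrow(x$points)))
  print(x$points, digits = 5)
  invisible(x)
}

#' Vertical electrode sweep
#'
#' Moves the tetrapolar array upwards from the reference position (bottom
#' electrodes level with the lower lung margin) in the given offsets,
#' re-meshing at each position, and records the transfer impedance.  A
#' placement failure at one offset flags that offset and the sweep
#' continues.
#'
#' @param geom Base `thorax_geometry` (fluid carved or not; no electrodes
#'   needed).
#' @param side Chest side for the array.
#' @param offsets Vertical offsets (m); default 0 to 0.10 in 2 cm steps.
#' @param spec A [solve_spec()].
#' @param refinement_level Mesh level.
#' @param separation,diameter Array geometry (m).
#' @return A `sweep_result` whose `points` has columns `offset`, `Z`, `ok`.
#' @export
vertical_sweep <- function(geom, side = c("right", "left"),
                           offsets = seq(0, 0.10, by = 0.02),
                           spec = solve_spec(),
                           refinement_level = "normal",
                           separation = 0.08, diameter = 0.01) {
  side <- match.arg(side)
  if (length(offsets) == 0)
    return(new_sweep_result("vertical_offset",
                            data.frame(offset = numeric(0), Z = numeric(0),
                                       ok = logical(0))))
  if (is.unsorted(offsets, strictly = TRUE))
    stop("offsets must be strictly increasing")
  rows <- lapply(offsets, function(off) {
    out <- tryCatch({
      g <- place_electrode_array(geom, side, vertical_offset = off,
                                 separation = separation,
                                 diameter = diameter)
      r <- thorax_impedance(g, spec, refinement_level)
      data.frame(offset = off, Z = r$Z, ok = TRUE)
    }, error = function(e) {
      warning("offset ", off, " m failed: ", conditionMessage(e))
      data.frame(offset = off, Z = NA_real_, ok = FALSE)
    })
    out
  })
  new_sweep_result("vertical_offset", do.call(rbind, rows),
                   meta = list(side = side, frequency = spec$frequency,
                               mode = spec$mode,
                               refinement_level = refinement_level,
                               separation = separation,
                               fluid = geom$fluid))
}

#' Relative impedance change caused by fluid
#'
#' `%dZ = 100 * (Z_baseline - Z_fluid) / Z_baseline`, positive when fluid
#' lowers the impedance.
#'
#' @param Z_baseline,Z_fluid Impedances (Ohm); vectors recycle.
#' @return Percent change.
#' @export
percent_delta_Z <- function(Z_baseline, Z_fluid) {
  if (any(Z_baseline <= 0)) stop("Z_baseline must be positive")
  100 * (Z_baseline - Z_fluid) / Z_baseline
}

#' Fluid-volume sweep
#'
#' Impedance as a function of the fluid volume carved into the lower lobe
#' of one lung, with the electrode array held at the lower (reference)
#' position on the same side, directly above the accumulating fluid.  The
#' mesh is generated once and relabeled per volume (the solids do not
#' move, only the fluid cut plane).
#'
#' @param geom Base `thorax_geometry` (no fluid).
#' @param side Lung/chest side.
#' @param volumes Fluid volumes (m^3), including 0 for the baseline;
#'   default 0 to 670 mL in six equispaced steps.
#' @param spec A [solve_spec()].
#' @param refinement_level Mesh level.
#' @param h_front Vertical element size across the band the fluid front
#'   traverses (m); the band is refined once, in the shared mesh, so that
#'   the moving air/fluid interface is resolved consistently for every
#'   volume of the sweep.
#' @return A `sweep_result` with columns `volume`, `Z`.
#' @export
fluid_volume_sweep <- function(geom, side = c("right", "left"),
                               volumes = seq(0, 670e-6, length.out = 6),
                               spec = solve_spec(),
                               refinement_level = "normal",
                               h_front = 0.0035) {
  side <- match.arg(side)
  if (length(volumes) == 0)
    return(new_sweep_result("fluid_volume",
                            data.frame(volume = numeric(0), Z = numeric(0))))
  g_el <- place_electrode_array(geom, side, vertical_offset = 0)
  vmax <- max(volumes)
  z_refine <- NULL
  if (vmax > 0) {
    cut_max <- carve_fluid_region(g_el, side, vmax)$fluid[[side]]$cut_height
    z_base <- lung_base_height(g_el, side)
    z_refine <- data.frame(center = (z_base + cut_max) / 2,
                           halfwidth = (cut_max - z_base) / 2 + 0.005,
                           h = h_front)
  }
  mesh <- generate_mesh(g_el, refinement_level, z_refine = z_refine)
  rows <- lapply(volumes, function(v) {
    g <- if (v > 0) carve_fluid_region(g_el, side, v) else g_el
    r <- thorax_impedance(g, spec, refinement_level, mesh = mesh)
    data.frame(volume = v, Z = r$Z)
  })
  new_sweep_result("fluid_volume", do.call(rbind, rows),
                   meta = list(side = side, frequency = spec$frequency,
                               mode = spec$mode,
                               refinement_level = refinement_level))
}

#' Ordinary least-squares fit of impedance on fluid volume
#'
#' Fits `Z = intercept + slope * volume` by OLS.  The slope is reported
#' both in Ohm/m^3 and in the conventional milliohm per 100 mL.
#'
#' @param sweep A `sweep_result` from [fluid_volume_sweep()] (or any data
#'   frame with `volume` (m^3) and `Z` columns and at least 3 points).
#' @return A `linear_fit` list: `slope_ohm_per_m3`,
#'   `slope_mohm_per_100ml`, `intercept`, `r_squared`.
#' @export
linear_fit_volume <- function(sweep) {
  pts <- if (inherits(sweep, "sweep_result")) sweep$points else sweep
  if (nrow(pts) < 3) stop("need at least 3 points for a linear fit")
  fit <- stats::lm(Z ~ volume, data = pts)
  sl <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  structure(list(slope_ohm_per_m3 = sl,
                 ## 100 mL = 1e-4 m^3; Ohm -> mOhm: 1e3
                 slope_mohm_per_100ml = sl * 1e-4 * 1e3,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, fit = fit),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Z vs volume: slope %.2f mOhm/100 mL, intercept %.3f Ohm, r^2 = %.5f\n",
              x$slope_mohm_per_100ml, x$intercept, x$r_squared))
  invisible(x)
}

#' Frequency sweep of the transfer impedance
#'
#' Impedance magnitude over the measurement frequencies under baseline
#' and, when a fluid spec is given, fluid conditions, in complex
#' (conduction + displacement) mode.  The mesh is generated once per
#' configuration and reused across frequencies.
#'
#' @param geom Base `thorax_geometry` (no fluid).
#' @param side Chest side.
#' @param fluid_volume Fluid volume for the fluid condition (m^3), or
#'   `NULL` for baseline only.
#' @param frequencies Frequencies (Hz); default the tabulated seven.
#' @param refinement_level Mesh level.
#' @param I0 Injected current (A).
#' @return A `sweep_result` with columns `frequency`, `Z_baseline` and
#'   (when applicable) `Z_fluid`.
#' @export
frequency_sweep <- function(geom, side = c("right", "left"),
                            fluid_volume = 670e-6,
                            frequencies = c(5, 10, 50, 100, 200, 500,
                                            1000) * 1e3,
                            refinement_level = "normal", I0 = 1e-3) {
  side <- match.arg(side)
  g_el <- place_electrode_array(geom, side, vertical_offset = 0)
  mesh <- generate_mesh(g_el, refinement_level)
  g_fl <- if (!is.null(fluid_volume) && fluid_volume > 0)
    carve_fluid_region(g_el, side, fluid_volume) else NULL
  rows <- lapply(frequencies, function(f) {
    sp <- solve_spec(frequency = f, I0 = I0, mode = "complex")
    zb <- thorax_impedance(g_el, sp, refinement_level, mesh = mesh)$Z
    out <- data.frame(frequency = f, Z_baseline = zb)
    if (!is.null(g_fl))
      out$Z_fluid <- thorax_impedance(g_fl, sp, refinement_level,
                                      mesh = mesh)$Z
    out
  })
  new_sweep_result("frequency", do.call(rbind, rows),
                   meta = list(side = side, fluid_volume = fluid_volume,
                               refinement_level = refinement_level))
}

#' Mesh convergence study
#'
#' Transfer impedance at a fixed configuration (right lower electrode
#' position by default) across mesh refinement levels, with deviations
#' reported relative to the finest level computed.
#'
#' @param geom Base `thorax_geometry`.
#' @param side Chest side.
#' @param levels Refinement levels, coarsest to finest; at least 2.
#' @param spec A [solve_spec()].
#' @return A list with `table` (level, elements, nodes, Z,
#'   deviation_from_finest) and `stats` from [convergence_deviation_stats()].
#' @export
mesh_convergence_study <- function(geom, side = c("right", "left"),
                                   levels = c("coarser", "coarse",
                                              "normal", "fine"),
                                   spec = solve_spec()) {
  side <- match.arg(side)
  if (length(levels) < 1) stop("need at least one refinement level")
  g <- place_electrode_array(geom, side, vertical_offset = 0)
  rows <- lapply(levels, function(lev) {
    r <- tryCatch(thorax_impedance(g, spec, refinement_level = lev),
                  error = function(e) NULL)
    if (is.null(r))
      return(data.frame(level = lev, elements = NA, nodes = NA,
                        Z = NA_real_, Z_voltage = NA_real_, ok = FALSE))
    data.frame(level = lev, elements = nrow(r$mesh$elems),
               nodes = nrow(r$mesh$nodes), Z = r$Z,
               Z_voltage = Mod(transfer_impedance_voltage(r$sol_drive)$meta$Z_complex),
               ok = TRUE)
  })
  tab <- do.call(rbind, rows)
  st <- convergence_deviation_stats(tab$Z[tab$ok])
  tab$deviation_from_finest <- NA_real_
  tab$deviation_from_finest[tab$ok] <- st$deviations
  list(table = tab, stats = st)
}

#' Deviation statistics of a convergence series
#'
#' Relative deviations of each level's impedance from the finest (last)
#' level: `|Z_i - Z_finest| / Z_finest`.
#'
#' @param Z Impedance series ordered coarsest to finest (Ohm).
#' @return A list with `deviations` (fractions, per level), `max_deviation`
#'   and `normal_vs_fine` (deviation of the second-finest level, `NA` for a
#'   single-level series).
#' @export
convergence_deviation_stats <- function(Z) {
  n <- length(Z)
  if (n == 0) return(list(deviations = numeric(0), max_deviation = NA_real_,
                          normal_vs_fine = NA_real_))
  dev <- abs(Z - Z[n]) / Z[n]
  list(deviations = dev,
       max_deviation = if (n > 1) max(dev[-n]) else 0,
       normal_vs_fine = if (n > 1) dev[n - 1] else 0)
}

#' Detectability of fluid against a measurement-noise band
#'
#' Flags the sweep points where the fluid-induced impedance change
#' exceeds a fractional noise band around the baseline (default +/- 2 %),
#' i.e. where the change is distinguishable from typical measurement
#' variability.
#'
#' @param baseline,fluid Data frames (or `sweep_result`s) with a shared
#'   abscissa column (first column) and a `Z` column.
#' @param band Fractional band (default 0.02).
#' @return The baseline abscissa with columns `dZ`, `band_halfwidth`,
#'   `detectable`.
#' @export
detectability_band <- function(baseline, fluid, band = 0.02) {
  pb <- if (inherits(baseline, "sweep_result")) baseline$points else baseline
  pf <- if (inherits(fluid, "sweep_result")) fluid$points else fluid
  ab <- pb[[1]]; af <- pf[[1]]
  if (length(ab) != length(af) || any(abs(ab - af) > 1e-12))
    stop("baseline and fluid series have mismatched abscissae")
  dZ <- abs(pb$Z - pf$Z)
  hw <- band * pb$Z
  data.frame(abscissa = ab, Z_baseline = pb$Z, Z_fluid = pf$Z, dZ = dZ,
             band_halfwidth = hw, detectable = dZ > hw)
}
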