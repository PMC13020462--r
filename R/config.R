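## Run configuration (YAML) and command dispatch.
##
## A RunConfig is a nested list mirroring the module parameters; unknown
## keys are rejected so typos fail loudly, and a write-then-read round
## trip is the identity.  run_command() exposes the experiment drivers
## under shell-style subcommands for use via Rscript.

#' Default run configuration
#'
#' All-defaults configuration: 10 kHz, 1 mA, real mode, right side,
#' 8 cm separation, 1 cm electrodes, normal refinement, no fluid.
#'
#' @return A `run_config` nested list.
#' @export
default_config <- function() {
  cfg <- list(
    thorax = list(
      torso_semi_axis_x = 0.149, torso_semi_axis_y = 0.100,
      torso_height = 0.50,
      ribs_enabled = TRUE, rib_count_pairs = 12L,
      airways_enabled = TRUE,
      target_thorax_volume = 23.4e-3,
      target_lung_volume_total = 4.84e-3),
    electrodes = list(
      side = "right", vertical_offset = 0,
      separation = 0.08, diameter = 0.01,
      corner_assignment = list(A = "bottom_left", B = "top_left",
                               C = "bottom_right", D = "top_right")),
    fluid = list(side = "right", volume = 0),
    solve = list(frequency = 1e4, I0 = 1e-3, mode = "real",
                 solver = "direct", rel_tolerance = 1e-8),
    mesh = list(refinement_level = "normal"),
    protocol = list(
      offsets = seq(0, 0.10, by = 0.02),
      volumes = seq(0, 670e-6, length.out = 6),
      frequencies = c(5, 10, 50, 100, 200, 500, 1000) * 1e3,
      levels = c("coarser", "coarse", "normal", "fine")),
    output = list(dir = ".", log_level = "info")
  )
  class(cfg) <- "run_config"
  cfg
}

validate_against <- function(cfg, ref, path = "") {
  errs <- character(0)
  for (nm in names(cfg)) {
    key <- if (path == "") nm else paste0(path, ".", nm)
    if (!(nm %in% names(ref))) {
      errs <- c(errs, paste0("unknown key: ", key))
    } else if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]]))) {
      if (is.list(cfg[[nm]]))
        errs <- c(errs, validate_against(cfg[[nm]], ref[[nm]], key))
      else errs <- c(errs, paste0("key ", key, " must be a mapping"))
    }
  }
  errs
}

validate_config <- function(cfg) {
  errs <- validate_against(unclass(cfg), unclass(default_config()))
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(cfg$electrodes$separation > 0, "electrodes.separation must be > 0")
  chk(cfg$electrodes$diameter > 0, "electrodes.diameter must be > 0")
  chk(cfg$electrodes$side %in% c("left", "right"),
      "electrodes.side must be left or right")
  chk(cfg$fluid$side %in% c("left", "right"),
      "fluid.side must be left or right")
  chk(cfg$fluid$volume >= 0, "fluid.volume must be >= 0")
  chk(cfg$solve$I0 > 0, "solve.I0 must be > 0")
  chk(cfg$solve$mode %in% c("real", "complex"),
      "solve.mode must be real or complex")
  chk(cfg$solve$solver %in% c("direct", "iterative"),
      "solve.solver must be direct or iterative")
  chk(cfg$mesh$refinement_level %in% c("coarser", "coarse", "normal",
                                       "fine"),
      "mesh.refinement_level must be coarser/coarse/normal/fine")
  errs
}

## deep-merge user values onto the defaults
merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills unset keys with the defaults and
#' validates; an empty file yields the all-defaults configuration.  All
#' violations (unknown keys, out-of-range values) are reported together.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated `run_config`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  errs <- validate_against(user, unclass(default_config()))
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  cfg <- merge_config(unclass(default_config()), user)
  class(cfg) <- "run_config"
  errs <- validate_config(cfg)
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  cfg
}

#' @rdname load_config
#' @param cfg A `run_config`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Hash of a run configuration
#'
#' MD5 over the canonical serialisation; identical hashes imply identical
#' result tables for the deterministic pipeline.
#'
#' @param cfg A `run_config`.
#' @return Character scalar.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(unclass(cfg)), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

config_geometry <- function(cfg) {
  th <- cfg$thorax
  build_geometry(thorax_params(
    torso_semi_axis_x = th$torso_semi_axis_x,
    torso_semi_axis_y = th$torso_semi_axis_y,
    torso_height = th$torso_height,
    ribs_enabled = th$ribs_enabled,
    rib_count_pairs = th$rib_count_pairs,
    airways_enabled = th$airways_enabled,
    target_thorax_volume = th$target_thorax_volume,
    target_lung_volume_total = th$target_lung_volume_total))
}

config_solve_spec <- function(cfg)
  solve_spec(frequency = cfg$solve$frequency, I0 = cfg$solve$I0,
             mode = cfg$solve$mode, solver = cfg$solve$solver,
             rel_tolerance = cfg$solve$rel_tolerance)

#' Run a pipeline subcommand
#'
#' Dispatches the experiment drivers under shell-style subcommands:
#' `build-geometry`, `solve`, `sweep-vertical`, `sweep-volume`,
#' `sweep-frequency`, `convergence`, `sensitivity-map`.  Artifacts
#' (delimited result tables, VTK exports, a run log echoing the full
#' configuration) are written to the output directory.
#'
#' Intended for use as
#' `Rscript -e 'thoraximp::run_command(commandArgs(TRUE))' <subcommand> ...`.
#'
#' @param argv Character vector: subcommand followed by options
#'   `--config <yaml>` and/or `--out-dir <dir>`.
#' @return Integer exit status, invisibly (0 on success); artifacts on
#'   disk.
#' @export
run_command <- function(argv = character()) {
  usage <- paste(
    "usage: <subcommand> [--config file.yaml] [--out-dir dir]",
    "subcommands: build-geometry solve sweep-vertical sweep-volume",
    "             sweep-frequency convergence sensitivity-map", sep = "\n")
  subcommands <- c("build-geometry", "solve", "sweep-vertical",
                   "sweep-volume", "sweep-frequency", "convergence",
                   "sensitivity-map")
  if (length(argv) == 0 || !(argv[1] %in% subcommands)) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- argv[1]
  opt <- function(flag, default) {
    i <- which(argv == flag)
    if (length(i) && i[1] < length(argv)) argv[i[1] + 1] else default
  }
  status <- tryCatch({
    cfg <- load_config(opt("--config", NULL))
    out_dir <- opt("--out-dir", cfg$output$dir)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    logf <- file.path(out_dir, paste0(cmd, ".log"))
    logcon <- file(logf, "w")
    on.exit(close(logcon), add = TRUE)
    log <- function(...) writeLines(paste0(...), logcon)
    log("thoraximp ", as.character(utils::packageVersion("thoraximp")),
        " | ", R.version.string)
    log("subcommand: ", cmd, " | config hash: ", config_hash(cfg))
    log(yaml::as.yaml(unclass(cfg)))

    geom <- config_geometry(cfg)
    spec <- config_solve_spec(cfg)
    lev <- cfg$mesh$refinement_level
    side <- cfg$electrodes$side
    tag <- function(stub) file.path(out_dir, paste0(
      stub, "_", side,
      if (cfg$fluid$volume > 0) sprintf("_fluid%.0fml", cfg$fluid$volume * 1e6)
      else "_baseline", ".tsv"))

    if (cmd == "build-geometry") {
      m <- generate_mesh(place_electrode_array(
        geom, side, cfg$electrodes$vertical_offset,
        cfg$electrodes$separation, cfg$electrodes$diameter), lev)
      log("mesh: ", nrow(m$elems), " tets, ", nrow(m$nodes), " nodes")
      vols <- region_volumes(m)
      utils::write.table(data.frame(region = names(vols),
                                    volume_m3 = as.numeric(vols),
                                    config_hash = config_hash(cfg)),
                         file.path(out_dir, "region_volumes.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      write_vtk(m, file.path(out_dir, "thorax_mesh.vtk"))
    } else if (cmd == "solve" || cmd == "sensitivity-map") {
      if (cfg$fluid$volume > 0)
        geom <- carve_fluid_region(geom, cfg$fluid$side, cfg$fluid$volume)
      g <- place_electrode_array(geom, side,
                                 cfg$electrodes$vertical_offset,
                                 cfg$electrodes$separation,
                                 cfg$electrodes$diameter)
      r <- thorax_impedance(g, spec, lev)
      log("mesh: ", nrow(r$mesh$elems), " tets; residual drive ",
          format(r$sol_drive$residual), ", sense ",
          format(r$sol_sense$residual))
      contrib <- vapply(c("lung_left", "lung_right", "heart", "rib",
                          "fluid", "soft_tissue"),
                        function(l) Re(regional_contribution(r$field, l)), 0)
      utils::write.table(
        data.frame(quantity = c("Z_ohm", paste0("contrib_", names(contrib))),
                   value = c(r$Z, as.numeric(contrib)),
                   config_hash = config_hash(cfg)),
        tag("impedance"), sep = "\t", row.names = FALSE, quote = FALSE)
      if (cmd == "sensitivity-map") {
        for (d in c(0.06, 0.08)) {
          mp <- planar_sensitivity_map(r$field, g, d)
          write_planar_map(mp, file.path(out_dir,
                                         sprintf("map_depth%.0fcm.tsv",
                                                 d * 100)))
          log(sprintf("planar average at %.0f cm: %.4g Ohm/m^3", d * 100,
                      mp$planar_average))
        }
        write_vtk(r$mesh, file.path(out_dir, "sensitivity.vtk"),
                  point_data = list(V = r$sol_drive$V),
                  cell_data = list(z = r$field$z,
                                   Jmag = sqrt(rowSums(Mod(r$sol_drive$J)^2))))
      }
    } else if (cmd == "sweep-vertical") {
      if (cfg$fluid$volume > 0)
        geom <- carve_fluid_region(geom, cfg$fluid$side, cfg$fluid$volume)
      sw <- vertical_sweep(geom, side, cfg$protocol$offsets, spec, lev,
                           cfg$electrodes$separation,
                           cfg$electrodes$diameter)
      write_sweep_table(sw, tag("sweep_vertical"), cfg)
    } else if (cmd == "sweep-volume") {
      sw <- fluid_volume_sweep(geom, cfg$fluid$side, cfg$protocol$volumes,
                               spec, lev)
      write_sweep_table(sw, tag("sweep_volume"), cfg)
      ft <- linear_fit_volume(sw)
      log(sprintf("fit: slope %.2f mOhm/100mL, r^2 %.5f",
                  ft$slope_mohm_per_100ml, ft$r_squared))
      utils::write.table(
        data.frame(slope_ohm_per_m3 = ft$slope_ohm_per_m3,
                   slope_mohm_per_100ml = ft$slope_mohm_per_100ml,
                   intercept = ft$intercept, r_squared = ft$r_squared,
                   config_hash = config_hash(cfg)),
        file.path(out_dir, paste0("fit_", side, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
    } else if (cmd == "sweep-frequency") {
      sw <- frequency_sweep(geom, side, cfg$fluid$volume,
                            cfg$protocol$frequencies, lev, cfg$solve$I0)
      write_sweep_table(sw, tag("sweep_frequency"), cfg)
    } else if (cmd == "convergence") {
      st <- mesh_convergence_study(geom, side, cfg$protocol$levels, spec)
      st$table$config_hash <- config_hash(cfg)
      utils::write.table(st$table, file.path(out_dir, "convergence.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      log(sprintf("max deviation %.4f%%, normal-vs-fine %.4f%%",
                  100 * st$stats$max_deviation,
                  100 * st$stats$normal_vs_fine))
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
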