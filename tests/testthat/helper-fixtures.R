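## Shared, lazily-built fixtures.  Everything is deterministic, so caching
## across test files is safe and avoids recomputing the heavy solves.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- expr
  .fixtures[[name]]
}

default_geom <- function() fx("default_geom", build_geometry(thorax_params()))

geom_right <- function() fx("geom_right",
                            place_electrode_array(default_geom(), "right"))

## coarser thorax mesh with the right-side array (shared by several files)
mesh_coarser <- function() fx("mesh_coarser",
                              generate_mesh(geom_right(), "coarser"))

mesh_normal <- function() fx("mesh_normal",
                             generate_mesh(geom_right(), "normal"))

## small homogeneous bar with full end-face electrodes (exact resistor)
bar_mesh <- function() fx("bar_mesh",
                          box_mesh(0.05, 0.04, 0.2, 0.012,
                                   end_electrodes = TRUE))

bar_system <- function() fx("bar_system",
                            assemble_system(bar_mesh(),
                                            spec = solve_spec(mode = "real")))

BAR_SIGMA <- 0.18233
BAR_R <- 0.2 / (BAR_SIGMA * 0.05 * 0.04)

## small box with a symmetric square four-electrode array on top
square_box <- function() fx("square_box", {
  s <- 0.06
  el <- data.frame(label = c("A", "B", "C", "D"),
                   cx = 0.15 + c(-s / 2, -s / 2, s / 2, s / 2),
                   cy = 0.15 + c(-s / 2, s / 2, -s / 2, s / 2),
                   radius = 0.004)
  box_mesh(0.3, 0.3, 0.12, 0.03, electrodes = el, h_band = 0.002,
           h_top = 0.002)
})

square_box_system <- function() fx("square_box_system",
                                   assemble_system(square_box(),
                                                   spec = solve_spec()))

## one solved thorax configuration on the coarser mesh (baseline)
thorax_coarser_run <- function() fx("thorax_coarser_run",
                                    thorax_impedance(geom_right(),
                                                     solve_spec(),
                                                     mesh = mesh_coarser()))
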