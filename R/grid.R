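#' Compartment lattice geometry
#'
#' Defines the simulation reaction volume as a 2-D lattice of cubic
#' compartments, one compartment thick (a slab). The default matches the
#' simulation geometry used throughout the package: a 16 x 16 x 1 lattice of
#' 500 nm compartments, i.e. an 8 um x 8 um x 0.5 um slab.
#'
#' @param nx,ny Number of compartments along x and y.
#' @param compartment_edge Compartment edge length in nm.
#' @param slab_height Slab thickness in nm (one compartment thick).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec()
#' grid_volume_l(g)  # litres
#' @export
grid_spec <- function(nx = 16L, ny = 16L, compartment_edge = 500,
                      slab_height = 500) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(nx >= 1L, ny >= 1L, compartment_edge > 0, slab_height > 0)
  structure(
    list(nx = nx, ny = ny, compartment_edge = compartment_edge,
         slab_height = slab_height),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Compartment grid: %d x %d x 1, edge %g nm, slab %g nm\n",
              x$nx, x$ny, x$compartment_edge, x$slab_height))
  cat(sprintf("  total volume: %.4g um^3 (%.4g L)\n",
              grid_volume_l(x) * 1e15, grid_volume_l(x)))
  invisible(x)
}

#' Total lattice volume in litres
#'
#' @param grid A [grid_spec()].
#' @return Volume in litres (1 nm^3 = 1e-24 L).
#' @export
grid_volume_l <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  grid$nx * grid$ny * grid$compartment_edge^2 * grid$slab_height * 1e-24
}

#' Single-compartment volume in litres
#' @param grid A [grid_spec()].
#' @export
compartment_volume_l <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  grid$compartment_edge^2 * grid$slab_height * 1e-24
}

# Avogadro constant (1/mol), CODATA exact value.
AVOGADRO <- 6.02214076e23
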