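#' Can geometry
#'
#' Inner dimensions of a cylindrical tin can. The default is the #9121 can:
#' inner diameter 98.9 mm, inner height 121 mm, wall 0.2 mm, with a 5 mm
#' vapor headspace under the lid. The metal wall is treated as thermally
#' thin (it is not meshed); the inner surface takes the retort temperature
#' directly.
#'
#' @param inner_radius m. @param inner_height m. @param wall_thickness m.
#' @param headspace_height m; may be 0 for a completely filled can.
#' @return An object of class `can_geometry`.
#' @export
can_geometry <- function(inner_radius = 0.0989 / 2, inner_height = 0.121,
                         wall_thickness = 2e-4, headspace_height = 0.005) {
  stopifnot(inner_radius > 0, inner_height > 0, wall_thickness > 0,
            headspace_height >= 0, headspace_height < inner_height)
  structure(list(inner_radius = inner_radius, inner_height = inner_height,
                 wall_thickness = wall_thickness,
                 headspace_height = headspace_height),
            class = "can_geometry")
}

#' @export
print.can_geometry <- function(x, ...) {
  cat(sprintf("<can_geometry> R = %.4f m, H = %.4f m, wall %.2g m, headspace %.4f m\n",
              x$inner_radius, x$inner_height, x$wall_thickness, x$headspace_height))
  invisible(x)
}

#' Build an axisymmetric structured mesh for a can
#'
#' Uniform cell spacing in r (axis at r = 0) and z (can bottom at z = 0).
#' Cell volumes are exact cylindrical shells, `pi * (r_{i+1}^2 - r_i^2) * dz`,
#' so they sum to the cylinder volume to round-off. The headspace boundary is
#' snapped to the nearest cell edge and the realized headspace height is
#' reported via `message()`; the top rows are masked `"headspace"`, the rest
#' `"puree"`.
#'
#' @param geometry a [can_geometry()].
#' @param nr,nz radial and axial cell counts (each >= 4).
#' @return An object of class `axi_mesh` with edges, centers, cell volumes
#'   (nr x nz matrix) and the puree mask.
#' @examples
#' m <- build_mesh(can_geometry(), nr = 10, nz = 20)
#' sum(m$cell_volumes)   # pi R^2 H
#' @export
build_mesh <- function(geometry, nr = 24, nz = 48) {
  stopifnot(inherits(geometry, "can_geometry"))
  if (nr < 4 || nz < 4) stop("nr and nz must both be >= 4", call. = FALSE)
  R <- geometry$inner_radius; H <- geometry$inner_height
  dr <- R / nr; dz <- H / nz
  r_edges <- seq(0, R, length.out = nr + 1L)
  z_edges <- seq(0, H, length.out = nz + 1L)
  r_c <- (r_edges[-1] + r_edges[-(nr + 1L)]) / 2
  z_c <- (z_edges[-1] + z_edges[-(nz + 1L)]) / 2
  n_hs <- as.integer(round(geometry$headspace_height / dz))
  if (geometry$headspace_height > 0 && n_hs == 0L)
    stop(sprintf(paste0("headspace (%.4g m) is thinner than half a cell row ",
                        "(dz = %.4g m); refine nz"),
                 geometry$headspace_height, dz), call. = FALSE)
  if (n_hs >= nz) stop("headspace cannot span the whole can", call. = FALSE)
  realized_headspace <- n_hs * dz
  if (abs(realized_headspace - geometry$headspace_height) > 1e-12)
    message(sprintf("headspace snapped to cell edge: requested %.4g m, realized %.4g m (%d row(s))",
                    geometry$headspace_height, realized_headspace, n_hs))
  shell <- pi * (r_edges[-1]^2 - r_edges[-(nr + 1L)]^2) * dz   # per radial ring
  cell_volumes <- matrix(shell, nrow = nr, ncol = nz)
  region <- matrix("puree", nrow = nr, ncol = nz)
  if (n_hs > 0L) region[, (nz - n_hs + 1L):nz] <- "headspace"
  structure(list(nr = as.integer(nr), nz = as.integer(nz),
                 r_edges = r_edges, z_edges = z_edges,
                 r_centers = r_c, z_centers = z_c, dr = dr, dz = dz,
                 cell_volumes = cell_volumes, region = region,
                 n_headspace_rows = n_hs, n_puree_rows = as.integer(nz - n_hs),
                 realized_headspace = realized_headspace,
                 geometry = geometry),
            class = "axi_mesh")
}

#' @export
print.axi_mesh <- function(x, ...) {
  cat(sprintf("<axi_mesh> %d x %d cells (dr = %.3g m, dz = %.3g m), %d headspace row(s)\n",
              x$nr, x$nz, x$dr, x$dz, x$n_headspace_rows))
  cat(sprintf("  total volume %.6g m^3, puree volume %.6g m^3\n",
              sum(x$cell_volumes), puree_volume(x)))
  invisible(x)
}

# logical nr x nz mask of puree cells
puree_mask <- function(mesh) mesh$region == "puree"

# total puree volume, m^3
puree_volume <- function(mesh) sum(mesh$cell_volumes[puree_mask(mesh)])

#' Volume-weighted mean of a cell field
#'
#' @param mesh an `axi_mesh`. @param field nr x nz matrix.
#' @param region `"all"`, `"puree"` or `"headspace"`.
#' @return scalar mean weighted by cylindrical cell volumes.
#' @export
volume_mean <- function(mesh, field, region = c("all", "puree", "headspace")) {
  region <- match.arg(region)
  m <- switch(region, all = matrix(TRUE, mesh$nr, mesh$nz),
              puree = puree_mask(mesh), headspace = !puree_mask(mesh))
  sum(field[m] * mesh$cell_volumes[m]) / sum(mesh$cell_volumes[m])
}
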