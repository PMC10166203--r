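#' Lethality (F-value) configuration
#'
#' Constants of the thermal-death-time model: the lethal rate at temperature
#' `T` (degC) is `10^((T - RT)/Z)` and the F value is its time integral in
#' minutes. Defaults are the low-acid canned food standard with Clostridium
#' botulinum as reference organism: `RT = 121.1` degC, `Z = 10` degC. The
#' overheat threshold (F > 25 min) is the browning proxy used for quality
#' assessment, and `target_F` is the commercial-sterility requirement the
#' cold point must reach.
#'
#' @param reference_temperature RT, degC. @param z_value Z, degC.
#' @param overheat_threshold min. @param target_F min.
#' @return An object of class `lethality_config`.
#' @export
lethality_config <- function(reference_temperature = 121.1, z_value = 10,
                             overheat_threshold = 25, target_F = 4.5) {
  stopifnot(reference_temperature > 0, z_value > 0, overheat_threshold > 0,
            target_F > 0)
  structure(list(reference_temperature = reference_temperature,
                 z_value = z_value,
                 overheat_threshold = overheat_threshold,
                 target_F = target_F),
            class = "lethality_config")
}

#' Lethal rate at a temperature
#'
#' `10^((T_degC - RT)/Z)`; equals 1 at the reference temperature and changes
#' tenfold per Z degrees.
#'
#' @param T temperature(s), K (vectorized; matrices allowed).
#' @param config a [lethality_config()].
#' @return dimensionless rate(s), same shape as `T`.
#' @examples
#' lethal_rate(394.25)  # 121.1 degC -> 1
#' @export
lethal_rate <- function(T, config = lethality_config()) {
  stopifnot(all(is.finite(T)))
  10^(((T - 273.15) - config$reference_temperature) / config$z_value)
}

#' Create an empty lethality field on a mesh
#'
#' @param mesh an `axi_mesh`.
#' @return An object of class `lethality_field` with zero accumulated F.
#' @export
lethality_field <- function(mesh) {
  structure(list(F = matrix(0, mesh$nr, mesh$nz),
                 mesh_dims = c(mesh$nr, mesh$nz),
                 F_min = 0, F_max = 0,
                 cold_point = c(r = mesh$r_centers[1], z = mesh$z_centers[1]),
                 oz_fraction = 0,
                 last_rate = NULL),
            class = "lethality_field")
}

#' Accumulate lethality from a temperature field over a time step
#'
#' Adds `lethal_rate(T) * dt / 60` minutes to every cell, using the
#' trapezoid rule between the previous and current temperature fields when
#' `T_prev` is supplied (the simulator always supplies it). Cold point,
#' F range and overheated fraction are refreshed over puree cells.
#'
#' @param field a [lethality_field()]. @param T_field nr x nz temperatures, K.
#' @param dt step length, s. @param mesh the `axi_mesh` the field lives on.
#' @param config a [lethality_config()].
#' @param T_prev optional temperature field at the start of the step.
#' @return the updated `lethality_field`.
#' @export
accumulate_lethality <- function(field, T_field, dt, mesh,
                                 config = lethality_config(), T_prev = NULL) {
  stopifnot(inherits(field, "lethality_field"), dt > 0)
  if (!all(dim(T_field) == field$mesh_dims))
    stop("temperature field does not match the lethality field's mesh", call. = FALSE)
  rate_new <- lethal_rate(T_field, config)
  rate_old <- if (!is.null(T_prev)) {
    if (!all(dim(T_prev) == field$mesh_dims))
      stop("T_prev does not match the lethality field's mesh", call. = FALSE)
    lethal_rate(T_prev, config)
  } else rate_new
  field$F <- field$F + (rate_new + rate_old) / 2 * dt / 60
  field$last_rate <- rate_new
  refresh_lethality_stats(field, mesh, config)
}

refresh_lethality_stats <- function(field, mesh, config) {
  pm <- puree_mask(mesh)
  field$F_min <- min(field$F[pm])
  field$F_max <- max(field$F[pm])
  cp <- cold_point(field, mesh)
  field$cold_point <- c(r = cp[["r"]], z = cp[["z"]])
  field$oz_fraction <- overheated_fraction(field, mesh, config$overheat_threshold)
  field
}

#' Locate the cold point (slowest heating zone)
#'
#' Cell-center coordinates of the minimum accumulated-F puree cell; ties are
#' broken deterministically toward the smallest z, then the smallest r.
#'
#' @param field a `lethality_field`. @param mesh the matching `axi_mesh`.
#' @return named numeric `c(r = , z = , F_min = )`.
#' @export
cold_point <- function(field, mesh) {
  pm <- puree_mask(mesh)
  if (!any(pm)) stop("mesh has no puree cells", call. = FALSE)
  Fp <- field$F
  Fp[!pm] <- Inf
  fmin <- min(Fp)
  idx <- which(Fp == fmin, arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]   # smallest z, then r
  i <- idx[1, 1]; j <- idx[1, 2]
  c(r = mesh$r_centers[i], z = mesh$z_centers[j], F_min = fmin)
}

#' Overheated puree-volume fraction
#'
#' Fraction of the puree volume whose accumulated F exceeds `threshold`
#' minutes; used as the browning proxy. The denominator is the puree volume
#' (headspace excluded).
#'
#' @param field a `lethality_field`. @param mesh the matching `axi_mesh`.
#' @param threshold min.
#' @return fraction in `[0, 1]`.
#' @export
overheated_fraction <- function(field, mesh, threshold = 25) {
  pm <- puree_mask(mesh)
  over <- pm & field$F > threshold
  sum(mesh$cell_volumes[over]) / sum(mesh$cell_volumes[pm])
}

#' @export
print.lethality_field <- function(x, ...) {
  cat(sprintf("<lethality_field> F_min %.3f min, F_max %.3f min, cold point (r = %.4f, z = %.4f) m, OZ %.2f%%\n",
              x$F_min, x$F_max, x$cold_point[["r"]], x$cold_point[["z"]],
              100 * x$oz_fraction))
  invisible(x)
}
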