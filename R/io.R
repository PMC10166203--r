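#' Read a can/process configuration file
#'
#' YAML configuration with `properties`, `geometry` and optional `schedule`
#' blocks. Property polynomial coefficients are listed highest order first
#' (constant term last) and every quantity carries a `units` annotation;
#' geometry accepts mm or m and is converted to m. See
#' `system.file("extdata", "chestnut_puree.yaml", package = "retortsim")`
#' for the shipped default.
#'
#' @param path YAML file path.
#' @return list with elements `properties` ([thermo_properties()]),
#'   `geometry` ([can_geometry()]) and, if present, `schedule`
#'   (a `retort_schedule`).
#' @export
read_can_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(cfg$properties)) {
    p <- cfg$properties
    need_units <- function(block, what) {
      if (is.null(block$units))
        stop(sprintf("config '%s' block lacks a units annotation", what),
             call. = FALSE)
      block
    }
    coef_desc <- function(block) rev(as.numeric(block$coefficients))
    out$properties <- thermo_properties(
      density_coeffs = coef_desc(need_units(p$density, "density")),
      viscosity_coeffs = coef_desc(need_units(p$viscosity, "viscosity")),
      conductivity_coeffs = coef_desc(need_units(p$conductivity, "conductivity")),
      specific_heat = need_units(p$specific_heat, "specific_heat")$value,
      valid_range = if (!is.null(p$valid_range_K)) as.numeric(p$valid_range_K)
        else c(303.15, 400.15),
      extrapolation_policy = if (!is.null(p$extrapolation_policy))
        p$extrapolation_policy else "extrapolate",
      name = if (!is.null(p$name)) p$name else "config")
  }
  if (!is.null(cfg$geometry)) {
    g <- cfg$geometry
    to_m <- function(block, what) {
      if (is.null(block$units))
        stop(sprintf("geometry '%s' lacks a units annotation", what), call. = FALSE)
      switch(block$units,
             mm = block$value / 1000, m = block$value,
             stop(sprintf("geometry '%s': unknown unit '%s'", what, block$units),
                  call. = FALSE))
    }
    out$geometry <- can_geometry(
      inner_radius = to_m(g$inner_diameter, "inner_diameter") / 2,
      inner_height = to_m(g$height, "height"),
      wall_thickness = to_m(g$wall_thickness, "wall_thickness"),
      headspace_height = to_m(g$headspace, "headspace"))
  }
  if (!is.null(cfg$schedule)) {
    s <- cfg$schedule
    out$schedule <- parse_schedule(
      s$notation,
      come_up_start = if (!is.null(s$come_up_start_C)) s$come_up_start_C + 273.15
        else 341.15,
      cooling_water = if (!is.null(s$cooling_water_C)) s$cooling_water_C + 273.15
        else 298.15)
  }
  out
}

#' Export cell fields as a legacy-VTK structured grid
#'
#' Writes an ASCII legacy VTK file (`STRUCTURED_POINTS`, r along x, z along
#' y) carrying one `CELL_DATA` scalar array per named field, for inspection
#' in ParaView or VisIt.
#'
#' @param mesh an `axi_mesh`.
#' @param fields named list of nr x nz matrices.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_vtk_fields <- function(mesh, fields, path) {
  stopifnot(inherits(mesh, "axi_mesh"), is.list(fields), length(names(fields)) > 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "axisymmetric can fields (r = x, z = y)",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", mesh$nr + 1L, mesh$nz + 1L),
               "ORIGIN 0 0 0",
               sprintf("SPACING %.9g %.9g 1", mesh$dr, mesh$dz),
               sprintf("CELL_DATA %d", mesh$nr * mesh$nz)), con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    stopifnot(all(dim(f) == c(mesh$nr, mesh$nz)))
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(format(as.vector(f), digits = 9, trim = TRUE), con)
  }
  invisible(path)
}

#' Export cell fields as long-format CSV
#'
#' One row per cell with its center coordinates, region and one column per
#' field.
#'
#' @param mesh an `axi_mesh`. @param fields named list of nr x nz matrices.
#' @param path output file (or `NULL` to just return the data.frame).
#' @return the data.frame, invisibly when written.
#' @export
write_fields_csv <- function(mesh, fields, path = NULL) {
  df <- data.frame(r = rep(mesh$r_centers, mesh$nz),
                   z = rep(mesh$z_centers, each = mesh$nr),
                   region = as.vector(mesh$region))
  for (nm in names(fields)) df[[nm]] <- as.vector(fields[[nm]])
  if (is.null(path)) return(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Summary JSON for a simulation
#'
#' Serializes the lethality block (F range, cold point, overheated volume
#' fraction, model constants) of a simulation result.
#'
#' @param result a [simulate_can()] result.
#' @param leth_config the [lethality_config()] used.
#' @param path output file (or `NULL` to return the JSON string).
#' @return the JSON string, invisibly when written.
#' @export
write_summary_json <- function(result, leth_config = lethality_config(),
                               path = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  leth <- result$lethality
  x <- list(F_min = leth$F_min, F_max = leth$F_max,
            cold_point_r_m = leth$cold_point[["r"]],
            cold_point_z_m = leth$cold_point[["z"]],
            oz_fraction = leth$oz_fraction,
            threshold = leth_config$overheat_threshold,
            RT_C = leth_config$reference_temperature,
            Z_C = leth_config$z_value,
            process_time_s = result$final_state$time,
            mode = result$mode)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
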