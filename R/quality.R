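#' Evaluate a retort schedule on the joint sterility/quality criteria
#'
#' Runs the full simulation under the given schedule and assembles a quality
#' report: cold-point lethality (F_min) against the commercial-sterility
#' target, the F range, and the overheated puree-volume fraction (the
#' F > threshold browning proxy).
#'
#' @param schedule a `retort_schedule`.
#' @param solver_config a [solver_config()].
#' @param leth_config a [lethality_config()].
#' @return An object of class `quality_report`.
#' @export
evaluate_schedule <- function(schedule, solver_config,
                              leth_config = lethality_config()) {
  res <- simulate_can(solver_config, schedule, leth_config = leth_config,
                      keep_snapshots = FALSE)
  leth <- res$lethality
  structure(list(schedule = schedule,
                 notation = if (is.na(schedule$notation))
                   format_schedule(schedule) else schedule$notation,
                 F_min = leth$F_min, F_max = leth$F_max,
                 cold_point = leth$cold_point,
                 oz_fraction = leth$oz_fraction,
                 overheat_threshold = leth_config$overheat_threshold,
                 target_F = leth_config$target_F,
                 meets_target = leth$F_min >= leth_config$target_F,
                 total_process_time = schedule$total_duration,
                 mesh_dims = c(solver_config$mesh$nr, solver_config$mesh$nz),
                 can = solver_config$mesh$geometry,
                 mode = solver_config$mode),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %s (%s mode)\n", x$notation, x$mode))
  cat(sprintf("  F_min %.2f min (target %.2f: %s), F_max %.2f min\n",
              x$F_min, x$target_F, if (x$meets_target) "met" else "NOT met",
              x$F_max))
  cat(sprintf("  cold point (r = %.4f, z = %.4f) m; overheated (F > %g) volume %.2f%%; %.0f s total\n",
              x$cold_point[["r"]], x$cold_point[["z"]], x$overheat_threshold,
              100 * x$oz_fraction, x$total_process_time))
  invisible(x)
}

#' Compare a candidate schedule against a baseline
#'
#' Computes the overheated-volume reduction
#' `100 * (1 - oz_candidate / oz_baseline)`, the cold-point lethality
#' difference and the process-time penalty, and flags sterilization
#' equivalence when the F_min difference is within 10 percent of the
#' baseline F_min.
#'
#' @param baseline,candidate `quality_report`s on the same can and mesh.
#' @param equivalence_band relative F_min band counted as "equivalent".
#' @return An object of class `comparison_report`.
#' @export
compare_schedules <- function(baseline, candidate, equivalence_band = 0.10) {
  stopifnot(inherits(baseline, "quality_report"), inherits(candidate, "quality_report"))
  if (!isTRUE(all.equal(unclass(baseline$can), unclass(candidate$can))) ||
      !all(baseline$mesh_dims == candidate$mesh_dims))
    stop("reports were produced on different geometries or meshes", call. = FALSE)
  oz_red <- if (baseline$oz_fraction > 0)
    100 * (1 - candidate$oz_fraction / baseline$oz_fraction) else NA_real_
  structure(list(baseline = baseline, candidate = candidate,
                 oz_reduction_percent = oz_red,
                 F_min_difference = candidate$F_min - baseline$F_min,
                 time_penalty = candidate$total_process_time -
                   baseline$total_process_time,
                 equivalent_lethality =
                   abs(candidate$F_min - baseline$F_min) <=
                     equivalence_band * baseline$F_min),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s vs %s\n",
              x$candidate$notation, x$baseline$notation))
  cat(sprintf("  overheated volume: %.2f%% -> %.2f%% (reduction %.1f%%)\n",
              100 * x$baseline$oz_fraction, 100 * x$candidate$oz_fraction,
              x$oz_reduction_percent))
  cat(sprintf("  F_min difference %+.2f min (%s); time penalty %+.0f s\n",
              x$F_min_difference,
              if (x$equivalent_lethality) "equivalent lethality" else "not equivalent",
              x$time_penalty))
  invisible(x)
}

#' Exhaustive schedule search under a sterility constraint
#'
#' Builds candidate schedules from hold temperatures and hold durations
#' (one- or two-stage), evaluates each by full simulation, keeps those whose
#' cold-point F meets the target, and ranks them by overheated volume
#' fraction, then by total process time (ties keep input order). Two-stage
#' candidates pair a hotter first hold with a cooler second hold
#' (`T1 > T2`) over all ordered duration pairs.
#'
#' @param hold_temps candidate hold temperatures, degC.
#' @param hold_times candidate hold durations, min.
#' @param stages 1 or 2.
#' @param solver_config a [solver_config()] (a coarse mesh keeps the sweep
#'   cheap).
#' @param leth_config a [lethality_config()]; its `target_F` is the
#'   feasibility constraint.
#' @param come_up_min,cool_min come-up and cooling durations, min.
#' @param budget maximum number of candidates evaluated.
#' @return An object of class `schedule_ranking`: a summary data.frame
#'   (`$summary`) of feasible schedules in rank order plus all reports
#'   (`$reports`). Empty, with a warning, when nothing is feasible.
#' @export
grid_search_schedules <- function(hold_temps, hold_times, stages = 1,
                                  solver_config,
                                  leth_config = lethality_config(),
                                  come_up_min = 10, cool_min = 24,
                                  budget = 64) {
  stopifnot(length(hold_temps) >= 1, length(hold_times) >= 1,
            stages %in% c(1, 2))
  cands <- character(0)
  if (stages == 1) {
    for (tm in hold_times) for (Tc in hold_temps)
      cands <- c(cands, sprintf("%g-%g-%g/%g", come_up_min, tm, cool_min, Tc))
  } else {
    for (t1 in hold_times) for (t2 in hold_times)
      for (T1 in hold_temps) for (T2 in hold_temps)
        if (T1 > T2)
          cands <- c(cands, sprintf("%g-%g-%g-%g/%g-%g",
                                    come_up_min, t1, t2, cool_min, T1, T2))
  }
  if (length(cands) > budget)
    stop(sprintf("%d candidates exceed the budget of %d", length(cands), budget),
         call. = FALSE)
  reports <- lapply(cands, function(s)
    evaluate_schedule(parse_schedule(s), solver_config, leth_config))
  feasible <- vapply(reports, `[[`, logical(1), "meets_target")
  if (!any(feasible)) {
    warning("no candidate schedule meets the cold-point F target", call. = FALSE)
    ranked <- list()
  } else {
    keep <- reports[feasible]
    oz <- vapply(keep, `[[`, numeric(1), "oz_fraction")
    tt <- vapply(keep, `[[`, numeric(1), "total_process_time")
    ranked <- keep[order(oz, tt)]   # order() is stable: input order breaks ties
  }
  summary <- if (length(ranked)) data.frame(
    rank = seq_along(ranked),
    schedule = vapply(ranked, `[[`, character(1), "notation"),
    F_min = vapply(ranked, `[[`, numeric(1), "F_min"),
    F_max = vapply(ranked, `[[`, numeric(1), "F_max"),
    oz_percent = 100 * vapply(ranked, `[[`, numeric(1), "oz_fraction"),
    total_time_s = vapply(ranked, `[[`, numeric(1), "total_process_time"))
  else data.frame(rank = integer(0), schedule = character(0),
                  F_min = numeric(0), F_max = numeric(0),
                  oz_percent = numeric(0), total_time_s = numeric(0))
  structure(list(summary = summary, reports = reports,
                 candidates = cands, feasible = feasible),
            class = "schedule_ranking")
}

#' @export
print.schedule_ranking <- function(x, ...) {
  cat(sprintf("<schedule_ranking> %d candidate(s), %d feasible\n",
              length(x$candidates), sum(x$feasible)))
  if (nrow(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}
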