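#' Parse retort-program notation into a schedule
#'
#' Canning practice writes a retort program as
#' `"d1-d2-...-dn/T1-...-T(n-2)"`: come-up of `d1` minutes ramping to the
#' first hold temperature, holds of `d2 ... d(n-1)` minutes at `T1 ...
#' T(n-2)` degC, and cooling over `dn` minutes. `"10-86-24/121"` is a 10 min
#' come-up to 121 degC, an 86 min hold, and 24 min of cooling;
#' `"10-65-48-14/118-110"` stacks two holds (65 min at 118 degC, then 48 min
#' at 110 degC).
#'
#' The come-up is a linear ramp from `come_up_start`; cooling is a linear
#' ramp from the last hold temperature down to `cooling_water`; a transition
#' between stacked holds is a ramp over `transition_width` seconds at the
#' start of the later hold.
#'
#' @param notation schedule string (durations in minutes, temperatures degC).
#' @param come_up_start retort temperature at t = 0, K (default: the 68 degC
#'   initial product temperature).
#' @param cooling_water cooling-water temperature, K.
#' @param transition_width smoothing width for hold-to-hold steps, s.
#' @return An object of class `retort_schedule`.
#' @examples
#' s <- parse_schedule("10-86-24/121")
#' retort_temperature(s, c(0, 300, 600, 3600, 7200))
#' @export
parse_schedule <- function(notation, come_up_start = 341.15,
                           cooling_water = 298.15, transition_width = 1) {
  stopifnot(is.character(notation), length(notation) == 1L)
  halves <- strsplit(trimws(notation), "/", fixed = TRUE)[[1]]
  if (length(halves) != 2L)
    stop(sprintf("cannot parse schedule '%s': expected one '/'", notation), call. = FALSE)
  durs <- suppressWarnings(as.numeric(strsplit(halves[1], "-", fixed = TRUE)[[1]]))
  temps_C <- suppressWarnings(as.numeric(strsplit(halves[2], "-", fixed = TRUE)[[1]]))
  if (anyNA(durs) || anyNA(temps_C))
    stop(sprintf("cannot parse schedule '%s': non-numeric token", notation), call. = FALSE)
  n <- length(durs)
  if (n < 3L)
    stop(sprintf("schedule '%s': need at least come-up, one hold and cooling (3 durations, got %d)",
                 notation, n), call. = FALSE)
  if (length(temps_C) != n - 2L)
    stop(sprintf("schedule '%s': %d durations require %d hold temperature(s), got %d",
                 notation, n, n - 2L, length(temps_C)), call. = FALSE)
  if (any(durs <= 0))
    stop(sprintf("schedule '%s': non-positive duration at position %d",
                 notation, which(durs <= 0)[1]), call. = FALSE)
  temps_K <- temps_C + 273.15
  if (any(temps_K <= cooling_water))
    stop(sprintf("schedule '%s': hold temperature at position %d is not above the cooling water",
                 notation, which(temps_K <= cooling_water)[1]), call. = FALSE)
  phases <- data.frame(
    kind = c("come_up", rep("hold", n - 2L), "cool"),
    duration_s = durs * 60,
    target_K = c(temps_K[1], temps_K, cooling_water))
  new_retort_schedule(phases, come_up_start, cooling_water, transition_width,
                      notation = notation)
}

new_retort_schedule <- function(phases, come_up_start, cooling_water,
                                transition_width = 1, notation = NA_character_) {
  stopifnot(phases$kind[1] == "come_up", phases$kind[nrow(phases)] == "cool")
  structure(list(phases = phases,
                 come_up_start = come_up_start,
                 cooling_water = cooling_water,
                 transition_width = transition_width,
                 total_duration = sum(phases$duration_s),
                 notation = notation),
            class = "retort_schedule")
}

#' Constant-temperature schedule
#'
#' Degenerate schedule holding a single temperature for a given duration
#' (zero-length come-up and cooling); handy for benchmarks against analytic
#' constant-wall solutions.
#'
#' @param temperature hold temperature, K. @param duration hold length, s.
#' @return A `retort_schedule`.
#' @export
constant_retort <- function(temperature, duration) {
  phases <- data.frame(kind = c("come_up", "hold", "cool"),
                       duration_s = c(0, duration, 0),
                       target_K = rep(temperature, 3))
  new_retort_schedule(phases, come_up_start = temperature,
                      cooling_water = temperature, transition_width = 0)
}

#' Format a schedule back to its notation
#'
#' Inverse of [parse_schedule()]: `format_schedule(parse_schedule(x)) == x`
#' for canonical notation strings.
#'
#' @param schedule a `retort_schedule`.
#' @return character notation string.
#' @export
format_schedule <- function(schedule) {
  ph <- schedule$phases
  durs <- ph$duration_s / 60
  holds <- ph$target_K[ph$kind == "hold"] - 273.15
  fmt <- function(x) sub("\\.?0+$", "", sprintf("%.4f", x))
  paste0(paste(vapply(durs, fmt, ""), collapse = "-"), "/",
         paste(vapply(holds, fmt, ""), collapse = "-"))
}

#' Retort (wall) temperature at time t
#'
#' Piecewise profile: linear during come-up and cooling, constant during
#' holds (with a short ramp of `transition_width` seconds where two holds at
#' different temperatures meet), continuous everywhere. Past the schedule
#' end the cooling-water temperature is returned.
#'
#' @param schedule a `retort_schedule` (or a `retort_log`, see
#'   [schedule_from_log()]).
#' @param t time(s) in seconds, vectorized; must be >= 0.
#' @return temperature(s) in K.
#' @export
retort_temperature <- function(schedule, t) UseMethod("retort_temperature")

#' @export
retort_temperature.retort_schedule <- function(schedule, t) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  ph <- schedule$phases
  starts <- cumsum(c(0, ph$duration_s[-nrow(ph)]))
  ends <- starts + ph$duration_s
  out <- rep(schedule$cooling_water, length(t))
  prev_target <- schedule$come_up_start
  for (p in seq_len(nrow(ph))) {
    dur <- ph$duration_s[p]
    if (dur <= 0) { prev_target <- ph$target_K[p]; next }
    # select t in [start, end); final phase end included below
    sel <- t >= starts[p] & (t < ends[p] | (p == nrow(ph) & t <= ends[p]))
    if (any(sel)) {
      tau <- t[sel] - starts[p]
      out[sel] <- switch(ph$kind[p],
        come_up = prev_target + (ph$target_K[p] - prev_target) * tau / dur,
        cool = prev_target + (schedule$cooling_water - prev_target) * tau / dur,
        hold = {
          w <- schedule$transition_width
          if (w > 0 && abs(ph$target_K[p] - prev_target) > 0) {
            ifelse(tau < w,
                   prev_target + (ph$target_K[p] - prev_target) * tau / w,
                   ph$target_K[p])
          } else rep(ph$target_K[p], length(tau))
        })
    }
    prev_target <- ph$target_K[p]
  }
  out
}

#' Replay a measured retort log as a boundary condition
#'
#' Wraps a measured (time, temperature) table; [retort_temperature()] then
#' interpolates it linearly, holding the last value past the end.
#'
#' @param times seconds, strictly increasing, starting at 0.
#' @param temperatures K, same length.
#' @return An object of class `retort_log` (also answers
#'   `retort_temperature()`).
#' @export
schedule_from_log <- function(times, temperatures) {
  stopifnot(length(times) == length(temperatures), length(times) >= 2,
            all(diff(times) > 0), times[1] == 0, all(is.finite(temperatures)))
  structure(list(times = as.numeric(times),
                 temperatures = as.numeric(temperatures),
                 total_duration = max(times),
                 cooling_water = temperatures[length(temperatures)]),
            class = "retort_log")
}

#' @export
retort_temperature.retort_log <- function(schedule, t) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  stats::approx(schedule$times, schedule$temperatures, xout = t,
                rule = 2)$y
}

#' @export
print.retort_schedule <- function(x, ...) {
  cat(sprintf("<retort_schedule> %s (total %.0f s)\n",
              if (is.na(x$notation)) "programmatic" else x$notation,
              x$total_duration))
  print(x$phases)
  invisible(x)
}
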