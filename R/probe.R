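#' Time-temperature probe series
#'
#' A thermal-penetration record at a fixed (r, z) position in the can: the
#' canonical probe position for validation runs is the axis, 18.8 mm above
#' the can bottom (the predicted slowest-heating zone height).
#'
#' @param times seconds, strictly increasing, starting at 0.
#' @param temperatures K, same length, finite.
#' @param position `c(r, z)` in m.
#' @param provenance `"simulated"`, `"synthetic"` or `"external"`.
#' @return An object of class `probe_series`.
#' @export
probe_series <- function(times, temperatures, position = c(0, 0.0188),
                         provenance = c("simulated", "synthetic", "external")) {
  provenance <- match.arg(provenance)
  stopifnot(length(times) == length(temperatures), length(times) >= 1)
  if (times[1] != 0 || (length(times) > 1 && any(diff(times) <= 0)))
    stop("times must start at 0 and increase strictly", call. = FALSE)
  if (any(!is.finite(temperatures)))
    stop("temperatures must be finite", call. = FALSE)
  structure(list(times = as.numeric(times),
                 temperatures = as.numeric(temperatures),
                 position = as.numeric(position), provenance = provenance),
            class = "probe_series")
}

#' Extract a probe series from a simulation result
#'
#' @param result a [simulate_can()] result run with probes.
#' @param probe probe index.
#' @return a [probe_series()] with provenance `"simulated"`.
#' @export
probe_from_simulation <- function(result, probe = 1L) {
  stopifnot(inherits(result, "simulation_result"), !is.null(result$probes))
  df <- result$probes[result$probes$probe == probe, ]
  if (!nrow(df)) stop("no such probe in the simulation result", call. = FALSE)
  probe_series(df$time_s, df$T_K,
               position = result$probe_positions[[probe]],
               provenance = "simulated")
}

#' Probe physics model: sensor lag and measurement noise
#'
#' First-order sensor lag with time constant `tau` plus i.i.d. Gaussian
#' reading noise of standard deviation `sigma`. The default `sigma` reflects
#' a fill-temperature tolerance of about +/- 0.5 degC on a 68 degC fill.
#'
#' @param sigma Gaussian noise s.d., K (>= 0).
#' @param tau sensor time constant, s (>= 0).
#' @param seed integer RNG seed for reproducible noise.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.25, tau = 5, seed = 1L) {
  stopifnot(sigma >= 0, tau >= 0)
  structure(list(sigma = sigma, tau = tau, seed = as.integer(seed)),
            class = "noise_model")
}

#' Synthesize a measured probe curve from a true one
#'
#' Emulates a physical penetration test: applies the first-order lag
#' `dT_m/dt = (T_true - T_m)/tau` with an exact exponential update per
#' sampling interval (treating the truth as piecewise linear), then adds
#' `N(0, sigma^2)` noise using the model's seed. With `sigma = 0, tau = 0`
#' the output equals the input.
#'
#' @param truth a [probe_series()].
#' @param noise a [noise_model()].
#' @return a `probe_series` with provenance `"synthetic"`.
#' @export
synthesize_probe <- function(truth, noise) {
  stopifnot(inherits(truth, "probe_series"), inherits(noise, "noise_model"))
  tt <- truth$times; Tt <- truth$temperatures
  n <- length(tt)
  Tm <- Tt
  if (noise$tau > 0 && n > 1) {
    for (k in 2:n) {
      dtk <- tt[k] - tt[k - 1]
      s <- (Tt[k] - Tt[k - 1]) / dtk          # local truth slope
      e <- exp(-dtk / noise$tau)
      # exact response of a first-order lag to a linear-in-time input
      Tm[k] <- Tt[k] - s * noise$tau +
        (Tm[k - 1] - Tt[k - 1] + s * noise$tau) * e
    }
  }
  if (noise$sigma > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(noise$seed)
    Tm <- Tm + stats::rnorm(n, 0, noise$sigma)
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }
  probe_series(tt, Tm, position = truth$position, provenance = "synthetic")
}

#' General-method (classical) F value of a probe series
#'
#' Trapezoidal integration of the lethal rate `10^((T - RT)/Z)` over the
#' recorded time-temperature curve, in minutes: the classical process
#' validation calculation applied to a penetration record.
#'
#' @param series a [probe_series()] with at least 2 samples.
#' @param config a [lethality_config()].
#' @return F in minutes.
#' @examples
#' s <- probe_series(c(0, 600), c(394.25, 394.25))
#' general_method_F(s)   # 10 minutes at the reference temperature
#' @export
general_method_F <- function(series, config = lethality_config()) {
  stopifnot(inherits(series, "probe_series"))
  tt <- series$times
  if (length(tt) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(diff(tt) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  rate <- lethal_rate(series$temperatures, config)
  sum(diff(tt) * (rate[-1] + rate[-length(rate)]) / 2) / 60
}

#' Compare a predicted and a measured probe curve
#'
#' Resamples the measured series onto the predicted time grid over the
#' overlapping time range by linear interpolation, and reports the RMSE and
#' maximum absolute deviation there, plus the general-method F value of each
#' curve over the overlap.
#'
#' @param predicted,measured [probe_series()] objects with overlapping times.
#' @param config a [lethality_config()].
#' @return list with `rmse` (K), `max_abs_dev` (K), `F_pred`, `F_meas`
#'   (min), `n_overlap`, `n_dropped` (measured samples outside the overlap).
#' @export
compare_probes <- function(predicted, measured, config = lethality_config()) {
  stopifnot(inherits(predicted, "probe_series"), inherits(measured, "probe_series"))
  lo <- max(min(predicted$times), min(measured$times))
  hi <- min(max(predicted$times), max(measured$times))
  if (hi <= lo) stop("probe series do not overlap in time", call. = FALSE)
  sel <- predicted$times >= lo & predicted$times <= hi
  tp <- predicted$times[sel]
  if (length(tp) < 2) stop("fewer than 2 predicted samples in the overlap", call. = FALSE)
  Tp <- predicted$temperatures[sel]
  Tmi <- stats::approx(measured$times, measured$temperatures, xout = tp)$y
  dev <- Tp - Tmi
  window <- function(s) {
    k <- s$times >= lo & s$times <= hi
    probe_series(s$times[k] - s$times[k][1], s$temperatures[k],
                 position = s$position, provenance = s$provenance)
  }
  n_dropped <- sum(measured$times < lo | measured$times > hi)
  if (n_dropped) message(sprintf("%d measured sample(s) outside the overlap ignored", n_dropped))
  list(rmse = sqrt(mean(dev^2)), max_abs_dev = max(abs(dev)),
       F_pred = general_method_F(window(predicted), config),
       F_meas = general_method_F(window(measured), config),
       n_overlap = length(tp), n_dropped = n_dropped)
}

#' @export
print.probe_series <- function(x, ...) {
  cat(sprintf("<probe_series> %s at (r = %.4g, z = %.4g) m, %d samples over %.0f s, T in [%.2f, %.2f] K\n",
              x$provenance, x$position[1], x$position[2], length(x$times),
              max(x$times), min(x$temperatures), max(x$temperatures)))
  invisible(x)
}
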