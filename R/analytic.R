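# first n positive zeros of J0, by Newton refinement of the McMahon estimate
bessel_j0_zeros <- function(n) {
  x <- (seq_len(n) - 0.25) * pi
  for (it in 1:5) x <- x + besselJ(x, 0) / besselJ(x, 1)   # J0' = -J1
  x
}

#' Analytic transient conduction in a finite cylinder
#'
#' Separable Fourier-Bessel series for a solid finite cylinder of radius `R`
#' and height `H` with constant thermal diffusivity `alpha`, uniform initial
#' temperature `T_0`, and all surfaces stepped to `T_wall` at t = 0:
#' the product of the infinite-cylinder (Bessel J0) and slab (odd sine)
#' solutions. Serves as the independent benchmark for the conduction mode of
#' the numerical solver.
#'
#' @param r,z position, m (vectorized together; `0 <= r <= R`, `0 <= z <= H`).
#' @param t time, s (scalar or vector recycled against positions).
#' @param alpha thermal diffusivity, m^2/s.
#' @param T_wall,T_0 wall and initial temperatures, K.
#' @param R,H cylinder radius and height, m.
#' @param n_terms series terms per direction (>= 1).
#' @return temperature(s), K.
#' @examples
#' analytic_cylinder_temperature(0, 0.0605, 1800, 1.4e-7, 394.15, 341.15,
#'                               0.04945, 0.121)
#' @export
analytic_cylinder_temperature <- function(r, z, t, alpha, T_wall, T_0, R, H,
                                          n_terms = 50) {
  stopifnot(n_terms >= 1, alpha > 0, R > 0, H > 0)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (any(r < 0 | r > R) || any(z < 0 | z > H))
    stop("point outside the cylinder", call. = FALSE)
  len <- max(length(r), length(z), length(t))
  r <- rep_len(r, len); z <- rep_len(z, len); t <- rep_len(t, len)
  lam <- bessel_j0_zeros(n_terms)
  crad <- 2 / (lam * besselJ(lam, 1))
  m <- seq(1, 2 * n_terms - 1, by = 2)
  cax <- 4 / (m * pi)
  out <- numeric(len)
  for (p in seq_len(len)) {
    Sr <- sum(crad * besselJ(lam * r[p] / R, 0) * exp(-lam^2 * alpha * t[p] / R^2))
    Sz <- sum(cax * sin(m * pi * z[p] / H) * exp(-(m * pi / H)^2 * alpha * t[p]))
    out[p] <- T_wall + (T_0 - T_wall) * Sr * Sz
  }
  out
}
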