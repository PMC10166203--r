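#' Solver configuration
#'
#' Bundles the mesh, puree property set, headspace properties and numerical
#' options for the transient thermal solver.
#'
#' Two modes are supported. In `"convection"` mode the incompressible
#' momentum equation with temperature-dependent viscosity and a
#' Boussinesq-type buoyancy source (full `rho(T)` in the gravity term,
#' constant reference density elsewhere) is advanced with implicit viscous
#' terms and a pressure projection on a staggered grid, and the energy
#' equation is advected by the resulting velocity with first-order upwind
#' fluxes. In `"conduction"` mode the velocity is identically zero and only
#' conjugate heat conduction is solved.
#'
#' @param mesh an [build_mesh()] mesh.
#' @param properties puree [thermo_properties()].
#' @param mode `"convection"` or `"conduction"`.
#' @param dt time step, s. Halved automatically (per step, up to 6 times)
#'   if the discrete maximum principle is violated.
#' @param gravity m/s^2.
#' @param initial_temperature uniform initial temperature, K; must lie in
#'   the property validity range.
#' @param snapshot_interval cadence of stored field snapshots, s.
#' @param headspace property set for the stagnant vapor headspace.
#' @param wall_bc `"dirichlet"` (inner surface at retort temperature;
#'   default), `"robin"` (external film with `film_coefficient`) or
#'   `"adiabatic"` (insulated; for conservation benchmarks).
#' @param film_coefficient W/(m^2 K), used when `wall_bc = "robin"`.
#' @param seed unused placeholder (the solver is deterministic; randomness
#'   lives in the probe noise generator).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(mesh, properties = chestnut_puree(),
                          mode = c("convection", "conduction"),
                          dt = 1, gravity = 9.81,
                          initial_temperature = 341.15,
                          snapshot_interval = 60,
                          headspace = headspace_vapor(),
                          wall_bc = c("dirichlet", "robin", "adiabatic"),
                          film_coefficient = Inf,
                          seed = NULL) {
  mode <- match.arg(mode)
  wall_bc <- match.arg(wall_bc)
  stopifnot(inherits(mesh, "axi_mesh"), inherits(properties, "thermo_properties"),
            dt > 0, snapshot_interval > 0)
  vr <- properties$valid_range
  if (initial_temperature < vr[1] || initial_temperature > vr[2])
    stop(sprintf("initial_temperature %.6g K outside property valid range [%.6g, %.6g] K",
                 initial_temperature, vr[1], vr[2]), call. = FALSE)
  if (wall_bc == "robin" && !(is.finite(film_coefficient) && film_coefficient > 0))
    stop("robin wall_bc requires a finite positive film_coefficient", call. = FALSE)
  structure(list(mesh = mesh, properties = properties, mode = mode, dt = dt,
                 gravity = gravity, initial_temperature = initial_temperature,
                 snapshot_interval = snapshot_interval, headspace = headspace,
                 wall_bc = wall_bc, film_coefficient = film_coefficient,
                 seed = seed, cache = new.env(parent = emptyenv())),
            class = "solver_config")
}

#' Uniform initial state
#'
#' Uniform temperature, zero velocity and zero (deviation) pressure, per the
#' uniform-initial-temperature assumption.
#'
#' @param config a [solver_config()].
#' @return An object of class `state_field` with fields `T` (nr x nz, K),
#'   `ur` ((nr+1) x nz, m/s on radial faces), `uz` (nr x (nz+1), m/s on
#'   axial faces), `P` (nr x nz, Pa) and `time` (s).
#' @export
initialize_state <- function(config) {
  stopifnot(inherits(config, "solver_config"))
  m <- config$mesh
  structure(list(T = matrix(config$initial_temperature, m$nr, m$nz),
                 ur = matrix(0, m$nr + 1L, m$nz),
                 uz = matrix(0, m$nr, m$nz + 1L),
                 P = matrix(0, m$nr, m$nz),
                 time = 0, div_rms = 0),
            class = "state_field")
}

#' @export
print.state_field <- function(x, ...) {
  cat(sprintf("<state_field> t = %.1f s, T in [%.2f, %.2f] K, peak speed %.3g m/s\n",
              x$time, min(x$T), max(x$T), peak_speed(x)))
  invisible(x)
}

#' Peak cell-centered speed of a state
#' @param state a `state_field`.
#' @return scalar, m/s.
#' @export
peak_speed <- function(state) {
  nr <- nrow(state$T); nz <- ncol(state$T)
  uc <- (state$ur[1:nr, , drop = FALSE] + state$ur[2:(nr + 1L), , drop = FALSE]) / 2
  wc <- (state$uz[, 1:nz, drop = FALSE] + state$uz[, 2:(nz + 1L), drop = FALSE]) / 2
  sqrt(max(uc^2 + wc^2))
}

# ---------------------------------------------------------------------------
# solver context: precomputed index tables and factorizations, cached in the
# config's environment so repeated advance()/simulate_can() calls reuse them
# ---------------------------------------------------------------------------
get_context <- function(config) {
  ctx <- get0("ctx", envir = config$cache, inherits = FALSE)
  if (is.null(ctx)) {
    ctx <- build_context(config)
    assign("ctx", ctx, envir = config$cache)
  }
  ctx
}

build_context <- function(config) {
  mesh <- config$mesh
  nr <- mesh$nr; nz <- mesh$nz; npz <- mesh$n_puree_rows
  dr <- mesh$dr; dz <- mesh$dz
  r_e <- mesh$r_edges; r_c <- mesh$r_centers
  lin <- function(i, j) i + (j - 1L) * nr
  ctx <- new.env(parent = emptyenv())
  ctx$nr <- nr; ctx$nz <- nz; ctx$npz <- npz
  ctx$dr <- dr; ctx$dz <- dz; ctx$r_e <- r_e; ctx$r_c <- r_c
  ctx$n <- nr * nz
  ctx$cells <- seq_len(nr * nz)
  ctx$pm <- puree_mask(mesh)
  ctx$pm_vec <- as.vector(ctx$pm)
  ctx$V <- as.vector(mesh$cell_volumes)
  ctx$Vp_mat <- mesh$cell_volumes[, seq_len(npz), drop = FALSE]
  ctx$arfA <- 2 * pi * r_e * dz            # radial face areas, by edge index
  ctx$az <- 2 * pi * r_c * dr              # axial face areas, by column

  # reference (Boussinesq) density and puree constants at the fill temperature
  pv <- eval_properties(config$properties, config$initial_temperature)
  ctx$rho_ref <- pv$density
  ctx$cp_p <- config$properties$specific_heat
  hs <- eval_properties(config$headspace, 373.15)
  ctx$k_hs <- hs$conductivity
  ctx$rhocp_hs <- hs$density * hs$specific_heat

  # --- energy face tables (all cells, conjugate puree + headspace) ---
  fi <- rep(2:nr, nz); fj <- rep(seq_len(nz), each = nr - 1L)
  ctx$rf_iL <- lin(fi - 1L, fj); ctx$rf_iH <- lin(fi, fj)
  ctx$rf_geo <- ctx$arfA[fi] / dr
  ctx$rf_A <- ctx$arfA[fi]
  ctx$rf_ur <- fi + (fj - 1L) * (nr + 1L)   # into the (nr+1) x nz ur array
  gi <- rep(seq_len(nr), nz - 1L); gj <- rep(2:nz, each = nr)
  ctx$zf_iL <- lin(gi, gj - 1L); ctx$zf_iH <- lin(gi, gj)
  ctx$zf_geo <- ctx$az[gi] / dz
  ctx$zf_A <- ctx$az[gi]
  ctx$zf_uz <- gi + (gj - 1L) * nr          # into the nr x (nz+1) uz array
  ctx$side_ids <- lin(rep(nr, nz), seq_len(nz))
  ctx$side_A <- rep(2 * pi * r_e[nr + 1L] * dz, nz)
  ctx$side_half <- dr / 2
  ctx$bot_ids <- lin(seq_len(nr), rep(1L, nr)); ctx$bot_A <- ctx$az
  ctx$top_ids <- lin(seq_len(nr), rep(nz, nr)); ctx$top_A <- ctx$az
  ctx$z_half <- dz / 2

  # --- u_r momentum table: faces i = 2..nr, j = 1..npz (puree only) ---
  iu <- rep(2:nr, npz); ju <- rep(seq_len(npz), each = nr - 1L)
  ctx$ur_iu <- iu; ctx$ur_ju <- ju; ctx$nur <- length(iu)
  ctx$ur_arr <- iu + (ju - 1L) * (nr + 1L)
  ctx$ur_cC <- lin(iu, ju); ctx$ur_cW <- lin(iu - 1L, ju)
  ctx$ur_east_ok <- iu < nr; ctx$ur_west_ok <- iu > 2L
  ctx$ur_up_ok <- ju < npz; ctx$ur_dn_ok <- ju > 1L
  ctx$ur_kE <- seq_along(iu) + 1L; ctx$ur_kW <- seq_along(iu) - 1L
  ctx$ur_kU <- seq_along(iu) + (nr - 1L); ctx$ur_kD <- seq_along(iu) - (nr - 1L)
  ctx$ur_gE <- r_c[iu] / (r_e[iu] * dr^2)
  ctx$ur_gW <- r_c[iu - 1L] / (r_e[iu] * dr^2)
  ctx$ur_rf2 <- r_e[iu]^2
  ctx$ur_cNE <- lin(iu, pmin(ju + 1L, npz)); ctx$ur_cNW <- lin(iu - 1L, pmin(ju + 1L, npz))
  ctx$ur_cSE <- lin(iu, pmax(ju - 1L, 1L)); ctx$ur_cSW <- lin(iu - 1L, pmax(ju - 1L, 1L))

  # --- u_z momentum table: faces i = 1..nr, j = 2..npz ---
  iz <- rep(seq_len(nr), npz - 1L); jz <- rep(2:npz, each = nr)
  ctx$uz_iz <- iz; ctx$uz_jz <- jz; ctx$nuz <- length(iz)
  ctx$uz_arr <- iz + (jz - 1L) * nr
  ctx$uz_cS <- lin(iz, jz - 1L); ctx$uz_cN <- lin(iz, jz)
  ctx$uz_up_ok <- jz < npz; ctx$uz_dn_ok <- jz > 2L
  ctx$uz_east_ok <- iz < nr; ctx$uz_west_ok <- iz > 1L
  ctx$uz_kU <- seq_along(iz) + nr; ctx$uz_kD <- seq_along(iz) - nr
  ctx$uz_kE <- seq_along(iz) + 1L; ctx$uz_kW <- seq_along(iz) - 1L
  ctx$uz_gE <- r_e[iz + 1L] / (r_c[iz] * dr^2)
  ctx$uz_gW <- r_e[iz] / (r_c[iz] * dr^2)
  ctx$uz_cSE <- lin(pmin(iz + 1L, nr), jz - 1L); ctx$uz_cNE <- lin(pmin(iz + 1L, nr), jz)
  ctx$uz_cSW <- lin(pmax(iz - 1L, 1L), jz - 1L); ctx$uz_cNW <- lin(pmax(iz - 1L, 1L), jz)

  # --- pressure Poisson operator over the puree block, factored once ---
  np <- nr * npz
  pf_i <- rep(2:nr, npz); pf_j <- rep(seq_len(npz), each = nr - 1L)
  pC <- ctx$arfA[pf_i] / dr
  pL <- (pf_i - 1L) + (pf_j - 1L) * nr; pH <- pf_i + (pf_j - 1L) * nr
  qf_i <- rep(seq_len(nr), npz - 1L); qf_j <- rep(2:npz, each = nr)
  qC <- ctx$az[qf_i] / dz
  qL <- qf_i + (qf_j - 2L) * nr; qH <- qf_i + (qf_j - 1L) * nr
  Lp <- Matrix::sparseMatrix(
    i = c(pL, pH, pL, pH, qL, qH, qL, qH),
    j = c(pL, pH, pH, pL, qL, qH, qH, qL),
    x = c(pC, pC, -pC, -pC, qC, qC, -qC, -qC),
    dims = c(np, np))
  Lp[1, ] <- 0; Lp[, 1] <- 0; Lp[1, 1] <- 1   # pin the reference cell
  ctx$chol_p <- Matrix::Cholesky(Matrix::forceSymmetric(Lp), LDL = FALSE)
  ctx$np <- np

  # constant-coefficient conduction admits a time-invariant energy matrix
  ctx$const_energy <- config$mode == "conduction" &&
    is_constant_props(config$properties)
  ctx
}

# harmonic mean of conductivities across a face
harm2 <- function(a, b) 2 * a * b / (a + b)

# boundary conductance per unit area for a half-cell of conductivity k,
# optionally behind an external film h (robin)
wall_conductance <- function(k, half, wall_bc, h) {
  if (wall_bc == "dirichlet") k / half else 1 / (1 / h + half / k)
}

energy_matrices <- function(Tn, ur, uz, dt, config, ctx, convective) {
  props <- config$properties
  pmv <- ctx$pm_vec
  Tv <- as.vector(Tn)
  kcell <- rep(ctx$k_hs, ctx$n)
  kcell[pmv] <- poly_eval(props$conductivity_coeffs, Tv[pmv])
  rhocp <- rep(ctx$rhocp_hs, ctx$n)
  rhocp[pmv] <- poly_eval(props$density_coeffs, Tv[pmv]) * ctx$cp_p
  ap0 <- ctx$V * rhocp / dt

  Gr <- ctx$rf_geo * harm2(kcell[ctx$rf_iL], kcell[ctx$rf_iH])
  Gz <- ctx$zf_geo * harm2(kcell[ctx$zf_iL], kcell[ctx$zf_iH])
  if (convective) {
    mr <- ctx$rho_ref * ctx$cp_p * ur[ctx$rf_ur] * ctx$rf_A
    mz <- ctx$rho_ref * ctx$cp_p * uz[ctx$zf_uz] * ctx$zf_A
  } else {
    mr <- numeric(length(Gr)); mz <- numeric(length(Gz))
  }
  if (config$wall_bc == "adiabatic") {
    bnd_ids <- integer(0); Gb <- numeric(0)
    bnd_sets <- list()
  } else {
    h <- config$film_coefficient
    Gb_side <- ctx$side_A * wall_conductance(kcell[ctx$side_ids], ctx$side_half,
                                             config$wall_bc, h)
    Gb_bot <- ctx$bot_A * wall_conductance(kcell[ctx$bot_ids], ctx$z_half,
                                           config$wall_bc, h)
    Gb_top <- ctx$top_A * wall_conductance(kcell[ctx$top_ids], ctx$z_half,
                                           config$wall_bc, h)
    bnd_ids <- c(ctx$side_ids, ctx$bot_ids, ctx$top_ids)
    Gb <- c(Gb_side, Gb_bot, Gb_top)
    # no duplicate ids within a set, so RHS adds can be vectorized per set
    bnd_sets <- list(list(ids = ctx$side_ids, G = Gb_side),
                     list(ids = ctx$bot_ids, G = Gb_bot),
                     list(ids = ctx$top_ids, G = Gb_top))
  }
  A <- Matrix::sparseMatrix(
    i = c(ctx$cells, ctx$rf_iL, ctx$rf_iH, ctx$rf_iL, ctx$rf_iH,
          ctx$zf_iL, ctx$zf_iH, ctx$zf_iL, ctx$zf_iH, bnd_ids),
    j = c(ctx$cells, ctx$rf_iL, ctx$rf_iH, ctx$rf_iH, ctx$rf_iL,
          ctx$zf_iL, ctx$zf_iH, ctx$zf_iH, ctx$zf_iL, bnd_ids),
    x = c(ap0,
          Gr + pmax(mr, 0), Gr + pmax(-mr, 0),
          -(Gr + pmax(-mr, 0)), -(Gr + pmax(mr, 0)),
          Gz + pmax(mz, 0), Gz + pmax(-mz, 0),
          -(Gz + pmax(-mz, 0)), -(Gz + pmax(mz, 0)),
          Gb),
    dims = c(ctx$n, ctx$n))
  list(A = A, ap0 = ap0, bnd_sets = bnd_sets)
}

energy_rhs <- function(ap0, Tn, bnd_sets, Twall) {
  b <- ap0 * as.vector(Tn)
  for (s in bnd_sets) b[s$ids] <- b[s$ids] + s$G * Twall
  b
}

energy_step <- function(Tn, ur, uz, Twall, dt, config, ctx, convective) {
  if (ctx$const_energy && !convective) {
    cache <- get0("energy_cache", envir = config$cache, inherits = FALSE)
    if (is.null(cache) || cache$dt != dt || cache$wall_bc != config$wall_bc) {
      em <- energy_matrices(Tn, ur, uz, dt, config, ctx, convective = FALSE)
      cache <- list(ch = Matrix::Cholesky(Matrix::forceSymmetric(em$A), LDL = FALSE),
                    ap0 = em$ap0, bnd_sets = em$bnd_sets,
                    dt = dt, wall_bc = config$wall_bc)
      assign("energy_cache", cache, envir = config$cache)
    }
    b <- energy_rhs(cache$ap0, Tn, cache$bnd_sets, Twall)
    return(matrix(as.numeric(Matrix::solve(cache$ch, b, system = "A")),
                  ctx$nr, ctx$nz))
  }
  em <- energy_matrices(Tn, ur, uz, dt, config, ctx, convective)
  b <- energy_rhs(em$ap0, Tn, em$bnd_sets, Twall)
  matrix(as.numeric(Matrix::solve(em$A, b)), ctx$nr, ctx$nz)
}

momentum_step <- function(Tn, ur, uz, P, dt, config, ctx) {
  props <- config$properties
  nr <- ctx$nr; npz <- ctx$npz; dr <- ctx$dr; dz <- ctx$dz
  Tp <- Tn[, seq_len(npz), drop = FALSE]
  mu <- matrix(poly_eval(props$viscosity_coeffs, as.vector(Tp)), nr, npz)
  rho <- matrix(poly_eval(props$density_coeffs, as.vector(Tp)), nr, npz)
  rho_bar <- sum(rho * ctx$Vp_mat) / sum(ctx$Vp_mat)
  rr <- ctx$rho_ref / dt
  g <- config$gravity

  # ---- radial momentum (u_r) ----
  muC <- mu[ctx$ur_cC]; muW <- mu[ctx$ur_cW]
  muU <- ifelse(ctx$ur_up_ok,
                0.25 * (muC + muW + mu[ctx$ur_cNE] + mu[ctx$ur_cNW]),
                0.5 * (muC + muW))
  muD <- ifelse(ctx$ur_dn_ok,
                0.25 * (muC + muW + mu[ctx$ur_cSE] + mu[ctx$ur_cSW]),
                0.5 * (muC + muW))
  cE <- ctx$ur_gE * muC
  cW <- ctx$ur_gW * muW
  cU <- ifelse(ctx$ur_up_ok, muU / dz^2, 2 * muU / dz^2)
  cD <- ifelse(ctx$ur_dn_ok, muD / dz^2, 2 * muD / dz^2)
  diag_r <- rr + cE + cW + cU + cD + 0.5 * (muC + muW) / ctx$ur_rf2
  kk <- seq_len(ctx$nur)
  Ar <- Matrix::sparseMatrix(
    i = c(kk, kk[ctx$ur_east_ok], kk[ctx$ur_west_ok],
          kk[ctx$ur_up_ok], kk[ctx$ur_dn_ok]),
    j = c(kk, ctx$ur_kE[ctx$ur_east_ok], ctx$ur_kW[ctx$ur_west_ok],
          ctx$ur_kU[ctx$ur_up_ok], ctx$ur_kD[ctx$ur_dn_ok]),
    x = c(diag_r, -cE[ctx$ur_east_ok], -cW[ctx$ur_west_ok],
          -cU[ctx$ur_up_ok], -cD[ctx$ur_dn_ok]),
    dims = c(ctx$nur, ctx$nur))
  rhs_r <- rr * ur[ctx$ur_arr] - (P[ctx$ur_cC] - P[ctx$ur_cW]) / dr
  ur_new <- ur
  ur_new[ctx$ur_arr] <- as.numeric(Matrix::solve(Ar, rhs_r))

  # ---- axial momentum (u_z) with buoyancy ----
  muS <- mu[ctx$uz_cS]; muN <- mu[ctx$uz_cN]
  muE <- 0.25 * (muS + muN + mu[ctx$uz_cSE] + mu[ctx$uz_cNE])
  muWc <- 0.25 * (muS + muN + mu[ctx$uz_cSW] + mu[ctx$uz_cNW])
  muEw <- 0.5 * (muS + muN)
  cU <- muN / dz^2
  cD <- muS / dz^2
  cE <- ifelse(ctx$uz_east_ok, ctx$uz_gE * muE, 2 * ctx$uz_gE * muEw)
  cW <- ifelse(ctx$uz_west_ok, ctx$uz_gW * muWc, 0)
  diag_z <- rr + cU + cD + cE + cW
  buoy <- (rho_bar - 0.5 * (rho[ctx$uz_cS] + rho[ctx$uz_cN])) * g
  kk <- seq_len(ctx$nuz)
  Az <- Matrix::sparseMatrix(
    i = c(kk, kk[ctx$uz_up_ok], kk[ctx$uz_dn_ok],
          kk[ctx$uz_east_ok], kk[ctx$uz_west_ok]),
    j = c(kk, ctx$uz_kU[ctx$uz_up_ok], ctx$uz_kD[ctx$uz_dn_ok],
          ctx$uz_kE[ctx$uz_east_ok], ctx$uz_kW[ctx$uz_west_ok]),
    x = c(diag_z, -cU[ctx$uz_up_ok], -cD[ctx$uz_dn_ok],
          -cE[ctx$uz_east_ok], -cW[ctx$uz_west_ok]),
    dims = c(ctx$nuz, ctx$nuz))
  rhs_z <- rr * uz[ctx$uz_arr] - (P[ctx$uz_cN] - P[ctx$uz_cS]) / dz + buoy
  uz_new <- uz
  uz_new[ctx$uz_arr] <- as.numeric(Matrix::solve(Az, rhs_z))

  # ---- pressure projection ----
  flux <- net_outflux(ur_new, uz_new, ctx)
  rhs_p <- -(ctx$rho_ref / dt) * as.vector(flux)
  rhs_p[1] <- 0
  phi <- as.numeric(Matrix::solve(ctx$chol_p, rhs_p, system = "A"))
  phim <- matrix(phi, nr, npz)
  corr <- dt / ctx$rho_ref
  ur_new[ctx$ur_arr] <- ur_new[ctx$ur_arr] -
    corr * (phim[ctx$ur_cC] - phim[ctx$ur_cW]) / dr
  uz_new[ctx$uz_arr] <- uz_new[ctx$uz_arr] -
    corr * (phim[ctx$uz_cN] - phim[ctx$uz_cS]) / dz
  P_new <- P
  P_new[, seq_len(npz)] <- P[, seq_len(npz)] + phim

  flux <- net_outflux(ur_new, uz_new, ctx)
  div <- as.vector(flux) / as.vector(ctx$Vp_mat)
  div_rms <- sqrt(sum(as.vector(ctx$Vp_mat) * div^2) / sum(ctx$Vp_mat))
  if (div_rms > 1e-6)
    stop(sprintf("pressure projection failed: divergence RMS %.3g 1/s exceeds 1e-6", div_rms),
         call. = FALSE)
  list(ur = ur_new, uz = uz_new, P = P_new, div_rms = div_rms)
}

# net volume outflux per puree cell, m^3/s (nr x npz matrix)
net_outflux <- function(ur, uz, ctx) {
  nr <- ctx$nr; npz <- ctx$npz
  urb <- ur[, seq_len(npz), drop = FALSE]
  uzb <- uz[, seq_len(npz + 1L), drop = FALSE]
  (urb[-1, , drop = FALSE] * ctx$arfA[-1] -
     urb[-(nr + 1L), , drop = FALSE] * ctx$arfA[-(nr + 1L)]) +
    (uzb[, -1, drop = FALSE] - uzb[, -(npz + 1L), drop = FALSE]) * ctx$az
}

step_once <- function(state, schedule, config, ctx, dt, depth = 0L) {
  t0 <- state$time
  Twall <- retort_temperature(schedule, t0 + dt)
  Tw0 <- retort_temperature(schedule, t0)
  convective <- config$mode == "convection"
  if (convective) {
    mom <- momentum_step(state$T, state$ur, state$uz, state$P, dt, config, ctx)
    ur <- mom$ur; uz <- mom$uz; P <- mom$P; div_rms <- mom$div_rms
  } else {
    ur <- state$ur; uz <- state$uz; P <- state$P; div_rms <- 0
  }
  Tn1 <- energy_step(state$T, ur, uz, Twall, dt, config, ctx, convective)
  tol <- 0.5
  lo <- min(min(state$T), Tw0, Twall) - tol
  hi <- max(max(state$T), Tw0, Twall) + tol
  if (config$wall_bc == "adiabatic") {
    lo <- min(state$T) - tol; hi <- max(state$T) + tol
  }
  if (min(Tn1) < lo || max(Tn1) > hi) {
    if (depth >= 6L)
      stop(sprintf(paste0("temperature outside maximum-principle bounds ",
                          "[%.2f, %.2f] K at t = %.1f s even at dt = %.4g s; ",
                          "reduce the base time step"), lo, hi, t0 + dt, dt),
           call. = FALSE)
    half <- step_once(state, schedule, config, ctx, dt / 2, depth + 1L)
    return(step_once(half, schedule, config, ctx, dt / 2, depth + 1L))
  }
  structure(list(T = Tn1, ur = ur, uz = uz, P = P, time = t0 + dt,
                 div_rms = div_rms),
            class = "state_field")
}

#' Advance the state by one time step
#'
#' One step of the coupled solver: implicit-viscous momentum with buoyancy,
#' pressure projection to the incompressibility tolerance, then the energy
#' equation advanced implicitly (conduction + upwind advection) with the
#' wall boundary at the retort temperature. In conduction mode the velocity
#' stages are skipped. The step is halved (recursively, up to 6 levels) if
#' the discrete maximum principle is violated.
#'
#' @param state a `state_field`. @param schedule a `retort_schedule`.
#' @param config the [solver_config()] (must match the state's mesh).
#' @return the advanced `state_field`.
#' @export
advance <- function(state, schedule, config) {
  stopifnot(inherits(state, "state_field"), inherits(config, "solver_config"))
  if (!all(dim(state$T) == c(config$mesh$nr, config$mesh$nz)))
    stop("state does not match the configured mesh", call. = FALSE)
  step_once(state, schedule, config, get_context(config), config$dt)
}

#' Run a full sterilization simulation
#'
#' Integrates from t = 0 to the end of the retort schedule, co-accumulating
#' the lethality field every step (trapezoid in time), recording
#' time-temperature series at the requested probe positions every step, and
#' storing field snapshots at the configured cadence.
#'
#' @param config a [solver_config()]. @param schedule a `retort_schedule`.
#' @param probes list of `c(r, z)` positions (m) inside the puree; each is
#'   sampled at the nearest cell center.
#' @param leth_config a [lethality_config()].
#' @param keep_snapshots set `FALSE` to skip storing field snapshots.
#' @return An object of class `simulation_result` with elements `lethality`
#'   (a `lethality_field`), `probes` (data.frame: `time_s`, `T_K`,
#'   `lethal_rate`, `F_cell_min`, `probe`), `snapshots`, `snapshot_times`,
#'   `schedule`, `mesh`, `final_state`, `runtime_s`.
#' @export
simulate_can <- function(config, schedule, probes = NULL,
                         leth_config = lethality_config(),
                         keep_snapshots = TRUE) {
  stopifnot(inherits(config, "solver_config"))
  t_start <- proc.time()[["elapsed"]]
  mesh <- config$mesh
  ctx <- get_context(config)
  state <- initialize_state(config)
  leth <- lethality_field(mesh)

  probe_cells <- NULL
  if (!is.null(probes)) {
    if (!is.list(probes)) probes <- list(probes)
    probe_cells <- vapply(probes, function(p) {
      i <- which.min(abs(mesh$r_centers - p[1]))
      j <- which.min(abs(mesh$z_centers - p[2]))
      if (mesh$region[i, j] != "puree")
        stop(sprintf("probe (%.4g, %.4g) m falls in the headspace", p[1], p[2]),
             call. = FALSE)
      i + (j - 1L) * mesh$nr
    }, integer(1))
  }
  np <- length(probe_cells)

  total <- schedule$total_duration
  nstep_max <- ceiling(total / config$dt) + 1L
  times <- numeric(nstep_max + 1L)
  probe_T <- if (np) matrix(NA_real_, nstep_max + 1L, np) else NULL
  probe_F <- if (np) matrix(NA_real_, nstep_max + 1L, np) else NULL
  if (np) { probe_T[1, ] <- state$T[probe_cells]; probe_F[1, ] <- 0 }

  snapshots <- list(); snapshot_times <- numeric(0)
  if (keep_snapshots) { snapshots[[1]] <- state; snapshot_times <- 0 }

  k <- 1L
  while (state$time < total - 1e-9) {
    dt_k <- min(config$dt, total - state$time)
    T_prev <- state$T
    state <- step_once(state, schedule, config, ctx, dt_k)
    leth <- accumulate_lethality(leth, state$T, dt_k, mesh, leth_config,
                                 T_prev = T_prev)
    k <- k + 1L
    times[k] <- state$time
    if (np) {
      probe_T[k, ] <- state$T[probe_cells]
      probe_F[k, ] <- leth$F[probe_cells]
    }
    if (keep_snapshots &&
        (floor(state$time / config$snapshot_interval) >
           floor(times[k - 1L] / config$snapshot_interval) ||
           state$time >= total - 1e-9)) {
      snapshots[[length(snapshots) + 1L]] <- state
      snapshot_times <- c(snapshot_times, state$time)
    }
  }
  times <- times[seq_len(k)]

  probe_df <- NULL
  if (np) {
    probe_df <- do.call(rbind, lapply(seq_len(np), function(p) {
      data.frame(time_s = times, T_K = probe_T[seq_len(k), p],
                 lethal_rate = lethal_rate(probe_T[seq_len(k), p], leth_config),
                 F_cell_min = probe_F[seq_len(k), p], probe = p)
    }))
  }
  structure(list(lethality = leth, probes = probe_df,
                 probe_positions = probes,
                 snapshots = snapshots, snapshot_times = snapshot_times,
                 schedule = schedule, mesh = mesh,
                 mode = config$mode, dt = config$dt,
                 final_state = state,
                 runtime_s = proc.time()[["elapsed"]] - t_start),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %s mode, %d x %d mesh, %.0f s of process (%.1f s wall clock)\n",
              x$mode, x$mesh$nr, x$mesh$nz, x$final_state$time, x$runtime_s))
  print(x$lethality)
  invisible(x)
}
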