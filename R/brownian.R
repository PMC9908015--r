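#' Medium description for Brownian dynamics
#'
#' @param viscosity Dynamic viscosity in Pa s (default water, 8.9e-4).
#' @param temperature Temperature in K (default 298).
#' @return An object of class `medium_spec`.
#' @export
medium_spec <- function(viscosity = 8.9e-4, temperature = 298) {
  stopifnot(viscosity > 0, temperature > 0)
  structure(list(viscosity = viscosity, temperature = temperature),
            class = "medium_spec")
}

#' Stokes-Einstein diffusion coefficient
#'
#' D = kT / (6 pi eta R) for a sphere of radius R = diameter/2.
#'
#' @param particle A [particle_spec()].
#' @param medium A [medium_spec()].
#' @return Diffusion coefficient in m^2/s.
#' @export
stokes_einstein <- function(particle = particle_spec(),
                            medium = medium_spec()) {
  r_m <- particle$diameter / 2 * 1e-9
  .kB * medium$temperature / (6 * pi * medium$viscosity * r_m)
}

#' Overdamped Brownian dynamics of the particle height
#'
#' Euler-Maruyama integration of dz = (D/kT) F(z) dt + sqrt(2 D dt) dW in
#' the potential of mean force, with constant (not height-hindered)
#' diffusion and reflecting boundaries at the film (z = 0) and at the
#' upper edge of the profile's sampled support (the potential is only
#' known where the equilibrium ensemble visited). The initial height is drawn
#' from the equilibrium density implied by the profile, so the trajectory
#' starts equilibrated. Forces are taken from a fine pre-tabulated lookup
#' of [force_at()] (0.01 nm resolution).
#'
#' @param profile An [invert_boltzmann()] energy profile.
#' @param particle A [particle_spec()] (sets D through Stokes-Einstein).
#' @param medium A [medium_spec()].
#' @param dt Time step in s (default 1e-8).
#' @param n_steps Number of steps (default 1e6, i.e. 10 ms simulated).
#' @param seed Integer RNG seed (required).
#' @return A `trajectory`: tibble with columns `time_s`, `z_nm`;
#'   attributes `dt`, `seed`, `diffusion_coefficient` (m^2/s).
#' @export
simulate_trajectory <- function(profile, particle = particle_spec(),
                                medium = medium_spec(),
                                dt = 1e-8, n_steps = 1e6, seed) {
  stopifnot(inherits(profile, "energy_profile"))
  if (missing(seed)) stop("an explicit integer `seed` is required", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  stopifnot(n_steps >= 1)
  n_steps <- as.integer(n_steps)

  D_m2 <- stokes_einstein(particle, medium)
  D <- D_m2 * 1e18                      # nm^2/s
  step_sd <- sqrt(2 * D * dt)           # nm
  bin_width <- attr(profile, "bin_width")
  if (step_sd > 5 * bin_width) {
    stop(sprintf(
      "unstable step: rms displacement %.3f nm exceeds 5 x bin width (%.3f nm); reduce dt",
      step_sd, bin_width), call. = FALSE)
  }

  # force lookup table, 0.01 nm resolution, padded above the support
  z_hi <- max(profile$z_nm) + 10 * bin_width
  dz_tab <- 0.01
  z_tab <- seq(0, z_hi, by = dz_tab)
  f_tab <- force_at(profile, z_tab)
  ng <- length(f_tab)

  set.seed(as.integer(seed))
  dens <- profile_density(profile)
  z0 <- sample(dens$z_nm, 1, prob = dens$density)
  noise <- stats::rnorm(n_steps, 0, step_sd)
  drift_scale <- D * dt                 # (D/kT) dt with F in kT/nm

  z <- numeric(n_steps)
  cur <- z0
  inv_dz <- 1 / dz_tab
  z_top <- max(profile$z_nm) + bin_width / 2  # upper edge of the sampled support
  for (i in seq_len(n_steps)) {
    idx <- as.integer(cur * inv_dz) + 1L
    if (idx > ng) idx <- ng
    cur <- cur + drift_scale * f_tab[idx] + noise[i]
    if (cur < 0) cur <- -cur            # reflecting film
    if (cur > z_top) cur <- 2 * z_top - cur  # reflect at the support edge
    if (cur < 0) cur <- 0
    z[i] <- cur
  }

  out <- tibble::tibble(time_s = dt * seq_len(n_steps), z_nm = z)
  attr(out, "dt") <- dt
  attr(out, "seed") <- as.integer(seed)
  attr(out, "diffusion_coefficient") <- D_m2
  class(out) <- c("trajectory", class(out))
  out
}

#' Height distribution of a trajectory
#'
#' @param traj A [simulate_trajectory()] trajectory (or data frame with
#'   `z_nm`).
#' @param bin_width Bin width in nm.
#' @param burn_in Fraction of initial samples to discard, in \[0, 1).
#' @return Tibble with `z_nm` (bin centers) and `density` (integrates
#'   to 1).
#' @export
trajectory_to_distribution <- function(traj, bin_width = 0.25, burn_in = 0) {
  if (!is.numeric(burn_in) || burn_in < 0 || burn_in >= 1) {
    stop("`burn_in` must lie in [0, 1)", call. = FALSE)
  }
  z <- traj$z_nm
  keep <- z[seq.int(floor(burn_in * length(z)) + 1, length(z))]
  if (length(keep) == 0) stop("burn-in discarded all samples", call. = FALSE)
  summarize_z(keep, bin_width = bin_width)$histogram
}
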