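#' Cavity specification
#'
#' A spherical observation volume of radius `R` acting as a passive probe
#' (no solvent interactions), optionally biased by a harmonic occupancy
#' umbrella `(k0/2) (n - n0)^2`.
#'
#' @param R cavity radius (Angstrom), > 0
#' @param k0 umbrella spring constant (kJ/mol per squared occupancy), >= 0;
#'   `k0 = 0` means an unbiased cavity
#' @param n0 umbrella center (occupancy at which the bias is minimal)
#' @return an object of class `cavity_spec`
#' @export
cavity_spec <- function(R, k0 = 0, n0 = 0) {
  stopifnot(R > 0, k0 >= 0)
  structure(list(R = R, k0 = k0, n0 = n0), class = "cavity_spec")
}

#' @export
print.cavity_spec <- function(x, ...) {
  cat(sprintf("cavity_spec: R = %.3f A, k0 = %.3f kJ/mol, n0 = %.1f\n",
              x$R, x$k0, x$n0))
  invisible(x)
}

#' Simulation configuration
#'
#' @param temperature temperature (K)
#' @param pressure pressure (atm)
#' @param n_particles number of solvent particles
#' @param solvent_model one of `"mw"`, `"ideal_gas"`, `"hard_sphere"`
#' @param seed integer RNG seed; every stream of the run derives from it
#' @param passes_equilibration,passes_production MC passes (one pass = one
#'   attempted move per particle); move sizes are tuned during equilibration
#'   only
#' @param volume_move_interval attempt a volume move every this many passes
#' @param target_acceptance tuning target for the move acceptance fraction
#' @param hs_diameter hard-sphere diameter (Angstrom), hard-sphere model only
#' @param init_density initial number density (1/A^3) used to size the box
#' @param sample_every record occupancy/volume/energy every this many passes
#' @param frame_every emit a configuration every this many passes (0 = none)
#' @param tune_every passes between step-size updates during equilibration
#' @param step_trans,step_cav initial displacement half-widths (Angstrom)
#' @param step_lnv initial log-volume half-width
#' @return an object of class `simulation_config`
#' @export
simulation_config <- function(temperature = 298.15, pressure = 1,
                              n_particles = 128,
                              solvent_model = c("mw", "ideal_gas",
                                                "hard_sphere"),
                              seed = 1L,
                              passes_equilibration = 200L,
                              passes_production = 1000L,
                              volume_move_interval = 5L,
                              target_acceptance = 0.3,
                              hs_diameter = 2.5,
                              init_density = 0.03333,
                              sample_every = 1L,
                              frame_every = 0L,
                              tune_every = 25L,
                              step_trans = 0.3,
                              step_cav = 0.3,
                              step_lnv = 0.02) {
  solvent_model <- match.arg(solvent_model)
  stopifnot(temperature > 0, n_particles >= 1,
            passes_equilibration >= 0, passes_production >= 0,
            target_acceptance > 0, target_acceptance < 1)
  structure(list(temperature = temperature, pressure = pressure,
                 n_particles = as.integer(n_particles),
                 solvent_model = solvent_model, seed = as.integer(seed),
                 passes_equilibration = as.integer(passes_equilibration),
                 passes_production = as.integer(passes_production),
                 volume_move_interval = as.integer(volume_move_interval),
                 target_acceptance = target_acceptance,
                 hs_diameter = hs_diameter, init_density = init_density,
                 sample_every = as.integer(sample_every),
                 frame_every = as.integer(frame_every),
                 tune_every = as.integer(tune_every),
                 step_trans = step_trans, step_cav = step_cav,
                 step_lnv = step_lnv),
            class = "simulation_config")
}

#' Cavity occupancy of a frame
#'
#' Counts particle centers whose minimum-image distance to the cavity center
#' is strictly less than `R` (a particle exactly at the boundary counts as
#' outside).
#'
#' @param frame a [solvent_frame()]
#' @param cavity a [cavity_spec()]
#' @return integer occupancy
#' @export
occupancy <- function(frame, cavity) {
  stopifnot(inherits(frame, "solvent_frame"), inherits(cavity, "cavity_spec"))
  if (nrow(frame$positions) == 0) return(0L)
  sum(min_image_dist(frame$positions, frame$cavity_center,
                     frame$box_lengths) < cavity$R)
}

#' Harmonic umbrella energy
#'
#' @param n occupancy (may be a vector)
#' @param cavity a [cavity_spec()]
#' @return `(k0/2) (n - n0)^2` in kJ/mol
#' @export
umbrella_energy <- function(n, cavity) {
  stopifnot(inherits(cavity, "cavity_spec"))
  0.5 * cavity$k0 * (n - cavity$n0)^2
}

#' Monte Carlo state for the R-level move operations
#'
#' A transparent (R-side) representation of the sampler state, used by the
#' single-move operations [displacement_move()], [cavity_move()] and
#' [volume_move()].  Production windows use the compiled engine in
#' [run_window()]; the R-level moves are the reference implementation.
#'
#' @param frame a [solvent_frame()]
#' @param model a [solvent_model()]
#' @param cavity a [cavity_spec()]
#' @param temperature temperature (K)
#' @param pressure pressure (atm)
#' @param step_trans,step_cav displacement half-widths (Angstrom)
#' @param step_vol_frac relative half-width of volume moves
#' @return an object of class `mc_state`
#' @export
mc_state <- function(frame, model, cavity, temperature = 298.15,
                     pressure = 1, step_trans = 0.3, step_cav = 0.3,
                     step_vol_frac = 0.05) {
  structure(list(frame = frame, model = model, cavity = cavity,
                 temperature = temperature, pressure = pressure,
                 step_trans = step_trans, step_cav = step_cav,
                 step_vol_frac = step_vol_frac,
                 energy = total_energy(frame, model),
                 n = occupancy(frame, cavity)),
            class = "mc_state")
}

#' Metropolis displacement move
#'
#' Attempts one single-particle displacement; acceptance uses the change in
#' interaction energy plus the umbrella term (the occupancy can change when
#' the particle crosses the cavity boundary).  Randomness is drawn from R's
#' RNG stream (seed with [set.seed()]).
#'
#' @param state an [mc_state()]
#' @param index particle to move; default a uniformly chosen one
#' @return list with `accepted` flag and updated `state`
#' @export
displacement_move <- function(state, index = NULL) {
  fr <- state$frame
  N <- nrow(fr$positions)
  i <- if (is.null(index)) sample.int(N, 1) else as.integer(index)
  newp <- fr$positions[i, ] + stats::runif(3, -1, 1) * state$step_trans
  newp <- newp %% fr$box_lengths
  dU <- delta_energy(fr, i, newp, state$model)
  inside <- function(p) sum((min_image_dist(matrix(p, 1), fr$cavity_center,
                                            fr$box_lengths) < state$cavity$R))
  dn <- inside(newp) - inside(fr$positions[i, ])
  dB <- umbrella_energy(state$n + dn, state$cavity) -
    umbrella_energy(state$n, state$cavity)
  beta <- 1 / kBT(state$temperature)
  arg <- -beta * (dU + dB)
  accepted <- is.finite(arg) && (arg >= 0 || stats::runif(1) < exp(arg))
  if (accepted) {
    state$frame$positions[i, ] <- newp
    state$energy <- state$energy + dU
    state$n <- state$n + dn
  }
  list(accepted = accepted, state = state)
}

#' Metropolis cavity move
#'
#' Displaces the (passive) cavity center; the acceptance test involves only
#' the umbrella-energy change since the cavity has no solvent interactions.
#'
#' @param state an [mc_state()]
#' @return list with `accepted` flag and updated `state`
#' @export
cavity_move <- function(state) {
  fr <- state$frame
  newc <- (fr$cavity_center + stats::runif(3, -1, 1) * state$step_cav) %%
    fr$box_lengths
  fr2 <- fr
  fr2$cavity_center <- newc
  n_new <- occupancy(fr2, state$cavity)
  beta <- 1 / kBT(state$temperature)
  dB <- umbrella_energy(n_new, state$cavity) -
    umbrella_energy(state$n, state$cavity)
  arg <- -beta * dB
  accepted <- arg >= 0 || stats::runif(1) < exp(arg)
  if (accepted) {
    state$frame <- fr2
    state$n <- n_new
  }
  list(accepted = accepted, state = state)
}

#' Metropolis volume move
#'
#' Isotropic box rescale with the standard NPT acceptance rule, including
#' the `N log(V'/V)` entropy term and a re-evaluated umbrella term (the
#' occupancy can change on rescale since the cavity radius is fixed).
#'
#' @param state an [mc_state()]
#' @return list with `accepted` flag and updated `state`
#' @export
volume_move <- function(state) {
  fr <- state$frame
  N <- nrow(fr$positions)
  V <- prod(fr$box_lengths)
  Vnew <- V * (1 + stats::runif(1, -1, 1) * state$step_vol_frac)
  if (Vnew <= 0) return(list(accepted = FALSE, state = state))
  s <- (Vnew / V)^(1 / 3)
  cutoff <- interaction_cutoff(state$model)
  if (cutoff > 0 && min(fr$box_lengths * s) < 2 * cutoff)
    return(list(accepted = FALSE, state = state))
  fr2 <- solvent_frame(fr$positions * s, fr$box_lengths * s,
                       fr$cavity_center * s)
  Unew <- total_energy(fr2, state$model)
  if (!is.finite(Unew)) return(list(accepted = FALSE, state = state))
  n_new <- occupancy(fr2, state$cavity)
  beta <- 1 / kBT(state$temperature)
  p_kj <- state$pressure * ATM_TO_KJ_MOL_A3
  arg <- N * log(Vnew / V) - beta * p_kj * (Vnew - V) -
    beta * (Unew - state$energy) -
    beta * (umbrella_energy(n_new, state$cavity) -
              umbrella_energy(state$n, state$cavity))
  accepted <- arg >= 0 || stats::runif(1) < exp(arg)
  if (accepted) {
    state$frame <- fr2
    state$energy <- Unew
    state$n <- n_new
  }
  list(accepted = accepted, state = state)
}

init_lattice <- function(n_particles, density, seed) {
  V <- n_particles / density
  L <- V^(1 / 3)
  m <- ceiling(n_particles^(1 / 3))
  g <- seq(0, L, length.out = m + 1)[seq_len(m)] + L / (2 * m)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))[seq_len(n_particles), ,
                                                     drop = FALSE]
  set.seed(seed)
  pts <- pts + matrix(stats::runif(3 * n_particles, -0.05, 0.05),
                      ncol = 3) * (L / m)
  solvent_frame(pts, rep(L, 3))
}

#' Run one umbrella window
#'
#' Runs NPT Metropolis Monte Carlo for one umbrella window: equilibration
#' passes (discarded, with move-size tuning toward the target acceptance),
#' followed by production passes with frozen move sizes.  Returns the
#' production occupancy histogram and an optionally thinned frame stream.
#'
#' @param config a [simulation_config()]
#' @param cavity a [cavity_spec()]
#' @param init optional initial [solvent_frame()]; default is a jittered
#'   lattice at `config$init_density`
#' @param move_cavity attempt one cavity move per pass (default TRUE)
#' @return an object of class `window_run` with elements `histogram` (an
#'   `occupancy_histogram`), `frames` (list of [solvent_frame()] with an
#'   `occupancy` attribute each), `samples` (data.frame pass/n/volume/energy)
#'   and `diagnostics`
#' @export
run_window <- function(config, cavity, init = NULL, move_cavity = TRUE) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(cavity, "cavity_spec"))
  model <- solvent_model(config$solvent_model,
                         hs_diameter = if (config$solvent_model ==
                                             "hard_sphere")
                           config$hs_diameter else NULL)
  if (is.null(init))
    init <- init_lattice(config$n_particles, config$init_density, config$seed)
  cutoff <- interaction_cutoff(model)
  if (cutoff > 0 && min(init$box_lengths) < 2 * cutoff)
    stop("box edge smaller than twice the interaction cutoff; ",
         "increase n_particles or density")
  res <- cpp_run_mc(init$positions, init$box_lengths, init$cavity_center,
                    cavity$R, cavity$k0, cavity$n0, model_params(model),
                    model_code(model), model$hs_diameter,
                    config$temperature,
                    config$pressure * ATM_TO_KJ_MOL_A3,
                    config$seed,
                    config$passes_equilibration, config$passes_production,
                    config$volume_move_interval, config$target_acceptance,
                    config$tune_every,
                    config$step_trans, config$step_cav, config$step_lnv,
                    config$sample_every, config$frame_every, move_cavity)
  counts <- as.integer(res$hist_counts)
  hist <- occupancy_histogram(counts = counts,
                              n_values = seq_along(counts) - 1L,
                              k0 = cavity$k0, n0 = cavity$n0)
  frames <- list()
  if (length(res$frames) > 0) {
    fb <- matrix(res$frame_box, ncol = 3, byrow = TRUE)
    fc <- matrix(res$frame_cavity, ncol = 3, byrow = TRUE)
    frames <- lapply(seq_along(res$frames), function(i) {
      fr <- solvent_frame(res$frames[[i]], fb[i, ], fc[i, ])
      attr(fr, "occupancy") <- res$frame_n[i]
      fr
    })
  }
  samples <- data.frame(pass = seq_along(res$n_series) *
                          config$sample_every,
                        n = res$n_series, volume = res$V_series,
                        energy = res$U_series)
  structure(list(histogram = hist, frames = frames, samples = samples,
                 cavity = cavity, config = config,
                 diagnostics = list(acc_trans = res$acc_trans,
                                    acc_cavity = res$acc_cavity,
                                    acc_volume = res$acc_volume,
                                    step_trans = res$step_trans,
                                    step_cavity = res$step_cavity,
                                    step_vol_frac = res$step_vol_frac),
                 final = list(positions = res$final_positions,
                              box = res$final_box,
                              cavity_center = res$final_cavity,
                              energy = res$final_energy, n = res$final_n)),
            class = "window_run")
}

#' Occupancy histogram for one umbrella window
#'
#' @param counts non-negative integer counts
#' @param n_values occupancies the counts refer to
#' @param k0,n0 umbrella parameters of the window
#' @return an object of class `occupancy_histogram`
#' @export
occupancy_histogram <- function(counts, n_values = seq_along(counts) - 1L,
                                k0 = 0, n0 = 0) {
  counts <- as.integer(counts)
  stopifnot(all(counts >= 0), length(counts) == length(n_values))
  structure(list(counts = counts, n_values = as.integer(n_values),
                 k0 = k0, n0 = n0, total = sum(counts)),
            class = "occupancy_histogram")
}

#' @export
print.occupancy_histogram <- function(x, ...) {
  cat(sprintf("occupancy_histogram: %d samples, n in [%d, %d], k0 = %.3g, n0 = %.3g\n",
              x$total, min(x$n_values[x$counts > 0]),
              max(x$n_values[x$counts > 0]), x$k0, x$n0))
  invisible(x)
}

#' Umbrella window ladder
#'
#' Constructs the set of umbrella windows used to sweep the occupancy range:
#' centers from 0 up past the mean occupancy in steps of `delta_n0`, with
#' spring constants interpolated so that stiffer umbrellas are used as the
#' cavity is emptied.
#'
#' @param n_mean mean unbiased occupancy the ladder must cover
#' @param delta_n0 spacing of umbrella centers (default 2)
#' @param k0_range spring constants (kJ/mol) at `n0 = 0` (first element) and
#'   at `n0 >= n_mean` (second element), linearly interpolated between
#' @param n0_max largest umbrella center; default `ceiling(n_mean) + 2 *
#'   delta_n0`
#' @param k0_override optional vector replacing the interpolated spring
#'   constants (recycled)
#' @return list of [cavity_spec()]-ready data.frames columns `n0`, `k0`
#' @export
window_ladder <- function(n_mean, delta_n0 = 2, k0_range = c(9, 2.5),
                          n0_max = NULL, k0_override = NULL) {
  if (is.null(n0_max)) n0_max <- ceiling(n_mean) + 2 * delta_n0
  n0 <- seq(0, n0_max, by = delta_n0)
  frac <- pmin(n0 / max(n_mean, 1e-12), 1)
  k0 <- k0_range[1] + (k0_range[2] - k0_range[1]) * frac
  if (!is.null(k0_override)) k0 <- rep_len(k0_override, length(n0))
  data.frame(n0 = n0, k0 = k0)
}

#' Widom test-particle insertion
#'
#' Estimates the excess chemical potential from the frame-averaged Boltzmann
#' factor of random trial insertions, `mu_ex = -kT log <exp(-beta dU)>`.
#' With `test = "hard_sphere"` the trial particle is a hard sphere of radius
#' `test_radius` (the Boltzmann factor is 1 iff no solvent center lies
#' within that radius), giving the empty-cavity hydration free energy for
#' small radii.
#'
#' @param frames list of [solvent_frame()] (or a `window_run`)
#' @param model a [solvent_model()]
#' @param temperature temperature (K)
#' @param trials_per_frame number of random insertions per frame
#' @param test `"solvent"` (a solvent test particle) or `"hard_sphere"`
#' @param test_radius hard-sphere test radius (Angstrom)
#' @param seed RNG seed for the insertion stream
#' @return list with `mu_ex` (kJ/mol), `se` (standard error, kJ/mol, by
#'   per-frame block statistics), `mean_boltzmann`, and `infinite` flag
#'   (TRUE when no insertion succeeded so `mu_ex = +Inf`)
#' @export
widom_mu_ex <- function(frames, model, temperature = 298.15,
                        trials_per_frame = 100L,
                        test = c("solvent", "hard_sphere"),
                        test_radius = 0, seed = 1L) {
  test <- match.arg(test)
  if (inherits(frames, "window_run")) frames <- frames$frames
  if (inherits(frames, "solvent_frame")) frames <- list(frames)
  stopifnot(length(frames) >= 1)
  mode <- if (test == "hard_sphere") 1L else 0L
  per_frame <- vapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    cpp_widom_frame(fr$positions, fr$box_lengths, model_params(model),
                    model_code(model), model$hs_diameter, mode, test_radius,
                    as.integer(trials_per_frame), temperature,
                    as.integer(seed) + i)$mean_boltzmann
  }, numeric(1))
  m <- mean(per_frame)
  kT <- kBT(temperature)
  if (m <= 0) {
    return(list(mu_ex = Inf, se = NA_real_, mean_boltzmann = 0,
                infinite = TRUE))
  }
  se_m <- stats::sd(per_frame) / sqrt(length(per_frame))
  list(mu_ex = -kT * log(m), se = kT * se_m / m, mean_boltzmann = m,
       infinite = FALSE)
}
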