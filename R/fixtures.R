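#' Ideal-gas frame fixture
#'
#' Generates i.i.d. uniform particle placements with a Poisson-distributed
#' particle count per frame (`N_f ~ Poisson(rho V)`), so the occupancy of
#' any fixed subvolume is exactly Poisson.
#'
#' @param rho number density (1/A^3), >= 0
#' @param box box edge length(s) (Angstrom; scalar for a cubic box)
#' @param n_frames number of frames
#' @param seed RNG seed
#' @param cavity_center optional fixed cavity center (default box center)
#' @return list of [solvent_frame()]s
#' @export
generate_ideal_gas_fixture <- function(rho, box, n_frames, seed,
                                       cavity_center = NULL) {
  stopifnot(rho >= 0, n_frames >= 1)
  L <- if (length(box) == 1) rep(box, 3) else as.numeric(box)
  if (is.null(cavity_center)) cavity_center <- L / 2
  V <- prod(L)
  set.seed(seed)
  counts <- stats::rpois(n_frames, rho * V)
  lapply(seq_len(n_frames), function(i) {
    n <- counts[i]
    pos <- matrix(stats::runif(3 * n), ncol = 3)
    pos <- sweep(pos, 2, L, `*`)
    solvent_frame(pos, L, cavity_center)
  })
}

#' Hard-sphere frame fixture
#'
#' Metropolis-equilibrated non-overlapping hard-sphere configurations at
#' fixed N and V: random sequential insertion to seed a valid start,
#' followed by displacement sweeps with overlap rejection.
#'
#' @param rho number density (1/A^3)
#' @param diameter hard-sphere diameter (Angstrom)
#' @param box box edge length(s) (Angstrom)
#' @param n_frames number of frames emitted
#' @param seed RNG seed
#' @param sweeps_between displacement sweeps between emitted frames
#' @param sweeps_burnin initial equilibration sweeps
#' @return list of [solvent_frame()]s
#' @export
generate_hard_sphere_fixture <- function(rho, diameter, box, n_frames, seed,
                                         sweeps_between = 5,
                                         sweeps_burnin = 20) {
  L <- if (length(box) == 1) rep(box, 3) else as.numeric(box)
  N <- round(rho * prod(L))
  if (N == 0)
    return(lapply(seq_len(n_frames), function(i)
      solvent_frame(matrix(numeric(0), ncol = 3), L)))
  packing <- pi * rho * diameter^3 / 6
  if (packing > 0.45)
    stop("infeasible packing fraction ", signif(packing, 3))
  set.seed(seed)
  # random sequential insertion
  pos <- matrix(NA_real_, nrow = N, ncol = 3)
  placed <- 0L
  attempts <- 0L
  while (placed < N) {
    attempts <- attempts + 1L
    if (attempts > 2000 * N)
      stop("could not place ", N, " non-overlapping spheres")
    cand <- stats::runif(3) * L
    if (placed == 0 ||
        min(min_image_dist(pos[seq_len(placed), , drop = FALSE], cand, L)) >=
          diameter) {
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
  }
  model <- solvent_model("hard_sphere", hs_diameter = diameter)
  sweep_once <- function(fr) {
    res <- cpp_run_mc(fr$positions, fr$box_lengths, fr$cavity_center,
                      1e-6, 0, 0, model_params(model), model_code(model),
                      diameter, 300, 0, sample.int(.Machine$integer.max, 1),
                      0L, 1L, 0L, 0.3, 0L, diameter, 0.3, 0, 0L, 0L, FALSE)
    solvent_frame(res$final_positions, res$final_box, res$final_cavity)
  }
  fr <- solvent_frame(pos, L)
  for (s in seq_len(sweeps_burnin)) fr <- sweep_once(fr)
  out <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    for (s in seq_len(sweeps_between)) fr <- sweep_once(fr)
    out[[i]] <- fr
  }
  out
}

#' Synthetic occupancy distributions
#'
#' Closed-form `p_n` fixtures for testing the estimators: a discretized
#' normalized Gaussian, a Poisson distribution, or the augmented
#' fluctuation-theory distribution `p_n = exp(-beta mu_n^AFT)` normalized
#' over the grid.
#'
#' @param kind one of `"gaussian"`, `"poisson"`, `"aft"`
#' @param mean mean parameter (`gaussian`/`poisson`)
#' @param var variance (`gaussian` only)
#' @param n_max largest occupancy on the grid (default chosen from the
#'   parameters)
#' @param R,inputs cavity radius and [theory_inputs()] (`aft` only)
#' @return a [pn_distribution()] with provenance `"theory"`
#' @export
synthetic_pn <- function(kind = c("gaussian", "poisson", "aft"),
                         mean = NULL, var = NULL, n_max = NULL,
                         R = NULL, inputs = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    stopifnot(!is.null(mean), !is.null(var), var > 0)
    if (is.null(n_max)) n_max <- ceiling(mean + 8 * sqrt(var))
    n <- 0:n_max
    p <- exp(-(n - mean)^2 / (2 * var))
  } else if (kind == "poisson") {
    stopifnot(!is.null(mean), mean > 0)
    if (is.null(n_max)) n_max <- max(ceiling(mean + 10 * sqrt(mean)), 10)
    n <- 0:n_max
    p <- stats::dpois(n, mean)
  } else {
    stopifnot(!is.null(R), inherits(inputs, "theory_inputs"))
    if (is.null(n_max)) {
      gm <- gaussian_model(R, inputs)
      n_max <- ceiling(gm$n_mean + 8 * sqrt(gm$sigma2))
    }
    n <- 0:n_max
    p <- exp(-mu_n_aft(n, R, inputs))
  }
  pn_distribution(p, n, provenance = "theory")
}

#' Sample biased occupancy histograms from a known distribution
#'
#' Draws multinomial window histograms from `p_n` reweighted by harmonic
#' umbrella biases, the generating oracle for WHAM tests.
#'
#' @param pn a [pn_distribution()] (the generating truth)
#' @param windows data.frame with columns `n0`, `k0` (e.g. from
#'   [window_ladder()])
#' @param n_samples samples per window
#' @param temperature temperature (K)
#' @param seed RNG seed
#' @return list of [occupancy_histogram()]s
#' @export
sample_biased_histograms <- function(pn, windows, n_samples, temperature,
                                     seed) {
  beta <- 1 / kBT(temperature)
  set.seed(seed)
  lapply(seq_len(nrow(windows)), function(w) {
    bias <- exp(-beta * 0.5 * windows$k0[w] *
                  (pn$n_values - windows$n0[w])^2)
    q <- pn$p * bias
    q <- q / sum(q)
    counts <- as.integer(stats::rmultinom(1, n_samples, q))
    occupancy_histogram(counts, pn$n_values,
                        k0 = windows$k0[w], n0 = windows$n0[w])
  })
}
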