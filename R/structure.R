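#' Radius of gyration of the interior solvent density
#'
#' Density-weighted second moment of the interior branch of the
#' occupancy-resolved RDF,
#' `R_g^2 = int_0^R g_n(r) r^4 dr / int_0^R g_n(r) r^2 dr`.
#' For a uniform interior density (`g_n = 1`) this reduces to the uniform
#' sphere value `sqrt(3/5) R`; its minimum versus `n` marks the migration of
#' interior waters onto the cavity surface that accompanies bubble
#' formation.
#'
#' @param gset an [occupancy_rdf_set()]
#' @param n occupancy state; must have interior density (`n >= 1`)
#' @return `R_g` in Angstrom; `NA` with a warning for an empty interior
#' @export
rg_from_gn <- function(gset, n) {
  stopifnot(inherits(gset, "occupancy_rdf_set"))
  i <- match(n, gset$n_values)
  if (is.na(i)) stop("occupancy state ", n, " not present in the RDF set")
  if (n == 0) {
    warning("radius of gyration is undefined for the empty cavity")
    return(NA_real_)
  }
  sel <- gset$r_grid < gset$R
  g <- gset$g[i, sel]
  r <- gset$r_grid[sel]
  denom <- sum(g * r^2)
  if (denom <= 0) {
    warning("no interior density for occupancy ", n)
    return(NA_real_)
  }
  sqrt(sum(g * r^4) / denom)
}

#' Uniform-sphere radius of gyration
#' @param R sphere radius (Angstrom)
#' @return `sqrt(3/5) R`
#' @export
rg_uniform_sphere <- function(R) sqrt(3 / 5) * R

#' Radius-of-gyration profile over occupancy states
#'
#' @param gset an [occupancy_rdf_set()]
#' @param n_mean mean occupancy used for the normalized axis (default
#'   `rho 4 pi R^3 / 3` from the set's metadata)
#' @param min_frames occupancy states observed in fewer frames are skipped
#' @return an object of class `rg_profile`: data.frame columns `n`, `Rg`,
#'   `Rg_norm` (relative to the uniform sphere), `n_norm`
#' @export
rg_profile <- function(gset, n_mean = NULL, min_frames = 1) {
  if (is.null(n_mean)) n_mean <- gset$rho * 4 / 3 * pi * gset$R^3
  ns <- gset$n_values[gset$n_values >= 1 & gset$frame_counts >= min_frames]
  rg <- vapply(ns, function(n) rg_from_gn(gset, n), numeric(1))
  out <- data.frame(n = ns, Rg = rg,
                    Rg_norm = rg / rg_uniform_sphere(gset$R),
                    n_norm = ns / n_mean)
  class(out) <- c("rg_profile", "data.frame")
  out
}

#' Coordinate-space radius of gyration cross-check
#'
#' Direct per-frame radius of gyration of the particles inside the cavity,
#' averaged over frames with the requested occupancy; the RDF route
#' [rg_from_gn()] must agree within stochastic error.  The second moment is
#' taken about the cavity center, matching the RDF definition.
#'
#' @param frames list of [solvent_frame()] with `"occupancy"` attributes
#'   (or occupancies computed from `cavity`)
#' @param cavity a [cavity_spec()]
#' @param n occupancy state
#' @return mean `R_g` (Angstrom) over matching frames
#' @export
rg_from_frames <- function(frames, cavity, n) {
  vals <- c()
  for (fr in frames) {
    o <- attr(fr, "occupancy")
    if (is.null(o)) o <- occupancy(fr, cavity)
    if (o != n || n == 0) next
    d <- min_image_dist(fr$positions, fr$cavity_center, fr$box_lengths)
    d <- d[d < cavity$R]
    vals <- c(vals, sqrt(mean(d^2)))
  }
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

running_mean <- function(x, width) {
  if (width <= 1) return(x)
  stats::filter(x, rep(1 / width, width), sides = 2)
}

#' Nucleation occupancy from the radius-of-gyration minimum
#'
#' The interior radius of gyration shrinks as waters first segregate toward
#' the cavity center, then grows again once they adsorb onto the inner
#' surface around the nascent bubble; the occupancy at its minimum estimates
#' the nucleation occupancy.  A 3-point discrete minimum test is used, with
#' ties broken toward larger `n` (closer to the mean occupancy, where the
#' transition is defined).
#'
#' @param profile an [rg_profile()] (or data.frame with columns `n`, `Rg`)
#' @param smooth optional odd running-mean window applied before detection
#'   (default 0 = none)
#' @return integer `n*` estimate, or `NA` for a monotone profile
#' @export
n_star_from_rg <- function(profile, smooth = 0) {
  n <- profile$n
  y <- profile$Rg
  o <- order(n)
  n <- n[o]; y <- y[o]
  if (any(diff(n) != 1))
    stop("profile must cover a contiguous occupancy range")
  if (smooth > 1) {
    ys <- running_mean(y, smooth)
    keep <- !is.na(ys)
    n <- n[keep]; y <- ys[keep]
  }
  k <- length(y)
  if (k < 3) return(NA_integer_)
  interior <- 2:(k - 1)
  is_min <- vapply(interior, function(i)
    y[i] <= y[i - 1] && y[i] <= y[i + 1], logical(1))
  if (!any(is_min)) return(NA_integer_)
  cand <- interior[is_min]
  best <- min(y[cand])
  as.integer(max(n[cand][y[cand] <= best + 1e-12]))
}

#' Nucleation occupancy from the ln K peak
#'
#' Along the Gaussian branch `ln K_n` falls linearly with `n`; on the
#' bubble branch the removal work drops, so `ln K_n` exhibits a peak at the
#' break.  The estimator returns the peak location shifted up by 1/2 (the
#' differential `ln K_n` compares states `n` and `n + 1`, so it probes the
#' derivative at `n + 1/2`).
#'
#' @param ln_K data.frame with columns `n`, `ln_K` (as from
#'   [ln_K_series()] or [knit_all()]) or a bare numeric vector over `n =
#'   0, 1, ...`
#' @param smooth optional running-mean window (default 0 = none)
#' @return real `n*` estimate, or `NA` when no interior peak exists
#' @export
n_star_from_lnK <- function(ln_K, smooth = 0) {
  if (is.data.frame(ln_K)) {
    n <- ln_K$n
    y <- ln_K$ln_K
  } else {
    y <- as.numeric(ln_K)
    n <- seq_along(y) - 1
  }
  o <- order(n)
  n <- n[o]; y <- y[o]
  if (smooth > 1) {
    ys <- running_mean(y, smooth)
    keep <- !is.na(ys)
    n <- n[keep]; y <- ys[keep]
  }
  k <- length(y)
  if (k < 3) return(NA_real_)
  interior <- 2:(k - 1)
  is_max <- vapply(interior, function(i)
    (y[i] >= y[i - 1] && y[i] > y[i + 1]) ||
      (y[i] > y[i - 1] && y[i] >= y[i + 1]), logical(1))
  if (!any(is_max)) return(NA_real_)
  cand <- interior[is_max]
  best <- max(y[cand])
  n[max(cand[y[cand] >= best - 1e-12])] + 0.5
}
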