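#' Occupancy-resolved cavity--solvent RDF set
#'
#' Radial distribution functions `g_n(r)` between the cavity center and the
#' solvent, conditioned on the cavity occupancy `n`, on a uniform radial
#' grid.  Interior (`r < R`) and exterior branches of each `g_n` come from
#' the same conditional ensemble; the RDF is discontinuous at the boundary
#' while the underlying cavity correlation function `y_n(r)` is continuous.
#'
#' @param r_grid bin centers (Angstrom, uniform spacing)
#' @param g matrix of RDF values, one row per occupancy state
#' @param counts matrix of raw pair counts, same shape as `g`
#' @param frame_counts frames observed per occupancy state
#' @param n_values occupancies corresponding to the rows
#' @param R cavity radius (Angstrom)
#' @param rho bulk number density (1/A^3)
#' @return an object of class `occupancy_rdf_set`
#' @export
occupancy_rdf_set <- function(r_grid, g, counts, frame_counts, n_values,
                              R, rho) {
  g <- as.matrix(g)
  stopifnot(nrow(g) == length(n_values), ncol(g) == length(r_grid),
            R > 0, rho > 0, all(frame_counts >= 0))
  dr <- diff(r_grid)
  if (length(dr) > 0 && max(abs(dr - dr[1])) > 1e-9 * dr[1])
    stop("r_grid must be uniform")
  structure(list(r_grid = r_grid, g = g, counts = as.matrix(counts),
                 frame_counts = frame_counts,
                 n_values = as.integer(n_values), R = R, rho = rho),
            class = "occupancy_rdf_set")
}

#' @export
print.occupancy_rdf_set <- function(x, ...) {
  cat(sprintf(
    "occupancy_rdf_set: R = %.3f A, rho = %.5f 1/A^3, n in [%d, %d], %d bins\n",
    x$R, x$rho, min(x$n_values), max(x$n_values), length(x$r_grid)))
  invisible(x)
}

#' Accumulate occupancy-resolved RDFs from a frame stream
#'
#' Histograms cavity--solvent distances separately for each observed cavity
#' occupancy and normalizes by ideal shell volumes and the bulk density.
#' Because the umbrella bias depends only on the occupancy, it is constant
#' within an occupancy class: conditioning on `n` already removes the bias,
#' and the optional per-frame weights (e.g. `exp(+beta * umbrella)`) only
#' change the relative weight of frames pooled from different windows.
#' Occupancy states with no frames are absent from the result (never
#' zero-filled).
#'
#' @param frames list of [solvent_frame()]s; occupancies are taken from each
#'   frame's `"occupancy"` attribute if present (as produced by
#'   [run_window()]), else computed from `cavity`
#' @param cavity a [cavity_spec()] (radius; the umbrella metadata is unused
#'   here)
#' @param rho bulk number density (1/A^3) used for normalization
#' @param bin_width radial bin width (Angstrom, default 0.05)
#' @param r_max largest distance accumulated (default `R + 3`, capped at the
#'   smallest half box length)
#' @param weights optional positive per-frame weights (default all 1)
#' @return an [occupancy_rdf_set()]
#' @export
accumulate_gn <- function(frames, cavity, rho, bin_width = 0.05,
                          r_max = NULL, weights = NULL) {
  stopifnot(length(frames) >= 1, inherits(cavity, "cavity_spec"), rho > 0)
  if (is.null(weights)) weights <- rep(1, length(frames))
  stopifnot(length(weights) == length(frames), all(weights > 0))
  half_box <- min(vapply(frames, function(f) min(f$box_lengths), 1)) / 2
  if (is.null(r_max)) r_max <- cavity$R + 3
  r_max <- min(r_max, half_box)
  if (r_max <= cavity$R)
    stop("r_max must exceed the cavity radius (box too small?)")
  # align the grid so the cavity boundary is a bin edge: a straddling bin
  # would mix the interior and exterior density levels and bias the knit
  m_in <- floor(cavity$R / bin_width + 1e-9)
  lo <- cavity$R - m_in * bin_width
  m_out <- floor((r_max - cavity$R) / bin_width + 1e-9)
  edges <- lo + bin_width * (0:(m_in + m_out))
  r_max <- edges[length(edges)]
  nb <- length(edges) - 1L
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  shell_vol <- 4 / 3 * pi * diff(edges^3)

  occ <- vapply(seq_along(frames), function(i) {
    o <- attr(frames[[i]], "occupancy")
    if (is.null(o)) o <- occupancy(frames[[i]], cavity)
    as.integer(o)
  }, integer(1))
  states <- sort(unique(occ))
  counts <- matrix(0, nrow = length(states), ncol = nb)
  wsum <- numeric(length(states))
  fcount <- integer(length(states))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    d <- min_image_dist(fr$positions, fr$cavity_center, fr$box_lengths)
    d <- d[d >= lo & d < r_max]
    k <- match(occ[i], states)
    if (length(d) > 0) {
      h <- tabulate(pmin(nb, floor((d - lo) / bin_width) + 1L), nbins = nb)
      counts[k, ] <- counts[k, ] + weights[i] * h
    }
    wsum[k] <- wsum[k] + weights[i]
    fcount[k] <- fcount[k] + 1L
  }
  g <- counts / outer(wsum, shell_vol * rho)
  occupancy_rdf_set(centers, g, counts, fcount, states, cavity$R, rho)
}

#' Quadratic-plus-step knit fit of the cavity correlation function
#'
#' Near the cavity boundary the potential of mean force `-kT ln y_n(r)` is
#' approximated by a quadratic in `(r - R)`.  Since
#' `y_n(r < R) = K_n g_{n+1}(r)` and `y_n(r >= R) = g_n(r)`, a simultaneous
#' least-squares fit of
#' `alpha2 (r-R)^2 + alpha1 (r-R) + alpha0 + ln K_n * Theta(R - r)`
#' to `-ln g_{n+1}` (interior) and `-ln g_n` (exterior) over `R +/-
#' half_width` yields the continuity constant `ln K_n = ln(p_{n+1}/p_n)`.
#'
#' @param gset an [occupancy_rdf_set()]
#' @param n occupancy state; requires `g_n` (exterior) and `g_{n+1}`
#'   (interior) in `gset`
#' @param half_width fit half-width around the boundary (Angstrom, default 1)
#' @param weighted weight bins by their raw counts (default TRUE); FALSE
#'   gives the unweighted fit
#' @return an object of class `knit_fit` with fields `alpha0`, `alpha1`,
#'   `alpha2`, `ln_Kn`, `ln_Kn_se`, `half_width`, `residual_norm`, `n_bins`
#' @export
knit_fit <- function(gset, n, half_width = 1.0, weighted = TRUE) {
  stopifnot(inherits(gset, "occupancy_rdf_set"))
  i_out <- match(n, gset$n_values)
  i_in <- match(n + 1L, gset$n_values)
  if (is.na(i_out) || is.na(i_in))
    stop("occupancy states ", n, " and ", n + 1,
         " must both be present to knit at n = ", n)
  R <- gset$R
  r <- gset$r_grid
  sel_in <- r >= R - half_width & r < R
  sel_out <- r >= R & r <= R + half_width
  x <- c(r[sel_in], r[sel_out]) - R
  g <- c(gset$g[i_in, sel_in], gset$g[i_out, sel_out])
  cnt <- c(gset$counts[i_in, sel_in], gset$counts[i_out, sel_out])
  interior <- c(rep(TRUE, sum(sel_in)), rep(FALSE, sum(sel_out)))
  usable <- g > 0
  if (any(!usable))
    warning(sum(!usable), " bin(s) with non-positive RDF excluded from knit",
            " fit at n = ", n)
  x <- x[usable]; g <- g[usable]; cnt <- cnt[usable]
  interior <- interior[usable]
  if (length(x) < 6 || sum(interior) < 2 || sum(!interior) < 2)
    stop("fewer than 6 usable bins (or a branch with fewer than 2) in the",
         " knit range at n = ", n)
  d <- -log(g)
  w <- if (weighted) pmax(cnt, 1e-12) else rep(1, length(x))
  fit <- stats::lm(d ~ x + I(x^2) + interior, weights = w)
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["interiorTRUE", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(alpha0 = unname(cf["(Intercept)"]),
                 alpha1 = unname(cf["x"]),
                 alpha2 = unname(cf["I(x^2)"]),
                 ln_Kn = unname(cf["interiorTRUE"]),
                 ln_Kn_se = se,
                 half_width = half_width,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 n_bins = length(x), n = n),
            class = "knit_fit")
}

#' @export
print.knit_fit <- function(x, ...) {
  cat(sprintf("knit_fit at n = %d: ln K = %.4f (se %.4f), %d bins\n",
              x$n, x$ln_Kn, x$ln_Kn_se, x$n_bins))
  invisible(x)
}

#' Knit all available occupancy states
#'
#' Runs [knit_fit()] for every `n` with both branches present and enough
#' frames, returning the `ln K_n` ladder.
#'
#' @param gset an [occupancy_rdf_set()]
#' @param half_width fit half-width (Angstrom)
#' @param min_frames occupancy states observed in fewer frames are excluded
#'   (default 100)
#' @param weighted passed to [knit_fit()]
#' @return data.frame with columns `n`, `ln_K`, `se`
#' @export
knit_all <- function(gset, half_width = 1.0, min_frames = 100,
                     weighted = TRUE) {
  ok <- gset$n_values[gset$frame_counts >= min_frames]
  ns <- ok[(ok + 1L) %in% ok]
  if (length(ns) == 0) stop("no adjacent occupancy pairs with >= ",
                            min_frames, " frames")
  fits <- lapply(ns, function(n) knit_fit(gset, n, half_width, weighted))
  data.frame(n = ns,
             ln_K = vapply(fits, `[[`, numeric(1), "ln_Kn"),
             se = vapply(fits, `[[`, numeric(1), "ln_Kn_se"))
}

#' Assemble the occupancy distribution from a ln K ladder
#'
#' `p_n` is proportional to `exp(sum_{i<n} ln K_i)` with `p` normalized to
#' one over the covered states.
#'
#' @param ln_K contiguous vector `ln K_{n_min} .. ln K_{n_max - 1}` (or the
#'   data.frame from [knit_all()])
#' @param n_min occupancy of the first state (default 0)
#' @param se optional standard errors on each `ln K`; propagated to `ln p`
#'   by accumulation
#' @return a [pn_distribution()] with provenance `"knitting"`
#' @export
assemble_pn <- function(ln_K, n_min = 0L, se = NULL) {
  if (is.data.frame(ln_K)) {
    if (any(diff(ln_K$n) != 1))
      stop("ln K ladder is not contiguous: missing n = ",
           paste(setdiff(seq(min(ln_K$n), max(ln_K$n)), ln_K$n),
                 collapse = ", "))
    n_min <- min(ln_K$n)
    se <- ln_K$se
    ln_K <- ln_K$ln_K
  }
  if (any(!is.finite(ln_K)))
    stop("non-finite ln K at n = ", n_min + which(!is.finite(ln_K))[1] - 1)
  ln_p <- c(0, cumsum(ln_K))
  p <- exp(ln_p - logsumexp(ln_p))
  se_lnp <- if (!is.null(se)) c(0, sqrt(cumsum(se^2))) else NULL
  pn_distribution(p, n_min + seq_along(p) - 1L, provenance = "knitting",
                  se = se_lnp)
}

#' Passivity check of an RDF set
#'
#' On average the cavity is uncorrelated with the solvent, so the
#' occupancy-averaged RDF `sum_n p_n g_n(r)` must equal 1 at every
#' separation.  States with `p_n` below `p_floor` (or missing from the RDF
#' set) are dropped and the remaining weights renormalized.
#'
#' @param gset an [occupancy_rdf_set()]
#' @param p a [pn_distribution()]
#' @param p_floor smallest occupancy probability included (default 1e-4)
#' @param min_count bins with fewer pooled pair counts are excluded from the
#'   scalar maximum (they carry no information); the full profile is
#'   returned regardless
#' @return list with `profile` (data.frame `r`, `mean_g`, `deviation`,
#'   `count`) and `max_abs_deviation`
#' @export
passivity_check <- function(gset, p, p_floor = 1e-4, min_count = 50) {
  stopifnot(inherits(gset, "occupancy_rdf_set"),
            inherits(p, "pn_distribution"))
  keep <- p$p >= p_floor & p$n_values %in% gset$n_values
  if (!any(keep)) stop("no occupancy states above the probability floor")
  w <- p$p[keep] / sum(p$p[keep])
  idx <- match(p$n_values[keep], gset$n_values)
  mean_g <- as.numeric(w %*% gset$g[idx, , drop = FALSE])
  cnt <- colSums(gset$counts[idx, , drop = FALSE])
  profile <- data.frame(r = gset$r_grid, mean_g = mean_g,
                        deviation = mean_g - 1, count = cnt)
  ok <- profile$count >= min_count
  list(profile = profile,
       max_abs_deviation = if (any(ok)) max(abs(profile$deviation[ok]))
       else NA_real_)
}

#' Ideal-gas closed forms for the cavity statistics
#'
#' In an ideal gas the cavity correlation function is identically 1, the
#' interior branch of `g_{n+1}` is flat at `(n+1)/<n>`, the continuity
#' constant is `K_n = <n>/(n+1)`, and `p_n` is Poisson with mean `<n>`.
#'
#' @param n_mean mean occupancy `<n> = rho * 4 pi R^3 / 3`, > 0
#' @param n occupancy (vectorized, >= 0)
#' @return list with `y_n`, `g_interior_np1` (interior level of
#'   `g_{n+1}`), `g_interior_n` (interior level of `g_n`), `K_n`, `ln_K_n`,
#'   `p_n`
#' @export
ideal_gas_reference <- function(n_mean, n) {
  stopifnot(n_mean > 0, all(n >= 0))
  list(y_n = rep(1, length(n)),
       g_interior_np1 = (n + 1) / n_mean,
       g_interior_n = n / n_mean,
       K_n = n_mean / (n + 1),
       ln_K_n = log(n_mean / (n + 1)),
       p_n = stats::dpois(n, n_mean))
}
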