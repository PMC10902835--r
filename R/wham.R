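#' Occupancy probability distribution
#'
#' Normalized distribution `p_n` over a contiguous occupancy range together
#' with the log-ratio differentials `ln K_n = ln p_{n+1} - ln p_n`.
#'
#' @param p probabilities (non-negative; normalized internally)
#' @param n_values occupancies (default `0:(length(p)-1)`)
#' @param provenance one of `"wham"`, `"knitting"`, `"theory"`
#' @param se optional standard errors on `ln p_n`
#' @return an object of class `pn_distribution`
#' @export
pn_distribution <- function(p, n_values = seq_along(p) - 1L,
                            provenance = c("wham", "knitting", "theory"),
                            se = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(all(p >= 0), sum(p) > 0, length(p) == length(n_values))
  # avoid 1-ulp churn on already-normalized input (keeps file round trips
  # byte-identical)
  if (abs(sum(p) - 1) > 1e-12) p <- p / sum(p)
  lnp <- ifelse(p > 0, log(p), -Inf)
  lnK <- lnp[-1] - lnp[-length(lnp)]
  lnK[!is.finite(lnK)] <- NA_real_
  structure(list(p = p, n_values = as.integer(n_values), ln_p = lnp,
                 ln_K = lnK, provenance = provenance, se = se),
            class = "pn_distribution")
}

#' @export
print.pn_distribution <- function(x, ...) {
  cat(sprintf("pn_distribution (%s): n in [%d, %d], p0 = %.4g\n",
              x$provenance, min(x$n_values), max(x$n_values),
              x$p[x$n_values == 0][1]))
  invisible(x)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Weighted histogram analysis of umbrella windows
#'
#' Reconstructs the unbiased occupancy distribution from a set of
#' harmonically biased occupancy histograms by self-consistent iteration of
#' the WHAM equations over the discrete occupancy grid.
#'
#' @param windows list of [occupancy_histogram()] objects (their `k0`, `n0`
#'   metadata defines the biases)
#' @param temperature temperature (K)
#' @param tolerance convergence threshold on the maximum change of the
#'   per-window free-energy shifts (in kT)
#' @param max_iters maximum number of iterations
#' @param shifts_init optional warm-start vector of per-window shifts
#' @return a [pn_distribution()] with attributes `shifts` (per-window
#'   dimensionless free energies), `iterations`, `converged`
#' @export
wham_combine <- function(windows, temperature = 298.15, tolerance = 1e-8,
                         max_iters = 1e5, shifts_init = NULL) {
  stopifnot(length(windows) >= 1)
  lapply(windows, function(w) stopifnot(inherits(w, "occupancy_histogram")))
  beta <- 1 / kBT(temperature)
  n_min <- min(vapply(windows, function(w) min(w$n_values), 1L))
  n_max <- max(vapply(windows, function(w) max(w$n_values[w$counts > 0]), 1L))
  n_grid <- n_min:n_max
  W <- length(windows)
  counts <- matrix(0, nrow = W, ncol = length(n_grid))
  for (w in seq_len(W)) {
    idx <- match(windows[[w]]$n_values, n_grid)
    keep <- !is.na(idx)
    counts[w, idx[keep]] <- windows[[w]]$counts[keep]
  }
  pooled <- colSums(counts)
  sampled <- which(pooled > 0)
  if (length(sampled) == 0) stop("no counts in any window")
  gaps <- setdiff(seq(min(sampled), max(sampled)), sampled)
  if (length(gaps) > 0)
    stop("occupancy coverage is not contiguous: no samples at n = ",
         paste(n_grid[gaps], collapse = ", "))
  # restrict to the sampled contiguous block
  n_grid <- n_grid[min(sampled):max(sampled)]
  counts <- counts[, min(sampled):max(sampled), drop = FALSE]
  pooled <- colSums(counts)
  totals <- rowSums(counts)
  # dimensionless bias beta * (k0/2)(n - n0)^2, per window x occupancy
  bias <- t(vapply(windows, function(w)
    beta * 0.5 * w$k0 * (n_grid - w$n0)^2, numeric(length(n_grid))))
  if (length(n_grid) == 1) bias <- matrix(bias, nrow = W)
  lnf <- if (is.null(shifts_init)) rep(0, W) else as.numeric(shifts_init)
  ln_pooled <- log(pooled)
  ln_totals <- log(totals)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # ln denominator_n = logsumexp_w [ ln N_w + lnf_w - bias_wn ]
    M <- sweep(-bias, 1, ln_totals + lnf, `+`)
    mmax <- apply(M, 2, max)
    ln_den <- mmax + log(colSums(exp(sweep(M, 2, mmax, `-`))))
    ln_p <- ln_pooled - ln_den
    ln_p <- ln_p - logsumexp(ln_p)
    # updated shifts: lnf_w = -ln sum_n exp(ln_p - bias_wn)
    A <- sweep(-bias, 2, ln_p, `+`)
    amax <- apply(A, 1, max)
    lnf_new <- -(amax + log(rowSums(exp(A - amax))))
    delta <- max(abs(lnf_new - lnf))
    lnf <- lnf_new
    if (delta < tolerance) break
    if (iter >= max_iters)
      stop("WHAM failed to converge after ", iter,
           " iterations (last shift change ", signif(delta, 3), ")")
  }
  out <- pn_distribution(exp(ln_p), n_grid, provenance = "wham")
  attr(out, "shifts") <- lnf
  attr(out, "iterations") <- iter
  attr(out, "converged") <- TRUE
  out
}

#' Block-bootstrap errors for a WHAM distribution
#'
#' Resamples contiguous blocks of each window's occupancy series and repeats
#' the WHAM solve, giving standard errors on `ln p_n`.
#'
#' @param window_runs list of `window_run` objects (from [run_window()]),
#'   whose `samples$n` series are resampled
#' @param temperature temperature (K)
#' @param n_blocks number of blocks per window (default 20)
#' @param n_boot bootstrap replicates (default 20)
#' @param seed RNG seed
#' @param ... passed to [wham_combine()]
#' @return list with `pn` (point estimate) and `se_ln_p` (per-occupancy
#'   standard error of `ln p_n`)
#' @export
wham_bootstrap <- function(window_runs, temperature = 298.15, n_blocks = 20,
                           n_boot = 20, seed = 1L, ...) {
  histograms <- lapply(window_runs, function(r) r$histogram)
  pn0 <- wham_combine(histograms, temperature, ...)
  set.seed(seed)
  reps <- matrix(NA_real_, nrow = n_boot, ncol = length(pn0$n_values))
  for (b in seq_len(n_boot)) {
    hb <- lapply(window_runs, function(r) {
      nser <- r$samples$n
      blocks <- split(nser, cut(seq_along(nser), n_blocks, labels = FALSE))
      pick <- sample.int(n_blocks, n_blocks, replace = TRUE)
      ns <- unlist(blocks[pick], use.names = FALSE)
      tab <- tabulate(ns + 1L, nbins = max(ns) + 1L)
      occupancy_histogram(tab, seq_along(tab) - 1L,
                          k0 = r$cavity$k0, n0 = r$cavity$n0)
    })
    pb <- tryCatch(wham_combine(hb, temperature,
                                shifts_init = attr(pn0, "shifts"), ...),
                   error = function(e) NULL)
    if (!is.null(pb)) {
      idx <- match(pn0$n_values, pb$n_values)
      reps[b, ] <- pb$ln_p[idx]
    }
  }
  se <- apply(reps, 2, stats::sd, na.rm = TRUE)
  list(pn = pn0, se_ln_p = se)
}

#' Hydration free energy from the empty-cavity probability
#'
#' `mu0_ex = -kT log p0`: the excess chemical potential of a hard-sphere
#' solute the size of the cavity.
#'
#' @param p0 probability of the empty cavity, in (0, 1]
#' @param temperature temperature (K)
#' @return free energy in kJ/mol
#' @export
mu_ex_from_p0 <- function(p0, temperature = 298.15) {
  if (any(p0 <= 0))
    stop("p0 must be positive: the empty state was not sampled")
  stopifnot(all(p0 <= 1))
  -kBT(temperature) * log(p0)
}

#' Log-ratio series of an occupancy distribution
#'
#' `ln K_n = ln(p_{n+1}/p_n)`.  Entries where either probability is zero are
#' returned as `NA` (flagged, never fabricated).
#'
#' @param p a [pn_distribution()] or a numeric probability vector
#' @return data.frame with columns `n` and `ln_K`
#' @export
ln_K_series <- function(p) {
  if (inherits(p, "pn_distribution")) {
    n <- p$n_values
    prob <- p$p
  } else {
    prob <- as.numeric(p)
    n <- seq_along(prob) - 1L
  }
  lnK <- ifelse(prob[-1] > 0 & prob[-length(prob)] > 0,
                log(prob[-1]) - log(prob[-length(prob)]), NA_real_)
  data.frame(n = n[-length(n)], ln_K = lnK)
}
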