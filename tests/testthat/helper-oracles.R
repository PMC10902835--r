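# Independent oracles used across the suite.  These deliberately do not
# share code with the package internals they check.

# golden-section minimization
golden_section <- function(f, lo, hi, tol = 1e-10) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - phi * (b - a)
  d <- a + phi * (b - a)
  while (abs(b - a) > tol) {
    if (f(c) < f(d)) b <- d else a <- c
    c <- b - phi * (b - a)
    d <- a + phi * (b - a)
  }
  (a + b) / 2
}

# second hand-coded Stillinger-Weber evaluations
sw_pair_ref <- function(r, P) {
  rc <- P$a_cut * P$sigma
  if (r >= rc) return(0)
  sr <- P$sigma / r
  P$A * P$epsilon * (P$B * sr^P$p - sr^P$q) * exp(P$sigma / (r - rc))
}

sw_triplet_ref <- function(rij, rik, P) {
  rc <- P$a_cut * P$sigma
  dij <- sqrt(sum(rij^2)); dik <- sqrt(sum(rik^2))
  if (dij >= rc || dik >= rc) return(0)
  ct <- sum(rij * rik) / (dij * dik)
  P$lambda3 * P$epsilon * (ct - P$cos_theta0)^2 *
    exp(P$gamma3 * P$sigma / (dij - rc)) *
    exp(P$gamma3 * P$sigma / (dik - rc))
}

# O(N^3) brute force over explicit periodic images (box >= 2 cutoff, so at
# most one image of each neighbor is in range)
total_energy_bruteforce <- function(pos, L, P) {
  rc <- P$a_cut * P$sigma
  N <- nrow(pos)
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  e <- 0
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (j <= i) next
      for (s in seq_len(nrow(shifts))) {
        d <- pos[j, ] + shifts[s, ] * L - pos[i, ]
        r <- sqrt(sum(d^2))
        if (r < rc) e <- e + sw_pair_ref(r, P)
      }
    }
  }
  for (i in seq_len(N)) {
    nb <- list()
    for (j in seq_len(N)) {
      if (j == i) next
      for (s in seq_len(nrow(shifts))) {
        d <- pos[j, ] + shifts[s, ] * L - pos[i, ]
        if (sqrt(sum(d^2)) < rc) nb[[length(nb) + 1]] <- d
      }
    }
    if (length(nb) >= 2) {
      for (a in seq_len(length(nb) - 1)) {
        for (b in (a + 1):length(nb)) {
          e <- e + sw_triplet_ref(nb[[a]], nb[[b]], P)
        }
      }
    }
  }
  e
}

# independent transcription of the chi interpolation (algebraically
# rearranged closed form)
chi_ref <- function(R, inputs) {
  s <- (R / (3.1764 * inputs$d_ww))^(4 / 3)
  ci <- inputs$chi_inf
  ci * (1 + s) / (ci + s)
}

# random frame with a minimum separation (rejection sampling)
random_frame <- function(N, L, min_sep, seed) {
  set.seed(seed)
  pos <- matrix(NA_real_, N, 3)
  placed <- 0
  while (placed < N) {
    cand <- runif(3) * L
    ok <- placed == 0 ||
      min(min_image_dist(pos[seq_len(placed), , drop = FALSE], cand,
                         rep(L, 3))) > min_sep
    if (ok) {
      placed <- placed + 1
      pos[placed, ] <- cand
    }
  }
  solvent_frame(pos, rep(L, 3))
}

# exact ideal-gas occupancy-resolved RDF set (flat branches) on a grid
# aligned with the cavity boundary
exact_ideal_gset <- function(R, n_mean, n_values, bin_width = 0.05,
                             r_max = R + 2, counts_per_bin = 1000) {
  rho <- n_mean / (4 / 3 * pi * R^3)
  m_in <- floor(R / bin_width + 1e-9)
  lo <- R - m_in * bin_width
  m_out <- floor((r_max - R) / bin_width + 1e-9)
  edges <- lo + bin_width * (0:(m_in + m_out))
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  g <- t(vapply(n_values, function(n)
    ifelse(centers < R, n / n_mean, 1), numeric(length(centers))))
  counts <- matrix(counts_per_bin, nrow = length(n_values),
                   ncol = length(centers))
  occupancy_rdf_set(centers, g, counts,
                    frame_counts = rep(10000, length(n_values)),
                    n_values = n_values, R = R, rho = rho)
}

blocked_se <- function(x, n_blocks = 20) {
  bm <- vapply(split(x, cut(seq_along(x), n_blocks, labels = FALSE)),
               mean, numeric(1))
  stats::sd(bm) / sqrt(n_blocks)
}
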