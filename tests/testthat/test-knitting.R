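# RDF accumulation and the knitting estimator, validated against the
# ideal-gas closed forms (flat branches, Poisson occupancies).

rho_ig <- 0.02
R_ig <- (3 * 3 / (4 * pi * rho_ig))^(1 / 3)  # mean occupancy 3
frames_ig <- generate_ideal_gas_fixture(rho_ig, 12, 10000, seed = 42)
gset_ig <- accumulate_gn(frames_ig, cavity_spec(R = R_ig), rho = rho_ig)

test_that("ideal-gas RDF branches sit at their exact levels", {
  r <- gset_ig$r_grid
  sel_in <- r < R_ig & r > R_ig - 1
  sel_out <- r >= R_ig & r < R_ig + 1.5
  for (n in 0:4) {
    i_in <- match(n + 1, gset_ig$n_values)
    i_out <- match(n, gset_ig$n_values)
    expect_lt(abs(mean(gset_ig$g[i_in, sel_in]) - (n + 1) / 3), 0.07)
    expect_lt(abs(mean(gset_ig$g[i_out, sel_out]) - 1), 0.07)
  }
})

test_that("interior normalization holds for every accumulated state", {
  # the interior mean of g_n equals n / (rho * cavity volume)
  r <- gset_ig$r_grid
  sel <- r < R_ig
  w <- r[sel]^2  # shell-volume weights (uniform grid)
  for (n in 1:5) {
    i <- match(n, gset_ig$n_values)
    m <- sum(gset_ig$g[i, sel] * w) / sum(w)
    expect_lt(abs(m - n / 3), 0.05 * max(1, n / 3))
  }
})

test_that("a single frame with one interior particle fills only its bin", {
  R <- 3
  fr <- solvent_frame(matrix(c(10 + 1.62, 10, 10), 1), 20, c(10, 10, 10))
  gs <- accumulate_gn(list(fr), cavity_spec(R = R), rho = 0.01,
                      bin_width = 0.05)
  i1 <- match(1, gs$n_values)
  inside <- gs$r_grid < R
  nz <- which(gs$counts[i1, inside] > 0)
  expect_length(nz, 1)
  expect_lt(abs(gs$r_grid[inside][nz] - 1.62), 0.05)
})

test_that("unconditioned uniform frames give a flat unit RDF", {
  pool <- colSums(gset_ig$counts)
  fc <- sum(gset_ig$frame_counts)
  dr <- gset_ig$r_grid[2] - gset_ig$r_grid[1]
  shell <- 4 / 3 * pi * ((gset_ig$r_grid + dr / 2)^3 -
                           (gset_ig$r_grid - dr / 2)^3)
  g_all <- pool / (fc * shell * rho_ig)
  sel <- gset_ig$r_grid > 1  # skip tiny-shell bins with few counts
  expect_lt(max(abs(g_all[sel] - 1)), 4 / sqrt(min(pool[sel])))
})

test_that("knitting recovers the ideal-gas continuity constants and
           Poisson distribution", {
  kn <- knit_all(gset_ig, min_frames = 100)
  exact <- log(3 / (kn$n + 1))
  expect_lt(max(abs(kn$ln_K - exact)), 0.2)  # pre-registered bound
  pn <- assemble_pn(kn)
  pois <- dpois(pn$n_values, 3)
  pois <- pois / sum(pois)
  expect_lt(max(abs(cumsum(pn$p) - cumsum(pois))), 0.05)
})

test_that("knit fit is exact on constructed fixtures", {
  # branches already continuous: no step
  gs0 <- exact_ideal_gset(R = 3.3, n_mean = 3, n_values = 2:4)
  gs0$g[] <- 1  # identical flat branches
  f0 <- knit_fit(gs0, 3)
  expect_lt(abs(f0$ln_Kn), 1e-10)
  # quadratic PMF with an injected step s is recovered exactly
  s <- 0.731
  gs <- exact_ideal_gset(R = 3.3, n_mean = 3, n_values = 2:4)
  x <- gs$r_grid - 3.3
  pmf <- 0.3 * x^2 - 0.2 * x + 0.05
  i3 <- match(3, gs$n_values)
  i4 <- match(4, gs$n_values)
  gs$g[i3, ] <- exp(-pmf)              # exterior branch of g_3
  gs$g[i4, ] <- exp(-(pmf + s))        # interior branch: -ln g_4 carries +s
  fit <- knit_fit(gs, 3)
  expect_equal(fit$ln_Kn, s, tolerance = 1e-10)
  expect_equal(fit$alpha2, 0.3, tolerance = 1e-8)
  expect_equal(fit$alpha1, -0.2, tolerance = 1e-8)
  # the fitted -ln y is continuous at R by construction: the interior
  # branch minus ln K meets the exterior quadratic exactly
  expect_equal(fit$alpha0, 0.05, tolerance = 1e-8)
})

test_that("degenerate knit inputs fail loudly", {
  gs <- exact_ideal_gset(R = 3.3, n_mean = 3, n_values = 2:4)
  expect_error(knit_fit(gs, 4), "must both be present")
  gs$g[match(4, gs$n_values), gs$r_grid < 3.3] <- 0
  expect_warning(expect_error(knit_fit(gs, 3), "fewer than 6"),
                 "non-positive")
})

test_that("assemble_pn reproduces closed-form ladders", {
  lam <- 2.7
  lnK <- log(lam / (0:14 + 1))
  pn <- assemble_pn(lnK)
  pois <- dpois(0:15, lam)
  expect_equal(pn$p, pois / sum(pois), tolerance = 1e-12)
  # constant ln K gives a geometric-like law
  cc <- -0.4
  pn2 <- assemble_pn(rep(cc, 10))
  direct <- exp(cc * (0:10))
  expect_equal(pn2$p, direct / sum(direct), tolerance = 1e-12)
  # a gap in the ladder is an error naming the missing state
  expect_error(assemble_pn(data.frame(n = c(0, 1, 3), ln_K = c(1, 1, 1),
                                      se = 0)), "missing n = 2")
})

test_that("the occupancy-averaged RDF is flat (passive cavity)", {
  # exact closed forms: Poisson weights on exact ideal branches sum to 1
  gs <- exact_ideal_gset(R = 3.3, n_mean = 3, n_values = 0:25)
  pn <- synthetic_pn("poisson", mean = 3, n_max = 25)
  pc <- passivity_check(gs, pn, p_floor = 0)
  expect_lt(pc$max_abs_deviation, 1e-9)
  # degenerate single-occupancy system: the average is g_k itself
  pk <- pn_distribution(c(0, 0, 1, 0), 2:5, provenance = "theory")
  stopifnot(4 %in% gs$n_values)
  pc2 <- passivity_check(gs, pk, p_floor = 0.5)
  i4 <- match(4, gs$n_values)
  expect_equal(pc2$max_abs_deviation, max(abs(gs$g[i4, ] - 1)),
               tolerance = 1e-12)
  # simulated ideal-gas data: deviation within stochastic error per bin
  kn <- knit_all(gset_ig, min_frames = 100)
  pn_sim <- assemble_pn(kn)
  pcs <- passivity_check(gset_ig, pn_sim, min_count = 100)
  prof <- pcs$profile[pcs$profile$count >= 100, ]
  sigma <- pmax(prof$mean_g, 0.1) / sqrt(prof$count)
  expect_true(all(abs(prof$deviation) < 4 * sigma + 0.02))
})

test_that("ideal-gas reference closed forms are exact", {
  ref <- ideal_gas_reference(2, 1)
  expect_identical(ref$y_n, 1)
  expect_equal(ref$g_interior_np1, 1)    # (1+1)/2
  expect_equal(ideal_gas_reference(2, 0)$K_n, 2)
  for (lam in c(0.5, 5, 50)) {
    n <- 0:ceiling(lam + 12 * sqrt(lam) + 20)
    expect_equal(sum(ideal_gas_reference(lam, n)$p_n), 1, tolerance = 1e-9)
  }
})
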