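ti <- theory_inputs()  # mW water at ambient conditions

test_that("theory inputs derive their reduced quantities correctly", {
  expect_equal(ti$Z, ti$beta * 1 * ATM_TO_KJ_MOL_A3 / ti$rho,
               tolerance = 1e-12)
  expect_equal(ti$eta, pi * ti$rho * 2.65^3 / 6, tolerance = 1e-12)
  expect_gt(ti$chi_inf, 0)
  expect_lt(ti$chi_inf, 1)
  expect_error(theory_inputs(rho = -1), "rho > 0")
  expect_error(theory_inputs(d_ww = 20), "eta < 1")
})

test_that("chi interpolation honors both exact limits and matches an
           independent transcription", {
  # macroscopic: compressibility value
  expect_equal(chi_igft(1e4, ti), ti$chi_inf, tolerance = 1e-4)
  expect_equal(chi_igft(1e6, ti), ti$chi_inf, tolerance = 1e-6)
  # microscopic: Poisson value, compared against the independent coding
  expect_equal(chi_igft(1e-6, ti), chi_ref(1e-6, ti), tolerance = 1e-12)
  expect_equal(chi_igft(1e-6, ti), 1, tolerance = 1e-6)
  # representative radii against the second implementation
  for (R in c(2.1, 3.7, 6.3))
    expect_equal(chi_igft(R, ti), chi_ref(R, ti), tolerance = 1e-12)
  # smooth and monotone over the studied range
  chis <- chi_igft(seq(0.5, 20, 0.1), ti)
  expect_true(all(diff(chis) < 0))
})

test_that("Gaussian free energy has its mode, symmetry and empty-cavity
           closed form", {
  R <- 3.3
  gm <- gaussian_model(R, ti)
  expect_equal(mu_n_gaussian(gm$n_mean, R, ti),
               0.5 * log(2 * pi * gm$sigma2), tolerance = 1e-12)
  for (x in c(0.5, 1.7, 3.1))
    expect_equal(mu_n_gaussian(gm$n_mean + x, R, ti),
                 mu_n_gaussian(gm$n_mean - x, R, ti), tolerance = 1e-12)
  # beta mu0 equals the negative log of the normalized Gaussian at n = 0
  expect_equal(mu0_igft(R, ti),
               -dnorm(0, gm$n_mean, sqrt(gm$sigma2), log = TRUE),
               tolerance = 1e-12)
  expect_equal(mu0_igft(R, ti),
               gm$n_mean / (2 * gm$chi) +
                 0.5 * log(2 * pi * gm$chi * gm$n_mean), tolerance = 1e-12)
})

test_that("bubble geometry obeys its identities", {
  R <- 6.3
  nm <- mean_occupancy(R, ti)
  b_full <- bubble_geometry(nm, R, ti)
  expect_equal(b_full$V_bubble, 0)
  expect_equal(b_full$R_bubble, 0)
  b_empty <- bubble_geometry(0, R, ti)
  expect_equal(b_empty$R_bubble, R, tolerance = 1e-12)
  expect_equal(b_empty$A_eff, 4 * pi * (R + b_empty$DeltaR)^2,
               tolerance = 1e-12)
  expect_error(bubble_geometry(nm + 1, R, ti), "no bubble")
  # the fitted interface offset gives a 1.6 A radial increment
  expect_equal(round(b_empty$DeltaR, 1), 1.6)
})

test_that("bubble free energy: constant at zero tension/pressure, linear
           in gamma, derivative matches finite differences", {
  ti0 <- theory_inputs(gamma = 0, pressure = 0)
  expect_equal(mu_n_bubble(c(0, 5, 10), 6.3, ti0, epsilon_continuity = 2.5),
               rep(2.5, 3), tolerance = 1e-12)
  # doubling gamma doubles the interfacial term
  t1 <- theory_inputs(gamma = 33)
  t2 <- theory_inputs(gamma = 66)
  e1 <- mu_n_bubble(10, 6.3, t1) - t1$Z * (mean_occupancy(6.3, t1) - 10)
  e2 <- mu_n_bubble(10, 6.3, t2) - t2$Z * (mean_occupancy(6.3, t2) - 10)
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
  # removal work equals the central finite difference of the bubble branch
  h <- 1e-6
  for (n in c(5, 12, 20)) {
    fd <- -(mu_n_bubble(n + h, 6.3, ti) - mu_n_bubble(n - h, 6.3, ti)) /
      (2 * h)
    expect_equal(removal_work(n, 6.3, ti)$bubble, fd, tolerance = 1e-6)
  }
  # Gaussian removal work likewise
  h <- 1e-6
  fd_g <- -(mu_n_gaussian(20 + h, 6.3, ti) -
              mu_n_gaussian(20 - h, 6.3, ti)) / (2 * h)
  expect_equal(removal_work(20, 6.3, ti)$gaussian, fd_g, tolerance = 1e-6)
})

test_that("nucleation occupancy: closed form at Z = delta = 0, series
           convergence, and disappearance under extreme tension", {
  tz <- theory_inputs(pressure = 0, delta = 0)
  R <- 6.3
  gm <- gaussian_model(R, tz)
  a <- (3 / (4 * pi * tz$rho))^(1 / 3)
  cc <- 2 * tz$beta_gamma / (tz$rho * a)
  exact <- gm$n_mean - (cc * gm$sigma2)^(3 / 4)
  expect_equal(n_star_numeric(R, tz), exact, tolerance = 1e-10)
  expect_equal(n_star_series(R, tz), exact, tolerance = 1e-12)
  # second-order accuracy: halving Z and delta shrinks the error >= 4x
  mk <- function(scale) {
    t <- theory_inputs(pressure = 40 * scale, delta = 0.8 * scale)
    abs(n_star_numeric(R, t) - n_star_series(R, t))
  }
  e1 <- mk(1); e2 <- mk(0.5)
  expect_gt(e1 / e2, 4)
  # enormous tension on a small cavity: the formal root is negative
  thuge <- theory_inputs(gamma = 5000)
  expect_true(is.na(n_star_numeric(2.1, thuge)))
  # series n* decreases monotonically with gamma at fixed R
  ns <- vapply(seq(30, 120, 10), function(g)
    n_star_series(R, theory_inputs(gamma = g)), numeric(1))
  expect_true(all(diff(ns) < 0))
  # n* < <n> whenever a root exists
  for (R in seq(3.3, 6.3, 0.5)) {
    v <- n_star_numeric(R, ti)
    if (!is.na(v)) expect_lt(v, mean_occupancy(R, ti))
  }
})

test_that("augmented free energy joins the branches continuously in value
           and derivative", {
  R <- 6.3
  ns <- n_star_numeric(R, ti)
  expect_false(is.na(ns))
  eps <- mu_n_aft(ns - 1e-9, R, ti) - mu_n_aft(ns + 1e-9, R, ti)
  expect_lt(abs(eps), 1e-6)  # value continuity (1e-9 occupancy offset)
  # exact equality of the two branch formulas at n*
  gm_val <- mu_n_gaussian(ns, R, ti)
  bub_val <- mu_n_aft(ns - 1e-12, R, ti)
  expect_equal(gm_val, bub_val, tolerance = 1e-12)
  # derivative continuity at n* (the defining property): the analytic
  # removal works agree to root-finder precision, and one-sided numeric
  # derivatives agree to finite-difference accuracy
  w <- removal_work(ns, R, ti)
  expect_lt(abs(w$gaussian - w$bubble), 1e-6)
  h <- 1e-5
  d_lo <- (mu_n_aft(ns, R, ti) - mu_n_aft(ns - h, R, ti)) / h
  d_hi <- (mu_n_aft(ns + h, R, ti) - mu_n_aft(ns, R, ti)) / h
  expect_lt(abs(d_lo - d_hi), 1e-4)
  # Gaussian branch untouched above n*
  n_hi <- seq(ceiling(ns), 50)
  expect_equal(mu_n_aft(n_hi, R, ti), mu_n_gaussian(n_hi, R, ti),
               tolerance = 1e-12)
  # two code paths, one number, for the empty cavity
  expect_equal(mu0_aft(R, ti), mu_n_aft(0, R, ti), tolerance = 1e-12)
  # without a nucleated bubble the theory is purely Gaussian
  expect_equal(mu_n_aft(0:3, 2.1, ti), mu_n_gaussian(0:3, 2.1, ti),
               tolerance = 1e-12)
})

test_that("the augmented distribution stays normalized at study-scale
           parameters", {
  for (R in c(4.3, 5.3, 6.3)) {
    gm <- gaussian_model(R, ti)
    n <- 0:ceiling(gm$n_mean + 8 * sqrt(gm$sigma2))
    s <- sum(exp(-mu_n_aft(n, R, ti)))
    expect_lt(abs(s - 1), 0.05)
  }
})

test_that("delta is recovered from empty-cavity free energies", {
  truth <- theory_inputs(delta = 0.5)
  Rs <- seq(4.3, 6.3, 0.4)
  clean <- data.frame(R = Rs,
                      bmu0 = vapply(Rs, function(R) mu0_aft(R, truth),
                                    numeric(1)))
  fit <- fit_delta(clean, theory_inputs())
  expect_true(fit$converged)
  expect_lt(abs(fit$delta - 0.5), 1e-8)
  # small noise: recovered within a loose interval
  set.seed(5)
  noisy <- clean
  noisy$bmu0 <- noisy$bmu0 + rnorm(nrow(noisy), sd = 0.3)
  noisy$err <- 0.3
  fit2 <- fit_delta(noisy, theory_inputs())
  expect_lt(abs(fit2$delta - 0.5), 0.1)
  # all-Gaussian data: flat objective is an error
  flat <- data.frame(R = c(1.6, 1.8, 2.0),
                     bmu0 = vapply(c(1.6, 1.8, 2.0), function(R)
                       mu0_igft(R, truth), numeric(1)))
  expect_error(fit_delta(flat, theory_inputs()), "not identifiable")
})

test_that("surface-tension transfer reproduces the experimental slope", {
  # moving a 300 K reference down to 298.15 K adds ~0.29 dyn/cm
  g <- corrected_surface_tension(66.0, 300, 298.15)
  expect_equal(round(g, 1), 66.3)
  expect_gt(water_surface_tension(298.15), water_surface_tension(300))
})
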