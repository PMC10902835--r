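# Sampler checks against exact reference-solvent statistics.

kT298 <- kBT(298.15)

ig_config <- function(rho, N, seed, passes, L = (N / rho)^(1 / 3),
                      sample_every = 1, ...) {
  simulation_config(solvent_model = "ideal_gas", n_particles = N,
                    seed = seed,
                    pressure = rho * kT298 / ATM_TO_KJ_MOL_A3,
                    init_density = rho, passes_equilibration = 300,
                    passes_production = passes,
                    sample_every = sample_every,
                    step_trans = L / 2, step_cav = L / 2, ...)
}

test_that("occupancy counts centers strictly inside the cavity", {
  cav <- cavity_spec(R = 3)
  empty <- solvent_frame(matrix(numeric(0), ncol = 3), 20)
  expect_identical(occupancy(empty, cav), 0L)
  one <- solvent_frame(matrix(c(10 + 1.5, 10, 10), 1), 20,
                       cavity_center = c(10, 10, 10))
  expect_equal(occupancy(one, cav), 1)
  # boundary convention: exactly at R counts as outside
  onR <- solvent_frame(matrix(c(13, 10, 10), 1), 20, c(10, 10, 10))
  expect_equal(occupancy(onR, cav), 0)
  # 100 random particles against a direct distance scan
  set.seed(2)
  pos <- matrix(runif(300) * 20, ncol = 3)
  fr <- solvent_frame(pos, 20, c(10, 10, 10))
  direct <- sum(min_image_dist(fr$positions, c(10, 10, 10), rep(20, 3)) < 3)
  expect_equal(occupancy(fr, cav), direct)
})

test_that("umbrella energy is the stated harmonic form", {
  expect_identical(umbrella_energy(7, cavity_spec(3, k0 = 4, n0 = 7)), 0)
  expect_identical(umbrella_energy(12, cavity_spec(3, k0 = 0, n0 = 2)), 0)
  expect_equal(umbrella_energy(5, cavity_spec(3, k0 = 2.5, n0 = 2)), 11.25)
})

test_that("identical seed and config reproduce the trajectory exactly", {
  cfg <- ig_config(0.02, 40, seed = 12, passes = 200)
  cav <- cavity_spec(R = 3, k0 = 2, n0 = 3)
  r1 <- run_window(cfg, cav)
  r2 <- run_window(cfg, cav)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$histogram$counts, r2$histogram$counts)
  r3 <- run_window(ig_config(0.02, 40, seed = 13, passes = 200), cav)
  expect_false(identical(r1$samples$n, r3$samples$n))
})

test_that("ideal-gas NPT reproduces the exact equation of state", {
  # <N/V> = beta P exactly for the ideal gas in the NPT ensemble
  rho <- 0.02
  cfg <- ig_config(rho, 100, seed = 5, passes = 6000)
  run <- run_window(cfg, cavity_spec(R = 3), move_cavity = FALSE)
  nv <- 100 / run$samples$volume
  se <- blocked_se(nv, 15)
  expect_lt(abs(mean(nv) - rho), 3 * se)
})

test_that("unbiased ideal-gas occupancy is Poisson", {
  rho <- 0.02
  R <- (3 * 3 / (4 * pi * rho))^(1 / 3)  # mean occupancy 3
  cfg <- ig_config(rho, 150, seed = 6, passes = 15000, sample_every = 5)
  run <- run_window(cfg, cavity_spec(R = R))
  n <- run$samples$n
  lam <- rho * 4 / 3 * pi * R^3
  k <- max(n)
  tab <- tabulate(n + 1, nbins = k + 1)
  p_exp <- dpois(0:(k - 1), lam)
  p_exp <- c(p_exp, 1 - sum(p_exp))
  ct <- suppressWarnings(chisq.test(tab, p = p_exp))
  expect_gt(ct$p.value, 0.01)
  expect_lt(abs(mean(n) - lam), 4 * blocked_se(n, 15))
})

test_that("biased sampling equals the unbiased law reweighted by the
           umbrella Boltzmann factor", {
  rho <- 0.02
  R <- (3 * 3 / (4 * pi * rho))^(1 / 3)
  cav <- cavity_spec(R = R, k0 = 3, n0 = 6)
  cfg <- ig_config(rho, 100, seed = 8, passes = 8000, sample_every = 2)
  run <- run_window(cfg, cav)
  n <- run$samples$n
  lam <- rho * 4 / 3 * pi * R^3
  grid <- 0:25
  q <- dpois(grid, lam) * exp(-umbrella_energy(grid, cav) / kT298)
  q <- q / sum(q)
  emp <- tabulate(n + 1, nbins = 26) / length(n)
  expect_lt(max(abs(emp - q)), 0.03)
  expect_lt(abs(mean(n) - sum(grid * q)), 0.15)
})

test_that("Widom insertion recovers its closed forms", {
  ig <- solvent_model("ideal_gas")
  rho <- 0.02
  frames <- generate_ideal_gas_fixture(rho, 14, 60, seed = 4)
  # a solvent test particle in an ideal gas costs nothing
  w0 <- widom_mu_ex(frames, ig, trials_per_frame = 50, test = "solvent")
  expect_identical(w0$mu_ex, 0)
  # trial radius zero never overlaps
  wr0 <- widom_mu_ex(frames, ig, trials_per_frame = 50,
                     test = "hard_sphere", test_radius = 0)
  expect_identical(wr0$mu_ex, 0)
  # hard-sphere test particle: Poisson vacancy probability exp(-rho v)
  Rt <- 2.2
  w <- widom_mu_ex(frames, ig, trials_per_frame = 4000,
                   test = "hard_sphere", test_radius = Rt, seed = 31)
  exact <- kT298 * rho * 4 / 3 * pi * Rt^3
  expect_lt(abs(w$mu_ex - exact), 3 * w$se + 0.01)
  expect_false(w$infinite)
})

test_that("move-size tuning happens in equilibration only and freezes", {
  cfg <- ig_config(0.02, 40, seed = 9, passes = 500, tune_every = 10)
  run <- run_window(cfg, cavity_spec(R = 3))
  # steps were tuned away from their initial values during equilibration
  expect_false(isTRUE(all.equal(run$diagnostics$step_trans, 0.3)))
  # production acceptance for the ideal gas with no bias is 100%
  expect_equal(run$diagnostics$acc_trans, 1)
})

test_that("R-level reference moves stay consistent with the energy model", {
  set.seed(14)
  mod <- solvent_model("ideal_gas")
  fr <- solvent_frame(matrix(runif(60) * 12, ncol = 3), 12)
  st <- mc_state(fr, mod, cavity_spec(R = 3, k0 = 2, n0 = 4))
  for (k in 1:30) {
    st <- displacement_move(st)$state
    st <- cavity_move(st)$state
    st <- volume_move(st)$state
  }
  expect_equal(st$n, occupancy(st$frame, st$cavity))
  expect_equal(st$energy, total_energy(st$frame, mod))
  # ideal-gas displacement with no umbrella is always accepted
  st2 <- mc_state(fr, mod, cavity_spec(R = 3))
  acc <- vapply(1:20, function(i) displacement_move(st2)$accepted,
                logical(1))
  expect_true(all(acc))
})

test_that("window ladder spans the occupancy range with stiffer springs
           when emptying", {
  lad <- window_ladder(10)
  expect_equal(lad$n0[1], 0)
  expect_gte(max(lad$n0), 10)
  expect_true(all(diff(lad$n0) == 2))
  expect_true(all(diff(lad$k0) <= 0))  # stiffest at n0 = 0
  expect_true(all(lad$k0 >= 2.5 & lad$k0 <= 9))
  lad2 <- window_ladder(10, k0_override = 4)
  expect_true(all(lad2$k0 == 4))
})
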