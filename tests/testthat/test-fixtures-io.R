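test_that("ideal-gas fixture is exactly Poisson and seed-reproducible", {
  empty <- generate_ideal_gas_fixture(0, 10, 5, seed = 1)
  expect_true(all(vapply(empty, function(f) nrow(f$positions), 1L) == 0))
  rho <- 0.02
  R <- (3 * 3 / (4 * pi * rho))^(1 / 3)
  frames <- generate_ideal_gas_fixture(rho, 12, 10000, seed = 2)
  cav <- cavity_spec(R = R)
  n <- vapply(frames, occupancy, integer(1), cavity = cav)
  k <- max(n)
  tab <- tabulate(n + 1, nbins = k + 1)
  p <- dpois(0:(k - 1), 3)
  ct <- suppressWarnings(chisq.test(tab, p = c(p, 1 - sum(p))))
  expect_gt(ct$p.value, 0.01)
  again <- generate_ideal_gas_fixture(rho, 12, 10000, seed = 2)
  expect_identical(lapply(frames[1:10], `[[`, "positions"),
                   lapply(again[1:10], `[[`, "positions"))
})

test_that("hard-sphere fixture has no overlaps and a step-like dilute
           RDF", {
  none <- generate_hard_sphere_fixture(0, 2.5, 12, 3, seed = 1)
  expect_true(all(vapply(none, function(f) nrow(f$positions), 1L) == 0))
  d <- 2.5
  frames <- generate_hard_sphere_fixture(0.008, d, 14, 40, seed = 6)
  mind <- vapply(frames, function(fr) {
    N <- nrow(fr$positions)
    m <- Inf
    for (i in seq_len(N - 1)) {
      di <- min_image_dist(fr$positions[(i + 1):N, , drop = FALSE],
                           fr$positions[i, ], fr$box_lengths)
      m <- min(m, di)
    }
    m
  }, numeric(1))
  expect_true(all(mind >= d))
  # dilute limit: pair counts just outside contact match the ideal value
  shell_lo <- d; shell_hi <- d + 1.5
  counts <- 0; frames_n <- 0
  for (fr in frames) {
    N <- nrow(fr$positions)
    for (i in seq_len(N - 1)) {
      di <- min_image_dist(fr$positions[(i + 1):N, , drop = FALSE],
                           fr$positions[i, ], fr$box_lengths)
      counts <- counts + sum(di >= shell_lo & di < shell_hi)
    }
    frames_n <- frames_n + N * (N - 1) / 2
  }
  vshell <- 4 / 3 * pi * (shell_hi^3 - shell_lo^3)
  expected <- frames_n * vshell / 14^3
  expect_lt(abs(counts / expected - 1), 4 / sqrt(expected) + 0.05)
  expect_error(generate_hard_sphere_fixture(0.1, 3, 12, 1, seed = 1),
               "packing")
})

test_that("synthetic occupancy distributions match their closed forms", {
  g <- synthetic_pn("gaussian", mean = 10, var = 5)
  expect_equal(sum(g$p), 1, tolerance = 1e-12)
  expect_equal(which.max(g$p) - 1 + min(g$n_values), 10)
  p <- synthetic_pn("poisson", mean = 4, n_max = 30)
  expect_equal(p$p, dpois(0:30, 4) / sum(dpois(0:30, 4)), tolerance = 1e-12)
  ti <- theory_inputs()
  a <- synthetic_pn("aft", R = 5.3, inputs = ti)
  mu <- mu_n_aft(a$n_values, 5.3, ti)
  expect_equal(a$p, exp(-mu) / sum(exp(-mu)), tolerance = 1e-10)
})

test_that("writers and readers round-trip byte-identically", {
  dir <- tempfile(); dir.create(dir)
  # occupancy distribution TSV
  pn <- synthetic_pn("poisson", mean = 3, n_max = 12)
  f1 <- file.path(dir, "pn.tsv")
  write_pn_tsv(pn, f1)
  pn2 <- read_pn_tsv(f1, provenance = "theory")
  f2 <- file.path(dir, "pn2.tsv")
  write_pn_tsv(pn2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(pn2$p, pn$p, tolerance = 1e-12)
  # RDF set directory
  gs <- exact_ideal_gset(R = 3.3, n_mean = 3, n_values = 0:4)
  d1 <- file.path(dir, "rdf")
  write_rdf_set(gs, d1)
  gs2 <- read_rdf_set(d1)
  expect_equal(gs2$g, gs$g, tolerance = 1e-12)
  expect_identical(gs2$n_values, gs$n_values)
  d2 <- file.path(dir, "rdf2")
  write_rdf_set(gs2, d2)
  expect_identical(readLines(file.path(d1, "g_n002.tsv")),
                   readLines(file.path(d2, "g_n002.tsv")))
  # extended-XYZ frames
  frames <- generate_ideal_gas_fixture(0.01, 9, 3, seed = 3)
  fx <- file.path(dir, "tr.xyz")
  write_extxyz(frames, fx)
  back <- read_extxyz(fx)
  expect_equal(length(back), 3)
  expect_equal(back[[2]]$positions, frames[[2]]$positions,
               tolerance = 1e-9)
  expect_equal(back[[1]]$box_lengths, frames[[1]]$box_lengths)
  fx2 <- file.path(dir, "tr2.xyz")
  write_extxyz(back, fx2)
  expect_identical(readLines(fx), readLines(fx2))
  # manifest
  m <- run_manifest(list(a = 1, b = "x"), seed = 7,
                    stages = list(s1 = list(inputs = "i", outputs = "o")))
  fm <- file.path(dir, "m.json")
  write_manifest(m, fm)
  m2 <- read_manifest(fm)
  expect_equal(m2$seed, 7)
  expect_equal(m2$config_hash, m$config_hash)
})

test_that("run configuration files reject unknown keys", {
  tmp <- tempfile()
  writeLines(c("temperature = 300", "R = 3.3"), tmp)
  cfg <- read_run_config(tmp)
  expect_equal(cfg$temperature, 300)
  writeLines(c("temperature = 300", "nonsense = 1"), tmp)
  expect_error(read_run_config(tmp), "unknown config key")
})

test_that("the command-line interface runs end to end", {
  cli <- system.file("cli", "cavityfluct", package = "cavityfluct")
  expect_true(nzchar(cli))
  dir <- tempfile(); dir.create(dir)
  out <- file.path(dir, "fix.xyz")
  res <- system2("Rscript", c(cli, "fixtures", "--kind", "ideal_gas",
                              "--rho", "0.02", "--box", "10",
                              "--frames", "5", "--seed", "3",
                              "--out", out), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  tout <- file.path(dir, "theory.tsv")
  res2 <- system2("Rscript", c(cli, "theory", "--mode", "aft",
                               "--R", "6.3", "--out", tout),
                  stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(tout))
  tt <- read.table(tout, header = TRUE, sep = "\t")
  expect_true(all(c("n", "beta_mu") %in% names(tt)))
})
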