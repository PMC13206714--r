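test_that("default panel has eight analytes partitioned over the four zones", {
  panel <- default_panel()
  expect_length(panel, 8)
  rts <- vapply(panel, `[[`, numeric(1), "retention_time")
  expect_true(all(rts >= 2.9227 & rts <= 4.6827))

  # explicit scan of each retention time against the printed windows
  zones <- default_zones()
  membership <- vapply(rts, function(rt) {
    hit <- vapply(zones, function(z) rt >= z$t_start && rt <= z$t_end,
                  logical(1))
    expect_equal(sum(hit), 1L)  # windows abut, no double membership
    which(hit)
  }, integer(1))
  expect_setequal(unique(membership), 1:4)

  # zone membership matches the expected analyte grouping
  for (z in zones)
    expect_setequal(names(membership[membership == which(names(zones) == z$name)]),
                    z$analytes)
})

test_that("panel spectra are nonnegative and mutually distinct", {
  wl <- seq(190, 400, length.out = 150)
  S <- reference_spectra(default_panel(), wl)
  expect_true(all(S >= 0))
  expect_equal(unname(sqrt(colSums(S^2))), rep(1, 8), tolerance = 1e-12)
  cc <- crossprod(S)
  diag(cc) <- 0
  expect_lt(max(cc), 0.99)
})

test_that("analyte_spec validates its invariants", {
  expect_error(analyte_spec("GC", 6, 0.02, list(c(210, 10, 1))),
               "acquisition window")
  expect_error(analyte_spec("GC", 3, -1, list(c(210, 10, 1))), "> 0")
  expect_error(analyte_spec("GC", 3, 0.02, list(c(210, 10, 0))),
               "at least one")
})

test_that("noiseless cubes reconstruct exactly from ground-truth factors", {
  sim <- make_component_cube(c("EGC", "EGCG"), seed = 3)
  tr <- sim$truth
  d <- dim(sim$cube$values)
  rec <- array(0, d)
  for (n in seq_len(ncol(tr$concentrations)))
    rec <- rec + outer(tr$concentrations[, n],
                       outer(tr$chrom_profiles[, n], tr$spec_profiles[, n]))
  dimnames(rec) <- NULL
  expect_equal(sim$cube$values, rec, tolerance = 1e-12)
})

test_that("cube simulation is bit-reproducible given the seed", {
  cfg <- cube_sim_config(n_time_points = 40, n_wavelengths = 30,
                         noise_sd = 0.5, n_interferents = 2, seed = 11)
  des <- table1_fixture()
  a <- simulate_cube(des, default_panel(), cfg)
  b <- simulate_cube(des, default_panel(), cfg)
  expect_identical(a$cube$values, b$cube$values)
  expect_identical(a$truth$interferent_concentrations,
                   b$truth$interferent_concentrations)
  cfg2 <- cube_sim_config(n_time_points = 40, n_wavelengths = 30,
                          noise_sd = 0.5, n_interferents = 2, seed = 12)
  expect_false(identical(simulate_cube(des, default_panel(), cfg2)$cube$values,
                         a$cube$values))
})

test_that("a single-analyte sample yields a rank-1 cube", {
  des <- calibration_design(c("S1", "S2"), c("calibration", "calibration"),
                            matrix(c(30, 30), 2, 1,
                                   dimnames = list(NULL, "CAF")))
  # two identical samples so the cube constructor is satisfied; each sample
  # slice must be rank 1
  sim <- simulate_cube(des, default_panel()["CAF"],
                       cube_sim_config(n_time_points = 60, n_wavelengths = 50,
                                       seed = 2))
  sv <- svd(sim$cube$values[1, , ])$d
  expect_lt(sv[2], 1e-10 * sv[1])
})

test_that("design rows drive exactly the expected number of components", {
  des <- table1_fixture()
  j01 <- des$nominal["J01", ]
  expect_equal(sum(j01 > 0), 4)          # GC, EC, EGCG, CAF
  expect_equal(unname(j01[c("GC", "EC", "EGCG", "CAF")]),
               c(20.00, 40.00, 93.10, 31.60))
  sub <- calibration_design(c("J01", "J01b"), rep("calibration", 2),
                            rbind(j01, j01))
  sim <- simulate_cube(sub, default_panel(),
                       cube_sim_config(n_time_points = 200,
                                       n_wavelengths = 80, seed = 1))
  sv <- svd(sim$cube$values[1, , ])$d
  expect_lt(sv[5], 1e-8 * sv[1])         # no 5th component
  expect_gt(sv[4], 1e-8 * sv[1])         # but 4 real ones
})

test_that("simulate_cube rejects invalid inputs", {
  des <- table1_fixture()
  expect_error(cube_sim_config(noise_sd = -1), ">= 0")
  bad <- calibration_design("a", "calibration",
                            matrix(1, 1, 1, dimnames = list(NULL, "XX")))
  expect_error(simulate_cube(bad, default_panel()), "mismatch")
})

test_that("origin dataset reproduces the field-study layout", {
  ds <- simulate_origin_dataset(seed = 4)
  expect_equal(nrow(ds$features), 63)
  expect_equal(as.integer(table(ds$labels)), c(22, 18, 23))
  expect_true(all(ds$features[, "GCG"] == 0))
  expect_true(all(ds$features >= 0))
  expect_identical(ds$features,
                   simulate_origin_dataset(seed = 4)$features)
})

test_that("empty and invalid origin requests behave per contract", {
  ds <- simulate_origin_dataset(c(FR = 0, GMEX = 0, YTS = 0))
  expect_equal(nrow(ds$features), 0)
  expect_error(simulate_origin_dataset(c(FR = -1, GMEX = 2, YTS = 2)),
               "nonnegative")
  expect_error(simulate_origin_dataset(c(FR = 1, GMEX = 1)), "3 origins")
})

test_that("empirical moments match configuration where truncation is mild", {
  n <- 2000
  ds <- simulate_origin_dataset(c(FR = n, GMEX = 0, YTS = 0), seed = 8)
  eff <- teatrace:::origin_effect_defaults()$FR
  # analytes whose configured mean sits >= 2 SD above zero: truncation bias
  # is below the Monte-Carlo tolerance there
  for (a in c("EGC", "EC", "CAF")) {
    se <- eff$sd[a] / sqrt(n)
    expect_lt(abs(mean(ds$features[, a]) - eff$mean[a]), 3 * se)
  }
})

test_that("Furongshan caffeine mean lands near its configured value", {
  ds <- simulate_origin_dataset(seed = 21)
  fr <- ds$features[ds$labels == "FR", "CAF"]
  se <- 38.69 / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 105.58), 3 * se)
})

test_that("xor structure hides class information from the feature means", {
  ds <- simulate_origin_dataset(c(FR = 60, GMEX = 60, YTS = 60), seed = 9,
                                structure_type = "xor")
  for (a in c("EGCG", "CAF", "EC", "EGC")) {
    mu <- tapply(ds$features[, a], ds$labels, mean)
    expect_lt(max(mu) - min(mu), 25)   # class means coincide (amp is 80)
    expect_gt(min(tapply(ds$features[, a], ds$labels, sd)), 40)  # bimodal
  }
})
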