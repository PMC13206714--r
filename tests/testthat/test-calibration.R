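test_that("resolved components are matched to their reference spectra", {
  sim <- make_component_cube(c("EGC", "EGCG"), seed = 31)
  m <- atld_decompose(sim$cube, 2)
  refs <- reference_spectra(sim$panel, sim$cube$wavelength_axis)
  asg <- assign_components(m, refs)
  expect_setequal(asg$analyte, c("EGC", "EGCG"))
  expect_true(all(asg$spectral_correlation > 0.9999))
})

test_that("an extra interferent component is labelled as such", {
  sim <- make_component_cube(c("EGC", "EGCG"), n_samples = 12, seed = 33,
                             n_interferents = 1, interferent_overlap = 0.6)
  m <- atld_decompose(sim$cube, 3)
  refs <- reference_spectra(sim$panel, sim$cube$wavelength_axis)
  asg <- assign_components(m, refs)
  expect_equal(sum(asg$analyte == "interferent"), 1)
  expect_setequal(asg$analyte[asg$analyte != "interferent"],
                  c("EGC", "EGCG"))
})

test_that("references below the correlation floor yield no assignments", {
  sim <- make_component_cube(c("EGC", "EGCG"), seed = 35)
  m <- atld_decompose(sim$cube, 2)
  # references orthogonal-ish to any smooth spectrum: alternating spikes
  K <- length(sim$cube$wavelength_axis)
  refs <- matrix(rep_len(c(1, -1), K), K, 2)
  colnames(refs) <- c("EGC", "EGCG")
  asg <- assign_components(m, refs)
  expect_true(all(asg$analyte == "interferent"))
})

test_that("scores exactly proportional to nominal predict nominal exactly", {
  des <- table1_fixture()
  m <- list(C = cbind(2.5 * des$nominal[, "EGC"], 0.7 * des$nominal[, "EGCG"]),
            B = NULL, N = 2, sample_ids = des$sample_ids)
  asg <- data.frame(component = 1:2, analyte = c("EGC", "EGCG"),
                    spectral_correlation = 1)
  zp <- calibrate_and_predict(m, des, asg)
  expect_equal(zp$predicted[, "EGC"], des$nominal[, "EGC"],
               tolerance = 1e-10)
  expect_equal(zp$predicted[, "EGCG"], des$nominal[, "EGCG"],
               tolerance = 1e-10)
  expect_false(any(zp$floored))
  expect_equal(zp$calibration$intercept, c(0, 0), tolerance = 1e-8)
})

test_that("end-to-end zone quantification recovers the standards design", {
  des <- table1_fixture()
  panel <- default_panel()
  sim <- simulate_cube(des, panel,
                       cube_sim_config(n_time_points = 400,
                                       n_wavelengths = 150, seed = 41))
  refs <- reference_spectra(panel, sim$cube$wavelength_axis)
  val <- des$roles == "validation"
  for (z in default_zones()) {
    m <- atld_decompose(slice_zone(sim$cube, z), length(z$analytes))
    asg <- assign_components(m, refs, zone = z)
    zp <- calibrate_and_predict(m, des, asg)
    for (an in colnames(zp$predicted)) {
      nom <- des$nominal[val, an]
      rel <- abs(zp$predicted[val, an] - nom)[nom > 0] / nom[nom > 0]
      expect_lt(max(rel), 0.005)
    }
  }
})

test_that("calibration contract violations raise errors", {
  des <- table1_fixture()
  m <- list(C = cbind(des$nominal[, "EGC"]), N = 1,
            sample_ids = des$sample_ids)
  bad_asg <- data.frame(component = 1, analyte = "interferent",
                        spectral_correlation = NA)
  expect_error(calibrate_and_predict(m, des, bad_asg), "no analytes")
  flat <- des
  flat$nominal[, "EGC"] <- 5
  expect_error(
    calibrate_and_predict(m, flat, data.frame(component = 1, analyte = "EGC",
                                              spectral_correlation = 1)),
    "zero-variance")
})

test_that("recovery and AVE reproduce the arithmetic of the printed table", {
  des <- table1_fixture()
  # recovery formula: prediction 14.50 at nominal 16.00 is 90.6%
  P <- reported_validation_predictions()
  q <- figures_of_merit(P, des)
  expect_equal(q$recovery["Y01", "GC"], 100 * 14.50 / 16.00,
               tolerance = 1e-12)
  expect_equal(round(q$recovery["Y01", "GC"], 1), 90.6)
  # AVE from the printed recoveries: mean(90.61, 102.01, 102.14) = 98.25
  rec <- reported_validation_recoveries()
  Pr <- rec * des$nominal[rownames(rec), colnames(rec)] / 100
  qr <- figures_of_merit(Pr, des)
  expect_equal(unname(qr$AVE["GC"]), mean(c(90.61, 102.01, 102.14)),
               tolerance = 1e-10)
  expect_equal(unname(round(qr$AVE["GC"], 2)), 98.25)
})

test_that("perfect predictions give zero RMSEP and unit correlation", {
  des <- table1_fixture()
  P <- des$nominal[des$roles == "validation", ]
  q <- figures_of_merit(P, des)
  expect_equal(unname(q$RMSEP), rep(0, 8))
  expect_true(all(q$recovery[!is.na(q$recovery)] == 100))
  expect_equal(unname(q$R), rep(1, 8))
  expect_equal(unname(q$AVE), rep(100, 8))
})

test_that("RMSEP follows the I-1 divisor formula", {
  des <- table1_fixture()
  # EGC: nominal 8, 12, 16 with printed recoveries 96.58/97.68/99.56
  rec <- reported_validation_recoveries()
  P <- rec * des$nominal[rownames(rec), colnames(rec)] / 100
  q <- figures_of_merit(P, des)
  pred <- P[, "EGC"]; nom <- des$nominal[rownames(P), "EGC"]
  expect_equal(unname(q$RMSEP["EGC"]),
               sqrt(sum((nom - pred)^2) / 2), tolerance = 1e-12)
  expect_equal(unname(q$RMSEP["EGC"]), 0.2806, tolerance = 0.01)
})

test_that("single-validation-row designs report RMSEP as missing", {
  des <- calibration_design(
    c("c1", "c2", "c3", "v1"),
    c(rep("calibration", 3), "validation"),
    matrix(c(1, 2, 3, 2), 4, 1, dimnames = list(NULL, "EGC")))
  P <- matrix(2.1, 1, 1, dimnames = list("v1", "EGC"))
  q <- figures_of_merit(P, des)
  expect_true(is.na(q$RMSEP["EGC"]))
  expect_false(is.na(q$AVE["EGC"]))
})

test_that("gross recovery outliers can be excluded from RMSEP", {
  des <- table1_fixture()
  P <- reported_validation_predictions()
  q <- figures_of_merit(P, des, exclude_outlier_recoveries = TRUE)
  expect_equal(q$rmsep_excluded$CG, "Y01")
  expect_equal(q$rmsep_excluded$ECG, "Y01")
  expect_length(unlist(q$rmsep_excluded[c("GC", "EGC", "GCG", "EC",
                                          "EGCG", "CAF")]), 0)
  # with Y01 dropped the CG/ECG values match the printed table
  expect_equal(unname(q$RMSEP["CG"]), 4.3895, tolerance = 0.01)
  expect_equal(unname(q$RMSEP["ECG"]), 2.9113, tolerance = 0.01)
})

test_that("LOQ exceeds LOD under the regression-based formulas", {
  sim <- make_component_cube(c("EGC", "EGCG"), n_samples = 10, seed = 51,
                             noise_sd = 0.02)
  des <- calibration_design(sim$design$sample_ids,
                            c(rep("calibration", 7), rep("validation", 3)),
                            sim$design$nominal)
  m <- atld_decompose(sim$cube, 2)
  refs <- reference_spectra(sim$panel, sim$cube$wavelength_axis)
  zp <- calibrate_and_predict(m, des, assign_components(m, refs))
  q <- figures_of_merit(zp$predicted, des, calibration = zp$calibration)
  expect_true(all(q$LOQ > q$LOD))
  expect_equal(unname(q$LOQ / q$LOD), rep(10 / 3.3, 2), tolerance = 1e-10)
})

test_that("predictions are invariant to uniform cube rescaling", {
  sim <- make_component_cube(c("GCG", "EC"), n_samples = 10, seed = 55,
                             time_range = c(3.7, 4.05))
  des <- calibration_design(sim$design$sample_ids,
                            c(rep("calibration", 7), rep("validation", 3)),
                            sim$design$nominal)
  refs <- reference_spectra(sim$panel, sim$cube$wavelength_axis)
  fit_predict <- function(cube) {
    m <- atld_decompose(cube, 2)
    calibrate_and_predict(m, des, assign_components(m, refs))$predicted
  }
  p1 <- fit_predict(sim$cube)
  scaled <- data_cube(sim$cube$values * 37.5, sim$cube$sample_ids,
                      sim$cube$time_axis, sim$cube$wavelength_axis)
  p2 <- fit_predict(scaled)
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("origin summaries use sample SD and preserve zero columns", {
  feats <- matrix(c(1, 3, 5,   2, 2, 2,   0, 0, 0), 3, 3,
                  dimnames = list(NULL, c("EGC", "CAF", "GCG")))
  ds <- structure(list(features = feats,
                       labels = factor(c("FR", "FR", "GMEX"),
                                       levels = c("FR", "GMEX", "YTS")),
                       sample_ids = c("a", "b", "c")),
                  class = "origin_dataset")
  s <- summarize_by_origin(ds)
  expect_equal(nrow(s), 2)              # YTS empty -> omitted
  fr <- s[s$origin == "FR", ]
  expect_equal(fr$EGC_mean, 2)
  expect_equal(fr$EGC_sd, sd(c(1, 3)))  # n-1 divisor
  expect_equal(fr$GCG_mean, 0)
  expect_equal(fr$GCG_sd, 0)
  gm <- s[s$origin == "GMEX", ]
  expect_equal(gm$EGC_mean, 5)
  expect_true(is.na(gm$EGC_sd))         # single-sample group
})
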