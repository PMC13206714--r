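# Small trilinear cubes with known ground truth, used across the suite.
# Components are analytes from the default panel restricted to a narrow
# window so the cube stays small (10 samples x 50 x 40 by default).
make_component_cube <- function(analytes = c("EGC", "EGCG"),
                                n_samples = 10, n_time = 50, n_wl = 40,
                                time_range = c(3.0, 3.8), seed = 1,
                                noise_sd = 0, n_interferents = 0,
                                interferent_overlap = 0.5,
                                conc_range = c(5, 100)) {
  panel <- default_panel()[analytes]
  set.seed(seed + 5000)
  conc <- matrix(stats::runif(n_samples * length(analytes),
                              conc_range[1], conc_range[2]),
                 n_samples, length(analytes),
                 dimnames = list(NULL, analytes))
  design <- calibration_design(sprintf("S%02d", seq_len(n_samples)),
                               rep("calibration", n_samples), conc)
  sim <- simulate_cube(design, panel, cube_sim_config(
    n_time_points = n_time, n_wavelengths = n_wl, time_range = time_range,
    noise_sd = noise_sd, n_interferents = n_interferents,
    interferent_overlap = interferent_overlap, seed = seed))
  c(sim, list(design = design, panel = panel))
}

# Best |cosine| match of each true profile against fitted columns.
match_cosines <- function(truth_mat, fitted_mat) {
  Tn <- apply(truth_mat, 2, function(v) v / sqrt(sum(v^2)))
  Fn <- apply(fitted_mat, 2, function(v) v / sqrt(sum(v^2)))
  apply(abs(crossprod(Tn, Fn)), 1, max)
}

# Origin dataset with well-separated classes: per-origin means pushed apart
# and SDs shrunk, for tests that need near-perfect separability.
make_separable_dataset <- function(seed = 1,
                                   n_per_origin = c(FR = 22, GMEX = 18,
                                                    YTS = 23)) {
  eff <- list(
    FR   = list(mean = c(GC = 5,  EGC = 10, GCG = 0, CG = 1,
                         EC = 10, EGCG = 150, ECG = 5,  CAF = 40),
                sd   = c(GC = 1,  EGC = 2,  GCG = 0, CG = 0.2,
                         EC = 2,  EGCG = 10,  ECG = 1,  CAF = 5)),
    GMEX = list(mean = c(GC = 20, EGC = 60, GCG = 0, CG = 5,
                         EC = 60, EGCG = 30,  ECG = 25, CAF = 150),
                sd   = c(GC = 2,  EGC = 5,  GCG = 0, CG = 0.5,
                         EC = 5,  EGCG = 5,   ECG = 2,  CAF = 10)),
    YTS  = list(mean = c(GC = 60, EGC = 25, GCG = 0, CG = 15,
                         EC = 25, EGCG = 80,  ECG = 60, CAF = 90),
                sd   = c(GC = 5,  EGC = 2,  GCG = 0, CG = 1,
                         EC = 2,  EGCG = 8,   ECG = 5,  CAF = 8)))
  simulate_origin_dataset(n_per_origin, effect_config = eff, seed = seed)
}

shuffle_labels <- function(dataset, seed) {
  set.seed(seed)
  dataset$labels <- sample(dataset$labels)
  dataset
}
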