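#' Configuration for cube simulation
#'
#' Defaults emulate the instrument's acquisition: 400 elution time points over
#' 0-5 min and 150 wavelengths over 190-400 nm.
#'
#' @param n_time_points Number of elution time points (>= 2).
#' @param n_wavelengths Number of wavelengths (>= 2).
#' @param time_range Length-2 numeric, acquisition window in minutes.
#' @param wavelength_range Length-2 numeric, spectral window in nm.
#' @param noise_sd SD of iid additive Gaussian noise, signal units (>= 0).
#' @param baseline_amplitude Amplitude of a smooth drifting baseline, signal
#'   units; 0 disables the baseline.
#' @param n_interferents Number of uncalibrated interfering components.
#'   Interferents carry signal only in non-calibration samples, so they
#'   exercise the second-order advantage.
#' @param interferent_overlap Fraction in \[0, 1\]: 1 places each interferent at
#'   the retention time of an analyte (maximal co-elution), 0 at the edge of
#'   its zone.
#' @param seed Integer seed; fully determines the simulated cube.
#' @return Object of class `cube_sim_config`.
#' @export
cube_sim_config <- function(n_time_points = 400, n_wavelengths = 150,
                            time_range = c(0, 5),
                            wavelength_range = c(190, 400),
                            noise_sd = 0, baseline_amplitude = 0,
                            n_interferents = 0, interferent_overlap = 0.5,
                            seed = 1L) {
  if (n_time_points < 2 || n_wavelengths < 2)
    stop("need at least 2 time points and 2 wavelengths")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (interferent_overlap < 0 || interferent_overlap > 1)
    stop("interferent_overlap must be in [0, 1]")
  structure(list(n_time_points = as.integer(n_time_points),
                 n_wavelengths = as.integer(n_wavelengths),
                 time_range = time_range,
                 wavelength_range = wavelength_range,
                 noise_sd = noise_sd,
                 baseline_amplitude = baseline_amplitude,
                 n_interferents = as.integer(n_interferents),
                 interferent_overlap = interferent_overlap,
                 seed = as.integer(seed)),
            class = "cube_sim_config")
}

# Gaussian elution profile, peak height response_factor.
chrom_profile <- function(spec, time_axis) {
  spec$response_factor *
    exp(-(time_axis - spec$retention_time)^2 / (2 * spec$peak_width_sigma^2))
}

#' Simulate an HPLC-DAD data cube with known ground truth
#'
#' Builds a trilinear cube `x[i,j,k] = sum_n conc[i,n] chrom[j,n] spec[k,n]`
#' from the design's nominal concentrations and the panel's elution/spectral
#' models, then adds optional uncalibrated interferents, a smooth baseline and
#' iid Gaussian noise. The returned ground truth holds the exact factors of
#' the noiseless trilinear part (analytes and interferents), so downstream
#' resolution can be scored against it.
#'
#' Interferent concentrations are zero in calibration samples and positive in
#' validation/unknown samples; their retention times fall inside the analyte
#' elution zones (controlled by `interferent_overlap`) and their spectra are
#' drawn from the same Gaussian-band family as the analytes.
#'
#' @param design A [calibration_design()]; unknown-role rows with NA nominals
#'   are treated as zero analyte signal unless `concentrations` is given.
#' @param panel List of [analyte_spec()]; names must cover the design's
#'   analyte columns.
#' @param config A [cube_sim_config()].
#' @param concentrations Optional sample x analyte matrix overriding the
#'   design's nominal values (e.g. true concentrations of unknowns).
#' @return List with elements `cube` (a [data_cube()]) and `truth` (class
#'   `ground_truth`: `concentrations`, `chrom_profiles`, `spec_profiles`,
#'   `interferent_concentrations`, plus the interferent factor columns).
#' @export
simulate_cube <- function(design, panel, config = cube_sim_config(),
                          concentrations = NULL) {
  if (length(panel) == 0) stop("panel must be nonempty")
  panel_names <- vapply(panel, `[[`, character(1), "name")
  if (!all(design$analyte_names %in% panel_names))
    stop("design/panel analyte-name mismatch: ",
         paste(setdiff(design$analyte_names, panel_names), collapse = ", "))
  panel <- panel[match(design$analyte_names, panel_names)]

  conc <- if (is.null(concentrations)) design$nominal else as.matrix(concentrations)
  conc[is.na(conc)] <- 0
  if (any(conc < 0)) stop("concentrations must be nonnegative")

  tax <- seq(config$time_range[1], config$time_range[2],
             length.out = config$n_time_points)
  wax <- seq(config$wavelength_range[1], config$wavelength_range[2],
             length.out = config$n_wavelengths)

  A <- vapply(panel, chrom_profile, numeric(length(tax)), time_axis = tax)
  B <- vapply(panel, analyte_spectrum, numeric(length(wax)), wavelengths = wax)
  colnames(A) <- colnames(B) <- design$analyte_names

  I <- nrow(conc); J <- length(tax); K <- length(wax)

  set.seed(config$seed)
  # interferents: zone placement + same spectral family
  n_int <- config$n_interferents
  Ai <- matrix(0, J, 0); Bi <- matrix(0, K, 0); Ci <- matrix(0, I, 0)
  if (n_int > 0) {
    zones <- default_zones()
    rt_analyte <- vapply(panel, `[[`, numeric(1), "retention_time")
    Ai <- matrix(0, J, n_int); Bi <- matrix(0, K, n_int)
    Ci <- matrix(0, I, n_int)
    for (q in seq_len(n_int)) {
      z <- zones[[sample.int(length(zones), 1)]]
      in_zone <- rt_analyte >= z$t_start & rt_analyte <= z$t_end
      anchor <- if (any(in_zone)) {
        pool <- rt_analyte[in_zone]
        pool[sample.int(length(pool), 1)]
      } else (z$t_start + z$t_end) / 2
      edge <- if (anchor < (z$t_start + z$t_end) / 2) z$t_end else z$t_start
      rt <- config$interferent_overlap * anchor +
        (1 - config$interferent_overlap) * edge
      sg <- stats::runif(1, 0.025, 0.05)
      bands <- list(c(stats::runif(1, 200, 230), stats::runif(1, 8, 16), 1),
                    c(stats::runif(1, 255, 295), stats::runif(1, 10, 18),
                      stats::runif(1, 0.3, 1)))
      isp <- analyte_spec(paste0("interferent", q), rt, sg, bands,
                          response_factor = stats::runif(1, 0.8, 1.3))
      Ai[, q] <- chrom_profile(isp, tax)
      Bi[, q] <- analyte_spectrum(isp, wax)
      free <- design$roles != "calibration"
      Ci[free, q] <- stats::runif(sum(free), 10, 40)
    }
    colnames(Ai) <- colnames(Bi) <- colnames(Ci) <-
      paste0("interferent", seq_len(n_int))
  }

  Cfull <- cbind(conc, Ci)
  Afull <- cbind(A, Ai)
  Bfull <- cbind(B, Bi)
  # unfold: X_(sample) = C (B kr A)^T, then refold
  KR <- matrix(0, J * K, ncol(Cfull))
  for (n in seq_len(ncol(Cfull))) KR[, n] <- as.vector(outer(Afull[, n], Bfull[, n]))
  Xmat <- Cfull %*% t(KR)                      # I x (J*K), time fastest
  arr <- array(0, c(I, J, K))
  for (i in seq_len(I)) arr[i, , ] <- matrix(Xmat[i, ], J, K)

  if (config$baseline_amplitude > 0) {
    base_t <- exp(-tax / max(tax))
    base_w <- exp(-(wax - min(wax)) / (diff(range(wax)) / 2))
    bl <- config$baseline_amplitude * outer(base_t, base_w)
    for (i in seq_len(I)) arr[i, , ] <- arr[i, , ] + bl
  }
  if (config$noise_sd > 0)
    arr <- arr + array(stats::rnorm(I * J * K, 0, config$noise_sd), c(I, J, K))

  truth <- structure(list(concentrations = conc,
                          chrom_profiles = A, spec_profiles = B,
                          interferent_concentrations = Ci,
                          interferent_chrom = Ai, interferent_spec = Bi),
                     class = "ground_truth")
  list(cube = data_cube(arr, design$sample_ids, tax, wax), truth = truth)
}

# Per-origin means and SDs of the 63-sample field study (ug/mL), used as the
# generator's default effect configuration. GCG is below detection in every
# sample and fixed at 0.
origin_effect_defaults <- function() {
  list(
    FR   = list(mean = c(GC = 2.78, EGC = 15.82, GCG = 0, CG = 0.17,
                         EC = 19.19, EGCG = 57.31, ECG = 10.48, CAF = 105.58),
                sd   = c(GC = 1.54, EGC = 6.62, GCG = 0, CG = 0.39,
                         EC = 3.99, EGCG = 57.99, ECG = 12.24, CAF = 38.69)),
    GMEX = list(mean = c(GC = 2.03, EGC = 21.74, GCG = 0, CG = 0.90,
                         EC = 24.24, EGCG = 34.80, ECG = 5.80, CAF = 92.24),
                sd   = c(GC = 2.14, EGC = 14.26, GCG = 0, CG = 1.84,
                         EC = 11.73, EGCG = 45.91, ECG = 11.28, CAF = 41.50)),
    YTS  = list(mean = c(GC = 2.83, EGC = 17.63, GCG = 0, CG = 0.53,
                         EC = 24.11, EGCG = 64.76, ECG = 10.79, CAF = 116.95),
                sd   = c(GC = 1.36, EGC = 10.33, GCG = 0, CG = 0.60,
                         EC = 7.57, EGCG = 55.88, ECG = 11.34, CAF = 31.67))
  )
}

#' Simulate an origin-labelled analyte concentration table
#'
#' Draws per-sample concentrations of the eight analytes for three mountain
#' origins (FR = Furongshan, GMEX = Gaoma Erxi, YTS = Yuntaishan) from
#' zero-truncated Gaussians with origin-specific means and SDs. Defaults are
#' the field study's per-origin summary statistics; GCG is fixed at 0
#' (below detection in all samples). Truncation at zero is required because
#' the EGCG SDs exceed their means; it inflates means of analytes whose
#' configured mean is within ~2 SD of zero.
#'
#' `structure_type = "xor"` builds an XOR-like interaction arrangement
#' instead: every analyte is drawn from the pooled (origin-independent)
#' distribution, and four analytes (EGCG, CAF, EC, EGC) receive sign-pattern
#' corner structure — each class is a mixture of two antipodal corners of a
#' 4-cube with mutually orthogonal class patterns, so all class means
#' coincide and no linear boundary separates the classes, while the corner
#' clusters remain recoverable by non-linear methods. A stress test for the
#' classifier comparison.
#'
#' @param n_per_origin Named or ordered length-3 integer vector (FR, GMEX,
#'   YTS); defaults to the field-study sizes 22/18/23.
#' @param effect_config List per origin with numeric `mean` and `sd` vectors
#'   over the analytes; defaults to the field-study summary.
#' @param seed Integer seed.
#' @param structure_type `"origin"` (default) or `"xor"`.
#' @return Object of class `origin_dataset`: `features` (sample x analyte
#'   matrix), `labels` (factor FR/GMEX/YTS), `sample_ids`.
#' @export
simulate_origin_dataset <- function(n_per_origin = c(FR = 22, GMEX = 18, YTS = 23),
                                    effect_config = origin_effect_defaults(),
                                    seed = 1L,
                                    structure_type = c("origin", "xor")) {
  structure_type <- match.arg(structure_type)
  if (any(n_per_origin < 0)) stop("n_per_origin must be nonnegative")
  if (length(n_per_origin) != 3) stop("n_per_origin must have 3 origins")
  origins <- if (!is.null(names(n_per_origin))) names(n_per_origin) else ORIGIN_LEVELS
  set.seed(seed)
  analytes <- names(effect_config[[1]]$mean)
  feats <- list(); labs <- character(0); ids <- character(0)
  for (g in seq_along(origins)) {
    n <- n_per_origin[g]
    if (n == 0) next
    mu <- effect_config[[origins[g]]]$mean
    sg <- effect_config[[origins[g]]]$sd
    M <- matrix(0, n, length(analytes), dimnames = list(NULL, analytes))
    for (a in seq_along(analytes)) {
      if (sg[a] == 0) { M[, a] <- mu[a]; next }
      # zero-truncated Gaussian by inverse-CDF
      p0 <- stats::pnorm(0, mu[a], sg[a])
      u <- stats::runif(n, p0, 1)
      M[, a] <- stats::qnorm(u, mu[a], sg[a])
    }
    feats[[g]] <- M
    labs <- c(labs, rep(origins[g], n))
    ids <- c(ids, sprintf("%s%02d", origins[g], seq_len(n)))
  }
  X <- if (length(feats)) do.call(rbind, feats) else
    matrix(0, 0, length(analytes), dimnames = list(NULL, analytes))

  if (structure_type == "xor" && nrow(X) > 0) {
    # Re-draw every analyte from the pooled (origin-independent) mixture so
    # no feature mean carries class information, then impose sign-pattern
    # corner structure on four analytes: each class is a mixture of two
    # antipodal corners of a 4-cube, patterns chosen mutually orthogonal.
    # Class means coincide (linearly invisible); corner clusters remain
    # (resolvable by a non-linear method).
    lab <- factor(labs, levels = origins)
    pooled_mu <- Reduce(`+`, lapply(effect_config, `[[`, "mean")) / 3
    pooled_sd <- Reduce(`+`, lapply(effect_config, `[[`, "sd")) / 3
    for (a in seq_along(analytes)) {
      if (pooled_sd[a] == 0) { X[, a] <- pooled_mu[a]; next }
      p0 <- stats::pnorm(0, pooled_mu[a], pooled_sd[a])
      X[, a] <- stats::qnorm(stats::runif(nrow(X), p0, 1),
                             pooled_mu[a], pooled_sd[a])
    }
    pat <- stats::setNames(list(c(1, 1, 1, 1), c(1, -1, 1, -1),
                                c(1, -1, -1, 1)), origins)
    sig_features <- c("EGCG", "CAF", "EC", "EGC")
    base <- 150; amp <- 80; jitter_sd <- 10
    corner <- sample(c(-1, 1), nrow(X), replace = TRUE)
    for (j in seq_along(sig_features)) {
      pj <- vapply(as.character(lab), function(g) pat[[g]][j], numeric(1))
      X[, sig_features[j]] <- pmax(0, base + corner * amp * pj +
                                     stats::rnorm(nrow(X), 0, jitter_sd))
    }
  }

  structure(list(features = X,
                 labels = factor(labs, levels = origins),
                 sample_ids = ids),
            class = "origin_dataset")
}

#' @export
print.origin_dataset <- function(x, ...) {
  cat(sprintf("<origin_dataset> %d samples x %d analytes; origins: %s\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}
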