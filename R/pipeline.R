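#' Read a design or origin table written by [write_design()]
#'
#' @param path CSV path with columns `sample_id`, `role` or `origin`, then
#'   analyte columns.
#' @return A [calibration_design()] (if the second column is `role`) or an
#'   `origin_dataset` (if it is `origin`).
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 3) stop("malformed design table: ", path)
  if (names(df)[2] == "role") {
    calibration_design(df$sample_id, df$role,
                       as.matrix(df[, -(1:2), drop = FALSE]))
  } else if (names(df)[2] == "origin") {
    structure(list(features = as.matrix(df[, -(1:2), drop = FALSE]),
                   labels = factor(df$origin, levels = unique(df$origin)),
                   sample_ids = as.character(df$sample_id)),
              class = "origin_dataset")
  } else stop("second column must be 'role' or 'origin': ", path)
}

#' Default pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]: the synthetic study it
#' emulates (standards design + origin-structured unknowns sharing one
#' augmented cube), the elution zones and decomposition settings, and the
#' classification protocol.
#'
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param out_dir Output directory for artifacts.
#' @param n_per_origin Unknown (tea) samples per origin.
#' @param n_time_points,n_wavelengths Cube grid (defaults 400 x 150).
#' @param noise_sd Instrument noise SD relative to max signal (e.g. 0.002).
#' @param n_interferents Uncalibrated interferents in unknown samples.
#' @param candidates Candidate component numbers for the per-zone selection;
#'   `NULL` fixes N to the zone's expected analytes + interferents.
#' @param tol,max_iter ATLD convergence settings.
#' @param methods Classifiers to run, subset of
#'   `c("lda", "plsda", "tsnerf")`.
#' @param n_validation Validation samples for the classifier split.
#' @param run_l9 Run the full L9 screen for t-SNE-RF (slower) instead of the
#'   single default configuration.
#' @param design_csv,cube_dir Optional file inputs replacing the synthetic
#'   stage: a design table (see [read_design()]) and a directory of
#'   per-sample cube matrices (see [write_cube()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = "teatrace_run",
                            n_per_origin = c(FR = 22, GMEX = 18, YTS = 23),
                            n_time_points = 400, n_wavelengths = 150,
                            noise_sd = 0.002, n_interferents = 1,
                            candidates = NULL, tol = 1e-6, max_iter = 500,
                            methods = c("lda", "plsda", "tsnerf"),
                            n_validation = 7, run_l9 = FALSE,
                            design_csv = NULL, cube_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config")
  if (!is.null(config$design_csv) && !file.exists(config$design_csv))
    stop("design_csv does not exist: ", config$design_csv)
  if (!is.null(config$cube_dir) && !dir.exists(config$cube_dir))
    stop("cube_dir does not exist: ", config$cube_dir)
  if (is.null(config$cube_dir) != is.null(config$design_csv) &&
      !is.null(config$cube_dir))
    stop("cube_dir requires design_csv")
  bad <- setdiff(config$methods, c("lda", "plsda", "tsnerf"))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  invisible(config)
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(vals$n_per_origin)) vals$n_per_origin <- unlist(vals$n_per_origin)
  do.call(pipeline_config, vals)
}

#' Run the full resolution / quantification / classification pipeline
#'
#' Executes the whole protocol in order: (1) obtain the augmented sample set
#' (standards + unknowns) and its data cube, synthetic by default; (2) slice
#' each elution zone and resolve it by ATLD, with the component number fixed
#' from the zone's expected content or chosen by core consistency; (3) match
#' resolved spectra to the reference panel, calibrate against the standards
#' and predict all concentrations; (4) figures of merit on the validation
#' standards and per-origin summaries of the unknowns; (5) origin
#' classification of the unknowns. Artifacts are written as CSV under
#' `config$out_dir`, plus a YAML run manifest with seeds, stage timings and
#' md5 checksums. Rerunning an unchanged config reproduces identical
#' artifact bytes.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the manifest and all stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_pipeline_config(config)
  t_start <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- as.numeric(Sys.time() - t0, units = "secs")
    out
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  panel <- default_panel()
  zones <- default_zones()

  inputs <- stage("input", {
    if (!is.null(config$design_csv)) {
      design <- read_design(config$design_csv)
      cube <- read_cube(list.files(config$cube_dir, full.names = TRUE))
      origin <- NULL
      truth <- NULL
    } else {
      std <- table1_fixture()
      origin <- simulate_origin_dataset(config$n_per_origin,
                                        seed = config$seed)
      ids <- c(std$sample_ids, origin$sample_ids)
      roles <- c(std$roles, rep("unknown", length(origin$sample_ids)))
      nominal <- rbind(std$nominal,
                       origin$features[, colnames(std$nominal), drop = FALSE])
      design <- calibration_design(ids, roles, nominal)
      # noiseless pass fixes the signal scale so noise_sd is relative to it
      scale0 <- simulate_cube(design, panel, cube_sim_config(
        n_time_points = config$n_time_points,
        n_wavelengths = config$n_wavelengths, seed = config$seed))
      sig <- max(abs(scale0$cube$values))
      sim <- simulate_cube(design, panel, cube_sim_config(
        n_time_points = config$n_time_points,
        n_wavelengths = config$n_wavelengths,
        noise_sd = config$noise_sd * sig,
        n_interferents = config$n_interferents,
        seed = config$seed + 1L))
      cube <- sim$cube
      truth <- sim$truth
    }
    list(design = design, cube = cube, origin = origin, truth = truth)
  })
  design <- inputs$design
  cube <- inputs$cube

  refs <- reference_spectra(panel, cube$wavelength_axis)

  # keep only zones whose expected analytes appear in the design
  zones <- Filter(function(z)
    length(intersect(z$analytes, design$analyte_names)) > 0, zones)
  zones <- lapply(zones, function(z) {
    z$analytes <- intersect(z$analytes, design$analyte_names)
    z
  })
  if (length(zones) == 0) stop("no elution zone matches the design's analytes")

  zone_fits <- stage("atld", {
    lapply(zones, function(z) {
      sub <- slice_zone(cube, z)
      n_expected <- length(z$analytes) + config$n_interferents
      if (is.null(config$candidates)) {
        model <- atld_decompose(sub, n_expected, tol = config$tol,
                                max_iter = config$max_iter,
                                seed = config$seed)
        report <- NULL
      } else {
        report <- select_components(sub, config$candidates,
                                    tol = config$tol,
                                    max_iter = config$max_iter,
                                    seed = config$seed)
        model <- report$model
      }
      list(zone = z, model = model, report = report)
    })
  })

  quant <- stage("calibration", {
    preds <- list()
    calinfos <- list()
    for (zf in zone_fits) {
      asg <- assign_components(zf$model, refs, zone = zf$zone)
      zp <- calibrate_and_predict(zf$model, design, asg)
      preds[[zf$zone$name]] <- zp$predicted
      calinfos[[zf$zone$name]] <- zp$calibration
    }
    predicted <- do.call(cbind, unname(preds))
    predicted <- predicted[, intersect(design$analyte_names,
                                       colnames(predicted)), drop = FALSE]
    calibration <- do.call(rbind, unname(calinfos))
    list(predicted = predicted, calibration = calibration)
  })

  report <- stage("figures_of_merit",
                  figures_of_merit(quant$predicted, design,
                                   calibration = quant$calibration))

  unk <- design$roles == "unknown"
  origin_summary <- NULL
  predicted_origin <- NULL
  if (any(unk) && !is.null(inputs$origin)) {
    predicted_origin <- stage("origin_table", {
      P <- matrix(0, sum(unk), length(design$analyte_names),
                  dimnames = list(design$sample_ids[unk],
                                  design$analyte_names))
      got <- intersect(colnames(quant$predicted), colnames(P))
      P[, got] <- quant$predicted[unk, got]
      structure(list(features = P, labels = inputs$origin$labels,
                     sample_ids = rownames(P)), class = "origin_dataset")
    })
    origin_summary <- stage("origin_summary",
                            summarize_by_origin(predicted_origin))
  }

  classif <- NULL
  if (!is.null(predicted_origin) && length(config$methods) > 0) {
    classif <- stage("classification", {
      split <- split_train_validation(predicted_origin, config$n_validation,
                                      seed = config$seed)
      out <- list()
      if ("lda" %in% config$methods)
        out$lda <- lda_classify(split$train, split$validation)
      if ("plsda" %in% config$methods)
        out$plsda <- suppressWarnings(
          plsda_classify(split$train, split$validation, seed = config$seed))
      if ("tsnerf" %in% config$methods) {
        out$tsnerf <- if (config$run_l9) {
          opt <- optimize_tsne_rf(predicted_origin, split,
                                  seed = config$seed)
          out$l9_scores <- opt$scores
          opt$best
        } else {
          n_unk <- length(predicted_origin$sample_ids)
          tsne_rf_classify(predicted_origin, split,
                           hyper = list(
                             perplexity = min(50, floor((n_unk - 1) / 2)),
                             learning_rate = 100, iterations = 250,
                             early_exaggeration = 12),
                           seed = config$seed)
        }
      }
      out$split <- split
      out
    })
  }

  artifacts <- stage("write", {
    paths <- character(0)
    fom <- data.frame(metric = c("AVE", "RMSEP", "DEV", "R", "LOD", "LOQ"),
                      rbind(report$AVE, report$RMSEP, report$DEV, report$R,
                            report$LOD, report$LOQ), check.names = FALSE)
    p <- file.path(config$out_dir, "quant_report.csv")
    utils::write.csv(fom, p, row.names = FALSE); paths <- c(paths, p)
    p <- file.path(config$out_dir, "predicted_concentrations.csv")
    utils::write.csv(data.frame(sample_id = rownames(quant$predicted),
                                role = design$roles, quant$predicted,
                                check.names = FALSE),
                     p, row.names = FALSE); paths <- c(paths, p)
    if (!is.null(origin_summary)) {
      p <- file.path(config$out_dir, "origin_summary.csv")
      utils::write.csv(origin_summary, p, row.names = FALSE)
      paths <- c(paths, p)
    }
    if (!is.null(classif)) {
      cm <- do.call(rbind, lapply(
        Filter(function(x) inherits(x, "classification_result"), classif),
        function(r) data.frame(method = r$method,
                               accuracy = r$accuracy,
                               silhouette = r$silhouette)))
      p <- file.path(config$out_dir, "classification.csv")
      utils::write.csv(cm, p, row.names = FALSE); paths <- c(paths, p)
    }
    paths
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("teatrace")),
    seed = config$seed,
    stages = names(timings),
    timings_sec = lapply(timings, function(x) round(x, 3)),
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(artifacts)), basename(artifacts))),
    total_sec = round(as.numeric(Sys.time() - t_start, units = "secs"), 3))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  invisible(list(manifest = manifest, design = design, cube_dim = dim(cube),
                 zone_fits = zone_fits, quant = quant, report = report,
                 origin_summary = origin_summary,
                 predicted_origin = predicted_origin,
                 classification = classif, artifacts = artifacts))
}
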