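#' Match resolved components to analyte reference spectra
#'
#' Greedy best-match assignment on Pearson correlation between each resolved
#' spectral profile (column of `model$B`) and the reference spectra of the
#' analytes expected in the zone. Pairs are assigned in decreasing order of
#' correlation; matches below `min_correlation` are refused, and components
#' left unmatched are labelled `"interferent"`. An exact tie in which two
#' analytes claim the same component at the same correlation is ambiguous and
#' raises an error.
#'
#' @param model A `trilinear_model` from [atld_decompose()].
#' @param references Matrix (wavelength x analyte) of reference spectra on
#'   the model's wavelength grid (see [reference_spectra()]).
#' @param zone Optional [zone_spec()]; restricts candidate analytes to
#'   `zone$analytes`.
#' @param min_correlation Minimum acceptable correlation (default 0.8).
#' @return Object of class `component_assignment`: data frame with one row
#'   per component (`component`, `analyte`, `spectral_correlation`), the
#'   zone name, and the full correlation matrix as attribute `"correlations"`.
#' @export
assign_components <- function(model, references, zone = NULL,
                              min_correlation = 0.8) {
  if (nrow(references) != nrow(model$B))
    stop("references must be on the model's wavelength grid")
  cand <- colnames(references)
  if (!is.null(zone)) cand <- intersect(cand, zone$analytes)
  if (length(cand) == 0) stop("no candidate analytes for this zone")
  R <- stats::cor(references[, cand, drop = FALSE], model$B)
  rownames(R) <- cand
  out <- data.frame(component = seq_len(model$N),
                    analyte = "interferent",
                    spectral_correlation = NA_real_,
                    stringsAsFactors = FALSE)
  W <- R
  repeat {
    if (all(!is.finite(W)) || max(W, na.rm = TRUE) < min_correlation) break
    best <- max(W, na.rm = TRUE)
    hits <- which(W == best, arr.ind = TRUE)
    if (nrow(hits) > 1 && length(unique(hits[, "row"])) > 1 &&
        length(unique(hits[, "col"])) == 1)
      stop("ambiguous match: analytes ",
           paste(rownames(W)[hits[, "row"]], collapse = ", "),
           " tie for component ", hits[1, "col"],
           " at correlation ", format(best))
    i <- hits[1, "row"]; j <- hits[1, "col"]
    out$analyte[j] <- rownames(W)[i]
    out$spectral_correlation[j] <- best
    W[i, ] <- -Inf; W[, j] <- -Inf
  }
  structure(out,
            zone = if (is.null(zone)) NA_character_ else zone$name,
            correlations = R,
            class = c("component_assignment", "data.frame"))
}

#' Calibrate resolved concentration scores and predict concentrations
#'
#' For each analyte matched in `assignment`, regresses the calibration
#' samples' resolved C-scores on their nominal concentrations (ordinary least
#' squares with intercept) and inverts the line to predict every sample's
#' concentration: `(score - intercept) / slope`. Negative predictions are
#' floored at zero and flagged. Analytes not matched to any component get NA
#' predictions (absent from the zone model).
#'
#' @param model A `trilinear_model` whose sample mode matches `design`.
#' @param design A [calibration_design()].
#' @param assignment A `component_assignment` from [assign_components()].
#' @return Object of class `zone_prediction`: `predicted` (sample x analyte
#'   matrix over the assigned analytes), `floored` (logical matrix),
#'   `calibration` (per-analyte slope/intercept/R2/slope_se data frame).
#' @export
calibrate_and_predict <- function(model, design, assignment) {
  if (length(model$sample_ids) != length(design$sample_ids) ||
      !all(model$sample_ids == design$sample_ids))
    stop("model and design sample sets differ")
  cal <- design$roles == "calibration"
  if (sum(cal) < 2) stop("need >= 2 calibration samples")
  matched <- assignment[assignment$analyte != "interferent", , drop = FALSE]
  if (nrow(matched) == 0) stop("no analytes assigned in this zone")
  pred <- matrix(NA_real_, length(design$sample_ids), nrow(matched),
                 dimnames = list(design$sample_ids, matched$analyte))
  floored <- matrix(FALSE, nrow(pred), ncol(pred), dimnames = dimnames(pred))
  calinfo <- data.frame(analyte = matched$analyte, slope = NA_real_,
                        intercept = NA_real_, r_squared = NA_real_,
                        slope_se = NA_real_, s_blank = NA_real_)
  for (r in seq_len(nrow(matched))) {
    an <- matched$analyte[r]
    scores <- model$C[, matched$component[r]]
    nom <- design$nominal[, an]
    if (stats::var(nom[cal]) == 0)
      stop("zero-variance nominal values for ", an)
    fit <- stats::lm(scores[cal] ~ nom[cal])
    b0 <- stats::coef(fit)[1]; b1 <- stats::coef(fit)[2]
    sfit <- suppressWarnings(summary(fit))  # perfect fits are fine here
    se <- sfit$coefficients[2, 2]
    if (!is.finite(b1) || abs(se / b1) > 0.5)
      stop("calibration slope indistinguishable from 0 for ", an)
    p <- (scores - b0) / b1
    fl <- p < -1e-10 * max(abs(p), 1)   # flag genuine negatives, not roundoff
    p[p < 0] <- 0
    pred[, r] <- p
    floored[, r] <- fl
    ncal <- sum(cal)
    s_yx <- sqrt(sum(stats::residuals(fit)^2) / (ncal - 2))
    cm <- mean(nom[cal])
    s0 <- (s_yx / abs(b1)) *
      sqrt(1 + 1 / ncal + cm^2 / sum((nom[cal] - cm)^2))
    calinfo[r, -1] <- c(b1, b0, sfit$r.squared, se, s0)
  }
  structure(list(predicted = pred, floored = floored, calibration = calinfo),
            class = "zone_prediction")
}

#' Figures of merit of the prediction step
#'
#' Computes, per analyte over the validation samples: recovery
#' (`100 * predicted / nominal` where nominal > 0), AVE (arithmetic mean of
#' the recoveries), RMSEP (`sqrt(sum((c_act - c_pred)^2) / (I - 1))` with I
#' validation samples), DEV (mean absolute relative deviation), R (Pearson
#' correlation of predicted vs nominal; 1 by convention when both are exactly
#' equal), and LOD/LOQ (`3.3 * s0` and `10 * s0`, with `s0` the concentration
#' standard error of a blank prediction propagated through the calibration
#' regression, when calibration info is available).
#'
#' With `exclude_outlier_recoveries = TRUE`, validation samples whose
#' recovery for an analyte falls outside `recovery_limits` are dropped from
#' that analyte's RMSEP (recoveries, AVE and R still use all samples).
#'
#' @param predicted Matrix (validation sample x analyte) of predicted
#'   concentrations, or a full sample x analyte matrix containing the
#'   validation rows.
#' @param design A [calibration_design()] with validation rows.
#' @param calibration Optional per-analyte calibration data frame (from
#'   [calibrate_and_predict()]) used for LOD/LOQ.
#' @param exclude_outlier_recoveries Drop gross-outlier recoveries from
#'   RMSEP (default FALSE).
#' @param recovery_limits Acceptance window (percent) used by the exclusion
#'   rule (default c(75, 130)).
#' @return Object of class `quant_report`: `recovery` (matrix, %), `AVE`,
#'   `RMSEP`, `DEV`, `R`, `LOD`, `LOQ` (named per-analyte vectors),
#'   `predicted`, `nominal`, `rmsep_excluded` (list of dropped sample ids).
#' @export
figures_of_merit <- function(predicted, design, calibration = NULL,
                             exclude_outlier_recoveries = FALSE,
                             recovery_limits = c(75, 130)) {
  val <- design$roles == "validation"
  if (!any(val)) stop("design has no validation rows")
  vids <- design$sample_ids[val]
  predicted <- as.matrix(predicted)
  if (is.null(rownames(predicted)))
    stop("predicted matrix must have sample ids as row names")
  if (!all(vids %in% rownames(predicted)))
    stop("predicted matrix is missing validation rows")
  analytes <- colnames(predicted)
  P <- predicted[vids, , drop = FALSE]
  Nom <- design$nominal[vids, analytes, drop = FALSE]

  recovery <- 100 * P / Nom
  recovery[Nom == 0] <- NA_real_

  I <- length(vids)
  AVE <- colMeans(recovery, na.rm = TRUE)
  DEV <- colMeans(abs(P - Nom) / ifelse(Nom > 0, Nom, NA_real_), na.rm = TRUE)

  RMSEP <- rep(NA_real_, length(analytes))
  names(RMSEP) <- analytes
  excluded <- stats::setNames(vector("list", length(analytes)), analytes)
  for (a in analytes) {
    keep <- rep(TRUE, I)
    if (exclude_outlier_recoveries) {
      rec <- recovery[, a]
      keep <- is.na(rec) | (rec >= recovery_limits[1] & rec <= recovery_limits[2])
      excluded[[a]] <- vids[!keep]
    }
    n_eff <- sum(keep)
    if (n_eff >= 2)
      RMSEP[a] <- sqrt(sum((Nom[keep, a] - P[keep, a])^2) / (n_eff - 1))
  }

  R <- vapply(analytes, function(a) {
    x <- Nom[, a]; y <- P[, a]
    if (isTRUE(all.equal(x, y))) return(1)
    if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))

  LOD <- LOQ <- stats::setNames(rep(NA_real_, length(analytes)), analytes)
  if (!is.null(calibration)) {
    ix <- match(analytes, calibration$analyte)
    LOD[] <- 3.3 * calibration$s_blank[ix]
    LOQ[] <- 10 * calibration$s_blank[ix]
  }

  structure(list(recovery = recovery, AVE = AVE, RMSEP = RMSEP, DEV = DEV,
                 R = R, LOD = LOD, LOQ = LOQ,
                 predicted = P, nominal = Nom, rmsep_excluded = excluded),
            class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat("<quant_report>\n")
  m <- rbind(AVE = x$AVE, RMSEP = x$RMSEP, DEV = x$DEV, R = x$R,
             LOD = x$LOD, LOQ = x$LOQ)
  print(round(m, 4))
  invisible(x)
}

#' Per-origin mean and SD summary of an analyte table
#'
#' Arithmetic mean and sample standard deviation (n - 1 divisor) of each
#' analyte within each origin. Origins with a single sample get NA SD;
#' origins with no samples are omitted.
#'
#' @param dataset An `origin_dataset` (see [simulate_origin_dataset()]).
#' @return Data frame with columns `origin`, `n`, and `<analyte>_mean` /
#'   `<analyte>_sd` pairs.
#' @export
summarize_by_origin <- function(dataset) {
  stopifnot(inherits(dataset, "origin_dataset"))
  out <- list()
  for (g in levels(dataset$labels)) {
    rows <- dataset$labels == g
    n <- sum(rows)
    if (n == 0) next
    M <- dataset$features[rows, , drop = FALSE]
    mu <- colMeans(M)
    sdv <- if (n > 1) apply(M, 2, stats::sd) else
      stats::setNames(rep(NA_real_, ncol(M)), colnames(M))
    row <- data.frame(origin = g, n = n, as.list(mu), as.list(sdv),
                      check.names = FALSE)
    names(row) <- c("origin", "n", paste0(colnames(M), "_mean"),
                    paste0(colnames(M), "_sd"))
    out[[g]] <- row
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
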