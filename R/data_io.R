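#' Construct a three-way HPLC-DAD data cube
#'
#' A `data_cube` holds the signal array (sample x elution time x wavelength)
#' together with its physical axis coordinates. This is the object the
#' trilinear decomposition operates on.
#'
#' @param values Numeric 3-way array, sample x time x wavelength; no missing
#'   or non-finite values.
#' @param sample_ids Character vector, one id per sample.
#' @param time_axis Strictly increasing numeric vector of elution times (min).
#' @param wavelength_axis Strictly increasing numeric vector of wavelengths (nm).
#' @return Object of class `data_cube`.
#' @export
data_cube <- function(values, sample_ids, time_axis, wavelength_axis) {
  if (length(dim(values)) != 3L)
    stop("values must be a 3-way array (sample x time x wavelength)")
  d <- dim(values)
  if (length(sample_ids) != d[1] || length(time_axis) != d[2] ||
      length(wavelength_axis) != d[3])
    stop("axis lengths must match array dimensions")
  if (anyNA(values) || !all(is.finite(values)))
    stop("cube contains missing or non-finite values")
  if (any(diff(time_axis) <= 0)) stop("time_axis must be strictly increasing")
  if (any(diff(wavelength_axis) <= 0))
    stop("wavelength_axis must be strictly increasing")
  dimnames(values) <- NULL
  structure(list(values = values,
                 sample_ids = as.character(sample_ids),
                 time_axis = as.numeric(time_axis),
                 wavelength_axis = as.numeric(wavelength_axis)),
            class = "data_cube")
}

#' @export
dim.data_cube <- function(x) dim(x$values)

#' @export
print.data_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<data_cube> %d samples x %d time points x %d wavelengths\n",
              d[1], d[2], d[3]))
  cat(sprintf("  time %.4f-%.4f min, wavelength %.1f-%.1f nm\n",
              min(x$time_axis), max(x$time_axis),
              min(x$wavelength_axis), max(x$wavelength_axis)))
  invisible(x)
}

#' Elution zone specification
#'
#' @param name Zone label.
#' @param t_start,t_end Window bounds in minutes, `t_start < t_end`. Both ends
#'   are inclusive when slicing.
#' @param analytes Character vector of analytes expected to elute in the zone.
#' @param n_components Component count for the trilinear model, or `"auto"` to
#'   select by core consistency.
#' @return Object of class `zone_spec`.
#' @export
zone_spec <- function(name, t_start, t_end, analytes = character(),
                      n_components = "auto") {
  if (!(t_start < t_end)) stop("t_start must be < t_end")
  structure(list(name = name, t_start = t_start, t_end = t_end,
                 analytes = analytes, n_components = n_components),
            class = "zone_spec")
}

#' The four analyzed elution zones
#'
#' The four overlapped elution windows resolved by ATLD, with the analytes
#' expected in each: zone 1 (2.9227-3.0613 min) GC; zone 2 (3.0720-3.7013 min)
#' EGC and EGCG; zone 3 (3.7120-4.0213 min) GCG and EC; zone 4
#' (4.0320-4.6827 min) ECG, CAF and CG. Windows abut at 4-decimal precision,
#' so no time point can belong to two zones.
#'
#' @return Named list of four [zone_spec()] objects.
#' @export
default_zones <- function() {
  list(
    zone1 = zone_spec("zone1", 2.9227, 3.0613, "GC"),
    zone2 = zone_spec("zone2", 3.0720, 3.7013, c("EGC", "EGCG")),
    zone3 = zone_spec("zone3", 3.7120, 4.0213, c("GCG", "EC")),
    zone4 = zone_spec("zone4", 4.0320, 4.6827, c("ECG", "CAF", "CG"))
  )
}

#' Slice a cube to one elution zone
#'
#' Keeps the time points t with `t_start <= t <= t_end` (inclusive both ends);
#' samples and the wavelength axis are unchanged.
#'
#' @param cube A [data_cube()].
#' @param zone A [zone_spec()].
#' @return A [data_cube()] restricted to the zone window.
#' @export
slice_zone <- function(cube, zone) {
  keep <- cube$time_axis >= zone$t_start & cube$time_axis <= zone$t_end
  if (!any(keep))
    stop(sprintf("zone [%g, %g] does not intersect the cube's time axis",
                 zone$t_start, zone$t_end))
  data_cube(cube$values[, keep, , drop = FALSE], cube$sample_ids,
            cube$time_axis[keep], cube$wavelength_axis)
}

#' Construct a calibration design
#'
#' Nominal concentrations of the analyte panel across calibration, validation
#' and unknown samples.
#'
#' @param sample_ids Character vector.
#' @param roles Per-sample role, each one of `"calibration"`, `"validation"`,
#'   `"unknown"`.
#' @param nominal Numeric matrix (sample x analyte) of nominal concentrations
#'   (ug/mL); calibration and validation rows must be fully specified and >= 0
#'   (unknown rows may be NA).
#' @param analyte_names Column names; defaults to `colnames(nominal)`.
#' @return Object of class `calibration_design`.
#' @export
calibration_design <- function(sample_ids, roles, nominal,
                               analyte_names = colnames(nominal)) {
  roles <- match.arg(roles, c("calibration", "validation", "unknown"),
                     several.ok = TRUE)
  nominal <- as.matrix(nominal)
  if (length(sample_ids) != nrow(nominal) || length(roles) != nrow(nominal))
    stop("sample_ids, roles and nominal rows must agree")
  known <- roles != "unknown"
  if (anyNA(nominal[known, , drop = FALSE]) ||
      any(nominal[known, ] < 0, na.rm = TRUE))
    stop("calibration/validation rows must be fully specified and >= 0")
  colnames(nominal) <- analyte_names
  rownames(nominal) <- sample_ids
  structure(list(sample_ids = as.character(sample_ids), roles = roles,
                 nominal = nominal, analyte_names = analyte_names),
            class = "calibration_design")
}

#' The ten-sample standards design
#'
#' The mixed-standards design used for second-order calibration: seven
#' calibration samples (J01-J07) and three validation samples (Y01-Y03) with
#' nominal concentrations (ug/mL) of the eight analytes in the canonical
#' column order GC, EGC, GCG, CG, EC, EGCG, ECG, CAF.
#'
#' @return A [calibration_design()] with 10 rows and 8 analytes.
#' @export
table1_fixture <- function() {
  m <- matrix(c(
    # GC     EGC    GCG    CG     EC     EGCG   ECG    CAF
    20.00,  0.00,  0.00,  0.00, 40.00, 93.10,  0.00, 31.60,  # J01
     0.00, 20.00, 20.00, 40.00,  0.00,  0.00, 60.00,  0.00,  # J02
    18.00, 10.00, 18.00, 20.00, 38.00, 83.89, 40.00, 28.44,  # J03
    14.00, 12.00, 14.00, 26.00, 34.00, 27.91, 56.00, 25.28,  # J04
    12.00, 14.00, 12.00, 30.00, 30.00, 65.17, 52.00, 22.12,  # J05
    10.00, 16.00, 10.00, 34.00, 26.00, 46.55, 48.00, 18.96,  # J06
     6.00, 18.00,  6.00, 38.00, 20.00, 55.86, 40.00, 15.80,  # J07
    16.00,  8.00,  8.00, 20.00, 30.00, 74.48, 50.00, 22.12,  # Y01
    12.00, 12.00, 12.00, 40.00, 20.00, 37.24, 60.00, 15.80,  # Y02
     8.00, 16.00, 16.00, 28.00, 40.00, 55.86, 40.00, 31.60   # Y03
  ), nrow = 10, byrow = TRUE)
  ids <- c(sprintf("J%02d", 1:7), sprintf("Y%02d", 1:3))
  calibration_design(ids,
                     c(rep("calibration", 7), rep("validation", 3)),
                     m, ANALYTE_ORDER)
}

#' Predicted validation concentrations of the reference study
#'
#' The predicted concentrations (ug/mL) reported for the three validation
#' samples after trilinear resolution, in the same layout as
#' [table1_fixture()]. Shipped so the figures-of-merit computations can be
#' exercised on the published numbers without the (unavailable) raw data.
#'
#' @return Matrix (3 validation samples x 8 analytes).
#' @export
reported_validation_predictions <- function() {
  m <- matrix(c(
    # GC     EGC    GCG    CG     EC     EGCG   ECG    CAF
    14.50,  7.73,  7.75, 34.15, 31.10, 73.90, 30.48, 22.81,  # Y01
    12.24, 11.72, 11.27, 35.61, 23.75, 42.98, 57.22, 15.45,  # Y02
     8.17, 15.93, 15.73, 27.97, 40.50, 62.55, 39.15, 31.70   # Y03
  ), nrow = 3, byrow = TRUE,
  dimnames = list(sprintf("Y%02d", 1:3), ANALYTE_ORDER))
  m
}

#' Reported per-sample validation recoveries of the reference study
#'
#' The recovery percentages (100 * predicted / nominal) reported for the
#' three validation samples, companion to
#' [reported_validation_predictions()].
#'
#' @return Matrix (3 validation samples x 8 analytes), percent.
#' @export
reported_validation_recoveries <- function() {
  m <- matrix(c(
    # GC      EGC     GCG     CG      EC      EGCG    ECG     CAF
     90.61,  96.58,  96.86, 170.73, 103.67,  99.22,  60.95, 103.14,  # Y01
    102.01,  97.68,  93.94,  89.03, 118.77, 115.43,  95.36,  97.78,  # Y02
    102.14,  99.56,  98.30,  99.88, 101.25, 111.97,  97.87, 100.31   # Y03
  ), nrow = 3, byrow = TRUE,
  dimnames = list(sprintf("Y%02d", 1:3), ANALYTE_ORDER))
  m
}

#' Write a data cube as delimited text, one matrix per sample
#'
#' Each file holds two header lines (`# time_axis:` and `# wavelength_axis:`
#' followed by the comma-separated coordinates) and then the time x wavelength
#' signal matrix, comma-separated.
#'
#' @param cube A [data_cube()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths (named by sample id).
#' @export
write_cube <- function(cube, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(cube$sample_ids, ".csv"))
  for (i in seq_along(paths)) {
    con <- file(paths[i], "w")
    writeLines(c(
      paste0("# time_axis: ",
             paste(format(cube$time_axis, digits = 17), collapse = ",")),
      paste0("# wavelength_axis: ",
             paste(format(cube$wavelength_axis, digits = 17), collapse = ","))),
      con)
    utils::write.table(format(cube$values[i, , ], digits = 17), con,
                       sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    close(con)
  }
  names(paths) <- cube$sample_ids
  invisible(paths)
}

read_cube_matrix <- function(path) {
  head2 <- readLines(path, n = 2L)
  if (length(head2) < 2L || !startsWith(head2[1], "# time_axis:") ||
      !startsWith(head2[2], "# wavelength_axis:"))
    stop("malformed header in ", path)
  parse_axis <- function(line)
    as.numeric(strsplit(sub("^# [a-z_]+: *", "", line), ",")[[1]])
  tax <- parse_axis(head2[1]); wax <- parse_axis(head2[2])
  if (anyNA(tax) || anyNA(wax)) stop("malformed axis header in ", path)
  m <- as.matrix(utils::read.table(path, sep = ",", skip = 2L,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  if (nrow(m) != length(tax) || ncol(m) != length(wax))
    stop("matrix shape does not match axis headers in ", path)
  list(values = m, time_axis = tax, wavelength_axis = wax)
}

#' Read a data cube from per-sample delimited-text matrices
#'
#' All files must share identical time and wavelength axes; a mismatch is an
#' error, never a silent resample.
#'
#' @param paths Character vector of file paths (as written by [write_cube()]).
#' @param sample_ids Sample ids; defaults to the file base names.
#' @return A [data_cube()].
#' @export
read_cube <- function(paths, sample_ids = NULL) {
  if (!all(file.exists(paths))) stop("missing input file(s)")
  if (is.null(sample_ids))
    sample_ids <- sub("\\.[^.]*$", "", basename(paths))
  mats <- lapply(paths, read_cube_matrix)
  ref <- mats[[1]]
  for (m in mats[-1]) {
    if (!isTRUE(all.equal(m$time_axis, ref$time_axis, tolerance = 1e-12)) ||
        !isTRUE(all.equal(m$wavelength_axis, ref$wavelength_axis,
                          tolerance = 1e-12)))
      stop("per-sample matrices do not share common axes")
  }
  arr <- array(0, c(length(mats), nrow(ref$values), ncol(ref$values)))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]$values
  data_cube(arr, sample_ids, ref$time_axis, ref$wavelength_axis)
}

#' Write a design or feature table as CSV
#'
#' @param design A [calibration_design()] or an origin dataset
#'   (see [simulate_origin_dataset()]).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_design <- function(design, path) {
  if (inherits(design, "calibration_design")) {
    df <- data.frame(sample_id = design$sample_ids, role = design$roles,
                     design$nominal, check.names = FALSE)
  } else if (inherits(design, "origin_dataset")) {
    df <- data.frame(sample_id = design$sample_ids, origin = design$labels,
                     design$features, check.names = FALSE)
  } else stop("unsupported object")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
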