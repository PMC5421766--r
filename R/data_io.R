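#' Generate self-calibration targets from a known parameter set
#'
#' Simulates a cohort at `true_params` and packages its aggregated outputs
#' as calibration target tables. With the same cohort seed the generating
#' parameter set scores a goodness of fit of exactly zero against these
#' targets, which makes download-free calibration tests possible.
#'
#' @param true_params the generating [param_set()].
#' @param inputs an [input_params()].
#' @param n cohort size used to build the targets.
#' @param seed cohort seed.
#' @param life_table a `life_table`.
#' @param weights passed to [calib_targets()].
#' @return a [calib_targets()] object.
#' @export
generate_synthetic_targets <- function(true_params, inputs = input_params(),
                                       n = 5e4, seed = 1,
                                       life_table = synthetic_life_table(),
                                       weights = c(incidence = 1, size = 1,
                                                   benign_fraction = 0.5,
                                                   benign_size = 0.1)) {
  out <- simulate_cohort(n, inputs, true_params, life_table, seed = seed)
  calib_targets(incidence = out$incidence_by_age,
                size = out$size_dist_by_age,
                benign_fraction = out$benign_detected_fraction,
                benign_size = out$benign_size_dist_by_age,
                weights = weights)
}

#' Read and write calibration target tables
#'
#' Targets are stored as plain CSV: `incidence.csv` with columns
#' `age_bin,value`; `size.csv` and `benign_size.csv` with columns
#' `age_bin,size_bin,value`; and `meta.json` carrying the benign detected
#' fraction, the table weights and a schema version.
#'
#' @param targets a [calib_targets()].
#' @param dir directory to write to / read from.
#' @return `write_calib_targets()` the directory, invisibly;
#'   `read_calib_targets()` a `calib_targets`.
#' @export
write_calib_targets <- function(targets, dir) {
  stopifnot(inherits(targets, "calib_targets"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(targets$incidence, file.path(dir, "incidence.csv"),
            row.names = FALSE)
  long <- function(m) data.frame(
    age_bin = rep(rownames(m), ncol(m)),
    size_bin = rep(colnames(m), each = nrow(m)),
    value = as.vector(m))
  write.csv(long(targets$size), file.path(dir, "size.csv"), row.names = FALSE)
  write.csv(long(targets$benign_size), file.path(dir, "benign_size.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(schema = "thyronod_targets_v1",
                            benign_fraction = targets$benign_fraction,
                            weights = as.list(targets$weights)),
                       file.path(dir, "meta.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_calib_targets
#' @export
read_calib_targets <- function(dir) {
  paths <- file.path(dir, c("incidence.csv", "size.csv", "benign_size.csv",
                            "meta.json"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing target file(s): ", paste(missing, collapse = ", "))
  inc <- read.csv(paths[1])
  if (!all(c("age_bin", "value") %in% names(inc)))
    stop("incidence.csv needs columns age_bin,value")
  wide <- function(path) {
    df <- read.csv(path)
    if (!all(c("age_bin", "size_bin", "value") %in% names(df)))
      stop(basename(path), " needs columns age_bin,size_bin,value")
    m <- matrix(0, N_AGE_BINS, 7,
                dimnames = list(age_bin_labels(), size_bin_labels()))
    bad <- which(!(df$age_bin %in% rownames(m)) |
                   !(df$size_bin %in% colnames(m)))
    if (length(bad))
      stop(basename(path), ": unknown bin at row(s) ",
           paste(bad, collapse = ", "))
    m[cbind(match(df$age_bin, rownames(m)),
            match(df$size_bin, colnames(m)))] <- df$value
    m
  }
  meta <- jsonlite::read_json(paths[4], simplifyVector = TRUE)
  inc <- inc[match(age_bin_labels(), inc$age_bin), ]
  if (anyNA(inc$value)) stop("incidence.csv does not cover all 14 age bins")
  rownames(inc) <- NULL
  calib_targets(incidence = inc, size = wide(paths[2]),
                benign_fraction = meta$benign_fraction,
                benign_size = wide(paths[3]),
                weights = unlist(meta$weights))
}

# ---- longitudinal tumor-diameter records -----------------------------------

#' Read longitudinal tumor-diameter records
#'
#' Expects a CSV with columns `patient_id,age,time_years,diameter_mm`: one
#' row per ultrasound observation, `time_years` measured from each
#' patient's entry. (Source data distributed as a spreadsheet should be
#' exported to this CSV schema; see the package vignette.)
#'
#' @param path CSV file path.
#' @return a list of `longitudinal_record` objects, one per patient, each
#'   with `patient_id`, `age_at_entry`, `times`, `diameters`.
#' @export
read_longitudinal <- function(path) {
  if (!file.exists(path)) stop("longitudinal file not found: ", path)
  df <- read.csv(path)
  need <- c("patient_id", "age", "time_years", "diameter_mm")
  if (!all(need %in% names(df)))
    stop("longitudinal CSV needs columns ", paste(need, collapse = ","))
  bad <- which(!is.finite(df$diameter_mm) | df$diameter_mm <= 0)
  if (length(bad))
    stop("nonpositive diameter at row(s) ", paste(bad, collapse = ", "))
  recs <- lapply(split(seq_len(nrow(df)), df$patient_id), function(idx) {
    idx <- idx[order(df$time_years[idx])]
    tt <- df$time_years[idx]
    if (any(diff(tt) <= 0))
      stop("non-increasing observation times for patient ",
           df$patient_id[idx[1]], " at row(s) ",
           paste(idx[which(diff(tt) <= 0) + 1], collapse = ", "))
    structure(list(patient_id = df$patient_id[idx[1]],
                   age_at_entry = df$age[idx[1]],
                   times = tt, diameters = df$diameter_mm[idx]),
              class = "longitudinal_record")
  })
  unname(recs)
}

check_record <- function(record, min_obs = 2) {
  if (!inherits(record, "longitudinal_record"))
    stop("expected a longitudinal_record")
  if (length(record$times) < min_obs)
    stop("record needs at least ", min_obs, " observations")
}

#' Classify a nodule's observed behavior
#'
#' A record is classified `grow` if the last-minus-first diameter change is
#' at least `+threshold_mm`, `shrink` if at most `-threshold_mm`, and
#' `stable` otherwise. The threshold (default 3 mm) is a reporting choice,
#' not an estimate.
#'
#' @param record a `longitudinal_record` with at least 2 observations.
#' @param threshold_mm classification threshold in mm.
#' @return one of `"grow"`, `"shrink"`, `"stable"`.
#' @export
classify_behavior <- function(record, threshold_mm = 3) {
  check_record(record)
  delta <- record$diameters[length(record$diameters)] - record$diameters[1]
  if (delta >= threshold_mm) "grow"
  else if (delta <= -threshold_mm) "shrink"
  else "stable"
}

#' Fit per-nodule kinetic rates from longitudinal records
#'
#' `fit_shrink_rate()` converts diameters to volumes and returns the
#' least-squares slope of `-log(volume)` against time (the exponential
#' decay rate, per year). `fit_stable_slope()` returns the ordinary
#' least-squares slope of volume against time (mm^3 per year).
#'
#' @param record a `longitudinal_record` with at least 2 observations.
#' @return a rate (per year) or slope (mm^3 per year).
#' @export
fit_shrink_rate <- function(record) {
  check_record(record)
  V <- diameter_to_volume(record$diameters)
  unname(-coef(lm(log(V) ~ record$times))[2])
}

#' @rdname fit_shrink_rate
#' @export
fit_stable_slope <- function(record) {
  check_record(record)
  V <- diameter_to_volume(record$diameters)
  unname(coef(lm(V ~ record$times))[2])
}

#' Summarize a longitudinal kinetics cohort
#'
#' Computes the Table-of-inputs style summary of an observational cohort:
#' patient count, median follow-up, the grow/shrink/stable proportions at
#' the given threshold, and the fitted shrink-rate and stable-slope means
#' and standard deviations within their classes.
#'
#' @param records list of `longitudinal_record`s.
#' @param threshold_mm classification threshold, mm.
#' @return a `kinetics_summary` list.
#' @export
summarize_kinetics <- function(records, threshold_mm = 3) {
  if (!length(records)) stop("no records supplied")
  cls <- vapply(records, classify_behavior, character(1),
                threshold_mm = threshold_mm)
  fup <- vapply(records, function(r) max(r$times), numeric(1))
  shrink_rates <- vapply(records[cls == "shrink"], fit_shrink_rate, numeric(1))
  stable_slopes <- vapply(records[cls == "stable"], fit_stable_slope,
                          numeric(1))
  structure(list(
    n_patients = length(records),
    median_followup = median(fup),
    proportions = c(grow = mean(cls == "grow"),
                    shrink = mean(cls == "shrink"),
                    stable = mean(cls == "stable")),
    shrink_rate = c(mean = if (length(shrink_rates)) mean(shrink_rates)
                           else NA_real_,
                    sd = if (length(shrink_rates) > 1) sd(shrink_rates)
                         else NA_real_),
    stable_slope = c(mean = if (length(stable_slopes)) mean(stable_slopes)
                            else NA_real_,
                     sd = if (length(stable_slopes) > 1) sd(stable_slopes)
                          else NA_real_),
    threshold_mm = threshold_mm
  ), class = "kinetics_summary")
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat("<kinetics_summary>", x$n_patients, "patients, median follow-up",
      format(x$median_followup), "years\n  grow/shrink/stable:",
      paste(sprintf("%.3f", x$proportions), collapse = "/"), "\n")
  invisible(x)
}
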