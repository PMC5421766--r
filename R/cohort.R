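#' Simulate a cohort of women from birth
#'
#' Runs the compiled annual-cycle engine for `n` individually simulated
#' women and aggregates their histories into the model's target metrics:
#' age-binned detected-malignant incidence proportions, 1-cm size
#' distributions at detection, the benign-only share of detections, and the
#' subclinical (alive, undetected) nodule prevalence by single year of age.
#'
#' The engine uses counter-based random streams keyed by
#' `(seed, person, purpose, cycle)`: results are deterministic given
#' `(n, seed)`, independent of evaluation order, and share random numbers
#' across parameter sets (common random numbers for calibration).
#'
#' @param n cohort size, at least 1.
#' @param inputs an [input_params()].
#' @param params a [param_set()].
#' @param life_table a `life_table` (see [read_life_table()]).
#' @param seed integer seed.
#' @param screen_age optional age at which to take a cross-sectional
#'   screening snapshot of alive, clinically undetected persons.
#' @param detection if `FALSE`, clinical detection is switched off (the
#'   pure natural-history reservoir).
#' @return a `cohort_outputs` object; see Details.
#' @details Fields: `incidence_by_age` (malignant detections per person
#'   alive and undetected entering each 5-year bin), `size_dist_by_age` and
#'   `benign_size_dist_by_age` (14 x 7 row-proportion matrices),
#'   `benign_detected_fraction`, `subclinical_prevalence_by_age` (per age
#'   0..100: persons at risk, any-nodule, any >= 3 mm, malignant >= 3 mm
#'   proportions), `persons` (per-person death/detection summary), and the
#'   screening snapshot when requested.
#' @export
simulate_cohort <- function(n, inputs = input_params(), params,
                            life_table = synthetic_life_table(), seed = 1,
                            screen_age = NA, detection = TRUE) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("n must be >= 1")
  stopifnot(inherits(params, "param_set"), inherits(inputs, "input_params"))
  if (!inherits(life_table, "life_table")) life_table <- as_life_table(life_table)
  raw <- .sim_cohort_cpp(as.integer(n), unclass(inputs), unclass(params),
                         life_table$qx, as.numeric(seed),
                         if (is.na(screen_age)) -1L else as.integer(screen_age),
                         isTRUE(detection))

  labs <- age_bin_labels()
  det_malig <- raw$detection_class == 1L
  det_benign <- raw$detection_class == 2L
  det_bin <- ifelse(raw$detection_age >= 0, age_bin(pmax(raw$detection_age, 0)),
                    NA_integer_)
  entering <- raw$alive_undetected[AGE_BIN_BREAKS[-length(AGE_BIN_BREAKS)] + 1L]

  n_malig_bin <- tabulate(det_bin[det_malig], nbins = N_AGE_BINS)
  incidence <- data.frame(age_bin = labs,
                          value = ifelse(entering > 0, n_malig_bin / entering, 0))

  size_matrix <- function(sizes, bins) {
    m <- matrix(0, N_AGE_BINS, 7, dimnames = list(labs, size_bin_labels()))
    ok <- !is.na(sizes) & !is.na(bins)
    if (any(ok)) {
      tab <- table(factor(bins[ok], levels = 1:N_AGE_BINS),
                   factor(size_bin(sizes[ok]), levels = 1:7))
      m[] <- as.numeric(tab)
      rs <- rowSums(m)
      m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
    }
    m
  }
  # malignant size at detection: the largest malignant nodule (the primary
  # tumor); benign-only detections use the largest nodule overall
  size_dist <- size_matrix(raw$detection_size_malig[det_malig],
                           det_bin[det_malig])
  ben_size_dist <- size_matrix(raw$detection_size[det_benign],
                               det_bin[det_benign])

  n_det <- sum(det_malig) + sum(det_benign)
  prev <- data.frame(
    age = 0:100,
    at_risk = raw$alive_undetected,
    p_any_nodule = ifelse(raw$alive_undetected > 0,
                          raw$any_nodule / raw$alive_undetected, 0),
    p_visible = ifelse(raw$alive_undetected > 0,
                       raw$any_visible / raw$alive_undetected, 0),
    p_malig_visible = ifelse(raw$alive_undetected > 0,
                             raw$malig_visible / raw$alive_undetected, 0))

  persons <- data.frame(
    death_age = ifelse(raw$death_age >= 0, raw$death_age, NA_integer_),
    detection_age = ifelse(raw$detection_age >= 0, raw$detection_age,
                           NA_integer_),
    detection_class = c(NA, "malignant_found", "benign_only")[
      raw$detection_class + 1L],
    detection_size = raw$detection_size,
    detection_size_malig = raw$detection_size_malig)

  screen <- NULL
  if (!is.na(screen_age)) {
    screen <- list(age = screen_age, n_persons = raw$screen_persons,
                   nodules = data.frame(person = raw$screen_person,
                                        diameter = raw$screen_diameter,
                                        malignant = raw$screen_malignant == 1L))
  }

  structure(list(
    incidence_by_age = incidence,
    size_dist_by_age = size_dist,
    benign_size_dist_by_age = ben_size_dist,
    benign_detected_fraction = if (n_det > 0) sum(det_benign) / n_det else 0,
    n_detected = n_det,
    subclinical_prevalence_by_age = prev,
    persons = persons,
    screen = screen,
    n_simulated = as.integer(n), seed = seed,
    detection = isTRUE(detection)
  ), class = "cohort_outputs")
}

#' @export
print.cohort_outputs <- function(x, ...) {
  cat("<cohort_outputs> n =", x$n_simulated, " seed =", x$seed, "\n")
  cat("  detections:", x$n_detected,
      sprintf("(benign-only fraction %.3f)", x$benign_detected_fraction), "\n")
  cat("  cumulative malignant incidence 15-85:",
      sprintf("%.4f", sum(x$incidence_by_age$value)), "\n")
  invisible(x)
}

#' Cross-sectional screening of the subclinical reservoir
#'
#' Emulates an ultrasound screen of all women of a given age: among persons
#' alive and clinically undetected at `screen_age`, the fraction with at
#' least one nodule of diameter `>= detect_floor` (sonographically
#' visible), the fraction with at least one such malignant nodule, the
#' nodule-size histogram, and the share of visible nodules under 10 mm.
#'
#' @param screen_age age screened, 0..100.
#' @param detect_floor minimum detectable diameter, mm (default 3; use 0 to
#'   count every nodule).
#' @param cohort either a `cohort_outputs` simulated with
#'   `screen_age = screen_age`, or a list of `person` objects (e.g. from
#'   [simulate_person()]) snapshotted at that age.
#' @return a `screening_result` with `prevalence_any_nodule`,
#'   `prevalence_malignant`, `nodule_size_histogram` (1-cm bins) and
#'   `fraction_below_10mm`.
#' @export
screening_cross_section <- function(screen_age, detect_floor = 3, cohort) {
  if (screen_age < 0 || screen_age > 100) stop("screen_age must be in 0..100")
  if (inherits(cohort, "cohort_outputs")) {
    if (is.null(cohort$screen) || cohort$screen$age != screen_age)
      stop("cohort was not simulated with screen_age = ", screen_age)
    n_pers <- cohort$screen$n_persons
    nod <- cohort$screen$nodules
  } else {
    # hand-built or R-engine cohort: a list of persons
    keep <- vapply(cohort, function(p) p$alive && !p$detected, logical(1))
    n_pers <- sum(keep)
    nod <- do.call(rbind, c(list(data.frame(person = integer(),
                                            diameter = numeric(),
                                            malignant = logical())),
      lapply(which(keep), function(i) {
        ns <- cohort[[i]]$nodules
        if (!length(ns)) return(NULL)
        data.frame(person = i,
                   diameter = vapply(ns, function(x)
                     volume_to_diameter(x$current_volume), numeric(1)),
                   malignant = vapply(ns, `[[`, logical(1), "malignant"))
      })))
  }
  vis <- nod[nod$diameter >= detect_floor, , drop = FALSE]
  hist_counts <- tabulate(size_bin(vis$diameter), nbins = 7)
  names(hist_counts) <- size_bin_labels()
  structure(list(
    screen_age = screen_age, detect_floor = detect_floor,
    n_screened = n_pers,
    prevalence_any_nodule = if (n_pers > 0)
      length(unique(vis$person)) / n_pers else 0,
    prevalence_malignant = if (n_pers > 0)
      length(unique(vis$person[vis$malignant])) / n_pers else 0,
    nodule_size_histogram = hist_counts,
    fraction_below_10mm = if (nrow(vis) > 0) mean(vis$diameter < 10) else NA_real_
  ), class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> age %d, floor %.1f mm, %d screened\n",
              x$screen_age, x$detect_floor, x$n_screened))
  cat(sprintf("  any-nodule prevalence:  %.2f%%\n",
              100 * x$prevalence_any_nodule))
  cat(sprintf("  malignant prevalence:   %.2f%%\n",
              100 * x$prevalence_malignant))
  cat(sprintf("  nodules < 10 mm:        %.1f%%\n",
              100 * x$fraction_below_10mm))
  invisible(x)
}

#' Cumulative probability of clinically detected thyroid cancer
#'
#' The fraction of persons alive at `start_age` who are clinically detected
#' with `detection_class = "malignant_found"` by `end_age`.
#'
#' @param start_age,end_age window in years, `start_age < end_age`.
#' @param cohort a `cohort_outputs` (detection enabled) or list of `person`s.
#' @return a proportion.
#' @export
lifetime_cancer_risk <- function(start_age = 15, end_age = 85, cohort) {
  if (start_age >= end_age) stop("start_age must be below end_age")
  if (inherits(cohort, "cohort_outputs")) {
    pp <- cohort$persons
    alive_at_start <- is.na(pp$death_age) | pp$death_age >= start_age
    hit <- !is.na(pp$detection_age) &
      pp$detection_age >= start_age & pp$detection_age <= end_age &
      pp$detection_class == "malignant_found" & !is.na(pp$detection_class)
  } else {
    alive_at_start <- vapply(cohort, function(p)
      is.na(p$death_age) || p$death_age >= start_age, logical(1))
    hit <- vapply(cohort, function(p)
      p$detected && !is.na(p$detection_age) &&
        p$detection_age >= start_age && p$detection_age <= end_age &&
        identical(p$detection_class, "malignant_found"), logical(1))
  }
  if (!any(alive_at_start)) return(0)
  sum(hit & alive_at_start) / sum(alive_at_start)
}

#' Align model prevalence with an external cross-sectional table
#'
#' Pairs the model's age-binned screening prevalence with an external table
#' (e.g. a published ultrasound survey) for plotting or reporting. No
#' statistics are computed.
#'
#' @param cohort a `cohort_outputs`.
#' @param external_table data frame with columns `age_bin` (labels matching
#'   [age_bin_labels()]) and `prevalence`.
#' @return data frame with `age_bin`, `model`, `external`, `difference`.
#' @export
prevalence_comparison_table <- function(cohort, external_table) {
  stopifnot(inherits(cohort, "cohort_outputs"))
  if (!all(c("age_bin", "prevalence") %in% names(external_table)))
    stop("external table needs columns 'age_bin' and 'prevalence'")
  if (nrow(external_table) == 0)
    return(data.frame(age_bin = character(), model = numeric(),
                      external = numeric(), difference = numeric()))
  missing <- setdiff(external_table$age_bin, age_bin_labels())
  if (length(missing))
    stop("unmatched age bin(s): ", paste(missing, collapse = ", "))
  prev <- cohort$subclinical_prevalence_by_age
  model <- vapply(external_table$age_bin, function(lab) {
    i <- match(lab, age_bin_labels())
    ages <- AGE_BIN_BREAKS[i]:(AGE_BIN_BREAKS[i + 1] - 1)
    w <- prev$at_risk[prev$age %in% ages]
    v <- prev$p_visible[prev$age %in% ages]
    if (sum(w) > 0) sum(v * w) / sum(w) else 0
  }, numeric(1))
  data.frame(age_bin = external_table$age_bin, model = unname(model),
             external = external_table$prevalence,
             difference = unname(model) - external_table$prevalence)
}
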