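# Age-stratified calibrated parameters live on 5-year bins spanning 15-85.
AGE_BIN_BREAKS <- seq(15, 85, by = 5)
N_AGE_BINS <- length(AGE_BIN_BREAKS) - 1L  # 14

#' Age bin index for the calibrated parameter strata
#'
#' Calibrated parameters are stratified in 5-year intervals from 15 to 85.
#' Ages below 15 use the 15-20 stratum; ages above 85 use the 80-85 stratum.
#'
#' @param age age in years, 0..100 (vectorised).
#' @return integer bin index in 1..14.
#' @export
age_bin <- function(age) {
  stopifnot(is.numeric(age))
  if (any(age < 0 | age > 100)) stop("age must be within 0..100")
  pmin(pmax(floor((age - 15) / 5) + 1, 1), N_AGE_BINS)
}

#' Age bin labels
#' @return character vector like `"15-20"`, ..., `"80-85"`.
#' @export
age_bin_labels <- function() {
  paste0(AGE_BIN_BREAKS[-length(AGE_BIN_BREAKS)], "-", AGE_BIN_BREAKS[-1])
}

# 1-cm size-at-detection bins; sizes above 6 cm pool into "6+".
SIZE_BIN_BREAKS_MM <- c(0, 10, 20, 30, 40, 50, 60, Inf)

#' Size bin labels (cm)
#' @return character vector `"0-1"`, ..., `"5-6"`, `"6+"`.
#' @export
size_bin_labels <- function() {
  c("0-1", "1-2", "2-3", "3-4", "4-5", "5-6", "6+")
}

size_bin <- function(diameter_mm) {
  findInterval(diameter_mm, SIZE_BIN_BREAKS_MM, rightmost.closed = FALSE)
}

#' Fixed model input parameters
#'
#' The literature- and primary-data-derived inputs of the natural-history
#' model: the probability a new nodule is benign; behavior-class
#' probabilities (grow/shrink/stable) for malignant and benign nodules,
#' decided five years after onset; the shrink-rate and stable-slope
#' distributions; the minimum sonographically detectable diameter; and the
#' share of detected patients carrying a malignancy. Defaults are the
#' base-case values; any field may be overridden.
#'
#' @param ... named overrides of the default fields.
#' @return an `input_params` object (named list).
#' @examples
#' input_params()$p_benign  # 0.9
#' @export
input_params <- function(...) {
  p <- list(
    p_benign = 0.90,
    p_malig_growth = 0.301, p_malig_shrink = 0.252, p_malig_stable = 0.447,
    p_ben_grow = 0.111, p_ben_shrink = 0.131, p_ben_stable = 0.758,
    shrink_rate_mean = 0.0170, shrink_rate_sd = 0.0016,
    stable_slope_mean = 0.0094, stable_slope_sd = 0.0096,
    min_size_detect = 3.0,
    p_detected_nod_is_malig = 0.164,
    cell_volume = CELL_VOLUME,
    max_diameter = 200
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown input parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  pr <- unlist(p[c("p_benign", "p_malig_growth", "p_malig_shrink",
                   "p_malig_stable", "p_ben_grow", "p_ben_shrink",
                   "p_ben_stable", "p_detected_nod_is_malig")])
  if (any(pr < 0 | pr > 1)) stop("probabilities must lie in [0, 1]")
  for (trip in list(c("p_malig_growth", "p_malig_shrink", "p_malig_stable"),
                    c("p_ben_grow", "p_ben_shrink", "p_ben_stable"))) {
    s <- sum(unlist(p[trip]))
    if (abs(s - 1) > 1e-6)
      stop("behavior probabilities ", paste(trip, collapse = "+"),
           " must sum to 1 (got ", format(s), ")")
  }
  structure(p, class = "input_params")
}

PARAM_FIELDS <- c("dev_rate", "malig_growth_logmu", "malig_growth_logsigma",
                  "ben_growth_logmu", "ben_growth_logsigma", "B1", "B2")

#' Age-stratified calibrated parameter set
#'
#' The unknowns estimated by calibration, one value per 5-year age stratum
#' (15-20 through 80-85): `dev_rate` (annual probability of initiating a
#' nodule), lognormal log-mean/log-sd of the initial growth rate for
#' malignant and benign nodules, and the detection coefficients `B1`
#' (baseline rate per year) and `B2` (rate per mm^3 of largest-nodule
#' volume).
#'
#' @param dev_rate,malig_growth_logmu,malig_growth_logsigma numeric(14).
#' @param ben_growth_logmu,ben_growth_logsigma,B1,B2 numeric(14).
#' @return a `param_set` object: a list of seven numeric(14) vectors.
#' @export
param_set <- function(dev_rate, malig_growth_logmu, malig_growth_logsigma,
                      ben_growth_logmu, ben_growth_logsigma, B1, B2) {
  p <- list(dev_rate = dev_rate,
            malig_growth_logmu = malig_growth_logmu,
            malig_growth_logsigma = malig_growth_logsigma,
            ben_growth_logmu = ben_growth_logmu,
            ben_growth_logsigma = ben_growth_logsigma,
            B1 = B1, B2 = B2)
  for (f in PARAM_FIELDS) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != N_AGE_BINS || any(!is.finite(v)))
      stop("field ", f, " must be finite numeric of length ", N_AGE_BINS)
  }
  if (any(p$dev_rate < 0 | p$dev_rate > 1)) stop("dev_rate must lie in [0, 1]")
  if (any(p$malig_growth_logsigma < 0) || any(p$ben_growth_logsigma < 0))
    stop("logsigma must be >= 0")
  structure(lapply(p, unname), class = "param_set")
}

#' @export
print.param_set <- function(x, ...) {
  cat("Calibrated parameter set (", N_AGE_BINS, " age strata, 15-85)\n", sep = "")
  m <- do.call(rbind, x)
  colnames(m) <- age_bin_labels()
  print(signif(m, 4))
  invisible(x)
}

#' Default parameter bounds for calibration
#'
#' Search-box bounds per parameter field, recycled across age strata.
#'
#' @return a list with numeric(7) `lower` and `upper`, named by field.
#' @export
param_bounds <- function() {
  lower <- c(dev_rate = 0, malig_growth_logmu = -8, malig_growth_logsigma = 0,
             ben_growth_logmu = -8, ben_growth_logsigma = 0, B1 = 0, B2 = 0)
  upper <- c(dev_rate = 0.2, malig_growth_logmu = 2, malig_growth_logsigma = 2,
             ben_growth_logmu = 2, ben_growth_logsigma = 2, B1 = 0.5, B2 = 1e-2)
  list(lower = lower, upper = upper)
}

# flat vector <-> param_set, used by the annealing move kernel
param_set_to_vector <- function(p) {
  stopifnot(inherits(p, "param_set"))
  unlist(p[PARAM_FIELDS], use.names = FALSE)
}

vector_to_param_set <- function(v) {
  stopifnot(length(v) == 7 * N_AGE_BINS)
  m <- matrix(v, nrow = N_AGE_BINS)
  do.call(param_set, setNames(lapply(seq_len(7), function(j) m[, j]),
                              PARAM_FIELDS))
}

param_bounds_vectors <- function(bounds = param_bounds()) {
  list(lower = rep(bounds$lower[PARAM_FIELDS], each = N_AGE_BINS),
       upper = rep(bounds$upper[PARAM_FIELDS], each = N_AGE_BINS))
}

#' Read and write parameter sets as JSON
#'
#' Serialisation is bit-exact: numbers are written with full precision so a
#' round trip reproduces the set identically.
#'
#' @param p a [param_set()].
#' @param path file path.
#' @return `read_param_set()` a `param_set`; `write_param_set()` the path,
#'   invisibly.
#' @export
write_param_set <- function(p, path) {
  stopifnot(inherits(p, "param_set"))
  obj <- c(list(schema = "thyronod_param_set_v1",
                age_bins = age_bin_labels()),
           lapply(unclass(p), I))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_param_set
#' @export
read_param_set <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || !identical(obj$schema, "thyronod_param_set_v1"))
    stop("not a thyronod parameter set: ", path)
  do.call(param_set, obj[PARAM_FIELDS])
}
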