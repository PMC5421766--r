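#' @useDynLib thyronod, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rlnorm qnorm median sd quantile coef lm setNames
#' @importFrom utils read.csv write.csv head modifyList
NULL

# one tumor cell: the volume floor for every trajectory (mm^3)
CELL_VOLUME <- 1e-6

#' Sphere geometry conversions
#'
#' Nodules are modelled as spheres, so diameter `d` (mm) and volume `V`
#' (mm^3) are linked by `V = (pi/6) d^3`. The single-cell volume
#' `1e-6 mm^3` corresponds to a diameter of about 0.012407 mm.
#'
#' @param d diameter in mm, nonnegative (vectorised).
#' @param V volume in mm^3, nonnegative (vectorised).
#' @return `diameter_to_volume()` the volume in mm^3;
#'   `volume_to_diameter()` the diameter in mm.
#' @examples
#' diameter_to_volume(10)          # 523.6 mm^3
#' volume_to_diameter(1e-6)        # 0.012407 mm, one cell
#' @export
diameter_to_volume <- function(d) {
  stopifnot(is.numeric(d))
  if (any(d < 0)) stop("diameter must be nonnegative")
  (pi / 6) * d^3
}

#' @rdname diameter_to_volume
#' @export
volume_to_diameter <- function(V) {
  stopifnot(is.numeric(V))
  if (any(V < 0)) stop("volume must be nonnegative")
  (6 * V / pi)^(1 / 3)
}

#' Maximum nodule volume (carrying capacity)
#'
#' The logistic carrying capacity is global: the volume of a sphere of the
#' configured maximum diameter (default 200 mm, i.e. 20 cm).
#'
#' @param max_diameter maximum nodule diameter in mm.
#' @return carrying capacity in mm^3.
#' @export
carrying_capacity <- function(max_diameter = 200) {
  diameter_to_volume(max_diameter)
}

#' Kinetic parameter constructors
#'
#' Parameter bundles for the three closed-form volume laws. `growth_params`
#' describes logistic growth with per-year rate `r`, initial volume `V0`
#' and carrying capacity `K`; `shrink_params` exponential decay at rate
#' `r >= 0` from `V0`; `stable_params` a linear drift of `r` mm^3 per year
#' (possibly negative) from `V0`.
#'
#' @param r rate: per year (growth, shrink) or mm^3 per year (stable).
#' @param V0 initial volume, mm^3, positive.
#' @param K carrying capacity, mm^3, must exceed `V0`.
#' @return a classed list of validated parameters.
#' @export
growth_params <- function(r, V0 = CELL_VOLUME, K = carrying_capacity()) {
  stopifnot(is.finite(r), V0 > 0, K > V0)
  structure(list(r = r, V0 = V0, K = K), class = "growth_params")
}

#' @rdname growth_params
#' @export
shrink_params <- function(r, V0) {
  stopifnot(is.finite(r), r >= 0, V0 > 0)
  structure(list(r = r, V0 = V0), class = "shrink_params")
}

#' @rdname growth_params
#' @export
stable_params <- function(r, V0) {
  stopifnot(is.finite(r), V0 > 0)
  structure(list(r = r, V0 = V0), class = "stable_params")
}

check_time <- function(t) {
  if (any(!is.finite(t)) || any(t < 0)) stop("time must be finite and >= 0")
}

#' Closed-form nodule volume trajectories
#'
#' `logistic_volume()` solves dV/dt = r V (1 - V/K):
#' `V(t) = K V0 exp(rt) / (K + V0 (exp(rt) - 1))`.
#' `shrink_volume()` is exponential decay `V0 exp(-rt)`; `stable_volume()`
#' is the linear form `V0 + r t`, clamped below at the one-cell volume
#' `1e-6 mm^3` (a nodule cannot have sub-cell volume).
#'
#' @param t time in years, nonnegative (vectorised).
#' @param p parameters from [growth_params()], [shrink_params()] or
#'   [stable_params()].
#' @return volume in mm^3 at each `t`.
#' @examples
#' p <- growth_params(r = 1, V0 = 1e-6)
#' logistic_volume(c(0, 10, 20), p)
#' @export
logistic_volume <- function(t, p) {
  stopifnot(inherits(p, "growth_params"))
  check_time(t)
  # exp(rt) overflows for large rt; in that regime V = K to double precision
  ert <- exp(pmin(p$r * t, 700))
  V <- p$K * p$V0 * ert / (p$K + p$V0 * (ert - 1))
  pmin(V, p$K)
}

#' @rdname logistic_volume
#' @export
shrink_volume <- function(t, p) {
  stopifnot(inherits(p, "shrink_params"))
  check_time(t)
  pmax(p$V0 * exp(-p$r * t), CELL_VOLUME)
}

#' @rdname logistic_volume
#' @export
stable_volume <- function(t, p) {
  stopifnot(inherits(p, "stable_params"))
  check_time(t)
  pmax(p$V0 + p$r * t, CELL_VOLUME)
}
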