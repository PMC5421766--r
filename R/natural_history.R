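#' Detection rate and per-cycle detection probability
#'
#' The annual rate of clinical detection for a person is linear in the
#' volume of the largest nodule: `r_i(V) = B1_i + B2_i V`, with `i` the age
#' stratum. It does not depend on the number of nodules or their location.
#' Negative values (possible for negative calibrated `B1`) are clamped to 0.
#' The rate is converted to a per-cycle probability as `1 - exp(-rate)`.
#'
#' @param V_largest volume of the largest nodule, mm^3.
#' @param age person age in years.
#' @param params a [param_set()].
#' @param rate nonnegative annual rate.
#' @return `detection_rate()` an annual rate; `detection_probability()` a
#'   probability in `[0, 1)`.
#' @export
detection_rate <- function(V_largest, age, params) {
  stopifnot(V_largest >= 0, inherits(params, "param_set"))
  i <- age_bin(age)
  pmax(params$B1[i] + params$B2[i] * V_largest, 0)
}

#' @rdname detection_rate
#' @export
detection_probability <- function(rate) {
  if (any(rate < 0)) stop("rate must be nonnegative")
  1 - exp(-rate)
}

#' Draw initial growth rates
#'
#' The initial (logistic) growth rate of a nodule is lognormally
#' distributed, with separate distributions for malignant and benign
#' nodules and an age-stratum effect.
#'
#' @param bin age-stratum index (see [age_bin()]).
#' @param malignant logical.
#' @param params a [param_set()].
#' @param n number of draws.
#' @return positive per-year rates. Uses R's RNG stream.
#' @export
sample_growth_rate <- function(bin, malignant, params, n = 1) {
  stopifnot(bin >= 1, bin <= N_AGE_BINS, inherits(params, "param_set"))
  if (malignant) {
    rlnorm(n, params$malig_growth_logmu[bin], params$malig_growth_logsigma[bin])
  } else {
    rlnorm(n, params$ben_growth_logmu[bin], params$ben_growth_logsigma[bin])
  }
}

#' Create a nodule at onset
#'
#' A nodule starts as a single cell (`1e-6 mm^3`) and grows logistically
#' with its sampled rate until the behavior decision five years after
#' onset.
#'
#' @param onset_age age at initiation, years.
#' @param malignant logical.
#' @param growth_rate sampled initial growth rate, per year.
#' @param side `"left"` or `"right"`.
#' @return a `nodule` object.
#' @export
new_nodule <- function(onset_age, malignant, growth_rate,
                       side = c("left", "right")) {
  side <- match.arg(side)
  structure(list(
    malignant = malignant, side = side, onset_age = onset_age,
    behavior = "pre_switch", growth_rate = growth_rate,
    shrink_rate = NA_real_, stable_slope = NA_real_,
    switch_volume = NA_real_, current_volume = CELL_VOLUME
  ), class = "nodule")
}

#' Behavior assignment five years after onset
#'
#' Five years after development a nodule's subsequent behavior is decided:
#' it keeps growing, shrinks, or remains stable, with class probabilities
#' from [input_params()] (malignant 0.301/0.252/0.447; benign
#' 0.111/0.131/0.758). A shrink rate is drawn Normal(0.0170, 0.0016)
#' truncated at 0; a stable slope Normal(0.0094, 0.0096), untruncated.
#' The volume at the switch becomes the new law's `V0`.
#'
#' @param nodule a pre-switch `nodule`.
#' @param inputs an [input_params()].
#' @param nodule_age if supplied, must equal 5 (contract check).
#' @return the nodule with `behavior`, rates and `switch_volume` set.
#'   Uses R's RNG stream.
#' @export
assign_behavior <- function(nodule, inputs = input_params(), nodule_age = NULL) {
  if (!identical(nodule$behavior, "pre_switch"))
    stop("behavior already assigned")
  if (!is.null(nodule_age) && nodule_age != 5)
    stop("behavior is decided exactly 5 years after onset (got age ",
         nodule_age, ")")
  probs <- if (nodule$malignant) {
    c(inputs$p_malig_growth, inputs$p_malig_shrink, inputs$p_malig_stable)
  } else {
    c(inputs$p_ben_grow, inputs$p_ben_shrink, inputs$p_ben_stable)
  }
  u <- runif(1)
  nodule$behavior <- if (u < probs[1]) "growing"
    else if (u < probs[1] + probs[2]) "shrinking" else "stable"
  if (nodule$behavior == "shrinking")
    nodule$shrink_rate <- max(rnorm(1, inputs$shrink_rate_mean,
                                    inputs$shrink_rate_sd), 0)
  if (nodule$behavior == "stable")
    nodule$stable_slope <- rnorm(1, inputs$stable_slope_mean,
                                 inputs$stable_slope_sd)
  nodule$switch_volume <- nodule$current_volume
  nodule
}

# volume of a nodule at integer age t (years since onset), by its law
nodule_volume_at <- function(nodule, t, K = carrying_capacity()) {
  if (t <= 5 || nodule$behavior == "growing" || nodule$behavior == "pre_switch")
    return(logistic_volume(t, growth_params(nodule$growth_rate,
                                            V0 = CELL_VOLUME, K = K)))
  switch(nodule$behavior,
    shrinking = shrink_volume(t - 5, shrink_params(nodule$shrink_rate,
                                                   nodule$switch_volume)),
    stable = stable_volume(t - 5, stable_params(nodule$stable_slope,
                                                nodule$switch_volume)))
}

#' Create a person at birth
#' @return a `person` object: age 0, alive, no nodules, undetected.
#' @export
new_person <- function() {
  structure(list(
    current_age = 0L, alive = TRUE, nodules = list(),
    detected = FALSE, detection_age = NA_integer_,
    detection_class = NA_character_, death_age = NA_integer_
  ), class = "sim_person")
}

#' One annual cycle of the natural-history model
#'
#' Within a cycle, in fixed order: (1) all-cause death draw from the life
#' table; (2) possible initiation of one new nodule (malignant with
#' probability `1 - p_benign`, side uniform); (3) volume update of every
#' nodule by its law, with behavior assignment for nodules reaching five
#' years since onset; (4) a detection draw on the largest nodule, only
#' permitted when that nodule's diameter is at least `min_size_detect`
#' (3 mm, the conservative limit of sonography); (5) age increment.
#' On detection the person is classed `malignant_found` if any malignant
#' nodule of at least 3 mm exists, else `benign_only`, and exits the
#' natural-history model.
#'
#' @param person a living, undetected `person`.
#' @param inputs an [input_params()].
#' @param params a [param_set()].
#' @param life_table a [read_life_table()] table.
#' @return the updated `person`. Uses R's RNG stream.
#' @export
annual_cycle <- function(person, inputs, params, life_table) {
  stopifnot(inherits(person, "sim_person"))
  if (!person$alive || person$detected)
    stop("dead or detected persons are not updated further")
  a <- person$current_age
  K <- carrying_capacity(inputs$max_diameter)

  # (1) all-cause mortality
  if (runif(1) < life_table$qx[a + 1L]) {  # rows ordered 0..100
    person$alive <- FALSE
    person$death_age <- a
    return(person)
  }

  # (2) nodule development (at most one new nodule per cycle)
  bin <- age_bin(a)
  if (runif(1) < params$dev_rate[bin]) {
    malignant <- runif(1) < (1 - inputs$p_benign)
    rate <- sample_growth_rate(bin, malignant, params)
    side <- if (runif(1) < 0.5) "left" else "right"
    person$nodules[[length(person$nodules) + 1L]] <-
      new_nodule(a, malignant, rate, side)
  }

  # (3) growth update + behavior switch at nodule age 5
  for (j in seq_along(person$nodules)) {
    nod <- person$nodules[[j]]
    t <- a + 1L - nod$onset_age
    if (t == 5) {
      nod$current_volume <- nodule_volume_at(nod, 5, K)
      nod <- assign_behavior(nod, inputs, nodule_age = 5)
    } else {
      nod$current_volume <- nodule_volume_at(nod, t, K)
    }
    person$nodules[[j]] <- nod
  }

  # (4) detection on the largest nodule, gated at the 3 mm sonographic floor
  if (length(person$nodules)) {
    vols <- vapply(person$nodules, `[[`, numeric(1), "current_volume")
    v_big <- max(vols)
    if (volume_to_diameter(v_big) >= inputs$min_size_detect) {
      p_det <- detection_probability(detection_rate(v_big, a, params))
      if (runif(1) < p_det) {
        person$detected <- TRUE
        person$detection_age <- a  # age whose cycle triggered detection
        malig_vis <- vapply(person$nodules, function(n) {
          n$malignant &&
            volume_to_diameter(n$current_volume) >= inputs$min_size_detect
        }, logical(1))
        person$detection_class <- if (any(malig_vis)) "malignant_found"
          else "benign_only"
      }
    }
  }

  # (5) age
  person$current_age <- a + 1L
  person
}

#' Simulate one person from birth
#'
#' Runs [annual_cycle()] from birth until clinical detection, death, or age
#' 100, whichever comes first. Replayable: the same seed yields the same
#' life history.
#'
#' @param seed integer seed for R's RNG.
#' @param inputs,params,life_table model configuration.
#' @param record if `TRUE`, attach a per-age snapshot data frame
#'   (`age`, `n_nodules`, `any_visible`, `malig_visible`) taken at the
#'   start of each cycle while alive and undetected.
#' @return the final `person`; with `record`, snapshots in
#'   `attr(, "snapshots")`.
#' @export
simulate_person <- function(seed, inputs = input_params(), params,
                            life_table = synthetic_life_table(),
                            record = FALSE) {
  set.seed(seed)
  person <- new_person()
  snaps <- if (record) vector("list", 100L)
  while (person$alive && !person$detected && person$current_age < 100L) {
    if (record) {
      d <- vapply(person$nodules, function(n)
        volume_to_diameter(n$current_volume), numeric(1))
      m <- vapply(person$nodules, `[[`, logical(1), "malignant")
      snaps[[person$current_age + 1L]] <- data.frame(
        age = person$current_age, n_nodules = length(d),
        any_visible = any(d >= inputs$min_size_detect),
        malig_visible = any(m & d >= inputs$min_size_detect))
    }
    person <- annual_cycle(person, inputs, params, life_table)
  }
  if (record)
    attr(person, "snapshots") <- do.call(rbind, snaps[!vapply(snaps, is.null,
                                                              logical(1))])
  person
}

#' @export
print.sim_person <- function(x, ...) {
  cat("<person> age", x$current_age,
      if (!x$alive) sprintf("(died at %d)", x$death_age) else "(alive)",
      "\n  nodules:", length(x$nodules),
      "\n  detected:", x$detected,
      if (x$detected) sprintf("at age %d as %s", x$detection_age,
                              x$detection_class) else "", "\n")
  invisible(x)
}
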