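GOF_EPS <- 1e-6

#' Calibration target tables
#'
#' Bundles the binned targets the model is fitted to: the age-binned
#' detected-malignant incidence proportions, the 1-cm size distribution of
#' malignant tumors at detection per age bin, the benign-only share of
#' detections (1 - 0.164 in the base case), and a benign size table
#' (assumed to follow the malignant distribution, and down-weighted because
#' the underlying data are weak).
#'
#' @param incidence data frame `age_bin,value`, one row per 5-year bin.
#' @param size 14 x 7 matrix of row proportions (age bin x cm bin).
#' @param benign_fraction scalar target share of benign-only detections.
#' @param benign_size 14 x 7 matrix; defaults to `size`.
#' @param weights named nonnegative weights per table.
#' @return a `calib_targets` object.
#' @export
calib_targets <- function(incidence, size,
                          benign_fraction = 1 - 0.164,
                          benign_size = size,
                          weights = c(incidence = 1, size = 1,
                                      benign_fraction = 0.5,
                                      benign_size = 0.1)) {
  stopifnot(nrow(incidence) == N_AGE_BINS,
            all(c("age_bin", "value") %in% names(incidence)),
            identical(dim(size), c(N_AGE_BINS, 7L)),
            identical(dim(benign_size), c(N_AGE_BINS, 7L)),
            benign_fraction >= 0, benign_fraction <= 1)
  w <- c(incidence = 1, size = 1, benign_fraction = 0.5, benign_size = 0.1)
  w[names(weights)] <- weights
  if (any(w < 0)) stop("weights must be nonnegative")
  rs <- rowSums(size)
  if (any(rs > 0 & abs(rs - 1) > 1e-6))
    stop("size target rows must each sum to 1 (or be all zero)")
  structure(list(incidence = incidence[, c("age_bin", "value")],
                 size = size, benign_fraction = benign_fraction,
                 benign_size = benign_size, weights = w),
            class = "calib_targets")
}

#' Weighted chi-squared goodness of fit
#'
#' `total = sum_tables w_t sum_bins (model_b - target_b)^2 / max(target_b, 1e-6)`.
#' The denominator floor avoids division by zero in empty bins. The score
#' is zero exactly when every weighted bin matches its target, is additive
#' over tables, and is invariant to bin order.
#'
#' @param outputs a `cohort_outputs` from [simulate_cohort()].
#' @param targets a [calib_targets()].
#' @return a `gof_result`: `total` and a per-table/per-bin `components`
#'   data frame.
#' @export
weighted_chi_squared <- function(outputs, targets) {
  stopifnot(inherits(outputs, "cohort_outputs"),
            inherits(targets, "calib_targets"))
  if (!identical(outputs$incidence_by_age$age_bin, targets$incidence$age_bin))
    stop("incidence binning mismatch between model output and targets")
  if (!identical(dim(outputs$size_dist_by_age), dim(targets$size)))
    stop("size-table binning mismatch between model output and targets")
  chi <- function(m, t) (m - t)^2 / pmax(t, GOF_EPS)
  w <- targets$weights
  comp <- rbind(
    data.frame(table = "incidence", bin = targets$incidence$age_bin,
               contribution = w[["incidence"]] *
                 chi(outputs$incidence_by_age$value, targets$incidence$value)),
    data.frame(table = "size",
               bin = paste(rep(rownames(targets$size), 7),
                           rep(colnames(targets$size), each = N_AGE_BINS),
                           sep = "/"),
               contribution = w[["size"]] *
                 as.vector(chi(outputs$size_dist_by_age, targets$size))),
    data.frame(table = "benign_fraction", bin = "all",
               contribution = w[["benign_fraction"]] *
                 chi(outputs$benign_detected_fraction,
                     targets$benign_fraction)),
    data.frame(table = "benign_size",
               bin = paste(rep(rownames(targets$benign_size), 7),
                           rep(colnames(targets$benign_size),
                               each = N_AGE_BINS), sep = "/"),
               contribution = w[["benign_size"]] *
                 as.vector(chi(outputs$benign_size_dist_by_age,
                               targets$benign_size))))
  rownames(comp) <- NULL
  structure(list(total = sum(comp$contribution), components = comp),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat("<gof_result> total =", format(x$total), "\n")
  print(vapply(split(x$components$contribution, x$components$table), sum,
               numeric(1)))
  invisible(x)
}

# --- move kernel ------------------------------------------------------------

reflect_into <- function(x, lo, hi) {
  if (hi <= lo) return(lo)
  span <- hi - lo
  while (x < lo || x > hi) {
    if (x > hi) x <- 2 * hi - x
    if (x < lo) x <- 2 * lo - x
    # pathological overshoot: fold into range
    if (abs(x - lo) > 2 * span) x <- lo + abs(x - lo) %% span
  }
  x
}

propose_vec <- function(current, scale, lower, upper) {
  if (scale == 0) return(current)
  j <- sample.int(length(current), 1)
  step <- rnorm(1, 0, scale * (upper[j] - lower[j]))
  current[j] <- reflect_into(current[j] + step, lower[j], upper[j])
  current
}

#' Propose a neighboring parameter set
#'
#' The annealing move kernel: one randomly chosen parameter is perturbed by
#' a Gaussian step scaled to its bound range, reflected at the bounds.
#'
#' @param current a [param_set()].
#' @param scale step standard deviation as a fraction of each bound range.
#' @param bounds as [param_bounds()].
#' @return a `param_set`. Uses R's RNG stream.
#' @export
propose_step <- function(current, scale = 0.05, bounds = param_bounds()) {
  stopifnot(inherits(current, "param_set"))
  bv <- param_bounds_vectors(bounds)
  vector_to_param_set(propose_vec(param_set_to_vector(current), scale,
                                  bv$lower, bv$upper))
}

# --- simulated annealing ----------------------------------------------------

#' Simulated annealing over a boxed parameter space
#'
#' Metropolis acceptance `exp(-delta/T)` under a geometric cooling schedule
#' `T_k = T0 * c^k`. Uphill moves are accepted with decreasing probability
#' so the search can escape local minima; as `T -> 0` the rule degenerates
#' to greedy descent. States that are abandoned via an uphill move without
#' any downhill proposal having been seen from them are archived as local
#' minima for later refinement.
#'
#' @param objective function mapping a numeric parameter vector to a scalar
#'   score (lower is better).
#' @param init initial parameter vector.
#' @param lower,upper bound vectors.
#' @param n_steps number of proposals (each one a unique evaluated set).
#' @param T0 initial temperature; default is the initial score (or 1 if it
#'   is zero).
#' @param cooling geometric factor per step; default chosen so the final
#'   temperature is `1e-3 * T0`.
#' @param scale proposal scale (fraction of bound range).
#' @param seed optional seed for R's RNG.
#' @param archive_max keep at most this many lowest-score local minima.
#' @return an `anneal_state`: `best`/`best_score`, `current`/
#'   `current_score`, the local-minima `archive`, and a step `trajectory`.
#' @export
anneal <- function(objective, init, lower, upper, n_steps = 2000,
                   T0 = NULL, cooling = NULL, scale = 0.05, seed = NULL,
                   archive_max = 64) {
  stopifnot(n_steps >= 1, length(init) == length(lower),
            length(init) == length(upper))
  if (!is.null(seed)) set.seed(seed)
  cur <- init
  cur_score <- objective(cur)
  if (is.null(T0)) T0 <- if (cur_score > 0) cur_score else 1
  if (is.null(cooling)) cooling <- (1e-3)^(1 / n_steps)
  best <- cur
  best_score <- cur_score
  archive <- list()
  downhill_seen <- FALSE
  n_prop_here <- 0L
  temp <- T0
  traj <- data.frame(step = 0:n_steps, current = NA_real_, best = NA_real_)
  traj$current[1] <- cur_score
  traj$best[1] <- best_score

  push_archive <- function(arch, vec, score) {
    arch[[length(arch) + 1]] <- list(params = vec, score = score)
    if (length(arch) > archive_max) {
      scores <- vapply(arch, `[[`, numeric(1), "score")
      arch <- arch[order(scores)[seq_len(archive_max)]]
    }
    arch
  }

  for (k in seq_len(n_steps)) {
    temp <- temp * cooling
    prop <- propose_vec(cur, scale, lower, upper)
    prop_score <- objective(prop)
    delta <- prop_score - cur_score
    if (delta < 0) downhill_seen <- TRUE
    n_prop_here <- n_prop_here + 1L
    accept <- delta <= 0 ||
      (temp > 0 && runif(1) < exp(-delta / temp))
    if (accept) {
      if (delta > 0 && !downhill_seen && n_prop_here > 1L)
        archive <- push_archive(archive, cur, cur_score)
      cur <- prop
      cur_score <- prop_score
      downhill_seen <- FALSE
      n_prop_here <- 0L
      if (cur_score < best_score) {
        best <- cur
        best_score <- cur_score
      }
    }
    traj$current[k + 1] <- cur_score
    traj$best[k + 1] <- best_score
  }
  if (!downhill_seen)
    archive <- push_archive(archive, cur, cur_score)
  structure(list(best = best, best_score = best_score,
                 current = cur, current_score = cur_score,
                 archive = archive, trajectory = traj,
                 n_steps = n_steps, T0 = T0, cooling = cooling),
            class = "anneal_state")
}

#' @export
print.anneal_state <- function(x, ...) {
  cat("<anneal_state>", x$n_steps, "steps; best score",
      format(x$best_score), ";", length(x$archive), "archived local minima\n")
  invisible(x)
}

#' Greedy refinement of archived local minima
#'
#' Archive members scoring within 5% of the best goodness of fit
#' (`score <= window * best_score`) are fine-tuned by coordinate-wise
#' greedy descent with shrinking step sizes; only strictly improving steps
#' are accepted. Returns the overall lowest-scoring parameter vector.
#'
#' @param archive list of `list(params, score)` as produced by [anneal()].
#' @param best_score best score so far (defines the 5% window).
#' @param objective the scoring function.
#' @param lower,upper bounds.
#' @param window inclusion multiplier, default 1.05.
#' @param step_frac initial step as a fraction of each bound range.
#' @param min_step_frac stop once steps shrink below this fraction.
#' @param max_evals total objective-evaluation budget.
#' @return `list(params, score, n_evals)`.
#' @export
refine <- function(archive, best_score, objective, lower, upper,
                   window = 1.05, step_frac = 0.05, min_step_frac = 1e-3,
                   max_evals = 2000) {
  if (!length(archive)) stop("archive is empty")
  scores <- vapply(archive, `[[`, numeric(1), "score")
  keep <- which(scores <= window * best_score)
  if (!length(keep)) keep <- which.min(scores)
  evals <- 0L
  out_best <- archive[[keep[which.min(scores[keep])]]]
  for (idx in keep[order(scores[keep])]) {
    x <- archive[[idx]]$params
    fx <- archive[[idx]]$score
    frac <- step_frac
    while (frac >= min_step_frac && evals < max_evals) {
      improved <- FALSE
      for (j in seq_along(x)) {
        if (evals >= max_evals) break
        for (sgn in c(1, -1)) {
          if (evals >= max_evals) break
          cand <- x
          cand[j] <- min(max(x[j] + sgn * frac * (upper[j] - lower[j]),
                             lower[j]), upper[j])
          if (cand[j] == x[j]) next
          fc <- objective(cand)
          evals <- evals + 1L
          if (fc < fx) {
            x <- cand
            fx <- fc
            improved <- TRUE
            break  # take the improving direction, move on
          }
        }
      }
      if (!improved) frac <- frac / 2
    }
    if (fx < out_best$score) out_best <- list(params = x, score = fx)
  }
  list(params = out_best$params, score = out_best$score, n_evals = evals)
}

# GOF objective over the flat parameter vector, with common random numbers:
# every evaluation simulates the same persons (same cohort seed)
make_gof_objective <- function(targets, inputs, life_table, sim_n, seed) {
  force(targets); force(inputs); force(life_table); force(sim_n); force(seed)
  function(vec) {
    out <- simulate_cohort(sim_n, inputs, vector_to_param_set(vec),
                           life_table, seed = seed)
    weighted_chi_squared(out, targets)$total
  }
}

#' Calibrate the age-stratified parameters
#'
#' Runs simulated annealing over the boxed parameter space against the
#' weighted chi-squared goodness of fit, then greedy refinement of archived
#' local minima within 5% of the best score. Every objective evaluation
#' simulates `sim_n` persons with a fixed cohort seed (common random
#' numbers), so the objective is a deterministic function of the
#' parameters.
#'
#' @param targets a [calib_targets()].
#' @param config list of settings: `n_steps` (annealing proposals, default
#'   2000), `sim_n` (persons per evaluation, default 2e4), `seed`, `T0`,
#'   `cooling`, `scale`, `refine_evals`, `inputs`, `life_table`, `bounds`,
#'   and optionally `init` (a `param_set` start; default random within
#'   bounds).
#' @return a `calibration_result`: `params` (best `param_set`), `score`,
#'   per-table GOF `components`, the annealing `trajectory`, and the
#'   annealing/refinement bookkeeping.
#' @export
calibrate <- function(targets, config = list()) {
  stopifnot(inherits(targets, "calib_targets"))
  cfg <- modifyList(list(n_steps = 2000, sim_n = 2e4, seed = 1,
                         T0 = NULL, cooling = NULL, scale = 0.05,
                         refine_evals = 400, inputs = input_params(),
                         life_table = synthetic_life_table(),
                         bounds = param_bounds(), init = NULL,
                         verbose = FALSE),
                    config)
  bv <- param_bounds_vectors(cfg$bounds)
  if (all(targets$weights == 0)) {
    warning("all target weights are zero: any parameter set scores 0")
    init <- if (is.null(cfg$init)) random_param_set(cfg$seed, cfg$bounds)
            else cfg$init
    return(structure(list(params = init, score = 0, components = NULL,
                          trajectory = NULL, anneal = NULL, refine = NULL),
                     class = "calibration_result"))
  }
  obj <- make_gof_objective(targets, cfg$inputs, cfg$life_table,
                            cfg$sim_n, cfg$seed)
  set.seed(cfg$seed)
  init_vec <- if (is.null(cfg$init)) {
    runif(length(bv$lower), bv$lower, bv$upper)
  } else {
    param_set_to_vector(cfg$init)
  }
  ann <- anneal(obj, init_vec, bv$lower, bv$upper, n_steps = cfg$n_steps,
                T0 = cfg$T0, cooling = cfg$cooling, scale = cfg$scale)
  archive <- ann$archive
  archive[[length(archive) + 1]] <- list(params = ann$best,
                                         score = ann$best_score)
  ref <- refine(archive, ann$best_score, obj, bv$lower, bv$upper,
                max_evals = cfg$refine_evals)
  best <- vector_to_param_set(ref$params)
  out <- simulate_cohort(cfg$sim_n, cfg$inputs, best, cfg$life_table,
                         seed = cfg$seed)
  gof <- weighted_chi_squared(out, targets)
  structure(list(params = best, score = ref$score, components = gof,
                 trajectory = ann$trajectory, anneal = ann, refine = ref,
                 config = cfg[c("n_steps", "sim_n", "seed", "scale",
                                "refine_evals")]),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> score", format(x$score), "after",
      x$config$n_steps, "annealing steps (sim_n =", x$config$sim_n, ")\n")
  invisible(x)
}

#' Draw a random parameter set within bounds
#' @param seed RNG seed.
#' @param bounds as [param_bounds()].
#' @return a `param_set`.
#' @export
random_param_set <- function(seed = NULL, bounds = param_bounds()) {
  if (!is.null(seed)) set.seed(seed)
  bv <- param_bounds_vectors(bounds)
  vector_to_param_set(runif(length(bv$lower), bv$lower, bv$upper))
}
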