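test_that("cohort simulation is deterministic and degenerates correctly", {
  ps <- flat_param_set()
  a <- simulate_cohort(2000, params = ps, seed = 9, screen_age = 50)
  b <- simulate_cohort(2000, params = ps, seed = 9, screen_age = 50)
  expect_identical(a, b)
  expect_error(simulate_cohort(0, params = ps), ">= 1")

  # no development: everything is zero
  z <- simulate_cohort(2000, params = flat_param_set(dev_rate = 0), seed = 1)
  expect_equal(sum(z$incidence_by_age$value), 0)
  expect_equal(sum(z$subclinical_prevalence_by_age$p_any_nodule), 0)
  expect_equal(z$n_detected, 0)

  # incidence proportions are proportions
  out <- simulate_cohort(5000, params = ps, seed = 2)
  expect_true(all(out$incidence_by_age$value >= 0 &
                    out$incidence_by_age$value <= 1))
  expect_lte(sum(out$incidence_by_age$value), 1)
  # size-distribution rows sum to one (or are empty)
  rs <- rowSums(out$size_dist_by_age)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-9))
})

test_that("subclinical malignant prevalence never exceeds any-nodule prevalence", {
  out <- simulate_cohort(5000, params = flat_param_set(dev_rate = 0.05),
                         seed = 4)
  prev <- out$subclinical_prevalence_by_age
  expect_true(all(prev$p_malig_visible <= prev$p_visible + 1e-12))
  expect_true(all(prev$p_visible <= prev$p_any_nodule + 1e-12))
})

test_that("detection off leaves the reservoir unchanged and size tables empty", {
  ps <- flat_param_set(B1 = 1e-6, B2 = 0)
  on <- simulate_cohort(8000, params = ps, seed = 3)
  off <- simulate_cohort(8000, params = ps, seed = 3, detection = FALSE)
  expect_equal(off$n_detected, 0)
  expect_equal(sum(off$size_dist_by_age), 0)
  # common random numbers + tiny detection rates: reservoirs nearly
  # identical at ages where the at-risk denominator is stable
  po <- off$subclinical_prevalence_by_age
  pn <- on$subclinical_prevalence_by_age
  big <- pn$at_risk >= 2000
  expect_lt(max(abs(po$p_any_nodule[big] - pn$p_any_nodule[big])), 0.005)
})

test_that("Monte Carlo error of prevalence scales like 1/sqrt(n)", {
  ps <- flat_param_set()
  p_at_50 <- function(n, seed) {
    out <- simulate_cohort(n, params = ps, seed = seed)
    prev <- out$subclinical_prevalence_by_age
    prev$p_visible[prev$age == 50]
  }
  ref <- p_at_50(64000, 1000)
  err <- function(n) {
    vapply(1:8, function(s) abs(p_at_50(n, s) - ref), numeric(1))
  }
  e1 <- sqrt(mean(err(1000)^2))
  e2 <- sqrt(mean(err(16000)^2))
  # 16x the sample size should shrink the RMS error about 4-fold
  expect_lt(e2, e1 / 1.8)
})

test_that("screening cross-section matches a hand-built enumeration", {
  # 4 persons: 2 with a 5 mm benign nodule, 1 with a 12 mm malignant
  # nodule, 1 nodule-free
  mk <- function(nods) {
    p <- new_person()
    p$current_age <- 50L
    p$nodules <- nods
    p
  }
  nod <- function(d, malignant) {
    n <- new_nodule(40, malignant, 1)
    n$current_volume <- diameter_to_volume(d)
    n
  }
  cohort <- list(mk(list(nod(5, FALSE))), mk(list(nod(5, FALSE))),
                 mk(list(nod(12, TRUE))), mk(list()))
  scr <- screening_cross_section(50, 3, cohort)
  expect_equal(scr$prevalence_any_nodule, 0.75)
  expect_equal(scr$prevalence_malignant, 0.25)
  expect_equal(scr$fraction_below_10mm, 2 / 3)
  expect_equal(unname(scr$nodule_size_histogram[1:2]), c(2, 1))

  # floor above every nodule: nothing found
  scr_inf <- screening_cross_section(50, 1e6, cohort)
  expect_equal(scr_inf$prevalence_any_nodule, 0)
  expect_true(is.na(scr_inf$fraction_below_10mm))
  expect_error(screening_cross_section(150, 3, cohort), "0..100")

  # engine route requires the matching snapshot
  out <- simulate_cohort(500, params = flat_param_set(), seed = 1)
  expect_error(screening_cross_section(50, 3, out), "screen_age")
})

test_that("lifetime cancer risk matches a hand-built enumeration", {
  mk <- function(death = NA, det = NA, class = NA) {
    p <- new_person()
    p$current_age <- 90L
    p$death_age <- death
    if (!is.na(det)) {
      p$detected <- TRUE
      p$detection_age <- det
      p$detection_class <- class
    }
    p
  }
  cohort <- c(list(mk(det = 40, class = "malignant_found"),
                   mk(det = 70, class = "malignant_found"),
                   mk(det = 50, class = "benign_only"),
                   mk(death = 10),  # dead before the window: excluded
                   mk(det = 90, class = "malignant_found")),  # after window
              replicate(6, mk(), simplify = FALSE))
  # 10 alive at 15; 2 malignant detections inside [15, 85]
  expect_equal(lifetime_cancer_risk(15, 85, cohort), 0.2)
  expect_error(lifetime_cancer_risk(85, 15, cohort), "below")

  # detection disabled: risk 0
  off <- simulate_cohort(1000, params = flat_param_set(), seed = 2,
                         detection = FALSE)
  expect_equal(lifetime_cancer_risk(15, 85, off), 0)
})

test_that("R and C++ engines agree distributionally", {
  # dual route: per-person R implementation vs the compiled cohort engine
  ps <- flat_param_set(dev_rate = 0.05, B1 = 0.005, B2 = 1e-4)
  n <- 1500
  persons <- lapply(seq_len(n), function(i)
    simulate_person(i, params = ps, record = TRUE))
  det_r <- mean(vapply(persons, `[[`, logical(1), "detected"))
  vis50_r <- mean(vapply(persons, function(p) {
    sn <- attr(p, "snapshots")
    any(sn$age == 50 & sn$any_visible)
  }, logical(1)))

  out <- simulate_cohort(20000, params = ps, seed = 77)
  det_c <- out$n_detected / out$n_simulated
  prev <- out$subclinical_prevalence_by_age
  vis50_c <- prev$p_visible[prev$age == 50] *
    prev$at_risk[prev$age == 50] / 20000

  se_det <- sqrt(det_r * (1 - det_r) / n)
  expect_lt(abs(det_r - det_c), 4 * se_det)
  se_vis <- sqrt(max(vis50_r * (1 - vis50_r), 0.002) / n)
  expect_lt(abs(vis50_r - vis50_c), 4 * se_vis)
})

test_that("prevalence comparison table aligns bins and flags unknown ones", {
  out <- simulate_cohort(2000, params = flat_param_set(), seed = 8)
  empty <- prevalence_comparison_table(
    out, data.frame(age_bin = character(), prevalence = numeric()))
  expect_equal(nrow(empty), 0)

  one <- prevalence_comparison_table(
    out, data.frame(age_bin = "45-50", prevalence = 0.3))
  expect_equal(nrow(one), 1)
  expect_equal(one$difference, one$model - 0.3)

  # identical tables: all differences zero
  ext <- data.frame(age_bin = age_bin_labels(), prevalence = one$model[1])
  cmp <- prevalence_comparison_table(out, ext)
  self_ext <- data.frame(age_bin = cmp$age_bin, prevalence = cmp$model)
  expect_equal(prevalence_comparison_table(out, self_ext)$difference,
               rep(0, 14))

  expect_error(prevalence_comparison_table(
    out, data.frame(age_bin = "95-100", prevalence = 0.1)), "unmatched")
})
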