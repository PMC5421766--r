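#' Synthetic longitudinal tumor-diameter cohort
#'
#' Emulates an observational active-surveillance cohort of low-risk
#' papillary microcarcinomas followed by serial ultrasound: by default 221
#' patients aged 21-80 with a median follow-up of exactly 9.7 years
#' (follow-up times are quantile-matched draws from a lognormal with median
#' 9.7, so the sample median of an odd-sized cohort is exact). Each tumor
#' starts between 3 and 10 mm and follows one of the three kinetic laws,
#' with class probabilities 0.301/0.252/0.447 (grow/shrink/stable), a
#' shrink rate drawn Normal(0.0170, 0.0016) truncated at zero, a stable
#' slope Normal(0.0094, 0.0096), and a slow exponential volume growth rate
#' for growers; diameters carry multiplicative lognormal measurement noise.
#'
#' This is a synthetic stand-in, not patient data: it reproduces the
#' cohort's stated size, age range, follow-up and generating kinetics, but
#' none of its individual trajectories.
#'
#' @param n number of patients.
#' @param seed RNG seed.
#' @param median_followup target median follow-up, years.
#' @param followup_sdlog lognormal spread of follow-up times.
#' @param growth_logmean,growth_sdlog lognormal parameters of the volume
#'   growth rate (per year) of growing tumors.
#' @param noise_sdlog measurement noise on diameters (log scale).
#' @param obs_interval years between ultrasound observations.
#' @return a data frame in the [read_longitudinal()] schema
#'   (`patient_id,age,time_years,diameter_mm`).
#' @export
synthetic_longitudinal <- function(n = 221, seed = 1,
                                   median_followup = 9.7,
                                   followup_sdlog = 0.45,
                                   growth_logmean = log(0.08),
                                   growth_sdlog = 0.5,
                                   noise_sdlog = 0.02,
                                   obs_interval = 1.5) {
  set.seed(seed)
  inputs <- input_params()
  # quantile-matched follow-up: the sample median is exact for odd n
  qs <- (seq_len(n) - 0.5) / n
  followup <- exp(log(median_followup) + followup_sdlog * qnorm(qs))
  followup <- sample(followup)
  age <- sample(21:80, n, replace = TRUE)
  cls <- sample(c("grow", "shrink", "stable"), n, replace = TRUE,
                prob = c(inputs$p_malig_growth, inputs$p_malig_shrink,
                         inputs$p_malig_stable))
  rows <- lapply(seq_len(n), function(i) {
    d0 <- runif(1, 3, 10)
    V0 <- diameter_to_volume(d0)
    tt <- unique(c(seq(0, followup[i], by = obs_interval), followup[i]))
    V <- switch(cls[i],
      grow = V0 * exp(rlnorm(1, growth_logmean, growth_sdlog) * tt),
      shrink = V0 * exp(-max(rnorm(1, inputs$shrink_rate_mean,
                                   inputs$shrink_rate_sd), 0) * tt),
      stable = pmax(V0 + rnorm(1, inputs$stable_slope_mean,
                               inputs$stable_slope_sd) * tt, CELL_VOLUME))
    d <- volume_to_diameter(V) * rlnorm(length(tt), 0, noise_sdlog)
    data.frame(patient_id = sprintf("P%03d", i), age = age[i],
               time_years = tt, diameter_mm = d)
  })
  do.call(rbind, rows)
}
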