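# Independent oracles and small fixtures used across the suite.

# Classical fixed-step RK4 integration of dV/dt = r V (1 - V/K); the
# independent route against the logistic closed form.
rk4_logistic <- function(t_end, r, V0, K, dt = 1e-3) {
  f <- function(V) r * V * (1 - V / K)
  V <- V0
  n <- ceiling(t_end / dt)
  dt <- t_end / n
  for (i in seq_len(n)) {
    k1 <- f(V)
    k2 <- f(V + dt / 2 * k1)
    k3 <- f(V + dt / 2 * k2)
    k4 <- f(V + dt * k3)
    V <- V + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  V
}

# a small flat parameter set for engine tests
flat_param_set <- function(dev_rate = 0.02, mg_mu = log(0.8), mg_sig = 0.5,
                           bg_mu = log(2.5), bg_sig = 0.25,
                           B1 = 0.002, B2 = 1e-4) {
  param_set(dev_rate = rep(dev_rate, 14),
            malig_growth_logmu = rep(mg_mu, 14),
            malig_growth_logsigma = rep(mg_sig, 14),
            ben_growth_logmu = rep(bg_mu, 14),
            ben_growth_logsigma = rep(bg_sig, 14),
            B1 = rep(B1, 14), B2 = rep(B2, 14))
}

# deterministic life tables for contract tests
no_death_life_table <- function() {
  as_lt <- function(q) {
    df <- data.frame(age = 0:100, qx = q)
    df$qx[101] <- 1
    structure(df, class = c("life_table", "data.frame"))
  }
  as_lt(rep(0, 101))
}

all_death_life_table <- function() {
  df <- data.frame(age = 0:100, qx = rep(1, 101))
  structure(df, class = c("life_table", "data.frame"))
}

# the bundled synthetic calibrated parameter set
bundled_params <- function() {
  read_param_set(system.file("extdata", "params_synthetic.json",
                             package = "thyronod"))
}

make_record <- function(times, diameters, id = "P1", age = 50) {
  structure(list(patient_id = id, age_at_entry = age,
                 times = times, diameters = diameters),
            class = "longitudinal_record")
}
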