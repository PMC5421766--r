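#' Read an age-indexed life table
#'
#' Expects a CSV with header `age,qx`: integer ages 0..100 (complete, each
#' exactly once) and annual all-cause death probabilities `qx` in `[0, 1]`.
#' `qx` at age 100 is forced to 1 (the model follows women to age 100 at
#' most, so the final age is absorbing).
#'
#' @param path CSV file path.
#' @return a `life_table`: data frame with columns `age`, `qx`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table not found: ", path)
  df <- read.csv(path)
  if (!all(c("age", "qx") %in% names(df)))
    stop("life table must have columns 'age' and 'qx' (got: ",
         paste(names(df), collapse = ", "), ")")
  bad <- which(!is.finite(df$qx) | df$qx < 0 | df$qx > 1)
  if (length(bad))
    stop("qx out of [0, 1] at row(s) ", paste(bad, collapse = ", "))
  as_life_table(df)
}

as_life_table <- function(df) {
  missing_ages <- setdiff(0:100, df$age)
  if (length(missing_ages))
    stop("life table missing age(s): ", paste(missing_ages, collapse = ", "))
  if (anyDuplicated(df$age)) stop("life table has duplicated ages")
  df <- df[order(df$age), c("age", "qx")]
  df <- df[df$age <= 100, ]
  df$qx[df$age == 100] <- 1
  rownames(df) <- NULL
  class(df) <- c("life_table", "data.frame")
  df
}

#' Synthetic female all-cause mortality life table
#'
#' A Gompertz-Makeham hazard with an infant/childhood component,
#' `h(a) = A + C exp(-D a) + B exp(G a)`, with constants chosen to
#' approximate US female period mortality around 2010-2012 (life expectancy
#' roughly 81 years; q50 about 3e-3; q80 about 5e-2). Used as a
#' download-free stand-in for CDC life tables; any table in the same
#' `age,qx` schema may be substituted.
#'
#' @param A Makeham background hazard.
#' @param B,G Gompertz senescent hazard scale and log-slope.
#' @param C,D infant component scale and decay.
#' @return a `life_table` data frame, ages 0..100.
#' @export
synthetic_life_table <- function(A = 2e-4, B = 2.5e-5, G = 0.095,
                                 C = 4.5e-3, D = 1.1) {
  age <- 0:100
  h <- A + C * exp(-D * age) + B * exp(G * age)
  qx <- pmin(1 - exp(-h), 1)
  as_life_table(data.frame(age = age, qx = qx))
}
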