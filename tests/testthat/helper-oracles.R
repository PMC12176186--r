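# Independent oracles and small fixtures shared across tests.

# the worked-example trajectory (volumes on the seven protocol days)
worked_example_trial <- function() {
  path <- system.file("extdata", "etgt_worked_example.csv",
                      package = "pdxscreen", mustWork = TRUE)
  read_trial_table(path)
}

# closed-form step-down q-values: q at rank j equals the minimum over the
# tail of (M/k) * p_(k); equivalent to the recursive step-down definition
storey_q_oracle <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pp <- p[ok]
  M <- length(pp)
  if (M == 0L) return(out)
  o <- order(pp)
  s <- pp[o]
  q <- vapply(seq_len(M), function(j) min((M / (j:M)) * s[j:M]), numeric(1))
  qq <- numeric(M)
  qq[o] <- pmin(q, 1)
  out[ok] <- qq
  out
}

# fine-grid trapezoid integration of the piecewise-linear trajectory
auc_grid_oracle <- function(day, pct, t = 21, step = 0.001) {
  g <- seq(0, t, by = step)
  v <- stats::approx(day, pct, xout = g)$y
  sum((v[-1] + v[-length(v)]) / 2) * step
}

# a random ETGT with plausible noisy-exponential shape (for property tests)
random_trajectory <- function(days = c(0, 4, 7, 11, 14, 18, 21)) {
  v0 <- stats::runif(1, 80, 300)
  g <- stats::rnorm(1, 0.06, 0.04)
  vol <- v0 * exp(g * days) * exp(stats::rnorm(length(days), 0, 0.1))
  list(day = days, volume = vol,
       pct = as.numeric(pct_delta_vol(days, vol)))
}

# random p-value matrix with occasional missing cells
random_p_matrix <- function(M = 5, L = 5, p_na = 0.1) {
  p <- matrix(stats::runif(M * L)^stats::runif(1, 1, 4), M, L,
              dimnames = list(paste0("m", 1:M), paste0("lab", 1:L)))
  p[stats::runif(M * L) < p_na] <- NA
  # keep at least one defined cell per column
  for (j in seq_len(L)) if (all(is.na(p[, j]))) p[1, j] <- stats::runif(1)
  p
}
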