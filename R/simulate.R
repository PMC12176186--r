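#' Simulate a multi-laboratory PDX trial with known ground truth
#'
#' Generates longitudinal tumor volumes for a control and a treated arm in
#' each of several labs under noisy exponential growth:
#' \deqn{Vol_i(t) = V_{0,i} \exp\{(g_i + \beta \cdot \mathrm{treated}_i)
#'   t\} \cdot \varepsilon_{i,t}}
#' with a lognormal baseline \eqn{V_{0,i}}, a per-mouse log-growth rate
#' \eqn{g_i \sim N(\mu_g, \sigma_g^2)}, a treatment shift \eqn{\beta} on
#' the log-growth rate (negative in the CR regime, 0 in the PD regime so
#' both arms share one generative law), and i.i.d. multiplicative
#' lognormal measurement noise \eqn{\varepsilon_{i,t}}. Volumes are
#' therefore always positive and every trajectory is anchored at day 0.
#'
#' Defaults emulate a typical five-lab breast-cancer PDX protocol:
#' measurement days \{0, 4, 7, 11, 14, 18, 21\}, ~150 mm^3 implant
#' baselines, control tumors roughly quintupling by day 21, and a CR-arm
#' net log-growth that is negative (tumor regression).
#'
#' @param regime \code{"CR"} (drug inhibits growth in the treated arm) or
#'   \code{"PD"} (no treatment effect; the null regime).
#' @param n_labs number of labs (default 5).
#' @param n_control,n_treated mice per arm per lab (default 5 each).
#' @param days measurement days, starting at 0 (default
#'   \code{c(0, 4, 7, 11, 14, 18, 21)}).
#' @param baseline_mean,baseline_cv mean (mm^3) and coefficient of
#'   variation of the day-0 volume (defaults 150 and 0.2).
#' @param growth_mean,growth_sd mean and between-mouse SD of the per-day
#'   control log-growth rate (defaults 0.08 and 0.015).
#' @param effect per-day shift of the treated arm's log-growth rate;
#'   default \code{-0.12} for CR and \code{0} for PD.
#' @param noise_sd SD of the log measurement noise (default 0.08).
#' @param dropout_day optional early-termination day, a scalar or one
#'   value per lab (\code{NA} = full protocol); measurements after that
#'   day are not recorded, emulating labs with shorter protocols.
#' @param tumor_model tumor-model identifier (default \code{"TM1"}).
#' @param seed optional integer seed.
#' @return a \code{pdx_trial} object.
#' @examples
#' trial <- simulate_pdx_trial("CR", n_labs = 2, seed = 1)
#' trial
#' @export
simulate_pdx_trial <- function(regime = c("CR", "PD"), n_labs = 5,
                               n_control = 5, n_treated = 5,
                               days = c(0, 4, 7, 11, 14, 18, 21),
                               baseline_mean = 150, baseline_cv = 0.2,
                               growth_mean = 0.08, growth_sd = 0.015,
                               effect = NULL, noise_sd = 0.08,
                               dropout_day = NULL, tumor_model = "TM1",
                               seed = NULL) {
  regime <- match.arg(regime)
  problems <- character()
  if (n_labs < 1 || n_control < 1 || n_treated < 1) {
    problems <- c(problems, "n_labs, n_control, n_treated must all be >= 1")
  }
  if (length(days) < 2 || days[1] != 0 || any(diff(days) <= 0)) {
    problems <- c(problems, "days must start at 0 and strictly increase")
  }
  if (noise_sd < 0 || growth_sd < 0 || baseline_cv < 0 || baseline_mean <= 0) {
    problems <- c(problems,
                  "noise_sd, growth_sd, baseline_cv must be >= 0 and baseline_mean > 0")
  }
  if (length(problems)) stop(paste(problems, collapse = "; "))
  if (is.null(effect)) effect <- if (regime == "CR") -0.12 else 0
  if (regime == "PD") effect <- 0
  if (!is.null(dropout_day) && length(dropout_day) == 1L) {
    dropout_day <- rep(dropout_day, n_labs)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  # lognormal baseline with the requested mean and CV
  sdlog <- sqrt(log(1 + baseline_cv^2))
  meanlog <- log(baseline_mean) - sdlog^2 / 2

  rows <- vector("list", n_labs * 2L)
  k <- 0L
  for (l in seq_len(n_labs)) {
    lab <- sprintf("Lab%d", l)
    lab_days <- days
    if (!is.null(dropout_day) && is.finite(dropout_day[l])) {
      lab_days <- days[days <= dropout_day[l]]
    }
    nd <- length(lab_days)
    for (grp in c("control", "treated")) {
      n <- if (grp == "control") n_control else n_treated
      g <- stats::rnorm(n, growth_mean, growth_sd) +
        if (grp == "treated") effect else 0
      v0 <- stats::rlnorm(n, meanlog, sdlog)
      noise <- exp(stats::rnorm(n * nd, 0, noise_sd))
      vol <- rep(v0, each = nd) * exp(rep(g, each = nd) * lab_days) * noise
      pct <- 100 * (vol / rep(vol[seq(1, n * nd, by = nd)], each = nd) - 1)
      pct[seq(1, n * nd, by = nd)] <- 0
      k <- k + 1L
      rows[[k]] <- data.frame(
        tumor_model = tumor_model, lab = lab, group = grp,
        mouse_id = rep(sprintf("%s_%s_%02d", lab, grp, seq_len(n)), each = nd),
        day = rep(lab_days, n), volume = vol, pct_delta_vol = pct,
        stringsAsFactors = FALSE)
    }
  }
  trial <- new_pdx_trial(do.call(rbind, rows),
                         labs = sprintf("Lab%d", seq_len(n_labs)))
  trial$regime <- regime
  trial
}
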