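table1 <- function() {
  trial <- worked_example_trial()
  list(day = trial$data$day, pct = trial$data$pct_delta_vol)
}

test_that("the five measures reproduce the worked-example mouse", {
  tr <- table1()
  expect_equal(round(measure_dtv(tr$day, tr$pct), 2), 405.62)
  # trapezoid area agrees with fine-grid numeric integration of the
  # piecewise-linear trajectory
  auc <- measure_auc(tr$day, tr$pct)
  expect_equal(auc, auc_grid_oracle(tr$day, tr$pct), tolerance = 1e-6)
  expect_equal(round(auc, 1), 3288.7, tolerance = 1e-3)
  # normalized by the number of measurement days (7 here)
  expect_equal(measure_aucmax(tr$day, tr$pct), auc / 7)
  expect_equal(measure_tgi(tr$day, tr$pct), log(405.62 / 100 + 1),
               tolerance = 1e-4)
  # 367.24 <= 400 at day 18 but 405.62 > 400 at day 21: event on day 21
  ev <- pfs_event(tr$day, tr$pct, delta = 4)
  expect_equal(ev$day, 21)
  expect_equal(ev$event, 1L)
})

test_that("flat and short trajectories hit the documented edge cases", {
  day <- c(0, 4, 7, 11, 14, 18, 21)
  flat <- rep(0, 7)
  expect_equal(measure_dtv(day, flat), 0)
  expect_equal(measure_auc(day, flat), 0)
  expect_equal(measure_aucmax(day, flat), 0)
  expect_equal(measure_tgi(day, flat), 0)
  expect_equal(pfs_event(day, flat, delta = 4)$event, 0L)
  expect_equal(pfs_event(day, flat, delta = 4)$day, 21)

  # ends before the day-21 horizon: day-21 measures undefined, AUCmax not
  short <- day[day <= 18]
  pct <- seq(0, 180, length.out = length(short))
  expect_true(is.na(measure_dtv(short, pct)))
  expect_true(is.na(measure_auc(short, pct)))
  expect_true(is.na(measure_tgi(short, pct)))
  expect_false(is.na(measure_aucmax(short, pct)))
  # survival below 10 days: AUCmax undefined too
  expect_true(is.na(measure_aucmax(c(0, 4, 7), c(0, 10, 30))))
  # censoring at the last observed day for early-terminated mice
  ev <- pfs_event(c(0, 4, 7, 11, 14), c(0, 10, 30, 60, 90), delta = 4)
  expect_equal(ev$day, 14)
  expect_equal(ev$event, 0L)
})

test_that("single-trapezoid and interpolated-horizon values follow the geometry", {
  expect_equal(measure_auc(c(0, 21), c(0, 100)), 0.5 * 21 * 100)
  # day 21 not measured, flanked by 20 and 22: linear interpolation
  expect_equal(measure_dtv(c(0, 20, 22), c(0, 100, 120)), 110)
  expect_equal(measure_auc(c(0, 20, 22), c(0, 100, 120)),
               auc_grid_oracle(c(0, 20, 22), c(0, 100, 120)),
               tolerance = 1e-6)
  # points beyond day 21 are dropped before AUCmax (TotalDays recounted)
  expect_equal(measure_aucmax(c(0, 7, 14, 21, 28), c(0, 50, 100, 150, 200)),
               measure_aucmax(c(0, 7, 14, 21), c(0, 50, 100, 150)))
})

test_that("trapezoid area is additive over a split at an existing day", {
  set.seed(7)
  for (i in 1:20) {
    tr <- random_trajectory()
    cut <- sample(tr$day[tr$day > 0 & tr$day < 21], 1)
    left <- tr$day <= cut
    right <- tr$day >= cut
    whole <- measure_auc(tr$day, tr$pct, t = 21)
    a <- measure_auc(tr$day[left], tr$pct[left], t = cut)
    # shift the right piece to start at 0 so the helper accepts it
    b <- measure_auc(tr$day[right] - cut, tr$pct[right], t = 21 - cut)
    expect_equal(whole, a + b, tolerance = 1e-9)
  }
})

test_that("per-lab tests match their references and handle degeneracy", {
  # identical per-mouse values in both arms: Welch t = 0, p = 1
  df <- do.call(rbind, lapply(c("c1", "c2", "c3", "t1", "t2", "t3"), function(m) {
    data.frame(tumor_model = "T", lab = "L",
               group = if (grepl("^c", m)) "control" else "treated",
               mouse_id = m, day = c(0, 11, 21),
               volume = c(100, 150, 220))
  }))
  trial <- as_pdx_trial(df)
  mp <- measure_pvalues(trial)
  expect_equal(mp$p_value[mp$measure %in% c("DTV", "AUC", "AUCMAX", "TGI")],
               rep(1, 4))
  # 120% growth never exceeds 400%: no events, log-rank undefined with note
  pfs <- mp[mp$measure == "PFS", ]
  expect_true(is.na(pfs$p_value))
  expect_match(pfs$note, "no progression events")
})

test_that("two-sided p-values are invariant to swapping the arm labels", {
  trial <- simulate_pdx_trial("CR", n_labs = 1, seed = 23)
  flipped <- trial
  flipped$data$group <- ifelse(trial$data$group == "control",
                               "treated", "control")
  flipped$mice$group <- ifelse(trial$mice$group == "control",
                               "treated", "control")
  p1 <- measure_pvalues(trial)$p_value
  p2 <- measure_pvalues(flipped)$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("the TGI regression p-value equals the pooled-variance t-test on log ratios", {
  set.seed(41)
  for (i in 1:10) {
    trial <- simulate_pdx_trial("CR", n_labs = 1, n_control = 6,
                                n_treated = 7)
    mm <- mouse_measures(trial)
    ols_p <- measure_pvalues(trial, measures = "TGI")$p_value
    tt <- t.test(mm$tgi[mm$group == "control"], mm$tgi[mm$group == "treated"],
                 var.equal = TRUE)
    expect_equal(ols_p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("arms with fewer than two usable mice yield a missing p-value and a note", {
  df <- data.frame(tumor_model = "T", lab = "L",
                   group = c(rep("control", 2), rep("treated", 6)),
                   mouse_id = rep(c("c1", "t1", "t2", "t3"), each = 2),
                   day = rep(c(0, 21), 4),
                   volume = c(100, 400, 100, 150, 110, 160, 90, 140))
  trial <- as_pdx_trial(df)  # one control mouse only
  mp <- measure_pvalues(trial, measures = "DTV")
  expect_true(is.na(mp$p_value))
  expect_match(mp$note, "fewer than 2")
  expect_equal(mp$n_control, 1L)
})

test_that("a 14-day protocol lab loses the day-21 measures but keeps AUCmax and PFS", {
  trial <- simulate_pdx_trial("PD", n_labs = 2, dropout_day = c(NA, 14),
                              seed = 9)
  mp <- measure_pvalues(trial)
  short <- mp[mp$lab == "Lab2", ]
  expect_true(all(is.na(short$p_value[short$measure %in%
                                        c("DTV", "AUC", "TGI")])))
  expect_false(is.na(short$p_value[short$measure == "AUCMAX"]))
  full <- mp[mp$lab == "Lab1", ]
  expect_true(all(!is.na(full$p_value)))
})

test_that("measure p-values are approximately uniform under the null", {
  # both arms drawn from one generative regime; fraction of p below alpha
  # must sit within 3 binomial SDs of alpha for each measure
  set.seed(1203)
  n_rep <- 2000
  ps <- matrix(NA_real_, n_rep, 5,
               dimnames = list(NULL, c("DTV", "AUC", "AUCMAX", "TGI", "PFS")))
  for (i in seq_len(n_rep)) {
    tr <- simulate_pdx_trial("PD", n_labs = 1, n_control = 8, n_treated = 8)
    mp <- measure_pvalues(tr)
    ps[i, mp$measure] <- mp$p_value
  }
  for (alpha in c(0.1, 0.05, 0.01)) {
    frac <- colMeans(ps <= alpha, na.rm = TRUE)
    band <- 3 * sqrt(alpha * (1 - alpha) / n_rep)
    expect_true(all(abs(frac - alpha) <= band),
                info = sprintf("alpha %.2f: %s", alpha,
                               paste(round(frac, 4), collapse = " ")))
  }
})
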