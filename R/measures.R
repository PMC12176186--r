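#' @name growth-measures
#' @title Per-mouse tumor growth measures
#'
#' @description Five scalar summaries of one empirical tumor growth
#' trajectory (ETGT), each taking the ordered measurement days and the
#' percent volume changes of a single mouse:
#' \describe{
#'   \item{\code{measure_dtv}}{DTV_t: the percent volume change at the
#'     horizon day \code{t} (default 21). If day \code{t} itself was not
#'     measured but flanking days were, the value is linearly interpolated;
#'     a trajectory ending before \code{t} yields \code{NA} (the mouse is
#'     excluded for this measure).}
#'   \item{\code{measure_auc}}{AUC_t: the trapezoid area under the
#'     piecewise-linear ETGT from day 0 to the horizon.}
#'   \item{\code{measure_aucmax}}{AUCmax: the trapezoid area over the whole
#'     trajectory truncated at day \code{t_max} (default 21), divided by
#'     the number of retained measurement days (TotalDays). Requires a
#'     minimum survival of \code{min_days} (default 10) days.}
#'   \item{\code{measure_tgi}}{TGI_t: the log tumor-growth ratio
#'     \code{ln(pct/100 + 1)} at the horizon, the response modelled by the
#'     treatment-indicator regression.}
#'   \item{\code{pfs_event}}{PFS_delta: time to progression, defined as the
#'     first measured day at which the percent change strictly exceeds
#'     \code{delta * 100}; mice that never progress by day \code{t} are
#'     right-censored (at day \code{t}, or at their last observed day for
#'     early-terminated protocols).}
#' }
#'
#' @param day numeric vector of measurement days, strictly increasing,
#'   starting at 0.
#' @param pct numeric vector of percent volume changes, same length.
#' @param t horizon day, default 21.
#' @param t_max truncation day for AUCmax, default 21.
#' @param min_days minimum survival (last observed day) for AUCmax,
#'   default 10.
#' @param delta fold-increase threshold for progression, default 4.
#' @return a scalar (\code{NA} when the measure is undefined for the
#'   mouse); \code{pfs_event} returns a list with \code{day} and
#'   \code{event} (1 = progressed, 0 = right-censored).
NULL

# value of the piecewise-linear ETGT at day t; NA when trajectory stops short
pct_at <- function(day, pct, t) {
  if (max(day) < t) return(NA_real_)
  if (t %in% day) return(pct[match(t, day)])
  stats::approx(day, pct, xout = t)$y
}

# trapezoid area of the ordered polyline
trapezoid_area <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  sum(0.5 * diff(x) * (y[-n] + y[-1]))
}

#' @rdname growth-measures
#' @export
measure_dtv <- function(day, pct, t = 21) {
  pct_at(day, pct, t)
}

#' @rdname growth-measures
#' @export
measure_auc <- function(day, pct, t = 21) {
  if (max(day) < t) return(NA_real_)
  keep <- day <= t
  d <- day[keep]; p <- pct[keep]
  if (max(day) > t && !(t %in% day)) {
    d <- c(d, t); p <- c(p, pct_at(day, pct, t))
  }
  if (length(d) < 2L) return(NA_real_)
  trapezoid_area(d, p)
}

#' @rdname growth-measures
#' @export
measure_aucmax <- function(day, pct, t_max = 21, min_days = 10) {
  keep <- day <= t_max
  d <- day[keep]; p <- pct[keep]
  if (length(d) < 2L || max(d) < min_days) return(NA_real_)
  trapezoid_area(d, p) / length(d)
}

#' @rdname growth-measures
#' @export
measure_tgi <- function(day, pct, t = 21) {
  v <- pct_at(day, pct, t)
  if (is.na(v)) return(NA_real_)
  r <- v / 100 + 1
  if (r <= 0) return(NA_real_)  # total regression to zero volume; logged upstream
  log(r)
}

#' @rdname growth-measures
#' @export
pfs_event <- function(day, pct, t = 21, delta = 4) {
  keep <- day <= t
  d <- day[keep]; p <- pct[keep]
  hit <- which(p > delta * 100)
  if (length(hit)) {
    list(day = d[hit[1]], event = 1L)
  } else {
    list(day = min(max(d), t), event = 0L)
  }
}

#' Per-mouse measure values for a whole trial
#'
#' Evaluates all five growth measures for every trajectory in a trial.
#'
#' @param trial a \code{pdx_trial} object.
#' @param t horizon day (default 21).
#' @param delta progression fold-increase threshold (default 4).
#' @param min_days minimum survival for AUCmax (default 10).
#' @return data.frame with one row per mouse: identifiers, \code{dtv},
#'   \code{auc}, \code{aucmax}, \code{tgi}, \code{pfs_day},
#'   \code{pfs_event}. \code{NA} measure values mark mice excluded for
#'   that measure (e.g. trajectory ends before the horizon).
#' @export
mouse_measures <- function(trial, t = 21, delta = 4, min_days = 10) {
  stopifnot(inherits(trial, "pdx_trial"))
  d <- trial$data
  key <- paste(d$tumor_model, d$lab, d$group, d$mouse_id, sep = "\r")
  idx <- split(seq_len(nrow(d)), key)
  n <- length(idx)
  first <- vapply(idx, `[`, integer(1), 1L)
  dtv <- auc <- aucmax <- tgi <- pfs_day <- numeric(n)
  pfs_evt <- integer(n)
  for (i in seq_len(n)) {
    rows <- idx[[i]]
    day <- d$day[rows]
    pct <- d$pct_delta_vol[rows]
    dtv[i] <- measure_dtv(day, pct, t = t)
    auc[i] <- measure_auc(day, pct, t = t)
    aucmax[i] <- measure_aucmax(day, pct, t_max = t, min_days = min_days)
    tgi[i] <- measure_tgi(day, pct, t = t)
    ev <- pfs_event(day, pct, t = t, delta = delta)
    pfs_day[i] <- ev$day
    pfs_evt[i] <- ev$event
  }
  out <- data.frame(
    tumor_model = d$tumor_model[first], lab = d$lab[first],
    group = d$group[first], mouse_id = d$mouse_id[first],
    dtv = dtv, auc = auc, aucmax = aucmax, tgi = tgi,
    pfs_day = pfs_day, pfs_event = pfs_evt, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.measure_names <- c("DTV", "AUC", "AUCMAX", "TGI", "PFS")

# Welch two-sample two-sided p-value, with the degenerate constant-data
# case resolved analytically (t = 0 when the arm means agree).
welch_p <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

# two-sided p for H0: beta = 0 in OLS of value on treatment indicator
ols_treatment_p <- function(value, treated) {
  if (sum(treated == 0) < 2L || sum(treated == 1) < 2L) return(NA_real_)
  if (stats::sd(value) == 0) return(1)
  fit <- stats::lm(value ~ treated)
  cf <- stats::coef(summary(fit))
  if (nrow(cf) < 2L || !is.finite(cf[2L, 4L])) {
    # perfect separation of a two-level factor with zero residual variance
    return(0)
  }
  cf[2L, 4L]
}

# log-rank chi-square (1 df) p-value, no continuity correction
logrank_p <- function(time, event, treated) {
  if (!length(unique(treated)) == 2L) return(NA_real_)
  if (sum(event) == 0L) return(NA_real_)  # no progression events at all
  fit <- tryCatch(
    survival::survdiff(survival::Surv(time, event) ~ treated),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$chisq)) return(NA_real_)
  stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE)
}

#' Per-(measure, lab) test statistics and p-values
#'
#' For each lab and measure, compares the control and treated arms:
#' two-sided Welch two-sample t-tests on the per-mouse DTV, AUC and AUCmax
#' values; the F-test (equivalent to the pooled t-test) for the treatment
#' coefficient in the OLS regression of the log growth ratio (TGI) on the
#' treatment indicator; and the log-rank test on the two arms'
#' progression-free survival.
#'
#' @inheritParams mouse_measures
#' @param measures subset of \code{c("DTV","AUC","AUCMAX","TGI","PFS")}.
#' @param tumor_model optional tumor model to restrict to (default: all
#'   pooled; trials in this framework carry one tumor model at a time).
#' @return data.frame with one row per (measure, lab):
#'   \code{measure}, \code{lab}, \code{statistic_value} (mean difference
#'   control minus treated for the Welch measures, the fitted treatment
#'   coefficient for TGI, the log-rank chi-square for PFS), \code{p_value}
#'   (\code{NA} when undefined), \code{n_control}, \code{n_treated}
#'   (usable mice) and \code{note} (why a p-value is missing).
#' @export
measure_pvalues <- function(trial, t = 21, delta = 4, min_days = 10,
                            measures = .measure_names, tumor_model = NULL) {
  stopifnot(inherits(trial, "pdx_trial"))
  measures <- match.arg(measures, .measure_names, several.ok = TRUE)
  mm <- mouse_measures(trial, t = t, delta = delta, min_days = min_days)
  if (!is.null(tumor_model)) mm <- mm[mm$tumor_model %in% tumor_model, ]
  out <- list()
  for (l in trial$labs) {
    d <- mm[mm$lab == l, , drop = FALSE]
    for (m in measures) {
      row <- .one_measure_p(d, m)
      row$measure <- m
      row$lab <- l
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE))
  res[, c("measure", "lab", "statistic_value", "p_value",
          "n_control", "n_treated", "note")]
}

.one_measure_p <- function(d, measure) {
  ctrl <- d[d$group == "control", , drop = FALSE]
  trt <- d[d$group == "treated", , drop = FALSE]
  note <- ""
  if (measure %in% c("DTV", "AUC", "AUCMAX")) {
    col <- c(DTV = "dtv", AUC = "auc", AUCMAX = "aucmax")[[measure]]
    x <- ctrl[[col]][!is.na(ctrl[[col]])]
    y <- trt[[col]][!is.na(trt[[col]])]
    stat <- if (length(x) && length(y)) mean(x) - mean(y) else NA_real_
    p <- welch_p(x, y)
    if (is.na(p)) note <- "fewer than 2 usable mice in an arm"
    list(statistic_value = stat, p_value = p,
         n_control = length(x), n_treated = length(y), note = note)
  } else if (measure == "TGI") {
    ok <- !is.na(d$tgi)
    value <- d$tgi[ok]
    treated <- as.integer(d$group[ok] == "treated")
    p <- ols_treatment_p(value, treated)
    stat <- if (sum(treated == 0) && sum(treated == 1)) {
      mean(value[treated == 1]) - mean(value[treated == 0])
    } else NA_real_
    if (is.na(p)) note <- "fewer than 2 usable mice in an arm"
    list(statistic_value = stat, p_value = p,
         n_control = sum(treated == 0), n_treated = sum(treated == 1),
         note = note)
  } else if (measure == "PFS") {
    ok <- !is.na(d$pfs_day)
    time <- d$pfs_day[ok]; event <- d$pfs_event[ok]
    treated <- as.integer(d$group[ok] == "treated")
    if (!sum(treated == 0) || !sum(treated == 1)) {
      list(statistic_value = NA_real_, p_value = NA_real_,
           n_control = sum(treated == 0), n_treated = sum(treated == 1),
           note = "an arm has no usable mice")
    } else if (sum(event) == 0L) {
      list(statistic_value = NA_real_, p_value = NA_real_,
           n_control = sum(treated == 0), n_treated = sum(treated == 1),
           note = "no progression events in either arm")
    } else {
      fit <- tryCatch(
        survival::survdiff(survival::Surv(time, event) ~ treated),
        error = function(e) NULL)
      degenerate <- is.null(fit) || !is.finite(fit$chisq)
      if (degenerate) {
        # zero-variance log-rank (e.g. every mouse progresses on the same
        # day): when the two arms share one event table the statistic is 0
        tab0 <- sort(paste(time[treated == 0], event[treated == 0]))
        tab1 <- sort(paste(time[treated == 1], event[treated == 1]))
        if (identical(tab0, tab1)) {
          fit <- list(chisq = 0)
          degenerate <- FALSE
        }
      }
      if (degenerate) {
        list(statistic_value = NA_real_, p_value = NA_real_,
             n_control = sum(treated == 0), n_treated = sum(treated == 1),
             note = "log-rank statistic undefined")
      } else {
        list(statistic_value = fit$chisq,
             p_value = stats::pchisq(fit$chisq, 1, lower.tail = FALSE),
             n_control = sum(treated == 0), n_treated = sum(treated == 1),
             note = "")
      }
    }
  } else {
    stop("unknown measure: ", measure)
  }
}
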