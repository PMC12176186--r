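#' Multi-measure, multi-laboratory drug-screening analysis
#'
#' End-to-end evaluation of a PDX trial: computes the five per-mouse
#' growth measures and their two-arm tests for every lab, assembles the
#' basis table (lab p-values, Fisher's-method column, Storey q-values),
#' applies the four screening decision rules (SMSL, SMNL, NMSL, NMNL) at
#' each significance level, scores them against the ground-truth
#' classification, and (optionally) estimates the sampling distribution
#' of sensitivity/specificity/accuracy by stratified bootstrap.
#'
#' @param trial a \code{pdx_trial} object (see
#'   \code{\link{read_trial_table}}, \code{\link{as_pdx_trial}} or
#'   \code{\link{simulate_pdx_trial}}).
#' @param ground_truth a single \code{"CR"}/\code{"PD"} label, or a named
#'   per-lab vector for heterogeneous trials.
#' @param alphas significance levels (default
#'   \code{c(0.1, 0.05, 0.01, 0.001)}).
#' @param t horizon day for the day-t measures (default 21).
#' @param delta progression fold-increase threshold (default 4).
#' @param min_days minimum survival for AUCmax (default 10).
#' @param n_boot bootstrap resamples; 0 (default) skips the bootstrap.
#' @param seed integer seed for the bootstrap streams.
#' @param keep_samples retain the per-resample metric draws (see
#'   \code{\link{bootstrap_screen}}).
#' @return an object of class \code{pdx_screen}: a list with
#'   \code{basis} (the \code{pdx_basis}), \code{screen} (point-estimate
#'   metrics per test and alpha), \code{boot} (bootstrap summary or
#'   \code{NULL}), \code{ground_truth} and the call parameters.
#' @examples
#' trial <- simulate_pdx_trial("CR", n_labs = 3, seed = 7)
#' fit <- pdx_screen(trial, ground_truth = "CR")
#' fit
#' @export
pdx_screen <- function(trial, ground_truth,
                       alphas = c(0.1, 0.05, 0.01, 0.001),
                       t = 21, delta = 4, min_days = 10,
                       n_boot = 0, seed = NULL, keep_samples = FALSE) {
  stopifnot(inherits(trial, "pdx_trial"))
  gt <- resolve_ground_truth(ground_truth, trial$labs)
  basis <- basis_table(trial, t = t, delta = delta, min_days = min_days)
  screen <- screen_basis(basis, gt, alphas = alphas)
  boot <- NULL
  if (n_boot > 0) {
    boot <- bootstrap_screen(trial, gt, n_resamples = n_boot,
                             alphas = alphas, t = t, delta = delta,
                             min_days = min_days, seed = seed,
                             keep_samples = keep_samples)
  }
  structure(
    list(basis = basis, screen = screen, boot = boot,
         ground_truth = gt, alphas = alphas,
         params = list(t = t, delta = delta, min_days = min_days,
                       n_boot = n_boot, seed = seed),
         call = match.call()),
    class = "pdx_screen")
}

#' @export
print.pdx_screen <- function(x, ...) {
  cat("PDX drug-screening analysis\n")
  cat("ground truth:",
      paste(sprintf("%s=%s", names(x$ground_truth), x$ground_truth),
            collapse = " "), "\n")
  cat("basis table:", length(x$basis$measures), "measures x",
      length(x$basis$labs), "labs (+ Fisher column)\n\n")
  df <- x$screen[, c("test", "alpha", "n_calls", "n_cr",
                     "sensitivity", "specificity", "accuracy")]
  print(df, row.names = FALSE, digits = 3)
  if (!is.null(x$boot)) {
    cat(sprintf("\nbootstrap: %d resamples (seed %s); see summary() for CIs\n",
                x$params$n_boot, format(x$params$seed)))
  }
  invisible(x)
}

#' @export
summary.pdx_screen <- function(object, ...) {
  out <- list(basis = object$basis, screen = object$screen,
              boot = object$boot, ground_truth = object$ground_truth)
  class(out) <- "summary.pdx_screen"
  out
}

#' @export
print.summary.pdx_screen <- function(x, ...) {
  print(x$basis)
  cat("\nPoint-estimate screening metrics:\n")
  print(x$screen, row.names = FALSE, digits = 3)
  if (!is.null(x$boot)) {
    cat("\nBootstrap medians and percentile 95% CIs:\n")
    print(x$boot, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Plot screening-test performance
#'
#' Grouped bar chart of a metric per screening test across significance
#' levels; with a bootstrap summary available, medians are plotted with
#' their percentile 95\% confidence intervals as vertical segments.
#'
#' @param x a \code{pdx_screen} object.
#' @param metric one of \code{"sensitivity"}, \code{"specificity"},
#'   \code{"accuracy"}.
#' @param ... passed to \code{\link[graphics]{barplot}}.
#' @export
plot.pdx_screen <- function(x, metric = c("sensitivity", "specificity",
                                          "accuracy"), ...) {
  metric <- match.arg(metric)
  tests <- unique(x$screen$test)
  alphas <- x$alphas
  if (!is.null(x$boot)) {
    d <- x$boot[x$boot$metric == metric, ]
    h <- matrix(d$median[order(match(d$test, tests), match(d$alpha, alphas))],
                nrow = length(tests), dimnames = list(tests, alphas))
    lcl <- matrix(d$lcl[order(match(d$test, tests), match(d$alpha, alphas))],
                  nrow = length(tests))
    ucl <- matrix(d$ucl[order(match(d$test, tests), match(d$alpha, alphas))],
                  nrow = length(tests))
  } else {
    d <- x$screen
    h <- matrix(d[[metric]][order(match(d$test, tests), match(d$alpha, alphas))],
                nrow = length(tests), dimnames = list(tests, alphas))
    lcl <- ucl <- NULL
  }
  mid <- graphics::barplot(h, beside = TRUE, ylim = c(0, 1.05),
                           legend.text = tests,
                           xlab = "significance level", ylab = metric,
                           args.legend = list(x = "bottomright", bty = "n"),
                           ...)
  if (!is.null(lcl)) {
    graphics::segments(mid, lcl, mid, ucl)
  }
  invisible(x)
}

#' Printed basis tables bundled with the package
#'
#' Loads one of the transcribed published basis tables shipped under
#' \code{inst/extdata}: p-values (and, for reference, the q-values as
#' printed) from a five-laboratory breast-cancer PDX drug trial.
#' \describe{
#'   \item{\code{"cr_multilab"}}{completely responsive tumor model, five
#'     named labs.}
#'   \item{\code{"pd_multilab"}}{progressive-disease tumor model, same
#'     labs; the 14-day lab has missing day-21 measures.}
#'   \item{\code{"cr_simlabs"}}{responsive tumor models in five simulated
#'     labs drawn from a single-source screen.}
#' }
#'
#' @param name which table to load.
#' @return a list with \code{basis} (a \code{pdx_basis} recomputed from
#'   the printed p-values) and \code{printed_q} (the q-value grid as
#'   printed, measures x labs + Fisher).
#' @export
example_basis <- function(name = c("cr_multilab", "pd_multilab",
                                   "cr_simlabs")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("basis_", name, ".csv"),
                      package = "pdxscreen", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  labs <- unique(df$lab[df$lab != "Fisher"])
  measures <- unique(df$measure)
  p <- matrix(NA_real_, length(measures), length(labs),
              dimnames = list(measures, labs))
  qprint <- matrix(NA_real_, length(measures), length(labs) + 1L,
                   dimnames = list(measures, c(labs, "Fisher")))
  for (i in seq_len(nrow(df))) {
    if (df$lab[i] != "Fisher") p[df$measure[i], df$lab[i]] <- df$p_value[i]
    qprint[df$measure[i], df$lab[i]] <- df$q_value[i]
  }
  list(basis = as_pdx_basis(p), printed_q = qprint,
       printed_p_fisher = {
         pf <- df$p_value[df$lab == "Fisher"]
         names(pf) <- df$measure[df$lab == "Fisher"]
         pf[measures]
       })
}
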