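#' Stratified bootstrap resample of a trial's mice
#'
#' Resamples mice with replacement independently within every
#' (tumor model, lab, group) stratum, keeping each drawn mouse's full
#' trajectory. Resampled mice receive fresh unique IDs; the original ID is
#' retained in a \code{source_mouse} column for provenance.
#'
#' Uses the current RNG state; seed the session (or use
#' \code{\link{bootstrap_screen}}, which manages per-resample streams) for
#' reproducibility.
#'
#' @param trial a \code{pdx_trial} object.
#' @return a new \code{pdx_trial} of the same stratum sizes.
#' @export
stratified_resample <- function(trial) {
  stopifnot(inherits(trial, "pdx_trial"))
  mice <- trial$mice
  strata <- split(seq_len(nrow(mice)),
                  mice[c("tumor_model", "lab", "group")], drop = TRUE)
  if (!length(strata)) stop("trial has no strata to resample")
  d <- trial$data
  mouse_key <- paste(d$tumor_model, d$lab, d$group, d$mouse_id, sep = "\r")
  row_idx <- split(seq_len(nrow(d)), mouse_key)
  key_of <- paste(mice$tumor_model, mice$lab, mice$group, mice$mouse_id,
                  sep = "\r")
  drawn <- unlist(lapply(strata, function(idx) {
    idx[sample.int(length(idx), length(idx), replace = TRUE)]
  }), use.names = FALSE)
  pieces <- row_idx[match(key_of[drawn], names(row_idx))]
  lens <- lengths(pieces)
  data <- d[unlist(pieces, use.names = FALSE), , drop = FALSE]
  data$source_mouse <- data$mouse_id
  data$mouse_id <- rep(sprintf("b%05d", seq_along(drawn)), lens)
  rownames(data) <- NULL
  new_pdx_trial(data, labs = trial$labs,
                log = "stratified bootstrap resample")
}

#' Bootstrap distributions of screening-test performance
#'
#' Draws stratified bootstrap resamples of the trial's mice, rebuilds the
#' basis table for every resample, applies all four screening tests at
#' each significance level, scores them against the ground truth, and
#' summarizes each metric by its median and percentile 95\% confidence
#' interval (2.5th and 97.5th percentiles, linearly interpolated order
#' statistics). Resamples in which a metric is undefined (zero
#' denominator) contribute a missing value, are excluded from the
#' percentiles, and are counted in \code{n_missing}.
#'
#' Reproducibility: the master \code{seed} draws one sub-seed per
#' resample, so summaries are bit-identical for identical seeds and
#' invariant to the order in which resamples are evaluated.
#'
#' @inheritParams screen_basis
#' @param trial a \code{pdx_trial} object.
#' @param n_resamples number of bootstrap resamples (the reference
#'   analysis uses 10000; smaller values trade precision for speed).
#' @param t,delta,min_days measure parameters, see
#'   \code{\link{mouse_measures}}.
#' @param seed integer seed for the resampling streams.
#' @param metrics which of \code{"sensitivity"}, \code{"specificity"},
#'   \code{"accuracy"} to summarize.
#' @param keep_samples if \code{TRUE}, the per-resample metric draws are
#'   attached as attribute \code{"samples"} (a data.frame with one row per
#'   (resample, test, alpha)).
#' @param resample set \code{FALSE} to disable resampling (identity mode,
#'   a diagnostic: every "resample" is the original data, so the summary
#'   collapses onto the point estimate with zero CI length).
#' @return data.frame with one row per (test, alpha, metric):
#'   \code{median}, \code{lcl}, \code{ucl} (percentile 95\% CI),
#'   \code{ci_length} and \code{n_missing}.
#' @export
bootstrap_screen <- function(trial, ground_truth, n_resamples = 10000,
                             alphas = c(0.1, 0.05, 0.01, 0.001),
                             t = 21, delta = 4, min_days = 10,
                             seed = NULL,
                             metrics = c("sensitivity", "specificity",
                                         "accuracy"),
                             keep_samples = FALSE, resample = TRUE) {
  stopifnot(inherits(trial, "pdx_trial"), n_resamples >= 1)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, n_resamples)
  draws <- vector("list", n_resamples)
  for (b in seq_len(n_resamples)) {
    set.seed(sub_seeds[b])
    rs <- if (resample) stratified_resample(trial) else trial
    bt <- basis_table(rs, t = t, delta = delta, min_days = min_days)
    sc <- screen_basis(bt, ground_truth, alphas = alphas)
    sc$resample <- b
    draws[[b]] <- sc[, c("resample", "test", "alpha", metrics)]
  }
  samples <- do.call(rbind, draws)
  rownames(samples) <- NULL

  out <- list()
  for (tst in unique(samples$test)) {
    for (a in alphas) {
      sub <- samples[samples$test == tst & samples$alpha == a, , drop = FALSE]
      for (met in metrics) {
        v <- sub[[met]]
        n_missing <- sum(is.na(v))
        v <- v[!is.na(v)]
        if (length(v)) {
          qs <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE,
                                type = 7)
        } else {
          qs <- rep(NA_real_, 3)
        }
        out[[length(out) + 1L]] <- data.frame(
          test = tst, alpha = a, metric = met,
          median = qs[2], lcl = qs[1], ucl = qs[3],
          ci_length = qs[3] - qs[1], n_missing = n_missing,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (keep_samples) attr(res, "samples") <- samples
  res
}
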