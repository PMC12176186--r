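.screen_tests <- c("SMSL", "SMNL", "NMSL", "NMNL")

#' Apply one drug-screening decision rule to a basis table
#'
#' The four rules read different blocks of the basis table. At
#' significance level \code{alpha} a value at or below \code{alpha} calls
#' the tumor type completely responsive (CR), otherwise progressive
#' disease (PD):
#' \describe{
#'   \item{SMSL}{one call per non-missing (measure, lab) p-value.}
#'   \item{SMNL}{one call per measure from its Fisher's-method combined
#'     p-value.}
#'   \item{NMSL}{one call per lab: CR when at least one of that lab's M
#'     q-values is at or below \code{alpha}.}
#'   \item{NMNL}{a single trial-wide call: CR when at least one q-value of
#'     the Fisher column is at or below \code{alpha}.}
#' }
#' Missing cells are excluded and shrink the denominator.
#'
#' @param basis a \code{pdx_basis} object.
#' @param test one of \code{"SMSL"}, \code{"SMNL"}, \code{"NMSL"},
#'   \code{"NMNL"}.
#' @param alpha significance level in (0, 1).
#' @return data.frame of calls with columns \code{test}, \code{alpha},
#'   \code{measure}, \code{lab} (\code{NA} where the rule aggregates over
#'   that dimension) and \code{call} (\code{"CR"}/\code{"PD"}).
#' @export
screening_calls <- function(basis, test = .screen_tests, alpha) {
  stopifnot(inherits(basis, "pdx_basis"))
  test <- match.arg(test)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  labs <- basis$labs
  M <- length(basis$measures)
  p_lab <- basis$p[, labs, drop = FALSE]
  q_lab <- basis$q[, labs, drop = FALSE]
  rows <- switch(
    test,
    SMSL = {
      idx <- which(!is.na(p_lab), arr.ind = TRUE)
      if (!nrow(idx)) return(.empty_calls(test, alpha))
      data.frame(
        measure = rownames(p_lab)[idx[, 1]],
        lab = labs[idx[, 2]],
        call = ifelse(p_lab[idx] <= alpha, "CR", "PD"),
        stringsAsFactors = FALSE)
    },
    SMNL = {
      pf <- basis$p[, "Fisher"]
      ok <- !is.na(pf)
      data.frame(
        measure = basis$measures[ok], lab = NA_character_,
        call = ifelse(pf[ok] <= alpha, "CR", "PD"),
        stringsAsFactors = FALSE)
    },
    NMSL = {
      keep <- vapply(labs, function(l) any(!is.na(q_lab[, l])), logical(1))
      data.frame(
        measure = NA_character_, lab = labs[keep],
        call = vapply(labs[keep], function(l) {
          if (any(q_lab[, l] <= alpha, na.rm = TRUE)) "CR" else "PD"
        }, character(1)),
        stringsAsFactors = FALSE)
    },
    NMNL = {
      qf <- basis$q[, "Fisher"]
      if (all(is.na(qf))) return(.empty_calls(test, alpha))
      data.frame(
        measure = NA_character_, lab = NA_character_,
        call = if (any(qf <= alpha, na.rm = TRUE)) "CR" else "PD",
        stringsAsFactors = FALSE)
    })
  cbind(data.frame(test = test, alpha = alpha, stringsAsFactors = FALSE),
        rows, row.names = NULL)
}

.empty_calls <- function(test, alpha) {
  data.frame(test = character(), alpha = numeric(), measure = character(),
             lab = character(), call = character(), stringsAsFactors = FALSE)
}

# normalize a ground-truth spec into one label per lab
resolve_ground_truth <- function(ground_truth, labs) {
  if (is.null(ground_truth)) stop("ground truth labels are required")
  gt <- toupper(as.character(ground_truth))
  if (!all(gt %in% c("CR", "PD"))) stop("ground-truth labels must be 'CR' or 'PD'")
  if (length(ground_truth) == 1L && is.null(names(ground_truth))) {
    gt <- rep(gt, length(labs))
    names(gt) <- labs
    return(gt)
  }
  names(gt) <- names(ground_truth)
  miss <- setdiff(labs, names(gt))
  if (length(miss)) {
    stop("missing ground-truth label(s) for lab(s): ",
         paste(miss, collapse = ", "))
  }
  gt[labs]
}

#' Score screening calls against ground truth
#'
#' Compares CR/PD calls with the ground-truth classification. Lab-specific
#' rules (SMSL, NMSL) are scored cell-by-cell against each lab's label;
#' the lab-aggregating rules (SMNL, NMNL) test the null that the drug is
#' non-inhibitory for every lab, so their calls are scored against CR
#' whenever at least one lab's label is CR.
#'
#' @param calls data.frame from \code{\link{screening_calls}}.
#' @param ground_truth either a single \code{"CR"}/\code{"PD"} label for
#'   the whole trial or a named vector of per-lab labels.
#' @param labs lab identifiers of the basis table (used to validate the
#'   labels); defaults to the labs appearing in \code{calls}.
#' @return a list of class \code{pdx_confusion} with \code{TP}, \code{FN},
#'   \code{FP}, \code{TN}, \code{sensitivity}, \code{specificity},
#'   \code{accuracy} (ratios are \code{NA} when their denominator is 0)
#'   and \code{n} (number of scored calls).
#' @export
score_calls <- function(calls, ground_truth, labs = NULL) {
  if (is.null(labs)) labs <- unique(calls$lab[!is.na(calls$lab)])
  gt <- resolve_ground_truth(ground_truth, labs)
  truth <- ifelse(is.na(calls$lab),
                  if (any(gt == "CR")) "CR" else "PD",
                  gt[calls$lab])
  tp <- sum(truth == "CR" & calls$call == "CR")
  fn <- sum(truth == "CR" & calls$call == "PD")
  fp <- sum(truth == "PD" & calls$call == "CR")
  tn <- sum(truth == "PD" & calls$call == "PD")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(
    list(TP = tp, FN = fn, FP = fp, TN = tn,
         sensitivity = ratio(tp, tp + fn),
         specificity = ratio(tn, tn + fp),
         accuracy = ratio(tp + tn, tp + fn + fp + tn),
         n = nrow(calls)),
    class = "pdx_confusion")
}

#' @export
print.pdx_confusion <- function(x, ...) {
  cat(sprintf("TP %d  FN %d  FP %d  TN %d (n = %d)\n",
              x$TP, x$FN, x$FP, x$TN, x$n))
  cat(sprintf("sensitivity %.3f  specificity %.3f  accuracy %.3f\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Run all screening tests over a grid of significance levels
#'
#' @param basis a \code{pdx_basis} object.
#' @param ground_truth see \code{\link{score_calls}}.
#' @param alphas significance levels (default the four conventional
#'   screening levels 0.1, 0.05, 0.01, 0.001).
#' @param tests subset of the four decision rules.
#' @return data.frame with one row per (test, alpha): confusion counts,
#'   \code{n_calls}, \code{n_cr} (CR calls) and the three metrics.
#' @export
screen_basis <- function(basis, ground_truth,
                         alphas = c(0.1, 0.05, 0.01, 0.001),
                         tests = .screen_tests) {
  tests <- match.arg(tests, .screen_tests, several.ok = TRUE)
  out <- list()
  for (a in alphas) {
    for (tst in tests) {
      calls <- screening_calls(basis, tst, a)
      cc <- score_calls(calls, ground_truth, labs = basis$labs)
      out[[length(out) + 1L]] <- data.frame(
        test = tst, alpha = a,
        n_calls = cc$n, n_cr = cc$TP + cc$FP,
        TP = cc$TP, FN = cc$FN, FP = cc$FP, TN = cc$TN,
        sensitivity = cc$sensitivity, specificity = cc$specificity,
        accuracy = cc$accuracy, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
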