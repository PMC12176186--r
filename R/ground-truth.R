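#' Dual-ranking threshold selection of ground-truth labels
#'
#' When no external ground truth is known, tumor-model replicates can be
#' labelled by consensus of two growth summaries: all replicates are
#' ranked from largest to smallest on AUCmax and, independently, on the
#' day-21 percent volume change. A replicate in the top
#' \code{floor(fraction * N)} of \emph{both} rankings is labelled PD
#' (grew fastest under treatment); one in the bottom
#' \code{floor(fraction * N)} of both is labelled CR; all others remain
#' unclassified. Only ranks are used, so labels are invariant under any
#' strictly monotone transform of either summary.
#'
#' @param summaries data.frame with columns \code{tm_id}, \code{auc_max}
#'   and \code{dtv_21} (one row per tumor-model replicate).
#' @param fraction tail fraction per side, in (0, 0.5); default 0.20.
#' @return \code{summaries} with an added \code{label} column taking
#'   values \code{"CR"}, \code{"PD"} or \code{"unclassified"}. Ties at a
#'   cutoff are broken by the stable original row order.
#' @export
threshold_select <- function(summaries, fraction = 0.20) {
  stopifnot(is.data.frame(summaries),
            all(c("tm_id", "auc_max", "dtv_21") %in% names(summaries)))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 0.5) {
    stop("fraction must lie in (0, 0.5)")
  }
  n <- nrow(summaries)
  k <- floor(fraction * n)
  if (k < 1L) stop("too few summaries for the requested fraction")
  top <- function(v) {  # indices of the k largest, ties by original order
    utils::head(order(-v), k)
  }
  bottom <- function(v) utils::head(order(v), k)
  pd <- intersect(top(summaries$auc_max), top(summaries$dtv_21))
  cr <- intersect(bottom(summaries$auc_max), bottom(summaries$dtv_21))
  label <- rep("unclassified", n)
  label[pd] <- "PD"
  label[cr] <- "CR"
  summaries$label <- label
  summaries
}

#' Construct simulated laboratories from labelled mouse pools
#'
#' Emulates a multi-lab trial from a single-source data set: each
#' simulated lab draws, with replacement, \code{n_treated} mice from the
#' treated pool and \code{n_control} mice from the control pool (for a
#' PD-regime construction both pools come from non-responding mice). The
#' draws are independent across labs.
#'
#' @param pool_treated,pool_control \code{pdx_trial} objects whose mice
#'   form the treated and control pools; their original lab and group
#'   labels are discarded.
#' @param n_treated,n_control mice drawn per lab (defaults 12 and 11).
#' @param n_labs number of simulated labs (default 5).
#' @param tumor_model tumor-model identifier for the output (default
#'   taken from the treated pool).
#' @param seed optional integer seed.
#' @return a \code{pdx_trial} with labs \code{"Simulated Lab 1"} ...;
#'   drawn mice receive fresh IDs, with the original retained in
#'   \code{source_mouse}.
#' @export
build_simulated_labs <- function(pool_treated, pool_control,
                                 n_treated = 12, n_control = 11,
                                 n_labs = 5, tumor_model = NULL,
                                 seed = NULL) {
  stopifnot(inherits(pool_treated, "pdx_trial"),
            inherits(pool_control, "pdx_trial"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  t_etgts <- split_etgt(pool_treated)
  c_etgts <- split_etgt(pool_control)
  if (!length(t_etgts) || !length(c_etgts)) stop("empty mouse pool")
  if (is.null(tumor_model)) tumor_model <- pool_treated$data$tumor_model[1]
  pieces <- list()
  counter <- 0L
  for (l in seq_len(n_labs)) {
    lab <- sprintf("Simulated Lab %d", l)
    for (spec in list(list(pool = t_etgts, n = n_treated, group = "treated"),
                      list(pool = c_etgts, n = n_control, group = "control"))) {
      draw <- sample.int(length(spec$pool), spec$n, replace = TRUE)
      for (i in draw) {
        counter <- counter + 1L
        e <- spec$pool[[i]]
        e$source_mouse <- e$mouse_id
        e$mouse_id <- sprintf("s%05d", counter)
        e$lab <- lab
        e$group <- spec$group
        e$tumor_model <- tumor_model
        pieces[[counter]] <- e
      }
    }
  }
  data <- do.call(rbind, pieces)
  rownames(data) <- NULL
  mice <- unique(data[, c("tumor_model", "lab", "group", "mouse_id")])
  rownames(mice) <- NULL
  structure(
    list(data = data, labs = sprintf("Simulated Lab %d", seq_len(n_labs)),
         mice = mice, log = "simulated labs drawn from mouse pools"),
    class = "pdx_trial")
}

#' Splice a mixed basis table from per-lab sources
#'
#' Builds a heterogeneous-ground-truth basis table by taking each lab's
#' p-value column from a designated source table (e.g. one lab from a
#' responsive trial, another from a progressive one), then recomputing the
#' Fisher's-method column and all q-value columns on the spliced grid.
#'
#' @param sources named list of \code{pdx_basis} objects; names are the
#'   lab identifiers of the new table, and each element must contain a
#'   column for that lab. All sources must share the same measure rows.
#' @return a \code{pdx_basis} over the named labs.
#' @export
splice_basis <- function(sources) {
  stopifnot(is.list(sources), length(sources) >= 1, !is.null(names(sources)))
  measures <- sources[[1]]$measures
  p <- sapply(names(sources), function(l) {
    b <- sources[[l]]
    stopifnot(inherits(b, "pdx_basis"))
    if (!identical(b$measures, measures)) {
      stop("all source tables must share the same measures")
    }
    if (!l %in% b$labs) stop("source table for '", l, "' lacks that lab")
    b$p[, l]
  })
  rownames(p) <- measures
  as_pdx_basis(p)
}
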