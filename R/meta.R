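#' Fisher's method for combining laboratory p-values
#'
#' Combines independent p-values for one measure across labs:
#' \code{X2 = -2 * sum(log(p))} is referred to a chi-square distribution
#' with \code{2 * L'} degrees of freedom, where \code{L'} is the number of
#' non-missing p-values (missing labs shrink the degrees of freedom). The
#' upper tail is evaluated in log space so that extremely small combined
#' p-values do not underflow prematurely.
#'
#' @param p numeric vector of p-values in [0, 1]; \code{NA} entries are
#'   dropped.
#' @return the combined p-value; \code{NA} if every entry is missing.
#'   A zero input yields a combined p of 0, with a warning.
#' @examples
#' fisher_combine(c(5.1e-4, 6.5e-4, 1.41e-8, 9.0e-5, 2.27e-3))
#' @export
fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("a p-value of 0 forces the combined p-value to 0")
    return(0)
  }
  x2 <- -2 * sum(log(p))
  exp(stats::pchisq(x2, df = 2 * length(p), lower.tail = FALSE, log.p = TRUE))
}

#' Storey's step-down q-values across measures
#'
#' Given the M p-values of one lab (one per measure), sorts them
#' ascending, sets the q-value at the largest p equal to that p, and steps
#' down with \code{q_j = min(q_{j+1}, (M/j) * p_(j))}. Missing entries are
#' excluded and M is the count of non-missing p-values. Results are
#' returned in the input order and clamped to at most 1.
#'
#' @param p numeric vector of p-values in [0, 1], possibly with \code{NA}.
#' @return numeric vector of q-values aligned with \code{p} (\code{NA}
#'   where the input is \code{NA}).
#' @examples
#' storey_q(c(5.10e-4, 3.90e-4, 1.50e-4, 2.15e-9, 2.00e-4))
#' @export
storey_q <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pp <- p[ok]
  M <- length(pp)
  if (M == 0L) return(out)
  if (any(pp < 0 | pp > 1)) stop("p-values must lie in [0, 1]")
  o <- order(pp)
  s <- pp[o]
  q <- numeric(M)
  q[M] <- s[M]
  if (M > 1L) {
    for (j in (M - 1L):1L) q[j] <- min(q[j + 1L], (M / j) * s[j])
  }
  q <- pmin(q, 1)
  qq <- numeric(M)
  qq[o] <- q
  out[ok] <- qq
  names(out) <- names(p)
  out
}

#' Assemble the basis table of p- and q-values
#'
#' Runs the per-(measure, lab) tests, appends the Fisher's-method column
#' (each measure's lab p-values combined across labs), and computes
#' Storey q-values down every column, including the Fisher column. The
#' result is the M x (L + 1) grid that the four screening tests read.
#'
#' @inheritParams measure_pvalues
#' @return an object of class \code{pdx_basis}: a list with matrices
#'   \code{p} and \code{q} (rows = measures, columns = labs plus
#'   \code{"Fisher"}), plus \code{measures}, \code{labs} and
#'   \code{details} (the \code{\link{measure_pvalues}} table with sample
#'   sizes and notes).
#' @export
basis_table <- function(trial, t = 21, delta = 4, min_days = 10,
                        measures = .measure_names, tumor_model = NULL) {
  details <- measure_pvalues(trial, t = t, delta = delta,
                             min_days = min_days, measures = measures,
                             tumor_model = tumor_model)
  labs <- trial$labs
  p <- matrix(NA_real_, nrow = length(measures), ncol = length(labs),
              dimnames = list(measures, labs))
  for (i in seq_len(nrow(details))) {
    p[details$measure[i], details$lab[i]] <- details$p_value[i]
  }
  if (any(apply(p, 2, function(col) all(is.na(col))))) {
    warning("a lab has no computable measure: its column is all missing")
  }
  b <- as_pdx_basis(p)
  b$details <- details
  b
}

#' Build a basis table from an existing p-value grid
#'
#' Constructs the full basis table (Fisher column and all q-value columns)
#' from a measures-by-labs matrix of p-values, e.g. values transcribed
#' from a published report.
#'
#' @param p numeric matrix, rows = measures, columns = labs; \code{NA}
#'   marks tests that could not be computed.
#' @return a \code{pdx_basis} object (see \code{\link{basis_table}}).
#' @export
as_pdx_basis <- function(p) {
  p <- as.matrix(p)
  if (is.null(rownames(p))) rownames(p) <- paste0("M", seq_len(nrow(p)))
  if (is.null(colnames(p))) colnames(p) <- paste0("Lab", seq_len(ncol(p)))
  fisher <- vapply(seq_len(nrow(p)), function(i) fisher_combine(p[i, ]),
                   numeric(1))
  pm <- cbind(p, Fisher = fisher)
  qm <- pm
  for (j in seq_len(ncol(pm))) qm[, j] <- storey_q(pm[, j])
  structure(
    list(p = pm, q = qm,
         measures = rownames(p), labs = colnames(p)),
    class = "pdx_basis")
}

#' @export
print.pdx_basis <- function(x, digits = 3, ...) {
  cat("PDX basis table:", length(x$measures), "measure(s) x",
      length(x$labs), "lab(s) + Fisher column\n")
  cat("p-values:\n")
  print(signif(x$p, digits))
  cat("q-values:\n")
  print(signif(x$q, digits))
  invisible(x)
}

#' Tidy export of a basis table
#'
#' @param basis a \code{pdx_basis} object.
#' @return data.frame with one row per cell: \code{measure}, \code{lab},
#'   \code{is_fisher_column}, \code{p_value}, \code{q_value}.
#' @export
basis_as_data_frame <- function(basis) {
  stopifnot(inherits(basis, "pdx_basis"))
  cols <- colnames(basis$p)
  out <- expand.grid(measure = rownames(basis$p), lab = cols,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$is_fisher_column <- out$lab == "Fisher"
  out$p_value <- as.vector(basis$p)
  out$q_value <- as.vector(basis$q)
  out
}
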