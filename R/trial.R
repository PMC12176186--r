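#' Percent change in tumor volume from baseline
#'
#' Converts one mouse's ordered volume series into the percent relative
#' change from the day-0 baseline, \code{100 * (Vol(t) - Vol(0)) / Vol(0)}.
#' The point at day 0 is exactly 0 by construction, and the result can never
#' fall below -100 for positive volumes.
#'
#' @param day numeric vector of measurement days; must include day 0.
#' @param volume positive numeric vector of tumor volumes (mm^3), same
#'   length as \code{day}.
#' @return numeric vector of percent changes, aligned with \code{day}
#'   sorted in increasing order (an attribute \code{"day"} carries the
#'   sorted days).
#' @examples
#' pct_delta_vol(c(0, 4, 21), c(138.9, 157.7, 702.3))
#' @export
pct_delta_vol <- function(day, volume) {
  if (length(day) != length(volume)) {
    stop("`day` and `volume` must have the same length")
  }
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    stop("all volumes must be positive and finite")
  }
  if (any(!is.finite(day)) || any(day < 0)) {
    stop("all days must be finite and non-negative")
  }
  o <- order(day)
  day <- day[o]
  volume <- volume[o]
  if (anyDuplicated(day)) stop("duplicate measurement days for one mouse")
  if (day[1] != 0) stop("baseline required: the smallest day must be 0")
  pct <- 100 * (volume - volume[1]) / volume[1]
  pct[1] <- 0
  structure(pct, day = day)
}

.trial_cols <- c("tumor_model", "lab", "group", "mouse_id", "day", "volume")

#' Build a PDX trial object from a long-format table
#'
#' Validates a long table of longitudinal tumor volumes (one row per mouse
#' per measurement day) and converts each mouse's series into an empirical
#' tumor growth trajectory (ETGT): the ordered points
#' \code{(day, pct_delta_vol)} anchored at (0, 0).
#'
#' @param df data.frame with the trial columns (defaults
#'   \code{tumor_model, lab, group, mouse_id, day, volume}; remap with
#'   \code{col_map}). \code{group} must be \code{"control"} or
#'   \code{"treated"}. Alternatively the table may carry a
#'   \code{pct_delta_vol} column instead of \code{volume} (trajectories
#'   already expressed as percent change), in which case volumes are
#'   unavailable but all downstream measures remain computable.
#' @param col_map optional named character vector mapping the canonical
#'   column names to the names used in \code{df}, e.g.
#'   \code{c(mouse_id = "Mouse", volume = "TV")}.
#' @return an object of class \code{pdx_trial}: a list with \code{data}
#'   (the validated long table including \code{pct_delta_vol}),
#'   \code{labs}, \code{mice} (one row per trajectory) and \code{log}
#'   (parse notes, e.g. dropped rows).
#' @export
as_pdx_trial <- function(df, col_map = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      idx <- match(col_map[[canon]], names(df))
      if (!is.na(idx)) names(df)[idx] <- canon
    }
  }
  has_vol <- "volume" %in% names(df)
  need <- setdiff(.trial_cols, if (has_vol) character() else "volume")
  if (!has_vol && !"pct_delta_vol" %in% names(df)) need <- .trial_cols
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  log <- character()

  value_col <- if (has_vol) "volume" else "pct_delta_vol"
  drop <- is.na(df[[value_col]]) | is.na(df$day)
  if (any(drop)) {
    log <- c(log, sprintf("dropped %d row(s) with missing %s or day",
                          sum(drop), value_col))
    df <- df[!drop, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no usable rows in trial table")
  if (has_vol && any(df$volume <= 0)) {
    stop("non-positive volume at row(s): ",
         paste(utils::head(which(df$volume <= 0), 5L), collapse = ", "))
  }
  if (any(df$day < 0)) stop("negative day values are not allowed")
  df$group <- tolower(as.character(df$group))
  if (!all(df$group %in% c("control", "treated"))) {
    stop("`group` must be 'control' or 'treated'")
  }
  for (col in c("tumor_model", "lab", "mouse_id")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$day <- as.numeric(df$day)

  key <- interaction(df$tumor_model, df$lab, df$group, df$mouse_id,
                     drop = TRUE, lex.order = TRUE)
  dup <- duplicated(data.frame(key, df$day))
  if (any(dup)) {
    stop("duplicate (mouse, day) record(s) at row(s): ",
         paste(utils::head(which(dup), 5L), collapse = ", "))
  }

  pieces <- split(df, key)
  out <- lapply(pieces, function(piece) {
    piece <- piece[order(piece$day), , drop = FALSE]
    if (piece$day[1] != 0) {
      return(NULL)  # no baseline: trajectory rejected
    }
    if (has_vol) {
      piece$pct_delta_vol <- as.numeric(pct_delta_vol(piece$day, piece$volume))
    } else {
      piece$pct_delta_vol <- as.numeric(piece$pct_delta_vol)
      if (abs(piece$pct_delta_vol[1]) > 1e-8) {
        return(NULL)  # pct trajectories must also be anchored at (0, 0)
      }
      piece$pct_delta_vol[1] <- 0
      piece$volume <- NA_real_
    }
    piece
  })
  rejected <- vapply(out, is.null, logical(1))
  if (any(rejected)) {
    log <- c(log, sprintf(
      "rejected %d trajectorie(s) without a day-0 baseline: %s",
      sum(rejected), paste(utils::head(names(pieces)[rejected], 5L), collapse = ", ")))
    out <- out[!rejected]
  }
  if (!length(out)) stop("no trajectory with a day-0 baseline")
  data <- do.call(rbind, out)
  rownames(data) <- NULL
  data <- data[, c(.trial_cols, "pct_delta_vol")]

  mice <- unique(data[, c("tumor_model", "lab", "group", "mouse_id")])
  rownames(mice) <- NULL
  incomplete <- character()
  for (l in unique(mice$lab)) {
    g <- mice$group[mice$lab == l]
    if (!all(c("control", "treated") %in% g)) incomplete <- c(incomplete, l)
  }
  if (length(incomplete)) {
    log <- c(log, sprintf("lab(s) without both arms: %s",
                          paste(incomplete, collapse = ", ")))
  }
  structure(
    list(data = data, labs = unique(data$lab), mice = mice, log = log),
    class = "pdx_trial")
}

#' Read a longitudinal tumor-volume table from CSV
#'
#' Reads a long-format trial table (one row per mouse per day) and returns
#' a validated \code{\link{as_pdx_trial}} object. Only plain-text CSV/TSV is
#' supported; spreadsheet exports should be saved as CSV first.
#'
#' @param path path to a CSV (or TSV) file with a header row.
#' @param col_map optional column-name mapping, see \code{\link{as_pdx_trial}}.
#' @param sep field separator, default comma.
#' @return a \code{pdx_trial} object.
#' @export
read_trial_table <- function(path, col_map = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("could not parse ", path, ": ", conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty or malformed trial table: ", path)
  trial <- as_pdx_trial(df, col_map = col_map)
  trial$source <- path
  trial
}

#' Write a trial's trajectories to canonical ETGT CSV
#'
#' Writes the long table \code{tumor_model, lab, group, mouse_id, day,
#' pct_delta_vol} at full floating-point precision, so a round trip through
#' \code{\link{read_trial_table}} reproduces the trajectories exactly.
#'
#' @param trial a \code{pdx_trial} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "pdx_trial"))
  out <- trial$data[, c("tumor_model", "lab", "group", "mouse_id",
                        "day", "pct_delta_vol")]
  out$pct_delta_vol <- format(out$pct_delta_vol, digits = 17, trim = TRUE,
                              scientific = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.pdx_trial <- function(x, ...) {
  cat("PDX trial:", nrow(x$mice), "trajectories,",
      length(x$labs), "lab(s),",
      length(unique(x$mice$tumor_model)), "tumor model(s)\n")
  tab <- table(x$mice$lab, x$mice$group)
  print(tab)
  if (length(x$log)) cat("notes:", paste(x$log, collapse = "; "), "\n")
  invisible(x)
}

#' @export
plot.pdx_trial <- function(x, lab = NULL, ...) {
  d <- x$data
  if (!is.null(lab)) d <- d[d$lab %in% lab, , drop = FALSE]
  cols <- c(control = "grey40", treated = "firebrick")
  graphics::plot(range(d$day), range(d$pct_delta_vol), type = "n",
                 xlab = "day", ylab = "% change in tumor volume", ...)
  for (piece in split(d, d[c("lab", "group", "mouse_id")], drop = TRUE)) {
    graphics::lines(piece$day, piece$pct_delta_vol,
                    col = cols[[piece$group[1]]])
  }
  graphics::legend("topleft", legend = names(cols), col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}

# split a trial's long table into one data.frame per trajectory
split_etgt <- function(trial) {
  split(trial$data,
        trial$data[c("tumor_model", "lab", "group", "mouse_id")],
        drop = TRUE)
}

# internal fast constructor for data already validated, day-sorted per mouse
new_pdx_trial <- function(data, labs = unique(data$lab), log = character()) {
  mice <- unique(data[, c("tumor_model", "lab", "group", "mouse_id")])
  rownames(mice) <- NULL
  structure(list(data = data, labs = labs, mice = mice, log = log),
            class = "pdx_trial")
}
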