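## Counting-process panel container and its invariants.

panel_columns <- c("id", "start", "stop", "event", "a1", "a2", "L", "L0")

#' Validate and class a counting-process panel
#'
#' A `long_panel` holds one row per person-interval with columns
#' `id, start, stop, event, a1, a2, L, L0` (times in months). The checks
#' enforce the panel invariants: per subject, intervals are contiguous
#' half-open months `[m, m+1)`; at most one row has
#' `event = 1` and it is the last row; both treatments are binary and
#' non-decreasing (monotone treatment); `L0` is constant within subject and
#' equals the first `L`.
#'
#' @param df a data frame with the schema above (extra columns are kept).
#' @return `df` with class `long_panel`, or a validation error naming the
#'   offending subject and row.
#' @export
as_long_panel <- function(df) {
  miss <- setdiff(panel_columns, names(df))
  if (length(miss))
    stop_validation("panel is missing column(s): %s", paste(miss, collapse = ", "))
  for (cl in panel_columns)
    if (!is.numeric(df[[cl]]))
      stop_validation("panel column '%s' must be numeric", cl)
  if (!all(df$event %in% c(0, 1)) || !all(df$a1 %in% c(0, 1)) ||
      !all(df$a2 %in% c(0, 1)))
    stop_validation("event, a1 and a2 must be 0/1 indicators")

  ord <- order(df$id, df$start)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  sid <- df$id
  first <- !duplicated(sid)
  last <- !duplicated(sid, fromLast = TRUE)

  bad <- which(df$stop != df$start + 1)
  if (length(bad))
    stop_validation("subject %s, row %d: interval [%g, %g) is not one month",
                    format(sid[bad[1]]), bad[1], df$start[bad[1]], df$stop[bad[1]])
  contiguous <- first | (df$start == c(NA, df$start[-nrow(df)] + 1))
  bad <- which(!contiguous)
  if (length(bad))
    stop_validation("subject %s, row %d: intervals are not contiguous",
                    format(sid[bad[1]]), bad[1])
  bad <- which(df$event == 1 & !last)
  if (length(bad))
    stop_validation("subject %s, row %d: event row is not the subject's last row",
                    format(sid[bad[1]]), bad[1])
  nondec <- function(x) first | (x >= c(NA, x[-nrow(df)]))
  if (any(!nondec(df$a1)) || any(!nondec(df$a2))) {
    bad <- which(!(nondec(df$a1) & nondec(df$a2)))
    stop_validation("subject %s, row %d: treatment switches off (non-monotone)",
                    format(sid[bad[1]]), bad[1])
  }
  L0ref <- df$L0[first][match(sid, sid[first])]
  bad <- which(df$L0 != L0ref)
  if (length(bad))
    stop_validation("subject %s: L0 is not constant within subject",
                    format(sid[bad[1]]))
  class(df) <- c("long_panel", "data.frame")
  df
}

#' @export
print.long_panel <- function(x, ...) {
  ev <- sum(x$event)
  cat(sprintf("<long_panel> %d person-months, %d subjects, %d events (%.2f%%/month)\n",
              nrow(x), length(unique(x$id)), ev, 100 * ev / nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Read / write a counting-process panel CSV
#'
#' The on-disk format is a flat comma-separated file (dot decimal, UTF-8)
#' with exactly the header `id,start,stop,event,a1,a2,L,L0`, optionally
#' extended by the weight columns `sw_a1,sw_a2,sw_c,sw`. Reading validates
#' every panel invariant and fails with a row-level message.
#'
#' @param path file path.
#' @return `read_panel()`: a validated `long_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop_validation("panel file not found: %s", path)
  df <- utils::read.csv(path)
  extra <- setdiff(names(df), c(panel_columns, c("sw_a1", "sw_a2", "sw_c", "sw")))
  if (length(extra))
    stop_validation("unexpected panel column(s): %s", paste(extra, collapse = ", "))
  as_long_panel(df)
}

#' @param panel a `long_panel` (possibly with appended weight columns).
#' @rdname read_panel
#' @return `write_panel()`: the path, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
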