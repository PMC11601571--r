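#' Cohort table of daily EAE clinical scores
#'
#' A `cohort_table` bundles validated per-mouse daily clinical scores
#' (classic and axial-rotary scales, each 0--5) over a fixed observation
#' window with the bookkeeping the downstream trait derivation needs:
#' mice excluded under the mortality rules, and days whose scores were
#' imputed by carry-forward.
#'
#' @param scores data.frame with columns `mouse_id`, `strain`, `sex`,
#'   `cohort`, `day`, `classic`, `ar`, `status`.
#' @param excluded data.frame with columns `mouse_id`, `reason`.
#' @param imputed data.frame with columns `mouse_id`, `day`.
#' @param window integer length-2, first and last observation day (closed).
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(scores,
                         excluded = data.frame(mouse_id = character(),
                                               reason = character()),
                         imputed = data.frame(mouse_id = character(),
                                              day = integer()),
                         window = c(5L, 50L)) {
  needed <- c("mouse_id", "strain", "sex", "cohort", "day",
              "classic", "ar", "status")
  missing_cols <- setdiff(needed, names(scores))
  if (length(missing_cols) > 0L)
    stop("scores table lacks column(s): ", paste(missing_cols, collapse = ", "))
  bad <- intersect(scores$mouse_id, excluded$mouse_id)
  if (length(bad) > 0L)
    stop("mouse_id present in both series and excluded: ",
         paste(bad, collapse = ", "))
  scores <- scores[order(scores$mouse_id, scores$day), , drop = FALSE]
  rownames(scores) <- NULL
  structure(list(scores = scores, excluded = excluded, imputed = imputed,
                 window = as.integer(window)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d mice, days %d-%d, %d excluded, %d imputed day(s)\n",
              length(unique(x$scores$mouse_id)), x$window[1], x$window[2],
              nrow(x$excluded), nrow(x$imputed)))
  invisible(x)
}

# Split the long score table into a per-mouse list of data.frames,
# preserving mouse order of first appearance.
split_mice <- function(scores) {
  ids <- unique(scores$mouse_id)
  split(scores, factor(scores$mouse_id, levels = ids))
}

#' Read and validate a daily clinical-score table
#'
#' Reads a long-format delimited file (comma or tab, auto-detected) with
#' one row per mouse-day, validates scores and metadata, restricts to the
#' observation window, and completes each mouse's day grid: days missing
#' before the first record become 0/alive, and days missing after a record
#' carry the previous day's scores and status forward.  Every imputed day
#' is logged in the returned table's `imputed` slot and reported with a
#' warning, because silently inserting zeros would fabricate remissions.
#'
#' @param path path to a UTF-8 delimited file with header columns
#'   `mouse_id`, `strain`, `sex`, `cohort`, `day`, `classic`, `ar` and
#'   optionally `status` (one of `alive`, `endpoint`, `dead`; default
#'   `alive`).
#' @param window integer length-2 observation window in days
#'   post-induction, closed; default `c(5, 50)` (the 50-day MOG protocol
#'   scored from day 5).
#' @return A [cohort_table()].
#' @export
read_scores <- function(path, window = c(5L, 50L)) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          fill = FALSE, comment.char = "")
  validate_scores_df(df, window)
}

#' Validate a long score data.frame into a cohort_table
#'
#' The in-memory counterpart of [read_scores()]: applies the same
#' validation and day-grid completion to an already-loaded data.frame.
#'
#' @inheritParams cohort_table
#' @param df long-format data.frame (see [read_scores()] for columns).
#' @return A [cohort_table()].
#' @export
validate_scores_df <- function(df, window = c(5L, 50L)) {
  window <- as.integer(window)
  needed <- c("mouse_id", "strain", "sex", "cohort", "day", "classic", "ar")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(df$status)) df$status <- "alive"
  df$status[is.na(df$status) | df$status == ""] <- "alive"

  for (col in c("day", "classic", "ar")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v != round(v))
    if (length(bad) > 0L)
      stop(sprintf("parse error: non-integer '%s' at data row %d", col, bad[1]))
    df[[col]] <- as.integer(v)
  }
  for (col in c("classic", "ar")) {
    bad <- which(df[[col]] < 0L | df[[col]] > 5L)
    if (length(bad) > 0L)
      stop(sprintf("validation error: %s score %d outside 0-5 at data row %d",
                   col, df[[col]][bad[1]], bad[1]))
  }
  bad_sex <- which(!df$sex %in% c("M", "F"))
  if (length(bad_sex) > 0L)
    stop("validation error: sex must be 'M' or 'F' (data row ", bad_sex[1], ")")
  if (any(!nzchar(df$cohort)))
    stop("validation error: empty cohort label")
  bad_status <- which(!df$status %in% c("alive", "endpoint", "dead"))
  if (length(bad_status) > 0L)
    stop("validation error: unknown status '", df$status[bad_status[1]],
         "' (data row ", bad_status[1], ")")
  dup <- duplicated(df[c("mouse_id", "day")])
  if (any(dup))
    stop(sprintf("validation error: duplicate (mouse, day) record (%s, day %d)",
                 df$mouse_id[which(dup)[1]], df$day[which(dup)[1]]))
  meta_chk <- unique(df[c("mouse_id", "strain", "sex", "cohort")])
  if (anyDuplicated(meta_chk$mouse_id))
    stop("validation error: inconsistent strain/sex/cohort within a mouse_id")

  df <- df[df$day >= window[1] & df$day <= window[2], , drop = FALSE]
  days_full <- window[1]:window[2]
  mice <- split_mice(df)
  out <- vector("list", length(mice))
  imputed <- list()
  for (i in seq_along(out)) {
    m <- mice[[i]]
    m <- m[order(m$day), , drop = FALSE]
    full <- data.frame(mouse_id = m$mouse_id[1], strain = m$strain[1],
                       sex = m$sex[1], cohort = m$cohort[1], day = days_full,
                       classic = 0L, ar = 0L, status = "alive",
                       stringsAsFactors = FALSE)
    idx <- match(m$day, days_full)
    full$classic[idx] <- m$classic
    full$ar[idx] <- m$ar
    full$status[idx] <- m$status
    present <- logical(length(days_full)); present[idx] <- TRUE
    # carry forward from the last recorded day; leading gaps stay 0/alive
    first_rec <- which(present)[1]
    gap <- which(!present & seq_along(present) > first_rec)
    for (j in gap) {
      full$classic[j] <- full$classic[j - 1L]
      full$ar[j] <- full$ar[j - 1L]
      full$status[j] <- full$status[j - 1L]
    }
    if (length(gap) > 0L)
      imputed[[length(imputed) + 1L]] <-
        data.frame(mouse_id = m$mouse_id[1], day = days_full[gap])
    out[[i]] <- full
  }
  imputed <- if (length(imputed)) do.call(rbind, imputed) else
    data.frame(mouse_id = character(), day = integer())
  if (nrow(imputed) > 0L)
    warning(sprintf("imputed %d missing day(s) by carry-forward (%d mouse/mice)",
                    nrow(imputed), length(unique(imputed$mouse_id))))
  cohort_table(do.call(rbind, out), imputed = imputed, window = window)
}

# maximum length of a consecutive run of TRUE
max_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Apply humane-endpoint and mortality carry-forward rules
#'
#' Implements the study's score-recording rules prior to any trait
#' derivation:
#' \enumerate{
#'   \item A mouse scoring 5 on either scale for 72 hours (3 consecutive
#'     recorded days) has that scale's score carried forward as 5 for all
#'     later days, with status `endpoint` thereafter.
#'   \item A mouse that dies after presenting with disease for more than 2
#'     consecutive days has the presenting scale's score carried forward
#'     as 5 for the remainder of the window (status stays `dead`).  The
#'     presenting scale is the one with the higher score on the last day
#'     alive; ties go to the classic scale.
#'   \item A mouse that dies with no clinical signs, or with at most 2
#'     consecutive days of disease, is excluded
#'     (reason `"death-without-established-EAE"`).
#' }
#' The operation is idempotent.
#'
#' @param table a [cohort_table()].
#' @return A `cohort_table` with carried-forward scores and updated
#'   exclusions.
#' @export
apply_endpoint_rules <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  mice <- split_mice(table$scores)
  keep <- list()
  newly_excluded <- list()
  for (m in mice) {
    m <- m[order(m$day), , drop = FALSE]
    dead_at <- which(m$status == "dead")[1]
    if (!is.na(dead_at)) {
      pre <- if (dead_at > 1L) m[seq_len(dead_at - 1L), ] else m[0L, ]
      disease <- combine_daily(pre$classic, pre$ar) > 0
      if (max_run(disease) <= 2L) {
        newly_excluded[[length(newly_excluded) + 1L]] <-
          data.frame(mouse_id = m$mouse_id[1],
                     reason = "death-without-established-EAE")
        next
      }
      last_alive <- dead_at - 1L
      sub <- if (m$ar[last_alive] > m$classic[last_alive]) "ar" else "classic"
      m[[sub]][dead_at:nrow(m)] <- 5L
    }
    # 72-hour maximal-score endpoint, each scale independently
    endpoint_from <- NA_integer_
    for (sub in c("classic", "ar")) {
      s5 <- m[[sub]] == 5L
      r <- rle(s5)
      ends <- cumsum(r$lengths)
      hit <- which(r$values & r$lengths >= 3L)[1]
      if (!is.na(hit)) {
        done <- ends[hit] - r$lengths[hit] + 3L  # day index completing 72h
        if (done < nrow(m)) m[[sub]][(done + 1L):nrow(m)] <- 5L
        endpoint_from <- min(endpoint_from, done + 1L, na.rm = TRUE)
      }
    }
    if (!is.na(endpoint_from) && endpoint_from <= nrow(m)) {
      idx <- endpoint_from:nrow(m)
      m$status[idx] <- ifelse(m$status[idx] == "dead", "dead", "endpoint")
    }
    keep[[length(keep) + 1L]] <- m
  }
  newly_excluded <- if (length(newly_excluded)) do.call(rbind, newly_excluded)
    else data.frame(mouse_id = character(), reason = character())
  cohort_table(if (length(keep)) do.call(rbind, keep) else table$scores[0L, ],
               excluded = rbind(table$excluded, newly_excluded),
               imputed = table$imputed, window = table$window)
}

#' Write a cohort table's score series to a delimited file
#'
#' @param table a [cohort_table()].
#' @param path output path; tab-separated.
#' @return `path`, invisibly.
#' @export
write_scores <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  utils::write.table(table$scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
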