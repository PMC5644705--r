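#' Construct a provisioning attempt
#'
#' A `provisioning_attempt` is the central record of the package: one nest's
#' ordered, day-segmented visit events, together with the day calendar and
#' optional attempt-level metadata (brood ages, fledge day, disturbance
#' windows, carer classes). All downstream analyses — carer classification,
#' Markov model fitting, alternation statistics, and the inter-visit-interval
#' randomization test — consume this object.
#'
#' @param visits data frame with columns `day_index` (integer, >= 1),
#'   `carer_id` (character) and `time` (numeric, absolute seconds). Visits
#'   are sorted by (day_index, time) on construction; ties keep input order.
#' @param days data frame with columns `day_index`, `day_start`, `day_end`
#'   (seconds; half-open observation windows `[day_start, day_end)`).
#' @param attempt_id label for the breeding attempt.
#' @param metadata optional list with any of: `brood_age` (numeric, named by
#'   day_index, in days), `brood_size`, `fledge_day_index`,
#'   `disturbance_windows` (list of length-2 numeric vectors, half-open
#'   seconds), `carer_class` (character named by carer_id; values
#'   `"breeding male"`, `"breeding female"`, `"helper"` or `"unknown"`).
#' @return An object of class `provisioning_attempt`.
#' @export
provisioning_attempt <- function(visits, days, attempt_id = "attempt",
                                 metadata = list()) {
  stopifnot(is.data.frame(visits), is.data.frame(days))
  need_v <- c("day_index", "carer_id", "time")
  if (!all(need_v %in% names(visits)))
    stop("visits must have columns: ", paste(need_v, collapse = ", "))
  need_d <- c("day_index", "day_start", "day_end")
  if (!all(need_d %in% names(days)))
    stop("days must have columns: ", paste(need_d, collapse = ", "))
  if (any(!is.finite(visits$time))) stop("non-finite visit times")
  if (any(!nzchar(as.character(visits$carer_id)))) stop("empty carer_id")
  days <- days[order(days$day_index), , drop = FALSE]
  if (anyDuplicated(days$day_index)) stop("duplicate day_index in days")
  o <- order(visits$day_index, visits$time)  # stable: ties keep input order
  visits <- visits[o, , drop = FALSE]
  visits$carer_id <- as.character(visits$carer_id)
  rownames(visits) <- NULL
  m <- match(visits$day_index, days$day_index)
  if (anyNA(m)) stop("visit day_index not present in day calendar")
  bad <- visits$time < days$day_start[m] | visits$time >= days$day_end[m]
  if (any(bad))
    stop(sum(bad), " visit(s) outside their day window [day_start, day_end)")
  structure(
    list(attempt_id = attempt_id, visits = visits, days = days,
         metadata = metadata, filter_report = NULL),
    class = "provisioning_attempt")
}

#' @export
print.provisioning_attempt <- function(x, ...) {
  cat("Provisioning attempt:", x$attempt_id, "\n")
  cat(sprintf("  %d visits by %d carer(s) over %d day(s)\n",
              nrow(x$visits), length(unique(x$visits$carer_id)),
              nrow(x$days)))
  if (!is.null(x$filter_report)) {
    fr <- x$filter_report
    cat(sprintf("  filters: %d day(s) removed (brood age), %d (fledge), %d visit(s) removed (disturbance)\n",
                fr$days_removed_brood_age, fr$days_removed_fledge,
                fr$visits_removed_disturbance))
  }
  invisible(x)
}

#' Count visits per carer
#'
#' @param attempt a [provisioning_attempt()].
#' @return Named integer vector of visit counts, one entry per carer.
#' @export
visit_counts <- function(attempt) {
  stopifnot(inherits(attempt, "provisioning_attempt"))
  tab <- table(attempt$visits$carer_id)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts
}

#' Read a table of raw PIT-tag reads or pre-formed visits
#'
#' Parses a CSV (or data frame) with header columns `attempt_id`,
#' `carer_id`, `timestamp`. Timestamps may be epoch seconds or ISO-8601
#' datetimes; they are converted to numeric seconds. Rows are sorted
#' ascending by time within attempt; the sort is stable so ties keep input
#' order.
#'
#' @param source path to a CSV file, a connection, or a data frame.
#' @return data frame with columns `attempt_id`, `carer_id`, `time`
#'   (seconds).
#' @export
read_visit_table <- function(source) {
  x <- if (is.data.frame(source)) source else
    utils::read.csv(source, stringsAsFactors = FALSE)
  need <- c("attempt_id", "carer_id", "timestamp")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  ts <- x$timestamp
  if (is.numeric(ts)) {
    time <- as.numeric(ts)
  } else {
    ts <- as.character(ts)
    time <- suppressWarnings(as.numeric(ts))
    chr <- which(is.na(time) & !is.na(ts))
    if (length(chr)) {
      parsed <- rep(NA_real_, length(chr))
      for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                    "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
        todo <- is.na(parsed)
        if (!any(todo)) break
        p <- as.POSIXct(ts[chr[todo]], tz = "UTC", format = fmt)
        parsed[todo] <- as.numeric(p)
      }
      time[chr] <- parsed
    }
  }
  if (anyNA(time)) {
    row <- which(is.na(time))[1]
    stop(sprintf("malformed timestamp %s in row %d",
                 dQuote(as.character(x$timestamp)[row]), row))
  }
  out <- data.frame(attempt_id = as.character(x$attempt_id),
                    carer_id = as.character(x$carer_id),
                    time = time, stringsAsFactors = FALSE)
  if (any(!nzchar(out$carer_id))) stop("empty carer_id")
  out <- out[order(out$attempt_id, out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse consecutive reads into discrete visits
#'
#' Chains consecutive reads by the same carer into a single visit while each
#' successive gap is at most `gap_window` seconds (default 2 min, the
#' standard grouping window for PIT provisioning data). The visit time is
#' the time of the first read in the chain — the bird's arrival at the nest.
#' Reads by different carers never merge.
#'
#' @param reads data frame with `attempt_id`, `carer_id`, `time` (as
#'   returned by [read_visit_table()]), sorted by time within attempt.
#' @param gap_window maximum gap (seconds) between successive reads of the
#'   same carer for them to belong to one visit.
#' @return data frame of visits with columns `attempt_id`, `carer_id`,
#'   `time`, `n_reads`, sorted by time within attempt.
#' @export
collapse_reads <- function(reads, gap_window = 120) {
  stopifnot(is.data.frame(reads))
  if (!is.numeric(gap_window) || length(gap_window) != 1L ||
      !is.finite(gap_window) || gap_window < 0)
    stop("gap_window must be a single nonnegative number of seconds")
  if (nrow(reads) == 0L)
    return(data.frame(attempt_id = character(), carer_id = character(),
                      time = numeric(), n_reads = integer()))
  o <- order(reads$attempt_id, reads$carer_id, reads$time)
  r <- reads[o, , drop = FALSE]
  same <- c(FALSE, r$attempt_id[-1] == r$attempt_id[-nrow(r)] &
                   r$carer_id[-1] == r$carer_id[-nrow(r)] &
                   (r$time[-1] - r$time[-nrow(r)]) <= gap_window)
  grp <- cumsum(!same)
  first <- !duplicated(grp)
  out <- data.frame(attempt_id = r$attempt_id[first],
                    carer_id = r$carer_id[first],
                    time = r$time[first],
                    n_reads = as.integer(tabulate(grp)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$attempt_id, out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segment visits into observation days
#'
#' Assigns each visit to the half-open calendar window `[day_start,
#' day_end)` containing its time. Visits outside every window are dropped
#' (with a message reporting the count). No inter-visit interval computed
#' downstream ever spans a day boundary.
#'
#' @param visits data frame with `carer_id`, `time` (and optionally
#'   `attempt_id`; a single attempt is expected).
#' @param day_calendar data frame with `day_start`, `day_end` (seconds) and
#'   optionally `day_index`; windows must be disjoint and ordered.
#' @param attempt_id attempt label; defaults to the one found in `visits`.
#' @param metadata forwarded to [provisioning_attempt()].
#' @return A [provisioning_attempt()]. The number of dropped visits is
#'   attached as attribute `"n_dropped"`.
#' @export
segment_days <- function(visits, day_calendar, attempt_id = NULL,
                         metadata = list()) {
  stopifnot(is.data.frame(visits), is.data.frame(day_calendar))
  if (!all(c("day_start", "day_end") %in% names(day_calendar)))
    stop("day_calendar must have day_start and day_end columns")
  cal <- day_calendar[order(day_calendar$day_start), , drop = FALSE]
  if (is.null(cal$day_index)) cal$day_index <- seq_len(nrow(cal))
  if (any(cal$day_end <= cal$day_start)) stop("day_end must exceed day_start")
  if (nrow(cal) > 1 && any(cal$day_start[-1] < cal$day_end[-nrow(cal)]))
    stop("overlapping day windows in calendar")
  if (!is.null(visits$attempt_id)) {
    ids <- unique(visits$attempt_id)
    if (length(ids) > 1) stop("segment_days expects a single attempt")
    attempt_id <- attempt_id %||% ids
  }
  attempt_id <- attempt_id %||% "attempt"
  idx <- rep(NA_integer_, nrow(visits))
  for (k in seq_len(nrow(cal))) {
    inside <- visits$time >= cal$day_start[k] & visits$time < cal$day_end[k]
    idx[inside] <- cal$day_index[k]
  }
  dropped <- sum(is.na(idx))
  if (dropped > 0)
    message(dropped, " visit(s) outside all day windows dropped")
  keep <- !is.na(idx)
  v <- data.frame(day_index = idx[keep],
                  carer_id = as.character(visits$carer_id)[keep],
                  time = visits$time[keep], stringsAsFactors = FALSE)
  att <- provisioning_attempt(
    v, cal[, c("day_index", "day_start", "day_end")], attempt_id, metadata)
  attr(att, "n_dropped") <- dropped
  att
}

#' Apply standard data filters to an attempt
#'
#' Removes (a) days whose brood age does not exceed `min_brood_age` days —
#' young broods confound brooding with provisioning; (b) the last day in the
#' nest before fledging, when `fledge_day_index` is set in the metadata; and
#' (c) visits falling inside any disturbance window (half-open seconds).
#' A filter report with per-rule removal counts is attached to the result.
#' Surviving visits are never reordered.
#'
#' @param attempt a [provisioning_attempt()] whose metadata carries
#'   `brood_age` (named by day_index), and optionally `fledge_day_index`
#'   and `disturbance_windows`.
#' @param min_brood_age days; a day is retained only if its brood age is
#'   strictly greater than this.
#' @param allow_missing_brood_age if `FALSE` (default), a retained day with
#'   no brood age entry is an error; set `TRUE` to skip the brood-age filter
#'   for such days.
#' @return The filtered `provisioning_attempt`, with `$filter_report` set.
#' @export
apply_filters <- function(attempt, min_brood_age = 10,
                          allow_missing_brood_age = FALSE) {
  stopifnot(inherits(attempt, "provisioning_attempt"))
  md <- attempt$metadata
  days <- attempt$days
  visits <- attempt$visits
  report <- list(days_removed_brood_age = 0L, days_removed_fledge = 0L,
                 visits_removed_disturbance = 0L)

  keep_day <- rep(TRUE, nrow(days))
  if (!is.null(md$brood_age)) {
    age <- md$brood_age[as.character(days$day_index)]
    if (anyNA(age) && !allow_missing_brood_age)
      stop("missing brood age for day(s) ",
           paste(days$day_index[is.na(age)], collapse = ", "))
    drop <- !is.na(age) & age <= min_brood_age
    report$days_removed_brood_age <- sum(drop)
    keep_day <- keep_day & !drop
  } else if (!allow_missing_brood_age) {
    stop("metadata$brood_age missing; set allow_missing_brood_age = TRUE to skip")
  }
  if (!is.null(md$fledge_day_index)) {
    drop <- keep_day & days$day_index == md$fledge_day_index
    report$days_removed_fledge <- sum(drop)
    keep_day <- keep_day & !drop
  }
  days <- days[keep_day, , drop = FALSE]
  visits <- visits[visits$day_index %in% days$day_index, , drop = FALSE]

  for (w in md$disturbance_windows %||% list()) {
    inside <- visits$time >= w[1] & visits$time < w[2]
    report$visits_removed_disturbance <-
      report$visits_removed_disturbance + sum(inside)
    visits <- visits[!inside, , drop = FALSE]
  }
  out <- provisioning_attempt(visits, days, attempt$attempt_id, md)
  out$filter_report <- report
  out
}
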