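#' Identify significant carers by iterative visit-count exclusion
#'
#' Carers are ranked by total visit count. Each round, the currently
#' lowest-visiting retained carer is excluded if its count fails to exceed
#' `threshold_frac` times the mean count of the other retained carers
#' (exclusion when `count <= threshold_frac * mean(others)`; e.g. a bird
#' with 10 or fewer visits is excluded from a group of four others that each
#' visited 50 times). The process repeats until the lowest retained carer
#' exceeds the cutoff. The result is independent of input order and is a
#' fixed point: re-running on the retained set changes nothing.
#'
#' @param counts named numeric vector (or a [provisioning_attempt()], from
#'   which counts are taken) of visits per carer.
#' @param threshold_frac fraction of the mean of the rest of the group that
#'   a carer must exceed to be retained; default 0.2.
#' @param carer_class optional character vector named by carer_id
#'   (`"breeding male"`, `"breeding female"`, `"helper"`, `"unknown"`).
#' @param attempt_id label carried into the result.
#' @return An object of class `carer_set`: `carers` (data frame of retained
#'   carers, sorted by descending count, with class labels and helper
#'   ranks), `excluded` (carer, count, exclusion round) and `c`, the number
#'   of significant carers.
#' @export
classify_significant <- function(counts, threshold_frac = 0.2,
                                 carer_class = NULL,
                                 attempt_id = "attempt") {
  if (inherits(counts, "provisioning_attempt")) {
    attempt_id <- counts$attempt_id
    carer_class <- carer_class %||% counts$metadata$carer_class
    counts <- visit_counts(counts)
  }
  if (length(counts) == 0L) stop("no carers in input")
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named by carer_id")
  if (all(counts <= 0)) stop("no carer with a positive visit count")
  if (!is.numeric(threshold_frac) || threshold_frac < 0)
    stop("threshold_frac must be a nonnegative fraction")

  ## canonical order: descending count, ties by carer_id (input order must
  ## not matter)
  ids <- names(counts)
  o <- order(-counts, ids)
  ids <- ids[o]; cnt <- as.numeric(counts[o])

  excluded <- data.frame(carer_id = character(), visit_count = numeric(),
                         exclusion_round = integer(),
                         stringsAsFactors = FALSE)
  round <- 0L
  while (length(ids) > 1L) {
    low <- length(ids)                      # current lowest-visiting carer
    cutoff <- threshold_frac * mean(cnt[-low])
    if (cnt[low] > cutoff) break
    round <- round + 1L
    excluded <- rbind(excluded, data.frame(
      carer_id = ids[low], visit_count = cnt[low],
      exclusion_round = round, stringsAsFactors = FALSE))
    ids <- ids[-low]; cnt <- cnt[-low]
  }

  cls <- if (is.null(carer_class)) rep("unknown", length(ids)) else {
    z <- unname(carer_class[ids]); z[is.na(z)] <- "unknown"; z
  }
  carers <- data.frame(carer_id = ids, visit_count = cnt, class = cls,
                       helper_rank = NA_integer_, stringsAsFactors = FALSE)
  structure(list(attempt_id = attempt_id, carers = carers,
                 excluded = excluded, c = nrow(carers),
                 threshold_frac = threshold_frac),
            class = "carer_set")
}

#' @export
print.carer_set <- function(x, ...) {
  cat(sprintf("Carer set for %s: %d significant carer(s), %d excluded\n",
              x$attempt_id, x$c, nrow(x$excluded)))
  print(x$carers, row.names = FALSE)
  if (nrow(x$excluded)) {
    cat("excluded:\n")
    print(x$excluded, row.names = FALSE)
  }
  invisible(x)
}

#' Validate a carer set for model fitting
#'
#' Produces a validity report rather than an error. The dataset is invalid
#' for fitting when any significant carer visited `min_visits` times or
#' fewer (validity requires strictly more). Groups larger than `max_carers`
#' are flagged with a warning — the data demand of the full model grows as
#' the square of the carer number — but fitting is not blocked. When
#' sufficient statistics are supplied, (previous, next) carer pairs with
#' zero observed transitions are listed: their full-model rates are
#' inestimable (zero at the maximum). A singleton group is flagged as
#' unusable for turn-taking analysis.
#'
#' @param carer_set a [classify_significant()] result.
#' @param stats optional [sufficient_stats()] result for the same carers.
#' @param min_visits validity requires every significant carer to have
#'   strictly more than this many visits; default 10.
#' @param max_carers warn above this carer count; default 6.
#' @return list of class `carer_validity` with `valid`, `warnings`,
#'   `low_count_carers`, `zero_transition_pairs`, `c`.
#' @export
validate_for_fitting <- function(carer_set, stats = NULL, min_visits = 10,
                                 max_carers = 6) {
  stopifnot(inherits(carer_set, "carer_set"))
  warnings <- character()
  low <- carer_set$carers$carer_id[carer_set$carers$visit_count <= min_visits]
  valid <- length(low) == 0L
  if (!valid)
    warnings <- c(warnings, sprintf(
      "carer(s) with <= %d visits: %s", min_visits, paste(low, collapse = ", ")))
  if (carer_set$c > max_carers)
    warnings <- c(warnings, sprintf(
      "%d significant carers: data demand grows as c^2", carer_set$c))
  if (carer_set$c < 2)
    warnings <- c(warnings,
                  "single significant carer: turn-taking analysis impossible")
  zero_pairs <- NULL
  if (!is.null(stats)) {
    z <- which(stats$n == 0, arr.ind = TRUE)
    if (nrow(z)) {
      zero_pairs <- data.frame(prev = stats$carers[z[, 1]],
                               nxt = stats$carers[z[, 2]],
                               stringsAsFactors = FALSE)
      warnings <- c(warnings, sprintf(
        "%d carer pair(s) with zero observed transitions (full-model rates inestimable)",
        nrow(z)))
    }
  }
  structure(list(valid = valid, warnings = warnings,
                 low_count_carers = low, zero_transition_pairs = zero_pairs,
                 c = carer_set$c, turn_taking_possible = carer_set$c >= 2),
            class = "carer_validity")
}

#' @export
print.carer_validity <- function(x, ...) {
  cat("Valid for fitting:", x$valid, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Rank helpers by visit count
#'
#' Helpers are differentiated purely by visit rate: the most-visiting helper
#' is the primary helper (rank 1) and the least-visiting one is labelled
#' "terminal". Ties are broken by count then stable carer order, and are
#' recorded in the `tied_helpers` attribute. Breeders receive no rank.
#'
#' @param carer_set a [classify_significant()] result with class labels.
#' @return The carer set with `helper_rank` filled in and a logical
#'   `terminal` column.
#' @export
rank_helpers <- function(carer_set) {
  stopifnot(inherits(carer_set, "carer_set"))
  ca <- carer_set$carers
  ca$terminal <- FALSE
  h <- which(ca$class == "helper")
  if (length(h)) {
    ## carers already sorted by descending count then id, so rank in place
    ca$helper_rank[h] <- seq_along(h)
    ca$terminal[h[length(h)]] <- TRUE
    dup <- duplicated(ca$visit_count[h]) |
      duplicated(ca$visit_count[h], fromLast = TRUE)
    if (any(dup))
      attr(carer_set, "tied_helpers") <- ca$carer_id[h][dup]
  }
  carer_set$carers <- ca
  carer_set
}
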