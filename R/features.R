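#' Build per-test keypress time windows
#'
#' Assigns every digital Trail Making Test (dTMT-B) administration a half-open
#' time window `[window_start_ms, window_end_ms)` from which its proximal
#' keypresses are drawn. The boundary toward a neighbouring test taken at most
#' 24 h away is the midpoint of the two test timestamps; when the neighbour is
#' more than 24 h away (or absent) the window is clipped to the test's own
#' calendar date, except that on days with two recorded tests the outer
#' boundary is the test's own timestamp, so keypresses before the morning test
#' and after the evening test on such days are omitted. The midpoint rule
#' takes precedence over date clipping when both could apply.
#'
#' @param dtmts data frame with columns `subject_id`, `timestamp_ms`, `slot`
#'   (`"morning"`/`"evening"`); may contain further columns (ignored). Records
#'   must be sorted by timestamp within subject, with at most one record per
#'   subject, calendar date and slot.
#' @param tz timezone used to derive calendar dates (default `"UTC"`).
#' @return data frame with one row per test: `subject_id`,
#'   `dtmt_timestamp_ms`, `window_start_ms`, `window_end_ms`. Windows of one
#'   subject are pairwise disjoint and each contains its test's timestamp or
#'   abuts it (the evening test on a trailing two-test day ends at the test
#'   itself).
#' @export
build_windows <- function(dtmts, tz = "UTC") {
  required <- c("subject_id", "timestamp_ms", "slot")
  missing_cols <- setdiff(required, names(dtmts))
  if (length(missing_cols) > 0L) {
    stop_validation("dtmts lacks column(s): %s",
                    paste(missing_cols, collapse = ", "))
  }
  if (nrow(dtmts) == 0L) {
    return(data.frame(subject_id = character(), dtmt_timestamp_ms = numeric(),
                      window_start_ms = numeric(), window_end_ms = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- split(seq_len(nrow(dtmts)), dtmts$subject_id)
  out <- lapply(names(parts), function(sid) {
    idx <- parts[[sid]]
    t <- dtmts$timestamp_ms[idx]
    if (is.unsorted(t, strictly = FALSE)) {
      stop_validation("dTMT-B records for subject '%s' are not sorted by timestamp",
                      sid)
    }
    d <- day_number(t, tz)
    slot <- dtmts$slot[idx]
    if (anyDuplicated(paste(d, slot))) {
      stop_validation("duplicate (date, slot) dTMT-B record for subject '%s'", sid)
    }
    n <- length(t)
    two_test_day <- as.vector(table(d)[as.character(d)]) == 2L

    start <- numeric(n)
    end <- numeric(n)
    prev_gap <- c(Inf, diff(t))
    next_gap <- c(diff(t), Inf)
    for (i in seq_len(n)) {
      start[i] <- if (prev_gap[i] <= 24 * MS_PER_HOUR) {
        (t[i] + t[i - 1L]) / 2
      } else if (two_test_day[i]) {
        t[i]                               # morning test: pre-test keys omitted
      } else {
        day_start_ms(d[i], tz)
      }
      end[i] <- if (next_gap[i] <= 24 * MS_PER_HOUR) {
        (t[i] + t[i + 1L]) / 2
      } else if (two_test_day[i]) {
        t[i]                               # evening test: post-test keys omitted
      } else {
        day_start_ms(d[i] + 1, tz)
      }
    }
    keep <- start < end   # degenerate zero-length windows impossible by rules
    data.frame(subject_id = sid, dtmt_timestamp_ms = t,
               window_start_ms = start, window_end_ms = end,
               stringsAsFactors = FALSE)[keep, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign keypresses to time windows
#'
#' Each keypress lands in at most one window (windows of a subject are
#' disjoint); keypresses outside every window are dropped. A keypress at a
#' shared boundary belongs to the later window (half-open convention).
#'
#' @param windows output of [build_windows()].
#' @param keys data frame with `subject_id`, `timestamp_ms` (sorted within
#'   subject), and optionally `category`.
#' @return `windows` with an added `n_keypresses` column; the attribute
#'   `"keys"` holds `keys` restricted to assigned keypresses with a
#'   `window` column giving the row index into the returned windows.
#' @export
assign_keypresses <- function(windows, keys) {
  if (!all(c("subject_id", "timestamp_ms") %in% names(keys))) {
    stop_validation("keys needs columns subject_id and timestamp_ms")
  }
  extra <- setdiff(unique(keys$subject_id), unique(windows$subject_id))
  if (length(extra) > 0L) {
    stop_validation("keypresses reference subject(s) with no windows: %s",
                    paste(extra, collapse = ", "))
  }
  windows$n_keypresses <- 0L
  key_window <- rep(NA_integer_, nrow(keys))
  wmap <- split(seq_len(nrow(windows)), windows$subject_id)
  kmap <- split(seq_len(nrow(keys)), keys$subject_id)
  for (sid in names(wmap)) {
    widx <- wmap[[sid]]
    kidx <- kmap[[sid]]
    if (is.null(kidx)) next
    ord <- widx[order(windows$window_start_ms[widx])]
    bounds <- as.vector(rbind(windows$window_start_ms[ord],
                              windows$window_end_ms[ord]))
    pos <- findInterval(keys$timestamp_ms[kidx], bounds)
    inside <- pos %% 2L == 1L
    key_window[kidx[inside]] <- ord[(pos[inside] + 1L) %/% 2L]
  }
  counts <- tabulate(key_window, nbins = nrow(windows))
  windows$n_keypresses <- as.integer(counts)
  assigned <- !is.na(key_window)
  keys_out <- keys[assigned, , drop = FALSE]
  keys_out$window <- key_window[assigned]
  attr(windows, "keys") <- keys_out
  windows
}

#' Inter-key delays within a window
#'
#' The inter-key delay (IKD) is the time lapse between two consecutive
#' keypresses. Returns `n - 1` non-negative delays in seconds for `n`
#' keypresses (empty for fewer than two). Simultaneous timestamps yield a
#' zero delay; filtering happens downstream.
#'
#' @param keys_in_window data frame with `timestamp_ms` sorted ascending, or a
#'   numeric vector of millisecond timestamps.
#' @return numeric vector of delays in seconds.
#' @export
interkey_delays <- function(keys_in_window) {
  ts <- if (is.data.frame(keys_in_window)) keys_in_window$timestamp_ms
        else keys_in_window
  if (length(ts) <= 1L) return(numeric(0))
  diff(ts) / 1000
}

#' Median inter-key delay of a window
#'
#' Delays at or above the session cutoff (8 s, the established end of a typing
#' session) are discarded; if fewer than `min_transitions` (20) valid
#' transitions remain the window has no typing-speed feature and `NA` is
#' returned. Otherwise the sample median (mean of the middle two for even
#' counts) of the surviving delays, in seconds.
#'
#' @param delays numeric vector of delays in seconds (from
#'   [interkey_delays()]).
#' @param cutoff session cutoff in seconds; delays `>= cutoff` are dropped.
#' @param min_transitions minimum number of valid transitions.
#' @return median IKD in seconds, or `NA_real_`.
#' @export
median_ikd <- function(delays, cutoff = 8, min_transitions = 20L) {
  valid <- delays[delays < cutoff]
  if (length(valid) < min_transitions) return(NA_real_)
  stats::median(valid)
}

#' Compute typing features for every window
#'
#' Runs [assign_keypresses()], then per window [interkey_delays()] and
#' [median_ikd()].
#'
#' @inheritParams assign_keypresses
#' @param cutoff,min_transitions passed to [median_ikd()].
#' @param categories either `"all"` (default: IKDs computed across all key
#'   categories, including backspaces and autocorrections) or a character
#'   vector of categories to retain before computing delays.
#' @return `windows` with `n_keypresses`, `n_valid_transitions` and
#'   `median_ikd_s` columns.
#' @export
compute_window_features <- function(windows, keys, cutoff = 8,
                                    min_transitions = 20L,
                                    categories = "all") {
  if (!identical(categories, "all")) {
    if (!"category" %in% names(keys)) {
      stop_validation("category filtering requested but keys has no category column")
    }
    keys <- keys[keys$category %in% categories, , drop = FALSE]
  }
  windows <- assign_keypresses(windows, keys)
  akeys <- attr(windows, "keys")
  windows$n_valid_transitions <- 0L
  windows$median_ikd_s <- NA_real_
  if (nrow(akeys) > 0L) {
    ord <- order(akeys$window, akeys$timestamp_ms)
    w <- akeys$window[ord]
    dt <- diff(akeys$timestamp_ms[ord]) / 1000
    same <- diff(w) == 0L
    dl <- split(dt[same], w[-1L][same])
    for (wid in names(dl)) {
      i <- as.integer(wid)
      delays <- dl[[wid]]
      windows$n_valid_transitions[i] <- sum(delays < cutoff)
      windows$median_ikd_s[i] <- median_ikd(delays, cutoff, min_transitions)
    }
  }
  attr(windows, "keys") <- akeys
  windows
}

#' Apply the study inclusion filters
#'
#' Windows need at least `min_keypresses` keypresses and a valid median IKD
#' (itself requiring at least 20 valid transitions); subjects then need at
#' least `min_tests` surviving tests. Counts dropped at each stage are
#' attached as the `"drop_log"` attribute.
#'
#' @param windows output of [compute_window_features()].
#' @param min_keypresses minimum keypresses per window (default 20).
#' @param min_tests minimum surviving tests per subject (default 6).
#' @return list with `windows` (kept rows) and `subjects` (kept subject ids);
#'   attribute `"drop_log"` records counts.
#' @export
apply_inclusion_filters <- function(windows, min_keypresses = 20L,
                                    min_tests = 6L) {
  n0 <- nrow(windows)
  keep <- windows$n_keypresses >= min_keypresses & !is.na(windows$median_ikd_s)
  w1 <- windows[keep, , drop = FALSE]
  dropped_windows <- n0 - nrow(w1)
  tab <- table(w1$subject_id)
  good <- names(tab)[tab >= min_tests]
  w2 <- w1[w1$subject_id %in% good, , drop = FALSE]
  res <- list(windows = w2, subjects = good)
  attr(res, "drop_log") <- list(
    windows_in = n0,
    windows_dropped_feature_filters = dropped_windows,
    subjects_in = length(unique(windows$subject_id)),
    subjects_dropped_min_tests =
      length(unique(windows$subject_id)) - length(good),
    windows_dropped_with_subjects = nrow(w1) - nrow(w2),
    windows_out = nrow(w2))
  res
}
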