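EVENT_COLUMNS <- c("person_id", "seq", "timestamp_ms", "kind", "page_id",
                   "page_kind", "task_id", "item_id", "option_id")

#' Parse a raw assessment event log
#'
#' Reads the delimited event log (one row per logged navigation or
#' response-option selection), validates it, sorts each person's events by
#' timestamp with ties broken by the log sequence number, and collects
#' malformed rows in a rejects report.
#'
#' Mandatory columns: `person_id`, `seq`, `timestamp_ms`, `kind` (`navigate`
#' or `select_option`), `page_id`, `page_kind` (`text`/`item`/`other`),
#' `task_id`, `item_id`, `option_id`. Missing values are empty fields.
#'
#' @param path file path (or a data frame already holding the columns).
#' @return data frame of class `dlc_events`; the rejects report (a data
#'   frame with a `reject_reason` column) is in `attr(x, "rejects")`.
#' @export
parse_event_log <- function(path) {
  d <- if (is.data.frame(path)) path
       else utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                            colClasses = "character")
  miss <- setdiff(EVENT_COLUMNS, names(d))
  if (length(miss))
    stop("event log misses mandatory columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- d[EVENT_COLUMNS]
  d$seq <- suppressWarnings(as.integer(d$seq))
  d$timestamp_ms <- suppressWarnings(as.numeric(d$timestamp_ms))
  reason <- rep(NA_character_, nrow(d))
  bad <- is.na(d$timestamp_ms) | is.na(d$seq)
  reason[bad] <- "missing or non-numeric timestamp/seq"
  k <- !bad & !(d$kind %in% c("navigate", "select_option"))
  reason[k] <- "unknown event kind"
  k <- is.na(reason) & d$kind == "navigate" & (is.na(d$page_id) |
         !(d$page_kind %in% c("text", "item", "other")))
  reason[k] <- "navigation without valid page"
  k <- is.na(reason) & d$kind == "select_option" &
       (is.na(d$item_id) | is.na(d$option_id))
  reason[k] <- "selection without item/option id"
  rejects <- d[!is.na(reason), , drop = FALSE]
  rejects$reject_reason <- reason[!is.na(reason)]
  d <- d[is.na(reason), , drop = FALSE]
  d <- d[order(d$person_id, d$timestamp_ms, d$seq), , drop = FALSE]
  if (anyDuplicated(d[c("person_id", "timestamp_ms", "seq")]))
    stop("unsortable events: duplicated (person, timestamp, seq)",
         call. = FALSE)
  rownames(d) <- NULL
  class(d) <- c("dlc_events", "data.frame")
  attr(d, "rejects") <- rejects
  d
}

# ordering of pages used to decide navigation direction; numeric page ids
# order numerically, otherwise lexicographically
page_order <- function(page_id) {
  num <- suppressWarnings(as.numeric(page_id))
  if (!anyNA(num)) num else match(page_id, sort(unique(page_id)))
}

#' Filter pass-through navigation events
#'
#' Removes navigation events whose resulting page visit lasts less than
#' `min_dwell_ms` *and* is immediately followed by a further navigation
#' continuing in the same direction within the same task (forward-forward or
#' backward-backward page order) — i.e. intermediate steps of paging through
#' the booklet that do not reflect an intention to stay. Selection events are
#' never removed. Applied repeatedly until a fixed point, so the operation is
#' idempotent; `min_dwell_ms = 0` is the identity.
#'
#' @param events a `dlc_events` data frame (per-person time-sorted).
#' @param min_dwell_ms dwell threshold in milliseconds (default 1000).
#' @return filtered `dlc_events`.
#' @export
filter_navigation <- function(events, min_dwell_ms = 1000) {
  stopifnot(min_dwell_ms >= 0)
  repeat {
    drop <- filter_pass(events, min_dwell_ms)
    if (!any(drop)) break
    att <- attr(events, "rejects")
    events <- events[!drop, , drop = FALSE]
    rownames(events) <- NULL
    class(events) <- c("dlc_events", "data.frame")
    attr(events, "rejects") <- att
  }
  events
}

filter_pass <- function(events, min_dwell_ms) {
  drop <- rep(FALSE, nrow(events))
  if (min_dwell_ms <= 0 || !nrow(events)) return(drop)
  ord <- page_order(events$page_id)
  for (pp in split(seq_len(nrow(events)), events$person_id)) {
    nav <- pp[events$kind[pp] == "navigate"]
    if (length(nav) < 3) next
    t <- events$timestamp_ms[nav]
    o <- ord[nav]
    task <- events$task_id[nav]
    n <- length(nav)
    # direction of the move into visit i (from visit i-1)
    dir_in <- c(NA, ifelse(task[-1] == task[-n], sign(o[-1] - o[-n]), NA))
    dur <- c(diff(t), Inf)              # last visit has no leaving click
    i <- 2:(n - 1)
    bad <- dur[i] < min_dwell_ms &
      !is.na(dir_in[i]) & !is.na(dir_in[i + 1]) &
      dir_in[i] == dir_in[i + 1] & dir_in[i] != 0
    drop[nav[i][bad]] <- TRUE
  }
  drop
}

#' Build page visits from navigation events
#'
#' Consecutive navigation events of a person delimit page visits: a visit
#' starts with the click that led to the page and ends with the click that
#' leaves it. The final visit, which has no leaving click, is closed at the
#' person's last logged event and flagged `unterminated`. Selection events
#' are attributed to the visit containing their timestamp; a selection before
#' any visit raises an attribution warning and is dropped from visit
#' attribution.
#'
#' @param events a (filtered) `dlc_events` data frame.
#' @return data frame of class `dlc_visits` with columns `person_id`,
#'   `page_id`, `page_kind`, `task_id`, `item_id`, `t_start`, `t_end`,
#'   `duration`, `unterminated`.
#' @export
build_page_visits <- function(events) {
  out <- lapply(split(seq_len(nrow(events)), events$person_id), function(pp) {
    nav <- pp[events$kind[pp] == "navigate"]
    if (!length(nav)) return(NULL)
    t <- events$timestamp_ms[nav]
    t_end <- c(t[-1], max(events$timestamp_ms[pp]))
    sel <- pp[events$kind[pp] == "select_option"]
    if (length(sel) && any(events$timestamp_ms[sel] < t[1]))
      warning("selection event before any page visit for person ",
              events$person_id[pp[1]], "; dropped from attribution",
              call. = FALSE)
    data.frame(person_id = events$person_id[nav],
               page_id = events$page_id[nav],
               page_kind = events$page_kind[nav],
               task_id = events$task_id[nav],
               item_id = events$item_id[nav],
               t_start = t, t_end = t_end, duration = t_end - t,
               unterminated = c(rep(FALSE, length(nav) - 1L), TRUE),
               stringsAsFactors = FALSE)
  })
  v <- do.call(rbind, out)
  rownames(v) <- NULL
  class(v) <- c("dlc_visits", "data.frame")
  v
}

#' Item response time from page visits
#'
#' Sum of the durations of all of a person's visits to the item's page, in
#' seconds; `NA` when the page was never visited.
#'
#' @param visits a `dlc_visits` data frame.
#' @param person,item identifiers.
#' @return seconds or `NA`.
#' @export
response_time <- function(visits, person, item) {
  d <- visits$duration[visits$person_id == person &
                       !is.na(visits$item_id) & visits$item_id == item &
                       visits$page_kind == "item"]
  if (!length(d)) return(NA_real_)
  sum(d) / 1000
}

#' Count answer changes
#'
#' A change is a selection of a response option *different* from the one
#' previously selected on the same item; the first selection never counts and
#' re-clicking the same option never counts.
#'
#' @param events a (filtered) `dlc_events` data frame.
#' @param person,item identifiers.
#' @return count.
#' @export
count_answer_changes <- function(events, person, item) {
  s <- events[events$kind == "select_option" & events$person_id == person &
              events$item_id == item, , drop = FALSE]
  if (nrow(s) < 2) return(0L)
  sum(s$option_id[-1] != s$option_id[-nrow(s)])
}

#' Count text rereads
#'
#' A reread is a navigation whose origin is the item's page and whose
#' destination is a text page of the same task. A subsequent hop between two
#' pages of a long text is not counted again (the outgoing transition from
#' the item page is what counts).
#'
#' @param events a (filtered) `dlc_events` data frame.
#' @param person,item identifiers.
#' @return count.
#' @export
count_text_rereads <- function(events, person, item) {
  nav <- events[events$kind == "navigate" & events$person_id == person, ,
                drop = FALSE]
  if (nrow(nav) < 2) return(0L)
  n <- nrow(nav)
  from_item <- nav$page_kind[-n] == "item" & !is.na(nav$item_id[-n]) &
    nav$item_id[-n] == item
  to_text <- nav$page_kind[-1] == "text" & nav$task_id[-1] == nav$task_id[-n]
  sum(from_item & to_text)
}

#' Count item revisits
#'
#' A revisit requires all three of: the person navigated to the item's page;
#' it was not the first visit; and at least one *other item* was visited
#' since the last visit to this item (so that returning from a text reread is
#' not a revisit).
#'
#' @param visits a `dlc_visits` data frame (time-ordered per person).
#' @param person,item identifiers.
#' @return count.
#' @export
count_item_revisits <- function(visits, person, item) {
  v <- visits[visits$person_id == person & visits$page_kind == "item", ,
              drop = FALSE]
  v <- v[order(v$t_start), , drop = FALSE]
  idx <- which(!is.na(v$item_id) & v$item_id == item)
  if (length(idx) < 2) return(0L)
  cnt <- 0L
  for (k in 2:length(idx)) {
    between <- v$item_id[(idx[k - 1] + 1):(idx[k] - 1)]
    if (idx[k] - idx[k - 1] > 1 && any(between != item, na.rm = TRUE))
      cnt <- cnt + 1L
  }
  cnt
}

#' Dichotomize an indicator count
#'
#' 1 if the behavior occurred at least once, 0 if it did not; missing
#' propagates.
#'
#' @param count non-negative count (vectorized).
#' @return 0/1/NA.
#' @export
dichotomize <- function(count) {
  if (any(count < 0, na.rm = TRUE))
    stop("counts must be non-negative", call. = FALSE)
  ifelse(is.na(count), NA_real_, as.numeric(count >= 1))
}

#' Extract all encounter-level indicators from an event log
#'
#' Applies the navigation filter, builds page visits, and computes response
#' time and the three indicator counts for every person-by-item encounter
#' that appears in the (filtered) log.
#'
#' @param events a `dlc_events` data frame (output of [parse_event_log()]).
#' @param min_dwell_ms navigation-filter dwell threshold; see
#'   [filter_navigation()].
#' @return data frame of class `dlc_indicator_counts` with columns
#'   `person_id`, `item_id`, `rt_seconds`, `n_answer_change`,
#'   `n_text_reread`, `n_item_revisit`, `visited`.
#' @export
indicator_counts <- function(events, min_dwell_ms = 1000) {
  fe <- filter_navigation(events, min_dwell_ms)
  visits <- build_page_visits(fe)
  iv <- visits[visits$page_kind == "item" & !is.na(visits$item_id), ,
               drop = FALSE]
  keys <- unique(rbind(
    iv[c("person_id", "item_id")],
    fe[fe$kind == "select_option" & !is.na(fe$item_id),
       c("person_id", "item_id")]))
  keys <- keys[order(keys$person_id, keys$item_id), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(r) {
    p <- keys$person_id[r]; it <- keys$item_id[r]
    rt <- response_time(visits, p, it)
    data.frame(person_id = p, item_id = it, rt_seconds = rt,
               n_answer_change = count_answer_changes(fe, p, it),
               n_text_reread = count_text_rereads(fe, p, it),
               n_item_revisit = count_item_revisits(visits, p, it),
               visited = !is.na(rt), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("dlc_indicator_counts", "data.frame")
  out
}

#' Join extracted indicators with scored responses
#'
#' Merges the indicator counts with the scored responses (long format:
#' `person_id`, `item_id`, `y`) into the model-side encounter table,
#' applying the missing rule — when the response time is missing or does not
#' exceed zero seconds, all four process-data indicators are set missing —
#' and computing `log_rt` and the dichotomized flags.
#'
#' @param counts a `dlc_indicator_counts` data frame.
#' @param responses data frame with `person_id`, `item_id`, `y`.
#' @param bank an [item_bank()].
#' @return a [dlc_data()] ready for fitting.
#' @export
assemble_encounters <- function(counts, responses, bank) {
  stopifnot(all(c("person_id", "item_id", "y") %in% names(responses)))
  responses$person_id <- as.character(responses$person_id)
  responses$item_id <- as.character(responses$item_id)
  if (anyDuplicated(counts[c("person_id", "item_id")]))
    stop("duplicate person x item rows in indicator counts", call. = FALSE)
  if (anyDuplicated(responses[c("person_id", "item_id")]))
    stop("duplicate person x item rows in responses", call. = FALSE)
  m <- merge(responses[c("person_id", "item_id", "y")],
             as.data.frame(counts), by = c("person_id", "item_id"),
             all = TRUE)
  enc <- data.frame(person_id = m$person_id, item_id = m$item_id, y = m$y,
                    rt_seconds = m$rt_seconds,
                    ac_count = m$n_answer_change,
                    tr_count = m$n_text_reread,
                    iv_count = m$n_item_revisit, stringsAsFactors = FALSE)
  enc <- enc[enc$item_id %in% bank$item_id, , drop = FALSE]
  dlc_data(dlc_encounters(enc), bank)
}

#' Per-item descriptive summary of an encounter table
#'
#' The layout of the classic descriptive table: encounters per item, mean
#' and SD of the response time, percent correct, and the percentage of
#' encounters on which each indicator occurred at least once.
#'
#' @param data a [dlc_data()] (or `dlc_encounters`).
#' @return data frame, one row per item.
#' @export
encounter_summary <- function(data) {
  enc <- if (inherits(data, "dlc_data")) data$encounters else data
  do.call(rbind, lapply(split(as.data.frame(enc), enc$item_id), function(d)
    data.frame(item_id = d$item_id[1],
               n = sum(!is.na(d$y)),
               rt_mean = mean(d$rt_seconds, na.rm = TRUE),
               rt_sd = stats::sd(d$rt_seconds, na.rm = TRUE),
               pct_correct = mean(d$y, na.rm = TRUE) * 100,
               pct_ac = mean(d$ac, na.rm = TRUE) * 100,
               pct_tr = mean(d$tr, na.rm = TRUE) * 100,
               pct_iv = mean(d$iv, na.rm = TRUE) * 100,
               stringsAsFactors = FALSE))) -> s
  s <- s[order(suppressWarnings(as.numeric(s$item_id)), s$item_id), ,
         drop = FALSE]
  rownames(s) <- NULL
  s
}
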