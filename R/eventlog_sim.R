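#' Generate a raw event log realizing planted encounter-level ground truth
#'
#' Emits, for every person, a navigation/selection event stream whose
#' extraction by [indicator_counts()] (after the default navigation filter)
#' reproduces the planted response time and answer-change / text-reread /
#' item-revisit counts exactly. The construction per task:
#' \enumerate{
#'   \item task entry onto the text page (dwell);
#'   \item optionally a fast forward "scan" through all item pages to the
#'     task's end page and a jump back to the text — pure pass-through noise
#'     that the navigation filter removes;
#'   \item one working visit per visited item, containing the selection
#'     sequence (ac + 1 alternating options) and `tr` text-reread cycles;
#'   \item `iv` revisit rounds, scheduled so that between two visits to the
#'     same item at least one other item is always visited;
#'   \item the task end page.
#' }
#' The planted response time is split over the item's `1 + tr + iv` visits in
#' whole milliseconds, each visit at least 1200 ms (so no real visit can be
#' mistaken for pass-through noise); the plant is infeasible — and an error —
#' when `rt_seconds < 1.2 * (1 + tr + iv)` seconds, when a revisit is
#' requested for a single-item task, or when the revisit schedule cannot
#' avoid two adjacent visits to the same item.
#'
#' @param encounters data frame with `person_id`, `item_id`, `rt_seconds`
#'   (NA = never visited), `ac_count`, `tr_count`, `iv_count`, and optionally
#'   `y` (NA suppresses selections and requires `ac_count = 0`).
#' @param bank an [item_bank()].
#' @param tasks data frame `item_id`, `task_id` mapping items to tasks; page
#'   order follows the row order.
#' @param seed integer seed (dwell-time draws).
#' @param noise add the filterable pass-through scan for every person?
#' @return list with `events` (a `dlc_events` data frame), `achieved` (the
#'   realized ground truth; equals the plant), and `responses` (long scored
#'   responses, when `y` is present).
#' @export
simulate_event_log <- function(encounters, bank, tasks, seed, noise = TRUE) {
  stopifnot(all(c("person_id", "item_id", "rt_seconds", "ac_count",
                  "tr_count", "iv_count") %in% names(encounters)))
  if (!"y" %in% names(encounters)) encounters$y <- NA_integer_
  encounters$person_id <- as.character(encounters$person_id)
  encounters$item_id <- as.character(encounters$item_id)
  tasks$item_id <- as.character(tasks$item_id)

  # global numeric page ids ordered within and across tasks
  task_ids <- unique(tasks$task_id)
  pages <- do.call(rbind, lapply(seq_along(task_ids), function(k) {
    its <- tasks$item_id[tasks$task_id == task_ids[k]]
    data.frame(task_id = task_ids[k],
               page_id = as.character(1000 * k + seq_len(length(its) + 2L)),
               page_kind = c("text", rep("item", length(its)), "other"),
               item_id = c(NA, its, NA), stringsAsFactors = FALSE)
  }))

  bad <- is.na(encounters$y) & encounters$ac_count > 0 &
    !is.na(encounters$rt_seconds)
  if (any(bad, na.rm = TRUE))
    stop("infeasible plant: answer changes without a scored response",
         call. = FALSE)
  vis <- encounters[!is.na(encounters$rt_seconds), , drop = FALSE]
  V <- 1L + vis$tr_count + vis$iv_count
  if (any(round(vis$rt_seconds * 1000) < 1200 * V))
    stop("infeasible plant: response time too short for the requested visits",
         call. = FALSE)

  ev <- with_seed(seed, {
    do.call(rbind, lapply(split(vis, vis$person_id), function(pv)
      person_events(pv, pages, tasks, noise)))
  })
  rownames(ev) <- NULL
  class(ev) <- c("dlc_events", "data.frame")
  attr(ev, "rejects") <- ev[0, , drop = FALSE]
  resp <- encounters[!is.na(encounters$y),
                     c("person_id", "item_id", "y"), drop = FALSE]
  list(events = ev, achieved = encounters, responses = resp)
}

# events of one person; timestamps in ms starting at 0
person_events <- function(pv, pages, tasks, noise) {
  t <- 0
  seqn <- 0L
  rows <- list()
  emit <- function(kind, page = NULL, item = NA, option = NA) {
    seqn <<- seqn + 1L
    pg <- if (is.null(page)) data.frame(task_id = NA, page_id = NA,
                                        page_kind = NA, item_id = item)
          else page
    rows[[length(rows) + 1L]] <<- data.frame(
      person_id = pv$person_id[1], seq = seqn, timestamp_ms = t,
      kind = kind, page_id = pg$page_id, page_kind = pg$page_kind,
      task_id = pg$task_id, item_id = if (kind == "select_option") item
                                      else pg$item_id,
      option_id = option, stringsAsFactors = FALSE)
  }
  page_of <- function(item) pages[!is.na(pages$item_id) &
                                  pages$item_id == item, , drop = FALSE]
  for (tk in unique(tasks$task_id)) {
    items <- tasks$item_id[tasks$task_id == tk]
    tv <- pv[pv$item_id %in% items, , drop = FALSE]
    if (!nrow(tv)) next
    tv <- tv[match(items[items %in% tv$item_id], tv$item_id), , drop = FALSE]
    # work on the revisit-heavy items first, so the last-worked item has the
    # fewest pending revisits and the schedule can always open elsewhere
    tv <- tv[order(-tv$iv_count, seq_len(nrow(tv))), , drop = FALSE]
    if (any(tv$iv_count > 0) && nrow(tv) < 2)
      stop("infeasible plant: item revisit in a single-item task",
           call. = FALSE)
    tpages <- pages[pages$task_id == tk, , drop = FALSE]
    text_pg <- tpages[tpages$page_kind == "text", , drop = FALSE][1, ]
    end_pg <- tpages[tpages$page_kind == "other", , drop = FALSE][1, ]

    emit("navigate", text_pg); t <- t + round(stats::runif(1, 1500, 5000))
    if (noise && nrow(tv) >= 2) {
      # fast forward scan in page order; every hop continues forward and
      # stays under the dwell threshold, so the filter removes it
      for (it in items[items %in% tv$item_id]) {
        emit("navigate", page_of(it)); t <- t + 300
      }
      emit("navigate", end_pg); t <- t + 1500
      emit("navigate", text_pg); t <- t + round(stats::runif(1, 1500, 3000))
    }

    # per-item visit-duration segments (ms): 1 + tr + iv parts, each >= 1200
    segs <- lapply(seq_len(nrow(tv)), function(r) {
      V <- 1L + tv$tr_count[r] + tv$iv_count[r]
      tot <- round(tv$rt_seconds[r] * 1000)
      extra <- tot - 1200L * V
      add <- if (V == 1L) extra
             else drop(stats::rmultinom(1, extra, rep(1 / V, V)))
      1200L + add
    })
    used <- integer(nrow(tv))       # segments consumed per item

    for (r in seq_len(nrow(tv))) {
      it <- tv$item_id[r]
      pg <- page_of(it)
      emit("navigate", pg)
      seg <- segs[[r]][1]; used[r] <- 1L
      n_sel <- if (!is.na(tv$y[r])) tv$ac_count[r] + 1L else 0L
      if (n_sel > 0) {
        final <- if (tv$y[r] == 1) "o1" else "o2"
        other <- if (final == "o2") "o1" else "o3"
        opts <- rev(rep_len(c(final, other), n_sel))
        off <- 100L + (seq_len(n_sel) - 1L) * 50L
        stopifnot(max(off) < seg)
        t0 <- t
        for (s in seq_len(n_sel)) { t <- t0 + off[s]; emit("select_option", item = it, option = opts[s]) }
        t <- t0
      }
      t <- t + seg
      if (tv$tr_count[r] > 0) {
        for (k in seq_len(tv$tr_count[r])) {
          emit("navigate", text_pg); t <- t + round(stats::runif(1, 1500, 4000))
          emit("navigate", pg)
          used[r] <- used[r] + 1L
          t <- t + segs[[r]][used[r]]
        }
      }
    }

    # revisit schedule: no two adjacent equal, first differs from the last
    # working item
    slots <- rep(tv$item_id, tv$iv_count)
    if (length(slots)) {
      sched <- schedule_revisits(slots, last = tv$item_id[nrow(tv)])
      for (it in sched) {
        r <- match(it, tv$item_id)
        emit("navigate", page_of(it))
        used[r] <- used[r] + 1L
        t <- t + segs[[r]][used[r]]
      }
    }
    emit("navigate", end_pg); t <- t + 1500
  }
  do.call(rbind, rows)
}

# greedy most-remaining-first arrangement with adjacency constraint
schedule_revisits <- function(slots, last) {
  out <- character(0)
  remaining <- table(slots)
  prev <- last
  while (sum(remaining) > 0) {
    cand <- names(remaining)[remaining > 0 & names(remaining) != prev]
    if (!length(cand))
      stop("infeasible plant: revisit schedule forces adjacent visits to one item",
           call. = FALSE)
    pick <- cand[which.max(remaining[cand])]
    out <- c(out, pick)
    remaining[pick] <- remaining[pick] - 1L
    prev <- pick
  }
  out
}

#' Draw a randomized, feasible set of encounter plants
#'
#' Utility for round-trip testing of the extraction pipeline: draws
#' answer-change / text-reread / item-revisit counts and responses for every
#' person-by-item encounter, then draws a response time guaranteed to be
#' long enough for the implied number of page visits.
#'
#' @param n_persons number of persons.
#' @param bank an [item_bank()].
#' @param tasks item-to-task map as in [simulate_event_log()].
#' @param seed integer seed.
#' @return encounter plant data frame accepted by [simulate_event_log()].
#' @export
simulate_plants <- function(n_persons, bank, tasks, seed) {
  with_seed(seed, {
    grid <- expand.grid(i = seq_len(n_persons), j = seq_len(nrow(bank)))
    n <- nrow(grid)
    task_size <- table(tasks$task_id)[tasks$task_id[match(bank$item_id[grid$j],
                                                          tasks$item_id)]]
    d <- data.frame(person_id = sprintf("p%04d", grid$i),
                    item_id = bank$item_id[grid$j],
                    ac_count = stats::rbinom(n, 1, 0.14) *
                      (1L + stats::rgeom(n, 0.55)),
                    tr_count = stats::rbinom(n, 1, 0.33) *
                      (1L + stats::rgeom(n, 0.58)),
                    iv_count = ifelse(task_size >= 2,
                                      stats::rbinom(n, 1, 0.07) *
                                        (1L + stats::rgeom(n, 0.90)), 0L),
                    y = stats::rbinom(n, 1, 0.55),
                    stringsAsFactors = FALSE)
    # trim revisit counts until every person-by-task schedule is realizable
    tmap <- tasks$task_id[match(d$item_id, tasks$item_id)]
    for (key in unique(paste(d$person_id, tmap))) {
      idx <- which(paste(d$person_id, tmap) == key)
      repeat {
        iv <- d$iv_count[idx]
        if (sum(iv) == 0) break
        ord <- order(-iv, seq_along(idx))
        slots <- rep(d$item_id[idx][ord], iv[ord])
        ok <- !inherits(tryCatch(
          schedule_revisits(slots, last = d$item_id[idx][ord][length(idx)]),
          error = function(e) e), "error")
        if (ok) break
        w <- which.max(iv)
        d$iv_count[idx][w] <- iv[w] - 1L
      }
    }
    V <- 1L + d$tr_count + d$iv_count
    d$rt_seconds <- round(1.3 * V + stats::rlnorm(n, log(12), 0.6), 3)
    miss <- stats::runif(n) < 0.02
    d$rt_seconds[miss] <- NA_real_
    d$y[miss] <- NA_integer_
    d$ac_count[miss] <- 0L; d$tr_count[miss] <- 0L; d$iv_count[miss] <- 0L
    d[order(d$person_id, as.numeric(d$item_id)), , drop = FALSE]
  })
}

#' Write / read an event log as delimited text
#'
#' @param events a `dlc_events` data frame.
#' @param path file path.
#' @export
write_event_log <- function(events, path) {
  utils::write.csv(as.data.frame(events)[EVENT_COLUMNS], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
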