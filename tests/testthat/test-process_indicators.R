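test_that("parse_event_log validates, sorts and reports rejects", {
  ev <- hand_events()
  expect_s3_class(ev, "dlc_events")
  expect_identical(nrow(ev), 10L)
  expect_true(all(diff(ev$timestamp_ms) >= 0))
  expect_identical(nrow(attr(ev, "rejects")), 0L)

  # empty log with header
  tf <- tempfile(fileext = ".csv")
  writeLines(paste(dlcirt:::EVENT_COLUMNS, collapse = ","), tf)
  e0 <- parse_event_log(tf)
  expect_identical(nrow(e0), 0L)

  # malformed selection row goes to the rejects report
  d <- as.data.frame(hand_events())
  d$option_id[3] <- NA
  e1 <- parse_event_log(d)
  expect_identical(nrow(e1), 9L)
  rej <- attr(e1, "rejects")
  expect_identical(nrow(rej), 1L)
  expect_match(rej$reject_reason, "selection")

  d2 <- as.data.frame(hand_events())[, -3]
  expect_error(parse_event_log(d2), "mandatory columns")
})

test_that("page visits delimit on navigation clicks and flag the open tail", {
  visits <- build_page_visits(hand_events())
  expect_identical(nrow(visits), 7L)   # 7 navigation events -> 7 visits
  i1 <- visits[visits$page_kind == "item" & visits$item_id == "1", ]
  expect_identical(nrow(i1), 3L)                 # two working + one revisit
  expect_equal(i1$duration, c(10000, 4000, 2000))
  expect_true(all(visits$duration >= 0))
  expect_identical(sum(visits$unterminated), 1L)
  expect_true(visits$unterminated[nrow(visits)])
  # per-person visit spans stay within the session span
  expect_lte(sum(visits$duration), diff(range(hand_events()$timestamp_ms)))
})

test_that("response_time sums all visits to the item page", {
  visits <- build_page_visits(hand_events())
  expect_equal(response_time(visits, "p1", "1"), 16)
  expect_equal(response_time(visits, "p1", "2"), 6)
  expect_true(is.na(response_time(visits, "p1", "99")))
})

test_that("answer changes count only switches to a different option", {
  ev <- hand_events()
  expect_identical(count_answer_changes(ev, "p1", "1"), 1L)  # o2 -> o1 -> o1
  expect_identical(count_answer_changes(ev, "p1", "2"), 0L)
  sel <- function(opts) {
    d <- data.frame(person_id = "q", seq = seq_along(opts),
                    timestamp_ms = seq_along(opts) * 1000,
                    kind = "select_option", page_id = NA, page_kind = NA,
                    task_id = "T1", item_id = "7", option_id = opts,
                    stringsAsFactors = FALSE)
    parse_event_log(d)
  }
  expect_identical(count_answer_changes(sel("A"), "q", "7"), 0L)
  expect_identical(count_answer_changes(sel(c("A", "B", "A")), "q", "7"), 2L)
  expect_identical(count_answer_changes(sel(c("A", "A", "B")), "q", "7"), 1L)
})

test_that("text rereads are item-to-text transitions, once per excursion", {
  ev <- hand_events()
  expect_identical(count_text_rereads(ev, "p1", "1"), 1L)
  expect_identical(count_text_rereads(ev, "p1", "2"), 0L)
  # two-page text: item -> text -> text -> item is still one reread
  d <- data.frame(person_id = "p9", seq = 1:5,
                  timestamp_ms = c(0, 5000, 10000, 13000, 16000),
                  kind = "navigate",
                  page_id = c("102", "100", "101", "100", "102"),
                  page_kind = c("item", "text", "text", "text", "item"),
                  task_id = "T1",
                  item_id = c("1", NA, NA, NA, "1"), option_id = NA,
                  stringsAsFactors = FALSE)
  expect_identical(count_text_rereads(parse_event_log(d), "p9", "1"), 1L)
})

test_that("item revisits require an intervening different item", {
  visits <- build_page_visits(hand_events())
  # item1 -> item2 -> item1 is one revisit; the text excursion return is not
  expect_identical(count_item_revisits(visits, "p1", "1"), 1L)
  expect_identical(count_item_revisits(visits, "p1", "2"), 0L)
  expect_lte(count_item_revisits(visits, "p1", "1"),
             sum(visits$item_id == "1", na.rm = TRUE) - 1L)
})

test_that("dichotomize maps counts to occurrence flags", {
  expect_identical(dichotomize(0), 0)
  expect_identical(dichotomize(3), 1)
  expect_identical(dichotomize(c(0, 1, NA, 5)), c(0, 1, NA, 1))
  expect_error(dichotomize(-1), "non-negative")
})

test_that("navigation filter removes directed pass-throughs and is idempotent", {
  # forward paging 1 -> 2 -> 3 in 300 ms each, then dwell on 4
  d <- data.frame(person_id = "p2", seq = 1:6,
                  timestamp_ms = c(0, 4000, 4300, 4600, 4900, 20000),
                  kind = "navigate",
                  page_id = c("101", "102", "103", "104", "105", "106"),
                  page_kind = c("text", "item", "item", "item", "item", "other"),
                  task_id = "T1",
                  item_id = c(NA, "1", "2", "3", "4", NA), option_id = NA,
                  stringsAsFactors = FALSE)
  ev <- parse_event_log(d)
  f <- filter_navigation(ev, 1000)
  expect_identical(f$page_id, c("101", "105", "106"))
  visits <- build_page_visits(f)
  expect_identical(visits$item_id[visits$page_kind == "item"], "4")
  expect_equal(response_time(visits, "p2", "4"), 15.1)
  # idempotence and the zero-threshold identity
  expect_identical(filter_navigation(f, 1000), f)
  expect_identical(filter_navigation(ev, 0), ev)
  # clean data are untouched
  evh <- hand_events()
  expect_identical(filter_navigation(evh, 1000), evh)
})

test_that("indicator extraction is isolated between persons", {
  ev1 <- hand_events("p1")
  both <- parse_event_log(rbind(as.data.frame(ev1),
                                as.data.frame(hand_events("p3"))))
  for (it in c("1", "2")) {
    expect_identical(count_answer_changes(both, "p1", it),
                     count_answer_changes(ev1, "p1", it))
    expect_identical(count_text_rereads(both, "p1", it),
                     count_text_rereads(ev1, "p1", it))
  }
  v1 <- build_page_visits(ev1)
  vb <- build_page_visits(both)
  expect_identical(count_item_revisits(vb, "p1", "1"),
                   count_item_revisits(v1, "p1", "1"))
  expect_equal(response_time(vb, "p1", "1"), response_time(v1, "p1", "1"))
})

test_that("assemble_encounters joins, applies the missing rule and summarizes", {
  ev <- hand_events()
  counts <- indicator_counts(ev, min_dwell_ms = 1000)
  bank <- item_bank(c("1", "2", "3"), c(4, 4, 4))
  responses <- data.frame(person_id = "p1", item_id = c("1", "2", "3"),
                          y = c(1, 0, NA), stringsAsFactors = FALSE)
  data <- assemble_encounters(counts, responses, bank)
  enc <- data$encounters
  expect_identical(nrow(enc), 3L)
  r1 <- enc[enc$item_id == "1", ]
  expect_equal(r1$rt_seconds, 16)
  expect_equal(r1$log_rt, log(16))
  expect_equal(c(r1$ac, r1$tr, r1$iv), c(1, 1, 1))
  # item 3 was never visited: all covariates missing
  r3 <- enc[enc$item_id == "3", ]
  expect_true(all(is.na(c(r3$rt_seconds, r3$log_rt, r3$ac, r3$tr, r3$iv))))
  # rt = 0 rows lose all four covariates
  enc0 <- dlc_encounters(data.frame(person_id = "a", item_id = "1", y = 1,
                                    rt_seconds = 0, ac_count = 2,
                                    tr_count = 1, iv_count = 0))
  expect_true(all(is.na(c(enc0$log_rt, enc0$ac, enc0$tr, enc0$iv))))
  # ln 20 spot value
  enc20 <- dlc_encounters(data.frame(person_id = "a", item_id = "1", y = 1,
                                     rt_seconds = 20, ac_count = 0,
                                     tr_count = 0, iv_count = 0))
  expect_equal(enc20$log_rt, 2.9957323, tolerance = 1e-6)
  s <- encounter_summary(data)
  expect_identical(nrow(s), 3L)
  expect_equal(s$rt_mean[s$item_id == "2"], 6)
  expect_error(assemble_encounters(counts,
                                   rbind(responses, responses[1, ]), bank),
               "duplicate")
})
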