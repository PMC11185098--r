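# Shared fixtures, built in code.

# tiny 5-person x 3-item toy with complete covariates
toy_data <- function(seed = 123, n = 5, J = 3) {
  ids <- as.character(seq_len(J))
  bank <- item_bank(ids, rep(4L, J), beta = seq(-0.5, 0.5, length.out = J))
  enc <- with_seed_test(seed, {
    g <- expand.grid(p = seq_len(n), j = seq_len(J))
    data.frame(person_id = sprintf("p%02d", g$p), item_id = ids[g$j],
               y = rbinom(nrow(g), 1, 0.6),
               rt_seconds = round(rlnorm(nrow(g), log(20), 0.5), 3),
               ac_count = rbinom(nrow(g), 1, 0.2),
               tr_count = rbinom(nrow(g), 1, 0.3),
               iv_count = rbinom(nrow(g), 1, 0.1),
               stringsAsFactors = FALSE)
  })
  dlc_data(dlc_encounters(enc), bank)
}

toy_tl_params <- function(bank) {
  dlc_params(beta = stats::setNames(bank$beta, bank$item_id),
             alpha0 = 0.5, gamma = c(log_rt = 0.4),
             var_theta = 1, sigma2_psi = 0.8, cov_psi_theta = 0.3)
}

toy_tl_spec <- function() dlc_spec("dlc_tl", covariates = "log_rt")

# local-seed evaluation that restores the caller's RNG state
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# hand-built event log: one person, one task, two items plus text page.
# Timeline (ms):
#   0     navigate text
#   5000  navigate item 1            (visit 1: 10 s)
#   7000  select o2 ; 8000 select o1 ; 8500 select o1   (1 answer change)
#   15000 navigate text              (text reread for item 1)
#   18000 navigate item 1            (visit 2: 4 s -> rt 14 s)
#   22000 navigate item 2            (visit: 6 s)
#   28000 navigate item 1            (revisit: item 2 in between; 2 s -> rt 16 s)
#   30000 navigate end page
hand_events <- function(person = "p1") {
  rows <- list(
    c("navigate", "101", "text", NA, NA),
    c("navigate", "102", "item", "1", NA),
    c("select_option", NA, NA, "1", "o2"),
    c("select_option", NA, NA, "1", "o1"),
    c("select_option", NA, NA, "1", "o1"),
    c("navigate", "101", "text", NA, NA),
    c("navigate", "102", "item", "1", NA),
    c("navigate", "103", "item", "2", NA),
    c("navigate", "102", "item", "1", NA),
    c("navigate", "104", "other", NA, NA))
  ts <- c(0, 5000, 7000, 8000, 8500, 15000, 18000, 22000, 28000, 30000)
  d <- data.frame(person_id = person, seq = seq_along(ts), timestamp_ms = ts,
                  kind = vapply(rows, `[[`, "", 1),
                  page_id = vapply(rows, `[[`, "", 2),
                  page_kind = vapply(rows, `[[`, "", 3),
                  task_id = "T1",
                  item_id = vapply(rows, `[[`, "", 4),
                  option_id = vapply(rows, `[[`, "", 5),
                  stringsAsFactors = FALSE)
  parse_event_log(d)
}
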