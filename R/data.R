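#' Item bank
#'
#' One row per item: identifier, number of response options `M` (>= 1), the
#' implied disengaged-class success probability `z = 1/M`, and optionally a
#' true difficulty `beta` (used by the simulator).
#'
#' @param item_id character vector of item ids.
#' @param n_options integer vector of response-option counts (>= 1).
#' @param beta optional numeric vector of difficulties.
#' @return data frame of class `dlc_item_bank`.
#' @export
item_bank <- function(item_id, n_options, beta = NULL) {
  item_id <- as.character(item_id)
  stopifnot(length(item_id) >= 1, !anyDuplicated(item_id),
            length(n_options) == length(item_id),
            all(n_options >= 1), all(n_options == round(n_options)))
  ib <- data.frame(item_id = item_id, n_options = as.integer(n_options),
                   z = 1 / as.integer(n_options), stringsAsFactors = FALSE)
  if (!is.null(beta)) {
    stopifnot(length(beta) == length(item_id), all(is.finite(beta)))
    ib$beta <- as.numeric(beta)
  }
  class(ib) <- c("dlc_item_bank", "data.frame")
  ib
}

#' Read / write an item bank as delimited text
#'
#' Columns: `item_id`, `n_options` (and optionally `beta`).
#'
#' @param path file path.
#' @param ib an item bank.
#' @export
read_item_bank <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(item_id = "character"))
  if (!all(c("item_id", "n_options") %in% names(d)))
    stop("item bank needs columns item_id, n_options", call. = FALSE)
  item_bank(d$item_id, d$n_options, beta = d$beta)
}

#' @rdname read_item_bank
#' @export
write_item_bank <- function(ib, path) {
  utils::write.csv(ib[setdiff(names(ib), "z")], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Build encounter records from a raw encounter table
#'
#' Takes one row per person-by-item encounter with the scored response, the
#' response time and the three indicator counts, and derives the model-side
#' quantities: `log_rt`, the dichotomized indicator flags `ac`, `tr`, `iv`,
#' and the missing-data rule — when `rt_seconds` is missing or does not
#' exceed zero, all four process-data covariates are set missing.
#'
#' @param df data frame with columns `person_id`, `item_id`, `y`,
#'   `rt_seconds`, `ac_count`, `tr_count`, `iv_count` (missing encoded as NA).
#' @return data frame of class `dlc_encounters`, sorted by person then item,
#'   with added columns `log_rt`, `ac`, `tr`, `iv`.
#' @export
dlc_encounters <- function(df) {
  need <- c("person_id", "item_id", "y", "rt_seconds",
            "ac_count", "tr_count", "iv_count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("encounter table misses columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$person_id <- as.character(df$person_id)
  df$item_id <- as.character(df$item_id)
  if (anyDuplicated(df[c("person_id", "item_id")]))
    stop("duplicate person_id x item_id rows in encounter table", call. = FALSE)
  ok_y <- is.na(df$y) | df$y %in% c(0, 1)
  if (!all(ok_y)) stop("y must be 0, 1 or missing", call. = FALSE)
  rt_ok <- !is.na(df$rt_seconds) & df$rt_seconds > 0
  df$log_rt <- ifelse(rt_ok, log(df$rt_seconds), NA_real_)
  df$ac <- ifelse(rt_ok, dichotomize(df$ac_count), NA_real_)
  df$tr <- ifelse(rt_ok, dichotomize(df$tr_count), NA_real_)
  df$iv <- ifelse(rt_ok, dichotomize(df$iv_count), NA_real_)
  df <- df[order(df$person_id, df$item_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("dlc_encounters", "data.frame")
  df
}

#' Read / write the encounter table
#'
#' Delimited text with columns `person_id`, `item_id`, `y`, `rt_seconds`,
#' `ac_count`, `tr_count`, `iv_count`; missing values are empty fields.
#'
#' @param path file path.
#' @param enc a `dlc_encounters` data frame (or raw encounter table).
#' @export
read_encounters <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                       colClasses = c(person_id = "character",
                                      item_id = "character"))
  dlc_encounters(d)
}

#' @rdname read_encounters
#' @export
write_encounters <- function(enc, path) {
  cols <- c("person_id", "item_id", "y", "rt_seconds",
            "ac_count", "tr_count", "iv_count")
  utils::write.csv(as.data.frame(enc)[cols], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Model-ready dataset
#'
#' Binds an encounter table to an item bank and validates the join. Validity
#' of individual encounters depends on the fitted spec (which covariates it
#' requires) and is resolved by [build_model_data()] at fit time.
#'
#' @param encounters a `dlc_encounters` data frame (or coercible).
#' @param bank a [item_bank()].
#' @return object of class `dlc_data`.
#' @export
dlc_data <- function(encounters, bank) {
  if (!inherits(encounters, "dlc_encounters"))
    encounters <- dlc_encounters(encounters)
  stopifnot(inherits(bank, "dlc_item_bank"))
  unknown <- setdiff(unique(encounters$item_id), bank$item_id)
  if (length(unknown))
    stop("encounters reference items absent from the bank: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(encounters = encounters, bank = bank), class = "dlc_data")
}

#' @export
print.dlc_data <- function(x, ...) {
  cat("DLC-IRT dataset:",
      length(unique(x$encounters$person_id)), "persons,",
      nrow(x$bank), "items,",
      nrow(x$encounters), "encounters\n")
  invisible(x)
}

# Encounter-level validity and index arrays for the likelihood code.
build_model_data <- function(spec, data) {
  stopifnot(inherits(spec, "dlc_spec"), inherits(data, "dlc_data"))
  enc <- data$encounters
  req <- spec_required_covariates(spec)
  valid <- !is.na(enc$y)
  for (v in req) valid <- valid & !is.na(enc[[v]])
  e <- enc[valid, , drop = FALSE]
  if (!nrow(e)) stop("no valid encounters for this spec", call. = FALSE)
  item_ids <- data$bank$item_id
  persons <- unique(e$person_id)
  pidx <- match(e$person_id, persons) - 1L
  jidx <- match(e$item_id, item_ids) - 1L
  X <- matrix(numeric(0), nrow(e), 0)
  if (spec$family != "rasch") {
    cols <- list(alpha0 = rep(1, nrow(e)))
    for (it in spec$intercept_items)
      cols[[paste0("alpha_item:", it)]] <- as.numeric(e$item_id == it)
    for (cv in spec$covariates) cols[[paste0("gamma:", cv)]] <- e[[cv]]
    for (ia in spec$interactions) {
      p <- strsplit(ia, ":", fixed = TRUE)[[1L]]
      cols[[paste0("gamma_int:", ia)]] <- e[[p[1]]] * e[[p[2]]]
    }
    X <- do.call(cbind, cols)
  }
  zvec <- data$bank$z[jidx + 1L]
  list(enc = e, persons = persons, item_ids = item_ids,
       pidx = pidx, jidx = jidx, y = as.integer(e$y), X = X, zvec = zvec,
       n_persons = length(persons), n_valid = nrow(e))
}

# md5 of the canonical serialized encounter table; guards model comparisons.
data_hash <- function(data) {
  stopifnot(inherits(data, "dlc_data"))
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  write_encounters(data$encounters, tf)
  unname(tools::md5sum(tf))
}
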