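COVARIATE_NAMES <- c("log_rt", "ac", "tr", "iv")

#' Declare a DLC-IRT model variant
#'
#' A model spec describes which member of the model family to fit:
#' \describe{
#'   \item{`rasch`}{plain Rasch model, no engagement mixture.}
#'   \item{`dlc`}{two-class mixture; class membership regressed on covariates
#'     with a single general intercept.}
#'   \item{`dlc_sl`}{adds item-specific engagement intercepts (dummy offsets
#'     relative to the retained general intercept) for `intercept_items`.}
#'   \item{`dlc_tl`}{adds a person-level random engagement threshold psi,
#'     correlated with ability theta.}
#' }
#'
#' @param family one of `"rasch"`, `"dlc"`, `"dlc_sl"`, `"dlc_tl"`.
#' @param intercept_items character vector of item ids receiving item-specific
#'   engagement intercepts (families `dlc_sl`/`dlc_tl` only).
#' @param covariates ordered subset of `c("log_rt", "ac", "tr", "iv")`.
#' @param interactions character vector of pairs `"a:b"` between covariates
#'   present in `covariates`.
#' @param z_mode `"fixed_reciprocal"` (guessing probability fixed at 1/M per
#'   item) or `"equal_free"` (one shared, freely estimated probability — the
#'   sensitivity analysis).
#' @param theta_variance_mode `"free"` (default; the convention under which
#'   the published model-comparison parameter counts are reproduced) or
#'   `"fixed_1"`.
#' @return object of class `dlc_spec`.
#' @seealso [spec_menu()] for the six standard variants, [fit_dlc()].
#' @export
dlc_spec <- function(family = c("rasch", "dlc", "dlc_sl", "dlc_tl"),
                     intercept_items = character(),
                     covariates = character(),
                     interactions = character(),
                     z_mode = c("fixed_reciprocal", "equal_free"),
                     theta_variance_mode = c("free", "fixed_1")) {
  family <- match.arg(family)
  z_mode <- match.arg(z_mode)
  theta_variance_mode <- match.arg(theta_variance_mode)
  intercept_items <- as.character(intercept_items)
  covariates <- as.character(covariates)
  interactions <- as.character(interactions)

  if (family == "rasch") {
    if (length(covariates) || length(interactions) || length(intercept_items))
      stop("family 'rasch' admits no covariates, interactions or intercept items",
           call. = FALSE)
  } else {
    if (!length(covariates))
      stop("mixture families need at least one covariate", call. = FALSE)
  }
  if (family == "dlc" && length(intercept_items))
    stop("family 'dlc' has a common intercept only; use 'dlc_sl'/'dlc_tl'",
         call. = FALSE)
  bad <- setdiff(covariates, COVARIATE_NAMES)
  if (length(bad))
    stop("unknown covariates: ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(covariates)) stop("duplicated covariates", call. = FALSE)
  for (ia in interactions) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !all(parts %in% covariates) || parts[1] == parts[2])
      stop("interaction '", ia, "' is not a pair of distinct present covariates",
           call. = FALSE)
  }
  if (anyDuplicated(normalize_interactions(interactions)))
    stop("duplicated interactions", call. = FALSE)

  structure(list(family = family,
                 intercept_items = intercept_items,
                 covariates = covariates,
                 interactions = normalize_interactions(interactions),
                 z_mode = z_mode,
                 theta_variance_mode = theta_variance_mode),
            class = "dlc_spec")
}

normalize_interactions <- function(interactions) {
  vapply(interactions, function(ia) {
    parts <- sort(strsplit(ia, ":", fixed = TRUE)[[1L]])
    paste(parts, collapse = ":")
  }, character(1), USE.NAMES = FALSE)
}

all_pairwise_interactions <- function(covariates) {
  if (length(covariates) < 2) return(character())
  cb <- utils::combn(covariates, 2)
  normalize_interactions(apply(cb, 2, paste, collapse = ":"))
}

#' The six standard model variants
#'
#' Returns the spec for one of the six models of the published model-comparison
#' table: the Rasch model, the DLC-IRT with a common intercept, the single- and
#' two-level variants with item-specific intercepts, and the two extended
#' two-level models with the three process-data indicators (and all six
#' pairwise interactions).
#'
#' @param name one of `"rasch"`, `"dlc"`, `"dlc-sl"`, `"dlc-tl"`,
#'   `"dlc-tl-ext"`, `"dlc-tl-ext-int"`.
#' @param intercept_items item ids with item-specific intercepts; the default
#'   is the set retained by the sequential selection in the motivating study
#'   (items 1, 2, 3, 7, 11 and 14 of a 14-item test).
#' @param ... passed on to [dlc_spec()] (e.g. `z_mode`).
#' @return a `dlc_spec`.
#' @export
spec_menu <- function(name = c("rasch", "dlc", "dlc-sl", "dlc-tl",
                               "dlc-tl-ext", "dlc-tl-ext-int"),
                      intercept_items = c("1", "2", "3", "7", "11", "14"),
                      ...) {
  name <- match.arg(name)
  ext <- c("log_rt", "ac", "tr", "iv")
  switch(name,
    "rasch" = dlc_spec("rasch", ...),
    "dlc" = dlc_spec("dlc", covariates = "log_rt", ...),
    "dlc-sl" = dlc_spec("dlc_sl", intercept_items = intercept_items,
                        covariates = "log_rt", ...),
    "dlc-tl" = dlc_spec("dlc_tl", intercept_items = intercept_items,
                        covariates = "log_rt", ...),
    "dlc-tl-ext" = dlc_spec("dlc_tl", intercept_items = intercept_items,
                            covariates = ext, ...),
    "dlc-tl-ext-int" = dlc_spec("dlc_tl", intercept_items = intercept_items,
                                covariates = ext,
                                interactions = all_pairwise_interactions(ext),
                                ...))
}

#' Number of free parameters of a model spec
#'
#' Counts item difficulties, the theta variance (when free), the engagement
#' intercept block (general intercept plus item-specific offsets), covariate
#' and interaction coefficients, the psi variance and psi-theta covariance of
#' the two-level family, and the shared guessing probability when it is freed.
#'
#' @param spec a [dlc_spec()].
#' @param n_items number of items in the data.
#' @return integer count.
#' @export
count_parameters <- function(spec, n_items) {
  stopifnot(inherits(spec, "dlc_spec"), n_items >= 1)
  k <- n_items +
    (spec$theta_variance_mode == "free") +
    (spec$z_mode == "equal_free")
  if (spec$family != "rasch") {
    k <- k + 1L + length(spec$intercept_items) +
      length(spec$covariates) + length(spec$interactions)
  }
  if (spec$family == "dlc_tl") k <- k + 2L
  as.integer(k)
}

#' Structural nesting check between two specs
#'
#' `nested` is a restriction of `full` when its family is no richer, its
#' intercept-item, covariate and interaction sets are subsets, and the
#' z/theta-variance handling matches. The Rasch model is treated as nested in
#' every mixture family (the published deviance tests do the same).
#'
#' @param nested,full [dlc_spec()] objects.
#' @return logical.
#' @export
spec_is_nested <- function(nested, full) {
  stopifnot(inherits(nested, "dlc_spec"), inherits(full, "dlc_spec"))
  rank <- c(rasch = 1, dlc = 2, dlc_sl = 3, dlc_tl = 4)
  if (rank[[nested$family]] > rank[[full$family]]) return(FALSE)
  if (nested$theta_variance_mode != full$theta_variance_mode) return(FALSE)
  if (nested$family == "rasch") return(TRUE)
  if (nested$z_mode != full$z_mode) return(FALSE)
  all(nested$intercept_items %in% full$intercept_items) &&
    all(nested$covariates %in% full$covariates) &&
    all(nested$interactions %in% full$interactions)
}

#' @export
print.dlc_spec <- function(x, ...) {
  cat("DLC-IRT model spec\n")
  cat("  family:             ", x$family, "\n")
  if (x$family != "rasch") {
    cat("  intercept items:    ",
        if (length(x$intercept_items)) paste(x$intercept_items, collapse = ", ")
        else "(none)", "\n")
    cat("  covariates:         ", paste(x$covariates, collapse = ", "), "\n")
    if (length(x$interactions))
      cat("  interactions:       ", paste(x$interactions, collapse = ", "), "\n")
  }
  cat("  z mode:             ", x$z_mode, "\n")
  cat("  theta variance:     ", x$theta_variance_mode, "\n")
  invisible(x)
}

#' Serialize / deserialize a model spec as JSON
#'
#' Field names match the spec type definition: `family`, `intercept_items`,
#' `covariates`, `interactions`, `z_mode`, `theta_variance_mode`.
#'
#' @param spec a `dlc_spec`.
#' @param path file path; for `read_spec_json`, the file to read.
#' @return `read_spec_json` returns a `dlc_spec`; `write_spec_json` returns
#'   `path` invisibly.
#' @export
write_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "dlc_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_spec_json
#' @export
read_spec_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dlc_spec(family = x$family,
           intercept_items = x$intercept_items %||% character(),
           covariates = x$covariates %||% character(),
           interactions = x$interactions %||% character(),
           z_mode = x$z_mode %||% "fixed_reciprocal",
           theta_variance_mode = x$theta_variance_mode %||% "free")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

# covariates actually required by a spec (incl. interaction members)
spec_required_covariates <- function(spec) {
  if (spec$family == "rasch") return(character())
  unique(c(spec$covariates,
           unlist(strsplit(spec$interactions, ":", fixed = TRUE))))
}
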