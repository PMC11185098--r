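#' Posterior engagement classification
#'
#' For each valid encounter, the posterior probability of solution behavior
#' given the person's *full* response vector: the engagement prior pi and the
#' class-conditional response probabilities are combined by Bayes' rule at
#' each quadrature node, and the latent variables are marginalized over the
#' person's posterior on the grid (not plugged in).
#'
#' @param fit a converged `dlc_fit` of a mixture family.
#' @param data the [dlc_data()] the model was fitted on.
#' @return data frame of class `dlc_posterior` with columns `person_id`,
#'   `item_id`, `y`, `p_solution`, `hard_class` (1 when `p_solution >= 0.5`).
#' @export
posterior_class_prob <- function(fit, data) {
  stopifnot(inherits(fit, "dlc_fit"), inherits(data, "dlc_data"))
  spec <- fit$spec
  if (spec$family == "rasch")
    stop("the Rasch family has no engagement classes", call. = FALSE)
  params <- fit$params
  md <- build_model_data(spec, data)
  grid <- quad_grid(fit$n_nodes %||% 15,
                    if (spec$family == "dlc_tl") 2 else 1)
  L <- latent_chol(params$var_theta,
                   if (spec$family == "dlc_tl") params$sigma2_psi else 0,
                   if (spec$family == "dlc_tl") params$cov_psi_theta else 0)
  if (spec$family == "dlc_tl") {
    gg <- expand.grid(b = seq_along(grid$u2), a = seq_along(grid$u1))
    theta_q <- L[1, 1] * grid$u1[gg$a]
    psi_q <- L[2, 1] * grid$u1[gg$a] + L[2, 2] * grid$u2[gg$b]
    w_q <- grid$w1[gg$a] * grid$w2[gg$b]
  } else {
    theta_q <- L[1, 1] * grid$u1
    psi_q <- rep(0, length(grid$u1))
    w_q <- grid$w1
  }
  beta_e <- params$beta[md$enc$item_id]
  P1 <- stats::plogis(outer(-beta_e, theta_q, `+`))
  z_e <- if (spec$z_mode == "equal_free") rep(params$z_free, nrow(md$enc)) else md$zvec
  eta <- as.numeric(md$X %*% pack_coefs(spec, params))
  PI <- stats::plogis(outer(eta, psi_q, `+`))
  Py <- ifelse(md$y == 1, 1, 0) * P1 + ifelse(md$y == 1, 0, 1) * (1 - P1)
  Zy <- ifelse(md$y == 1, z_e, 1 - z_e)
  P <- pmax(PI * Py + (1 - PI) * Zy, PROB_FLOOR)
  lp <- rowsum(log(P), group = md$pidx)
  lp <- sweep(lp, 2, log(w_q), `+`)
  m <- apply(lp, 1, max)
  Wn <- exp(lp - m)
  Wn <- Wn / rowSums(Wn)                       # persons x nodes posterior
  ratio <- PI * Py / P                         # P(C=1 | y_ij, theta, psi)
  p_sol <- rowSums(Wn[md$pidx + 1L, , drop = FALSE] * ratio)
  out <- data.frame(person_id = md$enc$person_id, item_id = md$enc$item_id,
                    y = md$enc$y, p_solution = pmin(pmax(p_sol, 0), 1),
                    stringsAsFactors = FALSE)
  out$hard_class <- as.integer(out$p_solution >= 0.5)
  class(out) <- c("dlc_posterior", "data.frame")
  out
}

#' Relative entropy of a classification
#'
#' `1 - sum(binary entropies) / (n * log 2)` over the classified encounters,
#' with `0 * log 0 == 0`; 1 means perfect separation, 0 means all posteriors
#' at 0.5.
#'
#' @param post a `dlc_posterior` (or numeric vector of posterior
#'   probabilities).
#' @return value in `[0, 1]`.
#' @export
entropy <- function(post) {
  p <- if (is.data.frame(post)) post$p_solution else post
  stopifnot(length(p) >= 1, all(p >= 0 & p <= 1))
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  h <- -xlx(p) - xlx(1 - p)
  1 - sum(h) / (length(p) * log(2))
}

#' Classification summary
#'
#' Per-item and overall mean posterior solution probabilities plus
#' class-conditional descriptives (mean response time, percent correct,
#' indicator rates by hard class), echoing the per-item classification
#' column of the descriptive table.
#'
#' @param post a `dlc_posterior`.
#' @param data the [dlc_data()] classification was computed on.
#' @return list with `per_item`, `overall` (mean posterior probability and
#'   hard-class share), and `by_class` data frames.
#' @export
classification_summary <- function(post, data) {
  stopifnot(inherits(post, "dlc_posterior"), inherits(data, "dlc_data"))
  enc <- merge(as.data.frame(post),
               as.data.frame(data$encounters)[c("person_id", "item_id",
                                                "rt_seconds", "ac", "tr", "iv")],
               by = c("person_id", "item_id"), sort = FALSE)
  per_item <- do.call(rbind, lapply(split(enc, enc$item_id), function(d)
    data.frame(item_id = d$item_id[1], n = nrow(d),
               mean_p_solution = mean(d$p_solution),
               share_solution = mean(d$hard_class),
               stringsAsFactors = FALSE)))
  per_item <- per_item[order(per_item$item_id), , drop = FALSE]
  rownames(per_item) <- NULL
  by_class <- do.call(rbind, lapply(split(enc, enc$hard_class), function(d)
    data.frame(hard_class = d$hard_class[1], n = nrow(d),
               mean_rt = mean(d$rt_seconds, na.rm = TRUE),
               pct_correct = mean(d$y) * 100,
               rate_ac = mean(d$ac, na.rm = TRUE),
               rate_tr = mean(d$tr, na.rm = TRUE),
               rate_iv = mean(d$iv, na.rm = TRUE))))
  rownames(by_class) <- NULL
  list(per_item = per_item,
       overall = data.frame(mean_p_solution = mean(enc$p_solution),
                            share_solution = mean(enc$hard_class)),
       by_class = by_class)
}
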