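#' Rasch solution-behavior success probability
#'
#' Probability of a correct response under engaged (solution) behavior:
#' `plogis(theta - beta)`, computed overflow-safely.
#'
#' @param theta ability (logits).
#' @param beta item difficulty (logits).
#' @return probability in (0, 1); vectorized.
#' @export
rasch_prob <- function(theta, beta) {
  if (!all(is.finite(theta)) || !all(is.finite(beta)))
    stop("theta and beta must be finite", call. = FALSE)
  stats::plogis(theta - beta)
}

#' Disengaged-class guessing probability
#'
#' With one correct option among `n_options`, a disengaged (random) response
#' succeeds with probability `1/n_options`.
#'
#' @param n_options integer count of response options (>= 1); vectorized.
#' @return probability.
#' @export
guess_prob <- function(n_options) {
  if (any(!is.finite(n_options)) || any(n_options < 1) ||
      any(n_options != round(n_options)))
    stop("n_options must be integers >= 1", call. = FALSE)
  1 / n_options
}

#' Engagement (solution-behavior) probability from a linear predictor
#'
#' Logistic link shared by all engagement regressions.
#'
#' @param eta linear predictor; finite.
#' @return probability in (0, 1); vectorized.
#' @export
engagement_prob <- function(eta) {
  if (!all(is.finite(eta))) stop("eta must be finite", call. = FALSE)
  stats::plogis(eta)
}

#' Linear predictor of the engagement regression
#'
#' `alpha0 (+ alpha_item for the matching item) + sum(gamma * covariate) +
#' sum(gamma_int * covariate products) + psi`. Covariates required by the
#' spec must be present and non-missing in the encounter.
#'
#' @param spec a [dlc_spec()] (mixture family).
#' @param params a [dlc_params()].
#' @param enc one encounter: list or one-row data frame with `item_id` and
#'   the covariates named in the spec (`log_rt`, `ac`, `tr`, `iv`).
#' @param psi random engagement threshold; must be 0 unless the family is
#'   `dlc_tl`.
#' @return numeric scalar.
#' @export
linear_predictor <- function(spec, params, enc, psi = 0) {
  stopifnot(inherits(spec, "dlc_spec"))
  if (spec$family == "rasch")
    stop("the Rasch family has no engagement regression", call. = FALSE)
  if (psi != 0 && spec$family != "dlc_tl")
    stop("psi must be 0 unless the family is dlc_tl", call. = FALSE)
  eta <- params$alpha0 %||% 0
  itm <- as.character(enc$item_id)
  if (length(spec$intercept_items) && itm %in% spec$intercept_items)
    eta <- eta + (params$alpha_item[[itm]] %||% 0)
  for (cv in spec$covariates) {
    v <- enc[[cv]]
    if (is.null(v) || is.na(v))
      stop("covariate '", cv, "' required by the spec is missing",
           call. = FALSE)
    eta <- eta + (params$gamma[[cv]] %||% 0) * v
  }
  for (ia in spec$interactions) {
    p <- strsplit(ia, ":", fixed = TRUE)[[1L]]
    v1 <- enc[[p[1]]]; v2 <- enc[[p[2]]]
    if (is.null(v1) || is.null(v2) || is.na(v1) || is.na(v2))
      stop("interaction '", ia, "' has a missing component", call. = FALSE)
    eta <- eta + (params$gamma_int[[ia]] %||% 0) * v1 * v2
  }
  eta + psi
}

#' Two-class mixture response probability
#'
#' `pi * p_sol + (1 - pi) * z` for a correct response, and the complement
#' mixture for an incorrect one.
#'
#' @param pi probability of solution behavior.
#' @param p_sol solution-behavior success probability.
#' @param z disengaged-class success probability.
#' @param y observed response, 0 or 1.
#' @return probability in `[0, 1]`; vectorized over the probabilities.
#' @export
mixture_response_prob <- function(pi, p_sol, z, y) {
  if (!all(y %in% c(0, 1))) stop("y must be 0 or 1", call. = FALSE)
  if (any(pi < 0 | pi > 1 | p_sol < 0 | p_sol > 1 | z < 0 | z > 1))
    stop("pi, p_sol, z must lie in [0, 1]", call. = FALSE)
  p1 <- pi * p_sol + (1 - pi) * z
  # the y = 0 branch as the exact complement, so that the two branches sum
  # to 1 in floating point as well
  ifelse(y == 1, p1, 1 - p1)
}

PROB_FLOOR <- 1e-12

#' Conditional log-likelihood of one person's encounters
#'
#' Sum over the person's valid encounters of the log mixture response
#' probability, conditional on fixed latent values `(theta, psi)`.
#' Encounters with a missing response or a missing required covariate
#' contribute 0. Items are conditionally independent given the latents.
#'
#' @param spec a [dlc_spec()].
#' @param params a [dlc_params()].
#' @param encounters data frame of one person's encounters (`item_id`, `y`,
#'   covariate columns).
#' @param bank an [item_bank()] supplying `n_options` per item.
#' @param theta,psi latent values.
#' @return log-likelihood (scalar).
#' @export
person_conditional_loglik <- function(spec, params, encounters, bank,
                                      theta, psi = 0) {
  stopifnot(inherits(spec, "dlc_spec"), inherits(bank, "dlc_item_bank"))
  req <- spec_required_covariates(spec)
  ll <- 0
  for (r in seq_len(nrow(encounters))) {
    enc <- encounters[r, , drop = FALSE]
    if (is.na(enc$y)) next
    if (length(req) && any(vapply(req, function(v) is.na(enc[[v]]),
                                  logical(1)))) next
    j <- match(as.character(enc$item_id), bank$item_id)
    p_sol <- rasch_prob(theta, params$beta[[bank$item_id[j]]])
    z <- if (spec$z_mode == "equal_free") params$z_free else bank$z[j]
    if (spec$family == "rasch") {
      p <- if (enc$y == 1) p_sol else 1 - p_sol
    } else {
      pi <- engagement_prob(linear_predictor(spec, params, enc,
                                             if (spec$family == "dlc_tl") psi else 0))
      p <- mixture_response_prob(pi, p_sol, z, enc$y)
    }
    ll <- ll + log(pmax(p, PROB_FLOOR))
  }
  ll
}

#' Marginal log-likelihood by Gauss-Hermite quadrature
#'
#' Integrates the conditional likelihood over the latent person variables —
#' theta alone for the `rasch`/`dlc`/`dlc_sl` families, jointly (theta, psi)
#' for `dlc_tl` — with standard-normal Gauss-Hermite nodes pushed through the
#' Cholesky factor of the latent covariance, and log-sum-exp stabilization.
#'
#' This is the vectorized R reference implementation; [fit_dlc()] uses an
#' equivalent compiled kernel with analytic gradients.
#'
#' @param spec a [dlc_spec()].
#' @param params a [dlc_params()].
#' @param data a [dlc_data()].
#' @param grid a [quad_grid()]; its dimension must match the family (2 for
#'   `dlc_tl`, 1 otherwise).
#' @return total marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(spec, params, data,
                            grid = quad_grid(15, if (spec$family == "dlc_tl") 2 else 1)) {
  stopifnot(inherits(grid, "dlc_grid"))
  need_dim <- if (spec$family == "dlc_tl") 2L else 1L
  if (grid$dim != need_dim)
    stop("grid dimension ", grid$dim, " does not match family ", spec$family,
         call. = FALSE)
  md <- build_model_data(spec, data)
  L <- latent_chol(params$var_theta,
                   if (spec$family == "dlc_tl") params$sigma2_psi else 0,
                   if (spec$family == "dlc_tl") params$cov_psi_theta else 0)
  if (need_dim == 2L) {
    gg <- expand.grid(b = seq_along(grid$u2), a = seq_along(grid$u1))
    theta_q <- L[1, 1] * grid$u1[gg$a]
    psi_q <- L[2, 1] * grid$u1[gg$a] + L[2, 2] * grid$u2[gg$b]
    w_q <- grid$w1[gg$a] * grid$w2[gg$b]
  } else {
    theta_q <- L[1, 1] * grid$u1
    psi_q <- rep(0, length(grid$u1))
    w_q <- grid$w1
  }
  Q <- length(w_q)
  beta_e <- params$beta[md$enc$item_id]
  # p_sol: encounters x nodes
  P1 <- stats::plogis(outer(-beta_e, theta_q, `+`))
  z_e <- if (spec$z_mode == "equal_free") rep(params$z_free, nrow(md$enc)) else md$zvec
  if (spec$family == "rasch") {
    P <- ifelse(md$y == 1, 1, 0) * P1 + ifelse(md$y == 1, 0, 1) * (1 - P1)
  } else {
    coefs <- pack_coefs(spec, params)
    eta <- as.numeric(md$X %*% coefs)
    PI <- stats::plogis(outer(eta, psi_q, `+`))
    Py <- ifelse(md$y == 1, 1, 0) * P1 + ifelse(md$y == 1, 0, 1) * (1 - P1)
    Zy <- ifelse(md$y == 1, z_e, 1 - z_e)
    P <- PI * Py + (1 - PI) * Zy
  }
  P <- pmax(P, PROB_FLOOR)
  lp <- rowsum(log(P), group = md$pidx)        # persons x nodes
  lp <- sweep(lp, 2, log(w_q), `+`)
  m <- apply(lp, 1, max)
  sum(m + log(rowSums(exp(lp - m))))
}

# engagement-regression coefficient vector in X-column order
pack_coefs <- function(spec, params) {
  co <- params$alpha0 %||% 0
  for (it in spec$intercept_items) co <- c(co, params$alpha_item[[it]] %||% 0)
  for (cv in spec$covariates) co <- c(co, params$gamma[[cv]] %||% 0)
  for (ia in spec$interactions) co <- c(co, params$gamma_int[[ia]] %||% 0)
  co
}
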