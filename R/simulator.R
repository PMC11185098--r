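#' Simulation configuration
#'
#' Bundles the generating model (item bank with true difficulties, model
#' spec, true parameter set), the response-time model (per-item log-scale
#' time intensity `mu_rt`, person slowness loading `lambda_speed`, residual
#' log-SD `sigma_rt`, correlation `speed_psi_cor` between the slowness factor
#' and the engagement threshold psi), and the indicator model (target
#' marginal rates for answer change / text reread / item revisit, loadings of
#' each indicator on the slowness factor, and geometric continuation
#' probabilities turning flags into counts).
#'
#' Three built-in scenarios:
#' \describe{
#'   \item{`recovery`}{moderated coefficients on a standardized log-RT scale
#'     (`alpha0 = 1.5`, `gamma_rt = 1`, `gamma_tr = -0.8`, `sigma2_psi = 1`,
#'     `corr(psi, theta) = 0.5`), slowness independent of the latents so the
#'     fitted model is correctly specified — the scenario under which
#'     parameter recovery is guaranteed to be well-conditioned.}
#'   \item{`paper_like`}{item RT means spanning 17-36 s, log-RT SD 0.59,
#'     indicator marginal rates (0.14, 0.33, 0.07), slowness linked to psi.}
#'   \item{`table5_like`}{the published extreme coefficients (e.g.
#'     `gamma_rt = 11.26`, near-perfect psi-theta correlation); a stress
#'     scenario near separation, without recovery guarantees.}
#' }
#'
#' @param scenario one of `"recovery"`, `"paper_like"`, `"table5_like"`.
#' @param n_persons number of simulated persons.
#' @param seed mandatory integer seed.
#' @param ... named overrides of any config field.
#' @return list of class `dlc_sim_config`.
#' @export
sim_config <- function(scenario = c("recovery", "paper_like", "table5_like"),
                       n_persons = 1000, seed, ...) {
  scenario <- match.arg(scenario)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  J <- 14
  ids <- as.character(seq_len(J))
  beta <- seq(-1.5, 1.5, length.out = J)
  bank <- item_bank(ids, rep(4L, J), beta = beta)
  sel_items <- c("1", "2", "3", "7", "11", "14")
  base <- list(
    scenario = scenario, n_persons = as.integer(n_persons),
    seed = as.integer(seed), bank = bank,
    tasks = data.frame(item_id = ids,
                       task_id = paste0("T", ceiling(seq_len(J) / 3)),
                       stringsAsFactors = FALSE),
    indicator_targets = c(ac = 0.14, tr = 0.33, iv = 0.07),
    indicator_loadings = c(ac = 0.45, tr = 0.80, iv = 0.35),
    count_continuation = c(ac = 0.45, tr = 0.42, iv = 0.10),
    miss_rate = 0)
  cfg <- switch(scenario,
    recovery = c(base, list(
      spec = spec_menu("dlc-tl-ext", intercept_items = sel_items),
      params = dlc_params(
        beta = stats::setNames(beta, ids), alpha0 = 1.5,
        alpha_item = stats::setNames(rep(0, 6), sel_items),
        gamma = c(log_rt = 1.0, ac = 0, tr = -0.8, iv = 0),
        var_theta = 1, sigma2_psi = 1, cov_psi_theta = 0.5),
      mu_rt = rep(0, J), lambda_speed = 0.6, sigma_rt = 0.8,
      speed_psi_cor = 0)),
    paper_like = c(base, list(
      spec = spec_menu("dlc-tl-ext", intercept_items = sel_items),
      params = dlc_params(
        beta = stats::setNames(beta, ids), alpha0 = -4.5,
        alpha_item = stats::setNames(rep(0, 6), sel_items),
        gamma = c(log_rt = 2.0, ac = 0, tr = -0.5, iv = 0),
        var_theta = 1, sigma2_psi = 1, cov_psi_theta = 0.4),
      mu_rt = log(seq(17, 36, length.out = J)) - 0.59^2 / 2,
      lambda_speed = 0.30, sigma_rt = sqrt(0.59^2 - 0.30^2),
      speed_psi_cor = 0.5, miss_rate = 0.03)),
    table5_like = c(base, list(
      spec = spec_menu("dlc-tl-ext", intercept_items = sel_items),
      params = dlc_params(
        beta = stats::setNames(beta, ids), alpha0 = -21.52,
        alpha_item = stats::setNames(
          c(-6.34, -9.83, -13.93, -8.43, -13.17, 3.92), sel_items),
        gamma = c(log_rt = 11.26, ac = -0.76, tr = -2.60, iv = -1.43),
        var_theta = 1, sigma2_psi = 7.26, cov_psi_theta = 2.69 * 0.995),
      mu_rt = log(seq(17, 36, length.out = J)) - 0.59^2 / 2,
      lambda_speed = 0.30, sigma_rt = sqrt(0.59^2 - 0.30^2),
      speed_psi_cor = 0.5, miss_rate = 0.03)))
  ov <- list(...)
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  cfg$n_persons <- as.integer(cfg$n_persons)
  structure(cfg, class = "dlc_sim_config")
}

#' Draw latent person variables
#'
#' `n` draws of (theta, psi) from the bivariate normal with zero means,
#' variances `var_theta` / `sigma2_psi` and covariance `cov`.
#'
#' @param n number of persons.
#' @param var_theta,sigma2_psi,cov latent covariance structure (must be
#'   positive semidefinite).
#' @param seed integer seed.
#' @return data frame `person_id`, `theta`, `psi`.
#' @export
simulate_persons <- function(n, var_theta = 1, sigma2_psi = 1, cov = 0,
                             seed) {
  stopifnot(n >= 1)
  L <- latent_chol(var_theta, sigma2_psi, cov)
  with_seed(seed, {
    u <- matrix(stats::rnorm(2 * n), n, 2)
    data.frame(person_id = sprintf("p%04d", seq_len(n)),
               theta = L[1, 1] * u[, 1],
               psi = L[2, 1] * u[, 1] + L[2, 2] * u[, 2],
               stringsAsFactors = FALSE)
  })
}

# intercept a with E[plogis(a + b * Z)] = target, Z ~ N(0,1)
solve_rate_intercept <- function(target, b, gh = gauss_hermite_normal(41)) {
  stopifnot(target > 0, target < 1)
  f <- function(a) sum(gh$weights * stats::plogis(a + b * gh$nodes)) - target
  if (f(-35) > 0 || f(35) < 0)
    stop("target indicator rate unattainable with the given loading",
         call. = FALSE)
  stats::uniroot(f, c(-35, 35), tol = 1e-10)$root
}

#' Simulate encounter covariates
#'
#' Response times are lognormal: `log rt = mu_rt[j] + lambda_speed * s_i +
#' sigma_rt * noise`, with `s_i` a standard-normal person slowness factor
#' correlated `speed_psi_cor` with the (standardized) engagement threshold
#' psi. Each binary indicator is Bernoulli with a logit loading on `s_i`
#' whose intercept is solved so the marginal rate matches the target; counts
#' are the flag times a geometric tail.
#'
#' @param latents output of [simulate_persons()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return data frame with one row per person-by-item encounter:
#'   `person_id`, `item_id`, `rt_seconds`, `ac_count`, `tr_count`,
#'   `iv_count`, and the slowness factor `speed`.
#' @export
simulate_covariates <- function(latents, config, seed) {
  bank <- config$bank
  n <- nrow(latents); J <- nrow(bank)
  rho <- config$speed_psi_cor
  with_seed(seed, {
    psi_sd <- stats::sd(latents$psi)
    psi_std <- if (psi_sd > 0) latents$psi / sqrt(mean(latents$psi^2) + 1e-12)
               else rep(0, n)
    s <- rho * psi_std + sqrt(max(1 - rho^2, 0)) * stats::rnorm(n)
    grid <- expand.grid(j = seq_len(J), i = seq_len(n))
    l <- config$mu_rt[grid$j] + config$lambda_speed * s[grid$i] +
      config$sigma_rt * stats::rnorm(nrow(grid))
    out <- data.frame(person_id = latents$person_id[grid$i],
                      item_id = bank$item_id[grid$j],
                      rt_seconds = exp(l), speed = s[grid$i],
                      stringsAsFactors = FALSE)
    for (ind in c("ac", "tr", "iv")) {
      b <- config$indicator_loadings[[ind]]
      a <- solve_rate_intercept(config$indicator_targets[[ind]], b)
      p <- stats::plogis(a + b * s[grid$i])
      flag <- stats::rbinom(nrow(grid), 1, p)
      extra <- stats::rgeom(nrow(grid), 1 - config$count_continuation[[ind]])
      out[[paste0(ind, "_count")]] <- flag * (1L + extra)
    }
    out
  })
}

#' Simulate responses and true engagement classes
#'
#' Draws the latent class `C ~ Bernoulli(engagement probability)` from the
#' spec's engagement regression evaluated at the true parameters, then the
#' response from the Rasch model (engaged) or the guessing constant
#' (disengaged).
#'
#' @param latents output of [simulate_persons()].
#' @param covariates output of [simulate_covariates()] (or any data frame
#'   with `person_id`, `item_id`, `rt_seconds` and indicator counts).
#' @param spec,params generating model.
#' @param bank the [item_bank()].
#' @param seed integer seed.
#' @return the covariates data frame with added columns `y` and `C_true`.
#' @export
simulate_responses <- function(latents, covariates, spec, params, bank,
                               seed) {
  cv <- covariates
  cv$log_rt <- log(cv$rt_seconds)
  for (ind in c("ac", "tr", "iv"))
    cv[[ind]] <- dichotomize(cv[[paste0(ind, "_count")]])
  i <- match(cv$person_id, latents$person_id)
  j <- match(cv$item_id, bank$item_id)
  stopifnot(!anyNA(i), !anyNA(j))
  eta <- rep(params$alpha0 %||% 0, nrow(cv))
  for (it in spec$intercept_items)
    eta <- eta + (params$alpha_item[[it]] %||% 0) * (cv$item_id == it)
  for (cvn in spec$covariates)
    eta <- eta + (params$gamma[[cvn]] %||% 0) * cv[[cvn]]
  for (ia in spec$interactions) {
    p2 <- strsplit(ia, ":", fixed = TRUE)[[1L]]
    eta <- eta + (params$gamma_int[[ia]] %||% 0) * cv[[p2[1]]] * cv[[p2[2]]]
  }
  if (spec$family == "dlc_tl") eta <- eta + latents$psi[i]
  p_sol <- rasch_prob(latents$theta[i], params$beta[cv$item_id])
  z <- if (spec$z_mode == "equal_free") params$z_free else bank$z[j]
  with_seed(seed, {
    C <- stats::rbinom(nrow(cv), 1, engagement_prob(eta))
    y <- ifelse(C == 1, stats::rbinom(nrow(cv), 1, p_sol),
                stats::rbinom(nrow(cv), 1, z))
    cv$y <- y
    cv$C_true <- C
    cv
  })
}

#' Simulate a complete dataset
#'
#' Orchestrates [simulate_persons()], [simulate_covariates()] and
#' [simulate_responses()] under a single seed and returns a model-ready
#' dataset together with the ground truth.
#'
#' @param config a [sim_config()].
#' @return list of class `dlc_sim` with `data` (a [dlc_data()]), `latents`,
#'   `classes` (per-encounter true class), `encounters_raw` (incl. counts and
#'   `C_true`), `truth` (the generating parameter set) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "dlc_sim_config"))
  p <- config$params
  seeds <- config$seed + c(0L, 1L, 2L, 3L)
  lat <- simulate_persons(config$n_persons, p$var_theta, p$sigma2_psi,
                          p$cov_psi_theta, seed = seeds[1])
  cv <- simulate_covariates(lat, config, seed = seeds[2])
  cv <- simulate_responses(lat, cv, config$spec, p, config$bank,
                           seed = seeds[3])
  if (config$miss_rate > 0) {
    cv <- with_seed(seeds[4], {
      drop <- stats::runif(nrow(cv)) < config$miss_rate
      cv$rt_seconds[drop] <- NA_real_
      cv$y[drop] <- NA_integer_
      cv$ac_count[drop] <- NA_integer_
      cv$tr_count[drop] <- NA_integer_
      cv$iv_count[drop] <- NA_integer_
      cv
    })
  }
  enc <- dlc_encounters(cv[c("person_id", "item_id", "y", "rt_seconds",
                             "ac_count", "tr_count", "iv_count")])
  structure(list(data = dlc_data(enc, config$bank), latents = lat,
                 classes = cv[c("person_id", "item_id", "C_true")],
                 encounters_raw = cv, truth = p, config = config),
            class = "dlc_sim")
}
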