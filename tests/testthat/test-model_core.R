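test_that("rasch_prob matches the closed-form logistic and its limits", {
  expect_identical(rasch_prob(0, 0), 0.5)
  expect_equal(rasch_prob(2, 0), 0.880797078, tolerance = 1e-8)
  expect_lt(rasch_prob(-50, 0), 1e-20)
  expect_error(rasch_prob(NA, 0), "finite")
  # monotone in theta, antitone in beta
  th <- seq(-4, 4, by = 0.5)
  expect_true(all(diff(rasch_prob(th, 0)) > 0))
  expect_true(all(diff(rasch_prob(0, th)) < 0))
})

test_that("guess_prob is the reciprocal of the option count", {
  expect_identical(guess_prob(4), 0.25)
  expect_identical(guess_prob(2), 0.5)
  expect_identical(guess_prob(1), 1)
  expect_error(guess_prob(0), "n_options")
  expect_error(guess_prob(2.5), "n_options")
})

test_that("linear_predictor assembles intercepts, covariates, interactions and psi", {
  spec <- dlc_spec("dlc_tl", intercept_items = "2",
                   covariates = c("log_rt", "tr"),
                   interactions = "log_rt:tr")
  p0 <- dlc_params(beta = c(`1` = 0, `2` = 0), alpha0 = 0,
                   alpha_item = c(`2` = 0),
                   gamma = c(log_rt = 0, tr = 0),
                   gamma_int = c("log_rt:tr" = 0), sigma2_psi = 1)
  enc <- list(item_id = "1", log_rt = 3, tr = 1)
  expect_identical(linear_predictor(spec, p0, enc, psi = 0), 0)

  # arithmetic with published-scale coefficients
  sp2 <- dlc_spec("dlc", covariates = "log_rt")
  pa <- dlc_params(beta = c(`1` = 0), alpha0 = -21.52,
                   gamma = c(log_rt = 11.26))
  expect_equal(linear_predictor(sp2, pa, list(item_id = "1", log_rt = 3)),
               12.26, tolerance = 1e-12)
  sp3 <- dlc_spec("dlc", covariates = c("log_rt", "tr"))
  pb <- dlc_params(beta = c(`1` = 0), alpha0 = -21.52,
                   gamma = c(log_rt = 11.26, tr = -2.60))
  expect_equal(linear_predictor(sp3, pb, list(item_id = "1", log_rt = 3, tr = 1)),
               9.66, tolerance = 1e-12)

  # item dummy contributes only for the matching item; psi adds on
  p1 <- dlc_params(beta = c(`1` = 0, `2` = 0), alpha0 = 1,
                   alpha_item = c(`2` = -2), gamma = c(log_rt = 0.5, tr = 0),
                   gamma_int = c("log_rt:tr" = 0.25), sigma2_psi = 1)
  expect_equal(linear_predictor(spec, p1, list(item_id = "2", log_rt = 2, tr = 1),
                                psi = 0.3),
               1 - 2 + 0.5 * 2 + 0.25 * 2 + 0.3)
  expect_equal(linear_predictor(spec, p1, list(item_id = "1", log_rt = 2, tr = 1),
                                psi = 0),
               1 + 0.5 * 2 + 0.25 * 2)
  # missing required covariate is a precondition violation
  expect_error(linear_predictor(spec, p1, list(item_id = "1", log_rt = NA, tr = 1)),
               "missing")
})

test_that("engagement_prob is an overflow-safe logistic", {
  expect_identical(engagement_prob(0), 0.5)
  expect_equal(engagement_prob(12.26), 0.9999952625, tolerance = 1e-9)
  eta <- c(-800, -5, 0.3, 5, 800)
  expect_true(all(engagement_prob(eta) >= 0 & engagement_prob(eta) <= 1))
  expect_equal(engagement_prob(eta) + engagement_prob(-eta), rep(1, 5))
  expect_error(engagement_prob(Inf), "finite")
})

test_that("mixture_response_prob mixes the two classes and sums to one", {
  expect_equal(mixture_response_prob(0, 0.9, 0.25, 1), 0.25)
  expect_equal(mixture_response_prob(1, 0.8, 0.25, 1), 0.8)
  expect_equal(mixture_response_prob(0.5, 0.8, 0.25, 1), 0.525)
  expect_error(mixture_response_prob(0.5, 0.8, 0.25, 2), "y")
  expect_error(mixture_response_prob(1.2, 0.8, 0.25, 1), "lie in")
  # exact complementarity and range, over random inputs
  set.seed(11)
  for (r in 1:200) {
    pi <- runif(1); p <- runif(1); z <- runif(1)
    s <- mixture_response_prob(pi, p, z, 1) + mixture_response_prob(pi, p, z, 0)
    expect_identical(s, 1)
    expect_true(mixture_response_prob(pi, p, z, 1) >= 0 &&
                mixture_response_prob(pi, p, z, 1) <= 1)
  }
})

test_that("person_conditional_loglik matches hand arithmetic and skips invalid rows", {
  bank <- item_bank(c("1", "2", "3"), c(4, 4, 4))
  spec <- toy_tl_spec()
  params <- dlc_params(beta = c(`1` = -0.5, `2` = 0, `3` = 0.5), alpha0 = 0.5,
                       gamma = c(log_rt = 0.4), sigma2_psi = 0.8)
  enc <- data.frame(item_id = c("1", "2", "3"), y = c(1, 0, NA),
                    log_rt = c(3, 2, 1), stringsAsFactors = FALSE)
  # frozen from closed-form arithmetic:
  # pi1 = plogis(0.5 + 1.2 + 0.2), P1 = pi1*plogis(0.8) + (1-pi1)*0.25
  # pi2 = plogis(0.5 + 0.8 + 0.2), P2 = pi2*(1-plogis(0.3)) + (1-pi2)*0.75
  expect_equal(person_conditional_loglik(spec, params, enc, bank,
                                         theta = 0.3, psi = 0.2),
               -1.181845572, tolerance = 1e-8)
  # zero valid encounters
  enc0 <- enc; enc0$y <- NA
  expect_identical(person_conditional_loglik(spec, params, enc0, bank, 0, 0), 0)
  # pi forced to ~1 collapses to the Rasch term
  pbig <- params; pbig$alpha0 <- 60
  enc1 <- enc[1, , drop = FALSE]
  expect_equal(person_conditional_loglik(spec, pbig, enc1, bank, 0.3, 0),
               log(rasch_prob(0.3, -0.5)), tolerance = 1e-9)
})

test_that("marginal_loglik is invariant to person and item permutation", {
  data <- toy_data(seed = 5, n = 12, J = 4)
  spec <- toy_tl_spec()
  params <- toy_tl_params(data$bank)
  ll <- marginal_loglik(spec, params, data)
  enc <- data$encounters
  set.seed(99)
  perm <- enc[sample(nrow(enc)), , drop = FALSE]
  data2 <- dlc_data(dlc_encounters(perm), data$bank)
  expect_equal(marginal_loglik(spec, params, data2), ll, tolerance = 1e-10)
  bank3 <- data$bank[rev(seq_len(nrow(data$bank))), , drop = FALSE]
  class(bank3) <- class(data$bank)
  data3 <- dlc_data(data$encounters, bank3)
  expect_equal(marginal_loglik(spec, params, data3), ll, tolerance = 1e-10)
})

test_that("marginal_loglik agrees between the R reference and the compiled kernel", {
  data <- toy_data(seed = 21, n = 15, J = 4)
  for (fam in list(dlc_spec("rasch"),
                   dlc_spec("dlc", covariates = c("log_rt", "tr")),
                   dlc_spec("dlc_sl", intercept_items = "2",
                            covariates = "log_rt"),
                   toy_tl_spec())) {
    params <- toy_tl_params(data$bank)
    if (fam$family != "dlc_tl") { params$sigma2_psi <- 0; params$cov_psi_theta <- 0 }
    if (fam$family == "dlc_sl") params$alpha_item <- c(`2` = -0.4)
    if (fam$family == "dlc") params$gamma <- c(log_rt = 0.4, tr = -0.3)
    llR <- marginal_loglik(fam, params, data)
    md <- dlcirt:::build_model_data(fam, data)
    u <- dlcirt:::pack_params(fam, params, md$item_ids)
    grid <- quad_grid(15, if (fam$family == "dlc_tl") 2 else 1)
    llC <- dlcirt:::mll_kernel(fam, u, md, grid)$loglik
    expect_equal(llC, llR, tolerance = 1e-10)
  }
})

test_that("degenerate psi variance collapses the 2-D integral onto the 1-D one", {
  data <- toy_data(seed = 31, n = 20, J = 4)
  params1 <- toy_tl_params(data$bank)
  params1$sigma2_psi <- 0; params1$cov_psi_theta <- 0
  ll2 <- marginal_loglik(toy_tl_spec(), params1, data, grid = quad_grid(15, 2))
  lld <- marginal_loglik(dlc_spec("dlc", covariates = "log_rt"), params1, data,
                         grid = quad_grid(15, 1))
  expect_equal(ll2, lld, tolerance = 1e-8)
})

test_that("doubling quadrature nodes barely moves the marginal log-likelihood", {
  cfg <- sim_config("recovery", n_persons = 150, seed = 44)
  sim <- simulate_dataset(cfg)
  ll15 <- marginal_loglik(cfg$spec, cfg$params, sim$data, quad_grid(15, 2))
  ll31 <- marginal_loglik(cfg$spec, cfg$params, sim$data, quad_grid(31, 2))
  expect_lt(abs(ll15 - ll31) / cfg$n_persons, 1e-4)
})

test_that("engagement is strictly increasing in log response time for positive gamma", {
  spec <- dlc_spec("dlc", covariates = "log_rt")
  params <- dlc_params(beta = c(`1` = 0), alpha0 = -2, gamma = c(log_rt = 1.5))
  lrt <- seq(0.5, 5, by = 0.25)
  pi <- vapply(lrt, function(l)
    engagement_prob(linear_predictor(spec, params, list(item_id = "1", log_rt = l))),
    numeric(1))
  expect_true(all(diff(pi) > 0))
})

test_that("non-PSD latent covariance is rejected", {
  expect_error(dlc_params(beta = c(`1` = 0), var_theta = 1, sigma2_psi = 0.5,
                          cov_psi_theta = 2), "positive semidefinite")
  expect_error(dlcirt:::latent_chol(1, 0.25, 1), "positive semidefinite")
})
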