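test_that("count_parameters reproduces the published model-menu counts", {
  J <- 14
  menu <- c("rasch", "dlc", "dlc-sl", "dlc-tl", "dlc-tl-ext", "dlc-tl-ext-int")
  counts <- vapply(menu, function(m) count_parameters(spec_menu(m), J),
                   integer(1))
  expect_identical(unname(counts), c(15L, 17L, 23L, 25L, 28L, 34L))
  expect_identical(unname(diff(counts)), c(2L, 6L, 2L, 3L, 6L))
  # hand-enumerated variants
  expect_identical(count_parameters(
    dlc_spec("dlc_tl", covariates = "log_rt", theta_variance_mode = "fixed_1"),
    14), 18L)
  expect_identical(count_parameters(
    spec_menu("dlc-tl", z_mode = "equal_free"), 14), 26L)
})

test_that("information criteria follow their closed forms", {
  ic <- information_criteria(-500, 10, 100)
  expect_equal(ic[["aic"]], 1020)
  expect_equal(ic[["bic"]], 1046.0517019, tolerance = 1e-6)
  expect_equal(ic[["abic"]], 1014.4691898, tolerance = 1e-6)
  expect_equal(unname(information_criteria(-500, 0, 100)), rep(1000, 3))
})

test_that("entropy has the right fixed points and hand value", {
  expect_identical(entropy(c(0, 1, 1, 0)), 1)
  expect_identical(entropy(c(0.5, 0.5)), 0)
  h <- -(0.9 * log(0.9) + 0.1 * log(0.1))      # closed-form oracle
  expect_equal(entropy(c(0.9, 0.1)), 1 - 2 * h / (2 * log(2)),
               tolerance = 1e-12)
  expect_equal(entropy(c(0.9, 0.1)), 0.531004, tolerance = 1e-5)
  # monotone: pushing posteriors toward 0.5 lowers entropy
  path <- vapply(seq(1, 0, by = -0.1), function(s)
    entropy(0.5 + s * c(0.4, -0.45, 0.3)), numeric(1))
  expect_true(all(diff(path) < 0))
})

test_that("lr_test clips at zero, uses the parameter-count df, and flags misuse", {
  data <- toy_data(seed = 77, n = 40, J = 4)
  cfg <- fit_config(n_starts = 2, n_final = 1, seed = 3, se = FALSE)
  f_rasch <- fit_dlc(dlc_spec("rasch"), data, cfg)
  f_dlc <- fit_dlc(dlc_spec("dlc", covariates = "log_rt"), data, cfg)
  t <- lr_test(f_rasch, f_dlc)
  expect_identical(t$df, 2L)
  expect_gte(t$delta_dev, 0)
  expect_equal(t$p_value,
               pchisq(t$delta_dev, 2, lower.tail = FALSE))
  expect_error(lr_test(f_dlc, f_rasch), "nested")
  # a full model at (numerically) the nested likelihood: deviance clipped
  # at zero, p = 1
  tied <- f_dlc
  tied$loglik <- f_rasch$loglik - 0.005
  t0 <- lr_test(f_rasch, tied)
  expect_identical(t0$delta_dev, 0)
  expect_identical(t0$p_value, 1)
  # chi-square quantile identity at the df = 1 critical value
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05004352,
               tolerance = 1e-7)
  # nested fits cannot beat the full model beyond optimizer tolerance
  expect_gte(f_dlc$loglik, f_rasch$loglik - 0.01)
})

test_that("posterior classification matches single-item Bayes rule exactly", {
  # one person, one item, flat engagement prior 0.5, p_sol = 0.8, z = 0.25:
  # P(C=1|y=1) = 0.8*0.5 / (0.8*0.5 + 0.25*0.5)
  bank <- item_bank(c("1", "2"), c(4, 4))
  enc <- data.frame(person_id = c("p1", "p1"), item_id = c("1", "2"),
                    y = c(1, NA), rt_seconds = c(10, NA),
                    ac_count = c(0, NA), tr_count = c(0, NA),
                    iv_count = c(0, NA), stringsAsFactors = FALSE)
  data <- dlc_data(dlc_encounters(enc), bank)
  # gamma = 0 and var_theta tiny make pi = 0.5 and p_sol = plogis(-beta)
  spec <- dlc_spec("dlc", covariates = "log_rt")
  beta <- -stats::qlogis(0.8)
  params <- dlc_params(beta = c(`1` = beta, `2` = 0), alpha0 = 0,
                       gamma = c(log_rt = 0), var_theta = 1e-8)
  fit <- structure(list(spec = spec, params = params, n_nodes = 15),
                   class = "dlc_fit")
  post <- posterior_class_prob(fit, data)
  expect_equal(post$p_solution, 0.8 * 0.5 / (0.8 * 0.5 + 0.25 * 0.5),
               tolerance = 1e-9)
  expect_identical(post$hard_class, 1L)
})

test_that("fit refitted from its own optimum is stationary and reproducible", {
  cfg0 <- sim_config("recovery", n_persons = 120, seed = 9)
  sim <- simulate_dataset(cfg0)
  spec <- dlc_spec("dlc", covariates = "log_rt")
  cfg <- fit_config(n_starts = 2, n_final = 2, seed = 5, se = FALSE)
  fit1 <- fit_dlc(spec, sim$data, cfg)
  expect_true(fit1$converged)
  fit2 <- fit_dlc(spec, sim$data, fit_config(n_starts = 1, seed = 5, se = FALSE),
                  start_params = fit1$params)
  expect_lt(abs(fit2$loglik - fit1$loglik), 1e-6)
  # determinism under identical seed and config
  fit3 <- fit_dlc(spec, sim$data, cfg)
  expect_identical(fit3$loglik, fit1$loglik)
  expect_identical(fit3$u, fit1$u)
  # FitResult invariants
  expect_equal(fit1$aic, -2 * fit1$loglik + 2 * fit1$n_free)
  expect_identical(fit1$n_free, count_parameters(spec, nrow(sim$data$bank)))
})

test_that("compare_models lines up counts, criteria and LR columns", {
  data <- toy_data(seed = 55, n = 50, J = 4)
  cfg <- fit_config(n_starts = 1, seed = 2, se = FALSE)
  f1 <- fit_dlc(dlc_spec("rasch"), data, cfg)
  f2 <- fit_dlc(dlc_spec("dlc", covariates = "log_rt"), data, cfg)
  tab <- compare_models(list(f1, f2), names = c("rasch", "dlc"))
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$df[2], f2$n_free - f1$n_free)
  expect_equal(tab$aic, c(f1$aic, f2$aic))
  expect_true(is.na(tab$delta_dev[1]))
  # a single fit yields one row without LR columns filled
  tab1 <- compare_models(list(f1))
  expect_identical(nrow(tab1), 1L)
  expect_true(is.na(tab1$p_value))
  # differing data are rejected
  dataB <- toy_data(seed = 56, n = 50, J = 4)
  f3 <- fit_dlc(dlc_spec("rasch"), dataB, cfg)
  expect_error(compare_models(list(f1, f3)), "identical data")
})

test_that("spec, params and fit serializations round-trip", {
  spec <- spec_menu("dlc-tl-ext-int")
  tf <- tempfile(fileext = ".json")
  write_spec_json(spec, tf)
  expect_identical(read_spec_json(tf), spec)

  params <- dlc_params(beta = c(a = -1, b = 0.5), alpha0 = 1.2,
                       alpha_item = c(a = -0.3), gamma = c(log_rt = 1),
                       var_theta = 1.4, sigma2_psi = 0.7, cov_psi_theta = 0.2)
  write_params_json(params, tf)
  p2 <- read_params_json(tf)
  expect_equal(p2$beta, params$beta)
  expect_equal(p2$cov_psi_theta, params$cov_psi_theta)

  data <- toy_data(seed = 60, n = 30, J = 3)
  fit <- fit_dlc(dlc_spec("dlc", covariates = "log_rt"), data,
                 fit_config(n_starts = 1, seed = 4, se = FALSE))
  write_fit_json(fit, tf)
  f2 <- read_fit_json(tf)
  expect_equal(f2$loglik, fit$loglik)
  expect_identical(f2$spec, fit$spec)
  expect_equal(f2$u, unname(fit$u))
  expect_identical(f2$data_hash, fit$data_hash)
  # reloaded fit supports classification
  post <- posterior_class_prob(f2, data)
  expect_true(all(post$p_solution >= 0 & post$p_solution <= 1))
})

test_that("the sensitivity variant with a freed guessing probability recovers z", {
  # a world with substantial disengagement so z is well identified
  p <- dlc_params(beta = setNames(seq(-1.5, 1.5, length.out = 14),
                                  as.character(1:14)),
                  alpha0 = -0.5,
                  alpha_item = setNames(rep(0, 6), c("1", "2", "3", "7", "11", "14")),
                  gamma = c(log_rt = 1, ac = 0, tr = -0.8, iv = 0),
                  var_theta = 1, sigma2_psi = 1, cov_psi_theta = 0.5)
  cfg <- sim_config("recovery", n_persons = 800, seed = 5, params = p)
  sim <- simulate_dataset(cfg)
  spec <- dlc_spec("dlc", covariates = "log_rt", z_mode = "equal_free")
  f <- fit_dlc(spec, sim$data, fit_config(n_starts = 2, n_final = 1, seed = 5))
  expect_true(f$converged)
  expect_identical(f$n_free, 18L)
  expect_lt(abs(f$params$z_free - 0.25), 3 * f$se[["z_free"]] + 0.02)
})

test_that("degenerate engagement prior drives all posteriors to solution", {
  data <- toy_data(seed = 61, n = 20, J = 3)
  spec <- dlc_spec("dlc", covariates = "log_rt")
  params <- dlc_params(beta = stats::setNames(data$bank$beta, data$bank$item_id),
                       alpha0 = 30, gamma = c(log_rt = 0), var_theta = 1)
  fit <- structure(list(spec = spec, params = params, n_nodes = 15),
                   class = "dlc_fit")
  post <- posterior_class_prob(fit, data)
  expect_true(all(post$p_solution > 0.999))
})
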