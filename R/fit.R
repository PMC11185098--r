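#' Estimation configuration
#'
#' @param n_starts number of random starts (start 1 is the unjittered
#'   neutral start; the rest are jittered with the run seed).
#' @param n_final number of best stage-1 starts polished to tight tolerance.
#' @param n_nodes quadrature nodes per latent dimension.
#' @param seed integer seed governing start jitter; mandatory for
#'   reproducibility.
#' @param jitter standard deviation of the start jitter on the unconstrained
#'   scale.
#' @param screen_nodes coarser node count used only to screen the random
#'   starts cheaply; the retained starts are polished (and all reported
#'   quantities computed) on the full `n_nodes` grid.
#' @param stage1_iter optimizer iteration cap for the screening stage.
#' @param final_iter iteration cap for the polishing stage.
#' @param se compute standard errors (numerically differentiated observed
#'   information plus delta method)?
#' @return list of class `dlc_config`.
#' @export
fit_config <- function(n_starts = 20, n_final = 5, n_nodes = 15, seed = 1,
                       jitter = 0.3, screen_nodes = 7, stage1_iter = 200,
                       final_iter = 1000, se = TRUE) {
  stopifnot(n_starts >= 1, n_final >= 1, n_nodes >= 5, screen_nodes >= 5)
  structure(list(n_starts = as.integer(n_starts),
                 n_final = as.integer(min(n_final, n_starts)),
                 n_nodes = as.integer(n_nodes), seed = as.integer(seed),
                 jitter = jitter,
                 screen_nodes = as.integer(min(screen_nodes, n_nodes)),
                 stage1_iter = as.integer(stage1_iter),
                 final_iter = as.integer(final_iter), se = isTRUE(se)),
            class = "dlc_config")
}

# split the packed unconstrained vector into the C++ kernel's arguments
mll_kernel <- function(spec, u, md, grid, want_grad = FALSE) {
  J <- length(md$item_ids)
  vt_free <- spec$theta_variance_mode == "free"
  has_mix <- spec$family != "rasch"
  has_psi <- spec$family == "dlc_tl"
  zfree <- spec$z_mode == "equal_free"
  pos <- J
  lvt <- if (vt_free) { pos <- pos + 1L; u[pos] } else 0
  K <- if (has_mix) ncol(md$X) else 0L
  coefs <- if (has_mix) u[pos + seq_len(K)] else numeric()
  pos <- pos + K
  lsig <- 0; zrho <- 0
  if (has_psi) { lsig <- u[pos + 1L]; zrho <- u[pos + 2L]; pos <- pos + 2L }
  lz <- if (zfree) { pos <- pos + 1L; u[pos] } else 0
  stopifnot(pos == length(u))
  dlc_mll_cpp(beta = u[seq_len(J)], lvt = lvt, vt_free = vt_free,
              vt_fixed = 1, coefs = coefs, has_mix = has_mix,
              has_psi = has_psi, lsig = lsig, zrho = zrho,
              zfree = zfree, lz = lz,
              pidx = md$pidx, jidx = md$jidx, y = md$y,
              zvec = md$zvec, X = md$X,
              u1 = grid$u1, w1 = grid$w1,
              u2 = grid$u2 %||% numeric(), w2 = grid$w2 %||% numeric(),
              want_grad = want_grad)
}

# neutral starting values on the natural scale
start_params_default <- function(spec, md, bank) {
  ag <- rowsum(md$y, md$jidx)
  n <- rowsum(rep(1L, length(md$y)), md$jidx)
  p <- (ag + 0.5) / (n + 1)
  beta <- rep(0, length(md$item_ids)); names(beta) <- md$item_ids
  beta[as.integer(rownames(ag)) + 1L] <- -stats::qlogis(as.numeric(p))
  gamma <- rep(0, length(spec$covariates)); names(gamma) <- spec$covariates
  if ("log_rt" %in% spec$covariates) gamma[["log_rt"]] <- 1
  gi <- rep(0, length(spec$interactions)); names(gi) <- spec$interactions
  ai <- rep(0, length(spec$intercept_items)); names(ai) <- spec$intercept_items
  dlc_params(beta = beta,
             alpha0 = if (spec$family != "rasch") 2 else NULL,
             alpha_item = ai, gamma = gamma, gamma_int = gi,
             var_theta = 1,
             sigma2_psi = if (spec$family == "dlc_tl") 0.5 else 0,
             cov_psi_theta = 0,
             z_free = if (spec$z_mode == "equal_free") 0.25 else NULL)
}

#' Fit a DLC-IRT model by marginal maximum likelihood
#'
#' Maximizes the Gauss-Hermite-approximated marginal likelihood over an
#' unconstrained reparameterization (variances via log, the psi-theta
#' correlation via atanh, a free guessing probability via logit) with a
#' multi-start strategy: `n_starts` jittered starts are screened with a
#' capped optimizer run and the best `n_final` are polished to tight
#' tolerance. Standard errors come from the numerically differentiated
#' observed information with a delta-method transform back to the natural
#' scale.
#'
#' @param spec a [dlc_spec()].
#' @param data a [dlc_data()] with at least 2 items and 2 persons carrying
#'   valid encounters.
#' @param config a [fit_config()].
#' @param start_params optional [dlc_params()] used as the first start
#'   (replacing the neutral default, e.g. for warm starts).
#' @return object of class `dlc_fit` with the maximized log-likelihood,
#'   estimates and SEs, information criteria, entropy, and convergence
#'   diagnostics.
#' @export
fit_dlc <- function(spec, data, config = fit_config(), start_params = NULL) {
  stopifnot(inherits(spec, "dlc_spec"), inherits(data, "dlc_data"),
            inherits(config, "dlc_config"))
  md <- build_model_data(spec, data)
  if (length(md$item_ids) < 2 || md$n_persons < 2)
    stop("need >= 2 items and >= 2 persons with valid encounters",
         call. = FALSE)
  dim <- if (spec$family == "dlc_tl") 2 else 1
  grid <- quad_grid(config$n_nodes, dim)
  grid_screen <- quad_grid(config$screen_nodes, dim)

  sp <- if (is.null(start_params)) start_params_default(spec, md, data$bank)
        else start_params
  u0 <- pack_params(spec, sp, md$item_ids)

  starts <- list(u0)
  if (config$n_starts > 1) {
    starts <- c(starts, with_seed(config$seed, {
      lapply(seq_len(config$n_starts - 1L), function(s)
        u0 + stats::rnorm(length(u0), sd = config$jitter))
    }))
  }

  memo <- new.env(parent = emptyenv())
  run1 <- function(u, iter, g) {
    memo$u <- NULL; memo$grad <- NULL
    evalk <- function(uu, want_grad) {
      if (!is.null(memo$u) && identical(memo$u, uu) &&
          (!want_grad || !is.null(memo$grad))) {
        return(list(loglik = memo$val, grad = memo$grad))
      }
      r <- mll_kernel(spec, uu, md, g, want_grad = want_grad)
      memo$u <- uu; memo$val <- r$loglik; memo$grad <- r$grad
      r
    }
    objfn <- function(uu) {
      v <- evalk(uu, want_grad = FALSE)$loglik
      if (!is.finite(v)) return(1e12)
      -v
    }
    grfn <- function(uu) {
      r <- evalk(uu, want_grad = TRUE)
      if (!is.finite(r$loglik) || is.null(r$grad)) return(rep(0, length(uu)))
      -r$grad
    }
    tryCatch(stats::nlminb(u, objfn, grfn,
                           control = list(iter.max = iter, eval.max = 4 * iter,
                                          rel.tol = 1e-10)),
             error = function(e) list(objective = Inf, par = u,
                                      convergence = 1L, message = conditionMessage(e)))
  }

  stage1 <- lapply(starts, run1, iter = config$stage1_iter, g = grid_screen)
  ord <- order(vapply(stage1, `[[`, numeric(1), "objective"))
  top <- ord[seq_len(min(config$n_final, length(ord)))]
  polished <- lapply(top, function(i)
    run1(stage1[[i]]$par, config$final_iter, g = grid))
  lls <- -vapply(polished, `[[`, numeric(1), "objective")
  if (!any(is.finite(lls)))
    stop("estimation failed: no start reached a finite likelihood",
         call. = FALSE)
  best <- polished[[which.max(lls)]]
  replicated <- if (length(lls) >= 2) {
    s <- sort(lls, decreasing = TRUE); (s[1] - s[2]) < 0.01
  } else NA
  u_hat <- best$par
  ll <- -best$objective
  converged <- identical(best$convergence, 0L)

  params <- unpack_params(spec, u_hat, md$item_ids)
  n_free <- count_parameters(spec, length(md$item_ids))
  stopifnot(n_free == length(u_hat))
  ic <- information_criteria(ll, n_free, md$n_persons)

  se <- rep(NA_real_, n_free)
  if (config$se) {
    H <- grad_hessian(function(u) {
      r <- mll_kernel(spec, u, md, grid, want_grad = TRUE)
      r$grad
    }, u_hat)
    Vu <- tryCatch(solve(-(H + t(H)) / 2), error = function(e) NULL)
    if (!is.null(Vu)) {
      Jac <- par_jacobian(spec, u_hat, md$item_ids)
      Vn <- Jac %*% Vu %*% t(Jac)
      v <- diag(Vn)
      se <- ifelse(v > 0, sqrt(v), NA_real_)
    }
  }
  names(se) <- natural_par_names(spec, md$item_ids)

  fit <- structure(list(spec = spec, params = params, se = se,
                        loglik = ll, n_free = n_free,
                        n_persons = md$n_persons,
                        n_valid_encounters = md$n_valid,
                        aic = ic[["aic"]], bic = ic[["bic"]],
                        abic = ic[["abic"]],
                        entropy = NA_real_, converged = converged,
                        n_starts_used = config$n_starts,
                        best_ll_replicated = replicated,
                        seed = config$seed, n_nodes = config$n_nodes,
                        data_hash = data_hash(data), u = u_hat),
                   class = "dlc_fit")
  if (spec$family != "rasch") {
    post <- posterior_class_prob(fit, data)
    fit$entropy <- entropy(post)
  }
  fit
}

# Hessian of the log-likelihood by central differences of the analytic
# gradient.
grad_hessian <- function(gradfun, u, h = 1e-4) {
  n <- length(u)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    hi <- h * (1 + abs(u[i]))
    up <- u; up[i] <- up[i] + hi
    um <- u; um[i] <- um[i] - hi
    H[, i] <- (gradfun(up) - gradfun(um)) / (2 * hi)
  }
  (H + t(H)) / 2
}

#' Information criteria
#'
#' `AIC = -2 LL + 2k`, `BIC = -2 LL + k log(N)`,
#' `aBIC = -2 LL + k log((N + 2) / 24)`, with `N` the number of persons
#' (the independent sampling units of the marginal likelihood).
#'
#' @param loglik maximized log-likelihood.
#' @param n_free number of free parameters.
#' @param n_persons number of persons (>= 1).
#' @return named numeric vector `c(aic, bic, abic)`.
#' @export
information_criteria <- function(loglik, n_free, n_persons) {
  stopifnot(n_persons >= 1)
  c(aic = -2 * loglik + 2 * n_free,
    bic = -2 * loglik + n_free * log(n_persons),
    abic = -2 * loglik + n_free * log((n_persons + 2) / 24))
}

#' Likelihood-ratio test between nested fits
#'
#' @param nested,full `dlc_fit` objects on the same data; `nested$spec` must
#'   be a structural restriction of `full$spec`.
#' @return list of class `dlc_lrt` with `delta_dev` (clipped at 0), `df`, and
#'   the upper-tail chi-square `p_value`. The chi-square reference is used
#'   even for boundary variance components (anti-conservative there).
#' @export
lr_test <- function(nested, full) {
  stopifnot(inherits(nested, "dlc_fit"), inherits(full, "dlc_fit"))
  if (!identical(nested$data_hash, full$data_hash))
    stop("fits are not on identical data", call. = FALSE)
  if (!spec_is_nested(nested$spec, full$spec))
    stop("specs are not nested", call. = FALSE)
  df <- full$n_free - nested$n_free
  if (df < 1) stop("full model has no additional parameters", call. = FALSE)
  delta <- max(2 * (full$loglik - nested$loglik), 0)
  structure(list(delta_dev = delta, df = df,
                 p_value = stats::pchisq(delta, df, lower.tail = FALSE)),
            class = "dlc_lrt")
}

#' @export
print.dlc_lrt <- function(x, ...) {
  cat(sprintf("LR test: delta deviance = %.3f, df = %d, p = %.4g\n",
              x$delta_dev, x$df, x$p_value))
  invisible(x)
}

#' Sequential selection of item-specific engagement intercepts
#'
#' Fits the common-intercept DLC-IRT base model, then for each item a model
#' augmented with that single item's engagement intercept (warm-started from
#' the base estimates), and retains the items whose augmentation improves the
#' base by a likelihood-ratio test at level `alpha` (df = 1). Each candidate
#' is tested independently against the same base fit.
#'
#' @param data a [dlc_data()].
#' @param config a [fit_config()].
#' @param alpha significance level of the per-item test.
#' @param covariates covariates of the engagement regression.
#' @return list with `items` (retained ids), `base_fit`, and `tests`
#'   (per-item data frame of delta deviance and p values).
#' @export
select_item_intercepts <- function(data, config = fit_config(), alpha = 0.05,
                                   covariates = "log_rt") {
  base_spec <- dlc_spec("dlc", covariates = covariates)
  base_fit <- fit_dlc(base_spec, data, config)
  cfg1 <- config
  cfg1$n_starts <- 1L
  cfg1$n_final <- 1L
  items <- data$bank$item_id
  warm <- base_fit$params
  res <- lapply(items, function(it) {
    sp <- dlc_spec("dlc_sl", intercept_items = it, covariates = covariates)
    w <- warm
    w$alpha_item <- stats::setNames(0, it)
    f <- fit_dlc(sp, data, cfg1, start_params = w)
    t <- lr_test(base_fit, f)
    data.frame(item_id = it, delta_dev = t$delta_dev, df = t$df,
               p_value = t$p_value, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, res)
  list(items = tests$item_id[tests$p_value < alpha],
       base_fit = base_fit, tests = tests)
}

#' Model comparison table
#'
#' One row per fit, in the given order, with parameter counts, information
#' criteria, entropy, and the likelihood-ratio test against the preceding
#' row where that row's spec is nested in the current one.
#'
#' @param fits list of `dlc_fit` objects on identical data.
#' @param names optional row labels.
#' @return data frame.
#' @export
compare_models <- function(fits, names = NULL) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "dlc_fit")))
  hashes <- vapply(fits, `[[`, character(1), "data_hash")
  if (length(unique(hashes)) != 1)
    stop("fits were not produced on identical data", call. = FALSE)
  if (is.null(names)) names <- paste0("model", seq_along(fits))
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    row <- data.frame(model = names[i], n_par = f$n_free,
                      loglik = f$loglik, aic = f$aic, bic = f$bic,
                      abic = f$abic, entropy = f$entropy,
                      delta_dev = NA_real_, df = NA_integer_,
                      p_value = NA_real_, stringsAsFactors = FALSE)
    if (i > 1 && spec_is_nested(fits[[i - 1]]$spec, f$spec)) {
      t <- lr_test(fits[[i - 1]], f)
      row$delta_dev <- t$delta_dev; row$df <- t$df; row$p_value <- t$p_value
    }
    row
  })
  do.call(rbind, rows)
}

#' @export
print.dlc_fit <- function(x, ...) {
  cat("DLC-IRT fit (", x$spec$family, ")\n", sep = "")
  cat(sprintf("  log-likelihood %.3f on %d parameters (%d persons, %d encounters)\n",
              x$loglik, x$n_free, x$n_persons, x$n_valid_encounters))
  cat(sprintf("  AIC %.1f  BIC %.1f  aBIC %.1f", x$aic, x$bic, x$abic))
  if (is.finite(x$entropy)) cat(sprintf("  entropy %.3f", x$entropy))
  cat("\n")
  cat(sprintf("  converged: %s  best LL replicated: %s (starts: %d, seed: %d)\n",
              x$converged, x$best_ll_replicated, x$n_starts_used, x$seed))
  invisible(x)
}

#' Coefficient table of a fit
#'
#' Estimates, standard errors, Wald `t = estimate/SE` and two-sided normal
#' p-values for every free parameter on the natural scale.
#'
#' @param object a `dlc_fit`.
#' @param ... unused.
#' @return data frame with columns `parameter`, `estimate`, `se`, `t`, `p`.
#' @export
coef_table <- function(object, ...) {
  stopifnot(inherits(object, "dlc_fit"))
  md_names <- names(object$se)
  est <- natural_par_vector(object$spec, object$params, md_names)
  t <- est / object$se
  data.frame(parameter = md_names, estimate = est, se = unname(object$se),
             t = unname(t),
             p = unname(2 * stats::pnorm(-abs(t))),
             stringsAsFactors = FALSE, row.names = NULL)
}

natural_par_vector <- function(spec, params, nat_names) {
  out <- numeric(length(nat_names))
  for (i in seq_along(nat_names)) {
    nm <- nat_names[i]
    out[i] <- if (startsWith(nm, "beta:")) {
      params$beta[[sub("^beta:", "", nm)]]
    } else if (nm == "var_theta") params$var_theta
    else if (nm == "alpha0") params$alpha0
    else if (startsWith(nm, "alpha_item:"))
      params$alpha_item[[sub("^alpha_item:", "", nm)]]
    else if (startsWith(nm, "gamma:")) params$gamma[[sub("^gamma:", "", nm)]]
    else if (startsWith(nm, "gamma_int:"))
      params$gamma_int[[sub("^gamma_int:", "", nm)]]
    else if (nm == "sigma2_psi") params$sigma2_psi
    else if (nm == "cov_psi_theta") params$cov_psi_theta
    else if (nm == "z_free") params$z_free
    else NA_real_
  }
  out
}

#' Serialize / deserialize a fit as JSON
#'
#' Contains the spec, estimates and SEs, fit indices, the convergence block
#' and the seed; round-trippable up to numerical formatting.
#'
#' @param fit a `dlc_fit`.
#' @param path file path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "dlc_fit"))
  pl <- unclass(fit$params)
  pl$beta <- as.list(pl$beta); pl$alpha_item <- as.list(pl$alpha_item)
  pl$gamma <- as.list(pl$gamma); pl$gamma_int <- as.list(pl$gamma_int)
  x <- list(spec = unclass(fit$spec), params = pl,
            se = as.list(fit$se), loglik = fit$loglik, n_free = fit$n_free,
            n_persons = fit$n_persons,
            n_valid_encounters = fit$n_valid_encounters,
            aic = fit$aic, bic = fit$bic, abic = fit$abic,
            entropy = fit$entropy,
            convergence = list(converged = fit$converged,
                               n_starts_used = fit$n_starts_used,
                               best_ll_replicated = fit$best_ll_replicated,
                               n_nodes = fit$n_nodes),
            seed = fit$seed, data_hash = fit$data_hash, u = fit$u)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- dlc_spec(family = x$spec$family,
                   intercept_items = x$spec$intercept_items %||% character(),
                   covariates = x$spec$covariates %||% character(),
                   interactions = x$spec$interactions %||% character(),
                   z_mode = x$spec$z_mode, theta_variance_mode = x$spec$theta_variance_mode)
  as_named <- function(v) if (is.null(v) || !length(v)) numeric() else unlist(v)
  params <- dlc_params(beta = as_named(x$params$beta), alpha0 = x$params$alpha0,
                       alpha_item = as_named(x$params$alpha_item),
                       gamma = as_named(x$params$gamma),
                       gamma_int = as_named(x$params$gamma_int),
                       var_theta = x$params$var_theta,
                       sigma2_psi = x$params$sigma2_psi,
                       cov_psi_theta = x$params$cov_psi_theta,
                       z_free = x$params$z_free)
  structure(list(spec = spec, params = params, se = unlist(x$se),
                 loglik = x$loglik, n_free = x$n_free,
                 n_persons = x$n_persons,
                 n_valid_encounters = x$n_valid_encounters,
                 aic = x$aic, bic = x$bic, abic = x$abic,
                 entropy = x$entropy,
                 converged = x$convergence$converged,
                 n_starts_used = x$convergence$n_starts_used,
                 best_ll_replicated = x$convergence$best_ll_replicated,
                 n_nodes = x$convergence$n_nodes,
                 seed = x$seed, data_hash = x$data_hash, u = unlist(x$u)),
            class = "dlc_fit")
}

# evaluate set.seed(code) without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
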